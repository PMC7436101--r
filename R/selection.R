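#' @name selection
#' @title Stage 1: per-patient statistical screening (lambda)
#' @description
#' For every feature and every patient with both apnea and normal minutes,
#' the apnea and normal feature values are compared twice: a one-way
#' two-group ANOVA and a Wilcoxon rank-sum test. A (feature, patient) pair
#' is *positive* when the ANOVA p-value is below alpha and the rank-sum test
#' rejects at alpha. `lambda` counts positive pairs per feature across the
#' contributing patients (nu); features with `lambda >= 1` are selected and
#' stratified into classes A (lambda = nu) through E (lambda = nu - 4).
NULL

#' One-way two-group ANOVA
#'
#' Computed from sums of squares: F = (SSG/df_group) / (SSE/df_error) with
#' df_group = 1 and df_error = n1 + n2 - 2; the p-value is the upper tail of
#' the F distribution.
#'
#' @param group_a,group_n numeric values of the two groups (each >= 2)
#' @return list with `F`, `p`, `df_group`, `df_error`
#' @export
#' @examples
#' anova_p(c(1, 2), c(3, 4))$F  # 8
anova_p <- function(group_a, group_n) {
  n1 <- length(group_a)
  n2 <- length(group_n)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 values")
  m1 <- mean(group_a)
  m2 <- mean(group_n)
  gm <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ssg <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  sse <- sum((group_a - m1)^2) + sum((group_n - m2)^2)
  df_e <- n1 + n2 - 2L
  if (sse == 0) {
    if (ssg == 0) {
      return(list(F = 0, p = 1, df_group = 1L, df_error = df_e))
    }
    log_msg("anova_p: zero within-group variance with unequal means")
    return(list(F = Inf, p = 0, df_group = 1L, df_error = df_e))
  }
  f <- ssg / (sse / df_e)
  list(F = f, p = stats::pf(f, 1, df_e, lower.tail = FALSE),
       df_group = 1L, df_error = df_e)
}

#' Wilcoxon rank-sum test with a rejection decision
#'
#' Ranks the pooled observations (mid-ranks for ties) and computes the
#' Mann-Whitney U. The null is exact (via the U distribution) when
#' `min(n1, n2) <= exact_max` and there are no ties; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param group_a,group_n numeric values (non-empty)
#' @param alpha rejection level (default 0.05)
#' @param exact_max largest min-group size for the exact branch
#' @return list with `p`, `reject`, `u` (min of the two U statistics)
#' @export
ranksum_decision <- function(group_a, group_n, alpha = 0.05,
                             exact_max = 10L) {
  n1 <- length(group_a)
  n2 <- length(group_n)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  z <- c(group_a, group_n)
  r <- rank(z)
  w1 <- sum(r[seq_len(n1)])
  u1 <- w1 - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  ties <- anyDuplicated(z) > 0L
  if (min(n1, n2) <= exact_max && !ties) {
    p <- min(1, 2 * stats::pwilcox(u, n1, n2))
  } else {
    nt <- n1 + n2
    tab <- table(z)
    tie_term <- sum(tab^3 - tab) / (nt * (nt - 1))
    sigma2 <- n1 * n2 / 12 * ((nt + 1) - tie_term)
    mu <- n1 * n2 / 2
    zstat <- u1 - mu
    p <- if (sigma2 <= 0) 1 else {
      min(1, 2 * stats::pnorm(abs(zstat) - 0.5, 0, sqrt(sigma2),
                              lower.tail = FALSE))
    }
  }
  list(p = p, reject = p < alpha, u = u)
}

#' Run both screening tests on one (feature, patient) pair
#' @inheritParams ranksum_decision
#' @param config pipeline configuration
#' @return list with the ANOVA and rank-sum results and `positive`
#' @export
stat_test_pair <- function(group_a, group_n, config = default_config()) {
  alpha <- config$selection$alpha
  an <- anova_p(group_a, group_n)
  rs <- ranksum_decision(group_a, group_n, alpha,
                         config$selection$exact_max)
  list(p_anova = an$p, F = an$F, df_group = an$df_group,
       df_error = an$df_error, p_ranksum = rs$p, ranksum_reject = rs$reject,
       positive = (an$p < alpha) && rs$reject)
}

#' Count positive pairs per feature across patients (lambda)
#'
#' Only patients possessing both apnea and normal epochs contribute test
#' pairs; the number of such patients is `nu`. A feature that is entirely
#' missing (or lacks two values per group) for a contributing patient skips
#' that pair — `nu` still counts the patient.
#'
#' @param feature_table a feature table from [extract_features_cohort()]
#'   (columns `record_id`, `label`, and feature columns)
#' @param feature_cols feature column names (default: registry ids present)
#' @param config pipeline configuration
#' @return an object of class `selection_result`: list with `lambda` (named
#'   integer vector), `nu`, `selected`, `class_of` (after
#'   [assign_classes()]), and `pairs` (per-patient p-value table)
#' @export
lambda_counts <- function(feature_table,
                          feature_cols = intersect(feature_registry()$id,
                                                   names(feature_table)),
                          config = default_config()) {
  pts <- unique(feature_table$record_id)
  contributing <- pts[vapply(pts, function(p) {
    lab <- feature_table$label[feature_table$record_id == p]
    all(c("A", "N") %in% lab)
  }, logical(1))]
  skipped <- setdiff(pts, contributing)
  if (length(skipped)) {
    log_msg("lambda_counts: ", length(skipped),
            " patient(s) without both labels skipped: ",
            paste(skipped, collapse = ", "))
  }
  nu <- length(contributing)
  lambda <- setNames(integer(length(feature_cols)), feature_cols)
  pair_rows <- list()
  for (p in contributing) {
    sub <- feature_table[feature_table$record_id == p, ]
    is_a <- sub$label == "A"
    for (f in feature_cols) {
      va <- sub[[f]][is_a]
      vn <- sub[[f]][!is_a]
      va <- va[is.finite(va)]
      vn <- vn[is.finite(vn)]
      if (length(va) < 2L || length(vn) < 2L) {
        log_msg("lambda_counts: pair (", f, ", ", p,
                ") skipped, too few finite values")
        next
      }
      res <- stat_test_pair(va, vn, config)
      lambda[f] <- lambda[f] + as.integer(res$positive)
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        feature = f, patient = p, p_anova = res$p_anova,
        p_ranksum = res$p_ranksum, positive = res$positive,
        stringsAsFactors = FALSE
      )
    }
  }
  sr <- structure(
    list(lambda = lambda, nu = nu,
         selected = names(lambda)[lambda >= 1L],
         class_of = NULL,
         pairs = do.call(rbind, pair_rows)),
    class = "selection_result"
  )
  assign_classes(sr)
}

#' Stratify features into classes A-E from lambda
#'
#' Class A holds features with `lambda = nu`, B with `nu - 1`, down to E
#' with `nu - 4`; features with `lambda = 0` (or below `nu - 4`) are
#' unselected (`NONE`).
#'
#' @param sr a `selection_result` (or a named lambda vector via
#'   `lambda_classes()`)
#' @return the `selection_result` with `class_of` filled in
#' @export
assign_classes <- function(sr) {
  sr$class_of <- lambda_classes(sr$lambda, sr$nu)
  sr
}

#' Map lambda values to class labels
#' @param lambda named integer vector
#' @param nu number of contributing patients
#' @return named character vector over `{A, B, C, D, E, NONE}`
#' @export
lambda_classes <- function(lambda, nu) {
  cls <- rep("NONE", length(lambda))
  for (i in 0:4) {
    lv <- nu - i
    if (lv >= 1L) cls[lambda == lv] <- LETTERS[i + 1L]
  }
  setNames(cls, names(lambda))
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> nu =", x$nu, "patients;",
      length(x$selected), "of", length(x$lambda),
      "features selected (lambda >= 1)\n")
  tab <- table(factor(x$class_of, levels = c(LETTERS[1:5], "NONE")))
  print(tab)
  invisible(x)
}

#' Apply the selection rule to a printed lambda column
#'
#' Applies the `lambda >= 1` selection rule and the class partition (with
#' `nu = 5`) to a vector of 87 published lambda values — by default the
#' bundled [reference_lambda()] table.
#'
#' @param lambdas 87 lambda values (default: the bundled fixture)
#' @param nu number of contributing patients the column was computed with
#' @return list with `n_selected`, `selected_no` (feature numbers),
#'   `class_of` (named by feature number), `class_sizes`, and
#'   `class_members` (list of feature-number vectors)
#' @export
#' @examples
#' sel <- select_from_printed_lambda()
#' sel$n_selected        # 66
#' sel$class_members$A   # 2 47 64 66 77
select_from_printed_lambda <- function(lambdas = NULL, nu = 5L) {
  if (is.null(lambdas)) {
    ref <- reference_lambda()
    lambdas <- setNames(ref$lambda, ref$no)
  }
  if (is.null(names(lambdas))) names(lambdas) <- seq_along(lambdas)
  cls <- lambda_classes(lambdas, nu)
  members <- lapply(setNames(nm = LETTERS[1:5]), function(cl) {
    as.integer(names(cls)[cls == cl])
  })
  list(
    n_selected = sum(lambdas >= 1L),
    selected_no = as.integer(names(lambdas)[lambdas >= 1L]),
    class_of = cls,
    class_sizes = vapply(members, length, integer(1)),
    class_members = members
  )
}

#' Write a selection report as CSV
#' @param sr a `selection_result`
#' @param path output CSV
#' @return invisibly, `path`
#' @export
write_selection_report <- function(sr, path) {
  reg <- feature_registry()
  idx <- match(names(sr$lambda), reg$id)
  df <- data.frame(
    no = reg$no[idx], channel = reg$channel[idx], feature = names(sr$lambda),
    lambda = as.integer(sr$lambda), class = sr$class_of,
    stringsAsFactors = FALSE
  )
  if (!is.null(sr$pairs)) {
    wide <- stats::reshape(
      sr$pairs[, c("feature", "patient", "p_anova", "p_ranksum")],
      idvar = "feature", timevar = "patient", direction = "wide"
    )
    df <- merge(df, wide, by = "feature", all.x = TRUE, sort = FALSE)
    df <- df[order(df$no), ]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
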