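test_that("the ANOVA F and p follow the sums-of-squares construction", {
  r <- anova_p(c(1, 2), c(3, 4))
  expect_equal(r$F, 8)            # SSG = 4, SSE = 1, df = (1, 2)
  expect_equal(r$df_group, 1L)
  expect_equal(r$df_error, 2L)
  expect_equal(r$p, pf(8, 1, 2, lower.tail = FALSE))
  same <- anova_p(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  # degenerate: separated constants
  sep <- anova_p(c(2, 2), c(5, 5))
  expect_equal(sep$p, 0)
  # all identical
  expect_equal(anova_p(c(4, 4), c(4, 4))$p, 1)
})

test_that("the ANOVA agrees with the linear-model reference on random data", {
  set.seed(19)
  for (i in 1:100) {
    a <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 3))
    n <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1))
    mine <- anova_p(a, n)
    ref <- anova(lm(y ~ g, data.frame(y = c(a, n),
                                      g = rep(c("A", "N"), c(length(a),
                                                             length(n))))))
    expect_equal(mine$F, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("the exact rank-sum p matches full enumeration", {
  # complete separation at n1 = n2 = 3: exact two-sided p = 0.1
  r <- ranksum_decision(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$p, 0.1)
  expect_false(r$reject)
  # enumeration oracle over all C(6,3) rank assignments
  ranks <- 1:6
  u_obs <- r$u
  all_u <- apply(combn(6, 3), 2, function(ix) {
    w <- sum(ranks[ix])
    u1 <- w - 6
    min(u1, 9 - u1)
  })
  p_enum <- mean(all_u <= u_obs)   # two-sided by min-U symmetry
  expect_equal(r$p, p_enum)
  # identical small groups never reject
  expect_false(ranksum_decision(c(1, 2, 3), c(1, 2, 3))$reject)
})

test_that("both rank-sum branches agree with the reference test", {
  set.seed(20)
  for (i in 1:50) {
    a <- rnorm(10)
    n <- rnorm(10, mean = runif(1, 0, 1.5))
    mine <- ranksum_decision(a, n)                    # exact branch
    ref <- wilcox.test(a, n, exact = TRUE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    approx <- ranksum_decision(a, n, exact_max = 0L)  # forced approximation
    refa <- wilcox.test(a, n, exact = FALSE, correct = TRUE)
    expect_equal(approx$p, refa$p.value, tolerance = 1e-12)
    expect_lt(abs(mine$p - approx$p), 0.02)
  }
  # ties route to the corrected normal approximation
  a <- c(1, 2, 2, 3, 5, 6, 7, 8, 9, 10)
  n <- c(2, 3, 3, 4, 6, 7, 8, 9, 10, 11)
  mine <- ranksum_decision(a, n)
  ref <- suppressWarnings(wilcox.test(a, n, correct = TRUE))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
})

test_that("lambda counts planted and null features correctly", {
  # a feature separated by 3 SDs reaches lambda = nu
  ft <- make_toy_feature_table(effect = 3, seed = 31)
  sr <- lambda_counts(ft, feature_cols = c("planted", paste0("noise", 1:5)))
  expect_equal(sr$nu, 5L)
  expect_equal(unname(sr$lambda["planted"]), 5L)
  expect_equal(unname(sr$class_of["planted"]), "A")
  # pure-noise features rarely accumulate lambda
  set.seed(32)
  null_lambdas <- unlist(lapply(1:20, function(s) {
    ftn <- make_toy_feature_table(effect = 0, n_noise = 4, seed = 100 + s,
                                  n_per = 60)
    srn <- lambda_counts(ftn, feature_cols = paste0("noise", 1:4))
    srn$lambda
  }))
  expect_gte(mean(null_lambdas <= 1), 0.95)
  expect_true(all(sr$lambda >= 0 & sr$lambda <= sr$nu))
})

test_that("patients without both labels are skipped (nu drops)", {
  ft <- make_toy_feature_table(seed = 33)
  ft$label[ft$record_id == "p03"] <- "N"
  sr <- lambda_counts(ft, feature_cols = c("planted", "noise1"))
  expect_equal(sr$nu, 4L)
  expect_equal(unname(sr$lambda["planted"]), 4L)
  expect_equal(unname(sr$class_of["planted"]), "A")
})

test_that("lambda is invariant to epoch order and patient relabeling", {
  ft <- make_toy_feature_table(n_patients = 3, n_per = 80, seed = 34)
  cols <- c("planted", "noise1")
  sr1 <- lambda_counts(ft, feature_cols = cols)
  set.seed(35)
  ft2 <- ft[sample(nrow(ft)), ]
  ft2$record_id <- chartr("p", "q", ft2$record_id)
  sr2 <- lambda_counts(ft2, feature_cols = cols)
  expect_equal(sr1$lambda, sr2$lambda)
})

test_that("classes map lambda relative to nu", {
  lam <- setNames(c(5L, 4L, 3L, 2L, 1L, 0L), paste0("f", 1:6))
  cls <- lambda_classes(lam, nu = 5L)
  expect_equal(unname(cls), c("A", "B", "C", "D", "E", "NONE"))
  # with nu = 4, lambda = 2 is class C
  expect_equal(unname(lambda_classes(c(x = 2L), nu = 4L)), "C")
  # lambda = 0 is never assigned a class
  expect_equal(unname(lambda_classes(c(x = 0L), nu = 2L)), "NONE")
})

test_that("the printed-lambda rule reproduces the published selection", {
  sel <- select_from_printed_lambda()
  expect_equal(sel$n_selected, 66L)
  expect_equal(sel$class_members$A, c(2L, 47L, 64L, 66L, 77L))
  expect_equal(select_from_printed_lambda(rep(0, 87))$n_selected, 0L)
})
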