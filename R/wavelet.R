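#' @name wavelet
#' @title Orthonormal discrete wavelet decomposition
#' @description
#' A periodized orthonormal DWT over the Daubechies/Symlet family used by the
#' feature extractors (db2, db3, db4, sym3; sym3 and db3 share coefficients,
#' as the minimum-phase and least-asymmetric constructions coincide for
#' 3 vanishing moments). Each analysis stage is a circular convolution with
#' the conjugate-quadrature filter pair followed by dyadic down-sampling;
#' odd-length stages are zero-padded to even length first, so energy is
#' conserved exactly (Parseval) at every depth.
NULL

# Orthonormal decomposition filter banks (low-pass, standard published
# coefficients; the high-pass is the conjugate quadrature mirror).
wt_dec_lo <- list(
  db2 = c(-0.12940952255126037, 0.22414386804201339,
          0.83651630373780790, 0.48296291314453416),
  db3 = c(0.03522629188570953, -0.08544127388202666, -0.13501102001025458,
          0.45987750211849154, 0.80689150931109257, 0.33267055295008263),
  db4 = c(-0.010597401785069032, 0.032883011666885169, 0.030841381835560764,
          -0.187034811719093084, -0.027983769416859854, 0.630880767929858908,
          0.714846570552915647, 0.230377813308896501)
)
wt_dec_lo$sym3 <- wt_dec_lo$db3

wt_filters <- function(wavelet) {
  lo <- wt_dec_lo[[wavelet]]
  if (is.null(lo)) {
    stop("unknown wavelet '", wavelet, "'; available: ",
         paste(names(wt_dec_lo), collapse = ", "))
  }
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1L)
  list(lo = lo, hi = hi, length = L)
}

# the periodized index matrices depend only on (n, L); cache them, as the
# extractor decomposes same-length epochs thousands of times
.dwt_idx_cache <- new.env(parent = emptyenv())
dwt_indices <- function(n, L) {
  key <- paste0(n, "_", L)
  idx <- .dwt_idx_cache[[key]]
  if (is.null(idx)) {
    starts <- seq(1L, n, by = 2L)
    idx <- outer(starts, 0:(L - 1L), function(i, j) ((i - j - 1L) %% n) + 1L)
    .dwt_idx_cache[[key]] <- idx
  }
  idx
}

dwt_step <- function(x, lo, hi) {
  n <- length(x)
  if (n %% 2L == 1L) {
    x <- c(x, 0)
    n <- n + 1L
  }
  L <- length(lo)
  xm <- matrix(x[dwt_indices(n, L)], nrow = n %/% 2L)
  list(a = drop(xm %*% lo), d = drop(xm %*% hi))
}

#' Maximum feasible decomposition depth
#'
#' Depth is limited by the filter support: a stage is taken only while the
#' current (even-padded) approximation is at least as long as the filter.
#'
#' @param n signal length
#' @param wavelet wavelet name
#' @return integer depth (possibly 0)
#' @export
wavedec_max_level <- function(n, wavelet) {
  L <- wt_filters(wavelet)$length
  lev <- 0L
  while (n >= L) {
    n <- (n + n %% 2L) %/% 2L
    lev <- lev + 1L
  }
  lev
}

#' Multi-level wavelet decomposition
#'
#' @param x numeric signal
#' @param wavelet one of "db2", "db3", "db4", "sym3"
#' @param level requested depth, or `NULL` for the maximum feasible depth.
#'   A request deeper than feasible is truncated (attribute
#'   `level_truncated`).
#' @return a list with `d` (list of detail coefficient vectors, `D1` =
#'   finest first), `a` (approximation at the final level), `level`, and
#'   `wavelet`
#' @export
#' @examples
#' w <- wavedec(sin(1:64), "db4", 3)
#' names(w$d)
wavedec <- function(x, wavelet, level = NULL) {
  f <- wt_filters(wavelet)
  max_lev <- wavedec_max_level(length(x), wavelet)
  lev <- if (is.null(level)) max_lev else min(as.integer(level), max_lev)
  truncated <- !is.null(level) && lev < level
  if (truncated) {
    log_msg("wavedec: depth ", level, " infeasible for n = ", length(x),
            " (", wavelet, "); decomposing to depth ", lev)
  }
  d <- vector("list", lev)
  a <- x
  for (j in seq_len(lev)) {
    st <- dwt_step(a, f$lo, f$hi)
    d[[j]] <- st$d
    a <- st$a
  }
  names(d) <- if (lev > 0) paste0("D", seq_len(lev)) else character(0)
  structure(list(d = d, a = a, level = lev, wavelet = wavelet),
            level_truncated = truncated)
}

#' Shannon entropy of a coefficient band
#'
#' Entropy of the normalized squared-coefficient distribution
#' `p_i = c_i^2 / sum(c^2)`, in nats, with `0 * log(0) := 0`. An all-zero
#' band has entropy 0 by convention.
#'
#' @param coefs coefficient vector
#' @return entropy in nats
#' @export
band_entropy <- function(coefs) {
  e <- coefs^2
  s <- sum(e)
  if (s == 0) return(0)
  p <- e / s
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Wavelet spectral density of a series
#'
#' Total detail-coefficient energy per input sample over a full-depth
#' decomposition: `sum over detail levels of sum(c^2) / length(x)`.
#'
#' @param x numeric series
#' @param wavelet wavelet name (default "sym3")
#' @return a single number, 0 for series too short to decompose
#' @export
wsd <- function(x, wavelet = "sym3") {
  if (wavedec_max_level(length(x), wavelet) < 1L) return(0)
  w <- wavedec(x, wavelet)
  sum(vapply(w$d, function(ci) sum(ci^2), numeric(1))) / length(x)
}
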