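# Sample entropy, coarse-graining, the multiscale-entropy curve, and the
# integrated complexity score K.

#' Coarse-grain a time series
#'
#' Non-overlapping block averaging at scale factor `tau`:
#' `y_j = mean(x[((j-1)*tau + 1) : (j*tau)])` for
#' `j = 1..floor(M/tau)`. The output mean equals the mean of the first
#' `floor(M/tau) * tau` input points.
#'
#' @param x numeric series.
#' @param tau integer scale factor, `1 <= tau <= length(x)`.
#' @return Numeric series of length `floor(length(x)/tau)`.
#' @examples
#' coarse_grain(1:6, 2)  # 1.5 3.5 5.5
#' @export
coarse_grain <- function(x, tau) {
  tau <- as.integer(tau)
  if (tau < 1L) stop("`tau` must be >= 1", call. = FALSE)
  if (tau > length(x))
    stop("`tau` exceeds the series length", call. = FALSE)
  if (tau == 1L) return(as.numeric(x))
  nblk <- length(x) %/% tau
  colMeans(matrix(x[seq_len(nblk * tau)], nrow = tau))
}

#' Sample entropy
#'
#' `S_E = -ln(A / B)`, where `B` counts pairs of length-`m` templates whose
#' distance is within tolerance `r`, and `A` counts the same pairs still
#' matching when extended to length `m + 1`. Self-matches are excluded; both
#' counts run over the `M - m` templates that admit an extension. The
#' template distance is the maximum absolute coordinate difference
#' (Chebyshev, the standard sample-entropy convention) or, optionally, the
#' full Euclidean norm.
#'
#' @param x numeric series of length `M > m + 1` (a warning is given below
#'   `10 * (m + 1)` points, where the estimate is unreliable).
#' @param m template length (default 2).
#' @param r absolute tolerance; commonly `0.15 * sd(x)`.
#' @param metric `"chebyshev"` (default) or `"euclidean"`.
#' @return The entropy value, with attributes `A` and `B` (the raw match
#'   counts). `NA` if either count is zero (degenerate series).
#' @examples
#' x <- gen_white_noise(500, seed = 1)
#' sample_entropy(x, m = 2, r = 0.15 * sd(x))
#' @export
sample_entropy <- function(x, m = 2L, r, metric = c("chebyshev",
                                                    "euclidean")) {
  metric <- match.arg(metric)
  m <- as.integer(m)
  if (m < 1L) stop("`m` must be >= 1", call. = FALSE)
  if (length(x) <= m + 1L)
    stop("series too short for template length `m`", call. = FALSE)
  if (length(x) < 10L * (m + 1L))
    warning("fewer than 10*(m+1) points: sample entropy is unreliable")
  if (r < 0) stop("`r` must be nonnegative", call. = FALSE)
  cnt <- sampen_counts_cpp(as.numeric(x), m, r, metric == "chebyshev")
  if (cnt[["A"]] == 0 || cnt[["B"]] == 0)
    return(structure(NA_real_, A = cnt[["A"]], B = cnt[["B"]]))
  structure(-log(cnt[["A"]] / cnt[["B"]]), A = cnt[["A"]], B = cnt[["B"]])
}

#' Multiscale-entropy curve
#'
#' Computes sample entropy on coarse-grained copies of the series over a
#' grid of scale factors. The tolerance `r = r_frac * sd(x)` is computed
#' once from the original (scale 1) series and held fixed across scales, so
#' the falling variance of coarse-grained noise lowers its entropy — the
#' classic multiscale-entropy signature. Scales whose match counts are
#' degenerate are flagged missing rather than propagated as infinities.
#'
#' @param x numeric series, an [lfp_series()], or a `qife_sim`.
#' @param taus integer scale factors (default `2:100`).
#' @param m template length (default 2).
#' @param r_frac tolerance as a fraction of the scale-1 standard deviation
#'   (default 0.15).
#' @param r absolute tolerance override; if given, `r_frac` is ignored.
#' @param metric passed to [sample_entropy()].
#' @param ... passed between methods.
#' @return An object of class `mse_curve`: list with `tau`, `se`, `m`, `r`,
#'   `r_frac`, `sd_ref`, `metric`, `n_missing`.
#' @examples
#' x <- gen_white_noise(5000, seed = 1)
#' cm <- mse(x, taus = c(2, 5, 10, 20))
#' cm
#' @export
mse <- function(x, ...) UseMethod("mse")

#' @rdname mse
#' @export
mse.default <- function(x, taus = 2:100, m = 2L, r_frac = 0.15, r = NULL,
                        metric = c("chebyshev", "euclidean"), ...) {
  metric <- match.arg(metric)
  x <- as.numeric(x)
  taus <- sort(unique(as.integer(taus)))
  if (any(taus < 1L)) stop("scale factors must be >= 1", call. = FALSE)
  if (max(taus) > length(x))
    stop("largest scale factor exceeds the series length", call. = FALSE)
  sd_ref <- sd(x)
  r_abs <- r %||% (r_frac * sd_ref)
  se <- vapply(taus, function(tau) {
    y <- coarse_grain(x, tau)
    if (length(y) <= m + 1L) return(NA_real_)
    as.numeric(suppressWarnings(sample_entropy(y, m = m, r = r_abs,
                                               metric = metric)))
  }, numeric(1L))
  structure(list(tau = taus, se = se, m = m, r = r_abs, r_frac = r_frac,
                 sd_ref = sd_ref, metric = metric,
                 n_missing = sum(is.na(se))),
            class = "mse_curve")
}

#' @rdname mse
#' @export
mse.lfp_series <- function(x, ...) mse.default(x$x, ...)

#' @rdname mse
#' @export
mse.qife_sim <- function(x, ...) mse.default(x$lfp$x, ...)

#' @export
print.mse_curve <- function(x, ...) {
  cat(sprintf(
    "Multiscale entropy: %d scales (tau %d..%d), m = %d, r = %.4g (%s)\n",
    length(x$tau), min(x$tau), max(x$tau), x$m, x$r, x$metric))
  if (x$n_missing > 0)
    cat(sprintf("  %d scale(s) degenerate (no template matches)\n",
                x$n_missing))
  ok <- is.finite(x$se)
  if (any(ok))
    cat(sprintf("  entropy range [%.3f, %.3f]\n", min(x$se[ok]),
                max(x$se[ok])))
  invisible(x)
}

#' @export
plot.mse_curve <- function(x, ..., xlab = "scale factor tau",
                           ylab = "sample entropy", type = "l") {
  plot(x$tau, x$se, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' @export
as.data.frame.mse_curve <- function(x, ...) {
  data.frame(tau = x$tau, sampen = x$se)
}

#' Integrated complexity score
#'
#' `K` is the area under the multiscale-entropy curve, computed by the
#' trapezoidal rule over the scale grid. Missing (degenerate) scales are
#' excluded by integrating each maximal run of finite scales separately and
#' summing; they are reported in `n_missing`. A constant series has zero
#' entropy at every scale and hence `K = 0`.
#'
#' @param curve an [mse()] curve.
#' @return An object of class `complexity_result`: list with `K`, `tau_max`
#'   and `n_missing`.
#' @examples
#' x <- gen_white_noise(5000, seed = 1)
#' complexity_K(mse(x, taus = 2:20))
#' @export
complexity_K <- function(curve) {
  stopifnot(inherits(curve, "mse_curve"))
  ok <- is.finite(curve$se)
  if (sum(ok) < 2L)
    stop("need at least 2 finite scales to integrate", call. = FALSE)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  K <- 0
  for (q in seq_along(runs$values)) {
    if (runs$values[q] && runs$lengths[q] >= 2L) {
      idx <- starts[q]:ends[q]
      K <- K + trapezoid(curve$tau[idx], curve$se[idx])
    }
  }
  structure(list(K = K, tau_max = max(curve$tau),
                 n_missing = curve$n_missing),
            class = "complexity_result")
}

#' @export
print.complexity_result <- function(x, ...) {
  cat(sprintf("Complexity K = %.4f (integrated to tau_max = %d", x$K,
              x$tau_max))
  if (x$n_missing > 0) cat(sprintf(", %d scale(s) missing", x$n_missing))
  cat(")\n")
  invisible(x)
}
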