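# Deterministic signal generators and a hand-checkable tiny network,
# so the entropy and dynamics machinery can be validated without running
# full-scale simulations.

#' Seeded Gaussian white noise
#'
#' @param n number of samples.
#' @param sd standard deviation (> 0).
#' @param seed integer seed, or `NULL` for the current RNG stream.
#' @return Numeric vector of iid `N(0, sd^2)` samples.
#' @export
gen_white_noise <- function(n, sd = 1, seed = NULL) {
  stopifnot_scalar_number(n, "n", lower = 1)
  if (sd <= 0) stop("`sd` must be positive", call. = FALSE)
  with_seed(seed, rnorm(n, mean = 0, sd = sd))
}

#' Seeded 1/f ("pink") noise by spectral shaping
#'
#' Builds the discrete spectrum directly: Fourier amplitudes proportional to
#' `f^(-1/2)` (so the power spectrum falls off as `1/f`), uniformly random
#' phases, Hermitian symmetry, zero DC; the inverse transform is rescaled to
#' unit sample variance. The exact amplitude profile makes the log-log
#' periodogram slope -1 by construction.
#'
#' @param n number of samples (>= 2).
#' @param seed integer seed, or `NULL`.
#' @return Numeric vector with mean ~0 and unit sample variance.
#' @export
gen_pink_noise <- function(n, seed = NULL) {
  stopifnot_scalar_number(n, "n", lower = 2)
  n <- as.integer(n)
  with_seed(seed, {
    m2 <- (n - 1L) %/% 2L                # free positive frequencies
    amp <- (seq_len(m2))^(-0.5)
    ph <- runif(m2, 0, 2 * pi)
    pos <- complex(modulus = amp, argument = ph)
    spec <- if (n %% 2L == 0L) {
      nyq <- (n / 2)^(-0.5) * sample(c(-1, 1), 1L)
      c(0, pos, nyq, Conj(rev(pos)))
    } else {
      c(0, pos, Conj(rev(pos)))
    }
    x <- Re(fft(spec, inverse = TRUE)) / n
    x / sd(x)
  })
}

#' Deterministic periodic signal
#'
#' @param n number of samples.
#' @param period period in samples.
#' @param amplitude peak amplitude.
#' @param phase phase offset in radians.
#' @return `amplitude * sin(2*pi*(0:(n-1))/period + phase)`.
#' @export
gen_periodic <- function(n, period, amplitude = 1, phase = 0) {
  stopifnot_scalar_number(n, "n", lower = 1)
  stopifnot_scalar_number(period, "period")
  amplitude * sin(2 * pi * (seq_len(n) - 1) / period + phase)
}

#' Tiny deterministic network fixture
#'
#' A four-neuron ring (`nb = 2`, no rewiring) with homogeneous parameters
#' `a = 25`, `b = 30`, drive 9.5 and ephaptic factor `1e-2` — small enough
#' that Euler steps can be unrolled by hand. Pass the components to
#' [run_network()] as the `graph`/`params` overrides.
#'
#' @return A list with `graph` ([build_small_world()]), `weights`
#'   ([ephaptic_weights()]), `params` (homogeneous data frame) and `i_bias`.
#' @examples
#' fx <- tiny_network_fixture()
#' ephaptic_current(c(10, 0, 0, 0), fx$weights)
#' @export
tiny_network_fixture <- function() {
  list(graph = build_small_world(4, 2, 0, seed = 1),
       weights = ephaptic_weights(4, factor = 1e-2, enabled = TRUE),
       params = data.frame(a = rep(25, 4), b = rep(30, 4),
                           sign = rep(1, 4)),
       i_bias = 9.5)
}

#' Write or read a delimited scalar time series
#'
#' The on-disk format shared by the command-line tools: comma-separated
#' text with a header, either a single `value` column or two columns
#' `(time_s, value)`.
#'
#' @param x numeric vector or [lfp_series()].
#' @param path file path.
#' @param dt optional sampling step used to emit a time column.
#' @return `read_series()` returns a numeric vector; `write_series()`
#'   returns `path` invisibly.
#' @export
write_series <- function(x, path, dt = NULL) {
  if (inherits(x, "lfp_series")) {
    utils::write.csv(data.frame(time_s = x$t, lfp_mV = x$x), path,
                     row.names = FALSE)
  } else if (!is.null(dt)) {
    utils::write.csv(data.frame(time_s = (seq_along(x) - 1) * dt,
                                value = as.numeric(x)),
                     path, row.names = FALSE)
  } else {
    utils::write.csv(data.frame(value = as.numeric(x)), path,
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  df <- utils::read.csv(path)
  as.numeric(df[[ncol(df)]])
}
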