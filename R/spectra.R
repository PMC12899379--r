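#' Construct a set of replicated time series
#'
#' Bundles a K x T matrix of equal-length, observation-aligned time series
#' with identifiers and an optional sampling rate. All frequency bookkeeping
#' inside the package is in cycles/sample; the sampling rate is only used to
#' derive Hz views in reports.
#'
#' @param values Numeric matrix with one row per series (K x T), or a data
#'   frame coercible to one.
#' @param series_ids Optional character vector of length K; defaults to
#'   rownames or `series_1..K`.
#' @param sampling_rate Optional positive sampling rate in samples/second.
#' @return An object of class `fbam_series`.
#' @export
fbam_series <- function(values, series_ids = NULL, sampling_rate = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix with one row per series.", call. = FALSE)
  }
  if (ncol(values) < 8) stop("Series must have length T >= 8.", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(apply(values, 1, function(r) anyNA(r) || any(!is.finite(r))))
    stop("Missing or non-finite values in series: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(series_ids)) {
    series_ids <- rownames(values)
    if (is.null(series_ids)) series_ids <- paste0("series_", seq_len(nrow(values)))
  }
  if (length(series_ids) != nrow(values)) {
    stop("`series_ids` must have one entry per series.", call. = FALSE)
  }
  if (!is.null(sampling_rate)) {
    stopifnot(is.numeric(sampling_rate), length(sampling_rate) == 1, sampling_rate > 0)
  }
  rownames(values) <- NULL
  structure(
    list(values = values, series_ids = as.character(series_ids),
         sampling_rate = sampling_rate),
    class = "fbam_series"
  )
}

#' @export
print.fbam_series <- function(x, ...) {
  cat(sprintf("<fbam_series> K = %d series, T = %d time points%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$sampling_rate)) "" else
                sprintf(", fs = %g Hz", x$sampling_rate)))
  invisible(x)
}

#' Sine taper
#'
#' The r-th orthonormal sine taper of length T,
#' \eqn{h_{rt} = \sqrt{2/(T+1)} \sin(\pi r t / (T+1))}, t = 1..T.
#'
#' @param r Taper order, integer in 1..T.
#' @param T Series length.
#' @return Numeric vector of length T with unit sum of squares.
#' @export
sine_taper <- function(r, T) {
  stopifnot(length(r) == 1, length(T) == 1, T >= 1)
  if (r < 1 || r > T) stop("Taper order r must satisfy 1 <= r <= T.", call. = FALSE)
  t <- seq_len(T)
  sqrt(2 / (T + 1)) * sin(pi * r * t / (T + 1))
}

#' Default number of sine tapers
#'
#' The consistency-preserving default \eqn{R = \lfloor \sqrt{T} \rfloor}.
#'
#' @param T Series length (>= 4).
#' @return Integer taper count.
#' @export
default_taper_count <- function(T) {
  stopifnot(length(T) == 1, T >= 4)
  as.integer(floor(sqrt(T)))
}

# Fourier grid size: interior frequencies m = 1..floor(T/2)-1 (omits 0 and
# the Nyquist index); all band operations act on this grid only.
n_fourier <- function(T) as.integer(floor(T / 2) - 1)

fourier_frequencies <- function(T) seq_len(n_fourier(T)) / T

#' Direct (tapered periodogram) spectral estimate
#'
#' Squared modulus of the tapered DFT divided by T, evaluated on the Fourier
#' grid \eqn{\omega_m = m/T}, m = 1..floor(T/2)-1.
#'
#' @param x Numeric vector of length T.
#' @param taper Numeric taper of the same length (use a taper of ones for the
#'   raw periodogram).
#' @return Nonnegative numeric vector of length floor(T/2)-1.
#' @export
direct_spectral_estimate <- function(x, taper) {
  if (length(x) != length(taper)) {
    stop("`x` and `taper` must have the same length.", call. = FALSE)
  }
  T <- length(x)
  d <- fft(x * taper)
  M <- n_fourier(T)
  (Mod(d[2:(M + 1)])^2) / T
}

#' Sine multitaper spectral estimate
#'
#' Average of the R sine-tapered direct estimates,
#' \eqn{R^{-1} \sum_r |\sum_t h_{rt} x_t e^{-2\pi i \omega_m t}|^2} with the
#' unit-norm tapers of [sine_taper()]; consistent when R grows like
#' \eqn{\sqrt{T}}. Under this normalization a unit-variance white noise
#' series has unit spectrum, and each tapered estimate equals
#' [direct_spectral_estimate()] evaluated with the \eqn{\sqrt{T}}-scaled
#' taper.
#'
#' @param x Numeric vector of length T.
#' @param R Number of sine tapers, 1 <= R <= T.
#' @return Nonnegative numeric vector on the Fourier grid.
#' @export
multitaper_spectrum <- function(x, R) {
  T <- length(x)
  stopifnot(length(R) == 1)
  if (R < 1 || R > T) stop("Taper count R must satisfy 1 <= R <= T.", call. = FALSE)
  t <- seq_len(T)
  H <- sqrt(2 / (T + 1)) * sin(pi * outer(t, seq_len(R)) / (T + 1))
  D <- stats::mvfft(H * x)
  M <- n_fourier(T)
  rowMeans(Mod(D[2:(M + 1), , drop = FALSE])^2)
}

#' Multitaper spectra for a collection of series
#'
#' Estimates every replicate-specific power spectrum on the common Fourier
#' grid. Optionally each series is first linearly detrended and divided by
#' its sample standard deviation, mirroring the usual preprocessing of
#' biomedical signals before normalized spectral analysis.
#'
#' @param data An `fbam_series`, numeric matrix (K x T) or data frame.
#' @param R Number of sine tapers; defaults to `default_taper_count(T)`.
#'   Values above T are capped at T with a warning.
#' @param standardize If `TRUE`, detrend (OLS line) and scale each series to
#'   unit sample variance before estimation.
#' @return An object of class `fbam_spectra` with elements `frequencies`
#'   (cycles/sample), `power` (K x M matrix), `n_tapers`, `T`, `series_ids`
#'   and `sampling_rate`.
#' @export
estimate_spectra <- function(data, R = NULL, standardize = FALSE) {
  if (!inherits(data, "fbam_series")) data <- fbam_series(data)
  X <- data$values
  T <- ncol(X)
  if (is.null(R)) R <- default_taper_count(T)
  R <- as.integer(R)
  if (R < 1) stop("Taper count R must be positive.", call. = FALSE)
  if (R > T) {
    warning("Only T sine tapers exist; capping R at T = ", T)
    R <- T
  }
  if (standardize) {
    t <- seq_len(T)
    tc <- t - mean(t)
    denom <- sum(tc^2)
    X <- t(apply(X, 1, function(x) {
      slope <- sum(tc * (x - mean(x))) / denom
      r <- x - mean(x) - slope * tc
      s <- sd(r)
      if (!is.finite(s) || s == 0) {
        stop("Cannot standardize a constant (or perfectly linear) series.",
             call. = FALSE)
      }
      r / s
    }))
  }
  # batch over tapers: one multi-column FFT per series
  t <- seq_len(T)
  H <- sqrt(2 / (T + 1)) * sin(pi * outer(t, seq_len(R)) / (T + 1))
  M <- n_fourier(T)
  P <- matrix(0, nrow(X), M)
  for (k in seq_len(nrow(X))) {
    D <- stats::mvfft(H * X[k, ])
    P[k, ] <- rowMeans(Mod(D[2:(M + 1), , drop = FALSE])^2)
  }
  structure(
    list(frequencies = fourier_frequencies(T), power = P, n_tapers = R,
         T = T, series_ids = data$series_ids, sampling_rate = data$sampling_rate),
    class = "fbam_spectra"
  )
}

#' @export
print.fbam_spectra <- function(x, ...) {
  cat(sprintf("<fbam_spectra> K = %d spectra on M = %d Fourier frequencies (T = %d, R = %d tapers)\n",
              nrow(x$power), ncol(x$power), x$T, x$n_tapers))
  invisible(x)
}

#' @describeIn estimate_spectra Tidy view: one row per (series, frequency).
#' @param x An `fbam_spectra` object.
#' @param ... Unused.
#' @export
tidy.fbam_spectra <- function(x, ...) {
  K <- nrow(x$power); M <- ncol(x$power)
  out <- tibble::tibble(
    series = rep(x$series_ids, each = M),
    frequency = rep(x$frequencies, times = K),
    power = as.vector(t(x$power))
  )
  if (!is.null(x$sampling_rate)) out$frequency_hz <- out$frequency * x$sampling_rate
  out
}

#' @export
autoplot.fbam_spectra <- function(object, ...) {
  df <- tidy.fbam_spectra(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency, .data$power, group = .data$series)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "frequency (cycles/sample)", y = "power") +
    ggplot2::theme_minimal()
}
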