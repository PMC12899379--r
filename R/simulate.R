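# Simulators for three families of spectral populations used to exercise the
# method end to end: piecewise-smooth spectra with banded levels (model 1),
# AR(2) processes parameterized by spectral peak location and bandwidth
# (models 2a-2c), and sums of two independent AR(2) components (model 3).

#' AR(2) coefficients from peak location and bandwidth
#'
#' \eqn{\phi_1 = 2\cos(2\pi\psi) e^{-\ell}}, \eqn{\phi_2 = -e^{-2\ell}}:
#' a stationary AR(2) whose spectrum peaks near frequency \eqn{\psi}
#' (cycles/sample), with larger \eqn{\ell} giving a broader peak.
#'
#' @param psi Peak location in [0, 0.5).
#' @param bandwidth Positive bandwidth parameter \eqn{\ell}.
#' @return Named numeric vector `c(phi1, phi2)`.
#' @export
ar2_coefficients <- function(psi, bandwidth) {
  stopifnot(psi >= 0, psi < 0.5, bandwidth > 0)
  c(phi1 = 2 * cos(2 * pi * psi) * exp(-bandwidth),
    phi2 = -exp(-2 * bandwidth))
}

#' Closed-form AR(2) power spectrum
#'
#' \eqn{g(\omega) = \sigma^2 / |1 - \phi_1 e^{-2\pi i \omega} -
#' \phi_2 e^{-4\pi i \omega}|^2} (two-sided convention on cycles/sample, so
#' the process variance is \eqn{2\int_0^{1/2} g}).
#'
#' @param phi1,phi2 Stationary AR(2) coefficients.
#' @param sigma Innovation standard deviation.
#' @param frequencies Frequencies (cycles/sample) to evaluate at.
#' @return Strictly positive numeric vector.
#' @export
ar2_spectrum <- function(phi1, phi2, sigma, frequencies) {
  roots <- Mod(polyroot(c(1, -phi1, -phi2)))
  if (any(roots <= 1)) {
    stop("Nonstationary AR(2) coefficients.", call. = FALSE)
  }
  z <- exp(-2i * pi * frequencies)
  sigma^2 / Mod(1 - phi1 * z - phi2 * z^2)^2
}

# Stationary variance of an AR(2) process (Yule-Walker closed form).
ar2_variance <- function(phi1, phi2, sigma) {
  sigma^2 * (1 - phi2) / ((1 + phi2) * ((1 - phi2)^2 - phi1^2))
}

#' Simulate a stationary AR(2) series
#'
#' Gaussian innovations, with a 500-sample burn-in discarded.
#'
#' @param phi1,phi2 Stationary AR(2) coefficients.
#' @param sigma Innovation standard deviation.
#' @param T Output length.
#' @return Numeric vector of length T.
#' @export
simulate_ar2 <- function(phi1, phi2, sigma, T) {
  roots <- Mod(polyroot(c(1, -phi1, -phi2)))
  if (any(roots <= 1)) stop("Nonstationary AR(2) coefficients.", call. = FALSE)
  if (sigma == 0) return(numeric(T))
  as.numeric(arima.sim(model = list(ar = c(phi1, phi2)), n = T,
                       n.start = 500, sd = sigma))
}

#' Piecewise-smooth three-band spectrum
#'
#' A three-plateau spectrum with continuous cubic (smoothstep) transitions
#' of half-width `transition_halfwidth` around each boundary: the transition
#' matches the plateau levels with zero slope at both ends, so the value at
#' the boundary itself is the mean of the adjacent levels.
#'
#' @param frequencies Evaluation frequencies in [0, 0.5).
#' @param boundaries Two interior boundaries (cycles/sample).
#' @param levels Three plateau levels.
#' @param transition_halfwidth Half-width of each transition window.
#' @return Nonnegative numeric vector.
#' @export
model1_spectrum <- function(frequencies, boundaries, levels,
                            transition_halfwidth = 0.025) {
  stopifnot(length(boundaries) == 2, length(levels) == 3,
            boundaries[1] < boundaries[2])
  h <- transition_halfwidth
  if (boundaries[1] + h > boundaries[2] - h) {
    stop("Overlapping transition windows.", call. = FALSE)
  }
  g <- numeric(length(frequencies))
  edges <- c(-Inf, boundaries, Inf)
  for (l in 1:3) {
    g[frequencies >= edges[l] & frequencies < edges[l + 1]] <- levels[l]
  }
  for (l in 1:2) {
    w <- frequencies >= boundaries[l] - h & frequencies < boundaries[l] + h
    u <- (frequencies[w] - (boundaries[l] - h)) / (2 * h)
    s <- 3 * u^2 - 2 * u^3
    g[w] <- levels[l] + (levels[l + 1] - levels[l]) * s
  }
  g
}

#' Simulate a Gaussian series with a prescribed spectrum
#'
#' Spectral synthesis on the Fourier grid:
#' \deqn{X_t = \sum_m \sqrt{2 g(\omega_m)/T}\,(A_m \cos 2\pi\omega_m t +
#'   B_m \sin 2\pi\omega_m t)} with i.i.d. standard normal \eqn{A_m, B_m},
#' giving a stationary Gaussian series whose expected periodogram matches g.
#'
#' @param g Nonnegative spectrum on the Fourier grid of length
#'   `floor(T/2) - 1`.
#' @param T Series length.
#' @return Numeric vector of length T.
#' @export
simulate_from_spectrum <- function(g, T) {
  if (any(g < 0)) stop("Spectrum must be nonnegative.", call. = FALSE)
  M <- n_fourier(T)
  stopifnot(length(g) == M)
  synth_from_spectra(matrix(g, ncol = 1), T)[1, ]
}

# Batch spectral synthesis: G is M x K (one column per replicate); returns
# a K x T matrix. One pair of T x M trig matrices serves all replicates.
synth_from_spectra <- function(G, T) {
  M <- nrow(G); K <- ncol(G)
  ang <- outer(seq_len(T), 2 * pi * seq_len(M) / T)
  S <- sqrt(2 * G / T)
  A <- matrix(rnorm(M * K), M, K) * S
  B <- matrix(rnorm(M * K), M, K) * S
  t(cos(ang) %*% A + sin(ang) %*% B)
}

model1_defaults <- list(
  boundaries = list(c(0.1, 0.25), c(0.2, 0.3), c(0.25, 0.4)),
  levels = list(c(15, 7.5, 2), c(25, 12.5, 4), c(35, 17.5, 6)),
  level_jitter = 2, transition_halfwidth = 0.025
)

model2_settings <- function(model) {
  psi <- switch(model,
    "2a" = c(0.23, 0.25, 0.27),
    "2b" = c(0.21, 0.25, 0.29),
    "2c" = c(0.19, 0.25, 0.31))
  bw_mid <- switch(model, "2a" = 0.15, "2b" = 0.155, "2c" = 0.165)
  bw <- c(bw_mid, 0.15, bw_mid)
  list(psi = psi, psi_halfwidth = 0.02, bandwidth = bw,
       bandwidth_halfwidth = 0.005, sigma = 2.25)
}

model3_settings <- list(
  psi1 = 0, bw1 = c(0.48, 0.52), sigma1 = 2.5,
  psi2 = c(0.2, 0.26, 0.32), psi2_halfwidth = 0.015,
  bw2 = c(0.05, 0.065, 0.095), sigma2 = 2
)

#' Generate a simulated spectral population with ground truth
#'
#' Three subpopulations of `K_j` series each, under one of the model
#' families: `"1"` piecewise-smooth banded spectra with uniformly jittered
#' plateau levels (via spectral synthesis); `"2a"`, `"2b"`, `"2c"` AR(2)
#' processes with increasingly separated mid-frequency peaks; `"3"` sums of
#' a broad low-frequency AR(2) and a subpopulation-specific mid-frequency
#' AR(2).
#'
#' @param model One of `"1"`, `"2a"`, `"2b"`, `"2c"`, `"3"`.
#' @param K_j Replicates per subpopulation.
#' @param T Series length (>= 64).
#' @param seed Optional integer seed.
#' @return A list of class `fbam_sim`: `data` (`fbam_series` of 3 K_j
#'   series), `true_labels`, `true_spectra` (K x M on the Fourier grid),
#'   `true_boundaries` (model 1 only), `params` (drawn parameters).
#' @export
simulate_fbam_model <- function(model = c("1", "2a", "2b", "2c", "3"),
                                K_j = 20, T = 500, seed = NULL) {
  model <- as.character(model)
  model <- match.arg(model)
  if (!is.null(seed)) {
    return(withr::with_seed(seed,
      simulate_fbam_model(model, K_j = K_j, T = T)))
  }
  stopifnot(K_j >= 1, T >= 64)
  K <- 3L * K_j
  M <- n_fourier(T)
  freq <- fourier_frequencies(T)
  labels <- rep(1:3, each = K_j)
  true_spectra <- matrix(0, K, M)
  true_boundaries <- NULL
  params <- list(model = model, K_j = K_j, T = T)

  if (model == "1") {
    d <- model1_defaults
    lev <- matrix(0, K, 3)
    for (k in seq_len(K)) {
      j <- labels[k]
      lev[k, ] <- runif(3, d$levels[[j]] - d$level_jitter,
                        d$levels[[j]] + d$level_jitter)
      true_spectra[k, ] <- model1_spectrum(freq, d$boundaries[[j]], lev[k, ],
                                           d$transition_halfwidth)
    }
    X <- synth_from_spectra(t(true_spectra), T)
    true_boundaries <- d$boundaries
    params$levels <- lev
  } else if (model %in% c("2a", "2b", "2c")) {
    s <- model2_settings(model)
    psi <- runif(K, s$psi[labels] - s$psi_halfwidth,
                 s$psi[labels] + s$psi_halfwidth)
    bw <- runif(K, s$bandwidth[labels] - s$bandwidth_halfwidth,
                s$bandwidth[labels] + s$bandwidth_halfwidth)
    X <- matrix(0, K, T)
    for (k in seq_len(K)) {
      ph <- ar2_coefficients(psi[k], bw[k])
      true_spectra[k, ] <- ar2_spectrum(ph[1], ph[2], s$sigma, freq)
      X[k, ] <- simulate_ar2(ph[1], ph[2], s$sigma, T)
    }
    params$psi <- psi
    params$bandwidth <- bw
  } else {
    s <- model3_settings
    bw1 <- runif(K, s$bw1[1], s$bw1[2])
    psi2 <- runif(K, s$psi2[labels] - s$psi2_halfwidth,
                  s$psi2[labels] + s$psi2_halfwidth)
    bw2 <- s$bw2[labels]
    X <- matrix(0, K, T)
    for (k in seq_len(K)) {
      p1 <- ar2_coefficients(s$psi1, bw1[k])
      p2 <- ar2_coefficients(psi2[k], bw2[k])
      true_spectra[k, ] <- ar2_spectrum(p1[1], p1[2], s$sigma1, freq) +
        ar2_spectrum(p2[1], p2[2], s$sigma2, freq)
      X[k, ] <- simulate_ar2(p1[1], p1[2], s$sigma1, T) +
        simulate_ar2(p2[1], p2[2], s$sigma2, T)
    }
    params$bw1 <- bw1
    params$psi2 <- psi2
  }

  structure(
    list(data = fbam_series(X, series_ids = sprintf("g%d_k%d", labels,
                                                    sequence(rep(K_j, 3)))),
         true_labels = labels, true_spectra = true_spectra,
         true_boundaries = true_boundaries, params = params),
    class = "fbam_sim"
  )
}

#' @export
print.fbam_sim <- function(x, ...) {
  cat(sprintf("<fbam_sim> model %s: 3 x %d series of length %d\n",
              x$params$model, x$params$K_j, x$params$T))
  invisible(x)
}
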