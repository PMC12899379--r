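#' Frequency band analysis of multiple stationary time series
#'
#' End-to-end pipeline: estimates replicate-specific power spectra with sine
#' multitapers, minimizes the least-squares band/cluster objective for every
#' (J, L) on a grid with an island-model genetic algorithm, and selects the
#' numbers of subpopulations and frequency bands with the similarity
#' criteria.
#'
#' @param data An `fbam_series`, numeric matrix (one row per series), data
#'   frame, or an already-estimated `fbam_spectra` object.
#' @param j_grid,l_grid Candidate numbers of subpopulations and bands.
#' @param mode Selection mode: `"joint"` (scaled S1 + S2), `"bands_only"`
#'   (minimize S1 at fixed J), or `"subpops_only"` (minimize S2 at fixed L).
#' @param tapers Number of sine tapers, or `NULL` for `floor(sqrt(T))`.
#' @param standardize Detrend and variance-standardize each series before
#'   spectral estimation.
#' @param sampling_rate Optional sampling rate (Hz) for reporting.
#' @param control GA settings from [fbam_control()].
#' @param seed Integer master seed; every grid cell derives its own stream
#'   from it, so runs are fully reproducible.
#' @return An object of class `fbam_fit` with the criterion table (tibble
#'   with columns J, L, loss, S1, S2, scaled_sum), all fitted solutions, the
#'   selected solution (`$best`, `$selected`), and provenance.
#' @examples
#' sim <- simulate_fbam_model("1", K_j = 5, T = 256, seed = 1)
#' fit <- fbam(sim$data, j_grid = 2:3, l_grid = 2:3,
#'             control = fbam_control(n_islands = 2, max_generations = 50),
#'             seed = 1)
#' glance(fit)
#' tidy(fit)
#' @export
fbam <- function(data, j_grid = 2:6, l_grid = 2:6,
                 mode = c("joint", "bands_only", "subpops_only"),
                 tapers = NULL, standardize = FALSE, sampling_rate = NULL,
                 control = fbam_control(), seed = 1L) {
  mode <- match.arg(mode)
  if (inherits(data, "fbam_spectra")) {
    spectra <- data
  } else {
    if (!inherits(data, "fbam_series")) {
      data <- fbam_series(data, sampling_rate = sampling_rate)
    } else if (!is.null(sampling_rate)) {
      data$sampling_rate <- sampling_rate
    }
    spectra <- estimate_spectra(data, R = tapers, standardize = standardize)
  }
  fit_grid(spectra, j_grid, l_grid, control = control, mode = mode,
           seed = seed)
}

#' @export
print.fbam_fit <- function(x, ...) {
  cat(sprintf("<fbam_fit> selected J = %d subpopulations, L = %d bands (mode = %s)\n",
              x$selected["J"], x$selected["L"], x$mode))
  cat(sprintf("  loss = %.4g over K = %d series, T = %d, R = %d tapers\n",
              x$best$loss, x$provenance$K, x$provenance$T, x$provenance$R))
  print(x$table, n = Inf)
  invisible(x)
}

# Boundary frequency of a cut: midpoint between the last Fourier index of
# band l and the first of band l+1, in cycles/sample.
cut_frequency <- function(cut, T) (cut - 0.5) / T

#' Tidy the selected FBAM solution
#'
#' One row per (subpopulation, band) with band edges in cycles/sample (and
#' Hz when a sampling rate is known), band sizes, and the mean collapsed
#' power level.
#'
#' @param x An `fbam_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.fbam_fit <- function(x, ...) {
  sol <- x$best
  sp <- x$spectra
  T <- sp$T
  fs <- sp$sampling_rate
  out <- purrr::map_dfr(seq_len(sol$J), function(j) {
    P <- sp$power[sol$labels == j, , drop = FALSE]
    cm <- collapsed_power(P, sol$cuts[[j]], sol$w_min)
    edges <- c(0, cut_frequency(sol$cuts[[j]], T), 0.5)
    tibble::tibble(
      subpopulation = j, band = seq_len(sol$L),
      lower = edges[-length(edges)], upper = edges[-1],
      n_frequencies = cm$band_sizes, n_series = nrow(P),
      mean_power = cm$per_band_mean
    )
  })
  if (!is.null(fs)) {
    out$lower_hz <- out$lower * fs
    out$upper_hz <- out$upper * fs
  }
  out
}

#' One-row summary of an FBAM fit
#'
#' @param x An `fbam_fit`.
#' @param ... Unused.
#' @return A tibble with the selected J and L, objective value, criteria,
#'   and data dimensions.
#' @export
glance.fbam_fit <- function(x, ...) {
  row <- x$table[x$table$J == x$selected["J"] & x$table$L == x$selected["L"], ]
  tibble::tibble(
    J = x$selected[["J"]], L = x$selected[["L"]], loss = x$best$loss,
    S1 = row$S1[1], S2 = row$S2[1], mode = x$mode,
    n_series = x$provenance$K, T = x$provenance$T, n_tapers = x$provenance$R
  )
}

#' Plot an FBAM fit
#'
#' Replicate spectra grouped by estimated subpopulation, with the selected
#' band boundaries (dashed) and the mean collapsed power spectrum (step
#' function) overlaid.
#'
#' @param object An `fbam_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fbam_fit <- function(object, ...) {
  sp <- object$spectra
  sol <- object$best
  K <- nrow(sp$power); M <- ncol(sp$power)
  df <- tibble::tibble(
    series = rep(seq_len(K), each = M),
    subpopulation = factor(rep(sol$labels, each = M)),
    frequency = rep(sp$frequencies, times = K),
    power = as.vector(t(sp$power))
  )
  steps <- purrr::map_dfr(seq_len(sol$J), function(j) {
    cm <- collapsed_power(sp$power[sol$labels == j, , drop = FALSE],
                          sol$cuts[[j]], sol$w_min)
    tibble::tibble(subpopulation = factor(j), frequency = sp$frequencies,
                   power = mean_collapsed_spectrum(cm, sol$cuts[[j]], M))
  })
  cuts <- purrr::map_dfr(seq_len(sol$J), function(j) {
    tibble::tibble(subpopulation = factor(j),
                   boundary = cut_frequency(sol$cuts[[j]], sp$T))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency, .data$power)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$series), alpha = 0.25) +
    ggplot2::geom_step(data = steps, colour = "red", linewidth = 0.8) +
    ggplot2::geom_vline(data = cuts,
                        ggplot2::aes(xintercept = .data$boundary),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~subpopulation, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "frequency (cycles/sample)", y = "power") +
    ggplot2::theme_minimal()
}
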