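# Band partitions are integer cut vectors on the Fourier index set {1..M}:
# cuts c_1 < ... < c_{L-1}, with implicit c_0 = 1 and c_L = M + 1; band l
# covers indices [c_{l-1}, c_l). Every band must contain >= w_min indices.

validate_cuts <- function(cuts, M, w_min = 5) {
  cuts <- as.integer(cuts)
  bounds <- c(1L, cuts, M + 1L)
  if (is.unsorted(cuts, strictly = TRUE)) {
    stop("Cut positions must be strictly increasing.", call. = FALSE)
  }
  if (any(diff(bounds) < w_min)) {
    stop(sprintf("Every band must contain at least w_min = %d Fourier frequencies.",
                 w_min), call. = FALSE)
  }
  cuts
}

band_sizes <- function(cuts, M) diff(c(1L, as.integer(cuts), M + 1L))

# Band membership index list for a cut vector.
band_indices <- function(cuts, M) {
  bounds <- c(1L, as.integer(cuts), M + 1L)
  lapply(seq_len(length(bounds) - 1L),
         function(l) seq.int(bounds[l], bounds[l + 1L] - 1L))
}

#' Collapsed band-average power measures
#'
#' Averages each replicate's spectrum within each band of a partition
#' (\eqn{\hat y_{jkl}}), together with the cross-replicate band means
#' (\eqn{\hat y_{j\cdot l}}) that define the subpopulation's mean collapsed
#' power spectrum.
#'
#' @param power Numeric matrix (K_j x M) of spectra for one subpopulation, or
#'   an `fbam_spectra` object.
#' @param cuts Integer vector of interior cut positions (possibly empty for a
#'   single band).
#' @param w_min Minimum band width in Fourier frequencies.
#' @return List with `per_replicate` (K_j x L), `per_band_mean` (length L)
#'   and `band_sizes` (length L).
#' @export
collapsed_power <- function(power, cuts = integer(), w_min = 5) {
  if (inherits(power, "fbam_spectra")) power <- power$power
  M <- ncol(power)
  cuts <- validate_cuts(cuts, M, w_min)
  idx <- band_indices(cuts, M)
  per_replicate <- vapply(idx, function(ii) rowMeans(power[, ii, drop = FALSE]),
                          numeric(nrow(power)))
  per_replicate <- matrix(per_replicate, nrow = nrow(power))
  list(per_replicate = per_replicate,
       per_band_mean = colMeans(per_replicate),
       band_sizes = band_sizes(cuts, M))
}

#' Mean collapsed power spectrum
#'
#' The piecewise-constant "cluster center": the step function on the Fourier
#' grid whose level on each band is the cross-replicate band mean.
#'
#' @param cm Output of [collapsed_power()].
#' @param cuts The cut vector the measures were computed from.
#' @param M Number of Fourier frequencies.
#' @return Numeric vector of length M.
#' @export
mean_collapsed_spectrum <- function(cm, cuts, M) {
  stopifnot(sum(cm$band_sizes) == M)
  rep(cm$per_band_mean, times = cm$band_sizes)
}

#' Refine a band partition with one extra cut
#'
#' @param cuts Existing interior cut vector.
#' @param extra_cut New interior cut position.
#' @param M Number of Fourier frequencies.
#' @param w_min Minimum band width.
#' @return The enlarged, validated cut vector.
#' @export
refine_partition <- function(cuts, extra_cut, M, w_min = 5) {
  extra_cut <- as.integer(extra_cut)
  if (extra_cut %in% cuts) stop("Duplicate cut position.", call. = FALSE)
  validate_cuts(sort(c(as.integer(cuts), extra_cut)), M, w_min)
}

#' Construct a candidate solution (clustering + band partitions)
#'
#' A solution pairs a partition of the K replicates into J nonempty
#' subpopulations with one band partition per subpopulation, all sharing the
#' same number of bands L.
#'
#' @param labels Integer vector of length K with values in 1..J; every label
#'   must occur.
#' @param cuts List of J integer cut vectors, each of length L - 1.
#' @param M Number of Fourier frequencies the cuts index into.
#' @param w_min Minimum band width.
#' @param loss Optional cached objective value.
#' @return An object of class `fbam_solution`.
#' @export
new_solution <- function(labels, cuts, M, w_min = 5, loss = NA_real_) {
  labels <- as.integer(labels)
  if (!is.list(cuts)) cuts <- list(cuts)
  J <- length(cuts)
  if (!setequal(unique(labels), seq_len(J))) {
    stop("Labels must use every value 1..J at least once.", call. = FALSE)
  }
  lens <- lengths(cuts)
  if (length(unique(lens)) != 1) {
    stop("All subpopulations must share the same number of bands L.", call. = FALSE)
  }
  cuts <- lapply(cuts, validate_cuts, M = M, w_min = w_min)
  structure(
    list(labels = labels, cuts = cuts, J = J, L = as.integer(lens[1] + 1L),
         M = as.integer(M), w_min = as.integer(w_min), loss = loss),
    class = "fbam_solution"
  )
}

#' @export
print.fbam_solution <- function(x, ...) {
  cat(sprintf("<fbam_solution> J = %d subpopulations, L = %d bands, K = %d series%s\n",
              x$J, x$L, length(x$labels),
              if (is.na(x$loss)) "" else sprintf(", loss = %.4g", x$loss)))
  invisible(x)
}

#' Least-squares band/cluster objective
#'
#' The scaled sum of squared deviations of every replicate spectrum from its
#' subpopulation's mean collapsed level within each band,
#' \deqn{\hat{\mathcal{L}} = T^{-1} \sum_j \sum_k \sum_l \sum_{\omega \in W_{jl}}
#'   (\hat g_{jk}(\omega) - \hat y_{j\cdot l})^2.}
#'
#' @param spectra An `fbam_spectra` object (or list with `power` and `T`).
#' @param solution An `fbam_solution` consistent with the spectra.
#' @return Nonnegative scalar.
#' @export
fbam_loss <- function(spectra, solution) {
  P <- spectra$power
  if (length(solution$labels) != nrow(P) || solution$M != ncol(P)) {
    stop("Solution dimensions are inconsistent with the spectra.", call. = FALSE)
  }
  total <- 0
  for (j in seq_len(solution$J)) {
    rows <- which(solution$labels == j)
    Pj <- P[rows, , drop = FALSE]
    idx <- band_indices(solution$cuts[[j]], solution$M)
    for (ii in idx) {
      block <- Pj[, ii, drop = FALSE]
      ybar <- mean(rowMeans(block))
      total <- total + sum((block - ybar)^2)
    }
  }
  total / spectra$T
}

# Fast loss path shared with the GA: cumulative row sums + the identity
# sum (g - ybar)^2 = sum g^2 - n * ybar^2 within each (group, band) cell.
spectra_cumsums <- function(spectra) {
  P <- spectra$power
  CS <- cbind(0, t(apply(P, 1, cumsum)))
  CS2 <- cbind(0, t(apply(P^2, 1, cumsum)))
  list(CS = CS, CS2 = CS2, total_ss = sum(P^2), T = spectra$T, M = ncol(P))
}

solution_loss <- function(pre, labels, cuts_flat, J, L) {
  cpp_solution_loss(pre$CS, pre$total_ss, pre$T, as.integer(labels),
                    as.integer(cuts_flat), as.integer(J), as.integer(L))
}

flatten_cuts <- function(cuts) as.integer(unlist(cuts, use.names = FALSE))

unflatten_cuts <- function(flat, J, L) {
  if (L == 1L) return(rep(list(integer()), J))
  unname(split(as.integer(flat), rep(seq_len(J), each = L - 1L)))
}
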