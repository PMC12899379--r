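# Similarity criteria used for selecting the number of bands (S1, built from
# adjacent-band ratios R1) and subpopulations (S2, built from pairwise group
# ratios R2). Degenerate denominators raise errors here; the selection step
# maps them to +Inf so such solutions are never chosen.

#' Adjacent-band similarity ratio
#'
#' Ratio of the within-band root-sums-of-squares of bands l and l+1 to the
#' root-sum-of-squares around the pooled two-band mean. Values near 0
#' indicate two clearly distinct bands; values near (or above) 1 indicate the
#' bands could be merged.
#'
#' @param power Spectra for one subpopulation (K_j x M matrix or
#'   `fbam_spectra`).
#' @param cuts Cut vector of the subpopulation's band partition.
#' @param l Band index in 1..L-1.
#' @param w_min Minimum band width.
#' @return Nonnegative scalar.
#' @export
band_similarity <- function(power, cuts, l, w_min = 5) {
  if (inherits(power, "fbam_spectra")) power <- power$power
  M <- ncol(power)
  cuts <- validate_cuts(cuts, M, w_min)
  L <- length(cuts) + 1L
  if (l < 1 || l > L - 1) stop("Band index l must be in 1..L-1.", call. = FALSE)
  idx <- band_indices(cuts, M)
  i1 <- idx[[l]]; i2 <- idx[[l + 1L]]
  y1 <- mean(rowMeans(power[, i1, drop = FALSE]))
  y2 <- mean(rowMeans(power[, i2, drop = FALSE]))
  n1 <- length(i1); n2 <- length(i2)
  mu <- (n1 * y1 + n2 * y2) / (n1 + n2)
  num <- sqrt(sum((power[, i1, drop = FALSE] - y1)^2)) +
    sqrt(sum((power[, i2, drop = FALSE] - y2)^2))
  den <- sqrt(sum((power[, c(i1, i2), drop = FALSE] - mu)^2))
  if (den == 0) {
    stop("Degenerate band similarity: spectra are identical across both bands.",
         call. = FALSE)
  }
  num / den
}

#' Subpopulation similarity ratio
#'
#' Ratio of the two groups' size-weighted within-group spectral variabilities
#' around their mean collapsed spectra to the distance between those collapsed
#' spectra on the full Fourier grid. Small values indicate well-separated
#' subpopulations.
#'
#' @param power_i,power_j Spectra matrices (K x M) of the two subpopulations.
#' @param cuts_i,cuts_j Their band partitions (same L).
#' @param w_min Minimum band width.
#' @return Nonnegative scalar, symmetric in its arguments.
#' @export
subpop_similarity <- function(power_i, power_j, cuts_i, cuts_j, w_min = 5) {
  if (inherits(power_i, "fbam_spectra")) power_i <- power_i$power
  if (inherits(power_j, "fbam_spectra")) power_j <- power_j$power
  M <- ncol(power_i)
  stopifnot(ncol(power_j) == M, length(cuts_i) == length(cuts_j))
  within_term <- function(power, cuts) {
    cm <- collapsed_power(power, cuts, w_min)
    step <- mean_collapsed_spectrum(cm, cuts, M)
    sqrt(sum(sweep(power, 2, step)^2) / nrow(power))
  }
  cm_i <- collapsed_power(power_i, cuts_i, w_min)
  cm_j <- collapsed_power(power_j, cuts_j, w_min)
  yi <- mean_collapsed_spectrum(cm_i, cuts_i, M)
  yj <- mean_collapsed_spectrum(cm_j, cuts_j, M)
  den <- sqrt(sum((yi - yj)^2))
  if (den == 0) {
    stop("Degenerate subpopulation similarity: identical mean collapsed spectra.",
         call. = FALSE)
  }
  (within_term(power_i, cuts_i) + within_term(power_j, cuts_j)) / den
}

#' Band-structure selection criterion S1
#'
#' Average adjacent-band similarity: the mean of the \eqn{J(L-1)}
#' adjacent-band ratios over all subpopulations and band pairs. Splitting a
#' genuinely heterogeneous band lowers the ratios; splitting a homogeneous
#' one introduces ratios near (or above) 1, so the criterion is minimized
#' at a parsimonious number of bands.
#'
#' @param spectra An `fbam_spectra` object.
#' @param solution An `fbam_solution` with L >= 2.
#' @return Nonnegative scalar (smaller is better).
#' @export
criterion_s1 <- function(spectra, solution) {
  if (solution$L < 2) stop("S1 is undefined for L = 1.", call. = FALSE)
  P <- spectra$power
  total <- 0
  for (j in seq_len(solution$J)) {
    Pj <- P[solution$labels == j, , drop = FALSE]
    for (l in seq_len(solution$L - 1L)) {
      total <- total + band_similarity(Pj, solution$cuts[[j]], l, solution$w_min)
    }
  }
  total / (solution$J * (solution$L - 1L))
}

#' Subpopulation-structure selection criterion S2
#'
#' Mean over subpopulations of the largest (worst-case) similarity to any
#' other subpopulation.
#'
#' @param spectra An `fbam_spectra` object.
#' @param solution An `fbam_solution` with J >= 2.
#' @return Nonnegative scalar (smaller is better).
#' @export
criterion_s2 <- function(spectra, solution) {
  J <- solution$J
  if (J < 2) stop("S2 is undefined for J = 1.", call. = FALSE)
  P <- spectra$power
  groups <- lapply(seq_len(J), function(j) P[solution$labels == j, , drop = FALSE])
  R2 <- matrix(NA_real_, J, J)
  for (i in seq_len(J - 1L)) {
    for (j in seq.int(i + 1L, J)) {
      R2[i, j] <- R2[j, i] <- subpop_similarity(
        groups[[i]], groups[[j]], solution$cuts[[i]], solution$cuts[[j]],
        solution$w_min)
    }
  }
  mean(apply(R2, 1, max, na.rm = TRUE))
}

#' Build the criterion table over a grid of fitted solutions
#'
#' Evaluates S1 and S2 for each fitted (J, L) solution and computes the
#' scale-equalization constants a1 and a2 (the maxima of the finite S1 and
#' S2 columns), so that the joint criterion S1/a1 + S2/a2 weighs both axes
#' equally. Degenerate criteria are stored as +Inf.
#'
#' @param spectra An `fbam_spectra` object.
#' @param solutions Named or unnamed list of `fbam_solution` objects.
#' @return A list of class `fbam_criteria`: `table` (tibble with columns J,
#'   L, loss, S1, S2, scaled_sum), `solutions`, `a1`, `a2`.
#' @export
criterion_table <- function(spectra, solutions) {
  safe <- function(expr) tryCatch(expr, error = function(e) Inf)
  rows <- purrr::map_dfr(solutions, function(sol) {
    tibble::tibble(
      J = sol$J, L = sol$L,
      loss = if (is.na(sol$loss)) fbam_loss(spectra, sol) else sol$loss,
      S1 = if (sol$L >= 2) safe(criterion_s1(spectra, sol)) else NA_real_,
      S2 = if (sol$J >= 2) safe(criterion_s2(spectra, sol)) else NA_real_
    )
  })
  a1 <- suppressWarnings(max(rows$S1[is.finite(rows$S1)]))
  a2 <- suppressWarnings(max(rows$S2[is.finite(rows$S2)]))
  rows$scaled_sum <- rows$S1 / a1 + rows$S2 / a2
  structure(list(table = rows, solutions = solutions, a1 = a1, a2 = a2),
            class = "fbam_criteria")
}

#' Select the number of subpopulations and bands from a criterion table
#'
#' Joint mode minimizes the equally-scaled sum S1/a1 + S2/a2 over grid
#' entries with J >= 2 and L >= 2; `bands_only` minimizes S1 (L axis, fixed
#' J); `subpops_only` minimizes S2 (J axis, fixed L). Ties break toward
#' smaller J, then smaller L (parsimony).
#'
#' @param crit An `fbam_criteria` object from [criterion_table()].
#' @param mode One of "joint", "bands_only", "subpops_only".
#' @return List with `J`, `L`, `index` (row of the table) and `solution`.
#' @export
select_solution <- function(crit, mode = c("joint", "bands_only", "subpops_only")) {
  mode <- match.arg(mode)
  tab <- crit$table
  score <- switch(mode,
    joint = ifelse(tab$J >= 2 & tab$L >= 2, tab$scaled_sum, Inf),
    bands_only = ifelse(!is.na(tab$S1), tab$S1, Inf),
    subpops_only = ifelse(!is.na(tab$S2), tab$S2, Inf)
  )
  score[!is.finite(score)] <- Inf
  if (all(score == Inf)) {
    stop("Selection failed: every grid entry has a degenerate or undefined criterion.",
         call. = FALSE)
  }
  ord <- order(score, tab$J, tab$L)
  best <- ord[1]
  list(J = tab$J[best], L = tab$L[best], index = best,
       solution = crit$solutions[[best]])
}
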