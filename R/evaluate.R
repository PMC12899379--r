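# Scoring recovered structure against simulator ground truth.

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions (Hubert-Arabie form):
#' 1 for identical partitions (up to label permutation), approximately 0 for
#' random agreement.
#'
#' @param labels_a,labels_b Integer (or factor) label vectors of equal
#'   length >= 2.
#' @return Scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("Label vectors must have equal length.", call. = FALSE)
  }
  if (length(labels_a) < 2) stop("Need at least two observations.", call. = FALSE)
  mclust::adjustedRandIndex(labels_a, labels_b)
}

# All permutations of 1..n (n <= 7 in practice).
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub), n - 1L))
  }))
}

#' Match estimated band boundaries to ground truth
#'
#' Matches estimated subpopulations to true subpopulations by the
#' assignment (over all permutations, exact for J <= 6) minimizing the
#' total absolute boundary discrepancy, then reports per-group absolute
#' boundary errors in cycles/sample.
#'
#' @param solution An `fbam_solution`.
#' @param truth An `fbam_sim` with `true_boundaries` (model 1) whose number
#'   of boundaries matches `solution$L - 1`.
#' @param T Series length used to convert cut indices to frequencies.
#' @return List with `errors` (J x (L-1) matrix of absolute errors) and
#'   `assignment` (true group matched to each estimated group).
#' @export
match_boundaries <- function(solution, truth, T) {
  tb <- truth$true_boundaries
  if (is.null(tb)) stop("Ground truth has no band boundaries.", call. = FALSE)
  nb <- length(tb[[1]])
  if (solution$L - 1L != nb) {
    stop(sprintf("Solution has %d boundaries per group but truth has %d.",
                 solution$L - 1L, nb), call. = FALSE)
  }
  J <- solution$J
  if (length(tb) != J) {
    stop("Numbers of subpopulations differ between solution and truth.",
         call. = FALSE)
  }
  est <- do.call(rbind, lapply(solution$cuts, cut_frequency, T = T))
  tru <- do.call(rbind, tb)
  cost <- matrix(0, J, J)
  for (i in seq_len(J)) {
    for (j in seq_len(J)) cost[i, j] <- sum(abs(est[i, ] - tru[j, ]))
  }
  perms <- permutations(J)
  totals <- apply(perms, 1, function(p) sum(cost[cbind(seq_len(J), p)]))
  best <- unname(perms[which.min(totals), ])
  errors <- abs(est - tru[best, , drop = FALSE])
  list(errors = errors, assignment = best)
}

#' Replicated simulation-and-recovery experiment
#'
#' For each replication: generate a simulated population, estimate spectra,
#' fit the (J, L) grid, and score the selected solution (adjusted Rand
#' index against the true memberships, selected J and L). Per-replication
#' seeds are derived from the master seed, so the experiment is
#' reproducible and replications are order-independent.
#'
#' @param model Simulation model passed to [simulate_fbam_model()].
#' @param K_j Replicates per subpopulation.
#' @param T Series length.
#' @param n_reps Number of independent replications.
#' @param j_grid,l_grid Candidate grids.
#' @param control GA settings from [fbam_control()].
#' @param seed Integer master seed.
#' @return An object of class `fbam_eval`: a list with `results` (tibble
#'   with one row per replication: rep, ari, J, L, loss) and the experiment
#'   settings.
#' @export
batch_evaluate <- function(model, K_j, T, n_reps = 10, j_grid = 2:4,
                           l_grid = 2:4, control = fbam_control(),
                           seed = 1L) {
  stopifnot(n_reps >= 1)
  results <- purrr::map_dfr(seq_len(n_reps), function(r) {
    rep_seed <- derive_seed(seed, 7L, r)
    sim <- simulate_fbam_model(model, K_j = K_j, T = T, seed = rep_seed)
    spectra <- estimate_spectra(sim$data)
    fit <- fit_grid(spectra, j_grid, l_grid, control = control,
                    seed = derive_seed(rep_seed, 11L))
    tibble::tibble(
      rep = r,
      ari = adjusted_rand_index(sim$true_labels, fit$best$labels),
      J = fit$selected[["J"]], L = fit$selected[["L"]],
      loss = fit$best$loss
    )
  })
  structure(list(results = results, model = model, K_j = K_j, T = T,
                 n_reps = n_reps, j_grid = j_grid, l_grid = l_grid,
                 seed = seed),
            class = "fbam_eval")
}

#' @export
print.fbam_eval <- function(x, ...) {
  cat(sprintf("<fbam_eval> model %s, K_j = %d, T = %d, %d replications\n",
              x$model, x$K_j, x$T, x$n_reps))
  print(glance.fbam_eval(x))
  invisible(x)
}

#' @describeIn batch_evaluate Per-replication results as a tibble.
#' @param x An `fbam_eval`.
#' @param ... Unused.
#' @export
tidy.fbam_eval <- function(x, ...) x$results

#' @describeIn batch_evaluate One-row summary (means and SDs, modal J and
#'   L) in the style of a simulation-study results table.
#' @export
glance.fbam_eval <- function(x, ...) {
  r <- x$results
  modal <- function(v) as.integer(names(which.max(table(v))))
  tibble::tibble(
    mean_ari = mean(r$ari), sd_ari = sd(r$ari),
    mean_J = mean(r$J), sd_J = sd(r$J), modal_J = modal(r$J),
    mean_L = mean(r$L), sd_L = sd(r$L), modal_L = modal(r$L),
    n_reps = nrow(r)
  )
}
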