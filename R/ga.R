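#' Genetic algorithm control parameters
#'
#' Defaults follow the island-model design used throughout the package:
#' 6 islands of 50 chromosomes, ring migration of 5 chromosomes every 50
#' generations, mutation-only variation with per-entry mutation probability
#' 0.05 and 2 offspring per parent, and a stopping rule of 500 generations
#' or a 100-generation stall of the global elite.
#'
#' @param population_size Chromosomes per island.
#' @param n_islands Number of islands evolving in parallel populations.
#' @param migration_interval Generations between ring migrations.
#' @param n_migrants Chromosomes exchanged per migration.
#' @param mutation_prob Per-entry mutation probability in (0, 1], or `NULL`
#'   (default) for the standard one-over-chromosome-length rule
#'   `1 / (K + J * (L - 1))`, which keeps the expected number of modified
#'   entries per offspring near one regardless of problem size.
#' @param offspring_per_parent Offspring produced by each parent per
#'   generation.
#' @param max_generations Hard cap on generations per island.
#' @param stall_generations Stop when the global elite has not improved (at
#'   relative tolerance 1e-10) for this many generations.
#' @param w_min Minimum band width in Fourier frequencies.
#' @return A list of class `fbam_control`.
#' @export
fbam_control <- function(population_size = 50, n_islands = 6,
                         migration_interval = 50, n_migrants = 5,
                         mutation_prob = NULL, offspring_per_parent = 2,
                         max_generations = 500, stall_generations = 100,
                         w_min = 5) {
  ctl <- list(population_size = as.integer(population_size),
              n_islands = as.integer(n_islands),
              migration_interval = as.integer(migration_interval),
              n_migrants = as.integer(n_migrants),
              mutation_prob = mutation_prob,
              offspring_per_parent = as.integer(offspring_per_parent),
              max_generations = as.integer(max_generations),
              stall_generations = as.integer(stall_generations),
              w_min = as.integer(w_min))
  stopifnot(ctl$population_size >= 1, ctl$n_islands >= 1,
            ctl$migration_interval >= 1,
            ctl$n_migrants <= ctl$population_size,
            is.null(ctl$mutation_prob) ||
              (ctl$mutation_prob > 0 && ctl$mutation_prob <= 1),
            ctl$offspring_per_parent >= 1, ctl$max_generations >= 1,
            ctl$stall_generations >= 1, ctl$w_min >= 1)
  structure(ctl, class = "fbam_control")
}

cut_jitter <- function(M) as.integer(ceiling(0.05 * M))

# Per-entry mutation probability: explicit value, or 1/(chromosome length).
effective_pm <- function(control, K, J, L) {
  if (!is.null(control$mutation_prob)) return(control$mutation_prob)
  1 / (K + J * max(L - 1, 0))
}

#' Draw a random valid solution
#'
#' Labels are uniform over 1..J then repaired so every subpopulation is
#' nonempty; each subpopulation's cuts are a sorted uniform draw of valid
#' positions respecting the minimum band width.
#'
#' @param K Number of series.
#' @param M Number of Fourier frequencies.
#' @param J,L Numbers of subpopulations and bands.
#' @param w_min Minimum band width.
#' @return An `fbam_solution` (loss not yet evaluated).
#' @export
random_solution <- function(K, M, J, L, w_min = 5) {
  if (J > K) stop("Infeasible: more subpopulations than series (J > K).", call. = FALSE)
  if (L * w_min > M) {
    stop("Infeasible: L * w_min exceeds the number of Fourier frequencies.",
         call. = FALSE)
  }
  labels <- sample.int(J, K, replace = TRUE)
  miss <- setdiff(seq_len(J), unique(labels))
  for (j in miss) {
    counts <- tabulate(labels, J)
    big <- which.max(counts)
    members <- which(labels == big)
    labels[members[sample.int(length(members), 1)]] <- j
  }
  cuts <- lapply(seq_len(J), function(j) as.integer(cpp_random_cuts(M, L, w_min)))
  new_solution(labels, cuts, M, w_min)
}

#' Mutate a solution
#'
#' Each label entry is independently resampled uniformly over 1..J with
#' probability `mutation_prob`; each cut is independently jittered with the
#' same probability by a nonzero uniform integer offset of at most
#' `ceiling(0.05 * M)`, then repaired (sorted, clamped, minimum band width
#' enforced; infeasible partitions resampled). Empty subpopulations are
#' repaired by reassigning a random member of the largest one.
#'
#' @param solution An `fbam_solution`.
#' @param control An [fbam_control()] list (supplies `mutation_prob`,
#'   `w_min`).
#' @return A valid mutated `fbam_solution` (loss cache cleared).
#' @export
mutate_solution <- function(solution, control = fbam_control()) {
  pm <- effective_pm(control, length(solution$labels), solution$J, solution$L)
  res <- cpp_mutate(solution$labels, flatten_cuts(solution$cuts),
                    solution$J, solution$L, solution$M,
                    pm, cut_jitter(solution$M), solution$w_min)
  new_solution(res$labels, unflatten_cuts(res$cuts, solution$J, solution$L),
               solution$M, solution$w_min)
}

new_island <- function(pre, K, J, L, control) {
  pop <- control$population_size
  labels <- matrix(0L, pop, K)
  nc <- if (L > 1) J * (L - 1L) else 0L
  cuts <- matrix(0L, pop, nc)
  losses <- numeric(pop)
  for (p in seq_len(pop)) {
    sol <- random_solution(K, pre$M, J, L, control$w_min)
    labels[p, ] <- sol$labels
    if (nc > 0) cuts[p, ] <- flatten_cuts(sol$cuts)
    losses[p] <- solution_loss(pre, sol$labels, flatten_cuts(sol$cuts), J, L)
  }
  ord <- order(losses)
  best <- ord[1]
  list(labels = labels[ord, , drop = FALSE], cuts = cuts[ord, , drop = FALSE],
       losses = losses[ord], elite_labels = labels[best, ],
       elite_cuts = if (nc > 0) cuts[best, ] else integer(),
       elite_loss = losses[best])
}

#' Evolve an island for a number of generations
#'
#' One generation: every parent produces `offspring_per_parent` mutated
#' offspring; parents and offspring are ranked by loss and the best
#' `population_size` survive; the previous generation's elite then replaces
#' the current worst chromosome, and the elite is updated.
#'
#' @param state Island state as produced internally by [run_ga()] (fields
#'   `labels`, `cuts`, `losses`, `elite_labels`, `elite_cuts`, `elite_loss`).
#' @param spectra An `fbam_spectra` object.
#' @param J,L Dimensions of the solutions on this island.
#' @param control An [fbam_control()] list.
#' @param n_generations Number of generations to run.
#' @return The updated island state.
#' @export
evolve_island <- function(state, spectra, J, L, control = fbam_control(),
                          n_generations = 1) {
  pre <- spectra_cumsums(spectra)
  res <- cpp_evolve_island(pre$CS, pre$total_ss, pre$T,
                           state$labels, state$cuts, state$losses,
                           as.integer(J), as.integer(L),
                           effective_pm(control, nrow(spectra$power), J, L),
                           control$offspring_per_parent,
                           cut_jitter(pre$M), control$w_min,
                           state$elite_labels, state$elite_cuts,
                           state$elite_loss, as.integer(n_generations))
  res
}

#' Ring migration between islands
#'
#' For islands i = 2..I, a random set of `n_migrants` chromosomes from
#' island i-1's pre-migration population replaces the same number of
#' randomly selected chromosomes of island i. For i = 1, `n_migrants`
#' random chromosomes from island I replace those that island 1 sent to
#' island 2. Cached losses travel with the chromosomes.
#'
#' @param islands List of island states.
#' @param control An [fbam_control()] list.
#' @return The list of island states after migration.
#' @export
migrate <- function(islands, control = fbam_control()) {
  I <- length(islands)
  if (I < 2) {
    warning("Migration with a single island is a no-op.")
    return(islands)
  }
  N <- control$n_migrants
  prev <- islands # pre-migration snapshot
  pop <- nrow(islands[[1]]$labels)
  sent_from_1 <- NULL
  for (i in seq.int(2L, I)) {
    src <- sample.int(pop, N)
    dst <- sample.int(pop, N)
    if (i == 2L) sent_from_1 <- src
    islands[[i]]$labels[dst, ] <- prev[[i - 1]]$labels[src, , drop = FALSE]
    islands[[i]]$cuts[dst, ] <- prev[[i - 1]]$cuts[src, , drop = FALSE]
    islands[[i]]$losses[dst] <- prev[[i - 1]]$losses[src]
  }
  src <- sample.int(pop, N)
  islands[[1]]$labels[sent_from_1, ] <- prev[[I]]$labels[src, , drop = FALSE]
  islands[[1]]$cuts[sent_from_1, ] <- prev[[I]]$cuts[src, , drop = FALSE]
  islands[[1]]$losses[sent_from_1] <- prev[[I]]$losses[src]
  islands
}

#' Minimize the band/cluster objective for fixed (J, L)
#'
#' Runs the island-model genetic algorithm: islands evolve independently
#' with mutation, truncation selection and elitism, exchanging chromosomes
#' in a ring every `migration_interval` generations. Stops at
#' `max_generations` or when the global elite has not improved (relative
#' tolerance 1e-10) for `stall_generations` generations.
#'
#' @param spectra An `fbam_spectra` object.
#' @param J,L Numbers of subpopulations and bands.
#' @param control An [fbam_control()] list.
#' @param seed Optional integer seed for a fully reproducible run.
#' @param verbose If `TRUE`, emit one log line per island and migration
#'   epoch (generation count and island elite loss).
#' @return The best `fbam_solution` found, with its loss cached.
#' @export
run_ga <- function(spectra, J, L, control = fbam_control(), seed = NULL,
                   verbose = FALSE) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, run_ga(spectra, J, L, control,
                                         verbose = verbose)))
  }
  K <- nrow(spectra$power)
  M <- ncol(spectra$power)
  J <- as.integer(J); L <- as.integer(L)
  if (J > K || L * control$w_min > M || J < 1 || L < 1) {
    stop(sprintf("Infeasible grid cell (J = %d, L = %d) for K = %d, M = %d.",
                 J, L, K, M), call. = FALSE)
  }
  pre <- spectra_cumsums(spectra)
  pre$M <- M

  if (J == 1L && L == 1L) {
    sol <- new_solution(rep(1L, K), list(integer()), M, control$w_min)
    sol$loss <- solution_loss(pre, sol$labels, integer(), 1L, 1L)
    return(sol)
  }

  islands <- lapply(seq_len(control$n_islands), function(i)
    new_island(pre, K, J, L, control))
  best_loss <- min(vapply(islands, `[[`, numeric(1), "elite_loss"))
  gens_done <- 0L
  stall <- 0L
  jit <- cut_jitter(M)
  pm <- effective_pm(control, K, J, L)
  while (gens_done < control$max_generations) {
    step <- min(control$migration_interval,
                control$max_generations - gens_done)
    for (i in seq_along(islands)) {
      isl <- cpp_evolve_island(
        pre$CS, pre$total_ss, pre$T, islands[[i]]$labels, islands[[i]]$cuts,
        islands[[i]]$losses, J, L, pm,
        control$offspring_per_parent, jit, control$w_min,
        islands[[i]]$elite_labels, islands[[i]]$elite_cuts,
        islands[[i]]$elite_loss, step)
      # memetic polish of the island elite: exact band segmentation given
      # labels (DP) alternated with best-fit reassignment of replicates
      ref <- cpp_refine(pre$CS, pre$CS2, pre$total_ss, pre$T,
                        isl$elite_labels, isl$elite_cuts, J, L,
                        control$w_min, 25L)
      if (ref$loss < isl$elite_loss - 1e-12) {
        isl$elite_labels <- ref$labels
        isl$elite_cuts <- ref$cuts
        isl$elite_loss <- ref$loss
        worst <- which.max(isl$losses)
        isl$labels[worst, ] <- ref$labels
        if (length(ref$cuts) > 0) isl$cuts[worst, ] <- ref$cuts
        isl$losses[worst] <- ref$loss
      }
      islands[[i]] <- isl
      if (verbose) {
        message(sprintf("generation %d island %d elite loss %.6g",
                        gens_done + step, i, isl$elite_loss))
      }
    }
    gens_done <- gens_done + step
    new_best <- min(vapply(islands, `[[`, numeric(1), "elite_loss"))
    if (best_loss - new_best > 1e-10 * max(1, abs(best_loss))) {
      stall <- 0L
    } else {
      stall <- stall + step
    }
    best_loss <- min(best_loss, new_best)
    if (stall >= control$stall_generations) break
    if (gens_done < control$max_generations && length(islands) > 1) {
      islands <- migrate(islands, control)
    }
  }
  ib <- which.min(vapply(islands, `[[`, numeric(1), "elite_loss"))
  el <- islands[[ib]]
  sol <- new_solution(el$elite_labels, unflatten_cuts(el$elite_cuts, J, L),
                      M, control$w_min)
  sol$loss <- el$elite_loss
  sol
}

#' Fit the objective over a (J, L) grid and select a final solution
#'
#' Runs [run_ga()] for every grid cell (with per-cell seeds derived
#' deterministically from `seed`), builds the criterion table, and applies
#' the requested selection mode.
#'
#' @param spectra An `fbam_spectra` object.
#' @param j_grid,l_grid Integer vectors of candidate J and L values.
#' @param control An [fbam_control()] list.
#' @param mode Selection mode passed to [select_solution()].
#' @param seed Integer master seed (defaults to 1).
#' @return An object of class `fbam_fit`; see [fbam()].
#' @export
fit_grid <- function(spectra, j_grid = 2:6, l_grid = 2:6,
                     control = fbam_control(),
                     mode = c("joint", "bands_only", "subpops_only"),
                     seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(j_grid) >= 1, length(l_grid) >= 1)
  if (length(j_grid) == 1 && j_grid[1] == 1 && mode == "joint") {
    mode <- "bands_only"
  }
  if (length(l_grid) == 1 && l_grid[1] == 1 && mode == "joint") {
    mode <- "subpops_only"
  }
  cells <- expand.grid(J = sort(unique(as.integer(j_grid))),
                       L = sort(unique(as.integer(l_grid))))
  cells <- cells[order(cells$J, cells$L), ]
  solutions <- purrr::pmap(cells, function(J, L) {
    run_ga(spectra, J, L, control, seed = derive_seed(seed, J, L))
  })
  crit <- criterion_table(spectra, solutions)
  sel <- select_solution(crit, mode)
  structure(
    list(table = crit$table, solutions = crit$solutions,
         a1 = crit$a1, a2 = crit$a2,
         selected = c(J = sel$J, L = sel$L), best = sel$solution,
         mode = mode, control = control, spectra = spectra,
         provenance = list(seed = as.integer(seed), T = spectra$T,
                           K = nrow(spectra$power), R = spectra$n_tapers)),
    class = "fbam_fit"
  )
}
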