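test_that("random solutions are valid and repair keeps groups nonempty", {
  set.seed(17)
  sol <- random_solution(10, 60, 1, 1)
  expect_equal(sol$labels, rep(1L, 10))
  expect_equal(sol$cuts, list(integer()))
  solK <- random_solution(5, 60, 5, 2)
  expect_setequal(solK$labels, 1:5)
  for (i in 1:200) {
    s <- random_solution(10, 60, 3, 3)
    expect_setequal(unique(s$labels), 1:3)
    for (cc in s$cuts) expect_true(all(diff(c(1L, cc, 61L)) >= 5))
  }
  expect_error(random_solution(4, 60, 5, 2), "J > K")
  expect_error(random_solution(10, 20, 2, 5), "w_min")
})

test_that("mutation honors the per-entry probability and repair contract", {
  set.seed(18)
  parent <- random_solution(50, 100, 3, 3)
  # p_m = 0 never changes anything (probe via an explicit zero-rate control)
  ctl0 <- fbam_control(mutation_prob = 1e-12)
  off <- mutate_solution(parent, ctl0)
  expect_equal(off$labels, parent$labels)
  expect_equal(off$cuts, parent$cuts)

  # p_m = 1: expected number of changed labels is K (J - 1) / J
  ctl1 <- fbam_control(mutation_prob = 1)
  changed <- replicate(200, sum(mutate_solution(parent, ctl1)$labels != parent$labels))
  expect_lt(abs(mean(changed) - 50 * 2 / 3), 2)

  # offspring always satisfy the solution invariants
  ctl <- fbam_control(mutation_prob = 0.3)
  for (i in 1:100) {
    o <- mutate_solution(parent, ctl)
    expect_setequal(unique(o$labels), 1:3)
    for (cc in o$cuts) {
      expect_true(all(diff(c(1L, cc, 101L)) >= 5))
      expect_true(all(cc >= 2 & cc <= 100))
    }
  }
})

test_that("one generation of island evolution respects elitism", {
  set.seed(19)
  P <- matrix(rexp(8 * 40), 8, 40)
  sp <- make_spectra(P)
  pre <- fbam:::spectra_cumsums(sp)
  pre$M <- 40
  ctl <- fbam_control(population_size = 10, mutation_prob = 0.1)
  isl <- fbam:::new_island(pre, 8, 2, 2, ctl)
  cur <- isl
  for (g in 1:20) {
    nxt <- evolve_island(cur, sp, 2, 2, ctl, n_generations = 1)
    expect_lte(nxt$elite_loss, cur$elite_loss + 1e-12)
    expect_lte(nxt$elite_loss, min(nxt$losses) + 1e-12)
    cur <- nxt
  }
  # a vanishing mutation rate leaves the population unchanged
  ctl0 <- fbam_control(population_size = 10, mutation_prob = 1e-12)
  same <- evolve_island(isl, sp, 2, 2, ctl0, n_generations = 1)
  expect_equal(same$losses, isl$losses)
  expect_equal(same$labels, isl$labels)
})

test_that("ring migration conserves chromosomes and their cached losses", {
  set.seed(20)
  P <- matrix(rexp(6 * 40), 6, 40)
  sp <- make_spectra(P)
  pre <- fbam:::spectra_cumsums(sp)
  pre$M <- 40
  ctl <- fbam_control(population_size = 8, n_islands = 3, n_migrants = 3)
  islands <- lapply(1:3, function(i) fbam:::new_island(pre, 6, 2, 2, ctl))
  out <- migrate(islands, ctl)
  expect_equal(sum(sapply(out, function(i) nrow(i$labels))), 24)
  # every migrated chromosome keeps the loss it arrived with
  for (i in seq_along(out)) {
    for (p in seq_len(8)) {
      sol_loss <- fbam:::solution_loss(pre, out[[i]]$labels[p, ],
                                       out[[i]]$cuts[p, ], 2, 2)
      expect_equal(out[[i]]$losses[p], sol_loss, tolerance = 1e-10)
    }
  }
  # full migration rotates entire populations for i >= 2
  ctlN <- fbam_control(population_size = 8, n_islands = 3, n_migrants = 8)
  prev <- lapply(islands, function(i) i$losses)
  outN <- migrate(islands, ctlN)
  expect_setequal(outN[[2]]$losses, prev[[1]])
  expect_setequal(outN[[3]]$losses, prev[[2]])
  expect_warning(migrate(islands[1], ctl), "single island")
})

test_that("run_ga is reproducible and exact on trivial cells", {
  set.seed(22)
  P <- matrix(rexp(6 * 40), 6, 40)
  sp <- make_spectra(P)
  ctl <- small_control()
  a <- run_ga(sp, 2, 2, control = ctl, seed = 5)
  b <- run_ga(sp, 2, 2, control = ctl, seed = 5)
  expect_identical(a, b)
  one <- run_ga(sp, 1, 1, control = ctl, seed = 5)
  expect_equal(one$labels, rep(1L, 6))
  expect_equal(one$loss, fbam_loss(sp, one))
  expect_error(run_ga(sp, 9, 2, control = ctl), "Infeasible")
})

test_that("run_ga attains the exhaustive optimum on tiny instances", {
  set.seed(23)
  sim <- simulate_fbam_model("1", K_j = 2, T = 64, seed = 3)
  sp <- estimate_spectra(sim$data)
  sp$power <- sp$power[1:6, , drop = FALSE]
  target <- exhaustive_min_loss(sp$power, sp$T)
  sol <- run_ga(sp, 2, 2, control = small_control(), seed = 31)
  expect_equal(sol$loss, target, tolerance = 1e-9)
})

test_that("fit_grid handles singleton grids and is seed-reproducible", {
  pop <- toy_piecewise_population(K_j = 4, M = 60, seed = 46)
  ctl <- small_control()
  fit1 <- fit_grid(pop$spectra, 3, 3, control = ctl, mode = "bands_only",
                   seed = 2)
  expect_equal(nrow(fit1$table), 1L)
  expect_equal(unname(fit1$selected), c(3, 3))
  fit2 <- fit_grid(pop$spectra, 2:3, 2:3, control = ctl, seed = 2)
  fit3 <- fit_grid(pop$spectra, 2:3, 2:3, control = ctl, seed = 2)
  expect_identical(fit2$table, fit3$table)
  expect_identical(fit2$best, fit3$best)
})
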