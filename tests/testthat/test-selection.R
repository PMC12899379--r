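test_that("band similarity matches its oracle and edge cases", {
  # equal band means with nonzero variability: ratio >= 1
  set.seed(12)
  P <- matrix(5 + rnorm(60), 3, 20)
  P[, 11:20] <- 5 + rnorm(30)   # both bands mean ~5
  # force exactly equal band means per construction
  P[, 11:20] <- P[, 11:20] - mean(P[, 11:20]) + mean(P[, 1:10])
  expect_gte(band_similarity(P, 11, 1), 1)

  # exactly piecewise-constant at two distinct levels: ratio 0
  Pc <- matrix(rep(c(3, 9), times = c(10, 10)), 4, 20, byrow = TRUE)
  expect_equal(band_similarity(Pc, 11, 1), 0)
  expect_error(band_similarity(Pc, 11, 2), "1..L-1")
  expect_error(band_similarity(matrix(1, 2, 20), 11, 1), "Degenerate")

  # random instance vs direct-loop oracle
  set.seed(13)
  P3 <- matrix(rexp(36), 3, 12)
  expect_equal(band_similarity(P3, 7, 1), oracle_r1(P3, 7, 1),
               tolerance = 1e-10)
  # scale invariance
  expect_equal(band_similarity(17 * P3, 7, 1), band_similarity(P3, 7, 1),
               tolerance = 1e-12)
})

test_that("subpopulation similarity matches its oracle and is symmetric", {
  set.seed(14)
  Pi <- matrix(rexp(48, 0.5), 4, 12)
  Pj <- matrix(rexp(36, 0.2), 3, 12)
  ci <- 6L; cj <- 8L
  v <- subpop_similarity(Pi, Pj, ci, cj)
  expect_equal(v, subpop_similarity(Pj, Pi, cj, ci), tolerance = 1e-12)
  expect_equal(v, oracle_r2(Pi, Pj, ci, cj), tolerance = 1e-10)
  expect_equal(subpop_similarity(3 * Pi, 3 * Pj, ci, cj), v,
               tolerance = 1e-12)

  # two flat groups at distinct levels, zero within variability: ratio 0
  A <- matrix(2, 3, 12); B <- matrix(6, 3, 12)
  expect_equal(subpop_similarity(A, B, 6L, 6L), 0)
  expect_error(subpop_similarity(A, A, 6L, 6L), "Degenerate")
})

test_that("S1 and S2 aggregate the ratios as documented", {
  set.seed(15)
  P <- matrix(rexp(80, 0.3), 4, 20)
  sp <- make_spectra(P)
  sol <- new_solution(rep(1, 4), list(c(8L, 14L)), 20)
  r <- sapply(1:2, function(l) oracle_r1(P, c(8, 14), l))
  expect_equal(criterion_s1(sp, sol), mean(r), tolerance = 1e-10)
  expect_error(criterion_s1(sp, new_solution(rep(1, 4), list(integer()), 20)),
               "L = 1")

  # S2: mean over groups of the worst-case pairwise similarity
  P2 <- rbind(matrix(rexp(40, 1), 2, 20), matrix(rexp(40, 0.3), 2, 20),
              matrix(rexp(40, 0.1), 2, 20))
  sp2 <- make_spectra(P2)
  labels <- rep(1:3, each = 2)
  cuts <- list(10L, 10L, 10L)
  sol2 <- new_solution(labels, cuts, 20)
  R2 <- matrix(NA, 3, 3)
  for (i in 1:2) for (j in (i + 1):3) {
    R2[i, j] <- R2[j, i] <- oracle_r2(P2[labels == i, ], P2[labels == j, ],
                                      10, 10)
  }
  expect_equal(criterion_s2(sp2, sol2), mean(apply(R2, 1, max, na.rm = TRUE)),
               tolerance = 1e-10)
  expect_error(criterion_s2(sp2, new_solution(rep(1, 6), list(10L), 20)),
               "J = 1")
  # J = 2 reduces to the single pairwise ratio
  sol22 <- new_solution(rep(1:2, each = 3), list(10L, 10L), 20)
  expect_equal(criterion_s2(sp2, sol22),
               oracle_r2(P2[1:3, ], P2[4:6, ], 10, 10), tolerance = 1e-10)
})

test_that("criterion table scales both criteria to a common maximum of 1", {
  pop <- toy_piecewise_population()
  sols <- list(
    new_solution(pop$labels, pop$cuts, 120),
    new_solution(pop$labels, list(c(25L, 97L), c(49L, 97L), c(61L, 97L)), 120),
    new_solution(rep(rep(1:2, c(2, 1)), 6)[1:18],
                 list(c(25L, 61L), c(49L, 73L)), 120)
  )
  crit <- criterion_table(pop$spectra, sols)
  expect_equal(max(crit$table$S1 / crit$a1), 1)
  expect_equal(max(crit$table$S2 / crit$a2), 1)
})

test_that("select minimizes the right column with parsimonious tie-breaks", {
  tab <- tibble::tibble(J = c(2, 2, 3, 3), L = c(2, 3, 2, 3),
                        loss = 1, S1 = c(0.4, 0.2, 0.4, 0.3),
                        S2 = c(0.5, 0.5, 0.25, 0.5))
  tab$scaled_sum <- tab$S1 / max(tab$S1) + tab$S2 / max(tab$S2)
  crit <- structure(list(table = tab, solutions = as.list(1:4),
                         a1 = max(tab$S1), a2 = max(tab$S2)),
                    class = "fbam_criteria")
  expect_equal(select_solution(crit, "joint")$index, 2L)
  expect_equal(select_solution(crit, "bands_only")[c("J", "L")],
               list(J = 2, L = 3))
  expect_equal(select_solution(crit, "subpops_only")[c("J", "L")],
               list(J = 3, L = 2))

  # ties break toward smaller J then smaller L
  tab2 <- tab
  tab2$S1 <- 0.3; tab2$S2 <- 0.5
  tab2$scaled_sum <- tab2$S1 / 0.3 + tab2$S2 / 0.5
  crit2 <- structure(list(table = tab2, solutions = as.list(1:4),
                          a1 = 0.3, a2 = 0.5), class = "fbam_criteria")
  expect_equal(select_solution(crit2, "joint")$index, 1L)

  # degenerate (infinite) criteria are never selected
  tab3 <- tab
  tab3$S2[2] <- Inf
  tab3$scaled_sum <- tab3$S1 / max(tab3$S1) + tab3$S2 / max(tab3$S2[is.finite(tab3$S2)])
  crit3 <- structure(list(table = tab3, solutions = as.list(1:4),
                          a1 = max(tab3$S1), a2 = 0.5), class = "fbam_criteria")
  expect_false(select_solution(crit3, "joint")$index == 2L)
})

test_that("on noiseless piecewise data S1 picks the true L and S2 the true J", {
  pop <- toy_piecewise_population(K_j = 8, M = 120, seed = 44)
  sp <- pop$spectra
  ctl <- small_control()
  fit <- fit_grid(sp, 2:4, 2:4, control = ctl, seed = 9)
  tabJ3 <- fit$table[fit$table$J == 3, ]
  expect_equal(tabJ3$L[which.min(tabJ3$S1)], 3)
  tabL3 <- fit$table[fit$table$L == 3, ]
  expect_equal(tabL3$J[which.min(tabL3$S2)], 3)
  expect_equal(unname(fit$selected), c(3, 3))
})
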