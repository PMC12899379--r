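test_that("collapsed power reproduces step levels and brute-force means", {
  P <- matrix(3, 4, 20)
  cm <- collapsed_power(P, c(8, 14))
  expect_equal(cm$per_replicate, matrix(3, 4, 3))
  expect_equal(cm$per_band_mean, rep(3, 3))
  expect_equal(cm$band_sizes, c(7, 6, 7))

  step <- rep(c(2, 7), times = c(5, 5))
  cm2 <- collapsed_power(matrix(step, 1, 10, byrow = TRUE), 6)
  expect_equal(cm2$per_band_mean, c(2, 7))

  set.seed(5)
  P3 <- matrix(rexp(30), 3, 10)
  cm3 <- collapsed_power(P3, 6)
  manual <- cbind(rowMeans(P3[, 1:5]), rowMeans(P3[, 6:10]))
  expect_equal(cm3$per_replicate, manual)
  expect_equal(cm3$per_band_mean, colMeans(manual))
  expect_error(collapsed_power(P3, c(3, 6)), "w_min")
})

test_that("mean collapsed spectrum is the band-mean step function", {
  set.seed(6)
  P <- matrix(runif(40, 1, 5), 4, 10)
  cm1 <- collapsed_power(P, integer())
  expect_equal(mean_collapsed_spectrum(cm1, integer(), 10), rep(mean(P), 10))
  cm2 <- collapsed_power(P, 6)
  y <- mean_collapsed_spectrum(cm2, 6, 10)
  expect_equal(sum(y), sum(cm2$band_sizes * cm2$per_band_mean))
})

test_that("refine_partition validates and inserts cuts", {
  expect_equal(refine_partition(integer(), 10, 30), 10L)
  expect_equal(refine_partition(c(10), 20, 30), c(10L, 20L))
  expect_error(refine_partition(c(10), 10, 30), "Duplicate")
  expect_error(refine_partition(c(10), 12, 30), "w_min")
})

test_that("loss matches hand algebra and the triple-loop oracle", {
  # identical piecewise-constant spectra aligned with the bands: zero loss
  step <- rep(c(4, 1), times = c(10, 10))
  sp0 <- make_spectra(matrix(step, 3, 20, byrow = TRUE))
  sol0 <- new_solution(rep(1, 3), list(11L), 20)
  expect_equal(fbam_loss(sp0, sol0), 0)

  # two flat spectra, J = 1, L = 1: loss = (M/T) (c1 - c2)^2 / 2
  M <- 24; T <- 50
  sp1 <- make_spectra(rbind(rep(2, M), rep(5, M)), T = T)
  sol1 <- new_solution(c(1, 1), list(integer()), M)
  expect_equal(fbam_loss(sp1, sol1), (M / T) * (5 - 2)^2 / 2)

  # random instances against the elementwise loop oracle, R and C++ paths
  set.seed(7)
  for (i in 1:5) {
    K <- sample(4:10, 1); M <- sample(30:50, 1); J <- sample(1:3, 1)
    L <- sample(1:3, 1)
    P <- matrix(rexp(K * M, 0.2), K, M)
    sp <- make_spectra(P)
    labels <- sort(rep_len(seq_len(J), K))
    cuts <- replicate(J, sort(sample(seq(6, M - 5), L - 1)), simplify = FALSE)
    cuts <- lapply(cuts, function(cc) if (L == 1) integer() else as.integer(cc))
    ok <- !any(vapply(cuts, function(cc) any(diff(c(1, cc, M + 1)) < 5), TRUE))
    if (!ok) next
    sol <- new_solution(labels, cuts, M)
    expect_equal(fbam_loss(sp, sol), oracle_loss(P, sp$T, labels, cuts),
                 tolerance = 1e-10)
    pre <- fbam:::spectra_cumsums(sp)
    expect_equal(fbam:::solution_loss(pre, labels, unlist(cuts), J, L),
                 fbam_loss(sp, sol), tolerance = 1e-10)
  }
})

test_that("refining a partition never increases the loss", {
  set.seed(8)
  for (i in 1:10) {
    K <- 5; M <- 60
    P <- matrix(rexp(K * M), K, M)
    sp <- make_spectra(P)
    cut1 <- sample(seq(6, M - 4), 1)
    sol1 <- new_solution(rep(1, K), list(as.integer(cut1)), M)
    valid <- setdiff(seq(6, M - 4), (cut1 - 4):(cut1 + 4))
    cut2 <- sample(valid, 1)
    sol2 <- new_solution(rep(1, K),
                         list(refine_partition(cut1, cut2, M)), M)
    expect_lte(fbam_loss(sp, sol2), fbam_loss(sp, sol1) + 1e-12)
  }
})

test_that("splitting a subpopulation never increases the minimized loss", {
  set.seed(9)
  for (i in 1:5) {
    K <- 8; M <- 40
    P <- matrix(rexp(K * M), K, M)
    sp <- make_spectra(P)
    cuts <- list(as.integer(c(14, 27)))
    sol1 <- new_solution(rep(1, K), cuts, M)
    lab2 <- c(rep(1, 4), rep(2, 4))
    sol2 <- new_solution(lab2, list(cuts[[1]], cuts[[1]]), M)
    expect_lte(fbam_loss(sp, sol2), fbam_loss(sp, sol1) + 1e-12)
  }
})

test_that("loss is invariant to label and within-group permutations", {
  set.seed(10)
  K <- 6; M <- 30
  P <- matrix(rexp(K * M), K, M)
  sp <- make_spectra(P)
  labels <- c(1, 1, 1, 2, 2, 2)
  cuts <- list(10L, 20L)
  base <- fbam_loss(sp, new_solution(labels, cuts, M))
  # swap group identities
  expect_equal(fbam_loss(sp, new_solution(3 - labels, rev(cuts), M)), base)
  # permute replicates within a group
  perm <- c(3, 1, 2, 4, 6, 5)
  sp2 <- make_spectra(P[perm, ])
  expect_equal(fbam_loss(sp2, new_solution(labels[perm], cuts, M)), base)
})

test_that("solution constructor enforces its invariants", {
  expect_error(new_solution(c(1, 1), list(integer(), integer()), 20),
               "every value")
  expect_error(new_solution(c(1, 2), list(10L, integer()), 20), "same number")
  expect_error(new_solution(c(1, 1), list(c(10L, 8L)), 20), "increasing")
})
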