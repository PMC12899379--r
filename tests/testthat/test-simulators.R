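test_that("AR(2) peak parameterization gives the closed-form coefficients", {
  co <- ar2_coefficients(0.25, 0.15)
  expect_equal(unname(co[1]), 0)
  expect_equal(unname(co[2]), -exp(-0.3))
  co2 <- ar2_coefficients(0, 0.5)
  expect_equal(unname(co2[1]), 2 * exp(-0.5))
  expect_equal(unname(co2[2]), -exp(-1))
  for (psi in c(0, 0.1, 0.3, 0.45)) {
    co3 <- ar2_coefficients(psi, 0.2)
    expect_equal(unname(co3[2]), -exp(-0.4))
    expect_lt(abs(co3[2]), 1)
  }
})

test_that("AR(2) spectrum peaks near psi and integrates to the variance", {
  expect_equal(ar2_spectrum(0, 0, 1, c(0.1, 0.2, 0.4)), rep(1, 3))
  co <- ar2_coefficients(0.25, 0.15)
  grid <- seq(0.001, 0.499, by = 0.0005)
  g <- ar2_spectrum(co[1], co[2], 2.25, grid)
  expect_lt(abs(grid[which.max(g)] - 0.25), 0.01)
  # two-sided integral equals the Yule-Walker process variance
  yw <- unname(2.25^2 * (1 - co[2]) /
    ((1 + co[2]) * ((1 - co[2])^2 - co[1]^2)))
  grid2 <- seq(0, 0.5, length.out = 20001)
  g2 <- ar2_spectrum(co[1], co[2], 2.25, grid2)
  integral <- 2 * sum((g2[-1] + g2[-length(g2)]) / 2) * diff(grid2[1:2])
  expect_equal(integral, yw, tolerance = 1e-6)
  expect_error(ar2_spectrum(2, -1, 1, 0.1), "Nonstationary")
})

test_that("AR(2) simulation matches its theoretical moments", {
  expect_equal(simulate_ar2(0.5, -0.2, 0, 100), numeric(100))
  co <- ar2_coefficients(0.25, 0.15)
  yw <- 2.25^2 * (1 - co[2]) / ((1 + co[2]) * ((1 - co[2])^2 - co[1]^2))
  set.seed(24)
  xs <- replicate(50, simulate_ar2(co[1], co[2], 2.25, 4096))
  expect_lt(abs(mean(apply(xs, 2, var)) / yw - 1), 0.1)
  r1 <- mean(apply(xs, 2, function(x) cor(x[-1], x[-4096])))
  expect_lt(abs(r1 - co[1] / (1 - co[2])), 0.05)
})

test_that("piecewise-smooth spectrum has exact plateaus and C1 transitions", {
  freq <- seq(0, 0.4999, by = 1e-4)
  g <- model1_spectrum(freq, c(0.1, 0.25), c(15, 7.5, 2))
  expect_true(all(g[freq < 0.075] == 15))
  expect_true(all(g[freq >= 0.125 & freq < 0.225] == 7.5))
  expect_true(all(g[freq >= 0.275] == 2))
  # continuity: adjacent jumps far below the plateau gap
  expect_lt(max(abs(diff(g))), (15 - 7.5) / 10)
  # midpoint of each transition is the mean of the adjacent levels
  expect_equal(g[which.min(abs(freq - 0.1))], (15 + 7.5) / 2, tolerance = 1e-2)
  expect_equal(g[which.min(abs(freq - 0.25))], (7.5 + 2) / 2, tolerance = 1e-2)
  expect_error(model1_spectrum(freq, c(0.1, 0.12), c(3, 2, 1)), "Overlapping")
})

test_that("spectral synthesis reproduces a target spectrum", {
  T <- 1024
  M <- floor(T / 2) - 1
  expect_equal(simulate_from_spectrum(numeric(M), T), numeric(T))
  expect_error(simulate_from_spectrum(rep(-1, M), T), "nonnegative")
  set.seed(25)
  vars <- replicate(50, var(simulate_from_spectrum(rep(1, M), T)))
  expect_lt(abs(mean(vars) - 1), 0.15)

  # band-averaged multitaper estimates recover the plateau levels
  T2 <- 512
  freq <- seq_len(floor(T2 / 2) - 1) / T2
  g <- model1_spectrum(freq, c(0.1, 0.25), c(15, 7.5, 2))
  est <- colMeans(t(replicate(20, {
    x <- simulate_from_spectrum(g, T2)
    multitaper_spectrum(x, default_taper_count(T2))
  })))
  for (band in list(c(0.01, 0.07), c(0.13, 0.22), c(0.28, 0.49))) {
    sel <- freq > band[1] & freq < band[2]
    expect_lt(abs(mean(est[sel]) / mean(g[sel]) - 1), 0.1)
  }
})

test_that("the generator bakes in the documented parameters", {
  sim <- simulate_fbam_model("2a", K_j = 5, T = 128, seed = 5)
  centers <- c(0.23, 0.25, 0.27)
  expect_true(all(abs(sim$params$psi - centers[sim$true_labels]) <= 0.02))
  expect_true(all(abs(sim$params$bandwidth - 0.15) <= 0.005))

  sim3 <- simulate_fbam_model("3", K_j = 3, T = 128, seed = 6)
  k <- 4  # a replicate from group 2
  p1 <- ar2_coefficients(0, sim3$params$bw1[k])
  p2 <- ar2_coefficients(sim3$params$psi2[k], 0.065)
  freq <- seq_len(63) / 128
  expect_equal(sim3$true_spectra[k, ],
               ar2_spectrum(p1[1], p1[2], 2.5, freq) +
                 ar2_spectrum(p2[1], p2[2], 2, freq))

  sim1 <- simulate_fbam_model("1", K_j = 4, T = 256, seed = 7)
  expect_equal(dim(sim1$data$values), c(12, 256))
  expect_equal(as.vector(table(sim1$true_labels)), rep(4L, 3))
  expect_equal(sim1$true_boundaries[[1]], c(0.1, 0.25))
  expect_true(all(is.finite(sim1$data$values)))
  expect_true(all(sim1$true_spectra >= 0))
  expect_error(simulate_fbam_model("9"), "arg")
})

test_that("peak separation ordering holds across the three AR(2) settings", {
  sep <- sapply(c("2a", "2b", "2c"), function(m) {
    sim <- simulate_fbam_model(m, K_j = 10, T = 128, seed = 8)
    mean(dist(tapply(sim$params$psi, sim$true_labels, mean)))
  })
  expect_true(sep["2c"] > sep["2b"] && sep["2b"] > sep["2a"])
})

test_that("simulation is reproducible under a fixed seed", {
  a <- simulate_fbam_model("2b", K_j = 3, T = 128, seed = 9)
  b <- simulate_fbam_model("2b", K_j = 3, T = 128, seed = 9)
  expect_identical(a$data$values, b$data$values)
  expect_identical(a$params, b$params)
})
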