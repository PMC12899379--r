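# Independent oracles and small fixture builders. The oracles deliberately
# use naive elementwise loops so they share no code with the implementation.

make_spectra <- function(power, T = 2 * (ncol(power) + 1)) {
  structure(
    list(frequencies = seq_len(ncol(power)) / T, power = power,
         n_tapers = 1L, T = T, series_ids = paste0("s", seq_len(nrow(power))),
         sampling_rate = NULL),
    class = "fbam_spectra"
  )
}

band_members <- function(cuts, M) {
  bounds <- c(1, cuts, M + 1)
  lapply(seq_len(length(bounds) - 1), function(l) bounds[l]:(bounds[l + 1] - 1))
}

# Triple-loop evaluation of the least-squares objective.
oracle_loss <- function(power, T, labels, cuts_list) {
  J <- length(cuts_list)
  M <- ncol(power)
  total <- 0
  for (j in seq_len(J)) {
    rows <- which(labels == j)
    bands <- band_members(cuts_list[[j]], M)
    for (band in bands) {
      ybar <- mean(sapply(rows, function(k) mean(power[k, band])))
      for (k in rows) for (m in band) total <- total + (power[k, m] - ybar)^2
    }
  }
  total / T
}

# Direct-loop adjacent-band similarity ratio for one subpopulation.
oracle_r1 <- function(power, cuts, l) {
  M <- ncol(power)
  bands <- band_members(cuts, M)
  b1 <- bands[[l]]; b2 <- bands[[l + 1]]
  y1 <- mean(sapply(seq_len(nrow(power)), function(k) mean(power[k, b1])))
  y2 <- mean(sapply(seq_len(nrow(power)), function(k) mean(power[k, b2])))
  mu <- (length(b1) * y1 + length(b2) * y2) / (length(b1) + length(b2))
  num1 <- 0; num2 <- 0; den <- 0
  for (k in seq_len(nrow(power))) {
    for (m in b1) { num1 <- num1 + (power[k, m] - y1)^2; den <- den + (power[k, m] - mu)^2 }
    for (m in b2) { num2 <- num2 + (power[k, m] - y2)^2; den <- den + (power[k, m] - mu)^2 }
  }
  (sqrt(num1) + sqrt(num2)) / sqrt(den)
}

# Direct-loop pairwise subpopulation similarity ratio.
oracle_r2 <- function(power_i, power_j, cuts_i, cuts_j) {
  M <- ncol(power_i)
  step_of <- function(power, cuts) {
    bands <- band_members(cuts, M)
    y <- numeric(M)
    for (band in bands) {
      lev <- mean(sapply(seq_len(nrow(power)), function(k) mean(power[k, band])))
      y[band] <- lev
    }
    y
  }
  yi <- step_of(power_i, cuts_i)
  yj <- step_of(power_j, cuts_j)
  wi <- 0
  for (k in seq_len(nrow(power_i))) for (m in seq_len(M)) wi <- wi + (power_i[k, m] - yi[m])^2
  wj <- 0
  for (k in seq_len(nrow(power_j))) for (m in seq_len(M)) wj <- wj + (power_j[k, m] - yj[m])^2
  (sqrt(wi / nrow(power_i)) + sqrt(wj / nrow(power_j))) / sqrt(sum((yi - yj)^2))
}

# Hubert-Arabie adjusted Rand index straight from the contingency table.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(as.vector(tab))
  e_row <- sum_comb(rowSums(tab))
  e_col <- sum_comb(colSums(tab))
  expected <- e_row * e_col / choose(n, 2)
  maximum <- (e_row + e_col) / 2
  (idx - expected) / (maximum - expected)
}

# Exhaustive minimizer of the objective for tiny instances with J = 2:
# enumerate all nonempty bipartitions; per group the optimal cuts decouple,
# so scan every valid cut vector per group.
exhaustive_min_loss <- function(power, T, L = 2, w_min = 5) {
  K <- nrow(power); M <- ncol(power)
  stopifnot(L == 2)
  valid_cuts <- seq(1 + w_min, M + 1 - w_min)
  group_best <- function(rows) {
    Pg <- power[rows, , drop = FALSE]
    min(sapply(valid_cuts, function(cut) {
      b1 <- Pg[, 1:(cut - 1), drop = FALSE]
      b2 <- Pg[, cut:M, drop = FALSE]
      (sum((b1 - mean(b1))^2) + sum((b2 - mean(b2))^2)) / T
    }))
  }
  best <- Inf
  for (code in 1:(2^(K - 1) - 1)) {
    lab <- c(1, as.integer(intToBits(code))[seq_len(K - 1)] + 1L)
    g1 <- which(lab == 1); g2 <- which(lab == 2)
    v <- group_best(g1) + group_best(g2)
    if (v < best) best <- v
  }
  best
}

# Piecewise-constant noiseless population: 3 groups with distinct levels and
# boundaries, replicate-level jitter only.
toy_piecewise_population <- function(K_j = 6, M = 120, seed = 42) {
  withr::with_seed(seed, {
    levels <- list(c(15, 7.5, 2), c(25, 12.5, 4), c(35, 17.5, 6))
    cuts <- lapply(list(c(0.21, 0.51), c(0.41, 0.61), c(0.51, 0.81)),
                   function(f) as.integer(round(f * M)))
    P <- do.call(rbind, lapply(1:3, function(j) {
      t(sapply(seq_len(K_j), function(k) {
        lev <- levels[[j]] + runif(3, -2, 2)
        rep(lev, diff(c(1, cuts[[j]], M + 1)))
      }))
    }))
    list(spectra = make_spectra(P, T = 2 * (M + 1)),
         labels = rep(1:3, each = K_j), cuts = cuts)
  })
}

small_control <- function(...) {
  fbam_control(n_islands = 2, population_size = 20, max_generations = 60,
               migration_interval = 20, n_migrants = 3,
               stall_generations = 40, ...)
}
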