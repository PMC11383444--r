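test_that("functional connectivity matches the definitional Pearson formula", {
  set.seed(10)
  x <- matrix(rnorm(200 * 5), 200, 5)
  fc <- compute_fc(x)
  expect_lt(max(abs(fc$values - oracle_pearson_matrix(x))), 1e-12)
  expect_equal(diag(fc$values), rep(1, 5))

  # perfectly (anti-)correlated columns
  y <- cbind(x[, 1], 2 * x[, 1] + 3, -x[, 1])
  fc2 <- compute_fc(y)$values
  expect_equal(fc2[1, 2], 1)
  expect_equal(fc2[1, 3], -1)

  # Pearson is invariant to affine rescaling of a column
  x2 <- x; x2[, 3] <- 5 * x2[, 3] - 7
  expect_lt(max(abs(compute_fc(x2)$values - fc$values)), 1e-12)

  xc <- x; xc[, 2] <- 1
  expect_error(compute_fc(xc), "zero-variance")
})

test_that("intrinsic timescale matches a brute-force autocorrelation oracle", {
  set.seed(11)
  for (i in 1:10) {
    phi <- runif(1, 0, 0.7)
    y <- as.numeric(arima.sim(list(ar = phi), n = 1000))
    expect_lt(abs(compute_int(matrix(y), tr = 0.8) - oracle_int(y, 0.8)), 1e-10)
  }
})

test_that("intrinsic timescale has the documented analytic properties", {
  # alternating signal: lag-1 autocorrelation is negative, so INT = 0
  alt <- rep(c(1, -1), 25)
  expect_identical(compute_int(matrix(alt), tr = 1), 0)

  # linear in the repetition time
  set.seed(12)
  y <- as.numeric(arima.sim(list(ar = 0.5), n = 300))
  expect_equal(compute_int(matrix(y), tr = 2),
               2 * compute_int(matrix(y), tr = 1))

  # invariant to affine rescaling of the signal
  expect_equal(compute_int(matrix(10 * y + 3), tr = 1),
               compute_int(matrix(y), tr = 1))

  expect_error(compute_int(matrix(rep(1, 50)), tr = 1), "constant")
})

test_that("SC normalization follows the volume-product formula", {
  set.seed(13)
  q <- 6
  raw <- matrix(rpois(q * q, 8), q); raw <- raw + t(raw); diag(raw) <- 0
  vol <- runif(q, 1000, 9000)
  out <- normalize_sc(raw, vol)
  expect_lt(max(abs(out$values - oracle_normalize_sc(raw, vol))), 1e-12)
  expect_true(out$normalized)
  expect_equal(diag(out$values), rep(0, q))
  expect_equal(range(out$values[upper.tri(out$values)]), c(0, 1))

  # zeros are preserved (sparse raw); equal volumes preserve entry ordering
  raw[1, 2] <- raw[2, 1] <- 0
  vol_eq <- rep(1234, q)
  out_eq <- normalize_sc(raw, vol_eq)$values
  expect_equal(out_eq == 0, raw == 0)
  ut <- upper.tri(raw)
  expect_equal(order(raw[ut]), order(out_eq[ut]))

  expect_equal(max(abs(normalize_sc(matrix(0, q, q), vol)$values)), 0)
  expect_error(normalize_sc(raw, c(vol[-q], -1)), "positive")
})

test_that("min-max scaling hits its endpoints and conventions", {
  expect_equal(minmax_scale(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_scale(rep(3, 5)), rep(0, 5))
  set.seed(14)
  m <- matrix(rnorm(30), 5)
  s <- minmax_scale(m)
  expect_equal(range(s), c(0, 1))
  expect_error(minmax_scale(c(1, NA)), "non-finite")
})

test_that("anatomical scaling is rank-preserving per column and in [0,1]", {
  set.seed(15)
  tab <- matrix(rlnorm(40 * 4), 40, 4)
  tab[, 2] <- 7                      # constant column
  tab[, 3] <- tab[, 3] - 2           # column with negative values
  s <- scale_anatomical(tab)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(s[, 2], rep(0, 40))
  for (j in c(1, 3, 4)) expect_equal(order(s[, j]), order(tab[, j]))
  expect_error(scale_anatomical(matrix(c(1, Inf), 2)), "non-finite")
  expect_error(scale_anatomical(matrix(c(0, 1), 2), log_fn = "log"),
               "strictly positive")
})

test_that("structure-function coupling matches a rank-based oracle", {
  set.seed(16)
  q <- 12
  sc <- matrix(runif(q * q), q); sc <- (sc + t(sc)) / 2; diag(sc) <- 0
  sc[sc < 0.4] <- 0
  fc <- matrix(runif(q * q, -1, 1), q); fc <- (fc + t(fc)) / 2; diag(fc) <- 1
  fc[3, ] <- round(fc[3, ], 1); fc[, 3] <- fc[3, ]  # introduce ties
  rho <- compute_coupling(sc, fc)
  for (i in seq_len(q)) {
    idx <- setdiff(which(sc[i, ] > 0), i)
    if (length(idx) >= 3)
      expect_lt(abs(rho[i] - oracle_spearman(sc[i, idx], fc[i, idx])), 1e-12)
  }
  expect_true(all(rho >= -1 & rho <= 1))
})

test_that("coupling is +/-1 on monotone constructions and handles sparsity", {
  q <- 6
  sc <- matrix(0, q, q)
  sc[1, 2:6] <- 1:5; sc[2:6, 1] <- 1:5
  fc <- matrix(0, q, q); diag(fc) <- 1
  fc[1, 2:6] <- c(.1, .2, .3, .4, .5); fc[2:6, 1] <- fc[1, 2:6]
  expect_equal(compute_coupling(sc, fc)[1], 1)
  fc[1, 2:6] <- rev(fc[1, 2:6]); fc[2:6, 1] <- fc[1, 2:6]
  expect_equal(compute_coupling(sc, fc)[1], -1)

  # monotone-transform invariance (Spearman property)
  set.seed(17)
  sc2 <- matrix(runif(36), 6); sc2 <- (sc2 + t(sc2)) / 2; diag(sc2) <- 0
  fcr <- matrix(runif(36, -1, 1), 6); fcr <- (fcr + t(fcr)) / 2; diag(fcr) <- 1
  expect_equal(compute_coupling(sc2^3, fcr), compute_coupling(sc2, fcr))

  # fewer than 3 structural connections: flagged and imputed as 0
  rho <- compute_coupling(sc, fc)
  expect_equal(unname(rho[3]), 0)
  expect_true(attr(rho, "imputed")[3])

  expect_error(compute_coupling(matrix(0, 4, 4), diag(4)), "all-zero")
})

test_that("feature table assembly fixes column order and round-trips", {
  set.seed(18)
  q <- 10
  morph <- matrix(rlnorm(q * 9), q, 9, dimnames = list(NULL, morphology_columns()))
  tab <- assemble_as(morph, runif(q, 0, 5), runif(q, -1, 1))
  expect_equal(dim(tab), c(q, 11))
  expect_equal(colnames(tab), c(morphology_columns(), "INT", "Coupling"))
  expect_true(all(tab >= 0 & tab <= 1))

  # 0-column morphology is allowed for ablations
  tab2 <- assemble_as(matrix(0, q, 0), runif(q), runif(q, -1, 1))
  expect_equal(ncol(tab2), 2)

  # names survive file round-trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_matrix(tab, path)
  expect_equal(colnames(read_matrix(path, header = TRUE)), colnames(tab))

  expect_error(assemble_as(morph, runif(3), runif(3)), "row count")
})
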