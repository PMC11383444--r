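test_that("the edge mask is symmetric, bounded and matches the logistic", {
  expect_equal(mask_from_params(matrix(0, 3, 3)), matrix(0.5, 3, 3))
  v <- matrix(0, 2, 2); v[1, 2] <- v[2, 1] <- 1
  m <- mask_from_params(v)
  expect_equal(m[1, 2], 1 / (1 + exp(-2)))
  set.seed(30)
  vr <- matrix(rnorm(49), 7)
  mr <- mask_from_params(vr)
  expect_identical(mr, t(mr))
  expect_true(all(mr > 0 & mr < 1))
  expect_error(mask_from_params(matrix(c(0, NA, 0, 0), 2)), "non-finite")
})

test_that("masked propagation matches the dense oracle and hand examples", {
  # isolated node, zero mask: exact identity mapping
  h <- matrix(c(2, -3), 1)
  expect_equal(masked_gcn_layer(h, matrix(0, 1, 1), matrix(0, 1, 1),
                                diag(2), phi = identity), h)

  # 2-node path, mask 0.5 everywhere: filter computed by hand
  a2 <- matrix(c(0, 1, 1, 0), 2)
  h2 <- matrix(c(1, 2, 3, 4), 2)
  m2 <- matrix(0.5, 2, 2)
  f_hand <- matrix(c(0.75, 0.25, 0.25, 0.75), 2)
  expect_lt(max(abs(masked_gcn_layer(h2, a2, m2, diag(2), phi = identity) -
                      f_hand %*% h2)), 1e-12)

  # random graphs against the dense elementwise oracle
  set.seed(31)
  for (i in 1:20) {
    q <- 10
    a <- rand_sym_graph(q)
    h <- matrix(rnorm(q * 4), q)
    m <- mask_from_params(matrix(rnorm(q * q), q))
    th <- matrix(rnorm(4 * 3), 4, 3)
    expect_lt(max(abs(masked_gcn_layer(h, a, m, th, phi = identity) -
                        oracle_masked_layer(h, a, m, th))), 1e-10)
  }
})

test_that("zero mask makes propagation node-local", {
  set.seed(32)
  q <- 8
  a <- rand_sym_graph(q)
  h <- matrix(rnorm(q * 3), q)
  m0 <- matrix(0, q, q)
  th <- diag(3)
  base <- masked_gcn_layer(h, a, m0, th, phi = identity)
  for (j in 1:q) {
    hp <- h
    hp[j, ] <- hp[j, ] + rnorm(3)
    pert <- masked_gcn_layer(hp, a, m0, th, phi = identity)
    changed <- rowSums(abs(pert - base)) > 1e-12
    expect_equal(which(changed), j)
  }
})

test_that("forward pass is permutation consistent and deterministic", {
  set.seed(33)
  q <- 9; d0 <- 2 * q; dc <- 4
  a <- rand_sym_graph(q)
  h0 <- matrix(rnorm(q * d0), q)
  cm <- matrix(runif(q * dc), q)
  st <- init_model_state(q, d0, dc, d1 = 6, d2 = 5, d_hidden = 4, n_out = 2)
  st$V <- matrix(rnorm(q * q, 0, 0.4), q)
  mk_graph <- function(a, h0, cm) build_graph_raw(a, h0, cm)
  g <- mk_graph(a, h0, cm)
  y0 <- model_forward(g, st)
  expect_length(y0, 2)            # joint two-target readout
  expect_identical(y0, model_forward(g, st))  # deterministic

  for (i in 1:20) {
    p <- sample(q)
    stp <- st
    stp$V <- st$V[p, p]
    # permute the node order everywhere: adjacency, feature rows, AS rows,
    # and both index dimensions of V
    gp <- mk_graph(a[p, p], h0[p, , drop = FALSE], cm[p, , drop = FALSE])
    expect_lt(max(abs(model_forward(gp, stp) - y0)), 1e-8)
  }
})

test_that("an all-zero anatomical block contributes nothing", {
  set.seed(34)
  q <- 6; d0 <- q; dc <- 3
  a <- rand_sym_graph(q)
  h0 <- matrix(rnorm(q * d0), q)
  st <- init_model_state(q, d0, dc, d1 = 4, d2 = 4, d_hidden = 3, n_out = 1)
  g0 <- build_graph_raw(a, h0, matrix(0, q, dc))
  y_zero_c <- suppressWarnings(model_forward(g0, st))

  st_nc <- init_model_state(q, d0, 0, d1 = 4, d2 = 4, d_hidden = 3, n_out = 1)
  st_nc$Theta1 <- st$Theta1
  st_nc$Theta2 <- st$Theta2[1:4, , drop = FALSE]  # drop the fusion rows
  st_nc$W1 <- st$W1; st_nc$b1 <- st$b1; st_nc$W2 <- st$W2; st_nc$b2 <- st$b2
  g_nc <- build_graph_raw(a, h0, matrix(0, q, 0))
  expect_equal(y_zero_c, model_forward(g_nc, st_nc))
})

test_that("analytic gradients agree with finite differences", {
  set.seed(35)
  q <- 5; d0 <- 6; dc <- 2
  a <- rand_sym_graph(q)
  g <- build_graph_raw(a, matrix(rnorm(q * d0), q), matrix(runif(q * dc), q))
  st <- init_model_state(q, d0, dc, d1 = 4, d2 = 3, d_hidden = 3, n_out = 2)
  st$V <- matrix(rnorm(q * q, 0, 0.3), q)
  y <- c(1, -0.5)
  alpha <- 0.05
  lap <- graph_laplacian(a)
  lossfun <- function(s) {
    fw <- model_forward(g, s, keep_cache = TRUE)
    prediction_loss(matrix(fw$yhat, 1), matrix(y, 1), "regression") +
      alpha * manifold_loss(fw$H2, a)
  }
  fw <- model_forward(g, st, keep_cache = TRUE)
  dy <- maskgnn:::prediction_loss_grad(fw$yhat, y, "regression")
  gr <- maskgnn:::model_backward(fw, st, dy, alpha = alpha, lap = lap)
  eps <- 1e-6
  for (nm in c("V", "Theta1", "Theta2", "W1", "b1", "W2", "b2")) {
    num <- st[[nm]] * 0
    for (i in seq_along(num)) {
      sp <- st; sp[[nm]][i] <- sp[[nm]][i] + eps
      sm <- st; sm[[nm]][i] <- sm[[nm]][i] - eps
      num[i] <- (lossfun(sp) - lossfun(sm)) / (2 * eps)
    }
    expect_lt(max(abs(num - gr[[nm]])), 1e-6)
  }
  # the V-gradient is symmetric: only V + V^T enters the model
  expect_equal(gr$V, t(gr$V))
})
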