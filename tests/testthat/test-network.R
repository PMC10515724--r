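# The feedforward network: weight counting, normalization, forward pass,
# Jacobians, initialization and dropout.

test_that("count_weights reproduces the published per-structure counts", {
  # 26-input / 25-output configuration (25 concentrations + volume)
  shallow26 <- function(n) network_layout(25, n, 25, "tanh", "volume")
  deep26 <- function(h) network_layout(25, h, 25, "relu", "volume")
  expect_equal(count_weights(shallow26(1)), 77)
  expect_equal(count_weights(shallow26(2)), 129)
  expect_equal(count_weights(shallow26(5)), 285)
  expect_equal(count_weights(shallow26(7)), 389)
  expect_equal(count_weights(shallow26(12)), 649)
  expect_equal(count_weights(shallow26(15)), 805)
  expect_equal(count_weights(deep26(c(5, 5))), 315)
  expect_equal(count_weights(deep26(c(7, 7))), 445)
  expect_equal(count_weights(deep26(c(10, 10))), 655)
  expect_equal(count_weights(deep26(c(7, 7, 7))), 501)
  expect_equal(count_weights(deep26(c(10, 10, 10))), 765)
  expect_equal(count_weights(deep26(c(15, 15))), 1045)
  expect_equal(count_weights(deep26(c(20, 20))), 1485)
  expect_equal(count_weights(deep26(c(20, 20, 20))), 1905)
  # 30-input / 30-output configuration (concentrations only)
  deep30 <- function(h) network_layout(30, h, 30, "relu")
  expect_equal(count_weights(deep30(7)), 457)
  expect_equal(count_weights(deep30(8)), 518)
  expect_equal(count_weights(deep30(17)), 1067)
  expect_equal(count_weights(deep30(18)), 1128)
  expect_equal(count_weights(deep30(c(7, 7, 7))), 569)
  expect_equal(count_weights(deep30(c(10, 10, 10))), 860)
  expect_equal(count_weights(deep30(c(20, 20, 20))), 2090)
  expect_equal(count_weights(deep30(c(25, 25, 25))), 2855)
  expect_equal(count_weights(deep30(c(30, 30, 30))), 3720)
  # one weight plus one bias
  expect_equal(count_weights(network_layout(1, integer(), 1, "tanh")), 2)
})

test_that("input normalization divides by cmax and appends scaled extras", {
  sp <- species_set(c("Xv", "A", "B"), cmax = c(2, 4, 8))
  expect_equal(normalize_inputs(c(2, 4, 8), sp), c(1, 1, 1))
  expect_equal(normalize_inputs(c(0, 0, 0), sp), c(0, 0, 0))
  lo <- network_layout(3, 2, 3, "tanh", extra_inputs = "volume")
  expect_equal(
    normalize_inputs(c(1, 2, 4), sp, extras = c(volume = 1.6),
                     extras_max = c(volume = 2), layout = lo),
    c(0.5, 0.5, 0.5, 0.8))
  # negative concentrations are clamped before normalization
  expect_equal(normalize_inputs(c(-1, 2, -4), sp), c(0, 0.5, 0))
  expect_error(
    normalize_inputs(c(1, 2, 4), sp, extras = NULL, layout = lo),
    "missing extra input")
})

test_that("forward pass matches hand evaluation and handles ReLU clamp", {
  lo <- network_layout(2, 1, 1, "tanh")
  w <- unflatten_weights(lo, c(1, 0, 0, 2, 0))
  expect_equal(nn_forward(lo, w, c(0.5, 0)), 2 * tanh(0.5))
  # all-zero weights give the zero vector
  lo2 <- network_layout(3, c(4, 2), 3, "tanh")
  expect_equal(nn_forward(lo2, rep(0, count_weights(lo2)), rep(0.3, 3)),
               rep(0, 3))
  # ReLU with all pre-activations negative: output equals the output bias
  lo3 <- network_layout(2, 2, 2, "relu")
  w3 <- unflatten_weights(lo3, c(-1, -1, -1, -1, -0.5, -0.5,   # layer 1
                                 1, 1, 1, 1, 0.7, -0.2))       # layer 2
  expect_equal(nn_forward(lo3, w3, c(0.5, 0.5)), c(0.7, -0.2))
})

test_that("weight flattening round-trips and orders layer-by-layer", {
  lo <- network_layout(2, 2, 1, "tanh")
  wv <- seq_len(count_weights(lo)) / 10
  W <- unflatten_weights(lo, wv)
  # row-major connections then biases: W1 rows, b1, W2, b2
  expect_equal(W$W[[1]], matrix(c(0.1, 0.2, 0.3, 0.4), 2, byrow = TRUE))
  expect_equal(W$b[[1]], c(0.5, 0.6))
  expect_equal(W$W[[2]], matrix(c(0.7, 0.8), 1))
  expect_equal(W$b[[2]], 0.9)
  expect_equal(flatten_weights(W), wv)
})

test_that("both Jacobians agree with central finite differences", {
  for (seed in 1:5) {
    set.seed(seed)
    act <- if (seed %% 2) "tanh" else "relu"
    lo <- network_layout(3, c(4, 3), 2, act)
    nw <- count_weights(lo)
    wv <- runif(nw, -0.8, 0.8)
    H0 <- runif(3, 0.1, 0.9)
    h <- 1e-6
    Jin <- nn_jacobian_inputs(lo, wv, H0)
    Jin_fd <- vapply(1:3, function(j) {
      e <- replace(numeric(3), j, h)
      (nn_forward(lo, wv, H0 + e) - nn_forward(lo, wv, H0 - e)) / (2 * h)
    }, numeric(2))
    expect_lt(max_rel_diff(Jin, Jin_fd), 1e-5)
    Jw <- nn_jacobian_weights(lo, wv, H0)
    Jw_fd <- vapply(seq_len(nw), function(j) {
      e <- replace(numeric(nw), j, h)
      (nn_forward(lo, wv + e, H0) - nn_forward(lo, wv - e, H0)) / (2 * h)
    }, numeric(2))
    expect_lt(max_rel_diff(Jw, Jw_fd), 1e-5)
  }
})

test_that("Jacobian structure: affine nets and output-bias identity block", {
  # no hidden layer: input Jacobian is exactly the weight matrix
  lo <- network_layout(3, integer(), 2, "tanh")
  wv <- c(1, 2, 3, 4, 5, 6, 0.1, 0.2)
  expect_equal(nn_jacobian_inputs(lo, wv, c(0.3, 0.5, 0.7)),
               matrix(c(1, 2, 3, 4, 5, 6), 2, byrow = TRUE))
  # zero weights give a zero input Jacobian
  lo2 <- network_layout(3, 2, 2, "tanh")
  expect_true(all(nn_jacobian_inputs(lo2, rep(0, count_weights(lo2)),
                                     c(0.1, 0.2, 0.3)) == 0))
  # output-bias columns always form an identity block
  set.seed(1)
  wv2 <- runif(count_weights(lo2), -1, 1)
  Jw <- nn_jacobian_weights(lo2, wv2, c(0.1, 0.2, 0.3))
  expect_equal(Jw[, (ncol(Jw) - 1):ncol(Jw)], diag(2))
})

test_that("initialization is uniform on [-0.01, 0.01] and reproducible", {
  lo <- network_layout(25, c(40, 40), 25, "relu", "volume")
  w1 <- flatten_weights(init_weights(lo, seed = 99))
  w2 <- flatten_weights(init_weights(lo, seed = 99))
  expect_identical(w1, w2)
  expect_true(all(abs(w1) <= 0.01))
  # moments of U(-0.01, 0.01): mean 0, sd 0.01/sqrt(3)
  set.seed(1)
  big <- flatten_weights(init_weights(network_layout(99, 300, 99, "relu")))
  n <- length(big)
  expect_gt(n, 1e5 / 2)
  se <- 0.01 / sqrt(3) / sqrt(n)
  expect_lt(abs(mean(big)), 3 * se)
})

test_that("dropout masks drop at the configured rate and are reproducible", {
  lo <- network_layout(5, c(50, 50), 5, "relu")
  set.seed(2)
  m0 <- sample_dropout_mask(lo, 0)
  expect_true(all(unlist(m0$keep) == 1))
  draws <- 100
  set.seed(3)
  kept <- replicate(draws, mean(unlist(sample_dropout_mask(lo, 0.2)$keep)))
  n <- draws * 100
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs((1 - mean(kept)) - 0.2), 3 * se)
  set.seed(5)
  a <- sample_dropout_mask(lo, 0.3)
  set.seed(5)
  b <- sample_dropout_mask(lo, 0.3)
  expect_identical(a, b)
  expect_error(sample_dropout_mask(lo, 1), "degenerate")
})

test_that("inverted dropout is unbiased on a linear (ReLU-positive) path", {
  # positive weights and inputs keep every ReLU pre-activation positive, so
  # the network is linear in its hidden activations and the inverted-dropout
  # expectation equals the maskless forward pass
  set.seed(8)
  lo <- network_layout(3, 6, 2, "relu")
  nw <- count_weights(lo)
  wv <- runif(nw, 0.05, 0.4)
  H0 <- runif(3, 0.2, 0.8)
  v0 <- nn_forward(lo, wv, H0)
  n <- 1e4
  vs <- matrix(0, n, 2)
  set.seed(9)
  for (i in seq_len(n))
    vs[i, ] <- nn_forward(lo, wv, H0, mask = sample_dropout_mask(lo, 0.2))
  se <- apply(vs, 2, sd) / sqrt(n)
  expect_true(all(abs(colMeans(vs) - v0) <= 3 * se))
  # p_drop = 0 leaves the forward pass unchanged
  expect_equal(nn_forward(lo, wv, H0, mask = sample_dropout_mask(lo, 0)), v0)
})
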