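# WMSE, AICc, resampling plans and structure comparison arithmetic.

test_that("wmse matches hand evaluation and its scaling law", {
  expect_equal(wmse(c(1, 2), c(1, 2), c(1, 1)), 0)
  expect_equal(wmse(c(2, 4), c(1, 2), c(1, 2)), 1)
  x <- c(0.3, 1.2, 5); y <- c(0.1, 1.0, 4.5); s <- c(0.2, 0.5, 1)
  expect_equal(wmse(x, y, 2 * s), wmse(x, y, s) / 4)
  # missing measurements are excluded from T
  expect_equal(wmse(c(2, 4, 9), c(1, 2, NA), c(1, 2, 1)), 1)
  expect_error(wmse(1, NA, 1), "empty residual")
  expect_error(wmse(1, 2, 0), "positive")
})

test_that("aicc matches direct evaluation of the corrected criterion", {
  expect_equal(aicc(1, 100, 10), 20 + 220 / 89)
  expect_equal(aicc(exp(1), 50, 5), 50 + 10 + 60 / 44)
  # strictly increasing in the training error
  w <- seq(0.5, 5, by = 0.5)
  a <- vapply(w, aicc, numeric(1), T = 200, nw = 20)
  expect_true(all(diff(a) > 0))
  # decomposition: aicc(w) - aicc(1) = T ln(w) exactly
  expect_equal(aicc(2.7, 120, 15) - aicc(1, 120, 15), 120 * log(2.7))
  expect_error(aicc(1, 10, 10), "T > nw \\+ 1")
  expect_error(aicc(0, 100, 10), "positive")
})

test_that("resampling plans partition experiments disjointly and reproducibly", {
  ids <- sprintf("exp%02d", 1:24)
  plan <- resample_partitions(ids, n_partitions = 10, n_test = 4, seed = 42)
  expect_length(plan$partitions, 10)
  for (p in plan$partitions) {
    expect_length(p$test, 4)
    expect_length(p$train, 20)
    expect_length(intersect(p$train, p$test), 0)
    expect_setequal(c(p$train, p$test), ids)
  }
  plan2 <- resample_partitions(ids, 10, 4, seed = 42)
  expect_identical(plan, plan2)
})

test_that("partition plans are exchangeable under label permutation", {
  ids <- sprintf("e%d", 1:9)
  set.seed(77)
  perm <- sample(ids)
  plan_a <- resample_partitions(ids, 5, 4, seed = 3)
  plan_b <- resample_partitions(perm, 5, 4, seed = 3)
  # the permuted plan selects the same positions, hence the relabeled sets
  map <- setNames(perm, ids)
  for (i in 1:5)
    expect_setequal(plan_b$partitions[[i]]$test,
                    unname(map[plan_a$partitions[[i]]$test]))
})

test_that("compare_structures reproduces the published percentage deltas", {
  # experimental-style campaign: best shallow (17 nodes) vs best deep
  shallow_exp <- list(train = 1.57, test = 2.46, weights = 1067)
  deep_exp <- list(train = 1.35, test = 1.88, weights = 2855)
  d <- compare_structures(shallow_exp, deep_exp)
  expect_equal(round(d$reduction_pct[["train"]], 1), 14.0)
  expect_equal(round(d$reduction_pct[["test"]], 1), 23.6)
  expect_equal(round(d$increase_pct[["weights"]], 1), 167.6)
  d_rev <- compare_structures(deep_exp, shallow_exp)
  # the published 30.8 rounds the exact quotient 30.85
  expect_lt(abs(d_rev$increase_pct[["test"]] - 30.8), 0.11)
  expect_equal(round(d_rev$increase_pct[["train"]], 1), 16.3)
  # synthetic study: best shallow (12 nodes) vs best deep (10x10x10)
  shallow_syn <- list(train = 1.54, test = 2.04, test_noisefree = 2.06,
                      weights = 649)
  deep_syn <- list(train = 0.982, test = 1.05, test_noisefree = 0.54,
                   weights = 765)
  d2 <- compare_structures(shallow_syn, deep_syn)
  expect_equal(round(d2$reduction_pct[["train"]], 1), 36.2)
  expect_equal(round(d2$reduction_pct[["test_noisefree"]], 1), 73.8)
  expect_equal(round(d2$reduction_pct[["test"]], 1), 48.5)
  expect_equal(round(d2$increase_pct[["weights"]], 1), 17.9)
  # identical summaries: all differences zero
  d0 <- compare_structures(shallow_exp, shallow_exp)
  expect_true(all(d0$reduction_pct == 0) && all(d0$increase_pct == 0))
})

test_that("selection_report flags the minimum mean test WMSE structure", {
  mk <- function(label, test_mean, aicc_mean, nw) {
    out <- data.frame(structure = label, trainer = "adam", n_weights = nw,
                      train_wmse_mean = test_mean * 0.8, train_wmse_sd = 0.1,
                      test_wmse_mean = test_mean, test_wmse_sd = 0.2,
                      test_wmse_noisefree_mean = NA_real_,
                      test_wmse_noisefree_sd = NA_real_,
                      aicc_mean = aicc_mean, aicc_sd = 1,
                      n_unstable = 0L, n_partitions = 3L)
    class(out) <- c("structure_eval", class(out))
    out
  }
  rep <- selection_report(list(mk("a", 2.5, 900, 100),
                               mk("b", 1.9, 1100, 200),
                               mk("c", 2.2, 800, 300)))
  expect_equal(rep$structure[rep$selected], "b")
  expect_equal(rep$structure[rep$selected_aicc], "c")
  # unstable (NA) structures can never be selected
  bad <- mk("d", NA_real_, NA_real_, 50)
  rep2 <- selection_report(list(mk("a", 2.5, 900, 100), bad))
  expect_equal(rep2$structure[rep2$selected], "a")
})

test_that("evaluate_structure trains per partition and reports statistics", {
  # four zero-noise experiments generated by one known network, with
  # varied initial states and feed rates so the kinetics are identifiable
  # from the training subset alone
  # the runs share the inoculum and differ only in feed rate, so any
  # held-out run stays inside the state region the others cover (an exact
  # fit of the visited manifold then transfers)
  sc <- self_consistent_problem(21, hidden = 1)
  ds <- sc$dataset
  sp <- ds$species
  m_true <- hybrid_model(sp, sc$layout, sc$w_true, vmax = 2, substep = 0.5)
  times <- seq(0, 36, by = 3)
  ds$experiments <- list()
  for (k in 1:4) {
    streams <- list(feed_stream(
      c(0, 5, 1), data.frame(t_start = 0, t_end = 36,
                             rate = 0.006 + 0.003 * (k - 1))))
    tr <- integrate_rk4(m_true, list(c = c(1, 4, 2), V = 1.2), streams,
                        times)
    ds$experiments[[paste0("e", k)]] <-
      experiment(paste0("e", k), times, tr$conc,
                 matrix(0.05, length(times), 3), c0 = c(1, 4, 2), V0 = 1.2,
                 streams = streams)
  }
  plan <- resample_partitions(experiment_ids(ds), 1, 1, seed = 9)
  # with zero-noise data the validation augmentation uses a (near-)zero
  # noise rule so the kept iterate is the exact fit
  ev <- evaluate_structure(
    sc$layout, ds, plan, trainer = "lmm",
    config = lmm_config(max_iterations = 300, restarts = 5, seed = 3,
                        patience = 300,
                        validation_error_model =
                          error_model_absolute(frac = 0, floor_frac = 1e-9)))
  expect_equal(ev$n_weights, count_weights(sc$layout))
  expect_equal(ev$n_partitions, 1)
  expect_true(is.finite(ev$train_wmse_mean))
  # zero-noise self-generated data with an exact-capacity net fits the
  # held-out experiment essentially exactly
  expect_lt(ev$test_wmse_mean, 1e-4)
  detail <- attr(ev, "detail")
  expect_equal(nrow(detail), 1)
  expect_false(any(detail$unstable))
})
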