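# Shared fixtures, built in code (no stored data).

.fixtures <- new.env(parent = emptyenv())

# the standard 9-run synthetic dataset (memoized; ~15 s to build)
shared_synth_dataset <- function() {
  if (is.null(.fixtures$ds))
    .fixtures$ds <- synthetic_cho_dataset(seed = 1L)
  .fixtures$ds
}

# a small random hybrid problem: 3 species (Xv + 2 metabolites), a small
# network, one feed stream, measurements from a perturbed true model
tiny_problem <- function(seed, hidden = 2, activation = "tanh",
                         n_times = 4, noise_sd = 0.1, substep = 0.5) {
  sp <- species_set(c("Xv", "A", "B"), cmax = c(5, 10, 8))
  lo <- network_layout(3, hidden, 3, activation, extra_inputs = "volume")
  nw <- count_weights(lo)
  streams <- list(feed_stream(
    c(0, 5, 1), data.frame(t_start = 0, t_end = 30, rate = 0.01)))
  times <- seq(0, 24, length.out = n_times)
  # rejection loop: random weights occasionally make the autocatalytic
  # system blow up; redraw (deterministically) until both the true and the
  # starting model integrate (ReLU nets are unbounded, so this matters)
  for (try in 0:20) {
    set.seed(seed + 7717 * try)
    w_true <- runif(nw, -0.15, 0.15)
    w_start <- runif(nw, -0.2, 0.2)
    m_true <- hybrid_model(sp, lo, w_true, vmax = 2, substep = substep)
    tr <- tryCatch(
      integrate_rk4(m_true, list(c = c(1, 4, 2), V = 1.2), streams, times),
      hybridfb_divergence = function(e) NULL)
    if (is.null(tr) || max(abs(tr$conc)) > 50) next
    meas <- tr$conc + matrix(rnorm(length(tr$conc), sd = noise_sd),
                             nrow = n_times)
    e <- experiment("e1", times, meas, matrix(0.5, n_times, 3),
                    c0 = c(1, 4, 2), V0 = 1.2, streams = streams)
    ds <- experiment_dataset(list(e), sp, vmax = 2)
    m_start <- hybrid_model(sp, lo, w_start, vmax = 2, substep = substep)
    ok <- tryCatch(is.finite(dataset_wmse(m_start, ds)$wmse),
                   hybridfb_divergence = function(e) FALSE)
    if (ok)
      return(list(model = m_start, dataset = ds, w_true = w_true,
                  w_start = w_start, layout = lo, species = sp,
                  streams = streams, times = times))
  }
  stop("could not build a stable tiny problem for seed ", seed)
}

# zero-noise self-generated dataset: data produced by a known network, so a
# net of identical layout can fit it exactly
self_consistent_problem <- function(seed, hidden = 2, sigma = 0.05) {
  sp <- species_set(c("Xv", "A", "B"), cmax = c(5, 10, 8))
  lo <- network_layout(3, hidden, 3, "tanh", extra_inputs = "volume")
  streams <- list(feed_stream(
    c(0, 5, 1), data.frame(t_start = 0, t_end = 36, rate = 0.01)))
  times <- seq(0, 36, by = 6)
  for (try in 0:20) {
    set.seed(seed + 7717 * try)
    w_true <- runif(count_weights(lo), -0.3, 0.3)
    m_true <- hybrid_model(sp, lo, w_true, vmax = 2, substep = 0.5)
    tr <- tryCatch(
      integrate_rk4(m_true, list(c = c(1, 4, 2), V = 1.2), streams, times),
      hybridfb_divergence = function(e) NULL)
    if (is.null(tr) || max(abs(tr$conc)) > 50) next
    e <- experiment("e1", times, tr$conc,
                    matrix(sigma, length(times), 3), c0 = c(1, 4, 2),
                    V0 = 1.2, streams = streams)
    return(list(model = hybrid_model(sp, lo, vmax = 2, substep = 0.5),
                dataset = experiment_dataset(list(e), sp, vmax = 2),
                w_true = w_true, layout = lo))
  }
  stop("could not build a stable self-consistent problem for seed ", seed)
}

max_rel_diff <- function(a, b) {
  max(abs(a - b)) / max(max(abs(a)), max(abs(b)), 1e-300)
}
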