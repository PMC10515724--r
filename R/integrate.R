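# Fixed-step RK4 integration of the hybrid (or any kinetic) fed-batch model.
#
# The substep grid between two output points is uniform; feed-schedule
# breakpoints force additional step boundaries so that every substep sees a
# constant feed rate (evaluated at the substep midpoint).

build_step_grid <- function(output_times, streams, substep) {
  output_times <- as.numeric(output_times)
  if (any(diff(output_times) <= 0))
    stop("output times must be strictly increasing")
  if (inherits(streams, "feed_stream")) streams <- list(streams)
  brk <- unlist(lapply(streams, function(s)
    c(s$schedule$t_start, s$schedule$t_end)))
  breaks <- sort(unique(c(output_times, brk)))
  breaks <- breaks[breaks >= output_times[1] &
                   breaks <= output_times[length(output_times)]]
  # drop breakpoints numerically identical to an output time
  keep <- !duplicated(round(breaks / max(substep * 1e-9, 1e-12)))
  breaks <- breaks[keep]
  grid <- numeric(0)
  for (i in seq_len(length(breaks) - 1L)) {
    n <- max(1L, ceiling((breaks[i + 1] - breaks[i]) / substep - 1e-9))
    seg <- seq(breaks[i], breaks[i + 1], length.out = n + 1L)
    grid <- c(grid, seg[-(n + 1L)])
  }
  grid <- c(grid, breaks[length(breaks)])
  out_idx <- vapply(output_times, function(t) which.min(abs(grid - t)),
                    integer(1))
  if (max(abs(grid[out_idx] - output_times)) > 1e-8)
    stop("internal error: output times not on the substep grid")
  grid[out_idx] <- output_times  # exact
  mid <- (grid[-length(grid)] + grid[-1]) / 2
  Fint <- vapply(streams, function(s)
    vapply(mid, function(t) feed_rate(s, t), numeric(1)),
    numeric(length(mid)))
  Fint <- matrix(Fint, nrow = length(mid))
  list(grid = grid, out_idx = out_idx, Fint = Fint)
}

streams_cin_matrix <- function(streams, n_species) {
  if (inherits(streams, "feed_stream")) streams <- list(streams)
  cin <- vapply(streams, function(s) {
    if (length(s$c_in) != n_species)
      stop("feed composition length does not match the species set")
    s$c_in
  }, numeric(n_species))
  matrix(cin, nrow = n_species)
}

divergence_error <- function(t_fail) {
  stop(structure(
    class = c("hybridfb_divergence", "error", "condition"),
    list(message = sprintf(
      "integration diverged (non-finite state) at t = %g", t_fail),
      call = sys.call(-1), t_fail = t_fail)))
}

new_trajectory <- function(times, conc, V, rates, species) {
  colnames(conc) <- species$names
  colnames(rates) <- species$names
  structure(list(times = times, conc = conc, V = V, rates = rates,
                 species = species), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$times), " time points, ",
      ncol(x$conc), " species, t in [", min(x$times), ", ",
      max(x$times), "]\n", sep = "")
  invisible(x)
}

#' Integrate a model through a fed-batch run with fixed-step RK4
#'
#' The classical 4th-order Runge-Kutta update is applied on a uniform
#' substep grid between output points; feed-schedule breakpoints force
#' additional step boundaries, so the piecewise-constant feed rates are
#' constant within every substep (which also makes the volume balance
#' exact). For a [hybrid_model()] the compiled core is used; for a plain
#' kinetic rate function `v_fun(c, V, t)` (e.g. a ground-truth simulator) a
#' reference R implementation of the same scheme is used.
#'
#' @param model a [hybrid_model()] or a function `v_fun(c, V, t)` returning
#'   the specific-rate vector.
#' @param initial list with `c` (initial concentrations) and `V` (initial
#'   volume > 0).
#' @param streams list of [feed_stream()] objects.
#' @param output_times strictly increasing vector of report times; the
#'   first entry is the initial time.
#' @param substep RK4 substep; defaults to the model's `substep` (0.5 for
#'   the rate-function method).
#' @param project project concentrations onto `>= 0` after each substep
#'   (off by default; the state is normally integrated unconstrained while
#'   only the network inputs are clamped).
#' @param ... further arguments for methods; the function method accepts
#'   `species` and `xv`.
#' @return a `trajectory`: output times, concentration matrix, volume
#'   vector and the specific-rate vector recorded at each output time.
#' @export
integrate_rk4 <- function(model, initial, streams, output_times,
                          substep = NULL, project = FALSE, ...) {
  UseMethod("integrate_rk4")
}

#' @rdname integrate_rk4
#' @param mask optional dropout mask applied to the network during the
#'   whole integration (training use only).
#' @export
integrate_rk4.hybrid_model <- function(model, initial, streams, output_times,
                                       substep = NULL, project = FALSE,
                                       mask = NULL, ...) {
  if (is.null(substep)) substep <- model$substep
  g <- build_step_grid(output_times, streams, substep)
  ns <- length(model$species)
  out <- cpp_run(layer_sizes(model$layout), act_code(model$layout),
                 model$weights, mask_scales(mask),
                 unname(model$species$cmax), model$vmax,
                 model$xv_index - 1L, model$vmax > 0, model$clamp_inputs,
                 project, as.numeric(initial$c), initial$V, g$grid, g$Fint,
                 streams_cin_matrix(streams, ns), g$out_idx - 1L, 0L,
                 matrix(NaN, length(output_times), ns),
                 matrix(1, length(output_times), ns), FALSE)
  if (!out$ok) divergence_error(out$t_fail)
  new_trajectory(as.numeric(output_times), out$C, drop(out$V), out$rates,
                 model$species)
}

#' @rdname integrate_rk4
#' @param species a [species_set()] (function method).
#' @param xv name of the viable-cell-density species (function method).
#' @export
integrate_rk4.function <- function(model, initial, streams, output_times,
                                   substep = 0.5, project = FALSE,
                                   species = NULL, xv = "Xv", ...) {
  if (is.null(substep)) substep <- 0.5
  stopifnot(inherits(species, "species_set"))
  if (inherits(streams, "feed_stream")) streams <- list(streams)
  g <- build_step_grid(output_times, streams, substep)
  ns <- length(species)
  cin <- streams_cin_matrix(streams, ns)
  xvi <- match(xv, species$names)
  c <- as.numeric(initial$c); V <- initial$V
  nT <- length(output_times)
  conc <- matrix(NA_real_, nT, ns); Vv <- numeric(nT)
  rates <- matrix(NA_real_, nT, ns)
  oi <- 1L
  rhs <- function(c, V, t, F) {
    v <- model(c, V, t)
    Ftot <- sum(F)
    list(dc = v * c[xvi] + drop(cin %*% F) / V - c * (Ftot / V),
         dV = Ftot, v = v)
  }
  record <- function(i) {
    conc[oi, ] <<- c; Vv[oi] <<- V
    rates[oi, ] <<- model(c, V, g$grid[i])
    oi <<- oi + 1L
  }
  if (g$out_idx[oi] == 1L) record(1L)
  for (m in seq_len(length(g$grid) - 1L)) {
    h <- g$grid[m + 1L] - g$grid[m]
    Fm <- g$Fint[m, ]
    t0 <- g$grid[m]
    k1 <- rhs(c, V, t0, Fm)
    k2 <- rhs(c + h / 2 * k1$dc, V + h / 2 * k1$dV, t0 + h / 2, Fm)
    k3 <- rhs(c + h / 2 * k2$dc, V + h / 2 * k2$dV, t0 + h / 2, Fm)
    k4 <- rhs(c + h * k3$dc, V + h * k3$dV, t0 + h, Fm)
    c <- c + h / 6 * (k1$dc + 2 * k2$dc + 2 * k3$dc + k4$dc)
    V <- V + h / 6 * (k1$dV + 2 * k2$dV + 2 * k3$dV + k4$dV)
    if (project) c <- pmax(c, 0)
    if (any(!is.finite(c)) || !is.finite(V)) divergence_error(g$grid[m + 1L])
    if (oi <= nT && g$out_idx[oi] == m + 1L) record(m + 1L)
  }
  new_trajectory(as.numeric(output_times), conc, Vv, rates, species)
}

#' Simulate one experiment of a dataset with a hybrid model
#'
#' Convenience wrapper: integrates the model from the experiment's initial
#' state through its feed schedule and reports at the measurement times.
#'
#' @param model a [hybrid_model()].
#' @param exp one experiment of an [experiment_dataset()].
#' @param substep optional RK4 substep override.
#' @return a `trajectory`.
#' @export
simulate_experiment <- function(model, exp, substep = NULL) {
  integrate_rk4(model, initial = list(c = exp$c0, V = exp$V0),
                streams = exp$streams, output_times = exp$times,
                substep = substep)
}
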