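# Synthetic fed-batch data generator.
#
# A reduced, fully documented CHO-like kinetic model (Monod growth on
# glucose and glutamine, overflow lactate production switching to lactate
# consumption on glucose depletion, ammonium production from glutaminolysis
# with late consumption, growth-coupled amino-acid uptake, product
# synthesis stepped up at an induction time) drives the same fed-batch
# balances as the hybrid model. A two-factor central composite design over
# the pre- and post-induction feed rates yields 9 simulated reactor runs;
# heterogeneous Gaussian noise (SD = a fraction of each species' maximum)
# turns the noiseless trajectories into measurement-like datasets.

synthetic_species_names <- function() {
  c("Xv", "mAb", "Ala", "Arg", "Asn", "Asp", "Cys", "Glc", "Gln", "Glu",
    "Pyr", "Gly", "His", "Ile", "Lac", "Leu", "Lys", "Met", "NH4", "Phe",
    "Pro", "Ser", "Thr", "Tyr", "Val")
}

experimental_species_names <- function() {
  c("Xv", "P", "Glc", "Lac", "Gln", "Glu", "NH4", "Pyr", "Glyc", "Cit",
    "Ala", "Arg", "Asn", "Asp", "Lcystin", "Gly", "His", "Ile", "Leu",
    "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val", "Ac",
    "For")
}

#' Kinetic parameters of the reduced CHO-like ground-truth model
#'
#' Units: viable cell density in 1e9 cells/L, metabolites in mM, product
#' in g/L, time in h; specific rates are per 1e9 cells per hour. The
#' defaults give a culture that seeds at 3e9 cells/L, peaks near
#' 20-28e9 cells/L, runs glutamine down over the first four days
#' (triggering the lactate production-to-consumption shift) and
#' accumulates a few g/L of product after induction.
#'
#' @param t_induction induction time (h): the product-synthesis rate steps
#'   up and the feed composition switches (emulating a temperature-shift
#'   induction).
#' @param ... named overrides of individual parameters.
#' @return a parameter list of class `cho_kinetics`.
#' @export
cho_kinetics <- function(t_induction = 96, ...) {
  p <- list(
    mu_max = 0.05, K_glc = 0.5, K_gln = 0.5, K_inh4 = 4.0,
    kd0 = 0.0015, kd_gln = 0.008, K_dgln = 0.3,
    Y_x_glc = 0.55, m_glc = 0.012, Km_glc = 0.5,
    y_lac = 1.4, K_over = 10, q_lac_cons = 0.035, K_lac = 1.5,
    K_lac_gln = 0.3,
    Y_x_gln = 5.5, m_gln = 0.003, Km_gln = 0.2,
    y_nh4 = 0.80, q_nh4_cons = 0.004, K_nh4 = 1.0, K_igln = 0.5,
    y_glu = 0.10, a_glu = 0.05,
    a_pyr = 0.08, m_pyr = 0.004,
    q_p0 = 5e-4, q_p1 = 1.2e-3, K_p = 0.5, t_induction = t_induction,
    y_ala = 0.25, m_ala = 0.003,
    K_aa = 0.5, m_aa = 0.001,
    a_aa = c(Arg = 0.08, Asn = 0.18, Asp = 0.07, Cys = 0.04, Gly = 0.06,
             His = 0.04, Ile = 0.12, Leu = 0.18, Lys = 0.14, Met = 0.05,
             Phe = 0.07, Pro = 0.09, Ser = 0.20, Thr = 0.11, Tyr = 0.06,
             Val = 0.14, Trp = 0.03, Lcystin = 0.04),
    # extra first-order pools of the 30-species (experimental-style) roster
    a_glyc = 0.04, m_glyc = 0.001, a_cit = 0.03, m_cit = 0.001,
    y_ac = 0.06, y_for = 0.03)
  over <- list(...)
  stopifnot(all(names(over) %in% names(p)))
  p[names(over)] <- over
  structure(p, class = "cho_kinetics")
}

#' Specific-rate function of the ground-truth model
#'
#' Returns a closure `v_fun(c, V, t)` suitable for
#' [integrate_rk4()] over the given species roster (the 25-variable
#' synthetic roster or the 30-variable experimental-style roster). All
#' uptake terms saturate (Monod) so rates vanish smoothly at zero
#' concentration; concentrations are clamped at zero before evaluating
#' kinetics.
#'
#' @param params a [cho_kinetics()] parameter set.
#' @param species a [species_set()] whose names come from
#'   [synthetic_species()] or [experimental_style_species()].
#' @return function `(c, V, t) -> v` (per-species specific rates).
#' @export
cho_rate_function <- function(params, species) {
  p <- params
  nm <- species$names
  idx <- setNames(seq_along(nm), nm)
  prod_name <- if ("mAb" %in% nm) "mAb" else "P"
  aa_names <- intersect(names(p$a_aa), nm)
  monod <- function(x, K) x / (K + x)
  function(c, V, t) {
    c <- pmax(c, 0)
    glc <- c[idx[["Glc"]]]; gln <- c[idx[["Gln"]]]
    lac <- c[idx[["Lac"]]]; nh4 <- c[idx[["NH4"]]]
    mu <- p$mu_max * monod(glc, p$K_glc) * monod(gln, p$K_gln) *
      p$K_inh4 / (p$K_inh4 + nh4)
    kd <- p$kd0 + p$kd_gln * p$K_dgln / (p$K_dgln + gln)
    q_glc_up <- mu / p$Y_x_glc + p$m_glc * monod(glc, p$Km_glc)
    q_gln_up <- mu / p$Y_x_gln + p$m_gln * monod(gln, p$Km_gln)
    v <- numeric(length(nm))
    v[idx[["Xv"]]] <- mu - kd
    v[idx[["Glc"]]] <- -q_glc_up
    v[idx[["Gln"]]] <- -q_gln_up
    v[idx[["Lac"]]] <- p$y_lac * (mu / p$Y_x_glc) * monod(glc, p$K_over) -
      p$q_lac_cons * monod(lac, p$K_lac) * p$K_lac_gln / (p$K_lac_gln + gln)
    v[idx[["NH4"]]] <- p$y_nh4 * q_gln_up -
      p$q_nh4_cons * monod(nh4, p$K_nh4) * p$K_igln / (p$K_igln + gln)
    v[idx[["Glu"]]] <- p$y_glu * q_gln_up -
      mu * p$a_glu * monod(c[idx[["Glu"]]], p$K_aa)
    if ("Pyr" %in% nm)
      v[idx[["Pyr"]]] <- -(mu * p$a_pyr + p$m_pyr) *
        monod(c[idx[["Pyr"]]], p$K_aa)
    v[idx[[prod_name]]] <- (p$q_p0 +
      p$q_p1 * as.numeric(t >= p$t_induction)) * monod(glc, p$K_p)
    v[idx[["Ala"]]] <- p$y_ala * q_gln_up -
      p$m_ala * monod(c[idx[["Ala"]]], p$K_aa)
    for (aa in aa_names)
      v[idx[[aa]]] <- -(mu * p$a_aa[[aa]] + p$m_aa) *
        monod(c[idx[[aa]]], p$K_aa)
    if ("Glyc" %in% nm)
      v[idx[["Glyc"]]] <- -(mu * p$a_glyc + p$m_glyc) *
        monod(c[idx[["Glyc"]]], p$K_aa)
    if ("Cit" %in% nm)
      v[idx[["Cit"]]] <- -(mu * p$a_cit + p$m_cit) *
        monod(c[idx[["Cit"]]], p$K_aa)
    if ("Ac" %in% nm) v[idx[["Ac"]]] <- p$y_ac * mu / p$mu_max * 0.02
    if ("For" %in% nm) v[idx[["For"]]] <- p$y_for * mu / p$mu_max * 0.02
    v
  }
}

synthetic_initial_state <- function(nm) {
  base <- c(Xv = 3, mAb = 0, P = 0, Glc = 40, Gln = 4.5, Glu = 0.6,
            Pyr = 1.0, Lac = 1.5, NH4 = 0.6, Ala = 0.8, Arg = 1.5,
            Asn = 2.5, Asp = 1.0, Cys = 0.8, Lcystin = 0.8, Gly = 1.2,
            His = 0.8, Ile = 1.8, Leu = 2.5, Lys = 2.0, Met = 0.8,
            Phe = 1.2, Pro = 1.5, Ser = 2.5, Thr = 1.8, Trp = 0.6,
            Tyr = 1.0, Val = 2.2, Glyc = 1.0, Cit = 0.8, Ac = 0.2,
            For = 0.1)
  unname(base[nm])
}

synthetic_feed_composition <- function(nm, phase = c("pre", "post")) {
  phase <- match.arg(phase)
  cin <- setNames(numeric(length(nm)), nm)
  aa6 <- 6 * synthetic_initial_state(nm)
  aa <- intersect(c("Arg", "Asn", "Asp", "Cys", "Lcystin", "Gly", "His",
                    "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                    "Thr", "Trp", "Tyr", "Val"), nm)
  cin[aa] <- aa6[match(aa, nm)]
  cin["Glc"] <- if (phase == "pre") 350 else 260
  cin["Gln"] <- if (phase == "pre") 35 else 25
  if ("Pyr" %in% nm) cin["Pyr"] <- if (phase == "pre") 5 else 8
  if ("Glu" %in% nm) cin["Glu"] <- 2
  cin
}

#' Central composite design over the two feed rates
#'
#' Builds the 9-run two-factor central composite design: 4 factorial
#' points at coded (+-1, +-1), 4 axial (star) points at (+-alpha, 0) and
#' (0, +-alpha), and 1 center point, mapped to physical feed rates as
#' `center + coded * half_range`.
#'
#' @param center physical center values `c(pre, post)` of the pre- and
#'   post-induction feed rates (volume/time).
#' @param half_range physical half-ranges of the two factors (> 0).
#' @param alpha axial scaling; the default `sqrt(2)` makes the design
#'   rotatable (all non-center points on a circle of radius sqrt(2) in
#'   coded units).
#' @return a `doe_plan` data.frame: run id, coded and physical factor
#'   levels, and the role (`center` / `factorial` / `axial`).
#' @export
ccdoe_feed_rates <- function(center = c(pre = 5e-4, post = 8e-4),
                             half_range = c(pre = 1.5e-4, post = 2.5e-4),
                             alpha = sqrt(2)) {
  stopifnot(all(half_range > 0), alpha > 0)
  coded <- rbind(
    expand.grid(pre = c(-1, 1), post = c(-1, 1)),
    data.frame(pre = c(-alpha, alpha, 0, 0),
               post = c(0, 0, -alpha, alpha)),
    data.frame(pre = 0, post = 0))
  role <- c(rep("factorial", 4), rep("axial", 4), "center")
  plan <- data.frame(
    run = sprintf("run%02d", seq_len(9)),
    role = role,
    coded_pre = coded$pre, coded_post = coded$post,
    F_pre = center[[1]] + coded$pre * half_range[[1]],
    F_post = center[[2]] + coded$post * half_range[[2]],
    stringsAsFactors = FALSE)
  if (any(plan$F_pre < 0) || any(plan$F_post < 0))
    stop("design maps to negative feed rates; shrink half_range or alpha")
  class(plan) <- c("doe_plan", class(plan))
  plan
}

#' Species roster of the synthetic dataset
#'
#' The 25 recorded extracellular variables of the synthetic configuration
#' (viable cells, monoclonal antibody, central carbon metabolites and
#' amino acids). `cmax` defaults to 1 and is replaced by the observed
#' maxima when a dataset is generated.
#'
#' @param cmax optional normalization maxima.
#' @return a [species_set()].
#' @export
synthetic_species <- function(cmax = NULL) {
  nm <- synthetic_species_names()
  if (is.null(cmax)) cmax <- rep(1, length(nm))
  units <- ifelse(nm == "Xv", "1e9 cells/L",
                  ifelse(nm == "mAb", "g/L", "mM"))
  species_set(nm, cmax, units)
}

#' Species roster of the experimental-style dataset (30 variables)
#' @param cmax optional normalization maxima.
#' @return a [species_set()].
#' @export
experimental_style_species <- function(cmax = NULL) {
  nm <- experimental_species_names()
  if (is.null(cmax)) cmax <- rep(1, length(nm))
  units <- ifelse(nm == "Xv", "1e9 cells/L",
                  ifelse(nm == "P", "g/L", "mM"))
  species_set(nm, cmax, units)
}

run_streams <- function(nm, F_pre, F_post, t_induction, horizon,
                        comp_scale = c(1, 1)) {
  pre <- feed_stream(synthetic_feed_composition(nm, "pre") * comp_scale[1],
                     data.frame(t_start = 0,
                                t_end = min(t_induction, horizon),
                                rate = F_pre),
                     id = "pre")
  if (horizon <= t_induction) return(list(pre))
  list(pre,
       feed_stream(synthetic_feed_composition(nm, "post") * comp_scale[2],
                   data.frame(t_start = t_induction, t_end = horizon,
                              rate = F_post),
                   id = "post"))
}

#' Simulate the noiseless ground-truth dataset over a design plan
#'
#' Integrates the ground-truth kinetics through each design run with the
#' fixed-step RK4 scheme (concentrations projected onto >= 0 after each
#' substep) and records the extracellular concentrations, volumes and true
#' specific-rate series at the sampling grid.
#'
#' @param params a [cho_kinetics()] set.
#' @param plan a [ccdoe_feed_rates()] plan.
#' @param horizon process horizon (h).
#' @param sampling sampling interval (h).
#' @param V0 initial volume.
#' @param substep RK4 substep.
#' @return a `ground_truth_sim`: per-run trajectories plus the roster and
#'   shared initial state.
#' @export
simulate_ground_truth <- function(params = cho_kinetics(),
                                  plan = ccdoe_feed_rates(),
                                  horizon = 240, sampling = 24,
                                  V0 = 0.25, substep = 0.5) {
  species <- synthetic_species()
  nm <- species$names
  times <- seq(0, horizon, by = sampling)
  c0 <- synthetic_initial_state(nm)
  v_fun <- cho_rate_function(params, species)
  runs <- lapply(seq_len(nrow(plan)), function(i) {
    streams <- run_streams(nm, plan$F_pre[i], plan$F_post[i],
                           params$t_induction, horizon)
    traj <- integrate_rk4(v_fun, initial = list(c = c0, V = V0),
                          streams = streams, output_times = times,
                          substep = substep, project = TRUE,
                          species = species, xv = "Xv")
    if (any(!is.finite(traj$conc)))
      stop("ground-truth generation diverged for ", plan$run[i])
    list(id = plan$run[i], role = plan$role[i], times = times,
         conc = traj$conc, V = traj$V, rates = traj$rates,
         streams = streams, c0 = c0, V0 = V0)
  })
  structure(list(runs = runs, species = species, params = params,
                 plan = plan, horizon = horizon, sampling = sampling),
            class = "ground_truth_sim")
}

#' Add heterogeneous Gaussian measurement noise to a ground-truth simulation
#'
#' Each species receives independent Gaussian noise with a constant SD
#' equal to `frac` times that species' maximum concentration over the
#' noiseless dataset. Negative noisy values are retained (measurement
#' error can undershoot). The per-point sigma table is stored with the
#' dataset for objective weighting, and the noiseless matrices are kept as
#' `truth` (never used by the trainers). Simulations of the returned
#' experiments start from the known shared inoculation state, not from the
#' noisy first sample.
#'
#' @param sim a [simulate_ground_truth()] result.
#' @param frac noise SD as a fraction of each species' maximum
#'   (default 0.10).
#' @param seed optional RNG seed.
#' @return an [experiment_dataset()] with `truth` attached.
#' @export
add_noise <- function(sim, frac = 0.10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(frac >= 0)
  allconc <- do.call(rbind, lapply(sim$runs, `[[`, "conc"))
  smax <- apply(allconc, 2, max)
  smax <- pmax(smax, 1e-6)
  sdv <- frac * smax
  species <- sim$species
  species$cmax[] <- smax
  exps <- lapply(sim$runs, function(r) {
    noise <- matrix(rnorm(length(r$conc), sd = rep(sdv, each = nrow(r$conc))),
                    nrow = nrow(r$conc))
    meas <- r$conc + if (frac > 0) noise else 0
    sigma <- matrix(pmax(rep(sdv, each = nrow(r$conc)), 1e-9),
                    nrow = nrow(r$conc))
    experiment(r$id, r$times, meas, sigma, c0 = r$c0, V0 = r$V0,
               streams = r$streams, role = r$role)
  })
  truth <- setNames(lapply(sim$runs, `[[`, "conc"),
                    vapply(sim$runs, `[[`, character(1), "id"))
  experiment_dataset(exps, species,
                     truth = truth,
                     provenance = list(generator = "synthetic_cho",
                                       noise_frac = frac,
                                       seed = seed))
}

#' Generate the 9-run synthetic CHO-like fed-batch dataset
#'
#' Convenience wrapper: central composite design over the pre-/post-
#' induction feed rates, ground-truth simulation over a 240 h horizon
#' with 24 h sampling, and Gaussian noise with SD = 10% of each species'
#' maximum.
#'
#' @param seed RNG seed for the noise.
#' @param params a [cho_kinetics()] set.
#' @param plan a [ccdoe_feed_rates()] plan.
#' @param frac noise fraction.
#' @param horizon,sampling time grid (h).
#' @param substep RK4 substep for the ground-truth integration.
#' @return an [experiment_dataset()] (noisy, with truth attached); the
#'   underlying simulation is in `attr(, "sim")`.
#' @export
synthetic_cho_dataset <- function(seed = 1L, params = cho_kinetics(),
                                  plan = ccdoe_feed_rates(), frac = 0.10,
                                  horizon = 240, sampling = 24,
                                  substep = 0.5) {
  sim <- simulate_ground_truth(params, plan, horizon = horizon,
                               sampling = sampling, substep = substep)
  ds <- add_noise(sim, frac = frac, seed = seed)
  attr(ds, "sim") <- sim
  ds
}

#' Design-based train/test split of a generated dataset
#'
#' Training experiments are the center and factorial (square) points of
#' the design; test experiments are the axial (star) points, which sit at
#' the extremes of the design region and make an extrapolating test.
#'
#' @param dataset a generated [experiment_dataset()] whose experiments
#'   carry design roles.
#' @return list with `train` and `test` id vectors.
#' @export
doe_split <- function(dataset) {
  roles <- vapply(dataset$experiments, `[[`, character(1), "role")
  list(train = names(roles)[roles %in% c("center", "factorial")],
       test = names(roles)[roles == "axial"])
}

#' Generate an experimental-style 30-variable dataset
#'
#' Emulates the shape of a process-development campaign: `n_experiments`
#' independent fed-batch runs of the 30-variable roster over ~12 days with
#' daily sampling, per-experiment randomized feed rates and compositions,
#' and a relative measurement-error model (5% for the product, 10% for the
#' viable cell density, 20% for the remaining metabolites, floored at 2%
#' of each species' maximum). This is synthetic stand-in data matching the
#' dimensions of such a campaign, not a reproduction of any real dataset.
#'
#' @param n_experiments number of reactor runs.
#' @param seed RNG seed (feeds and noise).
#' @param horizon process horizon in h (12 days).
#' @param sampling sampling interval in h (daily).
#' @param params a [cho_kinetics()] set.
#' @param V0 initial volume.
#' @param substep RK4 substep for the ground-truth integration.
#' @return an [experiment_dataset()] with `truth` attached.
#' @export
make_experimental_style_dataset <- function(n_experiments = 24, seed = 1L,
                                            horizon = 288, sampling = 24,
                                            params = cho_kinetics(),
                                            V0 = 0.25, substep = 0.5) {
  set.seed(seed)
  species <- experimental_style_species()
  nm <- species$names
  times <- seq(0, horizon, by = sampling)
  c0 <- synthetic_initial_state(nm)
  v_fun <- cho_rate_function(params, species)
  runs <- lapply(seq_len(n_experiments), function(i) {
    F_pre <- 5e-4 * runif(1, 0.6, 1.4)
    F_post <- 8e-4 * runif(1, 0.6, 1.4)
    comp_scale <- runif(2, 0.8, 1.2)
    streams <- run_streams(nm, F_pre, F_post, params$t_induction, horizon,
                           comp_scale = comp_scale)
    traj <- integrate_rk4(v_fun, initial = list(c = c0, V = V0),
                          streams = streams, output_times = times,
                          substep = substep, project = TRUE,
                          species = species, xv = "Xv")
    list(id = sprintf("exp%02d", i), role = NA_character_, times = times,
         conc = traj$conc, V = traj$V, rates = traj$rates,
         streams = streams, c0 = c0, V0 = V0)
  })
  allconc <- do.call(rbind, lapply(runs, `[[`, "conc"))
  smax <- pmax(apply(allconc, 2, max), 1e-6)
  species$cmax[] <- smax
  em <- error_model_relative(rel = c(P = 0.05, Xv = 0.10), default = 0.20,
                             floor_frac = 0.02)
  exps <- lapply(runs, function(r) {
    sigma <- sigma_matrix(em, r$conc, species)
    meas <- r$conc + matrix(rnorm(length(r$conc), sd = as.numeric(sigma)),
                            nrow = nrow(r$conc))
    # sigmas re-derived from the noisy values, as a practitioner would
    sigma_obs <- sigma_matrix(em, meas, species)
    experiment(r$id, r$times, meas, sigma_obs, c0 = r$c0, V0 = r$V0,
               streams = r$streams)
  })
  truth <- setNames(lapply(runs, `[[`, "conc"),
                    vapply(runs, `[[`, character(1), "id"))
  experiment_dataset(exps, species, truth = truth,
                     provenance = list(generator = "experimental_style",
                                       seed = seed, error_model = "relative"))
}
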