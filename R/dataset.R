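#' Build one fed-batch experiment
#'
#' @param id experiment identifier.
#' @param times measurement times (strictly increasing; first entry is the
#'   initial time).
#' @param meas `length(times) x n_species` matrix of measured
#'   concentrations; `NA` marks a missing measurement.
#' @param sigma matrix of per-point measurement standard deviations, same
#'   shape as `meas` (all positive where `meas` is observed).
#' @param c0 initial concentration vector used to start simulations
#'   (typically the measured initial sample, clamped at zero).
#' @param V0 initial culture volume.
#' @param streams list of [feed_stream()] objects.
#' @param role optional label (e.g. the design-point role of a generated
#'   run: `"center"`, `"factorial"`, `"axial"`).
#' @return an object of class `fb_experiment`.
#' @export
experiment <- function(id, times, meas, sigma, c0, V0, streams,
                       role = NA_character_) {
  times <- as.numeric(times)
  meas <- as.matrix(meas); sigma <- as.matrix(sigma)
  stopifnot(nrow(meas) == length(times), all(dim(meas) == dim(sigma)))
  if (any(diff(times) <= 0)) stop("measurement times must increase")
  obs <- !is.na(meas)
  if (any(!is.finite(sigma[obs])) || any(sigma[obs] <= 0))
    stop("sigmas must be positive wherever a measurement exists")
  if (V0 <= 0) stop("initial volume must be positive")
  structure(list(id = as.character(id), times = times, meas = meas,
                 sigma = sigma, c0 = as.numeric(c0), V0 = V0,
                 streams = streams, role = role),
            class = "fb_experiment")
}

#' Bundle experiments into a dataset
#'
#' @param experiments list of [experiment()] objects.
#' @param species the common [species_set()].
#' @param vmax volume normalization maximum for networks with a volume
#'   input; defaults to the largest volume reachable in the bundle (initial
#'   volume plus total fed volume, over all experiments).
#' @param truth optional named list of noiseless measurement matrices
#'   (generator output; never used for training).
#' @param provenance free-form provenance record (e.g. generator seed).
#' @return an object of class `experiment_dataset`.
#' @export
experiment_dataset <- function(experiments, species, vmax = NULL,
                               truth = NULL, provenance = list()) {
  ids <- vapply(experiments, function(e) e$id, character(1))
  if (anyDuplicated(ids)) stop("experiment ids must be unique")
  names(experiments) <- ids
  for (e in experiments)
    if (ncol(e$meas) != length(species))
      stop("experiment ", e$id, ": measurement columns do not match species")
  if (is.null(vmax)) {
    vmax <- max(vapply(experiments, function(e) {
      fed <- sum(vapply(e$streams, function(s)
        sum(s$schedule$rate * (s$schedule$t_end - s$schedule$t_start)),
        numeric(1)))
      e$V0 + fed
    }, numeric(1)))
  }
  structure(list(experiments = experiments, species = species, vmax = vmax,
                 truth = truth, provenance = provenance),
            class = "experiment_dataset")
}

#' @export
print.experiment_dataset <- function(x, ...) {
  cat("<experiment_dataset> ", length(x$experiments), " experiments, ",
      length(x$species), " species, ",
      n_residuals(x), " scalar measurements\n", sep = "")
  invisible(x)
}

#' Experiment ids of a dataset
#' @param dataset an [experiment_dataset()].
#' @return character vector.
#' @export
experiment_ids <- function(dataset) names(dataset$experiments)

#' Restrict a dataset to a subset of experiments
#' @param dataset an [experiment_dataset()].
#' @param ids experiment ids to keep.
#' @return an [experiment_dataset()].
#' @export
subset_dataset <- function(dataset, ids) {
  miss <- setdiff(ids, experiment_ids(dataset))
  if (length(miss)) stop("unknown experiment ids: ", paste(miss, collapse = ", "))
  dataset$experiments <- dataset$experiments[ids]
  if (!is.null(dataset$truth)) dataset$truth <- dataset$truth[ids]
  dataset
}

#' Number of scalar residuals (non-missing measurements) in a dataset
#' @param dataset an [experiment_dataset()].
#' @param ids optional subset of experiment ids.
#' @return integer count `T` used by the weighted objective and by AICc.
#' @export
n_residuals <- function(dataset, ids = NULL) {
  if (is.null(ids)) ids <- experiment_ids(dataset)
  sum(vapply(dataset$experiments[ids],
             function(e) sum(!is.na(e$meas)), numeric(1)))
}

# ---- measurement error models -------------------------------------------

#' Relative measurement-error model
#'
#' Assigns each species a relative standard deviation of the measured
#' value: by default 5% for the product, 10% for the viable cell density
#' and 20% for all remaining metabolites, with a floor expressed as a
#' fraction of the species maximum so that sigma never collapses at zero
#' concentrations.
#'
#' @param rel named numeric vector of relative SDs for specific species.
#' @param default relative SD for species not named in `rel`.
#' @param floor_frac sigma floor as a fraction of the species `cmax`.
#' @return an object of class `error_model`.
#' @export
error_model_relative <- function(rel = c(P = 0.05, Xv = 0.10),
                                 default = 0.20, floor_frac = 0.02) {
  structure(list(type = "relative", rel = rel, default = default,
                 floor_frac = floor_frac), class = "error_model")
}

#' Absolute measurement-error model
#'
#' Assigns each species a constant standard deviation equal to a fraction
#' of its maximum concentration over the dataset (the synthetic-data
#' convention: 10% of the maximum).
#'
#' @param frac fraction of the species maximum.
#' @param floor_frac sigma floor as a fraction of the species `cmax`.
#' @return an object of class `error_model`.
#' @export
error_model_absolute <- function(frac = 0.10, floor_frac = 1e-6) {
  structure(list(type = "absolute", frac = frac, floor_frac = floor_frac),
            class = "error_model")
}

#' Per-point measurement SDs implied by an error model
#'
#' @param error_model an `error_model`.
#' @param meas measurement matrix (times x species).
#' @param species the [species_set()] (supplies names and `cmax`).
#' @return matrix of standard deviations, floored to be positive.
#' @export
sigma_matrix <- function(error_model, meas, species) {
  cm <- unname(species$cmax)
  if (error_model$type == "absolute") {
    sg <- matrix(rep(error_model$frac * cm, each = nrow(meas)),
                 nrow = nrow(meas))
  } else {
    relv <- rep(error_model$default, length(species))
    hit <- match(names(error_model$rel), species$names)
    relv[hit[!is.na(hit)]] <- error_model$rel[!is.na(hit)]
    sg <- sweep(abs(meas), 2, relv, `*`)
  }
  floorv <- pmax(error_model$floor_frac, 1e-12) * cm
  pmax(sg, matrix(rep(floorv, each = nrow(meas)), nrow = nrow(meas)))
}

# ---- objective evaluation ------------------------------------------------

run_experiment_core <- function(model, exp, mode, mask = NULL,
                                substep = NULL, want_jres = FALSE,
                                meas = NULL, sigma = NULL) {
  if (is.null(substep)) substep <- model$substep
  g <- build_step_grid(exp$times, exp$streams, substep)
  ns <- length(model$species)
  if (is.null(meas)) meas <- exp$meas
  if (is.null(sigma)) sigma <- exp$sigma
  meas_na <- meas
  meas_na[is.na(meas_na)] <- NaN
  sigma_na <- sigma
  sigma_na[is.na(sigma_na)] <- 1
  out <- cpp_run(layer_sizes(model$layout), act_code(model$layout),
                 model$weights, mask_scales(mask),
                 unname(model$species$cmax), model$vmax,
                 model$xv_index - 1L, model$vmax > 0, model$clamp_inputs,
                 FALSE, exp$c0, exp$V0, g$grid, g$Fint,
                 streams_cin_matrix(exp$streams, ns), g$out_idx - 1L,
                 as.integer(mode), meas_na, sigma_na, want_jres)
  if (!out$ok) divergence_error(out$t_fail)
  out
}

#' Weighted mean squared error of a model over a dataset
#'
#' Simulates every requested experiment from its initial state and
#' evaluates the weighted objective: the mean over all non-missing scalar
#' measurements of the squared residual divided by the measurement error
#' variance. A model that fits exactly to the noise floor scores about 1.
#'
#' @param model a [hybrid_model()].
#' @param dataset an [experiment_dataset()].
#' @param ids experiment ids to include (default: all).
#' @param weights optional flat weight vector overriding the model's.
#' @param substep optional RK4 substep override.
#' @param mask optional dropout mask (training diagnostics only).
#' @param truth compare against the noiseless truth matrices instead of the
#'   noisy measurements (generated datasets only); sigmas are unchanged.
#' @return list with `wmse`, per-experiment decomposition and the residual
#'   count `T`.
#' @export
dataset_wmse <- function(model, dataset, ids = NULL, weights = NULL,
                         substep = NULL, mask = NULL, truth = FALSE) {
  if (!is.null(weights)) model <- set_model_weights(model, weights)
  if (is.null(ids)) ids <- experiment_ids(dataset)
  if (truth && is.null(dataset$truth))
    stop("dataset carries no noiseless truth")
  ss <- 0; Tn <- 0
  per <- setNames(numeric(length(ids)), ids)
  for (id in ids) {
    e <- dataset$experiments[[id]]
    meas <- if (truth) dataset$truth[[id]] else NULL
    out <- run_experiment_core(model, e, mode = 0L, mask = mask,
                               substep = substep, meas = meas)
    ss <- ss + out$ss; Tn <- Tn + out$nres
    per[id] <- out$ss / max(out$nres, 1)
  }
  if (Tn == 0) stop("no residuals: empty measurement set")
  list(wmse = ss / Tn, per_experiment = per, T = Tn)
}
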