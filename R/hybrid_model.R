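#' Assemble a hybrid model
#'
#' A hybrid model couples the fed-batch material balances with a network
#' that supplies the specific reaction rate of every species:
#' `dc/dt = v(c; w) * Xv + sum_k D_k c_in,k - c * sum_k D_k`,
#' `dV/dt = V * sum_k D_k`, with `D_k = F_k / V`. The volume is a state
#' variable in addition to the measured concentrations.
#'
#' @param species a [species_set()].
#' @param layout a [network_layout()] with `n_conc == length(species)` and
#'   `n_out == length(species)`.
#' @param weights optional `network_weights` or flat vector; defaults to a
#'   fresh uniform initialization (caller controls the RNG).
#' @param vmax volume normalization maximum; required when the layout lists
#'   `"volume"` among its extra inputs.
#' @param xv name of the viable-cell-density species (default `"Xv"`).
#' @param substep default RK4 substep (time units of the schedules; 0.5 h
#'   resolves 24 h sampling comfortably).
#' @param clamp_inputs clamp concentrations at zero before they enter the
#'   network (default TRUE); the state itself is integrated unconstrained.
#' @return an object of class `hybrid_model`.
#' @export
hybrid_model <- function(species, layout, weights = NULL, vmax = NULL,
                         xv = "Xv", substep = 0.5, clamp_inputs = TRUE) {
  stopifnot(inherits(species, "species_set"),
            inherits(layout, "network_layout"))
  if (layout$n_conc != length(species))
    stop("layout concentration inputs must match the species count")
  if (layout$n_out != length(species))
    stop("layout outputs must match the species count (one rate per species)")
  if (!xv %in% species$names)
    stop("Xv species '", xv, "' not found in the species set")
  volin <- "volume" %in% layout$extra_inputs
  extra_unknown <- setdiff(layout$extra_inputs, "volume")
  if (length(extra_unknown))
    stop("unsupported extra inputs: ", paste(extra_unknown, collapse = ", "))
  if (volin && (is.null(vmax) || vmax <= 0))
    stop("vmax must be supplied (and positive) for a volume input")
  if (is.null(weights)) weights <- init_weights(layout)
  structure(
    list(species = species, layout = layout,
         weights = as_flat_weights(layout, weights),
         vmax = if (volin) vmax else -1,
         xv = xv, xv_index = match(xv, species$names),
         substep = substep, clamp_inputs = clamp_inputs),
    class = "hybrid_model")
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat("<hybrid_model> ", length(x$species), " species (Xv = '", x$xv,
      "'), network ", x$layout$n_in, "-[",
      paste(x$layout$hidden, collapse = ","), "]-", x$layout$n_out,
      " (", x$layout$activation, "), ", count_weights(x$layout),
      " weights\n", sep = "")
  invisible(x)
}

set_model_weights <- function(model, wvec) {
  model$weights <- as_flat_weights(model$layout, wvec)
  model
}

#' Time derivatives of the hybrid state
#'
#' Evaluates the fed-batch material balances at one state for a given
#' specific-rate vector: every concentration changes by reaction
#' (`v * Xv`), feed inflow and dilution; the volume grows with the total
#' feed rate.
#'
#' @param state list with `c` (concentration vector), `V` (> 0), `t`.
#' @param v specific reaction rate vector, one entry per species.
#' @param streams list of [feed_stream()] objects.
#' @param species a [species_set()] (used to locate Xv by name).
#' @param xv name of the viable-cell-density species.
#' @return list with `dc` and `dV`.
#' @export
hybrid_rhs <- function(state, v, streams, species, xv = "Xv") {
  v <- as.numeric(v)
  if (length(v) != length(species$names))
    stop("rate vector must have one entry per species")
  d <- dilution_rate(streams, state$t, state$V)
  if (inherits(streams, "feed_stream")) streams <- list(streams)
  feedin <- 0
  for (k in seq_along(streams))
    feedin <- feedin + d$per_stream[k] * streams[[k]]$c_in
  Xv <- state$c[match(xv, species$names)]
  list(dc = v * Xv + feedin - state$c * d$total,
       dV = state$V * d$total)
}
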