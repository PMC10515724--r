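# Exact gradients of the weighted least-squares objective with respect to
# all network weights, computed by forward sensitivity propagation with the
# same RK4 substeps as the states (discretize-then-differentiate: the
# gradients match finite differences of the discrete objective that the
# optimizers actually minimize).

gradient_engine <- function(model, dataset, weights, ids, mask, substep,
                            mode, want_jres) {
  if (!is.null(weights)) model <- set_model_weights(model, weights)
  if (is.null(ids)) ids <- experiment_ids(dataset)
  nw <- count_weights(model$layout)
  ss <- 0; Tn <- 0
  g_ss <- numeric(nw)
  per <- setNames(numeric(length(ids)), ids)
  jres <- if (want_jres) vector("list", length(ids)) else NULL
  resid <- if (want_jres) vector("list", length(ids)) else NULL
  carried <- NULL
  for (i in seq_along(ids)) {
    e <- dataset$experiments[[ids[i]]]
    out <- run_experiment_core(model, e, mode = mode, mask = mask,
                               substep = substep, want_jres = want_jres)
    ss <- ss + out$ss; Tn <- Tn + out$nres
    g_ss <- g_ss + drop(out$g_ss)
    per[ids[i]] <- out$ss / max(out$nres, 1)
    carried <- out$carried_dim
    if (want_jres) {
      jres[[i]] <- out$jres
      resid[[i]] <- out$resid
    }
  }
  if (Tn == 0) stop("no residuals in the requested subset")
  res <- structure(
    list(g = g_ss / Tn, objective = ss / Tn, per_experiment = per, T = Tn,
         carried_dim = carried, method = c("indirect", "semidirect")[mode]),
    class = "gradient_result")
  if (want_jres) {
    res$jacobian <- do.call(rbind, jres)
    res$residuals <- unlist(resid, use.names = FALSE)
  }
  res
}

#' Objective gradient by the indirect sensitivity equations
#'
#' Integrates, jointly with the states and through the same RK4 stages,
#' the sensitivities of the full state vector with respect to every network
#' weight (`dS/dt = J_y S + (df/dv)(dv/dw)`, `S(t0) = 0`), and accumulates
#' the gradient of the weighted mean squared error at the measurement
#' times. The carried sensitivity system has dimension
#' `(n_species + 1) x nw`, growing with the network size.
#'
#' @param model a [hybrid_model()].
#' @param dataset an [experiment_dataset()].
#' @param weights optional flat weight vector overriding the model's.
#' @param ids experiment ids to include (default: all).
#' @param substep optional RK4 substep override.
#' @param return_jacobian also return the weighted residual Jacobian
#'   (one row per residual, `d((c - c*)/sigma)/dw`), used by the
#'   Levenberg-Marquardt trainer.
#' @return a `gradient_result`: flat gradient `g`, the objective (WMSE),
#'   its per-experiment decomposition, the residual count `T` and the
#'   carried sensitivity dimension.
#' @export
indirect_gradient <- function(model, dataset, weights = NULL, ids = NULL,
                              substep = NULL, return_jacobian = FALSE) {
  gradient_engine(model, dataset, weights, ids, mask = NULL,
                  substep = substep, mode = 1L, want_jres = return_jacobian)
}

#' Objective gradient by the semidirect sensitivity equations
#'
#' Carries through the RK4 stage recursion only quantities whose dimension
#' is independent of the number of weights: the per-step state transition
#' and the sensitivities of the state with respect to the network's output
#' channels (`(n_species + 1) x n_out`). These are composed with the
#' network weight Jacobian `dv/d(w,b)` evaluated along the trajectory to
#' assemble the same gradient as [indirect_gradient()] (the two methods
#' factorize the identical discrete derivative, so they agree to numerical
#' round-off). When a dropout mask is supplied, the forward passes and all
#' Jacobians use the masked network.
#'
#' @inheritParams indirect_gradient
#' @param mask optional dropout mask held fixed for the whole evaluation.
#' @return a `gradient_result` (see [indirect_gradient()]); its
#'   `carried_dim` is `c(n_species + 1, n_out)`.
#' @export
semidirect_gradient <- function(model, dataset, weights = NULL, ids = NULL,
                                mask = NULL, substep = NULL,
                                return_jacobian = FALSE) {
  gradient_engine(model, dataset, weights, ids, mask = mask,
                  substep = substep, mode = 2L, want_jres = return_jacobian)
}

#' Finite-difference gradient oracle
#'
#' Central finite differences of the weighted mean squared error, one
#' weight at a time (`O(nw)` objective evaluations). This is a test oracle
#' for the sensitivity engines, not a training tool.
#'
#' @inheritParams semidirect_gradient
#' @param h finite-difference step (> 0).
#' @return numeric gradient vector of length `count_weights`.
#' @export
fd_gradient <- function(model, dataset, weights = NULL, ids = NULL,
                        mask = NULL, substep = NULL, h = 1e-6) {
  stopifnot(h > 0)
  if (!is.null(weights)) model <- set_model_weights(model, weights)
  w <- model$weights
  g <- numeric(length(w))
  for (j in seq_along(w)) {
    wp <- w; wp[j] <- w[j] + h
    wm <- w; wm[j] <- w[j] - h
    fp <- dataset_wmse(model, dataset, ids = ids, weights = wp,
                       substep = substep, mask = mask)$wmse
    fm <- dataset_wmse(model, dataset, ids = ids, weights = wm,
                       substep = substep, mask = mask)$wmse
    g[j] <- (fp - fm) / (2 * h)
  }
  g
}
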