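# Two training regimes for hybrid models:
#   - classical: damped Levenberg-Marquardt on the weighted residuals,
#     indirect sensitivities, noise-augmented cross-validation stopping,
#     best of several random restarts;
#   - deep: ADAM on the weighted objective, semidirect sensitivities,
#     stochastic regularization (experiment minibatches + hidden-node
#     dropout), single initialization, weights kept at the iteration with
#     minimum full-batch training error.

#' ADAM trainer configuration
#'
#' Defaults are the standard ADAM hyperparameters with the stochastic
#' regularization settings used for deep hybrid structures: step size
#' 0.001, moment decays 0.9 / 0.999, denominator offset 1e-7, minibatch
#' fraction 0.8 and dropout probability 0.2.
#'
#' @param alpha step size.
#' @param beta1,beta2 first/second moment decay rates, in (0, 1).
#' @param eta denominator offset added to the square-rooted second moment.
#' @param iterations number of ADAM iterations.
#' @param minibatch_fraction fraction of training experiments sampled
#'   (without replacement) each iteration, in (0, 1].
#' @param dropout_p hidden-node drop probability, in [0, 1).
#' @param seed RNG seed for initialization, minibatches and masks.
#' @param substep optional RK4 substep override used during training.
#' @return an `adam_config` list.
#' @export
adam_config <- function(alpha = 0.001, beta1 = 0.9, beta2 = 0.999,
                        eta = 1e-7, iterations = 1000,
                        minibatch_fraction = 0.8, dropout_p = 0.2,
                        seed = 1L, substep = NULL) {
  stopifnot(alpha > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1, eta > 0,
            iterations >= 1, minibatch_fraction > 0, minibatch_fraction <= 1,
            dropout_p >= 0, dropout_p < 1)
  structure(list(alpha = alpha, beta1 = beta1, beta2 = beta2, eta = eta,
                 iterations = as.integer(iterations),
                 minibatch_fraction = minibatch_fraction,
                 dropout_p = dropout_p, seed = as.integer(seed),
                 substep = substep), class = "adam_config")
}

#' Levenberg-Marquardt trainer configuration
#'
#' @param max_iterations maximum accepted steps per restart.
#' @param restarts number of random re-initializations; only the best run
#'   (lowest validation error) is kept.
#' @param lambda0 initial damping.
#' @param lambda_up,lambda_down multiplicative damping adaptation on
#'   rejection / acceptance.
#' @param patience consecutive accepted steps with increasing validation
#'   error tolerated before stopping.
#' @param validation_error_model optional [error_model_relative()] /
#'   [error_model_absolute()] governing the SD of the noise added when the
#'   validation set is created; `NULL` (the default) uses each
#'   measurement's own error SD.
#' @param seed RNG seed for initializations and validation-set noise.
#' @param substep optional RK4 substep override used during training.
#' @return an `lmm_config` list.
#' @export
lmm_config <- function(max_iterations = 100, restarts = 10, lambda0 = 1e-3,
                       lambda_up = 10, lambda_down = 10, patience = 25,
                       validation_error_model = NULL, seed = 1L,
                       substep = NULL) {
  stopifnot(restarts >= 1, lambda0 > 0, max_iterations >= 1, patience >= 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 restarts = as.integer(restarts), lambda0 = lambda0,
                 lambda_up = lambda_up, lambda_down = lambda_down,
                 patience = as.integer(patience),
                 validation_error_model = validation_error_model,
                 seed = as.integer(seed),
                 substep = substep), class = "lmm_config")
}

#' One ADAM update
#'
#' Applies the standard bias-corrected update: exponentially decayed first
#' and second gradient moments, bias correction `1 - beta^t`, and the step
#' `alpha * m_hat / (sqrt(v_hat) + eta)` element-wise.
#'
#' @param weights flat weight vector.
#' @param gradient flat gradient vector.
#' @param moments list with `m` and `v` (initialize both at zero).
#' @param iteration 1-based iteration index.
#' @param config an [adam_config()].
#' @return list with updated `weights` and `moments`.
#' @export
adam_update <- function(weights, gradient, moments, iteration, config) {
  stopifnot(iteration >= 1)
  m <- config$beta1 * moments$m + (1 - config$beta1) * gradient
  v <- config$beta2 * moments$v + (1 - config$beta2) * gradient^2
  mhat <- m / (1 - config$beta1^iteration)
  vhat <- v / (1 - config$beta2^iteration)
  list(weights = weights - config$alpha * mhat / (sqrt(vhat) + config$eta),
       moments = list(m = m, v = v))
}

#' Generic ADAM loop over an arbitrary gradient function
#'
#' The engine behind [train_adam()], exposed so the update rule can be
#' exercised on closed-form objectives.
#'
#' @param grad_fn function(weights, iteration) returning the gradient.
#' @param w0 initial flat weight vector.
#' @param config an [adam_config()].
#' @return the final weight vector.
#' @export
adam_optimize <- function(grad_fn, w0, config) {
  w <- w0
  mom <- list(m = numeric(length(w0)), v = numeric(length(w0)))
  for (it in seq_len(config$iterations)) {
    g <- grad_fn(w, it)
    upd <- adam_update(w, g, mom, it, config)
    w <- upd$weights
    mom <- upd$moments
  }
  w
}

#' Generic damped Levenberg-Marquardt loop over a residual function
#'
#' Damped Gauss-Newton on a weighted residual vector: solves
#' `(J'J + lambda I) delta = -J'r`, accepts the step when the sum of
#' squares decreases (damping / `lambda_down`), otherwise increases the
#' damping. Singular normal equations raise the damping instead of
#' failing; residual functions may signal divergence at a trial point, in
#' which case the step is rejected.
#'
#' @param residual_fn function(weights) returning list(r = residual
#'   vector, J = residual Jacobian).
#' @param w0 initial flat weight vector.
#' @param config an [lmm_config()].
#' @param on_accept optional callback(weights, sse, iteration) run after
#'   each accepted step; returning `FALSE` stops the loop (used for
#'   cross-validation stopping).
#' @return list with `weights`, final `sse`, accepted `iterations`.
#' @export
lm_optimize <- function(residual_fn, w0, config, on_accept = NULL) {
  w <- w0
  rj <- residual_fn(w)
  sse <- sum(rj$r^2)
  lambda <- config$lambda0
  accepted <- 0L
  repeat {
    if (accepted >= config$max_iterations || lambda > 1e12) break
    JtJ <- crossprod(rj$J)
    Jtr <- crossprod(rj$J, rj$r)
    step_ok <- FALSE
    delta <- tryCatch(
      solve(JtJ + lambda * diag(nrow(JtJ)), -Jtr),
      error = function(e) NULL)
    if (!is.null(delta)) {
      trial <- w + drop(delta)
      rj_trial <- tryCatch(residual_fn(trial), error = function(e) NULL)
      if (!is.null(rj_trial) && all(is.finite(rj_trial$r))) {
        sse_trial <- sum(rj_trial$r^2)
        if (is.finite(sse_trial) && sse_trial < sse) {
          w <- trial; rj <- rj_trial; sse <- sse_trial
          lambda <- lambda / config$lambda_down
          accepted <- accepted + 1L
          step_ok <- TRUE
          if (!is.null(on_accept) &&
              identical(on_accept(w, sse, accepted), FALSE)) break
          # practical convergence: vanishing step
          if (sqrt(sum(delta^2)) < 1e-12 * (1 + sqrt(sum(w^2)))) break
        }
      }
    }
    if (!step_ok) lambda <- lambda * config$lambda_up
  }
  list(weights = w, sse = sse, iterations = accepted)
}

#' Create a noise-augmented validation set from a training subset
#'
#' Adds independent Gaussian noise to every training measurement, with the
#' standard deviation of the added noise equal to the standard deviation of
#' the measurement error at that point; times, feeds and initial states are
#' unchanged. The augmented copy is used purely as a cross-validation
#' stopping set by the classical trainer.
#'
#' @param dataset an [experiment_dataset()] (training subset).
#' @param ids experiment ids to include (default: all).
#' @param error_model optional [error_model_relative()] /
#'   [error_model_absolute()]; when supplied the SDs are recomputed from
#'   it, otherwise the dataset's stored sigmas are used.
#' @return an [experiment_dataset()] of the same shape with noisy
#'   measurements.
#' @export
make_validation_set <- function(dataset, ids = NULL, error_model = NULL) {
  if (is.null(ids)) ids <- experiment_ids(dataset)
  dataset <- subset_dataset(dataset, ids)
  dataset$experiments <- lapply(dataset$experiments, function(e) {
    sg <- if (is.null(error_model)) e$sigma
          else sigma_matrix(error_model, e$meas, dataset$species)
    noise <- matrix(rnorm(length(e$meas), sd = as.numeric(sg)),
                    nrow = nrow(e$meas))
    e$meas <- e$meas + ifelse(is.na(e$meas), 0, noise)
    e
  })
  dataset$provenance$augmented <- TRUE
  dataset
}

new_training_run <- function(trainer, trace, weights, kept_iteration,
                             config, extra = list()) {
  structure(c(list(trainer = trainer, trace = trace, weights = weights,
                   kept_iteration = kept_iteration, config = config),
              extra), class = "training_run")
}

#' @export
print.training_run <- function(x, ...) {
  cat("<training_run> ", x$trainer, ", ", nrow(x$trace),
      " iterations, kept iteration ", x$kept_iteration,
      " (train WMSE ", signif(x$best_train_wmse, 4),
      if (!is.null(x$best_val_wmse))
        paste0(", val WMSE ", signif(x$best_val_wmse, 4)),
      ")\n", sep = "")
  invisible(x)
}

#' Train a hybrid model with ADAM and stochastic regularization
#'
#' Per iteration: a minibatch of training experiments is sampled without
#' replacement (`ceil(fraction * n)` whole reactor runs, since the
#' integration unit is a trajectory) together with one dropout mask held
#' fixed across all time steps of the iteration; the semidirect sensitivity
#' gradient of the weighted objective is computed on the masked network and
#' the ADAM update applied; the full-batch maskless training WMSE is then
#' recorded. After the configured number of iterations the weights from the
#' iteration with minimum full-batch training WMSE are returned (iteration
#' 0, the initialization, is part of the trace). A single random
#' initialization is used. Iterations with non-finite gradients are skipped
#' with a warning; more than 10 consecutive skips abort the training.
#'
#' @param model a [hybrid_model()] (its weights are ignored; a fresh
#'   uniform initialization is drawn from the config seed).
#' @param dataset an [experiment_dataset()].
#' @param config an [adam_config()].
#' @param ids training experiment ids (default: all).
#' @return a `training_run` with the per-iteration WMSE trace, kept
#'   weights and kept-iteration index.
#' @export
train_adam <- function(model, dataset, config = adam_config(), ids = NULL) {
  if (is.null(ids)) ids <- experiment_ids(dataset)
  set.seed(config$seed)
  w <- flatten_weights(init_weights(model$layout))
  mom <- list(m = numeric(length(w)), v = numeric(length(w)))
  n_mb <- max(1L, ceiling(config$minibatch_fraction * length(ids)))
  trace <- data.frame(iteration = 0:config$iterations,
                      train_wmse = NA_real_)
  wmse0 <- dataset_wmse(model, dataset, ids = ids, weights = w,
                        substep = config$substep)$wmse
  trace$train_wmse[1] <- wmse0
  best <- list(iter = 0L, wmse = wmse0, w = w)
  skips <- 0L
  for (it in seq_len(config$iterations)) {
    mb <- if (n_mb < length(ids)) sample(ids, n_mb) else ids
    mask <- if (config$dropout_p > 0)
      sample_dropout_mask(model$layout, config$dropout_p) else NULL
    gr <- tryCatch(
      semidirect_gradient(model, dataset, weights = w, ids = mb,
                          mask = mask, substep = config$substep),
      hybridfb_divergence = function(e) NULL)
    if (is.null(gr) || any(!is.finite(gr$g))) {
      skips <- skips + 1L
      warning("skipping iteration ", it, ": non-finite gradient",
              call. = FALSE)
      if (skips > 10L) stop("ADAM training failed: >10 consecutive ",
                            "non-finite gradients")
      trace$train_wmse[it + 1] <- trace$train_wmse[it]
      next
    }
    skips <- 0L
    upd <- adam_update(w, gr$g, mom, it, config)
    w <- upd$weights; mom <- upd$moments
    full <- dataset_wmse(model, dataset, ids = ids, weights = w,
                         substep = config$substep)$wmse
    trace$train_wmse[it + 1] <- full
    if (is.finite(full) && full < best$wmse)
      best <- list(iter = it, wmse = full, w = w)
  }
  new_training_run("adam", trace, best$w, best$iter, config,
                   list(best_train_wmse = best$wmse, ids = ids,
                        seed = config$seed))
}

#' Train a hybrid model with Levenberg-Marquardt and cross-validation
#'
#' The classical regime: damped Gauss-Newton steps on the weighted
#' residual vector (residuals divided by their measurement SDs), with
#' gradient information from the indirect sensitivity equations. After
#' every accepted step the WMSE on a noise-augmented validation copy of
#' the training data is evaluated; training stops when the validation
#' error has not improved for `patience` consecutive accepted steps (or at
#' the iteration cap), and the weights at the minimum validation WMSE are
#' kept. The whole procedure is restarted from fresh uniform
#' initializations, keeping the restart with the lowest validation error.
#' The validation points are used purely for stopping, never in the
#' training objective.
#'
#' @param model a [hybrid_model()].
#' @param dataset an [experiment_dataset()].
#' @param config an [lmm_config()].
#' @param ids training experiment ids (default: all).
#' @return a `training_run`; its trace records training and validation
#'   WMSE per accepted step and the restart index.
#' @export
train_lmm <- function(model, dataset, config = lmm_config(), ids = NULL) {
  if (is.null(ids)) ids <- experiment_ids(dataset)
  set.seed(config$seed)
  valset <- make_validation_set(dataset, ids = ids,
                                error_model = config$validation_error_model)
  Tn <- n_residuals(dataset, ids)
  best_run <- NULL
  traces <- list()
  for (rs in seq_len(config$restarts)) {
    w0 <- flatten_weights(init_weights(model$layout))
    state <- new.env(parent = emptyenv())
    state$best_val <- Inf; state$best_w <- w0; state$best_iter <- 0L
    state$since <- 0L
    state$trace <- list()
    resfun <- function(w) {
      gr <- indirect_gradient(model, dataset, weights = w, ids = ids,
                              substep = config$substep,
                              return_jacobian = TRUE)
      list(r = gr$residuals, J = gr$jacobian)
    }
    val0 <- dataset_wmse(model, valset, weights = w0,
                         substep = config$substep)$wmse
    tr0 <- dataset_wmse(model, dataset, ids = ids, weights = w0,
                        substep = config$substep)$wmse
    state$best_val <- val0
    state$trace[[1]] <- c(iteration = 0, train_wmse = tr0, val_wmse = val0)
    on_accept <- function(w, sse, iter) {
      val <- tryCatch(
        dataset_wmse(model, valset, weights = w,
                     substep = config$substep)$wmse,
        hybridfb_divergence = function(e) Inf)
      state$trace[[iter + 1L]] <-
        c(iteration = iter, train_wmse = sse / Tn, val_wmse = val)
      if (val < state$best_val) {
        state$best_val <- val
        state$best_w <- w
        state$best_iter <- iter
        state$since <- 0L
      } else {
        state$since <- state$since + 1L
      }
      state$since < config$patience  # FALSE stops the LM loop
    }
    fit <- lm_optimize(resfun, w0, config, on_accept = on_accept)
    tr <- as.data.frame(do.call(rbind, state$trace))
    tr$restart <- rs
    traces[[rs]] <- tr
    train_at_best <- if (state$best_iter == 0L) tr$train_wmse[1]
                     else tr$train_wmse[state$best_iter + 1L]
    run <- list(w = state$best_w, val = state$best_val,
                train = train_at_best, iter = state$best_iter,
                restart = rs)
    if (is.null(best_run) || run$val < best_run$val ||
        (run$val == best_run$val && run$train < best_run$train))
      best_run <- run
  }
  trace <- do.call(rbind, traces)
  new_training_run("lmm", trace, best_run$w, best_run$iter, config,
                   list(best_train_wmse = best_run$train,
                        best_val_wmse = best_run$val,
                        best_restart = best_run$restart, ids = ids,
                        seed = config$seed))
}
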