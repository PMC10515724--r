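# Model performance metrics (weighted mean squared error, small-sample
# corrected AIC), batch-wise resampling plans and structure comparison.

#' Weighted mean squared error
#'
#' Mean over all aligned, non-missing pairs of the squared residual
#' divided by the measurement error variance:
#' `WMSE = (1/T) * sum((c* - c)^2 / sigma^2)`. A model matching the data
#' to the noise floor (with correctly specified sigmas) scores about 1.
#'
#' @param predicted,measured aligned numeric vectors or matrices; `NA`s in
#'   `measured` are excluded (and do not count towards `T`).
#' @param sigmas measurement SDs, same shape, positive where used.
#' @return scalar WMSE.
#' @export
wmse <- function(predicted, measured, sigmas) {
  p <- as.numeric(predicted); m <- as.numeric(measured)
  s <- as.numeric(sigmas)
  stopifnot(length(p) == length(m), length(s) == length(m))
  keep <- !is.na(m) & !is.na(p)
  if (!any(keep)) stop("empty residual set")
  if (any(s[keep] <= 0)) stop("sigmas must be positive")
  mean(((m[keep] - p[keep]) / s[keep])^2)
}

#' Corrected Akaike information criterion
#'
#' Small-sample corrected AIC computed from the training error:
#' `AICc = T * ln(WMSE) + 2 * nw + 2 * nw * (nw + 1) / (T - nw - 1)`,
#' trading training fit against the number of network parameters. The
#' correction requires `T > nw + 1`.
#'
#' @param wmse_train training WMSE (> 0).
#' @param T number of scalar training residuals.
#' @param nw number of network weights.
#' @return scalar AICc.
#' @export
aicc <- function(wmse_train, T, nw) {
  if (wmse_train <= 0) stop("wmse_train must be positive")
  if (T <= nw + 1) stop("AICc undefined: need T > nw + 1")
  T * log(wmse_train) + 2 * nw + 2 * nw * (nw + 1) / (T - nw - 1)
}

#' Random train/test partitions of whole experiments
#'
#' Draws `n_partitions` independent uniform selections of `n_test` test
#' experiments (the remainder trains). The same plan is reused across all
#' structures under comparison so that their statistics are comparable.
#'
#' @param experiment_ids character vector of experiment ids.
#' @param n_partitions number of partitions.
#' @param n_test number of test experiments per partition
#'   (< number of experiments).
#' @param seed RNG seed.
#' @return an object of class `partition_plan`: a list of
#'   `(train, test)` id pairs plus the seed.
#' @export
resample_partitions <- function(experiment_ids, n_partitions, n_test,
                                seed = 1L) {
  stopifnot(n_test >= 1, n_test < length(experiment_ids))
  set.seed(seed)
  parts <- lapply(seq_len(n_partitions), function(i) {
    test <- sample(experiment_ids, n_test)
    list(train = setdiff(experiment_ids, test), test = test)
  })
  structure(list(partitions = parts, seed = as.integer(seed)),
            class = "partition_plan")
}

#' @export
print.partition_plan <- function(x, ...) {
  p1 <- x$partitions[[1]]
  cat("<partition_plan> ", length(x$partitions), " partitions, |train| = ",
      length(p1$train), ", |test| = ", length(p1$test),
      " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

baseline_wmse <- function(dataset, ids) {
  # variance-normalized baseline: per-species mean of the training subset
  # as a constant predictor
  sub <- dataset$experiments[ids]
  meas <- do.call(rbind, lapply(sub, `[[`, "meas"))
  sig <- do.call(rbind, lapply(sub, `[[`, "sigma"))
  mu <- colMeans(meas, na.rm = TRUE)
  pred <- matrix(mu, nrow(meas), ncol(meas), byrow = TRUE)
  wmse(pred, meas, sig)
}

#' Train and score one network structure over a partition plan
#'
#' Trains the structure once per partition with the requested trainer and
#' reports mean and SD of the train and test WMSE over partitions, the
#' AICc (from the training WMSE, with `T` = number of scalar training
#' residuals) and the weight count. A partition whose training diverges,
#' produces a non-finite objective, or lands more than 10x above the
#' variance-normalized baseline of its training subset is recorded as
#' unstable and excluded from the statistics.
#'
#' @param layout a [network_layout()].
#' @param dataset an [experiment_dataset()].
#' @param plan a [resample_partitions()] plan.
#' @param trainer `"adam"` or `"lmm"`.
#' @param config an [adam_config()] or [lmm_config()]; its seed is offset
#'   by the partition index so partitions are independent.
#' @param substep optional RK4 substep override for train/test scoring.
#' @param label optional structure label for the report.
#' @param truth_test also report the noiseless ("noise-free") test WMSE
#'   when the dataset carries truth matrices.
#' @return a one-row data.frame of per-structure statistics (class
#'   `structure_eval`), with the per-partition detail in
#'   `attr(, "detail")` and kept weights in `attr(, "runs")`.
#' @export
evaluate_structure <- function(layout, dataset, plan, trainer = c("adam", "lmm"),
                               config = NULL, substep = NULL, label = NULL,
                               truth_test = FALSE) {
  trainer <- match.arg(trainer)
  if (is.null(config))
    config <- if (trainer == "adam") adam_config() else lmm_config()
  if (is.null(label))
    label <- paste0(layout$n_in, "-[", paste(layout$hidden, collapse = ","),
                    "]-", layout$n_out)
  nw <- count_weights(layout)
  rows <- list(); runs <- list()
  for (i in seq_along(plan$partitions)) {
    part <- plan$partitions[[i]]
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    model <- hybrid_model(dataset$species, layout, vmax = dataset$vmax,
                          substep = if (is.null(substep)) 0.5 else substep)
    res <- tryCatch({
      run <- if (trainer == "adam")
        train_adam(model, dataset, cfg, ids = part$train)
      else train_lmm(model, dataset, cfg, ids = part$train)
      m2 <- set_model_weights(model, run$weights)
      tr <- dataset_wmse(m2, dataset, ids = part$train, substep = substep)
      te <- dataset_wmse(m2, dataset, ids = part$test, substep = substep)
      te_nf <- if (truth_test && !is.null(dataset$truth))
        dataset_wmse(m2, dataset, ids = part$test, substep = substep,
                     truth = TRUE)$wmse else NA_real_
      bl <- baseline_wmse(dataset, part$train)
      unstable <- !is.finite(tr$wmse) || !is.finite(te$wmse) ||
        tr$wmse > 10 * bl
      list(row = data.frame(
             partition = i, train_wmse = tr$wmse, test_wmse = te$wmse,
             test_wmse_noisefree = te_nf,
             aicc = if (tr$T > nw + 1) aicc(tr$wmse, tr$T, nw) else NA_real_,
             T_train = tr$T, unstable = unstable),
           run = run)
    }, hybridfb_divergence = function(e) {
      list(row = data.frame(partition = i, train_wmse = NA_real_,
                            test_wmse = NA_real_,
                            test_wmse_noisefree = NA_real_, aicc = NA_real_,
                            T_train = NA_integer_, unstable = TRUE),
           run = NULL)
    })
    rows[[i]] <- res$row
    runs[[i]] <- res$run
  }
  detail <- do.call(rbind, rows)
  ok <- !detail$unstable
  stat <- function(x) if (any(ok)) c(mean(x[ok]), sd(x[ok])) else c(NA, NA)
  tw <- stat(detail$train_wmse); te <- stat(detail$test_wmse)
  ai <- stat(detail$aicc); nf <- stat(detail$test_wmse_noisefree)
  out <- data.frame(
    structure = label, trainer = trainer, n_weights = nw,
    train_wmse_mean = tw[1], train_wmse_sd = tw[2],
    test_wmse_mean = te[1], test_wmse_sd = te[2],
    test_wmse_noisefree_mean = nf[1], test_wmse_noisefree_sd = nf[2],
    aicc_mean = ai[1], aicc_sd = ai[2],
    n_unstable = sum(detail$unstable), n_partitions = nrow(detail),
    stringsAsFactors = FALSE)
  attr(out, "detail") <- detail
  attr(out, "runs") <- runs
  class(out) <- c("structure_eval", class(out))
  out
}

#' Compare a sweep of structures and flag the selected one
#'
#' Stacks per-structure evaluations (all computed over the same partition
#' plan) into a selection report and flags the completed structure with
#' the minimum mean test WMSE — the resampling selection rule. The
#' minimum-AICc structure is flagged separately for reference.
#'
#' @param evals list of [evaluate_structure()] results.
#' @return a `selection_report` data.frame with `selected` and
#'   `selected_aicc` logical columns.
#' @export
selection_report <- function(evals) {
  rep <- do.call(rbind, lapply(evals, function(e) {
    attributes(e)[c("detail", "runs")] <- NULL
    as.data.frame(e)
  }))
  rep$selected <- FALSE
  done <- !is.na(rep$test_wmse_mean)
  if (any(done))
    rep$selected[which(done)[which.min(rep$test_wmse_mean[done])]] <- TRUE
  rep$selected_aicc <- FALSE
  done_a <- !is.na(rep$aicc_mean)
  if (any(done_a))
    rep$selected_aicc[which(done_a)[which.min(rep$aicc_mean[done_a])]] <- TRUE
  class(rep) <- c("selection_report", class(rep))
  rep
}

#' Percentage differences between two structure summaries
#'
#' Reports, for each available error metric and for the weight count,
#' the reduction achieved by `b` relative to `a` (`100 * (a - b) / a`)
#' and the increase of `b` relative to `a` (`100 * (b - a) / a`). Rounding
#' to one decimal is left to display.
#'
#' @param a,b lists or one-row data.frames with (any of)
#'   `train_wmse_mean`, `test_wmse_mean`, `test_wmse_noisefree_mean` and
#'   `n_weights` (aliases `train`, `test`, `test_noisefree`, `weights`
#'   also accepted).
#' @return list with `reduction_pct` and `increase_pct`, named numeric
#'   vectors over the shared metrics.
#' @export
compare_structures <- function(a, b) {
  pick <- function(x, keys) {
    for (k in keys) if (!is.null(x[[k]]) && !is.na(x[[k]])) return(x[[k]])
    NA_real_
  }
  metrics <- list(
    train = c("train_wmse_mean", "train"),
    test = c("test_wmse_mean", "test"),
    test_noisefree = c("test_wmse_noisefree_mean", "test_noisefree"),
    weights = c("n_weights", "weights"))
  av <- vapply(metrics, function(k) pick(a, k), numeric(1))
  bv <- vapply(metrics, function(k) pick(b, k), numeric(1))
  keep <- !is.na(av) & !is.na(bv)
  list(reduction_pct = 100 * (av[keep] - bv[keep]) / av[keep],
       increase_pct = 100 * (bv[keep] - av[keep]) / av[keep])
}
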