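# Dataset file formats.
#
# A dataset directory holds plain CSV tables:
#   measurements.csv  experiment_id, time_h, <one column per species>
#   sigmas.csv        same shape as measurements
#   feeds.csv         experiment_id, stream_id, t_start_h, t_end_h, rate
#   compositions.csv  experiment_id, stream_id, <one column per species>
#   initial.csv       experiment_id, V0, <one column per species>
#   species.csv       name, unit, cmax
#   meta.json         vmax, provenance, roles
#   truth.csv         optional noiseless measurements (diagnostics only;
#                     never read into the training tables)
# Numbers are serialized at full precision; column order is deterministic.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

write_csv_precise <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

wide_table <- function(dataset, field) {
  sp <- dataset$species$names
  do.call(rbind, lapply(dataset$experiments, function(e) {
    m <- as.data.frame(e[[field]])
    names(m) <- sp
    cbind(data.frame(experiment_id = e$id, time_h = e$times), m)
  }))
}

#' Write a dataset to a directory of CSV files
#'
#' @param dataset an [experiment_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- dataset$species$names
  write_csv_precise(wide_table(dataset, "meas"),
                    file.path(dir, "measurements.csv"))
  write_csv_precise(wide_table(dataset, "sigma"),
                    file.path(dir, "sigmas.csv"))
  feeds <- do.call(rbind, lapply(dataset$experiments, function(e)
    do.call(rbind, lapply(e$streams, function(s)
      cbind(data.frame(experiment_id = e$id, stream_id = s$id),
            data.frame(t_start_h = s$schedule$t_start,
                       t_end_h = s$schedule$t_end,
                       rate = s$schedule$rate))))))
  write_csv_precise(feeds, file.path(dir, "feeds.csv"))
  comps <- do.call(rbind, lapply(dataset$experiments, function(e)
    do.call(rbind, lapply(e$streams, function(s) {
      m <- as.data.frame(matrix(s$c_in, nrow = 1))
      names(m) <- sp
      cbind(data.frame(experiment_id = e$id, stream_id = s$id), m)
    }))))
  write_csv_precise(comps, file.path(dir, "compositions.csv"))
  init <- do.call(rbind, lapply(dataset$experiments, function(e) {
    m <- as.data.frame(matrix(e$c0, nrow = 1))
    names(m) <- sp
    cbind(data.frame(experiment_id = e$id, V0 = e$V0), m)
  }))
  write_csv_precise(init, file.path(dir, "initial.csv"))
  write_csv_precise(
    data.frame(name = sp, unit = unname(dataset$species$units),
               cmax = unname(dataset$species$cmax)),
    file.path(dir, "species.csv"))
  roles <- vapply(dataset$experiments, function(e)
    if (is.na(e$role)) "" else e$role, character(1))
  meta <- list(vmax = dataset$vmax, provenance = dataset$provenance,
               roles = as.list(roles))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(dataset$truth)) {
    tr <- do.call(rbind, lapply(names(dataset$truth), function(id) {
      e <- dataset$experiments[[id]]
      m <- as.data.frame(dataset$truth[[id]])
      names(m) <- sp
      cbind(data.frame(experiment_id = id, time_h = e$times), m)
    }))
    write_csv_precise(tr, file.path(dir, "truth.csv"))
  }
  invisible(dir)
}

schema_stop <- function(file, ...) {
  stop("dataset schema error in ", file, ": ", ..., call. = FALSE)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' Validates the tables against the species roster; schema violations are
#' reported with the offending file and column/row. Missing measurement
#' cells are allowed and load as `NA` (they are excluded from the residual
#' count).
#'
#' @param dir dataset directory.
#' @return an [experiment_dataset()].
#' @export
read_dataset <- function(dir) {
  need <- c("measurements.csv", "sigmas.csv", "feeds.csv",
            "compositions.csv", "initial.csv", "species.csv", "meta.json")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop("missing dataset file: ", f, call. = FALSE)
  spdf <- read.csv(file.path(dir, "species.csv"), stringsAsFactors = FALSE)
  species <- species_set(spdf$name, spdf$cmax, spdf$unit)
  sp <- species$names
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  check_cols <- function(df, file, id_cols) {
    extra <- setdiff(names(df), c(id_cols, sp))
    if (length(extra))
      schema_stop(file, "unknown species column(s): ",
                  paste(extra, collapse = ", "))
    miss <- setdiff(sp, names(df))
    if (length(miss))
      schema_stop(file, "missing species column(s): ",
                  paste(miss, collapse = ", "))
  }
  meas <- read.csv(file.path(dir, "measurements.csv"),
                   stringsAsFactors = FALSE)
  check_cols(meas, "measurements.csv", c("experiment_id", "time_h"))
  sig <- read.csv(file.path(dir, "sigmas.csv"), stringsAsFactors = FALSE)
  check_cols(sig, "sigmas.csv", c("experiment_id", "time_h"))
  feeds <- read.csv(file.path(dir, "feeds.csv"), stringsAsFactors = FALSE)
  comps <- read.csv(file.path(dir, "compositions.csv"),
                    stringsAsFactors = FALSE)
  check_cols(comps, "compositions.csv", c("experiment_id", "stream_id"))
  init <- read.csv(file.path(dir, "initial.csv"), stringsAsFactors = FALSE)
  check_cols(init, "initial.csv", c("experiment_id", "V0"))
  truth_df <- if (file.exists(file.path(dir, "truth.csv")))
    read.csv(file.path(dir, "truth.csv"), stringsAsFactors = FALSE)
  else NULL
  ids <- unique(meas$experiment_id)
  roles <- meta$roles
  exps <- lapply(ids, function(id) {
    mi <- meas[meas$experiment_id == id, , drop = FALSE]
    si <- sig[sig$experiment_id == id, , drop = FALSE]
    if (nrow(si) != nrow(mi))
      schema_stop("sigmas.csv", "row count for experiment ", id,
                  " does not match measurements.csv")
    o <- order(mi$time_h)
    mi <- mi[o, ]; si <- si[order(si$time_h), ]
    ii <- init[init$experiment_id == id, , drop = FALSE]
    if (nrow(ii) != 1)
      schema_stop("initial.csv", "need exactly one row for experiment ", id)
    fi <- feeds[feeds$experiment_id == id, , drop = FALSE]
    streams <- lapply(unique(fi$stream_id), function(sid) {
      ci <- comps[comps$experiment_id == id & comps$stream_id == sid, ,
                  drop = FALSE]
      if (nrow(ci) != 1)
        schema_stop("compositions.csv", "need one row for experiment ", id,
                    " stream ", sid)
      fs <- fi[fi$stream_id == sid, , drop = FALSE]
      feed_stream(as.numeric(ci[1, sp]),
                  data.frame(t_start = fs$t_start_h, t_end = fs$t_end_h,
                             rate = fs$rate), id = sid)
    })
    role <- if (!is.null(roles[[id]]) && nzchar(roles[[id]]))
      roles[[id]] else NA_character_
    experiment(id, mi$time_h, as.matrix(mi[, sp]), as.matrix(si[, sp]),
               c0 = as.numeric(ii[1, sp]), V0 = ii$V0[1],
               streams = streams, role = role)
  })
  truth <- NULL
  if (!is.null(truth_df)) {
    check_cols(truth_df, "truth.csv", c("experiment_id", "time_h"))
    truth <- setNames(lapply(ids, function(id) {
      ti <- truth_df[truth_df$experiment_id == id, , drop = FALSE]
      as.matrix(ti[order(ti$time_h), sp])
    }), ids)
  }
  experiment_dataset(exps, species, vmax = meta$vmax, truth = truth,
                     provenance = as.list(meta$provenance))
}

#' Read a run configuration (JSON or YAML)
#'
#' Strictly validated: unknown top-level keys are rejected. Recognized
#' keys: `layout` (n_conc, hidden, n_out, activation, extra_inputs),
#' `trainer` (`"adam"` or `"lmm"` plus that trainer's settings),
#' `substep`, `partitions` (n_partitions, n_test), `seed`.
#'
#' @param path configuration file (`.json`, `.yml` or `.yaml`).
#' @return a validated named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configurations")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("layout", "trainer", "substep", "partitions", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "))
  if (!is.null(cfg$layout)) {
    lk <- setdiff(names(cfg$layout),
                  c("n_conc", "hidden", "n_out", "activation",
                    "extra_inputs"))
    if (length(lk))
      stop("unknown layout key(s): ", paste(lk, collapse = ", "))
  }
  if (!is.null(cfg$trainer)) {
    if (is.null(cfg$trainer$name) ||
        !cfg$trainer$name %in% c("adam", "lmm"))
      stop("trainer$name must be 'adam' or 'lmm'")
  }
  structure(cfg, class = "run_config")
}
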