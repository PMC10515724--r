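#' Define the species roster of a hybrid model
#'
#' The species set fixes the ordering of the concentration state vector, the
#' per-species normalization maxima used by the network input layer, and
#' (optionally) unit labels. One species plays the role of the viable cell
#' density `Xv`, the autocatalytic state that multiplies every specific rate
#' in the material balances; it is identified by name, not by position.
#'
#' @param names character vector of unique species identifiers.
#' @param cmax strictly positive numeric vector of per-species absolute
#'   maximum concentrations (normalization constants), same length and order
#'   as `names`.
#' @param units optional character vector of unit labels.
#' @return an object of class `species_set`.
#' @export
species_set <- function(names, cmax, units = NULL) {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("species names must be unique")
  cmax <- as.numeric(cmax)
  if (length(cmax) != length(names))
    stop("cmax must have one entry per species")
  if (any(!is.finite(cmax)) || any(cmax <= 0))
    stop("cmax must be finite and strictly positive")
  if (is.null(units)) units <- rep("conc", length(names))
  structure(
    list(names = names, cmax = setNames(cmax, names),
         units = setNames(as.character(units), names)),
    class = "species_set")
}

#' @export
length.species_set <- function(x) length(x$names)

#' @export
print.species_set <- function(x, ...) {
  cat("<species_set> ", length(x$names), " species: ",
      paste(utils::head(x$names, 8), collapse = ", "),
      if (length(x$names) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Define a feed stream
#'
#' A feed stream has a fixed inlet composition and a piecewise-constant rate
#' schedule. Outside every schedule segment the rate is zero.
#'
#' @param c_in named or ordered numeric vector of inlet concentrations, one
#'   entry per species (same order as the species set), all finite and >= 0.
#' @param schedule data.frame with columns `t_start`, `t_end`, `rate`
#'   (volume/time, >= 0); segments must be ordered and non-overlapping.
#' @param id optional stream identifier.
#' @return an object of class `feed_stream`.
#' @export
feed_stream <- function(c_in, schedule, id = NULL) {
  c_in <- as.numeric(c_in)
  if (any(!is.finite(c_in)) || any(c_in < 0))
    stop("inlet concentrations must be finite and non-negative")
  stopifnot(is.data.frame(schedule),
            all(c("t_start", "t_end", "rate") %in% names(schedule)))
  schedule <- schedule[order(schedule$t_start), , drop = FALSE]
  if (any(schedule$t_end <= schedule$t_start))
    stop("schedule segments must have t_end > t_start")
  if (any(schedule$rate < 0)) stop("feed rates must be >= 0")
  if (nrow(schedule) > 1 &&
      any(schedule$t_start[-1] < schedule$t_end[-nrow(schedule)] - 1e-12))
    stop("schedule segments must not overlap")
  structure(list(c_in = c_in, schedule = schedule,
                 id = if (is.null(id)) "feed" else as.character(id)),
            class = "feed_stream")
}

#' Feed rate of one stream at a time point
#'
#' @param stream a [feed_stream()].
#' @param t time.
#' @return the scheduled rate at `t` (zero outside every segment).
#' @export
feed_rate <- function(stream, t) {
  s <- stream$schedule
  hit <- which(s$t_start <= t & t < s$t_end)
  if (length(hit) == 0) 0 else s$rate[hit[1]]
}

#' Dilution rates of a set of feed streams
#'
#' The dilution rate of stream k is its current feed rate divided by the
#' culture volume, `D_k = F_k / V`; the reactor dilution rate is their sum.
#'
#' @param streams list of [feed_stream()] objects.
#' @param t time.
#' @param V culture volume, must be > 0.
#' @return list with `per_stream` (named numeric vector of D_k) and
#'   `total` (scalar D).
#' @export
dilution_rate <- function(streams, t, V) {
  if (!is.finite(V) || V <= 0) stop("invalid state: volume must be positive")
  if (inherits(streams, "feed_stream")) streams <- list(streams)
  Dk <- vapply(streams, function(s) feed_rate(s, t) / V, numeric(1))
  names(Dk) <- vapply(streams, function(s) s$id, character(1))
  list(per_stream = Dk, total = sum(Dk))
}
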