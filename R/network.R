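#' Describe a feedforward network layout
#'
#' The network maps normalized concentrations (plus optional extra inputs
#' such as the normalized culture volume) to the vector of specific reaction
#' rates. Hidden layers use a common activation; the output layer is affine
#' (linear, unscaled), so the network learns rate magnitudes directly.
#'
#' @param n_conc number of concentration inputs.
#' @param hidden integer vector of hidden layer widths (may be empty).
#' @param n_out number of outputs (one specific rate per species).
#' @param activation `"tanh"` (classical shallow choice) or `"relu"`
#'   (deep choice).
#' @param extra_inputs character vector naming non-concentration inputs
#'   appended after the concentrations (currently `"volume"` is understood
#'   by the hybrid model, normalized by its own maximum).
#' @return an object of class `network_layout`.
#' @export
network_layout <- function(n_conc, hidden = integer(), n_out,
                           activation = c("tanh", "relu"),
                           extra_inputs = character()) {
  activation <- match.arg(activation)
  hidden <- as.integer(hidden)
  if (length(hidden) && any(hidden < 1)) stop("hidden widths must be >= 1")
  n_conc <- as.integer(n_conc)
  n_out <- as.integer(n_out)
  if (n_conc < 0 || n_out < 1) stop("invalid layer sizes")
  structure(
    list(n_conc = n_conc, hidden = hidden, n_out = n_out,
         activation = activation, extra_inputs = as.character(extra_inputs),
         n_in = n_conc + length(extra_inputs)),
    class = "network_layout")
}

layer_sizes <- function(layout) {
  as.integer(c(layout$n_in, layout$hidden, layout$n_out))
}

act_code <- function(layout) if (layout$activation == "tanh") 0L else 1L

#' @export
print.network_layout <- function(x, ...) {
  cat("<network_layout> ", x$n_in, " -> [",
      paste(x$hidden, collapse = ", "), "] -> ", x$n_out,
      " (", x$activation, ")",
      if (length(x$extra_inputs))
        paste0("; extra inputs: ", paste(x$extra_inputs, collapse = ", ")),
      "\n", sep = "")
  cat("  weights: ", count_weights(x), "\n", sep = "")
  invisible(x)
}

#' Total number of trainable weights of a layout
#'
#' Counts all connection weights plus one bias per non-input node:
#' `sum over layers of (n_prev + 1) * n_layer`.
#'
#' @param layout a [network_layout()].
#' @return integer weight count.
#' @export
count_weights <- function(layout) {
  sz <- layer_sizes(layout)
  sum((sz[-length(sz)] + 1L) * sz[-1L])
}

#' Initialize network weights
#'
#' Every connection weight and bias is drawn i.i.d. from the uniform
#' distribution on `[-0.01, 0.01]`, the conventional small-magnitude
#' initialization for hybrid model training.
#'
#' @param layout a [network_layout()].
#' @param seed optional integer seed; when `NULL` the current RNG state is
#'   used (so callers can manage reproducibility themselves).
#' @param range half-width of the uniform initialization interval.
#' @return an object of class `network_weights`.
#' @export
init_weights <- function(layout, seed = NULL, range = 0.01) {
  if (!is.null(seed)) set.seed(seed)
  nw <- count_weights(layout)
  unflatten_weights(layout, runif(nw, -range, range))
}

#' Flatten structured weights into a single vector
#'
#' The flattening order is fixed and documented: layer by layer, connection
#' matrix row-major (all incoming weights of node 1, then node 2, ...),
#' followed by that layer's bias vector. Gradient vectors and the columns of
#' the weight Jacobian use the same order.
#'
#' @param weights a `network_weights` object.
#' @return numeric vector of length [count_weights()].
#' @export
flatten_weights <- function(weights) {
  unlist(lapply(seq_along(weights$W), function(l)
    c(as.vector(t(weights$W[[l]])), weights$b[[l]])), use.names = FALSE)
}

#' Rebuild structured weights from a flat vector
#'
#' @param layout a [network_layout()].
#' @param wvec numeric vector in the order documented in
#'   [flatten_weights()].
#' @return a `network_weights` object.
#' @export
unflatten_weights <- function(layout, wvec) {
  sz <- layer_sizes(layout)
  if (length(wvec) != count_weights(layout))
    stop("weight vector length does not match the layout")
  W <- list(); b <- list(); pos <- 0L
  for (l in seq_len(length(sz) - 1L)) {
    nin <- sz[l]; nout <- sz[l + 1L]
    W[[l]] <- matrix(wvec[pos + seq_len(nin * nout)], nrow = nout,
                     byrow = TRUE)
    pos <- pos + nin * nout
    b[[l]] <- wvec[pos + seq_len(nout)]
    pos <- pos + nout
  }
  structure(list(W = W, b = b, layout = layout), class = "network_weights")
}

as_flat_weights <- function(layout, weights) {
  if (inherits(weights, "network_weights")) flatten_weights(weights)
  else {
    if (length(weights) != count_weights(layout))
      stop("weight vector length does not match the layout")
    as.numeric(weights)
  }
}

#' Normalize raw inputs for the network input layer
#'
#' Concentrations are clamped at zero and divided element-wise by the
#' species maxima (Hadamard division); extra inputs are appended in layout
#' order, each divided by its own stated maximum.
#'
#' @param c concentration vector (species order).
#' @param species a [species_set()].
#' @param extras named numeric vector of raw extra-input values (e.g.
#'   `c(volume = 0.31)`); required when the layout declares extra inputs.
#' @param extras_max named numeric vector of maxima for the extra inputs.
#' @param layout optional [network_layout()]; when given, the extra inputs
#'   are checked and ordered against it.
#' @param clamp clamp concentrations at zero before normalization
#'   (default TRUE).
#' @return numeric input vector `H0`.
#' @export
normalize_inputs <- function(c, species, extras = NULL, extras_max = NULL,
                             layout = NULL, clamp = TRUE) {
  c <- as.numeric(c)
  if (length(c) != length(species$names))
    stop("concentration vector length does not match the species set")
  if (clamp) c <- pmax(c, 0)
  H0 <- c / unname(species$cmax)
  wanted <- if (!is.null(layout)) layout$extra_inputs else names(extras)
  if (length(wanted)) {
    if (is.null(extras) || !all(wanted %in% names(extras)))
      stop("missing extra input: ",
           paste(setdiff(wanted, names(extras)), collapse = ", "))
    if (is.null(extras_max) || !all(wanted %in% names(extras_max)))
      stop("missing extra input maximum")
    H0 <- c(H0, as.numeric(extras[wanted]) / as.numeric(extras_max[wanted]))
  }
  H0
}

#' Sample a dropout mask for the hidden layers
#'
#' Each hidden node is kept independently with probability `1 - p_drop`.
#' During training the kept activations are rescaled by `1/(1 - p_drop)`
#' (inverted dropout), which keeps the masked forward pass unbiased in
#' expectation; evaluation and simulation never apply a mask.
#'
#' @param layout a [network_layout()].
#' @param p_drop drop probability in `[0, 1)`.
#' @return an object of class `dropout_mask`: per-hidden-layer binary keep
#'   vectors plus the keep probability.
#' @export
sample_dropout_mask <- function(layout, p_drop) {
  if (p_drop < 0 || p_drop >= 1)
    stop("p_drop must be in [0, 1); dropping every node is degenerate")
  keep <- lapply(layout$hidden, function(nh)
    as.integer(runif(nh) >= p_drop))
  structure(list(keep = keep, p_keep = 1 - p_drop), class = "dropout_mask")
}

# concatenated per-node scale factors (0 or 1/p_keep); length-0 => no mask
mask_scales <- function(mask) {
  if (is.null(mask)) return(numeric(0))
  unlist(lapply(mask$keep, function(k) k / mask$p_keep), use.names = FALSE)
}

#' Evaluate the network
#'
#' Hidden layers apply the activation (after the optional dropout mask with
#' inverted scaling); the output layer is affine.
#'
#' @param layout a [network_layout()].
#' @param weights `network_weights` or a flat weight vector.
#' @param H0 input vector of length `layout$n_in`.
#' @param mask optional [sample_dropout_mask()] result.
#' @return rate vector of length `layout$n_out`.
#' @export
nn_forward <- function(layout, weights, H0, mask = NULL) {
  if (length(H0) != layout$n_in) stop("input length does not match layout")
  drop(cpp_nn_forward(layer_sizes(layout), act_code(layout),
                      as_flat_weights(layout, weights), as.numeric(H0),
                      mask_scales(mask))$v)
}

#' Jacobian of the network outputs with respect to its inputs
#'
#' @inheritParams nn_forward
#' @return `n_out x n_in` matrix. The ReLU derivative at 0 is taken as 0.
#' @export
nn_jacobian_inputs <- function(layout, weights, H0, mask = NULL) {
  if (length(H0) != layout$n_in) stop("input length does not match layout")
  cpp_nn_jac_inputs(layer_sizes(layout), act_code(layout),
                    as_flat_weights(layout, weights), as.numeric(H0),
                    mask_scales(mask))
}

#' Jacobian of the network outputs with respect to all weights
#'
#' Columns follow the flattening order documented in [flatten_weights()].
#'
#' @inheritParams nn_forward
#' @return `n_out x count_weights(layout)` matrix.
#' @export
nn_jacobian_weights <- function(layout, weights, H0, mask = NULL) {
  if (length(H0) != layout$n_in) stop("input length does not match layout")
  cpp_nn_jac_weights(layer_sizes(layout), act_code(layout),
                     as_flat_weights(layout, weights), as.numeric(H0),
                     mask_scales(mask))
}
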