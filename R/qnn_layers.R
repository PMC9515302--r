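## Add a bias row vector to every row of an N x d matrix (column-major
## recycling; avoids sweep() overhead in the training loop).
add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

#' Network architecture descriptor
#'
#' An architecture is the integer sequence `d1, ..., d(L+1)` of layer widths
#' (`d1` the input dimension, `d(L+1)` the class count) plus the neuron
#' type.  Printed in the conventional compact notation, e.g. `"Q(2-3)"` for
#' a single quadratic layer from 2 inputs to 3 outputs or `"C(2-100-3)"`
#' for a conventional network with one 100-unit hidden layer.
#'
#' @param dims integer vector of layer widths, length at least 2.
#' @param type `"conventional"` or `"quadratic"`.
#' @return An object of class `network_arch` with `dims`, `type`, `L`
#'   (number of weight layers) and `n_neurons` (`sum(dims[-1])`).
#' @export
network_arch <- function(dims, type = c("conventional", "quadratic")) {
  type <- match.arg(type)
  dims <- as.integer(dims)
  if (length(dims) < 2 || any(dims < 1))
    stop("dims must contain at least two positive integers")
  structure(list(dims = dims, type = type, L = length(dims) - 1L,
                 n_neurons = sum(dims[-1])),
            class = "network_arch")
}

#' @export
format.network_arch <- function(x, ...) {
  paste0(if (x$type == "quadratic") "Q" else "C",
         "(", paste(x$dims, collapse = "-"), ")")
}

#' @export
print.network_arch <- function(x, ...) {
  cat("<network_arch>", format(x), "-", x$n_neurons, "neurons\n")
  invisible(x)
}

#' Parse an architecture label
#'
#' Accepts `"Q(2-3)"`, `"C(2-100-3)"` or the colon form `"Q:2-3"`.
#'
#' @param label architecture string.
#' @return A [network_arch()].
#' @export
parse_arch <- function(label) {
  m <- regmatches(label, regexec("^([CQ])[(:]([0-9-]+)\\)?$", label))[[1]]
  if (length(m) != 3)
    stop("cannot parse architecture label '", label, "'")
  network_arch(as.integer(strsplit(m[3], "-")[[1]]),
               if (m[2] == "Q") "quadratic" else "conventional")
}

#' Affine (conventional) layer forward pass
#'
#' `z = a w + b` with the bias row broadcast over samples.
#'
#' @param a `N x d_from` input matrix.
#' @param layer list with `w` (`d_from x d_to`) and `b` (length `d_to`).
#' @return `N x d_to` pre-activation matrix.
#' @export
affine_forward <- function(a, layer) {
  if (ncol(a) != nrow(layer$w)) stop("input/weight shape mismatch")
  add_bias(a %*% layer$w, layer$b)
}

#' Quadratic layer forward pass
#'
#' The quadratic pre-activation is
#' `z = (a w_r + b_r) o (a w_g + b_g) + (a o a) w_b + c`
#' where `o` is the element-wise (Hadamard) product — so `a o a` squares the
#' inputs.  The three constituent parts `z_r`, `z_g`, `z_b` are returned
#' alongside `z` because backpropagation needs them.
#'
#' @param a `N x d_from` input matrix.
#' @param layer list with matrices `w_r`, `w_g`, `w_b` (`d_from x d_to`) and
#'   rows `b_r`, `b_g`, `c` (length `d_to`).
#' @return list with `z`, `z_r`, `z_g`, `z_b`.
#' @export
quadratic_forward <- function(a, layer) {
  if (ncol(a) != nrow(layer$w_r)) stop("input/weight shape mismatch")
  z_r <- add_bias(a %*% layer$w_r, layer$b_r)
  z_g <- add_bias(a %*% layer$w_g, layer$b_g)
  z_b <- add_bias((a * a) %*% layer$w_b, layer$c)
  list(z = z_r * z_g + z_b, z_r = z_r, z_g = z_g, z_b = z_b)
}

#' Layer activation
#'
#' Hidden layers use the ReLU `max(z, 0)`; the output layer uses a row-wise
#' softmax computed shift-invariantly (row max subtracted) so each output
#' row sums to 1.
#'
#' @param z pre-activation matrix.
#' @param output is this the output (softmax) layer?
#' @return activation matrix of the same shape.
#' @export
activate <- function(z, output = FALSE) {
  if (!all(is.finite(z))) stop("non-finite pre-activation")
  if (!output) return(pmax(z, 0))
  E <- exp(z - row_max(z))
  E / rowSums(E)
}

#' Full forward pass with cache
#'
#' Applies every layer's transform and activation, storing the per-layer
#' inputs and pre-activations (including the quadratic parts) that
#' backpropagation consumes.
#'
#' @param net a network as returned by [init_network()].
#' @param x `N x d1` input matrix.
#' @return An object of class `forward_cache`: per-layer list with `a_in`,
#'   `z` (and `z_r`, `z_g`, `z_b` for quadratic layers), `a_out`; element
#'   `output` is the final `N x K` softmax matrix.
#' @export
forward_pass <- function(net, x) {
  x <- as.matrix(x)
  if (ncol(x) != net$arch$dims[1]) stop("input has wrong dimension")
  L <- net$arch$L
  layers <- vector("list", L)
  a <- x
  for (l in seq_len(L)) {
    is_out <- l == L
    if (net$arch$type == "quadratic") {
      f <- quadratic_forward(a, net$layers[[l]])
      a_next <- activate(f$z, output = is_out)
      layers[[l]] <- list(a_in = a, z = f$z, z_r = f$z_r, z_g = f$z_g,
                          z_b = f$z_b, a_out = a_next)
    } else {
      z <- affine_forward(a, net$layers[[l]])
      a_next <- activate(z, output = is_out)
      layers[[l]] <- list(a_in = a, z = z, a_out = a_next)
    }
    a <- a_next
  }
  structure(list(layers = layers, output = a), class = "forward_cache")
}

#' Predicted labels from network output
#'
#' Row-wise argmax of the output probabilities; ties break toward the
#' smallest index.  Labels are 0-based.
#'
#' @param x a `forward_cache` or an `N x K` output matrix.
#' @return integer vector of 0-based labels.
#' @export
predict_labels <- function(x) {
  out <- if (inherits(x, "forward_cache")) x$output else as.matrix(x)
  max.col(out, ties.method = "first") - 1L
}

#' Cross-entropy loss
#'
#' `Q = -sum_n t_n . log y_n` over the batch; with `mode = "mean"` the sum
#' is divided by `N` so that one learning rate works across batch sizes.
#' Probabilities are clipped below at `1e-12` before the log.
#'
#' @param output `N x K` matrix of predicted class probabilities.
#' @param t_onehot `N x K` one-hot target matrix.
#' @param mode `"mean"` (default) or `"sum"`.
#' @return scalar loss.
#' @export
cross_entropy <- function(output, t_onehot, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  stopifnot(all(dim(output) == dim(t_onehot)))
  Q <- -sum(t_onehot * base::log(pmax(output, 1e-12)))
  if (mode == "mean") Q / nrow(output) else Q
}

#' Gradient at the softmax pre-activation
#'
#' For softmax output with cross-entropy loss, `dQ/dz = y - t` (divided by
#' `N` in mean mode).
#'
#' @inheritParams cross_entropy
#' @return `N x K` gradient matrix.
#' @export
output_grad <- function(output, t_onehot, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  G <- output - t_onehot
  if (mode == "mean") G / nrow(output) else G
}

#' ReLU backward pass
#'
#' Passes the upstream gradient where the activation is positive and zero
#' elsewhere (the derivative at the kink is taken as 0).
#'
#' @param upstream `dQ/da` for the layer's output.
#' @param activation the cached ReLU output `a`.
#' @return `dQ/dz`, same shape.
#' @export
relu_grad <- function(upstream, activation) {
  stopifnot(all(dim(upstream) == dim(activation)))
  upstream * (activation > 0)
}

#' Conventional layer backward pass
#'
#' `dQ/dw = a^T dQ/dz`, `dQ/db = column sums of dQ/dz`,
#' `dQ/da = dQ/dz w^T`.
#'
#' @param layer conventional layer parameters.
#' @param a_in cached layer input.
#' @param dz gradient at the pre-activation.
#' @return list with `dw`, `db`, `da`.
#' @export
conventional_backward <- function(layer, a_in, dz) {
  list(dw = crossprod(a_in, dz),
       db = colSums(dz),
       da = tcrossprod(dz, layer$w))
}

#' Quadratic layer backward pass
#'
#' With `dQ/dz_r = z_g o dQ/dz`, `dQ/dz_g = z_r o dQ/dz`, `dQ/dz_b = dQ/dz`,
#' the parameter gradients are `a^T`-products (the squared input
#' `(a o a)^T` for `w_b`) and column sums, and the input gradient is
#' `dQ/da = dQ/dz_r w_r^T + dQ/dz_g w_g^T + 2 a o (dQ/dz_b w_b^T)`.
#'
#' @param layer quadratic layer parameters.
#' @param a_in cached layer input.
#' @param z_r,z_g cached affine parts of the forward pass.
#' @param dz gradient at the pre-activation.
#' @return list with `dw_r`, `db_r`, `dw_g`, `db_g`, `dw_b`, `dc`, `da`.
#' @export
quadratic_backward <- function(layer, a_in, z_r, z_g, dz) {
  dz_r <- z_g * dz
  dz_g <- z_r * dz
  list(dw_r = crossprod(a_in, dz_r),
       db_r = colSums(dz_r),
       dw_g = crossprod(a_in, dz_g),
       db_g = colSums(dz_g),
       dw_b = crossprod(a_in * a_in, dz),
       dc = colSums(dz),
       da = tcrossprod(dz_r, layer$w_r) + tcrossprod(dz_g, layer$w_g) +
         2 * a_in * tcrossprod(dz, layer$w_b))
}

#' All parameter gradients of a network on a batch
#'
#' Runs the layer-wise backward recursion from the output gradient
#' ([output_grad()]) through ReLU masks and the per-layer backward rules.
#'
#' @param net a network.
#' @param cache the [forward_pass()] cache for the batch.
#' @param t_onehot one-hot targets for the batch.
#' @param mode loss normalization mode, see [cross_entropy()].
#' @return list of per-layer gradient lists, shape-congruent with
#'   `net$layers`.
#' @export
network_gradients <- function(net, cache, t_onehot,
                              mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  L <- net$arch$L
  grads <- vector("list", L)
  dz <- output_grad(cache$output, t_onehot, mode)
  for (l in rev(seq_len(L))) {
    cl <- cache$layers[[l]]
    if (net$arch$type == "quadratic") {
      g <- quadratic_backward(net$layers[[l]], cl$a_in, cl$z_r, cl$z_g, dz)
    } else {
      g <- conventional_backward(net$layers[[l]], cl$a_in, dz)
    }
    da <- g$da
    g$da <- NULL
    grads[[l]] <- g
    if (l > 1) dz <- relu_grad(da, cache$layers[[l - 1]]$a_out)
  }
  grads
}
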