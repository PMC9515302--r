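#' Randomly initialize a network
#'
#' Every weight matrix (`w`, or `w_r`/`w_g`/`w_b`) is `0.01` times a
#' standard-normal draw of shape `d_from x d_to`; every bias row (`b`, or
#' `b_r`/`b_g`/`c`) starts at zero.
#'
#' @param arch a [network_arch()].
#' @return An object of class `qnn`: list with `arch` and per-layer
#'   parameter lists.
#' @export
init_network <- function(arch) {
  stopifnot(inherits(arch, "network_arch"))
  w0 <- function(d_from, d_to) 0.01 * matrix(stats::rnorm(d_from * d_to),
                                             d_from, d_to)
  layers <- lapply(seq_len(arch$L), function(l) {
    d_from <- arch$dims[l]; d_to <- arch$dims[l + 1]
    if (arch$type == "quadratic")
      list(w_r = w0(d_from, d_to), b_r = numeric(d_to),
           w_g = w0(d_from, d_to), b_g = numeric(d_to),
           w_b = w0(d_from, d_to), c = numeric(d_to))
    else
      list(w = w0(d_from, d_to), b = numeric(d_to))
  })
  structure(list(arch = arch, layers = layers), class = "qnn")
}

#' @export
print.qnn <- function(x, ...) {
  cat("<qnn>", format(x$arch), "network,", x$arch$n_neurons, "neurons\n")
  invisible(x)
}

#' @export
predict.qnn <- function(object, newdata,
                        type = c("class", "prob"), ...) {
  type <- match.arg(type)
  cache <- forward_pass(object, newdata)
  if (type == "prob") cache$output else predict_labels(cache)
}

#' Training configuration
#'
#' @param max_epochs maximum number of full-batch epochs.
#' @param learning_rate Adam step size.
#' @param beta1,beta2,epsilon Adam moment decay rates and stabilizer.
#' @param patience epochs without validation-loss improvement before
#'   stopping.
#' @param loss_mode `"mean"` (default) or `"sum"`; see [cross_entropy()].
#' @return list of class `train_config`.
#' @export
train_config <- function(max_epochs = 2000, learning_rate = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                         patience = 100, loss_mode = c("mean", "sum")) {
  stopifnot(max_epochs >= 1, patience >= 0, learning_rate > 0)
  structure(list(max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, beta1 = beta1,
                 beta2 = beta2, epsilon = epsilon,
                 patience = as.integer(patience),
                 loss_mode = match.arg(loss_mode)),
            class = "train_config")
}

#' Fresh Adam optimizer state for a network
#'
#' First- and second-moment accumulators, zero-initialized and
#' shape-congruent with the network's parameters, plus a step counter.
#'
#' @param net a network.
#' @param config a [train_config()] supplying the hyperparameters.
#' @return list of class `adam_state`.
#' @export
adam_init <- function(net, config = train_config()) {
  zeros <- lapply(net$layers, function(ly) lapply(ly, function(p) p * 0))
  structure(list(m = zeros, v = zeros, step = 0L,
                 learning_rate = config$learning_rate,
                 beta1 = config$beta1, beta2 = config$beta2,
                 epsilon = config$epsilon),
            class = "adam_state")
}

#' One Adam update over all network parameters
#'
#' Standard Adam with bias-corrected first and second moments:
#' `theta <- theta - lr * mhat / (sqrt(vhat) + eps)`.
#'
#' @param net a network.
#' @param grads gradients from [network_gradients()].
#' @param state an [adam_init()] state.
#' @return list with the updated `net` and `state`.
#' @export
adam_update <- function(net, grads, state) {
  t_ <- state$step + 1L
  c1 <- 1 - state$beta1^t_
  c2 <- 1 - state$beta2^t_
  for (l in seq_along(net$layers)) {
    for (nm in names(net$layers[[l]])) {
      g <- grads[[l]][[if (nm == "c") "dc" else paste0("d", nm)]]
      m <- state$beta1 * state$m[[l]][[nm]] + (1 - state$beta1) * g
      v <- state$beta2 * state$v[[l]][[nm]] + (1 - state$beta2) * g * g
      state$m[[l]][[nm]] <- m
      state$v[[l]][[nm]] <- v
      net$layers[[l]][[nm]] <- net$layers[[l]][[nm]] -
        state$learning_rate * (m / c1) / (sqrt(v / c2) + state$epsilon)
    }
  }
  state$step <- t_
  list(net = net, state = state)
}

#' Train a network by full-batch Adam with validation monitoring
#'
#' Repeats forward computation and backpropagation on the full training
#' batch, recording cross-entropy on the training and validation samples
#' each epoch.  Stops at `max_epochs` or once the validation loss has not
#' improved for `patience` consecutive epochs; the parameters from the best
#' validation epoch are returned.
#'
#' @param net an initialized network ([init_network()]).
#' @param split a `data_split` (train/validation used here), or a list with
#'   `train` and `validation` `labeled_dataset`s.
#' @param config a [train_config()].
#' @return An object of class `qnn_fit`: `net` (best-validation
#'   parameters), `history` (data frame: epoch, train_loss, val_loss),
#'   `best_epoch`, `epochs_run`, `config`.
#' @export
train_network <- function(net, split, config = train_config()) {
  K <- net$arch$dims[net$arch$L + 1]
  if (split$train$K != K)
    stop("split class count (", split$train$K,
         ") does not match the output layer (", K, ")")
  Xtr <- split$train$samples
  Ttr <- one_hot(split$train$labels, K)
  Xva <- split$validation$samples
  ## indexed cross-entropy: on exact one-hot targets -sum(t * log y)
  ## reduces to -sum(log y[true class]), sparing two N x K products per
  ## evaluation; cached row/column indices
  itr <- cbind(seq_len(nrow(Xtr)), split$train$labels + 1L)
  iva <- cbind(seq_len(nrow(Xva)), split$validation$labels + 1L)
  ce_idx <- function(output, idx) {
    s <- -sum(base::log(pmax(output[idx], 1e-12)))
    if (config$loss_mode == "mean") s / nrow(output) else s
  }
  state <- adam_init(net, config)
  best_val <- Inf
  best_net <- net
  best_epoch <- 0L
  wait <- 0L
  tr_hist <- va_hist <- numeric(config$max_epochs)
  ep <- 0L
  for (ep in seq_len(config$max_epochs)) {
    cache <- forward_pass(net, Xtr)
    tr_loss <- ce_idx(cache$output, itr)
    if (!is.finite(tr_loss))
      stop("training diverged (non-finite loss) at epoch ", ep)
    grads <- network_gradients(net, cache, Ttr, config$loss_mode)
    upd <- adam_update(net, grads, state)
    net <- upd$net
    state <- upd$state
    va_loss <- ce_idx(forward_pass(net, Xva)$output, iva)
    tr_hist[ep] <- tr_loss
    va_hist[ep] <- va_loss
    if (va_loss < best_val) {
      best_val <- va_loss
      best_net <- net
      best_epoch <- ep
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience && config$patience > 0) break
    }
  }
  structure(list(net = best_net,
                 history = data.frame(epoch = seq_len(ep),
                                      train_loss = tr_hist[seq_len(ep)],
                                      val_loss = va_hist[seq_len(ep)]),
                 best_epoch = best_epoch, epochs_run = ep,
                 config = config),
            class = "qnn_fit")
}

#' @export
print.qnn_fit <- function(x, ...) {
  cat("<qnn_fit>", format(x$net$arch), "- trained", x$epochs_run,
      "epochs, best validation loss",
      format(min(x$history$val_loss), digits = 4),
      "at epoch", x$best_epoch, "\n")
  invisible(x)
}

#' @export
predict.qnn_fit <- function(object, newdata, ...) {
  predict(object$net, newdata, ...)
}

#' Serialize network parameters to JSON
#'
#' Stores the architecture label and the flattened parameter tensors.
#'
#' @param net a `qnn` or `qnn_fit`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  if (inherits(net, "qnn_fit")) net <- net$net
  obj <- list(arch = format(net$arch), dims = net$arch$dims,
              type = net$arch$type, layers = net$layers)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path)
  arch <- network_arch(unlist(obj$dims), obj$type)
  layers <- lapply(seq_len(arch$L), function(l) {
    ly <- obj$layers[[l]]
    lapply(ly, function(p) {
      if (is.list(p) && is.list(p[[1]])) json_matrix(p) else unlist(p)
    })
  })
  structure(list(arch = arch, layers = layers), class = "qnn")
}
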