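# Independent oracles used across the suite.  These deliberately avoid the
# package's own computational paths: densities via the textbook formula with
# solve()/det(), gradients via central finite differences of the full loss,
# label alignment via exhaustive permutation search.

# Textbook multivariate normal density (no log-space, no Cholesky).
naive_mvn_density <- function(x, mean, covariance) {
  x <- if (is.null(dim(x))) matrix(x, 1) else as.matrix(x)
  D <- ncol(x)
  Cinv <- solve(covariance)
  dt <- det(covariance)
  apply(x, 1, function(row) {
    d <- row - mean
    exp(-0.5 * drop(t(d) %*% Cinv %*% d)) / sqrt((2 * pi)^D * dt)
  })
}

# Direct evaluation of the posterior: weighted densities, row-normalized.
naive_posterior <- function(x, model) {
  priors <- model_priors(model)
  W <- sapply(seq_len(model$K), function(k)
    priors[k] * naive_mvn_density(x, model$components[[k]]$mean,
                                  model$components[[k]]$covariance))
  W <- matrix(W, ncol = model$K)
  W / rowSums(W)
}

# All permutations of 0:(K-1), K small.
all_permutations <- function(K) {
  if (K == 1) return(list(0L))
  sub <- all_permutations(K - 1)
  out <- list()
  for (p in sub) for (pos in 0:(K - 1)) {
    out[[length(out) + 1L]] <- append(p, K - 1L, after = pos)
  }
  out
}

# Best achievable accuracy over every relabelling of the predictions.
exhaustive_best_accuracy <- function(pred, truth, K) {
  best <- 0
  for (p in all_permutations(K)) {
    best <- max(best, mean(p[pred + 1L] == truth))
  }
  best
}

# Full-network loss as a function of one flattened parameter tensor, used
# for finite-difference gradient checks.
net_loss_perturbed <- function(net, x, t_onehot, l, nm, theta, mode) {
  dim_orig <- dim(net$layers[[l]][[nm]])
  net$layers[[l]][[nm]] <- if (is.null(dim_orig)) theta else
    matrix(theta, dim_orig[1], dim_orig[2])
  cross_entropy(forward_pass(net, x)$output, t_onehot, mode)
}

# Central finite differences of the loss w.r.t. every parameter of layer l.
fd_layer_gradients <- function(net, x, t_onehot, l, h = 1e-5,
                               mode = "mean") {
  out <- list()
  for (nm in names(net$layers[[l]])) {
    theta <- as.numeric(net$layers[[l]][[nm]])
    g <- vapply(seq_along(theta), function(i) {
      tp <- theta; tp[i] <- tp[i] + h
      tm <- theta; tm[i] <- tm[i] - h
      (net_loss_perturbed(net, x, t_onehot, l, nm, tp, mode) -
         net_loss_perturbed(net, x, t_onehot, l, nm, tm, mode)) / (2 * h)
    }, 1.0)
    dim_orig <- dim(net$layers[[l]][[nm]])
    out[[nm]] <- if (is.null(dim_orig)) g else
      matrix(g, dim_orig[1], dim_orig[2])
  }
  out
}

# Relative error between analytic and finite-difference tensors, with an
# absolute floor so near-zero entries do not blow up the ratio.
rel_err <- function(a, b, floor = 1e-6) {
  max(abs(a - b) / pmax(abs(a) + abs(b), floor))
}

# Map gradient names (dw, db_r, dc, ...) back to parameter names.
grad_name <- function(nm) if (nm == "c") "dc" else paste0("d", nm)

# A small random network of the given shape for gradient checks.
random_net <- function(dims, type, scale = 0.5) {
  net <- init_network(network_arch(dims, type))
  for (l in seq_along(net$layers))
    for (nm in names(net$layers[[l]]))
      net$layers[[l]][[nm]] <- net$layers[[l]][[nm]] * 0 +
        scale * stats::rnorm(length(net$layers[[l]][[nm]]))
  net
}

# Well-separated K-cluster mixture in D dimensions for recovery tests:
# means on a circle of radius 3 in the first two coordinates, isotropic
# covariances with sd sigma.  Pairwise mean distance is 6 sin(pi/K), i.e.
# > 10 sigma for K <= 4 at the default sigma, while the cluster region
# stays within reach of the standard-normal EM initialization (means much
# further out make single-restart EM's local optima, not the estimator,
# the thing under test).
separated_task <- function(D, K, n_per, sigma = 0.4) {
  stopifnot(D >= 2)
  comps <- lapply(seq_len(K), function(k) {
    ang <- 2 * pi * (k - 1) / K + 0.3
    mu <- rep(0, D)
    mu[1:2] <- 3 * c(cos(ang), sin(ang))
    gaussian_component(mu, diag(sigma^2, D), 1 / K)
  })
  model <- gmm_model(comps)
  X <- do.call(rbind, lapply(seq_len(K), function(k)
    sweep(matrix(stats::rnorm(n_per * D, sd = sigma), n_per, D), 2,
          comps[[k]]$mean, "+")))
  list(model = model,
       data = labeled_dataset(X, rep(seq_len(K) - 1L, each = n_per), K))
}
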