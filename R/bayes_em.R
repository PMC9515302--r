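## Row-wise maximum of an N x K matrix without apply() overhead: one
## C-level pass to locate the maxima, one indexing pass to extract them.
row_max <- function(M) {
  M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
}

## Stabilized upper Cholesky factor: falls back to C + 1e-6 I when the
## plain factorization fails (near-singular 2 a a^T draws, collapsed EM
## components).  Errors out if even the stabilized matrix is unusable.
stable_chol <- function(covariance) {
  ch <- tryCatch(chol(covariance), error = function(e) NULL)
  if (is.null(ch)) {
    D <- nrow(covariance)
    ch <- tryCatch(chol(covariance + 1e-6 * diag(D)), error = function(e) NULL)
    if (is.null(ch))
      stop("covariance cannot be stabilized for density evaluation")
  }
  ch
}

#' Multivariate normal density
#'
#' Density of `N(mean, covariance)` at each row of `x`, computed in log
#' space via the Cholesky factor.  Near-singular covariances are stabilized
#' by adding `1e-6 * I` only when the plain factorization fails.
#'
#' @param x `N x D` matrix (or length-`D` vector for a single point).
#' @param comp a [gaussian_component()], or any list with `mean` and
#'   `covariance`.
#' @param log return log-densities?
#' @return length-`N` numeric vector.
#' @export
gaussian_density <- function(x, comp, log = FALSE) {
  x <- if (is.null(dim(x))) matrix(x, 1) else as.matrix(x)
  D <- ncol(x)
  stopifnot(length(comp$mean) == D)
  ch <- stable_chol(comp$covariance)
  Xc <- x - rep(comp$mean, each = nrow(x))   # column-major broadcast
  ## rows of Z solve  t(ch) z = xc,  so rowSums(Z^2) is the Mahalanobis form
  Z <- Xc %*% backsolve(ch, diag(D))
  ld <- -0.5 * rowSums(Z * Z) - sum(base::log(diag(ch))) -
    0.5 * D * base::log(2 * pi)
  if (log) ld else exp(ld)
}

## N x K matrix of log(pi_k) + log N(x | mu_k, C_k); the shared core of
## posterior computation and EM's E step.
log_weighted_densities <- function(x, model) {
  x <- as.matrix(x)
  priors <- model_priors(model)
  LD <- matrix(0, nrow(x), model$K)
  for (k in seq_len(model$K))
    LD[, k] <- base::log(priors[k]) +
      gaussian_density(x, model$components[[k]], log = TRUE)
  LD
}

#' Posterior class probabilities under a mixture model
#'
#' `p(z_k = 1 | x_n) = pi_k N(x_n | mu_k, C_k) / sum_i pi_i N(x_n | mu_i, C_i)`,
#' computed with a log-sum-exp so rows normalize even when every component
#' density underflows.
#'
#' @param x `N x D` sample matrix.
#' @param model a `gmm_model` with valid priors.
#' @return `N x K` matrix; each row sums to 1.
#' @export
gmm_posterior <- function(x, model) {
  LD <- log_weighted_densities(x, model)
  m <- row_max(LD)
  S <- exp(LD - m)
  S / rowSums(S)
}

#' Bayes-rule class assignment
#'
#' Assigns each sample to the component with the largest posterior
#' probability; ties break toward the smallest index.
#'
#' @inheritParams gmm_posterior
#' @return integer vector of 0-based labels.
#' @export
bayes_infer <- function(x, model) {
  LD <- log_weighted_densities(x, model)
  max.col(LD, ties.method = "first") - 1L
}

#' Classification accuracy
#'
#' @param pred,truth equal-length label vectors.
#' @return fraction of exact matches, in `[0, 1]`.
#' @export
class_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length")
  mean(pred == truth)
}

#' Initial EM state
#'
#' Means are drawn from the standard normal, covariances start as identity
#' matrices, and priors are uniform `1/K`.
#'
#' @param D dimension.
#' @param K number of components.
#' @return An object of class `em_state`: `model`, `iteration = 0`,
#'   `log_likelihood = NA`, empty `ll_trace`.
#' @export
em_init <- function(D, K) {
  stopifnot(K >= 1, D >= 1)
  comps <- lapply(seq_len(K), function(k)
    gaussian_component(stats::rnorm(D), diag(1, D), 1 / K))
  structure(list(model = gmm_model(comps), iteration = 0L,
                 log_likelihood = NA_real_, ll_trace = numeric()),
            class = "em_state")
}

#' @export
print.em_state <- function(x, ...) {
  cat("<em_state> K =", x$model$K, "D =", x$model$D,
      "iteration =", x$iteration,
      "log-likelihood =", format(x$log_likelihood), "\n")
  invisible(x)
}

#' One EM iteration
#'
#' The E step evaluates responsibilities from the current parameters
#' (log-space, row-normalized); the M step re-estimates means, covariances
#' and priors from the weighted sample moments.  The log-likelihood recorded
#' in the returned state is that of the *entering* parameters, so the trace
#' across iterations is the usual EM objective sequence.
#'
#' @param state an `em_state`.
#' @param x `N x D` sample matrix.
#' @param cov_mean `"updated"` (default) recenters the covariance on the
#'   freshly updated mean — the standard M step; `"current"` uses the
#'   entering iterate's mean instead, a variant kept for comparison (it
#'   forfeits the monotonicity guarantee).
#' @return the updated `em_state` (iteration incremented).
#' @export
em_step <- function(state, x, cov_mean = c("updated", "current")) {
  cov_mean <- match.arg(cov_mean)
  x <- as.matrix(x)
  N <- nrow(x); D <- ncol(x); K <- state$model$K
  LD <- log_weighted_densities(x, state$model)
  m <- row_max(LD)
  S <- exp(LD - m)
  rs <- rowSums(S)
  ll <- sum(m + base::log(rs))
  if (!is.finite(ll))
    stop("non-finite log-likelihood at iteration ", state$iteration)
  R <- S / rs                       # responsibilities, rows sum to 1
  nk <- colSums(R)
  mus <- Cs <- vector("list", K)
  for (k in seq_len(K)) {
    if (nk[k] < .Machine$double.eps * N) {
      ## collapsed component: reinitialize from a random data point
      message("EM: component ", k, " lost all responsibility at iteration ",
              state$iteration, "; reinitializing from a random sample")
      mus[[k]] <- x[sample.int(N, 1), ]
      Cs[[k]] <- diag(1, D)
      nk[k] <- 1
      next
    }
    mu_new <- colSums(R[, k] * x) / nk[k]
    center <- if (cov_mean == "updated") mu_new else
      state$model$components[[k]]$mean
    Xc <- x - rep(center, each = N)
    C_new <- crossprod(Xc, R[, k] * Xc) / nk[k]
    mus[[k]] <- mu_new
    Cs[[k]] <- (C_new + t(C_new)) / 2   # kill round-off asymmetry
  }
  pri <- nk / sum(nk)
  comps <- lapply(seq_len(K), function(k)
    gaussian_component(mus[[k]], Cs[[k]], pri[k]))
  structure(list(model = gmm_model(comps),
                 iteration = state$iteration + 1L,
                 log_likelihood = ll,
                 ll_trace = c(state$ll_trace, ll)),
            class = "em_state")
}

#' Fit a Gaussian mixture by EM
#'
#' Iterates [em_step()] from an [em_init()] state until the relative change
#' in log-likelihood drops below `tol` or `max_iter` iterations have run.
#'
#' The default tolerance is deliberately tight: EM traverses long plateaus
#' while two components slowly disentangle, during which the per-iteration
#' log-likelihood gain is tiny although the parameters are still far from
#' a fixed point.  At `1e-6` fits on mixture classification tasks stop
#' mid-plateau (tightening the tolerance changes the fitted parameters and
#' the downstream accuracy); at `1e-8` further tightening changes nothing.
#'
#' @param x `N x D` sample matrix.
#' @param K number of components.
#' @param tol relative log-likelihood change below which to stop.
#' @param max_iter maximum number of EM iterations.
#' @inheritParams em_step
#' @return the final `em_state`, with an added logical element `converged`.
#' @export
em_fit <- function(x, K, tol = 1e-8, max_iter = 500,
                   cov_mean = c("updated", "current")) {
  cov_mean <- match.arg(cov_mean)
  stopifnot(max_iter >= 1)
  x <- as.matrix(x)
  state <- em_init(ncol(x), K)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    state <- em_step(state, x, cov_mean = cov_mean)
    ll <- state$log_likelihood
    ## relative-change rule in product form: with tol = Inf this accepts
    ## immediately (one step); with finite tol the first iteration cannot
    ## trigger it because ll_old is -Inf
    if (abs(ll - ll_old) <= tol * abs(ll)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  state$converged <- converged
  state
}

## Apply a label permutation: mapping[p + 1] relabels prediction p.
apply_permutation <- function(mapping, pred) mapping[pred + 1L]

#' Align predicted cluster labels to ground truth by pairwise swaps
#'
#' Mixture components are recovered in arbitrary order, so predicted labels
#' must be permuted before accuracy against ground truth is meaningful.
#' Exhaustive search over all `K!` permutations is exponential; instead an
#' alternating-variables hill climb sweeps all label pairs `(i < j)` in
#' lexicographic order, accepting any swap that strictly increases accuracy,
#' and repeats the sweep up to `max_cycle` times or until no swap helps.
#'
#' @param pred,truth 0-based label vectors of equal length.
#' @param K number of classes.
#' @param max_cycle maximum number of full sweeps (default 20, ample for
#'   `K <= 8`).
#' @return list with `mapping` (length-`K` permutation: prediction `p`
#'   becomes `mapping[p + 1]`), `labels` (corrected predictions) and
#'   `accuracy`.
#' @export
order_correction <- function(pred, truth, K, max_cycle = 20) {
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length")
  if (any(pred < 0 | pred >= K) || any(truth < 0 | truth >= K))
    stop("labels must lie in [0, K)")
  ## confusion counts: agreement of "pred == p scored as class m" is
  ## sum over p of conf[p + 1, mapping[p + 1] + 1]
  conf <- table(factor(pred, levels = 0:(K - 1)),
                factor(truth, levels = 0:(K - 1)))
  conf <- matrix(as.numeric(conf), K, K)
  mapping <- 0:(K - 1)
  score <- sum(conf[cbind(seq_len(K), mapping + 1L)])
  for (cyc in seq_len(max_cycle)) {
    improved <- FALSE
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      cand <- mapping
      cand[c(i, j)] <- cand[c(j, i)]
      s <- sum(conf[cbind(seq_len(K), cand + 1L)])
      if (s > score) {            # strict: ties rejected so sweeps terminate
        mapping <- cand
        score <- s
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  labels <- apply_permutation(mapping, pred)
  list(mapping = mapping, labels = labels,
       accuracy = score / length(pred))
}

#' Serialize a fitted or ground-truth mixture model to JSON
#'
#' Means, covariances and priors in the same schema for ground-truth and
#' EM-estimated models; `em_state` objects also store the log-likelihood
#' trace.
#'
#' @param model a `gmm_model` or `em_state`.
#' @param path output JSON file.
#' @param mapping optional label permutation from [order_correction()],
#'   stored alongside the parameters so the serialized model records how
#'   its component order was aligned to ground truth.
#' @return `path`, invisibly.
#' @export
write_gmm <- function(model, path, mapping = NULL) {
  extra <- list()
  if (!is.null(mapping)) extra$permutation <- as.integer(mapping)
  if (inherits(model, "em_state")) {
    extra <- c(extra,
               list(iteration = model$iteration, ll_trace = model$ll_trace,
                    converged = isTRUE(model$converged)))
    model <- model$model
  }
  obj <- c(list(D = model$D, K = model$K,
                means = lapply(model$components, function(cp) cp$mean),
                covariances = lapply(model$components,
                                     function(cp) cp$covariance),
                priors = model_priors(model)),
           extra)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_gmm
#' @export
read_gmm <- function(path) {
  obj <- jsonlite::read_json(path)
  comps <- lapply(seq_len(obj$K), function(k)
    gaussian_component(unlist(obj$means[[k]]),
                       json_matrix(obj$covariances[[k]]),
                       obj$priors[[k]]))
  gmm_model(comps)
}
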