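#' Gaussian mixture component
#'
#' Bundle a mean vector, covariance matrix and (optionally) a mixing prior
#' into a validated component object.  Components are the building blocks of
#' a [gmm_model()], used both for ground-truth task parameters and for
#' EM-estimated parameters.
#'
#' @param mean numeric vector of length `D`.
#' @param covariance `D x D` symmetric positive-semidefinite matrix.
#' @param prior mixing probability in `[0, 1]`, or `NA` when the component is
#'   used outside a mixture context.
#' @return An object of class `gaussian_component`.
#' @export
gaussian_component <- function(mean, covariance, prior = NA_real_) {
  mean <- as.numeric(mean)
  covariance <- as.matrix(covariance)
  D <- length(mean)
  stopifnot(nrow(covariance) == D, ncol(covariance) == D)
  if (max(abs(covariance - t(covariance))) > 1e-12)
    stop("covariance must be symmetric (tolerance 1e-12)")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("covariance must be positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  if (!is.na(prior) && (prior < 0 || prior > 1))
    stop("prior must lie in [0, 1]")
  structure(list(mean = mean, covariance = covariance, prior = prior),
            class = "gaussian_component")
}

#' @export
print.gaussian_component <- function(x, ...) {
  cat("<gaussian_component> D =", length(x$mean),
      if (!is.na(x$prior)) paste0("prior = ", signif(x$prior, 4)), "\n")
  invisible(x)
}

#' Gaussian mixture model
#'
#' An ordered list of [gaussian_component()]s sharing a common dimension.
#' When priors are present (Bayes inference, EM) they must sum to one.
#'
#' @param components list of `gaussian_component` objects.
#' @return An object of class `gmm_model` with elements `components`, `D`, `K`.
#' @export
gmm_model <- function(components) {
  stopifnot(length(components) >= 1,
            all(vapply(components, inherits, TRUE, "gaussian_component")))
  Ds <- vapply(components, function(cp) length(cp$mean), 1L)
  if (length(unique(Ds)) != 1)
    stop("all components must share the same dimension")
  priors <- vapply(components, function(cp) cp$prior, 1.0)
  if (!anyNA(priors) && abs(sum(priors) - 1) > 1e-9)
    stop("component priors must sum to 1 (got ", format(sum(priors)), ")")
  structure(list(components = components, D = Ds[1],
                 K = length(components)),
            class = "gmm_model")
}

#' @export
print.gmm_model <- function(x, ...) {
  cat("<gmm_model> K =", x$K, "components in D =", x$D, "dimensions\n")
  invisible(x)
}

#' Mixing priors of a mixture model
#' @param model a `gmm_model`.
#' @return numeric vector of length `K` (may contain `NA`).
#' @export
model_priors <- function(model) {
  vapply(model$components, function(cp) cp$prior, 1.0)
}

#' Labelled sample matrix
#'
#' @param samples `N x D` numeric matrix.
#' @param labels integer vector of length `N`, values in `[0, K)`.  Labels are
#'   0-based throughout the package.
#' @param K number of classes (defaults to `max(labels) + 1`).
#' @return An object of class `labeled_dataset` with elements `samples`,
#'   `labels`, `K`, `per_class_counts`.
#' @export
labeled_dataset <- function(samples, labels, K = max(labels) + 1L) {
  samples <- as.matrix(samples)
  labels <- as.integer(labels)
  stopifnot(nrow(samples) == length(labels))
  if (any(labels < 0L) || any(labels >= K))
    stop("labels must lie in [0, K)")
  counts <- tabulate(labels + 1L, nbins = K)
  structure(list(samples = samples, labels = labels, K = as.integer(K),
                 per_class_counts = counts),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset>", nrow(x$samples), "samples, D =", ncol(x$samples),
      ", K =", x$K, "\n  per-class counts:",
      paste(x$per_class_counts, collapse = " "), "\n")
  invisible(x)
}

## covariance construction shared by sample_cluster_params and tests:
## C = 2 a a^T is PSD by construction for any real square factor a.
cov_from_factor <- function(a) 2 * tcrossprod(a)

#' Draw random cluster parameters
#'
#' Mean entries are uniform on `[-5, 5)` (`(u - 0.5) * 10` with `u` uniform on
#' `[0, 1)`); the covariance is `2 a a^T` where `a` is a `D x D` matrix with
#' entries uniform on `[-1, 1)`.  Such covariances can be near-singular; the
#' generator does not regularize them — density evaluation downstream
#' stabilizes only when a Cholesky factorization fails.
#'
#' @param D dimension, a positive integer.
#' @return A `gaussian_component` (prior `NA`).
#' @export
sample_cluster_params <- function(D) {
  D <- as.integer(D)
  if (length(D) != 1 || is.na(D) || D < 1)
    stop("D must be a positive integer")
  mu <- (stats::runif(D) - 0.5) * 10
  a <- matrix(stats::runif(D * D) * 2 - 1, D, D)
  gaussian_component(mu, cov_from_factor(a))
}

#' Background component parameters
#'
#' Zero mean and `40 * I_D` covariance; the broad isotropic "background"
#' class of the illustrative task.
#'
#' @inheritParams sample_cluster_params
#' @return A `gaussian_component` (prior `NA`).
#' @export
background_params <- function(D) {
  D <- as.integer(D)
  if (length(D) != 1 || is.na(D) || D < 1)
    stop("D must be a positive integer")
  gaussian_component(rep(0, D), diag(40, D))
}

## Draw N points from N(mean, covariance) via the lower Cholesky factor.
## A tiny jitter keeps chol() defined for the (legitimately) rank-deficient
## covariances 2 a a^T can produce; it perturbs draws at the 1e-6 scale.
rmvn <- function(n, mean, covariance) {
  D <- length(mean)
  ch <- tryCatch(chol(covariance),
                 error = function(e) chol(covariance + 1e-12 * diag(D)))
  Z <- matrix(stats::rnorm(n * D), n, D)
  sweep(Z %*% ch, 2, mean, "+")
}

#' Generate a random GMM classification task
#'
#' Two recipes are supported.  `mode = "background"` (the illustrative task)
#' draws `K - 1` random clusters via [sample_cluster_params()], each with a
#' sample count drawn uniformly from `count_range`, plus one background class
#' ([background_params()]) with as many points as all clusters combined.
#' `mode = "all_clusters"` (the systematic task) draws `K` random clusters,
#' each with its own count from `count_range`.  Class priors recorded in the
#' returned model are the realized count fractions.
#'
#' @param D dimension.
#' @param K total number of classes (including the background class when
#'   `mode = "background"`); at least 2.
#' @param mode `"background"` or `"all_clusters"`.
#' @param count_range integer interval `c(lo, hi)` for per-cluster counts.
#' @return A list with elements `model` (a `gmm_model`, priors set to the
#'   realized class fractions) and `data` (a `labeled_dataset`, rows in class
#'   order — shuffle with [shuffle_split()]).
#' @export
generate_task <- function(D, K, mode = c("background", "all_clusters"),
                          count_range = c(6000, 9000)) {
  mode <- match.arg(mode)
  K <- as.integer(K)
  if (K < 2) stop("K must be at least 2")
  count_range <- as.integer(round(count_range))
  if (length(count_range) != 2 || any(count_range < 1) ||
      count_range[2] < count_range[1])
    stop("count_range must be a non-empty positive integer interval")
  n_random <- if (mode == "background") K - 1L else K
  comps <- lapply(seq_len(n_random), function(k) sample_cluster_params(D))
  counts <- sample(seq.int(count_range[1], count_range[2]), n_random,
                   replace = TRUE)
  if (mode == "background") {
    comps <- c(comps, list(background_params(D)))
    counts <- c(counts, sum(counts))  # N_b = sum over clusters
  }
  N <- sum(counts)
  X <- do.call(rbind, lapply(seq_len(K), function(k)
    rmvn(counts[k], comps[[k]]$mean, comps[[k]]$covariance)))
  labels <- rep(seq_len(K) - 1L, counts)
  comps <- lapply(seq_len(K), function(k)
    gaussian_component(comps[[k]]$mean, comps[[k]]$covariance, counts[k] / N))
  list(model = gmm_model(comps),
       data = labeled_dataset(X, labels, K))
}

#' Shuffle a dataset and split it 50/20/30
#'
#' A single global permutation of the rows followed by contiguous slicing
#' into training, validation and test parts (not stratified).
#'
#' @param ds a `labeled_dataset`.
#' @param fractions length-3 fractions summing to 1; default `c(.5, .2, .3)`.
#' @param perm optional explicit permutation of `1:N` (mainly for tests);
#'   by default a uniform random permutation is drawn.
#' @return An object of class `data_split` with `labeled_dataset` elements
#'   `train`, `validation`, `test`, plus `fractions` and the `permutation`
#'   used.
#' @export
shuffle_split <- function(ds, fractions = c(0.5, 0.2, 0.3), perm = NULL) {
  stopifnot(inherits(ds, "labeled_dataset"))
  N <- nrow(ds$samples)
  if (N < 10) stop("need at least 10 samples to populate all three parts")
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9)
  if (is.null(perm)) perm <- sample.int(N)
  stopifnot(length(perm) == N, all(sort(perm) == seq_len(N)))
  n_train <- floor(fractions[1] * N)
  n_val <- floor(fractions[2] * N)
  idx <- list(train = perm[seq_len(n_train)],
              validation = perm[n_train + seq_len(n_val)],
              test = perm[(n_train + n_val + 1):N])
  parts <- lapply(idx, function(i)
    labeled_dataset(ds$samples[i, , drop = FALSE], ds$labels[i], ds$K))
  structure(c(parts, list(fractions = fractions, permutation = perm)),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat("<data_split> train/validation/test =",
      nrow(x$train$samples), "/", nrow(x$validation$samples), "/",
      nrow(x$test$samples), "\n")
  invisible(x)
}

#' One-hot encode integer labels
#'
#' @param labels integer vector with values in `[0, K)`.
#' @param K number of classes.
#' @return `N x K` binary matrix with a single 1 per row.
#' @export
one_hot <- function(labels, K) {
  labels <- as.integer(labels)
  if (any(labels < 0L) || any(labels >= K))
    stop("labels must lie in [0, K)")
  M <- matrix(0, length(labels), K)
  M[cbind(seq_along(labels), labels + 1L)] <- 1
  M
}

#' Write / read a task as CSV plus JSON sidecar
#'
#' The dataset persists as a CSV with feature columns `x1..xD` and an integer
#' `label` column; the ground-truth parameters (means, covariances, counts,
#' mode) go to a JSON sidecar next to it.
#'
#' @param task list with `model` and `data` as returned by [generate_task()].
#' @param path CSV file path; the sidecar is `<path>.json`.
#' @param mode recipe tag stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_task <- function(task, path, mode = NA_character_) {
  X <- task$data$samples
  df <- as.data.frame(X)
  names(df) <- paste0("x", seq_len(ncol(X)))
  df$label <- task$data$labels
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(
    D = task$model$D, K = task$model$K, mode = mode,
    per_class_counts = task$data$per_class_counts,
    means = lapply(task$model$components, function(cp) cp$mean),
    covariances = lapply(task$model$components, function(cp) cp$covariance),
    priors = model_priors(task$model))
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

## Rebuild a matrix from jsonlite's row-list representation.
json_matrix <- function(rows) do.call(rbind, lapply(rows, unlist))

#' @rdname write_task
#' @export
read_task <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"))
  X <- as.matrix(df[grep("^x[0-9]+$", names(df))])
  comps <- lapply(seq_len(side$K), function(k)
    gaussian_component(unlist(side$means[[k]]),
                       json_matrix(side$covariances[[k]]),
                       side$priors[[k]]))
  list(model = gmm_model(comps),
       data = labeled_dataset(X, df$label, side$K))
}
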