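#' Collect repetition-level accuracies into a result table
#'
#' @param df data frame with columns `method`, `repetition`, `accuracy`.
#' @param spec list of experiment metadata stored as an attribute.
#' @return `df` with class `result_table`.
#' @export
result_table <- function(df, spec = list()) {
  stopifnot(all(c("method", "repetition", "accuracy") %in% names(df)))
  structure(df, spec = spec, class = c("result_table", "data.frame"))
}

#' Summarize a result table
#'
#' Mean and standard deviation of accuracy per method, recomputed from the
#' stored repetition-level values.
#'
#' @param object a `result_table`.
#' @param ... unused.
#' @return data frame with `method`, `mean`, `sd`, `n`.
#' @export
summary.result_table <- function(object, ...) {
  methods <- unique(object$method)
  out <- data.frame(
    method = methods,
    mean = vapply(methods, function(m)
      mean(object$accuracy[object$method == m]), 1.0),
    sd = vapply(methods, function(m) {
      a <- object$accuracy[object$method == m]
      if (length(a) < 2) 0 else stats::sd(a)   # single repetition: sd 0
    }, 1.0),
    n = vapply(methods, function(m) sum(object$method == m), 1L),
    row.names = NULL)
  if (any(out$n < 2))
    attr(out, "note") <- "methods with a single repetition report sd = 0"
  out
}

#' @export
print.result_table <- function(x, ...) {
  cat("<result_table>\n")
  s <- summary(x)
  s$mean <- sprintf("%.4f", s$mean)
  s$sd <- sprintf("%.4f", s$sd)
  print.data.frame(s, row.names = FALSE)
  invisible(x)
}

## Score EM on one task: fit on the training split, classify the test split
## by the posterior argmax under the fitted parameters, align labels to
## ground truth by pairwise-swap order correction.
em_test_accuracy <- function(split, K, tol = 1e-8, max_iter = 500) {
  fit <- em_fit(split$train$samples, K, tol = tol, max_iter = max_iter)
  pred <- bayes_infer(split$test$samples, fit$model)
  oc <- order_correction(pred, split$test$labels, K)
  list(accuracy = oc$accuracy, fit = fit, mapping = oc$mapping)
}

## Score the Bayes rule with the TRUE task parameters on the test split.
bayes_test_accuracy <- function(split, model) {
  class_accuracy(bayes_infer(split$test$samples, model),
                 split$test$labels)
}

## Train one network on the split and score the test split.
network_test_accuracy <- function(arch, split, config) {
  fit <- train_network(init_network(arch), split, config)
  list(accuracy = class_accuracy(predict(fit, split$test$samples),
                                 split$test$labels),
       fit = fit)
}

## Default architecture set of the comparisons: conventional networks with
## no / 10-unit / 100-unit hidden layer, and the single-layer quadratic
## network, all from D inputs to K outputs.
default_architectures <- function(D, K) {
  list(network_arch(c(D, K), "conventional"),
       network_arch(c(D, 10, K), "conventional"),
       network_arch(c(D, 100, K), "conventional"),
       network_arch(c(D, K), "quadratic"))
}

#' Run the illustrative background task
#'
#' One task with two random Gaussian clusters plus a broad isotropic
#' background in 2D (`K = 3`), cluster counts uniform on `count_range` and
#' as many background points as cluster points combined.  Trains the four
#' reference networks, fits EM with order correction, scores everything on
#' the test split, and rasterizes decision boundaries.
#'
#' @param seed RNG seed for the whole run.
#' @param count_range per-cluster count interval; default `[20000, 30000]`.
#' @param config a [train_config()]; the default uses learning rate 0.04
#'   (full-batch gradients are exact, so a larger Adam step than the
#'   minibatch-oriented package default converges in hundreds of epochs)
#'   and a 600-epoch cap.
#' @param architectures list of [network_arch()]; defaults to C(2-3),
#'   C(2-10-3), C(2-100-3), Q(2-3).
#' @param grid_resolution boundary raster resolution per axis (0 disables
#'   boundary export).
#' @return list with `results` (a [result_table()]), `boundaries` (named
#'   list of [decision_boundary()] grids), `histories` (per-network loss
#'   histories), `task`, `split`, `em` (the EM state).
#' @export
run_illustrative <- function(seed = 1, count_range = c(20000, 30000),
                             config = train_config(max_epochs = 600,
                                                   learning_rate = 0.04),
                             architectures = default_architectures(2, 3),
                             grid_resolution = 200) {
  set.seed(seed)
  task <- generate_task(2, 3, mode = "background",
                        count_range = count_range)
  split <- shuffle_split(task$data)
  rows <- list()
  boundaries <- list()
  histories <- list()

  em <- em_test_accuracy(split, 3)
  rows[["EM"]] <- em$accuracy
  bayes_acc <- bayes_test_accuracy(split, task$model)
  rows[["Bayes(true)"]] <- bayes_acc
  em_classifier <- function(X) {
    apply_permutation(em$mapping, bayes_infer(X, em$fit$model))
  }
  nets <- list()
  for (arch in architectures) {
    lab <- format(arch)
    r <- network_test_accuracy(arch, split, config)
    rows[[lab]] <- r$accuracy
    histories[[lab]] <- r$fit$history
    nets[[lab]] <- r$fit
  }
  if (grid_resolution > 0) {
    rng_x <- grid_ranges(split$train$samples)
    boundaries[["EM"]] <- decision_boundary(em_classifier, rng_x,
                                            resolution = grid_resolution)
    for (lab in names(nets))
      boundaries[[lab]] <- decision_boundary(
        function(X) predict(nets[[lab]], X), rng_x,
        resolution = grid_resolution)
  }
  df <- data.frame(method = names(rows), repetition = 1L,
                   accuracy = unlist(rows, use.names = FALSE))
  list(results = result_table(df, spec = list(seed = seed,
                                              count_range = count_range)),
       boundaries = boundaries, histories = histories,
       task = task, split = split, em = em$fit)
}

#' Run the systematic multi-cluster comparison
#'
#' Per repetition: a fresh all-clusters task (`D`, `K`, counts uniform on
#' `count_range`), a fresh 50/20/30 split, then every requested method is
#' scored on the test split — EM with order correction, the Bayes rule with
#' the true parameters, and each network architecture.
#'
#' @param D,K task dimension and cluster count.
#' @param repetitions number of independent tasks.
#' @param seed base RNG seed; repetition `r` uses `seed + r - 1` so any
#'   repetition can be reproduced in isolation.
#' @param methods character vector drawn from `"em"`, `"bayes"`, and
#'   architecture labels such as `"Q(2-5)"`, `"C(2-100-5)"` (see
#'   [parse_arch()]).
#' @param count_range per-cluster count interval.
#' @param config a [train_config()] shared by every network.
#' @param retry_failed re-draw a repetition (with an incremented seed
#'   offset) if EM aborts on it; the re-draw is recorded in the returned
#'   table's `spec`.
#' @return a [result_table()] with one row per method and repetition.
#' @export
run_systematic <- function(D, K, repetitions = 50, seed = 1,
                           methods = c("em", "bayes",
                                       vapply(default_architectures(D, K),
                                              format, "")),
                           count_range = c(6000, 9000),
                           config = train_config(max_epochs = 600,
                                                 learning_rate = 0.04),
                           retry_failed = TRUE) {
  stopifnot(D >= 2, K >= 2, repetitions >= 1)
  rows <- vector("list", 0)
  redraws <- integer(0)
  for (r in seq_len(repetitions)) {
    offset <- 0L
    repeat {
      set.seed(seed + r - 1L + offset * 100003L)
      task <- generate_task(D, K, mode = "all_clusters",
                            count_range = count_range)
      split <- shuffle_split(task$data)
      res <- tryCatch({
        acc <- list()
        for (m in methods) {
          if (m == "em") {
            acc[["EM"]] <- em_test_accuracy(split, K)$accuracy
          } else if (m == "bayes") {
            acc[["Bayes(true)"]] <- bayes_test_accuracy(split, task$model)
          } else {
            arch <- parse_arch(m)
            acc[[format(arch)]] <-
              network_test_accuracy(arch, split, config)$accuracy
          }
        }
        acc
      }, error = function(e) e)
      if (!inherits(res, "error")) break
      if (!retry_failed) stop(res)
      offset <- offset + 1L
      redraws <- c(redraws, r)
      message("repetition ", r, " failed (", conditionMessage(res),
              "); re-drawing with offset ", offset)
    }
    rows[[r]] <- data.frame(method = names(res), repetition = r,
                            accuracy = unlist(res, use.names = FALSE))
  }
  result_table(do.call(rbind, rows),
               spec = list(D = D, K = K, repetitions = repetitions,
                           seed = seed, count_range = count_range,
                           methods = methods, redraws = redraws))
}

## Axis ranges of a 2D sample cloud padded by 10% per side.
grid_ranges <- function(X) {
  stopifnot(ncol(X) == 2)
  r1 <- range(X[, 1]); r2 <- range(X[, 2])
  pad <- function(r) r + c(-1, 1) * 0.1 * diff(r)
  list(x = pad(r1), y = pad(r2))
}

#' Rasterize the decision boundary of a 2D classifier
#'
#' Evaluates the classifier on a regular lattice covering the given axis
#' ranges; the label changes in the raster trace the decision boundary.
#'
#' @param classifier function mapping an `N x 2` matrix to integer labels.
#' @param ranges list with numeric ranges `x` and `y` (e.g. from a sample
#'   bounding box padded 10%).
#' @param resolution number of lattice points per axis.
#' @return An object of class `boundary_grid`: `x`, `y` (axis coordinates)
#'   and `labels` (`resolution x resolution` integer matrix, rows indexed
#'   by `x`).
#' @export
decision_boundary <- function(classifier, ranges, resolution = 400) {
  stopifnot(resolution >= 1)
  xs <- if (resolution == 1) mean(ranges$x) else
    seq(ranges$x[1], ranges$x[2], length.out = resolution)
  ys <- if (resolution == 1) mean(ranges$y) else
    seq(ranges$y[1], ranges$y[2], length.out = resolution)
  G <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  lab <- classifier(G)
  structure(list(x = xs, y = ys,
                 labels = matrix(as.integer(lab), length(xs), length(ys))),
            class = "boundary_grid")
}

#' @export
print.boundary_grid <- function(x, ...) {
  cat("<boundary_grid>", length(x$x), "x", length(x$y), "lattice,",
      length(unique(as.vector(x$labels))), "distinct labels\n")
  invisible(x)
}

#' Write a boundary grid as a CSV raster
#'
#' Long format: columns `x`, `y`, `label`.
#'
#' @param grid a `boundary_grid`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_boundary <- function(grid, path) {
  df <- data.frame(x = rep(grid$x, times = length(grid$y)),
                   y = rep(grid$y, each = length(grid$x)),
                   label = as.vector(grid$labels))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read UCI-style tabular datasets
#'
#' `read_uci_yeast()` parses the whitespace-delimited yeast file: a leading
#' sequence-name column (dropped), 8 numeric features, and a string class
#' label mapped to integers 0..9 in order of first appearance (the mapping
#' is returned).  `read_uci_numeric()` parses the comma-delimited
#' pendigits/isolet layout: numeric feature columns with a trailing numeric
#' class column.
#'
#' @param path file path.
#' @return A list with `data` (a [labeled_dataset()]) and, for yeast,
#'   `class_map` (class name -> 0-based label).
#' @export
read_uci_yeast <- function(path) {
  df <- tryCatch(utils::read.table(path, header = FALSE,
                                   stringsAsFactors = FALSE),
                 error = function(e)
                   stop("cannot parse '", path, "': ",
                        conditionMessage(e)))
  feats <- df[, 2:(ncol(df) - 1), drop = FALSE]
  for (j in seq_along(feats))
    if (!is.numeric(feats[[j]]))
      stop("non-numeric feature in column ", j + 1, " of '", path, "'")
  cls <- as.character(df[[ncol(df)]])
  levels <- unique(cls)
  labels <- match(cls, levels) - 1L
  list(data = labeled_dataset(as.matrix(feats), labels, length(levels)),
       class_map = stats::setNames(seq_along(levels) - 1L, levels))
}

#' @rdname read_uci_yeast
#' @param class_offset subtract this from the trailing class column (use 1
#'   for 1-based class codes).
#' @export
read_uci_numeric <- function(path, class_offset = 0) {
  df <- tryCatch(utils::read.csv(path, header = FALSE),
                 error = function(e)
                   stop("cannot parse '", path, "': ",
                        conditionMessage(e)))
  for (j in seq_len(ncol(df)))
    if (!is.numeric(df[[j]]))
      stop("non-numeric value in column ", j, " of '", path, "'")
  labels <- as.integer(df[[ncol(df)]]) - as.integer(class_offset)
  X <- as.matrix(df[, -ncol(df), drop = FALSE])
  list(data = labeled_dataset(X, labels, max(labels) + 1L))
}

## Standardize features using train-split statistics.
standardize_split <- function(split) {
  mu <- colMeans(split$train$samples)
  sd_ <- apply(split$train$samples, 2, stats::sd)
  sd_[sd_ < 1e-12] <- 1
  scale_part <- function(part)
    labeled_dataset(sweep(sweep(part$samples, 2, mu), 2, sd_, "/"),
                    part$labels, part$K)
  split$train <- scale_part(split$train)
  split$validation <- scale_part(split$validation)
  split$test <- scale_part(split$test)
  split
}

#' Run networks on a real tabular dataset
#'
#' For `"yeast"` the whole file is shuffle-split 50/20/30 per repetition;
#' for `"pendigits"`/`"isolet"` the provided test file is kept as the test
#' set and 30% of the training file is held out for validation.  Each
#' repetition re-draws the split and the network initialization.
#'
#' @param dataset_path path to the data file (training file for
#'   pendigits/isolet).
#' @param dataset_name `"yeast"`, `"pendigits"` or `"isolet"`.
#' @param test_path test-file path (pendigits/isolet only).
#' @param architectures list of [network_arch()]; defaults to the standard
#'   four shapes at the dataset's `D` and `K`.
#' @param repetitions number of repeated runs (paper setting: 20).
#' @param seed base RNG seed.
#' @param config a [train_config()].
#' @param standardize per-feature standardization with train-split
#'   statistics (recommended: the 0.01-scale initialization assumes
#'   order-one inputs).
#' @param class_offset passed to [read_uci_numeric()].
#' @return a [result_table()].
#' @export
run_real <- function(dataset_path,
                     dataset_name = c("yeast", "pendigits", "isolet"),
                     test_path = NULL, architectures = NULL,
                     repetitions = 20, seed = 1,
                     config = train_config(max_epochs = 600,
                                           learning_rate = 0.04),
                     standardize = TRUE, class_offset = 0) {
  dataset_name <- match.arg(dataset_name)
  if (dataset_name == "yeast") {
    full <- read_uci_yeast(dataset_path)$data
    test_data <- NULL
  } else {
    if (is.null(test_path))
      stop(dataset_name, " requires test_path (test set provided by UCI)")
    full <- read_uci_numeric(dataset_path, class_offset)$data
    test_data <- read_uci_numeric(test_path, class_offset)$data
  }
  D <- ncol(full$samples); K <- full$K
  if (is.null(architectures)) architectures <- default_architectures(D, K)
  rows <- list()
  for (r in seq_len(repetitions)) {
    set.seed(seed + r - 1L)
    if (dataset_name == "yeast") {
      split <- shuffle_split(full)
    } else {
      ## hold out 30% of the training file for validation
      N <- nrow(full$samples)
      perm <- sample.int(N)
      n_val <- floor(0.3 * N)
      vi <- perm[seq_len(n_val)]; ti <- perm[-seq_len(n_val)]
      split <- structure(
        list(train = labeled_dataset(full$samples[ti, , drop = FALSE],
                                     full$labels[ti], K),
             validation = labeled_dataset(full$samples[vi, , drop = FALSE],
                                          full$labels[vi], K),
             test = test_data,
             fractions = c(0.7, 0.3, NA), permutation = perm),
        class = "data_split")
    }
    if (standardize) split <- standardize_split(split)
    for (arch in architectures) {
      acc <- network_test_accuracy(arch, split, config)$accuracy
      rows[[length(rows) + 1L]] <-
        data.frame(method = format(arch), repetition = r, accuracy = acc)
    }
  }
  result_table(do.call(rbind, rows),
               spec = list(dataset = dataset_name, repetitions = repetitions,
                           seed = seed, standardize = standardize))
}

#' Write a result table (and its summary) to CSV
#'
#' @param rt a `result_table`.
#' @param path CSV of repetition-level rows; the summary goes to
#'   `<path base>_summary.csv`.
#' @return `path`, invisibly.
#' @export
write_results <- function(rt, path) {
  utils::write.csv(as.data.frame(rt), path, row.names = FALSE)
  s <- summary(rt)
  utils::write.csv(s, sub("(\\.[^.]+)?$", "_summary\\1", path, perl = TRUE),
                   row.names = FALSE)
  invisible(path)
}
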