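test_that("architecture descriptors parse, format, and count neurons", {
  a <- network_arch(c(2, 3), "quadratic")
  expect_equal(format(a), "Q(2-3)")
  expect_equal(a$n_neurons, 3)
  b <- parse_arch("C(2-100-3)")
  expect_equal(b$dims, c(2L, 100L, 3L))
  expect_equal(b$type, "conventional")
  expect_equal(b$n_neurons, 103)
  expect_equal(parse_arch("Q:2-3")$dims, c(2L, 3L))
  expect_error(parse_arch("X(2-3)"), "parse")
  expect_error(network_arch(3), "two positive")
})

test_that("affine_forward is the matrix product plus broadcast bias", {
  layer <- list(w = matrix(c(1, 2, -1, 0), 2, 2), b = c(0, 1))
  expect_equal(affine_forward(matrix(c(1, 2), 1), layer), matrix(c(5, 0), 1))
  zero <- list(w = matrix(0, 2, 2), b = c(3, 3))
  expect_equal(affine_forward(matrix(rnorm(6), 3, 2), zero),
               matrix(3, 3, 2))
  id <- list(w = matrix(c(4, 7, 2, 9), 2, 2), b = c(0, 0))
  expect_equal(affine_forward(diag(2), id), id$w)  # identity rows pick out w
  expect_error(affine_forward(matrix(0, 1, 3), layer), "mismatch")
})

test_that("quadratic_forward computes (aw_r+b_r)o(aw_g+b_g) + (aoa)w_b + c", {
  # hand oracle: a=2, all weights 1, all biases 0 -> (2)(2) + 4 = 8
  ly <- list(w_r = matrix(1), b_r = 0, w_g = matrix(1), b_g = 0,
             w_b = matrix(1), c = 0)
  expect_equal(quadratic_forward(matrix(2), ly)$z, matrix(8))
  # reduction: w_g = 0, b_g = 1, w_b = 0, c = 0 collapses to the affine map
  set.seed(1)
  a <- matrix(rnorm(8), 4, 2)
  wr <- matrix(rnorm(6), 2, 3); br <- rnorm(3)
  red <- list(w_r = wr, b_r = br, w_g = matrix(0, 2, 3), b_g = rep(1, 3),
              w_b = matrix(0, 2, 3), c = rep(0, 3))
  expect_equal(quadratic_forward(a, red)$z,
               affine_forward(a, list(w = wr, b = br)))
  # zero input: every row is b_r o b_g + c
  full <- list(w_r = wr, b_r = br, w_g = matrix(rnorm(6), 2, 3),
               b_g = rnorm(3), w_b = matrix(rnorm(6), 2, 3), c = rnorm(3))
  z0 <- quadratic_forward(matrix(0, 5, 2), full)$z
  expect_equal(z0, matrix(rep(br * full$b_g + full$c, each = 5), 5, 3))
})

test_that("activations: ReLU clips at zero, softmax is shift-invariant", {
  expect_equal(activate(matrix(c(-1, 0, 2), 1)), matrix(c(0, 0, 2), 1))
  expect_equal(activate(matrix(c(0, 0), 1), output = TRUE),
               matrix(c(0.5, 0.5), 1))
  set.seed(2)
  z <- matrix(rnorm(12), 3, 4)
  s1 <- activate(z, output = TRUE)
  s2 <- activate(z + 1000, output = TRUE)
  expect_equal(s1, s2, tolerance = 1e-9)
  expect_equal(rowSums(s1), rep(1, 3), tolerance = 1e-9)
  expect_true(all(activate(z) >= 0))
  expect_error(activate(matrix(c(1, NaN), 1)), "finite")
})

test_that("forward_pass caches consistent activations and near-uniform cold output", {
  set.seed(3)
  arch <- network_arch(c(3, 4, 2), "conventional")
  net <- init_network(arch)   # 0.01-scale weights, zero biases
  x <- matrix(rnorm(15), 5, 3)
  cache <- forward_pass(net, x)
  # near-zero logits: output rows approximately uniform 1/K
  expect_lt(max(abs(cache$output - 0.5)), 0.05)
  # cached a_out equals re-activating the cached z
  for (l in 1:2)
    expect_equal(cache$layers[[l]]$a_out,
                 activate(cache$layers[[l]]$z, output = l == 2))
  expect_equal(cache$output, cache$layers[[2]]$a_out)
  # single layer: output is the softmax of the affine map
  net1 <- init_network(network_arch(c(2, 3), "conventional"))
  x1 <- matrix(rnorm(2), 1, 2)
  expect_equal(forward_pass(net1, x1)$output,
               activate(affine_forward(x1, net1$layers[[1]]), output = TRUE))
})

test_that("predict_labels takes the row argmax with ties to the lowest index", {
  expect_equal(predict_labels(matrix(c(0.1, 0.7, 0.2), 1)), 1L)
  expect_equal(predict_labels(matrix(c(0.5, 0.5), 1)), 0L)
  labs <- c(2L, 0L, 1L)
  expect_equal(predict_labels(one_hot(labs, 3)), labs)
})

test_that("cross_entropy matches closed forms in sum and mean modes", {
  H <- one_hot(c(0L, 1L), 2)
  expect_equal(cross_entropy(H, H), 0, tolerance = 1e-9)
  unif <- matrix(1 / 3, 6, 3)
  expect_equal(cross_entropy(unif, one_hot(rep(0L, 6), 3), mode = "sum"),
               6 * log(3), tolerance = 1e-12)
  out <- matrix(c(0.8, 0.2), 1)
  expect_equal(cross_entropy(out, matrix(c(1, 0), 1), mode = "sum"),
               -log(0.8), tolerance = 1e-12)
  expect_equal(cross_entropy(unif, one_hot(rep(0L, 6), 3)), log(3),
               tolerance = 1e-12)
})

test_that("output_grad is y - t and matches finite differences through softmax", {
  out <- matrix(c(0.8, 0.2), 1)
  t1 <- matrix(c(1, 0), 1)
  expect_equal(output_grad(out, t1, mode = "sum"), matrix(c(-0.2, 0.2), 1))
  expect_equal(output_grad(t1, t1, mode = "sum"), matrix(0, 1, 2))
  set.seed(4)
  z <- matrix(rnorm(8), 2, 4)
  tg <- one_hot(c(1L, 3L), 4)
  g <- output_grad(activate(z, output = TRUE), tg, mode = "sum")
  h <- 1e-6
  fd <- matrix(0, 2, 4)
  for (i in seq_along(z)) {
    zp <- z; zp[i] <- zp[i] + h
    zm <- z; zm[i] <- zm[i] - h
    fd[i] <- (cross_entropy(activate(zp, TRUE), tg, "sum") -
                cross_entropy(activate(zm, TRUE), tg, "sum")) / (2 * h)
  }
  expect_lt(max(abs(g - fd)), 1e-6)
})

test_that("relu_grad masks the upstream gradient at non-positive activations", {
  up <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(relu_grad(up, matrix(1, 2, 2)), up)
  expect_equal(relu_grad(up, matrix(0, 2, 2)), matrix(0, 2, 2))
  act <- matrix(c(0.5, 0, 2, 0), 2, 2)
  expect_equal(relu_grad(up, act), up * (act > 0))
})

test_that("conventional_backward reproduces the printed matrix expressions", {
  # hand oracle: a = [1 2], dz = [3] -> dw = [3; 6], db = [3]
  ly <- list(w = matrix(c(0.5, -1), 2, 1), b = 0)
  g <- conventional_backward(ly, matrix(c(1, 2), 1), matrix(3))
  expect_equal(g$dw, matrix(c(3, 6), 2, 1))
  expect_equal(g$db, 3)
  expect_equal(g$da, matrix(c(1.5, -3), 1))
  g0 <- conventional_backward(ly, matrix(c(1, 2), 1), matrix(0))
  expect_equal(g0$dw, matrix(0, 2, 1))
})

test_that("quadratic gradients collapse to conventional ones in the reduction", {
  set.seed(5)
  x <- matrix(rnorm(14), 7, 2)
  tg <- one_hot(sample(0:2, 7, replace = TRUE), 3)
  wr <- matrix(rnorm(6), 2, 3); br <- rnorm(3)
  qnet <- init_network(network_arch(c(2, 3), "quadratic"))
  qnet$layers[[1]] <- list(w_r = wr, b_r = br,
                           w_g = matrix(0, 2, 3), b_g = rep(1, 3),
                           w_b = matrix(0, 2, 3), c = rep(0, 3))
  cnet <- init_network(network_arch(c(2, 3), "conventional"))
  cnet$layers[[1]] <- list(w = wr, b = br)
  qc <- forward_pass(qnet, x)
  cc <- forward_pass(cnet, x)
  expect_equal(qc$output, cc$output, tolerance = 1e-12)
  qg <- network_gradients(qnet, qc, tg)[[1]]
  cg <- network_gradients(cnet, cc, tg)[[1]]
  expect_equal(qg$dw_r, cg$dw, tolerance = 1e-12)
  expect_equal(qg$db_r, cg$db, tolerance = 1e-12)
  # zero upstream gradient: every quadratic gradient is zero
  z0 <- quadratic_backward(qnet$layers[[1]], x,
                           qc$layers[[1]]$z_r, qc$layers[[1]]$z_g,
                           matrix(0, 7, 3))
  for (nm in c("dw_r", "db_r", "dw_g", "db_g", "dw_b", "dc"))
    expect_equal(max(abs(z0[[nm]])), 0)
})

test_that("analytic gradients match finite differences on random small nets", {
  set.seed(6)
  configs <- list(list(dims = c(3, 2), type = "quadratic"),
                  list(dims = c(2, 4, 3), type = "conventional"),
                  list(dims = c(3, 3, 2), type = "quadratic"))
  for (cf in configs) {
    net <- random_net(cf$dims, cf$type)
    N <- 7
    x <- matrix(rnorm(N * cf$dims[1]), N)
    tg <- one_hot(sample(0:(tail(cf$dims, 1) - 1), N, replace = TRUE),
                  tail(cf$dims, 1))
    cache <- forward_pass(net, x)
    grads <- network_gradients(net, cache, tg)
    for (l in seq_along(net$layers)) {
      fd <- fd_layer_gradients(net, x, tg, l)
      for (nm in names(fd))
        expect_lt(rel_err(grads[[l]][[grad_name(nm)]], fd[[nm]]), 1e-5)
    }
  }
})

test_that("init_network draws 0.01-scale weights and zero biases", {
  set.seed(7)
  net <- init_network(network_arch(c(2, 3), "quadratic"))
  expect_named(net$layers[[1]], c("w_r", "b_r", "w_g", "b_g", "w_b", "c"))
  for (nm in c("w_r", "w_g", "w_b"))
    expect_equal(dim(net$layers[[1]][[nm]]), c(2L, 3L))
  for (nm in c("b_r", "b_g", "c"))
    expect_equal(net$layers[[1]][[nm]], rep(0, 3))
  big <- init_network(network_arch(c(300, 350), "conventional"))
  expect_equal(stats::sd(big$layers[[1]]$w), 0.01, tolerance = 0.02)
})

test_that("adam_update performs the bias-corrected first step", {
  net <- init_network(network_arch(c(1, 1), "conventional"))
  net$layers[[1]]$w <- matrix(2)
  cfg <- train_config(learning_rate = 0.1)
  st <- adam_init(net, cfg)
  # zero gradient: parameters unchanged
  up0 <- adam_update(net, list(list(dw = matrix(0), db = 0)), st)
  expect_equal(up0$net$layers[[1]]$w, matrix(2))
  # unit gradient: first step is -lr to within epsilon rounding
  up1 <- adam_update(net, list(list(dw = matrix(1), db = 0)), st)
  expect_equal(up1$net$layers[[1]]$w, matrix(2 - 0.1), tolerance = 1e-6)
  expect_equal(up1$state$step, 1L)
  # repeated steps descend a convex quadratic loss 0.5 * w^2
  w <- 3; stq <- adam_init(net, cfg)
  nq <- net; nq$layers[[1]]$w <- matrix(w)
  for (i in 1:2) {
    g <- nq$layers[[1]]$w   # gradient of 0.5 w^2
    up <- adam_update(nq, list(list(dw = g, db = 0)), stq)
    nq <- up$net; stq <- up$state
  }
  expect_lt(abs(nq$layers[[1]]$w), abs(w))
})

test_that("a small gradient-descent step never increases the batch loss", {
  set.seed(8)
  net <- random_net(c(3, 4, 2), "quadratic", scale = 0.3)
  x <- matrix(rnorm(30), 10, 3)
  tg <- one_hot(sample(0:1, 10, replace = TRUE), 2)
  cache <- forward_pass(net, x)
  loss0 <- cross_entropy(cache$output, tg)
  grads <- network_gradients(net, cache, tg)
  for (l in seq_along(net$layers))
    for (nm in names(net$layers[[l]]))
      net$layers[[l]][[nm]] <- net$layers[[l]][[nm]] -
        1e-6 * grads[[l]][[grad_name(nm)]]
  expect_lte(cross_entropy(forward_pass(net, x)$output, tg), loss0)
})

test_that("training separates a linearly separable toy and is reproducible", {
  make_split <- function() {
    X <- rbind(matrix(rnorm(120), 60, 2) + 6, matrix(rnorm(120), 60, 2) - 6)
    ds <- labeled_dataset(X, rep(0:1, each = 60), 2)
    shuffle_split(ds)
  }
  set.seed(9)
  sp <- make_split()
  cfg <- train_config(max_epochs = 200, learning_rate = 0.05)
  set.seed(10)
  fit <- train_network(init_network(network_arch(c(2, 2), "conventional")),
                       sp, cfg)
  tr_acc <- class_accuracy(predict(fit, sp$train$samples), sp$train$labels)
  expect_gte(tr_acc, 0.99)
  # validation loss recorded every epoch, all finite
  expect_equal(nrow(fit$history), fit$epochs_run)
  expect_true(all(is.finite(fit$history$val_loss)))
  expect_true(all(is.finite(fit$history$train_loss)))
  # same seed, same data: bit-identical parameters
  set.seed(10)
  fit2 <- train_network(init_network(network_arch(c(2, 2), "conventional")),
                        sp, cfg)
  expect_identical(fit$net$layers, fit2$net$layers)
  expect_identical(fit$history, fit2$history)
})

test_that("networks round-trip through JSON serialization", {
  set.seed(11)
  for (type in c("conventional", "quadratic")) {
    net <- random_net(c(2, 3, 2), type)
    path <- file.path(tempdir(), paste0("net_", type, ".json"))
    write_network(net, path)
    back <- read_network(path)
    expect_equal(format(back$arch), format(net$arch))
    x <- matrix(rnorm(10), 5, 2)
    expect_equal(forward_pass(back, x)$output, forward_pass(net, x)$output,
                 tolerance = 1e-12)
    unlink(path)
  }
})
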