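fake_subjects <- function(n_normal = 18, n_scd = 18) {
  data.frame(
    subject_id = c(sprintf("N%02d", seq_len(n_normal)),
                   sprintf("S%02d", seq_len(n_scd))),
    label = rep(c("normal", "scd"), c(n_normal, n_scd)))
}

test_that("the patient split matches the 45/55 protocol", {
  tab <- fake_subjects(18, 18)
  sp <- split_by_patient(tab, 0.45, seed = 1L)
  expect_length(sp$train, 16L)       # 8 per class
  expect_length(sp$test, 20L)        # 10 per class
  lab <- function(ids) tab$label[match(ids, tab$subject_id)]
  expect_equal(sum(lab(sp$train) == "normal"), 8L)
  expect_equal(sum(lab(sp$train) == "scd"), 8L)
})

test_that("splits never share subjects and are seed-reproducible", {
  tab <- fake_subjects(7, 9)
  for (s in 1:20) {
    sp <- split_by_patient(tab, 0.45, seed = s)
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_setequal(c(sp$train, sp$test), tab$subject_id)
  }
  expect_identical(split_by_patient(tab, 0.45, seed = 4L),
                   split_by_patient(tab, 0.45, seed = 4L))
  sp2 <- split_by_patient(fake_subjects(2, 2), 0.5, seed = 1L)
  expect_length(sp2$train, 2L)
  expect_error(split_by_patient(fake_subjects(1, 5), 0.45, 1L),
               class = "scdemd_config_error")
})

test_that("augmented points fill the class bounding box", {
  tr <- data.frame(label = rep(c("normal", "scd"), each = 3),
                   f1 = c(0, 1, 0.5, 2, 3, 2.5),
                   f2 = c(0, 1, 0.2, -1, -2, -1.5))
  aug <- augment_bounding_box(tr, n_augment = 400L, seed = 2L)
  expect_equal(nrow(aug), 800L)
  nrm <- aug[aug$label == "normal", ]
  expect_true(all(nrm$f1 >= 0 & nrm$f1 <= 1 & nrm$f2 >= 0 & nrm$f2 <= 1))
  scd <- aug[aug$label == "scd", ]
  expect_true(all(scd$f1 >= 2 & scd$f1 <= 3 & scd$f2 >= -2 & scd$f2 <= -1))
  expect_identical(aug, augment_bounding_box(tr, 400L, seed = 2L))
  expect_equal(nrow(augment_bounding_box(tr, 0L, seed = 2L)), 0L)
})

test_that("augmentation draws are uniform within the box", {
  tr <- data.frame(label = "normal", f1 = c(0, 1), f2 = c(0, 1))
  aug <- augment_bounding_box(tr, n_augment = 100000L, seed = 3L)
  for (cn in c("f1", "f2")) {
    ks <- suppressWarnings(stats::ks.test(aug[[cn]], "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("a degenerate box dimension is pinned with a warning", {
  tr <- data.frame(label = "normal", f1 = c(0.7, 0.7), f2 = c(0, 1))
  expect_warning(aug <- augment_bounding_box(tr, 10L, 1L), "degenerate")
  expect_true(all(aug$f1 == 0.7))
})

# hand-assembled network for forward-pass oracles
manual_mlp <- function(W1, b1, W2, b2) {
  structure(list(layer_sizes = c(nrow(W1), ncol(W1), 1L),
                 weights = list(W1 = W1, b1 = b1,
                                W2 = matrix(W2, ncol = 1L), b2 = b2),
                 transfer = "logistic",
                 center = rep(0, nrow(W1)), scale = rep(1, nrow(W1)),
                 feature_names = NULL,
                 training_meta = list()),
            class = "scd_mlp")
}

test_that("forward pass matches direct arithmetic", {
  m0 <- manual_mlp(matrix(0, 2, 3), rep(0, 3), rep(0, 3), 0)
  expect_equal(mlp_forward(m0, c(1, 2)), 0.5)   # F(0) = 0.5

  m1 <- manual_mlp(matrix(1, 1, 1), 0, 1, 0)
  sig <- function(s) 1 / (1 + exp(-s))
  expect_equal(mlp_forward(m1, 0), sig(sig(0)))
  expect_lt(abs(mlp_forward(m1, 50) - sig(1)), 1e-10)  # hidden saturates at 1

  set.seed(16)
  W1 <- matrix(rnorm(20), 2, 10); b1 <- rnorm(10)
  W2 <- rnorm(10); b2 <- rnorm(1)
  m <- manual_mlp(W1, b1, W2, b2)
  x <- rnorm(2)
  # independent loop-based evaluation
  h <- numeric(10)
  for (j in 1:10) h[j] <- sig(sum(W1[, j] * x) + b1[j])
  y <- sig(sum(W2 * h) + b2)
  expect_equal(unname(mlp_forward(m, x)), y, tolerance = 1e-12)
  expect_error(mlp_forward(m, c(1, 2, 3)), class = "scdemd_config_error")
})

test_that("LM solves a linear least-squares problem to the analytic optimum", {
  set.seed(17)
  A <- matrix(rnorm(40), 20, 2); b <- rnorm(20)
  fn <- function(th) as.numeric(A %*% th - b)
  jac <- function(th) A
  fit <- scdemd:::lm_optimize(fn, jac, c(0, 0))
  analytic <- solve(crossprod(A), crossprod(A, b))
  expect_equal(fit$theta, as.numeric(analytic), tolerance = 1e-8)
  expect_lte(fit$iterations, 20L)
})

test_that("LM with huge damping reduces to small-step gradient descent", {
  set.seed(18)
  A <- matrix(rnorm(40), 20, 2); b <- rnorm(20)
  fn <- function(th) as.numeric(A %*% th - b)
  jac <- function(th) A
  th0 <- c(1, -1)
  lambda <- 1e8
  fit <- scdemd:::lm_optimize(fn, jac, th0, lambda0 = lambda, factor = 1,
                              max_iters = 1L, tol = 0)
  grad_step <- th0 - as.numeric(crossprod(A, fn(th0))) / lambda
  expect_equal(fit$theta, grad_step, tolerance = 1e-6)
  # and the loss never increases across iterations (acceptance rule)
  fit5 <- scdemd:::lm_optimize(fn, jac, th0, lambda0 = lambda, factor = 1,
                               max_iters = 5L, tol = 0)
  expect_lte(fit5$loss, 0.5 * sum(fn(th0)^2))
})

test_that("training separates well-separated clusters perfectly", {
  set.seed(19)
  x <- rbind(matrix(rnorm(60, 0, 1), ncol = 2),
             matrix(rnorm(60, 6, 1), ncol = 2))
  y <- rep(c(0, 1), each = 30)
  m <- train_mlp(x, y, train_config(n_hidden = 4, seed = 1))
  expect_equal(mean((mlp_forward(m, x) >= 0.5) == (y == 1)), 1)
})

test_that("a 4-hidden-unit network fits XOR in most seeded restarts", {
  x <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c(0, 1, 1, 0)
  ok <- 0L
  for (s in 1:10) {
    m <- train_mlp(x, y, train_config(n_hidden = 4, seed = s,
                                      max_iters = 500))
    mse <- mean((mlp_forward(m, x) - y)^2)
    if (mse < 0.05) ok <- ok + 1L
  }
  expect_gte(ok, 8L)
})

test_that("prediction applies the inclusive 0.5 threshold", {
  m0 <- manual_mlp(matrix(0, 1, 2), rep(0, 2), rep(0, 2), 0)  # output 0.5
  expect_equal(predict(m0, matrix(0)), "scd")   # boundary inclusive
  expect_equal(predict(m0, matrix(0), threshold = 1.1), "normal")
})

test_that("per-minute evaluation counts correctly", {
  # 1-feature model: output = F(z), z-scored identity; big positive = scd
  m <- manual_mlp(matrix(10, 1, 1), 0, 10, -5)
  tf <- data.frame(subject_id = rep(c("S1", "S2", "N1", "N2"), c(25, 25, 1, 1)),
                   label = rep(c("scd", "scd", "normal", "normal"),
                               c(25, 25, 1, 1)),
                   minute = c(1:25, 1:25, 0, 0),
                   f = c(rep(3, 25), rep(3, 24), -3, rep(-3, 2)))
  names(tf)[4] <- "HI.imf3"
  # S2 minute 25 has a normal-looking value -> one error in that minute
  ev <- evaluate_per_minute(m, tf)
  expect_equal(nrow(ev$per_minute), 25L)
  expect_equal(ev$per_minute$accuracy[ev$per_minute$minute == 25], 75)
  expect_true(all(ev$per_minute$accuracy[1:24] == 100))
  expect_equal(ev$mean_accuracy, mean(c(rep(100, 24), 75)))
})

test_that("models survive JSON serialisation to full precision", {
  set.seed(20)
  x <- matrix(rnorm(80), ncol = 2)
  y <- as.numeric(x[, 1] + x[, 2] > 0)
  m <- train_mlp(x, y, train_config(n_hidden = 3, seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$weights, m$weights, tolerance = 1e-12)
  expect_equal(mlp_forward(m2, x), mlp_forward(m, x), tolerance = 1e-12)
})
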