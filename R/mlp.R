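#' Training configuration for the MLP classifier
#'
#' @param n_hidden Hidden-layer size (default 10).
#' @param lm_lambda0 Initial Levenberg-Marquardt damping (default 1e-3).
#' @param lm_factor Multiplicative damping adaptation on step
#'   rejection/acceptance (default 10).
#' @param max_iters Maximum optimizer iterations (default 200).
#' @param tol Convergence tolerance on the loss decrease (default 1e-6).
#' @param n_augment Bounding-box augmentation size per class (default 400).
#' @param train_fraction Fraction of subjects per class assigned to
#'   training (default 0.45).
#' @param seed Integer seed controlling the split, augmentation and weight
#'   initialisation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(n_hidden = 10L, lm_lambda0 = 1e-3, lm_factor = 10,
                         max_iters = 200L, tol = 1e-6, n_augment = 400L,
                         train_fraction = 0.45, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    abort("`train_fraction` must lie in (0, 1)", "scdemd_config_error")
  if (n_augment < 0L) abort("`n_augment` must be >= 0", "scdemd_config_error")
  structure(list(n_hidden = as.integer(n_hidden), lm_lambda0 = lm_lambda0,
                 lm_factor = lm_factor, max_iters = as.integer(max_iters),
                 tol = tol, n_augment = as.integer(n_augment),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Split a cohort into training and test subjects
#'
#' The split is at subject level (no subject contributes windows to both
#' sets); per class, `round(train_fraction * n_class)` subjects are drawn
#' for training, reproducibly under `seed`.
#'
#' @param table Feature table (or any data.frame with `subject_id` and
#'   `label` columns).
#' @param train_fraction Fraction of each class's subjects for training.
#' @param seed Integer seed.
#' @return A list with character vectors `train` and `test`.
#' @export
split_by_patient <- function(table, train_fraction = 0.45, seed = 1L) {
  subj <- unique(table[, c("subject_id", "label")])
  train <- character(0)
  for (lb in c("normal", "scd")) {
    ids <- sort(subj$subject_id[subj$label == lb])
    if (length(ids) < 2L)
      abort(sprintf("class '%s' has fewer than 2 subjects", lb),
            "scdemd_config_error")
    n_tr <- round(train_fraction * length(ids))
    n_tr <- min(max(n_tr, 1L), length(ids) - 1L)
    pick <- with_seed(derive_seed(seed, match(lb, c("normal", "scd"))),
                      sample(ids, n_tr))
    train <- c(train, pick)
  }
  list(train = sort(train), test = sort(setdiff(subj$subject_id, train)))
}

#' Bounding-box training augmentation
#'
#' For each class, draws `n_augment` synthetic feature points uniformly
#' within the per-dimension `[min, max]` box of that class's training
#' features. Dimensions with a degenerate box (min == max) are fixed at
#' that value with a warning.
#'
#' @param train_features data.frame with a `label` column and numeric
#'   feature columns (as from [feature_matrix()]).
#' @param n_augment Points per class (default 400).
#' @param seed Integer seed.
#' @return data.frame of synthetic points with the same feature columns
#'   plus `label`.
#' @export
augment_bounding_box <- function(train_features, n_augment = 400L, seed = 1L) {
  feat_cols <- names(train_features)[vapply(train_features, is.numeric,
                                            logical(1))]
  feat_cols <- setdiff(feat_cols, "minute")
  out <- list()
  for (lb in unique(train_features$label)) {
    sub <- train_features[train_features$label == lb, feat_cols, drop = FALSE]
    if (nrow(sub) < 2L)
      abort("need >= 2 training points per class to form a bounding box",
            "scdemd_config_error")
    pts <- with_seed(derive_seed(seed, match(lb, unique(train_features$label))), {
      cols <- lapply(feat_cols, function(cn) {
        lo <- min(sub[[cn]]); hi <- max(sub[[cn]])
        if (lo == hi) {
          warning(sprintf("degenerate bounding box in '%s' for class '%s'",
                          cn, lb))
          rep(lo, n_augment)
        } else {
          stats::runif(n_augment, lo, hi)
        }
      })
      names(cols) <- feat_cols
      as.data.frame(cols)
    })
    if (n_augment > 0L) {
      pts$label <- lb
      out[[lb]] <- pts
    }
  }
  if (length(out) == 0L) {
    empty <- train_features[0, c(feat_cols, "label"), drop = FALSE]
    return(empty)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# ---- Levenberg-Marquardt core --------------------------------------------

# Damped Gauss-Newton minimisation of 0.5*||r(theta)||^2. `fn` returns the
# residual vector, `jac` its Jacobian (n_res x n_par). Lambda scales an
# identity damping term: accepted steps divide it by `factor`, rejected
# steps multiply, so at huge lambda the step tends to -J'r/lambda
# (small-step gradient descent).
lm_optimize <- function(fn, jac, theta0, lambda0 = 1e-3, factor = 10,
                        max_iters = 200L, tol = 1e-6) {
  theta <- theta0
  r <- fn(theta)
  loss <- 0.5 * sum(r^2)
  lambda <- lambda0
  converged <- FALSE
  it <- 0L
  while (it < max_iters) {
    it <- it + 1L
    J <- jac(theta)
    g <- crossprod(J, r)                     # gradient
    A <- crossprod(J)
    accepted <- FALSE
    for (try in 1:50) {
      step <- tryCatch(
        solve(A + diag(lambda, ncol(A)), -g),
        error = function(e) NULL)
      if (!is.null(step)) {
        cand <- theta + as.numeric(step)
        r_new <- fn(cand)
        loss_new <- 0.5 * sum(r_new^2)
        if (is.finite(loss_new) && loss_new <= loss) {
          theta <- cand; r <- r_new
          improvement <- loss - loss_new
          loss <- loss_new
          lambda <- max(lambda / factor, 1e-12)
          accepted <- TRUE
          if (improvement < tol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * factor
      if (lambda > 1e12) break
    }
    if (!accepted || converged) {
      converged <- converged || !accepted
      break
    }
  }
  list(theta = theta, loss = loss, iterations = it,
       converged = converged, lambda = lambda)
}

# ---- MLP ------------------------------------------------------------------

logistic <- function(s) 1 / (1 + exp(-s))

pack_theta <- function(W1, b1, W2, b2) c(as.numeric(W1), b1, as.numeric(W2), b2)

unpack_theta <- function(theta, n_in, n_hidden) {
  i <- 0L
  W1 <- matrix(theta[i + seq_len(n_in * n_hidden)], n_in, n_hidden)
  i <- i + n_in * n_hidden
  b1 <- theta[i + seq_len(n_hidden)]; i <- i + n_hidden
  W2 <- matrix(theta[i + seq_len(n_hidden)], n_hidden, 1L); i <- i + n_hidden
  b2 <- theta[i + 1L]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

mlp_forward_raw <- function(X, w) {
  S1 <- sweep(X %*% w$W1, 2L, w$b1, `+`)
  A1 <- logistic(S1)
  S2 <- A1 %*% w$W2 + w$b2
  list(y = logistic(as.numeric(S2)), A1 = A1)
}

#' Evaluate a trained MLP on feature points
#'
#' Applies the stored training standardisation, then the logistic
#' feedforward pass `y = F(W2 F(W1 x + b1) + b2)` with
#' `F(s) = 1/(1+exp(-s))`.
#'
#' @param model An `scd_mlp` from [train_mlp()].
#' @param x Numeric matrix (rows = points) or vector (one point) of raw
#'   (unstandardised) features.
#' @return Numeric vector of outputs in `(0, 1)`.
#' @export
mlp_forward <- function(model, x) {
  stopifnot(inherits(model, "scd_mlp"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$layer_sizes[1L])
    abort(sprintf("input has %d features, model expects %d",
                  ncol(x), model$layer_sizes[1L]), "scdemd_config_error")
  Xz <- sweep(sweep(x, 2L, model$center, `-`), 2L, model$scale, `/`)
  mlp_forward_raw(Xz, model$weights)$y
}

#' Train the MLP classifier with Levenberg-Marquardt
#'
#' A single-hidden-layer perceptron with logistic activations and one
#' output neuron (normal coded 0, SCD coded 1) is fitted by damped
#' Gauss-Newton minimisation of the sum-of-squares output error. Inputs
#' are z-scored by training-set statistics (stored in the model); initial
#' weights are seeded uniform on `[-0.5, 0.5]`; the Jacobian is computed
#' analytically by reverse accumulation.
#'
#' @param x Numeric matrix of training features (rows = points).
#' @param y Numeric vector of 0/1 targets (or labels `"normal"`/`"scd"`).
#' @param cfg A [train_config()].
#' @return An object of class `scd_mlp`: layer sizes, weights,
#'   standardisation, and training metadata (`seed`, `iterations`,
#'   `final_loss`, `converged`).
#' @export
train_mlp <- function(x, y, cfg = train_config()) {
  x <- as.matrix(x)
  if (is.character(y) || is.factor(y)) y <- as.numeric(as.character(y) == "scd")
  if (length(unique(y)) < 2L)
    abort("training data must contain both classes", "scdemd_config_error")
  n_in <- ncol(x); n_h <- cfg$n_hidden
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[scale == 0] <- 1
  Xz <- sweep(sweep(x, 2L, center, `-`), 2L, scale, `/`)
  n_par <- n_in * n_h + n_h + n_h + 1L
  theta0 <- with_seed(cfg$seed, stats::runif(n_par, -0.5, 0.5))

  fn <- function(theta) {
    w <- unpack_theta(theta, n_in, n_h)
    mlp_forward_raw(Xz, w)$y - y
  }
  jac <- function(theta) {
    w <- unpack_theta(theta, n_in, n_h)
    fw <- mlp_forward_raw(Xz, w)
    yhat <- fw$y; A1 <- fw$A1
    dy <- yhat * (1 - yhat)                       # dr/ds2, per point
    # output layer
    J_W2 <- A1 * dy                               # n x n_h
    J_b2 <- matrix(dy, ncol = 1L)
    # hidden layer: delta1[n, j] = dy * W2[j] * A1[,j](1 - A1[,j])
    delta1 <- (dy %o% as.numeric(w$W2)) * A1 * (1 - A1)
    J_W1 <- matrix(0, length(yhat), n_in * n_h)
    for (i in seq_len(n_in))
      J_W1[, (seq_len(n_h) - 1L) * n_in + i] <- delta1 * Xz[, i]
    cbind(J_W1, delta1, J_W2, J_b2)
  }
  fit <- lm_optimize(fn, jac, theta0, cfg$lm_lambda0, cfg$lm_factor,
                     cfg$max_iters, cfg$tol)
  if (!fit$converged && fit$iterations >= cfg$max_iters)
    warning("Levenberg-Marquardt reached max_iters without converging")
  structure(list(layer_sizes = c(n_in, n_h, 1L),
                 weights = unpack_theta(fit$theta, n_in, n_h),
                 transfer = "logistic",
                 center = center, scale = scale,
                 feature_names = colnames(x),
                 training_meta = list(seed = cfg$seed,
                                      iterations = fit$iterations,
                                      final_loss = fit$loss,
                                      converged = fit$converged)),
            class = "scd_mlp")
}

#' @export
print.scd_mlp <- function(x, ...) {
  cat(sprintf("<scd_mlp %s: loss %.4g after %d LM iterations%s>\n",
              paste(x$layer_sizes, collapse = "-"),
              x$training_meta$final_loss, x$training_meta$iterations,
              if (x$training_meta$converged) "" else " (not converged)"))
  invisible(x)
}

#' Predict class labels
#'
#' @param object An `scd_mlp`.
#' @param x Feature matrix or vector.
#' @param threshold Decision threshold on the network output; outputs
#'   `>= threshold` are labelled `"scd"` (boundary inclusive).
#' @param ... Unused.
#' @return Character vector of `"normal"`/`"scd"` labels.
#' @export
predict.scd_mlp <- function(object, x, threshold = 0.5, ...) {
  ifelse(mlp_forward(object, x) >= threshold, "scd", "normal")
}

#' Per-minute accuracy of the classifier on held-out subjects
#'
#' For each pre-onset minute `m`, accuracy is computed over the SCD test
#' windows of minute `m` together with all normal-group test windows; the
#' overall figure is the mean across minutes.
#'
#' @param model An `scd_mlp`.
#' @param test_features data.frame from [feature_matrix()] restricted to
#'   test subjects (raw features, never augmented).
#' @param threshold Decision threshold (default 0.5).
#' @return A list with `per_minute` (data.frame: minute, n, accuracy in
#'   percent; minutes with no SCD windows reported as `NA`) and
#'   `mean_accuracy` (percent).
#' @export
evaluate_per_minute <- function(model, test_features, threshold = 0.5) {
  feat_cols <- setdiff(names(test_features),
                       c("subject_id", "label", "minute"))
  X <- as.matrix(test_features[, feat_cols, drop = FALSE])
  pred <- predict(model, X, threshold)
  lab <- test_features$label
  minutes <- sort(unique(test_features$minute[lab == "scd"]))
  normal_i <- which(lab == "normal")
  rows <- lapply(minutes, function(m) {
    idx <- c(which(lab == "scd" & test_features$minute == m), normal_i)
    if (length(idx) == 0L)
      return(data.frame(minute = m, n = 0L, accuracy = NA_real_))
    data.frame(minute = m, n = length(idx),
               accuracy = 100 * mean(pred[idx] == lab[idx]))
  })
  per_minute <- do.call(rbind, rows)
  list(per_minute = per_minute,
       mean_accuracy = mean(per_minute$accuracy, na.rm = TRUE))
}

#' Serialize / restore a trained model
#'
#' Models are stored as self-describing JSON (layer sizes, weights,
#' standardisation, transfer function, training metadata).
#'
#' @param model An `scd_mlp`.
#' @param path Output JSON path.
#' @return `path` (write) or an `scd_mlp` (read).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "scd_mlp"))
  obj <- list(layer_sizes = model$layer_sizes,
              transfer = model$transfer,
              W1 = model$weights$W1, b1 = model$weights$b1,
              W2 = as.numeric(model$weights$W2), b2 = model$weights$b2,
              center = model$center, scale = model$scale,
              feature_names = model$feature_names,
              training_meta = model$training_meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n_in <- obj$layer_sizes[1L]; n_h <- obj$layer_sizes[2L]
  structure(list(layer_sizes = as.integer(obj$layer_sizes),
                 weights = list(W1 = matrix(obj$W1, n_in, n_h),
                                b1 = as.numeric(obj$b1),
                                W2 = matrix(obj$W2, n_h, 1L),
                                b2 = as.numeric(obj$b2)),
                 transfer = obj$transfer,
                 center = as.numeric(obj$center),
                 scale = as.numeric(obj$scale),
                 feature_names = obj$feature_names,
                 training_meta = obj$training_meta),
            class = "scd_mlp")
}
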