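#' Randomly partition labelled samples into train/validation/test
#'
#' The classifier training protocol divides the labelled pixel set into three
#' groups — training, validation (used only to monitor early stopping) and
#' test (used only for final reporting) — by default in proportions
#' 70/15/15. The split is a disjoint, exhaustive partition and is
#' deterministic for a fixed seed. Counts are the floors of the proportions,
#' with remainders assigned by largest fractional part, so 100 samples at
#' (0.7, 0.15, 0.15) give exactly 70/15/15.
#'
#' @param samples A data frame of labelled samples.
#' @param proportions Numeric length-3 vector summing to 1.
#' @param rng_seed Seed for the shuffle.
#' @return The input as a tibble with an added factor column `split`
#'   (levels `"train"`, `"validation"`, `"test"`).
#' @export
split_samples <- function(samples, proportions = c(0.70, 0.15, 0.15),
                          rng_seed = 1L) {
  stopifnot(is.data.frame(samples), length(proportions) == 3L,
            all(proportions >= 0))
  n <- nrow(samples)
  if (n == 0) abort("`samples` is empty.")
  if (abs(sum(proportions) - 1) > 1e-8) abort("`proportions` must sum to 1.")
  counts <- floor(proportions * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- proportions * n - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  if (any(proportions > 0 & counts == 0)) {
    abort("Each split with a positive proportion must receive at least one sample.")
  }
  set.seed(rng_seed)
  perm <- sample.int(n)
  lab <- rep(c("train", "validation", "test"), times = counts)
  split <- character(n)
  split[perm] <- lab
  out <- as_tibble(samples)
  out$split <- factor(split, levels = c("train", "validation", "test"))
  out
}

# ---- shallow feed-forward network internals ---------------------------------
# One hidden layer, logistic activations throughout; parameters packed as
# c(W1 [h x p], b1 [h], w2 [h], b2).

sigmoid <- function(x) 1 / (1 + exp(-x))

mlp_unpack <- function(theta, p, h) {
  list(W1 = matrix(theta[seq_len(p * h)], h, p),
       b1 = theta[p * h + seq_len(h)],
       w2 = theta[p * h + h + seq_len(h)],
       b2 = theta[p * h + 2 * h + 1])
}

mlp_forward <- function(theta, X, p, h) {
  w <- mlp_unpack(theta, p, h)
  A <- X %*% t(w$W1) + matrix(w$b1, nrow(X), h, byrow = TRUE)
  H <- sigmoid(A)
  z <- drop(H %*% w$w2) + w$b2
  y <- sigmoid(z)
  list(y = y, H = H)
}

# Jacobian of the network output w.r.t. all parameters (N x P).
mlp_jacobian <- function(theta, X, fwd, p, h) {
  w <- mlp_unpack(theta, p, h)
  y <- fwd$y; H <- fwd$H
  dy <- y * (1 - y)                      # N
  dH <- H * (1 - H)                      # N x h
  g_hidden <- dy * dH * matrix(w$w2, nrow(X), h, byrow = TRUE)  # d y / d a_j
  J_W1 <- do.call(cbind, lapply(seq_len(p), function(i) g_hidden * X[, i]))
  # column order of J_W1 blocks must match theta packing: W1 stored h x p
  # column-major => element (j,i) at index (i-1)*h + j, matching cbind above.
  cbind(J_W1, g_hidden, dy * H, dy)
}

mlp_mse <- function(theta, X, target, p, h) {
  mean((mlp_forward(theta, X, p, h)$y - target)^2)
}

# Full-batch Levenberg-Marquardt on the MSE objective.
train_mlp_lm <- function(X, target, Xval = NULL, val_target = NULL,
                         hidden_size = 8, mse_target = 1e-6,
                         max_epochs = 200, rng_seed = 1L, max_fail = 6,
                         mu0 = 1e-3, mu_max = 1e10) {
  p <- ncol(X); h <- hidden_size
  P <- p * h + 2 * h + 1
  set.seed(rng_seed)
  theta <- rnorm(P, sd = 0.5)
  mu <- mu0
  mse <- mlp_mse(theta, X, target, p, h)
  best_val <- Inf; best_theta <- theta; fails <- 0L
  epoch <- 0L
  stop_reason <- "max_epochs"
  while (epoch < max_epochs) {
    if (!is.finite(mse)) {
      abort(sprintf("Non-finite training loss at epoch %d.", epoch))
    }
    if (mse <= mse_target) { stop_reason <- "mse_target"; break }
    fwd <- mlp_forward(theta, X, p, h)
    r <- fwd$y - target
    J <- mlp_jacobian(theta, X, fwd, p, h)
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    improved <- FALSE
    while (mu <= mu_max) {
      step <- tryCatch(solve(JtJ + mu * diag(P), -g), error = function(e) NULL)
      if (!is.null(step)) {
        theta_new <- theta + drop(step)
        mse_new <- mlp_mse(theta_new, X, target, p, h)
        if (is.finite(mse_new) && mse_new < mse) {
          theta <- theta_new; mse <- mse_new
          mu <- max(mu / 10, 1e-20)
          improved <- TRUE
          break
        }
      }
      mu <- mu * 10
    }
    if (!improved) { stop_reason <- "mu_max"; break }
    epoch <- epoch + 1L
    if (!is.null(Xval) && nrow(Xval) > 0) {
      val_mse <- mlp_mse(theta, Xval, val_target, p, h)
      if (val_mse < best_val) {
        best_val <- val_mse; best_theta <- theta; fails <- 0L
      } else {
        fails <- fails + 1L
        if (fails >= max_fail) { stop_reason <- "validation_stop"; break }
      }
    }
  }
  if (is.finite(mse) && mse <= mse_target) stop_reason <- "mse_target"
  if (stop_reason == "validation_stop") theta <- best_theta
  list(theta = theta, epochs = epoch, stop_reason = stop_reason,
       mse_train = mlp_mse(theta, X, target, p, h))
}

# -----------------------------------------------------------------------------

#' Train the cell/background pixel classifier
#'
#' Fits a 3-layer (input, one hidden, output) feed-forward network that maps
#' per-pixel channel values to a cell-probability in \[0, 1\]. Optimisation is
#' full-batch Levenberg-Marquardt on the mean squared error; training stops
#' when the training MSE reaches `mse_target` (default 1e-6) or at
#' `max_epochs`, whichever comes first. The validation split is used only to
#' monitor early stopping; the test split is never used in fitting and its
#' MSE is reported for information.
#'
#' Features are either the three 8-bit channel values scaled to \[0, 1\]
#' (`"rgb"`, default) or a single luminance value (`"luminance"`,
#' 0.299 R + 0.587 G + 0.114 B); both are then standardised with statistics
#' estimated on the training split.
#'
#' @param samples A data frame with columns `r`, `g`, `b`, `label` and
#'   optionally `split` (from [split_samples()]; added with default
#'   proportions if missing).
#' @param hidden_size Hidden-layer width (>= 1).
#' @param mse_target Training-MSE convergence criterion.
#' @param max_epochs Epoch cap.
#' @param rng_seed Seed for weight initialisation (and the split, if added
#'   here).
#' @param features `"rgb"` or `"luminance"`.
#' @param check_classes If `TRUE` (default) a training split containing a
#'   single class is an error; set `FALSE` to allow degenerate constant-label
#'   training (the network then converges to a constant predictor).
#' @return An object of class `pixel_classifier`.
#' @export
train_pixel_classifier <- function(samples, hidden_size = 8,
                                   mse_target = 1e-6, max_epochs = 200,
                                   rng_seed = 1L,
                                   features = c("rgb", "luminance"),
                                   check_classes = TRUE) {
  features <- arg_match(features)
  stopifnot(is.data.frame(samples), hidden_size >= 1)
  need <- c("r", "g", "b", "label")
  if (!all(need %in% names(samples))) {
    abort("`samples` must have columns r, g, b, label.")
  }
  if (!"split" %in% names(samples)) {
    samples <- split_samples(samples, rng_seed = rng_seed)
  }
  X_all <- pixel_features(as.matrix(samples[, c("r", "g", "b")]), features)
  target_all <- as.numeric(samples$label == "cell")
  tr <- samples$split == "train"
  va <- samples$split == "validation"
  te <- samples$split == "test"
  if (check_classes && length(unique(target_all[tr])) < 2) {
    abort("Training split contains a single class.")
  }
  ctr <- colMeans(X_all[tr, , drop = FALSE])
  scl <- apply(X_all[tr, , drop = FALSE], 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Z <- sweep(sweep(X_all, 2, ctr), 2, scl, "/")
  fit <- train_mlp_lm(Z[tr, , drop = FALSE], target_all[tr],
                      Z[va, , drop = FALSE], target_all[va],
                      hidden_size = hidden_size, mse_target = mse_target,
                      max_epochs = max_epochs, rng_seed = rng_seed)
  p <- ncol(Z)
  mse_of <- function(sel) {
    if (!any(sel)) return(NA_real_)
    mlp_mse(fit$theta, Z[sel, , drop = FALSE], target_all[sel], p, hidden_size)
  }
  structure(
    list(theta = fit$theta, n_features = p, hidden_size = hidden_size,
         features = features, center = ctr, scale = scl,
         report = list(mse_train = fit$mse_train,
                       mse_validation = mse_of(va),
                       mse_test = mse_of(te),
                       epochs = fit$epochs,
                       stop_reason = fit$stop_reason,
                       mse_target = mse_target,
                       max_epochs = max_epochs,
                       n_train = sum(tr), n_validation = sum(va),
                       n_test = sum(te))),
    class = "pixel_classifier"
  )
}

pixel_features <- function(rgb255, features) {
  X <- rgb255 / 255
  if (features == "luminance") {
    X <- matrix(X %*% c(0.299, 0.587, 0.114), ncol = 1)
  }
  X
}

#' @export
print.pixel_classifier <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<pixel_classifier> %d-%d-1 network (%s features)\n  train MSE %.3g | validation %.3g | test %.3g | %d epochs (%s)\n",
    x$n_features, x$hidden_size, x$features, r$mse_train, r$mse_validation,
    r$mse_test, r$epochs, r$stop_reason))
  invisible(x)
}

#' @rdname train_pixel_classifier
#' @param object,x A `pixel_classifier`.
#' @param newdata A data frame with columns `r`, `g`, `b` or a numeric matrix
#'   of 8-bit channel values.
#' @param type `"response"` for probabilities, `"class"` for thresholded
#'   0/1 labels.
#' @param threshold Decision threshold for `type = "class"`.
#' @param ... Unused.
#' @export
predict.pixel_classifier <- function(object, newdata, type = c("response", "class"),
                                     threshold = 0.5, ...) {
  type <- arg_match(type)
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata[, c("r", "g", "b")])
  X <- pixel_features(newdata, object$features)
  Z <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  y <- mlp_forward(object$theta, Z, object$n_features, object$hidden_size)$y
  if (type == "class") as.integer(y >= threshold) else y
}

#' @rdname train_pixel_classifier
#' @export
glance.pixel_classifier <- function(x, ...) {
  r <- x$report
  tibble(mse_train = r$mse_train, mse_validation = r$mse_validation,
         mse_test = r$mse_test, epochs = r$epochs,
         stop_reason = r$stop_reason,
         n_parameters = length(x$theta),
         hidden_size = x$hidden_size, features = x$features)
}

#' Persist / restore a pixel classifier
#'
#' The classifier is stored as a single self-describing JSON file (weights at
#' full precision, normalisation statistics and a configuration echo), so a
#' reloaded classifier reproduces probabilities to machine precision and
#' thresholded masks exactly.
#'
#' @param classifier A `pixel_classifier`.
#' @param path File path.
#' @return `write_classifier()` returns `path` invisibly; `read_classifier()`
#'   returns the restored `pixel_classifier`.
#' @export
write_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "pixel_classifier"))
  obj <- unclass(classifier)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$theta <- as.numeric(obj$theta)
  obj$center <- as.numeric(obj$center)
  obj$scale <- as.numeric(obj$scale)
  structure(obj, class = "pixel_classifier")
}
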