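#' Training configuration for the gaze regressor
#'
#' Hyperparameters of the 14-200-2 sigmoid network trainer: stochastic
#' gradient descent with classical (heavy-ball) momentum, mini-batches of
#' four, and a step scheduler that halves the learning rate every 2,000
#' epochs. Validation loss is evaluated every 10 epochs and the parameters
#' from the best evaluation are returned.
#'
#' @param learning_rate0 Initial learning rate (default 0.03).
#' @param momentum Momentum coefficient (default 0.6).
#' @param halve_every_epochs Scheduler period (default 2000).
#' @param batch_size Mini-batch size (default 4).
#' @param max_epochs Number of training epochs (default 15000).
#' @param validate_every_epochs Evaluation cadence (default 10).
#' @param seed Integer seed for initialization and shuffling.
#' @param target_scale Divisor mapping screen-pixel targets to the
#'   normalized scale the network is trained on; default 2560 (screen width
#'   in px), so x targets lie in `[0, 1]`.
#' @param n_hidden Hidden-layer width (default 200).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate0 = 0.03, momentum = 0.6,
                         halve_every_epochs = 2000, batch_size = 4,
                         max_epochs = 15000, validate_every_epochs = 10,
                         seed = 1L, target_scale = 2560, n_hidden = 200) {
  stopifnot(learning_rate0 > 0, momentum >= 0, halve_every_epochs > 0,
            batch_size > 0, max_epochs > 0, validate_every_epochs > 0,
            target_scale > 0, n_hidden > 0)
  structure(list(learning_rate0 = learning_rate0, momentum = momentum,
                 halve_every_epochs = as.integer(halve_every_epochs),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 validate_every_epochs = as.integer(validate_every_epochs),
                 seed = as.integer(seed), target_scale = target_scale,
                 n_hidden = as.integer(n_hidden)),
            class = "train_config")
}

#' Scheduled learning rate at a given epoch
#'
#' `learning_rate0 * 0.5 ^ floor(epoch / halve_every_epochs)`; with the
#' defaults, 0.03 up to epoch 1999, 0.015 from epoch 2000, and
#' 0.000234375 at epoch 14000.
#'
#' @param epoch Epoch index (>= 0); vectorized.
#' @param cfg A [train_config()].
#' @return Learning rate(s).
#' @export
scheduled_lr <- function(epoch, cfg = train_config()) {
  stopifnot(all(epoch >= 0))
  cfg$learning_rate0 * 0.5^floor(epoch / cfg$halve_every_epochs)
}

#' Initialize network parameters
#'
#' Weights drawn uniformly in `+/- 1/sqrt(fan_in)` (the conventional choice
#' for sigmoid layers), biases zero.
#'
#' @param cfg A [train_config()] (hidden width); randomness comes from the
#'   current RNG state.
#' @return A `gaze_mlp` parameter list: `W1` (n_hidden x 14), `b1`, `W2`
#'   (2 x n_hidden), `b2`.
#' @export
init_gaze_mlp <- function(cfg = train_config()) {
  h <- cfg$n_hidden
  r1 <- 1 / sqrt(14); r2 <- 1 / sqrt(h)
  structure(list(
    W1 = matrix(stats::runif(h * 14, -r1, r1), h, 14),
    b1 = numeric(h),
    W2 = matrix(stats::runif(2 * h, -r2, r2), 2, h),
    b2 = numeric(2)
  ), class = "gaze_mlp")
}

#' Forward pass of the gaze regressor
#'
#' `output = W2 %*% sigmoid(W1 %*% x + b1) + b2`: one sigmoid hidden layer,
#' linear output layer.
#'
#' @param params A `gaze_mlp` parameter list.
#' @param features 14 x n matrix (or length-14 vector) of normalized
#'   features.
#' @return 2 x n matrix of normalized gaze estimates.
#' @export
gaze_mlp_forward <- function(params, features) {
  X <- if (is.matrix(features)) features else matrix(features, ncol = 1)
  if (nrow(X) != ncol(params$W1) || !all(is.finite(X))) {
    stop(sprintf("features must be finite with %d rows", ncol(params$W1)))
  }
  H <- 1 / (1 + exp(-(params$W1 %*% X + params$b1)))
  params$W2 %*% H + params$b2
}

#' Mean squared-norm (L2) loss
#'
#' Mean over samples of the squared Euclidean deviation
#' `(dx^2 + dy^2)` between predictions and ground truth.
#'
#' @param predictions,truths Equal-size 2 x n or n x 2 matrices.
#' @return Scalar loss.
#' @export
l2_loss <- function(predictions, truths) {
  p <- as.matrix(predictions); t_ <- as.matrix(truths)
  if (length(p) == 0) stop("empty input")
  if (!all(dim(p) == dim(t_))) stop("predictions and truths differ in shape")
  n <- if (nrow(p) == 2 && ncol(p) != 2) ncol(p) else nrow(p)
  sum((p - t_)^2) / n
}

#' Analytic gradient of the L2 loss for one mini-batch
#'
#' @param params A `gaze_mlp` parameter list.
#' @param X 14 x b feature matrix.
#' @param Y 2 x b normalized target matrix.
#' @return List of gradients with the same shapes as `params`.
#' @export
gaze_mlp_grad <- function(params, X, Y) {
  H <- 1 / (1 + exp(-(params$W1 %*% X + params$b1)))
  P <- params$W2 %*% H + params$b2
  D <- 2 * (P - Y) / ncol(X)
  DH <- crossprod(params$W2, D) * H * (1 - H)
  list(W1 = DH %*% t(X), b1 = rowSums(DH),
       W2 = D %*% t(H), b2 = rowSums(D))
}

#' Train the gaze regressor
#'
#' Mini-batch SGD with classical momentum (`v <- mu * v - lr * g;
#' theta <- theta + v`), shuffling each epoch and keeping the last
#' incomplete batch. The learning rate follows [scheduled_lr()]. Every
#' `validate_every_epochs` epochs the training and validation losses are
#' recorded; the parameters from the evaluation with the lowest validation
#' loss are returned (best-validation checkpointing).
#'
#' Internally the first layer is initialized and updated in a standardized
#' input basis (per-feature z-scores of the training set), a diagonal
#' preconditioner without which plain SGD stalls near the linear solution:
#' the homogeneously normalized landmark coordinates vary by only a few
#' hundredths around large offsets, so in the raw basis the hidden
#' sigmoids start (and stay) in their linear regime. The returned weights
#' are mapped back to the raw feature basis, so the trained network
#' consumes exactly the [assemble_features()] output; the fitted function
#' is unaffected by the reparameterization.
#'
#' @param x_train,x_val n x 14 matrices of normalized features.
#' @param y_train,y_val n x 2 matrices of normalized targets.
#' @param cfg A [train_config()].
#' @return List with `params` (best `gaze_mlp`), `trace` (data frame:
#'   `epoch`, `train_loss`, `val_loss`, `lr`), `best_epoch` and
#'   `best_val_loss`.
#' @export
train_gaze_mlp <- function(x_train, y_train, x_val, y_val,
                           cfg = train_config()) {
  X <- t(as.matrix(x_train)); Y <- t(as.matrix(y_train))
  XV <- t(as.matrix(x_val)); YV <- t(as.matrix(y_val))
  stopifnot(nrow(X) == 14, nrow(Y) == 2, ncol(X) == ncol(Y),
            ncol(X) > 0, ncol(XV) > 0)
  # standardized input basis (training-set statistics)
  feat_mean <- rowMeans(X)
  feat_sd <- apply(X, 1, stats::sd)
  feat_sd[!is.finite(feat_sd) | feat_sd < 1e-12] <- 1
  X <- (X - feat_mean) / feat_sd
  XV <- (XV - feat_mean) / feat_sd
  set.seed(cfg$seed)
  params <- init_gaze_mlp(cfg)
  vel <- lapply(params, function(p) p * 0)
  n <- ncol(X); bs <- cfg$batch_size; mu <- cfg$momentum
  n_evals <- cfg$max_epochs %/% cfg$validate_every_epochs
  trace <- matrix(NA_real_, n_evals, 4,
                  dimnames = list(NULL, c("epoch", "train_loss", "val_loss",
                                          "lr")))
  best <- list(val_loss = Inf, params = params, epoch = 0L)
  ev <- 0L
  starts <- seq(1, n, by = bs)
  for (e in seq_len(cfg$max_epochs)) {
    lr <- scheduled_lr(e, cfg)
    perm <- sample.int(n)
    for (s in starts) {
      ii <- perm[s:min(s + bs - 1L, n)]
      g <- gaze_mlp_grad(params, X[, ii, drop = FALSE],
                         Y[, ii, drop = FALSE])
      vel$W1 <- mu * vel$W1 - lr * g$W1; params$W1 <- params$W1 + vel$W1
      vel$b1 <- mu * vel$b1 - lr * g$b1; params$b1 <- params$b1 + vel$b1
      vel$W2 <- mu * vel$W2 - lr * g$W2; params$W2 <- params$W2 + vel$W2
      vel$b2 <- mu * vel$b2 - lr * g$b2; params$b2 <- params$b2 + vel$b2
    }
    if (e %% cfg$validate_every_epochs == 0) {
      tl <- l2_loss(gaze_mlp_forward(params, X), Y)
      vl <- l2_loss(gaze_mlp_forward(params, XV), YV)
      if (!is.finite(tl) || !is.finite(vl)) {
        stop(sprintf(paste0("training diverged at epoch %d ",
                            "(train loss %g, val loss %g)"), e, tl, vl))
      }
      ev <- ev + 1L
      trace[ev, ] <- c(e, tl, vl, lr)
      if (vl < best$val_loss) {
        best <- list(val_loss = vl, params = params, epoch = e)
      }
    }
  }
  # express the best parameters in the raw feature basis
  out <- best$params
  out$W1 <- sweep(out$W1, 2, feat_sd, "/")
  out$b1 <- out$b1 - as.numeric(out$W1 %*% feat_mean)
  list(params = out,
       trace = as.data.frame(trace[seq_len(ev), , drop = FALSE]),
       best_epoch = best$epoch, best_val_loss = best$val_loss)
}

#' Predict on-screen gaze positions
#'
#' Runs the forward pass and de-normalizes the output back to screen pixels
#' by `target_scale`.
#'
#' @param params A trained `gaze_mlp`.
#' @param features n x 14 matrix of normalized features.
#' @param target_scale Normalization divisor used during training.
#' @return n x 2 matrix of screen positions (px), columns `x`, `y`.
#' @export
predict_gaze <- function(params, features, target_scale = 2560) {
  out <- t(gaze_mlp_forward(params, t(as.matrix(features)))) * target_scale
  colnames(out) <- c("x", "y")
  out
}

#' Serialize / restore trained parameters
#'
#' Writes a flat JSON artifact (shape-tagged arrays plus metadata) so models
#' survive as plain text.
#'
#' @param params A `gaze_mlp`.
#' @param path File path.
#' @param meta Optional named list stored alongside the arrays.
#' @return `path` (writer) or the restored `gaze_mlp` (reader).
#' @export
write_gaze_mlp <- function(params, path, meta = list()) {
  obj <- list(meta = meta,
              shapes = lapply(params, function(p) dim(p) %||% length(p)),
              values = lapply(params, as.numeric))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_gaze_mlp
#' @export
read_gaze_mlp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- list(W1 = matrix(obj$values$W1, obj$shapes$W1[1], obj$shapes$W1[2]),
            b1 = as.numeric(obj$values$b1),
            W2 = matrix(obj$values$W2, obj$shapes$W2[1], obj$shapes$W2[2]),
            b2 = as.numeric(obj$values$b2))
  structure(p, class = "gaze_mlp", meta = obj$meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
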