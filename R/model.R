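#' Window-classifier architecture configuration
#'
#' The classifier is a small 1D convolutional network: three valid (unpadded)
#' convolution layers with stride 2 and relu activations, global average
#' pooling across time, one relu dense layer, and a single sigmoid output
#' giving the probability that the window contains eating. The conv weights
#' carry an L1 penalty. Global pooling makes the trainable parameter count
#' independent of the window length, so one architecture serves every window
#' size from 7.5 s to 15 min.
#'
#' Defaults: 10 filters per conv layer with kernel lengths 44 / 20 / 4
#' (44 samples is ~3 s at 15 Hz), a 200-unit dense layer, giving 7471
#' trainable weights in total.
#'
#' @param n_channels input channels (6: 3-axis accel + 3-axis gyro).
#' @param filters integer vector of 3 filter counts.
#' @param kernels integer vector of 3 kernel lengths.
#' @param conv_stride stride of every conv layer (default 2).
#' @param l1_penalty L1 regularization weight on conv kernels (default 1e-4;
#'   small enough not to dominate the cross-entropy on balanced batches).
#' @param fc units in the dense layer (default 200).
#' @return a `model_config` list.
#' @export
model_config <- function(n_channels = 6L, filters = c(10L, 10L, 10L),
                         kernels = c(44L, 20L, 4L), conv_stride = 2L,
                         l1_penalty = 1e-4, fc = 200L) {
  stopifnot(length(filters) == 3L, length(kernels) == 3L,
            all(filters >= 1L), all(kernels >= 1L),
            conv_stride >= 1L, fc >= 1L, n_channels >= 1L,
            l1_penalty >= 0)
  structure(list(n_channels = as.integer(n_channels),
                 filters = as.integer(filters),
                 kernels = as.integer(kernels),
                 conv_stride = as.integer(conv_stride),
                 l1_penalty = l1_penalty, fc = as.integer(fc)),
            class = "model_config")
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_size minibatch size (default 32).
#' @param epochs training epochs; the weights after the final epoch are used
#'   as-is (no early stopping; default 150).
#' @param seed integer seed driving shuffling (and weight init when the
#'   model was built without its own seed).
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 32L,
                         epochs = 150L, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1L, epochs >= 1L)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

conv_out_len <- function(n, k, s) {
  if (n < k) return(0L)
  (n - k) %/% s + 1L
}

# minimum input length for which every conv layer emits >= 1 position
min_input_length <- function(config) {
  s <- config$conv_stride
  m <- 1L                       # required length entering (after) layer 3
  for (k in rev(config$kernels)) m <- k + s * (m - 1L)
  m
}

#' Build the window classifier
#'
#' Instantiates the architecture for windows of `n_samples` samples and
#' initializes weights (Glorot-uniform, zero biases). The input must be long
#' enough that every conv layer produces at least one output position.
#'
#' @param config a [model_config()].
#' @param n_samples window length in samples (see [window_samples()]).
#' @param seed optional integer seed for weight initialization; if `NULL`
#'   the current RNG state is used.
#' @return an object of class `window_classifier`.
#' @export
build_model <- function(config = model_config(), n_samples, seed = NULL) {
  n_samples <- as.integer(n_samples)
  mn <- min_input_length(config)
  if (n_samples < mn)
    stop("n_samples = ", n_samples, " too small for the conv stack; ",
         "minimum is ", mn)
  s <- config$conv_stride
  n1 <- conv_out_len(n_samples, config$kernels[1L], s)
  n2 <- conv_out_len(n1, config$kernels[2L], s)
  n3 <- conv_out_len(n2, config$kernels[3L], s)
  glorot <- function(nrow_, ncol_, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(runif(nrow_ * ncol_, -lim, lim), nrow_, ncol_)
  }
  init <- function() {
    C <- config$n_channels; f <- config$filters; k <- config$kernels
    list(
      W1 = glorot(k[1L] * C, f[1L], k[1L] * C, k[1L] * f[1L]),
      b1 = numeric(f[1L]),
      W2 = glorot(k[2L] * f[1L], f[2L], k[2L] * f[1L], k[2L] * f[2L]),
      b2 = numeric(f[2L]),
      W3 = glorot(k[3L] * f[2L], f[3L], k[3L] * f[2L], k[3L] * f[3L]),
      b3 = numeric(f[3L]),
      W4 = glorot(f[3L], config$fc, f[3L], config$fc),
      b4 = numeric(config$fc),
      W5 = glorot(config$fc, 1L, config$fc, 1L),
      b5 = numeric(1L))
  }
  params <- if (is.null(seed)) init() else withr::with_seed(as.integer(seed),
                                                            init())
  structure(list(config = config, n_samples = n_samples,
                 feature_lengths = c(n1, n2, n3), params = params,
                 trained = FALSE),
            class = "window_classifier")
}

#' Trainable parameter count
#'
#' Equals the closed form
#' `(C*L1 + 1)*f1 + (f1*L2 + 1)*f2 + (f2*L3 + 1)*f3 + (f3 + 1)*fc + fc + 1`,
#' independent of the window length.
#'
#' @param model a `window_classifier` (or a `model_config`).
#' @return integer number of trainable weights and biases.
#' @export
n_trainable_params <- function(model) {
  if (inherits(model, "window_classifier"))
    return(sum(vapply(model$params, length, integer(1))))
  cfg <- model
  C <- cfg$n_channels; f <- cfg$filters; k <- cfg$kernels
  (C * k[1L] + 1L) * f[1L] + (f[1L] * k[2L] + 1L) * f[2L] +
    (f[2L] * k[3L] + 1L) * f[3L] + (f[3L] + 1L) * cfg$fc + cfg$fc + 1L
}

#' @export
print.window_classifier <- function(x, ...) {
  cat(sprintf(paste0("<window_classifier> input %d samples x %d ch; conv ",
                     "%s (k=%s, stride %d); fc %d; %d params%s\n"),
              x$n_samples, x$config$n_channels,
              paste(x$config$filters, collapse = "/"),
              paste(x$config$kernels, collapse = "/"),
              x$config$conv_stride, x$config$fc, n_trainable_params(x),
              if (x$trained) " (trained)" else ""))
  invisible(x)
}

relu <- function(z) { z[z < 0] <- 0; z }
sigmoid <- function(z) 1 / (1 + exp(-z))

# global average pool a (n3, F, B) cube to a (B, F) matrix
gap_pool <- function(a3) {
  d <- dim(a3)
  t(vapply(seq_len(d[3L]), function(s) {
    m <- a3[, , s, drop = FALSE]
    dim(m) <- d[1:2]
    colMeans(m)
  }, numeric(d[2L])))
}

# forward pass; x is (n_samples, C, B). Returns p and, if cache, all
# intermediates needed for backprop.
model_forward <- function(model, x, cache = FALSE) {
  p <- model$params; s <- model$config$conv_stride
  if (!cache) {
    a1 <- relu(.conv1d_forward(x, p$W1, p$b1, s))
    a2 <- relu(.conv1d_forward(a1, p$W2, p$b2, s))
    a3 <- relu(.conv1d_forward(a2, p$W3, p$b3, s))
  } else {
    c1 <- .conv1d_forward_cached(x, p$W1, p$b1, s);  z1 <- c1$y; a1 <- relu(z1)
    c2 <- .conv1d_forward_cached(a1, p$W2, p$b2, s); z2 <- c2$y; a2 <- relu(z2)
    c3 <- .conv1d_forward_cached(a2, p$W3, p$b3, s); z3 <- c3$y; a3 <- relu(z3)
  }
  g  <- gap_pool(a3)                               # B x f3
  h  <- sweep(g %*% p$W4, 2L, p$b4, "+")           # B x fc
  hr <- relu(h)
  zo <- as.numeric(hr %*% p$W5) + p$b5             # B
  prob <- sigmoid(zo)
  if (!cache) return(prob)
  list(prob = prob, z1 = z1, z2 = z2, z3 = z3, g = g, h = h, hr = hr,
       col1 = c1$col, col2 = c2$col, col3 = c3$col,
       dims = dim(x)[1:2], dims1 = dim(a1)[1:2], dims2 = dim(a2)[1:2])
}

# gradient of mean BCE (+ L1 on conv kernels) w.r.t. all parameters
model_gradients <- function(model, fw, y) {
  p <- model$params; s <- model$config$conv_stride
  B <- length(y)
  n3 <- dim(fw$z3)[1L]
  d5 <- matrix((fw$prob - y) / B, ncol = 1L)       # B x 1
  gW5 <- t(fw$hr) %*% d5
  gb5 <- sum(d5)
  dhr <- d5 %*% t(p$W5)                            # B x fc
  dh  <- dhr * (fw$h > 0)
  gW4 <- t(fw$g) %*% dh
  gb4 <- colSums(dh)
  dg  <- dh %*% t(p$W4)                            # B x f3
  da3 <- array(rep(t(dg) / n3, each = n3), dim = c(n3, dim(dg)[2L], B))
  dz3 <- da3 * (fw$z3 > 0)
  b3  <- .conv1d_backward(fw$col3, p$W3, dz3, s, TRUE,
                          fw$dims2[1L], fw$dims2[2L])
  dz2 <- b3$gx * (fw$z2 > 0)
  b2  <- .conv1d_backward(fw$col2, p$W2, dz2, s, TRUE,
                          fw$dims1[1L], fw$dims1[2L])
  dz1 <- b2$gx * (fw$z1 > 0)
  b1  <- .conv1d_backward(fw$col1, p$W1, dz1, s, FALSE, fw$dims[1L],
                          fw$dims[2L])
  lam <- model$config$l1_penalty
  list(W1 = b1$gw + lam * sign(p$W1), b1 = as.numeric(b1$gb),
       W2 = b2$gw + lam * sign(p$W2), b2 = as.numeric(b2$gb),
       W3 = b3$gw + lam * sign(p$W3), b3 = as.numeric(b3$gb),
       W4 = gW4, b4 = gb4, W5 = gW5, b5 = gb5)
}

bce_loss <- function(prob, y, model = NULL) {
  pc <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  l <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  if (!is.null(model)) {
    lam <- model$config$l1_penalty
    l <- l + lam * (sum(abs(model$params$W1)) + sum(abs(model$params$W2)) +
                    sum(abs(model$params$W3)))
  }
  l
}

#' Train the window classifier
#'
#' Minimizes binary cross-entropy (plus the L1 conv penalty) with Adam.
#' Training is fully deterministic given the seed in `config` (single
#' threaded; all shuffling goes through R's RNG).
#'
#' @param model a `window_classifier` from [build_model()].
#' @param x training windows, array `(n_samples, 6, B)` (see
#'   [extract_windows()]).
#' @param y integer labels (0/1), length `B`.
#' @param config a [train_config()].
#' @return the trained model, with a `history` data frame (`epoch`, `loss`,
#'   `accuracy`) attached.
#' @export
train_model <- function(model, x, y, config = train_config()) {
  stopifnot(inherits(model, "window_classifier"))
  y <- as.numeric(y)
  if (length(dim(x)) != 3L || dim(x)[3L] != length(y))
    stop("x must be (n_samples, channels, B) with B == length(y)")
  if (dim(x)[1L] != model$n_samples)
    stop("window length ", dim(x)[1L], " does not match model n_samples ",
         model$n_samples)
  if (length(unique(y)) < 2L)
    stop("training data contain a single class; cannot train")
  B <- length(y)
  lr <- config$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  mstate <- lapply(model$params, function(w) w * 0)
  vstate <- mstate
  step <- 0L
  history <- data.frame(epoch = integer(), loss = numeric(),
                        accuracy = numeric())
  withr::with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(B)
      ep_loss <- 0; ep_correct <- 0
      for (b0 in seq.int(1L, B, by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1L, B)]
        xb <- x[, , idx, drop = FALSE]
        yb <- y[idx]
        fw <- model_forward(model, xb, cache = TRUE)
        gr <- model_gradients(model, fw, yb)
        step <- step + 1L
        for (nm in names(model$params)) {
          mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * gr[[nm]]
          vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * gr[[nm]]^2
          mhat <- mstate[[nm]] / (1 - beta1^step)
          vhat <- vstate[[nm]] / (1 - beta2^step)
          model$params[[nm]] <- model$params[[nm]] -
            lr * mhat / (sqrt(vhat) + eps)
        }
        ep_loss <- ep_loss + bce_loss(fw$prob, yb, model) * length(idx)
        ep_correct <- ep_correct + sum((fw$prob >= 0.5) == (yb == 1))
      }
      history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / B,
                                           accuracy = ep_correct / B))
    }
  })
  model$trained <- TRUE
  model$history <- history
  model
}

#' Predict eating probabilities for windows
#'
#' @param model a `window_classifier`.
#' @param x array `(n_samples, 6, B)` of windows.
#' @param chunk_size windows evaluated per internal batch (memory knob only;
#'   results are identical for any value).
#' @return numeric vector of `B` probabilities in `[0, 1]`.
#' @export
predict_windows <- function(model, x, chunk_size = 64L) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[1L] != model$n_samples || dim(x)[2L] != model$config$n_channels)
    stop("window shape (", dim(x)[1L], " x ", dim(x)[2L],
         ") does not match model input (", model$n_samples, " x ",
         model$config$n_channels, ")")
  B <- dim(x)[3L]
  out <- numeric(B)
  for (b0 in seq.int(1L, B, by = chunk_size)) {
    idx <- b0:min(b0 + chunk_size - 1L, B)
    out[idx] <- model_forward(model, x[, , idx, drop = FALSE])
  }
  out
}

#' Window classification accuracy
#'
#' @param probabilities predicted probabilities.
#' @param labels true 0/1 labels.
#' @param threshold decision threshold (default 0.5; `p >= threshold` is
#'   called eating).
#' @return fraction of windows classified correctly.
#' @export
window_accuracy <- function(probabilities, labels, threshold = 0.5) {
  if (length(probabilities) == 0L) stop("empty input")
  if (length(probabilities) != length(labels))
    stop("probabilities and labels must have equal length")
  mean((probabilities >= threshold) == (labels == 1))
}

#' Save / load a trained classifier
#'
#' The checkpoint is an RDS of the full model object plus a JSON sidecar
#' (`<path>.json`) describing the architecture, for inspection without R.
#'
#' @param model a `window_classifier`.
#' @param path checkpoint file (`.rds`).
#' @return `path` (or, for load, the model), invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- list(n_samples = model$n_samples,
               n_params = n_trainable_params(model),
               config = unclass(model$config), trained = model$trained)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "window_classifier"))
  model
}
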