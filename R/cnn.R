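#' Output length of a 1-D convolutional layer
#'
#' The standard shape rule `X = (W - F + 2P) / S + 1` for a 1-D convolution
#' of kernel length `F`, padding `P` and stride `S` on an input of length
#' `W`. Non-integer results mean the layer specification is invalid and
#' raise an error rather than silently truncating.
#'
#' @param W Input length in samples.
#' @param F Kernel length.
#' @param P Padding added on each side (0 under Valid padding).
#' @param S Stride.
#' @return The integer output length `X`.
#' @export
#' @examples
#' conv_output_length(151, 5, 0, 1) # 147
conv_output_length <- function(W, F, P = 0, S = 1) {
  if (S < 1) stop("stride must be >= 1", call. = FALSE)
  if (W + 2 * P < F) stop("kernel longer than (padded) input", call. = FALSE)
  X <- (W - F + 2 * P) / S + 1
  if (X != round(X)) {
    stop(sprintf("invalid conv spec: (W=%d, F=%d, P=%d, S=%d) gives X=%.2f",
                 W, F, P, S, X), call. = FALSE)
  }
  as.integer(X)
}

#' Output length of a 1-D pooling layer
#'
#' The pooling shape rule `Y = (W - F) / S + 1`. Non-integer results raise an
#' error.
#'
#' @param W Input length in samples.
#' @param F Pooling kernel length.
#' @param S Stride.
#' @return The integer output length `Y`.
#' @export
#' @examples
#' pool_output_length(146, 2, 2) # 73
pool_output_length <- function(W, F, S) {
  if (S < 1) stop("stride must be >= 1", call. = FALSE)
  if (W < F) stop("pool kernel longer than input", call. = FALSE)
  Y <- (W - F) / S + 1
  if (Y != round(Y)) {
    stop(sprintf("invalid pool spec: (W=%d, F=%d, S=%d) gives Y=%.2f",
                 W, F, S, Y), call. = FALSE)
  }
  as.integer(Y)
}

# ---- layer constructors (weights drawn He-style from the current RNG) ----

.new_conv <- function(F, cin, cout, pad = c("valid", "same"), relu = TRUE) {
  pad <- match.arg(pad)
  W <- matrix(stats::rnorm(F * cin * cout, 0, sqrt(2 / (F * cin))),
              F * cin, cout)
  list(type = "conv", F = F, cin = cin, cout = cout, pad = pad,
       relu = relu, W = W, b = numeric(cout))
}

.new_pool <- function(F, S = 2L) list(type = "pool", F = F, S = S)

.new_resblock <- function(F, ch) {
  # inner transform: conv -> ReLU -> conv, both length-preserving
  list(type = "resblock",
       conv1 = .new_conv(F, ch, ch, pad = "same", relu = TRUE),
       conv2 = .new_conv(F, ch, ch, pad = "same", relu = FALSE))
}

.new_fc <- function(din, dout) {
  list(type = "fc", din = din, dout = dout,
       W = matrix(stats::rnorm(din * dout, 0, sqrt(2 / din)), din, dout),
       b = numeric(dout))
}

# pool kernel chosen (2 or 3) so the stride-2 chain stays integral for every
# supported input length; both satisfy the pooling shape rule exactly
.pool_kernel_for <- function(W, S = 2L) {
  if ((W - 2L) %% S == 0L) 2L else 3L
}

#' Build the residual 1-D CNN window classifier
#'
#' Constructs the binary (R-centred vs not) window classifier: an initial
#' Valid convolution, two residual blocks of two length-preserving
#' convolutions each (output = input + inner transform, so six convolutional
#' layers in total), three stride-2 max-pooling layers, one fully connected
#' layer and a softmax over the two classes. ReLU activations throughout the
#' trunk. Every layer's output length is validated against the convolution
#' and pooling shape rules at build time; an inconsistent chain errors naming
#' the offending layer.
#'
#' @param input_length Window length in samples; 101, 151 and 201 are the
#'   studied lengths (other odd lengths build if the shape chain validates).
#' @param channels Channel width of the trunk (default 32).
#' @param kernel Convolution kernel length (default 5).
#' @param seed Integer seed for weight initialisation.
#'
#' @return An object of class `qrs_cnn` with elements `layers`, `shapes`
#'   (predicted per-layer output lengths), `input_length`, `channels`.
#' @export
#' @examples
#' model <- build_model(151)
#' model$shapes
build_model <- function(input_length, channels = 32L, kernel = 5L,
                        seed = 1L) {
  set.seed(as.integer(seed))
  L <- as.integer(input_length)
  ch <- as.integer(channels)
  layers <- list()
  shapes <- list()
  add <- function(layer, name, out_len, out_ch) {
    layers[[length(layers) + 1L]] <<- layer
    shapes[[length(shapes) + 1L]] <<- data.frame(
      layer = name, out_length = out_len, out_channels = out_ch)
  }

  W <- L
  X <- tryCatch(conv_output_length(W, kernel, 0, 1),
                error = function(e) stop("layer conv1: ", conditionMessage(e),
                                         call. = FALSE))
  add(.new_conv(kernel, 1L, ch, "valid", relu = TRUE), "conv1", X, ch)
  W <- X

  pf <- .pool_kernel_for(W)
  Y <- tryCatch(pool_output_length(W, pf, 2L),
                error = function(e) stop("layer pool1: ", conditionMessage(e),
                                         call. = FALSE))
  add(.new_pool(pf), "pool1", Y, ch)
  W <- Y

  for (b in 1:2) {
    # length-preserving residual block: same padding keeps the skip addition
    # shape-consistent
    add(.new_resblock(kernel, ch), paste0("resblock", b), W, ch)
  }

  pf <- .pool_kernel_for(W)
  Y <- tryCatch(pool_output_length(W, pf, 2L),
                error = function(e) stop("layer pool2: ", conditionMessage(e),
                                         call. = FALSE))
  add(.new_pool(pf), "pool2", Y, ch)
  W <- Y

  X <- tryCatch(conv_output_length(W, kernel, 0, 1),
                error = function(e) stop("layer conv6: ", conditionMessage(e),
                                         call. = FALSE))
  add(.new_conv(kernel, ch, ch, "valid", relu = TRUE), "conv6", X, ch)
  W <- X

  pf <- .pool_kernel_for(W)
  Y <- tryCatch(pool_output_length(W, pf, 2L),
                error = function(e) stop("layer pool3: ", conditionMessage(e),
                                         call. = FALSE))
  add(.new_pool(pf), "pool3", Y, ch)
  W <- Y

  add(.new_fc(W * ch, 2L), "fc", 2L, 1L)

  structure(
    list(layers = layers, shapes = do.call(rbind, shapes),
         input_length = L, channels = ch, kernel = as.integer(kernel)),
    class = "qrs_cnn"
  )
}

#' @export
print.qrs_cnn <- function(x, ...) {
  cat(sprintf("<qrs_cnn> input length %d, %d channels\n",
              x$input_length, x$channels))
  print(x$shapes, row.names = FALSE)
  invisible(x)
}

# ---- forward / backward primitives ----
# feature maps are arrays (n, length, channels)

.im2col <- function(x, F) {
  d <- dim(x)
  n <- d[1]; W <- d[2]; cin <- d[3]
  X <- W - F + 1L
  cols <- matrix(0, n * X, F * cin)
  for (f in seq_len(F)) {
    cols[, ((f - 1L) * cin + 1L):(f * cin)] <-
      matrix(x[, f:(f + X - 1L), , drop = FALSE], n * X, cin)
  }
  cols
}

.pad_same <- function(x, p) {
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2L * p, d[3]))
  xp[, (p + 1L):(p + d[2]), ] <- x
  xp
}

.conv_forward <- function(layer, x) {
  p <- if (layer$pad == "same") (layer$F - 1L) %/% 2L else 0L
  xin <- if (p > 0) .pad_same(x, p) else x
  d <- dim(xin)
  X <- d[2] - layer$F + 1L
  cols <- .im2col(xin, layer$F)
  out <- sweep(cols %*% layer$W, 2, layer$b, "+")
  y <- array(out, c(d[1], X, layer$cout))
  mask <- NULL
  if (layer$relu) {
    mask <- y > 0
    y <- y * mask
  }
  list(y = y, cache = list(cols = cols, in_dim = d, pad = p, mask = mask))
}

.conv_backward <- function(layer, cache, dy) {
  d <- dim(dy)
  if (!is.null(cache$mask)) dy <- dy * cache$mask
  dmat <- matrix(dy, d[1] * d[2], d[3])
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- dmat %*% t(layer$W)
  din <- cache$in_dim
  dxp <- array(0, din)
  X <- d[2]
  cin <- layer$cin
  for (f in seq_len(layer$F)) {
    blk <- array(dcols[, ((f - 1L) * cin + 1L):(f * cin)], c(din[1], X, cin))
    dxp[, f:(f + X - 1L), ] <- dxp[, f:(f + X - 1L), , drop = FALSE] + blk
  }
  p <- cache$pad
  dx <- if (p > 0) dxp[, (p + 1L):(din[2] - p), , drop = FALSE] else dxp
  list(dx = dx, dW = dW, db = db)
}

.pool_forward <- function(layer, x) {
  d <- dim(x)
  Y <- pool_output_length(d[2], layer$F, layer$S)
  y <- array(-Inf, c(d[1], Y, d[3]))
  arg <- array(1L, c(d[1], Y, d[3]))
  for (f in seq_len(layer$F)) {
    idx <- seq.int(f, by = layer$S, length.out = Y)
    cand <- x[, idx, , drop = FALSE]
    better <- cand > y
    y[better] <- cand[better]
    arg[better] <- f
  }
  list(y = y, cache = list(arg = arg, in_dim = d))
}

.pool_backward <- function(layer, cache, dy) {
  din <- cache$in_dim
  dx <- array(0, din)
  Y <- dim(dy)[2]
  for (f in seq_len(layer$F)) {
    idx <- seq.int(f, by = layer$S, length.out = Y)
    sel <- cache$arg == f
    if (any(sel)) {
      blk <- dx[, idx, , drop = FALSE]
      blk[sel] <- blk[sel] + dy[sel]
      dx[, idx, ] <- blk
    }
  }
  dx
}

#' Apply a residual block to a feature map
#'
#' Computes `output = input + F(input)` where the inner transform `F` is
#' conv - ReLU - conv with length-preserving convolutions; zeroing the inner
#' weights therefore makes the block the identity map.
#'
#' @param x Feature map array of dimension (batch, length, channels).
#' @param block A residual-block layer as built by [build_model()] (an
#'   element of `model$layers` with `type == "resblock"`).
#' @return Feature map of identical dimension.
#' @export
residual_block <- function(x, block) {
  if (!identical(block$type, "resblock")) {
    stop("`block` must be a resblock layer", call. = FALSE)
  }
  .resblock_forward(block, x)$y
}

.resblock_forward <- function(layer, x) {
  f1 <- .conv_forward(layer$conv1, x)
  f2 <- .conv_forward(layer$conv2, f1$y)
  if (!all(dim(f2$y) == dim(x))) {
    stop("residual addition shape mismatch", call. = FALSE)
  }
  list(y = x + f2$y, cache = list(c1 = f1$cache, c2 = f2$cache))
}

.resblock_backward <- function(layer, cache, dy) {
  b2 <- .conv_backward(layer$conv2, cache$c2, dy)
  b1 <- .conv_backward(layer$conv1, cache$c1, b2$dx)
  list(dx = b1$dx + dy,
       grads = list(c1 = list(dW = b1$dW, db = b1$db),
                    c2 = list(dW = b2$dW, db = b2$db)))
}

.fc_forward <- function(layer, x) {
  d <- dim(x)
  xm <- matrix(x, d[1], d[2] * d[3])
  list(y = sweep(xm %*% layer$W, 2, layer$b, "+"),
       cache = list(xm = xm, in_dim = d))
}

.fc_backward <- function(layer, cache, dy) {
  list(dx = array(dy %*% t(layer$W), cache$in_dim),
       dW = crossprod(cache$xm, dy),
       db = colSums(dy))
}

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# full forward pass; keep_caches enables backprop, observe_shapes returns the
# per-layer output lengths actually produced (the shape oracle's observation)
.forward <- function(model, x, keep_caches = FALSE) {
  caches <- vector("list", length(model$layers))
  observed <- integer(length(model$layers))
  for (i in seq_along(model$layers)) {
    layer <- model$layers[[i]]
    out <- switch(layer$type,
      conv = .conv_forward(layer, x),
      pool = .pool_forward(layer, x),
      resblock = .resblock_forward(layer, x),
      fc = .fc_forward(layer, x))
    x <- out$y
    observed[i] <- if (layer$type == "fc") ncol(x) else dim(x)[2]
    if (keep_caches) caches[[i]] <- out$cache
  }
  list(logits = x, caches = caches, observed_lengths = observed)
}

#' Observed per-layer output lengths of a forward pass
#'
#' Runs an instrumented forward pass on a small batch and returns, for every
#' layer, the output length the implementation actually produced next to the
#' length predicted by the convolution/pooling shape rules at build time.
#' Used as the shape oracle: the two columns must agree exactly.
#'
#' @param model A [build_model()] network.
#' @param batch_size Number of probe windows (default 2).
#' @return `model$shapes` with an extra column `observed_length`.
#' @export
observed_shapes <- function(model, batch_size = 2L) {
  x <- array(stats::rnorm(batch_size * model$input_length),
             c(batch_size, model$input_length, 1L))
  fw <- .forward(model, x)
  out <- model$shapes
  out$observed_length <- fw$observed_lengths
  out
}

#' Training configuration for the window classifier
#'
#' @param epochs Number of passes over the training set (the "iterations" of
#'   the training-curve studies; default 100).
#' @param batch_size Mini-batch size (default 128).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Integer seed covering weight initialisation order and batch
#'   shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 128L,
                         learning_rate = 1e-3, seed = 1L) {
  if (epochs < 1) stop("`epochs` must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("`learning_rate` must be > 0", call. = FALSE)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "train_config")
}

# flatten model parameters into a named list of (layer index, slot) refs
.param_refs <- function(model) {
  refs <- list()
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$type == "conv") {
      refs[[length(refs) + 1L]] <- list(i = i, path = character(0))
    } else if (l$type == "resblock") {
      refs[[length(refs) + 1L]] <- list(i = i, path = "conv1")
      refs[[length(refs) + 1L]] <- list(i = i, path = "conv2")
    } else if (l$type == "fc") {
      refs[[length(refs) + 1L]] <- list(i = i, path = character(0))
    }
  }
  refs
}

#' Train the window classifier by mini-batch cross-entropy minimisation
#'
#' Minimises the softmax cross-entropy of R vs non-R window labels with the
#' Adam optimiser, recording mean training loss and training accuracy per
#' epoch. Deterministic for a fixed seed and thread configuration.
#'
#' @param model A [build_model()] network whose `input_length` matches the
#'   dataset's window length.
#' @param dataset A [build_window_dataset()] result (both classes must be
#'   present), or any list with a windows matrix `x` and factor `label`.
#' @param config A [train_config()].
#' @return A list with the trained `model` and `history`, a data frame with
#'   columns `epoch`, `loss`, `accuracy`.
#' @export
train_model <- function(model, dataset, config = train_config()) {
  stopifnot(inherits(model, "qrs_cnn"))
  x <- dataset$x
  lab <- dataset$label
  if (nlevels(droplevels(lab)) < 2) {
    stop("dataset must contain both classes", call. = FALSE)
  }
  if (ncol(x) != model$input_length) {
    stop(sprintf("segment length %d != model input length %d",
                 ncol(x), model$input_length), call. = FALSE)
  }
  n <- nrow(x)
  y <- as.integer(lab)  # 1 = nonR, 2 = R
  lr <- config$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  refs <- .param_refs(model)
  mW <- lapply(refs, function(r) 0); vW <- mW
  mb <- mW; vb <- mW
  t_step <- 0

  get_layer <- function(r) {
    l <- model$layers[[r$i]]
    if (length(r$path)) l[[r$path]] else l
  }
  set_layer <- function(r, l) {
    if (length(r$path)) model$layers[[r$i]][[r$path]] <<- l
    else model$layers[[r$i]] <<- l
  }

  set.seed(config$seed)
  loss_hist <- numeric(config$epochs)
  acc_hist <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      nb <- length(idx)
      xb <- array(t(x[idx, , drop = FALSE]),
                  c(model$input_length, nb, 1L))
      xb <- aperm(xb, c(2, 1, 3))
      yb <- y[idx]
      fw <- .forward(model, xb, keep_caches = TRUE)
      p <- .softmax(fw$logits)
      picked <- p[cbind(seq_len(nb), yb)]
      ep_loss <- ep_loss - sum(log(pmax(picked, 1e-12)))
      ep_correct <- ep_correct + sum(max.col(p) == yb)
      # d(loss)/d(logits) for mean CE over the batch
      dy <- p
      dy[cbind(seq_len(nb), yb)] <- dy[cbind(seq_len(nb), yb)] - 1
      dy <- dy / nb

      # backward pass collecting per-parameter gradients
      grads <- vector("list", length(model$layers))
      for (i in rev(seq_along(model$layers))) {
        layer <- model$layers[[i]]
        cache <- fw$caches[[i]]
        if (layer$type == "fc") {
          bk <- .fc_backward(layer, cache, dy)
          grads[[i]] <- list(dW = bk$dW, db = bk$db)
          dy <- bk$dx
        } else if (layer$type == "conv") {
          bk <- .conv_backward(layer, cache, dy)
          grads[[i]] <- list(dW = bk$dW, db = bk$db)
          dy <- bk$dx
        } else if (layer$type == "pool") {
          dy <- .pool_backward(layer, cache, dy)
        } else if (layer$type == "resblock") {
          bk <- .resblock_backward(layer, cache, dy)
          grads[[i]] <- bk$grads
          dy <- bk$dx
        }
      }

      # Adam update over every parameterised (sub)layer
      t_step <- t_step + 1
      for (k in seq_along(refs)) {
        r <- refs[[k]]
        g <- if (length(r$path)) grads[[r$i]][[if (r$path == "conv1") "c1" else "c2"]]
             else grads[[r$i]]
        l <- get_layer(r)
        mW[[k]] <- beta1 * mW[[k]] + (1 - beta1) * g$dW
        vW[[k]] <- beta2 * vW[[k]] + (1 - beta2) * g$dW^2
        mb[[k]] <- beta1 * mb[[k]] + (1 - beta1) * g$db
        vb[[k]] <- beta2 * vb[[k]] + (1 - beta2) * g$db^2
        mhW <- mW[[k]] / (1 - beta1^t_step)
        vhW <- vW[[k]] / (1 - beta2^t_step)
        mhb <- mb[[k]] / (1 - beta1^t_step)
        vhb <- vb[[k]] / (1 - beta2^t_step)
        l$W <- l$W - lr * mhW / (sqrt(vhW) + eps)
        l$b <- l$b - lr * mhb / (sqrt(vhb) + eps)
        set_layer(r, l)
      }
    }
    loss_hist[ep] <- ep_loss / n
    acc_hist[ep] <- ep_correct / n
  }

  list(model = model,
       history = data.frame(epoch = seq_len(config$epochs),
                            loss = loss_hist, accuracy = acc_hist))
}

#' Predict the probability that each window is R-centred
#'
#' Forward pass plus softmax; deterministic. Large batches are processed in
#' chunks to bound memory.
#'
#' @param model A trained [build_model()] network.
#' @param segments Numeric matrix, one window per row (already per-segment
#'   normalised, as in [build_window_dataset()]), or a single window vector.
#' @param chunk_size Rows per forward chunk.
#' @return Numeric vector of `P(R)` in `[0, 1]`, one per window.
#' @export
predict_proba <- function(model, segments, chunk_size = 1024L) {
  stopifnot(inherits(model, "qrs_cnn"))
  if (is.vector(segments)) segments <- matrix(segments, 1L)
  if (ncol(segments) != model$input_length) {
    stop(sprintf("segment length %d != model input length %d",
                 ncol(segments), model$input_length), call. = FALSE)
  }
  n <- nrow(segments)
  out <- numeric(n)
  for (start in seq(1, n, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n)
    xb <- aperm(array(t(segments[idx, , drop = FALSE]),
                      c(model$input_length, length(idx), 1L)), c(2, 1, 3))
    p <- .softmax(.forward(model, xb)$logits)
    out[idx] <- p[, 2L]  # column 2 = class "R"
  }
  out
}
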