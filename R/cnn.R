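# One-dimensional convolutional network for end-to-end symptom detection from
# raw (filtered) clips. Architecture: two ReLU convolution layers (kernels 32
# and 16 samples, 16 and 32 filters) each followed by max-pooling (4 and 6),
# two dense ReLU layers of 32 units with dropout 0.5, and a softmax output
# over the two classes. Implemented in base R: convolutions via im2col +
# matrix multiplication, trained with Adam on class-weighted cross-entropy.

#' Convolutional network specification
#'
#' Defaults reproduce the symptom-detection architecture: conv(kernel 32,
#' 16 filters, ReLU) -> maxpool(4) -> conv(kernel 16, 32 filters, ReLU) ->
#' maxpool(6) -> dense(32, ReLU, dropout 0.5) -> dense(32, ReLU, dropout 0.5)
#' -> softmax(2).
#'
#' @param conv_kernels integer kernel sizes (samples) per convolution layer.
#' @param conv_filters filters (ReLU units) per convolution layer.
#' @param pool_sizes max-pooling sizes, one per convolution layer.
#' @param dense_units widths of the dense layers.
#' @param dropout dropout proportion on dense layers during training.
#' @param n_classes softmax width (2: symptom absent / present).
#' @param epochs,batch_size,learning_rate training hyperparameters (Adam).
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return An object of class `cnn_spec`.
#' @export
cnn_spec <- function(conv_kernels = c(32L, 16L), conv_filters = c(16L, 32L),
                     pool_sizes = c(4L, 6L), dense_units = c(32L, 32L),
                     dropout = 0.5, n_classes = 2L, epochs = 30L,
                     batch_size = 64L, learning_rate = 1e-3, seed = 1L) {
  stopifnot(length(conv_kernels) == length(conv_filters),
            length(pool_sizes) == length(conv_kernels),
            all(conv_kernels >= 1), all(conv_filters >= 1),
            all(pool_sizes >= 1), all(dense_units >= 1),
            dropout >= 0, dropout < 1, n_classes >= 2,
            epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(conv_kernels = as.integer(conv_kernels),
                 conv_filters = as.integer(conv_filters),
                 pool_sizes = as.integer(pool_sizes),
                 dense_units = as.integer(dense_units),
                 dropout = dropout, n_classes = as.integer(n_classes),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "cnn_spec")
}

#' Describe the network for a given input shape
#'
#' Walks the architecture with 'same'-padded convolutions and floor-division
#' pooling, reporting each layer's output shape and trainable-parameter count
#' and the total.
#'
#' @param spec a [cnn_spec()].
#' @param input_samples samples per clip (default 312 = 5 s at 62.5 Hz).
#' @param input_channels channels per clip (default 6: acc + gyro).
#' @return An object of class `cnn_arch`: a layer table plus `total_params`.
#' @export
build_cnn <- function(spec = cnn_spec(), input_samples = 312L,
                      input_channels = 6L) {
  stopifnot(inherits(spec, "cnn_spec"), input_samples >= 1,
            input_channels >= 1)
  t_len <- as.integer(input_samples)
  ch <- as.integer(input_channels)
  rows <- list()
  for (i in seq_along(spec$conv_kernels)) {
    k <- spec$conv_kernels[i]
    f <- spec$conv_filters[i]
    rows[[length(rows) + 1]] <- data.frame(
      layer = sprintf("conv%d", i), type = "conv1d_relu", kernel = k,
      units = f, output_shape = sprintf("%d x %d", t_len, f),
      n_params = k * ch * f + f, stringsAsFactors = FALSE)
    ch <- f
    p <- spec$pool_sizes[i]
    t_len <- t_len %/% p
    if (t_len < 1L) {
      stop("pooled length < 1: input too short for this architecture",
           call. = FALSE)
    }
    rows[[length(rows) + 1]] <- data.frame(
      layer = sprintf("pool%d", i), type = "maxpool", kernel = p, units = NA,
      output_shape = sprintf("%d x %d", t_len, ch), n_params = 0L)
  }
  flat <- t_len * ch
  rows[[length(rows) + 1]] <- data.frame(
    layer = "flatten", type = "flatten", kernel = NA, units = NA,
    output_shape = as.character(flat), n_params = 0L)
  in_w <- flat
  for (i in seq_along(spec$dense_units)) {
    u <- spec$dense_units[i]
    rows[[length(rows) + 1]] <- data.frame(
      layer = sprintf("dense%d", i), type = "dense_relu_dropout", kernel = NA,
      units = u, output_shape = as.character(u), n_params = in_w * u + u)
    in_w <- u
  }
  rows[[length(rows) + 1]] <- data.frame(
    layer = "output", type = "dense_softmax", kernel = NA,
    units = spec$n_classes, output_shape = as.character(spec$n_classes),
    n_params = in_w * spec$n_classes + spec$n_classes)
  layers <- do.call(rbind, rows)
  structure(list(layers = layers, total_params = sum(layers$n_params),
                 input_shape = c(samples = as.integer(input_samples),
                                 channels = as.integer(input_channels)),
                 spec = spec),
            class = "cnn_arch")
}

#' @export
print.cnn_arch <- function(x, ...) {
  cat(sprintf("<cnn_arch> input %d samples x %d channels\n",
              x$input_shape[1], x$input_shape[2]))
  print(x$layers, row.names = FALSE)
  cat("total trainable parameters:", x$total_params, "\n")
  invisible(x)
}

# ---- internal forward/backward machinery --------------------------------

# 'same' zero padding along time for kernel k.
pad_same <- function(a, k) {
  d <- dim(a)
  pl <- (k - 1L) %/% 2L
  pr <- k - 1L - pl
  out <- array(0, c(d[1], d[2] + pl + pr, d[3]))
  out[, pl + seq_len(d[2]), ] <- a
  out
}

# (batch, T + k - 1, C) padded array -> (batch * T, k * C) matrix; column
# (c-1)*k + j holds tap j of channel c.
im2col <- function(ap, k, t_len) {
  d <- dim(ap)
  out <- matrix(0, d[1] * t_len, k * d[3])
  for (j in seq_len(k)) {
    sub <- ap[, j:(j + t_len - 1L), , drop = FALSE]
    dim(sub) <- c(d[1] * t_len, d[3])
    out[, seq.int(j, by = k, length.out = d[3])] <- sub
  }
  out
}

# scatter-add of dX2 (batch*T, k*C) back into the padded array gradient.
col2im <- function(dx2, k, t_len, batch, t_pad, n_ch) {
  dap <- array(0, c(batch, t_pad, n_ch))
  for (j in seq_len(k)) {
    sub <- dx2[, seq.int(j, by = k, length.out = n_ch), drop = FALSE]
    dim(sub) <- c(batch, t_len, n_ch)
    dap[, j:(j + t_len - 1L), ] <- dap[, j:(j + t_len - 1L), , drop = FALSE] + sub
  }
  dap
}

conv_fwd <- function(a, w, b, k) {
  d <- dim(a)
  x2 <- im2col(pad_same(a, k), k, d[2])
  y <- x2 %*% w
  y <- sweep(y, 2, b, "+")
  list(y = y, x2 = x2, t_len = d[2], batch = d[1], n_ch = d[3])
}

conv_bwd <- function(dy, cache, w, k) {
  dw <- crossprod(cache$x2, dy)
  db <- colSums(dy)
  dx2 <- tcrossprod(dy, w)
  pl <- (k - 1L) %/% 2L
  dap <- col2im(dx2, k, cache$t_len, cache$batch, cache$t_len + k - 1L,
                cache$n_ch)
  dx <- dap[, pl + seq_len(cache$t_len), , drop = FALSE]
  list(dw = dw, db = db, dx = dx)
}

pool_fwd <- function(y, p, batch, t_len) {
  f <- ncol(y)
  tq <- t_len %/% p
  ya <- y
  dim(ya) <- c(batch, t_len, f)
  z <- ya[, seq.int(1L, by = p, length.out = tq), , drop = FALSE]
  am <- array(1L, dim(z))
  if (p > 1) {
    for (o in 2:p) {
      cand <- ya[, seq.int(o, by = p, length.out = tq), , drop = FALSE]
      upd <- cand > z
      z[upd] <- cand[upd]
      am[upd] <- o
    }
  }
  list(z = z, am = am, tq = tq, f = f)
}

pool_bwd <- function(dz, cache, p, batch, t_len) {
  dy <- array(0, c(batch, t_len, cache$f))
  for (o in seq_len(p)) {
    sel <- cache$am == o
    slice <- dy[, seq.int(o, by = p, length.out = cache$tq), , drop = FALSE]
    slice[sel] <- dz[sel]
    dy[, seq.int(o, by = p, length.out = cache$tq), ] <- slice
  }
  dim(dy) <- c(batch * t_len, cache$f)
  dy
}

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * g
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * g^2
    mhat <- state[[nm]]$m / (1 - beta1^t)
    vhat <- state[[nm]]$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

cnn_forward <- function(params, xb, spec, training = FALSE,
                        dropout_masks = NULL) {
  batch <- dim(xb)[1]
  caches <- list()
  a <- xb
  for (i in seq_along(spec$conv_kernels)) {
    k <- spec$conv_kernels[i]
    cv <- conv_fwd(a, params[[paste0("W", i)]], params[[paste0("b", i)]], k)
    relu_mask <- cv$y > 0
    y <- cv$y * relu_mask
    pl <- pool_fwd(y, spec$pool_sizes[i], batch, cv$t_len)
    caches[[i]] <- list(conv = cv, relu = relu_mask, pool = pl)
    a <- pl$z
  }
  d <- dim(a)
  h <- a
  dim(h) <- c(d[1], d[2] * d[3])
  flat_dim <- d[2] * d[3]
  dense_caches <- list()
  for (i in seq_along(spec$dense_units)) {
    zin <- h
    z <- h %*% params[[paste0("Wd", i)]]
    z <- sweep(z, 2, params[[paste0("bd", i)]], "+")
    mask <- z > 0
    h <- z * mask
    drop <- NULL
    if (training && spec$dropout > 0) {
      drop <- dropout_masks[[i]]
      h <- h * drop
    }
    dense_caches[[i]] <- list(input = zin, relu = mask, drop = drop)
  }
  logits <- sweep(h %*% params$Wo, 2, params$bo, "+")
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  list(probs = probs, h = h, caches = caches, dense_caches = dense_caches,
       flat_dim = flat_dim, batch = batch)
}

cnn_backward <- function(params, fw, yb, wts, spec, xb) {
  batch <- fw$batch
  n_cls <- ncol(fw$probs)
  yoh <- matrix(0, batch, n_cls)
  yoh[cbind(seq_len(batch), yb + 1L)] <- 1
  wsum <- sum(wts)
  dlogits <- (fw$probs - yoh) * wts / wsum
  grads <- list()
  grads$Wo <- crossprod(fw$h, dlogits)
  grads$bo <- colSums(dlogits)
  dh <- tcrossprod(dlogits, params$Wo)
  for (i in rev(seq_along(spec$dense_units))) {
    dc <- fw$dense_caches[[i]]
    if (!is.null(dc$drop)) dh <- dh * dc$drop
    dz <- dh * dc$relu
    grads[[paste0("Wd", i)]] <- crossprod(dc$input, dz)
    grads[[paste0("bd", i)]] <- colSums(dz)
    dh <- tcrossprod(dz, params[[paste0("Wd", i)]])
  }
  # back through flatten into the conv/pool stack
  last <- length(spec$conv_kernels)
  dz_arr <- dh
  dim(dz_arr) <- dim(fw$caches[[last]]$pool$z)
  for (i in rev(seq_along(spec$conv_kernels))) {
    cache <- fw$caches[[i]]
    t_len <- cache$conv$t_len
    dy <- pool_bwd(dz_arr, cache$pool, spec$pool_sizes[i], batch, t_len)
    dy <- dy * cache$relu
    cb <- conv_bwd(dy, cache$conv, params[[paste0("W", i)]],
                   spec$conv_kernels[i])
    grads[[paste0("W", i)]] <- cb$dw
    grads[[paste0("b", i)]] <- cb$db
    if (i > 1) {
      dz_arr <- cb$dx
    }
  }
  grads
}

#' Train the convolutional symptom classifier
#'
#' Trains the [cnn_spec()] architecture on raw (filtered) clips with Adam on
#' class-weighted cross-entropy; channels are standardized with training-set
#' statistics and dropout is applied to the dense layers during training.
#' Deterministic given the spec seed and single-threaded numerics.
#'
#' @param x array `clips x samples x channels` (see [clips_to_array()]).
#' @param y binary labels (0/1), both classes present.
#' @param spec a [cnn_spec()].
#' @param verbose print per-epoch loss.
#' @return An object of class `pd_cnn` (weights, architecture report,
#'   channel normalization, training history).
#' @export
pd_cnn <- function(x, y, spec = cnn_spec(), verbose = FALSE) {
  stopifnot(length(dim(x)) == 3)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("training requires both classes", call. = FALSE)
  }
  if (dim(x)[1] != length(y)) stop("x/y length mismatch", call. = FALSE)
  n <- dim(x)[1]
  t_len <- dim(x)[2]
  n_ch <- dim(x)[3]
  arch <- build_cnn(spec, t_len, n_ch)

  mu <- apply(x, 3, mean)
  sg <- pmax(apply(x, 3, sd), 1e-8)
  for (c in seq_len(n_ch)) x[, , c] <- (x[, , c] - mu[c]) / sg[c]

  tab <- table(factor(y, levels = c(0, 1)))
  cw <- as.numeric(n / (2 * pmax(tab, 1)))

  set.seed(spec$seed)
  params <- list()
  ch <- n_ch
  for (i in seq_along(spec$conv_kernels)) {
    k <- spec$conv_kernels[i]
    f <- spec$conv_filters[i]
    params[[paste0("W", i)]] <- matrix(rnorm(k * ch * f, 0,
                                             sqrt(2 / (k * ch))), k * ch, f)
    params[[paste0("b", i)]] <- numeric(f)
    ch <- f
  }
  tq <- t_len
  for (p in spec$pool_sizes) tq <- tq %/% p
  flat <- tq * ch
  in_w <- flat
  for (i in seq_along(spec$dense_units)) {
    u <- spec$dense_units[i]
    params[[paste0("Wd", i)]] <- matrix(rnorm(in_w * u, 0, sqrt(2 / in_w)),
                                        in_w, u)
    params[[paste0("bd", i)]] <- numeric(u)
    in_w <- u
  }
  params$Wo <- matrix(rnorm(in_w * spec$n_classes, 0, sqrt(2 / in_w)),
                      in_w, spec$n_classes)
  params$bo <- numeric(spec$n_classes)

  state <- adam_init(params)
  step <- 0L
  history <- numeric(spec$epochs)
  for (ep in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    n_batches <- 0L
    for (bs in seq.int(1L, n, by = spec$batch_size)) {
      idx <- ord[bs:min(bs + spec$batch_size - 1L, n)]
      xb <- x[idx, , , drop = FALSE]
      yb <- y[idx]
      wts <- cw[yb + 1L]
      masks <- NULL
      if (spec$dropout > 0) {
        masks <- lapply(spec$dense_units, function(u) {
          matrix(
            (runif(length(idx) * u) > spec$dropout) / (1 - spec$dropout),
            length(idx), u)
        })
      }
      fw <- cnn_forward(params, xb, spec, training = TRUE,
                        dropout_masks = masks)
      pl <- fw$probs[cbind(seq_along(idx), yb + 1L)]
      ep_loss <- ep_loss + sum(-wts * log(pmax(pl, 1e-12))) / sum(wts)
      n_batches <- n_batches + 1L
      grads <- cnn_backward(params, fw, yb, wts, spec, xb)
      step <- step + 1L
      upd <- adam_step(params, grads, state, spec$learning_rate, step)
      params <- upd$params
      state <- upd$state
    }
    history[ep] <- ep_loss / n_batches
    if (verbose) message(sprintf("epoch %d/%d loss %.4f", ep, spec$epochs,
                                 history[ep]))
  }

  structure(list(weights = params, spec = spec, arch = arch,
                 norm = list(mu = mu, sd = sg),
                 input_shape = c(samples = t_len, channels = n_ch),
                 class_counts = as.integer(tab), history = history),
            class = "pd_cnn")
}

#' Predict symptom probabilities from a fitted network
#'
#' @param object a [pd_cnn()] fit.
#' @param newdata clip array `clips x samples x channels` matching the
#'   training shape, or a list of clip matrices.
#' @param type `"prob"` (default) for the probability of the symptom-present
#'   class, `"matrix"` for the full softmax matrix.
#' @param ... ignored.
#' @return Numeric vector (or matrix) of class probabilities in input order.
#' @export
predict.pd_cnn <- function(object, newdata, type = c("prob", "matrix"), ...) {
  type <- match.arg(type)
  if (is.list(newdata) && !is.array(newdata)) {
    arr <- array(0, c(length(newdata), dim(newdata[[1]])))
    for (i in seq_along(newdata)) arr[i, , ] <- newdata[[i]]
    newdata <- arr
  }
  if (length(dim(newdata)) != 3 ||
      !all(dim(newdata)[2:3] == object$input_shape)) {
    stop("input shape mismatch with the trained network", call. = FALSE)
  }
  for (c in seq_len(dim(newdata)[3])) {
    newdata[, , c] <- (newdata[, , c] - object$norm$mu[c]) / object$norm$sd[c]
  }
  n <- dim(newdata)[1]
  out <- matrix(0, n, object$spec$n_classes)
  for (bs in seq.int(1L, n, by = 256L)) {
    idx <- bs:min(bs + 255L, n)
    fw <- cnn_forward(object$weights, newdata[idx, , , drop = FALSE],
                      object$spec, training = FALSE)
    out[idx, ] <- fw$probs
  }
  if (type == "prob") out[, 2] else out
}

#' @export
print.pd_cnn <- function(x, ...) {
  cat(sprintf("<pd_cnn> input %d x %d | %d parameters | %d epochs, final loss %.4f\n",
              x$input_shape[1], x$input_shape[2], x$arch$total_params,
              x$spec$epochs, tail(x$history, 1)))
  invisible(x)
}
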