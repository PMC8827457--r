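#' U-Net configuration
#'
#' Encoder-decoder with skip connections: `depth` downsampling levels of two
#' 3x3 convolutions each (batch normalization + ReLU after every
#' convolution), 2x2 max-pooling between levels, a two-convolution
#' bottleneck, 2x2 stride-2 up-convolutions on the expansive path (filters
#' doubled after each downsampling and halved after each upsampling), He
#' weight initialization, and a sigmoid-activated 1x1 output convolution.
#' At the default depth 4 the network has exactly 23 convolutional layers
#' (up-convolutions counted as convolutional).
#'
#' @param input_size `c(H, W)`, must be divisible by `2^depth`.
#' @param depth number of downsampling levels (default 4).
#' @param base_filters filters at the first level (default 64).
#' @param batch_size frames per optimization step (default 16).
#' @param epochs training epochs (head segmentation default 20; use 40 for
#'   the placenta, whose texture converges more slowly).
#' @param learning_rate Adam step size.
#' @param seed seed controlling initialization and shuffling.
#' @return A `unet_config`.
#' @export
unet_config <- function(input_size = c(128, 128), depth = 4, base_filters = 64,
                        batch_size = 16, epochs = 20, learning_rate = 1e-3,
                        seed = 1L) {
  if (any(input_size %% 2^depth != 0))
    stop_field("input_size", sprintf("must be divisible by 2^depth = %d", 2^depth))
  if (batch_size < 1) stop_field("batch_size", "must be at least 1")
  if (epochs < 1) stop_field("epochs", "must be at least 1")
  structure(list(input_size = as.integer(input_size), depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "unet_config")
}

#' Enumerate the convolutional layers of a U-Net configuration
#'
#' @param config a [unet_config()].
#' @return data.frame with one row per convolutional layer (up-convolutions
#'   included): name, kind, input and output channels.
#' @export
unet_layers <- function(config) {
  d <- config$depth; bf <- config$base_filters
  filt <- bf * 2^(seq_len(d + 1) - 1)   # filters at levels 1..d and bottleneck
  rows <- list()
  add <- function(name, kind, cin, cout)
    rows[[length(rows) + 1L]] <<- data.frame(name = name, kind = kind,
                                             c_in = cin, c_out = cout)
  for (l in seq_len(d)) {
    cin <- if (l == 1) 1L else filt[l - 1]
    add(sprintf("e%dc1", l), "conv3x3", cin, filt[l])
    add(sprintf("e%dc2", l), "conv3x3", filt[l], filt[l])
  }
  add("bc1", "conv3x3", filt[d], filt[d + 1])
  add("bc2", "conv3x3", filt[d + 1], filt[d + 1])
  for (l in rev(seq_len(d))) {
    add(sprintf("u%d", l), "upconv2x2", filt[l + 1], filt[l])
    add(sprintf("d%dc1", l), "conv3x3", 2L * filt[l], filt[l])
    add(sprintf("d%dc2", l), "conv3x3", filt[l], filt[l])
  }
  add("out", "conv1x1", filt[1], 1L)
  do.call(rbind, rows)
}

new_bn <- function(f) list(gamma = rep(1, f), beta = rep(0, f),
                           rm = rep(0, f), rv = rep(1, f))

#' Build an untrained U-Net model
#'
#' He-initialized weights; all batch-normalization scales start at 1,
#' shifts at 0, running statistics at (0, 1).
#'
#' @param config a [unet_config()].
#' @return A `unet_model` with fields `config`, `params`, `history`.
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  layers <- unet_layers(config)
  params <- list()
  with_seed(config$seed, {
    for (i in seq_len(nrow(layers))) {
      ly <- layers[i, ]
      if (ly$kind == "conv3x3") {
        fan <- 9L * ly$c_in
        params[[ly$name]] <- list(
          W = matrix(rnorm(fan * ly$c_out, sd = sqrt(2 / fan)), fan, ly$c_out),
          b = rep(0, ly$c_out), bn = new_bn(ly$c_out))
      } else if (ly$kind == "upconv2x2") {
        params[[ly$name]] <- list(
          W = array(rnorm(ly$c_in * 4L * ly$c_out, sd = sqrt(2 / ly$c_in)),
                    dim = c(ly$c_in, 4L, ly$c_out)),
          b = rep(0, ly$c_out), bn = new_bn(ly$c_out))
      } else { # 1x1 output conv, no batch norm (sigmoid head)
        params[[ly$name]] <- list(
          W = matrix(rnorm(ly$c_in, sd = sqrt(2 / ly$c_in)), ly$c_in, 1L),
          b = 0)
      }
    }
  })
  structure(list(config = config, params = params, history = NULL),
            class = "unet_model")
}

# ---- tensor ops on [H, W, C, N] arrays -------------------------------------
# Batch normalization and ReLU are fused in compiled code (bnrelu_fw/bw).

maxpool_fw <- function(x) {
  dm <- dim(x)
  i1 <- seq(1, dm[1], by = 2); i2 <- i1 + 1
  j1 <- seq(1, dm[2], by = 2); j2 <- j1 + 1
  a <- x[i1, j1, , , drop = FALSE]; b <- x[i2, j1, , , drop = FALSE]
  cc <- x[i1, j2, , , drop = FALSE]; d <- x[i2, j2, , , drop = FALSE]
  y <- pmax(a, b, cc, d)
  # deterministic routing: first maximum in order a, b, c, d
  ma <- a == y
  mb <- !ma & b == y
  mc <- !ma & !mb & cc == y
  md <- !(ma | mb | mc)
  list(y = y, masks = list(ma, mb, mc, md), in_dim = dm)
}

maxpool_bw <- function(cache, dy) {
  dm <- cache$in_dim
  i1 <- seq(1, dm[1], by = 2); i2 <- i1 + 1
  j1 <- seq(1, dm[2], by = 2); j2 <- j1 + 1
  dx <- array(0, dm)
  dx[i1, j1, , ] <- dy * cache$masks[[1]]
  dx[i2, j1, , ] <- dy * cache$masks[[2]]
  dx[i1, j2, , ] <- dy * cache$masks[[3]]
  dx[i2, j2, , ] <- dy * cache$masks[[4]]
  dx
}

# 2x2 stride-2 transposed convolution. W: array (Cin, 4, Cout); quadrant
# order 1 = (odd row, odd col), 2 = (even, odd), 3 = (odd, even), 4 = (even,
# even) of the output lattice.
upconv_fw <- function(x, W, b) {
  dm <- dim(x); H <- dm[1]; Wd <- dm[2]; C <- dm[3]; N <- dm[4]
  Fo <- dim(W)[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)       # (H*W*N) x C
  Z <- xm %*% matrix(W, nrow = C)                        # (H*W*N) x (4*Fo)
  dim(Z) <- c(H, Wd, N, 4L, Fo)
  y <- array(0, c(2L * H, 2L * Wd, Fo, N))
  ro <- seq(1, 2 * H, by = 2); co <- seq(1, 2 * Wd, by = 2)
  quad <- function(q) {
    s <- Z[, , , q, , drop = FALSE]
    dim(s) <- c(H, Wd, N, Fo)
    aperm(s, c(1, 2, 4, 3))
  }
  y[ro, co, , ]         <- quad(1L)
  y[ro + 1, co, , ]     <- quad(2L)
  y[ro, co + 1, , ]     <- quad(3L)
  y[ro + 1, co + 1, , ] <- quad(4L)
  y <- y + rep(rep(b, times = N), each = 4L * H * Wd)
  y
}

upconv_bw <- function(x, W, dy) {
  dm <- dim(x); H <- dm[1]; Wd <- dm[2]; C <- dm[3]; N <- dm[4]
  Fo <- dim(W)[3]
  ro <- seq(1, 2 * H, by = 2); co <- seq(1, 2 * Wd, by = 2)
  grab <- function(ri, ci)
    matrix(aperm(dy[ri, ci, , , drop = FALSE], c(1, 2, 4, 3)), ncol = Fo)
  dZ <- cbind(grab(ro, co), grab(ro + 1, co), grab(ro, co + 1), grab(ro + 1, co + 1))
  # cbind gives column order (q, then f); the weight matrix layout is
  # (f, then q) i.e. column (f-1)*4+q, so permute accordingly
  qf <- as.vector(t(matrix(seq_len(4L * Fo), nrow = Fo)))
  dZ <- dZ[, qf, drop = FALSE]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)
  dW <- crossprod(xm, dZ)                    # C x (4*Fo)
  dim(dW) <- c(C, 4L, Fo)
  db <- vapply(seq_len(Fo), function(f) sum(dy[, , f, ]), numeric(1))
  dxm <- dZ %*% t(matrix(W, nrow = C))       # (H*W*N) x C
  dx <- aperm(array(dxm, c(H, Wd, N, C)), c(1, 2, 4, 3))
  list(dx = dx, dW = dW, db = db)
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  y
}

conv1x1_fw <- function(x, W, b) {
  dm <- dim(x); C <- dm[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)
  z <- xm %*% W + b
  aperm(array(z, c(dm[1], dm[2], dm[4], 1L)), c(1, 2, 4, 3))
}

conv1x1_bw <- function(x, W, dy) {
  dm <- dim(x); C <- dm[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = 1L)
  dW <- crossprod(xm, dym)
  db <- sum(dym)
  dxm <- dym %*% t(W)
  dx <- aperm(array(dxm, c(dm[1], dm[2], dm[4], C)), c(1, 2, 4, 3))
  list(dx = dx, dW = dW, db = db)
}

# conv3x3 + BN + ReLU block
cbr_fw <- function(x, p, train) {
  z <- conv3x3_fw(x, p$W, p$b, dim(x))
  r <- bnrelu_fw(z, p$bn$gamma, p$bn$beta, dim(z), train, p$bn$rm, p$bn$rv)
  cache <- if (train) list(x = x, z = z, mu = r$mu, var = r$var, mask = r$mask)
  list(y = r$y, cache = cache,
       stats = if (train) list(mu = r$mu, var = r$var))
}

cbr_bw <- function(cache, p, dy) {
  bn <- bnrelu_bw(cache$z, dy, cache$mask, cache$mu, cache$var, p$bn$gamma,
                  dim(cache$z))
  cv <- conv3x3_bw(cache$x, p$W, bn$dz, dim(cache$x))
  list(dx = cv$dx, grads = list(W = cv$dW, b = cv$db,
                                gamma = bn$dgamma, beta = bn$dbeta))
}

# 2x2 up-convolution + BN + ReLU block
ubr_fw <- function(x, p, train) {
  z <- upconv_fw(x, p$W, p$b)
  r <- bnrelu_fw(z, p$bn$gamma, p$bn$beta, dim(z), train, p$bn$rm, p$bn$rv)
  cache <- if (train) list(x = x, z = z, mu = r$mu, var = r$var, mask = r$mask)
  list(y = r$y, cache = cache,
       stats = if (train) list(mu = r$mu, var = r$var))
}

ubr_bw <- function(cache, p, dy) {
  bn <- bnrelu_bw(cache$z, dy, cache$mask, cache$mu, cache$var, p$bn$gamma,
                  dim(cache$z))
  uv <- upconv_bw(cache$x, p$W, bn$dz)
  list(dx = uv$dx, grads = list(W = uv$dW, b = uv$db,
                                gamma = bn$dgamma, beta = bn$dbeta))
}

# Full forward pass. Returns logits; in train mode also caches and the batch
# statistics of every BN layer (for the running-average update).
unet_forward <- function(model, x, train = FALSE) {
  d <- model$config$depth
  p <- model$params
  caches <- list(); stats <- list()
  skips <- list()
  h <- x
  for (l in seq_len(d)) {
    for (k in 1:2) {
      nm <- sprintf("e%dc%d", l, k)
      r <- cbr_fw(h, p[[nm]], train)
      h <- r$y; caches[[nm]] <- r$cache; stats[[nm]] <- r$stats
    }
    skips[[l]] <- h
    r <- maxpool_fw(h)
    caches[[sprintf("pool%d", l)]] <- if (train) r else list(in_dim = r$in_dim)
    h <- r$y
  }
  for (nm in c("bc1", "bc2")) {
    r <- cbr_fw(h, p[[nm]], train)
    h <- r$y; caches[[nm]] <- r$cache; stats[[nm]] <- r$stats
  }
  for (l in rev(seq_len(d))) {
    nm <- sprintf("u%d", l)
    r <- ubr_fw(h, p[[nm]], train)
    h <- r$y; caches[[nm]] <- r$cache; stats[[nm]] <- r$stats
    caches[[sprintf("skipdim%d", l)]] <- dim(r$y)
    h <- concat_channels(h, skips[[l]])
    for (k in 1:2) {
      nm <- sprintf("d%dc%d", l, k)
      r <- cbr_fw(h, p[[nm]], train)
      h <- r$y; caches[[nm]] <- r$cache; stats[[nm]] <- r$stats
    }
  }
  z <- conv1x1_fw(h, p$out$W, p$out$b)
  if (train) caches$out_x <- h
  list(logits = z, caches = caches, stats = stats)
}

# Backward pass from d(loss)/d(logits); returns gradients per parameter.
unet_backward <- function(model, fw, dz) {
  d <- model$config$depth
  p <- model$params
  caches <- fw$caches
  grads <- list()
  r <- conv1x1_bw(caches$out_x, p$out$W, dz)
  grads$out <- list(W = r$dW, b = r$db)
  dh <- r$dx
  dskips <- list()
  for (l in seq_len(d)) {
    for (k in 2:1) {
      nm <- sprintf("d%dc%d", l, k)
      r <- cbr_bw(caches[[nm]], p[[nm]], dh)
      grads[[nm]] <- r$grads; dh <- r$dx
    }
    # split concat: first block came from the up-conv, second from the skip
    fdim <- caches[[sprintf("skipdim%d", l)]]
    Cu <- fdim[3]
    dup <- dh[, , seq_len(Cu), , drop = FALSE]
    dskips[[l]] <- dh[, , Cu + seq_len(dim(dh)[3] - Cu), , drop = FALSE]
    nm <- sprintf("u%d", l)
    r <- ubr_bw(caches[[nm]], p[[nm]], dup)
    grads[[nm]] <- r$grads; dh <- r$dx
  }
  for (nm in c("bc2", "bc1")) {
    r <- cbr_bw(caches[[nm]], p[[nm]], dh)
    grads[[nm]] <- r$grads; dh <- r$dx
  }
  for (l in rev(seq_len(d))) {
    dh <- maxpool_bw(caches[[sprintf("pool%d", l)]], dh)
    dh <- dh + dskips[[l]]
    for (k in 2:1) {
      nm <- sprintf("e%dc%d", l, k)
      r <- cbr_bw(caches[[nm]], p[[nm]], dh)
      grads[[nm]] <- r$grads; dh <- r$dx
    }
  }
  grads
}

update_running_stats <- function(model, stats, momentum = 0.9) {
  for (nm in names(stats)) {
    if (is.null(stats[[nm]])) next
    bn <- model$params[[nm]]$bn
    bn$rm <- momentum * bn$rm + (1 - momentum) * stats[[nm]]$mu
    bn$rv <- momentum * bn$rv + (1 - momentum) * stats[[nm]]$var
    model$params[[nm]]$bn <- bn
  }
  model
}

# Sigmoid-BCE loss and its gradient w.r.t. logits (mean over all pixels).
bce_loss <- function(logits, targets) {
  # stable: softplus(z) - y z, with softplus via log1p(exp(-|z|)) + max(z, 0)
  sp <- pmax(logits, 0) + log1p(exp(-abs(logits)))
  mean(sp - targets * logits)
}

bce_grad <- function(logits, targets) {
  (stats::plogis(logits) - targets) / length(logits)
}

adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

# One Adam step over the nested parameter/gradient lists. Gradients cover
# W/b (+ gamma/beta for BN layers); running stats are untouched.
adam_step <- function(model, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    slots <- names(g)
    for (s in slots) {
      tgt <- if (s %in% c("gamma", "beta")) c("bn", s) else s
      cur <- if (length(tgt) == 2) model$params[[nm]][["bn"]][[s]] else model$params[[nm]][[s]]
      mg <- opt$m[[nm]][[s]] %||% (g[[s]] * 0)
      vg <- opt$v[[nm]][[s]] %||% (g[[s]] * 0)
      mg <- beta1 * mg + (1 - beta1) * g[[s]]
      vg <- beta2 * vg + (1 - beta2) * g[[s]]^2
      opt$m[[nm]][[s]] <- mg
      opt$v[[nm]][[s]] <- vg
      step <- lr * (mg / bc1) / (sqrt(vg / bc2) + eps)
      cur <- cur - step
      if (length(tgt) == 2) model$params[[nm]][["bn"]][[s]] <- cur
      else model$params[[nm]][[s]] <- cur
    }
  }
  list(model = model, opt = opt)
}

frames_to_tensor <- function(frames, input_size) {
  N <- length(frames)
  x <- array(0, c(input_size[1], input_size[2], 1L, N))
  for (i in seq_len(N)) {
    f <- frames[[i]]
    m <- if (is.list(f)) f$pixels else f
    if (!all(dim(m) == input_size))
      stop("frame size does not match the network input size", call. = FALSE)
    x[, , 1L, i] <- m
  }
  x
}

masks_to_tensor <- function(masks, input_size) {
  N <- length(masks)
  y <- array(0, c(input_size[1], input_size[2], 1L, N))
  for (i in seq_len(N)) y[, , 1L, i] <- masks[[i]] * 1
  y
}

# Pixel-global Dice and Jaccard over a set of predicted/true mask tensors.
overlap_scores <- function(pred, truth) {
  inter <- sum(pred & truth)
  ps <- sum(pred); ts <- sum(truth)
  if (ps + ts == 0) return(c(dice = 1, jaccard = 1))
  dice <- 2 * inter / (ps + ts)
  jac <- inter / (ps + ts - inter)
  c(dice = dice, jaccard = jac)
}

#' Train a U-Net segmenter
#'
#' Trains with Adam on the binary cross-entropy loss; Dice and Jaccard are
#' monitored per epoch on the training and validation splits. 80% of the
#' structure-present frames form the training positives and 20% the
#' validation set (seeded); structure-absent frames all join the training
#' split. Images are shuffled every epoch.
#'
#' @param dataset a `vsi_dataset` (see [gen_training_set()]).
#' @param config a [unet_config()].
#' @param structure `"head"` or `"placenta"`.
#' @param verbose print one line per epoch.
#' @return A trained `unet_model`; `$history` holds per-epoch loss, Dice and
#'   Jaccard for both splits, `$split` the frame indices used.
#' @export
train_segmenter <- function(dataset, config, structure = c("head", "placenta"),
                            verbose = FALSE) {
  structure <- match.arg(structure)
  stopifnot(inherits(config, "unet_config"))
  n <- length(dataset$frames)
  if (n == 0) stop("empty dataset", call. = FALSE)
  present <- dataset[[paste0(structure, "_present")]]
  masks <- dataset[[paste0(structure, "_masks")]]
  pos <- which(present)
  split <- with_seed(derive_seed(config$seed, 7L), {
    if (length(pos) > 0) {
      val <- sort(sample(pos, max(1L, round(0.2 * length(pos)))))
      train <- setdiff(seq_len(n), val)
      list(train = train, val = val)
    } else {
      val <- sort(sample(seq_len(n), max(1L, round(0.2 * n))))
      list(train = setdiff(seq_len(n), val), val = val)
    }
  })
  isz <- config$input_size
  x_train <- frames_to_tensor(dataset$frames[split$train], isz)
  y_train <- masks_to_tensor(masks[split$train], isz)
  x_val <- frames_to_tensor(dataset$frames[split$val], isz)
  y_val <- masks_to_tensor(masks[split$val], isz)
  ntr <- length(split$train)

  model <- build_unet(config)
  opt <- adam_init(model$params)
  hist <- NULL
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, 100L + epoch), sample(ntr))
    ep_loss <- 0; nb <- 0L
    for (start in seq(1, ntr, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, ntr)]
      xb <- x_train[, , , idx, drop = FALSE]
      yb <- y_train[, , , idx, drop = FALSE]
      fw <- unet_forward(model, xb, train = TRUE)
      loss <- bce_loss(fw$logits, yb)
      if (!is.finite(loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
             call. = FALSE)
      model <- update_running_stats(model, fw$stats)
      grads <- unet_backward(model, fw, bce_grad(fw$logits, yb))
      upd <- adam_step(model, grads, opt, config$learning_rate)
      model <- upd$model; opt <- upd$opt
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    tr_sub <- seq_len(min(ntr, 64L))  # bound the per-epoch monitoring cost
    tr_eval <- evaluate_tensor(model, x_train[, , , tr_sub, drop = FALSE],
                               y_train[, , , tr_sub, drop = FALSE])
    va_eval <- evaluate_tensor(model, x_val, y_val)
    hist <- rbind(hist, data.frame(
      epoch = epoch, train_loss = ep_loss / nb,
      train_dice = tr_eval["dice"], train_jaccard = tr_eval["jaccard"],
      val_loss = va_eval["loss"], val_dice = va_eval["dice"],
      val_jaccard = va_eval["jaccard"], row.names = NULL))
    if (verbose)
      message(sprintf("epoch %2d  loss %.4f  val dice %.4f",
                      epoch, ep_loss / nb, va_eval["dice"]))
  }
  model$history <- hist
  model$split <- split
  model$structure <- structure
  model
}

# Batched inference; returns loss/dice/jaccard against targets.
evaluate_tensor <- function(model, x, y, batch = 16L, threshold = 0.5) {
  N <- dim(x)[4]
  loss <- 0
  inter <- 0; psum <- 0; tsum <- 0
  for (start in seq(1, N, by = batch)) {
    idx <- start:min(start + batch - 1L, N)
    fw <- unet_forward(model, x[, , , idx, drop = FALSE], train = FALSE)
    yb <- y[, , , idx, drop = FALSE]
    loss <- loss + bce_loss(fw$logits, yb) * length(idx)
    pb <- stats::plogis(fw$logits) >= threshold
    inter <- inter + sum(pb & (yb > 0.5))
    psum <- psum + sum(pb); tsum <- tsum + sum(yb > 0.5)
  }
  dice <- if (psum + tsum == 0) 1 else 2 * inter / (psum + tsum)
  jac <- if (psum + tsum == 0) 1 else inter / (psum + tsum - inter)
  c(loss = loss / N, dice = dice, jaccard = jac)
}

#' Predict a segmentation mask for one frame
#'
#' Generic over segmenter types: trained U-Net models and the ground-truth
#' oracle segmenter share this contract.
#'
#' @param model a segmenter (`unet_model` or `oracle_segmenter`).
#' @param frame matrix or frame list (`pixels` + identity fields).
#' @param threshold binarization threshold on the sigmoid probability map
#'   (default 0.5, the sigmoid midpoint).
#' @param ... unused.
#' @return list(prob = probability map, mask = logical matrix).
#' @export
predict_mask <- function(model, frame, threshold = 0.5, ...) {
  UseMethod("predict_mask")
}

#' @rdname predict_mask
#' @export
predict_mask.unet_model <- function(model, frame, threshold = 0.5, ...) {
  x <- frames_to_tensor(list(frame), model$config$input_size)
  fw <- unet_forward(model, x, train = FALSE)
  prob <- stats::plogis(fw$logits[, , 1L, 1L])
  list(prob = prob, mask = prob >= threshold)
}

#' Ground-truth oracle segmenter
#'
#' Satisfies the [predict_mask()] contract by returning the phantom's true
#' mask for the requested structure, keyed on the frame's `sweep_id` and
#' `frame_index`. Used to test every pipeline stage downstream of
#' segmentation in isolation.
#'
#' @param truth a `phantom_truth`.
#' @param structure `"head"` or `"placenta"`.
#' @return An `oracle_segmenter`.
#' @export
oracle_segmenter <- function(truth, structure = c("head", "placenta")) {
  structure <- match.arg(structure)
  structure(list(masks = truth$masks[[structure]], structure = structure),
            class = "oracle_segmenter")
}

#' @rdname predict_mask
#' @export
predict_mask.oracle_segmenter <- function(model, frame, threshold = 0.5, ...) {
  if (is.null(frame$sweep_id))
    stop("oracle segmenter needs frames carrying sweep_id/frame_index",
         call. = FALSE)
  m <- model$masks[[frame$sweep_id]][[frame$frame_index + 1L]]
  list(prob = m * 1, mask = if (threshold > 1) m & FALSE else m != 0)
}

#' Save / load a trained segmenter
#'
#' Weights go to an opaque binary file, the configuration to a JSON sidecar
#' next to it.
#'
#' @param model a `unet_model`.
#' @param path file path for the weights (sidecar gets `.json` appended).
#' @return `save_model`: the path, invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model[c("params", "history", "structure")], path)
  cfgpath <- paste0(path, ".json")
  jsonlite::write_json(unclass(model$config), cfgpath, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  blob <- readRDS(path)
  cfg <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  config <- unet_config(input_size = cfg$input_size, depth = cfg$depth,
                        base_filters = cfg$base_filters,
                        batch_size = cfg$batch_size, epochs = cfg$epochs,
                        learning_rate = cfg$learning_rate, seed = cfg$seed)
  structure(list(config = config, params = blob$params,
                 history = blob$history, structure = blob$structure),
            class = "unet_model")
}
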