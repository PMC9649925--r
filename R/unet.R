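## A compact 2D U-Net implemented natively in R: im2col 3x3 convolutions,
## 2x2 max pooling with recorded argmax, nearest-neighbour upsampling with
## skip concatenation, sigmoid output, and a combined binary cross-entropy
## + soft-DICE loss optimised with Adam. Activations are kept as (H*W) x C
## matrices; all spatial index maps are precomputed per slice shape. Sized
## for CPU training on phantom slices in seconds to minutes.

.geom_cache <- new.env(parent = emptyenv())

geom_key <- function(h, w) paste0(h, "x", w)

## 3x3 im2col indices into the zero-padded (h+2) x (w+2) plane.
im2col_idx <- function(h, w) {
  key <- paste0("conv", geom_key(h, w))
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  i <- rep(seq_len(h), times = w)
  j <- rep(seq_len(w), each = h)
  idx <- matrix(0L, h * w, 9L)
  k <- 0L
  for (dj in -1:1) for (di in -1:1) {
    k <- k + 1L
    idx[, k] <- (i + di + 1L) + (j + dj) * (h + 2L)
  }
  .geom_cache[[key]] <- idx
  idx
}

## 2x2 pooling candidate indices: one row per block, 4 linear indices.
pool_idx <- function(h, w) {
  key <- paste0("pool", geom_key(h, w))
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  bi <- rep(seq_len(h / 2L), times = w / 2L)
  bj <- rep(seq_len(w / 2L), each = h / 2L)
  lin <- function(i, j) i + (j - 1L) * h
  idx <- cbind(lin(2L * bi - 1L, 2L * bj - 1L), lin(2L * bi, 2L * bj - 1L),
               lin(2L * bi - 1L, 2L * bj), lin(2L * bi, 2L * bj))
  .geom_cache[[key]] <- idx
  idx
}

## Nearest-neighbour 2x upsampling map: output pixel -> source pixel.
upsample_idx <- function(h, w) {
  key <- paste0("up", geom_key(h, w))
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  i <- rep(seq_len(2L * h), times = 2L * w)
  j <- rep(seq_len(2L * w), each = 2L * h)
  .geom_cache[[key]] <- ceiling(i / 2) + (ceiling(j / 2) - 1L) * h
  .geom_cache[[key]]
}

conv3_forward <- function(x, h, w, W, b, relu = TRUE) {
  cin <- ncol(x)
  padded <- matrix(0, (h + 2L) * (w + 2L), cin)
  core <- as.vector(outer(seq_len(h) + 1L, (seq_len(w)) * (h + 2L), "+"))
  padded[core, ] <- x
  idx <- im2col_idx(h, w)
  cols <- matrix(0, h * w, 9L * cin)
  for (c in seq_len(cin)) {
    cols[, (c - 1L) * 9L + (1:9)] <- padded[, c][idx]
  }
  z <- cols %*% W + rep(b, each = h * w)
  a <- if (relu) pmax(z, 0) else z
  list(a = a, z = z, cols = cols, relu = relu)
}

conv3_backward <- function(da, cache, W, h, w) {
  dz <- if (cache$relu) da * (cache$z > 0) else da
  dW <- crossprod(cache$cols, dz)
  db <- colSums(dz)
  dcols <- dz %*% t(W)
  cin <- nrow(W) / 9L
  idx <- im2col_idx(h, w)
  core <- as.vector(outer(seq_len(h) + 1L, (seq_len(w)) * (h + 2L), "+"))
  dx <- matrix(0, h * w, cin)
  for (c in seq_len(cin)) {
    dpad <- numeric((h + 2L) * (w + 2L))
    for (k in 1:9) {
      ii <- idx[, k]
      dpad[ii] <- dpad[ii] + dcols[, (c - 1L) * 9L + k]
    }
    dx[, c] <- dpad[core]
  }
  list(dx = dx, dW = dW, db = db)
}

pool_forward <- function(x, h, w) {
  idx <- pool_idx(h, w)
  nb <- nrow(idx)
  cc <- ncol(x)
  out <- matrix(0, nb, cc)
  sel <- matrix(0L, nb, cc)
  for (c in seq_len(cc)) {
    cand <- matrix(x[, c][idx], nb, 4L)
    am <- max.col(cand, ties.method = "first")
    out[, c] <- cand[cbind(seq_len(nb), am)]
    sel[, c] <- idx[cbind(seq_len(nb), am)]
  }
  list(out = out, sel = sel, n_in = h * w)
}

pool_backward <- function(dout, cache) {
  dx <- matrix(0, cache$n_in, ncol(dout))
  for (c in seq_len(ncol(dout))) {
    dx[cache$sel[, c], c] <- dout[, c]
  }
  dx
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

#' U-Net segmenter configuration
#'
#' @param depth number of resolution levels (>= 1; default 3). Slice height
#'   and width must be divisible by `2^(depth - 1)`.
#' @param base_channels channels at the top level (doubled per level).
#' @param epochs training epochs.
#' @param learning_rate Adam step size.
#' @param threshold probability cut for binarising predictions.
#' @param bce_weight,dice_weight loss mixing weights (binary cross-entropy
#'   and soft DICE).
#' @param seed RNG seed for initialisation and slice shuffling.
#' @return object of class `seg_config`.
#' @export
seg_config <- function(depth = 3L, base_channels = 16L, epochs = 30L,
                       learning_rate = 1e-3, threshold = 0.5,
                       bce_weight = 0.5, dice_weight = 0.5, seed = 1L) {
  if (depth < 1L) stop("depth must be >= 1")
  structure(list(depth = as.integer(depth), base_channels = as.integer(base_channels),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 threshold = threshold, bce_weight = bce_weight,
                 dice_weight = dice_weight, seed = as.integer(seed)),
            class = "seg_config")
}

unet_init_params <- function(depth, base) {
  p <- list()
  cin <- 1L
  for (i in seq_len(depth - 1L)) {
    cc <- base * 2L^(i - 1L)
    p[[paste0("enc", i, "a")]] <- list(W = glorot(9L * cin, cc), b = rep(0.01, cc))
    p[[paste0("enc", i, "b")]] <- list(W = glorot(9L * cc, cc), b = rep(0.01, cc))
    cin <- cc
  }
  cb <- base * 2L^(depth - 1L)
  p[["botta"]] <- list(W = glorot(9L * cin, cb), b = rep(0.01, cb))
  p[["bottb"]] <- list(W = glorot(9L * cb, cb), b = rep(0.01, cb))
  cup <- cb
  for (i in rev(seq_len(depth - 1L))) {
    cc <- base * 2L^(i - 1L)
    p[[paste0("dec", i, "a")]] <- list(W = glorot(9L * (cup + cc), cc), b = rep(0.01, cc))
    p[[paste0("dec", i, "b")]] <- list(W = glorot(9L * cc, cc), b = rep(0.01, cc))
    cup <- cc
  }
  p[["out"]] <- list(W = glorot(cup, 1L), b = 0)
  p
}

## Full forward pass on one slice; returns per-pixel probabilities and, if
## `train`, the caches needed for backprop.
unet_forward <- function(params, x, h, w, depth, train = FALSE) {
  caches <- list()
  dims <- list()
  skips <- list()
  a <- x
  hh <- h; ww <- w
  for (i in seq_len(depth - 1L)) {
    c1 <- conv3_forward(a, hh, ww, params[[paste0("enc", i, "a")]]$W,
                        params[[paste0("enc", i, "a")]]$b)
    c2 <- conv3_forward(c1$a, hh, ww, params[[paste0("enc", i, "b")]]$W,
                        params[[paste0("enc", i, "b")]]$b)
    pl <- pool_forward(c2$a, hh, ww)
    if (train) caches[[paste0("enc", i)]] <- list(c1 = c1, c2 = c2, pl = pl)
    skips[[i]] <- c2$a
    dims[[i]] <- c(hh, ww)
    a <- pl$out
    hh <- hh %/% 2L; ww <- ww %/% 2L
  }
  b1 <- conv3_forward(a, hh, ww, params$botta$W, params$botta$b)
  b2 <- conv3_forward(b1$a, hh, ww, params$bottb$W, params$bottb$b)
  if (train) caches$bott <- list(c1 = b1, c2 = b2, dims = c(hh, ww))
  a <- b2$a
  for (i in rev(seq_len(depth - 1L))) {
    up <- a[upsample_idx(hh, ww), , drop = FALSE]
    hh <- hh * 2L; ww <- ww * 2L
    cat_in <- cbind(up, skips[[i]])
    d1 <- conv3_forward(cat_in, hh, ww, params[[paste0("dec", i, "a")]]$W,
                        params[[paste0("dec", i, "a")]]$b)
    d2 <- conv3_forward(d1$a, hh, ww, params[[paste0("dec", i, "b")]]$W,
                        params[[paste0("dec", i, "b")]]$b)
    if (train) caches[[paste0("dec", i)]] <- list(d1 = d1, d2 = d2, n_up = ncol(up))
    a <- d2$a
  }
  z <- as.vector(a %*% params$out$W) + params$out$b
  prob <- plogis(z)
  list(prob = prob, z = z, a_last = a, caches = caches, dims = dims,
       bott_dims = if (train) caches$bott$dims else NULL)
}

## Backward pass; returns gradient list parallel to params.
unet_backward <- function(params, fw, target, h, w, depth, bce_weight, dice_weight) {
  p <- fw$prob; t <- as.vector(target)
  npix <- length(t)
  eps <- 1e-7
  Tn <- 2 * sum(p * t) + 1
  Sn <- sum(p) + sum(t) + 1
  ddice_dp <- -(2 * t * Sn - Tn) / Sn^2
  dz <- bce_weight * (p - t) / npix + dice_weight * ddice_dp * p * (1 - p)
  grads <- list()
  grads$out <- list(W = crossprod(fw$a_last, dz), b = sum(dz))
  da <- matrix(dz, ncol = 1L) %*% t(params$out$W)
  ## walk the decoder from full resolution down to the bottleneck
  hh <- h; ww <- w
  for (i in seq_len(depth - 1L)) {
    cache <- fw$caches[[paste0("dec", i)]]
    g2 <- conv3_backward(da, cache$d2, params[[paste0("dec", i, "b")]]$W, hh, ww)
    grads[[paste0("dec", i, "b")]] <- list(W = g2$dW, b = g2$db)
    g1 <- conv3_backward(g2$dx, cache$d1, params[[paste0("dec", i, "a")]]$W, hh, ww)
    grads[[paste0("dec", i, "a")]] <- list(W = g1$dW, b = g1$db)
    n_up <- cache$n_up
    dup <- g1$dx[, seq_len(n_up), drop = FALSE]
    dskip <- g1$dx[, -seq_len(n_up), drop = FALSE]
    ## push upsample gradient to the coarser grid
    hh2 <- hh %/% 2L; ww2 <- ww %/% 2L
    dcoarse <- rowsum(dup, upsample_idx(hh2, ww2))
    fw$caches[[paste0("dskip", i)]] <- dskip
    da <- dcoarse
    hh <- hh2; ww <- ww2
  }
  cache <- fw$caches$bott
  g2 <- conv3_backward(da, cache$c2, params$bottb$W, hh, ww)
  grads$bottb <- list(W = g2$dW, b = g2$db)
  g1 <- conv3_backward(g2$dx, cache$c1, params$botta$W, hh, ww)
  grads$botta <- list(W = g1$dW, b = g1$db)
  da <- g1$dx
  for (i in rev(seq_len(depth - 1L))) {
    cache <- fw$caches[[paste0("enc", i)]]
    dpool <- pool_backward(da, cache$pl)
    hh <- hh * 2L; ww <- ww * 2L
    dc2 <- dpool + fw$caches[[paste0("dskip", i)]]
    g2 <- conv3_backward(dc2, cache$c2, params[[paste0("enc", i, "b")]]$W, hh, ww)
    grads[[paste0("enc", i, "b")]] <- list(W = g2$dW, b = g2$db)
    g1 <- conv3_backward(g2$dx, cache$c1, params[[paste0("enc", i, "a")]]$W, hh, ww)
    grads[[paste0("enc", i, "a")]] <- list(W = g1$dW, b = g1$db)
    da <- g1$dx
  }
  grads
}

unet_loss <- function(prob, target, bce_weight, dice_weight) {
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  t <- as.vector(target)
  bce <- -mean(t * log(p) + (1 - t) * log(1 - p))
  dice <- 1 - (2 * sum(prob * t) + 1) / (sum(prob) + sum(t) + 1)
  bce_weight * bce + dice_weight * dice
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    for (slot in c("W", "b")) {
      g <- grads[[nm]][[slot]]
      key <- paste0(nm, ".", slot)
      if (is.null(state$m[[key]])) {
        state$m[[key]] <- g * 0
        state$v[[key]] <- g * 0
      }
      state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
      state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
      mhat <- state$m[[key]] / (1 - beta1^t)
      vhat <- state$v[[key]] / (1 - beta2^t)
      params[[nm]][[slot]] <- params[[nm]][[slot]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

#' Train the 2D U-Net lesion segmenter
#'
#' Trains the native U-Net on (image, mask) slice pairs with a combined
#' binary cross-entropy + soft-DICE loss and Adam. Images must already be
#' normalized to `[0, 1]` (see [normalize_intensity()]); slice height and
#' width must be divisible by `2^(depth - 1)`. Training is deterministic
#' for a fixed `config$seed`.
#'
#' @param slice_pairs list of `list(image = matrix, mask = matrix)` with at
#'   least one lesion-containing slice.
#' @param config a [seg_config()].
#' @return object of class `unet_segmenter` with the trained parameters,
#'   the config and a per-epoch `history` (loss, training DICE).
#' @export
train_unet <- function(slice_pairs, config = seg_config()) {
  if (!length(slice_pairs)) stop("empty training set")
  if (!any(vapply(slice_pairs, function(s) any(s$mask > 0), logical(1))))
    stop("training set has no lesion-containing slice")
  h <- nrow(slice_pairs[[1]]$image); w <- ncol(slice_pairs[[1]]$image)
  div <- 2L^(config$depth - 1L)
  if (h %% div != 0L || w %% div != 0L)
    stop(sprintf("slice shape %dx%d not divisible by 2^(depth-1) = %d", h, w, div))
  set.seed(config$seed)
  params <- unet_init_params(config$depth, config$base_channels)
  state <- list(m = list(), v = list())
  history <- data.frame(epoch = integer(0), loss = numeric(0), dice = numeric(0))
  step <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(slice_pairs))
    losses <- numeric(length(ord)); dices <- numeric(length(ord))
    for (k in seq_along(ord)) {
      s <- slice_pairs[[ord[k]]]
      x <- matrix(as.vector(s$image), ncol = 1L)
      fw <- unet_forward(params, x, h, w, config$depth, train = TRUE)
      losses[k] <- unet_loss(fw$prob, s$mask, config$bce_weight, config$dice_weight)
      pred <- matrix(as.integer(fw$prob >= config$threshold), h, w)
      dices[k] <- dice_coefficient(pred, s$mask)
      grads <- unet_backward(params, fw, s$mask, h, w, config$depth,
                             config$bce_weight, config$dice_weight)
      step <- step + 1L
      upd <- adam_step(params, grads, state, config$learning_rate, step)
      params <- upd$params; state <- upd$state
    }
    history <- rbind(history, data.frame(epoch = ep, loss = mean(losses),
                                         dice = mean(dices)))
  }
  structure(list(params = params, config = config, history = history,
                 slice_shape = c(h, w)),
            class = "unet_segmenter")
}

#' Per-pixel lesion probability for one slice
#'
#' @param segmenter a trained [train_unet()] model.
#' @param slice numeric matrix normalized to `[0, 1]`.
#' @return matrix of probabilities, same shape as `slice`.
#' @export
predict_unet_slice <- function(segmenter, slice) {
  h <- nrow(slice); w <- ncol(slice)
  div <- 2L^(segmenter$config$depth - 1L)
  if (h %% div != 0L || w %% div != 0L)
    stop(sprintf("slice shape %dx%d incompatible with network (needs divisibility by %d)",
                 h, w, div))
  fw <- unet_forward(segmenter$params, matrix(as.vector(slice), ncol = 1L),
                     h, w, segmenter$config$depth, train = FALSE)
  matrix(fw$prob, h, w)
}

#' Segment a 3D volume slice by slice
#'
#' Runs the trained U-Net on every axial slice of a normalized volume and
#' thresholds the probabilities into a binary mask.
#'
#' @param segmenter a trained [train_unet()] model.
#' @param volume numeric 3D array normalized as in training.
#' @param threshold probability cut (default the training config threshold).
#' @return integer 3D mask, same shape as `volume`.
#' @export
segment_volume <- function(segmenter, volume, threshold = NULL) {
  threshold <- threshold %||% segmenter$config$threshold
  out <- array(0L, dim(volume))
  for (z in seq_len(dim(volume)[3])) {
    pr <- predict_unet_slice(segmenter, volume[, , z])
    out[, , z] <- as.integer(pr >= threshold)
  }
  out
}
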