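## Classifier arms: the under-sampled training split, a weighted
## cross-entropy loss, a natively implemented GRU recurrent classifier over
## the 9 x 57 radiomic timestep layout (image domain + 8 wavelet sub-bands,
## with an optional zero-padded clinical timestep), and the clinical
## logistic baseline.

#' Under-sampled train/test split
#'
#' Samples the requested number of positive and negative subjects into the
#' training cohort uniformly without replacement (the under-sampling used
#' to rebalance a rare-event cohort) and assigns every remaining subject to
#' the test cohort. Deterministic given `seed`.
#'
#' @param labels binary 0/1 vector for the whole cohort.
#' @param n_pos_train,n_neg_train training-cohort class counts (the study
#'   design used 57 recurrence / 100 non-recurrence).
#' @param seed integer RNG seed.
#' @return object of class `split_plan`: list with `train`, `test` (index
#'   vectors) and a `counts` list.
#' @export
build_split <- function(labels, n_pos_train = 57L, n_neg_train = 100L, seed = 1L) {
  labels <- as.integer(labels)
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  if (length(pos) < n_pos_train)
    stop(sprintf("insufficient positives: need %d, have %d", n_pos_train, length(pos)))
  if (length(neg) < n_neg_train)
    stop(sprintf("insufficient negatives: need %d, have %d", n_neg_train, length(neg)))
  with_seed(seed, {
    tr_pos <- if (n_pos_train > 0L) sort(sample(pos, n_pos_train)) else integer(0)
    tr_neg <- if (n_neg_train > 0L) sort(sample(neg, n_neg_train)) else integer(0)
    train <- sort(c(tr_pos, tr_neg))
    test <- setdiff(seq_along(labels), train)
    structure(list(
      train = train, test = test,
      counts = list(train_pos = n_pos_train, train_neg = n_neg_train,
                    test_pos = sum(labels[test] == 1L),
                    test_neg = sum(labels[test] == 0L)),
      seed = seed
    ), class = "split_plan")
  })
}

#' Weighted cross-entropy loss
#'
#' Mean over samples of `-weight(y) * log p(y)`, the loss used to train the
#' classifier under class imbalance; reduces to standard cross-entropy at
#' unit weights. Probabilities are clamped to `[eps, 1 - eps]`.
#'
#' @param prob_pos predicted probability of the positive class, per sample.
#' @param labels binary 0/1 labels.
#' @param class_weights length-2 positive weights `c(negative, positive)`.
#' @param eps clamp (default 1e-7).
#' @return scalar loss.
#' @export
weighted_cross_entropy <- function(prob_pos, labels, class_weights = c(1, 1),
                                   eps = 1e-7) {
  if (any(class_weights <= 0)) stop("class weights must be > 0")
  labels <- as.integer(labels)
  p <- pmin(pmax(prob_pos, eps), 1 - eps)
  py <- ifelse(labels == 1L, p, 1 - p)
  w <- class_weights[labels + 1L]
  mean(-w * log(py))
}

## ---------------------------------------------------------------------------
## GRU classifier

#' Recurrent classifier configuration
#'
#' The 513-feature radiomic vector is presented to the recurrent network as
#' a sequence of 9 timesteps of 57 features (image domain first, then the 8
#' wavelet sub-bands in LLL..HHH order); with clinical covariates, a 10th
#' timestep zero-padded to 57 is appended. A single-layer GRU consumes the
#' sequence and its final hidden state feeds an affine 2-class softmax.
#'
#' @param hidden_size GRU hidden width (default 64).
#' @param epochs maximum training epochs (default 200).
#' @param learning_rate Adam step size (default 1e-4, the study setting).
#' @param batch_size minibatch size (default 10, the study setting).
#' @param class_weights optional length-2 loss weights `c(neg, pos)`;
#'   default NULL = inverse training-class frequencies (normalised to mean
#'   1).
#' @param weight_decay decoupled L2 weight decay applied after each Adam
#'   step (default 25; the rebalanced training cohorts are small relative
#'   to the network, so substantial shrinkage generalises better).
#' @param ensemble number of independently initialised networks whose
#'   predicted probabilities are averaged (default 3; averaging over
#'   initialisation seeds reduces the variance of the small-sample fit).
#' @param validation_fraction share of the training cohort held out for
#'   early stopping (0 disables; default 0.15).
#' @param patience epochs without validation improvement before stopping.
#' @param seed RNG seed for initialisation, shuffling and the validation
#'   split.
#' @return object of class `rnn_config`.
#' @export
rnn_config <- function(hidden_size = 64L, epochs = 200L, learning_rate = 1e-4,
                       batch_size = 10L, class_weights = NULL,
                       weight_decay = 25, validation_fraction = 0.15,
                       patience = 25L, ensemble = 3L, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (!is.null(class_weights) && any(class_weights <= 0))
    stop("class weights must be > 0")
  structure(list(hidden_size = as.integer(hidden_size), epochs = as.integer(epochs),
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 class_weights = class_weights, weight_decay = weight_decay,
                 validation_fraction = validation_fraction,
                 patience = as.integer(patience),
                 ensemble = max(1L, as.integer(ensemble)),
                 seed = as.integer(seed)),
            class = "rnn_config")
}

## Reshape an n x 513 feature matrix (+ optional clinical block) into a
## list of T matrices of n x 57.
sequence_layout <- function(features, clinical = NULL) {
  n <- nrow(features)
  if (ncol(features) != 513L)
    stop(sprintf("feature layout mismatch: expected 513 radiomic columns, got %d", ncol(features)))
  steps <- lapply(0:8, function(tt) features[, tt * 57L + seq_len(57L), drop = FALSE])
  if (!is.null(clinical)) {
    cl <- as.matrix(clinical)
    if (ncol(cl) > 57L) stop("clinical block exceeds the 57-wide timestep")
    pad <- matrix(0, n, 57L - ncol(cl))
    steps[[10]] <- cbind(cl, pad)
  }
  steps
}

gru_init <- function(input_size, hidden, seed) {
  set.seed(seed)
  gl <- function(nin, nout) glorot(nin, nout)
  list(
    Wz = gl(input_size, hidden), Uz = gl(hidden, hidden), bz = numeric(hidden),
    Wr = gl(input_size, hidden), Ur = gl(hidden, hidden), br = numeric(hidden),
    Wh = gl(input_size, hidden), Uh = gl(hidden, hidden), bh = numeric(hidden),
    Wo = gl(hidden, 2L), bo = numeric(2L)
  )
}

## Forward over a list of timestep matrices (each B x D). Returns softmax
## probabilities and caches for BPTT.
gru_forward <- function(params, steps, train = FALSE) {
  B <- nrow(steps[[1]])
  H <- ncol(params$Uz)
  h <- matrix(0, B, H)
  caches <- if (train) vector("list", length(steps)) else NULL
  for (tt in seq_along(steps)) {
    x <- steps[[tt]]
    z <- plogis(x %*% params$Wz + h %*% params$Uz + rep(params$bz, each = B))
    r <- plogis(x %*% params$Wr + h %*% params$Ur + rep(params$br, each = B))
    hh <- tanh(x %*% params$Wh + (r * h) %*% params$Uh + rep(params$bh, each = B))
    hnew <- (1 - z) * h + z * hh
    if (train) caches[[tt]] <- list(x = x, hprev = h, z = z, r = r, hh = hh)
    h <- hnew
  }
  logits <- h %*% params$Wo + rep(params$bo, each = B)
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(probs = probs, h_final = h, caches = caches)
}

## BPTT given dlogits (B x 2).
gru_backward <- function(params, fw, dlogits) {
  g <- lapply(params, function(p) p * 0)
  g$Wo <- crossprod(fw$h_final, dlogits)
  g$bo <- colSums(dlogits)
  dh <- dlogits %*% t(params$Wo)
  for (tt in rev(seq_along(fw$caches))) {
    c <- fw$caches[[tt]]
    dz <- dh * (c$hh - c$hprev) * c$z * (1 - c$z)
    dhh <- dh * c$z * (1 - c$hh^2)
    dr <- (dhh %*% t(params$Uh)) * c$hprev * c$r * (1 - c$r)
    g$Wz <- g$Wz + crossprod(c$x, dz)
    g$Uz <- g$Uz + crossprod(c$hprev, dz)
    g$bz <- g$bz + colSums(dz)
    g$Wr <- g$Wr + crossprod(c$x, dr)
    g$Ur <- g$Ur + crossprod(c$hprev, dr)
    g$br <- g$br + colSums(dr)
    g$Wh <- g$Wh + crossprod(c$x, dhh)
    g$Uh <- g$Uh + crossprod(c$r * c$hprev, dhh)
    g$bh <- g$bh + colSums(dhh)
    dh <- dh * (1 - c$z) + (dhh %*% t(params$Uh)) * c$r +
      dz %*% t(params$Uz) + dr %*% t(params$Ur)
  }
  g
}

adam_step_flat <- function(params, grads, state, lr, t, beta1 = 0.9,
                           beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  for (nm in names(grads)) {
    gmat <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- gmat * 0
      state$v[[nm]] <- gmat * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / (1 - beta1^t)) / (sqrt(state$v[[nm]] / (1 - beta2^t)) + eps)
    ## decoupled weight decay (biases included; harmless at these scales)
    if (weight_decay > 0) params[[nm]] <- params[[nm]] * (1 - lr * weight_decay)
  }
  list(params = params, state = state)
}

#' Train the GRU recurrent classifier
#'
#' Standardizes features with training-set statistics, arranges them into
#' the 9-timestep layout (10 with a clinical block), optionally zero-masks
#' the positions outside a selected feature set (preserving the layout),
#' and trains a single-layer GRU with weighted cross-entropy and Adam.
#' Early stopping monitors loss on a small validation split; the best
#' weights are restored. Deterministic given `config$seed`.
#'
#' @param features n x 513 radiomic feature matrix.
#' @param labels binary 0/1 vector.
#' @param config an [rnn_config()].
#' @param clinical optional numeric matrix/data.frame of clinical
#'   covariates, appended as a zero-padded 10th timestep (standardized with
#'   training statistics, never masked by `selected`).
#' @param selected optional integer indices (into the 513 columns) to keep;
#'   all other radiomic positions are zeroed after standardization.
#' @return object of class `rnn_classifier`.
#' @export
train_rnn <- function(features, labels, config = rnn_config(), clinical = NULL,
                      selected = NULL) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  n <- nrow(features)
  fz <- standardize_features(features)
  ctr <- attr(fz, "center"); scl <- attr(fz, "scale")
  if (!is.null(selected)) {
    mask <- rep(0, ncol(fz)); mask[selected] <- 1
    fz <- sweep(fz, 2L, mask, "*")
  } else mask <- NULL
  cl_ctr <- cl_scl <- NULL
  clz <- NULL
  if (!is.null(clinical)) {
    clinical <- as.matrix(clinical)
    clz <- standardize_features(clinical)
    cl_ctr <- attr(clz, "center"); cl_scl <- attr(clz, "scale")
  }
  cw <- config$class_weights
  if (is.null(cw)) {
    freq <- c(mean(labels == 0L), mean(labels == 1L))
    if (any(freq == 0)) stop("both classes are required for training")
    cw <- (1 / freq) / mean(1 / freq)
  }
  set.seed(config$seed)
  ## validation split for early stopping (stratified would starve rare
  ## positives; plain random split is used on the already-rebalanced cohort)
  n_val <- floor(config$validation_fraction * n)
  val_idx <- if (n_val >= 2L) sample.int(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(unique(labels[tr_idx])) < 2L) { tr_idx <- seq_len(n); val_idx <- integer(0) }

  input_size <- 57L
  params <- gru_init(input_size, config$hidden_size, config$seed)
  state <- list(m = list(), v = list())
  steps_all <- sequence_layout(fz, clz)
  subset_steps <- function(idx) lapply(steps_all, function(s) s[idx, , drop = FALSE])
  eval_loss <- function(idx) {
    fwv <- gru_forward(params, subset_steps(idx))
    weighted_cross_entropy(fwv$probs[, 2], labels[idx], cw)
  }
  history <- data.frame(epoch = integer(0), loss = numeric(0), val_loss = numeric(0))
  best <- list(loss = Inf, params = params, epoch = 0L)
  step <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    batch_losses <- numeric(0)
    for (b0 in seq(1L, length(ord), by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
      steps <- subset_steps(idx)
      fw <- gru_forward(params, steps, train = TRUE)
      y <- labels[idx]
      B <- length(idx)
      w <- cw[y + 1L]
      batch_losses <- c(batch_losses, weighted_cross_entropy(fw$probs[, 2], y, cw))
      onehot <- cbind(1 - y, y)
      dlogits <- w * (fw$probs - onehot) / B
      grads <- gru_backward(params, fw, dlogits)
      step <- step + 1L
      upd <- adam_step_flat(params, grads, state, config$learning_rate, step,
                            weight_decay = config$weight_decay %||% 0)
      params <- upd$params; state <- upd$state
    }
    vl <- if (length(val_idx)) eval_loss(val_idx) else mean(batch_losses)
    history <- rbind(history, data.frame(epoch = ep, loss = mean(batch_losses),
                                         val_loss = vl))
    if (vl < best$loss - 1e-6) best <- list(loss = vl, params = params, epoch = ep)
    if (ep - best$epoch >= config$patience && length(val_idx)) break
  }
  structure(list(params = best$params, config = config, history = history,
                 center = ctr, scale = scl, mask = mask,
                 clinical_center = cl_ctr, clinical_scale = cl_scl,
                 has_clinical = !is.null(clinical),
                 class_weights = cw, best_epoch = best$epoch),
            class = "rnn_classifier")
}

#' Predict recurrence probabilities
#'
#' @param object a trained [train_rnn()] classifier.
#' @param features n x 513 feature matrix in the training layout.
#' @param clinical clinical covariate block (required iff the model was
#'   trained with one).
#' @param ... unused.
#' @return numeric vector of positive-class probabilities.
#' @export
predict.rnn_classifier <- function(object, features, clinical = NULL, ...) {
  features <- as.matrix(features)
  fz <- standardize_features(features, object$center, object$scale)
  if (!is.null(object$mask)) fz <- sweep(fz, 2L, object$mask, "*")
  clz <- NULL
  if (object$has_clinical) {
    if (is.null(clinical)) stop("this model was trained with a clinical block")
    clz <- standardize_features(as.matrix(clinical), object$clinical_center,
                                object$clinical_scale)
  }
  steps <- sequence_layout(fz, clz)
  gru_forward(object$params, steps)$probs[, 2]
}

## ---------------------------------------------------------------------------
## Clinical logistic baseline

#' Clinical logistic regression baseline
#'
#' Multivariable logistic regression on one-hot-encoded clinical
#' covariates. Fits by maximum likelihood; if the fit fails to converge or
#' exhibits separation (fitted probabilities at 0/1), refits with a light
#' L2 ridge penalty via iterated re-weighted least squares and warns.
#'
#' @param clinical data.frame of covariates (factors/characters are
#'   one-hot encoded, first level as reference).
#' @param labels binary 0/1 vector.
#' @param ridge penalty used by the fallback (default 1e-3).
#' @return object of class `clinical_logistic` with `coefficients`.
#' @export
train_clinical_logistic <- function(clinical, labels, ridge = 1e-3) {
  labels <- as.integer(labels)
  X <- model_matrix_clinical(clinical)
  fit <- suppressWarnings(glm.fit(cbind(`(Intercept)` = 1, X), labels,
                                  family = binomial()))
  sep <- any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)
  if (!fit$converged || sep) {
    warning("logistic fit did not converge cleanly (possible separation); using ridge-penalised fit")
    beta <- ridge_logistic(cbind(1, X), labels, ridge)
  } else {
    beta <- coef(fit)
  }
  beta[is.na(beta)] <- 0   # aliased columns carry no information
  names(beta) <- c("(Intercept)", colnames(X))
  structure(list(coefficients = beta, columns = colnames(X),
                 levels = attr(X, "levels_map")),
            class = "clinical_logistic")
}

## one-hot encoding with remembered factor levels, so prediction uses the
## training design
model_matrix_clinical <- function(clinical, levels_map = NULL) {
  cols <- list()
  lm_out <- list()
  for (v in names(clinical)) {
    x <- clinical[[v]]
    if (is.numeric(x) || is.logical(x)) {
      cols[[v]] <- as.numeric(x)
    } else {
      levs <- if (!is.null(levels_map) && !is.null(levels_map[[v]]))
        levels_map[[v]] else sort(unique(as.character(x)))
      lm_out[[v]] <- levs
      for (lv in levs[-1]) {
        cols[[paste0(v, "_", lv)]] <- as.numeric(as.character(x) == lv)
      }
    }
  }
  X <- do.call(cbind, cols)
  attr(X, "levels_map") <- if (is.null(levels_map)) lm_out else levels_map
  X
}

ridge_logistic <- function(X, y, lambda, iter = 100L) {
  beta <- numeric(ncol(X))
  pen <- diag(lambda, ncol(X)); pen[1, 1] <- 0  # do not penalise the intercept
  for (i in seq_len(iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    Wd <- mu * (1 - mu)
    H <- crossprod(X, X * Wd) + pen
    g <- crossprod(X, y - mu) - pen %*% beta
    delta <- solve(H, g)
    beta <- beta + delta
    if (max(abs(delta)) < 1e-10) break
  }
  drop(beta)
}

#' @export
predict.clinical_logistic <- function(object, clinical, ...) {
  X <- model_matrix_clinical(clinical, object$levels)
  X <- X[, object$columns, drop = FALSE]
  drop(plogis(cbind(1, X) %*% object$coefficients))
}


#' Train an ensemble of GRU classifiers
#'
#' Trains `config$ensemble` networks that differ only in their
#' initialisation/shuffling seed (`config$seed`, `config$seed + 1`, ...)
#' and averages their predicted probabilities. With `ensemble = 1` this is
#' identical to [train_rnn()].
#'
#' @inheritParams train_rnn
#' @return object of class `rnn_ensemble` (a list of [train_rnn()] fits).
#' @export
train_rnn_ensemble <- function(features, labels, config = rnn_config(),
                               clinical = NULL, selected = NULL) {
  fits <- lapply(seq_len(config$ensemble), function(k) {
    cfg <- config
    cfg$seed <- config$seed + (k - 1L)
    train_rnn(features, labels, cfg, clinical = clinical, selected = selected)
  })
  structure(list(fits = fits, config = config), class = "rnn_ensemble")
}

#' @export
predict.rnn_ensemble <- function(object, features, clinical = NULL, ...) {
  preds <- vapply(object$fits,
                  function(f) predict(f, features, clinical = clinical),
                  numeric(nrow(as.matrix(features))))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  rowMeans(preds)
}
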