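## Sparse-representation feature selection: approximate minimisation of
## ||l - F w||^2 + eta * ||w||_0 over coefficient vectors w, with labels
## coded -1/+1 and standardized feature columns. Small problems are solved
## exactly by subset enumeration; larger ones by greedy orthogonal matching
## pursuit (OMP) with a least-squares refit on the selected support.

#' Standardize feature columns
#'
#' Centers and scales each column to mean 0, SD 1. Constant columns are
#' centred and left at zero scale (returned as all-zero). When reference
#' `center`/`scale` vectors are supplied (e.g. training-set statistics)
#' they are applied instead.
#'
#' @param x numeric matrix.
#' @param center,scale optional reference statistics.
#' @return matrix with attributes `center` and `scale`.
#' @export
standardize_features <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  center <- center %||% colMeans(x)
  scale <- scale %||% apply(x, 2L, sd)
  scale_safe <- ifelse(is.na(scale) | scale <= 0, 1, scale)
  out <- sweep(sweep(x, 2L, center, "-"), 2L, scale_safe, "/")
  out[, !is.na(scale) & scale <= 0] <- 0
  attr(out, "center") <- center
  attr(out, "scale") <- scale_safe
  out
}

## Least-squares refit on a support; minimum-norm solution (via SVD
## pseudo-inverse) with a warning when the support is rank deficient.
refit_support <- function(F, l, support) {
  if (!length(support)) return(numeric(0))
  Fs <- F[, support, drop = FALSE]
  fit <- qr(Fs)
  if (fit$rank < length(support)) {
    warning("rank-deficient support in sparse refit; returning the minimum-norm solution")
    sv <- svd(Fs)
    pos <- sv$d > max(dim(Fs)) * .Machine$double.eps * sv$d[1]
    drop(sv$v[, pos, drop = FALSE] %*%
           ((crossprod(sv$u[, pos, drop = FALSE], l)) / sv$d[pos]))
  } else {
    drop(qr.coef(fit, l))
  }
}

## Greedy OMP path up to `kmax` atoms; returns the visited supports and
## their residual sums of squares.
omp_path <- function(F, l, kmax) {
  p <- ncol(F)
  support <- integer(0)
  resid <- l
  rss <- numeric(kmax)
  supports <- vector("list", kmax)
  for (k in seq_len(kmax)) {
    corrs <- abs(crossprod(F, resid))
    corrs[support] <- -Inf
    j <- which.max(corrs)      # ties: lowest index (which.max convention)
    support <- c(support, j)
    w <- refit_support(F, l, support)
    resid <- l - F[, support, drop = FALSE] %*% w
    rss[k] <- sum(resid^2)
    supports[[k]] <- support
  }
  list(supports = supports, rss = rss)
}

## Exhaustive minimisation of ||l - Fw||^2 + eta*|S| over all 2^p supports.
exhaustive_l0 <- function(F, l, eta) {
  p <- ncol(F)
  best_obj <- sum(l^2)          # empty support
  best_support <- integer(0)
  for (code in seq_len(2^p - 1L)) {
    support <- which(bitwAnd(code, bitwShiftL(1L, 0:(p - 1L))) != 0L)
    w <- suppressWarnings(refit_support(F, l, support))
    obj <- sum((l - F[, support, drop = FALSE] %*% w)^2) + eta * length(support)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best_support <- support
    }
  }
  list(support = best_support, objective = best_obj)
}

#' Solve the L0 sparse-representation selection problem
#'
#' Minimises `||l - F w||^2 + eta * ||w||_0` (or the residual under a fixed
#' support-size budget `k`). Labels are coded -1/+1; feature columns are
#' expected to be standardized (see [standardize_features()]). The exact
#' L0 problem is combinatorial: for `p <= max_exhaustive` columns with an
#' `eta` budget the solver enumerates all supports exactly; otherwise it
#' runs greedy orthogonal matching pursuit with a least-squares refit,
#' choosing the support size that minimises the penalised objective (for
#' `eta`) or stopping at `k` atoms (for a size budget). Deterministic given
#' its inputs; when both `eta` and `k` are supplied the size budget wins.
#'
#' @param F numeric matrix (samples x features), standardized columns.
#' @param l label vector: -1/+1, or 0/1 (recoded), length `nrow(F)`.
#' @param eta sparsity penalty (>= 0).
#' @param k support-size budget (overrides `eta` when both given).
#' @param method `"auto"` (default), `"omp"` or `"exhaustive"`.
#' @param max_exhaustive largest `p` solved exactly under `"auto"` (12).
#' @return list with `w` (length-p coefficient vector, zeros off support),
#'   `support`, `objective` (penalised when `eta` drives the fit) and
#'   `method`.
#' @export
solve_sparse <- function(F, l, eta = NULL, k = NULL,
                         method = c("auto", "omp", "exhaustive"),
                         max_exhaustive = 12L) {
  method <- match.arg(method)
  F <- as.matrix(F)
  p <- ncol(F)
  l <- recode_labels(l)
  if (length(l) != nrow(F)) stop("length(l) must equal nrow(F)")
  if (is.null(eta) && is.null(k)) stop("supply a sparsity budget: `eta` or `k`")
  if (!is.null(eta) && eta < 0) stop("eta must be >= 0")
  if (p == 0L) {
    return(list(w = numeric(0), support = integer(0), objective = sum(l^2),
                method = "empty"))
  }
  w <- numeric(p)
  if (!is.null(k)) {
    k <- min(k, p, nrow(F))
    if (k == 0L) {
      return(list(w = w, support = integer(0), objective = sum(l^2),
                  method = "budget"))
    }
    path <- omp_path(F, l, k)
    support <- path$supports[[k]]
    w[support] <- refit_support(F, l, support)
    obj <- path$rss[k]
    meth <- "omp"
  } else if (method == "exhaustive" ||
             (method == "auto" && p <= max_exhaustive)) {
    ex <- exhaustive_l0(F, l, eta)
    support <- ex$support
    if (length(support)) w[support] <- suppressWarnings(refit_support(F, l, support))
    obj <- ex$objective
    meth <- "exhaustive"
  } else {
    kmax <- min(p, nrow(F) - 1L, 200L)
    path <- omp_path(F, l, max(kmax, 1L))
    objs <- c(sum(l^2), path$rss + eta * seq_along(path$rss))
    kbest <- which.min(objs) - 1L
    support <- if (kbest == 0L) integer(0) else path$supports[[kbest]]
    if (length(support)) w[support] <- refit_support(F, l, support)
    obj <- objs[kbest + 1L]
    meth <- "omp"
  }
  if (!is.null(colnames(F))) names(w) <- colnames(F)
  list(w = w, support = sort(support), objective = obj, method = meth)
}

recode_labels <- function(l) {
  if (is.factor(l)) l <- as.integer(l) - 1L
  u <- sort(unique(l))
  if (identical(as.numeric(u), c(0, 1))) l <- 2 * l - 1
  if (!all(l %in% c(-1, 1))) stop("labels must be codable as -1/+1")
  as.numeric(l)
}

#' Select the top-K features by coefficient magnitude
#'
#' Orders features by `|w|` (descending, ties broken toward the lower
#' index), drops exact zeros, and returns the first `k` indices — the
#' "simple threshold comparison" on the sparse-representation coefficients.
#'
#' @param w coefficient vector (optionally named).
#' @param k number of features to keep (default 100).
#' @return object of class `selection_result`: list with `selected`
#'   (1-based indices in rank order), `names`, `coefficients` (matching
#'   `selected`) and `k`.
#' @export
select_top_k <- function(w, k = 100L) {
  if (k < 0) stop("k must be >= 0")
  p <- length(w)
  if (k > p) {
    warning(sprintf("k = %d exceeds the %d available features; returning all", k, p))
    k <- p
  }
  ord <- order(-abs(w), seq_along(w))
  ord <- ord[abs(w[ord]) > 0]
  sel <- head(ord, k)
  structure(list(selected = sel,
                 names = if (!is.null(names(w))) names(w)[sel] else NULL,
                 coefficients = unname(w[sel]), k = k),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d of k = %d features (top |w| = %.4g)\n",
              length(x$selected), x$k,
              if (length(x$coefficients)) max(abs(x$coefficients)) else NA))
  invisible(x)
}
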