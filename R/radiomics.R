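## Radiomic feature extraction: 18 first-order (intensity) features and 39
## gray-level texture features (23 co-occurrence + 16 run-length), computed
## in the image domain and in each of the 8 wavelet sub-bands: 57 per
## domain, 513 in total.

INTENSITY_NAMES <- c(
  "mean", "median", "minimum", "maximum", "range", "variance", "sd",
  "skewness", "kurtosis", "energy", "entropy", "uniformity",
  "p10", "p90", "iqr", "mad", "rmad", "rms"
)

GLCM_NAMES <- c(
  "autocorrelation", "cluster_prominence", "cluster_shade",
  "cluster_tendency", "contrast", "correlation", "difference_average",
  "difference_entropy", "difference_variance", "joint_energy",
  "joint_entropy", "inverse_difference", "inverse_difference_moment",
  "imc1", "imc2", "idn", "idmn", "inverse_variance",
  "maximum_probability", "sum_average", "sum_entropy", "sum_variance",
  "sum_squares"
)

GLRLM_NAMES <- c(
  "sre", "lre", "gln", "glnn", "rln", "rlnn", "rp", "glv", "rv",
  "run_entropy", "lglre", "hglre", "srlgle", "srhgle", "lrlgle", "lrhgle"
)

## The 13 unique distance-1 3D direction offsets (26-neighbourhood up to sign).
texture_offsets <- function() {
  rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
  )
}

#' Gray-level quantization specification
#'
#' Texture matrices require discretised gray levels. Values are binned into
#' `n_levels` equal-width bins spanning the min--max range of the masked
#' voxels (per domain, independently). A constant region maps to a single
#' level.
#'
#' @param n_levels integer number of gray levels, at least 2 (default 32).
#' @return object of class `quantization_spec`.
#' @export
quantization_spec <- function(n_levels = 32L) {
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 2L) stop("`n_levels` must be an integer >= 2")
  structure(list(n_levels = n_levels), class = "quantization_spec")
}

## Min-max quantization of a numeric vector to integer levels 1..n.
quantize_levels <- function(values, n_levels) {
  lo <- min(values); hi <- max(values)
  if (hi <= lo) return(rep(1L, length(values)))
  lev <- floor((values - lo) / (hi - lo) * n_levels) + 1L
  pmin.int(as.integer(lev), n_levels)
}

#' First-order intensity features
#'
#' Computes the 18 first-order statistics of the masked voxel values:
#' mean, median, minimum, maximum, range, variance, standard deviation,
#' skewness, kurtosis, energy, histogram entropy, uniformity, 10th and 90th
#' percentiles, interquartile range, mean absolute deviation, robust mean
#' absolute deviation (values within the p10--p90 band) and root mean
#' square. Entropy/uniformity use a fixed-width histogram with `n_bins`
#' bins over the value range (base-2 logarithm). Zero-variance conventions:
#' skewness and kurtosis are 0, entropy 0, uniformity 1.
#'
#' @param values numeric vector of masked voxel values (non-empty, finite).
#' @param n_bins histogram bin count for entropy/uniformity (default 32).
#' @return named numeric vector of length 18.
#' @examples
#' intensity_features(c(1, 2, 3, 4))[c("mean", "range", "energy")]
#' @export
intensity_features <- function(values, n_bins = 32L) {
  if (length(values) < 1L) stop("empty value list: at least one voxel is required")
  if (!all(is.finite(values))) stop("masked voxel values must be finite")
  n <- length(values)
  m <- mean(values)
  cen <- values - m
  m2 <- mean(cen^2)
  v <- if (n > 1L) var(values) else 0
  s <- sqrt(v)
  if (m2 > 0) {
    skw <- mean(cen^3) / m2^1.5
    krt <- mean(cen^4) / m2^2 - 3
  } else {
    skw <- 0; krt <- 0
  }
  ## fixed-bin histogram probabilities for entropy / uniformity
  lev <- quantize_levels(values, as.integer(n_bins))
  p <- tabulate(lev, nbins = as.integer(n_bins)) / n
  p <- p[p > 0]
  q <- quantile(values, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  band <- values[values >= q[1] & values <= q[4]]
  c(
    mean = m,
    median = median(values),
    minimum = min(values),
    maximum = max(values),
    range = max(values) - min(values),
    variance = v,
    sd = s,
    skewness = skw,
    kurtosis = krt,
    energy = sum(values^2),
    entropy = -sum(p * log2(p)),
    uniformity = sum(p^2),
    p10 = q[1],
    p90 = q[4],
    iqr = q[3] - q[2],
    mad = mean(abs(cen)),
    rmad = if (length(band)) mean(abs(band - mean(band))) else 0,
    rms = sqrt(mean(values^2))
  )
}

## ---------------------------------------------------------------------------
## Texture geometry: pair lists (GLCM) and run decompositions (GLRLM) depend
## only on the mask and the direction set, so they are precomputed once per
## subject and reused across the 9 domains.

texture_geometry <- function(mask, offsets = texture_offsets()) {
  dm <- dim(mask)
  idx <- which(mask > 0)
  m <- length(idx)
  co <- arrayInd(idx, dm)
  inside <- array(FALSE, dm)
  inside[idx] <- TRUE
  ## map linear voxel index -> position in the masked-value vector
  pos <- integer(prod(dm))
  pos[idx] <- seq_len(m)
  ndir <- nrow(offsets)
  pairs <- vector("list", ndir)   # 2-col matrices of masked-vector positions
  runs <- vector("list", ndir)    # list(ord, newline): run scan order + line breaks
  for (d in seq_len(ndir)) {
    off <- offsets[d, ]
    nb <- sweep(co, 2L, off, "+")
    ok <- nb[, 1] >= 1L & nb[, 1] <= dm[1] & nb[, 2] >= 1L & nb[, 2] <= dm[2] &
      nb[, 3] >= 1L & nb[, 3] <= dm[3]
    if (any(ok)) {
      nbl <- nb[ok, 1L] + (nb[ok, 2L] - 1L) * dm[1] + (nb[ok, 3L] - 1L) * dm[1] * dm[2]
      hit <- inside[nbl]
      pairs[[d]] <- cbind(pos[idx[ok][hit]], pos[nbl[hit]])
    } else {
      pairs[[d]] <- matrix(integer(0), ncol = 2L)
    }
    ## run decomposition: voxels on the same line differ by a multiple of off;
    ## step t taken from the first nonzero offset axis (|component| = 1).
    ax <- which(off != 0L)[1]
    t_step <- co[, ax] * off[ax]
    key <- co - tcrossprod(t_step, off)
    ord <- order(key[, 1], key[, 2], key[, 3], t_step)
    ks <- key[ord, , drop = FALSE]
    ts <- t_step[ord]
    if (m > 1L) {
      newline <- c(TRUE, ks[-1, 1] != ks[-m, 1] | ks[-1, 2] != ks[-m, 2] |
                     ks[-1, 3] != ks[-m, 3] | ts[-1] != ts[-m] + 1L)
    } else newline <- rep(TRUE, m)
    runs[[d]] <- list(ord = ord, newline = newline)
  }
  list(n_voxels = m, pairs = pairs, runs = runs, ndir = ndir)
}

## Build the direction-pooled symmetric normalized GLCM from precomputed
## pair lists and per-voxel quantized levels.
glcm_matrix <- function(levels, geom, n_levels) {
  counts <- numeric(n_levels * n_levels)
  total <- 0
  for (d in seq_len(geom$ndir)) {
    pr <- geom$pairs[[d]]
    if (nrow(pr) == 0L) next
    g1 <- levels[pr[, 1]]; g2 <- levels[pr[, 2]]
    ## each unordered pair appears once in each scan direction; the pair list
    ## already contains both (i,j) and (j,i), so the matrix is symmetric.
    counts <- counts + tabulate((g1 - 1L) * n_levels + g2, nbins = n_levels * n_levels)
    total <- total + nrow(pr)
  }
  if (total == 0) {
    ## no co-occurring pairs (e.g. single-voxel mask): degenerate convention,
    ## a single cell of mass 1 at the (only) observed level.
    counts[(levels[1] - 1L) * n_levels + levels[1]] <- 1
    total <- 1
  }
  matrix(counts / total, n_levels, n_levels)
}

glcm_features <- function(p) {
  n <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p)
  mu <- sum(seq_len(n) * px)          # symmetric: mu_x = mu_y
  sig2 <- sum((seq_len(n) - mu)^2 * px)
  sig <- sqrt(sig2)
  dif <- abs(i - j)
  ## diagonal (i+j) and cross-diagonal (|i-j|) marginals
  psum <- as.vector(rowsum(as.vector(p), as.vector(i + j)))  # k = 2..2n
  ksum <- seq(2, 2 * n)
  pdiff <- as.vector(rowsum(as.vector(p), as.vector(dif)))   # k = 0..n-1
  kdiff <- seq(0, n - 1)
  nz <- p[p > 0]
  hxy <- -sum(nz * log2(nz))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  ## marginal-product entropies: HXY1 = HXY2 = HX + HY = 2*HX for the
  ## symmetric pooled matrix (log of a product splits over the marginals)
  hxy1 <- 2 * hx
  hxy2 <- 2 * hx
  da <- sum(kdiff * pdiff)
  sa <- sum(ksum * psum)
  pdz <- pdiff[pdiff > 0]; psz <- psum[psum > 0]
  corr <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 1
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  out <- c(
    sum(i * j * p),                                   # autocorrelation
    sum((i + j - 2 * mu)^4 * p),                      # cluster prominence
    sum((i + j - 2 * mu)^3 * p),                      # cluster shade
    sum((i + j - 2 * mu)^2 * p),                      # cluster tendency
    sum((i - j)^2 * p),                               # contrast
    corr,                                             # correlation
    da,                                               # difference average
    -sum(pdz * log2(pdz)),                            # difference entropy
    sum((kdiff - da)^2 * pdiff),                      # difference variance
    sum(p^2),                                         # joint energy
    hxy,                                              # joint entropy
    sum(p / (1 + dif)),                               # inverse difference
    sum(p / (1 + (i - j)^2)),                         # inverse difference moment
    imc1, imc2,
    sum(p / (1 + dif / n)),                           # idn
    sum(p / (1 + (i - j)^2 / n^2)),                   # idmn
    sum(p[dif > 0] / dif[dif > 0]^2),                 # inverse variance
    max(p),                                           # maximum probability
    sa,                                               # sum average
    -sum(psz * log2(psz)),                            # sum entropy
    sum((ksum - sa)^2 * psum),                        # sum variance
    sum((i - mu)^2 * p)                               # sum of squares (variance)
  )
  names(out) <- GLCM_NAMES
  out
}

## Run-length features for one direction, working directly on the run list
## (one entry per run) with tabulate-based marginals.
glrlm_features_dir <- function(levels, run, n_levels, n_voxels) {
  lv <- levels[run$ord]
  m <- length(lv)
  brk <- run$newline
  if (m > 1L) brk <- brk | c(TRUE, lv[-1] != lv[-m])
  starts <- which(brk)
  rl <- diff(c(starts, m + 1L))        # run lengths, one per run
  gl <- lv[starts]                     # run gray levels
  Nr <- length(rl)
  maxlen <- max(rl)
  gcnt <- tabulate(gl, n_levels)                      # runs per gray level
  lcnt <- tabulate(rl, maxlen)                        # runs per length
  paircnt <- tabulate((gl - 1L) * maxlen + rl, n_levels * maxlen)
  pr <- paircnt[paircnt > 0] / Nr
  pg <- gcnt / Nr
  pl <- lcnt / Nr
  glev <- seq_len(n_levels)
  llev <- seq_len(maxlen)
  gmu <- sum(glev * pg)
  lmu <- sum(llev * pl)
  c(
    sre    = sum(1 / rl^2) / Nr,
    lre    = sum(rl^2) / Nr,
    gln    = sum(gcnt^2) / Nr,
    glnn   = sum(pg^2),
    rln    = sum(lcnt^2) / Nr,
    rlnn   = sum(pl^2),
    rp     = Nr / n_voxels,
    glv    = sum((glev - gmu)^2 * pg),
    rv     = sum((llev - lmu)^2 * pl),
    run_entropy = -sum(pr * log2(pr)),
    lglre  = sum(1 / gl^2) / Nr,
    hglre  = sum(gl^2) / Nr,
    srlgle = sum(1 / (gl^2 * rl^2)) / Nr,
    srhgle = sum(gl^2 / rl^2) / Nr,
    lrlgle = sum(rl^2 / gl^2) / Nr,
    lrhgle = sum(gl^2 * rl^2) / Nr
  )
}

## 39 texture features for one domain given precomputed geometry.
texture_features_geom <- function(values, geom, n_levels) {
  lev <- quantize_levels(values, n_levels)
  p <- glcm_matrix(lev, geom, n_levels)
  glcm <- glcm_features(p)
  rlm <- matrix(0, geom$ndir, 16L)
  for (d in seq_len(geom$ndir)) {
    rlm[d, ] <- glrlm_features_dir(lev, geom$runs[[d]], n_levels, geom$n_voxels)
  }
  glrlm <- colMeans(rlm)
  names(glrlm) <- GLRLM_NAMES
  c(setNames(glcm, paste0("glcm_", GLCM_NAMES)),
    setNames(glrlm, paste0("glrlm_", GLRLM_NAMES)))
}

#' Gray-level texture features
#'
#' Computes 39 texture features of the masked region: 23 gray-level
#' co-occurrence (GLCM) features and 16 gray-level run-length (GLRLM)
#' features. Voxel values are quantized to `q$n_levels` equal-width levels
#' over the masked min--max range. Co-occurrence counts from the 13
#' distance-1 3D directions are symmetrised and pooled into one matrix;
#' run-length features are computed per direction and averaged. A mask
#' without any co-occurring voxel pair (e.g. a single voxel) uses the
#' degenerate single-cell co-occurrence convention.
#'
#' @param volume numeric 3D array.
#' @param mask binary 3D array of the same shape (1 = lesion).
#' @param q a [quantization_spec()].
#' @param offsets integer matrix of direction offsets (rows), default the
#'   13 canonical distance-1 directions.
#' @return named numeric vector of length 39 (`glcm_*` then `glrlm_*`).
#' @export
texture_features <- function(volume, mask, q = quantization_spec(),
                             offsets = texture_offsets()) {
  if (!identical(dim(volume), dim(mask))) stop("volume and mask shapes differ")
  if (!any(mask > 0)) stop("empty mask: texture features are undefined")
  vals <- volume[mask > 0]
  if (!all(is.finite(vals))) stop("masked voxels must be finite")
  geom <- texture_geometry(mask, offsets)
  texture_features_geom(vals, geom, q$n_levels)
}

#' Feature manifest
#'
#' The deterministic name/order contract of the 513-entry radiomic feature
#' vector: 57 features (18 intensity + 39 texture) in the image domain
#' followed by the same 57 in each of the 8 wavelet sub-bands.
#'
#' @return data.frame with columns `name`, `domain`, `family`.
#' @export
feature_manifest <- function() {
  domains <- c("image", paste0("wavelet_", subband_names()))
  rows <- lapply(domains, function(d) {
    data.frame(
      name = c(paste0(d, "_intensity_", INTENSITY_NAMES),
               paste0(d, "_glcm_", GLCM_NAMES),
               paste0(d, "_glrlm_", GLRLM_NAMES)),
      domain = d,
      family = c(rep("intensity", 18L), rep("texture", 39L)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Extract the 513-feature radiomic vector
#'
#' Extracts 18 first-order and 39 texture features from the masked region
#' of an ADC volume, in the image domain and in each of the 8 undecimated
#' wavelet sub-bands (the original-space mask applies unchanged to every
#' sub-band). Subjects whose cleaned mask holds fewer than `min_voxels`
#' voxels are rejected, mirroring the cohort inclusion rule for lesions
#' too small to carry texture.
#'
#' @param adc numeric 3D array (the ADC map; any co-registered volume works).
#' @param mask binary 3D array, same shape.
#' @param q a [quantization_spec()].
#' @param min_voxels minimum mask size (default 50); smaller masks raise an
#'   exclusion error.
#' @return named numeric vector of length 513, ordered per
#'   [feature_manifest()].
#' @export
extract_features <- function(adc, mask, q = quantization_spec(), min_voxels = 50L) {
  if (!identical(dim(adc), dim(mask))) stop("volume and mask shapes differ")
  nvox <- sum(mask > 0)
  if (nvox < min_voxels) {
    stop(sprintf("lesion too small for feature extraction (%d < %d voxels): subject excluded",
                 nvox, min_voxels))
  }
  geom <- texture_geometry(mask)
  midx <- which(mask > 0)
  nlev <- q$n_levels
  ## image domain
  vals <- adc[midx]
  out <- c(
    setNames(intensity_features(vals), paste0("image_intensity_", INTENSITY_NAMES)),
    setNames(texture_features_geom(vals, geom, nlev),
             paste0("image_", c(paste0("glcm_", GLCM_NAMES), paste0("glrlm_", GLRLM_NAMES))))
  )
  sb <- wavelet_subbands(adc)
  for (b in names(sb)) {
    v <- sb[[b]][midx]
    out <- c(
      out,
      setNames(intensity_features(v), paste0("wavelet_", b, "_intensity_", INTENSITY_NAMES)),
      setNames(texture_features_geom(v, geom, nlev),
               paste0("wavelet_", b, "_",
                      c(paste0("glcm_", GLCM_NAMES), paste0("glrlm_", GLRLM_NAMES))))
    )
  }
  stopifnot(length(out) == 513L)
  out
}
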