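## One-level undecimated (stationary) 3D wavelet decomposition.
##
## Sub-bands keep the shape of the input so the lesion mask applies
## unchanged in every domain. The letter code gives the filter applied
## along each array dimension in order: e.g. "LLH" = low-pass along dims
## 1 and 2, high-pass along dim 3.

## Circular shift of a 3D array by one voxel along `axis`.
shift1 <- function(x, axis) {
  d <- dim(x)
  idx <- lapply(d, seq_len)
  idx[[axis]] <- c(2:d[axis], 1L)
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

## Apply the Haar analysis pair along one axis (periodic boundary):
## low  = (x[i] + x[i+1]) / sqrt(2), high = (x[i+1] - x[i]) / sqrt(2).
haar_axis <- function(x, axis) {
  xs <- shift1(x, axis)
  list(L = (x + xs) / sqrt(2), H = (xs - x) / sqrt(2))
}

#' Undecimated one-level 3D wavelet sub-bands
#'
#' Decomposes a 3D volume into its 8 one-level stationary wavelet sub-bands
#' (`LLL`, `LLH`, `LHL`, `LHH`, `HLL`, `HLH`, `HHL`, `HHH`), each the same
#' shape as the input so that a voxel mask defined on the original volume
#' applies unchanged to every sub-band. The Haar (order-1 Daubechies) filter
#' pair is used with periodic boundary handling; for a constant volume all
#' seven detail sub-bands are identically zero.
#'
#' @param volume numeric 3D array with every dimension at least 2.
#' @return named list of 8 arrays, same shape as `volume`. The k-th letter
#'   of a name is the filter (`L` low-pass, `H` high-pass) applied along
#'   array dimension k.
#' @examples
#' v <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
#' sb <- wavelet_subbands(v)
#' names(sb)
#' @export
wavelet_subbands <- function(volume) {
  if (length(dim(volume)) != 3L) stop("`volume` must be a 3D array")
  if (any(dim(volume) < 2L)) stop("every dimension must be >= 2 for a one-level wavelet transform")
  a1 <- haar_axis(volume, 1L)
  out <- vector("list", 8L)
  nms <- character(8L)
  k <- 0L
  for (f1 in c("L", "H")) {
    a2 <- haar_axis(a1[[f1]], 2L)
    for (f2 in c("L", "H")) {
      a3 <- haar_axis(a2[[f2]], 3L)
      for (f3 in c("L", "H")) {
        k <- k + 1L
        out[[k]] <- a3[[f3]]
        nms[k] <- paste0(f1, f2, f3)
      }
    }
  }
  names(out) <- nms
  ## spec order of domains downstream: LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH
  out[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}

#' @rdname wavelet_subbands
#' @format NULL
#' @export
subband_names <- function() c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
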