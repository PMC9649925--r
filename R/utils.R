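#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbinom rpois sd var median quantile IQR
#'   pt pchisq pnorm qnorm plogis qlogis uniroot fisher.test pwilcox glm
#'   glm.fit binomial coef cov predict setNames complete.cases
#' @importFrom utils head write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `expr` under a temporary RNG state seeded with `seed`; if `seed` is
## NULL the current stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## Fan a master seed out to per-stage seeds, kept inside 32-bit range.
stage_seed <- function(master, offset) {
  (as.integer(master) + 1013L * as.integer(offset)) %% 2147483647L
}

is_binary_array <- function(x) all(x %in% c(0, 1))

## Format a p-value the way clinical tables print them.
format_pvalue <- function(p, digits = 3) {
  ifelse(p < 10^(-digits), paste0("<", format(10^(-digits), scientific = FALSE)),
         formatC(round(p, digits), format = "f", digits = digits))
}
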