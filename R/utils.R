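#' Canonical epigenomic marker order
#'
#' The fixed row order of every feature matrix produced by this package:
#' H3K27me3, H3K36me3, H3K4me1, H3K4me3, H3K9me3, CTCF, DNase. All track
#' readers, the feature extractor and the synthetic generator use this
#' order so that matrices from different sources are row-compatible.
#'
#' @return Character vector of the seven marker names.
#' @export
epi_markers <- function() {
  c("H3K27me3", "H3K36me3", "H3K4me1", "H3K4me3", "H3K9me3", "CTCF", "DNase")
}

# Run `code` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All seedable operations in the package
# go through this so determinism never depends on global RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      suppressWarnings(rm(".Random.seed", envir = env))
  })
  set.seed(as.integer(seed))
  force(code)
}

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope = 0.2) ifelse(x > 0, 1, slope)
elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))
sigmoid <- function(x) 1 / (1 + exp(-x))

# Stable log(sigmoid(x)) for BCE.
log_sigmoid <- function(x) ifelse(x > 0, -log1p(exp(-x)), x - log1p(exp(x)))

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}
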