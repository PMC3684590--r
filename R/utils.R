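#' @keywords internal
#' @useDynLib dysconnect, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef cor cor.test lm median predict pt qt residuals rnorm runif sd t.test var
#' @importFrom graphics abline axis barplot hist legend lines par plot points
#' @importFrom utils write.csv read.csv
"_PACKAGE"

# Evaluate `code` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic per-fold (or per-exclusion) sub-seed, kept well below 2^31.
fold_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1000003) * 2000 + (k %% 2000))
}

stopifnot_scalar_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
}
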