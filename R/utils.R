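#' @keywords internal
"_PACKAGE"

#' @useDynLib qolclasses, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats as.dist binomial cmdscale complete.cases dbinom glm.fit
#'   kmeans lm.fit median model.matrix optimise plogis pnorm prcomp predict
#'   qnorm qt quantile rbinom rchisq relevel rgamma rgeom rnorm sd setNames
#'   var
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic derivation of stage-local seeds from a master seed.
# Kept strictly below 2^31 so the result is a valid R integer seed.
derive_seed <- function(seed, ...) {
  offsets <- c(...)
  s <- as.double(seed) %% 2147483629
  for (o in offsets) {
    s <- (s * 69069 + as.double(o) + 1) %% 2147483629
  }
  as.integer(s)
}

# log(sum(exp(a))) column-wise for a K x N matrix, numerically stable.
col_log_sum_exp <- function(a) {
  m <- apply(a, 2, max)
  m[!is.finite(m)] <- 0
  m + log(colSums(exp(sweep(a, 2, m, "-"))))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_field <- function(field, msg) {
  stop(sprintf("field '%s': %s", field, msg), call. = FALSE)
}

# Rolling polynomial hash of a character vector; used for run manifests.
content_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
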