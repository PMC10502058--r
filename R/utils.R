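#' @keywords internal
#' @importFrom e1071 svm
#' @importFrom ranger ranger
#' @importFrom glmnet glmnet
#' @importFrom rpart rpart rpart.control
#' @importFrom jsonlite write_json read_json
#' @importFrom stats median predict rbinom runif rbeta rpois rnorm setNames
#' @importFrom utils read.table write.table
"_PACKAGE"

# Deterministic child seed from a master seed and a stage tag; kept well
# below .Machine$integer.max so it is always a valid set.seed() argument.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483399 + 1)
}

# Evaluate code under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 1 && x == floor(x)
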