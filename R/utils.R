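#' @keywords internal
#' @import methods
#' @importFrom stats dist median pchisq quantile rnorm runif sd setNames var dnorm
#' @importFrom utils head read.table write.table
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

## Run `expr` under a reproducible RNG stream without disturbing the caller's
## RNG state. `seed` may be an integer (set.seed) or a full .Random.seed
## vector (restored verbatim, used to resume a training stream).
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  if (length(seed) > 1L) assign(".Random.seed", seed, envir = globalenv())
  else set.seed(as.integer(seed))
  expr
}

## Capture the current RNG state (after seeding) for later resumption.
captureRngState <- function() {
  get(".Random.seed", envir = globalenv(), inherits = FALSE)
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

## One-hot encode labels against an ordered class vector.
oneHot <- function(labels, classes) {
  stopifnot(all(labels %in% classes))
  Y <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  Y
}

stopifnotFinite <- function(x, what = "matrix") {
  if (!all(is.finite(x))) {
    stop(sprintf("%s contains non-finite (NaN/Inf/NA) entries", what),
         call. = FALSE)
  }
  invisible(TRUE)
}
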