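#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a per-stage seed from a master seed
#'
#' One master seed drives a whole pipeline run; each stage gets its own
#' reproducible stream via a fixed integer offset, so adding a stage never
#' perturbs the draws of another.
#'
#' @param master integer master seed.
#' @param offset integer stage offset (>= 0).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, offset) {
  stopifnot(is.numeric(master), length(master) == 1,
            is.numeric(offset), length(offset) == 1, offset >= 0)
  as.integer((as.double(master) + as.double(offset) * 100003) %% 2147483647)
}

stop_if_not_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict && x <= lower)
    stop(sprintf("'%s' must be > %s", name, lower), call. = FALSE)
  if (!strict && x < lower)
    stop(sprintf("'%s' must be >= %s", name, lower), call. = FALSE)
  invisible(x)
}

geomean <- function(x) exp(mean(log(x)))
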