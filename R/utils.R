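# internal helpers shared across modules

.tetmat <- new.env(parent = emptyenv())

#' Derive a stage-specific RNG seed from a master seed
#'
#' A single pipeline seed fans out to per-stage seeds through a fixed integer
#' hash of the stage name, so adding or reordering downstream stages never
#' perturbs the random draws of earlier ones. The result is always a valid
#' 32-bit R integer seed.
#'
#' @param seed Master integer seed.
#' @param stage Character stage label, e.g. `"bootstrap"` or `"gene:un-3"`.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "bootstrap")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483646)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_tetmat <- function(message, class, ...) {
  abort(message, class = c(class, "tetmat_error"), ...)
}

# strict %in% helper for validated categorical columns
check_values <- function(x, allowed, what) {
  bad <- setdiff(unique(x), allowed)
  if (length(bad) > 0) {
    stop_tetmat(
      sprintf("invalid %s: %s (allowed: %s)", what,
              paste(bad, collapse = ", "), paste(allowed, collapse = ", ")),
      "tetmat_validation_error"
    )
  }
  invisible(x)
}
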