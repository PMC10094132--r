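#' @keywords internal
"_PACKAGE"

#' @import stats
#' @import utils
#' @importFrom grDevices png dev.off
#' @importFrom graphics boxplot matplot legend abline axis points par title
NULL

# Run code with a temporary RNG state seeded by `seed`; the caller's RNG
# stream is restored afterwards so seeded generators do not perturb it.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive `n` independent sub-seeds from a master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_dq <- function(..., class) {
  stop(structure(class = c(class, "dysquant_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}
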