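#' @keywords internal
"_PACKAGE"

# Run code with a locally seeded RNG stream, restoring the caller's state.
# All generators route their draws through this so that identical configs
# give bit-identical outputs without clobbering the global stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed (< 2^31) from a master seed, so that the
# per-generator streams are decoupled from one another.
derive_seed <- function(seed, offset) {
  # double arithmetic keeps the product exact (< 2^53) before the modulus
  as.integer((as.numeric(seed) * 1103 + as.numeric(offset) * 12347) %%
               2147483629)
}

#' Standard error of the mean
#'
#' @param x numeric vector; `NA`s are dropped.
#' @return `sd(x)/sqrt(n)`.
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  stats::sd(x) / sqrt(length(x))
}

stop_ca1 <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "ca1quant_error")))
}
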