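#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a local random seed
#'
#' Runs `expr` with the RNG seeded at `seed`, then restores the caller's RNG
#' state, so seeded helpers never perturb the global random stream. With
#' `seed = NULL` the expression runs on the current stream.
#'
#' @param seed integer seed or NULL.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' The five mediotemporal regions covered by the recordings
#' @return character vector of region labels.
#' @export
mtl_regions <- function() {
  c("amygdala", "hippocampus", "entorhinal", "parahippocampal", "piriform")
}

stop_if_not_scalar <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower) {
    stop(sprintf("'%s' must be a finite scalar >= %s", name, lower),
         call. = FALSE)
  }
  invisible(x)
}
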