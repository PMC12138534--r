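# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#'
#' All generators are pure functions of their spec: the global `.Random.seed`
#' is saved, the supplied seed installed, and the previous state restored on
#' exit, so repeated calls with the same spec are bit-identical and never
#' perturb user code.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Trapezoidal integral of y(x) over the sampled grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# scalar check with informative error
check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}

check_flag_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !(is.logical(x) || all(x %in% c(0, 1))))
    stop(sprintf("'%s' must be a logical (or 0/1) matrix", name), call. = FALSE)
  matrix(as.logical(x), nrow(x), ncol(x))
}

# Format numeric columns with enough digits to round-trip, so that repeated
# runs write byte-identical CSV files.
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- sprintf("%.17g", v)
    # shortest representation that still round-trips
    for (d in 1:16) {
      c <- sprintf(sprintf("%%.%dg", d), v)
      if (as.numeric(c) == v) return(c)
    }
    s
  }, character(1))
  out
}
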