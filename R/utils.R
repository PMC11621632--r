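# Internal helpers shared across the package.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the caller's
#' RNG state afterwards so that seeded generators do not perturb the session
#' stream. A `NULL` seed evaluates `code` against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # initialise the stream so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a block of child seeds from one master seed, all < 2^31 - 1.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Coerce positions input (2-column matrix / data.frame / eye_trace) to a
# numeric matrix with columns x, y.
as_positions <- function(x) {
  if (inherits(x, "eye_trace")) {
    return(x$positions)
  }
  m <- as.matrix(x)
  if (ncol(m) != 2L) {
    stop("positions must have exactly two columns (x, y)", call. = FALSE)
  }
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y")
  m
}

# Frame rate of a trace-like object, with a fallback default.
frame_rate_of <- function(x, default = 60) {
  if (inherits(x, "eye_trace")) x$frame_rate else default
}

stopifnot_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
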