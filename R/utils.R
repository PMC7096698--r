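# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG state
#'
#' Seeds the global RNG with `seed`, runs `code`, and restores the previous
#' RNG state so that generators are pure functions of their parameters.
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                      strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper)
    stop(sprintf("'%s' = %g outside allowed range", name, x), call. = FALSE)
  invisible(x)
}

# voxel center coordinates (mm) for linear indices into a 3D array
voxel_coords_mm <- function(idx, dim, voxel_size) {
  a <- arrayInd(idx, dim)
  sweep(a - 1, 2, voxel_size, `*`)
}

as_binary_array <- function(x, name) {
  x <- (x != 0) * 1L
  storage.mode(x) <- "integer"
  x
}
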