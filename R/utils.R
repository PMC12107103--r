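# Run expr under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Convert first-order rates between per-minute and per-second
#'
#' Plate readers commonly report observed rates in min^-1 while association
#' rate constants are quoted in M^-1 s^-1; these helpers keep the units
#' audit explicit.
#'
#' @param k rate(s) in min^-1 (\code{per_min_to_per_s}) or s^-1
#'   (\code{per_s_to_per_min}).
#' @return the converted rate(s).
#' @export
per_min_to_per_s <- function(k) k / 60

#' @rdname per_min_to_per_s
#' @export
per_s_to_per_min <- function(k) k * 60
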