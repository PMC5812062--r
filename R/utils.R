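# internal helpers shared across modules

#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Wrap an angle into (-90, +90] degrees
#'
#' Orientations of axisymmetric particles are defined modulo 180 degrees;
#' all angle-valued results in the package live on (-90, +90].
#'
#' @param theta angle(s) in degrees.
#' @return angle(s) wrapped into (-90, +90].
#' @export
wrap_angle <- function(theta) {
  out <- (theta + 90) %% 180 - 90
  out[out == -90] <- 90
  out
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# consistent sub-window count along one image dimension
n_subwindows <- function(npx, window) {
  if (npx %% window != 0)
    stop("window size ", window, " does not divide image dimension ", npx)
  npx %/% window
}
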