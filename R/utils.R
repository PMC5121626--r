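#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` with the R random number generator seeded at `seed`,
#' then restores the caller's RNG state, so that seeded package internals
#' never perturb user-level random streams.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Linear interpolation of a complex-valued series sampled on a regular grid.
# Used to read out echoes at times that are not multiples of the step dt.
interp_complex <- function(times, values, t) {
  re <- stats::approx(times, Re(values), xout = t, rule = 2)$y
  im <- stats::approx(times, Im(values), xout = t, rule = 2)$y
  complex(real = re, imaginary = im)
}

# Minimum-image signed displacement on a periodic interval of length L.
min_image <- function(d, L) d - L * round(d / L)

#' Physical and acquisition constants
#'
#' Default physical constants of the 4.7 T USPIO protocol: gyromagnetic
#' ratio, main field, the susceptibility increase produced by the iron-oxide
#' contrast agent, the oxy/deoxy-hemoglobin susceptibility difference and the
#' microvascular hematocrit (0.42 x 0.85). All susceptibilities are in ppm,
#' SI convention.
#'
#' @param gamma Gyromagnetic ratio, rad/s/T.
#' @param b0 Main magnetic field, T.
#' @param delta_chi_uspio Susceptibility increase due to the contrast agent,
#'   ppm (SI).
#' @param delta_chi0 Susceptibility difference between fully deoxygenated and
#'   fully oxygenated blood, ppm (SI).
#' @param hct Microvascular hematocrit, fraction.
#' @return An object of class `mrvf_physics` (a named list).
#' @export
#' @examples
#' physics_constants()
physics_constants <- function(gamma = 2.67502e8, b0 = 4.7,
                              delta_chi_uspio = 3.5, delta_chi0 = 3.32,
                              hct = 0.357) {
  stopifnot(gamma > 0, b0 > 0, delta_chi_uspio >= 0, delta_chi0 > 0,
            hct > 0, hct < 1)
  structure(list(gamma = gamma, b0 = b0, delta_chi_uspio = delta_chi_uspio,
                 delta_chi0 = delta_chi0, hct = hct),
            class = "mrvf_physics")
}

#' @export
print.mrvf_physics <- function(x, ...) {
  cat("MR physics constants\n")
  cat(sprintf("  gamma          : %.6g rad/s/T\n", x$gamma))
  cat(sprintf("  B0             : %.3g T\n", x$b0))
  cat(sprintf("  delta_chi_USPIO: %.3g ppm (SI)\n", x$delta_chi_uspio))
  cat(sprintf("  delta_chi0     : %.3g ppm (SI)\n", x$delta_chi0))
  cat(sprintf("  Hct            : %.3g\n", x$hct))
  invisible(x)
}

#' Blood-tissue susceptibility difference from oxygen saturation
#'
#' The susceptibility difference between blood and the surrounding tissue is
#' set by the oxygen saturation through
#' \deqn{\Delta\chi = \Delta\chi_0 \cdot Hct \cdot (1 - StO_2).}
#'
#' @param sto2 Blood oxygen saturation, fraction in \[0, 1\].
#' @param hct Microvascular hematocrit, fraction.
#' @param delta_chi0 Oxy/deoxy-hemoglobin susceptibility difference, ppm (SI).
#' @return Susceptibility difference in ppm (SI).
#' @export
#' @examples
#' delta_chi_from_sto2(0.6)           # typical tissue
#' delta_chi_from_sto2(0, hct = 0.42) # fully deoxygenated: 1.39 ppm
delta_chi_from_sto2 <- function(sto2, hct = 0.357, delta_chi0 = 3.32) {
  if (any(sto2 < 0 | sto2 > 1))
    stop("`sto2` must lie in [0, 1]", call. = FALSE)
  delta_chi0 * hct * (1 - sto2)
}
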