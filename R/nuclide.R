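#' Radionuclide decay constants
#'
#' Physical half-life and decay constant used for decay correction and
#' physical-decay tail extrapolation.  The default is Lutetium-177
#' (half-life 6.6475 days); supplying a different half-life makes the rest
#' of the package radionuclide-agnostic.
#'
#' @param half_life_h physical half-life in hours (> 0)
#' @return object of class `nuclide_constants` with fields `half_life`
#'   (hours) and `lam_physical` (1/h, `log(2)/half_life`).
#' @examples
#' lu177 <- nuclide_constants()
#' lu177$lam_physical * lu177$half_life  # log(2)
#' @export
nuclide_constants <- function(half_life_h = 6.6475 * 24) {
  if (!is.numeric(half_life_h) || length(half_life_h) != 1L ||
      !is.finite(half_life_h) || half_life_h <= 0) {
    stop("'half_life_h' must be a single positive number")
  }
  structure(
    list(half_life = half_life_h, lam_physical = log(2) / half_life_h),
    class = "nuclide_constants"
  )
}

#' @export
print.nuclide_constants <- function(x, ...) {
  cat(sprintf("Nuclide constants: half-life %.4f h (%.4f d), lambda %.6g /h\n",
              x$half_life, x$half_life / 24, x$lam_physical))
  invisible(x)
}
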