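#' Ready-made fiber phantoms
#'
#' Builds a labeled phantom with an isotropic (gray-matter-like) border and
#' a central region holding the requested fiber constellation:
#' `parallel_inplane` (one bundle at 30 degrees), `outofplane` (one bundle
#' at 30 degrees inclined by 60), `crossing2` (bundles at 30 and 120) or
#' `crossing3` (bundles at 30, 90 and 150).
#'
#' @param kind constellation name
#' @param size (H, W) of the phantom in image pixels
#' @param border width of the isotropic border, pixels
#' @return an [sli_phantom()]; ground-truth directions are stored in
#'   `attr(, "truth")`
#' @export
phantom_preset <- function(kind, size = c(24, 24), border = 4) {
  dirs <- switch(kind,
    parallel_inplane = 30,
    outofplane = 30,
    crossing2 = c(30, 120),
    crossing3 = c(30, 90, 150),
    stopf("unknown phantom preset '%s'", kind))
  incl <- if (kind == "outofplane") 60 else 0
  H <- size[1]; W <- size[2]
  lm <- matrix(1L, H, W)
  if (2 * border < min(H, W) && border > 0)
    lm[(border + 1):(H - border), (border + 1):(W - border)] <- 2L
  bundles <- lapply(dirs, function(d) fiber_bundle(d, inclination = incl))
  ph <- sli_phantom(lm, list(`1` = list(), `2` = bundles))
  attr(ph, "truth") <- list(kind = kind, directions = dirs, inclination = incl,
                            region = c(border + 1, H - border, border + 1, W - border))
  ph
}
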