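#' Relative air kerma of a spectrum
#'
#' Midpoint-rule quadrature of \eqn{\int k\,\Phi_k\,[\mu_{en}(k)/\rho]_{air}\,dk}
#' over the spectrum grid. The absolute scale is arbitrary; all uses are
#' ratios of this quantity.
#'
#' @param spectrum A `fluence_spectrum`.
#' @return Positive scalar (arbitrary units).
#' @export
air_kerma <- function(spectrum) {
  stopifnot(inherits(spectrum, "fluence_spectrum"))
  if (!any(spectrum$fluence > 0))
    stop("degenerate input: spectrum has no fluence", call. = FALSE)
  w <- diff(spectrum$bin_edges)
  sum(spectrum$energy_kev * spectrum$fluence *
        muen("air", spectrum$energy_kev) * w)
}

#' Narrow-beam air-kerma transmission through a material
#'
#' Ratio of the air kerma of the spectrum behind `thickness_mm` of
#' `material` to the unattenuated air kerma. Equals 1 at zero thickness
#' and decreases strictly with thickness.
#'
#' @param spec A [beam_spec()] or a precomputed `fluence_spectrum`.
#' @param material Attenuator material.
#' @param thickness_mm Thickness in mm (vectorized).
#' @return Transmission fraction(s) in (0, 1].
#' @export
narrow_transmission <- function(spec, material, thickness_mm) {
  sp <- as_spectrum(spec)
  if (any(thickness_mm < 0)) stop("thickness must be >= 0", call. = FALSE)
  k0 <- air_kerma(sp)
  vapply(thickness_mm, function(t)
    kerma_after(sp, material, t) / k0, 0)
}

# air kerma behind a filter; a fully underflowed spectrum means total
# absorption, i.e. zero kerma (not a degenerate input)
kerma_after <- function(sp, material, t) {
  f <- apply_filter(sp, material, t)
  if (!any(f$fluence > 0)) return(0)
  air_kerma(f)
}

as_spectrum <- function(spec) {
  if (inherits(spec, "fluence_spectrum")) return(spec)
  if (inherits(spec, "beam_spec")) return(make_spectrum(spec))
  stop("expected a beam_spec or fluence_spectrum", call. = FALSE)
}

#' Thickness of material giving a target transmission
#'
#' Inverts [narrow_transmission()] by bracketed root finding. The
#' transmission is strictly monotone in thickness, so the root is unique;
#' convergence is to |T(t) - fraction| < 1e-6.
#'
#' @inheritParams narrow_transmission
#' @param fraction Target air-kerma transmission in (0, 1].
#' @param t_max_mm Upper bracket for the search (default 100 mm).
#' @return Thickness in mm.
#' @export
thickness_for_transmission <- function(spec, material, fraction,
                                       t_max_mm = 100) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  if (fraction == 1) return(0)
  sp <- as_spectrum(spec)
  k0 <- air_kerma(sp)
  f <- function(t) kerma_after(sp, material, t) / k0 - fraction
  if (f(t_max_mm) > 0)
    stop("no bracket: transmission above target even at ", t_max_mm,
         " mm", call. = FALSE)
  r <- uniroot(f, c(0, t_max_mm), tol = 1e-10)
  # polish until the transmission residual (not just t) is tight
  if (abs(r$f.root) > 1e-6)
    r <- uniroot(f, c(max(r$root - 0.01, 0), r$root + 0.01), tol = 1e-13)
  r$root
}

#' Beam-quality metrics
#'
#' Computes the standard quality descriptors of a beam: first and second
#' aluminium half-value layers, the homogeneity coefficient
#' h = HVL1/HVL2, and the lead thicknesses for 10% and 1% transmission
#' (TVL1 and TVL1+2). HVL2 is the thickness at 25% transmission minus
#' HVL1.
#'
#' @param spec A [beam_spec()] or `fluence_spectrum`.
#' @return Object of class `beam_quality_metrics`: `hvl1_mm_al`,
#'   `hvl2_mm_al`, `h`, `tvl1_mm_pb`, `tvl12_mm_pb`.
#' @export
beam_quality <- function(spec) {
  sp <- as_spectrum(spec)
  hvl1 <- thickness_for_transmission(sp, "Al", 0.5)
  hvl2 <- thickness_for_transmission(sp, "Al", 0.25) - hvl1
  structure(list(hvl1_mm_al = hvl1, hvl2_mm_al = hvl2, h = hvl1 / hvl2,
                 tvl1_mm_pb = thickness_for_transmission(sp, "Pb", 0.1),
                 tvl12_mm_pb = thickness_for_transmission(sp, "Pb", 0.01)),
            class = "beam_quality_metrics")
}

#' @export
print.beam_quality_metrics <- function(x, ...) {
  cat(sprintf(
    "<beam_quality_metrics> HVL1 %.3g mm Al, h %.3f, TVL1 %.3g mm Pb, TVL1+2 %.3g mm Pb\n",
    x$hvl1_mm_al, x$h, x$tvl1_mm_pb, x$tvl12_mm_pb))
  invisible(x)
}
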