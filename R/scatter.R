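# Monte Carlo front end: material channel decomposition, form factors,
# scatter-spectrum simulation and the lead-buildup estimator.

# Cromer-Mann atomic form factor fits f(x) with x = sin(theta/2)/lambda
# in 1/Angstrom (valid to x ~ 2/A, slowly biased beyond; coherent scatter
# at such momentum transfers is a minor channel here).
.cm_coeffs <- list(
  H  = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
            b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  O  = list(a = c(3.0485, 2.2868, 1.5463, 0.867),
            b = c(13.2771, 5.7011, 0.3239, 32.9089), c = 0.2508),
  Pb = list(a = c(31.0617, 13.0637, 18.442, 5.9696),
            b = c(0.6902, 2.3576, 8.618, 47.2579), c = 13.4118))

cm_ff <- function(el, x) {
  cf <- .cm_coeffs[[el]]
  f <- rowSums(vapply(seq_along(cf$a),
                      function(i) cf$a[i] * exp(-cf$b[i] * x^2), x)) + cf$c
  # beyond the fit's validity (x ~ 2/A) the constant term would floor the
  # form factor; splice in the physical ~x^-3 high-momentum decay instead
  xc <- 2
  hi <- x > xc
  if (any(hi)) {
    fc <- sum(cf$a * exp(-cf$b * xc^2)) + cf$c
    f[hi] <- fc * (xc / x[hi])^3
  }
  f
}

# squared molecular form factor (independent-atom sum)
ff_squared <- function(material, x) {
  switch(material,
         water = 2 * cm_ff("H", x)^2 + cm_ff("O", x)^2,
         Pb = cm_ff("Pb", x)^2,
         stop("no form factor for ", material))
}

# cumulative int F^2 d(x^2) table used by the C++ sampler
ff_table <- function(material, x_max = 13) {
  key <- paste0("ff_", material)
  if (!is.null(.pbeq_cache[[key]])) return(.pbeq_cache[[key]])
  x2 <- seq(0, x_max^2, length.out = 2000L)[-1]
  f2 <- ff_squared(material, sqrt(x2))
  cum <- cumsum(c(f2[1] * x2[1], (f2[-1] + f2[-length(f2)]) / 2 * diff(x2)))
  out <- list(x2 = x2, cum = cum)
  .pbeq_cache[[key]] <- out
  out
}

# Klein-Nishina total cross section per electron (cm^2)
sigma_kn <- function(e_kev) {
  k <- e_kev / 510.99895
  re2 <- 7.940775e-26
  2 * pi * re2 * ((1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) -
                                     log(1 + 2 * k) / k) +
                    log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2)
}

# coherent cross section per molecule/atom (cm^2) by Gauss-type quadrature
sigma_coh <- function(material, e_kev) {
  re2 <- 7.940775e-26
  cth <- seq(-1, 1, length.out = 401L)
  vapply(e_kev, function(e) {
    xe <- e / 12.398419
    f2 <- ff_squared(material, xe * sqrt(pmax((1 - cth) / 2, 0)))
    integrand <- (1 + cth^2) / 2 * f2
    2 * pi * re2 * sum((integrand[-1] + integrand[-length(cth)]) / 2 *
                         diff(cth))
  }, 0)
}

# electrons per gram, molar mass, and the incoherent-scattering-function
# scale x_h (Angstrom^-1) in the one-parameter Thomas-Fermi-style shape
# S(x)/Z = x^2/(x^2 + x_h^2); x_h = 0 means free electrons (S = Z).
.mc_material_const <- list(
  water = list(ne_per_g = 3.3428e23, mol_g = 18.015, xh = 0),
  Pb = list(ne_per_g = 2.3832e23, mol_g = 207.2, xh = 1.1))

# ratio of the S-weighted incoherent cross section to the free-electron
# Klein-Nishina value, by quadrature over the KN angular kernel
incoherent_binding_ratio <- function(e_kev, xh) {
  if (xh <= 0) return(rep(1, length(e_kev)))
  cth <- seq(-1, 1, length.out = 401L)
  vapply(e_kev, function(e) {
    a <- e / 510.99895
    eps <- 1 / (1 + a * (1 - cth))
    kn <- eps^2 * (eps + 1 / eps - 1 + cth^2)  # dsigma/dOmega kernel
    x2 <- (e / 12.398419)^2 * (1 - cth) / 2
    s <- x2 / (x2 + xh^2)
    num <- kn * s
    sum((num[-1] + num[-length(num)]) / 2 * diff(cth)) /
      sum((kn[-1] + kn[-length(kn)]) / 2 * diff(cth))
  }, 0)
}

# Channel decomposition on a uniform energy grid: the bundled total
# attenuation coefficient is preserved exactly; incoherent is the
# free-electron Klein-Nishina value, coherent the form-factor integral,
# and photoelectric the (clamped) residual. This keeps the MC's total
# interaction rate consistent with the analytic transmission model.
mc_material <- function(material, emin = 5, emax = 160, estep = 0.25,
                        coherent = TRUE, with_ncoh = FALSE) {
  key <- sprintf("mc_%s_%d_%d", material, coherent, with_ncoh)
  if (!is.null(.pbeq_cache[[key]])) return(.pbeq_cache[[key]])
  e <- seq(emin, emax, by = estep)
  rho <- material_density(material)
  etab <- pmin(e, 150)  # grid tail above the table reuses the 150-keV point
  mu_tot <- mu(material, etab) * rho
  cst <- .mc_material_const[[material]]
  rinc <- incoherent_binding_ratio(e, cst$xh)
  mu_inc <- cst$ne_per_g * sigma_kn(e) * rho * rinc
  mu_coh <- if (coherent)
    6.02214e23 / cst$mol_g * sigma_coh(material, e) * rho else 0 * e
  mu_pe <- pmax(mu_tot - mu_inc - mu_coh, 0)
  tot <- mu_pe + mu_inc + mu_coh
  out <- list(emin = emin, estep = estep, mu = mu_tot,
              f_pe = mu_pe / tot, f_inc = mu_inc / tot,
              f_coh = mu_coh / tot, xh = cst$xh, rinc = rinc)
  if (with_ncoh) {
    # norm of the (1+cos^2)/2 F^2 angular kernel over 4 pi, per energy
    re2 <- 7.940775e-26
    out$ncoh <- sigma_coh(material, e) / re2
  }
  .pbeq_cache[[key]] <- out
  out
}

#' Geometry of the scatter simulation
#'
#' A 30-cm-diameter water cylinder at the isocenter of a divergent beam
#' with a 10 x 10 cm field at 80 cm source-to-isocenter distance; scatter
#' is tallied in spherical regions of 5-degree half-angle centered at the
#' requested angles from the beam axis, 50 cm from the isocenter in the
#' horizontal plane.
#'
#' @param cylinder_diameter_cm,cylinder_height_cm Water phantom size.
#' @param field_cm Side of the square field at the isocenter.
#' @param sid_cm Source-to-isocenter distance.
#' @param tally_angles_deg Scatter angles from the incident direction.
#' @param tally_dist_cm Distance of tally centers from the isocenter.
#' @param tally_half_angle_deg Angular half-width of each tally region.
#' @return A `scatter_geometry` list.
#' @export
scatter_geometry <- function(cylinder_diameter_cm = 30,
                             cylinder_height_cm = 30,
                             field_cm = 10, sid_cm = 80,
                             tally_angles_deg = c(45, 90, 135),
                             tally_dist_cm = 50,
                             tally_half_angle_deg = 5) {
  stopifnot(cylinder_diameter_cm > 0, field_cm > 0, sid_cm > 0,
            all(tally_angles_deg > 0 & tally_angles_deg < 180))
  structure(list(cylinder_diameter_cm = cylinder_diameter_cm,
                 cylinder_height_cm = cylinder_height_cm,
                 field_cm = field_cm, sid_cm = sid_cm,
                 tally_angles_deg = tally_angles_deg,
                 tally_dist_cm = tally_dist_cm,
                 tally_half_angle_deg = tally_half_angle_deg),
            class = "scatter_geometry")
}

#' Simulate scatter fluence spectra from the water phantom
#'
#' Photon histories are sampled from the primary spectrum of `spec` and
#' the divergent field, transported through water (photoelectric
#' absorption, free-electron Klein-Nishina incoherent scattering, and
#' form-factor coherent scattering), terminated below a 10-keV cutoff,
#' and scored by a track-length estimator in 1-keV bins as they stream
#' through the tally regions. A boundary-crossing estimate is kept
#' alongside as an internal cross-check.
#'
#' @param spec A [beam_spec()].
#' @param geometry A [scatter_geometry()].
#' @param n_histories Total histories (split into `n_batches`).
#' @param seed Integer seed; identical seed and histories reproduce the
#'   tallies bitwise.
#' @param n_batches Batches for the statistical-uncertainty estimate.
#' @param single_scatter_only Diagnostic mode: photons stream out
#'   unattenuated after their first scatter (isolates Compton kinematics).
#' @param coherent Include coherent scattering.
#' @param cutoff_kev Photon termination energy.
#' @param n_azimuthal Number of azimuthal replicas of each tally sphere
#'   around the beam axis. The geometry is rotationally symmetric about
#'   the axis, so replicating the in-plane tally around its ring leaves
#'   the expectation unchanged while improving the statistics about
#'   n_azimuthal-fold. Set 1 to score strictly the in-plane region.
#' @return A list of `scatter_tally` objects (one per angle) with fields
#'   `angle_deg`, `energy_kev` (1-keV bin midpoints), `fluence`
#'   (track-length, per history), `fluence_bc` (boundary-crossing),
#'   `rel_unc` (per-bin relative standard error from batch variance),
#'   `n_histories`, `seed`.
#' @export
simulate_scatter <- function(spec, geometry = scatter_geometry(),
                             n_histories = 2e6, seed = 1L,
                             n_batches = 20L, single_scatter_only = FALSE,
                             coherent = TRUE, cutoff_kev = 10,
                             n_azimuthal = 24L) {
  stopifnot(n_histories >= 1)
  sp <- as_spectrum(spec)
  w <- sp$fluence * diff(sp$bin_edges)
  cdf <- cumsum(w) / sum(w)
  wat <- mc_material("water", coherent = coherent)
  ff <- ff_table("water")
  tally_radius <- geometry$tally_dist_cm *
    tan(geometry$tally_half_angle_deg * pi / 180)
  res <- cpp_scatter_sim(sp$energy_kev, cdf, wat, ff,
                         geometry$cylinder_diameter_cm / 2,
                         geometry$cylinder_height_cm / 2,
                         geometry$sid_cm, geometry$field_cm,
                         geometry$tally_angles_deg,
                         geometry$tally_dist_cm, tally_radius,
                         sp$kv_max, cutoff_kev,
                         as.integer(n_histories), as.integer(n_batches),
                         as.integer(seed), single_scatter_only, coherent,
                         as.integer(n_azimuthal))
  lapply(seq_along(geometry$tally_angles_deg), function(a) {
    m <- res$track_length[[a]]
    mb <- res$boundary_cross[[a]]
    fl <- rowMeans(m)
    se <- apply(m, 1, stats::sd) / sqrt(ncol(m))
    structure(list(angle_deg = geometry$tally_angles_deg[a],
                   energy_kev = seq_len(res$n_bin) - 0.5,
                   fluence = fl, fluence_bc = rowMeans(mb),
                   rel_unc = ifelse(fl > 0, se / fl, NA_real_),
                   n_histories = res$histories, seed = seed,
                   beam = if (inherits(spec, "beam_spec")) spec else NULL,
                   geometry = geometry),
              class = "scatter_tally")
  })
}

#' Beam-quality metrics of a tallied scatter spectrum
#'
#' Treats the tallied fluence as an incident spectrum and computes its
#' lead TVLs (and Al HVLs) through the same air-kerma-weighted narrow
#' transmission used for primary beams.
#'
#' @param tally A `scatter_tally` (or any `fluence_spectrum`).
#' @return A `beam_quality_metrics` object.
#' @export
scatter_quality <- function(tally) {
  beam_quality(as_tally_spectrum(tally))
}

as_tally_spectrum <- function(tally) {
  if (inherits(tally, "fluence_spectrum")) return(tally)
  stopifnot(inherits(tally, "scatter_tally"))
  keep <- tally$energy_kev >= 5
  if (!any(tally$fluence[keep] > 0))
    stop("degenerate input: empty scatter tally", call. = FALSE)
  e <- tally$energy_kev[keep]
  fluence_spectrum(c(e - 0.5, max(e) + 0.5), tally$fluence[keep])
}

#' @export
print.scatter_tally <- function(x, ...) {
  cat(sprintf(
    "<scatter_tally> %g deg, %d bins, %.3g histories, max rel. unc. (top bins) %.2g\n",
    x$angle_deg, length(x$fluence), x$n_histories,
    max(x$rel_unc[x$fluence > 0.5 * max(x$fluence)], na.rm = TRUE)))
  invisible(x)
}

#' Monte Carlo estimate of the lead buildup factor
#'
#' Reproduces the broad-beam layout (point detector on the beam axis, a
#' lead sheet just upstream, a wide cone irradiating it): the ratio of
#' air kerma at the detector including secondary photons from the sheet
#' (K-shell fluorescence, Compton and coherent scatter, estimated with a
#' next-event point-detector estimator at every collision) to the
#' primary-only air kerma.
#'
#' @param spec A [beam_spec()].
#' @param lead_thickness_mm Sheet thickness (> 0).
#' @param broad_geometry List with `source_detector_cm` (default 130),
#'   `sheet_detector_cm` (default 3) and `field_diameter_cm` (default 30
#'   at the sheet).
#' @param n_histories Histories (default 2e5; the next-event estimator
#'   converges quickly).
#' @param seed,n_batches As in [simulate_scatter()].
#' @param max_order Maximum collisions followed per history.
#' @param forward_acceptance_deg Half-angle of the forward cone within
#'   which deflected photons are still registered as primary by the
#'   narrow-beam reference geometry (shield midway between source and a
#'   5-cm detector aperture gives about 2 degrees); such scatter cancels
#'   in the broad/narrow ratio and is excluded from the secondary
#'   estimate. Set 0 to score strictly all scatter.
#' @return List with `b` (buildup factor >= 1), `se` (batch standard
#'   error), `kp`, `ks`, `n_histories`, `seed`.
#' @export
simulate_buildup <- function(spec, lead_thickness_mm,
                             broad_geometry = list(source_detector_cm = 130,
                                                   sheet_detector_cm = 3,
                                                   field_diameter_cm = 30),
                             n_histories = 2e5, seed = 1L, n_batches = 10L,
                             max_order = 4L, forward_acceptance_deg = 2) {
  stopifnot(inherits(spec, "beam_spec"), lead_thickness_mm > 0)
  g <- broad_geometry
  need <- c("source_detector_cm", "sheet_detector_cm", "field_diameter_cm")
  if (!all(need %in% names(g)))
    stop("broad_geometry must supply ", paste(need, collapse = ", "),
         call. = FALSE)
  sp <- make_spectrum(spec)
  w <- sp$fluence * diff(sp$bin_edges)
  # Coherent scattering participates in attenuation and in analog
  # transport, but is not scored as a secondary: it is elastic and
  # quasi-forward, so it rides with the primary beam in the broad and the
  # narrow geometry alike (independent-atom Rayleigh would grossly
  # overstate small-angle elastic scatter from solid lead anyway). The
  # scored buildup mechanisms are K fluorescence and Compton scatter.
  pb <- mc_material("Pb", with_ncoh = FALSE)
  ff <- ff_table("Pb")
  air <- attenuation_table("air")
  t_cm <- lead_thickness_mm / 10
  slab_entry <- g$source_detector_cm - g$sheet_detector_cm - t_cm
  cone_cos <- cos(atan((g$field_diameter_cm / 2) / slab_entry))
  res <- cpp_buildup_sim(sp$energy_kev, w, pb, ff,
                         air$energies, air$muen_over_rho,
                         slab_entry, g$source_detector_cm, cone_cos, t_cm,
                         88.005, 0.78, 0.96,
                         c(74.97, 72.80, 84.94), c(0.52, 0.30, 0.18),
                         10, cos(forward_acceptance_deg * pi / 180),
                         as.integer(n_histories), as.integer(n_batches),
                         as.integer(seed), as.integer(max_order))
  ks <- mean(res$ks_batch)
  se <- stats::sd(res$ks_batch) / sqrt(length(res$ks_batch)) / res$kp
  list(b = 1 + ks / res$kp, se = se, kp = res$kp, ks = ks,
       n_histories = res$histories, seed = seed)
}
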