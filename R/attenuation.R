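#' @useDynLib pbeq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats uniroot optim rlnorm runif median approx setNames
#' @importFrom utils read.csv write.csv packageVersion
"_PACKAGE"

# Package-level cache for parsed attenuation tables (loaded lazily once).
.pbeq_cache <- new.env(parent = emptyenv())

#' Materials with bundled attenuation data
#'
#' @return Character vector of material identifiers accepted by [mu()],
#'   [muen()] and the filtration arguments of the spectrum functions.
#' @export
attenuation_materials <- function() c("Al", "Cu", "Pb", "W", "air", "water")

#' Load the bundled attenuation table for a material
#'
#' Tables give the photon mass attenuation coefficient \eqn{\mu/\rho} and,
#' where tabulated, the mass energy-absorption coefficient
#' \eqn{\mu_{en}/\rho} (both cm^2/g) on the standard 1--150 keV compilation
#' grid. Absorption edges appear as duplicated grid energies so that
#' interpolation never crosses an edge.
#'
#' @param material One of [attenuation_materials()].
#' @return An object of class `attenuation_table` with fields `material`,
#'   `energies` (keV), `mu_over_rho`, `muen_over_rho` (cm^2/g, may be `NULL`),
#'   `density` (g/cm^3) and `edges` (keV).
#' @export
attenuation_table <- function(material) {
  material <- match_material(material)
  key <- paste0("att_", material)
  if (!is.null(.pbeq_cache[[key]])) return(.pbeq_cache[[key]])
  path <- system.file("extdata", paste0("mu_", material, ".csv"),
                      package = "pbeq", mustWork = TRUE)
  hdr <- readLines(path, n = 20L)
  hdr <- hdr[startsWith(hdr, "#")]
  density <- as.numeric(sub(".*density_g_cm3:\\s*", "",
                            grep("density_g_cm3:", hdr, value = TRUE)))
  edge_line <- sub(".*edges_keV:\\s*", "", grep("edges_keV:", hdr, value = TRUE))
  edges <- as.numeric(strsplit(trimws(edge_line), "\\s+")[[1]])
  edges <- edges[is.finite(edges)]
  d <- read.csv(path, comment.char = "#")
  stopifnot(all(diff(d$energy_keV) >= 0), all(d$mu_over_rho > 0))
  muen <- d$muen_over_rho
  if (all(is.na(muen))) muen <- NULL else stopifnot(all(muen > 0))
  tab <- structure(list(material = material,
                        energies = d$energy_keV,
                        mu_over_rho = d$mu_over_rho,
                        muen_over_rho = muen,
                        density = density,
                        edges = edges),
                   class = "attenuation_table")
  .pbeq_cache[[key]] <- tab
  tab
}

match_material <- function(material) {
  m <- attenuation_materials()
  hit <- m[tolower(m) == tolower(material)]
  if (length(hit) != 1L)
    stop("unknown material '", material, "'; known: ",
         paste(m, collapse = ", "), call. = FALSE)
  hit
}

# Segment-restricted log-log interpolation. Duplicated edge energies split
# the grid into segments; a query strictly between two nodes uses only that
# pair, so values just below an edge never mix with supra-edge physics.
# A query exactly at a duplicated edge energy returns the supra-edge value.
loglog_interp <- function(x, xq, y) {
  i <- findInterval(xq, x, all.inside = TRUE)
  # findInterval with duplicated nodes can land on a zero-width segment
  # (exactly at an edge); step past it to the supra-edge segment.
  zero <- x[i + 1L] == x[i]
  i[zero] <- i[zero] + 1L
  i <- pmin(i, length(x) - 1L)
  x0 <- x[i]; x1 <- x[i + 1L]
  w <- log(xq / x0) / log(x1 / x0)
  exp((1 - w) * log(y[i]) + w * log(y[i + 1L]))
}

coeff_query <- function(material, energy_keV, what = c("mu", "muen")) {
  what <- match.arg(what)
  tab <- attenuation_table(material)
  if (any(!is.finite(energy_keV)))
    stop("non-finite energy", call. = FALSE)
  if (any(energy_keV < min(tab$energies) | energy_keV > max(tab$energies)))
    stop("energy outside tabulated range [", min(tab$energies), ", ",
         max(tab$energies), "] keV for ", material, call. = FALSE)
  y <- if (what == "mu") tab$mu_over_rho else tab$muen_over_rho
  if (is.null(y))
    stop("muen/rho not tabulated for ", material, call. = FALSE)
  loglog_interp(tab$energies, energy_keV, y)
}

#' Mass attenuation coefficient
#'
#' Log-log interpolation of the bundled table, restricted to the segment
#' between bracketing grid points so that absorption edges are respected.
#'
#' @param material One of [attenuation_materials()].
#' @param energy_keV Photon energy (keV), vectorized; must lie within the
#'   tabulated 1--150 keV range.
#' @return \eqn{\mu/\rho} in cm^2/g.
#' @examples
#' mu("Pb", 89) > mu("Pb", 87)  # K-edge jump
#' @export
mu <- function(material, energy_keV) coeff_query(material, energy_keV, "mu")

#' Mass energy-absorption coefficient
#'
#' @inheritParams mu
#' @return \eqn{\mu_{en}/\rho} in cm^2/g.
#' @export
muen <- function(material, energy_keV) coeff_query(material, energy_keV, "muen")

#' Density of a bundled material
#' @inheritParams mu
#' @return Density in g/cm^3.
#' @export
material_density <- function(material) attenuation_table(material)$density

#' Mass-weighted mixture of attenuation tables
#'
#' Combines bundled materials by mass fraction (mixture rule) on the union
#' of their grids. Intended for ad-hoc composite shields; the bundled air
#' and water tables are compiled directly, not built through this helper.
#'
#' @param fractions Named numeric vector of mass fractions (summing to 1);
#'   names are materials from [attenuation_materials()].
#' @param density Bulk density of the mixture in g/cm^3.
#' @return An `attenuation_table`.
#' @export
mixture_table <- function(fractions, density) {
  stopifnot(abs(sum(fractions) - 1) < 1e-6, density > 0)
  mats <- names(fractions)
  tabs <- lapply(mats, attenuation_table)
  grid <- sort(unique(unlist(lapply(tabs, `[[`, "energies"))))
  lo <- max(vapply(tabs, function(t) min(t$energies), 0))
  hi <- min(vapply(tabs, function(t) max(t$energies), 0))
  grid <- grid[grid >= lo & grid <= hi]
  mu_mix <- rowSums(mapply(function(t, f) f * loglog_interp(t$energies, grid, t$mu_over_rho),
                           tabs, fractions))
  have_muen <- !vapply(tabs, function(t) is.null(t$muen_over_rho), TRUE)
  muen_mix <- NULL
  if (all(have_muen))
    muen_mix <- rowSums(mapply(function(t, f) f * loglog_interp(t$energies, grid, t$muen_over_rho),
                               tabs, fractions))
  structure(list(material = paste0("mix(", paste(mats, collapse = "+"), ")"),
                 energies = grid, mu_over_rho = mu_mix,
                 muen_over_rho = muen_mix, density = density,
                 edges = sort(unique(unlist(lapply(tabs, `[[`, "edges"))))),
            class = "attenuation_table")
}

#' @export
print.attenuation_table <- function(x, ...) {
  cat("<attenuation_table>", x$material,
      sprintf("| %d grid points, %.4g-%.4g keV | rho = %g g/cm3\n",
              length(x$energies), min(x$energies), max(x$energies), x$density))
  if (length(x$edges)) cat("  edges (keV):", paste(x$edges, collapse = ", "), "\n")
  invisible(x)
}
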