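#' Specify an x-ray tube beam
#'
#' A beam is defined by the tube voltage, the anode inclination and an
#' ordered list of external filters. Filters are applied in order with
#' Beer--Lambert attenuation (order is immaterial in the narrow-beam model,
#' but it is preserved for provenance). The typical inherent filtration of
#' a clinical tube is represented explicitly as a 3 mm Al filter rather
#' than being folded into the anode model.
#'
#' @param kv Tube voltage in kV (peak). Calibrated range 40--150.
#' @param anode_angle_deg Anode inclination in degrees (default 12, a common
#'   value for interventional tubes).
#' @param filters Either a data frame with columns `material` and
#'   `thickness_mm`, or a compact string such as `"Al:3.0;Cu:0.2"`.
#' @param label Free-text label carried through to outputs.
#' @return An object of class `beam_spec`.
#' @examples
#' beam_spec(90, filters = "Al:3.0;Cu:0.2")
#' @export
beam_spec <- function(kv, anode_angle_deg = 12, filters = "Al:3.0",
                      label = NULL) {
  if (!is.numeric(kv) || length(kv) != 1L || kv < 40 || kv > 150)
    stop("kv must be a single value in the calibrated range [40, 150]",
         call. = FALSE)
  if (anode_angle_deg <= 0) stop("anode_angle_deg must be > 0", call. = FALSE)
  filters <- parse_filters(filters)
  if (any(filters$thickness_mm < 0))
    stop("filter thicknesses must be >= 0", call. = FALSE)
  if (is.null(label))
    label <- paste0(kv, "kV/", paste(sprintf("%s:%g", filters$material,
                                             filters$thickness_mm),
                                     collapse = ";"))
  structure(list(kv = kv, anode_angle_deg = anode_angle_deg,
                 filters = filters, label = label),
            class = "beam_spec")
}

#' Parse a compact filter string
#'
#' @param x `"MAT:MM"` tokens separated by `";"`, e.g. `"Al:3.0;Cu:0.2"`,
#'   or an already-conforming data frame. An empty string means no filters.
#' @return Data frame with columns `material`, `thickness_mm`.
#' @export
parse_filters <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("material", "thickness_mm") %in% names(x)))
    x$material <- vapply(x$material, match_material, "")
    return(x[, c("material", "thickness_mm")])
  }
  if (length(x) == 1L && (is.na(x) || !nzchar(trimws(x))))
    return(data.frame(material = character(), thickness_mm = numeric()))
  toks <- strsplit(trimws(unlist(strsplit(x, ";", fixed = TRUE))), ":",
                   fixed = TRUE)
  bad <- lengths(toks) != 2L
  if (any(bad)) stop("malformed filter token; expected MAT:MM", call. = FALSE)
  data.frame(material = vapply(toks, function(t) match_material(t[[1]]), ""),
             thickness_mm = vapply(toks, function(t) as.numeric(t[[2]]), 0))
}

format_filters <- function(filters) {
  if (nrow(filters) == 0L) return("")
  paste(sprintf("%s:%g", filters$material, filters$thickness_mm),
        collapse = ";")
}

#' @export
print.beam_spec <- function(x, ...) {
  cat(sprintf("<beam_spec> %g kV, %g deg anode, filters: %s\n",
              x$kv, x$anode_angle_deg,
              if (nrow(x$filters)) format_filters(x$filters) else "none"))
  invisible(x)
}
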