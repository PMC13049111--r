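# Run configuration, synthetic-measurement fixtures, measurement-file I/O
# and the batch report — the plumbing that makes every computational
# module testable without instruments.

#' Run configuration
#'
#' Bundles the knobs shared by batch runs; serialized (with a content
#' hash and the package version) into every report so a run can be
#' reproduced exactly.
#'
#' @param seed Integer seed for all randomness.
#' @param n_histories,n_batches Monte Carlo scale.
#' @param buildup_source `"table"` (bundled empirical anchors) or `"mc"`
#'   (estimate B with [simulate_buildup()] per measurement).
#' @param u_rel Relative standard uncertainty assigned to measured
#'   transmissions (propagated to thickness, k = 2).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n_histories = 2e6, n_batches = 20L,
                       buildup_source = c("table", "mc"), u_rel = 0.02) {
  buildup_source <- match.arg(buildup_source)
  structure(list(seed = as.integer(seed), n_histories = n_histories,
                 n_batches = as.integer(n_batches),
                 buildup_source = buildup_source, u_rel = u_rel,
                 package_version = as.character(packageVersion("pbeq"))),
            class = "run_config")
}

config_hash <- function(config) {
  # small FNV-1a over the serialized config; stable across sessions
  s <- utf8ToInt(paste(names(config), vapply(config, paste, ""),
                       collapse = "|"))
  h <- 5381
  for (b in s) h <- (h * 31 + b) %% 1000000007
  sprintf("%08x", h)
}

#' Generate a synthetic transmission measurement
#'
#' Forward-models a reading pair for a known true lead thickness:
#' narrow-beam transmission is the computed T_N(Q, t); broad-beam
#' transmission is T_N(Q, t) x B(Q, t) (the shield's secondaries raise
#' the reading). Multiplicative lognormal noise of relative sigma
#' `noise_rel` is applied to each reading independently.
#'
#' @param spec A [beam_spec()].
#' @param true_pb_mm True lead thickness (>= 0).
#' @param geometry `"narrow"` or `"broad"`.
#' @param noise_rel Relative noise sigma (>= 0; 0 gives exact readings).
#' @param seed Integer seed (reproducible).
#' @param model Buildup model for the broad geometry.
#' @param k_air_without Free-in-air reading scale (arbitrary units).
#' @return A [transmission_measurement()].
#' @export
generate_synthetic_measurement <- function(spec, true_pb_mm,
                                           geometry = c("narrow", "broad"),
                                           noise_rel = 0, seed = 1L,
                                           model = buildup_model(),
                                           k_air_without = 100) {
  geometry <- match.arg(geometry)
  stopifnot(true_pb_mm >= 0, noise_rel >= 0)
  tn <- narrow_transmission(spec, "Pb", true_pb_mm)
  tr <- if (geometry == "broad" && true_pb_mm > 0)
    min(tn * buildup_factor(model, spec, true_pb_mm), 1) else tn
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  noise <- if (noise_rel > 0)
    rlnorm(2, meanlog = -noise_rel^2 / 2, sdlog = noise_rel) else c(1, 1)
  k0 <- k_air_without * noise[1]
  k1 <- min(tr * k_air_without * noise[2], k0)
  transmission_measurement(spec, geometry, k_air_with = k1,
                           k_air_without = k0,
                           specified_pbeq_mm = true_pb_mm,
                           label = sprintf("synthetic %s t=%g", geometry,
                                           true_pb_mm))
}

#' Write / read a measurement CSV
#'
#' Columns: `label, kv, anode_angle_deg, filters, geometry, k_with,
#' k_without, c_with, c_without, specified_pbeq_mm`; `filters` uses the
#' compact `"MAT:MM;MAT:MM"` encoding of [parse_filters()].
#'
#' @param measurements List of [transmission_measurement()] objects.
#' @param path File path.
#' @export
write_measurement_csv <- function(measurements, path) {
  if (!length(measurements)) {
    writeLines(paste(c("label", "kv", "anode_angle_deg", "filters",
                       "geometry", "k_with", "k_without", "c_with",
                       "c_without", "specified_pbeq_mm"), collapse = ","),
               path)
    return(invisible(path))
  }
  rows <- do.call(rbind, lapply(measurements, function(m)
    data.frame(label = m$label, kv = m$beam$kv,
               anode_angle_deg = m$beam$anode_angle_deg,
               filters = format_filters(m$beam$filters),
               geometry = m$geometry, k_with = m$k_air_with,
               k_without = m$k_air_without,
               c_with = m$correction_with, c_without = m$correction_without,
               specified_pbeq_mm = m$specified_pbeq_mm)))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurement_csv
#' @export
read_measurement_csv <- function(path) read.csv(path)

#' Batch lead-equivalence report
#'
#' Processes every row of a measurement CSV: inverts the transmission to
#' a lead-equivalent thickness (narrow or broad as recorded), propagates
#' the configured transmission uncertainty, and checks IEC compliance
#' where a specified lead equivalence is present. Malformed rows become
#' per-row error records; the run continues.
#'
#' @param path Measurement CSV in the dialect of
#'   [write_measurement_csv()].
#' @param config A [run_config()].
#' @param out_csv,out_json Optional output paths; the JSON carries the
#'   config, its hash and the package version alongside the rows.
#' @return Data frame with one row per input row: `t_mm`, `u_t_mm`
#'   (k = 2), `buildup`, `transmission`, `compliance_pass`, `margin`,
#'   `error` (NA unless the row failed).
#' @export
run_report <- function(path, config = run_config(), out_csv = NULL,
                       out_json = NULL) {
  d <- read_measurement_csv(path)
  empty <- data.frame(label = character(), t_mm = numeric(),
                      u_t_mm = numeric(), buildup = numeric(),
                      transmission = numeric(), compliance_pass = logical(),
                      margin = numeric(), error = character())
  if (nrow(d) == 0L) warning("empty measurement file; empty report")
  model <- buildup_model()
  rows <- lapply(seq_len(nrow(d)), function(i) {
    r <- d[i, ]
    base <- data.frame(label = as.character(r$label), t_mm = NA_real_,
                       u_t_mm = NA_real_, buildup = NA_real_,
                       transmission = NA_real_,
                       compliance_pass = NA, margin = NA_real_,
                       error = NA_character_)
    tryCatch({
      beam <- beam_spec(r$kv, r$anode_angle_deg, filters = r$filters)
      m <- transmission_measurement(beam, r$geometry, r$k_with, r$k_without,
                                    correction_with = r$c_with,
                                    correction_without = r$c_without,
                                    specified_pbeq_mm = r$specified_pbeq_mm,
                                    label = as.character(r$label))
      res <- if (m$geometry == "narrow")
        lead_equivalence_narrow(m, u_rel = config$u_rel)
      else lead_equivalence_broad(m, model, u_rel = config$u_rel)
      base$t_mm <- res$t_mm
      base$u_t_mm <- res$u_t_mm
      base$buildup <- res$buildup
      base$transmission <- res$transmission
      if (is.finite(m$specified_pbeq_mm) && m$specified_pbeq_mm > 0) {
        cc <- compliance_check(res, m$specified_pbeq_mm)
        base$compliance_pass <- cc$pass
        base$margin <- cc$margin
      }
      base
    }, error = function(e) {
      base$error <- conditionMessage(e)
      base
    })
  })
  rep <- if (length(rows)) do.call(rbind, rows) else empty
  attr(rep, "config") <- config
  attr(rep, "config_hash") <- config_hash(config)
  if (!is.null(out_csv)) write.csv(rep, out_csv, row.names = FALSE)
  if (!is.null(out_json))
    jsonlite::write_json(list(config = unclass(config),
                              config_hash = config_hash(config),
                              rows = rep),
                         out_json, auto_unbox = TRUE, digits = NA,
                         na = "null")
  rep
}
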