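# Scatter-mimicking primary-beam designer: exhaustive grid search over
# tube voltage and copper filtration, matching lead TVL metrics of a
# target (typically a Monte Carlo scatter spectrum).

surrogate_grid_metrics <- function(kv_grid = 40:120,
                                   cu_grid = seq(0, 1, by = 0.1),
                                   al_mm = 3.0) {
  key <- sprintf("surrogate_grid_%s", paste0(range(kv_grid), collapse = "_"))
  if (!is.null(.pbeq_cache[[key]])) return(.pbeq_cache[[key]])
  rows <- expand.grid(kv = kv_grid, cu = cu_grid)
  tv <- t(vapply(seq_len(nrow(rows)), function(i) {
    f <- data.frame(material = c("Al", "Cu"),
                    thickness_mm = c(al_mm, rows$cu[i]))
    f <- f[f$thickness_mm > 0, ]
    sp <- make_spectrum(beam_spec(rows$kv[i], filters = f))
    tvl1 <- thickness_for_transmission(sp, "Pb", 0.1)
    tvl12 <- thickness_for_transmission(sp, "Pb", 0.01)
    c(tvl1 = tvl1, tvl12 = tvl12)
  }, c(tvl1 = 0, tvl12 = 0)))
  out <- cbind(rows, tv)
  out$tvl2 <- out$tvl12 - out$tvl1
  .pbeq_cache[[key]] <- out
  out
}

#' Find a primary tube beam matching target lead TVL metrics
#'
#' Exhaustive search over tube voltage (40--120 kV, 1-kV steps) and added
#' copper (0--1 mm, 0.1-mm steps) with a fixed 3 mm Al filter. A
#' candidate qualifies when its TVL1, TVL2 and TVL1+2 in lead each match
#' the target within the relative `margin`; among qualifiers the least
#' copper, then the lowest voltage, is selected (minimizing tube load).
#' If none qualifies the least-worst candidate is reported with
#' `matched = FALSE`.
#'
#' @param target A `beam_quality_metrics` (e.g. from [scatter_quality()])
#'   or a list with `tvl1_mm_pb` and `tvl12_mm_pb`.
#' @param margin Relative matching margin (default 0.05).
#' @return A `surrogate_result`: `kv`, `cu_mm`, `matched`, `rel_errors`
#'   (TVL1, TVL2, TVL1+2), `candidates_within_margin`.
#' @export
match_surrogate <- function(target, margin = 0.05) {
  tvl1 <- target$tvl1_mm_pb
  tvl12 <- target$tvl12_mm_pb
  if (is.null(tvl1) || is.null(tvl12) || !is.finite(tvl1) ||
      !is.finite(tvl12) || tvl1 <= 0 || tvl12 <= tvl1)
    stop("target must supply positive tvl1_mm_pb < tvl12_mm_pb",
         call. = FALSE)
  tvl2 <- tvl12 - tvl1
  g <- surrogate_grid_metrics()
  err <- cbind(abs(g$tvl1 - tvl1) / tvl1,
               abs(g$tvl2 - tvl2) / tvl2,
               abs(g$tvl12 - tvl12) / tvl12)
  worst <- apply(err, 1, max)
  ok <- worst <= margin
  if (any(ok)) {
    cand <- which(ok)
    # total order: least Cu, then lowest kV
    sel <- cand[order(g$cu[cand], g$kv[cand])][1]
    matched <- TRUE
  } else {
    sel <- which.min(worst)
    matched <- FALSE
  }
  structure(list(kv = g$kv[sel], cu_mm = g$cu[sel], matched = matched,
                 rel_errors = setNames(err[sel, ],
                                       c("tvl1", "tvl2", "tvl12")),
                 candidates_within_margin = sum(ok),
                 target = list(tvl1_mm_pb = tvl1, tvl12_mm_pb = tvl12)),
            class = "surrogate_result")
}

#' Recommended scatter-mimicking test beams
#'
#' The three beams proposed in this framework (soft, intermediate, hard:
#' 50 kV/no Cu, 75 kV/0.1 mm Cu, 100 kV/0.2 mm Cu, each behind 3 mm Al)
#' and the three ASTM F3094-style beams, with their tabulated first Al
#' HVLs and lead buildup factors attached.
#'
#' @return Data frame with a `beam` list-column of [beam_spec()] objects,
#'   tabulated `hvl` (mm Al) and buildup factors `b025`...`b100`.
#' @export
recommended_beams <- function() {
  d <- .buildup_anchors()
  d <- d[order(d$source, decreasing = TRUE), ]  # this-work first
  d$beam <- lapply(seq_len(nrow(d)), function(i) {
    f <- data.frame(material = c("Al", "Cu"),
                    thickness_mm = c(d$al[i], d$cu[i]))
    beam_spec(d$kv[i], filters = f[f$thickness_mm > 0, ],
              label = sprintf("%s %g kV", d$source[i], d$kv[i]))
  })
  rownames(d) <- NULL
  d
}

#' @export
print.surrogate_result <- function(x, ...) {
  cat(sprintf(
    "<surrogate_result> %d kV + %.1f mm Cu (%s; %d candidate(s) within margin; worst rel. err %.3f)\n",
    x$kv, x$cu_mm, if (x$matched) "matched" else "least-worst",
    x$candidates_within_margin, max(x$rel_errors)))
  invisible(x)
}
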