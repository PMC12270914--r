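# Composite intrinsic capacity (IC) score.
#
# Scoring pipeline: strict complete-case filtering over the five domains,
# rescaling of each instrument to [0,1] with "higher is better" (PHQ-9
# reversed), averaging of the vision and hearing scores into one sensory
# domain, per-domain z-transform, row-mean of the five z-scores, and finally
# cohort min-max normalization so the overall IC spans exactly [0,1].

#' Domain specifications for the five IC instruments
#'
#' MMSE (cognition, 0-30, higher better), SPPB (locomotion, 0-12, higher
#' better), PHQ-9 (psychological, 0-27, higher worse), WHO simple eye chart
#' (vision, 0-3), whisper test (hearing, 0-2), and handgrip strength
#' (vitality), which has no fixed bounds: the cohort-observed minimum and
#' maximum define its rescaling.
#'
#' @return data.frame with columns name, min, max, direction.
#' @export
default_domain_specs <- function() {
  data.frame(
    name = c("cognition", "locomotion", "psychological",
             "sensory_vision", "sensory_hearing", "vitality"),
    min = c(0, 0, 0, 0, 0, NA),
    max = c(30, 12, 27, 3, 2, NA),
    direction = c("higher_better", "higher_better", "higher_worse",
                  "higher_better", "higher_better", "higher_better"),
    stringsAsFactors = FALSE
  )
}

#' Keep only participants assessed in all five domains
#'
#' @param cohort cohort data.frame containing the six raw-score columns.
#' @param domains raw-score column names to require.
#' @return the complete-case subset, with the number of removed rows
#'   attached as `attr(, "n_removed")`.
#' @export
complete_case_filter <- function(cohort,
                                 domains = default_domain_specs()$name) {
  missing_cols <- setdiff(domains, names(cohort))
  if (length(missing_cols)) {
    stop_ic("cohort lacks domain columns: ",
            paste(missing_cols, collapse = ", "),
            class = "icclock_contract_error")
  }
  keep <- stats::complete.cases(cohort[, domains, drop = FALSE])
  if (!any(keep)) {
    stop_ic("no complete cases across the five IC domains",
            class = "icclock_no_complete_cases")
  }
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Rescale a raw domain score to the unit interval
#'
#' `(raw - min) / (max - min)`, then reversed (`1 - value`) for instruments
#' where higher raw scores are worse (PHQ-9). For unbounded instruments pass
#' the cohort-observed extremes as `min`/`max`.
#'
#' @param raw numeric raw scores (NA propagates).
#' @param min,max instrument bounds.
#' @param direction `"higher_better"` or `"higher_worse"`.
#' @return scores in \[0,1\].
#' @export
rescale_domain <- function(raw, min, max, direction = "higher_better") {
  if (!is.finite(min) || !is.finite(max) || max <= min) {
    stop_ic("degenerate domain bounds: min=", min, ", max=", max,
            class = "icclock_degenerate_domain")
  }
  ok <- is.na(raw) | (raw >= min & raw <= max)
  if (!all(ok)) {
    stop_ic("raw scores outside declared bounds [", min, ", ", max, "]: ",
            paste(utils::head(raw[!ok], 3), collapse = ", "),
            class = "icclock_range_error")
  }
  val <- (raw - min) / (max - min)
  if (identical(direction, "higher_worse")) val <- 1 - val
  val
}

#' Sensory domain score
#'
#' Arithmetic mean of the rescaled visual and hearing scores; a missing
#' input propagates so that the participant is dropped by the complete-case
#' rule.
#'
#' @param vision,hearing unit-interval scores.
#' @return unit-interval sensory scores.
#' @export
sensory_score <- function(vision, hearing) {
  (vision + hearing) / 2
}

#' Z-transform rescaled domain scores
#'
#' Per-domain `(x - mean) / sd` over the cohort, with the sample (n-1) sd
#' convention. Standardization parameters are attached so the same transform
#' can be reapplied to new individuals.
#'
#' @param rescaled data.frame/matrix of rescaled domain scores (no NAs).
#' @return data.frame of z-scores with `attr(, "center")` and
#'   `attr(, "scale")`.
#' @export
zscore_domains <- function(rescaled) {
  rescaled <- as.data.frame(rescaled)
  if (nrow(rescaled) < 2L) {
    stop_ic("need at least 2 participants to z-transform",
            class = "icclock_contract_error")
  }
  ctr <- vapply(rescaled, mean, numeric(1))
  scl <- vapply(rescaled, stats::sd, numeric(1))
  bad <- !is.finite(scl) | scl == 0
  if (any(bad)) {
    stop_ic("zero within-domain variance in: ",
            paste(names(rescaled)[bad], collapse = ", "),
            class = "icclock_degenerate_domain")
  }
  z <- as.data.frame(Map(function(x, m, s) (x - m) / s, rescaled, ctr, scl))
  attr(z, "center") <- ctr
  attr(z, "scale") <- scl
  z
}

#' Overall IC from domain z-scores
#'
#' Row mean of the five domain z-scores followed by cohort min-max
#' normalization, so the overall IC spans exactly \[0,1\] with 1 the best
#' observed outcome. The min-max parameters are attached for reuse.
#'
#' @param z data.frame of exactly five domain z-score columns (sensory
#'   already collapsed).
#' @return numeric overall IC in \[0,1\] with `attr(, "minmax")`.
#' @export
overall_ic <- function(z) {
  z <- as.data.frame(z)
  if (ncol(z) != 5L) {
    stop_ic("overall IC requires exactly five domain z-scores, got ",
            ncol(z), class = "icclock_contract_error")
  }
  avg <- rowMeans(z)
  lo <- min(avg); hi <- max(avg)
  if (hi <= lo) {
    stop_ic("degenerate min-max normalization: all participants identical",
            class = "icclock_degenerate_domain")
  }
  out <- (avg - lo) / (hi - lo)
  attr(out, "minmax") <- c(min = lo, max = hi)
  out
}

#' Compute the composite IC score table for a cohort
#'
#' Runs the full scoring pipeline: complete-case filter, per-instrument
#' rescaling (grip strength rescaled by cohort-observed extremes), sensory
#' averaging, z-transform, domain averaging and min-max normalization.
#'
#' @param cohort cohort data.frame with the six raw-score columns.
#' @param specs domain specification table as [default_domain_specs()].
#' @return an `ic_score_table` data.frame: participant_id, five rescaled
#'   domain scores, five z-scores (`z_` prefix) and `overall_ic`; frozen
#'   transform parameters in `attr(, "params")`, dropped-row count in
#'   `attr(, "n_removed")`.
#' @export
ic_score <- function(cohort, specs = default_domain_specs()) {
  cc <- complete_case_filter(cohort, specs$name)
  n_removed <- attr(cc, "n_removed")

  bounds <- specs
  for (i in seq_len(nrow(bounds))) {
    if (is.na(bounds$min[i]) || is.na(bounds$max[i])) {
      bounds$min[i] <- min(cc[[bounds$name[i]]])
      bounds$max[i] <- max(cc[[bounds$name[i]]])
    }
  }
  unit <- as.data.frame(lapply(seq_len(nrow(bounds)), function(i) {
    rescale_domain(cc[[bounds$name[i]]], bounds$min[i], bounds$max[i],
                   bounds$direction[i])
  }))
  names(unit) <- bounds$name

  dom <- data.frame(
    cognition = unit$cognition,
    locomotion = unit$locomotion,
    psychological = unit$psychological,
    sensory = sensory_score(unit$sensory_vision, unit$sensory_hearing),
    vitality = unit$vitality
  )
  z <- zscore_domains(dom)
  ic <- overall_ic(z)

  out <- data.frame(participant_id = cc$participant_id, dom,
                    stats::setNames(z, paste0("z_", names(z))),
                    overall_ic = as.numeric(ic),
                    stringsAsFactors = FALSE)
  attr(out, "params") <- list(bounds = bounds,
                              center = attr(z, "center"),
                              scale = attr(z, "scale"),
                              minmax = attr(ic, "minmax"))
  attr(out, "n_removed") <- n_removed
  class(out) <- c("ic_score_table", "data.frame")
  out
}
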