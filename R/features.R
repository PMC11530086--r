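# From raw cohort to analysis table: clean each patient's series, build the
# 15-second MAP grid, compute every registry definition, and join covariates
# and outcomes.

#' Compute the per-patient exposure-metric table for a cohort
#'
#' Runs [clean_artifacts()] and [interpolate_to_grid()] on every patient's
#' raw series, evaluates every registry definition on the resulting grid and
#' joins the values onto covariates and outcomes. Patients with no valid
#' blood pressure, or fewer than two surviving samples, are excluded with
#' reasons (an attrition table in the spirit of a study flowchart).
#'
#' @param cohort An `ioh_cohort` ([generate_cohort()] / [read_cohort()]).
#' @param registry Registry data frame, default [ioh_registry()].
#' @param rule6_channels Passed to [clean_artifacts()].
#' @param max_gap_s Passed to [interpolate_to_grid()].
#' @return A data frame (class `ioh_cohort_table`) with covariates, outcomes,
#'   `anesthesia_min` and one column per definition; attributes `attrition`
#'   (exclusion table), `cleaning` (aggregate per-rule removal counts) and
#'   `registry`.
#' @export
cohort_features <- function(cohort, registry = ioh_registry(),
                            rule6_channels = "all", max_gap_s = Inf) {
  stopifnot(inherits(cohort, "ioh_cohort"))
  n <- length(cohort$bp)
  rows <- vector("list", n)
  excl <- list()
  clean_counts <- NULL
  anes_min <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- cohort$bp[[i]]
    cr <- clean_artifacts(s, rule6_channels = rule6_channels)
    clean_counts <- if (is.null(clean_counts)) cr$report$removed
                    else clean_counts + cr$report$removed
    if (cr$excluded) {
      excl[[length(excl) + 1L]] <-
        data.frame(patient_id = s$patient_id,
                   reason = "no valid blood pressure")
      next
    }
    grid <- tryCatch(interpolate_to_grid(cr$series, max_gap_s = max_gap_s),
                     error = function(e) NULL)
    if (is.null(grid)) {
      excl[[length(excl) + 1L]] <-
        data.frame(patient_id = s$patient_id,
                   reason = "fewer than two valid samples")
      next
    }
    anes_min[i] <- grid$duration_min
    rows[[i]] <- compute_all_definitions(grid, registry)
  }
  ok <- !vapply(rows, is.null, logical(1))
  defs <- do.call(rbind, rows[ok])
  tab <- cbind(cohort$covariates[ok, , drop = FALSE],
               cohort$outcomes[ok, setdiff(names(cohort$outcomes),
                                           "patient_id"), drop = FALSE],
               anesthesia_min = anes_min[ok],
               as.data.frame(defs))
  rownames(tab) <- NULL
  attr(tab, "attrition") <- if (length(excl)) do.call(rbind, excl)
                            else data.frame(patient_id = character(0),
                                            reason = character(0))
  attr(tab, "cleaning") <- clean_counts
  attr(tab, "registry") <- registry
  class(tab) <- c("ioh_cohort_table", "data.frame")
  tab
}
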