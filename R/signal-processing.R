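# Artifact cleaning of intraoperative blood-pressure records and
# interpolation to a homogeneous 15-second MAP grid.

#' Construct a blood-pressure series
#'
#' @param patient_id Scalar identifier.
#' @param time_s Timestamps in seconds from anesthesia start, strictly
#'   increasing.
#' @param sbp,dbp,map Systolic / diastolic / mean arterial pressure in mmHg;
#'   `NA` marks a missing channel.
#' @return A `bp_series` object (a data frame with metadata).
#' @export
bp_series <- function(patient_id, time_s, sbp = NA_real_, dbp = NA_real_,
                      map = NA_real_) {
  n <- length(time_s)
  if (n < 1L) stop("a blood-pressure series needs at least one sample")
  if (n > 1L && any(diff(time_s) <= 0))
    stop("timestamps must be strictly increasing")
  # built without data.frame() validation overhead; hot path in simulation
  df <- list(time_s = as.numeric(time_s),
             sbp = rep_len(as.numeric(sbp), n),
             dbp = rep_len(as.numeric(dbp), n),
             map = rep_len(as.numeric(map), n))
  class(df) <- "data.frame"
  attr(df, "row.names") <- .set_row_names(n)
  structure(list(patient_id = patient_id, samples = df),
            class = "bp_series")
}

#' Mean arterial pressure from systolic and diastolic pressure
#'
#' Standard fallback `(sbp + 2 dbp) / 3`, used only for samples whose MAP
#' channel is missing.
#'
#' @param sbp,dbp Pressures in mmHg, `sbp > dbp` required.
#' @return MAP in mmHg.
#' @export
#' @examples
#' derive_map(120, 60) # 80
derive_map <- function(sbp, dbp) {
  if (any(!is.na(sbp) & !is.na(dbp) & sbp <= dbp))
    stop("derive_map requires sbp > dbp")
  (sbp + 2 * dbp) / 3
}

RULE_LABELS <- c(rule1 = "sbp >= 300 mmHg",
                 rule2 = "sbp <= 20 mmHg",
                 rule3 = "dbp <= 5 mmHg",
                 rule4 = "dbp >= 225 mmHg",
                 rule5 = "sbp <= dbp + 5 mmHg",
                 rule6 = "outside 3 SD of patient mean")

#' Apply the six artifact-cleaning rules to a blood-pressure series
#'
#' Rules 1--5 are absolute per-sample cut-offs on the raw systolic and
#' diastolic channels: (1) sbp >= 300, (2) sbp <= 20, (3) dbp <= 5,
#' (4) dbp >= 225, (5) sbp <= dbp + 5 mmHg. Rule 6 removes samples lying
#' outside three standard deviations of the patient's mean pressure, with
#' mean and SD computed once on the survivors of rules 1--5 (a single,
#' non-iterated pass). A sample violating several rules is attributed to the
#' lowest-numbered one. Samples whose MAP is missing are completed from
#' sbp/dbp via [derive_map()]; samples with no computable MAP are dropped
#' with reason `missing_pressure`.
#'
#' @param series A [bp_series()].
#' @param rule6_channels Which channels rule 6 monitors: `"all"` (default;
#'   sbp, dbp and map each checked against their own mean +/- 3 SD, removal
#'   on any violation) or `"map"` (MAP only).
#' @return A list with class `cleaning_result`: `series` (the retained
#'   samples as a `bp_series`), `report` (a `cleaning_report`: per-rule
#'   removal counts, total retained, per-sample reason codes) and
#'   `excluded` -- `TRUE` when no valid sample survives (the patient is then
#'   excluded downstream with reason `"no valid blood pressure"`).
#' @export
clean_artifacts <- function(series, rule6_channels = c("all", "map")) {
  rule6_channels <- match.arg(rule6_channels)
  stopifnot(inherits(series, "bp_series"))
  s <- series$samples
  n <- nrow(s)
  sbp <- s$sbp; dbp <- s$dbp; map <- s$map
  reason <- rep("retained", n)

  # MAP completion: samples with a missing MAP channel but valid sbp/dbp.
  can_derive <- is.na(map) & !is.na(sbp) & !is.na(dbp) & sbp > dbp
  map[can_derive] <- (sbp[can_derive] + 2 * dbp[can_derive]) / 3

  viol <- function(x) !is.na(x) & x
  rules <- list(
    rule1 = viol(sbp >= 300),
    rule2 = viol(sbp <= 20),
    rule3 = viol(dbp <= 5),
    rule4 = viol(dbp >= 225),
    rule5 = viol(!is.na(sbp) & !is.na(dbp) & sbp <= dbp + 5)
  )
  for (r in names(rules)) {
    hit <- rules[[r]] & reason == "retained"
    reason[hit] <- r
  }
  # Samples with no computable MAP that no rule claimed.
  reason[is.na(map) & reason == "retained"] <- "missing_pressure"

  # Rule 6 statistics on the survivors of rules 1-5, single pass.
  surv <- reason == "retained"
  channels <- if (rule6_channels == "all") list(sbp, dbp, map) else list(map)
  out6 <- rep(FALSE, n)
  for (x in channels) {
    xs <- x[surv & !is.na(x)]
    if (length(xs) >= 2L) {
      m <- mean(xs); sdv <- stats::sd(xs)
      out6 <- out6 | (!is.na(x) & abs(x - m) > 3 * sdv)
    }
  }
  reason[surv & out6] <- "rule6"
  s$map <- map

  keep <- reason == "retained"
  counts <- vapply(c(names(RULE_LABELS), "missing_pressure"),
                   function(r) sum(reason == r), integer(1))
  report <- structure(list(patient_id = series$patient_id,
                           removed = counts,
                           retained = sum(keep),
                           n_input = n,
                           reasons = reason,
                           rule6_channels = rule6_channels),
                      class = "cleaning_report")
  cleaned <- series
  if (all(keep)) {
    cleaned$samples <- s
  } else {
    cleaned$samples <- s[keep, , drop = FALSE]
    attr(cleaned$samples, "row.names") <- .set_row_names(sum(keep))
  }
  structure(list(series = cleaned, report = report,
                 excluded = !any(keep),
                 exclusion_reason = if (!any(keep)) "no valid blood pressure"
                                    else NA_character_),
            class = "cleaning_result")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("Cleaning report for patient %s: %d of %d samples retained\n",
              x$patient_id, x$retained, x$n_input))
  rem <- x$removed[x$removed > 0]
  if (length(rem))
    for (r in names(rem))
      cat(sprintf("  %-16s %d removed (%s)\n", r, rem[[r]],
                  RULE_LABELS[r] %||% "no computable MAP"))
  invisible(x)
}

#' Interpolate a cleaned series to a homogeneous 15-second MAP grid
#'
#' Grid ticks run every 15 s from the first to the last retained
#' measurement; values are linear between bracketing measurements and never
#' extrapolated beyond the record. Series natively on a 15-s grid pass
#' through unchanged.
#'
#' @param series A cleaned [bp_series()] with at least two samples.
#' @param max_gap_s Optional cap on the internal gap (seconds) across which
#'   interpolation is allowed; `Inf` (default) interpolates across any gap.
#' @return A `map_grid`: list with `patient_id`, `time_s` (tick timestamps),
#'   `map` (mmHg per tick), `duration_min` (anesthesia exposure time,
#'   `0.25 * number of ticks`) and `span_min` (last minus first retained
#'   timestamp). Errors for records with fewer than two surviving samples;
#'   such patients are excluded upstream.
#' @export
interpolate_to_grid <- function(series, max_gap_s = Inf) {
  stopifnot(inherits(series, "bp_series"))
  tt <- series$samples$time_s
  mp <- series$samples$map
  ok <- !is.na(mp)
  tt <- tt[ok]; mp <- mp[ok]
  if (length(tt) < 2L)
    stop("fewer than two valid samples; patient excluded", call. = FALSE)
  if (is.finite(max_gap_s) && any(diff(tt) > max_gap_s))
    stop(sprintf("internal gap exceeds max_gap_s = %g s", max_gap_s),
         call. = FALSE)
  t0 <- tt[1L]
  t1 <- tt[length(tt)]
  ticks <- seq(t0, t1, by = 15)
  vals <- stats::approx(tt, mp, xout = ticks, method = "linear",
                        rule = 1)$y
  structure(list(patient_id = series$patient_id,
                 time_s = ticks,
                 map = vals,
                 duration_min = length(ticks) * MIN_PER_TICK,
                 span_min = (t1 - t0) / 60),
            class = "map_grid")
}

#' @export
print.map_grid <- function(x, ...) {
  cat(sprintf("MAP grid, patient %s: %d ticks (%.2f min), MAP %.0f-%.0f mmHg\n",
              x$patient_id, length(x$map), x$duration_min,
              min(x$map), max(x$map)))
  invisible(x)
}
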