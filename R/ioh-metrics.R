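# Exposure metrics: the candidate definitions of intraoperative hypotension
# (IOH) computed from a homogeneous 15-second MAP grid.
#
# All metrics use the tick-exposure convention: one grid tick represents a
# 15-second (0.25-minute) interval of exposure, so "N minutes" corresponds to
# 4*N consecutive ticks and a grid of n ticks carries n/4 minutes of
# anesthesia exposure time.

TICKS_PER_MIN <- 4L
MIN_PER_TICK <- 0.25

#' Registry of candidate IOH definitions
#'
#' Builds the table of exposure metrics that are compared against each other.
#' Four families are supported: the lowest mean arterial pressure (MAP)
#' sustained continuously for a number of minutes; the lowest MAP reached for
#' a cumulative (possibly interrupted) number of minutes; the absolute time
#' with MAP under a threshold; and that time relative to the duration of
#' anesthesia.
#'
#' @param which `"tables_24"` (default) uses sustained/cumulative durations
#'   of 1, 3, 5, 10 and 15 minutes plus thresholds 50--80 mmHg in steps of 5
#'   (24 definitions); `"methods_22"` restricts durations to 1, 3, 5 and 10
#'   minutes (22 definitions). Both counts appear in the source literature on
#'   IOH metric comparisons; neither is privileged here.
#' @return A data frame with columns `name`, `kind`
#'   (`sustained_min_map`, `cumulative_min_map`, `abs_time_below`,
#'   `rel_time_below`), `parameter` (minutes or mmHg) and `label`.
#' @export
#' @examples
#' nrow(ioh_registry())            # 24
#' nrow(ioh_registry("methods_22")) # 22
ioh_registry <- function(which = c("tables_24", "methods_22")) {
  which <- match.arg(which)
  durations <- if (which == "tables_24") c(1, 3, 5, 10, 15) else c(1, 3, 5, 10)
  thresholds <- seq(50, 80, by = 5)
  reg <- rbind(
    data.frame(kind = "sustained_min_map", parameter = durations),
    data.frame(kind = "cumulative_min_map", parameter = durations),
    data.frame(kind = "abs_time_below", parameter = thresholds),
    data.frame(kind = "rel_time_below", parameter = thresholds)
  )
  reg$name <- definition_name(reg$kind, reg$parameter)
  reg$label <- ifelse(
    reg$kind == "sustained_min_map",
    sprintf("Lowest MAP sustained for %g min", reg$parameter),
    ifelse(reg$kind == "cumulative_min_map",
           sprintf("Lowest MAP for %g cumulative min", reg$parameter),
           ifelse(reg$kind == "abs_time_below",
                  sprintf("Absolute time with MAP < %g mmHg", reg$parameter),
                  sprintf("Relative time with MAP < %g mmHg", reg$parameter))))
  reg[, c("name", "kind", "parameter", "label")]
}

definition_name <- function(kind, parameter) {
  ifelse(kind == "sustained_min_map", sprintf("sust_%gmin", parameter),
  ifelse(kind == "cumulative_min_map", sprintf("cum_%gmin", parameter),
  ifelse(kind == "abs_time_below", sprintf("abs_t_lt%g", parameter),
  ifelse(kind == "rel_time_below", sprintf("rel_t_lt%g", parameter),
         NA_character_))))
}

#' Look up one definition in a registry
#'
#' @param name Definition name, e.g. `"rel_t_lt80"` or `"sust_1min"`.
#' @param registry A registry data frame from [ioh_registry()].
#' @return A one-row data frame (name, kind, parameter, label).
#' @export
ioh_definition <- function(name, registry = ioh_registry()) {
  hit <- registry[registry$name == name, , drop = FALSE]
  if (nrow(hit) != 1L)
    stop(sprintf("unknown IOH definition '%s'", name), call. = FALSE)
  hit
}

# Rolling maximum over windows of exactly `w` consecutive values.
# Uses binary composition of window maxima -- M_{a+b}[i] = max(M_a[i],
# M_b[i+a]) -- so only O(log w) vectorized pmax passes are needed.
roll_max <- function(x, w) {
  w <- as.integer(w)
  if (w > length(x)) return(numeric(0))
  roll_max_cache(x, w)$get(w)
}

# Shared composition cache: window maxima for sizes built greedily from
# powers of two. Returns closures over a plain list (cheap lookups).
roll_max_cache <- function(x, maxw) {
  n <- length(x)
  sizes <- 1L
  mats <- list(x)
  a <- 1L
  while (2L * a <= maxw) {      # powers of two up to the largest window
    M <- mats[[match(a, sizes)]]
    len <- n - 2L * a + 1L
    mats[[length(mats) + 1L]] <- pmax.int(M[seq_len(len)],
                                          M[seq_len(len) + a])
    sizes <- c(sizes, 2L * a)
    a <- 2L * a
  }
  get_m <- function(w) {
    i <- match(w, sizes)
    if (!is.na(i)) return(mats[[i]])
    a <- max(sizes[sizes < w])
    Mb <- get_m(w - a)
    Ma <- mats[[match(a, sizes)]]
    len <- n - w + 1L
    M <- pmax.int(Ma[seq_len(len)], Mb[seq_len(len) + a])
    mats[[length(mats) + 1L]] <<- M
    sizes <<- c(sizes, w)
    M
  }
  list(get = get_m)
}

# min(rolling max) for several window sizes, sharing one composition cache;
# NA where the record is shorter than the window.
roll_max_mins <- function(x, ws) {
  n <- length(x)
  ws <- as.integer(ws)
  feasible <- ws[ws <= n]
  if (!length(feasible)) return(rep(NA_real_, length(ws)))
  cache <- roll_max_cache(x, max(feasible))
  vapply(ws, function(w) {
    if (w > n) NA_real_ else min(cache$get(w))
  }, numeric(1))
}

grid_values <- function(grid) {
  if (inherits(grid, "map_grid")) grid$map else as.numeric(grid)
}

grid_duration_min <- function(grid) {
  if (inherits(grid, "map_grid")) grid$duration_min
  else length(grid) * MIN_PER_TICK
}

#' Lowest MAP sustained for a given number of minutes
#'
#' The smallest pressure threshold T such that MAP stayed at or below T
#' continuously for the full duration; equivalently the minimum over all
#' windows of `4 * duration` consecutive ticks of the maximum MAP within the
#' window. This is the upper "low MAP" limit of the patient's lowest
#' hypotensive episode of that length.
#'
#' @param grid A `map_grid` (see [interpolate_to_grid()]) or a bare numeric
#'   vector of MAP values on a 15-second grid.
#' @param duration Episode duration in minutes.
#' @return MAP in mmHg, or `NA` with attribute `reason` when the record is
#'   shorter than the requested window.
#' @export
#' @examples
#' lowest_sustained_map(c(80, 80, 70, 65, 62, 62, 66, 75), 1) # 66
lowest_sustained_map <- function(grid, duration) {
  x <- grid_values(grid)
  w <- as.integer(round(TICKS_PER_MIN * duration))
  if (w < 1L) stop("`duration` must be at least one tick (0.25 min)")
  if (length(x) < w) {
    return(structure(NA_real_, reason = "record shorter than duration"))
  }
  min(roll_max(x, w))
}

#' Lowest MAP reached for a cumulative number of minutes
#'
#' The smallest threshold T such that the total (possibly interrupted) time
#' with MAP at or below T reaches the given duration: the k-th smallest grid
#' value with `k = 4 * duration`.
#'
#' @inheritParams lowest_sustained_map
#' @return MAP in mmHg, or `NA` with attribute `reason` for short records.
#' @export
#' @examples
#' lowest_cumulative_map(c(50, 90, 50, 90, 50, 90, 50, 90), 1) # 50
lowest_cumulative_map <- function(grid, duration) {
  x <- grid_values(grid)
  k <- as.integer(round(TICKS_PER_MIN * duration))
  if (k < 1L) stop("`duration` must be at least one tick (0.25 min)")
  if (length(x) < k) {
    return(structure(NA_real_, reason = "record shorter than duration"))
  }
  sort(x, partial = k)[k]
}

#' Absolute time with MAP under a threshold
#'
#' @inheritParams lowest_sustained_map
#' @param threshold MAP threshold in mmHg; ticks strictly below it count.
#' @return Minutes (each tick contributes 0.25 min).
#' @export
time_below <- function(grid, threshold) {
  x <- grid_values(grid)
  if (length(x) == 0L) stop("empty grid")
  MIN_PER_TICK * sum(x < threshold)
}

#' Relative time with MAP under a threshold
#'
#' Time below the threshold divided by the anesthesia exposure duration,
#' clipped to \[0, 1\].
#'
#' @inheritParams time_below
#' @return Fraction in \[0, 1\], or `NA` for a zero-duration record.
#' @export
relative_time_below <- function(grid, threshold) {
  dur <- grid_duration_min(grid)
  if (!is.finite(dur) || dur <= 0)
    return(structure(NA_real_, reason = "zero-duration record"))
  min(1, time_below(grid, threshold) / dur)
}

#' Compute every definition in a registry for one MAP grid
#'
#' @inheritParams lowest_sustained_map
#' @param registry Registry data frame; defaults to [ioh_registry()].
#' @return Named numeric vector, one entry per registry row (`NA` where a
#'   record is too short for the definition).
#' @export
compute_all_definitions <- function(grid, registry = ioh_registry()) {
  if (nrow(registry) == 0L)
    return(stats::setNames(numeric(0), character(0)))
  bad <- setdiff(registry$kind, c("sustained_min_map", "cumulative_min_map",
                                  "abs_time_below", "rel_time_below"))
  if (length(bad))
    stop(sprintf("unknown definition kind '%s'", bad[1L]), call. = FALSE)
  x <- grid_values(grid)
  n <- length(x)
  dur_min <- grid_duration_min(grid)
  out <- rep(NA_real_, nrow(registry))

  sus <- registry$kind == "sustained_min_map"
  if (any(sus)) {
    # one shared window-composition cache across all durations
    ws <- as.integer(round(TICKS_PER_MIN * registry$parameter[sus]))
    out[sus] <- roll_max_mins(x, ws)
  }
  cum <- registry$kind == "cumulative_min_map"
  if (any(cum)) {
    ks <- as.integer(round(TICKS_PER_MIN * registry$parameter[cum]))
    xs <- sort(x)
    out[cum] <- ifelse(ks <= n, xs[pmin(ks, n)], NA_real_)
  }
  ab <- registry$kind == "abs_time_below"
  if (any(ab))
    out[ab] <- vapply(registry$parameter[ab],
                      function(th) MIN_PER_TICK * sum(x < th), numeric(1))
  rel <- registry$kind == "rel_time_below"
  if (any(rel))
    out[rel] <- vapply(registry$parameter[rel], function(th)
      min(1, MIN_PER_TICK * sum(x < th) / dur_min), numeric(1))
  stats::setNames(out, registry$name)
}
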