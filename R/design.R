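# Outcome-specific model inputs: winsorization, spike-at-zero indicators,
# natural cubic spline bases, trimmed log length-of-stay outcomes, and
# adjustment-covariate encoding.

REF_LEVELS <- list(sex = "male",
                   specialty = "Urology, gynecology, general surgery",
                   asa = 2L)

#' Winsorize the upper tail of a numeric vector
#'
#' Values above the empirical percentile are replaced by it; the lower tail
#' is untouched. The cap is an order-statistic (type-1) quantile, so the cap
#' is an attained value and re-winsorizing a winsorized vector changes
#' nothing.
#'
#' @param values Numeric vector with at least two finite values.
#' @param percentile Upper percentile, default 0.99.
#' @return Winsorized vector with attribute `cap` (the value used).
#' @export
winsorize <- function(values, percentile = 0.99) {
  fin <- values[is.finite(values)]
  if (length(fin) < 2L) stop("winsorize needs at least two finite values")
  cap <- unname(stats::quantile(fin, percentile, type = 1, names = FALSE))
  out <- pmin(values, cap)
  attr(out, "cap") <- cap
  out
}

#' Spike-at-zero indicator for time-below exposure metrics
#'
#' Absolute and relative time-below-threshold metrics have a point mass at
#' zero (many patients are never hypotensive by a given threshold); models
#' carry an extra binary column flagging exactly those zeros. The indicator
#' is defined only for the time-below families.
#'
#' @param values Metric values.
#' @param kind Definition kind; must be `abs_time_below` or `rel_time_below`.
#' @return Integer 0/1 vector, 1 where the value is exactly zero.
#' @export
zero_spike_indicator <- function(values, kind = "abs_time_below") {
  if (!kind %in% c("abs_time_below", "rel_time_below"))
    stop("zero-spike indicator is defined only for time-below definitions",
         call. = FALSE)
  as.integer(values == 0)
}

#' Natural cubic spline basis with quantile knots
#'
#' Wraps [splines::ns()] with interior knots at equally spaced quantiles and
#' boundary knots at the data extremes, recording the knots so the same
#' parameterization rule can be re-applied on new data (e.g. when rebuilding
#' the design on the estimation half or evaluating effect curves). Interior
#' knots that collide (heavily tied data, e.g. spike-at-zero metrics) are
#' dropped, reducing the basis dimension; with fewer distinct values than
#' needed the basis degrades to a single linear column with a warning.
#'
#' @param values Numeric vector.
#' @param df Requested degrees of freedom (2, 3 or 4).
#' @param knots,boundary Optional explicit interior/boundary knots (reuse an
#'   existing parameterization).
#' @return Matrix of basis columns with attributes `knots`, `boundary`,
#'   `linear` (TRUE when degraded).
#' @export
natural_spline_basis <- function(values, df, knots = NULL, boundary = NULL) {
  if (is.null(boundary)) boundary <- range(values, finite = TRUE)
  if (is.null(knots)) {
    if (length(unique(values[is.finite(values)])) <= df) {
      warning("fewer distinct values than knots; using a linear term")
      out <- matrix(values, ncol = 1)
      attr(out, "knots") <- numeric(0)
      attr(out, "boundary") <- boundary
      attr(out, "linear") <- TRUE
      return(out)
    }
    if (df >= 2) {
      probs <- seq_len(df - 1) / df
      knots <- emp_quantile(values[is.finite(values)], probs)
      knots <- unique(knots[knots > boundary[1] & knots < boundary[2]])
    } else {
      knots <- numeric(0)
    }
  }
  basis <- splines::ns(values, knots = knots, Boundary.knots = boundary)
  out <- matrix(as.numeric(basis), nrow = length(values))
  attr(out, "knots") <- knots
  attr(out, "boundary") <- boundary
  attr(out, "linear") <- FALSE
  out
}

#' Trim and log-transform a length-of-stay outcome
#'
#' Deaths before discharge are assigned an infinite stay; the largest
#' `ceil(trim_fraction * n)` values (infinities ranking first, ties broken
#' by position/patient id) are removed, and the natural log of the remainder
#' is returned. The kept mask identifies the trimmed "best" patients the
#' model describes.
#'
#' @param los Positive stays (days or hours).
#' @param died_before_discharge Logical flags; these stays are set to `Inf`
#'   before trimming.
#' @param trim_fraction Fraction trimmed from the top, in (0, 0.5).
#' @param ids Optional ids used for deterministic tie-breaking.
#' @return List with `log_los` (length = kept count), `kept` (logical mask
#'   over the input) and `n_trimmed`.
#' @export
trim_and_log_los <- function(los, died_before_discharge = NULL,
                             trim_fraction = 0.01, ids = NULL) {
  if (!is.numeric(trim_fraction) || trim_fraction <= 0 ||
      trim_fraction >= 0.5)
    stop_field("trim_fraction", "must lie in (0, 0.5)")
  n <- length(los)
  x <- as.numeric(los)
  if (!is.null(died_before_discharge)) x[died_before_discharge] <- Inf
  if (any(x[is.finite(x)] <= 0)) stop("length of stay must be positive")
  if (is.null(ids)) ids <- seq_len(n)
  n_trim <- ceiling(trim_fraction * n)
  ord <- order(x, ids, decreasing = TRUE)
  drop_idx <- ord[seq_len(min(n_trim, n))]
  kept <- rep(TRUE, n)
  kept[drop_idx] <- FALSE
  list(log_los = log(x[kept]), kept = kept, n_trimmed = length(drop_idx))
}

#' Modeling settings shared by the shaping and estimation stages
#'
#' @param ioh_df Spline df for the IOH definition (3 by default; the
#'   sensitivity analysis uses 4).
#' @param df3 Spline df for duration of surgery, time to surgery and
#'   comorbidity score.
#' @param df2 Spline df for age and BMI.
#' @param winsor_p Winsorization percentile for IOH definitions, BMI and
#'   duration of surgery.
#' @param trim_fraction Upper trim fraction for length-of-stay outcomes.
#' @param univariable If `TRUE`, drop the adjustment covariates (exposure
#'   block plus intercept only).
#' @return A `model_settings` list.
#' @export
model_settings <- function(ioh_df = 3, df3 = 3, df2 = 2, winsor_p = 0.99,
                           trim_fraction = 0.01, univariable = FALSE) {
  stopifnot(ioh_df %in% 1:4, df3 %in% 1:4, df2 %in% 1:4)
  assert_fraction(winsor_p, "winsor_p")
  if (trim_fraction <= 0 || trim_fraction >= 0.5)
    stop_field("trim_fraction", "must lie in (0, 0.5)")
  structure(list(ioh_df = ioh_df, df3 = df3, df2 = df2,
                 winsor_p = winsor_p, trim_fraction = trim_fraction,
                 univariable = isTRUE(univariable)),
            class = "model_settings")
}

# One design block: returns columns plus the metadata needed to rebuild the
# same columns for new values.
spline_block <- function(x, df, winsor_p = NULL, prefix) {
  cap <- NULL
  if (!is.null(winsor_p)) {
    x <- winsorize(x, winsor_p)
    cap <- attr(x, "cap")
  }
  B <- suppressWarnings(natural_spline_basis(as.numeric(x), df))
  colnames(B) <- paste0(prefix, seq_len(ncol(B)))
  list(X = B,
       meta = list(type = "spline", cap = cap,
                   knots = attr(B, "knots"),
                   boundary = attr(B, "boundary"),
                   linear = attr(B, "linear")))
}

dummy_block <- function(x, levels, ref, prefix) {
  levs <- setdiff(levels, ref)
  X <- vapply(levs, function(l) as.numeric(x == l), numeric(length(x)))
  X <- matrix(X, nrow = length(x))
  colnames(X) <- paste0(prefix, gsub("[^A-Za-z0-9]+", "_", levs))
  list(X = X, meta = list(type = "dummy", levels = levels, ref = ref))
}

#' Build the outcome-specific model matrix
#'
#' Assembles, for one IOH definition and one outcome, the winsorized IOH
#' spline block (plus a zero indicator for time-below kinds), the adjustment
#' covariate blocks (sex, surgical specialty and ASA class as dummies with
#' reference male / "Urology, gynecology, general surgery" / ASA 2; age and
#' BMI as 2-df splines; duration of surgery, time to surgery and comorbidity
#' score as 3-df splines), and the outcome vector: the 30-day death flag, or
#' the trimmed log length of stay. Winsorization caps and knots are computed
#' once on the rows being modeled, then held fixed (also across CV folds).
#'
#' @param cohort A cohort table: data frame with covariates, outcomes and
#'   definition-value columns (see [cohort_features()]).
#' @param definition Definition name (column in `cohort`).
#' @param outcome `"mortality"`, `"hlos"` or `"pacu"`.
#' @param settings A [model_settings()].
#' @param registry Registry used to resolve the definition's kind.
#' @return An `ioh_model_matrix`: list with `y`, `X` (including intercept),
#'   `groups` (named list of column indices), `patient_id`, `outcome`,
#'   `binary`, `meta` (per-block parameterization) and `exclusions`
#'   (data frame of dropped patients with reasons).
#' @export
build_model_matrix <- function(cohort, definition, outcome,
                               settings = model_settings(),
                               registry = ioh_registry()) {
  outcome <- match.arg(outcome, c("mortality", "hlos", "pacu"))
  def <- ioh_definition(definition, registry)
  if (!definition %in% names(cohort))
    stop(sprintf("definition '%s' not computed on this cohort", definition),
         call. = FALSE)

  excl <- data.frame(patient_id = character(0), reason = character(0))
  keep <- rep(TRUE, nrow(cohort))

  miss_def <- is.na(cohort[[definition]])
  if (any(miss_def)) {
    excl <- rbind(excl, data.frame(patient_id = cohort$patient_id[miss_def],
                                   reason = "missing definition value"))
    keep <- keep & !miss_def
  }
  if (outcome == "pacu") {
    icu <- cohort$icu_direct | is.na(cohort$pacu_los)
    icu[is.na(icu)] <- TRUE
    drop <- icu & keep
    if (any(drop))
      excl <- rbind(excl, data.frame(patient_id = cohort$patient_id[drop],
                                     reason = "direct ICU admission"))
    keep <- keep & !icu
  }
  d <- cohort[keep, , drop = FALSE]
  if (nrow(d) == 0L) stop("empty analysis set", call. = FALSE)

  # Outcome vector (trimming for LOS outcomes happens on the analysis rows).
  if (outcome == "mortality") {
    y <- as.numeric(d$died_30d)
    binary <- TRUE
    trim_meta <- NULL
  } else {
    los <- if (outcome == "hlos") d$hlos else d$pacu_los
    dbd <- if (outcome == "hlos") d$died_before_discharge else NULL
    tr <- trim_and_log_los(los, dbd, settings$trim_fraction,
                           ids = d$patient_id)
    if (any(!tr$kept))
      excl <- rbind(excl,
                    data.frame(patient_id = d$patient_id[!tr$kept],
                               reason = "trimmed length of stay"))
    d <- d[tr$kept, , drop = FALSE]
    y <- tr$log_los
    # Deaths before discharge beyond the trim budget leave infinite stays;
    # such rows cannot enter a linear model and are excluded with a warning.
    if (any(!is.finite(y))) {
      inf <- !is.finite(y)
      warning(sprintf(paste0("%d death(s) before discharge exceed the trim ",
                             "fraction; excluded from the %s model"),
                      sum(inf), outcome))
      excl <- rbind(excl,
                    data.frame(patient_id = d$patient_id[inf],
                               reason = "death before discharge beyond trim"))
      d <- d[!inf, , drop = FALSE]
      y <- y[!inf]
    }
    binary <- FALSE
    trim_meta <- list(fraction = settings$trim_fraction,
                      n_trimmed = tr$n_trimmed)
  }
  if (nrow(d) == 0L) stop("empty analysis set", call. = FALSE)

  blocks <- list()
  meta <- list(definition = definition, kind = def$kind, outcome = outcome,
               settings = settings, trim = trim_meta, blocks = list())

  ioh <- spline_block(d[[definition]], settings$ioh_df,
                      winsor_p = settings$winsor_p, prefix = "ioh_s")
  ioh_X <- ioh$X
  if (def$kind %in% c("abs_time_below", "rel_time_below")) {
    ind <- zero_spike_indicator(d[[definition]], def$kind)
    ioh_X <- cbind(ioh_X, ioh_zero = ind)
    ioh$meta$zero_indicator <- TRUE
  } else {
    ioh$meta$zero_indicator <- FALSE
  }
  blocks$ioh <- list(X = ioh_X, meta = ioh$meta)

  if (!settings$univariable) {
    blocks$sex <- dummy_block(d$sex, c("male", "female"), REF_LEVELS$sex,
                              "sex_")
    blocks$age <- spline_block(d$age, settings$df2, prefix = "age_s")
    blocks$bmi <- spline_block(d$bmi, settings$df2,
                               winsor_p = settings$winsor_p, prefix = "bmi_s")
    blocks$duration <- spline_block(d$duration_surgery, settings$df3,
                                    winsor_p = settings$winsor_p,
                                    prefix = "dur_s")
    blocks$time_to_surgery <- spline_block(d$time_to_surgery, settings$df3,
                                           prefix = "tts_s")
    blocks$specialty <- dummy_block(d$specialty, SPECIALTIES,
                                    REF_LEVELS$specialty, "spec_")
    blocks$asa <- dummy_block(as.integer(d$asa), 1:4, REF_LEVELS$asa, "asa_")
    blocks$comorbidity <- spline_block(d$comorbidity_score, settings$df3,
                                       prefix = "cmb_s")
  }

  X <- cbind(`(Intercept)` = 1,
             do.call(cbind, lapply(blocks, `[[`, "X")))
  groups <- list(intercept = 1L)
  idx <- 1L
  for (b in names(blocks)) {
    p <- ncol(blocks[[b]]$X)
    groups[[b]] <- idx + seq_len(p)
    idx <- idx + p
  }
  meta$blocks <- lapply(blocks, `[[`, "meta")

  structure(list(y = y, X = X, groups = groups,
                 patient_id = d$patient_id, outcome = outcome,
                 binary = binary, meta = meta, exclusions = excl),
            class = "ioh_model_matrix")
}

#' @export
print.ioh_model_matrix <- function(x, ...) {
  cat(sprintf("Model matrix: outcome %s, definition %s, %d rows x %d cols\n",
              x$outcome, x$meta$definition, length(x$y), ncol(x$X)))
  cat("  blocks:", paste(names(x$groups), collapse = ", "), "\n")
  if (nrow(x$exclusions))
    cat(sprintf("  %d patients excluded\n", nrow(x$exclusions)))
  invisible(x)
}

# Rebuild one design row for arbitrary values using stored parameterization.
# `values` is a named list: definition value plus covariates.
design_row <- function(mm, def_value, ref = reference_patient()) {
  meta <- mm$meta
  blocks <- meta$blocks
  row <- c(`(Intercept)` = 1)
  eval_spline <- function(bm, v) {
    if (!is.null(bm$cap)) v <- min(v, bm$cap)
    if (isTRUE(bm$linear)) return(v)
    as.numeric(splines::ns(v, knots = bm$knots,
                           Boundary.knots = bm$boundary))
  }
  vals <- list(ioh = def_value, sex = ref$sex, age = ref$age, bmi = ref$bmi,
               duration = ref$duration_surgery,
               time_to_surgery = ref$time_to_surgery,
               specialty = ref$specialty, asa = ref$asa,
               comorbidity = ref$comorbidity_score)
  for (b in setdiff(names(mm$groups), "intercept")) {
    bm <- blocks[[b]]
    v <- vals[[b]]
    if (bm$type == "spline") {
      cols <- eval_spline(bm, v)
      if (b == "ioh" && isTRUE(bm$zero_indicator))
        cols <- c(cols, as.integer(v == 0))
    } else {
      cols <- as.numeric(setdiff(bm$levels, bm$ref) == v)
    }
    row <- c(row, cols)
  }
  stats::setNames(row, colnames(mm$X))
}
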