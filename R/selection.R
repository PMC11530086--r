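# The shaping stage: split the cohort into equal halves, cross-validate
# every candidate definition's model per outcome, rank by Brier/MSE, and
# compute the 0.95 Akaike-weight confidence set.

#' Randomly split a cohort into shaping and estimation halves
#'
#' Uniform random permutation split into two halves differing in size by at
#' most one patient; deterministic given the seed.
#'
#' @param cohort A cohort table or anything with a `patient_id` column, or a
#'   plain vector of ids.
#' @param seed Integer seed.
#' @return A `split_assignment`: data frame (`patient_id`, `half` in
#'   `{"shaping", "estimation"}`) with the seed as attribute.
#' @export
split_cohort <- function(cohort, seed = 1L) {
  ids <- if (is.atomic(cohort)) cohort else cohort$patient_id
  n <- length(ids)
  if (n < 2L) stop("need at least two patients to split")
  set.seed(seed)
  perm <- sample.int(n)
  half <- rep("estimation", n)
  half[perm <= ceiling(n / 2)] <- "shaping"
  structure(data.frame(patient_id = ids, half = half,
                       stringsAsFactors = FALSE),
            seed = seed, class = c("split_assignment", "data.frame"))
}

#' Take one half of a split cohort table
#'
#' @param cohort A cohort table.
#' @param split A `split_assignment` from [split_cohort()].
#' @param half `"shaping"` or `"estimation"`.
#' @return The subset table (attributes preserved).
#' @export
cohort_half <- function(cohort, split, half = c("shaping", "estimation")) {
  half <- match.arg(half)
  ids <- split$patient_id[split$half == half]
  out <- cohort[cohort$patient_id %in% ids, , drop = FALSE]
  attr(out, "registry") <- attr(cohort, "registry")
  class(out) <- class(cohort)
  out
}

# Fold assignments: list (one per repetition) of integer fold labels.
# Binary outcomes are stratified so every fold sees events.
make_folds <- function(y, k, reps, seed, stratify = TRUE) {
  set.seed(seed)
  n <- length(y)
  lapply(seq_len(reps), function(r) {
    f <- integer(n)
    if (stratify && length(unique(y)) == 2L) {
      for (lev in unique(y)) {
        idx <- which(y == lev)
        f[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      f <- sample(rep_len(seq_len(k), n))
    }
    f
  })
}

# Deterministic IRLS for logistic regression (deviance tolerance 1e-8, max
# 100 iterations), following the standard GLM recipe: mu0 = (y + 0.5)/2
# initialization, weighted least squares by pivoted QR per step. A warm
# start from the full-data fit makes the thousands of cross-validation
# refits cheap.
logit_irls <- function(X, y, start = NULL, tol = 1e-8, maxit = 100L) {
  p_ <- ncol(X)
  warm <- !is.null(start)
  eta <- if (warm) drop(X %*% start) else stats::qlogis((y + 0.5) / 2)
  beta <- if (warm) start else rep(0, p_)
  dev_old <- Inf
  done <- FALSE
  qr_step <- function(Xw, zw) {
    ls <- .lm.fit(Xw, zw)
    cf <- ls$coefficients
    cf[is.na(cf)] <- 0
    b <- numeric(p_)
    b[ls$pivot] <- cf
    b
  }
  clamp_mu <- function(eta) pmin(pmax(stats::plogis(eta), 1e-10), 1 - 1e-10)
  deviance_of <- function(mu) -2 * sum(y * log(mu) + (1 - y) * log1p(-mu))
  mu <- clamp_mu(eta)
  for (it in seq_len(maxit)) {
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    Xw <- X * sw
    beta_new <- NULL
    if (warm) {
      # fast normal-equations step; near the optimum this is safe, and the
      # deviance guard below retries by QR if it is not
      beta_new <- tryCatch(drop(solve(crossprod(Xw), crossprod(Xw, sw * z))),
                           error = function(e) NULL)
    }
    if (is.null(beta_new)) beta_new <- qr_step(Xw, sw * z)
    eta_new <- drop(X %*% beta_new)
    mu_new <- clamp_mu(eta_new)
    dev <- deviance_of(mu_new)
    if (warm && (!is.finite(dev) || dev > dev_old + 1)) {
      warm <- FALSE                     # stable QR steps from here on
      beta_new <- qr_step(Xw, sw * z)
      eta_new <- drop(X %*% beta_new)
      mu_new <- clamp_mu(eta_new)
      dev <- deviance_of(mu_new)
    }
    beta <- beta_new
    eta <- eta_new
    mu <- mu_new
    if (is.finite(dev) && abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
      done <- TRUE
      break
    }
    dev_old <- dev
  }
  structure(beta, converged = done)
}

# Core CV engine shared by the shaping stage and the variable-contribution
# analysis: scores a fixed design matrix under precomputed fold partitions.
cv_engine <- function(X, y, binary, folds, k, warm_start = NULL) {
  if (binary && is.null(warm_start))
    warm_start <- logit_irls(X, y)
  rep_means <- vapply(folds, function(f) {
    scores <- rep(NA_real_, k)
    for (fold in seq_len(k)) {
      test <- f == fold
      if (!any(test) || !any(!test)) next
      if (binary && length(unique(y[!test])) < 2L) next  # zero-event fold
      beta <- if (binary)
        logit_irls(X[!test, , drop = FALSE], y[!test], start = warm_start,
                   maxit = 25L)
      else stats::lm.fit(X[!test, , drop = FALSE], y[!test])$coefficients
      beta[is.na(beta)] <- 0
      eta <- drop(X[test, , drop = FALSE] %*% beta)
      pred <- if (binary) stats::plogis(eta) else eta
      scores[fold] <- mean((pred - y[test])^2)
    }
    mean(scores, na.rm = TRUE)
  }, numeric(1))
  list(mean = mean(rep_means), rep_means = rep_means)
}

#' Cross-validate one definition's model on a cohort half
#'
#' Builds the model matrix once on the half (winsorization caps and spline
#' knots fixed from the full half), then for each repetition draws a fresh
#' random k-fold partition (stratified by outcome for mortality), fits on
#' k-1 folds and scores the held-out fold with the Brier score (binary) or
#' MSE (metric). The reported score is the mean over all folds and
#' repetitions.
#'
#' @param half Cohort-table half (see [cohort_half()]).
#' @param definition Definition name.
#' @param outcome `"mortality"`, `"hlos"` or `"pacu"`.
#' @param k Folds (default 10).
#' @param reps Repetitions (default 40).
#' @param seed Seed for the fold partitions.
#' @param settings [model_settings()].
#' @param registry Definition registry.
#' @param stratify Stratify binary folds by outcome (default `TRUE`).
#' @return A `cv_score`: definition, outcome, mean score, per-repetition
#'   means, fold scheme, AIC and parameter count of the full-half fit, and
#'   the separation flag.
#' @export
cross_validate <- function(half, definition, outcome, k = 10, reps = 40,
                           seed = 1L, settings = model_settings(),
                           registry = ioh_registry(), stratify = TRUE) {
  mm <- build_model_matrix(half, definition, outcome, settings, registry)
  full_fit <- suppressWarnings(fit_model(mm))
  folds <- make_folds(mm$y, k, reps, seed, stratify = stratify)
  ws <- if (mm$binary && length(full_fit$coefficients) == ncol(mm$X))
    unname(full_fit$coefficients) else NULL
  cv <- cv_engine(mm$X, mm$y, mm$binary, folds, k, warm_start = ws)
  structure(list(definition = definition, outcome = outcome,
                 score = cv$mean, rep_means = cv$rep_means,
                 k = k, reps = reps, seed = seed,
                 n = length(mm$y), n_params = full_fit$k,
                 aic = full_fit$aic, separated = full_fit$separated),
            class = "cv_score")
}

#' Rank candidate definitions by cross-validated score
#'
#' Ascending by mean score; ties broken by fewer model parameters, then by
#' registry order. Separation-flagged models are excluded with a reason.
#'
#' @param scores List of `cv_score` objects for one outcome.
#' @return Data frame ranked best-first with columns `definition`, `score`,
#'   `n_params`, `aic`, `rank`.
#' @export
rank_definitions <- function(scores) {
  outc <- unique(vapply(scores, `[[`, character(1), "outcome"))
  if (length(outc) != 1L) stop("scores mix outcomes; rank one outcome")
  tab <- data.frame(
    definition = vapply(scores, `[[`, character(1), "definition"),
    score = vapply(scores, `[[`, numeric(1), "score"),
    n_params = vapply(scores, `[[`, numeric(1), "n_params"),
    aic = vapply(scores, `[[`, numeric(1), "aic"),
    separated = vapply(scores, `[[`, logical(1), "separated"),
    registry_order = seq_along(scores))
  if (any(tab$separated)) {
    if (all(tab$separated)) {
      # Exclusion would empty the candidate list (tiny event counts flag
      # every model); keep them ranked but say so.
      message("all models are separation-flagged; ranking retained")
    } else {
      message(sprintf("excluding %d separation-flagged model(s) from ranking",
                      sum(tab$separated)))
      tab <- tab[!tab$separated, , drop = FALSE]
    }
  }
  ord <- order(tab$score, tab$n_params, tab$registry_order)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab[, c("definition", "score", "n_params", "aic", "rank")]
}

#' Akaike weights and the 0.95 model confidence set
#'
#' Weights are `exp(-(AIC_i - min AIC)/2)`, normalized to sum to one. Models
#' are accumulated in decreasing weight order until the cumulative weight
#' first exceeds the level; the model crossing the boundary is included.
#'
#' @param aics Named numeric vector of AICs (one full-data fit per
#'   definition). Non-finite entries are excluded with a warning.
#' @param level Confidence level, default 0.95.
#' @return Data frame (`definition`, `aic`, `delta`, `weight`,
#'   `cum_weight`, `in_set`) sorted by decreasing weight.
#' @export
akaike_confidence_set <- function(aics, level = 0.95) {
  if (length(aics) < 1L) stop("need at least one AIC")
  bad <- !is.finite(aics)
  if (any(bad)) {
    warning(sprintf("excluding %d model(s) with non-finite AIC", sum(bad)))
    aics <- aics[!bad]
  }
  delta <- aics - min(aics)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  ord <- order(w, decreasing = TRUE)
  out <- data.frame(definition = names(aics)[ord] %||%
                      as.character(seq_along(aics))[ord],
                    aic = unname(aics[ord]), delta = unname(delta[ord]),
                    weight = unname(w[ord]))
  out$cum_weight <- cumsum(out$weight)
  first_cross <- match(TRUE, out$cum_weight > level)
  out$in_set <- seq_len(nrow(out)) <= first_cross
  out
}

#' Shaping stage: select the best-fitting definition for one outcome
#'
#' Cross-validates every registry definition on the shaping half, ranks by
#' cross-validated Brier score (mortality) or MSE (length-of-stay outcomes),
#' and attaches the Akaike-weight confidence set computed from single
#' full-half fits.
#'
#' @param half Shaping half of a cohort table.
#' @param outcome Outcome name.
#' @param registry Definition registry.
#' @param k,reps,seed CV scheme.
#' @param settings [model_settings()].
#' @return An `ioh_selection`: `outcome`, `table` (ranked scores with
#'   weights and confidence-set membership), `best`, `scheme` and the
#'   shaping patient ids (used to enforce split independence downstream).
#' @export
shape_outcome <- function(half, outcome, registry = ioh_registry(),
                          k = 10, reps = 40, seed = 1L,
                          settings = model_settings()) {
  scores <- lapply(registry$name, function(d)
    cross_validate(half, d, outcome, k = k, reps = reps, seed = seed,
                   settings = settings, registry = registry))
  ranked <- rank_definitions(scores)
  aics <- stats::setNames(vapply(scores, `[[`, numeric(1), "aic"),
                          vapply(scores, `[[`, character(1), "definition"))
  cset <- akaike_confidence_set(aics)
  ranked$weight <- cset$weight[match(ranked$definition, cset$definition)]
  ranked$in_confidence_set <- cset$in_set[match(ranked$definition,
                                                cset$definition)]
  structure(list(outcome = outcome, table = ranked,
                 best = ranked$definition[1L],
                 confidence_set = cset$definition[cset$in_set],
                 scheme = list(k = k, reps = reps, seed = seed,
                               settings = settings),
                 registry = registry,
                 shaping_ids = half$patient_id),
            class = "ioh_selection")
}

#' @export
print.ioh_selection <- function(x, ...) {
  cat(sprintf("Shaping-stage selection for %s (%d candidates)\n",
              x$outcome, nrow(x$table)))
  cat(sprintf("  best: %s (score %.7f)\n", x$best, x$table$score[1]))
  cat(sprintf("  0.95 confidence set: %d definition(s)\n",
              length(x$confidence_set)))
  invisible(x)
}
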