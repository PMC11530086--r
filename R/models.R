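# Outcome models and scores: logistic regression for 30-day mortality,
# linear regression for log-trimmed length-of-stay outcomes; Brier score,
# MSE, AIC and Hosmer-Lemeshow goodness of fit.

#' Fit the outcome model for a model matrix
#'
#' Maximum-likelihood logistic regression (binary outcome, IRLS) or ordinary
#' least squares (metric outcome). Rank-deficient designs drop aliased
#' columns with a warning; quasi-separated logistic fits (any coefficient
#' exceeding 15 in absolute value on standardized columns) are flagged so
#' the selection stage can exclude them.
#'
#' @param mm An `ioh_model_matrix` from [build_model_matrix()], or any list
#'   with `y`, `X`, `binary`.
#' @return An `ioh_fit`: coefficients, covariance matrix, log-likelihood,
#'   AIC (`2k - 2 loglik`), n, outcome type, link, convergence and
#'   separation flags, plus the model-matrix metadata.
#' @export
fit_model <- function(mm) {
  X <- mm$X
  y <- mm$y
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning(sprintf("rank-deficient design; dropping: %s",
                    paste(dropped, collapse = ", ")))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  binary <- isTRUE(mm$binary)
  n <- length(y)
  if (binary) {
    beta <- logit_irls(X, y)
    converged <- isTRUE(attr(beta, "converged"))
    attributes(beta) <- NULL
    p <- stats::plogis(drop(X %*% beta))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    w <- p * (1 - p)
    XtWX <- crossprod(X * sqrt(w))
    vcov <- tryCatch(chol2inv(chol(XtWX)),
                     error = function(e) MASS_ginv(XtWX))
    loglik <- sum(y * log(p) + (1 - y) * log1p(-p))
    k <- ncol(X)
    aic <- 2 * k - 2 * loglik
    sds <- apply(X, 2, stats::sd)
    sds[sds == 0] <- 1
    separated <- any(abs(beta * sds) > 15, na.rm = TRUE) || !converged
    sigma2 <- NA_real_
  } else {
    fit <- stats::lm.fit(X, y)
    beta <- fit$coefficients
    res <- fit$residuals
    sigma2 <- sum(res^2) / n
    vcov <- chol2inv(qr.R(fit$qr)) * (sum(res^2) / (n - ncol(X)))
    loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
    k <- ncol(X) + 1  # residual variance is estimated too
    aic <- 2 * k - 2 * loglik
    separated <- FALSE
    converged <- TRUE
  }
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 vcov = vcov, loglik = loglik, aic = aic, n = n,
                 k = k, outcome = mm$outcome %||% if (binary) "binary"
                                                  else "metric",
                 link = if (binary) "logit" else "identity",
                 binary = binary, converged = converged,
                 separated = separated, sigma2 = sigma2,
                 meta = mm$meta %||% NULL),
            class = "ioh_fit")
}

# Moore-Penrose fallback for near-singular information matrices.
MASS_ginv <- function(M) {
  s <- svd(M)
  pos <- s$d > max(s$d) * 1e-12
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.ioh_fit <- function(x, ...) {
  cat(sprintf("%s model (%s link): n = %d, %d coefficients, AIC = %.2f\n",
              if (x$binary) "Logistic" else "Linear", x$link, x$n,
              length(x$coefficients), x$aic))
  if (x$separated) cat("  WARNING: quasi-separation flagged\n")
  invisible(x)
}

#' Predict from a fitted model on a design matrix
#'
#' @param object An `ioh_fit`.
#' @param X Design matrix with the fitted columns.
#' @param type `"response"` (probability / identity) or `"link"`.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.ioh_fit <- function(object, X, type = c("response", "link"), ...) {
  type <- match.arg(type)
  nm <- names(object$coefficients)
  if (!is.null(nm) && all(nzchar(nm)) && all(nm %in% colnames(X)))
    X <- X[, nm, drop = FALSE]
  eta <- drop(X %*% object$coefficients)
  if (type == "link" || !object$binary) eta else stats::plogis(eta)
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes; lower is better.
#'
#' @param predicted_probs Probabilities in \[0, 1\].
#' @param outcomes Binary outcomes (0/1 or logical).
#' @return Mean of `(prob - outcome)^2`.
#' @export
brier_score <- function(predicted_probs, outcomes) {
  if (length(predicted_probs) != length(outcomes))
    stop("length mismatch between predictions and outcomes")
  if (any(predicted_probs < 0 | predicted_probs > 1, na.rm = TRUE))
    stop("predicted probabilities must lie in [0, 1]")
  mean((predicted_probs - as.numeric(outcomes))^2)
}

#' Mean squared error
#'
#' @param predictions,outcomes Equal-length numeric vectors (outcomes on the
#'   scale used for fitting, i.e. log length of stay).
#' @return Mean squared residual.
#' @export
mse <- function(predictions, outcomes) {
  if (length(predictions) != length(outcomes))
    stop("length mismatch between predictions and outcomes")
  mean((predictions - outcomes)^2)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' The C-hat variant: observations grouped into deciles of predicted risk
#' (ties kept in one group), chi-square statistic
#' `sum((obs - exp)^2 / (exp * (1 - exp / n_g)))` with `groups - 2` degrees
#' of freedom.
#'
#' @param model An `ioh_fit` for a binary outcome.
#' @param mm The model matrix it was fitted on.
#' @param groups Number of risk groups (default 10).
#' @return List with `statistic`, `p_value`, `df`, `groups_used` and the
#'   per-group observed/expected table.
#' @export
hosmer_lemeshow <- function(model, mm, groups = 10) {
  if (!model$binary) stop("Hosmer-Lemeshow requires a binary-outcome model")
  p <- predict(model, mm$X, type = "response")
  y <- mm$y
  breaks <- unique(emp_quantile(p, seq(0, 1, length.out = groups + 1)))
  if (length(breaks) - 1 < groups) {
    warning(sprintf("only %d distinct risk groups available",
                    length(breaks) - 1))
  }
  g <- cut(p, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  tab <- do.call(rbind, lapply(sort(unique(g)), function(gi) {
    sel <- g == gi
    data.frame(group = gi, n = sum(sel), obs = sum(y[sel]),
               exp = sum(p[sel]))
  }))
  stat <- sum((tab$obs - tab$exp)^2 / (tab$exp * (1 - tab$exp / tab$n)))
  df <- max(nrow(tab) - 2, 1)  # degenerate grouping keeps the test defined
  list(statistic = stat,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       df = df, groups_used = nrow(tab), table = tab)
}
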