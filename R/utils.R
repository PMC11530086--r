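#' @keywords internal
"_PACKAGE"

# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

assert_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_field(field, "must be a single number in [0, 1]")
  invisible(x)
}

assert_positive <- function(x, field) {
  if (!is.numeric(x) || any(is.na(x)) || any(x <= 0))
    stop_field(field, "must be positive")
  invisible(x)
}

# Derive a 32-bit child seed from a master seed and a stream index.
# Counter-based so that enlarging a cohort never reshuffles earlier patients.
child_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 16807) %%
               2147483647)
}

# djb2-style rolling hash of a character scalar; used for run-manifest
# config hashes (content fingerprint, not cryptographic).
config_hash <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Linear-interpolation empirical quantile (type 7), the convention used for
# winsorization caps and spline knots throughout.
emp_quantile <- function(x, probs) {
  unname(stats::quantile(x, probs = probs, type = 7, names = FALSE,
                         na.rm = FALSE))
}
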