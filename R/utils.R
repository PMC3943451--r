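# Internal validation and small numeric helpers.

stop_invalid <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_invalid(field, "must be a probability in [0, 1]")
  invisible(x)
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_invalid(field, "must be TRUE or FALSE")
  invisible(x)
}

check_count <- function(x, field, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    stop_invalid(field, sprintf("must be an integer >= %d", min))
  invisible(as.integer(x))
}

check_number <- function(x, field, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower ||
      x > upper)
    stop_invalid(field, sprintf("must be a number in [%s, %s]", lower, upper))
  invisible(as.numeric(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# logistic cdf (D = 1 metric throughout the package)
lgs <- function(x) plogis(x)

# clip correlations away from +-1 so likelihoods stay finite
clip_cor <- function(r, bound = 0.999) pmin(pmax(r, -bound), bound)
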