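#' Hill response specification
#'
#' Container for the parameters of one saturating (Hill) dose-response law.
#' The increasing form is `offset + m * x^h / (e^h + x^h)`; the decreasing
#' form is `offset + m / (1 + (x/e)^h)`.  `e` is the half-saturation
#' constant (EC50, in units of the input) and `h` the dimensionless Hill
#' coefficient quantifying cooperativity.
#'
#' @param m Maximal response span (units of the response); must be positive.
#' @param e Half-saturation constant (units of the input); must be positive.
#' @param h Hill coefficient (dimensionless); must be positive.
#' @param offset Constant added to the response (same units as `m`,
#'   default 0); must be nonnegative.
#' @param direction `"increasing"` or `"decreasing"`.
#' @return An object of class `hill_spec`.
#' @examples
#' sp <- hill_spec(m = 100, e = 20, h = 2.5)
#' hill_increasing(20, sp)  # half-saturation: 50
#' @export
hill_spec <- function(m, e, h, offset = 0,
                      direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(m), length(m) == 1L, is.finite(m),
            is.numeric(e), length(e) == 1L, is.finite(e),
            is.numeric(h), length(h) == 1L, is.finite(h),
            is.numeric(offset), length(offset) == 1L, is.finite(offset))
  if (m <= 0) stop("'m' must be positive", call. = FALSE)
  if (e <= 0) stop("'e' must be positive", call. = FALSE)
  if (h <= 0) stop("'h' must be positive", call. = FALSE)
  if (offset < 0) stop("'offset' must be nonnegative", call. = FALSE)
  structure(list(m = m, e = e, h = h, offset = offset,
                 direction = direction),
            class = "hill_spec")
}

#' @export
print.hill_spec <- function(x, ...) {
  cat(sprintf("Hill response (%s): m = %g, e = %g, h = %g, offset = %g\n",
              x$direction, x$m, x$e, x$h, x$offset))
  invisible(x)
}

#' @export
predict.hill_spec <- function(object, newdata, ...) {
  if (object$direction == "increasing") hill_increasing(newdata, object)
  else hill_decreasing(newdata, object)
}

# bare-parameter kernels, vectorised over x; 0^h is 0 for all h > 0 in R,
# which is the continuous limit used throughout
.hill_up <- function(x, m, e, h) m * x^h / (e^h + x^h)
.hill_down <- function(x, m, e, h) m / (1 + (x / e)^h)

.check_nonneg <- function(x, what = "x") {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(sprintf("'%s' must be finite numeric", what), call. = FALSE)
  if (any(x < 0))
    stop(sprintf("'%s' must be nonnegative", what), call. = FALSE)
  invisible(x)
}

#' Increasing Hill response
#'
#' Evaluates `offset + m * x^h / (e^h + x^h)`.  At `x = 0` the response is
#' exactly `offset` (the numerator vanishes for any `h > 0`).
#'
#' @param x Nonnegative input level(s).
#' @param spec A [hill_spec()] with `direction = "increasing"`.
#' @return Numeric vector of responses.
#' @export
hill_increasing <- function(x, spec) {
  stopifnot(inherits(spec, "hill_spec"))
  if (spec$direction != "increasing")
    stop("'spec' must have direction \"increasing\"", call. = FALSE)
  .check_nonneg(x)
  spec$offset + .hill_up(x, spec$m, spec$e, spec$h)
}

#' Decreasing Hill response
#'
#' Evaluates `offset + m / (1 + (x/e)^h)`.  At `x = 0` the response is the
#' maximum `offset + m`; at `x = e` it is `offset + m/2`.
#'
#' @param x Nonnegative input level(s).
#' @param spec A [hill_spec()]; its `direction` field is not consulted, the
#'   decreasing form is always evaluated.
#' @return Numeric vector of responses.
#' @export
hill_decreasing <- function(x, spec) {
  stopifnot(inherits(spec, "hill_spec"))
  .check_nonneg(x)
  spec$offset + .hill_down(x, spec$m, spec$e, spec$h)
}

#' Shifted self-limiting response
#'
#' The state-dependent decay factor of each endocrine axis:
#' `k(x) = 1 + 4 / (1 + (alpha * x / e_k)^h_k)`.  It approaches 5 as `x`
#' tends to zero (self-inhibition dominates) and 1 as `x` grows (mutual
#' inhibition dominates), so its value always lies in (1, 5].
#'
#' @param x Nonnegative activity level(s).
#' @param e_k Half-saturation constant of the shift (activity units).
#' @param h_k Hill coefficient (dimensionless).
#' @param alpha Modulation factor, strictly inside (0, 1).
#' @return Numeric vector of `k` values in (1, 5].
#' @examples
#' shifted_self_limit(0, 25.57, 6.6, 0.48)  # 5
#' @export
shifted_self_limit <- function(x, e_k, h_k, alpha) {
  stopifnot(is.numeric(e_k), e_k > 0, is.numeric(h_k), h_k > 0)
  if (!is.numeric(alpha) || length(alpha) != 1L ||
      alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly inside (0, 1)", call. = FALSE)
  .check_nonneg(x)
  1 + 4 / (1 + (alpha * x / e_k)^h_k)
}

#' Per-field medians of a set of parameter records
#'
#' Aggregates fitted Hill parameters (or any numeric records) by taking the
#' sample median of each numeric field, skipping missing entries per field.
#' For an even number of values the midpoint of the two central order
#' statistics is returned (the [stats::median()] convention).
#'
#' @param x A data frame, or a list of named lists / `hill_spec` objects
#'   with numeric fields.
#' @return Named numeric vector of per-field medians.
#' @examples
#' aggregate_medians(data.frame(h = c(2, 2, 2, 2, 1.2, 1.15, 2.8)))
#' @export
aggregate_medians <- function(x) {
  if (is.data.frame(x)) {
    df <- x
  } else if (is.list(x) && length(x) > 0L) {
    recs <- lapply(x, function(r) {
      r <- unclass(r)
      r[vapply(r, function(v) is.numeric(v) && length(v) == 1L,
               logical(1))]
    })
    fields <- unique(unlist(lapply(recs, names)))
    df <- as.data.frame(lapply(fields, function(f)
      vapply(recs, function(r) if (is.null(r[[f]])) NA_real_ else r[[f]],
             numeric(1))))
    names(df) <- fields
  } else {
    stop("'x' must be a nonempty data frame or list of records",
         call. = FALSE)
  }
  if (nrow(df) == 0L)
    stop("no records to aggregate", call. = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  if (!any(num))
    stop("no numeric fields to aggregate", call. = FALSE)
  vapply(df[num], function(col) stats::median(col, na.rm = TRUE),
         numeric(1))
}
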