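#' Fit a Hill function to a dose-response table
#'
#' Bounded least-squares fit of an increasing or decreasing Hill law to a
#' table of (input, output) pairs, with multi-start initial values: `e`
#' started at the input quartiles and `h` at 1, 2, 4 and 8; the start with
#' the smallest residual sum of squares wins, ties broken towards the
#' smaller `h`.  Optionally the two columns are first rescaled so each
#' spans 0-100 (observed minimum to 0, maximum to 100), the normalisation
#' used when pooling heterogeneous dose-response sources.
#'
#' Degenerate inputs fail loudly rather than fitting silently: a constant
#' input or output column, or a rank (Spearman) association whose sign
#' contradicts the requested direction, raises an error of class
#' `fmloop_fit_failure`.
#'
#' @param table Data frame whose first two numeric columns (or columns
#'   named `input` and `output`) hold the dose-response pairs; at least 3
#'   rows, all inputs finite and nonnegative.
#' @param direction `"increasing"` or `"decreasing"`.
#' @param normalize Logical; rescale both columns to the 0-100 span before
#'   fitting (default `FALSE`).
#' @param m Fixed maximal response span, or `NULL` (default) to estimate it.
#' @param offset Fixed response offset (default 0), or `NULL` to estimate.
#' @return An object of class `hill_fit` with components `spec` (the fitted
#'   [hill_spec()]), `coefficients`, `rss`, `spearman` (rank-correlation
#'   estimate and p-value, reported as a diagnostic only), `data`,
#'   `normalize` and `n_starts`.  Methods: `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`.
#' @examples
#' tab <- synth_dose_response(hill_spec(100, 28, 4.2,
#'                                      direction = "decreasing"),
#'                            n = 12, noise_sd = 0, seed = 1)
#' fit <- fit_hill(tab, direction = "decreasing")
#' coef(fit)
#' @export
fit_hill <- function(table, direction = c("decreasing", "increasing"),
                     normalize = FALSE, m = NULL, offset = 0) {
  direction <- match.arg(direction)
  xy <- .extract_xy(table)
  x <- xy$x
  y <- xy$y
  if (length(x) < 3L)
    stop("at least 3 rows are required for fitting", call. = FALSE)
  .check_nonneg(x, "input")

  free <- c(e = TRUE, h = TRUE, m = is.null(m), offset = is.null(offset))
  if (length(x) < sum(free))
    stop("fewer data points than free parameters", call. = FALSE)

  if (normalize) {
    x <- .normalize_0_100(x, "input")
    y <- .normalize_0_100(y, "output")
  }
  if (diff(range(y)) == 0)
    .fit_failure("output column is constant; nothing to fit")
  if (diff(range(x)) == 0)
    .fit_failure("input column is constant; nothing to fit")

  sp <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  rho <- unname(sp$estimate)
  expected_sign <- if (direction == "increasing") 1 else -1
  if (!is.finite(rho) || sign(rho) != expected_sign)
    .fit_failure(sprintf(
      "data are not monotone %s (Spearman rho = %.3f)", direction, rho))

  span <- diff(range(y))
  xmax <- max(x)
  lower <- c(e = xmax * 1e-4, h = 0.2, m = span * 1e-3, offset = 0)
  upper <- c(e = xmax * 10, h = 20, m = span * 10,
             offset = max(y))
  fixed <- c(m = if (is.null(m)) NA_real_ else m,
             offset = if (is.null(offset)) NA_real_ else offset)

  model_fun <- function(p) {
    mm <- if (free[["m"]]) p[["m"]] else fixed[["m"]]
    oo <- if (free[["offset"]]) p[["offset"]] else fixed[["offset"]]
    if (direction == "increasing") oo + .hill_up(x, mm, p[["e"]], p[["h"]])
    else oo + .hill_down(x, mm, p[["e"]], p[["h"]])
  }

  e_starts <- unique(stats::quantile(x[x > 0], c(0.25, 0.5, 0.75),
                                     names = FALSE))
  h_starts <- c(1, 2, 4, 8)
  best <- NULL
  n_starts <- 0L
  for (e0 in e_starts) for (h0 in h_starts) {
    p0 <- c(e = e0, h = h0)
    if (free[["m"]]) p0 <- c(p0, m = span)
    if (free[["offset"]]) p0 <- c(p0, offset = min(y))
    nm <- names(p0)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0,
        lower = lower[nm], upper = upper[nm],
        fn = function(p) y - model_fun(p),
        control = minpack.lm::nls.lm.control(
          ftol = 1e-14, ptol = 1e-14, maxiter = 500)),
      error = function(e) NULL)
    n_starts <- n_starts + 1L
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    better <- is.null(best) || rss < best$rss * (1 - 1e-10) ||
      (abs(rss - best$rss) <= best$rss * 1e-10 + 1e-300 &&
         fit$par[["h"]] < best$par[["h"]])
    if (better) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best))
    .fit_failure("no optimiser start converged")

  par <- best$par
  co <- c(e = unname(par[["e"]]), h = unname(par[["h"]]),
          m = if (free[["m"]]) unname(par[["m"]]) else fixed[["m"]],
          offset = if (free[["offset"]]) unname(par[["offset"]])
                   else fixed[["offset"]])
  structure(list(
    spec = hill_spec(m = co[["m"]], e = co[["e"]], h = co[["h"]],
                     offset = co[["offset"]], direction = direction),
    coefficients = co,
    rss = best$rss,
    spearman = list(rho = rho, p.value = sp$p.value),
    data = data.frame(input = x, output = y),
    direction = direction,
    normalize = normalize,
    free = free,
    n_starts = n_starts),
    class = "hill_fit")
}

.fit_failure <- function(msg) {
  stop(structure(class = c("fmloop_fit_failure", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.extract_xy <- function(table) {
  if (!is.data.frame(table))
    stop("'table' must be a data frame", call. = FALSE)
  if (all(c("input", "output") %in% names(table)))
    return(list(x = as.numeric(table$input),
                y = as.numeric(table$output)))
  num <- which(vapply(table, is.numeric, logical(1)))
  if (length(num) < 2L)
    stop("'table' needs two numeric columns (input, output)",
         call. = FALSE)
  list(x = as.numeric(table[[num[1]]]), y = as.numeric(table[[num[2]]]))
}

# observed min -> 0, max -> 100; constant columns are a fit failure
.normalize_0_100 <- function(v, what) {
  r <- range(v)
  if (diff(r) == 0)
    .fit_failure(sprintf("%s column is constant; cannot normalise", what))
  100 * (v - r[1]) / diff(r)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit (%s%s)\n", x$direction,
              if (x$normalize) ", 0-100 normalised" else ""))
  co <- x$coefficients
  cat(sprintf("  e = %.6g  h = %.6g  m = %.6g  offset = %.6g\n",
              co[["e"]], co[["h"]], co[["m"]], co[["offset"]]))
  cat(sprintf("  RSS = %.4g on %d points; Spearman rho = %.3f (p = %.2g)\n",
              x$rss, nrow(x$data), x$spearman$rho, x$spearman$p.value))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  xx <- if (is.null(newdata)) object$data$input
        else if (is.data.frame(newdata)) .extract_xy(newdata)$x
        else as.numeric(newdata)
  predict(object$spec, xx)
}

#' @export
fitted.hill_fit <- function(object, ...) predict(object)

#' @export
residuals.hill_fit <- function(object, ...)
  object$data$output - fitted(object)

#' @export
summary.hill_fit <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object,
                 sigma = sqrt(object$rss /
                                max(1L, nrow(object$data) -
                                      sum(object$free))),
                 residual_range = range(res)),
            class = "summary.hill_fit")
}

#' @export
print.summary.hill_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual sd = %.4g, residual range [%.4g, %.4g]\n",
              x$sigma, x$residual_range[1], x$residual_range[2]))
  invisible(x)
}
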