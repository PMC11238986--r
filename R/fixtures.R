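#' Load a packaged reference table
#'
#' The package ships, as plain CSV resources, the small reference tables
#' that parameterise the models: representative steroid concentrations
#' across female reproductive phases (`"t002"`), Hill parameters of
#' allopregnanolone effects on GABA-A receptors (`"t003"`, including the
#' printed median row), Hill parameters fitted to matched gonadal
#' hormone / corticosteroid samples (`"t005"`), and the endocrine-loop ODE
#' parameters (`"t006"`).  Dashes in the sources are stored as missing
#' values.
#'
#' @param id Table identifier, one of `"t002"`, `"t003"`, `"t005"`,
#'   `"t006"`.
#' @return A data frame of class `paper_table` with a `units` attribute.
#' @examples
#' t3 <- load_table("t003")
#' aggregate_medians(t3[t3$model != "Median values", ])
#' @export
load_table <- function(id) {
  available <- c("t002", "t003", "t005", "t006")
  if (!is.character(id) || length(id) != 1L || !(id %in% available))
    stop(sprintf("unknown table id %s; available: %s",
                 deparse(id), paste(available, collapse = ", ")),
         call. = FALSE)
  path <- system.file("extdata", paste0(id, ".csv"), package = "fmloop",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  units_path <- system.file("extdata", "units.json", package = "fmloop",
                            mustWork = TRUE)
  units <- jsonlite::fromJSON(units_path)[[id]]
  structure(tab, units = units, table_id = id,
            class = c("paper_table", "data.frame"))
}

#' Generate a synthetic dose-response table
#'
#' Samples a Hill curve at `n` log-spaced inputs spanning `[e/10, 10 e]`
#' and adds Gaussian noise, producing a table suitable for exercising
#' [fit_hill()] parameter recovery.  The generator restores the caller's
#' random-number state, so it does not disturb outer simulations.
#'
#' @param spec A [hill_spec()] giving the true curve.
#' @param n Number of points (at least 3, default 12).
#' @param noise_sd Standard deviation of additive Gaussian noise, in
#'   response units (default 0 = noiseless).
#' @param seed Integer seed recorded in the output; `NULL` uses the
#'   current random state.
#' @return A data frame with columns `input`, `output`, `label`, and
#'   attributes `seed`, `true_spec`.
#' @export
synth_dose_response <- function(spec, n = 12, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(spec, "hill_spec"))
  if (!is.numeric(n) || n < 3)
    stop("'n' must be at least 3", call. = FALSE)
  if (noise_sd < 0)
    stop("'noise_sd' must be nonnegative", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  x <- exp(seq(log(spec$e / 10), log(10 * spec$e), length.out = n))
  y <- predict(spec, x)
  if (noise_sd > 0) y <- y + stats::rnorm(n, sd = noise_sd)
  structure(data.frame(input = x, output = y,
                       label = sprintf("synthetic e=%g h=%g", spec$e,
                                       spec$h)),
            seed = seed, true_spec = spec,
            class = c("dose_response", "data.frame"))
}
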