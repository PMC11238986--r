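#' Default run configuration
#'
#' Nested list of every tunable parameter with its published default,
#' grouped by module, plus the solver block and seed.  [load_config()]
#' merges user files over this structure and rejects unknown keys.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    thalamo = list(a = 0.3, b = 1, theta = 1, tau = 0.5, m1 = 100,
                   m2 = 80, e = 20, e0 = 20, h = 2.5),
    steroid = list(a_f = 0.4, e_w = 1.8, h_w = 6.5, e_g = 18, h_g = 2),
    endocrine = list(e_x = 28, h_x = 4.2, e_k = 25.57, h_k = 6.6,
                     alpha = 0.48, tau = 30),
    coupling = list(hpg_low = 20, b_rest = 0.5, b_gain = 0.2),
    prevalence = list(cycles = 460, years = 37, p_man = 0.005,
                      days_per_year = 365),
    solver = list(rtol = 1e-8, atol = 1e-10, conv_tol = 1e-6,
                  horizon_thalamo = 60, horizon_endocrine = 1e4,
                  basin_n = 101, capture_radius = 0.5,
                  bifurcation_tol = 1e-3, grid_n = 2001),
    output_dir = ".")
}

.config_error <- function(msg) {
  stop(structure(class = c("fmloop_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# recursive merge of user values over defaults; unknown keys and type
# mismatches are named in the error
.merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      .config_error(sprintf("unknown configuration key '%s'", full))
    d <- defaults[[key]]
    u <- user[[key]]
    if (is.list(d)) {
      if (!is.list(u))
        .config_error(sprintf("key '%s' must be a block, got a scalar",
                              full))
      defaults[[key]] <- .merge_config(d, u, full)
    } else {
      if (is.list(u))
        .config_error(sprintf("key '%s' must be a scalar, got a block",
                              full))
      if (is.numeric(d) && !is.numeric(u))
        .config_error(sprintf("key '%s' must be numeric, got %s", full,
                              class(u)[1]))
      if (is.character(d) && !is.character(u))
        .config_error(sprintf("key '%s' must be character, got %s", full,
                              class(u)[1]))
      defaults[[key]] <- u
    }
  }
  defaults
}

#' Load a run configuration
#'
#' Reads a YAML or JSON configuration file and merges it over
#' [default_config()].  An empty file yields the full defaults; unknown
#' keys and type mismatches raise an error of class
#' `fmloop_config_error` naming the offending key.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for
#'   the defaults.
#' @param defaults Base configuration (default [default_config()]).
#' @return The effective configuration, with attribute `config_hash`.
#' @export
load_config <- function(path = NULL, defaults = default_config()) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path))
      .config_error(sprintf("configuration file '%s' does not exist",
                            path))
    ext <- tolower(tools::file_ext(path))
    user <- tryCatch(
      if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
      else yaml::read_yaml(path),
      error = function(e)
        .config_error(sprintf("cannot parse '%s': %s", path,
                              conditionMessage(e))))
    if (is.null(user)) user <- list()
    if (!is.list(user))
      .config_error(sprintf("'%s' does not contain a mapping", path))
  }
  cfg <- .merge_config(defaults, user)
  attr(cfg, "config_hash") <- config_hash(cfg)
  cfg
}

#' Hash of an effective configuration
#'
#' Order-independent FNV-1a hash of the configuration's canonical JSON
#' serialisation; embedded in every result file so any output can be
#' traced back to the exact configuration (plus seed) that produced it.
#'
#' @param config A configuration list.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  attr(config, "config_hash") <- NULL
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(js))
  # 32-bit FNV-1a carried in a double; the multiply is split into 16-bit
  # halves so every intermediate stays inside the exact-integer range
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b))
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Write a result object to disk
#'
#' Tabular results (data frames: trajectories, bifurcation curves, basin
#' grids) are written as CSV with `#`-prefixed header lines carrying the
#' configuration hash and seed; structured results (equilibria sets,
#' scenario reports, arbitrary lists) as JSON with the same metadata
#' embedded, eigenvalues serialised as (re, im) pairs.
#'
#' @param object The result to serialise.
#' @param path Output file path; format follows the extension unless
#'   `format` is given.
#' @param format `"auto"` (default), `"csv"` or `"json"`.
#' @param config Optional effective configuration (hashed into the file).
#' @param seed Optional integer seed recorded in the file.
#' @return `path`, invisibly.
#' @export
write_results <- function(object, path, format = c("auto", "csv", "json"),
                          config = NULL, seed = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (is.data.frame(object)) "csv" else "json"
  hash <- if (is.null(config)) NA_character_ else config_hash(config)
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop(sprintf("cannot write to '%s': directory does not exist", path),
         call. = FALSE)
  if (format == "csv") {
    if (!is.data.frame(object))
      stop("CSV output requires a data frame", call. = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# config_hash: %s", hash), con)
    writeLines(sprintf("# seed: %s",
                       if (is.null(seed)) NA else seed), con)
    utils::write.table(object, con, sep = ",", row.names = FALSE,
                       qmethod = "double")
  } else {
    payload <- .jsonify(object)
    out <- list(config_hash = hash,
                seed = if (is.null(seed)) NA else seed,
                result = payload)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}

# lossless-enough JSON form for the package's classed objects
.jsonify <- function(x) {
  if (inherits(x, "equilibria_set")) {
    list(system = attr(x, "system"),
         equilibria = lapply(unclass(x), .jsonify))
  } else if (inherits(x, "loop_equilibrium")) {
    list(state = as.list(x$state),
         eigenvalues = lapply(x$eigenvalues,
                              function(z) c(Re(z), Im(z))),
         stability = x$stability,
         residual = x$residual)
  } else if (inherits(x, "fm_scenario") || inherits(x, "steroid_chain")) {
    lapply(unclass(x), function(s)
      list(value = .jsonify(s$value), provenance = s$provenance))
  } else if (inherits(x, "steroid_map_params") ||
             inherits(x, "thalamo_params") ||
             inherits(x, "endocrine_params")) {
    unclass(x)
  } else if (is.function(x)) {
    "<function>"
  } else if (is.list(x) && !is.data.frame(x)) {
    lapply(x, .jsonify)
  } else x
}

#' Read back a result file
#'
#' Inverse of [write_results()]: CSV comment headers are skipped, JSON
#' files return the full `list(config_hash, seed, result)` structure.
#'
#' @param path File written by [write_results()].
#' @return Data frame (CSV) or list (JSON).
#' @export
read_results <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv")
    utils::read.csv(path, comment.char = "#")
  else
    jsonlite::fromJSON(path, simplifyVector = TRUE)
}
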