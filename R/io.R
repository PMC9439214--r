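#' Read and write daily temperature series as CSV
#'
#' The CSV schema is a header row `date,temp_C` with ISO-8601 dates, one row
#' per day. Duplicate or missing days are rejected: the daily model needs a
#' complete series. `write_temperature_csv()` writes temperatures with 17
#' significant digits so a round trip preserves values exactly.
#'
#' @param path File path.
#' @param series A [temperature_series()].
#' @return `read_temperature_csv()` returns a [temperature_series()];
#'   `write_temperature_csv()` returns `path` invisibly.
#' @export
read_temperature_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tc <- intersect(c("temp_C", "temperature_C", "temp"), names(df))
  if (!"date" %in% names(df) || length(tc) == 0)
    stop("temperature CSV needs columns 'date' and 'temp_C'", call. = FALSE)
  temp <- suppressWarnings(as.numeric(df[[tc[1]]]))
  bad <- which(!is.finite(temp))
  if (length(bad))
    stop("malformed temperature at line ", bad[1] + 1L, " of ", path, call. = FALSE)
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  bad <- which(is.na(dates))
  if (length(bad))
    stop("malformed date at line ", bad[1] + 1L, " of ", path, call. = FALSE)
  temperature_series(temp, dates = dates)
}

#' @rdname read_temperature_csv
#' @export
write_temperature_csv <- function(series, path) {
  stopifnot(inherits(series, "temperature_series"))
  df <- data.frame(date = format(series$date, "%Y-%m-%d"),
                   temp_C = sprintf("%.17g", series$temp))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write bioassay datasets as CSV
#'
#' Schema: `female_id,week,eggs,alive,host,regime_name`. On read, rows are
#' validated: nonnegative egg counts, weeks contiguous from 1 within each
#' female, and no "resurrection" (once dead, a female stays dead).
#'
#' @param path File path.
#' @param data A `"bioassay_data"` frame (or compatible data frame).
#' @return `read_bioassay_csv()` returns a `"bioassay_data"` frame;
#'   `write_bioassay_csv()` returns `path` invisibly.
#' @export
read_bioassay_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("female_id", "week", "eggs", "alive", "host", "regime_name")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("bioassay CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$alive <- as.logical(df$alive)
  bad <- which(!is.finite(df$eggs) | df$eggs < 0)
  if (length(bad))
    stop("malformed egg count at line ", bad[1] + 1L, " of ", path, call. = FALSE)
  if (anyNA(df$alive))
    stop("malformed alive flag at line ",
         which(is.na(df$alive))[1] + 1L, " of ", path, call. = FALSE)
  for (d in split(df, df$female_id)) {
    d <- d[order(d$week), ]
    if (!identical(as.integer(d$week), seq_len(nrow(d))))
      stop("weeks not contiguous from 1 for female ", d$female_id[1], call. = FALSE)
    if (any(diff(d$alive) > 0))
      stop("alive flag becomes TRUE after death for female ", d$female_id[1],
           call. = FALSE)
  }
  structure(df, n_females = length(unique(df$female_id)),
            class = c("bioassay_data", "data.frame"))
}

#' @rdname read_bioassay_csv
#' @export
write_bioassay_csv <- function(data, path) {
  req <- c("female_id", "week", "eggs", "alive", "host", "regime_name")
  stopifnot(is.data.frame(data), all(req %in% names(data)))
  utils::write.csv(as.data.frame(data)[, req], path, row.names = FALSE)
  invisible(path)
}

#' Host-plant parameter bundles: load, write, defaults
#'
#' Parameter bundles are stored as a small YAML file: a top-level `hosts`
#' map whose entries each carry the four component parameter sets plus an
#' optional provenance note. All model invariants are validated on load, and
#' the file round-trips losslessly (write, read, write gives identical
#' bytes).
#'
#' `default_host_models()` returns the bundle shipped with the package: the
#' fitted beet-leafhopper parameter sets for sugar beet (the baseline host)
#' and the four non-agricultural hosts (*Erodium cicutarium*, *Kochia
#' scoparia*, *Plantago ovata*, *Salsola tragus*). The fecundity curves share
#' `t_max` and `k` and differ in `r_m`; the aging curves share `a`, `b`, `c`
#' and differ in `sigma`; the oviposition schedule and survival curves are
#' common to all hosts.
#'
#' @param path YAML file path.
#' @param models A named list of [host_plant_model()] objects.
#' @return `load_host_models()` and `default_host_models()` return a named
#'   list of [host_plant_model()] objects; `write_host_models()` returns
#'   `path` invisibly.
#' @examples
#' hosts <- default_host_models()
#' names(hosts)
#' hosts$sugar_beet$fecundity$r_m
#' @export
load_host_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (!is.list(y) || is.null(y$hosts))
    stop("parameter bundle lacks a top-level 'hosts' map", call. = FALSE)
  out <- lapply(names(y$hosts), function(key) {
    h <- y$hosts[[key]]
    need <- function(block, field) {
      v <- h[[block]][[field]]
      if (is.null(v) || !is.numeric(v))
        stop("parameter bundle entry '", key, "': missing or non-numeric field '",
             block, ".", field, "'", call. = FALSE)
      v
    }
    if (is.null(h$host) || !nzchar(h$host))
      stop("parameter bundle entry '", key, "': missing field 'host'", call. = FALSE)
    par_string <- h$survival$parameterization
    if (is.null(par_string)) par_string <- "slope_multiplier"
    host_plant_model(
      host = h$host,
      fecundity = fecundity_params(need("fecundity", "r_m"),
                                   need("fecundity", "t_max"),
                                   need("fecundity", "k")),
      aging = aging_params(need("aging", "a"), need("aging", "b"),
                           need("aging", "c"), need("aging", "sigma")),
      schedule = schedule_params(need("schedule", "alpha"),
                                 need("schedule", "beta")),
      survival = survival_params(need("survival", "gamma"),
                                 need("survival", "delta"), par_string),
      note = h$note)
  })
  names(out) <- names(y$hosts)
  out
}

#' @rdname load_host_models
#' @export
write_host_models <- function(models, path) {
  stopifnot(is.list(models), length(models) > 0, !is.null(names(models)))
  hosts <- lapply(models, function(m) {
    stopifnot(inherits(m, "host_model"))
    entry <- list(
      host = m$host,
      fecundity = list(r_m = m$fecundity$r_m, t_max = m$fecundity$t_max,
                       k = m$fecundity$k),
      aging = list(a = m$aging$a, b = m$aging$b, c = m$aging$c,
                   sigma = m$aging$sigma),
      schedule = list(alpha = m$schedule$alpha, beta = m$schedule$beta),
      survival = list(gamma = m$survival$gamma, delta = m$survival$delta,
                      parameterization = m$survival$parameterization))
    if (!is.null(m$note)) entry$note <- m$note
    entry
  })
  writeLines(yaml::as.yaml(list(hosts = hosts), precision = 15), path)
  invisible(path)
}

#' @rdname load_host_models
#' @export
default_host_models <- function() {
  load_host_models(system.file("extdata", "host_parameters.yaml",
                               package = "ovitherm", mustWork = TRUE))
}
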