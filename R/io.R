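# Trace CSV and configuration file I/O.  Traces are plain CSV with header
# `time_s,temp_c[,label]`; lines starting with '#' carry provenance and are
# ignored on read.  Configurations are YAML or JSON in clinical units.

#' Read a temperature trace from CSV
#'
#' Expects a header `time_s,temp_c` with an optional `label` column;
#' comment lines beginning with `#` are skipped.  Non-numeric cells and
#' non-increasing times are rejected with the offending file line number.
#'
#' @param path Path to the CSV file.
#' @return A [temperature_trace()].
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  if (!length(raw)) stop("empty trace file: ", path, call. = FALSE)
  lineno <- seq_along(raw)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  raw <- raw[keep]; lineno <- lineno[keep]
  if (length(raw) < 3L)
    stop("trace file needs a header and >= 2 data rows: ", path,
         call. = FALSE)
  header <- trimws(strsplit(raw[1L], ",")[[1L]])
  if (length(header) < 2L || header[1L] != "time_s" || header[2L] != "temp_c")
    stop("bad trace header (expected 'time_s,temp_c[,label]') in ", path,
         call. = FALSE)
  cells <- strsplit(raw[-1L], ",")
  dl <- lineno[-1L]
  bad <- which(vapply(cells, length, integer(1)) < 2L)
  if (length(bad))
    stop("line ", dl[bad[1L]], " of ", path, ": expected >= 2 fields",
         call. = FALSE)
  times <- suppressWarnings(as.numeric(vapply(cells, `[[`, "", 1L)))
  temps <- suppressWarnings(as.numeric(vapply(cells, `[[`, "", 2L)))
  bad <- which(is.na(times) | is.na(temps))
  if (length(bad))
    stop("line ", dl[bad[1L]], " of ", path, ": non-numeric value",
         call. = FALSE)
  nonmono <- which(diff(times) <= 0)
  if (length(nonmono))
    stop("line ", dl[nonmono[1L] + 1L], " of ", path,
         ": time is not strictly increasing", call. = FALSE)
  label <- if (length(header) >= 3L && header[3L] == "label" &&
               length(cells[[1L]]) >= 3L) cells[[1L]][3L] else "trace"
  temperature_trace(times, temps, label = label)
}

#' Write a temperature trace to CSV
#'
#' Writes `time_s,temp_c,label` rows in 6-decimal fixed point, preceded by
#' a `#` provenance comment (package version, label, sample count).
#'
#' @param trace A [temperature_trace()].
#' @param path Output path.
#' @param provenance Write the provenance comment line?
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, provenance = TRUE) {
  if (!inherits(trace, "temperature_trace"))
    stop("'trace' must be a temperature_trace", call. = FALSE)
  lab <- attr(trace, "label")
  lines <- c(
    if (provenance)
      sprintf("# lithotherm %s trace label=%s n=%d",
              as.character(utils::packageVersion("lithotherm")), lab,
              nrow(trace)),
    "time_s,temp_c,label",
    sprintf("%.6f,%.6f,%s", trace$time_s, trace$temp_c, lab))
  writeLines(lines, path)
  invisible(path)
}

CONFIG_KEYS <- c("volume_ml", "flow_ml_min", "t_in_c", "t0_c",
                 "beta_w_per_c", "laser", "fluid", "dose")
DOSE_KEYS <- c("threshold_min", "horizon_s")
FLUID_KEYS <- c("k", "rho", "c")

#' Read a run configuration file
#'
#' Loads a YAML (`.yml`/`.yaml`) or JSON configuration holding the system
#' settings in clinical units — `volume_ml`, `flow_ml_min`, `t_in_c`,
#' `t0_c`, `beta_w_per_c`, an optional `laser` list of
#' `{on_s, off_s, power_w}` intervals, optional `fluid` properties
#' `{k, rho, c}` and optional `dose` policy `{threshold_min, horizon_s}`.
#' Unknown keys are rejected.
#'
#' @param path Path to the configuration file.
#' @return A list with elements `cfg` ([system_config()]), `schedule`
#'   ([laser_schedule()] or `NULL`) and `dose` (list of policy settings).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  unknown <- setdiff(names(obj), CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (req in c("volume_ml", "t0_c"))
    if (is.null(obj[[req]]))
      stop("configuration is missing '", req, "'", call. = FALSE)
  fl <- fluid_properties()
  if (!is.null(obj$fluid)) {
    unknown <- setdiff(names(obj$fluid), FLUID_KEYS)
    if (length(unknown))
      stop("unknown fluid key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    fa <- utils::modifyList(list(k = fl$k, rho = fl$rho, c = fl$c),
                            obj$fluid)
    fl <- fluid_properties(fa$k, fa$rho, fa$c)
  }
  cfg <- system_config(
    volume_ml = obj$volume_ml, t0_c = obj$t0_c,
    beta_w_per_c = if (is.null(obj$beta_w_per_c)) NA else obj$beta_w_per_c,
    flow_ml_min = if (is.null(obj$flow_ml_min)) 0 else obj$flow_ml_min,
    tin_c = if (is.null(obj$t_in_c)) obj$t0_c else obj$t_in_c,
    fluid = fl)
  schedule <- NULL
  if (!is.null(obj$laser)) {
    iv <- obj$laser
    if (!is.null(names(iv))) iv <- list(iv)   # single interval as a map
    schedule <- laser_schedule(
      vapply(iv, function(x) as.numeric(x$on_s), numeric(1)),
      vapply(iv, function(x) as.numeric(x$off_s), numeric(1)),
      vapply(iv, function(x) as.numeric(x$power_w), numeric(1)))
  }
  dose <- list(threshold_min = DOSE_THRESHOLD_MIN, horizon_s = NULL)
  if (!is.null(obj$dose)) {
    unknown <- setdiff(names(obj$dose), DOSE_KEYS)
    if (length(unknown))
      stop("unknown dose key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    dose <- utils::modifyList(dose, obj$dose)
  }
  list(cfg = cfg, schedule = schedule, dose = dose)
}
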