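# Trace files: CSV (time_s, o2_um) plus a YAML sidecar carrying injection
# times and system metadata, so the trace file itself stays tool-agnostic.

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".meta.yaml")
}

#' Write an oxygen-uptake trace to CSV plus metadata sidecar
#'
#' The trace goes to `path` as UTF-8 CSV with header `time_s,o2_um`
#' ('.' decimal separator, seconds and micromolar at the file boundary); the
#' injection times and system metadata go to a YAML sidecar named
#' `<stem>.meta.yaml` next to it.
#'
#' @param trace An [ox_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "ox_trace"))
  df <- data.frame(time_s = trace$times, o2_um = trace$o2 * 1e6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  meta <- trace$meta
  meta$t_init <- trace$t_init
  meta$t_aox <- if (is.na(trace$t_aox)) NULL else trace$t_aox
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read an oxygen-uptake trace from CSV plus metadata sidecar
#'
#' Validates the file against the trace invariants and refuses malformed
#' input rather than coercing it: a missing `time_s`/`o2_um` header,
#' non-monotone times or negative O2 raise a format error naming the
#' offending line. The round trip through [write_trace()] reproduces times
#' and O2 to better than 1e-12 relative and all metadata exactly.
#'
#' @param path CSV path (sidecar `<stem>.meta.yaml` must exist for injection
#'   times; without it `t_init` defaults to 0 and `t_aox` to absent).
#' @return An [ox_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("no such trace file: %s", path))
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("time_s", "o2_um") %in% names(df)))
    stop_format(sprintf("trace file %s lacks required 'time_s'/'o2_um' header",
                        path))
  sc <- sidecar_path(path)
  meta <- if (file.exists(sc)) yaml::read_yaml(sc) else list()
  t_init <- if (!is.null(meta$t_init)) meta$t_init else 0
  t_aox <- if (!is.null(meta$t_aox)) meta$t_aox else NA_real_
  meta$t_init <- NULL
  meta$t_aox <- NULL
  ox_trace(df$time_s, df$o2_um * 1e-6, t_init = t_init, t_aox = t_aox,
           meta = meta)
}

#' Write a kinetic report (or several) as JSON and aligned text
#'
#' @param reports A single `kinetic_report` or a list of them.
#' @param path_json JSON output path (machine-readable; SI units).
#' @param path_txt Optional text output path (display conventions: nM/s,
#'   minutes, chain-length rounding).
#' @return `path_json`, invisibly.
#' @export
write_report <- function(reports, path_json, path_txt = NULL) {
  if (inherits(reports, "kinetic_report")) reports <- list(reports)
  tab <- kinetic_table(reports, display = FALSE)
  jsonlite::write_json(tab, path_json, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(path_txt)) {
    disp <- kinetic_table(reports, display = TRUE)
    con <- file(path_txt, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(utils::capture.output(print(disp, row.names = FALSE)), con)
  }
  invisible(path_json)
}

#' Read a tidy endpoint table (group, replicate, value) from CSV
#'
#' @param path CSV path with columns `group`, `replicate`, `value`.
#' @return Data frame.
#' @export
read_endpoints <- function(path) {
  if (!file.exists(path))
    stop_format(sprintf("no such endpoint file: %s", path))
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("group", "replicate", "value") %in% names(df)))
    stop_format("endpoint file lacks required 'group,replicate,value' header")
  df
}

#' Write an effect table as CSV
#'
#' @param effects An `effect_table` from [summarize_endpoint()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_effects <- function(effects, path) {
  utils::write.csv(as.data.frame(effects), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
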