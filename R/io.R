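#' Read a decay curve from a two-column CSV
#'
#' Expects a header row `time_ms,signal` followed by numeric rows. Leading
#' lines starting with `#` are parsed as `key: value` metadata (e.g.
#' `# temperature_c: 60`) and attached to the curve's `meta`. Validation
#' errors name the offending line.
#'
#' @param path file path.
#' @return a [decay_curve()].
#' @seealso [write_decay_csv()]
#' @export
read_decay_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  meta <- list()
  for (cl in lines[is_comment]) {
    m <- regmatches(cl, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", cl))[[1]]
    if (length(m) == 3) {
      val <- type.convert(trimws(m[3]), as.is = TRUE)
      meta[[trimws(m[2])]] <- val
    }
  }
  body <- lines[!is_comment & nzchar(trimws(lines))]
  if (length(body) < 2) stop("no data rows in ", path, call. = FALSE)
  tab <- tryCatch(
    utils::read.csv(text = paste(body, collapse = "\n")),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  if (!all(c("time_ms", "signal") %in% names(tab)))
    stop(path, " must have columns time_ms and signal", call. = FALSE)
  bad <- which(!is.finite(tab$time_ms) | !is.finite(tab$signal))
  if (length(bad))
    stop("non-numeric value(s) in ", path, " at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  if (any(diff(tab$time_ms) <= 0)) {
    i <- which(diff(tab$time_ms) <= 0)[1]
    stop("echo times not strictly increasing in ", path, " at data row ",
         i + 1L, call. = FALSE)
  }
  if (nrow(tab) < 4)
    stop(path, " has only ", nrow(tab), " samples; at least 4 required",
         call. = FALSE)
  decay_curve(tab$time_ms, tab$signal, meta)
}

#' Write a decay curve as a two-column CSV
#'
#' Scalar metadata entries are written as `# key: value` comment lines above
#' the header, so [read_decay_csv()] round-trips the curve.
#'
#' @param curve a [decay_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_decay_csv <- function(curve, path) {
  if (!inherits(curve, "decay_curve"))
    stop("`curve` must be a decay_curve", call. = FALSE)
  scalars <- Filter(function(v) is.atomic(v) && length(v) == 1, curve$meta)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(scalars))
    writeLines(sprintf("# %s: %s", k, format(scalars[[k]], digits = 15)), con)
  writeLines("time_ms,signal", con)
  writeLines(paste(format(curve$times, digits = 15, trim = TRUE),
                   format(curve$signal, digits = 15, trim = TRUE), sep = ","),
             con)
  invisible(path)
}

## Cheap deterministic content hash (djb2-style polynomial mod 2^31) for
## provenance stamps; all arithmetic stays exact in doubles.
content_hash <- function(x) {
  h <- 5381
  for (b in utf8ToInt(x)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}
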