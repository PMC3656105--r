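#' Blood-flow trace
#'
#' A uniformly sampled laser-Doppler-style skin blood-flow record with its
#' acquisition metadata. Flux is in arbitrary perfusion units.
#'
#' @param values flux samples (finite, arbitrary perfusion units).
#' @param fs sampling rate in Hz, positive.
#' @param subject_id subject label.
#' @param group `"CTRL"` or `"SCI"`.
#' @param t_release time (s) at which the occluding pressure was released;
#'   must lie within the record.
#' @return An object of class `bf_trace` with fields `t`, `flux`, `fs`,
#'   `subject_id`, `group`, `t_release`.
#' @export
bf_trace <- function(values, fs, subject_id = "S1", group = c("CTRL", "SCI"),
                     t_release = 0) {
  group <- match.arg(group)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a positive number", call. = FALSE)
  if (!all(is.finite(values)))
    stop("trace values must be finite", call. = FALSE)
  n <- length(values)
  t <- (seq_len(n) - 1) / fs
  if (t_release < 0 || t_release > t[n])
    stop("t_release must lie within the record", call. = FALSE)
  structure(list(t = t, flux = as.numeric(values), fs = fs,
                 subject_id = subject_id, group = group,
                 t_release = t_release),
            class = "bf_trace")
}

#' @export
print.bf_trace <- function(x, ...) {
  cat(sprintf("<bf_trace> %s [%s]  %d samples @ %g Hz (%.1f s), release at %g s\n",
              x$subject_id, x$group, length(x$flux), x$fs,
              max(x$t), x$t_release))
  invisible(x)
}

#' Write a trace to CSV
#'
#' The canonical on-disk format: commented metadata header lines
#' (`# key: value`) followed by `t_s,flux` columns.
#'
#' @param trace a [bf_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# subject_id: %s", trace$subject_id),
    sprintf("# group: %s", trace$group),
    sprintf("# fs: %.10g", trace$fs),
    sprintf("# t_release: %.10g", trace$t_release),
    "t_s,flux"), con)
  writeLines(sprintf("%.10g,%.10g", trace$t, trace$flux), con)
  invisible(path)
}

#' Read a trace from CSV
#'
#' @param path file written by [write_trace_csv()].
#' @return A [bf_trace()].
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  body <- lines[!grepl("^#", lines)]
  dat <- utils::read.csv(text = paste(body, collapse = "\n"))
  bf_trace(values = dat$flux,
           fs = as.numeric(meta$fs),
           subject_id = meta$subject_id %||% "S1",
           group = meta$group %||% "CTRL",
           t_release = as.numeric(meta$t_release))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate trace with a new flux vector, keeping metadata.
retrace <- function(trace, values, fs = trace$fs, t_release = trace$t_release) {
  bf_trace(values, fs = fs, subject_id = trace$subject_id,
           group = trace$group, t_release = t_release)
}
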