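#' @name smat_io
#' @title CSV and TIFF interchange
#' @description
#' Tabular results are exchanged as CSV with a small commented metadata
#' header (tool version, seed, config hash) so every output is traceable
#' to the run that produced it; images as multi-page grayscale TIFF
#' (8- or 16-bit unsigned), page order = time order, accompanied by a
#' manifest CSV (`path`, `condition`, `replicate`, `field`, `time_min`
#' as a semicolon-separated list).
NULL

# Polynomial rolling hash of a character string, as 8 hex digits.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a CSV with a commented metadata header
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param seed Seed recorded in the header.
#' @param extra Named list of extra metadata fields.
#' @return `path`, invisibly.
#' @export
write_csv_meta <- function(df, path, seed = NA, extra = list()) {
  meta <- c(list(tool = paste0("smatkit ",
                               as.character(utils::packageVersion("smatkit"))),
                 seed = seed, config_hash = config_hash(extra)), extra)
  hdr <- vapply(names(meta), function(k)
    sprintf("# %s: %s", k, paste(meta[[k]], collapse = ";")), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_csv_meta()]
#' @param path CSV path.
#' @return Data frame (metadata lines are skipped).
#' @export
read_csv_meta <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Read a time-lapse manifest and its TIFF stacks into traces
#'
#' Loads every stack listed in a manifest CSV, measures the per-frame
#' mean gray value, and assembles the long trace table. Unreadable files
#' are skipped with a warning and listed in the `failures` attribute so a
#' batch never aborts on one bad stack.
#'
#' @param manifest_path Path to `manifest.csv` (stack paths are resolved
#'   relative to its directory).
#' @param background `"none"` (raw mean gray value, the default),
#'   `"manifest"` (subtract the manifest's recorded constant background),
#'   or `"auto"` (estimate from the first frame's 25th percentile).
#' @return Long trace table; attribute `failures` lists unreadable paths.
#' @export
read_stack_traces <- function(manifest_path,
                              background = c("none", "manifest", "auto")) {
  background <- match.arg(background)
  man <- utils::read.csv(manifest_path, comment.char = "#")
  base <- dirname(manifest_path)
  rows <- list(); failures <- character(0)
  for (i in seq_len(nrow(man))) {
    path <- file.path(base, man$path[i])
    frames <- tryCatch(tiff::readTIFF(path, all = TRUE),
                       error = function(e) NULL)
    if (is.null(frames)) {
      warning("unreadable stack skipped: ", path)
      failures <- c(failures, path)
      next
    }
    times <- as.numeric(strsplit(as.character(man$time_min[i]), ";")[[1]])
    bg <- switch(background,
                 none = 0,
                 manifest = if ("background" %in% names(man))
                   man$background[i] else 0,
                 auto = "auto")
    rows[[length(rows) + 1]] <- image_series_trace(
      frames, times, condition = man$condition[i],
      replicate = man$replicate[i], field = man$field[i], background = bg)
  }
  out <- do.call(rbind, rows)
  if (length(failures))
    warning(length(failures), " of ", nrow(man), " stacks unreadable")
  attr(out, "failures") <- failures
  out
}
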