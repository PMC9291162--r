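#' Read a gas-exchange CSV time series
#'
#' The package's CSV dialect: UTF-8, '.' decimal separator, a block of
#' `# key: value` metadata lines, then a header row and the data columns
#' (`time_s, A, gs, Ci, Ca, PAR, Tleaf, RH`, in any order; extra columns
#' such as `ca_set`/`par_set` are kept). Columns are matched by name.
#'
#' @param path file path.
#' @param require_time require a strictly increasing `time_s` column
#'   (disable for response-curve tables indexed by setpoint).
#' @return tibble of class `c4_gx` with a `meta` attribute (named list of
#'   the metadata block).
#' @export
read_gas_exchange <- function(path, require_time = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "c4dyn_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  meta_idx <- grep("^#", lines)
  meta <- list()
  for (ln in lines[meta_idx]) {
    kv <- sub("^#\\s*", "", ln)
    pos <- regexpr(":", kv, fixed = TRUE)
    if (pos > 0) {
      key <- trimws(substr(kv, 1, pos - 1))
      val <- trimws(substr(kv, pos + 1, nchar(kv)))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (is.na(num)) val else num
    }
  }
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) {
    abort("no data rows found", class = "c4dyn_io_error")
  }
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  ncol_expected <- length(header)
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  bad <- which(lengths(rows) != ncol_expected)
  if (length(bad) > 0) {
    file_lines <- setdiff(seq_along(lines), meta_idx)[-1][bad]
    abort(paste0("malformed row(s) at line(s): ",
                 paste(head(file_lines, 5), collapse = ", "),
                 if (length(bad) > 5) " ..." else ""),
          class = "c4dyn_io_error")
  }
  d <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(d) <- trimws(header)
  d[] <- lapply(d, function(x) suppressWarnings(as.numeric(x)))
  d <- as_tibble(d)
  mandatory <- c("time_s", "A", "gs")
  absent <- setdiff(mandatory, names(d))
  if (length(absent) > 0) {
    abort(paste0("missing mandatory column(s): ",
                 paste(absent, collapse = ", ")),
          class = "c4dyn_io_error")
  }
  if (require_time && any(diff(d$time_s) <= 0)) {
    abort("time_s is not strictly increasing", class = "c4dyn_io_error")
  }
  attr(d, "meta") <- meta
  class(d) <- c("c4_gx", class(d))
  d
}

#' Write a gas-exchange series (or simulation) to CSV
#'
#' Writes the package CSV dialect with a '#'-prefixed metadata header. If
#' the series carries a ground-truth attribute (synthetic data), the truth
#' parameters are written alongside as `<path>.truth.csv`.
#'
#' @param x tibble to write.
#' @param path output file.
#' @param meta named list of metadata to place in the header block.
#' @return `path`, invisibly.
#' @export
write_gas_exchange <- function(x, path, meta = list()) {
  truth <- attr(x, "truth")
  proto <- attr(x, "protocol")
  if (!is.null(proto) && is.null(meta$protocol)) meta$protocol <- proto
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (key in names(meta)) {
    writeLines(paste0("# ", key, ": ", meta[[key]]), con)
  }
  utils::write.table(as.data.frame(x), con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(truth)) {
    tr <- within_species(truth)
    utils::write.csv(as.data.frame(tr), paste0(path, ".truth.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Export a simulation result as CSV
#'
#' Column order: `time_s, A, gs, ci, tleaf, phi`, the per-enzyme effective
#' activation fractions, every reaction flux, then the metabolite
#' concentrations.
#'
#' @param sim a `c4_sim` tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  utils::write.csv(as.data.frame(sim), path, row.names = FALSE)
  invisible(path)
}
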