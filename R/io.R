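# Spectra container: one plain-text file per participant-region holding a
# commented key/value header (acquisition metadata + provenance) followed by
# a CSV block (index, real, imaginary).

#' Write an FID to the package's plain-text spectra container
#'
#' @param fid an \code{fid} object.
#' @param path output file path.
#' @param provenance optional named list written into the header.
#' @return invisibly, the path.
#' @export
write_fid <- function(fid, path, provenance = list()) {
  stopifnot(inherits(fid, "fid"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(n_points = fid$acq$n_points,
           spectral_width = fid$acq$spectral_width,
           transmitter_frequency = fid$acq$transmitter_frequency,
           repetition_time = fid$acq$repetition_time,
           echo_time = fid$acq$echo_time,
           center_ppm = fid$acq$center_ppm)
  for (k in names(hdr))
    writeLines(sprintf("# %s: %.10g", k, hdr[[k]]), con)
  for (k in names(provenance))
    writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
  writeLines(sprintf("# history: %s", paste(fid$history, collapse = " -> ")),
             con)
  writeLines("index,real,imaginary", con)
  utils::write.table(
    data.frame(seq_along(fid$samples), Re(fid$samples), Im(fid$samples)),
    con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an FID from the plain-text spectra container
#'
#' @param path file written by \code{\link{write_fid}}.
#' @return an \code{fid} object (header metadata restored).
#' @export
read_fid <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^# ", lines, value = TRUE)
  kv <- list()
  for (l in hdr_lines) {
    m <- regmatches(l, regexec("^# ([^:]+): (.*)$", l))[[1L]]
    if (length(m) == 3L) kv[[m[2L]]] <- m[3L]
  }
  body <- lines[!grepl("^# ", lines)]
  dat <- utils::read.csv(textConnection(paste(body, collapse = "\n")))
  acq <- acq_params(n_points = as.integer(as.numeric(kv$n_points)),
                    spectral_width = as.numeric(kv$spectral_width),
                    transmitter_frequency = as.numeric(kv$transmitter_frequency),
                    repetition_time = as.numeric(kv$repetition_time),
                    echo_time = as.numeric(kv$echo_time),
                    center_ppm = as.numeric(kv$center_ppm))
  new_fid(complex(real = dat$real, imaginary = dat$imaginary), acq,
          history = strsplit(kv$history %||% "", " -> ")[[1L]])
}

#' Write the cohort table as delimited text
#'
#' One row per participant; gender is a binary indicator column.
#'
#' @param cohort wide cohort data.frame.
#' @param path output path (tab-separated).
#' @return invisibly, the path.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a cohort table written by \code{\link{write_cohort_table}}
#' @param path tab-separated cohort table.
#' @return data.frame with \code{group} restored as a CN/aMCI/AD factor.
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("group" %in% names(df))
    df$group <- factor(df$group, levels = c("CN", "aMCI", "AD"))
  df
}

#' Write the long marker table (one row per participant x region)
#' @param markers long marker data.frame.
#' @param path output path (tab-separated).
#' @return invisibly, the path.
#' @export
write_marker_table <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
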