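# Plain-text file formats: trace CSV with commented metadata header, quench
# CSV, TCSPC CSV and key-value report files.

#' Write a stopped-flow trace as CSV
#'
#' Columns `time_s, signal_au`; concentrations, channel, id and bleach
#' calibration go into `#`-prefixed header comment lines.
#'
#' @param trace A [kin_trace()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# enzyme_uM=%.10g", trace$conc_enzyme),
               sprintf("# primer_uM=%.10g", trace$conc_primer),
               sprintf("# nucleotide_uM=%.10g", trace$conc_nucleotide),
               sprintf("# channel=%s", trace$channel),
               sprintf("# id=%s", trace$id),
               sprintf("# kbleach_per_s=%.10g", trace$kbleach),
               sprintf("# F0_au=%.10g", trace$F0)), con)
  write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(path)
}

# parse "# key=value" comment headers
read_header_comments <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  setNames(as.list(vals), keys)
}

#' Read a stopped-flow trace CSV written by [write_trace_csv()]
#' @param path CSV file.
#' @return A [kin_trace()].
#' @export
read_trace_csv <- function(path) {
  meta <- read_header_comments(path)
  df <- read.csv(path, comment.char = "#")
  if (!all(c("time_s", "signal_au") %in% names(df)))
    stop("malformed trace CSV '", path, "': need columns time_s, signal_au")
  num <- function(k, default = NA_real_)
    if (is.null(meta[[k]])) default else as.numeric(meta[[k]])
  kin_trace(df$time_s, df$signal_au,
            channel = if (is.null(meta$channel)) "Trp" else meta$channel,
            conc_enzyme = num("enzyme_uM"), conc_primer = num("primer_uM"),
            conc_nucleotide = num("nucleotide_uM"),
            id = if (is.null(meta$id)) basename(path) else meta$id,
            kbleach = num("kbleach_per_s", 0), F0 = num("F0_au", 0))
}

#' Write a quench-flow product time course as CSV
#' @param tc A [product_time_course()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_quench_csv <- function(tc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# conc_uM=%.10g", tc$conc_titrant),
               sprintf("# label=%s", tc$label)), con)
  write.csv(data.frame(time_s = tc$times,
                       product_fraction = tc$product_fraction),
            con, row.names = FALSE)
  invisible(path)
}

#' Read a quench-flow CSV
#'
#' Accepts the per-concentration format of [write_quench_csv()] or a long
#' format with a `conc_uM` column (returning one course per concentration).
#' @param path CSV file.
#' @return A [product_time_course()] or a list of them (long format).
#' @export
read_quench_csv <- function(path) {
  meta <- read_header_comments(path)
  df <- read.csv(path, comment.char = "#")
  if (!all(c("time_s", "product_fraction") %in% names(df)))
    stop("malformed quench CSV '", path,
         "': need columns time_s, product_fraction")
  if ("conc_uM" %in% names(df)) {
    return(lapply(split(df, df$conc_uM), function(d)
      product_time_course(d$time_s, d$product_fraction,
                          conc_titrant = d$conc_uM[1])))
  }
  product_time_course(df$time_s, df$product_fraction,
                      conc_titrant = if (is.null(meta$conc_uM)) NA_real_
                                     else as.numeric(meta$conc_uM),
                      label = if (is.null(meta$label)) "" else meta$label)
}

#' Write a TCSPC decay histogram as CSV (`bin_ns, counts, irf_counts`)
#' @param h A [decay_histogram()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_decay_csv <- function(h, path) {
  write.csv(data.frame(bin_ns = h$bin_centers, counts = h$counts,
                       irf_counts = h$irf_counts),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a TCSPC decay CSV
#' @param path CSV with columns `bin_ns, counts, irf_counts`.
#' @return A [decay_histogram()].
#' @export
read_decay_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("bin_ns", "counts", "irf_counts") %in% names(df)))
    stop("malformed decay CSV '", path,
         "': need columns bin_ns, counts, irf_counts")
  decay_histogram(df$bin_ns, df$counts, df$irf_counts)
}

#' Write a flat key-value report file
#' @param values Named list of scalars.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(values, path) {
  lines <- vapply(names(values), function(k)
    sprintf("%s = %s", k, format(values[[k]], digits = 12)), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a key-value report file written by [write_report()]
#' @param path Report file.
#' @return Named list (numeric where parseable).
#' @export
read_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  out <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (is.na(n) && v != "NA") v else n
  })
  setNames(out, keys)
}
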