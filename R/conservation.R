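# Alignment-column conservation profiling of the TdT dNTP-binding pocket:
# redundancy filtering, reference-position mapping and residue frequencies.

#' The seven dNTP-binding-pocket positions (human TdT numbering)
#' @return Integer vector: 395, 397, 404, 449, 453, 456, 457.
#' @export
pocket_positions <- function() c(395L, 397L, 404L, 449L, 453L, 456L, 457L)

#' Construct an aligned sequence set
#'
#' @param records Named character vector of gapped amino-acid sequences
#'   (gap `"-"`), all of equal width.
#' @param reference_id Name of the reference (human TdT) record, whose ungapped
#'   numbering anchors residue positions.
#' @return Object of class `"aligned_set"`.
#' @export
aligned_set <- function(records, reference_id) {
  if (is.null(names(records)) || anyDuplicated(names(records)))
    stop("records must have unique names")
  if (length(unique(nchar(records))) != 1L)
    stop("all gapped sequences must have equal length")
  if (!reference_id %in% names(records))
    stop("reference_id '", reference_id, "' not present")
  structure(list(records = toupper(records), reference_id = reference_id),
            class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat("<aligned_set>", length(x$records), "sequences, width",
      nchar(x$records[[1]]), "- reference:", x$reference_id, "\n")
  invisible(x)
}

#' Read an aligned FASTA file
#' @param path FASTA file with gapped sequences.
#' @param reference_id Reference record name; defaults to the first record.
#' @return An [aligned_set()].
#' @export
read_alignment_fasta <- function(path, reference_id = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  records <- setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  if (is.null(reference_id)) reference_id <- names(records)[1]
  aligned_set(records, reference_id)
}

#' Write an aligned set as FASTA
#' @param a An [aligned_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(a, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(a$records), path)
  invisible(path)
}

ungap <- function(s) gsub("-", "", s, fixed = TRUE)

#' Remove duplicate and fragment sequences
#'
#' Drops exact duplicates (on the ungapped sequence; first occurrence kept) and
#' fragments whose ungapped length is below `min_coverage` times the reference
#' ungapped length. The reference is always retained. Idempotent. True isoform
#' detection would need database metadata and is not attempted; exact-duplicate
#' plus fragment filtering approximates it.
#'
#' @param a An [aligned_set()].
#' @param min_coverage Minimum ungapped length as a fraction of the reference
#'   (default 0.8).
#' @return Filtered [aligned_set()].
#' @export
filter_redundancy <- function(a, min_coverage = 0.8) {
  seqs <- ungap(a$records)
  ref_len <- nchar(seqs[[a$reference_id]])
  keep <- nchar(seqs) >= min_coverage * ref_len
  # duplicate filter: reference wins its duplicate class, else first occurrence
  ord <- order(names(a$records) != a$reference_id)  # reference first
  first_of_class <- !duplicated(seqs[ord])[order(ord)]
  keep <- keep & first_of_class
  keep[names(a$records) == a$reference_id] <- TRUE
  if (!any(keep)) stop("filtering removed every sequence")
  aligned_set(a$records[keep], a$reference_id)
}

#' Map a reference residue position to an alignment column
#'
#' Returns the alignment column holding the `ref_position`-th non-gap character
#' of the reference row (1-based residue numbering on the ungapped reference,
#' matching the field's "Asp395"-style numbering).
#'
#' @param a An [aligned_set()].
#' @param ref_position 1-based ungapped residue position in the reference.
#' @return Column index (1-based).
#' @export
map_reference_position <- function(a, ref_position) {
  ref <- strsplit(a$records[[a$reference_id]], "")[[1]]
  nongap <- cumsum(ref != "-")
  if (ref_position < 1 || ref_position > max(nongap))
    stop("ref_position ", ref_position, " outside reference ungapped length ",
         max(nongap))
  which(nongap == ref_position & ref != "-")[1]
}

#' Residue frequencies at one reference-numbered column
#'
#' Percentages are over the non-gap characters of the mapped column (gap count
#' reported separately); ambiguity characters (X, B, Z) are counted in the
#' denominator unless `exclude_ambiguous = TRUE`, which drops them from the
#' named-residue percentage denominator.
#'
#' @param a An [aligned_set()].
#' @param ref_position Residue position in reference numbering.
#' @param exclude_ambiguous Drop X/B/Z from the percentage denominator.
#' @return Object of class `"column_profile"`: `ref_position`, `percent`
#'   (named, sums to 100), `count`, `n_sequences`, `n_gap`.
#' @export
column_frequencies <- function(a, ref_position, exclude_ambiguous = FALSE) {
  col_idx <- map_reference_position(a, ref_position)
  chars <- vapply(a$records, function(s) substr(s, col_idx, col_idx), "")
  n_gap <- sum(chars == "-")
  res <- chars[chars != "-"]
  if (exclude_ambiguous) res <- res[!res %in% c("X", "B", "Z")]
  if (!length(res)) stop("column for position ", ref_position, " is all gaps")
  tab <- sort(table(res), decreasing = TRUE)
  structure(list(ref_position = ref_position,
                 percent = 100 * as.numeric(tab) / sum(tab),
                 residue = names(tab), count = as.integer(tab),
                 n_sequences = length(a$records), n_gap = n_gap),
            class = "column_profile")
}

#' @export
print.column_profile <- function(x, ...) {
  cat("<column_profile> position", x$ref_position,
      sprintf("(%d sequences, %d gaps)\n", x$n_sequences, x$n_gap))
  for (i in seq_along(x$residue))
    cat(sprintf("  %s  %6.2f%%  (%d)\n", x$residue[i], x$percent[i], x$count[i]))
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.column_profile <- function(x, ...) {
  data.frame(position = x$ref_position, residue = x$residue,
             percent = x$percent, count = x$count)
}

#' Conservation profiles of the dNTP-binding-pocket positions
#'
#' @param a An [aligned_set()].
#' @param positions Reference-numbered residue positions
#'   (default [pocket_positions()]).
#' @param exclude_ambiguous Passed to [column_frequencies()].
#' @return List of [column_frequencies()] profiles, in input order.
#' @export
pocket_profile <- function(a, positions = pocket_positions(),
                           exclude_ambiguous = FALSE) {
  setNames(lapply(positions, column_frequencies, a = a,
                  exclude_ambiguous = exclude_ambiguous),
           as.character(positions))
}

#' Flatten profiles to a position/residue/percent/count table
#' @param profiles Output of [pocket_profile()] (or a single profile).
#' @return Data frame with columns position, residue, percent, count.
#' @export
profile_table <- function(profiles) {
  if (inherits(profiles, "column_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, as.data.frame))
}

#' Write a conservation profile table as TSV
#' @param profiles Output of [pocket_profile()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profiles, path) {
  utils::write.table(profile_table(profiles), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
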