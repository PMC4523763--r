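# Characters allowed in input sequences: the four bases, gap, and the IUPAC
# ambiguity codes (incl. N). Everything outside this set is a format error.
IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-", "?", ".")

bg_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "barcodegap_error")))
}

#' Construct a barcode alignment object
#'
#' Container for a set of (optionally aligned) DNA sequences plus per-specimen
#' metadata. Sequences are stored as upper-case character strings; labels must
#' be unique and non-empty, and every metadata label must match a record.
#'
#' @param seqs named character vector of sequences (names are specimen labels).
#' @param metadata optional data.frame with columns `label`, `region`, `group`
#'   (`group` is `"ingroup"` or `"outgroup"`).
#' @param aligned logical; if `TRUE` all sequences must have identical length.
#' @return An object of class `barcode_aln` with elements `seq`, `length`
#'   (number of sites, `NA` if unaligned), `aligned` and `metadata`.
#' @export
barcode_aln <- function(seqs, metadata = NULL, aligned = TRUE) {
  if (length(seqs) == 0L)
    bg_error("alignment has no records", "barcodegap_format_error")
  labels <- names(seqs)
  if (is.null(labels) || any(is.na(labels)) || any(!nzchar(labels)))
    bg_error("all records must have non-empty labels", "barcodegap_format_error")
  if (anyDuplicated(labels))
    bg_error(sprintf("duplicate record label(s): %s",
                     paste(unique(labels[duplicated(labels)]), collapse = ", ")),
             "barcodegap_format_error")
  seqs <- toupper(seqs)
  bad <- vapply(strsplit(seqs, ""), function(s) any(!s %in% IUPAC_CHARS), logical(1))
  if (any(bad))
    bg_error(sprintf("non-IUPAC character(s) in record(s): %s",
                     paste(labels[bad], collapse = ", ")),
             "barcodegap_format_error")
  lens <- nchar(seqs)
  if (aligned && length(unique(lens)) != 1L)
    bg_error(sprintf("sequences are not aligned: lengths %s",
                     paste(sort(unique(lens)), collapse = ", ")),
             "barcodegap_alignment_error")
  if (!is.null(metadata)) {
    metadata <- validate_metadata(metadata)
    extra <- setdiff(metadata$label, labels)
    if (length(extra))
      bg_error(sprintf("metadata label(s) not in alignment: %s",
                       paste(extra, collapse = ", ")),
               "barcodegap_format_error")
  }
  structure(
    list(seq = seqs,
         length = if (aligned) lens[[1L]] else NA_integer_,
         aligned = aligned,
         metadata = metadata),
    class = "barcode_aln")
}

validate_metadata <- function(md) {
  md <- as.data.frame(md, stringsAsFactors = FALSE)
  need <- c("label", "region", "group")
  miss <- setdiff(need, names(md))
  if (length(miss))
    bg_error(sprintf("metadata missing column(s): %s", paste(miss, collapse = ", ")),
             "barcodegap_format_error")
  if (anyDuplicated(md$label))
    bg_error("duplicate label(s) in metadata", "barcodegap_format_error")
  ok <- md$group %in% c("ingroup", "outgroup")
  if (any(!ok))
    bg_error(sprintf("unknown group token(s): %s",
                     paste(unique(md$group[!ok]), collapse = ", ")),
             "barcodegap_format_error")
  md
}

#' @export
print.barcode_aln <- function(x, ...) {
  cat(sprintf("barcode_aln: %d sequence(s)%s\n", length(x$seq),
              if (x$aligned) sprintf(", %d aligned sites", x$length) else " (unaligned)"))
  if (!is.null(x$metadata))
    cat(sprintf("  metadata: %d ingroup, %d outgroup\n",
                sum(x$metadata$group == "ingroup"),
                sum(x$metadata$group == "outgroup")))
  invisible(x)
}

#' @export
length.barcode_aln <- function(x) length(x$seq)

#' Read a (multi-)FASTA file
#'
#' Records are returned in file order; labels are the header up to the first
#' whitespace. With `require_aligned = TRUE` unequal sequence lengths are an
#' error.
#'
#' @param path path to a FASTA file.
#' @param require_aligned logical; enforce equal sequence lengths.
#' @param metadata optional metadata data.frame or path to a metadata TSV
#'   (see [read_metadata()]).
#' @return A [barcode_aln] object.
#' @export
read_fasta <- function(path, require_aligned = TRUE, metadata = NULL) {
  if (!file.exists(path))
    bg_error(sprintf("file not found: %s", path), "barcodegap_io_error")
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e)
      bg_error(sprintf("cannot parse FASTA '%s': %s", path, conditionMessage(e)),
               "barcodegap_format_error"))
  if (length(set) == 0L)
    bg_error(sprintf("no FASTA records in '%s'", path), "barcodegap_format_error")
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (is.character(metadata) && length(metadata) == 1L)
    metadata <- read_metadata(metadata)
  barcode_aln(seqs, metadata = metadata, aligned = require_aligned)
}

#' Write an alignment to FASTA
#'
#' @param aln a [barcode_aln] object.
#' @param path output path.
#' @param width line-wrap width in columns (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, width = 70L) {
  set <- Biostrings::DNAStringSet(aln$seq)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a specimen metadata table
#'
#' Tab-separated with a header containing at least `label`, `region`, `group`;
#' `group` must be `ingroup` or `outgroup`.
#'
#' @param path path to a TSV file.
#' @return data.frame with one row per specimen.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path))
    bg_error(sprintf("file not found: %s", path), "barcodegap_io_error")
  md <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = TRUE)
  if (nrow(md) == 0L) {
    need <- c("label", "region", "group")
    if (!all(need %in% names(md)))
      bg_error("metadata missing column(s)", "barcodegap_format_error")
    return(md[, need, drop = FALSE])
  }
  validate_metadata(md)
}

#' Read a region-set file
#'
#' One region name per line; blank lines and `#` comments ignored. Used to
#' restrict species counts to a geographic area (e.g. the Italian region).
#'
#' @param path path to a text file.
#' @return character vector of region names.
#' @export
read_region_set <- function(path) {
  if (!file.exists(path))
    bg_error(sprintf("file not found: %s", path), "barcodegap_io_error")
  x <- readLines(path)
  x <- trimws(sub("#.*$", "", x))
  x[nzchar(x)]
}
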