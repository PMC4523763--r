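#' Per-sequence GC composition statistics
#'
#' GC-content is computed over unambiguous called bases only,
#' `(G + C) / (A + C + G + T)`; GC-skew is `(G - C) / (G + C)`, oriented so
#' that a C-rich strand gives a negative skew (mitochondrial COI is typically
#' negative on the deposited strand). Gaps, `N` and IUPAC ambiguity codes are
#' excluded from both counts. A sequence with no unambiguous base yields `NA`
#' statistics with `defined = FALSE`, never a silent zero.
#'
#' @param x a character vector of sequences, or a [barcode_aln] object.
#' @param ... unused.
#' @return data.frame with columns `label`, `n_bases`, `gc_content`,
#'   `gc_skew`, `defined`. Fractions in `[0, 1]`; multiply `gc_content` by 100
#'   for the conventional percent report.
#' @examples
#' composition(c(x = "GGCC", y = "ATGC"))
#' @export
composition <- function(x, ...) UseMethod("composition")

#' @export
composition.character <- function(x, ...) {
  if (length(x) == 0L || any(!nzchar(x)))
    bg_error("sequences must be non-empty", "barcodegap_format_error")
  labels <- names(x)
  if (is.null(labels)) labels <- paste0("seq", seq_along(x))
  counts <- t(vapply(strsplit(toupper(x), ""), function(s) {
    c(A = sum(s == "A"), C = sum(s == "C"), G = sum(s == "G"), T = sum(s == "T"))
  }, numeric(4)))
  n <- rowSums(counts)
  gc <- counts[, "G"] + counts[, "C"]
  out <- data.frame(
    label = labels,
    n_bases = as.integer(n),
    gc_content = ifelse(n > 0, gc / n, NA_real_),
    gc_skew = ifelse(gc > 0, (counts[, "G"] - counts[, "C"]) / gc, NA_real_),
    defined = n > 0 & gc > 0,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
composition.barcode_aln <- function(x, ...) {
  out <- composition(x$seq)
  if (!is.null(x$metadata))
    out$group <- x$metadata$group[match(out$label, x$metadata$label)]
  out
}

#' Screen outgroup sequences for compositional comparability
#'
#' Compositional bias can attract unrelated sequences in phylogenetic
#' reconstruction, so outgroups whose GC-content or GC-skew fall outside the
#' ingroup's observed min-max range are flagged before tree building.
#'
#' @param x a [barcode_aln] with metadata assigning every label to
#'   `ingroup`/`outgroup`, or a composition table (data.frame) with columns
#'   `label`, `group` and the statistic columns.
#' @param stats names of the statistic columns to screen.
#' @param ... unused.
#' @return data.frame with one row per outgroup x statistic: the value, the
#'   ingroup `range_lo`/`range_hi`, `flagged`, and `direction`
#'   (`"within"`, `"higher"`, `"lower"`). Zero rows when there is no outgroup.
#' @export
screen_outgroups <- function(x, stats = c("gc_content", "gc_skew"), ...)
  UseMethod("screen_outgroups")

#' @export
screen_outgroups.barcode_aln <- function(x, stats = c("gc_content", "gc_skew"), ...) {
  if (is.null(x$metadata))
    bg_error("screening requires ingroup/outgroup metadata", "barcodegap_format_error")
  screen_outgroups(composition(x), stats = stats)
}

#' @export
screen_outgroups.data.frame <- function(x, stats = c("gc_content", "gc_skew"), ...) {
  if (!all(c("label", "group") %in% names(x)))
    bg_error("composition table needs 'label' and 'group' columns",
             "barcodegap_format_error")
  miss <- setdiff(stats, names(x))
  if (length(miss))
    bg_error(sprintf("statistic column(s) not found: %s", paste(miss, collapse = ", ")),
             "barcodegap_format_error")
  ing <- x[x$group == "ingroup", , drop = FALSE]
  out <- x[x$group == "outgroup", , drop = FALSE]
  if (nrow(ing) == 0L)
    bg_error("ingroup is empty", "barcodegap_format_error")
  if (nrow(out) == 0L)
    return(data.frame(label = character(), stat = character(), value = numeric(),
                      range_lo = numeric(), range_hi = numeric(),
                      flagged = logical(), direction = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, lapply(stats, function(st) {
    v <- ing[[st]]
    rng <- range(v, na.rm = TRUE)
    val <- out[[st]]
    dir <- ifelse(is.na(val), NA_character_,
                  ifelse(val > rng[2], "higher",
                         ifelse(val < rng[1], "lower", "within")))
    data.frame(label = out$label, stat = st, value = val,
               range_lo = rng[1], range_hi = rng[2],
               flagged = !is.na(dir) & dir != "within",
               direction = dir, stringsAsFactors = FALSE)
  }))
  if (is.null(res))
    res <- data.frame(label = character(), stat = character(), value = numeric(),
                      range_lo = numeric(), range_hi = numeric(),
                      flagged = logical(), direction = character(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Write a composition report as TSV
#'
#' Columns mirror the conventional published layout: label, group, GC-skew and
#' GC-content (in percent, one decimal).
#'
#' @param comp a composition table from [composition()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_composition_tsv <- function(comp, path) {
  out <- data.frame(
    label = comp$label,
    group = if ("group" %in% names(comp)) comp$group else NA_character_,
    gc_skew = round(comp$gc_skew, 3),
    gc_content_pct = round(100 * comp$gc_content, 1),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
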