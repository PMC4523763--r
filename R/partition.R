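# Threshold species delimitation: putative species are the connected
# components of the graph linking specimen pairs with d <= threshold
# (single linkage). The threshold associated with a barcoding gap is the
# gap's lower endpoint, inclusive.

#' Delimit putative species at a distance threshold
#'
#' @param dm a `barcode_dist`. Undefined entries are treated as above the
#'   threshold, with a warning.
#' @param threshold non-negative distance, in the matrix's units. Pairs with
#'   `d <= threshold` are linked (inclusive rule).
#' @param linkage `"single"` (connected components; the standard for barcode
#'   cluster formation) or `"complete"`.
#' @return An object of class `species_partition`: `assignment` (named
#'   integer vector, cluster ids ordered by first member's matrix position),
#'   `threshold`, `linkage`, `n_species`, `units`.
#' @export
delimit <- function(dm, threshold, linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  if (threshold < 0) bg_error("threshold must be >= 0", "barcodegap_format_error")
  d <- dm$d
  n <- nrow(d)
  if (anyNA(d[upper.tri(d)])) {
    warning("undefined distance(s) treated as above threshold")
    # hclust rejects non-finite input; any value above the threshold works
    d[is.na(d)] <- max(d[is.finite(d)], threshold) * 2 + 1
  }
  if (n == 1L) {
    cl <- stats::setNames(1L, dm$labels)
  } else {
    hc <- stats::hclust(stats::as.dist(d), method = linkage)
    cl <- stats::cutree(hc, h = threshold)
    names(cl) <- dm$labels
    cl <- stats::setNames(match(cl, unique(cl)), names(cl))
  }
  structure(list(assignment = cl, threshold = threshold, linkage = linkage,
                 n_species = length(unique(cl)), units = dm$units),
            class = "species_partition")
}

#' @export
print.species_partition <- function(x, ...) {
  cat(sprintf("species_partition: %d cluster(s) at threshold %.4g (%s, %s linkage)\n",
              x$n_species, x$threshold, x$units, x$linkage))
  cl <- split(names(x$assignment), x$assignment)
  for (i in seq_along(cl))
    cat(sprintf("  %d: %s\n", i, paste(cl[[i]], collapse = ", ")))
  invisible(x)
}

#' Count species restricted to a region set
#'
#' A cluster counts if at least one of its members was sampled in a region of
#' `region_set` (so a species spanning the boundary still counts once).
#'
#' @param partition a `species_partition`.
#' @param metadata data.frame with `label` and `region` covering every label.
#' @param region_set character vector of region names (empty set gives 0).
#' @return integer species count.
#' @export
count_by_region <- function(partition, metadata, region_set) {
  labs <- names(partition$assignment)
  reg <- metadata$region[match(labs, metadata$label)]
  if (anyNA(reg))
    bg_error(sprintf("no metadata for label(s): %s",
                     paste(labs[is.na(reg)], collapse = ", ")),
             "barcodegap_format_error")
  if (length(region_set) == 0L) return(0L)
  keep <- reg %in% region_set
  length(unique(partition$assignment[keep]))
}

#' Delimitation scenarios under the top-ranked gaps
#'
#' For each of the top-ranked gap intervals, clusters at that gap's lower
#' endpoint (inclusive) and reports total and region-restricted species
#' counts. The two widest gaps of a barcode distance distribution typically
#' encode a "many shallow species" vs "few deep species" pair of scenarios.
#'
#' @param dm a `barcode_dist`.
#' @param gap_report a `gap_report` from [find_gaps()] on the same matrix.
#' @param metadata optional specimen metadata (needed for region counts).
#' @param region_set optional character vector of regions.
#' @return An object of class `gap_scenarios`: `scenarios` (data.frame with
#'   `gap_rank`, `gap_lo`, `gap_hi`, `threshold`, `n_species`, and
#'   `n_species_region` when a region set is given) and `partitions` (list of
#'   `species_partition`, in gap order).
#' @export
delimit_under_gaps <- function(dm, gap_report, metadata = NULL, region_set = NULL) {
  tg <- top_gaps(gap_report)
  if (nrow(tg) == 0L)
    bg_error("gap report has no intervals", "barcodegap_format_error")
  parts <- lapply(tg$lo, function(th) delimit(dm, th))
  sc <- data.frame(gap_rank = seq_len(nrow(tg)),
                   gap_lo = tg$lo, gap_hi = tg$hi,
                   threshold = tg$lo,
                   n_species = vapply(parts, function(p) p$n_species, integer(1)))
  if (!is.null(region_set)) {
    if (is.null(metadata))
      bg_error("region counts need metadata", "barcodegap_format_error")
    sc$n_species_region <- vapply(parts, count_by_region, integer(1),
                                  metadata = metadata, region_set = region_set)
  }
  structure(list(scenarios = sc, partitions = parts, units = dm$units),
            class = "gap_scenarios")
}

#' @export
print.gap_scenarios <- function(x, ...) {
  cat("delimitation scenarios (threshold = gap lower endpoint, inclusive):\n")
  print(x$scenarios, row.names = FALSE)
  invisible(x)
}

#' Write a species partition as TSV
#'
#' Columns: label, cluster, and region when metadata is supplied.
#'
#' @param partition a `species_partition`.
#' @param path output path.
#' @param metadata optional metadata for the region column.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(partition, path, metadata = NULL) {
  df <- data.frame(label = names(partition$assignment),
                   cluster = unname(partition$assignment),
                   stringsAsFactors = FALSE)
  if (!is.null(metadata))
    df$region <- metadata$region[match(df$label, metadata$label)]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
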