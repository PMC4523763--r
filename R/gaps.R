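# Barcoding-gap detection. The barcoding gap is the interval expected to
# separate within-species from between-species pairwise distances. Candidate
# gaps are found on the exact sorted distinct values of the upper triangle
# (never on histogram bins): every interval between consecutive distinct
# observed values is a zero-frequency interval; candidates are ranked by
# width, widest first, ties broken by the smaller lower endpoint.

#' Detect barcoding-gap candidates in a pairwise-distance distribution
#'
#' @param dm a `barcode_dist` (undefined entries are excluded with a note).
#' @param top_k number of top-ranked gap intervals to highlight (default 2,
#'   matching the usual lower/higher candidate pair). All intervals are kept
#'   in the report; `top_k` only selects the candidates used downstream.
#' @param bin_width histogram bin width for plotting, in the matrix's units
#'   (default 1, i.e. one percentage point for a percent matrix).
#' @return An object of class `gap_report`: sorted observed `distances`
#'   (upper triangle), `intervals` (data.frame `lo`, `hi`, `width`, ranked),
#'   `top_k`, `units`, and `hist` (bin counts for plotting).
#' @export
find_gaps <- function(dm, top_k = 2L, bin_width = NULL) {
  vals <- dm$d[upper.tri(dm$d)]
  n_undef <- sum(is.na(vals))
  vals <- sort(vals[!is.na(vals)])
  if (length(vals) < 2L)
    bg_error("gap detection needs at least 2 finite pairwise distances",
             "barcodegap_format_error")
  v <- unique(vals)
  if (length(v) < 2L) {
    intervals <- data.frame(lo = numeric(), hi = numeric(), width = numeric())
  } else {
    lo <- v[-length(v)]
    hi <- v[-1L]
    intervals <- data.frame(lo = lo, hi = hi, width = hi - lo)
    intervals <- intervals[order(-intervals$width, intervals$lo), , drop = FALSE]
    rownames(intervals) <- NULL
  }
  if (is.null(bin_width)) bin_width <- if (dm$units == "percent") 1 else 0.01
  breaks <- seq(0, max(vals) + bin_width, by = bin_width)
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  structure(list(distances = vals, intervals = intervals,
                 top_k = as.integer(top_k), units = dm$units,
                 n_undefined = n_undef, bin_width = bin_width,
                 hist = data.frame(bin_lo = h$breaks[-length(h$breaks)],
                                   bin_hi = h$breaks[-1L], count = h$counts)),
            class = "gap_report")
}

#' Top-ranked gap intervals of a report
#'
#' @param report a `gap_report`.
#' @param k how many (default the report's `top_k`).
#' @return data.frame of the `k` widest intervals, width-ranked.
#' @export
top_gaps <- function(report, k = report$top_k) {
  utils::head(report$intervals, k)
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("gap_report: %d pairwise distances (%s units)%s\n",
              length(x$distances), x$units,
              if (x$n_undefined) sprintf(", %d undefined excluded", x$n_undefined) else ""))
  tg <- top_gaps(x)
  if (nrow(tg) == 0L) {
    cat("  no zero-frequency interval (all distances equal)\n")
  } else {
    for (i in seq_len(nrow(tg)))
      cat(sprintf("  gap %d: (%.4g, %.4g), width %.4g\n",
                  i, tg$lo[i], tg$hi[i], tg$width[i]))
  }
  invisible(x)
}

#' @export
plot.gap_report <- function(x, shade = TRUE, ...) {
  graphics::barplot(x$hist$count, names.arg = sprintf("%.3g", x$hist$bin_lo),
                    space = 0, col = "grey70", border = "grey40",
                    xlab = sprintf("pairwise distance (%s)", x$units),
                    ylab = "frequency", ...)
  if (shade) {
    tg <- top_gaps(x)
    for (i in seq_len(nrow(tg))) {
      graphics::rect(tg$lo[i] / x$bin_width, 0, tg$hi[i] / x$bin_width,
                     max(x$hist$count), col = grDevices::adjustcolor("red", 0.15),
                     border = NA)
    }
  }
  invisible(x)
}

#' Write the gap histogram as CSV
#'
#' @param report a `gap_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gap_histogram <- function(report, path) {
  utils::write.csv(report$hist, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
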