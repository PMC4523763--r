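# Readers/writers for distance matrices: square CSV, relaxed PHYLIP, and the
# combined published-table layout (correction-model distances in the upper
# triangle, p-distances in the lower, percent units, one decimal, SEs in a
# parallel file).

#' Write a distance matrix as a square CSV
#'
#' Optional `#`-prefixed provenance header lines are written before the table.
#'
#' @param dm a `barcode_dist`.
#' @param path output path.
#' @param header optional character vector of provenance lines.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(dm, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(sprintf("# model: %s; units: %s", dm$model, dm$units), con)
  df <- data.frame(label = dm$labels, dm$d, check.names = FALSE)
  colnames(df) <- c("label", dm$labels)
  utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square distance CSV written by [write_distance_csv()]
#'
#' @param path input path.
#' @param model,units recorded on the result when the file header lacks them.
#' @return a `barcode_dist`.
#' @export
read_distance_csv <- function(path, model = "K2P", units = "fraction") {
  if (!file.exists(path)) bg_error(sprintf("file not found: %s", path), "barcodegap_io_error")
  hdr <- grep("^#", readLines(path, n = 20L), value = TRUE)
  m <- regmatches(hdr, regexec("model: *([A-Za-z0-9]+); *units: *([a-z]+)", hdr))
  m <- Filter(length, m)
  if (length(m)) {
    model <- m[[1L]][2L]
    units <- m[[1L]][3L]
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  d <- as.matrix(df[, -1L, drop = FALSE])
  rownames(d) <- df[[1L]]
  storage.mode(d) <- "double"
  new_barcode_dist(d, model, units)
}

#' Write a distance matrix in relaxed PHYLIP format
#'
#' @inheritParams write_distance_csv
#' @export
write_phylip <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d", length(dm$labels)), con)
  for (i in seq_along(dm$labels))
    writeLines(paste(c(dm$labels[i], formatC(dm$d[i, ], format = "g", digits = 8)),
                     collapse = " "), con)
  invisible(path)
}

#' Write a combined published-style distance table
#'
#' One CSV with the `upper` model's distances in the upper-right triangle and
#' the `lower` model's in the lower-left, percent units rounded to one
#' decimal; a parallel CSV holds the SEs in the same layout.
#'
#' @param upper,lower `barcode_dist` objects on the same labels (typically
#'   K2P upper, p lower).
#' @param path output CSV path for the distances.
#' @param se_path optional output path for the SE table.
#' @return `path`, invisibly.
#' @export
write_combined_table <- function(upper, lower, path, se_path = NULL) {
  stopifnot(identical(upper$labels, lower$labels))
  up <- convert_units(upper, "percent")
  lo <- convert_units(lower, "percent")
  n <- length(up$labels)
  d <- matrix("", n, n, dimnames = list(up$labels, up$labels))
  d[upper.tri(d)] <- sprintf("%.1f", up$d[upper.tri(up$d)])
  d[lower.tri(d)] <- sprintf("%.1f", lo$d[lower.tri(lo$d)])
  write_char_matrix(d, path,
                    sprintf("# upper: %s; lower: %s; units: percent", up$model, lo$model))
  if (!is.null(se_path)) {
    se <- matrix("", n, n, dimnames = list(up$labels, up$labels))
    if (!is.null(up$se)) se[upper.tri(se)] <- sprintf("%.1f", up$se[upper.tri(up$se)])
    if (!is.null(lo$se)) se[lower.tri(se)] <- sprintf("%.1f", lo$se[lower.tri(lo$se)])
    write_char_matrix(se, se_path,
                      sprintf("# bootstrap SEs; upper: %s; lower: %s; units: percent",
                              up$model, lo$model))
  }
  invisible(path)
}

write_char_matrix <- function(m, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(c("label", colnames(m)), collapse = ","), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], m[i, ]), collapse = ","), con)
  invisible(path)
}

#' Read a printed combined distance table (percent units)
#'
#' Parses the combined layout written by [write_combined_table()] (and used
#' for the packaged 12-specimen centipede COI fixture): one triangle per
#' model, percent units. A trailing `*` on an SE cell marks the printed value
#' as suspect (kept as printed, flagged, never corrected).
#'
#' @param path distance CSV (upper triangle = `upper_model`, lower =
#'   `lower_model`).
#' @param se_path optional parallel SE CSV.
#' @param upper_model,lower_model model tags for the two triangles.
#' @return list with elements named by model tag (e.g. `$K2P`, `$p`), each a
#'   `barcode_dist` in percent units with `se` and `suspect_se` attached when
#'   available.
#' @export
read_printed_matrix <- function(path, se_path = NULL,
                                upper_model = "K2P", lower_model = "p") {
  raw <- read_char_table(path)
  labels <- raw$labels
  n <- length(labels)
  vals <- suppressWarnings(matrix(as.numeric(raw$cells), n, n,
                                  dimnames = list(labels, labels)))
  up <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  lo <- up
  up[upper.tri(up)] <- vals[upper.tri(vals)]
  up[lower.tri(up)] <- t(up)[lower.tri(up)]
  diag(up) <- 0
  lo[lower.tri(lo)] <- vals[lower.tri(vals)]
  lo[upper.tri(lo)] <- t(lo)[upper.tri(lo)]
  diag(lo) <- 0
  se_up <- se_lo <- sus_up <- sus_lo <- NULL
  if (!is.null(se_path)) {
    se_raw <- read_char_table(se_path)
    stopifnot(identical(se_raw$labels, labels))
    cells <- se_raw$cells
    suspect <- matrix(grepl("\\*$", cells), n, n, dimnames = list(labels, labels))
    senum <- suppressWarnings(matrix(as.numeric(sub("\\*$", "", cells)), n, n,
                                     dimnames = list(labels, labels)))
    mk <- function(tri) {
      m <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
      s <- matrix(FALSE, n, n, dimnames = list(labels, labels))
      m[tri(m)] <- senum[tri(senum)]
      s[tri(s)] <- suspect[tri(suspect)]
      m[t(tri(m))] <- t(m)[t(tri(m))]
      s[t(tri(s))] <- t(s)[t(tri(s))]
      diag(m) <- 0
      list(se = m, suspect = s)
    }
    u <- mk(upper.tri)
    l <- mk(lower.tri)
    se_up <- u$se; sus_up <- u$suspect
    se_lo <- l$se; sus_lo <- l$suspect
  }
  out <- list(
    new_barcode_dist(up, upper_model, "percent", se = se_up, suspect_se = sus_up),
    new_barcode_dist(lo, lower_model, "percent", se = se_lo, suspect_se = sus_lo))
  names(out) <- c(upper_model, lower_model)
  out
}

read_char_table <- function(path) {
  if (!file.exists(path)) bg_error(sprintf("file not found: %s", path), "barcodegap_io_error")
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  parts <- strsplit(lines, ",")
  hdr <- parts[[1L]]
  labels <- hdr[-1L]
  rows <- parts[-1L]
  n <- length(labels)
  cells <- matrix("", n, n)
  rlab <- character(n)
  for (i in seq_len(n)) {
    r <- rows[[i]]
    length(r) <- n + 1L # pad trailing empties
    r[is.na(r)] <- ""
    rlab[i] <- r[1L]
    cells[i, ] <- r[-1L]
  }
  if (!identical(rlab, labels))
    bg_error("row labels do not match column labels", "barcodegap_format_error")
  list(labels = labels, cells = cells)
}

#' Packaged fixture paths
#'
#' Access the small plain-text data shipped with the package: the published
#' 12-specimen centipede COI distance table (K2P upper / p lower, percent),
#' its SE table, the specimen metadata, the Italian-region set and the
#' published composition (GC) table.
#'
#' @param which one of `"table3"`, `"table3_se"`, `"metadata"`,
#'   `"italian_regions"`, `"composition"`.
#' @return a file path inside the installed package.
#' @export
bg_fixture <- function(which = c("table3", "table3_se", "metadata",
                                 "italian_regions", "composition")) {
  which <- match.arg(which)
  fn <- c(table3 = "coi_distances_published.csv",
          table3_se = "coi_distances_published_se.csv",
          metadata = "specimen_metadata.tsv",
          italian_regions = "italian_regions.txt",
          composition = "composition_published.tsv")[[which]]
  path <- system.file("extdata", fn, package = "barcodegap")
  if (!nzchar(path)) bg_error(sprintf("fixture '%s' not found", which), "barcodegap_io_error")
  path
}
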