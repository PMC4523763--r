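#' Fit a barcoding-gap species delimitation
#'
#' The main entry point of the package: from an aligned barcode marker (or a
#' precomputed distance matrix), computes pairwise distances, detects
#' barcoding-gap candidates as zero-frequency intervals of the distance
#' distribution, and delimits putative species by single-linkage clustering
#' at each candidate gap's lower endpoint.
#'
#' @param x a [barcode_aln] (distances are computed) or a `barcode_dist`
#'   (used as is, e.g. loaded from a published table).
#' @param model distance model when `x` is an alignment: `"K2P"` or `"p"`.
#' @param policy,coverage gap-deletion policy, see [distance_matrix()].
#' @param B bootstrap pseudoreplicates for distance SEs (0 disables; default
#'   500 when fitting from sequences).
#' @param top_k number of candidate gaps to delimit under (default 2).
#' @param metadata optional specimen metadata (data.frame or TSV path).
#' @param region_set optional region names (character vector or file path)
#'   for stratified species counts.
#' @param seed seed for the bootstrap.
#' @param ... unused.
#' @return An object of class `barcode_delim` with components `dist`
#'   (`barcode_dist`), `gaps` (`gap_report`), `scenarios` (`gap_scenarios`),
#'   `metadata`, `region_set`, and `call`. Methods: `print`, `summary`,
#'   `plot` (distance histogram with the candidate gaps shaded).
#' @examples
#' fix <- read_printed_matrix(bg_fixture("table3"), bg_fixture("table3_se"))
#' md <- read_metadata(bg_fixture("metadata"))
#' fit <- barcode_delimit(fix$K2P, metadata = md,
#'                        region_set = read_region_set(bg_fixture("italian_regions")))
#' fit
#' @export
barcode_delimit <- function(x, model = c("K2P", "p"),
                            policy = c("partial", "pairwise"), coverage = 0.95,
                            B = 500L, top_k = 2L,
                            metadata = NULL, region_set = NULL, seed = NULL, ...) {
  cl <- match.call()
  if (is.character(metadata) && length(metadata) == 1L)
    metadata <- read_metadata(metadata)
  if (is.character(region_set) && length(region_set) == 1L && file.exists(region_set))
    region_set <- read_region_set(region_set)
  if (inherits(x, "barcode_aln")) {
    model <- match.arg(model)
    policy <- match.arg(policy)
    if (is.null(metadata)) metadata <- x$metadata
    dm <- if (B > 0)
      bootstrap_se(x, model = model, policy = policy, coverage = coverage,
                   B = B, seed = seed)
    else distance_matrix(x, model = model, policy = policy, coverage = coverage)
  } else if (inherits(x, "barcode_dist")) {
    dm <- x
  } else {
    bg_error("x must be a barcode_aln or barcode_dist", "barcodegap_format_error")
  }
  gaps <- find_gaps(dm, top_k = top_k)
  scen <- delimit_under_gaps(dm, gaps, metadata = metadata, region_set = region_set)
  structure(list(dist = dm, gaps = gaps, scenarios = scen,
                 metadata = metadata, region_set = region_set, call = cl),
            class = "barcode_delim")
}

#' @export
print.barcode_delim <- function(x, ...) {
  cat("Barcoding-gap species delimitation\n")
  vals <- x$dist$d[upper.tri(x$dist$d)]
  vals <- vals[!is.na(vals)]
  cat(sprintf("  %d taxa, %d pairwise %s distances (%s), range %.4g - %.4g\n",
              length(x$dist$labels), length(vals), x$dist$model, x$dist$units,
              min(vals), max(vals)))
  tg <- top_gaps(x$gaps)
  for (i in seq_len(nrow(tg)))
    cat(sprintf("  candidate gap %d: (%.4g, %.4g)\n", i, tg$lo[i], tg$hi[i]))
  print(x$scenarios)
  invisible(x)
}

#' @export
summary.barcode_delim <- function(object, ...) {
  vals <- object$dist$d[upper.tri(object$dist$d)]
  structure(list(n_taxa = length(object$dist$labels),
                 model = object$dist$model, units = object$dist$units,
                 min_dist = min(vals, na.rm = TRUE),
                 max_dist = max(vals, na.rm = TRUE),
                 n_undefined = sum(is.na(vals)),
                 gaps = top_gaps(object$gaps),
                 scenarios = object$scenarios$scenarios),
            class = "summary.barcode_delim")
}

#' @export
print.summary.barcode_delim <- function(x, ...) {
  cat(sprintf("%d taxa; %s distances (%s): min %.4g, max %.4g\n",
              x$n_taxa, x$model, x$units, x$min_dist, x$max_dist))
  cat("candidate gaps:\n")
  print(x$gaps, row.names = FALSE)
  cat("scenarios:\n")
  print(x$scenarios, row.names = FALSE)
  invisible(x)
}

#' @export
plot.barcode_delim <- function(x, ...) {
  plot(x$gaps, ...)
}
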