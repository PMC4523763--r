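# Distance engine: p-distance and Kimura 2-parameter (K2P) distance with
# pairwise- or partial-deletion gap handling and site-bootstrap SEs.
#
# K2P separates the transition proportion P (A<->G, C<->T) from the
# transversion proportion Q and corrects for multiple hits:
#   d = -1/2 * log(1 - 2P - Q) - 1/4 * log(1 - 2Q)
# When a log argument is non-positive the pair is saturated and the distance
# is flagged undefined (NA), never silently zero.

BASE_CODES <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# n x L integer matrix; gaps, N and ambiguity codes become NA (missing)
encode_alignment <- function(aln) {
  if (!aln$aligned) bg_error("distances need an aligned input", "barcodegap_alignment_error")
  m <- matrix(NA_integer_, nrow = length(aln$seq), ncol = aln$length,
              dimnames = list(names(aln$seq), NULL))
  for (i in seq_along(aln$seq)) {
    s <- strsplit(aln$seq[[i]], "")[[1L]]
    m[i, ] <- unname(BASE_CODES[s])
  }
  m
}

# Site mask for the partial-deletion policy: keep sites where the fraction of
# sequences with a called, unambiguous base is >= coverage. Computed once per
# alignment. Pairwise deletion keeps all sites (each pair masks its own).
site_mask <- function(enc, policy = c("partial", "pairwise"), coverage = 0.95) {
  policy <- match.arg(policy)
  if (policy == "pairwise") return(rep(TRUE, ncol(enc)))
  colMeans(!is.na(enc)) >= coverage
}

# Per-site pair category: 0 identical, 1 transition, 2 transversion, NA masked.
# Transitions are within-class changes (purines A/G, pyrimidines C/T).
pair_categories <- function(a, b) {
  cat <- rep(NA_integer_, length(a))
  ok <- !is.na(a) & !is.na(b)
  pur <- c(TRUE, FALSE, TRUE, FALSE) # A, C, G, T
  same <- ok & a == b
  diff <- ok & a != b
  cat[same] <- 0L
  cat[diff & (pur[a] == pur[b])] <- 1L
  cat[diff & (pur[a] != pur[b])] <- 2L
  cat
}

#' Transition/transversion site counts for a pair of aligned sequences
#'
#' Sites where either sequence has a gap, `N` or an ambiguity code are
#' excluded; under the partial-deletion policy, sites with below-threshold
#' coverage across the whole alignment are additionally excluded via
#' `mask`.
#'
#' @param seqA,seqB aligned sequences (character strings of equal length).
#' @param policy `"pairwise"` or `"partial"` deletion. For `"partial"` supply
#'   `mask` (or `coverage` to compute a two-sequence mask).
#' @param mask optional logical site mask (the alignment-wide retained sites).
#' @param coverage coverage cutoff used when `mask` is not supplied.
#' @return list of class `pair_counts`: `L` (valid sites), `n_ts`, `n_tv`,
#'   `P = n_ts/L`, `Q = n_tv/L`, `defined` (`FALSE` when `L == 0`).
#' @examples
#' pair_counts("AC-T", "ATGT", policy = "pairwise")
#' @export
pair_counts <- function(seqA, seqB, policy = c("pairwise", "partial"),
                        mask = NULL, coverage = 0.95) {
  policy <- match.arg(policy)
  if (nchar(seqA) != nchar(seqB))
    bg_error("sequences must have equal length", "barcodegap_alignment_error")
  a <- unname(BASE_CODES[strsplit(toupper(seqA), "")[[1L]]])
  b <- unname(BASE_CODES[strsplit(toupper(seqB), "")[[1L]]])
  if (policy == "partial" && is.null(mask)) {
    enc <- rbind(a, b)
    mask <- site_mask(enc, "partial", coverage)
  }
  if (!is.null(mask)) {
    a[!mask] <- NA_integer_
    b[!mask] <- NA_integer_
  }
  cat <- pair_categories(a, b)
  counts_from_categories(cat)
}

counts_from_categories <- function(cat) {
  L <- sum(!is.na(cat))
  n_ts <- sum(cat == 1L, na.rm = TRUE)
  n_tv <- sum(cat == 2L, na.rm = TRUE)
  structure(list(L = L, n_ts = n_ts, n_tv = n_tv,
                 P = if (L > 0) n_ts / L else NA_real_,
                 Q = if (L > 0) n_tv / L else NA_real_,
                 defined = L > 0L),
            class = "pair_counts")
}

#' @export
print.pair_counts <- function(x, ...) {
  cat(sprintf("pair_counts: L=%d, transitions=%d, transversions=%d%s\n",
              x$L, x$n_ts, x$n_tv, if (!x$defined) " (undefined: no valid sites)" else ""))
  invisible(x)
}

#' p-distance from pair site counts
#'
#' The proportion of differing sites, `(n_ts + n_tv) / L`.
#'
#' @param counts a `pair_counts` object (or anything with `L`, `n_ts`, `n_tv`).
#' @return distance as a fraction; `NA` when the counts are undefined.
#' @export
p_distance <- function(counts) {
  if (!isTRUE(counts$defined)) return(NA_real_)
  (counts$n_ts + counts$n_tv) / counts$L
}

#' Kimura 2-parameter distance from pair site counts
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` in substitutions/site. A
#' non-positive log argument means the pair is saturated under the model and
#' `NA` is returned (flagged, not an error, so a full matrix computation can
#' proceed).
#'
#' @inheritParams p_distance
#' @return distance in substitutions/site; `NA` when undefined or saturated.
#' @examples
#' k2p_distance(list(L = 100, n_ts = 10, n_tv = 5, P = 0.1, Q = 0.05, defined = TRUE))
#' @export
k2p_distance <- function(counts) {
  if (!isTRUE(counts$defined)) return(NA_real_)
  k2p_from_pq(counts$P, counts$Q)
}

k2p_from_pq <- function(P, Q) {
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  out <- rep(NA_real_, length(a1))
  ok <- !is.na(a1) & !is.na(a2) & a1 > 0 & a2 > 0
  out[ok] <- -0.5 * log(a1[ok]) - 0.25 * log(a2[ok])
  unname(out)
}

# counts matrices -> distance vector (vectorised over pairs)
dist_from_counts <- function(n_ts, n_tv, L, model) {
  P <- ifelse(L > 0, n_ts / L, NA_real_)
  Q <- ifelse(L > 0, n_tv / L, NA_real_)
  if (model == "p") P + Q else k2p_from_pq(P, Q)
}

new_barcode_dist <- function(d, model, units, se = NULL, suspect_se = NULL,
                             boot = NULL) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  structure(list(labels = rownames(d), d = d, model = model, units = units,
                 se = se, suspect_se = suspect_se, boot = boot),
            class = "barcode_dist")
}

#' Pairwise distance matrix for an alignment
#'
#' Computes all unordered pairs under the chosen model and deletion policy.
#' Saturated or empty pairs are recorded as `NA` with the diagonal fixed at 0.
#'
#' @param aln a [barcode_aln] object with at least 2 records.
#' @param model `"K2P"` or `"p"`.
#' @param policy `"partial"` (site-coverage deletion, MEGA-style, the default
#'   used for published COI barcode tables) or `"pairwise"`.
#' @param coverage site coverage cutoff for partial deletion (default 0.95).
#' @return An object of class `barcode_dist`: `labels`, symmetric matrix `d`
#'   (fractions, substitutions/site), `model`, `units = "fraction"`, and
#'   optional `se` (see [bootstrap_se()]).
#' @export
distance_matrix <- function(aln, model = c("K2P", "p"),
                            policy = c("partial", "pairwise"), coverage = 0.95) {
  model <- match.arg(model)
  policy <- match.arg(policy)
  enc <- encode_alignment(aln)
  if (nrow(enc) < 2L)
    bg_error("distance matrix needs at least 2 records", "barcodegap_format_error")
  mask <- site_mask(enc, policy, coverage)
  enc[, !mask] <- NA_integer_
  n <- nrow(enc)
  d <- matrix(0, n, n, dimnames = list(rownames(enc), rownames(enc)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cat <- pair_categories(enc[i, ], enc[j, ])
      cts <- counts_from_categories(cat)
      dij <- if (model == "p") p_distance(cts) else k2p_distance(cts)
      d[i, j] <- d[j, i] <- dij
    }
  }
  new_barcode_dist(d, model, "fraction")
}

#' @export
print.barcode_dist <- function(x, digits = 3, ...) {
  n <- length(x$labels)
  vals <- x$d[upper.tri(x$d)]
  cat(sprintf("barcode_dist: %d taxa, model %s, units %s\n", n, x$model, x$units))
  if (any(is.na(vals)))
    cat(sprintf("  %d undefined pair(s)\n", sum(is.na(vals))))
  fin <- vals[!is.na(vals)]
  if (length(fin))
    cat(sprintf("  range %.*f - %.*f%s\n", digits, min(fin), digits, max(fin),
                if (!is.null(x$se)) ", bootstrap SEs attached" else ""))
  invisible(x)
}

#' Convert a distance matrix between fraction and percent units
#'
#' @param dm a `barcode_dist`.
#' @param units target units, `"percent"` or `"fraction"`.
#' @return the converted `barcode_dist`.
#' @export
convert_units <- function(dm, units = c("percent", "fraction")) {
  units <- match.arg(units)
  if (dm$units == units) return(dm)
  f <- if (units == "percent") 100 else 0.01
  dm$d <- dm$d * f
  if (!is.null(dm$se)) dm$se <- dm$se * f
  dm$units <- units
  dm
}

#' Bootstrap standard errors for a distance matrix
#'
#' Site columns of the full alignment are resampled with replacement `B`
#' times (partial-deletion site masking is carried along with the resampled
#' columns, then each pair applies its own missing-data deletion, matching the
#' usual distance-software scheme). The SE of a pair is the standard deviation
#' of its distance across replicates; replicates where the pair is undefined
#' are excluded and counted.
#'
#' @inheritParams distance_matrix
#' @param B number of bootstrap pseudoreplicates (default 500).
#' @param seed integer seed for reproducible resampling.
#' @return A `barcode_dist` (same point distances as [distance_matrix()]) with
#'   `se` (symmetric SE matrix, `NA` where every replicate was undefined) and
#'   `boot = list(B, n_undefined)` attached.
#' @export
bootstrap_se <- function(aln, model = c("K2P", "p"),
                         policy = c("partial", "pairwise"), coverage = 0.95,
                         B = 500L, seed = NULL) {
  model <- match.arg(model)
  policy <- match.arg(policy)
  if (B < 2L) bg_error("bootstrap needs B >= 2", "barcodegap_format_error")
  enc <- encode_alignment(aln)
  mask <- site_mask(enc, policy, coverage)
  enc[, !mask] <- NA_integer_
  n <- nrow(enc)
  L <- ncol(enc)
  npair <- n * (n - 1L) / 2L
  # per-pair per-site categories, computed once
  cats <- matrix(NA_integer_, npair, L)
  k <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    k <- k + 1L
    cats[k, ] <- pair_categories(enc[i, ], enc[j, ])
  }
  is_ts <- !is.na(cats) & cats == 1L
  is_tv <- !is.na(cats) & cats == 2L
  is_ok <- !is.na(cats)
  point <- dist_from_counts(rowSums(is_ts), rowSums(is_tv), rowSums(is_ok), model)

  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  reps <- matrix(NA_real_, npair, B)
  for (b in seq_len(B)) {
    idx <- sample.int(L, L, replace = TRUE)
    reps[, b] <- dist_from_counts(
      rowSums(is_ts[, idx, drop = FALSE]),
      rowSums(is_tv[, idx, drop = FALSE]),
      rowSums(is_ok[, idx, drop = FALSE]), model)
  }
  n_def <- rowSums(!is.na(reps))
  se_vec <- ifelse(n_def >= 2L, apply(reps, 1L, stats::sd, na.rm = TRUE), NA_real_)
  # identical pairs have zero distance in every replicate -> sd 0 (handled above)
  d <- matrix(0, n, n, dimnames = list(rownames(enc), rownames(enc)))
  se <- matrix(NA_real_, n, n, dimnames = dimnames(d))
  diag(se) <- 0
  d[upper.tri(d)] <- upper_from_pairvec(point, n)
  se[upper.tri(se)] <- upper_from_pairvec(se_vec, n)
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  se[lower.tri(se)] <- t(se)[lower.tri(se)]
  new_barcode_dist(d, model, "fraction", se = se,
                   boot = list(B = B, n_undefined = B - n_def))
}

# pair vector is stored row-major over (i < j); map onto upper triangle which
# R fills column-major
upper_from_pairvec <- function(v, n) {
  m <- matrix(NA_real_, n, n)
  k <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    k <- k + 1L
    m[i, j] <- v[k]
  }
  m[upper.tri(m)]
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}
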