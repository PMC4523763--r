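# Independent oracles and small fixture builders. The oracles deliberately
# use the most naive formulation (per-site double loops, transitive closure,
# exhaustive scans) so they share no code path with the implementation.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

# naive per-site pair counts on character vectors (mask: logical keep-sites)
naive_pair_counts <- function(sa, sb, mask = NULL) {
  a <- strsplit(sa, "")[[1]]
  b <- strsplit(sb, "")[[1]]
  L <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(a)) {
    if (!is.null(mask) && !mask[i]) next
    x <- a[i]; y <- b[i]
    if (!(x %in% c(PURINES, PYRIMIDINES)) || !(y %in% c(PURINES, PYRIMIDINES))) next
    L <- L + 1L
    if (x != y) {
      same_class <- (x %in% PURINES) == (y %in% PURINES)
      if (same_class) ts <- ts + 1L else tv <- tv + 1L
    }
  }
  list(L = L, n_ts = ts, n_tv = tv)
}

naive_distance <- function(sa, sb, model, mask = NULL) {
  ct <- naive_pair_counts(sa, sb, mask)
  if (ct$L == 0L) return(NA_real_)
  P <- ct$n_ts / ct$L; Q <- ct$n_tv / ct$L
  if (model == "p") return(P + Q)
  a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) return(NA_real_)
  -0.5 * log(a1) - 0.25 * log(a2)
}

naive_distance_matrix <- function(aln, model, policy = "pairwise", coverage = 0.95) {
  seqs <- aln$seq
  n <- length(seqs)
  mask <- NULL
  if (policy == "partial") {
    chars <- do.call(rbind, strsplit(seqs, ""))
    called <- matrix(chars %in% c(PURINES, PYRIMIDINES), nrow = n)
    mask <- colMeans(called) >= coverage
  }
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- naive_distance(seqs[[i]], seqs[[j]], model, mask)
  d
}

# connected components of d <= threshold by repeated transitive closure
brute_components <- function(d, threshold) {
  n <- nrow(d)
  adj <- !is.na(d) & d <= threshold
  diag(adj) <- TRUE
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      k <- k + 1L
      comp[adj[i, ]] <- k
    }
  }
  stats::setNames(comp, rownames(d))
}

# random alignment with optional gaps/ambiguities
rand_alignment <- function(n, L, gap_prob = 0.05, amb_prob = 0.02) {
  pool <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(pool, L, replace = TRUE)
    r <- runif(L)
    s[r < gap_prob] <- "-"
    s[r >= gap_prob & r < gap_prob + amb_prob] <- sample(c("N", "R", "Y"), L, TRUE)[r >= gap_prob & r < gap_prob + amb_prob]
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", seq_len(n))
  barcode_aln(seqs, aligned = TRUE)
}

# barcode_dist wrapper around a plain symmetric matrix
as_bdist <- function(d, model = "p", units = "fraction") {
  structure(list(labels = rownames(d), d = d, model = model, units = units,
                 se = NULL, suspect_se = NULL, boot = NULL),
            class = "barcode_dist")
}

# additive (path-length) distance matrix of a phylo
tree_metric <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  m[tree$tip.label, tree$tip.label]
}

# write a small fasta file, returning the path
write_tmp_fasta <- function(records, width = 70) {
  f <- tempfile(fileext = ".fasta")
  con <- file(f, "w")
  for (nm in names(records)) {
    writeLines(paste0(">", nm), con)
    s <- records[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  close(con)
  f
}

fixture_k2p <- function() read_printed_matrix(bg_fixture("table3"), bg_fixture("table3_se"))$K2P
fixture_p <- function() read_printed_matrix(bg_fixture("table3"), bg_fixture("table3_se"))$p

# cluster tips by which child of the root they descend from
cutree_root_side <- function(rooted) {
  n <- length(rooted$tip.label)
  root <- n + 1L
  kids <- rooted$edge[rooted$edge[, 1] == root, 2]
  side <- integer(n)
  for (i in seq_along(kids)) {
    tips <- if (kids[i] <= n) kids[i]
            else ape::extract.clade(rooted, kids[i])$tip.label
    if (is.character(tips)) tips <- match(tips, rooted$tip.label)
    side[tips] <- i
  }
  side
}
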