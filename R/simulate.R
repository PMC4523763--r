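# Seeded generators with known ground truth: Yule species trees, K2P
# sequence evolution along them, and planted-partition distance matrices
# with a controllable barcoding-gap structure. These emulate the
# data-generating assumptions of the analysis (clock-like evolution under a
# transition/transversion model; a bimodal distance distribution) so that
# every downstream stage can be validated end to end.

#' Simulation parameters
#'
#' Defaults mirror a typical 12-specimen COI barcode study: 12 tips, 650
#' aligned sites, a substitution rate of 0.0016 substitutions/site/Ma,
#' transition/transversion rate ratio 4, and a birth rate of 0.03/Ma (giving
#' an expected root age near 65 Ma, the depth of the dated ingroup).
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate Yule speciation rate, events per lineage per Ma.
#' @param clock_rate substitution rate, substitutions/site/Ma.
#' @param kappa transition/transversion rate ratio (> 0).
#' @param L alignment length in sites.
#' @param seed integer seed.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_tips = 12L, birth_rate = 0.03, clock_rate = 0.0016,
                       kappa = 4, L = 650L, seed = NULL) {
  if (n_tips < 2L) bg_error("n_tips must be >= 2", "barcodegap_format_error")
  if (L < 1L) bg_error("L must be >= 1", "barcodegap_format_error")
  if (kappa <= 0 || clock_rate <= 0 || birth_rate <= 0)
    bg_error("rates and kappa must be > 0", "barcodegap_format_error")
  structure(list(n_tips = as.integer(n_tips), birth_rate = birth_rate,
                 clock_rate = clock_rate, kappa = kappa, L = as.integer(L),
                 seed = seed),
            class = "sim_params")
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Simulate a Yule (pure-birth) tree with a fixed tip count
#'
#' Lineages split independently at the birth rate, starting from a single
#' lineage; with k extant lineages the wait to the next split is
#' Exp(k * birth_rate). The process stops at the first would-be split after
#' reaching `n_tips`, so tips have positive pendant branches; the root age is
#' the elapsed time since the basal split.
#'
#' @param params a [sim_params()].
#' @return a rooted ultrametric `phylo` with branch lengths in Ma, a
#'   `"root_age"` attribute and node `"heights"` (ages in Ma).
#' @export
simulate_yule_tree <- function(params) {
  with_seed(params$seed, {
    n <- params$n_tips
    lambda <- params$birth_rate
    # event times: split k happens while k lineages are extant (k = 1..n),
    # the last "split" is the stopping time
    waits <- stats::rexp(n, rate = lambda * seq_len(n))
    times <- cumsum(waits)
    present <- times[n]
    # branching order: at split j (creating j+1 lineages) a uniform extant
    # lineage splits
    # build as lists of (active lineage -> birth time); record edges
    labels <- paste0("t", seq_len(n))
    # grow a table of nodes: tips 1..n, internals n+1..2n-1 assigned in split order
    parent <- integer(0); child <- integer(0); length_ <- numeric(0)
    next_internal <- n + 1L
    # active set holds provisional ids; provisional internal ids become real
    # internal node numbers at their split, tips get tip numbers at the end
    active <- data.frame(id = 1L, birth = 0)
    edges <- list()
    node_of <- list() # provisional id -> final number (assigned lazily)
    next_prov <- 2L
    splits <- list()
    for (j in seq_len(n - 1L)) {
      t_split <- times[j]
      k <- sample.int(nrow(active), 1L)
      lin <- active[k, ]
      prov_children <- c(next_prov, next_prov + 1L)
      next_prov <- next_prov + 2L
      splits[[length(splits) + 1L]] <-
        list(prov = lin$id, time = t_split, birth = lin$birth,
             children = prov_children)
      active <- rbind(active[-k, , drop = FALSE],
                      data.frame(id = prov_children, birth = t_split))
    }
    # final numbering: surviving provisional ids are tips (in id order),
    # split ids are internals in split order (root first)
    tip_ids <- sort(active$id)
    tip_num <- stats::setNames(seq_len(n), tip_ids)
    int_num <- stats::setNames(n + seq_along(splits),
                               vapply(splits, function(s) s$prov, numeric(1)))
    num_of <- function(prov) {
      p <- as.character(prov)
      if (p %in% names(tip_num)) tip_num[[p]] else int_num[[p]]
    }
    edge <- matrix(0L, 2L * (n - 1L), 2L)
    elen <- numeric(2L * (n - 1L))
    r <- 0L
    for (s in splits) {
      for (ch in s$children) {
        r <- r + 1L
        edge[r, ] <- c(num_of(s$prov), num_of(ch))
        chs <- Filter(function(z) z$prov == ch, splits)
        end_time <- if (length(chs)) chs[[1L]]$time else present
        elen[r] <- end_time - s$time
      }
    }
    tr <- structure(list(edge = edge, edge.length = elen,
                         tip.label = labels, Nnode = n - 1L),
                    class = "phylo")
    tr <- ape::reorder.phylo(tr, "cladewise")
    depth <- ape::node.depth.edgelength(tr)
    h <- max(depth) - depth
    attr(tr, "heights") <- h
    attr(tr, "root_age") <- unname(h[n + 1L])
    tr
  })
}

# K2P per-branch substitution probabilities. With transition rate alpha and
# per-target transversion rate beta (total rate alpha + 2 beta = r):
#   p_same = 1/4 + 1/4 e^{-4 beta t} + 1/2 e^{-2 (alpha + beta) t}
#   p_ts   = 1/4 + 1/4 e^{-4 beta t} - 1/2 e^{-2 (alpha + beta) t}
#   p_tv   = 1/4 - 1/4 e^{-4 beta t}   (each of the two transversion targets)
k2p_branch_probs <- function(d, kappa) {
  beta <- d / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta)
  e2 <- exp(-2 * (alpha + beta))
  c(same = 0.25 + 0.25 * e1 + 0.5 * e2,
    ts = 0.25 + 0.25 * e1 - 0.5 * e2,
    tv = 0.25 - 0.25 * e1)
}

TS_PARTNER <- c(3L, 4L, 1L, 2L)                 # A<->G, C<->T
TV_TARGETS <- matrix(c(2L, 4L,  1L, 3L,  2L, 4L,  1L, 3L), nrow = 4L, byrow = TRUE)

#' Evolve sequences along a tree under the K2P model
#'
#' The root sequence is uniform over \{A,C,G,T\}; along each branch of
#' duration `t` Ma each site changes independently with exact K2P transition
#' probabilities at total rate `clock_rate * t` and ts/tv rate ratio `kappa`
#' (matrix-exponential form, not event-by-event simulation).
#'
#' @param tree a `phylo` with branch lengths in Ma (typically from
#'   [simulate_yule_tree()]).
#' @param params a [sim_params()] providing `clock_rate`, `kappa`, `L`, `seed`.
#' @return a [barcode_aln] of the tip sequences, in tip-label order.
#' @export
evolve_k2p <- function(tree, params) {
  with_seed(params$seed, {
    n <- length(tree$tip.label)
    L <- params$L
    nn <- n + tree$Nnode
    seqs <- matrix(NA_integer_, nn, L)
    root <- n + 1L
    seqs[root, ] <- sample.int(4L, L, replace = TRUE)
    pre <- ape::reorder.phylo(tree, "cladewise")
    for (k in seq_len(nrow(pre$edge))) {
      p <- pre$edge[k, 1L]; ch <- pre$edge[k, 2L]
      d <- params$clock_rate * pre$edge.length[k]
      pr <- k2p_branch_probs(d, params$kappa)
      s <- seqs[p, ]
      u <- stats::runif(L)
      out <- s
      ts_idx <- u >= pr[["same"]] & u < pr[["same"]] + pr[["ts"]]
      out[ts_idx] <- TS_PARTNER[s[ts_idx]]
      tv_idx <- u >= pr[["same"]] + pr[["ts"]]
      if (any(tv_idx)) {
        pick <- 1L + (stats::runif(sum(tv_idx)) < 0.5)
        out[tv_idx] <- TV_TARGETS[cbind(s[tv_idx], pick)]
      }
      seqs[ch, ] <- out
    }
    bases <- c("A", "C", "G", "T")
    tipseq <- apply(seqs[seq_len(n), , drop = FALSE], 1L,
                    function(r) paste(bases[r], collapse = ""))
    names(tipseq) <- tree$tip.label
    barcode_aln(tipseq, aligned = TRUE)
  })
}

#' Planted-partition specification
#'
#' Describes a distance matrix with a known species partition and an enforced
#' barcoding gap: within-species distances uniform in `(0, a)`,
#' between-species distances uniform in `(b, c)` with `a < b`.
#'
#' @param sizes integer vector of species sizes.
#' @param within_max upper bound `a` of within-species distances.
#' @param between_lo,between_hi bounds `b`, `c` of between-species distances.
#' @param units units tag for the generated matrix (default `"percent"`).
#' @return a `planted_spec` list.
#' @export
planted_spec <- function(sizes, within_max = 1, between_lo = 10, between_hi = 28,
                         units = "percent") {
  if (any(sizes < 1L)) bg_error("species sizes must be >= 1", "barcodegap_format_error")
  if (!(within_max < between_lo && between_lo <= between_hi))
    bg_error("need within_max < between_lo <= between_hi", "barcodegap_format_error")
  structure(list(sizes = as.integer(sizes), within_max = within_max,
                 between_lo = between_lo, between_hi = between_hi, units = units),
            class = "planted_spec")
}

#' Generate a planted-partition distance matrix
#'
#' @param spec a [planted_spec()].
#' @param seed integer seed.
#' @return list with `matrix` (a `barcode_dist`, model tag `"planted"`) and
#'   `partition` (the true `species_partition`).
#' @export
make_planted_matrix <- function(spec, seed = NULL) {
  with_seed(seed, {
    n <- sum(spec$sizes)
    species <- rep(seq_along(spec$sizes), spec$sizes)
    labels <- sprintf("s%02d_%d", seq_len(n), species)
    d <- matrix(0, n, n, dimnames = list(labels, labels))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- if (species[i] == species[j])
        stats::runif(1L, 0, spec$within_max)
      else stats::runif(1L, spec$between_lo, spec$between_hi)
    }
    part <- structure(list(assignment = stats::setNames(species, labels),
                           threshold = NA_real_, linkage = "single",
                           n_species = length(spec$sizes), units = spec$units),
                      class = "species_partition")
    list(matrix = new_barcode_dist(d, "planted", spec$units), partition = part)
  })
}

#' Emit a full synthetic dataset to disk
#'
#' Writes a FASTA alignment evolved on a simulated Yule tree, a metadata TSV
#' (all specimens `ingroup`, regions assigned round-robin from
#' `region_names`), the true species tree in Newick, and the true partition
#' implied by cutting the tree at `species_cut_ma` (TSV), so the whole
#' pipeline can run end to end on data with known truth.
#'
#' @param params a [sim_params()].
#' @param dir output directory (created if missing).
#' @param region_names regions cycled over the tips.
#' @param species_cut_ma age (Ma) below which tips are considered
#'   conspecific in the true partition.
#' @return named list of the file paths written.
#' @export
simulate_dataset <- function(params, dir, region_names = c("north", "south"),
                             species_cut_ma = 5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_yule_tree(params)
  aln_seed <- if (is.null(params$seed)) NULL else params$seed + 1L
  params2 <- params
  params2$seed <- aln_seed
  aln <- evolve_k2p(tree, params2)
  md <- data.frame(label = tree$tip.label,
                   region = rep_len(region_names, params$n_tips),
                   group = "ingroup", stringsAsFactors = FALSE)
  # true partition: connected components of tips whose MRCA is younger than
  # the cut (equivalently, cophenetic distance in Ma <= 2 * cut)
  coph <- stats::cophenetic(tree)
  dm <- new_barcode_dist(coph[tree$tip.label, tree$tip.label], "p", "fraction")
  truth <- delimit(dm, 2 * species_cut_ma)
  paths <- list(
    fasta = file.path(dir, "alignment.fasta"),
    metadata = file.path(dir, "metadata.tsv"),
    tree = file.path(dir, "true_tree.nwk"),
    partition = file.path(dir, "true_partition.tsv"))
  write_fasta(aln, paths$fasta)
  utils::write.table(md, paths$metadata, sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(tree, file = paths$tree)
  write_partition_tsv(truth, paths$partition, metadata = md)
  paths
}
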