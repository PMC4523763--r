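# Surrogate phylogeny and simplified strict-clock dating. A neighbor-joining
# tree from the distance matrix stands in for likelihood/Bayesian inference;
# node heights are made clock-like by least-squares averaging of tip path
# lengths, and heights (substitutions/site) are converted to ages in Ma by a
# single substitution rate with truncated-normal uncertainty.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via \pkg{ape}); negative branch-length
#' estimates are clamped to zero with a warning, and the number clamped is
#' recorded in the `"n_clamped"` attribute.
#'
#' @param dm a `barcode_dist` with at least 3 labels and no undefined entries.
#' @return an unrooted `phylo`, branch lengths in the matrix's units.
#' @export
nj_tree <- function(dm) {
  if (length(dm$labels) < 3L)
    bg_error("NJ needs at least 3 taxa", "barcodegap_format_error")
  if (anyNA(dm$d))
    bg_error("NJ needs a complete distance matrix (undefined entries present)",
             "barcodegap_format_error")
  tr <- ape::nj(stats::as.dist(dm$d))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    warning(sprintf("%d negative NJ branch length(s) clamped to 0", sum(neg)))
    tr$edge.length[neg] <- 0
  }
  attr(tr, "n_clamped") <- sum(neg)
  tr
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest tip-to-tip path.
#'
#' @param tree an unrooted `phylo` with branch lengths.
#' @return a rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length))
    bg_error("midpoint rooting needs branch lengths", "barcodegap_format_error")
  if (max(stats::cophenetic(tree)) == 0) {
    warning("zero-diameter tree: root placed on an arbitrary edge")
    return(ape::root(tree, outgroup = tree$tip.label[1L], resolve.root = TRUE))
  }
  phangorn::midpoint(tree)
}

#' Root a tree on the outgroup stem
#'
#' Roots on the edge separating the outgroup labels from the ingroup,
#' splitting that edge at its midpoint. If no single edge separates them
#' (outgroup not monophyletic on the unrooted tree), the root goes on the
#' edge whose outgroup side is purest (ties: most outgroup members, then
#' lowest edge index), with a warning.
#'
#' @param tree an unrooted `phylo`.
#' @param outgroup_labels character vector of outgroup tip labels.
#' @return a rooted `phylo`.
#' @export
outgroup_root <- function(tree, outgroup_labels) {
  tips <- tree$tip.label
  if (!all(outgroup_labels %in% tips))
    bg_error("outgroup label(s) not in tree", "barcodegap_format_error")
  if (all(tips %in% outgroup_labels))
    bg_error("all tips are outgroup; nothing to root against", "barcodegap_format_error")
  og <- which(tips %in% outgroup_labels)
  n <- length(tips)
  # tip bipartition induced by each edge: tips on the child side
  sides <- edge_tip_sides(tree)
  best <- NULL
  for (e in seq_len(nrow(tree$edge))) {
    side <- sides[[e]]
    for (s in list(side, setdiff(seq_len(n), side))) {
      n_og <- sum(s %in% og)
      if (n_og == 0L) next
      purity <- n_og / length(s)
      cand <- c(purity, n_og, -e)
      if (is.null(best) || compare_lex(cand, best$score) > 0)
        best <- list(score = cand, edge = e, exact = purity == 1 && n_og == length(og))
    }
  }
  if (!best$exact)
    warning("outgroup is not separable by a single edge; rooting on the purest edge")
  root_on_edge(tree, best$edge)
}

compare_lex <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i]) return(1L)
    if (a[i] < b[i]) return(-1L)
  }
  0L
}

# list over edges: tip indices on the child side of each edge
edge_tip_sides <- function(tree) {
  n <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  for (k in seq_len(nrow(post$edge))) {
    p <- post$edge[k, 1L]; ch <- post$edge[k, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) desc[[tree$edge[e, 2L]]])
}

# root at the midpoint of edge e by inserting a degree-2 node, then rooting
root_on_edge <- function(tree, e) {
  parent <- tree$edge[e, 1L]
  child <- tree$edge[e, 2L]
  len <- tree$edge.length[e]
  n <- length(tree$tip.label)
  # renumber: new internal node appended
  new_node <- n + tree$Nnode + 1L
  tree$edge[e, ] <- c(parent, new_node)
  tree$edge <- rbind(tree$edge, c(new_node, child))
  tree$edge.length[e] <- len / 2
  tree$edge.length <- c(tree$edge.length, len / 2)
  tree$Nnode <- tree$Nnode + 1L
  attr(tree, "order") <- NULL
  rooted <- ape::root(tree, node = new_node, resolve.root = TRUE)
  ape::collapse.singles(rooted)
}

#' Make a rooted tree ultrametric by least-squares node heights
#'
#' Each internal node's height is set to the mean of the path lengths from
#' the node to its descendant tips (tips at height 0), preserving the
#' topology. If averaging produces a parent at or below a child, the parent
#' is projected just above the tallest child, with a warning.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param eps projection offset used on constraint violations.
#' @return a rooted ultrametric `phylo`.
#' @export
ultrametricize <- function(tree, eps = 1e-9) {
  if (!ape::is.rooted(tree))
    bg_error("ultrametricize needs a rooted tree", "barcodegap_format_error")
  n <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  nn <- n + tree$Nnode
  # mean and count of tip path lengths below each node
  sum_path <- numeric(nn)
  n_tip <- integer(nn)
  n_tip[seq_len(n)] <- 1L
  h <- numeric(nn)
  for (k in seq_len(nrow(post$edge))) {
    p <- post$edge[k, 1L]; ch <- post$edge[k, 2L]; len <- post$edge.length[k]
    sum_path[p] <- sum_path[p] + sum_path[ch] + n_tip[ch] * len
    n_tip[p] <- n_tip[p] + n_tip[ch]
  }
  h[(n + 1L):nn] <- sum_path[(n + 1L):nn] / n_tip[(n + 1L):nn]
  # enforce child < parent bottom-up (postorder visits children first)
  violated <- FALSE
  parents <- unique(post$edge[, 1L])
  for (p in parents) {
    ch <- post$edge[post$edge[, 1L] == p, 2L]
    mx <- max(h[ch])
    if (h[p] < mx) {
      h[p] <- mx + eps
      violated <- TRUE
    }
  }
  if (violated) warning("node-height constraint violated by averaging; projected")
  out <- tree
  out$edge.length <- h[tree$edge[, 1L]] - h[tree$edge[, 2L]]
  attr(out, "heights") <- h
  out
}

#' Strict-clock configuration
#'
#' Defaults follow rate estimates for arthropod nuclear rRNA commonly used
#' for centipedes: 0.0016 substitutions/site/Ma with SD 0.0010, and a
#' permissive root-age reference of 200 +/- 50 Ma used only as a sanity
#' check (a warning if the estimated root age falls outside mean +/- 3 SD).
#'
#' @param rate substitution rate, substitutions/site/Ma (> 0).
#' @param rate_sd SD of the rate; draws are truncated at 0.
#' @param root_age_prior_mean,root_age_prior_sd root-age reference, Ma.
#' @param n_draws rate draws for age intervals.
#' @param seed seed for the draws.
#' @return a `clock_config` list.
#' @export
clock_config <- function(rate = 0.0016, rate_sd = 0.0010,
                         root_age_prior_mean = 200, root_age_prior_sd = 50,
                         n_draws = 1000L, seed = NULL) {
  if (rate <= 0) bg_error("clock rate must be > 0", "barcodegap_format_error")
  structure(list(rate = rate, rate_sd = rate_sd,
                 root_age_prior_mean = root_age_prior_mean,
                 root_age_prior_sd = root_age_prior_sd,
                 n_draws = as.integer(n_draws), seed = seed),
            class = "clock_config")
}

rtruncnorm0 <- function(n, mean, sd) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x > 0])
  }
  out[seq_len(n)]
}

#' Node ages under a strict molecular clock
#'
#' Converts the heights of an ultrametric tree (substitutions/site) to ages
#' in Ma: `age = height / rate`. Age intervals are the 2.5-97.5 percentiles
#' over truncated-normal rate draws.
#'
#' @param tree a rooted ultrametric `phylo` (heights in substitutions/site).
#' @param clock a [clock_config()].
#' @return An object of class `dated_tree`: `tree` (ultrametric, branch
#'   lengths rescaled to Ma), `ages` (named by node number; tips 0),
#'   `interval` (matrix with `lo`/`hi` columns), `clock`.
#' @export
clock_dates <- function(tree, clock = clock_config()) {
  h <- attr(tree, "heights")
  if (is.null(h)) {
    tree <- ultrametricize(tree)
    h <- attr(tree, "heights")
  }
  ages <- h / clock$rate
  if (!is.null(clock$seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(clock$seed))
  }
  r <- rtruncnorm0(clock$n_draws, clock$rate, clock$rate_sd)
  qs <- stats::quantile(r, c(0.975, 0.025), names = FALSE)
  interval <- cbind(lo = h / qs[1L], hi = h / qs[2L])
  root_age <- max(ages)
  lim <- clock$root_age_prior_mean + c(-3, 3) * clock$root_age_prior_sd
  if (root_age > 0 && (root_age < lim[1L] || root_age > lim[2L]))
    warning(sprintf(paste0("estimated root age %.3g Ma is outside the reference ",
                           "range %.3g-%.3g Ma"), root_age, max(0, lim[1L]), lim[2L]))
  out <- tree
  out$edge.length <- ages[tree$edge[, 1L]] - ages[tree$edge[, 2L]]
  structure(list(tree = out, ages = ages, interval = interval, clock = clock),
            class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, digits = 3, ...) {
  n <- length(x$tree$tip.label)
  root <- n + 1L
  cat(sprintf("dated_tree: %d tips, root age %.*g Ma (%.*g - %.*g)\n",
              n, digits, x$ages[root], digits, x$interval[root, "lo"],
              digits, x$interval[root, "hi"]))
  cat(sprintf("  rate %.4g subs/site/Ma, %d draws\n", x$clock$rate, x$clock$n_draws))
  invisible(x)
}

#' Export a dated tree
#'
#' Writes a Newick file (internal node labels carry the point ages in Ma) and
#' a TSV of node ages with their rate-uncertainty intervals.
#'
#' @param dated a `dated_tree`.
#' @param newick_path,ages_path output paths (either may be `NULL` to skip).
#' @param digits decimals for node-label ages.
#' @return invisibly, the node-age data.frame.
#' @export
write_dated_tree <- function(dated, newick_path = NULL, ages_path = NULL, digits = 2) {
  tr <- dated$tree
  n <- length(tr$tip.label)
  nodes <- (n + 1L):(n + tr$Nnode)
  tr$node.label <- sprintf("%.*f", digits, dated$ages[nodes])
  if (!is.null(newick_path)) ape::write.tree(tr, file = newick_path)
  df <- data.frame(node = nodes,
                   age_ma = dated$ages[nodes],
                   age_lo = dated$interval[nodes, "lo"],
                   age_hi = dated$interval[nodes, "hi"])
  if (!is.null(ages_path))
    utils::write.table(df, ages_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
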