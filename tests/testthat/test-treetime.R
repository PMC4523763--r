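test_that("NJ recovers the 3-taxon closed form and rejects incomplete matrices", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(as_bdist(d))
  lens <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 2, C = 3))

  d[1, 2] <- d[2, 1] <- NA
  expect_error(nj_tree(as_bdist(d)), class = "barcodegap_format_error")
  expect_error(nj_tree(as_bdist(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))))),
               class = "barcodegap_format_error")
})

test_that("NJ exactly recovers trees behind additive matrices", {
  set.seed(13)
  for (n in c(4, 6, 8)) {
    for (rep in 1:5) {
      true <- ape::rtree(n, rooted = FALSE)
      true$edge.length <- round(runif(nrow(true$edge), 0.05, 1), 3)
      dm <- as_bdist(tree_metric(true))
      got <- nj_tree(dm)
      expect_equal(ape::dist.topo(got, true), structure(0, names = "PH85"),
                   ignore_attr = TRUE)
      # branch lengths: path metric of the estimate equals the input exactly
      expect_equal(tree_metric(got)[rownames(dm$d), colnames(dm$d)], dm$d,
                   tolerance = 1e-10)
    }
  }
})

test_that("NJ topology is the unique additive fit among all small topologies", {
  # exhaustive oracle at n = 5: the generating topology is the only one whose
  # best additive fit is exact, and NJ finds it
  set.seed(8)
  tips <- paste0("t", 1:5)
  true <- ape::rtree(5, rooted = FALSE, tip.label = tips)
  true$edge.length <- round(runif(nrow(true$edge), 0.1, 1), 3)
  d <- tree_metric(true)
  all_tops <- phangorn::allTrees(5, rooted = FALSE, tip.label = tips)
  exact_fit <- vapply(all_tops, function(top) {
    # least-squares branch lengths for this topology
    fit <- try(phangorn::nnls.tree(stats::as.dist(d), ape::unroot(top)), silent = TRUE)
    if (inherits(fit, "try-error")) return(FALSE)
    max(abs(tree_metric(fit)[rownames(d), colnames(d)] - d)) < 1e-6
  }, logical(1))
  matching <- all_tops[exact_fit]
  expect_identical(length(matching), 1L)
  expect_equal(ape::dist.topo(matching[[1]], true), structure(0, names = "PH85"),
               ignore_attr = TRUE)
  expect_equal(ape::dist.topo(nj_tree(as_bdist(d)), true),
               structure(0, names = "PH85"), ignore_attr = TRUE)
})

test_that("negative NJ branch estimates are clamped to zero with a warning", {
  # a non-additive matrix that produces a negative internal estimate
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d[upper.tri(d)] <- c(0.339, 0.435, 0.616, 0.917, 0.282, 0.909)
  d <- d + t(d)
  raw <- ape::nj(stats::as.dist(d))
  expect_true(any(raw$edge.length < 0)) # precondition for the clamp check
  expect_warning(tr <- nj_tree(as_bdist(d)), "clamped")
  expect_true(all(tr$edge.length >= 0))
  expect_identical(attr(tr, "n_clamped"), sum(raw$edge.length < 0))
})

test_that("midpoint rooting splits the longest tip-to-tip path in half", {
  t2 <- ape::read.tree(text = "(a:1,b:3);")
  r <- midpoint_root(t2)
  depth <- ape::node.depth.edgelength(r)
  expect_equal(unname(depth[1:2]), c(2, 2))

  sym <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  r4 <- midpoint_root(ape::unroot(sym))
  d4 <- ape::node.depth.edgelength(r4)
  expect_equal(unname(d4[1:4]), rep(2, 4))
})

test_that("midpoint rooting minimizes root-to-tip spread over all edge placements", {
  set.seed(29)
  for (rep in 1:10) {
    tr <- ape::rtree(8, rooted = FALSE)
    r <- midpoint_root(tr)
    depth <- ape::node.depth.edgelength(r)
    spread_mid <- max(depth[1:8]) - min(depth[1:8])
    # oracle: scan every edge, rooting at many points along it
    best <- Inf
    for (e in seq_len(nrow(tr$edge))) {
      len <- tr$edge.length[e]
      for (frac in seq(0, 1, length.out = 21)) {
        rr <- phytools::reroot(tr, tr$edge[e, 2], position = frac * len)
        dd <- ape::node.depth.edgelength(rr)
        best <- min(best, max(dd[1:8]) - min(dd[1:8]))
      }
    }
    expect_lte(spread_mid, best + 1e-8)
  }
})

test_that("outgroup rooting places the root on the separating stem", {
  t4 <- ape::unroot(ape::read.tree(text = "((a:1,b:1):1,(c:1,o:2):1);"))
  r <- outgroup_root(t4, "o")
  expect_true(ape::is.rooted(r))
  kids <- r$edge[r$edge[, 1] == length(r$tip.label) + 1L, 2]
  expect_true(which(r$tip.label == "o") %in% kids) # o's pendant edge holds the root

  t6 <- ape::unroot(ape::read.tree(
    text = "(((a:1,b:1):1,c:1):1,(d:1,(o1:1,o2:1):2):1);"))
  r6 <- outgroup_root(t6, c("o1", "o2"))
  # the outgroup pair must be monophyletic on one side of the root
  expect_true(ape::is.monophyletic(r6, c("o1", "o2")))
  split_sizes <- table(cutree_root_side(r6))
  expect_true(2 %in% split_sizes)
})

test_that("outgroup rooting handles non-separable and degenerate outgroups", {
  # o1 and o2 on opposite sides: not separable by one edge
  t4 <- ape::unroot(ape::read.tree(text = "((o1:1,b:1):1,(c:1,o2:1):1);"))
  expect_warning(r <- outgroup_root(t4, c("o1", "o2")), "not separable")
  expect_true(ape::is.rooted(r))
  # deterministic: same call, same result
  r2 <- suppressWarnings(outgroup_root(t4, c("o1", "o2")))
  expect_identical(ape::write.tree(r), ape::write.tree(r2))
  expect_error(outgroup_root(t4, c("o1", "o2", "b", "c")),
               class = "barcodegap_format_error")
  expect_error(outgroup_root(t4, "missing"), class = "barcodegap_format_error")
})

test_that("ultrametricize averages tip paths and is a fixed point on clock trees", {
  t2 <- ape::read.tree(text = "(a:0.1,b:0.3);")
  u <- ultrametricize(t2)
  expect_equal(unname(attr(u, "heights")[3]), 0.2)
  expect_equal(u$edge.length, c(0.2, 0.2))

  clockt <- ape::read.tree(text = "((a:1,b:1):1,(c:0.5,d:0.5):1.5);")
  u2 <- ultrametricize(clockt)
  expect_equal(u2$edge.length, clockt$edge.length, tolerance = 1e-12)
})

test_that("ultrametricize recovers true heights from noisy clock trees", {
  sigma <- 0.01
  errs <- numeric(0)
  set.seed(55)
  for (rep in 1:100) {
    tr <- ape::rcoal(6) # ultrametric truth
    true_h <- max(ape::node.depth.edgelength(tr))
    noisy <- tr
    noisy$edge.length <- pmax(tr$edge.length + rnorm(nrow(tr$edge), 0, sigma), 0)
    u <- suppressWarnings(ultrametricize(noisy))
    est_h <- unname(attr(u, "heights")[length(tr$tip.label) + 1L])
    errs <- c(errs, est_h - true_h)
  }
  # averaging tip paths keeps the root-height error at the branch-noise scale
  expect_lt(mean(abs(errs)), 2 * sigma)
  expect_gt(mean(abs(errs) <= 2 * sigma), 0.8)
})

test_that("clock dating converts heights to ages with rate scaling", {
  t2 <- ape::read.tree(text = "(a:0.0016,b:0.0016);") # pairwise distance 0.0032
  d1 <- suppressWarnings(
    clock_dates(ultrametricize(t2), clock_config(rate = 0.0016, seed = 1)))
  expect_equal(unname(d1$ages[3]), 1.0)
  d2 <- suppressWarnings(
    clock_dates(ultrametricize(t2), clock_config(rate = 0.0032, seed = 1)))
  expect_equal(unname(d2$ages[3]), 0.5)

  zero <- ape::read.tree(text = "(a:0,b:0);")
  dz <- clock_dates(ultrametricize(zero), clock_config(seed = 1))
  expect_equal(unname(dz$ages), c(0, 0, 0))
})

test_that("dated trees keep parent > child and intervals bracket point ages", {
  set.seed(91)
  for (rep in 1:10) {
    tr <- ape::rcoal(8)
    tr$edge.length <- tr$edge.length * 0.01
    u <- ultrametricize(tr)
    dd <- suppressWarnings(clock_dates(u, clock_config(seed = rep)))
    ages <- dd$ages
    for (e in seq_len(nrow(u$edge)))
      expect_gt(ages[u$edge[e, 1]], ages[u$edge[e, 2]] - 1e-12)
    expect_equal(unname(ages[1:8]), rep(0, 8))
    expect_equal(max(ages), unname(ages[9])) # root age is the maximum
    nodes <- 9:15
    expect_true(all(dd$interval[nodes, "lo"] <= ages[nodes] + 1e-12))
    expect_true(all(dd$interval[nodes, "hi"] >= ages[nodes] - 1e-12))
  }
})

test_that("relabeling taxa permutes the dated pipeline consistently", {
  pm <- make_planted_matrix(planted_spec(c(2, 2, 2), within_max = 0.5,
                                         between_lo = 5, between_hi = 9,
                                         units = "fraction"), seed = 2)
  dm <- pm$matrix
  dm$d <- dm$d / 100
  perm <- c(4, 1, 6, 2, 5, 3)
  dm2 <- dm
  dm2$d <- dm$d[perm, perm]
  dm2$labels <- dm$labels[perm]
  date_it <- function(m) suppressWarnings(
    clock_dates(ultrametricize(midpoint_root(nj_tree(m))), clock_config(seed = 3)))
  age1 <- date_it(dm)
  age2 <- date_it(dm2)
  expect_equal(max(age1$ages), max(age2$ages), tolerance = 1e-10)
  # tip-to-tip divergence times agree under the relabeling
  c1 <- ape::cophenetic.phylo(age1$tree)
  c2 <- ape::cophenetic.phylo(age2$tree)
  expect_equal(c2[rownames(c1), colnames(c1)], c1, tolerance = 1e-10)
})

test_that("dated tree export writes newick node ages and a TSV", {
  t2 <- ape::read.tree(text = "(a:0.008,b:0.008);")
  dd <- suppressWarnings(clock_dates(ultrametricize(t2), clock_config(seed = 1)))
  nwk <- tempfile(fileext = ".nwk")
  tsv <- tempfile(fileext = ".tsv")
  df <- write_dated_tree(dd, nwk, tsv)
  expect_equal(df$age_ma, 5)
  expect_match(readLines(nwk), "5.00")
  expect_equal(utils::read.delim(tsv)$age_ma, 5)
})
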