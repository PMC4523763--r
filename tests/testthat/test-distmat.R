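test_that("pair_counts classifies transitions and transversions after masking", {
  ct <- pair_counts("AAAA", "AAAA")
  expect_equal(ct[c("L", "n_ts", "n_tv")], list(L = 4L, n_ts = 0L, n_tv = 0L))
  ct <- pair_counts("AAGA", "AAAA")
  expect_equal(ct[c("L", "n_ts", "n_tv")], list(L = 4L, n_ts = 1L, n_tv = 0L))
  ct <- pair_counts("AC-T", "ATGT", policy = "pairwise")
  expect_equal(ct[c("L", "n_ts", "n_tv")], list(L = 3L, n_ts = 1L, n_tv = 0L))
  # ambiguity codes are excluded like gaps
  ct <- pair_counts("ACNT", "ATGT", policy = "pairwise")
  expect_equal(ct$L, 3L)
  # no valid sites -> flagged, not an error
  ct <- pair_counts("--", "AA")
  expect_false(ct$defined)
  expect_true(is.na(p_distance(ct)))
})

test_that("p and K2P distances match their closed forms", {
  expect_equal(p_distance(pair_counts("AAAA", "AAAA")), 0)
  expect_equal(p_distance(pair_counts("AAAA", "AAAT")), 0.25)
  cts <- list(L = 100L, n_ts = 10L, n_tv = 5L, P = 0.1, Q = 0.05, defined = TRUE)
  expect_equal(p_distance(cts), 0.15)
  expect_equal(k2p_distance(cts), -0.5 * log(1 - 0.25) - 0.25 * log(0.9))
  expect_equal(k2p_distance(cts), 0.1702, tolerance = 1e-3)
  expect_equal(k2p_distance(list(L = 10L, n_ts = 0L, n_tv = 0L, P = 0, Q = 0,
                                 defined = TRUE)), 0)
  # saturation: log argument hits zero -> flagged undefined
  expect_true(is.na(k2p_distance(list(L = 10L, n_ts = 5L, n_tv = 0L, P = 0.5,
                                      Q = 0, defined = TRUE))))
})

test_that("distance_matrix matches a hand-computed 3-sequence toy", {
  # len 20; b differs from a at 2 sites (1 ts + 1 tv), c at 4 (2 ts + 2 tv)
  a <- "AAAAACCCCCGGGGGTTTTT"
  b <- "GAAAAACCCCGGGGGTTTTT" # site1 A->G ts, site6 C->A tv... recompute below
  c_ <- "GGAAACCCAACGGGGTTTTT"
  aln <- barcode_aln(c(a = a, b = b, c = c_))
  for (model in c("p", "K2P")) {
    dm <- distance_matrix(aln, model, policy = "pairwise")
    expect_equal(dm$d, naive_distance_matrix(aln, model, "pairwise"))
    expect_true(isSymmetric(dm$d))
    expect_equal(diag(dm$d), stats::setNames(rep(0, 3), c("a", "b", "c")))
  }
})

test_that("two identical sequences give a zero matrix", {
  aln <- barcode_aln(c(x = "ACGTACGT", y = "ACGTACGT"))
  dm <- distance_matrix(aln, "K2P")
  expect_equal(unname(dm$d), matrix(0, 2, 2))
})

test_that("distance engine agrees exactly with the naive oracle", {
  set.seed(101)
  for (rep in 1:12) {
    n <- sample(3:10, 1)
    L <- sample(20:50, 1)
    aln <- rand_alignment(n, L)
    for (model in c("p", "K2P")) {
      for (policy in c("pairwise", "partial")) {
        got <- distance_matrix(aln, model, policy = policy, coverage = 0.95)
        expect_equal(got$d, naive_distance_matrix(aln, model, policy, 0.95),
                     info = sprintf("model=%s policy=%s rep=%d", model, policy, rep))
      }
    }
  }
})

test_that("K2P matches an independent implementation and dominates p", {
  # related sequences (evolved on a tree) so pairs stay below saturation
  yt <- simulate_yule_tree(sim_params(n_tips = 8, birth_rate = 0.05, seed = 77))
  aln <- evolve_k2p(yt, sim_params(n_tips = 8, clock_rate = 0.0016, L = 400, seed = 78))
  set.seed(79)
  gapped <- strsplit(aln$seq, "")
  for (i in seq_along(gapped)) # sprinkle a few gaps to exercise deletion
    gapped[[i]][sample(400, 8)] <- "-"
  aln <- barcode_aln(vapply(gapped, paste, character(1), collapse = ""))
  dm_k <- distance_matrix(aln, "K2P", policy = "pairwise")
  dm_p <- distance_matrix(aln, "p", policy = "pairwise")
  # p <= K2P entrywise (multiple-hit correction inflates distances)
  up <- upper.tri(dm_k$d)
  expect_false(anyNA(dm_k$d[up]))
  expect_true(all(dm_p$d[up] <= dm_k$d[up] + 1e-12))
  # cross-check against ape's K80 engine with pairwise deletion
  chars <- do.call(rbind, strsplit(tolower(aln$seq), ""))
  rownames(chars) <- names(aln$seq)
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(chars), model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(dm_k$d, ref[rownames(dm_k$d), colnames(dm_k$d)], tolerance = 1e-10)
})

test_that("K2P equals p to first order at shallow divergence", {
  set.seed(5)
  tr <- ape::read.tree(text = "(a:0.004,b:0.004);")
  for (i in 1:10) {
    aln <- evolve_k2p(tr, sim_params(n_tips = 2, L = 5000, seed = i))
    p <- distance_matrix(aln, "p")$d[1, 2]
    k <- distance_matrix(aln, "K2P")$d[1, 2]
    if (p > 0) expect_lt(abs(k - p) / p, 0.05)
  }
})

test_that("bootstrap SEs are deterministic under a seed and zero for identical pairs", {
  aln <- rand_alignment(5, 120)
  aln$seq[2] <- aln$seq[1] # identical pair
  b1 <- bootstrap_se(aln, "K2P", B = 50, seed = 9)
  b2 <- bootstrap_se(aln, "K2P", B = 50, seed = 9)
  expect_identical(b1$se, b2$se)
  expect_equal(b1$se[1, 2], 0)
  expect_true(all(b1$se[upper.tri(b1$se)] >= 0))
  # point distances equal the non-bootstrap matrix
  expect_equal(b1$d, distance_matrix(aln, "K2P")$d)
})

test_that("distance writers round-trip and the combined table mirrors the fixture", {
  dm <- fixture_k2p()
  f <- tempfile(fileext = ".csv")
  write_distance_csv(dm, f, header = "test")
  back <- read_distance_csv(f)
  expect_equal(back$d, dm$d)
  expect_identical(back$model, "K2P")
  expect_identical(back$units, "percent")

  # writing the fixture's two triangles back out reproduces its data lines
  both <- read_printed_matrix(bg_fixture("table3"), bg_fixture("table3_se"))
  f2 <- tempfile(fileext = ".csv")
  write_combined_table(both$K2P, both$p, f2)
  orig <- grep("^#", readLines(bg_fixture("table3")), value = TRUE, invert = TRUE)
  got <- grep("^#", readLines(f2), value = TRUE, invert = TRUE)
  expect_identical(gsub(",$", "", got), gsub(",$", "", orig))

  f3 <- tempfile(fileext = ".phy")
  write_phylip(dm, f3)
  expect_identical(readLines(f3)[1], "12")
})

test_that("suspect SE marker in the printed table is preserved, not guessed", {
  both <- read_printed_matrix(bg_fixture("table3"), bg_fixture("table3_se"))
  k <- both$K2P
  expect_equal(k$se["Barbarano", "Frosinone"], 0.17)
  expect_true(k$suspect_se["Barbarano", "Frosinone"])
  expect_true(k$suspect_se["Frosinone", "Barbarano"])
  expect_identical(sum(k$suspect_se), 2L)
  expect_identical(sum(both$p$suspect_se), 0L)
})
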