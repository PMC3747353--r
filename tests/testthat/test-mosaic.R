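make_occ <- function(duplicon_id, chrom, start, end, identity = 99) {
  data.frame(duplicon_id = duplicon_id, chrom = chrom, start = start,
             end = end, identity = identity, length = end - start,
             stringsAsFactors = FALSE)
}

test_that("profiles apply the identity, length and duplicon-count thresholds", {
  seg <- data.frame(chrom = c("A", "B"), start = 0L, end = 10000L,
                    name = c("segA", "segB"))
  # segA: 12 qualifying duplicons; segB: 9 qualifying + 1 below identity
  occA <- make_occ(sprintf("d%02d", 1:12), "A", seq(0, by = 300, length.out = 12),
                   seq(0, by = 300, length.out = 12) + 200)
  occB <- make_occ(sprintf("d%02d", 1:9), "B", seq(0, by = 300, length.out = 9),
                   seq(0, by = 300, length.out = 9) + 200)
  occB_low <- make_occ("d10", "B", 3000, 3200, identity = 94.9)
  prof <- build_profiles(seg, rbind(occA, occB, occB_low))
  expect_equal(rownames(prof), "segA")       # segB dropped (9 < 10)
  expect_equal(sum(prof), 12)
  # short occurrences never set a bit
  occ_short <- make_occ("d99", "A", 50, 149)
  prof2 <- build_profiles(seg, rbind(occA, occ_short))
  expect_false("d99" %in% colnames(prof2))
})

test_that("profile distance is the Hamming fraction and flags unrelated pairs", {
  expect_equal(as.numeric(profile_distance(c(1, 1, 0, 0), c(1, 1, 0, 0))), 0)
  expect_equal(as.numeric(profile_distance(rep(1, 8), rep(0, 8))), 1)
  d <- profile_distance(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(as.numeric(d), 0.5)
  expect_false(attr(d, "unrelated"))
  expect_true(attr(profile_distance(c(1, 0), c(0, 1)), "unrelated"))
  expect_error(profile_distance(c(1, 0), c(1, 0, 1)), "index")
})

test_that("profile distance behaves as a metric on random binary profiles", {
  set.seed(14)
  for (rep in 1:30) {
    p <- matrix(rbinom(3 * 16, 1, 0.5), nrow = 3)
    dab <- as.numeric(profile_distance(p[1, ], p[2, ]))
    dba <- as.numeric(profile_distance(p[2, ], p[1, ]))
    dac <- as.numeric(profile_distance(p[1, ], p[3, ]))
    dcb <- as.numeric(profile_distance(p[3, ], p[2, ]))
    expect_equal(dab, dba)
    expect_lte(dab, dac + dcb + 1e-12)
    expect_equal(as.numeric(profile_distance(p[1, ], p[1, ])), 0)
  }
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    tr <- ape::unroot(tr)
    d <- ape::cophenetic.phylo(tr)
    rec <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(rec), tr), 0, ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(rec)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3")
})

test_that("three leaves resolve by the closed-form three-point formulas", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], (3 + 5 - 6) / 2)
  expect_equal(bl[["b"]], (3 + 6 - 5) / 2)
  expect_equal(bl[["c"]], (5 + 6 - 3) / 2)
})

test_that("planted duplication groups are bipartitioned by the profile tree", {
  ss <- generate_segment_set(2, 5, duplicons_per_group = 12L, sharing = 0.9,
                             seed = 6)
  prof <- build_profiles(ss$segments, ss$occurrences, min_duplicons = 5L)
  tr <- nj_tree(profile_dist(prof))
  grpA <- names(ss$groups)[ss$groups == "group_1"]
  expect_true(has_split(tr, intersect(grpA, tr$tip.label)))
})

test_that("core duplicons require strictly more than the sharing threshold", {
  # 10-segment clade: one duplicon in 7 (core), one in exactly 67/100 scaled
  segs <- sprintf("s%02d", 1:10)
  prof <- matrix(0L, nrow = 10, ncol = 12,
                 dimnames = list(segs, sprintf("d%02d", 1:12)))
  prof[1:7, "d01"] <- 1L                      # 0.70 > 0.67 -> core
  prof[, sprintf("d%02d", 3:12)] <- 1L        # keep rows profiled
  tr <- nj_tree(stats::dist(cbind(prof, matrix(runif(10 * 3), 10))))
  cores <- core_duplicons(tr, prof, share_threshold = 0.67)
  root_clade <- cores[cores$n_leaves == 10, ]
  expect_true("d01" %in% root_clade$duplicon_id)

  # share exactly equal to the threshold is not core (strict inequality)
  at_thr <- core_duplicons(tr, prof, share_threshold = 0.70)
  expect_false("d01" %in% at_thr$duplicon_id[at_thr$n_leaves == 10])
})

test_that("core threshold extremes behave as stated", {
  set.seed(44)
  prof <- matrix(rbinom(8 * 10, 1, 0.6), nrow = 8,
                 dimnames = list(sprintf("s%d", 1:8), sprintf("d%02d", 1:10)))
  tr <- nj_tree(stats::dist(prof) + 1e-6)
  cores0 <- core_duplicons(tr, prof, share_threshold = 0)
  cores1 <- core_duplicons(tr, prof, share_threshold = 1)
  clades <- cores0[!duplicated(cores0$clade), c("clade", "n_leaves")]
  parts <- ape::prop.part(tr)
  labels <- attr(parts, "labels")
  for (ci in seq_along(parts)) {
    leaves <- labels[parts[[ci]]]
    if (length(leaves) < 3) next
    id <- sprintf("clade_%d", ci)
    present_any <- colnames(prof)[colSums(prof[leaves, , drop = FALSE]) > 0]
    expect_setequal(cores0$duplicon_id[cores0$clade == id], present_any)
    expect_length(cores1$duplicon_id[cores1$clade == id], 0)  # share > 1 impossible
  }
})

test_that("planted core duplicon is detected at the 0.67 rule", {
  ss <- generate_segment_set(2, 10, duplicons_per_group = 14L, sharing = 0.5,
                             seed = 19)
  prof <- build_profiles(ss$segments, ss$occurrences, min_duplicons = 3L)
  tr <- nj_tree(profile_dist(prof))
  cores <- core_duplicons(tr, prof, share_threshold = 0.67)
  for (g in names(ss$cores)) {
    leaves <- intersect(names(ss$groups)[ss$groups == g], rownames(prof))
    clade_rows <- cores[cores$duplicon_id == ss$cores[[g]], ]
    expect_gt(nrow(clade_rows), 0)
  }
})

test_that("flanking pairs respect the end windows and match rules", {
  cnv <- data.frame(chrom = "X", start = 0L, end = 1000L, name = "cnv")
  occ <- make_occ(c("d1", "d1"), "X", c(50L, 900L), c(200L, 990L))
  pairs <- flanking_pairs(cnv, occ)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$left_start, 50L)
  expect_equal(pairs$right_start, 900L)

  # second copy in the middle half: no pair
  occ2 <- make_occ(c("d1", "d1"), "X", c(50L, 400L), c(200L, 500L))
  expect_equal(nrow(flanking_pairs(cnv, occ2)), 0L)

  # different duplicon ids do not pair in coordinate mode
  occ3 <- make_occ(c("d1", "d2"), "X", c(50L, 900L), c(200L, 990L))
  expect_equal(nrow(flanking_pairs(cnv, occ3)), 0L)

  # 3 left x 2 right copies of one duplicon: exhaustive cross product
  occ5 <- make_occ(rep("d1", 5), "X", c(0L, 60L, 120L, 800L, 880L),
                   c(0L, 60L, 120L, 800L, 880L) + 100L)
  expect_equal(nrow(flanking_pairs(cnv, occ5)), 6L)

  expect_error(flanking_pairs(data.frame(chrom = "X", start = 0L, end = 3L),
                              occ), "too short")
})

test_that("sequence mode screens flanking pairs by identity and length ratio", {
  skip_if_not_installed("Biostrings")
  cnv <- data.frame(chrom = "X", start = 0L, end = 1000L, name = "cnv")
  set.seed(73)
  base <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                collapse = "")
  mutated <- strsplit(base, "")[[1]]
  flip <- sample(150, 40)   # ~73% identity: fails the >90% rule
  mutated[flip] <- vapply(mutated[flip], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  occ <- make_occ(c("d1", "d1", "d2", "d2"), "X",
                  c(10L, 840L, 30L, 820L), c(160L, 990L, 180L, 970L))
  rownames(occ) <- c("o1", "o2", "o3", "o4")
  seqs <- c(o1 = base, o2 = base,                       # identical pair
            o3 = base, o4 = paste(mutated, collapse = ""))
  pairs <- flanking_pairs(cnv, occ, sequences = seqs)
  # o1-o2 and o3-o2 (identical sequences); diverged o4 never pairs
  expect_equal(nrow(pairs), 2L)
  expect_false(any(pairs$right_start == 820L))

  # length ratio below the threshold blocks an otherwise identical pair
  occ_short <- make_occ(c("d1", "d1"), "X", c(10L, 840L), c(160L, 940L))
  rownames(occ_short) <- c("a", "b")
  seqs_short <- c(a = base, b = substr(base, 1, 100))
  expect_equal(nrow(flanking_pairs(cnv, occ_short, sequences = seqs_short)), 0L)
})

test_that("flanking pairs are invariant under coordinate reflection", {
  set.seed(77)
  for (rep in 1:10) {
    gen <- generate_flanked_cnv(2000L, sample(0:4, 1), seed = 500 + rep)
    n_fwd <- nrow(flanking_pairs(gen$cnv, gen$occurrences))
    occ_ref <- gen$occurrences
    occ_ref$start2 <- 2000L - gen$occurrences$end
    occ_ref$end <- 2000L - gen$occurrences$start
    occ_ref$start <- occ_ref$start2
    occ_ref$start2 <- NULL
    expect_equal(nrow(flanking_pairs(gen$cnv, occ_ref)), n_fwd)
  }
})

test_that("weighted density sums member weights over the region length", {
  region <- data.frame(chrom = "X", start = 0L, end = 1000L)
  occ <- make_occ(c("d1", "d2"), "X", c(100L, 500L), c(200L, 600L))
  w <- c(d1 = 3, d2 = 5)
  expect_equal(weighted_density(region, occ, w), 0.008)
  expect_equal(weighted_density(region, occ[0, ], w), 0)

  # exactly half inside still counts (>= 50% rule); just under does not
  occ_edge <- make_occ("d1", "X", 950L, 1050L)
  expect_equal(weighted_density(region, occ_edge, w), 3 / 1000)
  occ_out <- make_occ("d1", "X", 951L, 1051L)
  expect_equal(weighted_density(region, occ_out, w), 0)

  # linear in the weights
  expect_equal(weighted_density(region, occ, w * 2),
               2 * weighted_density(region, occ, w))
})

test_that("duplicon weights count training CNVs per duplicon", {
  calls <- data.frame(cnv_id = c("c1", "c1", "c2", "c3", "c3"),
                      duplicon_id = c("d1", "d1", "d1", "d2", "d2"))
  w <- duplicon_weights(calls)
  expect_equal(w[["d1"]], 2)   # c1 counted once despite two calls
  expect_equal(w[["d2"]], 1)
})

test_that("non-CNV regions are the complement of merged CNVs", {
  cnvs <- data.frame(chrom = c("chr1", "chr1", "chr1"),
                     start = c(100L, 150L, 500L), end = c(200L, 300L, 700L))
  nc <- noncnv_regions(cnvs, c(chr1 = 1000))
  expect_equal(nc$start, c(0L, 300L, 700L))
  expect_equal(nc$end, c(100L, 500L, 1000L))
})

test_that("Welch test separates density groups and handles identical input", {
  same <- c(1, 2, 3, 4)
  res <- compare_densities(same, same)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)

  # hand-computed two-sample example
  x <- c(1, 2); y <- c(4, 6)
  res2 <- compare_densities(x, y)
  se <- sqrt(var(x) / 2 + var(y) / 2)
  expect_equal(res2$t, (mean(x) - mean(y)) / se)

  expect_error(compare_densities(c(1, 1), c(2, 2)), "zero variance")

  # power at the reported effect size: means 4.3 vs 1.8, sd 0.5, n = 24
  set.seed(55)
  hits <- sum(replicate(50, {
    compare_densities(rnorm(24, 4.3, 0.5), rnorm(24, 1.8, 0.5))$p_value < 1e-5
  }))
  expect_gte(hits, 49)
})
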