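test_that("ohnolog classification splits conserved WGD genes into pairs and singles", {
  ref <- pair_reference(3L, "tf")
  # identical descendant: full retention in every category present
  cen <- classify_ohnologs(ref, ref)
  tf <- cen[cen$category == "tf", ]
  expect_equal(tf$n_conserved, 6)
  expect_equal(tf$n_in_intact_pairs, 6)
  expect_equal(tf$retention_fraction, 1)
  # one member of one pair deleted: pairs 2, singles 1, fraction 4/5
  tags <- vapply(ref$genes, function(g) g$ancestry, integer(1))
  pairs <- vapply(ref$genes, function(g) g$ohnolog, integer(1))
  one_member <- tags[match(unique(pairs)[1L], pairs)]
  cen1 <- classify_ohnologs(ref, drop_tags(ref, one_member))
  tf1 <- cen1[cen1$category == "tf", ]
  expect_equal(tf1$n_conserved, 5)
  expect_equal(tf1$n_in_intact_pairs, 4)
  expect_equal(tf1$n_singles, 1)
  expect_equal(tf1$retention_fraction, 4 / 5)
  # all WGD genes gone: empty denominator reported as not-a-value
  cen0 <- classify_ohnologs(ref, drop_tags(ref, tags))
  expect_equal(cen0$n_conserved, rep(0, 3))
  expect_true(all(is.na(cen0$retention_fraction)))
  # invariants: pair genes + singles = conserved, pair count even
  expect_true(all(cen1$n_in_intact_pairs %% 2 == 0))
  expect_true(all(cen1$n_in_intact_pairs + cen1$n_singles == cen1$n_conserved))
  # descendant without tags is rejected
  bare <- ref
  bare$genes <- lapply(bare$genes, function(g) { g$ancestry <- NA_integer_; g })
  expect_error(classify_ohnologs(ref, bare), "ancestry tags")
})

test_that("a single only ever moves out of the ohnolog class, never back", {
  ref <- pair_reference(2L, "enzyme")
  tags <- vapply(ref$genes, function(g) g$ancestry, integer(1))
  pairs <- vapply(ref$genes, function(g) g$ohnolog, integer(1))
  p1 <- tags[pairs == unique(pairs)[1L]]
  full <- classify_ohnologs(ref, ref)
  after1 <- classify_ohnologs(ref, drop_tags(ref, p1[1L]))
  after2 <- classify_ohnologs(ref, drop_tags(ref, p1))
  ez <- function(cen) cen[cen$category == "enzyme", ]
  expect_equal(ez(full)$n_singles, 0)
  expect_equal(ez(after1)$n_singles, 1)
  expect_equal(ez(after2)$n_singles, 0)      # the partner lineage died too
  expect_equal(ez(after2)$n_conserved, 2)
})

test_that("uniform random-deletion null matches exhaustive enumeration", {
  ref <- pair_reference(2L, "tf")
  losses <- data.frame(generation = 100L, category = "tf", count = 2L)
  set.seed(71)
  null <- random_deletion_null(ref, losses, mode = "uniform",
                               n_replicates = 4000L)
  tf <- null[null$category == "tf", ]
  want <- enumerate_retention(2L, 2L)     # = 1/3 by enumeration of C(4,2)
  expect_equal(want, 1 / 3)
  se <- tf$null_sd / sqrt(tf$n_replicates)
  expect_lt(abs(tf$null_mean - want), 3 * se)
  # zero deletions: retention stays exactly 1
  none <- data.frame(generation = 100L, category = "tf", count = 0L)
  n0 <- random_deletion_null(ref, none, mode = "uniform", n_replicates = 5L)
  expect_equal(n0$null_mean[n0$category == "tf"], 1)
  # more deletions than genes is an infeasible spec
  toomany <- data.frame(generation = 100L, category = "tf", count = 5L)
  expect_error(random_deletion_null(ref, toomany, n_replicates = 2L),
               "infeasible-spec")
})

test_that("connectivity-binned null with flat profile reproduces the uniform null", {
  set.seed(72)
  base <- retag_ancestry(random_genome(n_range = c(16L, 16L), L = 6L,
                                       n_motif_words = 3L))
  ref <- whole_genome_duplicate(base)$genome
  ref <- retag_ancestry_keep_pairs(ref)
  n_tf <- sum(gene_categories(ref) == "tf")
  losses <- data.frame(generation = 100L, category = "tf",
                       count = max(1L, n_tf %/% 3L))
  cb <- connectivity_bins(ref, n_bins = 3L)
  conn <- list(bins = cb,
               profile = matrix(0.5, nrow = 1L, ncol = max(cb$bin)))
  u <- random_deletion_null(ref, losses, "uniform", n_replicates = 3000L)
  c2 <- random_deletion_null(ref, losses, "connectivity", n_replicates = 3000L,
                             conn = conn)
  tu <- u[u$category == "tf", ]
  tc <- c2[c2$category == "tf", ]
  se <- sqrt(tu$null_sd^2 + tc$null_sd^2) / sqrt(3000)
  expect_lt(abs(tu$null_mean - tc$null_mean), 4 * se + 1e-8)
})

test_that("binding-site conservation is the discrete motif identity", {
  ref <- pair_reference(1L, "tf")
  a <- ref$genes[[1L]]
  b <- a
  expect_equal(bs_conservation(a, b), 1)
  m <- as.integer(b$bind_motif)
  m[2L] <- 1L - m[2L]
  b$bind_motif <- motif(m, 2L)
  expect_equal(bs_conservation(a, b), 0)
  expect_error(bs_conservation(a, pump_enzyme_genome()$genes[[1L]]),
               "TFs")
  c2 <- a
  c2$ancestry <- a$ancestry + 99L
  expect_error(bs_conservation(a, c2), "descend")
})

test_that("relative outdegree measures connectivity bias of retention", {
  outd <- c(`1` = 0, `2` = 2, `3` = 4)
  expect_equal(relative_outdegree(outd, c(1, 2, 3)), 1)
  expect_equal(relative_outdegree(outd, 3), 2)
  expect_lt(relative_outdegree(outd, 1), 1)
  expect_true(is.nan(relative_outdegree(outd, integer(0))))
  expect_error(relative_outdegree(outd, 7), "subset")
})

test_that("rank-sum comparison matches exact enumeration and is rank-invariant", {
  rs <- rank_sum_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$statistic, 0)
  expect_equal(enumerate_rank_sum_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(rs$p_value, 0.1)
  # invariance under monotone transformation of the scores
  a <- c(0.2, 0.5, 0.9, 0.4)
  b <- c(0.3, 0.7, 0.8)
  r1 <- rank_sum_compare(a, b)
  r2 <- rank_sum_compare(exp(5 * a), exp(5 * b))
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$statistic, r2$statistic)
  expect_warning(rs0 <- rank_sum_compare(c(1, 1), c(1, 1)), "identical")
  expect_equal(rs0$p_value, 1)
  expect_error(rank_sum_compare(numeric(), 1), "non-empty")
})

test_that("divergence statistics separate ohnologs from singles", {
  set.seed(73)
  base <- retag_ancestry(random_genome(n_range = c(12L, 12L), L = 6L,
                                       n_motif_words = 3L))
  ids <- gene_ids(base)
  tf_ids <- ids[gene_categories(base) == "tf"]
  lod <- make_synthetic_lod(base, list(
    list(kind = "wgd", generation = 10L),
    # delete one member of the first TF pair -> that TF becomes a single
    list(kind = "delete", generation = 20L, gene_ids = tf_ids[1L]),
    list(kind = "flip_bs", generation = 30L, gene_id = tf_ids[2L])),
    end_generation = 100L)
  div <- divergence_stats(lod, 10L, bin_width = 100L)
  fin <- div[div$generation == 100L, ]
  expect_setequal(fin$group, c("ohnolog", "single"))
  expect_equal(fin$n[fin$group == "single"], 1L)
  # the flipped-motif TF is still an intact pair member: its score is 0 on
  # the mutated copy; the single's motif never changed, so its score is 1
  expect_equal(fin$mean_bs_conservation[fin$group == "single"], 1)
  # census bookkeeping agrees
  cen <- ohnolog_census(lod, 10L, 100L)
  tfc <- cen[cen$generation == 100L & cen$category == "tf", ]
  expect_equal(tfc$n_singles, 1)
})
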