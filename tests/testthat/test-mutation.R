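rates0 <- mutation_rates()

test_that("default rates follow the published regime", {
  expect_equal(rates0$dup, 0.024)
  expect_equal(rates0$del, 0.024)
  expect_equal(rates0$trans, 0.048)
  expect_equal(rates0$wgd, 0.003)
  expect_equal(rates0$max_segment_fraction, 0.25)
  # point mutations hit genes 5x more often than large-scale events
  expect_equal(rates0$point_per_gene * rates0$G_ref,
               5 * (rates0$dup + rates0$del + rates0$trans))
  expect_error(mutation_rates(dup = 1.5), "probabilities")
  expect_error(mutation_rates(max_segment_fraction = 1.5),
               "max_segment_fraction")
})

test_that("point mutation hit counts are Bernoulli per gene", {
  g <- random_test_genome(10L)
  # rate 0: identity, no events
  res <- point_mutate(g, mutation_rates(point_per_gene = 0))
  expect_identical(res$genome, g)
  expect_length(res$events, 0L)
  # rate 1 on a single-gene genome: exactly one event per call
  g1 <- pump_enzyme_genome()
  g1$genes <- g1$genes[1]
  set.seed(41)
  for (i in 1:5)
    expect_length(point_mutate(g1, mutation_rates(point_per_gene = 1))$events,
                  1L)
  # Monte-Carlo mean hit count vs binomial expectation (10 genes, p = 0.1)
  set.seed(42)
  trials <- 4000L
  hits <- vapply(seq_len(trials), function(i)
    length(point_mutate(g, mutation_rates(point_per_gene = 0.1))$events),
    numeric(1))
  se <- sqrt(10 * 0.1 * 0.9 / trials)
  expect_lt(abs(mean(hits) - 1), 3 * se)
})

test_that("point mutations touch only the mutable attribute set", {
  set.seed(43)
  g <- random_test_genome(30L)
  res <- point_mutate(g, mutation_rates(point_per_gene = 1))
  attrs <- vapply(res$events, function(e) e$attr, character(1))
  cats <- gene_categories(g)[match(vapply(res$events, function(e) e$gene_id,
                                          integer(1)), gene_ids(g))]
  for (k in seq_along(attrs)) {
    allowed <- switch(cats[[k]],
      tf = c("operator", "basal", "bind_motif", "K_lig", "eff_bound",
             "eff_free", "ligand"),
      enzyme = c("operator", "basal", "k_cat", "K_A", "K_X"),
      pump = c("operator", "basal", "k_cat", "K_Aext", "K_X"))
    expect_true(attrs[[k]] %in% allowed)
  }
  # motif mutations flip exactly one symbol
  mv <- which(attrs %in% c("operator", "bind_motif"))
  for (k in mv) {
    ev <- res$events[[k]]
    expect_identical(sum(as.integer(ev$old) != as.integer(ev$new)), 1L)
  }
})

test_that("segmental operators respect the quarter-genome cap", {
  set.seed(44)
  g <- random_test_genome(20L)
  # G_ref equal to the genome size so every operator fires with certainty
  r <- mutation_rates(dup = 1, del = 1, trans = 1, point_per_gene = 0,
                      wgd = 0, G_ref = 20L)
  kinds <- character(0)
  for (i in 1:300) {
    res <- segmental_mutate(g, r)
    for (e in res$events) {
      kinds <- c(kinds, e$kind)
      expect_gte(e$len, 1L)
      # the cap applies to the genome size at the time of the event
      expect_lte(e$len, ceiling(0.25 * e$size_before))
    }
  }
  expect_setequal(unique(kinds), c("duplication", "deletion", "translocation"))
  # mean deleted fraction per event matches the uniform segment-length draw
  del_fracs <- replicate(2000, {
    res <- segmental_mutate(g, mutation_rates(del = 1, dup = 0, trans = 0,
                                              point_per_gene = 0, wgd = 0,
                                              G_ref = 20L))
    res$events[[1]]$len / 20
  })
  expected <- mean(seq_len(ceiling(0.25 * 20))) / 20
  se <- stats::sd(del_fracs) / sqrt(length(del_fracs))
  expect_lt(abs(mean(del_fracs) - expected), 4 * se)
})

test_that("duplication inserts tandem copies with fresh ids", {
  g <- toy_regulated_genome()
  res <- vcellevo:::apply_duplication(g, start = 2L, len = 2L,
                                      new_ids = c(10L, 11L))
  expect_identical(genome_size(res), 6L)
  expect_identical(gene_ids(res), c(1L, 2L, 3L, 10L, 11L, 4L))
  expect_identical(res$genes[[4]]$category, res$genes[[2]]$category)
  expect_true(res$genes[[4]]$duplicate)
  # full-genome deletion leaves an empty (inviable) genome
  res2 <- vcellevo:::apply_deletion(g, 1L, 4L)
  expect_identical(genome_size(res2), 0L)
})

test_that("whole-genome duplication doubles genes and quadruples edges", {
  set.seed(45)
  g <- retag_ancestry(random_test_genome(7L, L = 4L))
  e0 <- nrow(derive_network(g)$edges)
  res <- whole_genome_duplicate(g)
  w <- res$genome
  expect_identical(genome_size(w), 14L)
  t0 <- table(gene_categories(g))
  t1 <- table(gene_categories(w))
  expect_identical(as.integer(t1[names(t0)]), 2L * as.integer(t0))
  expect_identical(nrow(derive_network(w)$edges), 4L * e0)
  # 7 ohnolog pairs, parameters conserved bit-exactly in both copies
  pairs <- vapply(w$genes, function(x) x$ohnolog, integer(1))
  expect_identical(sort(unique(pairs)), sort(gene_ids(g)))
  expect_true(all(table(pairs) == 2L))
  for (i in seq_len(7)) {
    a <- w$genes[[i]]; b <- w$genes[[i + 7L]]
    a$id <- b$id; a$duplicate <- b$duplicate
    expect_identical(a, b)
  }
  expect_warning(whole_genome_duplicate(genome(list(), L = 4L)), "empty")
})

test_that("event logs replay the child genome exactly", {
  set.seed(46)
  g <- retag_ancestry(random_test_genome(15L))
  r <- mutation_rates(point_per_gene = 0.2, dup = 0.3, del = 0.3,
                      trans = 0.3, wgd = 0.05)
  for (i in 1:300) {
    res <- apply_mutations(g, r, generation = i)
    expect_identical(replay_events(g, res$events), res$genome)
    g <- res$genome
    if (genome_size(g) == 0L || genome_size(g) > 120L)
      g <- retag_ancestry(random_test_genome(15L))
  }
})

test_that("event logs round-trip through the tab-separated format", {
  set.seed(47)
  g <- random_test_genome(12L)
  r <- mutation_rates(point_per_gene = 0.5, dup = 1, del = 1, trans = 1,
                      wgd = 1)
  res <- apply_mutations(g, r, generation = 3L)
  expect_gt(length(res$events), 0L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_event_log(res$events, f, cell_ids = rep(7L, length(res$events)))
  back <- read_event_log(f)
  stripped <- lapply(back, function(e) { attributes(e)$cell_id <- NULL; e })
  # replay from the deserialized log reconstructs the same child
  expect_identical(replay_events(g, stripped), res$genome)
  expect_identical(attr(back[[1]], "cell_id"), 7L)
})

test_that("per-gene rates are constant across genome sizes", {
  set.seed(48)
  r <- mutation_rates()
  count_events <- function(n, trials) {
    g <- random_test_genome(n)
    kinds <- c(point = 0, duplication = 0, deletion = 0,
               translocation = 0, wgd = 0)
    for (i in seq_len(trials)) {
      evs <- apply_mutations(g, r)$events
      for (e in evs) kinds[[e$kind]] <- kinds[[e$kind]] + 1
    }
    kinds / trials
  }
  trials <- 8000L
  c25 <- count_events(25L, trials)
  c50 <- count_events(50L, trials)
  check <- function(obs, p) {
    se <- sqrt(p * (1 - p) / trials)
    expect_lt(abs(obs - p), 3.5 * se + 1e-9)
  }
  check(c25[["duplication"]], r$dup * 25 / 50)
  check(c50[["duplication"]], r$dup)
  check(c25[["deletion"]], r$del * 25 / 50)
  check(c50[["deletion"]], r$del)
  check(c25[["translocation"]], r$trans * 25 / 50)
  check(c50[["translocation"]], r$trans)
  check(c25[["wgd"]], r$wgd)        # WGD is size-independent
  check(c50[["wgd"]], r$wgd)
  # point events: binomial(n, p) mean, doubling with genome size
  seP <- sqrt(25 * r$point_per_gene / trials)
  expect_lt(abs(c25[["point"]] - 25 * r$point_per_gene), 4 * seP)
  expect_lt(abs(c50[["point"]] - 50 * r$point_per_gene), 4 * sqrt(2) * seP)
})

test_that("all-zero rates leave the genome untouched", {
  g <- random_test_genome(10L)
  r <- mutation_rates(point_per_gene = 0, dup = 0, del = 0, trans = 0, wgd = 0)
  res <- apply_mutations(g, r)
  expect_identical(res$genome, g)
  expect_length(res$events, 0L)
})
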