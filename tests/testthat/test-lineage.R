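test_that("the line of descent is the unique parent chain, reconstructed by replay", {
  env <- environment_params()
  cfg <- evolution_config()
  set.seed(61)
  pop <- init_population(6L, function() random_genome(n_range = c(8L, 12L)))
  tr <- run_stage(pop, env, mutation_rates(point_per_gene = 0.3), 3L, cfg)
  lod <- trace_line_of_descent(tr, final_cell = 2L)
  expect_identical(lod$generations, 0:3)
  expect_identical(lod$cell_index[[4L]], 2L)
  # chain genomes equal event-replay reconstruction at every step
  g <- lod$snapshots[["0"]]
  for (s in 1:3) {
    g <- replay_events(g, lod$events[[s]])
    expect_identical(lod_genome_at(lod, s), g)
  }
  # the traced final genome is the final population member
  expect_identical(lod_genome_at(lod, 3L), tr$final_pop$genomes[[2L]])
  # parent chain consistency
  for (s in 3:1)
    expect_identical(lod$cell_index[[s]],
                     tr$parents[[s]][[lod$cell_index[[s + 1L]]]])
})

test_that("WGD lineages are classified by WGD events on the chain", {
  ref <- make_viable_genome()
  lod_w <- make_synthetic_lod(ref, list(list(kind = "wgd", generation = 5L)),
                              end_generation = 10L)
  expect_true(is_wgd_lineage(lod_w))
  expect_identical(lod_w$wgd_generations, 5L)
  expect_false(is_wgd_lineage(lod_w, after = 6L))
  lod_p <- make_synthetic_lod(ref, list(), end_generation = 10L)
  expect_false(is_wgd_lineage(lod_p))
})

test_that("ancestral content fraction counts surviving tag lineages once", {
  ref <- retag_ancestry(random_test_genome(8L))
  expect_equal(ancestral_content_fraction(ref, ref), 1)
  emptyg <- genome(list(), L = ref$L)
  expect_equal(ancestral_content_fraction(ref, emptyg), 0)
  # 4 genes, one deleted, one duplicated: 3/4 regardless of copy choice
  r4 <- retag_ancestry(random_test_genome(4L))
  lod <- make_synthetic_lod(r4, list(
    list(kind = "delete", generation = 1L, gene_ids = gene_ids(r4)[2L]),
    list(kind = "duplicate", generation = 2L, gene_ids = gene_ids(r4)[3L])),
    end_generation = 2L)
  desc <- lod_genome_at(lod, 2L)
  expect_identical(genome_size(desc), 4L)
  expect_equal(ancestral_content_fraction(r4, desc), 0.75)
  # representatives: one surviving copy per conserved tag, any seed
  for (seed in 1:5) {
    set.seed(seed)
    reps <- ancestral_representatives(r4, desc)
    expect_length(reps, 3L)
    expect_equal(ancestral_content_fraction(r4, desc), 0.75)
  }
})

test_that("content conservation is monotonically non-increasing along a lineage", {
  set.seed(62)
  g <- retag_ancestry(random_test_genome(20L))
  r <- mutation_rates(point_per_gene = 0.05, dup = 0.3, del = 0.4, trans = 0.2)
  events <- list()
  cur <- g
  for (gen in 1:60) {
    res <- apply_mutations(cur, r, gen)
    events[[gen]] <- res$events
    cur <- res$genome
    if (genome_size(cur) == 0L) break
  }
  fracs <- numeric(0)
  cur <- g
  for (gen in seq_along(events)) {
    cur <- replay_events(cur, events[[gen]])
    fracs <- c(fracs, ancestral_content_fraction(g, cur))
  }
  expect_true(all(diff(fracs) <= 1e-12))
})

test_that("effective rates average accepted events over generation bins", {
  set.seed(63)
  base <- retag_ancestry(random_test_genome(30L))
  ids <- gene_ids(base)
  lod <- make_synthetic_lod(base, list(
    list(kind = "delete", generation = 10L, gene_ids = ids[5:7]),
    list(kind = "flip_bs", generation = 400L,
         gene_id = ids[which(gene_categories(base) == "tf")[1L]]),
    list(kind = "wgd", generation = 1500L)),
    end_generation = 2000L)
  rb <- effective_rates(lod, bin_width = 1000L)
  expect_identical(nrow(rb), 2L)
  # one deletion of 3 genes from a 30-gene genome in the first 1000-gen bin
  expect_equal(rb$n_deletion[[1L]], 1)
  expect_equal(rb$del_frac_per_event[[1L]], 0.1)
  expect_equal(rb$del_frac_per_generation[[1L]], 1e-4)
  expect_equal(rb$n_point[[1L]], 1)
  expect_equal(rb$n_wgd[[2L]], 1)
  # conservation: per-bin counts sum to the total accepted event count
  expect_equal(sum(rb$n_point + rb$n_duplication + rb$n_deletion +
                   rb$n_translocation + rb$n_wgd),
               sum(lengths(lod$events)))
  # a lineage with zero events has all-zero rates
  lod0 <- make_synthetic_lod(base, list(), end_generation = 1000L)
  rb0 <- effective_rates(lod0, bin_width = 1000L)
  expect_true(all(rb0$n_point == 0 & rb0$n_deletion == 0))
  expect_true(all(rb0$del_frac_per_generation == 0))
  expect_true(is.na(rb0$del_frac_per_event[[1L]]))
})

test_that("rate bins are invariant to within-bin event order", {
  base <- retag_ancestry(random_test_genome(30L))
  ids <- gene_ids(base)
  s1 <- list(list(kind = "delete", generation = 5L, gene_ids = ids[1L]),
             list(kind = "delete", generation = 8L, gene_ids = ids[3L]))
  s2 <- list(list(kind = "delete", generation = 2L, gene_ids = ids[3L]),
             list(kind = "delete", generation = 9L, gene_ids = ids[1L]))
  r1 <- effective_rates(make_synthetic_lod(base, s1, end_generation = 100L),
                        bin_width = 100L)
  r2 <- effective_rates(make_synthetic_lod(base, s2, end_generation = 100L),
                        bin_width = 100L)
  expect_equal(r1$n_deletion, r2$n_deletion)
  expect_equal(r1$del_frac_per_event, r2$del_frac_per_event)
  expect_equal(r1$del_frac_per_generation, r2$del_frac_per_generation)
})

test_that("tagged replay from a reference isolates one-to-one descendants", {
  set.seed(64)
  base <- retag_ancestry(random_test_genome(10L))
  ids <- gene_ids(base)
  lod <- make_synthetic_lod(base, list(
    list(kind = "wgd", generation = 50L),
    list(kind = "delete", generation = 80L, gene_ids = ids[1L])),
    end_generation = 100L)
  tg <- lod_tagged_genomes(lod, 50L, at = c(50L, 100L))
  # reference is the first post-WGD genome: 20 genes, all uniquely tagged
  expect_identical(genome_size(tg$reference), 20L)
  tags <- vapply(tg$reference$genes, function(x) x$ancestry, integer(1))
  expect_false(anyDuplicated(tags) > 0)
  expect_equal(ancestral_content_fraction(tg$reference, tg$genomes[["100"]]),
               19 / 20)
})

test_that("conservation curves aggregate into per-bin run summaries", {
  c1 <- data.frame(generation = c(0L, 100L), fraction = c(1, 0.5))
  c2 <- data.frame(generation = c(0L, 100L), fraction = c(1, 0.9))
  c3 <- data.frame(generation = c(0L, 100L), fraction = c(1, 0.7))
  sm <- summarize_conservation(list(c1, c2, c3))
  expect_equal(sm$mean_fraction, c(1, 0.7))
  expect_equal(sm$median, c(1, 0.7))
  expect_equal(sm$q25, c(1, 0.6))
  expect_equal(sm$n_runs, c(3L, 3L))
  f <- withr::local_tempfile(fileext = ".tsv")
  summarize_conservation(list(c1, c2, c3), f)
  back <- utils::read.delim(f, comment.char = "#")
  expect_equal(back$median, c(1, 0.7))
})
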