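#' Specification of the hand-designed viable genome
#'
#' The fixture genome implements the minimal regulated metabolism: a pump
#' importing resource A, a catabolic enzyme converting A to energy X, a weak
#' anabolic sink, and two sensor TFs closing negative feedback loops —
#' an A-sensing TF that represses the pump when internal A is high, and an
#' X-sensing TF that represses the catabolic enzyme when energy is high.
#' Kinetic presets were chosen so the standard-environment score clears the
#' fixture contract floor of 0.5 (verified in the test suite).
#'
#' @param L,S Motif length and alphabet size.
#' @return A list spec consumed by [make_viable_genome()].
#' @export
viable_genome_spec <- function(L = 12L, S = 2L) {
  # deterministic motif vocabulary: W1 pump operator, W2 catabolic operator,
  # W3 anabolic operator, W4 unbound TF operator
  words <- list(
    W1 = motif(rep(c(0L, 1L), length.out = L), S),
    W2 = motif(rep(c(1L, 0L), length.out = L), S),
    W3 = motif(rep(c(0L, 0L, 1L), length.out = L), S),
    W4 = motif(rep(c(1L, 1L, 0L), length.out = L), S))
  list(L = L, S = S, words = words,
       pump = list(basal = 1.6, k_cat = 3.2, K_Aext = 0.5, K_X = 0.3, cost = 0.5),
       cat_enzyme = list(basal = 0.75, k_cat = 9, K_A = 0.5, K_X = 0.5),
       ana_enzyme = list(basal = 0.7, k_cat = 10, K_A = 1, K_X = 1),
       tf_pump = list(basal = 0.4, ligand = "A", K_lig = 1.0,
                      eff_bound = -2.6, eff_free = 0.5),
       tf_cat = list(basal = 0.4, ligand = "X", K_lig = 1.9,
                     eff_bound = -5.7, eff_free = 0.7),
       wiring = list(tf_pump = "W1", tf_cat = "W2"))
}

#' Build the hand-designed viable genome
#'
#' Deterministic (no randomness): the same spec always yields byte-identical
#' genome files. The wiring plan (which TF binds which operator word) is
#' reproduced exactly by [derive_network()], and the genome's score under
#' the standard environment exceeds 0.5 by construction.
#'
#' @param spec A [viable_genome_spec()].
#' @return A `vc_genome` with ancestry tags set.
#' @export
make_viable_genome <- function(spec = viable_genome_spec()) {
  w <- spec$words
  for (tfname in names(spec$wiring))
    if (!spec$wiring[[tfname]] %in% names(w))
      stop("make_viable_genome: wiring refers to unknown word ",
           spec$wiring[[tfname]], call. = FALSE)
  p <- spec$pump; ce <- spec$cat_enzyme; ae <- spec$ana_enzyme
  t1 <- spec$tf_pump; t2 <- spec$tf_cat
  genes <- list(
    gene_pump(1L, w$W1, p$basal, k_cat = p$k_cat, K_Aext = p$K_Aext,
              K_X = p$K_X, cost = p$cost),
    gene_enzyme(2L, w$W2, ce$basal, reaction = "cat", k_cat = ce$k_cat,
                K_A = ce$K_A, K_X = ce$K_X),
    gene_enzyme(3L, w$W3, ae$basal, reaction = "ana", k_cat = ae$k_cat,
                K_A = ae$K_A, K_X = ae$K_X),
    gene_tf(4L, w$W4, t1$basal, ligand = t1$ligand,
            bind_motif = w[[spec$wiring$tf_pump]], K_lig = t1$K_lig,
            eff_bound = t1$eff_bound, eff_free = t1$eff_free),
    gene_tf(5L, w$W4, t2$basal, ligand = t2$ligand,
            bind_motif = w[[spec$wiring$tf_cat]], K_lig = t2$K_lig,
            eff_bound = t2$eff_bound, eff_free = t2$eff_free))
  retag_ancestry(genome(genes, L = spec$L, S = spec$S))
}

segment_positions <- function(ids, gene_ids) {
  pos <- match(gene_ids, ids)
  if (anyNA(pos))
    stop("make_synthetic_lod: gene ", gene_ids[which(is.na(pos))[1L]],
         " not present", call. = FALSE)
  if (length(pos) > 1L && !all(diff(pos) == 1L))
    stop("make_synthetic_lod: scripted segment must be contiguous",
         call. = FALSE)
  pos
}

script_event <- function(g, item) {
  ids <- gene_ids(g)
  gen <- item$generation %||% NA_integer_
  switch(item$kind,
    wgd = whole_genome_duplicate(g, gen)$events[[1L]],
    delete = {
      pos <- segment_positions(ids, item$gene_ids)
      new_event("deletion", gen, start = pos[[1L]],
                len = length(pos), gene_ids = as.integer(item$gene_ids),
                size_before = length(ids),
                fraction = length(pos) / length(ids))
    },
    duplicate = {
      pos <- segment_positions(ids, item$gene_ids)
      new_event("duplication", gen, start = pos[[1L]], len = length(pos),
                new_ids = g$next_id + seq_along(pos) - 1L,
                gene_ids = as.integer(item$gene_ids),
                size_before = length(ids),
                fraction = length(pos) / length(ids))
    },
    flip_bs = {
      pos <- match(item$gene_id, ids)
      if (is.na(pos)) stop("make_synthetic_lod: gene ", item$gene_id,
                           " not present", call. = FALSE)
      gene <- g$genes[[pos]]
      if (gene$category != "tf")
        stop("make_synthetic_lod: flip_bs target is not a TF", call. = FALSE)
      m <- as.integer(gene$bind_motif)
      m[[1L]] <- (m[[1L]] + 1L) %% g$S
      new_event("point", gen, gene_id = item$gene_id, attr = "bind_motif",
                old = gene$bind_motif, new = motif(m, g$S))
    },
    stop("make_synthetic_lod: unknown scripted kind ", item$kind,
         call. = FALSE))
}

#' Build a synthetic line of descent from a scripted event list
#'
#' Applies a deterministic script of mutation events (each item a list with
#' `generation` and `kind` in `wgd`, `delete`, `duplicate`, `flip_bs`, plus
#' the targeted `gene_ids` / `gene_id`) to a reference genome and packages
#' the result as a `vc_lod`, so conservation curves, rate bins and ohnolog
#' censuses have closed-form expected values.
#'
#' @param reference Founding `vc_genome` (generation 0 of the lineage).
#' @param script List of scripted event items, generations strictly
#'   increasing.
#' @param end_generation Final generation of the lineage (default: last
#'   scripted generation).
#' @param snapshot_stride Generations between stored snapshots.
#' @return A `vc_lod`.
#' @export
make_synthetic_lod <- function(reference, script, end_generation = NULL,
                               snapshot_stride = 100L) {
  gens_scripted <- vapply(script, function(s) as.integer(s$generation), integer(1))
  if (is.unsorted(gens_scripted))
    stop("make_synthetic_lod: script generations must be non-decreasing",
         call. = FALSE)
  if (is.null(end_generation))
    end_generation <- if (length(gens_scripted)) max(gens_scripted) else 0L
  n <- as.integer(end_generation)
  events <- replicate(n, list(), simplify = FALSE)
  g <- reference
  sizes <- matrix(0L, nrow = n + 1L, ncol = 4L)
  snapshots <- list()
  cat_counts <- function(g) {
    tab <- table(factor(gene_categories(g), levels = GENE_CATEGORIES))
    c(genome_size(g), as.integer(tab))
  }
  sizes[1L, ] <- cat_counts(g)
  snapshots[["0"]] <- g
  wgd_gens <- integer(0)
  si <- 1L
  for (s in seq_len(n)) {
    while (si <= length(script) && gens_scripted[[si]] == s) {
      ev <- script_event(g, script[[si]])
      events[[s]] <- c(events[[s]], list(ev))
      g <- replay_events(g, list(ev))
      if (ev$kind == "wgd") wgd_gens <- c(wgd_gens, s)
      si <- si + 1L
    }
    sizes[s + 1L, ] <- cat_counts(g)
    if (s %% snapshot_stride == 0L || s == n)
      snapshots[[as.character(s)]] <- g
  }
  if (si <= length(script))
    stop("make_synthetic_lod: script generations exceed end_generation",
         call. = FALSE)
  structure(list(start_generation = 0L, generations = 0:n,
                 cell_index = rep(NA_integer_, n + 1L), events = events,
                 sizes = data.frame(generation = 0:n, size = sizes[, 1L],
                                    n_tf = sizes[, 2L], n_enzyme = sizes[, 3L],
                                    n_pump = sizes[, 4L]),
                 snapshots = snapshots, wgd_generations = wgd_gens,
                 change_generation = NA_integer_),
            class = "vc_lod")
}
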