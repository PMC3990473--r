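# Shared builders for small deterministic genomes.

std_env <- function(...) environment_params(...)

op <- function(bits, L = 4L) motif(rep_len(bits, L), 2L)

# constitutive pump + catabolic enzyme, no TFs (closed-form-checkable);
# the pump's energy cost exceeds the catabolic yield so X stays bounded
pump_enzyme_genome <- function() {
  genome(list(
    gene_pump(1L, op(c(0, 1)), basal = 0.5, k_cat = 1.5, K_Aext = 0.5,
              K_X = 0.5, cost = 2),
    gene_enzyme(2L, op(c(1, 0)), basal = 0.5, reaction = "cat", k_cat = 1,
                K_A = 0.5, K_X = 0.5)), L = 4L)
}

# one TF regulating two of three genes
toy_regulated_genome <- function() {
  m <- op(c(0, 1, 1, 0))
  other <- op(c(1, 1, 1, 1))
  genome(list(
    gene_tf(1L, other, 0.4, ligand = "A", bind_motif = m, K_lig = 0.5,
            eff_bound = -1, eff_free = 0.5),
    gene_enzyme(2L, m, 0.5, reaction = "cat", k_cat = 2, K_A = 0.5, K_X = 0.5),
    gene_pump(3L, m, 0.5, k_cat = 2, K_Aext = 0.5, K_X = 0.5, cost = 0.5),
    gene_enzyme(4L, other, 0.5, reaction = "ana", k_cat = 1, K_A = 1, K_X = 1)),
    L = 4L)
}

random_test_genome <- function(n = 20L, L = 6L) {
  random_genome(n_range = c(n, n), L = L, n_motif_words = 4L)
}

# post-WGD reference with p ohnolog pairs of one category, retagged
pair_reference <- function(p = 3L, category = "tf") {
  genes <- lapply(seq_len(p), function(i) {
    switch(category,
      tf = gene_tf(i, op(c(0, 1)), 0.5, ligand = "A", bind_motif = op(c(1, 0)),
                   K_lig = 0.5, eff_bound = 1, eff_free = -1),
      enzyme = gene_enzyme(i, op(c(0, 1)), 0.5, reaction = "cat", k_cat = 1,
                           K_A = 0.5, K_X = 0.5),
      pump = gene_pump(i, op(c(0, 1)), 0.5, k_cat = 1, K_Aext = 0.5,
                       K_X = 0.5, cost = 0.5))
  })
  g <- retag_ancestry(genome(genes, L = 4L))
  whole_genome_duplicate(g)$genome |> retag_ancestry_keep_pairs()
}

# retag ancestry but keep the ohnolog pair tags (as lod_tagged_genomes does)
retag_ancestry_keep_pairs <- function(g) {
  pairs <- vapply(g$genes, function(x) x$ohnolog, integer(1))
  g <- retag_ancestry(g)
  for (i in seq_along(g$genes)) g$genes[[i]]$ohnolog <- pairs[[i]]
  g
}

# drop genes by ancestry tag, keeping order (simulated deletions)
drop_tags <- function(g, tags) {
  keep <- vapply(g$genes, function(x) !(x$ancestry %in% tags), logical(1))
  g$genes <- g$genes[keep]
  g
}
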