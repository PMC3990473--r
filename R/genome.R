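#' @useDynLib vcellevo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rbinom rnorm rlnorm setNames wilcox.test median quantile cor
#' @importFrom utils head tail
NULL

# Gene categories recognised throughout the package.
GENE_CATEGORIES <- c("tf", "enzyme", "pump")

#' Create a binding motif
#'
#' Motifs are fixed-length sequences over a small discrete alphabet
#' `{0, ..., S-1}`. Transcription factors carry a binding motif and every
#' promoter carries an operator motif; a TF regulates a gene exactly when the
#' two motifs are identical symbol-by-symbol.
#'
#' @param symbols Integer vector of symbols in `0:(S-1)`.
#' @param S Alphabet size (default 2).
#' @return An integer vector with attribute `S`, class `vc_motif`.
#' @examples
#' motif(c(0, 1, 1, 0))
#' @export
motif <- function(symbols, S = 2L) {
  symbols <- as.integer(symbols)
  S <- as.integer(S)
  if (S < 2L) stop("invalid-motif: alphabet size S must be >= 2", call. = FALSE)
  if (length(symbols) < 1L || anyNA(symbols) || any(symbols < 0L | symbols >= S))
    stop("invalid-motif: symbols must lie in 0:(S-1)", call. = FALSE)
  structure(symbols, S = S, class = "vc_motif")
}

#' @export
print.vc_motif <- function(x, ...) {
  cat("<motif> ", paste(unclass(x), collapse = ""), " (S=", attr(x, "S"), ")\n", sep = "")
  invisible(x)
}

motif_key <- function(m) paste(as.integer(m), collapse = "")

#' Test whether a TF binding motif matches a promoter operator
#'
#' Matching is exact: the two sequences must be identical at every position.
#' There is no mismatch tolerance; regulatory interactions are therefore
#' discrete and can only be rewired by symbol flips, never partially eroded.
#'
#' @param tf_motif,operator Motifs as produced by [motif()].
#' @return `TRUE` or `FALSE`.
#' @export
motif_matches <- function(tf_motif, operator) {
  a <- as.integer(tf_motif); b <- as.integer(operator)
  Sa <- attr(tf_motif, "S") %||% 2L
  Sb <- attr(operator, "S") %||% 2L
  if (length(a) != length(b) || Sa != Sb)
    stop("invalid-motif: motifs differ in length or alphabet", call. = FALSE)
  all(a == b)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

new_gene <- function(id, category, operator, basal,
                     ancestry = NA_integer_, ohnolog = NA_integer_,
                     duplicate = FALSE, payload = list()) {
  stopifnot(category %in% GENE_CATEGORIES)
  if (!is.finite(basal) || basal < 0)
    stop("gene: basal_rate must be >= 0", call. = FALSE)
  structure(
    c(list(id = as.integer(id), category = category, operator = operator,
           basal = as.numeric(basal), ancestry = as.integer(ancestry),
           ohnolog = as.integer(ohnolog), duplicate = isTRUE(duplicate)),
      payload),
    class = "vc_gene")
}

check_pos <- function(x, what) {
  if (!is.numeric(x) || !is.finite(x) || x <= 0)
    stop("gene: ", what, " must be a positive finite number", call. = FALSE)
  as.numeric(x)
}

#' Gene constructors
#'
#' A gene couples a promoter (operator motif plus basal expression rate) to a
#' category-specific payload:
#' * `gene_tf()` — a transcription factor sensing ligand `"A"` (resource) or
#'   `"X"` (energy) with dissociation constant `K_lig`, carrying a binding
#'   motif and signed regulatory strengths for its ligand-bound
#'   (`eff_bound`) and ligand-free (`eff_free`) forms.
#' * `gene_enzyme()` — `reaction = "cat"` converts resource A into energy X;
#'   `reaction = "ana"` consumes A and X in an anabolic reaction (a sink).
#' * `gene_pump()` — imports external A at the expense of `cost` units of X
#'   per imported molecule.
#'
#' @param id Integer gene id, unique within a genome.
#' @param operator Operator motif of the gene's promoter.
#' @param basal Basal expression rate (concentration / time), `>= 0`.
#' @param ligand `"A"` or `"X"`.
#' @param bind_motif Binding motif of the TF.
#' @param K_lig,K_A,K_X,K_Aext Half-saturation / dissociation constants, `> 0`.
#' @param eff_bound,eff_free Signed regulation strengths (dimensionless).
#' @param reaction `"cat"` (A -> X) or `"ana"` (A + X -> product).
#' @param k_cat Turnover rate (1 / time), `> 0`.
#' @param cost Energy cost of import (X per A, dimensionless), `> 0`.
#' @param ancestry,ohnolog Integer lineage tags (`NA` when untagged).
#' @param duplicate Logical; set on copies created by duplication events.
#' @return A `vc_gene` object.
#' @name gene-constructors
NULL

#' @rdname gene-constructors
#' @export
gene_tf <- function(id, operator, basal, ligand, bind_motif, K_lig,
                    eff_bound, eff_free,
                    ancestry = NA_integer_, ohnolog = NA_integer_,
                    duplicate = FALSE) {
  if (!ligand %in% c("A", "X")) stop("gene: TF ligand must be 'A' or 'X'", call. = FALSE)
  new_gene(id, "tf", operator, basal, ancestry, ohnolog, duplicate,
           list(ligand = ligand, bind_motif = bind_motif,
                K_lig = check_pos(K_lig, "K_lig"),
                eff_bound = as.numeric(eff_bound),
                eff_free = as.numeric(eff_free)))
}

#' @rdname gene-constructors
#' @export
gene_enzyme <- function(id, operator, basal, reaction, k_cat, K_A, K_X,
                        ancestry = NA_integer_, ohnolog = NA_integer_,
                        duplicate = FALSE) {
  if (!reaction %in% c("cat", "ana"))
    stop("gene: enzyme reaction must be 'cat' or 'ana'", call. = FALSE)
  new_gene(id, "enzyme", operator, basal, ancestry, ohnolog, duplicate,
           list(reaction = reaction, k_cat = check_pos(k_cat, "k_cat"),
                K_A = check_pos(K_A, "K_A"), K_X = check_pos(K_X, "K_X")))
}

#' @rdname gene-constructors
#' @export
gene_pump <- function(id, operator, basal, k_cat, K_Aext, K_X, cost,
                      ancestry = NA_integer_, ohnolog = NA_integer_,
                      duplicate = FALSE) {
  new_gene(id, "pump", operator, basal, ancestry, ohnolog, duplicate,
           list(k_cat = check_pos(k_cat, "k_cat"),
                K_Aext = check_pos(K_Aext, "K_Aext"),
                K_X = check_pos(K_X, "K_X"), cost = check_pos(cost, "cost")))
}

#' Create a circular genome
#'
#' The genome is an ordered, circular sequence of genes: the successor of the
#' last gene is the first. Position on the circle matters for segmental
#' mutations (duplication, deletion, translocation of contiguous stretches).
#'
#' @param genes List of `vc_gene` objects with unique ids.
#' @param L Motif length shared by all operators and binding motifs.
#' @param S Motif alphabet size.
#' @param next_id Next fresh gene id to hand out (defaults to max id + 1).
#' @return A `vc_genome` object.
#' @export
genome <- function(genes, L = 12L, S = 2L, next_id = NULL) {
  ids <- vapply(genes, function(g) g$id, integer(1))
  if (anyDuplicated(ids)) stop("genome: gene ids must be unique", call. = FALSE)
  for (g in genes) {
    if (length(g$operator) != L)
      stop("genome: operator length must equal L", call. = FALSE)
    if (g$category == "tf" && length(g$bind_motif) != L)
      stop("genome: binding motif length must equal L", call. = FALSE)
  }
  if (is.null(next_id)) next_id <- if (length(ids)) max(ids) + 1L else 1L
  structure(list(genes = genes, L = as.integer(L), S = as.integer(S),
                 next_id = as.integer(next_id)),
            class = "vc_genome")
}

#' @export
print.vc_genome <- function(x, ...) {
  tab <- table(factor(gene_categories(x), levels = GENE_CATEGORIES))
  cat("<vc_genome> ", genome_size(x), " genes (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "), L=", x$L, " S=", x$S, "\n", sep = "")
  invisible(x)
}

#' @export
length.vc_genome <- function(x) length(x$genes)

#' Basic genome accessors
#'
#' @param g A `vc_genome`.
#' @return `genome_size()` the number of genes; `gene_ids()` the integer ids
#'   in circular order; `gene_categories()` a character vector of categories.
#' @export
genome_size <- function(g) length(g$genes)

#' @rdname genome_size
#' @export
gene_ids <- function(g) vapply(g$genes, function(x) x$id, integer(1))

#' @rdname genome_size
#' @export
gene_categories <- function(g) vapply(g$genes, function(x) x$category, character(1))

genome_gene <- function(g, id) {
  idx <- match(id, gene_ids(g))
  if (is.na(idx)) stop("genome: unknown gene id ", id, call. = FALSE)
  g$genes[[idx]]
}

#' Assign fresh ancestry tags to every gene
#'
#' Establishes a genome as an ancestral reference point: each gene receives a
#' unique ancestry tag equal to its own id and its duplicate flag is cleared.
#' Downstream copies created by duplication inherit the tag, so the surviving
#' carriers of a tag are exactly the one-to-one descendants of that reference
#' gene (plus later duplicates, which analyses count only once).
#'
#' @param g A `vc_genome`.
#' @return The retagged genome.
#' @export
retag_ancestry <- function(g) {
  g$genes <- lapply(g$genes, function(gene) {
    gene$ancestry <- gene$id
    gene$duplicate <- FALSE
    gene
  })
  g
}

#' Derive the gene regulatory network of a genome
#'
#' Edges are purely motif-determined: TF `t` regulates gene `j` (including
#' itself and other TFs) exactly when `t`'s binding motif is identical to
#' `j`'s operator. The regulatory strengths on an edge are the TF's
#' ligand-bound and ligand-free effects.
#'
#' @param g A `vc_genome`.
#' @return A `vc_network`: list with `edges` (data.frame `tf_id`, `target_id`,
#'   `eff_bound`, `eff_free`), `outdegree` (named integer over all TF ids) and
#'   `tf_ids`.
#' @export
derive_network <- function(g) {
  ids <- gene_ids(g)
  cats <- gene_categories(g)
  ops <- vapply(g$genes, function(x) motif_key(x$operator), character(1))
  tf_idx <- which(cats == "tf")
  tf_ids <- ids[tf_idx]
  edges <- list()
  if (length(tf_idx)) {
    motifs <- vapply(g$genes[tf_idx], function(x) motif_key(x$bind_motif), character(1))
    for (k in seq_along(tf_idx)) {
      hit <- which(ops == motifs[[k]])
      if (length(hit)) {
        tf <- g$genes[[tf_idx[k]]]
        edges[[length(edges) + 1L]] <- data.frame(
          tf_id = rep.int(tf$id, length(hit)), target_id = ids[hit],
          eff_bound = tf$eff_bound, eff_free = tf$eff_free)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(tf_id = integer(), target_id = integer(),
               eff_bound = numeric(), eff_free = numeric())
  outd <- setNames(integer(length(tf_ids)), as.character(tf_ids))
  if (nrow(edges)) {
    tt <- table(factor(as.character(edges$tf_id), levels = as.character(tf_ids)))
    outd[names(tt)] <- as.integer(tt)
  }
  structure(list(edges = edges, outdegree = outd, tf_ids = tf_ids),
            class = "vc_network")
}

#' @export
print.vc_network <- function(x, ...) {
  cat("<vc_network> ", nrow(x$edges), " edges, ", length(x$tf_ids), " TFs\n", sep = "")
  invisible(x)
}

#' Outdegree of a transcription factor
#'
#' Number of distinct target genes whose operator the TF's binding motif
#' matches exactly.
#'
#' @param network A `vc_network` from [derive_network()].
#' @param tf_id Gene id of a TF present in the network.
#' @return Integer count of targets.
#' @export
outdegree <- function(network, tf_id) {
  key <- as.character(tf_id)
  if (!key %in% names(network$outdegree))
    stop("outdegree: id ", tf_id, " is not a TF in this network", call. = FALSE)
  unname(network$outdegree[[key]])
}
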