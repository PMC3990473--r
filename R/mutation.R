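#' Mutation rates
#'
#' Default rates follow the published regime: segmental duplications and
#' deletions each occur at probability 0.024 per cell per generation,
#' translocations (excision + reinsertion) at 0.048, and whole-genome
#' duplication at 0.003 (about a factor 10 below the summed small-scale
#' rates, hitting ~0.3% of the population per generation). Rates are
#' interpreted at a reference genome size `G_ref` and scale linearly with
#' gene count for point and segmental events, so the per-gene rate is
#' constant across genome sizes; WGD is per cell and size-independent.
#' Point mutations hit genes 5 times more often than large-scale events:
#' `point_per_gene = 5 * (dup + del + trans) / G_ref = 0.0096` by default.
#'
#' @param point_per_gene Probability per gene per generation of a point
#'   mutation.
#' @param dup,del,trans Segmental event probabilities per cell per generation
#'   at genome size `G_ref`.
#' @param wgd Whole-genome duplication probability per cell per generation.
#' @param max_segment_fraction Maximum segment length as a fraction of the
#'   genome (cap of the uniform segment-length draw).
#' @param G_ref Reference genome size for rate scaling.
#' @param sigma_param Log-normal sd of multiplicative steps on positive
#'   kinetic parameters.
#' @param sigma_effect Gaussian sd of additive steps on TF regulation
#'   strengths (sign changes possible).
#' @return A `vc_rates` list.
#' @export
mutation_rates <- function(point_per_gene = 0.0096, dup = 0.024, del = 0.024,
                           trans = 0.048, wgd = 0.003,
                           max_segment_fraction = 0.25, G_ref = 50L,
                           sigma_param = 1.6, sigma_effect = 1.6) {
  probs <- c(point_per_gene, dup, del, trans, wgd)
  if (any(probs < 0 | probs > 1))
    stop("mutation_rates: probabilities must lie in [0, 1]", call. = FALSE)
  if (max_segment_fraction <= 0 || max_segment_fraction > 1)
    stop("mutation_rates: max_segment_fraction must lie in (0, 1]", call. = FALSE)
  structure(list(point_per_gene = point_per_gene, dup = dup, del = del,
                 trans = trans, wgd = wgd,
                 max_segment_fraction = max_segment_fraction,
                 G_ref = as.integer(G_ref), sigma_param = sigma_param,
                 sigma_effect = sigma_effect),
            class = "vc_rates")
}

mutable_attrs <- function(category) {
  switch(category,
    tf = c("operator", "basal", "bind_motif", "K_lig", "eff_bound",
           "eff_free", "ligand"),
    enzyme = c("operator", "basal", "k_cat", "K_A", "K_X"),
    pump = c("operator", "basal", "k_cat", "K_Aext", "K_X"))
}

new_event <- function(kind, generation = NA_integer_, ...) {
  structure(list(kind = kind, generation = generation, ...),
            class = "vc_event")
}

#' @export
print.vc_event <- function(x, ...) {
  extra <- switch(x$kind,
    point = sprintf("gene %d attr %s", x$gene_id, x$attr),
    duplication = sprintf("start %d len %d", x$start, x$len),
    deletion = sprintf("start %d len %d of %d", x$start, x$len, x$size_before),
    translocation = sprintf("start %d len %d -> %d", x$start, x$len, x$insert_at),
    wgd = sprintf("%d pairs", length(x$orig_ids)), "")
  cat("<event ", x$kind, "> ", extra, "\n", sep = "")
  invisible(x)
}

flip_motif <- function(m, S) {
  pos <- sample.int(length(m), 1L)
  old <- m[[pos]]
  alt <- setdiff(0:(S - 1L), old)
  m[[pos]] <- if (length(alt) == 1L) alt else sample(alt, 1L)
  m
}

mutate_attr <- function(gene, attr, rates, S) {
  old <- gene[[attr]]
  new <- switch(attr,
    operator = ,
    bind_motif = motif(flip_motif(as.integer(old), S), S),
    ligand = if (old == "A") "X" else "A",
    eff_bound = ,
    eff_free = old + rnorm(1L, 0, rates$sigma_effect),
    # positive kinetic parameters and the basal rate take scale-free
    # multiplicative log-normal steps
    old * rlnorm(1L, 0, rates$sigma_param))
  gene[[attr]] <- new
  list(gene = gene, old = old, new = new)
}

#' Point mutations
#'
#' Every gene is hit independently with probability `point_per_gene`. A hit
#' picks one mutable attribute of the gene's category uniformly: positive
#' kinetic parameters and the basal rate are multiplied by a log-normal
#' factor, operator and TF binding motifs get a single random symbol flip,
#' a TF's ligand is toggled between A and X, and TF regulation strengths are
#' perturbed additively (allowing sign changes).
#'
#' @param g A `vc_genome`.
#' @param rates A `vc_rates`.
#' @param generation Generation stamp recorded in the events.
#' @return List with the mutated `genome` and the list of `events`.
#' @export
point_mutate <- function(g, rates, generation = NA_integer_) {
  n <- genome_size(g)
  events <- list()
  if (n == 0L || rates$point_per_gene == 0) return(list(genome = g, events = events))
  hits <- which(runif(n) < rates$point_per_gene)
  for (i in hits) {
    gene <- g$genes[[i]]
    attr <- sample(mutable_attrs(gene$category), 1L)
    res <- mutate_attr(gene, attr, rates, g$S)
    g$genes[[i]] <- res$gene
    events[[length(events) + 1L]] <-
      new_event("point", generation, gene_id = gene$id, attr = attr,
                old = res$old, new = res$new)
  }
  list(genome = g, events = events)
}

circular_segment <- function(n, start, len) ((start - 1L + seq_len(len) - 1L) %% n) + 1L

insert_genes <- function(genes, block, after) {
  # insert `block` after position `after` (0 = before the first gene)
  append(genes, block, after = after)
}

apply_duplication <- function(g, start, len, new_ids) {
  n <- genome_size(g)
  idx <- circular_segment(n, start, len)
  block <- lapply(seq_along(idx), function(k) {
    cp <- g$genes[[idx[k]]]
    cp$id <- new_ids[[k]]
    cp$duplicate <- TRUE
    cp
  })
  g$genes <- insert_genes(g$genes, block, after = idx[len])
  g$next_id <- max(g$next_id, max(new_ids) + 1L)
  g
}

apply_deletion <- function(g, start, len) {
  idx <- circular_segment(genome_size(g), start, len)
  g$genes <- g$genes[-idx]
  g
}

apply_translocation <- function(g, start, len, insert_at) {
  idx <- circular_segment(genome_size(g), start, len)
  block <- g$genes[idx]
  rest <- g$genes[-idx]
  g$genes <- insert_genes(rest, block, after = insert_at)
  g
}

#' Segmental mutations: duplication, deletion, translocation
#'
#' Each operator independently fires with probability `rate * n / G_ref`
#' (capped at 1), so per-gene rates stay constant across genome sizes. A
#' firing event picks a contiguous circular segment with uniform start and
#' uniform length in `1:ceiling(max_segment_fraction * n)`. Duplications
#' insert the copies in tandem after the segment (copies receive fresh ids,
#' inherit ancestry and ohnolog tags and are flagged as duplicates);
#' deletions remove the segment (deleting the entire genome leaves an empty,
#' inviable genome); translocations excise the segment and reinsert it at a
#' uniform random position.
#'
#' @inheritParams point_mutate
#' @return List with the mutated `genome` and the list of `events`.
#' @export
segmental_mutate <- function(g, rates, generation = NA_integer_) {
  events <- list()
  for (kind in c("duplication", "deletion", "translocation")) {
    n <- genome_size(g)
    if (n == 0L) break
    rate <- switch(kind, duplication = rates$dup, deletion = rates$del,
                   translocation = rates$trans)
    p <- min(1, rate * n / rates$G_ref)
    if (runif(1L) >= p) next
    len_max <- max(1L, ceiling(rates$max_segment_fraction * n))
    len <- sample.int(len_max, 1L)
    start <- sample.int(n, 1L)
    if (kind == "duplication") {
      new_ids <- g$next_id + seq_len(len) - 1L
      ev <- new_event("duplication", generation, start = start, len = len,
                      new_ids = new_ids,
                      gene_ids = gene_ids(g)[circular_segment(n, start, len)],
                      size_before = n, fraction = len / n)
      g <- apply_duplication(g, start, len, new_ids)
    } else if (kind == "deletion") {
      ev <- new_event("deletion", generation, start = start, len = len,
                      gene_ids = gene_ids(g)[circular_segment(n, start, len)],
                      size_before = n, fraction = len / n)
      g <- apply_deletion(g, start, len)
    } else {
      insert_at <- sample.int(n - len + 1L, 1L) - 1L
      ev <- new_event("translocation", generation, start = start, len = len,
                      insert_at = insert_at,
                      gene_ids = gene_ids(g)[circular_segment(n, start, len)],
                      size_before = n, fraction = len / n)
      g <- apply_translocation(g, start, len, insert_at)
    }
    events[[length(events) + 1L]] <- ev
  }
  list(genome = g, events = events)
}

apply_wgd <- function(g, orig_ids, new_ids) {
  n <- genome_size(g)
  stopifnot(length(orig_ids) == n)
  copies <- vector("list", n)
  for (i in seq_len(n)) {
    gn <- g$genes[[i]]
    gn$ohnolog <- orig_ids[[i]]      # pair tag shared by both members
    g$genes[[i]] <- gn
    cp <- gn
    cp$id <- new_ids[[i]]
    cp$duplicate <- TRUE
    copies[[i]] <- cp
  }
  g$genes <- c(g$genes, copies)
  g$next_id <- max(g$next_id, max(new_ids) + 1L)
  g
}

#' Whole-genome duplication
#'
#' Every gene is copied; the duplicate block is appended preserving circular
#' order, so the new genome has exactly `2n` genes. Each ancestral gene and
#' its copy share a fresh ohnolog pair tag (the ancestral gene's id), and
#' all gene parameters are conserved bit-exactly in both copies. On an empty
#' genome this is a no-op with a warning event.
#'
#' @param g A `vc_genome`.
#' @param generation Generation stamp.
#' @return List with the duplicated `genome` and the single `event`.
#' @export
whole_genome_duplicate <- function(g, generation = NA_integer_) {
  n <- genome_size(g)
  if (n == 0L) {
    warning("whole_genome_duplicate: empty genome, no-op", call. = FALSE)
    return(list(genome = g,
                events = list(new_event("wgd_noop", generation))))
  }
  orig_ids <- gene_ids(g)
  new_ids <- g$next_id + seq_len(n) - 1L
  ev <- new_event("wgd", generation, orig_ids = orig_ids, new_ids = new_ids,
                  size_before = n, fraction = 1)
  list(genome = apply_wgd(g, orig_ids, new_ids), events = list(ev))
}

#' Apply one generation's worth of mutations
#'
#' Composition order within a generation: the WGD decision first (Bernoulli
#' with the per-cell, size-independent WGD probability), then the segmental
#' operators, then point mutations. All events carry the generation stamp
#' and are exactly replayable with [replay_events()].
#'
#' @inheritParams point_mutate
#' @return List with the mutated `genome` and the ordered list of `events`.
#' @export
apply_mutations <- function(g, rates, generation = NA_integer_) {
  events <- list()
  if (genome_size(g) > 0L && rates$wgd > 0 && runif(1L) < rates$wgd) {
    res <- whole_genome_duplicate(g, generation)
    g <- res$genome
    events <- c(events, res$events)
  }
  res <- segmental_mutate(g, rates, generation)
  g <- res$genome
  events <- c(events, res$events)
  res <- point_mutate(g, rates, generation)
  g <- res$genome
  events <- c(events, res$events)
  list(genome = g, events = events)
}

#' Deterministically replay a mutation event log
#'
#' Reconstructs a child genome from its parent and the ordered event list,
#' without any randomness: all stochastic choices (segment bounds, new gene
#' ids, new parameter values) were recorded in the events when they first
#' occurred. `replay(parent, events)` is the definition of the parent-child
#' relationship used by the line-of-descent machinery.
#'
#' @param g The parent `vc_genome`.
#' @param events Ordered list of `vc_event`s.
#' @return The child `vc_genome`.
#' @export
replay_events <- function(g, events) {
  for (ev in events) {
    g <- switch(ev$kind,
      point = {
        idx <- match(ev$gene_id, gene_ids(g))
        if (is.na(idx)) stop("replay: gene ", ev$gene_id, " not found", call. = FALSE)
        g$genes[[idx]][[ev$attr]] <- ev$new
        g
      },
      duplication = apply_duplication(g, ev$start, ev$len, ev$new_ids),
      deletion = apply_deletion(g, ev$start, ev$len),
      translocation = apply_translocation(g, ev$start, ev$len, ev$insert_at),
      wgd = apply_wgd(g, ev$orig_ids, ev$new_ids),
      wgd_noop = g,
      stop("replay: unknown event kind ", ev$kind, call. = FALSE))
  }
  g
}
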