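# sample() treats a length-1 numeric x as 1:x; always sample indices instead
sample_vec <- function(x, size, prob = NULL) x[sample.int(length(x), size, prob = prob)]

ref_tag_table <- function(reference) {
  data.frame(
    tag = vapply(reference$genes, function(g) g$ancestry, integer(1)),
    pair = vapply(reference$genes, function(g) g$ohnolog, integer(1)),
    category = vapply(reference$genes, function(g) g$category, character(1)))
}

census_from_tags <- function(ref_tab, alive_tags) {
  ref_tab$alive <- ref_tab$tag %in% alive_tags
  pair_ok <- tapply(ref_tab$alive, ref_tab$pair, all)
  ref_tab$pair_intact <- ref_tab$alive & unname(pair_ok[as.character(ref_tab$pair)])
  rows <- lapply(GENE_CATEGORIES, function(cat) {
    sub <- ref_tab[ref_tab$category == cat, ]
    conserved <- sum(sub$alive)
    in_pairs <- sum(sub$pair_intact)
    data.frame(category = cat, n_conserved = conserved,
               n_in_intact_pairs = in_pairs, n_singles = conserved - in_pairs,
               retention_fraction = if (conserved > 0) in_pairs / conserved
                                    else NA_real_)
  })
  do.call(rbind, rows)
}

#' Classify conserved WGD genes into ohnologs and singles
#'
#' The reference is the first post-WGD genome: every gene carries a unique
#' ancestry tag and an ohnolog tag shared with its duplication partner. In
#' the descendant, a reference gene counts as conserved when at least one
#' carrier of its tag survives (duplicates that arose after the reference
#' carry reference tags and are therefore counted at most once, never as new
#' content). A pair is intact when both members are conserved; conserved
#' genes whose partner died are singles. The retention fraction per category
#' is genes in intact pairs divided by all conserved WGD genes, reported as
#' `NA` when no WGD gene of that category survives.
#'
#' @param wgd_reference The first post-WGD `vc_genome`, retagged (see
#'   [lod_tagged_genomes()]).
#' @param descendant A descendant `vc_genome` with propagated tags.
#' @return data.frame with one row per gene category: `n_conserved`,
#'   `n_in_intact_pairs`, `n_singles`, `retention_fraction`.
#' @export
classify_ohnologs <- function(wgd_reference, descendant) {
  ref_tab <- ref_tag_table(wgd_reference)
  if (anyNA(ref_tab$pair))
    stop("classify_ohnologs: reference genes lack ohnolog tags", call. = FALSE)
  desc_tags <- vapply(descendant$genes, function(g) g$ancestry, integer(1))
  if (length(desc_tags) && all(is.na(desc_tags)))
    stop("classify_ohnologs: descendant lacks ancestry tags", call. = FALSE)
  census_from_tags(ref_tab, desc_tags[!is.na(desc_tags)])
}

#' Ohnolog census of a WGD lineage in generation bins
#'
#' @param lod A `vc_lod` whose chain contains a WGD.
#' @param wgd_generation Generation of the first post-WGD genome (defaults
#'   to the first WGD on the lineage).
#' @param bin_width Census interval in generations.
#' @return data.frame of per-category censuses with a `generation` column.
#' @export
ohnolog_census <- function(lod, wgd_generation = NULL, bin_width = 1000L) {
  if (is.null(wgd_generation)) {
    if (!length(lod$wgd_generations))
      stop("ohnolog_census: lineage has no WGD", call. = FALSE)
    wgd_generation <- lod$wgd_generations[[1L]]
  }
  last <- max(lod$generations)
  at <- unique(c(seq(wgd_generation, last, by = bin_width), last))
  tg <- lod_tagged_genomes(lod, wgd_generation, at = at)
  out <- lapply(names(tg$genomes), function(gen) {
    cbind(generation = as.integer(gen),
          classify_ohnologs(tg$reference, tg$genomes[[gen]]))
  })
  do.call(rbind, out)
}

#' Per-bin losses of ancestral WGD genes along a lineage
#'
#' Counts, per census interval and per gene category, how many reference
#' tags went extinct in that interval. These observed loss counts drive the
#' random-deletion null models.
#'
#' @inheritParams ohnolog_census
#' @return data.frame with `generation` (end of interval), `category`,
#'   `count`.
#' @export
ancestral_losses <- function(lod, wgd_generation = NULL, bin_width = 1000L) {
  if (is.null(wgd_generation)) wgd_generation <- lod$wgd_generations[[1L]]
  last <- max(lod$generations)
  at <- unique(c(seq(wgd_generation, last, by = bin_width), last))
  tg <- lod_tagged_genomes(lod, wgd_generation, at = at)
  ref_tab <- ref_tag_table(tg$reference)
  alive_prev <- ref_tab$tag
  out <- list()
  for (gen in names(tg$genomes)[-1L]) {
    tags <- vapply(tg$genomes[[gen]]$genes, function(g) g$ancestry, integer(1))
    alive_now <- intersect(alive_prev, tags)
    lost <- setdiff(alive_prev, alive_now)
    cats <- ref_tab$category[match(lost, ref_tab$tag)]
    for (cat in GENE_CATEGORIES)
      out[[length(out) + 1L]] <- data.frame(
        generation = as.integer(gen), category = cat,
        count = sum(cats == cat))
    alive_prev <- alive_now
  }
  do.call(rbind, out)
}

#' Connectivity binning of ancestral TFs
#'
#' Assigns the reference TFs to bins of relative ancestral outdegree
#' (outdegree divided by the mean outdegree of all ancestral TFs), using
#' quantile breaks so bins are evenly populated.
#'
#' @param reference The retagged post-WGD reference `vc_genome`.
#' @param n_bins Number of connectivity bins (default quintiles).
#' @return List with `tags` (TF ancestry tags), `rel_outdegree`, `bin`
#'   (integer bin per TF) and `outdegree` (named by tag).
#' @export
connectivity_bins <- function(reference, n_bins = 5L) {
  net <- derive_network(reference)
  tf_idx <- which(gene_categories(reference) == "tf")
  tags <- vapply(reference$genes[tf_idx], function(g) g$ancestry, integer(1))
  ids <- gene_ids(reference)[tf_idx]
  outd <- vapply(ids, function(id) outdegree(net, id), integer(1))
  rel <- if (mean(outd) > 0) outd / mean(outd) else rep(0, length(outd))
  breaks <- unique(quantile(rel, probs = seq(0, 1, length.out = n_bins + 1L)))
  bin <- if (length(breaks) > 1L)
    as.integer(cut(rel, breaks, include.lowest = TRUE)) else rep(1L, length(rel))
  list(tags = tags, rel_outdegree = rel, bin = bin,
       outdegree = setNames(outd, as.character(tags)))
}

#' Per-connectivity-bin deletion likelihoods from an evolutionary run
#'
#' For each census interval, estimates the per-capita probability that a TF
#' in each connectivity bin was lost, from the matched evolutionary line of
#' descent. These likelihoods drive the connectivity-biased null model.
#'
#' @inheritParams ohnolog_census
#' @param n_bins Number of connectivity bins.
#' @return List with `bins` (from [connectivity_bins()]) and `profile`
#'   (matrix intervals x bins of per-capita loss probabilities).
#' @export
connectivity_loss_profile <- function(lod, wgd_generation = NULL,
                                      bin_width = 1000L, n_bins = 5L) {
  if (is.null(wgd_generation)) wgd_generation <- lod$wgd_generations[[1L]]
  last <- max(lod$generations)
  at <- unique(c(seq(wgd_generation, last, by = bin_width), last))
  tg <- lod_tagged_genomes(lod, wgd_generation, at = at)
  cb <- connectivity_bins(tg$reference, n_bins)
  n_int <- length(tg$genomes) - 1L
  profile <- matrix(0, nrow = max(0L, n_int), ncol = max(cb$bin))
  alive_prev <- cb$tags
  for (k in seq_len(n_int)) {
    tags <- vapply(tg$genomes[[k + 1L]]$genes, function(g) g$ancestry, integer(1))
    alive_now <- intersect(alive_prev, tags)
    lost <- setdiff(alive_prev, alive_now)
    for (b in seq_len(ncol(profile))) {
      members <- cb$tags[cb$bin == b]
      n_alive <- sum(members %in% alive_prev)
      profile[k, b] <- if (n_alive > 0) sum(lost %in% members) / n_alive else 0
    }
    alive_prev <- alive_now
  }
  list(bins = cb, profile = profile)
}

#' Random-deletion null expectation for ohnolog retention
#'
#' Replays the observed per-interval, per-category loss counts on the
#' post-WGD reference genome without selection: in `uniform` mode every
#' surviving gene of the category is equally likely to be deleted; in
#' `connectivity` mode TF deletion probabilities are proportional to the
#' per-capita loss likelihood of the TF's ancestral-outdegree bin in that
#' interval (other categories stay uniform). The expected census is averaged
#' over replicates.
#'
#' @param wgd_reference The retagged post-WGD reference `vc_genome`.
#' @param losses data.frame from [ancestral_losses()] (`generation`,
#'   `category`, `count`), interval order preserved.
#' @param mode `"uniform"` or `"connectivity"`.
#' @param n_replicates Number of null replicates (default 100).
#' @param conn A [connectivity_loss_profile()] result (required for
#'   connectivity mode).
#' @return data.frame per interval end and category: expected
#'   `retention_fraction` (`null_mean`), its sd over replicates and the mean
#'   conserved counts.
#' @export
random_deletion_null <- function(wgd_reference, losses,
                                 mode = c("uniform", "connectivity"),
                                 n_replicates = 100L, conn = NULL) {
  mode <- match.arg(mode)
  if (mode == "connectivity" && is.null(conn))
    stop("random_deletion_null: connectivity mode needs a loss profile",
         call. = FALSE)
  ref_tab <- ref_tag_table(wgd_reference)
  n_genes <- nrow(ref_tab)
  # index of the ohnolog partner of each gene (pairs have exactly 2 members)
  partner <- rep(NA_integer_, n_genes)
  for (pr in split(seq_len(n_genes), ref_tab$pair)) {
    if (length(pr) == 2L) { partner[pr[1L]] <- pr[2L]; partner[pr[2L]] <- pr[1L] }
  }
  cat_idx <- lapply(GENE_CATEGORIES, function(cat)
    which(ref_tab$category == cat))
  names(cat_idx) <- GENE_CATEGORIES
  gens <- unique(losses$generation)
  n_bins <- length(gens)
  counts <- array(0L, dim = c(n_bins, 3L),
                  dimnames = list(NULL, GENE_CATEGORIES))
  for (k in seq_len(n_bins)) for (cat in GENE_CATEGORIES) {
    cnt <- losses$count[losses$generation == gens[[k]] &
                        losses$category == cat]
    if (length(cnt)) counts[k, cat] <- as.integer(cnt[[1L]])
  }
  frac_sum <- frac_sq <- frac_n <- cons_sum <- array(0, dim = c(n_bins, 3L))
  for (r in seq_len(n_replicates)) {
    alive <- rep(TRUE, n_genes)
    for (k in seq_len(n_bins)) {
      for (cat in GENE_CATEGORIES) {
        cnt <- counts[k, cat]
        if (cnt == 0L) next
        pool <- cat_idx[[cat]][alive[cat_idx[[cat]]]]
        if (cnt > length(pool))
          stop("infeasible-spec: more deletions than surviving genes",
               call. = FALSE)
        if (mode == "connectivity" && cat == "tf") {
          w <- conn$profile[min(k, nrow(conn$profile)),
                            conn$bins$bin[match(ref_tab$tag[pool],
                                                conn$bins$tags)]]
          if (all(w == 0)) w <- rep(1, length(pool))
          kill <- sample_vec(pool, cnt, prob = w)
        } else {
          kill <- sample_vec(pool, cnt)
        }
        alive[kill] <- FALSE
      }
      in_pair <- alive & !is.na(partner) & alive[ifelse(is.na(partner), 1L,
                                                        partner)]
      for (ci in seq_along(GENE_CATEGORIES)) {
        idx <- cat_idx[[ci]]
        conserved <- sum(alive[idx])
        cons_sum[k, ci] <- cons_sum[k, ci] + conserved
        if (conserved > 0L) {
          fr <- sum(in_pair[idx]) / conserved
          frac_sum[k, ci] <- frac_sum[k, ci] + fr
          frac_sq[k, ci] <- frac_sq[k, ci] + fr * fr
          frac_n[k, ci] <- frac_n[k, ci] + 1L
        }
      }
    }
  }
  out <- expand.grid(category = GENE_CATEGORIES, generation = gens,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("generation", "category")]
  nm <- sd <- cons <- numeric(nrow(out))
  for (row in seq_len(nrow(out))) {
    k <- match(out$generation[[row]], gens)
    ci <- match(out$category[[row]], GENE_CATEGORIES)
    nn <- frac_n[k, ci]
    nm[[row]] <- if (nn > 0) frac_sum[k, ci] / nn else NA_real_
    sd[[row]] <- if (nn > 1)
      sqrt(pmax(0, (frac_sq[k, ci] - frac_sum[k, ci]^2 / nn) / (nn - 1)))
      else NA_real_
    cons[[row]] <- cons_sum[k, ci] / n_replicates
  }
  out$null_mean <- nm
  out$null_sd <- sd
  out$null_conserved <- cons
  out$n_replicates <- n_replicates
  rownames(out) <- NULL
  out
}

#' Binding-site conservation score of a descendant TF
#'
#' 1 when the descendant TF's binding motif is identical to its ancestral
#' reference motif, 0 as soon as any symbol differs — the discrete analogue
#' of binding-site divergence.
#'
#' @param reference_tf,descendant_tf TF `vc_gene`s; the descendant must
#'   carry the reference's ancestry tag.
#' @return 0 or 1.
#' @export
bs_conservation <- function(reference_tf, descendant_tf) {
  if (reference_tf$category != "tf" || descendant_tf$category != "tf")
    stop("bs_conservation: both genes must be TFs", call. = FALSE)
  if (!is.na(reference_tf$ancestry) && !is.na(descendant_tf$ancestry) &&
      reference_tf$ancestry != descendant_tf$ancestry)
    stop("bs_conservation: descendant does not descend from the reference TF",
         call. = FALSE)
  as.numeric(motif_matches(reference_tf$bind_motif, descendant_tf$bind_motif))
}

#' Relative ancestral outdegree of retained TFs
#'
#' Mean ancestral outdegree of the retained TFs divided by the mean
#' outdegree of all ancestral TFs; values above 1 mean retention is biased
#' towards highly connected TFs.
#'
#' @param ancestral_outdegrees Named numeric vector of ancestral outdegrees
#'   keyed by TF ancestry tag.
#' @param retained_tags Tags of the retained subset.
#' @return Ratio (`NaN` for an empty retained set).
#' @export
relative_outdegree <- function(ancestral_outdegrees, retained_tags) {
  retained_tags <- as.character(retained_tags)
  if (!all(retained_tags %in% names(ancestral_outdegrees)))
    stop("relative_outdegree: retained set is not a subset of the ancestral TFs",
         call. = FALSE)
  if (!length(retained_tags)) return(NaN)
  mean(ancestral_outdegrees[retained_tags]) / mean(ancestral_outdegrees)
}

#' Two-sided Mann-Whitney rank-sum comparison of run scores
#'
#' Thin wrapper over the rank-sum test with tie correction, following the
#' convention of ranking one score per simulation run within each group.
#'
#' @param scores_a,scores_b Non-empty numeric vectors, one score per run.
#' @param alternative Test direction (default two-sided).
#' @return List with `statistic` (U) and `p_value`.
#' @export
rank_sum_compare <- function(scores_a, scores_b, alternative = "two.sided") {
  if (!length(scores_a) || !length(scores_b))
    stop("rank_sum_compare: both groups must be non-empty", call. = FALSE)
  pooled <- c(scores_a, scores_b)
  if (length(unique(pooled)) == 1L) {
    warning("rank_sum_compare: all scores identical; p = 1", call. = FALSE)
    return(list(statistic = length(scores_a) * length(scores_b) / 2,
                p_value = 1))
  }
  wt <- suppressWarnings(wilcox.test(scores_a, scores_b,
                                     alternative = alternative))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Binding-site and connectivity divergence of conserved TFs along a lineage
#'
#' At each census interval after the reference point, conserved ancestral
#' TFs are identified (one random surviving copy per tag is the original),
#' split into ohnologs and singles when the reference is a post-WGD genome,
#' and summarized by mean binding-site conservation and relative ancestral
#' outdegree.
#'
#' @inheritParams ohnolog_census
#' @param ref_generation Reference generation (WGD point for WGD lineages,
#'   otherwise e.g. the environmental-change point).
#' @param split_pairs Split conserved TFs into ohnolog/single groups
#'   (requires ohnolog tags on the reference).
#' @return data.frame per generation and group: `n`, `mean_bs_conservation`,
#'   `relative_outdegree`.
#' @export
divergence_stats <- function(lod, ref_generation, bin_width = 1000L,
                             split_pairs = TRUE) {
  last <- max(lod$generations)
  at <- unique(c(seq(ref_generation, last, by = bin_width), last))
  tg <- lod_tagged_genomes(lod, ref_generation, at = at)
  ref <- tg$reference
  ref_tab <- ref_tag_table(ref)
  cb <- connectivity_bins(ref)
  ref_tfs <- ref$genes[gene_categories(ref) == "tf"]
  names(ref_tfs) <- vapply(ref_tfs, function(g) as.character(g$ancestry),
                           character(1))
  out <- list()
  for (gen in names(tg$genomes)) {
    desc <- tg$genomes[[gen]]
    reps <- ancestral_representatives(ref, desc)
    alive <- as.integer(names(reps))
    groups <- if (split_pairs && !anyNA(ref_tab$pair)) {
      cen_tab <- ref_tab
      cen_tab$alive <- cen_tab$tag %in% alive
      intact <- tapply(cen_tab$alive, cen_tab$pair, all)
      tf_tags <- cb$tags[cb$tags %in% alive]
      pair_of <- cen_tab$pair[match(tf_tags, cen_tab$tag)]
      list(ohnolog = tf_tags[unname(intact[as.character(pair_of)])],
           single = tf_tags[!unname(intact[as.character(pair_of)])])
    } else {
      list(all = cb$tags[cb$tags %in% alive])
    }
    for (grp in names(groups)) {
      tags <- groups[[grp]]
      bs <- if (length(tags))
        mean(vapply(as.character(tags), function(tg_) {
          d <- reps[[tg_]]
          if (d$category != "tf") return(NA_real_)
          bs_conservation(ref_tfs[[tg_]], d)
        }, numeric(1)), na.rm = TRUE) else NaN
      rod <- if (length(tags)) relative_outdegree(cb$outdegree, tags) else NaN
      out[[length(out) + 1L]] <- data.frame(
        generation = as.integer(gen), group = grp, n = length(tags),
        mean_bs_conservation = bs, relative_outdegree = rod)
    }
  }
  do.call(rbind, out)
}

#' Tab-separated retention report
#'
#' Joins the evolutionary ohnolog census with a random-deletion null
#' expectation and writes one row per census interval and gene category.
#'
#' @param census data.frame from [ohnolog_census()].
#' @param null data.frame from [random_deletion_null()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_retention_report <- function(census, null, path) {
  merged <- merge(census, null, by = c("generation", "category"),
                  all.x = TRUE, sort = FALSE)
  merged <- merged[order(merged$generation,
                         match(merged$category, GENE_CATEGORIES)), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# ohnolog retention: evolutionary census vs random-deletion null", con)
  utils::write.table(merged, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
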