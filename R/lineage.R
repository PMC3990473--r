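#' Trace the line of descent of a final individual
#'
#' Walks the unique backward chain of parent pointers from one individual of
#' the final population to the founding generation, collecting the mutation
#' events accepted at every step, and reconstructs the genome along the
#' chain by deterministic event replay. Genomes are stored as snapshots
#' every `snapshot_stride` generations (plus first and last); intermediate
#' genomes are reconstructed exactly by replay on demand.
#'
#' @param trace A `vc_trace` from [run_stage()] / [run_experiment()].
#' @param final_cell Index of the individual to trace; defaults to the
#'   fittest cell of the final population.
#' @param snapshot_stride Generations between stored genome snapshots.
#' @return A `vc_lod`: list with `generations`, `cell_index`, per-step
#'   `events`, a `sizes` data.frame (genome size and category counts per
#'   generation), genome `snapshots`, and `wgd_generations` (a lineage is a
#'   "WGD lineage" when this is non-empty after the change point).
#' @export
trace_line_of_descent <- function(trace, final_cell = NULL,
                                  snapshot_stride = 100L) {
  n <- length(trace$parents)
  if (is.null(final_cell))
    final_cell <- which.max(trace$final_pop$fitness)
  idx <- integer(n + 1L)
  idx[n + 1L] <- final_cell
  for (s in rev(seq_len(n))) {
    p <- trace$parents[[s]][[idx[s + 1L]]]
    if (is.null(p) || is.na(p)) stop("corrupt-trace: broken parent pointer",
                                     call. = FALSE)
    idx[s] <- p
  }
  gens <- trace$start_generation + 0:n
  events <- lapply(seq_len(n), function(s) trace$events[[s]][[idx[s + 1L]]])
  g <- trace$init_genomes[[idx[1L]]]
  sizes <- matrix(0L, nrow = n + 1L, ncol = 4L)
  snapshots <- list()
  cat_counts <- function(g) {
    tab <- table(factor(gene_categories(g), levels = GENE_CATEGORIES))
    c(genome_size(g), as.integer(tab))
  }
  sizes[1L, ] <- cat_counts(g)
  snapshots[[as.character(gens[1L])]] <- g
  wgd_gens <- integer(0)
  for (s in seq_len(n)) {
    g <- replay_events(g, events[[s]])
    sizes[s + 1L, ] <- cat_counts(g)
    if (any(vapply(events[[s]], function(e) e$kind == "wgd", logical(1))))
      wgd_gens <- c(wgd_gens, gens[s + 1L])
    if (gens[s + 1L] %% snapshot_stride == 0L || s == n)
      snapshots[[as.character(gens[s + 1L])]] <- g
  }
  sizes <- data.frame(generation = gens, size = sizes[, 1L],
                      n_tf = sizes[, 2L], n_enzyme = sizes[, 3L],
                      n_pump = sizes[, 4L])
  structure(list(start_generation = trace$start_generation,
                 generations = gens, cell_index = idx, events = events,
                 sizes = sizes, snapshots = snapshots,
                 wgd_generations = wgd_gens,
                 change_generation = trace$change_generation %||% NA_integer_),
            class = "vc_lod")
}

#' @export
print.vc_lod <- function(x, ...) {
  cat("<vc_lod> generations ", min(x$generations), "..", max(x$generations),
      ", ", sum(lengths(x$events)), " accepted events, ",
      length(x$wgd_generations), " WGD\n", sep = "")
  invisible(x)
}

#' Is this a WGD lineage?
#'
#' A line of descent is classified as a WGD lineage when at least one
#' whole-genome duplication was accepted on it; for re-adaptation
#' experiments, only WGDs at or after the environmental change count.
#'
#' @param lod A `vc_lod`.
#' @param after Optional generation (defaults to the change generation when
#'   recorded, otherwise the start).
#' @return `TRUE` or `FALSE`.
#' @export
is_wgd_lineage <- function(lod, after = NULL) {
  if (is.null(after))
    after <- if (!is.na(lod$change_generation)) lod$change_generation
             else min(lod$generations)
  any(lod$wgd_generations >= after)
}

#' Reconstruct the genome at a generation of a line of descent
#'
#' @param lod A `vc_lod`.
#' @param generation A generation covered by the lineage.
#' @return The `vc_genome` at that generation (exact event replay from the
#'   nearest earlier snapshot).
#' @export
lod_genome_at <- function(lod, generation) {
  if (!generation %in% lod$generations)
    stop("lod_genome_at: generation not covered by the lineage", call. = FALSE)
  snap_gens <- as.integer(names(lod$snapshots))
  base <- max(snap_gens[snap_gens <= generation])
  g <- lod$snapshots[[as.character(base)]]
  if (base < generation) {
    steps <- which(lod$generations > base & lod$generations <= generation)
    for (s in steps - 1L) g <- replay_events(g, lod$events[[s]])
  }
  g
}

#' Replay a line of descent from a retagged reference genome
#'
#' Establishes the genome at `ref_generation` as the ancestral reference
#' (fresh unique ancestry tags, see [retag_ancestry()]) and replays the
#' recorded events forward, returning the tagged genomes at the requested
#' generations. Because copies inherit their template's tag while the
#' reference tags are unique, the surviving carriers of each tag are exactly
#' the descendants of that reference gene, and duplicates that arose after
#' the reference never add new tags.
#'
#' @param lod A `vc_lod`.
#' @param ref_generation Reference generation.
#' @param at Generations at which tagged genomes are wanted (default: all
#'   from the reference to the end).
#' @return List with `reference` (the retagged genome) and `genomes` (named
#'   list of tagged genomes at the requested generations).
#' @export
lod_tagged_genomes <- function(lod, ref_generation, at = NULL) {
  if (is.null(at))
    at <- lod$generations[lod$generations >= ref_generation]
  at <- sort(unique(at))
  ref <- retag_ancestry(lod_genome_at(lod, ref_generation))
  out <- list()
  g <- ref
  if (ref_generation %in% at) out[[as.character(ref_generation)]] <- g
  steps <- which(lod$generations > ref_generation)
  for (s in steps - 1L) {
    g <- replay_events(g, lod$events[[s]])
    gen <- lod$generations[[s + 1L]]
    if (gen %in% at) out[[as.character(gen)]] <- g
  }
  list(reference = ref, genomes = out)
}

#' Fraction of ancestral gene content conserved in a descendant
#'
#' Counts the reference genes with at least one surviving one-to-one
#' descendant copy. When duplication multiplied a reference gene's lineage,
#' only one copy counts towards the ancestral content (the surviving-tag
#' count is by construction invariant to which copy is called the
#' original).
#'
#' @param reference A retagged reference `vc_genome` (see
#'   [retag_ancestry()], [lod_tagged_genomes()]).
#' @param descendant A descendant `vc_genome` carrying propagated tags.
#' @return Fraction in `[0, 1]` of reference genes still represented.
#' @export
ancestral_content_fraction <- function(reference, descendant) {
  ref_tags <- vapply(reference$genes, function(g) g$ancestry, integer(1))
  if (anyNA(ref_tags))
    stop("ancestral_content_fraction: reference genes lack ancestry tags",
         call. = FALSE)
  if (!length(ref_tags)) return(NaN)
  desc_tags <- vapply(descendant$genes, function(g) g$ancestry, integer(1))
  sum(ref_tags %in% desc_tags) / length(ref_tags)
}

#' Pick one random surviving copy per conserved reference gene
#'
#' Implements the "one random copy is the original" bookkeeping rule used
#' for identity-level comparisons (e.g. binding-site conservation): for each
#' reference gene with surviving descendants, one carrier of its tag is
#' chosen uniformly at random as the original.
#'
#' @inheritParams ancestral_content_fraction
#' @return Named list mapping reference ancestry tag to the chosen
#'   descendant `vc_gene`.
#' @export
ancestral_representatives <- function(reference, descendant) {
  ref_tags <- vapply(reference$genes, function(g) g$ancestry, integer(1))
  desc_tags <- vapply(descendant$genes, function(g) g$ancestry, integer(1))
  out <- list()
  for (tag in ref_tags) {
    hits <- which(desc_tags == tag)
    if (!length(hits)) next
    pick <- if (length(hits) == 1L) hits else hits[[sample.int(length(hits), 1L)]]
    out[[as.character(tag)]] <- descendant$genes[[pick]]
  }
  out
}

#' Ancestral gene-content conservation curve along a line of descent
#'
#' @param lod A `vc_lod`.
#' @param ref_generation Reference generation (e.g. the environmental-change
#'   point).
#' @param bin_width Sampling interval in generations.
#' @return data.frame with `generation` and conserved `fraction`.
#' @export
conservation_curve <- function(lod, ref_generation, bin_width = 1000L) {
  last <- max(lod$generations)
  at <- unique(c(seq(ref_generation, last, by = bin_width), last))
  tg <- lod_tagged_genomes(lod, ref_generation, at = at)
  data.frame(
    generation = as.integer(names(tg$genomes)),
    fraction = vapply(tg$genomes, function(g)
      ancestral_content_fraction(tg$reference, g), numeric(1)),
    row.names = NULL)
}

#' Effective (accepted) mutation rates in generation bins
#'
#' Converts the events accepted on a line of descent into rates by
#' averaging over fixed-width generation bins: per bin the accepted counts
#' of every mutation kind, the genes deleted per accepted deletion event as
#' a fraction of the genome size at the event, the deleted fraction per
#' generation, and the accepted point mutations per generation as a
#' fraction of genome size.
#'
#' @param lod A `vc_lod`.
#' @param bin_width Bin width in generations (published analyses use 1000).
#' @param from First generation of the first bin (defaults to the lineage
#'   start).
#' @return data.frame, one row per bin.
#' @export
effective_rates <- function(lod, bin_width = 1000L, from = NULL) {
  if (is.null(from)) from <- min(lod$generations)
  last <- max(lod$generations)
  n_steps <- length(lod$events)
  size_at <- setNames(lod$sizes$size, as.character(lod$sizes$generation))
  n_bins <- max(1L, ceiling((last - from) / bin_width))
  zero <- numeric(n_bins)
  out <- data.frame(bin_start = from + (seq_len(n_bins) - 1L) * bin_width,
                    bin_end = pmin(from + seq_len(n_bins) * bin_width, last),
                    n_point = zero, n_duplication = zero, n_deletion = zero,
                    n_translocation = zero, n_wgd = zero,
                    del_frac_event_sum = zero, del_frac_gen_sum = zero,
                    point_frac_gen_sum = zero)
  for (s in seq_len(n_steps)) {
    gen <- lod$generations[[s + 1L]]
    if (gen <= from) next
    b <- min(n_bins, ceiling((gen - from) / bin_width))
    for (ev in lod$events[[s]]) {
      if (ev$kind == "point") {
        out$n_point[b] <- out$n_point[b] + 1
        out$point_frac_gen_sum[b] <- out$point_frac_gen_sum[b] +
          1 / size_at[[as.character(gen)]]
      } else if (ev$kind == "deletion") {
        out$n_deletion[b] <- out$n_deletion[b] + 1
        frac <- ev$len / ev$size_before
        out$del_frac_event_sum[b] <- out$del_frac_event_sum[b] + frac
        out$del_frac_gen_sum[b] <- out$del_frac_gen_sum[b] + frac
      } else if (ev$kind == "duplication") {
        out$n_duplication[b] <- out$n_duplication[b] + 1
      } else if (ev$kind == "translocation") {
        out$n_translocation[b] <- out$n_translocation[b] + 1
      } else if (ev$kind == "wgd") {
        out$n_wgd[b] <- out$n_wgd[b] + 1
      }
    }
  }
  gens_in_bin <- pmax(1L, out$bin_end - out$bin_start)
  out$del_frac_per_event <- ifelse(out$n_deletion > 0,
                                   out$del_frac_event_sum / out$n_deletion, NA_real_)
  out$del_frac_per_generation <- out$del_frac_gen_sum / gens_in_bin
  out$point_frac_per_generation <- out$point_frac_gen_sum / gens_in_bin
  out$del_frac_event_sum <- out$del_frac_gen_sum <- out$point_frac_gen_sum <- NULL
  out
}

#' Summarize conservation curves across runs as a tab-separated table
#'
#' Aggregates per-run conservation curves (see [conservation_curve()]) into
#' the box/whisker-style summary used to compare lineage groups: per
#' generation bin the mean, median and quartiles of the conserved fraction
#' over runs.
#'
#' @param curves List of data.frames from [conservation_curve()] (one per
#'   run, sharing generation bins).
#' @param path Optional file path; when given, the summary is written as
#'   annotated TSV.
#' @return data.frame with `generation`, `mean_fraction`, `median`, `q25`,
#'   `q75`, `n_runs` (invisibly when writing).
#' @export
summarize_conservation <- function(curves, path = NULL) {
  all <- do.call(rbind, curves)
  gens <- sort(unique(all$generation))
  out <- do.call(rbind, lapply(gens, function(g) {
    v <- all$fraction[all$generation == g]
    data.frame(generation = g, mean_fraction = mean(v),
               median = median(v), q25 = unname(quantile(v, 0.25)),
               q75 = unname(quantile(v, 0.75)), n_runs = length(v))
  }))
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# conserved ancestral gene content: summary over runs per generation bin",
               con)
    utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Export a line of descent as a tab-separated table
#'
#' @param lod A `vc_lod`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_lod <- function(lod, path) {
  df <- lod$sizes
  df$n_events <- c(0L, lengths(lod$events))
  df$event_kinds <- c("", vapply(lod$events, function(evs)
    paste(vapply(evs, function(e) e$kind, character(1)), collapse = ","),
    character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# line of descent: generation, genome size, category counts, accepted events", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
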