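#' Scaled-down replication study of post-WGD genome evolution
#'
#' Runs `n_replicates` independent miniature versions of the two-stage
#' experiment and extracts the headline analyses. Each replicate evolves a
#' random founding population under the standard environment (initial
#' stage), then branches three ways from the change point:
#' * a neutral control continuing under the standard environment
#'   (streamlining and ancestral-content loss),
#' * a re-adaptation branch in a changed environment drawn from the
#'   perturbation panel with WGD imposed at the change point (ohnolog
#'   retention, connectivity and divergence analyses, which condition on a
#'   WGD lineage),
#' * a re-adaptation branch in the same changed environment with natural
#'   mutation pressure only (frequency of spontaneous WGD fixation in the
#'   line of descent).
#'
#' Analyses mirror the full-scale protocol at reduced scale: line-of-descent
#' tracing with event replay, conservation curves, ohnolog censuses against
#' uniform random-deletion nulls, and relative-outdegree / binding-site
#' statistics, with census bins of `bin_width` generations.
#'
#' @param n_replicates Number of independent replicates.
#' @param seed Root RNG seed; replicate r uses `seed + r`.
#' @param N Population size.
#' @param generations Named list with stage lengths `initial`, `neutral`,
#'   `post_wgd`, `post_natural`.
#' @param bin_width Census/analysis bin width in generations.
#' @param n_null Replicates of the random-deletion null per run.
#' @param rates,standard_env,config Simulation settings (published defaults).
#' @param genome_prior Arguments for [random_genome()].
#' @param verbose Print per-replicate progress.
#' @return A list with one entry per replicate (fitness trajectories,
#'   neutral streamlining and content loss, ohnolog retention vs null,
#'   relative outdegrees, natural-WGD classification) plus the `panel` used.
#' @export
run_scaled_study <- function(n_replicates = 10L, seed = 1L, N = 64L,
                             generations = list(initial = 150L,
                                                neutral = 250L,
                                                post_wgd = 200L,
                                                post_natural = 100L),
                             bin_width = 50L, n_null = 100L,
                             rates = mutation_rates(),
                             standard_env = environment_params(),
                             config = evolution_config(snapshot_interval = 10000L),
                             genome_prior = list(n_range = c(12L, 24L)),
                             verbose = FALSE) {
  panel <- make_environment_panel(standard_env)
  env_idx <- round(seq(1L, length(panel$panel), length.out = n_replicates))
  replicates <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(seed + r)
    change_env <- panel$panel[[env_idx[[r]]]]
    pop <- init_population(N, function() do.call(random_genome, genome_prior))
    initial <- run_stage(pop, standard_env, rates, generations$initial,
                         config, label = "initial")
    change_gen <- initial$final_pop$generation

    neutral <- bind_traces(initial,
      run_stage(initial$final_pop, standard_env, rates, generations$neutral,
                config, label = "control"))
    lod_n <- trace_line_of_descent(neutral)
    cons_n <- conservation_curve(lod_n, change_gen, bin_width)

    post_w <- bind_traces(initial,
      run_stage(initial$final_pop, change_env, rates, generations$post_wgd,
                config, force_wgd_at = change_gen + 1L, label = "post_wgd"))
    lod_w <- trace_line_of_descent(post_w)
    wgd_gen <- lod_w$wgd_generations[[1L]]
    census <- ohnolog_census(lod_w, wgd_gen, bin_width)
    losses <- ancestral_losses(lod_w, wgd_gen, bin_width)
    null_u <- random_deletion_null(lod_tagged_genomes(lod_w, wgd_gen,
                                                      at = wgd_gen)$reference,
                                   losses, mode = "uniform",
                                   n_replicates = n_null)
    div <- divergence_stats(lod_w, wgd_gen, bin_width)

    post_n <- bind_traces(initial,
      run_stage(initial$final_pop, change_env, rates,
                generations$post_natural, config, label = "post_natural"))
    lod_nat <- trace_line_of_descent(post_n)

    last_gen <- max(census$generation)
    final_census <- census[census$generation == last_gen, ]
    final_null <- null_u[null_u$generation == last_gen, ]
    final_div <- div[div$generation == max(div$generation), ]

    replicates[[r]] <- list(
      change_env = attr(change_env, "label"),
      change_generation = change_gen,
      initial_summary = initial$summary,
      neutral_summary = neutral$summary,
      neutral_conservation = cons_n,
      neutral_final_fraction = cons_n$fraction[[nrow(cons_n)]],
      census = census, null_uniform = null_u, divergence = div,
      final_census = final_census, final_null = final_null,
      final_divergence = final_div,
      rates_bins_wgd = effective_rates(lod_w, bin_width, from = change_gen),
      natural_wgd = is_wgd_lineage(lod_nat, after = change_gen),
      post_natural_final_fitness = max(post_n$final_pop$fitness))
    if (verbose)
      message(sprintf("replicate %d/%d done (change env %s)", r,
                      n_replicates, attr(change_env, "label")))
  }
  list(replicates = replicates, panel = panel, seed = seed,
       generations = generations, bin_width = bin_width)
}

#' Summary metrics of a scaled study
#'
#' Collapses [run_scaled_study()] output into the per-replicate scores used
#' for group comparisons: initial fitness trend, neutral streamlining and
#' content loss, final TF ohnolog retention against the uniform null, and
#' the relative ancestral outdegree of retained TF ohnologs.
#'
#' @param study Result of [run_scaled_study()].
#' @return data.frame with one row per replicate.
#' @export
summarize_study <- function(study) {
  rows <- lapply(seq_along(study$replicates), function(r) {
    rep <- study$replicates[[r]]
    s <- rep$initial_summary
    ns <- rep$neutral_summary
    post_change <- ns[ns$generation >= rep$change_generation, ]
    tf_cen <- rep$final_census[rep$final_census$category == "tf", ]
    tf_null <- rep$final_null[rep$final_null$category == "tf", ]
    ohn <- rep$final_divergence[rep$final_divergence$group == "ohnolog", ]
    sng <- rep$final_divergence[rep$final_divergence$group == "single", ]
    data.frame(
      replicate = r,
      fitness_start = s$mean_fitness[[1L]],
      fitness_end = s$mean_fitness[[nrow(s)]],
      fitness_trend = suppressWarnings(
        cor(s$generation, s$mean_fitness, method = "spearman")),
      neutral_peak_size = max(post_change$mean_genome_size),
      neutral_final_size = post_change$mean_genome_size[[nrow(post_change)]],
      neutral_final_content = rep$neutral_final_fraction,
      tf_retention = tf_cen$retention_fraction,
      tf_retention_null = tf_null$null_mean,
      rel_outdegree_ohnolog = if (nrow(ohn)) ohn$relative_outdegree else NA_real_,
      rel_outdegree_single = if (nrow(sng)) sng$relative_outdegree else NA_real_,
      bs_conservation_ohnolog = if (nrow(ohn)) ohn$mean_bs_conservation else NA_real_,
      natural_wgd = rep$natural_wgd)
  })
  do.call(rbind, rows)
}
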