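#' Default low/high levels for the environmental-change panel
#'
#' Each of the five non-evolvable parameters gets a low and a high level a
#' factor 2 to 4 away from its standard value; the severest change (factor
#' 4) is placed on the protein degradation rate, whose perturbations have
#' the strongest effect on the cells.
#'
#' @param standard A `vc_env`.
#' @return Named list of `c(low, high)` per panel parameter.
#' @export
default_panel_levels <- function(standard = environment_params()) {
  fac <- c(permeability = 2, degradation = 4, conversion_rate = 2,
           target_A = 2, target_X = 2)
  out <- lapply(PANEL_PARAMS, function(p)
    c(low = standard[[p]] / fac[[p]], high = standard[[p]] * fac[[p]]))
  setNames(out, PANEL_PARAMS)
}

#' Build the systematic environmental-change panel
#'
#' Enumerates every way of changing exactly `n_change` of the panel
#' parameters to one of their levels, keeping the remaining parameters at
#' the standard value. With five parameters, three changed at a time and two
#' levels each, this yields the systematic set of
#' `choose(5,3) * 2^3 = 80` novel environments.
#'
#' @param standard A `vc_env` (the standard condition).
#' @param levels Named list, one entry per changeable parameter, each a
#'   named numeric vector of alternative levels (default
#'   [default_panel_levels()]).
#' @param n_change How many parameters differ from standard in each panel
#'   member.
#' @return A `vc_panel`: list with `standard`, `levels` and `panel` (a list
#'   of labelled `vc_env`s).
#' @export
make_environment_panel <- function(standard = environment_params(),
                                   levels = default_panel_levels(standard),
                                   n_change = 3L) {
  params <- names(levels)
  if (is.null(params) || any(!nzchar(params)))
    stop("config error: panel levels must be a named list", call. = FALSE)
  for (p in params)
    if (length(levels[[p]]) < 1L)
      stop("config error: no levels defined for ", p, call. = FALSE)
  n_change <- as.integer(n_change)
  if (n_change > length(params))
    stop("config error: cannot change more parameters than are defined",
         call. = FALSE)
  panel <- list()
  subsets <- if (n_change == 0L) list(integer(0)) else
    utils::combn(length(params), n_change, simplify = FALSE)
  for (sub in subsets) {
    grids <- expand.grid(lapply(sub, function(i) seq_along(levels[[i]])),
                         KEEP.OUT.ATTRS = FALSE)
    if (nrow(grids) == 0L) grids <- data.frame(row.names = 1L)
    for (r in seq_len(max(1L, nrow(grids)))) {
      env <- standard
      lab <- character(0)
      for (j in seq_along(sub)) {
        p <- params[sub[j]]
        li <- grids[r, j]
        env[[p]] <- unname(levels[[p]][[li]])
        lev_name <- names(levels[[p]])[li] %||% as.character(li)
        lab <- c(lab, paste0(p, ":", lev_name))
      }
      attr(env, "label") <- if (length(lab)) paste(lab, collapse = "|") else "standard"
      panel[[length(panel) + 1L]] <- env
    }
  }
  structure(list(standard = standard, levels = levels, panel = panel),
            class = "vc_panel")
}

#' @export
print.vc_panel <- function(x, ...) {
  cat("<vc_panel> ", length(x$panel), " environments over ",
      length(x$levels), " parameters\n", sep = "")
  invisible(x)
}

#' Draw the resource conditions a cell experiences in its lifetime
#'
#' Each cell sees between one and three resource conditions that differ from
#' the standard environment only in the external resource concentration,
#' which is sampled log-uniformly over `fluct_range` times the standard
#' `A_ext`.
#'
#' @param standard A `vc_env`.
#' @param fluct_range Multiplicative fluctuation range (default 0.1 to 10).
#' @param k_max Maximum number of conditions (default 3).
#' @return List of 1 to `k_max` `vc_env`s.
#' @export
lifetime_environments <- function(standard, fluct_range = c(0.1, 10),
                                  k_max = 3L) {
  k <- sample.int(k_max, 1L)
  lapply(seq_len(k), function(i) {
    env <- standard
    env$A_ext <- standard$A_ext *
      exp(runif(1L, log(fluct_range[[1]]), log(fluct_range[[2]])))
    attr(env, "label") <- "lifetime"
    env
  })
}

#' Standardized fitness on a fixed resource set
#'
#' Deterministic fitness used for the high-fitness cutoff of the experiment
#' protocol: the geometric mean of the scores at a fixed reference set of
#' external resource concentrations (multiples of the standard `A_ext`),
#' with no stochastic fluctuation.
#'
#' @param g A `vc_genome`.
#' @param standard A `vc_env`.
#' @param multipliers Reference `A_ext` multipliers.
#' @param control Integration settings.
#' @param encoded Optional pre-encoded genome.
#' @return Fitness in `[0, 1]`.
#' @export
standard_fitness <- function(g, standard, multipliers = c(1 / 3, 1, 3),
                             control = ss_control(), encoded = NULL) {
  envs <- lapply(multipliers, function(m) {
    env <- standard; env$A_ext <- standard$A_ext * m; env
  })
  evaluate_cell(g, envs, control = control, encoded = encoded)$fitness
}

#' Generate a random founding genome
#'
#' Gene counts are drawn uniformly from `n_range` with categories in the
#' given proportions. Kinetic parameters come from broad log-normal priors
#' and regulation strengths from a standard normal. Operator and TF binding
#' motifs are drawn from a small shared vocabulary of `n_motif_words` random
#' motifs: with exact discrete matching a shared vocabulary is what gives
#' random founders any initial regulatory wiring at all, which evolution can
#' then prune and rewire by symbol flips.
#'
#' @param n_range Range of gene counts.
#' @param proportions Category proportions (tf, enzyme, pump).
#' @param L,S Motif length and alphabet size.
#' @param n_motif_words Size of the shared motif vocabulary.
#' @return A `vc_genome` with ancestry tags set to the gene ids.
#' @export
random_genome <- function(n_range = c(30L, 60L),
                          proportions = c(tf = 0.4, enzyme = 0.4, pump = 0.2),
                          L = 12L, S = 2L, n_motif_words = 8L) {
  n <- n_range[[1]] + sample.int(n_range[[2]] - n_range[[1]] + 1L, 1L) - 1L
  words <- replicate(n_motif_words,
                     motif(sample.int(S, L, replace = TRUE) - 1L, S),
                     simplify = FALSE)
  rnd_word <- function() words[[sample.int(length(words), 1L)]]
  cats <- sample(GENE_CATEGORIES, n, replace = TRUE,
                 prob = proportions[GENE_CATEGORIES])
  # ensure the minimal metabolic repertoire is present
  if (!"pump" %in% cats) cats[[sample.int(n, 1L)]] <- "pump"
  if (!"enzyme" %in% cats) cats[[sample.int(n, 1L)]] <- "enzyme"
  rk <- function(mu, sd = 0.5) rlnorm(1L, log(mu), sd)
  genes <- lapply(seq_len(n), function(i) {
    op <- rnd_word()
    basal <- rk(0.3)
    switch(cats[[i]],
      tf = gene_tf(i, op, basal, ligand = sample(c("A", "X"), 1L),
                   bind_motif = rnd_word(), K_lig = rk(0.5),
                   eff_bound = rnorm(1L), eff_free = rnorm(1L),
                   ancestry = i),
      enzyme = gene_enzyme(i, op, basal,
                           reaction = sample(c("cat", "ana"), 1L,
                                             prob = c(0.7, 0.3)),
                           k_cat = rk(3), K_A = rk(0.5), K_X = rk(0.5),
                           ancestry = i),
      pump = gene_pump(i, op, basal, k_cat = rk(3), K_Aext = rk(0.5),
                       K_X = rk(0.5), cost = rk(0.5, 0.3), ancestry = i))
  })
  genome(genes, L = L, S = S)
}

#' Initialize a population
#'
#' @param N Population size (constant across generations; published runs use
#'   1024).
#' @param genome_fn Zero-argument function generating one founding genome.
#' @return A `vc_population`.
#' @export
init_population <- function(N = 1024L, genome_fn = random_genome) {
  genomes <- replicate(N, genome_fn(), simplify = FALSE)
  structure(list(genomes = genomes,
                 encoded = vector("list", N),
                 fitness = rep(NA_real_, N),
                 generation = 0L),
            class = "vc_population")
}

#' @export
print.vc_population <- function(x, ...) {
  cat("<vc_population> N=", length(x$genomes), " generation=", x$generation,
      if (!anyNA(x$fitness))
        sprintf(" mean fitness=%.3f", mean(x$fitness)) else "", "\n", sep = "")
  invisible(x)
}

pop_encoded <- function(pop, i) {
  if (is.null(pop$encoded[[i]]))
    pop$encoded[[i]] <- encode_genome(pop$genomes[[i]])
  pop$encoded[[i]]
}

evaluate_population <- function(pop, env, config) {
  N <- length(pop$genomes)
  lr <- log(config$fluct_range)
  for (i in seq_len(N)) {
    if (genome_size(pop$genomes[[i]]) == 0L) { pop$fitness[[i]] <- 0; next }
    enc <- pop_encoded(pop, i)
    pop$encoded[[i]] <- enc
    k <- sample.int(config$k_max, 1L)
    A_exts <- env$A_ext * exp(runif(k, lr[[1]], lr[[2]]))
    scores <- eval_scores_fast(enc, env, A_exts, config$ss)
    pop$fitness[[i]] <- if (any(scores == 0)) 0 else exp(mean(log(scores)))
  }
  pop
}

#' Advance a population by one generation
#'
#' Every cell's fitness is evaluated on its own randomly drawn lifetime
#' resource conditions; `N` offspring are then drawn by fitness-proportional
#' sampling with replacement and each offspring is a mutated copy of its
#' parent. If every cell has fitness zero (as can happen immediately after a
#' harsh environmental change) parents are drawn uniformly so the population
#' does not dead-lock.
#'
#' @param pop A `vc_population` .
#' @param env The standard `vc_env` for this stage.
#' @param rates A `vc_rates`.
#' @param config An evolution config, see [evolution_config()].
#' @return List with the offspring `pop`, the integer `parents` map, the
#'   per-cell `events` lists and the evaluated parent `fitness`.
#' @export
run_generation <- function(pop, env, rates, config = evolution_config()) {
  N <- length(pop$genomes)
  pop <- evaluate_population(pop, env, config)
  fit <- pop$fitness
  parents <- if (all(fit == 0)) sample.int(N, N, replace = TRUE)
             else sample.int(N, N, replace = TRUE, prob = fit)
  gen <- pop$generation + 1L
  genomes <- vector("list", N)
  encoded <- vector("list", N)
  events <- vector("list", N)
  for (i in seq_len(N)) {
    res <- apply_mutations(pop$genomes[[parents[[i]]]], rates, gen)
    genomes[[i]] <- res$genome
    events[[i]] <- res$events
    penc <- pop$encoded[[parents[[i]]]]
    if (!length(res$events)) {
      if (!is.null(penc)) encoded[[i]] <- penc
    } else if (!is.null(penc)) {
      upd <- patch_encoded(penc, res$genome, res$events)
      if (!is.null(upd)) encoded[[i]] <- upd
    }
  }
  child <- structure(list(genomes = genomes, encoded = encoded,
                          fitness = rep(NA_real_, N), generation = gen),
                     class = "vc_population")
  list(pop = child, parents = parents, events = events, fitness = fit)
}

#' Evolution configuration
#'
#' @param fluct_range Lifetime `A_ext` fluctuation range.
#' @param k_max Maximum number of lifetime resource conditions.
#' @param ss Integration settings ([ss_control()]); evolution runs default
#'   to a 150-time-unit homeostasis horizon and relaxed trajectory
#'   tolerances — only the attractor matters for scoring, and the
#'   convergence criterion is checked on the true derivative either way.
#' @param snapshot_interval Record full population snapshots every this many
#'   generations in traces.
#' @param standard_multipliers Reference `A_ext` multipliers for
#'   [standard_fitness()].
#' @return A config list.
#' @export
evolution_config <- function(fluct_range = c(0.1, 10), k_max = 3L,
                             ss = ss_control(t_max = 80, rtol = 2e-3,
                                             atol = 1e-6, conv_tol = 1e-4,
                                             f_max = 1500),
                             snapshot_interval = 100L,
                             standard_multipliers = c(1 / 3, 1, 3)) {
  list(fluct_range = fluct_range, k_max = k_max, ss = ss,
       snapshot_interval = snapshot_interval,
       standard_multipliers = standard_multipliers)
}

summary_row <- function(pop, best_std, n_wgd) {
  data.frame(generation = pop$generation,
             best_fitness = max(pop$fitness),
             mean_fitness = mean(pop$fitness),
             best_standard_fitness = best_std,
             mean_genome_size = mean(vapply(pop$genomes, genome_size, integer(1))),
             wgd_count = n_wgd)
}

#' Run one evolutionary stage, recording a full trace
#'
#' Evolves `pop` under `env` for up to `n_generations`, recording parent
#' pointers and complete mutation-event logs every generation (the trace is
#' exactly replayable), a per-generation summary, and population snapshots.
#' If `cutoff` is given, the stage stops `post_cutoff_delay` generations
#' after the population's best standardized fitness first exceeds it.
#' `force_wgd_at` applies a whole-genome duplication to every offspring at
#' that generation (logged as ordinary WGD events); it is used to condition
#' scaled-down experiments on WGD fixation.
#'
#' @param pop A `vc_population`.
#' @param env The standard `vc_env` of the stage.
#' @param rates A `vc_rates`.
#' @param n_generations Maximum generations for this stage.
#' @param config See [evolution_config()].
#' @param cutoff Optional high-fitness cutoff (e.g. 0.85).
#' @param post_cutoff_delay Generations to continue after the cutoff is first
#'   passed.
#' @param force_wgd_at Optional generation at which WGD is imposed.
#' @param label Stage label stored in the trace.
#' @return A `vc_trace`.
#' @export
run_stage <- function(pop, env, rates, n_generations,
                      config = evolution_config(), cutoff = NULL,
                      post_cutoff_delay = 1000L, force_wgd_at = NULL,
                      label = "stage") {
  start_gen <- pop$generation
  init_genomes <- pop$genomes
  parents <- list(); events <- list(); summaries <- list()
  snapshots <- list()
  first_pass <- NA_integer_
  stop_at <- start_gen + n_generations
  g <- start_gen
  while (g < stop_at) {
    step <- run_generation(pop, env, rates, config)
    # summary describes the generation that was just evaluated
    best_i <- which.max(step$fitness)
    evaluated <- pop; evaluated$fitness <- step$fitness
    best_std <- standard_fitness(evaluated$genomes[[best_i]], env,
                                 config$standard_multipliers, config$ss,
                                 encoded = pop_encoded(evaluated, best_i))
    if (!is.null(cutoff) && is.na(first_pass) && best_std > cutoff) {
      first_pass <- g
      stop_at <- min(stop_at, g + post_cutoff_delay)
    }
    pop <- step$pop
    g <- pop$generation
    if (!is.null(force_wgd_at) && g == force_wgd_at) {
      for (i in seq_along(pop$genomes)) {
        res <- whole_genome_duplicate(pop$genomes[[i]], g)
        pop$genomes[[i]] <- res$genome
        pop$encoded[i] <- list(NULL)
        step$events[[i]] <- c(step$events[[i]], res$events)
      }
    }
    n_wgd <- sum(vapply(step$events, function(evs)
      sum(vapply(evs, function(e) e$kind == "wgd", logical(1))), numeric(1)))
    summaries[[length(summaries) + 1L]] <- summary_row(evaluated, best_std, n_wgd)
    parents[[length(parents) + 1L]] <- step$parents
    events[[length(events) + 1L]] <- step$events
    if (g %% config$snapshot_interval == 0L)
      snapshots[[as.character(g)]] <- pop$genomes
  }
  # evaluate the final population so the trace ends with known fitnesses
  pop <- evaluate_population(pop, env, config)
  best_i <- which.max(pop$fitness)
  best_std <- standard_fitness(pop$genomes[[best_i]], env,
                               config$standard_multipliers, config$ss,
                               encoded = pop_encoded(pop, best_i))
  summaries[[length(summaries) + 1L]] <- summary_row(pop, best_std, 0)
  structure(list(label = label, env = env, rates = rates, config = config,
                 start_generation = start_gen, init_genomes = init_genomes,
                 parents = parents, events = events,
                 summary = do.call(rbind, summaries), snapshots = snapshots,
                 first_pass_generation = first_pass, final_pop = pop),
            class = "vc_trace")
}

#' @export
print.vc_trace <- function(x, ...) {
  n <- length(x$parents)
  cat("<vc_trace '", x$label, "'> generations ", x$start_generation, "..",
      x$start_generation + n, ", N=", length(x$init_genomes), "\n", sep = "")
  invisible(x)
}

#' Concatenate two consecutive traces
#'
#' `b` must have been started from `a`'s final population (same ordering),
#' so `b`'s first parent map indexes into `a`'s final generation.
#'
#' @param a,b `vc_trace`s.
#' @return A combined `vc_trace`.
#' @export
bind_traces <- function(a, b) {
  if (b$start_generation != a$start_generation + length(a$parents))
    stop("bind_traces: traces are not consecutive", call. = FALSE)
  out <- a
  out$parents <- c(a$parents, b$parents)
  out$events <- c(a$events, b$events)
  out$summary <- rbind(a$summary[-nrow(a$summary), ], b$summary)
  out$snapshots <- c(a$snapshots, b$snapshots)
  out$final_pop <- b$final_pop
  out$label <- paste(a$label, b$label, sep = "+")
  out$change_generation <- b$start_generation
  out
}

#' Run the two-stage environmental-change experiment
#'
#' Stage one evolves a random founding population under the standard
#' environment until `post_cutoff_delay` generations after the population's
#' best standardized fitness first exceeds `cutoff` (capped at
#' `max_generations`). The end of stage one is the environmental-change
#' point. Stage two either continues under the standard environment (the
#' neutral control) or clones the population into a changed environment from
#' the perturbation panel and lets it re-adapt for `post_generations`.
#'
#' @param config A [run_config()] (or [default_config()]) list.
#' @param change_env Optional `vc_env` for the post-change stage; `NULL`
#'   runs only the neutral control.
#' @param force_wgd Logical: impose WGD on the whole population at the
#'   change point of the post-change stage.
#' @return List with `initial`, `control` and `post` traces (the latter two
#'   already bound to the initial stage) and `change_generation`.
#' @export
run_experiment <- function(config = default_config(), change_env = NULL,
                           force_wgd = FALSE) {
  ec <- config$evolution
  env <- config$standard_env
  rates <- config$rates
  pop <- init_population(config$pop_size, function()
    do.call(random_genome, config$genome_prior))
  initial <- run_stage(pop, env, rates, config$max_generations, ec,
                       cutoff = config$high_fitness_cutoff,
                       post_cutoff_delay = config$post_cutoff_delay,
                       label = "initial")
  change_gen <- initial$final_pop$generation
  out <- list(initial = initial, change_generation = change_gen)
  if (config$control_generations > 0L) {
    ctrl <- run_stage(initial$final_pop, env, rates,
                      config$control_generations, ec, label = "control")
    out$control <- bind_traces(initial, ctrl)
  }
  if (!is.null(change_env) && config$post_generations > 0L) {
    post <- run_stage(initial$final_pop, change_env, rates,
                      config$post_generations, ec,
                      force_wgd_at = if (force_wgd) change_gen + 1L else NULL,
                      label = "post_change")
    out$post <- bind_traces(initial, post)
  }
  out
}
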