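#' Full run configuration with published defaults
#'
#' Collects every tunable of a simulation run: mutation rates (0.024
#' duplication, 0.024 deletion, 0.048 translocation, 0.003 WGD, point
#' mutations 5x the large-scale rate per gene), the standard environment,
#' the perturbation-panel levels, the experiment protocol constants
#' (population size 1024, high-fitness cutoff 0.85, 1000-generation delay,
#' 15000-generation cap) and the founding-genome prior.
#'
#' @param seed Integer RNG seed of the run.
#' @param pop_size Population size `N`.
#' @param max_generations Cap of the initial adaptation stage.
#' @param high_fitness_cutoff Standardized-fitness threshold.
#' @param post_cutoff_delay Generations between first cutoff passage and the
#'   environmental change.
#' @param post_generations Length of the re-adaptation stage.
#' @param control_generations Length of the neutral-control stage.
#' @param rates A [mutation_rates()].
#' @param standard_env An [environment_params()].
#' @param panel_levels Levels for [make_environment_panel()].
#' @param evolution An [evolution_config()].
#' @param genome_prior List of arguments to [random_genome()].
#' @return A `vc_config` list.
#' @export
run_config <- function(seed = 1L, pop_size = 1024L, max_generations = 15000L,
                       high_fitness_cutoff = 0.85, post_cutoff_delay = 1000L,
                       post_generations = 15000L, control_generations = 15000L,
                       rates = mutation_rates(),
                       standard_env = environment_params(),
                       panel_levels = default_panel_levels(standard_env),
                       evolution = evolution_config(),
                       genome_prior = list()) {
  if (pop_size < 1L) stop("config error: pop_size must be >= 1", call. = FALSE)
  if (max_generations < 0L)
    stop("config error: max_generations must be >= 0", call. = FALSE)
  if (high_fitness_cutoff <= 0 || high_fitness_cutoff > 1)
    stop("config error: high_fitness_cutoff must lie in (0, 1]", call. = FALSE)
  structure(list(seed = as.integer(seed), pop_size = as.integer(pop_size),
                 max_generations = as.integer(max_generations),
                 high_fitness_cutoff = high_fitness_cutoff,
                 post_cutoff_delay = as.integer(post_cutoff_delay),
                 post_generations = as.integer(post_generations),
                 control_generations = as.integer(control_generations),
                 rates = rates, standard_env = standard_env,
                 panel_levels = panel_levels, evolution = evolution,
                 genome_prior = genome_prior),
            class = "vc_config")
}

#' @rdname run_config
#' @export
default_config <- function() run_config()

config_to_list <- function(config) {
  list(seed = config$seed, pop_size = config$pop_size,
       max_generations = config$max_generations,
       high_fitness_cutoff = config$high_fitness_cutoff,
       post_cutoff_delay = config$post_cutoff_delay,
       post_generations = config$post_generations,
       control_generations = config$control_generations,
       rates = unclass(config$rates),
       standard_env = unclass(config$standard_env),
       panel_levels = lapply(config$panel_levels, as.list),
       evolution = config$evolution,
       genome_prior = config$genome_prior)
}

#' Load / save a run configuration (YAML)
#'
#' Omitted keys fall back to the published defaults; unknown keys and
#' out-of-range values raise a config error naming the offending key.
#' `load_config(write_config(cfg))` is the identity.
#'
#' @param path YAML (or JSON, which YAML subsumes) file path.
#' @param config A `vc_config`.
#' @return `load_config()` a `vc_config`; `write_config()` `path`,
#'   invisibly.
#' @export
load_config <- function(path) {
  raw <- if (file.exists(path)) yaml::read_yaml(path) else
    stop("config error: file not found: ", path, call. = FALSE)
  if (is.null(raw)) raw <- list()
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("config error: unknown key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  args <- raw[setdiff(names(raw), c("rates", "standard_env", "panel_levels",
                                    "evolution"))]
  if (!is.null(raw$rates)) args$rates <- do.call(mutation_rates, raw$rates)
  if (!is.null(raw$standard_env))
    args$standard_env <- do.call(environment_params, raw$standard_env)
  if (!is.null(raw$panel_levels))
    args$panel_levels <- lapply(raw$panel_levels, function(x) unlist(x))
  if (!is.null(raw$evolution)) {
    ev <- raw$evolution
    if (!is.null(ev$ss)) ev$ss <- do.call(ss_control, ev$ss)
    if (!is.null(ev$fluct_range)) ev$fluct_range <- as.numeric(ev$fluct_range)
    args$evolution <- do.call(evolution_config, ev)
  }
  do.call(run_config, args)
}

#' @rdname load_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' Write / read an environment panel as a tab-separated table
#'
#' One environment per row: label, the five panel parameters, `A_ext` and
#' `K_op`.
#'
#' @param panel A `vc_panel` (or list of `vc_env`).
#' @param path File path.
#' @return `write_env_panel()` returns `path` invisibly; `read_env_panel()`
#'   a list of `vc_env`.
#' @export
write_env_panel <- function(panel, path) {
  envs <- if (inherits(panel, "vc_panel")) panel$panel else panel
  cols <- c("A_ext", PANEL_PARAMS, "K_op")
  rows <- vapply(envs, function(e)
    paste(c(attr(e, "label"), fmt_num(unlist(e[cols]))), collapse = "\t"),
    character(1))
  writeLines(c(paste(c("label", cols), collapse = "\t"), rows), path)
  invisible(path)
}

#' @rdname write_env_panel
#' @export
read_env_panel <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    args <- as.list(df[i, -1, drop = FALSE])
    args$label <- df$label[[i]]
    do.call(environment_params, args)
  })
}

#' Write the per-generation summary of a trace
#'
#' @param trace A `vc_trace`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trace_summary <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage %s: per-generation population summary", trace$label),
             con)
  utils::write.table(trace$summary, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
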