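#' Environment parameters
#'
#' The five global, non-evolvable parameters of the cellular environment plus
#' the external resource concentration. The perturbation panel (see
#' [make_environment_panel()]) varies the five parameters; the external
#' resource `A_ext` fluctuates stochastically during a cell's lifetime.
#'
#' @param A_ext External resource concentration.
#' @param permeability Membrane diffusion rate for A (1/time).
#' @param degradation Protein decay rate (1/time), applied to all proteins.
#' @param conversion_rate Energy yield per catabolised A (dimensionless).
#' @param target_A,target_X Homeostasis targets for internal A and X.
#' @param K_op Promoter occupancy constant of TF-operator binding
#'   (concentration); a global model constant, not part of the panel.
#' @param label Optional environment label.
#' @return A `vc_env` list.
#' @export
environment_params <- function(A_ext = 1, permeability = 1, degradation = 0.5,
                               conversion_rate = 1, target_A = 0.6,
                               target_X = 0.6, K_op = 0.5, label = "standard") {
  vals <- c(A_ext = A_ext, permeability = permeability,
            degradation = degradation, conversion_rate = conversion_rate,
            target_A = target_A, target_X = target_X, K_op = K_op)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("environment_params: all parameters must be positive and finite",
         call. = FALSE)
  structure(as.list(vals), label = label, class = "vc_env")
}

#' @export
print.vc_env <- function(x, ...) {
  cat("<vc_env ", attr(x, "label") %||% "", "> ",
      paste(sprintf("%s=%g", names(x), unlist(x)), collapse = " "), "\n", sep = "")
  invisible(x)
}

# Names of the five panel parameters (A_ext and K_op excluded).
PANEL_PARAMS <- c("permeability", "degradation", "conversion_rate",
                  "target_A", "target_X")

#' Cell state
#'
#' @param A_int,X_int Internal resource and energy concentrations.
#' @param protein Named numeric vector of protein concentrations keyed by
#'   gene id (in genome order).
#' @return A `vc_state` list.
#' @export
cell_state <- function(A_int, X_int, protein = numeric()) {
  if (A_int < 0 || X_int < 0 || any(protein < 0))
    stop("cell_state: concentrations must be >= 0", call. = FALSE)
  structure(list(A_int = A_int, X_int = X_int, protein = protein),
            class = "vc_state")
}

#' Default initial state for steady-state evaluation
#'
#' Deterministic, biologically neutral start: internal A at the external
#' concentration, internal X at its homeostasis target, every protein at its
#' constitutive level `basal / degradation`.
#'
#' @param g A `vc_genome`.
#' @param env A `vc_env`.
#' @return A `vc_state`.
#' @export
default_cell_state <- function(g, env) {
  basal <- vapply(g$genes, function(x) x$basal, numeric(1))
  cell_state(env$A_ext, env$target_X,
             setNames(basal / env$degradation, as.character(gene_ids(g))))
}

#' Quasi-steady-state ligand binding of a TF
#'
#' Ligand binding is fast relative to gene expression, so the bound fraction
#' is the equilibrium `[ligand] / ([ligand] + K_lig)` with the ligand
#' concentration taken from the current cell state (internal A or X according
#' to the TF's ligand type).
#'
#' @param tf A TF `vc_gene`.
#' @param state A `vc_state`.
#' @return Named numeric `c(bound = , free = )`, summing to 1.
#' @export
tf_activity <- function(tf, state) {
  if (tf$category != "tf")
    stop("tf_activity: gene is not a TF", call. = FALSE)
  lig <- if (tf$ligand == "A") state$A_int else state$X_int
  b <- lig / (lig + tf$K_lig)
  c(bound = b, free = 1 - b)
}

#' Expression rate of a gene under its current regulators
#'
#' Each regulating TF `t` contributes `w_t = occ_t * (b_t * eff_bound +
#' (1 - b_t) * eff_free)` to the log expression rate, where `b_t` is the
#' ligand-bound fraction ([tf_activity()]) and `occ_t = P_t / (P_t + K_op)`
#' the promoter occupancy of the TF. The rate is
#' `basal * exp(sum of w_t)` — always positive, equal to the basal rate for
#' unregulated genes, and with a regulation sign that can switch with the
#' TF's ligand state.
#'
#' @param gene A `vc_gene` (the regulated gene).
#' @param g The `vc_genome` containing it.
#' @param network The `vc_network` derived from `g`.
#' @param state A `vc_state` (protein vector keyed by gene id).
#' @return Non-negative expression rate.
#' @export
expression_rate <- function(gene, g, network, state) {
  e <- network$edges
  regs <- e$tf_id[e$target_id == gene$id]
  if (!length(regs)) return(gene$basal)
  K_op <- attr(state, "K_op") %||% 0.5
  w <- 0
  for (tid in regs) {
    tf <- genome_gene(g, tid)
    b <- tf_activity(tf, state)[["bound"]]
    P <- state$protein[[as.character(tid)]]
    occ <- P / (P + K_op)
    w <- w + occ * (b * tf$eff_bound + (1 - b) * tf$eff_free)
  }
  gene$basal * exp(w)
}

#' Time derivatives of the cell state (reference implementation)
#'
#' Pure-R evaluation of the ODE right-hand side; the production path uses the
#' compiled integrator, and the two are cross-checked in the test suite.
#' Fluxes are saturating: catabolic `v = k_cat P A/(K_A+A)` (A -> X with
#' yield `conversion_rate`), anabolic `v = k_cat P A/(K_A+A) X/(K_X+X)`
#' (consumes one A and one X), pump
#' `v = k_cat P A_ext/(K_Aext+A_ext) X/(K_X+X)` (imports A, consumes
#' `cost * v` of X). Proteins follow `dP = expression - degradation * P`.
#'
#' @inheritParams expression_rate
#' @param env A `vc_env`.
#' @return Named numeric vector `(A_int, X_int, P_<id>...)` of derivatives.
#' @export
derivatives <- function(state, g, network, env) {
  attr(state, "K_op") <- env$K_op
  A <- state$A_int; X <- state$X_int
  dA <- env$permeability * (env$A_ext - A)
  dX <- 0
  dP <- numeric(genome_size(g))
  for (i in seq_along(g$genes)) {
    gn <- g$genes[[i]]
    P <- state$protein[[as.character(gn$id)]]
    dP[i] <- expression_rate(gn, g, network, state) - env$degradation * P
    if (gn$category == "enzyme") {
      satA <- A / (gn$K_A + A)
      if (gn$reaction == "cat") {
        v <- gn$k_cat * P * satA
        dA <- dA - v; dX <- dX + env$conversion_rate * v
      } else {
        v <- gn$k_cat * P * satA * X / (gn$K_X + X)
        dA <- dA - v; dX <- dX - v
      }
    } else if (gn$category == "pump") {
      v <- gn$k_cat * P * (env$A_ext / (gn$K_Aext + env$A_ext)) * X / (gn$K_X + X)
      dA <- dA + v; dX <- dX - gn$cost * v
    }
  }
  p_names <- if (genome_size(g)) paste0("P_", gene_ids(g)) else character(0)
  setNames(c(dA, dX, dP), c("A_int", "X_int", p_names))
}

# Per-gene regulator position lists, computed directly from motif identity
# (equivalent to the edge set of derive_network(), but without building the
# edge data.frame; this sits on the per-generation hot path). Motifs are
# compared through packed numeric keys when the motif space fits in a
# double, falling back to string keys otherwise.
regulator_indices <- function(g) {
  n <- genome_size(g)
  reg <- replicate(n, integer(0), simplify = FALSE)
  if (n == 0L) return(reg)
  if (g$S^g$L < 2^52) {
    pw <- as.numeric(g$S)^(seq_len(g$L) - 1L)
    ops <- vapply(g$genes, function(x) sum(x$operator * pw), numeric(1))
    tf_pos <- which(gene_categories(g) == "tf")
    if (!length(tf_pos)) return(reg)
    keys <- vapply(g$genes[tf_pos], function(x) sum(x$bind_motif * pw),
                   numeric(1))
  } else {
    ops <- vapply(g$genes, function(x) motif_key(x$operator), character(1))
    tf_pos <- which(gene_categories(g) == "tf")
    if (!length(tf_pos)) return(reg)
    keys <- vapply(g$genes[tf_pos], function(x) motif_key(x$bind_motif),
                   character(1))
  }
  for (i in seq_len(n)) {
    hit <- tf_pos[keys == ops[[i]]]
    if (length(hit)) reg[[i]] <- hit
  }
  reg
}

# Encode a genome into the compact matrix representation consumed by the
# compiled integrator, together with per-gene regulator index lists.
encode_genome <- function(g) {
  n <- genome_size(g)
  mat <- t(vapply(g$genes, function(gn) {
    switch(gn$category,
      tf = c(1, gn$basal, if (gn$ligand == "A") 0 else 1,
             gn$K_lig, gn$eff_bound, gn$eff_free, 0),
      enzyme = c(2, gn$basal, if (gn$reaction == "cat") 0 else 1,
                 gn$k_cat, gn$K_A, gn$K_X, 0),
      pump = c(3, gn$basal, 0, gn$k_cat, gn$K_Aext, gn$K_X, gn$cost))
  }, numeric(7)))
  if (n == 0L) mat <- matrix(0, 0, 7)
  list(mat = mat, reg = regulator_indices(g), ids = gene_ids(g))
}

env_vector <- function(env) {
  c(env$A_ext, env$permeability, env$degradation, env$conversion_rate, env$K_op)
}

#' Integration control settings
#'
#' @param t_max Integration time cap (time units).
#' @param rtol,atol Relative and absolute local-error tolerances of the
#'   adaptive Runge-Kutta integrator.
#' @param conv_tol Convergence threshold on the maximum relative derivative
#'   `|dy_i/dt| / (1 + |y_i|)`.
#' @param h_max Maximum step size.
#' @param f_max Budget of right-hand-side evaluations per steady-state
#'   solve; cells that exhaust it have no resolvable steady state on the
#'   homeostasis timescale and score 0.
#' @param method Integration method: `"rkc"` (stabilized explicit
#'   Runge-Kutta-Chebyshev, the default — these reaction systems are
#'   dissipative and mildly stiff) or `"rk45"` (adaptive Cash-Karp 4/5,
#'   kept as an independent cross-check).
#' @return A list of settings.
#' @export
ss_control <- function(t_max = 1000, rtol = 1e-6, atol = 1e-8,
                       conv_tol = 1e-6, h_max = 25, method = "rkc",
                       f_max = 50000) {
  list(t_max = t_max, rtol = rtol, atol = atol, conv_tol = conv_tol,
       h_max = h_max, method = method, f_max = f_max)
}

#' Integrate a cell to steady state and measure homeostasis deviations
#'
#' Integrates the intracellular ODEs from `init` until the maximum relative
#' derivative drops below `conv_tol` or the time cap is reached. Deviations
#' are relative absolute errors against the homeostasis targets:
#' `deviation_A = |A_int - target_A| / target_A` (analogously for X).
#' Cells whose dynamics diverge (non-finite state) are flagged and score 0.
#'
#' @param g A `vc_genome`.
#' @param env A `vc_env`.
#' @param init Initial `vc_state`; defaults to [default_cell_state()].
#' @param control Settings from [ss_control()].
#' @param encoded Optional pre-encoded genome (internal fast path).
#' @return A `vc_steady_state`: list with `state`, `converged`, `diverged`,
#'   `deviation_A`, `deviation_X`, `score`, `t`.
#' @export
steady_state <- function(g, env, init = NULL, control = ss_control(),
                         encoded = NULL) {
  if (is.null(encoded)) encoded <- encode_genome(g)
  if (is.null(init)) init <- default_cell_state(g, env)
  y0 <- c(init$A_int, init$X_int,
          as.numeric(init$protein[as.character(encoded$ids)]))
  res <- cc_steady_state(encoded$mat, encoded$reg, env_vector(env), y0,
                         t_max = control$t_max, rtol = control$rtol,
                         atol = control$atol, conv_tol = control$conv_tol,
                         h_max = control$h_max,
                         method = control$method %||% "rkc",
                         f_max = control$f_max %||% 50000)
  st <- res$state
  state <- cell_state(st[[1]], st[[2]],
                      setNames(st[-(1:2)], as.character(encoded$ids)))
  dev_A <- abs(st[[1]] - env$target_A) / env$target_A
  dev_X <- abs(st[[2]] - env$target_X) / env$target_X
  out <- structure(
    list(state = state, converged = isTRUE(res$converged) && !isTRUE(res$diverged),
         diverged = isTRUE(res$diverged), deviation_A = dev_A,
         deviation_X = dev_X, t = res$t),
    class = "vc_steady_state")
  out$score <- environment_score(out)
  out
}

#' @export
print.vc_steady_state <- function(x, ...) {
  cat(sprintf("<steady state> converged=%s A=%.4g X=%.4g devA=%.4g devX=%.4g score=%.4g\n",
              x$converged, x$state$A_int, x$state$X_int,
              x$deviation_A, x$deviation_X, x$score))
  invisible(x)
}

#' Per-environment performance score
#'
#' `score = 1 / (1 + deviation_A + deviation_X)`: equal to 1 exactly when
#' both internal concentrations sit on their targets, strictly decreasing in
#' each deviation, and 0 for cells whose dynamics failed to converge.
#'
#' @param ss A `vc_steady_state` (or any list with `converged`, `diverged`,
#'   `deviation_A`, `deviation_X`).
#' @return Score in `(0, 1]`, or 0 on non-convergence.
#' @export
environment_score <- function(ss) {
  if (!isTRUE(ss$converged) || isTRUE(ss$diverged)) return(0)
  1 / (1 + ss$deviation_A + ss$deviation_X)
}

#' Lifetime fitness of a cell
#'
#' The geometric mean of the per-environment scores of the (one to three)
#' resource conditions the cell experienced. The geometric mean is
#' non-decreasing in every score and strongly penalises failure in any single
#' condition, which is what selects for regulation rather than a fixed
#' compromise phenotype.
#'
#' @param scores Numeric vector of per-environment scores, length 1-3.
#' @return Fitness in `[0, 1]`.
#' @export
cell_fitness <- function(scores) {
  if (length(scores) < 1L || length(scores) > 3L)
    stop("cell_fitness: between 1 and 3 scores required", call. = FALSE)
  if (any(scores < 0 | scores > 1))
    stop("cell_fitness: scores must lie in [0, 1]", call. = FALSE)
  if (any(scores == 0)) return(0)
  exp(mean(log(scores)))
}

# Incrementally update an encoded genome after point mutations. Returns
# NULL when a structural event (or a wiring change) requires re-encoding
# the affected parts from scratch.
patch_encoded <- function(encoded, g, events) {
  for (ev in events) {
    if (ev$kind != "point") return(NULL)
    row <- match(ev$gene_id, encoded$ids)
    if (is.na(row)) return(NULL)
    if (ev$attr %in% c("operator", "bind_motif")) {
      encoded$reg <- regulator_indices(g)
      next
    }
    col <- switch(ev$attr,
      basal = 2L, ligand = 3L, K_lig = 4L, k_cat = 4L,
      eff_bound = 5L, K_A = 5L, K_Aext = 5L,
      eff_free = 6L, K_X = 6L, NULL)
    if (is.null(col)) return(NULL)
    encoded$mat[row, col] <- if (ev$attr == "ligand")
      (if (ev$new == "A") 0 else 1) else ev$new
  }
  encoded
}

# Fast path used by the population loop: per-environment scores for a set
# of external resource concentrations, entirely inside the compiled core.
eval_scores_fast <- function(encoded, env, A_ext_values, control) {
  cc_eval_scores(encoded$mat, encoded$reg, env_vector(env), A_ext_values,
                 env$target_A, env$target_X, t_max = control$t_max,
                 rtol = control$rtol, atol = control$atol,
                 conv_tol = control$conv_tol, h_max = control$h_max,
                 method = control$method %||% "rkc",
                 f_max = control$f_max %||% 50000)
}

#' Evaluate a cell's fitness over a set of environments
#'
#' @param g A `vc_genome`.
#' @param envs List of `vc_env` (one per experienced resource condition).
#' @param control Settings from [ss_control()].
#' @param encoded Optional pre-encoded genome.
#' @return List with `fitness` and the per-environment `scores`.
#' @export
evaluate_cell <- function(g, envs, control = ss_control(), encoded = NULL) {
  if (genome_size(g) == 0L) return(list(fitness = 0, scores = rep(0, length(envs))))
  if (is.null(encoded)) encoded <- encode_genome(g)
  scores <- vapply(envs, function(e)
    steady_state(g, e, control = control, encoded = encoded)$score, numeric(1))
  list(fitness = cell_fitness(scores), scores = scores)
}
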