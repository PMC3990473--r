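env0 <- environment_params()

test_that("quasi-steady-state TF binding follows the ligand saturation curve", {
  tf <- gene_tf(1L, op(c(0, 1)), 0.5, ligand = "A", bind_motif = op(c(1, 0)),
                K_lig = 2, eff_bound = 1, eff_free = -1)
  expect_equal(tf_activity(tf, cell_state(2, 0))[["bound"]], 0.5)
  expect_equal(tf_activity(tf, cell_state(0, 5))[["bound"]], 0)
  expect_equal(tf_activity(tf, cell_state(6, 0))[["bound"]], 0.75)
  tfx <- gene_tf(1L, op(c(0, 1)), 0.5, ligand = "X", bind_motif = op(c(1, 0)),
                 K_lig = 1, eff_bound = 1, eff_free = -1)
  expect_equal(tf_activity(tfx, cell_state(0, 3))[["bound"]], 0.75)
  expect_error(tf_activity(pump_enzyme_genome()$genes[[1]], cell_state(1, 1)),
               "not a TF")
})

test_that("expression rate multiplies exponential regulator contributions", {
  g <- toy_regulated_genome()
  net <- derive_network(g)
  st <- cell_state(1, 1, setNames(c(0.8, 1, 1, 1), as.character(1:4)))
  attr(st, "K_op") <- env0$K_op
  # unregulated gene: basal rate regardless of state
  expect_equal(expression_rate(g$genes[[4]], g, net, st), 0.5)
  # regulated gene: basal * exp(occ * (b*eb + (1-b)*ef)), hand-computed
  b <- 1 / (1 + 0.5)
  occ <- 0.8 / (0.8 + env0$K_op)
  w <- occ * (b * -1 + (1 - b) * 0.5)
  expect_equal(expression_rate(g$genes[[2]], g, net, st), 0.5 * exp(w))
  # neutral regulator (both effects zero) leaves the basal rate
  g2 <- g
  g2$genes[[1]]$eff_bound <- 0
  g2$genes[[1]]$eff_free <- 0
  expect_equal(expression_rate(g2$genes[[2]], g2, derive_network(g2), st), 0.5)
  # two regulators: contributions add in log space
  m <- g$genes[[2]]$operator
  g3 <- g
  g3$genes[[4]] <- gene_tf(4L, op(c(1, 1)), 0.5, ligand = "X",
                           bind_motif = m, K_lig = 1, eff_bound = 2,
                           eff_free = -1)
  net3 <- derive_network(g3)
  st3 <- cell_state(1, 1, setNames(c(0.8, 1, 1, 0.6), as.character(1:4)))
  attr(st3, "K_op") <- env0$K_op
  b2 <- 1 / (1 + 1)
  occ2 <- 0.6 / (0.6 + env0$K_op)
  w2 <- occ2 * (b2 * 2 + (1 - b2) * -1)
  expect_equal(expression_rate(g3$genes[[2]], g3, net3, st3),
               0.5 * exp(w + w2))
})

test_that("derivatives vanish at diffusion equilibrium and saturate correctly", {
  eg <- genome(list(), L = 4L)
  d <- derivatives(cell_state(env0$A_ext, 0), eg, derive_network(eg), env0)
  expect_equal(unname(d), c(0, 0))
  # single saturated catabolic enzyme: dX = conversion * k_cat * P
  g <- genome(list(gene_enzyme(1L, op(c(0, 1)), 0.5, "cat", k_cat = 2,
                               K_A = 0.01, K_X = 1)), L = 4L)
  st <- cell_state(100, 0, setNames(1, "1"))
  d <- derivatives(st, g, derive_network(g), env0)
  expect_equal(d[["X_int"]], env0$conversion_rate * 2 * 1 * (100 / 100.01))
  expect_equal(d[["P_1"]], 0.5 - env0$degradation * 1)
})

test_that("compiled derivatives agree with the R reference implementation", {
  set.seed(21)
  for (i in 1:4) {
    g <- random_test_genome(12L)
    net <- derive_network(g)
    enc <- vcellevo:::encode_genome(g)
    st <- cell_state(runif(1, 0, 2), runif(1, 0, 2),
                     setNames(runif(genome_size(g), 0, 2),
                              as.character(gene_ids(g))))
    want <- derivatives(st, g, net, env0)
    got <- vcellevo:::cc_derivatives(enc$mat, enc$reg,
                                     vcellevo:::env_vector(env0),
                                     c(st$A_int, st$X_int,
                                       st$protein[as.character(enc$ids)]))
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("toy pump+enzyme steady state matches an independent root-finding oracle", {
  skip_if_not_installed("pracma")
  g <- pump_enzyme_genome()
  ss <- steady_state(g, env0, control = ss_control(conv_tol = 1e-10))
  expect_true(ss$converged)
  P <- 0.5 / env0$degradation     # constitutive level, no regulation
  flux <- function(y) {
    A <- y[1]; X <- y[2]
    v_p <- 1.5 * P * (env0$A_ext / (0.5 + env0$A_ext)) * X / (0.5 + X)
    v_c <- 1 * P * A / (0.5 + A)
    c(env0$permeability * (env0$A_ext - A) + v_p - v_c,
      env0$conversion_rate * v_c - 2 * v_p)
  }
  # solve on the log scale so the root search stays in the positive orthant
  root <- exp(pracma::fsolve(function(z) flux(exp(z)), c(0, 0))$x)
  expect_equal(ss$state$A_int, root[1], tolerance = 1e-6)
  expect_equal(ss$state$X_int, root[2], tolerance = 1e-6)
  expect_equal(unname(ss$state$protein), c(P, P), tolerance = 1e-6)
})

test_that("trajectory endpoint agrees with an independent stiff ODE solver", {
  skip_if_not_installed("deSolve")
  g <- make_viable_genome()
  net <- derive_network(g)
  init <- default_cell_state(g, env0)
  rhs <- function(t, y, parms) {
    st <- cell_state(max(y[1], 0), max(y[2], 0),
                     setNames(pmax(y[-(1:2)], 0), as.character(gene_ids(g))))
    list(unname(derivatives(st, g, net, env0)))
  }
  y0 <- c(init$A_int, init$X_int, unname(init$protein))
  sol <- deSolve::lsoda(y0, times = c(0, 400), func = rhs,
                        rtol = 1e-9, atol = 1e-10)
  ss <- steady_state(g, env0, control = ss_control(conv_tol = 1e-9))
  expect_equal(ss$state$A_int, unname(sol[2, 2]), tolerance = 1e-5)
  expect_equal(ss$state$X_int, unname(sol[2, 3]), tolerance = 1e-5)
})

test_that("steady state is solver- and tolerance-independent", {
  g <- make_viable_genome()
  a <- steady_state(g, env0, control = ss_control(rtol = 1e-6, conv_tol = 1e-8))
  b <- steady_state(g, env0, control = ss_control(rtol = 1e-8, conv_tol = 1e-8))
  d <- steady_state(g, env0, control = ss_control(rtol = 1e-8, conv_tol = 1e-8,
                                                  method = "rk45", h_max = 5))
  expect_equal(a$state$A_int, b$state$A_int, tolerance = 1e-6)
  expect_equal(a$state$X_int, b$state$X_int, tolerance = 1e-6)
  expect_equal(a$state$A_int, d$state$A_int, tolerance = 1e-6)
  expect_equal(a$state$X_int, d$state$X_int, tolerance = 1e-6)
})

test_that("steady state handles degenerate genomes per contract", {
  eg <- genome(list(), L = 4L)
  ss <- steady_state(eg, env0, init = cell_state(env0$A_ext, 0))
  expect_true(ss$converged)
  expect_equal(ss$state$A_int, env0$A_ext)
  expect_equal(ss$state$X_int, 0)
  # internal A exactly on target gives zero deviation
  envT <- environment_params(A_ext = env0$target_A)
  ssT <- steady_state(eg, envT, init = cell_state(envT$target_A, 0))
  expect_equal(ssT$deviation_A, 0)
  # with no sinks or sources, A converges to A_ext and constitutive
  # proteins to basal/degradation (closed-form limits)
  gP <- genome(list(gene_tf(1L, op(c(0, 1)), 0.7, ligand = "A",
                            bind_motif = op(c(1, 0)), K_lig = 1,
                            eff_bound = 1, eff_free = 1)), L = 4L)
  ssP <- steady_state(gP, env0, init = cell_state(0.2, 0.3,
                                                  setNames(0.01, "1")),
                      control = ss_control(conv_tol = 1e-9))
  expect_equal(ssP$state$A_int, env0$A_ext, tolerance = 1e-5)
  expect_equal(unname(ssP$state$protein), 0.7 / env0$degradation,
               tolerance = 1e-5)
})

test_that("environment score and lifetime fitness follow the stated forms", {
  mk <- function(dA, dX, conv = TRUE)
    list(converged = conv, diverged = FALSE, deviation_A = dA, deviation_X = dX)
  expect_equal(environment_score(mk(0, 0)), 1)
  expect_equal(environment_score(mk(1, 0)), 0.5)
  expect_equal(environment_score(mk(0.5, 0.5)), 0.5)
  expect_equal(environment_score(mk(0, 0, conv = FALSE)), 0)
  # strictly decreasing in each deviation
  expect_lt(environment_score(mk(0.4, 0.2)), environment_score(mk(0.3, 0.2)))
  expect_lt(environment_score(mk(0.4, 0.3)), environment_score(mk(0.4, 0.2)))
  expect_equal(cell_fitness(c(1, 1, 1)), 1)
  expect_equal(cell_fitness(c(0.25, 1)), 0.5)
  expect_equal(cell_fitness(0.7), 0.7)
  expect_error(cell_fitness(numeric()), "between 1 and 3")
  expect_error(cell_fitness(rep(0.5, 4)), "between 1 and 3")
  # monotone: raising any score never lowers fitness, over a random grid
  set.seed(31)
  for (i in 1:50) {
    s <- runif(3)
    j <- sample(3, 1)
    s2 <- s
    s2[j] <- min(1, s[j] + runif(1, 0, 1 - s[j]))
    expect_gte(cell_fitness(s2), cell_fitness(s) - 1e-12)
  }
})
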