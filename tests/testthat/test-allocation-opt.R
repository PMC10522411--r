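test_that("the objective maps infeasibility to the penalty value", {
  p <- default_parameters()
  penalty <- 1 / .Machine$double.eps
  # free fractions exhausting the budget drive the ribosomal residual
  # negative
  expect_identical(objective(c(0.5, 0.4, 0.3), p, "core"), penalty)
  expect_identical(objective(c(-0.01, 0.2, 0.1), p, "core"), penalty)
  # a feasible allocation returns ln 2 / mu of its steady state
  free <- c(0.2, 0.2, 0.2)  # f_C, f_Af, f_N; residual f_R = 0.2
  td <- objective(free, p, "core")
  ss <- solve_steady_state(balanced_core_allocation(), p, variant = "core")
  expect_equal(td, log(2) / ss$mu_ss, tolerance = 1e-9)
})

test_that("the zero-subset family skips structurally dead restarts", {
  fam_core <- cgram:::zero_subset_family(model_variant("core"))
  # zeroable in core: f_C only (f_Af must stay, f_Ar already forced)
  expect_length(fam_core, 2L)
  fam_two <- cgram:::zero_subset_family(model_variant("two_pathway"))
  # subsets of {f_C, f_Af, f_Ar} minus those killing both pathways
  expect_length(fam_two, 6L)
  fam_full <- cgram:::zero_subset_family(model_variant("full"))
  expect_length(fam_full, 24L)
  for (s in fam_full)
    expect_false(all(c("f_Af", "f_Ar") %in% s))
})

test_that("core optimization is feasible, deterministic and locally optimal", {
  p <- default_parameters()  # default k_C = 10
  res <- optimize_allocation(p, "core", fast_opts)
  f <- res$f_opt
  expect_equal(sum(f), 1, tolerance = 1e-9)
  expect_true(all(f >= 0))
  expect_identical(unname(f[c("f_Kre", "f_Kex", "f_Ar")]), rep(0, 3))
  expect_equal(f[["f_Z"]], p$f_Z)
  expect_equal(res$doubling_time, log(2) / res$mu_opt, tolerance = 1e-12)
  # restart dominance (up to the tie-break band)
  ok <- res$restart_log$feasible
  expect_gte(res$mu_opt,
             max(res$restart_log$mu[ok]) * (1 - 2 * fast_opts$tie_tol))
  # determinism: no randomness beyond the fixed initial simplex
  res2 <- optimize_allocation(p, "core", fast_opts)
  expect_identical(res$f_opt, res2$f_opt)
  expect_identical(res$mu_opt, res2$mu_opt)

  # local optimality: random feasible perturbations projected back to the
  # constraint do not improve the growth rate
  set.seed(19)
  labs <- c("f_C", "f_Af", "f_N", "f_R")
  worst <- -Inf
  for (i in 1:50) {
    g <- f
    d <- rnorm(4) * 1e-3
    d <- d - mean(d)  # stay on the constraint plane
    g[labs] <- pmax(unname(f[labs]) + d, 0)
    g[labs] <- g[labs] / sum(g[labs]) * (1 - p$f_Z)
    ss <- solve_steady_state(g, p, variant = "core",
                             options = fast_opts$solver)
    if (ss$converged) worst <- max(worst, ss$mu_ss)
  }
  expect_lte(worst, res$mu_opt + 1e-6)
})

test_that("impossible optimizations raise an explicit no-solution error", {
  # both transporters effectively dead: the doubling time exceeds the
  # penalty scale in every restart, so no restart is feasible
  p <- default_parameters(k_C = 1e-20, k_N = 1e-20)
  expect_error(optimize_allocation(p, "core", opt_options(nm_max_iter = 30L)),
               "no feasible allocation")
})

test_that("two-pathway optima express exactly one amino-acid pathway", {
  for (kC in c(0.3, 10)) {
    res <- optimize_allocation(default_parameters(k_C = kC), "two_pathway",
                               fast_opts)
    f <- res$f_opt
    expressed <- c(f[["f_Af"]] > 1e-4, f[["f_Ar"]] > 1e-4)
    expect_identical(sum(expressed), 1L)
  }
})

test_that("optimal growth is monotone in the carbon uptake efficiency", {
  mus <- vapply(c(0.1, 1, 10, 100), function(kC) {
    optimize_allocation(default_parameters(k_C = kC), "core",
                        fast_opts)$mu_opt
  }, numeric(1))
  expect_true(all(diff(mus) > -1e-6))
})
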