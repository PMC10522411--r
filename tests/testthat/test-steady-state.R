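test_that("initial condition follows the 0.05 / 0.8 f rule", {
  f <- balanced_core_allocation()
  x0 <- initial_condition(f, "full")
  expect_equal(sum(x0), 1.0)
  expect_equal(unname(x0[c("a", "k", "c", "n")]), rep(0.05, 4))
  expect_equal(unname(x0[5:12]), 0.8 * unname(f))
  # half-ribosomal allocation seeds r0 = 0.40
  f2 <- allocation_vector(f_Af = 0.2, f_N = 0.1, f_R = 0.5, f_Z = 0.2)
  expect_equal(initial_condition(f2, "full")[["r"]], 0.40)
  # reduced variants start without ketoacid; total 0.95
  x0c <- initial_condition(f, "core")
  expect_identical(x0c[["k"]], 0)
  expect_equal(sum(x0c), 0.95)
})

test_that("the core model reaches balanced growth from the standard start", {
  p <- default_parameters()
  f <- balanced_core_allocation()
  ss <- solve_steady_state(f, p, variant = "core")
  expect_true(ss$converged)
  expect_false(ss$degenerate)
  expect_gt(ss$mu_ss, 0)
  expect_equal(sum(ss$x_ss), 1, tolerance = 1e-8)
  expect_lt(ss$residual, 1e-9)
  expect_equal(ss$mu_ss, growth_rate(ss$x_ss, p), tolerance = 1e-12)
  # balanced growth: every expressed protein satisfies e_i mu = f_i j_R
  jR <- compute_fluxes(ss$x_ss, p)[["j_R"]]
  for (i in which(unname(f) > 0)) {
    expect_equal(ss$x_ss[[4 + i]] * ss$mu_ss, unname(f)[i] * jR,
                 tolerance = 1e-8)
  }
  # forced zeros stay zero
  expect_identical(unname(ss$x_ss[c("k", "e_Kre", "e_Kex", "e_Ar")]),
                   rep(0, 4))
})

test_that("solve_steady_state enforces variant forced zeros", {
  f_bad <- allocation_vector(f_Ar = 0.2, f_Af = 0.2, f_C = 0.2, f_N = 0.1,
                             f_R = 0.1, f_Z = 0.2)
  expect_error(solve_steady_state(f_bad, default_parameters(),
                                  variant = "core"),
               "forced zeros")
})

test_that("steady state is idempotent and solver-independent", {
  p <- default_parameters()
  f <- balanced_core_allocation()
  ss <- solve_steady_state(f, p, variant = "core")
  # restarting from the converged state moves nothing
  ss2 <- solve_steady_state(f, p, variant = "core", x0 = ss$x_ss)
  expect_true(ss2$converged)
  expect_lt(max(abs(ss2$x_ss - ss$x_ss)), 1e-8)
  # halving the integrator tolerances leaves mu essentially unchanged
  tight <- ss_options(rtol = 5e-9, atol = 5e-11)
  ss3 <- solve_steady_state(f, p, variant = "core", options = tight)
  expect_lt(abs(ss3$mu_ss - ss$mu_ss), 1e-6)
})

test_that("event-based detection agrees with brute-force long integration", {
  p <- default_parameters()
  f <- balanced_core_allocation()
  ss <- solve_steady_state(f, p, variant = "core")
  long <- cgram:::integrate_to_time(f, p, "core", t_end = 1e4)
  expect_lt(max(abs(ss$x_ss - long$x)), 1e-6)
  expect_lt(abs(ss$mu_ss - long$mu), 1e-6)
})

test_that("degenerate allocations short-circuit to flagged zero growth", {
  p <- default_parameters()
  # no ribosome: nothing can be synthesized
  f0 <- allocation_vector(f_C = 0.3, f_Af = 0.3, f_N = 0.2, f_Z = 0.2)
  ss0 <- solve_steady_state(f0, p, variant = "core")
  expect_false(ss0$converged)
  expect_true(ss0$degenerate)
  expect_identical(ss0$mu_ss, 0)
  expect_identical(ss0$steps, 0L)
  # no amino-acid synthesis pathway at all
  f1 <- allocation_vector(f_C = 0.3, f_N = 0.2, f_R = 0.3, f_Z = 0.2)
  ss1 <- solve_steady_state(f1, p, variant = "core")
  expect_true(ss1$degenerate)
})

test_that("regulated steady states satisfy the regulation rule", {
  p <- default_parameters(k_C = 100)
  base <- allocation_vector(f_C = 0.25, f_Af = 0.3, f_N = 0.1, f_R = 0.15,
                            f_Z = 0.2)
  ss <- solve_steady_state_regulated(base, p, delta = 3, variant = "core")
  expect_true(ss$converged)
  expect_gt(ss$mu_ss, 0)
  expect_equal(sum(ss$x_ss), 1, tolerance = 1e-8)
  # realized ribosomal allocation equals delta * a at the steady state
  expect_equal(ss$f_ss[["f_R"]], 3 * ss$x_ss[["a"]], tolerance = 1e-9)
  # and the ribosome pool is consistent with it: e_i mu = f_i j_R
  jR <- compute_fluxes(ss$x_ss, p)[["j_R"]]
  expect_equal(ss$x_ss[["r"]] * ss$mu_ss, ss$f_ss[["f_R"]] * jR,
               tolerance = 1e-8)
})

test_that("nonnegativity is preserved along trajectories", {
  set.seed(5)
  p <- default_parameters(gamma_K = 0.6)
  for (i in 1:5) {
    f <- random_allocation()
    for (t_end in c(0.5, 5)) {
      r <- cgram:::integrate_to_time(f, p, "full", t_end = t_end)
      expect_true(all(r$x >= 0))
    }
  }
})
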