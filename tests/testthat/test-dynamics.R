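test_that("fluxes follow Michaelis-Menten kinetics and products thereof", {
  p <- default_parameters()
  # no catalyst, no flux
  x0 <- concentration_state(a = 0.3, k = 0.1, c = 0.3, n = 0.3)
  expect_true(all(compute_fluxes(x0, p) == 0))
  # ribosomal flux at half saturation: k_R * r * 1/2
  x1 <- concentration_state(a = p$a_sat, r = 0.1)
  expect_equal(unname(compute_fluxes(x1, p)[["j_R"]]), 6.46 * 0.1 * 0.5)
  # two-substrate product form at double half-saturation: 1/2 * 1/2
  x2 <- concentration_state(c = p$c_sat, n = p$n_sat, e_Af = 0.2)
  expect_equal(unname(compute_fluxes(x2, p)[["j_Af"]]), 15 * 0.2 * 0.25)
  # uptake is first order in the transporter only
  x3 <- concentration_state(e_C = 0.1, e_N = 0.05)
  j3 <- compute_fluxes(x3, p)
  expect_equal(unname(j3[["j_C"]]), 1.0)
  expect_equal(unname(j3[["j_N"]]), 1.0)
  expect_error(compute_fluxes(c(x0[-1], a = -0.1), p), "nonnegative")
})

test_that("growth rate is net import: uptake minus excretion", {
  p <- default_parameters()
  expect_identical(growth_rate(concentration_state(a = 1), p), 0)
  expect_equal(growth_rate(concentration_state(e_C = 0.1), p), 1.0)
  # excretion can push it negative; value is returned unclipped
  x <- concentration_state(k = 1, e_Kex = 0.2)
  expect_lt(growth_rate(x, p), 0)
  # identity: mu equals the total mass production sum(S j)
  set.seed(42)
  for (i in 1:20) {
    x <- random_state()
    f <- random_allocation()
    mu <- growth_rate(x, p)
    expect_equal(sum(stoichiometry_matrix(f, p) %*% compute_fluxes(x, p)),
                 mu, tolerance = 1e-12)
  }
})

test_that("stoichiometry columns balance mass", {
  p <- default_parameters(gamma_K = 0.6)
  f <- random_allocation()
  S <- stoichiometry_matrix(f, p)
  cs <- colSums(S)
  # internal reactions conserve mass, uptake imports, excretion exports
  expect_equal(unname(cs[c("j_Kre", "j_Af", "j_Ar", "j_R")]), rep(0, 4),
               tolerance = 1e-15)
  expect_equal(unname(cs[c("j_C", "j_N")]), c(1, 1), tolerance = 1e-15)
  expect_equal(unname(cs[["j_Kex"]]), -1, tolerance = 1e-15)
})

test_that("compiled rhs equals the plain-R stoichiometry oracle", {
  set.seed(7)
  for (i in 1:25) {
    p <- default_parameters(gamma_K = runif(1, 0, 0.9),
                            k_C = runif(1, 0.5, 50),
                            k_Kre = runif(1, 0, 20))
    x <- random_state(total = runif(1, 0.5, 1.5))
    f <- random_allocation()
    oracle <- unname(drop(stoichiometry_matrix(f, p) %*%
                            compute_fluxes(x, p))) -
      growth_rate(x, p) * unname(x)
    expect_equal(unname(rhs(x, f, p)), oracle, tolerance = 1e-13)
  }
})

test_that("mass conservation: derivatives sum to mu (1 - sum x)", {
  set.seed(11)
  p <- default_parameters(gamma_K = 0.5)
  for (i in 1:25) {
    total <- runif(1, 0.3, 1.7)
    x <- random_state(total = total)
    f <- random_allocation()
    lhs <- sum(rhs(x, f, p))
    expect_equal(lhs, growth_rate(x, p) * (1 - total), tolerance = 1e-12)
  }
  # exactly zero on the simplex
  x1 <- random_state(total = 1)
  expect_equal(sum(rhs(x1, random_allocation(), p)), 0, tolerance = 1e-12)
})

test_that("allocation structure propagates into protein synthesis", {
  p <- default_parameters()
  x <- concentration_state(a = 0.2, c = 0.1, n = 0.1, e_Af = 0.1, r = 0.3,
                           z = 0.2)
  f <- allocation_vector(f_R = 1)  # all flux to ribosomes
  dx <- rhs(x, f, p)
  mu <- growth_rate(x, p)
  jR <- unname(compute_fluxes(x, p)[["j_R"]])
  expect_equal(unname(dx[["r"]]), jR - mu * 0.3)
  # every other protein only dilutes
  others <- c("e_Kre", "e_Kex", "e_C", "e_Af", "e_Ar", "e_N", "z")
  expect_equal(unname(dx[others]), unname(-mu * x[others]))
})

test_that("analytic Jacobian matches finite differences", {
  set.seed(3)
  p <- default_parameters(gamma_K = 0.4, k_Kre = 8)
  pv <- cgram:::as_par_vector(p)
  x <- unname(random_state())
  f <- unname(random_allocation())
  J <- cgram:::cg_jac_cpp(x, f, pv)
  h <- 1e-7
  for (q in seq_len(12)) {
    xp <- x; xp[q] <- xp[q] + h
    xm <- x; xm[q] <- max(xm[q] - h, 0)
    fd <- (cgram:::cg_rhs_cpp(xp, f, pv) - cgram:::cg_rhs_cpp(xm, f, pv)) /
      (xp[q] - xm[q])
    expect_equal(J[, q], fd, tolerance = 1e-5)
  }
})

test_that("regulated allocation clamps and rescales", {
  p <- default_parameters()
  base <- allocation_vector(f_C = 0.25, f_Af = 0.25, f_N = 0.1, f_R = 0.2,
                            f_Z = 0.2)
  # a = a0: ribosomal fraction clamps at zero
  f0 <- regulated_allocation(0.05, base, p, delta = 5, a0 = 0.05)
  expect_identical(f0[["f_R"]], 0)
  expect_equal(sum(f0), 1, tolerance = 1e-12)
  # steep regulation: clamps at 1 - f_Z and zeroes metabolism
  f1 <- regulated_allocation(0.5, base, p, delta = 100)
  expect_equal(f1[["f_R"]], 1 - p$f_Z)
  expect_equal(unname(f1[c("f_C", "f_Af", "f_N")]), rep(0, 3))
  # intermediate: metabolic proportions preserved
  f2 <- regulated_allocation(0.04, base, p, delta = 5)
  expect_equal(f2[["f_R"]], 0.2)
  expect_equal(f2[["f_C"]] / f2[["f_Af"]], 1, tolerance = 1e-12)
  expect_equal(sum(f2), 1, tolerance = 1e-12)
  # rescaling impossible: no metabolic base fractions at all
  base0 <- allocation_vector(f_R = 0.8, f_Z = 0.2)
  expect_error(regulated_allocation(0.04, base0, p, delta = 5),
               "infeasible")
  # regulated rhs agrees with fixed-allocation rhs at the realized f
  x <- concentration_state(a = 0.04, c = 0.1, n = 0.1, e_C = 0.1,
                           e_Af = 0.15, e_N = 0.05, r = 0.2, z = 0.2)
  expect_equal(rhs_regulated(x, p, delta = 5, base_f = base),
               rhs(x, f2, p), tolerance = 1e-13)
})
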