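test_that("default parameters carry the published values", {
  p <- default_parameters()
  expect_equal(p$k_R, 6.46)
  expect_equal(p$a_sat, 0.0167)
  expect_equal(c(p$k_sat, p$c_sat, p$n_sat), rep(0.0167, 3))
  expect_equal(c(p$k_Kre, p$k_Kex, p$k_C, p$k_Af, p$k_Ar, p$k_N),
               c(10, 20, 10, 15, 7.5, 20))
  expect_identical(p$alpha_Cf, 48 / 55)
  expect_identical(p$alpha_Cr, 24 / 31)
  expect_identical(p$gamma_K, 0)
  expect_identical(gamma_N(p), 1)
  expect_equal(p$f_Z, 0.2)
  # complements close exactly
  expect_identical(p$alpha_Cf + alpha_Nf(p), 1)
  expect_identical(p$alpha_Cr + alpha_Nr(p), 1)
  expect_identical(p$gamma_K + gamma_N(p), 1)
})

test_that("parameter validation is eager and field-specific", {
  expect_error(default_parameters(k_C = -1), "k_C")
  expect_error(default_parameters(k_C = 0), "k_C")
  expect_error(default_parameters(gamma_K = 1.5), "gamma_K")
  expect_error(default_parameters(f_Z = 1), "f_Z")
  expect_error(default_parameters(nonsense = 1), "unknown")
  # submodels may disable these
  expect_silent(p <- default_parameters(k_Kre = 0, k_Kex = 0, k_Ar = 0))
  expect_error(default_parameters(a_sat = NA_real_), "a_sat")
})

test_that("gamma_from_cn_ratio implements the elemental mass-fraction rule", {
  expect_equal(gamma_from_cn_ratio(2), 12 / 19, tolerance = 1e-15)
  expect_equal(gamma_from_cn_ratio(9), 54 / 61, tolerance = 1e-15)
  expect_identical(gamma_from_cn_ratio(0), 0)
  expect_error(gamma_from_cn_ratio(-1), "nonnegative")
  # strictly increasing and bounded by 1; the 0..20 grid gives 41 distinct
  # values up to 240/254
  grid <- seq(0, 20, by = 0.5)
  g <- gamma_from_cn_ratio(grid)
  expect_length(unique(g), 41L)
  expect_true(all(diff(g) > 0))
  expect_true(all(g >= 0 & g < 1))
  expect_equal(max(g), 240 / 254, tolerance = 1e-15)
})

test_that("alpha_from_carbon_atoms reproduces the table stoichiometries", {
  expect_equal(alpha_from_carbon_atoms(4), 24 / 31, tolerance = 1e-15)
  expect_equal(alpha_from_carbon_atoms(8), 48 / 55, tolerance = 1e-15)
  expect_identical(alpha_from_carbon_atoms(0), 0)
  expect_error(alpha_from_carbon_atoms(-0.1), "nonnegative")
  # complement closes exactly (mass balance of amino-acid synthesis)
  p <- default_parameters(alpha_Cr = alpha_from_carbon_atoms(4))
  expect_identical(p$alpha_Cr + alpha_Nr(p), 1)
})

test_that("model variants force the right structure", {
  core <- model_variant("core")
  expect_setequal(core$forced_zero, c("f_Kre", "f_Kex", "f_Ar"))
  expect_true(core$k0_zero)
  two <- model_variant("two_pathway")
  expect_setequal(two$forced_zero, c("f_Kre", "f_Kex"))
  full <- model_variant("full")
  expect_length(full$forced_zero, 0L)
  expect_false(full$k0_zero)
  expect_error(model_variant("bogus"))

  # make_variant pairs parameters with the variant and zeroes gamma_K for
  # the reduced models
  m <- make_variant(default_parameters(gamma_K = 0.5), "core")
  expect_identical(m$params$gamma_K, 0)
  m2 <- make_variant(default_parameters(gamma_K = 0.5), "full")
  expect_identical(m2$params$gamma_K, 0.5)
  # build-up configuration is allowed but flagged
  expect_warning(
    make_variant(default_parameters(gamma_K = 0.5, k_Kre = 0, k_Kex = 0),
                 "full"),
    "build up")
})
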