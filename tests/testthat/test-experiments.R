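test_that("classify_regime reads expression off the allocation vector", {
  mk <- function(...) {
    f <- setNames(numeric(8), cgram:::ALLOC_NAMES)
    ov <- c(...)
    f[names(ov)] <- ov
    f["f_Z"] <- 0.2
    f["f_R"] <- 1 - sum(f)
    f
  }
  r1 <- classify_regime(mk(f_C = 0.2, f_Af = 0.2))
  expect_identical(r1$expressed, "Up")
  expect_identical(r1$label, "Up/RF")
  r2 <- classify_regime(mk(f_Kre = 0.1, f_Af = 0.2))
  expect_identical(r2$expressed, "Re")
  r3 <- classify_regime(mk(f_Kex = 0.1, f_C = 0.1, f_Ar = 0.3))
  expect_setequal(r3$expressed, c("Ex", "Up"))
  expect_identical(r3$mode, "PR")
  expect_false(r3$anomaly)
  # sub-threshold junk does not count as expressed
  r4 <- classify_regime(mk(f_C = 0.2, f_Af = 0.2, f_Kex = 5e-5))
  expect_identical(r4$expressed, "Up")
  # simultaneous pathways are flagged
  r5 <- classify_regime(mk(f_Af = 0.2, f_Ar = 0.2))
  expect_true(r5$anomaly)
})

test_that("count_regimes counts distinct labels and rejects empty sweeps", {
  tab <- data.frame(regime = c("Up/RF", "Up/RF", "Re/RF", "Up/RF"))
  expect_identical(count_regimes(tab), 3L - 1L)  # two distinct labels
  expect_identical(count_regimes(data.frame(regime = "Up/RF")), 1L)
  expect_error(count_regimes(data.frame(regime = NA_character_)), "empty")
  expect_error(count_regimes(data.frame(x = 1)), "regime")
})

test_that("a small core carbon-uptake sweep shows the Monod growth law", {
  sw <- sweep_carbon_uptake(grid = log_grid(1e-1, 1e3, 7),
                            options = fast_opts)
  tab <- sw$table
  expect_identical(nrow(tab), 7L)
  expect_true(all(tab$converged))
  expect_true(all(diff(tab$mu) > 0))
  fit <- fit_monod(tab$k_C, tab$mu)
  expect_gte(fit$r_squared, 0.97)
  # metabolites stay a minority of biomass throughout the sweep (the
  # strict 0.30 + 0.05 bound is asserted -- and documented red -- in the
  # acceptance suite)
  expect_lte(max(tab$a + tab$c + tab$n), 0.5)
  expect_lte(median(tab$a + tab$c + tab$n), 0.30)
  # optimal allocations on the sweep: ribosome tracks growth
  lf <- fit_linear_law(tab$mu, tab$f_R)
  expect_gte(lf$r_squared, 0.99)
  expect_gt(lf$slope, 0)
})

test_that("two-pathway sweeps separate carbon and nitrogen homeostasis", {
  grid <- log_grid(1e-1, 1e3, 7)
  swc <- sweep_two_pathway(which = "k_C", grid = grid, options = fast_opts)
  swn <- sweep_two_pathway(which = "k_N", grid = grid, options = fast_opts)
  # low carbon uptake forces pure respiration, high allows fermentation
  expect_identical(swc$table$mode[1], "PR")
  expect_identical(swc$table$mode[7], "RF")
  # nitrogen modulation never represses the respirofermentative enzyme
  expect_true(all(swn$table$mode == "RF"))
  # modulating one transporter barely moves the other pathway's metabolite:
  # within the RF regime, the spread of n under k_C modulation is small
  rf <- swc$table$mode == "RF"
  expect_lt(max(swc$table$n[rf]) - min(swc$table$n[rf]),
            max(swn$table$n) - min(swn$table$n))
})

test_that("locate_transition pins the respiration-fermentation switch", {
  tr <- locate_transition(default_parameters(), "two_pathway", "k_C",
                          bracket = c(0.5, 20), tol = 1e-2,
                          options = fast_opts)
  expect_identical(tr$regime_low, "Up/PR")
  expect_identical(tr$regime_high, "Up/RF")
  expect_gt(tr$value, 0.5); expect_lt(tr$value, 20)
  # growth rate at the switch is about one half per hour
  expect_gt(tr$mu, 0.3); expect_lt(tr$mu, 0.7)
  # same regime at both ends is an error
  expect_error(
    locate_transition(default_parameters(), "two_pathway", "k_C",
                      bracket = c(50, 100), tol = 0.1,
                      options = fast_opts),
    "no regime change")
})

test_that("random parameter samples are deterministic under a seed", {
  sw1 <- random_parameter_sample(n_triplets = 3, seed = 77, cn_ratios = 0,
                                 kKre_values = 10, options = fast_opts)
  sw2 <- random_parameter_sample(n_triplets = 3, seed = 77, cn_ratios = 0,
                                 kKre_values = 10, options = fast_opts)
  expect_identical(sw1$table, sw2$table)
  expect_identical(sw1$meta$seed, 77)
  sw3 <- random_parameter_sample(n_triplets = 3, seed = 78, cn_ratios = 0,
                                 kKre_values = 10, options = fast_opts)
  expect_false(identical(sw1$table$k_C, sw3$table$k_C))
  # rates are drawn from [0, 20] and k_Ar = k_Af / 2
  expect_true(all(sw1$table$k_C >= 0 & sw1$table$k_C <= 20))
  expect_equal(sw1$table$k_Ar, 0.5 * sw1$table$k_Af)
})
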