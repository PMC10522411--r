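# shared helpers: desk-scale optimizer options and random feasible objects

# relaxed simplex tolerances for sweeps inside the test suite; steady
# states behind each evaluation are still solved to the full residual
# criterion, so optima agree with the default protocol to ~1e-4
fast_opts <- cgram:::fast_opt_options()

# a random valid allocation vector (sums to 1, respects f_Z)
random_allocation <- function(f_Z = 0.2, zeros = character(0)) {
  labs <- setdiff(cgram:::ALLOC_NAMES, "f_Z")
  w <- stats::runif(length(labs))
  names(w) <- labs
  w[zeros] <- 0
  w <- w / sum(w) * (1 - f_Z)
  allocation_vector(f_Kre = w[["f_Kre"]], f_Kex = w[["f_Kex"]],
                    f_C = w[["f_C"]], f_Af = w[["f_Af"]],
                    f_Ar = w[["f_Ar"]], f_N = w[["f_N"]],
                    f_R = w[["f_R"]], f_Z = f_Z)
}

# a random nonnegative state with a given total mass
random_state <- function(total = 1) {
  x <- stats::runif(12)
  setNames(x / sum(x) * total, cgram:::STATE_NAMES)
}

# a hand-balanced allocation for the core model, converges quickly
balanced_core_allocation <- function() {
  allocation_vector(f_C = 0.2, f_Af = 0.2, f_N = 0.2, f_R = 0.2, f_Z = 0.2)
}
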