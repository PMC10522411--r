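#' Construct an allocation vector
#'
#' The eight translational allocation fractions: the share of ribosomal
#' protein-synthesis flux directed to each protein sector.  Components must
#' be nonnegative and sum to one.
#'
#' @param f_Kre,f_Kex,f_C,f_Af,f_Ar,f_N,f_R,f_Z allocation fractions.
#' @return A named numeric vector of class `cgram_alloc`.
#' @export
allocation_vector <- function(f_Kre = 0, f_Kex = 0, f_C = 0, f_Af = 0,
                              f_Ar = 0, f_N = 0, f_R = 0, f_Z = 0) {
  f <- c(f_Kre = f_Kre, f_Kex = f_Kex, f_C = f_C, f_Af = f_Af,
         f_Ar = f_Ar, f_N = f_N, f_R = f_R, f_Z = f_Z)
  validate_allocation(f)
  structure(f, class = "cgram_alloc")
}

validate_allocation <- function(f, tol = 1e-8) {
  if (length(f) != 8L || !is.numeric(f))
    stop("allocation vector must have 8 numeric components", call. = FALSE)
  if (any(!is.finite(f)) || any(f < 0))
    stop("allocation fractions must be finite and nonnegative",
         call. = FALSE)
  if (abs(sum(f) - 1) > tol)
    stop("allocation fractions must sum to 1 (got ", format(sum(f)), ")",
         call. = FALSE)
  invisible(f)
}

as_alloc_vector <- function(f) {
  if (is.null(names(f))) {
    if (length(f) != 8L) stop("allocation vector must have length 8",
                              call. = FALSE)
    f <- setNames(as.numeric(f), ALLOC_NAMES)
  } else {
    if (!all(ALLOC_NAMES %in% names(f)))
      stop("allocation vector is missing components: ",
           paste(setdiff(ALLOC_NAMES, names(f)), collapse = ", "),
           call. = FALSE)
    f <- setNames(as.numeric(f[ALLOC_NAMES]), ALLOC_NAMES)
  }
  f
}

#' Construct a concentration state
#'
#' The twelve biomass mass fractions: metabolites `a` (amino acid), `k`
#' (ketoacid), `c` (carbon), `n` (free nitrogen), the six catalytic
#' enzymes, the ribosome `r` and housekeeping proteins `z`.  Components
#' must be nonnegative; the dynamics attract the total to 1, so the sum is
#' only required to be 1 at (and after) convergence to balanced growth.
#'
#' @param a,k,c,n,e_Kre,e_Kex,e_C,e_Af,e_Ar,e_N,r,z mass fractions.
#' @return A named numeric vector of class `cgram_state`.
#' @export
concentration_state <- function(a = 0, k = 0, c = 0, n = 0, e_Kre = 0,
                                e_Kex = 0, e_C = 0, e_Af = 0, e_Ar = 0,
                                e_N = 0, r = 0, z = 0) {
  x <- c(a = a, k = k, c = c, n = n, e_Kre = e_Kre, e_Kex = e_Kex,
         e_C = e_C, e_Af = e_Af, e_Ar = e_Ar, e_N = e_N, r = r, z = z)
  if (any(!is.finite(x)) || any(x < 0))
    stop("mass fractions must be finite and nonnegative", call. = FALSE)
  structure(x, class = "cgram_state")
}

as_state_vector <- function(x) {
  if (is.null(names(x))) {
    if (length(x) != 12L) stop("state vector must have length 12",
                               call. = FALSE)
    x <- setNames(as.numeric(x), STATE_NAMES)
  } else {
    if (!all(STATE_NAMES %in% names(x)))
      stop("state vector is missing components: ",
           paste(setdiff(STATE_NAMES, names(x)), collapse = ", "),
           call. = FALSE)
    x <- setNames(as.numeric(x[STATE_NAMES]), STATE_NAMES)
  }
  if (any(!is.finite(x)) || any(x < 0))
    stop("mass fractions must be finite and nonnegative", call. = FALSE)
  x
}

#' Specific fluxes catalysed by the protein sectors
#'
#' Michaelis-Menten kinetics (and products thereof for the two-substrate
#' amino-acid synthesis enzymes): linear in the catalysing enzyme, linear
#' in substrates at low concentration, saturating at high concentration.
#' The nutrient transporters are first order in the enzyme only; external
#' nutrient availability is carried by the catalytic rates `k_C` and
#' `k_N`.  This is the plain-R reference implementation; the integrator
#' uses an equivalent compiled version.
#'
#' @param x a concentration state (named or in standard order).
#' @param p a `cgram_params` object.
#' @return Named vector of the seven specific fluxes, per hour.
#' @export
compute_fluxes <- function(x, p) {
  x <- as_state_vector(x)
  sat <- function(s, K) s / (s + K)
  c(j_Kre = p$k_Kre * x[["e_Kre"]] * sat(x[["k"]], p$k_sat),
    j_Kex = p$k_Kex * x[["e_Kex"]] * sat(x[["k"]], p$k_sat),
    j_C   = p$k_C * x[["e_C"]],
    j_Af  = p$k_Af * x[["e_Af"]] * sat(x[["c"]], p$c_sat) *
            sat(x[["n"]], p$n_sat),
    j_Ar  = p$k_Ar * x[["e_Ar"]] * sat(x[["c"]], p$c_sat) *
            sat(x[["n"]], p$n_sat),
    j_N   = p$k_N * x[["e_N"]],
    j_R   = p$k_R * x[["r"]] * sat(x[["a"]], p$a_sat))
}

#' Instantaneous growth rate
#'
#' The growth rate equals the net import of nutrient mass from the
#' environment: uptake through the carbon and nitrogen transporters minus
#' ketoacid excretion, `mu = j_C + j_N - j_Kex`.  It can be negative when
#' excretion exceeds uptake; the value is returned as is (never clipped) so
#' callers can flag such states.
#'
#' @inheritParams compute_fluxes
#' @return Growth rate in 1/h.
#' @export
growth_rate <- function(x, p) {
  j <- compute_fluxes(x, p)
  unname(j[["j_C"]] + j[["j_N"]] - j[["j_Kex"]])
}

#' Stoichiometry matrix
#'
#' The 12 x 7 matrix `S` such that the dynamics read
#' `dx/dt = S j(x) - mu x`.  Internal reaction columns sum to zero (mass
#' balance), the two uptake columns to +1 and the excretion column to -1.
#' The ribosomal column distributes protein synthesis according to the
#' allocation vector `f`.
#'
#' @param f an allocation vector.
#' @param p a `cgram_params` object.
#' @return A 12 x 7 numeric matrix with dimnames.
#' @export
stoichiometry_matrix <- function(f, p) {
  f <- as_alloc_vector(f)
  S <- matrix(0, nrow = 12, ncol = 7,
              dimnames = list(STATE_NAMES, FLUX_NAMES))
  S["a", c("j_Af", "j_Ar", "j_R")] <- c(1, 1, -1)
  S["k", c("j_Kre", "j_Kex", "j_N")] <- c(-1, -1, p$gamma_K)
  S["c", c("j_Kre", "j_C", "j_Af", "j_Ar")] <-
    c(1, 1, -p$alpha_Cf, -p$alpha_Cr)
  S["n", c("j_Af", "j_Ar", "j_N")] <- c(-alpha_Nf(p), -alpha_Nr(p),
                                        gamma_N(p))
  S[5:12, "j_R"] <- f
  S
}

#' Time derivative of the concentration state
#'
#' Evaluates the right-hand side of the mass-fraction ODEs for a fixed
#' allocation: each metabolite pool balances its producing and consuming
#' fluxes, every protein sector receives `f_i j_R` of synthesis flux, and
#' every component is diluted at rate `mu`.  Summing the components gives
#' `mu (1 - sum(x))`, so total mass is attracted to 1.
#'
#' @param x a concentration state.
#' @param f an allocation vector.
#' @param p a `cgram_params` object.
#' @return Named numeric vector of time derivatives, per hour.
#' @export
rhs <- function(x, f, p) {
  x <- as_state_vector(x)
  f <- as_alloc_vector(f)
  dx <- cg_rhs_cpp(unname(x), unname(f), as_par_vector(p))
  setNames(dx, STATE_NAMES)
}

#' Regulated allocation from the amino-acid pool
#'
#' In regulated mode the ribosomal allocation is not optimized but follows
#' the amino-acid pool through the proportional rule
#' `f_R = delta (a - a0)`, clamped to `[0, 1 - f_Z]`.  The metabolic
#' entries of the base allocation are rescaled proportionally so the full
#' vector sums to one; the housekeeping fraction stays fixed.
#'
#' @param a amino-acid mass fraction.
#' @param base_f base allocation vector whose metabolic proportions are
#'   kept.
#' @param p a `cgram_params` object (supplies `f_Z`).
#' @param delta regulation gain (> 0).
#' @param a0 amino-acid offset of the regulation rule.
#' @return A named allocation vector.
#' @export
regulated_allocation <- function(a, base_f, p, delta, a0 = 0) {
  if (delta <= 0) stop("delta must be positive", call. = FALSE)
  base_f <- as_alloc_vector(base_f)
  f <- cg_regulated_alloc_cpp(a, unname(base_f), p$f_Z, delta, a0)
  setNames(f, ALLOC_NAMES)
}

#' Time derivative under amino-acid-regulated allocation
#'
#' As [rhs()], but the allocation is recomputed from the current
#' amino-acid pool via [regulated_allocation()] before evaluating the
#' dynamics.
#'
#' @inheritParams regulated_allocation
#' @param x a concentration state.
#' @return Named numeric vector of time derivatives, per hour.
#' @export
rhs_regulated <- function(x, p, delta, a0 = 0, base_f) {
  if (delta <= 0) stop("delta must be positive", call. = FALSE)
  x <- as_state_vector(x)
  base_f <- as_alloc_vector(base_f)
  dx <- cg_rhs_regulated_cpp(unname(x), unname(base_f), as_par_vector(p),
                             delta, a0)
  setNames(dx, STATE_NAMES)
}
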