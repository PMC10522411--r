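#' Construct a validated parameter set
#'
#' A parameter set collects the Michaelis constants, enzyme efficiencies
#' (catalytic rates, per hour), mass stoichiometries and the fixed
#' housekeeping allocation that together define a nutrient environment.
#' Validation is eager: downstream code assumes a valid set.
#'
#' The complements `gamma_N = 1 - gamma_K`, `alpha_Nf = 1 - alpha_Cf` and
#' `alpha_Nr = 1 - alpha_Cr` are derived on demand (see [gamma_N()]) rather
#' than stored, so the mass-balance constraints hold exactly.
#'
#' @param a_sat,k_sat,c_sat,n_sat Michaelis constants for the amino-acid,
#'   ketoacid, carbon and nitrogen pools (mass-fraction units,
#'   dimensionless, strictly positive).
#' @param k_Kre,k_Kex,k_C,k_Af,k_Ar,k_N,k_R enzyme efficiencies in 1/h.
#'   `k_Kre`, `k_Kex` and `k_Ar` may be zero (submodels); the others must
#'   be strictly positive.
#' @param alpha_Cf,alpha_Cr mass of carbon consumed per unit amino acid
#'   produced in respirofermentative / purely respiratory metabolism, in
#'   `[0, 1]`.
#' @param gamma_K mass fraction of nitrogen-compound uptake routed to the
#'   ketoacid pool, in `[0, 1]`.
#' @param f_Z fixed housekeeping allocation fraction, in `[0, 1)`; excluded
#'   from the growth-rate optimization.
#' @return An object of class `cgram_params` (a named list).
#' @seealso [default_parameters()], [gamma_from_cn_ratio()],
#'   [alpha_from_carbon_atoms()]
#' @export
parameter_set <- function(a_sat, k_sat, c_sat, n_sat,
                          k_Kre, k_Kex, k_C, k_Af, k_Ar, k_N, k_R,
                          alpha_Cf, alpha_Cr, gamma_K, f_Z) {
  p <- list(a_sat = a_sat, k_sat = k_sat, c_sat = c_sat, n_sat = n_sat,
            k_Kre = k_Kre, k_Kex = k_Kex, k_C = k_C, k_Af = k_Af,
            k_Ar = k_Ar, k_N = k_N, k_R = k_R,
            alpha_Cf = alpha_Cf, alpha_Cr = alpha_Cr,
            gamma_K = gamma_K, f_Z = f_Z)
  validate_parameter_set(p)
  structure(p, class = "cgram_params")
}

validate_parameter_set <- function(p) {
  for (nm in PARAM_NAMES) {
    v <- p[[nm]]
    if (is.null(v) || length(v) != 1L || !is.numeric(v) || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  strictly_pos <- c("a_sat", "k_sat", "c_sat", "n_sat", "k_C", "k_Af",
                    "k_N", "k_R")
  for (nm in strictly_pos)
    if (p[[nm]] <= 0)
      stop("parameter '", nm, "' must be strictly positive", call. = FALSE)
  for (nm in c("k_Kre", "k_Kex", "k_Ar"))
    if (p[[nm]] < 0)
      stop("parameter '", nm, "' must be nonnegative", call. = FALSE)
  for (nm in c("alpha_Cf", "alpha_Cr", "gamma_K"))
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop("parameter '", nm, "' must lie in [0, 1]", call. = FALSE)
  if (p$f_Z < 0 || p$f_Z >= 1)
    stop("parameter 'f_Z' must lie in [0, 1)", call. = FALSE)
  invisible(p)
}

#' Default model parametrization
#'
#' All Michaelis constants are 0.0167 (mass-fraction units); the enzyme
#' efficiencies are `k_Kre = 10`, `k_Kex = 20`, `k_C = 10`, `k_Af = 15`,
#' `k_Ar = 7.5`, `k_N = 20` and `k_R = 6.46` per hour.  The carbon
#' stoichiometries follow from elemental composition: proteinogenic amino
#' acids carry roughly four carbon atoms per nitrogen atom
#' (`alpha_Cr = 24/31`), and respirofermentative metabolism consumes about
#' twice that much carbon because the excess is lost as overflow products
#' (`alpha_Cf = 48/55`).  The default nitrogen source is carbon-free
#' (`gamma_K = 0`).  The housekeeping allocation defaults to `f_Z = 0.2`,
#' chosen so that the maximal ribosomal allocation matches fast-growing
#' *E. coli* proteome data.
#'
#' @param ... named overrides of individual parameters.
#' @return A `cgram_params` object.
#' @examples
#' default_parameters()$k_R
#' default_parameters(k_C = 1e3)$k_C
#' @export
default_parameters <- function(...) {
  p <- list(a_sat = 0.0167, k_sat = 0.0167, c_sat = 0.0167, n_sat = 0.0167,
            k_Kre = 10.0, k_Kex = 20.0, k_C = 10.0, k_Af = 15.0, k_Ar = 7.5,
            k_N = 20.0, k_R = 6.46,
            alpha_Cf = 48 / 55, alpha_Cr = 24 / 31,
            gamma_K = 0.0, f_Z = 0.20)
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), PARAM_NAMES)
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    p[names(overrides)] <- overrides
  }
  do.call(parameter_set, p)
}

#' Derived stoichiometric complements
#'
#' Mass balance requires `gamma_K + gamma_N = 1`, `alpha_Cf + alpha_Nf = 1`
#' and `alpha_Cr + alpha_Nr = 1`; the complements are computed from the
#' stored values so these sums hold exactly.
#'
#' @param p a `cgram_params` object.
#' @return A single number.
#' @export
gamma_N <- function(p) 1 - p$gamma_K

#' @rdname gamma_N
#' @export
alpha_Nf <- function(p) 1 - p$alpha_Cf

#' @rdname gamma_N
#' @export
alpha_Nr <- function(p) 1 - p$alpha_Cr

#' Ketoacid stoichiometry from a nutrient's carbon-to-nitrogen atom ratio
#'
#' For a nitrogen source carrying `cn_ratio` carbon atoms per nitrogen
#' atom, the mass fraction of uptake routed to the ketoacid pool is
#' `gamma_K = 12 cn / (12 cn + 14)`, using molar masses of 12 (carbon) and
#' 14 (nitrogen) g/mol.  Glycine (2 C per N) gives 12/19, isoleucine
#' (9 C per N) gives 54/61; ammonium (0 C) gives 0.
#'
#' @param cn_ratio nonnegative number(s): carbon atoms per nitrogen atom.
#' @return `gamma_K` value(s) in `[0, 1)`.
#' @examples
#' gamma_from_cn_ratio(2)   # 12/19
#' gamma_from_cn_ratio(9)   # 54/61
#' @export
gamma_from_cn_ratio <- function(cn_ratio) {
  if (!is.numeric(cn_ratio) || any(!is.finite(cn_ratio)) || any(cn_ratio < 0))
    stop("cn_ratio must be nonnegative and finite", call. = FALSE)
  12 * cn_ratio / (12 * cn_ratio + 14)
}

#' Carbon mass stoichiometry from a carbon-atom count
#'
#' Same mass-fraction formula as [gamma_from_cn_ratio()], applied to the
#' carbon demand of amino-acid synthesis: with `n` carbon atoms consumed
#' per nitrogen atom, `alpha_C = 12 n / (12 n + 14)`.  `n = 4` yields the
#' purely respiratory stoichiometry 24/31; `n = 8` (half the carbon lost to
#' overflow products) yields the respirofermentative 48/55.
#'
#' @param n_carbon_per_nitrogen nonnegative number(s).
#' @return `alpha_C` value(s) in `[0, 1)`.
#' @export
alpha_from_carbon_atoms <- function(n_carbon_per_nitrogen) {
  if (!is.numeric(n_carbon_per_nitrogen) ||
      any(!is.finite(n_carbon_per_nitrogen)) ||
      any(n_carbon_per_nitrogen < 0))
    stop("n_carbon_per_nitrogen must be nonnegative and finite",
         call. = FALSE)
  12 * n_carbon_per_nitrogen / (12 * n_carbon_per_nitrogen + 14)
}

#' Model variants
#'
#' Submodels are obtained by forcing parameters and allocations to zero:
#' * `core`: one amino-acid synthesis pathway; forces `f_Kre`, `f_Kex` and
#'   `f_Ar` to zero, `gamma_K = 0`, and a zero initial ketoacid pool.
#' * `two_pathway`: parallel respirofermentative and purely respiratory
#'   pathways; forces `f_Kre` and `f_Kex` to zero, `gamma_K = 0`, `k0 = 0`.
#' * `full`: nothing forced; ketoacid recycling and excretion available.
#'
#' @param name one of `"core"`, `"two_pathway"`, `"full"`.
#' @return A `cgram_variant` object with elements `name`,
#'   `forced_zero` (allocation labels held at zero) and `k0_zero`.
#' @export
model_variant <- function(name = c("core", "two_pathway", "full")) {
  name <- match.arg(name)
  forced <- switch(name,
                   core        = c("f_Kre", "f_Kex", "f_Ar"),
                   two_pathway = c("f_Kre", "f_Kex"),
                   full        = character(0))
  structure(list(name = name, forced_zero = forced,
                 k0_zero = name != "full"),
            class = "cgram_variant")
}

as_variant <- function(variant) {
  if (inherits(variant, "cgram_variant")) variant else model_variant(variant)
}

#' Pair a parameter set with a model variant
#'
#' Returns the parametrized model environment used by the steady-state
#' solver and the optimizer.  For the `core` and `two_pathway` variants the
#' ketoacid stoichiometry `gamma_K` is forced to zero.  A `full` model with
#' `gamma_K > 0` but both ketoacid enzymes disabled (`k_Kre = k_Kex = 0`)
#' is allowed -- the ketoacid then simply builds up -- but is flagged with
#' a warning.
#'
#' @param params a `cgram_params` object.
#' @param variant a `cgram_variant` or a variant name.
#' @return A `cgram_model` object with elements `params` and `variant`.
#' @export
make_variant <- function(params, variant = "full") {
  validate_parameter_set(params)
  variant <- as_variant(variant)
  if (variant$name != "full" && params$gamma_K != 0) {
    params$gamma_K <- 0
  }
  if (variant$name == "full" && params$gamma_K > 0 &&
      params$k_Kre == 0 && params$k_Kex == 0) {
    warning("gamma_K > 0 with k_Kre = k_Kex = 0: ketoacid can neither be ",
            "recycled nor excreted and will build up", call. = FALSE)
  }
  structure(list(params = params, variant = variant), class = "cgram_model")
}

as_model <- function(object, variant = NULL) {
  if (inherits(object, "cgram_model")) return(object)
  if (inherits(object, "cgram_params"))
    return(make_variant(object, if (is.null(variant)) "full" else variant))
  stop("expected a cgram_params or cgram_model object", call. = FALSE)
}

# parameter vector in the fixed order expected by the compiled core
as_par_vector <- function(p) {
  vapply(PARAM_NAMES, function(nm) as.numeric(p[[nm]]), numeric(1))
}

#' @export
print.cgram_params <- function(x, ...) {
  cat("<cgram_params>\n")
  for (nm in PARAM_NAMES) cat(sprintf("  %-9s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
print.cgram_variant <- function(x, ...) {
  cat("<cgram_variant> ", x$name, "\n", sep = "")
  if (length(x$forced_zero))
    cat("  forced zero:", paste(x$forced_zero, collapse = ", "), "\n")
  cat("  k0_zero:", x$k0_zero, "\n")
  invisible(x)
}
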