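#' Classify the metabolic regime of an optimal allocation
#'
#' A regime is the subset of the ketoacid recycling (`Re`), ketoacid
#' excretion (`Ex`) and canonical carbon uptake (`Up`) enzymes expressed at
#' the growth-rate optimum, together with the energy mode:
#' respirofermentative (`RF`) when the respirofermentative enzyme is
#' expressed, purely respiratory (`PR`) otherwise.  "Expressed" means the
#' allocation fraction exceeds `threshold`; the threshold only affects
#' reporting, never the optimizer.  Simultaneous expression of both
#' amino-acid pathways is flagged as an anomaly (the optimum uses exactly
#' one).
#'
#' @param f_opt an allocation vector at the optimum.
#' @param threshold expression threshold on allocation fractions.
#' @return A `cgram_regime` list with `expressed` (character subset of
#'   Re/Ex/Up), `mode` ("PR"/"RF"), `label` (e.g. `"Re+Up/RF"`) and
#'   `anomaly`.
#' @export
classify_regime <- function(f_opt, threshold = 1e-4) {
  f <- as_alloc_vector(f_opt)
  expressed <- c("Re", "Ex", "Up")[c(f[["f_Kre"]] > threshold,
                                     f[["f_Kex"]] > threshold,
                                     f[["f_C"]] > threshold)]
  rf <- f[["f_Af"]] > threshold
  rr <- f[["f_Ar"]] > threshold
  mode <- if (rf) "RF" else "PR"
  label <- paste0(if (length(expressed)) paste(expressed, collapse = "+")
                  else "none", "/", mode)
  structure(list(expressed = expressed, mode = mode, label = label,
                 anomaly = rf && rr),
            class = "cgram_regime")
}

new_sweep <- function(table, meta) {
  structure(list(table = table, meta = meta), class = "cgram_sweep")
}

# one optimized grid point flattened to a sweep row; failed optimizations
# are kept as flagged rows, never dropped
sweep_row <- function(p, variant, options, threshold = 1e-4) {
  res <- tryCatch(optimize_allocation(p, variant, options),
                  error = function(e) e)
  if (inherits(res, "error")) {
    row <- as.list(setNames(rep(NA_real_, 2 + 8 + 12),
                            c("mu", "doubling_time", ALLOC_NAMES,
                              STATE_NAMES)))
    row$regime <- NA_character_
    row$mode <- NA_character_
    row$converged <- FALSE
    return(as.data.frame(row, stringsAsFactors = FALSE))
  }
  ss <- solve_steady_state(res$f_opt, p, variant = variant,
                           options = options$solver)
  regime <- classify_regime(res$f_opt, threshold)
  row <- c(list(mu = res$mu_opt, doubling_time = res$doubling_time),
           as.list(res$f_opt), as.list(ss$x_ss),
           list(regime = regime$label, mode = regime$mode,
                converged = ss$converged))
  as.data.frame(row, stringsAsFactors = FALSE)
}

run_sweep <- function(grid, p_of_row, variant, options, threshold,
                      meta) {
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p_i <- p_of_row(grid[i, , drop = FALSE])
    rows[[i]] <- cbind(grid[i, , drop = FALSE],
                       sweep_row(p_i, variant, options, threshold))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  new_sweep(tab, meta)
}

#' Log-spaced sweep grid
#'
#' @param from,to range endpoints (positive).
#' @param n number of points, equidistant after log transformation.
#' @return Numeric vector of length `n`.
#' @export
log_grid <- function(from = 1e-2, to = 1e3, n = 41) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Carbon-uptake sweep of the core model
#'
#' Optimizes the allocation of the single-pathway core model at each value
#' of the carbon uptake efficiency `k_C` on a log grid, emulating growth
#' media of varying carbon quality.  The growth rate follows a Monod curve
#' in `k_C` and the optimal allocations vary near-linearly with `mu`.
#'
#' @param p base `cgram_params`.
#' @param grid `k_C` values (default 41 log-spaced points in
#'   `[1e-2, 1e3]` per hour).
#' @param options an [opt_options()] list.
#' @param threshold expression threshold for regime labels.
#' @return A `cgram_sweep`; `$table` has one row per grid point.
#' @export
sweep_carbon_uptake <- function(p = default_parameters(),
                                grid = log_grid(), options = opt_options(),
                                threshold = 1e-4) {
  run_sweep(data.frame(k_C = grid),
            function(row) { p$k_C <- row$k_C; p },
            model_variant("core"), options, threshold,
            meta = list(sweep = "carbon_uptake", variant = "core",
                        fixed = unclass(p)[setdiff(PARAM_NAMES, "k_C")],
                        grid = list(param = "k_C", values = grid)))
}

#' Uptake-rate sweep of the two-pathway model
#'
#' Varies either the carbon (`k_C`) or nitrogen (`k_N`) transporter
#' efficiency with both amino-acid synthesis pathways available.  Under
#' carbon modulation the optimum switches discontinuously between purely
#' respiratory (low `k_C`) and respirofermentative (high `k_C`) growth;
#' under nitrogen modulation it stays respirofermentative.
#'
#' @param p base `cgram_params`.
#' @param which `"k_C"` or `"k_N"`.
#' @param grid swept values (default 41 log-spaced in `[1e-2, 1e3]`).
#' @inheritParams sweep_carbon_uptake
#' @return A `cgram_sweep` whose rows carry the PR/RF mode.
#' @export
sweep_two_pathway <- function(p = default_parameters(),
                              which = c("k_C", "k_N"), grid = log_grid(),
                              options = opt_options(), threshold = 1e-4) {
  which <- match.arg(which)
  g <- data.frame(v = grid); names(g) <- which
  run_sweep(g,
            function(row) { p[[which]] <- row[[which]]; p },
            model_variant("two_pathway"), options, threshold,
            meta = list(sweep = "two_pathway", variant = "two_pathway",
                        fixed = unclass(p)[setdiff(PARAM_NAMES, which)],
                        grid = list(param = which, values = grid)))
}

#' Carbon-to-nitrogen ratio sweep of the full model
#'
#' Emulates growth on amino-acid nitrogen sources: for each
#' carbon-to-nitrogen atom ratio on the grid the ketoacid stoichiometry is
#' set via [gamma_from_cn_ratio()], and the allocation is optimized for
#' each ketoacid recycling efficiency in `kKre_values`.  Growth rate
#' decreases monotonically with the nutrient's carbon content, and the
#' expressed enzyme set partitions the sweep into distinct regimes.
#'
#' @param p base `cgram_params`.
#' @param kKre_values ketoacid recycling efficiencies to explore.
#' @param cn_grid carbon-to-nitrogen atom ratios.
#' @inheritParams sweep_carbon_uptake
#' @return A `cgram_sweep` with columns `k_Kre`, `cn_ratio`, `gamma_K`.
#' @export
sweep_cn_ratio <- function(p = default_parameters(),
                           kKre_values = c(10.0, 5.0),
                           cn_grid = seq(0, 20, by = 0.5),
                           options = opt_options(), threshold = 1e-4) {
  grid <- expand.grid(k_Kre = kKre_values, cn_ratio = cn_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$k_Kre, grid$cn_ratio), , drop = FALSE]
  grid$gamma_K <- gamma_from_cn_ratio(grid$cn_ratio)
  run_sweep(grid,
            function(row) {
              p$k_Kre <- row$k_Kre
              p$gamma_K <- row$gamma_K
              p
            },
            model_variant("full"), options, threshold,
            meta = list(sweep = "cn_ratio", variant = "full",
                        fixed = unclass(p)[setdiff(PARAM_NAMES,
                                                   c("k_Kre", "gamma_K"))],
                        grid = list(kKre_values = kKre_values,
                                    cn_grid = cn_grid)))
}

#' Phase diagram over nutrient carbon content and one enzyme efficiency
#'
#' Full-model regime map: the nutrient carbon-to-nitrogen ratio is crossed
#' with one of the ketoacid-metabolism efficiencies (`k_Kre`, `k_Kex` or
#' `k_N`) on a log-spaced grid, holding the other efficiencies at `fixed`.
#' Regime labels over the grid trace which of recycling, excretion and
#' carbon uptake the optimal cell expresses.
#'
#' @param p base `cgram_params`.
#' @param axis which efficiency to vary: `"k_Kre"`, `"k_Kex"` or `"k_N"`.
#' @param fixed named overrides applied before sweeping (e.g.
#'   `list(k_Kre = 5)` for the low-recycling panels).
#' @param grid_size points per axis (41 at paper scale; smaller for desk
#'   runs).
#' @param cn_range,efficiency_range axis ranges; the efficiency grid is
#'   equidistant after log transformation.
#' @inheritParams sweep_carbon_uptake
#' @return A `cgram_sweep` with columns `cn_ratio`, `gamma_K` and the
#'   varied efficiency.
#' @export
phase_diagram <- function(p = default_parameters(),
                          axis = c("k_Kre", "k_Kex", "k_N"),
                          fixed = list(), grid_size = 41,
                          cn_range = c(0, 20),
                          efficiency_range = c(1e-1, 1e3),
                          options = opt_options(), threshold = 1e-4) {
  axis <- match.arg(axis)
  if (length(fixed)) {
    bad <- setdiff(names(fixed), PARAM_NAMES)
    if (length(bad)) stop("unknown fixed parameter(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    p[names(fixed)] <- fixed
    validate_parameter_set(p)
  }
  cn_grid <- seq(cn_range[1], cn_range[2], length.out = grid_size)
  eff_grid <- log_grid(efficiency_range[1], efficiency_range[2], grid_size)
  grid <- expand.grid(cn_ratio = cn_grid, eff = eff_grid,
                      KEEP.OUT.ATTRS = FALSE)
  names(grid)[2] <- axis
  grid$gamma_K <- gamma_from_cn_ratio(grid$cn_ratio)
  run_sweep(grid,
            function(row) {
              p[[axis]] <- row[[axis]]
              p$gamma_K <- row$gamma_K
              p
            },
            model_variant("full"), options, threshold,
            meta = list(sweep = "phase_diagram", variant = "full",
                        axis = axis, fixed = fixed,
                        grid = list(cn_grid = cn_grid,
                                    efficiency = eff_grid)))
}

#' Random-parametrization sample of the full model
#'
#' Draws `n_triplets` rate triplets `(k_C, k_N, k_Af)` from independent
#' uniform distributions on `[0, 20]` per hour, sets `k_Ar = 0.5 k_Af`,
#' crosses them with the given carbon-to-nitrogen ratios and recycling
#' efficiencies, and optimizes each parametrization.  This probes whether
#' the ribosomal growth law and the `f_R`-versus-`a` relation are
#' properties of the model rather than artefacts of one sweep direction.
#'
#' @param n_triplets number of random rate triplets.
#' @param seed integer seed; recorded in the sweep metadata.
#' @param cn_ratios carbon-to-nitrogen atom ratios to cross with.
#' @param kKre_values recycling efficiencies to cross with.
#' @param p base `cgram_params`.
#' @inheritParams sweep_carbon_uptake
#' @return A `cgram_sweep`; rows carry the triplet, `cn_ratio`, `k_Kre`
#'   and the optimization outcome.
#' @export
random_parameter_sample <- function(n_triplets = 100, seed = 1,
                                    cn_ratios = c(0, 3, 6, 12),
                                    kKre_values = c(10.0, 5.0),
                                    p = default_parameters(),
                                    options = opt_options(),
                                    threshold = 1e-4) {
  if (n_triplets < 1) stop("n_triplets must be >= 1", call. = FALSE)
  set.seed(seed)
  triplets <- data.frame(triplet = seq_len(n_triplets),
                         k_C = runif(n_triplets, 0, 20),
                         k_N = runif(n_triplets, 0, 20),
                         k_Af = runif(n_triplets, 0, 20))
  triplets$k_Ar <- 0.5 * triplets$k_Af
  grid <- merge(expand.grid(triplet = triplets$triplet,
                            cn_ratio = cn_ratios, k_Kre = kKre_values,
                            KEEP.OUT.ATTRS = FALSE),
                triplets, by = "triplet")
  grid <- grid[order(grid$k_Kre, grid$cn_ratio, grid$triplet), ,
               drop = FALSE]
  grid$gamma_K <- gamma_from_cn_ratio(grid$cn_ratio)
  run_sweep(grid,
            function(row) {
              for (nm in c("k_C", "k_N", "k_Af", "k_Ar", "k_Kre",
                           "gamma_K"))
                p[[nm]] <- row[[nm]]
              # rates are drawn from [0, 20] and may be arbitrarily small
              # but must stay positive for a valid parameter set
              for (nm in c("k_C", "k_N", "k_Af"))
                p[[nm]] <- max(p[[nm]], 1e-6)
              p
            },
            model_variant("full"), options, threshold,
            meta = list(sweep = "random_parameter_sample", seed = seed,
                        n_triplets = n_triplets, cn_ratios = cn_ratios,
                        kKre_values = kKre_values,
                        fixed = unclass(p)[c("a_sat", "k_sat", "c_sat",
                                             "n_sat", "k_Kex", "k_R",
                                             "alpha_Cf", "alpha_Cr",
                                             "f_Z")]))
}

#' Count distinct metabolic regimes in a sweep
#'
#' Counts the distinct regime labels (expressed enzyme set plus energy
#' mode) over the converged rows of a sweep, each distinct label counted
#' once regardless of how many contiguous stretches show it.
#'
#' @param sweep a `cgram_sweep` (or its table).
#' @return Integer count.
#' @export
count_regimes <- function(sweep) {
  tab <- if (inherits(sweep, "cgram_sweep")) sweep$table else sweep
  if (is.null(tab$regime)) stop("sweep has no regime column", call. = FALSE)
  labels <- tab$regime[!is.na(tab$regime)]
  if (!length(labels)) stop("empty sweep: no classified rows",
                            call. = FALSE)
  length(unique(labels))
}

#' Localize a regime transition by bisection
#'
#' Bisects (geometrically) on a swept parameter until the bracket width is
#' below `tol` relative to its midpoint, classifying the optimal regime at
#' each midpoint; used e.g. to pin down the discontinuous
#' respiration-to-fermentation switch of the two-pathway model under
#' carbon-uptake modulation.
#'
#' @param p base `cgram_params`.
#' @param variant variant name or `cgram_variant`.
#' @param swept_param parameter name to bisect on.
#' @param bracket length-2 numeric; the regime must differ at the two
#'   endpoints.
#' @param tol relative bracket width at which to stop.
#' @param options an [opt_options()] list.
#' @param threshold expression threshold for regime labels.
#' @return A list with `value` (critical parameter value), `mu` (optimized
#'   growth rate there), `regime_low`, `regime_high`, `iterations`.
#' @export
locate_transition <- function(p, variant = "two_pathway",
                              swept_param = "k_C", bracket = c(1e-2, 1e3),
                              tol = 1e-3, options = opt_options(),
                              threshold = 1e-4) {
  stopifnot(length(bracket) == 2, all(bracket > 0))
  variant <- as_variant(variant)
  regime_at <- function(v) {
    p[[swept_param]] <- v
    res <- optimize_allocation(p, variant, options)
    list(label = classify_regime(res$f_opt, threshold)$label,
         mu = res$mu_opt)
  }
  lo <- min(bracket); hi <- max(bracket)
  rlo <- regime_at(lo); rhi <- regime_at(hi)
  if (rlo$label == rhi$label)
    stop("no regime change in bracket: both endpoints are '", rlo$label,
         "'", call. = FALSE)
  iter <- 0L
  while ((hi - lo) > tol * 0.5 * (hi + lo)) {
    mid <- sqrt(lo * hi)
    rmid <- regime_at(mid)
    if (rmid$label == rlo$label) { lo <- mid; rlo <- rmid }
    else { hi <- mid; rhi <- rmid }
    iter <- iter + 1L
    if (iter > 200L) break
  }
  mid <- sqrt(lo * hi)
  rmid <- regime_at(mid)
  list(value = mid, mu = rmid$mu, regime_low = rlo$label,
       regime_high = rhi$label, iterations = iter)
}

#' @export
print.cgram_sweep <- function(x, ...) {
  cat("<cgram_sweep> ", x$meta$sweep %||% "custom", ", ",
      nrow(x$table), " rows\n", sep = "")
  print(utils::head(x$table, 4))
  if (nrow(x$table) > 4) cat("  ...\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
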