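#' Optimizer options
#'
#' The allocation optimizer minimizes the doubling time `ln 2 / mu` with a
#' Nelder-Mead simplex.  One allocation entry (the ribosomal fraction) is
#' eliminated through the allocation constraint; trial points that drive
#' any fraction negative are assigned the penalty `1/.Machine$double.eps`.
#' Because the simplex is unreliable when optimal fractions sit exactly at
#' zero, the search is restarted once per member of a family of zero
#' subsets (fractions pinned at zero and excluded from the search) and the
#' best restart wins.
#'
#' @param nm_tol Nelder-Mead convergence tolerance (applied to the spread
#'   of objective values across the simplex and to the simplex diameter).
#' @param nm_max_iter iteration cap per restart.
#' @param simplex_a,simplex_b affine initial simplex: vertex `i` displaces
#'   coordinate `i` by `a + b x_i`.
#' @param tie_tol relative doubling-time tolerance within which restarts
#'   count as tied; ties are broken towards the restart with more
#'   fractions pinned at zero.  A free fraction whose true optimum is zero
#'   only reaches a small positive value under the simplex, so the pinned
#'   restart is the reliable representation of the same optimum.
#' @param solver [ss_options()] used for every steady-state evaluation.
#' @return A list of class `cgram_opt_options`.
#' @export
opt_options <- function(nm_tol = 1e-10, nm_max_iter = 750L,
                        simplex_a = 0.0, simplex_b = -0.1,
                        tie_tol = 1e-7, solver = ss_options()) {
  structure(list(nm_tol = nm_tol, nm_max_iter = as.integer(nm_max_iter),
                 simplex_a = simplex_a, simplex_b = simplex_b,
                 tie_tol = tie_tol, solver = solver),
            class = "cgram_opt_options")
}

# desk-scale options: same protocol, relaxed simplex tolerances.  The
# steady state behind each evaluation is still solved to the full residual
# criterion (the Newton polish is tolerance-independent), so optimal
# allocations agree with the default protocol to ~1e-4.
fast_opt_options <- function(nm_tol = 1e-7, nm_max_iter = 250L, ...) {
  opt_options(nm_tol = nm_tol, nm_max_iter = nm_max_iter,
              solver = ss_options(rtol = 1e-6, atol = 1e-8), ...)
}

# allocation labels that may be pinned at zero across restarts; the
# nitrogen-uptake and ribosomal fractions are always optimized
ZEROABLE <- c("f_Kre", "f_Kex", "f_C", "f_Af", "f_Ar")

# all admissible zero subsets for a variant: subsets of the zeroable labels
# not already forced to zero, skipping those that disable both amino-acid
# synthesis pathways (structurally zero growth)
zero_subset_family <- function(variant) {
  variant <- as_variant(variant)
  free <- setdiff(ZEROABLE, variant$forced_zero)
  subsets <- list(character(0))
  for (lab in free)
    subsets <- c(subsets, lapply(subsets, function(s) c(s, lab)))
  keep <- vapply(subsets, function(s) {
    dead <- union(s, variant$forced_zero)
    !all(c("f_Af", "f_Ar") %in% dead)
  }, logical(1))
  subsets[keep]
}

#' Doubling-time objective
#'
#' Reconstructs the full allocation from the optimized entries (`f_Z`
#' fixed, zero-subset entries pinned at zero, `f_R` eliminated as the
#' residual of the allocation constraint), solves the steady state and
#' returns the doubling time `ln 2 / mu`.  All infeasibility -- a negative
#' entry, a negative residual, a non-converged solve, or `mu <= 0` -- maps
#' to the penalty value `1/.Machine$double.eps` so the simplex can recover.
#'
#' @param free_fractions numeric vector of the optimized allocation
#'   entries, named or ordered as `free_labels`.
#' @param p a `cgram_params` object.
#' @param variant a `cgram_variant` or variant name.
#' @param zero_subset labels pinned at zero for this restart.
#' @param options an [opt_options()] list.
#' @param free_labels labels of the optimized entries; defaults to all
#'   metabolic labels not forced or pinned to zero, in standard order.
#' @return Doubling time in hours (or the penalty value).
#' @export
objective <- function(free_fractions, p, variant = "full",
                      zero_subset = character(0),
                      options = opt_options(), free_labels = NULL) {
  variant <- as_variant(variant)
  if (is.null(free_labels))
    free_labels <- setdiff(ALLOC_NAMES[1:6],
                           union(variant$forced_zero, zero_subset))
  if (length(free_fractions) != length(free_labels))
    stop("free_fractions must match free_labels", call. = FALSE)
  penalty <- 1 / .Machine$double.eps
  if (any(free_fractions < 0)) return(penalty)
  f <- setNames(numeric(8), ALLOC_NAMES)
  f[free_labels] <- free_fractions
  f["f_Z"] <- p$f_Z
  f["f_R"] <- 1 - sum(f)
  if (f[["f_R"]] <= 0) return(penalty)
  ss <- solve_steady_state(f, p, variant = variant, options = options$solver)
  if (!ss$converged || ss$mu_ss <= 0) return(penalty)
  log(2) / ss$mu_ss
}

#' Growth-rate-maximizing allocation
#'
#' Runs one Nelder-Mead minimization of the doubling time per admissible
#' zero subset (see [opt_options()] for the protocol) and returns the best
#' restart.  Each restart starts from an equal split of `1 - f_Z` over the
#' searched fractions plus the ribosomal residual, with an affine initial
#' simplex.  The procedure is deterministic: rerunning with identical
#' options reproduces the result exactly.
#'
#' @param p a `cgram_params` object.
#' @param variant a `cgram_variant`, variant name, or `cgram_model`.
#' @param options an [opt_options()] list.
#' @return A `cgram_opt_result` with elements `f_opt` (named allocation),
#'   `mu_opt`, `doubling_time`, `best_zero_subset`, `restart_log` (one row
#'   per restart) and `evaluations`.
#' @examples
#' \donttest{
#' res <- optimize_allocation(default_parameters(k_C = 1e3), "core")
#' res$f_opt
#' }
#' @export
optimize_allocation <- function(p, variant = "full",
                                options = opt_options()) {
  model <- if (inherits(variant, "cgram_model")) variant
           else as_model(p, variant)
  p <- model$params
  variant <- model$variant
  pvec <- as_par_vector(p)
  subsets <- zero_subset_family(variant)

  log_rows <- vector("list", length(subsets))
  best <- NULL
  for (i in seq_along(subsets)) {
    zs <- subsets[[i]]
    free_labels <- setdiff(ALLOC_NAMES[1:6],
                           union(variant$forced_zero, zs))
    nfree <- length(free_labels)
    start <- rep((1 - p$f_Z) / (nfree + 1), nfree)
    free_idx <- match(free_labels, ALLOC_NAMES) - 1L
    r <- cg_restart_cpp(pvec, as.integer(free_idx), start,
                        variant$k0_zero, options$nm_tol,
                        options$nm_max_iter, options$simplex_a,
                        options$simplex_b,
                        options$solver$rtol, options$solver$atol,
                        options$solver$ss_tol, options$solver$t_max,
                        options$solver$max_steps)
    log_rows[[i]] <- data.frame(
      subset = if (length(zs)) paste(zs, collapse = "+") else "(none)",
      n_zeroed = length(zs),
      feasible = r$feasible, nm_converged = r$nm_converged,
      mu = if (r$feasible) r$mu else NA_real_,
      doubling_time = if (r$feasible) r$td else NA_real_,
      evaluations = r$evaluations, stringsAsFactors = FALSE)
    better <- r$feasible &&
      (is.null(best) ||
         r$td < best$td * (1 - options$tie_tol) ||
         (r$td <= best$td * (1 + options$tie_tol) &&
            length(zs) > length(best$zero_subset)))
    if (better) {
      best <- r
      best$zero_subset <- zs
    }
  }
  restart_log <- do.call(rbind, log_rows)
  if (is.null(best))
    stop("no feasible allocation found in any restart (variant '",
         variant$name, "')", call. = FALSE)

  structure(list(f_opt = setNames(best$f, ALLOC_NAMES),
                 mu_opt = best$mu,
                 doubling_time = best$td,
                 best_zero_subset = best$zero_subset,
                 restart_log = restart_log,
                 evaluations = sum(restart_log$evaluations),
                 variant = variant$name),
            class = "cgram_opt_result")
}

#' @export
print.cgram_opt_result <- function(x, ...) {
  cat("<cgram_opt_result> variant ", x$variant, "\n", sep = "")
  cat(sprintf("  mu = %.6g /h (doubling time %.4g h), %d restarts, %g evaluations\n",
              x$mu_opt, x$doubling_time, nrow(x$restart_log),
              x$evaluations))
  cat("  f_opt:\n")
  print(round(x$f_opt, 6))
  invisible(x)
}
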