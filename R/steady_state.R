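#' Solver options for the steady-state integration
#'
#' Balanced growth is detected by a residual criterion on the relative time
#' derivatives, `max_i |dx_i| / max(|x_i|, 1e-8) < ss_tol`, checked after
#' every accepted integrator step.  The integrator is an L-stable
#' Rosenbrock 4(3) method with analytic Jacobian; `rtol`/`atol` control its
#' local error.  Integration stops unconverged when the model-time budget
#' `t_max` or the step budget `max_steps` is exhausted.
#'
#' @param rtol relative integration tolerance.
#' @param atol absolute integration tolerance.
#' @param ss_tol steady-state residual tolerance.
#' @param t_max model-time budget in hours.
#' @param max_steps cap on accepted integrator steps.
#' @param h0 initial step size in hours.
#' @return A list of class `cgram_ss_options`.
#' @export
ss_options <- function(rtol = 1e-8, atol = 1e-10, ss_tol = 1e-9,
                       t_max = 1e6, max_steps = 50000L, h0 = 1e-5) {
  structure(list(rtol = rtol, atol = atol, ss_tol = ss_tol, t_max = t_max,
                 max_steps = as.integer(max_steps), h0 = h0),
            class = "cgram_ss_options")
}

#' Initial condition for the steady-state integration
#'
#' Metabolite pools start at 0.05 each and every protein sector at 0.8
#' times its allocation fraction (protein content in balanced growth is
#' proportional to allocation, so this is a cheap first guess).  Variants
#' without ketoacid metabolism start with an empty ketoacid pool; the total
#' is then 0.95, which the dynamics restore to 1.
#'
#' @param f an allocation vector.
#' @param variant a `cgram_variant`, variant name, or `cgram_model`.
#' @return A named concentration state.
#' @export
initial_condition <- function(f, variant = "full") {
  f <- as_alloc_vector(f)
  if (inherits(variant, "cgram_model")) variant <- variant$variant
  variant <- as_variant(variant)
  x0 <- c(a = 0.05, k = if (variant$k0_zero) 0 else 0.05,
          c = 0.05, n = 0.05, 0.8 * unname(f))
  setNames(x0, STATE_NAMES)
}

new_steady_state_result <- function(x, mu, converged, degenerate, residual,
                                    t, steps, status) {
  structure(list(x_ss = setNames(x, STATE_NAMES), mu_ss = mu,
                 converged = converged, degenerate = degenerate,
                 residual = residual, t = t, steps = steps,
                 status = status),
            class = "cgram_steady_state")
}

SOLVE_STATUS <- c(`0` = "converged", `1` = "budget exhausted",
                  `2` = "negative component", `3` = "numerical failure",
                  `4` = "infeasible regulated allocation",
                  `5` = "degenerate allocation")

#' Integrate the model to balanced growth
#'
#' Integrates the stiff mass-fraction ODEs from [initial_condition()] (or a
#' caller-supplied state) until the steady-state residual criterion holds,
#' and returns the converged state with its growth rate and diagnostics.
#' Balanced growth corresponds to this steady state: all mass fractions
#' constant while every component grows exponentially at rate `mu`.
#'
#' Allocations that cannot sustain growth for structural reasons (no
#' ribosomal allocation, or no amino-acid synthesis pathway at all) are
#' short-circuited to a flagged zero-growth result without spending
#' integrator time.  Integration failures yield `converged = FALSE`, never
#' an error.  A converged steady state with `mu <= 0` is returned with
#' `converged = TRUE` but flagged `degenerate`.
#'
#' @param f an allocation vector (must respect the variant's forced zeros).
#' @param p a `cgram_params` object.
#' @param variant a `cgram_variant`, variant name, or `cgram_model`.
#' @param options a [ss_options()] list.
#' @param x0 optional initial state overriding [initial_condition()].
#' @return A `cgram_steady_state` with elements `x_ss`, `mu_ss`,
#'   `converged`, `degenerate`, `residual`, `t`, `steps`, `status`.
#' @examples
#' p <- default_parameters()
#' f <- allocation_vector(f_C = 0.2, f_Af = 0.2, f_N = 0.2, f_R = 0.2,
#'                        f_Z = 0.2)
#' solve_steady_state(f, p, variant = "core")$mu_ss
#' @export
solve_steady_state <- function(f, p, variant = "full",
                               options = ss_options(), x0 = NULL) {
  model <- if (inherits(variant, "cgram_model")) variant
           else as_model(p, variant)
  p <- model$params
  variant <- model$variant
  f <- as_alloc_vector(f)
  validate_allocation(f)
  bad <- variant$forced_zero[f[variant$forced_zero] != 0]
  if (length(bad))
    stop("allocation violates the variant's forced zeros: ",
         paste(bad, collapse = ", "), call. = FALSE)

  if (is.null(x0)) x0 <- initial_condition(f, variant)
  x0 <- as_state_vector(x0)

  # structurally degenerate allocations: no protein synthesis, or no
  # amino-acid production at all
  if (f[["f_R"]] == 0 || (f[["f_Af"]] == 0 && f[["f_Ar"]] == 0)) {
    return(new_steady_state_result(unname(x0), 0, converged = FALSE,
                                   degenerate = TRUE, residual = NA_real_,
                                   t = 0, steps = 0L,
                                   status = "degenerate allocation"))
  }

  res <- cg_solve_cpp(unname(x0), unname(f), as_par_vector(p),
                      options$rtol, options$atol, options$ss_tol,
                      options$t_max, options$max_steps, TRUE, options$h0)
  new_steady_state_result(res$x, res$mu, res$converged,
                          degenerate = res$converged && res$mu <= 0,
                          residual = res$residual, t = res$t,
                          steps = res$steps,
                          status = unname(SOLVE_STATUS[as.character(res$status)]))
}

#' Integrate the regulated model to balanced growth
#'
#' As [solve_steady_state()], but the ribosomal allocation follows the
#' amino-acid pool through `f_R = delta (a - a0)` (see
#' [regulated_allocation()]) instead of being fixed.
#'
#' @inheritParams solve_steady_state
#' @param base_f base allocation whose metabolic proportions are rescaled.
#' @param delta regulation gain (> 0).
#' @param a0 amino-acid offset.
#' @return A `cgram_steady_state`; the realized allocation at the steady
#'   state is attached as element `f_ss`.
#' @export
solve_steady_state_regulated <- function(base_f, p, delta, a0 = 0,
                                         variant = "full",
                                         options = ss_options(),
                                         x0 = NULL) {
  if (delta <= 0) stop("delta must be positive", call. = FALSE)
  model <- if (inherits(variant, "cgram_model")) variant
           else as_model(p, variant)
  p <- model$params
  variant <- model$variant
  base_f <- as_alloc_vector(base_f)
  if (is.null(x0)) x0 <- initial_condition(base_f, variant)
  x0 <- as_state_vector(x0)

  res <- cg_solve_regulated_cpp(unname(x0), unname(base_f),
                                as_par_vector(p), delta, a0,
                                options$rtol, options$atol, options$ss_tol,
                                options$t_max, options$max_steps, TRUE,
                                options$h0)
  out <- new_steady_state_result(res$x, res$mu, res$converged,
                                 degenerate = res$converged && res$mu <= 0,
                                 residual = res$residual, t = res$t,
                                 steps = res$steps,
                                 status = unname(SOLVE_STATUS[as.character(res$status)]))
  out$f_ss <- regulated_allocation(out$x_ss[["a"]], base_f, p, delta, a0)
  out
}

# fixed-horizon integration without steady-state detection; brute-force
# oracle for the event-based detection (internal, used by tests)
integrate_to_time <- function(f, p, variant = "full", t_end = 1e4,
                              options = ss_options()) {
  model <- if (inherits(variant, "cgram_model")) variant
           else as_model(p, variant)
  f <- as_alloc_vector(f)
  x0 <- initial_condition(f, model$variant)
  res <- cg_solve_cpp(unname(x0), unname(f), as_par_vector(model$params),
                      options$rtol, options$atol, options$ss_tol,
                      t_end, options$max_steps, FALSE, options$h0)
  list(x = setNames(res$x, STATE_NAMES), mu = res$mu, t = res$t,
       steps = res$steps)
}

#' @export
print.cgram_steady_state <- function(x, ...) {
  cat("<cgram_steady_state> ",
      if (x$converged) "converged" else "NOT converged",
      if (x$degenerate) " (degenerate)" else "", "\n", sep = "")
  cat(sprintf("  mu = %.6g /h, residual = %.3g, t = %.4g h, steps = %d\n",
              x$mu_ss, x$residual, x$t, x$steps))
  print(round(x$x_ss, 6))
  invisible(x)
}
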