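#' Ordinary least-squares linear fit
#'
#' Plain OLS of `ys` on `xs` with the exact closed-form (QR) solution, used
#' for the ribosomal growth law `f_R = phi_R0 + sigma^-1 mu` and the
#' `f_R`-versus-amino-acid relation.
#'
#' @param xs,ys numeric vectors (at least 3 points; `xs` not all equal).
#' @return A `cgram_linear_fit` with `slope`, `intercept`, `r_squared`,
#'   `n_points` and `residuals`.
#' @export
fit_linear_law <- function(xs, ys) {
  ok <- is.finite(xs) & is.finite(ys)
  xs <- xs[ok]; ys <- ys[ok]
  if (length(xs) < 3) stop("need at least 3 finite points", call. = FALSE)
  if (max(xs) - min(xs) <= 0)
    stop("degenerate fit: xs are all equal", call. = FALSE)
  fit <- lm(ys ~ xs)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ys - mean(ys))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 n_points = length(xs),
                 residuals = unname(fit$residuals)),
            class = "cgram_linear_fit")
}

#' Monod-curve fit
#'
#' Least-squares fit of the hyperbolic growth law
#' `mu = mu_max k / (k + K)` to a sweep of growth rates against an uptake
#' efficiency, by bounded quasi-Newton minimization of the sum of squares.
#' The initial guess is `mu_max = max(mus)`, `K = median(rates)`.
#'
#' @param rates positive swept rate values (at least 4).
#' @param mus growth rates at those values.
#' @return A `cgram_monod_fit` with `mu_max`, `K` and `r_squared`.
#' @export
fit_monod <- function(rates, mus) {
  ok <- is.finite(rates) & is.finite(mus)
  rates <- rates[ok]; mus <- mus[ok]
  if (length(rates) < 4) stop("need at least 4 finite points", call. = FALSE)
  if (any(rates <= 0)) stop("rates must be positive", call. = FALSE)
  if (var(mus) == 0)
    stop("constant growth rates: half-saturation constant unidentifiable",
         call. = FALSE)
  sse <- function(par) sum((mus - par[1] * rates / (rates + par[2]))^2)
  start <- c(max(mus), median(rates))
  fit <- optim(start, sse, method = "L-BFGS-B",
               lower = c(1e-12, 1e-12),
               control = list(factr = 10, pgtol = 0, maxit = 2000))
  # polish: L-BFGS-B can stop short on very flat objectives
  fit <- optim(fit$par, sse, method = "L-BFGS-B",
               lower = c(1e-12, 1e-12),
               control = list(factr = 10, pgtol = 0, maxit = 2000))
  if (fit$convergence != 0)
    stop("Monod fit did not converge: ", fit$message, call. = FALSE)
  ss_tot <- sum((mus - mean(mus))^2)
  structure(list(mu_max = fit$par[1], K = fit$par[2],
                 r_squared = 1 - fit$value / ss_tot,
                 n_points = length(rates)),
            class = "cgram_monod_fit")
}

#' Numerical check of the regulated-allocation growth-law offset
#'
#' When the ribosomal allocation follows the amino-acid pool,
#' `f_R = delta (a - a0)`, and ribosomes obey Michaelis-Menten kinetics,
#' the ribosomal growth law acquires the offset `phi_R0 = delta a_sat`
#' even though no inactive ribosome pool exists: at balanced growth
#' `f_R = mu / k_R + delta a_sat a / (a + a_sat)`, so in the
#' substrate-saturated regime (`a >> a_sat`) the `f_R`-versus-`mu` line
#' extrapolates to `delta a_sat` at `mu = 0`.  This routine solves
#' regulated steady states over a nutrient-quality sweep, fits the line,
#' and reports the discrepancy against the prediction.
#'
#' @param p a `cgram_params` object.
#' @param delta regulation gain (> 0); the asserted identity uses
#'   `a0 = 0`.
#' @param base_f base allocation whose metabolic proportions are used.
#' @param kc_values swept carbon-uptake efficiencies (at least 6).
#' @param a0 amino-acid offset (default 0, the asserted case).
#' @param variant model variant for the regulated solves.
#' @param options an [ss_options()] list.
#' @return A list with `intercept` (fitted), `predicted`
#'   (`delta * a_sat`), `relative_discrepancy`, `fit`
#'   (the `cgram_linear_fit`), `n` (converged sweep points) and the
#'   per-point table `data`.
#' @export
check_offset_relation <- function(p, delta, base_f,
                                  kc_values = log_grid(10, 1e3, 8),
                                  a0 = 0, variant = "core",
                                  options = ss_options()) {
  if (delta <= 0) stop("delta must be positive", call. = FALSE)
  if (length(kc_values) < 6)
    stop("need at least 6 sweep values", call. = FALSE)
  base_f <- as_alloc_vector(base_f)
  rows <- lapply(kc_values, function(kc) {
    p$k_C <- kc
    ss <- solve_steady_state_regulated(base_f, p, delta, a0,
                                       variant = variant,
                                       options = options)
    data.frame(k_C = kc, mu = ss$mu_ss, f_R = ss$f_ss[["f_R"]],
               a = ss$x_ss[["a"]], converged = ss$converged)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$converged & tab$mu > 0
  if (sum(ok) < 3)
    stop("fewer than 3 converged regulated steady states", call. = FALSE)
  fit <- fit_linear_law(tab$mu[ok], tab$f_R[ok])
  predicted <- delta * p$a_sat
  list(intercept = fit$intercept, predicted = predicted,
       relative_discrepancy = abs(fit$intercept - predicted) / predicted,
       fit = fit, n = sum(ok), data = tab)
}

#' @export
print.cgram_linear_fit <- function(x, ...) {
  cat(sprintf("<cgram_linear_fit> slope %.6g, intercept %.6g, R^2 %.6f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' @export
print.cgram_monod_fit <- function(x, ...) {
  cat(sprintf("<cgram_monod_fit> mu_max %.6g /h, K %.6g, R^2 %.6f (n = %d)\n",
              x$mu_max, x$K, x$r_squared, x$n_points))
  invisible(x)
}
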