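# Closed-form optimal enzyme allocation for the trivial, Michaelis-Menten,
# thermodynamic and mass-action rate laws.

#' Optimizer output
#'
#' Container for the solution of the flux-maximization problem: optimal
#' enzyme profile `eps_star`, metabolite profile `s_star` (concentrations
#' `s0..sn`; `NA` where a concentration plays no role), per-reaction driving
#' forces `theta_star`, maximal pathway flux `J_star`, the rate law, and
#' solver diagnostics.
#'
#' @param eps_star per-reaction enzyme levels.
#' @param s_star metabolite concentrations, length n + 1.
#' @param theta_star per-reaction driving forces (NA for irreversible laws).
#' @param J_star pathway flux.
#' @param rate_law one of [RATE_LAWS].
#' @param diagnostics named list of solver metadata.
#' @return An object of class `"optimal_state"`.
#' @export
optimal_state <- function(eps_star, s_star, theta_star, J_star, rate_law,
                          diagnostics = list()) {
  structure(list(eps_star = eps_star, s_star = s_star,
                 theta_star = theta_star, J_star = J_star,
                 rate_law = rate_law, diagnostics = diagnostics),
            class = "optimal_state")
}

#' @export
print.optimal_state <- function(x, ...) {
  cat(sprintf("Optimal state (%s rate law)\n", x$rate_law))
  cat(sprintf("  J* = %.12g\n", x$J_star))
  cat("  eps* =", paste(format(x$eps_star, digits = 12), collapse = " "), "\n")
  if (!all(is.na(x$s_star)))
    cat("  s*   =", paste(format(x$s_star, digits = 12), collapse = " "), "\n")
  invisible(x)
}

#' Optimal allocation for the trivial rate law
#'
#' With every reaction irreversible and fully saturated (`v_i = eps_i *
#' kcat_i`), the optimum spends the enzyme budget in proportion to the
#' turnover times `alpha_i = 1/kcat_i`, and the maximal flux is
#' `J* = eps_tot / ||alpha||_1`. Pathway turnover times are additive:
#' `eps_tot / J* = sum(1/kcat_i)`.
#'
#' @param pw a [pathway_spec()] with `kcat_fwd` on every reaction.
#' @return An [optimal_state()].
#' @examples
#' pw <- pathway_spec(lapply(c(1, 2, 4), reaction_kinetics), eps_tot = 1)
#' solve_trivial(pw)$J_star  # 4/7
#' @export
solve_trivial <- function(pw) {
  sc <- scaled_pathway(pw)
  nc <- norm_cache(sc)
  eps <- sc$eps_tot * nc$alpha / norm_l1(nc$alpha)
  J <- sc$eps_tot / norm_l1(nc$alpha)
  optimal_state(unscale_eps(pw, eps),
                s_star = rep(NA_real_, pw$n + 1L),
                theta_star = rep(NA_real_, pw$n),
                J_star = J, rate_law = "trivial")
}

#' Pathway specific activity and turnover times
#'
#' The pathway specific activity (PSA) is the maximal flux per total enzyme
#' when every reaction is irreversible and saturated, `1 / sum(1/kcat_i)`;
#' the per-reaction turnover times are `tau_i = alpha_i = 1/kcat_i` and they
#' add up to `eps_tot / J*` of [solve_trivial()].
#'
#' @param pw a [pathway_spec()].
#' @return A list with components `PSA` and `turnover_times`.
#' @export
pathway_specific_activity <- function(pw) {
  nc <- norm_cache(scaled_pathway(pw))
  list(PSA = 1 / norm_l1(nc$alpha), turnover_times = nc$alpha)
}

#' Optimal allocation for the Michaelis-Menten rate law
#'
#' Maximizes the steady-state flux of an irreversible saturable chain under
#' the enzyme budget and a bound `s_tot` on the summed free metabolite
#' concentrations. Without the metabolite bound the problem has no optimum:
#' the objective keeps improving as every substrate concentration grows, so
#' the "solution" `s_i -> Inf` is not a state (the unbounded metabolite
#' paradox); by default this raises an infeasibility error.
#'
#' With all metabolites free (including `s0`), the optimal substrate levels
#' are `s_{i-1}* = s_tot * sqrt(beta_i) / sum_j sqrt(beta_j)` with
#' `beta_i = K_M,i / kcat_i`, the enzyme profile is
#' `eps_i* \eqn{\propto} alpha_i + sqrt(beta_i) * sum_j sqrt(beta_j) / s_tot`, and
#' `J* = eps_tot / (||alpha||_1 + ||beta||_{1/2} / s_tot)`.
#' With a fixed upstream concentration `s0`, reaction 1 contributes
#' `alpha_1 + beta_1/s0` and only `beta_2..beta_n` enter the square-root
#' term (only `s_1..s_{n-1}` count toward `s_tot`).
#'
#' @param pw a [pathway_spec()] with `kcat_fwd` and `K_S` on every reaction,
#'   and `s_tot` present (unless `s0` is fixed and n = 1, when there is no
#'   free metabolite).
#' @param on_unbounded what to do when `s_tot` is absent: `"error"` (default)
#'   or `"trivial_limit"`, which returns the fully saturated limit solution
#'   flagged with `diagnostics$limit = TRUE` — a limit, not an attainable
#'   state.
#' @return An [optimal_state()]. The downstream product concentration `s_n`
#'   does not enter the rate law and is reported as `NA` (or its fixed value).
#' @export
solve_michaelis_menten <- function(pw, on_unbounded = c("error", "trivial_limit")) {
  on_unbounded <- match.arg(on_unbounded)
  sc <- scaled_pathway(pw)
  nc <- norm_cache(sc)
  if (any(!is.finite(nc$beta)))
    stop_validation("the Michaelis-Menten solver requires K_S on every reaction")
  n <- pw$n
  fixed_s0 <- !is.null(pw$s0)
  needs_bound <- !(fixed_s0 && n == 1L)
  if (is.null(pw$s_tot) && needs_bound) {
    if (on_unbounded == "error")
      stop_infeasible(paste0(
        "unbounded metabolite paradox: without a bound s_tot on the free ",
        "metabolite concentrations the Michaelis-Menten optimum is s_i -> Inf, ",
        "which is not a well-defined steady state; supply s_tot or request ",
        "on_unbounded = 'trivial_limit'"))
    st <- solve_trivial(pw)
    st$rate_law <- "michaelis_menten"
    st$s_star <- rep(Inf, n + 1L)
    st$diagnostics$limit <- TRUE
    return(st)
  }
  s <- rep(NA_real_, n + 1L)
  if (fixed_s0) {
    s[1L] <- pw$s0
    denom0 <- norm_l1(nc$alpha) + nc$beta[1L] / pw$s0
    if (n > 1L) {
      rb <- sqrt(nc$beta[-1L])
      s[seq(2L, n)] <- pw$s_tot * rb / sum(rb)
      denom0 <- denom0 + sum(rb)^2 / pw$s_tot
    }
    J <- sc$eps_tot / denom0
  } else {
    rb <- sqrt(nc$beta)
    s[seq_len(n)] <- pw$s_tot * rb / sum(rb)
    J <- sc$eps_tot / (norm_l1(nc$alpha) + norm_half(nc$beta) / pw$s_tot)
  }
  if (!is.null(pw$sn)) s[n + 1L] <- pw$sn
  eps <- J * (nc$alpha + nc$beta / s[seq_len(n)])
  optimal_state(unscale_eps(pw, eps), s_star = s,
                theta_star = rep(NA_real_, n), J_star = J,
                rate_law = "michaelis_menten",
                diagnostics = list(fixed_s0 = fixed_s0, bound_active = TRUE))
}

#' Solve for the driving-force multiplier Psi
#'
#' For the thermodynamic rate law the optimal split of the overall driving
#' force `theta_tot` among reactions is governed by a single auxiliary scalar
#' `Psi`, the unique positive root of
#' `2 * sum_i asinh(sqrt(Psi * alpha_i)) = theta_tot` with
#' `alpha_i = 1/kcat_i`. The left-hand side is strictly increasing in `Psi`,
#' so the root is found by bracket expansion followed by safeguarded
#' Newton/bisection iteration to relative residual below 1e-12.
#'
#' @param pw a [pathway_spec()] with fixed boundaries, `kcat_fwd` and `K_eq`
#'   on every reaction, and positive overall driving force.
#' @return A list with components `psi`, `residual` (relative residual of the
#'   defining equation) and `iterations`.
#' @export
psi_from_theta_tot <- function(pw) {
  th <- theta_tot(pw)
  if (!is.finite(th) || th <= 0)
    stop_infeasible("theta_tot = %.6g <= 0: the pathway has no positive overall driving force", th)
  alpha <- norm_cache(scaled_pathway(pw))$alpha
  f <- function(psi) 2 * sum(asinh(sqrt(psi * alpha)))
  fp <- function(psi) sum(sqrt(alpha / psi) / sqrt(1 + psi * alpha))
  lo <- 0; hi <- 1
  while (f(hi) < th) {
    hi <- hi * 4
    if (hi > 1e300) stop_numerical("Psi bracket expansion failed")
  }
  # start from the small-theta closed form psi ~ (theta/2)^2 / norm_half(alpha) scale
  psi <- min(hi, max(1e-300, (th / (2 * sum(sqrt(alpha))))^2))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    r <- f(psi) - th
    if (r > 0) hi <- psi else lo <- psi
    if (abs(r) <= 1e-14 * th || iter > 200L) break
    step <- r / fp(psi)
    cand <- psi - step
    psi <- if (is.finite(cand) && cand > lo && cand < hi) cand else (lo + hi) / 2
  }
  list(psi = psi, residual = abs(f(psi) - th) / th, iterations = iter)
}

#' Optimal allocation for the thermodynamic rate law
#'
#' For the reversible unsaturable law `v_i = eps_i * kcat_i * (1 -
#' exp(-theta_i))`, the optimum splits the overall driving force according to
#' `theta_i* = 2 * asinh(sqrt(Psi * alpha_i))` with `Psi` from
#' [psi_from_theta_tot()]; the enzyme profile is `eps_i* = J* * alpha_i /
#' (1 - exp(-theta_i*))` and `J* = eps_tot / sum_i(alpha_i /
#' (1 - exp(-theta_i*)))`. Slow enzymes (large `alpha`) receive more driving
#' force. The allocation depends on the equilibrium constants only through
#' their product `K_eq_tot`: intermediate concentrations absorb any
#' redistribution of the individual `K_eq_i`.
#'
#' @inheritParams psi_from_theta_tot
#' @return An [optimal_state()] with `diagnostics$psi` and the Psi-equation
#'   residual.
#' @export
solve_thermodynamic <- function(pw) {
  sc <- scaled_pathway(pw)
  nc <- norm_cache(sc)
  root <- psi_from_theta_tot(pw)
  theta <- 2 * asinh(sqrt(root$psi * nc$alpha))
  demand <- nc$alpha / (1 - exp(-theta))
  J <- sc$eps_tot / sum(demand)
  eps <- J * demand
  n <- pw$n
  s <- numeric(n + 1L)
  s[1L] <- pw$s0
  for (i in seq_len(n)) s[i + 1L] <- s[i] * nc$K_eq[i] * exp(-theta[i])
  optimal_state(unscale_eps(pw, eps), s_star = s, theta_star = theta,
                J_star = J, rate_law = "thermodynamic",
                diagnostics = list(psi = root$psi, psi_residual = root$residual,
                                   iterations = root$iterations))
}

#' Closed-form approximation to the thermodynamic optimum flux
#'
#' Interpolates the two exact limits of the thermodynamic solution —
#' `J* -> eps_tot/||alpha||_1` as `theta_tot -> Inf` and slope
#' `eps_tot/||alpha||_{1/2}` at `theta_tot = 0` — with a curve of the same
#' shape as the thermodynamic rate law itself:
#' `J ~ (eps_tot/||alpha||_1) * (1 - exp(-(||alpha||_1/||alpha||_{1/2}) *
#' theta_tot))`.
#'
#' @inheritParams psi_from_theta_tot
#' @return The approximate maximal flux (scalar).
#' @export
approx_thermodynamic_flux <- function(pw) {
  th <- theta_tot(pw)
  if (!is.finite(th) || th <= 0)
    stop_infeasible("theta_tot = %.6g <= 0: no positive overall driving force", th)
  sc <- scaled_pathway(pw)
  alpha <- norm_cache(sc)$alpha
  (sc$eps_tot / norm_l1(alpha)) *
    (1 - exp(-(norm_l1(alpha) / norm_half(alpha)) * th))
}

#' Optimal allocation for the mass-action rate law
#'
#' For the reversible linear law `v_i = eps_i / beta_i * (s_{i-1} -
#' s_i/K_eq_i)` with fixed boundaries, the optimum is
#' `eps_i* = eps_tot * sqrt(gamma_i) / sum_j sqrt(gamma_j)` and
#' `J* = eps_tot * (s0 * K_eq_tot - sn) / ||gamma||_{1/2}`, where
#' `gamma_i = beta_i * prod_{j=i..n} K_eq_j`. The flux is linear in `s0`
#' (no saturation), and for identical `gamma` it falls off as `1/n^2` with
#' pathway length.
#'
#' @param pw a [pathway_spec()] with fixed `s0`, `sn` and `kcat_fwd`, `K_S`,
#'   `K_eq` on every reaction; requires `s0 * K_eq_tot > sn`.
#' @return An [optimal_state()].
#' @export
solve_mass_action <- function(pw) {
  sc <- scaled_pathway(pw)
  nc <- norm_cache(sc)
  if (any(!is.finite(nc$gamma)))
    stop_validation("the mass-action solver requires K_S and K_eq on every reaction")
  if (is.null(pw$s0) || is.null(pw$sn))
    stop_validation("the mass-action solver requires fixed boundary concentrations")
  Keq_tot <- prod(nc$K_eq)
  if (pw$s0 * Keq_tot <= pw$sn)
    stop_infeasible("s0 * K_eq_tot = %.6g <= sn = %.6g: non-positive overall driving force",
                    pw$s0 * Keq_tot, pw$sn)
  n <- pw$n
  rg <- sqrt(nc$gamma)
  eps <- sc$eps_tot * rg / sum(rg)
  J <- sc$eps_tot * (pw$s0 * Keq_tot - pw$sn) / norm_half(nc$gamma)
  s <- numeric(n + 1L)
  s[1L] <- pw$s0
  for (i in seq_len(n))
    s[i + 1L] <- nc$K_eq[i] * (s[i] - J * nc$beta[i] / eps[i])
  theta <- log(nc$K_eq * s[seq_len(n)] / s[seq_len(n) + 1L])
  optimal_state(unscale_eps(pw, eps), s_star = s, theta_star = theta,
                J_star = J, rate_law = "mass_action")
}
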