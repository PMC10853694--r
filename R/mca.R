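# Metabolic control analysis: unscaled elasticities, flux and concentration
# control coefficients (numeric and analytic routes), theorem residuals, and
# the optimality rules linking enzyme profiles to control.

#' Unscaled elasticity matrix
#'
#' `E[j, i+1] = dv_j / ds_i` — the partial derivative of reaction rate `v_j`
#' (including its enzyme level) with respect to metabolite concentration
#' `s_i`, evaluated analytically from the rate law. For an unbranched chain
#' the matrix is bidiagonal: reaction `j` responds only to its substrate
#' `s_{j-1}` and product `s_j`.
#'
#' @param pw a [pathway_spec()].
#' @param kind one of [RATE_LAWS].
#' @param eps enzyme levels (length n).
#' @param s metabolite concentrations `s0..sn` (length n + 1).
#' @return An `n x (n+1)` matrix; columns are metabolites `s0..sn`.
#' @export
elasticities <- function(pw, kind, eps, s) {
  kind <- match_rate_law(kind)
  n <- pw$n
  E <- matrix(0, n, n + 1L)
  for (j in seq_len(n)) {
    dk <- rate_per_enzyme_grad(kind, pw$reactions[[j]], s[j], s[j + 1L])
    E[j, j] <- eps[j] * dk[1L]
    E[j, j + 1L] <- eps[j] * dk[2L]
  }
  E
}

#' Control profile
#'
#' @param E elasticity matrix.
#' @param flux_control flux control coefficients `C^J` (length n).
#' @param conc_control concentration control coefficient matrix
#'   (internal metabolites x reactions).
#' @param residuals named list of theorem residuals.
#' @return An object of class `"control_profile"`.
#' @export
control_profile <- function(E, flux_control, conc_control, residuals) {
  structure(list(E = E, flux_control = flux_control,
                 conc_control = conc_control, residuals = residuals),
            class = "control_profile")
}

#' @export
print.control_profile <- function(x, ...) {
  cat("Control profile\n")
  cat("  C^J =", paste(format(x$flux_control, digits = 10), collapse = " "), "\n")
  cat(sprintf("  summation residual: %.3g  connectivity residual: %.3g\n",
              x$residuals$summation, max(0, x$residuals$connectivity)))
  invisible(x)
}

# Richardson-extrapolated central difference. The relative step 1e-4 keeps
# the roundoff error (~1e-15/h) below the truncation error (~h^4) so that
# the theorem residuals stay near 1e-10.
.richardson <- function(g, x0, h) {
  d1 <- (g(x0 + h) - g(x0 - h)) / (2 * h)
  d2 <- (g(x0 + h / 2) - g(x0 - h / 2)) / h
  (4 * d2 - d1) / 3
}

#' Flux and concentration control coefficients (numeric route)
#'
#' Computes the steady state at the given enzyme levels, perturbs each
#' enzyme in turn (central differences, relative step 1e-4, Richardson
#' extrapolation) and forms the normalized control coefficients
#' `C^J_l = (dJ/deps_l) * eps_l / J` and
#' `C^{s_i}_l = (ds_i/deps_l) * eps_l / J` for the internal metabolites.
#' The summation theorem (`sum_l C^J_l = 1`) and the connectivity theorem
#' (`sum_l C^J_l E_{l,i} = 0` for every internal metabolite) are checked and
#' their residuals reported.
#'
#' @inheritParams elasticities
#' @return A [control_profile()].
#' @export
control_coefficients <- function(pw, kind, eps) {
  kind <- match_rate_law(kind)
  n <- pw$n
  ref <- steady_state(pw, kind, eps)
  if (kind == "trivial")
    stop_validation(paste0(
      "control coefficients not defined for the trivial rate law: ",
      "any enzyme variation would break the steady state"))
  CJ <- numeric(n)
  n_int <- max(0L, n - 1L)
  CS <- matrix(0, n_int, n)
  for (l in seq_len(n)) {
    h <- 1e-4 * eps[l]
    gJ <- function(e) {
      ee <- eps; ee[l] <- e
      steady_state(pw, kind, ee)$J
    }
    CJ[l] <- .richardson(gJ, eps[l], h) * eps[l] / ref$J
    if (n_int > 0L) for (i in seq_len(n_int)) {
      gs <- function(e) {
        ee <- eps; ee[l] <- e
        steady_state(pw, kind, ee)$s[i + 1L]
      }
      CS[i, l] <- .richardson(gs, eps[l], h) * eps[l] / ref$J
    }
  }
  E <- elasticities(pw, kind, eps, ref$s)
  conn <- if (n_int > 0L) {
    vapply(seq_len(n_int), function(i) {
      terms <- CJ * E[, i + 1L]
      denom <- sum(abs(terms))
      if (denom == 0) 0 else abs(sum(terms)) / denom
    }, numeric(1))
  } else numeric(0)
  control_profile(E, CJ, CS,
                  residuals = list(summation = abs(sum(CJ) - 1),
                                   connectivity = if (length(conn)) max(conn) else 0,
                                   conc_summation = if (n_int > 0L)
                                     max(abs(rowSums(CS)) / pmax(rowSums(abs(CS)), 1))
                                   else 0))
}

#' Analytic flux control coefficients, mass-action law
#'
#' For the reversible mass-action chain the flux control coefficients are
#' `C^J_l = (gamma_l/eps_l) / sum_j(gamma_j/eps_j)`, obtained by
#' differentiating the closed-form steady-state flux.
#'
#' @param pw a [pathway_spec()] with fixed boundaries and mass-action
#'   constants.
#' @param eps enzyme levels.
#' @return A vector of flux control coefficients summing to 1.
#' @export
control_mass_action_analytic <- function(pw, eps) {
  nc <- norm_cache(pw, use_weights = FALSE)
  if (any(!is.finite(nc$gamma)))
    stop_validation("mass-action control requires K_S and K_eq on every reaction")
  ss <- steady_state(pw, "mass_action", eps)
  if (ss$J <= 0) stop_infeasible("non-positive steady-state flux")
  x <- nc$gamma / eps
  x / sum(x)
}

#' Analytic flux control coefficients, thermodynamic law
#'
#' Implicit differentiation of the steady-state product relation
#' `prod_i (1 - J/(eps_i kcat_i)) = sn/(s0 K_eq_tot)` gives
#' `C^J_l = (eps_l kcat_l - J)^-1 / sum_i (eps_i kcat_i - J)^-1`.
#'
#' @inheritParams control_mass_action_analytic
#' @return A vector of flux control coefficients summing to 1.
#' @export
control_thermodynamic_analytic <- function(pw, eps) {
  kcat <- kin_field(pw, "kcat_fwd")
  J <- steady_state(pw, "thermodynamic", eps)$J
  slack <- eps * kcat - J
  if (any(slack <= 0))
    stop_numerical("eps_l * kcat_l <= J at reaction %d: inconsistent steady state",
                   which(slack <= 0)[1L])
  x <- 1 / slack
  x / sum(x)
}

.check_plain_budget <- function(state) {
  if (isTRUE(state$diagnostics$bound_active) ||
      state$rate_law == "michaelis_menten")
    stop_validation(paste0(
      "rule scope: this state was optimized under an active metabolite bound; ",
      "the plain enzyme-control/elasticity rules do not apply — use ",
      "generalized_enzyme_control_rule()"))
  invisible(TRUE)
}

#' Enzyme-control rule at an optimum
#'
#' At a flux-maximal state under the plain enzyme budget (no metabolite
#' bound), enzyme levels and flux control coefficients are proportional:
#' `eps_i* = eps_tot * C^J_i`. Returns the maximal relative residual of that
#' identity and the enzyme profile predicted from the control coefficients.
#'
#' @param state an [optimal_state()] from an allocate-module solver or
#'   [min_enzyme_demand()].
#' @param profile a [control_profile()] evaluated at `state`.
#' @return A list with `residual` and `eps_from_C`.
#' @export
enzyme_control_rule <- function(state, profile) {
  .check_plain_budget(state)
  eps_tot <- sum(state$eps_star)
  pred <- eps_tot * profile$flux_control
  list(residual = max(abs(pred - state$eps_star) / state$eps_star),
       eps_from_C = pred)
}

#' Generalized enzyme-control rule under a joint density constraint
#'
#' At an optimum of the flux under `a * sum(eps) + b * sum(s) <= rho`
#' (uniform weights), the enzyme profile satisfies
#' `eps_l* = eps_tot* * C^J_l - J* * (b/a) * sum_i C^{s_i}_l`,
#' where `eps_tot*` is the emerging (non-fixed) total enzyme level and the
#' concentration control coefficients run over the internal (dynamic)
#' metabolites. Setting `b = 0` recovers the plain enzyme-control rule.
#'
#' @inheritParams enzyme_control_rule
#' @param a enzyme weight (> 0).
#' @param b metabolite weight (>= 0).
#' @return A list with `residual` and `eps_from_C`.
#' @export
generalized_enzyme_control_rule <- function(state, profile, a, b) {
  if (is.null(profile$conc_control))
    stop_validation("concentration control coefficients unavailable")
  eps_tot <- sum(state$eps_star)
  corr <- if (nrow(profile$conc_control) > 0)
    colSums(profile$conc_control) else rep(0, length(state$eps_star))
  pred <- eps_tot * profile$flux_control - state$J_star * (b / a) * corr
  list(residual = max(abs(pred - state$eps_star) / state$eps_star),
       eps_from_C = pred)
}

#' Enzyme-elasticity rule at an optimum
#'
#' At a flux-maximal state under the plain enzyme budget, the connectivity
#' theorem combined with the enzyme-control rule implies, for every internal
#' metabolite `i`, `sum_j eps_j * E_{j,i} = 0`: the enzyme levels around a
#' metabolite are inversely proportional to the absolute elasticities of
#' their reactions with respect to it. Returns the normalized residual
#' `|sum_j eps_j E_{j,i}| / sum_j |eps_j E_{j,i}|` per internal metabolite.
#'
#' @param state an [optimal_state()].
#' @param E an elasticity matrix from [elasticities()] evaluated at `state`.
#' @return A numeric vector of per-metabolite residuals (length n - 1).
#' @export
enzyme_elasticity_rule <- function(state, E) {
  .check_plain_budget(state)
  n <- length(state$eps_star)
  if (n < 2L) return(numeric(0))
  vapply(seq_len(n - 1L), function(i) {
    terms <- state$eps_star * E[, i + 1L]
    abs(sum(terms)) / sum(abs(terms))
  }, numeric(1))
}

#' Flux maximization under a joint enzyme-metabolite density bound
#'
#' Maximizes the steady-state flux subject to
#' `a * sum(eps) + b * sum(s_free) <= rho` with uniform weights `a` (enzymes)
#' and `b` (free metabolites). For a fixed metabolite profile the whole
#' remaining budget goes to enzymes, so the problem reduces to maximizing
#' `(rho - b * sum(s)) / (a * sum(demand(s)))` over the free
#' log-concentrations, which is solved by quasi-Newton iteration.
#'
#' @inheritParams min_enzyme_demand
#' @param a enzyme weight (> 0).
#' @param b metabolite weight (>= 0).
#' @param rho total density budget (> 0).
#' @return An [optimal_state()]; `sum(eps_star)` is the emerging total enzyme
#'   level and `diagnostics$s_total` the metabolite share.
#' @export
solve_joint_density <- function(pw, kind, a, b, rho) {
  kind <- match_rate_law(kind)
  if (a <= 0 || b < 0 || rho <= 0)
    stop_validation("solve_joint_density() requires a > 0, b >= 0, rho > 0")
  if (any(pw$enzyme_weights != 1))
    stop_validation("solve_joint_density() is defined for uniform enzyme weights")
  free <- free_metabolites(pw, kind)
  if (length(free) == 0L)
    stop_validation("no free metabolites: the joint-density problem is degenerate")
  if (b == 0) {
    # the constraint degenerates to a plain enzyme budget eps_tot = rho/a
    pw0 <- pw
    pw0$eps_tot <- rho / a
    st <- min_enzyme_demand(pw0, kind)
    st$diagnostics$a <- a; st$diagnostics$b <- 0; st$diagnostics$rho <- rho
    return(st)
  }
  n <- pw$n
  assemble <- function(x) {
    s <- rep(NA_real_, n + 1L)
    if (!is.null(pw$s0)) s[1L] <- pw$s0
    if (!is.null(pw$sn)) s[n + 1L] <- pw$sn
    s[free + 1L] <- exp(x)
    s
  }
  negloJ <- function(x) {
    s <- assemble(x)
    slack <- rho - b * sum(s[free + 1L])
    if (slack <= 0) return(1e10 + sum(exp(x)))
    d <- demand_objective(pw, kind, s)$value
    if (!is.finite(d)) return(1e10)
    log(a * d) - log(slack)
  }
  grad <- function(x) {
    s <- assemble(x)
    slack <- rho - b * sum(s[free + 1L])
    od <- demand_objective(pw, kind, s, grad = TRUE)
    gs <- od$grad[free + 1L] / od$value + b / slack
    gs * s[free + 1L]
  }
  x0 <- rep(log(rho / (b * length(free) + 1) / max(1, length(free))), length(free))
  fit <- stats::nlminb(x0, negloJ, gradient = grad, control = .nlminb_ctl)
  s <- assemble(fit$par)
  d <- demand_objective(pw, kind, s)$value
  J <- (rho - b * sum(s[free + 1L])) / (a * d)
  demand <- vapply(seq_len(n), function(i)
    1 / rate_per_enzyme(kind, pw$reactions[[i]], s[i], s[i + 1L]), numeric(1))
  optimal_state(J * demand, s_star = s, theta_star = rep(NA_real_, n),
                J_star = J, rate_law = kind,
                diagnostics = list(a = a, b = b, rho = rho,
                                   s_total = sum(s[free + 1L]),
                                   bound_active = TRUE,
                                   convergence = fit$convergence))
}
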