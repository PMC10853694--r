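# Numerical machinery: convex enzyme-cost minimization over
# log-concentrations (oracle for every rate law and the only solver for the
# Haldane law), steady-state computation given enzyme levels, and a numeric
# Jacobian stability check.

# Which metabolite indices (0-based, 0..n) are decision variables.
free_metabolites <- function(pw, kind) {
  n <- pw$n
  if (kind == "trivial") return(integer(0))
  if (kind == "michaelis_menten") {
    # s_n never enters an irreversible chain; s0 is free unless fixed.
    idx <- seq.int(0L, n - 1L)
    if (!is.null(pw$s0)) idx <- setdiff(idx, 0L)
    return(idx)
  }
  if (is.null(pw$s0) || is.null(pw$sn))
    stop_validation("reversible rate laws require fixed boundary concentrations s0 and sn")
  if (n < 2L) integer(0) else seq.int(1L, n - 1L)
}

# Total weighted enzyme demand at unit flux, given the full metabolite
# vector s (length n+1), plus its gradient d f / d s.
demand_objective <- function(pw, kind, s, grad = FALSE) {
  n <- pw$n
  f <- 0
  g <- numeric(n + 1L)
  for (i in seq_len(n)) {
    kin <- pw$reactions[[i]]
    k <- rate_per_enzyme(kind, kin, s[i], s[i + 1L])
    if (!is.finite(k) || k <= 0) return(list(value = Inf, grad = g))
    w <- pw$enzyme_weights[i]
    f <- f + w / k
    if (grad) {
      dk <- rate_per_enzyme_grad(kind, kin, s[i], s[i + 1L])
      g[i] <- g[i] - w * dk[1L] / k^2
      g[i + 1L] <- g[i + 1L] - w * dk[2L] / k^2
    }
  }
  list(value = f, grad = g)
}

.nlminb_ctl <- list(eval.max = 5000L, iter.max = 3000L, rel.tol = 1e-14,
                    x.tol = 1e-14, abs.tol = 0)

# Quasi-Newton minimization followed by a Newton polish on the analytic
# gradient (Hessian by central differences of the gradient). The polish
# sharpens the *argument* accuracy, which nlminb's objective-based stopping
# rule leaves at ~sqrt(tol) because the optimum is flat.
.solve_smooth <- function(z0, val, grd) {
  m <- length(z0)
  if (m == 0L) return(z0)
  fit <- stats::nlminb(z0, val, gradient = grd, control = .nlminb_ctl)
  z <- fit$par
  for (it in seq_len(30L)) {
    g <- grd(z)
    if (max(abs(g)) < 1e-13 * max(1, abs(val(z)))) break
    H <- matrix(0, m, m)
    for (j in seq_len(m)) {
      h <- 1e-5 * max(1, abs(z[j]))
      up <- z; up[j] <- up[j] + h
      dn <- z; dn[j] <- dn[j] - h
      H[, j] <- (grd(up) - grd(dn)) / (2 * h)
    }
    H <- (H + t(H)) / 2
    step <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(step)) break
    f0 <- val(z); lam <- 1
    repeat {
      zt <- z + lam * step
      if (is.finite(val(zt)) && val(zt) <= f0 || lam < 1e-6) break
      lam <- lam / 2
    }
    if (lam < 1e-6) break
    z <- z + lam * step
  }
  attr(z, "fit") <- fit
  z
}

# Minimize total enzyme demand for an irreversible saturable chain: the
# optimum always exhausts the metabolite bound, so the free metabolites are
# parameterized on the simplex sum(s) = s_tot via a softmax map with the
# last coordinate pinned at 0 (removing the shift null-direction).
.minimize_mm <- function(pw, free) {
  m <- length(free)
  assemble <- function(z) {
    s <- rep(NA_real_, pw$n + 1L)
    if (!is.null(pw$s0)) s[1L] <- pw$s0
    if (!is.null(pw$sn)) s[pw$n + 1L] <- pw$sn
    zf <- c(z, 0)
    p <- exp(zf - max(zf)); p <- p / sum(p)
    s[free + 1L] <- pw$s_tot * p
    s
  }
  obj <- function(z) demand_objective(pw, "michaelis_menten", assemble(z))$value
  gr <- function(z) {
    s <- assemble(z)
    gs <- demand_objective(pw, "michaelis_menten", s, grad = TRUE)$grad
    sf <- s[free + 1L]; gf <- gs[free + 1L]
    (sf * (gf - sum(gf * sf) / pw$s_tot))[-m]
  }
  z <- .solve_smooth(rep(0, m - 1L), obj, gr)
  list(s = assemble(z), value = obj(z),
       fit = attr(z, "fit") %||% list(convergence = 0L, iterations = 0L))
}

# Reversible laws: decision variables are the per-reaction driving forces on
# the simplex sum(theta) = theta_tot (theta = theta_tot * softmax(z)), which
# keeps every reaction thermodynamically feasible by construction and is an
# affine function of the log-concentrations, preserving convexity. An
# optional bound on the free internal metabolites is handled by a log-barrier
# continuation (the objective itself diverges at theta -> 0, acting as its
# own barrier there).
.minimize_reversible <- function(pw, kind) {
  n <- pw$n
  th_tot <- theta_tot(pw)
  if (th_tot <= 0)
    stop_infeasible("theta_tot = %.6g <= 0: no positive overall driving force", th_tot)
  K_eq <- kin_field(pw, "K_eq")
  free <- free_metabolites(pw, kind)
  s_from_theta <- function(theta) {
    s <- numeric(n + 1L)
    s[1L] <- pw$s0
    for (i in seq_len(n)) s[i + 1L] <- s[i] * K_eq[i] * exp(-theta[i])
    s[n + 1L] <- pw$sn  # exact by construction; avoid rounding drift
    s
  }
  theta_from_z <- function(z) {
    zf <- c(z, 0)  # last coordinate pinned: removes the softmax shift direction
    p <- exp(zf - max(zf)); th_tot * p / sum(p)
  }
  make_obj <- function(mu) {
    # mu = 0: plain objective; mu > 0: log-barrier on sum(s_free) < s_tot
    val <- function(z) {
      theta <- theta_from_z(z)
      s <- s_from_theta(theta)
      f <- demand_objective(pw, kind, s)$value
      if (mu > 0) {
        slack <- pw$s_tot - sum(s[free + 1L])
        if (slack <= 0) return(Inf)
        f <- f - mu * log(slack)
      }
      f
    }
    grd <- function(z) {
      theta <- theta_from_z(z)
      s <- s_from_theta(theta)
      gs <- demand_objective(pw, kind, s, grad = TRUE)$grad
      if (mu > 0) {
        slack <- pw$s_tot - sum(s[free + 1L])
        gs[free + 1L] <- gs[free + 1L] + mu / slack
      }
      # d f / d x_i with x_i = ln s_i, internal i = 1..n-1
      gx <- gs[seq_len(n - 1L) + 1L] * s[seq_len(n - 1L) + 1L]
      # x_i = ln s0 + sum_{j<=i} (ln Keq_j - theta_j) => dx_i/dtheta_k = -1 (k<=i)
      gtheta <- vapply(seq_len(n), function(k) {
        if (k > n - 1L) 0 else -sum(gx[seq.int(k, n - 1L)])
      }, numeric(1))
      gtheta[n] <- 0
      # softmax Jacobian, last coordinate pinned
      (theta * (gtheta - sum(theta * gtheta) / th_tot))[-n]
    }
    list(val = val, grd = grd)
  }
  o <- make_obj(0)
  z <- .solve_smooth(rep(0, n - 1L), o$val, o$grd)  # even driving-force start
  fit <- attr(z, "fit") %||% list(convergence = 0L, iterations = 0L)
  s <- s_from_theta(theta_from_z(z))
  if (!is.null(pw$s_tot) && length(free) > 0 &&
      sum(s[free + 1L]) > pw$s_tot) {
    # Bound violated by the unconstrained optimum: barrier continuation.
    s_sum <- function(zz) sum(s_from_theta(theta_from_z(zz))[free + 1L])
    pre <- stats::nlminb(z, s_sum,
                         control = list(iter.max = 2000L, eval.max = 4000L))
    if (s_sum(pre$par) >= pw$s_tot)
      stop_infeasible(paste0(
        "metabolite bound violated: no driving-force split keeps ",
        "sum(s_free) <= s_tot = %.6g"), pw$s_tot)
    # start just inside the bound, between the unconstrained optimum and the
    # most-interior point, so gradients stay on the optimum's scale
    z_u <- z
    tgrid <- seq(0.02, 1, by = 0.02)
    tok <- tgrid[vapply(tgrid, function(t)
      s_sum((1 - t) * z_u + t * pre$par) <= 0.9 * pw$s_tot, logical(1))]
    z <- if (length(tok)) (1 - tok[1L]) * z_u + tok[1L] * pre$par else pre$par
    f0 <- demand_objective(pw, kind, s_from_theta(theta_from_z(z)))$value
    for (mu in f0 * 10^seq(-1, -13, by = -1)) {
      o <- make_obj(mu)
      z <- .solve_smooth(z, o$val, o$grd)
    }
    fit <- attr(z, "fit") %||% fit
    s <- s_from_theta(theta_from_z(z))
  }
  list(s = s, value = demand_objective(pw, kind, s)$value, fit = fit)
}

#' Minimize enzyme demand at unit flux (convex solver)
#'
#' Numerically minimizes the total weighted enzyme demand
#' `sum_i w_i * enzyme_demand(kind, kin_i, 1, s_{i-1}, s_i)` over the free
#' metabolite concentrations (in log-space, where the demand is convex),
#' subject to the optional metabolite bound `s_tot`. The result is converted
#' to the equivalent flux-maximization answer via
#' `J* = eps_tot / (minimal demand)` and `eps_i* = J* * demand_i`. This is
#' the general solver for the Haldane rate law and the independent oracle for
#' every analytic solver.
#'
#' @param pw a [pathway_spec()].
#' @param kind one of [RATE_LAWS].
#' @return An [optimal_state()]; `diagnostics` records the minimized demand,
#'   optimizer convergence code and iteration count.
#' @export
min_enzyme_demand <- function(pw, kind) {
  kind <- match_rate_law(kind)
  for (kin in pw$reactions) check_required_fields(kind, kin)
  sc <- scaled_pathway(pw)
  n <- pw$n
  if (kind == "trivial") {
    st <- solve_trivial(pw)
    st$diagnostics <- list(demand = sc$eps_tot / st$J_star, solver = "closed_form")
    return(st)
  }
  if (kind == "michaelis_menten") {
    free <- free_metabolites(sc, kind)
    if (length(free) == 0L) {
      s <- rep(NA_real_, n + 1L); s[1L] <- pw$s0
      if (!is.null(pw$sn)) s[n + 1L] <- pw$sn
      res <- list(s = s, value = demand_objective(sc, kind, s)$value,
                  fit = list(convergence = 0L, iterations = 0L))
    } else {
      if (is.null(pw$s_tot))
        stop_infeasible(paste0(
          "unbounded metabolite paradox: the Michaelis-Menten demand keeps ",
          "decreasing as s_i -> Inf; the bound 'sum(s_i) <= s_tot' is the ",
          "violated (missing) constraint"))
      res <- .minimize_mm(sc, free)
    }
  } else {
    res <- .minimize_reversible(sc, kind)
  }
  demand <- vapply(seq_len(n), function(i)
    1 / rate_per_enzyme(kind, sc$reactions[[i]], res$s[i], res$s[i + 1L]),
    numeric(1))
  J <- sc$eps_tot / res$value
  eps <- J * demand
  theta <- rep(NA_real_, n)
  if (kind %in% c("thermodynamic", "mass_action", "haldane")) {
    K_eq <- kin_field(pw, "K_eq")
    theta <- log(K_eq * res$s[seq_len(n)] / res$s[seq_len(n) + 1L])
  }
  free <- free_metabolites(pw, kind)
  bound_active <- !is.null(pw$s_tot) && length(free) > 0L &&
    sum(res$s[free + 1L]) > (1 - 1e-6) * pw$s_tot
  optimal_state(unscale_eps(pw, eps), s_star = res$s, theta_star = theta,
                J_star = J, rate_law = kind,
                diagnostics = list(demand = res$value,
                                   convergence = res$fit$convergence,
                                   iterations = res$fit$iterations,
                                   bound_active = bound_active,
                                   solver = "nlminb_log_concentration"))
}

#' Steady state of the pathway at given enzyme levels
#'
#' Computes the stationary pathway flux `J` and internal metabolite
#' concentrations for fixed boundaries, by the route appropriate to the rate
#' law: mass-action uses the closed-form linear-chain solution
#' `J = (s0 K_eq_tot - sn) / sum_i(gamma_i/eps_i)`; the thermodynamic law
#' solves `prod_i(1 - J/(eps_i kcat_i)) = sn/(s0 K_eq_tot)` for the unique
#' root `J` in `(0, min_i eps_i kcat_i)` (bisection plus Newton polish);
#' Michaelis-Menten propagates the fixed upstream flux down the chain; the
#' Haldane law uses a damped Newton relaxation with step halving on the
#' internal metabolite balances.
#'
#' @param pw a [pathway_spec()] with fixed boundaries as the law requires.
#' @param kind one of [RATE_LAWS].
#' @param eps vector of positive enzyme levels (length n).
#' @return A list with components `J`, `s` (concentrations `s0..sn`) and
#'   `theta` (per-reaction driving forces, `NA` for irreversible laws).
#' @export
steady_state <- function(pw, kind, eps) {
  kind <- match_rate_law(kind)
  n <- pw$n
  if (length(eps) != n || any(!is.finite(eps)) || any(eps <= 0))
    stop_validation("eps must be a vector of %d positive enzyme levels", n)
  kcat <- kin_field(pw, "kcat_fwd")
  if (kind == "trivial") {
    v <- eps * kcat
    if (diff(range(v)) > 1e-9 * max(v))
      stop_infeasible(paste0(
        "no steady state: the trivial rate law fixes every reaction rate, and ",
        "the rates differ (bottleneck: reaction %d)"), which.min(v))
    return(list(J = mean(v), s = rep(NA_real_, n + 1L),
                theta = rep(NA_real_, n)))
  }
  if (kind == "michaelis_menten") {
    if (is.null(pw$s0))
      stop_validation("steady_state() for Michaelis-Menten requires fixed s0")
    K_S <- kin_field(pw, "K_S")
    s <- rep(NA_real_, n + 1L)
    s[1L] <- pw$s0
    J <- eps[1L] * kcat[1L] * pw$s0 / (pw$s0 + K_S[1L])
    if (n > 1L) for (i in seq.int(2L, n)) {
      cap <- eps[i] * kcat[i]
      if (cap <= J)
        stop_infeasible(paste0(
          "no steady state: downstream capacity eps*kcat = %.6g of reaction %d ",
          "is below the upstream inflow J = %.6g (bottleneck: reaction %d)"),
          cap, i, J, i)
      s[i] <- K_S[i] * J / (cap - J)
    }
    if (!is.null(pw$sn)) s[n + 1L] <- pw$sn
    return(list(J = J, s = s, theta = rep(NA_real_, n)))
  }
  if (is.null(pw$s0) || is.null(pw$sn))
    stop_validation("steady_state() for reversible laws requires fixed s0 and sn")
  K_eq <- kin_field(pw, "K_eq")
  if (kind == "mass_action") {
    nc <- norm_cache(pw, use_weights = FALSE)
    denom <- sum(nc$gamma / eps)
    J <- (pw$s0 * prod(K_eq) - pw$sn) / denom
    s <- numeric(n + 1L)
    s[1L] <- pw$s0
    for (i in seq_len(n)) s[i + 1L] <- K_eq[i] * (s[i] - J * nc$beta[i] / eps[i])
    if (any(s <= 0))
      stop_infeasible("no physical steady state: reconstructed s_%d <= 0 (bottleneck: reaction %d)",
                      which(s <= 0)[1L] - 1L, which(s <= 0)[1L] - 1L)
    theta <- log(K_eq * s[seq_len(n)] / s[seq_len(n) + 1L])
    return(list(J = J, s = s, theta = theta))
  }
  if (kind == "thermodynamic") {
    cap <- eps * kcat
    rhs <- pw$sn / (pw$s0 * prod(K_eq))
    if (rhs >= 1)
      stop_infeasible("theta_tot <= 0: no forward steady state exists")
    g <- function(J) sum(log1p(-J / cap)) - log(rhs)
    lo <- 0; hi <- min(cap)
    for (it in 1:200) {  # bisection with Newton polish
      mid <- (lo + hi) / 2
      if (g(mid) > 0) lo <- mid else hi <- mid
    }
    J <- (lo + hi) / 2
    for (it in 1:5) {
      gp <- -sum(1 / (cap - J))
      J <- J - g(J) / gp
    }
    theta <- -log1p(-J / cap)
    s <- numeric(n + 1L)
    s[1L] <- pw$s0
    for (i in seq_len(n)) s[i + 1L] <- s[i] * K_eq[i] * exp(-theta[i])
    return(list(J = J, s = s, theta = theta))
  }
  # Haldane: damped Newton on the n-1 internal metabolite balances
  s <- numeric(n + 1L)
  s[1L] <- pw$s0
  th0 <- theta_tot(pw)
  if (th0 <= 0) stop_infeasible("theta_tot <= 0: no forward steady state exists")
  for (i in seq_len(n)) s[i + 1L] <- s[i] * K_eq[i] * exp(-th0 / n)
  s[n + 1L] <- pw$sn
  rates <- function(s) vapply(seq_len(n), function(i)
    eps[i] * rate_per_enzyme("haldane", pw$reactions[[i]], s[i], s[i + 1L]),
    numeric(1))
  balance <- function(s) { v <- rates(s); v[-n] - v[-1L] }
  if (n > 1L) {
    x <- log(s[2:n])
    for (it in seq_len(200L)) {
      s[2:n] <- exp(x)
      Fv <- balance(s)
      if (max(abs(Fv)) <= 1e-13 * max(abs(rates(s)))) break
      # tridiagonal Jacobian in log-concentrations
      Jm <- matrix(0, n - 1L, n - 1L)
      dk <- lapply(seq_len(n), function(i)
        eps[i] * rate_per_enzyme_grad("haldane", pw$reactions[[i]], s[i], s[i + 1L]))
      for (i in seq_len(n - 1L)) {
        # F_i = v_i(s_{i-1}, s_i) - v_{i+1}(s_i, s_{i+1}); vars s_1..s_{n-1}
        if (i > 1L) Jm[i, i - 1L] <- dk[[i]][1L] * s[i]
        Jm[i, i] <- (dk[[i]][2L] - dk[[i + 1L]][1L]) * s[i + 1L]
        if (i < n - 1L) Jm[i, i + 1L] <- -dk[[i + 1L]][2L] * s[i + 2L]
      }
      step <- tryCatch(solve(Jm, -Fv), error = function(e) NULL)
      if (is.null(step)) stop_numerical("singular Jacobian in Haldane steady-state iteration")
      lam <- 1; f0 <- sum(Fv^2)
      repeat {
        xt <- x + lam * step
        st <- s; st[2:n] <- exp(xt)
        if (sum(balance(st)^2) < f0 || lam < 1e-8) break
        lam <- lam / 2
      }
      x <- x + lam * step
      if (it == 200L) stop_numerical("Haldane steady-state iteration did not converge")
    }
    s[2:n] <- exp(x)
  }
  v <- rates(s)
  J <- v[n]
  if (max(abs(v - J)) > 1e-8 * abs(J))
    stop_numerical("Haldane steady-state residual too large (max |v_i - J|/J = %.3g)",
                   max(abs(v - J)) / abs(J))
  theta <- log(K_eq * s[seq_len(n)] / s[seq_len(n) + 1L])
  list(J = J, s = s, theta = theta)
}

#' Numeric Jacobian stability check
#'
#' Evaluates the Jacobian of the internal metabolite dynamics
#' `ds_i/dt = v_i - v_{i+1}` at a steady state by central finite differences
#' and reports its eigenvalues. The state is asymptotically stable when all
#' real parts are negative; eigenvalues with `|Re| <= 1e-10` are reported as
#' marginal.
#'
#' @inheritParams steady_state
#' @param s the steady-state metabolite vector `s0..sn` (must satisfy the
#'   steady-state balance to relative 1e-6).
#' @return A list with `eigenvalues`, `stable` (logical) and `marginal`
#'   (logical).
#' @export
jacobian_stability <- function(pw, kind, eps, s) {
  kind <- match_rate_law(kind)
  n <- pw$n
  rate_i <- function(i, s) eps[i] *
    rate_per_enzyme(kind, pw$reactions[[i]], s[i], s[i + 1L])
  v <- vapply(seq_len(n), rate_i, numeric(1), s = s)
  if (max(abs(v - mean(v))) > 1e-6 * max(abs(v)))
    stop_validation("jacobian_stability() requires a steady state (max rate imbalance %.3g)",
                    max(abs(v - mean(v))) / max(abs(v)))
  if (n < 2L)
    return(list(eigenvalues = complex(0), stable = TRUE, marginal = FALSE))
  fvec <- function(sint) {
    ss <- s; ss[2:n] <- sint
    vv <- vapply(seq_len(n), rate_i, numeric(1), s = ss)
    vv[-n] - vv[-1L]
  }
  sint <- s[2:n]
  m <- n - 1L
  Jm <- matrix(0, m, m)
  for (j in seq_len(m)) {
    h <- 1e-6 * sint[j]
    up <- sint; up[j] <- up[j] + h
    dn <- sint; dn[j] <- dn[j] - h
    Jm[, j] <- (fvec(up) - fvec(dn)) / (2 * h)
  }
  ev <- eigen(Jm, only.values = TRUE)$values
  re <- Re(ev)
  list(eigenvalues = ev, stable = all(re < 1e-10),
       marginal = any(abs(re) <= 1e-10))
}

#' Brute-force grid oracle for the enzyme-demand minimum
#'
#' Exhaustively evaluates the unit-flux enzyme demand on a logarithmic grid
#' over the free metabolite concentrations and returns the best grid point.
#' Intended as an independent cross-check of [min_enzyme_demand()] on tiny
#' problems; refuses more than three free metabolites.
#'
#' @inheritParams min_enzyme_demand
#' @param resolution number of grid points per free metabolite.
#' @param log10_range numeric length-2 vector: the grid spans
#'   `10^log10_range[1]` to `10^log10_range[2]` times the reference scale
#'   (the fixed boundary geometric mean, or `s_tot`, or 1).
#' @return An [optimal_state()] whose `diagnostics$demand` is the best grid
#'   objective.
#' @export
grid_oracle <- function(pw, kind, resolution = 40L, log10_range = c(-3, 3)) {
  kind <- match_rate_law(kind)
  sc <- scaled_pathway(pw)
  free <- free_metabolites(sc, kind)
  if (length(free) > 3L)
    stop_validation("grid_oracle() refuses more than 3 free metabolites (got %d)",
                    length(free))
  n <- pw$n
  base <- rep(NA_real_, n + 1L)
  if (!is.null(pw$s0)) base[1L] <- pw$s0
  if (!is.null(pw$sn)) base[n + 1L] <- pw$sn
  ref <- exp(mean(log(c(base[is.finite(base)], pw$s_tot, 1))))
  hi <- if (!is.null(pw$s_tot)) pw$s_tot else ref * 10^log10_range[2]
  if (length(free) == 0L) {
    val <- demand_objective(sc, kind, base)$value
    best <- base
  } else {
    axes <- rep(list(exp(seq(log(ref * 10^log10_range[1]), log(hi),
                             length.out = resolution))), length(free))
    grid <- as.matrix(expand.grid(axes))
    val <- Inf; best <- NULL
    for (r in seq_len(nrow(grid))) {
      s <- base
      s[free + 1L] <- grid[r, ]
      if (!is.null(pw$s_tot) && sum(grid[r, ]) > pw$s_tot) next
      f <- demand_objective(sc, kind, s)$value
      if (f < val) { val <- f; best <- s }
    }
    if (!is.finite(val))
      stop_infeasible("grid oracle found no feasible grid point")
  }
  demand <- vapply(seq_len(n), function(i)
    1 / rate_per_enzyme(kind, sc$reactions[[i]], best[i], best[i + 1L]),
    numeric(1))
  J <- sc$eps_tot / val
  optimal_state(unscale_eps(pw, J * demand), s_star = best,
                theta_star = rep(NA_real_, n), J_star = J, rate_law = kind,
                diagnostics = list(demand = val, solver = "grid"))
}
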