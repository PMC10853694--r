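test_that("trivial allocation spends the budget in proportion to turnover times", {
  st <- solve_trivial(chain(c(1, 1)))
  expect_equal(st$eps_star, c(0.5, 0.5))
  expect_equal(st$J_star, 0.5)
  expect_equal(solve_trivial(chain(5, eps_tot = 2))$J_star, 10)
  st3 <- solve_trivial(chain(c(1, 2, 4)))
  expect_equal(st3$J_star, 4 / 7)
  expect_equal(st3$eps_star, c(4, 2, 1) / 7)
})

test_that("pathway specific activity is the inverse summed turnover time", {
  expect_equal(pathway_specific_activity(chain(c(1, 1)))$PSA, 0.5)
  expect_equal(pathway_specific_activity(chain(7))$PSA, 7)
  psa <- pathway_specific_activity(chain(c(1, 2, 4)))
  expect_equal(psa$PSA, solve_trivial(chain(c(1, 2, 4)))$J_star)
  expect_equal(sum(psa$turnover_times), 1 / psa$PSA)
})

test_that("Michaelis-Menten optimum balances alpha against the metabolite bound", {
  pw <- pathway_spec(list(mk(1, K_S = 1), mk(1, K_S = 1)), eps_tot = 1, s_tot = 4)
  st <- solve_michaelis_menten(pw)
  expect_equal(st$s_star[1:2], c(2, 2))
  expect_equal(st$eps_star, c(0.5, 0.5))
  expect_equal(st$J_star, 1 / 3)
  # direct steady-state check: v_i = 0.5 * 2 / (2 + 1)
  expect_equal(evaluate_rate("michaelis_menten", pw$reactions[[1]], 0.5, 2), st$J_star)
  # s_tot -> Inf approaches the saturated (trivial) flux
  pw2 <- pathway_spec(list(mk(2, K_S = 1), mk(3, K_S = 0.5)), eps_tot = 1, s_tot = 1e9)
  expect_equal(solve_michaelis_menten(pw2)$J_star,
               solve_trivial(pw2)$J_star, tolerance = 1e-6)
  # vanishing K_S reduces to the trivial allocation
  pw3 <- pathway_spec(list(mk(2, K_S = 1e-12), mk(3, K_S = 1e-12)),
                      eps_tot = 1, s_tot = 1)
  expect_equal(solve_michaelis_menten(pw3)$eps_star,
               solve_trivial(pw3)$eps_star, tolerance = 1e-5)
})

test_that("missing metabolite bound raises the unbounded paradox with a limit escape hatch", {
  pw <- pathway_spec(list(mk(1, K_S = 1), mk(1, K_S = 1)), eps_tot = 1)
  expect_error(solve_michaelis_menten(pw), regexp = "unbounded metabolite paradox",
               class = "enzalloc_infeasibility_error")
  lim <- solve_michaelis_menten(pw, on_unbounded = "trivial_limit")
  expect_true(lim$diagnostics$limit)
  expect_equal(lim$J_star, solve_trivial(pw)$J_star)
})

test_that("fixed-s0 Michaelis-Menten variant keeps s0 out of the bound", {
  pw <- pathway_spec(list(mk(1, K_S = 1), mk(1, K_S = 2), mk(1, K_S = 1)),
                     s0 = 0.5, eps_tot = 1, s_tot = 1)
  st <- solve_michaelis_menten(pw)
  expect_equal(st$s_star[1], 0.5)
  expect_equal(sum(st$s_star[2:3]), 1)  # only the internal metabolites
  # closed form: J = eps_tot / (||alpha||_1 + beta_1/s0 + (sum sqrt(beta_-1))^2/s_tot)
  expect_equal(st$J_star, 1 / (3 + 1 / 0.5 + (sqrt(2) + 1)^2 / 1))
  expect_equal(sum(st$eps_star), 1, tolerance = 1e-12)
})

test_that("Psi root solves its defining equation at machine precision", {
  # n = 1 closed form: Psi = kcat * sinh(theta_tot/2)^2
  pw1 <- pathway_spec(list(mk(1, K_eq = exp(2))), s0 = 1, sn = 1, eps_tot = 1)
  r <- psi_from_theta_tot(pw1)
  expect_equal(r$psi, sinh(1)^2, tolerance = 1e-12)
  expect_lt(r$residual, 1e-12)
  pwk <- pathway_spec(list(mk(3, K_eq = 1), mk(100, K_eq = 1)),
                      s0 = 1, sn = exp(-1), eps_tot = 1)  # theta_tot = 1
  rk <- psi_from_theta_tot(pwk)
  expect_lt(rk$residual, 1e-12)
  alpha <- c(1 / 3, 1 / 100)
  expect_equal(2 * sum(asinh(sqrt(rk$psi * alpha))), 1, tolerance = 1e-12)
  # theta_tot -> 0+ sends Psi -> 0
  pw0 <- pathway_spec(list(mk(1, K_eq = exp(1e-6))), s0 = 1, sn = 1, eps_tot = 1)
  expect_lt(psi_from_theta_tot(pw0)$psi, 1e-6)
  expect_error(psi_from_theta_tot(
    pathway_spec(list(mk(1, K_eq = 0.5)), s0 = 1, sn = 1, eps_tot = 1)),
    class = "enzalloc_infeasibility_error")
})

test_that("thermodynamic solver satisfies its own optimality structure", {
  pw <- pathway_spec(list(mk(3, K_eq = 2), mk(7, K_eq = 5)),
                     s0 = 2, sn = 0.3, eps_tot = 1.5)
  st <- solve_thermodynamic(pw)
  expect_equal(sum(st$theta_star), theta_tot(pw), tolerance = 1e-12)
  expect_equal(sum(st$eps_star), 1.5, tolerance = 1e-12)
  # every reaction carries J* at the reconstructed concentrations
  for (i in 1:2)
    expect_equal(evaluate_rate("thermodynamic", pw$reactions[[i]], st$eps_star[i],
                               st$s_star[i], st$s_star[i + 1]),
                 st$J_star, tolerance = 1e-10)
  # n = 1: whole budget on the only enzyme
  pw1 <- pathway_spec(list(mk(4, K_eq = 10)), s0 = 1, sn = 2, eps_tot = 2)
  st1 <- solve_thermodynamic(pw1)
  expect_equal(st1$eps_star, 2)
  expect_equal(st1$J_star, 2 * 4 * (1 - exp(-theta_tot(pw1))))
  # theta_tot -> Inf approaches the saturated flux
  pwI <- pathway_spec(list(mk(3, K_eq = 1e9), mk(7, K_eq = 1e9)),
                      s0 = 10, sn = 0.01, eps_tot = 1)
  expect_equal(solve_thermodynamic(pwI)$J_star, solve_trivial(pwI)$J_star,
               tolerance = 1e-6)
  # theta_tot -> 0: J ~ eps_tot * theta_tot / ||alpha||_1/2, theta_i ~ sqrt(alpha_i)
  th <- 1e-5
  pw0 <- pathway_spec(list(mk(3, K_eq = 1), mk(7, K_eq = 1)),
                      s0 = 1, sn = exp(-th), eps_tot = 1)
  st0 <- solve_thermodynamic(pw0)
  alpha <- c(1 / 3, 1 / 7)
  expect_equal(st0$J_star, th / norm_half(alpha), tolerance = 1e-4)
  expect_equal(st0$theta_star / th, sqrt(alpha) / sum(sqrt(alpha)), tolerance = 1e-4)
})

test_that("thermodynamic allocation depends on K_eq only through the product", {
  make <- function(keqs) pathway_spec(
    list(mk(3, K_eq = keqs[1]), mk(7, K_eq = keqs[2]), mk(2, K_eq = keqs[3])),
    s0 = 1, sn = 0.2, eps_tot = 1)
  a <- solve_thermodynamic(make(c(2, 5, 1)))
  b <- solve_thermodynamic(make(c(10, 1, 1)))   # same product = 10
  expect_equal(a$eps_star, b$eps_star, tolerance = 1e-10)
  expect_equal(a$J_star, b$J_star, tolerance = 1e-10)
})

test_that("flux approximation interpolates the exact thermodynamic optimum", {
  pw <- pathway_spec(list(mk(3, K_eq = 1), mk(100, K_eq = 1)),
                     s0 = 1, sn = 0.999, eps_tot = 1)
  alpha <- c(1 / 3, 1 / 100)
  # slope at theta_tot = 0 equals eps_tot/||alpha||_1/2
  th <- theta_tot(pw)
  expect_equal(approx_thermodynamic_flux(pw) / th, 1 / norm_half(alpha),
               tolerance = 1e-3)
  # large-force limit equals eps_tot/||alpha||_1
  pwI <- pathway_spec(list(mk(3, K_eq = 1e12), mk(100, K_eq = 1e12)),
                      s0 = 1, sn = 1, eps_tot = 1)
  expect_equal(approx_thermodynamic_flux(pwI), 1 / norm_l1(alpha), tolerance = 1e-9)
  # within 5% of the exact solution over theta_tot in [0.1, 10], both Figure-4 cases
  for (k2 in c(100, 2)) {
    for (th in exp(seq(log(0.1), log(10), length.out = 15))) {
      pwg <- pathway_spec(list(mk(3, K_eq = 1), mk(k2, K_eq = 1)),
                          s0 = 1, sn = exp(-th), eps_tot = 1)
      expect_equal(approx_thermodynamic_flux(pwg), solve_thermodynamic(pwg)$J_star,
                   tolerance = 0.05)
    }
  }
})

test_that("mass-action optimum follows the square-root-of-gamma rule", {
  # n = 1: rate law at full budget
  pw1 <- pathway_spec(list(mk(2, K_S = 0.5, K_eq = 4)), s0 = 3, sn = 1, eps_tot = 2)
  st1 <- solve_mass_action(pw1)
  expect_equal(st1$eps_star, 2)
  expect_equal(st1$J_star, 2 * (2 / 0.5) * (3 - 1 / 4))
  # identical gamma: flux decreases quadratically with length
  J_n <- vapply(1:6, function(n) {
    pw <- pathway_spec(replicate(n, mk(1, K_S = 1, K_eq = 1), simplify = FALSE),
                       s0 = 2, sn = 1, eps_tot = 1)
    solve_mass_action(pw)$J_star
  }, numeric(1))
  expect_equal(J_n * (1:6)^2, rep(J_n[1], 6), tolerance = 1e-12)
  # an a-fold kcat improvement shrinks that enzyme's optimal share by sqrt(a)
  base <- pathway_spec(list(mk(1, K_S = 1, K_eq = 1), mk(1, K_S = 1, K_eq = 1),
                            mk(1, K_S = 1, K_eq = 1)), s0 = 2, sn = 1, eps_tot = 1)
  fast <- base; fast$reactions[[2]] <- mk(4, K_S = 1, K_eq = 1)
  sb <- solve_mass_action(base); sf <- solve_mass_action(fast)
  # relative weight sqrt(gamma_2) halves; shares renormalize by the new total
  expect_equal(sf$eps_star[2] * sum(sqrt(c(1, 1 / 4, 1))),
               sb$eps_star[2] * sum(sqrt(c(1, 1, 1))) / sqrt(4), tolerance = 1e-12)
  expect_gt(sf$J_star, sb$J_star)
  expect_error(solve_mass_action(
    pathway_spec(list(mk(1, K_S = 1, K_eq = 1)), s0 = 1, sn = 2, eps_tot = 1)),
    class = "enzalloc_infeasibility_error")
})

test_that("optimal states conserve the budget, balance rates and scale homogeneously", {
  cases <- list(
    list(pw = generate_fixture(21, 4, "mass_action"), solve = solve_mass_action,
         kind = "mass_action"),
    list(pw = generate_fixture(22, 4, "thermodynamic"), solve = solve_thermodynamic,
         kind = "thermodynamic"),
    list(pw = generate_fixture(23, 4, "michaelis_menten"), solve = solve_michaelis_menten,
         kind = "michaelis_menten"))
  for (cs in cases) {
    st <- cs$solve(cs$pw)
    expect_equal(sum(st$eps_star), cs$pw$eps_tot, tolerance = 1e-9)
    expect_true(all(st$eps_star > 0))
    expect_gt(st$J_star, 0)
    for (i in seq_len(cs$pw$n)) {
      if (cs$kind == "michaelis_menten" && i == cs$pw$n) next  # s_n unused
      v <- evaluate_rate(cs$kind, cs$pw$reactions[[i]], st$eps_star[i],
                         st$s_star[i], st$s_star[i + 1])
      expect_equal(v, st$J_star, tolerance = 1e-8)
    }
    # doubling the budget doubles J* and every eps*
    pw2 <- cs$pw; pw2$eps_tot <- 2 * cs$pw$eps_tot
    st2 <- cs$solve(pw2)
    expect_equal(st2$J_star, 2 * st$J_star, tolerance = 1e-12)
    expect_equal(st2$eps_star, 2 * st$eps_star, tolerance = 1e-12)
  }
})

test_that("optimal flux is monotone in kinetic quality and constraint generosity", {
  pw <- generate_fixture(24, 3, "michaelis_menten")
  J_s <- vapply(c(1, 2, 4, 8), function(stot) {
    p <- pw; p$s_tot <- stot; solve_michaelis_menten(p)$J_star
  }, numeric(1))
  expect_true(all(diff(J_s) > 0))
  pwt <- generate_fixture(25, 3, "thermodynamic")
  J_th <- vapply(c(1, 2, 4), function(f) {
    p <- pwt; p$sn <- pwt$sn / f; solve_thermodynamic(p)$J_star
  }, numeric(1))
  expect_true(all(diff(J_th) > 0))
  pwm <- generate_fixture(26, 3, "mass_action")
  base <- solve_mass_action(pwm)$J_star
  faster <- pwm
  faster$reactions[[2]]$kcat_fwd <- faster$reactions[[2]]$kcat_fwd * 3
  expect_gt(solve_mass_action(faster)$J_star, base)
})

test_that("weighted enzyme budgets rescale to effective turnover numbers", {
  pw <- pathway_spec(list(mk(1, K_S = 1, K_eq = 2), mk(2, K_S = 0.5, K_eq = 3)),
                     s0 = 2, sn = 0.5, eps_tot = 1, enzyme_weights = c(2, 0.5))
  st <- solve_mass_action(pw)
  expect_equal(sum(pw$enzyme_weights * st$eps_star), 1, tolerance = 1e-12)
  # equivalent unweighted problem with kcat_i / w_i
  pw2 <- pathway_spec(list(mk(0.5, K_S = 1, K_eq = 2), mk(4, K_S = 0.5, K_eq = 3)),
                      s0 = 2, sn = 0.5, eps_tot = 1)
  st2 <- solve_mass_action(pw2)
  expect_equal(st$J_star, st2$J_star, tolerance = 1e-12)
  expect_equal(st$eps_star * pw$enzyme_weights, st2$eps_star, tolerance = 1e-12)
})
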