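test_that("analytic elasticities match central finite differences", {
  set.seed(71)
  for (kind in c("michaelis_menten", "thermodynamic", "mass_action", "haldane")) {
    pw <- generate_fixture(71, 3, if (kind == "michaelis_menten") "haldane" else kind)
    if (kind == "michaelis_menten") pw$s0 <- 1
    eps <- c(0.4, 0.35, 0.25)
    s <- exp(runif(4, -1, 1))
    if (!is.null(pw$s0)) s[1] <- pw$s0
    if (!is.null(pw$sn)) s[4] <- pw$sn
    E <- elasticities(pw, kind, eps, s)
    for (j in 1:3) for (i in 0:3) {
      h <- 1e-6 * s[i + 1]
      up <- s; up[i + 1] <- up[i + 1] + h
      dn <- s; dn[i + 1] <- dn[i + 1] - h
      fd <- (evaluate_rate(kind, pw$reactions[[j]], eps[j], up[j], up[j + 1]) -
             evaluate_rate(kind, pw$reactions[[j]], eps[j], dn[j], dn[j + 1])) / (2 * h)
      expect_equal(E[j, i + 1], fd, tolerance = 1e-6)
    }
  }
  # trivial law: all elasticities vanish; MM: no product sensitivity
  pw0 <- chain(c(1, 2))
  expect_true(all(elasticities(pw0, "trivial", c(1, 1), c(1, 1, 1)) == 0))
  pwm <- pathway_spec(list(mk(1, K_S = 2), mk(1, K_S = 1)), s0 = 1, eps_tot = 1)
  Em <- elasticities(pwm, "michaelis_menten", c(1, 1), c(1, 1, 1))
  expect_equal(Em[1, 1], 1 * 1 * 2 / (1 + 2)^2)
  expect_equal(Em[1, 2], 0)
})

test_that("numeric control coefficients satisfy the summation and connectivity theorems", {
  for (cs in list(list(law = "mass_action", seed = 72),
                  list(law = "thermodynamic", seed = 73),
                  list(law = "haldane", seed = 74))) {
    pw <- generate_fixture(cs$seed, 4, cs$law)
    eps <- c(0.3, 0.25, 0.25, 0.2)
    prof <- control_coefficients(pw, cs$law, eps)
    expect_lt(prof$residuals$summation, 1e-9)
    expect_lt(prof$residuals$connectivity, 1e-7)
    # concentration control coefficients sum to zero over reactions
    expect_lt(prof$residuals$conc_summation, 1e-7)
  }
  expect_error(control_coefficients(chain(c(1, 1)), "trivial", c(0.5, 0.5)),
               regexp = "not defined", class = "enzalloc_validation_error")
})

test_that("symmetric two-step mass-action pathways split control evenly", {
  pw <- pathway_spec(list(mk(1, K_S = 1, K_eq = 1), mk(1, K_S = 1, K_eq = 1)),
                     s0 = 2, sn = 1, eps_tot = 1)
  prof <- control_coefficients(pw, "mass_action", c(0.5, 0.5))
  expect_equal(prof$flux_control, c(0.5, 0.5), tolerance = 1e-8)
})

test_that("analytic mass-action control matches finite differences and the gamma formula", {
  pw <- generate_fixture(75, 5, "mass_action")
  eps <- c(0.3, 0.2, 0.1, 0.25, 0.15)
  ca <- control_mass_action_analytic(pw, eps)
  expect_equal(sum(ca), 1, tolerance = 1e-12)
  prof <- control_coefficients(pw, "mass_action", eps)
  expect_lt(max(abs(ca - prof$flux_control)), 1e-8)
  expect_lt(rel_err(ca, prof$flux_control), 1e-6)
  # uniform gamma/eps gives uniform control
  pwu <- pathway_spec(replicate(3, mk(1, K_S = 1, K_eq = 1), simplify = FALSE),
                      s0 = 2, sn = 1, eps_tot = 1)
  expect_equal(control_mass_action_analytic(pwu, rep(1 / 3, 3)), rep(1 / 3, 3))
  # at the optimum the control profile is proportional to eps* (enzyme-control rule)
  st <- solve_mass_action(pw)
  expect_lt(rel_err(control_mass_action_analytic(pw, st$eps_star),
                    st$eps_star / sum(st$eps_star)), 1e-8)
})

test_that("analytic thermodynamic control matches the numeric route", {
  pw <- pathway_spec(list(mk(2, K_eq = 1), mk(3, K_eq = 1)),
                     s0 = 2, sn = 0.5, eps_tot = 2)
  ca <- control_thermodynamic_analytic(pw, c(1, 1))
  expect_equal(ca, c(0.6889822, 0.3110178), tolerance = 1e-6)
  prof <- control_coefficients(pw, "thermodynamic", c(1, 1))
  expect_lt(rel_err(ca, prof$flux_control), 1e-6)
  # n = 1: full control
  pw1 <- pathway_spec(list(mk(2, K_eq = 4)), s0 = 2, sn = 1, eps_tot = 1)
  expect_equal(control_thermodynamic_analytic(pw1, 1), 1)
  # at the optimum: control proportional to eps*
  pwr <- generate_fixture(76, 4, "thermodynamic")
  st <- solve_thermodynamic(pwr)
  expect_lt(rel_err(control_thermodynamic_analytic(pwr, st$eps_star),
                    st$eps_star / sum(st$eps_star)), 1e-8)
})

test_that("the enzyme-control rule holds at optima and discriminates perturbed profiles", {
  for (cs in list(list(pw = generate_fixture(77, 4, "mass_action"),
                       st = solve_mass_action(generate_fixture(77, 4, "mass_action")),
                       law = "mass_action"),
                  list(pw = pathway_spec(list(mk(3, K_eq = 1), mk(100, K_eq = 1)),
                                         s0 = 1, sn = exp(-1), eps_tot = 1),
                       st = NULL, law = "thermodynamic"))) {
    st <- cs$st %||% solve_thermodynamic(cs$pw)
    prof <- control_coefficients(cs$pw, cs$law, st$eps_star)
    res <- enzyme_control_rule(st, prof)
    expect_lt(res$residual, 1e-6)
    # 10% perturbation (renormalized to the same budget) breaks the rule
    eps_bad <- st$eps_star * c(1.1, rep(1, cs$pw$n - 2), 0.9)
    eps_bad <- eps_bad * sum(st$eps_star) / sum(eps_bad)
    stb <- st; stb$eps_star <- eps_bad
    profb <- control_coefficients(cs$pw, cs$law, eps_bad)
    expect_gt(enzyme_control_rule(stb, profb)$residual, 1e-2)
  }
})

test_that("the enzyme-elasticity rule balances enzyme-weighted elasticities at optima", {
  # mass-action: eps2/eps1 equals the absolute inverse elasticity ratio
  pw <- generate_fixture(78, 3, "mass_action")
  st <- solve_mass_action(pw)
  E <- elasticities(pw, "mass_action", st$eps_star, st$s_star)
  expect_true(all(enzyme_elasticity_rule(st, E) < 1e-6))
  for (i in 1:2)
    expect_equal(st$eps_star[i + 1] / st$eps_star[i],
                 abs(E[i, i + 1]) / abs(E[i + 1, i + 1]), tolerance = 1e-6)
  # thermodynamic optimum, n = 3
  pwt <- generate_fixture(79, 3, "thermodynamic")
  stt <- solve_thermodynamic(pwt)
  Et <- elasticities(pwt, "thermodynamic", stt$eps_star, stt$s_star)
  expect_true(all(enzyme_elasticity_rule(stt, Et) < 1e-6))
  # negative control
  stb <- st; stb$eps_star <- st$eps_star * c(1.15, 1, 0.85)
  ssb <- steady_state(pw, "mass_action", stb$eps_star)
  Eb <- elasticities(pw, "mass_action", stb$eps_star, ssb$s)
  expect_true(any(enzyme_elasticity_rule(stb, Eb) > 1e-2))
})

test_that("plain rules refuse states optimized under an active metabolite bound", {
  pw <- generate_fixture(80, 3, "michaelis_menten")
  pw$s0 <- 1
  st <- solve_michaelis_menten(pw)
  prof <- control_coefficients(pw, "michaelis_menten", st$eps_star)
  expect_error(enzyme_control_rule(st, prof), regexp = "generalized",
               class = "enzalloc_validation_error")
  E <- elasticities(pw, "michaelis_menten", st$eps_star, st$s_star)
  expect_error(enzyme_elasticity_rule(st, E), class = "enzalloc_validation_error")
})

test_that("the generalized enzyme-control rule holds at joint-density optima", {
  # MM pathway with a joint bound on enzyme plus metabolite mass
  pw <- generate_fixture(81, 2, "michaelis_menten")
  pw$s0 <- 2; pw$s_tot <- NULL
  st <- solve_joint_density(pw, "michaelis_menten", a = 1, b = 0.5, rho = 2)
  expect_equal(sum(st$eps_star) + 0.5 * st$diagnostics$s_total, 2, tolerance = 1e-9)
  prof <- control_coefficients(pw, "michaelis_menten", st$eps_star)
  expect_lt(generalized_enzyme_control_rule(st, prof, a = 1, b = 0.5)$residual, 1e-5)
  # a = b on a symmetric two-step pathway (free boundary): symmetric profile
  pws <- pathway_spec(list(mk(1, K_S = 1), mk(1, K_S = 1)), eps_tot = 1)
  sts <- solve_joint_density(pws, "michaelis_menten", a = 1, b = 1, rho = 2)
  expect_equal(sts$eps_star[1], sts$eps_star[2], tolerance = 1e-8)
  expect_equal(sts$s_star[1], sts$s_star[2], tolerance = 1e-8)
  pwf <- pws; pwf$s0 <- sts$s_star[1]  # clamp the boundary at its optimum
  profs <- control_coefficients(pwf, "michaelis_menten", sts$eps_star)
  expect_lt(generalized_enzyme_control_rule(sts, profs, a = 1, b = 1)$residual, 1e-5)
  # b = 0 reduces to the plain budget (paradox for MM; exact match for mass-action)
  pwm <- generate_fixture(82, 3, "mass_action")
  st0 <- solve_joint_density(pwm, "mass_action", a = 1, b = 0, rho = 1)
  expect_equal(st0$J_star, solve_mass_action(pwm)$J_star, tolerance = 1e-6)
  expect_error(solve_joint_density(pw, "michaelis_menten", a = 1, b = 0, rho = 2),
               class = "enzalloc_infeasibility_error")
})
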