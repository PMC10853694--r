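# Rate laws for uni-uni enzymatic reactions S <-> P and their efficiency
# factorization v = eps * kcat * eta_for(theta) * eta_sat(s, p).

#' Rate-law kinds
#'
#' The five rate laws handled by the package, in increasing order of
#' kinetic detail: `"trivial"` (irreversible, saturated), `"michaelis_menten"`
#' (irreversible, saturable), `"thermodynamic"` (reversible, unsaturable),
#' `"mass_action"` (reversible, linear in reactants) and `"haldane"`
#' (reversible, saturable).
#'
#' @format A character vector of length 5.
#' @export
RATE_LAWS <- c("trivial", "michaelis_menten", "thermodynamic",
               "mass_action", "haldane")

# Kinetic constants each kind needs before a rate can be evaluated.
.required_fields <- list(
  trivial          = "kcat_fwd",
  michaelis_menten = c("kcat_fwd", "K_S"),
  thermodynamic    = c("kcat_fwd", "K_eq"),
  mass_action      = c("kcat_fwd", "K_S", "K_eq"),
  haldane          = c("kcat_fwd", "K_S", "K_P", "K_eq")
)

match_rate_law <- function(kind) {
  if (length(kind) != 1L || !kind %in% RATE_LAWS)
    stop_validation("unknown rate law '%s' (must be one of: %s)",
                    paste(kind, collapse = ","), paste(RATE_LAWS, collapse = ", "))
  kind
}

#' Kinetic constants of a uni-uni reaction
#'
#' Bundles the turnover number, Michaelis constants and equilibrium constant
#' of one reaction. All supplied constants must be strictly positive. When
#' `kcat_rev`, `K_S`, `K_P` and `K_eq` are all supplied they must satisfy the
#' Haldane relationship `K_eq = (kcat_fwd/kcat_rev) * (K_P/K_S)` to within
#' relative 1e-9; when `kcat_rev` is omitted but the other three constants are
#' present, it is derived from that relationship.
#'
#' @param kcat_fwd forward turnover number (time^-1, or specific activity).
#' @param K_S substrate Michaelis constant (concentration), optional.
#' @param K_P product Michaelis constant (concentration), optional.
#' @param K_eq equilibrium constant (dimensionless for uni-uni), optional.
#' @param kcat_rev reverse turnover number, optional.
#' @return An object of class `"reaction_kinetics"`.
#' @examples
#' reaction_kinetics(kcat_fwd = 1, K_S = 1, K_P = 10, K_eq = 1)
#' @export
reaction_kinetics <- function(kcat_fwd, K_S = NULL, K_P = NULL, K_eq = NULL,
                              kcat_rev = NULL) {
  kin <- list(kcat_fwd = kcat_fwd, K_S = K_S, K_P = K_P, K_eq = K_eq,
              kcat_rev = kcat_rev)
  for (nm in names(kin)) {
    x <- kin[[nm]]
    if (!is.null(x)) {
      if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
        stop_validation("kinetic constant '%s' must be a single positive number", nm)
    }
  }
  if (!is.null(kin$kcat_rev) && !is.null(kin$K_S) && !is.null(kin$K_P) &&
      !is.null(kin$K_eq)) {
    haldane <- (kin$kcat_fwd / kin$kcat_rev) * (kin$K_P / kin$K_S)
    if (abs(haldane - kin$K_eq) > 1e-9 * kin$K_eq)
      stop_validation(paste0(
        "kinetic constants violate the Haldane relationship: ",
        "(kcat_fwd/kcat_rev)*(K_P/K_S) = %.12g but K_eq = %.12g"),
        haldane, kin$K_eq)
  }
  if (is.null(kin$kcat_rev) && !is.null(kin$K_S) && !is.null(kin$K_P) &&
      !is.null(kin$K_eq)) {
    kin$kcat_rev <- kin$kcat_fwd * kin$K_P / (kin$K_S * kin$K_eq)
  }
  structure(kin, class = "reaction_kinetics")
}

check_required_fields <- function(kind, kin) {
  need <- .required_fields[[kind]]
  have <- vapply(need, function(nm) !is.null(kin[[nm]]), logical(1))
  if (!all(have))
    stop_validation("rate law '%s' requires kinetic constants: %s (missing: %s)",
                    kind, paste(need, collapse = ", "),
                    paste(need[!have], collapse = ", "))
  invisible(TRUE)
}

#' Thermodynamic driving force of a reaction
#'
#' Computes `theta = ln(K_eq * s / p)`, the dimensionless driving force
#' (the negative Gibbs free energy of reaction in units of RT). Positive
#' `theta` means the net flux runs forward; `p = 0` gives `theta = Inf`
#' (irreversible limit).
#'
#' @param s_sub substrate concentration (> 0).
#' @param s_prod product concentration (>= 0; 0 maps to `Inf`).
#' @param K_eq equilibrium constant (> 0).
#' @return The driving force, a dimensionless scalar (may be negative).
#' @examples
#' driving_force(10, 1, 1)   # log(10)
#' driving_force(1, 1, exp(1)) # 1
#' @export
driving_force <- function(s_sub, s_prod, K_eq) {
  if (!is.finite(s_sub) || s_sub <= 0 || !is.finite(K_eq) || K_eq <= 0)
    stop_validation("driving_force() requires s_sub > 0 and K_eq > 0")
  if (length(s_prod) != 1L || is.na(s_prod) || s_prod < 0)
    stop_validation("driving_force() requires s_prod >= 0")
  if (s_prod == 0) return(Inf)
  log(K_eq * s_sub / s_prod)
}

#' Thermodynamic and saturation efficiencies
#'
#' Factorizes the reversible saturable (Haldane) rate law into the
#' thermodynamic force efficiency `eta_for = 1 - exp(-theta)` and the
#' saturation efficiency `eta_sat = (s/K_S) / (1 + s/K_S + p/K_P)`, so that
#' `v = eps * kcat_fwd * eta_for * eta_sat`.
#'
#' @param s_sub substrate concentration (>= 0).
#' @param s_prod product concentration (>= 0; 0 gives `eta_for = 1`).
#' @param kin a [reaction_kinetics()] object with `K_S`, `K_P`, `K_eq`.
#' @return A named list with components `eta_for` and `eta_sat`.
#' @examples
#' kin <- reaction_kinetics(1, K_S = 1, K_P = 10, K_eq = 1)
#' efficiencies(10, 1, kin)
#' @export
efficiencies <- function(s_sub, s_prod, kin) {
  check_required_fields("haldane", kin)
  if (s_sub < 0 || s_prod < 0)
    stop_validation("concentrations must be non-negative")
  eta_for <- if (s_prod == 0) 1 else 1 - exp(-driving_force(s_sub, s_prod, kin$K_eq))
  eta_sat <- (s_sub / kin$K_S) / (1 + s_sub / kin$K_S + s_prod / kin$K_P)
  list(eta_for = eta_for, eta_sat = eta_sat)
}

# Rate per unit enzyme k(s, p) for each law, plus its partial derivatives.
# These are the computational core shared by evaluate_rate(), enzyme_demand(),
# the convex objective and the elasticity matrix.
rate_per_enzyme <- function(kind, kin, s_sub, s_prod) {
  kind <- match_rate_law(kind)
  check_required_fields(kind, kin)
  switch(kind,
    trivial = kin$kcat_fwd,
    michaelis_menten = kin$kcat_fwd * s_sub / (s_sub + kin$K_S),
    thermodynamic = kin$kcat_fwd * (1 - s_prod / (s_sub * kin$K_eq)),
    mass_action = (kin$kcat_fwd / kin$K_S) * (s_sub - s_prod / kin$K_eq),
    haldane = {
      kr <- kin$kcat_rev
      if (is.null(kr)) kr <- kin$kcat_fwd * kin$K_P / (kin$K_S * kin$K_eq)
      num <- kin$kcat_fwd * s_sub / kin$K_S - kr * s_prod / kin$K_P
      den <- 1 + s_sub / kin$K_S + s_prod / kin$K_P
      num / den
    })
}

# Partial derivatives (d k/d s, d k/d p) of the rate per unit enzyme.
rate_per_enzyme_grad <- function(kind, kin, s_sub, s_prod) {
  kind <- match_rate_law(kind)
  switch(kind,
    trivial = c(0, 0),
    michaelis_menten = c(kin$kcat_fwd * kin$K_S / (s_sub + kin$K_S)^2, 0),
    thermodynamic = c(kin$kcat_fwd * s_prod / (s_sub^2 * kin$K_eq),
                      -kin$kcat_fwd / (s_sub * kin$K_eq)),
    mass_action = c(kin$kcat_fwd / kin$K_S,
                    -kin$kcat_fwd / (kin$K_S * kin$K_eq)),
    haldane = {
      kr <- kin$kcat_rev
      if (is.null(kr)) kr <- kin$kcat_fwd * kin$K_P / (kin$K_S * kin$K_eq)
      k <- rate_per_enzyme(kind, kin, s_sub, s_prod)
      den <- 1 + s_sub / kin$K_S + s_prod / kin$K_P
      c((kin$kcat_fwd - k) / (kin$K_S * den),
        -(kr + k) / (kin$K_P * den))
    })
}

#' Evaluate a rate law
#'
#' Computes the flux `v` of a single reaction at enzyme level `eps` and
#' reactant concentrations `s_sub`, `s_prod`. The rate is linear in `eps`
#' for every law.
#'
#' @param kind one of [RATE_LAWS].
#' @param kin a [reaction_kinetics()] object carrying the constants the law
#'   requires.
#' @param eps enzyme level (>= 0).
#' @param s_sub,s_prod substrate and product concentrations. Laws that ignore
#'   the product (`"trivial"`, `"michaelis_menten"`) accept a missing
#'   `s_prod`.
#' @return The flux `v` (may be negative for reversible laws when the
#'   driving force is negative).
#' @examples
#' kin <- reaction_kinetics(1, K_S = 1, K_eq = 2)
#' evaluate_rate("mass_action", kin, eps = 1, s_sub = 1, s_prod = 1) # 0.5
#' @export
evaluate_rate <- function(kind, kin, eps, s_sub = NULL, s_prod = NULL) {
  if (is.null(eps) || eps < 0) stop_validation("enzyme level must be >= 0")
  kind <- match_rate_law(kind)
  if (kind != "trivial" && (is.null(s_sub) || s_sub < 0))
    stop_validation("rate law '%s' requires a substrate concentration", kind)
  if (kind %in% c("thermodynamic", "mass_action", "haldane")) {
    if (is.null(s_prod) || s_prod < 0)
      stop_validation("rate law '%s' requires a product concentration", kind)
  }
  if (is.null(s_sub)) s_sub <- 1
  if (is.null(s_prod)) s_prod <- 0
  eps * rate_per_enzyme(kind, kin, s_sub, s_prod)
}

#' Enzyme demand at a given rate
#'
#' Inverts [evaluate_rate()] in the enzyme level: the enzyme amount needed to
#' sustain flux `v` at the given reactant concentrations,
#' `eps = v / k(s, p)` where `k` is the rate per unit enzyme.
#'
#' @inheritParams evaluate_rate
#' @param v required flux (> 0).
#' @return The enzyme level `eps` such that
#'   `evaluate_rate(kind, kin, eps, s_sub, s_prod) == v`.
#' @examples
#' enzyme_demand("trivial", reaction_kinetics(2), v = 1) # 0.5
#' @export
enzyme_demand <- function(kind, kin, v, s_sub = NULL, s_prod = NULL) {
  if (is.null(v) || !is.finite(v) || v <= 0)
    stop_validation("enzyme_demand() requires v > 0")
  kind <- match_rate_law(kind)
  if (is.null(s_sub)) s_sub <- 1
  if (is.null(s_prod)) s_prod <- 0
  k <- rate_per_enzyme(kind, kin, s_sub, s_prod)
  if (!is.finite(k) || k <= 0)
    stop_infeasible(paste0(
      "non-positive rate per unit enzyme (%.6g) at s = %.6g, p = %.6g: ",
      "the reaction cannot carry a positive flux at these concentrations"),
      k, s_sub, s_prod)
  v / k
}

#' Reduce a two-substrate two-product reaction to effective uni-uni constants
#'
#' For a convenience-kinetics reaction A + B <-> P + Q in which the
#' co-substrate `b` and co-product `q` are held at fixed concentrations, the
#' rate as a function of the remaining free substrate `a = s` and product
#' `p` has exactly the uni-uni Haldane form with effective constants. This
#' function returns those constants; the reduced law reproduces the full
#' convenience-kinetics rate for all `(s, p)`.
#'
#' Convenience kinetics for A + B <-> P + Q:
#' `v = eps * (kcat_fwd (a/K_A)(b/K_B) - kcat_rev (p/K_P)(q/K_Q)) /
#'   ((1 + a/K_A)(1 + b/K_B) + (1 + p/K_P)(1 + q/K_Q) - 1)`.
#'
#' @param kcat_fwd,kcat_rev forward/reverse turnover numbers of the full
#'   reaction.
#' @param K_A,K_B,K_P,K_Q Michaelis constants of the four reactants.
#' @param b,q fixed co-substrate and co-product concentrations (> 0).
#' @return A [reaction_kinetics()] object with effective constants
#'   `kcat_fwd'`, `kcat_rev'`, `K_S'`, `K_P'` and `K_eq'` satisfying the
#'   Haldane relationship. The effective equilibrium constant equals
#'   `K_eq * b / q`, consistent with fixing `b` and `q` in the mass-action
#'   ratio.
#' @export
effective_uniuni_params <- function(kcat_fwd, kcat_rev, K_A, K_B, K_P, K_Q,
                                    b, q) {
  for (x in list(kcat_fwd, kcat_rev, K_A, K_B, K_P, K_Q, b, q))
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop_validation("all kinetic constants and fixed concentrations must be positive")
  D0 <- 1 + b / K_B + q / K_Q
  kf_eff <- kcat_fwd * (b / K_B) / (1 + b / K_B)
  kr_eff <- kcat_rev * (q / K_Q) / (1 + q / K_Q)
  KS_eff <- K_A * D0 / (1 + b / K_B)
  KP_eff <- K_P * D0 / (1 + q / K_Q)
  Keq_eff <- (kf_eff / kr_eff) * (KP_eff / KS_eff)
  reaction_kinetics(kcat_fwd = kf_eff, K_S = KS_eff, K_P = KP_eff,
                    K_eq = Keq_eff, kcat_rev = kr_eff)
}

#' Full convenience-kinetics rate (reference form)
#'
#' Direct evaluation of the two-substrate two-product convenience-kinetics
#' rate law; used as the independent reference that
#' [effective_uniuni_params()] must reproduce.
#'
#' @inheritParams effective_uniuni_params
#' @param eps enzyme level.
#' @param a,p free substrate and product concentrations.
#' @return The flux `v`.
#' @export
convenience_rate <- function(eps, kcat_fwd, kcat_rev, K_A, K_B, K_P, K_Q,
                             a, b, p, q) {
  num <- kcat_fwd * (a / K_A) * (b / K_B) - kcat_rev * (p / K_P) * (q / K_Q)
  den <- (1 + a / K_A) * (1 + b / K_B) + (1 + p / K_P) * (1 + q / K_Q) - 1
  eps * num / den
}
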