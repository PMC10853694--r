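# Coarse-grained three-sector cell: transport -> metabolism -> translation.
# With Michaelis-Menten kinetics and a fixed external nutrient concentration,
# the optimal allocation yields a Monod growth law whose parameters are
# explicit functions of the kinetic constants.

#' Three-step cell model specification
#'
#' Lumped kinetics of a growing cell: a transporter (kcat_t, K_Mt) importing
#' the external nutrient `s_sugar`, a metabolic sector (kcat_m, K_Mm) and a
#' ribosomal/translation sector (kcat_r, K_Mr), under a protein budget
#' `eps_tot` and a bound `s_tot` on the two internal metabolite pools.
#' `s_sugar` is an environmental parameter: it is fixed, not optimized, and
#' excluded from the `s_tot` sum.
#'
#' @param kcat_t,kcat_m,kcat_r turnover numbers of the three sectors
#'   (time^-1).
#' @param K_Mt,K_Mm,K_Mr Michaelis constants (concentration).
#' @param eps_tot protein budget (> 0).
#' @param s_tot internal metabolite budget (> 0).
#' @return An object of class `"cell_model_spec"`.
#' @examples
#' cm <- cell_model_spec()        # the all-ones toy cell with K_Mm = 2
#' monod_parameters(cm)
#' @export
cell_model_spec <- function(kcat_t = 1, kcat_m = 1, kcat_r = 1,
                            K_Mt = 1, K_Mm = 2, K_Mr = 1,
                            eps_tot = 1, s_tot = 1) {
  vals <- list(kcat_t = kcat_t, kcat_m = kcat_m, kcat_r = kcat_r,
               K_Mt = K_Mt, K_Mm = K_Mm, K_Mr = K_Mr,
               eps_tot = eps_tot, s_tot = s_tot)
  for (nm in names(vals))
    if (!is.numeric(vals[[nm]]) || length(vals[[nm]]) != 1L || vals[[nm]] <= 0)
      stop_validation("cell model parameter '%s' must be a single positive number", nm)
  structure(vals, class = "cell_model_spec")
}

# The 3-reaction pathway underlying the cell model, with fixed s0 = s_sugar.
cell_pathway <- function(cm, s_sugar) {
  pathway_spec(
    reactions = list(
      reaction_kinetics(cm$kcat_t, K_S = cm$K_Mt),
      reaction_kinetics(cm$kcat_m, K_S = cm$K_Mm),
      reaction_kinetics(cm$kcat_r, K_S = cm$K_Mr)),
    s0 = s_sugar, eps_tot = cm$eps_tot, s_tot = cm$s_tot)
}

#' Growth law container
#'
#' Parameters of an optimal-allocation growth law: hyperbolic (Monod) for
#' Michaelis-Menten kinetics, or the thermodynamic variant
#' `mu = mu_max * (1 - (A/s_sugar)^B)`. The mass-action rate law admits no
#' growth law of either form — its flux is exactly linear in the nutrient
#' concentration with no saturation, so the constructor refuses it.
#'
#' @param mu_max maximal growth rate (> 0).
#' @param K_Monod half-saturation nutrient concentration (monod law).
#' @param law_kind `"monod"` or `"thermodynamic"`.
#' @param A,B thermodynamic-variant parameters: `A` is the nutrient level of
#'   zero growth (`sn / K_eq_tot`), `B = ||alpha||_1 / ||alpha||_{1/2}` in
#'   (0, 1].
#' @return An object of class `"growth_law"`.
#' @export
growth_law <- function(mu_max, K_Monod = NULL, law_kind = c("monod", "thermodynamic"),
                       A = NULL, B = NULL) {
  if (identical(law_kind, "mass_action"))
    stop_validation(paste0(
      "no growth law exists for the mass-action rate law: the optimal flux is ",
      "linear in s_sugar without saturation, so mu_max and K_Monod are undefined"))
  law_kind <- match.arg(law_kind)
  if (mu_max <= 0) stop_validation("mu_max must be positive")
  if (law_kind == "monod") {
    if (is.null(K_Monod) || K_Monod <= 0)
      stop_validation("the Monod law requires K_Monod > 0")
  } else {
    if (is.null(A) || is.null(B) || A <= 0 || B <= 0 || B > 1)
      stop_validation("the thermodynamic law requires A > 0 and 0 < B <= 1")
  }
  structure(list(mu_max = mu_max, K_Monod = K_Monod, law_kind = law_kind,
                 A = A, B = B), class = "growth_law")
}

#' @export
print.growth_law <- function(x, ...) {
  if (x$law_kind == "monod")
    cat(sprintf("Monod growth law: mu_max = %.12g, K_Monod = %.12g\n",
                x$mu_max, x$K_Monod))
  else
    cat(sprintf("Thermodynamic growth law: mu_max = %.12g, A = %.12g, B = %.12g\n",
                x$mu_max, x$A, x$B))
  invisible(x)
}

#' Monod parameters from cell kinetics
#'
#' The optimal fixed-s0 Michaelis-Menten allocation on the three-step chain
#' gives a growth rate of Monod form
#' `mu = mu_max * s_sugar / (s_sugar + K_Monod)` with
#' `mu_max = eps_tot / D` and `K_Monod = (K_Mt/kcat_t) / D`, where
#' `D = 1/kcat_t + 1/kcat_m + 1/kcat_r +
#'   (sqrt(K_Mm/kcat_m) + sqrt(K_Mr/kcat_r))^2 / s_tot`.
#' `mu_max` and `K_Monod` are proportional with ratio
#' `eps_tot / (K_Mt/kcat_t)`, so only `eps_tot` (numerator of `mu_max`),
#' `K_Mt` (numerator of `K_Monod`) and `kcat_t` break the trade-off in which
#' every denominator parameter moves both together.
#'
#' @param cm a [cell_model_spec()].
#' @return A [growth_law()] of kind `"monod"`.
#' @export
monod_parameters <- function(cm) {
  beta_m <- cm$K_Mm / cm$kcat_m
  beta_r <- cm$K_Mr / cm$kcat_r
  D <- 1 / cm$kcat_t + 1 / cm$kcat_m + 1 / cm$kcat_r +
    (sqrt(beta_m) + sqrt(beta_r))^2 / cm$s_tot
  growth_law(mu_max = cm$eps_tot / D,
             K_Monod = (cm$K_Mt / cm$kcat_t) / D, law_kind = "monod")
}

#' Growth rate at a nutrient concentration
#'
#' Evaluates the growth law at `s_sugar`. For the Monod law this equals the
#' fixed-s0 Michaelis-Menten allocation flux on the underlying three-step
#' pathway (the Monod curve is a consequence of optimal allocation, not an
#' independent model).
#'
#' @param law a [growth_law()].
#' @param s_sugar external nutrient concentration (>= 0).
#' @return The growth rate `mu`.
#' @export
growth_rate <- function(law, s_sugar) {
  if (any(s_sugar < 0)) stop_validation("s_sugar must be non-negative")
  if (law$law_kind == "monod")
    return(law$mu_max * s_sugar / (s_sugar + law$K_Monod))
  mu <- law$mu_max * (1 - (law$A / s_sugar)^law$B)
  if (any(mu <= 0))
    stop_infeasible("s_sugar <= A = %.6g: no positive growth is possible", law$A)
  mu
}

#' Protein-sector allocation at a given growth rate
#'
#' Because the irreversible transport step buffers the cytoplasm, the
#' optimal internal metabolite concentrations are independent of the growth
#' rate, and the metabolic and ribosomal sectors grow linearly through the
#' origin with slopes `alpha_m + sqrt(beta_m)*(sqrt(beta_m)+sqrt(beta_r))/s_tot`
#' and the analogous r-term; the transporter takes the remainder
#' `eps_t = eps_tot - eps_m - eps_r` (a falling straight line). At
#' `mu = mu_max` the transporter is fully saturated with abundance
#' `mu_max / kcat_t`.
#'
#' @param cm a [cell_model_spec()].
#' @param mu growth rate, `0 <= mu <= mu_max`.
#' @return A named numeric vector `c(eps_t, eps_m, eps_r)`.
#' @export
sector_allocation <- function(cm, mu) {
  law <- monod_parameters(cm)
  if (any(mu < 0) || any(mu > law$mu_max * (1 + 1e-12)))
    stop_infeasible("mu = %.6g exceeds mu_max = %.6g: infeasible growth rate",
                    max(mu), law$mu_max)
  beta_m <- cm$K_Mm / cm$kcat_m
  beta_r <- cm$K_Mr / cm$kcat_r
  slope_m <- 1 / cm$kcat_m + sqrt(beta_m) * (sqrt(beta_m) + sqrt(beta_r)) / cm$s_tot
  slope_r <- 1 / cm$kcat_r + sqrt(beta_r) * (sqrt(beta_m) + sqrt(beta_r)) / cm$s_tot
  eps_m <- mu * slope_m
  eps_r <- mu * slope_r
  c(eps_t = cm$eps_tot - eps_m - eps_r, eps_m = eps_m, eps_r = eps_r)
}

#' Thermodynamic growth law from pathway kinetics
#'
#' For a cell living on a limited overall driving force (all reactions
#' saturated, thermodynamic rate law), the approximate optimal flux yields
#' `mu(s_sugar) = mu_max * (1 - (A/s_sugar)^B)` with
#' `mu_max = eps_tot/||alpha||_1`, `A = sn/K_eq_tot` and
#' `B = ||alpha||_1/||alpha||_{1/2}`. Growth vanishes as `s_sugar -> A`
#' (product accumulation) and saturates at `mu_max`.
#'
#' @param kcat vector of turnover numbers along the chain.
#' @param K_eq_tot overall equilibrium constant.
#' @param sn downstream product concentration.
#' @param eps_tot protein budget.
#' @return A [growth_law()] of kind `"thermodynamic"`.
#' @export
thermo_growth_parameters <- function(kcat, K_eq_tot, sn, eps_tot) {
  if (any(kcat <= 0) || K_eq_tot <= 0 || sn <= 0 || eps_tot <= 0)
    stop_validation("all thermodynamic growth parameters must be positive")
  alpha <- 1 / kcat
  growth_law(mu_max = eps_tot / norm_l1(alpha), law_kind = "thermodynamic",
             A = sn / K_eq_tot, B = norm_l1(alpha) / norm_half(alpha))
}

#' Sweep one cell-model parameter
#'
#' Recomputes the Monod parameters along a (by default logarithmic) grid of
#' one parameter and classifies its effect: `eps_tot` moves only `mu_max`,
#' `K_Mt` only `K_Monod`, `kcat_t` improves both, and every denominator
#' parameter (`kcat_m`, `kcat_r`, `K_Mm`, `K_Mr`, `s_tot`) trades one off
#' against the other.
#'
#' @param cm a [cell_model_spec()].
#' @param parameter name of a [cell_model_spec()] field.
#' @param grid numeric vector of parameter values.
#' @param s_sugar optional nutrient concentration at which to evaluate `mu`.
#' @return A data frame with columns `value`, `mu_max`, `K_Monod` (and `mu`
#'   when `s_sugar` is given); the classification is in
#'   `attr(, "effect")`.
#' @export
parameter_sweep <- function(cm, parameter, grid, s_sugar = NULL) {
  if (!parameter %in% setdiff(names(unclass(cm)), NULL))
    stop_validation("unknown cell model parameter '%s'", parameter)
  rows <- lapply(grid, function(v) {
    cm2 <- cm; cm2[[parameter]] <- v
    law <- monod_parameters(cm2)
    data.frame(value = v, mu_max = law$mu_max, K_Monod = law$K_Monod,
               mu = if (is.null(s_sugar)) NA_real_ else growth_rate(law, s_sugar))
  })
  out <- do.call(rbind, rows)
  if (is.null(s_sugar)) out$mu <- NULL
  attr(out, "effect") <- switch(parameter,
    eps_tot = "mu_max_only", K_Mt = "K_Monod_only", kcat_t = "both_beneficial",
    "trade_off")
  out
}
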