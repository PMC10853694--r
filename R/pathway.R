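# The unbranched pathway container S0 <-> S1 <-> ... <-> Sn and the derived
# per-reaction cost coefficients alpha, beta, gamma.

#' Define an unbranched pathway
#'
#' An ordered chain of uni-uni reactions with boundary concentrations and the
#' resource constraints of the allocation problem: an enzyme budget
#' `eps_tot` (`sum(w_i * eps_i) <= eps_tot`) and an optional bound `s_tot` on
#' the summed concentration of the free metabolites.
#'
#' Boundary metabolites `s0` and `sn` are *fixed* when supplied and free when
#' `NULL`. Reversible rate laws (thermodynamic, mass-action, Haldane) require
#' both boundaries fixed and a positive overall driving force
#' `s0 * K_eq_tot > sn`.
#'
#' @param reactions a list of [reaction_kinetics()] objects (length n >= 1),
#'   ordered from upstream to downstream.
#' @param s0 upstream boundary concentration, or `NULL` if free.
#' @param sn downstream boundary concentration, or `NULL` if free.
#' @param eps_tot total enzyme budget (> 0).
#' @param s_tot bound on the summed free metabolite concentrations, or `NULL`.
#' @param enzyme_weights per-reaction cost weights `w_i` (default 1).
#' @param metabolite_weights per-metabolite weights `b_i` (default 1).
#' @return An object of class `"pathway_spec"`.
#' @examples
#' pw <- pathway_spec(
#'   reactions = list(reaction_kinetics(1), reaction_kinetics(2),
#'                    reaction_kinetics(4)),
#'   eps_tot = 1)
#' solve_trivial(pw)
#' @export
pathway_spec <- function(reactions, s0 = NULL, sn = NULL, eps_tot,
                         s_tot = NULL, enzyme_weights = 1,
                         metabolite_weights = 1) {
  if (!is.list(reactions) || length(reactions) < 1L)
    stop_validation("'reactions' must be a non-empty list of reaction_kinetics")
  if (!all(vapply(reactions, inherits, logical(1), "reaction_kinetics")))
    stop_validation("every element of 'reactions' must be a reaction_kinetics object")
  n <- length(reactions)
  if (!is.numeric(eps_tot) || length(eps_tot) != 1L || eps_tot <= 0)
    stop_validation("eps_tot must be a single positive number")
  if (!is.null(s_tot) && (!is.numeric(s_tot) || s_tot <= 0))
    stop_validation("s_tot must be positive when supplied")
  for (nm in c("s0", "sn")) {
    x <- get(nm)
    if (!is.null(x) && (!is.numeric(x) || length(x) != 1L || x <= 0))
      stop_validation("%s must be a single positive concentration when supplied", nm)
  }
  enzyme_weights <- rep_len(enzyme_weights, n)
  metabolite_weights <- rep_len(metabolite_weights, n + 1L)
  if (any(enzyme_weights <= 0) || any(metabolite_weights <= 0))
    stop_validation("weights must be strictly positive")
  structure(list(reactions = reactions, s0 = s0, sn = sn, eps_tot = eps_tot,
                 s_tot = s_tot, enzyme_weights = enzyme_weights,
                 metabolite_weights = metabolite_weights, n = n),
            class = "pathway_spec")
}

#' @export
print.pathway_spec <- function(x, ...) {
  cat(sprintf("Unbranched pathway with %d reaction(s)\n", x$n))
  cat(sprintf("  s0: %s  sn: %s  eps_tot: %g  s_tot: %s\n",
              if (is.null(x$s0)) "free" else format(x$s0),
              if (is.null(x$sn)) "free" else format(x$sn),
              x$eps_tot,
              if (is.null(x$s_tot)) "unbounded" else format(x$s_tot)))
  invisible(x)
}

kin_field <- function(pw, field) {
  vapply(pw$reactions, function(k) {
    v <- k[[field]]
    if (is.null(v)) NA_real_ else v
  }, numeric(1))
}

# alpha_i = 1/kcat_i, beta_i = K_M,i/kcat_i, gamma_i = beta_i * prod_{j>=i} Keq_j.
# The "norm cache" of the allocation formulas; weighted budgets are absorbed
# here by rescaling kcat_i -> kcat_i / w_i before any solver runs.
norm_cache <- function(pw, use_weights = TRUE) {
  kcat <- kin_field(pw, "kcat_fwd")
  if (use_weights) kcat <- kcat / pw$enzyme_weights
  K_S <- kin_field(pw, "K_S")
  K_eq <- kin_field(pw, "K_eq")
  alpha <- 1 / kcat
  beta <- K_S / kcat
  gamma <- if (all(is.finite(K_eq)))
    beta * rev(cumprod(rev(K_eq))) else rep(NA_real_, pw$n)
  list(alpha = alpha, beta = beta, gamma = gamma, K_eq = K_eq)
}

#' Norms used by the allocation optima
#'
#' `norm_l1(x)` is `sum(x)`; `norm_half(x)` is `(sum(sqrt(x)))^2`, the
#' "l-1/2 norm" that appears in every square-root allocation optimum.
#' `norm_half(x) >= norm_l1(x)`, with equality iff `x` has a single nonzero
#' entry.
#'
#' @param x a non-negative numeric vector.
#' @return A scalar.
#' @export
norm_l1 <- function(x) sum(x)

#' @rdname norm_l1
#' @export
norm_half <- function(x) sum(sqrt(x))^2

#' Overall equilibrium constant and driving force of a pathway
#'
#' `K_eq_tot` is the product of the per-reaction equilibrium constants;
#' `theta_tot = ln(s0 * K_eq_tot / sn)` is the overall driving force between
#' the fixed boundaries.
#'
#' @param pw a [pathway_spec()] with fixed boundaries and `K_eq` on every
#'   reaction.
#' @return A dimensionless scalar.
#' @export
theta_tot <- function(pw) {
  K_eq <- kin_field(pw, "K_eq")
  if (any(!is.finite(K_eq)))
    stop_validation("theta_tot() requires K_eq on every reaction")
  if (is.null(pw$s0) || is.null(pw$sn))
    stop_validation("theta_tot() requires fixed boundary concentrations s0 and sn")
  log(pw$s0 * prod(K_eq) / pw$sn)
}

# Rescale kcat (fwd and rev) by 1/w_i so that all solvers can assume unit
# enzyme weights; reported enzyme levels are un-scaled by unscale_eps().
scaled_pathway <- function(pw) {
  if (all(pw$enzyme_weights == 1)) return(pw)
  pw2 <- pw
  pw2$reactions <- lapply(seq_len(pw$n), function(i) {
    k <- pw$reactions[[i]]
    w <- pw$enzyme_weights[i]
    k$kcat_fwd <- k$kcat_fwd / w
    if (!is.null(k$kcat_rev)) k$kcat_rev <- k$kcat_rev / w
    k
  })
  pw2$enzyme_weights <- rep(1, pw$n)
  pw2
}

unscale_eps <- function(pw, eps_scaled) eps_scaled / pw$enzyme_weights
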