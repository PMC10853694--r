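# Structured-text (YAML) pathway documents, TSV result export, and the
# seeded fixture generator.

SCHEMA_VERSION <- "1.0"

.doc_fields <- c("schema_version", "rate_law", "task", "pathway")
.pathway_fields <- c("reactions", "s0", "sn", "eps_tot", "s_tot",
                     "enzyme_weights", "metabolite_weights")
.reaction_fields <- c("kcat_fwd", "kcat_rev", "K_S", "K_P", "K_eq")
.tasks <- c("allocate", "mca", "steady_state", "growth", "sweep")

.reject_unknown <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop_validation("unknown field '%s' in %s (allowed: %s)",
                    extra[1L], where, paste(allowed, collapse = ", "))
  invisible(TRUE)
}

#' Read a pathway document
#'
#' Parses a YAML pathway document, validates it against the schema (unknown
#' fields are rejected by name; the rate law's required kinetic constants
#' must be present; the Haldane relationship is enforced when over-specified)
#' and returns the document with its `pathway` element materialized as a
#' [pathway_spec()].
#'
#' @param path path to a YAML document written by [write_pathway()] (fields:
#'   `schema_version`, `rate_law`, `task`, `pathway`).
#' @return A list with elements `schema_version`, `rate_law`, `task`,
#'   `pathway`.
#' @export
read_pathway <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  doc <- yaml::read_yaml(path)
  .reject_unknown(doc, .doc_fields, "document")
  for (f in .doc_fields) if (is.null(doc[[f]]))
    stop_validation("missing required field '%s' in document", f)
  if (!identical(doc$schema_version, SCHEMA_VERSION))
    stop_validation("unsupported schema_version '%s' (expected '%s')",
                    doc$schema_version, SCHEMA_VERSION)
  match_rate_law(doc$rate_law)
  if (!doc$task %in% .tasks)
    stop_validation("unknown task '%s' (allowed: %s)", doc$task,
                    paste(.tasks, collapse = ", "))
  p <- doc$pathway
  .reject_unknown(p, .pathway_fields, "pathway")
  if (is.null(p$reactions)) stop_validation("pathway has no reactions")
  reactions <- lapply(seq_along(p$reactions), function(i) {
    r <- p$reactions[[i]]
    .reject_unknown(r, .reaction_fields, sprintf("reaction %d", i))
    do.call(reaction_kinetics, r)
  })
  for (i in seq_along(reactions))
    check_required_fields(doc$rate_law, reactions[[i]])
  pw <- pathway_spec(reactions = reactions, s0 = p$s0, sn = p$sn,
                     eps_tot = p$eps_tot, s_tot = p$s_tot,
                     enzyme_weights = p$enzyme_weights %||% 1,
                     metabolite_weights = p$metabolite_weights %||% 1)
  list(schema_version = doc$schema_version, rate_law = doc$rate_law,
       task = doc$task, pathway = pw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pathway document
#'
#' Serializes a [pathway_spec()] to the versioned YAML schema read by
#' [read_pathway()]; `read_pathway(write_pathway(...))` round-trips to an
#' identical object.
#'
#' @param pw a [pathway_spec()].
#' @param rate_law one of [RATE_LAWS].
#' @param task one of `allocate`, `mca`, `steady_state`, `growth`, `sweep`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pathway <- function(pw, rate_law, task, path) {
  match_rate_law(rate_law)
  reactions <- lapply(pw$reactions, function(k) Filter(Negate(is.null), unclass(k)))
  p <- list(reactions = reactions)
  if (!is.null(pw$s0)) p$s0 <- pw$s0
  if (!is.null(pw$sn)) p$sn <- pw$sn
  p$eps_tot <- pw$eps_tot
  if (!is.null(pw$s_tot)) p$s_tot <- pw$s_tot
  p$enzyme_weights <- as.list(pw$enzyme_weights)
  p$metabolite_weights <- as.list(pw$metabolite_weights)
  doc <- list(schema_version = SCHEMA_VERSION, rate_law = rate_law,
              task = task, pathway = p)
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

.fmt12 <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = 12, format = "g"))

#' Export results as a tab-separated table
#'
#' Writes an [optimal_state()] (one row per reaction with `eps_star`,
#' `theta_star`, plus one row per metabolite with `s_star`), a
#' [control_profile()] (one row per reaction with `CJ`), or a
#' [growth_law()] (key-value rows) as TSV with 12 significant digits.
#'
#' @param x the result object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  if (inherits(x, "optimal_state")) {
    n <- length(x$eps_star)
    tab <- data.frame(
      row_type = c(rep("reaction", n), rep("metabolite", n + 1L)),
      index = c(seq_len(n), 0:n),
      eps_star = c(.fmt12(x$eps_star), rep("NA", n + 1L)),
      theta_star = c(.fmt12(x$theta_star), rep("NA", n + 1L)),
      s_star = c(rep("NA", n), .fmt12(x$s_star)),
      stringsAsFactors = FALSE)
    tab <- rbind(tab, data.frame(row_type = "flux", index = NA,
                                 eps_star = "NA", theta_star = "NA",
                                 s_star = .fmt12(x$J_star)))
  } else if (inherits(x, "control_profile")) {
    n <- length(x$flux_control)
    tab <- data.frame(row_type = "reaction", index = seq_len(n),
                      CJ = .fmt12(x$flux_control), stringsAsFactors = FALSE)
  } else if (inherits(x, "growth_law")) {
    keys <- c("mu_max", "K_Monod", "A", "B")
    vals <- unlist(lapply(keys, function(k) x[[k]] %||% NA_real_))
    tab <- data.frame(row_type = "parameter", index = keys,
                      value = .fmt12(vals), stringsAsFactors = FALSE)
  } else if (is.data.frame(x)) {
    tab <- x
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], .fmt12)
  } else {
    stop_validation("write_results() does not know how to serialize a %s",
                    paste(class(x), collapse = "/"))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a random pathway fixture
#'
#' Draws kinetic constants log-uniformly within the given ranges and picks
#' boundary concentrations so that the overall driving force `theta_tot`
#' falls in `theta_range` — every fixture is feasible by construction, and
#' identical `seed` plus configuration reproduces the identical pathway.
#' The caller's RNG state is left untouched.
#'
#' @param seed integer seed.
#' @param n pathway length.
#' @param law one of [RATE_LAWS]; controls which constants are drawn and
#'   whether boundaries are fixed (reversible laws) or free with a metabolite
#'   bound (`michaelis_menten` gets `s_tot = n` unless overridden).
#' @param kcat_range,K_range,Keq_range log-uniform draw ranges.
#' @param theta_range range of the overall driving force (reversible laws).
#' @param s0_range log-uniform range of the upstream boundary concentration.
#' @param eps_tot enzyme budget.
#' @param s_tot metabolite bound (`NULL` = law-specific default).
#' @return A [pathway_spec()].
#' @export
generate_fixture <- function(seed, n, law, kcat_range = c(1, 100),
                             K_range = c(0.01, 10), Keq_range = c(0.1, 1000),
                             theta_range = c(0.5, 10), s0_range = c(0.1, 10),
                             eps_tot = 1, s_tot = NULL) {
  law <- match_rate_law(law)
  for (rng in list(kcat_range, K_range, Keq_range, theta_range, s0_range))
    if (length(rng) != 2L || any(rng <= 0) || rng[1L] >= rng[2L])
      stop_validation("fixture ranges must be positive with lower < upper")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  runif_log <- function(m, rng) exp(stats::runif(m, log(rng[1L]), log(rng[2L])))
  kcat <- runif_log(n, kcat_range)
  K_S <- runif_log(n, K_range)
  K_P <- runif_log(n, K_range)
  K_eq <- runif_log(n, Keq_range)
  reactions <- lapply(seq_len(n), function(i) switch(law,
    trivial = reaction_kinetics(kcat[i]),
    michaelis_menten = reaction_kinetics(kcat[i], K_S = K_S[i]),
    thermodynamic = reaction_kinetics(kcat[i], K_eq = K_eq[i]),
    mass_action = reaction_kinetics(kcat[i], K_S = K_S[i], K_eq = K_eq[i]),
    haldane = reaction_kinetics(kcat[i], K_S = K_S[i], K_P = K_P[i],
                                K_eq = K_eq[i])))
  reversible <- law %in% c("thermodynamic", "mass_action", "haldane")
  s0 <- sn <- NULL
  if (reversible) {
    s0 <- runif_log(1L, s0_range)
    th <- stats::runif(1L, theta_range[1L], theta_range[2L])
    sn <- s0 * prod(K_eq) * exp(-th)
  }
  if (is.null(s_tot) && law == "michaelis_menten") s_tot <- n
  pathway_spec(reactions, s0 = s0, sn = sn, eps_tot = eps_tot, s_tot = s_tot)
}
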