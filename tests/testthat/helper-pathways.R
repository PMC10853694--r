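# Shorthand constructors used across the suite.
mk <- function(kcat, K_S = NULL, K_P = NULL, K_eq = NULL, kcat_rev = NULL)
  reaction_kinetics(kcat, K_S = K_S, K_P = K_P, K_eq = K_eq, kcat_rev = kcat_rev)

chain <- function(kcats, ..., eps_tot = 1)
  pathway_spec(lapply(kcats, mk), eps_tot = eps_tot, ...)

# n cycling over 1..8 as seeds advance, one pathway per (seed, law)
fixture_batch <- function(law, n_fixtures, seed_offset = 0L)
  lapply(seq_len(n_fixtures), function(i)
    generate_fixture(seed = seed_offset + i, n = ((i - 1L) %% 8L) + 1L, law = law))

rel_err <- function(x, ref) max(abs(x - ref) / pmax(abs(ref), .Machine$double.xmin))
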