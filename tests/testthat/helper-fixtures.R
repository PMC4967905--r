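# Shared fixtures, built in code and memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixture_env[[name]]))
    .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

fix_catalog <- function() memo("catalog", build_domain_catalog(8, seed = 1))

# Small two-species scenario with all error kinds injected into species B.
fix_sim <- function() memo("sim", simulate_proteome_pair(
  n_genes = 60, n_families = 16, seed = 2))

fix_survey <- function() memo("survey", {
  sim <- fix_sim()
  run_survey(sim$predicted_a, sim$predicted_b, sim$reference,
             sim$ests_a, sim$ests_b, sim$catalog,
             survey_config(sample_size = 30, seed = 5))
})

# Error-free, divergence-free scenario: the round-trip baseline.
fix_sim_clean <- function() memo("sim_clean", simulate_proteome_pair(
  n_genes = 40, n_families = 12, divergence = 0,
  profile_b = error_profile(), seed = 7))

fix_survey_clean <- function() memo("survey_clean", {
  sim <- fix_sim_clean()
  run_survey(sim$predicted_a, sim$predicted_b, sim$reference,
             sim$ests_a, sim$ests_b, sim$catalog,
             survey_config(sample_size = 20, seed = 3))
})

# Truth-level domain architecture (family names in order) for a gene.
truth_arch <- function(proteome, gene_id) {
  d <- proteome$domains
  d <- d[d$protein_id == gene_id, ]
  d$family[order(d$start)]
}
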