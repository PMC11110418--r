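# end-to-end fixture: a panel with one fully supported causal protein
make_tier1_inputs <- function(seed = 100, drop_ppi = FALSE,
                              null_external = FALSE) {
  panel <- simulate_panel(n_proteins = 8, causal_ids = 3, theta = 0.4,
                          n_instruments = 10, seed = seed)
  target <- "protein_003"
  cohorts <- simulate_cohorts(
    sim_config(theta = 0.4, n_instruments = 10, n_cohorts = 3, tau = 0,
               seed = seed + 1))
  regions <- list()
  regions[[target]] <- local({
    reg <- simulate_coloc_region("H4", n_snps_region = 60, causal_z = 10,
                                 seed = seed + 2)
    list(ds1 = reg$ds1, ds2 = reg$ds2)
  })
  external <- data.frame(protein_id = target,
                         twas_q = if (null_external) NA_real_ else 0.001,
                         pwas_q = NA_real_, stringsAsFactors = FALSE)
  ppi <- list(edges = data.frame(node1 = target, node2 = "drug_target_A",
                                 score = 0.9, stringsAsFactors = FALSE),
              drug_targets = "drug_target_A")
  if (drop_ppi) ppi <- NULL
  list(discovery = panel,
       replication = stats::setNames(list(cohorts$cohorts), target),
       coloc_regions = regions, external = external, ppi = ppi)
}
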