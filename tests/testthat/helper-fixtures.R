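# Shared fixtures: toy genes, small configurations, random panels.

# the 6-nt toy pair: trimmed V "CATTGA" / trimmed J "GATCAC" share "GA"
toy_v <- function() germline_gene("Vt", "CATTGA", end = "V_3prime")
toy_j <- function() germline_gene("Jt", "GATCAC", end = "J_5prime")
toy_pair <- function() gene_pair(toy_v(), toy_j())

# same junction-proximal structure embedded in genes long enough for the
# full [-2, 14] trim grid (289 scenarios)
long_v <- function() germline_gene("Vl", "GGCCGGCCGGCATTGA", end = "V_3prime")
long_j <- function() germline_gene("Jl", "GATCACGGCCGGCCGG", end = "J_5prime")
long_pair <- function() gene_pair(long_v(), long_j())

# bounds small enough for 6-nt toy genes (t + 2 <= 8)
toy_config <- function(...) feature_config(trim_bounds = c(-2L, 4L), ...)

random_gene <- function(len, end, name) {
  germline_gene(name, paste(sample(c("A", "C", "G", "T"), len,
                                   replace = TRUE), collapse = ""),
                end = end)
}

random_pair <- function(len_range = c(16L, 24L)) {
  gene_pair(random_gene(sample(len_range[1]:len_range[2], 1), "V_3prime", "Vr"),
            random_gene(sample(len_range[1]:len_range[2], 1), "J_5prime", "Jr"))
}

random_params <- function(config = feature_config(), sd = 0.2) {
  tn <- trim_feature_names(config)
  model_params(stats::setNames(stats::rnorm(length(tn), 0, sd), tn),
               beta_lig = stats::rnorm(1, 0, sd))
}

# small simulated world used by several tests
small_sim_world <- function(seed, n = 2000L, regime = "both",
                            n_v = 4L, n_j = 3L, q_filter = "both") {
  cfg <- simulation_config(n_v = n_v, n_j = n_j, regime = regime,
                           n_sequences = n, q_filter = q_filter,
                           seed = seed)
  panel <- make_fixture_germlines(cfg)
  records <- simulate_repertoire(panel, cfg)
  dataset <- annotate_records(records, panel)
  list(cfg = cfg, panel = panel, records = records, dataset = dataset)
}
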