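# Shared fixtures built in code.

threshold_model <- function() {
  load_model(system.file("extdata", "models", "threshold.json",
                         package = "tipigtow", mustWork = TRUE))
}

oscillator_model <- function() {
  load_model(system.file("extdata", "models", "oscillator.json",
                         package = "tipigtow", mustWork = TRUE))
}

# Threshold-style model with the steady-state threshold exposed as a
# parameter, for randomized closed-form checks (limit = s / theta).
threshold_model_theta <- function(s = 10, theta = 2, horizon = 30) {
  define_model(species = c(X = 0),
               parameters = c(s = s, kd = 1, theta = theta),
               rates = c(X = "s - kd*X"),
               viability = list(expression = "X >= theta", horizon = horizon),
               gene_map = list(G1 = list(synthesis = "s", products = "X")),
               name = "threshold-theta")
}

# Toy cell-cycle model exercising lumped genes and complex-activity
# parameters for the strain-to-mutant mapping tests. Dynamics are not
# integrated in those tests; only gene_map/parameters matter.
mapping_model <- function() {
  define_model(
    species = c(cln = 0.1, clb = 0.1, apc = 0.1),
    parameters = c(ks_cln = 1, ks_clb = 1, ks_apc = 1, act_SBF = 1,
                   act_MBF = 1, kd_apc = 1),
    rates = c(cln = "ks_cln*act_SBF - cln", clb = "ks_clb*act_MBF - clb",
              apc = "ks_apc - kd_apc*apc"),
    viability = list(expression = "apc >= 0", horizon = 1),
    gene_map = list(
      CLN1_CLN2 = list(synthesis = "ks_cln", products = "cln"),
      CLB1_CLB2 = list(synthesis = "ks_clb", products = "clb"),
      CLB5_CLB6 = list(synthesis = "ks_clb", products = "clb"),
      CLN3_BCK2 = list(synthesis = "ks_cln", products = "cln"),
      MAD2 = list(synthesis = "ks_apc", products = "apc")),
    name = "mapping-toy")
}

# Published CDC20 deletion-panel values recomputed once by direct
# arithmetic on the packaged means (the independent oracle for the
# pipeline's ratio/relative-change columns).
panel_oracle <- function() {
  tab <- utils::read.delim(system.file("extdata", "cdc20_panel.tsv",
                                       package = "tipigtow", mustWork = TRUE))
  ratio <- tab$tev_mean / tab$vector_mean
  change <- ratio / ratio[tab$strain == "Wild type"] - 1
  change[tab$strain == "Wild type"] <- NA_real_
  list(strain = tab$strain, ratio = ratio, relative_change = change)
}
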