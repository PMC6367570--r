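# Small in-code fixtures shared across tests.

# A minimal native-dialect site table for the default 4-experiment design.
make_site_table <- function(design = default_design()) {
  df <- data.frame(
    protein_id = c("pA", "pA", "pB"),
    position = c(6L, 12L, 7L),
    residue = c("S", "T", "S"),
    sequence_window = c("HARAASAAAAA", "AAKAATAAAAA", "AAAAASAAAAA"),
    stringsAsFactors = FALSE)
  for (id in design$experiment_id) {
    df[[paste0("ratio_", id)]] <- c(0.25, 1, 2)
    df[[paste0("locprob_", id)]] <- c(0.99, 0.8, 0.95)
  }
  df$site_id <- paste(df$protein_id, df$position, sep = "_")
  df
}

make_quant <- function(site_id, log2fc, log2fc_norm = NA_real_,
                       locprob = 1, experiment_id = "R1") {
  q <- data.frame(site_id = site_id, log2fc = log2fc,
                  log2fc_norm = rep_len(log2fc_norm, length(site_id)),
                  locprob = rep_len(locprob, length(site_id)),
                  stringsAsFactors = FALSE)
  attr(q, "experiment_id") <- experiment_id
  q
}

# noise-free generator configuration used by several exact-limit tests
noise_free_config <- function(...) {
  args <- utils::modifyList(
    list(n_proteins = 40L, protein_length_mean = 120,
         n_null_sites = 60L, n_true_substrates = 10L,
         noise_sd_log2 = 0, missing_rate = 0,
         locprob_alpha = 200, locprob_beta = 1,
         frac_abundance_shifted_proteins = 0,
         protein_noise_sd_log2 = 0, seed = 11L),
    list(...))
  do.call(synthetic_config, args)
}
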