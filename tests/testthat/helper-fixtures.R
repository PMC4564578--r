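# Small shared fixtures, built in code at test time.

small_config <- function(...) {
  defaults <- list(n_genes = 600, frac_down = 0.15, frac_up = 0.15,
                   n_decoy_tfs = 40, n_decoy_marks = 20,
                   n_decoy_pathways = 40, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

identity_map <- function(genes) {
  data.frame(rat_symbol = genes, human_symbol = toupper(genes),
             stringsAsFactors = FALSE)
}

# Hand-built target calls covering all four flag combinations twice,
# with chip and roadmap evidence agreeing for some genes only.
toy_calls <- function() {
  df <- data.frame(
    gene = paste0("g", 1:6),
    human_symbol = paste0("G", 1:6),
    is_REST_target = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
    is_PRC_target = c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE),
    has_H3K4me1 = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
    has_H3K27me3 = c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE),
    rest_terms = "", prc_terms = "", h3k4me1_terms = "",
    h3k27me3_terms = "",
    stringsAsFactors = FALSE)
  class(df) <- c("target_calls", "data.frame")
  df
}
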