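# Small shared fixtures built in code.

# A tiny end-to-end cohort: 10 kb genome, a handful of loci, modest coverage.
# Cached per session because several test files reuse it.
tiny_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- alu_run_config(
        chrom_len = 2.5e4,
        design = c(fixed_ingroup = 2, polymorphic_ingroup = 2,
                   species_indicative = 6, intergeneric_shared = 6,
                   intergeneric_private = 1),
        readsim = read_sim_params(coverage = 18, err_rate = 0),
        seed = 11L)
      cache <<- run_alu_pipeline(cfg)
    }
    cache
  }
})

# Hand-built detection matrix: carriers given as a list of id vectors.
manual_matrix <- function(carrier_sets, cohort = papio_gelada_cohort(),
                          spacing = 1000L) {
  calls <- do.call(rbind, lapply(seq_along(carrier_sets), function(i) {
    ids <- carrier_sets[[i]]
    if (!length(ids)) return(NULL)
    data.frame(call_id = paste0("c", i, "_", ids), individual_id = ids,
               chrom = "chr1", pos = i * spacing, support = 1L, n_5p = 1L,
               max_5p_flank = 50L, strand = "+", stringsAsFactors = FALSE)
  }))
  loci <- cluster_calls(calls, 25L)
  build_matrix(loci, cohort)
}
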