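# Shared fixtures: one small genome/architecture pair and one noiseless
# simulation, built once per test run.

fix_config <- sim_config(
  chromosomes = data.frame(name = c("chr1", "chr2", "chr3"),
                           length = c(8e6, 6e6, 4e6)),
  n_reads = 400)
fix_genome <- build_genome(fix_config, seed = 11)
fix_arch <- plant_architecture(fix_genome, fix_config, seed = 12)

noiseless_config <- sim_config(
  chromosomes = data.frame(name = c("chr1", "chr2", "chr3"),
                           length = c(8e6, 6e6, 4e6)),
  n_reads = 400, split_rate = 0, jitter_sd = 0, low_mapq_rate = 0,
  gap_pass_rate = 0)
fix_noiseless <- simulate_reads(fix_genome, fix_arch, noiseless_config,
                                seed = 13)

# truth fragments as an assembled multiway table (clean reads)
truth_as_multiway <- function(sim) {
  tf <- data.table::copy(sim$truth_fragments)
  tf[, mapq := 60L]
  tf[, frag_class := "both_ends_matched"]
  assemble_multiway(tf)
}
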