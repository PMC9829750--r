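# Small cohorts and tables shared across test files.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_patients = 2, pairs_per_patient = 1, n_chromosomes = 2,
                   cpgs_per_chromosome = 150, seed = 11L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# A hand-built methylome tibble (already valid and sorted).
make_methylome <- function(sample_id, patient_id, tissue, cpg_id, chrom, pos,
                           log2ratio) {
  tibble::tibble(sample_id = sample_id, patient_id = patient_id,
                 tissue = tissue, cpg_id = cpg_id, chrom = chrom, pos = pos,
                 log2ratio = log2ratio)
}

node_sets_for_test <- function(hc) methpair:::node_leaf_sets(hc)

# State-call tibble shortcut.
make_calls <- function(patient_id, pair_id, cpg_id, state) {
  tibble::tibble(patient_id = patient_id, pair_id = pair_id,
                 cpg_id = cpg_id, state = state)
}
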