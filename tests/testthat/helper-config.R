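# Small simulation configurations shared by the unit tests.

small_sim_config <- function(seed = 7, ...) {
  simulation_config(
    seed = seed,
    architecture_counts = c(NBS_ONLY = 5, CNL = 12, TNL = 2,
                            KINASE_ONLY = 4, LRR_RLK = 8, LRR_RLP = 1,
                            DECOY = 6),
    family_specs = list(family_spec("CNL", 3, 80, co_clustered = TRUE),
                        family_spec("CNL", 2, 80),
                        family_spec("LRR_RLK", 4, 80)),
    ...)
}

# hit-table constructor for catalog tests
mk_hits <- function(gene_id, role, evalue = 1e-10, ali_start = 1,
                    ali_end = 50) {
  acc <- c(NBS = "PF00931", LRR = "PF00560", KINASE = "PF00069",
           TIR = "PF01582", OTHER = "PF99999")[role]
  data.frame(gene_id = gene_id, accession = unname(acc), role = role,
             ali_start = ali_start, ali_end = ali_end, evalue = evalue,
             stringsAsFactors = FALSE)
}
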