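# Shared study system for the analysis scripts.
#
# Every script rebuilds the synthetic study system deterministically from
# MASTER_SEED (generation takes seconds), so each step is self-contained
# and re-runnable in isolation. Results are written under results/.

library(invscan)

MASTER_SEED <- 20240101
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

# Study conditions: a 1-Mb reference region, a 200-kb central inversion
# flanked by 3-kb inverted cassettes (95 % identity), 2 % SNP + 1e-4 indel
# divergence, a three-scaffold draft with 606-bp and 4.3-kb gaps, and an
# introgression line carrying the inversion-spanning wild segment.
build_study_system <- function(master_seed = MASTER_SEED) {
  ref <- generate_reference(1e6, gc = 0.36,
                            seed = derive_seed(master_seed, "reference"))
  spec <- inversion_spec(300001, 500000, cassette_len = 3000,
                         cassette_identity = 0.95)
  wd <- derive_wild_genome(ref, spec, snp_rate = 0.02, indel_rate = 1e-4,
                           seed = derive_seed(master_seed, "wild"))
  frag <- fragment_scaffolds(wd$wild, c(250000, 700000), c(606, 4300),
                             seed = derive_seed(master_seed, "fragment"))
  intro <- make_introgression_line(ref, wd$wild, wd$truth,
                                   c(250000, 550000))
  list(ref = ref, wild = wd$wild, truth = wd$truth, spec = spec,
       frag = frag, intro = intro, master_seed = master_seed)
}
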