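#!/usr/bin/env Rscript
# Build the synthetic study system and write its sequences and ground
# truth. Everything downstream is scored against these files.

source("analysis/common.R")

sys <- build_study_system()
out <- file.path(RESULTS_DIR, "synthetic")
dir.create(out, showWarnings = FALSE)

write_fasta(sys$ref, file.path(out, "reference.fasta"))
write_fasta(sys$wild, file.path(out, "wild.fasta"))
write_fasta(sys$frag$scaffolds, file.path(out, "scaffolds.fasta"))
write_fasta(sys$intro$record, file.path(out, "introgression_line.fasta"))
write.table(sys$frag$truth, file.path(out, "scaffold_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
truth_df <- data.frame(
  item = c("inversion_ref_start", "inversion_ref_end",
           "inversion_wild_start", "inversion_wild_end",
           "cassette_len", "introgression_left_junction",
           "introgression_right_junction"),
  value = c(sys$truth$breakpoints_ref, sys$truth$breakpoints_wild,
            sys$truth$cassette_len, sys$intro$junctions)
)
write.table(truth_df, file.path(out, "truth_ledger.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("reference: %s bp; wild: %s bp (%d scaffolds); line: %s bp\n",
            formatC(seq_len_bp(sys$ref), format = "d", big.mark = ","),
            formatC(seq_len_bp(sys$wild), format = "d", big.mark = ","),
            length(sys$frag$scaffolds),
            formatC(seq_len_bp(sys$intro$record), format = "d", big.mark = ",")))
cat(sprintf("planted inversion on reference: %s-%s (wild: %s-%s)\n",
            formatC(sys$truth$breakpoints_ref[1], format = "d", big.mark = ","),
            formatC(sys$truth$breakpoints_ref[2], format = "d", big.mark = ","),
            formatC(sys$truth$breakpoints_wild[1], format = "d", big.mark = ","),
            formatC(sys$truth$breakpoints_wild[2], format = "d", big.mark = ",")))
cat("wrote", out, "\n")
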