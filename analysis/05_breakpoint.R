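#!/usr/bin/env Rscript
# Breakpoint localization from a BAC-like clone of the introgression line,
# and the diagnostic in-silico PCR panel over the three templates.

source("analysis/common.R")

sys <- build_study_system()

## BAC spanning the inversion breakpoint carried by the introgression line
bp_line <- sys$intro$inversion_in_line[1]
bac <- seq_record("bac_breakpoint",
                  subseq_bp(sys$intro$record, bp_line - 40000,
                            bp_line + 40000))
calls <- locate_breakpoints(bac, sys$ref, k = 21)
write.table(as.data.frame(calls),
            file.path(RESULTS_DIR, "breakpoint_calls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
stopifnot(nrow(calls) >= 1)
cat(sprintf("breakpoint call on BAC: query interval %s-%s (truth junction at 40,001), strand switch: %s\n",
            formatC(calls$q_gap_start[1], format = "d", big.mark = ","),
            formatC(calls$q_gap_end[1], format = "d", big.mark = ","),
            calls$strand_switch[1]))
cat(sprintf("left locus %s-%s (%s), right locus %s-%s (%s) on reference\n",
            formatC(calls$left_t_start[1], format = "d", big.mark = ","),
            formatC(calls$left_t_end[1], format = "d", big.mark = ","),
            calls$left_strand[1],
            formatC(calls$right_t_start[1], format = "d", big.mark = ","),
            formatC(calls$right_t_end[1], format = "d", big.mark = ","),
            calls$right_strand[1]))

## diagnostic primer pairs and presence/absence panel
pairs <- design_diagnostic_pairs(sys$ref, sys$wild, sys$intro,
                                 cassette_len = sys$truth$cassette_len)
primers <- data.frame(
  pair = rep(names(pairs), each = 2),
  primer = unlist(lapply(pairs, function(p) c(p$fwd_name, p$rev_name))),
  sequence = unlist(lapply(pairs, function(p) c(p$fwd_seq, p$rev_seq)))
)
write.table(primers, file.path(RESULTS_DIR, "primers.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
panel <- breakpoint_pcr_panel(
  list(reference = sys$ref, wild = sys$wild,
       introgression = sys$intro$record),
  pairs)
write.table(panel, file.path(RESULTS_DIR, "pcr_panel.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("PCR presence/absence panel:\n")
print(panel)
cat(sprintf("pattern matches the diagnostic expectation: %s\n",
            panel_matches_expectation(panel)))
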