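#!/usr/bin/env Rscript
# Compare the wild genome against the reference region: unique k-mer
# anchors, chained synteny blocks, dot-plot data and the inversion call.

source("analysis/common.R")

sys <- build_study_system()
anchors <- find_anchors(sys$wild, sys$ref, k = 21)
blocks <- chain_anchors(anchors)
calls <- call_inversions(blocks, min_size = 10000)

export_dotplot(anchors, file.path(RESULTS_DIR, "dotplot.tsv"))
write_bed(blocks, file.path(RESULTS_DIR, "synteny_blocks.bed"),
          chrom = sys$ref$id)
write_bed(calls, file.path(RESULTS_DIR, "inversion_calls.bed"),
          chrom = sys$ref$id)

cat(sprintf("%d anchors -> %d blocks (%s)\n", nrow(anchors), nrow(blocks),
            paste(blocks$strand, collapse = " ")))
stopifnot(nrow(calls) >= 1)
tr <- sys$truth$breakpoints_ref
cat(sprintf("inversion call: %s-%s (%.0f kb); truth %s-%s; boundary errors %d / %d bp\n",
            formatC(calls$t_start, format = "d", big.mark = ","),
            formatC(calls$t_end, format = "d", big.mark = ","), calls$size_t / 1000,
            formatC(tr[1], format = "d", big.mark = ","), formatC(tr[2], format = "d", big.mark = ","),
            abs(calls$t_start - tr[[1]]), abs(calls$t_end - tr[[2]])))
cat(sprintf("breakpoint intervals (anchor-free): %s-%s and %s-%s\n",
            formatC(calls$left_bp_start, format = "d", big.mark = ","),
            formatC(calls$left_bp_end, format = "d", big.mark = ","),
            formatC(calls$right_bp_start, format = "d", big.mark = ","),
            formatC(calls$right_bp_end, format = "d", big.mark = ",")))
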