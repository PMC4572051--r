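# Readers/writers for the package's interchange formats.
#
# FASTA via Biostrings (60-column wrapping); genotype tables, marker maps,
# placements and truth ledgers as plain TSV. All tabular coordinates are
# 1-based closed except BED (written by write_bed, which states its
# convention in a header line).

#' Read FASTA into a list of sequence records
#'
#' Mixed-case input is uppercased with a warning.
#'
#' @param path FASTA file path.
#' @param build_tag Build tag attached to every record.
#' @return List of [seq_record()] (empty list for an empty file).
#' @export
read_fasta <- function(path, build_tag = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(list())
  set <- Biostrings::readBStringSet(path)
  lapply(seq_along(set), function(i) {
    s <- as.character(set[[i]])
    if (grepl("[a-z]", s)) {
      warning("lower-case bases uppercased in record ", names(set)[i])
      s <- toupper(s)
    }
    seq_record(names(set)[i], s, build_tag = build_tag)
  })
}

#' Write sequence records as FASTA (60-column lines)
#'
#' @param records A [seq_record()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "seq_record")) records <- list(records)
  set <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "seq"))
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' Read a genotype table TSV
#'
#' Expected layout: first column `individual`, remaining columns one per
#' marker, cells in `A,H,B,AH,-`.
#'
#' @param path TSV path.
#' @param markers Optional marker data frame (must match the header); by
#'   default markers are built from the header names.
#' @return A [genotype_table()].
#' @export
read_genotype_table <- function(path, markers = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2) stop("genotype table needs individual + marker columns")
  if (names(df)[1] != "individual") stop("first column must be 'individual'")
  mnames <- names(df)[-1]
  if (is.null(markers)) markers <- data.frame(name = mnames)
  if (!identical(markers$name, mnames)) {
    stop("marker map does not match genotype table header")
  }
  calls <- as.matrix(df[, -1, drop = FALSE])
  genotype_table(df$individual, markers, calls)
}

#' Write a genotype table TSV
#' @param table A [genotype_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(table, path) {
  df <- data.frame(individual = table$individuals, table$calls,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a marker map TSV (name, ref_pos_bp, map_pos_cM)
#' @param path File path.
#' @return Data frame.
#' @export
read_marker_map <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @rdname read_marker_map
#' @param markers Marker data frame.
#' @export
write_marker_map <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All stage parameters for [run_pipeline()], with the study conditions as
#' defaults: a 1-Mb reference region at GC 0.36; a 200-kb central inversion
#' (300,001-500,000) with 3-kb inverted cassettes at 95 % identity; 2 %
#' SNP and 1e-4 indel divergence; fragmentation into three scaffolds with
#' 606-bp and 4.3-kb gaps; an introgression segment spanning the inversion;
#' an intraspecific F2 (n = 100, no suppression, truly inverted marker
#' order) and an interspecific cross (suppressed inverted interval).
#' Per-stage seeds are derived from `master_seed` by the fixed offsets in
#' [derive_seed()].
#'
#' @param master_seed Integer master seed.
#' @param out_dir Output directory for reports and files.
#' @param ... Overrides for any top-level config entry.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(master_seed = 1, out_dir = tempfile("invscan_"),
                            ...) {
  cfg <- list(
    master_seed = as.integer(master_seed),
    out_dir = out_dir,
    ref_length = 1000000, gc = 0.36,
    inversion = list(start = 300001, end = 500000, cassette_len = 3000,
                     cassette_identity = 0.95),
    snp_rate = 0.02, indel_rate = 1e-04,
    breaks = c(250000, 700000), gap_sizes = c(606, 4300),
    introgression_segment = c(250000, 550000),
    k = 21, max_occurrences = 1, max_gap = 20000, max_diag_drift = 1000,
    min_block_anchors = 3, min_inversion_size = 10000,
    f2_n = 100, f2_marker_cM = c(0, 6, 12, 18, 24, 30),
    f2_true_inverted_segment = c(3, 4),
    inter_n = 88, inter_generation = 2,
    suppression_cM = c(10, 20),
    genomewide_cM_per_Mbp = 2, alpha = 0.05,
    max_product_len = 5000
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML (lossless round trip)
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `path` invisibly; for the reader, the config.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Simulate -> synteny -> scaffolding -> genetics -> breakpoint -> PCR, with
#' every result compared against the generator's ground truth. Writes
#' FASTA/TSV/BED/AGP outputs plus a JSON report under `config$out_dir` and
#' returns the report.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return The report, an invisible list (also serialized as
#'   `report.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ms <- config$master_seed

  ## simulate
  say("simulate: reference %d bp (seed %d)", config$ref_length, ms)
  ref <- generate_reference(config$ref_length, config$gc,
                            seed = derive_seed(ms, "reference"))
  invc <- config$inversion
  inv <- inversion_spec(invc$start, invc$end, invc$cassette_len,
                        invc$cassette_identity)
  wd <- derive_wild_genome(ref, inv, snp_rate = config$snp_rate,
                           indel_rate = config$indel_rate,
                           seed = derive_seed(ms, "wild"))
  frag <- fragment_scaffolds(wd$wild, config$breaks, config$gap_sizes,
                             seed = derive_seed(ms, "fragment"))
  intro <- make_introgression_line(ref, wd$wild, wd$truth,
                                   config$introgression_segment)
  write_fasta(ref, file.path(config$out_dir, "reference.fasta"))
  write_fasta(wd$wild, file.path(config$out_dir, "wild.fasta"))
  write_fasta(frag$scaffolds, file.path(config$out_dir, "scaffolds.fasta"))
  write_fasta(intro$record,
              file.path(config$out_dir, "introgression_line.fasta"))
  utils::write.table(frag$truth,
                     file.path(config$out_dir, "scaffold_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## synteny
  say("synteny: anchoring wild vs reference (k=%d)", config$k)
  anchors <- find_anchors(wd$wild, ref, k = config$k,
                          max_occurrences = config$max_occurrences)
  blocks <- chain_anchors(anchors, max_gap = config$max_gap,
                          max_diag_drift = config$max_diag_drift,
                          min_block_anchors = config$min_block_anchors)
  inv_calls <- call_inversions(blocks, min_size = config$min_inversion_size)
  export_dotplot(anchors, file.path(config$out_dir, "dotplot.tsv"))
  write_bed(blocks, file.path(config$out_dir, "blocks.bed"), chrom = ref$id)
  write_bed(inv_calls, file.path(config$out_dir, "inversions.bed"),
            chrom = ref$id)
  inv_truth <- wd$truth$breakpoints_ref
  inv_report <- list(
    n_calls = nrow(inv_calls),
    called = nrow(inv_calls) > 0,
    truth_start = unname(inv_truth["left"]),
    truth_end = unname(inv_truth["right"])
  )
  if (nrow(inv_calls) > 0) {
    best <- inv_calls[which.max(inv_calls$size_t), ]
    inv_report$called_start <- best$t_start
    inv_report$called_end <- best$t_end
    inv_report$size_t <- best$size_t
    if (!is.null(inv_truth)) {
      inv_report$start_error_bp <- abs(best$t_start - inv_truth[["left"]])
      inv_report$end_error_bp <- abs(best$t_end - inv_truth[["right"]])
    }
  }

  ## scaffolding
  say("scaffolding: placing %d scaffolds", length(frag$scaffolds))
  pl <- place_scaffolds(frag$scaffolds, ref, k = config$k,
                        max_occurrences = config$max_occurrences,
                        max_gap = config$max_gap,
                        max_diag_drift = config$max_diag_drift)
  pg <- estimate_gaps(pl$placements)
  ss <- build_superscaffold(pg, frag$scaffolds)
  write_fasta(ss$record, file.path(config$out_dir, "superscaffold.fasta"))
  write_agp(ss, file.path(config$out_dir, "superscaffold.agp"))
  utils::write.table(pg, file.path(config$out_dir, "placements.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- frag$truth
  order_ok <- identical(pg$scaffold_id, tr$scaffold_id)
  orient_ok <- order_ok &&
    all((pg$orientation == "-") == tr$flipped)
  gaps_est <- pg$est_gap_to_next[-nrow(pg)]
  gaps_true <- tr$gap_after[-nrow(tr)]
  scaf_report <- list(
    n_placed = nrow(pg), n_unplaced = length(pl$unplaced),
    order_recovered = order_ok, orientation_recovered = orient_ok,
    gap_estimates = as.numeric(gaps_est), gap_truth = as.numeric(gaps_true),
    gap_errors = as.numeric(abs(gaps_est - gaps_true))
  )

  ## genetics
  say("genetics: intraspecific F2 (n=%d) and interspecific cross (n=%d)",
      config$f2_n, config$inter_n)
  m <- length(config$f2_marker_cM)
  seg <- config$f2_true_inverted_segment
  true_order <- seq_len(m)
  true_order[seg[1]:seg[2]] <- rev(true_order[seg[1]:seg[2]])
  # markers simulated on the true (wild) map, reported in reference order:
  # genotypes observed under the reference order are the simulated columns
  # permuted by the true order
  cfg_f2 <- cross_config(config$f2_n, 2, config$f2_marker_cM,
                         seed = derive_seed(ms, "cross"))
  sim_f2 <- simulate_cross(cfg_f2, inversion_het = FALSE)
  obs_f2 <- genotype_table(sim_f2$table$individuals,
                           sim_f2$table$markers,
                           sim_f2$table$calls[, true_order, drop = FALSE])
  rank <- best_order(obs_f2)
  best_lab <- rank$best$label
  true_lab <- if (seg[2] > seg[1]) sprintf("rev_%d_%d", seg[1], seg[2]) else
    "reference"
  cfg_int <- cross_config(config$inter_n, config$inter_generation,
                          config$f2_marker_cM,
                          suppression_intervals = rbind(config$suppression_cM),
                          seed = derive_seed(ms, "cross") + 1L)
  sim_int <- simulate_cross(cfg_int, inversion_het = TRUE)
  sup_markers <- which(config$f2_marker_cM >= config$suppression_cM[1] &
                         config$f2_marker_cM <= config$suppression_cM[2])
  mA <- sim_int$table$markers$name[sup_markers[1]]
  mB <- sim_int$table$markers$name[sup_markers[length(sup_markers)]]
  pair_bp <- 162000  # physical analogue of the suppressed marker interval
  sup <- detect_suppression(
    sim_int$table,
    data.frame(markerA = mA, markerB = mB, physical_bp = pair_bp,
               expected_cM = diff(config$f2_marker_cM[range(sup_markers)])),
    genomewide_cM_per_Mbp = config$genomewide_cM_per_Mbp,
    alpha = config$alpha
  )
  write_genotype_table(obs_f2,
                       file.path(config$out_dir, "genotypes_intra_f2.tsv"))
  write_genotype_table(sim_int$table,
                       file.path(config$out_dir, "genotypes_inter.tsv"))
  gen_report <- list(
    f2_best_order = best_lab, f2_true_order = true_lab,
    f2_order_recovered = identical(best_lab, true_lab),
    f2_best_total = rank$best$total_crossovers,
    f2_reference_total = rank$reference_total,
    f2_margin = rank$margin,
    inter_recombinants_suppressed_interval = sup$n_recombinant[1],
    inter_n_informative = sup$n_informative[1],
    suppression_flagged = isTRUE(sup$suppressed[1])
  )

  ## breakpoint + PCR
  say("breakpoint: BAC split alignment and diagnostic PCR panel")
  # the BAC-like query spans the inversion breakpoint carried by the
  # introgression line; without an inversion it spans the (collinear)
  # introgression junction and no breakpoint is expected
  bp_line <- if (!is.null(intro$inversion_in_line)) {
    intro$inversion_in_line[1]
  } else intro$junctions[["left"]]
  bac_half <- min(40000, bp_line - 1,
                  seq_len_bp(intro$record) - bp_line)
  bac <- seq_record("bac_breakpoint",
                    subseq_bp(intro$record, bp_line - bac_half,
                              bp_line + bac_half))
  bp_calls <- locate_breakpoints(bac, ref, k = config$k,
                                 max_gap = config$max_gap,
                                 max_diag_drift = config$max_diag_drift)
  bp_report <- list(n_calls = nrow(bp_calls))
  if (nrow(bp_calls) > 0) {
    truth_q <- bac_half + 1
    hit <- bp_calls[which.min(abs((bp_calls$q_gap_start +
                                     bp_calls$q_gap_end) / 2 - truth_q)), ]
    pad <- invc$cassette_len + config$k
    bp_report$truth_in_interval <-
      truth_q >= hit$q_gap_start - pad && truth_q <= hit$q_gap_end + pad
    bp_report$q_interval <- c(hit$q_gap_start, hit$q_gap_end)
    bp_report$strand_switch <- hit$strand_switch
  }

  pairs <- design_diagnostic_pairs(ref, wd$wild, intro,
                                   max_product_len = config$max_product_len,
                                   cassette_len = invc$cassette_len)
  panel <- breakpoint_pcr_panel(
    list(reference = ref, wild = wd$wild, introgression = intro$record),
    pairs
  )
  utils::write.table(panel, file.path(config$out_dir, "pcr_panel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pat_ok <- panel_matches_expectation(panel)

  report <- list(
    coordinates = "1-based closed unless stated otherwise",
    master_seed = ms,
    inversion = inv_report,
    scaffolding = scaf_report,
    genetics = gen_report,
    breakpoint = bp_report,
    pcr_panel = panel,
    pcr_pattern_ok = pat_ok
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  say("report written to %s", file.path(config$out_dir, "report.json"))
  invisible(report)
}

#' Design the three diagnostic primer pairs of the synthetic scenario
#'
#' `junction`: spans the left introgression junction — forward primer from
#' the reference background (absent from the wild genome), reverse from the
#' wild-derived side (absent from the reference) — so only the
#' introgression line amplifies. `reference`: forward as above, reverse
#' from the reference side right of the junction (absent from the
#' introgression line) — only the reference amplifies. `inversion_flank`:
#' spans the inversion breakpoint carried by the introgression line, with
#' both primer sites present in the reference where they lie in the same
#' orientation — the arrangement that yields no standard product from the
#' reference.
#'
#' @param ref,wild Reference and wild [seq_record()].
#' @param intro Output of [make_introgression_line()].
#' @param max_product_len Product size limit for all pairs.
#' @return Named list of [primer_pair()] objects.
#' @export
design_diagnostic_pairs <- function(ref, wild, intro,
                                    max_product_len = 5000,
                                    cassette_len = 0) {
  line <- intro$record
  jL <- intro$junctions[["left"]]
  fwd_j <- design_primer(line, jL - 30, side = "left",
                         present_in = list(ref), absent_in = list(wild))
  rev_site <- design_primer(line, jL + 30, side = "right",
                            absent_in = list(ref))
  fwd_ref <- design_primer(ref, jL - 30, side = "left",
                           present_in = list(line), absent_in = list(wild))
  rev_ref_site <- design_primer(ref, jL + 30, side = "right",
                                absent_in = list(line))
  if (is.null(fwd_j) || is.null(rev_site) || is.null(fwd_ref) ||
      is.null(rev_ref_site)) {
    stop("could not design junction-diagnostic primers")
  }
  out <- list(
    junction = primer_pair("jxnF", fwd_j$seq, "jxnR", revcomp(rev_site$seq),
                           max_product_len = max_product_len),
    reference = primer_pair("refF", fwd_ref$seq, "refR",
                            revcomp(rev_ref_site$seq),
                            max_product_len = max_product_len)
  )
  if (!is.null(intro$inversion_in_line)) {
    bp <- intro$inversion_in_line[1]
    # the inverted repeat cassette sits immediately left of the breakpoint
    # and is absent from the reference; start the forward scan left of it
    fwd_b <- design_primer(line, bp - cassette_len - 30, side = "left",
                           present_in = list(ref))
    rev_b_site <- design_primer(line, bp + 30, side = "right",
                                present_in = list(ref))
    if (!is.null(fwd_b) && !is.null(rev_b_site)) {
      out$inversion_flank <- primer_pair(
        "bpF", fwd_b$seq, "bpR", revcomp(rev_b_site$seq),
        max_product_len = max_product_len)
    }
  }
  out
}

#' Check a PCR panel against the expected diagnostic pattern
#'
#' Expected: the junction pair amplifies only from the introgression line
#' (reference and wild: no standard product); the reference pair amplifies
#' from the reference but not the introgression line; an `inversion_flank`
#' pair, when present, amplifies from the introgression line but gives no
#' standard product from the reference.
#'
#' @param panel A `pcr_panel` data frame with templates `reference`,
#'   `wild`, `introgression`.
#' @return Logical.
#' @export
panel_matches_expectation <- function(panel) {
  g <- function(tmpl, pair) panel[[pair]][panel$template == tmpl]
  ok <- g("introgression", "junction") == "product" &&
    g("reference", "junction") %in% c("none", "over_max_len") &&
    g("wild", "junction") %in% c("none", "over_max_len") &&
    g("reference", "reference") == "product" &&
    g("introgression", "reference") %in% c("none", "over_max_len")
  if ("inversion_flank" %in% names(panel)) {
    ok <- ok && g("introgression", "inversion_flank") == "product" &&
      g("reference", "inversion_flank") %in% c("none", "over_max_len")
  }
  ok
}
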