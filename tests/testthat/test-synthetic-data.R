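# Synthetic genome pair, fragmentation, introgression and cross generators.

test_that("reference generation is deterministic and honours GC content", {
  a <- generate_reference(10000, gc = 0.36, seed = 7)
  b <- generate_reference(10000, gc = 0.36, seed = 7)
  expect_identical(a$seq, b$seq)
  expect_false(identical(a$seq,
                         generate_reference(10000, gc = 0.36, seed = 8)$seq))

  tiny <- generate_reference(10, gc = 0.5, seed = 1)
  expect_equal(seq_len_bp(tiny), 10)
  expect_true(grepl("^[ACGT]+$", tiny$seq))

  big <- generate_reference(100000, gc = 0.36, seed = 7)
  gc <- mean(strsplit(big$seq, "")[[1]] %in% c("G", "C"))
  expect_gt(gc, 0.34)
  expect_lt(gc, 0.38)

  expect_error(generate_reference(0, 0.36), "positive")
  expect_error(generate_reference(100, 1.2), "gc")
})

test_that("derive_wild_genome: identity, pure inversion and round trip", {
  ref <- generate_reference(50000, seed = 3)
  none <- inversion_spec(1, 0, 0)
  w0 <- derive_wild_genome(ref, none, snp_rate = 0, indel_rate = 0, seed = 5)
  expect_identical(w0$wild$seq, ref$seq)

  inv <- inversion_spec(20001, 35000, cassette_len = 0)
  w1 <- derive_wild_genome(ref, inv, snp_rate = 0, indel_rate = 0, seed = 5)
  expect_identical(subseq_bp(w1$wild, 20001, 35000),
                   revcomp(subseq_bp(ref, 20001, 35000)))
  expect_identical(subseq_bp(w1$wild, 1, 20000), subseq_bp(ref, 1, 20000))
  expect_identical(subseq_bp(w1$wild, 35001, 50000),
                   subseq_bp(ref, 35001, 50000))
  # re-inverting the inverted span reproduces the reference exactly
  fixed <- paste0(subseq_bp(w1$wild, 1, 20000),
                  revcomp(subseq_bp(w1$wild, 20001, 35000)),
                  subseq_bp(w1$wild, 35001, 50000))
  expect_identical(fixed, ref$seq)

  expect_error(derive_wild_genome(ref, inv, snp_rate = 0.5), "0.2")
  expect_error(derive_wild_genome(ref, inversion_spec(40000, 60000, 0)),
               "bounds")
})

test_that("SNP divergence of collinear flanks matches the requested rate", {
  ref <- generate_reference(100000, seed = 11)
  inv <- inversion_spec(30001, 50000, cassette_len = 0)
  w <- derive_wild_genome(ref, inv, snp_rate = 0.02, indel_rate = 0,
                          seed = 12)
  rv <- strsplit(ref$seq, "")[[1]]
  wv <- strsplit(w$wild$seq, "")[[1]]
  flank <- c(1:30000, 50001:100000)
  ident <- mean(rv[flank] == wv[flank])
  expect_gt(ident, 0.975)
  expect_lt(ident, 0.985)
})

test_that("wild genome truth ledger records realized coordinates", {
  pr <- make_pair(ref_len = 100000, inv = c(30001, 60000),
                  cassette_len = 1000, seed = 21)
  tr <- pr$truth
  iw <- tr$inv_wild
  # inverted segment on the wild genome is the (mutated) reverse complement
  # of the reference interval: compare a mutation-light window via mismatch
  # fraction rather than exact identity
  wseg <- subseq_bp(pr$wild, iw[1], iw[2])
  rseg <- revcomp(subseq_bp(pr$ref, tr$breakpoints_ref[["left"]],
                            tr$breakpoints_ref[["right"]]))
  # indels shift interior alignment; check the first 500 bp only, which the
  # generator keeps indel-free around breakpoints
  expect_lt(mean(strsplit(substr(wseg, 1, 500), "")[[1]] !=
                   strsplit(substr(rseg, 1, 500), "")[[1]]), 0.06)
  # coordinate map takes flank positions onto equal-or-SNP bases
  pos <- c(1000, 15000, 95000)
  mp <- map_ref_to_wild(tr, pos)
  for (i in seq_along(pos)) {
    if (!pos[i] %in% tr$snp_pos) {
      expect_identical(subseq_bp(pr$wild, mp[i], mp[i]),
                       subseq_bp(pr$ref, pos[i], pos[i]))
    }
  }
})

test_that("fragmentation conserves length and records truth", {
  ref <- generate_reference(60000, seed = 9)
  w <- derive_wild_genome(ref, inversion_spec(1, 0, 0), snp_rate = 0,
                          indel_rate = 0, seed = 2)$wild

  one <- fragment_scaffolds(w, 40000, 606, seed = 4)
  lens <- sort(vapply(one$scaffolds, seq_len_bp, numeric(1)))
  expect_equal(lens, sort(c(40000, 60000 - 40606)))

  none <- fragment_scaffolds(w, numeric(0), numeric(0), seed = 4)
  expect_length(none$scaffolds, 1)
  s <- none$scaffolds[[1]]$seq
  expect_true(identical(s, w$seq) || identical(s, revcomp(w$seq)))
  expect_identical(none$truth$flipped, !identical(s, w$seq))

  three <- fragment_scaffolds(w, c(20000, 40000), c(606, 4300), seed = 8)
  expect_equal(sum(vapply(three$scaffolds, seq_len_bp, numeric(1))) +
                 606 + 4300, seq_len_bp(w))
  # reconstruction from the truth ledger reproduces the input
  tr <- three$truth
  by_id <- setNames(three$scaffolds,
                    vapply(three$scaffolds, `[[`, "", "id"))
  parts <- vapply(seq_len(nrow(tr)), function(i) {
    s <- by_id[[tr$scaffold_id[i]]]$seq
    if (tr$flipped[i]) revcomp(s) else s
  }, "")
  gaps <- c(vapply(tr$gap_after[-nrow(tr)],
                   function(g) subseq_bp(w, 1, g), ""), "")
  # splice the deleted gap sequence back in at the true coordinates
  rebuilt <- paste0(parts[1], subseq_bp(w, tr$src_end[1] + 1,
                                        tr$src_start[2] - 1),
                    parts[2], subseq_bp(w, tr$src_end[2] + 1,
                                        tr$src_start[3] - 1), parts[3])
  expect_identical(rebuilt, w$seq)

  expect_error(fragment_scaffolds(w, c(20000, 20300), c(606, 4300)),
               "overlap")
  expect_error(fragment_scaffolds(w, c(30000, 20000), c(1, 1)), "increase")
})

test_that("introgression line substitutes exactly the homologous segment", {
  pr <- make_pair(ref_len = 100000, inv = c(30001, 60000),
                  cassette_len = 1000, seed = 31)
  L <- seq_len_bp(pr$ref)

  whole <- make_introgression_line(pr$ref, pr$wild, pr$truth, c(1, L))
  expect_identical(whole$record$seq, pr$wild$seq)

  nothing <- make_introgression_line(pr$ref, pr$wild, pr$truth,
                                     c(5000, 4999))
  expect_identical(nothing$record$seq, pr$ref$seq)

  seg <- c(20000, 70000)
  il <- make_introgression_line(pr$ref, pr$wild, pr$truth, seg)
  expect_identical(subseq_bp(il$record, 1, seg[1] - 1),
                   subseq_bp(pr$ref, 1, seg[1] - 1))
  jr <- il$junctions[["right"]]
  expect_identical(subseq_bp(il$record, jr + 1, seq_len_bp(il$record)),
                   subseq_bp(pr$ref, seg[2] + 1, L))
  # wild-derived interior differs from the reference (divergence + inversion)
  expect_false(identical(subseq_bp(il$record, seg[1], jr),
                         subseq_bp(pr$ref, seg[1], seg[2])))

  expect_error(
    make_introgression_line(pr$ref, pr$wild, pr$truth, c(20000, 45000)),
    "whole inversion")
})

test_that("cross simulation reproduces Haldane expectations", {
  # outermost-marker recombinant fraction ~ (1 - exp(-2 * 0.30)) / 2
  cfg <- cross_config(100, 2, marker_positions_cM = seq(0, 30, 6),
                      seed = 17)
  r_exp <- (1 - exp(-0.6)) / 2
  fracs <- vapply(1:10, function(s) {
    cfg$seed <- 17 + s
    sim <- simulate_cross(cfg)
    xo <- sim$truth$F2$crossovers
    mean(rowSums(xo) %% 2 == 1)
  }, numeric(1))
  # 10 x 200 gametes: binomial 3 s.d. on the pooled mean
  tol <- 3 * sqrt(r_exp * (1 - r_exp) / (10 * 200))
  expect_lt(abs(mean(fracs) - r_exp), tol)

  expect_identical(simulate_cross(cfg)$table$calls,
                   simulate_cross(cfg)$table$calls)
  expect_error(cross_config(10, 2, numeric(0)), "nonempty")
  expect_error(cross_config(0, 2, c(0, 10)), "n_individuals")
})

test_that("heterozygous inversions suppress recombination absolutely", {
  for (s in 1:5) {
    cfg <- cross_config(150, 4, marker_positions_cM = c(0, 5, 10, 15, 20, 25),
                        suppression_intervals = rbind(c(8, 17)), seed = s)
    sim <- simulate_cross(cfg, inversion_het = TRUE)
    for (gen in sim$truth) {
      expect_identical(gen$allele_switches_in_suppressed, 0L)
    }
    rf <- recombination_fraction(sim$table, "M3", "M4")
    expect_identical(rf$n_recombinant_individuals, 0L)
  }
  # the same config without inversion heterozygosity does recombine
  cfg <- cross_config(287, 2, marker_positions_cM = c(0, 4.5),
                      suppression_intervals = NULL, seed = 99)
  sim <- simulate_cross(cfg, inversion_het = FALSE)
  rf <- recombination_fraction(sim$table, "M1", "M2")
  # P(no recombinant in 574 gametes at 4.5 cM) < 1e-10
  expect_gt(rf$n_recombinant_individuals, 0)
})

test_that("dominant markers are scored AH and never B", {
  cfg <- cross_config(200, 2, marker_positions_cM = c(0, 10, 20),
                      dominance_mask = c(FALSE, TRUE, FALSE), seed = 5)
  sim <- simulate_cross(cfg)
  dom <- sim$table$calls[, 2]
  expect_true(all(dom %in% c("AH", "B")))
  expect_true(any(dom == "AH"))
  codom <- sim$table$calls[, c(1, 3)]
  expect_true(all(codom %in% c("A", "H", "B")))
})
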