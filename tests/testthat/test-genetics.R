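# Minimum-crossover parsimony, order ranking, recombination fractions and
# suppression detection.

test_that("the six-marker worked example needs 3 crossovers in reference
           order and 1 with the central pair swapped", {
  v <- c("A", "H", "A", "H", "H", "H")
  expect_equal(min_crossovers(v), 3)
  swapped <- c(1, 3, 2, 4, 5, 6)
  # swapping the two inversion markers makes the vector [A,A,H,H,H,H]
  expect_equal(v[swapped], c("A", "A", "H", "H", "H", "H"))
  expect_equal(min_crossovers(v[swapped]), 1)
  expect_equal(min_crossovers(v, order = swapped), 1)

  tab <- genotype_table("r1", data.frame(name = sprintf("m%d", 1:6)),
                        matrix(v, 1))
  expect_equal(order_parsimony(tab)$total_crossovers, 3)
  expect_equal(order_parsimony(tab, swapped)$total_crossovers, 1)
})

test_that("minimum crossover counts on hand-checked vectors", {
  expect_equal(min_crossovers(c("A", "B")), 2)
  expect_equal(min_crossovers(c("A", "-", "B")), 2)
  expect_equal(min_crossovers(c("A", "AH", "B")), 2)
  expect_equal(min_crossovers(rep("H", 6)), 0)
  expect_equal(min_crossovers(c("A", "H")), 1)
  expect_equal(min_crossovers("B"), 0)
  expect_error(min_crossovers(c("A", "X")), "unknown")
})

test_that("DP equals the exhaustive phase enumeration on random vectors", {
  set.seed(12)
  codes <- c("A", "H", "B", "AH", "-")
  for (i in 1:120) {
    m <- sample(2:6, 1)
    v <- sample(codes, m, replace = TRUE)
    expect_equal(min_crossovers(v), brute_force_min_crossovers(v),
                 info = paste(v, collapse = ","))
  }
})

test_that("adding markers never decreases the minimum, and AH relaxes A/H", {
  set.seed(13)
  codes <- c("A", "H", "B", "AH", "-")
  for (i in 1:40) {
    v <- sample(codes, 5, replace = TRUE)
    expect_lte(min_crossovers(v[1:4]), min_crossovers(v))
    j <- sample(5, 1)
    for (repl in c("A", "H")) {
      w <- v; w[j] <- repl
      if (v[j] == "AH") expect_lte(min_crossovers(v), min_crossovers(w))
    }
  }
})

test_that("order totals are symmetric under full order reversal", {
  set.seed(14)
  calls <- matrix(sample(c("A", "H", "B", "AH", "-"), 60, TRUE), nrow = 10)
  tab <- genotype_table(sprintf("i%d", 1:10),
                        data.frame(name = sprintf("m%d", 1:6)), calls)
  for (i in 1:5) {
    ord <- sample(6)
    expect_equal(order_parsimony(tab, ord)$total_crossovers,
                 order_parsimony(tab, rev(ord))$total_crossovers)
  }
  empty <- genotype_table(character(0),
                          data.frame(name = sprintf("m%d", 1:6)),
                          matrix(character(0), 0, 6))
  expect_equal(order_parsimony(empty)$total_crossovers, 0)
})

test_that("best_order finds the segment reversal explaining the worked
           example, with deterministic tie-breaking", {
  tab <- genotype_table("r1", data.frame(name = sprintf("m%d", 1:6)),
                        matrix(c("A", "H", "A", "H", "H", "H"), 1))
  rk <- best_order(tab)
  expect_equal(rk$best$label, "rev_2_3")
  expect_equal(rk$best$total_crossovers, 1)
  expect_equal(rk$reference_total, 3)
  expect_equal(rk$margin, 2)
  # exhaustive search over all 720 orders cannot do better
  rk_ex <- best_order(tab, exhaustive = TRUE)
  expect_equal(rk_ex$best$total_crossovers, 1)

  flat <- genotype_table(c("i1", "i2"),
                         data.frame(name = sprintf("m%d", 1:4)),
                         matrix(c("A", "A", "A", "A",
                                  "H", "H", "H", "H"), 2, byrow = TRUE))
  rk0 <- best_order(flat)
  expect_equal(rk0$best$label, "reference")
  expect_equal(rk0$margin, 0)
})

test_that("simulated intraspecific F2s recover the truly inverted marker
           order", {
  wins <- 0L
  for (s in 1:10) {
    cfg <- cross_config(100, 2, marker_positions_cM = seq(0, 30, 6),
                        seed = 300 + s)
    sim <- simulate_cross(cfg, inversion_het = FALSE)
    true_order <- c(1, 2, 4, 3, 5, 6)  # reference view of the wild map
    obs <- genotype_table(sim$table$individuals, sim$table$markers,
                          sim$table$calls[, true_order])
    rk <- best_order(obs)
    if (rk$best$label == "rev_3_4") wins <- wins + 1L
    # whenever the winner beats the reference, some individual needed
    # fewer crossovers under the reversed order
    if (rk$margin > 0) {
      expect_lt(rk$best$total_crossovers, rk$reference_total)
    }
  }
  expect_gte(wins, 9)
})

test_that("recombination fractions, counts and Haldane distances", {
  mk <- data.frame(name = c("L", "R"))
  all_a <- genotype_table(sprintf("i%d", 1:10), mk,
                          matrix("A", 10, 2))
  rf <- recombination_fraction(all_a, "L", "R")
  expect_equal(rf$n_recombinant_individuals, 0)
  expect_equal(rf$r_per_gamete, 0)
  expect_equal(rf$cM_haldane, 0)

  calls <- matrix("A", 91, 2)
  calls[1, 2] <- "H"
  one <- genotype_table(sprintf("i%d", 1:91), mk, calls)
  rf1 <- recombination_fraction(one, "L", "R")
  expect_equal(rf1$n_recombinant_individuals, 1)
  expect_equal(rf1$r_per_gamete, 1 / 182)

  calls[2, 1] <- "-"
  miss <- genotype_table(sprintf("i%d", 1:91), mk, calls)
  expect_equal(recombination_fraction(miss, "L", "R")$n_informative, 90)
  expect_error(recombination_fraction(one, "L", "nope"), "unknown marker")
})

test_that("the per-gamete estimator is calibrated at short map distances", {
  ests <- vapply(1:120, function(s) {
    cfg <- cross_config(287, 2, marker_positions_cM = c(0, 4.5),
                        seed = 1000 + s)
    sim <- simulate_cross(cfg)
    recombination_fraction(sim$table, "M1", "M2")$cM_haldane
  }, numeric(1))
  expect_lt(abs(mean(ests) - 4.5), 1)
})

test_that("suppression is flagged only when zero recombinants are
           improbable", {
  mk <- data.frame(name = c("L", "R"))
  none <- genotype_table(sprintf("i%d", 1:88), mk, matrix("A", 88, 2))
  flagged <- detect_suppression(
    none, data.frame(markerA = "L", markerB = "R", physical_bp = 162000,
                     expected_cM = 4.5))
  expect_true(flagged$suppressed)
  expect_lt(flagged$p_zero, 0.05)

  small <- genotype_table(sprintf("i%d", 1:10), mk, matrix("A", 10, 2))
  tiny <- detect_suppression(
    small, data.frame(markerA = "L", markerB = "R", physical_bp = 1000),
    genomewide_cM_per_Mbp = 2)
  expect_false(tiny$suppressed)

  calls <- matrix("A", 88, 2); calls[1:3, 2] <- "H"
  some <- genotype_table(sprintf("i%d", 1:88), mk, calls)
  rec <- detect_suppression(
    some, data.frame(markerA = "L", markerB = "R", physical_bp = 162000,
                     expected_cM = 4.5))
  expect_false(rec$suppressed)
  expect_equal(rec$n_recombinant, 3)
})
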