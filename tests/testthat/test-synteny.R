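# Anchoring, chaining, inversion calling, coordinates and dot-plot export.

test_that("self- and reverse-complement comparisons give one full anchor", {
  s <- repeat_free_dna(500, k = 11, seed = 3)
  a <- find_anchors(s, s, k = 11)
  expect_equal(nrow(a), 1)
  expect_equal(a$q_start, 1)
  expect_equal(a$q_end, 500)
  expect_equal(a$strand, "+")
  expect_equal(a$length, a$t_end - a$t_start + 1)

  b <- find_anchors(revcomp(s), s, k = 11)
  expect_equal(nrow(b), 1)
  expect_equal(b$strand, "-")
  expect_equal(b$length, 500)

  # k longer than the sequence: empty set, not an error
  expect_equal(nrow(find_anchors("ACGTACGTACGT", s, k = 20)), 0)
})

test_that("toy inverted-segment pair yields +/-/+ anchors matching the
           brute-force oracle", {
  toy <- toy_triple(k = 11, seed = 42)
  a <- find_anchors(toy$query, toy$target, k = 11)
  expect_setequal(a$strand, c("+", "-"))
  # the minus anchor covers the Y segment on both sequences (within k-1)
  neg <- a[a$strand == "-", ]
  expect_equal(nrow(neg), 1)
  expect_lt(abs(neg$t_start - 201), 11)
  expect_lt(abs(neg$t_end - 400), 11)

  bf <- brute_force_anchors(toy$query, toy$target, k = 11)
  expect_equal(anchors_as_plain(a), anchors_as_plain(bf))
})

test_that("anchors equal the brute-force scan on random divergent pairs", {
  set.seed(5)
  for (rep in 1:3) {
    t_seq <- paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = "")
    q_chars <- strsplit(t_seq, "")[[1]]
    mut <- sample(800, 16)
    q_chars[mut] <- sample(c("A", "C", "G", "T"), 16, TRUE)
    q_seq <- paste(q_chars, collapse = "")
    a <- find_anchors(q_seq, t_seq, k = 12)
    bf <- brute_force_anchors(q_seq, t_seq, k = 12)
    expect_equal(anchors_as_plain(a), anchors_as_plain(bf))
  }
})

test_that("strand antisymmetry: reverse-complementing the query flips
           strands and mirrors query coordinates", {
  toy <- toy_triple(k = 11, seed = 7)
  a <- find_anchors(toy$query, toy$target, k = 11)
  b <- find_anchors(revcomp(toy$query), toy$target, k = 11)
  qlen <- nchar(toy$query)
  mirrored <- data.frame(
    q_start = qlen - a$q_end + 1, q_end = qlen - a$q_start + 1,
    t_start = a$t_start, t_end = a$t_end,
    strand = ifelse(a$strand == "+", "-", "+"), length = a$length
  )
  expect_equal(anchors_as_plain(b), anchors_as_plain(mirrored))
})

test_that("N-containing k-mers are skipped", {
  s <- repeat_free_dna(300, k = 11, seed = 13)
  sN <- paste0(substr(s, 1, 150), strrep("N", 20), substr(s, 171, 300))
  a <- find_anchors(sN, s, k = 11)
  expect_true(all(a$q_end < 151 | a$q_start > 170))
})

test_that("chaining groups anchors into oriented collinear blocks", {
  toy <- toy_triple(k = 11, seed = 42)
  a <- find_anchors(toy$query, toy$target, k = 11)
  b <- chain_anchors(a, max_gap = 50, min_block_anchors = 1)
  expect_equal(b$strand, c("+", "-", "+"))
  expect_true(all(diff(b$t_start) > 0))

  empty <- find_anchors("ACGTACGTACGTACG", repeat_free_dna(100, seed = 2),
                        k = 15)
  expect_equal(nrow(chain_anchors(empty)), 0)

  # single-diagonal anchors chain into one block with summed coverage
  s <- repeat_free_dna(400, k = 11, seed = 23)
  broken <- paste0(substr(s, 1, 180), "NNNNN", substr(s, 186, 400))
  a2 <- find_anchors(broken, s, k = 11)
  b2 <- chain_anchors(a2, min_block_anchors = 1)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$coverage_bp, sum(a2$length))
  expect_equal(b2$n_anchors, nrow(a2))
})

test_that("inversion calling reports minus runs with breakpoint intervals", {
  toy <- toy_triple(k = 11, seed = 42)
  a <- find_anchors(toy$query, toy$target, k = 11)
  b <- chain_anchors(a, max_gap = 50, min_block_anchors = 1)
  calls <- call_inversions(b, min_size = 50)
  expect_equal(nrow(calls), 1)
  expect_lt(abs(calls$size_t - 200), 11)
  expect_lt(abs(calls$t_start - 201), 11)
  expect_lt(abs(calls$t_end - 400), 11)
  # breakpoint intervals flank the inverted core and exclude it
  expect_lte(calls$left_bp_end, calls$t_start - 1)
  expect_gte(calls$right_bp_start, calls$t_end + 1)

  # all-plus input: no calls
  s <- repeat_free_dna(400, k = 11, seed = 31)
  bp <- chain_anchors(find_anchors(s, s, k = 11), min_block_anchors = 1)
  expect_equal(nrow(call_inversions(bp, min_size = 10)), 0)
})

test_that("inversion boundaries are recovered on a divergent genome pair", {
  pr <- make_pair(ref_len = 200000, inv = c(60001, 140000),
                  cassette_len = 2000, seed = 51)
  a <- find_anchors(pr$wild, pr$ref, k = 21)
  b <- chain_anchors(a)
  calls <- call_inversions(b, min_size = 10000)
  expect_equal(nrow(calls), 1)
  tol <- 2000 + 21
  expect_lte(abs(calls$t_start - 60001), tol)
  expect_lte(abs(calls$t_end - 140000), tol)
})

test_that("perfect inverted repeat cassettes are masked, leaving
           breakpoint intervals anchor-free", {
  pr <- make_pair(ref_len = 120000, inv = c(40001, 90000),
                  cassette_len = 1500, cassette_identity = 1,
                  snp_rate = 0, indel_rate = 0, seed = 61)
  cas <- pr$truth$cassette_wild
  k <- 21
  a <- find_anchors(pr$wild, pr$ref, k = k)
  # maximal anchors may extend chance-homologous bases up to k-1 into a
  # cassette edge; the interior must carry no anchor
  for (row in 1:2) {
    interior <- c(cas[row, 1] + k - 1, cas[row, 2] - k + 1)
    inside <- a$q_start <= interior[2] & a$q_end >= interior[1]
    expect_false(any(inside))
  }
})

test_that("marker distances and build liftover reproduce coordinate
           arithmetic", {
  mt <- data.frame(
    name = c("UP8", "M1", "W1", "W2"),
    genome = c("refA", "refA", "wild", "wild"),
    pos_bp = c(51344943, 51646517, 100000, 126000)
  )
  expect_equal(marker_distance(mt, "UP8", "M1", "refA"), 301574)
  expect_equal(marker_distance(mt, "UP8", "UP8", "refA"), 0)
  expect_equal(marker_distance(mt, "W1", "W2", "wild"), 26000)
  expect_error(marker_distance(mt, "UP8", "M1", "wild"), "no coordinate")

  expect_equal(liftover_position(51646517, 51646517, 54563017), 54563017)
  expect_equal(liftover_position(51344943, 51646517, 54563017), 54261443)
  lifted <- liftover_position(c(51344943, 51646517), 51646517, 54563017)
  expect_equal(diff(lifted), 301574)
})

test_that("dot-plot export round-trips and separates strands", {
  toy <- toy_triple(k = 11, seed = 42)
  a <- find_anchors(toy$query, toy$target, k = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_dotplot(a, path)
  back <- read_dotplot(path)
  expect_equal(back, as.data.frame(a)[, names(back)])
  expect_setequal(unique(back$strand), c("+", "-"))

  empty <- chain_anchors(find_anchors("ACGTACGTACGTACG",
                                      repeat_free_dna(100, seed = 2),
                                      k = 15))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  export_dotplot(structure(data.frame(q_start = integer(0),
                                      q_end = integer(0),
                                      t_start = integer(0),
                                      t_end = integer(0),
                                      strand = character(0)),
                           class = c("anchor_set", "data.frame")), path2)
  expect_equal(readLines(path2), "q_start\tq_end\tt_start\tt_end\tstrand")
})
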