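# Fixture builders and independent oracles, all generated in code.

# DNA with no duplicate canonical k-mer (so unique-anchor logic sees a
# repeat-free sequence); retries until clean.
repeat_free_dna <- function(n, k = 11, seed = 1) {
  set.seed(seed)
  canon <- function(s) {
    km <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
    rc <- vapply(km, invscan::revcomp, "", USE.NAMES = FALSE)
    pmin(km, rc)
  }
  for (i in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    if (!anyDuplicated(canon(s))) return(s)
  }
  stop("could not build repeat-free fixture")
}

# X / revcomp(Y) / Z toy: target = XYZ, query = X rc(Y) Z, each 200 bp,
# jointly repeat-free at the given k
toy_triple <- function(k = 11, seed = 42) {
  set.seed(seed)
  canon <- function(s) {
    km <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
    rc <- vapply(km, invscan::revcomp, "", USE.NAMES = FALSE)
    pmin(km, rc)
  }
  for (i in 1:200) {
    X <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    Y <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    Z <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    target <- paste0(X, Y, Z)
    query <- paste0(X, invscan::revcomp(Y), Z)
    if (!anyDuplicated(canon(target)) && !anyDuplicated(canon(query))) {
      return(list(X = X, Y = Y, Z = Z, target = target, query = query))
    }
  }
  stop("could not build toy triple")
}

# Independent anchor oracle: all-pairs k-mer scan on strings, with the same
# canonical occurrence rule, merged by explicit seed-walking.
brute_force_anchors <- function(query, target, k, max_occurrences = 1) {
  kmers <- function(s) substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
  qk <- kmers(query); tk <- kmers(target)
  rc <- function(v) vapply(v, invscan::revcomp, "", USE.NAMES = FALSE)
  q_can <- pmin(qk, rc(qk)); t_can <- pmin(tk, rc(tk))
  q_keep <- !grepl("N", qk, fixed = TRUE) &
    table(q_can)[q_can] <= max_occurrences
  t_keep <- !grepl("N", tk, fixed = TRUE) &
    table(t_can)[t_can] <= max_occurrences
  tk_rc <- rc(tk)
  seeds <- list()
  for (i in which(q_keep)) {
    for (j in which(t_keep & tk == qk[i])) {
      seeds[[length(seeds) + 1]] <- c(i, j, 1L)
    }
    for (j in which(t_keep & tk_rc == qk[i])) {
      seeds[[length(seeds) + 1]] <- c(i, j, -1L)
    }
  }
  if (length(seeds) == 0) {
    return(data.frame(q_start = integer(0), q_end = integer(0),
                      t_start = integer(0), t_end = integer(0),
                      strand = character(0), length = integer(0)))
  }
  sd <- do.call(rbind, seeds)
  # walk in (strand, q) order so every run is entered at its first seed
  sd <- sd[order(-sd[, 3], sd[, 1]), , drop = FALSE]
  used <- rep(FALSE, nrow(sd))
  out <- list()
  for (i in seq_len(nrow(sd))) {
    if (used[i]) next
    q0 <- sd[i, 1]; t0 <- sd[i, 2]; st <- sd[i, 3]
    len <- 1L
    repeat {
      nxt <- which(!used & sd[, 1] == q0 + len & sd[, 2] == t0 + st * len &
                     sd[, 3] == st)
      if (length(nxt) == 0) break
      used[nxt] <- TRUE
      len <- len + 1L
    }
    used[i] <- TRUE
    t_lo <- if (st == 1L) t0 else t0 - (len - 1L)
    out[[length(out) + 1]] <- data.frame(
      q_start = q0, q_end = q0 + len + k - 2L,
      t_start = t_lo, t_end = t_lo + len + k - 2L,
      strand = if (st == 1L) "+" else "-", length = len + k - 1L
    )
  }
  df <- do.call(rbind, out)
  df <- df[order(df$t_start, df$q_start), ]
  rownames(df) <- NULL
  df
}

# merged-anchor starts can begin mid-run when a prefix seed was consumed by
# an earlier walk; canonicalize both sides before comparing
anchors_as_plain <- function(a) {
  df <- as.data.frame(a)[, c("q_start", "q_end", "t_start", "t_end",
                             "strand", "length")]
  df <- df[order(df$t_start, df$q_start, df$strand), ]
  rownames(df) <- NULL
  df
}

# Exhaustive minimum-crossover oracle over all 4^m phase state sequences.
.BF_STATES <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
.BF_ALLOW <- list(A = 1L, H = c(2L, 3L), B = 4L, AH = c(1L, 2L, 3L),
                  `-` = 1:4)
brute_force_min_crossovers <- function(genotypes) {
  m <- length(genotypes)
  grids <- rep(list(1:4), m)
  paths <- as.matrix(expand.grid(grids))
  ok <- rep(TRUE, nrow(paths))
  for (j in seq_len(m)) {
    ok <- ok & paths[, j] %in% .BF_ALLOW[[genotypes[j]]]
  }
  if (!any(ok)) stop("no consistent assignment")
  cost <- rep(0L, nrow(paths))
  if (m > 1) {
    for (j in seq_len(m - 1)) {
      a <- paths[, j]; b <- paths[, j + 1]
      cost <- cost + (.BF_STATES[a, 1] != .BF_STATES[b, 1]) +
        (.BF_STATES[a, 2] != .BF_STATES[b, 2])
    }
  }
  min(cost[ok])
}

# small synthetic genome pair used across test files
make_pair <- function(ref_len = 200000, inv = c(60001, 140000),
                      cassette_len = 2000, cassette_identity = 0.95,
                      snp_rate = 0.02, indel_rate = 1e-4, seed = 7) {
  ref <- generate_reference(ref_len, gc = 0.36, seed = seed)
  spec <- inversion_spec(inv[1], inv[2], cassette_len, cassette_identity)
  wd <- derive_wild_genome(ref, spec, snp_rate = snp_rate,
                           indel_rate = indel_rate, seed = seed + 1)
  list(ref = ref, wild = wd$wild, truth = wd$truth, spec = spec)
}
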