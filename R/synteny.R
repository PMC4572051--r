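# Strand-aware unique k-mer anchoring, chaining and inversion calling.
#
# The comparison engine replaces interactive alignment viewers with an
# explicit, testable pipeline: exact-match k-mer seeds between query and
# target on both strands (k-mers occurring more often than max_occurrences
# in either sequence are dropped, which automatically masks the inverted
# repeat cassettes that confound visual comparison around inversion
# breakpoints), merging of same-diagonal seeds into maximal anchors, greedy
# chaining into same-strand collinear blocks, and calling of inverted
# segments as maximal minus-strand runs flanked by plus-strand context.
#
# K-mers are encoded as base-4 integers held in doubles (k <= 25 keeps the
# code below 2^51, exact in double precision); occurrence counting uses the
# canonical (strand-collapsed) code so a k-mer and its reverse complement
# count as the same repeat.

kmer_codes <- function(v, k) {
  n <- length(v) - k + 1L
  if (n < 1L) return(list(fwd = numeric(0), rc = numeric(0)))
  vn <- as.numeric(v)
  # one-pass convolutions; all terms and sums are < 2^53, hence exact
  fwd <- as.numeric(stats::filter(vn, 4^(0:(k - 1)), sides = 1))[k:length(v)]
  rc <- as.numeric(stats::filter(3 - vn, 4^((k - 1):0), sides = 1))[k:length(v)]
  list(fwd = fwd, rc = rc)
}

#' Find strand-aware unique exact-match anchors
#'
#' All maximal runs of shared k-mers between query and target, on both
#' strands, restricted to k-mers whose canonical form occurs at most
#' `max_occurrences` times in each sequence. K-mers containing `N` are
#' skipped. Overlapping seeds on one diagonal are merged into maximal
#' anchors. A minus-strand anchor means the query segment equals the
#' reverse complement of the target segment.
#'
#' @param query,target [seq_record()] objects (or plain strings).
#' @param k K-mer size (>= 8, <= 25).
#' @param max_occurrences Maximum canonical k-mer count per sequence.
#' @return A data frame of class `anchor_set` with columns `q_start`,
#'   `q_end`, `t_start`, `t_end` (1-based closed), `strand` (`+`/`-`),
#'   `length`; attributes `k`, `query_id`, `target_id`, `query_len`,
#'   `target_len`.
#' @export
find_anchors <- function(query, target, k = 21, max_occurrences = 1) {
  if (k < 8 || k > 25) stop("k must be in [8, 25]")
  qs <- if (inherits(query, "seq_record")) query$seq else query
  ts <- if (inherits(target, "seq_record")) target$seq else target
  if (!nzchar(qs) || !nzchar(ts)) stop("sequences must be nonempty")
  qid <- if (inherits(query, "seq_record")) query$id else "query"
  tid <- if (inherits(target, "seq_record")) target$id else "target"

  empty <- data.frame(q_start = integer(0), q_end = integer(0),
                      t_start = integer(0), t_end = integer(0),
                      strand = character(0), length = integer(0))
  finish <- function(df) {
    structure(df, class = c("anchor_set", "data.frame"), k = k,
              query_id = qid, target_id = tid,
              query_len = nchar(qs), target_len = nchar(ts))
  }
  if (nchar(qs) < k || nchar(ts) < k) return(finish(empty))

  qv <- dna_to_int(qs); tv <- dna_to_int(ts)
  qc <- kmer_codes(qv, k); tc <- kmer_codes(tv, k)
  q_ok <- !is.na(qc$fwd); t_ok <- !is.na(tc$fwd)
  q_can <- pmin(qc$fwd, qc$rc); t_can <- pmin(tc$fwd, tc$rc)

  # canonical occurrence filter per sequence
  keep_unique <- function(can, ok) {
    ok2 <- ok
    if (max_occurrences <= 1) {
      x <- can[ok]
      ok2[ok] <- !(duplicated(x) | duplicated(x, fromLast = TRUE))
    } else {
      x <- can[ok]
      u <- unique(x)
      mm <- match(x, u)
      ok2[ok] <- tabulate(mm)[mm] <= max_occurrences
    }
    ok2
  }
  q_ok <- keep_unique(q_can, q_ok)
  t_ok <- keep_unique(t_can, t_ok)

  qpos <- which(q_ok); tpos <- which(t_ok)
  if (length(qpos) == 0 || length(tpos) == 0) return(finish(empty))

  # join query and target positions on canonical code
  if (max_occurrences <= 1) {
    qhit <- match(q_can[qpos], t_can[tpos])
    sel <- !is.na(qhit)
    if (!any(sel)) return(finish(empty))
    qp <- qpos[sel]
    tp <- tpos[qhit[sel]]
  } else {
    tu <- unique(t_can[tpos])
    tgrp <- match(t_can[tpos], tu)
    qhit <- match(q_can[qpos], tu)
    sel <- !is.na(qhit)
    if (!any(sel)) return(finish(empty))
    # general small join: expand multiplicity
    tl <- split(tpos, tgrp)
    qp0 <- qpos[sel]; gl <- tl[qhit[sel]]
    reps <- lengths(gl)
    qp <- rep(qp0, reps)
    tp <- unlist(gl, use.names = FALSE)
  }
  plus <- qc$fwd[qp] == tc$fwd[tp]
  # (odd k has no palindromes, so a hit is + xor -)

  # merge consecutive same-diagonal seeds into maximal anchors
  diag <- ifelse(plus, qp - tp, qp + tp)
  o <- order(!plus, diag, qp)
  qp <- qp[o]; tp <- tp[o]; plus <- plus[o]; diag <- diag[o]
  nb <- length(qp)
  new_run <- c(TRUE, plus[-1] != plus[-nb] | diag[-1] != diag[-nb] |
                 qp[-1] != qp[-nb] + 1L)
  run <- cumsum(new_run)
  first <- which(new_run)
  last <- c(first[-1] - 1L, nb)
  q_start <- qp[first]
  len <- (qp[last] - qp[first]) + k
  str_plus <- plus[first]
  t_start <- ifelse(str_plus, tp[first], tp[last])
  df <- data.frame(
    q_start = q_start, q_end = q_start + len - 1L,
    t_start = t_start, t_end = t_start + len - 1L,
    strand = ifelse(str_plus, "+", "-"), length = len
  )
  df <- df[order(df$t_start, df$q_start), ]
  rownames(df) <- NULL
  finish(df)
}

#' Chain anchors into collinear synteny blocks
#'
#' Greedy chaining in target order: within each strand, anchors sorted by
#' target start are split into chains wherever the target gap exceeds
#' `max_gap`, the diagonal drifts by more than `max_diag_drift`, or query
#' monotonicity (increasing for `+`, decreasing for `-`) is violated.
#' Chains with fewer than `min_block_anchors` anchors are discarded.
#'
#' @param anchors An `anchor_set` from [find_anchors()].
#' @param max_gap Maximum inter-anchor target gap in bp.
#' @param max_diag_drift Maximum diagonal drift in bp (absorbs indel
#'   divergence).
#' @param min_block_anchors Minimum anchors per reported block.
#' @return A data frame of class `synteny_blocks`: `block_id`, `strand`,
#'   `q_start`, `q_end`, `t_start`, `t_end`, `n_anchors`, `coverage_bp`,
#'   sorted by `t_start`. Attributes are carried over from the anchor set.
#' @export
chain_anchors <- function(anchors, max_gap = 20000, max_diag_drift = 1000,
                          min_block_anchors = 3) {
  empty <- data.frame(block_id = integer(0), strand = character(0),
                      q_start = integer(0), q_end = integer(0),
                      t_start = integer(0), t_end = integer(0),
                      n_anchors = integer(0), coverage_bp = integer(0))
  finish <- function(df) {
    structure(df, class = c("synteny_blocks", "data.frame"),
              k = attr(anchors, "k"),
              query_id = attr(anchors, "query_id"),
              target_id = attr(anchors, "target_id"),
              query_len = attr(anchors, "query_len"),
              target_len = attr(anchors, "target_len"))
  }
  if (nrow(anchors) == 0) return(finish(empty))
  a <- as.data.frame(anchors)
  a <- a[order(a$strand, a$t_start, a$q_start), ]
  n <- nrow(a)
  diag <- ifelse(a$strand == "+", a$q_start - a$t_start,
                 a$q_start + a$t_start)
  if (n > 1) {
    same <- a$strand[-1] == a$strand[-n]
    gap <- a$t_start[-1] - a$t_end[-n]
    drift <- abs(diag[-1] - diag[-n])
    mono <- ifelse(a$strand[-1] == "+",
                   a$q_start[-1] > a$q_start[-n],
                   a$q_start[-1] < a$q_start[-n])
    new_chain <- c(TRUE, !same | gap > max_gap | drift > max_diag_drift |
                     !mono)
  } else new_chain <- TRUE
  chain <- cumsum(new_chain)
  agg <- function(f, x) as.vector(tapply(x, chain, f))
  df <- data.frame(
    strand = agg(function(x) x[1], a$strand),
    q_start = agg(min, a$q_start), q_end = agg(max, a$q_end),
    t_start = agg(min, a$t_start), t_end = agg(max, a$t_end),
    n_anchors = agg(length, a$q_start),
    coverage_bp = agg(sum, a$length)
  )
  df <- df[df$n_anchors >= min_block_anchors, , drop = FALSE]
  df <- df[order(df$t_start), , drop = FALSE]
  if (nrow(df) > 0) df <- cbind(block_id = seq_len(nrow(df)), df)
  else df <- empty
  rownames(df) <- NULL
  finish(df)
}

#' Call inversions from chained synteny blocks
#'
#' An inversion is a maximal run of minus-strand blocks flanked on both
#' sides by plus-strand blocks (or a sequence end) whose target span is at
#' least `min_size`. Breakpoint intervals are the anchor-free target gaps
#' between the inverted core and its flanking plus-strand blocks; around a
#' real inversion these gaps hold the repeat cassettes whose k-mers were
#' masked as non-unique. Nested orientation structure within a minus run is
#' not separately called.
#'
#' @param blocks A `synteny_blocks` data frame sorted by `t_start`.
#' @param min_size Minimum target span in bp.
#' @return Data frame of class `inversion_calls`: `t_start`, `t_end`,
#'   `q_start`, `q_end`, `size_t`, `size_q`, `left_bp_start`,
#'   `left_bp_end`, `right_bp_start`, `right_bp_end`, `n_blocks`.
#'   Breakpoint intervals are 1-based closed and may extend to the sequence
#'   ends when no flanking block exists.
#' @export
call_inversions <- function(blocks, min_size = 10000) {
  empty <- data.frame(t_start = integer(0), t_end = integer(0),
                      q_start = integer(0), q_end = integer(0),
                      size_t = integer(0), size_q = integer(0),
                      left_bp_start = integer(0), left_bp_end = integer(0),
                      right_bp_start = integer(0), right_bp_end = integer(0),
                      n_blocks = integer(0))
  out <- structure(empty, class = c("inversion_calls", "data.frame"))
  if (nrow(blocks) == 0) return(out)
  b <- as.data.frame(blocks)
  if (is.unsorted(b$t_start)) stop("blocks must be sorted by t_start")
  tlen <- attr(blocks, "target_len")
  neg <- b$strand == "-"
  if (!any(neg)) return(out)
  r <- rle(neg)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  rows <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    run <- starts[i]:ends[i]
    t0 <- min(b$t_start[run]); t1 <- max(b$t_end[run])
    if (t1 - t0 + 1 < min_size) next
    left_end <- if (starts[i] > 1) b$t_end[starts[i] - 1L] else 0L
    right_start <- if (ends[i] < nrow(b)) b$t_start[ends[i] + 1L] else
      (if (!is.null(tlen)) tlen + 1L else t1 + 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      t_start = t0, t_end = t1,
      q_start = min(b$q_start[run]), q_end = max(b$q_end[run]),
      size_t = t1 - t0 + 1L,
      size_q = max(b$q_end[run]) - min(b$q_start[run]) + 1L,
      left_bp_start = left_end + 1L, left_bp_end = t0 - 1L,
      right_bp_start = t1 + 1L, right_bp_end = right_start - 1L,
      n_blocks = length(run)
    )
  }
  if (length(rows) == 0) return(out)
  structure(do.call(rbind, rows),
            class = c("inversion_calls", "data.frame"))
}

#' Physical distance between two markers on one genome
#'
#' @param marker_table Data frame with columns `name`, `genome`, `pos_bp`
#'   (long format: one row per marker per genome).
#' @param markerA,markerB Marker names.
#' @param genome_tag Genome/build tag to look up.
#' @return Absolute distance in bp.
#' @export
marker_distance <- function(marker_table, markerA, markerB, genome_tag) {
  lookup <- function(m) {
    row <- marker_table$name == m & marker_table$genome == genome_tag
    if (!any(row)) stop(sprintf("marker %s has no coordinate on %s",
                                m, genome_tag))
    marker_table$pos_bp[row][1]
  }
  abs(lookup(markerA) - lookup(markerB))
}

#' Lift a position between assembly builds by constant offset
#'
#' Given one locus's coordinate in both builds, every position is shifted by
#' the same offset, so interval lengths are preserved.
#'
#' @param pos Position(s) in the source build.
#' @param pair_from,pair_to The same locus's coordinate in the source and
#'   destination build.
#' @return Lifted position(s).
#' @examples
#' liftover_position(51344943, 51646517, 54563017)  # 54261443
#' @export
liftover_position <- function(pos, pair_from, pair_to) {
  pos + (pair_to - pair_from)
}

#' Export anchors as a dot-plot table
#'
#' Writes a TSV with columns `q_start`, `q_end`, `t_start`, `t_end`,
#' `strand` (1-based closed coordinates), the data behind a comparative dot
#' plot where plus- and minus-strand anchors are drawn in different colours.
#'
#' @param anchors An `anchor_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_dotplot <- function(anchors, path) {
  df <- as.data.frame(anchors)[, c("q_start", "q_end", "t_start", "t_end",
                                   "strand"), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dot-plot table written by [export_dotplot()]
#' @param path Input path.
#' @return Data frame with the dot-plot columns.
#' @export
read_dotplot <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(rep("integer", 4), "character"))
}

#' Write synteny blocks or inversion calls as BED
#'
#' BED uses 0-based half-open target coordinates (stated in a `#` header
#' line); the name field carries the strand and size.
#'
#' @param x A `synteny_blocks` or `inversion_calls` data frame.
#' @param path Output path.
#' @param chrom Chromosome/sequence name for column 1.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, chrom = "target") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED: 0-based half-open target coordinates", con)
  if (nrow(x) > 0) {
    is_inv <- inherits(x, "inversion_calls")
    name <- if (is_inv) {
      sprintf("inversion;size=%d", x$size_t)
    } else sprintf("block;strand=%s;size=%d", x$strand,
                   x$t_end - x$t_start + 1L)
    strand <- if (is_inv) rep("-", nrow(x)) else x$strand
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", chrom, x$t_start - 1L,
                       x$t_end, name, strand), con)
  }
  invisible(path)
}
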