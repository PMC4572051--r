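# Synthetic genome pairs with a known inversion.
#
# The generator emulates the comparative setting of a ~1-Mb reference region
# whose central ~200 kb is inverted in a wild relative, with the inversion
# flanked by an inverted repeat cassette pair (standing in for the NB-LRR
# genes that flank such inversions in real genomes), plus a draft-assembly
# fragmentation of the wild sequence and an introgression line carrying the
# wild segment in a reference background. Every derived object comes with a
# ground-truth ledger so downstream calls can be scored exactly.

#' Specify an inversion on the reference
#'
#' @param start,end 1-based closed interval on the reference that is
#'   reverse-complemented in the wild genome.
#' @param cassette_len Length in bp of the inverted repeat cassettes inserted
#'   at the two inversion flanks of the wild genome (0 = none).
#' @param cassette_identity Sequence identity in `[0,1]` between the two
#'   cassette copies (1 = perfect inverted repeat).
#' @return An object of class `inversion_spec`.
#' @export
inversion_spec <- function(start, end, cassette_len = 3000,
                           cassette_identity = 0.95) {
  stopifnot(start >= 1, end >= start - 1, cassette_len >= 0,
            cassette_identity >= 0, cassette_identity <= 1)
  if (end - start + 1 > 0 && end - start + 1 <= 2 * cassette_len) {
    stop("inversion must be longer than twice the cassette length")
  }
  structure(list(start = start, end = end, cassette_len = cassette_len,
                 cassette_identity = cassette_identity),
            class = "inversion_spec")
}

#' Generate a random reference region
#'
#' @param length Region length in bp (>= 1).
#' @param gc GC fraction in (0, 1).
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @param id,build_tag Record metadata.
#' @param origin_offset Coordinate of base 1 in the parent (chromosome)
#'   coordinate system.
#' @return A [seq_record()].
#' @export
generate_reference <- function(length, gc = 0.36, seed = 1, id = "ref_region",
                               build_tag = "refA", origin_offset = 0) {
  if (length < 1) stop("length must be positive")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  withr_seed(seed)
  seq_record(id, random_dna(length, gc), origin_offset = origin_offset,
             build_tag = build_tag)
}

# set.seed wrapper kept in one place so every generator uses the same RNG kind
withr_seed <- function(seed) {
  set.seed(as.integer(seed %% (2^31 - 1)), kind = "Mersenne-Twister",
           sample.kind = "Rejection")
}

#' Derive a wild genome from a reference
#'
#' Applies, in order: substitutions at `snp_rate`, short indels at
#' `indel_rate` (sizes 1..`indel_max`, insertions and deletions equally
#' likely), reverse complementation of the inversion interval, insertion of
#' an inverted cassette pair at the two inversion flanks, and `n_gap_runs`
#' runs of `N` (assembly-gap mimics that replace bases in place). Indels are
#' kept clear of the inversion boundaries so the realized breakpoints are
#' well defined; the truth ledger records the realized coordinates after all
#' shifts.
#'
#' @param ref A [seq_record()].
#' @param inversion An [inversion_spec()] (use `inversion_spec(1, 0, 0)` for
#'   none).
#' @param snp_rate,indel_rate Per-base event rates in `[0, 0.2]`.
#' @param indel_max Maximum indel size in bp.
#' @param n_gap_runs Number of N-runs to place (outside the inversion
#'   neighbourhood).
#' @param gap_run_len Length of each N-run in bp.
#' @param seed Integer seed.
#' @param id Id for the wild record.
#' @return A list with elements `wild` (a [seq_record()]) and `truth`, the
#'   ground-truth ledger (class `genome_pair_truth`) recording SNP positions,
#'   indels, realized inversion/cassette coordinates on the wild sequence and
#'   the breakpoint positions on both genomes.
#' @export
derive_wild_genome <- function(ref, inversion, snp_rate = 0.02,
                               indel_rate = 1e-04, indel_max = 6,
                               n_gap_runs = 0, gap_run_len = 200,
                               seed = 1, id = "wild_region") {
  if (snp_rate < 0 || snp_rate > 0.2 || indel_rate < 0 || indel_rate > 0.2) {
    stop("snp_rate and indel_rate must lie in [0, 0.2]")
  }
  L <- seq_len_bp(ref)
  inv_len <- inversion$end - inversion$start + 1
  has_inv <- inv_len > 0
  if (has_inv && (inversion$start < 1 || inversion$end > L)) {
    stop("inversion outside reference bounds")
  }
  withr_seed(seed)

  base <- dna_to_int(ref$seq)

  # substitutions: draw positions, force a different base at each
  n_snp <- rbinom(1, L, snp_rate)
  snp_pos <- sort(sample.int(L, n_snp))
  if (n_snp > 0) {
    shift <- sample.int(3, n_snp, replace = TRUE)
    base[snp_pos] <- (base[snp_pos] + shift) %% 4L
  }

  # indels on reference coordinates, kept >= indel_max away from the
  # inversion boundaries (and never inside an N run source: none yet)
  n_ind <- rbinom(1, L, indel_rate)
  indels <- data.frame(ref_pos = integer(0), len = integer(0),
                       type = character(0))
  if (n_ind > 0) {
    pos <- sort(sample.int(L - indel_max, n_ind))
    if (has_inv) {
      guard <- 2L * indel_max
      bad <- (abs(pos - inversion$start) <= guard) |
        (abs(pos - inversion$end) <= guard)
      pos <- pos[!bad]
    }
    pos <- pos[c(TRUE, diff(pos) > indel_max)]  # non-overlapping
    if (length(pos) > 0) {
      indels <- data.frame(
        ref_pos = pos,
        len = sample.int(indel_max, length(pos), replace = TRUE),
        type = sample(c("ins", "del"), length(pos), replace = TRUE)
      )
    }
  }

  # apply indels piecewise; ins = insert after ref_pos, del = delete
  # ref[ref_pos .. ref_pos + len - 1]
  pieces <- list()
  cur <- 1L
  if (nrow(indels) > 0) {
    for (i in seq_len(nrow(indels))) {
      p <- indels$ref_pos[i]; l <- indels$len[i]
      if (indels$type[i] == "ins") {
        pieces[[length(pieces) + 1L]] <- base[cur:p]
        pieces[[length(pieces) + 1L]] <- sample(0:3, l, replace = TRUE)
        cur <- p + 1L
      } else {
        if (p > cur) pieces[[length(pieces) + 1L]] <- base[cur:(p - 1L)]
        cur <- p + l
      }
    }
  }
  if (cur <= L) pieces[[length(pieces) + 1L]] <- base[cur:L]
  wildv <- unlist(pieces, use.names = FALSE)

  # ref -> post-indel coordinate shift
  shift_at <- function(pos) {
    if (nrow(indels) == 0) return(rep(0L, length(pos)))
    s <- ifelse(indels$type == "ins", indels$len, -indels$len)
    vapply(pos, function(p) sum(s[indels$ref_pos < p]), numeric(1))
  }

  inv_pre <- if (has_inv) {
    c(inversion$start + shift_at(inversion$start),
      inversion$end + shift_at(inversion$end))
  } else c(NA_real_, NA_real_)

  if (has_inv) {
    seg <- wildv[inv_pre[1]:inv_pre[2]]
    wildv[inv_pre[1]:inv_pre[2]] <- rev(3L - seg)  # reverse complement
  }

  # inverted cassette pair flanking the inversion (wild-only novel repeat)
  clen <- if (has_inv) inversion$cassette_len else 0L
  cassette_iv <- NULL
  if (clen > 0) {
    cass <- sample(0:3, clen, replace = TRUE)
    cass2 <- cass
    n_mut <- round((1 - inversion$cassette_identity) * clen)
    if (n_mut > 0) {
      mp <- sample.int(clen, n_mut)
      cass2[mp] <- (cass2[mp] + sample.int(3, n_mut, replace = TRUE)) %% 4L
    }
    left <- wildv[seq_len(inv_pre[1] - 1L)]
    mid <- wildv[inv_pre[1]:inv_pre[2]]
    right <- if (inv_pre[2] < length(wildv)) {
      wildv[(inv_pre[2] + 1L):length(wildv)]
    } else integer(0)
    wildv <- c(left, cass, mid, rev(3L - cass2), right)
    cassette_iv <- rbind(
      left = c(inv_pre[1], inv_pre[1] + clen - 1L),
      right = c(inv_pre[2] + clen + 1L, inv_pre[2] + 2L * clen)
    )
  }
  inv_wild <- if (has_inv) c(inv_pre[1] + clen, inv_pre[2] + clen) else
    c(NA_real_, NA_real_)

  # N runs replacing bases in place, clear of the inversion flanks
  n_runs <- data.frame(start = integer(0), end = integer(0))
  if (n_gap_runs > 0) {
    WL <- length(wildv)
    ok <- FALSE
    for (try in 1:50) {
      st <- sort(sample.int(WL - gap_run_len, n_gap_runs))
      en <- st + gap_run_len - 1L
      clear <- all(diff(st) > gap_run_len)
      if (has_inv) {
        margin <- clen + 100L
        clear <- clear && all(en < inv_wild[1] - margin | st > inv_wild[1] + margin) &&
          all(en < inv_wild[2] - margin | st > inv_wild[2] + margin)
      }
      if (clear) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place N runs clear of the inversion flanks")
    for (i in seq_len(n_gap_runs)) wildv[st[i]:en[i]] <- NA_integer_
    n_runs <- data.frame(start = st, end = en)
  }

  truth <- structure(list(
    inversion = inversion,
    snp_rate = snp_rate, indel_rate = indel_rate,
    snp_pos = snp_pos, indels = indels,
    cassette_len = clen,
    inv_pre = inv_pre,                    # post-indel, pre-cassette coords
    inv_wild = inv_wild,                  # inverted segment span on wild
    cassette_wild = cassette_iv,
    breakpoints_ref = if (has_inv) c(left = inversion$start,
                                     right = inversion$end) else NULL,
    breakpoints_wild = if (has_inv) c(left = inv_wild[1],
                                      right = inv_wild[2]) else NULL,
    n_runs = n_runs,
    ref_len = L, wild_len = length(wildv)
  ), class = "genome_pair_truth")

  list(wild = seq_record(id, int_to_dna(wildv), build_tag = "wild"),
       truth = truth)
}

#' Map a reference coordinate onto the wild genome
#'
#' Composes the indel shifts, the inversion reflection and the cassette
#' insertions recorded in a truth ledger. Positions inside the inversion map
#' to their reflected wild position.
#'
#' @param truth A `genome_pair_truth` from [derive_wild_genome()].
#' @param pos Vector of 1-based reference positions.
#' @return Numeric vector of wild positions.
#' @export
map_ref_to_wild <- function(truth, pos) {
  ind <- truth$indels
  shift <- if (nrow(ind) == 0) rep(0, length(pos)) else {
    s <- ifelse(ind$type == "ins", ind$len, -ind$len)
    vapply(pos, function(p) sum(s[ind$ref_pos < p]), numeric(1))
  }
  pre <- pos + shift
  inv <- truth$inversion
  clen <- truth$cassette_len
  has_inv <- !is.null(truth$breakpoints_ref)
  if (!has_inv) return(pre)
  out <- pre
  before <- pos < inv$start
  inside <- pos >= inv$start & pos <= inv$end
  after <- pos > inv$end
  out[inside] <- truth$inv_pre[1] + clen + (truth$inv_pre[2] - pre[inside])
  out[after] <- pre[after] + 2 * clen
  out[before] <- pre[before]
  out
}

#' Fragment a genome into draft scaffolds
#'
#' Cuts the sequence at `break_positions` (the last base of each left-hand
#' scaffold), deleting `gap_sizes` bases at each cut — emulating
#' between-scaffold sequence a draft assembly failed to capture. Output
#' scaffolds are returned in shuffled order with random strand flips, as a
#' real draft assembly gives no ordering or orientation guarantees; the
#' truth ledger records the true layout.
#'
#' @param wild A [seq_record()].
#' @param break_positions Strictly increasing 1-based positions.
#' @param gap_sizes Non-negative gap (deleted bases) at each break; same
#'   length as `break_positions`.
#' @param seed Integer seed for the shuffle/flips.
#' @param id_prefix Prefix for scaffold ids.
#' @return A list with `scaffolds` (list of [seq_record()]) and `truth`, a
#'   data frame with one row per scaffold in true left-to-right order:
#'   `scaffold_id`, `true_index`, `src_start`, `src_end` (coordinates on the
#'   input sequence), `flipped` (stored sequence is the reverse complement),
#'   and `gap_after` (true gap to the next scaffold, NA for the last).
#' @export
fragment_scaffolds <- function(wild, break_positions, gap_sizes, seed = 1,
                               id_prefix = "scaffold") {
  L <- seq_len_bp(wild)
  nb <- length(break_positions)
  stopifnot(length(gap_sizes) == nb, all(gap_sizes >= 0))
  if (nb > 0) {
    if (any(diff(break_positions) <= 0)) stop("break positions must increase")
    ends <- break_positions + gap_sizes
    if (any(break_positions < 1) || any(ends >= L)) {
      stop("breaks/gaps fall outside the sequence")
    }
    if (nb > 1 && any(ends[-nb] >= break_positions[-1])) {
      stop("breaks overlap after applying gaps")
    }
  }
  starts <- c(1, if (nb > 0) break_positions + gap_sizes + 1)
  stops <- c(break_positions, L)
  n <- nb + 1L
  withr_seed(seed)
  ord <- sample.int(n)           # position in output of true scaffold i
  flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
  ids <- sprintf("%s_%d", id_prefix, seq_len(n))
  scaffolds <- vector("list", n)
  for (i in seq_len(n)) {
    s <- subseq_bp(wild, starts[i], stops[i])
    if (flip[i]) s <- revcomp(s)
    scaffolds[[ord[i]]] <- seq_record(ids[ord[i]], s, build_tag = "draft")
  }
  truth <- data.frame(
    scaffold_id = ids[ord], true_index = seq_len(n),
    src_start = starts, src_end = stops, flipped = flip,
    gap_after = c(if (nb > 0) gap_sizes, NA_real_)
  )
  list(scaffolds = scaffolds, truth = truth)
}

#' Build an introgression line
#'
#' Substitutes the wild-genome segment homologous to a reference interval
#' into the reference background — the comparative analogue of a line
#' carrying a small wild introgression after repeated backcrossing. The
#' segment must either contain the whole inversion or not touch it.
#'
#' @param ref,wild [seq_record()] objects related by `truth`.
#' @param truth The `genome_pair_truth` for the pair.
#' @param segment_on_ref Length-2 vector, 1-based closed interval on the
#'   reference. A zero-length segment (`end < start`) returns the reference.
#' @param id Record id.
#' @return List with `record` (the introgression line), `junctions`
#'   (`left`/`right`: first and last wild-derived base in line coordinates),
#'   `segment_on_ref`, and `inversion_in_line` (realized inversion interval
#'   in line coordinates, if the segment carries it).
#' @export
make_introgression_line <- function(ref, wild, truth, segment_on_ref,
                                    id = "introgression_line") {
  s <- segment_on_ref[1]; e <- segment_on_ref[2]
  if (e < s) {
    return(list(record = seq_record(id, ref$seq, build_tag = "introgression"),
                junctions = NULL, segment_on_ref = segment_on_ref,
                inversion_in_line = NULL))
  }
  L <- seq_len_bp(ref)
  stopifnot(s >= 1, e <= L)
  has_inv <- !is.null(truth$breakpoints_ref)
  carries_inv <- FALSE
  if (has_inv) {
    inv <- truth$inversion
    overlaps <- !(e < inv$start || s > inv$end)
    carries_inv <- s < inv$start && e > inv$end
    if (overlaps && !carries_inv) {
      stop("segment must contain the whole inversion or avoid it")
    }
  }
  ws <- map_ref_to_wild(truth, s)
  we <- map_ref_to_wild(truth, e)
  wild_seg <- subseq_bp(wild, ws, we)
  left <- if (s > 1) subseq_bp(ref, 1, s - 1) else ""
  right <- if (e < L) subseq_bp(ref, e + 1, L) else ""
  rec <- seq_record(id, paste0(left, wild_seg, right),
                    build_tag = "introgression")
  shift <- (s - 1) - (ws - 1)   # wild coord -> line coord
  list(
    record = rec,
    junctions = c(left = s, right = s - 1 + nchar(wild_seg)),
    segment_on_ref = segment_on_ref,
    inversion_in_line = if (carries_inv) truth$inv_wild + shift else NULL
  )
}
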