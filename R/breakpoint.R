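# Breakpoint localization from split alignments, and in-silico PCR.
#
# A BAC-like query is chained against the reference; walking along the
# query, every adjacent block pair whose target loci disagree in strand or
# jump by more than a threshold marks a breakpoint, reported as the
# anchor-free query interval between the blocks (never a single base — the
# true switch point cannot be resolved more finely than the anchors allow).
# In-silico PCR finds primer annealing sites on both strands and reports
# every convergent forward/reverse arrangement within a product-size limit,
# which is enough to reproduce the diagnostic presence/absence logic of
# breakpoint-spanning primer pairs.

#' Locate breakpoints in a query against a target
#'
#' @param query,target [seq_record()] objects; the query is typically a
#'   BAC/contig-sized slice, the target a reference region.
#' @param k,max_occurrences,max_gap,max_diag_drift,min_block_anchors
#'   Anchoring/chaining parameters (see [find_anchors()],
#'   [chain_anchors()]).
#' @param jump_threshold Positional jump on the target (bp) that counts as
#'   a breakpoint even without a strand switch.
#' @param from_pos Query position from which `collinear_prefix_len` is
#'   measured (distance to the nearest breakpoint interval).
#' @return Data frame of class `breakpoint_calls`: `q_gap_start`,
#'   `q_gap_end` (anchor-free query interval), `left_t_start`,
#'   `left_t_end`, `left_strand`, `right_t_start`, `right_t_end`,
#'   `right_strand`, `t_jump`, `strand_switch`, `collinear_prefix_len`.
#'   Empty (with a warning) when the query has no anchors.
#' @export
locate_breakpoints <- function(query, target, k = 21, max_occurrences = 1,
                               max_gap = 20000, max_diag_drift = 1000,
                               min_block_anchors = 1,
                               jump_threshold = 20000, from_pos = 1) {
  a <- find_anchors(query, target, k = k, max_occurrences = max_occurrences)
  empty <- data.frame(q_gap_start = integer(0), q_gap_end = integer(0),
                      left_t_start = integer(0), left_t_end = integer(0),
                      left_strand = character(0),
                      right_t_start = integer(0), right_t_end = integer(0),
                      right_strand = character(0), t_jump = numeric(0),
                      strand_switch = logical(0),
                      collinear_prefix_len = numeric(0))
  if (nrow(a) == 0) {
    warning("query has no anchors against the target")
    return(structure(empty, class = c("breakpoint_calls", "data.frame")))
  }
  b <- chain_anchors(a, max_gap = max_gap, max_diag_drift = max_diag_drift,
                     min_block_anchors = min_block_anchors)
  b <- b[order(b$q_start), , drop = FALSE]
  rows <- list()
  if (nrow(b) > 1) {
    for (i in seq_len(nrow(b) - 1)) {
      L <- b[i, ]; R <- b[i + 1, ]
      switch_ <- L$strand != R$strand
      # expected continuation locus on target of the left block's end
      jump <- if (L$strand == "+") abs(R$t_start - L$t_end) else
        abs(L$t_start - R$t_end)
      if (switch_ || jump > jump_threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          q_gap_start = L$q_end + 1L, q_gap_end = R$q_start - 1L,
          left_t_start = L$t_start, left_t_end = L$t_end,
          left_strand = L$strand,
          right_t_start = R$t_start, right_t_end = R$t_end,
          right_strand = R$strand,
          t_jump = jump, strand_switch = switch_,
          collinear_prefix_len = NA_real_
        )
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else empty
  if (nrow(out) > 0) {
    mid <- (out$q_gap_start + out$q_gap_end) / 2
    out$collinear_prefix_len <- abs(mid - from_pos)
  }
  structure(out, class = c("breakpoint_calls", "data.frame"))
}

#' Define a primer pair
#'
#' @param fwd_name,fwd_seq,rev_name,rev_seq Primer names and sequences
#'   (15-35 bases over `A,C,G,T`).
#' @param max_product_len Maximum product size (bp) under standard PCR
#'   conditions; convergent sites further apart are reported as
#'   `over_max_len` (the long-range PCR regime).
#' @param max_mismatches Mismatches tolerated per annealing site; the last
#'   3 bases at the 3' end must always match exactly.
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(fwd_name, fwd_seq, rev_name, rev_seq,
                        max_product_len = 5000, max_mismatches = 0) {
  check <- function(s, nm) {
    s <- toupper(s)
    if (nchar(s) < 15 || nchar(s) > 35) {
      stop(sprintf("primer %s must be 15-35 bases", nm))
    }
    if (grepl("[^ACGT]", s)) stop(sprintf("primer %s has non-ACGT bases", nm))
    s
  }
  structure(list(fwd_name = fwd_name, fwd_seq = check(fwd_seq, fwd_name),
                 rev_name = rev_name, rev_seq = check(rev_seq, rev_name),
                 max_product_len = max_product_len,
                 max_mismatches = max_mismatches),
            class = "primer_pair")
}

# All annealing sites of one primer on a template. A "+" site means the
# primer sequence matches the template strand (primer extends rightward
# from its 3' end at site end); a "-" site means the primer matches the
# reverse strand (extends leftward from site start).
primer_sites <- function(template_seq, primer, max_mismatches = 0) {
  subject <- Biostrings::DNAString(template_seq)
  find <- function(pat) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                     max.mismatch = max_mismatches,
                                     with.indels = FALSE)
    data.frame(start = BiocGenerics::start(hits),
               end = BiocGenerics::end(hits))
  }
  plus <- find(primer)
  minus <- find(revcomp(primer))
  if (max_mismatches > 0) {
    # 3'-terminal 3 bases must match exactly
    tail3 <- substr(primer, nchar(primer) - 2, nchar(primer))
    if (nrow(plus) > 0) {
      obs <- substr(template_seq, plus$end - 2, plus$end)
      plus <- plus[obs == tail3, , drop = FALSE]
    }
    if (nrow(minus) > 0) {
      obs <- substr(template_seq, minus$start, minus$start + 2)
      minus <- minus[obs == revcomp(tail3), , drop = FALSE]
    }
  }
  list(plus = plus, minus = minus)
}

#' Predict PCR products on a template
#'
#' Finds all annealing sites of both primers on both strands and reports
#' every convergent arrangement — one primer on the plus strand upstream of
#' the other primer's minus-strand site — as a product (`product` if within
#' `max_product_len`, else `over_max_len`). Divergent or same-orientation
#' site pairs yield nothing.
#'
#' @param template A [seq_record()] (or plain string).
#' @param pair A [primer_pair()].
#' @return Data frame of class `amplicons`: `template_id`, `fwd_primer`
#'   (name of the plus-strand primer of the arrangement), `fwd_start`,
#'   `rev_primer`, `rev_end`, `product_len`, `status`. Zero rows when no
#'   convergent arrangement exists.
#' @export
insilico_pcr <- function(template, pair) {
  stopifnot(inherits(pair, "primer_pair"))
  ts <- if (inherits(template, "seq_record")) template$seq else template
  tid <- if (inherits(template, "seq_record")) template$id else "template"
  f <- primer_sites(ts, pair$fwd_seq, pair$max_mismatches)
  r <- primer_sites(ts, pair$rev_seq, pair$max_mismatches)
  combos <- list(
    list(up = f$plus, up_name = pair$fwd_name,
         dn = r$minus, dn_name = pair$rev_name),
    list(up = r$plus, up_name = pair$rev_name,
         dn = f$minus, dn_name = pair$fwd_name)
  )
  rows <- list()
  for (cb in combos) {
    if (nrow(cb$up) == 0 || nrow(cb$dn) == 0) next
    for (i in seq_len(nrow(cb$up))) {
      for (j in seq_len(nrow(cb$dn))) {
        len <- cb$dn$end[j] - cb$up$start[i] + 1L
        if (len < max(nchar(pair$fwd_seq), nchar(pair$rev_seq))) next
        if (cb$dn$start[j] <= cb$up$end[i]) next  # overlapping sites
        rows[[length(rows) + 1L]] <- data.frame(
          template_id = tid,
          fwd_primer = cb$up_name, fwd_start = cb$up$start[i],
          rev_primer = cb$dn_name, rev_end = cb$dn$end[j],
          product_len = len,
          status = if (len <= pair$max_product_len) "product" else
            "over_max_len"
        )
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(template_id = character(0), fwd_primer = character(0),
               fwd_start = integer(0), rev_primer = character(0),
               rev_end = integer(0), product_len = integer(0),
               status = character(0))
  structure(out, class = c("amplicons", "data.frame"))
}

#' Presence/absence PCR matrix over templates and primer pairs
#'
#' Runs [insilico_pcr()] for every template/pair combination and summarises
#' each to its best status: `product` if any in-size product exists, else
#' `over_max_len` if only long-range products exist, else `none`.
#'
#' @param templates Named list of [seq_record()] templates.
#' @param pairs Named list of [primer_pair()] objects.
#' @return Data frame of class `pcr_panel` with one row per template and
#'   one column per pair holding the status, plus a `template` column.
#' @export
breakpoint_pcr_panel <- function(templates, pairs) {
  if (is.null(names(templates))) {
    names(templates) <- vapply(templates, `[[`, "", "id")
  }
  if (length(pairs) > 0 && is.null(names(pairs))) {
    names(pairs) <- sprintf("pair%d", seq_along(pairs))
  }
  out <- data.frame(template = names(templates))
  for (pn in names(pairs)) {
    stat <- vapply(templates, function(tp) {
      amp <- insilico_pcr(tp, pairs[[pn]])
      if (any(amp$status == "product")) "product"
      else if (any(amp$status == "over_max_len")) "over_max_len"
      else "none"
    }, character(1))
    out[[pn]] <- unname(stat)
  }
  structure(out, class = c("pcr_panel", "data.frame"))
}

#' Design a primer anchored near a position, with specificity checks
#'
#' Scans candidate windows near `around` on `template` (alternating right
#' and left of it) for a primer whose exact sequence occurs exactly once in
#' `template`, occurs in every sequence of `present_in`, and is absent from
#' every sequence of `absent_in` (both orientations throughout) — the
#' in-silico counterpart of designing a diagnostic primer and checking its
#' specificity. Deterministic: the first window satisfying all constraints
#' wins.
#'
#' @param template [seq_record()] (or string) the primer is taken from.
#' @param around Template position the scan starts from.
#' @param side `"left"` keeps the primer 3' end at or left of `around`;
#'   `"right"` keeps its start at or right of `around`.
#' @param length Primer length.
#' @param search_bp Maximum scan distance.
#' @param present_in,absent_in Lists of [seq_record()]/strings.
#' @return List: `seq`, `start`, `end` on the template; `NULL` when no
#'   window qualifies.
#' @export
design_primer <- function(template, around, side = c("right", "left"),
                          length = 22, search_bp = 5000,
                          present_in = list(), absent_in = list()) {
  side <- match.arg(side)
  ts <- if (inherits(template, "seq_record")) template$seq else template
  occ <- function(seqstr, pat) {
    s <- Biostrings::DNAString(seqstr)
    length(Biostrings::matchPattern(pat, s)) +
      length(Biostrings::matchPattern(revcomp(pat), s))
  }
  offs <- 0:search_bp
  for (o in offs) {
    st <- if (side == "right") around + o else around - o - length + 1L
    en <- st + length - 1L
    if (st < 1 || en > nchar(ts)) next
    cand <- substr(ts, st, en)
    if (grepl("N", cand, fixed = TRUE)) next
    if (occ(ts, cand) != 1) next
    ok <- TRUE
    for (p in present_in) {
      ps <- if (inherits(p, "seq_record")) p$seq else p
      if (occ(ps, cand) < 1) { ok <- FALSE; break }
    }
    if (ok) for (p in absent_in) {
      ps <- if (inherits(p, "seq_record")) p$seq else p
      if (occ(ps, cand) > 0) { ok <- FALSE; break }
    }
    if (ok) return(list(seq = cand, start = st, end = en))
  }
  NULL
}
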