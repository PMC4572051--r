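# Reference-guided scaffold placement, gap estimation and superscaffolding.
#
# Draft scaffolds are anchored onto the reference region with the same
# unique k-mer machinery as the synteny module; each scaffold's placement is
# the hull of its chained blocks, its orientation is decided by majority
# anchor coverage (a scaffold spanning an inversion breakpoint chains in
# both orientations — the split is recorded, not hidden), inter-scaffold
# gaps are estimated by reference projection, and the ordered, oriented
# scaffolds are joined into a superscaffold with N-runs at the gaps,
# described by AGP v2.0 rows.

#' Place draft scaffolds on a reference region
#'
#' @param scaffolds List of [seq_record()] scaffolds.
#' @param target Reference [seq_record()].
#' @param k,max_occurrences Anchoring parameters (see [find_anchors()]).
#' @param max_gap,max_diag_drift,min_block_anchors Chaining parameters (see
#'   [chain_anchors()]).
#' @param noise_frac Blocks covering less than this fraction of the
#'   scaffold's best block are treated as chance matches and ignored for
#'   placement (a lone 1-anchor stray would otherwise drag the placement
#'   hull far off).
#' @return List with `placements` — a data frame sorted by `t_start` with
#'   columns `scaffold_id`, `t_start`, `t_end` (hull over all chained
#'   blocks), `orientation` (strand of the dominant chain by anchor
#'   coverage), `anchor_support`, `minority_coverage_bp` (coverage on the
#'   non-dominant strand; > 0 flags a breakpoint-spanning scaffold),
#'   `scaffold_len` — and `unplaced`, ids of scaffolds with no chained
#'   anchors.
#' @export
place_scaffolds <- function(scaffolds, target, k = 21, max_occurrences = 1,
                            max_gap = 20000, max_diag_drift = 1000,
                            min_block_anchors = 1, noise_frac = 0.01) {
  stopifnot(length(scaffolds) > 0)
  rows <- list(); unplaced <- character(0)
  for (sc in scaffolds) {
    a <- find_anchors(sc, target, k = k, max_occurrences = max_occurrences)
    b <- chain_anchors(a, max_gap = max_gap,
                       max_diag_drift = max_diag_drift,
                       min_block_anchors = min_block_anchors)
    if (nrow(b) == 0) {
      unplaced <- c(unplaced, sc$id)
      next
    }
    b <- b[b$coverage_bp >= noise_frac * max(b$coverage_bp), , drop = FALSE]
    cov <- tapply(b$coverage_bp, b$strand, sum)
    dominant <- names(cov)[which.max(cov)]
    # project the unanchored scaffold tails beyond the anchor hull onto the
    # target, so placement extents (and hence gap estimates) are not biased
    # by terminal anchors trimmed back over divergent bases
    slen <- seq_len_bp(sc)
    q_min <- min(b$q_start); q_max <- max(b$q_end)
    t_lo <- min(b$t_start); t_hi <- max(b$t_end)
    if (dominant == "+") {
      t_lo <- t_lo - (q_min - 1L)
      t_hi <- t_hi + (slen - q_max)
    } else {
      t_lo <- t_lo - (slen - q_max)
      t_hi <- t_hi + (q_min - 1L)
    }
    tlen <- attr(b, "target_len")
    rows[[length(rows) + 1L]] <- data.frame(
      scaffold_id = sc$id,
      t_start = max(1L, t_lo), t_end = min(tlen, t_hi),
      orientation = dominant,
      anchor_support = sum(b$n_anchors),
      minority_coverage_bp = sum(cov) - max(cov),
      scaffold_len = slen
    )
  }
  placements <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(scaffold_id = character(0), t_start = integer(0),
               t_end = integer(0), orientation = character(0),
               anchor_support = integer(0),
               minority_coverage_bp = integer(0),
               scaffold_len = integer(0))
  placements <- placements[order(placements$t_start), , drop = FALSE]
  rownames(placements) <- NULL
  list(placements = placements, unplaced = unplaced)
}

#' Estimate inter-scaffold gaps by reference projection
#'
#' @param placements Placement data frame sorted by `t_start`.
#' @return The data frame with added `est_gap_to_next` (bp; `NA` for the
#'   last scaffold; projected overlaps are reported as 0) and
#'   `overlap_to_next` (positive where placements overlap on the
#'   reference).
#' @export
estimate_gaps <- function(placements) {
  n <- nrow(placements)
  if (n > 1 && is.unsorted(placements$t_start)) {
    stop("placements must be sorted by t_start")
  }
  gap <- rep(NA_real_, n)
  ov <- rep(0, n)
  if (n > 1) {
    raw <- placements$t_start[-1] - placements$t_end[-n] - 1
    gap[-n] <- pmax(0, raw)
    ov[-n] <- pmax(0, -raw)
  }
  placements$est_gap_to_next <- gap
  placements$overlap_to_next <- ov
  placements
}

#' Join placed scaffolds into a superscaffold
#'
#' Concatenates the oriented scaffold sequences in placement order with
#' N-runs of the estimated gap sizes (a gap of unknown or zero size gets a
#' single N so component boundaries stay visible), and emits AGP v2.0
#' component/gap rows that tile the superscaffold exactly.
#'
#' @param placements Output of [estimate_gaps()].
#' @param scaffolds The scaffold [seq_record()] list placements refer to.
#' @param object_id Name of the superscaffold.
#' @return List of class `superscaffold`: `record` (a [seq_record()]),
#'   `placements`, and `agp` (data frame of AGP v2.0 rows).
#' @export
build_superscaffold <- function(placements, scaffolds,
                                object_id = "superscaffold") {
  if (nrow(placements) == 0) stop("no placements")
  if (!"est_gap_to_next" %in% names(placements)) {
    placements <- estimate_gaps(placements)
  }
  by_id <- stats::setNames(scaffolds,
                           vapply(scaffolds, `[[`, "", "id"))
  missing <- setdiff(placements$scaffold_id, names(by_id))
  if (length(missing) > 0) {
    stop("placement refers to unknown scaffold: ", missing[1])
  }
  pieces <- character(0)
  agp <- list()
  pos <- 0L; part <- 0L
  n <- nrow(placements)
  for (i in seq_len(n)) {
    sc <- by_id[[placements$scaffold_id[i]]]
    s <- sc$seq
    if (placements$orientation[i] == "-") s <- revcomp(s)
    part <- part + 1L
    agp[[part]] <- data.frame(
      object = object_id, object_beg = pos + 1L,
      object_end = pos + nchar(s), part_number = part,
      component_type = "W", component_id = sc$id,
      component_beg = 1L, component_end = nchar(s),
      orientation = placements$orientation[i]
    )
    pieces <- c(pieces, s)
    pos <- pos + nchar(s)
    if (i < n) {
      g <- placements$est_gap_to_next[i]
      g <- if (is.na(g) || g < 1) 1L else as.integer(g)
      part <- part + 1L
      agp[[part]] <- data.frame(
        object = object_id, object_beg = pos + 1L,
        object_end = pos + g, part_number = part,
        component_type = "N", component_id = as.character(g),
        component_beg = NA_integer_, component_end = NA_integer_,
        orientation = "scaffold"
      )
      pieces <- c(pieces, strrep("N", g))
      pos <- pos + g
    }
  }
  rec <- seq_record(object_id, paste(pieces, collapse = ""),
                    build_tag = "superscaffold")
  structure(list(record = rec, placements = placements,
                 agp = do.call(rbind, agp)),
            class = "superscaffold")
}

#' Write AGP v2.0
#'
#' @param x A `superscaffold` or an AGP data frame as built by
#'   [build_superscaffold()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(x, path) {
  agp <- if (inherits(x, "superscaffold")) x$agp else x
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version 2.0", con)
  for (i in seq_len(nrow(agp))) {
    r <- agp[i, ]
    fields <- if (r$component_type == "N") {
      c(r$object, r$object_beg, r$object_end, r$part_number, "N",
        r$component_id, "scaffold", "yes", "paired-ends")
    } else {
      c(r$object, r$object_beg, r$object_end, r$part_number, "W",
        r$component_id, r$component_beg, r$component_end, r$orientation)
    }
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read AGP v2.0 written by [write_agp()]
#'
#' @param path Input path.
#' @return AGP data frame with the columns of `build_superscaffold()$agp`.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  rows <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (f[5] == "N") {
      data.frame(object = f[1], object_beg = as.integer(f[2]),
                 object_end = as.integer(f[3]),
                 part_number = as.integer(f[4]), component_type = "N",
                 component_id = f[6], component_beg = NA_integer_,
                 component_end = NA_integer_, orientation = "scaffold")
    } else {
      data.frame(object = f[1], object_beg = as.integer(f[2]),
                 object_end = as.integer(f[3]),
                 part_number = as.integer(f[4]), component_type = f[5],
                 component_id = f[6], component_beg = as.integer(f[7]),
                 component_end = as.integer(f[8]), orientation = f[9])
    }
  })
  do.call(rbind, rows)
}
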