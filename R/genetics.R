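# Crossover-parsimony genetics on phase-unknown F2 genotype tables.
#
# Genotype codes follow CAPS-marker scoring: A (homozygous for the first
# parent), B (homozygous for the other parent), H (heterozygous), AH (a
# dominant assay that cannot distinguish A from H — never B), "-" (missing).
# The central statistic is the minimum number of meiotic crossovers needed
# to explain an individual's genotypes under a given marker order, minimized
# exactly over all phase assignments by dynamic programming over the four
# ordered haplotype-pair states (aa, ab, ba, bb).

GENO_CODES <- c("A", "H", "B", "AH", "-")

# ordered haplotype-pair states as rows: hap1 allele, hap2 allele (0=a, 1=b)
.STATES <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
# transition cost = number of haplotype positions that switch
.TCOST <- outer(seq_len(4), seq_len(4), function(i, j) {
  (( .STATES[i, 1] != .STATES[j, 1]) + (.STATES[i, 2] != .STATES[j, 2]))
})

# allowed states per code (columns: states aa, ab, ba, bb)
.ALLOWED <- rbind(
  A  = c(TRUE, FALSE, FALSE, FALSE),
  H  = c(FALSE, TRUE, TRUE, FALSE),
  B  = c(FALSE, FALSE, FALSE, TRUE),
  AH = c(TRUE, TRUE, TRUE, FALSE),
  `-` = c(TRUE, TRUE, TRUE, TRUE)
)

#' Construct a genotype table
#'
#' @param individuals Character vector of individual ids.
#' @param markers Data frame with at least a `name` column; optional
#'   `ref_pos_bp`, `map_pos_cM`, `assay` columns.
#' @param calls Character matrix (individuals x markers) over
#'   `A,H,B,AH,-`.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(individuals, markers, calls) {
  calls <- as.matrix(calls)
  stopifnot(nrow(calls) == length(individuals),
            ncol(calls) == nrow(markers))
  bad <- matrix(!(calls %in% GENO_CODES), nrow = nrow(calls))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("unknown genotype code '%s' (individual %s, marker %s)",
                 calls[bad][1], individuals[idx[1]], markers$name[idx[2]]))
  }
  dimnames(calls) <- list(individuals, markers$name)
  structure(list(individuals = individuals, markers = markers,
                 calls = calls), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d individuals x %d markers\n",
              length(x$individuals), nrow(x$markers)))
  invisible(x)
}

#' Minimum crossovers explaining one genotype vector
#'
#' Exact minimum, over all phase assignments consistent with the codes, of
#' the number of haplotype switches between adjacent markers taken in the
#' given order. `AH` is treated as \{A or H\} and missing as unconstrained,
#' so both relax toward the non-recombinant resolution.
#'
#' @param genotypes Character vector of codes in `A,H,B,AH,-`.
#' @param order Integer permutation of marker indices (default: as given).
#' @return Integer minimum crossover count.
#' @examples
#' min_crossovers(c("A", "H", "A", "H", "H", "H"))          # 3
#' min_crossovers(c("A", "A", "H", "H", "H", "H"))          # 1
#' @export
min_crossovers <- function(genotypes, order = seq_along(genotypes)) {
  g <- genotypes[order]
  bad <- !(g %in% GENO_CODES)
  if (any(bad)) stop("unknown genotype code: ", g[bad][1])
  v <- ifelse(.ALLOWED[g[1], ], 0, Inf)
  for (i in seq_along(g)[-1]) {
    step <- pmin(v[1] + .TCOST[1, ], v[2] + .TCOST[2, ],
                 v[3] + .TCOST[3, ], v[4] + .TCOST[4, ])
    v <- ifelse(.ALLOWED[g[i], ], step, Inf)
  }
  out <- min(v)
  if (!is.finite(out)) stop("no consistent phase assignment")
  as.integer(out)
}

#' Total parsimony crossovers of a table under a marker order
#'
#' @param table A [genotype_table()].
#' @param order Integer permutation of marker indices.
#' @param label Optional label for the order.
#' @return A list of class `parsimony_result`: `order`, `label`,
#'   `total_crossovers`, `per_individual`.
#' @export
order_parsimony <- function(table, order = seq_len(ncol(table$calls)),
                            label = "given") {
  stopifnot(inherits(table, "genotype_table"))
  per <- if (nrow(table$calls) == 0) integer(0) else
    apply(table$calls, 1, min_crossovers, order = order)
  structure(list(order = order, label = label,
                 total_crossovers = sum(per),
                 per_individual = as.integer(per)),
            class = "parsimony_result")
}

# candidate orders: reference plus every contiguous-segment reversal
segment_reversal_orders <- function(m) {
  out <- list(list(order = seq_len(m), label = "reference", seg = 0L))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      ord <- seq_len(m)
      ord[i:j] <- rev(ord[i:j])
      out[[length(out) + 1L]] <- list(
        order = ord, label = sprintf("rev_%d_%d", i, j), seg = j - i + 1L)
    }
  }
  out
}

#' Rank candidate marker orders by crossover parsimony
#'
#' Candidates are the reference order plus every contiguous-segment
#' reversal (the inversion hypothesis class); with `exhaustive = TRUE` and
#' at most 7 markers, all permutations are searched instead. Ties are broken
#' by: reference order first, then smaller reversed segment, then
#' lexicographic order of the permutation.
#'
#' @param table A [genotype_table()].
#' @param exhaustive Search all permutations (<= 7 markers only).
#' @return A list of class `order_ranking`: `results` (list of
#'   `parsimony_result`, best first), `best`, `reference_total`, and
#'   `margin` (reference total minus best total).
#' @export
best_order <- function(table, exhaustive = FALSE) {
  m <- ncol(table$calls)
  if (m < 2) stop("need at least two markers")
  cands <- if (exhaustive) {
    if (m > 7) stop("exhaustive search supported for <= 7 markers")
    perms <- all_permutations(m)
    lapply(seq_len(nrow(perms)), function(i) {
      ord <- perms[i, ]
      list(order = ord,
           label = if (all(ord == seq_len(m))) "reference" else
             paste0("perm_", paste(ord, collapse = "")),
           seg = if (all(ord == seq_len(m))) 0L else m)
    })
  } else {
    segment_reversal_orders(m)
  }
  res <- lapply(cands, function(cc) {
    r <- order_parsimony(table, cc$order, cc$label)
    r$seg <- cc$seg
    r
  })
  totals <- vapply(res, function(r) r$total_crossovers, numeric(1))
  segs <- vapply(res, function(r) r$seg, numeric(1))
  is_ref <- vapply(res, function(r) identical(r$label, "reference"),
                   logical(1))
  lex <- vapply(res, function(r) paste(sprintf("%03d", r$order),
                                       collapse = ""), character(1))
  o <- order(totals, !is_ref, segs, lex)
  res <- res[o]
  ref_total <- totals[is_ref][1]
  structure(list(results = res, best = res[[1]],
                 reference_total = ref_total,
                 margin = ref_total - res[[1]]$total_crossovers),
            class = "order_ranking")
}

all_permutations <- function(m) {
  if (m == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(m - 1)
  do.call(rbind, lapply(seq_len(m), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Two-point recombination fraction and Haldane distance
#'
#' An individual is recombinant iff the pairwise minimum crossover count
#' over just the two markers is positive, so `AH` ambiguity and missing data
#' default to the non-recombinant resolution. The per-gamete fraction uses
#' the total minimum crossover count over 2 gametes per informative
#' individual; map distance is the Haldane inverse `-50 ln(1 - 2r)`.
#'
#' @param table A [genotype_table()].
#' @param markerA,markerB Marker names.
#' @return List: `n_recombinant_individuals`, `n_crossover_events` (total
#'   minimum crossovers), `n_informative` (both calls non-missing),
#'   `n_missing`, `r_per_gamete`, `cM_haldane` (`Inf` when r >= 0.5).
#' @export
recombination_fraction <- function(table, markerA, markerB) {
  ia <- match(markerA, table$markers$name)
  ib <- match(markerB, table$markers$name)
  if (is.na(ia) || is.na(ib)) stop("unknown marker")
  a <- table$calls[, ia]; b <- table$calls[, ib]
  informative <- a != "-" & b != "-"
  xo <- mapply(function(x, y) min_crossovers(c(x, y)), a, b)
  n_rec <- sum(xo[informative] > 0)
  n_xo <- sum(xo[informative])
  n_inf <- sum(informative)
  r <- if (n_inf > 0) n_xo / (2 * n_inf) else NA_real_
  cm <- if (is.na(r)) NA_real_ else if (r >= 0.5) Inf else -50 * log(1 - 2 * r)
  list(n_recombinant_individuals = n_rec,
       n_crossover_events = n_xo,
       n_informative = n_inf,
       n_missing = sum(!informative),
       r_per_gamete = r,
       cM_haldane = cm)
}

#' Flag marker pairs with suppressed recombination
#'
#' A pair is flagged iff zero recombinants were observed while the expected
#' number under a genome-wide cM/Mb rate (or an explicitly supplied expected
#' map distance) makes that improbable: `P(0 recombinant gametes) =
#' (1 - r)^(2n) < alpha`, with Haldane `r` from the expected cM.
#'
#' @param table A [genotype_table()].
#' @param pairs Data frame with columns `markerA`, `markerB`,
#'   `physical_bp`, and optionally `expected_cM` (overrides the rate-based
#'   expectation).
#' @param genomewide_cM_per_Mbp Genome-wide recombination rate.
#' @param alpha Significance threshold.
#' @return `pairs` with added columns `n_recombinant`, `n_informative`,
#'   `expected_cM`, `p_zero`, `suppressed`.
#' @export
detect_suppression <- function(table, pairs, genomewide_cM_per_Mbp = 2,
                               alpha = 0.05) {
  out <- pairs
  out$n_recombinant <- NA_integer_
  out$n_informative <- NA_integer_
  if (!"expected_cM" %in% names(out)) out$expected_cM <- NA_real_
  out$p_zero <- NA_real_
  out$suppressed <- NA
  for (i in seq_len(nrow(out))) {
    rf <- recombination_fraction(table, out$markerA[i], out$markerB[i])
    exp_cm <- out$expected_cM[i]
    if (is.na(exp_cm)) {
      exp_cm <- out$physical_bp[i] / 1e6 * genomewide_cM_per_Mbp
    }
    r_exp <- (1 - exp(-2 * exp_cm / 100)) / 2
    p0 <- (1 - r_exp)^(2 * rf$n_informative)
    out$n_recombinant[i] <- rf$n_recombinant_individuals
    out$n_informative[i] <- rf$n_informative
    out$expected_cM[i] <- exp_cm
    out$p_zero[i] <- p0
    out$suppressed[i] <- rf$n_recombinant_individuals == 0 && p0 < alpha
  }
  out
}
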