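# Meiosis simulation for F2/Fn progenies under a Haldane model.
#
# Crossovers per inter-marker interval are Poisson(d_cM/100) with no
# interference; a gamete switches parental haplotype wherever the realized
# count is odd. When the cross is heterozygous for an inversion, intervals
# overlapping a suppression interval contribute zero crossovers in any
# meiosis whose parent carries two different haplotypes inside that
# interval — crossover products of an inversion heterozygote are inviable —
# which yields the hard guarantee that no allele switch is ever observed
# inside a suppressed interval.

#' Configure a simulated cross
#'
#' @param n_individuals Number of progeny individuals (>= 1).
#' @param generation 2 for an F2; larger values are produced by repeated
#'   selfing with independent meioses (4 = F4).
#' @param marker_positions_cM Strictly increasing map positions.
#' @param marker_names Optional marker names (default `M1..Mm`).
#' @param suppression_intervals Two-column matrix (start_cM, end_cM) of
#'   intervals where crossovers are suppressed in inversion heterozygotes;
#'   `NULL` for none.
#' @param halo_cM Extra suppressed flank added to each side of every
#'   suppression interval (the suppressed block around a real inversion can
#'   extend beyond the physical inversion; default 0).
#' @param dominance_mask Logical per marker; `TRUE` marks a dominant assay
#'   whose A and H classes are indistinguishable (scored `AH`).
#' @param missing_rate Per-call probability of a missing genotype.
#' @param seed Integer seed.
#' @return An object of class `cross_config`.
#' @export
cross_config <- function(n_individuals, generation = 2, marker_positions_cM,
                         marker_names = NULL, suppression_intervals = NULL,
                         halo_cM = 0, dominance_mask = NULL,
                         missing_rate = 0, seed = 1) {
  m <- length(marker_positions_cM)
  if (m == 0) stop("marker list must be nonempty")
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  if (generation < 2) stop("generation must be >= 2")
  if (m > 1 && any(diff(marker_positions_cM) <= 0)) {
    stop("map positions must be strictly increasing")
  }
  if (is.null(marker_names)) marker_names <- sprintf("M%d", seq_len(m))
  if (is.null(dominance_mask)) dominance_mask <- rep(FALSE, m)
  stopifnot(length(marker_names) == m, length(dominance_mask) == m)
  if (!is.null(suppression_intervals)) {
    suppression_intervals <- matrix(as.numeric(suppression_intervals),
                                    ncol = 2)
    if (any(suppression_intervals[, 2] < suppression_intervals[, 1])) {
      stop("malformed suppression interval")
    }
    rng <- range(marker_positions_cM)
    if (any(suppression_intervals[, 1] < rng[1] - halo_cM - 1e-9) ||
        any(suppression_intervals[, 2] > rng[2] + halo_cM + 1e-9)) {
      stop("suppression intervals must lie within the marker map range")
    }
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    generation = as.integer(generation),
    marker_positions_cM = as.numeric(marker_positions_cM),
    marker_names = marker_names,
    suppression_intervals = suppression_intervals,
    halo_cM = halo_cM,
    dominance_mask = dominance_mask,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "cross_config")
}

#' Simulate a cross and genotype its progeny
#'
#' Parents are fully homozygous (`P1` all `a`, `P2` all `b`); the F1 is
#' heterozygous at every marker. Each later generation is produced by
#' selfing every individual once. Genotypes are coded `A` (homozygous P1),
#' `B` (homozygous P2), `H` (heterozygous), `AH` (dominant marker: A or H,
#' never B) and `-` (missing).
#'
#' @param config A [cross_config()].
#' @param inversion_het `TRUE` when the two parents differ by the inversion,
#'   so meioses heterozygous inside a suppression interval produce no
#'   crossovers there.
#' @param parent_labels Labels for the two parents (report metadata).
#' @return A list with `table` (a [genotype_table()]) and `truth`: per
#'   generation, the per-gamete crossover-count matrix (`gametes x
#'   intervals`), the matching suppressed-meiosis flags, and realized
#'   allele-switch counts inside suppression intervals (always 0 when
#'   `inversion_het` is `TRUE`).
#' @export
simulate_cross <- function(config, inversion_het = FALSE,
                           parent_labels = c("P1", "P2")) {
  stopifnot(inherits(config, "cross_config"))
  withr_seed(config$seed)
  pos <- config$marker_positions_cM
  m <- length(pos)
  n <- config$n_individuals

  sup <- config$suppression_intervals
  if (!is.null(sup) && config$halo_cM > 0) {
    sup <- cbind(sup[, 1] - config$halo_cM, sup[, 2] + config$halo_cM)
  }

  # interval structure between consecutive markers
  if (m > 1) {
    iv_start <- pos[-m]; iv_end <- pos[-1]
    d <- iv_end - iv_start
    sup_iv <- rep(FALSE, m - 1)
    if (!is.null(sup)) {
      for (j in seq_len(nrow(sup))) {
        sup_iv <- sup_iv | (iv_start < sup[j, 2] & iv_end > sup[j, 1])
      }
    }
  } else {
    d <- numeric(0); sup_iv <- logical(0)
  }

  # one meiosis per row of (hap1, hap2): returns gamete alleles and truth
  meiose <- function(hap1, hap2) {
    ng <- nrow(hap1)
    if (m > 1) {
      xo <- matrix(rpois(ng * (m - 1), rep(d / 100, each = ng)),
                   nrow = ng)
      # a meiosis is suppressed in an interval iff the parent is
      # heterozygous anywhere inside that interval's markers
      if (inversion_het && any(sup_iv)) {
        het_marker <- hap1 != hap2
        for (j in which(sup_iv)) {
          het_here <- het_marker[, j] | het_marker[, j + 1]
          xo[het_here, j] <- 0L
        }
      }
      sw <- xo %% 2L
      cum <- matrix(0L, ng, m)
      for (j in 2:m) cum[, j] <- cum[, j - 1] + sw[, j - 1]
    } else {
      xo <- matrix(0L, ng, 0); sw <- xo
      cum <- matrix(0L, ng, 1)
    }
    start <- sample(0:1, ng, replace = TRUE)
    chooser <- (start + cum) %% 2L
    gam <- ifelse(chooser == 0L, hap1, hap2)
    # allele switches realized inside suppressed intervals (must be 0 when
    # the meiosis was het there)
    asw <- if (m > 1 && any(sup_iv)) {
      sum((sw[, sup_iv, drop = FALSE] == 1L) &
            (hap1[, sup_iv, drop = FALSE] != hap2[, sup_iv, drop = FALSE] |
               hap1[, which(sup_iv) + 1L, drop = FALSE] !=
                 hap2[, which(sup_iv) + 1L, drop = FALSE]))
    } else 0L
    list(gam = gam, xo = xo, asw = asw)
  }

  # F1: het at every marker (alleles 0 = P1, 1 = P2)
  hap1 <- matrix(0L, n, m); hap2 <- matrix(1L, n, m)
  truth <- list()
  for (g in 2:config$generation) {
    m1 <- meiose(hap1, hap2)
    m2 <- meiose(hap1, hap2)
    truth[[sprintf("F%d", g)]] <- list(
      crossovers = rbind(m1$xo, m2$xo),
      allele_switches_in_suppressed = m1$asw + m2$asw
    )
    hap1 <- m1$gam; hap2 <- m2$gam
  }

  geno <- matrix("H", n, m)
  geno[hap1 == 0L & hap2 == 0L] <- "A"
  geno[hap1 == 1L & hap2 == 1L] <- "B"
  if (any(config$dominance_mask)) {
    dom <- which(config$dominance_mask)
    sub <- geno[, dom, drop = FALSE]
    sub[sub %in% c("A", "H")] <- "AH"
    geno[, dom] <- sub
  }
  if (config$missing_rate > 0) {
    miss <- matrix(runif(n * m) < config$missing_rate, n, m)
    geno[miss] <- "-"
  }

  markers <- data.frame(
    name = config$marker_names,
    map_pos_cM = pos,
    assay = ifelse(config$dominance_mask, "dominant", "codominant")
  )
  tab <- genotype_table(
    individuals = sprintf("%s_ind%03d",
                          paste(parent_labels, collapse = "x"), seq_len(n)),
    markers = markers, calls = geno
  )
  list(table = tab, truth = truth,
       config = config, inversion_het = inversion_het)
}
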