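# Sequence records and low-level DNA utilities.
#
# Sequences are stored as plain uppercase character strings over {A,C,G,T,N};
# Biostrings is used for reverse complementation and FASTA I/O. All
# coordinates in this package are 1-based and closed (the IRanges
# convention); every text report states this.

#' Create a sequence record
#'
#' A lightweight container for a named DNA sequence. `origin_offset` carries
#' the coordinate of base 1 in a parent coordinate system (e.g. a region
#' excised from a chromosome), so region-local coordinates can be reported on
#' the chromosome scale without storing the whole chromosome.
#'
#' @param id Character scalar, the sequence name.
#' @param seq Character scalar, DNA over `A,C,G,T,N` (lower case is
#'   uppercased).
#' @param origin_offset Non-negative integer, bp offset of base 1 in the
#'   parent coordinate system (0 = the record starts at the origin).
#' @param build_tag Character scalar labelling the assembly build the
#'   coordinates refer to.
#' @return An object of class `seq_record`: a list with elements `id`, `seq`,
#'   `origin_offset`, `build_tag`.
#' @examples
#' r <- seq_record("toy", "ACGTN")
#' seq_len_bp(r)
#' @export
seq_record <- function(id, seq, origin_offset = 0, build_tag = "refA") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("sequence must be nonempty")
  if (grepl("[^ACGTN]", seq)) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  if (origin_offset < 0) stop("origin_offset must be >= 0")
  structure(
    list(id = id, seq = seq, origin_offset = as.numeric(origin_offset),
         build_tag = build_tag),
    class = "seq_record"
  )
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s: %s bp (offset %s, build %s)\n",
              x$id, format(nchar(x$seq), big.mark = ","),
              format(x$origin_offset, big.mark = ","), x$build_tag))
  invisible(x)
}

#' Sequence length in bp
#' @param x A `seq_record`.
#' @return Integer length.
#' @export
seq_len_bp <- function(x) nchar(x$seq)

#' Reverse complement of a DNA string
#'
#' @param s Character scalar over `A,C,G,T,N`.
#' @return The reverse complement, same alphabet.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Extract a subsequence (1-based, closed)
#' @param x A `seq_record` or character scalar.
#' @param start,end 1-based closed interval.
#' @return Character scalar.
#' @export
subseq_bp <- function(x, start, end) {
  s <- if (inherits(x, "seq_record")) x$seq else x
  substr(s, start, end)
}

# Map A,C,G,T -> 0..3; N and anything else -> NA. Returns an integer vector.
dna_to_int <- function(s) {
  v <- utf8ToInt(s)
  out <- rep(NA_integer_, length(v))
  out[v == 65L] <- 0L  # A
  out[v == 67L] <- 1L  # C
  out[v == 71L] <- 2L  # G
  out[v == 84L] <- 3L  # T
  out
}

int_to_dna <- function(v) {
  chars <- c("A", "C", "G", "T")
  x <- chars[v + 1L]
  x[is.na(v)] <- "N"
  paste(x, collapse = "")
}

#' Derive a stage seed from a master seed
#'
#' All randomness in the pipeline flows from one master seed; each stage uses
#' `master + offset` (mod 2^31 - 1) with a fixed, documented per-stage offset
#' so stages are decoupled but jointly reproducible.
#'
#' @param master_seed Integer master seed.
#' @param stage One of `"reference"`, `"wild"`, `"fragment"`,
#'   `"introgression"`, `"cross"`, `"primers"`, or an integer offset.
#' @return An integer seed.
#' @export
derive_seed <- function(master_seed, stage) {
  offsets <- c(reference = 101L, wild = 211L, fragment = 307L,
               introgression = 401L, cross = 503L, primers = 601L)
  off <- if (is.character(stage)) {
    if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
    offsets[[stage]]
  } else as.integer(stage)
  as.integer((as.numeric(master_seed) + off) %% (2^31 - 1))
}

# Random DNA string of length n at the given GC fraction.
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
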