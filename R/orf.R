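#' Open reading frame scanning
#'
#' `find_longest_orf()` scans the three sense-strand reading frames of a
#' spliced transcript sequence for the longest complete open reading frame
#' (ATG through the codon preceding an in-frame stop).  `orf_runs_sixframe()`
#' additionally scans the reverse complement and counts open-ended runs,
#' which is what the synthetic generator uses to certify that planted
#' noncoding sequences contain no credible ORF in any frame.
#'
#' @param seq character scalar, ACGT (N allowed; codons containing N never
#'   start or extend an ORF).
#' @return `find_longest_orf()`: a list with `codons` (ORF length in
#'   codons, ATG included, stop excluded; 0 if no complete ORF), `start`
#'   (0-based offset of the ATG) and `frame` (0..2).
#' @examples
#' find_longest_orf("AAATGGCCGCCTAAGG")$codons  # ATG GCC GCC -> 3
#' @export
find_longest_orf <- function(seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) abort("sequence contains non-ACGTN symbols")
  best <- list(codons = 0L, start = NA_integer_, frame = NA_integer_)
  n <- nchar(seq)
  for (frame in 0:2) {
    if (frame + 3L > n) next
    starts <- seq.int(frame + 1L, n - 2L, by = 3L)
    cods <- substring(seq, starts, starts + 2L)
    is_atg <- cods == "ATG"
    is_stop <- cods %in% STOP_CODONS
    stop_idx <- which(is_stop)
    for (i in which(is_atg)) {
      nxt <- stop_idx[stop_idx > i]
      if (length(nxt) == 0L) next       # no in-frame stop: not a complete ORF
      len <- nxt[1L] - i                # codons ATG..before stop
      if (len > best$codons)
        best <- list(codons = len, start = starts[i] - 1L, frame = frame)
    }
  }
  best
}

# Longest stop-free codon run starting at an ATG, counting runs that hit
# the sequence end as open ORFs too, over all six frames.  Used to patch
# synthetic noncoding sequences.  Returns max run length in codons and the
# location of the worst run (strand, frame, 0-based codon index of ATG).
orf_runs_sixframe <- function(seq) {
  scan_one <- function(s, strand_lab) {
    n <- nchar(s)
    worst <- NULL
    for (frame in 0:2) {
      if (frame + 3L > n) next
      starts <- seq.int(frame + 1L, n - 2L, by = 3L)
      cods <- substring(s, starts, starts + 2L)
      is_stop <- cods %in% STOP_CODONS
      stop_after <- c(which(is_stop), length(cods) + 1L)
      for (i in which(cods == "ATG")) {
        nxt <- stop_after[stop_after > i][1L]
        len <- nxt - i
        if (is.null(worst) || len > worst$codons)
          worst <- list(codons = len, strand = strand_lab, frame = frame,
                        codon_index = i, offset = starts[i] - 1L)
      }
    }
    worst
  }
  fw <- scan_one(seq, "+")
  rv <- scan_one(revcomp(seq), "-")
  cand <- Filter(Negate(is.null), list(fw, rv))
  if (length(cand) == 0L) return(list(codons = 0L))
  cand[[which.max(vapply(cand, `[[`, numeric(1), "codons"))]]
}

#' Stand-in coding/noncoding hexamer calibration
#'
#' A synthetic codon-usage table drives both the synthetic generator's
#' coding ORFs and the hexamer log-ratio scorer: each amino acid has one
#' preferred codon carrying 70% of its mass, the remainder split evenly
#' among synonyms; amino acids are used uniformly.  The in-frame hexamer
#' probability under the coding model is the product of two codon
#' probabilities; the noncoding background is uniform over all 4096
#' hexamers.  Stop-containing hexamers get a small floor probability.
#'
#' @return `coding_codon_table()`: named numeric vector of 61 sense-codon
#'   probabilities (sums to 1).
#' @export
coding_codon_table <- function() {
  if (!is.null(.ribolnc_cache$codon)) return(.ribolnc_cache$codon)
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES,
                              stringsAsFactors = FALSE)[, 3:1], 1, paste,
                  collapse = "")
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  sense <- codons[aa != "*"]
  aa <- aa[aa != "*"]
  p <- numeric(length(sense))
  names(p) <- sense
  for (a in unique(aa)) {
    syn <- sense[aa == a]
    pref <- syn[1L]  # lexicographically first synonym is 'preferred'
    if (length(syn) == 1L) {
      p[syn] <- 1
    } else {
      p[pref] <- 0.7
      p[setdiff(syn, pref)] <- 0.3 / (length(syn) - 1L)
    }
    p[syn] <- p[syn] / length(unique(aa))
  }
  .ribolnc_cache$codon <- p / sum(p)
  .ribolnc_cache$codon
}

# log2 likelihood ratio per hexamer: coding (codon-pair product, stop
# floor 1e-6) vs uniform noncoding background.
hexamer_log_ratio_table <- function() {
  ct <- coding_codon_table()
  codons <- names(ct)
  hex <- as.vector(outer(codons, codons, paste0))
  p_cod <- as.vector(outer(ct, ct))
  names(p_cod) <- hex
  all_hex <- apply(expand.grid(rep(list(DNA_BASES), 6),
                               stringsAsFactors = FALSE)[, 6:1], 1, paste,
                   collapse = "")
  tab <- setNames(rep(1e-6, length(all_hex)), all_hex)
  tab[names(p_cod)] <- tab[names(p_cod)] + p_cod
  tab <- tab / sum(tab)
  log2(tab * 4096)
}

# cache: the tables are pure functions of constants
.ribolnc_cache <- new.env(parent = emptyenv())

get_hexamer_table <- function() {
  if (is.null(.ribolnc_cache$hex)) .ribolnc_cache$hex <- hexamer_log_ratio_table()
  .ribolnc_cache$hex
}

#' Toy protein-domain motif library
#'
#' Five 30-base motifs (ten codons each, drawn from the fixed codon list
#' of the coding calibration, hence stop-free in frame).  The synthetic
#' generator embeds one motif in every planted coding ORF; the domain-scan
#' scorer searches transcripts against this library.
#'
#' @return character vector of five 30-mers.
#' @export
toy_domain_motifs <- function() {
  if (!is.null(.ribolnc_cache$motifs)) return(.ribolnc_cache$motifs)
  ct <- coding_codon_table()
  # 50 highest-probability codons, alphabetical within ties, deterministic
  ord <- names(ct)[order(-ct, names(ct))][1:50]
  .ribolnc_cache$motifs <- vapply(1:5, function(i)
    paste(ord[((i - 1) * 10 + 1):(i * 10)], collapse = ""), character(1))
  .ribolnc_cache$motifs
}
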