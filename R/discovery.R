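#' Coverage filter
#'
#' Drops transcripts whose read coverage is strictly below the cutoff
#' (coverage exactly at the cutoff passes).
#'
#' @param records support records ([pool_models()]).
#' @param min_coverage cutoff (default 3).
#' @return list with `pass` and `drop` record tables.
#' @export
filter_coverage <- function(records, min_coverage = 3) {
  if (nrow(records) > 0 && anyNA(records$coverage))
    abort("missing coverage for record '%s'",
          records$key[which(is.na(records$coverage))[1]])
  keep <- records$coverage >= min_coverage
  list(pass = records[keep, , drop = FALSE],
       drop = records[!keep, , drop = FALSE])
}

#' Structure filter
#'
#' Drops single-exon transcripts and transcripts whose total exonic
#' length is strictly below the length cutoff.
#'
#' @param records support records.
#' @param min_exons,min_length cutoffs (defaults 2 exons, 200 bases).
#' @return list with `pass` and `drop` record tables; `drop` carries a
#'   `reason` column (`single_exon` takes precedence over `too_short`).
#' @export
filter_structure <- function(records, min_exons = 2L, min_length = 200L) {
  too_few <- records$n_exons < min_exons
  too_short <- records$length < min_length
  keep <- !(too_few | too_short)
  drop <- records[!keep, , drop = FALSE]
  if (nrow(drop) > 0)
    drop$reason <- ifelse(too_few[!keep], "single_exon", "too_short")
  list(pass = records[keep, , drop = FALSE], drop = drop)
}

#' Remove annotated transcripts
#'
#' A record whose structure key matches an annotated mRNA (same intron
#' chain, or same exon interval for single-exon models) is labelled a
#' known mRNA.  A record with same-strand exonic overlap of at least one
#' base against an annotated pseudogene, pre-miRNA, tRNA, rRNA or snoRNA
#' locus is discarded.  Antisense overlap does not remove a record.
#' Everything else survives to coding-potential scoring.
#'
#' @param records support records.
#' @param annotation transcript table with a `biotype` column (`mRNA` or
#'   one of the five noncoding biotypes).
#' @param noncoding_biotypes biotypes whose overlap removes a record.
#' @return list with `known` (records plus `matched_id`),
#'   `annotated_noncoding` (records plus `matched_id`) and `survivors`.
#' @export
remove_annotated <- function(records, annotation,
                             noncoding_biotypes = BIOTYPES_NONCODING) {
  if (is.null(annotation$biotype) || all(is.na(annotation$biotype)))
    abort("annotation has no biotype attribute")
  if (nrow(records) == 0L)
    return(list(known = records, annotated_noncoding = records,
                survivors = records))
  anno_keys <- structure_keys(annotation)
  is_mrna <- annotation$biotype == "mRNA"
  mrna_key_map <- setNames(annotation$transcript_id[is_mrna],
                           anno_keys[is_mrna])
  known_match <- mrna_key_map[records$key]
  is_known <- !is.na(known_match)

  nc <- annotation[annotation$biotype %in% noncoding_biotypes, , drop = FALSE]
  nc_match <- rep(NA_character_, nrow(records))
  if (nrow(nc) > 0) {
    nc_gr <- exons_granges(nc)
    rec_gr <- exons_granges(records, id_col = "key")
    hits <- GenomicRanges::findOverlaps(rec_gr, nc_gr, ignore.strand = FALSE)
    if (length(hits) > 0) {
      qi <- match(names(rec_gr)[S4Vectors::queryHits(hits)], records$key)
      nc_match[qi] <- nc$transcript_id[
        match(names(nc_gr)[S4Vectors::subjectHits(hits)], nc$transcript_id)]
    }
  }
  is_nc <- !is.na(nc_match) & !is_known
  known <- records[is_known, , drop = FALSE]
  if (nrow(known) > 0) known$matched_id <- unname(known_match[is_known])
  ncr <- records[is_nc, , drop = FALSE]
  if (nrow(ncr) > 0) ncr$matched_id <- nc_match[is_nc]
  list(known = known, annotated_noncoding = ncr,
       survivors = records[!is_known & !is_nc, , drop = FALSE])
}

# one GRanges element per exon, named by transcript identifier
exons_granges <- function(tx, id_col = "transcript_id") {
  n_ex <- vapply(tx$exons, nrow, integer(1))
  flat_start <- unlist(lapply(tx$exons, function(e) e[, 1])) + 1L
  flat_end <- unlist(lapply(tx$exons, function(e) e[, 2]))
  gr <- GenomicRanges::GRanges(
    seqnames = rep(tx$chrom, n_ex),
    ranges = IRanges::IRanges(start = flat_start, end = flat_end),
    strand = rep(tx$strand, n_ex))
  names(gr) <- rep(tx[[id_col]], n_ex)
  gr
}

#' Score the coding potential of a transcript sequence
#'
#' Four stand-in scorers exposing the decision thresholds of the tools
#' they emulate, combined by an any-coding (OR) consensus:
#' * `s1` - mean in-frame hexamer log2 likelihood ratio (coding codon-pair
#'   model vs uniform background) over the longest ORF; `-1` when no ORF
#'   of at least 50 codons exists (hexamer statistics are too unstable on
#'   shorter frames to call coding).  Coding iff `s1 >= 0`.
#' * `s2` - longest-ORF fraction of transcript length centred at 0.5, so
#'   0 is the decision point.  Coding iff `s2 >= 0`.
#' * `s3` - best E-value of a motif scan against the bundled toy domain
#'   library ([toy_domain_motifs()]; exact 16-mer seed required, binomial
#'   tail E-value).  Coding iff `s3 < 0.001`.
#' * `s4` - longest ORF length in codons.  Coding iff at least
#'   `min_orf_codons` (default 100).
#'
#' Externally computed scores can replace these via the `scores` argument
#' of [run_discovery()].
#'
#' @param seq character scalar, spliced sense-strand sequence (ACGTN).
#' @param min_orf_codons S4 threshold.
#' @return list with the four scores, four logical flags and `coding`
#'   (the OR consensus).
#' @export
score_coding <- function(seq, min_orf_codons = 100L) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) abort("sequence contains non-ACGTN symbols")
  orf <- find_longest_orf(seq)
  # S1: hexamer log-ratio over the longest ORF
  s1 <- -1
  if (orf$codons >= 50L) {
    hex_tab <- get_hexamer_table()
    orf_seq <- substring(seq, orf$start + 1L, orf$start + 3L * orf$codons)
    pos <- seq.int(1L, 3L * orf$codons - 5L, by = 3L)
    hex <- substring(orf_seq, pos, pos + 5L)
    lr <- hex_tab[hex]
    lr[is.na(lr)] <- 0  # hexamers containing N
    s1 <- mean(lr)
  }
  # S2: ORF fraction of transcript length, centred
  s2 <- (3 * orf$codons) / nchar(seq) - 0.5
  # S3: toy domain scan
  s3 <- domain_scan_evalue(seq)
  # S4: ORF length
  s4 <- orf$codons
  flags <- c(s1 = s1 >= 0, s2 = s2 >= 0, s3 = s3 < 0.001,
             s4 = s4 >= min_orf_codons)
  list(s1 = s1, s2 = s2, s3 = s3, s4 = unname(s4), flags = flags,
       coding = any(flags))
}

# Best E-value of the toy domain library against a query.  A candidate
# placement requires an exact 16-mer seed shared between query and motif
# (the scanner's word size); the placement is scored by its full-overlap
# identity count with a binomial tail p-value, multiplied by the number
# of scanned placements (query positions x motifs) to give an E-value.
# Returns Inf when no seed matches.
domain_scan_evalue <- function(seq, motifs = toy_domain_motifs(),
                               word = 16L) {
  L <- nchar(seq)
  w <- nchar(motifs[1])
  if (L < word) return(Inf)
  trials <- max(1L, L - w + 1L) * length(motifs)
  best <- Inf
  for (m in motifs) {
    offsets <- integer(0)
    for (k in seq_len(w - word + 1L)) {
      seed <- substring(m, k, k + word - 1L)
      hit <- gregexpr(seed, seq, fixed = TRUE)[[1]]
      if (hit[1] != -1L) offsets <- c(offsets, as.integer(hit) - k)
    }
    for (off in unique(offsets)) {   # motif start aligned at query off+1
      q_from <- max(1L, off + 1L); q_to <- min(L, off + w)
      m_from <- q_from - off; m_to <- q_to - off
      qs <- substring(seq, q_from, q_to)
      ms <- substring(m, m_from, m_to)
      n_over <- nchar(qs)
      n_match <- sum(strsplit(qs, "")[[1]] == strsplit(ms, "")[[1]])
      pval <- pbinom(n_match - 1L, n_over, 0.25, lower.tail = FALSE)
      best <- min(best, pval * trials)
    }
  }
  best
}

#' Classify cascade survivors by coding-potential consensus
#'
#' A survivor flagged coding by any scorer becomes a novel mRNA; the rest
#' are candidate lncRNAs.  The two sets are disjoint and exhaustive.
#'
#' @param survivors record table.
#' @param verdicts list of [score_coding()] results, one per survivor row
#'   (names matching `survivors$key`).
#' @return list with `novel_mrna` and `candidate_lncrna` record tables.
#' @export
classify_survivors <- function(survivors, verdicts) {
  if (nrow(survivors) == 0L)
    return(list(novel_mrna = survivors, candidate_lncrna = survivors))
  if (!all(survivors$key %in% names(verdicts)))
    abort("missing coding verdict for record '%s'",
          setdiff(survivors$key, names(verdicts))[1])
  coding <- vapply(survivors$key, function(k) verdicts[[k]]$coding, logical(1))
  list(novel_mrna = survivors[coding, , drop = FALSE],
       candidate_lncrna = survivors[!coding, , drop = FALSE])
}

# Build score_coding-compatible verdicts from an external scores table
# (columns key, tool in {s1,s2,s3,s4}, score), applying the same
# thresholds as the built-in scorers.
verdicts_from_scores <- function(scores, keys, min_orf_codons = 100L) {
  need <- c("key", "tool", "score")
  if (!all(need %in% names(scores))) abort("scores table needs key/tool/score")
  out <- list()
  for (k in keys) {
    sub <- scores[scores$key == k, , drop = FALSE]
    get <- function(tool, default) {
      v <- sub$score[sub$tool == tool]
      if (length(v)) v[1] else default
    }
    s1 <- get("s1", -1); s2 <- get("s2", -1)
    s3 <- get("s3", Inf); s4 <- get("s4", 0)
    flags <- c(s1 = s1 >= 0, s2 = s2 >= 0, s3 = s3 < 0.001,
               s4 = s4 >= min_orf_codons)
    out[[k]] <- list(s1 = s1, s2 = s2, s3 = s3, s4 = s4, flags = flags,
                     coding = any(flags))
  }
  out
}

#' Run the discovery filter cascade
#'
#' Applies, in order: the reliability rule, the coverage filter, the
#' structure filter, annotation removal, and the coding-potential
#' consensus, producing a full classification of every pooled record and
#' a per-stage survivor count table.
#'
#' @param records pooled support records ([pool_models()]).
#' @param annotation annotation transcript table with biotypes.
#' @param genome named character vector (or `DNAStringSet`) of chromosome
#'   sequences, used to extract survivor sequences for scoring.
#' @param scores optional external scores table (columns `key`, `tool`
#'   in `s1..s4`, `score`) that bypasses the built-in scorers.
#' @param min_coverage,min_exons,min_length,min_orf_codons thresholds.
#' @return list with `classification` (`key`, `label`, `discard_reason`,
#'   `matched_id`), `stage_counts` (stage, n_in, n_out), and the record
#'   tables `known_mrna`, `novel_mrna`, `candidate_lncrna`.
#' @export
run_discovery <- function(records, annotation, genome, scores = NULL,
                          min_coverage = 3, min_exons = 2L,
                          min_length = 200L, min_orf_codons = 100L) {
  n0 <- nrow(records)
  rel <- apply_reliability_rule(records)
  cov <- filter_coverage(rel$retained, min_coverage)
  str <- filter_structure(cov$pass, min_exons, min_length)
  ann <- remove_annotated(str$pass, annotation)
  survivors <- ann$survivors
  if (nrow(survivors) > 0) {
    if (is.null(scores)) {
      seqs <- vapply(seq_len(nrow(survivors)), function(i)
        extract_tx_seq(genome, survivors$chrom[i], survivors$strand[i],
                       survivors$exons[[i]]), character(1))
      verdicts <- lapply(seqs, score_coding, min_orf_codons = min_orf_codons)
      names(verdicts) <- survivors$key
    } else {
      verdicts <- verdicts_from_scores(scores, survivors$key, min_orf_codons)
    }
  } else verdicts <- list()
  cls <- classify_survivors(survivors, verdicts)

  lab <- function(recs, label, reason = "none", matched = NULL) {
    if (nrow(recs) == 0L)
      return(data.frame(key = character(0), label = character(0),
                        discard_reason = character(0),
                        matched_id = character(0), stringsAsFactors = FALSE))
    data.frame(key = recs$key, label = label, discard_reason = reason,
               matched_id = if (!is.null(matched)) recs$matched_id
                            else NA_character_, stringsAsFactors = FALSE)
  }
  classification <- rbind(
    lab(rel$dropped, "discarded", "unreliable"),
    lab(cov$drop, "discarded", "low_coverage"),
    if (nrow(str$drop) > 0)
      data.frame(key = str$drop$key, label = "discarded",
                 discard_reason = str$drop$reason, matched_id = NA_character_,
                 stringsAsFactors = FALSE) else lab(str$drop, "discarded"),
    lab(ann$known, "known_mRNA", matched = TRUE),
    lab(ann$annotated_noncoding, "discarded", "annotated_noncoding_biotype",
        matched = TRUE),
    lab(cls$novel_mrna, "novel_mRNA"),
    lab(cls$candidate_lncrna, "candidate_lncRNA"))
  rownames(classification) <- NULL

  stage_counts <- data.frame(
    stage = c("input", "reliability", "coverage", "structure",
              "annotation", "coding_consensus"),
    n_out = c(n0, nrow(rel$retained), nrow(cov$pass), nrow(str$pass),
              nrow(survivors), nrow(cls$candidate_lncrna)),
    stringsAsFactors = FALSE)

  list(classification = classification, stage_counts = stage_counts,
       known_mrna = ann$known, novel_mrna = cls$novel_mrna,
       candidate_lncrna = cls$candidate_lncrna, verdicts = verdicts)
}
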