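#' Transcript-model tables
#'
#' Throughout the package a set of transcript models is a plain
#' `data.frame` with one row per transcript and columns:
#' `transcript_id`, `gene_id`, `chrom`, `strand` (`"+"`/`"-"`),
#' `sample_id`, `assembler`, `coverage` (read coverage, may be `NA` for
#' annotation records), `biotype` (annotation records only), and `exons`,
#' a list column of two-column integer matrices (`start`, `end`) in
#' internal 0-based half-open coordinates, sorted by start and
#' non-overlapping.  GTF files (1-based, inclusive) are converted at the
#' I/O edge only.
#'
#' @param transcript_id,gene_id,chrom,strand,sample_id,assembler,coverage,biotype
#'   scalar fields as described above.
#' @param exons two-column numeric matrix of 0-based half-open exon
#'   intervals.
#' @return `transcript_model()` returns a one-row transcript table.
#' @examples
#' tx <- transcript_model("t1", "g1", "chr1", "+",
#'                        exons = cbind(c(0, 200), c(100, 300)))
#' tx_length(tx$exons[[1]])
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             sample_id = NA_character_,
                             assembler = NA_character_,
                             coverage = NA_real_,
                             biotype = NA_character_) {
  exons <- validate_exons(exons, transcript_id)
  df <- data.frame(transcript_id = transcript_id, gene_id = gene_id,
                   chrom = chrom, strand = strand, sample_id = sample_id,
                   assembler = assembler, coverage = coverage,
                   biotype = biotype, stringsAsFactors = FALSE)
  df$exons <- list(exons)
  df
}

# Exon chains must be sorted, non-overlapping and non-adjacent
# (introns >= 1 base); total exonic length >= 1.
validate_exons <- function(exons, id = "?") {
  exons <- matrix(as.integer(round(exons)), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L || any(exons[, 2] <= exons[, 1]))
    abort("transcript '%s': malformed exon chain (end <= start)", id)
  if (nrow(exons) > 1L) {
    exons <- exons[order(exons[, 1]), , drop = FALSE]
    if (any(exons[-1L, 1] <= exons[-nrow(exons), 2]))
      abort("transcript '%s': overlapping or adjacent exons", id)
  }
  exons
}

#' @rdname transcript_model
#' @export
tx_length <- function(exons) sum(exons[, 2] - exons[, 1])

#' Structure key of a transcript model
#'
#' The identity used for pooling and deduplication: for multi-exon
#' transcripts the chromosome, strand and exact intron chain (so terminal
#' exon ends may differ); for single-exon transcripts the exact exon
#' interval.
#'
#' @param chrom,strand scalars.
#' @param exons exon matrix as in [transcript_model()].
#' @return character scalar key.
#' @export
structure_key <- function(chrom, strand, exons) {
  n <- nrow(exons)
  if (n == 1L) {
    sprintf("%s%s:se:%d-%d", chrom, strand, exons[1, 1], exons[1, 2])
  } else {
    introns <- paste(exons[-n, 2], exons[-1L, 1], sep = "^", collapse = ",")
    sprintf("%s%s:ic:%s", chrom, strand, introns)
  }
}

# Vectorised over the rows of a transcript table.
structure_keys <- function(tx) {
  vapply(seq_len(nrow(tx)), function(i)
    structure_key(tx$chrom[i], tx$strand[i], tx$exons[[i]]), character(1))
}

#' Read transcript models from a GTF file
#'
#' Exon rows are grouped by `transcript_id` and assembled into the
#' internal transcript table (0-based half-open coordinates).  Optional
#' `cov` and `biotype` attributes are carried through.  Exon rows may
#' appear in any order.
#'
#' @param path GTF file path.
#' @return transcript table (see [transcript_model()]).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) abort("no exon records in '%s'", path)
  meta <- S4Vectors::mcols(gr)
  if (is.null(meta$transcript_id) || anyNA(meta$transcript_id))
    abort("GTF '%s': exon record without transcript_id", path)
  if (is.null(meta$gene_id) || anyNA(meta$gene_id))
    abort("GTF '%s': exon record without gene_id", path)
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*"))
    abort("GTF '%s': exon record with unknown strand", path)
  df <- data.frame(transcript_id = meta$transcript_id,
                   gene_id = meta$gene_id,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = strand,
                   start = BiocGenerics::start(gr) - 1L,  # to 0-based
                   end = BiocGenerics::end(gr),
                   stringsAsFactors = FALSE)
  df$coverage <- if (!is.null(meta$cov)) as.numeric(meta$cov) else NA_real_
  df$biotype <- if (!is.null(meta$biotype)) as.character(meta$biotype)
                else NA_character_
  df$sample_id <- if (!is.null(meta$sample_id)) as.character(meta$sample_id)
                  else NA_character_
  df$assembler <- if (!is.null(meta$assembler)) as.character(meta$assembler)
                  else NA_character_
  pieces <- split(df, df$transcript_id)
  out <- lapply(pieces, function(p) {
    transcript_model(p$transcript_id[1], p$gene_id[1], p$chrom[1],
                     p$strand[1], cbind(p$start, p$end),
                     sample_id = p$sample_id[1], assembler = p$assembler[1],
                     coverage = p$coverage[1], biotype = p$biotype[1])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write transcript models to a GTF file
#'
#' One exon row per exon, 1-based inclusive coordinates, with `gene_id`,
#' `transcript_id` and, when present, `cov`, `biotype`, `sample_id` and
#' `assembler` attributes.  `write_gtf(read_gtf(x))` reproduces `x`.
#'
#' @param tx transcript table.
#' @param path output path.
#' @param source value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(tx, path, source = "ribolnc") {
  rows <- lapply(seq_len(nrow(tx)), function(i) {
    e <- tx$exons[[i]]
    data.frame(chrom = tx$chrom[i], start = e[, 1] + 1L, end = e[, 2],
               strand = tx$strand[i], transcript_id = tx$transcript_id[i],
               gene_id = tx$gene_id[i], coverage = tx$coverage[i],
               biotype = tx$biotype[i], sample_id = tx$sample_id[i],
               assembler = tx$assembler[i], stringsAsFactors = FALSE)
  })
  flat <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = flat$chrom,
    ranges = IRanges::IRanges(start = flat$start, end = flat$end),
    strand = flat$strand)
  gr$source <- source
  gr$type <- "exon"
  gr$gene_id <- flat$gene_id
  gr$transcript_id <- flat$transcript_id
  if (!all(is.na(flat$coverage))) gr$cov <- flat$coverage
  if (!all(is.na(flat$biotype))) gr$biotype <- flat$biotype
  if (!all(is.na(flat$sample_id))) gr$sample_id <- flat$sample_id
  if (!all(is.na(flat$assembler))) gr$assembler <- flat$assembler
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Extract the spliced transcript sequence from a genome
#'
#' Exon slices are concatenated in genomic order; minus-strand transcripts
#' are reverse-complemented so the result reads 5' to 3' on the sense
#' strand.
#'
#' @param genome named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @param chrom,strand transcript location.
#' @param exons exon matrix, 0-based half-open.
#' @return character scalar sequence.
#' @export
extract_tx_seq <- function(genome, chrom, strand, exons) {
  if (methods::is(genome, "DNAStringSet"))
    genome <- setNames(as.character(genome), names(genome))
  if (!chrom %in% names(genome)) abort("chromosome '%s' not in genome", chrom)
  chunks <- substring(genome[[chrom]], exons[, 1] + 1L, exons[, 2])
  s <- paste(chunks, collapse = "")
  if (strand == "-") s <- revcomp(s)
  s
}

# Reverse complement of an ACGTN character scalar.
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
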