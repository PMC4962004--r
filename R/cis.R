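#' Gene-body intervals from a transcript table
#'
#' Collapses transcripts to gene level: the gene body is the range of all
#' exon coordinates of the gene's transcripts (0-based half-open).
#'
#' @param tx transcript table.
#' @return data.frame `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @export
gene_bodies <- function(tx) {
  groups <- split(seq_len(nrow(tx)), tx$gene_id)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    idx <- groups[[g]]
    coords <- do.call(rbind, tx$exons[idx])
    data.frame(gene_id = g, chrom = tx$chrom[idx[1]],
               strand = tx$strand[idx[1]],
               start = min(coords[, 1]), end = max(coords[, 2]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Find mRNA genes within a window of a lncRNA gene
#'
#' An mRNA gene is a neighbour if it lies on the same chromosome and the
#' gap between the two gene-body intervals is at most `window` bases
#' (boundary inclusive; gap 0 when the intervals overlap).  The search is
#' strand-agnostic.  The signed distance is positive when the mRNA lies
#' downstream of the lncRNA in the lncRNA's strand orientation, negative
#' upstream, 0 when overlapping.
#'
#' @param lnc_loci,mrna_loci gene-body data.frames ([gene_bodies()]).
#' @param window maximum gap in bases (default 100,000).
#' @return data.frame `lnc_gene`, `mrna_gene`, `distance` (gap, >= 0),
#'   `signed_distance`, `position` in `upstream`/`downstream`/`overlapping`.
#' @export
find_neighbors <- function(lnc_loci, mrna_loci, window = 100000) {
  empty <- data.frame(lnc_gene = character(0), mrna_gene = character(0),
                      distance = numeric(0), signed_distance = numeric(0),
                      position = character(0), stringsAsFactors = FALSE)
  if (nrow(lnc_loci) == 0 || nrow(mrna_loci) == 0) return(empty)
  lgr <- GenomicRanges::GRanges(lnc_loci$chrom,
                                IRanges::IRanges(lnc_loci$start + 1L,
                                                 lnc_loci$end))
  mgr <- GenomicRanges::GRanges(mrna_loci$chrom,
                                IRanges::IRanges(mrna_loci$start + 1L,
                                                 mrna_loci$end))
  hits <- GenomicRanges::findOverlaps(lgr, mgr, maxgap = window,
                                      ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  gap <- GenomicRanges::distance(lgr[qi], mgr[si], ignore.strand = TRUE)
  keep <- !is.na(gap) & gap <= window
  qi <- qi[keep]; si <- si[keep]; gap <- as.numeric(gap[keep])
  if (length(qi) == 0) return(empty)
  # orientation relative to the lncRNA's strand
  right_of <- mrna_loci$start[si] >= lnc_loci$end[qi]
  left_of <- mrna_loci$end[si] <= lnc_loci$start[qi]
  minus <- lnc_loci$strand[qi] == "-"
  downstream <- ifelse(minus, left_of, right_of)
  position <- ifelse(gap == 0 & !(right_of | left_of), "overlapping",
                     ifelse(downstream, "downstream", "upstream"))
  signed <- ifelse(position == "downstream", gap,
                   ifelse(position == "upstream", -gap, 0))
  out <- data.frame(lnc_gene = lnc_loci$gene_id[qi],
                    mrna_gene = mrna_loci$gene_id[si],
                    distance = gap, signed_distance = signed,
                    position = position, stringsAsFactors = FALSE)
  out[order(out$lnc_gene, out$mrna_gene), , drop = FALSE]
}

#' Direction class of a DE lncRNA-mRNA pair
#'
#' @param lnc_direction,mrna_direction `"up"` or `"down"` (a pair is
#'   formed from differentially expressed genes only, so `ns` is an
#'   error).
#' @return list with `class` (e.g. `"up-up"`) and `same` (logical).
#' @export
classify_direction <- function(lnc_direction, mrna_direction) {
  ok <- c("up", "down")
  if (!lnc_direction %in% ok || !mrna_direction %in% ok)
    abort("pair directions must be 'up' or 'down'")
  list(class = paste(lnc_direction, mrna_direction, sep = "-"),
       same = lnc_direction == mrna_direction)
}

#' Predict cis lncRNA-mRNA pairs
#'
#' Pairs each differentially expressed lncRNA gene with every
#' differentially expressed mRNA gene whose gene body lies within the
#' window, annotating each pair with its distance, relative position and
#' joint direction class.
#'
#' @param de_lnc data.frame of DE lncRNA genes: `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `direction` (`up`/`down`).
#' @param de_mrna same layout for DE mRNA genes.
#' @param window maximum gap (default 100,000 bases, inclusive).
#' @return list with `pairs` (one row per pair, including
#'   `direction_class` and `same_direction`) and `summary`
#'   (`n_pairs`, `same`, `opposite`, per-class counts, and per-lncRNA
#'   target multiplicities).
#' @export
predict_pairs <- function(de_lnc, de_mrna, window = 100000) {
  nb <- find_neighbors(de_lnc, de_mrna, window)
  if (nrow(nb) > 0) {
    ld <- setNames(de_lnc$direction, de_lnc$gene_id)[nb$lnc_gene]
    md <- setNames(de_mrna$direction, de_mrna$gene_id)[nb$mrna_gene]
    cls <- vapply(seq_len(nrow(nb)), function(i)
      classify_direction(ld[i], md[i])$class, character(1))
    nb$direction_class <- cls
    nb$same_direction <- ld == md
  } else {
    nb$direction_class <- character(0)
    nb$same_direction <- logical(0)
  }
  mult <- if (nrow(nb) > 0) table(nb$lnc_gene) else table(character(0))
  by_class <- c("up-up" = 0, "up-down" = 0, "down-up" = 0, "down-down" = 0)
  if (nrow(nb) > 0) {
    tc <- table(nb$direction_class)
    by_class[names(tc)] <- as.numeric(tc)
  }
  list(pairs = nb,
       summary = list(n_pairs = nrow(nb),
                      same = sum(nb$same_direction),
                      opposite = sum(!nb$same_direction),
                      by_class = by_class,
                      multiplicity = mult))
}
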