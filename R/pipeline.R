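#' Run the full analysis pipeline on a synthetic dataset
#'
#' Chains every stage: simulation, pooling and reliability filtering,
#' the discovery cascade, FPKM quantification and expression sets,
#' negative-binomial differential expression (one global test with BH
#' adjustment, summarised per class), cis pair prediction for DE
#' lncRNAs, homology classification of the candidate lncRNAs, term
#' enrichment of DE known mRNAs, and the phenotype/qPCR statistics.  The
#' report carries the additive identities every run must satisfy:
#' expressed = shared + breed-specific sets, DE total = up + down, cis
#' pairs = same-direction + opposite-direction.
#'
#' @param config a [simulation_config()]; or pass a ready-made `sim`.
#' @param sim optionally a dataset from [simulate_dataset()] (overrides
#'   `config`).
#' @param window cis window in bases (default 100,000).
#' @param q_threshold DE significance cutoff (default 0.05).
#' @return list with all stage outputs and a `report` list of summary
#'   counts and identities.
#' @export
run_pipeline <- function(config = simulation_config(), sim = NULL,
                         window = 100000, q_threshold = 0.05) {
  if (is.null(sim)) sim <- simulate_dataset(config)
  cfg <- sim$config

  # merge + discovery ---------------------------------------------------
  records <- pool_models(sim$models)
  disc <- run_discovery(records, sim$annotation, sim$genome)
  cls <- disc$classification

  # structure key -> planted truth id (models carry the truth gene id)
  rec_gene <- setNames(records$gene_id, records$key)
  truth_id_of <- function(keys) sub("^G\\.", "", rec_gene[keys])

  # quant ---------------------------------------------------------------
  fpkm <- compute_fpkm(sim$expr$counts, sim$expr$lengths, sim$expr$lib_sizes)
  esets <- expression_sets(fpkm, sim$expr$breed_map)
  shares <- expression_share(fpkm, sim$expr$breed_map)

  # de -------------------------------------------------------------------
  de_res <- run_de(sim$expr$counts, sim$expr$breed_map,
                   q_threshold = q_threshold)
  label_of <- setNames(cls$label, truth_id_of(cls$key))
  de_res$class <- label_of[de_res$transcript_id]
  de_summary <- lapply(split(de_res, de_res$class), function(d)
    call_de(d, q_threshold)$summary)

  # cis -------------------------------------------------------------------
  keep_lnc <- cls$key[cls$label == "candidate_lncRNA"]
  keep_mrna <- cls$key[cls$label %in% c("known_mRNA", "novel_mRNA")]
  dir_of <- setNames(de_res$direction, de_res$transcript_id)
  body_of <- function(keys) {
    recs <- records[match(keys, records$key), , drop = FALSE]
    gb <- gene_bodies(recs)
    gb$direction <- unname(dir_of[sub("^G\\.", "", gb$gene_id)])
    gb[!is.na(gb$direction) & gb$direction != "ns", , drop = FALSE]
  }
  cis <- predict_pairs(body_of(keep_lnc), body_of(keep_mrna), window)

  # homology --------------------------------------------------------------
  lnc_recs <- records[match(keep_lnc, records$key), , drop = FALSE]
  homology <- NULL
  if (nrow(lnc_recs) > 0 && length(sim$db_human) > 0) {
    seqs <- setNames(vapply(seq_len(nrow(lnc_recs)), function(i)
      extract_tx_seq(sim$genome, lnc_recs$chrom[i], lnc_recs$strand[i],
                     lnc_recs$exons[[i]]), character(1)),
      truth_id_of(lnc_recs$key))
    homology <- classify_homology(seqs, sim$db_human, sim$db_mouse)
  }

  # enrichment -------------------------------------------------------------
  known_genes <- unique(paste0("G.", de_res$transcript_id[
    de_res$class == "known_mRNA" & !is.na(de_res$class)]))
  de_known_genes <- unique(paste0("G.", de_res$transcript_id[
    !is.na(de_res$class) & de_res$class == "known_mRNA" &
      de_res$direction != "ns"]))
  enrichment <- NULL
  if (length(de_known_genes) > 0 && nrow(sim$term_map) > 0)
    enrichment <- enrich_terms(de_known_genes, known_genes, sim$term_map)

  # phenotype / qPCR stats --------------------------------------------------
  pheno_tests <- phenotype_ttests(sim$phenotypes$summary)
  qpcr <- if (nrow(sim$phenotypes$ct) > 0)
    qpcr_fold_changes(sim$phenotypes$ct, calibrator = "breed1") else NULL

  breeds <- unique(unname(sim$expr$breed_map))
  n_specific <- sum(vapply(breeds, function(b)
    length(esets[[paste0("specific_", b)]]), numeric(1)))
  report <- list(
    stage_counts = disc$stage_counts,
    class_totals = table(cls$label),
    de_summary = de_summary,
    expressed_total = length(esets$expressed),
    expressed_identity = length(esets$expressed) ==
      length(esets$shared) + n_specific,
    de_identity = all(vapply(de_summary, function(s)
      s[["total"]] == s[["up"]] + s[["down"]], logical(1))),
    cis_total = cis$summary$n_pairs,
    cis_identity = cis$summary$n_pairs ==
      cis$summary$same + cis$summary$opposite,
    homology_percentages = if (!is.null(homology)) homology$percentages,
    top_terms = if (!is.null(enrichment)) head(enrichment, 3),
    phenotype_p = setNames(pheno_tests$p, pheno_tests$trait))

  list(sim = sim, records = records, discovery = disc, fpkm = fpkm,
       expression_sets = esets, expression_shares = shares, de = de_res,
       cis = cis, homology = homology, enrichment = enrichment,
       phenotype_tests = pheno_tests, qpcr = qpcr, report = report)
}
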