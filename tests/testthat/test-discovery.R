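mk_rec <- function(id, exons, coverage = 10, chrom = "chr1", strand = "+",
                   sample_id = "S1") {
  pool_models(rand_tx(id, chrom = chrom, strand = strand, exons = exons,
                      coverage = coverage, sample_id = sample_id))
}

test_that("coverage filter uses a strict < 3 boundary", {
  low <- mk_rec("a", cbind(c(0, 500), c(300, 800)), coverage = 2.9)
  at <- mk_rec("b", cbind(c(0, 500), c(300, 800)), coverage = 3.0)
  recs <- rbind(low, at)
  out <- filter_coverage(recs)
  expect_identical(out$drop$transcript_id, "a")
  expect_identical(out$pass$transcript_id, "b")
  empty <- filter_coverage(recs[0, ])
  expect_identical(nrow(empty$pass) + nrow(empty$drop), 0L)
  bad <- recs; bad$coverage[1] <- NA
  expect_error(filter_coverage(bad), "coverage")
})

test_that("structure filter drops single-exon and sub-200-base models", {
  recs <- rbind(
    mk_rec("one_exon_long", cbind(0, 5000)),            # 1 exon, 5 kb
    mk_rec("two_ex_199", cbind(c(0, 500), c(100, 599))),  # 199 bases
    mk_rec("two_ex_200", cbind(c(0, 500), c(100, 600))),  # 200 bases
    mk_rec("three_ex_1k", cbind(c(0, 500, 1200), c(400, 800, 1500))))
  out <- filter_structure(recs)
  expect_setequal(out$pass$transcript_id, c("two_ex_200", "three_ex_1k"))
  reasons <- setNames(out$drop$reason, out$drop$transcript_id)
  expect_identical(unname(reasons["one_exon_long"]), "single_exon")
  expect_identical(unname(reasons["two_ex_199"]), "too_short")
})

test_that("coverage and structure filters commute", {
  rec <- default_records()
  a <- filter_structure(filter_coverage(rec)$pass)$pass
  b <- filter_coverage(filter_structure(rec)$pass)$pass
  expect_setequal(a$key, b$key)
})

test_that("annotation removal distinguishes known mRNA, noncoding overlap and survivors", {
  anno <- rbind(
    transcript_model("ann.m", "G.m", "chr1", "+",
                     cbind(c(0, 500), c(100, 700)), biotype = "mRNA"),
    transcript_model("ann.r", "G.r", "chr1", "+", cbind(5000, 6500),
                     biotype = "rRNA"))
  recs <- rbind(
    mk_rec("match_known", cbind(c(10, 500), c(100, 650))),  # same intron chain
    mk_rec("rrna_overlap", cbind(c(4800, 6000), c(5100, 6400))),
    mk_rec("antisense", cbind(c(4800, 6000), c(5100, 6400)), strand = "-"),
    mk_rec("clean", cbind(c(20000, 21000), c(20400, 21500))))
  out <- remove_annotated(recs, anno)
  expect_identical(out$known$transcript_id, "match_known")
  expect_identical(out$known$matched_id, "ann.m")
  expect_identical(out$annotated_noncoding$transcript_id, "rrna_overlap")
  expect_identical(out$annotated_noncoding$matched_id, "ann.r")
  # antisense overlap with a noncoding biotype does not remove the record
  expect_setequal(out$survivors$transcript_id, c("antisense", "clean"))
  no_bio <- anno; no_bio$biotype <- NA
  expect_error(remove_annotated(recs, no_bio), "biotype")
})

test_that("coding scorers behave at their documented thresholds", {
  # no ATG anywhere: S4 sees no ORF, consensus can only come from others
  no_atg <- paste(rep("CCT", 100), collapse = "")
  v <- score_coding(no_atg)
  expect_identical(v$s4, 0L)
  expect_false(v$flags[["s4"]])
  # planted mRNA: brute-force ORF scan confirms S4 fires, consensus coding
  sim <- default_sim()
  mr <- sim$truth[sim$truth$coding, ][1, ]
  expect_gte(bf_longest_orf_sixframe(mr$seq), 200)
  vm <- score_coding(mr$seq)
  expect_true(vm$flags[["s4"]])
  expect_true(vm$coding)
  # planted lncRNA: all four scorers negative
  ln <- sim$truth[sim$truth$label == "lncRNA", ][1, ]
  vl <- score_coding(ln$seq)
  expect_false(vl$coding)
  expect_error(score_coding("ACGTXQ"), "non-ACGTN")
})

test_that("consensus is the OR of the four flags and respects thresholds", {
  keys <- "k1"
  surv <- mk_rec("t", cbind(c(0, 500), c(300, 800)))
  surv$key <- keys
  # S3 E-value just below 0.001 alone makes a novel mRNA
  sc <- data.frame(key = "k1", tool = "s3", score = 0.0005)
  v <- ribolnc:::verdicts_from_scores(sc, keys)
  expect_true(v$k1$coding)
  out <- classify_survivors(surv, v)
  expect_identical(nrow(out$novel_mrna), 1L)
  # all four scores on the noncoding side -> candidate lncRNA
  sc2 <- data.frame(key = rep("k1", 4), tool = c("s1", "s2", "s3", "s4"),
                    score = c(-0.5, -1, 0.5, 0))
  v2 <- ribolnc:::verdicts_from_scores(sc2, keys)
  expect_false(v2$k1$coding)
  out2 <- classify_survivors(surv, v2)
  expect_identical(nrow(out2$candidate_lncrna), 1L)
  # boundary: CNCI/CPC-style score exactly 0 counts as coding
  sc3 <- data.frame(key = "k1", tool = "s1", score = 0)
  expect_true(ribolnc:::verdicts_from_scores(sc3, keys)$k1$coding)
  # monotonicity: adding a coding flag never demotes novel -> candidate
  sc4 <- rbind(sc, data.frame(key = "k1", tool = "s4", score = 150))
  v4 <- ribolnc:::verdicts_from_scores(sc4, keys)
  expect_true(v4$k1$coding)
  # empty survivor set
  out0 <- classify_survivors(surv[0, ], list())
  expect_identical(nrow(out0$novel_mrna) + nrow(out0$candidate_lncrna), 0L)
  expect_error(classify_survivors(surv, list()), "verdict")
})

test_that("longest-ORF finder agrees with the naive scanner", {
  expect_identical(find_longest_orf("AAATGGCCGCCTAAGG")$codons, 3L)
  set.seed(42)
  for (i in 1:30) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(30:200, 1),
                      replace = TRUE), collapse = "")
    mine <- find_longest_orf(s)$codons
    # naive scanner looks at both strands; restrict to the sense strand
    comp <- bf_longest_orf_sixframe_sense(s)
    expect_identical(mine, comp)
  }
})

test_that("the cascade classifies the default synthetic corpus exactly", {
  sim <- default_sim()
  disc <- default_discovery()
  cls <- disc$classification
  truth_lab <- setNames(sim$truth$label, sim$truth$transcript_id)
  tid <- truth_ids_of(cls$key)
  pred <- cls$label
  # partition: one class per record, sizes sum to input
  expect_identical(anyDuplicated(cls$key), 0L)
  expect_identical(nrow(cls), nrow(default_records()))
  # stage counts monotonically non-increasing
  expect_true(all(diff(disc$stage_counts$n_out) <= 0))
  # perfect recovery: precision = recall = 1 for all three classes
  for (cl in c("known_mRNA", "novel_mRNA")) {
    expect_setequal(tid[pred == cl], names(truth_lab)[truth_lab == cl])
  }
  expect_setequal(tid[pred == "candidate_lncRNA"],
                  names(truth_lab)[truth_lab == "lncRNA"])
  # every noise transcript is discarded with its planted reason
  nc <- setNames(sim$truth$noise_class, sim$truth$transcript_id)
  disc_reason <- setNames(cls$discard_reason, tid)[!is.na(nc[tid])]
  reason_map <- c(low_coverage = "low_coverage", single_exon = "single_exon",
                  too_short = "too_short",
                  private_singleton = "unreliable",
                  anno_overlap = "annotated_noncoding_biotype")
  expect_identical(unname(disc_reason),
                   unname(reason_map[nc[names(disc_reason)]]))
})

test_that("an all-noise corpus yields zero candidates", {
  cfg <- simulation_config(seed = 12, n_chromosomes = 1,
                           chrom_length = 400000, n_known_mrna = 0,
                           n_novel_mrna = 0, n_lncrna = 0, n_noise = 12)
  sim <- simulate_dataset(cfg)
  disc <- run_discovery(pool_models(sim$models), sim$annotation, sim$genome)
  expect_identical(sum(disc$classification$label != "discarded"), 0L)
  expect_true(all(disc$classification$discard_reason != "none"))
})
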