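loci <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(gene_id = r[[1]], chrom = r[[2]], strand = r[[3]],
               start = as.numeric(r[[4]]), end = as.numeric(r[[5]]),
               direction = if (length(r) > 5) r[[6]] else NA,
               stringsAsFactors = FALSE)))
}

test_that("the 100 kb window boundary is inclusive", {
  lnc <- loci(list("L", "chr1", "+", 0, 1000))
  near <- loci(list("Mnear", "chr1", "+", 101000, 102000))   # gap 100,000
  far <- loci(list("Mfar", "chr1", "+", 101001, 102000))     # gap 100,001
  other <- loci(list("Mchr2", "chr2", "+", 1000, 2000))
  ovl <- loci(list("Movl", "chr1", "-", 500, 1500))
  nb <- find_neighbors(lnc, rbind(near, far, other, ovl))
  expect_setequal(nb$mrna_gene, c("Mnear", "Movl"))
  expect_identical(nb$distance[nb$mrna_gene == "Mnear"], 100000)
  expect_identical(nb$distance[nb$mrna_gene == "Movl"], 0)
  expect_identical(nb$position[nb$mrna_gene == "Movl"], "overlapping")
  # orientation is relative to the lncRNA strand
  expect_identical(nb$position[nb$mrna_gene == "Mnear"], "downstream")
  lnc_minus <- loci(list("L", "chr1", "-", 0, 1000))
  nb2 <- find_neighbors(lnc_minus, near)
  expect_identical(nb2$position, "upstream")
  expect_identical(nb2$signed_distance, -100000)
})

test_that("direction classes concatenate lncRNA then mRNA", {
  expect_identical(classify_direction("up", "up"),
                   list(class = "up-up", same = TRUE))
  expect_identical(classify_direction("down", "up"),
                   list(class = "down-up", same = FALSE))
  expect_identical(classify_direction("down", "down"),
                   list(class = "down-down", same = TRUE))
  expect_error(classify_direction("ns", "up"), "up")
})

test_that("pairs are DE x DE with additive direction summaries", {
  de_lnc <- loci(list("L1", "chr1", "+", 0, 1000, "up"),
                 list("L2", "chr1", "+", 500000, 501000, "down"),
                 list("L3", "chr2", "+", 0, 1000, "up"))
  de_mrna <- loci(list("M1", "chr1", "+", 11000, 12000, "up"),
                  list("M2", "chr1", "+", 520000, 521000, "up"),
                  list("M3", "chr1", "+", 900000, 901000, "up"))
  out <- predict_pairs(de_lnc, de_mrna)
  expect_identical(out$summary$n_pairs, 2L)
  expect_identical(out$summary$same + out$summary$opposite,
                   out$summary$n_pairs)
  expect_identical(sum(out$summary$by_class), 2)
  expect_identical(unname(out$summary$by_class[["up-up"]]), 1)
  expect_identical(unname(out$summary$by_class[["down-up"]]), 1)
  expect_identical(sum(out$summary$multiplicity), 2L)
  # an lncRNA with no DE mRNA in range contributes nothing
  expect_false("L3" %in% out$pairs$lnc_gene)
})

test_that("the planted synthetic pair is found and the decoy excluded", {
  sim <- default_sim()
  de <- run_de(sim$expr$counts, sim$expr$breed_map)
  dir_of <- setNames(de$direction, de$transcript_id)
  gb <- function(label) {
    t <- sim$truth[sim$truth$label %in% label, ]
    t$gene_id <- t$gene_id
    g <- gene_bodies(t)
    g$direction <- unname(dir_of[sub("^G\\.", "", g$gene_id)])
    g[!is.na(g$direction) & g$direction != "ns", ]
  }
  out <- predict_pairs(gb("lncRNA"), gb(c("known_mRNA", "novel_mRNA")))
  # cis units 1 and 2 are planted at 10 kb (in window); unit 3 at 150 kb
  pair_str <- paste(out$pairs$lnc_gene, out$pairs$mrna_gene)
  expect_true(all(c("G.LNC0001 G.KM0001", "G.LNC0002 G.KM0002") %in% pair_str))
  expect_false("G.LNC0003 G.KM0003" %in% pair_str)
  d1 <- out$pairs$distance[pair_str == "G.LNC0001 G.KM0001"]
  expect_identical(d1, 10000)
  # direction classes reflect the planted signs (unit 1 up-up, unit 2 down-up)
  expect_identical(out$pairs$direction_class[pair_str == "G.LNC0001 G.KM0001"],
                   "up-up")
  expect_identical(out$pairs$direction_class[pair_str == "G.LNC0002 G.KM0002"],
                   "down-up")
})

test_that("the interval engine matches an all-pairs brute-force scan", {
  set.seed(8)
  for (rep in 1:5) {
    n1 <- sample(3:12, 1); n2 <- sample(5:25, 1)
    mk <- function(n, pre) {
      st <- sample(0:4e5, n)
      data.frame(gene_id = paste0(pre, seq_len(n)),
                 chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 start = st, end = st + sample(500:5000, n, replace = TRUE),
                 stringsAsFactors = FALSE)
    }
    lnc <- mk(n1, "L"); mrna <- mk(n2, "M")
    window <- sample(c(10000, 50000, 100000), 1)
    nb <- find_neighbors(lnc, mrna, window)
    got <- sort(paste(nb$lnc_gene, nb$mrna_gene, nb$distance, sep = "|"))
    expect_identical(got, bf_cis_pairs(lnc, mrna, window))
    # window monotonicity: enlarging never removes a pair
    nb_big <- find_neighbors(lnc, mrna, window * 2)
    expect_true(all(paste(nb$lnc_gene, nb$mrna_gene) %in%
                      paste(nb_big$lnc_gene, nb_big$mrna_gene)))
  }
})
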