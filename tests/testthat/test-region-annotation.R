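# A PCG with well-separated structure for targeted placement checks:
# '+' strand, exons [10000,10200) and [12000,12500), CDS [10100,12300),
# so utr5 = [10000,10100), utr3 = [12300,12500), intron [10200,12000).
host_model <- function() {
  toy_model("Host", "chr1", "+",
            exons = rbind(c(10000L, 10200L), c(12000L, 12500L)),
            cds = rbind(c(10100L, 10200L), c(12000L, 12300L)))
}

test_that("anchors inside each feature get the expected class", {
  index <- build_gene_index(list(Host = host_model()))
  cls <- function(s, e) {
    classify_region(list(chrom = "chr1", start = s, end = e, strand = "+"),
                    index, lnc_id = "L")
  }
  # lncRNA fully inside the intron of its host (intron-resident lncRNA)
  intr <- cls(10500, 11500)
  expect_equal(intr$region, "intronic")
  expect_equal(intr$assigned_pcg_id, "Host")
  expect_equal(intr$distance_to_gene, 0L)
  expect_equal(cls(10020, 10080)$region, "five_prime_utr")
  expect_equal(cls(12320, 12480)$region, "three_prime_utr")
  expect_equal(cls(10120, 10180)$region, "exonic")
  expect_equal(cls(9000, 9400)$region, "upstream")     # anchor 9200
  expect_equal(cls(12600, 13200)$region, "downstream") # anchor 12900
  # anchor 6000 bp upstream of the TSS -> outside the 5 kb window
  far <- cls(3800, 4200)
  expect_equal(far$region, "intergenic")
  expect_true(is.na(far$assigned_pcg_id))
})

test_that("windows are strand-aware and ties break lexicographically", {
  minus <- toy_model("Minus", "chr1", "-", cbind(20000L, 21000L))
  index <- build_gene_index(list(Minus = minus))
  ann_up <- classify_region(list(chrom = "chr1", start = 21500, end = 22500,
                                 strand = "+"), index, lnc_id = "L")
  expect_equal(ann_up$region, "upstream")   # 5' of a '-' gene is rightward
  ann_dn <- classify_region(list(chrom = "chr1", start = 19400, end = 19800,
                                 strand = "+"), index, lnc_id = "L")
  expect_equal(ann_dn$region, "downstream")

  # equidistant candidates: lexicographically smaller id wins
  a <- toy_model("Bb", "chr1", "+", cbind(0L, 1000L))
  b <- toy_model("Aa", "chr1", "+", cbind(3000L, 4000L))
  idx2 <- build_gene_index(list(Bb = a, Aa = b))
  tie <- classify_region(list(chrom = "chr1", start = 1990, end = 2010,
                              strand = "+"), idx2, lnc_id = "L")
  expect_equal(tie$anchor_position, 2000L)
  expect_equal(tie$assigned_pcg_id, "Aa")
})

test_that("empty index and malformed intervals behave as specified", {
  empty <- build_gene_index(list())
  ann <- classify_region(list(chrom = "chr1", start = 10, end = 20,
                              strand = "+"), empty, lnc_id = "L")
  expect_equal(ann$region, "intergenic")
  expect_error(
    classify_region(list(chrom = "chr1", start = 20, end = 20,
                         strand = "+"), empty),
    "malformed")
})

test_that("classification equals the per-definition oracle on random loci", {
  n_checked <- 0L
  for (seed in 1:5) {
    g <- small_genome(seed, n_pcg = 25, n_lnc = 3)
    set.seed(seed + 100)
    chrom_max <- max(g$pcg_index$table$end) + 20000
    for (i in 1:200) {
      s <- sample.int(chrom_max, 1)
      e <- s + sample.int(10000, 1)
      lnc <- list(chrom = "chr1", start = s, end = e,
                  strand = sample(c("+", "-"), 1))
      got <- classify_region(lnc, g$pcg_index, lnc_id = "L")
      expect_identical(got$region, oracle_classify(lnc, g$pcg_models))
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 1000L)
})

test_that("classification ignores gene insertion order", {
  g <- small_genome(9, n_pcg = 15, n_lnc = 3)
  set.seed(42)
  shuffled <- build_gene_index(sample(g$pcg_models))
  for (i in 1:50) {
    s <- sample.int(6e5, 1); e <- s + sample.int(5000, 1)
    lnc <- list(chrom = "chr1", start = s, end = e, strand = "+")
    expect_identical(classify_region(lnc, g$pcg_index, lnc_id = "L"),
                     classify_region(lnc, shuffled, lnc_id = "L"))
  }
})

test_that("region distributions count all seven classes", {
  ann <- data.frame(lncrna_gene_id = sprintf("L%d", 1:10),
                    region = "intergenic")
  d <- region_distribution(ann)
  expect_equal(sum(d$count), 10)
  expect_equal(d$fraction[d$region == "intergenic"], 1)
  expect_equal(sum(d$fraction), 1)

  ann2 <- data.frame(lncrna_gene_id = sprintf("L%d", 1:4),
                     region = c("intronic", "intronic", "exonic",
                                "upstream"))
  d2 <- region_distribution(ann2)
  expect_equal(d2$fraction[d2$region == "intronic"], 0.5)
  expect_equal(d2$fraction[d2$region == "exonic"], 0.25)
  expect_equal(d2$fraction[d2$region == "upstream"], 0.25)
  expect_equal(nrow(d2), 7)
  expect_error(region_distribution(ann[0, ]), "no annotations")
})

test_that("planted class proportions are recovered on a large cohort", {
  cfg <- sim_config(seed = 17, n_chromosomes = 4L, n_pcg = 200L,
                    n_lnc = 2000L)
  g <- generate_genome(cfg)
  ann <- annotate_regions(g$lnc_models, g$pcg_index)
  d <- region_distribution(ann)
  planted <- cfg$region_class_proportions[d$region]
  expect_true(all(abs(d$fraction - planted) <= 0.03))
  # planted truth recovered exactly, by construction
  expect_identical(ann$region[match(g$truth$lnc_id, ann$lncrna_gene_id)],
                   g$truth$planted_class)
})
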