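de_call_row <- function(gene_id, organ, lfc, q, expressed = TRUE) {
  dr <- expressed & q < 0.05
  data.frame(gene_id = gene_id, organ = organ,
             mean_fpkm_cv = 5, mean_fpkm_gf = 5 * 2^lfc,
             log2_fold_change = lfc, p_value = q / 2, q_value = q,
             expressed = expressed, differentially_regulated = dr,
             direction = ifelse(!dr, "none",
                                ifelse(lfc > 0, "up_in_gf", "down_in_gf")),
             stringsAsFactors = FALSE)
}

test_that("candidate finding uses interval overlap with extended windows", {
  a <- toy_model("P1", "chr1", "+", cbind(20000L, 25000L))
  b <- toy_model("P2", "chr1", "+", cbind(31000L, 36000L))
  index <- build_gene_index(list(P1 = a, P2 = b))
  cfg <- pairing_config()
  # lncRNA spanning the gap reaches both windows
  both <- find_candidate_pcgs(list(chrom = "chr1", start = 25500,
                                   end = 26500, strand = "+"), index, cfg)
  expect_identical(both$pcg_id, c("P1", "P2"))
  # exactly 5,001 bp upstream of the TSS: outside the 5 kb window
  lone <- toy_model("P3", "chr2", "+", cbind(50000L, 55000L))
  idx3 <- build_gene_index(list(P3 = lone))
  out <- find_candidate_pcgs(list(chrom = "chr2", start = 44000,
                                  end = 44999, strand = "+"), idx3, cfg)
  expect_equal(nrow(out), 0)
  # one base further right overlaps the window edge
  edge <- find_candidate_pcgs(list(chrom = "chr2", start = 44000,
                                   end = 45001, strand = "+"), idx3, cfg)
  expect_identical(edge$pcg_id, "P3")
})

test_that("candidate sets equal the brute-force all-pairs scan", {
  n_checked <- 0L
  for (seed in 1:5) {
    g <- small_genome(seed, n_pcg = 25, n_lnc = 3)
    set.seed(seed + 500)
    chrom_max <- max(g$pcg_index$table$end) + 20000
    for (i in 1:100) {
      s <- sample.int(chrom_max, 1); e <- s + sample.int(10000, 1)
      lnc <- list(chrom = "chr1", start = s, end = e, strand = "+")
      got <- find_candidate_pcgs(lnc, g$pcg_index)
      expect_identical(got$pcg_id, oracle_candidates(lnc, g$pcg_models))
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 500L)
})

# shared fixture: lncRNA inside the host's intron, a second far-away PCG
pair_fixture <- function() {
  host <- toy_model("Pcg1", "chr1", "-",
                    exons = rbind(c(30000L, 30500L), c(34000L, 35000L)),
                    cds = rbind(c(30100L, 30500L), c(34000L, 34800L)))
  far <- toy_model("Pcg2", "chr1", "+", cbind(200000L, 210000L))
  lnc <- toy_model("Lnc1", "chr1", "+", cbind(31000L, 33000L))
  list(lnc_models = list(Lnc1 = lnc),
       index = build_gene_index(list(Pcg1 = host, Pcg2 = far)))
}

test_that("pairs require proximity plus DE of both members", {
  fx <- pair_fixture()
  # both up, expressed, q < 0.05 -> one both_up pair
  pairs <- call_pairs(de_call_row("Lnc1", "liver", 2, 0.01),
                      de_call_row("Pcg1", "liver", 1.5, 0.02),
                      fx$lnc_models, fx$index)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$category, "both_up")
  expect_equal(pairs$relation, "intronic")

  # discordant: lncRNA up, PCG down
  disc <- call_pairs(de_call_row("Lnc1", "liver", 2, 0.01),
                     de_call_row("Pcg1", "liver", -1.2, 0.02),
                     fx$lnc_models, fx$index)
  expect_equal(disc$category, "lnc_up_pcg_down")

  # neighbor PCG q = 0.2 -> no pair
  none <- call_pairs(de_call_row("Lnc1", "liver", 2, 0.01),
                     de_call_row("Pcg1", "liver", 1.5, 0.2),
                     fx$lnc_models, fx$index)
  expect_equal(nrow(none), 0)

  # symmetric evidence: dropping either member's DE removes the pair
  no_lnc <- call_pairs(de_call_row("Lnc1", "liver", 2, 0.2),
                       de_call_row("Pcg1", "liver", 1.5, 0.02),
                       fx$lnc_models, fx$index)
  expect_equal(nrow(no_lnc), 0)
  not_expr <- call_pairs(de_call_row("Lnc1", "liver", 2, 0.01,
                                     expressed = FALSE),
                         de_call_row("Pcg1", "liver", 1.5, 0.02),
                         fx$lnc_models, fx$index)
  expect_equal(nrow(not_expr), 0)
})

test_that("a DE call without a gene model is an error naming the id", {
  fx <- pair_fixture()
  expect_error(
    call_pairs(de_call_row("Ghost", "liver", 2, 0.01),
               de_call_row("Pcg1", "liver", 1.5, 0.02),
               fx$lnc_models, fx$index),
    "Ghost")
})

test_that("pair summaries reproduce a brute-force group-by", {
  set.seed(123)
  organs <- c("liver", "colon")
  n <- 200
  pairs <- data.frame(
    organ = sample(organs, n, replace = TRUE),
    lncrna_gene_id = sprintf("L%03d", sample(50, n, TRUE)),
    pcg_gene_id = sprintf("P%03d", sample(50, n, TRUE)),
    relation = "intronic",
    category = sample(pair_categories(), n, TRUE,
                      prob = c(0.45, 0.45, 0.05, 0.05)),
    stringsAsFactors = FALSE)
  s <- summarize_pairs(pairs)
  for (org in organs) {
    sub <- pairs[pairs$organ == org, ]
    row <- s[s$organ == org, ]
    expect_equal(row$total, nrow(sub))
    expect_equal(row$n_both_up, sum(sub$category == "both_up"))
    expect_equal(row$n_lnc_down_pcg_up,
                 sum(sub$category == "lnc_down_pcg_up"))
    expect_equal(row$total, row$n_both_up + row$n_both_down +
                   row$n_lnc_up_pcg_down + row$n_lnc_down_pcg_up)
  }
  expect_equal(nrow(summarize_pairs(pairs[0, ])), 0)
  withz <- summarize_pairs(pairs[0, ], organs = "liver")
  expect_equal(withz$total, 0)
})

test_that("paired-PCG exports write one unique id per line per organ", {
  pairs <- data.frame(
    organ = c("liver", "liver", "liver", "colon"),
    lncrna_gene_id = c("L1", "L2", "L3", "L1"),
    pcg_gene_id = c("P1", "P1", "P1", "P2"),
    category = "both_up", stringsAsFactors = FALSE)
  dir <- withr::local_tempdir()
  paths <- export_paired_pcgs(pairs, dir)
  expect_setequal(basename(paths),
                  c("liver_paired_pcgs.txt", "colon_paired_pcgs.txt"))
  expect_equal(readLines(file.path(dir, "liver_paired_pcgs.txt")), "P1")
  # empty pairs with declared organs -> empty files
  paths2 <- export_paired_pcgs(pairs[0, ], dir, organs = "muscle")
  expect_equal(length(readLines(paths2[["muscle"]])), 0)
})

test_that("pairing configs reject non-positive parameters", {
  expect_error(pairing_config(upstream_window = 0), "positive")
  expect_error(pairing_config(fdr_alpha = -0.05), "positive")
})
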