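test_that("sim_config validates proportions and counts", {
  cfg <- sim_config()
  expect_equal(sum(cfg$region_class_proportions), 1, tolerance = 1e-12)
  expect_setequal(names(cfg$region_class_proportions), region_classes())
  bad <- setNames(rep(1, 7), region_classes())
  expect_error(sim_config(region_class_proportions = bad), "sum to 1")
  expect_error(sim_config(n_pcg = 0), "positive")
})

test_that("generators are deterministic given the seed", {
  cfg <- sim_config(seed = 4, n_pcg = 20L, n_lnc = 15L,
                    n_chromosomes = 1L, chrom_length = 8e5,
                    organs = c("liver", "colon"))
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_gtf(g1$lnc_records, p1)
  write_gtf(g2$lnc_records, p2)
  expect_identical(readLines(p1), readLines(p2))
  e1 <- generate_expression(cfg, g1)
  e2 <- generate_expression(cfg, g2)
  expect_identical(e1$table$values, e2$table$values)
  s1 <- generate_sequences(cfg, g1, e1$truth)
  s2 <- generate_sequences(cfg, g2, e2$truth)
  expect_identical(s1$lnc_seqs, s2$lnc_seqs)
  # a different seed changes the data
  g3 <- generate_genome(sim_config(seed = 5, n_pcg = 20L, n_lnc = 15L,
                                   n_chromosomes = 1L, chrom_length = 8e5))
  expect_false(identical(g1$lnc_records, g3$lnc_records))
})

test_that("every planted region class is recovered by classification", {
  g <- generate_genome(sim_config(seed = 1))
  ann <- annotate_regions(g$lnc_models, g$pcg_index)
  m <- match(g$truth$lnc_id, ann$lncrna_gene_id)
  expect_identical(ann$region[m], g$truth$planted_class)
  hosted <- !is.na(g$truth$host_pcg)
  expect_identical(ann$assigned_pcg_id[m][hosted],
                   g$truth$host_pcg[hosted])
})

test_that("an all-intergenic cohort stays clear of every proximity window", {
  props <- setNames(c(0, 1, 0, 0, 0, 0, 0),
                    c("intronic", "intergenic", "three_prime_utr", "exonic",
                      "upstream", "downstream", "five_prime_utr"))
  g <- generate_genome(sim_config(seed = 2, n_lnc = 40L,
                                  region_class_proportions = props))
  for (m in g$lnc_models) {
    hits <- index_query(g$pcg_index, m$chrom, m$start, m$end,
                        upstream = 5000, downstream = 1000)
    expect_length(hits, 0)
  }
})

test_that("planted expression effects drive recoverable pairs", {
  cfg <- sim_config(seed = 11, n_pcg = 60L, n_lnc = 90L,
                    n_chromosomes = 1L, chrom_length = 1.6e6,
                    organs = c("liver", "colon"))
  g <- generate_genome(cfg)
  ex <- generate_expression(cfg, g)
  planted <- ex$truth$planted_pairs
  expect_gt(nrow(planted), 0)
  # planted members clear the expression filter in their organ
  for (org in unique(planted$organ)) {
    flags <- rbind(
      call_expressed(subset_genes(ex$table, names(g$lnc_models)), org),
      call_expressed(subset_genes(ex$table, names(g$pcg_models)), org))
    members <- unique(c(planted$lnc_id[planted$organ == org],
                        planted$pcg_id[planted$organ == org]))
    expect_true(all(flags$expressed[flags$gene_id %in% members]))
  }
  # concordant pairs dominate; categories match the planted deltas
  expect_identical(planted$category,
                   lncpair:::.pair_category(
                     ifelse(planted$lnc_delta > 0, "up_in_gf", "down_in_gf"),
                     ifelse(planted$pcg_delta > 0, "up_in_gf",
                            "down_in_gf")))
  # a specific planted pair is recovered with the right category
  rec <- evaluate_planted_recovery(list(config = cfg, genome = g,
                                        expression = ex,
                                        sequences = generate_sequences(
                                          cfg, g, ex$truth)),
                                   n_nonbinders = 5)
  called_keys <- paste(rec$pairs$organ, rec$pairs$lncrna_gene_id,
                       rec$pairs$pcg_gene_id)
  hit <- match(paste(planted$organ, planted$lnc_id, planted$pcg_id),
               called_keys)
  recovered <- !is.na(hit)
  expect_gt(mean(recovered), 0.9)
  expect_identical(rec$pairs$category[hit[recovered]],
                   planted$category[recovered])
})

test_that("planted binder windows guarantee strong bound duplexes", {
  cfg <- sim_config(seed = 21, n_pcg = 30L, n_lnc = 40L,
                    n_chromosomes = 1L, chrom_length = 9e5, n_binders = 6L)
  g <- generate_genome(cfg)
  sq <- generate_sequences(cfg, g)
  expect_equal(nrow(sq$binders), 6)
  scores <- score_interactions(sq$binders, sq$lnc_seqs, sq$mrna_seqs)
  expect_true(all(scores$dG <= -100))
  expect_true(all(scores$bound))
})

test_that("null generation leaves the differential test uncalibrated by
           no planted structure", {
  tab <- generate_null_expression(n_genes = 800, seed = 3)
  d <- fallback_de_test(tab, "null")
  calls <- call_differential(d, call_expressed(tab, "null"))
  # essentially nothing passes FDR on pure null data
  expect_lte(sum(calls$differentially_regulated), 8)
})
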