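# Download-free synthetic inputs with the statistical structure the
# analysis assumes: a two-reference genome (coding genes with exon/CDS/UTR
# structure; single-exon lncRNAs placed so that region classification
# recovers a planted class for every lncRNA), FPKM tables with log-normal
# noise and planted differential effects on neighbor pairs (including a
# small discordant fraction), and transcript sequences with planted
# reverse-complement windows for the interaction screen. Every generator is
# a pure function of the config: generate_genome() seeds the RNG stream
# with `seed`, generate_expression() with `seed + 1`, generate_sequences()
# with `seed + 2`, so inserting draws into one generator never perturbs the
# others.

#' Simulation configuration
#'
#' Defaults emulate the study design: 8 organs with n = 3 replicates per
#' enterotype, and lncRNA region-class proportions matching the aggregate
#' genomic-annotation distribution (intronic 35.4%, intergenic 24.4%,
#' 3'UTR 16.0%, exonic 10.3%, upstream 6.8%, downstream 6.1%, 5'UTR 1.1%;
#' normalized to sum to one). Replicate noise `sigma_rep` is the standard
#' deviation of the per-replicate log2-FPKM, the same scale as the planted
#' effects.
#'
#' @param seed integer RNG seed.
#' @param n_chromosomes,chrom_length genome shape (default 2 x 2 Mb).
#' @param n_pcg,n_lnc gene counts (defaults 200 coding, 300 lncRNA).
#' @param region_class_proportions named 7-vector over [region_classes()].
#' @param organs organ labels (default the study's eight tissues).
#' @param replicates replicates per enterotype per organ (default 3).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline FPKM for
#'   expressed genes.
#' @param low_meanlog,low_sdlog log-normal baseline for the low-expression
#'   gene fraction.
#' @param frac_low fraction of genes drawn below the expression threshold.
#' @param sigma_rep replicate noise sd on the log2 scale (default 0.2).
#' @param frac_pairs_de fraction of eligible neighbor pairs planted as
#'   differentially regulated per organ (default 0.15).
#' @param lfc_range range of planted |log2 fold change| (default c(1, 3)).
#' @param discordant_frac fraction of planted pairs with opposite-sign
#'   members (default 0.01).
#' @param min_expressed_baseline lower bound enforced on planted pair
#'   members' baseline FPKM so planted pairs pass the expression filter by
#'   construction.
#' @param n_binders number of planted binder transcript pairs.
#' @param window_length minimum planted complementary window (nt). The
#'   planted window grows with the shorter transcript
#'   (`max(window_length, ceil(0.06 * min_len))`) so that every planted
#'   binder exceeds the ndG threshold by construction.
#' @param lnc_length range of lncRNA locus lengths (bases).
#' @param intergenic_max_length cap on intergenic lncRNA locus length so the
#'   locus fits between neighboring proximity windows.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L, chrom_length = 2e6,
                       n_pcg = 200L, n_lnc = 300L,
                       region_class_proportions = NULL,
                       organs = c("liver", "duodenum", "jejunum", "ileum",
                                  "colon", "BAT", "WAT", "muscle"),
                       replicates = 3L,
                       baseline_meanlog = 1, baseline_sdlog = 1,
                       low_meanlog = -2, low_sdlog = 0.5,
                       frac_low = 0.2, sigma_rep = 0.2,
                       frac_pairs_de = 0.15, lfc_range = c(1, 3),
                       discordant_frac = 0.01,
                       min_expressed_baseline = 1.5,
                       n_binders = 10L, window_length = 50L,
                       lnc_length = c(200L, 2000L),
                       intergenic_max_length = 1000L) {
  if (is.null(region_class_proportions)) {
    p <- c(intronic = 0.354, intergenic = 0.244, three_prime_utr = 0.160,
           exonic = 0.103, upstream = 0.068, downstream = 0.061,
           five_prime_utr = 0.011)
    region_class_proportions <- p / sum(p)
  }
  if (!setequal(names(region_class_proportions), region_classes())) {
    stop("region_class_proportions must name all seven region classes")
  }
  if (abs(sum(region_class_proportions) - 1) > 1e-9) {
    stop("region_class_proportions must sum to 1")
  }
  counts <- c(n_chromosomes, chrom_length, n_pcg, n_lnc, replicates)
  if (any(counts <= 0)) stop("all counts must be positive")
  structure(as.list(environment()), class = "sim_config")
}

# integer uniform draw in [lo, hi]
.pick_in <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (hi < lo) stop("empty placement range")
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

.sim_organs <- function(cfg) cfg$organs

# --- genome -----------------------------------------------------------------

.place_pcgs <- function(cfg) {
  margin <- 6000L
  per_chrom <- rep(cfg$n_pcg %/% cfg$n_chromosomes, cfg$n_chromosomes)
  extra <- cfg$n_pcg %% cfg$n_chromosomes
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  rows <- list()
  gid <- 0L
  for (ci in seq_len(cfg$n_chromosomes)) {
    chrom <- paste0("chr", ci)
    pos <- margin
    for (g in seq_len(per_chrom[ci])) {
      gid <- gid + 1L
      gene_id <- sprintf("PCG%04d", gid)
      tx_id <- paste0(gene_id, ".1")
      n_ex <- .pick_in(2L, 10L)
      ex_len <- 100L + sample.int(201L, n_ex, replace = TRUE) - 1L
      in_len <- if (n_ex > 1) {
        200L + sample.int(1301L, n_ex - 1L, replace = TRUE) - 1L
      } else integer()
      gap <- .pick_in(12000L, 14000L)
      start0 <- pos + gap # 0-based gene start
      ex_s <- start0 + cumsum(c(0L, head(ex_len, -1) + in_len))
      ex_e <- ex_s + ex_len
      end0 <- ex_e[n_ex]
      if (end0 > cfg$chrom_length - margin) {
        stop("synthetic genome too dense on ", chrom,
             "; increase chrom_length or reduce n_pcg")
      }
      strand <- sample(c("+", "-"), 1L)
      u5 <- .pick_in(30L, 60L); u3 <- .pick_in(30L, 60L)
      # CDS extent in genomic coordinates (UTRs at the strand-aware ends)
      cds_lo <- start0 + (if (strand == "+") u5 else u3)
      cds_hi <- end0 - (if (strand == "+") u3 else u5)
      cds_s <- pmax(ex_s, cds_lo); cds_e <- pmin(ex_e, cds_hi)
      keep <- cds_s < cds_e
      one <- function(feature, s0, e0) {
        data.frame(chrom = chrom, source = "lncpair_sim", feature = feature,
                   start = as.integer(s0) + 1L, end = as.integer(e0),
                   strand = strand,
                   gene_id = gene_id, transcript_id = tx_id,
                   stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- rbind(
        one("transcript", start0, end0),
        do.call(rbind, Map(one, "exon", ex_s, ex_e)),
        do.call(rbind, Map(one, "CDS", cds_s[keep], cds_e[keep])))
      pos <- end0
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dialect") <- "pcg"
  out
}

# free intervals between window-extended gene spans, per chromosome
.intergenic_free <- function(pcg_models, cfg, pad = 5100) {
  tab <- build_gene_index(pcg_models)$table
  free <- list()
  for (chrom in unique(tab$chrom)) {
    sub <- tab[tab$chrom == chrom, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    gaps_lo <- c(500, sub$end + pad)
    gaps_hi <- c(sub$start - pad, cfg$chrom_length - 500)
    keep <- gaps_hi - gaps_lo > 2 * pad / 5 # require some usable width
    if (any(keep)) {
      free[[length(free) + 1L]] <- data.frame(
        chrom = chrom, lo = gaps_lo[keep], hi = gaps_hi[keep],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, free)
}

# propose an anchor for one planted class relative to a host model
.propose_anchor <- function(class, model) {
  pick_interval_pos <- function(iv) {
    if (nrow(iv) == 0) return(NA_integer_)
    r <- sample.int(nrow(iv), 1L)
    .pick_in(iv[r, 1], iv[r, 2] - 1L)
  }
  switch(class,
    intronic = pick_interval_pos(model$introns),
    exonic = pick_interval_pos(model$cds),
    five_prime_utr = pick_interval_pos(model$utr5),
    three_prime_utr = pick_interval_pos(model$utr3),
    upstream = if (model$strand == "+") {
      .pick_in(model$start - 4900L, model$start - 100L)
    } else {
      .pick_in(model$end + 100L, model$end + 4899L)
    },
    downstream = if (model$strand == "+") {
      .pick_in(model$end + 100L, model$end + 899L)
    } else {
      .pick_in(model$start - 900L, model$start - 100L)
    })
}

#' Generate a synthetic two-reference genome with planted lncRNA classes
#'
#' Places non-overlapping coding genes (2-10 exons with CDS-derived UTRs,
#' random strands, inter-gene gaps wide enough that proximity windows never
#' overlap) and then places each lncRNA so that [classify_region()] with
#' default settings returns its planted class and assigns its planted host
#' gene. Intergenic lncRNAs are kept entirely outside every proximity
#' window. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return List with `pcg_records`, `lnc_records` (GTF record tables),
#'   `pcg_models`, `lnc_models`, `pcg_index`, and `truth` (data.frame:
#'   `lnc_id`, `planted_class`, `host_pcg`, `anchor`).
#' @export
generate_genome <- function(cfg) {
  set.seed(cfg$seed)
  pcg_records <- .place_pcgs(cfg)
  pcg_models <- build_gene_models(pcg_records)
  index <- build_gene_index(pcg_models)
  free <- .intergenic_free(pcg_models, cfg)
  classes <- sample(names(cfg$region_class_proportions), cfg$n_lnc,
                    replace = TRUE, prob = cfg$region_class_proportions)
  hosts <- names(pcg_models)
  lnc_rows <- list(); truth_rows <- list()
  for (i in seq_len(cfg$n_lnc)) {
    cls <- classes[i]
    lnc_id <- sprintf("LNC%04d", i)
    placed <- FALSE
    for (try in seq_len(60L)) {
      if (cls == "intergenic") {
        len <- .pick_in(cfg$lnc_length[1], cfg$intergenic_max_length)
        ok_rows <- which(free$hi - free$lo >= len + 400)
        if (length(ok_rows) == 0) break
        r <- ok_rows[sample.int(length(ok_rows), 1L)]
        anchor <- .pick_in(free$lo[r] + len %/% 2 + 100,
                           free$hi[r] - len %/% 2 - 100)
        chrom <- free$chrom[r]
        host <- NA_character_
      } else {
        host <- hosts[sample.int(length(hosts), 1L)]
        model <- pcg_models[[host]]
        anchor <- .propose_anchor(cls, model)
        if (is.na(anchor)) next
        chrom <- model$chrom
        len <- .pick_in(cfg$lnc_length[1], cfg$lnc_length[2])
      }
      s0 <- anchor - len %/% 2L
      e0 <- s0 + len
      if (s0 < 0) next
      strand <- sample(c("+", "-"), 1L)
      cand <- index_query(index, chrom, s0, e0,
                          upstream = 5000, downstream = 1000)
      if (cls == "intergenic" && length(cand) > 0) next
      if (cls != "intergenic" && !identical(cand, host)) next
      ann <- classify_region(list(chrom = chrom, start = s0, end = e0,
                                  strand = strand), index, lnc_id = lnc_id)
      if (ann$region != cls) next
      if (cls != "intergenic" && !identical(ann$assigned_pcg_id, host)) next
      tx_id <- paste0(lnc_id, ".1")
      lnc_rows[[length(lnc_rows) + 1L]] <- data.frame(
        chrom = chrom, source = "lncpair_sim",
        feature = c("transcript", "exon"),
        start = s0 + 1L, end = e0, strand = strand,
        gene_id = lnc_id, transcript_id = tx_id, stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        lnc_id = lnc_id, planted_class = cls, host_pcg = host,
        anchor = anchor, stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place lncRNA ", lnc_id, " with class ", cls,
           " after bounded retries; increase chrom_length")
    }
  }
  lnc_records <- do.call(rbind, lnc_rows)
  rownames(lnc_records) <- NULL
  attr(lnc_records, "dialect") <- "lncrna"
  list(pcg_records = pcg_records, lnc_records = lnc_records,
       pcg_models = pcg_models, lnc_models = build_gene_models(lnc_records),
       pcg_index = index,
       truth = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))))
}

# --- expression -------------------------------------------------------------

.draw_baseline <- function(n, cfg, low) {
  ifelse(low,
         rlnorm(n, cfg$low_meanlog, cfg$low_sdlog),
         rlnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog))
}

#' Generate an FPKM table with planted differential neighbor pairs
#'
#' For each organ a fraction of eligible lncRNA-host pairs (both members
#' drawn from the expressed baseline pool) is planted as differentially
#' regulated: both members receive a log2 effect of magnitude
#' `Uniform(lfc_range)` with a common sign (opposite signs for the
#' discordant fraction), applied to the GF samples. FPKM values are
#' `baseline * 2^(delta * [GF]) * 2^N(0, sigma_rep)`. Planted members'
#' baselines are floored at `min_expressed_baseline` so planted pairs pass
#' the expression filter by construction. Deterministic given
#' `cfg$seed + 1`.
#'
#' @param cfg a [sim_config()].
#' @param genome output of [generate_genome()].
#' @return List with `table` (an [expression_table()] over all organs),
#'   and `truth`: `planted_pairs` (organ, lnc_id, pcg_id, lnc_delta,
#'   pcg_delta, category), `delta` (gene x organ matrix of planted log2
#'   effects), `low_genes`, `neighbor_pairs`.
#' @export
generate_expression <- function(cfg, genome) {
  set.seed(cfg$seed + 1L)
  genes <- c(names(genome$pcg_models), names(genome$lnc_models))
  organs <- .sim_organs(cfg)
  low_genes <- sample(genes, round(cfg$frac_low * length(genes)))
  neighbor <- genome$truth[!is.na(genome$truth$host_pcg),
                           c("lnc_id", "host_pcg")]
  eligible <- neighbor[!(neighbor$lnc_id %in% low_genes) &
                         !(neighbor$host_pcg %in% low_genes), , drop = FALSE]
  delta <- matrix(0, nrow = length(genes), ncol = length(organs),
                  dimnames = list(genes, organs))
  planted <- list()
  for (org in organs) {
    n_plant <- round(cfg$frac_pairs_de * nrow(eligible))
    if (n_plant == 0) next
    sel <- eligible[sample.int(nrow(eligible), n_plant), , drop = FALSE]
    for (i in seq_len(nrow(sel))) {
      pcg <- sel$host_pcg[i]; lnc <- sel$lnc_id[i]
      if (delta[pcg, org] == 0) {
        delta[pcg, org] <- sample(c(-1, 1), 1L) *
          runif(1, cfg$lfc_range[1], cfg$lfc_range[2])
      }
      sgn <- sign(delta[pcg, org])
      discordant <- runif(1) < cfg$discordant_frac
      if (delta[lnc, org] == 0) {
        delta[lnc, org] <- (if (discordant) -sgn else sgn) *
          runif(1, cfg$lfc_range[1], cfg$lfc_range[2])
      }
      planted[[length(planted) + 1L]] <- data.frame(
        organ = org, lnc_id = lnc, pcg_id = pcg,
        lnc_delta = delta[lnc, org], pcg_delta = delta[pcg, org],
        category = .pair_category(
          ifelse(delta[lnc, org] > 0, "up_in_gf", "down_in_gf"),
          ifelse(delta[pcg, org] > 0, "up_in_gf", "down_in_gf")),
        stringsAsFactors = FALSE)
    }
  }
  planted <- if (length(planted)) {
    do.call(rbind, c(planted, list(make.row.names = FALSE)))
  } else {
    data.frame(organ = character(), lnc_id = character(),
               pcg_id = character(), lnc_delta = numeric(),
               pcg_delta = numeric(), category = character(),
               stringsAsFactors = FALSE)
  }
  baseline <- matrix(.draw_baseline(length(genes) * length(organs), cfg,
                                    rep(genes %in% low_genes,
                                        times = length(organs))),
                     nrow = length(genes), ncol = length(organs),
                     dimnames = list(genes, organs))
  # planted members must clear the expression filter in their organ
  for (i in seq_len(nrow(planted))) {
    for (g in c(planted$lnc_id[i], planted$pcg_id[i])) {
      if (baseline[g, planted$organ[i]] < cfg$min_expressed_baseline) {
        baseline[g, planted$organ[i]] <- cfg$min_expressed_baseline +
          rlnorm(1, 0, 0.5)
      }
    }
  }
  n_rep <- cfg$replicates
  cols <- list(); design_rows <- list()
  for (org in organs) {
    for (ent in c("CV", "GF")) {
      for (r in seq_len(n_rep)) {
        sid <- paste(org, ent, r, sep = "_")
        eff <- if (ent == "GF") delta[, org] else 0
        cols[[sid]] <- baseline[, org] * 2^eff *
          2^rnorm(length(genes), 0, cfg$sigma_rep)
        design_rows[[sid]] <- data.frame(
          sample_id = sid, organ = org, enterotype = ent, replicate = r,
          stringsAsFactors = FALSE)
      }
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- genes
  table <- expression_table(values, do.call(rbind, design_rows))
  list(table = table,
       truth = list(planted_pairs = planted, delta = delta,
                    low_genes = low_genes, neighbor_pairs = neighbor))
}

#' Generate a null expression table (no planted effects)
#'
#' One organ, `replicates` samples per enterotype, log-normal baselines and
#' replicate noise as in [generate_expression()], zero effects everywhere.
#' Used for type-I error calibration of the differential test.
#'
#' @param n_genes number of genes.
#' @param seed RNG seed.
#' @param replicates replicates per enterotype.
#' @param baseline_meanlog,baseline_sdlog,sigma_rep as in [sim_config()].
#' @return An [expression_table()] for organ `"null"`.
#' @export
generate_null_expression <- function(n_genes = 5000, seed = 1L,
                                     replicates = 3L, baseline_meanlog = 1,
                                     baseline_sdlog = 1, sigma_rep = 0.2) {
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  baseline <- rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
  design <- expand.grid(replicate = seq_len(replicates),
                        enterotype = c("CV", "GF"), stringsAsFactors = FALSE)
  design$organ <- "null"
  design$sample_id <- paste("null", design$enterotype, design$replicate,
                            sep = "_")
  values <- vapply(seq_len(nrow(design)), function(j) {
    baseline * 2^rnorm(n_genes, 0, sigma_rep)
  }, numeric(n_genes))
  colnames(values) <- design$sample_id
  rownames(values) <- genes
  expression_table(values, design[, c("sample_id", "organ", "enterotype",
                                      "replicate")])
}

# --- sequences --------------------------------------------------------------

.random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

.revcomp_rna <- function(seq) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Generate transcript sequences with planted complementary windows
#'
#' Every gene gets one random-composition transcript (lengths uniform in
#' 500-3000 nt). For each planted binder pair a reverse-complement window
#' copied from the mRNA is inserted into the lncRNA at a random position;
#' the window length is `max(window_length, ceil(0.06 * min(lengths)))`,
#' which guarantees `ndG < -0.08` under the default energies (every planted
#' pair contributes at most -2 kcal/mol). Deterministic given
#' `cfg$seed + 2`.
#'
#' @param cfg a [sim_config()].
#' @param genome output of [generate_genome()].
#' @param expression_truth optional `truth` element of
#'   [generate_expression()]; planted binders are then drawn from planted
#'   differential pairs first.
#' @return List with `lnc_seqs`, `mrna_seqs` (named by transcript id,
#'   `<gene>.1`) and `binders` (data.frame `lnc_tx`, `pcg_tx`, `window`).
#' @export
generate_sequences <- function(cfg, genome, expression_truth = NULL) {
  set.seed(cfg$seed + 2L)
  lnc_tx <- paste0(names(genome$lnc_models), ".1")
  pcg_tx <- paste0(names(genome$pcg_models), ".1")
  lens_l <- 500L + sample.int(2501L, length(lnc_tx), replace = TRUE) - 1L
  lens_p <- 500L + sample.int(2501L, length(pcg_tx), replace = TRUE) - 1L
  lnc_seqs <- setNames(vapply(lens_l, .random_rna, ""), lnc_tx)
  mrna_seqs <- setNames(vapply(lens_p, .random_rna, ""), pcg_tx)
  pool <- genome$truth[!is.na(genome$truth$host_pcg),
                       c("lnc_id", "host_pcg")]
  if (!is.null(expression_truth) &&
      nrow(expression_truth$planted_pairs) > 0) {
    pp <- unique(expression_truth$planted_pairs[, c("lnc_id", "pcg_id")])
    names(pp) <- c("lnc_id", "host_pcg")
    pool <- rbind(pp, pool[!(pool$lnc_id %in% pp$lnc_id), , drop = FALSE])
  }
  pool <- unique(pool)
  n_bind <- min(cfg$n_binders, nrow(pool))
  binders <- pool[seq_len(n_bind), , drop = FALSE]
  rows <- list()
  for (i in seq_len(n_bind)) {
    lt <- paste0(binders$lnc_id[i], ".1")
    pt <- paste0(binders$host_pcg[i], ".1")
    lmin <- min(nchar(lnc_seqs[[lt]]), nchar(mrna_seqs[[pt]]))
    if (cfg$window_length > lmin) {
      stop("planted window longer than transcript ", lt, "/", pt)
    }
    w <- max(cfg$window_length, as.integer(ceiling(0.06 * lmin)))
    a <- .pick_in(1L, nchar(lnc_seqs[[lt]]) - w + 1L)
    b <- .pick_in(1L, nchar(mrna_seqs[[pt]]) - w + 1L)
    window <- substr(mrna_seqs[[pt]], b, b + w - 1L)
    substr(lnc_seqs[[lt]], a, a + w - 1L) <- .revcomp_rna(window)
    rows[[i]] <- data.frame(lnc_tx = lt, pcg_tx = pt, window = w,
                            stringsAsFactors = FALSE)
  }
  list(lnc_seqs = lnc_seqs, mrna_seqs = mrna_seqs,
       binders = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper running [generate_genome()],
#' [generate_expression()] and [generate_sequences()].
#'
#' @param cfg a [sim_config()].
#' @return List with elements `config`, `genome`, `expression`,
#'   `sequences`.
#' @export
generate_cohort <- function(cfg = sim_config()) {
  genome <- generate_genome(cfg)
  expr <- generate_expression(cfg, genome)
  seqs <- generate_sequences(cfg, genome, expr$truth)
  list(config = cfg, genome = genome, expression = expr, sequences = seqs)
}

#' Evaluate planted-truth recovery on a synthetic cohort
#'
#' Runs the full analysis on a generated cohort — per-organ differential
#' tests (separately for the lncRNA and PCG classes), pair calling — and
#' compares the called pair set with the planted pair set; then scores the
#' planted binder transcript pairs and a deterministic sample of non-binder
#' pairs with [compute_ndg()].
#'
#' @param cohort output of [generate_cohort()].
#' @param n_nonbinders number of non-binder pairs to score.
#' @param cfg_pairs a [pairing_config()].
#' @param params an [energy_params()].
#' @return List with `sensitivity`, `precision`, `n_planted`, `n_called`,
#'   `pairs` (the called pair records), `binder_bound_fraction`,
#'   `nonbinder_bound_fraction`, `n_binders`, `n_nonbinders`.
#' @export
evaluate_planted_recovery <- function(cohort, n_nonbinders = 40,
                                      cfg_pairs = pairing_config(),
                                      params = energy_params()) {
  genome <- cohort$genome
  table <- cohort$expression$table
  lnc_ids <- names(genome$lnc_models)
  pcg_ids <- names(genome$pcg_models)
  lnc_tab <- subset_genes(table, lnc_ids)
  pcg_tab <- subset_genes(table, pcg_ids)
  organs <- unique(table$design$organ)
  calls <- function(tab, org) {
    diff <- fallback_de_test(tab, org, threshold = cfg_pairs$fpkm_threshold)
    expr <- call_expressed(tab, org, threshold = cfg_pairs$fpkm_threshold)
    call_differential(diff, expr, alpha = cfg_pairs$fdr_alpha)
  }
  lnc_calls <- do.call(rbind, lapply(organs, function(o) calls(lnc_tab, o)))
  pcg_calls <- do.call(rbind, lapply(organs, function(o) calls(pcg_tab, o)))
  pairs <- call_pairs(lnc_calls, pcg_calls, genome$lnc_models,
                      genome$pcg_index, cfg_pairs)
  planted <- cohort$expression$truth$planted_pairs
  key <- function(org, l, p) paste(org, l, p, sep = "\r")
  called_keys <- key(pairs$organ, pairs$lncrna_gene_id, pairs$pcg_gene_id)
  planted_keys <- key(planted$organ, planted$lnc_id, planted$pcg_id)
  tp <- length(intersect(called_keys, planted_keys))
  sens <- if (length(planted_keys)) tp / length(planted_keys) else NA_real_
  prec <- if (length(called_keys)) tp / length(called_keys) else NA_real_

  seqs <- cohort$sequences
  bound_b <- score_interactions(seqs$binders, seqs$lnc_seqs, seqs$mrna_seqs,
                                params)
  # deterministic non-binder sample: first lnc x pcg combinations not
  # planted as binders
  binder_key <- paste(seqs$binders$lnc_tx, seqs$binders$pcg_tx)
  grid <- expand.grid(lnc_tx = names(seqs$lnc_seqs),
                      pcg_tx = names(seqs$mrna_seqs),
                      stringsAsFactors = FALSE)
  grid <- grid[!(paste(grid$lnc_tx, grid$pcg_tx) %in% binder_key), ]
  grid <- grid[seq_len(min(n_nonbinders, nrow(grid))), , drop = FALSE]
  bound_n <- score_interactions(grid, seqs$lnc_seqs, seqs$mrna_seqs, params)
  list(sensitivity = sens, precision = prec,
       n_planted = length(planted_keys), n_called = length(called_keys),
       pairs = pairs,
       lnc_calls = lnc_calls, pcg_calls = pcg_calls,
       binder_bound_fraction = mean(bound_b$bound),
       nonbinder_bound_fraction = mean(bound_n$bound),
       n_binders = nrow(bound_b), n_nonbinders = nrow(bound_n))
}
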