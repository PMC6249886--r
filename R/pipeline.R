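# End-to-end orchestration: simulate (or load) -> differential calls ->
# region annotation -> pair calling -> tissue overlaps -> interaction
# screen -> consolidated text report. Every stage error aborts with the
# stage name; all thresholds are surfaced in the config.

#' Pipeline configuration
#'
#' Either a simulation config (`sim`) or paths to real inputs (`inputs`:
#' named list with `pcg_gtf`, `lnc_gtf`, `expression`, `design`) must be
#' provided, never both.
#'
#' @param out_dir output directory.
#' @param sim a [sim_config()], or NULL when real inputs are given.
#' @param inputs named list of input paths, or NULL when simulating.
#' @param pairing a [pairing_config()].
#' @param energy an [energy_params()].
#' @param organ_groups named list of tissue groups for the overlap stage;
#'   defaults to the enterohepatic (liver + intestine) and peripheral
#'   (fat + muscle) groupings when the organs allow it.
#' @param max_interactions cap on the number of unique called pairs scored
#'   by the interaction screen.
#' @param verbose log per-stage counts to the console?
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, sim = sim_config(), inputs = NULL,
                            pairing = pairing_config(),
                            energy = energy_params(),
                            organ_groups = NULL, max_interactions = 200L,
                            verbose = FALSE) {
  if (is.null(sim) == is.null(inputs)) {
    stop("provide exactly one of sim= or inputs=")
  }
  structure(list(out_dir = out_dir, sim = sim, inputs = inputs,
                 pairing = pairing, energy = energy,
                 organ_groups = organ_groups,
                 max_interactions = as.integer(max_interactions),
                 verbose = verbose), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys: `out_dir`, `sim` (a mapping of [sim_config()]
#' arguments), `inputs`, `pairing`, `energy` (mappings of the respective
#' constructor arguments), `organ_groups`, `max_interactions`, `verbose`.
#' Unknown keys are an error, so typos never silently fall back to
#' defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("out_dir", "sim", "inputs", "pairing", "energy",
             "organ_groups", "max_interactions", "verbose")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(y$out_dir)) stop("pipeline config requires out_dir")
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else NULL
  pairing <- if (!is.null(y$pairing)) {
    do.call(pairing_config, y$pairing)
  } else {
    pairing_config()
  }
  energy <- if (!is.null(y$energy)) {
    pe <- unlist(y$energy$pair_energies)
    args <- y$energy
    if (!is.null(pe)) args$pair_energies <- pe
    do.call(energy_params, args)
  } else {
    energy_params()
  }
  pipeline_config(out_dir = y$out_dir, sim = sim, inputs = y$inputs,
                  pairing = pairing, energy = energy,
                  organ_groups = y$organ_groups,
                  max_interactions = y$max_interactions %||% 200L,
                  verbose = isTRUE(y$verbose))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(name, verbose, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

.default_groups <- function(organs) {
  entero <- intersect(c("liver", "duodenum", "jejunum", "ileum", "colon"),
                      organs)
  periph <- intersect(c("BAT", "WAT", "muscle"), organs)
  groups <- list()
  if (length(entero) >= 2) groups$enterohepatic <- entero
  if (length(periph) >= 2) groups$peripheral <- periph
  if (length(groups) == 0 && length(organs) >= 2) groups$all <- organs
  groups
}

#' Run the full analysis pipeline
#'
#' Emits, under `cfg$out_dir`: per-organ differential call TSVs for both
#' gene classes, region annotation and class-distribution TSVs, pair
#' records with per-organ direction summaries, a BED export and per-organ
#' paired-PCG gene lists, overlap signature counts per tissue group, an
#' interaction TSV over the called pairs, and `report.txt` with the
#' filter-step attrition counts. Outputs are reproducible from
#' (inputs, config, seed).
#'
#' @param cfg a [pipeline_config()] or path to a YAML config.
#' @return Invisibly, a list with the main in-memory results
#'   (`lnc_calls`, `pcg_calls`, `annotations`, `distribution`, `pairs`,
#'   `summary`, `overlaps`, `interactions`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) if (isTRUE(cfg$verbose)) message(...)

  if (!is.null(cfg$sim)) {
    cohort <- .stage("simulate", cfg$verbose, {
      co <- generate_cohort(cfg$sim)
      idir <- file.path(cfg$out_dir, "inputs")
      dir.create(idir, showWarnings = FALSE)
      write_gtf(co$genome$pcg_records, file.path(idir, "pcg.gtf"))
      write_gtf(co$genome$lnc_records, file.path(idir, "lnc.gtf"))
      write_expression(co$expression$table, file.path(idir, "fpkm.tsv"),
                       file.path(idir, "design.tsv"))
      write_fasta(co$sequences$lnc_seqs, file.path(idir, "lnc_tx.fa"))
      write_fasta(co$sequences$mrna_seqs, file.path(idir, "mrna_tx.fa"))
      write_result_tsv(co$genome$truth, file.path(idir, "truth_regions.tsv"))
      write_result_tsv(co$expression$truth$planted_pairs,
                       file.path(idir, "truth_pairs.tsv"))
      co
    })
    inputs <- list(pcg_gtf = file.path(cfg$out_dir, "inputs", "pcg.gtf"),
                   lnc_gtf = file.path(cfg$out_dir, "inputs", "lnc.gtf"),
                   expression = file.path(cfg$out_dir, "inputs", "fpkm.tsv"),
                   design = file.path(cfg$out_dir, "inputs", "design.tsv"),
                   lnc_fasta = file.path(cfg$out_dir, "inputs", "lnc_tx.fa"),
                   mrna_fasta = file.path(cfg$out_dir, "inputs",
                                          "mrna_tx.fa"))
  } else {
    inputs <- cfg$inputs
  }

  models <- .stage("gene_models", cfg$verbose, {
    pcg_rec <- read_gtf(inputs$pcg_gtf, "pcg")
    lnc_rec <- read_gtf(inputs$lnc_gtf, "lncrna")
    pcg_models <- build_gene_models(pcg_rec)
    lnc_models <- build_gene_models(lnc_rec)
    list(pcg = pcg_models, lnc = lnc_models,
         index = build_gene_index(pcg_models))
  })
  log("gene_models: ", length(models$pcg), " PCGs, ",
      length(models$lnc), " lncRNAs")

  expr <- .stage("expression", cfg$verbose, {
    read_expression(inputs$expression, inputs$design)
  })
  organs <- unique(expr$design$organ)

  de <- .stage("differential", cfg$verbose, {
    lnc_tab <- subset_genes(expr, names(models$lnc))
    pcg_tab <- subset_genes(expr, names(models$pcg))
    one_class <- function(tab, label) {
      out <- lapply(organs, function(org) {
        diff <- fallback_de_test(tab, org,
                                 threshold = cfg$pairing$fpkm_threshold)
        flags <- call_expressed(tab, org,
                                threshold = cfg$pairing$fpkm_threshold)
        calls <- call_differential(diff, flags,
                                   alpha = cfg$pairing$fdr_alpha)
        write_result_tsv(calls,
                         file.path(cfg$out_dir,
                                   sprintf("de_%s_%s.tsv", label, org)),
                         params = c(alpha = cfg$pairing$fdr_alpha,
                                    fpkm = cfg$pairing$fpkm_threshold))
        calls
      })
      do.call(rbind, out)
    }
    list(lnc = one_class(lnc_tab, "lnc"), pcg = one_class(pcg_tab, "pcg"))
  })
  log("differential: ", sum(de$lnc$expressed), " lnc expressed calls, ",
      sum(de$lnc$differentially_regulated), " lnc DE calls")

  ann <- .stage("annotate", cfg$verbose, {
    de_lnc_ids <- unique(
      de$lnc$gene_id[de$lnc$differentially_regulated])
    target <- if (length(de_lnc_ids)) {
      models$lnc[de_lnc_ids]
    } else {
      models$lnc
    }
    a <- annotate_regions(target, models$index,
                          up_window = cfg$pairing$upstream_window,
                          down_window = cfg$pairing$downstream_window)
    write_result_tsv(a, file.path(cfg$out_dir, "region_annotation.tsv"),
                     params = c(up = cfg$pairing$upstream_window,
                                down = cfg$pairing$downstream_window))
    d <- region_distribution(a)
    write_result_tsv(d, file.path(cfg$out_dir, "region_distribution.tsv"))
    list(annotations = a, distribution = d)
  })

  pairs <- .stage("pair", cfg$verbose, {
    p <- call_pairs(de$lnc, de$pcg, models$lnc, models$index, cfg$pairing)
    write_result_tsv(p, file.path(cfg$out_dir, "pairs.tsv"))
    s <- summarize_pairs(p, organs = organs)
    write_result_tsv(s, file.path(cfg$out_dir, "pair_summary.tsv"))
    write_pairs_bed(p, c(models$lnc, models$pcg),
                    file.path(cfg$out_dir, "pairs.bed"))
    export_paired_pcgs(p, file.path(cfg$out_dir, "paired_pcgs"),
                       organs = organs)
    list(pairs = p, summary = s)
  })
  log("pair: ", nrow(pairs$pairs), " pair records")

  overlaps <- .stage("overlap", cfg$verbose, {
    groups <- cfg$organ_groups %||% .default_groups(organs)
    res <- list()
    for (grp in names(groups)) {
      tissues <- groups[[grp]]
      expressed_sets <- lapply(setNames(tissues, tissues), function(org) {
        de$lnc$gene_id[de$lnc$organ == org & de$lnc$expressed]
      })
      de_sets <- lapply(setNames(tissues, tissues), function(org) {
        de$lnc$gene_id[de$lnc$organ == org &
                         de$lnc$differentially_regulated]
      })
      vp_expr <- venn_partition(expressed_sets)
      vp_de <- venn_partition(de_sets)
      write_result_tsv(vp_expr$counts,
                       file.path(cfg$out_dir,
                                 sprintf("overlap_expressed_%s.tsv", grp)))
      write_result_tsv(vp_de$counts,
                       file.path(cfg$out_dir,
                                 sprintf("overlap_de_%s.tsv", grp)))
      res[[grp]] <- list(expressed = vp_expr, de = vp_de,
                         common_de = intersect_de(de_sets, tissues))
    }
    res
  })

  interactions <- .stage("interact", cfg$verbose, {
    if (is.null(inputs$lnc_fasta) || nrow(pairs$pairs) == 0) {
      NULL
    } else {
      lnc_seqs <- read_transcript_fasta(inputs$lnc_fasta, as_rna = TRUE)
      mrna_seqs <- read_transcript_fasta(inputs$mrna_fasta, as_rna = TRUE)
      uniq <- unique(pairs$pairs[, c("lncrna_gene_id", "pcg_gene_id")])
      uniq <- head(uniq, cfg$max_interactions)
      tx <- data.frame(lnc_tx = paste0(uniq$lncrna_gene_id, ".1"),
                       pcg_tx = paste0(uniq$pcg_gene_id, ".1"),
                       stringsAsFactors = FALSE)
      tx <- tx[tx$lnc_tx %in% names(lnc_seqs) &
                 tx$pcg_tx %in% names(mrna_seqs), , drop = FALSE]
      res <- score_interactions(tx, lnc_seqs, mrna_seqs, cfg$energy)
      write_result_tsv(res, file.path(cfg$out_dir, "interactions.tsv"),
                       params = c(ndg_threshold =
                                    cfg$energy$ndg_threshold))
      res
    }
  })

  report <- c(
    sprintf("lncpair %s pipeline report", .lncpair_version()),
    sprintf("organs: %s", paste(organs, collapse = ", ")),
    sprintf("lncRNA genes: %d; PCGs: %d", length(models$lnc),
            length(models$pcg)),
    sprintf("expressed lncRNA calls: %d; differentially regulated: %d",
            sum(de$lnc$expressed), sum(de$lnc$differentially_regulated)),
    sprintf("expressed PCG calls: %d; differentially regulated: %d",
            sum(de$pcg$expressed), sum(de$pcg$differentially_regulated)),
    sprintf("pair records: %d", nrow(pairs$pairs)),
    sprintf("interactions scored: %d; bound: %d",
            if (is.null(interactions)) 0L else nrow(interactions),
            if (is.null(interactions)) 0L else sum(interactions$bound)),
    "", "pair summary:",
    utils::capture.output(print(pairs$summary, row.names = FALSE)))
  writeLines(report, file.path(cfg$out_dir, "report.txt"))

  invisible(list(lnc_calls = de$lnc, pcg_calls = de$pcg,
                 annotations = ann$annotations,
                 distribution = ann$distribution,
                 pairs = pairs$pairs, summary = pairs$summary,
                 overlaps = overlaps, interactions = interactions))
}
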