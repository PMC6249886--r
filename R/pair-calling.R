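# Call lncRNA-PCG pairs by the three-criterion rule: (1) the lncRNA locus
# overlaps the PCG's strand-aware extended window [TSS - 5 kb, TTS + 1 kb]
# by at least one base; (2) both members are expressed (mean FPKM > 1 in
# either enterotype); (3) both are differentially regulated (FDR-BH q <
# 0.05) in the same organ. Pairing is many-to-many: a lncRNA may pair with
# several PCGs and vice versa, and no strand filter is applied.

#' Pairing configuration
#'
#' @param upstream_window bases 5' of the TSS (default 5000).
#' @param downstream_window bases 3' of the TTS (default 1000).
#' @param fpkm_threshold expression threshold (default 1, strict `>`).
#' @param fdr_alpha FDR threshold (default 0.05, strict `<`).
#' @return A `pairing_config` list.
#' @export
pairing_config <- function(upstream_window = 5000, downstream_window = 1000,
                           fpkm_threshold = 1, fdr_alpha = 0.05) {
  vals <- c(upstream_window, downstream_window, fpkm_threshold, fdr_alpha)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all pairing parameters must be positive")
  }
  structure(list(upstream_window = upstream_window,
                 downstream_window = downstream_window,
                 fpkm_threshold = fpkm_threshold,
                 fdr_alpha = fdr_alpha), class = "pairing_config")
}

#' Find candidate PCG neighbors of a lncRNA
#'
#' Returns every coding gene whose strand-aware extended interval overlaps
#' the lncRNA locus by at least one base (interval overlap, not the anchor
#' rule used for region classification), together with the relative
#' placement of the lncRNA anchor with respect to that gene alone.
#'
#' @param lnc a lncRNA `gene_model` (or list with `chrom`, `start`, `end`,
#'   `strand`).
#' @param index [build_gene_index()] over coding genes.
#' @param cfg a [pairing_config()].
#' @return data.frame with `pcg_id` and `relation`, sorted by `pcg_id`.
#' @export
find_candidate_pcgs <- function(lnc, index, cfg = pairing_config()) {
  ids <- index_query(index, lnc$chrom, lnc$start, lnc$end,
                     upstream = cfg$upstream_window,
                     downstream = cfg$downstream_window)
  if (length(ids) == 0) {
    return(data.frame(pcg_id = character(), relation = character(),
                      stringsAsFactors = FALSE))
  }
  pos <- .anchor_position(lnc$start, lnc$end, lnc$strand, "midpoint")
  relation <- vapply(ids, function(id) {
    .class_vs_gene(pos, index$models[[id]],
                   cfg$upstream_window, cfg$downstream_window)
  }, "")
  data.frame(pcg_id = ids, relation = unname(relation),
             row.names = NULL, stringsAsFactors = FALSE)
}

.pair_category <- function(lnc_dir, pcg_dir) {
  ifelse(lnc_dir == "up_in_gf",
         ifelse(pcg_dir == "up_in_gf", "both_up", "lnc_up_pcg_down"),
         ifelse(pcg_dir == "up_in_gf", "lnc_down_pcg_up", "both_down"))
}

#' Call lncRNA-PCG pairs
#'
#' A pair record exists for a (lncRNA, PCG, organ) triple iff the proximity
#' criterion holds and both members are expressed and differentially
#' regulated in that organ.
#'
#' @param lnc_calls,pcg_calls differential call data.frames from
#'   [call_differential()] (one or more organs).
#' @param lnc_models named list of lncRNA gene models covering every
#'   differentially regulated lncRNA.
#' @param pcg_index [build_gene_index()] over the coding gene models.
#' @param cfg a [pairing_config()].
#' @return data.frame sorted by (organ, lncrna_gene_id, pcg_gene_id) with
#'   columns `organ`, `lncrna_gene_id`, `pcg_gene_id`, `relation`,
#'   `lnc_direction`, `pcg_direction`, `category`.
#' @export
call_pairs <- function(lnc_calls, pcg_calls, lnc_models, pcg_index,
                       cfg = pairing_config()) {
  empty <- data.frame(organ = character(), lncrna_gene_id = character(),
                      pcg_gene_id = character(), relation = character(),
                      lnc_direction = character(), pcg_direction = character(),
                      category = character(), stringsAsFactors = FALSE)
  de_lnc <- lnc_calls[lnc_calls$differentially_regulated, , drop = FALSE]
  de_pcg <- pcg_calls[pcg_calls$differentially_regulated, , drop = FALSE]
  miss_l <- setdiff(de_lnc$gene_id, names(lnc_models))
  miss_p <- setdiff(de_pcg$gene_id, names(pcg_index$models))
  if (length(miss_l) || length(miss_p)) {
    stop("differential calls without a gene model: ",
         paste(head(c(miss_l, miss_p), 10), collapse = ", "))
  }
  out <- list()
  for (org in sort(unique(de_lnc$organ))) {
    lnc_o <- de_lnc[de_lnc$organ == org, , drop = FALSE]
    pcg_o <- de_pcg[de_pcg$organ == org, , drop = FALSE]
    if (nrow(pcg_o) == 0) next
    pcg_dir <- setNames(pcg_o$direction, pcg_o$gene_id)
    for (i in seq_len(nrow(lnc_o))) {
      cand <- find_candidate_pcgs(lnc_models[[lnc_o$gene_id[i]]],
                                  pcg_index, cfg)
      cand <- cand[cand$pcg_id %in% pcg_o$gene_id, , drop = FALSE]
      if (nrow(cand) == 0) next
      out[[length(out) + 1L]] <- data.frame(
        organ = org, lncrna_gene_id = lnc_o$gene_id[i],
        pcg_gene_id = cand$pcg_id, relation = cand$relation,
        lnc_direction = lnc_o$direction[i],
        pcg_direction = unname(pcg_dir[cand$pcg_id]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  pairs <- do.call(rbind, out)
  pairs$category <- .pair_category(pairs$lnc_direction, pairs$pcg_direction)
  pairs <- pairs[order(pairs$organ, pairs$lncrna_gene_id, pairs$pcg_gene_id), ]
  rownames(pairs) <- NULL
  pairs
}

#' Per-organ pair summary by co-regulation direction
#'
#' @param pairs pair records from [call_pairs()].
#' @param organs optional organ vector; organs without pairs are then
#'   included with zero counts.
#' @return data.frame with `organ`, `total`, `n_both_up`, `n_both_down`,
#'   `n_lnc_up_pcg_down`, `n_lnc_down_pcg_up`.
#' @export
summarize_pairs <- function(pairs, organs = NULL) {
  orgs <- if (is.null(organs)) sort(unique(pairs$organ)) else organs
  if (length(orgs) == 0) {
    return(data.frame(organ = character(), total = integer(),
                      n_both_up = integer(), n_both_down = integer(),
                      n_lnc_up_pcg_down = integer(),
                      n_lnc_down_pcg_up = integer(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(orgs, function(org) {
    sub <- pairs[pairs$organ == org, , drop = FALSE]
    counts <- table(factor(sub$category, levels = pair_categories()))
    data.frame(organ = org, total = nrow(sub),
               n_both_up = as.integer(counts[["both_up"]]),
               n_both_down = as.integer(counts[["both_down"]]),
               n_lnc_up_pcg_down = as.integer(counts[["lnc_up_pcg_down"]]),
               n_lnc_down_pcg_up = as.integer(counts[["lnc_down_pcg_up"]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(organ = character(), total = integer(),
                      n_both_up = integer(), n_both_down = integer(),
                      n_lnc_up_pcg_down = integer(),
                      n_lnc_down_pcg_up = integer(), stringsAsFactors = FALSE)
  }
  out
}

#' Export paired PCG gene lists for external enrichment tools
#'
#' Writes one text file per organ containing the unique PCG ids paired with
#' a lncRNA in that organ (one id per line), the input format expected by
#' protein-association enrichment services. No enrichment is computed here.
#'
#' @param pairs pair records from [call_pairs()].
#' @param dir output directory (created if needed).
#' @param organs optional organ vector; listed organs without pairs get an
#'   empty file.
#' @return Named character vector of file paths, invisibly.
#' @export
export_paired_pcgs <- function(pairs, dir, organs = NULL) {
  orgs <- if (is.null(organs)) sort(unique(pairs$organ)) else organs
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(orgs, function(org) {
    ids <- sort(unique(pairs$pcg_gene_id[pairs$organ == org]))
    p <- file.path(dir, paste0(org, "_paired_pcgs.txt"))
    writeLines(ids, p)
    p
  }, "")
  invisible(paths)
}
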