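# Assign each lncRNA one genomic region class relative to protein-coding
# gene models: up to 5 kb upstream of the TSS, 5'UTR, exonic, intronic,
# 3'UTR, or up to 1 kb downstream of the TTS of the nearest candidate PCG;
# anything else is intergenic. The anchor is a single position of the lncRNA
# locus (midpoint by default), so a lncRNA is never assigned two classes.

.anchor_position <- function(start, end, strand,
                             anchor = c("midpoint", "five_prime_end")) {
  anchor <- match.arg(anchor)
  if (anchor == "midpoint") {
    as.integer((start + end) %/% 2)
  } else {
    if (strand == "+") as.integer(start) else as.integer(end - 1L)
  }
}

# Distance from a point to a span [start, end): 0 inside.
.point_span_distance <- function(pos, start, end) {
  ifelse(pos < start, start - pos, ifelse(pos >= end, pos - end + 1L, 0L))
}

# Class of an anchor relative to a single gene model, honoring the feature
# precedence 5'UTR > 3'UTR > exonic > intronic inside the gene body and
# strand-aware upstream/downstream in the flanks. Returns "intergenic" when
# the anchor is outside the extended window.
.class_vs_gene <- function(pos, model, up_window, down_window) {
  if (pos >= model$start && pos < model$end) {
    if (point_in_intervals(pos, model$utr5)) return("five_prime_utr")
    if (point_in_intervals(pos, model$utr3)) return("three_prime_utr")
    if (point_in_intervals(pos, model$exons)) return("exonic")
    return("intronic")
  }
  if (model$strand == "+") {
    if (pos < model$start && pos >= model$start - up_window) return("upstream")
    if (pos >= model$end && pos < model$end + down_window) return("downstream")
  } else {
    if (pos >= model$end && pos < model$end + up_window) return("upstream")
    if (pos < model$start && pos >= model$start - down_window) {
      return("downstream")
    }
  }
  "intergenic"
}

#' Classify a lncRNA locus into a genomic region relative to PCGs
#'
#' The anchor (locus midpoint by default, integer floor) is tested against
#' every coding gene whose span or strand-aware extended window
#' (`up_window` bases 5' of the TSS, `down_window` bases 3' of the TTS)
#' contains it. The nearest candidate wins (distance from anchor to gene
#' span; ties break to the lexicographically smallest gene id). Inside a
#' gene body the class is the feature containing the anchor with precedence
#' 5'UTR > 3'UTR > exonic > intronic; anchors in the extended windows only
#' are upstream/downstream; no candidate means intergenic.
#'
#' @param lnc a `gene_model`, or a list/one-row data.frame with `chrom`,
#'   `start`, `end` (0-based half-open) and `strand`.
#' @param index [build_gene_index()] built from coding gene models only.
#' @param up_window,down_window window sizes in bases (defaults 5000, 1000).
#' @param anchor `"midpoint"` (default) or `"five_prime_end"`.
#' @param lnc_id id to report (taken from `lnc$gene_id` when present).
#' @return One-row data.frame: `lncrna_gene_id`, `region`,
#'   `assigned_pcg_id` (`NA` when intergenic), `anchor_position`,
#'   `distance_to_gene` (0 when overlapping, `NA` when intergenic).
#' @export
classify_region <- function(lnc, index, up_window = 5000, down_window = 1000,
                            anchor = c("midpoint", "five_prime_end"),
                            lnc_id = NULL) {
  if (is.null(lnc_id)) {
    lnc_id <- if (!is.null(lnc$gene_id)) lnc$gene_id else NA_character_
  }
  if (is.null(lnc$start) || is.null(lnc$end) || lnc$start >= lnc$end) {
    stop("malformed lncRNA interval")
  }
  pos <- .anchor_position(lnc$start, lnc$end, lnc$strand, anchor)
  res <- function(region, pcg = NA_character_, dist = NA_integer_) {
    data.frame(lncrna_gene_id = lnc_id, region = region,
               assigned_pcg_id = pcg, anchor_position = pos,
               distance_to_gene = dist, stringsAsFactors = FALSE)
  }
  cand <- index_query(index, lnc$chrom, pos, pos + 1L,
                      upstream = up_window, downstream = down_window)
  if (length(cand) == 0) return(res("intergenic"))
  tab <- index$table[match(cand, index$table$gene_id), , drop = FALSE]
  dist <- .point_span_distance(pos, tab$start, tab$end)
  pick <- order(dist, tab$gene_id)[1] # nearest, then lexicographic id
  model <- index$models[[tab$gene_id[pick]]]
  cls <- .class_vs_gene(pos, model, up_window, down_window)
  res(cls, model$gene_id, as.integer(dist[pick]))
}

#' Annotate a set of lncRNA loci
#'
#' Vectorized wrapper around [classify_region()].
#'
#' @param lnc_models named list of lncRNA `gene_model`s (or a data.frame
#'   with `gene_id`, `chrom`, `start`, `end`, `strand`).
#' @inheritParams classify_region
#' @return data.frame with one [classify_region()] row per lncRNA.
#' @export
annotate_regions <- function(lnc_models, index, up_window = 5000,
                             down_window = 1000,
                             anchor = c("midpoint", "five_prime_end")) {
  anchor <- match.arg(anchor)
  if (is.data.frame(lnc_models)) {
    rows <- lapply(seq_len(nrow(lnc_models)), function(i) {
      classify_region(as.list(lnc_models[i, ]), index, up_window,
                      down_window, anchor)
    })
  } else {
    rows <- lapply(lnc_models, classify_region, index = index,
                   up_window = up_window, down_window = down_window,
                   anchor = anchor)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Distribution of region classes
#'
#' Counts and fractions over all seven region classes (zero-filled).
#'
#' @param annotations data.frame from [annotate_regions()].
#' @return data.frame with `region`, `count`, `fraction` for every class.
#' @export
region_distribution <- function(annotations) {
  if (nrow(annotations) == 0) stop("no annotations to summarize")
  counts <- table(factor(annotations$region, levels = region_classes()))
  data.frame(region = region_classes(),
             count = as.integer(counts),
             fraction = as.numeric(counts) / nrow(annotations),
             stringsAsFactors = FALSE)
}
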