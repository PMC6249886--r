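# Collapse transcript-level GTF records into strand-aware gene models and
# build an overlap-queryable index over them. All coordinates here are
# 0-based half-open; intervals are 2-column integer matrices (start, end).

.interval_matrix <- function(start = integer(), end = integer()) {
  cbind(start = as.integer(start), end = as.integer(end))
}

# Merge sorted/unsorted intervals; gap-0 (adjacent) intervals merge, a gap of
# >= 1 base is preserved.
merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  out_s <- iv[1, 1]; out_e <- iv[1, 2]
  res_s <- integer(); res_e <- integer()
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      if (iv[i, 1] <= out_e) {
        out_e <- max(out_e, iv[i, 2])
      } else {
        res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
        out_s <- iv[i, 1]; out_e <- iv[i, 2]
      }
    }
  }
  .interval_matrix(c(res_s, out_s), c(res_e, out_e))
}

# Complement of a merged interval set within [lo, hi).
complement_intervals <- function(iv, lo, hi) {
  if (nrow(iv) == 0) return(.interval_matrix(lo, hi))
  starts <- c(lo, iv[, 2])
  ends <- c(iv[, 1], hi)
  keep <- starts < ends
  .interval_matrix(starts[keep], ends[keep])
}

# Intersection of a merged interval set with a single window [lo, hi).
clip_intervals <- function(iv, lo, hi) {
  s <- pmax(iv[, 1], lo); e <- pmin(iv[, 2], hi)
  keep <- s < e
  .interval_matrix(s[keep], e[keep])
}

point_in_intervals <- function(pos, iv) {
  nrow(iv) > 0 && any(pos >= iv[, 1] & pos < iv[, 2])
}

#' Collapse the GTF records of one gene into a gene model
#'
#' Exons are the union over transcripts (adjacent exons merge); introns are
#' the complement of the exon union within the gene span. For coding genes
#' the 5'/3' UTRs are derived from the CDS extent strand-aware (exonic
#' sequence 5' of the 5'-most CDS base, and 3' of the 3'-most), unless
#' explicit `five_prime_utr`/`three_prime_utr` features are present, which
#' take precedence. Genes without CDS or UTR features are non-coding.
#'
#' @param records GTF record data.frame rows for a single gene
#'   (see [read_gtf()]).
#' @return A `gene_model`: list with `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (0-based half-open span), `tss`, `tts` (strand-aware positions),
#'   `exons`, `introns`, `utr5`, `utr3` (interval matrices), `is_coding`.
#' @export
collapse_gene <- function(records) {
  if (nrow(records) == 0) stop("no records to collapse")
  gene_id <- unique(records$gene_id)
  if (length(gene_id) != 1) {
    stop("records span multiple gene_ids: ", paste(gene_id, collapse = ", "))
  }
  if (length(unique(records$chrom)) != 1) {
    stop("gene ", gene_id, ": records on mixed chromosomes")
  }
  if (length(unique(records$strand)) != 1) {
    stop("gene ", gene_id, ": records on mixed strands")
  }
  chrom <- records$chrom[1]
  strand <- records$strand[1]
  z <- to_zero_based(records$start, records$end)

  take <- function(feat) {
    sel <- records$feature == feat
    merge_intervals(.interval_matrix(z$start[sel], z$end[sel]))
  }
  exons <- take("exon")
  if (nrow(exons) == 0) {
    # fall back to transcript/gene extent as a single exon
    exons <- merge_intervals(.interval_matrix(z$start, z$end))
  }
  span_lo <- min(exons[, 1]); span_hi <- max(exons[, 2])
  introns <- complement_intervals(exons, span_lo, span_hi)

  cds <- take("CDS")
  utr5 <- take("five_prime_utr")
  utr3 <- take("three_prime_utr")
  if (nrow(cds)) {
    # every CDS base must be exonic
    cov <- clip_intervals(exons, min(cds[, 1]), max(cds[, 2]))
    for (i in seq_len(nrow(cds))) {
      inside <- any(cov[, 1] <= cds[i, 1] & cov[, 2] >= cds[i, 2])
      if (!inside) stop("gene ", gene_id, ": CDS outside exons")
    }
  }
  if (nrow(utr5) == 0 && nrow(utr3) == 0 && nrow(cds)) {
    cds_lo <- min(cds[, 1]); cds_hi <- max(cds[, 2])
    left <- clip_intervals(exons, span_lo, cds_lo)
    right <- clip_intervals(exons, cds_hi, span_hi)
    if (strand == "+") {
      utr5 <- left; utr3 <- right
    } else {
      utr5 <- right; utr3 <- left
    }
  }
  is_coding <- nrow(cds) > 0 || nrow(utr5) > 0 || nrow(utr3) > 0

  structure(list(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = span_lo, end = span_hi,
    tss = if (strand == "+") span_lo else span_hi - 1L,
    tts = if (strand == "+") span_hi - 1L else span_lo,
    exons = exons, introns = introns, utr5 = utr5, utr3 = utr3,
    cds = cds, is_coding = is_coding), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s %s:%d-%d(%s), %d exon(s), %scoding\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand,
              nrow(x$exons), if (x$is_coding) "" else "non-"))
  invisible(x)
}

#' Build gene models for every gene in a GTF record table
#'
#' @param records GTF records from [read_gtf()].
#' @return Named list of `gene_model` objects, sorted by gene id.
#' @export
build_gene_models <- function(records) {
  ids <- sort(unique(records$gene_id))
  models <- lapply(ids, function(g) {
    collapse_gene(records[records$gene_id == g, , drop = FALSE])
  })
  setNames(models, ids)
}

#' Build an overlap-queryable index over gene models
#'
#' The index supports interval overlap queries against gene spans, optionally
#' extended strand-aware by upstream/downstream windows, with results
#' identical to a linear scan.
#'
#' @param models named list of `gene_model` objects.
#' @return An object of class `gene_index`.
#' @export
build_gene_index <- function(models) {
  if (length(models) == 0) {
    tab <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(
      gene_id = vapply(models, `[[`, "", "gene_id"),
      chrom = vapply(models, `[[`, "", "chrom"),
      start = vapply(models, `[[`, 0L, "start"),
      end = vapply(models, `[[`, 0L, "end"),
      strand = vapply(models, `[[`, "", "strand"),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(table = tab, models = models), class = "gene_index")
}

#' @export
print.gene_index <- function(x, ...) {
  cat("gene_index over", nrow(x$table), "gene(s)\n")
  invisible(x)
}

# Strand-aware extended spans: upstream bases are added 5' of the TSS,
# downstream bases 3' of the TTS, on the gene's own strand.
.extended_spans <- function(tab, upstream, downstream) {
  plus <- tab$strand == "+"
  s <- ifelse(plus, tab$start - upstream, tab$start - downstream)
  e <- ifelse(plus, tab$end + downstream, tab$end + upstream)
  list(start = pmax(as.numeric(s), 0), end = as.numeric(e))
}

#' Query genes overlapping an interval
#'
#' Returns the gene ids whose (optionally window-extended) span overlaps the
#' query interval by at least one base, sorted by gene id. Extension is
#' strand-aware: `upstream` bases 5' of the TSS and `downstream` bases 3' of
#' the TTS on each gene's strand. Backed by an IRanges interval overlap.
#'
#' @param index a [build_gene_index()] object.
#' @param chrom chromosome of the query interval.
#' @param start,end 0-based half-open query interval.
#' @param upstream,downstream window extensions in bases.
#' @return Character vector of gene ids (possibly empty), sorted.
#' @export
index_query <- function(index, chrom, start, end, upstream = 0,
                        downstream = 0) {
  tab <- index$table
  if (nrow(tab) == 0) return(character())
  if (start >= end) stop("malformed query interval: start >= end")
  sel <- tab$chrom == chrom
  if (!any(sel)) return(character())
  ext <- .extended_spans(tab[sel, , drop = FALSE], upstream, downstream)
  subject <- IRanges::IRanges(start = ext$start + 1, end = ext$end)
  query <- IRanges::IRanges(start = start + 1, end = end)
  hits <- IRanges::findOverlaps(query, subject)
  sort(tab$gene_id[sel][S4Vectors::subjectHits(hits)])
}

#' Sum of interval lengths
#' @param iv interval matrix.
#' @return Total length in bases.
#' @keywords internal
interval_length <- function(iv) {
  if (nrow(iv) == 0) 0L else sum(iv[, 2] - iv[, 1])
}
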