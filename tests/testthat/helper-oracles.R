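# Shared fixtures and independent brute-force oracles. The oracles never
# call the code paths they check: classification and candidate finding are
# re-derived from the window definitions with plain loops, BH from the
# step-up definition, the duplex energy from explicit offset enumeration,
# and the set partition from a per-element tally.

write_tmp_gtf <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gtf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

gtf_line <- function(chrom, feature, start, end, strand, gene, tx = NULL,
                     source = "test") {
  attrs <- if (is.null(tx)) {
    sprintf('gene_id "%s";', gene)
  } else {
    sprintf('gene_id "%s"; transcript_id "%s";', gene, tx)
  }
  sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
          chrom, source, feature, start, end, strand, attrs)
}

# a coding '+'/'-' gene model directly from 0-based intervals
toy_model <- function(gene_id, chrom, strand, exons, cds = NULL) {
  rows <- list()
  for (i in seq_len(nrow(exons))) {
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, source = "t", feature = "exon",
      start = exons[i, 1] + 1L, end = exons[i, 2], strand = strand,
      gene_id = gene_id, transcript_id = paste0(gene_id, ".1"),
      stringsAsFactors = FALSE)
  }
  if (!is.null(cds)) {
    for (i in seq_len(nrow(cds))) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, source = "t", feature = "CDS",
        start = cds[i, 1] + 1L, end = cds[i, 2], strand = strand,
        gene_id = gene_id, transcript_id = paste0(gene_id, ".1"),
        stringsAsFactors = FALSE)
    }
  }
  collapse_gene(do.call(rbind, rows))
}

# --- oracles ---------------------------------------------------------------

oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  q <- numeric(m)
  ord <- order(p)
  for (i in seq_len(m)) {
    # q for the i-th smallest p: min over j >= i of p_(j) * m / j
    vals <- vapply(i:m, function(j) p[ord[j]] * m / j, 0)
    q[ord[i]] <- min(1, min(vals))
  }
  q
}

# direct re-derivation of the region-class definitions for one anchor
oracle_classify <- function(lnc, models, up = 5000, down = 1000) {
  pos <- (lnc$start + lnc$end) %/% 2
  best_id <- NA_character_
  best_dist <- Inf
  for (m in models) {
    if (m$chrom != lnc$chrom) next
    if (m$strand == "+") {
      w_lo <- m$start - up; w_hi <- m$end + down
    } else {
      w_lo <- m$start - down; w_hi <- m$end + up
    }
    if (pos < max(w_lo, 0) || pos >= w_hi) next
    d <- if (pos < m$start) {
      m$start - pos
    } else if (pos >= m$end) {
      pos - m$end + 1
    } else 0
    if (d < best_dist || (d == best_dist && m$gene_id < best_id)) {
      best_dist <- d; best_id <- m$gene_id
    }
  }
  if (is.na(best_id)) return("intergenic")
  m <- models[[best_id]]
  inside <- function(iv) nrow(iv) > 0 && any(pos >= iv[, 1] & pos < iv[, 2])
  if (pos >= m$start && pos < m$end) {
    if (inside(m$utr5)) return("five_prime_utr")
    if (inside(m$utr3)) return("three_prime_utr")
    if (inside(m$exons)) return("exonic")
    return("intronic")
  }
  if (m$strand == "+") {
    if (pos < m$start) "upstream" else "downstream"
  } else {
    if (pos < m$start) "downstream" else "upstream"
  }
}

# all-pairs interval-overlap scan against window-extended spans
oracle_candidates <- function(lnc, models, up = 5000, down = 1000) {
  hits <- character()
  for (m in models) {
    if (m$chrom != lnc$chrom) next
    if (m$strand == "+") {
      w_lo <- m$start - up; w_hi <- m$end + down
    } else {
      w_lo <- m$start - down; w_hi <- m$end + up
    }
    if (lnc$start < w_hi && lnc$end > max(w_lo, 0)) {
      hits <- c(hits, m$gene_id)
    }
  }
  sort(hits)
}

# quadratic duplex scorer: enumerate every ungapped antiparallel offset and
# every maximal complementary run explicitly
oracle_dg <- function(s, t, e_gc = -3, e_au = -2, e_gu = -1, min_run = 2) {
  pair_e <- function(a, b) {
    key <- paste0(a, b)
    if (key %in% c("GC", "CG")) return(e_gc)
    if (key %in% c("AU", "UA")) return(e_au)
    if (key %in% c("GU", "UG")) return(e_gu)
    1
  }
  sv <- strsplit(chartr("T", "U", toupper(s)), "")[[1]]
  uv <- rev(strsplit(chartr("T", "U", toupper(t)), "")[[1]])
  n <- length(sv); m <- length(uv)
  best <- 0
  for (shift in (1 - m):(n - 1)) {
    i <- max(1, 1 + shift):min(n, m + shift)
    e <- mapply(pair_e, sv[i], uv[i - shift])
    runs <- rle(e < 0)
    idx_end <- cumsum(runs$lengths)
    idx_start <- idx_end - runs$lengths + 1
    for (r in seq_along(runs$lengths)) {
      if (runs$values[r] && runs$lengths[r] >= min_run) {
        best <- min(best, sum(e[idx_start[r]:idx_end[r]]))
      }
    }
  }
  best
}

oracle_venn <- function(sets) {
  labels <- names(sets)
  universe <- unique(unlist(sets))
  out <- list()
  for (id in universe) {
    sig <- paste(labels[vapply(sets, function(s) id %in% s, TRUE)],
                 collapse = "&")
    out[[sig]] <- (out[[sig]] %||% 0L) + 1L
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

revcomp_rna <- function(seq) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# small synthetic genome reused by randomized oracle tests
small_genome <- function(seed, n_pcg = 30, n_lnc = 5) {
  generate_genome(sim_config(seed = seed, n_chromosomes = 1L,
                             chrom_length = 8e5, n_pcg = n_pcg,
                             n_lnc = n_lnc))
}
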