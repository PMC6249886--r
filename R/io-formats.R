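# I/O for the external representations the pipeline touches: GTF, FPKM
# matrices with a sample design, Cuffdiff-style differential tables, BED6
# exports and transcript FASTA. Coordinates are 1-based closed only at these
# boundaries; everything downstream is 0-based half-open.

.gtf_features <- c("gene", "transcript", "exon", "CDS",
                   "five_prime_utr", "three_prime_utr")

#' Convert 1-based closed coordinates to 0-based half-open (and back)
#'
#' A 1-based closed interval `[start, end]` maps to the half-open interval
#' `[start - 1, end)`; the end coordinate is numerically unchanged.
#'
#' @param start,end integer vectors of 1-based closed coordinates.
#' @return `to_zero_based()` returns a list with `start` and `end` in 0-based
#'   half-open convention; `to_one_based()` is its inverse.
#' @export
to_zero_based <- function(start, end) {
  stopifnot(all(start >= 1), all(start <= end))
  list(start = as.integer(start) - 1L, end = as.integer(end))
}

#' @rdname to_zero_based
#' @export
to_one_based <- function(start, end) {
  stopifnot(all(start >= 0), all(start < end))
  list(start = as.integer(start) + 1L, end = as.integer(end))
}

.parse_gtf_attributes <- function(attr_string) {
  # key "value"; pairs, tolerant of trailing semicolons and extra spaces
  parts <- strsplit(attr_string, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  m <- regmatches(parts, regexec('^(\\S+)\\s+"?([^"]*)"?$', parts))
  keys <- vapply(m, function(x) if (length(x) == 3) x[2] else NA_character_, "")
  vals <- vapply(m, function(x) if (length(x) == 3) x[3] else NA_character_, "")
  setNames(vals, keys)
}

#' Read a GTF file
#'
#' Parses a 9-column GTF into a record table. Only the feature types used by
#' the pipeline (`gene`, `transcript`, `exon`, `CDS`, `five_prime_utr`,
#' `three_prime_utr`) are retained; other feature rows are dropped. Records
#' with strand other than `+`/`-` are rejected, as are malformed lines and
#' records lacking a `gene_id` attribute. Duplicate
#' (transcript_id, feature, start, end) records are deduplicated.
#'
#' @param path path to a tab-separated GTF file.
#' @param dialect `"pcg"` for a coding-gene reference (CDS expected) or
#'   `"lncrna"` for a non-coding reference that may lack CDS/UTR features.
#' @return A data.frame with columns `chrom`, `source`, `feature`, `start`,
#'   `end` (1-based closed), `strand`, `gene_id`, `transcript_id`, carrying
#'   the dialect as attribute `"dialect"`.
#' @export
read_gtf <- function(path, dialect = c("pcg", "lncrna")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield != 9)) {
    bad <- idx[which(nfield != 9)[1]]
    stop("malformed GTF line ", bad, ": expected 9 tab-separated columns, got ",
         nfield[which(nfield != 9)[1]])
  }
  mat <- do.call(rbind, fields)
  feature <- mat[, 3]
  sel <- feature %in% .gtf_features
  if (!any(sel)) {
    rec <- data.frame(chrom = character(), source = character(),
                      feature = character(), start = integer(),
                      end = integer(), strand = character(),
                      gene_id = character(), transcript_id = character(),
                      stringsAsFactors = FALSE)
    attr(rec, "dialect") <- dialect
    return(rec)
  }
  mat <- mat[sel, , drop = FALSE]
  idx <- idx[sel]
  strand <- mat[, 7]
  if (any(!strand %in% c("+", "-"))) {
    bad <- which(!strand %in% c("+", "-"))[1]
    stop("GTF line ", idx[bad], ": strand must be '+' or '-', got '",
         strand[bad], "'")
  }
  start <- suppressWarnings(as.integer(mat[, 4]))
  end <- suppressWarnings(as.integer(mat[, 5]))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop("GTF line ", idx[bad], ": non-integer coordinates")
  }
  if (any(start < 1) || any(start > end)) {
    bad <- which(start < 1 | start > end)[1]
    stop("GTF line ", idx[bad], ": requires 1 <= start <= end")
  }
  attrs <- lapply(mat[, 9], .parse_gtf_attributes)
  gene_id <- vapply(attrs, function(a) {
    if ("gene_id" %in% names(a)) a[["gene_id"]] else NA_character_
  }, "")
  if (anyNA(gene_id)) {
    stop("GTF line ", idx[which(is.na(gene_id))[1]],
         ": missing gene_id attribute")
  }
  transcript_id <- vapply(attrs, function(a) {
    if ("transcript_id" %in% names(a)) a[["transcript_id"]] else NA_character_
  }, "")
  rec <- data.frame(chrom = mat[, 1], source = mat[, 2],
                    feature = mat[, 3], start = start, end = end,
                    strand = strand, gene_id = gene_id,
                    transcript_id = transcript_id, stringsAsFactors = FALSE)
  dup <- duplicated(rec[, c("transcript_id", "feature", "start", "end")])
  rec <- rec[!dup, , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "dialect") <- dialect
  rec
}

#' Write GTF records
#'
#' Inverse of [read_gtf()]: emits 9-column GTF with a `#` header naming the
#' tool version. Score and frame are written as `.`.
#'
#' @param records a record data.frame as returned by [read_gtf()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(records, path) {
  attrs <- ifelse(
    is.na(records$transcript_id),
    sprintf('gene_id "%s";', records$gene_id),
    sprintf('gene_id "%s"; transcript_id "%s";',
            records$gene_id, records$transcript_id))
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   records$chrom, records$source, records$feature,
                   records$start, records$end, records$strand, attrs)
  writeLines(c(sprintf("# lncpair %s GTF export", .lncpair_version()), lines),
             path)
  invisible(path)
}

#' Construct an expression table
#'
#' Bundles a gene-by-sample FPKM matrix with its sample design. Enterotype
#' labels are case-folded to `CV`/`GF`.
#'
#' @param values numeric matrix (genes x samples) of FPKM, with rownames and
#'   colnames.
#' @param design data.frame with columns `sample_id`, `organ`, `enterotype`,
#'   `replicate`, one row per sample column.
#' @return An object of class `expression_table`.
#' @export
expression_table <- function(values, design) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyNA(values)) stop("expression values must be complete (NA found)")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("FPKM values must be finite and non-negative")
  }
  need <- c("sample_id", "organ", "enterotype", "replicate")
  if (!all(need %in% names(design))) {
    stop("design must have columns: ", paste(need, collapse = ", "))
  }
  design$enterotype <- toupper(trimws(design$enterotype))
  if (any(!design$enterotype %in% c("CV", "GF"))) {
    stop("enterotype must be CV or GF (case-insensitive)")
  }
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample_id in design")
  }
  missing <- setdiff(colnames(values), design$sample_id)
  if (length(missing)) {
    stop("samples absent from design: ", paste(missing, collapse = ", "))
  }
  design <- design[match(colnames(values), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(values = values, design = design),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression_table:", nrow(x$values), "genes x", ncol(x$values),
      "samples;", length(unique(x$design$organ)), "organ(s)\n")
  invisible(x)
}

#' Read an FPKM matrix and its sample design
#'
#' The matrix TSV has a header of sample ids and a first column of gene ids;
#' the design TSV maps each sample id to (organ, enterotype, replicate).
#' Missing values and negative FPKM are errors, never silently zeroed.
#'
#' @param path path to the gene x sample FPKM TSV.
#' @param design_path path to the design TSV.
#' @return An [expression_table()].
#' @export
read_expression <- function(path, design_path) {
  mat <- read.delim(path, check.names = FALSE, comment.char = "#")
  gene_ids <- as.character(mat[[1]])
  values <- as.matrix(mat[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  design <- read.delim(design_path, comment.char = "#",
                       stringsAsFactors = FALSE)
  design$sample_id <- as.character(design$sample_id)
  expression_table(values, design)
}

#' Write an expression table and design to TSV
#'
#' @param table an [expression_table()].
#' @param path,design_path output paths for the FPKM matrix and design.
#' @return `path`, invisibly.
#' @export
write_expression <- function(table, path, design_path) {
  hdr <- sprintf("# lncpair %s FPKM matrix", .lncpair_version())
  con <- file(path, "w")
  writeLines(hdr, con)
  df <- data.frame(gene_id = rownames(table$values), table$values,
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  con <- file(design_path, "w")
  writeLines(sprintf("# lncpair %s sample design", .lncpair_version()), con)
  write.table(table$design, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Accepts either the full Cuffdiff `gene_exp.diff` header (keyed on the
#' column names `log2(fold_change)` and `q_value`; `value_1`/`value_2` are
#' taken as the CV/GF condition means) or a minimal TSV with columns
#' `gene_id`, `mean_fpkm_cv`, `mean_fpkm_gf`, `log2_fold_change`, `p_value`,
#' `q_value` and optionally `organ`. Unknown extra columns are ignored.
#'
#' @param path path to the TSV.
#' @param organ organ label to assign when the file carries none.
#' @return A data.frame with the canonical columns `gene_id`, `organ`,
#'   `mean_fpkm_cv`, `mean_fpkm_gf`, `log2_fold_change`, `p_value`, `q_value`.
#' @export
read_diff_table <- function(path, organ = NA_character_) {
  df <- read.delim(path, check.names = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if ("log2(fold_change)" %in% names(df)) {
    out <- data.frame(
      gene_id = as.character(df$gene_id),
      organ = if ("organ" %in% names(df)) as.character(df$organ) else organ,
      mean_fpkm_cv = as.numeric(df$value_1),
      mean_fpkm_gf = as.numeric(df$value_2),
      log2_fold_change = as.numeric(df[["log2(fold_change)"]]),
      p_value = as.numeric(df$p_value),
      q_value = as.numeric(df$q_value),
      stringsAsFactors = FALSE)
  } else {
    need <- c("gene_id", "mean_fpkm_cv", "mean_fpkm_gf",
              "log2_fold_change", "p_value", "q_value")
    if (!all(need %in% names(df))) {
      stop("unrecognized differential table dialect; need columns ",
           paste(need, collapse = ", "), " or a Cuffdiff gene_exp.diff header")
    }
    out <- df[, c(need[1], intersect("organ", names(df)), need[-1])]
    if (!"organ" %in% names(out)) out$organ <- organ
    out <- out[, c("gene_id", "organ", "mean_fpkm_cv", "mean_fpkm_gf",
                   "log2_fold_change", "p_value", "q_value")]
  }
  ok <- !is.na(out$p_value) & !is.na(out$q_value)
  if (any(out$p_value[ok] < 0 | out$p_value[ok] > 1) ||
      any(out$q_value[ok] < 0 | out$q_value[ok] > 1)) {
    stop("p_value and q_value must lie in [0, 1]")
  }
  out
}

#' Write called pairs as BED6
#'
#' One BED line per pair member (lncRNA then PCG), 0-based half-open, with
#' `name = "lncid|pcgid|organ|category"` and the member gene's strand.
#'
#' @param pairs pair records from [call_pairs()].
#' @param gene_models named list of gene models covering every gene in
#'   `pairs` (see [build_gene_models()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs_bed <- function(pairs, gene_models, path) {
  lines <- sprintf("# lncpair %s pair BED export", .lncpair_version())
  if (nrow(pairs)) {
    ids <- unique(c(pairs$lncrna_gene_id, pairs$pcg_gene_id))
    unknown <- setdiff(ids, names(gene_models))
    if (length(unknown)) {
      stop("no gene model for: ", paste(unknown, collapse = ", "))
    }
    for (i in seq_len(nrow(pairs))) {
      name <- paste(pairs$lncrna_gene_id[i], pairs$pcg_gene_id[i],
                    pairs$organ[i], pairs$category[i], sep = "|")
      for (id in c(pairs$lncrna_gene_id[i], pairs$pcg_gene_id[i])) {
        m <- gene_models[[id]]
        lines <- c(lines, sprintf("%s\t%d\t%d\t%s\t0\t%s",
                                  m$chrom, m$start, m$end, name, m$strand))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read transcript sequences from FASTA
#'
#' Sequences are uppercased on read; both `T` and `U` are accepted. With
#' `as_rna = TRUE`, `T` is normalized to `U` (the convention required by the
#' interaction screen).
#'
#' @param path FASTA path.
#' @param as_rna normalize thymine to uracil?
#' @return Named character vector of sequences.
#' @export
read_transcript_fasta <- function(path, as_rna = FALSE) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  if (as_rna) seqs <- chartr("T", "U", seqs)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

# Shared writer for result tables: '#' header naming tool version and the
# generating parameters, then a TSV body.
write_result_tsv <- function(df, path, params = character()) {
  hdr <- sprintf("# lncpair %s%s", .lncpair_version(),
                 if (length(params)) {
                   paste0("; ", paste(names(params), params, sep = "=",
                                      collapse = "; "))
                 } else "")
  con <- file(path, "w")
  writeLines(hdr, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}
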