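# Hybridization screen between lncRNA and mRNA transcripts. The energy
# model is a deliberately simple stacked-pair scheme: scan every ungapped
# antiparallel offset of the two sequences, and take dG as the energy of the
# single most stable maximal complementary run (length >= min_run), with
# per-pair energies for G:C, A:U and G:U wobble pairs. ndG normalizes dG by
# the shorter transcript's length; binding is declared at ndG strictly
# below -0.08 (the lowest recommended screening threshold).

#' Energy parameters for the duplex screen
#'
#' @param pair_energies named numeric vector with elements `GC`, `AU`, `GU`
#'   (kcal/mol per stacked pair, all <= 0).
#' @param min_run minimum consecutive complementary pairs that count
#'   (default 2).
#' @param ndg_threshold binding threshold on ndG (default -0.08, strict).
#' @return An `energy_params` list.
#' @export
energy_params <- function(pair_energies = c(GC = -3.0, AU = -2.0, GU = -1.0),
                          min_run = 2L, ndg_threshold = -0.08) {
  if (!all(c("GC", "AU", "GU") %in% names(pair_energies))) {
    stop("pair_energies must name GC, AU and GU")
  }
  if (any(pair_energies > 0)) stop("pair energies must be <= 0")
  if (ndg_threshold >= 0) stop("ndg_threshold must be negative")
  if (min_run < 1) stop("min_run must be >= 1")
  structure(list(pair_energies = pair_energies,
                 min_run = as.integer(min_run),
                 ndg_threshold = ndg_threshold), class = "energy_params")
}

# Validate and encode an RNA sequence (A=0, C=1, G=2, U=3); T is accepted
# and normalized to U.
.encode_rna <- function(seq, what = "sequence") {
  if (length(seq) != 1 || !nzchar(seq)) stop("empty ", what)
  seq <- chartr("T", "U", toupper(seq))
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]],
                 c("A", "C", "G", "U")) - 1L
  if (anyNA(codes)) stop("invalid character in ", what,
                         " (must be A/C/G/U or T)")
  codes
}

#' Compute the hybridization free energy of a lncRNA-mRNA transcript pair
#'
#' `dG` is the minimum over all ungapped antiparallel offsets of the energy
#' of a maximal complementary run of length >= `min_run` (0 when no such
#' run exists); `ndG = dG / min(length(lnc), length(mrna))`; the pair is
#' bound when `ndG` is strictly below the threshold.
#'
#' @param lnc_seq,mrna_seq RNA sequences (strings over A/C/G/U; T accepted).
#' @param params an [energy_params()].
#' @param lnc_id,mrna_id transcript ids to report.
#' @return One-row data.frame: `lncrna_transcript_id`, `pcg_transcript_id`,
#'   `dG`, `ndG`, `bound`.
#' @export
compute_ndg <- function(lnc_seq, mrna_seq, params = energy_params(),
                        lnc_id = NA_character_, mrna_id = NA_character_) {
  s <- .encode_rna(lnc_seq, "lncRNA sequence")
  t <- .encode_rna(mrna_seq, "mRNA sequence")
  e <- params$pair_energies
  dG <- .duplex_min_dg(s, t, e[["GC"]], e[["AU"]], e[["GU"]], params$min_run)
  ndG <- dG / min(length(s), length(t))
  data.frame(lncrna_transcript_id = lnc_id, pcg_transcript_id = mrna_id,
             dG = dG, ndG = ndG, bound = ndG < params$ndg_threshold,
             stringsAsFactors = FALSE)
}

#' Apply the ndG binding threshold
#'
#' @param x either a numeric vector of ndG values or a data.frame with an
#'   `ndG` column (e.g. rows from [compute_ndg()]).
#' @param params an [energy_params()].
#' @return List with `bound` (logical vector, `ndG < threshold` strictly)
#'   and `n_bound`.
#' @export
threshold_interactions <- function(x, params = energy_params()) {
  ndg <- if (is.data.frame(x)) x$ndG else x
  if (!is.numeric(ndg)) stop("need numeric ndG values or an ndG column")
  bound <- ndg < params$ndg_threshold
  list(bound = bound, n_bound = sum(bound))
}

#' Score a table of transcript pairs
#'
#' @param pairs data.frame with columns `lnc_tx` and `pcg_tx`.
#' @param lnc_seqs,mrna_seqs named character vectors of transcript
#'   sequences.
#' @param params an [energy_params()].
#' @return data.frame of [compute_ndg()] rows, one per input pair, sorted
#'   by ascending ndG (strongest predicted interaction first).
#' @export
score_interactions <- function(pairs, lnc_seqs, mrna_seqs,
                               params = energy_params()) {
  missing <- c(setdiff(pairs$lnc_tx, names(lnc_seqs)),
               setdiff(pairs$pcg_tx, names(mrna_seqs)))
  if (length(missing)) {
    stop("transcript sequences missing for: ",
         paste(head(missing, 5), collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    compute_ndg(lnc_seqs[[pairs$lnc_tx[i]]], mrna_seqs[[pairs$pcg_tx[i]]],
                params, lnc_id = pairs$lnc_tx[i], mrna_id = pairs$pcg_tx[i])
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    out <- out[order(out$ndG), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- compute_ndg("A", "A")[0, ]
  }
  out
}
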