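# Expression and differential-regulation thresholds: a gene is "expressed"
# in an organ when its mean FPKM over the replicates of either enterotype is
# strictly above 1, and "differentially regulated" when additionally its
# Benjamini-Hochberg q-value is strictly below 0.05. The fallback two-group
# test (for cohorts without a precomputed Cuffdiff table) is a moderated
# t-test on log2(FPKM + eps): with n = 3 replicates per enterotype a
# per-gene variance estimate is too noisy to recover moderate fold changes,
# so the gene-wise variances are shrunk toward a common prior in the usual
# empirical-Bayes way (limma), mirroring how Cuffdiff pools dispersion
# across genes.

.subset_organ <- function(table, organ) {
  sel <- table$design$organ == organ
  if (!any(sel)) stop("organ not present in design: ", organ)
  list(values = table$values[, sel, drop = FALSE],
       design = table$design[sel, , drop = FALSE])
}

#' Subset an expression table to a set of genes
#'
#' @param table an [expression_table()].
#' @param gene_ids gene ids to keep (must all be present).
#' @return An [expression_table()] restricted to `gene_ids`.
#' @export
subset_genes <- function(table, gene_ids) {
  missing <- setdiff(gene_ids, rownames(table$values))
  if (length(missing)) {
    stop("genes absent from expression table: ",
         paste(head(missing, 5), collapse = ", "))
  }
  expression_table(table$values[gene_ids, , drop = FALSE], table$design)
}

#' Flag expressed genes in one organ
#'
#' A gene is expressed when its arithmetic mean FPKM over the CV replicates
#' or over the GF replicates is strictly above the threshold (zeros included
#' in the mean).
#'
#' @param table an [expression_table()].
#' @param organ organ to evaluate; must have at least one sample per
#'   enterotype.
#' @param threshold FPKM threshold (default 1, strict `>`).
#' @return data.frame with `gene_id`, `organ`, `mean_fpkm_cv`,
#'   `mean_fpkm_gf`, `expressed`.
#' @export
call_expressed <- function(table, organ, threshold = 1) {
  sub <- .subset_organ(table, organ)
  cv <- sub$design$enterotype == "CV"
  gf <- sub$design$enterotype == "GF"
  if (!any(cv) || !any(gf)) {
    stop("organ ", organ, " lacks samples for one enterotype")
  }
  mean_cv <- rowMeans(sub$values[, cv, drop = FALSE])
  mean_gf <- rowMeans(sub$values[, gf, drop = FALSE])
  data.frame(gene_id = rownames(sub$values), organ = organ,
             mean_fpkm_cv = mean_cv, mean_fpkm_gf = mean_gf,
             expressed = mean_cv > threshold | mean_gf > threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up procedure: after sorting p-values ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, mapped back to the
#' input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0) stop("empty p-value vector")
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  o <- order(p_values)
  q_sorted <- pmin(1, rev(cummin(rev(p_values[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Moderated two-group fit on a log2 matrix (columns: CV then GF per `is_gf`).
# Falls back to the ordinary t-statistic if empirical-Bayes moderation is
# not estimable (e.g. toy inputs where every gene has zero residual var).
.moderated_p <- function(log2_mat, is_gf) {
  design <- cbind(Intercept = 1, GF = as.numeric(is_gf))
  fit <- limma::lmFit(log2_mat, design)
  p <- tryCatch({
    eb <- limma::eBayes(fit)
    eb$p.value[, "GF"]
  }, error = function(e) {
    tstat <- fit$coefficients[, "GF"] / (fit$stdev.unscaled[, "GF"] * fit$sigma)
    2 * stats::pt(-abs(tstat), df = fit$df.residual)
  })
  # degenerate genes: zero variance in both groups
  v_cv <- apply(log2_mat[, !is_gf, drop = FALSE], 1, stats::var)
  v_gf <- apply(log2_mat[, is_gf, drop = FALSE], 1, stats::var)
  m_cv <- rowMeans(log2_mat[, !is_gf, drop = FALSE])
  m_gf <- rowMeans(log2_mat[, is_gf, drop = FALSE])
  zero_var <- v_cv == 0 & v_gf == 0
  p[zero_var & m_cv == m_gf] <- 1
  p[zero_var & m_cv != m_gf] <- .Machine$double.xmin
  p[is.na(p) & m_cv == m_gf] <- 1
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Two-group differential test for one organ
#'
#' Moderated t-test between enterotypes on `log2(FPKM + epsilon)` per gene,
#' with `log2_fold_change = log2((mean_gf + eps) / (mean_cv + eps))` (GF
#' relative to CV). q-values are Benjamini-Hochberg adjusted over the
#' organ's expressed genes only; non-expressed genes get `NA` p/q. Genes with
#' zero variance in both groups get p = 1 when the group means are equal and
#' the smallest representable positive p when they differ.
#'
#' @param table an [expression_table()] (typically already restricted to one
#'   gene class, lncRNA or PCG, so that FDR adjustment mirrors separate
#'   per-reference differential runs).
#' @param organ organ to test; needs >= 2 replicates per enterotype.
#' @param epsilon pseudocount added to FPKM before the log (default 0.01).
#' @param threshold FPKM expression threshold.
#' @return Differential table: `gene_id`, `organ`, `mean_fpkm_cv`,
#'   `mean_fpkm_gf`, `log2_fold_change`, `p_value`, `q_value`.
#' @export
fallback_de_test <- function(table, organ, epsilon = 0.01, threshold = 1) {
  sub <- .subset_organ(table, organ)
  is_gf <- sub$design$enterotype == "GF"
  if (sum(is_gf) < 2 || sum(!is_gf) < 2) {
    stop("organ ", organ, ": need >= 2 replicates per enterotype")
  }
  expr <- call_expressed(table, organ, threshold = threshold)
  lfc <- log2((expr$mean_fpkm_gf + epsilon) / (expr$mean_fpkm_cv + epsilon))
  p <- rep(NA_real_, nrow(expr))
  q <- rep(NA_real_, nrow(expr))
  idx <- which(expr$expressed)
  if (length(idx)) {
    log2_mat <- log2(sub$values[idx, , drop = FALSE] + epsilon)
    p[idx] <- .moderated_p(log2_mat, is_gf)
    q[idx] <- benjamini_hochberg(p[idx])
  }
  data.frame(gene_id = expr$gene_id, organ = organ,
             mean_fpkm_cv = expr$mean_fpkm_cv,
             mean_fpkm_gf = expr$mean_fpkm_gf,
             log2_fold_change = lfc, p_value = p, q_value = q,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Combine differential statistics and expression flags into calls
#'
#' A gene is differentially regulated iff it is expressed and `q < alpha`
#' (strict). Direction is `up_in_gf` for positive log2 fold change
#' ("up-regulated by lack of gut microbiota"), `down_in_gf` for negative.
#'
#' @param diff differential table ([fallback_de_test()] or
#'   [read_diff_table()]).
#' @param expressed either a logical vector aligned with `diff`, or a
#'   data.frame from [call_expressed()] keyed by `gene_id`.
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame of differential calls with `expressed`,
#'   `differentially_regulated` and `direction` columns appended.
#' @export
call_differential <- function(diff, expressed, alpha = 0.05) {
  if (is.data.frame(expressed)) {
    m <- match(diff$gene_id, expressed$gene_id)
    if (anyNA(m)) {
      stop("expressed flags missing for: ",
           paste(head(diff$gene_id[is.na(m)], 5), collapse = ", "))
    }
    expressed <- expressed$expressed[m]
  }
  stopifnot(length(expressed) == nrow(diff))
  dr <- expressed & !is.na(diff$q_value) & diff$q_value < alpha
  direction <- rep("none", nrow(diff))
  direction[dr & diff$log2_fold_change > 0] <- "up_in_gf"
  direction[dr & diff$log2_fold_change < 0] <- "down_in_gf"
  out <- diff
  out$expressed <- expressed
  out$differentially_regulated <- dr
  out$direction <- direction
  out
}
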