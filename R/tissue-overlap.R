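# Multi-set partitions of expressed / differentially regulated gene sets
# across tissue groups: every element of the union is assigned its exact
# membership signature (which tissues contain it), giving the region counts
# a Venn diagram would display.

#' Partition gene sets by membership signature
#'
#' Computes exact counts for all `2^k - 1` non-empty membership signatures
#' of `k` tissue sets. The full-intersection signature is the "commonly
#' expressed" region; singleton signatures are the "uniquely expressed"
#' regions. Ids are compared as exact strings after whitespace trimming
#' (version suffixes are significant).
#'
#' @param sets named list of character id vectors, `2 <= length(sets) <= 8`.
#' @return Object of class `venn_partition`: list with `set_labels` and a
#'   `counts` data.frame (`signature` as `label1&label2...` in input label
#'   order, `count`), zero-filled over all signatures.
#' @export
venn_partition <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 8) stop("need between 2 and 8 sets, got ", k)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be named")
  }
  labels <- names(sets)
  sets <- lapply(sets, function(x) unique(trimws(x)))
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  sig_of <- function(bits) paste(labels[bits], collapse = "&")
  observed <- if (length(universe)) {
    apply(member, 1, function(b) sig_of(as.logical(b)))
  } else {
    character()
  }
  # enumerate all non-empty signatures in a stable order
  all_sigs <- unlist(lapply(seq_len(2^k - 1), function(mask) {
    sig_of(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
  }))
  counts <- table(factor(observed, levels = all_sigs))
  structure(list(set_labels = labels,
                 counts = data.frame(signature = all_sigs,
                                     count = as.integer(counts),
                                     stringsAsFactors = FALSE)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn_partition over", length(x$set_labels), "sets;",
      sum(x$counts$count), "elements in the union\n")
  nz <- x$counts[x$counts$count > 0, ]
  if (nrow(nz)) print(nz, row.names = FALSE)
  invisible(x)
}

#' Count for one membership signature
#'
#' @param partition a [venn_partition()].
#' @param tissues tissues forming the signature (exactly these, no others).
#' @return Integer count of ids present in exactly these tissues.
#' @export
signature_count <- function(partition, tissues) {
  bits <- partition$set_labels %in% tissues
  if (!all(tissues %in% partition$set_labels)) {
    stop("unknown tissue(s): ",
         paste(setdiff(tissues, partition$set_labels), collapse = ", "))
  }
  sig <- paste(partition$set_labels[bits], collapse = "&")
  partition$counts$count[partition$counts$signature == sig]
}

#' Intersection of differentially regulated sets over a tissue group
#'
#' @param sets named list of id vectors.
#' @param group tissues to intersect (must all be set labels).
#' @return Sorted character vector of ids present in every listed tissue.
#' @export
intersect_de <- function(sets, group) {
  unknown <- setdiff(group, names(sets))
  if (length(unknown)) {
    stop("unknown tissue(s): ", paste(unknown, collapse = ", "))
  }
  sets <- lapply(sets[group], function(x) unique(trimws(x)))
  sort(Reduce(intersect, sets))
}
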