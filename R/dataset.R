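# Signed differential-expression gene sets.

#' Construct a signed dataset
#'
#' A dataset is the set of differentially expressed genes with their
#' regulation direction only: expression magnitudes are discarded after
#' thresholding, each gene carries sign +1 (up) or -1 (down).
#'
#' @param signs named integer vector; names are gene ids, values are +1/-1.
#' @return object of class \code{causal_dataset} (a named integer vector).
#' @export
#' @examples
#' d <- causal_dataset(c(G1 = 1, G2 = -1))
causal_dataset <- function(signs) {
  if (length(signs) == 0L)
    return(structure(stats::setNames(integer(), character()),
                     class = "causal_dataset"))
  ids <- names(signs)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    stop("dataset genes must be named")
  if (anyDuplicated(ids)) stop("duplicate gene id: ", ids[duplicated(ids)][1L])
  v <- as.integer(signs)
  if (anyNA(v) || any(!v %in% c(-1L, 1L)))
    stop("dataset signs must be exactly -1 or +1")
  structure(stats::setNames(v, ids), class = "causal_dataset")
}

#' @export
print.causal_dataset <- function(x, ...) {
  cat("causal_dataset: ", length(x), " genes (", sum(x == 1L), " up, ",
      sum(x == -1L), " down)\n", sep = "")
  invisible(x)
}

#' Threshold an expression table into a signed dataset
#'
#' Reads a TSV with columns \code{gene_id}, \code{logfc} and optional
#' \code{pvalue}. A gene is included iff |logfc| >= \code{fc_cutoff} and,
#' when \code{p_cutoff} is given, pvalue <= \code{p_cutoff}; its sign is the
#' sign of logfc. Among duplicated gene ids the row with the largest |logfc|
#' wins; an exact tie is an error. A pre-thresholded two-column table
#' (\code{gene_id}, \code{sign}) bypasses the cutoffs entirely.
#'
#' @param path path to the TSV.
#' @param fc_cutoff positive log-fold-change threshold (ignored for
#'   pre-thresholded input).
#' @param p_cutoff optional p-value threshold in (0, 1].
#' @return a [causal_dataset()].
#' @export
load_dataset <- function(path, fc_cutoff = 1, p_cutoff = NULL) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(tab))
    stop("load error: dataset table needs a gene_id column")
  tab$gene_id <- as.character(tab$gene_id)
  if ("sign" %in% names(tab) && !"logfc" %in% names(tab)) {
    v <- suppressWarnings(as.integer(tab$sign))
    if (anyNA(v) && nrow(tab) > 0L) stop("load error: non-numeric sign")
    return(causal_dataset(stats::setNames(v, tab$gene_id)))
  }
  if (!"logfc" %in% names(tab))
    stop("load error: dataset table needs logfc (or sign) column")
  stopifnot(fc_cutoff > 0)
  lfc <- suppressWarnings(as.numeric(tab$logfc))
  if (anyNA(lfc) && nrow(tab) > 0L) stop("load error: non-numeric logfc")
  keep_p <- rep(TRUE, nrow(tab))
  if (!is.null(p_cutoff)) {
    if (!"pvalue" %in% names(tab))
      stop("load error: p_cutoff given but no pvalue column")
    pv <- suppressWarnings(as.numeric(tab$pvalue))
    if (anyNA(pv) && nrow(tab) > 0L) stop("load error: non-numeric pvalue")
    keep_p <- pv <= p_cutoff
  }
  # resolve duplicates before thresholding: largest |logfc| represents the gene
  ord <- order(tab$gene_id, -abs(lfc))
  tab <- tab[ord, , drop = FALSE]; lfc <- lfc[ord]; keep_p <- keep_p[ord]
  dup <- duplicated(tab$gene_id)
  firsts <- which(!dup)
  for (i in firsts) {
    j <- i + 1L
    if (j <= nrow(tab) && tab$gene_id[j] == tab$gene_id[i] &&
        abs(lfc[j]) == abs(lfc[i]) && lfc[j] != lfc[i])
      stop("load error: tied |logfc| for duplicated gene '", tab$gene_id[i],
           "'")
  }
  keep <- !dup & abs(lfc) >= fc_cutoff & keep_p
  causal_dataset(stats::setNames(ifelse(lfc[keep] > 0, 1L, -1L),
                                 tab$gene_id[keep]))
}

#' Restrict a dataset to genes present in the network
#'
#' Drops dataset genes that are not nodes of the graph; warns with the count
#' dropped. Idempotent.
#'
#' @param dataset a [causal_dataset()].
#' @param graph a [causal_graph()].
#' @return a [causal_dataset()] containing only network genes.
#' @export
restrict_to_network <- function(dataset, graph) {
  keep <- names(dataset) %in% graph$nodes$id
  dropped <- sum(!keep)
  if (dropped > 0L)
    warning(dropped, " dataset gene(s) absent from the network were dropped")
  causal_dataset(unclass(dataset)[keep])
}
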