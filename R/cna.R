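# Causal Network Analysis: sign-consistent shortest-path hypotheses with
# per-depth scoring and an Occam retention filter.

#' Prune a causal graph for multi-step path analysis
#'
#' Keeps only T and A edges whose regulation direction is unambiguous
#' (sign != 0) and whose confidence weight reaches \code{delta}; all kept
#' weights are reset to 1 (path analysis ignores continuous weights).
#' P and B edges are dropped.
#'
#' @param graph a [causal_graph()].
#' @param delta confidence cutoff in [0, 1] (default 0.25).
#' @return a pruned [causal_graph()] over the same node set.
#' @export
prune_graph <- function(graph, delta = 0.25) {
  stopifnot(delta >= 0, delta <= 1)
  e <- graph$edges
  keep <- e$edge_type %in% c("T", "A") & e$sign != 0L & e$weight >= delta
  e <- e[keep, , drop = FALSE]
  e$weight <- rep(1, nrow(e))
  causal_graph(graph$nodes, e)
}

#' Composite sign of a causal path
#'
#' The net direction of regulation transmitted along a chain of signed
#' edges: the product of the edge signs.
#'
#' @param edge_signs nonempty vector of values in \{-1, +1\}.
#' @return -1 or +1.
#' @export
#' @examples
#' path_sign(c(1, -1))   # -1: activation then inhibition nets to inhibition
path_sign <- function(edge_signs) {
  if (length(edge_signs) == 0L) stop("empty path")
  if (any(!edge_signs %in% c(-1, 1))) stop("path edges must have sign -1 or +1")
  prod(edge_signs)
}

#' Virtual edges from a root regulator
#'
#' For each gene of the pruned T-universe, enumerates all simple shortest
#' paths from the root whose final hop is a T edge (intermediate hops may be
#' T or A; parallel T and A edges between the same pair count as distinct
#' steps). If the shortest such paths exist within \code{max_K} hops and all
#' agree in composite sign, the gene receives a single virtual edge of that
#' length and sign; a sign disagreement among the shortest paths suppresses
#' the gene entirely.
#'
#' @param pruned a graph from [prune_graph()].
#' @param root a non-process node id.
#' @param max_K maximal path length in edges (default 3).
#' @return list of virtual edges, each a list with \code{target},
#'   \code{length}, \code{sign}, and \code{paths} (node-id sequences) plus
#'   \code{path_signs}; ordered by target id.
#' @export
virtual_edges_for_root <- function(pruned, root, max_K = 3L) {
  stopifnot(max_K >= 1L)
  if (node_class_of(pruned, root) == "process")
    stop("processes cannot be CNA roots")
  e <- pruned$edges
  adj <- split(seq_len(nrow(e)), e$source)

  hits <- list()  # per gene: list of (length, sign, nodes)
  walk <- function(node, path_nodes, sign_so_far, len) {
    idx <- adj[[node]]
    if (is.null(idx)) return(invisible(NULL))
    for (i in idx) {
      tgt <- e$target[i]
      if (tgt %in% path_nodes) next  # simple paths only
      s <- sign_so_far * e$sign[i]
      if (e$edge_type[i] == "T") {
        hits[[tgt]][[length(hits[[tgt]]) + 1L]] <<-
          list(length = len + 1L, sign = s, nodes = c(path_nodes, tgt))
      }
      if (len + 1L < max_K)
        walk(tgt, c(path_nodes, tgt), s, len + 1L)
    }
    invisible(NULL)
  }
  walk(root, root, 1L, 0L)

  out <- lapply(sort(names(hits)), function(g) {
    paths <- hits[[g]]
    lens <- vapply(paths, `[[`, integer(1L), "length")
    kmin <- min(lens)
    shortest <- paths[lens == kmin]
    signs <- vapply(shortest, `[[`, numeric(1L), "sign")
    if (length(unique(signs)) > 1L) return(NULL)  # inconsistent pair
    list(target = g, length = kmin, sign = as.integer(signs[1L]),
         paths = lapply(shortest, `[[`, "nodes"),
         path_signs = as.integer(signs))
  })
  out[!vapply(out, is.null, logical(1L))]
}

#' Score depth-K hypothesis networks for a root regulator
#'
#' For each K = 1..max_K the virtual edges of length <= K are treated as
#' direct unit-weight regulator-to-gene edges and scored with the URA
#' statistics: the overlap p-value against the pruned T-universe and the
#' activation Z-score of the composite signs. Depths with no dataset
#' overlap produce no hypothesis; by construction the regulated gene sets
#' are nested over K.
#'
#' @param pruned a graph from [prune_graph()].
#' @param dataset a [causal_dataset()] restricted to the network.
#' @param root a non-process node id.
#' @param max_K maximal depth (default 3).
#' @param z_threshold activation-call threshold (default 2).
#' @return list of hypothesis objects (class \code{cna_hypothesis}), one
#'   per depth with nonzero overlap, each with fields root, depth,
#'   virtual_edges, regulated_genes, overlap_pvalue, activation_z,
#'   predicted_state, intermediate_regulators, n_targets.
#' @export
score_hypotheses <- function(pruned, dataset, root, max_K = 3L,
                             z_threshold = 2) {
  universe <- regulated_gene_universe(pruned)
  ds <- unclass(dataset)
  ds_u <- ds[names(ds) %in% universe]
  if (length(ds_u) == 0L) return(list())
  ve <- virtual_edges_for_root(pruned, root, max_K)
  if (length(ve) == 0L) return(list())
  lens <- vapply(ve, `[[`, integer(1L), "length")
  out <- list()
  for (K in seq_len(max_K)) {
    sub <- ve[lens <= K]
    if (length(sub) == 0L) next
    tgt <- vapply(sub, `[[`, character(1L), "target")
    sgn <- vapply(sub, `[[`, integer(1L), "sign")
    in_d <- tgt %in% names(ds_u)
    if (!any(in_d)) next
    p <- overlap_pvalue(length(universe), length(tgt), length(ds_u),
                        sum(in_d))
    conc <- sgn[in_d] * ds_u[tgt[in_d]]
    z <- activation_zscore(rep(1, sum(in_d)), conc)
    # hypothesis network = union of paths reaching dataset molecules
    inter <- unique(unlist(lapply(sub[in_d], function(v)
      lapply(v$paths, function(p) p[-c(1L, length(p))]))))
    ves <- data.frame(target = tgt, length = vapply(sub, `[[`, integer(1L),
                                                    "length"),
                      sign = sgn, stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- structure(
      list(root = root, depth = K, virtual_edges = ves,
           regulated_genes = sort(tgt[in_d]), overlap_pvalue = p,
           activation_z = z,
           predicted_state = predict_state(z, z_threshold),
           intermediate_regulators = sort(inter),
           n_targets = length(tgt)),
      class = "cna_hypothesis")
  }
  out
}

#' Occam filter over nested hypotheses
#'
#' Within each root, hypotheses are examined in order of increasing depth.
#' The shallowest hypothesis is always retained; a deeper one is retained
#' only if (i) its overlap p-value is strictly smaller than that of every
#' retained shallower hypothesis of the same root and (ii) its regulated
#' gene set differs from each of theirs. Preference thus goes to the
#' simplest network that explains the data.
#'
#' @param hypotheses list of \code{cna_hypothesis} objects (possibly mixing
#'   roots).
#' @return the retained sublist, in (root, depth) order.
#' @export
filter_hypotheses <- function(hypotheses) {
  if (length(hypotheses) == 0L) return(hypotheses)
  roots <- vapply(hypotheses, `[[`, character(1L), "root")
  out <- list()
  for (r in unique(roots)) {
    hs <- hypotheses[roots == r]
    hs <- hs[order(vapply(hs, `[[`, integer(1L), "depth"))]
    kept <- list()
    for (h in hs) {
      ok <- all(vapply(kept, function(k)
        h$overlap_pvalue < k$overlap_pvalue &&
          !setequal(h$regulated_genes, k$regulated_genes), logical(1L)))
      if (ok) kept[[length(kept) + 1L]] <- h
    }
    out <- c(out, kept)
  }
  out
}

#' Causal Network Analysis
#'
#' End-to-end CNA: prunes the graph, enumerates sign-consistent
#' shortest-path hypotheses up to \code{max_K} hops for every candidate
#' root (non-process nodes with at least one outgoing pruned edge, unless
#' \code{roots} is given), scores each depth with the URA statistics, and
#' applies the Occam filter.
#'
#' @param graph a [causal_graph()].
#' @param dataset a [causal_dataset()] restricted to the network.
#' @param roots optional character vector of root ids.
#' @param max_K maximal hypothesis depth (default 3).
#' @param delta edge-confidence pruning cutoff (default 0.25).
#' @param z_threshold activation-call threshold (default 2).
#' @return data.frame of class \code{cna_result} with one row per retained
#'   hypothesis: root, depth, overlap_pvalue, activation_z,
#'   predicted_state, n_regulated, intermediate_regulators,
#'   regulated_genes; sorted by overlap p-value. The full hypothesis
#'   objects are in \code{attr(, "hypotheses")}.
#' @export
run_cna <- function(graph, dataset, roots = NULL, max_K = 3L, delta = 0.25,
                    z_threshold = 2) {
  pruned <- prune_graph(graph, delta)
  if (is.null(roots)) {
    roots <- unique(pruned$edges$source)
    roots <- sort(roots[node_class_of(pruned, roots) != "process"])
  }
  hyps <- list()
  for (r in roots)
    hyps <- c(hyps, score_hypotheses(pruned, dataset, r, max_K, z_threshold))
  kept <- filter_hypotheses(hyps)
  if (length(kept) == 0L) {
    res <- data.frame(root = character(), depth = integer(),
                      overlap_pvalue = numeric(), activation_z = numeric(),
                      predicted_state = character(), n_regulated = integer(),
                      intermediate_regulators = character(),
                      regulated_genes = character(), stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, lapply(kept, function(h)
      data.frame(root = h$root, depth = h$depth,
                 overlap_pvalue = h$overlap_pvalue,
                 activation_z = h$activation_z,
                 predicted_state = h$predicted_state,
                 n_regulated = length(h$regulated_genes),
                 intermediate_regulators = paste(h$intermediate_regulators,
                                                 collapse = ","),
                 regulated_genes = paste(h$regulated_genes, collapse = ","),
                 stringsAsFactors = FALSE)))
    res <- res[order(res$overlap_pvalue, res$root, res$depth), , drop = FALSE]
    rownames(res) <- NULL
  }
  structure(res, class = c("cna_result", "data.frame"),
            hypotheses = kept)
}

#' @export
print.cna_result <- function(x, n = 10L, ...) {
  cat("Causal Network Analysis: ", nrow(x), " hypothesis network(s)\n",
      sep = "")
  top <- utils::head(as.data.frame(x)[, c("root", "depth", "overlap_pvalue",
                                          "activation_z", "predicted_state",
                                          "n_regulated")], n)
  top$overlap_pvalue <- signif(top$overlap_pvalue, 4)
  top$activation_z <- signif(top$activation_z, 4)
  print(top, row.names = FALSE)
  if (nrow(x) > n) cat("... and ", nrow(x) - n, " more\n", sep = "")
  invisible(x)
}
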