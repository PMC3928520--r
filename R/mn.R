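# Mechanistic Networks: causal-transitive-triangle enrichment and the
# breadth/depth-bounded recursive network construction.

#' Causal-transitive-triangle enrichment of a regulator-regulator edge
#'
#' If r2 relays r1's effect on the dataset, the genes of the dataset that r1
#' regulates should be unusually often regulated by r2 as well (triangles
#' r1 -> r2, r2 -> g, r1 -> g). The score is a one-sided hypergeometric
#' p-value of the intersection of the two regulators' dataset target sets,
#' with the dataset genes under at least one T edge serving as the
#' universe.
#'
#' @param graph a [causal_graph()] containing an edge r1 -> r2 of type T, A
#'   or B.
#' @param dataset a [causal_dataset()] restricted to the network.
#' @param r1,r2 regulator node ids (upstream, downstream).
#' @return list of class \code{triangle_score}: \code{upstream},
#'   \code{downstream}, \code{edge_type}, \code{pvalue},
#'   \code{shared_targets}.
#' @export
triangle_pvalue <- function(graph, dataset, r1, r2) {
  e <- graph$edges
  sel <- e$source == r1 & e$target == r2 & e$edge_type %in% c("T", "A", "B")
  if (!any(sel))
    stop("no causal edge ", r1, " -> ", r2)
  etype <- c("T", "A", "B")[min(match(e$edge_type[sel], c("T", "A", "B")))]
  u <- intersect(names(dataset), regulated_gene_universe(graph))
  if (length(u) == 0L) stop("empty triangle universe (no dataset gene under a T edge)")
  a1 <- intersect(regulator_targets(graph, r1)$gene, u)
  a2 <- intersect(regulator_targets(graph, r2)$gene, u)
  shared <- intersect(a1, a2)
  p <- overlap_pvalue(length(u), length(a1), length(a2), length(shared))
  structure(list(upstream = r1, downstream = r2, edge_type = etype,
                 pvalue = p, shared_targets = sort(shared)),
            class = "triangle_score")
}

#' Grow a mechanistic network downstream of a master regulator
#'
#' Depth-first recursion from the root: at each regulator, the outgoing T, A
#' and B edges leading to other significant regulators (those passing the
#' overlap-p and |Z| cutoffs in \code{ura_results}) are ranked by triangle
#' p-value (ties broken by smaller regulator id) and the best
#' \code{breadth} children are traversed, skipping a child that already
#' lies on the current path (cycle) or when the path has reached
#' \code{depth} edges. Activation-state consistency along edges is not
#' enforced.
#'
#' @param graph a [causal_graph()].
#' @param dataset a [causal_dataset()] restricted to the network.
#' @param ura_results a \code{ura_result} data.frame from [run_ura()].
#' @param root regulator id; must itself pass the cutoffs.
#' @param breadth maximum children per regulator (default 5).
#' @param depth maximum path length in edges (default 3).
#' @param p_cut overlap p-value cutoff (default 0.01).
#' @param z_cut |Z| cutoff (default 2).
#' @return object of class \code{mechanistic_network}: root, traversed edge
#'   table (upstream, downstream, edge_type, pvalue, shared_targets),
#'   regulators, covered_dataset_genes, breadth, depth.
#' @export
build_mechanistic_network <- function(graph, dataset, ura_results, root,
                                      breadth = 5L, depth = 3L,
                                      p_cut = 0.01, z_cut = 2) {
  stopifnot(breadth >= 1L, depth >= 1L)
  ok <- !is.na(ura_results$activation_z) &
    abs(ura_results$activation_z) >= z_cut &
    ura_results$overlap_pvalue <= p_cut
  passing <- ura_results$regulator[ok]
  if (!root %in% passing) stop("root not significant")

  e <- graph$edges[graph$edges$edge_type %in% c("T", "A", "B"), , drop = FALSE]
  edges_out <- list()
  seen_edge <- character()
  recurse <- function(node, path) {
    if (length(path) - 1L >= depth) return(invisible(NULL))
    kids <- unique(e$target[e$source == node])
    kids <- setdiff(intersect(kids, passing), node)
    if (length(kids) == 0L) return(invisible(NULL))
    scores <- lapply(kids, function(k) triangle_pvalue(graph, dataset, node, k))
    pv <- vapply(scores, `[[`, numeric(1L), "pvalue")
    ord <- order(pv, kids)
    take <- utils::head(ord, breadth)
    for (i in take) {
      child <- kids[i]
      if (child %in% path) next  # cycle: skip
      key <- paste0(node, "\r", child)
      if (!key %in% seen_edge) {
        seen_edge <<- c(seen_edge, key)
        edges_out[[key]] <<- scores[[i]]
      }
      recurse(child, c(path, child))
    }
    invisible(NULL)
  }
  recurse(root, root)

  edge_df <- if (length(edges_out)) {
    do.call(rbind, lapply(edges_out, function(s)
      data.frame(upstream = s$upstream, downstream = s$downstream,
                 edge_type = s$edge_type, pvalue = s$pvalue,
                 shared_targets = paste(s$shared_targets, collapse = ","),
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(upstream = character(), downstream = character(),
               edge_type = character(), pvalue = numeric(),
               shared_targets = character(), stringsAsFactors = FALSE)
  }
  rownames(edge_df) <- NULL
  regs <- sort(unique(c(root, edge_df$upstream, edge_df$downstream)))
  covered <- sort(unique(unlist(lapply(regs, function(r)
    intersect(regulator_targets(graph, r)$gene, names(dataset))))))
  structure(list(root = root, edges = edge_df, regulators = regs,
                 covered_dataset_genes = covered,
                 breadth = as.integer(breadth), depth = as.integer(depth)),
            class = "mechanistic_network")
}

#' @export
print.mechanistic_network <- function(x, ...) {
  cat("Mechanistic network rooted at ", x$root, ": ",
      length(x$covered_dataset_genes), " (", length(x$regulators), ")\n",
      "  [dataset genes covered (regulators); breadth=", x$breadth,
      ", depth=", x$depth, "]\n", sep = "")
  if (nrow(x$edges)) {
    e <- x$edges
    e$pvalue <- signif(e$pvalue, 4)
    print(e[, c("upstream", "downstream", "edge_type", "pvalue")],
          row.names = FALSE)
  }
  invisible(x)
}
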