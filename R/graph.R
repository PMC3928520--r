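# Causal multigraph data model: typed, signed, weighted edges over molecules
# and biological processes.

NODE_CLASSES <- c("gene", "chemical", "protein_family", "complex",
                  "microRNA", "process")
EDGE_TYPES <- c("T", "A", "P", "B")

#' Construct a causal network
#'
#' Builds a validated causal multigraph from a node table and an edge table.
#' The graph is directed; edges carry a type (\code{"T"} transcription /
#' expression, \code{"A"} functional activation or inhibition, \code{"P"}
#' process regulation, \code{"B"} protein-protein binding), a causal sign
#' (+1 activating, -1 inhibiting, 0 ambiguous) and a confidence weight in
#' [0, 1]. Two nodes may be connected by several edges of different types
#' (multigraph), but at most one edge per (source, target, type) triple.
#'
#' Structural constraints enforced at construction time: no self-edges;
#' T edges must target gene nodes and P edges must target process nodes;
#' B edges always carry sign 0; a sign of 0 forces weight 0.
#'
#' @param nodes data.frame with columns \code{id} (unique, nonempty) and
#'   \code{node_class} (one of gene, chemical, protein_family, complex,
#'   microRNA, process).
#' @param edges data.frame with columns \code{source}, \code{target},
#'   \code{edge_type}, \code{sign}, \code{weight}.
#' @return An object of class \code{causal_graph}: a list with components
#'   \code{nodes} and \code{edges}.
#' @seealso [load_network()], [regulated_gene_universe()]
#' @export
#' @examples
#' nodes <- data.frame(id = c("R1", "G1"), node_class = c("gene", "gene"))
#' edges <- data.frame(source = "R1", target = "G1", edge_type = "T",
#'                     sign = 1, weight = 1)
#' g <- causal_graph(nodes, edges)
causal_graph <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "node_class") %in% names(nodes)))
  if (nrow(edges) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        edge_type = character(), sign = integer(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("source", "target", "edge_type", "sign", "weight") %in%
                  names(edges)))
  nodes$id <- as.character(nodes$id)
  nodes$node_class <- as.character(nodes$node_class)
  if (anyNA(nodes$id) || any(!nzchar(nodes$id)))
    stop("node ids must be nonempty")
  if (anyDuplicated(nodes$id))
    stop("duplicate node id: ", nodes$id[duplicated(nodes$id)][1L])
  bad_class <- setdiff(unique(nodes$node_class), NODE_CLASSES)
  if (length(bad_class))
    stop("unknown node_class: ", bad_class[1L])

  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$edge_type <- as.character(edges$edge_type)
  edges$sign <- as.integer(edges$sign)
  edges$weight <- as.numeric(edges$weight)

  cls <- stats::setNames(nodes$node_class, nodes$id)
  validate_edges(edges, cls)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "causal_graph")
}

validate_edges <- function(edges, cls) {
  n <- nrow(edges)
  if (n == 0L) return(invisible(TRUE))
  where <- function(i) paste0(" (row ", i, ": ", edges$source[i], " -", # nolint
                              edges$edge_type[i], "-> ", edges$target[i], ")")
  i <- which(!edges$edge_type %in% EDGE_TYPES)
  if (length(i)) stop("unknown edge_type '", edges$edge_type[i[1L]], "'",
                      where(i[1L]))
  i <- which(edges$source == edges$target)
  if (length(i)) stop("self-edge not allowed", where(i[1L]))
  i <- which(!(edges$source %in% names(cls)) | !(edges$target %in% names(cls)))
  if (length(i)) stop("edge endpoint is not a declared node", where(i[1L]))
  i <- which(edges$edge_type == "T" & cls[edges$target] != "gene")
  if (length(i)) stop("T edge must target a gene node", where(i[1L]))
  i <- which(edges$edge_type == "P" & cls[edges$target] != "process")
  if (length(i)) stop("P edge must target a process node", where(i[1L]))
  i <- which(is.na(edges$sign) | !(edges$sign %in% c(-1L, 0L, 1L)))
  if (length(i)) stop("edge sign must be -1, 0 or +1", where(i[1L]))
  i <- which(edges$edge_type == "B" & edges$sign != 0L)
  if (length(i)) stop("B edges carry sign 0", where(i[1L]))
  i <- which(is.na(edges$weight) | edges$weight < 0 | edges$weight > 1)
  if (length(i)) stop("edge weight must lie in [0, 1]", where(i[1L]))
  i <- which(edges$sign == 0L & edges$weight != 0)
  if (length(i)) stop("sign 0 implies weight 0", where(i[1L]))
  key <- paste(edges$source, edges$target, edges$edge_type)
  i <- which(duplicated(key))
  if (length(i)) stop("duplicate (source, target, edge_type) edge", where(i[1L]))
  invisible(TRUE)
}

#' @export
print.causal_graph <- function(x, ...) {
  tab <- table(factor(x$edges$edge_type, levels = EDGE_TYPES))
  cat("causal_graph: ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (T=", tab[["T"]], ", A=", tab[["A"]], ", P=", tab[["P"]],
      ", B=", tab[["B"]], ")\n", sep = "")
  invisible(x)
}

node_class_of <- function(graph, id) {
  m <- match(id, graph$nodes$id)
  if (anyNA(m)) stop("unknown node: ", id[which(is.na(m))[1L]])
  graph$nodes$node_class[m]
}

edges_of_type <- function(graph, types) {
  graph$edges[graph$edges$edge_type %in% types, , drop = FALSE]
}

#' Aggregate per-finding signs into an edge sign and confidence weight
#'
#' Individual curated findings each carry a sign in \{-1, 0, +1\}. The edge
#' direction is taken by strict majority vote among the nonzero finding
#' signs; the weight is the fraction of signed findings that agree with the
#' majority. A tie, or an all-zero finding list, yields sign 0 and weight 0
#' (ambiguous direction).
#'
#' @param signs integer vector of finding signs, each in \{-1, 0, +1\};
#'   must be nonempty.
#' @return list with components \code{sign} (integer) and \code{weight}
#'   (numeric in [0, 1]).
#' @export
#' @examples
#' aggregate_findings(c(1, 1, -1, 0))  # sign +1, weight 2/3
aggregate_findings <- function(signs) {
  if (length(signs) == 0L) stop("no findings")
  signs <- as.integer(signs)
  if (anyNA(signs) || any(!signs %in% c(-1L, 0L, 1L)))
    stop("finding signs must be -1, 0 or +1")
  n_plus <- sum(signs == 1L)
  n_minus <- sum(signs == -1L)
  n_signed <- n_plus + n_minus
  if (n_signed == 0L || n_plus == n_minus)
    return(list(sign = 0L, weight = 0))
  if (n_plus > n_minus)
    list(sign = 1L, weight = n_plus / n_signed)
  else
    list(sign = -1L, weight = n_minus / n_signed)
}

#' Read a causal network from tab-separated files
#'
#' The edge list is a TSV with header columns \code{source}, \code{target},
#' \code{edge_type}, and either pre-aggregated \code{sign} / \code{weight}
#' columns or a \code{findings} column holding comma-separated finding signs
#' (e.g. \code{"+1,+1,-1"}). Rows sharing the same (source, target,
#' edge_type) triple are merged by pooling their findings and re-aggregating
#' with [aggregate_findings()]; duplicate pre-aggregated rows are an error.
#' A SIF-style 3-column file (source, edge_type, target) is also accepted,
#' with signs defaulting per edge type.
#'
#' Node classes come from an optional two-column TSV (\code{node_id},
#' \code{node_class}). Without it, classes are inferred: targets of T edges
#' are genes, targets of P edges are processes, everything else defaults to
#' gene.
#'
#' @param path path to the edge-list TSV.
#' @param node_path optional path to the node-class TSV.
#' @param format \code{"edge_list"} (default) or \code{"sif"}.
#' @param sif_signs named integer vector giving the default sign per edge
#'   type for SIF input.
#' @return a [causal_graph()].
#' @export
load_network <- function(path, node_path = NULL,
                         format = c("edge_list", "sif"),
                         sif_signs = c(T = 1L, A = 1L, P = 1L, B = 0L)) {
  format <- match.arg(format)
  raw <- utils::read.delim(path, header = (format == "edge_list"),
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (format == "sif") {
    if (ncol(raw) < 3L) stop("SIF input needs 3 columns")
    raw <- data.frame(source = raw[[1L]], edge_type = raw[[2L]],
                      target = raw[[3L]], stringsAsFactors = FALSE)
    bad <- setdiff(unique(raw$edge_type), names(sif_signs))
    if (length(bad)) stop("load error: unknown edge_type '", bad[1L], "'")
    raw$sign <- as.integer(sif_signs[raw$edge_type])
    raw$weight <- ifelse(raw$sign == 0L, 0, 1)
    raw$findings <- NA_character_
  }
  need <- c("source", "target", "edge_type")
  if (!all(need %in% names(raw)))
    stop("load error: edge list needs columns source, target, edge_type")
  has_findings <- "findings" %in% names(raw) & !is.na(raw[["findings"]]) &
    nzchar(trimws(ifelse(is.na(raw[["findings"]]), "", raw[["findings"]])))
  if (!"findings" %in% names(raw)) has_findings <- rep(FALSE, nrow(raw))

  for (i in seq_len(nrow(raw))) {
    if (!has_findings[i] &&
        (!"sign" %in% names(raw) || is.na(raw$sign[i]) || !nzchar(raw$sign[i])))
      stop("load error in row ", i, ": needs sign/weight or findings")
  }

  key <- paste(raw$source, raw$target, raw$edge_type)
  merged <- lapply(split(seq_len(nrow(raw)), key), function(idx) {
    first <- idx[1L]
    if (length(idx) > 1L || any(has_findings[idx])) {
      if (!all(has_findings[idx]))
        stop("load error: duplicate pre-aggregated rows for edge ",
             raw$source[first], " -", raw$edge_type[first], "-> ",
             raw$target[first])
      pooled <- unlist(lapply(raw$findings[idx], parse_findings))
      ag <- aggregate_findings(pooled)
      data.frame(source = raw$source[first], target = raw$target[first],
                 edge_type = raw$edge_type[first], sign = ag$sign,
                 weight = ag$weight, stringsAsFactors = FALSE)
    } else {
      sg <- suppressWarnings(as.integer(raw$sign[first]))
      wt <- if ("weight" %in% names(raw))
        suppressWarnings(as.numeric(raw$weight[first])) else 1
      if (is.na(sg) || !sg %in% c(-1L, 0L, 1L))
        stop("load error in row ", first, ": sign '", raw$sign[first],
             "' outside {-1, 0, 1}")
      if (is.na(wt))
        stop("load error in row ", first, ": non-numeric weight")
      data.frame(source = raw$source[first], target = raw$target[first],
                 edge_type = raw$edge_type[first], sign = sg, weight = wt,
                 stringsAsFactors = FALSE)
    }
  })
  edges <- do.call(rbind, merged)
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        edge_type = character(), sign = integer(),
                        weight = numeric())
  edges <- edges[order(edges$source, edges$target, edges$edge_type), ,
                 drop = FALSE]

  if (!is.null(node_path)) {
    nt <- utils::read.delim(node_path, header = TRUE,
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    if (!all(c("node_id", "node_class") %in% names(nt)))
      stop("load error: node table needs columns node_id, node_class")
    nodes <- data.frame(id = nt$node_id, node_class = nt$node_class,
                        stringsAsFactors = FALSE)
    extra <- setdiff(unique(c(edges$source, edges$target)), nodes$id)
    if (length(extra))
      stop("load error: edge endpoint '", extra[1L],
           "' missing from node table")
  } else {
    nodes <- infer_node_classes(edges)
  }
  causal_graph(nodes, edges)
}

parse_findings <- function(s) {
  parts <- trimws(strsplit(s, ",", fixed = TRUE)[[1L]])
  parts <- parts[nzchar(parts)]
  v <- suppressWarnings(as.integer(gsub("^\\+", "", parts)))
  if (anyNA(v)) stop("load error: unparseable findings string '", s, "'")
  v
}

infer_node_classes <- function(edges) {
  ids <- unique(c(edges$source, edges$target))
  cls <- stats::setNames(rep("gene", length(ids)), ids)
  cls[unique(edges$target[edges$edge_type == "P"])] <- "process"
  conflict <- intersect(unique(edges$target[edges$edge_type == "T"]),
                        names(cls)[cls == "process"])
  if (length(conflict))
    stop("load error: node '", conflict[1L],
         "' is targeted by both T and P edges; supply a node table")
  data.frame(id = ids, node_class = unname(cls), stringsAsFactors = FALSE)
}

#' Write a causal network to tab-separated files
#'
#' Inverse of [load_network()] for pre-aggregated graphs: a round trip
#' reproduces the edge set, signs and weights exactly.
#'
#' @param graph a [causal_graph()].
#' @param path output path for the edge-list TSV.
#' @param node_path output path for the node-class TSV (optional).
#' @export
write_network <- function(graph, path, node_path = NULL) {
  e <- graph$edges[order(graph$edges$source, graph$edges$target,
                         graph$edges$edge_type), , drop = FALSE]
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(node_path)) {
    nt <- data.frame(node_id = graph$nodes$id,
                     node_class = graph$nodes$node_class)
    utils::write.table(nt, node_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Genes regulated by at least one transcription edge
#'
#' The universe used by the overlap statistics: every gene that is the
#' target of one or more T edges. Edges of other types never contribute.
#'
#' @param graph a [causal_graph()].
#' @return character vector of gene ids (possibly empty).
#' @export
regulated_gene_universe <- function(graph) {
  sort(unique(graph$edges$target[graph$edges$edge_type == "T"]))
}

#' Transcriptional in-degree of a regulated gene
#'
#' Number of distinct T edges targeting the gene (parallel raw records of
#' the same edge are merged at load time, so each regulator counts once).
#'
#' @param graph a [causal_graph()].
#' @param gene a gene id inside [regulated_gene_universe()].
#' @return nonnegative integer.
#' @export
in_degree_T <- function(graph, gene) {
  stopifnot(length(gene) == 1L)
  if (!gene %in% regulated_gene_universe(graph))
    stop("gene '", gene, "' is not in the regulated gene universe")
  sum(graph$edges$edge_type == "T" & graph$edges$target == gene)
}
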