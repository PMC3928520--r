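# Small constructed graphs used across the suite.

# build a causal_graph from an edge data.frame, inferring node classes:
# P-edge targets become processes, everything else is a gene unless
# overridden via `classes` (named vector id -> class).
mk_graph <- function(edges, extra_nodes = character(), classes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  ids <- unique(c(edges$source, edges$target, extra_nodes))
  cls <- stats::setNames(rep("gene", length(ids)), ids)
  if (nrow(edges))
    cls[unique(edges$target[edges$edge_type == "P"])] <- "process"
  if (!is.null(classes)) cls[names(classes)] <- classes
  causal_graph(data.frame(id = ids, node_class = unname(cls)), edges)
}

edge_row <- function(source, target, type = "T", sign = 1L, weight = 1) {
  data.frame(source = source, target = target, edge_type = type,
             sign = as.integer(sign), weight = weight,
             stringsAsFactors = FALSE)
}

# graph whose gene in-degrees are chosen exactly: gene i gets degs[i]
# distinct regulators
degree_toy <- function(degs) {
  genes <- sprintf("g%02d", seq_along(degs))
  regs <- sprintf("r%02d", seq_len(max(degs)))
  edges <- do.call(rbind, lapply(seq_along(degs), function(i)
    edge_row(regs[seq_len(degs[i])], genes[i])))
  mk_graph(edges)
}

# bare cna_hypothesis stub for exercising the Occam filter in isolation
mk_hyp <- function(root, depth, p, genes) {
  structure(list(root = root, depth = depth, overlap_pvalue = p,
                 regulated_genes = genes, activation_z = 0,
                 predicted_state = "none",
                 intermediate_regulators = character(),
                 n_targets = length(genes)), class = "cna_hypothesis")
}

# regulator R1 matches all six dataset signs, R2 only three
toy_ura <- function() {
  genes <- paste0("G", 1:6)
  edges <- rbind(
    edge_row("R1", genes, sign = 1L),
    edge_row("R2", genes, sign = c(1L, 1L, 1L, -1L, -1L, -1L)))
  list(graph = mk_graph(edges),
       dataset = causal_dataset(stats::setNames(rep(1L, 6), genes)))
}

# r2 perfectly relays r1: every dataset target of r1 is also under r2;
# r3 is a size-matched control with targets sampled at random
relay_toy <- function(seed, n_universe = 40L, n_shared = 8L) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_universe))
  shared <- genes[seq_len(n_shared)]
  ctrl <- genes[sample.int(n_universe, n_shared)]
  edges <- rbind(
    edge_row("r1", shared),
    edge_row("r2", shared),
    edge_row("r3", ctrl),
    edge_row("anchor", genes, sign = 0L, weight = 0),  # fills the universe
    edge_row("r1", "r2", type = "A"),
    edge_row("r1", "r3", type = "A"))
  extra <- sample(setdiff(genes, union(shared, ctrl)), 4L)
  ds_genes <- c(union(shared, ctrl), extra)
  ds_signs <- stats::setNames(rep(1L, length(ds_genes)), ds_genes)
  ds_signs[extra] <- sample(c(-1L, 1L), length(extra), replace = TRUE)
  list(graph = mk_graph(edges), dataset = causal_dataset(ds_signs))
}
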