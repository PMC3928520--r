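# Synthetic causal networks and planted-perturbation datasets.  These give
# every statistic in the package a ground truth to recover, at toy scale.

#' Generate a random causal network
#'
#' Builds a directed multigraph with the structure the analyses assume:
#' regulators carrying signed T edges into a gene pool, optional
#' regulator-to-regulator A edges, and optional gene-to-process P edges.
#' Out-degrees are either fixed or drawn from a discrete power law
#' (Pareto with minimum \code{out_degree} and exponent
#' \code{power_exponent}, capped at \code{n_genes}). Edge signs are +1 with
#' probability \code{activating_fraction}; weights are all 1
#' (\code{weight_law = "unit"}) or uniform on [0.5, 1]
#' (\code{"uniform"}). No self-edges are produced and the result is
#' deterministic given \code{seed}.
#'
#' @param n_regulators,n_genes,n_processes node counts (processes default
#'   to 0).
#' @param out_degree T edges per regulator (fixed law) or the power-law
#'   minimum.
#' @param degree_law \code{"fixed"} or \code{"power_law"}.
#' @param power_exponent Pareto exponent (> 1), default 2.5.
#' @param activating_fraction probability of a +1 edge sign (default 0.7).
#' @param a_density probability of an A edge for each ordered regulator
#'   pair (default 0.05).
#' @param p_edges_per_process gene sources sampled per process (default 5).
#' @param weight_law \code{"unit"} or \code{"uniform"}.
#' @param seed integer seed (required).
#' @return a [causal_graph()] with regulators \code{R...}, genes
#'   \code{G...} and processes \code{P...}.
#' @export
generate_network <- function(n_regulators, n_genes, n_processes = 0L,
                             out_degree = 20L,
                             degree_law = c("fixed", "power_law"),
                             power_exponent = 2.5,
                             activating_fraction = 0.7,
                             a_density = 0.05,
                             p_edges_per_process = 5L,
                             weight_law = c("unit", "uniform"),
                             seed) {
  degree_law <- match.arg(degree_law)
  weight_law <- match.arg(weight_law)
  stopifnot(n_regulators >= 0L, n_genes >= 0L, n_processes >= 0L,
            activating_fraction >= 0, activating_fraction <= 1)
  if (missing(seed)) stop("seed is required")
  set.seed(seed)

  regs <- sprintf("R%03d", seq_len(n_regulators))
  genes <- sprintf("G%04d", seq_len(n_genes))
  procs <- if (n_processes > 0L) sprintf("P%03d", seq_len(n_processes))
           else character()
  nodes <- data.frame(
    id = c(regs, genes, procs),
    node_class = c(rep("gene", n_regulators + n_genes),
                   rep("process", n_processes)),
    stringsAsFactors = FALSE)

  degs <- switch(degree_law,
    fixed = rep(as.integer(out_degree), n_regulators),
    power_law = pmin(n_genes,
                     floor(out_degree *
                             stats::runif(n_regulators)^(-1 /
                                                         (power_exponent - 1)))))
  if (any(degs > n_genes)) stop("out-degree exceeds the number of genes")

  rand_sign <- function(n)
    ifelse(stats::runif(n) < activating_fraction, 1L, -1L)
  rand_weight <- function(n)
    if (weight_law == "unit") rep(1, n) else stats::runif(n, 0.5, 1)

  t_edges <- do.call(rbind, lapply(seq_len(n_regulators), function(i) {
    tgt <- genes[sample.int(n_genes, degs[i])]
    data.frame(source = regs[i], target = tgt, edge_type = "T",
               sign = rand_sign(degs[i]), weight = rand_weight(degs[i]),
               stringsAsFactors = FALSE)
  }))

  a_edges <- NULL
  if (n_regulators > 1L && a_density > 0) {
    pairs <- expand.grid(src = regs, tgt = regs, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$src != pairs$tgt, , drop = FALSE]
    sel <- stats::runif(nrow(pairs)) < a_density
    if (any(sel)) {
      n <- sum(sel)
      a_edges <- data.frame(source = pairs$src[sel], target = pairs$tgt[sel],
                            edge_type = "A", sign = rand_sign(n),
                            weight = rand_weight(n), stringsAsFactors = FALSE)
    }
  }

  p_edges <- NULL
  if (n_processes > 0L && p_edges_per_process > 0L) {
    p_edges <- do.call(rbind, lapply(procs, function(pr) {
      src <- genes[sample.int(n_genes, min(p_edges_per_process, n_genes))]
      n <- length(src)
      data.frame(source = src, target = pr, edge_type = "P",
                 sign = rand_sign(n), weight = rand_weight(n),
                 stringsAsFactors = FALSE)
    }))
  }

  edges <- rbind(t_edges, a_edges, p_edges)
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        edge_type = character(), sign = integer(),
                        weight = numeric())
  causal_graph(nodes, edges)
}

#' Plant a perturbed-regulator dataset
#'
#' Emulates the transcriptional footprint of a regulator in a known
#' activation state: each signed T target of the regulator enters the
#' dataset with sign = edge sign (activated) or its negation (inhibited),
#' independently flipped with probability 1 - \code{fidelity}; a further
#' \code{n_background} regulated genes outside the target set enter with
#' uniform random signs, keeping the enrichment margins nontrivial.
#' Deterministic given \code{seed}.
#'
#' @param graph a [causal_graph()].
#' @param regulator the planted regulator; needs at least one signed T
#'   edge.
#' @param state \code{"activated"} or \code{"inhibited"}.
#' @param fidelity probability in [0.5, 1] that a target keeps its implied
#'   sign (default 0.9).
#' @param n_background number of random non-target genes added (default
#'   60).
#' @param seed integer seed (required).
#' @return a [causal_dataset()].
#' @export
plant_perturbation <- function(graph, regulator,
                               state = c("activated", "inhibited"),
                               fidelity = 0.9, n_background = 60L, seed) {
  state <- match.arg(state)
  stopifnot(fidelity >= 0.5, fidelity <= 1)
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  tg <- regulator_targets(graph, regulator)
  tg <- tg[tg$sign != 0L, , drop = FALSE]
  if (nrow(tg) == 0L) stop("regulator has no signed T edges")
  dir <- if (state == "activated") 1L else -1L
  flip <- ifelse(stats::runif(nrow(tg)) < fidelity, 1L, -1L)
  signs <- stats::setNames(tg$sign * dir * flip, tg$gene)
  pool <- setdiff(regulated_gene_universe(graph), tg$gene)
  if (n_background > length(pool))
    stop("n_background exceeds available non-target genes")
  if (n_background > 0L) {
    bg <- pool[sample.int(length(pool), n_background)]
    signs <- c(signs, stats::setNames(
      ifelse(stats::runif(n_background) < 0.5, 1L, -1L), bg))
  }
  causal_dataset(signs)
}
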