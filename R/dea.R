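# Downstream Effects Analysis: scoring biological processes through P edges
# with the causal direction reversed relative to upstream analysis.

#' Genes regulating a biological process
#'
#' Sources of P edges into the process, each with that edge's sign and
#' weight. Edges of other types into the process node are ignored.
#'
#' @param graph a [causal_graph()].
#' @param process a node id of class process.
#' @return data.frame with columns \code{gene}, \code{sign}, \code{weight}.
#' @export
process_regulators <- function(graph, process) {
  stopifnot(length(process) == 1L)
  if (node_class_of(graph, process) != "process")
    stop("node '", process, "' is not a process")
  e <- graph$edges
  sel <- e$edge_type == "P" & e$target == process
  data.frame(gene = e$source[sel], sign = e$sign[sel], weight = e$weight[sel],
             stringsAsFactors = FALSE)
}

#' Downstream Effects Analysis
#'
#' Predicts which biological processes are causally affected by the observed
#' expression changes, and in which direction. The machinery is that of
#' [run_ura()] with the edge direction reversed: for each process, the
#' genes carrying P edges into it play the role the targets play in URA.
#' The overlap p-value is an ordinary enrichment test with the universe of
#' all genes holding at least one P edge; the activation Z-score matches
#' edge signs against dataset signs, and its sign predicts whether the
#' process is increased or decreased. Bias metrics are computed exactly as
#' for regulators.
#'
#' @param graph a [causal_graph()] with at least one P edge.
#' @param dataset a [causal_dataset()] restricted to the network.
#' @param z_threshold direction-call threshold (default 2).
#' @param mu_threshold bias flag threshold (default 0.25).
#' @return data.frame of class \code{dea_result}, one row per process with
#'   nonzero dataset overlap, sorted like a URA table. Columns: process,
#'   predicted_direction, activation_z, corrected_z, bias_mu, bias_flagged,
#'   overlap_pvalue, n_genes, genes.
#' @export
run_dea <- function(graph, dataset, z_threshold = 2, mu_threshold = 0.25) {
  pe <- edges_of_type(graph, "P")
  if (nrow(pe) == 0L) stop("graph has no P edges")
  universe <- sort(unique(pe$source))
  ds <- unclass(dataset)
  ds_u <- ds[names(ds) %in% universe]
  d_d <- if (length(ds)) mean(ds) else NA_real_

  procs <- sort(unique(pe$target))
  rows <- lapply(procs, function(pr) {
    sel <- pe$target == pr
    genes <- pe$source[sel]; sgn <- pe$sign[sel]; wt <- pe$weight[sel]
    in_d <- genes %in% names(ds_u)
    if (!any(in_d)) return(NULL)
    p <- overlap_pvalue(length(universe), length(genes), length(ds_u),
                        sum(in_d))
    zi <- in_d & sgn != 0L & wt > 0
    z <- cz <- NA_real_; mu <- NA_real_; flagged <- NA
    if (any(sgn != 0L)) {
      mu <- d_d * mean(sgn[sgn != 0L])
      flagged <- abs(mu) > mu_threshold
    }
    if (any(zi)) {
      conc <- sgn[zi] * ds_u[genes[zi]]
      z <- activation_zscore(wt[zi], conc)
      if (!is.na(mu) && abs(mu) < 1) cz <- corrected_zscore(wt[zi], conc, mu)
    }
    dir <- c(activated = "increased", inhibited = "decreased",
             none = "none")[[predict_state(z, z_threshold)]]
    data.frame(process = pr, predicted_direction = dir, activation_z = z,
               corrected_z = cz, bias_mu = mu, bias_flagged = flagged,
               overlap_pvalue = p, n_genes = sum(in_d),
               genes = paste(sort(genes[in_d]), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(process = character(), predicted_direction = character(),
                      activation_z = numeric(), corrected_z = numeric(),
                      bias_mu = numeric(), bias_flagged = logical(),
                      overlap_pvalue = numeric(), n_genes = integer(),
                      genes = character(), stringsAsFactors = FALSE)
  } else {
    az <- abs(res$activation_z)
    az[is.na(az)] <- -Inf
    res <- res[order(-az, res$overlap_pvalue, res$process), , drop = FALSE]
    rownames(res) <- NULL
  }
  structure(res, class = c("dea_result", "data.frame"))
}

#' @export
print.dea_result <- function(x, n = 10L, ...) {
  cat("Downstream Effects Analysis: ", nrow(x), " process(es)\n", sep = "")
  top <- utils::head(as.data.frame(x)[, c("process", "predicted_direction",
                                          "activation_z", "overlap_pvalue",
                                          "n_genes")], n)
  top$activation_z <- signif(top$activation_z, 4)
  top$overlap_pvalue <- signif(top$overlap_pvalue, 4)
  print(top, row.names = FALSE)
  if (nrow(x) > n) cat("... and ", nrow(x) - n, " more\n", sep = "")
  invisible(x)
}
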