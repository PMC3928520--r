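# Upstream Regulator Analysis: overlap enrichment and activation Z-scores.

#' Transcriptional targets of a regulator
#'
#' Genes reachable from the regulator through exactly one T edge, each
#' carrying that edge's sign and weight. A and B edges are excluded; a
#' sign-0 T edge (protein-DNA binding with ambiguous direction) is retained
#' here and enters the overlap p-value, but is excluded later from the
#' activation Z-score.
#'
#' @param graph a [causal_graph()].
#' @param regulator a node id; any class except process.
#' @return data.frame with columns \code{gene}, \code{sign}, \code{weight}.
#' @export
regulator_targets <- function(graph, regulator) {
  stopifnot(length(regulator) == 1L)
  cls <- node_class_of(graph, regulator)
  if (cls == "process") stop("processes cannot be URA regulators")
  e <- graph$edges
  sel <- e$edge_type == "T" & e$source == regulator
  data.frame(gene = e$target[sel], sign = e$sign[sel], weight = e$weight[sel],
             stringsAsFactors = FALSE)
}

#' One-sided overlap p-value
#'
#' Enrichment of a regulator's target set in the dataset under the
#' hypergeometric null of a random dataset of fixed size drawn from the
#' universe: P(X >= n_overlap) with margins (n_targets, n_dataset) in a
#' universe of size n_universe (one-sided Fisher exact test).
#'
#' @param n_universe size of the gene universe (genes under >= 1 T edge).
#' @param n_targets number of universe genes targeted by the regulator.
#' @param n_dataset number of dataset genes inside the universe.
#' @param n_overlap observed overlap between targets and dataset.
#' @return p-value in (0, 1].
#' @export
#' @examples
#' overlap_pvalue(20, 5, 6, 4)
overlap_pvalue <- function(n_universe, n_targets, n_dataset, n_overlap) {
  stopifnot(length(n_universe) == 1L, length(n_targets) == 1L,
            length(n_dataset) == 1L, length(n_overlap) == 1L)
  if (n_universe < 1L) stop("empty universe")
  if (n_targets < 0L || n_targets > n_universe ||
      n_dataset < 0L || n_dataset > n_universe)
    stop("margins exceed the universe")
  if (n_overlap < 0L || n_overlap > min(n_targets, n_dataset))
    stop("overlap exceeds its margins")
  stats::phyper(n_overlap - 1, n_targets, n_universe - n_targets, n_dataset,
                lower.tail = FALSE)
}

#' Activation Z-score
#'
#' Standardized weighted sum of concordances between edge signs and dataset
#' regulation signs: z = sum(w * x) / sqrt(sum(w^2)), where each x is +1
#' when the regulation observed for a gene matches the direction the edge
#' predicts under regulator activation, and -1 otherwise. Under the null of
#' independent random signs, z is approximately standard normal for large
#' overlaps; its sign predicts the activation state.
#'
#' @param weight positive edge weights (one per overlapping signed edge).
#' @param concordance matching values in \{-1, +1\}.
#' @return the Z-score, or NA when no signed overlap edges exist.
#' @export
#' @examples
#' activation_zscore(rep(1, 4), rep(1, 4))  # 2.0
activation_zscore <- function(weight, concordance) {
  stopifnot(length(weight) == length(concordance))
  if (length(weight) == 0L) return(NA_real_)
  if (any(weight <= 0)) stop("weights must be positive")
  if (any(!concordance %in% c(-1, 1)))
    stop("concordance values must be -1 or +1")
  sum(weight * concordance) / sqrt(sum(weight^2))
}

#' Bias metrics for the sign-flipping null
#'
#' The plain activation Z-score assumes each concordance is +1/-1 with equal
#' probability. When the dataset signs and the regulator's downstream edge
#' signs are both skewed, the null expectation of the concordance is
#' mu = d_D * d_R, where d_D is the mean dataset sign over all dataset genes
#' and d_R the mean edge sign over the regulator's nonzero-sign target
#' edges. Regulators with |mu| above \code{mu_threshold} are flagged: their
#' plain Z-score should not be used for significance calls.
#'
#' @param dataset a [causal_dataset()]; nonempty.
#' @param targets data.frame as returned by [regulator_targets()], with at
#'   least one nonzero-sign row.
#' @param mu_threshold flagging threshold on |mu| (default 0.25).
#' @return list with \code{bias_dataset}, \code{bias_regulator},
#'   \code{bias_mu}, \code{flagged}.
#' @export
bias_metrics <- function(dataset, targets, mu_threshold = 0.25) {
  if (length(dataset) == 0L) stop("empty dataset")
  signed <- targets$sign[targets$sign != 0L]
  if (length(signed) == 0L) stop("regulator has no signed target edges")
  d_d <- mean(unclass(dataset))
  d_r <- mean(signed)
  mu <- d_d * d_r
  list(bias_dataset = d_d, bias_regulator = d_r, bias_mu = mu,
       flagged = abs(mu) > mu_threshold)
}

#' Bias-corrected activation Z-score
#'
#' Standardizes the weighted concordance sum against a skewed null in which
#' each concordance has expectation mu and variance 1 - mu^2:
#' z_c = (sum(w x) - mu * sum(w)) / sqrt((1 - mu^2) * sum(w^2)).
#' Reduces exactly to [activation_zscore()] at mu = 0.
#'
#' @param weight positive edge weights; nonempty.
#' @param concordance matching values in \{-1, +1\}.
#' @param bias_mu the null concordance expectation, |bias_mu| < 1.
#' @return the corrected Z-score.
#' @export
#' @examples
#' corrected_zscore(rep(1, 4), rep(1, 4), 0.6)  # 1.0
corrected_zscore <- function(weight, concordance, bias_mu) {
  stopifnot(length(weight) == length(concordance), length(weight) > 0L)
  if (any(weight <= 0)) stop("weights must be positive")
  if (abs(bias_mu) >= 1) stop("degenerate null (zero variance)")
  (sum(weight * concordance) - bias_mu * sum(weight)) /
    sqrt((1 - bias_mu^2) * sum(weight^2))
}

#' Predict an activation state from a Z-score
#'
#' @param z a Z-score (NA allowed).
#' @param z_threshold positive call threshold (default 2).
#' @return \code{"activated"}, \code{"inhibited"} or \code{"none"}.
#' @export
predict_state <- function(z, z_threshold = 2) {
  stopifnot(z_threshold > 0)
  ifelse(is.na(z), "none",
         ifelse(z >= z_threshold, "activated",
                ifelse(z <= -z_threshold, "inhibited", "none")))
}

#' Upstream Regulator Analysis
#'
#' Scores every candidate regulator (any non-process node with at least one
#' T edge and at least one target in the dataset) by (i) the one-sided
#' overlap p-value of its target set against the dataset in the universe of
#' T-regulated genes, and (ii) the activation Z-score of the sign pattern
#' match, together with the bias diagnostics and the bias-corrected
#' Z-score. Sign-0 edges count toward the overlap but not toward Z.
#'
#' @param graph a [causal_graph()] with at least one T edge.
#' @param dataset a [causal_dataset()] already restricted to the network
#'   (see [restrict_to_network()]).
#' @param z_threshold activation-call threshold (default 2).
#' @param mu_threshold bias flag threshold on |mu| (default 0.25).
#' @return data.frame of class \code{ura_result}, one row per regulator,
#'   sorted by |activation_z| decreasing (NA last), ties by overlap p-value
#'   then regulator id. Columns: regulator, predicted_state, activation_z,
#'   corrected_z, bias_mu, bias_dataset, bias_regulator, bias_flagged,
#'   overlap_pvalue, overlap_size, n_targets, target_genes (comma-joined
#'   overlap genes).
#' @export
run_ura <- function(graph, dataset, z_threshold = 2, mu_threshold = 0.25) {
  universe <- regulated_gene_universe(graph)
  if (length(universe) == 0L) stop("graph has no T edges")
  ds <- unclass(dataset)
  ds_u <- ds[names(ds) %in% universe]
  if (length(ds_u) == 0L) stop("no regulated dataset genes")
  d_d <- if (length(ds)) mean(ds) else NA_real_

  te <- edges_of_type(graph, "T")
  cand <- unique(te$source)
  cand <- cand[node_class_of(graph, cand) != "process"]
  rows <- lapply(sort(cand), function(r) {
    sel <- te$source == r
    genes <- te$target[sel]; sgn <- te$sign[sel]; wt <- te$weight[sel]
    in_d <- genes %in% names(ds_u)
    n_overlap <- sum(in_d)
    if (n_overlap == 0L) return(NULL)
    p <- overlap_pvalue(length(universe), length(genes), length(ds_u),
                        n_overlap)
    # Z: signed, positively weighted overlap edges only
    zi <- in_d & sgn != 0L & wt > 0
    z <- cz <- NA_real_
    d_r <- mu <- NA_real_; flagged <- NA
    if (any(sgn != 0L)) {
      d_r <- mean(sgn[sgn != 0L])
      mu <- d_d * d_r
      flagged <- abs(mu) > mu_threshold
    }
    if (any(zi)) {
      conc <- sgn[zi] * ds_u[genes[zi]]
      z <- activation_zscore(wt[zi], conc)
      if (!is.na(mu) && abs(mu) < 1)
        cz <- corrected_zscore(wt[zi], conc, mu)
    }
    data.frame(regulator = r, predicted_state = predict_state(z, z_threshold),
               activation_z = z, corrected_z = cz, bias_mu = mu,
               bias_dataset = d_d, bias_regulator = d_r,
               bias_flagged = flagged, overlap_pvalue = p,
               overlap_size = n_overlap, n_targets = length(genes),
               target_genes = paste(sort(genes[in_d]), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no regulated dataset genes")
  az <- abs(res$activation_z)
  az[is.na(az)] <- -Inf  # undefined Z sorts after every finite Z
  res <- res[order(-az, res$overlap_pvalue, res$regulator), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("ura_result", "data.frame"))
}

#' @export
print.ura_result <- function(x, n = 10L, ...) {
  cat("Upstream Regulator Analysis: ", nrow(x), " regulator(s)\n", sep = "")
  top <- utils::head(as.data.frame(x)[, c("regulator", "predicted_state",
                                          "activation_z", "corrected_z",
                                          "overlap_pvalue", "overlap_size")],
                     n)
  top$activation_z <- signif(top$activation_z, 4)
  top$corrected_z <- signif(top$corrected_z, 4)
  top$overlap_pvalue <- signif(top$overlap_pvalue, 4)
  print(top, row.names = FALSE)
  if (nrow(x) > n) cat("... and ", nrow(x) - n, " more\n", sep = "")
  invisible(x)
}
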