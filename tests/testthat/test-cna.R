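test_that("pruning keeps signed confident T/A edges at unit weight", {
  edges <- rbind(edge_row("R1", "G1", sign = 1L, weight = 0.9),
                 edge_row("R1", "G2", sign = -1L, weight = 0.1),
                 edge_row("R1", "G3", sign = 0L, weight = 0),
                 edge_row("R1", "R2", type = "A", sign = -1L, weight = 0.5),
                 edge_row("G1", "Apop", type = "P", sign = 1L, weight = 1),
                 edge_row("R1", "R3", type = "B", sign = 0L, weight = 0))
  g <- mk_graph(edges)
  p <- prune_graph(g, delta = 0.25)
  expect_setequal(p$edges$target, c("G1", "R2"))
  expect_true(all(p$edges$weight == 1))
  # a vacuous cutoff keeps every signed T/A edge
  p0 <- prune_graph(g, delta = 0)
  expect_setequal(p0$edges$target, c("G1", "G2", "R2"))
  expect_false("G3" %in% p0$edges$target)  # ambiguous sign always dropped
})

test_that("path signs multiply along the chain", {
  expect_equal(path_sign(c(1, -1)), -1)
  expect_equal(path_sign(c(-1, -1)), 1)
  expect_equal(path_sign(c(1, 1, 1)), 1)
  expect_error(path_sign(numeric()), "empty")
  expect_error(path_sign(c(1, 0)), "sign")
})

test_that("virtual edges keep shortest consistent paths only", {
  # direct T edge beats a longer consistent path; sign from the short one
  g1 <- prune_graph(mk_graph(rbind(
    edge_row("r", "G", sign = -1L),
    edge_row("r", "m", type = "A", sign = 1L),
    edge_row("m", "G", sign = 1L))))
  ve <- virtual_edges_for_root(g1, "r")
  expect_length(ve, 1L)
  expect_equal(ve[[1]]$length, 1L)
  expect_equal(ve[[1]]$sign, -1L)

  # two shortest paths of opposite composite sign suppress the gene
  g2 <- prune_graph(mk_graph(rbind(
    edge_row("r", "m1", type = "A", sign = 1L),
    edge_row("r", "m2", type = "A", sign = -1L),
    edge_row("m1", "G", sign = 1L),
    edge_row("m2", "G", sign = 1L))))
  expect_length(virtual_edges_for_root(g2, "r"), 0L)

  # A then T: a single two-hop virtual edge with the product sign
  g3 <- prune_graph(mk_graph(rbind(
    edge_row("r", "a", type = "A", sign = 1L),
    edge_row("a", "G", sign = 1L))))
  ve3 <- virtual_edges_for_root(g3, "r")
  expect_length(ve3, 1L)
  expect_equal(ve3[[1]][c("target", "length", "sign")],
               list(target = "G", length = 2L, sign = 1L))

  # the terminal hop must be transcriptional: an A edge into a gene ends no path
  g4 <- prune_graph(mk_graph(rbind(
    edge_row("r", "G", type = "A", sign = 1L),
    edge_row("x", "G", sign = 1L))))
  expect_length(virtual_edges_for_root(g4, "r"), 0L)

  expect_error(virtual_edges_for_root(
    prune_graph(mk_graph(edge_row("G1", "Apop", type = "P"),
                         extra_nodes = "r")), "Apop"), "process")
})

test_that("depth-1 hypotheses equal URA on the pruned unit-weight graph", {
  g <- generate_network(10, 80, out_degree = 12, weight_law = "uniform",
                        seed = 31)
  d <- plant_perturbation(g, "R003", "activated", fidelity = 0.8,
                          n_background = 25, seed = 32)
  pruned <- prune_graph(g, delta = 0.25)
  ura <- run_ura(pruned, d)
  for (r in ura$regulator) {
    hyps <- score_hypotheses(pruned, d, r, max_K = 1L)
    expect_length(hyps, 1L)
    h <- hyps[[1]]
    i <- match(r, ura$regulator)
    expect_equal(h$overlap_pvalue, ura$overlap_pvalue[i])
    expect_equal(h$activation_z, ura$activation_z[i])
    expect_equal(h$predicted_state, ura$predicted_state[i])
  }
})

test_that("regulated gene sets are nested over depth", {
  g <- generate_network(12, 100, out_degree = 10, a_density = 0.15, seed = 41)
  d <- plant_perturbation(g, "R001", "activated", n_background = 30,
                          seed = 42)
  pruned <- prune_graph(g)
  for (r in c("R001", "R002", "R005")) {
    hyps <- score_hypotheses(pruned, d, r, max_K = 3L)
    if (length(hyps) < 2L) next
    depths <- vapply(hyps, `[[`, integer(1L), "depth")
    for (i in seq_along(hyps)[-1]) {
      expect_true(all(hyps[[i - 1]]$regulated_genes %in%
                        hyps[[i]]$regulated_genes))
      expect_gte(hyps[[i]]$n_targets, hyps[[i - 1]]$n_targets)
    }
  }
})

test_that("the Occam filter keeps deeper hypotheses only when they add value", {
  h1 <- mk_hyp("r", 1L, 1e-3, c("a", "b"))
  # more significant and a different gene set: both kept
  kept <- filter_hypotheses(list(h1, mk_hyp("r", 2L, 1e-5, c("a", "b", "c"))))
  expect_length(kept, 2L)
  # identical gene set: dropped even when more significant
  kept <- filter_hypotheses(list(h1, mk_hyp("r", 2L, 1e-5, c("a", "b"))))
  expect_length(kept, 1L)
  # non-improving p: dropped
  kept <- filter_hypotheses(list(h1, mk_hyp("r", 2L, 1e-3, c("a", "b", "c"))))
  expect_length(kept, 1L)
  # a K=3 must beat every retained shallower hypothesis
  kept <- filter_hypotheses(list(h1, mk_hyp("r", 2L, 1e-5, c("a", "b", "c")),
                                 mk_hyp("r", 3L, 1e-4, c("a", "b", "c", "d"))))
  expect_equal(vapply(kept, `[[`, integer(1L), "depth"), c(1L, 2L))
  # roots are filtered independently
  kept <- filter_hypotheses(list(h1, mk_hyp("s", 2L, 0.5, "x")))
  expect_length(kept, 2L)
})

test_that("retained hypotheses are sign-consistent along their paths", {
  g <- generate_network(12, 100, out_degree = 10, a_density = 0.15, seed = 51)
  d <- plant_perturbation(g, "R001", "activated", n_background = 30,
                          seed = 52)
  res <- run_cna(g, d)
  for (h in attr(res, "hypotheses")) {
    pruned <- prune_graph(g)
    e <- pruned$edges
    esign <- stats::setNames(e$sign, paste(e$source, e$target))
    for (j in seq_len(nrow(h$virtual_edges))) {
      ve <- h$virtual_edges[j, ]
      paths <- virtual_edges_for_root(pruned, h$root,
                                      max_K = h$depth)
      tgt_match <- vapply(paths, function(v) v$target == ve$target,
                          logical(1L))
      v <- paths[tgt_match][[1]]
      for (pn in v$paths) {
        steps <- paste(pn[-length(pn)], pn[-1])
        expect_equal(prod(esign[steps]), ve$sign)
      }
    }
  }
})

test_that("a root wired through two intermediates emerges only at depth 3", {
  genes <- sprintf("g%02d", 1:30)
  edges <- rbind(
    edge_row("root", "i1", type = "A", sign = -1L),
    edge_row("i1", "i2", type = "A", sign = 1L),
    edge_row("i2", genes[1:8], sign = -1L),
    edge_row("filler", genes, sign = 0L, weight = 0))
  g <- mk_graph(edges)
  # all eight planted genes up-regulated: net path sign from root is +1
  d <- causal_dataset(stats::setNames(rep(1L, 12), genes[1:12]))
  pruned <- prune_graph(g)
  hyps <- score_hypotheses(pruned, d, "root", max_K = 3L)
  expect_equal(vapply(hyps, `[[`, integer(1L), "depth"), 3L)
  h <- hyps[[1]]
  expect_gte(abs(h$activation_z), 2)
  expect_equal(h$predicted_state, "activated")
  expect_setequal(h$intermediate_regulators, c("i1", "i2"))
  expect_length(score_hypotheses(pruned, d, "root", max_K = 1L), 0L)
})

test_that("run_cna returns an ordered, filtered hypothesis table", {
  g <- generate_network(10, 80, out_degree = 12, a_density = 0.2, seed = 61)
  d <- plant_perturbation(g, "R002", "activated", n_background = 20,
                          seed = 62)
  res <- run_cna(g, d)
  expect_s3_class(res, "cna_result")
  expect_false(is.unsorted(res$overlap_pvalue))
  expect_true(all(res$depth <= 3L))
  expect_true(all(res$n_regulated >= 1L))
})
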