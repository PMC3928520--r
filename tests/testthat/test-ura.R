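test_that("regulator targets come from T edges only, keeping sign-0 edges", {
  g <- mk_graph(rbind(edge_row("R1", "G1", sign = 1L, weight = 1),
                      edge_row("R1", "G2", sign = -1L, weight = 0.5),
                      edge_row("R1", "G3", sign = 0L, weight = 0),
                      edge_row("R1", "R2", type = "A")),
                classes = c(Apop = "process"), extra_nodes = "Apop")
  tg <- regulator_targets(g, "R1")
  expect_equal(tg[order(tg$gene), ],
               data.frame(gene = c("G1", "G2", "G3"), sign = c(1L, -1L, 0L),
                          weight = c(1, 0.5, 0)),
               ignore_attr = TRUE)
  expect_equal(nrow(regulator_targets(g, "R2")), 0L)
  expect_error(regulator_targets(g, "Apop"), "processes cannot")
})

test_that("overlap p-value matches exhaustive enumeration", {
  # frozen value computed with enum_overlap_tail over all C(20,6) draws
  expect_equal(overlap_pvalue(20, 5, 6, 4), 540 / 38760, tolerance = 1e-12)
  expect_equal(overlap_pvalue(20, 5, 6, 4), enum_overlap_tail(20, 5, 6, 4),
               tolerance = 1e-12)
  for (u in c(4L, 6L, 8L)) {
    for (d in 0:u) {
      draws <- if (d > 0) utils::combn(u, d) else NULL
      for (t in 0:u) {
        ov <- if (is.null(draws)) 0L else colSums(draws <= t)
        for (k in 0:min(t, d))
          expect_equal(overlap_pvalue(u, t, d, k), mean(ov >= k),
                       tolerance = 1e-12)
      }
    }
  }
})

test_that("overlap p-value margins are validated and degenerate cases hit 1", {
  expect_equal(overlap_pvalue(20, 5, 6, 0), 1)
  expect_equal(overlap_pvalue(10, 10, 4, 4), 1)  # targets fill the universe
  expect_error(overlap_pvalue(10, 11, 4, 2), "margins")
  expect_error(overlap_pvalue(10, 5, 4, 5), "overlap")
  expect_error(overlap_pvalue(0, 0, 0, 0), "empty universe")
})

test_that("activation Z-score standardizes the weighted concordance sum", {
  expect_equal(activation_zscore(rep(1, 4), rep(1, 4)), 2)
  expect_equal(activation_zscore(rep(1, 4), rep(-1, 4)), -2)
  # oracle: all 2^3 sign assignments have mean 0, sd sqrt(6); observed 2/sqrt(6)
  expect_equal(activation_zscore(c(2, 1, 1), c(1, 1, -1)), 2 / sqrt(6))
  expect_true(is.na(activation_zscore(numeric(), numeric())))
  expect_error(activation_zscore(c(1, 0), c(1, 1)), "positive")
  expect_error(activation_zscore(1, 0.5), "concordance")
})

test_that("the sign-flip null behind z has mean 0 and unit variance", {
  w <- c(2, 1, 1)
  signs <- expand.grid(rep(list(c(-1, 1)), 3))
  sums <- apply(signs, 1, function(x) sum(w * x))
  expect_equal(mean(sums), 0)
  expect_equal(sqrt(mean(sums^2)), sqrt(sum(w^2)))
  z <- apply(signs, 1, function(x) activation_zscore(w, x))
  expect_equal(mean(z), 0)
  expect_equal(mean(z^2), 1)
})

test_that("bias metrics take the product of mean dataset and edge signs", {
  ds <- causal_dataset(stats::setNames(c(rep(1L, 8), rep(-1L, 2)),
                                       paste0("G", 1:10)))
  tg <- data.frame(gene = paste0("G", 1:10), sign = rep(1L, 10),
                   weight = rep(1, 10))
  b <- bias_metrics(ds, tg)
  expect_equal(b$bias_dataset, 0.6)
  expect_equal(b$bias_regulator, 1)
  expect_equal(b$bias_mu, 0.6)
  expect_true(b$flagged)

  bal <- causal_dataset(stats::setNames(rep(c(1L, -1L), 5), paste0("G", 1:10)))
  b2 <- bias_metrics(bal, tg)
  expect_equal(b2$bias_mu, 0)
  expect_false(b2$flagged)

  expect_error(bias_metrics(causal_dataset(integer()), tg), "empty")
  tg0 <- transform(tg, sign = 0L, weight = 0)
  expect_error(bias_metrics(ds, tg0), "no signed")
})

test_that("corrected z standardizes against the skewed null", {
  expect_equal(corrected_zscore(rep(1, 4), rep(1, 4), 0.6), 1)
  w <- c(2, 1, 1); x <- c(1, 1, -1)
  expect_equal(corrected_zscore(w, x, 0), activation_zscore(w, x))
  expect_error(corrected_zscore(rep(1, 4), rep(1, 4), 1), "degenerate")
  # empirical standardization oracle at P(x = +1) = 0.8 (mu = 0.6)
  set.seed(1)
  draws <- matrix(sample(c(1, -1), 4 * 20000, TRUE, c(0.8, 0.2)), ncol = 4)
  zc <- apply(draws, 1, function(x) corrected_zscore(rep(1, 4), x, 0.6))
  expect_lt(abs(mean(zc)), 0.03)
  expect_lt(abs(stats::var(zc) - 1), 0.05)
})

test_that("state calls follow the z threshold", {
  expect_equal(predict_state(2.5), "activated")
  expect_equal(predict_state(-3), "inhibited")
  expect_equal(predict_state(1), "none")
  expect_equal(predict_state(NA_real_), "none")
  expect_equal(predict_state(1.5, z_threshold = 1), "activated")
})

test_that("run_ura ranks a fully concordant regulator first with z = sqrt(6)", {
  toy <- toy_ura()
  res <- run_ura(toy$graph, toy$dataset)
  expect_equal(res$regulator[1], "R1")
  expect_equal(res$activation_z[1], sqrt(6))
  expect_equal(res$predicted_state[1], "activated")
  expect_equal(res$activation_z[res$regulator == "R2"], 0)
  # overlap p equal for both (same margins)
  expect_equal(res$overlap_pvalue[1], res$overlap_pvalue[2])
  expect_equal(res$target_genes[1], paste(paste0("G", 1:6), collapse = ","))
})

test_that("flipping every dataset sign negates z and leaves p unchanged", {
  set.seed(5)
  for (i in 1:5) {
    g <- generate_network(8, 60, out_degree = 10, seed = 100 + i)
    d <- plant_perturbation(g, "R001", "activated", fidelity = 0.8,
                            n_background = 20, seed = 200 + i)
    flipped <- causal_dataset(-unclass(d))
    a <- run_ura(g, d); b <- run_ura(g, flipped)
    b <- b[match(a$regulator, b$regulator), ]
    expect_equal(b$activation_z, -a$activation_z)
    expect_equal(b$overlap_pvalue, a$overlap_pvalue)
  }
})

test_that("adding a concordant unit-weight gene never decreases z", {
  set.seed(9)
  for (i in 1:30) {
    n <- sample(1:12, 1)
    w <- stats::runif(n, 0.2, 1)
    x <- sample(c(-1, 1), n, TRUE)
    z0 <- activation_zscore(w, x)
    z1 <- activation_zscore(c(w, 1), c(x, 1))
    expect_gte(z1, z0)
  }
})

test_that("regulators with only sign-0 edges score overlap but not z", {
  g <- mk_graph(rbind(edge_row("R1", paste0("G", 1:4)),
                      edge_row("R0", paste0("G", 1:3), sign = 0L, weight = 0)))
  d <- causal_dataset(stats::setNames(rep(1L, 4), paste0("G", 1:4)))
  res <- run_ura(g, d)
  r0 <- res[res$regulator == "R0", ]
  expect_true(is.na(r0$activation_z))
  expect_equal(r0$predicted_state, "none")
  expect_gt(r0$overlap_pvalue, 0)
  expect_equal(res$regulator[nrow(res)], "R0")  # NA z sorts last
})

test_that("run_ura rejects unusable inputs", {
  toy <- toy_ura()
  expect_error(run_ura(toy$graph, causal_dataset(c(ZZZ = 1L))),
               "no regulated dataset genes")
  g <- mk_graph(edge_row("R1", "R2", type = "A"))
  expect_error(run_ura(g, causal_dataset(c(R2 = 1L))), "no T edges")
})
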