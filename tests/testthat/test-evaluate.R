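test_that("edge and direction metrics match hand enumeration", {
  genes <- c("A", "B", "C")
  truth <- causal_graph(genes, directed = rbind(c("A", "B"), c("B", "C")))
  out <- causal_graph(genes, directed = rbind(c("A", "B"), c("C", "B"), c("A", "C")))
  ev <- eval_report(out, truth)
  ## adjacencies: out {AB, BC, AC}; truth {AB, BC}
  expect_equal(ev$tp_edge, 2); expect_equal(ev$fp_edge, 1); expect_equal(ev$fn_edge, 0)
  expect_equal(ev$precision_edge, 2 / 3); expect_equal(ev$recall_edge, 1)
  expect_equal(ev$f_edge, 0.8)
  ## directions: TP A>B; C>B reversed, A>C absent; B>C missed
  expect_equal(ev$tp_dir, 1); expect_equal(ev$fp_dir, 2); expect_equal(ev$fn_dir, 1)
  expect_equal(ev$precision_dir, 1 / 3); expect_equal(ev$recall_dir, 1 / 2)
  expect_equal(ev$f_dir, 0.4)
  expect_equal(ev$add, 1 / 2)
})

test_that("perfect, reversed and empty outputs hit the metric extremes", {
  genes <- c("A", "B", "C")
  truth <- causal_graph(genes, directed = rbind(c("A", "B"), c("B", "C")))
  perfect <- eval_report(truth, truth)
  for (m in c("precision_edge", "recall_edge", "f_edge",
              "precision_dir", "recall_dir", "f_dir", "add"))
    expect_equal(perfect[[m]], 1)
  reversed <- causal_graph(genes, directed = rbind(c("B", "A"), c("C", "B")))
  ev <- eval_report(reversed, truth)
  expect_equal(ev$precision_edge, 1); expect_equal(ev$recall_edge, 1)
  expect_equal(ev$tp_dir, 0); expect_equal(ev$add, 0)
  empty <- causal_graph(genes)
  ev0 <- eval_report(empty, truth)
  expect_equal(ev0$recall_edge, 0)
  expect_true(is.na(ev0$precision_edge))
  expect_true("precision_edge" %in% ev0$undefined)
})

test_that("an undirected output edge over a directed truth is a direction error", {
  genes <- c("A", "B")
  truth <- causal_graph(genes, directed = cbind("A", "B"))
  out <- causal_graph(genes, undirected = cbind("A", "B"))
  ev <- eval_report(out, truth)
  expect_equal(ev$tp_edge, 1)                 # adjacency found
  expect_equal(ev$tp_dir, 0)
  expect_equal(ev$fp_dir, 1)                  # undirected over directed truth
  expect_equal(ev$fn_dir, 1)                  # true edge not correctly directed
  expect_equal(ev$add, 0)
})

test_that("direction counts bound the edge counts", {
  set.seed(51)
  for (rep in 1:20) {
    genes <- paste0("g", 1:8)
    rnd_graph <- function() {
      pairs <- t(combn(genes, 2))
      pick <- runif(nrow(pairs)) < 0.3
      flip <- runif(nrow(pairs)) < 0.5
      m <- pairs[pick, , drop = FALSE]
      m[flip[pick], ] <- m[flip[pick], 2:1]
      und <- runif(sum(pick)) < 0.2
      causal_graph(genes, directed = m[!und, , drop = FALSE],
                   undirected = m[und, , drop = FALSE])
    }
    ev <- eval_report(rnd_graph(), rnd_graph())
    expect_lte(ev$tp_dir, ev$tp_edge)
    for (m in c("precision_edge", "recall_edge", "f_edge",
                "precision_dir", "recall_dir", "f_dir", "add")) {
      if (!is.na(ev[[m]])) { expect_gte(ev[[m]], 0); expect_lte(ev[[m]], 1) }
    }
  }
})

test_that("Fisher's exact comparison reproduces known values and enumeration", {
  p <- fisher_exact_direction_comparison(13, 14, 2, 11)
  expect_equal(signif(p, 2), 0.00024)
  expect_equal(fisher_exact_direction_comparison(5, 10, 5, 10), 1)
  ## symmetric under swapping the groups
  expect_equal(fisher_exact_direction_comparison(2, 11, 13, 14), p)
  ## brute-force hypergeometric enumeration oracle on random small tables
  fisher_oracle <- function(k1, n1, k2, n2) {
    K <- k1 + k2
    support <- max(0, K - n2):min(n1, K)
    probs <- dhyper(support, n1, n2, K)
    obs <- dhyper(k1, n1, n2, K)
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  set.seed(52)
  for (rep in 1:25) {
    n1 <- sample(1:10, 1); n2 <- sample(1:10, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    expect_equal(fisher_exact_direction_comparison(k1, n1, k2, n2),
                 fisher_oracle(k1, n1, k2, n2), tolerance = 1e-9,
                 info = sprintf("table %d/%d vs %d/%d", k1, n1, k2, n2))
  }
})

test_that("ROC/PR: extremes, random scores, and the tie-aware oracle", {
  genes <- paste0("g", 1:6)
  truth <- causal_graph(genes, directed = rbind(c("g1", "g2"), c("g3", "g4")))
  pairs <- expand.grid(source = genes, target = genes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  lab <- paste(pairs$source, pairs$target, sep = ">") %in% c("g1>g2", "g3>g4")
  ## perfect ranking
  s <- ifelse(lab, 1, 0) + seq_len(nrow(pairs)) * 1e-9
  expect_equal(roc_pr(cbind(pairs, score = s), truth)$auroc, 1, tolerance = 1e-6)
  ## pairwise-comparison oracle, including heavy ties
  auroc_oracle <- function(score, lab) {
    pos <- score[lab]; neg <- score[!lab]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  set.seed(53)
  for (rep in 1:10) {
    score <- sample(seq(0, 1, 0.25), nrow(pairs), replace = TRUE)
    got <- roc_pr(cbind(pairs, score = score), truth)$auroc
    expect_equal(got, auroc_oracle(score, lab), tolerance = 1e-12)
  }
  ## random scores on a larger problem: AUROC near 1/2
  set.seed(54)
  big_truth <- causal_graph(paste0("g", 1:40),
                            directed = cbind(paste0("g", 1:20), paste0("g", 21:40)))
  bp <- expand.grid(source = paste0("g", 1:40), target = paste0("g", 1:40),
                    stringsAsFactors = FALSE)
  bp <- bp[bp$source != bp$target, ]
  aucs <- replicate(20, roc_pr(cbind(bp, score = runif(nrow(bp))), big_truth)$auroc)
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
  ## one-class truth is flagged undefined
  none <- causal_graph(genes)
  expect_true(is.na(roc_pr(cbind(pairs, score = runif(nrow(pairs))), none)$auroc))
})

test_that("correlated-set intersections: degenerate identity and brute force", {
  set.seed(55)
  n_genes <- 120
  cur <- matrix(rnorm(200 * n_genes), 200, n_genes)
  panel <- expression_panel(X_cur = cur, X_cha = cur)   # velocity := current
  res <- correlated_set_intersections(panel, per_set_size = 100)
  expect_true(all(res$cc_ch == 100))                    # identical sets
  expect_true(all(res$cc_random >= 0 & res$cc_random <= 100))
  ## independent brute-force recomputation for a few genes
  panel2 <- expression_panel(X_cur = cur,
                             X_cha = matrix(rnorm(200 * n_genes), 200, n_genes))
  set.seed(56)
  res2 <- correlated_set_intersections(panel2, per_set_size = 20)
  for (i in c(1, 60, 120)) {
    r_cc <- cor(panel2$X_cur[, i], panel2$X_cur); r_cc[i] <- NA
    r_ch <- cor(panel2$X_cur[, i], panel2$X_cha); r_ch[i] <- NA
    top <- function(r) {
      o <- order(r, decreasing = TRUE, na.last = NA)
      c(head(o, 10), tail(o, 10))
    }
    expect_equal(res2$cc_ch[i], length(intersect(top(r_cc), top(r_ch))))
  }
})

test_that("benchmark harness: truth oracle is perfect; table is complete", {
  cfg <- sim_config(n_genes = 10, edge_prob = 0.3, n_cells_per_trace = 100)
  res <- benchmark(cfg, methods = c("truth", "approach0"), n_reps = 3,
                   seed = 57, threshold = 0.3)
  expect_equal(nrow(res), 6)
  tr <- res[res$method == "truth", ]
  expect_true(all(tr$precision_edge == 1 & tr$recall_edge == 1 & tr$add == 1))
  summ <- summarize_benchmark(res)
  expect_true(all(summ$mean[summ$method == "truth"] == 1))
  expect_true(all(summ$n_used + summ$n_undefined == 3))
  ## reproducible under the same master seed
  res2 <- benchmark(cfg, methods = c("truth", "approach0"), n_reps = 3,
                    seed = 57, threshold = 0.3)
  expect_identical(res, res2)
})
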