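test_that("random graph density matches the binomial expectation", {
  set.seed(11)
  expect_equal(nrow(random_causal_graph(50, 0)$directed), 0)
  n_draws <- 10000
  counts <- replicate(n_draws, nrow(random_causal_graph(50, 0.041)$directed))
  n_pairs <- 50 * 49 / 2
  expected <- 0.041 * n_pairs                       # ~50.2 edges on average
  se <- sqrt(n_pairs * 0.041 * (1 - 0.041) / n_draws)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("instant-mode graphs are acyclic, time-lagged may cycle", {
  set.seed(2)
  for (i in 1:50) {
    g <- random_causal_graph(12, 0.3, mode = "instant")
    expect_silent(citl:::topological_order(g))
  }
  cyc <- causal_graph(c("a", "b"), directed = rbind(c("a", "b"), c("b", "a")))
  expect_error(citl:::topological_order(cyc), "cycle")
})

test_that("previous expression follows the log-normal specification", {
  set.seed(3)
  cfg <- sim_config(n_genes = 50, n_cells_per_trace = 3000)
  prev <- draw_previous(cfg)
  ln <- log(prev$X_pre)
  m <- length(ln)
  expect_lt(abs(mean(ln) - 0), 3 * sqrt(0.04 / m))
  expect_lt(abs(var(as.vector(ln)) - 0.04), 4 * 0.04 * sqrt(2 / m))
  ## degenerate sigma: exactly exp(mu)
  cfg0 <- sim_config(n_genes = 5, n_cells_per_trace = 10, lognormal_sigma2 = 0,
                     lognormal_mu = 0.7)
  expect_true(all(draw_previous(cfg0)$X_pre == exp(0.7)))
})

test_that("multi-trace log-means track the drawn trace means", {
  set.seed(4)
  cfg <- sim_config(n_genes = 20, n_traces = 3, n_cells_per_trace = 1000)
  prev <- draw_previous(cfg)
  expect_equal(dim(prev$mu), c(3, 20))
  expect_true(all(prev$mu >= 0 & prev$mu <= 2))
  for (tr in 1:3) {
    rows <- prev$trace_labels == paste0("trace", tr)
    obs <- colMeans(log(prev$X_pre[rows, ]))
    expect_true(all(abs(obs - prev$mu[tr, ]) < 4 * sqrt(0.04 / 1000)))
  }
})

test_that("time-lagged propagation matches its closed forms at zero noise", {
  beta <- 0.8
  cfg <- sim_config(n_genes = 5, n_cells_per_trace = 200, noise_sd = 0, seed = 5)
  ## empty graph: X_cha = (beta^2 - beta) * X_pre = -0.16 * X_pre exactly
  g_empty <- causal_graph(paste0("g", 1:5))
  set.seed(5)
  pre <- draw_previous(cfg)
  panel <- propagate_time_lagged(g_empty, pre$X_pre, cfg)
  expect_equal(panel$X_cha, (beta^2 - beta) * pre$X_pre, ignore_attr = TRUE,
               tolerance = 1e-12)
  ## single edge A -> B: X_cha_B = -0.2 * X_cur_B + X_cur_A exactly
  g_ab <- causal_graph(paste0("g", 1:5), directed = cbind("g1", "g2"))
  panel2 <- propagate_time_lagged(g_ab, pre$X_pre, cfg)
  expect_equal(panel2$X_cha[, "g2"],
               (beta - 1) * panel2$X_cur[, "g2"] + panel2$X_cur[, "g1"],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("instant propagation follows topological order and rejects cycles", {
  cfg <- sim_config(n_genes = 3, n_cells_per_trace = 100, noise_sd = 0, seed = 6)
  g <- causal_graph(paste0("g", 1:3), directed = cbind("g1", "g2"))
  set.seed(6)
  pre <- draw_previous(cfg)
  panel <- propagate_instant(g, pre$X_pre, cfg)
  expect_equal(panel$X_cur[, "g2"],
               0.8 * pre$X_pre[, 2] + panel$X_cur[, "g1"],
               tolerance = 1e-12, ignore_attr = TRUE)
  ## no causes: instant and time-lagged coincide
  g0 <- causal_graph(paste0("g", 1:3))
  p_inst <- propagate_instant(g0, pre$X_pre, cfg)
  p_lag <- propagate_time_lagged(g0, pre$X_pre, cfg)
  expect_equal(p_inst$X_cha, p_lag$X_cha, tolerance = 1e-12)
  cyc <- causal_graph(paste0("g", 1:3),
                      directed = rbind(c("g1", "g2"), c("g2", "g1")))
  expect_error(propagate_instant(cyc, pre$X_pre, cfg), "cycle")
})

test_that("the changing layer equals subsequent minus current in every mode", {
  for (mode in c("time_lagged", "instant")) {
    sim <- simulate_panel(sim_config(n_genes = 15, n_cells_per_trace = 200,
                                     mode = mode, seed = 7))
    expect_equal(sim$panel$X_cha, sim$panel$X_sub - sim$panel$X_cur,
                 tolerance = 1e-12)
  }
})

test_that("asynchrony rescales chosen cha columns and nothing else", {
  sim <- simulate_panel(sim_config(n_genes = 20, n_cells_per_trace = 100, seed = 8))
  expect_identical(apply_asynchrony(sim$panel, 0, 0.5), sim$panel)
  expect_identical(apply_asynchrony(sim$panel, 0.5, 0), sim$panel)
  set.seed(8)
  dist <- apply_asynchrony(sim$panel, 1, 0.9)
  ratio <- dist$X_cha / sim$panel$X_cha
  per_gene <- apply(ratio, 2, function(x) diff(range(x)))
  expect_true(all(per_gene < 1e-10))              # constant per column
  expect_true(all(ratio[1, ] > 0.1 & ratio[1, ] < 1.9))
  expect_identical(dist$X_sub, sim$panel$X_sub)   # truth untouched
  expect_identical(dist$X_cur, sim$panel$X_cur)
  expect_true(validate_panel(dist)$ok)            # distortion flag honoured
})

test_that("latent removal matches the set-algebra oracle", {
  sim <- simulate_panel(sim_config(n_genes = 50, n_cells_per_trace = 50, seed = 9))
  r0 <- remove_latent(sim$panel, sim$graph, 0)
  expect_identical(r0$panel, sim$panel)
  set.seed(9)
  red <- remove_latent(sim$panel, sim$graph, 0.5)
  expect_length(red$panel$genes, 25)
  expect_length(red$removed, 25)
  expect_false(any(red$removed %in% red$panel$genes))
  expect_false(any(red$removed %in% colnames(red$panel$X_cur)))
  ## surviving edges = brute-force filter of the full truth
  keep <- red$panel$genes
  expected <- sim$graph$directed[sim$graph$directed[, 1] %in% keep &
                                 sim$graph$directed[, 2] %in% keep, , drop = FALSE]
  expect_setequal(dir_keys(red$graph),
                  paste(expected[, 1], expected[, 2], sep = ">"))
  tiny <- simulate_panel(sim_config(n_genes = 3, n_cells_per_trace = 10, seed = 1))
  expect_error(remove_latent(tiny$panel, tiny$graph, 0.9), "fewer than 2")
})

test_that("identical configuration and seed reproduce bit-identical output", {
  cfg <- sim_config(n_genes = 15, n_cells_per_trace = 100,
                    async_fraction = 0.4, async_d = 0.3,
                    latent_fraction = 0.2, seed = 123)
  s1 <- simulate_panel(cfg)
  s2 <- simulate_panel(cfg)
  expect_identical(s1$panel, s2$panel)
  expect_identical(s1$graph, s2$graph)
  expect_identical(s1$removed, s2$removed)
})

test_that("a time-lagged edge leaves a strong current-to-changing signal", {
  ## the natural-confounder phenomenon: the cause's current level correlates
  ## strongly with the target's changing level, while the current-current
  ## correlation stays comparatively weak
  g <- causal_graph(c("A", "B"), directed = cbind("A", "B"))
  for (nt in c(1L, 3L)) {
    cfg <- sim_config(n_genes = 2, n_traces = nt,
                      n_cells_per_trace = if (nt == 1) 3000 else 1000, seed = 10 + nt)
    set.seed(cfg$seed)
    prev <- draw_previous(cfg)
    panel <- propagate_time_lagged(g, prev$X_pre, cfg)
    r_cha <- cor(panel$X_cur[, "A"], panel$X_cha[, "B"])
    r_cur <- cor(panel$X_cur[, "A"], panel$X_cur[, "B"])
    expect_gt(r_cha, 0.3)
    expect_gt(r_cha, abs(r_cur))
  }
})
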