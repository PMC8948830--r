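#' Draw a random ground-truth causal graph
#'
#' Each unordered gene pair carries an edge independently with probability
#' `edge_prob`; each edge's direction is assigned uniformly at random. In
#' `"instant"` mode edges are instead oriented along a uniformly random node
#' permutation, so the result is acyclic (instant propagation needs a
#' topological order); time-lagged propagation is well-defined across time
#' steps, so cycles are allowed there.
#'
#' @param n_genes number of genes (>= 2).
#' @param edge_prob per-pair edge probability in \[0,1\].
#' @param mode `"time_lagged"` or `"instant"`.
#' @param genes optional gene names.
#' @return a [causal_graph()] with directed edges only.
#' @export
random_causal_graph <- function(n_genes, edge_prob = 0.041,
                                mode = c("time_lagged", "instant"),
                                genes = paste0("g", seq_len(n_genes))) {
  mode <- match.arg(mode)
  stopifnot(n_genes >= 2, edge_prob >= 0, edge_prob <= 1)
  pairs <- which(upper.tri(matrix(0, n_genes, n_genes)), arr.ind = TRUE)
  has_edge <- stats::runif(nrow(pairs)) < edge_prob
  pairs <- pairs[has_edge, , drop = FALSE]
  if (mode == "instant") {
    ord <- sample.int(n_genes)               # random topological order
    rank <- order(ord)
    flip <- rank[pairs[, 1]] > rank[pairs[, 2]]
  } else {
    flip <- stats::runif(nrow(pairs)) < 0.5
  }
  pairs[flip, ] <- pairs[flip, 2:1]
  causal_graph(genes, directed = cbind(genes[pairs[, 1]], genes[pairs[, 2]]))
}

## genes x genes coefficient matrix B with B[cause, target] = cause_coeff
graph_coef_matrix <- function(graph, cause_coeff = 1) {
  n <- length(graph$genes)
  B <- matrix(0, n, n, dimnames = list(graph$genes, graph$genes))
  if (nrow(graph$directed))
    B[graph$directed] <- cause_coeff
  B
}

#' Draw previous expression levels
#'
#' Single-trace: `ln(X_pre)` i.i.d. Normal(`lognormal_mu`,
#' `lognormal_sigma2`) per cell and gene. Multi-trace: for each trace and
#' gene an independent log-mean `mu ~ Uniform(trace_mu_range)` is drawn, then
#' `ln(X_pre) ~ N(mu, lognormal_sigma2)`; traces are concatenated. The drawn
#' means are returned so that downstream checks can condition on them; trace
#' labels are bookkeeping only and are never passed to inference.
#'
#' @param config a [sim_config()].
#' @return list with `X_pre` (cells x genes), `trace_labels`, and `mu`
#'   (traces x genes matrix of log-means).
#' @export
draw_previous <- function(config) {
  n <- config$n_genes
  nt <- config$n_traces
  m <- config$n_cells_per_trace
  sdl <- sqrt(config$lognormal_sigma2)
  if (nt == 1L) {
    mu <- matrix(config$lognormal_mu, 1, n)
  } else {
    mu <- matrix(stats::runif(nt * n, config$trace_mu_range[1], config$trace_mu_range[2]),
                 nt, n)
  }
  X <- matrix(NA_real_, nt * m, n)
  for (tr in seq_len(nt)) {
    rows <- (tr - 1L) * m + seq_len(m)
    X[rows, ] <- exp(matrix(stats::rnorm(m * n, mean = rep(mu[tr, ], each = m), sd = sdl), m, n))
  }
  list(X_pre = X, trace_labels = rep(paste0("trace", seq_len(nt)), each = m), mu = mu)
}

#' Propagate expression through a time-lagged linear model
#'
#' One unit-time step of the lagged structural model: for every gene i,
#' `X_cur_i = b*X_pre_i + sum_c X_pre_c + e_cur` and
#' `X_sub_i = b*X_cur_i + sum_c X_cur_c + e_sub`, where the sums run over the
#' causes (parents) of i, `b` is the decay coefficient and the noise is
#' i.i.d. Normal(0, `noise_sd`^2) per cell, gene and step. The changing
#' expression is the difference `X_cha = X_sub - X_cur`. Cycles are allowed:
#' causes act with a one-step lag, so the system is always well-defined.
#'
#' @param graph a [causal_graph()] whose genes match the columns of `X_pre`.
#' @param X_pre cells x genes matrix of previous expression.
#' @param config a [sim_config()].
#' @param trace_labels optional per-cell labels forwarded to the panel.
#' @return an [expression_panel()] with all four layers.
#' @export
propagate_time_lagged <- function(graph, X_pre, config, trace_labels = NULL) {
  X_pre <- as.matrix(X_pre)
  if (ncol(X_pre) != length(graph$genes))
    stop("X_pre columns must match graph genes")
  B <- graph_coef_matrix(graph, config$cause_coeff)
  b <- config$decay_coeff
  noise <- function() matrix(stats::rnorm(length(X_pre), 0, config$noise_sd),
                             nrow(X_pre), ncol(X_pre))
  X_cur <- b * X_pre + X_pre %*% B + noise()
  X_sub <- b * X_cur + X_cur %*% B + noise()
  expression_panel(X_cur = X_cur, X_sub = X_sub, X_pre = X_pre,
                   genes = graph$genes, trace_labels = trace_labels)
}

## topological order of a causal_graph's directed edges; error naming a cycle
topological_order <- function(graph) {
  n <- length(graph$genes)
  idx <- stats::setNames(seq_len(n), graph$genes)
  parents <- lapply(seq_len(n), function(i) integer(0))
  for (e in seq_len(nrow(graph$directed))) {
    t <- idx[[graph$directed[e, 2]]]
    parents[[t]] <- c(parents[[t]], idx[[graph$directed[e, 1]]])
  }
  indeg <- lengths(parents)
  children <- lapply(seq_len(n), function(i) integer(0))
  for (e in seq_len(nrow(graph$directed))) {
    s <- idx[[graph$directed[e, 1]]]
    children[[s]] <- c(children[[s]], idx[[graph$directed[e, 2]]])
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (w in children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) < n) {
    stop("graph contains a cycle involving: ",
         paste(graph$genes[setdiff(seq_len(n), out)], collapse = ", "))
  }
  out
}

#' Propagate expression through an instant linear model
#'
#' Causes act within the same time step: `X_cur_i` depends on the *current*
#' values of its causes and `X_sub_i` on their *subsequent* values, so genes
#' are evaluated in topological order and the graph must be acyclic.
#'
#' @inheritParams propagate_time_lagged
#' @return an [expression_panel()].
#' @export
propagate_instant <- function(graph, X_pre, config, trace_labels = NULL) {
  X_pre <- as.matrix(X_pre)
  if (ncol(X_pre) != length(graph$genes))
    stop("X_pre columns must match graph genes")
  ord <- topological_order(graph)
  B <- graph_coef_matrix(graph, config$cause_coeff)
  b <- config$decay_coeff
  m <- nrow(X_pre); n <- ncol(X_pre)
  X_cur <- matrix(NA_real_, m, n)
  X_sub <- matrix(NA_real_, m, n)
  for (i in ord) {
    pa <- which(B[, i] != 0)
    ccur <- if (length(pa)) X_cur[, pa, drop = FALSE] %*% B[pa, i] else 0
    X_cur[, i] <- b * X_pre[, i] + ccur + stats::rnorm(m, 0, config$noise_sd)
    csub <- if (length(pa)) X_sub[, pa, drop = FALSE] %*% B[pa, i] else 0
    X_sub[, i] <- b * X_cur[, i] + csub + stats::rnorm(m, 0, config$noise_sd)
  }
  expression_panel(X_cur = X_cur, X_sub = X_sub, X_pre = X_pre,
                   genes = graph$genes, trace_labels = trace_labels)
}

#' Distort changing expression of asynchronous genes
#'
#' Models biased velocity estimation for regulations with different reaction
#' times: a uniformly chosen subset of `ceiling(fraction * n)` genes has its
#' `X_cha` column multiplied by a bias factor `a ~ Uniform(1-d, 1+d)`, drawn
#' once per gene (or per cell and gene when `per_cell = TRUE`). `X_sub` is
#' left untouched -- the distortion misreports the velocity, it does not
#' change the underlying truth -- so the panel is flagged `cha_distorted`.
#'
#' @param panel an [expression_panel()] with `X_cha`.
#' @param fraction fraction of genes to distort, in \[0,1\].
#' @param d bias half-width, in \[0,1).
#' @param per_cell draw an independent bias per cell instead of per gene.
#' @return the distorted panel; attribute `async_genes` lists the affected
#'   genes and `async_bias` their factors (per-gene mode).
#' @export
apply_asynchrony <- function(panel, fraction, d, per_cell = FALSE) {
  stopifnot(fraction >= 0, fraction <= 1, d >= 0, d < 1)
  if (fraction == 0 || d == 0) return(panel)
  n <- length(panel$genes)
  n_async <- min(n, ceiling(fraction * n))
  pick <- sort(sample.int(n, n_async))
  X_cha <- panel$X_cha
  if (per_cell) {
    a <- matrix(stats::runif(nrow(X_cha) * n_async, 1 - d, 1 + d), nrow(X_cha), n_async)
    X_cha[, pick] <- X_cha[, pick, drop = FALSE] * a
    bias <- NULL
  } else {
    bias <- stats::runif(n_async, 1 - d, 1 + d)
    X_cha[, pick] <- sweep(X_cha[, pick, drop = FALSE], 2, bias, `*`)
  }
  out <- expression_panel(X_cur = panel$X_cur, X_cha = X_cha, X_sub = panel$X_sub,
                          X_pre = panel$X_pre, genes = panel$genes,
                          cells = panel$cells, trace_labels = panel$trace_labels)
  attr(out, "cha_distorted") <- TRUE
  attr(out, "async_genes") <- panel$genes[pick]
  attr(out, "async_bias") <- bias
  out
}

#' Remove genes to emulate latent variables
#'
#' Removes `floor(fraction * n + 0.5)` genes uniformly at random from every
#' layer and restricts the ground-truth graph to the survivors (edges touching
#' a removed gene are dropped; evaluation then compares against this
#' restricted truth, since an output graph cannot name unobserved genes).
#'
#' @param panel an [expression_panel()].
#' @param graph the ground-truth [causal_graph()].
#' @param fraction fraction of genes to hide, in \[0,1).
#' @return list with `panel`, `graph` (both restricted) and `removed`
#'   (character vector of hidden genes).
#' @export
remove_latent <- function(panel, graph, fraction) {
  stopifnot(fraction >= 0, fraction < 1)
  n <- length(panel$genes)
  n_remove <- floor(fraction * n + 0.5)
  if (n - n_remove < 2L)
    stop("latent removal would leave fewer than 2 genes")
  if (n_remove == 0L)
    return(list(panel = panel, graph = graph, removed = character(0)))
  removed <- sort(sample.int(n, n_remove))
  keep <- setdiff(seq_len(n), removed)
  sub <- function(m) if (is.null(m)) NULL else m[, keep, drop = FALSE]
  out <- expression_panel(X_cur = sub(panel$X_cur), X_cha = sub(panel$X_cha),
                          X_sub = sub(panel$X_sub), X_pre = sub(panel$X_pre),
                          genes = panel$genes[keep], cells = panel$cells,
                          trace_labels = panel$trace_labels)
  if (isTRUE(attr(panel, "cha_distorted"))) attr(out, "cha_distorted") <- TRUE
  list(panel = out, graph = restrict_graph(graph, panel$genes[keep]),
       removed = panel$genes[removed])
}

#' Simulate a ground-truth graph and expression panel
#'
#' End-to-end generator: draws a random causal graph, previous expression
#' (single- or multi-trace), propagates one time step (time-lagged or
#' instant), then optionally distorts asynchronous genes and removes latent
#' genes. Identical configurations with the same seed give bit-identical
#' output.
#'
#' @param config a [sim_config()].
#' @return list with `panel`, `graph` (truth restricted to observed genes),
#'   `full_graph` (pre-removal truth), `removed`, `mu` (drawn log-means) and
#'   `config`.
#' @export
simulate_panel <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  graph <- random_causal_graph(config$n_genes, config$edge_prob, config$mode)
  prev <- draw_previous(config)
  panel <- if (config$mode == "instant") {
    propagate_instant(graph, prev$X_pre, config, prev$trace_labels)
  } else {
    propagate_time_lagged(graph, prev$X_pre, config, prev$trace_labels)
  }
  if (config$async_fraction > 0 && config$async_d > 0)
    panel <- apply_asynchrony(panel, config$async_fraction, config$async_d,
                              config$async_per_cell)
  removed <- character(0)
  obs_graph <- graph
  if (config$latent_fraction > 0) {
    red <- remove_latent(panel, graph, config$latent_fraction)
    panel <- red$panel
    obs_graph <- red$graph
    removed <- red$removed
  }
  list(panel = panel, graph = obs_graph, full_graph = graph,
       removed = removed, mu = prev$mu, config = config)
}
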