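#' Expression panel: aligned cells-by-genes matrices
#'
#' Container for the four expression layers used throughout the package:
#' previous (`X_pre`, simulation only), current (`X_cur`), subsequent
#' (`X_sub`) and changing (`X_cha`) expression. `X_cha` is the per-cell,
#' per-gene expression change over one unit of time; on real data it is the
#' RNA velocity layer. All matrices are cells-as-rows, genes-as-columns and
#' share the same dimnames.
#'
#' If only one of `X_sub`/`X_cha` is supplied the other is completed from the
#' identity `X_cha = X_sub - X_cur`.
#'
#' @param X_cur numeric matrix, cells x genes. Required.
#' @param X_cha numeric matrix, changing expression (velocity), or `NULL`.
#' @param X_sub numeric matrix, subsequent expression, or `NULL`.
#' @param X_pre numeric matrix, previous expression, or `NULL`.
#' @param genes character vector of gene names; defaults to the column names
#'   of `X_cur`, or `g1..gn` when unnamed.
#' @param cells character vector of cell identifiers; defaults to row names
#'   of `X_cur`, or `c1..cm`.
#' @param trace_labels optional per-cell trace (time-point batch) identifier;
#'   kept for bookkeeping, never used by inference.
#' @return an object of class `expression_panel`.
#' @export
expression_panel <- function(X_cur, X_cha = NULL, X_sub = NULL, X_pre = NULL,
                             genes = NULL, cells = NULL, trace_labels = NULL) {
  X_cur <- as.matrix(X_cur)
  if (is.null(genes)) {
    genes <- colnames(X_cur)
    if (is.null(genes)) genes <- paste0("g", seq_len(ncol(X_cur)))
  }
  if (is.null(cells)) {
    cells <- rownames(X_cur)
    if (is.null(cells)) cells <- paste0("c", seq_len(nrow(X_cur)))
  }
  if (anyDuplicated(genes)) stop("duplicated gene names")
  layers <- list(X_pre = X_pre, X_cur = X_cur, X_sub = X_sub, X_cha = X_cha)
  for (nm in names(layers)) {
    if (is.null(layers[[nm]])) next
    m <- as.matrix(layers[[nm]])
    if (!identical(dim(m), dim(X_cur)))
      stop(sprintf("layer %s has dimensions %s, expected %s", nm,
                   paste(dim(m), collapse = "x"), paste(dim(X_cur), collapse = "x")))
    dimnames(m) <- list(cells, genes)
    layers[[nm]] <- m
  }
  if (is.null(layers$X_cha) && !is.null(layers$X_sub))
    layers$X_cha <- layers$X_sub - layers$X_cur
  if (is.null(layers$X_sub) && !is.null(layers$X_cha))
    layers$X_sub <- layers$X_cur + layers$X_cha
  if (!is.null(trace_labels) && length(trace_labels) != nrow(X_cur))
    stop("trace_labels must have one entry per cell")
  structure(
    c(layers, list(genes = as.character(genes), cells = as.character(cells),
                   trace_labels = trace_labels)),
    class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  present <- names(x)[vapply(x[c("X_pre", "X_cur", "X_sub", "X_cha")], Negate(is.null), logical(1))]
  cat(sprintf("<expression_panel> %d cells x %d genes; layers: %s\n",
              length(x$cells), length(x$genes), paste(present, collapse = ", ")))
  if (!is.null(x$trace_labels))
    cat(sprintf("  traces: %s\n", paste(unique(x$trace_labels), collapse = ", ")))
  invisible(x)
}

#' Validate an expression panel
#'
#' Reports (rather than errors on) shape mismatches, non-finite values and
#' violations of the `X_cha = X_sub - X_cur` identity. Panels whose changing
#' expression has been deliberately distorted (asynchronous-velocity
#' simulation, see [apply_asynchrony()]) carry a `cha_distorted` attribute and
#' are exempt from the identity check.
#'
#' @param panel an [expression_panel()].
#' @param tol numeric tolerance for the layer identity.
#' @return a list with elements `ok` (logical) and `issues` (character).
#' @export
validate_panel <- function(panel, tol = 1e-8) {
  issues <- character(0)
  if (!inherits(panel, "expression_panel")) {
    return(list(ok = FALSE, issues = "not an expression_panel"))
  }
  ref <- dim(panel$X_cur)
  for (nm in c("X_pre", "X_cur", "X_sub", "X_cha")) {
    m <- panel[[nm]]
    if (is.null(m)) next
    if (!identical(dim(m), ref))
      issues <- c(issues, sprintf("shape mismatch in %s", nm))
    else if (!all(is.finite(m)))
      issues <- c(issues, sprintf("non-finite values in %s", nm))
  }
  if (!is.null(panel$X_sub) && !is.null(panel$X_cha) &&
      !isTRUE(attr(panel, "cha_distorted"))) {
    dev <- max(abs(panel$X_sub - panel$X_cur - panel$X_cha))
    if (!is.na(dev) && dev > tol)
      issues <- c(issues, sprintf("X_cha deviates from X_sub - X_cur by up to %.3g", dev))
  }
  if (length(panel$genes) != ncol(panel$X_cur))
    issues <- c(issues, "gene label count does not match columns")
  if (length(panel$cells) != nrow(panel$X_cur))
    issues <- c(issues, "cell label count does not match rows")
  list(ok = length(issues) == 0L, issues = issues)
}

#' Gene-level causal graph
#'
#' Holds directed edges (ordered pairs, cause -> target) and undirected edges
#' (unordered pairs) over a fixed gene universe. No self-loops; a pair may
#' appear in at most one of the two edge sets (a pair directed both ways is
#' allowed and kept as two directed edges).
#'
#' @param genes character vector of node names.
#' @param directed two-column matrix/data.frame (source, target) or `NULL`.
#' @param undirected two-column matrix/data.frame of unordered pairs or `NULL`.
#' @return an object of class `causal_graph`.
#' @export
causal_graph <- function(genes, directed = NULL, undirected = NULL) {
  genes <- as.character(genes)
  as_pairs <- function(x) {
    if (is.null(x) || NROW(x) == 0L)
      return(matrix(character(0), ncol = 2, dimnames = list(NULL, c("source", "target"))))
    x <- as.matrix(x)
    storage.mode(x) <- "character"
    colnames(x) <- c("source", "target")
    x
  }
  directed <- as_pairs(directed)
  undirected <- as_pairs(undirected)
  if (nrow(undirected)) {
    swap <- undirected[, 1] > undirected[, 2]
    undirected[swap, ] <- undirected[swap, 2:1]
    undirected <- unique(undirected)
  }
  directed <- unique(directed)
  all_nodes <- c(directed, undirected)
  if (length(all_nodes) && !all(all_nodes %in% genes))
    stop("edge endpoints must be declared genes: ",
         paste(setdiff(all_nodes, genes), collapse = ", "))
  if (any(directed[, 1] == directed[, 2]) || any(undirected[, 1] == undirected[, 2]))
    stop("self-loops are not allowed")
  dkey <- pair_key(directed[, 1], directed[, 2])
  ukey <- pair_key(undirected[, 1], undirected[, 2])
  if (any(ukey %in% dkey))
    stop("a gene pair may not be both directed and undirected")
  structure(list(genes = genes, directed = directed, undirected = undirected),
            class = "causal_graph")
}

## canonical unordered-pair key
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' @export
print.causal_graph <- function(x, ...) {
  cat(sprintf("<causal_graph> %d genes, %d directed, %d undirected edges\n",
              length(x$genes), nrow(x$directed), nrow(x$undirected)))
  invisible(x)
}

#' Restrict a causal graph to a gene subset
#'
#' Drops every edge touching a gene outside `keep`. Idempotent.
#'
#' @param graph a [causal_graph()].
#' @param keep character vector of genes to retain.
#' @return a [causal_graph()] over `keep`.
#' @export
restrict_graph <- function(graph, keep) {
  keep <- intersect(graph$genes, keep)
  d <- graph$directed[graph$directed[, 1] %in% keep & graph$directed[, 2] %in% keep, , drop = FALSE]
  u <- graph$undirected[graph$undirected[, 1] %in% keep & graph$undirected[, 2] %in% keep, , drop = FALSE]
  causal_graph(keep, d, u)
}

#' Undirected adjacency keys of a causal graph
#'
#' @param graph a [causal_graph()].
#' @return character vector of canonical `a|b` pair keys, one per adjacency.
#' @keywords internal
graph_adjacencies <- function(graph) {
  unique(c(pair_key(graph$directed[, 1], graph$directed[, 2]),
           pair_key(graph$undirected[, 1], graph$undirected[, 2])))
}

#' CITL inference configuration
#'
#' @param n_genes number of genes the configuration is for (used for the
#'   default `k`).
#' @param k maximum conditioning-set size of the CI test. Default
#'   `floor(sqrt(n_genes))`, the square root of the number of genes.
#' @param alpha type-one error of the CI test, in (0,1). Default 0.05.
#' @return a list of class `citl_config`.
#' @export
citl_config <- function(n_genes, k = floor(sqrt(n_genes)), alpha = 0.05) {
  stopifnot(k >= 0, alpha > 0, alpha < 1)
  structure(list(k = as.integer(k), alpha = alpha), class = "citl_config")
}

#' Simulation configuration
#'
#' Every knob of the synthetic-data generator. Defaults are the study
#' conditions of the simulation design this package replicates: 50 genes,
#' per-pair edge probability 4.1% (50 directed edges on average), 3000 cells
#' for a single trace or 3 traces of 1000 cells, decay coefficient 0.8,
#' cause coefficient 1, standard Gaussian step noise ("Cvariance"), previous
#' expression log-normal with ln X ~ N(0, 0.04), and multi-trace per-trace
#' gene means mu ~ Uniform(0, 2) ("Ivariance").
#'
#' @param n_genes number of genes.
#' @param edge_prob probability of an edge between each unordered gene pair.
#' @param n_traces number of traces (time-point batches); 1 = single-trace.
#' @param n_cells_per_trace cells per trace; default 3000 when `n_traces == 1`
#'   and 1000 otherwise.
#' @param decay_coeff coefficient of the self term f1 (spontaneous decay).
#' @param cause_coeff coefficient of every causal gene in f2.
#' @param noise_sd standard deviation of the per-step Gaussian noise e_cur,
#'   e_sub (the "Cvariance" knob; default 1).
#' @param lognormal_mu,lognormal_sigma2 mean and variance of ln X_pre for
#'   single-trace data.
#' @param trace_mu_range range of the uniform distribution the per-trace,
#'   per-gene log-mean is drawn from in multi-trace mode (the "Ivariance"
#'   knob).
#' @param mode `"time_lagged"` (causes act with a one-step lag) or
#'   `"instant"` (causes act within the step; requires an acyclic graph).
#' @param async_fraction fraction of genes whose changing expression is
#'   distorted by a gene-specific bias factor.
#' @param async_d half-width of the bias factor distribution Uniform(1-d, 1+d).
#' @param async_per_cell draw the bias per cell instead of once per gene.
#' @param latent_fraction fraction of genes removed after generation.
#' @param seed integer seed or `NULL`.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 50, edge_prob = 0.041,
                       n_traces = 1,
                       n_cells_per_trace = if (n_traces == 1) 3000 else 1000,
                       decay_coeff = 0.8, cause_coeff = 1, noise_sd = 1,
                       lognormal_mu = 0, lognormal_sigma2 = 0.04,
                       trace_mu_range = c(0, 2),
                       mode = c("time_lagged", "instant"),
                       async_fraction = 0, async_d = 0, async_per_cell = FALSE,
                       latent_fraction = 0, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_genes >= 2, edge_prob >= 0, edge_prob <= 1,
            n_traces >= 1, n_cells_per_trace >= 1,
            noise_sd >= 0, lognormal_sigma2 >= 0,
            length(trace_mu_range) == 2, trace_mu_range[1] <= trace_mu_range[2],
            async_fraction >= 0, async_fraction <= 1,
            async_d >= 0, async_d < 1,
            latent_fraction >= 0, latent_fraction < 1)
  structure(list(n_genes = as.integer(n_genes), edge_prob = edge_prob,
                 n_traces = as.integer(n_traces),
                 n_cells_per_trace = as.integer(n_cells_per_trace),
                 decay_coeff = decay_coeff, cause_coeff = cause_coeff,
                 noise_sd = noise_sd, lognormal_mu = lognormal_mu,
                 lognormal_sigma2 = lognormal_sigma2,
                 trace_mu_range = trace_mu_range, mode = mode,
                 async_fraction = async_fraction, async_d = async_d,
                 async_per_cell = async_per_cell,
                 latent_fraction = latent_fraction, seed = seed),
            class = "sim_config")
}
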