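## role-tagged variable names for the stacked data
role_names <- function(genes, role) paste0(role, "_", genes)

## stack two panel layers into one samples x 2n matrix with role-tagged names
stack_layers <- function(panel, roles = c("cur", "cha")) {
  layer_of <- c(cur = "X_cur", cha = "X_cha", sub = "X_sub", pre = "X_pre")
  mats <- lapply(roles, function(r) {
    m <- panel[[layer_of[[r]]]]
    if (is.null(m)) stop("panel is missing the ", layer_of[[r]], " layer")
    colnames(m) <- role_names(panel$genes, r)
    m
  })
  do.call(cbind, mats)
}

#' Infer time-lagged causal relationships (CITL)
#'
#' The core method. The current and changing expression levels of all genes
#' are stacked into one 2n-variable data set and an undirected graph (UG) is
#' learned over them with the PC-stable skeleton search
#' ([learn_skeleton()]). Every UG edge joining the *current* expression of
#' gene i to the *changing* expression of a different gene j is then read as
#' the time-lagged causal call i -> j: the current level precedes the change
#' it drives, so the temporal order of the two roles supplies the direction
#' without relying on causal sufficiency. Edges between two current levels,
#' two changing levels, or the current and changing level of the same gene
#' produce no call; they are tallied in the diagnostics.
#'
#' @param panel an [expression_panel()] with `X_cur` and `X_cha`.
#' @param config a [citl_config()]; defaults to `k = floor(sqrt(n_genes))`
#'   and `alpha = 0.05`.
#' @return a [causal_graph()] of directed calls. Attributes: `ug` (the
#'   variable-level skeleton) and `diagnostics` (edge-type counts, including
#'   the number of reciprocal call pairs, a possible feedback signature).
#' @export
citl_infer <- function(panel, config = citl_config(length(panel$genes))) {
  n <- length(panel$genes)
  if (n < 2) stop("need at least 2 genes")
  data <- stack_layers(panel, c("cur", "cha"))
  vg <- learn_skeleton(data, k = config$k, alpha = config$alpha)
  graph <- calls_from_ug(vg, panel$genes, cha_role = "cha")
  graph
}

## extract directed gene calls cur_i -- <role>_j (i != j) from a UG over
## cur + <role> variables; attach diagnostics
calls_from_ug <- function(vg, genes, cha_role = "cha") {
  n <- length(genes)
  A <- vg$A
  cur_idx <- seq_len(n)
  cha_idx <- n + seq_len(n)
  cross <- A[cur_idx, cha_idx, drop = FALSE]   # cross[i, j]: cur_i -- role_j
  self_pairs <- sum(diag(cross))
  diag(cross) <- FALSE
  calls <- which(cross, arr.ind = TRUE)
  graph <- causal_graph(genes,
                        directed = cbind(genes[calls[, 1]], genes[calls[, 2]]))
  recip <- sum(cross & t(cross)) / 2
  diag_counts <- list(
    cur_cur_edges = sum(A[cur_idx, cur_idx]) / 2,
    cha_cha_edges = sum(A[cha_idx, cha_idx]) / 2,
    self_pairs = self_pairs,
    reciprocal_calls = recip)
  attr(graph, "ug") <- vg
  attr(graph, "diagnostics") <- diag_counts
  graph
}

#' Pearson-correlation baseline (Approach 0)
#'
#' Scores every ordered gene pair (i, j), i != j, by the absolute Pearson
#' correlation between the current expression of i and the changing
#' expression of j, and calls i -> j whenever the score exceeds the
#' threshold. The full score table is returned for ROC/PR evaluation.
#'
#' @param panel an [expression_panel()] with `X_cur` and `X_cha`.
#' @param threshold correlation threshold in \[0,1\].
#' @return list with `graph` (directed [causal_graph()]) and `scores`
#'   (data.frame `source`, `target`, `score`).
#' @export
approach0 <- function(panel, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  sds_cur <- apply(panel$X_cur, 2, stats::sd)
  sds_cha <- apply(panel$X_cha, 2, stats::sd)
  if (any(sds_cur == 0) || any(sds_cha == 0))
    warning("constant columns: ",
            paste(unique(panel$genes[sds_cur == 0 | sds_cha == 0]), collapse = ", "),
            "; their pairs are excluded")
  S <- suppressWarnings(abs(stats::cor(panel$X_cur, panel$X_cha)))
  diag(S) <- NA
  idx <- which(!is.na(S), arr.ind = TRUE)
  scores <- data.frame(source = panel$genes[idx[, 1]],
                       target = panel$genes[idx[, 2]],
                       score = S[idx], stringsAsFactors = FALSE)
  called <- idx[S[idx] > threshold, , drop = FALSE]
  graph <- causal_graph(panel$genes,
                        directed = cbind(panel$genes[called[, 1]],
                                         panel$genes[called[, 2]]))
  list(graph = graph, scores = scores)
}

#' PC-stable comparison approaches 1-3
#'
#' * Approach 1 runs full PC-stable (skeleton, v-structures, Meek rules) on
#'   the current expression alone; the CPDAG is the gene-level answer.
#' * Approach 2 runs PC-stable on current + subsequent expression stacked
#'   (2n variables); `X_sub` is taken as `X_cur + X_cha` when absent.
#' * Approach 3 runs PC-stable on current + changing expression -- the same
#'   variables CITL uses, but directions come from PC-stable's own
#'   orientation rules instead of the time-lagged assumption.
#'
#' For approaches 2 and 3 the variable-level CPDAG is projected to genes:
#' a cross-role edge oriented from `cur_i` into the subsequent/changing node
#' of gene j maps to the directed edge i -> j; any other cross-role edge
#' (undirected, or oriented back into `cur_i`) maps to the undirected edge
#' i - j; role-homogeneous and same-gene edges are dropped. When a pair
#' receives both a directed and an undirected mapping, the directed one wins.
#'
#' @param panel an [expression_panel()].
#' @param which 1, 2 or 3.
#' @param config a [citl_config()].
#' @return a [causal_graph()]; the variable-level CPDAG is attached as
#'   attribute `cpdag`.
#' @export
run_approach <- function(panel, which, config = citl_config(length(panel$genes))) {
  stopifnot(which %in% 1:3)
  genes <- panel$genes
  n <- length(genes)
  if (which == 1) {
    data <- panel$X_cur
    colnames(data) <- genes
    cp <- pc_stable(data, k = config$k, alpha = config$alpha)
    g <- cpdag_to_graph(cp)
    attr(g, "cpdag") <- cp
    return(g)
  }
  role <- if (which == 2) "sub" else "cha"
  if (which == 2 && is.null(panel$X_sub)) {
    if (is.null(panel$X_cha)) stop("panel has neither X_sub nor X_cha")
    panel$X_sub <- panel$X_cur + panel$X_cha
  }
  data <- stack_layers(panel, c("cur", role))
  cp <- pc_stable(data, k = config$k, alpha = config$alpha)
  g <- project_cross_cpdag(cp, genes)
  attr(g, "cpdag") <- cp
  g
}

## gene-level projection of a CPDAG over stacked cur + {sub|cha} variables
project_cross_cpdag <- function(cp, genes) {
  n <- length(genes)
  cur_idx <- seq_len(n)
  oth_idx <- n + seq_len(n)
  fwd <- cp[cur_idx, oth_idx, drop = FALSE] == 1L  # cur_i -> or - role_j
  bwd <- t(cp[oth_idx, cur_idx, drop = FALSE] == 1L)  # role_j -> or - cur_i, as [i, j]
  diag(fwd) <- FALSE; diag(bwd) <- FALSE
  dir_call <- fwd & !bwd       # oriented cur_i -> role_j
  und_call <- (fwd & bwd) | (!fwd & bwd)  # undirected, or oriented into cur_i
  ## directed beats undirected for the same unordered pair
  und_idx <- which(und_call, arr.ind = TRUE)
  dir_idx <- which(dir_call, arr.ind = TRUE)
  und_pairs <- unique(cbind(pmin(und_idx[, 1], und_idx[, 2]),
                            pmax(und_idx[, 1], und_idx[, 2])))
  if (nrow(dir_idx) && nrow(und_pairs)) {
    dkeys <- pair_key(dir_idx[, 1], dir_idx[, 2])
    und_pairs <- und_pairs[!(pair_key(und_pairs[, 1], und_pairs[, 2]) %in% dkeys), ,
                           drop = FALSE]
  }
  causal_graph(genes,
               directed = cbind(genes[dir_idx[, 1]], genes[dir_idx[, 2]]),
               undirected = cbind(genes[und_pairs[, 1]], genes[und_pairs[, 2]]))
}
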