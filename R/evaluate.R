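## safe ratio: NA (undefined) when the denominator is zero
ratio_or_na <- function(num, den) if (den > 0) num / den else NA_real_

f_measure <- function(p, r) {
  if (is.na(p) || is.na(r) || p + r == 0) return(NA_real_)
  2 * p * r / (p + r)
}

#' Edge and direction metrics of an output graph against the truth
#'
#' Edge metrics compare adjacencies (the undirected projections of both
#' graphs): TP is the number of adjacencies in both graphs, FP those only in
#' the output, FN those only in the truth. Direction metrics compare
#' directed edges: TP_dir counts edges directed identically in both graphs;
#' FP_dir counts output edges inconsistent with the truth -- adjacency
#' absent from the truth, undirected in the output over a directed truth, or
#' reversed; FN_dir counts true edges not correctly directed in the output.
#' ADD (ability of determining directions) is TP_dir / TP_edge. Reciprocal
#' output pairs count once per ordered edge. Metrics with a zero denominator
#' are reported as `NA` and listed in `undefined`.
#'
#' @param g_out,g_true [causal_graph()] objects over a shared gene universe.
#' @return a list of class `citl_eval` with counts and metrics.
#' @export
eval_report <- function(g_out, g_true) {
  out_adj <- graph_adjacencies(g_out)
  true_adj <- graph_adjacencies(g_true)
  tp_edge <- length(intersect(out_adj, true_adj))
  fp_edge <- length(setdiff(out_adj, true_adj))
  fn_edge <- length(setdiff(true_adj, out_adj))

  okey <- function(m) if (nrow(m)) paste(m[, 1], m[, 2], sep = ">") else character(0)
  out_dir <- okey(g_out$directed)
  true_dir <- okey(g_true$directed)
  tp_dir <- length(intersect(out_dir, true_dir))
  ## inconsistent output edges: every directed or undirected output edge that
  ## is not an exactly matching directed edge of the truth
  fp_dir <- (length(out_dir) - tp_dir) + nrow(g_out$undirected)
  fn_dir <- length(setdiff(true_dir, out_dir))

  precision_edge <- ratio_or_na(tp_edge, tp_edge + fp_edge)
  recall_edge <- ratio_or_na(tp_edge, tp_edge + fn_edge)
  precision_dir <- ratio_or_na(tp_dir, tp_dir + fp_dir)
  recall_dir <- ratio_or_na(tp_dir, tp_dir + fn_dir)
  res <- list(
    tp_edge = tp_edge, fp_edge = fp_edge, fn_edge = fn_edge,
    tp_dir = tp_dir, fp_dir = fp_dir, fn_dir = fn_dir,
    precision_edge = precision_edge, recall_edge = recall_edge,
    f_edge = f_measure(precision_edge, recall_edge),
    precision_dir = precision_dir, recall_dir = recall_dir,
    f_dir = f_measure(precision_dir, recall_dir),
    add = ratio_or_na(tp_dir, tp_edge))
  metric_names <- c("precision_edge", "recall_edge", "f_edge",
                    "precision_dir", "recall_dir", "f_dir", "add")
  res$undefined <- metric_names[vapply(res[metric_names], is.na, logical(1))]
  class(res) <- "citl_eval"
  res
}

#' @export
print.citl_eval <- function(x, ...) {
  cat(sprintf("edges:      TP %d FP %d FN %d | P %.3f R %.3f F %.3f\n",
              x$tp_edge, x$fp_edge, x$fn_edge,
              x$precision_edge, x$recall_edge, x$f_edge))
  cat(sprintf("directions: TP %d FP %d FN %d | P %.3f R %.3f F %.3f | ADD %.3f\n",
              x$tp_dir, x$fp_dir, x$fn_dir,
              x$precision_dir, x$recall_dir, x$f_dir, x$add))
  if (length(x$undefined))
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' ROC and PR curves for scored ordered pairs
#'
#' Labels are the truth's directed edges over the ordered-pair space of the
#' score table, so a reversed prediction scores as a negative. The ROC curve
#' is integrated by the trapezoidal rule (ties grouped, which equals the
#' pairwise-comparison estimator with ties counted half); AUPR uses step
#' integration of precision over recall increments.
#'
#' @param scores data.frame with `source`, `target`, `score` (e.g. from
#'   [approach0()]).
#' @param g_true directed truth [causal_graph()].
#' @return list with `auroc`, `aupr` and a data.frame `curve` of
#'   (threshold, tpr, fpr, precision, recall) points.
#' @export
roc_pr <- function(scores, g_true) {
  stopifnot(all(c("source", "target", "score") %in% names(scores)),
            all(is.finite(scores$score)))
  true_keys <- paste(g_true$directed[, 1], g_true$directed[, 2], sep = ">")
  lab <- paste(scores$source, scores$target, sep = ">") %in% true_keys
  P <- sum(lab); N <- sum(!lab)
  if (P == 0L || N == 0L)
    return(list(auroc = NA_real_, aupr = NA_real_, curve = NULL,
                undefined = "single-class truth"))
  ord <- order(scores$score, decreasing = TRUE)
  s <- scores$score[ord]; l <- lab[ord]
  grp <- cumsum(!duplicated(s))                # tie groups share a threshold
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tp <- tp[last]; fp <- fp[last]
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  prec <- tp / (tp + fp); rec <- tp / P
  aupr <- sum(diff(c(0, rec)) * prec)
  list(auroc = auroc, aupr = aupr,
       curve = data.frame(threshold = s[last], tpr = tpr[-1], fpr = fpr[-1],
                          precision = prec, recall = rec))
}

#' Fisher's exact comparison of two direction accuracies
#'
#' Two-sided Fisher's exact test on the 2x2 table of correct/incorrect
#' direction calls in two groups (e.g. an inference method versus random
#' assignment).
#'
#' @param k1_correct,n1_total correct calls and total calls in group 1.
#' @param k2_correct,n2_total same for group 2.
#' @return the two-sided p-value.
#' @export
fisher_exact_direction_comparison <- function(k1_correct, n1_total,
                                              k2_correct, n2_total) {
  stopifnot(k1_correct >= 0, k1_correct <= n1_total,
            k2_correct >= 0, k2_correct <= n2_total)
  tab <- matrix(c(k1_correct, n1_total - k1_correct,
                  k2_correct, n2_total - k2_correct),
                nrow = 2, byrow = TRUE)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Top-correlated gene-set intersections
#'
#' For each gene i, three partner sets of size `per_set_size` are built from
#' the genes with the largest positive and largest negative correlations
#' (half each) between the current expression of i and, respectively, the
#' current (set `Scc`), subsequent (`Scs`) and changing (`Sch`) expression
#' of the partners. Pairwise intersection sizes are reported together with a
#' random-set control (|Scc n random| for a fresh uniform draw per gene).
#' Large `Scc`-vs-`Sch` intersections would mean the velocity layer carries
#' no information beyond the current one.
#'
#' @param panel an [expression_panel()] with `X_cur`, `X_sub`, `X_cha`.
#' @param per_set_size partner-set size (default 100: 50 positive + 50
#'   negative).
#' @return data.frame with one row per gene: `cc_cs`, `cc_ch`, `cs_ch`,
#'   `cc_random`.
#' @export
correlated_set_intersections <- function(panel, per_set_size = 100) {
  n <- length(panel$genes)
  if (n <= per_set_size)
    stop("need more genes than per_set_size")
  half <- per_set_size %/% 2
  Rcc <- stats::cor(panel$X_cur, panel$X_cur)
  Rcs <- stats::cor(panel$X_cur, panel$X_sub)
  Rch <- stats::cor(panel$X_cur, panel$X_cha)
  top_set <- function(r, i) {
    r[i] <- NA                              # exclude the gene itself
    ord <- order(r, decreasing = TRUE, na.last = NA)
    c(utils::head(ord, half), utils::tail(ord, half))
  }
  out <- t(vapply(seq_len(n), function(i) {
    scc <- top_set(Rcc[i, ], i)
    scs <- top_set(Rcs[i, ], i)
    sch <- top_set(Rch[i, ], i)
    rnd <- sample(setdiff(seq_len(n), i), per_set_size)
    c(cc_cs = length(intersect(scc, scs)),
      cc_ch = length(intersect(scc, sch)),
      cs_ch = length(intersect(scs, sch)),
      cc_random = length(intersect(scc, rnd)))
  }, numeric(4)))
  data.frame(gene = panel$genes, out, stringsAsFactors = FALSE)
}
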