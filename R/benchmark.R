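#' Replicated simulation benchmark
#'
#' Runs `n_reps` independent replicates of: draw a fresh ground-truth graph
#' and expression panel from `config`, run each requested method, and score
#' it against the (latent-restricted) truth with [eval_report()]. CITL and
#' Approach 3 operate on the same current + changing variables, so their
#' shared skeleton is learned once per replicate.
#'
#' Methods: `"citl"`, `"approach0"` (needs `threshold`), `"approach1"`,
#' `"approach2"`, `"approach3"`, and `"truth"` (an oracle returning the true
#' graph, useful for harness checks).
#'
#' @param config a [sim_config()] describing one replicate.
#' @param methods character vector of method names.
#' @param n_reps number of replicates.
#' @param seed integer master seed; per-replicate seeds are derived from it.
#' @param threshold correlation threshold for `approach0`.
#' @param citl_k,citl_alpha CI-test parameters; default
#'   `k = floor(sqrt(n_genes))` over the *observed* genes, `alpha = 0.05`.
#' @return data.frame with one row per (replicate, method) and the
#'   [eval_report()] counts and metrics as columns.
#' @export
benchmark <- function(config, methods = c("citl", "approach1", "approach2", "approach3"),
                      n_reps = 100, seed = 1, threshold = 0.2,
                      citl_k = NULL, citl_alpha = 0.05) {
  known <- c("citl", "approach0", "approach1", "approach2", "approach3", "truth")
  stopifnot(all(methods %in% known), n_reps >= 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  rows <- vector("list", n_reps * length(methods))
  ri <- 0L
  for (rep in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- rep_seeds[rep]
    sim <- simulate_panel(cfg)
    panel <- sim$panel
    truth <- sim$graph
    cf <- citl_config(length(panel$genes), alpha = citl_alpha)
    if (!is.null(citl_k)) cf$k <- as.integer(citl_k)
    shared_vg <- NULL
    if (any(c("citl", "approach3") %in% methods)) {
      shared_vg <- learn_skeleton(stack_layers(panel, c("cur", "cha")),
                                  k = cf$k, alpha = cf$alpha)
    }
    for (m in methods) {
      g <- switch(m,
        truth = truth,
        citl = calls_from_ug(shared_vg, panel$genes),
        approach0 = approach0(panel, threshold)$graph,
        approach1 = run_approach(panel, 1, cf),
        approach2 = run_approach(panel, 2, cf),
        approach3 = project_cross_cpdag(orient_cpdag(shared_vg), panel$genes))
      ev <- eval_report(g, truth)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        rep = rep, seed = rep_seeds[rep], method = m,
        n_true_edges = nrow(truth$directed),
        ev[c("tp_edge", "fp_edge", "fn_edge", "tp_dir", "fp_dir", "fn_dir",
             "precision_edge", "recall_edge", "f_edge",
             "precision_dir", "recall_dir", "f_dir", "add")],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Summarize a benchmark table
#'
#' Mean and sample standard deviation (n-1 denominator) of every metric per
#' method, skipping undefined (`NA`) replicate values and reporting how many
#' were skipped.
#'
#' @param results data.frame from [benchmark()].
#' @return data.frame with one row per (method, metric): `mean`, `sd`,
#'   `n_used`, `n_undefined`.
#' @export
summarize_benchmark <- function(results) {
  metrics <- c("precision_edge", "recall_edge", "f_edge",
               "precision_dir", "recall_dir", "f_dir", "add")
  out <- list()
  for (m in unique(results$method)) {
    sub <- results[results$method == m, , drop = FALSE]
    for (met in metrics) {
      v <- sub[[met]]
      out[[length(out) + 1L]] <- data.frame(
        method = m, metric = met,
        mean = mean(v, na.rm = TRUE),
        sd = stats::sd(v, na.rm = TRUE),
        n_used = sum(!is.na(v)), n_undefined = sum(is.na(v)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
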