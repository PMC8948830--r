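## read one delimited matrix: gene-name header, cell IDs in the first column
read_matrix_file <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  m
}

write_matrix_file <- function(m, path, sep = "\t") {
  df <- data.frame(cell = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Read an expression panel from delimited matrix files
#'
#' Matrices are cells x genes with a gene-name header row and cell
#' identifiers in the first column. Gene (and cell) order is harmonized by
#' name against the current-expression file; a gene or cell present in one
#' file but not another is an error naming the offenders. Velocity (`X_cha`)
#' is signed and used as-is; when only `cha` is given, `X_sub` is completed
#' as `X_cur + X_cha`, and vice versa.
#'
#' @param cur_path path of the current-expression matrix. Required.
#' @param cha_path,sub_path,pre_path optional paths for the changing,
#'   subsequent and previous layers (at least one of `cha_path`/`sub_path`
#'   is needed for inference).
#' @param sep field separator (default tab; use "," for CSV).
#' @return an [expression_panel()].
#' @export
read_panel <- function(cur_path, cha_path = NULL, sub_path = NULL,
                       pre_path = NULL, sep = "\t") {
  cur <- read_matrix_file(cur_path, sep)
  align <- function(m, what) {
    miss_g <- setdiff(colnames(cur), colnames(m))
    extra_g <- setdiff(colnames(m), colnames(cur))
    if (length(miss_g) || length(extra_g))
      stop(sprintf("gene mismatch in %s: missing [%s], unexpected [%s]", what,
                   paste(miss_g, collapse = ", "), paste(extra_g, collapse = ", ")))
    miss_c <- setdiff(rownames(cur), rownames(m))
    if (length(miss_c))
      stop(sprintf("cell mismatch in %s: missing [%s]", what,
                   paste(miss_c, collapse = ", ")))
    m[rownames(cur), colnames(cur), drop = FALSE]
  }
  cha <- if (!is.null(cha_path)) align(read_matrix_file(cha_path, sep), "cha") else NULL
  sub <- if (!is.null(sub_path)) align(read_matrix_file(sub_path, sep), "sub") else NULL
  pre <- if (!is.null(pre_path)) align(read_matrix_file(pre_path, sep), "pre") else NULL
  expression_panel(X_cur = cur, X_cha = cha, X_sub = sub, X_pre = pre)
}

#' Write an expression panel to a directory of delimited matrices
#'
#' Writes `cur.tsv`, and `cha.tsv`/`sub.tsv`/`pre.tsv` for the layers
#' present, in the format [read_panel()] expects.
#'
#' @param panel an [expression_panel()].
#' @param dir output directory (created if needed).
#' @param sep field separator.
#' @return the directory, invisibly.
#' @export
write_panel <- function(panel, dir, sep = "\t") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(X_cur = "cur.tsv", X_cha = "cha.tsv", X_sub = "sub.tsv", X_pre = "pre.tsv")
  for (nm in names(files)) {
    if (!is.null(panel[[nm]]))
      write_matrix_file(panel[[nm]], file.path(dir, files[[nm]]), sep)
  }
  invisible(dir)
}

#' Write / read a causal graph as a TSV edge list
#'
#' Columns `source`, `target`, `orientation` (`directed` or `undirected`),
#' plus any extra columns passed through `extra` (e.g. Approach-0 scores).
#' Reading validates rows and rejects duplicate contradictory entries.
#'
#' @param graph a [causal_graph()].
#' @param path output file.
#' @param extra optional data.frame of additional columns, one row per edge
#'   (directed edges first, then undirected).
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path, extra = NULL) {
  df <- rbind(
    if (nrow(graph$directed))
      data.frame(source = graph$directed[, 1], target = graph$directed[, 2],
                 orientation = "directed", stringsAsFactors = FALSE),
    if (nrow(graph$undirected))
      data.frame(source = graph$undirected[, 1], target = graph$undirected[, 2],
                 orientation = "undirected", stringsAsFactors = FALSE))
  if (is.null(df))
    df <- data.frame(source = character(0), target = character(0),
                     orientation = character(0))
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_graph
#' @param genes optional gene universe; defaults to the genes seen in the
#'   file.
#' @return for `read_graph`, a [causal_graph()].
#' @export
read_graph <- function(path, genes = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("source", "target", "orientation")
  if (!all(need %in% names(df)))
    stop("graph file must have columns source, target, orientation")
  bad <- which(!df$orientation %in% c("directed", "undirected"))
  if (length(bad))
    stop("malformed orientation at line(s) ", paste(bad + 1L, collapse = ", "))
  if (is.null(genes)) genes <- sort(unique(c(df$source, df$target)))
  d <- df[df$orientation == "directed", c("source", "target"), drop = FALSE]
  u <- df[df$orientation == "undirected", c("source", "target"), drop = FALSE]
  dk <- pair_key(d$source, d$target)
  uk <- pair_key(u$source, u$target)
  if (any(uk %in% dk))
    stop("contradictory duplicate rows: pair(s) both directed and undirected: ",
         paste(unique(uk[uk %in% dk]), collapse = ", "))
  causal_graph(genes, directed = as.matrix(d), undirected = as.matrix(u))
}

#' Write a provenance record
#'
#' JSON record of the package version, resolved configuration and seed --
#' enough to reproduce a run bit-exactly.
#'
#' @param path output JSON file.
#' @param config configuration object (list-like).
#' @param seed the seed used.
#' @param extra optional named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, config, seed = NULL, extra = list()) {
  rec <- c(list(package = "citl",
                version = as.character(utils::packageVersion("citl")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                seed = seed,
                config = unclass(config)),
           extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
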