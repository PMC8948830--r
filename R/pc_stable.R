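#' Learn a PC-stable skeleton
#'
#' Order-independent skeleton search (the "stable" PC variant): starting from
#' the complete undirected graph, for each level l = 0, 1, ..., k every
#' remaining edge (x, y) is tested against all conditioning sets of size l
#' drawn from the adjacency sets of x and of y *as frozen at the start of the
#' level*; the edge is deleted (and the separating set recorded) on the first
#' accepted independence. The search stops early once no adjacency set
#' exceeds the current level.
#'
#' @param data samples x variables matrix; column names become node names.
#' @param k maximum conditioning-set size.
#' @param alpha CI-test type-one error.
#' @return an object of class `variable_graph`: `nodes`, logical adjacency
#'   matrix `A`, `sepsets` (named list keyed by `i|j` column indices),
#'   `n_tests`, and the `k`, `alpha`, `n` used.
#' @export
learn_skeleton <- function(data, k, alpha = 0.05) {
  data <- as.matrix(data)
  p <- ncol(data)
  n <- nrow(data)
  stopifnot(k >= 0, alpha > 0, alpha < 1)
  nodes <- colnames(data)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(p))
  if (p == 1L) {
    return(structure(list(nodes = nodes, A = matrix(FALSE, 1, 1),
                          sepsets = list(), n_tests = 0L, k = k,
                          alpha = alpha, n = n),
                     class = "variable_graph"))
  }
  if (n <= 3) stop("need more than 3 samples")
  C <- stats::cor(data)
  sepsets <- list()
  n_tests <- p * (p - 1L) / 2L
  ## level 0: marginal Fisher-z tests, vectorized
  Cc <- pmin(pmax(C, -1 + 1e-15), 1 - 1e-15)
  pv <- 2 * stats::pnorm(-abs(atanh(Cc) * sqrt(n - 3)))
  A <- pv < alpha
  diag(A) <- FALSE
  rm0 <- which(!A & upper.tri(A), arr.ind = TRUE)
  if (nrow(rm0)) {
    keys <- paste(rm0[, 1], rm0[, 2], sep = "|")
    sepsets[keys] <- rep(list(integer(0)), length(keys))
  }
  ell <- 1L
  while (ell <= k && n > ell + 3) {
    adj_frozen <- lapply(seq_len(p), function(v) which(A[v, ]))
    if (!any(lengths(adj_frozen) - 1L >= ell)) break
    edges <- which(A & upper.tri(A), arr.ind = TRUE)
    for (e in seq_len(nrow(edges))) {
      x <- edges[e, 1]; y <- edges[e, 2]
      removed <- FALSE
      for (side in 1:2) {
        nb <- if (side == 1L) setdiff(adj_frozen[[x]], y) else setdiff(adj_frozen[[y]], x)
        if (length(nb) < ell) next
        combs <- if (length(nb) == ell) matrix(nb, ncol = 1) else utils::combn(nb, ell)
        for (ci in seq_len(ncol(combs))) {
          S <- combs[, ci]
          r <- pcor_from_cor(C, x, y, S)
          n_tests <- n_tests + 1L
          if (fisher_z_pvalue(r, n, ell) >= alpha) {
            A[x, y] <- A[y, x] <- FALSE
            sepsets[[paste(x, y, sep = "|")]] <- S
            removed <- TRUE
            break
          }
        }
        if (removed) break
      }
    }
    ell <- ell + 1L
  }
  dimnames(A) <- list(nodes, nodes)
  structure(list(nodes = nodes, A = A, sepsets = sepsets, n_tests = n_tests,
                 k = k, alpha = alpha, n = n),
            class = "variable_graph")
}

#' @export
print.variable_graph <- function(x, ...) {
  cat(sprintf("<variable_graph> %d nodes, %d edges (%d CI tests, k = %d, alpha = %g)\n",
              length(x$nodes), sum(x$A) / 2, x$n_tests, x$k, x$alpha))
  invisible(x)
}

## retrieve the recorded sepset for an unordered index pair, or NULL
get_sepset <- function(vg, i, j) {
  vg$sepsets[[paste(min(i, j), max(i, j), sep = "|")]]
}

#' Orient a skeleton into a CPDAG
#'
#' Standard constraint-based orientation: every unshielded triple x - z - y
#' with z outside the recorded separating set of (x, y) becomes the collider
#' x -> z <- y, then Meek rules 1-4 are applied to closure. Conflicting
#' collider demands (an edge pushed in both directions) leave the edge
#' undirected, and a Meek rule never overrides an existing orientation;
#' conflicts are counted in the `n_conflicts` attribute.
#'
#' @param vg a `variable_graph` from [learn_skeleton()] (with sepsets).
#' @return an integer adjacency matrix `amat` with `amat[i, j] = 1` when
#'   there is an edge i -> j; an undirected edge has 1 in both positions.
#'   Class `citl_cpdag`, with the skeleton attached as attribute.
#' @export
orient_cpdag <- function(vg) {
  p <- length(vg$nodes)
  amat <- matrix(0L, p, p, dimnames = list(vg$nodes, vg$nodes))
  amat[vg$A] <- 1L
  n_conflicts <- 0L
  ## v-structures: collect demands, then resolve
  into <- matrix(FALSE, p, p)  # into[x, z]: demand x -> z
  if (p >= 3) {
    for (z in seq_len(p)) {
      nbz <- which(vg$A[z, ])
      if (length(nbz) < 2) next
      prs <- utils::combn(nbz, 2)
      for (q in seq_len(ncol(prs))) {
        x <- prs[1, q]; y <- prs[2, q]
        if (vg$A[x, y]) next                      # shielded
        if (!(z %in% get_sepset(vg, x, y))) {
          into[x, z] <- TRUE
          into[y, z] <- TRUE
        }
      }
    }
    conflict <- into & t(into)
    n_conflicts <- sum(conflict & upper.tri(conflict))
    orient <- into & !t(into)
    amat[t(orient)] <- 0L                         # x -> z: drop z -> x
  }
  directed <- function(a, b) amat[a, b] == 1L && amat[b, a] == 0L
  undirected <- function(a, b) amat[a, b] == 1L && amat[b, a] == 1L
  adjacent <- function(a, b) amat[a, b] == 1L || amat[b, a] == 1L
  orient_edge <- function(a, b) {
    ## a -> b, unless already directed the other way (never override)
    if (amat[a, b] == 1L && amat[b, a] == 1L) {
      amat[b, a] <<- 0L
      TRUE
    } else FALSE
  }
  ## Meek rules to closure
  repeat {
    changed <- FALSE
    und <- which(amat == 1L & t(amat) == 1L, arr.ind = TRUE)  # both orders present
    for (e in seq_len(nrow(und))) {
      a <- und[e, 1]; b <- und[e, 2]
      if (!(amat[a, b] == 1L && amat[b, a] == 1L)) next       # already oriented this pass
      ## R1: c -> a, a - b, c and b nonadjacent  =>  a -> b
      fired <- FALSE
      for (c in which(amat[, a] == 1L & amat[a, ] == 0L)) {
        if (!adjacent(c, b)) { fired <- orient_edge(a, b); break }
      }
      if (fired) { changed <- TRUE; next }
      ## R2: a -> c -> b with a - b  =>  a -> b
      for (c in seq_len(p)) {
        if (directed(a, c) && directed(c, b)) { fired <- orient_edge(a, b); break }
      }
      if (fired) { changed <- TRUE; next }
      ## R3: a - c -> b, a - d -> b, c and d nonadjacent  =>  a -> b
      cand <- which(vapply(seq_len(p), function(c)
        undirected(a, c) && directed(c, b), logical(1)))
      if (length(cand) >= 2) {
        prs <- utils::combn(cand, 2)
        for (q in seq_len(ncol(prs))) {
          if (!adjacent(prs[1, q], prs[2, q])) { fired <- orient_edge(a, b); break }
        }
      }
      if (fired) { changed <- TRUE; next }
      ## R4: a - d, c -> d? chain c -> e -> b with a adjacent to both,
      ##     b and c nonadjacent  =>  a -> b
      for (c in seq_len(p)) {
        if (!adjacent(a, c) || adjacent(b, c)) next
        hit <- FALSE
        for (d in seq_len(p)) {
          if (directed(c, d) && directed(d, b) && adjacent(a, d)) { hit <- TRUE; break }
        }
        if (hit) { fired <- orient_edge(a, b); break }
      }
      if (fired) changed <- TRUE
    }
    if (!changed) break
  }
  structure(amat, class = c("citl_cpdag", class(amat)),
            skeleton = vg, n_conflicts = n_conflicts)
}

#' Run PC-stable end to end
#'
#' [learn_skeleton()] followed by [orient_cpdag()].
#'
#' @inheritParams learn_skeleton
#' @return a `citl_cpdag` adjacency matrix (skeleton attached as attribute).
#' @export
pc_stable <- function(data, k, alpha = 0.05) {
  orient_cpdag(learn_skeleton(data, k, alpha))
}

#' Convert a CPDAG adjacency matrix to a causal graph
#'
#' One-way entries become directed edges, two-way entries undirected edges.
#'
#' @param amat a `citl_cpdag` (or any 0/1 adjacency matrix with names).
#' @return a [causal_graph()].
#' @export
cpdag_to_graph <- function(amat) {
  nodes <- colnames(amat)
  dir_idx <- which(amat == 1L & t(amat) == 0L, arr.ind = TRUE)
  und_idx <- which(amat == 1L & t(amat) == 1L & upper.tri(amat), arr.ind = TRUE)
  causal_graph(nodes,
               directed = cbind(nodes[dir_idx[, 1]], nodes[dir_idx[, 2]]),
               undirected = cbind(nodes[und_idx[, 1]], nodes[und_idx[, 2]]))
}
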