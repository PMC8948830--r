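## Shared fixtures: all data are generated in code at test time.

## linear-Gaussian sample from a chain A -> B -> C with unit noise
chain_data <- function(n = 3000, seed = 1) {
  set.seed(seed)
  A <- rnorm(n)
  B <- A + rnorm(n)
  C <- B + rnorm(n)
  cbind(A = A, B = B, C = C)
}

## collider A -> C <- B with independent A, B
collider_data <- function(n = 3000, seed = 1) {
  set.seed(seed)
  A <- rnorm(n)
  B <- rnorm(n)
  C <- A + B + rnorm(n)
  cbind(A = A, B = B, C = C)
}

## sample n observations from a linear-Gaussian DAG given a coefficient
## matrix B (B[i, j] = weight of edge i -> j), unit noise
dag_data <- function(Bmat, n, seed = 1) {
  set.seed(seed)
  p <- ncol(Bmat)
  X <- matrix(NA_real_, n, p)
  remaining <- seq_len(p)
  done <- logical(p)
  while (any(!done)) {
    for (j in which(!done)) {
      pa <- which(Bmat[, j] != 0)
      if (all(done[pa])) {
        contrib <- if (length(pa)) X[, pa, drop = FALSE] %*% Bmat[pa, j] else 0
        X[, j] <- contrib + rnorm(n)
        done[j] <- TRUE
      }
    }
  }
  colnames(X) <- colnames(Bmat)
  X
}

## residual-on-residual partial correlation oracle (independent of the
## correlation-matrix-inversion path in the package)
pcor_oracle <- function(data, x, y, z) {
  if (length(z) == 0) return(cor(data[, x], data[, y]))
  rx <- resid(lm(data[, x] ~ data[, z, drop = FALSE]))
  ry <- resid(lm(data[, y] ~ data[, z, drop = FALSE]))
  cor(rx, ry)
}

## exhaustive-conditioning skeleton oracle: an edge survives only if no
## subset of the remaining variables (size <= k) renders the pair independent
skeleton_oracle <- function(data, k, alpha = 0.05) {
  p <- ncol(data)
  n <- nrow(data)
  A <- matrix(TRUE, p, p); diag(A) <- FALSE
  for (x in seq_len(p - 1)) for (y in (x + 1):p) {
    others <- setdiff(seq_len(p), c(x, y))
    for (l in 0:min(k, length(others))) {
      sets <- if (l == 0) list(integer(0)) else if (length(others) == l)
        list(others) else asplit(combn(others, l), 2)
      for (S in sets) {
        r <- pcor_oracle(data, x, y, S)
        pval <- 2 * pnorm(-abs(atanh(max(min(r, 1 - 1e-15), -1 + 1e-15)) * sqrt(n - l - 3)))
        if (pval >= alpha) { A[x, y] <- A[y, x] <- FALSE }
      }
    }
  }
  A
}

## extract the set of directed-edge strings "a>b" from a causal_graph
dir_keys <- function(g) {
  if (nrow(g$directed) == 0) return(character(0))
  sort(paste(g$directed[, 1], g$directed[, 2], sep = ">"))
}
und_keys <- function(g) {
  if (nrow(g$undirected) == 0) return(character(0))
  sort(paste(g$undirected[, 1], g$undirected[, 2], sep = "|"))
}
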