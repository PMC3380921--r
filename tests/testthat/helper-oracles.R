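# Independent oracles, deliberately implemented through different
# primitives than the package (matrix algebra / enumeration instead of
# edge-list set operations).

# undirected, sign-blind adjacency matrix (no self-loops)
adjMatrix <- function(g) {
  n <- nodes(g)
  A <- matrix(0L, length(n), length(n), dimnames = list(n, n))
  e <- edges(g)
  e <- e[e$from != e$to, , drop = FALSE]
  A[cbind(e$from, e$to)] <- 1L
  A[cbind(e$to, e$from)] <- 1L
  A
}

# NSI from raw adjacency sets: (M + C)/(D + C)
nsiOracle <- function(g, i, j) {
  A <- adjMatrix(g)
  ni <- setdiff(names(which(A[i, ] > 0)), c(i, j))
  nj <- setdiff(names(which(A[j, ] > 0)), c(i, j))
  e <- edges(g)
  C <- sum(e$from == i & e$to == j) + sum(e$from == j & e$to == i)
  M <- length(intersect(ni, nj))
  D <- length(union(ni, nj))
  (M + C) / (D + C)
}

# exact two-sided mid-p of the signed-rank test by enumerating all
# 2^n sign assignments (n <= 14); the mid-p is what the uncorrected
# normal approximation targets
exactWilcoxonMidP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  wpos <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wp <- as.vector(signs %*% r)
  pl <- mean(Wp < wpos) + 0.5 * mean(Wp == wpos)
  pu <- mean(Wp > wpos) + 0.5 * mean(Wp == wpos)
  min(1, 2 * min(pl, pu))
}

# brute-force degree counts by scanning the edge list row by row
degreesOracle <- function(g) {
  e <- edges(g)
  sapply(nodes(g), function(nd)
    c(in_d = sum(e$to == nd), out_d = sum(e$from == nd)))
}

# two-pass Pearson with explicit t transform
pearsonOracle <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# small random test graph distinct from the fixtures generator
randomTestGraph <- function(n, p = 0.2, seed) {
  set.seed(seed)
  nm <- paste0("n", seq_len(n))
  pairs <- expand.grid(from = nm, to = nm, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  e <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
  if (!nrow(e)) e <- data.frame(from = nm[1], to = nm[2])
  signedDigraph(data.frame(from = e$from, to = e$to,
                           sign = ifelse(runif(nrow(e)) < 0.2, -1L, 1L)),
                nodes = nm)
}
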