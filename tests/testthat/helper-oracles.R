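# Independent oracles used to validate the package's own implementations.

# Union-find connected components (oracle for connected_components()).
uf_components <- function(n, edges) {
  edges <- matrix(as.integer(edges), ncol = ncol(edges))
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (nrow(edges) > 0) for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1]); b <- find(edges[k, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

# All set partitions of n elements as membership vectors (restricted growth).
enum_partitions <- function(n) {
  out <- list()
  rec <- function(memb, kmax) {
    i <- length(memb) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- memb; return() }
    for (c in seq_len(kmax + 1L)) rec(c(memb, c), max(kmax, c))
  }
  rec(integer(0), 0L)
  out
}

# Brute-force two-category assortativity via the explicit 2x2 e-matrix.
assort_oracle <- function(el, target) {
  e <- matrix(0, 2, 2)
  m <- nrow(el)
  for (k in seq_len(m)) {
    ci <- if (target[el[k, 1]]) 1 else 2
    cj <- if (target[el[k, 2]]) 1 else 2
    e[ci, cj] <- e[ci, cj] + 1 / (2 * m)
    e[cj, ci] <- e[cj, ci] + 1 / (2 * m)
  }
  a <- rowSums(e)
  denom <- 1 - sum(a^2)
  if (denom <= 1e-12) return(NA_real_)  # float slack on the accumulated sums
  (sum(diag(e)) - sum(a^2)) / denom
}

# Exact Hamming-based percent identity for equal-length, indel-free pairs.
hamming_pid <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  100 * mean(av == bv)
}

# Random weighted graph via igraph, seeded.
random_weighted_graph <- function(n, p, seed, wmin = 85, wmax = 100) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  if (igraph::ecount(g) > 0)
    igraph::E(g)$weight <- stats::runif(igraph::ecount(g), wmin, wmax)
  g
}
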