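# independent brute-force oracles used to verify the implementations

# naive double-loop versions of the four similarity metrics
bf_mean_pairwise <- function(set, D) {
  set <- unique(set)
  acc <- c()
  for (i in seq_along(set)) for (j in seq_along(set))
    if (i < j) acc <- c(acc, D[set[i], set[j]])
  mean(acc)
}

bf_mean_nearest <- function(set, D) {
  set <- unique(set)
  mins <- c()
  for (i in seq_along(set)) {
    best <- Inf
    for (j in seq_along(set))
      if (i != j && D[set[i], set[j]] < best) best <- D[set[i], set[j]]
    mins <- c(mins, best)
  }
  mean(mins)
}

bf_in_mean <- function(sp, set, D) {
  set <- setdiff(unique(set), sp)
  acc <- c()
  for (j in seq_along(set)) acc <- c(acc, D[sp, set[j]])
  mean(acc)
}

bf_in_nearest <- function(sp, set, D) {
  set <- setdiff(unique(set), sp)
  best <- Inf
  for (j in seq_along(set)) if (D[sp, set[j]] < best) best <- D[sp, set[j]]
  best
}

# random species-labelled distance matrix
random_dist <- function(n, seed) {
  withr::with_seed(seed, {
    M <- matrix(runif(n * n, 0.1, 5), n, n)
    D <- (M + t(M)) / 2
    diag(D) <- 0
    dimnames(D) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
    D
  })
}

# exhaustive permutation enumeration for the Mantel p-value, written
# independently of the package internals (iterative heap-style recursion)
enumerate_perms <- function(n) {
  if (n == 1) return(list(1L))
  # insert n into every slot of each permutation of n-1
  out <- list()
  for (sub in enumerate_perms(n - 1L))
    for (pos in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
  out
}

oracle_mantel_p <- function(D1, D2) {
  ut <- upper.tri(D1)
  x <- D1[ut]
  r_obs <- cor(x, D2[ut])
  rs <- vapply(enumerate_perms(nrow(D1)), function(p)
    cor(x, D2[p, p][ut]), numeric(1))
  list(r = r_obs, p = mean(rs >= r_obs - 1e-12))
}

# brute-force d-separation oracle: ancestral subgraph, moralize,
# delete conditioning set, then check undirected connectivity
oracle_dsep <- function(edges, x, y, cond) {
  nodes <- unique(c(edges$from, edges$to, x, y, cond))
  parents <- function(v) edges$from[edges$to == v]
  anc <- unique(c(x, y, cond))
  repeat {
    more <- unique(unlist(lapply(anc, parents)))
    new <- union(anc, more)
    if (length(new) == length(anc)) break
    anc <- new
  }
  sub <- edges[edges$from %in% anc & edges$to %in% anc, , drop = FALSE]
  # undirected adjacency of the moral graph
  adj <- matrix(FALSE, length(anc), length(anc),
                dimnames = list(anc, anc))
  for (i in seq_len(nrow(sub))) {
    adj[sub$from[i], sub$to[i]] <- TRUE
    adj[sub$to[i], sub$from[i]] <- TRUE
  }
  for (v in anc) {                     # marry co-parents
    pa <- intersect(parents(v), anc)
    if (length(pa) > 1)
      for (a in pa) for (b in pa) if (a != b) adj[a, b] <- TRUE
  }
  keep <- setdiff(anc, cond)           # remove conditioning nodes
  adj <- adj[keep, keep, drop = FALSE]
  # BFS from x
  frontier <- x; seen <- x
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(v)
      keep[adj[v, ]])))
    frontier <- setdiff(nxt, seen)
    seen <- union(seen, frontier)
  }
  !(y %in% seen)                       # TRUE = d-separated
}

# sem_dag over an edge list that may be empty (skip those cases)
sem_dag_or_null <- function(edges, n) {
  if (nrow(edges) == 0) return(NULL)
  sem_dag(edges, binary = character(), random = NULL)
}

# all DAGs whose edges respect the node order 1 < 2 < ... < n (every DAG
# is isomorphic to one of these, and d-separation is label-invariant)
ordered_dags <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  lapply(seq_len(2^m) - 1L, function(mask) {
    sel <- bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0
    data.frame(from = sprintf("n%d", pairs[sel, 1]),
               to = sprintf("n%d", pairs[sel, 2]))
  })
}

# minimal hand-built dredge table for averaging arithmetic tests
fake_dredge <- function(deltas, coefs, ses) {
  tab <- data.frame(subset = letters[seq_along(deltas)],
                    df = 3, loglik = 0, aicc = deltas,
                    delta = deltas - min(deltas))
  tab$weight <- exp(-tab$delta / 2) / sum(exp(-tab$delta / 2))
  fits <- lapply(seq_along(deltas), function(i)
    list(coef = coefs[[i]], se = ses[[i]]))
  structure(tab, fits = fits, class = c("dredge_table", "data.frame"))
}

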