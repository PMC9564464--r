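# Brute-force oracles for small graphs, deliberately independent of the
# package's (igraph-backed) implementations: reachability by repeated
# boolean matrix products, shortest paths by exhaustive simple-path
# enumeration.

bf_reach <- function(a) {
  n <- nrow(a)
  r <- a > 0
  for (step in seq_len(n)) r <- r | ((r %*% a) > 0)
  diag(r) <- FALSE
  r
}

bf_components <- function(a) {
  u <- (a + t(a)) > 0
  r <- bf_reach(u * 1)
  diag(r) <- TRUE
  comp <- rep(NA_integer_, nrow(a))
  k <- 0
  for (i in seq_len(nrow(a))) {
    if (is.na(comp[i])) { k <- k + 1; comp[which(r[i, ] | seq_len(nrow(a)) == i)] <- k }
  }
  comp
}

bf_connectedness <- function(a) {
  n <- nrow(a)
  comp <- bf_components(a)
  pairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (comp[i] == comp[j]) pairs <- pairs + 1
  pairs / choose(n, 2)
}

bf_hierarchy <- function(a) {
  n <- nrow(a)
  r <- bf_reach(a)
  either <- 0; both <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (r[i, j] || r[j, i]) either <- either + 1
    if (r[i, j] && r[j, i]) both <- both + 1
  }
  if (either == 0) 0 else 1 - both / either
}

bf_efficiency <- function(a) {
  u <- (a + t(a)) > 0
  L <- sum(u) / 2
  comp <- bf_components(a)
  cs <- as.integer(table(comp))
  extra <- L - sum(cs - 1)
  max_extra <- sum(choose(cs, 2) - (cs - 1))
  if (max_extra == 0) 1 else 1 - extra / max_extra
}

# all simple paths i -> j in an undirected 0/1 matrix; returns list of paths
bf_all_paths <- function(u, from, to) {
  paths <- list()
  recurse <- function(path) {
    last <- path[length(path)]
    if (last == to) { paths[[length(paths) + 1]] <<- path; return() }
    for (nxt in which(u[last, ] > 0)) if (!nxt %in% path) recurse(c(path, nxt))
  }
  recurse(from)
  paths
}

# undirected Freeman betweenness percentages by exhaustive path enumeration
bf_betweenness <- function(a) {
  n <- nrow(a)
  u <- ((a + t(a)) > 0) * 1
  raw <- numeric(n)
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    paths <- bf_all_paths(u, j, k)
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1))
    sp <- paths[lens == min(lens)]
    for (i in seq_len(n)) {
      if (i == j || i == k) next
      thru <- sum(vapply(sp, function(p) i %in% p, logical(1)))
      raw[i] <- raw[i] + thru / length(sp)
    }
  }
  100 * raw / ((n - 1) * (n - 2) / 2)
}

# undirected geodesic distances by shortest simple path enumeration
bf_distances <- function(a) {
  n <- nrow(a)
  u <- ((a + t(a)) > 0) * 1
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    paths <- bf_all_paths(u, j, k)
    if (length(paths))
      d[j, k] <- d[k, j] <- min(vapply(paths, length, integer(1))) - 1
  }
  d
}

bf_closeness <- function(a, strict = FALSE) {
  n <- nrow(a)
  d <- bf_distances(a)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    di <- d[i, -i]
    reach <- is.finite(di)
    if (all(reach)) cc[i] <- 100 * (n - 1) / sum(di)
    else if (strict || !any(reach)) cc[i] <- 0
    else cc[i] <- 100 * sum(reach) / sum(di[reach])
  }
  cc
}

# random digraph helper
random_digraph <- function(n, p) {
  a <- matrix(as.integer(stats::runif(n * n) < p), n, n)
  diag(a) <- 0L
  directed_network(a)
}
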