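#' Whole-network structure indices
#'
#' Four overall measures of a directed association network, in the
#' Krackhardt tradition used by standard SNA software:
#'
#' * **density** — arcs divided by the n(n-1) possible arcs;
#' * **connectedness** (association degree) — fraction of unordered node
#'   pairs joined by some path in the underlying undirected graph;
#' * **hierarchy** (rank degree) — among unordered pairs reachable in at
#'   least one direction, the fraction that are *not* mutually reachable
#'   (0 when no pair is reachable at all);
#' * **efficiency** — 1 minus the proportion of redundant undirected edges
#'   beyond a spanning forest, relative to the maximum possible redundancy
#'   given the component structure (1 when no redundancy is possible).
#'
#' Higher efficiency means fewer redundant ties, i.e. a sparser and less
#' stable linkage structure.
#'
#' @param net A `directed_network`.
#' @return `whole_network_summary()` returns a classed list with `n_arcs`,
#'   `density`, `connectedness`, `hierarchy`, `efficiency`; the individual
#'   functions return a single number in \[0, 1\].
#' @examples
#' net <- generate_block_network(c(3, 3), p_in = 1, p_out = 0)
#' whole_network_summary(net)
#' @export
whole_network_summary <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  structure(list(n_arcs = sum(net$a),
                 density = network_density(net),
                 connectedness = connectedness(net),
                 hierarchy = hierarchy(net),
                 efficiency = efficiency(net)),
            class = "whole_network_summary")
}

#' @export
print.whole_network_summary <- function(x, ...) {
  cat(sprintf(paste0("Whole-network indices: %d arcs\n",
                     "  density       %.4f\n  connectedness %.4f\n",
                     "  hierarchy     %.4f\n  efficiency    %.4f\n"),
              x$n_arcs, x$density, x$connectedness, x$hierarchy, x$efficiency))
  invisible(x)
}

#' @rdname whole_network_summary
#' @export
network_density <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  n <- net$n
  if (n < 2) stop("need at least two nodes")
  sum(net$a) / (n * (n - 1))
}

#' @rdname whole_network_summary
#' @export
connectedness <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  n <- net$n
  if (n < 2) stop("need at least two nodes")
  comp <- igraph::components(as_igraph(net, directed = FALSE))
  reachable_pairs <- sum(choose(comp$csize, 2))
  reachable_pairs / choose(n, 2)
}

#' @rdname whole_network_summary
#' @export
hierarchy <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  n <- net$n
  if (n < 2) stop("need at least two nodes")
  d <- igraph::distances(as_igraph(net), mode = "out")
  reach <- is.finite(d) & (row(d) != col(d))   # i reaches j
  either <- reach | t(reach)
  both <- reach & t(reach)
  n_either <- sum(either) / 2
  if (n_either == 0) return(0)
  1 - (sum(both) / 2) / n_either
}

#' @rdname whole_network_summary
#' @export
efficiency <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  if (net$n < 2) stop("need at least two nodes")
  und <- symmetrize(net$a)
  L <- sum(und) / 2
  csize <- igraph::components(as_igraph(net, directed = FALSE))$csize
  extra <- L - sum(csize - 1)
  max_extra <- sum(choose(csize, 2) - (csize - 1))
  if (max_extra == 0) return(1)
  1 - extra / max_extra
}
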