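#' Degree centrality
#'
#' Two conventions are supported, both reported as percentages:
#'
#' * `"neighbor"` (default): 100 times the number of *distinct* neighbours
#'   in the symmetrized graph divided by (n - 1). This is the convention
#'   standard SNA software labels "Degree" for a directed network and the
#'   one the packaged reference table uses.
#' * `"eq2"`: 100 * (in-degree + out-degree) / (2 (n - 1)), the textbook
#'   normalized average of in- and out-degree. The two coincide only when
#'   no dyad is reciprocated.
#'
#' @param net A `directed_network`.
#' @param convention `"neighbor"` or `"eq2"`.
#' @return Named numeric vector of percentages, one per node.
#' @export
degree_centrality <- function(net, convention = c("neighbor", "eq2")) {
  stopifnot(inherits(net, "directed_network"))
  convention <- match.arg(convention)
  n <- net$n
  if (n < 2) stop("need at least two nodes")
  if (convention == "neighbor") {
    v <- 100 * rowSums(symmetrize(net$a)) / (n - 1)
  } else {
    v <- 100 * (colSums(net$a) + rowSums(net$a)) / (2 * (n - 1))
  }
  stats::setNames(as.numeric(v), net$labels)
}

#' Betweenness centrality
#'
#' Freeman shortest-path betweenness, normalized to a percentage:
#' `100 * 2 * sum_{j<k} g_jk(i)/g_jk / ((n-1)(n-2))`, where `g_jk` counts
#' shortest paths between j and k and `g_jk(i)` those passing through i;
#' disconnected pairs contribute 0. Computed on the symmetrized graph by
#' default (the normalization is the undirected one); set
#' `symmetrize = FALSE` for directed betweenness over ordered pairs,
#' normalized by (n-1)(n-2).
#'
#' @param net A `directed_network` with at least 3 nodes.
#' @param symmetrize Use the underlying undirected graph. Default `TRUE`.
#' @return Named numeric vector of percentages.
#' @export
betweenness_centrality <- function(net, symmetrize = TRUE) {
  stopifnot(inherits(net, "directed_network"))
  n <- net$n
  if (n < 3) stop("betweenness normalization requires at least 3 nodes")
  g <- as_igraph(net, directed = !symmetrize)
  b <- igraph::betweenness(g, directed = !symmetrize)
  denom <- if (symmetrize) (n - 1) * (n - 2) / 2 else (n - 1) * (n - 2)
  stats::setNames(100 * as.numeric(b) / denom, net$labels)
}

#' Closeness centrality
#'
#' Reciprocal-farness closeness as a percentage:
#' `CC_i = 100 * (n - 1) / sum_j d_ij` with geodesic distances `d_ij` on
#' the symmetrized graph by default. On a disconnected graph each node's
#' closeness is computed within its own component (with `n` replaced by the
#' component size) and the result carries a `disconnected` attribute; under
#' `strict = TRUE` nodes that cannot reach the whole graph score 0.
#' Isolates score 0 in either mode.
#'
#' @param net A `directed_network`.
#' @param symmetrize Use the underlying undirected graph. Default `TRUE`.
#' @param strict Score nodes in broken components as 0. Default `FALSE`.
#' @return Named numeric vector of percentages; attribute `disconnected`
#'   is `TRUE` when any pair was unreachable.
#' @export
closeness_centrality <- function(net, symmetrize = TRUE, strict = FALSE) {
  stopifnot(inherits(net, "directed_network"))
  n <- net$n
  if (n < 2) stop("need at least two nodes")
  g <- as_igraph(net, directed = !symmetrize)
  d <- igraph::distances(g, mode = "out")
  cc <- numeric(n)
  disconnected <- any(is.infinite(d[row(d) != col(d)]))
  for (i in seq_len(n)) {
    di <- d[i, -i]
    reach <- is.finite(di)
    if (all(reach)) {
      cc[i] <- 100 * (n - 1) / sum(di)
    } else if (strict || !any(reach)) {
      cc[i] <- 0
    } else {
      cc[i] <- 100 * sum(reach) / sum(di[reach])   # within own component
    }
  }
  out <- stats::setNames(cc, net$labels)
  attr(out, "disconnected") <- disconnected
  out
}

#' Per-node centrality table
#'
#' Assembles the standard report: raw in- and out-degree plus the three
#' centralities as percentages, in node order. Values are rounded to
#' `digits` decimals for presentation (3 matches the reference table).
#'
#' @param net A `directed_network`.
#' @param convention Degree convention, see [degree_centrality()].
#' @param symmetrize Passed to betweenness and closeness.
#' @param digits Rounding for the percentage columns; `NULL` keeps full
#'   precision.
#' @return Data frame with columns `region`, `in_degree`, `out_degree`,
#'   `degree`, `betweenness`, `closeness`.
#' @export
centrality_table <- function(net, convention = "neighbor", symmetrize = TRUE,
                             digits = NULL) {
  stopifnot(inherits(net, "directed_network"))
  out <- data.frame(
    region = net$labels,
    in_degree = as.integer(colSums(net$a)),
    out_degree = as.integer(rowSums(net$a)),
    degree = degree_centrality(net, convention),
    betweenness = betweenness_centrality(net, symmetrize),
    closeness = as.numeric(closeness_centrality(net, symmetrize)),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(digits))
    for (cl in c("degree", "betweenness", "closeness"))
      out[[cl]] <- round(out[[cl]], digits)
  out
}
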