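#' Directed binary association network
#'
#' Lightweight container for a directed, unweighted network over labelled
#' regions: a square 0/1 adjacency matrix with a zero diagonal, where
#' `a[i, j] == 1` means region `i` sends an association to region `j`.
#'
#' @param a Square numeric matrix with entries in \{0, 1\} and zero diagonal.
#' @param labels Character vector of region labels; defaults to the row names
#'   of `a` (or `V1..Vn` if unnamed).
#' @return An object of class `directed_network`: a list with elements
#'   `a` (integer adjacency matrix with dimnames), `labels`, and `n`.
#' @examples
#' a <- matrix(0, 3, 3); a[1, 2] <- 1; a[2, 3] <- 1
#' net <- directed_network(a, labels = c("A", "B", "C"))
#' net$n
#' @export
directed_network <- function(a, labels = NULL) {
  a <- as.matrix(a)
  if (nrow(a) != ncol(a)) stop("adjacency matrix must be square")
  if (any(is.na(a))) stop("adjacency matrix contains NA")
  if (!all(a %in% c(0, 1))) stop("adjacency entries must be 0 or 1")
  if (any(diag(a) != 0)) stop("adjacency diagonal must be zero (no self-loops)")
  n <- nrow(a)
  if (is.null(labels)) labels <- rownames(a)
  if (is.null(labels)) labels <- paste0("V", seq_len(n))
  if (length(labels) != n) stop("labels length must equal matrix dimension")
  storage.mode(a) <- "integer"
  dimnames(a) <- list(labels, labels)
  structure(list(a = a, labels = labels, n = n), class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("Directed association network: %d nodes, %d arcs, density %.4f\n",
              x$n, sum(x$a), network_density(x)))
  invisible(x)
}

#' Convert a directed network to an igraph graph
#'
#' @param net A `directed_network`.
#' @param directed Keep arc directions (`TRUE`) or collapse to the underlying
#'   undirected graph (`FALSE`), in which case a tie in either direction
#'   becomes one edge.
#' @return An `igraph` graph with vertex names taken from the node labels.
#' @export
as_igraph <- function(net, directed = TRUE) {
  stopifnot(inherits(net, "directed_network"))
  m <- net$a
  if (!directed) {
    m <- (m + t(m)) > 0
    storage.mode(m) <- "integer"
    return(igraph::graph_from_adjacency_matrix(m, mode = "undirected"))
  }
  igraph::graph_from_adjacency_matrix(m, mode = "directed")
}

# symmetrized 0/1 matrix: tie in either direction
symmetrize <- function(a) {
  s <- (a + t(a)) > 0
  storage.mode(s) <- "integer"
  s
}

#' Read / write labelled square matrices
#'
#' Square matrices (adjacency, gravity, distance, dyadic covariates) are
#' stored as delimited text with the region labels in the first row and
#' first column.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return `read_square_matrix()` returns a numeric matrix with identical
#'   row and column names.
#' @export
read_square_matrix <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                         check.names = FALSE)
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) stop("matrix in ", path, " is not square")
  if (!identical(rownames(m), colnames(m)))
    stop("row and column labels differ in ", path)
  m
}

#' @param m Matrix with dimnames to write.
#' @rdname read_square_matrix
#' @export
write_square_matrix <- function(m, path, sep = ",") {
  utils::write.table(cbind(label = rownames(m), as.data.frame(m)),
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a network as an edge list or GraphML
#'
#' @param net A `directed_network`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "directed_network"))
  idx <- which(net$a == 1L, arr.ind = TRUE)
  el <- data.frame(source = net$labels[idx[, 1]], target = net$labels[idx[, 2]])
  el <- el[order(el$source, el$target), , drop = FALSE]
  utils::write.table(el, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
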