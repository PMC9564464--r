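#' CONCOR block partition
#'
#' CONvergence of iterated CORrelations. Each node's profile is the
#' concatenation of its adjacency row and column (ties sent and received;
#' configurable). Nodes are correlated pairwise, the correlation matrix is
#' itself correlated repeatedly until every off-diagonal entry is within
#' `conv_tol` of +/-1 (or `max_iter` is reached), and the node set is split
#' in two by the sign pattern of the converged matrix. The split recurses
#' on each group to the requested depth; groups of two or fewer nodes are
#' not split further, so the partition has at most `2^depth` blocks.
#'
#' A node whose profile has zero variance (e.g. an isolate) cannot be
#' correlated; its correlations are set to 0 with a warning and it is
#' grouped by its mean correlation to the two emerging groups.
#'
#' @param net A `directed_network` with at least 4 nodes.
#' @param depth Number of recursive bisection levels (>= 1). Default 2.
#' @param conv_tol Convergence tolerance on `abs(abs(r) - 1)`. Default 0.2,
#'   the conventional "concentration criterion".
#' @param max_iter Iteration cap per split. Default 25.
#' @param profile Which profile to correlate: `"both"` rows and columns
#'   (default), `"rows"` ties sent only, `"cols"` ties received only.
#' @return An object of class `block_partition`: list with `assignment`
#'   (integer block id named by node label), `labels`, `depth`, `n_blocks`.
#' @examples
#' net <- generate_block_network(c(8, 8), p_in = 0.9, p_out = 0.05, seed = 1)
#' concor_partition(net, depth = 1)
#' @export
concor_partition <- function(net, depth = 2, conv_tol = 0.2, max_iter = 25,
                             profile = c("both", "rows", "cols")) {
  stopifnot(inherits(net, "directed_network"))
  profile <- match.arg(profile)
  if (net$n < 4) stop("CONCOR needs at least 4 nodes")
  if (depth < 1) stop("depth must be at least 1")
  a <- net$a
  prof <- switch(profile,
                 both = rbind(a, t(a)),   # column i = row & column of node i
                 rows = t(a),
                 cols = a)
  assignment <- rep(1L, net$n)
  groups <- list(seq_len(net$n))
  for (level in seq_len(depth)) {
    new_groups <- list()
    for (g in groups) {
      if (length(g) <= 2) { new_groups <- c(new_groups, list(g)); next }
      halves <- concor_split(prof[, g, drop = FALSE], conv_tol, max_iter)
      if (length(unique(halves)) < 2) {       # degenerate: no polarization
        new_groups <- c(new_groups, list(g))
      } else {
        new_groups <- c(new_groups, list(g[halves == 1], g[halves == 2]))
      }
    }
    groups <- new_groups
  }
  for (b in seq_along(groups)) assignment[groups[[b]]] <- b
  structure(list(assignment = stats::setNames(assignment, net$labels),
                 labels = net$labels, depth = depth,
                 n_blocks = length(groups)),
            class = "block_partition")
}

# one CONCOR bisection on profile columns; returns 1/2 labels per column
concor_split <- function(prof, conv_tol, max_iter) {
  r <- safe_cor(prof)
  off <- row(r) != col(r)
  iter <- 0
  while (any(abs(abs(r[off]) - 1) > conv_tol) && iter < max_iter) {
    r <- safe_cor(r)
    iter <- iter + 1
  }
  s <- sign(r[1, ])
  s[1] <- 1
  ambiguous <- which(s == 0)
  if (length(ambiguous)) {
    for (i in ambiguous) {
      g1 <- which(s > 0); g2 <- which(s < 0)
      m1 <- mean(r[i, g1]); m2 <- if (length(g2)) mean(r[i, g2]) else -Inf
      s[i] <- if (m1 >= m2) 1 else -1
    }
  }
  ifelse(s > 0, 1L, 2L)
}

# Pearson correlation with zero-variance columns mapped to r = 0 (warned)
safe_cor <- function(m) {
  sds <- apply(m, 2, stats::sd)
  zero <- !is.finite(sds) | sds == 0
  if (any(zero))
    warning("constant profile(s): correlations set to 0 for ",
            sum(zero), " node(s)", call. = FALSE)
  r <- suppressWarnings(stats::cor(m))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  r
}

#' @export
print.block_partition <- function(x, ...) {
  cat(sprintf("CONCOR partition: %d blocks (depth %d)\n", x$n_blocks, x$depth))
  print(table(block = x$assignment))
  invisible(x)
}

#' Block flow accounting and spillover roles
#'
#' Counts, for every block, the ties received and sent inside versus
#' outside the block, computes the expected internal-relationship ratio
#' `100 (n_k - 1)/(n - 1)` and the actual ratio
#' `100 * inside_sent / (inside_sent + outside_sent)`, and classifies each
#' block's spillover role from its receive/send balance (see
#' [classify_roles()]).
#'
#' @param net A `directed_network`.
#' @param part A `block_partition` (or an integer/factor assignment named
#'   or ordered by node).
#' @param role_thresholds Passed to [classify_roles()].
#' @return Data frame of class `block_flow_summary`, one row per block:
#'   `block`, `n_regions`, `inside_received`, `outside_received`,
#'   `inside_sent`, `outside_sent`, `expected_internal_ratio`,
#'   `actual_internal_ratio`, `role`.
#' @export
block_flow_summary <- function(net, part,
                               role_thresholds = c(net_benefit = 2,
                                                   two_way = 1,
                                                   broker = 0.25)) {
  stopifnot(inherits(net, "directed_network"))
  assign <- block_assignment(part, net)
  blocks <- sort(unique(assign))
  n <- net$n
  flow <- arc_counts_by_block(net$a, assign, blocks)
  res <- data.frame(block = blocks,
                    n_regions = as.integer(table(factor(assign, blocks))),
                    stringsAsFactors = FALSE)
  res$inside_received <- diag(flow)
  res$outside_received <- colSums(flow) - diag(flow)
  res$inside_sent <- diag(flow)
  res$outside_sent <- rowSums(flow) - diag(flow)
  res$expected_internal_ratio <- 100 * (res$n_regions - 1) / (n - 1)
  tot_sent <- res$inside_sent + res$outside_sent
  res$actual_internal_ratio <- ifelse(tot_sent > 0,
                                      100 * res$inside_sent / tot_sent, NA_real_)
  res$role <- classify_roles(res$inside_received + res$outside_received,
                             tot_sent, thresholds = role_thresholds)
  class(res) <- c("block_flow_summary", "data.frame")
  res
}

# arcs from block k to block l
arc_counts_by_block <- function(a, assign, blocks) {
  f <- factor(assign, levels = blocks)
  idx <- which(a == 1L, arr.ind = TRUE)
  tab <- table(from = f[idx[, 1]], to = f[idx[, 2]])
  m <- matrix(as.integer(tab), nrow = length(blocks),
              dimnames = list(blocks, blocks))
  m
}

block_assignment <- function(part, net) {
  a <- if (inherits(part, "block_partition")) part$assignment else part
  if (!is.null(names(a))) {
    if (!setequal(names(a), net$labels)) stop("partition does not cover all nodes")
    a <- a[net$labels]
  } else if (length(a) != net$n) {
    stop("partition does not cover all nodes")
  }
  as.integer(factor(a, levels = sort(unique(a))))
}

#' Block-to-block density matrix
#'
#' `d[k, l]` is the number of arcs from block k to block l divided by the
#' number of possible arcs (`n_k * n_l` off the diagonal, `n_k (n_k - 1)`
#' on it). The size-weighted average over all cells equals the overall
#' network density exactly.
#'
#' @inheritParams block_flow_summary
#' @return Square numeric matrix over blocks.
#' @export
block_density_matrix <- function(net, part) {
  stopifnot(inherits(net, "directed_network"))
  assign <- block_assignment(part, net)
  blocks <- sort(unique(assign))
  sizes <- as.integer(table(factor(assign, blocks)))
  flow <- arc_counts_by_block(net$a, assign, blocks)
  possible <- outer(sizes, sizes)
  diag(possible) <- sizes * (sizes - 1)
  d <- ifelse(possible > 0, flow / possible, 0)
  dimnames(d) <- list(blocks, blocks)
  d
}

#' Image matrix
#'
#' Binarizes a block density matrix at the overall network density: a
#' block-to-block cell becomes 1 when its density reaches the overall
#' density (`>=` by default; `strict = TRUE` uses `>`).
#'
#' @param dm Block density matrix from [block_density_matrix()].
#' @param overall_density Cut-off, normally [network_density()] of the
#'   same network.
#' @param strict Use a strict inequality. Default `FALSE`.
#' @return Binary matrix of the same shape.
#' @export
image_matrix <- function(dm, overall_density, strict = FALSE) {
  b <- if (strict) dm > overall_density else dm >= overall_density
  storage.mode(b) <- "integer"
  b
}

#' Classify block spillover roles
#'
#' Deterministic operationalization of the four qualitative roles via the
#' receive/send ratio `rho = total_received / total_sent` (inside and
#' outside ties both counted):
#' `rho >= 2` net benefit; `1 <= rho < 2` two-way spillover;
#' `0.25 <= rho < 1` broker; `rho < 0.25` net spillover. The thresholds are
#' calibrated, not canonical, and are configurable. Blocks that send
#' nothing are unclassifiable (`NA`).
#'
#' @param received,sent Total ties received / sent per block.
#' @param thresholds Named numeric vector with elements `net_benefit`,
#'   `two_way`, `broker` (descending cut-points on `rho`).
#' @return Character vector of roles: `"net_benefit"`, `"two_way_spillover"`,
#'   `"broker"`, `"net_spillover"`, or `NA`.
#' @export
classify_roles <- function(received, sent,
                           thresholds = c(net_benefit = 2, two_way = 1,
                                          broker = 0.25)) {
  stopifnot(length(received) == length(sent))
  rho <- ifelse(sent > 0, received / sent, NA_real_)
  out <- rep(NA_character_, length(rho))
  out[!is.na(rho) & rho >= thresholds[["net_benefit"]]] <- "net_benefit"
  out[!is.na(rho) & rho < thresholds[["net_benefit"]] &
        rho >= thresholds[["two_way"]]] <- "two_way_spillover"
  out[!is.na(rho) & rho < thresholds[["two_way"]] &
        rho >= thresholds[["broker"]]] <- "broker"
  out[!is.na(rho) & rho < thresholds[["broker"]]] <- "net_spillover"
  if (any(is.na(rho) & (received > 0 | sent == 0)))
    warning("block(s) with zero sent ties are unclassifiable", call. = FALSE)
  out
}
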