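#' Modified-gravity intensity matrix
#'
#' Computes the dyadic gravitational intensity between regions from
#' IPAT-style masses and an asymmetric pollution-share weight:
#' \deqn{y_{ij} = k_{ij} \frac{(G_i P_i T_i C_i)^{1/4} (G_j P_j T_j C_j)^{1/4}}{D_{ij}^2},
#'       \quad k_{ij} = \frac{C_i}{C_i + C_j}}
#' where P is population, G gross regional product, T technology level
#' (patent counts), C pollutant concentration, and D inter-region distance.
#' The weight splits each dyad's intensity by the two sides' pollution
#' shares, so `k[i,j] + k[j,i] == 1` and the matrix is asymmetric.
#'
#' @param panel_year Data frame with one row per region and columns
#'   `region`, `population`, `grp`, `tech`, `pm25`, all strictly positive.
#' @param dist Labelled symmetric distance matrix; its labels must match
#'   `panel_year$region` as a set (rows are aligned by label).
#' @return An object of class `gravity_matrix`: list with `labels`,
#'   `y` (intensity matrix, zero diagonal) and `k` (share weights).
#' @examples
#' p <- data.frame(region = c("A", "B"), population = c(16, 27),
#'                 grp = 1, tech = 1, pm25 = c(1, 3))
#' d <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' g <- gravity_matrix(p, d)
#' g$y  # y_AB = 0.25 * 2 * 3 / 4 = 0.375
#' @export
gravity_matrix <- function(panel_year, dist) {
  req <- c("region", "population", "grp", "tech", "pm25")
  if (!all(req %in% names(panel_year)))
    stop("panel_year must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(panel_year$region))
    stop("panel_year must have one row per region")
  labels <- as.character(panel_year$region)
  if (!setequal(labels, rownames(dist)))
    stop("region labels of panel and distance matrix do not match")
  d <- dist[labels, labels]
  n <- length(labels)
  if (n < 2) stop("need at least two regions")
  off <- row(d) != col(d)
  if (any(d[off] <= 0)) stop("off-diagonal distances must be strictly positive")
  P <- panel_year$population; G <- panel_year$grp
  Tl <- panel_year$tech; C <- panel_year$pm25
  if (any(c(P, G, Tl, C) <= 0))
    stop("all attributes must be strictly positive (pollution share undefined)")

  mass <- (G * P * Tl * C)^(1 / 4)
  k <- outer(C, C, function(ci, cj) ci / (ci + cj))
  y <- k * outer(mass, mass) / d^2
  diag(y) <- 0
  diag(k) <- 0.5
  dimnames(y) <- dimnames(k) <- list(labels, labels)
  structure(list(labels = labels, y = y, k = k), class = "gravity_matrix")
}

#' @export
print.gravity_matrix <- function(x, ...) {
  cat(sprintf("Gravity intensity matrix over %d regions (mean off-diagonal %.4g)\n",
              length(x$labels), mean(x$y[row(x$y) != col(x$y)])))
  invisible(x)
}

#' Dichotomize a gravity matrix by the row-mean rule
#'
#' Each row's critical value is the mean of its off-diagonal intensities
#' (structural zeros on the diagonal are excluded so they do not bias the
#' threshold downward); an arc i -> j is recorded when `y[i, j]` exceeds
#' the critical value of row i. Because the threshold is a per-row mean,
#' the resulting network is invariant to rescaling any row of `y`.
#'
#' @param g A `gravity_matrix` (or a plain square nonnegative matrix).
#' @param include_diagonal Include the structural zero diagonal in the row
#'   mean (not recommended; kept for sensitivity checks). Default `FALSE`.
#' @param strict Ties at exactly the row mean map to 0 when `TRUE`
#'   (default), to 1 when `FALSE`.
#' @return A `directed_network`.
#' @export
binarize_row_mean <- function(g, include_diagonal = FALSE, strict = TRUE) {
  y <- if (inherits(g, "gravity_matrix")) g$y else as.matrix(g)
  n <- nrow(y)
  if (n < 2) stop("need at least two regions")
  denom <- if (include_diagonal) n else n - 1
  thr <- rowSums(y) / denom          # diagonal is structurally zero
  a <- if (strict) sweep(y, 1, thr, ">") else sweep(y, 1, thr, ">=")
  storage.mode(a) <- "integer"
  diag(a) <- 0L
  directed_network(a, labels = rownames(y))
}
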