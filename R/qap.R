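#' Dyadic matrices from node attributes
#'
#' `difference_matrix()` builds the symmetric absolute-difference matrix
#' `m[i, j] = |v_i - v_j|` used to express attribute dissimilarity between
#' regions. `proximity_matrix()` turns a distance matrix into a geographic
#' covariate: elementwise inverse distance (closer pairs score higher), or
#' a binary shared-border indicator given a set of border pairs.
#' `binary_network_as_dyads()` passes an adjacency matrix into the
#' dyadic-matrix role unchanged.
#'
#' @param values Named numeric vector, one value per region (names are the
#'   labels); or unnamed with `labels` supplied.
#' @param labels Optional region labels.
#' @return A square matrix with zero diagonal and matching dimnames.
#' @examples
#' difference_matrix(c(A = 1, B = 3, C = 6))
#' @export
difference_matrix <- function(values, labels = NULL) {
  if (is.null(labels)) labels <- names(values)
  if (is.null(labels)) labels <- paste0("V", seq_along(values))
  if (length(labels) != length(values)) stop("one value per region required")
  if (any(is.na(values))) stop("missing region value(s)")
  m <- abs(outer(as.numeric(values), as.numeric(values), "-"))
  dimnames(m) <- list(labels, labels)
  m
}

#' @param dist Labelled symmetric distance matrix (positive off-diagonal).
#' @param mode `"inverse_distance"` (default) or `"border_adjacency"`.
#' @param border_pairs For border mode: a two-column matrix or data frame
#'   of label pairs sharing a border (unordered).
#' @rdname difference_matrix
#' @export
proximity_matrix <- function(dist, mode = c("inverse_distance", "border_adjacency"),
                             border_pairs = NULL) {
  mode <- match.arg(mode)
  d <- as.matrix(dist)
  off <- row(d) != col(d)
  if (any(d[off] <= 0)) stop("off-diagonal distances must be positive")
  if (mode == "inverse_distance") {
    m <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
    m[off] <- 1 / d[off]
    return(m)
  }
  if (is.null(border_pairs))
    stop("border_adjacency mode requires border_pairs")
  m <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  bp <- as.matrix(border_pairs)
  for (r in seq_len(nrow(bp))) {
    i <- bp[r, 1]; j <- bp[r, 2]
    m[i, j] <- 1; m[j, i] <- 1
  }
  diag(m) <- 0
  m
}

#' @param net A `directed_network`.
#' @rdname difference_matrix
#' @export
binary_network_as_dyads <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  m <- net$a
  storage.mode(m) <- "double"
  m
}

# off-diagonal vectorization (column-major over ordered dyads)
offdiag <- function(m) m[row(m) != col(m)]

# linear indices of the off-diagonal cells of b under node permutation p,
# one column per permutation -> matrix of permuted off-diagonal vectors
permuted_offdiag <- function(b, perms) {
  n <- nrow(b)
  od <- which(row(diag(n)) != col(diag(n)))
  r <- ((od - 1L) %% n) + 1L
  cc <- ((od - 1L) %/% n) + 1L
  vapply(seq_len(ncol(perms)), function(k) {
    p <- perms[, k]
    b[p[r] + (p[cc] - 1L) * n]       # linear indices of permuted cells
  }, numeric(length(od)))
}

align_dyads <- function(a, b) {
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    if (!setequal(rownames(a), rownames(b))) stop("dyadic matrix labels do not match")
    b <- b[rownames(a), rownames(a)]
  } else if (nrow(a) != nrow(b)) {
    stop("dyadic matrices must have the same dimension")
  }
  b
}

#' QAP correlation between two dyadic matrices
#'
#' Pearson correlation of the off-diagonal vectorizations, with a
#' permutation test that respects dyadic dependence: each draw applies one
#' random node relabelling simultaneously to the rows and columns of `b`
#' and recomputes the correlation. `p_ge` is the fraction of permuted
#' correlations at least the observed one, `p_le` the fraction at most it
#' (ties count in both tails, making the test conservative); `sig` is the
#' smaller tail.
#'
#' @param a,b Square dyadic matrices over the same regions (diagonal
#'   ignored).
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed for reproducibility.
#' @return Object of class `qap_cor`: list with `coefficient`, `sig`,
#'   `p_ge`, `p_le`, `perm_mean`, `perm_sd`, `perm_min`, `perm_max`,
#'   `n_perm`, `seed`.
#' @export
qap_correlation <- function(a, b, n_perm = 5000, seed = NULL) {
  a <- as.matrix(a); b <- align_dyads(a, as.matrix(b))
  if (n_perm < 1) stop("n_perm must be at least 1")
  va <- offdiag(a); vb <- offdiag(b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("zero variance in an off-diagonal vector: correlation undefined")
  r_obs <- stats::cor(va, vb)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(a)
  perms <- vapply(seq_len(n_perm), function(k) sample.int(n), integer(n))
  bv <- permuted_offdiag(b, perms)
  r_perm <- as.numeric(stats::cor(va, bv))
  r_perm[!is.finite(r_perm)] <- 0
  structure(list(coefficient = r_obs,
                 sig = min(mean(r_perm >= r_obs), mean(r_perm <= r_obs)),
                 p_ge = mean(r_perm >= r_obs),
                 p_le = mean(r_perm <= r_obs),
                 perm_mean = mean(r_perm), perm_sd = stats::sd(r_perm),
                 perm_min = min(r_perm), perm_max = max(r_perm),
                 n_perm = n_perm, seed = seed),
            class = "qap_cor")
}

#' @export
print.qap_cor <- function(x, ...) {
  cat(sprintf(paste0("QAP correlation: r = %.3f (sig = %.3f, %d permutations)\n",
                     "  permuted r: mean %.3f sd %.3f min %.3f max %.3f",
                     "  p>= %.3f  p<= %.3f\n"),
              x$coefficient, x$sig, x$n_perm, x$perm_mean, x$perm_sd,
              x$perm_min, x$perm_max, x$p_ge, x$p_le))
  invisible(x)
}

#' MRQAP regression of a dyadic matrix on dyadic covariates
#'
#' Ordinary least squares with intercept on the off-diagonal
#' vectorizations, with permutation inference by Y-permutation: each draw
#' relabels the nodes of `y` (rows and columns simultaneously) and refits
#' the full model, building a null distribution for every coefficient.
#' Per-coefficient significance is the tail probability on the side of the
#' observed coefficient's sign; both tails are reported, with ties counted
#' in both. Standardized coefficients are `b_k sd(x_k)/sd(y)`; adjusted
#' R-squared uses the dyad count m = n(n-1).
#'
#' @param y Square response matrix (e.g. a binary adjacency).
#' @param xs Named list of square covariate matrices over the same regions.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return Object of class `qap_lm`: list with `coefficients` (data frame:
#'   term, estimate, std_estimate, sig, p_ge, p_le), `r_squared`,
#'   `adj_r_squared`, `n_dyads`, `n_perm`, `seed`.
#' @export
qap_regression <- function(y, xs, n_perm = 10000, seed = NULL) {
  y <- as.matrix(y)
  if (!length(xs)) stop("at least one covariate matrix is required")
  if (is.null(names(xs)) || any(!nzchar(names(xs))))
    names(xs) <- paste0("x", seq_along(xs))
  xs <- lapply(xs, function(x) align_dyads(y, as.matrix(x)))
  n <- nrow(y)
  m <- n * (n - 1)
  p <- length(xs)
  if (m <= p + 1) stop("more covariates than dyads support")
  yv <- offdiag(y)
  X <- cbind(`(Intercept)` = 1, vapply(xs, offdiag, numeric(m)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop("collinear covariates: ", paste(dropped, collapse = ", "))
  }
  coefs <- qr.coef(qrX, yv)
  fitted <- as.numeric(X %*% coefs)
  ssr <- sum((fitted - mean(yv))^2)
  sst <- sum((yv - mean(yv))^2)
  if (sst == 0) stop("response has zero variance")
  r2 <- ssr / sst
  adj_r2 <- 1 - (1 - r2) * (m - 1) / (m - p - 1)

  if (!is.null(seed)) set.seed(seed)
  perms <- vapply(seq_len(n_perm), function(k) sample.int(n), integer(n))
  yperm <- permuted_offdiag(y, perms)          # m x n_perm
  bperm <- qr.coef(qrX, yperm)                 # (p+1) x n_perm, one QR solve
  p_ge <- rowMeans(bperm >= coefs)
  p_le <- rowMeans(bperm <= coefs)
  sig <- ifelse(coefs >= 0, p_ge, p_le)

  sdy <- stats::sd(yv)
  std <- c(NA_real_, vapply(seq_len(p), function(k)
    coefs[k + 1] * stats::sd(X[, k + 1]) / sdy, numeric(1)))
  coef_df <- data.frame(term = colnames(X),
                        estimate = as.numeric(coefs),
                        std_estimate = std,
                        sig = as.numeric(sig),
                        p_ge = as.numeric(p_ge),
                        p_le = as.numeric(p_le),
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coef_df, r_squared = r2,
                 adj_r_squared = adj_r2, n_dyads = m,
                 n_perm = n_perm, seed = seed),
            class = "qap_lm")
}

#' @export
print.qap_lm <- function(x, ...) {
  cat(sprintf("MRQAP regression on %d dyads (%d permutations)\n",
              x$n_dyads, x$n_perm))
  df <- x$coefficients
  df$estimate <- round(df$estimate, 4)
  df$std_estimate <- round(df$std_estimate, 4)
  df$sig <- round(df$sig, 4)
  print(df[, c("term", "estimate", "std_estimate", "sig")], row.names = FALSE)
  cat(sprintf("R-squared %.4f (adjusted %.4f)\n", x$r_squared, x$adj_r_squared))
  invisible(x)
}

#' @export
coef.qap_lm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
summary.qap_lm <- function(object, ...) object
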