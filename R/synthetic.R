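#' Generate a synthetic regional attribute panel and distance matrix
#'
#' Emulates the statistical shape of a province-level panel: strictly
#' positive, right-skewed attributes (population, gross regional product,
#' patent counts, pollutant concentration) plus six dyadic-regression
#' covariates, observed for every region in every year, together with a
#' Euclidean inter-capital distance matrix on a km-like scale.
#'
#' Attributes are log-normal. For each attribute, the log-scale value of
#' region i in year t is
#' `meanlog + sdlog * (sqrt(rho) * f_i + sqrt(1 - rho) * e_it)`,
#' where `f_i` is a region-level factor shared by all attributes (inducing
#' cross-attribute correlation `rho` and persistence across years) and
#' `e_it` is idiosyncratic noise. A mild common yearly drift is added so the
#' panel has a trend, as real regional aggregates do.
#'
#' @param n_regions Number of regions (>= 4). Default 31.
#' @param years Number of consecutive years (>= 1). Default 12.
#' @param seed Integer seed; the output is reproducible bit-for-bit.
#' @param params List of generator settings, see [panel_params()].
#' @return A list with `panel` (data.frame: region, year, population, grp,
#'   tech, pm25, gdp, ti, gov, er, is, co) and `dist` (labelled symmetric
#'   distance matrix in km, zero diagonal).
#' @examples
#' d <- generate_panel(n_regions = 6, years = 2, seed = 1)
#' dim(d$panel); d$dist[1:3, 1:3]
#' @export
generate_panel <- function(n_regions = 31, years = 12, seed = NULL,
                           params = panel_params()) {
  if (n_regions < 4) stop("n_regions must be at least 4")
  if (years < 1) stop("years must be at least 1")
  if (!is.null(seed)) set.seed(seed)

  attrs <- c("population", "grp", "tech", "pm25",
             "gdp", "ti", "gov", "er", "is", "co")
  regions <- sprintf("R%02d", seq_len(n_regions))
  yrs <- params$first_year + seq_len(years) - 1L

  f <- stats::rnorm(n_regions)            # persistent region factor
  drift <- params$drift * (seq_len(years) - 1)
  rho <- params$rho
  panel <- expand.grid(region = regions, year = yrs,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  panel <- panel[order(panel$year, panel$region), , drop = FALSE]
  rownames(panel) <- NULL
  fi <- rep(f, times = years)
  dr <- rep(drift, each = n_regions)
  for (a in attrs) {
    ml <- params$meanlog[[a]]
    sl <- params$sdlog[[a]]
    e <- stats::rnorm(n_regions * years)
    panel[[a]] <- exp(ml + dr + sl * (sqrt(rho) * fi + sqrt(1 - rho) * e))
  }

  xy <- cbind(stats::runif(n_regions, 0, params$coord_km),
              stats::runif(n_regions, 0, params$coord_km))
  d <- as.matrix(stats::dist(xy))
  dimnames(d) <- list(regions, regions)

  list(panel = panel, dist = d)
}

#' Settings for the synthetic panel generator
#'
#' Log-scale locations and spreads are chosen so that the simulated marginals
#' have the magnitude and skew of province-level aggregates: populations of
#' order 10^7 persons, gross regional product of order 10^4 (hundred-million
#' currency units), patent grants of order 10^4, and PM2.5 concentrations of
#' a few tens of ug/m3. Coordinates are uniform on a square of side
#' `coord_km` km, giving Euclidean inter-capital-like distances up to about
#' 2800 km.
#'
#' @param rho Cross-attribute/persistence correlation in \[0, 1). Default 0.5.
#' @param drift Common log-scale yearly drift. Default 0.02.
#' @param coord_km Side of the coordinate square in km. Default 2000.
#' @param first_year First calendar year of the panel. Default 2009.
#' @param meanlog,sdlog Named lists of log-normal parameters per attribute.
#' @return A list of settings accepted by [generate_panel()].
#' @export
panel_params <- function(rho = 0.5, drift = 0.02, coord_km = 2000,
                         first_year = 2009L,
                         meanlog = NULL, sdlog = NULL) {
  stopifnot(rho >= 0, rho < 1, coord_km > 0)
  ml_def <- list(population = log(3e7), grp = log(2e4), tech = log(3e4),
                 pm25 = log(35), gdp = log(2e4), ti = log(3e4),
                 gov = log(0.25), er = log(50), is = log(0.4), co = log(800))
  sl_def <- list(population = 0.8, grp = 0.9, tech = 1.1, pm25 = 0.35,
                 gdp = 0.9, ti = 1.1, gov = 0.3, er = 0.8, is = 0.2, co = 0.7)
  if (!is.null(meanlog)) ml_def[names(meanlog)] <- meanlog
  if (!is.null(sdlog)) sl_def[names(sdlog)] <- sdlog
  list(rho = rho, drift = drift, coord_km = coord_km,
       first_year = as.integer(first_year), meanlog = ml_def, sdlog = sl_def)
}

#' Generate a planted-partition directed network
#'
#' Arc i -> j (i != j) is present independently with probability `p_in` when
#' i and j share a block and `p_out` otherwise. Used to validate block
#' recovery: the planted structure is identifiable only when `p_in > p_out`.
#'
#' @param sizes Integer vector of block sizes.
#' @param p_in Within-block arc probability.
#' @param p_out Between-block arc probability; must be strictly below `p_in`.
#' @param seed Integer seed.
#' @return A `directed_network` with a `block` attribute giving the planted
#'   assignment.
#' @examples
#' net <- generate_block_network(c(5, 5), p_in = 1, p_out = 0)
#' sum(net$a)  # two directed 5-cliques: 2 * 5*4 arcs
#' @export
generate_block_network <- function(sizes, p_in, p_out, seed = NULL) {
  if (any(sizes < 1)) stop("block sizes must be positive")
  if (p_in > 1 || p_out < 0 || p_in <= p_out)
    stop("need 0 <= p_out < p_in <= 1 (planted structure undefined otherwise)")
  if (!is.null(seed)) set.seed(seed)
  n <- sum(sizes)
  block <- rep(seq_along(sizes), times = sizes)
  same <- outer(block, block, "==")
  p <- ifelse(same, p_in, p_out)
  diag(p) <- 0
  a <- matrix(as.integer(stats::runif(n * n) < p), n, n)
  diag(a) <- 0L
  net <- directed_network(a, labels = sprintf("N%02d", seq_len(n)))
  attr(net, "block") <- block
  net
}

#' Generate a dyadic regression design with known coefficients
#'
#' Draws independent standard-normal node attributes, forms symmetric
#' absolute-difference matrices `X_k`, and sets the off-diagonal of `Y` to
#' `sum_k beta_k * X_k + N(0, noise_sd^2)` (independent noise per ordered
#' dyad). Used for parameter-recovery and calibration checks of QAP/MRQAP.
#'
#' @param n Number of nodes (>= 4).
#' @param betas Numeric coefficient vector, one per covariate matrix.
#' @param noise_sd Standard deviation of the dyadic noise.
#' @param seed Integer seed.
#' @return A list with `y` (square matrix, zero diagonal) and `xs`
#'   (list of symmetric covariate matrices).
#' @export
generate_dyadic_design <- function(n, betas, noise_sd = 1, seed = NULL) {
  if (n < 4) stop("n must be at least 4")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  labels <- sprintf("N%02d", seq_len(n))
  xs <- lapply(seq_along(betas), function(k) {
    v <- stats::rnorm(n)
    m <- abs(outer(v, v, "-"))
    dimnames(m) <- list(labels, labels)
    m
  })
  y <- matrix(0, n, n, dimnames = list(labels, labels))
  for (k in seq_along(betas)) y <- y + betas[k] * xs[[k]]
  noise <- matrix(stats::rnorm(n * n, sd = noise_sd), n, n)
  y <- y + noise
  diag(y) <- 0
  list(y = y, xs = xs)
}

#' Load the packaged reference tables
#'
#' Returns the transcribed reference tables from the published 2020
#' province-level PM2.5 network analysis: per-province centralities
#' (31 rows), block flow accounting (4 blocks), the 4x4 block density
#' matrix, and the 4x4 binary image matrix. Basic integrity checks
#' (shapes; arc bookkeeping: in-degree and out-degree columns both sum to
#' the total arc count) run on every load.
#'
#' @return A list with `table1` (data.frame), `table2` (data.frame),
#'   `table3` (4x4 numeric matrix), `table4` (4x4 binary matrix).
#' @export
load_fixtures <- function() {
  path <- function(f) {
    p <- system.file("extdata", f, package = "gravnet")
    if (p == "") stop("fixture file missing: ", f)
    p
  }
  t1 <- utils::read.table(path("table1_centrality.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  t2 <- utils::read.table(path("table2_block_flows.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  t3 <- as.matrix(utils::read.table(path("table3_block_density.tsv"),
                                    header = TRUE, sep = "\t", row.names = 1))
  t4 <- as.matrix(utils::read.table(path("table4_image_matrix.tsv"),
                                    header = TRUE, sep = "\t", row.names = 1))
  colnames(t3) <- rownames(t3)
  colnames(t4) <- rownames(t4)
  if (nrow(t1) != 31) stop("fixture integrity: centrality table must have 31 rows")
  if (nrow(t2) != 4) stop("fixture integrity: block flow table must have 4 rows")
  if (!identical(dim(t3), c(4L, 4L)) || !identical(dim(t4), c(4L, 4L)))
    stop("fixture integrity: block matrices must be 4x4")
  if (sum(t1$in_degree) != sum(t1$out_degree))
    stop("fixture integrity: in-degree and out-degree sums differ")
  if (!all(t4 %in% c(0, 1)))
    stop("fixture integrity: image matrix must be binary")
  list(table1 = t1, table2 = t2, table3 = t3, table4 = t4)
}
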