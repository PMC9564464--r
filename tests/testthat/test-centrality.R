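star <- function(n) {
  a <- matrix(0L, n, n)
  a[1, 2:n] <- 1L
  directed_network(a)
}

test_that("degree centrality supports both conventions", {
  # node with in-degree 0, out-degree 13 among n = 31
  a <- matrix(0L, 31, 31)
  a[1, 2:14] <- 1L
  net <- directed_network(a)
  expect_equal(unname(degree_centrality(net, "neighbor")[1]), 100 * 13 / 30)
  expect_equal(unname(degree_centrality(net, "eq2")[1]), 100 * 13 / 60)
  # out-degree 4 variant
  a2 <- matrix(0L, 31, 31); a2[1, 2:5] <- 1L
  expect_equal(unname(degree_centrality(directed_network(a2))[1]),
               100 * 4 / 30, tolerance = 1e-12)
  expect_error(degree_centrality(net, "bogus"))
})

test_that("reciprocated dyads count once under the neighbor convention", {
  a <- matrix(0L, 4, 4)
  a[1, 2] <- a[2, 1] <- 1L   # mutual dyad
  a[1, 3] <- 1L
  net <- directed_network(a)
  dc <- degree_centrality(net, "neighbor")
  expect_equal(unname(dc[1]), 100 * 2 / 3)   # neighbours {2, 3}
  eq2 <- degree_centrality(net, "eq2")
  expect_equal(unname(eq2[1]), 100 * 3 / 6)  # (ind 1 + out 2) / (2*3)
  # bounds: max(ind,out)/(n-1) <= neighbor <= (ind+out)/(n-1)
  ind <- colSums(net$a); out <- rowSums(net$a)
  expect_true(all(dc >= 100 * pmax(ind, out) / 3 - 1e-9))
  expect_true(all(dc <= 100 * (ind + out) / 3 + 1e-9))
})

test_that("betweenness is 100 for a star center and 0 for leaves", {
  bc <- betweenness_centrality(star(5))
  expect_equal(unname(bc[1]), 100)
  expect_equal(unname(bc[-1]), rep(0, 4))
  expect_error(betweenness_centrality(star(2)), "at least 3")
})

test_that("betweenness matches exhaustive path enumeration", {
  # fixed 5-node graph with edges {ab, bc, cd, de, ea, bd}
  a <- matrix(0L, 5, 5)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 1), c(2, 4)))
    a[e[1], e[2]] <- 1L
  net <- directed_network(a)
  expect_equal(unname(betweenness_centrality(net)), bf_betweenness(net$a))

  set.seed(9)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    net <- random_digraph(n, runif(1, 0.25, 0.7))
    expect_equal(unname(betweenness_centrality(net)), bf_betweenness(net$a))
  }
})

test_that("closeness is reciprocal farness on the symmetrized graph", {
  expect_equal(as.numeric(closeness_centrality(star(5))[1]), 100)
  # end of a 3-node path: distances 1, 2
  path3 <- directed_network(matrix(c(0, 1, 0, 0, 0, 1, 0, 0, 0), 3,
                                   byrow = TRUE))
  expect_equal(as.numeric(closeness_centrality(path3)[1]), 100 * 2 / 3)
  # 27 neighbours at distance 1, 3 at distance 2, n = 31
  a <- matrix(0L, 31, 31)
  a[1, 2:28] <- 1L
  a[28, 29:31] <- 1L
  cc <- closeness_centrality(directed_network(a))
  expect_equal(unname(cc[1]), 100 * 30 / 33)   # 90.909...
})

test_that("closeness matches the oracle and handles disconnection", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    net <- random_digraph(n, runif(1, 0.2, 0.7))
    expect_equal(as.numeric(closeness_centrality(net)), bf_closeness(net$a))
    expect_equal(as.numeric(closeness_centrality(net, strict = TRUE)),
                 bf_closeness(net$a, strict = TRUE))
  }
  split <- directed_network(matrix(c(0, 1, 0, 0,
                                     1, 0, 0, 0,
                                     0, 0, 0, 1,
                                     0, 0, 1, 0), 4, byrow = TRUE))
  cc <- closeness_centrality(split)
  expect_true(attr(cc, "disconnected"))
  expect_equal(as.numeric(cc), rep(100, 4))  # each within its own 2-node component
  expect_equal(as.numeric(closeness_centrality(split, strict = TRUE)), rep(0, 4))
})

test_that("closeness is invariant under node relabeling", {
  set.seed(3)
  net <- random_digraph(6, 0.4)
  p <- sample(6)
  relab <- directed_network(net$a[p, p])
  expect_equal(as.numeric(closeness_centrality(relab)),
               as.numeric(closeness_centrality(net))[p])
})

test_that("centrality table is consistent with arc bookkeeping", {
  set.seed(5)
  net <- random_digraph(8, 0.35)
  tab <- centrality_table(net, digits = 3)
  expect_equal(sum(tab$in_degree), sum(net$a))
  expect_equal(sum(tab$out_degree), sum(net$a))
  expect_named(tab, c("region", "in_degree", "out_degree", "degree",
                      "betweenness", "closeness"))
  expect_equal(unname(tab$degree), unname(round(degree_centrality(net), 3)))
})
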