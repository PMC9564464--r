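test_that("CONCOR exactly recovers a separable planted bipartition", {
  net <- generate_block_network(c(5, 5), p_in = 1, p_out = 0)
  part <- concor_partition(net, depth = 1)
  planted <- attr(net, "block")
  expect_equal(part$n_blocks, 2)
  # same partition up to block labels
  expect_true(all(table(part$assignment, planted) %in% c(0, 5)))
})

test_that("depth bounds the number of blocks and small groups stop splitting", {
  set.seed(4)
  net <- random_digraph(12, 0.3)
  part <- concor_partition(net, depth = 2)
  expect_lte(part$n_blocks, 4)
  expect_equal(sort(unique(unname(part$assignment))), seq_len(part$n_blocks))
  expect_error(concor_partition(random_digraph(3, 0.5)), "at least 4")
})

test_that("mirrored star components land in different blocks", {
  a <- matrix(0L, 8, 8)
  a[1, 2:4] <- 1L            # star 1
  a[5, 6:8] <- 1L            # identical star 2
  net <- directed_network(a)
  part <- concor_partition(net, depth = 1)
  expect_equal(length(unique(part$assignment[1:4])), 1)
  expect_equal(length(unique(part$assignment[5:8])), 1)
  expect_false(part$assignment[1] == part$assignment[5])
})

test_that("isolates (constant profiles) are handled with a warning, not an error", {
  a <- matrix(0L, 6, 6)
  a[1, 2] <- a[2, 1] <- a[3, 4] <- a[4, 3] <- 1L   # nodes 5, 6 isolated
  net <- directed_network(a)
  expect_warning(part <- concor_partition(net, depth = 1), "constant profile")
  expect_equal(length(part$assignment), 6)
})

test_that("CONCOR is invariant under node relabeling", {
  net <- generate_block_network(c(6, 6), p_in = 0.9, p_out = 0.05, seed = 8)
  part <- concor_partition(net, depth = 1)
  set.seed(21)
  p <- sample(net$n)
  relab <- directed_network(net$a[p, p], labels = net$labels[p])
  part2 <- concor_partition(relab, depth = 1)
  # compare as partitions of the same labels
  g1 <- part$assignment[sort(net$labels)]
  g2 <- part2$assignment[sort(net$labels)]
  expect_true(all(table(g1, g2) %in% c(0, as.vector(table(g1)))))
})

flows_from_counts <- function() {
  # reference block flow accounting (4 blocks over 31 regions)
  load_fixtures()$table2
}

test_that("block flow accounting reproduces the reference bookkeeping", {
  net <- generate_block_network(c(4, 4, 4), p_in = 0.9, p_out = 0.1, seed = 5)
  part <- concor_partition(net, depth = 2)
  fl <- block_flow_summary(net, part)
  expect_equal(sum(fl$inside_sent) + sum(fl$outside_sent), sum(net$a))
  expect_equal(fl$inside_sent, fl$inside_received)
  expect_equal(sum(fl$outside_sent), sum(fl$outside_received))
  expect_equal(fl$actual_internal_ratio,
               100 * fl$inside_sent / (fl$inside_sent + fl$outside_sent))
  expect_equal(fl$expected_internal_ratio,
               100 * (fl$n_regions - 1) / (net$n - 1))
})

test_that("single-block partition has no outside flows", {
  net <- generate_block_network(c(6), p_in = 0.5, p_out = 0, seed = 2)
  fl <- block_flow_summary(net, rep(1L, 6))
  expect_equal(fl$outside_sent, 0L)
  expect_equal(fl$outside_received, 0L)
  expect_equal(fl$actual_internal_ratio, 100)
})

test_that("block density matrix averages back to overall density", {
  set.seed(13)
  for (rep in 1:10) {
    net <- random_digraph(10, runif(1, 0.15, 0.5))
    assign <- sample(1:3, 10, replace = TRUE)
    assign[1:3] <- 1:3          # ensure all blocks present
    dm <- block_density_matrix(net, assign)
    sizes <- as.integer(table(assign))
    possible <- outer(sizes, sizes); diag(possible) <- sizes * (sizes - 1)
    expect_equal(sum(dm * possible) / (10 * 9), network_density(net))
    expect_true(all(dm >= 0 & dm <= 1))
  }
  empty <- directed_network(matrix(0, 6, 6))
  expect_true(all(block_density_matrix(empty, rep(1:2, 3)) == 0))
})

test_that("image matrix binarizes at the overall density", {
  dm <- rbind(c(0.364, 0.018, 0.444, 0.355))
  expect_equal(as.vector(image_matrix(dm, 0.2688)), c(1L, 0L, 1L, 1L))
  dm2 <- rbind(c(0.867, 0.250, 0.178, 0.055))
  expect_equal(as.vector(image_matrix(dm2, 0.2688)), c(1L, 0L, 0L, 0L))
  expect_equal(as.vector(image_matrix(dm, 0)), rep(1L, 4))
  expect_equal(as.vector(image_matrix(dm, 0.355, strict = TRUE)),
               c(1L, 0L, 1L, 0L))
})

test_that("role classifier reproduces the reference assignments from flows", {
  t2 <- flows_from_counts()
  roles <- classify_roles(t2$inside_received + t2$outside_received,
                          t2$inside_sent + t2$outside_sent)
  expect_equal(roles, c("net_benefit", "net_spillover",
                        "two_way_spillover", "broker"))
  expect_warning(r0 <- classify_roles(c(5, 3), c(2, 0)), "unclassifiable")
  expect_true(is.na(r0[2]))
})
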