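test_that("newick parsing keeps leaves, lengths and support labels", {
  tr <- parse_newick("((a:1,b:1)90:1,(c:1,d:1)85:1);")
  expect_length(tr$tip.label, 4)
  expect_setequal(suppressWarnings(as.numeric(tr$node.label)[-1]), c(90, 85))
  star <- parse_newick("(a,b,c);")
  expect_length(bipartitions(star), 0)
  expect_error(parse_newick("((a,b),(c,d);"), "unclosed", class = "parse_error")
  expect_error(parse_newick("(a,b)),c;"), "offset", class = "parse_error")
})

test_that("serialize/parse round trip preserves the bipartition set", {
  set.seed(21)
  for (i in 1:25) {
    tr <- ape::rtree(sample(4:15, 1))
    back <- parse_newick(serialize_newick(tr))
    expect_setequal(as.character(bipartitions(back)),
                    as.character(bipartitions(tr)))
  }
})

test_that("bipartitions enumerate non-trivial splits only", {
  one <- parse_newick("((a,b),(c,d));")
  expect_identical(length(bipartitions(one)), 1L)
  side <- attr(bipartitions(one), "sides")[[1]]
  expect_true(setequal(side, c("c", "d")) || setequal(side, c("a", "b")))
  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:20, 1)
    tr <- ape::rtree(n)
    expect_identical(length(bipartitions(ape::unroot(tr))), n - 3L)
  }
})

test_that("normalized RF matches the brute-force split oracle and phangorn", {
  t1 <- parse_newick("((a,b),(c,d));")
  t2 <- parse_newick("((a,c),(b,d));")
  expect_identical(normalized_rf(t1, t1), 0)
  expect_identical(normalized_rf(t1, t2), 1)
  set.seed(41)
  for (i in 1:40) {
    n <- sample(4:20, 1)
    ta <- ape::rtree(n)
    tb <- ape::rtree(n)
    got <- normalized_rf(ta, tb)
    expect_equal(got, oracle_nrf(ta, tb))
    expect_equal(got, as.numeric(phangorn::RF.dist(ta, tb, normalize = TRUE)))
    expect_equal(normalized_rf(ta, tb), normalized_rf(tb, ta))  # symmetry
    expect_gte(got, 0); expect_lte(got, 1)
  }
  t3 <- parse_newick("((a,b),(c,e));")
  expect_error(normalized_rf(t1, t3), class = "leaf_set_mismatch")
})

test_that("average bipartition support is the mean of present values", {
  expect_identical(average_bipartition_support(
    parse_newick("((a:1,b:1)90:1,(c:1,d:1)85:1);")), 87.5)
  expect_identical(average_bipartition_support(
    parse_newick("((a,b)100,(c,d)100);")), 100)
  # one of three internal edges lacks support: mean of the two present
  tr <- parse_newick("(((a,b)80,c),((d,e)90,f));")
  expect_identical(average_bipartition_support(tr), 85)
  expect_error(average_bipartition_support(parse_newick("((a,b),(c,d));")),
               class = "no_support_values")
})

test_that("desirability maps extremes to the anchors and clamps", {
  expect_identical(desirability(c(0.2, 0.5, 0.8), "low_is_best"), c(1, 0.5, 0))
  expect_identical(desirability(c(70, 85, 100), "high_is_best"), c(0, 0.5, 1))
  expect_identical(desirability(c(0.3, 0.3), "low_is_best"), c(1, 1))
  # affine invariance: Y -> cY + d (c > 0) leaves the outputs unchanged
  set.seed(5)
  y <- runif(10)
  for (dir in c("low_is_best", "high_is_best")) {
    expect_equal(desirability(3.7 * y + 2, dir), desirability(y, dir))
  }
})

test_that("integration and ranking agree with a brute-force recomputation", {
  two <- data.frame(gene = "g1", strategy = c("s1", "s2"),
                    nrf = c(0, 1), abs = c(100, 50))
  r <- integrate_and_rank(two)
  expect_identical(r$per_gene$integrated, c(1, 0))
  expect_identical(r$per_gene$rank, c(1, 2))

  tied <- data.frame(gene = "g1", strategy = c("s1", "s2"),
                     nrf = c(0.4, 0.4), abs = c(90, 90))
  expect_identical(integrate_and_rank(tied)$per_gene$rank, c(1.5, 1.5))

  set.seed(61)
  grid <- expand.grid(gene = paste0("g", 1:5), strategy = paste0("s", 1:3))
  grid$nrf <- runif(nrow(grid))
  grid$abs <- runif(nrow(grid), 50, 100)
  res <- integrate_and_rank(grid)
  # oracle: per-gene min-max maps recomputed longhand
  oracle_rank <- sapply(split(grid, grid$gene), function(df) {
    d1 <- (df$nrf - max(df$nrf)) / (min(df$nrf) - max(df$nrf))
    d2 <- (df$abs - min(df$abs)) / (max(df$abs) - min(df$abs))
    rank(-(d1 + d2) / 2)
  })
  want <- rowMeans(oracle_rank)
  got <- res$summary$mean_rank[match(paste0("s", 1:3), res$summary$strategy)]
  expect_equal(got, unname(want))
  # permutation equivariance in strategy order
  perm <- grid[sample(nrow(grid)), ]
  res2 <- integrate_and_rank(perm)
  expect_equal(res2$summary[order(res2$summary$strategy), ],
               res$summary[order(res$summary$strategy), ],
               ignore_attr = TRUE)
})

test_that("branch-length rho is 1 for identical or rescaled lengths, -1 reversed", {
  tr <- parse_newick("((a:1,b:2):3,c:4,d:5);")
  expect_identical(branch_length_rho(tr, tr), 1)
  doubled <- parse_newick("((a:2,b:4):6,c:8,d:10);")
  expect_identical(branch_length_rho(tr, doubled), 1)
  reversed <- parse_newick("((a:5,b:4):3,c:2,d:1);")
  expect_identical(branch_length_rho(tr, reversed), -1)
  other_topology <- parse_newick("((a:1,c:2):3,b:4,d:5);")
  expect_error(branch_length_rho(tr, other_topology), class = "topology_mismatch")
  # invariant under any strictly increasing transform of either tree's lengths
  set.seed(71)
  big <- ape::rtree(12)
  warped <- big
  warped$edge.length <- exp(big$edge.length)
  expect_equal(branch_length_rho(big, warped), 1)
})
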