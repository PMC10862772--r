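test_that("node coverage equals the per-base depth oracle", {
  g <- chain_graph(4)
  # two reads over bases [0,2): profile [2,2,0,0], mean 1.0
  aln <- parse_gaf(gaf_file(gaf_line("r1", ">s1", 4, 0, 2),
                            gaf_line("r2", ">s1", 4, 0, 2)))
  expect_equal(unname(node_coverage(aln, g)), 1.0)
  expect_equal(mean(brute_depth_profile("s1", c(s1 = 4),
                                        list("s1", "s1"), c(0, 0), c(2, 2))),
               1.0)

  # profile [2,2,4,4]: two full reads plus two over [2,4), mean 3.0
  aln <- parse_gaf(gaf_file(gaf_line("r1", ">s1", 4, 0, 4),
                            gaf_line("r2", ">s1", 4, 0, 4),
                            gaf_line("r3", ">s1", 4, 2, 4),
                            gaf_line("r4", ">s1", 4, 2, 4)))
  expect_equal(unname(node_coverage(aln, g)), 3.0)
  expect_equal(brute_depth_profile("s1", c(s1 = 4),
                                   list("s1", "s1", "s1", "s1"),
                                   c(0, 0, 2, 2), c(4, 4, 4, 4)),
               c(2, 2, 4, 4))

  # node with no alignments stays at 0 raw
  g2 <- chain_graph(c(4, 10))
  cov <- node_coverage(aln, g2)
  expect_equal(unname(cov["s2"]), 0)
})

test_that("multi-segment paths clip terminal segments only", {
  g <- chain_graph(c(10, 20, 30))
  # read spans s1[5..10) + all of s2 + s3[0..7)
  aln <- parse_gaf(gaf_file(gaf_line("r1", ">s1>s2>s3", 60, 5, 37)))
  cov <- node_coverage(aln, g)
  oracle <- vapply(c("s1", "s2", "s3"), function(s)
    mean(brute_depth_profile(s, c(s1 = 10, s2 = 20, s3 = 30),
                             list(c("s1", "s2", "s3")), 5, 37)), 0)
  expect_equal(cov, oracle)
  expect_equal(unname(cov), c(5 / 10, 20 / 20, 7 / 30))
  # conservation: mean depth x length sums to the aligned span
  expect_equal(sum(cov * g$nodes$length), 37 - 5)
})

test_that("unknown path segments are an error naming the read", {
  g <- chain_graph(10)
  aln <- parse_gaf(gaf_file(gaf_line("bad_read", ">s1>sX", 20, 0, 20)))
  expect_error(node_coverage(aln, g), "bad_read")
  expect_error(node_coverage(aln, g), "sX")
})

test_that("coverage floor and normalization follow the series rules", {
  expect_equal(floor_coverage(0.4), 1.0)
  expect_equal(floor_coverage(1.0), 1.0)
  expect_equal(floor_coverage(3.7), 3.7)
  expect_error(floor_coverage(-0.1), "non-negative")

  cfg <- series_config(c("a", "b", "c"), bp_totals = c(100, 200, 300))
  cov <- matrix(3, nrow = 3, ncol = 2)
  # median 200: multipliers 2, 1, 2/3 (median_ratio)
  expect_equal(normalize_series(cov, cfg)[, 1], c(6, 3, 2))
  cfg_lit <- series_config(c("a", "b", "c"), bp_totals = c(100, 200, 300),
                           normalization_mode = "bp_ratio")
  expect_equal(normalize_series(cov, cfg_lit)[, 1], c(1.5, 3, 4.5))
  # equal totals: identity in any mode
  cfg_eq <- series_config(c("a", "b"), bp_totals = c(500, 500))
  expect_equal(normalize_series(matrix(2, 2, 2), cfg_eq), matrix(2, 2, 2))
  # the floor is re-applied after scaling
  cfg2 <- series_config(c("a", "b"), bp_totals = c(400, 100))
  expect_equal(normalize_series(matrix(c(2, 2), 2, 1), cfg2)[, 1],
               c(1.25, 5))
})

test_that("normalization equalizes depth when coverage tracks bp totals", {
  bp <- c(120, 300, 240)
  cfg <- series_config(c("a", "b", "c"), bp_totals = bp)
  cov <- outer(bp / median(bp), c(5, 9, 2))  # raw depth proportional to bp
  norm <- normalize_series(cov, cfg)
  for (j in 1:3) expect_equal(norm[, j], rep(norm[1, j], 3))
})

test_that("edge traversals pool directions and count self-loops", {
  g <- chain_graph(c(10, 10))
  aln <- parse_gaf(gaf_file(gaf_line("r1", ">s1>s2", 20, 0, 20)))
  expect_equal(as.integer(edge_traversals(aln, g)), 1L)
  # reverse-strand traversal pools into the same undirected count
  aln_rev <- parse_gaf(gaf_file(gaf_line("r1", "<s2<s1", 20, 0, 20)))
  expect_equal(as.integer(edge_traversals(aln_rev, g)), 1L)

  loop <- make_graph(data.frame(from = "s1", to = "s1", weight = 1L),
                     lengths = 10L)
  aln_loop <- parse_gaf(gaf_file(gaf_line("r1", ">s1>s1", 20, 0, 20)))
  expect_equal(as.integer(edge_traversals(aln_loop, loop)), 1L)

  # an adjacency missing from the graph is logged, not fatal
  g_gap <- make_graph(data.frame(from = "s1", to = "s2", weight = 1L),
                      lengths = c(10L, 10L))
  g_gap$members <- stats::setNames(c("s1", "s2", "s3"),
                                   c("s1", "s2", "s3"))
  aln_off <- parse_gaf(gaf_file(gaf_line("r1", ">s2>s3", 20, 0, 20)))
  suppressMessages({
    tv <- edge_traversals(aln_off, g_gap)
  })
  expect_equal(attr(tv, "off_graph"), 1L)
  expect_equal(as.integer(tv), 0L)
})

test_that("edge counting is invariant to reversing every read path", {
  withr::with_seed(42, {
    fx <- build_fixture(fixture_config(seed = 5, n_samples = 2, events =
      data.frame(sv_type = "tandem_duplication", step_pair = 1, fold = 4,
                 genome = 1, motif = "parallel_edge")))
    g <- collapse_graph(parse_gfa(fx$gfa))
    aln <- parse_gaf(fx$gafs[1])
    fwd <- edge_traversals(aln, g)
    rev_aln <- aln
    rev_aln$path_segs <- lapply(aln$path_segs, rev)
    rev_aln$path_orients <- lapply(aln$path_orients,
                                   function(o) rev(ifelse(o == "+", "-", "+")))
    expect_equal(as.integer(edge_traversals(rev_aln, g)), as.integer(fwd))
  })
})

test_that("coverage_table fills bp totals from mapped read lengths", {
  g <- chain_graph(c(100, 100))
  gaf1 <- gaf_file(gaf_line("r1", ">s1>s2", 200, 0, 200),
                   gaf_line("r2", ">s1", 100, 0, 100))
  gaf2 <- gaf_file(gaf_line("r1", ">s1>s2", 200, 0, 200))
  cfg <- series_config(c("t0", "t1"), normalization_mode = "none")
  ct <- coverage_table(c(gaf1, gaf2), g, cfg)
  expect_equal(ct$config$bp_totals, c(300, 200))
  expect_equal(unname(ct$node_cov["t0", ]), c(2, 1))
  expect_true(all(ct$node_cov >= 1))
  expect_error(coverage_table(gaf1, g, cfg), "one GAF per sample")
})
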