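pop_sd <- function(v) sqrt(sum((v - mean(v))^2) / length(v))

test_that("outlier rule uses the median and population sd, strictly", {
  # constant vector: sd 0 and a strict inequality mean no outliers
  o <- outliers_of(c(1, 1, 1))
  expect_length(o$outliers, 0)
  expect_equal(o$sd, 0)

  v <- c(0, 0.1, 2)
  o <- outliers_of(v)
  expect_equal(o$median, 0.1)
  expect_equal(o$sd, pop_sd(v))
  expect_equal(o$sd, 0.9201449, tolerance = 1e-6)
  expect_equal(o$outliers, 3L)

  # symmetric spread: both ends beyond one population sd
  v <- c(-1, 0, 1)
  o <- outliers_of(v)
  expect_equal(o$sd, pop_sd(v))
  expect_equal(o$sd, 0.8164966, tolerance = 1e-6)
  expect_equal(o$outliers, c(1L, 3L))
  # under the sample-sd convention the same vector has no outliers
  expect_length(outliers_of(v, sd_mode = "sample")$outliers, 0)

  # median of 4 is the mean of the middle two
  expect_equal(outliers_of(c(2, 0, -2, 0.1))$median, 0.05)
  expect_error(outliers_of(c(1, Inf, 0)), "finite")
})

test_that("triangles call one-outlier insertions and deletions only", {
  ins <- call_triangle(c("a", "b", "c"), c(0, 0.1, 2))
  expect_equal(ins$sv_type, "insertion")
  expect_equal(ins$called_nodes, "c")

  del <- call_triangle(c("a", "b", "c"), c(-2, 0, 0.1))
  expect_equal(del$sv_type, "deletion")
  expect_equal(del$called_nodes, "a")
  expect_equal(pop_sd(c(-2, 0, 0.1)), 0.9672412, tolerance = 1e-6)

  # two outliers: decline to call
  expect_null(call_triangle(c("a", "b", "c"), c(-1, 0, 1)))
  expect_null(call_triangle(c("a", "b", "c"), c(0, 0, 0)))
})

test_that("squares call complex indels per the one/two-outlier rule", {
  sq <- list(cycle = c("a", "b", "c", "d"),
             pairs = list(c("a", "c"), c("b", "d")))
  one <- call_square(sq, c(0, 0, 3, 0))
  expect_equal(one$sv_type, "complex_indel")
  expect_equal(one$called_nodes, "c")
  expect_equal(pop_sd(c(0, 0, 3, 0)), 1.299038, tolerance = 1e-6)

  # opposite corners, opposite signs: both called
  two <- call_square(sq, c(2, 0, -2, 0.1))
  expect_equal(sort(two$called_nodes), c("a", "c"))
  expect_equal(pop_sd(c(2, 0, -2, 0.1)), 1.414876, tolerance = 1e-6)

  # symmetric spread at exactly one sd: strict rule yields no outliers
  expect_null(call_square(sq, c(2, 2, -2, -2)))
  # ...but the slightly larger pair clears the sd and sits on opposite
  # corners with opposite signs, so it is a two-node complex indel
  v <- c(2, 2.1, -2, -2.1)
  expect_gt(2.1, pop_sd(v))
  expect_lt(2, pop_sd(v))
  expect_equal(sort(call_square(sq, v)$called_nodes), c("b", "d"))
  # adjacent outliers (cycle edge between them) do not qualify
  expect_null(call_square(sq, c(4, -4, 0.1, -0.1)))
})

test_that("tandem duplications follow the two scenarios with precedence", {
  g <- make_graph(data.frame(from = c("a", "a"), to = c("a", "b"),
                             weight = c(1L, 2L)))
  nl <- c(a = 0.2, b = 0.9)
  # self-loop lfc log2(5/2) > 1 calls the loop node; counts 4->8 is exactly
  # 1.0 and the strict rule excludes it
  el_row <- c(log2(5 / 2), 1.5)
  calls <- call_tandem_duplications(g, nl, el_row)
  expect_equal(vapply(calls, function(c) c$motif, ""),
               c("self_loop", "parallel_edge"))
  # weight-2 edge picks the endpoint with the greater node lfc
  expect_equal(calls[[2]]$called_nodes, "b")

  expect_length(call_tandem_duplications(g, nl, c(1.0, 1.0)), 0)
  # precedence: an existing call on b suppresses the parallel-edge call
  calls2 <- call_tandem_duplications(g, nl, c(0, 1.5), called_nodes = "b")
  expect_length(calls2, 0)
  # ...but not the self-loop scenario on a
  calls3 <- call_tandem_duplications(g, nl, c(1.5, 0), called_nodes = "a")
  expect_equal(calls3[[1]]$motif, "self_loop")
  # node-lfc tie falls to the lexicographically smaller endpoint
  tie <- call_tandem_duplications(g, c(a = 0.5, b = 0.5), c(0, 1.5))
  expect_equal(tie[[1]]$called_nodes, "a")
})

test_that("call_all dedupes multi-motif support and keeps instance counts", {
  # double bubble: two flank pairs, both triangles sharing the variant v
  g <- make_graph(data.frame(
    from = c("a", "a", "b", "c", "c", "d"),
    to = c("b", "v", "v", "d", "v", "v"), weight = 1L
  ))
  nl <- matrix(c(0, 0.05, -0.05, 0.02, 2), 1, 5,
               dimnames = list(NULL, c("a", "b", "c", "d", "v")))
  el <- matrix(0, 1, 6)
  calls <- call_all(g, make_lfc(g, nl, el))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$sv_type, "insertion")
  expect_equal(calls$called_node, "v")
  expect_equal(calls$n_motifs, 2L)
  inst <- attr(calls, "motif_instances")
  expect_equal(inst$n_instances[inst$sv_type == "insertion"], 2L)
})

test_that("call_all on an empty or motif-free graph returns no calls", {
  g <- make_graph(data.frame(from = c("a", "b"), to = c("b", "c"),
                             weight = 1L))
  nl <- matrix(c(0, 3, 0), 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  calls <- call_all(g, make_lfc(g, nl, matrix(0, 1, 2)))
  expect_equal(nrow(calls), 0)
})

test_that("series reversal swaps insertion and deletion calls", {
  withr::with_seed(99, {
    for (i in 1:20) {
      cg <- collapse_graph(random_assembly_graph(sample(5:14, 1),
                                                 p_edge = 0.35))
      n <- nrow(cg$nodes)
      nl <- matrix(rnorm(n), 1, n, dimnames = list(NULL, cg$nodes$id))
      el <- matrix(rnorm(nrow(cg$edges), 0, 0.4), 1, nrow(cg$edges))
      fwd <- call_all(cg, make_lfc(cg, nl, el))
      bwd <- call_all(cg, make_lfc(cg, -nl, el))
      tri_f <- fwd[fwd$motif == "triangle", ]
      tri_b <- bwd[bwd$motif == "triangle", ]
      swap <- c(insertion = "deletion", deletion = "insertion")
      expect_equal(
        sort(paste(swap[tri_f$sv_type], tri_f$called_node)),
        sort(paste(tri_b$sv_type, tri_b$called_node))
      )
    }
  })
})

test_that("outlier status is invariant to adding a constant", {
  withr::with_seed(123, {
    for (i in 1:50) {
      v <- rnorm(sample(3:4, 1))
      shift <- runif(1, -10, 10)
      expect_equal(outliers_of(v + shift)$outliers, outliers_of(v)$outliers)
    }
  })
})

test_that("call_all matches the brute-force caller on random graphs", {
  withr::with_seed(2024, {
    for (i in 1:30) {
      cg <- collapse_graph(random_assembly_graph(sample(5:16, 1),
                                                 p_edge = 0.3, p_dup = 0.3))
      n_steps <- sample(1:2, 1)
      n <- nrow(cg$nodes)
      nl <- matrix(rnorm(n_steps * n), n_steps, n,
                   dimnames = list(NULL, cg$nodes$id))
      el <- matrix(rnorm(n_steps * nrow(cg$edges), 0.5, 0.7), n_steps,
                   nrow(cg$edges))
      lfc <- make_lfc(cg, nl, el)
      expect_equal(call_keys(call_all(cg, lfc)),
                   brute_call_keys(cg, nl, el))
    }
  })
})
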