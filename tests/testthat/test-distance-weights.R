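pair <- function(s1, e1, st1, s2, e2, st2, chrom = "chr1") {
  list(g1 = data.frame(gene_id = "p1", chromosome = chrom, start = s1,
                       end = e1, strand = st1),
       g2 = data.frame(gene_id = "p2", chromosome = chrom, start = s2,
                       end = e2, strand = st2))
}

test_that("the four base metrics match their definitions", {
  p <- pair(1000, 1500, 1L, 5000, 5400, 1L)
  expect_equal(gene_distance(p$g1, p$g2, "positional"), 4000)
  # promoter of a -1-strand gene sits at its end coordinate
  q <- pair(5000, 6000, 1L, 2000, 3000, -1L)
  expect_equal(gene_distance(q$g1, q$g2, "functional"), 2000)
  cc <- pair(100, 200, 1L, 300, 401, 1L)
  expect_equal(gene_distance(cc$g1, cc$g2, "centre"), 200.5)
  ig <- pair(100, 200, 1L, 350, 500, 1L)
  expect_equal(gene_distance(ig$g1, ig$g2, "intragenic"), 150)
  ov <- pair(100, 400, 1L, 350, 500, 1L)
  expect_equal(gene_distance(ov$g1, ov$g2, "intragenic"), 0)
})

test_that("metrics are symmetric, non-negative, and error across chromosomes", {
  set.seed(21)
  for (i in 1:25) {
    s <- sort(sample.int(1e6, 2))
    p <- pair(s[1], s[1] + sample.int(5000, 1), sample(c(1L, -1L), 1),
              s[2], s[2] + sample.int(5000, 1), sample(c(1L, -1L), 1))
    for (metric in c("positional", "functional", "centre", "intragenic")) {
      d12 <- gene_distance(p$g1, p$g2, metric)
      expect_gte(d12, 0)
      expect_equal(gene_distance(p$g2, p$g1, metric), d12)
    }
    # the body gap never exceeds the start-to-start distance
    expect_lte(gene_distance(p$g1, p$g2, "intragenic"),
               gene_distance(p$g1, p$g2, "positional"))
  }
  x <- pair(1, 10, 1L, 1, 10, 1L)
  x$g2$chromosome <- "chr2"
  expect_error(gene_distance(x$g1, x$g2), "across chromosomes")
})

test_that("positional distance is zero iff starts coincide", {
  p0 <- pair(500, 900, 1L, 500, 1200, -1L)
  expect_equal(gene_distance(p0$g1, p0$g2, "positional"), 0)
  p1 <- pair(500, 900, 1L, 501, 1200, 1L)
  expect_gt(gene_distance(p1$g1, p1$g2, "positional"), 0)
})

test_that("density profiles count starts within the window", {
  # uniform spacing: constant interior profile
  d <- quick_dataset(seq(0, 9) * 1000 + 10000)
  lay <- chromosome_layout(d, "chr1", length = 30000)
  prof <- density_profile(lay, window = 5000, step = 500)
  interior <- prof$density[prof$position >= 13000 & prof$position <= 16000]
  expect_true(all(interior == interior[1]))
  # single gene: nonzero only within W/2 of its start
  d1 <- quick_dataset(c(10000))
  p1 <- density_profile(chromosome_layout(d1, "chr1", length = 20000),
                        window = 1000, step = 100)
  nz <- p1$position[p1$density > 0]
  expect_true(all(abs(nz - 10000) <= 500))
  # two blocks with a desert between: bimodal with zero in the middle
  d2 <- quick_dataset(c(1000, 2000, 3000, 200000, 201000, 202000))
  p2 <- density_profile(chromosome_layout(d2, "chr1", length = 210000),
                        window = 10000, step = 1000)
  mid <- p2$density[p2$position > 50000 & p2$position < 150000]
  expect_true(all(mid == 0))
  expect_gt(max(p2$density[p2$position < 10000]), 0)
  expect_gt(max(p2$density[p2$position > 195000]), 0)
  # direct window-count oracle at one position
  expect_equal(local_density(chromosome_layout(d2, "chr1"), "chr1", 2000,
                             10000), 3 / 10000)
})

test_that("TF weight is the floored Jaccard complement", {
  d <- quick_dataset(c(100, 200, 300, 400), ids = sprintf("g%d", 1:4))
  d <- attach_tf(d, tf_ann(g1 = c("A", "B"), g2 = c("A", "B"), g3 = c("C"),
                           g4 = character(0)))
  ctx <- distance_context(d)
  spec <- weighted_distance_spec(weights = "tf", eps = 0.01)
  gr <- function(i) d$genes[i, , drop = FALSE]
  expect_equal(compute_weight(gr(1), gr(2), "tf", spec, ctx), 0.01)  # identical
  expect_equal(compute_weight(gr(1), gr(3), "tf", spec, ctx), 1)     # disjoint
  expect_equal(compute_weight(gr(4), gr(4), "tf", spec, ctx), 1)     # both empty
  # monotone in shared TFs at fixed union size
  d2 <- attach_tf(d, tf_ann(g1 = c("A", "B", "C"), g2 = c("A", "B", "D"),
                            g3 = c("A", "E", "F")))
  ctx2 <- distance_context(d2)
  w_2shared <- compute_weight(d2$genes[1, ], d2$genes[2, ], "tf", spec, ctx2)
  w_1shared <- compute_weight(d2$genes[1, ], d2$genes[3, ], "tf", spec, ctx2)
  expect_lt(w_2shared, w_1shared)
})

test_that("ANOVA expression weight complements the p-value with a floor", {
  d <- quick_dataset(c(100, 200, 300), ids = c("g1", "g2", "g3"))
  m <- rbind(g1 = c(5, 5, 5), g2 = c(5, 5, 5), g3 = c(9, 9.1, 8.9))
  colnames(m) <- c("c1", "c2", "c3")
  d <- attach_expression(d, m)
  ctx <- distance_context(d)
  spec <- weighted_distance_spec(weights = "expression",
                                 expression_mode = "anova", eps = 0.01)
  gr <- function(i) d$genes[i, , drop = FALSE]
  # identical replicate sets: no between-group variance, p = 1, weight = eps
  expect_equal(compute_weight(gr(1), gr(2), "expression", spec, ctx), 0.01)
  # clearly different means: p near 0, weight near 1
  w13 <- compute_weight(gr(1), gr(3), "expression", spec, ctx)
  expect_gt(w13, 0.99)
  # cross-check 1 - p against R's own one-way ANOVA
  vals <- c(m["g2", ], m["g3", ])
  grp <- factor(rep(c("a", "b"), each = 3))
  p_ref <- summary(stats::aov(vals ~ grp))[[1]][["Pr(>F)"]][1]
  w23 <- compute_weight(gr(2), gr(3), "expression", spec, ctx)
  expect_equal(w23, max(0.01, 1 - p_ref), tolerance = 1e-10)
  # fewer than two replicates is an error
  d1 <- attach_expression(d, m[, 1, drop = FALSE])
  expect_error(compute_weight(d1$genes[1, ], d1$genes[2, ], "expression",
                              spec, distance_context(d1)), ">= 2")
})

test_that("custom expression weight is the normalized absolute difference", {
  d <- quick_dataset(c(100, 200, 300), ids = c("g1", "g2", "g3"))
  d <- attach_expression(d, matrix(c(4, -4, 4), 3, 1,
                                   dimnames = list(c("g1", "g2", "g3"), "c1")))
  ctx <- distance_context(d)
  spec <- weighted_distance_spec(weights = "expression",
                                 expression_mode = "custom", eps = 0.01)
  gr <- function(i) d$genes[i, , drop = FALSE]
  expect_equal(compute_weight(gr(1), gr(2), "expression", spec, ctx), 1,
               tolerance = 1e-6)
  expect_equal(compute_weight(gr(1), gr(3), "expression", spec, ctx), 0.01)
})

test_that("density weight inflates dense regions relative to sparse ones", {
  # same base gap, one pair inside a packed block, one in a desert
  starts <- c(seq(100000, 109000, by = 1000),  # dense block
              500000, 509000)                  # sparse pair, same 9 kb span
  d <- quick_dataset(starts, ids = sprintf("g%02d", seq_along(starts)))
  ctx <- distance_context(d, chromosome_lengths = c(chr1 = 600000))
  spec <- weighted_distance_spec(weights = "density", density_window = 20000)
  dense_w <- compute_weight(d$genes[1, ], d$genes[10, ], "density", spec, ctx)
  sparse_w <- compute_weight(d$genes[11, ], d$genes[12, ], "density", spec, ctx)
  expect_gt(dense_w, sparse_w)
  # window-count oracle: 10 starts vs 2 starts in a 20 kb window, against a
  # genome-wide mean of 12 genes / 600 kb
  rho_bar <- 12 / 600000
  expect_equal(dense_w, (10 / 20000) / rho_bar)
  expect_equal(sparse_w, (2 / 20000) / rho_bar)
})

test_that("weighted distance composes multiplicatively over active weights", {
  d <- quick_dataset(c(1, 10001), ids = c("g1", "g2"))
  d <- attach_tf(d, tf_ann(g1 = c("A", "B"), g2 = c("A", "B")))
  ctx <- distance_context(d)
  g1 <- d$genes[1, ]; g2 <- d$genes[2, ]
  # uniform weighting reproduces the base metric bitwise
  spec_u <- weighted_distance_spec(weights = "uniform")
  expect_identical(weighted_distance(g1, g2, spec_u, ctx),
                   gene_distance(g1, g2, "positional"))
  # identical TF sets: base x eps
  spec_tf <- weighted_distance_spec(weights = "tf", eps = 0.01)
  expect_equal(weighted_distance(g1, g2, spec_tf, ctx), 100)
  # product of declared factors
  spec_2 <- weighted_distance_spec(weights = c("density", "tf"), eps = 0.01)
  manual <- gene_distance(g1, g2, "positional") *
    compute_weight(g1, g2, "density", spec_2, ctx) *
    compute_weight(g1, g2, "tf", spec_2, ctx)
  expect_equal(weighted_distance(g1, g2, spec_2, ctx), manual)
  # adding uniform to any weight list changes nothing
  spec_3 <- weighted_distance_spec(weights = c("uniform", "tf"), eps = 0.01)
  expect_equal(weighted_distance(g1, g2, spec_3, ctx),
               weighted_distance(g1, g2, spec_tf, ctx))
})

test_that("weight plug-ins register, apply, clamp and reject duplicates", {
  withr::defer({
    unregister_weight_plugin("const1")
    unregister_weight_plugin("wild")
  })
  register_weight_plugin("const1", function(g1, g2, ctx) 1)
  expect_error(register_weight_plugin("const1", function(g1, g2, ctx) 1),
               "already registered")
  expect_true("const1" %in% weight_plugins())
  d <- quick_dataset(c(1, 5001))
  ctx <- distance_context(d)
  g1 <- d$genes[1, ]; g2 <- d$genes[2, ]
  spec_p <- weighted_distance_spec(weights = "plugin:const1")
  spec_u <- weighted_distance_spec(weights = "uniform")
  expect_equal(weighted_distance(g1, g2, spec_p, ctx),
               weighted_distance(g1, g2, spec_u, ctx))
  register_weight_plugin("wild", function(g1, g2, ctx) 7)
  spec_w <- weighted_distance_spec(weights = "plugin:wild")
  expect_warning(w <- compute_weight(g1, g2, "plugin:wild", spec_w, ctx),
                 "clamped")
  expect_lte(w, 1)
  expect_error(weighted_distance(g1, g2,
                                 weighted_distance_spec(weights = "plugin:none"),
                                 ctx), "unknown weight plugin")
  expect_error(weighted_distance_spec(weights = "bogus"), "unknown weighting")
})
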