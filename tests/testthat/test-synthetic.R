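test_that("generation is a pure function of spec and seed", {
  spec <- planted_genome_spec()
  g1 <- generate_genome(spec, seed = 11)
  g2 <- generate_genome(spec, seed = 11)
  expect_identical(g1$dataset$genes, g2$dataset$genes)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_genome(spec, seed = 12)
  expect_false(identical(g1$dataset$genes, g3$dataset$genes))
  # attribute generation is deterministic too
  a1 <- generate_attributes(g1, seed = 4)
  a2 <- generate_attributes(g1, seed = 4)
  expect_identical(a1$dataset$expression, a2$dataset$expression)
  expect_identical(a1$dataset$tf, a2$dataset$tf)
})

test_that("planted gap bounds hold within and between blocks", {
  spec <- planted_genome_spec(gap_within = 1e4, gap_between = 2e5)
  g <- generate_genome(spec, seed = 13)
  genes <- g$dataset$genes
  truth <- g$truth
  for (ch in unique(genes$chromosome)) {
    idx <- which(genes$chromosome == ch)
    gaps <- diff(genes$start[idx])
    same_block <- !is.na(truth$block[idx][-1]) &
      !is.na(truth$block[idx][-length(idx)]) &
      truth$block[idx][-1] == truth$block[idx][-length(idx)]
    expect_true(all(gaps[same_block] <= 1e4))
    expect_true(all(gaps[!same_block] >= 2e5))
  }
})

test_that("a threshold between the gap bounds recovers blocks exactly", {
  g <- generate_genome(planted_genome_spec(gap_within = 1e4,
                                           gap_between = 2e5), seed = 14)
  r <- sequential_cluster(g$dataset, threshold = 83000)
  expect_equal(rand_index(r$assignments$cluster, g$truth$block), 1)
})

test_that("a block-free genome clusters into singletons", {
  spec <- planted_genome_spec(blocks_per_chromosome = 0L,
                              background_per_chromosome = 6L)
  g <- generate_genome(spec, seed = 15)
  r <- sequential_cluster(g$dataset, threshold = 83000)
  expect_equal(n_clusters(r), n_genes(g$dataset))
})

test_that("infeasible packing is rejected", {
  spec <- planted_genome_spec(chromosome_length = 1e5,
                              blocks_per_chromosome = 5L)
  expect_error(generate_genome(spec, seed = 16), "infeasible packing")
})

test_that("noise-free expression makes within-block ANOVA weights collapse", {
  g <- generate_genome(planted_genome_spec(chromosomes = 1L), seed = 17)
  a <- generate_attributes(g, mode = "expression", noise_sd = 0, seed = 18)
  d <- a$dataset
  blocks <- a$truth$block
  in_block <- which(!is.na(blocks))
  b1 <- blocks[in_block[1]]
  members <- which(!is.na(blocks) & blocks == b1)
  expect_true(all(d$expression[members[1], ] == d$expression[members[2], ]))
  spec <- weighted_distance_spec(weights = "expression",
                                 expression_mode = "anova", eps = 0.01)
  ctx <- distance_context(d)
  w <- compute_weight(d$genes[members[1], ], d$genes[members[2], ],
                      "expression", spec, ctx)
  expect_equal(w, 0.01)
})

test_that("deterministic TF planting pins the Jaccard boundary weights", {
  g <- generate_genome(planted_genome_spec(chromosomes = 1L), seed = 19)
  a <- generate_attributes(g, mode = "tf", q = 1, q0 = 0, seed = 20)
  d <- a$dataset
  blocks <- a$truth$block
  spec <- weighted_distance_spec(weights = "tf", eps = 0.01)
  ctx <- distance_context(d)
  b_levels <- unique(blocks[!is.na(blocks)])
  m1 <- which(!is.na(blocks) & blocks == b_levels[1])
  m2 <- which(!is.na(blocks) & blocks == b_levels[2])
  w_in <- compute_weight(d$genes[m1[1], ], d$genes[m1[2], ], "tf", spec, ctx)
  w_out <- compute_weight(d$genes[m1[1], ], d$genes[m2[1], ], "tf", spec, ctx)
  expect_equal(w_in, 0.01)  # identical repertoires
  expect_equal(w_out, 1)    # disjoint repertoires
})

test_that("ortholog fixtures realize the planted gap structure", {
  g <- generate_genome(planted_genome_spec(chromosomes = 1L,
                                           blocks_per_chromosome = 3L,
                                           genes_per_block = 5L,
                                           background_per_chromosome = 4L),
                       seed = 21)
  # fully conserved, no insertions: the max-gap result at g = 0 equals the
  # fixture's own expectation, and no planted block is ever split
  f0 <- generate_ortholog_fixture(g, conserved_fraction = 1,
                                  insertions_per_block = 0, seed = 22)
  r0 <- maxgap_cluster(g$dataset, f0$map, maxgap = 0, minsize = 1)
  got <- lapply(unname(clusters(r0)), sort)
  want <- lapply(f0$expected_clusters(0, 1), sort)
  expect_setequal(got, want)
  blocks <- g$truth$block
  cl <- r0$assignments$cluster
  for (b in unique(blocks[!is.na(blocks)]))
    expect_equal(length(unique(cl[!is.na(blocks) & blocks == b])), 1)
  # one interior insertion per block: intact at g = 1, split at g = 0
  f1 <- generate_ortholog_fixture(g, conserved_fraction = 1,
                                  insertions_per_block = 1, seed = 22)
  r1 <- maxgap_cluster(g$dataset, f1$map, maxgap = 1, minsize = 1)
  cl1 <- r1$assignments$cluster
  for (b in unique(blocks[!is.na(blocks)])) {
    members <- which(!is.na(blocks) & blocks == b & f1$orthologous)
    expect_equal(length(unique(cl1[members])), 1)
  }
  r1b <- maxgap_cluster(g$dataset, f1$map, maxgap = 0, minsize = 1)
  split_counts <- vapply(unique(blocks[!is.na(blocks)]), function(b) {
    members <- which(!is.na(blocks) & blocks == b & f1$orthologous)
    length(unique(r1b$assignments$cluster[members]))
  }, numeric(1))
  expect_true(all(split_counts == 2))
  # zero conservation: empty result
  fnone <- generate_ortholog_fixture(g, conserved_fraction = 0, seed = 23)
  expect_equal(n_clusters(maxgap_cluster(g$dataset, fnone$map, 1)), 0)
})

test_that("fixtures round-trip through the file readers", {
  g <- generate_genome(planted_genome_spec(chromosomes = 1L), seed = 24)
  a <- generate_attributes(g, mode = "both", seed = 25)
  dir <- withr::local_tempdir()
  paths <- write_genome_fixture(a, dir)
  d2 <- read_gene_annotation(paths[["annotation"]], "tsv",
                             organism = a$dataset$organism,
                             name = a$dataset$name)
  expect_equal(d2$genes, a$dataset$genes)
  expect_equal(read_expression_csv(paths[["expression"]]),
               a$dataset$expression)
  tf2 <- read_tf_annotation(paths[["tf"]])
  nonempty <- a$dataset$tf[lengths(a$dataset$tf) > 0]
  expect_equal(tf2[order(names(tf2))], nonempty[order(names(nonempty))])
  f <- generate_ortholog_fixture(g, seed = 26)
  orth_path <- file.path(dir, "orth.tsv")
  write_ortholog_map(f$map, orth_path)
  m2 <- read_ortholog_map(orth_path, f$map$organisms[1], f$map$organisms[2])
  expect_equal(m2$pairs, f$map$pairs)
})
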