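two_sets <- function() {
  a <- quick_dataset(c(100, 5000), ids = c("g1", "g2"), name = "A")
  b <- gene_dataset(make_genes(c(5000, 9000), ids = c("g2", "g3")),
                    name = "B", organism = "org")
  list(a = a, b = b)
}

test_that("dataset set operations follow set algebra on ids", {
  s <- two_sets()
  expect_equal(gene_ids(combine_datasets(s$a, s$a, "intersect")),
               gene_ids(s$a))
  empty <- subset_genes(s$a, character(0))
  expect_equal(gene_ids(combine_datasets(s$a, empty, "subtract")),
               gene_ids(s$a))
  merged <- combine_datasets(s$a, s$b, "merge")
  expect_setequal(gene_ids(merged), c("g1", "g2", "g3"))
  # subtract(merge(A,B), B) is a subset of A
  left <- combine_datasets(merged, s$b, "subtract")
  expect_true(all(gene_ids(left) %in% gene_ids(s$a)))
  # intersect commutes on id sets
  expect_setequal(gene_ids(combine_datasets(s$a, s$b, "intersect")),
                  gene_ids(combine_datasets(s$b, s$a, "intersect")))
  c_org <- gene_dataset(make_genes(c(10)), organism = "other")
  expect_error(combine_datasets(s$a, c_org, "merge"), "organism")
})

test_that("merge keeps the left operand's attributes on conflict", {
  s <- two_sets()
  a <- attach_expression(s$a, matrix(c(1, 2), 2, 1,
                                     dimnames = list(c("g1", "g2"), "c1")))
  b <- attach_expression(s$b, matrix(c(99, 3), 2, 1,
                                     dimnames = list(c("g2", "g3"), "c1")))
  m <- combine_datasets(a, b, "merge")
  expect_equal(m$expression["g2", "c1"], 2)
  expect_equal(m$expression["g3", "c1"], 3)
})

test_that("expression scalar combination skips missing values", {
  d <- quick_dataset(c(1, 2, 3), ids = c("g1", "g2", "g3"))
  m <- matrix(c(2, NA, -1, 4, NA, 0, 6, NA, NA), 3,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2", "c3")))
  d <- attach_expression(d, m)
  expect_equal(combine_expressions(d, "g1", reducer = "mean"), 4)
  expect_equal(combine_expressions(d, "g3", reducer = "max"), 0)
  expect_equal(combine_expressions(d, "g1", conditions = c("c1", "c3"),
                                   reducer = "sum"), 8)
  expect_error(combine_expressions(d, "g2"), "no non-missing")
})

test_that("expression filters evaluate Boolean combinations and partition", {
  d <- quick_dataset(seq(1, 10) * 1000, ids = sprintf("g%d", 1:10))
  set.seed(4)
  m <- matrix(rnorm(20), 10, dimnames = list(gene_ids(d), c("c1", "c2")))
  d <- attach_expression(d, m)
  f_and <- expression_filter(list(c("c1", ">", 0), c("c2", ">", 0)), "and")
  f_or <- expression_filter(list(c("c1", ">", 0), c("c2", ">", 0)), "or")
  keep_and <- gene_ids(filter_by_expression(d, f_and))
  keep_or <- gene_ids(filter_by_expression(d, f_or))
  # brute force over genes
  expect_setequal(keep_and, rownames(m)[m[, 1] > 0 & m[, 2] > 0])
  expect_setequal(keep_or, rownames(m)[m[, 1] > 0 | m[, 2] > 0])
  # complement partitions the dataset
  f_not <- expression_filter(list(c("c1", ">", 0), c("c2", ">", 0)),
                             combine = function(x) !(x[1] && x[2]))
  keep_not <- gene_ids(filter_by_expression(d, f_not))
  expect_setequal(c(keep_and, keep_not), gene_ids(d))
  expect_length(intersect(keep_and, keep_not), 0)
  expect_error(filter_by_expression(d, expression_filter(list(c("nope", ">", 0)))),
               "unknown condition")
})

test_that("missing-policy controls how NA cells meet thresholds", {
  d <- quick_dataset(c(100, 200), ids = c("g1", "g2"))
  m <- matrix(c(5, NA), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
  d <- attach_expression(d, m)
  f_fail <- expression_filter(list(c("c1", ">", 0)), missing_policy = "fail")
  f_pass <- expression_filter(list(c("c1", ">", 0)), missing_policy = "pass")
  expect_equal(gene_ids(filter_by_expression(d, f_fail)), "g1")
  expect_setequal(gene_ids(filter_by_expression(d, f_pass)), c("g1", "g2"))
})

test_that("expression comparison ranks shared genes by |delta|", {
  s <- two_sets()
  a <- attach_expression(s$a, matrix(c(5, 1), 2, 1,
                                     dimnames = list(c("g1", "g2"), "c1")))
  b <- attach_expression(s$b, matrix(c(2, 2), 2, 1,
                                     dimnames = list(c("g2", "g3"), "c1")))
  rep_ab <- compare_datasets_by_expression(a, b, "c1")
  expect_equal(rep_ab$gene_id, "g2")
  expect_equal(rep_ab$delta, -1)
  # identical tables -> all deltas zero
  rep_aa <- compare_datasets_by_expression(a, a, "c1")
  expect_true(all(rep_aa$delta == 0))
  # disjoint id sets -> empty report
  d2 <- attach_expression(quick_dataset(c(7), ids = "z9"),
                          matrix(1, 1, 1, dimnames = list("z9", "c1")))
  expect_equal(nrow(compare_datasets_by_expression(a, d2, "c1")), 0)
})

test_that("forward and reverse TF queries are mutually consistent", {
  d <- quick_dataset(c(1, 2, 3, 4) * 1000, ids = sprintf("g%d", 1:4))
  d <- attach_tf(d, list(g1 = c(A = 2), g2 = c(B = 1), g4 = c(A = 1, B = 3)))
  fwd <- tfs_of_genes(d)
  expect_length(fwd, 4)
  expect_length(fwd$g3, 0)
  rev_a <- genes_of_tf(d, "A")
  expect_equal(rev_a$genes$gene_id, c("g1", "g4"))
  expect_equal(rev_a$frequency, 0.5)
  expect_equal(genes_of_tf(d, "Z")$frequency, 0)
  for (tf in c("A", "B"))
    for (g in names(fwd))
      expect_equal(g %in% genes_of_tf(d, tf)$genes$gene_id,
                   tf %in% names(fwd[[g]]))
})

test_that("TF dataset comparison categorizes from the first dataset's view", {
  a <- attach_tf(quick_dataset(c(1, 2, 3, 4, 5) * 100,
                               ids = sprintf("a%d", 1:5), name = "A"),
                 tf_ann(a1 = "X", a2 = "X", a3 = "X", a4 = "Y"))
  b <- attach_tf(gene_dataset(make_genes(c(1, 2, 3, 4, 5) * 100,
                                         ids = sprintf("b%d", 1:5)),
                              name = "B", organism = "org"),
                 tf_ann(b1 = "X", b2 = "Y", b3 = c("Y", "Z")))
  cmp <- compare_datasets_by_tf(a, b)
  row <- function(tf) cmp[cmp$tf_name == tf, ]
  expect_equal(row("X")$category, "higher")
  expect_equal(row("X")$difference, 0.6 - 0.2)
  expect_equal(row("Y")$category, "lower")
  expect_equal(row("Z")$category, "absent")
  expect_equal(cmp$tf_name[1], "X")  # largest difference first
  same <- compare_datasets_by_tf(a, a)
  expect_true(all(same$category == "equal"))
  expect_true(all(same$difference == 0))
})

test_that("chromosome statistics merge intervals before computing coverage", {
  d <- gene_dataset(make_genes(c(100, 301), lengths = c(101, 200)))
  st <- chromosome_stats(d, "chr1", chromosome_length = 1000)
  expect_equal(st$coverage, 0.301)
  expect_equal(st$gap_min, 201)  # start-to-start
  # overlapping genes are merged
  d2 <- gene_dataset(make_genes(c(100, 200), lengths = c(201, 201)))
  expect_equal(chromosome_stats(d2, "chr1", 1000)$coverage, 0.301)
  # intergenic gap convention
  expect_equal(chromosome_stats(d, "chr1", 1000, gap = "intergenic")$gap_min,
               100)
  # single gene: min = mean = max length, no gap statistic
  d3 <- quick_dataset(c(500), lengths = 50)
  st3 <- chromosome_stats(d3, "chr1", 1000)
  expect_equal(st3$length_min, st3$length_max)
  expect_true(is.na(st3$gap_mean))
  # empty chromosome
  st0 <- chromosome_stats(d3, "chr9")
  expect_equal(st0$n_genes, 0)
  expect_true(is.na(st0$coverage))
  # coverage never exceeds 1
  dense <- gene_dataset(make_genes(seq(1, 901, by = 100), lengths = 500))
  expect_lte(chromosome_stats(dense, "chr1", 1000)$coverage, 1)
  # triples are ordered
  st4 <- chromosome_stats(gene_dataset(make_genes(c(1, 50, 500),
                                                  lengths = c(10, 200, 30))),
                          "chr1")
  expect_true(st4$length_min <= st4$length_mean &&
                st4$length_mean <= st4$length_max)
  expect_true(st4$gap_min <= st4$gap_mean && st4$gap_mean <= st4$gap_max)
})
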