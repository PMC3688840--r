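# Name-, expression-, TF- and position-based dataset processing.

#' Set operations on gene datasets
#'
#' Membership is decided by gene id.  `merge` is the union (on id conflict the
#' left operand's record and attachments win), `intersect` keeps ids present
#' in both, `subtract` keeps ids of `a` absent from `b`.
#'
#' @param a,b `GeneDataset`s of the same organism.
#' @param mode `"merge"`, `"intersect"` or `"subtract"`.
#' @param name name for the result.
#' @return a `GeneDataset`.
#' @export
combine_datasets <- function(a, b, mode = c("merge", "intersect", "subtract"),
                             name = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "GeneDataset"), inherits(b, "GeneDataset"))
  if (!identical(a$organism, b$organism))
    stop("organism mismatch: ", a$organism, " vs ", b$organism)
  if (is.null(name)) name <- paste0(mode, "(", a$name, ",", b$name, ")")
  if (mode == "merge") {
    extra <- setdiff(b$genes$gene_id, a$genes$gene_id)
    genes <- rbind(a$genes, b$genes[b$genes$gene_id %in% extra, , drop = FALSE])
    out <- gene_dataset(genes, name = name, organism = a$organism,
                        unresolved = union(a$unresolved, b$unresolved))
    out$expression <- merge_expression(a$expression, b$expression)
    out$tf <- merge_tf(a$tf, b$tf)
    return(out)
  }
  ids <- switch(mode,
                intersect = intersect(a$genes$gene_id, b$genes$gene_id),
                subtract = setdiff(a$genes$gene_id, b$genes$gene_id))
  subset_genes(a, ids, name = name)
}

merge_expression <- function(ea, eb) {
  if (is.null(ea)) return(eb)
  if (is.null(eb)) return(ea)
  conditions <- union(colnames(ea), colnames(eb))
  ids <- union(rownames(ea), rownames(eb))
  m <- matrix(NA_real_, length(ids), length(conditions),
              dimnames = list(ids, conditions))
  m[rownames(eb), colnames(eb)] <- eb
  m[rownames(ea), colnames(ea)] <- ea  # left operand wins
  m
}

merge_tf <- function(ta, tb) {
  if (is.null(ta)) return(tb)
  if (is.null(tb)) return(ta)
  out <- tb
  out[names(ta)] <- ta
  out
}

#' Reduce several expression values of one gene to a scalar
#'
#' Missing values are skipped; at least one non-missing value is required.
#'
#' @param d a `GeneDataset` with an expression table attached.
#' @param gene_id gene id.
#' @param conditions condition names to combine (default: all).
#' @param reducer `"mean"`, `"median"`, `"min"`, `"max"` or `"sum"`.
#' @return a single numeric value.
#' @export
combine_expressions <- function(d, gene_id,
                                conditions = colnames(d$expression),
                                reducer = c("mean", "median", "min", "max",
                                            "sum")) {
  reducer <- match.arg(reducer)
  vals <- expression_values(d, gene_id, conditions)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L)
    stop("no non-missing expression values for gene ", gene_id)
  switch(reducer, mean = mean(vals), median = median(vals), min = min(vals),
         max = max(vals), sum = sum(vals))
}

expression_values <- function(d, gene_id, conditions = colnames(d$expression)) {
  stopifnot(inherits(d, "GeneDataset"))
  if (is.null(d$expression)) stop("no expression table attached")
  unknown <- setdiff(conditions, colnames(d$expression))
  if (length(unknown) > 0L)
    stop("unknown condition(s): ", paste(unknown, collapse = ", "))
  if (!gene_id %in% rownames(d$expression))
    return(setNames(rep(NA_real_, length(conditions)), conditions))
  d$expression[gene_id, conditions]
}

#' Build an expression filter
#'
#' A filter is a list of threshold clauses combined by a Boolean rule.  Each
#' clause compares one condition's value with a threshold.
#'
#' @param clauses list of clauses, each a list/vector
#'   `(condition, comparator, threshold)` with comparator one of
#'   `<, <=, >, >=, =`.
#' @param combine `"and"`, `"or"`, or a function taking the logical vector of
#'   clause results for one gene and returning a single logical (arbitrary
#'   Boolean trees can be expressed this way, e.g.
#'   `function(x) x[1] && !(x[2] || x[3])`).
#' @param missing_policy how a clause on a missing value evaluates:
#'   `"fail"` (default: a missing value cannot satisfy a threshold) or
#'   `"pass"`.
#' @return an `ExpressionFilter`.
#' @export
expression_filter <- function(clauses, combine = "and",
                              missing_policy = c("fail", "pass")) {
  missing_policy <- match.arg(missing_policy)
  clauses <- lapply(clauses, function(cl) {
    cl <- as.list(cl)
    names(cl) <- c("condition", "comparator", "threshold")[seq_along(cl)]
    if (!cl$comparator %in% c("<", "<=", ">", ">=", "="))
      stop("unknown comparator: ", cl$comparator)
    cl$threshold <- as.numeric(cl$threshold)
    cl
  })
  if (is.character(combine)) {
    combine <- match.arg(combine, c("and", "or"))
    combine <- if (combine == "and") function(x) all(x) else function(x) any(x)
  }
  stopifnot(is.function(combine))
  structure(list(clauses = clauses, combine = combine,
                 missing_policy = missing_policy),
            class = "ExpressionFilter")
}

eval_clause <- function(value, comparator, threshold, missing_policy) {
  if (is.na(value)) return(missing_policy == "pass")
  switch(comparator,
         "<" = value < threshold, "<=" = value <= threshold,
         ">" = value > threshold, ">=" = value >= threshold,
         "=" = value == threshold)
}

#' Filter a dataset by expression thresholds
#'
#' @param d a `GeneDataset` with an expression table attached.
#' @param filter an [expression_filter()].
#' @return the `GeneDataset` of genes whose combined clause result is `TRUE`.
#' @export
filter_by_expression <- function(d, filter) {
  stopifnot(inherits(d, "GeneDataset"), inherits(filter, "ExpressionFilter"))
  if (is.null(d$expression)) stop("no expression table attached")
  for (cl in filter$clauses)
    if (!cl$condition %in% colnames(d$expression))
      stop("clause references unknown condition: ", cl$condition)
  keep <- vapply(d$genes$gene_id, function(id) {
    known <- id %in% rownames(d$expression)
    res <- vapply(filter$clauses, function(cl) {
      v <- if (known) d$expression[id, cl$condition] else NA_real_
      eval_clause(v, cl$comparator, cl$threshold, filter$missing_policy)
    }, logical(1))
    isTRUE(filter$combine(res))
  }, logical(1))
  subset_genes(d, d$genes$gene_id[keep],
               name = paste0(d$name, ":filtered"))
}

#' Compare two datasets by expression under one condition
#'
#' For each gene id present in both datasets, the per-gene delta
#' `expr_a - expr_b` is computed and the report is sorted by decreasing
#' absolute delta.
#'
#' @param a,b `GeneDataset`s with expression attached.
#' @param condition shared condition name.
#' @return data.frame with columns `gene_id`, `expr_a`, `expr_b`, `delta`,
#'   `rank` (1 = largest |delta|).
#' @export
compare_datasets_by_expression <- function(a, b, condition) {
  stopifnot(inherits(a, "GeneDataset"), inherits(b, "GeneDataset"))
  if (is.null(a$expression) || is.null(b$expression))
    stop("both datasets need an expression table attached")
  if (!condition %in% colnames(a$expression) ||
      !condition %in% colnames(b$expression))
    stop("condition not shared by both datasets: ", condition)
  shared <- intersect(intersect(a$genes$gene_id, rownames(a$expression)),
                      intersect(b$genes$gene_id, rownames(b$expression)))
  out <- data.frame(gene_id = shared,
                    expr_a = if (length(shared)) a$expression[shared, condition]
                             else numeric(0),
                    expr_b = if (length(shared)) b$expression[shared, condition]
                             else numeric(0))
  out$delta <- out$expr_a - out$expr_b
  out <- out[order(-abs(out$delta), out$gene_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' TF repertoires of all genes in a dataset
#'
#' @param d a `GeneDataset` with a TF annotation attached.
#' @return named list with one entry per dataset gene (in positional order):
#'   a named numeric vector of site counts, empty for unannotated genes.
#' @export
tfs_of_genes <- function(d) {
  stopifnot(inherits(d, "GeneDataset"))
  if (is.null(d$tf)) stop("no TF annotation attached")
  setNames(lapply(d$genes$gene_id, function(id) tf_of_gene(d, id)),
           d$genes$gene_id)
}

#' Genes of a dataset recognized by one TF
#'
#' @param d a `GeneDataset` with a TF annotation attached.
#' @param tf_name TF name.
#' @return list with `genes` (data.frame `gene_id`, `site_count`), `n_genes`,
#'   and `frequency` = recognized genes / dataset size (0 for an empty
#'   dataset or unknown TF).
#' @export
genes_of_tf <- function(d, tf_name) {
  stopifnot(inherits(d, "GeneDataset"))
  if (is.null(d$tf)) stop("no TF annotation attached")
  counts <- vapply(d$genes$gene_id, function(id) {
    v <- tf_of_gene(d, id)
    if (tf_name %in% names(v)) v[[tf_name]] else 0
  }, numeric(1))
  hit <- counts > 0
  genes <- data.frame(gene_id = d$genes$gene_id[hit],
                      site_count = unname(counts[hit]))
  list(tf_name = tf_name, genes = genes, n_genes = nrow(genes),
       frequency = if (n_genes(d) > 0L) nrow(genes) / n_genes(d) else 0)
}

#' Compare two datasets by TF recognition frequencies
#'
#' For every TF seen in either dataset the per-dataset recognition frequency
#' (fraction of genes with at least one site) is computed; the category is
#' from `a`'s perspective (`higher`, `lower`, `equal`, or `absent` when the
#' TF recognizes no gene of `a`).  Rows are ordered by decreasing
#' |freq_a - freq_b|.
#'
#' @param a,b `GeneDataset`s with TF annotations attached.
#' @return data.frame with columns `tf_name`, `freq_a`, `freq_b`, `n_a`,
#'   `n_b`, `difference`, `category`.
#' @export
compare_datasets_by_tf <- function(a, b) {
  stopifnot(inherits(a, "GeneDataset"), inherits(b, "GeneDataset"))
  if (is.null(a$tf) || is.null(b$tf))
    stop("both datasets need a TF annotation attached")
  tfs <- sort(unique(c(
    unlist(lapply(a$genes$gene_id, function(id) names(tf_of_gene(a, id)))),
    unlist(lapply(b$genes$gene_id, function(id) names(tf_of_gene(b, id)))))))
  rows <- lapply(tfs, function(tf) {
    ra <- genes_of_tf(a, tf); rb <- genes_of_tf(b, tf)
    category <- if (ra$n_genes == 0L) "absent"
      else if (ra$frequency > rb$frequency) "higher"
      else if (ra$frequency < rb$frequency) "lower" else "equal"
    data.frame(tf_name = tf, freq_a = ra$frequency, freq_b = rb$frequency,
               n_a = ra$n_genes, n_b = rb$n_genes,
               difference = ra$frequency - rb$frequency, category = category)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tf_name = character(), freq_a = numeric(), freq_b = numeric(),
               n_a = integer(), n_b = integer(), difference = numeric(),
               category = character())
  out <- out[order(-abs(out$difference), out$tf_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Positional statistics of a dataset on one chromosome
#'
#' Gene lengths use `end - start + 1`; consecutive-gene gaps are start-to-start
#' by default (`gap = "start"`) or end-to-next-start (`gap = "intergenic"`,
#' clamped at 0 for overlaps); coverage is the merged-interval union of the
#' dataset's genes divided by the chromosome length.
#'
#' @param d a `GeneDataset` (or gene table).
#' @param chromosome chromosome name.
#' @param chromosome_length length in bp (default: inferred as max gene end).
#' @param gap gap convention, `"start"` or `"intergenic"`.
#' @return a `ChromosomeStats` list: `chromosome`, `n_genes`, length triple
#'   (`length_min`/`length_mean`/`length_max`), gap triple (`NA` when fewer
#'   than two genes), and `coverage` in `[0, 1]`.
#' @export
chromosome_stats <- function(d, chromosome, chromosome_length = NULL,
                             gap = c("start", "intergenic")) {
  gap <- match.arg(gap)
  layout <- chromosome_layout(d, chromosome, length = chromosome_length)
  g <- layout$genes
  n <- nrow(g)
  if (n == 0L)
    return(structure(list(chromosome = chromosome, n_genes = 0L,
                          length_min = NA_real_, length_mean = NA_real_,
                          length_max = NA_real_, gap_min = NA_real_,
                          gap_mean = NA_real_, gap_max = NA_real_,
                          coverage = NA_real_),
                     class = "ChromosomeStats"))
  lens <- gene_length(g)
  gaps <- if (n >= 2L) {
    if (gap == "start") diff(g$start)
    else pmax(0, g$start[-1L] - g$end[-n] - 1)
  } else numeric(0)
  covered <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(start = g$start, end = g$end))))
  structure(list(
    chromosome = chromosome, n_genes = n,
    length_min = min(lens), length_mean = mean(lens), length_max = max(lens),
    gap_min = if (length(gaps)) min(gaps) else NA_real_,
    gap_mean = if (length(gaps)) mean(gaps) else NA_real_,
    gap_max = if (length(gaps)) max(gaps) else NA_real_,
    coverage = min(1, covered / layout$length)),
    class = "ChromosomeStats")
}
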