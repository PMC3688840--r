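# Post-clustering statistics: summaries, random-set significance, the
# neighbourhood null model for adjacent selected genes, TF co-occurrence
# across clusters, expression-group comparisons, gene-list localization and
# the per-TF cluster census.

new_stat_report <- function(test, statistic, p_value, tails, sample_sizes,
                            replicates = NULL, seed = NULL,
                            null_description = "", ...) {
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 tails = tails, sample_sizes = sample_sizes,
                 replicates = replicates, seed = seed,
                 null_description = null_description, ...),
            class = "StatReport")
}

#' @export
print.StatReport <- function(x, ...) {
  cat(sprintf("StatReport: %s\n  statistic = %s, p = %s (%s-tailed)\n",
              x$test, format(x$statistic), format(x$p_value), x$tails))
  if (nzchar(x$null_description))
    cat("  null:", x$null_description, "\n")
  invisible(x)
}

#' Summary statistics of a clustering result
#'
#' Within-cluster distances are start-to-start gaps between consecutive
#' member genes; between-cluster distances are start-to-start gaps from the
#' last gene of one cluster to the first gene of the next cluster on the same
#' chromosome.  "Large" clusters contain three or more genes.
#'
#' @param r a `ClusterResult`.
#' @return a `ClusterSummary` list: cluster and clustered-gene counts,
#'   min/mean/max cluster size, min/mean/max within- and between-cluster
#'   distance (bp), the cluster-size histogram (named vector size -> count),
#'   and the large-cluster count and gene fraction (clustered genes in
#'   size >= 3 clusters over all genes).
#' @export
cluster_summary <- function(r) {
  stopifnot(inherits(r, "ClusterResult"))
  a <- r$assignments[!is.na(r$assignments$cluster), , drop = FALSE]
  n_total <- nrow(r$assignments)
  if (nrow(a) == 0L)
    return(structure(list(
      n_clusters = 0L, n_clustered_genes = 0L,
      size_min = 0, size_mean = 0, size_max = 0,
      within_min = NA_real_, within_mean = NA_real_, within_max = NA_real_,
      between_min = NA_real_, between_mean = NA_real_, between_max = NA_real_,
      size_histogram = integer(0), n_large_clusters = 0L,
      large_gene_fraction = 0), class = "ClusterSummary"))
  sizes <- as.integer(table(a$cluster))
  within <- unlist(lapply(split(a$start, a$cluster), function(s)
    if (length(s) >= 2L) diff(sort(s)) else numeric(0)), use.names = FALSE)
  between <- unlist(lapply(split(a, a$chromosome), function(chrom_a) {
    cl_order <- unique(chrom_a$cluster)
    if (length(cl_order) < 2L) return(numeric(0))
    firsts <- vapply(cl_order, function(cl)
      min(chrom_a$start[chrom_a$cluster == cl]), numeric(1))
    lasts <- vapply(cl_order, function(cl)
      max(chrom_a$start[chrom_a$cluster == cl]), numeric(1))
    o <- order(firsts)
    firsts[o][-1L] - lasts[o][-length(o)]
  }), use.names = FALSE)
  hist <- table(factor(sizes, levels = sort(unique(sizes))))
  large <- sizes >= 3L
  structure(list(
    n_clusters = length(sizes), n_clustered_genes = nrow(a),
    size_min = min(sizes), size_mean = mean(sizes), size_max = max(sizes),
    within_min = if (length(within)) min(within) else NA_real_,
    within_mean = if (length(within)) mean(within) else NA_real_,
    within_max = if (length(within)) max(within) else NA_real_,
    between_min = if (length(between)) min(between) else NA_real_,
    between_mean = if (length(between)) mean(between) else NA_real_,
    between_max = if (length(between)) max(between) else NA_real_,
    size_histogram = setNames(as.integer(hist), names(hist)),
    n_large_clusters = sum(large),
    large_gene_fraction = sum(sizes[large]) / n_total),
    class = "ClusterSummary")
}

#' Compare a clustering against random gene sets
#'
#' Repeatedly draws `n_genes(d)` genes without replacement from `pool`, runs
#' the identical clustering function, and records the number of clusters.
#' The replicate counts are compared with the observed count by a one-sample
#' t-test with the observed count as reference mean; the default one-tailed
#' direction asks whether the observed clustering produced *more* clusters
#' than random sets (t = (observed - replicate mean) / (SD/sqrt(reps))).
#'
#' @param d the clustered `GeneDataset`.
#' @param pool a `GeneDataset` to draw random sets from (larger than `d`;
#'   it may overlap `d`).
#' @param cluster_fn function `GeneDataset -> ClusterResult`, applied
#'   identically to `d` and to every random set.
#' @param reps number of random replicates (>= 2).
#' @param seed integer seed for the draws.
#' @param tails `"one"` (observed > random, default) or `"two"`.
#' @return a `StatReport` with the t statistic, p-value, replicate mean/SD
#'   (`$replicate_mean`, `$replicate_sd`, `$replicate_counts`), the observed
#'   count (`$observed`), and `$degenerate = TRUE` when the replicates had
#'   zero variance (p is then 0, 1 or 0.5 by the sign of the difference).
#' @export
random_set_comparison <- function(d, pool, cluster_fn, reps = 100L,
                                  seed = NULL, tails = c("one", "two")) {
  tails <- match.arg(tails)
  stopifnot(inherits(d, "GeneDataset"), inherits(pool, "GeneDataset"))
  n <- n_genes(d)
  if (n_genes(pool) <= n)
    stop("pool must be larger than the dataset (", n_genes(pool),
         " <= ", n, ")")
  if (reps < 2L) stop("need reps >= 2 for a variance estimate")
  if (!is.null(seed)) set.seed(seed)
  observed <- n_clusters(cluster_fn(d))
  counts <- vapply(seq_len(reps), function(i) {
    ids <- sample(pool$genes$gene_id, n)
    n_clusters(cluster_fn(subset_genes(pool, ids, name = "random")))
  }, numeric(1))
  m <- mean(counts); s <- sd(counts)
  degenerate <- s == 0
  if (degenerate) {
    t_stat <- if (observed == m) 0 else sign(observed - m) * Inf
    p <- if (observed > m) 0 else if (observed < m) 1 else 0.5
    if (tails == "two") p <- if (observed == m) 1 else 0
  } else {
    t_stat <- (observed - m) / (s / sqrt(reps))
    p <- if (tails == "one") pt(t_stat, reps - 1L, lower.tail = FALSE)
      else 2 * pt(abs(t_stat), reps - 1L, lower.tail = FALSE)
  }
  new_stat_report(
    test = "one-sample t-test, observed cluster count vs random sets",
    statistic = t_stat, p_value = p, tails = tails,
    sample_sizes = c(dataset = n, pool = n_genes(pool)),
    replicates = reps, seed = seed,
    null_description = sprintf(
      "cluster counts of %d random %d-gene subsets of '%s'", reps, n,
      pool$name),
    observed = observed, replicate_mean = m, replicate_sd = s,
    replicate_counts = counts, degenerate = degenerate)
}

# Exact first two moments of the number of adjacent selected pairs when n of
# N ordered slots are selected uniformly at random.
adjacency_null_moments <- function(N, n) {
  if (N < 2L || n < 2L) return(c(mean = 0, sd = 0))
  r2 <- n * (n - 1) / (N * (N - 1))
  r3 <- if (N >= 3) r2 * (n - 2) / (N - 2) else 0
  r4 <- if (N >= 4) r3 * (n - 3) / (N - 3) else 0
  e <- (N - 1) * r2
  e2 <- (N - 1) * r2 + 2 * (N - 2) * r3 + (N - 2) * (N - 3) * r4
  c(mean = e, sd = sqrt(max(0, e2 - e^2)))
}

#' Neighbourhood null model for adjacent selected genes
#'
#' For each chromosome, counts the pairs of genes adjacent in the background
#' annotation order whose two members both belong to the dataset, and
#' compares the count with its exact null distribution under a uniformly
#' random placement of the dataset's genes among the chromosome's background
#' genes: mean `n(n-1)/N` and the SD derived from the exact first two moments
#' of the sum of adjacency indicators.
#'
#' @param d the selected `GeneDataset`.
#' @param background `GeneDataset` with the full gene annotation; it must
#'   contain every gene of `d`.
#' @param method `"exact"` (analytic moments) or `"permutation"` (Monte-Carlo
#'   re-placement, for verification).
#' @param reps permutation replicates (permutation method only).
#' @param seed seed for the permutation method.
#' @return data.frame (class `NeighbourhoodReport`) with one row per
#'   chromosome carrying `N`, `n`, `observed`, `expected`, `sd`, `z` and the
#'   upper-tail normal `p` (z-based; `NA` when `n < 2` or `sd = 0`).
#' @export
neighbourhood_model <- function(d, background, method = c("exact", "permutation"),
                                reps = 1e4L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(d, "GeneDataset"), inherits(background, "GeneDataset"))
  if (!all(d$genes$gene_id %in% background$genes$gene_id))
    stop("background annotation must contain every dataset gene")
  if (!is.null(seed)) set.seed(seed)
  bg <- background$genes
  rows <- lapply(unique(bg$chromosome), function(ch) {
    ids <- bg$gene_id[bg$chromosome == ch]        # background order
    sel <- ids %in% d$genes$gene_id
    N <- length(ids); n <- sum(sel)
    observed <- if (N >= 2L) sum(sel[-1L] & sel[-N]) else 0L
    if (method == "exact") {
      mo <- adjacency_null_moments(N, n)
    } else {
      draws <- vapply(seq_len(reps), function(i) {
        s <- rep(FALSE, N); s[sample.int(N, n)] <- TRUE
        sum(s[-1L] & s[-N])
      }, numeric(1))
      mo <- c(mean = mean(draws), sd = sd(draws))
    }
    z <- if (n >= 2L && mo[["sd"]] > 0)
      (observed - mo[["mean"]]) / mo[["sd"]] else NA_real_
    data.frame(chromosome = ch, N = N, n = n, observed = observed,
               expected = mo[["mean"]], sd = mo[["sd"]], z = z,
               p = if (is.na(z)) NA_real_ else
                 stats::pnorm(z, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("NeighbourhoodReport", "data.frame")
  attr(out, "method") <- method
  out
}

#' TF pair co-occurrence across clusters
#'
#' Each cluster is scored for presence of each TF (>= 1 binding site in >= 1
#' member gene); the resulting 2x2 presence/absence contingency table over
#' clusters is tested with a two-sided Fisher's exact test.  A marginal
#' both/only-one/neither view of the same counts is also reported.
#'
#' @param r a `ClusterResult`.
#' @param d the `GeneDataset` carrying the TF annotation.
#' @param tf_a,tf_b the TF pair.
#' @return list with `table` (2x2 matrix, rows = `tf_a` present/absent,
#'   columns = `tf_b` present/absent), `marginal` (named counts `both`,
#'   `only_one`, `neither`), and `report` (a `StatReport`).
#' @export
tf_cooccurrence <- function(r, d, tf_a, tf_b) {
  stopifnot(inherits(r, "ClusterResult"), inherits(d, "GeneDataset"))
  if (is.null(d$tf)) stop("no TF annotation attached")
  cl <- clusters(r)
  if (length(cl) == 0L) stop("empty clustering result")
  presence <- function(tf) vapply(cl, function(ids)
    any(vapply(ids, function(id) tf %in% names(tf_of_gene(d, id)),
               logical(1))), logical(1))
  pa <- presence(tf_a); pb <- presence(tf_b)
  tab <- matrix(c(sum(pa & pb), sum(!pa & pb),
                  sum(pa & !pb), sum(!pa & !pb)),
                nrow = 2L,
                dimnames = list(c("present", "absent"),
                                c("present", "absent")))
  names(dimnames(tab)) <- c(tf_a, tf_b)
  p <- fisher_exact_2x2(tab)
  report <- new_stat_report(
    test = "Fisher's exact test, TF co-occurrence across clusters",
    statistic = tab[1L, 1L], p_value = p, tails = "two",
    sample_sizes = c(clusters = length(cl)),
    null_description = sprintf(
      "independent presence of %s and %s across %d clusters", tf_a, tf_b,
      length(cl)))
  list(table = tab,
       marginal = c(both = sum(pa & pb), only_one = sum(xor(pa, pb)),
                    neither = sum(!pa & !pb)),
       report = report)
}

#' Two-sided Fisher's exact p-value for a 2x2 table
#'
#' Sums, over all tables with the observed margins, the hypergeometric
#' probabilities not exceeding that of the observed table.
#'
#' @param tab 2x2 integer matrix.
#' @return p-value in `[0, 1]`.
#' @export
fisher_exact_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0))
  if (sum(tab) == 0L) return(1)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Mann-Whitney U comparison of two value groups
#'
#' Exact p by enumeration of all group assignments of the pooled values when
#' the combined sample size is at most `exact_limit` (midranks handle ties;
#' two-sided extremity is measured by `|U - mn/2|`); above the limit, the
#' tie-corrected normal approximation is used.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param exact_limit combined-size crossover between the exact and
#'   approximate path.
#' @return a `StatReport` with `$statistic` = U of the first group,
#'   `$median_x`, `$median_y` and `$method`.
#' @export
mann_whitney <- function(x, y, exact_limit = 20L) {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("missing values in comparison groups")
  m <- length(x); n <- length(y); N <- m + n
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_of <- function(sum_ranks) sum_ranks - m * (m + 1) / 2
  u_obs <- u_of(sum(rk[seq_len(m)]))
  mu <- m * n / 2
  if (N <= exact_limit) {
    subsets <- utils::combn(N, m)
    u_all <- u_of(colSums(matrix(rk[subsets], nrow = m)))
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    p <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
    method <- "normal approximation with tie correction"
  }
  new_stat_report(
    test = "Mann-Whitney U", statistic = u_obs, p_value = p, tails = "two",
    sample_sizes = c(x = m, y = n),
    null_description = "exchangeable group labels",
    median_x = median(x), median_y = median(y), method = method)
}

#' Compare expression between two gene groups
#'
#' Intended for the post-clustering contrasts "clustered TF targets vs
#' clustered non-targets" and "clustered TF targets vs unclustered TF
#' targets", but accepts any two gene-id sets.
#'
#' @param d a `GeneDataset` with expression attached.
#' @param genes_a,genes_b character vectors of gene ids (non-empty after
#'   dropping genes with missing values).
#' @param condition condition name.
#' @return a `StatReport` from [mann_whitney()].
#' @export
expression_group_comparison <- function(d, genes_a, genes_b, condition) {
  stopifnot(inherits(d, "GeneDataset"))
  if (is.null(d$expression)) stop("no expression table attached")
  if (!condition %in% colnames(d$expression))
    stop("unknown condition: ", condition)
  grab <- function(ids) {
    ids <- intersect(ids, rownames(d$expression))
    v <- d$expression[ids, condition]
    v[!is.na(v)]
  }
  x <- grab(genes_a); y <- grab(genes_b)
  if (length(x) == 0L || length(y) == 0L)
    stop("empty group after removing missing values")
  mann_whitney(x, y)
}

#' Locate a gene list within clusters
#'
#' @param r a `ClusterResult`.
#' @param query character vector of gene ids.
#' @return list with `flagged` (per flagged cluster: cluster id, the query
#'   genes it contains with their locations, and the co-clustered non-query
#'   genes), `n_flagged`, and `query_clustered_fraction` (query genes inside
#'   any cluster / query size).
#' @export
locate_genes_in_clusters <- function(r, query) {
  stopifnot(inherits(r, "ClusterResult"))
  query <- unique(as.character(query))
  a <- r$assignments[!is.na(r$assignments$cluster), , drop = FALSE]
  cl_ids <- unique(a$cluster[a$gene_id %in% query])
  flagged <- lapply(sort(cl_ids), function(cl) {
    members <- a[a$cluster == cl, , drop = FALSE]
    hit <- members$gene_id %in% query
    list(cluster = cl,
         query_genes = members[hit, c("gene_id", "chromosome", "start", "end")],
         other_genes = members$gene_id[!hit])
  })
  n_in_clusters <- sum(query %in% a$gene_id)
  list(flagged = flagged, n_flagged = length(flagged),
       query_clustered_fraction =
         if (length(query) > 0L) n_in_clusters / length(query) else 0)
}

#' Per-TF census of a clustering result
#'
#' @param r a `ClusterResult`.
#' @param d the `GeneDataset` carrying the TF annotation (its annotation
#'   defines each TF's full target set).
#' @return data.frame with one row per TF: clustered target count, number of
#'   clusters containing a target, total and average binding sites over
#'   clustered targets, `high_density` flag (average > 2 sites/promoter), and
#'   `pct_targets_clustered` (clustered / annotated targets, in percent).
#' @export
tf_cluster_census <- function(r, d) {
  stopifnot(inherits(r, "ClusterResult"), inherits(d, "GeneDataset"))
  if (is.null(d$tf)) stop("no TF annotation attached")
  a <- r$assignments
  clustered_ids <- a$gene_id[!is.na(a$cluster)]
  all_tfs <- sort(unique(unlist(lapply(d$genes$gene_id, function(id)
    names(tf_of_gene(d, id))))))
  rows <- lapply(all_tfs, function(tf) {
    hit <- genes_of_tf(d, tf)$genes
    clustered <- hit[hit$gene_id %in% clustered_ids, , drop = FALSE]
    cl_of <- a$cluster[match(clustered$gene_id, a$gene_id)]
    avg <- if (nrow(clustered) > 0L) mean(clustered$site_count) else 0
    data.frame(
      tf_name = tf,
      n_targets = nrow(hit),
      n_targets_clustered = nrow(clustered),
      n_clusters_with_target = length(unique(cl_of)),
      total_sites_clustered = sum(clustered$site_count),
      avg_sites_per_target = avg,
      high_density = avg > 2,
      pct_targets_clustered = if (nrow(hit) > 0L)
        100 * nrow(clustered) / nrow(hit) else 0)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tf_name = character(), n_targets = integer(),
               n_targets_clustered = integer(),
               n_clusters_with_target = integer(),
               total_sites_clustered = numeric(),
               avg_sites_per_target = numeric(), high_density = logical(),
               pct_targets_clustered = numeric())
  rownames(out) <- NULL
  out
}
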