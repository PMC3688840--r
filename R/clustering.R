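# The three positional clustering algorithms: sequential threshold scanning,
# 1-D k-means (random / uniform / ++ seeding, optional automatic k), and
# max-gap clustering of orthology-bearing genes.  Every algorithm partitions
# per chromosome; clusters never span chromosomes.

new_cluster_result <- function(dataset, algorithm, parameters, assignments,
                               n_evaluations = NULL) {
  stopifnot(is.data.frame(assignments))
  structure(list(dataset = dataset, algorithm = algorithm,
                 parameters = parameters, assignments = assignments,
                 n_evaluations = n_evaluations),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  k <- n_clusters(x)
  cat(sprintf("ClusterResult (%s) on '%s': %d cluster(s), %d/%d gene(s) clustered\n",
              x$algorithm, x$dataset, k,
              sum(!is.na(x$assignments$cluster)), nrow(x$assignments)))
  invisible(x)
}

#' Clusters of a result as gene-id lists
#' @param r a `ClusterResult`.
#' @return named list of character vectors, one per cluster, genes in
#'   positional order.
#' @export
clusters <- function(r) {
  stopifnot(inherits(r, "ClusterResult"))
  a <- r$assignments[!is.na(r$assignments$cluster), , drop = FALSE]
  split(a$gene_id, a$cluster)
}

#' Number of clusters in a result
#' @param r a `ClusterResult`.
#' @return integer.
#' @export
n_clusters <- function(r) {
  stopifnot(inherits(r, "ClusterResult"))
  length(unique(r$assignments$cluster[!is.na(r$assignments$cluster)]))
}

# Renumber cluster labels 1..K in (chromosome, first-gene-position) order.
renumber_clusters <- function(assignments) {
  a <- assignments
  ok <- !is.na(a$cluster)
  if (!any(ok)) return(a)
  key <- paste(a$chromosome, a$cluster)[ok]
  first <- !duplicated(key)                     # rows already position-sorted
  order_keys <- key[first]
  a$cluster[ok] <- match(key, order_keys)
  a
}

#' Sequential threshold clustering
#'
#' Genes are scanned per chromosome in position order; each gene joins the
#' previous gene's cluster when their weighted distance is strictly below the
#' threshold, and opens a new cluster otherwise.  Exactly one adjacent pair is
#' evaluated per scanned gene, so the scan performs `n - c` distance
#' evaluations on an `n`-gene, `c`-chromosome dataset (the count is reported
#' in the result).  Singleton clusters are retained; size filtering is a
#' post-processing concern.
#'
#' @param d a `GeneDataset`.
#' @param threshold distance threshold T (> 0), in units of the weighted
#'   distance.
#' @param spec a [weighted_distance_spec()] (default: unweighted positional).
#' @param context optional [distance_context()]; built from `d` when omitted.
#' @return a `ClusterResult` whose `n_evaluations` records the number of
#'   weighted-distance evaluations performed.
#' @export
sequential_cluster <- function(d, threshold,
                               spec = weighted_distance_spec(),
                               context = NULL) {
  stopifnot(inherits(d, "GeneDataset"), threshold > 0)
  if (is.null(context)) context <- distance_context(d)
  genes <- d$genes
  assignments <- cbind(genes, cluster = rep(NA_integer_, nrow(genes)))
  n_eval <- 0L
  next_id <- 0L
  for (ch in unique(genes$chromosome)) {
    idx <- which(genes$chromosome == ch)
    g <- genes[idx, , drop = FALSE]
    dist <- adjacent_weighted_distances(g, spec, context)
    n_eval <- n_eval + length(dist)
    breaks <- c(TRUE, dist >= threshold)        # strict "< T" joins
    local <- cumsum(breaks)
    assignments$cluster[idx] <- next_id + local
    next_id <- next_id + max(local)
  }
  assignments <- renumber_clusters(assignments)
  new_cluster_result(
    dataset = d$name, algorithm = "sequential",
    parameters = list(threshold = threshold, metric = spec$metric,
                      weights = spec$weights, eps = spec$eps),
    assignments = assignments, n_evaluations = n_eval)
}

#' Rule-of-thumb number of clusters
#'
#' `k = max(1, round(sqrt(n / 2)))` for a dataset of `n` genes; used by
#' [kmeans_cluster()] when `k = "auto"`.
#'
#' @param n number of genes (>= 1).
#' @return positive integer.
#' @export
mardia_k <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1) stop("need n >= 1")
  max(1L, as.integer(round(sqrt(n / 2))))
}

#' One-dimensional k-means clustering of gene positions
#'
#' Genes are embedded on the chromosome axis at the point the metric anchors
#' (start, promoter anchor or centre; the intragenic metric has no point
#' embedding and is rejected) and Lloyd iterations are run per chromosome.
#' Attribute weights do not apply against virtual centroid points, so
#' clustering is driven by the position embedding alone.
#'
#' Initialization: `"random"` draws k distinct gene positions; `"uniform"`
#' places k points evenly along the chromosome, whether or not genes sit
#' there; `"plusplus"` draws the first centroid uniformly from gene positions
#' and each further one from the remaining positions with probability
#' proportional to its squared distance to the closest chosen centroid.
#' An emptied cluster is re-seeded at the gene position farthest from its
#' nearest centroid.  All draws are deterministic given `seed`.
#'
#' @param d a `GeneDataset`.
#' @param k number of clusters per chromosome, or `"auto"` for
#'   [mardia_k()] of the chromosome's gene count.
#' @param spec a [weighted_distance_spec()]; only its metric anchor is used.
#' @param init `"random"`, `"uniform"` or `"plusplus"`.
#' @param max_iterations Lloyd iteration cap.
#' @param tolerance convergence threshold on the largest centroid movement
#'   (bp).
#' @param seed integer seed for the initialization draws.
#' @return a `ClusterResult`; `parameters$cost` holds the total
#'   within-cluster sum of squared anchor distances.
#' @export
kmeans_cluster <- function(d, k, spec = weighted_distance_spec(),
                           init = c("random", "uniform", "plusplus"),
                           max_iterations = 100L, tolerance = 1e-6,
                           seed = NULL) {
  init <- match.arg(init)
  stopifnot(inherits(d, "GeneDataset"), max_iterations >= 1)
  if (spec$metric == "intragenic")
    stop("k-means needs a point embedding; the intragenic metric has none")
  if (!identical(k, "auto")) stopifnot(k >= 1)
  genes <- d$genes
  if (nrow(genes) == 0L) stop("empty dataset")
  if (!is.null(seed)) set.seed(seed)
  assignments <- cbind(genes, cluster = rep(NA_integer_, nrow(genes)))
  total_cost <- 0
  k_used <- list()
  next_id <- 0L
  for (ch in unique(genes$chromosome)) {
    idx <- which(genes$chromosome == ch)
    pos <- metric_anchor(genes[idx, , drop = FALSE], spec$metric)
    k_ch <- if (identical(k, "auto")) mardia_k(length(pos)) else as.integer(k)
    if (k_ch > length(pos))
      stop(sprintf("k = %d exceeds the %d gene(s) on chromosome %s",
                   k_ch, length(pos), ch))
    chrom_len <- max(genes$end[idx])
    fit <- lloyd_1d(pos, k_ch, init, chrom_len, max_iterations, tolerance)
    assignments$cluster[idx] <- next_id + fit$assignment
    next_id <- next_id + k_ch
    total_cost <- total_cost + fit$cost
    k_used[[ch]] <- k_ch
  }
  assignments <- renumber_clusters(assignments)
  new_cluster_result(
    dataset = d$name, algorithm = "kmeans",
    parameters = list(k = k_used, init = init, metric = spec$metric,
                      seed = seed, cost = total_cost),
    assignments = assignments)
}

lloyd_1d <- function(pos, k, init, chrom_len, max_iterations, tolerance) {
  centroids <- switch(init,
    random = sample(pos, k),
    uniform = (seq_len(k) - 0.5) / k * chrom_len,
    plusplus = seed_plusplus(pos, k))
  assignment <- integer(length(pos))
  for (iter in seq_len(max_iterations)) {
    # nearest centroid; ties go to the lower centroid index
    dmat <- abs(outer(pos, centroids, "-"))
    assignment <- max.col(-dmat, ties.method = "first")
    updated <- centroids
    for (j in seq_len(k)) {
      members <- pos[assignment == j]
      if (length(members) > 0L) {
        updated[j] <- mean(members)
      } else {
        # deterministic empty-cluster repair: farthest point from its
        # nearest centroid (smallest position on ties)
        nearest <- apply(abs(outer(pos, updated, "-")), 1L, min)
        far <- which(nearest == max(nearest))
        updated[j] <- min(pos[far])
      }
    }
    moved <- max(abs(updated - centroids))
    centroids <- updated
    if (moved <= tolerance) break
  }
  dmat <- abs(outer(pos, centroids, "-"))
  assignment <- max.col(-dmat, ties.method = "first")
  cost <- sum((pos - centroids[assignment])^2)
  # relabel so cluster ids follow chromosome order of first occurrence
  relabel <- match(assignment, unique(assignment[order(pos, seq_along(pos))]))
  list(assignment = relabel, centroids = centroids, cost = cost,
       iterations = iter)
}

# k-means++ seeding: D^2-proportional draws over gene positions.
seed_plusplus <- function(pos, k) {
  centroids <- numeric(k)
  available <- seq_along(pos)
  pick <- available[sample.int(length(available), 1L)]
  centroids[1L] <- pos[pick]
  available <- available[available != pick]
  for (j in seq_len(k - 1L)) {
    d2 <- vapply(pos[available], function(p)
      min((p - centroids[seq_len(j)])^2), numeric(1))
    pick_i <- if (sum(d2) > 0) sample.int(length(available), 1L, prob = d2)
      else sample.int(length(available), 1L)
    centroids[j + 1L] <- pos[available[pick_i]]
    available <- available[-pick_i]
  }
  centroids
}

#' Max-gap clustering of orthology-bearing genes
#'
#' Step 1: dataset genes are restricted to those with at least one ortholog in
#' the comparison organism and taken in chromosome order.  Step 2: two such
#' genes belong to the same cluster iff the number of non-orthologous genes
#' between them — counted over the full background annotation of the
#' chromosome — is at most `maxgap`; the cluster relation is the transitive
#' closure over adjacent orthology-bearing genes.  Step 3: clusters with
#' fewer than `minsize` genes are discarded.
#'
#' @param d the `GeneDataset` to cluster.
#' @param map an [ortholog_map()] covering `d`'s organism and
#'   `comparison_organism`.
#' @param maxgap maximum number of intervening non-orthologous genes
#'   (>= 0).
#' @param minsize minimum surviving cluster size (>= 1).
#' @param background `GeneDataset` giving the full gene order used for gap
#'   counting (default: `d` itself, i.e. the dataset is the annotation).
#' @param comparison_organism the partner organism of the map (default: the
#'   map organism that is not `d`'s).
#' @return a `ClusterResult`; genes without orthologs or in discarded
#'   clusters have `NA` cluster.
#' @export
maxgap_cluster <- function(d, map, maxgap, minsize = 1L, background = d,
                           comparison_organism = NULL) {
  stopifnot(inherits(d, "GeneDataset"), inherits(map, "OrthologMap"),
            maxgap >= 0, minsize >= 1)
  side <- match(d$organism, map$organisms)
  if (is.na(side))
    stop("ortholog map does not cover organism ", d$organism)
  other <- map$organisms[3L - side]
  if (is.null(comparison_organism)) comparison_organism <- other
  if (!identical(comparison_organism, other))
    stop("ortholog map does not pair ", d$organism, " with ",
         comparison_organism)
  bg <- background$genes
  if (!all(d$genes$gene_id %in% bg$gene_id))
    stop("background annotation must contain every dataset gene")
  orth <- has_ortholog(map, bg$gene_id, organism = d$organism)
  member <- orth & bg$gene_id %in% d$genes$gene_id
  assignments <- cbind(d$genes, cluster = rep(NA_integer_, nrow(d$genes)))
  next_id <- 0L
  for (ch in unique(bg$chromosome)) {
    idx <- which(bg$chromosome == ch)
    non_orth_cum <- cumsum(!orth[idx])
    mem_i <- which(member[idx])
    if (length(mem_i) == 0L) next
    gaps <- if (length(mem_i) >= 2L)
      non_orth_cum[mem_i[-1L]] - non_orth_cum[mem_i[-length(mem_i)]]
    else integer(0)
    local <- cumsum(c(TRUE, gaps > maxgap))
    keep_sizes <- table(local)
    surviving <- as.integer(names(keep_sizes)[keep_sizes >= minsize])
    ids <- bg$gene_id[idx][mem_i]
    for (s in surviving) {
      next_id <- next_id + 1L
      in_cluster <- ids[local == s]
      assignments$cluster[assignments$gene_id %in% in_cluster] <- next_id
    }
  }
  assignments <- renumber_clusters(assignments)
  new_cluster_result(
    dataset = d$name, algorithm = "maxgap",
    parameters = list(maxgap = as.integer(maxgap),
                      minsize = as.integer(minsize),
                      comparison_organism = comparison_organism),
    assignments = assignments)
}
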