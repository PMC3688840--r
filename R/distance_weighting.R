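# Gene distance metrics and weighting strategies, composed into the single
# weighted-distance contract consumed by every clustering algorithm.
#
# All metrics are defined for genes on one chromosome only and are O(1),
# symmetric and non-negative.  Weights modulate the base distance
# multiplicatively: values < 1 shrink the effective distance (attribute
# similarity pulls genes together), values > 1 inflate it (dense
# neighbourhoods make the same bp gap count as farther).

DISTANCE_METRICS <- c("positional", "functional", "centre", "intragenic")

#' Clustering distance configuration
#'
#' Bundles a base metric with a set of weighting strategies and their
#' parameters; serializable, so a clustering run is fully reproducible from
#' configuration plus inputs.
#'
#' @param metric `"positional"` (start-to-start, the default), `"functional"`
#'   (promoter-anchor to promoter-anchor), `"centre"` (centre-to-centre) or
#'   `"intragenic"` (gap between gene bodies, 0 for overlapping genes).
#' @param weights character vector, a subset of `"uniform"`, `"density"`,
#'   `"expression"`, `"tf"` and `"plugin:<name>"` entries; `"uniform"`
#'   contributes a factor of 1 and may be combined with (or replaced by) the
#'   others.  Factors compose by multiplication.
#' @param eps weight floor in `(0, 1]`; similarity weights never drop below
#'   it, so weighted distances keep their positional character and never
#'   collapse to 0 for distinct loci.
#' @param density_window window width W (bp) of the local gene-density
#'   estimate.
#' @param density_step step (bp) between evaluation points of a rendered
#'   density profile (the weight itself evaluates density exactly at the
#'   inter-gene midpoint).
#' @param expression_mode `"anova"` (one-way ANOVA on the two genes'
#'   replicate values; weight = `max(eps, 1 - p)`) or `"custom"`
#'   (normalized absolute difference of scalarized expressions).
#' @param expression_conditions conditions used by the expression weight
#'   (default: all attached).
#' @param reducer scalarizer for `expression_mode = "custom"`.
#' @param delta guard constant of the custom expression weight.
#' @return a `WeightedDistanceSpec`.
#' @export
weighted_distance_spec <- function(metric = "positional",
                                   weights = "uniform",
                                   eps = 0.01,
                                   density_window = 1e5,
                                   density_step = 1e4,
                                   expression_mode = c("anova", "custom"),
                                   expression_conditions = NULL,
                                   reducer = "mean",
                                   delta = 1e-9) {
  metric <- match.arg(metric, DISTANCE_METRICS)
  expression_mode <- match.arg(expression_mode)
  stopifnot(eps > 0, eps <= 1, density_window > 0, density_step > 0)
  known <- c("uniform", "density", "expression", "tf")
  bad <- weights[!(weights %in% known | startsWith(weights, "plugin:"))]
  if (length(bad) > 0L)
    stop("unknown weighting strategy: ", paste(bad, collapse = ", "))
  structure(list(metric = metric, weights = unique(weights), eps = eps,
                 density_window = density_window, density_step = density_step,
                 expression_mode = expression_mode,
                 expression_conditions = expression_conditions,
                 reducer = reducer, delta = delta),
            class = "WeightedDistanceSpec")
}

#' Distance between two genes
#'
#' @param g1,g2 single gene records (1-row data.frames with the standard gene
#'   columns) on the same chromosome.
#' @param metric one of the four base metrics (see
#'   [weighted_distance_spec()]).
#' @return distance in bp (real-valued for the centre metric).
#' @export
gene_distance <- function(g1, g2, metric = "positional") {
  metric <- match.arg(metric, DISTANCE_METRICS)
  if (!identical(g1$chromosome, g2$chromosome))
    stop("gene distance is undefined across chromosomes (",
         g1$chromosome, " vs ", g2$chromosome, ")")
  pair_distance(g1$start, g1$end, g1$strand, g2$start, g2$end, g2$strand,
                metric)
}

# Vectorized core shared by gene_distance and the clustering scan.
pair_distance <- function(s1, e1, st1, s2, e2, st2, metric) {
  switch(metric,
         positional = abs(s1 - s2),
         functional = abs(ifelse(st1 > 0, s1, e1) - ifelse(st2 > 0, s2, e2)),
         centre = abs((s1 + e1) - (s2 + e2)) / 2,
         intragenic = {
           lo_end <- ifelse(s1 <= s2, e1, e2)
           hi_start <- pmax(s1, s2)
           pmax(0, hi_start - lo_end)
         })
}

# Anchor coordinate used when a metric needs a point embedding (k-means,
# density midpoints).  The intragenic metric has no point embedding.
metric_anchor <- function(genes, metric) {
  switch(metric,
         positional = genes$start,
         functional = promoter_anchor(genes),
         centre = gene_centre(genes),
         intragenic = stop("the intragenic metric has no point embedding"))
}

## ---- density ---------------------------------------------------------------

#' Evaluation context for weighted distances
#'
#' Precomputes what the weighting strategies need: per-chromosome gene start
#' positions (for local density) and the genome-wide mean density
#' (total genes / total chromosome length).
#'
#' @param d the `GeneDataset` being clustered.
#' @param chromosome_lengths optional named vector of chromosome lengths (bp);
#'   missing lengths are inferred as the maximum gene end.
#' @return a `DistanceContext`.
#' @export
distance_context <- function(d, chromosome_lengths = NULL) {
  stopifnot(inherits(d, "GeneDataset"))
  chroms <- unique(d$genes$chromosome)
  starts <- split(d$genes$start, d$genes$chromosome)
  lens <- vapply(chroms, function(ch) {
    if (!is.null(chromosome_lengths) && ch %in% names(chromosome_lengths))
      as.numeric(chromosome_lengths[[ch]])
    else max(d$genes$end[d$genes$chromosome == ch])
  }, numeric(1))
  names(lens) <- chroms
  rho_bar <- if (nrow(d$genes) > 0L) nrow(d$genes) / sum(lens) else NA_real_
  structure(list(dataset = d, starts = starts, chromosome_lengths = lens,
                 rho_bar = rho_bar),
            class = "DistanceContext")
}

#' Local gene density at a position
#'
#' Number of gene starts within the window `[x - W/2, x + W/2]`, per bp.
#'
#' @param context a `DistanceContext` (or `ChromosomeLayout`).
#' @param chromosome chromosome name.
#' @param x positions (bp) at which to evaluate.
#' @param window window width W in bp.
#' @return numeric vector of densities (genes/bp).
#' @export
local_density <- function(context, chromosome, x, window) {
  starts <- if (inherits(context, "ChromosomeLayout")) context$genes$start
    else context$starts[[chromosome]]
  if (is.null(starts)) starts <- numeric(0)
  starts <- sort(starts)
  half <- window / 2
  counts <- findInterval(x + half, starts) -
    findInterval(x - half, starts, left.open = TRUE)
  counts / window
}

#' Gene density profile along a chromosome
#'
#' @param layout a `ChromosomeLayout`.
#' @param window window width W in bp.
#' @param step distance between evaluation points in bp.
#' @return a `DensityProfile`: data.frame-backed list with evaluation
#'   `position`s, `density` values (genes/bp) and the chromosome mean density.
#' @export
density_profile <- function(layout, window = 1e5, step = 1e4) {
  stopifnot(inherits(layout, "ChromosomeLayout"), window > 0, step > 0)
  len <- max(layout$length, 1)
  positions <- seq(1, len, by = step)
  dens <- local_density(layout, layout$chromosome, positions, window)
  structure(list(chromosome = layout$chromosome, window = window, step = step,
                 position = positions, density = dens,
                 mean_density = nrow(layout$genes) / len),
            class = "DensityProfile")
}

## ---- weight plug-ins -------------------------------------------------------

.weight_plugins <- new.env(parent = emptyenv())

#' Register a user-defined weighting function
#'
#' The function receives `(g1, g2, context)` — two 1-row gene records and the
#' `DistanceContext` — and must return a single factor in `(0, 1]`; values
#' outside are clamped with a warning.  Registered plug-ins are referenced in
#' a [weighted_distance_spec()] as `"plugin:<name>"`.
#'
#' @param name unique plug-in name.
#' @param fn the weighting function.
#' @return the name, invisibly.
#' @export
register_weight_plugin <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  if (exists(name, envir = .weight_plugins, inherits = FALSE))
    stop("a weight plugin named '", name, "' is already registered")
  assign(name, fn, envir = .weight_plugins)
  invisible(name)
}

#' Remove a registered weight plug-in
#' @param name plug-in name (unknown names are ignored).
#' @return `TRUE` if a plug-in was removed.
#' @export
unregister_weight_plugin <- function(name) {
  if (exists(name, envir = .weight_plugins, inherits = FALSE)) {
    rm(list = name, envir = .weight_plugins)
    return(invisible(TRUE))
  }
  invisible(FALSE)
}

#' Names of registered weight plug-ins
#' @return character vector.
#' @export
weight_plugins <- function() sort(ls(envir = .weight_plugins))

get_weight_plugin <- function(name) {
  if (!exists(name, envir = .weight_plugins, inherits = FALSE))
    stop("unknown weight plugin: ", name)
  get(name, envir = .weight_plugins)
}

## ---- weights ---------------------------------------------------------------

#' Weighting factor for a gene pair under one strategy
#'
#' Strategies:
#' * `uniform` — 1.
#' * `density` — local density at the inter-gene midpoint relative to the
#'   genome-wide mean, clamped to `[eps, 1/eps]`; pairs in gene-dense regions
#'   get factors > 1 (inflated effective distance), pairs in deserts < 1.
#' * `expression` — with mode `"anova"`, `max(eps, 1 - p)` where `p` is the
#'   one-way ANOVA p-value for equality of the two genes' replicate means
#'   (each gene needs >= 2 non-missing values); with mode `"custom"`,
#'   `max(eps, |e1 - e2| / (|e1| + |e2| + delta))` on scalarized expressions,
#'   usable with a single value per gene.
#' * `tf` — `max(eps, 1 - J)` where `J` is the Jaccard index of the two TF
#'   name sets; two empty repertoires give 1 (no evidence of similarity).
#' * `plugin:<name>` — a registered plug-in, clamped into `(0, 1]`.
#'
#' @param g1,g2 1-row gene records.
#' @param strategy strategy name as in [weighted_distance_spec()] `weights`.
#' @param spec a `WeightedDistanceSpec` (supplies `eps` and parameters).
#' @param context a [distance_context()] built from the dataset carrying the
#'   needed attachments.
#' @return a single positive factor.
#' @export
compute_weight <- function(g1, g2, strategy, spec, context) {
  eps <- spec$eps
  if (strategy == "uniform") return(1)
  if (strategy == "density") {
    mid <- (metric_anchor(g1, spec$metric) + metric_anchor(g2, spec$metric)) / 2
    rho <- local_density(context, g1$chromosome, mid, spec$density_window)
    if (!is.finite(context$rho_bar) || context$rho_bar <= 0) return(1)
    return(min(max(rho / context$rho_bar, eps), 1 / eps))
  }
  if (strategy == "expression") {
    d <- context$dataset
    if (is.null(d$expression)) stop("expression weight needs an expression table")
    conditions <- spec$expression_conditions
    if (is.null(conditions)) conditions <- colnames(d$expression)
    v1 <- expression_values(d, g1$gene_id, conditions)
    v2 <- expression_values(d, g2$gene_id, conditions)
    v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
    if (spec$expression_mode == "anova") {
      if (length(v1) < 2L || length(v2) < 2L)
        stop("ANOVA expression weight needs >= 2 values per gene")
      p <- anova_pvalue(v1, v2)
      return(max(eps, 1 - p))
    }
    if (length(v1) == 0L || length(v2) == 0L)
      stop("custom expression weight needs >= 1 value per gene")
    e1 <- scalarize(v1, spec$reducer); e2 <- scalarize(v2, spec$reducer)
    return(max(eps, abs(e1 - e2) / (abs(e1) + abs(e2) + spec$delta)))
  }
  if (strategy == "tf") {
    d <- context$dataset
    if (is.null(d$tf)) stop("tf weight needs a TF annotation")
    t1 <- names(tf_of_gene(d, g1$gene_id))
    t2 <- names(tf_of_gene(d, g2$gene_id))
    if (length(t1) == 0L && length(t2) == 0L) return(1)
    jaccard <- length(intersect(t1, t2)) / length(union(t1, t2))
    return(max(eps, 1 - jaccard))
  }
  if (startsWith(strategy, "plugin:")) {
    fn <- get_weight_plugin(sub("^plugin:", "", strategy))
    w <- fn(g1, g2, context)
    if (!is.finite(w) || w <= 0 || w > 1) {
      warning("plugin weight ", format(w), " outside (0, 1]; clamped")
      w <- min(max(w, spec$eps), 1)
    }
    return(w)
  }
  stop("unknown weighting strategy: ", strategy)
}

scalarize <- function(v, reducer) {
  switch(reducer, mean = mean(v), median = median(v), min = min(v),
         max = max(v), sum = sum(v),
         stop("unknown reducer: ", reducer))
}

# One-way ANOVA p-value with the two genes as groups and their replicate
# expression values as observations.  Zero between-group variance gives p = 1
# by convention; zero within-group variance with distinct means gives p = 0.
anova_pvalue <- function(v1, v2) {
  n1 <- length(v1); n2 <- length(v2); n <- n1 + n2
  grand <- mean(c(v1, v2))
  ss_between <- n1 * (mean(v1) - grand)^2 + n2 * (mean(v2) - grand)^2
  ss_within <- sum((v1 - mean(v1))^2) + sum((v2 - mean(v2))^2)
  if (ss_between <= .Machine$double.eps * max(1, ss_within)) return(1)
  if (ss_within <= 0) return(0)
  f <- (ss_between / 1) / (ss_within / (n - 2))
  stats::pf(f, 1, n - 2, lower.tail = FALSE)
}

#' Weighted distance between two genes
#'
#' Base metric distance multiplied by every active weighting factor.
#'
#' @param g1,g2 1-row gene records on one chromosome.
#' @param spec a `WeightedDistanceSpec`.
#' @param context a [distance_context()]; built on the fly from `dataset`
#'   when omitted.
#' @param dataset the `GeneDataset` (used only to build a default context).
#' @return weighted distance (bp x dimensionless factors).
#' @export
weighted_distance <- function(g1, g2, spec, context = NULL, dataset = NULL) {
  stopifnot(inherits(spec, "WeightedDistanceSpec"))
  if (is.null(context)) {
    if (is.null(dataset)) stop("need a context or a dataset")
    context <- distance_context(dataset)
  }
  base <- gene_distance(g1, g2, spec$metric)
  for (s in spec$weights) base <- base * compute_weight(g1, g2, s, spec, context)
  base
}

# Weighted distances between consecutive genes of one chromosome (the only
# pairs the sequential scan evaluates).  Vectorized for the pure-positional
# case; attribute weights fall back to a per-pair loop.
adjacent_weighted_distances <- function(genes, spec, context) {
  n <- nrow(genes)
  if (n < 2L) return(numeric(0))
  i <- seq_len(n - 1L); j <- i + 1L
  base <- pair_distance(genes$start[i], genes$end[i], genes$strand[i],
                        genes$start[j], genes$end[j], genes$strand[j],
                        spec$metric)
  active <- setdiff(spec$weights, "uniform")
  if (length(active) == 0L) return(base)
  for (k in i) {
    g1 <- genes[k, , drop = FALSE]; g2 <- genes[k + 1L, , drop = FALSE]
    for (s in active)
      base[k] <- base[k] * compute_weight(g1, g2, s, spec, context)
  }
  base
}
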