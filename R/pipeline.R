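# Config-driven pipeline: import -> filter -> cluster -> stats -> report.
# The command-line wrapper in inst/cli/geneclust.R is a thin shell over
# run_pipeline(); identical config + inputs + seed give byte-identical
# reports.

config_error <- function(...) {
  stop(structure(class = c("geneclust_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

KNOWN_CONFIG_KEYS <- c("name", "seed", "organism", "annotation", "expression",
                       "tf_annotation", "ortholog_map", "gene_list", "filter",
                       "distance", "clustering", "stats", "output_dir")

validate_config <- function(config) {
  if (!is.list(config)) config_error("config must be a mapping")
  unknown <- setdiff(names(config), KNOWN_CONFIG_KEYS)
  if (length(unknown) > 0L)
    config_error("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$annotation) || is.null(config$annotation$path))
    config_error("config needs annotation: {path, dialect}")
  if (is.null(config$clustering) || is.null(config$clustering$algorithm))
    config_error("config needs clustering: {algorithm, ...}")
  alg <- config$clustering$algorithm
  if (!alg %in% c("sequential", "kmeans", "maxgap"))
    config_error("unknown clustering algorithm: ", alg)
  if (alg == "sequential") {
    t <- config$clustering$threshold_bp
    if (is.null(t) || !is.numeric(t) || t <= 0)
      config_error("sequential clustering needs threshold_bp > 0")
  }
  if (alg == "kmeans") {
    k <- config$clustering$k
    if (is.null(k) || (!identical(k, "auto") && (!is.numeric(k) || k < 1)))
      config_error("kmeans needs k >= 1 or k: auto")
  }
  if (alg == "maxgap") {
    if (is.null(config$clustering$maxgap) || config$clustering$maxgap < 0)
      config_error("maxgap clustering needs maxgap >= 0")
    if (is.null(config$ortholog_map))
      config_error("maxgap clustering needs an ortholog_map input")
  }
  invisible(config)
}

build_spec <- function(config) {
  dist <- config$distance
  if (is.null(dist)) return(weighted_distance_spec())
  args <- list(metric = dist$metric %||% "positional",
               weights = unlist(dist$weights) %||% "uniform")
  for (key in c("eps", "density_window", "density_step", "expression_mode",
                "reducer", "delta"))
    if (!is.null(dist[[key]])) args[[key]] <- dist[[key]]
  if (!is.null(dist$expression_conditions))
    args$expression_conditions <- unlist(dist$expression_conditions)
  do.call(weighted_distance_spec, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline from a configuration
#'
#' Stages, in order: import of the annotation and optional attachments;
#' optional expression filtering; positional clustering under the configured
#' weighted distance; optional significance statistics; report writing.
#' Reports (cluster TSV + JSON, summary JSON, stats JSON, run manifest) are
#' written to `output_dir`.
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list.  See the package vignette for the schema.
#' @param output_dir overrides the config's `output_dir`.
#' @param seed overrides the config's `seed`.
#' @return (invisibly) a list with the clustered dataset, the
#'   `ClusterResult`, its `ClusterSummary`, any stat reports, and the paths
#'   written.
#' @export
run_pipeline <- function(config, output_dir = NULL, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) config_error("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  validate_config(config)
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(output_dir)) config$output_dir <- output_dir
  if (is.null(config$output_dir)) config_error("config needs output_dir")
  run_seed <- as.integer(config$seed %||% 1L)

  ## import
  ann <- config$annotation
  d <- read_gene_annotation(ann$path, dialect = ann$dialect %||% "tsv",
                            organism = config$organism %||% "unknown",
                            name = config$name %||% "dataset")
  if (!is.null(config$expression))
    d <- attach_expression(d, read_expression_csv(config$expression))
  if (!is.null(config$tf_annotation))
    d <- attach_tf(d, read_tf_annotation(config$tf_annotation))
  map <- NULL
  if (!is.null(config$ortholog_map)) {
    om <- config$ortholog_map
    map <- read_ortholog_map(om$path, om$organism_a %||% d$organism,
                             om$organism_b %||% "comparison")
  }
  if (!is.null(config$gene_list)) {
    wanted <- utils::read.csv(config$gene_list, header = FALSE,
                              colClasses = "character")[[1L]]
    unresolved <- setdiff(wanted, d$genes$gene_id)
    d <- subset_genes(d, wanted, name = d$name)
    d$unresolved <- unresolved
    if (length(unresolved) > 0L)
      message(length(unresolved), " gene id(s) not found in the annotation")
  }

  ## filter
  if (!is.null(config$filter)) {
    f <- config$filter
    filt <- expression_filter(f$clauses, combine = f$combine %||% "and",
                              missing_policy = f$missing_policy %||% "fail")
    d <- filter_by_expression(d, filt)
  }

  ## cluster
  spec <- build_spec(config)
  cl_cfg <- config$clustering
  result <- switch(cl_cfg$algorithm,
    sequential = sequential_cluster(d, threshold = cl_cfg$threshold_bp,
                                    spec = spec),
    kmeans = kmeans_cluster(d, k = cl_cfg$k, spec = spec,
                            init = cl_cfg$init %||% "plusplus",
                            seed = run_seed),
    maxgap = maxgap_cluster(d, map, maxgap = cl_cfg$maxgap,
                            minsize = cl_cfg$minsize %||% 1L,
                            comparison_organism = cl_cfg$comparison_organism))
  summary <- cluster_summary(result)

  ## stats
  stat_reports <- list()
  if (!is.null(config$stats)) {
    st <- config$stats
    if (!is.null(st$random_set)) {
      pool <- read_gene_annotation(st$random_set$pool,
                                   dialect = st$random_set$dialect %||% "tsv",
                                   organism = d$organism, name = "pool")
      cluster_fn <- function(x) switch(cl_cfg$algorithm,
        sequential = sequential_cluster(x, threshold = cl_cfg$threshold_bp,
                                        spec = spec),
        kmeans = kmeans_cluster(x, k = cl_cfg$k, spec = spec,
                                init = cl_cfg$init %||% "plusplus"),
        maxgap = maxgap_cluster(x, map, maxgap = cl_cfg$maxgap,
                                minsize = cl_cfg$minsize %||% 1L))
      stat_reports$random_set <- random_set_comparison(
        d, pool, cluster_fn, reps = st$random_set$reps %||% 100L,
        seed = run_seed)
    }
    if (isTRUE(st$neighbourhood)) {
      bg_path <- st$neighbourhood_background
      bg <- if (!is.null(bg_path))
        read_gene_annotation(bg_path, organism = d$organism, name = "background")
      else d
      stat_reports$neighbourhood <- neighbourhood_model(d, bg)
    }
    if (!is.null(st$tf_pairs)) {
      stat_reports$tf_pairs <- lapply(st$tf_pairs, function(pair) {
        pair <- unlist(pair)
        tf_cooccurrence(result, d, pair[1L], pair[2L])
      })
    }
  }

  ## report
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(clusters_tsv = file.path(out_dir, "clusters.tsv"),
             clusters_json = file.path(out_dir, "clusters.json"),
             summary_json = file.path(out_dir, "summary.json"),
             manifest_json = file.path(out_dir, "manifest.json"))
  write_cluster_report(result, paths[["clusters_tsv"]], "tsv")
  write_cluster_report(result, paths[["clusters_json"]], "json")
  write_json_report(unclass(summary), paths[["summary_json"]])
  if (length(stat_reports) > 0L) {
    paths[["stats_json"]] <- file.path(out_dir, "stats.json")
    write_json_report(serialize_stats(stat_reports), paths[["stats_json"]])
  }
  config_echo <- config
  config_echo$output_dir <- NULL   # reports stay byte-identical across out dirs
  manifest <- list(tool = "geneclust",
                   version = as.character(utils::packageVersion("geneclust")),
                   seed = run_seed, config = config_echo)
  write_json_report(manifest, paths[["manifest_json"]])
  invisible(list(dataset = d, result = result, summary = summary,
                 stats = stat_reports, paths = paths))
}

write_json_report <- function(x, path) {
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null", pretty = TRUE,
                              force = TRUE),
             path, sep = "\n")
  invisible(path)
}

serialize_stats <- function(stat_reports) {
  lapply(stat_reports, function(x) {
    if (inherits(x, "StatReport")) return(unclass(x))
    if (inherits(x, "NeighbourhoodReport")) return(as.data.frame(x))
    if (is.list(x)) return(lapply(x, serialize_stats_item))
    x
  })
}

serialize_stats_item <- function(x) {
  if (inherits(x, "StatReport")) return(unclass(x))
  if (is.list(x) && !is.null(x$report))
    return(list(table = x$table, marginal = as.list(x$marginal),
                report = unclass(x$report)))
  x
}
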