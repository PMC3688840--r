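# Readers and writers for the file-backed inputs: gene annotation (TSV /
# BED / GFF3), expression CSV, TF annotation TSV, ortholog TSV, plus cluster
# reports and whole-project persistence as JSON.  BED and GFF3 parsing is
# delegated to rtracklayer; the plain TSV dialect is parsed directly so that
# malformed rows can be reported with their line number.

#' Read a gene annotation table
#'
#' @param path input file.
#' @param dialect one of `"tsv"` (tab-separated with header columns
#'   `gene_id`, `chromosome`, `start`, `end`, `strand`; 1-based inclusive
#'   coordinates), `"bed"` (0-based half-open, converted on read; the BED
#'   `name` field is the gene id) or `"gff3"` (1-based inclusive; only rows of
#'   type `gene` are used, the id taken from the `ID` attribute, stripped of a
#'   `gene:` prefix).
#' @param organism organism label for the resulting dataset.
#' @param name dataset name (default: file base name).
#' @return a `GeneDataset`.  Records with unknown strand are dropped; their
#'   number is available as `attr(x, "n_rejected")` and a warning is emitted.
#' @export
read_gene_annotation <- function(path, dialect = c("tsv", "bed", "gff3"),
                                 organism = "unknown",
                                 name = sub("\\.[^.]*$", "", basename(path))) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  genes <- switch(dialect,
                  tsv = read_annotation_tsv(path),
                  bed = read_annotation_ranges(path, "bed"),
                  gff3 = read_annotation_ranges(path, "gff3"))
  n_rejected <- sum(is.na(genes$strand))
  if (n_rejected > 0L) {
    warning(sprintf("%d record(s) with unknown strand dropped from %s",
                    n_rejected, path))
    genes <- genes[!is.na(genes$strand), , drop = FALSE]
  }
  d <- gene_dataset(genes, name = name, organism = organism)
  attr(d, "n_rejected") <- n_rejected
  d
}

read_annotation_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(gene_id = character(), chromosome = character(),
                      start = numeric(), end = numeric(), strand = integer())
  if (length(lines) == 0L) return(empty)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  need <- c("gene_id", "chromosome", "start", "end", "strand")
  idx <- match(need, header)
  if (anyNA(idx))
    stop("TSV annotation header lacks column(s): ",
         paste(need[is.na(idx)], collapse = ", "))
  if (length(lines) == 1L) return(empty)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  for (i in seq_along(rows)) {
    line_no <- i + 1L
    f <- rows[[i]]
    if (length(f) < length(header))
      stop(sprintf("malformed annotation row at line %d of %s", line_no, path))
    start <- suppressWarnings(as.numeric(f[idx[3L]]))
    end <- suppressWarnings(as.numeric(f[idx[4L]]))
    if (is.na(start) || is.na(end) || start < 1 || end < start)
      stop(sprintf("invalid coordinates at line %d of %s", line_no, path))
  }
  m <- do.call(rbind, rows)
  data.frame(gene_id = m[, idx[1L]], chromosome = m[, idx[2L]],
             start = as.numeric(m[, idx[3L]]), end = as.numeric(m[, idx[4L]]),
             strand = normalize_strand(m[, idx[5L]]))
}

read_annotation_ranges <- function(path, format) {
  if (file.size(path) == 0L)
    return(data.frame(gene_id = character(), chromosome = character(),
                      start = numeric(), end = numeric(), strand = integer()))
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3") {
    keep <- !is.na(gr$type) & as.character(gr$type) == "gene"
    gr <- gr[keep]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
    ids <- sub("^gene:", "", ids)
  } else {
    ids <- if (!is.null(gr$name)) as.character(gr$name) else
      paste0("gene_", seq_along(gr))
  }
  strand_chr <- as.character(BiocGenerics::strand(gr))
  data.frame(gene_id = ids,
             chromosome = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr),
             end = BiocGenerics::end(gr),
             strand = ifelse(strand_chr == "+", 1L,
                             ifelse(strand_chr == "-", -1L, NA_integer_)))
}

#' Read an expression table from CSV
#'
#' First column: gene id; header row: condition names.  Blank or `NA` cells
#' become the explicit missing state.
#'
#' @param path CSV file.
#' @return numeric matrix (genes x conditions) with gene ids as rownames.
#' @export
read_expression_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop("expression CSV needs gene_id plus >=1 condition")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicated gene_id in expression table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  conditions <- colnames(raw)[-1L]
  m <- matrix(NA_real_, nrow = nrow(raw), ncol = length(conditions),
              dimnames = list(ids, conditions))
  for (j in seq_along(conditions)) {
    cells <- trimws(raw[[j + 1L]])
    blank <- !nzchar(cells) | toupper(cells) %in% c("NA", "NAN")
    vals <- suppressWarnings(as.numeric(cells))
    bad <- which(!blank & is.na(vals))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric expression value '%s' (gene %s, condition %s)",
                   cells[bad[1L]], ids[bad[1L]], conditions[j]))
    vals[blank] <- NA_real_
    m[, j] <- vals
  }
  m
}

#' Read a TF binding-site annotation table
#'
#' Tab-separated columns `gene_id`, `tf_name` and optionally `count`
#' (default 1).  Counts for repeated (gene, TF) rows are summed; the result is
#' order-independent.
#'
#' @param path TSV file (header row required).
#' @return named list: gene id -> named numeric vector of site counts per TF.
#' @export
read_tf_annotation <- function(path) {
  if (file.size(path) == 0L) return(structure(list(), names = character()))
  tab <- read.delim(path, colClasses = "character")
  if (nrow(tab) == 0L) return(structure(list(), names = character()))
  if (!all(c("gene_id", "tf_name") %in% names(tab)))
    stop("TF annotation needs columns gene_id, tf_name")
  counts <- if ("count" %in% names(tab)) as.numeric(tab$count) else
    rep(1, nrow(tab))
  if (anyNA(counts)) stop("non-numeric TF site count")
  if (any(counts < 0)) stop("negative TF site count")
  agg <- aggregate(counts, by = list(gene_id = tab$gene_id,
                                     tf_name = tab$tf_name), FUN = sum)
  split_idx <- split(seq_len(nrow(agg)), agg$gene_id)
  lapply(split_idx, function(i) {
    v <- setNames(agg$x[i], agg$tf_name[i])
    v[order(names(v))]
  })
}

#' Read a two-genome ortholog map
#'
#' Tab-separated pairs (gene in organism A, gene in organism B); a gene may
#' appear in several pairs (many-to-many orthology is kept as-is).
#'
#' @param path TSV file with two columns (header optional; a header row is
#'   detected when the first line matches `gene_a`/`gene_b`).
#' @param organism_a,organism_b organism labels of the two columns.
#' @return an `OrthologMap`: list with `organisms` and the `pairs` table.
#' @export
read_ortholog_map <- function(path, organism_a = "A", organism_b = "B") {
  empty <- data.frame(gene_a = character(), gene_b = character())
  if (file.size(path) == 0L) {
    tab <- empty
  } else {
    first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
    has_header <- identical(tolower(first[1:2]), c("gene_a", "gene_b"))
    tab <- read.delim(path, header = has_header, colClasses = "character")
    if (ncol(tab) < 2L) stop("ortholog map needs two columns")
    tab <- data.frame(gene_a = tab[[1L]], gene_b = tab[[2L]])
  }
  ortholog_map(tab, organism_a, organism_b)
}

#' Construct an ortholog map from a pair table
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param organism_a,organism_b organism labels.
#' @return an `OrthologMap`.
#' @export
ortholog_map <- function(pairs, organism_a = "A", organism_b = "B") {
  stopifnot(is.data.frame(pairs), all(c("gene_a", "gene_b") %in% names(pairs)))
  pairs <- data.frame(gene_a = as.character(pairs$gene_a),
                      gene_b = as.character(pairs$gene_b))
  pairs <- unique(pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE])
  rownames(pairs) <- NULL
  structure(list(organisms = c(organism_a, organism_b), pairs = pairs),
            class = "OrthologMap")
}

#' Which genes have at least one ortholog?
#' @param map an `OrthologMap`.
#' @param ids gene ids to look up.
#' @param organism which side of the map the ids belong to.
#' @return logical vector parallel to `ids`.
#' @export
has_ortholog <- function(map, ids, organism = map$organisms[1L]) {
  stopifnot(inherits(map, "OrthologMap"))
  side <- match(organism, map$organisms)
  if (is.na(side)) stop("organism not covered by this ortholog map: ", organism)
  known <- if (side == 1L) map$pairs$gene_a else map$pairs$gene_b
  ids %in% known
}

#' Ortholog partners of one gene
#' @param map an `OrthologMap`.
#' @param id gene id.
#' @param organism side of the map the id belongs to.
#' @return character vector of partner gene ids (possibly empty).
#' @export
ortholog_partners <- function(map, id, organism = map$organisms[1L]) {
  stopifnot(inherits(map, "OrthologMap"))
  side <- match(organism, map$organisms)
  if (is.na(side)) stop("organism not covered by this ortholog map: ", organism)
  if (side == 1L) map$pairs$gene_b[map$pairs$gene_a == id]
  else map$pairs$gene_a[map$pairs$gene_b == id]
}

## ---- cluster reports -------------------------------------------------------

#' Write a cluster report
#'
#' TSV: one row per assigned gene with its cluster id and coordinates.
#' JSON: full result (parameters, assignments, summary) that round-trips
#' through [read_cluster_report()].  Output is byte-deterministic for a fixed
#' result.
#'
#' @param result a `ClusterResult`.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(result, "ClusterResult"))
  if (format == "tsv") {
    a <- result$assignments
    a <- a[!is.na(a$cluster), , drop = FALSE]
    out <- data.frame(cluster = a$cluster, gene_id = a$gene_id,
                      chromosome = a$chromosome, start = a$start, end = a$end)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(colnames(out), collapse = "\t"), con, sep = "\n")
    if (nrow(out) > 0L)
      writeLines(do.call(paste, c(lapply(out, as.character), sep = "\t")),
                 con, sep = "\n")
  } else {
    json <- jsonlite::toJSON(cluster_result_to_list(result),
                             auto_unbox = TRUE, digits = NA, null = "null",
                             na = "null", pretty = TRUE)
    writeLines(json, path, sep = "\n")
  }
  invisible(path)
}

#' Read a JSON cluster report back into a `ClusterResult`
#' @param path JSON file written by [write_cluster_report()].
#' @return a `ClusterResult`.
#' @export
read_cluster_report <- function(path) {
  cluster_result_from_list(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

cluster_result_to_list <- function(r) {
  a <- r$assignments
  list(dataset = r$dataset, algorithm = r$algorithm,
       parameters = r$parameters,
       assignments = list(gene_id = a$gene_id, chromosome = a$chromosome,
                          start = a$start, end = a$end, strand = a$strand,
                          cluster = a$cluster),
       n_evaluations = r$n_evaluations)
}

cluster_result_from_list <- function(x) {
  a <- x$assignments
  assignments <- data.frame(gene_id = as.character(a$gene_id),
                            chromosome = as.character(a$chromosome),
                            start = as.numeric(a$start),
                            end = as.numeric(a$end),
                            strand = as.integer(a$strand),
                            cluster = as.integer(a$cluster))
  params <- x$parameters
  new_cluster_result(dataset = x$dataset, algorithm = x$algorithm,
                     parameters = params, assignments = assignments,
                     n_evaluations = x$n_evaluations)
}

## ---- project persistence ---------------------------------------------------

#' Create a project container
#'
#' A project bundles datasets, ortholog maps, stored clustering results and a
#' registry of named random seeds, and persists losslessly as JSON.
#'
#' @param datasets named list of `GeneDataset`s.
#' @param ortholog_maps list of `OrthologMap`s.
#' @param results list of `ClusterResult`s.
#' @param seeds named list of integer seeds used in the session.
#' @return a `ProjectState`.
#' @export
project_state <- function(datasets = list(), ortholog_maps = list(),
                          results = list(), seeds = list()) {
  if (length(datasets) > 0L && is.null(names(datasets)))
    names(datasets) <- vapply(datasets, function(d) d$name, character(1))
  structure(list(datasets = datasets, ortholog_maps = ortholog_maps,
                 results = results, seeds = seeds),
            class = "ProjectState")
}

dataset_to_list <- function(d) {
  g <- d$genes
  out <- list(name = d$name, organism = d$organism,
              genes = list(gene_id = g$gene_id, chromosome = g$chromosome,
                           start = g$start, end = g$end, strand = g$strand),
              unresolved = d$unresolved)
  if (!is.null(d$expression))
    out$expression <- list(gene_id = rownames(d$expression),
                           conditions = colnames(d$expression),
                           values = unname(apply(d$expression, 1L, identity,
                                                 simplify = FALSE)))
  if (!is.null(d$tf)) out$tf <- lapply(d$tf, as.list)
  out
}

dataset_from_list <- function(x) {
  genes <- data.frame(gene_id = as.character(x$genes$gene_id),
                      chromosome = as.character(x$genes$chromosome),
                      start = as.numeric(x$genes$start),
                      end = as.numeric(x$genes$end),
                      strand = as.integer(x$genes$strand))
  expression <- NULL
  if (!is.null(x$expression)) {
    vals <- x$expression$values
    if (is.list(vals)) vals <- do.call(rbind, lapply(vals, as.numeric))
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
    expression <- matrix(as.numeric(vals), nrow = length(x$expression$gene_id),
                         dimnames = list(as.character(x$expression$gene_id),
                                         as.character(x$expression$conditions)))
  }
  tf <- NULL
  if (!is.null(x$tf))
    tf <- lapply(x$tf, function(v) {
      v <- unlist(v)
      if (is.null(v)) return(setNames(numeric(0), character(0)))
      v[order(names(v))]
    })
  gene_dataset(genes, name = x$name, organism = x$organism,
               expression = expression, tf = tf,
               unresolved = as.character(x$unresolved))
}

#' Save a project to JSON
#' @param project a `ProjectState`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_project <- function(project, path) {
  stopifnot(inherits(project, "ProjectState"))
  body <- list(
    format = "geneclust-project", version = 1L,
    datasets = lapply(unname(project$datasets), dataset_to_list),
    ortholog_maps = lapply(project$ortholog_maps, function(m)
      list(organisms = m$organisms,
           pairs = list(gene_a = m$pairs$gene_a, gene_b = m$pairs$gene_b))),
    results = lapply(project$results, cluster_result_to_list),
    seeds = project$seeds)
  json <- jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", pretty = TRUE)
  writeLines(json, path, sep = "\n")
  invisible(path)
}

#' Load a project from JSON
#' @param path file written by [save_project()].
#' @return a `ProjectState`.
#' @export
load_project <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  if (!identical(x$format, "geneclust-project"))
    stop("not a geneclust project file: ", path)
  datasets <- lapply(x$datasets, dataset_from_list)
  names(datasets) <- vapply(datasets, function(d) d$name, character(1))
  maps <- lapply(x$ortholog_maps, function(m)
    ortholog_map(data.frame(gene_a = as.character(m$pairs$gene_a),
                            gene_b = as.character(m$pairs$gene_b)),
                 m$organisms[[1L]], m$organisms[[2L]]))
  results <- lapply(x$results, cluster_result_from_list)
  seeds <- lapply(x$seeds, as.integer)
  project_state(datasets = datasets, ortholog_maps = maps, results = results,
                seeds = seeds)
}
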