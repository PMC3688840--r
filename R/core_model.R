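#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate median pt qt sd setNames var
#' @importFrom utils head read.delim tail
NULL

# Coordinates are 1-based and inclusive throughout (Ensembl/Biomart
# convention); BED input is converted on read.  Strand is stored as the
# integer +1 / -1.

GENE_COLUMNS <- c("gene_id", "chromosome", "start", "end", "strand")

#' Construct a gene dataset
#'
#' A `GeneDataset` is a named, per-organism collection of gene records with
#' 1-based inclusive coordinates, optionally carrying an expression table
#' (genes x conditions) and a transcription-factor annotation (per gene, a
#' named vector of binding-site counts per TF).  Genes are kept sorted by
#' (chromosome, start, end, gene_id), which makes every positional operation
#' downstream deterministic.
#'
#' @param genes data.frame with columns `gene_id`, `chromosome`, `start`,
#'   `end` (1-based inclusive, `end >= start >= 1`) and `strand` (`+1`/`-1`,
#'   also accepted as `"+"`/`"-"`).
#' @param name dataset name.
#' @param organism organism label; all member genes belong to it.
#' @param expression optional numeric matrix (rownames = gene ids, colnames =
#'   condition names); `NA` entries are the explicit "not available" state.
#' @param tf optional TF annotation: named list mapping gene id to a named
#'   numeric vector of site counts per TF name.
#' @param unresolved character vector of gene ids that were requested but are
#'   absent from the positional annotation; they are carried along for
#'   reporting but excluded from positional operations.
#' @return an object of class `GeneDataset`.
#' @export
gene_dataset <- function(genes, name = "dataset", organism = "unknown",
                         expression = NULL, tf = NULL,
                         unresolved = character()) {
  stopifnot(is.data.frame(genes))
  missing_cols <- setdiff(GENE_COLUMNS, names(genes))
  if (length(missing_cols) > 0L)
    stop("gene table lacks column(s): ", paste(missing_cols, collapse = ", "))
  genes <- genes[GENE_COLUMNS]
  genes$gene_id <- as.character(genes$gene_id)
  genes$chromosome <- as.character(genes$chromosome)
  genes$start <- as.numeric(genes$start)
  genes$end <- as.numeric(genes$end)
  genes$strand <- normalize_strand(genes$strand)
  validate_gene_table(genes)
  genes <- sort_gene_table(genes)
  rownames(genes) <- NULL
  d <- structure(
    list(name = as.character(name), organism = as.character(organism),
         genes = genes, expression = NULL, tf = NULL,
         unresolved = as.character(unresolved)),
    class = "GeneDataset")
  if (!is.null(expression)) d <- attach_expression(d, expression)
  if (!is.null(tf)) d <- attach_tf(d, tf)
  d
}

normalize_strand <- function(strand) {
  if (is.character(strand) || is.factor(strand)) {
    s <- as.character(strand)
    out <- ifelse(s %in% c("+", "+1", "1"), 1L,
                  ifelse(s %in% c("-", "−", "-1"), -1L, NA_integer_))
  } else {
    out <- as.integer(strand)
    out[!out %in% c(1L, -1L)] <- NA_integer_
  }
  out
}

validate_gene_table <- function(genes) {
  if (nrow(genes) == 0L) return(invisible(genes))
  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  bad <- which(!is.finite(genes$start) | !is.finite(genes$end) |
                 genes$start < 1 | genes$end < genes$start)
  if (length(bad) > 0L)
    stop("invalid coordinates (need 1 <= start <= end) for gene(s): ",
         paste(genes$gene_id[head(bad, 5L)], collapse = ", "))
  if (anyNA(genes$strand))
    stop("unknown strand for gene(s): ",
         paste(genes$gene_id[head(which(is.na(genes$strand)), 5L)],
               collapse = ", "))
  invisible(genes)
}

# Deterministic order: chromosome, then start, ties broken by end then id.
sort_gene_table <- function(genes) {
  genes[order(genes$chromosome, genes$start, genes$end, genes$gene_id), ,
        drop = FALSE]
}

#' @export
print.GeneDataset <- function(x, ...) {
  cat(sprintf("GeneDataset '%s' (%s): %d genes on %d chromosome(s)\n",
              x$name, x$organism, nrow(x$genes),
              length(unique(x$genes$chromosome))))
  if (!is.null(x$expression))
    cat(sprintf("  expression: %d condition(s)\n", ncol(x$expression)))
  if (!is.null(x$tf))
    cat(sprintf("  TF annotation: %d annotated gene(s)\n",
                sum(lengths(x$tf) > 0)))
  if (length(x$unresolved) > 0L)
    cat(sprintf("  unresolved ids: %d\n", length(x$unresolved)))
  invisible(x)
}

#' Number of genes in a dataset
#' @param d a `GeneDataset`.
#' @return integer count.
#' @export
n_genes <- function(d) {
  stopifnot(inherits(d, "GeneDataset"))
  nrow(d$genes)
}

#' Gene ids of a dataset
#' @param d a `GeneDataset`.
#' @return character vector in positional order.
#' @export
gene_ids <- function(d) {
  stopifnot(inherits(d, "GeneDataset"))
  d$genes$gene_id
}

#' Restrict a dataset to a set of gene ids
#'
#' Attachments (expression, TF annotation) are carried over, restricted to the
#' surviving genes.  Ids absent from the dataset are ignored.
#'
#' @param d a `GeneDataset`.
#' @param ids character vector of gene ids to keep.
#' @param name optional name for the result (default: the input's name).
#' @return a `GeneDataset`.
#' @export
subset_genes <- function(d, ids, name = d$name) {
  stopifnot(inherits(d, "GeneDataset"))
  keep <- d$genes$gene_id %in% ids
  out <- gene_dataset(d$genes[keep, , drop = FALSE], name = name,
                      organism = d$organism, unresolved = d$unresolved)
  if (!is.null(d$expression)) {
    rows <- intersect(rownames(d$expression), out$genes$gene_id)
    out$expression <- d$expression[rows, , drop = FALSE]
  }
  if (!is.null(d$tf)) out$tf <- d$tf[intersect(names(d$tf), out$genes$gene_id)]
  out
}

#' Attach an expression table to a dataset
#'
#' @param d a `GeneDataset`.
#' @param expression numeric matrix or data.frame, rows = genes (rownames are
#'   gene ids), columns = conditions.  `NA` marks a missing measurement; it is
#'   never treated as zero.
#' @return the dataset with the table attached.
#' @export
attach_expression <- function(d, expression) {
  stopifnot(inherits(d, "GeneDataset"))
  m <- as.matrix(expression)
  storage.mode(m) <- "double"
  if (is.null(rownames(m))) stop("expression table needs gene ids as rownames")
  if (is.null(colnames(m))) stop("expression table needs condition names")
  if (anyDuplicated(rownames(m))) stop("duplicated gene_id in expression table")
  d$expression <- m
  d
}

#' Attach a TF annotation to a dataset
#'
#' @param d a `GeneDataset`.
#' @param tf named list: gene id -> named numeric vector of per-TF site
#'   counts.  Genes missing from the list have an empty TF repertoire.
#' @return the dataset with the annotation attached.
#' @export
attach_tf <- function(d, tf) {
  stopifnot(inherits(d, "GeneDataset"), is.list(tf))
  if (length(tf) > 0L && is.null(names(tf)))
    stop("TF annotation must be a named list keyed by gene id")
  bad <- vapply(tf, function(v) length(v) > 0L &&
                  (is.null(names(v)) || any(v < 0)), logical(1))
  if (any(bad)) stop("TF annotation entries must be named, non-negative counts")
  d$tf <- lapply(tf, function(v) {
    v <- v[order(names(v))]
    storage.mode(v) <- "double"
    v
  })
  d
}

#' TF repertoire of one gene
#' @param d a `GeneDataset` with a TF annotation attached.
#' @param gene_id gene id.
#' @return named numeric vector of site counts (empty if unannotated).
#' @export
tf_of_gene <- function(d, gene_id) {
  stopifnot(inherits(d, "GeneDataset"))
  if (is.null(d$tf) || is.null(d$tf[[gene_id]])) return(setNames(numeric(0), character(0)))
  d$tf[[gene_id]]
}

#' Promoter anchor coordinate of genes
#'
#' The promoter is taken to sit at the transcriptional start.  Annotation
#' exports keep plus-strand coordinates for minus-strand genes, so the anchor
#' is `start` for strand `+1` and `end` for strand `-1`.
#'
#' @param genes data.frame of gene records (or a `GeneDataset`).
#' @return numeric vector of anchor coordinates, one per gene.
#' @export
promoter_anchor <- function(genes) {
  genes <- as_gene_table(genes)
  ifelse(genes$strand > 0, genes$start, genes$end)
}

#' Centre coordinate of genes
#'
#' May be half-integer; distances derived from centres are real-valued.
#'
#' @param genes data.frame of gene records (or a `GeneDataset`).
#' @return numeric vector of `(start + end) / 2`.
#' @export
gene_centre <- function(genes) {
  genes <- as_gene_table(genes)
  (genes$start + genes$end) / 2
}

#' Gene lengths in bp
#' @param genes data.frame of gene records (or a `GeneDataset`).
#' @return numeric vector of `end - start + 1`.
#' @export
gene_length <- function(genes) {
  genes <- as_gene_table(genes)
  genes$end - genes$start + 1
}

as_gene_table <- function(genes) {
  if (inherits(genes, "GeneDataset")) return(genes$genes)
  stopifnot(is.data.frame(genes))
  genes
}

#' Per-chromosome layout of a dataset
#'
#' @param d a `GeneDataset` (or gene table).
#' @param chromosome chromosome name.
#' @param length chromosome length in bp; if `NULL`, inferred as the maximum
#'   gene end on the chromosome.
#' @return a `ChromosomeLayout`: list with the chromosome name, its length and
#'   the position-ordered gene table.
#' @export
chromosome_layout <- function(d, chromosome, length = NULL) {
  genes <- as_gene_table(d)
  genes <- genes[genes$chromosome == chromosome, , drop = FALSE]
  genes <- sort_gene_table(genes)
  rownames(genes) <- NULL
  if (is.null(length)) length <- if (nrow(genes) > 0L) max(genes$end) else 0
  structure(list(chromosome = chromosome, length = as.numeric(length),
                 genes = genes),
            class = "ChromosomeLayout")
}
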