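# Writers mirroring the annotation/expression/TF/ortholog readers, so any
# in-memory dataset (notably the synthetic fixtures) can be materialized in
# the exact dialects the readers consume.  All outputs are UTF-8 with LF
# line endings and byte-deterministic for a fixed input.

write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write a gene annotation table as TSV
#' @param d a `GeneDataset`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_annotation_tsv <- function(d, path) {
  stopifnot(inherits(d, "GeneDataset"))
  g <- d$genes
  lines <- c(paste(c("gene_id", "chromosome", "start", "end", "strand"),
                   collapse = "\t"),
             if (nrow(g) > 0L)
               paste(g$gene_id, g$chromosome, format(g$start, scientific = FALSE,
                                                     trim = TRUE),
                     format(g$end, scientific = FALSE, trim = TRUE),
                     ifelse(g$strand > 0, "+", "-"), sep = "\t"))
  write_lines_lf(lines, path)
}

#' Write an expression table as CSV
#' @param expression numeric matrix (genes x conditions, rownames = ids).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_csv <- function(expression, path) {
  m <- as.matrix(expression)
  header <- paste(c("gene_id", colnames(m)), collapse = ",")
  body <- vapply(seq_len(nrow(m)), function(i) {
    vals <- ifelse(is.na(m[i, ]), "",
                   format(m[i, ], scientific = FALSE, trim = TRUE, digits = 15))
    paste(c(rownames(m)[i], vals), collapse = ",")
  }, character(1))
  write_lines_lf(c(header, body), path)
}

#' Write a TF annotation as TSV
#' @param tf named list: gene id -> named numeric vector of site counts.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tf_annotation <- function(tf, path) {
  header <- paste(c("gene_id", "tf_name", "count"), collapse = "\t")
  rows <- unlist(lapply(sort(names(tf)), function(id) {
    v <- tf[[id]]
    if (length(v) == 0L) return(character(0))
    paste(id, names(v), format(v, scientific = FALSE, trim = TRUE), sep = "\t")
  }))
  write_lines_lf(c(header, rows), path)
}

#' Write an ortholog map as TSV
#' @param map an `OrthologMap`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ortholog_map <- function(map, path) {
  stopifnot(inherits(map, "OrthologMap"))
  header <- paste(c("gene_a", "gene_b"), collapse = "\t")
  rows <- if (nrow(map$pairs) > 0L)
    paste(map$pairs$gene_a, map$pairs$gene_b, sep = "\t") else character(0)
  write_lines_lf(c(header, rows), path)
}
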