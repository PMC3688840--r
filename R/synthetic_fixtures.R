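# Deterministic generators for synthetic genomes with planted positional
# cluster structure, cluster-correlated expression, cluster-shared TF
# repertoires and ortholog maps with known gap patterns.  Everything is a
# pure function of (specification, seed); ground-truth labels travel beside
# the dataset, never inside it.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic genome with planted clusters
#'
#' Each chromosome carries `blocks_per_chromosome` planted blocks of
#' `genes_per_block` genes plus `background_per_chromosome` isolated
#' background genes.  Consecutive gene starts inside a block are separated by
#' gaps drawn uniformly from `[1, gap_within]` bp; gaps between blocks /
#' background genes are drawn uniformly from `[gap_between, 2 * gap_between]`
#' bp, so any clustering threshold strictly between the two bounds separates
#' the blocks exactly.
#'
#' @param chromosomes number of chromosomes.
#' @param blocks_per_chromosome planted blocks per chromosome.
#' @param genes_per_block genes in each block.
#' @param gap_within upper bound G_in (bp) on within-block start gaps.
#' @param gap_between lower bound G_out (bp) on between-element start gaps;
#'   must exceed `gap_within`.
#' @param background_per_chromosome isolated background genes per chromosome.
#' @param gene_length_range min/max gene length (bp).
#' @param strand_prob probability of the + strand.
#' @param chromosome_length optional hard chromosome length (bp); generation
#'   fails if the placed genes exceed it.
#' @param organism organism label.
#' @return a `PlantedGenomeSpec`.
#' @export
planted_genome_spec <- function(chromosomes = 2L,
                                blocks_per_chromosome = 4L,
                                genes_per_block = 5L,
                                gap_within = 1e4,
                                gap_between = 2e5,
                                background_per_chromosome = 3L,
                                gene_length_range = c(300, 900),
                                strand_prob = 0.5,
                                chromosome_length = NULL,
                                organism = "synthA") {
  stopifnot(gap_between > gap_within, gap_within > 0,
            chromosomes >= 1, genes_per_block >= 1,
            blocks_per_chromosome >= 0, background_per_chromosome >= 0,
            strand_prob >= 0, strand_prob <= 1)
  structure(list(chromosomes = as.integer(chromosomes),
                 blocks_per_chromosome = as.integer(blocks_per_chromosome),
                 genes_per_block = as.integer(genes_per_block),
                 gap_within = gap_within, gap_between = gap_between,
                 background_per_chromosome = as.integer(background_per_chromosome),
                 gene_length_range = gene_length_range,
                 strand_prob = strand_prob,
                 chromosome_length = chromosome_length,
                 organism = organism),
            class = "PlantedGenomeSpec")
}

#' Generate a synthetic genome with planted positional clusters
#'
#' @param spec a [planted_genome_spec()].
#' @param seed integer seed; the output is a pure function of
#'   `(spec, seed)`.
#' @param name dataset name.
#' @return list with `dataset` (a `GeneDataset`), `truth` (data.frame
#'   `gene_id`, `chromosome`, `block`; `block` is `NA` for background genes)
#'   and the `spec`/`seed` used.
#' @export
generate_genome <- function(spec, seed = 1L, name = "planted") {
  stopifnot(inherits(spec, "PlantedGenomeSpec"))
  with_seed(seed, {
    rows <- list()
    truth <- list()
    for (c_i in seq_len(spec$chromosomes)) {
      ch <- paste0("chr", c_i)
      # element sequence: blocks and background singletons in shuffled order
      elements <- c(rep("block", spec$blocks_per_chromosome),
                    rep("bg", spec$background_per_chromosome))
      elements <- sample(elements)
      cur <- round(runif(1, 1e4, 5e4))
      block_no <- 0L; bg_no <- 0L
      for (el in elements) {
        if (el == "block") {
          block_no <- block_no + 1L
          block_id <- sprintf("%s_b%d", ch, block_no)
          for (g_i in seq_len(spec$genes_per_block)) {
            len <- round(runif(1, spec$gene_length_range[1L],
                               spec$gene_length_range[2L]))
            id <- sprintf("%s_g%d", block_id, g_i)
            rows[[length(rows) + 1L]] <- data.frame(
              gene_id = id, chromosome = ch, start = cur, end = cur + len - 1,
              strand = if (runif(1) < spec$strand_prob) 1L else -1L)
            truth[[length(truth) + 1L]] <- data.frame(
              gene_id = id, chromosome = ch, block = block_id)
            if (g_i < spec$genes_per_block)
              cur <- cur + round(runif(1, 1, spec$gap_within))
          }
        } else {
          bg_no <- bg_no + 1L
          len <- round(runif(1, spec$gene_length_range[1L],
                             spec$gene_length_range[2L]))
          id <- sprintf("%s_bg%d", ch, bg_no)
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = id, chromosome = ch, start = cur, end = cur + len - 1,
            strand = if (runif(1) < spec$strand_prob) 1L else -1L)
          truth[[length(truth) + 1L]] <- data.frame(
            gene_id = id, chromosome = ch, block = NA_character_)
        }
        cur <- cur + round(runif(1, spec$gap_between, 2 * spec$gap_between))
      }
      if (!is.null(spec$chromosome_length)) {
        max_end <- max(vapply(rows, function(r) r$end, numeric(1))[
          vapply(rows, function(r) r$chromosome, character(1)) == ch])
        if (max_end > spec$chromosome_length)
          stop(sprintf(
            "infeasible packing: chromosome %s needs %d bp but length is %d",
            ch, max_end, spec$chromosome_length))
      }
    }
    genes <- do.call(rbind, rows)
    truth <- do.call(rbind, truth)
    d <- gene_dataset(genes, name = name, organism = spec$organism)
    truth <- truth[match(d$genes$gene_id, truth$gene_id), , drop = FALSE]
    rownames(truth) <- NULL
    list(dataset = d, truth = truth, spec = spec, seed = seed)
  })
}

#' Plant expression and/or TF attributes on a synthetic genome
#'
#' Expression: genes of one block share a block mean drawn from
#' `N(0, block_mean_sd^2)`; each measured value adds replicate noise
#' `N(0, noise_sd^2)`.  Background genes get independent means.  TF: each
#' block owns a repertoire of `tfs_per_block` private TFs; block members
#' carry each repertoire TF with probability `q`, and every gene carries each
#' TF of a shared background pool with probability `q0 < q`.
#'
#' @param genome output of [generate_genome()].
#' @param mode `"expression"`, `"tf"` or `"both"`.
#' @param n_conditions expression conditions to simulate.
#' @param block_mean_sd SD of the block-level expression means.
#' @param noise_sd replicate noise SD.
#' @param q probability a block member carries a repertoire TF.
#' @param q0 probability any gene carries a background-pool TF.
#' @param tfs_per_block repertoire size per block.
#' @param n_background_tfs size of the shared background TF pool.
#' @param seed integer seed.
#' @return list with `dataset` (attributes attached), `truth`, and
#'   `parameters` echoing every distribution parameter used.
#' @export
generate_attributes <- function(genome, mode = c("both", "expression", "tf"),
                                n_conditions = 5L, block_mean_sd = 2,
                                noise_sd = 0.25, q = 0.8, q0 = 0.1,
                                tfs_per_block = 3L, n_background_tfs = 5L,
                                seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(q >= q0)
  d <- genome$dataset
  truth <- genome$truth
  with_seed(seed, {
    ids <- d$genes$gene_id
    blocks <- truth$block[match(ids, truth$gene_id)]
    if (mode %in% c("expression", "both")) {
      block_levels <- unique(blocks[!is.na(blocks)])
      mu_b <- setNames(stats::rnorm(length(block_levels), 0, block_mean_sd),
                       block_levels)
      mu <- ifelse(is.na(blocks), stats::rnorm(length(ids), 0, block_mean_sd),
                   mu_b[blocks])
      m <- matrix(stats::rnorm(length(ids) * n_conditions, mean = mu,
                               sd = noise_sd),
                  nrow = length(ids),
                  dimnames = list(ids, paste0("cond", seq_len(n_conditions))))
      d <- attach_expression(d, m)
    }
    if (mode %in% c("tf", "both")) {
      block_levels <- unique(blocks[!is.na(blocks)])
      repertoire <- setNames(lapply(block_levels, function(b)
        paste0("TF_", b, "_", seq_len(tfs_per_block))), block_levels)
      bg_pool <- if (n_background_tfs > 0L)
        paste0("TF_bg", seq_len(n_background_tfs)) else character(0)
      tf <- lapply(seq_along(ids), function(i) {
        own <- if (!is.na(blocks[i]))
          repertoire[[blocks[i]]][runif(tfs_per_block) < q] else character(0)
        extra <- bg_pool[runif(length(bg_pool)) < q0]
        tfs <- unique(c(own, extra))
        if (length(tfs) == 0L) return(setNames(numeric(0), character(0)))
        setNames(1 + stats::rpois(length(tfs), 0.5), tfs)
      })
      names(tf) <- ids
      d <- attach_tf(d, tf)
    }
    list(dataset = d, truth = truth,
         parameters = list(mode = mode, n_conditions = n_conditions,
                           block_mean_sd = block_mean_sd, noise_sd = noise_sd,
                           q = q, q0 = q0, tfs_per_block = tfs_per_block,
                           n_background_tfs = n_background_tfs, seed = seed))
  })
}

#' Generate an ortholog fixture with known gap structure
#'
#' A fraction of the planted blocks is "conserved": their member genes are
#' paired gene-to-gene with a synthetic partner genome.  Within each
#' conserved block, `insertions_per_block` interior genes are withheld from
#' the map, so they act as non-orthologous insertions with known positions
#' and realize known gap counts for max-gap clustering.  Background genes
#' and non-conserved blocks are never orthologous.
#'
#' @param genome output of [generate_genome()].
#' @param conserved_fraction fraction of blocks that are conserved.
#' @param insertions_per_block interior member genes per conserved block
#'   withheld from the ortholog map.
#' @param comparison_organism label of the partner organism.
#' @param seed integer seed (used to pick which blocks are conserved).
#' @return list with `map` (an `OrthologMap`), `dataset_b` (the partner
#'   `GeneDataset`), `orthologous` (logical per gene of the source genome),
#'   and `expected_clusters(maxgap, minsize)`, a function giving the planted
#'   max-gap clusters as gene-id lists.
#' @export
generate_ortholog_fixture <- function(genome, conserved_fraction = 1,
                                      insertions_per_block = 0L,
                                      comparison_organism = "synthB",
                                      seed = 1L) {
  d <- genome$dataset
  truth <- genome$truth
  blocks <- unique(truth$block[!is.na(truth$block)])
  with_seed(seed, {
    n_cons <- round(conserved_fraction * length(blocks))
    conserved <- if (n_cons > 0L) sort(sample(blocks, n_cons)) else character(0)
    orth <- rep(FALSE, nrow(truth))
    for (b in conserved) {
      members <- which(!is.na(truth$block) & truth$block == b)
      excl <- integer(0)
      if (insertions_per_block > 0L && length(members) > 2L) {
        interior <- members[-c(1L, length(members))]
        pick <- unique(round(seq(1L, length(interior),
                                 length.out = min(insertions_per_block,
                                                  length(interior)))))
        excl <- interior[pick]
      }
      orth[setdiff(members, excl)] <- TRUE
    }
    src_ids <- truth$gene_id[orth]
    pairs <- data.frame(gene_a = src_ids,
                        gene_b = if (length(src_ids)) paste0(src_ids, "_o")
                                 else character(0))
    map <- ortholog_map(pairs, d$organism, comparison_organism)
    dataset_b <- if (length(src_ids) > 0L) {
      gene_dataset(data.frame(
        gene_id = paste0(src_ids, "_o"), chromosome = "chrB1",
        start = 1e4 * seq_along(src_ids),
        end = 1e4 * seq_along(src_ids) + 500, strand = 1L),
        name = "partner", organism = comparison_organism)
    } else NULL
    expected_clusters <- function(maxgap, minsize) {
      out <- list()
      for (ch in unique(truth$chromosome)) {
        i <- which(truth$chromosome == ch)       # positional order
        flags <- orth[i]
        mem <- which(flags)
        if (length(mem) == 0L) next
        cum <- cumsum(!flags)
        gaps <- if (length(mem) >= 2L)
          cum[mem[-1L]] - cum[mem[-length(mem)]] else integer(0)
        run <- cumsum(c(TRUE, gaps > maxgap))
        for (s in unique(run)) {
          ids <- truth$gene_id[i][mem[run == s]]
          if (length(ids) >= minsize) out[[length(out) + 1L]] <- ids
        }
      }
      out
    }
    list(map = map, dataset_b = dataset_b,
         orthologous = setNames(orth, truth$gene_id),
         conserved_blocks = conserved,
         expected_clusters = expected_clusters)
  })
}

#' Write a synthetic genome (and attachments) to fixture files
#'
#' Materializes the dataset in the exact dialects the package readers
#' consume: annotation TSV, expression CSV, TF TSV.
#'
#' @param genome output of [generate_genome()] or [generate_attributes()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
write_genome_fixture <- function(genome, dir) {
  d <- genome$dataset
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(annotation = file.path(dir, "genes.tsv"))
  write_gene_annotation_tsv(d, paths[["annotation"]])
  if (!is.null(d$expression)) {
    paths[["expression"]] <- file.path(dir, "expression.csv")
    write_expression_csv(d$expression, paths[["expression"]])
  }
  if (!is.null(d$tf)) {
    paths[["tf"]] <- file.path(dir, "tf.tsv")
    write_tf_annotation(d$tf, paths[["tf"]])
  }
  paths
}
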