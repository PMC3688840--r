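# Fixture builders and independent oracles used across the suite.

# Quick gene-table builder: genes laid on one chromosome at given starts.
make_genes <- function(starts, lengths = 100, strand = 1L,
                       chromosome = "chr1", ids = NULL) {
  n <- length(starts)
  if (length(lengths) == 1L) lengths <- rep(lengths, n)
  if (length(strand) == 1L) strand <- rep(strand, n)
  if (length(chromosome) == 1L) chromosome <- rep(chromosome, n)
  if (is.null(ids)) ids <- sprintf("g%02d", seq_len(n))
  data.frame(gene_id = ids, chromosome = chromosome, start = starts,
             end = starts + lengths - 1, strand = strand)
}

quick_dataset <- function(starts, ..., name = "fix", organism = "org") {
  gene_dataset(make_genes(starts, ...), name = name, organism = organism)
}

# Rand index between two partitions given as label vectors over the same
# element order (NA labels = singletons of their own).
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(1)
  a <- as.character(a); b <- as.character(b)
  a[is.na(a)] <- paste0(".na_a", seq_len(n))[is.na(a)]
  b[is.na(b)] <- paste0(".na_b", seq_len(n))[is.na(b)]
  pairs <- utils::combn(n, 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  mean(same_a == same_b)
}

# Brute-force sequential-clustering oracle: per chromosome, link consecutive
# genes whose weighted distance is strictly below T, then take connected
# components by label propagation (independent of the package's scan).
oracle_sequential <- function(d, threshold, spec = weighted_distance_spec(),
                              context = NULL) {
  if (is.null(context)) context <- distance_context(d)
  g <- d$genes
  labels <- seq_len(nrow(g))
  for (ch in unique(g$chromosome)) {
    idx <- which(g$chromosome == ch)
    if (length(idx) < 2) next
    for (k in seq_len(length(idx) - 1)) {
      g1 <- g[idx[k], , drop = FALSE]
      g2 <- g[idx[k + 1], , drop = FALSE]
      if (weighted_distance(g1, g2, spec, context) < threshold) {
        old <- labels[idx[k + 1]]
        labels[labels == old] <- labels[idx[k]]
      }
    }
  }
  labels
}

# Exhaustive max-gap oracle: all-pairs relation "number of non-orthologous
# background genes strictly between <= maxgap", transitive closure over the
# orthology-bearing dataset genes, then the minsize filter.
oracle_maxgap <- function(d, map, maxgap, minsize, background = d) {
  bg <- background$genes
  orth <- has_ortholog(map, bg$gene_id, organism = d$organism)
  member <- orth & bg$gene_id %in% d$genes$gene_id
  out <- list()
  for (ch in unique(bg$chromosome)) {
    idx <- which(bg$chromosome == ch)
    mem <- idx[member[idx]]
    m <- length(mem)
    if (m == 0) next
    link <- matrix(FALSE, m, m)
    for (i in seq_len(m)) for (j in seq_len(m)) {
      lo <- min(mem[i], mem[j]); hi <- max(mem[i], mem[j])
      between <- idx[idx > lo & idx < hi]
      link[i, j] <- sum(!orth[between]) <= maxgap
    }
    # transitive closure (Floyd-Warshall style)
    for (k in seq_len(m)) for (i in seq_len(m)) for (j in seq_len(m))
      if (link[i, k] && link[k, j]) link[i, j] <- TRUE
    comp <- rep(NA_integer_, m)
    nc <- 0
    for (i in seq_len(m)) if (is.na(comp[i])) {
      nc <- nc + 1
      comp[link[i, ]] <- nc
      comp[i] <- nc
    }
    for (c_id in unique(comp)) {
      ids <- bg$gene_id[mem[comp == c_id]]
      if (length(ids) >= minsize) out[[length(out) + 1]] <- sort(ids)
    }
  }
  out[order(vapply(out, function(x) x[1], character(1)))]
}

# Exhaustive two-sided Fisher oracle for a 2x2 table: enumerate all tables
# with the observed margins and sum probabilities <= that of the observed.
oracle_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d_ <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d_
  if (n == 0) return(1)
  a_values <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(a_values, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Independent Mann-Whitney enumeration (constructed differently from the
# package's: walks assignments recursively rather than via combn).
oracle_mwu <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_stat <- function(sel) sum(rk[sel]) - m * (m + 1) / 2
  u_obs <- u_stat(seq_len(m))
  mu <- m * n / 2
  count <- 0; total <- 0
  recurse <- function(sel, next_i) {
    if (length(sel) == m) {
      total <<- total + 1
      if (abs(u_stat(sel) - mu) >= abs(u_obs - mu) - 1e-9)
        count <<- count + 1
      return(invisible())
    }
    if (next_i > m + n) return(invisible())
    for (i in next_i:(m + n)) recurse(c(sel, i), i + 1)
  }
  recurse(integer(0), 1)
  count / total
}

# Exhaustive adjacency-count moments: all C(N, n) placements of n marks on N
# ordered slots.
oracle_adjacency_moments <- function(N, n) {
  if (n < 2 || N < 2) return(c(mean = 0, sd = 0))
  sets <- utils::combn(N, n)
  counts <- apply(sets, 2, function(s) sum(diff(sort(s)) == 1))
  c(mean = mean(counts), sd = sqrt(mean(counts^2) - mean(counts)^2))
}

# Optimal 1-D k-means cost by dynamic programming over contiguous segments
# of the sorted positions (optimal 1-D clusters are contiguous).
oracle_kmeans_cost <- function(pos, k) {
  x <- sort(pos)
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  seg_cost <- function(i, j) {  # cost of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  dp <- matrix(Inf, k, n)
  for (j in seq_len(n)) dp[1, j] <- seg_cost(1, j)
  if (k >= 2) for (q in 2:k) for (j in q:n)
    dp[q, j] <- min(vapply((q - 1):(j - 1), function(t)
      dp[q - 1, t] + seg_cost(t + 1, j), numeric(1)))
  dp[k, n]
}

# Tiny TF-annotation builder: list(gene = c(TF names)) -> count-1 repertoire.
tf_ann <- function(...) {
  lst <- list(...)
  lapply(lst, function(tfs) setNames(rep(1, length(tfs)), tfs))
}
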