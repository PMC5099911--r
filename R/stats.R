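#' Permutation colocalization test of two genomic region sets
#'
#' Observed statistic: the number of `set_a` regions overlapping at least
#' one `set_b` region (>= 1 bp). Each permutation relocates every `set_a`
#' region uniformly at random, preserving its length, either on its own
#' chromosome (`mode = "per_chromosome"`, the default) or anywhere in the
#' genome with chromosomes drawn proportionally to their placeable length
#' (`mode = "genome"`). The empirical p-value for the enrichment
#' alternative is `(1 + #\{perm stat >= observed\}) / (1 + n_perm)`, and the
#' z-score is `(observed - null_mean) / null_sd`.
#'
#' @param set_a,set_b interval tables.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed (recorded in the result).
#' @param mode `"per_chromosome"` or `"genome"`.
#' @param alternative `"greater"` (enrichment, default) or `"less"`
#'   (depletion).
#' @return list of class `permutation_result`: observed, null_mean,
#'   null_sd, z_score, p_value, n_perm, seed, mode, null (the permuted
#'   statistics).
#' @export
permutation_colocalization <- function(set_a, set_b, chrom_sizes,
                                       n_perm = 1000, seed = 1,
                                       mode = c("per_chromosome", "genome"),
                                       alternative = c("greater", "less")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  stopifnot(n_perm >= 1, nrow(set_a) > 0, nrow(set_b) > 0)
  sizes <- .as_chrom_sizes(chrom_sizes)
  .check_chrom_dialect(names(sizes), set_a$chrom, "set_a")
  .check_chrom_dialect(names(sizes), set_b$chrom, "set_b")
  len <- set_a$end - set_a$start
  if (any(len > sizes[set_a$chrom]))
    stop("set_a region longer than its chromosome")

  # pre-merge set_b per chromosome for O(log n) membership tests
  bm <- merge_intervals(set_b)
  b_by_chrom <- split(bm, bm$chrom)
  count_hits <- function(chrom, start, end) {
    total <- 0L
    for (ch in unique(chrom)) {
      bi <- b_by_chrom[[ch]]
      if (is.null(bi)) next
      sel <- chrom == ch
      n_start <- findInterval(end[sel] - 0.5, bi$start)
      n_done <- findInterval(start[sel] + 0.5, bi$end)
      total <- total + sum(n_start > n_done)
    }
    total
  }
  observed <- count_hits(set_a$chrom, set_a$start, set_a$end)

  n <- nrow(set_a)
  chrom_names <- names(sizes)
  place_room <- function(chrom, l) sizes[chrom] - l  # start in [0, room]
  null <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      if (mode == "per_chromosome") {
        ch <- set_a$chrom
      } else {
        # chromosome choice proportional to placeable length per region
        ch <- vapply(len, function(l) {
          w <- pmax(sizes - l + 1, 0)
          sample(chrom_names, 1, prob = w)
        }, "")
      }
      room <- place_room(ch, len)
      s <- floor(stats::runif(n, 0, room + 1))
      count_hits(ch, s, s + len)
    }, numeric(1))
  })
  null_mean <- mean(null)
  null_sd <- stats::sd(null)
  z <- if (is.na(null_sd) || null_sd == 0) NA_real_ else
    (observed - null_mean) / null_sd
  p <- if (alternative == "greater")
    (1 + sum(null >= observed)) / (1 + n_perm)
  else
    (1 + sum(null <= observed)) / (1 + n_perm)
  structure(list(observed = observed, null_mean = null_mean,
                 null_sd = null_sd, z_score = z, p_value = p,
                 n_perm = n_perm, seed = seed, mode = mode,
                 alternative = alternative, null = null),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation colocalization: observed %d, null %.2f +/- %.2f, z = %s, p = %.4g (n_perm = %d, seed = %d)\n",
    x$observed, x$null_mean, x$null_sd,
    ifelse(is.na(x$z_score), "NA", sprintf("%.3f", x$z_score)),
    x$p_value, x$n_perm, x$seed))
  invisible(x)
}

#' Expression correlation between two genes
#'
#' Pearson correlation on log2(RPKM + 1)-transformed profiles by default
#' (Spearman available); genes with > `threshold` correlation are flagged
#' highly correlated (default threshold 0.6).
#'
#' @param expression an [expression_set()].
#' @param gene_a,gene_b gene ids (matrix rows).
#' @param method `"pearson"` or `"spearman"`.
#' @param log_transform apply log2(x + 1) first (default TRUE).
#' @param threshold high-correlation flag threshold (default 0.6).
#' @return list with `r` (NA if either profile has zero variance),
#'   `highly_correlated`, `n_samples`.
#' @export
expression_correlation <- function(expression, gene_a, gene_b,
                                   method = c("pearson", "spearman"),
                                   log_transform = TRUE, threshold = 0.6) {
  method <- match.arg(method)
  for (g in c(gene_a, gene_b))
    if (!g %in% rownames(expression$values))
      stop("gene absent from expression matrix: ", g)
  va <- expression$values[gene_a, ]
  vb <- expression$values[gene_b, ]
  if (length(va) < 3) stop("need >= 3 shared samples")
  if (log_transform) { va <- log2(va + 1); vb <- log2(vb + 1) }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    return(list(r = NA_real_, highly_correlated = NA, n_samples = length(va)))
  r <- stats::cor(va, vb, method = method)
  list(r = r, highly_correlated = r > threshold, n_samples = length(va))
}

#' Correlation-ranked protein-coding gene list for a lincRNA
#'
#' Protein-coding genes sorted by descending expression correlation with
#' the lincRNA (the guilt-by-association ranking fed to preranked GSEA);
#' ties break lexicographically on gene_id so the ranking is deterministic.
#' Genes with undefined correlation (zero variance) are dropped.
#'
#' @param expression an [expression_set()].
#' @param lincrna lincRNA gene id.
#' @param coding_genes character vector of protein-coding gene ids.
#' @inheritParams expression_correlation
#' @return data.frame with `gene_id`, `score` in rank order.
#' @export
rank_genes_for_lincrna <- function(expression, lincrna, coding_genes,
                                   method = "pearson", log_transform = TRUE) {
  coding_genes <- intersect(coding_genes, rownames(expression$values))
  vl <- expression$values[lincrna, ]
  if (log_transform) vl <- log2(vl + 1)
  if (stats::sd(vl) == 0) stop("lincRNA has zero expression variance: ", lincrna)
  mat <- expression$values[coding_genes, , drop = FALSE]
  if (log_transform) mat <- log2(mat + 1)
  sds <- apply(mat, 1, stats::sd)
  mat <- mat[sds > 0, , drop = FALSE]
  r <- suppressWarnings(as.numeric(stats::cor(t(mat), vl, method = method)))
  out <- data.frame(gene_id = rownames(mat), score = r,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# weighted Kolmogorov-Smirnov running-sum enrichment score:
# hit steps are proportional to |score|^p, miss steps uniform; the ES is the
# running sum's maximum deviation from zero (signed)
.gsea_es <- function(scores, is_hit, weight_p = 1) {
  nh <- sum(is_hit)
  n <- length(scores)
  stopifnot(nh >= 1, nh < n)
  w <- abs(scores)^weight_p
  hit_step <- ifelse(is_hit, w / sum(w[is_hit]), 0)
  if (sum(w[is_hit]) == 0) hit_step[is_hit] <- 1 / nh  # all-zero scores
  miss_step <- ifelse(is_hit, 0, 1 / (n - nh))
  rs <- cumsum(hit_step - miss_step)
  rs[which.max(abs(rs))]
}

#' Preranked gene set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov enrichment score (hit increments
#' proportional to |score|^`weight_p`, default 1; miss decrements uniform);
#' null distribution by gene-label permutation; NES = ES / mean(|null ES|
#' of the same sign); empirical p per term; Benjamini-Hochberg FDR across
#' terms. Terms with `fdr_q <= fdr_threshold` (default 0.01) are flagged
#' significant.
#'
#' @param ranked_list data.frame with `gene_id`, `score`, sorted descending
#'   (see [rank_genes_for_lincrna()]).
#' @param gene_sets named list of character vectors.
#' @param weight_p exponent on |score| for hit increments (0 = classic KS).
#' @param n_perm permutations for the null (>= 1).
#' @param seed RNG seed.
#' @param min_size gene sets with fewer members present in the list are
#'   skipped with a warning (default 5).
#' @param fdr_threshold significance threshold on fdr_q.
#' @return data.frame of class `gsea_result`: term, size, es, nes, p_value,
#'   fdr_q, significant.
#' @export
gsea_preranked <- function(ranked_list, gene_sets, weight_p = 1,
                           n_perm = 1000, seed = 1, min_size = 5,
                           fdr_threshold = 0.01) {
  stopifnot(n_perm >= 1)
  genes <- ranked_list$gene_id
  scores <- ranked_list$score
  n <- length(genes)
  keep <- vapply(gene_sets, function(s) {
    k <- sum(genes %in% s)
    if (k == n) stop("gene set identical to the ranked universe")
    k >= min_size
  }, logical(1))
  if (any(!keep))
    warning("skipping ", sum(!keep), " gene set(s) with < ", min_size,
            " members in the list")
  gene_sets <- gene_sets[keep]
  if (length(gene_sets) == 0)
    return(structure(data.frame(term = character(), size = integer(),
                                es = numeric(), nes = numeric(),
                                p_value = numeric(), fdr_q = numeric(),
                                significant = logical()),
                     class = c("gsea_result", "data.frame")))
  rows <- .with_seed(seed, {
    lapply(names(gene_sets), function(term) {
      is_hit <- genes %in% gene_sets[[term]]
      k <- sum(is_hit)
      es <- .gsea_es(scores, is_hit, weight_p)
      null_es <- vapply(seq_len(n_perm), function(p) {
        .gsea_es(scores, seq_len(n) %in% sample.int(n, k), weight_p)
      }, numeric(1))
      same_sign <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
      nes <- if (length(same_sign) == 0 || mean(abs(same_sign)) == 0)
        NA_real_ else es / mean(abs(same_sign))
      p <- if (es >= 0)
        (1 + sum(null_es >= es)) / (1 + max(sum(null_es >= 0), 1))
      else
        (1 + sum(null_es <= es)) / (1 + max(sum(null_es < 0), 1))
      data.frame(term = term, size = k, es = es, nes = nes,
                 p_value = min(p, 1), stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  out$fdr_q <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$fdr_q <= fdr_threshold
  rownames(out) <- NULL
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' Build and cluster a lincRNA x GO-term association matrix
#'
#' Entries are signed significances, `sign(NES) * min(-log10(fdr_q), cap)`,
#' zeroed for non-significant terms (fdr_q above the threshold). Rows
#' (lincRNAs) and columns (terms) are clustered by k-means with a fixed
#' seed and multiple restarts.
#'
#' @param gsea_by_lincrna named list of [gsea_preranked()] results, one per
#'   lincRNA.
#' @param k number of clusters for rows and columns (default 10).
#' @param fdr_threshold significance cut for non-zero entries (default 0.01).
#' @param cap cap on -log10(fdr_q) (default 10).
#' @param seed RNG seed for k-means.
#' @param nstart k-means restarts (default 10).
#' @return list of class `association_matrix`: `matrix` (lincRNAs x terms),
#'   `row_clusters`, `col_clusters`.
#' @export
build_association_matrix <- function(gsea_by_lincrna, k = 10,
                                     fdr_threshold = 0.01, cap = 10,
                                     seed = 1, nstart = 10) {
  terms <- sort(unique(unlist(lapply(gsea_by_lincrna, function(x) x$term))))
  lincs <- names(gsea_by_lincrna)
  if (length(lincs) < k) stop("fewer lincRNAs (rows) than k = ", k)
  if (length(terms) < k) stop("fewer terms (columns) than k = ", k)
  mat <- matrix(0, length(lincs), length(terms),
                dimnames = list(lincs, terms))
  for (l in lincs) {
    res <- gsea_by_lincrna[[l]]
    sig <- res[res$fdr_q <= fdr_threshold, , drop = FALSE]
    if (nrow(sig) > 0)
      mat[l, sig$term] <- sign(sig$nes) *
        pmin(-log10(pmax(sig$fdr_q, 10^(-cap))), cap)
  }
  # duplicate rows/columns always co-cluster: k-means runs on the distinct
  # profiles (capping k at their count) and labels map back
  km_safe <- function(m, k) {
    uq <- unique(m)
    kk <- min(k, nrow(uq))
    cl <- if (kk >= nrow(uq)) seq_len(nrow(uq)) else
      stats::kmeans(uq, centers = kk, nstart = nstart)$cluster
    key <- function(x) apply(x, 1, paste, collapse = "\r")
    idx <- match(key(m), key(uq))
    stats::setNames(cl[idx], rownames(m))
  }
  clusters <- .with_seed(seed, {
    list(rows = km_safe(mat, k), cols = km_safe(t(mat), k))
  })
  structure(list(matrix = mat, row_clusters = clusters$rows,
                 col_clusters = clusters$cols, k = k, seed = seed),
            class = "association_matrix")
}

#' Hypergeometric over-representation test for a ChIN community
#'
#' One-sided hypergeometric tail per gene set against the supplied
#' universe, with Benjamini-Hochberg FDR across terms (the functional
#' enrichment applied to communities of at least 20 nodes).
#'
#' @param community_genes character vector (subset of the universe).
#' @param universe_genes character vector.
#' @param gene_sets named list of character vectors.
#' @return data.frame with `term`, `overlap`, `set_size`, `odds_ratio`,
#'   `p_value`, `fdr_q`.
#' @export
enrich_community <- function(community_genes, universe_genes, gene_sets) {
  if (length(universe_genes) == 0) stop("empty universe")
  community_genes <- intersect(community_genes, universe_genes)
  n_comm <- length(community_genes)
  n_univ <- length(universe_genes)
  rows <- lapply(names(gene_sets), function(term) {
    set <- intersect(gene_sets[[term]], universe_genes)
    k <- length(intersect(set, community_genes))
    m <- length(set)
    p <- stats::phyper(k - 1, m, n_univ - m, n_comm, lower.tail = FALSE)
    or <- (k * (n_univ - m - n_comm + k)) /
      max((m - k) * (n_comm - k), .Machine$double.eps)
    data.frame(term = term, overlap = k, set_size = m, odds_ratio = or,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_q <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Two-group comparison by Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with normal approximation and tie correction
#' (the package's default test for whether two populations differ).
#'
#' @param values_a,values_b numeric vectors (each >= 1 value).
#' @return list with `statistic` (W) and `p_value`.
#' @export
compare_groups <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 1, length(values_b) >= 1)
  ht <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided",
                                            exact = FALSE, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}
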