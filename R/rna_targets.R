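#' Call target genes of a lincRNA from chromatin proximity and RNA binding
#'
#' Combines three evidence channels for every candidate gene:
#' \describe{
#'   \item{interacting}{the gene sits on a ChIN node within `k` hops
#'     (default 3) of the lincRNA's promoter node; paths may pass through
#'     DRE nodes (intermediate interacting regions).}
#'   \item{bound}{the gene's genic region (+/- 2.5 kb of the gene body)
#'     overlaps at least one RNA binding peak by >= 1 bp.}
#'   \item{correlated}{expression correlation with the lincRNA exceeds
#'     `r_threshold` (default 0.6).}
#' }
#' Genes with interacting or bound evidence partition into three groups:
#' (1) bound and interacting, (2) only bound, (3) only interacting.
#'
#' @param lincrna lincRNA gene id.
#' @param chin a [build_chin()] result.
#' @param genes gene table.
#' @param peaks interval table of CHART/ChIRP binding peaks (peaks from
#'   multiple capture-oligo sets should be unioned beforehand, the default
#'   treatment).
#' @param k hop radius (default 3).
#' @param chart_track optional [coverage_track()] of CHART read coverage;
#'   mean coverage over each genic region is reported when given.
#' @param expression optional [expression_set()] enabling the correlated
#'   channel.
#' @param r_threshold correlation threshold (default 0.6).
#' @param flank genic-region extension (default 2500).
#' @return data.frame of class `target_calls`: gene_id, interacting, bound,
#'   correlated, group (1/2/3 or NA), chart_mean_coverage; attribute `k`;
#'   attribute `n_nodes` (node count of the k-hop neighborhood).
#' @export
call_targets <- function(lincrna, chin, genes, peaks, k = 3,
                         chart_track = NULL, expression = NULL,
                         r_threshold = 0.6, flank = 2500) {
  stopifnot(k >= 0)
  node_of <- .gene_node_map(chin)
  seed_nodes <- node_of[[lincrna]]
  if (is.null(seed_nodes)) {
    warning("lincRNA ", lincrna, " is not in the ChIN; no interacting genes")
    hood <- integer(0)
  } else {
    hood <- k_hop_neighborhood(chin, seed_nodes, k)
  }
  interacting_genes <- setdiff(
    unique(unlist(chin$nodes$gene_ids[match(hood, chin$nodes$node_id)])),
    lincrna)
  cand <- genes[genes$gene_id != lincrna, , drop = FALSE]
  gen <- genic_regions(cand, flank = flank)
  bound_genes <- cand$gene_id[.overlaps_any(gen, peaks)]
  all_ids <- sort(union(interacting_genes, bound_genes))
  if (length(all_ids) == 0) {
    out <- data.frame(gene_id = character(), interacting = logical(),
                      bound = logical(), correlated = logical(),
                      group = integer(), chart_mean_coverage = numeric())
  } else {
    interacting <- all_ids %in% interacting_genes
    bound <- all_ids %in% bound_genes
    correlated <- rep(NA, length(all_ids))
    if (!is.null(expression) && lincrna %in% rownames(expression$values)) {
      correlated <- vapply(all_ids, function(g) {
        if (!g %in% rownames(expression$values)) return(NA)
        r <- expression_correlation(expression, lincrna, g,
                                    threshold = r_threshold)$r
        if (is.na(r)) NA else r > r_threshold
      }, logical(1))
    }
    cmc <- rep(NA_real_, length(all_ids))
    if (!is.null(chart_track)) {
      gi <- gen[match(all_ids, gen$gene_id), , drop = FALSE]
      cmc <- vapply(seq_len(nrow(gi)), function(i)
        suppressWarnings(mean_coverage(chart_track, gi[i, ])), numeric(1))
    }
    group <- ifelse(bound & interacting, 1L, ifelse(bound, 2L, 3L))
    out <- data.frame(gene_id = all_ids, interacting = interacting,
                      bound = bound, correlated = correlated, group = group,
                      chart_mean_coverage = cmc, stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "k") <- k
  attr(out, "n_nodes") <- length(hood)
  class(out) <- c("target_calls", "data.frame")
  out
}

#' Enrichment of RNA binding peaks inside a k-hop ChIN neighborhood
#'
#' Tests whether binding peaks colocalize with the node regions within `k`
#' hops of the lincRNA's promoter node, by delegating to
#' [permutation_colocalization()] with set_a = peaks and set_b = the
#' neighborhood regions.
#'
#' @inheritParams call_targets
#' @param chrom_sizes named numeric vector.
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @return a `permutation_result`; observed is 0 (with NA z) when the
#'   neighborhood is empty.
#' @export
binding_enrichment_in_neighborhood <- function(lincrna, chin, peaks,
                                               chrom_sizes, k = 3,
                                               n_perm = 1000, seed = 1) {
  node_of <- .gene_node_map(chin)
  seed_nodes <- node_of[[lincrna]]
  hood <- if (is.null(seed_nodes)) integer(0) else
    k_hop_neighborhood(chin, seed_nodes, k)
  regions <- chin$nodes[chin$nodes$node_id %in% hood,
                        c("chrom", "start", "end"), drop = FALSE]
  if (nrow(regions) == 0 || nrow(peaks) == 0) {
    return(structure(list(observed = 0L, null_mean = NA_real_,
                          null_sd = NA_real_, z_score = NA_real_,
                          p_value = 1, n_perm = n_perm, seed = seed,
                          mode = "per_chromosome", alternative = "greater",
                          null = numeric(0)),
                     class = "permutation_result"))
  }
  permutation_colocalization(peaks, regions, chrom_sizes, n_perm = n_perm,
                             seed = seed, mode = "per_chromosome")
}

#' Compare CHART coverage between target-call groups
#'
#' Mean CHART coverage over genic regions per gene, contrasted between
#' named groups by Wilcoxon rank-sum tests (for example group 1, bound and
#' interacting, versus group 2, only bound).
#'
#' @param groups named list of character vectors of gene ids (a partition).
#' @param chart_track a [coverage_track()].
#' @param genes gene table.
#' @param flank genic-region extension (default 2500).
#' @return list with `values` (named list of per-gene coverage vectors) and
#'   `comparisons` (data.frame group_a, group_b, statistic, p_value; pairs
#'   with an empty group are skipped and noted with NA).
#' @export
coverage_contrast <- function(groups, chart_track, genes, flank = 2500) {
  stopifnot(length(groups) >= 2)
  values <- lapply(groups, function(ids) {
    sub <- genes[genes$gene_id %in% ids, , drop = FALSE]
    if (nrow(sub) == 0) return(numeric(0))
    gen <- genic_regions(sub, flank = flank)
    stats::setNames(vapply(seq_len(nrow(gen)), function(i)
      suppressWarnings(mean_coverage(chart_track, gen[i, ])), numeric(1)),
      gen$gene_id)
  })
  nm <- names(groups)
  pairs <- utils::combn(nm, 2)
  comp <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    if (length(values[[a]]) == 0 || length(values[[b]]) == 0) {
      message("group ", ifelse(length(values[[a]]) == 0, a, b),
              " is empty; comparison skipped")
      data.frame(group_a = a, group_b = b, statistic = NA_real_,
                 p_value = NA_real_)
    } else {
      res <- compare_groups(values[[a]], values[[b]])
      data.frame(group_a = a, group_b = b, statistic = res$statistic,
                 p_value = res$p_value)
    }
  })
  list(values = values, comparisons = do.call(rbind, comp))
}
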