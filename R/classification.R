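#' Assign lincRNAs to interaction categories C1-C5
#'
#' Deterministic decision cascade over chromatin interactions and RNAPII
#' binding:
#' \describe{
#'   \item{C1}{a ChIN edge joins the lincRNA's promoter node to a node
#'     carrying a protein-coding gene (multi-gene model with coding partner).}
#'   \item{C2}{no coding partner, but an edge to a node carrying any other
#'     annotated gene (other lincRNAs, antisense, miRNA, ...).}
#'   \item{C3}{edges exist but only to pure-DRE nodes (single-gene model).}
#'   \item{C4}{no chromatin interactions, but an RNAPII peak overlaps a
#'     promoter window by >= 1 bp (basal promoter).}
#'   \item{C5}{no interaction and no RNAPII promoter peak (not transcribed).}
#' }
#' The categories are mutually exclusive and exhaustive over the supplied
#' lincRNAs.
#'
#' @param lincrnas character vector of lincRNA gene ids (must be annotated).
#' @param chin a [build_chin()] result.
#' @param genes gene table.
#' @param rnapii_peaks interval table of RNAPII peak calls (narrowPeak).
#' @param expression optional [expression_set()]; used only to record max
#'   RPKM as evidence.
#' @param half_width promoter half-width for the C4 peak test.
#' @return data.frame with `gene_id`, `category`, and evidence columns
#'   `n_coding_partners`, `n_noncoding_partners`, `n_dre_partners`,
#'   `n_promoter_peaks`, `max_rpkm`.
#' @export
classify_categories <- function(lincrnas, chin, genes, rnapii_peaks = NULL,
                                expression = NULL, half_width = 2500) {
  missing <- setdiff(lincrnas, genes$gene_id)
  if (length(missing) > 0)
    stop("lincRNA(s) absent from annotation: ", paste(missing, collapse = ", "))
  bt <- stats::setNames(genes$biotype, genes$gene_id)
  node_of <- .gene_node_map(chin)
  adj <- rbind(as.matrix(chin$edges[, c("from", "to")]),
               as.matrix(chin$edges[, c("to", "from")]))
  node_genes <- chin$nodes$gene_ids
  node_role <- chin$nodes$role

  out <- lapply(lincrnas, function(g) {
    nids <- node_of[[g]]
    nb <- if (is.null(nids)) integer(0) else unique(adj[adj[, 1] %in% nids, 2])
    partner_genes <- setdiff(unique(unlist(node_genes[nb])), g)
    n_coding <- sum(bt[partner_genes] == "protein_coding")
    n_noncoding <- length(partner_genes) - n_coding
    n_dre <- sum(node_role[nb] == "dre")
    gene <- genes[genes$gene_id == g, , drop = FALSE]
    prom <- promoter_windows(gene, half_width = half_width)
    n_peaks <- if (is.null(rnapii_peaks) || nrow(rnapii_peaks) == 0) 0 else
      sum(.overlaps_any(rnapii_peaks, prom))
    max_rpkm <- if (!is.null(expression) && g %in% rownames(expression$values))
      max(expression$values[g, ]) else NA_real_
    category <- if (n_coding > 0) "C1"
      else if (n_noncoding > 0) "C2"
      else if (length(nb) > 0) "C3"
      else if (n_peaks > 0) "C4"
      else "C5"
    data.frame(gene_id = g, category = category,
               n_coding_partners = n_coding,
               n_noncoding_partners = n_noncoding,
               n_dre_partners = n_dre, n_promoter_peaks = n_peaks,
               max_rpkm = max_rpkm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Profile a promoter's H3K4me1/H3K4me3 chromatin state
#'
#' The +/- `half_width` window around the canonical TSS is divided into 20
#' bins of mean coverage per mark (left-to-right in genome coordinates);
#' the decision statistic is the mean coverage over the +/- 1 kb core,
#' `log2((me1_2kb + eps) / (me3_2kb + eps))`. Promoters with ratio > 0 are
#' `enhancer_like` (H3K4me1-dominant), otherwise `promoter_like` (a ratio
#' of exactly 0 is promoter-like: enhancer-like requires > 0). If both
#' 2-kb means are zero the ratio is undefined and flagged, and the label
#' falls back to promoter_like.
#'
#' @param gene single-row gene table.
#' @param me1_track,me3_track depth-normalized [coverage_track()]s for
#'   H3K4me1 and H3K4me3.
#' @param epsilon pseudocount guarding zero denominators (default 0.01).
#' @param half_width promoter window half-width (default 2500).
#' @param core_half_width half-width of the decision window (default 1000).
#' @param n_bins bin count for the profile (default 20).
#' @return list of class `promoter_profile`: gene_id, me1_bins, me3_bins,
#'   me1_2kb, me3_2kb, log2_ratio, label, ratio_defined.
#' @export
profile_promoter <- function(gene, me1_track, me3_track, epsilon = 0.01,
                             half_width = 2500, core_half_width = 1000,
                             n_bins = 20) {
  tss <- canonical_tss(gene)
  win <- data.frame(chrom = gene$chrom, start = max(tss - half_width, 0),
                    end = tss + half_width)
  core <- data.frame(chrom = gene$chrom, start = max(tss - core_half_width, 0),
                     end = tss + core_half_width)
  me1_bins <- suppressWarnings(binned_coverage(me1_track, win, n_bins))
  me3_bins <- suppressWarnings(binned_coverage(me3_track, win, n_bins))
  me1_2kb <- suppressWarnings(mean_coverage(me1_track, core))
  me3_2kb <- suppressWarnings(mean_coverage(me3_track, core))
  ratio_defined <- !(me1_2kb == 0 && me3_2kb == 0)
  log2_ratio <- if (ratio_defined)
    log2((me1_2kb + epsilon) / (me3_2kb + epsilon)) else NA_real_
  label <- if (ratio_defined && log2_ratio > 0) "enhancer_like" else "promoter_like"
  structure(list(gene_id = gene$gene_id, me1_bins = me1_bins,
                 me3_bins = me3_bins, me1_2kb = me1_2kb, me3_2kb = me3_2kb,
                 log2_ratio = log2_ratio, label = label,
                 ratio_defined = ratio_defined),
            class = "promoter_profile")
}

#' Profile many promoters into a flat table
#'
#' @param genes gene table (typically the C1 lincRNAs plus their coding
#'   partners).
#' @inheritParams profile_promoter
#' @return data.frame with 20 bin columns per mark, the 2-kb means,
#'   log2_ratio and label per gene.
#' @export
profile_promoters <- function(genes, me1_track, me3_track, epsilon = 0.01,
                              half_width = 2500) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    p <- profile_promoter(genes[i, ], me1_track, me3_track, epsilon,
                          half_width)
    row <- data.frame(gene_id = p$gene_id, stringsAsFactors = FALSE)
    for (j in 1:20) row[[sprintf("me1_bin%02d", j)]] <- p$me1_bins[j]
    for (j in 1:20) row[[sprintf("me3_bin%02d", j)]] <- p$me3_bins[j]
    row$me1_2kb <- p$me1_2kb; row$me3_2kb <- p$me3_2kb
    row$log2_ratio <- p$log2_ratio; row$label <- p$label
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify RNA binding sites by their chromatin-interaction context
#'
#' A peak overlapping a CTCF ChIN anchor that is itself co-bound by cohesin
#' is a TAD/sub-TAD-level site; otherwise a peak overlapping any RNAPII
#' ChIN anchor is transcriptionally involved; everything else is `other`.
#' Precedence is tad_subtad first, so the classes are mutually exclusive.
#'
#' @param peaks interval table of RNA (CHART/ChIRP) binding peaks.
#' @param ctcf_chin ChIN built from CTCF-mediated interaction clusters.
#' @param cohesin_peaks interval table of cohesin ChIP peaks.
#' @param rnapii_chin ChIN built from RNAPII-mediated interaction clusters.
#' @return character vector (`tad_subtad`, `rnapii_transcriptional`,
#'   `other`), one per peak.
#' @export
classify_binding_sites <- function(peaks, ctcf_chin, cohesin_peaks,
                                   rnapii_chin) {
  if (nrow(peaks) == 0) return(character(0))
  ctcf_nodes <- ctcf_chin$nodes
  cohesin_bound <- .overlaps_any(ctcf_nodes, cohesin_peaks)
  ctcf_cohesin_anchors <- ctcf_nodes[cohesin_bound, , drop = FALSE]
  is_tad <- .overlaps_any(peaks, ctcf_cohesin_anchors)
  is_rnapii <- .overlaps_any(peaks, rnapii_chin$nodes)
  ifelse(is_tad, "tad_subtad",
         ifelse(is_rnapii, "rnapii_transcriptional", "other"))
}

#' Cell-specificity of a gene's expression
#'
#' Fold change between the maximum expression over the target cell type's
#' samples (all subcellular fractions) and the maximum over all remaining
#' cell types, with a pseudocount; a gene is exclusively expressed in the
#' target cell when the fold change is >= `fc_threshold` (default 2).
#'
#' @param expression an [expression_set()].
#' @param gene gene id (must be a matrix row).
#' @param target_cell cell-type label.
#' @param epsilon pseudocount in RPKM (default 0.01).
#' @param fc_threshold specificity threshold (default 2).
#' @return list with `fold_change`, `is_specific`, `max_target`, `max_other`.
#' @export
cell_specificity <- function(expression, gene, target_cell, epsilon = 0.01,
                             fc_threshold = 2) {
  if (!gene %in% rownames(expression$values))
    stop("gene absent from expression matrix: ", gene)
  in_target <- expression$samples$cell_type == target_cell
  if (!any(in_target)) stop("no samples for cell type ", target_cell)
  if (all(in_target)) stop("no samples outside cell type ", target_cell)
  v <- expression$values[gene, ]
  max_target <- max(v[in_target])
  max_other <- max(v[!in_target])
  fc <- (max_target + epsilon) / (max_other + epsilon)
  list(fold_change = fc, is_specific = fc >= fc_threshold,
       max_target = max_target, max_other = max_other)
}
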