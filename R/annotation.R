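#' The fixed ChromHMM state vocabulary, highest priority first
#'
#' When a DRE overlaps several chromatin-state segments it takes the state
#' of highest priority: strong enhancer, weak enhancer, transcriptional
#' transition/elongation, weak transcribed, insulator, polycomb-repressed,
#' heterochromatin/repetitive; anything else is `others`.
#'
#' @return character vector of the 8 states in priority order (rank 1 first).
#' @export
chrom_state_vocabulary <- function() {
  c("strong_enhancer", "weak_enhancer", "txn_transition_elongation",
    "weak_transcribed", "insulator", "polycomb_repressed",
    "heterochromatin_repetitive", "others")
}

#' Promoter windows of a gene
#'
#' One symmetric window `[TSS - half_width, TSS + half_width)` per distinct
#' annotated TSS (default 2.5 kb up- and downstream). Windows are symmetric,
#' so strand affects only which positions are TSSs, never window shape.
#'
#' @param gene single-row gene table (or a multi-row table: all genes'
#'   windows are returned, with a `gene_id` column).
#' @param half_width window half-width in bp (default 2500).
#' @param chrom_sizes optional named vector; windows are clipped to
#'   chromosome bounds when given.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `tss`.
#' @export
promoter_windows <- function(gene, half_width = 2500, chrom_sizes = NULL) {
  out <- do.call(rbind, lapply(seq_len(nrow(gene)), function(i) {
    tss <- sort(unique(gene$tss[[i]]))
    data.frame(gene_id = gene$gene_id[i], chrom = gene$chrom[i],
               start = pmax(tss - half_width, 0), end = tss + half_width,
               tss = tss, stringsAsFactors = FALSE)
  }))
  if (!is.null(chrom_sizes)) out <- clip_to_chrom(out, chrom_sizes)
  rownames(out) <- NULL
  out
}

#' Genic region of a gene (extended gene body)
#'
#' The gene body extended by `flank` bp on both sides (default +/- 2.5 kb),
#' clipped at chromosome bounds when sizes are given.
#'
#' @param gene gene table (one or more rows).
#' @param flank extension in bp (default 2500).
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @export
genic_regions <- function(gene, flank = 2500, chrom_sizes = NULL) {
  out <- data.frame(gene_id = gene$gene_id, chrom = gene$chrom,
                    start = pmax(gene$start - flank, 0),
                    end = gene$end + flank, stringsAsFactors = FALSE)
  if (!is.null(chrom_sizes)) out <- clip_to_chrom(out, chrom_sizes)
  rownames(out) <- NULL
  out
}

#' Label DREs with ChromHMM states under the fixed priority
#'
#' Each DRE receives the highest-priority vocabulary state among all
#' segmentation segments it overlaps by >= 1 bp; DREs overlapping none of
#' the listed states are `others`. Segmentation state names are translated
#' to the vocabulary through an explicit mapping table; unmapped names are
#' an error (never guessed by substring).
#'
#' @param dres interval table of DRE regions (ChIN nodes with role `dre`).
#' @param segmentation interval table with a `name` column of state labels
#'   (ChromHMM BED column 4).
#' @param state_map data.frame with `input_label`, `vocab_label` columns
#'   (see [read_state_map()]); `NULL` if the segmentation already uses the
#'   vocabulary.
#' @return character vector of vocabulary states, one per DRE row.
#' @export
label_dre_states <- function(dres, segmentation, state_map = NULL) {
  vocab <- chrom_state_vocabulary()
  labels <- segmentation$name
  if (!is.null(state_map)) {
    idx <- match(labels, state_map$input_label)
    if (any(is.na(idx)))
      stop("segmentation state(s) with no vocabulary mapping: ",
           paste(unique(labels[is.na(idx)]), collapse = ", "))
    labels <- state_map$vocab_label[idx]
  }
  bad <- setdiff(unique(labels), vocab)
  if (length(bad) > 0)
    stop("state(s) outside the fixed vocabulary: ", paste(bad, collapse = ", "))
  rank <- match(labels, vocab)
  if (nrow(dres) == 0) return(character(0))
  out <- rep("others", nrow(dres))
  if (nrow(segmentation) > 0) {
    dg <- .gi_to_granges(dres)
    sg <- .gi_to_granges(segmentation)
    hits <- suppressWarnings(GenomicRanges::findOverlaps(dg, sg))
    if (length(hits) > 0) {
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      # "others" segments never beat a listed state: they rank last anyway
      best <- tapply(rank[sh], qh, min)
      out[as.integer(names(best))] <- vocab[best]
    }
  }
  out
}

#' Super-enhancer / DRE overlap and SE-linked lincRNAs
#'
#' Pairs each super-enhancer with every DRE node it overlaps by >= 1 bp,
#' and flags a lincRNA as SE-linked iff some ChIN edge joins its promoter
#' node to a DRE node overlapping a super-enhancer.
#'
#' @param chin a [build_chin()] result.
#' @param super_enhancers interval table of SE regions.
#' @param genes gene table (used to identify lincRNAs).
#' @return list with `se_map` (data.frame se_index, node_id) and
#'   `linc_flags` (data.frame gene_id, se_linked).
#' @export
super_enhancer_overlap <- function(chin, super_enhancers, genes) {
  nodes <- chin$nodes
  dre_nodes <- nodes[nodes$role == "dre", , drop = FALSE]
  se_map <- data.frame(se_index = integer(), node_id = integer())
  if (nrow(dre_nodes) > 0 && nrow(super_enhancers) > 0) {
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(.gi_to_granges(super_enhancers),
                                  .gi_to_granges(dre_nodes)))
    se_map <- data.frame(se_index = S4Vectors::queryHits(hits),
                         node_id = dre_nodes$node_id[S4Vectors::subjectHits(hits)])
  }
  se_dres <- unique(se_map$node_id)
  adj <- rbind(as.matrix(chin$edges[, c("from", "to")]),
               as.matrix(chin$edges[, c("to", "from")]))
  lincs <- genes$gene_id[genes$biotype == "lincRNA"]
  node_of <- .gene_node_map(chin)
  se_linked <- vapply(lincs, function(g) {
    nids <- node_of[[g]]
    if (is.null(nids)) return(FALSE)
    nb <- adj[adj[, 1] %in% nids, 2]
    any(nb %in% se_dres)
  }, logical(1))
  list(se_map = se_map,
       linc_flags = data.frame(gene_id = lincs, se_linked = unname(se_linked),
                               stringsAsFactors = FALSE))
}

# gene_id -> integer vector of node ids carrying that gene
.gene_node_map <- function(chin) {
  ids <- chin$nodes$gene_ids
  n <- lengths(ids)
  if (sum(n) == 0) return(list())
  split(rep(chin$nodes$node_id, n), unlist(ids))
}

#' Map GWAS SNPs to ChIN genes and interaction-inferred targets
#'
#' Direct hit: the SNP lies inside the extended (+/- 2.5 kb) gene body of a
#' gene present in the ChIN. Interaction-inferred target: for a SNP inside a
#' lincRNA genic region (or inside a DRE node interacting with a lincRNA
#' promoter), every gene whose promoter node is adjacent to the hit node in
#' the ChIN is a potential target of the SNP.
#'
#' @param snps SNP table (see [read_snps()]).
#' @param chin a [build_chin()] result.
#' @param genes gene table.
#' @param flank genic-region extension (default 2500).
#' @return data.frame with one row per (rsid, kind, gene) where kind is
#'   `direct` or `inferred`.
#' @export
map_snps_to_targets <- function(snps, chin, genes, flank = 2500) {
  chin_gene_ids <- unique(unlist(chin$nodes$gene_ids))
  chin_genes <- genes[genes$gene_id %in% chin_gene_ids, , drop = FALSE]
  gen <- genic_regions(chin_genes, flank = flank)
  node_of <- .gene_node_map(chin)
  adj <- rbind(as.matrix(chin$edges[, c("from", "to")]),
               as.matrix(chin$edges[, c("to", "from")]))
  dre_nodes <- chin$nodes[chin$nodes$role == "dre", , drop = FALSE]
  linc_ids <- chin_genes$gene_id[chin_genes$biotype == "lincRNA"]
  # DREs adjacent to at least one lincRNA promoter node
  linc_nodes <- unique(unlist(node_of[linc_ids]))
  linc_adj_dres <- intersect(adj[adj[, 1] %in% linc_nodes, 2],
                             dre_nodes$node_id)

  genes_on <- function(nids) {
    sort(unique(unlist(chin$nodes$gene_ids[match(nids, chin$nodes$node_id)])))
  }
  rows <- list()
  known_chroms <- unique(c(gen$chrom, chin$nodes$chrom))
  for (i in seq_len(nrow(snps))) {
    s <- snps[i, ]
    if (!s$chrom %in% known_chroms) {
      warning("SNP ", s$rsid, " on unknown chromosome ", s$chrom, "; skipped")
      next
    }
    hit_genes <- gen$gene_id[gen$chrom == s$chrom & gen$start <= s$start &
                               gen$end > s$start]
    for (g in hit_genes)
      rows[[length(rows) + 1]] <- data.frame(rsid = s$rsid, kind = "direct",
                                             gene_id = g, via = NA_character_)
    # inferred targets via lincRNA genic hits
    linc_hits <- intersect(hit_genes, linc_ids)
    for (lg in linc_hits) {
      nb <- adj[adj[, 1] %in% node_of[[lg]], 2]
      for (t in setdiff(genes_on(nb), lg))
        rows[[length(rows) + 1]] <- data.frame(rsid = s$rsid, kind = "inferred",
                                               gene_id = t, via = lg)
    }
    # inferred targets via DREs interacting with lincRNA promoters
    dre_hits <- dre_nodes$node_id[dre_nodes$chrom == s$chrom &
                                    dre_nodes$start <= s$start &
                                    dre_nodes$end > s$start]
    dre_hits <- intersect(dre_hits, linc_adj_dres)
    for (d in dre_hits) {
      nb <- adj[adj[, 1] == d, 2]
      for (t in genes_on(nb))
        rows[[length(rows) + 1]] <- data.frame(rsid = s$rsid, kind = "inferred",
                                               gene_id = t,
                                               via = paste0("node_", d))
    }
  }
  if (length(rows) == 0)
    return(data.frame(rsid = character(), kind = character(),
                      gene_id = character(), via = character()))
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
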