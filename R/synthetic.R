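#' Generate a synthetic genome annotation
#'
#' Places `n_genes` non-overlapping gene bodies on `n_chrom` chromosomes
#' using an even slot layout with generous intergenic margins, so that
#' promoter windows (+/- 2.5 kb) of distinct genes never overlap and
#' lincRNAs are intergenic by construction. The last ~10% of every
#' chromosome is kept gene-free as placement space for distal regulatory
#' elements. Biotypes follow `biotype_mix` (default 60% protein_coding,
#' 25% lincRNA, 10% antisense, 5% miRNA). Each gene gets 1-3 transcripts
#' whose TSSs all lie within the gene body.
#'
#' @param n_chrom number of chromosomes (default 2).
#' @param chrom_length chromosome length in bp (default 1e6).
#' @param n_genes total gene count (default 200).
#' @param seed RNG seed; the same seed reproduces the annotation exactly.
#' @param biotype_mix named proportions over the biotype vocabulary.
#' @return list with `genes` (gene table), `chrom_sizes` (named vector),
#'   and `dre_space` (per-chromosome gene-free interval).
#' @export
make_genome <- function(n_chrom = 2, chrom_length = 1e6, n_genes = 200,
                        seed = 1,
                        biotype_mix = c(protein_coding = 0.60,
                                        lincRNA = 0.25, antisense = 0.10,
                                        miRNA = 0.05)) {
  per_chrom <- ceiling(n_genes / n_chrom)
  gene_space <- floor(chrom_length * 0.9)
  pitch <- floor(gene_space / per_chrom)
  if (pitch < 5000)
    stop("infeasible packing: need >= 50 kb of chromosome per 10 genes; ",
         "increase chrom_length or reduce n_genes")
  len_max <- min(3000, floor(pitch / 3))
  len_min <- min(1000, len_max)
  margin <- min(3000, floor((pitch - len_max) / 2))
  chrom_sizes <- stats::setNames(rep(chrom_length, n_chrom),
                                 sprintf("chr%d", seq_len(n_chrom)))
  if (n_genes == 0) {
    g <- .empty_gene_table()
    return(list(genes = g, chrom_sizes = chrom_sizes,
                dre_space = data.frame(chrom = names(chrom_sizes),
                                       start = gene_space + 5000,
                                       end = chrom_length - 1000)))
  }
  counts <- floor(biotype_mix * n_genes)
  counts[1] <- counts[1] + (n_genes - sum(counts))
  .with_seed(seed, {
    biotypes <- sample(rep(names(counts), counts))
    prefix <- c(protein_coding = "PC", lincRNA = "LNC", antisense = "AS",
                miRNA = "MIR", sense_overlapping = "SO",
                sense_intronic = "SI", processed_transcript = "PT",
                others = "OT")
    ids_by_bt <- stats::ave(seq_along(biotypes), biotypes, FUN = seq_along)
    gene_id <- sprintf("%s%04d", prefix[biotypes], ids_by_bt)
    rows <- lapply(seq_len(n_genes), function(i) {
      ci <- ((i - 1) %% n_chrom) + 1
      slot <- (i - 1) %/% n_chrom
      len <- sample(len_min:len_max, 1)
      lo <- slot * pitch + margin
      hi <- slot * pitch + pitch - margin - len
      start <- lo + sample.int(max(hi - lo, 1), 1) - 1
      strand <- sample(c("+", "-"), 1)
      n_tx <- sample(1:3, 1)
      tss0 <- if (strand == "-") start + len - 1 else start
      extra <- if (n_tx > 1) {
        off <- sample.int(max(floor(len / 2), 2) - 1, n_tx - 1)
        if (strand == "-") tss0 - off else tss0 + off
      } else integer(0)
      list(chrom = names(chrom_sizes)[ci], start = start, end = start + len,
           strand = strand, tss = sort(unique(c(tss0, extra))))
    })
    genes <- data.frame(gene_id = gene_id, name = gene_id,
                        biotype = biotypes,
                        chrom = vapply(rows, `[[`, "", "chrom"),
                        start = vapply(rows, `[[`, 0, "start"),
                        end = vapply(rows, `[[`, 0, "end"),
                        strand = vapply(rows, `[[`, "", "strand"),
                        stringsAsFactors = FALSE)
    genes$tss <- lapply(rows, `[[`, "tss")
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
    rownames(genes) <- NULL
    class(genes) <- c("gene_table", "data.frame")
    list(genes = genes, chrom_sizes = chrom_sizes,
         dre_space = data.frame(chrom = names(chrom_sizes),
                                start = gene_space + 5000,
                                end = chrom_length - 1000,
                                stringsAsFactors = FALSE))
  })
}

#' Sample a scale-free graph with a target degree exponent
#'
#' Configuration-model generation: degrees are drawn from an exact discrete
#' power law (Zipf) with the target exponent, wired by stub matching and
#' simplified to a simple graph. The fitted exponent of the result
#' (discrete MLE, KS xmin) recovers the target.
#'
#' @param n number of vertices.
#' @param exponent target power-law exponent (default 2.5).
#' @param kmax truncation of the degree law (default 300).
#' @param seed RNG seed.
#' @return an igraph undirected simple graph.
#' @export
make_scalefree_graph <- function(n, exponent = 2.5, kmax = 300, seed = 1) {
  .with_seed(seed, {
    k <- seq_len(kmax)
    d <- sample(k, n, replace = TRUE, prob = k^(-exponent))
    if (sum(d) %% 2 == 1) d[1] <- d[1] + 1
    igraph::simplify(igraph::sample_degseq(d, method = "configuration"))
  })
}

#' Generate interaction clusters with planted lincRNA categories
#'
#' Wires edges so that each lincRNA lands in its planted category under the
#' C1-C5 decision cascade: C1 lincRNAs get anchors to protein-coding
#' promoters, C2 to non-coding (antisense/miRNA) promoters, C3 to distal
#' regulatory elements placed in gene-free space; C4 and C5 lincRNAs get no
#' anchors at all (C4 is distinguished later by an RNAPII promoter peak
#' from [make_tracks()]). Additional promoter-promoter clusters among
#' protein-coding genes follow a scale-free graph targeting `exponent`
#' (see [make_scalefree_graph()]), emitted with 1-3 parallel clusters per
#' edge; extra coding-DRE clusters diversify the DRE side.
#'
#' @param genome a [make_genome()] result.
#' @param category_targets named integer vector of desired C1-C5 lincRNA
#'   counts; `NULL` plants a default split over all lincRNAs (C5 largest,
#'   C1 largest among the interacting categories).
#' @param exponent target degree exponent of the coding-coding subgraph.
#' @param n_dre_edges extra coding-DRE clusters (default 120).
#' @param n_dre_dre_edges extra DRE-DRE clusters among already-placed DREs
#'   (default 100).
#' @param seed RNG seed.
#' @return list with `clusters` (BEDPE-style table), `truth` (data.frame
#'   gene_id, category for every lincRNA), `partners` (named list: planted
#'   partner gene ids per lincRNA), `exponent`.
#' @export
make_interactions <- function(genome, category_targets = NULL,
                              exponent = 2.5, n_dre_edges = 120,
                              n_dre_dre_edges = 100, seed = 1) {
  genes <- genome$genes
  lincs <- genes$gene_id[genes$biotype == "lincRNA"]
  coding <- genes$gene_id[genes$biotype == "protein_coding"]
  noncoding <- genes$gene_id[genes$biotype %in% c("antisense", "miRNA")]
  nl <- length(lincs)
  if (is.null(category_targets)) {
    c1 <- round(0.28 * nl); c2 <- round(0.10 * nl); c3 <- round(0.10 * nl)
    c4 <- round(0.12 * nl)
    category_targets <- c(C1 = c1, C2 = c2, C3 = c3, C4 = c4,
                          C5 = nl - c1 - c2 - c3 - c4)
  }
  if (sum(category_targets) != nl)
    stop("category targets must sum to the lincRNA count (", nl, ")")
  if (category_targets["C1"] > 0 && length(coding) == 0)
    stop("C1 targets need protein-coding genes")
  if (category_targets["C2"] > 0 && length(noncoding) == 0)
    stop("C2 targets need antisense/miRNA genes")

  anchor_at_promoter <- function(g, jitter = 0) {
    row <- genes[genes$gene_id == g, ]
    tss <- canonical_tss(row)
    s <- tss - 250 + jitter
    data.frame(chrom = row$chrom, start = s, end = s + 500)
  }
  .with_seed(seed, {
    cat_vec <- sample(rep(names(category_targets), category_targets))
    truth <- data.frame(gene_id = lincs, category = cat_vec,
                        stringsAsFactors = FALSE)
    partners <- stats::setNames(vector("list", nl), lincs)
    cl <- list()
    add_cluster <- function(a, b, pet = 1) {
      cl[[length(cl) + 1]] <<- data.frame(
        chrom_a = a$chrom, start_a = a$start, end_a = a$end,
        chrom_b = b$chrom, start_b = b$start, end_b = b$end,
        pet_count = pet, stringsAsFactors = FALSE)
    }
    # DRE anchor supply from the reserved gene-free space
    dre_pool <- do.call(rbind, lapply(seq_len(nrow(genome$dre_space)), function(i) {
      sp <- genome$dre_space[i, ]
      starts <- seq(sp$start, sp$end - 600, by = 1200)
      data.frame(chrom = sp$chrom, start = starts, end = starts + 500)
    }))
    dre_cursor <- 0L
    next_dre <- function() {
      dre_cursor <<- dre_cursor + 1L
      if (dre_cursor > nrow(dre_pool)) stop("DRE pool exhausted")
      dre_pool[dre_cursor, ]
    }
    for (i in seq_len(nl)) {
      g <- lincs[i]
      cat_i <- truth$category[i]
      if (cat_i == "C1") {
        p <- sample(coding, min(sample(1:3, 1), length(coding)))
        for (pg in p) add_cluster(anchor_at_promoter(g),
                                  anchor_at_promoter(pg),
                                  pet = 1 + stats::rpois(1, 2))
        partners[[g]] <- p
      } else if (cat_i == "C2") {
        p <- sample(noncoding, 1)
        add_cluster(anchor_at_promoter(g), anchor_at_promoter(p),
                    pet = 1 + stats::rpois(1, 2))
        partners[[g]] <- p
      } else if (cat_i == "C3") {
        d <- next_dre()
        add_cluster(anchor_at_promoter(g), d, pet = 1 + stats::rpois(1, 1))
        partners[[g]] <- sprintf("%s:%d-%d", d$chrom, d$start, d$end)
      }
    }
    # scale-free coding-coding promoter clusters
    if (length(coding) >= 10) {
      sf <- make_scalefree_graph(length(coding), exponent = exponent,
                                 kmax = min(100, length(coding) - 1),
                                 seed = sample.int(1e6, 1))
      em <- igraph::as_edgelist(sf)
      for (r in seq_len(nrow(em))) {
        ga <- coding[em[r, 1]]; gb <- coding[em[r, 2]]
        for (dup in seq_len(sample(2:4, 1))) {
          # small jitter: anchors at one promoter stay mutually overlapping,
          # so a gene's promoter forms a single merged node
          ja <- sample(-200:200, 1); jb <- sample(-200:200, 1)
          add_cluster(anchor_at_promoter(ga, ja), anchor_at_promoter(gb, jb),
                      pet = 1 + stats::rpois(1, 3))
        }
      }
    }
    # coding-DRE clusters
    n_dre_edges <- min(n_dre_edges, nrow(dre_pool) - dre_cursor)
    if (length(coding) > 0 && n_dre_edges > 0) {
      for (r in seq_len(n_dre_edges)) {
        add_cluster(anchor_at_promoter(sample(coding, 1)), next_dre(),
                    pet = 1 + stats::rpois(1, 1))
      }
    }
    # DRE-DRE clusters among the DREs already in play (skipping the C3
    # plantings, whose lincRNAs must stay single-gene-model pure)
    used_dres <- dre_pool[seq_len(dre_cursor), , drop = FALSE]
    n_c3 <- sum(cat_vec == "C3")
    free_dres <- used_dres[setdiff(seq_len(dre_cursor), seq_len(n_c3)), ,
                           drop = FALSE]
    if (nrow(free_dres) >= 2 && n_dre_dre_edges > 0) {
      for (r in seq_len(n_dre_dre_edges)) {
        pick <- sample.int(nrow(free_dres), 2)
        add_cluster(free_dres[pick[1], ], free_dres[pick[2], ],
                    pet = 1 + stats::rpois(1, 1))
      }
    }
    clusters <- do.call(rbind, cl)
    clusters$self_contact <- FALSE
    rownames(clusters) <- NULL
    list(clusters = clusters, truth = truth, partners = partners,
         exponent = exponent)
  })
}

#' Generate histone coverage tracks and RNAPII peaks with planted labels
#'
#' Every labeled promoter receives Poisson coverage in 50-bp bins across
#' its +/- 2.5 kb window on both tracks: enhancer-like promoters get
#' H3K4me1 at `snr` times the base rate and H3K4me3 at the base rate,
#' promoter-like promoters the reverse. RNAPII narrowPeak calls are
#' emitted at the promoters listed in `peak_genes` (the planted C1-C4
#' lincRNAs and interacting partners): C5 means no peak.
#'
#' @param genome a [make_genome()] result.
#' @param labels named character vector, gene_id -> `enhancer_like` /
#'   `promoter_like`.
#' @param peak_genes gene ids that get an RNAPII promoter peak.
#' @param snr signal-to-noise ratio between dominant and recessive mark
#'   (must be > 1 for recoverable labels; 1 plants pure chance).
#' @param base_rate Poisson mean per 50-bp bin for the recessive mark.
#' @param seed RNG seed.
#' @return list with `me1`, `me3` ([coverage_track()]s, library depth set
#'   to total signal) and `rnapii_peaks` (interval table).
#' @export
make_tracks <- function(genome, labels, peak_genes = character(0), snr = 4,
                        base_rate = 5, seed = 1) {
  stopifnot(snr >= 1)
  genes <- genome$genes
  bin <- 50
  .with_seed(seed, {
    rows_me1 <- list(); rows_me3 <- list()
    for (g in names(labels)) {
      row <- genes[genes$gene_id == g, ]
      tss <- canonical_tss(row)
      starts <- seq(max(tss - 2500, 0), tss + 2500 - bin, by = bin)
      lam1 <- if (labels[[g]] == "enhancer_like") base_rate * snr else base_rate
      lam3 <- if (labels[[g]] == "enhancer_like") base_rate else base_rate * snr
      rows_me1[[g]] <- data.frame(chrom = row$chrom, start = starts,
                                  end = starts + bin,
                                  value = stats::rpois(length(starts), lam1))
      rows_me3[[g]] <- data.frame(chrom = row$chrom, start = starts,
                                  end = starts + bin,
                                  value = stats::rpois(length(starts), lam3))
    }
    mk <- function(rows) {
      cov <- if (length(rows) == 0)
        NULL else do.call(rbind, rows)
      coverage_track(cov, library_depth = if (is.null(cov)) NULL else
        sum(cov$value * (cov$end - cov$start)))
    }
    peaks <- if (length(peak_genes) > 0) {
      do.call(rbind, lapply(peak_genes, function(g) {
        row <- genes[genes$gene_id == g, ]
        tss <- canonical_tss(row)
        data.frame(chrom = row$chrom, start = max(tss - 200, 0),
                   end = tss + 200, name = paste0("rnapii_", g),
                   signal = round(stats::runif(1, 5, 50), 2),
                   stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 name = character(), signal = numeric())
    }
    list(me1 = mk(rows_me1), me3 = mk(rows_me3), rnapii_peaks = peaks)
  })
}

#' Generate an expression matrix with planted correlations and specificity
#'
#' Log-normal RPKM baselines over a sample design of `n_cells` cell types
#' (the first two carry all six subcellular fractions; the rest one or two
#' whole-cell samples, totalling 108 samples at the defaults). Listed gene
#' pairs are drawn from a bivariate normal in log space with the planted
#' correlation; planted specific genes are forced above the 2-fold
#' cell-exclusivity rule in their target cell.
#'
#' @param genome a [make_genome()] result.
#' @param pair_correlations data.frame `gene_a`, `gene_b`, `r` (each gene in
#'   at most one pair; r in (-1, 1)).
#' @param specific_genes data.frame `gene_id`, `cell_type`.
#' @param n_cells number of cell types (default 55).
#' @param seed RNG seed.
#' @return an [expression_set()].
#' @export
make_expression <- function(genome, pair_correlations = NULL,
                            specific_genes = NULL, n_cells = 55, seed = 1) {
  genes <- genome$genes$gene_id
  if (!is.null(pair_correlations)) {
    if (any(abs(pair_correlations$r) >= 1))
      stop("planted correlations must lie in (-1, 1)")
    pg <- c(pair_correlations$gene_a, pair_correlations$gene_b)
    if (anyDuplicated(pg) > 0)
      stop("each gene may appear in at most one planted pair")
    missing <- setdiff(pg, genes)
    if (length(missing) > 0)
      stop("planted pair gene(s) absent from annotation: ",
           paste(missing, collapse = ", "))
  }
  fractions <- c("cell", "chromatin", "nucleus", "nucleolus",
                 "nucleoplasm", "cytosol")
  cells <- sprintf("cell%02d", seq_len(n_cells))
  meta <- list()
  for (i in seq_len(n_cells)) {
    fr <- if (i <= 2) fractions
      else if (i <= min(45, n_cells)) c("cell", "nucleus")
      else "cell"
    meta[[i]] <- data.frame(sample_id = paste(cells[i], fr, sep = "_"),
                            cell_type = cells[i], fraction = fr,
                            stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  n_samp <- nrow(meta)
  .with_seed(seed, {
    mu <- stats::rnorm(length(genes), mean = 3, sd = 1.5)
    logx <- matrix(stats::rnorm(length(genes) * n_samp, mean = mu, sd = 1),
                   nrow = length(genes), dimnames = list(genes, meta$sample_id))
    if (!is.null(pair_correlations)) {
      for (i in seq_len(nrow(pair_correlations))) {
        a <- pair_correlations$gene_a[i]; b <- pair_correlations$gene_b[i]
        r <- pair_correlations$r[i]
        za <- stats::rnorm(n_samp)
        zb <- r * za + sqrt(1 - r^2) * stats::rnorm(n_samp)
        logx[a, ] <- mu[match(a, genes)] + za
        logx[b, ] <- mu[match(b, genes)] + zb
      }
    }
    values <- 2^logx
    if (!is.null(specific_genes)) {
      for (i in seq_len(nrow(specific_genes))) {
        g <- specific_genes$gene_id[i]
        tc <- specific_genes$cell_type[i]
        if (!tc %in% meta$cell_type)
          stop("unknown target cell type: ", tc)
        in_t <- meta$cell_type == tc
        values[g, !in_t] <- stats::runif(sum(!in_t), 0, 1)
        values[g, in_t] <- stats::runif(sum(in_t), 5, 15)
      }
    }
    expression_set(values, meta)
  })
}

#' Generate auxiliary inputs: ChromHMM, super-enhancers, CHART, CTCF, SNPs
#'
#' ChromHMM-style segmentation tiles every chromosome with the 8-state
#' vocabulary under cell-line-style input labels plus a translation table.
#' Super-enhancers are placed over a subset of ChIN DRE nodes (extended),
#' plus unrelated background regions. CHART binding peaks fall inside the
#' k-hop neighborhood of the focus lincRNA with probability
#' `enrichment_factor` times the background area rate (factor 1 = uniform
#' null). CTCF interaction clusters and cohesin peaks support binding-site
#' classification, and GWAS-style SNPs are planted inside chosen lincRNA
#' gene bodies.
#'
#' @param genome a [make_genome()] result.
#' @param chin a [build_chin()] result on the generated clusters.
#' @param focus_lincrna lincRNA whose k-hop neighborhood receives enriched
#'   CHART peaks.
#' @param snp_lincrnas lincRNAs that receive a planted SNP in their gene
#'   body (default: none).
#' @param enrichment_factor CHART peak enrichment inside the neighborhood
#'   (>= 1; default 10).
#' @param k hop radius for the enriched neighborhood (default 3).
#' @param n_chart_peaks total CHART peaks (default 400 — abundant-RNA
#'   binding density at desk scale, so a planted 10-fold enrichment stands
#'   clear of the permutation null).
#' @param n_snps_background random background SNPs (default 20).
#' @param seed RNG seed.
#' @return list with `segmentation`, `state_map`, `super_enhancers`,
#'   `chart_peaks`, `ctcf_clusters`, `cohesin_peaks`, `snps`.
#' @export
make_aux <- function(genome, chin, focus_lincrna = NULL,
                     snp_lincrnas = character(0), enrichment_factor = 10,
                     k = 3, n_chart_peaks = 400, n_snps_background = 20,
                     seed = 1) {
  stopifnot(enrichment_factor >= 1)
  sizes <- genome$chrom_sizes
  genes <- genome$genes
  vocab <- chrom_state_vocabulary()
  input_labels <- c("1_Strong_Enhancer", "2_Weak_Enhancer", "3_Txn_Elongation",
                    "4_Weak_Txn", "5_Insulator", "6_Polycomb",
                    "7_Heterochrom", "8_Other")
  state_map <- data.frame(input_label = input_labels, vocab_label = vocab,
                          stringsAsFactors = FALSE)
  .with_seed(seed, {
    seg <- do.call(rbind, lapply(names(sizes), function(ch) {
      pos <- 0; rows <- list()
      while (pos < sizes[[ch]]) {
        w <- sample(500:2000, 1)
        end <- min(pos + w, sizes[[ch]])
        rows[[length(rows) + 1]] <- data.frame(
          chrom = ch, start = pos, end = end,
          name = sample(input_labels, 1,
                        prob = c(2, 3, 2, 3, 1.5, 1.5, 2, 4)),
          stringsAsFactors = FALSE)
        pos <- end
      }
      do.call(rbind, rows)
    }))
    dres <- chin$nodes[chin$nodes$role == "dre", , drop = FALSE]
    ses <- NULL
    if (nrow(dres) > 0) {
      picked <- dres[sample.int(nrow(dres), min(10, nrow(dres))), , drop = FALSE]
      ses <- data.frame(chrom = picked$chrom,
                        start = pmax(picked$start - 5000, 0),
                        end = picked$end + 5000)
    }
    bg_ses <- data.frame(
      chrom = sample(names(sizes), 5, replace = TRUE),
      start = floor(stats::runif(5, 0, min(sizes) - 20000)))
    bg_ses$end <- bg_ses$start + 15000
    se_parts <- bg_ses[, c("chrom", "start", "end")]
    if (!is.null(ses))
      se_parts <- rbind(ses[, c("chrom", "start", "end")], se_parts)
    ses <- merge_intervals(se_parts)
    ses$name <- sprintf("SE_%03d", seq_len(nrow(ses)))

    # CHART peaks: enriched in the k-hop neighborhood of the focus lincRNA
    hood_regions <- NULL
    if (!is.null(focus_lincrna)) {
      node_of <- .gene_node_map(chin)
      sn <- node_of[[focus_lincrna]]
      if (!is.null(sn)) {
        hood <- k_hop_neighborhood(chin, sn, k)
        hood_regions <- chin$nodes[chin$nodes$node_id %in% hood,
                                   c("chrom", "start", "end")]
      }
    }
    peak_w <- 300
    genome_len <- sum(sizes)
    place_uniform <- function(n) {
      ch <- sample(names(sizes), n, replace = TRUE,
                   prob = sizes / genome_len)
      s <- floor(stats::runif(n, 0, sizes[ch] - peak_w))
      data.frame(chrom = ch, start = s, end = s + peak_w,
                 stringsAsFactors = FALSE)
    }
    if (!is.null(hood_regions) && nrow(hood_regions) > 0) {
      area <- sum(hood_regions$end - hood_regions$start)
      p_in <- enrichment_factor * area /
        (enrichment_factor * area + (genome_len - area))
      inside <- stats::runif(n_chart_peaks) < p_in
      n_in <- sum(inside)
      rows_in <- if (n_in > 0) {
        ri <- sample.int(nrow(hood_regions), n_in, replace = TRUE,
                         prob = hood_regions$end - hood_regions$start)
        ctr <- floor(stats::runif(n_in, hood_regions$start[ri],
                                  hood_regions$end[ri]))
        data.frame(chrom = hood_regions$chrom[ri],
                   start = pmax(ctr - peak_w %/% 2, 0),
                   end = pmax(ctr - peak_w %/% 2, 0) + peak_w,
                   stringsAsFactors = FALSE)
      } else NULL
      chart <- rbind(rows_in, place_uniform(n_chart_peaks - n_in))
    } else {
      chart <- place_uniform(n_chart_peaks)
    }
    chart <- chart[order(chart$chrom, chart$start), , drop = FALSE]
    chart$name <- sprintf("chart_%03d", seq_len(nrow(chart)))
    rownames(chart) <- NULL

    # CTCF interaction clusters + cohesin peaks over half the CTCF anchors
    n_ctcf <- 40
    a1 <- place_uniform(n_ctcf); a2 <- place_uniform(n_ctcf)
    ctcf <- data.frame(chrom_a = a1$chrom, start_a = a1$start, end_a = a1$end,
                       chrom_b = a2$chrom, start_b = a2$start, end_b = a2$end,
                       pet_count = 1 + stats::rpois(n_ctcf, 2),
                       self_contact = FALSE, stringsAsFactors = FALSE)
    anchors <- rbind(a1, a2)
    coh_idx <- sample.int(nrow(anchors), nrow(anchors) %/% 2)
    cohesin <- anchors[coh_idx, , drop = FALSE]
    cohesin$name <- sprintf("cohesin_%03d", seq_along(coh_idx))
    rownames(cohesin) <- NULL

    planted_snps <- NULL
    if (length(snp_lincrnas) > 0) {
      rows <- genes[match(snp_lincrnas, genes$gene_id), , drop = FALSE]
      pos <- floor(stats::runif(nrow(rows), rows$start, rows$end - 1))
      planted_snps <- data.frame(
        rsid = sprintf("rs%07d", sample.int(9e6, nrow(rows))),
        chrom = rows$chrom, start = pos, end = pos + 1,
        trait = "planted_trait", stringsAsFactors = FALSE)
    }
    bg_pos <- place_uniform(n_snps_background)
    bg_snps <- data.frame(
      rsid = sprintf("rs%07d", sample.int(9e6, n_snps_background)),
      chrom = bg_pos$chrom, start = bg_pos$start, end = bg_pos$start + 1,
      trait = "background_trait", stringsAsFactors = FALSE)
    snps <- rbind(planted_snps, bg_snps)
    rownames(snps) <- NULL

    list(segmentation = seg, state_map = state_map, super_enhancers = ses,
         chart_peaks = chart, ctcf_clusters = ctcf, cohesin_peaks = cohesin,
         snps = snps)
  })
}

#' Generate every pipeline input with a manifest of planted truth
#'
#' The one-call generator: genome annotation, interaction clusters with
#' planted C1-C5 categories, histone tracks with planted enhancer-like /
#' promoter-like promoter labels, RNAPII peaks, an expression matrix with
#' planted pair correlations and cell-specific genes, ChromHMM
#' segmentation, super-enhancers, CHART peaks enriched around a focus
#' lincRNA, CTCF/cohesin inputs, GWAS-style SNPs, and gene sets. When
#' `outdir` is given all inputs are written as plain-text files
#' (GTF/BEDPE/bedGraph/narrowPeak/BED/TSV/GMT) together with
#' `manifest.json`; regeneration from the same seed is byte-identical.
#'
#' The desk preset: 2 chromosomes x 1 Mb, 200 genes, around 600
#' interaction clusters — the full pipeline runs in well under a minute.
#'
#' @param seed master RNG seed; stage seeds are derived from it.
#' @param outdir optional output directory (created if needed).
#' @param preset only `"desk"` currently.
#' @param snr histone signal-to-noise for planted promoter labels.
#' @param enrichment_factor CHART neighborhood enrichment factor.
#' @param n_cells cell types in the expression design.
#' @return list with all generated objects plus `manifest` (and `paths`
#'   when written).
#' @export
simulate_inputs <- function(seed = 1, outdir = NULL, preset = "desk",
                            snr = 4, enrichment_factor = 10, n_cells = 55) {
  stopifnot(preset == "desk")
  genome <- make_genome(n_chrom = 2, chrom_length = 1e6, n_genes = 200,
                        seed = seed)
  genes <- genome$genes
  inter <- make_interactions(genome, seed = seed + 101)
  lincs <- inter$truth$gene_id

  # planted promoter labels for all lincRNAs and a sample of coding genes
  coding <- genes$gene_id[genes$biotype == "protein_coding"]
  labelled <- c(lincs, coding[seq_len(min(30, length(coding)))])
  labels <- .with_seed(seed + 202, {
    stats::setNames(sample(c("enhancer_like", "promoter_like"),
                           length(labelled), replace = TRUE), labelled)
  })
  interacting_partners <- unique(unlist(
    inter$partners[vapply(inter$partners, is.character, TRUE)]))
  interacting_partners <- intersect(interacting_partners, genes$gene_id)
  peak_genes <- unique(c(
    inter$truth$gene_id[inter$truth$category %in% c("C1", "C2", "C3", "C4")],
    interacting_partners))
  tracks <- make_tracks(genome, labels, peak_genes = peak_genes, snr = snr,
                        seed = seed + 303)

  # planted correlated pairs: C1 lincRNAs with their first coding partner
  c1 <- inter$truth$gene_id[inter$truth$category == "C1"]
  pair_rows <- list()
  used <- character(0)
  for (g in c1) {
    p <- inter$partners[[g]]
    p <- setdiff(p[p %in% coding], used)
    if (length(p) > 0) {
      pair_rows[[g]] <- data.frame(gene_a = g, gene_b = p[1], r = 0.8)
      used <- c(used, g, p[1])
    }
  }
  pairs <- if (length(pair_rows) > 0) do.call(rbind, pair_rows) else NULL
  if (!is.null(pairs)) rownames(pairs) <- NULL
  specific <- data.frame(gene_id = utils::head(lincs, 3),
                         cell_type = c("cell01", "cell01", "cell02"),
                         stringsAsFactors = FALSE)
  expr <- make_expression(genome, pair_correlations = pairs,
                          specific_genes = specific, n_cells = n_cells,
                          seed = seed + 404)

  prom <- promoter_windows(genes, chrom_sizes = genome$chrom_sizes)
  chin <- build_chin(inter$clusters, prom)
  focus <- if (length(c1) > 0) c1[1] else lincs[1]
  snp_lincs <- utils::head(c1, 2)
  aux <- make_aux(genome, chin, focus_lincrna = focus,
                  snp_lincrnas = snp_lincs,
                  enrichment_factor = enrichment_factor, seed = seed + 505)

  gene_sets <- .with_seed(seed + 606, {
    sets <- lapply(seq_len(10), function(i)
      sort(sample(coding, min(15, length(coding)))))
    names(sets) <- sprintf("GO_SET_%02d", seq_len(10))
    sets
  })

  manifest <- list(
    seed = seed, preset = preset,
    chrom_sizes = as.list(genome$chrom_sizes),
    n_genes = nrow(genes),
    biotypes = as.list(table(genes$biotype)),
    categories = stats::setNames(as.list(inter$truth$category),
                                 inter$truth$gene_id),
    promoter_labels = as.list(labels),
    pair_correlations = if (is.null(pairs)) list() else
      lapply(seq_len(nrow(pairs)), function(i) as.list(pairs[i, ])),
    specific_genes = lapply(seq_len(nrow(specific)), function(i)
      as.list(specific[i, ])),
    network_exponent = inter$exponent,
    enrichment_factor = enrichment_factor,
    snr = snr,
    focus_lincrna = focus,
    snp_lincrnas = snp_lincs
  )

  out <- list(genome = genome, genes = genes, clusters = inter$clusters,
              truth = inter$truth, partners = inter$partners,
              labels = labels, tracks = tracks, expression = expr,
              aux = aux, gene_sets = gene_sets, chin = chin,
              focus_lincrna = focus, manifest = manifest)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    write_gtf(genes, p("genome.gtf"))
    write_chrom_sizes(genome$chrom_sizes, p("genome.chrom.sizes"))
    write_bedpe(inter$clusters, p("interactions.bedpe"))
    write_bedgraph(tracks$me1, p("h3k4me1.bedgraph"))
    write_bedgraph(tracks$me3, p("h3k4me3.bedgraph"))
    write_narrowpeak(tracks$rnapii_peaks, p("rnapii_peaks.narrowPeak"))
    write_expression(expr, p("expression.tsv"), p("samples.tsv"))
    write_bed(aux$segmentation, p("chromhmm.bed"))
    .write_tsv(aux$state_map, p("state_map.tsv"))
    write_bed(aux$super_enhancers, p("super_enhancers.bed"))
    write_bed(aux$chart_peaks, p("chart_peaks.bed"))
    write_bedpe(aux$ctcf_clusters, p("ctcf.bedpe"))
    write_narrowpeak(aux$cohesin_peaks, p("cohesin_peaks.narrowPeak"))
    write_snps(aux$snps, p("snps.tsv"))
    write_gmt(gene_sets, p("gene_sets.gmt"))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    out$paths <- stats::setNames(
      file.path(outdir, c("genome.gtf", "genome.chrom.sizes",
                          "interactions.bedpe", "h3k4me1.bedgraph",
                          "h3k4me3.bedgraph", "rnapii_peaks.narrowPeak",
                          "expression.tsv", "samples.tsv", "chromhmm.bed",
                          "state_map.tsv", "super_enhancers.bed",
                          "chart_peaks.bed", "ctcf.bedpe",
                          "cohesin_peaks.narrowPeak", "snps.tsv",
                          "gene_sets.gmt", "manifest.json")),
      c("gtf", "chrom_sizes", "bedpe", "me1", "me3", "rnapii", "expression",
        "samples", "chromhmm", "state_map", "super_enhancers", "chart",
        "ctcf", "cohesin", "snps", "gene_sets", "manifest"))
  }
  out
}
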