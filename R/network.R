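#' Build a chromatin interaction network (ChIN)
#'
#' Raw ChIA-PET anchors are merged into node regions (overlapping or
#' neighboring anchors collapse, see [merge_intervals()]); each interaction
#' cluster contributes one edge between the nodes containing its two
#' anchors. Clusters whose anchors land in the same merged node would be
#' self-loops and are dropped (counted in `n_self_dropped`). Parallel
#' clusters between one node pair collapse into a single edge whose `weight`
#' is the cluster count and `total_pet` the summed PET count. A node is a
#' `promoter` node if its region overlaps any promoter window by >= 1 bp
#' (carrying the overlapping gene ids), otherwise a distal regulatory
#' element (`dre`).
#'
#' @param clusters cluster table (see [read_bedpe()]).
#' @param promoters data.frame of promoter windows with columns `gene_id`,
#'   `chrom`, `start`, `end` (one row per TSS window, from
#'   [promoter_windows()]).
#' @param max_gap merge gap for neighboring anchors (default 0: overlapping
#'   or directly abutting).
#' @return object of class `chin`: list with `nodes` (node_id, region, role,
#'   `gene_ids` list-column), `edges` (from, to, weight, total_pet),
#'   `graph` (igraph), and `n_self_dropped`.
#' @export
build_chin <- function(clusters, promoters = NULL, max_gap = 0) {
  stopifnot(nrow(clusters) > 0)
  anchors <- data.frame(
    chrom = c(clusters$chrom_a, clusters$chrom_b),
    start = c(clusters$start_a, clusters$start_b),
    end = c(clusters$end_a, clusters$end_b))
  nodes <- merge_intervals(anchors, max_gap = max_gap)
  nodes$node_id <- seq_len(nrow(nodes))

  locate <- function(chrom, start, end) {
    # every anchor is contained in exactly one merged node by construction
    idx <- integer(length(chrom))
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      ni <- nodes[nodes$chrom == ch, , drop = FALSE]
      pos <- findInterval(start[sel], ni$start)
      stopifnot(pos >= 1, end[sel] <= ni$end[pos])
      idx[sel] <- ni$node_id[pos]
    }
    idx
  }
  na <- locate(clusters$chrom_a, clusters$start_a, clusters$end_a)
  nb <- locate(clusters$chrom_b, clusters$start_b, clusters$end_b)

  self <- na == nb
  n_self <- sum(self)
  if (n_self > 0)
    message(n_self, " cluster(s) with both anchors in one merged node dropped")
  ek <- data.frame(from = pmin(na, nb)[!self], to = pmax(na, nb)[!self],
                   pet = clusters$pet_count[!self])
  if (nrow(ek) > 0) {
    key <- paste(ek$from, ek$to)
    agg_w <- tapply(rep(1, nrow(ek)), key, sum)
    agg_p <- tapply(ek$pet, key, sum)
    parts <- strsplit(names(agg_w), " ", fixed = TRUE)
    edges <- data.frame(from = as.integer(vapply(parts, `[[`, "", 1)),
                        to = as.integer(vapply(parts, `[[`, "", 2)),
                        weight = as.numeric(agg_w),
                        total_pet = as.numeric(agg_p))
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = integer(), to = integer(),
                        weight = numeric(), total_pet = numeric())
  }

  gene_ids <- rep(list(character(0)), nrow(nodes))
  if (!is.null(promoters) && nrow(promoters) > 0) {
    pg <- .gi_to_granges(promoters)
    ng <- .gi_to_granges(nodes)
    hits <- suppressWarnings(GenomicRanges::findOverlaps(ng, pg))
    if (length(hits) > 0) {
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      sp <- split(promoters$gene_id[sh], qh)
      for (nm in names(sp))
        gene_ids[[as.integer(nm)]] <- sort(unique(sp[[nm]]))
    }
  }
  nodes$role <- ifelse(lengths(gene_ids) > 0, "promoter", "dre")
  nodes$gene_ids <- gene_ids
  nodes <- nodes[, c("node_id", "chrom", "start", "end", "role", "gene_ids")]

  graph <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  if (nrow(edges) > 0)
    graph <- igraph::add_edges(graph, rbind(edges$from, edges$to),
                               weight = edges$weight,
                               total_pet = edges$total_pet)
  structure(list(nodes = nodes, edges = edges, graph = graph,
                 n_self_dropped = n_self),
            class = "chin")
}

#' @export
print.chin <- function(x, ...) {
  cat("ChIN:", nrow(x$nodes), "nodes (",
      sum(x$nodes$role == "promoter"), "promoter /",
      sum(x$nodes$role == "dre"), "DRE ),",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Basic descriptors of a ChIN
#'
#' Degree distribution, a discrete maximum-likelihood power-law fit with
#' Kolmogorov-Smirnov-selected xmin (scale-freeness), k-core distribution,
#' transitivity (global clustering coefficient), graph density, per-node
#' betweenness and closeness (topological, edge weights ignored), and
#' connected component sizes.
#'
#' @param chin a [build_chin()] result.
#' @return list of class `chin_descriptors`.
#' @export
compute_descriptors <- function(chin) {
  g <- chin$graph
  stopifnot(igraph::vcount(g) >= 1)
  deg <- igraph::degree(g)
  dd <- table(deg)
  pl <- if (length(unique(deg[deg > 0])) < 2) {
    list(exponent = NA_real_, xmin = NA_real_)
  } else {
    fit <- igraph::fit_power_law(deg[deg > 0], implementation = "plfit")
    list(exponent = fit$alpha, xmin = fit$xmin)
  }
  comps <- igraph::components(g)
  structure(list(
    degree_distribution = stats::setNames(as.integer(dd), names(dd)),
    power_law_exponent = pl$exponent,
    power_law_xmin = pl$xmin,
    kcore_distribution = table(igraph::coreness(g)),
    transitivity = igraph::transitivity(g, type = "global"),
    graph_density = igraph::edge_density(g),
    betweenness = igraph::betweenness(g, weights = NA),
    closeness = suppressWarnings(igraph::closeness(g, weights = NA)),
    component_sizes = sort(as.integer(comps$csize), decreasing = TRUE),
    n_components = comps$no
  ), class = "chin_descriptors")
}

#' Fit a discrete power law to a degree sequence
#'
#' Thin wrapper over the Clauset-style discrete MLE with KS-selected xmin.
#'
#' @param degrees non-negative integer vector; zeros are dropped.
#' @return list with `exponent` and `xmin` (NA when degenerate).
#' @export
fit_degree_exponent <- function(degrees) {
  degrees <- degrees[degrees > 0]
  if (length(unique(degrees)) < 2)
    return(list(exponent = NA_real_, xmin = NA_real_))
  fit <- igraph::fit_power_law(degrees, implementation = "plfit")
  list(exponent = fit$alpha, xmin = fit$xmin)
}

#' Detect communities in a ChIN
#'
#' Weighted modularity optimization (Louvain), the documented stand-in for
#' overlapping influence-function community detection: downstream analysis
#' consumes only community membership and size. Deterministic for a fixed
#' seed; ties inside the algorithm are resolved by igraph's fixed vertex
#' order.
#'
#' @param chin a [build_chin()] result.
#' @param resolution Louvain resolution parameter (1 = classic modularity).
#' @param min_size communities with at least this many nodes are flagged
#'   `qualifying` for downstream functional enrichment (default 20).
#' @param seed RNG seed.
#' @return list of class `chin_communities`: `membership` (node_id ->
#'   label), `sizes`, `qualifying` (labels with >= min_size nodes).
#' @export
detect_communities <- function(chin, resolution = 1, min_size = 20, seed = 1) {
  g <- chin$graph
  memb <- .with_seed(seed, {
    if (igraph::ecount(g) == 0) {
      seq_len(igraph::vcount(g))
    } else {
      as.integer(igraph::membership(
        igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                                resolution = resolution)))
    }
  })
  sizes <- table(memb)
  structure(list(
    membership = stats::setNames(memb, chin$nodes$node_id),
    sizes = stats::setNames(as.integer(sizes), names(sizes)),
    qualifying = as.integer(names(sizes)[sizes >= min_size]),
    min_size = min_size, seed = seed
  ), class = "chin_communities")
}

#' Nodes within k hops of a seed set
#'
#' All nodes at shortest-path distance `<= k` (unweighted hops) from any
#' seed node, seeds included.
#'
#' @param chin a [build_chin()] result.
#' @param seed_nodes integer node ids.
#' @param k non-negative hop count.
#' @return sorted integer vector of node ids.
#' @export
k_hop_neighborhood <- function(chin, seed_nodes, k) {
  stopifnot(k >= 0)
  unknown <- setdiff(seed_nodes, chin$nodes$node_id)
  if (length(unknown) > 0)
    stop("unknown seed node id(s): ", paste(unknown, collapse = ", "))
  if (length(seed_nodes) == 0) return(integer(0))
  d <- igraph::distances(chin$graph, v = seed_nodes, weights = NA)
  sort(unique(chin$nodes$node_id[apply(d, 2, min) <= k]))
}

#' Gene-level subnetwork between two biotypes
#'
#' One gene-pair edge for every ChIN edge joining a node carrying a
#' `biotype_a` gene to a node carrying a `biotype_b` gene; nodes carrying
#' several genes expand to all pairs. This is how the lincRNA-mRNA
#' promoter-promoter interaction network is extracted.
#'
#' @param chin a [build_chin()] result.
#' @param genes gene table (for biotype lookup).
#' @param biotype_a,biotype_b biotype names (`gene_a` column carries
#'   `biotype_a` genes).
#' @return data.frame with `gene_a`, `gene_b`, deduplicated; plus gene-level
#'   degrees (distinct partner count) as attribute `degrees`.
#' @export
extract_gene_subnetwork <- function(chin, genes, biotype_a = "lincRNA",
                                    biotype_b = "protein_coding") {
  bt <- stats::setNames(genes$biotype, genes$gene_id)
  pairs_a <- character(0); pairs_b <- character(0)
  gl <- chin$nodes$gene_ids
  for (i in seq_len(nrow(chin$edges))) {
    gf <- gl[[chin$edges$from[i]]]
    gt <- gl[[chin$edges$to[i]]]
    for (swap in c(FALSE, TRUE)) {
      ga <- if (swap) gt else gf
      gb <- if (swap) gf else gt
      a <- ga[bt[ga] %in% biotype_a]
      b <- gb[bt[gb] %in% biotype_b]
      if (length(a) > 0 && length(b) > 0) {
        grid <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
        pairs_a <- c(pairs_a, grid$a)
        pairs_b <- c(pairs_b, grid$b)
      }
    }
  }
  out <- unique(data.frame(gene_a = pairs_a, gene_b = pairs_b,
                           stringsAsFactors = FALSE))
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  deg_a <- table(out$gene_a[!duplicated(paste(out$gene_a, out$gene_b))])
  deg_b <- table(out$gene_b[!duplicated(paste(out$gene_b, out$gene_a))])
  attr(out, "degrees") <- list(gene_a = deg_a, gene_b = deg_b)
  out
}

#' TSS-to-TSS distance of a gene pair
#'
#' Uses each gene's canonical TSS (the 5'-most on its strand). Pairs on
#' different chromosomes are flagged inter-chromosomal with `NA` distance.
#'
#' @param gene_a,gene_b gene ids.
#' @param genes gene table.
#' @return list with `distance` (bp or NA) and `inter_chromosomal` flag.
#' @export
gene_pair_distance <- function(gene_a, gene_b, genes) {
  ga <- genes[genes$gene_id == gene_a, ]
  gb <- genes[genes$gene_id == gene_b, ]
  stopifnot(nrow(ga) == 1, nrow(gb) == 1)
  if (ga$chrom != gb$chrom)
    return(list(distance = NA_real_, inter_chromosomal = TRUE))
  list(distance = abs(canonical_tss(ga) - canonical_tss(gb)),
       inter_chromosomal = FALSE)
}

#' Canonical TSS of a gene (5'-most on its strand)
#'
#' @param gene single-row gene table.
#' @return 0-based TSS position.
#' @export
canonical_tss <- function(gene) {
  tss <- gene$tss[[1]]
  if (identical(gene$strand, "-")) max(tss) else min(tss)
}

#' Serialize a ChIN to GraphML
#'
#' Node attributes: region coordinates, role, semicolon-joined gene ids;
#' edge attributes: weight (cluster count) and total PET count.
#'
#' @param chin a [build_chin()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chin_graphml <- function(chin, path) {
  g <- chin$graph
  igraph::V(g)$node_id <- chin$nodes$node_id
  igraph::V(g)$region <- sprintf("%s:%d-%d", chin$nodes$chrom,
                                 as.integer(chin$nodes$start),
                                 as.integer(chin$nodes$end))
  igraph::V(g)$role <- chin$nodes$role
  igraph::V(g)$gene_ids <- vapply(chin$nodes$gene_ids, paste, "",
                                  collapse = ";")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# run expr under a local RNG state so callers' streams are untouched
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
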