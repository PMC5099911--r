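#' Assemble and validate a pipeline configuration
#'
#' A configuration is a plain named list; this helper fills defaults and
#' validates before any stage runs. Every default traces to a documented
#' analysis choice: promoter half-width 2500 bp, anchor merge gap 0, hop
#' radius 3, pseudocount 0.01, correlation threshold 0.6, specificity fold
#' change 2, GSEA FDR 0.01, community minimum size 20.
#'
#' @param inputs named list (or YAML path via `config_path`) of input file
#'   paths: gtf, chrom_sizes, bedpe, me1, me3, rnapii, expression, samples,
#'   chromhmm, state_map, super_enhancers, chart, ctcf, cohesin, snps,
#'   gene_sets (the last eight optional).
#' @param config_path optional YAML file with `inputs:` and parameter keys;
#'   explicit arguments override it.
#' @param promoter_half_width,merge_max_gap,hop_k,epsilon,cor_threshold,fc_threshold,gsea_fdr,community_min_size,n_perm,seed
#'   pipeline parameters (see Details).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs = NULL, config_path = NULL,
                            promoter_half_width = 2500, merge_max_gap = 0,
                            hop_k = 3, epsilon = 0.01, cor_threshold = 0.6,
                            fc_threshold = 2, gsea_fdr = 0.01,
                            community_min_size = 20, n_perm = 200, seed = 1) {
  cfg <- list(promoter_half_width = promoter_half_width,
              merge_max_gap = merge_max_gap, hop_k = hop_k,
              epsilon = epsilon, cor_threshold = cor_threshold,
              fc_threshold = fc_threshold, gsea_fdr = gsea_fdr,
              community_min_size = community_min_size, n_perm = n_perm,
              seed = seed, inputs = inputs)
  if (!is.null(config_path)) {
    # YAML is the base; arguments passed explicitly in this call override it
    yml <- yaml::read_yaml(config_path)
    called <- names(match.call())
    for (key in setdiff(names(yml), c("inputs", called)))
      cfg[[key]] <- yml[[key]]
    if (is.null(cfg$inputs)) cfg$inputs <- yml$inputs
  }
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Collects every problem (all missing files at once, invalid thresholds)
#' before failing, so a broken configuration reports completely.
#'
#' @param cfg list as built by [pipeline_config()].
#' @return `cfg` invisibly; errors with a combined message otherwise.
#' @export
validate_pipeline_config <- function(cfg) {
  problems <- character(0)
  pos <- c("promoter_half_width", "epsilon", "cor_threshold", "fc_threshold",
           "gsea_fdr", "community_min_size", "n_perm")
  for (p in pos)
    if (is.null(cfg[[p]]) || cfg[[p]] <= 0)
      problems <- c(problems, paste0(p, " must be positive"))
  if (is.null(cfg$hop_k) || cfg$hop_k < 0)
    problems <- c(problems, "hop_k must be >= 0")
  if (is.null(cfg$merge_max_gap) || cfg$merge_max_gap < 0)
    problems <- c(problems, "merge_max_gap must be >= 0")
  req <- c("gtf", "chrom_sizes", "bedpe", "me1", "me3", "rnapii",
           "expression", "samples")
  if (is.null(cfg$inputs)) {
    problems <- c(problems, "no inputs supplied")
  } else {
    miss <- setdiff(req, names(cfg$inputs))
    if (length(miss) > 0)
      problems <- c(problems, paste("missing input key(s):",
                                    paste(miss, collapse = ", ")))
    for (key in intersect(names(cfg$inputs), c(req, "chromhmm", "state_map",
                                               "super_enhancers", "chart",
                                               "ctcf", "cohesin", "snps",
                                               "gene_sets")))
      if (!file.exists(cfg$inputs[[key]]))
        problems <- c(problems, paste0("input file not found (", key, "): ",
                                       cfg$inputs[[key]]))
  }
  if (length(problems) > 0)
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  invisible(cfg)
}

#' Run the full lincRNA chromatin-interaction pipeline
#'
#' Stages in dependency order: input reading, ChIN construction, network
#' descriptors and communities, DRE chromatin-state labelling and
#' super-enhancer overlap, SNP-target mapping, C1-C5 classification,
#' promoter profiling, cell-specificity scoring, and (when CHART peaks are
#' supplied) k-hop target calling with permutation enrichment. All outputs
#' are plain text (TSV/JSON/GraphML) under `outdir`; a rerun with the same
#' configuration and seed reproduces them byte-identically. The run log
#' records the configuration hash and seed.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return named list of output paths, invisibly; also a `results` attribute
#'   with the in-memory stage results.
#' @export
run_pipeline <- function(config, outdir) {
  validate_pipeline_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  inp <- config$inputs
  log_lines <- c(sprintf("lincChIN run, seed %d", config$seed),
                 sprintf("config_hash %s", .config_hash(config)))
  logit <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  logit("stage io: reading inputs")
  genes <- read_gtf(inp$gtf)
  sizes <- read_chrom_sizes(inp$chrom_sizes)
  .check_chrom_dialect(names(sizes), genes$chrom, "annotation")
  clusters <- read_bedpe(inp$bedpe)
  me1 <- read_bedgraph(inp$me1)
  me3 <- read_bedgraph(inp$me3)
  rnapii <- read_narrowpeak(inp$rnapii)
  expr <- read_expression(inp$expression, inp$samples)

  logit("stage network: building ChIN from %d clusters", nrow(clusters))
  prom <- promoter_windows(genes, half_width = config$promoter_half_width,
                           chrom_sizes = sizes)
  chin <- build_chin(clusters, prom, max_gap = config$merge_max_gap)
  logit("ChIN: %d nodes, %d edges", nrow(chin$nodes), nrow(chin$edges))
  desc <- compute_descriptors(chin)
  comm <- detect_communities(chin, min_size = config$community_min_size,
                             seed = config$seed)
  write_chin_graphml(chin, file.path(outdir, "network.graphml"))
  jsonlite::write_json(
    list(n_nodes = nrow(chin$nodes), n_edges = nrow(chin$edges),
         n_promoter_nodes = sum(chin$nodes$role == "promoter"),
         n_dre_nodes = sum(chin$nodes$role == "dre"),
         power_law_exponent = desc$power_law_exponent,
         transitivity = desc$transitivity,
         graph_density = desc$graph_density,
         n_components = desc$n_components,
         n_communities = length(comm$sizes),
         n_qualifying_communities = length(comm$qualifying),
         seed = config$seed),
    file.path(outdir, "descriptors.json"), auto_unbox = TRUE, digits = NA)
  .write_tsv(data.frame(node_id = chin$nodes$node_id,
                        community = unname(comm$membership)),
             file.path(outdir, "communities.tsv"))

  logit("stage annotation")
  dres <- chin$nodes[chin$nodes$role == "dre", , drop = FALSE]
  if (!is.null(inp$chromhmm)) {
    seg <- read_bed(inp$chromhmm)
    smap <- if (!is.null(inp$state_map)) read_state_map(inp$state_map) else NULL
    states <- label_dre_states(dres, seg, smap)
    .write_tsv(data.frame(node_id = dres$node_id, chrom = dres$chrom,
                          start = dres$start, end = dres$end, state = states),
               file.path(outdir, "dre_states.tsv"))
  }
  if (!is.null(inp$super_enhancers)) {
    ses <- read_bed(inp$super_enhancers)
    seo <- super_enhancer_overlap(chin, ses, genes)
    .write_tsv(seo$linc_flags, file.path(outdir, "se_linked_lincrnas.tsv"))
  }
  if (!is.null(inp$snps)) {
    snps <- read_snps(inp$snps)
    snp_map <- map_snps_to_targets(snps, chin, genes,
                                   flank = config$promoter_half_width)
    .write_tsv(snp_map, file.path(outdir, "snp_targets.tsv"))
  }

  logit("stage classification")
  lincs <- genes$gene_id[genes$biotype == "lincRNA"]
  categories <- classify_categories(lincs, chin, genes, rnapii, expr,
                                    half_width = config$promoter_half_width)
  .write_tsv(categories, file.path(outdir, "categories.tsv"))
  profiled <- genes[genes$gene_id %in% lincs, , drop = FALSE]
  profiles <- profile_promoters(profiled, me1, me3, epsilon = config$epsilon,
                                half_width = config$promoter_half_width)
  .write_tsv(profiles, file.path(outdir, "promoter_profiles.tsv"))
  spec_rows <- lapply(lincs, function(g) {
    per_cell <- lapply(unique(expr$samples$cell_type)[1:2], function(ct) {
      cs <- cell_specificity(expr, g, ct, epsilon = config$epsilon,
                             fc_threshold = config$fc_threshold)
      data.frame(gene_id = g, cell_type = ct,
                 fold_change = cs$fold_change, is_specific = cs$is_specific)
    })
    do.call(rbind, per_cell)
  })
  .write_tsv(do.call(rbind, spec_rows), file.path(outdir, "specificity.tsv"))

  results <- list(chin = chin, descriptors = desc, communities = comm,
                  categories = categories, profiles = profiles)

  if (!is.null(inp$chart)) {
    logit("stage rna_targets")
    chart <- read_bed(inp$chart)
    c1 <- categories$gene_id[categories$category == "C1"]
    focus <- if (length(c1) > 0) sort(c1)[1] else lincs[1]
    targets <- call_targets(focus, chin, genes, chart, k = config$hop_k,
                            expression = expr,
                            r_threshold = config$cor_threshold,
                            flank = config$promoter_half_width)
    .write_tsv(cbind(lincrna = focus, as.data.frame(targets)),
               file.path(outdir, "targets.tsv"))
    enr <- binding_enrichment_in_neighborhood(focus, chin, chart, sizes,
                                              k = config$hop_k,
                                              n_perm = config$n_perm,
                                              seed = config$seed)
    jsonlite::write_json(
      list(lincrna = focus, k = config$hop_k, observed = enr$observed,
           null_mean = enr$null_mean, null_sd = enr$null_sd,
           z_score = enr$z_score, p_value = enr$p_value,
           n_perm = enr$n_perm, seed = enr$seed),
      file.path(outdir, "binding_enrichment.json"), auto_unbox = TRUE,
      digits = NA)
    results$targets <- targets
    results$binding_enrichment <- enr
  }

  if (!is.null(inp$gene_sets)) {
    logit("stage stats: guilt-by-association GSEA")
    gene_sets <- read_gmt(inp$gene_sets)
    coding <- genes$gene_id[genes$biotype == "protein_coding"]
    c1 <- categories$gene_id[categories$category == "C1"]
    gsea_lincs <- utils::head(sort(c1), 5)
    gsea_all <- list()
    for (g in gsea_lincs) {
      ranked <- rank_genes_for_lincrna(expr, g, coding)
      gsea_all[[g]] <- gsea_preranked(ranked, gene_sets,
                                      n_perm = config$n_perm,
                                      seed = config$seed,
                                      fdr_threshold = config$gsea_fdr)
    }
    flat <- do.call(rbind, lapply(names(gsea_all), function(g)
      cbind(lincrna = g, gsea_all[[g]])))
    .write_tsv(flat, file.path(outdir, "gsea.tsv"))
    results$gsea <- gsea_all
  }

  writeLines(log_lines, file.path(outdir, "run.log"))
  paths <- list.files(outdir, full.names = TRUE)
  out <- stats::setNames(as.list(paths), basename(paths))
  attr(out, "results") <- results
  invisible(out)
}

# stable hash of the configuration (parameters + input basenames)
.config_hash <- function(config) {
  core <- config[setdiff(names(config), "inputs")]
  core$input_files <- unname(vapply(config$inputs, basename, ""))
  raw <- serialize(core[order(names(core))], NULL, version = 2)
  # fold the serialized bytes into a short hex digest
  v <- as.integer(raw)
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2^31
  sprintf("%08x", as.integer(h))
}
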