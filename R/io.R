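#' Read ChIA-PET interaction clusters from a BEDPE file
#'
#' Expects >= 6 tab-separated columns (chromA, startA, endA, chromB, startB,
#' endB) with an optional 7th column carrying the PET count (paired-end tags
#' supporting the contact). A missing PET column defaults every cluster to 1.
#' Rows whose two anchors are identical after parsing are retained but
#' flagged in the `self_contact` column.
#'
#' @param path BEDPE file path.
#' @return data.frame with columns `chrom_a`, `start_a`, `end_a`, `chrom_b`,
#'   `start_b`, `end_b`, `pet_count`, `self_contact`; zero rows for an empty
#'   file.
#' @export
read_bedpe <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(.empty_clusters())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 6))
    stop("BEDPE line ", which(ncols < 6)[1], ": fewer than 6 columns")
  df <- data.frame(
    chrom_a = vapply(fields, `[[`, "", 1),
    start_a = as.numeric(vapply(fields, `[[`, "", 2)),
    end_a   = as.numeric(vapply(fields, `[[`, "", 3)),
    chrom_b = vapply(fields, `[[`, "", 4),
    start_b = as.numeric(vapply(fields, `[[`, "", 5)),
    end_b   = as.numeric(vapply(fields, `[[`, "", 6)),
    pet_count = ifelse(ncols >= 7,
                       suppressWarnings(as.numeric(vapply(fields, function(f)
                         if (length(f) >= 7) f[[7]] else "1", ""))),
                       1),
    stringsAsFactors = FALSE)
  df$pet_count[is.na(df$pet_count)] <- 1
  bad <- which(df$end_a <= df$start_a | df$end_b <= df$start_b |
                 df$start_a < 0 | df$start_b < 0)
  if (length(bad) > 0)
    stop("BEDPE line ", bad[1], ": malformed coordinates (end <= start)")
  if (any(df$pet_count < 1))
    stop("BEDPE: pet_count must be >= 1 at line ",
         which(df$pet_count < 1)[1])
  df$self_contact <- df$chrom_a == df$chrom_b &
    df$start_a == df$start_b & df$end_a == df$end_b
  df
}

.empty_clusters <- function() {
  data.frame(chrom_a = character(), start_a = numeric(), end_a = numeric(),
             chrom_b = character(), start_b = numeric(), end_b = numeric(),
             pet_count = numeric(), self_contact = logical())
}

#' Write interaction clusters as BEDPE
#'
#' @param clusters cluster table from [read_bedpe()] or the generator.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(clusters, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%d",
                   clusters$chrom_a, as.integer(clusters$start_a),
                   as.integer(clusters$end_a), clusters$chrom_b,
                   as.integer(clusters$start_b), as.integer(clusters$end_b),
                   as.integer(clusters$pet_count))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GENCODE-dialect GTF into a gene table
#'
#' One row per `gene_id`. Gene bodies come from `gene` features; the TSS
#' list is collected over all `transcript` features of the gene,
#' strand-aware (TSS = body start on `+`, body end - 1 on `-`, in 0-based
#' coordinates) and deduplicated. Genes without any transcript feature fall
#' back to a single TSS derived from the gene feature itself. GTF 1-based
#' closed coordinates are converted to 0-based half-open here.
#'
#' @param path GTF file with `gene_id`, `gene_name`, `gene_type` attributes.
#' @return data.frame of class `gene_table` with columns `gene_id`, `name`,
#'   `biotype`, `chrom`, `start`, `end`, `strand`, and list-column `tss`.
#' @export
read_gtf <- function(path) {
  stopifnot(file.exists(path))
  head_lines <- readLines(path)
  if (!any(nzchar(head_lines) & !startsWith(head_lines, "#")))
    return(.empty_gene_table())
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  if (nrow(df) == 0) return(.empty_gene_table())
  for (col in c("gene_id", "gene_type"))
    if (!col %in% names(df)) stop("GTF lacks required attribute: ", col)
  if (!"gene_name" %in% names(df)) df$gene_name <- df$gene_id
  genes <- df[df$type == "gene", , drop = FALSE]
  txs <- df[df$type == "transcript", , drop = FALSE]
  if (nrow(genes) == 0) stop("GTF contains no 'gene' features")
  known <- c("protein_coding", "lincRNA", "antisense", "miRNA",
             "sense_overlapping", "sense_intronic", "processed_transcript",
             "others")
  biotype <- as.character(genes$gene_type)
  unk <- !biotype %in% known
  if (any(unk)) {
    warning("unknown gene_type(s) mapped to 'others': ",
            paste(unique(biotype[unk]), collapse = ", "))
    biotype[unk] <- "others"
  }
  tss_of <- function(start1, end1, strand) {
    # 1-based closed -> 0-based position of the transcription start
    ifelse(strand == "-", end1 - 1, start1 - 1)
  }
  tss_list <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$gene_id[i]
    tx <- txs[txs$gene_id == gid, , drop = FALSE]
    if (nrow(tx) == 0)
      tx <- genes[i, , drop = FALSE]
    sort(unique(tss_of(tx$start, tx$end, as.character(tx$strand))))
  })
  out <- data.frame(gene_id = as.character(genes$gene_id),
                    name = as.character(genes$gene_name),
                    biotype = biotype,
                    chrom = as.character(genes$seqnames),
                    start = genes$start - 1,
                    end = genes$end,
                    strand = as.character(genes$strand),
                    stringsAsFactors = FALSE)
  out$tss <- tss_list
  class(out) <- c("gene_table", "data.frame")
  rownames(out) <- NULL
  out
}

.empty_gene_table <- function() {
  out <- data.frame(gene_id = character(), name = character(),
                    biotype = character(), chrom = character(),
                    start = numeric(), end = numeric(), strand = character(),
                    stringsAsFactors = FALSE)
  out$tss <- list()
  class(out) <- c("gene_table", "data.frame")
  out
}

#' Write a gene table as a GENCODE-dialect GTF
#'
#' Emits one `gene` feature per gene and one `transcript` feature per
#' annotated TSS (transcript end = gene body end on `+`, body start on `-`),
#' converting back to 1-based closed coordinates. Output is deterministic:
#' same gene table, byte-identical file.
#'
#' @param genes gene table (see [read_gtf()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##description: lincChIN gene annotation", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    attr_g <- sprintf('gene_id "%s"; gene_name "%s"; gene_type "%s";',
                      g$gene_id, g$name, g$biotype)
    writeLines(sprintf("%s\tlincChIN\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       g$chrom, as.integer(g$start + 1), as.integer(g$end),
                       g$strand, attr_g), con)
    tss <- sort(unique(g$tss[[1]]))
    for (j in seq_along(tss)) {
      if (g$strand == "-") {
        s1 <- g$start + 1; e1 <- tss[j] + 1
      } else {
        s1 <- tss[j] + 1; e1 <- g$end
      }
      writeLines(sprintf(
        '%s\tlincChIN\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t%d"; gene_name "%s"; gene_type "%s";',
        g$chrom, as.integer(s1), as.integer(e1), g$strand,
        g$gene_id, g$gene_id, j, g$name, g$biotype), con)
    }
  }
  invisible(path)
}

#' Read a bedGraph coverage file
#'
#' @param path bedGraph path.
#' @param library_depth optional total mapped reads for depth normalization;
#'   defaults to the track's own total signal (sum of value x width).
#' @return a [coverage_track()].
#' @export
read_bedgraph <- function(path, library_depth = NULL) {
  stopifnot(file.exists(path))
  info <- file.info(path)
  if (info$size == 0 || length(readLines(path, n = 1)) == 0)
    return(coverage_track())
  gr <- rtracklayer::import(path, format = "bedGraph")
  cov <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1,
                    end = GenomicRanges::end(gr),
                    value = gr$score,
                    stringsAsFactors = FALSE)
  if (is.null(library_depth)) library_depth <- sum(cov$value * (cov$end - cov$start))
  coverage_track(cov, library_depth = library_depth)
}

#' Write a coverage track as bedGraph
#'
#' @param track a [coverage_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  cov <- track$cov
  writeLines(sprintf("%s\t%d\t%d\t%s", cov$chrom, as.integer(cov$start),
                     as.integer(cov$end), format(cov$value, trim = TRUE,
                                                 scientific = FALSE)),
             path)
  invisible(path)
}

#' Read a BED3/BED4/BED6 file
#'
#' Column 4, when present, is kept as `name` (ChromHMM segmentations carry
#' the state label there).
#'
#' @param path BED path.
#' @return interval table with optional `name` column.
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1),
    start = as.numeric(vapply(fields, `[[`, "", 2)),
    end = as.numeric(vapply(fields, `[[`, "", 3)),
    stringsAsFactors = FALSE)
  if (all(lengths(fields) >= 4))
    df$name <- vapply(fields, `[[`, "", 4)
  if (all(lengths(fields) >= 6))
    df$strand <- vapply(fields, `[[`, "", 6)
  validate_gintervals(df, paste("BED file", basename(path)))
  df
}

#' Write intervals as BED
#'
#' @param intervals interval table; `name` column used as BED column 4 when
#'   present.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if ("name" %in% names(intervals)) {
    lines <- sprintf("%s\t%d\t%d\t%s", intervals$chrom,
                     as.integer(intervals$start), as.integer(intervals$end),
                     intervals$name)
  } else {
    lines <- sprintf("%s\t%d\t%d", intervals$chrom,
                     as.integer(intervals$start), as.integer(intervals$end))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a narrowPeak (ENCODE peak) file
#'
#' @param path narrowPeak path (BED6+4).
#' @return interval table with `name` and `signal` columns.
#' @export
read_narrowpeak <- function(path) {
  stopifnot(file.exists(path))
  if (file.info(path)$size == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), signal = numeric()))
  extra <- c(signalValue = "numeric", pValue = "numeric",
             qValue = "numeric", peak = "integer")
  gr <- rtracklayer::import(path, format = "BED", extraCols = extra)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else NA_character_,
             signal = gr$signalValue,
             stringsAsFactors = FALSE)
}

#' Write peaks in narrowPeak format
#'
#' @param peaks interval table; optional `name` and `signal` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  n <- nrow(peaks)
  nm <- if ("name" %in% names(peaks)) peaks$name else sprintf("peak_%d", seq_len(n))
  sg <- if ("signal" %in% names(peaks)) peaks$signal else rep(1, n)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t.\t%s\t-1\t-1\t-1",
                   peaks$chrom, as.integer(peaks$start), as.integer(peaks$end),
                   nm, format(sg, trim = TRUE, scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column chrom.sizes file
#'
#' @param path TSV with chromosome name and length.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  sizes <- as.numeric(df[[2]])
  names(sizes) <- as.character(df[[1]])
  sizes
}

#' Write a chrom.sizes file
#' @param sizes named numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%d", names(sizes), as.integer(sizes)), path)
  invisible(path)
}

#' Read an expression matrix with sample metadata
#'
#' The matrix TSV has gene ids in the first column and sample ids as the
#' header; values are RPKM. The side-car metadata TSV has columns
#' `sample_id`, `cell_type`, `fraction` (subcellular fraction: cell,
#' chromatin, nucleus, nucleolus, nucleoplasm or cytosol).
#'
#' @param matrix_path expression TSV.
#' @param meta_path sample metadata TSV.
#' @return object of class `expression_set`: list with `values`
#'   (genes x samples matrix) and `samples` (metadata data.frame).
#' @export
read_expression <- function(matrix_path, meta_path) {
  mat <- utils::read.delim(matrix_path, row.names = 1, check.names = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  expression_set(as.matrix(mat), meta)
}

#' Construct an expression set
#'
#' @param values genes x samples numeric matrix (RPKM, >= 0).
#' @param samples data.frame with `sample_id`, `cell_type`, `fraction`.
#' @return object of class `expression_set`.
#' @export
expression_set <- function(values, samples) {
  stopifnot(is.matrix(values))
  req <- c("sample_id", "cell_type")
  if (!all(req %in% names(samples)))
    stop("sample metadata needs columns: ", paste(req, collapse = ", "))
  if (!"fraction" %in% names(samples)) samples$fraction <- "cell"
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  if (any(is.na(samples$sample_id)))
    stop("sample metadata is missing entries for some matrix columns")
  if (any(values < 0)) stop("RPKM values must be >= 0")
  if (any(is.na(samples$cell_type)) || any(!nzchar(samples$cell_type)))
    stop("every sample needs a cell-type label")
  structure(list(values = values, samples = samples), class = "expression_set")
}

#' Write an expression set to TSV (matrix + metadata side-car)
#'
#' @param expr an [expression_set()].
#' @param matrix_path,meta_path output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(expr, matrix_path, meta_path) {
  df <- data.frame(gene_id = rownames(expr$values),
                   expr$values, check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(expr$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

#' Read a GWAS catalog extract
#'
#' Expects TSV columns `rsid`, `chrom`, `pos_1based`, `trait`. Positions are
#' converted to 0-based half-open single-base intervals here.
#'
#' @param path SNP table path.
#' @return data.frame with `rsid`, `chrom`, `start`, `end`, `trait`.
#' @export
read_snps <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("rsid", "chrom", "pos_1based", "trait")
  if (!all(req %in% names(df)))
    stop("SNP table needs columns: ", paste(req, collapse = ", "))
  data.frame(rsid = df$rsid, chrom = df$chrom,
             start = df$pos_1based - 1, end = df$pos_1based,
             trait = df$trait, stringsAsFactors = FALSE)
}

#' Write a GWAS SNP table
#' @param snps data.frame from [read_snps()] or the generator.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snps <- function(snps, path) {
  out <- data.frame(rsid = snps$rsid, chrom = snps$chrom,
                    pos_1based = as.integer(snps$start + 1),
                    trait = snps$trait)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' @param path GMT path (term, description, member genes, tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1)
  sets
}

#' Write gene sets in GMT format
#' @param gene_sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm)
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a ChromHMM state-name mapping table
#'
#' Two-column TSV translating segmentation-specific state names (for
#' example `4_Strong_Enhancer`) onto the fixed vocabulary used by
#' [label_dre_states()].
#'
#' @param path mapping TSV with columns `input_label`, `vocab_label`.
#' @return data.frame with those two columns.
#' @export
read_state_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("input_label", "vocab_label") %in% names(df)))
    stop("state map needs columns input_label, vocab_label")
  df
}

# deterministic TSV writer used for all pipeline outputs
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
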