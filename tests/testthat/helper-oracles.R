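# Independent oracles and hand-built fixtures shared across tests.
# Oracles deliberately use different algorithms / representations than the
# package implementation.

# pixel-based merge oracle: mark covered bases on a small coordinate grid,
# then bridge runs separated by <= max_gap, per chromosome
naive_merge <- function(intervals, max_gap = 0) {
  out <- list()
  for (ch in sort(unique(intervals$chrom))) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    maxc <- max(iv$end)
    covered <- logical(maxc + 1)
    for (i in seq_len(nrow(iv)))
      covered[(iv$start[i] + 1):iv$end[i]] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- data.frame(start = starts[r$values] - 1, end = ends[r$values])
    if (nrow(runs) > 1) {
      keep <- list(runs[1, ])
      for (i in 2:nrow(runs)) {
        last <- keep[[length(keep)]]
        if (runs$start[i] - last$end <= max_gap) {
          last$end <- runs$end[i]
          keep[[length(keep)]] <- last
        } else keep[[length(keep) + 1]] <- runs[i, ]
      }
      runs <- do.call(rbind, keep)
    }
    if (nrow(runs) > 0)
      out[[ch]] <- data.frame(chrom = ch, start = runs$start, end = runs$end,
                              strand = ".", stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# closed-interval brute-force overlap check after convention conversion
brute_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(FALSE)
  a1 <- a$start; a2 <- a$end - 1    # closed [a1, a2]
  b1 <- b$start; b2 <- b$end - 1
  a1 <= b2 && b1 <= a2
}

# k-hop reachability by boolean adjacency-matrix powers
khop_bruteforce <- function(adj, seeds, k) {
  n <- nrow(adj)
  reach <- rep(FALSE, n)
  reach[seeds] <- TRUE
  frontier <- reach
  if (k > 0) for (step in seq_len(k)) {
    frontier <- (adj %*% frontier) > 0
    reach <- reach | frontier
  }
  which(reach)
}

# literal running-sum GSEA enrichment score, step by step
gsea_es_bruteforce <- function(scores, is_hit, weight_p = 1) {
  n <- length(scores)
  nh <- sum(is_hit)
  denom_hit <- sum(abs(scores[is_hit])^weight_p)
  rs <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (is_hit[i]) {
      rs <- rs + if (denom_hit > 0) abs(scores[i])^weight_p / denom_hit else 1 / nh
    } else {
      rs <- rs - 1 / (n - nh)
    }
    if (abs(rs) > abs(best)) best <- rs
  }
  best
}

# hypergeometric upper tail by explicit summation of choose() terms
hyper_tail <- function(k, set_size, universe, draws) {
  total <- 0
  for (x in k:min(set_size, draws))
    total <- total + choose(set_size, x) *
      choose(universe - set_size, draws - x) / choose(universe, draws)
  total
}

# small hand-buildable gene table
genes_fixture <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(gene_id = r$gene_id, name = r$gene_id, biotype = r$biotype,
               chrom = r$chrom, start = r$start, end = r$end,
               strand = if (is.null(r$strand)) "+" else r$strand,
               stringsAsFactors = FALSE)))
  df$tss <- lapply(rows, function(r)
    if (is.null(r$tss)) {
      if (is.null(r$strand) || r$strand == "+") r$start else r$end - 1
    } else r$tss)
  class(df) <- c("gene_table", "data.frame")
  df
}

# random interval table on a small grid
random_intervals <- function(n, chroms = c("chr1", "chr2"), max_coord = 2000,
                             max_len = 120) {
  start <- sample.int(max_coord - max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             strand = ".", stringsAsFactors = FALSE)
}

# one desk-preset simulation shared across test files (lazy, memoized)
.desk_env <- new.env(parent = emptyenv())
get_desk_sim <- function() {
  if (is.null(.desk_env$sim))
    .desk_env$sim <- suppressMessages(simulate_inputs(seed = 20260921 %% 1e6))
  .desk_env$sim
}
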