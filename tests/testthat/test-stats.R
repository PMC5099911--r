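sizes2 <- c(chr1 = 1e6, chr2 = 1e6)

test_that("permutation colocalization hits the self-overlap ceiling", {
  set.seed(801)
  # well-separated regions so random placement rarely lands on them
  s <- data.frame(chrom = "chr1", start = seq(10000, 490000, 50000))
  s$end <- s$start + 200
  res <- permutation_colocalization(s, s, sizes2, n_perm = 99, seed = 3)
  expect_equal(res$observed, nrow(s))
  expect_equal(res$p_value, 1 / 100)   # minimal attainable p
  expect_gt(res$z_score, 3)
})

test_that("permutation results are deterministic given the seed", {
  set.seed(802)
  a <- random_intervals(20, max_coord = 900000)
  b <- random_intervals(20, max_coord = 900000)
  r1 <- permutation_colocalization(a, b, sizes2, n_perm = 50, seed = 11)
  r2 <- permutation_colocalization(a, b, sizes2, n_perm = 50, seed = 11)
  expect_identical(r1$null, r2$null)
  expect_identical(r1$p_value, r2$p_value)
  r3 <- permutation_colocalization(a, b, sizes2, n_perm = 50, seed = 12)
  expect_false(identical(r1$null, r3$null))
})

test_that("attainable p-values have granularity k / (1 + n_perm)", {
  set.seed(803)
  for (rep in 1:10) {
    a <- random_intervals(10, max_coord = 900000)
    b <- random_intervals(10, max_coord = 900000)
    r <- permutation_colocalization(a, b, sizes2, n_perm = 19, seed = rep)
    expect_equal(r$p_value * 20, round(r$p_value * 20))
    expect_gt(r$p_value, 0)
    expect_lte(r$p_value, 1)
  }
})

test_that("oversized regions and foreign chromosomes are rejected", {
  big <- data.frame(chrom = "chr1", start = 0, end = 2e6)
  b <- data.frame(chrom = "chr1", start = 0, end = 100)
  expect_error(permutation_colocalization(big, b, sizes2, 10), "longer")
  alien <- data.frame(chrom = "chrZ", start = 0, end = 100)
  expect_error(permutation_colocalization(alien, b, sizes2, 10), "chrZ")
})

test_that("genome-mode permutation relocates across chromosomes", {
  # all observed regions on chr1; set_b only on chr2: per-chromosome
  # permutation can never overlap, genome mode can
  a <- data.frame(chrom = "chr1", start = seq(1000, 9000, 1000))
  a$end <- a$start + 100
  b <- data.frame(chrom = "chr2", start = seq(0, 9e5, 1e4))
  b$end <- b$start + 5000
  rp <- permutation_colocalization(a, b, sizes2, n_perm = 50, seed = 4,
                                   mode = "per_chromosome")
  rg <- permutation_colocalization(a, b, sizes2, n_perm = 50, seed = 4,
                                   mode = "genome")
  expect_equal(sum(rp$null), 0)
  expect_gt(sum(rg$null), 0)
})

test_that("expression correlation behaves at the identities", {
  set.seed(804)
  vals <- matrix(2^rnorm(50 * 4, 3), 4,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:50)))
  vals["g3", ] <- 5  # zero variance
  meta <- data.frame(sample_id = paste0("s", 1:50), cell_type = "K562",
                     fraction = "cell")
  ex <- expression_set(vals, meta)
  expect_equal(expression_correlation(ex, "g1", "g1")$r, 1)
  expect_true(is.na(expression_correlation(ex, "g1", "g3")$r))
  # exact negatives (on the raw scale, no transform)
  vals2 <- vals
  vals2["g2", ] <- max(vals2["g1", ]) - vals2["g1", ]
  ex2 <- expression_set(vals2, meta)
  expect_equal(
    expression_correlation(ex2, "g1", "g2", log_transform = FALSE)$r, -1)
  expect_error(expression_correlation(ex, "g1", "missing"), "absent")
})

test_that("gene ranking sorts by correlation with deterministic ties", {
  vals <- matrix(0, 5, 10,
                 dimnames = list(c("L", "b", "a", "c", "d"), paste0("s", 1:10)))
  base <- 1:10
  vals["L", ] <- 2^base
  vals["a", ] <- 2^(base + rnorm(10, 0, .01))        # r ~ 1
  vals["b", ] <- 2^(-0.3 * base + rnorm(10, 0, .2)) # negative
  vals["c", ] <- 2^(0.5 * base + rnorm(10, 0, .5))  # middling
  vals["d", ] <- 2^base                              # r = 1 exactly
  meta <- data.frame(sample_id = paste0("s", 1:10), cell_type = "x",
                     fraction = "cell")
  ex <- expression_set(vals, meta)
  rk <- rank_genes_for_lincrna(ex, "L", c("a", "b", "c", "d"))
  expect_equal(rk$gene_id[1], "d")
  expect_true(which(rk$gene_id == "b") == 4)
  expect_equal(order(-rk$score), seq_len(nrow(rk)))
  # all-tie scores fall back to lexicographic ids
  vals_t <- vals; vals_t["a", ] <- vals_t["d", ] <- vals_t["L", ]
  vals_t["b", ] <- vals_t["c", ] <- vals_t["L", ]
  ext <- expression_set(vals_t, meta)
  rkt <- rank_genes_for_lincrna(ext, "L", c("a", "b", "c", "d"))
  expect_equal(rkt$gene_id, c("a", "b", "c", "d"))
  # ranking invariant under strictly monotone transform of expression
  ex_m <- expression_set(vals^1.7, meta)
  rk_m <- rank_genes_for_lincrna(ex_m, "L", c("a", "b", "c", "d"),
                                 method = "spearman")
  rk_s <- rank_genes_for_lincrna(ex, "L", c("a", "b", "c", "d"),
                                 method = "spearman")
  expect_equal(rk_m$gene_id, rk_s$gene_id)
})

test_that("GSEA enrichment score matches the literal running sum", {
  set.seed(805)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    scores <- sort(round(rnorm(n), 3), decreasing = TRUE)
    genes <- sprintf("g%03d", 1:n)
    k <- sample(3:(n - 2), 1)
    hits <- genes %in% sample(genes, k)
    for (p in c(0, 1)) {
      got <- lincChIN:::.gsea_es(scores, hits, p)
      want <- gsea_es_bruteforce(scores, hits, p)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("GSEA of a top-heavy set gives the analytic maximum", {
  # 10 genes, equal scores, set = top 3; with weight 1 and equal |scores|
  # the running sum peaks after the third hit at 1 - 0/7... compute by hand:
  # each hit adds 1/3, each miss subtracts 1/7; peak = 3/3 - 0 = 1 at pos 3
  scores <- rep(2, 10)
  hits <- c(TRUE, TRUE, TRUE, rep(FALSE, 7))
  expect_equal(lincChIN:::.gsea_es(scores, hits, 1), 1)
  # reversing a symmetric ranking flips the ES sign at weight 0
  sym_scores <- c(5, 4, 3, -3, -4, -5)
  hits2 <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  es_fwd <- lincChIN:::.gsea_es(sym_scores, hits2, 0)
  es_rev <- lincChIN:::.gsea_es(rev(sym_scores), rev(hits2), 0)
  expect_equal(es_fwd, -es_rev)
})

test_that("gsea_preranked reports calibrated terms with BH FDR", {
  set.seed(806)
  n <- 60
  ranked <- data.frame(gene_id = sprintf("g%03d", 1:n),
                       score = seq(3, -3, length.out = n))
  sets <- list(TOP = ranked$gene_id[1:10],
               RANDOM = sample(ranked$gene_id, 10),
               TINY = ranked$gene_id[1:2],        # below min_size
               ABSENT = c("x1", "x2", "x3", "x4", "x5"))
  expect_warning(res <- gsea_preranked(ranked, sets, n_perm = 200, seed = 2),
                 "skipping")
  expect_setequal(res$term, c("TOP", "RANDOM"))
  expect_true(res$es[res$term == "TOP"] > 0.5)
  expect_lt(res$p_value[res$term == "TOP"],
            res$p_value[res$term == "RANDOM"] + 1e-9)
  expect_true(all(res$fdr_q >= res$p_value - 1e-12))
  expect_true(all(abs(res$es) <= 1))
  # a set equal to the whole universe is rejected
  expect_error(gsea_preranked(ranked, list(ALL = ranked$gene_id), n_perm = 10),
               "universe")
  # determinism
  r2 <- suppressWarnings(gsea_preranked(ranked, sets, n_perm = 200, seed = 2))
  expect_equal(res$p_value, r2$p_value)
})

test_that("GSEA ES agrees with fgsea's enrichment statistic", {
  skip_if_not_installed("fgsea")
  set.seed(807)
  n <- 40
  scores <- sort(rnorm(n), decreasing = TRUE)
  genes <- sprintf("g%03d", 1:n)
  for (rep in 1:10) {
    hits <- genes %in% sample(genes, 8)
    ours <- lincChIN:::.gsea_es(scores, hits, 1)
    theirs <- fgsea::calcGseaStat(stats::setNames(scores, genes),
                                  selectedStats = which(hits),
                                  gseaParam = 1)
    if (theirs == 0 && ours != 0) {
      # fgsea reports 0 when the positive and negative extremes tie exactly;
      # we keep the first extreme. Verify it really is a tie.
      w <- abs(scores)^1
      hit_step <- ifelse(hits, w / sum(w[hits]), 0)
      rs <- cumsum(hit_step - ifelse(hits, 0, 1 / (n - sum(hits))))
      expect_equal(max(rs), -min(rs), tolerance = 1e-10)
      expect_equal(abs(ours), max(rs), tolerance = 1e-10)
    } else {
      expect_equal(ours, theirs, tolerance = 1e-10)
    }
  }
})

test_that("association matrices zero non-significant terms and find blocks", {
  mk_res <- function(terms, nes, q) {
    structure(data.frame(term = terms, size = 10, es = nes / 2, nes = nes,
                         p_value = q, fdr_q = q,
                         significant = q <= 0.01),
              class = c("gsea_result", "data.frame"))
  }
  terms <- sprintf("T%02d", 1:4)
  # two orthogonal blocks: lincs 1-3 hit T01/T02, lincs 4-6 hit T03/T04
  gl <- list()
  for (i in 1:3)
    gl[[sprintf("L%d", i)]] <- mk_res(terms, c(2, 2, 0.1, 0.1),
                                      c(1e-5, 1e-5, 0.9, 0.9))
  for (i in 4:6)
    gl[[sprintf("L%d", i)]] <- mk_res(terms, c(0.1, 0.1, 2, 2),
                                      c(0.9, 0.9, 1e-5, 1e-5))
  am <- build_association_matrix(gl, k = 2, seed = 3)
  expect_equal(dim(am$matrix), c(6, 4))
  # non-significant entries are exactly 0
  expect_true(all(am$matrix[1:3, c("T03", "T04")] == 0))
  # planted row blocks recovered
  expect_equal(length(unique(am$row_clusters[1:3])), 1)
  expect_equal(length(unique(am$row_clusters[4:6])), 1)
  expect_false(am$row_clusters[1] == am$row_clusters[4])
  # identical rows always land in one cluster, whatever k asks for
  same <- build_association_matrix(gl[c(1, 2, 3)], k = 2, seed = 3)
  expect_equal(length(unique(same$row_clusters)), 1)
  expect_error(build_association_matrix(gl[1:2], k = 10), "fewer")
})

test_that("community enrichment equals the explicit hypergeometric tail", {
  universe <- sprintf("u%03d", 1:40)
  sets <- list(S1 = universe[1:10], S2 = universe[31:40])
  community <- universe[1:10]       # community = all of S1
  res <- enrich_community(community, universe, sets)
  expect_equal(res$p_value[res$term == "S1"],
               hyper_tail(10, 10, 40, 10), tolerance = 1e-12)
  expect_equal(res$p_value[res$term == "S2"],
               hyper_tail(0, 10, 40, 10), tolerance = 1e-12)
  expect_equal(res$p_value[res$term == "S2"], 1)
  # community = universe: every term has p = 1
  res_all <- enrich_community(universe, universe, sets)
  expect_true(all(res_all$p_value == 1))
  expect_error(enrich_community(community, character(0), sets), "empty")
  # random configurations against the summation oracle
  set.seed(808)
  for (rep in 1:20) {
    nu <- sample(10:50, 1)
    u <- sprintf("x%03d", 1:nu)
    s <- list(S = sample(u, sample(2:nu, 1)))
    comm <- sample(u, sample(2:nu, 1))
    got <- enrich_community(comm, u, s)$p_value
    k <- length(intersect(s$S, comm))
    expect_equal(got, hyper_tail(k, length(s$S), nu, length(comm)),
                 tolerance = 1e-12)
  }
})

test_that("group comparisons detect separation and respect rank invariance", {
  same <- compare_groups(1:20, 1:20)
  expect_gt(same$p_value, 0.9)
  sep <- compare_groups(1:20, 101:120)
  expect_lt(sep$p_value, 1e-6)
  # invariant under common monotone transform
  set.seed(809)
  a <- rnorm(15); b <- rnorm(15, 1)
  p1 <- compare_groups(a, b)$p_value
  p2 <- compare_groups(exp(a), exp(b))$p_value
  expect_equal(p1, p2)
})
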