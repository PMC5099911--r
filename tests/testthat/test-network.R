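cluster_row <- function(ca, sa, ea, cb, sb, eb, pet = 1) {
  data.frame(chrom_a = ca, start_a = sa, end_a = ea,
             chrom_b = cb, start_b = sb, end_b = eb,
             pet_count = pet, self_contact = FALSE)
}

test_that("a single cluster away from promoters yields two DRE nodes, one edge", {
  cl <- cluster_row("chr1", 100, 200, "chr1", 5000, 5100)
  prom <- data.frame(gene_id = "G1", chrom = "chr1", start = 9000, end = 14000)
  chin <- build_chin(cl, prom)
  expect_equal(nrow(chin$nodes), 2)
  expect_true(all(chin$nodes$role == "dre"))
  expect_equal(nrow(chin$edges), 1)
  expect_equal(chin$edges$weight, 1)
})

test_that("overlapping anchors merge into shared nodes (4-anchor fixture)", {
  cl <- rbind(cluster_row("chr1", 100, 300, "chr1", 5000, 5100),
              cluster_row("chr1", 250, 400, "chr1", 8000, 8100))
  chin <- build_chin(cl)
  # left anchors chain-overlap -> one node; 3 nodes total, 2 edges
  expect_equal(nrow(chin$nodes), 3)
  expect_equal(nrow(chin$edges), 2)
  left <- chin$nodes[chin$nodes$start == 100, ]
  expect_equal(left$end, 400)
})

test_that("self-loop clusters are dropped but their node remains", {
  cl <- rbind(cluster_row("chr1", 100, 200, "chr1", 150, 250),
              cluster_row("chr1", 5000, 5100, "chr1", 9000, 9100))
  expect_message(chin <- build_chin(cl), "dropped")
  expect_equal(nrow(chin$edges), 1)
  # the merged self-loop node exists with degree 0
  expect_equal(nrow(chin$nodes), 3)
  deg <- igraph::degree(chin$graph)
  expect_equal(sort(unname(deg)), c(0, 1, 1))
})

test_that("parallel clusters collapse into one weighted edge", {
  cl <- rbind(cluster_row("chr1", 100, 200, "chr1", 5000, 5100, pet = 3),
              cluster_row("chr1", 120, 190, "chr1", 5010, 5090, pet = 4))
  chin <- build_chin(cl)
  expect_equal(nrow(chin$edges), 1)
  expect_equal(chin$edges$weight, 2)
  expect_equal(chin$edges$total_pet, 7)
})

test_that("node regions are disjoint and degree sum equals twice the edges", {
  set.seed(601)
  for (rep in 1:10) {
    n <- 40
    a <- random_intervals(n, max_coord = 5000)
    b <- random_intervals(n, max_coord = 5000)
    cl <- data.frame(chrom_a = a$chrom, start_a = a$start, end_a = a$end,
                     chrom_b = b$chrom, start_b = b$start, end_b = b$end,
                     pet_count = 1, self_contact = FALSE)
    chin <- suppressMessages(build_chin(cl))
    nd <- chin$nodes[order(chin$nodes$chrom, chin$nodes$start), ]
    same <- nd$chrom[-1] == nd$chrom[-nrow(nd)]
    expect_true(all(!same | nd$start[-1] >= nd$end[-nrow(nd)]))
    dd <- compute_descriptors(chin)$degree_distribution
    expect_equal(sum(as.integer(names(dd)) * dd), 2 * nrow(chin$edges))
  }
})

test_that("promoter roles come from >= 1 bp overlap with promoter windows", {
  cl <- cluster_row("chr1", 100, 200, "chr1", 5000, 5100)
  # promoter window abuts the left anchor: zero shared bases -> dre
  prom0 <- data.frame(gene_id = "G1", chrom = "chr1", start = 200, end = 700)
  expect_true(all(build_chin(cl, prom0)$nodes$role == "dre"))
  # one shared base -> promoter
  prom1 <- data.frame(gene_id = "G1", chrom = "chr1", start = 199, end = 700)
  chin <- build_chin(cl, prom1)
  n1 <- chin$nodes[chin$nodes$start == 100, ]
  expect_equal(n1$role, "promoter")
  expect_equal(n1$gene_ids[[1]], "G1")
})

test_that("descriptors match closed forms on canonical graphs", {
  # triangle: transitivity 1, density 1
  tri <- rbind(cluster_row("chr1", 0, 10, "chr1", 100, 110),
               cluster_row("chr1", 100, 110, "chr1", 200, 210),
               cluster_row("chr1", 200, 210, "chr1", 0, 10))
  d <- compute_descriptors(build_chin(tri))
  expect_equal(d$transitivity, 1)
  expect_equal(d$graph_density, 1)
  expect_equal(d$component_sizes, 3L)

  # star with 5 leaves: center betweenness = choose(5,2) = 10
  star <- do.call(rbind, lapply(1:5, function(i)
    cluster_row("chr1", 0, 10, "chr1", i * 1000, i * 1000 + 10)))
  ds <- compute_descriptors(build_chin(star))
  expect_equal(max(ds$betweenness), 10)
  expect_equal(sort(unname(ds$degree_distribution)), c(1, 5))

  # all-equal degrees: exponent undefined, reported absent
  expect_true(is.na(d$power_law_exponent))
})

test_that("community detection splits planted structures", {
  # two 10-cliques joined by one bridge edge
  clique <- function(offset, chrom) {
    pairs <- utils::combn(1:10, 2)
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(j)
      cluster_row(chrom, offset + pairs[1, j] * 1000,
                  offset + pairs[1, j] * 1000 + 10,
                  chrom, offset + pairs[2, j] * 1000,
                  offset + pairs[2, j] * 1000 + 10)))
  }
  cl <- rbind(clique(0, "chr1"), clique(0, "chr2"),
              cluster_row("chr1", 1000, 1010, "chr2", 1000, 1010))
  chin <- build_chin(cl)
  comm <- detect_communities(chin, seed = 5)
  expect_equal(length(comm$sizes), 2)
  expect_equal(sort(unname(comm$sizes)), c(10, 10))
  # the partition covers every node exactly once
  expect_equal(length(comm$membership), nrow(chin$nodes))

  # single-node graph (arises from a self-loop-only cluster set)
  sl <- suppressMessages(build_chin(cluster_row("chr1", 0, 10, "chr1", 5, 15)))
  cs <- detect_communities(sl, seed = 1)
  expect_equal(length(cs$sizes), 1)

  # edgeless graph of n nodes -> n singleton communities
  el <- suppressMessages(build_chin(rbind(
    cluster_row("chr1", 0, 10, "chr1", 5, 15),
    cluster_row("chr1", 1000, 1010, "chr1", 1005, 1015),
    cluster_row("chr1", 2000, 2010, "chr1", 2005, 2015))))
  ce <- detect_communities(el, seed = 1)
  expect_equal(length(ce$sizes), 3)
  expect_true(all(ce$sizes == 1))
})

test_that("community detection is deterministic and beats the trivial partition", {
  sim <- get_desk_sim()
  c1 <- detect_communities(sim$chin, seed = 9)
  c2 <- detect_communities(sim$chin, seed = 9)
  expect_identical(c1$membership, c2$membership)
  g <- sim$chin$graph
  mod <- igraph::modularity(g, c1$membership, weights = igraph::E(g)$weight)
  triv <- igraph::modularity(g, rep(1, igraph::vcount(g)),
                             weights = igraph::E(g)$weight)
  expect_gt(mod, triv)
})

test_that("k-hop neighborhoods follow shortest-path distance", {
  # path a-b-c-d-e as 4 chained clusters
  path <- do.call(rbind, lapply(1:4, function(i)
    cluster_row("chr1", i * 1000, i * 1000 + 10,
                "chr1", (i + 1) * 1000, (i + 1) * 1000 + 10)))
  chin <- build_chin(path)
  a <- chin$nodes$node_id[chin$nodes$start == 1000]
  expect_equal(k_hop_neighborhood(chin, a, 0), a)             # k=0: seeds
  expect_equal(length(k_hop_neighborhood(chin, a, 3)), 4)     # {a,b,c,d}
  expect_equal(length(k_hop_neighborhood(chin, a, 10)), 5)
  expect_error(k_hop_neighborhood(chin, 999, 1), "999")
  # nesting property
  for (k in 0:3)
    expect_true(all(k_hop_neighborhood(chin, a, k) %in%
                      k_hop_neighborhood(chin, a, k + 1)))
})

test_that("k-hop equals boolean adjacency-power reachability on random graphs", {
  set.seed(602)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    cl <- do.call(rbind, lapply(seq_len(n), function(i) {
      j <- sample(setdiff(seq_len(n), i), 1)
      cluster_row("chr1", i * 1000, i * 1000 + 10,
                  "chr1", j * 1000, j * 1000 + 10)
    }))
    chin <- suppressMessages(build_chin(cl))
    m <- nrow(chin$nodes)
    adj <- matrix(FALSE, m, m)
    for (r in seq_len(nrow(chin$edges))) {
      adj[chin$edges$from[r], chin$edges$to[r]] <- TRUE
      adj[chin$edges$to[r], chin$edges$from[r]] <- TRUE
    }
    seeds <- sample(chin$nodes$node_id, 2)
    for (k in 0:4)
      expect_equal(k_hop_neighborhood(chin, seeds, k),
                   khop_bruteforce(adj, seeds, k))
  }
})

test_that("gene subnetwork expansion matches a brute-force double loop", {
  sim <- get_desk_sim()
  sub <- extract_gene_subnetwork(sim$chin, sim$genes)
  # brute force over edges x gene annotations
  bt <- setNames(sim$genes$biotype, sim$genes$gene_id)
  want <- list()
  for (i in seq_len(nrow(sim$chin$edges))) {
    gf <- sim$chin$nodes$gene_ids[[sim$chin$edges$from[i]]]
    gt <- sim$chin$nodes$gene_ids[[sim$chin$edges$to[i]]]
    for (x in gf) for (y in gt) {
      if (bt[x] == "lincRNA" && bt[y] == "protein_coding")
        want[[length(want) + 1]] <- c(x, y)
      if (bt[y] == "lincRNA" && bt[x] == "protein_coding")
        want[[length(want) + 1]] <- c(y, x)
    }
  }
  want <- unique(do.call(rbind, want))
  expect_equal(nrow(sub), nrow(want))
  expect_setequal(paste(sub$gene_a, sub$gene_b),
                  paste(want[, 1], want[, 2]))
  # every C1 lincRNA appears; no C2+ lincRNA does
  c1 <- sim$truth$gene_id[sim$truth$category == "C1"]
  expect_setequal(unique(sub$gene_a), c1)
})

test_that("a node carrying two coding genes expands to two gene pairs", {
  cl <- cluster_row("chr1", 100, 200, "chr1", 5000, 5100)
  prom <- data.frame(gene_id = c("L1", "P1", "P2"), chrom = "chr1",
                     start = c(90, 4990, 5050), end = c(210, 5090, 5150))
  genes <- genes_fixture(
    list(gene_id = "L1", biotype = "lincRNA", chrom = "chr1", start = 100,
         end = 200),
    list(gene_id = "P1", biotype = "protein_coding", chrom = "chr1",
         start = 4990, end = 5090),
    list(gene_id = "P2", biotype = "protein_coding", chrom = "chr1",
         start = 5050, end = 5150))
  chin <- build_chin(cl, prom)
  sub <- extract_gene_subnetwork(chin, genes)
  expect_equal(nrow(sub), 2)
  expect_setequal(sub$gene_b, c("P1", "P2"))
  # no cross-biotype edges -> empty
  none <- extract_gene_subnetwork(chin, genes, "miRNA", "antisense")
  expect_equal(nrow(none), 0)
})

test_that("gene pair distances use canonical 5'-most TSSs", {
  genes <- genes_fixture(
    list(gene_id = "A", biotype = "lincRNA", chrom = "chr1", start = 10000,
         end = 12000, tss = c(10000, 10500)),
    list(gene_id = "B", biotype = "protein_coding", chrom = "chr1",
         start = 110000, end = 115000, strand = "-",
         tss = c(112000, 114999)),
    list(gene_id = "C", biotype = "protein_coding", chrom = "chr2",
         start = 10000, end = 11000))
  d <- gene_pair_distance("A", "B", genes)
  expect_equal(d$distance, 114999 - 10000)  # + gene min TSS, - gene max TSS
  expect_false(d$inter_chromosomal)
  expect_equal(gene_pair_distance("A", "A", genes)$distance, 0)
  expect_true(gene_pair_distance("A", "C", genes)$inter_chromosomal)
})

test_that("GraphML serialization preserves structure and attributes", {
  sim <- get_desk_sim()
  f <- withr::local_tempfile(fileext = ".graphml")
  write_chin_graphml(sim$chin, f)
  back <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(back), nrow(sim$chin$nodes))
  expect_equal(igraph::ecount(back), nrow(sim$chin$edges))
  expect_setequal(unique(igraph::V(back)$role), c("promoter", "dre"))
  expect_equal(sort(igraph::E(back)$weight), sort(sim$chin$edges$weight))
})

test_that("rebuilding a ChIN from its own node regions is a fixed point", {
  sim <- get_desk_sim()
  nodes <- sim$chin$nodes
  remerged <- merge_intervals(nodes[, c("chrom", "start", "end")])
  expect_equal(nrow(remerged), nrow(nodes))
  expect_equal(remerged$start, sort_by <- nodes[order(nodes$chrom, nodes$start), ]$start)
})
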