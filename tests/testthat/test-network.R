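# fixture: 8 sites x 6 OTUs with two planted correlated blocks
fixture_table <- function() {
  base <- c(30, 25, 20, 35, 28, 22, 31, 26)
  cnt <- cbind(o1 = base, o2 = base + 2, # strongly positively correlated
               o3 = 60 - base, # anti-correlated with o1/o2
               o4 = c(5, 9, 2, 8, 3, 7, 4, 6), # unrelated
               o5 = c(12, 0, 10, 0, 11, 0, 9, 0), # low prevalence
               o6 = c(40, 42, 38, 45, 41, 37, 44, 39))
  rownames(cnt) <- paste0("s", 1:8)
  meta <- data.frame(site = rownames(cnt),
                     area = rep(c("anomaly", "reference"), each = 4),
                     au = c(8, 4, 3, 12, 1, 2, 1.5, 1))
  tax <- data.frame(otu = colnames(cnt),
                    phylum = "Ascomycota",
                    order = paste0("Order", 1:6))
  otu_table(cnt, meta, tax)
}

test_that("edges equal a brute-force correlation scan on the fixture", {
  tab <- fixture_table()
  net <- build_network(tab, min_prevalence = 6, threshold = 0.7, level = "otu")
  # brute force: same preprocessing, direct double loop over pairs
  cnt <- tab$counts[, colSums(tab$counts > 0) >= 6]
  rel <- cnt / rowSums(cnt)
  want <- NULL
  for (i in seq_len(ncol(rel) - 1)) {
    for (j in seq(i + 1, ncol(rel))) {
      r <- cor(rel[, i], rel[, j])
      if (abs(r) >= 0.7)
        want <- rbind(want, data.frame(from = colnames(rel)[i],
                                       to = colnames(rel)[j], r = r))
    }
  }
  got <- net$edges[order(net$edges$from, net$edges$to), ]
  want <- want[order(want$from, want$to), ]
  expect_equal(got$from, want$from)
  expect_equal(got$to, want$to)
  expect_equal(got$r, want$r)
  expect_equal(got$sign, ifelse(want$r >= 0, "positive", "negative"))
  # the low-prevalence OTU was filtered before correlating
  expect_false("o5" %in% net$nodes)
})

test_that("order-level aggregation sums counts before correlating", {
  tab <- fixture_table()
  tab$taxonomy$order <- c("A", "A", "B", "B", "C", "C")
  net <- build_network(tab, min_prevalence = 6, threshold = 0.7,
                       level = "order")
  expect_setequal(net$nodes, c("A", "B", "C"))
  agg <- t(rowsum(t(tab$counts), tab$taxonomy$order))
  rel <- agg / rowSums(agg)
  ab <- net$edges$r[net$edges$from == "A" & net$edges$to == "B"]
  expect_equal(ab, cor(rel[, "A"], rel[, "B"]))
})

test_that("constant taxa are excluded with a message", {
  cnt <- cbind(o1 = c(10, 20, 30, 40), o2 = c(40, 30, 20, 10),
               o3 = c(25, 25, 25, 25))
  rel_const <- cnt / rowSums(cnt) # o3 has constant relative abundance
  expect_true(sd(rel_const[, "o3"]) == 0)
  rownames(cnt) <- paste0("s", 1:4)
  meta <- data.frame(site = rownames(cnt), area = "anomaly", au = 1:4)
  expect_message(
    net <- build_network(otu_table(cnt, meta), min_prevalence = 1,
                         threshold = 0.5, level = "otu"),
    "constant taxa: o3")
  expect_equal(net$excluded, "o3")
  expect_setequal(net$nodes, c("o1", "o2"))
})

test_that("network construction validates its inputs", {
  tab <- fixture_table()
  expect_error(build_network(tab, sites = c("s1", "s2", "s3")),
               "at least four sites")
  expect_error(build_network(tab, min_prevalence = 9), "fewer than two taxa")
})

test_that("toy motifs give the classic centrality and modularity cases", {
  path3 <- gen_toy_network("path", n = 3)
  expect_equal(stress_centrality(path3), c(a = 0, b = 1, c = 0))
  star <- gen_toy_network("star", n = 3)
  cs <- stress_centrality(star)
  expect_equal(unname(cs["center"]), 3) # all C(3,2) leaf pairs pass through
  expect_true(all(cs[names(cs) != "center"] == 0))
  clique <- gen_toy_network("clique", n = 4)
  expect_true(all(stress_centrality(clique) == 0))
  two <- gen_toy_network("two_cliques", n = 3)
  mods <- greedy_modules(two)
  expect_equal(mods$Q, 0.5)
  expect_equal(mods$n_modules, 2)
  expect_equal(as.vector(table(mods$membership)), c(3L, 3L))
  expect_error(gen_toy_network("wheel"))
  expect_error(gen_toy_network("custom"), "edge list")
  expect_error(stress_centrality(path3, "z"), "unknown node")
  expect_equal(stress_centrality(path3, "b"), c(b = 1))
})

test_that("stress centrality counts multiple shortest paths", {
  # diamond a-b, a-c, b-d, c-d: two shortest a-d paths, one through each mid
  net <- gen_toy_network("custom", edges = data.frame(
    from = c("a", "a", "b", "c"), to = c("b", "c", "d", "d")))
  expect_equal(stress_centrality(net), c(a = 1, b = 1, c = 1, d = 1))
})

test_that("stress centrality matches path enumeration on random graphs", {
  for (seed in 1:12) {
    net <- random_toy_network(n = 8, p = 0.35, seed = seed)
    expect_equal(stress_centrality(net), oracle_stress(net),
                 label = paste("seed", seed))
  }
})

test_that("greedy modularity matches the independent greedy oracle and is
           bounded by the exhaustive optimum", {
  for (seed in 1:12) {
    net <- random_toy_network(n = 7, p = 0.4, seed = seed)
    mods <- greedy_modules(net)
    expect_equal(mods$Q, oracle_greedy_Q(net), tolerance = 1e-12,
                 label = paste("seed", seed))
    expect_lte(mods$Q, oracle_best_modularity(net) + 1e-12)
    # reported Q is the modularity of the reported membership
    expect_equal(mods$Q, igraph::modularity(net$graph, mods$membership))
  }
})

test_that("greedy modularity finds the exhaustive optimum on separable toys", {
  for (net in list(gen_toy_network("two_cliques", 3),
                   gen_toy_network("two_cliques", 4),
                   gen_toy_network("star", 4))) {
    expect_equal(greedy_modules(net)$Q, oracle_best_modularity(net))
  }
  expect_error(greedy_modules(network_from_edges(
    data.frame(from = character(0), to = character(0)),
    nodes = c("a", "b"))), "no edges")
})

test_that("network export writes edges, nodes and graphml", {
  d <- tempfile("net")
  dir.create(d)
  net <- gen_toy_network("two_cliques", 3)
  paths <- export_network(net, file.path(d, "toy"), header = "h1")
  expect_true(all(file.exists(paths)))
  nodes <- read.delim(paths[2], comment.char = "#")
  expect_equal(nrow(nodes), 6)
  expect_equal(sort(unique(nodes$module)), c(1, 2))
  g2 <- igraph::read_graph(paths[3], format = "graphml")
  expect_equal(igraph::ecount(g2), 6)
  # isolated-node networks export with NA modules instead of failing
  lone <- network_from_edges(data.frame(from = character(0), to = character(0)),
                             nodes = c("a", "b"))
  paths2 <- export_network(lone, file.path(d, "lone"))
  expect_true(all(is.na(read.delim(paths2[2], comment.char = "#")$module)))
})
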