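test_that("protein graph uses the min-evalue rule, threshold, and no self-loops", {
  hits <- rbind(hit_row("A", "B", 95, 100, 1e-10, 200, 1, 100),
                hit_row("B", "A", 95, 100, 1e-8, 190, 1, 100),
                hit_row("A", "A", 100, 100, 1e-50, 400, 1, 100),
                hit_row("A", "C", 40, 80, 1e-4, 50, 1, 80))
  g <- build_protein_graph(hits)
  expect_setequal(g$nodes, c("A", "B", "C"))
  expect_equal(nrow(g$edges), 1L)                 # C fails 1e-5; A-A dropped
  expect_equal(sort(c(g$edges$from, g$edges$to)), c("A", "B"))
  expect_equal(g$edges$weight, 10)                # -log10(min(1e-10, 1e-8))
  # weight cap at 200
  h0 <- hit_row("X", "Y", 99, 100, 0, 500, 1, 100)
  expect_equal(build_protein_graph(h0)$edges$weight, 200)
  # empty hit list with explicit nodes -> isolated nodes only
  g0 <- build_protein_graph(empty_hits_df <- hit_row("q", "s", 1, 1, 1, 1, 1, 1)[0, ],
                            nodes = c("p1", "p2"))
  expect_equal(g0$nodes, c("p1", "p2"))
  expect_equal(nrow(g0$edges), 0L)
})

test_that("MCL separates cliques, keeps singletons, splits a bridged pair", {
  # two 3-cliques, no bridge
  g <- graph_of(c(paste0("a", 1:3), paste0("b", 1:3)),
                c(clique_pairs(paste0("a", 1:3)),
                  clique_pairs(paste0("b", 1:3))))
  part <- mcl_cluster(g)
  expect_identical(canon_partition(part),
                   canon_partition(list(paste0("a", 1:3), paste0("b", 1:3))))
  expect_true(attr(part, "converged"))

  # single node
  p1 <- mcl_cluster(graph_of("solo", list()))
  expect_identical(canon_partition(p1), list("solo"))

  # two 4-cliques joined by one unit-weight bridge split at the bridge;
  # expectation frozen from the independent dense oracle
  nodes <- c(paste0("a", 1:4), paste0("b", 1:4))
  g2 <- graph_of(nodes, c(clique_pairs(paste0("a", 1:4)),
                          clique_pairs(paste0("b", 1:4)),
                          list(c("a1", "b1"))))
  oracle <- oracle_mcl(g2$nodes, g2$edges)
  expect_identical(canon_partition(oracle),
                   canon_partition(list(paste0("a", 1:4), paste0("b", 1:4))))
  expect_identical(canon_partition(mcl_cluster(g2)), canon_partition(oracle))
})

test_that("MCL agrees with the dense oracle on random graphs (property)", {
  for (s in 1:30) {
    n <- sample(3:12, 1)
    g <- random_graph(n, p = stats::runif(1, 0.15, 0.6), seed = 1000 + s)
    got <- canon_partition(mcl_cluster(g))
    want <- canon_partition(oracle_mcl(g$nodes, g$edges))
    expect_identical(got, want, info = paste("seed", 1000 + s))
    # partition property: every node exactly once
    expect_setequal(unlist(got), g$nodes)
    expect_equal(length(unlist(got)), length(g$nodes))
  }
})

test_that("clusters never span disconnected components", {
  g <- graph_of(c("x1", "x2", "y1", "y2"),
                list(c("x1", "x2"), c("y1", "y2")))
  part <- mcl_cluster(g)
  for (cl in part) {
    expect_true(all(startsWith(cl, "x")) || all(startsWith(cl, "y")))
  }
})

test_that("filter_clusters sizes, ordering, ties and representatives", {
  prots <- c(a = "MAAAAA", b = "MCCCCCCC", c = "MDD",
             d = "MEEEE", e = "MFFFF", f = "MGG")
  # sizes 3 and 2 -> token ids 2 and 3; singleton dropped
  vocab <- filter_clusters(list(c("a", "b", "c"), c("d", "e"), "f"), prots)
  expect_equal(names(vocab$clusters), c("2", "3"))
  expect_equal(vocab$clusters[["2"]], c("a", "b", "c"))
  expect_equal(vocab$clusters[["3"]], c("d", "e"))
  # representative = longest member; tie -> lexicographically smallest id
  expect_equal(unname(vocab$representatives[["2"]]), "b")
  expect_equal(unname(vocab$representatives[["3"]]), "d")
  expect_equal(vocab_size(vocab), 4L)

  # all singletons -> only reserved ids
  v0 <- filter_clusters(list("a", "b"), prots)
  expect_length(v0$clusters, 0L)
  expect_equal(vocab_size(v0), 2L)

  # deterministic under input order permutation
  v1 <- filter_clusters(list(c("d", "e"), c("c", "b", "a")), prots)
  expect_identical(v1$clusters, vocab$clusters)
  expect_identical(v1$representatives, vocab$representatives)

  # equal sizes tie-break: lexicographically smallest member id first
  v2 <- filter_clusters(list(c("d", "e"), c("a", "b")), prots)
  expect_equal(v2$clusters[["2"]], c("a", "b"))
  expect_equal(v2$clusters[["3"]], c("d", "e"))
})

test_that("internal SW engine: identical proteins hit, random pairs do not", {
  set.seed(55)
  p <- random_aa(100)
  eng <- sw_protein_engine()
  hits <- eng(c(q1 = p), c(s1 = p))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$pident, 100)
  expect_lt(hits$evalue, 1e-20)
  expect_equal(hits$qcovhsp, 100)
  # unrelated random proteins never reach the 1e-5 edge threshold
  set.seed(56)
  rand <- vapply(1:5, function(i) random_aa(100), "")
  h2 <- eng(c(q = rand[1]), stats::setNames(rand[-1], paste0("s", 1:4)))
  if (nrow(h2)) expect_true(all(h2$evalue > 1e-5))
})

test_that("assign_pc applies best-bitscore rule, thresholds, unknown fallback", {
  set.seed(57)
  repA <- random_aa(120); repB <- random_aa(90)
  vocab <- filter_clusters(list(c("pA1", "pA2"), c("pB1", "pB2")),
                           c(pA1 = repA, pA2 = substr(repA, 1, 100),
                             pB1 = repB, pB2 = substr(repB, 1, 80)))
  eng <- sw_protein_engine()
  # member identical to a representative -> that cluster's id
  expect_equal(unname(assign_pc(repA, vocab, eng)), 2L)
  expect_equal(unname(assign_pc(repB, vocab, eng)), 3L)
  # random protein -> unknown token 1
  expect_equal(unname(assign_pc(random_aa(80, seed = 58), vocab, eng)), 1L)
  # self-consistency: every member maps to its own cluster
  for (tok in names(vocab$clusters)) {
    for (m in vocab$clusters[[tok]]) {
      seqs <- c(pA1 = repA, pA2 = substr(repA, 1, 100),
                pB1 = repB, pB2 = substr(repB, 1, 80))
      expect_equal(unname(assign_pc(seqs[m], vocab, eng)),
                   as.integer(tok), info = m)
    }
  }
  # empty vocabulary -> unknown for everything
  v0 <- filter_clusters(list(), c(x = "MAA"))
  expect_equal(unname(assign_pc(repA, v0, eng)), 1L)
})

test_that("vocabulary bundle round-trips through FASTA + TSV", {
  prots <- c(a = "MAAAAAWWA", b = "MCCHHCCC", c = "MDDWWDD", d = "MEE")
  vocab <- filter_clusters(list(c("a", "b"), c("c", "d")), prots)
  prefix <- tempfile()
  write_vocab(vocab, prefix)
  back <- read_vocab(prefix)
  expect_identical(back$clusters, vocab$clusters)
  expect_identical(back$representatives, vocab$representatives)
  expect_identical(back$rep_seqs, vocab$rep_seqs)
})

test_that("tabular hit parsing round-trips the standard dialect", {
  hits <- rbind(hit_row("q1", "s1", 99.5, 120, 1e-30, 250, 1, 120),
                hit_row("q2", "s2", 80.0, 60, 1e-6, 90, 5, 64))
  path <- tempfile()
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  back <- read_tabular_hits(path)
  expect_equal(back, hits, ignore_attr = TRUE)
  expect_equal(nrow(read_tabular_hits(tempfile())), 0L)
})
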