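test_that("gene ranking is by Wald z with deterministic tie-breaking", {
  de <- data.frame(gene_id = c("A", "B", "C"), wald_z = c(3, -1, 0))
  expect_equal(names(rankGenes(de)), c("A", "C", "B"))
  det <- data.frame(gene_id = c("zz", "aa", "mm"), wald_z = c(1, 1, 1))
  expect_equal(names(rankGenes(det)), c("aa", "mm", "zz"))
  ## reversing all signs reverses the ranking
  de2 <- data.frame(gene_id = paste0("g", 1:10), wald_z = rnorm(10))
  de3 <- de2; de3$wald_z <- -de3$wald_z
  expect_equal(names(rankGenes(de2)), rev(names(rankGenes(de3))))
})

test_that("running-sum enrichment score matches a hand-walked oracle", {
  ranked <- setNames(seq(10, 1), paste0("g", 1:10))
  set <- c("g1", "g3")
  ## brute-force walk
  w <- abs(ranked); hit <- names(ranked) %in% set
  rs <- 0; walk <- numeric(10)
  for (i in 1:10) {
    rs <- rs + if (hit[i]) w[i] / sum(w[hit]) else -1 / 8
    walk[i] <- rs
  }
  es_brute <- walk[which.max(abs(walk))]
  res <- enrichmentScore(ranked, set)
  expect_equal(res$es, es_brute, tolerance = 1e-12)
  expect_equal(abs(walk[10]), 0, tolerance = 1e-12)   # sum returns to zero
  ## all members at the very top: maximal enrichment
  expect_equal(enrichmentScore(ranked, c("g1", "g2"))$es, 1)
  ## complement symmetry under equal scores
  eq <- setNames(rep(1, 10), paste0("g", 1:10))
  for (s in list(c("g2", "g5"), c("g1", "g9", "g10"))) {
    expect_equal(enrichmentScore(eq, s)$es,
                 -enrichmentScore(eq, setdiff(names(eq), s))$es,
                 tolerance = 1e-12)
  }
  expect_error(enrichmentScore(ranked, "nope"), "no members")
})

test_that("vectorized null enrichment scores equal the direct computation", {
  set.seed(71)
  ranked <- setNames(sort(rnorm(50), decreasing = TRUE), paste0("g", 1:50))
  seeds <- 1:20
  for (s in c(3, 10)) {
    set.seed(101)
    nulls <- trisomics:::.nullES(ranked, s, 20)
    set.seed(101)
    direct <- vapply(1:20, function(b) {
      members <- names(ranked)[sort(sample.int(50, s))]
      enrichmentScore(ranked, members)$es
    }, 0)
    expect_equal(nulls, direct, tolerance = 1e-12)
  }
})

test_that("preranked GSEA detects planted sets with signed NES", {
  set.seed(72)
  genes <- sprintf("g%03d", 1:400)
  ranked <- setNames(sort(rnorm(400, 0, 2), decreasing = TRUE), genes)
  coll <- list(up = sample(genes[1:40], 20),
               dn = sample(genes[361:400], 20),
               rnd = sample(genes, 30))
  res <- gseaPreranked(ranked, coll, n_perm = 500, seed = 73)
  expect_true(res$signif[res$set == "up"])
  expect_gt(res$nes[res$set == "up"], 0)
  expect_true(res$signif[res$set == "dn"])
  expect_lt(res$nes[res$set == "dn"], 0)
  expect_false(res$signif[res$set == "rnd"])
  ## sign(nes) always matches sign(es)
  expect_true(all(sign(res$nes) == sign(res$es)))
  ## nes invariant to positive rescaling of the ranking scores
  res2 <- gseaPreranked(setNames(ranked * 7, names(ranked)), coll,
                        n_perm = 500, seed = 73)
  expect_equal(res2$nes, res$nes, tolerance = 1e-10)
  expect_equal(res2$p, res$p)
})

test_that("greedy parent-set collapsing keeps the strongest representative", {
  coll <- list(A = paste0("x", 1:10),
               B = paste0("x", c(1:8, 11, 12)),
               C = paste0("x", c(7, 8, 13:20)))
  ## J(A,B) = 8/12 = 0.67, J(B,C) = 2/18, J(A,C) = 2/18 with these members
  gsea <- data.frame(set = c("A", "B", "C"), p = c(0.001, 0.002, 0.003))
  out <- collapseGeneSets(gsea, coll, threshold = 0.5)
  expect_setequal(out$set, c("A", "C"))
  expect_equal(out$collapsed[out$set == "A"], "B")
  ## identical sets: the lower-p one wins
  two <- data.frame(set = c("P", "Q"), p = c(0.01, 0.002))
  out2 <- collapseGeneSets(two, list(P = c("a", "b"), Q = c("a", "b")))
  expect_equal(out2$set, "Q")
  ## disjoint sets all survive
  dis <- data.frame(set = c("U", "V"), p = c(0.1, 0.2))
  expect_equal(nrow(collapseGeneSets(dis, list(U = "a", V = "b"))), 2)
})

test_that("Jaccard clustering equals a brute-force union-find", {
  expect_equal(length(intersect(c("a", "b"), c("b", "c"))) /
               length(union(c("a", "b"), c("b", "c"))), 1 / 3)
  g1 <- data.frame(set = c("S1", "S2"), p = c(0.01, 0.02))
  cl <- clusterGeneSets(g1, list(S1 = c("a", "b"), S2 = c("b", "c")),
                        threshold = 0.25)
  expect_equal(length(unique(cl$cluster)), 1)
  expect_equal(unique(cl$representative), "S1")
  cl2 <- clusterGeneSets(g1, list(S1 = c("a", "b"), S2 = c("c", "d")))
  expect_equal(length(unique(cl2$cluster)), 2)

  ## randomized instances against union-find
  set.seed(74)
  for (rep in 1:10) {
    k <- sample(4:9, 1)
    coll <- lapply(1:k, function(i) sample(letters, sample(3:8, 1)))
    names(coll) <- paste0("S", 1:k)
    gsea <- data.frame(set = names(coll), p = runif(k))
    got <- clusterGeneSets(gsea, coll, threshold = 0.25)
    parent <- 1:k
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      J <- length(intersect(coll[[i]], coll[[j]])) /
        length(union(coll[[i]], coll[[j]]))
      if (J >= 0.25) parent[find(j)] <- find(i)
    }
    roots <- vapply(1:k, find, 1L)
    expect_equal(length(unique(got$cluster)), length(unique(roots)))
    ## same partition, not just the same count
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      expect_equal(got$cluster[i] == got$cluster[j], roots[i] == roots[j])
  }
})

test_that("hypergeometric overrepresentation matches phyper directly", {
  universe <- paste0("g", 1:100)
  query <- paste0("g", 1:20)
  coll <- list(hot = paste0("g", 1:10), cold = paste0("g", 91:100))
  res <- overrepresentationTest(query, universe, coll)
  expect_equal(res$p[res$set == "hot"],
               phyper(9, 10, 90, 20, lower.tail = FALSE))
  expect_equal(res$overlap, c(10, 0))
  expect_equal(res$expected, c(2, 2))
})
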