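test_that("dissimilarity matches closed forms and the brute-force oracle", {
  # diag-1 identity-like matrix: all off-diagonal distances sqrt(2)
  I3 <- diag(3)
  D <- to_dissimilarity(I3)
  expect_equal(D[upper.tri(D)], rep(sqrt(2), 3))
  expect_equal(diag(D), rep(0, 3))

  set.seed(41)
  for (i in 1:50) {
    M <- matrix(rnorm(16), 4)
    expect_equal(to_dissimilarity(M), oracle_dissimilarity(M),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  M <- matrix(rnorm(16), 4); M[2, 3] <- NA
  expect_error(to_dissimilarity(M), "NaN entries")
})

test_that("metric MDS: exact 2-D recovery, seed invariance, distance
           preservation", {
  set.seed(42)
  X <- matrix(rnorm(32), 16)
  d <- as.matrix(dist(X))
  e1 <- mds_embed(d, seed = 1)
  expect_lt(e1$stress, 1e-4)
  e2 <- mds_embed(d, seed = 77)
  expect_lt(procrustes_dist(e1$points, e2$points), 1e-3)

  for (i in 1:3) {
    D <- as.matrix(dist(matrix(rnorm(16 * 3), 16)))
    e <- mds_embed(D, seed = i)
    expect_gt(cor(as.vector(dist(e$points)), as.vector(as.dist(D))), 0.9)
  }
  expect_error(mds_embed(matrix(0, 3, 3)), "degenerate")
})

test_that("leading-eigenvector communities: cliques, uniform graphs, planted
           blocks, igraph cross-check", {
  # two disconnected 4-cliques: perfect split at Q = 0.5
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1
  diag(W) <- 0
  cm <- spectral_communities(W)
  expect_equal(cm$n_communities, 2L)
  expect_equal(cm$Q, 0.5)
  expect_equal(length(unique(cm$membership[1:4])), 1L)

  # complete uniform graph has no structure
  U <- matrix(1, 6, 6); diag(U) <- 0
  cu <- spectral_communities(U)
  expect_lte(cu$Q, 0)
  expect_equal(spectral_communities(matrix(0, 5, 5))$n_communities, 1L)

  # random planted two-block matrices agree with igraph's implementation
  set.seed(43)
  for (i in 1:5) {
    B <- matrix(runif(100, 0, 0.2), 10)
    B[1:5, 1:5] <- B[1:5, 1:5] + 0.6
    B[6:10, 6:10] <- B[6:10, 6:10] + 0.6
    B <- (B + t(B)) / 2; diag(B) <- 0
    mine <- spectral_communities(B)
    g <- igraph::graph_from_adjacency_matrix(B, "undirected",
                                             weighted = TRUE)
    ref <- igraph::cluster_leading_eigen(g)
    expect_gt(rand_index(mine$membership,
                         igraph::membership(ref)), 0.99)
    expect_lt(abs(mine$Q - igraph::modularity(g, igraph::membership(ref),
                                              weights = igraph::E(g)$weight)),
              0.02)
  }
})

test_that("communities recover the planted three-stream organization", {
  parc <- test_parc()
  truth <- planted_communities("three")
  truth_vec <- setNames(rep(seq_along(truth), lengths(truth)),
                        unlist(truth))
  ds <- simulate_rest(parc, test_spec(), 1, 2000, seed = 44)
  A <- area_matrix(ds, parc, "across_hemi", n_iter = 3, seed = 1)
  cm <- spectral_communities((A$values + t(A$values)) / 2)
  expect_gt(rand_index(cm$membership[names(truth_vec)], truth_vec), 0.95)
})

test_that("Ward tree matches scipy linkage/inconsistent/fcluster frozen
           values and the ESS oracle", {
  # frozen scipy oracle (7 points, ward linkage, depth 2 and 3)
  dvec <- c(2.3340113739, 1.0694687052, 2.2416925836, 2.1986115709,
            2.502253831, 1.4779027349, 2.2327707324, 3.9439402964,
            3.6568283991, 2.9561369371, 2.2060082241, 1.7386973916,
            1.5238184205, 1.5268152039, 0.8139928519, 1.001199142,
            1.8102038677, 2.1882455184, 1.8617531115, 1.5720486248,
            1.9478571347)
  d <- matrix(0, 7, 7)
  d[lower.tri(d)] <- dvec
  d <- d + t(d)
  w <- ward_hierarchy(d, cutoff_inconsistency = 1, depth = 2)
  expect_equal(w$hclust$height,
               c(0.8139928519, 1.001199142, 1.4134278955, 2.0398958846,
                 2.6428360838, 3.6925309948), tolerance = 1e-9)
  expect_equal(w$inconsistency,
               c(0, 0, 0.7071067812, 0.7071067812, 0.7071067812,
                 1.0770702121), tolerance = 1e-9)
  w3 <- ward_hierarchy(d, cutoff_inconsistency = 1, depth = 3)
  expect_equal(w3$inconsistency,
               c(0, 0, 0.7071067812, 0.7071067812, 1.0934081624,
                 1.4473733926), tolerance = 1e-9)
  ref_cut <- c(2, 2, 2, 1, 1, 1, 2)
  expect_equal(rand_index(w$cut_clusters, ref_cut), 1)

  # merge order equals the exhaustive ESS oracle on random instances
  set.seed(45)
  for (i in 1:50) {
    X <- matrix(rnorm(5 * 3), 5)
    D <- as.matrix(dist(X))
    w5 <- ward_hierarchy(D)
    o <- oracle_ward(X)
    expect_equal(w5$hclust$height, o$height, tolerance = 1e-10)
    # compare merges as unordered pairs (row conventions differ)
    canon <- function(m) t(apply(m, 1, function(r)
      c(sort(r[r < 0], decreasing = TRUE), sort(r[r > 0]))))
    expect_equal(canon(unname(w5$hclust$merge)), canon(unname(o$merge)))
  }
})

test_that("ultrametric input is represented exactly; separated clouds give
           two clusters", {
  # ultrametric: two tight pairs far apart
  d <- matrix(c(0, 1, 8, 8,
                1, 0, 8, 8,
                8, 8, 0, 1,
                8, 8, 1, 0), 4)
  w <- ward_hierarchy(d)
  expect_equal(w$cophenetic_r, 1, tolerance = 1e-12)

  set.seed(46)
  A <- matrix(rnorm(10 * 2, sd = 0.2), 10)
  B <- matrix(rnorm(10 * 2, sd = 0.2), 10) + 10
  D <- as.matrix(dist(rbind(A, B)))
  w2 <- ward_hierarchy(D, cutoff_inconsistency = 1)
  expect_equal(w2$n_clusters, 2L)
  expect_gt(w2$cophenetic_r, 0.95)
  expect_error(ward_hierarchy(matrix(0, 2, 2)), "at least 3")
})

test_that("optimal leaf order minimizes adjacent dissimilarity over all
           flips", {
  set.seed(47)
  for (i in 1:5) {
    X <- matrix(rnorm(7 * 2), 7)
    D <- as.matrix(dist(X))
    w <- ward_hierarchy(D)
    cost <- function(ord) sum(D[cbind(ord[-length(ord)], ord[-1])])
    got <- cost(match(w$leaf_order, rownames(D)))
    # enumerate all orderings consistent with the tree by flipping merges
    hc <- w$hclust
    orders <- list(list())
    leaf_sets <- function(k) {
      if (k < 0) return(list(-k))
      l <- leaf_sets(hc$merge[k, 1]); r <- leaf_sets(hc$merge[k, 2])
      out <- list()
      for (a in l) for (b in r) out <- c(out, list(c(a, b), c(b, a)))
      out
    }
    best <- min(vapply(leaf_sets(length(hc$height)), cost, numeric(1)))
    expect_equal(got, best, tolerance = 1e-10)
  }
})

test_that("relabeling invariance of the structure analysis", {
  parc <- test_parc()
  ds <- simulate_rest(parc, test_spec(), 1, 500, seed = 48)
  A <- area_matrix(ds, parc, "across_hemi", n_iter = 3, seed = 1)
  M <- (A$values + t(A$values)) / 2
  perm <- sample(16)
  Mp <- M[perm, perm]
  c1 <- spectral_communities(M)
  c2 <- spectral_communities(Mp)
  expect_equal(c2$Q, c1$Q, tolerance = 1e-10)
  expect_equal(rand_index(c2$membership, c1$membership[perm]), 1)
  w1 <- ward_hierarchy(to_dissimilarity(M))
  w2 <- ward_hierarchy(to_dissimilarity(Mp))
  expect_equal(w2$cophenetic_r, w1$cophenetic_r, tolerance = 1e-10)
  expect_equal(rand_index(w2$cut_clusters, w1$cut_clusters[perm]), 1)
})
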