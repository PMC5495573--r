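#' Row-profile Euclidean dissimilarity
#'
#' Converts an area-by-area correlation matrix to a dissimilarity matrix:
#' `d(i, j)` is the Euclidean distance between rows i and j.
#'
#' @param M A 16 x 16 `corr_matrix` or plain numeric matrix.
#' @return Symmetric distance matrix with zero diagonal and the area labels
#'   as dimnames.
#' @export
to_dissimilarity <- function(M) {
  V <- if (inherits(M, "corr_matrix")) M$values else as.matrix(M)
  if (anyNA(V)) {
    bad <- which(is.na(V), arr.ind = TRUE)
    abort(paste0("NaN entries at: ",
                 paste(sprintf("(%s,%s)", rownames(V)[bad[, 1]] %||% bad[, 1],
                               colnames(V)[bad[, 2]] %||% bad[, 2]),
                       collapse = ", ")))
  }
  D <- as.matrix(stats::dist(V))
  dimnames(D) <- list(rownames(V), rownames(V))
  D
}

# Kruskal normalized stress-1 of configuration X against dissimilarities d
kruskal_stress <- function(X, d) {
  dhat <- as.matrix(stats::dist(X))
  lt <- lower.tri(d)
  sqrt(sum((dhat[lt] - d[lt])^2) / sum(d[lt]^2))
}

#' Metric multidimensional scaling under Kruskal's normalized stress
#'
#' Embeds the areas in `n_dims` dimensions by direct minimization of
#' normalized stress-1, `sqrt(sum((dhat - d)^2) / sum(d^2))`, with BFGS from
#' a classical-scaling start plus random restarts; the best configuration is
#' kept.
#'
#' @param d Symmetric dissimilarity matrix.
#' @param n_dims Embedding dimension (default 2).
#' @param seed Integer seed for the restarts.
#' @param n_restarts Random restarts beyond the classical start (default
#'   20).
#' @return List of class `mds_embedding`: `points` (n x n_dims, labeled),
#'   `stress`.
#' @export
mds_embed <- function(d, n_dims = 2, seed = 1, n_restarts = 20) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) abort("need at least 3 points")
  if (any(d[lower.tri(d)] <= 0)) {
    abort("degenerate dissimilarities: off-diagonal entries must be positive")
  }
  lt <- lower.tri(d)
  denom <- sum(d[lt]^2)
  obj <- function(par) {
    X <- matrix(par, n)
    dh <- as.matrix(stats::dist(X))
    sum((dh[lt] - d[lt])^2) / denom
  }
  grad <- function(par) {
    X <- matrix(par, n)
    dh <- as.matrix(stats::dist(X))
    dh[dh == 0] <- .Machine$double.eps
    W <- (dh - d) / dh
    diag(W) <- 0
    G <- 2 * (X * rowSums(W) - W %*% X) * 2 / denom
    as.vector(G)
  }
  starts <- list(cmdscale(as.dist(d), k = n_dims))
  set.seed(seed)
  scale0 <- sd(d[lt])
  for (i in seq_len(n_restarts)) {
    starts[[i + 1]] <- matrix(rnorm(n * n_dims, sd = scale0), n)
  }
  best <- NULL
  for (X0 in starts) {
    fit <- optim(as.vector(X0), obj, grad, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  pts <- matrix(best$par, n)
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("dim", seq_len(n_dims))
  structure(list(points = pts, stress = sqrt(best$value)),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("<mds_embedding> %d points in %d dims, stress %.4g\n",
              nrow(x$points), ncol(x$points), x$stress))
  invisible(x)
}

# modularity of a partition on a non-negative weight matrix
modularity_q <- function(W, membership) {
  diag(W) <- 0
  m2 <- sum(W)
  if (m2 == 0) return(0)
  k <- rowSums(W)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    q <- q + sum(W[idx, idx]) / m2 - (sum(k[idx]) / m2)^2
  }
  q
}

#' Leading-eigenvector community detection
#'
#' Newman's spectral modularity maximization by recursive bisection: the
#' leading eigenvector of the (generalized) modularity matrix splits each
#' group by sign; a split is accepted only while it increases modularity.
#' Negative correlation weights are clipped to zero by default; set
#' `signed = TRUE` to decompose the matrix into positive and negative
#' layers and maximize the signed modularity instead.
#'
#' @param M A `corr_matrix` or numeric weight matrix (symmetric).
#' @param signed Use signed modularity rather than clipping negatives.
#' @return List of class `community_result`: `membership` (named integer
#'   vector), `Q` (modularity of the final partition), `n_communities`.
#' @export
spectral_communities <- function(M, signed = FALSE) {
  W <- if (inherits(M, "corr_matrix")) M$values else as.matrix(M)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  Wp <- pmax(W, 0)
  Wn <- pmax(-W, 0)
  use <- if (signed) W else Wp
  n <- nrow(W)
  labels <- rownames(W) %||% as.character(seq_len(n))

  if (sum(Wp) == 0 && (!signed || sum(Wn) == 0)) {
    return(structure(list(membership = setNames(rep(1L, n), labels), Q = 0,
                          n_communities = 1L), class = "community_result"))
  }

  # modularity matrix for one layer
  bmat <- function(A) {
    m2 <- sum(A)
    if (m2 == 0) matrix(0, n, n) else A - outer(rowSums(A), rowSums(A)) / m2
  }
  # signed modularity uses B+ scaled-combined with B- (Gomez et al. form)
  B <- if (!signed) bmat(Wp) else {
    wp <- sum(Wp); wn <- sum(Wn)
    (if (wp > 0) bmat(Wp) else 0) - (if (wn > 0) bmat(Wn) else 0)
  }
  norm_const <- if (!signed) sum(Wp) else sum(Wp) + sum(Wn)

  membership <- rep(1L, n)
  next_id <- 2L
  queue <- list(seq_len(n))
  while (length(queue) > 0) {
    g <- queue[[1]]; queue <- queue[-1]
    if (length(g) < 2) next
    Bg <- B[g, g, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)      # generalized modularity matrix
    e <- eigen(Bg, symmetric = TRUE)
    if (e$values[1] <= 1e-10) next          # indivisible
    s <- ifelse(e$vectors[, 1] >= 0, 1, -1)
    if (all(s == s[1])) next
    dq <- as.numeric(t(s) %*% Bg %*% s) / (2 * norm_const)
    if (dq <= 1e-12) next
    g2 <- g[s < 0]
    membership[g2] <- next_id
    next_id <- next_id + 1L
    queue <- c(queue, list(g[s > 0]), list(g2))
  }
  membership <- as.integer(factor(membership))
  Q <- if (!signed) {
    modularity_q(Wp, membership)
  } else {
    wp <- sum(Wp); wn <- sum(Wn)
    (wp * modularity_q(Wp, membership) - wn * modularity_q(Wn, membership)) /
      (wp + wn)
  }
  structure(list(membership = setNames(membership, labels), Q = Q,
                 n_communities = length(unique(membership))),
            class = "community_result")
}

#' @export
print.community_result <- function(x, ...) {
  cat(sprintf("<community_result> %d communities, Q = %.3f\n",
              x$n_communities, x$Q))
  for (c in sort(unique(x$membership))) {
    cat(sprintf("  [%d] %s\n", c,
                paste(names(x$membership)[x$membership == c],
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
tidy.community_result <- function(x, ...) {
  tibble(area = names(x$membership), community = as.integer(x$membership))
}

#' @export
glance.community_result <- function(x, ...) {
  tibble(Q = x$Q, n_communities = x$n_communities)
}

# --- inconsistency statistic and cut (MATLAB-style) ------------------------

# links within `depth` levels below link k (k itself at level 1)
links_below <- function(merge, k, depth) {
  out <- k
  frontier <- k
  for (lev in seq_len(depth - 1)) {
    nxt <- integer(0)
    for (j in frontier) {
      kids <- merge[j, ]
      nxt <- c(nxt, kids[kids > 0])
    }
    out <- c(out, nxt)
    frontier <- nxt
    if (length(frontier) == 0) break
  }
  out
}

# inconsistency coefficient per link of an hclust tree
inconsistency <- function(hc, depth = 2) {
  h <- hc$height
  vapply(seq_along(h), function(k) {
    set <- links_below(hc$merge, k, depth)
    hs <- h[set]
    if (length(hs) < 2 || sd(hs) == 0) 0 else (h[k] - mean(hs)) / sd(hs)
  }, numeric(1))
}

# cluster cut: a link is consistent when its inconsistency and that of all
# its descendants stay below the cutoff; maximal consistent links form
# clusters, remaining leaves are singletons.
inconsistency_cut <- function(hc, cutoff, depth = 2) {
  n <- length(hc$order) + 0L
  inc <- inconsistency(hc, depth)
  n_links <- length(hc$height)
  consistent_below <- logical(n_links)   # link + all descendants below cutoff
  leaves_of <- vector("list", n_links)
  for (k in seq_len(n_links)) {
    kids <- hc$merge[k, ]
    leaf_sets <- lapply(kids, function(kk)
      if (kk < 0) -kk else leaves_of[[kk]])
    leaves_of[[k]] <- unlist(leaf_sets)
    kid_ok <- all(vapply(kids, function(kk)
      kk < 0 || consistent_below[kk], logical(1)))
    consistent_below[k] <- kid_ok && inc[k] < cutoff
  }
  membership <- rep(NA_integer_, n)
  next_id <- 1L
  # maximal consistent links: consistent but parent is not
  parent <- rep(NA_integer_, n_links)
  for (k in seq_len(n_links)) {
    for (kk in hc$merge[k, ]) if (kk > 0) parent[kk] <- k
  }
  for (k in seq_len(n_links)) {
    if (consistent_below[k] &&
        (is.na(parent[k]) || !consistent_below[parent[k]])) {
      membership[leaves_of[[k]]] <- next_id
      next_id <- next_id + 1L
    }
  }
  for (i in which(is.na(membership))) {
    membership[i] <- next_id
    next_id <- next_id + 1L
  }
  membership
}

# --- optimal leaf ordering --------------------------------------------------

# Bar-Joseph style DP: per node, best cost of each (leftmost, rightmost)
# leaf pair; minimizes the summed dissimilarity between adjacent leaves.
optimal_leaf_order <- function(hc, d) {
  n <- length(hc$order)
  d <- as.matrix(d)
  solve_node <- function(k) {
    if (k < 0) return(fix_leaf(-k))
    L <- solve_node(hc$merge[k, 1])
    R <- solve_node(hc$merge[k, 2])
    combine <- function(A, B) {
      la <- as.integer(rownames(A$cost)); ra <- as.integer(colnames(A$cost))
      lb <- as.integer(rownames(B$cost)); rb <- as.integer(colnames(B$cost))
      cost <- matrix(Inf, length(la) + length(lb), length(ra) + length(rb),
                     dimnames = list(c(la, lb), c(ra, rb)))
      orders <- list()
      # A left of B: leftmost u in A, rightmost w in B; bridge over (v, x)
      for (u in la) for (w in rb) {
        best <- Inf; arg <- NULL
        for (v in ra) for (x in lb) {
          cc <- A$cost[as.character(u), as.character(v)] + d[v, x] +
            B$cost[as.character(x), as.character(w)]
          if (cc < best) { best <- cc; arg <- c(v, x) }
        }
        cost[as.character(u), as.character(w)] <- best
        orders[[paste(u, w, sep = "_")]] <-
          c(A$orders[[paste(u, arg[1], sep = "_")]],
            B$orders[[paste(arg[2], w, sep = "_")]])
      }
      list(cost = cost, orders = orders)
    }
    AB <- combine(L, R)
    BA <- combine(R, L)
    cost <- matrix(Inf, nrow(AB$cost) , ncol(AB$cost),
                   dimnames = dimnames(AB$cost))
    # merge the two arrangements (entries live in disjoint index pairs)
    full_rows <- rownames(AB$cost); full_cols <- colnames(AB$cost)
    cost_ba <- matrix(Inf, length(full_rows), length(full_cols),
                      dimnames = list(full_rows, full_cols))
    cost_ba[rownames(BA$cost), colnames(BA$cost)] <- BA$cost
    cost_ab <- matrix(Inf, length(full_rows), length(full_cols),
                      dimnames = list(full_rows, full_cols))
    cost_ab[rownames(AB$cost), colnames(AB$cost)] <- AB$cost
    cost <- pmin(cost_ab, cost_ba)
    orders <- c(AB$orders, BA$orders)
    list(cost = cost, orders = orders)
  }
  root <- solve_node(length(hc$height))
  idx <- which(root$cost == min(root$cost), arr.ind = TRUE)[1, ]
  key <- paste(rownames(root$cost)[idx[1]], colnames(root$cost)[idx[2]],
               sep = "_")
  root$orders[[key]]
}

# leaf orders in a leaf-node cost matrix carry a single entry keyed "i_i";
# fix the leaf base case to match the combine() conventions
fix_leaf <- function(leaf) {
  list(cost = matrix(0, 1, 1, dimnames = list(leaf, leaf)),
       orders = setNames(list(leaf), paste(leaf, leaf, sep = "_")))
}

#' Ward hierarchy with inconsistency cut and optimal leaf order
#'
#' Agglomerates the dissimilarity matrix with Ward linkage, reports the
#' cophenetic correlation between the input distances and the tree, cuts the
#' tree with the inconsistency statistic (each link's height compared to the
#' mean and SD of link heights within `depth` levels below it; a cluster is a
#' maximal subtree whose links all stay below `cutoff_inconsistency`), and
#' orders the leaves to minimize the summed dissimilarity between adjacent
#' leaves.
#'
#' @param d Symmetric dissimilarity matrix (n >= 3).
#' @param cutoff_inconsistency Cut level (default 1).
#' @param depth Levels entering the inconsistency statistic (default 2).
#' @return List of class `ward_result`: `hclust`, `cophenetic_r`,
#'   `cut_clusters` (named), `n_clusters`, `leaf_order` (labels),
#'   `inconsistency`.
#' @export
ward_hierarchy <- function(d, cutoff_inconsistency = 1, depth = 2) {
  d <- as.matrix(d)
  if (nrow(d) < 3) abort("need at least 3 items")
  labels <- rownames(d) %||% as.character(seq_len(nrow(d)))
  dimnames(d) <- list(labels, labels)
  hc <- hclust(as.dist(d), method = "ward.D2")
  coph <- cor(as.dist(d), cophenetic(hc))
  inc <- inconsistency(hc, depth)
  cut <- inconsistency_cut(hc, cutoff_inconsistency, depth)
  names(cut) <- labels
  ord <- optimal_leaf_order(hc, d)
  structure(list(hclust = hc, cophenetic_r = coph, cut_clusters = cut,
                 n_clusters = length(unique(cut)),
                 leaf_order = labels[ord], inconsistency = inc),
            class = "ward_result")
}

#' @export
print.ward_result <- function(x, ...) {
  cat(sprintf("<ward_result> cophenetic r = %.3f; %d clusters at the cut\n",
              x$cophenetic_r, x$n_clusters))
  cat("  leaf order:", paste(x$leaf_order, collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.ward_result <- function(x, ...) {
  tibble(area = names(x$cut_clusters),
         cluster = as.integer(x$cut_clusters))
}

#' @export
glance.ward_result <- function(x, ...) {
  tibble(cophenetic_r = x$cophenetic_r, n_clusters = x$n_clusters)
}

#' Export a Ward tree as Newick
#'
#' Branch lengths encode the merge heights.
#'
#' @param x A `ward_result`.
#' @param path Output file.
#' @export
write_dendrogram_newick <- function(x, path) {
  phy <- ape::as.phylo(x$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Full structure analysis of an areal correlation matrix
#'
#' Convenience wrapper producing the dissimilarity matrix, MDS embedding,
#' spectral communities, and Ward hierarchy in one object.
#'
#' @param M 16 x 16 `corr_matrix` (typically across-hemisphere, averaged
#'   over directions).
#' @inheritParams mds_embed
#' @inheritParams ward_hierarchy
#' @return List of class `cluster_result` with `embedding`, `communities`,
#'   `ward`, `dissimilarity`.
#' @export
structure_analysis <- function(M, seed = 1, cutoff_inconsistency = 1) {
  V <- if (inherits(M, "corr_matrix")) M$values else as.matrix(M)
  Vs <- (V + t(V)) / 2                  # symmetrize over direction
  Ms <- if (inherits(M, "corr_matrix")) {
    new_corr_matrix(Vs, M$row_ids, M$col_ids, M$df, M$scope, M$thresholds)
  } else Vs
  d <- to_dissimilarity(Ms)
  structure(list(embedding = mds_embed(d, seed = seed),
                 communities = spectral_communities(Ms),
                 ward = ward_hierarchy(d, cutoff_inconsistency),
                 dissimilarity = d),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>\n")
  print(x$embedding); print(x$communities); print(x$ward)
  invisible(x)
}

#' @export
glance.cluster_result <- function(x, ...) {
  tibble(Q = x$communities$Q,
         n_communities = x$communities$n_communities,
         cophenetic_r = x$ward$cophenetic_r,
         n_clusters = x$ward$n_clusters,
         stress = x$embedding$stress)
}

#' @export
tidy.cluster_result <- function(x, ...) {
  dplyr::left_join(tidy(x$communities), tidy(x$ward), by = "area") |>
    dplyr::left_join(
      tibble(area = rownames(x$embedding$points),
             dim1 = x$embedding$points[, 1],
             dim2 = x$embedding$points[, 2]), by = "area")
}
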