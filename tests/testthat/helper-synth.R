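# Shared fixtures and independent oracles for the test suite.

# small parcellation reused across tests (deterministic)
test_parc <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_parcellation(16, 8, seed = 1)
    cache
  }
})

# default coupling spec (the study conditions)
test_spec <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- coupling_spec()
    cache
  }
})

rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

procrustes_dist <- function(A, B) {
  A <- scale(A, scale = FALSE); B <- scale(B, scale = FALSE)
  s <- svd(t(B) %*% A)
  R <- s$u %*% t(s$v)
  sqrt(sum((A - B %*% R)^2) / sum(A^2))
}

# independent double-loop profile correlation
oracle_profile <- function(W, A) {
  S <- matrix(NA_real_, nrow(W), ncol(A))
  for (i in seq_len(nrow(W))) {
    for (v in seq_len(ncol(A))) {
      S[i, v] <- suppressWarnings(cor(W[i, ], A[, v]))
    }
  }
  S
}

# independent Euclidean row distance
oracle_dissimilarity <- function(M) {
  n <- nrow(M)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- sqrt(sum((M[i, ] - M[j, ])^2))
  }
  D
}

# brute-force Ward agglomeration from coordinates: at every step merge the
# pair of clusters whose union minimizes the increase in within-cluster sum
# of squares; height = sqrt(2 * increase) (the ward.D2 height convention).
oracle_ward <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), function(i) i)
  ess <- function(idx) {
    if (length(idx) == 1) return(0)
    sum(sweep(X[idx, , drop = FALSE], 2,
              colMeans(X[idx, , drop = FALSE]))^2)
  }
  merges <- list(); heights <- numeric(0)
  ids <- -seq_len(nrow(X))                 # hclust merge coding
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        dess <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (is.null(best) || dess < best$dess) best <- list(i = i, j = j,
                                                            dess = dess)
      }
    }
    merges[[length(merges) + 1]] <- sort(c(ids[best$i], ids[best$j]))
    heights <- c(heights, sqrt(2 * best$dess))
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    ids[best$i] <- length(merges)
    clusters <- clusters[-best$j]
    ids <- ids[-best$j]
  }
  list(merge = do.call(rbind, merges), height = heights)
}

# brute-force binned tuning slope for one area
oracle_tuning_slope <- function(values, ecc, bin_deg = 1, max_deg = 8,
                                min_voxels = 5) {
  keep <- ecc < max_deg & is.finite(values)
  b <- floor(ecc[keep] / bin_deg) + 1
  n_bins <- max_deg / bin_deg
  centers <- (seq_len(n_bins) - 0.5) * bin_deg
  counts <- tabulate(b, n_bins)
  use <- counts >= min_voxels
  if (sum(!use) >= 2 || sum(use) < 2) return(NULL)
  means <- vapply(which(use), function(k) mean(values[keep][b == k]),
                  numeric(1))
  unname(coef(stats::lm(means ~ centers[use]))[2])
}
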