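test_that("DTW distance satisfies its closed-form special cases", {
  a <- matrix(c(0, 1, 2), ncol = 1)
  expect_equal(dtw_distance(a, a), 0)
  # lengths 1 and 2: single forced alignment path
  v <- c(1, 2); w1 <- c(0, 0); w2 <- c(3, 3)
  expect_equal(dtw_distance(matrix(v, 1), rbind(w1, w2)),
               sqrt(sum((v - w1)^2) + sum((v - w2)^2)))
  expect_error(dtw_distance(matrix(1, 1, 2), matrix(1, 1, 3)),
               "dimensions")
  expect_error(dtw_distance(matrix(numeric(0), 0, 1), a), "empty")
})

test_that("DTW equals exhaustive path enumeration on short sequences", {
  set.seed(101)
  grid <- c(-1, 0, 0.5, 2)
  for (rep in 1:60) {
    d <- sample(1:2, 1)
    la <- sample(1:4, 1); lb <- sample(1:4, 1)
    a <- matrix(sample(grid, la * d, replace = TRUE), la, d)
    b <- matrix(sample(grid, lb * d, replace = TRUE), lb, d)
    expect_equal(dtw_distance(a, b), dtw_bruteforce(a, b),
                 tolerance = 1e-12)
  }
})

test_that("DTW is symmetric, non-negative, and zero only on identical sequences", {
  set.seed(102)
  for (rep in 1:25) {
    a <- matrix(rnorm(sample(1:3, 1) * 2), ncol = 2)
    b <- matrix(rnorm(sample(1:3, 1) * 2), ncol = 2)
    dab <- dtw_distance(a, b)
    expect_gte(dab, 0)
    expect_equal(dab, dtw_distance(b, a), tolerance = 1e-12)
  }
  x <- matrix(rnorm(6), 3, 2)
  expect_equal(dtw_distance(x, x), 0)
})

test_that("DBA centroid solves the tractable cases", {
  tr <- matrix(c(1, 2, 3), ncol = 1)
  out <- dba_centroid(list(tr), L = 3)
  expect_equal(out$centroid, tr, ignore_attr = TRUE)
  two <- list(tr, tr)
  out2 <- dba_centroid(two, L = 3)
  expect_equal(out2$centroid, tr, ignore_attr = TRUE)
  expect_equal(out2$objective, 0)
  # equal-length constant sequences: diagonal alignment, pointwise mean
  out3 <- dba_centroid(list(matrix(0, 3, 1), matrix(2, 3, 1)), L = 3)
  expect_equal(as.numeric(out3$centroid), c(1, 1, 1))
})

test_that("temporal k-means recovers well-separated blobs and is deterministic", {
  set.seed(103)
  mk <- function(center, n) {
    lapply(seq_len(n), function(i) {
      len <- sample(1:3, 1)
      matrix(rep(center, len), len, 2, byrow = TRUE) +
        matrix(rnorm(len * 2, 0, 0.05), len, 2)
    })
  }
  trajs <- c(mk(c(0, 0), 20), mk(c(5, 5), 20))
  names(trajs) <- sprintf("T%02d", 1:40)
  truth <- rep(1:2, each = 20)
  m <- temporal_kmeans(trajs, 2, seed = 1, n_init = 4)
  expect_equal(length(unique(m$labels[1:20])), 1)
  expect_equal(length(unique(m$labels[21:40])), 1)
  expect_false(m$labels[1] == m$labels[21])
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(truth, m$labels), 1)
  # determinism and k = 1
  m2 <- temporal_kmeans(trajs, 2, seed = 1, n_init = 4)
  expect_identical(m$labels, m2$labels)
  expect_identical(m$inertia, m2$inertia)
  m1 <- temporal_kmeans(trajs, 1, seed = 1, n_init = 2)
  expect_true(all(m1$labels == 1))
  expect_error(temporal_kmeans(trajs, 50, seed = 1), "exceeds")
})

test_that("returned restart is at least as good as a single-restart fit", {
  set.seed(104)
  trajs <- lapply(1:30, function(i) matrix(rnorm(4), 2, 2))
  names(trajs) <- paste0("r", 1:30)
  multi <- temporal_kmeans(trajs, 3, seed = 5, n_init = 8)
  single <- temporal_kmeans(trajs, 3, seed = 5, n_init = 1)
  expect_lte(multi$inertia, single$inertia + 1e-12)
})

test_that("Davies-Bouldin matches the direct formula", {
  # two tight clusters: members identical to centroids -> DB = 0
  trajs <- c(lapply(1:3, function(i) matrix(0, 2, 1)),
             lapply(1:3, function(i) matrix(4, 2, 1)))
  names(trajs) <- paste0("p", 1:6)
  m <- temporal_kmeans(trajs, 2, seed = 1, n_init = 2)
  expect_equal(davies_bouldin(trajs, m), 0)
  # hand-built model: S1 = S2 = 1, M12 = 4 -> DB = 0.5
  model <- structure(list(
    k = 2L,
    centroids = list(matrix(0, 1, 1), matrix(4, 1, 1)),
    labels = setNames(c(1L, 1L, 2L, 2L), paste0("q", 1:4))),
    class = "cluster_model")
  trj <- list(matrix(-1, 1, 1), matrix(1, 1, 1),
              matrix(3, 1, 1), matrix(5, 1, 1))
  names(trj) <- paste0("q", 1:4)
  expect_equal(davies_bouldin(trj, model), 0.5)
  expect_error(davies_bouldin(trj, structure(list(k = 1L),
                                            class = "cluster_model")),
               "k >= 2")
})

test_that("Davies-Bouldin agrees with an independent reimplementation on a 3-cluster toy", {
  set.seed(105)
  trajs <- c(lapply(1:5, function(i) matrix(rnorm(2, 0, .2), 1, 2)),
             lapply(1:5, function(i) matrix(rnorm(2, 4, .2), 1, 2)),
             lapply(1:5, function(i) matrix(rnorm(2, -4, .2), 1, 2)))
  names(trajs) <- paste0("s", 1:15)
  m <- temporal_kmeans(trajs, 3, seed = 2, n_init = 3)
  # oracle from raw pairwise distances
  S <- sapply(1:3, function(j) {
    mean(sapply(trajs[m$labels == j],
                function(tr) dtw_distance(tr, m$centroids[[j]])))
  })
  M <- outer(1:3, 1:3, Vectorize(function(i, j)
    dtw_distance(m$centroids[[i]], m$centroids[[j]])))
  oracle <- mean(sapply(1:3, function(i)
    max(sapply(setdiff(1:3, i), function(j) (S[i] + S[j]) / M[i, j]))))
  expect_equal(davies_bouldin(trajs, m), oracle, tolerance = 1e-12)
})

test_that("select_k finds the generative cluster count", {
  set.seed(106)
  mk <- function(center) lapply(1:15, function(i)
    matrix(rnorm(2, center, .15), 1, 2))
  trajs <- c(mk(0), mk(5))
  names(trajs) <- paste0("u", seq_along(trajs))
  sel <- select_k(trajs, 2:5, seed = 3, n_init = 3)
  expect_equal(sel$k, 2L)
  expect_equal(nrow(sel$curve), 4L)
  sel3 <- select_k(trajs, 3, seed = 3, n_init = 2)
  expect_equal(sel3$k, 3L)
  expect_error(select_k(trajs, integer(0)), "empty")
})

test_that("archetype naming follows level and slope, and flips with orientation", {
  # four synthetic clusters with known level/slope structure
  set.seed(107)
  ids <- sprintf("w%02d", 1:40)
  cl <- rep(1:4, each = 10)
  level <- c(-2, 2, -1.8, 1.5)[cl]
  slope <- c(-0.01, 0.01, -0.3, -0.15)[cl]
  comp <- dplyr::bind_rows(lapply(seq_along(ids), function(i) {
    ages <- c(58, 63, 67)
    tibble::tibble(participant_id = ids[i], visit_index = 1:3, age = ages,
                   score = level[i] + slope[i] * (ages - 57) +
                     rnorm(3, 0, 0.01))
  }))
  model <- structure(list(k = 4L, labels = setNames(cl, ids)),
                     class = "cluster_model")
  map <- label_archetypes(model, comp)
  expect_equal(unname(map[c("1", "2", "3", "4")]),
               c("low_stable", "high_upper", "low_declining", "high_lower"))
  flipped <- label_archetypes(model, comp, orientation = -1)
  expect_true(all(grepl("^high", flipped[c("1", "3")])))
  # k != 4 -> rank-based names
  m3 <- structure(list(k = 3L, labels = setNames(rep(1:3, len = 40), ids)),
                  class = "cluster_model")
  expect_true(all(grepl("^cluster_rank", label_archetypes(m3, comp))))
})
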