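#' Multivariate dynamic time warping distance
#'
#' Dependent multivariate DTW: a single monotone, boundary-anchored,
#' continuity-constrained alignment path shared by all feature dimensions,
#' local cost = squared Euclidean distance between aligned feature vectors.
#' The returned value is the square root of the accumulated cost; it is
#' symmetric, non-negative, and zero iff the sequences are identical
#' (triangle inequality is not guaranteed). Ages are not used: alignment is
#' ordinal over visits.
#'
#' @param a,b Numeric matrices, rows = time points, columns = features
#'   (plain vectors are treated as 1-feature sequences).
#' @return Non-negative DTW distance.
#' @export
dtw_distance <- function(a, b) {
  a <- as_trajectory(a)
  b <- as_trajectory(b)
  dtw_dist_cpp(a, b)
}

#' Optimal DTW alignment path
#' @inheritParams dtw_distance
#' @return Two-column integer matrix of aligned (row of `a`, row of `b`)
#'   index pairs.
#' @export
dtw_path <- function(a, b) {
  dtw_path_cpp(as_trajectory(a), as_trajectory(b))
}

as_trajectory <- function(x) {
  if (is.matrix(x)) {
    if (nrow(x) == 0) stop("empty trajectory", call. = FALSE)
    storage.mode(x) <- "double"
    x
  } else {
    if (length(x) == 0) stop("empty trajectory", call. = FALSE)
    matrix(as.numeric(x), ncol = 1)
  }
}

#' Build trajectories from a latent table
#'
#' @param latent Tibble with `participant_id`, `visit_index`, and latent
#'   feature columns (default: all columns named `L..`).
#' @param feature_cols Latent column names.
#' @return A named list of matrices (rows = visits ordered by visit index),
#'   one per participant.
#' @export
build_trajectories <- function(latent,
                               feature_cols = grep("^L", names(latent),
                                                   value = TRUE)) {
  stopifnot(length(feature_cols) >= 1)
  latent <- latent[order(latent$participant_id, latent$visit_index), ]
  split_rows <- split(seq_len(nrow(latent)), latent$participant_id)
  lapply(split_rows, function(idx) {
    as.matrix(latent[idx, feature_cols, drop = FALSE])
  })
}

resample_to_length <- function(traj, L) {
  n <- nrow(traj)
  if (n == L) return(traj)
  if (n == 1) return(traj[rep(1, L), , drop = FALSE])
  pos <- seq(1, n, length.out = L)
  lo <- floor(pos); hi <- ceiling(pos); w <- pos - lo
  traj[lo, , drop = FALSE] * (1 - w) + traj[hi, , drop = FALSE] * w
}

#' DTW barycenter averaging (DBA) centroid
#'
#' Iteratively aligns all member trajectories to the current centroid and
#' replaces each centroid point by the mean of the member points aligned to
#' it; the sum of squared DTW distances is non-increasing across sweeps.
#'
#' @param trajectories List of trajectory matrices (same feature dimension).
#' @param L Centroid length (default 3, the maximum visit count).
#' @param max_iter,tol Convergence controls (relative objective change).
#' @param init Optional initial centroid; default is the member closest to
#'   the medoid, resampled to length `L`.
#' @return A list with `centroid` (L x d matrix), `objective` (final sum of
#'   squared DTW distances), `iterations`.
#' @export
dba_centroid <- function(trajectories, L = 3, max_iter = 30, tol = 1e-8,
                         init = NULL) {
  stopifnot(length(trajectories) >= 1)
  trajectories <- lapply(trajectories, as_trajectory)
  if (is.null(init)) {
    if (length(trajectories) > 2) {
      D <- dtw_cross_dist_cpp(trajectories, trajectories)
      medoid <- which.min(rowSums(D))
      init <- trajectories[[medoid]]
    } else {
      init <- trajectories[[1]]
    }
  }
  centroid <- resample_to_length(as_trajectory(init), L)
  obj_prev <- Inf
  iterations <- 0L
  objective <- NA_real_
  for (it in seq_len(max_iter)) {
    upd <- dba_update_cpp(trajectories, centroid)
    objective <- upd$objective   # evaluated at the incoming centroid
    iterations <- it
    if (is.finite(obj_prev) &&
        abs(obj_prev - objective) <= tol * max(obj_prev, 1e-12)) {
      break
    }
    centroid <- upd$centroid
    obj_prev <- objective
  }
  # final objective at the returned centroid
  final <- sum(dtw_cross_dist_cpp(trajectories, list(centroid))^2)
  list(centroid = centroid, objective = final, iterations = iterations)
}

kmeanspp_init <- function(trajectories, k) {
  n <- length(trajectories)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- dtw_cross_dist_cpp(trajectories,
                           trajectories[centers[1]])[, 1]^2
  if (k > 1) {
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j] <- sample.int(n, 1, prob = p)
      dn <- dtw_cross_dist_cpp(trajectories,
                               trajectories[centers[j]])[, 1]^2
      d2 <- pmin(d2, dn)
    }
  }
  centers
}

#' Temporal k-means over DTW distances
#'
#' Alternates nearest-centroid assignment (ties to the lowest cluster
#' index) with DBA centroid updates until assignments stabilize, restarting
#' `n_init` times from distance-weighted (k-means++-style) seeds and keeping
#' the restart with the lowest inertia. Deterministic given `seed`.
#'
#' @param trajectories Named list of trajectory matrices.
#' @param k Number of clusters (`<=` number of trajectories).
#' @param seed Integer seed.
#' @param n_init Number of restarts.
#' @param max_iter Maximum assignment/update sweeps per restart.
#' @param L Centroid length.
#' @return A `cluster_model`: list with `k`, `centroids`, `labels` (named
#'   integer vector), `inertia` (sum of DTW distances to assigned
#'   centroids), `db_index`, `iterations_run`, `seed`.
#' @export
temporal_kmeans <- function(trajectories, k, seed = 1L, n_init = 10,
                            max_iter = 50, L = 3) {
  n <- length(trajectories)
  if (k > n) stop(sprintf("k = %d exceeds the %d trajectories", k, n),
                  call. = FALSE)
  trajectories <- lapply(trajectories, as_trajectory)
  best <- NULL
  for (ini in seq_len(n_init)) {
    run <- local_seed(child_seed(seed, 40L + ini), {
      centers <- kmeanspp_init(trajectories, k)
      centroids <- lapply(trajectories[centers], resample_to_length, L = L)
      labels <- rep(0L, n)
      iterations <- 0L
      for (it in seq_len(max_iter)) {
        D <- dtw_cross_dist_cpp(trajectories, centroids)
        new_labels <- max.col(-D, ties.method = "first")
        # empty-cluster repair: reassign the farthest point
        for (j in seq_len(k)) {
          if (!any(new_labels == j)) {
            far <- which.max(D[cbind(seq_len(n), new_labels)])
            new_labels[far] <- j
          }
        }
        iterations <- it
        if (identical(new_labels, labels)) break
        labels <- new_labels
        for (j in seq_len(k)) {
          members <- trajectories[labels == j]
          centroids[[j]] <- dba_centroid(members, L = L,
                                         init = centroids[[j]])$centroid
        }
      }
      D <- dtw_cross_dist_cpp(trajectories, centroids)
      inertia <- sum(D[cbind(seq_len(n), labels)])
      list(centroids = centroids, labels = labels, inertia = inertia,
           iterations = iterations)
    })
    if (is.null(best) || run$inertia < best$inertia) best <- run
  }
  labels <- best$labels
  names(labels) <- names(trajectories)
  if (length(unique(labels)) < k) {
    warning("degenerate data: fewer effective clusters than k")
  }
  model <- structure(list(k = as.integer(k), centroids = best$centroids,
                          labels = labels, inertia = best$inertia,
                          iterations_run = best$iterations,
                          seed = as.integer(seed), db_index = NA_real_),
                     class = "cluster_model")
  if (k >= 2) model$db_index <- davies_bouldin(trajectories, model)
  model
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model k=%d, inertia %.4g, DB %.4g, sizes %s>\n",
              x$k, x$inertia, x$db_index,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

#' Davies-Bouldin index of a fitted trajectory clustering
#'
#' `DB = (1/k) * sum_i max_{j != i} (S_i + S_j) / M_ij`, where `S_i` is the
#' mean DTW distance of cluster-i members to centroid i and `M_ij` the DTW
#' distance between centroids i and j. Lower is better.
#'
#' @param trajectories List of trajectory matrices the model was fitted on.
#' @param model A `cluster_model` with `k >= 2`.
#' @return The DB index (non-negative; `Inf` with a warning if two
#'   centroids coincide).
#' @export
davies_bouldin <- function(trajectories, model) {
  k <- model$k
  if (k < 2) stop("Davies-Bouldin requires k >= 2", call. = FALSE)
  trajectories <- lapply(trajectories, as_trajectory)
  D <- dtw_cross_dist_cpp(trajectories, model$centroids)
  S <- vapply(seq_len(k), function(j) {
    mean(D[model$labels == j, j])
  }, numeric(1))
  M <- dtw_cross_dist_cpp(model$centroids, model$centroids)
  ratios <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) {
      ratios[i, j] <- if (M[i, j] > 0) (S[i] + S[j]) / M[i, j] else Inf
    }
  }
  db <- mean(apply(ratios, 1, max, na.rm = TRUE))
  if (!is.finite(db)) warning("coincident centroids: DB index is infinite")
  db
}

#' Select the number of clusters by Davies-Bouldin minimization
#'
#' @param trajectories Named list of trajectory matrices.
#' @param k_range Candidate cluster counts (within `[2, n - 1]`).
#' @param seed Integer seed (shared across k).
#' @param ... Passed to [temporal_kmeans()].
#' @return A list with `k` (argmin-DB, ties to the smaller k), `curve`
#'   (tibble k, db, inertia), `models` (one per k).
#' @export
select_k <- function(trajectories, k_range = 2:8, seed = 1L, ...) {
  if (length(k_range) == 0) stop("empty k_range", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  models <- lapply(k_range, function(k) {
    temporal_kmeans(trajectories, k, seed = seed, ...)
  })
  curve <- tibble::tibble(
    k = k_range,
    db = vapply(models, function(m) m$db_index, numeric(1)),
    inertia = vapply(models, function(m) m$inertia, numeric(1)))
  k_star <- k_range[which.min(curve$db)]
  list(k = k_star, curve = curve, models = setNames(models, k_range))
}

#' Composite cognitive score per participant-visit
#'
#' Direction-corrected mean of the standardized cognitive scores (flagged
#' latency/error tests are sign-flipped), oriented so higher = better.
#'
#' @param table Preprocessed long cognitive table.
#' @param catalog Score catalog with `variable`, `higher_is_worse`.
#' @return Tibble `participant_id`, `visit_index`, `age`, `score`.
#' @export
composite_cognitive <- function(table, catalog = cognitive_score_catalog()) {
  fm <- feature_matrix(table)
  st <- standardize_features(fm$X)
  flip <- catalog$higher_is_worse[match(colnames(st$X), catalog$variable)]
  flip[is.na(flip)] <- FALSE
  Xo <- sweep(st$X, 2, ifelse(flip, -1, 1), `*`)
  dplyr::bind_cols(fm$keys,
                   tibble::tibble(score = rowMeans(Xo, na.rm = TRUE)))
}

#' Name clusters by level/slope archetype
#'
#' Splits the k = 4 clusters into low/high by mean composite level (bottom
#' two = low); within each pair the cluster with the more negative mean
#' within-participant slope is named `declining` (low pair) / `lower` (high
#' pair), the other `stable` / `upper`. For k != 4, rank-based names
#' (`cluster_rank1` lowest level, ...) are emitted.
#'
#' @param model A `cluster_model`.
#' @param composite Output of [composite_cognitive()] (oriented so higher =
#'   better); set `orientation = -1` if inverted.
#' @param orientation +1 (default) if higher composite = better.
#' @return Named character vector: cluster index -> archetype name.
#' @export
label_archetypes <- function(model, composite, orientation = 1) {
  comp <- composite
  comp$score <- comp$score * orientation
  cl <- model$labels[comp$participant_id]
  level <- tapply(comp$score, cl, mean)
  # mean within-participant slope per cluster (participants with >= 2 visits)
  slopes <- vapply(split(comp, comp$participant_id), function(d) {
    if (nrow(d) < 2) return(NA_real_)
    stats::cov(d$age, d$score) / stats::var(d$age)
  }, numeric(1))
  cl_of <- model$labels[names(slopes)]
  slope <- tapply(slopes, cl_of, mean, na.rm = TRUE)
  ord_lvl <- order(level)                     # ascending level
  ids <- as.integer(names(level))[ord_lvl]
  if (model$k != 4) {
    out <- setNames(sprintf("cluster_rank%d", seq_along(ids)),
                    as.character(ids))
    return(out)
  }
  if (length(unique(round(level, 12))) < 4) {
    warning("tied cluster levels; breaking ties by cluster index")
  }
  low <- ids[1:2]; high <- ids[3:4]
  name_pair <- function(pair, neg, pos) {
    s <- slope[as.character(pair)]
    s[is.na(s)] <- 0
    dec <- pair[which.min(s)]
    oth <- setdiff(pair, dec)
    setNames(c(neg, pos), c(dec, oth))
  }
  out <- c(name_pair(low, "low_declining", "low_stable"),
           name_pair(high, "high_lower", "high_upper"))
  out[order(as.integer(names(out)))]
}
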