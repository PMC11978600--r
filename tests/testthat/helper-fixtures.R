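# Small cohort configurations and oracles shared across test files.

small_config <- function(seed = 1L, n_cognitive_scores = 12L, ...) {
  cohort_config(
    n_participants = 60L,
    wave_sizes = c(30L, 40L, 20L),
    wave_overlaps = c(20L, 8L, 2L),
    n_cognitive_scores = n_cognitive_scores,
    cognitive_dropout_rate = 0,
    missing_rate = 0,
    mri_rate = 1, eeg_rate = 1,
    seed = seed, ...)
}

# exhaustive DTW oracle: enumerate every monotone boundary-anchored path
dtw_bruteforce <- function(a, b) {
  a <- if (is.matrix(a)) a else matrix(a, ncol = 1)
  b <- if (is.matrix(b)) b else matrix(b, ncol = 1)
  n <- nrow(a); m <- nrow(b)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + sum((a[i, ] - b[j, ])^2)
    if (acc >= best) return(invisible())
    if (i == n && j == m) {
      best <<- acc
      return(invisible())
    }
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    if (i < n && j < m) walk(i + 1, j + 1, acc)
  }
  walk(1, 1, 0)
  sqrt(best)
}

# long feature table from a wide matrix of complete data (one visit)
long_from_matrix <- function(X, visit = 1L, ages = 60) {
  ids <- sprintf("S%03d", seq_len(nrow(X)))
  vars <- colnames(X) %||% sprintf("v%02d", seq_len(ncol(X)))
  tibble::tibble(
    participant_id = rep(ids, times = ncol(X)),
    visit_index = as.integer(visit),
    age = rep_len(ages, nrow(X) * ncol(X)),
    variable = rep(vars, each = nrow(X)),
    value = as.vector(X))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
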