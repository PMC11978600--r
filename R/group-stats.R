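comparison_result <- function(variable, test, statistic, p_value,
                              group_sizes, effect) {
  tibble::tibble(variable = variable, test = test,
                 statistic = unname(statistic), p_value = unname(p_value),
                 group_sizes = list(group_sizes), effect = list(effect))
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Midrank ties; exact enumeration for small samples (combined n <= 10
#' without ties), otherwise the tie-corrected normal approximation (no
#' continuity correction, so the two-group Kruskal-Wallis test agrees).
#'
#' @param x,y Numeric samples.
#' @param variable Label carried into the result.
#' @return A one-row comparison tibble (statistic = rank-sum W, two-sided
#'   p, group medians as effect summary).
#' @export
wilcoxon_rank_sum <- function(x, y, variable = "x") {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must contain at least one value", call. = FALSE)
  }
  exact <- (length(x) + length(y) <= 10) &&
    !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = FALSE))
  comparison_result(variable, "wilcoxon_rank_sum", ht$statistic,
                    ht$p.value, c(length(x), length(y)),
                    c(median_x = median(x), median_y = median(y)))
}

#' Kruskal-Wallis comparison of multiple groups
#'
#' @param groups List of numeric samples (>= 2 groups).
#' @param variable Label carried into the result.
#' @return A one-row comparison tibble (H statistic with tie correction,
#'   chi-square p on g - 1 df).
#' @export
kruskal_wallis <- function(groups, variable = "x") {
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    stop("need >= 2 non-empty groups", call. = FALSE)
  }
  v <- unlist(groups)
  if (length(unique(v)) == 1) {
    return(comparison_result(variable, "kruskal_wallis", 0, 1,
                             lengths(groups),
                             vapply(groups, median, numeric(1))))
  }
  ht <- kruskal.test(v, factor(rep(seq_along(groups), lengths(groups))))
  comparison_result(variable, "kruskal_wallis", ht$statistic, ht$p.value,
                    lengths(groups), vapply(groups, median, numeric(1)))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by the probability-mass method (hypergeometric enumeration).
#' The effect summary reports both the sample (cross-product) odds ratio
#' and the conditional MLE.
#'
#' @param table_2x2 2x2 matrix of non-negative integer counts.
#' @param variable Label carried into the result.
#' @return A one-row comparison tibble.
#' @export
fisher_exact <- function(table_2x2, variable = "x") {
  m <- as.matrix(table_2x2)
  stopifnot(all(dim(m) == c(2, 2)), all(m >= 0))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(comparison_result(variable, "fisher_exact", NA_real_, 1,
                             rowSums(m),
                             c(sample_or = NA_real_, conditional_or = NA_real_,
                               degenerate_margin = 1)))
  }
  ht <- fisher.test(m)
  sample_or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  comparison_result(variable, "fisher_exact", unname(ht$estimate),
                    ht$p.value, rowSums(m),
                    c(sample_or = sample_or,
                      conditional_or = unname(ht$estimate)))
}

#' Pearson chi-square test on an r x c table
#'
#' No continuity correction; warns when any expected count is below 5.
#'
#' @param table_rc Matrix of non-negative counts, no zero margins.
#' @param variable Label carried into the result.
#' @return A one-row comparison tibble.
#' @export
chi_square <- function(table_rc, variable = "x") {
  m <- as.matrix(table_rc)
  stopifnot(all(m >= 0))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero row/column margin; collapse sparse categories first",
         call. = FALSE)
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    warning("expected counts below 5; chi-square approximation is rough")
  }
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  comparison_result(variable, "chi_square", ht$statistic, ht$p.value,
                    rowSums(m), c(df = unname(ht$parameter)))
}

#' Per-group per-visit trajectory summaries
#'
#' Mean, SD, n, and the 95% confidence half-width of the mean
#' (`1.96 * SD / sqrt(n)`; `NA` for single-observation cells) — the payload
#' behind group-trajectory plots with error bars.
#'
#' @param values Numeric vector.
#' @param group,visit Parallel grouping vectors.
#' @return Tibble with one row per (group, visit), ordered by visit.
#' @export
trajectory_summary <- function(values, group, visit) {
  d <- tibble::tibble(value = values, group = group, visit = visit)
  d <- d[is.finite(d$value), ]
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$group, .data$visit),
    mean = mean(.data$value),
    sd = if (dplyr::n() > 1) sd(.data$value) else 0,
    n = dplyr::n(), .groups = "drop")
  out$ci_half_width <- ifelse(out$n > 1, 1.96 * out$sd / sqrt(out$n),
                              NA_real_)
  out[order(out$group, out$visit), ]
}

#' Compare all variables across cognitive groups
#'
#' Dispatch per variable type: continuous variables get Kruskal-Wallis
#' across the four groups, or Wilcoxon rank-sum after merging into
#' high/low; categorical variables get chi-square across groups, or
#' Fisher's exact (binary) / chi-square (multi-category) after merging.
#' No multiple-testing correction by default; Benjamini-Hochberg optional.
#'
#' @param features Wide tibble, one row per participant: `participant_id`
#'   plus variable columns (numeric = continuous, character/factor =
#'   categorical).
#' @param labels Tibble `participant_id`, `group`.
#' @param merge Merge into high/low before testing (groups named
#'   `high_*`/`low_*`).
#' @param adjust Add a Benjamini-Hochberg adjusted p column.
#' @param alpha Significance threshold for the flag column.
#' @return Tibble of comparison results with `significant` flag.
#' @export
compare_all <- function(features, labels, merge = FALSE, adjust = FALSE,
                        alpha = 0.05) {
  stopifnot("participant_id" %in% names(features))
  g <- labels$group[match(features$participant_id, labels$participant_id)]
  keep <- !is.na(g)
  features <- features[keep, , drop = FALSE]
  g <- g[keep]
  if (merge) {
    g <- ifelse(grepl("^high", g), "high", "low")
  }
  g <- factor(g)
  vars <- setdiff(names(features), c("participant_id", "archetype"))
  rows <- lapply(vars, function(v) {
    x <- features[[v]]
    if (is.numeric(x)) {
      if (merge) {
        wilcoxon_rank_sum(x[g == levels(g)[1]], x[g == levels(g)[2]],
                          variable = v)
      } else {
        kruskal_wallis(split(x, g), variable = v)
      }
    } else {
      tab <- table(g, x)
      if (merge && ncol(tab) == 2) {
        fisher_exact(tab, variable = v)
      } else {
        tryCatch(chi_square(tab, variable = v),
                 error = function(e) comparison_result(
                   v, "chi_square", NA_real_, NA_real_, rowSums(tab),
                   c(error = 1)))
      }
    }
  })
  out <- dplyr::bind_rows(rows)
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out
}
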