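#' Merge four archetype clusters into a high/low binary labeling
#'
#' @param labels Named cluster labels (participant -> cluster index) or a
#'   tibble `participant_id`, `cluster`.
#' @param archetype_map Named map cluster index -> archetype name, e.g.
#'   from [label_archetypes()].
#' @return A tibble `participant_id`, `class` (`"high"`/`"low"`), plus the
#'   merge provenance as an attribute.
#' @export
merge_high_low <- function(labels, archetype_map) {
  if (is.data.frame(labels)) {
    ids <- labels$participant_id
    cl <- labels$cluster
  } else {
    ids <- names(labels)
    cl <- unname(labels)
  }
  arch <- archetype_map[as.character(cl)]
  known <- c("high_upper", "high_lower", "low_stable", "low_declining")
  if (any(!arch %in% known)) {
    stop("unknown archetype name(s): ",
         paste(unique(arch[!arch %in% known]), collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    participant_id = ids,
    class = ifelse(grepl("^high", arch), "high", "low"))
  attr(out, "merge_map") <- list(high = c("high_upper", "high_lower"),
                                 low = c("low_stable", "low_declining"))
  out
}

#' First-visit feature matrix for one modality
#'
#' Per participant, selects the earliest visit carrying any data for the
#' modality; features missing at that visit are mean-imputed (count
#' reported); participants with no data at all are excluded.
#'
#' @param table Long feature table for the modality.
#' @return A numeric matrix (rows = participants, named), with attributes
#'   `n_imputed` and `visit_used`.
#' @export
first_visit_features <- function(table) {
  obs <- table[is.finite(table$value), , drop = FALSE]
  if (nrow(obs) == 0) stop("no participants with data for this modality",
                           call. = FALSE)
  first <- dplyr::summarise(
    dplyr::group_by(obs, .data$participant_id),
    visit_index = min(.data$visit_index), .groups = "drop")
  sel <- dplyr::inner_join(obs, first,
                           by = c("participant_id", "visit_index"))
  wide <- tidyr::pivot_wider(sel, id_cols = "participant_id",
                             names_from = "variable",
                             values_from = "value")
  X <- as.matrix(wide[, -1, drop = FALSE])
  rownames(X) <- wide$participant_id
  n_imp <- sum(!is.finite(X))
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- mean(X[!bad, j])
  }
  attr(X, "n_imputed") <- n_imp
  attr(X, "visit_used") <- setNames(first$visit_index,
                                    first$participant_id)
  X
}

#' Ridge-penalized logistic regression
#'
#' Penalized maximum likelihood via glmnet (ridge, fixed small lambda) on
#' standardized features, so perfectly separable data still yield finite
#' coefficients. Zero-variance features are dropped by a guard and reported
#' with zero coefficients.
#'
#' @param X Numeric feature matrix.
#' @param y Binary outcome (two levels; factor, character, or 0/1).
#' @param standardize Center/scale features before fitting.
#' @param l2 Ridge penalty (glmnet lambda).
#' @return A `logistic_model` list with `coefficients`, `intercept`,
#'   `predict` data (`center`, `scale`), `levels`.
#' @export
fit_logistic <- function(X, y, standardize = TRUE, l2 = 1e-4) {
  X <- as.matrix(X)
  yf <- factor(y)
  if (nlevels(yf) != 2) stop("y must have exactly two classes",
                             call. = FALSE)
  if (nrow(X) <= 2) stop("need n > 2", call. = FALSE)
  sds <- apply(X, 2, sd)
  keep <- is.finite(sds) & sds > 0
  Xk <- X[, keep, drop = FALSE]
  center <- colMeans(Xk)
  scale <- apply(Xk, 2, sd)
  if (!standardize) {
    center <- center * 0
    scale <- scale * 0 + 1
  }
  Xs <- sweep(sweep(Xk, 2, center), 2, scale, `/`)
  if (ncol(Xs) == 1) {
    # glmnet requires >= 2 columns; duplicate-with-zero trick
    Xs2 <- cbind(Xs, 0)
    fit <- glmnet::glmnet(Xs2, yf, family = "binomial", alpha = 0,
                          lambda = l2, standardize = FALSE, thresh = 1e-12)
    beta <- as.numeric(coef(fit))[2]
  } else {
    fit <- glmnet::glmnet(Xs, yf, family = "binomial", alpha = 0,
                          lambda = l2, standardize = FALSE, thresh = 1e-12)
    beta <- as.numeric(coef(fit))[-1]
  }
  intercept <- as.numeric(coef(fit))[1]
  coefs <- setNames(numeric(ncol(X)), colnames(X))
  coefs[keep] <- beta
  structure(list(coefficients = coefs, intercept = intercept,
                 center = center, scale = scale, kept = keep,
                 levels = levels(yf)),
            class = "logistic_model")
}

#' Predicted class-2 probabilities from a [fit_logistic()] model
#' @param model A `logistic_model`.
#' @param X Feature matrix with the training columns.
#' @return Probability of the second factor level.
#' @export
predict_logistic <- function(model, X) {
  X <- as.matrix(X)[, names(model$coefficients), drop = FALSE]
  Xk <- X[, model$kept, drop = FALSE]
  Xs <- sweep(sweep(Xk, 2, model$center), 2, model$scale, `/`)
  eta <- model$intercept +
    as.numeric(Xs %*% model$coefficients[model$kept])
  1 / (1 + exp(-eta))
}

#' ROC curve and AUC
#'
#' AUC from the rank statistic (Mann-Whitney, ties get half credit), which
#' equals the trapezoidal area under the stored ROC curve.
#'
#' @param scores Numeric scores (higher = more positive-class).
#' @param y Binary labels; `positive` names the positive class.
#' @param positive Positive-class label (default: the second factor level).
#' @param modality Label carried into the result.
#' @return A `roc_result` list: `modality`, `thresholds`, `tpr`, `fpr`,
#'   `auc`, `n_used`.
#' @export
roc_auc <- function(scores, y, positive = NULL, modality = "scores") {
  yf <- factor(y)
  if (nlevels(yf) != 2) stop("need exactly two classes", call. = FALSE)
  positive <- positive %||% levels(yf)[2]
  pos <- yf == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # ROC curve over unique-score thresholds, descending
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  pos_sorted <- pos[ord]
  grp_end <- which(!duplicated(s_sorted, fromLast = TRUE))
  tp <- cumsum(pos_sorted)[grp_end]
  fp <- cumsum(!pos_sorted)[grp_end]
  tpr <- c(0, tp / n1)
  fpr <- c(0, fp / n0)
  structure(list(modality = modality,
                 thresholds = c(Inf, s_sorted[grp_end]),
                 tpr = tpr, fpr = fpr, auc = auc,
                 n_used = n0 + n1),
            class = "roc_result")
}

#' Trapezoidal area under a stored ROC curve
#' @param roc A `roc_result`.
#' @return The trapezoidal area (equals `roc$auc` up to float error).
#' @export
roc_trapezoid_area <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

#' Per-modality multivariate classification of high vs low performers
#'
#' One ridge-logistic model per modality on first-visit features, scored by
#' in-sample ROC/AUC (the default; a k-fold cross-validated variant is
#' available since in-sample AUC is optimistic).
#'
#' @param tables Named list of long feature tables (one per modality).
#' @param labeling Tibble `participant_id`, `class` from
#'   [merge_high_low()].
#' @param cv_folds `NULL` for in-sample AUC, or a fold count.
#' @param seed Fold-assignment seed.
#' @return Named list of `roc_result`s, ranked by decreasing AUC.
#' @export
modality_auc_comparison <- function(tables, labeling, cv_folds = NULL,
                                    seed = 1L) {
  res <- lapply(names(tables), function(mod) {
    X <- first_visit_features(tables[[mod]])
    y <- labeling$class[match(rownames(X), labeling$participant_id)]
    ok <- !is.na(y)
    X <- X[ok, , drop = FALSE]; y <- factor(y[ok], c("low", "high"))
    if (is.null(cv_folds)) {
      fit <- fit_logistic(X, y)
      p <- predict_logistic(fit, X)
    } else {
      fold <- local_seed(child_seed(seed, 50L),
                         sample(rep_len(seq_len(cv_folds), nrow(X))))
      p <- numeric(nrow(X))
      for (f in seq_len(cv_folds)) {
        fit <- fit_logistic(X[fold != f, , drop = FALSE], y[fold != f])
        p[fold == f] <- predict_logistic(fit, X[fold == f, , drop = FALSE])
      }
    }
    roc_auc(p, y, positive = "high", modality = mod)
  })
  names(res) <- names(tables)
  res[order(-vapply(res, function(r) r$auc, numeric(1)))]
}

#' Univariate AUC scan over cognitive scores
#'
#' Per score: a single-feature logistic model and its AUC for detecting the
#' low-performing class, direction-corrected so AUC >= 0.5.
#'
#' @param cognitive Long cognitive feature table.
#' @param labeling Tibble `participant_id`, `class`.
#' @return Tibble `variable`, `auc`, `n`, ranked descending by AUC.
#' @export
univariate_auc_scan <- function(cognitive, labeling) {
  X <- first_visit_features(cognitive)
  y <- labeling$class[match(rownames(X), labeling$participant_id)]
  ok <- !is.na(y)
  X <- X[ok, , drop = FALSE]
  yf <- factor(y[ok], c("low", "high"))
  rows <- lapply(colnames(X), function(v) {
    x <- X[, v]
    if (sd(x) == 0) {
      return(tibble::tibble(variable = v, auc = 0.5, n = length(x)))
    }
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, x), as.integer(yf) - 1L,
                     family = stats::binomial()))
    p <- fit$fitted.values
    a <- roc_auc(p, yf, positive = "high")$auc
    tibble::tibble(variable = v, auc = max(a, 1 - a), n = length(x))
  })
  out <- dplyr::bind_rows(rows)
  out[order(-out$auc), ]
}
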