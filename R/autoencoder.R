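#' Pivot a long cognitive table to a participant-visit matrix with a mask
#'
#' @param table Long feature table.
#' @return A list with `X` (rows = participant-visits, columns = variables,
#'   `NA` where unobserved), `mask` (1 observed / 0 missing), and `keys`
#'   (tibble `participant_id`, `visit_index`, `age`).
#' @export
feature_matrix <- function(table) {
  validate_feature_table(table, require_rows = TRUE)
  wide <- tidyr::pivot_wider(table,
                             id_cols = c("participant_id", "visit_index",
                                         "age"),
                             names_from = "variable",
                             values_from = "value")
  keys <- wide[, c("participant_id", "visit_index", "age")]
  X <- as.matrix(wide[, setdiff(names(wide), names(keys)), drop = FALSE])
  list(X = X, mask = 1 * is.finite(X), keys = keys)
}

#' Standardize a feature matrix
#'
#' Per-variable z-scoring over all participant-visits; missing entries stay
#' missing and are excluded from the mean/SD.
#'
#' @param X Numeric matrix (may contain `NA`).
#' @return A list with `X` (standardized, `NA` preserved), `center`,
#'   `scale`.
#' @export
standardize_features <- function(X) {
  center <- colMeans(X, na.rm = TRUE)
  scale <- apply(X, 2, sd, na.rm = TRUE)
  if (any(!is.finite(scale) | scale == 0)) {
    stop("zero-SD variable(s): ",
         paste(colnames(X)[!is.finite(scale) | scale == 0],
               collapse = ", "),
         " (should have been removed by the constancy filter)",
         call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2, center), 2, scale, `/`)
  list(X = Xs, center = center, scale = scale)
}

#' Invert [standardize_features()]
#' @param Xs Standardized matrix.
#' @param params A list with `center` and `scale`.
#' @return The matrix on the original scale.
#' @export
unstandardize_features <- function(Xs, params) {
  sweep(sweep(Xs, 2, params$scale, `*`), 2, params$center, `+`)
}

#' Autoencoder specification
#'
#' Two fully connected layers per side: encoder
#' `input -> round(hidden_fraction * input) -> latent`, decoder mirrored,
#' nonlinearity on the hidden layers, linear latent and output.
#'
#' @param input_dim Number of input variables.
#' @param latent_fraction Latent size as a fraction of the input (default
#'   0.65, i.e. 50 latent features for 77 inputs).
#' @param hidden_fraction Hidden width as a fraction of the input.
#' @param activation `"tanh"` or `"linear"`.
#' @param epochs,learning_rate Full-batch Adam schedule.
#' @param seed Weight-initialization seed.
#' @return An `autoencoder_spec` list; `latent_dim = round(latent_fraction *
#'   input_dim)`, floored at 1.
#' @export
autoencoder_spec <- function(input_dim, latent_fraction = 0.65,
                             hidden_fraction = 0.8,
                             activation = c("tanh", "linear"),
                             epochs = 300L, learning_rate = 0.01,
                             seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(input_dim >= 1, latent_fraction > 0, latent_fraction <= 1)
  latent_dim <- max(1L, as.integer(round(latent_fraction * input_dim)))
  hidden_dim <- max(latent_dim, as.integer(round(hidden_fraction *
                                                 input_dim)))
  structure(list(input_dim = as.integer(input_dim),
                 latent_fraction = latent_fraction,
                 latent_dim = latent_dim, hidden_dim = hidden_dim,
                 activation = activation, epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "autoencoder_spec")
}

act_fun <- function(a) if (a == "tanh") tanh else identity
act_grad <- function(a) {
  if (a == "tanh") function(h) 1 - h^2 else function(h) 1
}

ae_forward <- function(par, X, activation) {
  f <- act_fun(activation)
  H1 <- f(X %*% par$W1 + rep(1, nrow(X)) %*% t(par$b1))
  Z <- H1 %*% par$W2 + rep(1, nrow(X)) %*% t(par$b2)
  H2 <- f(Z %*% par$W3 + rep(1, nrow(X)) %*% t(par$b3))
  Xhat <- H2 %*% par$W4 + rep(1, nrow(X)) %*% t(par$b4)
  list(H1 = H1, Z = Z, H2 = H2, Xhat = Xhat)
}

#' Train a masked two-layer autoencoder
#'
#' Minimizes mean squared reconstruction error over the observed entries
#' only (missing entries contribute neither loss nor gradient; they enter
#' the forward pass as zeros, i.e. the variable mean on the standardized
#' scale). Optimization is full-batch Adam; training is deterministic given
#' the spec seed.
#'
#' @param X Standardized matrix, `NA` for missing entries.
#' @param spec An [autoencoder_spec()].
#' @return An `autoencoder` model (weights, spec, loss trace).
#' @export
train_autoencoder <- function(X, spec) {
  stopifnot(inherits(spec, "autoencoder_spec"),
            ncol(X) == spec$input_dim)
  M <- 1 * is.finite(X)
  X0 <- ifelse(is.finite(X), X, 0)
  p <- spec$input_dim; h <- spec$hidden_dim; q <- spec$latent_dim
  glorot <- function(nin, nout) {
    matrix(runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
  }
  par <- local_seed(spec$seed, list(
    W1 = glorot(p, h), b1 = numeric(h),
    W2 = glorot(h, q), b2 = numeric(q),
    W3 = glorot(q, h), b3 = numeric(h),
    W4 = glorot(h, p), b4 = numeric(p)))
  m <- lapply(par, function(w) w * 0)
  v <- lapply(par, function(w) w * 0)
  b1c <- 0.9; b2c <- 0.999; eps <- 1e-8
  g <- act_grad(spec$activation)
  n_obs <- sum(M)
  losses <- numeric(spec$epochs)
  ones <- rep(1, nrow(X0))
  for (epoch in seq_len(spec$epochs)) {
    fw <- ae_forward(par, X0, spec$activation)
    R <- (fw$Xhat - X0) * M
    loss <- sum(R^2) / n_obs
    if (!is.finite(loss)) {
      stop(sprintf("non-finite loss at epoch %d (lr too high?)", epoch),
           call. = FALSE)
    }
    losses[epoch] <- loss
    dXhat <- 2 * R / n_obs
    grads <- list()
    grads$W4 <- t(fw$H2) %*% dXhat
    grads$b4 <- colSums(dXhat)
    dH2 <- (dXhat %*% t(par$W4)) * g(fw$H2)
    grads$W3 <- t(fw$Z) %*% dH2
    grads$b3 <- colSums(dH2)
    dZ <- dH2 %*% t(par$W3)
    grads$W2 <- t(fw$H1) %*% dZ
    grads$b2 <- colSums(dZ)
    dH1 <- (dZ %*% t(par$W2)) * g(fw$H1)
    grads$W1 <- t(X0) %*% dH1
    grads$b1 <- colSums(dH1)
    for (nm in names(par)) {
      m[[nm]] <- b1c * m[[nm]] + (1 - b1c) * grads[[nm]]
      v[[nm]] <- b2c * v[[nm]] + (1 - b2c) * grads[[nm]]^2
      mhat <- m[[nm]] / (1 - b1c^epoch)
      vhat <- v[[nm]] / (1 - b2c^epoch)
      par[[nm]] <- par[[nm]] - spec$learning_rate * mhat /
        (sqrt(vhat) + eps)
    }
  }
  structure(list(par = par, spec = spec, losses = losses,
                 final_loss = tail(losses, 1)),
            class = "autoencoder")
}

#' @export
print.autoencoder <- function(x, ...) {
  cat(sprintf("<autoencoder %d -> %d -> %d (%s), final masked MSE %.4g>\n",
              x$spec$input_dim, x$spec$hidden_dim, x$spec$latent_dim,
              x$spec$activation, x$final_loss))
  invisible(x)
}

#' Encode rows into the latent space
#'
#' Missing inputs are imputed to 0 on the standardized scale (the variable
#' mean) before encoding; the number of imputed entries is reported as an
#' attribute.
#'
#' @param model A trained `autoencoder`.
#' @param X Standardized matrix (may contain `NA`).
#' @return Latent matrix, rows aligned with `X`; attribute `n_imputed`.
#' @export
encode <- function(model, X) {
  stopifnot(inherits(model, "autoencoder"))
  if (ncol(X) != model$spec$input_dim) {
    stop(sprintf("input has %d columns, model expects %d", ncol(X),
                 model$spec$input_dim), call. = FALSE)
  }
  n_imp <- sum(!is.finite(X))
  X0 <- ifelse(is.finite(X), X, 0)
  fw <- ae_forward(model$par, X0, model$spec$activation)
  structure(fw$Z, n_imputed = n_imp)
}

#' Reconstruct rows through the autoencoder
#' @inheritParams encode
#' @return Reconstructed matrix on the standardized scale.
#' @export
reconstruct <- function(model, X) {
  X0 <- ifelse(is.finite(X), X, 0)
  ae_forward(model$par, X0, model$spec$activation)$Xhat
}

masked_mse <- function(model, X) {
  M <- is.finite(X)
  R <- (reconstruct(model, X) - ifelse(M, X, 0))[M]
  mean(R^2)
}

#' Choose the latent fraction by k-fold cross-validation
#'
#' For each candidate fraction, trains on `folds - 1` folds of
#' participant-visit rows and evaluates masked reconstruction MSE on the
#' held-out rows. The chosen fraction is the smallest whose mean CV error is
#' within one standard error of the minimum.
#'
#' @param X Standardized matrix.
#' @param candidate_fractions Latent fractions to scan.
#' @param folds Number of folds (default 10).
#' @param seed Fold-assignment and training seed.
#' @param ... Passed to [autoencoder_spec()] (e.g. `epochs`).
#' @return A list with `chosen_fraction`, `curve` (tibble fraction,
#'   mean_mse, se), and `fold_assignment`.
#' @export
cross_validate_latent_size <- function(X, candidate_fractions =
                                         c(0.2, 0.4, 0.65, 0.8, 1.0),
                                       folds = 10, seed = 1L, ...) {
  n <- nrow(X)
  if (folds > n) stop("more folds than rows", call. = FALSE)
  if (length(candidate_fractions) == 0) stop("empty candidate set",
                                             call. = FALSE)
  fold_of <- local_seed(child_seed(seed, 21L),
                        sample(rep_len(seq_len(folds), n)))
  res <- lapply(candidate_fractions, function(fr) {
    errs <- vapply(seq_len(folds), function(f) {
      tr <- X[fold_of != f, , drop = FALSE]
      te <- X[fold_of == f, , drop = FALSE]
      spec <- autoencoder_spec(ncol(X), latent_fraction = fr,
                               seed = child_seed(seed, 30L + f), ...)
      masked_mse(train_autoencoder(tr, spec), te)
    }, numeric(1))
    c(mean = mean(errs), se = sd(errs) / sqrt(folds))
  })
  curve <- tibble::tibble(
    fraction = candidate_fractions,
    mean_mse = vapply(res, `[[`, numeric(1), "mean"),
    se = vapply(res, `[[`, numeric(1), "se"))
  best <- which.min(curve$mean_mse)
  thresh <- curve$mean_mse[best] + curve$se[best]
  ok <- which(curve$mean_mse <= thresh)
  chosen <- min(curve$fraction[ok])
  list(chosen_fraction = chosen, curve = curve, fold_assignment = fold_of)
}

#' Summarize a cognitive table into latent features
#'
#' Convenience wrapper: pivot, standardize, train, encode; returns a latent
#' table ready for trajectory clustering.
#'
#' @param table Preprocessed long cognitive table.
#' @param latent_fraction Latent size fraction (default 0.65).
#' @param epochs,seed Training controls.
#' @return A list with `latent` (tibble: keys + `L1..Lq` columns), `model`,
#'   `standardization`.
#' @export
summarize_cognitive <- function(table, latent_fraction = 0.65,
                                epochs = 300L, seed = 1L) {
  fm <- feature_matrix(table)
  st <- standardize_features(fm$X)
  spec <- autoencoder_spec(ncol(st$X), latent_fraction = latent_fraction,
                           epochs = epochs, seed = seed)
  model <- train_autoencoder(st$X, spec)
  Z <- encode(model, st$X)
  colnames(Z) <- sprintf("L%02d", seq_len(ncol(Z)))
  latent <- dplyr::bind_cols(fm$keys, tibble::as_tibble(Z))
  list(latent = latent, model = model,
       standardization = st[c("center", "scale")])
}
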