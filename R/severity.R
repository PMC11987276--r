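#' Neighborhood component analysis weights for regression
#'
#' Learns non-negative per-feature relevance weights by minimising the
#' leave-one-out soft-neighbour regression objective
#' \deqn{f(w) = \sum_i \sum_{j \ne i} p_{ij} |y_i - y_j| + \lambda \sum_r w_r^2}
#' with \eqn{p_{ij} = \exp(-d_w(x_i, x_j)) / \sum_{k \ne i} \exp(-d_w(x_i, x_k))}
#' and the weighted L1 metric \eqn{d_w(x_i, x_j) = \sum_r w_r^2 |x_{ir} - x_{jr}|}.
#' Gradient descent from `w = 1` with a step-halving line search; features are
#' standardised internally. Irrelevant features shrink towards 0 under the
#' ridge pull while informative ones keep large weights.
#'
#' @param X n x p feature matrix (n >= 10).
#' @param y length-n continuous target.
#' @param lambda_reg ridge penalty (default `1/n`).
#' @param iters maximum gradient iterations.
#' @param seed integer seed (recorded; the optimiser itself is deterministic).
#' @param tol stop when the objective improves by less than `tol`.
#' @return `nca_weights`: list with `w` (named), `lambda_reg`,
#'   `objective_trace` (non-increasing over accepted steps), `seed`.
#' @export
nca_regression_weights <- function(X, y, lambda_reg = NULL, iters = 500,
                                   seed = 1, tol = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 10) pq_stop("need at least 10 samples")
  stopifnot(length(y) == n)
  if (is.null(lambda_reg)) lambda_reg <- 1 / n
  mu <- colMeans(X); sg <- apply(X, 2, sd)
  if (any(sg == 0)) pq_stop("constant feature column(s): ",
                            paste(colnames(X)[sg == 0], collapse = ", "))
  Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
  A <- array(0, c(n, n, p)) # |z_ir - z_jr|
  for (r in seq_len(p)) A[, , r] <- abs(outer(Z[, r], Z[, r], "-"))
  Lmat <- abs(outer(y, y, "-"))
  objective_and_grad <- function(w) {
    D <- matrix(0, n, n)
    for (r in seq_len(p)) D <- D + w[r]^2 * A[, , r]
    # row-wise softmax over j != i
    E <- exp(-(D - apply(D + diag(Inf, n), 1, min)))
    diag(E) <- 0
    P <- E / rowSums(E)
    Li <- rowSums(P * Lmat)
    f <- sum(Li) + lambda_reg * sum(w^2)
    g <- vapply(seq_len(p), function(r)
      2 * w[r] * sum(P * A[, , r] * (Li - Lmat)), numeric(1))
    list(f = f, g = g + 2 * lambda_reg * w)
  }
  w <- rep(1, p)
  og <- objective_and_grad(w)
  trace <- og$f
  step <- 0.1
  for (it in seq_len(iters)) {
    ok <- FALSE
    for (h in 0:30) {
      w_new <- w - step * og$g
      w_new <- abs(w_new) # weights enter as squares; keep the canonical branch
      og_new <- tryCatch(objective_and_grad(w_new), error = function(e) NULL)
      if (!is.null(og_new) && is.finite(og_new$f) && og_new$f <= og$f) {
        ok <- TRUE
        break
      }
      step <- step / 2
    }
    if (!ok) break
    improved <- og$f - og_new$f
    w <- w_new; og <- og_new
    trace <- c(trace, og$f)
    step <- step * 1.5
    if (improved < tol) break
  }
  names(w) <- colnames(X)
  structure(list(w = w, lambda_reg = lambda_reg, objective_trace = trace,
                 seed = seed),
            class = "nca_weights")
}

#' Select the k highest-weight features
#'
#' @param weights an `nca_weights` object (or bare numeric vector).
#' @param k number of features to keep.
#' @return Integer indices of the k largest weights, ties broken by feature
#'   order.
#' @export
select_features <- function(weights, k) {
  w <- if (inherits(weights, "nca_weights")) weights$w else weights
  stopifnot(k <= length(w), k >= 1)
  sort(order(-w, seq_along(w))[seq_len(k)])
}

#' Fit the linear severity model
#'
#' Ordinary least squares of the continuous severity target on standardised
#' selected features; the standardisation is stored for prediction.
#'
#' @param X n x k matrix of the selected features.
#' @param y continuous severity target (typically the panel average score).
#' @param feature_names optional names (default from `colnames`).
#' @return `severity_model`: intercept, coefficients (on standardised scale),
#'   selected feature names, per-feature `(mean, sd)`, `training_n`.
#' @export
fit_linear <- function(X, y, feature_names = colnames(X)) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (is.null(feature_names)) feature_names <- paste0("x", seq_len(k))
  if (n <= k + 1) pq_stop("need n > k + 1 samples")
  mu <- colMeans(X); sg <- apply(X, 2, sd)
  if (any(sg == 0))
    pq_stop("zero-variance feature(s): ",
            paste(feature_names[sg == 0], collapse = ", "))
  Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
  qz <- qr(cbind(1, Z))
  if (qz$rank < k + 1) {
    bad <- feature_names[qz$pivot[seq(qz$rank + 1, k + 1)] - 1]
    pq_stop("rank-deficient design; collinear feature(s): ",
            paste(bad, collapse = ", "))
  }
  df <- data.frame(y = y, Z)
  names(df) <- c("y", feature_names)
  fit <- lm(stats::reformulate(feature_names, "y"), data = df)
  structure(list(intercept = unname(coef(fit)[1]),
                 coefficients = coef(fit)[-1],
                 selected_features = feature_names,
                 feature_mean = stats::setNames(mu, feature_names),
                 feature_sd = stats::setNames(sg, feature_names),
                 training_n = n),
            class = "severity_model")
}

#' Predict the continuous Plus severity index
#'
#' Affine prediction from the stored standardisation and coefficients. Both
#' the raw value and a copy clamped to the 1-5 severity scale are returned.
#'
#' @param model a `severity_model`.
#' @param x named numeric vector (or single-row data frame / matrix)
#'   containing the model's features.
#' @return List with `raw` and `clamped` (in `[1, 5]`).
#' @export
predict_severity <- function(model, x) {
  if (is.data.frame(x) || is.matrix(x)) x <- unlist(x[1, , drop = TRUE])
  miss <- setdiff(model$selected_features, names(x))
  if (length(miss)) pq_stop("missing feature(s): ", paste(miss, collapse = ", "))
  z <- (as.numeric(x[model$selected_features]) - model$feature_mean) /
       model$feature_sd
  raw <- model$intercept + sum(model$coefficients * z)
  list(raw = raw, clamped = min(5, max(1, raw)))
}

#' k-fold cross-validated MSE/MAE of the severity model
#'
#' Seeded shuffled fold assignment (balanced within one sample), per-fold OLS
#' fit on the remaining folds, MSE and MAE on the held-out fold against the
#' continuous target; reported as mean and sd over folds.
#'
#' @param X n x k feature matrix.
#' @param y continuous target.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return `cv_report`: `mse_mean`, `mse_sd`, `mae_mean`, `mae_sd`,
#'   `fold_assignments`, `seed`.
#' @export
kfold_cv <- function(X, y, k = 5, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(k >= 2, n >= k)
  set.seed(derive_seed(seed, "cv-folds"))
  folds <- sample(rep_len(seq_len(k), n))
  if (min(table(folds)) < 2) pq_stop("a fold has fewer than 2 samples")
  mse <- numeric(k); mae <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    m <- fit_linear(X[tr, , drop = FALSE], y[tr],
                    feature_names = colnames(X))
    Zte <- sweep(sweep(X[!tr, , drop = FALSE], 2, m$feature_mean), 2,
                 m$feature_sd, "/")
    pred <- m$intercept + as.numeric(Zte %*% m$coefficients)
    mse[f] <- mean((pred - y[!tr])^2)
    mae[f] <- mean(abs(pred - y[!tr]))
  }
  structure(list(mse_mean = mean(mse), mse_sd = sd(mse),
                 mae_mean = mean(mae), mae_sd = sd(mae),
                 fold_mse = mse, fold_mae = mae,
                 fold_assignments = folds, seed = seed),
            class = "cv_report")
}

#' Welch t-tests between severity levels for each feature
#'
#' For every pair of severity levels (by RSD grade) and every feature, a
#' Welch two-sample t-test, annotated with the conventional significance
#' stars (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001). Raw p-values are
#' reported without multiple-testing correction (noted in the output
#' attributes); level pairs with fewer than 2 samples on either side are
#' skipped with a flag.
#'
#' @param features data frame / matrix of per-image features.
#' @param rsd per-image integer severity level.
#' @param feature_names columns to test (default all).
#' @return Data frame with level pair, feature, p-value, stars and a
#'   `skipped` flag; attribute `correction = "none"`.
#' @export
group_ttests <- function(features, rsd, feature_names = colnames(features)) {
  features <- as.data.frame(features)
  stopifnot(nrow(features) == length(rsd))
  levs <- sort(unique(rsd))
  out <- list()
  for (i in seq_along(levs)) for (j in seq_along(levs)) {
    if (j <= i) next
    a <- rsd == levs[i]; b <- rsd == levs[j]
    for (fn in feature_names) {
      if (sum(a) < 2 || sum(b) < 2) {
        out[[length(out) + 1]] <- data.frame(
          level_a = levs[i], level_b = levs[j], feature = fn,
          p_value = NA_real_, stars = "", skipped = TRUE)
        next
      }
      xa <- features[[fn]][a]; xb <- features[[fn]][b]
      p <- if (sd(xa) == 0 && sd(xb) == 0 && mean(xa) == mean(xb)) 1
           else t.test(xa, xb, var.equal = FALSE)$p.value
      out[[length(out) + 1]] <- data.frame(
        level_a = levs[i], level_b = levs[j], feature = fn,
        p_value = p, stars = p_stars(p), skipped = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "correction") <- "none"
  res
}

p_stars <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else ""
}

#' Save / load a severity model as JSON
#' @param model a `severity_model`.
#' @param path JSON path.
#' @export
save_severity_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_severity_model
#' @export
load_severity_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(intercept = m$intercept,
                 coefficients = stats::setNames(unlist(m$coefficients),
                                                m$selected_features),
                 selected_features = m$selected_features,
                 feature_mean = stats::setNames(unlist(m$feature_mean),
                                                m$selected_features),
                 feature_sd = stats::setNames(unlist(m$feature_sd),
                                              m$selected_features),
                 training_n = m$training_n),
            class = "severity_model")
}
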