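#' Stratified train/test split
#'
#' Splits samples into training and testing subsets, stratified by a label so
#' that each stratum contributes its share: per stratum, `round(fraction * n)`
#' samples go to training (always leaving at least one sample per side where
#' possible).
#'
#' @param n Number of samples, or a vector whose length is used.
#' @param strata Stratification labels (one per sample).
#' @param fraction Training fraction (default 0.70).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_data <- function(n, strata, fraction = 0.70, seed = 1) {
  if (length(n) > 1) n <- length(n)
  strata <- factor(strata)
  .assert(length(strata) == n, "one stratum label per sample required")
  sizes <- table(strata)
  if (any(sizes < 2)) {
    stop("stratification error: stratum of size 1 (",
         paste(names(sizes)[sizes < 2], collapse = ", "), ")", call. = FALSE)
  }
  set.seed(seed)
  train <- unlist(lapply(split(seq_len(n), strata), function(ix) {
    k <- round(fraction * length(ix))
    k <- min(max(k, 1L), length(ix) - 1L)
    sample(ix, k)
  }), use.names = FALSE)
  list(train = sort(train), test = sort(setdiff(seq_len(n), train)))
}

# NIPALS component extraction shared by PLS1/PLS2. Returns weights W, X
# loadings P, y loadings Q, score norms tt, plus centering vectors.
.nipals_pls <- function(X, Y, n_components, scale = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  xmean <- colMeans(X); ymean <- colMeans(Y)
  xsd <- if (scale) apply(X, 2, stats::sd) else rep(1, ncol(X))
  xsd[xsd == 0] <- 1
  Xc <- sweep(sweep(X, 2, xmean), 2, xsd, "/")
  Yc <- sweep(Y, 2, ymean)
  p <- ncol(Xc); m <- ncol(Yc)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Q <- matrix(0, m, n_components)
  TT <- numeric(n_components)
  Tm <- matrix(0, nrow(Xc), n_components)
  a_used <- 0L
  for (a in seq_len(n_components)) {
    M <- crossprod(Xc, Yc)
    if (m == 1) {
      w <- M[, 1]
    } else {
      w <- svd(M, nu = 1, nv = 0)$u[, 1]
    }
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    tsc <- Xc %*% w
    tt <- sum(tsc^2)
    if (tt < 1e-12) break
    pl <- crossprod(Xc, tsc) / tt
    ql <- crossprod(Yc, tsc) / tt
    Xc <- Xc - tsc %*% t(pl)
    Yc <- Yc - tsc %*% t(ql)
    W[, a] <- w; P[, a] <- pl; Q[, a] <- ql; TT[a] <- tt; Tm[, a] <- tsc
    a_used <- a
  }
  .assert(a_used >= 1, "no usable latent component (degenerate inputs)")
  if (a_used < n_components) {
    warning("training matrix rank limits components to ", a_used)
  }
  ix <- seq_len(a_used)
  list(W = W[, ix, drop = FALSE], P = P[, ix, drop = FALSE],
       Q = Q[, ix, drop = FALSE], TT = TT[ix],
       scores = Tm[, ix, drop = FALSE],
       xmean = xmean, ymean = ymean, xsd = xsd, n_components = a_used)
}

.pls_coefficients <- function(fit) {
  R <- fit$W %*% solve(crossprod(fit$P, fit$W))
  B <- R %*% t(fit$Q)
  sweep(B, 1, fit$xsd, "/")
}

#' Fit a PLSR model (NIPALS)
#'
#' Sequential latent components maximizing the covariance of the deflated
#' band matrix with the trait; prediction is a linear map of the centered
#' spectra. Wavelet-coefficient inputs share units across bands, so the
#' default is centering without unit-variance scaling.
#'
#' @param X Band matrix (samples x bands).
#' @param y Numeric trait vector.
#' @param n_components Number of latent components (>= 1, < rows).
#' @param scale Scale bands to unit variance before fitting (default FALSE).
#' @return A `pls_model` with coefficients, loadings, training `r2` and
#'   `rmsep`.
#' @export
fit_plsr <- function(X, y, n_components, scale = FALSE) {
  X <- as.matrix(X)
  .assert(nrow(X) == length(y), "rows of X must match length of y")
  .assert(nrow(X) > n_components, "need more samples than components")
  .assert(stats::sd(y) > 0, "degenerate target: y is constant")
  fit <- .nipals_pls(X, matrix(y, ncol = 1), n_components, scale = scale)
  B <- .pls_coefficients(fit)
  pred <- as.numeric(sweep(X, 2, fit$xmean) %*% B + fit$ymean)
  resid <- y - pred
  model <- structure(c(fit, list(
    coefficients = B, target = "y", type = "regression",
    r2 = 1 - sum(resid^2) / sum((y - mean(y))^2),
    rmsep = sqrt(mean(resid^2)),
    ssy = as.numeric(fit$Q[1, ])^2 * fit$TT)), class = "pls_model")
  model
}

#' @export
print.pls_model <- function(x, ...) {
  if (x$type == "regression") {
    cat(sprintf("<pls_model> PLSR, %d components, %d bands; training R2 = %.3f, RMSEP = %.4g\n",
                x$n_components, nrow(x$W), x$r2, x$rmsep))
  } else {
    cat(sprintf("<pls_model> PLS-DA, %d components, %d bands, %d classes\n",
                x$n_components, nrow(x$W), ncol(x$Q)))
  }
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Band matrix.
#' @param ... Unused.
#' @return Numeric vector (regression) or matrix of class scores
#'   (discriminant models).
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  out <- sweep(newdata, 2, object$xmean) %*% object$coefficients
  out <- sweep(out, 2, object$ymean, "+")
  if (object$type == "regression") as.numeric(out) else out
}

#' Choose the number of PLSR components by cross-validation
#'
#' K-fold cross-validated RMSEP for 1..`max_comp` components; the selected
#' count is the smallest one whose mean RMSEP lies within one standard error
#' of the global minimum (the one-SE rule), which collapses to a single
#' component for pure-noise targets.
#'
#' @param X Band matrix.
#' @param y Trait vector.
#' @param max_comp Largest component count considered.
#' @param k_folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer component count (attribute `cv` holds the RMSEP table).
#' @export
select_ncomp <- function(X, y, max_comp = 10, k_folds = 10, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  .assert(max_comp >= 1, "max_comp must be >= 1")
  max_comp <- min(max_comp, n - ceiling(n / k_folds) - 1L)
  set.seed(seed)
  fold <- sample(rep(seq_len(k_folds), length.out = n))
  errs <- matrix(NA_real_, k_folds, max_comp)
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    fit <- .nipals_pls(X[tr, , drop = FALSE], matrix(y[tr], ncol = 1),
                       max_comp)
    for (a in seq_len(fit$n_components)) {
      sub <- list(W = fit$W[, 1:a, drop = FALSE],
                  P = fit$P[, 1:a, drop = FALSE],
                  Q = fit$Q[, 1:a, drop = FALSE], xsd = fit$xsd)
      B <- .pls_coefficients(sub)
      pred <- sweep(X[!tr, , drop = FALSE], 2, fit$xmean) %*% B + fit$ymean
      errs[f, a] <- sqrt(mean((y[!tr] - pred)^2))
    }
  }
  mu <- colMeans(errs, na.rm = TRUE)
  se <- apply(errs, 2, function(v) stats::sd(v, na.rm = TRUE)) / sqrt(k_folds)
  best <- which.min(mu)
  chosen <- min(which(mu <= mu[best] + se[best]))
  structure(chosen, cv = data.frame(n_comp = seq_len(max_comp),
                                    rmsep = mu, se = se))
}

#' Variable importance in projection (VIP) scores
#'
#' `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)` with `p` the band
#' count and `SSY_a` the response variance explained by component `a`
#' (weights are unit-norm per component). The scores satisfy
#' `sum(VIP^2) = p`, i.e. mean squared VIP of 1; the conventional selection
#' thresholds are 0.8 (important) with a relaxed 0.4 floor for broader band
#' sets.
#'
#' @param model A fitted `pls_model`.
#' @return Numeric vector of per-band VIP scores.
#' @export
vip_scores <- function(model) {
  .assert(inherits(model, "pls_model"), "state error: model must be a fitted pls_model")
  ssy <- if (model$type == "regression") {
    model$ssy
  } else {
    colSums(model$Q^2) * model$TT
  }
  p <- nrow(model$W)
  w2 <- model$W^2
  sqrt(p * as.numeric(w2 %*% ssy) / sum(ssy))
}

#' Select bands by VIP thresholds
#'
#' Implements the two-tier rule: keep bands with VIP above `primary`
#' (strict), then extend with bands at or above `secondary`.
#'
#' @param vip Numeric VIP vector.
#' @param primary Strict threshold (default 0.8, exclusive).
#' @param secondary Relaxed threshold (default 0.4, inclusive).
#' @return Logical selection vector.
#' @export
vip_select <- function(vip, primary = 0.8, secondary = 0.4) {
  if (!any(vip > primary)) return(vip > primary)
  vip > primary | vip >= secondary
}

#' Fit an iterative bootstrap PLS-DA classifier
#'
#' One-hot class targets; per iteration every class is resampled with
#' replacement to the minimum class size (balancing classes), a PLS2 model is
#' fitted, and test samples are assigned to the class with the largest
#' predicted target score (ties break to the lowest class index). Confusion
#' counts are aggregated over iterations; rows are predicted classes, columns
#' observed.
#'
#' @param X Training band matrix.
#' @param labels Training class labels (>= 2 classes; a warning is issued for
#'   classes below 20 samples).
#' @param n_components Latent components.
#' @param X_test,labels_test Evaluation set; defaults to the training set.
#' @param n_iterations Bootstrap iterations (default 50).
#' @param seed Integer seed.
#' @return A `plsda_result`: final `model` (fitted on all training data),
#'   `confusion` (counts), `confusion_percent` (column percentages),
#'   `accuracy`, `kappa`, `sensitivity`, `specificity`.
#' @export
fit_plsda <- function(X, labels, n_components, X_test = X,
                      labels_test = labels, n_iterations = 50, seed = 1) {
  X <- as.matrix(X); X_test <- as.matrix(X_test)
  labels <- factor(labels)
  classes <- levels(labels)
  .assert(length(classes) >= 2, "need >= 2 classes")
  sizes <- table(labels)
  if (any(sizes < 20)) {
    warning("classes below the recommended minimum of 20 samples: ",
            paste(names(sizes)[sizes < 20], collapse = ", "))
  }
  labels_test <- factor(labels_test, levels = classes)
  onehot <- function(f) {
    Y <- matrix(0, length(f), length(classes),
                dimnames = list(NULL, classes))
    Y[cbind(seq_along(f), as.integer(f))] <- 1
    Y
  }
  min_size <- min(sizes)
  idx_by_class <- split(seq_along(labels), labels)
  set.seed(seed)
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(predicted = classes, observed = classes))
  for (it in seq_len(n_iterations)) {
    ix <- unlist(lapply(idx_by_class, function(ii)
      ii[sample.int(length(ii), min_size, replace = TRUE)]),
      use.names = FALSE)
    fit <- .nipals_pls(X[ix, , drop = FALSE], onehot(labels[ix]),
                       n_components)
    B <- .pls_coefficients(fit)
    scores <- sweep(sweep(X_test, 2, fit$xmean) %*% B, 2, fit$ymean, "+")
    pred <- max.col(scores, ties.method = "first")
    for (j in seq_along(pred)) {
      conf[pred[j], as.integer(labels_test[j])] <-
        conf[pred[j], as.integer(labels_test[j])] + 1L
    }
  }
  final_fit <- .nipals_pls(X, onehot(labels), n_components)
  model <- structure(c(final_fit, list(
    coefficients = .pls_coefficients(final_fit),
    target = "class", type = "classification", classes = classes)),
    class = "pls_model")
  total <- sum(conf)
  acc <- sum(diag(conf)) / total
  p_obs <- acc
  p_exp <- sum(rowSums(conf) * colSums(conf)) / total^2
  kappa <- (p_obs - p_exp) / (1 - p_exp)
  sens <- diag(conf) / colSums(conf)
  spec <- vapply(seq_along(classes), function(k) {
    tn <- total - sum(conf[k, ]) - sum(conf[, k]) + conf[k, k]
    tn / (total - colSums(conf)[k])
  }, numeric(1))
  names(spec) <- classes
  structure(list(model = model, confusion = conf,
                 confusion_percent = sweep(conf, 2, colSums(conf), "/") * 100,
                 accuracy = acc, kappa = kappa,
                 sensitivity = sens, specificity = spec),
            class = "plsda_result")
}

#' @export
print.plsda_result <- function(x, ...) {
  cat(sprintf("<plsda_result> %d classes; accuracy = %.3f, kappa = %.3f\n",
              ncol(x$confusion), x$accuracy, x$kappa))
  invisible(x)
}
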