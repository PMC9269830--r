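#' Default classifier specifications
#'
#' The six classical classifiers of the offline comparison, with the
#' published hyperparameter settings: KNN (k = 5, Euclidean), L2-regularised
#' logistic regression (C = 1), RBF-kernel SVM (C = 1, gamma = 1/(p * Var)),
#' Gaussian naive Bayes, a multilayer perceptron with hidden layers
#' (100, 3), L2 penalty 1e-5 and an L-BFGS optimiser, and bagging of 500
#' logistic-regression base learners.
#'
#' @param bagging_estimators number of bagging base learners (default 500;
#'   scaled runs may lower it).
#' @param mlp_maxit L-BFGS iteration cap for the MLP (default 1000).
#' @return named list of classifier specs (`knn`, `lr`, `svm`, `gnb`,
#'   `mlp`, `bagging`); each spec carries `name`, `params`, `seed`, and
#'   `rotation_invariant` (whether the method depends on the features only
#'   through inner products/distances, allowing the exact row-space
#'   reduction).
#' @export
classifier_specs <- function(bagging_estimators = 500, mlp_maxit = 1000) {
  list(
    knn = list(name = "KNN", params = list(k = 5), seed = 0L,
               rotation_invariant = TRUE),
    lr = list(name = "LR", params = list(C = 1), seed = 10L,
              rotation_invariant = TRUE),
    svm = list(name = "SVM", params = list(cost = 1), seed = 10L,
               rotation_invariant = TRUE),
    gnb = list(name = "GNB", params = list(), seed = 0L,
               rotation_invariant = FALSE),
    mlp = list(name = "MLP",
               params = list(hidden = c(100, 3), alpha = 1e-5,
                             maxit = mlp_maxit),
               seed = 1L, rotation_invariant = TRUE),
    bagging = list(name = "Bagging",
                   params = list(n_estimators = bagging_estimators,
                                 base_C = 1),
                   seed = 1L, rotation_invariant = TRUE)
  )
}

#' Exact row-space reduction for wide sample matrices
#'
#' When n << p, replaces the n x p sample matrix X by an n x r matrix Z
#' with Z Z' = X X' (eigendecomposition of the Gram matrix). Pairwise
#' distances and inner products among the samples are preserved exactly,
#' and the optima of L2-penalised linear and neural models lie in the row
#' space, so classifiers that depend on the data only through inner
#' products or distances give identical predictions on Z. Gaussian naive
#' Bayes is not rotation-invariant and must see the original features.
#'
#' The original dimension and total variance are kept as attributes
#' (`orig_p`, `orig_var`) so kernel parameters defined on the original
#' scale can still be computed.
#'
#' @param x n x p numeric matrix.
#' @return n x r matrix (r <= n) with attributes, or `x` unchanged when
#'   p <= n.
#' @export
reduce_rowspace <- function(x) {
  n <- nrow(x); p <- ncol(x)
  ov <- mean((x - mean(x))^2)
  if (p <= n) {
    attr(x, "orig_p") <- p
    attr(x, "orig_var") <- ov
    return(x)
  }
  K <- tcrossprod(x)
  e <- eigen(K, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  z <- e$vectors %*% diag(sqrt(vals), n, n)
  attr(z, "orig_p") <- p
  attr(z, "orig_var") <- ov
  z
}

# sklearn-style gamma = 'scale' = 1 / (p * Var(X)), computed on the
# original feature scale even after row-space reduction.
gamma_scale <- function(x) {
  p <- attr(x, "orig_p"); v <- attr(x, "orig_var")
  if (is.null(p)) { p <- ncol(x); v <- mean((x - mean(x))^2) }
  if (v <= 0) v <- 1
  1 / (p * v)
}

#' Train one classifier
#'
#' @param spec one element of [classifier_specs()].
#' @param x n x p training matrix (possibly row-space reduced).
#' @param y factor of class labels.
#' @return fitted model of class `eegtw_model`.
#' @export
train_classifier <- function(spec, x, y) {
  y <- droplevels(as.factor(y))
  set.seed(spec$seed)
  fit <- switch(spec$name,
    KNN = list(x = x, y = y, k = spec$params$k),
    LR = fit_lr(x, y, C = spec$params$C),
    SVM = e1071::svm(x, y, kernel = "radial", cost = spec$params$cost,
                     gamma = gamma_scale(x), scale = FALSE,
                     probability = FALSE),
    GNB = gnb_fit(x, y),
    MLP = mlp_fit(x, y, hidden = spec$params$hidden,
                  alpha = spec$params$alpha, maxit = spec$params$maxit,
                  seed = spec$seed),
    Bagging = bagging_fit(x, y, n_estimators = spec$params$n_estimators,
                          C = spec$params$base_C, seed = spec$seed),
    stop("unknown classifier: ", spec$name)
  )
  structure(list(name = spec$name, fit = fit, levels = levels(y)),
            class = "eegtw_model")
}

#' Predict classes or class probabilities
#'
#' @param model an `eegtw_model`.
#' @param x matrix of samples in the same representation as training.
#' @param type `"class"` or `"prob"` (probabilities unavailable for KNN
#'   and SVM, which are used for accuracy only).
#' @return factor of classes, or n x k probability matrix.
#' @export
predict_classifier <- function(model, x, type = c("class", "prob")) {
  type <- match.arg(type)
  lev <- model$levels
  out <- switch(model$name,
    KNN = {
      if (type == "prob") stop("KNN backend emits classes only")
      class::knn(model$fit$x, x, model$fit$y, k = model$fit$k)
    },
    LR = predict_lr(model$fit, x, type),
    SVM = {
      if (type == "prob") stop("SVM backend emits classes only")
      stats::predict(model$fit, x)
    },
    GNB = gnb_predict(model$fit, x, type),
    MLP = mlp_predict(model$fit, x, type),
    Bagging = bagging_predict(model$fit, x, type)
  )
  if (type == "class") factor(as.character(out), levels = lev) else out
}

# ---- logistic regression (ridge multinomial, lambda = 1/(n*C)) ----------

fit_lr <- function(x, y, C = 1) {
  n <- nrow(x)
  # glmnet advises when a class has < 8 observations; routine at the small
  # per-fold scales used in tests, so that advisory is muffled
  g <- withCallingHandlers(
    glmnet::glmnet(x, y, family = "multinomial", alpha = 0,
                   lambda = 1 / (n * C), standardize = FALSE),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(glmnet = g, levels = levels(y))
}

predict_lr <- function(fit, x, type) {
  pr <- stats::predict(fit$glmnet, x, type = "response")[, , 1]
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1,
                                     dimnames = list(NULL, names(pr)))
  if (type == "prob") return(pr)
  factor(colnames(pr)[max.col(pr, ties.method = "first")],
         levels = fit$levels)
}

# ---- Gaussian naive Bayes (vectorised) -----------------------------------
# Class-conditional diagonal Gaussians with variance smoothing
# eps = 1e-9 * max feature variance, matching the usual GNB stabilisation.
# Implemented with matrix algebra because looping backends are infeasible
# at p ~ 5e4; cross-checked against e1071::naiveBayes in the test suite.

gnb_fit <- function(x, y) {
  lev <- levels(y)
  p <- ncol(x)
  mu <- matrix(0, length(lev), p)
  v <- matrix(0, length(lev), p)
  prior <- numeric(length(lev))
  for (i in seq_along(lev)) {
    xi <- x[y == lev[i], , drop = FALSE]
    mu[i, ] <- colMeans(xi)
    v[i, ] <- colMeans(xi^2) - mu[i, ]^2
    prior[i] <- nrow(xi) / nrow(x)
  }
  eps <- 1e-9 * max(colMeans(x^2) - colMeans(x)^2)
  v <- v + max(eps, .Machine$double.eps)
  list(mu = mu, v = v, prior = prior, levels = lev)
}

gnb_predict <- function(fit, x, type = "class") {
  k <- length(fit$levels)
  ll <- matrix(0, nrow(x), k)
  x2 <- x^2
  for (i in seq_len(k)) {
    iv <- 1 / fit$v[i, ]
    ll[, i] <- -0.5 * (x2 %*% iv) + x %*% (fit$mu[i, ] * iv) -
      0.5 * sum(fit$mu[i, ]^2 * iv) -
      0.5 * sum(log(2 * pi * fit$v[i, ])) + log(fit$prior[i])
  }
  if (type == "prob") {
    m <- apply(ll, 1, max)
    pr <- exp(ll - m)
    pr <- pr / rowSums(pr)
    colnames(pr) <- fit$levels
    return(pr)
  }
  factor(fit$levels[max.col(ll, ties.method = "first")], levels = fit$levels)
}

# ---- multilayer perceptron (hidden layers (100, 3), ReLU, softmax) -------
# Trained by limited-memory BFGS on the mean cross-entropy plus
# alpha/(2n) * sum of squared weights. Written in-package because no
# installed backend supports two hidden layers at these dimensions; used
# on row-space-reduced inputs, where the L2-penalised optimum is
# representation-equivalent to the full-space fit.

mlp_unpack <- function(theta, sizes) {
  out <- list(); pos <- 0
  for (i in seq_len(length(sizes) - 1)) {
    nw <- sizes[i] * sizes[i + 1]
    out[[paste0("W", i)]] <- matrix(theta[pos + seq_len(nw)], sizes[i], sizes[i + 1])
    pos <- pos + nw
    out[[paste0("b", i)]] <- theta[pos + seq_len(sizes[i + 1])]
    pos <- pos + sizes[i + 1]
  }
  out
}

mlp_fit <- function(x, y, hidden = c(100, 3), alpha = 1e-5, maxit = 1000,
                    seed = 1L) {
  lev <- levels(y)
  k <- length(lev)
  n <- nrow(x)
  Y <- outer(y, lev, "==") * 1
  sizes <- c(ncol(x), hidden, k)
  nlayer <- length(sizes) - 1
  set.seed(seed)
  theta0 <- unlist(lapply(seq_len(nlayer), function(i) {
    lim <- sqrt(6 / (sizes[i] + sizes[i + 1]))
    c(stats::runif(sizes[i] * sizes[i + 1], -lim, lim), rep(0, sizes[i + 1]))
  }))
  fwd <- function(w, X) {
    a <- list(X)
    for (i in seq_len(nlayer)) {
      z <- sweep(a[[i]] %*% w[[paste0("W", i)]], 2, w[[paste0("b", i)]], "+")
      a[[i + 1]] <- if (i < nlayer) pmax(z, 0) else z
    }
    a
  }
  obj <- function(theta) {
    w <- mlp_unpack(theta, sizes)
    a <- fwd(w, x)
    z <- a[[nlayer + 1]]
    zs <- z - apply(z, 1, max)
    lse <- log(rowSums(exp(zs)))
    ce <- -mean(rowSums(Y * zs) - lse)
    pen <- sum(vapply(seq_len(nlayer),
                      function(i) sum(w[[paste0("W", i)]]^2), 0))
    ce + alpha / (2 * n) * pen
  }
  grad <- function(theta) {
    w <- mlp_unpack(theta, sizes)
    a <- fwd(w, x)
    z <- a[[nlayer + 1]]
    zs <- exp(z - apply(z, 1, max))
    P <- zs / rowSums(zs)
    d <- (P - Y) / n
    g <- numeric(0)
    gs <- vector("list", nlayer)
    for (i in nlayer:1) {
      gW <- crossprod(a[[i]], d) + (alpha / n) * w[[paste0("W", i)]]
      gb <- colSums(d)
      gs[[i]] <- c(as.vector(gW), gb)
      if (i > 1) d <- (d %*% t(w[[paste0("W", i)]])) * (a[[i]] > 0)
    }
    unlist(gs)
  }
  opt <- stats::optim(theta0, obj, grad, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  list(w = mlp_unpack(opt$par, sizes), sizes = sizes, levels = lev,
       value = opt$value, convergence = opt$convergence)
}

mlp_predict <- function(fit, x, type = "class") {
  w <- fit$w
  nlayer <- length(fit$sizes) - 1
  a <- x
  for (i in seq_len(nlayer)) {
    z <- sweep(a %*% w[[paste0("W", i)]], 2, w[[paste0("b", i)]], "+")
    a <- if (i < nlayer) pmax(z, 0) else z
  }
  zs <- exp(a - apply(a, 1, max))
  pr <- zs / rowSums(zs)
  colnames(pr) <- fit$levels
  if (type == "prob") return(pr)
  factor(fit$levels[max.col(pr, ties.method = "first")], levels = fit$levels)
}

# ---- bagging of logistic-regression base learners ------------------------
# Bootstrap-resampled LR models whose predicted probabilities are averaged
# (soft voting). Written in-package: no bagging meta-learner is installed.

bagging_fit <- function(x, y, n_estimators = 500, C = 1, seed = 1L) {
  set.seed(seed)
  n <- nrow(x)
  models <- vector("list", n_estimators)
  for (i in seq_len(n_estimators)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == nlevels(y)) break
    }
    models[[i]] <- fit_lr(x[idx, , drop = FALSE], droplevels(y[idx]), C = C)
  }
  list(models = models, levels = levels(y))
}

bagging_predict <- function(fit, x, type = "class") {
  pr <- 0
  for (m in fit$models) pr <- pr + predict_lr(m, x, "prob")
  pr <- pr / length(fit$models)
  if (type == "prob") return(pr)
  factor(colnames(pr)[max.col(pr, ties.method = "first")],
         levels = fit$levels)
}
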