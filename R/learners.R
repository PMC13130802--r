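# Nine-regressor registry behind a uniform fit/predict/importance surface.
# Tree ensembles run on the compiled CART core in src/; PLS, MARS, SVR and
# the single-hidden-layer network are compact in-package implementations
# (their usual CRAN homes are not part of this stack); ElasticNet and kNN
# delegate to glmnet and FNN.

ALGORITHMS <- c("PLS", "ElasticNet", "RF", "GBT", "ESR", "MARS", "kNN",
                "SVM", "ANN")

#' Hyperparameter grids for the regression spot-check
#'
#' Small fixed grids searched by repeated k-fold cross-validation during
#' [spot_check()]. Each element is a data frame of candidate settings for
#' one algorithm; pass a modified copy through `spot_check(grids = ...)`
#' to override.
#'
#' @param p Number of predictors.
#' @param n Number of training rows.
#' @return Named list of data frames.
#' @export
default_grids <- function(p, n) {
  list(
    PLS = data.frame(ncomp = seq_len(min(10L, p))),
    ElasticNet = expand.grid(alpha = c(0, 0.5, 1),
                             lambda = 10^seq(-3, 1, length.out = 5)),
    RF = data.frame(mtry = unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3), p))),
                    ntrees = 200L),
    GBT = expand.grid(max_depth = c(2L, 4L, 6L),
                      eta = c(0.05, 0.1, 0.3),
                      nrounds = c(100L, 300L)),
    ESR = data.frame(dummy = 0),
    MARS = data.frame(degree = c(1L, 2L)),
    kNN = data.frame(k = c(3L, 5L, 7L, 9L)),
    SVM = data.frame(cost = c(0.25, 1, 4)),
    ANN = expand.grid(size = c(3L, 5L, 8L), decay = c(0.01, 0.1))
  )
}

fit_learner <- function(algorithm, x, y, params) {
  fit <- switch(
    algorithm,
    PLS = fit_pls(x, y, ncomp = params$ncomp),
    ElasticNet = fit_enet(x, y, alpha = params$alpha, lambda = params$lambda),
    RF = fit_rf(x, y, mtry = params$mtry, ntrees = params$ntrees),
    GBT = fit_gbt(x, y, max_depth = params$max_depth, eta = params$eta,
                  nrounds = params$nrounds),
    ESR = fit_esr(x, y),
    MARS = fit_mars(x, y, degree = params$degree),
    kNN = fit_knn(x, y, k = params$k),
    SVM = fit_svr(x, y, cost = params$cost),
    ANN = fit_ann(x, y, size = params$size, decay = params$decay),
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  )
  structure(list(algorithm = algorithm, fit = fit, params = params,
                 predictors = colnames(x)),
            class = "mediaopt_learner")
}

#' @export
predict.mediaopt_learner <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$predictors, drop = FALSE])
  storage.mode(x) <- "double"
  switch(
    object$algorithm,
    PLS = predict_pls(object$fit, x),
    ElasticNet = as.numeric(stats::predict(object$fit$model, newx = scale_apply(x, object$fit$sc),
                                           s = object$fit$lambda)),
    RF = cpp_forest_predict(object$fit$trees, x),
    GBT = cpp_gbt_predict(object$fit, x),
    ESR = predict_esr(object$fit, x),
    MARS = predict_mars(object$fit, x),
    kNN = predict_knn(object$fit, x),
    SVM = predict_svr(object$fit, x),
    ANN = predict_ann(object$fit, x)
  )
}

# ---- scaling helpers --------------------------------------------------------

scale_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}

scale_apply <- function(x, sc) sweep(sweep(x, 2, sc$mu), 2, sc$sd, "/")

# ---- PLS (NIPALS) -----------------------------------------------------------

fit_pls <- function(x, y, ncomp) {
  sc <- scale_fit(x)
  xs <- scale_apply(x, sc)
  ym <- mean(y)
  ys <- y - ym
  n <- nrow(xs); p <- ncol(xs)
  ncomp <- min(ncomp, p, n - 1L)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); Q <- numeric(ncomp)
  Xd <- xs
  yd <- ys
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) { ncomp <- a - 1L; break }
    pvec <- drop(crossprod(Xd, t)) / tt
    q <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pvec)
    yd <- yd - q * t
    W[, a] <- w; P[, a] <- pvec; Q[a] <- q
  }
  if (ncomp < 1L) {
    return(list(sc = sc, ym = ym, beta = rep(0, p)))
  }
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  Q <- Q[seq_len(ncomp)]
  R <- W %*% solve(crossprod(P, W))
  beta <- drop(R %*% Q)
  list(sc = sc, ym = ym, beta = beta)
}

predict_pls <- function(fit, x) {
  drop(scale_apply(x, fit$sc) %*% fit$beta) + fit$ym
}

# ---- ElasticNet (glmnet) ----------------------------------------------------

fit_enet <- function(x, y, alpha, lambda) {
  sc <- scale_fit(x)
  model <- glmnet::glmnet(scale_apply(x, sc), y, alpha = alpha,
                          lambda = sort(unique(c(lambda, 10^seq(-4, 2, length.out = 40))),
                                        decreasing = TRUE),
                          standardize = FALSE)
  list(model = model, sc = sc, lambda = lambda)
}

# ---- tree ensembles (compiled core) ----------------------------------------

fit_rf <- function(x, y, mtry, ntrees = 200L, max_depth = 25L, min_node = 5L) {
  fit <- cpp_forest_fit(x, y, as.integer(ntrees), as.integer(mtry),
                        as.integer(max_depth), as.integer(min_node))
  names(fit$importance) <- colnames(x)
  fit
}

fit_gbt <- function(x, y, max_depth, eta, nrounds, min_node = 5L,
                    subsample = 1.0) {
  fit <- cpp_gbt_fit(x, y, as.integer(nrounds), as.integer(max_depth), eta,
                     as.integer(min_node), subsample)
  names(fit$importance) <- colnames(x)
  fit
}

# ---- stacked ensemble (ESR) -------------------------------------------------
# RF + GBT + ElasticNet base learners combined by a non-negative
# least-squares meta-learner trained on out-of-fold predictions.

fit_esr <- function(x, y, folds = 5L) {
  n <- nrow(x)
  folds <- min(folds, n)
  fold_id <- rep_len(seq_len(folds), n)[sample.int(n)]
  base_fit <- function(xi, yi) {
    list(rf = fit_rf(xi, yi, mtry = max(1L, floor(sqrt(ncol(xi))))),
         gbt = fit_gbt(xi, yi, max_depth = 4L, eta = 0.1, nrounds = 100L),
         enet = fit_enet(xi, yi, alpha = 0.5, lambda = 0.01))
  }
  base_predict <- function(fits, xi) {
    cbind(rf = cpp_forest_predict(fits$rf$trees, xi),
          gbt = cpp_gbt_predict(fits$gbt, xi),
          enet = as.numeric(stats::predict(fits$enet$model,
                                           newx = scale_apply(xi, fits$enet$sc),
                                           s = fits$enet$lambda)))
  }
  oof <- matrix(NA_real_, n, 3L)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fits <- base_fit(x[tr, , drop = FALSE], y[tr])
    oof[!tr, ] <- base_predict(fits, x[!tr, , drop = FALSE])
  }
  # non-negative least squares via box-constrained ridge-free glmnet
  meta <- glmnet::glmnet(oof, y, alpha = 0, lambda = 1e-6,
                         lower.limits = 0, standardize = FALSE)
  full <- base_fit(x, y)
  list(base = full, meta = meta, base_predict = base_predict)
}

predict_esr <- function(fit, x) {
  z <- fit$base_predict(fit$base, x)
  as.numeric(stats::predict(fit$meta, newx = z, s = 1e-6))
}

# ---- MARS (forward hinge selection + GCV pruning) ---------------------------

mars_hinge <- function(x, knot, sign) pmax(0, sign * (x - knot))

fit_mars <- function(x, y, degree = 1L, max_terms = NULL, n_knots = 15L,
                     penalty = NULL) {
  n <- nrow(x); p <- ncol(x)
  if (is.null(max_terms)) max_terms <- min(21L, 2L * floor(n / 3) + 1L)
  if (is.null(penalty)) penalty <- if (degree > 1L) 3 else 2
  # term description: list of components, each (var, knot, sign)
  terms <- list(list())            # intercept
  B <- matrix(1, n, 1)
  term_vars <- list(integer(0))
  rss_of <- function(B) {
    f <- stats::lm.fit(B, y)
    sum(f$residuals^2)
  }
  best_rss <- rss_of(B)
  repeat {
    if (ncol(B) + 2L > max_terms) break
    best <- NULL
    for (m in seq_along(terms)) {
      if (length(terms[[m]]) >= degree) next
      parent <- B[, m]
      for (v in seq_len(p)) {
        if (v %in% term_vars[[m]]) next
        xv <- x[, v]
        ks <- unique(stats::quantile(xv, probs = seq(0.05, 0.95,
                                                     length.out = n_knots),
                                     type = 7, names = FALSE))
        for (k in ks) {
          b1 <- parent * mars_hinge(xv, k, 1)
          b2 <- parent * mars_hinge(xv, k, -1)
          if (stats::sd(b1) < 1e-10 || stats::sd(b2) < 1e-10) next
          rss <- rss_of(cbind(B, b1, b2))
          if (is.null(best) || rss < best$rss - 1e-12) {
            best <- list(rss = rss, m = m, v = v, k = k)
          }
        }
      }
    }
    if (is.null(best) || best$rss > best_rss * (1 - 1e-4)) break
    xv <- x[, best$v]
    B <- cbind(B, B[, best$m] * mars_hinge(xv, best$k, 1),
               B[, best$m] * mars_hinge(xv, best$k, -1))
    parent_term <- terms[[best$m]]
    terms <- c(terms, list(c(parent_term, list(list(var = best$v, knot = best$k, sign = 1)))),
               list(c(parent_term, list(list(var = best$v, knot = best$k, sign = -1)))))
    term_vars <- c(term_vars, list(c(term_vars[[best$m]], best$v)),
                   list(c(term_vars[[best$m]], best$v)))
    best_rss <- best$rss
  }
  # backward pruning by generalized cross-validation
  gcv <- function(rss, M) {
    cM <- M + penalty * (M - 1) / 2
    rss / n / (1 - cM / n)^2
  }
  keep <- seq_len(ncol(B))
  best_gcv <- gcv(rss_of(B[, keep, drop = FALSE]), length(keep))
  repeat {
    if (length(keep) <= 1L) break
    cand <- NULL
    for (j in keep[-1]) {    # never drop the intercept
      k2 <- setdiff(keep, j)
      g <- gcv(rss_of(B[, k2, drop = FALSE]), length(k2))
      if (is.null(cand) || g < cand$g) cand <- list(g = g, j = j)
    }
    if (cand$g >= best_gcv) break
    keep <- setdiff(keep, cand$j)
    best_gcv <- cand$g
  }
  fit <- stats::lm.fit(B[, keep, drop = FALSE], y)
  list(terms = terms[keep], coef = fit$coefficients)
}

mars_basis <- function(terms, x) {
  vapply(terms, function(tm) {
    b <- rep(1, nrow(x))
    for (cmp in tm) b <- b * mars_hinge(x[, cmp$var], cmp$knot, cmp$sign)
    b
  }, numeric(nrow(x)))
}

predict_mars <- function(fit, x) {
  B <- mars_basis(fit$terms, x)
  if (is.null(dim(B))) B <- matrix(B, nrow = nrow(x))
  co <- fit$coef
  co[is.na(co)] <- 0
  drop(B %*% co)
}

# ---- kNN (FNN) --------------------------------------------------------------

fit_knn <- function(x, y, k) {
  sc <- scale_fit(x)
  list(x = scale_apply(x, sc), y = y, k = min(k, nrow(x)), sc = sc)
}

predict_knn <- function(fit, x) {
  FNN::knn.reg(train = fit$x, test = scale_apply(x, fit$sc), y = fit$y,
               k = fit$k)$pred
}

# ---- epsilon-SVR with RBF kernel (dual QP via quadprog) --------------------

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

fit_svr <- function(x, y, cost, epsilon = 0.1, gamma = NULL) {
  sc <- scale_fit(x)
  xs <- scale_apply(x, sc)
  ym <- mean(y); ysd <- stats::sd(y); if (!is.finite(ysd) || ysd == 0) ysd <- 1
  ys <- (y - ym) / ysd
  n <- nrow(xs)
  if (is.null(gamma)) gamma <- 1 / ncol(xs)     # "scale" on standardized inputs
  K <- rbf_kernel(xs, xs, gamma)
  D <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-7, 2 * n)
  d <- c(ys - epsilon, -ys - epsilon)
  A <- cbind(c(rep(1, n), rep(-1, n)), diag(2 * n), -diag(2 * n))
  b0 <- c(0, rep(0, 2 * n), rep(-cost, 2 * n))
  sol <- quadprog::solve.QP(D, d, A, b0, meq = 1)
  a <- sol$solution
  beta <- a[1:n] - a[(n + 1):(2 * n)]
  fx <- drop(K %*% beta)
  on_margin <- which(a[1:n] > 1e-6 & a[1:n] < cost - 1e-6)
  on_margin_star <- which(a[(n + 1):(2 * n)] > 1e-6 & a[(n + 1):(2 * n)] < cost - 1e-6)
  b <- if (length(on_margin) + length(on_margin_star) > 0) {
    mean(c(ys[on_margin] - fx[on_margin] - epsilon,
           ys[on_margin_star] - fx[on_margin_star] + epsilon))
  } else {
    mean(ys - fx)
  }
  sv <- which(abs(beta) > 1e-8)
  list(sc = sc, ym = ym, ysd = ysd, gamma = gamma, b = b,
       sv = xs[sv, , drop = FALSE], beta = beta[sv])
}

predict_svr <- function(fit, x) {
  xs <- scale_apply(x, fit$sc)
  f <- if (length(fit$beta) == 0) rep(0, nrow(xs)) else
    drop(rbf_kernel(xs, fit$sv, fit$gamma) %*% fit$beta)
  (f + fit$b) * fit$ysd + fit$ym
}

# ---- single-hidden-layer network (BFGS + weight decay) ----------------------

fit_ann <- function(x, y, size, decay, maxit = 300L) {
  sc <- scale_fit(x)
  xs <- cbind(1, scale_apply(x, sc))
  ym <- mean(y); ysd <- stats::sd(y); if (!is.finite(ysd) || ysd == 0) ysd <- 1
  ys <- (y - ym) / ysd
  p1 <- ncol(xs); h <- size
  n_w1 <- p1 * h
  unpack <- function(w) list(W1 = matrix(w[seq_len(n_w1)], p1, h),
                             W2 = w[n_w1 + seq_len(h)],
                             b2 = w[n_w1 + h + 1L])
  sigmoid <- function(z) 1 / (1 + exp(-z))
  fwd <- function(w) {
    pw <- unpack(w)
    H <- sigmoid(xs %*% pw$W1)
    list(H = H, pred = drop(H %*% pw$W2) + pw$b2, pw = pw)
  }
  obj <- function(w) {
    fw <- fwd(w)
    sum((fw$pred - ys)^2) + decay * sum(w^2)
  }
  grad <- function(w) {
    fw <- fwd(w)
    e <- 2 * (fw$pred - ys)
    gW2 <- drop(crossprod(fw$H, e))
    gb2 <- sum(e)
    dH <- tcrossprod(e, fw$pw$W2) * fw$H * (1 - fw$H)
    gW1 <- crossprod(xs, dH)
    c(as.numeric(gW1), gW2, gb2) + 2 * decay * w
  }
  w0 <- stats::runif(n_w1 + h + 1L, -0.5, 0.5)
  opt <- stats::optim(w0, obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-9))
  list(sc = sc, ym = ym, ysd = ysd, w = opt$par, size = h, unpack = unpack)
}

predict_ann <- function(fit, x) {
  xs <- cbind(1, scale_apply(x, fit$sc))
  pw <- fit$unpack(fit$w)
  H <- 1 / (1 + exp(-(xs %*% pw$W1)))
  (drop(H %*% pw$W2) + pw$b2) * fit$ysd + fit$ym
}

# ---- importances ------------------------------------------------------------

# raw (unnormalized) per-predictor importance for a fitted learner
learner_importance <- function(model, x, y) {
  alg <- model$algorithm
  p <- ncol(x)
  imp <- if (alg %in% c("RF", "GBT")) {
    model$fit$importance
  } else if (alg %in% c("PLS", "ElasticNet")) {
    beta <- if (alg == "PLS") {
      model$fit$beta                       # already on standardized scale
    } else {
      drop(stats::coef(model$fit$model, s = model$fit$lambda))[-1]
    }
    abs(beta)
  } else {
    # permutation importance on the training data (5 shuffles)
    base <- rmse(y, predict(model, as.data.frame(x)))
    vapply(seq_len(p), function(j) {
      mean(vapply(1:5, function(r) {
        xp <- x
        xp[, j] <- xp[sample.int(nrow(x)), j]
        rmse(y, predict(model, as.data.frame(xp))) - base
      }, numeric(1)))
    }, numeric(1))
  }
  imp <- pmax(as.numeric(imp), 0)
  names(imp) <- colnames(x)
  imp
}

# scale so the strongest predictor scores 100
normalize_importance <- function(imp) {
  m <- max(imp)
  if (!is.finite(m) || m <= 0) return(imp * 0)
  imp / m * 100
}
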