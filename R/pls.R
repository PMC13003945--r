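# Partial least squares machinery: standardization, collinearity filters,
# NIPALS fit, cross-validated component selection, VIP, report helpers.

#' Column-wise z-score standardization
#'
#' Centres and scales every column to mean 0, SD 1 (n - 1 denominator) and
#' stores the transform so it can be inverted.
#'
#' @param table data.frame or matrix of numeric columns.
#' @return list `scaled` (matrix), `center`, `scale`; class `zscore_transform`.
#' @export
zscore_columns <- function(table) {
  X <- as.matrix(table)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  zero <- sdv <= .Machine$double.eps^0.5 * pmax(1, abs(mu))
  if (any(zero))
    stop("zero-variance column(s): ",
         paste(colnames(X)[zero], collapse = ", "))
  structure(list(scaled = sweep(sweep(X, 2, mu), 2, sdv, "/"),
                 center = mu, scale = sdv),
            class = "zscore_transform")
}

#' Invert a z-score transform
#' @param z a `zscore_transform`.
#' @param scaled optionally a matrix in standardized space (defaults to the
#'   stored one).
#' @return matrix on the original scale.
#' @export
zscore_invert <- function(z, scaled = z$scaled) {
  sweep(sweep(scaled, 2, z$scale, "*"), 2, z$center, "+")
}

#' Pairwise-correlation redundancy filter
#'
#' Iteratively finds the pair of retained predictors with the largest |r|;
#' while it exceeds the threshold, drops the member with the larger mean
#' absolute correlation with all other retained predictors (ties broken by
#' column order), then repeats. Deterministic by construction.
#'
#' @param X standardized predictor matrix with column names.
#' @param threshold absolute-correlation threshold (default 0.95).
#' @return `filter_report` list: `removed` (data.frame name/partner/r/
#'   mean_abs_r), `retained` (names).
#' @export
correlation_filter <- function(X, threshold = 0.95) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- colnames(X)
  removed <- data.frame(name = character(), partner = character(),
                        r = numeric(), mean_abs_r = numeric())
  repeat {
    if (length(keep) < 2) break
    C <- abs(stats::cor(X[, keep, drop = FALSE]))
    diag(C) <- 0
    mx <- max(C)
    if (mx <= threshold) break
    idx <- which(C == mx, arr.ind = TRUE)[1, ]
    pair <- keep[sort(idx)]
    mean_r <- vapply(pair, function(v) {
      others <- setdiff(keep, v)
      mean(abs(stats::cor(X[, v], X[, others, drop = FALSE])))
    }, numeric(1))
    drop_v <- pair[which.max(mean_r)]   # ties: which.max takes the first
    removed <- rbind(removed, data.frame(
      name = drop_v, partner = setdiff(pair, drop_v)[1],
      r = mx, mean_abs_r = max(mean_r)))
    keep <- setdiff(keep, drop_v)
  }
  structure(list(removed = removed, retained = keep,
                 rule = "correlation", threshold = threshold),
            class = "filter_report")
}

# VIF of every column: 1 / (1 - R^2 of column j on the others).
compute_vifs <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X); n <- nrow(X)
  vapply(seq_len(p), function(j) {
    y <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(Z, y)
    if (fit$df.residual <= 0) return(Inf)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Variance-inflation-factor filter
#'
#' Iteratively removes the predictor with the largest VIF until all VIFs are
#' at or below the threshold. Perfectly collinear columns get VIF = Inf and
#' are removed first.
#'
#' @param X standardized predictor matrix.
#' @param threshold VIF threshold (default 10).
#' @return `filter_report` list (`removed` with `vif` values, `retained`).
#' @export
vif_filter <- function(X, threshold = 10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- colnames(X)
  removed <- data.frame(name = character(), vif = numeric())
  repeat {
    if (length(keep) < 2) break
    v <- compute_vifs(X[, keep, drop = FALSE])
    if (max(v) <= threshold) break
    j <- which.max(v)
    removed <- rbind(removed, data.frame(name = keep[j], vif = v[j]))
    keep <- keep[-j]
  }
  structure(list(removed = removed, retained = keep,
                 rule = "vif", threshold = threshold),
            class = "filter_report")
}

#' Fit a PLS regression by NIPALS
#'
#' Single-response NIPALS with X- and y-deflation. Components maximize the
#' covariance between X scores and the response. Inputs are standardized
#' internally unless `scale = FALSE`.
#'
#' @param X predictor matrix (rows = observations).
#' @param y numeric response.
#' @param n_components number of latent variables; must not exceed rank(X).
#' @param scale z-score X and y first (default TRUE).
#' @return `pls_model` list with `weights` (p x a, unit norm per component),
#'   `loadings`, `scores` (n x a), `y_loadings` (q), `coefficients`
#'   (standardized-space regression vector), `r2y_cum` (% per component),
#'   `ss_comp` (y variance explained per component), `fitted`, plus the
#'   scaling info.
#' @export
fit_pls <- function(X, y, n_components, scale = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (scale) {
    zx <- zscore_columns(X); zy <- zscore_columns(matrix(y, ncol = 1))
    Xs <- zx$scaled; ys <- zy$scaled[, 1]
  } else {
    zx <- zy <- NULL; Xs <- X; ys <- as.numeric(y)
  }
  rk <- qr(Xs)$rank
  if (n_components > rk)
    stop("n_components (", n_components, ") exceeds rank(X) = ", rk)
  n <- nrow(Xs); p <- ncol(Xs)
  Xd <- Xs; yd <- ys
  Wm <- matrix(0, p, n_components); Pm <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components); qv <- numeric(n_components)
  ss0 <- sum(ys^2)
  ss_comp <- numeric(n_components)
  for (a in seq_len(n_components)) {
    w <- crossprod(Xd, yd)
    w <- w / sqrt(sum(w^2))
    t <- Xd %*% w
    tt <- sum(t^2)
    pvec <- crossprod(Xd, t) / tt
    q <- sum(yd * t) / tt
    Xd <- Xd - t %*% t(pvec)
    ss_before <- sum(yd^2)
    yd <- yd - q * t
    ss_comp[a] <- ss_before - sum(yd^2)
    Wm[, a] <- w; Pm[, a] <- pvec; Tm[, a] <- t; qv[a] <- q
  }
  r2y_cum <- cumsum(ss_comp) / ss0 * 100
  # regression vector in standardized space: B = W (P'W)^-1 q
  Wstar <- Wm %*% solve(crossprod(Pm, Wm))
  beta <- Wstar %*% qv
  fitted_s <- Xs %*% beta
  structure(list(
    n_components = n_components, weights = Wm, loadings = Pm,
    scores = Tm, y_loadings = qv, wstar = Wstar,
    coefficients = beta[, 1], r2y_cum = r2y_cum, ss_comp = ss_comp,
    fitted_scaled = fitted_s[, 1],
    var_names = colnames(X), zx = zx, zy = zy,
    y_scaled = ys
  ), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model: %d components, %d predictors, R2Y = %.1f%%>\n",
              x$n_components, length(x$var_names),
              x$r2y_cum[x$n_components]))
  invisible(x)
}

#' Predict from a PLS model
#' @param object a `pls_model`.
#' @param newdata predictor matrix on the original scale.
#' @param ... unused.
#' @return predicted response on the original scale.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  Xn <- as.matrix(newdata)[, object$var_names, drop = FALSE]
  if (!is.null(object$zx)) {
    Xn <- sweep(sweep(Xn, 2, object$zx$center), 2, object$zx$scale, "/")
    ys <- Xn %*% object$coefficients
    ys * object$zy$scale + object$zy$center
  } else {
    (Xn %*% object$coefficients)[, 1]
  }
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a(SS_a (w_ja / ||w_a||)^2) / sum_a(SS_a))`, where
#' `SS_a` is the response variance explained by component a. Satisfies
#' `mean(VIP^2) = 1` for any fitted model.
#'
#' @param model a `pls_model`.
#' @return named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  if (sum(model$ss_comp) <= 0) stop("model explains no response variance")
  p <- nrow(model$weights)
  wnorm2 <- colSums(model$weights^2)       # = 1 by construction
  contrib <- sweep(model$weights^2, 2, model$ss_comp / wnorm2, "*")
  vip <- sqrt(p * rowSums(contrib) / sum(model$ss_comp))
  stats::setNames(vip, model$var_names)
}

#' Assign each predictor to the component where its weight peaks
#'
#' Produces the per-component report layout: every retained predictor is
#' assigned to the component with its maximal |weight|; rows are sorted by
#' component, then descending VIP; VIP > 1 flagged.
#'
#' @param model a `pls_model`.
#' @param weight_type `"w"` (per-component X-weights, default) or `"wstar"`
#'   (transformed weights).
#' @return data.frame `variable`, `component`, `vip`, `weight`, `important`.
#' @export
assign_variables_to_components <- function(model, weight_type = c("w", "wstar")) {
  weight_type <- match.arg(weight_type)
  W <- if (weight_type == "w") model$weights else model$wstar
  vip <- vip_scores(model)
  comp <- apply(abs(W), 1, which.max)
  weight <- W[cbind(seq_len(nrow(W)), comp)]
  out <- data.frame(variable = model$var_names, component = comp,
                    vip = as.numeric(vip), weight = weight,
                    important = as.numeric(vip) > 1)
  out[order(out$component, -out$vip), , drop = FALSE]
}

#' Cross-validated component selection
#'
#' K-fold cross-validation of the PLS model over component counts
#' 1..`max_components`: per fold, standardization (and, in leak-free mode,
#' both collinearity filters) are refit on the training folds only;
#' `RMSECV = sqrt(PRESS / n)` in standardized-response units and
#' `Q2 = 1 - PRESS / TSS` are reported per component count. The selected
#' count minimizes RMSECV.
#'
#' @param X predictor matrix (original scale).
#' @param y response (original scale).
#' @param k number of folds (default 10).
#' @param max_components largest component count to evaluate.
#' @param seed integer seed for the fold shuffle.
#' @param refit_filters re-apply correlation and VIF filters inside each
#'   training fold (leak-free). With FALSE (paper-faithful mode) `X` is used
#'   as supplied, filters having been applied once globally beforehand.
#' @param cor_threshold,vif_threshold filter thresholds for leak-free mode.
#' @return list `rmsecv`, `q2` (per component count), `selected`, `folds`.
#' @export
cross_validate_components <- function(X, y, k = 10, max_components = 6,
                                      seed = 1L, refit_filters = FALSE,
                                      cor_threshold = 0.95,
                                      vif_threshold = 10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  if (k > n) stop("k must not exceed the number of observations")
  set.seed(as.integer(seed))
  fold <- sample(rep(seq_len(k), length.out = n))
  press <- numeric(max_components)
  # standardized-y TSS computed per held-out fold against the training mean
  y_sd_all <- stats::sd(y)
  tss <- 0
  pred_err <- matrix(0, n, max_components)
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    if (refit_filters) {
      zs <- zscore_columns(Xtr)
      cf <- correlation_filter(zs$scaled, cor_threshold)
      vf <- vif_filter(zs$scaled[, cf$retained, drop = FALSE], vif_threshold)
      keep <- vf$retained
    } else keep <- colnames(X)
    mc <- min(max_components, qr(scale(Xtr[, keep, drop = FALSE]))$rank)
    fit <- fit_pls(Xtr[, keep, drop = FALSE], ytr, mc)
    # per-component predictions on the held-out fold, standardized-y units
    Xte <- sweep(sweep(X[te, keep, drop = FALSE], 2, fit$zx$center),
                 2, fit$zx$scale, "/")
    yte_s <- (y[te] - fit$zy$center) / fit$zy$scale
    tss <- tss + sum(yte_s^2)
    for (a in seq_len(max_components)) {
      aa <- min(a, mc)
      beta_a <- fit$wstar[, seq_len(aa), drop = FALSE] %*%
        fit$y_loadings[seq_len(aa)]
      pred <- Xte %*% beta_a
      pred_err[te, a] <- yte_s - pred
    }
  }
  press <- colSums(pred_err^2)
  rmsecv <- sqrt(press / n)
  q2 <- 1 - press / tss
  list(rmsecv = rmsecv, q2 = q2, selected = which.min(rmsecv),
       folds = fold, press = press)
}

#' F-test p-value of the latent-variable regression
#'
#' Approximates the PLS model by an ordinary multiple regression of the
#' response on the first `c` score vectors and returns the overall F-test
#' p-value (df1 = c, df2 = n - c - 1), for each component count requested.
#'
#' @param model a `pls_model` (scores from the full-data fit).
#' @param n_components component counts to test (default all fitted).
#' @return named numeric vector of p-values.
#' @export
model_p_value <- function(model, n_components = seq_len(model$n_components)) {
  y <- model$y_scaled
  n <- length(y)
  vapply(n_components, function(cc) {
    if (n - cc - 1 <= 0) stop("no residual degrees of freedom (c = ", cc, ")")
    Tm <- model$scores[, seq_len(cc), drop = FALSE]
    fit <- stats::lm.fit(cbind(1, Tm), y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    fstat <- ((tss - rss) / cc) / (rss / (n - cc - 1))
    stats::pf(fstat, cc, n - cc - 1, lower.tail = FALSE)
  }, numeric(1)) -> p
  stats::setNames(p, paste0("c", n_components))
}

#' A-priori sample size for the R2-deviation-from-zero F test
#'
#' Smallest N such that the noncentral-F power of the test of R2 = 0 in a
#' multiple regression with `n_predictors` predictors reaches the target
#' power, with noncentrality `lambda = f2 * N` (the G*Power convention),
#' df1 = `n_predictors`, df2 = `N - n_predictors - 1`.
#'
#' @param f2 Cohen's effect size f^2 (> 0).
#' @param alpha significance level.
#' @param power target power.
#' @param n_predictors number of predictors.
#' @param n_max search bound.
#' @return required sample size N (integer).
#' @export
required_sample_size <- function(f2, alpha = 0.05, power = 0.80,
                                 n_predictors = 4, n_max = 100000) {
  if (f2 <= 0) stop("f2 must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)")
  for (N in (n_predictors + 2):n_max) {
    df2 <- N - n_predictors - 1
    crit <- stats::qf(1 - alpha, n_predictors, df2)
    pw <- stats::pf(crit, n_predictors, df2, ncp = f2 * N, lower.tail = FALSE)
    if (pw >= power) return(N)
  }
  stop("target power unreachable within n_max observations")
}
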