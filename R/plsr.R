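#' Partial least squares regression of allele frequencies on environment
#'
#' Fits a PLS regression by sequential extraction of components: at each
#' step the weight vector is the leading left singular vector of the
#' deflated cross-product `X'Y` (for a single response this reduces to the
#' normalised covariance vector), the X-score is `t = X w`, and `X` is
#' deflated by the rank-one approximation `t p'` (`Y` by `t q'`).
#' Predictors and responses are centred and scaled to unit variance by
#' default.  Signs are fixed so that the largest-magnitude entry of each
#' weight vector is positive, making the fit deterministic.
#'
#' With `ncomp = rank(X)` the fitted values equal ordinary least squares.
#'
#' @param x predictor matrix (breeds x environmental variables).
#' @param y response matrix or vector (breeds x allele frequencies).
#' @param ncomp number of components to extract.
#' @param scale scale columns to unit variance.
#' @param center centre columns (disable only when the data are already
#'   centred, e.g. inside cross-validation with fixed scaling).
#' @return an object of class `plsr_gea` with components `weights` (p x A),
#'   `x_loadings`, `y_loadings` (q x A), `scores` (n x A), `coefficients`
#'   (p x q, scaled scale), `R2` (per response), `ssy_comp` (per-component
#'   explained-Y sums of squares, used by VIP), `x_center`, `x_scale`,
#'   `y_center`, `y_scale`, `fitted.values`, `residuals` (raw scale) and
#'   the call.
#' @seealso [press_q2()], [vip_vt2()], [eliminate_variables()],
#'   [select_n_components()]
#' @export
plsr_fit <- function(x, y, ncomp = 2, scale = TRUE, center = TRUE) {
  cl <- match.call()
  x <- as.matrix(x); y <- as.matrix(y)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  n <- nrow(x)
  if (nrow(y) != n) stop("x and y row counts differ")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (is.null(colnames(y))) colnames(y) <- paste0("y", seq_len(ncol(y)))
  xc <- stats::setNames(if (center) colMeans(x) else numeric(ncol(x)),
                        colnames(x))
  xs <- stats::setNames(if (scale) apply(x, 2, stats::sd) else
    rep(1, ncol(x)), colnames(x))
  drop_const <- xs == 0
  if (any(drop_const)) {
    warning("dropping constant predictor(s): ",
            paste(colnames(x)[drop_const], collapse = ", "))
    x <- x[, !drop_const, drop = FALSE]
    xc <- xc[!drop_const]; xs <- xs[!drop_const]
  }
  yc <- if (center) colMeans(y) else rep(0, ncol(y))
  ys <- if (scale) apply(y, 2, stats::sd) else rep(1, ncol(y))
  if (any(ys == 0)) stop("constant response")
  X <- sweep(sweep(x, 2, xc), 2, xs, "/")
  Y <- sweep(sweep(y, 2, yc), 2, ys, "/")
  p <- ncol(X); q <- ncol(Y)
  A <- min(ncomp, n - 1, p)
  W <- P <- matrix(0, p, A); Q <- matrix(0, q, A); TT <- matrix(0, n, A)
  ssy <- numeric(A)
  Xd <- X; Yd <- Y
  a <- 0
  for (k in seq_len(A)) {
    cp <- crossprod(Xd, Yd)
    sv <- svd(cp, nu = 1, nv = 0)
    if (sv$d[1] < 1e-12) break
    w <- sv$u[, 1]
    imax <- which.max(abs(w))
    if (w[imax] < 0) w <- -w
    tt <- drop(Xd %*% w)
    t2 <- sum(tt^2)
    if (t2 < 1e-12) break
    pl <- drop(crossprod(Xd, tt)) / t2
    ql <- drop(crossprod(Yd, tt)) / t2
    Xd <- Xd - tcrossprod(tt, pl)
    Yd <- Yd - tcrossprod(tt, ql)
    a <- a + 1
    W[, a] <- w; P[, a] <- pl; Q[, a] <- ql; TT[, a] <- tt
    ssy[a] <- sum(ql^2) * t2
  }
  if (a == 0) stop("no component could be extracted (X'Y is null)")
  W <- W[, 1:a, drop = FALSE]; P <- P[, 1:a, drop = FALSE]
  Q <- Q[, 1:a, drop = FALSE]; TT <- TT[, 1:a, drop = FALSE]
  ssy <- ssy[1:a]
  B <- W %*% solve(crossprod(P, W), t(Q))
  dimnames(B) <- list(colnames(x), colnames(y))
  fitted_s <- X %*% B
  fitted <- sweep(sweep(fitted_s, 2, ys, "*"), 2, yc, "+")
  res <- y - fitted
  r2 <- 1 - colSums((Y - fitted_s)^2) / colSums(Y^2)
  structure(list(
    weights = W, x_loadings = P, y_loadings = Q, scores = TT,
    coefficients = B, R2 = stats::setNames(r2, colnames(y)),
    ssy_comp = ssy, ncomp = a,
    x_center = xc, x_scale = xs, y_center = yc, y_scale = ys,
    fitted.values = fitted, residuals = res,
    x = x, y = y, scaled = scale, call = cl), class = "plsr_gea")
}

#' @export
print.plsr_gea <- function(x, ...) {
  cat("PLS regression:", nrow(x$x), "observations,",
      ncol(x$x), "predictors,", ncol(x$y), "response(s),",
      x$ncomp, "component(s)\n")
  cat("R2 per response:\n")
  print(round(x$R2, 3))
  invisible(x)
}

#' @export
summary.plsr_gea <- function(object, ...) {
  v <- vip_vt2(object)
  xvar <- colSums(object$x_loadings^2 * colSums(object$scores^2)) /
    sum(scale(object$x, scale = object$scaled)^2)
  out <- list(model = object, vip = v,
              x_var_explained = cumsum(xvar))
  class(out) <- "summary.plsr_gea"
  out
}

#' @export
print.summary.plsr_gea <- function(x, ...) {
  print(x$model)
  cat("\nCumulative X-variance explained by components:\n")
  print(round(x$x_var_explained, 4))
  cat("\nPer-predictor importance (VIP) and top-two-component variance (VT2, %):\n")
  print(cbind(VIP = round(x$vip$VIP, 3), VT2 = round(x$vip$VT2, 2)))
  invisible(x)
}

#' @export
coef.plsr_gea <- function(object, raw = FALSE, ...) {
  if (!raw) return(object$coefficients)
  # back-transformed to the raw scale, with intercept
  B <- sweep(object$coefficients, 1, object$x_scale, "/")
  B <- sweep(B, 2, object$y_scale, "*")
  icpt <- object$y_center - drop(object$x_center %*% B)
  rbind(`(Intercept)` = icpt, B)
}

#' @export
predict.plsr_gea <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)))
    newdata <- newdata[, names(object$x_center), drop = FALSE]
  else if (ncol(newdata) != length(object$x_center))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$x_center))
  Xs <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, "/")
  fs <- Xs %*% object$coefficients
  sweep(sweep(fs, 2, object$y_scale, "*"), 2, object$y_center, "+")
}

#' @export
residuals.plsr_gea <- function(object, ...) object$residuals

#' @export
fitted.plsr_gea <- function(object, ...) object$fitted.values

#' @export
plot.plsr_gea <- function(x, response = 1, ...) {
  b <- x$coefficients[, response]
  graphics::barplot(b, las = 2, ylab = "scaled coefficient",
                    main = colnames(x$y)[response], ...)
  invisible(x)
}

#' Leave-one-out PRESS, Q2 and R2
#'
#' For each left-out row the model (and, by default, the centring/scaling)
#' is refit on the remaining rows and the held-out response predicted.
#' `PRESS` is the sum of squared prediction errors on the scaled response
#' (scaling taken from the full data so folds are comparable) and
#' `Q2 = 1 - PRESS / SSY` per response, with `SSY` the corrected sum of
#' squares of the scaled response.  `R2` comes from the full-data fit.
#'
#' Responses can be cross-validated jointly (one multi-response model, the
#' components shared) or per response (independent single-response fits,
#' the default, matching per-polymorphism modelling).
#'
#' @param x,y as in [plsr_fit()].
#' @param ncomp components.
#' @param fit `"per-response"` or `"joint"`.
#' @param refit_scaling recompute centring/scaling inside each fold
#'   (default TRUE).
#' @return list with `PRESS` (per response, scaled scale), `Q2`, `R2`,
#'   `press_total`, and `loo_residuals` (n x q matrix, raw scale).
#' @export
press_q2 <- function(x, y, ncomp, fit = c("per-response", "joint"),
                     refit_scaling = TRUE) {
  fit <- match.arg(fit)
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 rows for cross-validation")
  if (fit == "per-response" && ncol(y) > 1) {
    parts <- lapply(seq_len(ncol(y)), function(j)
      press_q2(x, y[, j, drop = FALSE], ncomp, fit = "joint",
               refit_scaling = refit_scaling))
    loo <- do.call(cbind, lapply(parts, `[[`, "loo_residuals"))
    colnames(loo) <- colnames(y)
    return(list(PRESS = stats::setNames(vapply(parts, `[[`, 0, "PRESS"), colnames(y)),
                Q2 = stats::setNames(vapply(parts, `[[`, 0, "Q2"), colnames(y)),
                R2 = stats::setNames(vapply(parts, `[[`, 0, "R2"), colnames(y)),
                press_total = sum(vapply(parts, `[[`, 0, "press_total")),
                loo_residuals = loo))
  }
  full <- plsr_fit(x, y, ncomp)
  loo <- matrix(NA_real_, n, ncol(y), dimnames = list(rownames(x), colnames(y)))
  for (i in seq_len(n)) {
    if (refit_scaling) {
      m <- plsr_fit(x[-i, , drop = FALSE], y[-i, , drop = FALSE], ncomp)
      pred <- predict(m, x[i, , drop = FALSE])
    } else {
      Xs <- sweep(sweep(x, 2, full$x_center), 2, full$x_scale, "/")
      Ys <- sweep(sweep(y, 2, full$y_center), 2, full$y_scale, "/")
      m <- plsr_fit(Xs[-i, , drop = FALSE], Ys[-i, , drop = FALSE],
                    ncomp, scale = FALSE, center = FALSE)
      ps <- predict(m, Xs[i, , drop = FALSE])
      pred <- sweep(sweep(ps, 2, full$y_scale, "*"), 2, full$y_center, "+")
    }
    loo[i, ] <- y[i, ] - pred
  }
  ssy <- colSums(sweep(y, 2, colMeans(y))^2)
  press_scaled <- colSums(loo^2) / full$y_scale^2
  q2 <- 1 - colSums(loo^2) / ssy
  list(PRESS = if (ncol(y) == 1) unname(sum(press_scaled)) else press_scaled,
       Q2 = if (ncol(y) == 1) unname(q2) else q2,
       R2 = if (ncol(y) == 1) unname(full$R2) else full$R2,
       press_total = sum(press_scaled),
       loo_residuals = loo)
}

#' van der Voet randomization test for comparing model PRESS
#'
#' Tests whether two models' squared leave-one-out prediction residuals
#' differ beyond chance, by sign-flipping the paired differences
#' `d_i = e_Ai^2 - e_Bi^2`.  Exhaustive enumeration over all `2^n` sign
#' patterns when `n <= exact_max`, Monte Carlo otherwise.
#'
#' @param res_a,res_b numeric vectors (or matrices, summed over responses
#'   row-wise) of LOO residuals from the two models on identical rows.
#' @param n_draws Monte-Carlo draws when enumeration is infeasible.
#' @param exact_max enumeration threshold.
#' @return list `p`, `statistic` (observed mean difference), `method`.
#' @export
van_der_voet_test <- function(res_a, res_b, n_draws = 2000, exact_max = 12) {
  d <- rowSums(as.matrix(res_a)^2) - rowSums(as.matrix(res_b)^2)
  n <- length(d)
  t_obs <- abs(mean(d))
  if (t_obs < 1e-300) return(list(p = 1, statistic = 0, method = "degenerate"))
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    t_perm <- abs(signs %*% d) / n
    p <- mean(t_perm >= t_obs - 1e-12)
    return(list(p = p, statistic = mean(d), method = "exact"))
  }
  flips <- matrix(sample(c(-1, 1), n * n_draws, replace = TRUE), n_draws, n)
  t_perm <- abs(flips %*% d) / n
  p <- (1 + sum(t_perm >= t_obs - 1e-12)) / (1 + n_draws)
  list(p = p, statistic = mean(d), method = "randomization")
}

#' Choose the number of PLS components
#'
#' The candidate with minimum total PRESS is found; the chosen model is the
#' one with fewest components whose LOO residuals are not significantly
#' larger than the minimum-PRESS model's (van der Voet test, p above
#' `p_threshold`).
#'
#' @param x,y data.
#' @param max_a largest candidate.
#' @param p_threshold indistinguishability threshold (default 0.1).
#' @param fit passed to [press_q2()].
#' @return list `ncomp` (chosen), `ncomp_min_press`, `press` (per
#'   candidate), `p_values` (vs the minimum-PRESS model).
#' @export
select_n_components <- function(x, y, max_a, p_threshold = 0.1,
                                fit = "per-response") {
  cvs <- lapply(seq_len(max_a), function(a) press_q2(x, y, a, fit = fit))
  press <- vapply(cvs, `[[`, 0, "press_total")
  a_star <- which.min(press)
  pv <- vapply(seq_len(max_a), function(a)
    van_der_voet_test(cvs[[a]]$loo_residuals,
                      cvs[[a_star]]$loo_residuals)$p, 0)
  chosen <- min(which(pv > p_threshold))
  list(ncomp = chosen, ncomp_min_press = a_star,
       press = press, p_values = pv)
}

#' Variable importance in projection and top-two-component variance
#'
#' `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)` where `SSY_a` is
#' the Y-variance captured by component `a`; squared VIPs average to 1 over
#' predictors.  `VT2_j` is the percentage of predictor `j`'s (scaled)
#' variance reconstructed by the first two components, a check that a
#' seemingly important predictor is actually represented in the dominant
#' structure.
#'
#' @param model a fitted `plsr_gea`.
#' @return data frame `predictor`, `VIP`, `VT2`, row per predictor.
#' @export
vip_vt2 <- function(model) {
  W <- model$weights; ssy <- model$ssy_comp
  p <- nrow(W)
  vip <- sqrt(p * colSums(t(W^2) * ssy) / sum(ssy))
  if (model$ncomp < 2)
    warning("VT2 computed on fewer than 2 components")
  a2 <- seq_len(min(2, model$ncomp))
  t2 <- colSums(model$scores^2)[a2]
  expl <- model$x_loadings[, a2, drop = FALSE]^2 %*% t2
  Xs <- sweep(sweep(model$x, 2, model$x_center), 2, model$x_scale, "/")
  vt2 <- 100 * drop(expl) / colSums(Xs^2)
  data.frame(predictor = colnames(model$x), VIP = unname(vip),
             VT2 = unname(vt2), row.names = colnames(model$x))
}

#' Uninformative-variable elimination by VIP and VT2
#'
#' Drops predictors failing `VIP > vip_threshold` or `VT2 >=
#' vt2_threshold`, refits, and reports PRESS for the full and reduced
#' models; elimination is judged useful when the reduced PRESS is smaller.
#'
#' @param x,y data.
#' @param ncomp components used for both fits and cross-validation.
#' @param vip_threshold retain predictors with VIP strictly above this
#'   (default 0.83).
#' @param vt2_threshold retain predictors with VT2 at least this percent
#'   (default 40).
#' @param fit passed to [press_q2()].
#' @return list `retained`, `dropped`, `press_full`, `press_reduced`
#'   (totals on the scaled scale), `root_mean_press_full/_reduced`
#'   (`sqrt(PRESS / (n q))`, the scale cross-validation summaries are
#'   conventionally printed on), `improved`, `vip_vt2` (full-model table),
#'   `model` (reduced fit).
#' @export
eliminate_variables <- function(x, y, ncomp, vip_threshold = 0.83,
                                vt2_threshold = 40, fit = "per-response") {
  x <- as.matrix(x)
  full <- plsr_fit(x, y, ncomp)
  v <- vip_vt2(full)
  keep <- v$VIP > vip_threshold & v$VT2 >= vt2_threshold
  if (!any(keep)) stop("all predictors eliminated")
  cv_full <- press_q2(x, y, ncomp, fit = fit)
  xr <- x[, keep, drop = FALSE]
  cv_red <- press_q2(xr, y, ncomp, fit = fit)
  nq <- nrow(x) * ncol(as.matrix(y))
  list(retained = v$predictor[keep], dropped = v$predictor[!keep],
       press_full = cv_full$press_total, press_reduced = cv_red$press_total,
       root_mean_press_full = sqrt(cv_full$press_total / nq),
       root_mean_press_reduced = sqrt(cv_red$press_total / nq),
       improved = cv_red$press_total < cv_full$press_total,
       vip_vt2 = v, model = plsr_fit(xr, y, ncomp))
}

#' Regression coefficients on the centred/scaled scale
#' @param model fitted `plsr_gea`.
#' @return predictors x responses coefficient matrix.
#' @export
scaled_coefficients <- function(model) model$coefficients
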