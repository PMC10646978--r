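# Exact Gaussian-process regression surrogates.
#
# One isotropic squared-exponential (RBF) GP per functional goal maps latent
# coordinates to the signed log2 fold-change target.  Targets are
# standardized internally per fit; hyperparameters (signal variance, length
# scale, noise variance) are obtained either by marginal-likelihood
# maximization with seeded multi-restart L-BFGS or by a fast median-distance
# heuristic used at campaign scale.

.sq_dist <- function(A, B) {
  # squared euclidean distances between rows of A (n x d) and B (m x d)
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- -2 * tcrossprod(A, B)
  d2 <- d2 + an                      # recycles down columns
  d2 <- d2 + rep(bn, each = nrow(d2))
  d2[d2 < 0] <- 0
  d2
}

.rbf <- function(D2, sf2, ell) sf2 * exp(-0.5 * D2 / ell^2)

.chol_jitter <- function(K, jitter = 1e-8, max_tries = 6L) {
  n <- nrow(K)
  for (t in seq_len(max_tries)) {
    L <- tryCatch(t(chol(K + diag(jitter, n))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = jitter))
    jitter <- jitter * 100
  }
  stop("numerical error: kernel matrix not positive definite ",
       "(condition estimate ", format(kappa(K)), ")")
}

.heuristic_hyper <- function(X, y) {
  n <- nrow(X)
  idx <- if (n > 500L) sample.int(n, 500L) else seq_len(n)
  d2 <- .sq_dist(X[idx, , drop = FALSE], X[idx, , drop = FALSE])
  med <- stats::median(sqrt(d2[upper.tri(d2)]))
  if (!is.finite(med) || med <= 0) med <- 1
  c(sf2 = 1, ell = med, sn2 = 0.1)
}

.nlml <- function(theta, D2, y) {
  # theta = log(sf2, ell, sn2); y standardized
  sf2 <- exp(theta[1]); ell <- exp(theta[2]); sn2 <- exp(theta[3])
  n <- length(y)
  Kf <- .rbf(D2, sf2, ell)
  K <- Kf + diag(sn2 + 1e-10, n)
  ch <- tryCatch(t(chol(K)), error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e10, grad = rep(0, 3)))
  a <- backsolve(t(ch), forwardsolve(ch, y))
  val <- 0.5 * sum(y * a) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(t(ch))
  W <- Kinv - tcrossprod(a)
  g1 <- 0.5 * sum(W * Kf)                       # d/d log sf2
  g2 <- 0.5 * sum(W * (Kf * D2 / ell^2))        # d/d log ell
  g3 <- 0.5 * sum(diag(W)) * sn2                # d/d log sn2
  list(value = val, grad = c(g1, g2, g3))
}

#' Fit a Gaussian-process surrogate
#'
#' @param X numeric matrix of latent coordinates (rows = molecules).
#' @param y numeric response (signed log2 fold-change targets).
#' @param hyper_strategy `"ml"` — maximize the log marginal likelihood with
#'   `restarts` seeded restarts; `"median"` — median-pairwise-distance
#'   length scale, unit signal variance and 10% noise on the standardized
#'   scale (fast path for large campaigns); `"fixed"` — use `hyper` as given.
#' @param restarts number of optimizer restarts for `"ml"`.
#' @param seed integer seed controlling restart draws.
#' @param hyper named vector `c(sf2=, ell=, sn2=)` for `"fixed"` (on the
#'   standardized-response scale).
#' @return object of class `gpr_model`.
#' @export
fit_gpr <- function(X, y, hyper_strategy = c("ml", "median", "fixed"),
                    restarts = 5L, seed = 1L, hyper = NULL) {
  hyper_strategy <- match.arg(hyper_strategy)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(is.finite(X)), all(is.finite(y)))
  if (nrow(X) < 2L) stop("need at least 2 training points")
  mu_y <- mean(y); sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  ys <- (y - mu_y) / sd_y
  set.seed(seed)
  h <- .heuristic_hyper(X, ys)
  if (hyper_strategy == "fixed") {
    stopifnot(!is.null(hyper))
    h <- hyper[c("sf2", "ell", "sn2")]
  } else if (hyper_strategy == "ml") {
    D2 <- .sq_dist(X, X)
    best <- NULL
    for (r in seq_len(restarts)) {
      th0 <- log(c(h["sf2"], h["ell"], h["sn2"])) +
        if (r == 1L) 0 else stats::rnorm(3, 0, 1)
      fit <- tryCatch(
        stats::optim(th0,
                     fn = function(t) .nlml(t, D2, ys)$value,
                     gr = function(t) .nlml(t, D2, ys)$grad,
                     method = "L-BFGS-B",
                     lower = log(c(1e-4, 1e-3, 1e-6)),
                     upper = log(c(1e4, 1e4, 1e2)),
                     control = list(maxit = 200)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best)) stop("hyperparameter optimization failed")
    h <- stats::setNames(exp(best$par), c("sf2", "ell", "sn2"))
  }
  sf2 <- unname(h["sf2"]); ell <- unname(h["ell"]); sn2 <- unname(h["sn2"])
  K <- .rbf(.sq_dist(X, X), sf2, ell) + diag(sn2, nrow(X))
  ch <- .chol_jitter(K)
  alpha <- backsolve(t(ch$L), forwardsolve(ch$L, ys))
  structure(list(X = X, y = y, mu_y = mu_y, sd_y = sd_y,
                 sf2 = sf2, ell = ell, sn2 = sn2,
                 L = ch$L, alpha = alpha, jitter = ch$jitter,
                 hyper_strategy = hyper_strategy, seed = seed),
            class = "gpr_model")
}

#' @export
print.gpr_model <- function(x, ...) {
  cat("<gpr_model> n =", nrow(x$X), " dim =", ncol(x$X),
      sprintf(" sf2=%.3g ell=%.3g sn2=%.3g (%s)\n",
              x$sf2, x$ell, x$sn2, x$hyper_strategy))
  invisible(x)
}

#' Posterior prediction
#'
#' Exact GP posterior mean and variance (the variance includes the fitted
#' noise term, so far from all training points it tends to
#' `sf2 + sn2` on the standardized scale).  Evaluation is chunked; results
#' are identical for any chunk size.
#'
#' @param object a `gpr_model`.
#' @param Xq query matrix (columns must match the training dimension).
#' @param chunk_size rows per evaluation block.
#' @param ... unused.
#' @return list with numeric vectors `mean` and `var`.
#' @export
predict.gpr_model <- function(object, Xq, chunk_size = 4096L, ...) {
  Xq <- as.matrix(Xq)
  if (ncol(Xq) != ncol(object$X)) stop("dimension error: query dim mismatch")
  n <- nrow(Xq)
  mu <- numeric(n); va <- numeric(n)
  for (from in seq(1L, n, by = chunk_size)) {
    to <- min(n, from + chunk_size - 1L)
    Kq <- .rbf(.sq_dist(object$X, Xq[from:to, , drop = FALSE]),
               object$sf2, object$ell)
    v <- forwardsolve(object$L, Kq)
    mu[from:to] <- object$mu_y + object$sd_y * drop(crossprod(Kq, object$alpha))
    va[from:to] <- object$sd_y^2 *
      pmax(object$sf2 + object$sn2 - colSums(v^2), 0)
  }
  list(mean = mu, var = va)
}

#' Cross-validated mean absolute error of a GP surrogate
#'
#' Random (seeded) k-fold partition, per-fold refit with the requested
#' hyperparameter strategy, MAE in the response units (signed log2 fold
#' change).  With fewer points than folds, falls back to leave-one-out with
#' a warning.
#'
#' @param X,y training data.
#' @param folds number of folds (default 5).
#' @param seed integer seed for the fold assignment and refits.
#' @param hyper_strategy,restarts passed to [fit_gpr()].
#' @return list with `mae`, per-fold `fold_mae`, and `fold_sd`.
#' @export
cv_mae <- function(X, y, folds = 5L, seed = 1L,
                   hyper_strategy = "ml", restarts = 3L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < folds) {
    warning("fewer points than folds; using leave-one-out")
    folds <- n
  }
  set.seed(seed)
  assign <- sample(rep_len(seq_len(folds), n))
  fold_mae <- numeric(folds)
  for (f in seq_len(folds)) {
    te <- assign == f
    m <- fit_gpr(X[!te, , drop = FALSE], y[!te],
                 hyper_strategy = hyper_strategy,
                 restarts = restarts, seed = seed + f)
    p <- predict(m, X[te, , drop = FALSE])
    fold_mae[f] <- mean(abs(p$mean - y[te]))
  }
  list(mae = mean(fold_mae), fold_mae = fold_mae,
       fold_sd = stats::sd(fold_mae))
}
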