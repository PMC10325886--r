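#' Delay embedding of a scalar series
#'
#' Reconstructs state-space points from a scalar series by taking lagged
#' coordinates: the point at time t is (x_t, x_{t-tau}, ..., x_{t-(E-1)tau}).
#'
#' @param x Numeric series without missing values.
#' @param E Embedding dimension (positive integer).
#' @param tau Time delay between coordinates (default 1).
#' @return Matrix with one row per point and `E` columns, most recent
#'   coordinate first; attribute `"time"` holds each point's source index.
#' @export
delay_embed <- function(x, E, tau = 1L) {
  E <- as.integer(E); tau <- as.integer(tau)
  if (E < 1L || tau < 1L) stop("E and tau must be positive integers")
  if (anyNA(x)) stop("series contains missing values")
  n <- length(x)
  need <- (E - 1L) * tau + 1L
  if (n < need) {
    stop("series too short to embed: need at least ", need,
         " points for E = ", E, ", tau = ", tau)
  }
  times <- seq.int(need, n)
  pts <- vapply(0:(E - 1L), function(k) x[times - k * tau],
                numeric(length(times)))
  pts <- matrix(pts, nrow = length(times), ncol = E)
  attr(pts, "time") <- times
  pts
}

#' Standardized root-mean-square forecast error
#'
#' RMSE between predictions and observations divided by the population
#' standard deviation of the observations. The population (1/n) convention
#' makes "always predict the mean" score exactly 1, so sRMSE >= 1 marks
#' deterministic prediction failure.
#'
#' @param pred,obs Equal-length numeric vectors.
#' @return Scalar sRMSE; NA (with a warning) when the observations are
#'   constant.
#' @export
srmse <- function(pred, obs) {
  if (length(pred) != length(obs) || length(obs) < 2) {
    stop("pred and obs must have equal length >= 2")
  }
  s <- pop_sd(obs)
  if (s == 0) {
    warning("constant test targets: sRMSE undefined")
    return(NA_real_)
  }
  sqrt(mean((pred - obs)^2)) / s
}

# Library/target preparation: embedded points whose Tp-step future lies inside
# the same window. `start` anchors window positions on the absolute time axis
# so overlap between library and target windows can be excluded exactly.
embed_with_futures <- function(x, E, tau, Tp, start = 1L) {
  pts <- delay_embed(x, E, tau)
  t_local <- attr(pts, "time")
  has_future <- t_local + Tp <= length(x)
  list(points = pts[has_future, , drop = FALSE],
       future = x[t_local[has_future] + Tp],
       time = t_local[has_future] + start - 1L)
}

#' Simplex projection forecasting
#'
#' Nearest-neighbour forecasting in delay-embedded state space. For each
#' target point the E+1 nearest library points (Euclidean distance) are found
#' and the prediction is their exponentially distance-weighted average future,
#' with weights exp(-d_k / d_min); if the nearest distance is zero, all
#' zero-distance neighbours get weight 1 and the rest 0.
#'
#' Library points that coincide with the target in absolute time, or whose
#' future falls inside the target's own coordinate span, are excluded. With
#' `library == targets` (the default) this is leave-one-out self-prediction;
#' with overlapping sliding windows it removes exactly the shared self-pairs.
#'
#' @param library Numeric vector: the training window.
#' @param targets Numeric vector: the test window (defaults to `library`).
#' @param E Embedding dimension.
#' @param tau Time delay (default 1).
#' @param Tp Prediction horizon (default 1).
#' @param lib_start,tgt_start Absolute start indices of the two windows on the
#'   common time axis (used for overlap exclusion).
#' @return List of class `prediction_result`: `predicted`, `observed`, `time`
#'   (absolute target times), `rmse`, and `srmse` (standardized by the
#'   population sd of the observed targets).
#' @export
simplex_predict <- function(library, targets = library, E, tau = 1L, Tp = 1L,
                            lib_start = 1L, tgt_start = lib_start) {
  lib <- embed_with_futures(library, E, tau, Tp, start = lib_start)
  tgt <- embed_with_futures(targets, E, tau, Tp, start = tgt_start)
  if (nrow(lib$points) < E + 1L) {
    stop("library supplies fewer than E + 1 points with known futures")
  }
  preds <- vapply(seq_len(nrow(tgt$points)), function(i) {
    tt <- tgt$time[i]
    span_lo <- tt - (E - 1L) * tau
    usable <- lib$time != tt &
      !(lib$time + Tp >= span_lo & lib$time + Tp <= tt)
    if (sum(usable) < E + 1L) {
      stop("fewer than E + 1 usable neighbours after exclusion at time ", tt)
    }
    d <- sqrt(colSums((t(lib$points[usable, , drop = FALSE]) -
                         tgt$points[i, ])^2))
    fut <- lib$future[usable]
    nb <- order(d)[seq_len(E + 1L)]
    dn <- d[nb]
    w <- if (dn[1] == 0) as.numeric(dn == 0) else exp(-dn / dn[1])
    sum(w * fut[nb]) / sum(w)
  }, numeric(1))
  obs <- tgt$future
  rmse <- sqrt(mean((preds - obs)^2))
  s <- pop_sd(obs)
  structure(list(predicted = preds, observed = obs, time = tgt$time,
                 rmse = rmse,
                 srmse = if (s > 0) rmse / s else NA_real_),
            class = "prediction_result")
}

#' Optimal embedding dimension by self-prediction skill
#'
#' Scans candidate embedding dimensions and returns the one minimizing the
#' leave-one-out self-prediction sRMSE of the window. Candidates that would
#' leave the library with fewer than E + 2 points are dropped; ties break
#' toward smaller E.
#'
#' @param x Numeric window values.
#' @param E_range Candidate dimensions (default 1:10).
#' @param tau,Tp Delay and horizon as in [simplex_predict()].
#' @return List with `E` (the chosen dimension) and `srmse` (named vector of
#'   self-prediction sRMSE per candidate).
#' @export
optimal_embedding <- function(x, E_range = 1:10, tau = 1L, Tp = 1L) {
  n <- length(x)
  # library points with known futures, minus the worst-case leave-one-out
  # exclusion (the target plus up to E overlapping-future points), must still
  # supply E + 2 candidates
  usable <- n - (E_range - 1L) * tau - Tp - (E_range + 1L)
  feasible <- E_range[usable >= E_range + 2L]
  if (length(feasible) == 0) stop("no feasible embedding dimension for n = ", n)
  errs <- vapply(feasible, function(E) {
    tryCatch(simplex_predict(x, E = E, tau = tau, Tp = Tp)$srmse,
             error = function(e) NA_real_)
  }, numeric(1))
  names(errs) <- feasible
  if (all(is.na(errs))) stop("self-prediction undefined for all E (constant window?)")
  best <- feasible[which.min(errs)]  # which.min: first minimum => smallest E
  list(E = best, srmse = errs)
}

# single-predictor weighted elastic net (glmnet needs >= 2 columns);
# soft-threshold / shrink closed form on weighted-centred data
enet_1d <- function(x, y, wts, lambda, alpha) {
  W <- sum(wts)
  xm <- sum(wts * x) / W; ym <- sum(wts * y) / W
  xc <- x - xm; yc <- y - ym
  sxx <- sum(wts * xc^2) / W
  sxy <- sum(wts * xc * yc) / W
  b <- vapply(lambda, function(l) {
    num <- sign(sxy) * max(abs(sxy) - l * alpha, 0)
    num / (sxx + l * (1 - alpha))
  }, numeric(1))
  list(b = b, b0 = ym - b * xm)
}

#' Regularized S-map forecast error at a given state-dependence theta
#'
#' Locally weighted linear forecasting: for each embedded point a linear map
#' to its one-step future is fit on all other points with state-space weights
#' exp(-theta * d / dbar) (dbar = mean distance to the target) and an
#' elastic-net penalty (mixing `alpha`, default 0.5). The penalty strength is
#' chosen by leave-one-out cross-validation over a common lambda path, and the
#' minimized out-of-sample sRMSE is returned. theta = 0 is a global linear
#' model; error decreasing with theta > 0 indicates state-dependent
#' (nonlinear) dynamics.
#'
#' @param x Numeric window values.
#' @param E Embedding dimension.
#' @param theta State-dependence parameter (>= 0).
#' @param lambda Optional penalty path; by default taken from an unweighted
#'   reference `glmnet` fit on the window.
#' @param tau,Tp Delay and horizon.
#' @param alpha Elastic-net mixing (default 0.5).
#' @return List: `srmse` (minimum over the path), `lambda`, `errors` (sRMSE per
#'   lambda), `lambda_best`, `predicted` (at the best lambda), `observed`.
#' @export
regularized_smap <- function(x, E, theta, lambda = NULL, tau = 1L, Tp = 1L,
                             alpha = 0.5) {
  if (theta < 0) stop("theta must be >= 0")
  emb <- embed_with_futures(x, E, tau, Tp)
  X <- emb$points; y <- emb$future
  n <- nrow(X)
  if (n < E + 3L) stop("window too short for S-map with E = ", E)
  if (pop_sd(y) == 0) stop("constant targets: S-map error undefined")
  if (is.null(lambda)) {
    lambda <- if (E >= 2) {
      glmnet::glmnet(X, y, alpha = alpha, nlambda = 12,
                     lambda.min.ratio = 1e-4)$lambda
    } else {
      W <- n
      sxy <- abs(sum((X[, 1] - mean(X[, 1])) * (y - mean(y))) / W)
      max(sxy, 1e-8) / max(alpha, 0.1) * 10^seq(0, -4, length.out = 12)
    }
  }
  preds <- matrix(NA_real_, n, length(lambda))
  dall <- as.matrix(stats::dist(X))
  for (i in seq_len(n)) {
    d <- dall[i, -i]
    dbar <- mean(d)
    wts <- if (dbar > 0) exp(-theta * d / dbar) else rep(1, length(d))
    if (E >= 2) {
      fit <- glmnet::glmnet(X[-i, , drop = FALSE], y[-i], weights = wts,
                            alpha = alpha, lambda = lambda)
      preds[i, ] <- stats::predict(fit, X[i, , drop = FALSE],
                                   s = lambda, exact = FALSE)
    } else {
      f <- enet_1d(X[-i, 1], y[-i], wts, lambda, alpha)
      preds[i, ] <- f$b0 + f$b * X[i, 1]
    }
  }
  errs <- apply(preds, 2, srmse, obs = y)
  k <- which.min(errs)
  sq <- (preds[, k] - y)^2
  list(srmse = errs[k], lambda = lambda, errors = errs,
       lambda_best = lambda[k], predicted = preds[, k], observed = y,
       mse = mean(sq), mse_se = stats::sd(sq) / sqrt(n))
}

#' Default theta grid for the nonlinearity scan
#' @export
default_theta_grid <- function() {
  c(0, 0.1, 0.3, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8)
}

#' Estimate the nonlinearity parameter theta of a window
#'
#' Runs the regularized S-map over a grid of theta values (the grid must
#' include 0, the linear null) and selects the state-dependence theta by
#' leave-one-out forecast error. Because the error curve in theta is nearly
#' flat for linear-stochastic series, a raw argmin inherits selection noise
#' and is biased away from 0 under the null; the default `rule = "1se"`
#' therefore picks the smallest theta whose leave-one-out mean squared error
#' lies within one standard error of the minimum — the usual
#' one-standard-error model-selection rule, conservative for the linearity
#' null. `rule = "min"` gives the raw argmin (exact ties still break toward
#' theta = 0).
#'
#' @param x Numeric window values.
#' @param E Embedding dimension; chosen by [optimal_embedding()] when NULL.
#' @param theta_grid Candidate thetas including 0.
#' @param tau,Tp,alpha Passed to [regularized_smap()].
#' @param rule Selection rule, `"1se"` (default) or `"min"`.
#' @return List of class `nonlinearity_result`: `theta` (the selection),
#'   `grid`, `errors` (sRMSE per theta), and `E`.
#' @export
estimate_theta <- function(x, E = NULL, theta_grid = default_theta_grid(),
                           tau = 1L, Tp = 1L, alpha = 0.5,
                           rule = c("1se", "min")) {
  rule <- match.arg(rule)
  if (!any(theta_grid == 0)) stop("theta grid must include 0")
  theta_grid <- sort(theta_grid)
  if (is.null(E)) E <- optimal_embedding(x, tau = tau, Tp = Tp)$E
  # common lambda path across thetas so errors are comparable
  emb <- embed_with_futures(x, E, tau, Tp)
  lambda <- if (E >= 2) {
    glmnet::glmnet(emb$points, emb$future, alpha = alpha, nlambda = 12,
                   lambda.min.ratio = 1e-4)$lambda
  } else NULL
  fits <- lapply(theta_grid, function(th) {
    regularized_smap(x, E, th, lambda = lambda, tau = tau, Tp = Tp,
                     alpha = alpha)
  })
  errs <- vapply(fits, `[[`, numeric(1), "srmse")
  mse <- vapply(fits, `[[`, numeric(1), "mse")
  k_min <- which.min(mse)  # first minimum: smallest theta on exact ties
  k <- if (rule == "1se") {
    which(mse <= mse[k_min] + fits[[k_min]]$mse_se)[1]
  } else {
    k_min
  }
  structure(list(theta = theta_grid[k], grid = theta_grid,
                 errors = errs, E = E, rule = rule),
            class = "nonlinearity_result")
}
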