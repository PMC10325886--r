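#' Sliding windows over a series
#'
#' Contiguous, overlapping windows of length `w` at stride 1; a series of
#' length n yields exactly n - w + 1 windows.
#'
#' @param n Series length.
#' @param w Window length.
#' @return Data frame with columns `start` and `end` (inclusive indices).
#' @export
make_windows <- function(n, w) {
  n <- as.integer(n); w <- as.integer(w)
  if (w < 4L) stop("window length must be at least 4")
  if (n < w) stop("series of length ", n, " is shorter than the window (", w, ")")
  starts <- seq_len(n - w + 1L)
  data.frame(start = starts, end = starts + w - 1L)
}

#' Mutual prediction matrix of an indicator series
#'
#' Slides windows of length `w` over the series; for each training window i
#' an embedding dimension E_i is chosen by leave-one-out self-prediction
#' ([optimal_embedding()]), and a simplex model with library i forecasts the
#' one-step futures of every test window j. Entry (i, j) is the sRMSE
#' standardized by the population sd of window j's observed targets; the
#' diagonal is leave-one-out self-prediction. Values >= 1 mean the model does
#' no better than predicting the test-window mean.
#'
#' @param x Numeric indicator series without missing values.
#' @param w Window length (48 for the monthly fish surveys).
#' @param name Indicator name carried in the result.
#' @param E_range Candidate embedding dimensions.
#' @param tau,Tp Delay and prediction horizon.
#' @return Object of class `mutual_prediction`: `srmse` (n_w x n_w matrix),
#'   `E` (chosen dimension per training window), `windows`, `w`, `name`.
#' @export
mutual_prediction_matrix <- function(x, w, name = "indicator",
                                     E_range = 1:10, tau = 1L, Tp = 1L) {
  if (anyNA(x)) {
    stop("series '", name, "' has missing values at surveys ",
         paste(which(is.na(x)), collapse = ", "),
         "; windows must be free of missing values")
  }
  win <- make_windows(length(x), w)
  n_w <- nrow(win)
  E_star <- rep(NA_integer_, n_w)
  for (i in seq_len(n_w)) {
    sel <- tryCatch(
      optimal_embedding(x[win$start[i]:win$end[i]], E_range, tau, Tp),
      error = function(e) NULL)
    if (is.null(sel)) {
      warning("window ", i, " of '", name,
              "' has no defined self-prediction; row left undefined")
    } else {
      E_star[i] <- sel$E
    }
  }
  m <- matrix(NA_real_, n_w, n_w)
  const_col <- logical(n_w)
  for (i in seq_len(n_w)) {
    if (is.na(E_star[i])) next
    lib <- x[win$start[i]:win$end[i]]
    for (j in seq_len(n_w)) {
      if (const_col[j]) next
      res <- withCallingHandlers(
        simplex_predict(lib, x[win$start[j]:win$end[j]], E = E_star[i],
                        tau = tau, Tp = Tp,
                        lib_start = win$start[i], tgt_start = win$start[j]),
        warning = function(w_) invokeRestart("muffleWarning"))
      if (is.na(res$srmse) && !const_col[j]) {
        const_col[j] <- TRUE
        warning("test window ", j, " of '", name,
                "' is constant; column left undefined")
      }
      m[i, j] <- res$srmse
    }
  }
  structure(list(name = name, srmse = m, E = E_star, windows = win, w = w,
                 tau = tau, Tp = Tp),
            class = "mutual_prediction")
}

#' @exportS3Method base::print
print.mutual_prediction <- function(x, ...) {
  n_w <- nrow(x$srmse)
  cat("mutual_prediction '", x$name, "': ", n_w, " x ", n_w,
      " windows of length ", x$w, "\n", sep = "")
  cat("  E* range: ", paste(range(x$E, na.rm = TRUE), collapse = "-"),
      "; determinism fraction: ",
      tryCatch(round(determinism_fraction(x), 3), error = function(e) NA),
      "\n", sep = "")
  invisible(x)
}

#' Determinism fraction of an indicator
#'
#' Proportion of sliding windows whose leave-one-out self-prediction sRMSE is
#' strictly below 1 — i.e. windows where the indicator's own recent dynamics
#' beat the "predict the mean" baseline.
#'
#' @param m A `mutual_prediction` object or a square sRMSE matrix.
#' @return Fraction in \[0, 1\].
#' @export
determinism_fraction <- function(m) {
  d <- diag(if (inherits(m, "mutual_prediction")) m$srmse else as.matrix(m))
  if (anyNA(d)) stop("diagonal (self-prediction) has undefined entries")
  mean(d < 1)
}

#' Within- vs cross-regime block contrast of a mutual prediction matrix
#'
#' Splits the sliding windows into two blocks at a boundary on the original
#' time axis (a window belongs to the first block when its midpoint falls at
#' or before the boundary) and contrasts the mean off-diagonal sRMSE of
#' cross-block pairs against within-block pairs. A positive contrast means
#' models trained in one regime forecast the other regime worse than their
#' own — the signature of a change in the dynamical rule.
#'
#' @param m A `mutual_prediction` object.
#' @param boundary Time index splitting the series (default: its midpoint).
#' @return List: `within_mean`, `cross_mean`, `contrast` (cross - within).
#' @export
block_contrast <- function(m, boundary = NULL) {
  stopifnot(inherits(m, "mutual_prediction"))
  win <- m$windows
  n <- max(win$end)
  if (is.null(boundary)) boundary <- n / 2
  first <- (win$start + win$end) / 2 <= boundary
  if (all(first) || !any(first)) {
    stop("boundary leaves all windows in one block")
  }
  off <- row(m$srmse) != col(m$srmse)
  same <- outer(first, first, "==")
  within_mean <- mean(m$srmse[off & same], na.rm = TRUE)
  cross_mean <- mean(m$srmse[off & !same], na.rm = TRUE)
  list(within_mean = within_mean, cross_mean = cross_mean,
       contrast = cross_mean - within_mean)
}

#' Determinism and nonlinearity summary for a set of indicators
#'
#' For each indicator: the determinism fraction (windows with self-prediction
#' sRMSE < 1) and the per-window nonlinearity parameter theta of the
#' regularized S-map, with a simultaneous test of the null that theta = 0 for
#' all windows.
#'
#' @param matrices Named list of `mutual_prediction` objects.
#' @param series Named list/data frame of the indicator series (same names).
#' @param theta_grid Candidate thetas.
#' @param alpha Significance level for the nonlinearity call.
#' @param method Adjustment passed to [nonlinearity_test()].
#' @return List: `determinism` (named vector), `theta` (windows x indicators
#'   matrix), `test` (data frame from [nonlinearity_test()]).
#' @export
determinism_nonlinearity <- function(matrices, series,
                                     theta_grid = default_theta_grid(),
                                     alpha = 0.05, method = "maxt") {
  nms <- names(matrices)
  det_frac <- vapply(matrices, determinism_fraction, numeric(1))
  theta <- sapply(nms, function(nm) {
    m <- matrices[[nm]]
    x <- as.numeric(series[[nm]])
    vapply(seq_len(nrow(m$windows)), function(i) {
      estimate_theta(x[m$windows$start[i]:m$windows$end[i]],
                     E = m$E[i], theta_grid = theta_grid,
                     tau = m$tau, Tp = m$Tp)$theta
    }, numeric(1))
  })
  list(determinism = det_frac, theta = theta,
       test = nonlinearity_test(theta, alpha = alpha, method = method))
}

#' Simultaneous test of the linearity null theta = 0
#'
#' One-sided many-to-one comparison of each indicator's mean window theta
#' against the reference value 0, with familywise adjustment across
#' indicators. `method = "maxt"` uses the max-T bound under an independence
#' working correlation (equal degrees of freedom: p_adj = 1 - pt(t)^K);
#' `method = "signflip"` replaces the t reference by a sign-flip permutation
#' null with a Sidak-type adjustment, for when the t assumptions are doubted.
#' Degenerate inputs are decided exactly: all thetas 0 gives p = 1; all
#' windows equal at a positive theta gives p = 0.
#'
#' @param theta Matrix of per-window theta estimates, columns = indicators.
#' @param alpha Familywise significance level (default 0.05).
#' @param method "maxt" or "signflip".
#' @param n_perm Permutations for the sign-flip method.
#' @return Data frame: indicator, mean_theta, statistic, p_raw, p_adj,
#'   significant.
#' @export
nonlinearity_test <- function(theta, alpha = 0.05, method = c("maxt", "signflip"),
                              n_perm = 999) {
  method <- match.arg(method)
  theta <- as.matrix(theta)
  if (nrow(theta) < 5) stop("need at least 5 windows per indicator")
  K <- ncol(theta)
  nms <- colnames(theta)
  if (is.null(nms)) nms <- paste0("ind", seq_len(K))
  res <- lapply(seq_len(K), function(k) {
    th <- theta[, k]
    n <- length(th)
    s <- stats::sd(th)
    if (s == 0) {
      p <- if (mean(th) == 0) 1 else 0
      return(list(mean = mean(th), stat = if (p == 1) 0 else Inf, p = p))
    }
    t_stat <- mean(th) / (s / sqrt(n))
    if (method == "maxt") {
      p <- stats::pt(t_stat, df = n - 1, lower.tail = FALSE)
    } else {
      signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
      null_means <- colMeans(signs * th)
      p <- (1 + sum(null_means >= mean(th))) / (1 + n_perm)
    }
    list(mean = mean(th), stat = t_stat, p = p)
  })
  p_raw <- vapply(res, `[[`, numeric(1), "p")
  # familywise: max-T under independence working correlation == Sidak-type
  p_adj <- pmin(1, 1 - (1 - p_raw)^K)
  p_adj[p_raw %in% c(0, 1)] <- p_raw[p_raw %in% c(0, 1)]
  data.frame(indicator = nms,
             mean_theta = vapply(res, `[[`, numeric(1), "mean"),
             statistic = vapply(res, `[[`, numeric(1), "stat"),
             p_raw = p_raw, p_adj = p_adj,
             significant = p_adj <= alpha,
             row.names = NULL)
}

#' Window-size trade-off report
#'
#' For each candidate window length: the mean self-prediction sRMSE (skill —
#' longer windows predict themselves better) and the block contrast around
#' the series midpoint (sensitivity to a mid-series change in dynamics —
#' shorter windows localize changes better). The report exposes the
#' trade-off; it makes no automatic selection.
#'
#' @param x Indicator series.
#' @param sizes Candidate window lengths.
#' @param boundary Split point for the sensitivity proxy (default midpoint).
#' @param ... Passed to [mutual_prediction_matrix()].
#' @return Data frame: w, n_windows, mean_self_srmse, block_contrast.
#' @export
window_size_scan <- function(x, sizes, boundary = NULL, ...) {
  rows <- lapply(sizes, function(w) {
    ok <- tryCatch({
      m <- mutual_prediction_matrix(x, w, name = paste0("w", w), ...)
      bc <- block_contrast(m, boundary)
      data.frame(w = w, n_windows = nrow(m$windows),
                 mean_self_srmse = mean(diag(m$srmse), na.rm = TRUE),
                 block_contrast = bc$contrast)
    }, error = function(e) {
      warning("window size ", w, " skipped: ", conditionMessage(e))
      NULL
    })
    ok
  })
  do.call(rbind, rows)
}
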