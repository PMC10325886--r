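#' Euclidean distance between two mutual prediction matrices
#'
#' Square root of the sum of squared entrywise differences over defined
#' entries. Undefined (NA) entries must sit at identical positions in both
#' matrices; otherwise the distance is not comparable and an error is raised.
#'
#' @param A,B `mutual_prediction` objects or plain matrices of equal shape.
#' @return Non-negative scalar.
#' @export
matrix_distance <- function(A, B) {
  a <- if (inherits(A, "mutual_prediction")) A$srmse else as.matrix(A)
  b <- if (inherits(B, "mutual_prediction")) B$srmse else as.matrix(B)
  if (!all(dim(a) == dim(b))) stop("matrices differ in shape")
  if (!identical(which(is.na(a)), which(is.na(b)))) {
    stop("undefined entries sit at different positions in the two matrices")
  }
  sqrt(sum((a - b)^2, na.rm = TRUE))
}

#' Ward clustering of indicators from a distance table
#'
#' Agglomerative clustering under the Ward criterion on squared Euclidean
#' distances (the `ward.D2` convention, with merge heights on the original
#' distance scale). Labels are ordered lexicographically before clustering so
#' the merge tree is deterministic and invariant to input order.
#'
#' @param d `dist` object or symmetric distance matrix with labels.
#' @return An `hclust` tree.
#' @export
ward_clustering <- function(d) {
  dm <- as.matrix(d)
  if (any(!is.finite(dm))) stop("non-finite distance")
  if (nrow(dm) < 2) stop("need at least 2 indicators")
  ord <- order(rownames(dm))
  dm <- dm[ord, ord, drop = FALSE]
  stats::hclust(stats::as.dist(dm), method = "ward.D2")
}

# rows of `xs` permuted independently within each column (exchangeable null)
permute_columns <- function(xs) {
  k <- nrow(xs); V <- ncol(xs)
  o <- order(rep.int(seq_len(V), rep.int(k, V)), stats::runif(k * V))
  matrix(xs[o], k, V)
}

sorted_profile <- function(xs) sort(stats::dist(xs))

# SIMPROF test of multivariate structure within one group of objects.
# pi = sum |ordered observed profile - mean ordered permuted profile|;
# the null pi distribution comes from a second, independent permutation set.
simprof_node_test <- function(xs, n_perm) {
  obs <- sorted_profile(xs)
  mean_prof <- rowMeans(vapply(seq_len(n_perm), function(i) {
    sorted_profile(permute_columns(xs))
  }, numeric(length(obs))))
  pi_obs <- sum(abs(obs - mean_prof))
  pi_null <- vapply(seq_len(n_perm), function(i) {
    sum(abs(sorted_profile(permute_columns(xs)) - mean_prof))
  }, numeric(1))
  (1 + sum(pi_null >= pi_obs)) / (1 + n_perm)
}

# leaves under each side of merge row `i` of an hclust tree
merge_members <- function(hc) {
  n <- length(hc$labels)
  mem <- vector("list", nrow(hc$merge))
  side <- function(v) if (v < 0) -v else mem[[v]]
  for (i in seq_len(nrow(hc$merge))) {
    mem[[i]] <- c(side(hc$merge[i, 1]), side(hc$merge[i, 2]))
  }
  mem
}

#' SIMPROF: similarity-profile permutation test over a dendrogram
#'
#' Tests for multivariate structure by comparing the ordered profile of
#' pairwise Euclidean distances among objects with the mean profile obtained
#' after permuting each variable independently across objects. The dendrogram
#' (Ward.D2 on the same distances, unless supplied) is traversed from the
#' root; a node is split only when its profile departs significantly
#' (p <= alpha) from the exchangeable null, and the leaves of the stopped
#' traversal are the significant clusters. Nodes with fewer than three
#' objects are untestable and treated as homogeneous.
#'
#' @param x Objects x variables numeric matrix with row names.
#' @param alpha Significance level (default 0.01).
#' @param n_perm Permutations per node (>= 99; default 999).
#' @param seed Seed making the permutation stream reproducible.
#' @param hc Optional precomputed `hclust` on the same objects.
#' @return Object of class `simprof_result`: `hclust`, `node_p` (p-value per
#'   tested merge node), `clusters` (named integer assignment), `n_clusters`,
#'   `alpha`, `n_perm`, `seed`.
#' @export
simprof <- function(x, alpha = 0.01, n_perm = 999, seed = 1L, hc = NULL) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("obj", seq_len(nrow(x)))
  if (n_perm < 99) stop("n_perm must be at least 99")
  x <- x[order(rownames(x)), , drop = FALSE]  # order invariance
  if (is.null(hc)) hc <- ward_clustering(stats::dist(x))
  if (!identical(sort(hc$labels), rownames(x))) {
    stop("dendrogram labels do not match the table's objects")
  }
  n <- nrow(x)
  mem <- merge_members(hc)
  node_p <- rep(NA_real_, length(mem))
  clusters <- stats::setNames(rep(NA_integer_, n), hc$labels)
  next_id <- 0L
  set.seed(seed)
  assign_cluster <- function(leaves) {
    next_id <<- next_id + 1L
    clusters[hc$labels[leaves]] <<- next_id
  }
  visit <- function(v) {
    leaves <- if (v < 0) -v else mem[[v]]
    if (length(leaves) < 3) {  # untestable node: treated as homogeneous
      assign_cluster(leaves)
      return(invisible(NULL))
    }
    idx <- match(hc$labels[leaves], rownames(x))
    p <- simprof_node_test(x[idx, , drop = FALSE], n_perm)
    node_p[v] <<- p
    if (p <= alpha) {
      visit(hc$merge[v, 1])
      visit(hc$merge[v, 2])
    } else {
      assign_cluster(leaves)
    }
    invisible(NULL)
  }
  visit(nrow(hc$merge))
  structure(list(hclust = hc, node_p = node_p, clusters = clusters,
                 n_clusters = next_id, alpha = alpha, n_perm = n_perm,
                 seed = seed),
            class = "simprof_result")
}

#' @exportS3Method base::print
print.simprof_result <- function(x, ...) {
  cat("SIMPROF at alpha =", x$alpha, "with", x$n_perm, "permutations (seed",
      paste0(x$seed, "):"), x$n_clusters, "significant cluster(s)\n")
  for (k in seq_len(x$n_clusters)) {
    cat("  cluster ", k, ": ",
        paste(names(x$clusters)[x$clusters == k], collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Classify indicators by their environmental responsiveness
#'
#' End-to-end classification: flattens each indicator's mutual prediction
#' matrix into a variable vector, computes pairwise Euclidean distances,
#' clusters with Ward's method, and extracts significant groups with SIMPROF.
#' Positions undefined in any matrix are dropped from all (with a warning) so
#' distances stay comparable.
#'
#' @param matrices Named list of `mutual_prediction` objects or plain
#'   matrices of identical shape (one per indicator).
#' @param alpha SIMPROF significance level (default 0.01).
#' @param n_perm Permutations (default 999).
#' @param seed Seed for the permutation stream.
#' @return `simprof_result` augmented with `dist` (the indicator distance
#'   table) and `table` (the flattened matrix used).
#' @export
classify_indicators <- function(matrices, alpha = 0.01, n_perm = 999,
                                seed = 1L) {
  if (is.null(names(matrices)) || anyDuplicated(names(matrices))) {
    stop("matrices must be a uniquely named list")
  }
  flat <- lapply(matrices, function(m) {
    as.numeric(if (inherits(m, "mutual_prediction")) m$srmse else as.matrix(m))
  })
  len <- unique(lengths(flat))
  if (length(len) != 1) stop("all matrices must have the same shape")
  X <- do.call(rbind, flat)
  rownames(X) <- names(matrices)
  bad <- colSums(is.na(X)) > 0
  if (any(bad)) {
    warning(sum(bad), " undefined matrix positions dropped from all indicators")
    X <- X[, !bad, drop = FALSE]
  }
  if (nrow(X) == 2) {
    warning("only 2 indicators: SIMPROF untestable, reporting 1 cluster")
  }
  res <- simprof(X, alpha = alpha, n_perm = n_perm, seed = seed)
  res$dist <- stats::dist(X[order(rownames(X)), , drop = FALSE])
  res$table <- X
  res
}
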