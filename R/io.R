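#' Read a community abundance time series
#'
#' Expects a delimited table with a header row of species identifiers, a
#' first column of ISO-8601 survey dates, and non-negative integer counts in
#' the cells. Surveys are returned in date order; duplicate dates and
#' malformed cells are rejected with the offending row and column named.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return A `community_ts`.
#' @export
read_community <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("community file needs a date column plus species")
  dates <- as.Date(df[[1]], format = "%Y-%m-%d")
  if (anyNA(dates)) {
    stop("unparseable ISO-8601 date in row(s) ",
         paste(which(is.na(dates)), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  bad <- which(!is.finite(m) | m < 0 | abs(m - round(m)) > 1e-8,
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-integer or negative count at row ", bad[1, 1],
         ", species '", colnames(m)[bad[1, 2]], "'")
  }
  community_ts(m, dates)
}

#' Write a community time series
#' @param ct A `community_ts`.
#' @param path File path.
#' @param sep Field separator.
#' @export
write_community <- function(ct, path, sep = ",") {
  stopifnot(inherits(ct, "community_ts"))
  df <- data.frame(date = format(ct$date), ct$abundance,
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Read a species metadata table
#'
#' Delimited table with columns species, genus, family, order, cod_latitude.
#' Identifier uniqueness, non-empty taxonomy labels, taxonomic nesting
#' (a genus may not straddle families, nor a family orders) and finite COD
#' latitudes are validated.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return Data frame of species metadata.
#' @export
read_species <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  st <- validate_species_table(df)
  if (!"cod_latitude" %in% names(st)) {
    stop("species table lacks column cod_latitude")
  }
  if (any(!is.finite(st$cod_latitude))) stop("COD latitudes must be finite")
  st
}

#' Write a species metadata table
#' @param st Species table.
#' @param path File path.
#' @param sep Field separator.
#' @export
write_species <- function(st, path, sep = ",") {
  utils::write.table(st, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Write / read an indicator time-series table
#'
#' One row per survey, ten indicator columns in Table order, missing values
#' as empty cells.
#' @param ind Data frame from [indicator_time_series()].
#' @param path File path.
#' @param sep Field separator.
#' @export
write_indicators <- function(ind, path, sep = ",") {
  df <- ind
  if ("date" %in% names(df)) df$date <- format(df$date)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
}

#' @rdname write_indicators
#' @export
read_indicators <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if ("date" %in% names(df)) df$date <- as.Date(df$date)
  df
}

#' Write a mutual prediction matrix as delimited text
#'
#' Row and column headers label the windows by their start date when survey
#' dates are supplied, else by start index.
#'
#' @param m `mutual_prediction` object.
#' @param path File path.
#' @param dates Optional survey dates indexed by the window start.
#' @param sep Field separator.
#' @export
write_mutual <- function(m, path, dates = NULL, sep = ",") {
  stopifnot(inherits(m, "mutual_prediction"))
  lab <- if (is.null(dates)) paste0("t", m$windows$start) else
    format(dates[m$windows$start])
  out <- m$srmse
  dimnames(out) <- list(lab, lab)
  utils::write.table(cbind(window = lab, as.data.frame(out)), path,
                     sep = sep, row.names = FALSE, quote = FALSE, na = "")
}

#' @rdname write_mutual
#' @export
read_mutual <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, na.strings = c("NA", ""))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are differences of merge heights, so root-to-leaf path
#' lengths reproduce each leaf's merge height.
#'
#' @param hc An `hclust` tree.
#' @param path File path.
#' @export
write_dendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
}

#' Write the significant-cluster table
#'
#' One row per indicator: cluster id and the p-value of the last SIMPROF
#' node tested on the path that froze the indicator's cluster (NA when the
#' cluster came from an untestable node).
#'
#' @param res `simprof_result`.
#' @param path File path.
#' @param sep Field separator.
#' @export
write_cluster_table <- function(res, path, sep = ",") {
  stopifnot(inherits(res, "simprof_result"))
  df <- cluster_table(res)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
}

#' @rdname write_cluster_table
#' @export
cluster_table <- function(res) {
  hc <- res$hclust
  mem <- merge_members(hc)
  stop_p <- stats::setNames(rep(NA_real_, length(res$clusters)),
                            names(res$clusters))
  for (v in rev(seq_along(mem))) {  # descending: deepest tested node wins
    if (!is.na(res$node_p[v])) {
      labs <- hc$labels[mem[[v]]]
      stop_p[labs] <- res$node_p[v]
    }
  }
  data.frame(indicator = names(res$clusters),
             cluster = as.integer(res$clusters),
             node_p = as.numeric(stop_p[names(res$clusters)]),
             row.names = NULL)
}
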