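# population (1/n) moments; chosen so that "predict the mean" gives sRMSE = 1
pop_var <- function(x) mean((x - mean(x))^2)
pop_sd <- function(x) sqrt(pop_var(x))

#' Community time-series container
#'
#' Lightweight container pairing a surveys x species abundance matrix with
#' survey dates. Surveys are stored in date order; the time index used by all
#' windowed analyses is the ordinal rank of the survey, not calendar time
#' (real survey spacing varies around monthly).
#'
#' @param abundance Numeric matrix, rows = surveys, columns = species (named).
#' @param date Vector of survey dates (`Date` or coercible).
#' @return Object of class `community_ts`.
#' @export
community_ts <- function(abundance, date) {
  abundance <- as.matrix(abundance)
  if (is.null(colnames(abundance))) {
    stop("abundance matrix needs species column names")
  }
  date <- as.Date(date)
  if (length(date) != nrow(abundance)) {
    stop("one date per survey required")
  }
  if (anyDuplicated(date)) stop("duplicate survey dates")
  if (any(!is.finite(abundance)) || any(abundance < 0)) {
    stop("abundances must be finite and non-negative")
  }
  ord <- order(date)
  structure(list(abundance = abundance[ord, , drop = FALSE],
                 date = date[ord]),
            class = "community_ts")
}

as_community_ts <- function(x) {
  if (inherits(x, "community_ts")) return(x)
  if (is.matrix(x) || is.data.frame(x)) {
    m <- as.matrix(x)
    return(community_ts(m, as.Date(seq_len(nrow(m)),
                                   origin = "2000-01-01")))
  }
  stop("cannot interpret object as a community time series")
}

#' @exportS3Method base::print
print.community_ts <- function(x, ...) {
  cat("community_ts:", nrow(x$abundance), "surveys x",
      ncol(x$abundance), "species (",
      format(min(x$date)), "to", format(max(x$date)), ")\n")
  invisible(x)
}

# timestamped stage log used by the pipeline
log_stage <- function(stage, ..., verbose = TRUE) {
  if (verbose) {
    message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", stage, "] ", ...)
  }
  invisible(NULL)
}
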