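#' Relative abundances of present species
#'
#' Converts an abundance vector to proportions over the species actually
#' present (count > 0). Species with zero counts are dropped, so the returned
#' vector sums to one over present species only.
#'
#' @param counts Non-negative integer abundance vector, optionally named.
#' @return Named numeric vector of proportions over present species.
#' @export
relative_abundances <- function(counts) {
  check_abundance(counts)
  present <- counts > 0
  p <- counts[present] / sum(counts[present])
  p
}

check_abundance <- function(counts) {
  if (length(counts) == 0L || !is.numeric(counts)) {
    stop("abundance vector must be a non-empty numeric vector")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("abundances must be finite and non-negative")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("abundances must be integer counts")
  }
  if (sum(counts) <= 0) {
    stop("empty community: all counts are zero")
  }
  invisible(TRUE)
}

#' Alpha-diversity indicators for one survey
#'
#' Computes the abundance-based indicators for a single survey: species
#' richness S, total abundance N, species dominance p_max, Simpson diversity
#' D = 1 - sum(p_i^2), Shannon diversity H' = -sum(p_i log p_i), Simpson
#' evenness E_D = D * S / (S - 1), Shannon evenness E_H = H'/log(S), and
#' Smith-Wilson evenness
#' E_var = 1 - (2/pi) * atan(var_pop(log n_i)), where var_pop uses the 1/S
#' normalization. Natural logarithms throughout. For a single-species survey
#' D = H' = 0, p_max = 1, E_var = 1, and E_D, E_H are undefined (NA).
#'
#' @param counts Non-negative integer abundance vector.
#' @return Named list with elements S, N, p_max, D, H, E_D, E_H, E_var.
#' @export
alpha_indicators <- function(counts) {
  p <- relative_abundances(counts)
  n <- counts[counts > 0]
  S <- length(p)
  N <- sum(n)
  D <- 1 - sum(p^2)
  H <- -sum(p * log(p))
  if (S > 1) {
    E_D <- D * S / (S - 1)
    E_H <- H / log(S)
  } else {
    E_D <- NA_real_
    E_H <- NA_real_
  }
  ln_n <- log(n)
  E_var <- 1 - (2 / pi) * atan(sum((ln_n - mean(ln_n))^2) / S)
  list(S = S, N = N, p_max = max(p), D = D, H = H,
       E_D = E_D, E_H = E_H, E_var = E_var)
}

#' Taxonomic relatedness weights between species
#'
#' Pairwise path-length weights from a species taxonomy: 1 for species in the
#' same genus, 2 same family, 3 same order, 4 otherwise (the finest shared
#' rank decides). The diagonal is 0.
#'
#' @param species_table Species metadata (see [read_species()]).
#' @return Symmetric integer matrix with species identifiers as dimnames.
#' @export
taxonomic_weights <- function(species_table) {
  st <- validate_species_table(species_table)
  n <- nrow(st)
  w <- matrix(4L, n, n, dimnames = list(st$species, st$species))
  same <- function(col) outer(st[[col]], st[[col]], "==")
  w[same("order")] <- 3L
  w[same("family")] <- 2L
  w[same("genus")] <- 1L
  diag(w) <- 0L
  w
}

#' Taxonomic diversity (Warwick-Clarke delta)
#'
#' Abundance-weighted mean taxonomic path length between pairs of
#' individuals:
#' delta = sum_{i<j} w_ij n_i n_j / (sum_{i<j} n_i n_j + sum_i n_i(n_i-1)/2).
#' The denominator equals N(N-1)/2, the number of individual pairs; it is zero
#' only for a survey holding a single individual, in which case delta is
#' undefined (NA).
#'
#' @param counts Abundance vector aligned to `species_table` rows (or named by
#'   species identifier).
#' @param species_table Species metadata with genus/family/order labels.
#' @return Scalar delta >= 0, or NA when a single individual was seen.
#' @export
taxonomic_diversity <- function(counts, species_table) {
  check_abundance(counts)
  st <- validate_species_table(species_table)
  counts <- align_counts(counts, st$species)
  keep <- counts > 0
  n <- counts[keep]
  N <- sum(n)
  if (N < 2) {
    return(NA_real_)
  }
  if (length(n) == 1L) {
    return(0)
  }
  w <- taxonomic_weights(st[keep, , drop = FALSE])
  cross <- outer(n, n)
  num <- sum(w[upper.tri(w)] * cross[upper.tri(cross)])
  num / (N * (N - 1) / 2)
}

align_counts <- function(counts, species) {
  if (!is.null(names(counts))) {
    missing <- setdiff(names(counts), species)
    if (length(missing) > 0) {
      stop("species missing from the species table: ",
           paste(missing, collapse = ", "))
    }
    full <- stats::setNames(numeric(length(species)), species)
    full[names(counts)] <- counts
    return(full)
  }
  if (length(counts) != length(species)) {
    stop("unnamed abundance vector must have one entry per species-table row")
  }
  stats::setNames(as.numeric(counts), species)
}

validate_species_table <- function(st) {
  st <- as.data.frame(st, stringsAsFactors = FALSE)
  needed <- c("species", "genus", "family", "order")
  miss <- setdiff(needed, names(st))
  if (length(miss) > 0) {
    stop("species table lacks columns: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(st$species)) {
    stop("species identifiers must be unique")
  }
  lab <- st[needed[-1]]
  if (any(vapply(lab, function(x) any(is.na(x) | !nzchar(x)), logical(1)))) {
    stop("taxonomy labels must be non-empty")
  }
  # genus nesting: one genus may not straddle families, nor a family orders
  for (pair in list(c("genus", "family"), c("family", "order"))) {
    k <- tapply(st[[pair[2]]], st[[pair[1]]], function(x) length(unique(x)))
    if (any(k > 1)) {
      stop("taxonomy is not nested: ", pair[1], " ",
           paste(names(k)[k > 1], collapse = ", "),
           " spans several ", pair[2], " labels")
    }
  }
  st
}

#' Standardized latitudinal centres of distribution
#'
#' z-scores each species' COD latitude using the mean and population variance
#' (1/n) over the pool of all species ever observed in the dataset. The
#' standardization is computed once per dataset, not per survey.
#'
#' @param species_table Species metadata with a `cod_latitude` column.
#' @param observed Character vector of species ever observed (defaults to all).
#' @return Named numeric vector of z-scored CODs for the observed pool.
#' @export
standardized_cod <- function(species_table, observed = NULL) {
  st <- validate_species_table(species_table)
  if (!"cod_latitude" %in% names(st)) {
    stop("species table lacks column cod_latitude")
  }
  if (is.null(observed)) observed <- st$species
  if (!all(observed %in% st$species)) {
    stop("species missing from the species table: ",
         paste(setdiff(observed, st$species), collapse = ", "))
  }
  cod <- st$cod_latitude[match(observed, st$species)]
  if (any(!is.finite(cod))) stop("COD latitudes must be finite")
  v <- pop_var(cod)
  if (v <= 0) stop("degenerate COD distribution: all CODs equal")
  stats::setNames((cod - mean(cod)) / sqrt(v), observed)
}

#' Community mean of standardized COD
#'
#' Proportion-weighted mean of standardized CODs over present species:
#' cCOD = sum_i p_i z_i. Tracks the low-latitude affinity of the community.
#'
#' @param p Named proportion vector over present species (sums to 1).
#' @param z Named z-scored COD vector covering at least the species in `p`.
#' @return Scalar cCOD.
#' @export
community_cod <- function(p, z) {
  if (abs(sum(p) - 1) > 1e-8) stop("proportions must sum to 1")
  if (is.null(names(p)) || !all(names(p) %in% names(z))) {
    stop("every present species needs a standardized COD")
  }
  sum(p * z[names(p)])
}

#' Indicator order used throughout the package
#' @export
indicator_names <- function() {
  c("S", "N", "p_max", "D", "H", "E_D", "E_H", "E_var", "delta", "cCOD")
}

#' Biodiversity indicator time series
#'
#' Computes the ten biodiversity indicators (richness S, total abundance N,
#' dominance p_max, Simpson D, Shannon H', Simpson evenness E_D, Shannon
#' evenness E_H, Smith-Wilson evenness E_var, taxonomic diversity delta, and
#' community COD) for every survey of a community time series. Surveys with an
#' empty community yield a row of NA with a warning; single-species surveys
#' yield NA for the undefined evenness indicators.
#'
#' @param community A `community_ts` (see [community_ts()]) or a surveys x
#'   species abundance matrix with species column names.
#' @param species_table Species metadata covering every species column.
#' @return Data frame with one row per survey: a `date` column followed by the
#'   ten indicator columns in the order of [indicator_names()].
#' @export
indicator_time_series <- function(community, species_table) {
  ct <- as_community_ts(community)
  st <- validate_species_table(species_table)
  missing <- setdiff(colnames(ct$abundance), st$species)
  if (length(missing) > 0) {
    stop("species missing from the species table: ",
         paste(missing, collapse = ", "))
  }
  observed <- colnames(ct$abundance)[colSums(ct$abundance) > 0]
  z <- standardized_cod(st, observed)
  n_surv <- nrow(ct$abundance)
  out <- as.data.frame(matrix(NA_real_, n_surv, 10,
                              dimnames = list(NULL, indicator_names())))
  for (i in seq_len(n_surv)) {
    counts <- ct$abundance[i, ]
    if (sum(counts) == 0) {
      warning("survey ", format(ct$date[i]),
              " has an empty community; indicators set to NA")
      next
    }
    a <- alpha_indicators(counts)
    p <- relative_abundances(counts)
    out[i, ] <- c(a$S, a$N, a$p_max, a$D, a$H, a$E_D, a$E_H, a$E_var,
                  taxonomic_diversity(counts, st),
                  community_cod(p, z))
  }
  cbind(date = ct$date, out)
}
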