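# Independent brute-force simplex oracle: explicit loops, exhaustive neighbor
# sort, and a recomputed weighted mean. Mirrors only the *stated* rules
# (E+1 neighbours, exp(-d/dmin) weights, exclusion of the target time and of
# library points whose future overlaps the target's coordinate span).
brute_simplex <- function(library, targets = library, E, tau = 1, Tp = 1,
                          lib_start = 1, tgt_start = lib_start) {
  embed_pts <- function(x, start) {
    first <- (E - 1) * tau + 1
    pts <- list()
    for (t in seq(first, length(x))) {
      if (t + Tp <= length(x)) {
        pts[[length(pts) + 1]] <- list(
          coord = x[t - (0:(E - 1)) * tau],
          future = x[t + Tp],
          time = t + start - 1)
      }
    }
    pts
  }
  lib <- embed_pts(library, lib_start)
  tgt <- embed_pts(targets, tgt_start)
  pred <- obs <- numeric(length(tgt))
  for (i in seq_along(tgt)) {
    tt <- tgt[[i]]$time
    ok <- Filter(function(p) {
      fut_t <- p$time + Tp
      p$time != tt && !(fut_t >= tt - (E - 1) * tau && fut_t <= tt)
    }, lib)
    d <- vapply(ok, function(p) sqrt(sum((p$coord - tgt[[i]]$coord)^2)),
                numeric(1))
    sel <- order(d)[seq_len(E + 1)]
    dn <- d[sel]
    fn <- vapply(ok[sel], `[[`, numeric(1), "future")
    w <- if (dn[1] == 0) as.numeric(dn == 0) else exp(-dn / dn[1])
    pred[i] <- sum(w * fn) / sum(w)
    obs[i] <- tgt[[i]]$future
  }
  list(predicted = pred, observed = obs)
}

pop_sd_oracle <- function(x) sqrt(mean((x - mean(x))^2))
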