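test_that("relative abundances are proportions over present species", {
  expect_equal(relative_abundances(c(10, 10, 10, 10)), rep(0.25, 4))
  expect_equal(relative_abundances(c(3, 1)), c(0.75, 0.25))
  p <- relative_abundances(c(a = 2, b = 0, c = 6))
  expect_named(p, c("a", "c"))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_error(relative_abundances(c(0, 0)), "empty community")
  expect_error(relative_abundances(c(1.5, 2)), "integer")
})

test_that("equal-abundance communities have maximal evenness", {
  for (S in c(2, 3, 5, 9, 40)) {
    a <- alpha_indicators(rep(7, S))
    expect_equal(a$D, 1 - 1 / S)
    expect_equal(a$E_D, 1)
    expect_equal(a$E_H, 1)
    expect_equal(a$E_var, 1)
    expect_equal(a$H, log(S))
    expect_equal(a$p_max, 1 / S)
  }
})

test_that("uneven two-species survey matches the closed forms", {
  a <- alpha_indicators(c(3, 1))
  expect_equal(a$S, 2)
  expect_equal(a$N, 4)
  expect_equal(a$p_max, 0.75)
  expect_equal(a$D, 1 - 0.75^2 - 0.25^2, tolerance = 1e-12)
  H <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expect_equal(a$H, H, tolerance = 1e-12)
  expect_equal(a$E_D, (1 - 0.75^2 - 0.25^2) * 2, tolerance = 1e-12)
  expect_equal(a$E_H, H / log(2), tolerance = 1e-12)
  v <- mean((log(c(3, 1)) - mean(log(c(3, 1))))^2)
  expect_equal(a$E_var, 1 - (2 / pi) * atan(v), tolerance = 1e-12)
})

test_that("single-species surveys flag undefined evenness", {
  a <- alpha_indicators(c(5))
  expect_equal(a$S, 1)
  expect_equal(a$N, 5)
  expect_equal(a$p_max, 1)
  expect_equal(a$D, 0)
  expect_equal(a$H, 0)
  expect_equal(a$E_var, 1)
  expect_true(is.na(a$E_D) && is.na(a$E_H))
})

test_that("indicator bounds hold on random communities", {
  set.seed(101)
  for (i in 1:50) {
    S_pool <- sample(2:30, 1)
    counts <- rpois(S_pool, lambda = sample(1:20, 1)) + rbinom(S_pool, 1, 0.5)
    if (sum(counts) == 0) counts[1] <- 1
    a <- alpha_indicators(counts)
    expect_gte(a$D, 0); expect_lt(a$D, 1)
    expect_lte(a$D, 1 - 1 / a$S + 1e-12)
    expect_gte(a$H, 0); expect_lte(a$H, log(a$S) + 1e-12)
    expect_gte(a$p_max, 1 / a$S); expect_lte(a$p_max, 1)
    expect_gt(a$E_var, 0); expect_lte(a$E_var, 1)
    # permuting species order leaves every indicator unchanged
    perm <- sample(length(counts))
    expect_identical(unlist(a), unlist(alpha_indicators(counts[perm])))
  }
})

test_that("Shannon and Simpson agree with vegan on random communities", {
  skip_if_not_installed("vegan")
  set.seed(11)
  for (i in 1:10) {
    counts <- rpois(15, 5); counts[1] <- counts[1] + 1
    a <- alpha_indicators(counts)
    expect_equal(a$H, unname(vegan::diversity(counts, "shannon")),
                 tolerance = 1e-12)
    expect_equal(a$D, unname(vegan::diversity(counts, "simpson")),
                 tolerance = 1e-12)
  }
})

test_that("taxonomic diversity matches hand enumeration and vegan", {
  st <- tax3()
  # single between-species pair in one genus: delta = weight = 1
  st2 <- data.frame(species = c("x", "y"), genus = "g", family = "f",
                    order = "o", cod_latitude = c(1, 2))
  expect_equal(taxonomic_diversity(c(1, 1), st2), 1)
  # no between-species pairs
  expect_equal(taxonomic_diversity(c(5, 0, 0), st), 0)
  expect_true(is.na(taxonomic_diversity(c(1, 0, 0), st)))
  # hand enumeration: w12=2 (family), w13=w23=4 (different order)
  expect_equal(taxonomic_diversity(c(2, 1, 1), st), 16 / 6, tolerance = 1e-12)
  skip_if_not_installed("vegan")
  w <- taxonomic_weights(st)
  td <- vegan::taxondive(matrix(c(2, 1, 1), 1), as.dist(w))
  expect_equal(taxonomic_diversity(c(2, 1, 1), st), unname(td$D),
               tolerance = 1e-12)
})

test_that("relabelling a congeneric pair to different orders raises delta", {
  st <- data.frame(species = c("a", "b", "c"),
                   genus = c("g1", "g1", "g2"),
                   family = c("f1", "f1", "f2"),
                   order = c("o1", "o1", "o1"),
                   cod_latitude = 1:3)
  base <- taxonomic_diversity(c(2, 3, 1), st)
  st_split <- st
  st_split$genus <- c("g1", "g9", "g2")
  st_split$family <- c("f1", "f9", "f2")
  st_split$order <- c("o1", "o9", "o1")
  expect_gt(taxonomic_diversity(c(2, 3, 1), st_split), base)
  # renaming labels bijectively changes nothing
  st_ren <- st
  st_ren$genus <- paste0("G_", st$genus)
  st_ren$family <- paste0("F_", st$family)
  st_ren$order <- paste0("O_", st$order)
  expect_equal(taxonomic_diversity(c(2, 3, 1), st_ren), base)
})

test_that("taxonomy validation rejects broken nesting and blanks", {
  st <- tax3()
  st$family <- c("f1", "f1", "f1")  # f1 now spans o1 and o2
  expect_error(validate <- taxonomic_weights(st), "not nested")
  st2 <- tax3(); st2$genus[2] <- ""
  expect_error(taxonomic_weights(st2), "non-empty")
})

test_that("COD standardization is a population z-score over the pool", {
  st2 <- data.frame(species = c("a", "b"), genus = c("g1", "g2"),
                    family = c("f1", "f2"), order = c("o1", "o2"),
                    cod_latitude = c(20, 40))
  expect_equal(unname(standardized_cod(st2)), c(-1, 1))
  st2$cod_latitude <- c(30, 30)
  expect_error(standardized_cod(st2), "degenerate COD")
  z <- standardized_cod(tax3())
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(mean(z^2), 1, tolerance = 1e-12)
})

test_that("community COD is the proportion-weighted mean of z-scores", {
  expect_equal(community_cod(c(a = 1), c(a = 1.7)), 1.7)
  expect_equal(community_cod(c(a = 0.75, b = 0.25), c(a = -1, b = 1)), -0.5)
  expect_equal(community_cod(c(a = 0.5, b = 0.3, c = 0.2),
                             c(a = -1.2, b = 0.3, c = 0.9)), -0.33)
  # equal proportions over the whole pool average the z-scores to 0
  z <- standardized_cod(tax3())
  p <- setNames(rep(1 / 3, 3), names(z))
  expect_equal(community_cod(p, z), 0, tolerance = 1e-12)
})

test_that("indicator time series has one row per survey in Table order", {
  st <- tax3()
  m <- rbind(c(2, 1, 1), c(0, 3, 2), c(1, 0, 0), c(4, 4, 4))
  colnames(m) <- st$species
  ct <- community_ts(m, as.Date("2020-01-01") + (0:3) * 30)
  ind <- indicator_time_series(ct, st)
  expect_equal(nrow(ind), 4)
  expect_equal(names(ind), c("date", indicator_names()))
  expect_equal(ind$S, c(3, 2, 1, 3))
  expect_true(is.na(ind$E_D[3]))  # single-species survey
  # single survey input
  ind1 <- indicator_time_series(ct$abundance[1, , drop = FALSE], st)
  expect_equal(nrow(ind1), 1)
  # empty community propagates NA with a warning
  m2 <- m; m2[2, ] <- 0
  expect_warning(
    ind2 <- indicator_time_series(community_ts(m2, ct$date), st),
    "empty community")
  expect_true(all(is.na(ind2[2, indicator_names()])))
  # unknown species are reported by name
  m3 <- cbind(m, ghost = 1)
  expect_error(indicator_time_series(community_ts(m3, ct$date), st), "ghost")
  # permuting species columns changes nothing
  perm <- c(3, 1, 2)
  ind_p <- indicator_time_series(community_ts(m[, perm], ct$date), st)
  expect_equal(ind_p, ind)
})
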