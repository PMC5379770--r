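make_geno <- function(cols) {
  # build a markers x individuals matrix from a list of genotype vectors
  m <- do.call(rbind, cols)
  rownames(m) <- paste0("M", seq_len(nrow(m)))
  m
}

test_that("two-point rf and LOD match the closed forms", {
  x <- rep(c("aa", "ab"), 50)
  st <- pairwise_rf_lod(make_geno(list(x, x)))
  expect_equal(st$rf[1, 2], 0)
  expect_equal(st$lod[1, 2], 100 * log10(2), tolerance = 1e-3)
  y <- x; y[1:50] <- ifelse(x[1:50] == "aa", "ab", "aa")   # R = 50
  st <- pairwise_rf_lod(make_geno(list(x, y)))
  expect_equal(st$rf[1, 2], 0.5)
  expect_equal(st$lod[1, 2], 0, tolerance = 1e-9)
  z <- x; z[1:10] <- ifelse(x[1:10] == "aa", "ab", "aa")   # R = 10
  st <- pairwise_rf_lod(make_geno(list(x, z)))
  expect_equal(st$rf[1, 2], 0.1)
  expect_equal(st$lod[1, 2], 15.985, tolerance = 1e-3)
})

test_that("LOD decreases in R and missing pairs are flagged", {
  x <- rep(c("aa", "ab"), 10)
  lods <- vapply(0:10, function(R) {
    y <- x
    if (R > 0) y[seq_len(R)] <- ifelse(x[seq_len(R)] == "aa", "ab", "aa")
    pairwise_rf_lod(make_geno(list(x, y)))$lod[1, 2]
  }, numeric(1))
  expect_true(all(diff(lods) < 0))
  # a pair with no joint observations is unavailable
  a <- c("aa", "aa", "--", "--")
  b <- c("--", "--", "ab", "ab")
  st <- pairwise_rf_lod(make_geno(list(a, b)))
  expect_true(is.na(st$rf[1, 2]) && is.na(st$lod[1, 2]))
})

test_that("LOD grouping yields connected components and drops singletons", {
  f1 <- sim_small(seed = 41, lg_lengths = c(80, 80), markers = 10,
                  n_off = 100, err = 0)
  gm <- build_genotype_matrix(f1$counts)
  st <- pairwise_rf_lod(gm)
  grp <- group_markers(st, 5)
  expect_length(grp$groups, 2L)
  truth_lg <- stats::setNames(f1$truth$markers$lg, f1$truth$markers$marker_id)
  for (g in grp$groups) expect_length(unique(truth_lg[g]), 1L)
  # an impossibly high threshold drops everything
  grp_inf <- group_markers(st, 1e9)
  expect_length(grp_inf$groups, 0L)
  expect_length(grp_inf$dropped, 20L)
})

test_that("annealed orders reach the exhaustive SARF minimum on small sets", {
  set.seed(55)
  for (rep in 1:4) {
    m <- sample(4:7, 1)
    f <- sim_small(seed = 100 + rep, lg_lengths = 60, markers = m,
                   n_off = 80)
    gm <- build_genotype_matrix(f$counts)
    st <- pairwise_rf_lod(gm)
    rf <- st$rf; rf[is.na(rf)] <- 0.5
    ord <- order_markers(st$rf, seed = rep)
    expect_equal(attr(ord, "sarf"), sarf_exhaustive(rf), tolerance = 1e-9)
  }
})

test_that("a marker order and its reversal have equal SARF", {
  f <- sim_small(seed = 61, markers = 15, n_off = 80)
  st <- pairwise_rf_lod(build_genotype_matrix(f$counts))
  ord <- order_markers(st$rf, seed = 1)
  expect_equal(sarf(ord, st$rf), sarf(rev(ord), st$rf))
  # canonical orientation: the first id sorts before the last
  expect_true(ord[1] < ord[length(ord)])
})

test_that("ordering recovers a simulated 50-marker group", {
  f <- sim_small(seed = 71, lg_lengths = 100, markers = 50, n_off = 148)
  gm <- build_genotype_matrix(f$counts)
  st <- pairwise_rf_lod(gm)
  ord <- order_markers(st$rf, seed = 1)
  tp <- f$truth$markers$cM[match(ord, f$truth$markers$marker_id)]
  tau <- abs(stats::cor(seq_along(ord), tp, method = "kendall"))
  expect_gte(tau, 0.95)
})

test_that("error correction erases confident singletons and nothing else", {
  # clean matrix: fixed point
  base <- matrix(rep(c("aa", "ab"), each = 11), 11, 2,
                 dimnames = list(paste0("M", 1:11), c("i1", "i2")))
  sm <- smooth_correct(base)
  expect_identical(sm$geno, base)
  expect_equal(nrow(sm$changes), 0L)
  # a flipped genotype surrounded by consistent neighbours becomes missing
  flip <- base; flip[6, 1] <- "ab"
  sm <- smooth_correct(flip)
  expect_equal(sm$geno[6, 1], "--")
  expect_equal(nrow(sm$changes), 1L)
  expect_identical(sm$geno[-6, ], base[-6, ])
  # a fully missing column is untouched
  miss <- base; miss[, 2] <- "--"
  sm <- smooth_correct(miss)
  expect_identical(sm$geno[, 2], miss[, 2])
})

test_that("knn imputation votes among nearest markers with near-tie rule", {
  g <- matrix(c("ab", "ab", "--", "ab", "ab"), 5, 1,
              dimnames = list(paste0("M", 1:5), "i1"))
  expect_equal(knn_impute(g, k = 4)$geno[3, 1], "ab")
  # k = 1 copies the nearest informative marker
  g2 <- matrix(c("aa", "--", "ab", "ab"), 4, 1,
               dimnames = list(paste0("M", 1:4), "i1"))
  expect_equal(knn_impute(g2, k = 1)$geno[2, 1], "aa")
  # 2-2 vote: the genotype of the nearest tied marker wins
  g3 <- matrix(c("aa", "--", "ab", "ab", "aa"), 5, 1,
               dimnames = list(paste0("M", 1:5), "i1"))
  expect_equal(knn_impute(g3, k = 4,
                          positions = c(1, 2, 3.5, 4, 2.9))$geno[2, 1], "aa")
  # non-missing cells are never altered; empty columns are reported
  g4 <- cbind(g2, i2 = rep("--", 4))
  out <- knn_impute(g4, k = 2)
  expect_identical(out$geno[c(1, 3, 4), "i1"], g2[c(1, 3, 4), 1])
  expect_equal(out$unimputable, "i2")
})

test_that("map functions match closed forms and invert exactly", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi(0.25), 25 * log(3), tolerance = 1e-12)
  expect_equal(kosambi(0.1), 25 * log(1.5), tolerance = 1e-12)
  r <- seq(0, 0.49, by = 0.01)
  expect_lt(max(abs(kosambi_inverse(kosambi(r)) - r)), 1e-12)
  expect_lt(max(abs(haldane_inverse(haldane(r)) - r)), 1e-12)
  # Kosambi distance dominates 100r and blows up near 0.5
  expect_true(all(kosambi(r) >= 100 * r - 1e-9))
  expect_gt(kosambi(0.4999), 200)
  expect_error(kosambi(0.5))
  expect_error(kosambi(-0.01))
})

test_that("map summaries reproduce the six-group arithmetic", {
  lens <- c(184.18, 187.43, 201.28, 194.01, 180.41, 178.66)
  cnts <- c(903, 922, 446, 552, 411, 846)
  gaps <- c(0.94, 3.95, 4.44, 10.38, 7.31, 9.78)
  snps <- c(1329, 1361, 602, 798, 576, 1200)
  s <- map_summary_table(lens, cnts, gaps, snps)
  expect_equal(s$totals$length_cM, 1125.97)
  expect_equal(s$totals$mean_lg_length_cM, 187.66)
  expect_equal(s$totals$n_markers, 4080)
  expect_equal(s$totals$snp_count, 5866)
  expect_equal(s$totals$max_gap_cM, 10.38)
  # length/count average, rounded half-up: 201.28/446 -> 0.45
  expect_equal(s$per_lg$avg_distance_cM[3], 0.45)
  expect_equal(s$per_lg$avg_distance_cM[4], 0.35)
  # overall average = mean of per-LG averages
  expect_equal(s$totals$avg_distance_cM,
               round_half_up(mean(s$per_lg$avg_distance_cM), 2))
})

test_that("assembled maps cumulate Kosambi distances and handle singletons", {
  rf <- matrix(0, 3, 3, dimnames = list(paste0("M", 1:3), paste0("M", 1:3)))
  rf["M1", "M2"] <- rf["M2", "M1"] <- 0.1
  rf["M2", "M3"] <- rf["M3", "M2"] <- 0.25
  m <- assemble_map(list(c("M1", "M2", "M3")), rf)
  expect_equal(m$map$position_cM, c(0, 25 * log(1.5), 25 * log(1.5) +
                                      25 * log(3)), tolerance = 1e-9)
  m1 <- assemble_map(list("M1"), rf)
  expect_equal(m1$summary$length_cM, 0)
  expect_equal(m1$summary$avg_distance_cM, 0)
  expect_equal(m1$summary$max_gap_cM, 0)
})

test_that("a simulated 100 cM group is recovered within 15% of its length", {
  f <- sim_small(seed = 1, lg_lengths = 100, markers = 51, n_off = 148)
  gm <- build_genotype_matrix(f$counts)
  st <- pairwise_rf_lod(gm)
  ord <- order_markers(st$rf, seed = 1)
  sm <- smooth_correct(gm$geno[ord, ])
  imp <- knn_impute(sm$geno)
  st2 <- pairwise_rf_lod(imp$geno)
  ord2 <- order_markers(st2$rf, ord, seed = 1)
  sm2 <- smooth_correct(gm$geno[ord2, ])
  st3 <- pairwise_rf_lod(knn_impute(sm2$geno)$geno)
  m <- assemble_map(list(ord2), st3)
  est <- max(m$map$position_cM)
  truth_len <- diff(range(f$truth$markers$cM))
  expect_lt(abs(est - truth_len) / truth_len, 0.15)
  # correction and imputation never produce illegal codes
  expect_true(all(knn_impute(sm2$geno)$geno %in% c("aa", "ab", "--")))
})
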