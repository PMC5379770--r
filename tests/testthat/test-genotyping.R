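test_that("phred quality and error rate convert exactly", {
  expect_equal(q_from_error(0.001), 30)
  expect_equal(q_from_error(1), 0)
  expect_equal(q_from_error(0.01), 20)
  e <- c(1e-4, 0.003, 0.2, 1)
  expect_equal(error_from_q(q_from_error(e)), e, tolerance = 1e-12)
  expect_error(q_from_error(0))
  expect_error(q_from_error(-0.1))
})

test_that("tag clustering is single-linkage on strict 95% identity", {
  a <- rand_seq(100, seed = 21)
  expect_length(cluster_tags(c(a, a)), 1L)
  # 10 mismatches in 100 bp: identity 0.90, not grouped
  b10 <- mutate_seq(a, 10, seed = 22)$seq
  expect_length(cluster_tags(c(a, b10)), 2L)
  # chain A~B 0.97, B~C 0.97 but A~C 0.94 still forms one group
  mb <- mutate_seq(a, 3, seed = 23)
  mc <- mutate_seq(mb$seq, 3, avoid = mb$pos, seed = 24)
  expect_length(cluster_tags(c(a, mb$seq, mc$seq)), 1L)
  # input order does not change the grouping
  g1 <- cluster_tags(c(a, mb$seq, b10))
  g2 <- cluster_tags(c(b10, mb$seq, a))
  expect_identical(g1, g2)
  expect_identical(cluster_tags(character(0)), list())
})

test_that("group filters fire in order with one reason each", {
  g_low <- make_group(c("AAAA", "AAAT"), parent_depth = c(9, 9))
  g_rep <- make_group(c("AAAA", "AAAT", "AATT", "ATTT", "TTTT"))
  g_amb <- make_group(c("AAAA", "AAAT"), tag_reads = c(100, 1))
  g_ok <- make_group(c("AAAA", "AAAT"), tag_reads = c(22, 18))
  res <- filter_groups(list(g_low, g_rep, g_amb, g_ok))
  expect_equal(res$removed$reason, c("low", "repeat", "ambiguous"))
  expect_length(res$kept, 1L)
  # CV of (100, 1) is about 1.386, above the default 1.0 cut
  expect_equal(stats::sd(c(100, 1)) / mean(c(100, 1)), 1.3861, tolerance = 1e-4)
  # partition property: kept plus removed covers the input exactly once
  expect_equal(length(res$kept) + nrow(res$removed), 4L)
  # a group failing several rules is charged to the first one
  g_multi <- make_group(rep("AAAA", 6), parent_depth = c(5, 5))
  expect_equal(filter_groups(list(g_multi))$removed$reason, "low")
})

test_that("polymorphism classification follows tag counts per parent", {
  expect_equal(classify_polymorphism(make_group("AAAA")), "non_polymorphic")
  g3m <- make_group(c("AAAA", "AAAT", "AATT"), tags_maternal = 3)
  expect_equal(classify_polymorphism(g3m), "repetitive")
  g2 <- make_group(c("AAAA", "AAAT"), tags_maternal = 1)
  expect_equal(classify_polymorphism(g2), "polymorphic")
  g_empty <- make_group(character(0))
  expect_error(classify_polymorphism(g_empty), "no tags")
})

test_that("segregation patterns encode all standard parental combinations", {
  cases <- list(
    list(c("a", "b"), c("c", "d"), "abxcd", c("ac", "ad", "bc", "bd", "--")),
    list(c("e", "f"), c("e", "g"), "efxeg", c("ee", "ef", "eg", "fg", "--")),
    list(c("h", "k"), c("h", "k"), "hkxhk", c("hh", "hk", "kk", "--")),
    list(c("l", "m"), "ll", "lmxll", c("lm", "ll", "--")),
    list("nn", c("n", "p"), "nnxnp", c("nn", "np", "--")),
    list("aa", "bb", "aaxbb", c("aa", "bb", "ab", "--")),
    list(c("a", "b"), "cc", "abxcc", c("ac", "bc", "--")),
    list("cc", c("a", "b"), "ccxab", c("ac", "bc", "--")))
  for (cs in cases) {
    enc <- encode_segregation_pattern(cs[[1]], cs[[2]])
    expect_equal(enc$pattern, cs[[3]])
    expect_setequal(enc$offspring_codes, cs[[4]])
  }
  expect_error(encode_segregation_pattern("aa", "aa"), "identical")
  expect_error(encode_segregation_pattern(c("a", "b", "c"), "aa"))
})

test_that("genotype calling uses depth and read-fraction thresholds", {
  expect_equal(call_genotype(c(10, 0)), "aa")
  expect_equal(call_genotype(c(5, 5)), "ab")
  expect_equal(call_genotype(c(2, 1)), "--")   # depth 3 below min_depth 4
  expect_equal(call_genotype(c(0, 12)), "bb")
  expect_equal(call_genotype(c(9, 1)), "aa")   # fraction exactly 0.9
  expect_equal(call_genotype(c(8, 2)), "ab")
  expect_equal(call_genotype(c(2, 1), min_depth = 3), "ab")  # 2/3 in between
  expect_error(call_genotype(c(-1, 5)))
})

test_that("distortion test matches the 1-df chi-square closed form", {
  r <- segregation_distortion_test(74, 74)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  r <- segregation_distortion_test(90, 58)
  expect_equal(r$chi2, 32^2 / 148, tolerance = 1e-12)
  expect_equal(r$p, 0.0085289, tolerance = 1e-4)
  r <- segregation_distortion_test(100, 48)
  expect_equal(r$chi2, 52^2 / 148, tolerance = 1e-12)
  expect_equal(r$p, 1.9168e-05, tolerance = 1e-4)
  expect_error(segregation_distortion_test(0, 0))
  # exact binomial alternative stays close at moderate counts
  expect_equal(segregation_distortion_test(74, 74, exact = TRUE)$p, 1)
})

test_that("null 1:1 markers are filtered at close to the nominal 5% rate", {
  set.seed(77)
  n_mark <- 2000
  n_aa <- stats::rbinom(n_mark, 148, 0.5)
  p <- segregation_distortion_test(n_aa, 148 - n_aa)$p
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_mark))
})

test_that("marker quality filters apply in order on metadata", {
  meta <- data.frame(
    marker_id = paste0("M", 1:5),
    pattern = c("aaxbb", "aaxbb", "aaxbb", "aaxbb", "hkxhk"),
    maternal_depth = c(30, 8, 30, 30, 30),
    paternal_depth = c(30, 30, 30, 30, 30),
    integrity = c(1, 1, 88 / 148, 1, 1),
    snp_count = c(2, 2, 2, 8, 2),
    n_aa = c(74, 74, 44, 74, 74), n_ab = c(74, 74, 44, 74, 74),
    n_impossible = 0, chi2 = 0, p_distortion = 1)
  geno <- matrix("aa", 5, 148, dimnames = list(meta$marker_id, NULL))
  gm <- structure(list(geno = geno, meta = meta), class = "slaf_genmat")
  res <- marker_quality_filter(gm)
  expect_equal(res$kept$meta$marker_id, "M1")
  rep <- stats::setNames(res$report$n, res$report$rule)
  expect_equal(rep[["parent_depth"]], 1)
  expect_equal(rep[["integrity"]], 1)   # 88/148 = 59.46% < 60%
  expect_equal(rep[["snp_count"]], 1)
  expect_equal(rep[["not_aaxbb"]], 1)
  # a clean 74:74 marker with good depth passes every rule
  expect_equal(rep[["kept"]], 1)
})

test_that("distorted markers are removed at the configured alpha", {
  meta <- data.frame(
    marker_id = c("Ma", "Mb"), pattern = "aaxbb",
    maternal_depth = 30, paternal_depth = 30, integrity = 1,
    snp_count = 2, n_aa = c(90, 80), n_ab = c(58, 68), n_impossible = 0,
    chi2 = NA, p_distortion = segregation_distortion_test(
      c(90, 80), c(58, 68))$p)
  geno <- matrix("aa", 2, 148, dimnames = list(meta$marker_id, NULL))
  gm <- structure(list(geno = geno, meta = meta), class = "slaf_genmat")
  res <- marker_quality_filter(gm)
  expect_equal(res$kept$meta$marker_id, "Mb")  # 90:58 has p < 0.05
})

test_that("report percentages reproduce the printed-table arithmetic", {
  pr <- polymorphism_report(c(polymorphic = 27800,
                              non_polymorphic = 116814,
                              repetitive = 842))
  expect_equal(unname(pr$percentages), c(19.11, 80.31, 0.58))
  expect_equal(pr$total, 145456)
  expect_equal(effective_polymorphism(14840, 145456), 10.20)
  expect_equal(mapping_ratio(4080, 4092), 99.71)
  expect_equal(unname(polymorphism_report(c(10, 0, 0))$percentages),
               c(100, 0, 0))
  expect_error(polymorphism_report(c(0, 0, 0)))
})

test_that("most true aaxbb markers survive the full filter chain", {
  f <- sim_small(seed = 31, lg_lengths = c(100, 120), markers = 100,
                 n_off = 148)
  groups <- build_tag_groups(f$counts)
  filt <- filter_groups(groups)
  cls <- vapply(filt$kept, classify_polymorphism, character(1))
  gm <- build_genotype_matrix(f$counts, filt$kept[cls == "polymorphic"])
  res <- marker_quality_filter(gm)
  expect_gte(nrow(res$kept$meta) / nrow(f$truth$markers), 0.95)
  # pattern legality: only BC1-legal codes are present
  expect_true(all(res$kept$geno %in% c("aa", "ab", "--")))
})
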