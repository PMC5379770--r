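#' Phred quality from a per-base error probability
#'
#' `Q = -10 * log10(e)`; `error_from_q()` is its exact inverse. Q30 marks the
#' 0.1 percent per-base error rate used to screen raw tag reads.
#'
#' @param e error probability in `(0, 1]`
#' @return quality value Q
#' @export
q_from_error <- function(e) {
  if (any(!is.finite(e)) || any(e <= 0) || any(e > 1))
    stop("'e' must be in (0, 1]", call. = FALSE)
  -10 * log10(e)
}

#' @rdname q_from_error
#' @param q quality value (>= 0)
#' @export
error_from_q <- function(q) {
  if (any(!is.finite(q)) || any(q < 0)) stop("'q' must be >= 0", call. = FALSE)
  10^(-q / 10)
}

.pairwise_identity <- function(seqs) {
  # fraction of matching positions between equal-length sequences,
  # computed via per-nucleotide indicator cross-products
  L <- nchar(seqs[1])
  m <- do.call(rbind, strsplit(seqs, ""))
  acc <- matrix(0, length(seqs), length(seqs))
  for (n in NUCS) {
    ind <- (m == n) * 1
    acc <- acc + tcrossprod(ind)
  }
  acc / L
}

#' Cluster tag sequences into loci by sequence identity
#'
#' Single-linkage grouping of fixed-length tag sequences: two tags join the
#' same locus when their pairwise identity (matching positions / length)
#' exceeds the threshold, directly or through a chain of intermediates.
#' Input order does not matter; tags are processed in lexicographic order.
#'
#' @param tag_sequences character vector of equal-length A/C/G/T sequences
#' @param identity_threshold identity that must be strictly exceeded,
#'   in `(0.5, 1]`
#' @return list of character vectors, one per locus, in order of each
#'   group's lexicographically smallest member
#' @export
cluster_tags <- function(tag_sequences, identity_threshold = 0.95) {
  if (length(tag_sequences) == 0) return(list())
  if (identity_threshold <= 0.5 || identity_threshold > 1)
    stop("'identity_threshold' must be in (0.5, 1]", call. = FALSE)
  if (length(unique(nchar(tag_sequences))) != 1)
    stop("tag sequences must have equal length", call. = FALSE)
  seqs <- sort(tag_sequences)
  n <- length(seqs)
  idm <- .pairwise_identity(seqs)
  parent <- seq_len(n)
  find2 <- function(i) { r <- i; while (parent[r] != r) r <- parent[r]; r }
  edges <- which(upper.tri(idm) & idm > identity_threshold, arr.ind = TRUE)
  if (nrow(edges)) for (e in seq_len(nrow(edges))) {
    ri <- find2(edges[e, 1]); rj <- find2(edges[e, 2])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), find2, integer(1))
  unname(lapply(split(seqs, roots), unname))
}

#' Build SLAF tag groups from a simulated count table
#'
#' Clusters all parental tag sequences and assembles, per resulting locus, the
#' member tags with their per-parent depths, per-tag total read counts and the
#' marker ids contributing tags. Loci whose tags come from more than one true
#' marker (e.g. repeats collapsing) carry all contributing markers.
#'
#' @param counts an `slaf_counts`
#' @param identity_threshold passed to [cluster_tags()]
#' @return list of `tag_group` objects (id, tags, marker_ids, parent_depth
#'   c(maternal, paternal), tag_reads per tag)
#' @export
build_tag_groups <- function(counts, identity_threshold = 0.95) {
  stopifnot(inherits(counts, "slaf_counts"))
  tagseq <- c(counts$tags[, "maternal"], counts$tags[, "paternal"])
  origin <- rep(rownames(counts$tags), 2)
  parent_of <- rep(c("maternal", "paternal"), each = nrow(counts$tags))
  groups <- cluster_tags(tagseq, identity_threshold)
  lapply(seq_along(groups), function(g) {
    idx <- match(groups[[g]], tagseq)
    mk <- unique(origin[idx])
    pdep <- c(maternal = sum(counts$depth[mk, "P1_maternal"]),
              paternal = sum(counts$depth[mk, "P2_paternal"]))
    # per-tag reads: the originating parent's depth at the source marker
    treads <- vapply(idx, function(i) {
      pcol <- if (parent_of[i] == "maternal") "P1_maternal" else "P2_paternal"
      counts$depth[origin[i], pcol]
    }, numeric(1))
    # which parents carry each tag (a duplicated tag is carried by its source)
    in_mat <- parent_of[idx] == "maternal"
    structure(list(id = sprintf("G%05d", g),
                   tags = groups[[g]],
                   marker_ids = mk,
                   parent_depth = pdep,
                   tag_reads = treads,
                   tags_maternal = sum(in_mat),
                   tags_paternal = sum(!in_mat)),
              class = "tag_group")
  })
}

#' Filter tag groups by depth, repeat content and read-count spread
#'
#' Applies the three tag-level quality rules in order: `low` (either parental
#' depth below `min_parent_depth`), `repeat` (more distinct tags than
#' `max_tags`, impossible for a single diploid locus), `ambiguous`
#' (coefficient of variation of the per-tag read counts above `ambiguity_cv`).
#' Each removed group gets exactly the first reason that applies.
#'
#' @param groups list of `tag_group` objects
#' @param min_parent_depth minimum depth required in each parent
#' @param max_tags maximum distinct tags per locus
#' @param ambiguity_cv maximum sd/mean of per-tag read counts
#' @return list with `kept` (groups) and `removed` (data.frame id, reason)
#' @export
filter_groups <- function(groups, min_parent_depth = 10, max_tags = 4,
                          ambiguity_cv = 1.0) {
  reason <- vapply(groups, function(g) {
    if (min(g$parent_depth) < min_parent_depth) return("low")
    if (length(g$tags) > max_tags) return("repeat")
    cv <- if (length(g$tag_reads) > 1 && mean(g$tag_reads) > 0)
      stats::sd(g$tag_reads) / mean(g$tag_reads) else 0
    if (cv > ambiguity_cv) return("ambiguous")
    ""
  }, character(1))
  list(kept = groups[reason == ""],
       removed = data.frame(
         id = vapply(groups[reason != ""], `[[`, character(1), "id"),
         reason = reason[reason != ""]))
}

#' Classify a tag group's polymorphism type
#'
#' One tag in the whole group: non-polymorphic. More than two distinct tags in
#' a single parent: repetitive (a diploid parent carries at most two alleles).
#' Otherwise (2-4 tags): polymorphic, a candidate marker.
#'
#' @param group a `tag_group`
#' @return one of "polymorphic", "non_polymorphic", "repetitive"
#' @export
classify_polymorphism <- function(group) {
  n <- length(group$tags)
  if (n == 0) stop("group has no tags", call. = FALSE)
  if (n == 1) return("non_polymorphic")
  if (max(group$tags_maternal, group$tags_paternal) > 2) return("repetitive")
  "polymorphic"
}

.seg_patterns <- list(
  "abxcd" = c("ac", "ad", "bc", "bd", "--"),
  "efxeg" = c("ee", "ef", "eg", "fg", "--"),
  "hkxhk" = c("hh", "hk", "kk", "--"),
  "lmxll" = c("lm", "ll", "--"),
  "nnxnp" = c("nn", "np", "--"),
  "aaxbb" = c("aa", "bb", "ab", "--"),
  "abxcc" = c("ac", "bc", "--"),
  "ccxab" = c("ac", "bc", "--"))

#' Encode the segregation pattern of a marker from the parental genotypes
#'
#' Maps the paternal x maternal genotype pair onto the standard two-allele
#' encoding patterns (abxcd, efxeg, hkxhk, lmxll, nnxnp, aaxbb, abxcc, ccxab),
#' paternal genotype first. Only aaxbb (both parents homozygous for different
#' alleles) is fully informative in a BC1.
#'
#' @param paternal,maternal parental genotypes as length-1 or length-2
#'   character vectors of allele symbols (e.g. `c("a","b")` or `"ab"`)
#' @return list with `pattern` and the pattern's legal `offspring_codes`
#' @export
encode_segregation_pattern <- function(paternal, maternal) {
  norm <- function(g) {
    if (length(g) == 1 && nchar(g) == 2) g <- strsplit(g, "")[[1]]
    if (length(g) == 1) g <- c(g, g)
    if (length(g) != 2) stop("parental genotype must have 1 or 2 alleles",
                             call. = FALSE)
    sort(g)
  }
  p <- norm(paternal); m <- norm(maternal)
  p_het <- p[1] != p[2]; m_het <- m[1] != m[2]
  shared <- length(intersect(unique(p), unique(m)))
  pattern <-
    if (p_het && m_het) {
      if (shared == 0) "abxcd"
      else if (shared == 1) "efxeg"
      else "hkxhk"
    } else if (p_het && !m_het) {
      if (m[1] %in% p) "lmxll" else "abxcc"
    } else if (!p_het && m_het) {
      if (p[1] %in% m) "nnxnp" else "ccxab"
    } else {
      if (p[1] != m[1]) "aaxbb"
      else stop("identical homozygous parents carry no segregation pattern",
                call. = FALSE)
    }
  list(pattern = pattern, offspring_codes = .seg_patterns[[pattern]])
}

#' Call one genotype from two allele read counts
#'
#' Depth below `min_depth` gives a missing call. Otherwise, with `f` the
#' first-allele read fraction: `f >= hom_fraction` calls the first homozygote,
#' `f <= 1 - hom_fraction` the second, anything between is heterozygous.
#' These thresholds are pragmatic calling defaults of this package, exposed in
#' the configuration.
#'
#' @param allele_counts length-2 non-negative counts over the two parental
#'   alleles (first = recurrent-parent allele)
#' @param min_depth minimum total depth for a call
#' @param hom_fraction homozygote read-fraction threshold in `(0.5, 1]`
#' @return one of "aa", "bb", "ab", "--"
#' @export
call_genotype <- function(allele_counts, min_depth = 4, hom_fraction = 0.9) {
  if (length(allele_counts) != 2 || any(allele_counts < 0))
    stop("'allele_counts' must be two non-negative counts", call. = FALSE)
  d <- sum(allele_counts)
  if (d < min_depth) return("--")
  f <- allele_counts[1] / d
  if (f >= hom_fraction) "aa"
  else if (f <= 1 - hom_fraction) "bb"
  else "ab"
}

#' Chi-square test for segregation distortion against 1:1
#'
#' Plain 1-df goodness-of-fit chi-square without continuity correction
#' (`exact = TRUE` substitutes the two-sided exact binomial test).
#'
#' @param n_aa,n_ab genotype class counts (vectorized)
#' @param exact use `binom.test` instead of the chi-square approximation
#' @return data.frame with `chi2` and `p`
#' @export
segregation_distortion_test <- function(n_aa, n_ab, exact = FALSE) {
  n <- n_aa + n_ab
  if (any(n < 1)) stop("need at least one scored genotype", call. = FALSE)
  if (exact) {
    p <- mapply(function(a, tot) stats::binom.test(a, tot, 0.5)$p.value,
                n_aa, n)
    chi2 <- (n_aa - n_ab)^2 / n
  } else {
    chi2 <- (n_aa - n_ab)^2 / n
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  data.frame(chi2 = chi2, p = p)
}

#' Build the BC1 genotype matrix from filtered tag groups
#'
#' For every kept polymorphic locus backed by a single true marker, calls each
#' offspring from its two parental-allele read counts (reads of the two other
#' nucleotides are attributed to sequencing error and dropped). Calls of the
#' non-recurrent homozygote, which cannot arise in a BC1, are set missing and
#' counted. Marker metadata records the segregation pattern, parental depths,
#' integrity (fraction of non-missing offspring calls), SNP count and the 1:1
#' distortion p-value.
#'
#' @param counts an `slaf_counts`
#' @param groups kept `tag_group` list (default: all single-marker groups)
#' @param min_depth,hom_fraction passed to [call_genotype()]
#' @return object of class `slaf_genmat`: `geno` (character matrix markers x
#'   offspring of "aa"/"ab"/"--") and `meta` (data.frame of per-marker
#'   metadata)
#' @export
build_genotype_matrix <- function(counts, groups = NULL,
                                  min_depth = 4, hom_fraction = 0.9) {
  stopifnot(inherits(counts, "slaf_counts"))
  mk <- counts$markers
  if (is.null(groups)) {
    keep_ids <- mk$marker_id
  } else {
    keep_ids <- unlist(lapply(groups, function(g)
      if (length(g$marker_ids) == 1) g$marker_ids else character(0)))
    keep_ids <- intersect(mk$marker_id, keep_ids)
  }
  off <- setdiff(counts$individuals, counts$parents)
  geno <- matrix("--", length(keep_ids), length(off),
                 dimnames = list(keep_ids, off))
  impossible <- integer(length(keep_ids))
  for (r in seq_along(keep_ids)) {
    i <- match(keep_ids[r], mk$marker_id)
    ai <- mk$allele_a[i]; bi <- mk$allele_b[i]
    na <- counts$counts[i, off, ai]
    nb <- counts$counts[i, off, bi]
    d <- na + nb
    f <- ifelse(d > 0, na / d, NA_real_)
    code <- rep("--", length(off))
    ok <- d >= min_depth
    code[ok & f >= hom_fraction] <- "aa"
    code[ok & f <= 1 - hom_fraction] <- "bb"
    code[ok & f > 1 - hom_fraction & f < hom_fraction] <- "ab"
    impossible[r] <- sum(code == "bb")
    code[code == "bb"] <- "--"   # not a legal BC1 genotype
    geno[r, ] <- code
  }
  n_aa <- rowSums(geno == "aa")
  n_ab <- rowSums(geno == "ab")
  scored <- n_aa + n_ab
  dist <- data.frame(chi2 = NA_real_, p = NA_real_)[rep(1, length(keep_ids)), ]
  has <- scored >= 1
  if (any(has)) dist[has, ] <- segregation_distortion_test(n_aa[has], n_ab[has])
  idx <- match(keep_ids, mk$marker_id)
  meta <- data.frame(
    marker_id = keep_ids,
    pattern = "aaxbb",
    maternal_depth = counts$depth[idx, "P1_maternal"],
    paternal_depth = counts$depth[idx, "P2_paternal"],
    integrity = scored / length(off),
    snp_count = mk$snp_count[idx],
    n_aa = n_aa, n_ab = n_ab,
    n_impossible = impossible,
    chi2 = dist$chi2, p_distortion = dist$p,
    row.names = NULL)
  structure(list(geno = geno, meta = meta), class = "slaf_genmat")
}

#' Apply the four high-quality-marker filters
#'
#' Restricts the matrix to aaxbb markers (the only fully informative pattern
#' in a BC1), then removes markers in order by: parental depth below
#' `min_parent_depth` in either parent; integrity below `integrity_min`; SNP
#' count above `max_snp`; significant 1:1 segregation distortion at `alpha`.
#' Each removed marker is charged to the first failing rule.
#'
#' @param genmat an `slaf_genmat`
#' @param min_parent_depth,integrity_min,max_snp,alpha filter thresholds
#' @return list with `kept` (`slaf_genmat`) and `report` (data.frame of
#'   removal counts per rule)
#' @export
marker_quality_filter <- function(genmat, min_parent_depth = 10,
                                  integrity_min = 0.6, max_snp = 7,
                                  alpha = 0.05) {
  stopifnot(inherits(genmat, "slaf_genmat"))
  m <- genmat$meta
  reason <- rep("", nrow(m))
  reason[m$pattern != "aaxbb"] <- "not_aaxbb"
  sel <- reason == ""
  reason[sel & pmin(m$maternal_depth, m$paternal_depth) < min_parent_depth] <-
    "parent_depth"
  sel <- reason == ""
  reason[sel & m$integrity < integrity_min] <- "integrity"
  sel <- reason == ""
  reason[sel & m$snp_count > max_snp] <- "snp_count"
  sel <- reason == ""
  reason[sel & !is.na(m$p_distortion) & m$p_distortion < alpha] <- "distortion"
  keep <- reason == ""
  report <- data.frame(
    rule = c("not_aaxbb", "parent_depth", "integrity", "snp_count",
             "distortion", "kept"),
    n = c(sum(reason == "not_aaxbb"), sum(reason == "parent_depth"),
          sum(reason == "integrity"), sum(reason == "snp_count"),
          sum(reason == "distortion"), sum(keep)))
  kept <- structure(list(geno = genmat$geno[keep, , drop = FALSE],
                         meta = m[keep, , drop = FALSE]),
                    class = "slaf_genmat")
  list(kept = kept, report = report)
}

#' Polymorphism class percentages
#'
#' Percentages of polymorphic / non-polymorphic / repetitive loci, rounded
#' half-up to two decimals as in the package's printed reports.
#'
#' @param class_counts named or ordered counts (polymorphic, non_polymorphic,
#'   repetitive)
#' @return list with `counts`, `percentages` and `total`
#' @export
polymorphism_report <- function(class_counts) {
  if (any(class_counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(class_counts)
  if (total == 0) stop("total count is zero", call. = FALSE)
  pct <- round_half_up(100 * class_counts / total, 2)
  list(counts = class_counts, percentages = pct, total = total)
}

#' @rdname polymorphism_report
#' @param n_aaxbb count of fully informative aaxbb markers
#' @param total total high-quality loci
#' @return `effective_polymorphism()`: percentage of loci in the aaxbb
#'   pattern, 2 decimals
#' @export
effective_polymorphism <- function(n_aaxbb, total) {
  if (total <= 0) stop("total must be positive", call. = FALSE)
  round_half_up(100 * n_aaxbb / total, 2)
}

#' @rdname polymorphism_report
#' @param mapped markers placed on the map
#' @param available markers available for mapping
#' @return `mapping_ratio()`: percentage mapped, 2 decimals
#' @export
mapping_ratio <- function(mapped, available) {
  if (available <= 0) stop("available must be positive", call. = FALSE)
  round_half_up(100 * mapped / available, 2)
}
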