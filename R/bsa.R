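#' Pooled allele frequencies at each SNP
#'
#' Converts per-pool nucleotide counts to frequency 4-vectors (count/total
#' per pool). SNPs with zero depth in either pool carry no frequency
#' information and are excluded with a logged reason.
#'
#' @param pools data.frame with columns `A_F,C_F,G_F,T_F,A_M,C_M,G_M,T_M`
#'   (as produced by [build_pools()]) plus any identifier/position columns
#' @return list with `freq` (the usable rows, frequency columns `fA_F..fT_M`
#'   appended) and `excluded` (data.frame row id and reason)
#' @export
pool_allele_frequencies <- function(pools) {
  fc <- paste0(NUCS, "_F"); mc <- paste0(NUCS, "_M")
  stopifnot(all(c(fc, mc) %in% names(pools)))
  F <- as.matrix(pools[, fc]); M <- as.matrix(pools[, mc])
  if (any(F < 0) || any(M < 0))
    stop("pool counts must be non-negative", call. = FALSE)
  dF <- rowSums(F); dM <- rowSums(M)
  usable <- dF > 0 & dM > 0
  id <- pools$marker_id %||% seq_len(nrow(pools))
  excluded <- data.frame(
    id = id[!usable],
    reason = ifelse(dF[!usable] == 0 & dM[!usable] == 0, "zero_depth_both",
                    ifelse(dF[!usable] == 0, "zero_depth_F", "zero_depth_M")))
  out <- pools[usable, , drop = FALSE]
  ff <- F[usable, , drop = FALSE] / dF[usable]
  fm <- M[usable, , drop = FALSE] / dM[usable]
  colnames(ff) <- paste0("f", NUCS, "_F")
  colnames(fm) <- paste0("f", NUCS, "_M")
  list(freq = cbind(out, as.data.frame(ff), as.data.frame(fm)),
       excluded = excluded)
}

#' Euclidean distance between two pooled frequency vectors
#'
#' `ED = sqrt((A_F-A_M)^2 + (C_F-C_M)^2 + (G_F-G_M)^2 + (T_F-T_M)^2)`, the
#' allele-segregation statistic contrasted between the two phenotype pools.
#' It is 0 for identical pools and reaches `sqrt(2)` at a fully
#' differentiated biallelic site.
#'
#' @param freq_F,freq_M numeric 4-vectors of nucleotide frequencies, each
#'   summing to 1 (or matrices with 4 columns for the vectorized profile)
#' @return the ED value(s)
#' @export
ed <- function(freq_F, freq_M) {
  F <- rbind(freq_F); M <- rbind(freq_M)
  if (ncol(F) != 4 || ncol(M) != 4 || nrow(F) != nrow(M))
    stop("frequency inputs must be 4-vectors", call. = FALSE)
  if (any(!is.finite(F)) || any(!is.finite(M)) ||
      any(abs(rowSums(F) - 1) > 1e-6) || any(abs(rowSums(M) - 1) > 1e-6))
    stop("frequency vectors must each sum to 1", call. = FALSE)
  out <- sqrt(rowSums((F - M)^2))
  if (is.vector(freq_F) && length(freq_F) == 4) out[[1]] else out
}

#' Raise ED values to a power
#'
#' The ED profile is raised elementwise to `k` (default 5) before smoothing,
#' which suppresses background noise while preserving the ranking of sites
#' (the transform is strictly monotone on non-negative values).
#'
#' @param ed_values non-negative ED values
#' @param k exponent
#' @return `ed_values^k`
#' @export
ed_power <- function(ed_values, k = 5) {
  if (any(ed_values < 0)) stop("ED values must be >= 0", call. = FALSE)
  ed_values^k
}

#' LOESS smoothing of a statistic along one linkage group
#'
#' Local polynomial regression with tricube weights over the `span` fraction
#' of nearest neighbours, evaluated exactly at every input position
#' (`stats::loess` with `surface = "direct"`, so each fitted value is the
#' tricube-weighted least-squares fit at that point). With too few points for
#' a local fit the group falls back to its mean value, with a warning.
#'
#' @param positions_cM SNP positions on one linkage group
#' @param values statistic values (same length)
#' @param span fraction of points in each local neighbourhood
#' @param degree local polynomial degree (1 = local linear)
#' @return fitted values, same length and order as the input
#' @export
loess_fit <- function(positions_cM, values, span = 0.3, degree = 1) {
  n <- length(values)
  stopifnot(length(positions_cM) == n)
  if (n < 2) return(values)
  # need at least degree+2 points in the local window
  span_eff <- max(span, min(1, (degree + 2) / n + 1e-9))
  fit <- withCallingHandlers(
    tryCatch(
      stats::loess(values ~ positions_cM, span = span_eff, degree = degree,
                   family = "gaussian", surface = "direct")$fitted,
      error = function(e) {
        warning("LOESS fit failed (", conditionMessage(e),
                "); falling back to the group mean", call. = FALSE)
        rep(mean(values), n)
      }),
    warning = function(w) {
      # tied map positions make some local designs singular; the
      # pseudoinverse fit loess falls back on is the intended behaviour
      if (grepl("pseudoinverse|singularit|condition number",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  fit
}

#' Genome-wide association threshold: mean + c SD of the fitted values
#'
#' Computed over all fitted sites genome-wide with the sample (n-1) standard
#' deviation; sites whose fitted statistic exceeds this value are candidates
#' for trait-associated regions.
#'
#' @param fitted_values fitted statistic at every scanned SNP
#' @param sd_mult multiplier on the SD (default 3)
#' @return the threshold value
#' @export
association_threshold <- function(fitted_values, sd_mult = 3) {
  if (length(fitted_values) < 2)
    stop("need at least 2 fitted values", call. = FALSE)
  mean(fitted_values) + sd_mult * stats::sd(fitted_values)
}

#' Call trait-associated regions from a fitted genome scan
#'
#' Within each linkage group, maximal runs of consecutive SNPs whose fitted
#' value exceeds the threshold become candidate regions; runs separated by
#' less than `merge_gap_cM` are merged; merged runs carrying fewer than
#' `min_markers` above-threshold SNPs are dropped. Region size is
#' `end - start` in cM.
#'
#' @param positions data.frame with columns `lg` and `cM`, sorted by (lg, cM)
#' @param fitted fitted statistic per SNP (same order)
#' @param threshold association threshold
#' @param min_markers minimum above-threshold SNPs per region
#' @param merge_gap_cM merge runs closer than this many cM
#' @return data.frame with `lg`, `start_cM`, `end_cM`, `size_cM`, `n_markers`
#' @export
call_regions <- function(positions, fitted, threshold,
                         min_markers = 3, merge_gap_cM = 2) {
  stopifnot(nrow(positions) == length(fitted))
  out <- list()
  for (lg in unique(positions$lg)) {
    sel <- positions$lg == lg
    cm <- positions$cM[sel]
    if (is.unsorted(cm)) stop("positions must be sorted within LG",
                              call. = FALSE)
    above <- fitted[sel] > threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- data.frame(s = starts[r$values], e = ends[r$values])
    # merge runs separated by a small cM gap
    merged <- runs[1, , drop = FALSE]
    if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
      gap <- cm[runs$s[i]] - cm[merged$e[nrow(merged)]]
      if (gap < merge_gap_cM) merged$e[nrow(merged)] <- runs$e[i]
      else merged <- rbind(merged, runs[i, ])
    }
    for (i in seq_len(nrow(merged))) {
      idx <- merged$s[i]:merged$e[i]
      n_above <- sum(above[idx])
      if (n_above < min_markers) next
      out[[length(out) + 1]] <- data.frame(
        lg = lg, start_cM = cm[merged$s[i]], end_cM = cm[merged$e[i]],
        size_cM = cm[merged$e[i]] - cm[merged$s[i]], n_markers = n_above)
    }
  }
  if (!length(out))
    return(data.frame(lg = integer(), start_cM = numeric(),
                      end_cM = numeric(), size_cM = numeric(),
                      n_markers = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count genes falling inside called regions
#'
#' @param regions data.frame from [call_regions()]
#' @param gene_table data.frame with `lg` and `position_cM` gene midpoints
#' @return `regions` with an `n_genes` column (inclusive interval membership)
#' @export
count_genes_in_regions <- function(regions, gene_table) {
  regions$n_genes <- vapply(seq_len(nrow(regions)), function(i) {
    sum(gene_table$lg == regions$lg[i] &
          gene_table$position_cM >= regions$start_cM[i] &
          gene_table$position_cM <= regions$end_cM[i])
  }, integer(1))
  regions
}

#' Run the full Euclidean-distance bulked-segregant scan
#'
#' Pool frequencies, ED, ED^k, per-LG LOESS smoothing, the genome-wide
#' mean + `sd_mult` SD threshold, and region calling, in one call.
#'
#' @param pools pooled count table with `lg` and `cM` position columns
#'   (from [build_pools()] or [read_pool_tsv()])
#' @param k ED exponent
#' @param span,degree LOESS parameters, see [loess_fit()]
#' @param sd_mult threshold SD multiplier
#' @param min_markers,merge_gap_cM region-calling parameters
#' @return object of class `ed_scan`: `profile` (per-SNP data.frame with
#'   `ed`, `ed_k`, `fitted`), `threshold`, `regions`, `excluded`
#' @export
bsa_scan <- function(pools, k = 5, span = 0.3, degree = 1, sd_mult = 3,
                     min_markers = 3, merge_gap_cM = 2) {
  stopifnot(all(c("lg", "cM") %in% names(pools)))
  pf <- pool_allele_frequencies(pools)
  d <- pf$freq
  d <- d[order(d$lg, d$cM), , drop = FALSE]
  F <- as.matrix(d[, paste0("f", NUCS, "_F")])
  M <- as.matrix(d[, paste0("f", NUCS, "_M")])
  d$ed <- ed(F, M)
  d$ed_k <- ed_power(d$ed, k)
  d$fitted <- NA_real_
  for (lg in unique(d$lg)) {
    sel <- d$lg == lg
    d$fitted[sel] <- loess_fit(d$cM[sel], d$ed_k[sel],
                               span = span, degree = degree)
  }
  thr <- association_threshold(d$fitted, sd_mult)
  regions <- call_regions(d[, c("lg", "cM")], d$fitted, thr,
                          min_markers = min_markers,
                          merge_gap_cM = merge_gap_cM)
  structure(list(profile = d, threshold = thr, regions = regions,
                 excluded = pf$excluded,
                 params = list(k = k, span = span, degree = degree,
                               sd_mult = sd_mult, min_markers = min_markers,
                               merge_gap_cM = merge_gap_cM)),
            class = "ed_scan")
}
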