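#' Two-point recombination fractions and LOD scores for BC1 markers
#'
#' For every marker pair, individuals non-missing at both markers are scored;
#' a recombinant is a discordant genotype pair (aa/ab), so `rf = R/n`, capped
#' at 0.5. The two-point LOD of linkage versus independence is
#' `n*log10(2) + R*log10(rf) + (n-R)*log10(1-rf)` with `0*log10(0) = 0`.
#'
#' @param geno character matrix markers x individuals of "aa"/"ab"/"--"
#'   (or an `slaf_genmat`)
#' @return object of class `linkage_stats`: matrices `n`, `R`, `rf`, `lod`;
#'   pairs with no jointly scored individual have `rf`/`lod` `NA`
#' @export
pairwise_rf_lod <- function(geno) {
  if (inherits(geno, "slaf_genmat")) geno <- geno$geno
  X <- matrix(NA_real_, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  X[geno == "aa"] <- 0
  X[geno == "ab"] <- 1
  M <- !is.na(X) * 1
  A <- X; A[is.na(A)] <- 0          # 1 where observed "ab"
  B <- M - A                         # 1 where observed "aa"
  n <- M %*% t(M)
  conc <- A %*% t(A) + B %*% t(B)
  R <- n - conc
  rf <- ifelse(n > 0, pmin(R / n, 0.5), NA_real_)
  lod <- matrix(NA_real_, nrow(geno), nrow(geno), dimnames = dimnames(n))
  ok <- n > 0
  lt <- function(r, x) ifelse(x > 0, x * log10(r), 0)
  lod[ok] <- n[ok] * log10(2) + lt(rf[ok], R[ok]) +
    lt(1 - rf[ok], n[ok] - R[ok])
  lod[ok] <- pmax(lod[ok], 0)
  diag(rf) <- 0; diag(lod) <- NA_real_
  structure(list(n = n, R = R, rf = rf, lod = lod,
                 markers = rownames(geno)),
            class = "linkage_stats")
}

#' Partition markers into linkage groups by LOD threshold
#'
#' Single-linkage connected components of the graph whose edges are marker
#' pairs with LOD at or above the threshold. Markers with no edge at all are
#' dropped and reported rather than forming singleton groups.
#'
#' @param stats a `linkage_stats`
#' @param mlod_threshold minimum LOD for an edge (default 5)
#' @return list with `groups` (list of marker-id vectors, largest first) and
#'   `dropped` (marker ids with no qualifying edge)
#' @export
group_markers <- function(stats, mlod_threshold = 5) {
  stopifnot(inherits(stats, "linkage_stats"))
  lod <- stats$lod
  adj <- !is.na(lod) & lod >= mlod_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected")
  comp <- igraph::components(g)
  ids <- stats$markers
  groups <- split(ids, comp$membership)
  isolated <- vapply(groups, length, integer(1)) == 1
  dropped <- unlist(groups[isolated], use.names = FALSE)
  groups <- groups[!isolated]
  groups <- groups[order(-vapply(groups, length, integer(1)))]
  list(groups = unname(lapply(groups, unname)),
       dropped = dropped %||% character(0))
}

.sarf <- function(ord, rf) {
  r <- rf[cbind(ord[-length(ord)], ord[-1])]
  sum(ifelse(is.na(r), 0.5, r))
}

#' Order the markers of one linkage group
#'
#' Minimizes SARF, the sum of adjacent recombination fractions, by a greedy
#' nearest-neighbour seriation start followed by simulated annealing over
#' segment-reversal and single-marker-relocation moves and a final steepest
#' 2-opt/relocation descent to a local optimum. Unavailable pairwise rf values
#' count as 0.5. The returned order is canonically oriented: its first marker
#' id sorts lexicographically before its last.
#'
#' @param rf square recombination-fraction matrix with marker dimnames (or a
#'   `linkage_stats`, from which the submatrix for `markers` is taken)
#' @param markers marker ids to order (default: all rows of `rf`)
#' @param seed integer seed for the annealing stream
#' @param n_anneal annealing iterations
#' @param t0 initial temperature
#' @param cooling geometric cooling factor per iteration
#' @return character vector of ordered marker ids with attribute `sarf`
#' @export
order_markers <- function(rf, markers = NULL, seed = 1,
                          n_anneal = 10000, t0 = 1, cooling = 0.999) {
  if (inherits(rf, "linkage_stats")) rf <- rf$rf
  if (is.null(markers)) markers <- rownames(rf)
  if (length(markers) < 2) return(markers)
  rf <- rf[markers, markers, drop = FALSE]
  rf[is.na(rf)] <- 0.5
  m <- length(markers)
  set.seed(seed)
  # greedy seriation from the most peripheral marker
  start <- which.max(rowSums(rf))
  ord <- start
  free <- setdiff(seq_len(m), start)
  while (length(free)) {
    dl <- rf[ord[1], free]
    dr <- rf[ord[length(ord)], free]
    if (min(dl) < min(dr)) ord <- c(free[which.min(dl)], ord)
    else ord <- c(ord, free[which.min(dr)])
    free <- setdiff(free, ord)
  }
  best <- ord; best_s <- .sarf(ord, rf)
  cur <- ord; cur_s <- best_s
  temp <- t0
  if (m > 2) for (it in seq_len(n_anneal)) {
    ij <- sort(sample.int(m, 2))
    i <- ij[1]; j <- ij[2]
    if (stats::runif(1) < 0.5 || i == 1 && j == m) {
      # reverse cur[i..j]: only the two boundary adjacencies change
      d <- 0
      if (i > 1) d <- d + rf[cur[i - 1], cur[j]] - rf[cur[i - 1], cur[i]]
      if (j < m) d <- d + rf[cur[i], cur[j + 1]] - rf[cur[j], cur[j + 1]]
      if (d < 0 || stats::runif(1) < exp(-d / temp)) {
        cur[i:j] <- cur[j:i]
        cur_s <- cur_s + d
      }
    } else {
      # relocate marker at i to position j
      v <- cur[i]
      prop <- append(cur[-i], v, after = j - 1)
      d <- .sarf(prop, rf) - cur_s
      if (d < 0 || stats::runif(1) < exp(-d / temp)) {
        cur <- prop
        cur_s <- cur_s + d
      }
    }
    if (cur_s < best_s - 1e-12) { best <- cur; best_s <- cur_s }
    temp <- temp * cooling
  }
  # descent to a local optimum under reversal and relocation moves
  improved <- TRUE
  while (improved && m > 2) {
    improved <- FALSE
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      d <- 0
      if (i > 1) d <- d + rf[best[i - 1], best[j]] - rf[best[i - 1], best[i]]
      if (j < m) d <- d + rf[best[i], best[j + 1]] - rf[best[j], best[j + 1]]
      if (d < -1e-12) {
        best[i:j] <- best[j:i]
        best_s <- best_s + d
        improved <- TRUE
      }
    }
    # relocate short segments (either orientation) into their best gap;
    # tightly linked marker pairs misplaced together need the block move
    for (L in 1:3) {
      if (m <= L + 1) next
      for (i in seq_len(m - L + 1)) {
        seg <- best[i:(i + L - 1)]
        rest <- best[-(i:(i + L - 1))]
        mr <- length(rest)
        gain <- 0
        if (i > 1) gain <- gain + rf[best[i - 1], seg[1]]
        if (i + L - 1 < m) gain <- gain + rf[seg[L], best[i + L]]
        if (i > 1 && i + L - 1 < m) gain <- gain - rf[best[i - 1], best[i + L]]
        bd <- 0; bk <- NA; bseg <- seg
        for (sg in if (L > 1) list(seg, rev(seg)) else list(seg)) {
          ins <- c(rf[sg[L], rest[1]],
                   if (mr > 1) rf[rest[-mr], sg[1]] + rf[sg[L], rest[-1]] -
                     rf[cbind(rest[-mr], rest[-1])],
                   rf[rest[mr], sg[1]])
          k <- which.min(ins)
          d <- ins[k] - gain
          if (d < bd) { bd <- d; bk <- k; bseg <- sg }
        }
        if (bd < -1e-12) {
          best <- append(rest, bseg, after = bk - 1)
          best_s <- best_s + bd
          improved <- TRUE
        }
      }
    }
  }
  out <- markers[best]
  if (out[1] > out[length(out)]) out <- rev(out)
  attr(out, "sarf") <- .sarf(best, rf)
  out
}

#' SARF of a marker order
#' @param ord ordered marker ids
#' @param rf recombination-fraction matrix (NA counts as 0.5)
#' @return sum of adjacent recombination fractions
#' @export
sarf <- function(ord, rf) {
  if (inherits(rf, "linkage_stats")) rf <- rf$rf
  .sarf(ord, rf)
}

#' SMOOTH-style genotyping-error detection on an ordered matrix
#'
#' For each cell, the genotype is predicted from the non-missing genotypes of
#' up to `window` flanking markers on each side, weighted by 1/(index
#' distance). When the observed call disagrees with the prediction and the
#' prediction's weight share exceeds `mismatch_p`, the cell is set to missing
#' (a suspect singleton is erased, never overwritten with the prediction, so
#' correction cannot amplify its own errors). Passes repeat until no cell
#' changes or `max_rounds` is reached; following the classic iterative
#' correction strategy, each pass widens the disagreement band: pass k erases
#' at confidence above `1 - (1 - mismatch_p) * relax^(k-1)`, so the first
#' pass removes only near-unanimous singletons and later passes reach errors
#' sitting close to genuine crossover breakpoints (set `relax = 1` for a
#' fixed threshold).
#'
#' @param geno ordered character matrix markers x individuals ("aa"/"ab"/"--")
#' @param window flanking markers considered on each side
#' @param mismatch_p weight share the prediction must exceed in the first pass
#' @param max_rounds maximum correction passes
#' @param relax per-pass widening factor of the erasure band
#' @return list with `geno` (corrected matrix) and `changes` (data.frame
#'   round, marker, individual, observed)
#' @export
smooth_correct <- function(geno, window = 5, mismatch_p = 0.98,
                           max_rounds = 4, relax = 2) {
  m <- nrow(geno)
  log_rows <- list()
  for (round in seq_len(max_rounds)) {
    thr <- 1 - (1 - mismatch_p) * relax^(round - 1)
    X <- matrix(NA_real_, m, ncol(geno))
    X[geno == "ab"] <- 1
    X[geno == "aa"] <- 0
    num <- matrix(0, m, ncol(geno))
    den <- matrix(0, m, ncol(geno))
    obs <- !is.na(X)
    X0 <- X; X0[!obs] <- 0
    for (off in seq_len(window)) {
      w <- 1 / off
      up <- rbind(X0[-seq_len(off), , drop = FALSE],
                  matrix(0, off, ncol(geno)))
      upo <- rbind(obs[-seq_len(off), , drop = FALSE],
                   matrix(FALSE, off, ncol(geno)))
      dn <- rbind(matrix(0, off, ncol(geno)),
                  X0[seq_len(m - off), , drop = FALSE])
      dno <- rbind(matrix(FALSE, off, ncol(geno)),
                   obs[seq_len(m - off), , drop = FALSE])
      num <- num + w * (up + dn)
      den <- den + w * (upo + dno)
    }
    share_ab <- ifelse(den > 0, num / den, NA_real_)
    pred <- ifelse(share_ab > 0.5, 1, 0)
    conf <- pmax(share_ab, 1 - share_ab)
    suspect <- obs & !is.na(share_ab) & X != pred & conf > thr
    if (!any(suspect) && relax == 1) break
    if (!any(suspect)) next
    idx <- which(suspect, arr.ind = TRUE)
    log_rows[[round]] <- data.frame(
      round = round,
      marker = rownames(geno)[idx[, 1]] %||% idx[, 1],
      individual = colnames(geno)[idx[, 2]] %||% idx[, 2],
      observed = geno[suspect])
    geno[suspect] <- "--"
  }
  list(geno = geno,
       changes = if (length(log_rows)) do.call(rbind, log_rows)
       else data.frame(round = integer(), marker = character(),
                       individual = character(), observed = character()))
}

#' k-nearest-neighbour imputation of missing genotypes
#'
#' Each missing cell receives the majority genotype of the `k` nearest
#' non-missing markers (by map position, or row index if no positions are
#' given) of the same individual; a tied vote goes to the genotype of the
#' nearest of the tied markers. Individuals with no call at all on the group
#' are left missing and reported.
#'
#' @param geno ordered character matrix markers x individuals
#' @param k neighbours to vote
#' @param positions optional numeric marker positions (default: row index)
#' @return list with `geno` (imputed matrix) and `unimputable` (individual
#'   ids with an all-missing column)
#' @export
knn_impute <- function(geno, k = 5, positions = NULL) {
  m <- nrow(geno)
  pos <- positions %||% seq_len(m)
  stopifnot(length(pos) == m)
  unimputable <- character(0)
  for (j in seq_len(ncol(geno))) {
    col <- geno[, j]
    obs <- which(col != "--")
    miss <- which(col == "--")
    if (!length(miss)) next
    if (!length(obs)) {
      unimputable <- c(unimputable, colnames(geno)[j] %||% as.character(j))
      next
    }
    for (i in miss) {
      d <- abs(pos[obs] - pos[i])
      o <- order(d)
      nb <- obs[o][seq_len(min(k, length(obs)))]
      votes <- table(col[nb])
      top <- names(votes)[votes == max(votes)]
      geno[i, j] <- if (length(top) == 1) top else col[nb][col[nb] %in% top][1]
    }
  }
  list(geno = geno, unimputable = unimputable)
}

#' Kosambi map function and inverse
#'
#' `kosambi(r) = 25 * ln((1+2r)/(1-2r))` cM; `kosambi_inverse(d) =
#' 0.5 * tanh(d/50)`. The Kosambi function allows partial crossover
#' interference and is the mapping function used for all reported distances.
#'
#' @param rf recombination fraction(s) in `[0, 0.5)`
#' @return map distance in cM
#' @export
kosambi <- function(rf) {
  if (any(rf < 0 | rf >= 0.5)) stop("'rf' must be in [0, 0.5)", call. = FALSE)
  25 * log((1 + 2 * rf) / (1 - 2 * rf))
}

#' @rdname kosambi
#' @param d map distance(s) in cM (>= 0)
#' @export
kosambi_inverse <- function(d) {
  if (any(d < 0)) stop("'d' must be >= 0", call. = FALSE)
  0.5 * tanh(d / 50)
}

#' Haldane map function and inverse (no interference)
#' @inheritParams kosambi
#' @return map distance in cM, or recombination fraction for the inverse
#' @export
haldane <- function(rf) {
  if (any(rf < 0 | rf >= 0.5)) stop("'rf' must be in [0, 0.5)", call. = FALSE)
  -50 * log(1 - 2 * rf)
}

#' @rdname haldane
#' @param d map distance(s) in cM (>= 0)
#' @export
haldane_inverse <- function(d) {
  if (any(d < 0)) stop("'d' must be >= 0", call. = FALSE)
  0.5 * (1 - exp(-d / 50))
}

#' Summary table for a set of linkage groups
#'
#' Pure arithmetic over per-LG lengths and marker counts: average adjacent
#' distance is length/count rounded half-up to 2 decimals; totals sum
#' markers, lengths and SNPs; the overall average distance is the mean of the
#' per-LG averages and the overall max gap the largest per-LG gap.
#'
#' @param lengths_cM per-LG map lengths
#' @param n_markers per-LG marker counts
#' @param max_gaps optional per-LG largest adjacent gap (cM)
#' @param snp_counts optional per-LG SNP totals
#' @return list with `per_lg` (data.frame) and `totals` (list: n_markers,
#'   length_cM, mean_lg_length_cM, avg_distance_cM, max_gap_cM, snp_count)
#' @export
map_summary_table <- function(lengths_cM, n_markers,
                              max_gaps = NULL, snp_counts = NULL) {
  stopifnot(length(lengths_cM) == length(n_markers))
  avg <- ifelse(n_markers > 0, round_half_up(lengths_cM / n_markers, 2), 0)
  per_lg <- data.frame(
    lg = seq_along(lengths_cM),
    n_markers = n_markers,
    length_cM = round_half_up(lengths_cM, 2),
    avg_distance_cM = avg,
    max_gap_cM = if (is.null(max_gaps)) NA_real_
      else round_half_up(max_gaps, 2),
    snp_count = if (is.null(snp_counts)) NA_integer_ else snp_counts)
  totals <- list(
    n_markers = sum(n_markers),
    length_cM = round_half_up(sum(lengths_cM), 2),
    mean_lg_length_cM = round_half_up(mean(lengths_cM), 2),
    avg_distance_cM = round_half_up(mean(avg), 2),
    max_gap_cM = if (is.null(max_gaps)) NA_real_
      else round_half_up(max(max_gaps), 2),
    snp_count = if (is.null(snp_counts)) NA_integer_ else sum(snp_counts))
  list(per_lg = per_lg, totals = totals)
}

#' Assemble a genetic map from ordered groups
#'
#' Cumulates Kosambi (or Haldane) distances along each ordered group:
#' position(1) = 0 and position(i+1) = position(i) + map_function(adjacent
#' rf). Adjacent rf values of 0.5 or more (possible only through missing
#' data) are capped just below 0.5. Produces the per-LG summary via
#' [map_summary_table()].
#'
#' @param orders list of ordered marker-id vectors, one per LG
#' @param stats a `linkage_stats` (for adjacent rf values)
#' @param map_function "kosambi" (default) or "haldane"
#' @param snp_counts optional named per-marker SNP counts for the summary
#' @return object of class `genetic_map`: `map` (data.frame marker_id, lg,
#'   position_cM), `summary` (per-LG data.frame) and `totals`
#' @export
assemble_map <- function(orders, stats, map_function = c("kosambi", "haldane"),
                         snp_counts = NULL) {
  map_function <- match.arg(map_function)
  mf <- if (map_function == "kosambi") kosambi else haldane
  rf <- if (inherits(stats, "linkage_stats")) stats$rf else stats
  rows <- list(); lens <- numeric(); gaps <- numeric(); snps <- integer()
  for (lg in seq_along(orders)) {
    ord <- orders[[lg]]
    if (length(ord) == 1) {
      pos <- 0
    } else {
      r <- rf[cbind(ord[-length(ord)], ord[-1])]
      r[is.na(r)] <- 0.5
      r <- pmin(r, 0.5 - 1e-6)
      pos <- c(0, cumsum(mf(r)))
    }
    rows[[lg]] <- data.frame(marker_id = ord, lg = lg, position_cM = pos)
    lens[lg] <- max(pos)
    gaps[lg] <- if (length(pos) > 1) max(diff(pos)) else 0
    snps[lg] <- if (!is.null(snp_counts)) sum(snp_counts[ord]) else NA_integer_
  }
  summ <- map_summary_table(lens, vapply(orders, length, integer(1)),
                            max_gaps = gaps,
                            snp_counts = if (is.null(snp_counts)) NULL
                            else snps)
  structure(list(map = do.call(rbind, rows),
                 summary = summ$per_lg, totals = summ$totals,
                 map_function = map_function),
            class = "genetic_map")
}
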