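# shared fixture builders; everything is generated in code at test time

# small BC1 simulation: one call for truth + counts
sim_small <- function(seed = 1, lg_lengths = 100, markers = 21,
                      n_off = 60, err = 0.001, sex = list(lg = 1, cM = 50),
                      map_function = "haldane") {
  sp <- map_spec(lg_lengths, markers, map_function)
  tr <- simulate_cross(sp, n_off, sex, seed = seed)
  ct <- simulate_read_counts(tr, c(34.39, 31.31), 7.22, err, seed = seed + 1)
  list(spec = sp, truth = tr, counts = ct)
}

# hand-built tag_group for filter/classification tests
make_group <- function(tags, parent_depth = c(maternal = 30, paternal = 30),
                       tag_reads = NULL, tags_maternal = NULL) {
  n <- length(tags)
  structure(list(id = "Gtest", tags = tags, marker_ids = "M1",
                 parent_depth = parent_depth,
                 tag_reads = tag_reads %||% rep(20, n),
                 tags_maternal = tags_maternal %||% min(1, n),
                 tags_paternal = n - (tags_maternal %||% min(1, n))),
            class = "tag_group")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random nucleotide string
rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate a sequence at k fresh positions
mutate_seq <- function(s, k, avoid = integer(0), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- strsplit(s, "")[[1]]
  pos <- sample(setdiff(seq_along(x), avoid), k)
  for (p in pos) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
  list(seq = paste(x, collapse = ""), pos = pos)
}

# independent brute-force digestion oracle: scan every offset for a site
digest_oracle <- function(seq, site_a, site_b, min_len, max_len) {
  find_all <- function(s, site) {
    L <- nchar(site)
    hits <- integer(0)
    for (i in seq_len(nchar(s) - L + 1))
      if (substr(s, i, i + L - 1) == site) hits <- c(hits, i - 1L)
    hits
  }
  cuts <- sort(unique(c(find_all(seq, site_a), find_all(seq, site_b))))
  if (length(cuts) < 2) return(integer(0))
  lens <- diff(cuts)
  st <- cuts[-length(cuts)]
  st[lens >= min_len & lens <= max_len]
}

# independent tricube local-WLS oracle for the LOESS fit
loess_oracle <- function(x, y, span = 0.3, degree = 1) {
  n <- length(x)
  q <- floor(n * span)
  vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    h <- sort(d)[q]
    w <- pmax(1 - (d / h)^3, 0)^3
    ok <- w > 0
    X <- outer(x[ok] - x[i], 0:degree, `^`)
    stats::lm.wfit(X, y[ok], w[ok])$coefficients[1]
  }, numeric(1))
}

# exhaustive minimum-SARF search over all distinct orders
sarf_exhaustive <- function(rf) {
  ids <- rownames(rf)
  m <- length(ids)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  # fix the first element set to half the permutations (reversal symmetry)
  best <- Inf
  for (p in perms(seq_len(m))) {
    if (p[1] > p[m]) next
    s <- sarf(ids[p], rf)
    if (s < best) best <- s
  }
  best
}
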