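#' Generate a synthetic genome
#'
#' Draws i.i.d. nucleotides at a target GC content and optionally overwrites a
#' fraction of each chromosome with copies of one source block, so that
#' downstream tag clustering sees genuinely repeated sequence.
#'
#' @param n_chrom number of chromosomes
#' @param lengths_bp integer vector (recycled to `n_chrom`) of chromosome
#'   lengths in bp; each must be at least 1000
#' @param gc_target target GC fraction in `[0, 1]`; realized GC is within
#'   about 0.02 of the target for lengths of 10 kb and more
#' @param repeat_fraction fraction in `[0, 0.5)` of each chromosome occupied
#'   by duplicated 200 bp blocks
#' @param seed integer seed; the same seed reproduces the genome exactly
#' @return an object of class `slaf_genome`: a list with `chromosomes`
#'   (named character vector of sequences) and `gc_target`
#' @examples
#' g <- generate_genome(1, 10000, gc_target = 0.38, seed = 1)
#' nchar(g$chromosomes)
#' @export
generate_genome <- function(n_chrom = 1, lengths_bp = 100000,
                            gc_target = 0.38, repeat_fraction = 0,
                            seed = 1) {
  if (any(!is.finite(lengths_bp)) || any(lengths_bp < 1000))
    stop("chromosome lengths must be >= 1000 bp", call. = FALSE)
  .assert_scalar_prob(gc_target, "gc_target")
  if (repeat_fraction < 0 || repeat_fraction >= 0.5)
    stop("'repeat_fraction' must be in [0, 0.5)", call. = FALSE)
  lengths_bp <- as.integer(rep_len(lengths_bp, n_chrom))
  set.seed(seed)
  p <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
         G = gc_target / 2, T = (1 - gc_target) / 2)
  block <- 200L
  chrs <- vapply(seq_len(n_chrom), function(i) {
    L <- lengths_bp[i]
    s <- sample(NUCS, L, replace = TRUE, prob = p)
    if (repeat_fraction > 0) {
      n_rep <- floor(repeat_fraction * L / block)
      if (n_rep >= 1) {
        src <- s[seq_len(block)]
        # disjoint landing slots after the source block
        n_slots <- (L - block) %/% block
        take <- sample(n_slots, min(n_rep, n_slots))
        for (sl in take) s[(sl * block) + seq_len(block)] <- src
      }
    }
    paste(s, collapse = "")
  }, character(1))
  names(chrs) <- sprintf("chr%d", seq_len(n_chrom))
  structure(list(chromosomes = chrs, gc_target = gc_target),
            class = "slaf_genome")
}

#' GC fraction of a genome
#' @param genome an `slaf_genome` or character vector of sequences
#' @return realized GC fraction over all chromosomes
#' @export
gc_content <- function(genome) {
  seqs <- if (inherits(genome, "slaf_genome")) genome$chromosomes else genome
  tab <- table(factor(unlist(strsplit(seqs, "")), levels = NUCS))
  sum(tab[c("G", "C")]) / sum(tab)
}

#' In-silico double restriction digestion with size selection
#'
#' Cuts every occurrence of either recognition site on the forward strand, at
#' the 5' end of the site, and returns the fragments between successive cut
#' positions whose length lies in `[min_len, max_len]` (the size-selection
#' window of the tag library). Coordinates are 0-based half-open.
#'
#' @param genome an `slaf_genome` or named character vector of sequences
#' @param site_a,site_b recognition sites (non-empty A/C/G/T strings)
#' @param min_len,max_len inclusive retained fragment length bounds in bp
#' @return data.frame with columns `chrom`, `start`, `end`, `length`
#' @export
digest_genome <- function(genome, site_a, site_b,
                          min_len = 364, max_len = 414) {
  seqs <- if (inherits(genome, "slaf_genome")) genome$chromosomes else genome
  for (s in c(site_a, site_b))
    if (!is.character(s) || nchar(s) == 0 || grepl("[^ACGT]", s))
      stop("recognition sites must be non-empty A/C/G/T strings",
           call. = FALSE)
  if (length(seqs) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), length = integer()))
  out <- lapply(names(seqs) %||% as.character(seq_along(seqs)), function(nm) {
    x <- seqs[[nm]]
    cuts <- integer()
    for (site in unique(c(site_a, site_b))) {
      hit <- gregexpr(site, x, fixed = TRUE)[[1]]
      if (hit[1] != -1L) cuts <- c(cuts, as.integer(hit) - 1L)  # 0-based 5'
    }
    cuts <- sort(unique(cuts))
    if (length(cuts) < 2L) return(NULL)
    st <- cuts[-length(cuts)]
    en <- cuts[-1L]
    keep <- (en - st) >= min_len & (en - st) <= max_len
    if (!any(keep)) return(NULL)
    data.frame(chrom = nm, start = st[keep], end = en[keep],
               length = en[keep] - st[keep])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), length = integer())
  rownames(out) <- NULL
  out
}

#' Specify the linkage groups of a simulated map
#'
#' @param lg_lengths_cM positive linkage-group lengths in cM; the default is
#'   the six spinach linkage-group lengths of the mapping study this package
#'   emulates
#' @param markers_per_lg marker count per LG (recycled)
#' @param map_function crossover model used when simulating gametes:
#'   `"haldane"` (no interference; exact Markov process) or `"kosambi"`
#'   (adjacent-interval recombination fractions from the Kosambi inverse;
#'   a Markov approximation to partial interference)
#' @param positions optional list of explicit marker positions (cM) per LG;
#'   default is equally spaced from 0 to the LG length
#' @return object of class `map_spec`
#' @export
map_spec <- function(lg_lengths_cM = c(184.18, 187.43, 201.28,
                                       194.01, 180.41, 178.66),
                     markers_per_lg = 100,
                     map_function = c("haldane", "kosambi"),
                     positions = NULL) {
  map_function <- match.arg(map_function)
  if (any(lg_lengths_cM <= 0)) stop("LG lengths must be > 0", call. = FALSE)
  n_lg <- length(lg_lengths_cM)
  markers_per_lg <- rep_len(as.integer(markers_per_lg), n_lg)
  if (is.null(positions)) {
    positions <- lapply(seq_len(n_lg), function(i)
      seq(0, lg_lengths_cM[i], length.out = markers_per_lg[i]))
  }
  stopifnot(length(positions) == n_lg)
  for (i in seq_len(n_lg)) {
    p <- positions[[i]]
    if (any(diff(p) <= 0) || any(p < 0) || any(p > lg_lengths_cM[i]))
      stop("marker positions must be strictly increasing within [0, length]",
           call. = FALSE)
  }
  structure(list(lg_lengths_cM = lg_lengths_cM,
                 markers_per_lg = markers_per_lg,
                 map_function = map_function,
                 positions = positions),
            class = "map_spec")
}

.rf_from_cM <- function(d, map_function) {
  switch(map_function,
         haldane = 0.5 * (1 - exp(-d / 50)),
         kosambi = 0.5 * tanh(d / 50),
         stop("unknown map function"))
}

#' Simulate a BC1 cross with a planted sex locus
#'
#' Gametes of the F1 are generated per linkage group as a Markov chain along
#' marker positions: the allele at the first position is drawn 50/50 and
#' switches between adjacent positions with the recombination fraction implied
#' by the configured map function. The BC1 genotype at every marker is the
#' recurrent-parent allele plus the gamete allele, so each marker is an
#' informative aa x bb marker segregating aa : ab. An individual is male
#' exactly when its F1 gamete carries the non-recurrent (donor, "Y") allele at
#' the sex locus.
#'
#' @param spec a [map_spec()]
#' @param n_offspring number of BC1 individuals (>= 2)
#' @param sex_locus list with `lg` (index) and `cM` (position within that LG)
#' @param seed integer seed
#' @return object of class `slaf_truth`: `markers` (data.frame marker_id, lg,
#'   cM, allele_a, allele_b, snp_count), `gametes` (0/1 matrix markers x
#'   offspring; 1 = donor allele), `genotypes` ("aa"/"ab" matrix), `sexes`
#'   (factor female/male), `sex_locus`, and the `map_spec` used
#' @export
simulate_cross <- function(spec, n_offspring = 148,
                           sex_locus = list(lg = 4, cM = 80), seed = 1) {
  stopifnot(inherits(spec, "map_spec"))
  if (n_offspring < 2) stop("n_offspring must be >= 2", call. = FALSE)
  lg_sex <- sex_locus$lg
  if (lg_sex < 1 || lg_sex > length(spec$lg_lengths_cM) ||
      sex_locus$cM < 0 || sex_locus$cM > spec$lg_lengths_cM[lg_sex])
    stop("sex locus must lie on a declared LG within its length",
         call. = FALSE)
  set.seed(seed)
  n_lg <- length(spec$lg_lengths_cM)
  gam <- list(); ids <- list(); lgs <- list(); cms <- list()
  sex_allele <- NULL
  for (lg in seq_len(n_lg)) {
    pos <- spec$positions[[lg]]
    aug <- pos
    sex_i <- NA_integer_
    if (lg == lg_sex) {
      # track the sex locus as an extra (non-marker) position in the chain
      aug <- sort(unique(c(pos, sex_locus$cM)))
      sex_i <- match(sex_locus$cM, aug)
    }
    m <- length(aug)
    r <- .rf_from_cM(diff(aug), spec$map_function)
    g <- matrix(0L, m, n_offspring)
    g[1, ] <- rbinom(n_offspring, 1, 0.5)
    if (m > 1) for (j in 2:m) {
      sw <- rbinom(n_offspring, 1, r[j - 1])
      g[j, ] <- ifelse(sw == 1L, 1L - g[j - 1, ], g[j - 1, ])
    }
    if (lg == lg_sex) {
      sex_allele <- g[sex_i, ]
      if (!(sex_locus$cM %in% pos)) g <- g[-sex_i, , drop = FALSE]
      else g <- g[match(pos, aug), , drop = FALSE]
    }
    gam[[lg]] <- g
    ids[[lg]] <- sprintf("M%d_%03d", lg, seq_along(pos))
    lgs[[lg]] <- rep(lg, length(pos))
    cms[[lg]] <- pos
  }
  gametes <- do.call(rbind, gam)
  marker_id <- unlist(ids)
  rownames(gametes) <- marker_id
  colnames(gametes) <- sprintf("BC%03d", seq_len(n_offspring))
  n_mark <- length(marker_id)
  # parental alleles: two distinct nucleotides per marker
  a <- sample(NUCS, n_mark, replace = TRUE)
  b <- vapply(a, function(x) sample(setdiff(NUCS, x), 1), character(1))
  # SNPs per tag pair: at least the scored site, occasionally more
  snp_count <- 1L + rpois(n_mark, 0.45)
  genotypes <- matrix(ifelse(gametes == 1L, "ab", "aa"),
                      n_mark, n_offspring, dimnames = dimnames(gametes))
  sexes <- factor(ifelse(sex_allele == 1L, "male", "female"),
                  levels = c("female", "male"))
  names(sexes) <- colnames(gametes)
  structure(list(
    markers = data.frame(marker_id = marker_id, lg = unlist(lgs),
                         cM = unlist(cms), allele_a = unname(a),
                         allele_b = unname(b), snp_count = snp_count),
    gametes = gametes, genotypes = genotypes,
    sexes = sexes, sex_locus = sex_locus, map_spec = spec),
    class = "slaf_truth")
}

#' Simulate per-locus read counts for parents and offspring
#'
#' Per individual and marker the depth is Poisson with the individual-class
#' mean; each read reports the true template allele with probability
#' `1 - error_rate` and otherwise one of the three other nucleotides uniformly.
#' Heterozygous templates are drawn 50/50 between the two alleles. Missing
#' genotypes downstream arise only from low depth; there is no separate
#' dropout process.
#'
#' @param truth an `slaf_truth` from [simulate_cross()]
#' @param depth_parent_mean length-2 numeric (maternal, paternal) mean depths
#' @param depth_offspring_mean mean offspring depth
#' @param error_rate per-base error probability in `[0, 0.25)`
#' @param seed integer seed
#' @param tag_length length of the simulated tag sequences in bp
#' @return object of class `slaf_counts`: `counts` (3-d array markers x
#'   individuals x nucleotide A/C/G/T), `depth` (markers x individuals),
#'   `tags` (per-marker maternal/paternal tag sequences), `individuals`,
#'   `parents`, and the originating `truth` marker table
#' @export
simulate_read_counts <- function(truth,
                                 depth_parent_mean = c(34.39, 31.31),
                                 depth_offspring_mean = 7.22,
                                 error_rate = 0.001, seed = 1,
                                 tag_length = 100) {
  stopifnot(inherits(truth, "slaf_truth"))
  if (any(depth_parent_mean <= 0) || depth_offspring_mean <= 0)
    stop("depths must be > 0", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.25)
    stop("'error_rate' must be in [0, 0.25)", call. = FALSE)
  set.seed(seed)
  mk <- truth$markers
  n_mark <- nrow(mk)
  off <- colnames(truth$genotypes)
  inds <- c("P1_maternal", "P2_paternal", off)
  n_ind <- length(inds)
  means <- c(depth_parent_mean[1], depth_parent_mean[2],
             rep(depth_offspring_mean, length(off)))
  counts <- array(0L, dim = c(n_mark, n_ind, 4L),
                  dimnames = list(mk$marker_id, inds, NUCS))
  ai <- match(mk$allele_a, NUCS)
  bi <- match(mk$allele_b, NUCS)
  # template copies of allele b per individual: P1 none, P2 all, offspring het/hom
  for (i in seq_len(n_mark)) {
    D <- rpois(n_ind, means)
    het <- c(FALSE, FALSE, truth$genotypes[i, ] == "ab")
    homb <- c(FALSE, TRUE, rep(FALSE, length(off)))
    nb_true <- integer(n_ind)
    nb_true[het] <- rbinom(sum(het), D[het], 0.5)
    nb_true[homb] <- D[homb]
    na_true <- D - nb_true
    # sequencing errors off each true template, spread over the 3 others
    ea <- rbinom(n_ind, na_true, error_rate)
    eb <- rbinom(n_ind, nb_true, error_rate)
    cell <- matrix(0L, n_ind, 4L)
    cell[, ai[i]] <- na_true - ea
    cell[, bi[i]] <- cell[, bi[i]] + nb_true - eb
    for (src in 1:2) {
      err <- if (src == 1) ea else eb
      others <- setdiff(1:4, if (src == 1) ai[i] else bi[i])
      n1 <- rbinom(n_ind, err, 1 / 3)
      n2 <- rbinom(n_ind, err - n1, 1 / 2)
      cell[, others[1]] <- cell[, others[1]] + n1
      cell[, others[2]] <- cell[, others[2]] + n2
      cell[, others[3]] <- cell[, others[3]] + err - n1 - n2
    }
    counts[i, , ] <- cell
  }
  # fixed-length tag pair per marker differing at snp_count sites
  tags <- matrix("", n_mark, 2,
                 dimnames = list(mk$marker_id, c("maternal", "paternal")))
  for (i in seq_len(n_mark)) {
    base <- sample(NUCS, tag_length, replace = TRUE)
    k <- min(mk$snp_count[i], tag_length)
    sites <- sample(tag_length, k)
    alt <- base
    alt[sites[1]] <- mk$allele_b[i]
    base[sites[1]] <- mk$allele_a[i]
    if (base[sites[1]] == alt[sites[1]])  # defensive; alleles are distinct
      alt[sites[1]] <- setdiff(NUCS, base[sites[1]])[1]
    if (k > 1) for (s in sites[-1]) {
      alt[s] <- sample(setdiff(NUCS, base[s]), 1)
    }
    tags[i, 1] <- paste(base, collapse = "")
    tags[i, 2] <- paste(alt, collapse = "")
  }
  structure(list(counts = counts,
                 depth = apply(counts, c(1, 2), sum),
                 tags = tags,
                 individuals = inds,
                 parents = inds[1:2],
                 markers = mk),
            class = "slaf_counts")
}

#' Pool offspring read counts by sex
#'
#' Sums the per-nucleotide read counts of all female offspring into the F pool
#' and of all male offspring into the M pool, marker by marker (an in-silico
#' bulk: pooling of reads, not of genotype calls).
#'
#' @param counts an `slaf_counts` from [simulate_read_counts()]
#' @param sexes factor/character of "female"/"male", one per offspring,
#'   named by individual
#' @return data.frame with marker_id, lg, cM and columns `A_F..T_F`,
#'   `A_M..T_M`
#' @export
build_pools <- function(counts, sexes) {
  stopifnot(inherits(counts, "slaf_counts"))
  off <- setdiff(counts$individuals, counts$parents)
  sx <- as.character(sexes)
  names(sx) <- names(sexes) %||% off
  if (!setequal(names(sx), off) || length(sx) != length(off))
    stop("need exactly one sex label per offspring", call. = FALSE)
  bad <- names(sx)[!sx %in% c("female", "male")]
  if (length(bad))
    stop("unknown sex label for individual(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  fem <- names(sx)[sx == "female"]
  mal <- names(sx)[sx == "male"]
  sum_pool <- function(ids) {
    if (length(ids) == 0)
      return(matrix(0L, dim(counts$counts)[1], 4,
                    dimnames = list(NULL, NUCS)))
    apply(counts$counts[, ids, , drop = FALSE], c(1, 3), sum)
  }
  f <- sum_pool(fem); m <- sum_pool(mal)
  colnames(f) <- paste0(NUCS, "_F")
  colnames(m) <- paste0(NUCS, "_M")
  out <- cbind(counts$markers[, c("marker_id", "lg", "cM")],
               as.data.frame(f), as.data.frame(m))
  rownames(out) <- NULL
  out
}
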