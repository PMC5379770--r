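#' Read and write FASTA sequence files
#'
#' Thin wrappers over Biostrings; sequences are handled in memory as named
#' character vectors and written wrapped at 60 columns.
#'
#' @param path file path
#' @return `read_fasta()`: named character vector of sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

.read_tsv <- function(path, required) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("NA", "."))
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  d
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Read and write the genotype matrix as TSV
#'
#' Rows are markers with the metadata columns of an `slaf_genmat` followed by
#' one column per individual (codes `aa`/`ab`/`--`); tab-separated with a
#' header row.
#'
#' @param genmat an `slaf_genmat`
#' @param path file path
#' @return `read_genotype_tsv()`: an `slaf_genmat`
#' @export
write_genotype_tsv <- function(genmat, path) {
  stopifnot(inherits(genmat, "slaf_genmat"))
  .write_tsv(cbind(genmat$meta, as.data.frame(genmat$geno,
                                              check.names = FALSE)), path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  d <- .read_tsv(path, c("marker_id", "pattern", "integrity"))
  meta_cols <- intersect(
    c("marker_id", "pattern", "maternal_depth", "paternal_depth",
      "integrity", "snp_count", "n_aa", "n_ab", "n_impossible",
      "chi2", "p_distortion"), names(d))
  ind_cols <- setdiff(names(d), meta_cols)
  geno <- as.matrix(d[, ind_cols, drop = FALSE])
  rownames(geno) <- d$marker_id
  bad <- which(!geno %in% c("aa", "ab", "bb", "--"), arr.ind = FALSE)
  if (length(bad))
    stop("invalid genotype code at marker ",
         rownames(geno)[(bad[1] - 1) %% nrow(geno) + 1], call. = FALSE)
  structure(list(geno = geno, meta = d[, meta_cols, drop = FALSE]),
            class = "slaf_genmat")
}

#' Read and write a genetic map as TSV
#'
#' Columns `marker_id`, `lg`, `position_cM`; on read, positions must be
#' non-decreasing within each linkage group.
#'
#' @param map a `genetic_map` or its `map` data.frame
#' @param path file path
#' @return `read_map_tsv()`: data.frame marker_id, lg, position_cM
#' @export
write_map_tsv <- function(map, path) {
  d <- if (inherits(map, "genetic_map")) map$map else map
  .write_tsv(d[, c("marker_id", "lg", "position_cM")], path)
}

#' @rdname write_map_tsv
#' @export
read_map_tsv <- function(path) {
  d <- .read_tsv(path, c("marker_id", "lg", "position_cM"))
  for (lg in unique(d$lg)) {
    p <- d$position_cM[d$lg == lg]
    if (any(diff(p) < 0)) {
      bad <- d$marker_id[d$lg == lg][which(diff(p) < 0)[1] + 1]
      stop("non-monotone position at marker ", bad, " (LG ", lg, ")",
           call. = FALSE)
    }
  }
  d
}

#' Read and write pooled allele-count tables as TSV
#'
#' Columns `marker_id`, `lg`, `cM`, then `A_F,C_F,G_F,T_F,A_M,C_M,G_M,T_M`.
#'
#' @param pools pooled count data.frame (see [build_pools()])
#' @param path file path
#' @return `read_pool_tsv()`: the pooled count data.frame
#' @export
write_pool_tsv <- function(pools, path) .write_tsv(pools, path)

#' @rdname write_pool_tsv
#' @export
read_pool_tsv <- function(path) {
  .read_tsv(path, c("marker_id", "lg", "cM",
                    paste0(NUCS, "_F"), paste0(NUCS, "_M")))
}

#' Write called regions as TSV
#'
#' Mirrors the association-region report: linkage group, start, end, size
#' (cM, 2 decimals), above-threshold marker count and (when present) gene
#' count.
#'
#' @param regions data.frame from [call_regions()] /
#'   [count_genes_in_regions()]
#' @param path file path
#' @export
write_region_tsv <- function(regions, path) {
  d <- regions
  for (cc in c("start_cM", "end_cM", "size_cM"))
    d[[cc]] <- sprintf("%.2f", round_half_up(d[[cc]], 2))
  .write_tsv(d, path)
}

#' Write a minimal VCF 4.2 of BC1 genotypes placed on the map
#'
#' One record per mapped marker: CHROM is the linkage group, POS the map
#' position in hundredths of a cM (+1, to stay positive and integral), REF /
#' ALT the recurrent / donor alleles, and a GT field per individual
#' (aa = 0/0, ab = 0/1, bb = 1/1, missing = ./.). A convenience export, not a
#' substitute for the TSV dialect.
#'
#' @param genmat an `slaf_genmat`
#' @param map data.frame marker_id, lg, position_cM (mapped markers only)
#' @param alleles data.frame marker_id, allele_a, allele_b
#' @param path file path
#' @export
write_vcf_min <- function(genmat, map, alleles, path) {
  stopifnot(inherits(genmat, "slaf_genmat"))
  gt_code <- c(aa = "0/0", ab = "0/1", bb = "1/1", "--" = "./.")
  m <- map[order(map$lg, map$position_cM), ]
  m <- m[m$marker_id %in% rownames(genmat$geno), ]
  al <- alleles[match(m$marker_id, alleles$marker_id), ]
  inds <- colnames(genmat$geno)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=slafmap",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", inds), collapse = "\t")), con)
  for (i in seq_len(nrow(m))) {
    g <- gt_code[genmat$geno[m$marker_id[i], ]]
    writeLines(paste(c(paste0("LG", m$lg[i]),
                       as.integer(round(m$position_cM[i] * 100)) + 1L,
                       m$marker_id[i], al$allele_a[i], al$allele_b[i],
                       ".", "PASS", ".", "GT", g), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write truth files of a simulated cross as TSV
#'
#' @param truth an `slaf_truth`
#' @param marker_path,sex_path output paths (either may be `NULL` to skip)
#' @export
write_truth_tsv <- function(truth, marker_path = NULL, sex_path = NULL) {
  stopifnot(inherits(truth, "slaf_truth"))
  if (!is.null(marker_path)) .write_tsv(truth$markers, marker_path)
  if (!is.null(sex_path))
    .write_tsv(data.frame(individual = names(truth$sexes),
                          sex = as.character(truth$sexes)), sex_path)
  invisible(NULL)
}
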