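#' Assemble a validated pipeline configuration
#'
#' Collects every tunable of the simulate / genotype / map / bsa stages with
#' its default. Unknown keys are rejected, so configs round-trip losslessly
#' through YAML.
#'
#' @param ... named overrides of the defaults listed below
#' @return object of class `slaf_config` (a named list)
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1,
    # simulate
    lg_lengths_cM = c(184.18, 187.43, 201.28, 194.01, 180.41, 178.66),
    markers_per_lg = 100,
    map_function_sim = "haldane",
    n_offspring = 148,
    sex_lg = 4, sex_cM = 80,
    depth_parent_mean = c(34.39, 31.31),
    depth_offspring_mean = 7.22,
    error_rate = 0.001,
    tag_length = 100,
    # genotype
    identity_threshold = 0.95,
    min_parent_depth = 10, max_tags = 4, ambiguity_cv = 1.0,
    min_depth = 4, hom_fraction = 0.9,
    integrity_min = 0.6, max_snp = 7, distortion_alpha = 0.05,
    # map
    mlod_threshold = 5,
    n_anneal = 10000, t0 = 1, cooling = 0.999,
    smooth_window = 5, smooth_mismatch_p = 0.98, smooth_rounds = 4,
    smooth_relax = 2, knn_k = 5,
    map_function_est = "kosambi",
    # bsa
    ed_k = 5, loess_span = 0.3, loess_degree = 1, sd_mult = 3,
    region_min_markers = 3, region_merge_gap_cM = 2,
    # stage toggles
    stages = c("simulate", "genotype", "map", "bsa"))
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults[names(over)] <- over
  structure(defaults, class = "slaf_config")
}

#' @rdname pipeline_config
#' @param path YAML file path
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param config an `slaf_config`
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full simulate - genotype - map - bsa pipeline
#'
#' Executes the enabled stages in order on a single configuration, fanning
#' per-stage seeds from the master seed so a fixed config gives a
#' byte-identical run. Later stages may be fed pre-built inputs (`genmat`,
#' `map`, `pools`) when earlier stages are disabled, e.g. for real data read
#' with the `read_*` functions.
#'
#' @param config an `slaf_config` from [pipeline_config()]
#' @param outdir optional directory; when given, all stage artifacts (FASTA
#'   tags, truth, genotype/map/pool/region TSVs, minimal VCF, report JSON and
#'   config echo) are written there
#' @param genmat,map,pools optional stage inputs used when the producing
#'   stage is disabled
#' @return object of class `slaf_run`: stage outputs (`truth`, `counts`,
#'   `genotype`, `map`, `bsa`) plus `report` (see [make_report()]) and
#'   `config`
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         genmat = NULL, map = NULL, pools = NULL) {
  stopifnot(inherits(config, "slaf_config"))
  st <- config$stages
  need <- function(stage, dep, obj)
    if (!(dep %in% st) && is.null(obj))
      stop("stage '", stage, "' requires output of disabled stage '", dep,
           "' and none was supplied", call. = FALSE)
  truth <- NULL; counts <- NULL
  genostage <- NULL; mapstage <- NULL; bsastage <- NULL

  if ("simulate" %in% st) {
    spec <- map_spec(config$lg_lengths_cM, config$markers_per_lg,
                     config$map_function_sim)
    truth <- simulate_cross(spec, config$n_offspring,
                            list(lg = config$sex_lg, cM = config$sex_cM),
                            seed = fan_seed(config$seed, "cross"))
    counts <- simulate_read_counts(
      truth, config$depth_parent_mean, config$depth_offspring_mean,
      config$error_rate, seed = fan_seed(config$seed, "reads"),
      tag_length = config$tag_length)
  }

  if ("genotype" %in% st) {
    need("genotype", "simulate", counts)
    groups <- build_tag_groups(counts, config$identity_threshold)
    filt <- filter_groups(groups, config$min_parent_depth, config$max_tags,
                          config$ambiguity_cv)
    cls <- vapply(filt$kept, classify_polymorphism, character(1))
    poly <- filt$kept[cls == "polymorphic"]
    gm <- build_genotype_matrix(counts, poly,
                                config$min_depth, config$hom_fraction)
    qf <- marker_quality_filter(gm, config$min_parent_depth,
                                config$integrity_min, config$max_snp,
                                config$distortion_alpha)
    genostage <- list(groups = groups, filtered = filt,
                      class_counts = table(factor(cls, levels = c(
                        "polymorphic", "non_polymorphic", "repetitive"))),
                      raw = gm, kept = qf$kept, quality_report = qf$report)
    genmat <- qf$kept
  }

  if ("map" %in% st) {
    need("map", "genotype", genmat)
    stats <- pairwise_rf_lod(genmat)
    grp <- group_markers(stats, config$mlod_threshold)
    orders <- list(); imputed <- list(); changes <- list()
    for (i in seq_along(grp$groups)) {
      ids <- grp$groups[[i]]
      # iterate ordering and error correction until the order stabilizes
      ord <- order_markers(stats$rf, ids,
                           seed = fan_seed(config$seed, paste0("order", i)),
                           n_anneal = config$n_anneal,
                           t0 = config$t0, cooling = config$cooling)
      chg <- list()
      for (pass in 1:3) {
        sm <- smooth_correct(genmat$geno[ord, , drop = FALSE],
                             config$smooth_window, config$smooth_mismatch_p,
                             config$smooth_rounds, config$smooth_relax)
        chg[[pass]] <- sm$changes
        imp <- knn_impute(sm$geno, config$knn_k)
        st_i <- pairwise_rf_lod(imp$geno)
        ord_new <- order_markers(st_i$rf, ord,
                                 seed = fan_seed(config$seed,
                                                 paste0("order", pass, "_", i)),
                                 n_anneal = config$n_anneal,
                                 t0 = config$t0, cooling = config$cooling)
        stable <- identical(as.character(ord_new), as.character(ord))
        ord <- ord_new
        if (stable) break
        if (pass == 3) {
          sm <- smooth_correct(genmat$geno[ord, , drop = FALSE],
                               config$smooth_window, config$smooth_mismatch_p,
                               config$smooth_rounds, config$smooth_relax)
          imp <- knn_impute(sm$geno, config$knn_k)
        }
      }
      orders[[i]] <- as.character(ord)
      imputed[[i]] <- imp$geno[orders[[i]], , drop = FALSE]
      changes[[i]] <- unique(do.call(rbind, chg))
    }
    full <- do.call(rbind, imputed)
    stats2 <- pairwise_rf_lod(full)
    snpc <- stats::setNames(genmat$meta$snp_count, genmat$meta$marker_id)
    gmap <- assemble_map(orders, stats2, config$map_function_est,
                         snp_counts = snpc)
    mapstage <- list(stats = stats, groups = grp, map = gmap,
                     geno_clean = full,
                     changes = do.call(rbind, changes))
    map <- gmap$map
  }

  if ("bsa" %in% st) {
    need("bsa", "map", map)
    if (is.null(pools)) {
      need("bsa", "simulate", counts)
      pools <- build_pools(counts, truth$sexes)
    }
    # scan positions come from the genetic map
    mpos <- map[match(pools$marker_id, map$marker_id), ]
    keep <- !is.na(mpos$lg)
    scanp <- pools[keep, , drop = FALSE]
    scanp$lg <- mpos$lg[keep]
    scanp$cM <- mpos$position_cM[keep]
    bsastage <- bsa_scan(scanp, k = config$ed_k, span = config$loess_span,
                         degree = config$loess_degree,
                         sd_mult = config$sd_mult,
                         min_markers = config$region_min_markers,
                         merge_gap_cM = config$region_merge_gap_cM)
  }

  report <- make_report(counts = counts, genotype = genostage,
                        map = mapstage, bsa = bsastage, config = config)
  run <- structure(list(truth = truth, counts = counts,
                        genotype = genostage, map = mapstage,
                        bsa = bsastage, report = report, config = config),
                   class = "slaf_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

#' Paper-style run report
#'
#' Builds the four summary tables of a run: per-sample depth (Table-1 style),
#' polymorphism classes with percentages (Table-2 style), per-LG map summary
#' with totals (Table-4 style), and the called association regions (Table-5
#' style), plus per-stage marker counts and the config echo. Every number is
#' recomputed from the stage outputs passed in.
#'
#' @param counts,genotype,map,bsa stage outputs of [run_pipeline()] (any may
#'   be `NULL`)
#' @param config the run's `slaf_config`
#' @return list of class `slaf_report`
#' @export
make_report <- function(counts = NULL, genotype = NULL, map = NULL,
                        bsa = NULL, config = NULL) {
  rep <- list(config = if (!is.null(config)) unclass(config))
  if (!is.null(counts)) {
    off <- setdiff(counts$individuals, counts$parents)
    rep$depth_summary <- data.frame(
      sample = c("maternal_parent", "paternal_parent", "offspring"),
      n_loci = c(rep(nrow(counts$depth), 2), nrow(counts$depth)),
      total_depth = c(sum(counts$depth[, "P1_maternal"]),
                      sum(counts$depth[, "P2_paternal"]),
                      sum(counts$depth[, off])),
      average_depth = round_half_up(
        c(mean(counts$depth[, "P1_maternal"]),
          mean(counts$depth[, "P2_paternal"]),
          mean(counts$depth[, off])), 2))
  }
  if (!is.null(genotype)) {
    cc <- as.integer(genotype$class_counts)
    names(cc) <- names(genotype$class_counts)
    pr <- polymorphism_report(cc)
    rep$polymorphism <- data.frame(
      type = names(cc), number = cc, percentage = pr$percentages,
      row.names = NULL)
    rep$quality_filter <- genotype$quality_report
    rep$n_mapping_markers <- nrow(genotype$kept$meta)
  }
  if (!is.null(map)) {
    rep$map_summary <- map$map$summary
    rep$map_totals <- map$map$totals
    rep$n_grouped <- sum(vapply(map$groups$groups, length, integer(1)))
    rep$n_dropped_grouping <- length(map$groups$dropped)
    if (!is.null(genotype))
      rep$mapping_ratio_pct <- mapping_ratio(rep$map_totals$n_markers,
                                             rep$n_mapping_markers)
  }
  if (!is.null(bsa)) {
    rg <- bsa$regions
    rg$start_cM <- round_half_up(rg$start_cM, 2)
    rg$end_cM <- round_half_up(rg$end_cM, 2)
    rg$size_cM <- round_half_up(rg$size_cM, 2)
    rep$regions <- rg
    rep$threshold <- bsa$threshold
  }
  structure(rep, class = "slaf_report")
}

#' Write all artifacts of a pipeline run
#'
#' @param run an `slaf_run`
#' @param outdir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_run <- function(run, outdir) {
  stopifnot(inherits(run, "slaf_run"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  paths <- character(0)
  if (!is.null(run$counts)) {
    tags <- c(stats::setNames(run$counts$tags[, 1],
                              paste0(rownames(run$counts$tags), "_mat")),
              stats::setNames(run$counts$tags[, 2],
                              paste0(rownames(run$counts$tags), "_pat")))
    paths <- c(paths, write_fasta(tags, p("tags.fasta")))
  }
  if (!is.null(run$truth)) {
    write_truth_tsv(run$truth, p("truth_markers.tsv"), p("truth_sexes.tsv"))
    paths <- c(paths, p("truth_markers.tsv"), p("truth_sexes.tsv"))
  }
  if (!is.null(run$genotype))
    paths <- c(paths, write_genotype_tsv(run$genotype$kept,
                                         p("genotypes.tsv")))
  if (!is.null(run$map)) {
    paths <- c(paths, write_map_tsv(run$map$map, p("map.tsv")))
    if (!is.null(run$genotype) && !is.null(run$truth)) {
      al <- run$truth$markers[, c("marker_id", "allele_a", "allele_b")]
      paths <- c(paths, write_vcf_min(run$genotype$kept, run$map$map$map,
                                      al, p("genotypes.vcf")))
    }
  }
  if (!is.null(run$bsa)) {
    paths <- c(paths, .write_tsv(run$bsa$profile, p("ed_profile.tsv")),
               write_region_tsv(run$bsa$regions, p("regions.tsv")))
  }
  rep <- unclass(run$report)
  jsonlite::write_json(rep, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_config(run$config, p("config.yaml"))
  invisible(c(paths, p("report.json"), p("config.yaml")))
}
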