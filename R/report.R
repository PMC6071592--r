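#' Pipeline run configuration
#'
#' Bundles the thresholds, input locations and seed of a pipeline run.
#' All thresholds default to the values used throughout the package
#' (retention r-squared 0.3, strong r-squared 0.6, target filter 0.6,
#' 1 Mb cis window, MAF 0.05, nominal alpha 0.05 with all-pairs Bonferroni
#' correction). The configuration (and therefore its hash, which is
#' embedded in every output file together with the seed) fully determines
#' the outputs, so a rerun with the same configuration reproduces them
#' byte for byte.
#'
#' @param out_dir Output directory (created on demand).
#' @param seed Integer seed recorded in, and used by, all runs.
#' @param keep_r2,strong_r2,target_filter_r2,window_bp Scan thresholds,
#'   see [scan_triplets()].
#' @param maf_min MAF filter applied to input panels (strict, see
#'   [filter_maf()]).
#' @param alpha Nominal familywise significance level.
#' @param n_tests_mode `"all_pairs"` (Bonferroni over all marker pairs) or
#'   `"explicit"` (use `n_tests`, e.g. an externally estimated number of
#'   independent LD blocks).
#' @param n_tests Effective number of tests when `n_tests_mode = "explicit"`.
#' @param predictor_file,target_file,phenotype_file Optional input paths
#'   (genotype tables, VCF, phenotype table) used when the run functions
#'   are not handed objects directly.
#' @param n_sub Optional subsample size applied to the aligned panels.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir = ".", seed = 1L,
                       keep_r2 = 0.3, strong_r2 = 0.6,
                       target_filter_r2 = 0.6, window_bp = 1e6,
                       maf_min = 0.05, alpha = 0.05,
                       n_tests_mode = c("all_pairs", "explicit"),
                       n_tests = NULL,
                       predictor_file = NULL, target_file = NULL,
                       phenotype_file = NULL, n_sub = NULL) {
  n_tests_mode <- match.arg(n_tests_mode)
  stopifnot(
    keep_r2 >= 0, keep_r2 <= 1, strong_r2 >= 0, strong_r2 <= 1,
    target_filter_r2 >= 0, target_filter_r2 <= 1, window_bp > 0,
    maf_min >= 0, maf_min < 0.5, alpha > 0, alpha < 1
  )
  if (n_tests_mode == "explicit" && (is.null(n_tests) || n_tests < 1)) {
    stop("`n_tests` required (>= 1) when n_tests_mode = \"explicit\"", call. = FALSE)
  }
  structure(
    list(
      out_dir = out_dir, seed = as.integer(seed),
      keep_r2 = keep_r2, strong_r2 = strong_r2,
      target_filter_r2 = target_filter_r2, window_bp = window_bp,
      maf_min = maf_min, alpha = alpha,
      n_tests_mode = n_tests_mode, n_tests = n_tests,
      predictor_file = predictor_file, target_file = target_file,
      phenotype_file = phenotype_file, n_sub = n_sub
    ),
    class = "run_config"
  )
}

.config_hash <- function(config) {
  h <- config
  h$out_dir <- NULL
  rlang::hash(h)
}

.write_report <- function(tab, path, config, what) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  header <- c(
    paste0("# phantomepi ", what),
    paste0("# config_hash: ", .config_hash(config)),
    paste0("# seed: ", config$seed)
  )
  body <- readr::format_tsv(tab, na = "NA")
  readr::write_lines(c(header, sub("\n$", "", body)), path)
  invisible(path)
}

.load_panel <- function(path, maf_min, quiet = TRUE) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    read_vcf(path, maf_min = maf_min, quiet = quiet)
  } else {
    filter_maf(read_geno_table(path), maf_min = maf_min, quiet = quiet)
  }
}

.resolve_panel <- function(obj, path, maf_min, what) {
  if (!is.null(obj)) {
    return(filter_maf(obj, maf_min = maf_min, quiet = TRUE))
  }
  if (is.null(path)) stop("no ", what, " panel supplied", call. = FALSE)
  .load_panel(path, maf_min)
}

#' Run a triplet scan and write its report tables
#'
#' Loads (or takes) the predictor and target panels, applies the MAF
#' filter and optional subsampling from the configuration, runs
#' [scan_triplets()], and writes `triplets.tsv` (retained records) and
#' `scan_summary.tsv` (per-class evaluated / kept / strong counts plus the
#' filter accounting) into the output directory. Both files carry the
#' configuration hash and seed as comment lines, so reruns are
#' byte-identical.
#'
#' @param config A [run_config()].
#' @param predictors,targets Optional [geno_matrix()] objects (otherwise
#'   read from the configured paths).
#' @return The `triplet_scan` object, invisibly.
#' @export
run_scan <- function(config, predictors = NULL, targets = NULL) {
  stopifnot(inherits(config, "run_config"))
  P <- .resolve_panel(predictors, config$predictor_file, config$maf_min, "predictor")
  Tg <- .resolve_panel(targets, config$target_file, config$maf_min, "target")
  if (!is.null(config$n_sub)) {
    P <- subsample_individuals(P, config$n_sub, config$seed, quiet = TRUE)
    Tg <- Tg[match(P$individual_ids, Tg$individual_ids), ]
  }
  scan <- scan_triplets(
    P, Tg,
    keep_r2 = config$keep_r2, strong_r2 = config$strong_r2,
    target_filter_r2 = config$target_filter_r2,
    window_bp = config$window_bp, quiet = TRUE
  )
  .write_report(
    scan$triplets, file.path(config$out_dir, "triplets.tsv"), config, "triplets"
  )
  summary_tab <- dplyr::mutate(
    scan$evaluated,
    n_targets = scan$n_targets,
    n_targets_filtered = scan$n_targets_filtered,
    n_individuals = scan$n_individuals
  )
  .write_report(
    summary_tab, file.path(config$out_dir, "scan_summary.tsv"), config,
    "scan summary"
  )
  if (scan$n_targets_filtered == scan$n_targets) {
    warning("all targets filtered out; empty triplet table", call. = FALSE)
  }
  invisible(scan)
}

#' Extrapolate windowed scans genome-wide and write the report
#'
#' Combines per-window scan results (scan objects, or `scan_summary.tsv`
#' paths written by [run_scan()]) with genome-wide possible-triplet totals
#' ([count_possible_pairs()]) into an [extrapolate_genome()] estimate, and
#' writes `extrapolation.tsv`.
#'
#' @param config A [run_config()].
#' @param windows List of `triplet_scan` objects or paths to
#'   `scan_summary.tsv` files (one per window).
#' @param genome_totals Tibble from [count_possible_pairs()] on the
#'   genome-wide maps.
#' @return The `extrapolation_estimate`, invisibly.
#' @export
run_extrapolate <- function(config, windows, genome_totals) {
  stopifnot(inherits(config, "run_config"))
  window_results <- purrr::imap_dfr(windows, function(w, idx) {
    ev <- if (inherits(w, "triplet_scan")) {
      w$evaluated
    } else {
      readr::read_tsv(w, comment = "#", show_col_types = FALSE, progress = FALSE)
    }
    dplyr::mutate(
      ev[c("class", "observed_strong", "evaluated_pairs")],
      window = idx, .before = 1
    )
  })
  est <- extrapolate_genome(window_results, genome_totals)
  .write_report(
    est, file.path(config$out_dir, "extrapolation.tsv"), config, "extrapolation"
  )
  invisible(est)
}

#' Run the two-stage epistasis scan and write the pair table
#'
#' Stage 1: exhaustive uncorrected OLS scan ([epistasis_scan()]) at the
#' configured Bonferroni threshold. Stage 2: every pair passing stage 1 is
#' refitted with a polygenic random effect ([refit_with_kinship()]) whose
#' covariance is the genomic kinship of the scanned panel. Writes
#' `epistasis_pairs.tsv` with both uncorrected and corrected estimates.
#'
#' @param config A [run_config()].
#' @param genotypes Optional [geno_matrix()] (else `config$predictor_file`).
#' @param pheno Optional phenotype tibble (else `config$phenotype_file`).
#' @return Tibble of significant pairs with corrected refit columns,
#'   invisibly (attributes `n_tests`, `p_threshold`).
#' @export
run_episcan <- function(config, genotypes = NULL, pheno = NULL) {
  stopifnot(inherits(config, "run_config"))
  G <- .resolve_panel(genotypes, config$predictor_file, config$maf_min, "genotype")
  if (is.null(pheno)) {
    if (is.null(config$phenotype_file)) stop("no phenotype supplied", call. = FALSE)
    pheno <- read_phenotype(config$phenotype_file)
  }
  al <- align_phenotype(G, pheno)
  m <- n_markers(al$g)
  n_tests <- if (config$n_tests_mode == "all_pairs") n_marker_pairs(m) else config$n_tests
  thr <- bonferroni_threshold(config$alpha, n_tests)

  hits <- epistasis_scan(al$y, al$g, p_threshold = thr)
  if (nrow(hits) > 0) {
    K <- genomic_kinship(al$g)
    refits <- purrr::map(seq_len(nrow(hits)), function(r) {
      refit_with_kinship(
        al$y,
        marker_codes(al$g, hits$marker_i[r]),
        marker_codes(al$g, hits$marker_j[r]),
        K
      )
    })
    hits$beta12_corrected <- purrr::map_dbl(
      refits, ~ .x$coefficients$estimate[4]
    )
    hits$p12_corrected <- purrr::map_dbl(refits, p_interaction)
    hits$lambda <- purrr::map_dbl(refits, "lambda")
  } else {
    hits$beta12_corrected <- numeric(0)
    hits$p12_corrected <- numeric(0)
    hits$lambda <- numeric(0)
  }
  .write_report(
    hits, file.path(config$out_dir, "epistasis_pairs.tsv"), config,
    "epistasis pairs"
  )
  attr(hits, "n_tests") <- n_tests
  attr(hits, "p_threshold") <- thr
  invisible(hits)
}

#' Generate synthetic fixtures and write them as pipeline inputs
#'
#' Thin wrapper over the synthetic-data generators that writes genotype /
#' phenotype / truth tables in the formats the readers accept.
#'
#' @param config A [run_config()] (its seed drives the generator).
#' @param scenario `"perfect_tag"` ([make_perfect_tag_scenario()]), `"complex_locus"`
#'   ([make_complex_locus_scenario()]) or `"mosaic"`
#'   ([simulate_mosaic_genome()]).
#' @param ... Passed on to the generator.
#' @return Named character vector of written file paths, invisibly.
#' @export
run_simulate <- function(config, scenario = c("perfect_tag", "complex_locus", "mosaic"),
                         ...) {
  stopifnot(inherits(config, "run_config"))
  scenario <- match.arg(scenario)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  if (scenario == "perfect_tag") {
    sc <- make_perfect_tag_scenario(seed = config$seed, ...)
    paths["genotypes"] <- write_geno_table(
      sc$genotypes, file.path(config$out_dir, "perfect_tag_genotypes.tsv")
    )
    paths["phenotype"] <- write_phenotype(
      sc$phenotype, file.path(config$out_dir, "perfect_tag_phenotype.tsv")
    )
  } else if (scenario == "complex_locus") {
    sc <- make_complex_locus_scenario(seed = config$seed, ...)
    paths["predictors"] <- write_geno_table(
      sc$predictors, file.path(config$out_dir, "complex_predictors.tsv")
    )
    paths["targets"] <- write_geno_table(
      sc$targets, file.path(config$out_dir, "complex_targets.tsv")
    )
    paths["phenotype"] <- write_phenotype(
      sc$phenotype, file.path(config$out_dir, "complex_phenotype.tsv")
    )
    truth_path <- file.path(config$out_dir, "complex_truth.tsv")
    readr::write_tsv(sc$truth, truth_path, progress = FALSE)
    paths["truth"] <- truth_path
  } else {
    g <- simulate_mosaic_genome(seed = config$seed, ...)
    paths["genotypes"] <- write_geno_table(
      g, file.path(config$out_dir, "mosaic_genotypes.tsv")
    )
  }
  invisible(paths)
}
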