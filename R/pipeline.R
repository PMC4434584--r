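#' Rescale a contact map to a given total
#'
#' Uniform rescaling so two corrected maps become depth-comparable before
#' per-bin metrics are computed.
#'
#' @param map A `ContactMap`.
#' @param total Target total (sum of the full matrix).
#' @return The rescaled map (same `value_kind`, same raw support).
#' @export
rescale_total <- function(map, total) {
  if (map$total == 0) stop("cannot rescale an empty map")
  out <- contact_map(map$binning, map$counts * (total / map$total),
                     value_kind = map$value_kind, raw = map$raw,
                     masked = map$masked)
  if (!is.null(map$biases)) out$biases <- map$biases
  out
}

#' Serialize / read a synthetic spec as JSON
#' @param spec A `SyntheticSpec`.
#' @param path JSON path.
#' @export
write_synthetic_spec <- function(spec, path) {
  jsonlite::write_json(list(
    chrom_bins = as.list(spec$chrom_bins),
    bin_size = spec$bin_size,
    alpha = as.list(spec$alpha),
    compartment_profile = spec$compartment_profile,
    tads = spec$tads,
    trans_weight = spec$trans_weight,
    coverage_bias = spec$coverage_bias,
    planted = spec$planted,
    depth = spec$depth,
    seed = spec$seed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @return `read_synthetic_spec()` returns the `SyntheticSpec`.
#' @export
read_synthetic_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  planted <- list()
  if (length(j$planted)) {
    planted <- if (is.data.frame(j$planted)) {
      lapply(seq_len(nrow(j$planted)), function(k) {
        p <- as.list(j$planted[k, ])
        p$bins <- unlist(p$bins); p$partner <- unlist(p$partner)
        p
      })
    } else {
      j$planted
    }
  }
  synthetic_spec(unlist(j$chrom_bins), bin_size = j$bin_size,
                 alpha = unlist(j$alpha),
                 compartment = j$compartment_profile,
                 tads = j$tads, trans_weight = j$trans_weight,
                 coverage_bias = j$coverage_bias,
                 planted = planted, depth = j$depth, seed = j$seed)
}

#' Simulate a contact-map pair to disk
#'
#' Generates the two maps of a spec and writes them in the package's
#' standard formats: chrom.sizes, BED bin table, two sparse triplet
#' matrices, the ground-truth record (JSON + BED of planted bins) and an
#' echo of the spec.
#'
#' @param spec A `SyntheticSpec`, or the path to a spec JSON.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named list of written paths plus the in-memory
#'   pair.
#' @export
simulate_maps <- function(spec, out_dir) {
  if (is.character(spec)) spec <- read_synthetic_spec(spec)
  if (!inherits(spec, "SyntheticSpec")) stop("spec must be a SyntheticSpec or a path")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pair <- generate_pair(spec)
  binning <- spec$binning

  paths <- list(
    chrom_sizes = file.path(out_dir, "genome.chrom.sizes"),
    bins = file.path(out_dir, "bins.bed"),
    map_a = file.path(out_dir, "map_a.triplets.tsv"),
    map_b = file.path(out_dir, "map_b.triplets.tsv"),
    truth = file.path(out_dir, "truth.json"),
    planted_bed = file.path(out_dir, "planted.bed"),
    spec = file.path(out_dir, "spec.json")
  )
  utils::write.table(binning$chromosomes, paths$chrom_sizes, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_bins_bed(binning, paths$bins)
  write_contact_map(pair$map_a, paths$map_a)
  write_contact_map(pair$map_b, paths$map_b)
  jsonlite::write_json(pair$truth, paths$truth, auto_unbox = TRUE, digits = NA)
  planted_bins <- sort(unique(unlist(lapply(spec$planted, `[[`, "bins"))))
  bed <- binning$bins[planted_bins, , drop = FALSE]
  utils::write.table(
    data.frame(bed$chrom, format(bed$start, scientific = FALSE, trim = TRUE),
               format(bed$end, scientific = FALSE, trim = TRUE)),
    paths$planted_bed, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  write_synthetic_spec(spec, paths$spec)
  invisible(c(paths, list(pair = pair)))
}

#' Build a run configuration
#'
#' @param synthetic Preset name (see [preset_spec()]) or a `SyntheticSpec`;
#'   `NULL` when real input paths are given.
#' @param map_a,map_b,chrom_sizes Paths to input matrices and sizes (used
#'   when `synthetic` is NULL).
#' @param bin_size Bin size for file inputs.
#' @param reference `"a"`, `"b"`, `"deep"` (synthetic runs only: an
#'   independent 4x-depth plant-free draw, see [sample_reference_map()]),
#'   or a path to a reference raw map used for split-half bias filtering.
#' @param q_threshold,fold,n_candidates,error_gate Analysis thresholds;
#'   defaults 0.05, 2, 100 and 0.05.
#' @param mask_percentile Bottom coverage fraction masked before balancing
#'   (default 0.02; see [mask_low_coverage()]).
#' @param seed Master seed.
#' @return A `RunConfig` list.
#' @export
run_config <- function(synthetic = "compression", map_a = NULL, map_b = NULL,
                       chrom_sizes = NULL, bin_size = 1e6, reference = "a",
                       q_threshold = 0.05, fold = 2, n_candidates = 100,
                       error_gate = 0.05, mask_percentile = 0.02, seed = 1L) {
  cfg <- list(synthetic = synthetic, map_a = map_a, map_b = map_b,
              chrom_sizes = chrom_sizes, bin_size = bin_size,
              reference = reference, q_threshold = q_threshold, fold = fold,
              n_candidates = n_candidates, error_gate = error_gate,
              mask_percentile = mask_percentile, seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

#' Run the full two-map comparison
#'
#' Orchestrates the pipeline in analysis order: load or simulate the raw
#' maps, iteratively correct and depth-match them, compute E1 tracks,
#' per-bin region differences with split-half bias filtering, per-contact
#' differential tests, P(s) scaling and architecture metrics, then the
#' compression normalization of map b onto map a's P(s) followed by a
#' re-test. All tables and a deterministic JSON summary are written to
#' `out_dir`.
#'
#' @param config A `RunConfig` (see [run_config()]).
#' @param out_dir Output directory.
#' @return The summary list, invisibly; written as `summary.json`.
#' @export
run_comparison <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  }
  cat(sprintf("hicpair %s | seed %d | started %s\n",
              as.character(utils::packageVersion("hicpair")), config$seed,
              format(Sys.time())), file = log_path)

  stage <- "input"
  result <- tryCatch({
    truth <- NULL
    if (!is.null(config$synthetic)) {
      spec <- if (inherits(config$synthetic, "SyntheticSpec")) config$synthetic
              else preset_spec(config$synthetic, seed = config$seed)
      pair <- generate_pair(spec)
      raw_a <- pair$map_a; raw_b <- pair$map_b; truth <- pair$truth
      logf("stage input: simulated preset with %d bins", spec$binning$n_bins)
    } else {
      for (p in c(config$map_a, config$map_b, config$chrom_sizes)) {
        if (!file.exists(p)) stop("input path not found: ", p)
      }
      raw_a <- read_contact_map(config$map_a, config$chrom_sizes, config$bin_size)
      raw_b <- read_contact_map(config$map_b, config$chrom_sizes, config$bin_size)
      logf("stage input: read %s and %s", config$map_a, config$map_b)
    }

    stage <- "correct"
    shared_mask <- mask_low_coverage(raw_a, raw_b, config$mask_percentile)
    raw_a$masked <- shared_mask
    raw_b$masked <- shared_mask
    corr_a <- iterative_correction(raw_a)
    corr_b <- rescale_total(iterative_correction(raw_b), corr_a$total)
    write_biases(corr_a, file.path(out_dir, "biases_a.tsv"))
    write_biases(corr_b, file.path(out_dir, "biases_b.tsv"))

    stage <- "compartments"
    ref_track <- if (!is.null(truth)) truth$compartment_profile else NULL
    e1_a <- compute_e1(corr_a, reference = ref_track)
    e1_b <- compute_e1(corr_b, reference = ref_track)
    write_bedgraph(e1_a, file.path(out_dir, "e1_a.bedGraph"))
    write_bedgraph(e1_b, file.path(out_dir, "e1_b.bedGraph"))
    e1_cmp <- compare_e1(e1_a, e1_b)

    stage <- "regions"
    ref_map <- switch(config$reference,
                      a = raw_a, b = raw_b,
                      deep = {
                        if (is.null(config$synthetic)) {
                          stop("reference = 'deep' requires a synthetic run")
                        }
                        sample_reference_map(spec)
                      },
                      read_contact_map(config$reference, config$chrom_sizes,
                                       config$bin_size))
    ref <- reference_difference_table(ref_map, seed = config$seed)
    tab <- bin_difference_table(corr_a, corr_b, e1_a = e1_a, e1_b = e1_b,
                                reference_c = ref$c_i)
    cand <- select_candidates(tab, ref$table, n = config$n_candidates)
    write_difference_table(tab, file.path(out_dir, "bin_differences.tsv"))
    inter_bed <- corr_a$binning$bins[cand$intersection, , drop = FALSE]
    utils::write.table(
      data.frame(inter_bed$chrom,
                 format(inter_bed$start, scientific = FALSE, trim = TRUE),
                 format(inter_bed$end, scientific = FALSE, trim = TRUE)),
      file.path(out_dir, "different_regions.bed"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)

    stage <- "contacts"
    tests <- test_contacts(corr_a, corr_b, q_threshold = config$q_threshold,
                           fold = config$fold)
    write_contact_tests(tests, corr_a$binning,
                        file.path(out_dir, "contact_tests.tsv"))

    stage <- "architecture"
    ps_a <- ps_curve(corr_a); ps_b <- ps_curve(corr_b)
    fit_a <- fit_power_law(ps_a); fit_b <- fit_power_law(ps_b)
    write_scaling_curve(ps_a, file.path(out_dir, "ps_a.tsv"))
    write_scaling_curve(ps_b, file.path(out_dir, "ps_b.tsv"))
    ct_a <- cis_trans_ratio(raw_a); ct_b <- cis_trans_ratio(raw_b)
    ldc <- NULL
    if (nrow(corr_a$binning$chromosomes) >= 3) {
      ic_a <- interchrom_enrichment(raw_a)
      ldc <- length_diff_correlation(ic_a, corr_a$binning)
    } else {
      logf("stage architecture: < 3 chromosomes, interchromosomal metrics skipped")
    }

    stage <- "compression"
    coeffs <- compression_coefficients(corr_a, corr_b,
                                       error_gate = config$error_gate)
    utils::write.table(
      data.frame(distance_bp = coeffs$separation * corr_a$binning$bin_size,
                 K = coeffs$K, error = coeffs$error, applied = coeffs$applied),
      file.path(out_dir, "compression_coefficients.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    comp_b <- apply_compression(corr_b, coeffs)
    tests_post <- test_contacts(corr_a, comp_b,
                                q_threshold = config$q_threshold,
                                fold = config$fold)

    stage <- "summary"
    cls <- function(tt) as.list(attr(tt, "counts"))
    cfg_echo <- unclass(config)
    if (inherits(cfg_echo$synthetic, "SyntheticSpec")) {
      write_synthetic_spec(cfg_echo$synthetic, file.path(out_dir, "spec.json"))
      cfg_echo$synthetic <- "spec.json"
    }
    summary <- list(
      config = cfg_echo[!vapply(cfg_echo, is.null, TRUE)],
      n_bins = corr_a$binning$n_bins,
      e1 = list(pearson = e1_cmp$pearson, spearman = e1_cmp$spearman),
      regions = list(
        intersection = cand$intersection,
        n_eucl = cand$n_eucl, n_p = cand$n_p, n_e1 = cand$n_e1,
        n_t = cand$n_t, expected_overlap = cand$expected),
      contacts = list(n_tests = attr(tests, "n_tests"), classes = cls(tests)),
      scaling = list(exponent_a = fit_a$exponent, se_a = fit_a$se,
                     exponent_b = fit_b$exponent, se_b = fit_b$se),
      cis_trans = list(a = ct_a$genome_wide, b = ct_b$genome_wide),
      length_diff_correlation = ldc,
      compression = list(
        n_applied = sum(coeffs$applied),
        classes_post = cls(tests_post),
        n_significant_pre = sum(tests$class %in%
                                c("significant", "significant_2fold")),
        n_significant_post = sum(tests_post$class %in%
                                 c("significant", "significant_2fold")))
    )
    if (!is.null(truth) && length(truth$planted)) {
      planted_bins <- sort(unique(unlist(lapply(truth$planted, `[[`, "bins"))))
      summary$regions$planted_bins <- planted_bins
      summary$regions$planted_recovered <-
        sum(planted_bins %in% cand$intersection)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    logf("stage summary: done")
    summary
  }, error = function(e) {
    logf("FAILED at stage %s: %s", stage, conditionMessage(e))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
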