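#' Default pipeline configuration
#'
#' The conventional analysis constants: differential statistic at 6.5 Mb
#' with 500,000 null interactions, compartments at 250 kb, insulation-square
#' TADs at 40 kb (25-bin square, 0.15 strength cutoff, 90% reciprocal TAD
#' overlap), telomere ends at 5% of chromosome length, differential
#' expression filters log2FC > 1 and adjusted p < 0.01.
#'
#' @param ... Overrides of any default entry.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    res_differential = 6.5e6,
    res_compartments = 2.5e5,
    res_tads = 4e4,
    res_scaling = 1e6,
    insulation_w = 25L,
    boundary_strength = 0.15,
    tad_min_overlap = 0.90,
    end_fraction = 0.05,
    n_null = 500000L,
    mask_fraction = 0.02,
    de_log2fc = 1,
    de_padj = 0.01,
    seed = 1L
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

#' Run the comparative Hi-C pipeline on a synthetic study
#'
#' End-to-end recipe on generated data: simulate two conditions x two
#' replicates, ICE-balance, z-score, differential map, compartments and
#' switches, insulation/TAD boundaries per condition, scaling curves and
#' telomere statistics; write every stage's outputs plus a run manifest
#' (config echo and md5 checksum per file) into \code{out_dir}.
#' Deterministic given (spec, config).
#'
#' @param spec A \code{SyntheticSpec} (or NULL to use
#'   \code{synthetic_spec()} defaults with the config seed).
#' @param config List from \code{\link{default_config}}. The analysis runs
#'   at the spec's own bin size (one resolution; the per-analysis
#'   resolutions in the config apply when maps at several resolutions are
#'   supplied).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the principal per-stage results.
#' @export
run_pipeline <- function(spec = NULL, config = default_config(),
                         out_dir = tempfile("hicdelta_run")) {
  if (is.null(spec)) spec <- synthetic_spec(seed = config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[hicdelta] ", sprintf(...))

  log_stage("simulating 2 conditions x 2 replicates (%d bins)",
            spec$binning$n_bins)
  raws <- list(A1 = sample_map(spec, 1, 1), A2 = sample_map(spec, 1, 2),
               B1 = sample_map(spec, 2, 1), B2 = sample_map(spec, 2, 2))
  write_truth(spec, file.path(out_dir, "truth"))

  log_stage("ICE balancing")
  iced <- lapply(raws, function(m)
    ice_balance(mask_low_coverage(m, config$mask_fraction))$map)
  combined <- list()
  for (cond in c("A", "B")) {
    s <- raws[[paste0(cond, "1")]]
    s$values <- s$values + raws[[paste0(cond, "2")]]$values
    combined[[cond]] <- ice_balance(mask_low_coverage(
      s, config$mask_fraction))$map
  }

  log_stage("z-score transform")
  zmaps <- lapply(iced, function(m)
    zscore_transform(m, distance_expected(m)))

  log_stage("differential score (n_null=%d)", config$n_null)
  dm <- suppressWarnings(differential_score(
    zmaps$A1, zmaps$A2, zmaps$B1, zmaps$B2,
    n_null = config$n_null, seed = config$seed))
  write_contact_map(contact_map(dm$binning,
                                ifelse(is.finite(dm$score), dm$score, NA),
                                mask = rep(FALSE, dm$binning$n_bins),
                                state = "raw"),
                    file.path(out_dir, "differential_scores.tsv"), "dense")

  log_stage("compartments")
  genes <- truth_genes(spec)
  zc <- lapply(combined, function(m)
    zscore_transform(m, distance_expected(m)))
  profs <- lapply(zc, function(z)
    suppressWarnings(call_compartments(z, genes)))
  sw <- classify_switches(profs$A, profs$B)
  for (cond in c("A", "B")) {
    p <- profs[[cond]]
    write_bedgraph(data.frame(chrom = p$chrom, start = p$start, end = p$end,
                              value = p$eigen),
                   file.path(out_dir, sprintf("eigenvector_%s.bedgraph", cond)))
  }
  write_bed(interval_set(sw$chrom, sw$start, sw$end, name = sw$category),
            file.path(out_dir, "switches.bed"))

  log_stage("insulation / boundaries")
  tracks <- lapply(combined, insulation, w = config$insulation_w)
  bounds <- lapply(tracks, call_boundaries,
                   strength_threshold = config$boundary_strength)
  for (cond in c("A", "B")) {
    tr <- tracks[[cond]]
    write_bedgraph(data.frame(chrom = tr$chrom, start = tr$start,
                              end = tr$end, value = tr$normalized),
                   file.path(out_dir, sprintf("insulation_%s.bedgraph", cond)))
    bd <- bounds[[cond]]
    if (nrow(bd))
      write_bed(interval_set(bd$chrom, bd$start, bd$end,
                             name = sprintf("b%03d", seq_len(nrow(bd))),
                             score = bd$strength),
                file.path(out_dir, sprintf("boundaries_%s.bed", cond)))
  }
  bc <- classify_boundaries(bounds$A, bounds$B)
  log_stage("boundaries: %d/%d called, %d/%d overlapping",
            nrow(bounds$A), nrow(bounds$B), bc$n_overlap1, bc$n_overlap2)

  log_stage("scaling / telomeres")
  curves <- lapply(combined, scaling_curve, scope = "genome")
  for (cond in c("A", "B"))
    utils::write.table(as.data.frame(curves[[cond]]),
                       file.path(out_dir, sprintf("scaling_%s.tsv", cond)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  tel <- lapply(combined, function(m)
    suppressWarnings(telomere_interaction(m, config$end_fraction)))
  telcmp <- if (!is.null(tel$A) && !is.null(tel$B) &&
                nrow(tel$A) >= 1 && nrow(tel$B) >= 1)
    suppressWarnings(compare_telomere(tel$A, tel$B)) else NULL

  manifest <- list(
    package = "hicdelta",
    version = as.character(utils::packageVersion("hicdelta")),
    config = config,
    spec_seed = spec$seed,
    files = list()
  )
  fl <- list.files(out_dir, recursive = TRUE)
  fl <- fl[fl != "manifest.json"]
  manifest$files <- as.list(tools::md5sum(file.path(out_dir, fl)))
  names(manifest$files) <- fl
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(differential = dm, switches = sw, boundaries = bounds,
                 boundary_classes = bc, curves = curves, telomere = telcmp,
                 out_dir = out_dir))
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys override \code{\link{default_config}}.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}
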