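#' Validate a pipeline run configuration
#'
#' A run configuration names the inputs and thresholds of a full analysis run.
#' Required fields: `gff`, `peaks` (BED), `contigs` (TSV), `go_annotations`
#' (TSV), `out_dir`. Optional: `coverage` (bedGraph), `cov_threshold` (50),
#' `ppkm_threshold` (10), `p_high` (0.01), `p_void` (0.05), `count_mode`
#' (`body`), `criterion` (`any`), `nested` (`cumulative`), `flank_sizes`
#' (1000, 5000, 10000).
#'
#' @param config Named list, or path to a YAML file holding one.
#' @return The completed configuration list (defaults filled in).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  required <- c("gff", "peaks", "contigs", "go_annotations", "out_dir")
  miss <- setdiff(required, names(config))
  if (length(miss))
    stop("config is missing field(s): ", paste(miss, collapse = ", "))
  defaults <- list(coverage = NULL, cov_threshold = 50, ppkm_threshold = 10,
                   p_high = 0.01, p_void = 0.05, count_mode = "body",
                   criterion = "any", nested = "cumulative",
                   flank_sizes = c(1000, 5000, 10000))
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[nm] <- list(defaults[[nm]])
  with(config, stopifnot(cov_threshold > 0, ppkm_threshold > 0,
                         p_high > 0, p_void > 0, all(flank_sizes > 0)))
  for (f in c("gff", "peaks", "contigs", "go_annotations"))
    if (!file.exists(config[[f]]))
      stop("config input does not exist: ", f, " = ", config[[f]])
  if (!is.null(config$coverage) && !file.exists(config$coverage))
    stop("config input does not exist: coverage = ", config$coverage)
  config
}

.stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%OS1"), stage, msg))
}

.write_tsv <- function(d, path, header_comment) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0("# ", header_comment), con, sep = "\n")
  writeLines(paste(names(d), collapse = "\t"), con, sep = "\n")
  if (nrow(d)) {
    body <- do.call(paste, c(lapply(d, as.character), sep = "\t"))
    writeLines(body, con, sep = "\n")
  }
  invisible(path)
}

#' Run the full peak-annotation pipeline
#'
#' Executes the four analysis stages in order — element map, density table,
#' PPKM scoring/classification, GO-term comparison — writing every
#' intermediate table under `out_dir` and a JSON manifest recording the
#' package version, a hash of the configuration, input checksums, and
#' per-stage row counts. Outputs are a pure function of (inputs, config):
#' rerunning an identical configuration reproduces identical files.
#'
#' @param config Named list or YAML path; see [validate_config()].
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ## out_dir is a location, not an analysis parameter: keep it out of the hash
  ## so identical analyses into different directories share a config hash
  cfg_analysis <- config[setdiff(names(config), "out_dir")]
  cfg_canon <- jsonlite::toJSON(cfg_analysis[base::order(names(cfg_analysis))],
                                auto_unbox = TRUE, null = "null")
  cfg_hash <- substr(.md5_string(as.character(cfg_canon)), 1, 12)
  hdr <- paste0("hmcpeaks ", as.character(utils::packageVersion("hmcpeaks")),
                " config=", cfg_hash)
  inputs <- c(gff = config$gff, peaks = config$peaks, contigs = config$contigs,
              go_annotations = config$go_annotations,
              if (!is.null(config$coverage)) c(coverage = config$coverage))
  manifest <- list(tool = "hmcpeaks",
                   version = as.character(utils::packageVersion("hmcpeaks")),
                   config_hash = cfg_hash,
                   config = config,
                   input_md5 = as.list(tools::md5sum(inputs)),
                   stages = list())
  run_stage <- function(name, fn) {
    .stage_log(name, "start")
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    .stage_log(name, sprintf("done in %.2fs", proc.time()[["elapsed"]] - t0))
    res
  }

  gm <- run_stage("load", function() read_gff_genes(config$gff))
  contigs <- read_contigs(config$contigs)
  peaks <- read_bed_peaks(config$peaks)

  emap <- run_stage("elements", function()
    build_element_map(gm, contigs, config$flank_sizes))
  edir <- file.path(config$out_dir, "elements")
  write_element_map(emap, edir)
  manifest$stages$elements <- list(n_classes = length(emap$ranges),
                                   total_bases = as.list(emap$total_bases))

  if (!is.null(config$coverage)) {
    cov <- read_coverage_bedgraph(config$coverage)
    mask <- build_coverage_mask(cov, config$cov_threshold)
    peaks_f <- filter_peaks(peaks, mask)
  } else {
    peaks_f <- suppressWarnings(filter_peaks(peaks, NULL))
    .stage_log("coverage", "no bedGraph supplied; peaks pass through unfiltered")
  }

  dt <- run_stage("density", function()
    density_table(peaks_f, emap, criterion = config$criterion,
                  nested = config$nested))
  .write_tsv(as.data.frame(dt), file.path(config$out_dir, "density.tsv"), hdr)
  manifest$stages$density <- list(
    n_rows = nrow(dt), n_peaks_input = attr(dt, "n_peaks_input"),
    n_peaks_unassigned = attr(dt, "n_peaks_unassigned"))

  pp <- run_stage("ppkm", function()
    classify_genes(gm, peaks_f, threshold = config$ppkm_threshold,
                   count_mode = config$count_mode))
  .write_tsv(pp, file.path(config$out_dir, "ppkm.tsv"), hdr)
  manifest$stages$ppkm <- list(n_genes = nrow(pp),
                               n_void = sum(pp$group == "void"),
                               n_high = sum(pp$group == "high"))

  go <- run_stage("go-compare", function() {
    ann <- read_go_annotations(config$go_annotations)
    compare_go_terms(pp$gene_id[pp$group == "high"],
                     pp$gene_id[pp$group == "void"],
                     ann, config$p_high, config$p_void)
  })
  .write_tsv(as.data.frame(go), file.path(config$out_dir, "go_comparison.tsv"), hdr)
  manifest$stages$go_compare <- list(n_terms = nrow(go),
                                     n_selected = sum(go$selected))

  outs <- c(file.path(config$out_dir, c("density.tsv", "ppkm.tsv",
                                        "go_comparison.tsv")),
            file.path(edir, "total_bases.tsv"))
  manifest$output_md5 <- as.list(tools::md5sum(outs))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  .stage_log("pipeline", "4 stages completed")
  invisible(manifest)
}

.md5_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}
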