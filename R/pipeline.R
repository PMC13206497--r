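#' Run the full analysis pipeline on a dataset directory
#'
#' Reads the four input tables from `input_dir` (the layout written by
#' [simulate_to_dir()]: `abundance.tsv`, `volatiles.tsv`, `indicators.tsv`,
#' `omission.tsv` with sample sidecars), then executes the stages in order —
#' dominance screen, co-occurrence network and hubs, flavor association,
#' candidate core, omission pruning, phase segmentation, indicator
#' assignment, taxa-phase correspondence — and writes every report plus a
#' JSON run manifest into `output_dir`. Any stage failure halts with an
#' error naming the stage.
#'
#' @param input_dir Directory holding the input tables.
#' @param output_dir Directory for reports (created if absent).
#' @param config An [analysis_config()].
#' @param level Taxonomic level tag of the abundance table.
#' @param normalized Whether the stored abundance values are already
#'   relative abundances; raw values are closed automatically.
#' @return A list of class `run_manifest`: config snapshot, input file MD5
#'   digests, package version, per-stage outputs and timings, plus the
#'   in-memory `core_report`, `phase_segmentation`, `indicator_assignment`
#'   and `phase_correspondence` results.
#' @export
run_pipeline <- function(input_dir, output_dir, config = analysis_config(),
                         level = "species", normalized = TRUE) {
  inputs <- file.path(input_dir, c("abundance.tsv", "volatiles.tsv",
                                   "indicators.tsv", "omission.tsv"))
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in)) {
    abort(sprintf("missing input file(s): %s",
                  paste(basename(missing_in), collapse = ", ")))
  }
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  digests <- tools::md5sum(inputs)

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    list(result = res,
         seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  io <- stage("read_inputs", {
    list(
      abundance = read_abundance(inputs[1], level = level,
                                 normalized = normalized),
      volatiles = read_volatiles(inputs[2]),
      indicators = read_indicators(inputs[3]),
      omission = read_omission(inputs[4])
    )
  })
  dat <- io$result
  if (!dat$abundance$normalized) dat$abundance <- normalize_relative(dat$abundance)

  core_stage <- stage("core_selection", {
    identify_core(dat$abundance, dat$volatiles, omission = dat$omission,
                  config = config)
  })
  report <- core_stage$result
  seg_stage <- stage("phase_segmentation", {
    segment_phases(community_trajectory(dat$abundance), k = config$n_phases)
  })
  seg <- seg_stage$result
  assign_stage <- stage("indicator_assignment", {
    assign_indicators(dat$indicators, seg)
  })
  corr_stage <- stage("phase_correspondence", {
    taxa_phase_correspondence(dat$abundance, dat$volatiles, dat$indicators,
                              report$final_core, seg, config)
  })

  write_dominance(report$dominance, file.path(output_dir, "dominance.tsv"))
  write_network_edges(report$network, file.path(output_dir, "network_edges.tsv"),
                      file.path(output_dir, "network_degree.tsv"))
  write_core_report(report, file.path(output_dir, "core_report"))
  jsonlite::write_json(
    list(boundaries = seg$boundaries, labels = seg$labels,
         assignment = seg$assignment),
    file.path(output_dir, "segmentation.json"), digits = NA
  )
  readr::write_tsv(assign_stage$result$assignment,
                   file.path(output_dir, "indicator_assignment.tsv"),
                   progress = FALSE)
  readr::write_tsv(corr_stage$result$mapping,
                   file.path(output_dir, "taxa_phases.tsv"), progress = FALSE)

  timings <- tibble(
    stage = c("read_inputs", "core_selection", "phase_segmentation",
              "indicator_assignment", "phase_correspondence"),
    seconds = c(io$seconds, core_stage$seconds, seg_stage$seconds,
                assign_stage$seconds, corr_stage$seconds)
  )
  manifest <- structure(
    list(
      config = unclass(config),
      inputs = tibble(file = basename(inputs), md5 = unname(digests)),
      version = as.character(utils::packageVersion("syncomcore")),
      outputs = union(list.files(output_dir), "manifest.json"),
      timings = timings,
      core_report = report,
      segmentation = seg,
      indicator_assignment = assign_stage$result,
      phase_correspondence = corr_stage$result
    ),
    class = "run_manifest"
  )
  manifest_json <- manifest[c("config", "version", "outputs")]
  manifest_json$inputs <- manifest$inputs
  manifest_json$final_core <- report$final_core
  jsonlite::write_json(manifest_json, file.path(output_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> syncomcore %s\n", x$version))
  cat(sprintf("  final core (%d): %s\n", length(x$core_report$final_core),
              paste(x$core_report$final_core, collapse = ", ")))
  cat(sprintf("  phase boundaries: day %s\n",
              paste(x$segmentation$boundaries, collapse = ", ")))
  invisible(x)
}
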