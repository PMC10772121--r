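# End-to-end orchestration: a declarative YAML config drives footprint ->
# contacts -> (optional) overlap -> (optional) variants -> (optional)
# kinetics, producing one versioned JSON report. Optional stages whose
# inputs are absent are skipped with a warning, never an error; no network
# access ever occurs (structure files must be local).

PIPELINE_SCHEMA_VERSION <- 1L

#' Read and validate a pipeline configuration
#'
#' The configuration is a single YAML document. Required fields:
#' `structure` (path), `target_chains`, `binder_chains`. Optional:
#' `epitope_threshold` (default 1.0), `sasa` (probe_radius,
#' n_sphere_points), `overlap` (source_seq, reference_seq, footprint_b: a
#' CSV with position,dsasa columns), `variants` (msa, table, reference),
#' `kinetics` (manifest, model: global|steady), `seed`, `output_dir`.
#'
#' @param path YAML file path.
#' @return A validated list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg, base = dirname(path))
}

validate_pipeline_config <- function(cfg, base = ".") {
  need <- c("structure", "target_chains", "binder_chains")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0)
    stop("config schema error: missing field(s) ", paste(missing, collapse = ", "))
  resolve <- function(p) if (is.null(p) || file.exists(p)) p else file.path(base, p)
  cfg$structure <- resolve(cfg$structure)
  if (!file.exists(cfg$structure))
    stop("config schema error: structure file not found: ", cfg$structure)
  cfg$epitope_threshold <- cfg$epitope_threshold %||% 1.0
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  for (sect in c("variants", "kinetics", "overlap")) {
    for (f in intersect(names(cfg[[sect]]), c("msa", "table", "manifest", "footprint_b")))
      cfg[[sect]][[f]] <- resolve(cfg[[sect]][[f]])
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a pipeline configuration back to YAML
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  path
}

#' Run the full epitope-analysis pipeline
#'
#' Chains footprint computation, contact classification and, when their
#' inputs are configured, footprint overlap, variant intersection and
#' kinetics fitting into one report. The run is deterministic for a fixed
#' config and seed. A missing optional stage input produces a warning and
#' the report omits that section; the run still succeeds.
#'
#' @param config A [read_pipeline_config()] result (or a list with the same
#'   fields, validated on the fly).
#' @param output Optional path for the JSON report; when `NULL` no file is
#'   written.
#' @return The report as a list (class `pipeline_report`), invisibly
#'   written to `output` when requested. Timestamps are excluded so reruns
#'   are byte-identical.
#' @export
run_pipeline <- function(config, output = NULL) {
  if (!inherits(config, "pipeline_config"))
    config <- validate_pipeline_config(config)
  sasa_cfg <- config$sasa %||% list()
  params <- sasa_params(
    probe_radius = sasa_cfg$probe_radius %||% 1.4,
    n_sphere_points = sasa_cfg$n_sphere_points %||% 960
  )
  s <- read_structure(config$structure)
  fp <- compute_footprint(s, config$target_chains, config$binder_chains,
                          params = params,
                          epitope_threshold = config$epitope_threshold)
  contacts <- classify_contacts(s, config$binder_chains, config$target_chains)

  report <- list(
    schema_version = PIPELINE_SCHEMA_VERSION,
    tool = paste0("epifoot ", as.character(utils::packageVersion("epifoot"))),
    config_digest = unname(tools::md5sum(write_pipeline_config(config, tempfile(fileext = ".yaml")))),
    seed = config$seed,
    footprint = footprint_report(fp, contacts)
  )

  ov <- config$overlap
  if (!is.null(ov)) {
    if (is.null(ov$footprint_b) || !file.exists(ov$footprint_b)) {
      warning("overlap stage skipped: footprint_b input missing")
    } else {
      fpb <- utils::read.csv(ov$footprint_b)
      ma <- map_footprint(fp, ov$source_seq, ov$reference_seq,
                          numbering_offset = ov$numbering_offset %||% 0)
      mb <- map_footprint(fpb, ov$reference_seq, ov$reference_seq)
      res <- footprint_overlap(ma, mb)
      report$overlap <- list(
        overlap_area = res$overlap_area,
        shared_positions = res$shared_positions,
        occlusion_fraction = occlusion_check(ma, mb)
      )
    }
  }

  va <- config$variants
  if (!is.null(va)) {
    if (is.null(va$msa) || !file.exists(va$msa) ||
        is.null(va$table) || !file.exists(va$table)) {
      warning("variants stage skipped: msa or variant table missing")
    } else {
      msa <- read_msa(va$msa)
      vtab <- read_variant_table(va$table)
      rep_df <- intersect_epitope(vtab, msa, fp,
                                  reference_id = va$reference %||% msa$ids[1],
                                  contacts = contacts)
      report$variants <- as.data.frame(rep_df)
    }
  }

  ki <- config$kinetics
  if (!is.null(ki)) {
    if (is.null(ki$manifest) || !file.exists(ki$manifest)) {
      warning("kinetics stage skipped: manifest missing")
    } else {
      traces <- read_bli_dataset(ki$manifest)
      fit <- if (identical(ki$model %||% "global", "steady"))
        fit_steady_state(traces) else fit_langmuir_global(traces, seed = config$seed)
      report$kinetics <- list(
        model = fit$model, kon = fit$params$kon, koff = fit$params$koff,
        rmax = fit$params$rmax, kd = fit$params$kd, rss = fit$rss,
        converged = fit$converged,
        nonsaturating = fit$nonsaturating %||% FALSE
      )
    }
  }

  class(report) <- "pipeline_report"
  if (!is.null(output)) {
    dir.create(dirname(output), recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report), output, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== epifoot pipeline report (schema v", x$schema_version, ") ==\n", sep = "")
  print(x$footprint)
  if (!is.null(x$overlap))
    cat(sprintf("overlap: %.1f A^2, occlusion fraction %.2f\n",
                x$overlap$overlap_area, x$overlap$occlusion_fraction))
  if (!is.null(x$variants))
    cat("variants:", nrow(x$variants), "records,",
        sum(x$variants$in_epitope), "in epitope\n")
  if (!is.null(x$kinetics))
    cat(sprintf("kinetics (%s): KD %.3g nM%s\n", x$kinetics$model,
                x$kinetics$kd * 1e9,
                if (isTRUE(x$kinetics$nonsaturating)) " [non-saturating]" else ""))
  invisible(x)
}
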