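#' Estimate rates from assay outputs
#'
#' The pipeline-level rate stage: aggregates per-enzyme colony counts over
#' replicates, computes mutant frequencies, takes mean mutations per
#' sequenced clone from the callsets, derives the detectable-sites error
#' rate for the scored region, and assembles the full report table via
#' [build_table1()].
#'
#' @param counts data.frame with columns `enzyme_label`, `replicate_id`,
#'   `n_tet`, `n_amp` (one or more replicates per enzyme).
#' @param callsets named list (by enzyme label) of event data.frames from
#'   [call_clones()].
#' @param rosters named list (by enzyme label) of sequenced clone ids —
#'   the denominators for per-clone means; defaults to the ids present in
#'   each callset (i.e. assumes every sequenced clone had at least one
#'   event, which holds in this assay since false-positive colonies are
#'   absent).
#' @param model a [gene_model()].
#' @param catalogue a [site_catalogue()].
#' @param params an [assay_params()].
#' @param region interval set scored for the detectable-sites estimator;
#'   defaults to the model's scoring region.
#' @param baseline,comparator enzyme labels passed to [build_table1()].
#' @param multihit see [error_rate_from_callset()].
#' @return a `fidelity_table` (see [build_table1()]).
#' @export
estimate_rates <- function(counts, callsets, rosters = NULL,
                           model, catalogue, params = assay_params(),
                           region = NULL, baseline = "WT",
                           comparator = "Taq", multihit = TRUE) {
  agg <- stats::aggregate(cbind(n_tet, n_amp) ~ enzyme_label, data = counts,
                          FUN = sum)
  rows <- lapply(seq_len(nrow(agg)), function(i) {
    enz <- agg$enzyme_label[i]
    mf <- mutant_frequency(agg$n_tet[i], agg$n_amp[i], params$e)
    cs <- callsets[[enz]]
    roster <- rosters[[enz]] %||% unique(cs$clone_id)
    if (is.null(cs) || length(roster) == 0L) {
      return(data.frame(enzyme = enz, mf = mf, m = NA_real_,
                        er_detectable = NA_real_))
    }
    m <- mean(mutations_per_clone(cs, roster))
    er <- error_rate_from_callset(mf, cs, roster, catalogue, model,
                                  region = region, P = params$P,
                                  multihit = multihit)
    data.frame(enzyme = enz, mf = mf, m = m, er_detectable = er$ER)
  })
  datasets <- do.call(rbind, rows)
  build_table1(datasets, params, baseline = baseline,
               comparator = comparator)
}

#' Run the complete synthetic-assay pipeline
#'
#' simulate -> call -> spectrum/rates -> report, for one enzyme
#' configuration, writing all stage outputs and a run manifest to
#' `out_dir`. This is the programmatic equivalent of the bundled command
#' line tool's `all` subcommand.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param window complex-merge window for calling.
#' @return invisible list with the assay, callset, spectrum and the
#'   detectable-sites rate estimate.
#' @export
run_pipeline <- function(config, out_dir, window = 2L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assay <- simulate_assay(config)
  write_sim_assay(assay, out_dir)
  callset <- call_clones(assay$clones, config$model, window = window)
  write_events(callset, file.path(out_dir, "events.tsv"))
  write_events_vcf(callset, config$model, file.path(out_dir, "events.vcf"))
  spec_tab <- tabulate_spectrum(callset, config$model,
                                enzyme_label = config$enzyme_label)
  write_spectrum(spec_tab, file.path(out_dir, "spectrum.tsv"))
  dist <- adjacent_distances(callset)
  write_distances(dist, file.path(out_dir, "distances.tsv"))
  mf <- mutant_frequency(assay$colony_counts$n_tet,
                         assay$colony_counts$n_amp, config$e)
  roster <- names(assay$clones)
  er <- if (length(roster)) {
    error_rate_from_callset(mf, callset, roster, config$catalogue,
                            config$model,
                            region = config$model$replicated_interval,
                            P = config$P)
  } else NULL
  write_manifest(out_dir, command = "all", seed = config$seed,
                 config = config,
                 inputs = character(0))
  res <- list(assay = assay, callset = callset, spectrum = spec_tab,
              distances = dist, mf = mf, rate = er)
  jsonlite::write_json(
    list(enzyme = config$enzyme_label, mf = mf,
         er_detectable = if (is.null(er)) NA else er$ER,
         n_tet = assay$colony_counts$n_tet,
         n_amp = assay$colony_counts$n_amp),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Write a run manifest
#'
#' Records command, seed, tool version, timestamp, the digest of the
#' configuration and the md5 digests of all input files — enough to re-run
#' the command.
#'
#' @param dir output directory.
#' @param command the (sub)command executed.
#' @param seed integer seed used.
#' @param config configuration object (digested, model/catalogue omitted).
#' @param inputs character vector of input file paths.
#' @return path of the manifest, invisibly.
#' @export
write_manifest <- function(dir, command, seed, config = NULL,
                           inputs = character(0)) {
  manifest <- list(
    command = command,
    seed = seed,
    config_digest = if (is.null(config)) NA_character_ else
      object_digest(unclass(config)[setdiff(names(config),
                                            c("model", "catalogue"))]),
    input_digests = as.list(tools::md5sum(inputs)),
    tool = "popfid",
    version = as.character(utils::packageVersion("popfid")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Published-inputs report fixture
#'
#' Loads the bundled per-enzyme summary table (mutant colony frequencies,
#' mean mutations per gene, detectable-sites error rates where available)
#' together with the default assay parameters, and builds the full report
#' table. This runs the rate stage on published summary inputs and is the
#' quickest worked example of the package.
#'
#' @return a `fidelity_table`.
#' @export
published_rates_table <- function() {
  inputs <- read_tsv_dot(system.file("extdata", "published_inputs.tsv",
                                     package = "popfid", mustWork = TRUE))
  params <- load_assay_params(system.file("extdata", "assay_params.yaml",
                                          package = "popfid",
                                          mustWork = TRUE))
  build_table1(inputs, params, baseline = "WT", comparator = "Taq")
}
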