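#' Reporter gene model for the gap-filling fidelity assay
#'
#' Describes the reporter gene replicated in the assay: its coding sequence,
#' the single-stranded gap that is filled by the polymerase under test, the
#' full replicated interval (gap plus the strand-displaced stretch running
#' to the start codon), and the scoring region used for detectable-site
#' error-rate estimation.
#'
#' All coordinates are 1-based closed intervals on the coding strand, which
#' is the template strand of the assay (the gap lies on the non-coding
#' strand). The defaults describe a 714-nt repressor gene with a 162-nt gap
#' at 354..515, a 515-nt replicated interval, and a 99-nt (33-codon)
#' scoring region.
#'
#' @param coding_sequence character scalar, the coding-strand sequence
#'   (A/C/G/T only).
#' @param gene_id identifier used in output files.
#' @param gap_interval length-2 integer vector, the single-stranded gap.
#' @param replicated_interval length-2 integer vector, the full interval
#'   copied by the polymerase (gap plus strand displacement).
#' @param scoring_region set of closed intervals (list of pairs or 2-column
#'   matrix) used for detectable-site scoring; may be `NULL`.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(coding_sequence, gene_id = "gene",
                       gap_interval = c(354L, 515L),
                       replicated_interval = c(1L, 515L),
                       scoring_region = NULL) {
  coding_sequence <- toupper(as.character(coding_sequence))
  if (length(coding_sequence) != 1L || nchar(coding_sequence) == 0L) {
    stop("coding_sequence: need a single non-empty sequence", call. = FALSE)
  }
  if (grepl("[^ACGT]", coding_sequence)) {
    stop("coding_sequence: non-ACGT characters present", call. = FALSE)
  }
  L <- nchar(coding_sequence)
  gap <- as_intervals(gap_interval)
  rep <- as_intervals(replicated_interval)
  if (nrow(gap) != 1L || nrow(rep) != 1L) {
    stop("gap_interval and replicated_interval must each be one interval",
         call. = FALSE)
  }
  if (rep[1, 1] < 1L || rep[1, 2] > L) {
    stop("replicated_interval: interval out of bounds (gene length ", L, ")",
         call. = FALSE)
  }
  if (gap[1, 1] < rep[1, 1] || gap[1, 2] > rep[1, 2]) {
    stop("gap_interval: interval out of bounds (must lie within ",
         "replicated_interval)", call. = FALSE)
  }
  scoring <- as_intervals(scoring_region)
  if (nrow(scoring) > 0L && (min(scoring[, 1]) < 1L || max(scoring[, 2]) > L)) {
    stop("scoring_region: interval out of bounds (gene length ", L, ")",
         call. = FALSE)
  }
  structure(list(
    gene_id = gene_id,
    coding_sequence = coding_sequence,
    length = L,
    gap_interval = gap[1, ],
    replicated_interval = rep[1, ],
    scoring_region = scoring,
    start_codon_position = 1L
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("Gene model:", x$gene_id, "(", x$length, "nt )\n")
  cat("  gap:        ", x$gap_interval[1], "..", x$gap_interval[2],
      " (", x$gap_interval[2] - x$gap_interval[1] + 1L, " nt)\n", sep = "")
  cat("  replicated: ", x$replicated_interval[1], "..",
      x$replicated_interval[2],
      " (", x$replicated_interval[2] - x$replicated_interval[1] + 1L,
      " nt)\n", sep = "")
  if (nrow(x$scoring_region) > 0L) {
    cat("  scoring:    ",
        paste(sprintf("%d..%d", x$scoring_region[, 1], x$scoring_region[, 2]),
              collapse = ", "),
        " (", interval_total_length(x$scoring_region), " nt)\n", sep = "")
  }
  invisible(x)
}

#' Load a gene model from a reference FASTA and a config file
#'
#' The config (YAML or JSON, decided by extension) may define `gene_id`,
#' `gap_interval`, `replicated_interval` and `scoring_region` (a list of
#' `[start, end]` pairs). Intervals are validated against the single FASTA
#' record.
#'
#' @param config_file path to a YAML/JSON model config.
#' @param reference_fasta path to a FASTA file with exactly one record.
#' @return a [gene_model()] object.
#' @export
load_gene_model <- function(config_file, reference_fasta) {
  seqs <- Biostrings::readDNAStringSet(reference_fasta)
  if (length(seqs) != 1L) {
    stop("reference_fasta: expected exactly one record, found ",
         length(seqs), call. = FALSE)
  }
  cfg <- read_config(config_file)
  gene_model(
    coding_sequence = as.character(seqs[[1]]),
    gene_id = cfg$gene_id %||% sub("\\s.*$", "", names(seqs)[1]),
    gap_interval = unlist(cfg$gap_interval) %||% c(354L, 515L),
    replicated_interval = unlist(cfg$replicated_interval) %||% c(1L, 515L),
    scoring_region = cfg$scoring_region
  )
}

read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config: unsupported extension '", ext, "' (use YAML or JSON)",
         call. = FALSE)
  }
}

#' Assay parameters
#'
#' Holds the experimentally determined assay constants: the probability `P`
#' that a mutation on the newly synthesized strand of the transformed
#' heteroduplex is phenotypically expressed, the plating efficiency `e` of
#' the selective (tetracycline) medium relative to the non-selective
#' (ampicillin) medium, and per-base error rates of comparator enzymes used
#' for comparator-scaled error-rate estimation.
#'
#' @param P expression probability, in (0, 1]; default 0.025.
#' @param e plating efficiency, in (0, 1]; default 0.61.
#' @param comparator_error_rates named numeric vector of comparator
#'   mutations-per-base rates; defaults to a high and a low published
#'   estimate for Taq polymerase.
#' @return an object of class `assay_params`.
#' @export
assay_params <- function(P = 0.025, e = 0.61,
                         comparator_error_rates = c(taq_high = 2.85e-4,
                                                    taq_low  = 4.3e-5)) {
  if (!is.numeric(P) || length(P) != 1L || P <= 0 || P > 1) {
    stop("P: expression probability must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(e) || length(e) != 1L || e <= 0 || e > 1) {
    stop("e: plating efficiency must lie in (0, 1]", call. = FALSE)
  }
  cmp <- unlist(comparator_error_rates)
  if (length(cmp) > 0 && (is.null(names(cmp)) || any(!nzchar(names(cmp))) ||
                          any(cmp <= 0))) {
    stop("comparator_error_rates: need named, strictly positive rates",
         call. = FALSE)
  }
  structure(list(P = P, e = e, comparator_error_rates = cmp),
            class = "assay_params")
}

#' @export
print.assay_params <- function(x, ...) {
  cat("Assay parameters: P =", x$P, " plating efficiency e =", x$e, "\n")
  if (length(x$comparator_error_rates)) {
    cat("  comparator error rates (mut/base):\n")
    for (nm in names(x$comparator_error_rates)) {
      cat(sprintf("    %-10s %.3g\n", nm, x$comparator_error_rates[[nm]]))
    }
  }
  invisible(x)
}

#' Load assay parameters from a YAML/JSON config
#'
#' @param config_file path; recognised fields `P` (or
#'   `expression_probability`), `e` (or `plating_efficiency`) and
#'   `comparator_error_rates` (a named map).
#' @return an [assay_params()] object.
#' @export
load_assay_params <- function(config_file) {
  cfg <- read_config(config_file)
  cmp <- cfg$comparator_error_rates
  assay_params(
    P = cfg$P %||% cfg$expression_probability %||% 0.025,
    e = cfg$e %||% cfg$plating_efficiency %||% 0.61,
    comparator_error_rates =
      if (is.null(cmp)) c(taq_high = 2.85e-4, taq_low = 4.3e-5)
      else unlist(cmp)
  )
}

#' Bundled synthetic reporter gene model
#'
#' Loads the synthetic 714-nt reporter gene shipped with the package
#' (`inst/extdata/synthetic_cI.fasta`, a randomly generated stand-in with
#' the assay's geometry: gap 354..515, replicated interval 1..515, and a
#' 99-nt two-interval scoring region). It is synthetic — not the real
#' lambda repressor sequence — and exists so the simulator and examples run
#' without external data.
#'
#' @return a [gene_model()] object.
#' @export
synthetic_gene_model <- function() {
  load_gene_model(
    system.file("extdata", "synthetic_cI_model.yaml", package = "popfid",
                mustWork = TRUE),
    system.file("extdata", "synthetic_cI.fasta", package = "popfid",
                mustWork = TRUE)
  )
}
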