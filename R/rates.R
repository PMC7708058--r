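#' Mutant frequency from colony counts
#'
#' MF = (n_tet / n_amp) / e: the fraction of plasmid-bearing cells whose
#' reporter is inactivated, estimated from the ratio of tetracycline- to
#' ampicillin-resistant colonies and corrected for the plating efficiency
#' `e` of the selective medium (a fully mutant plasmid yields only `e`
#' times as many tet as amp colonies).
#'
#' @param n_tet tetracycline-resistant colony count (>= 0).
#' @param n_amp ampicillin-resistant colony count (> 0).
#' @param e plating efficiency in (0, 1].
#' @return mutant frequency (dimensionless); vectorised.
#' @export
mutant_frequency <- function(n_tet, n_amp, e = 0.61) {
  if (any(e <= 0 | e > 1)) stop("e must lie in (0, 1]", call. = FALSE)
  if (any(n_amp <= 0)) stop("n_amp must be positive", call. = FALSE)
  if (any(n_tet < 0)) stop("n_tet must be >= 0", call. = FALSE)
  (n_tet / n_amp) / e
}

#' Relative mutant frequency
#' @param MF_x mutant frequency of the enzyme of interest.
#' @param MF_ref baseline (wild-type) mutant frequency, > 0.
#' @return the ratio at full precision (report layers round to 2
#'   significant figures).
#' @export
relative_mf <- function(MF_x, MF_ref) {
  if (any(MF_ref <= 0)) stop("MF_ref must be > 0", call. = FALSE)
  MF_x / MF_ref
}

#' Error rate from detectable sites: ER = MF / (D x P)
#'
#' The detectable-sites estimator: with `D` detectable sites in the scored
#' stretch and expression probability `P`, a per-base error rate ER
#' produces an expected mutant frequency ER x D x P, so ER is recovered as
#' MF / (D x P).
#'
#' @param MF_region mutant frequency attributable to the scored region.
#' @param D detectable-site count (> 0); see [count_detectable_sites()].
#' @param P expression probability in (0, 1].
#' @return error rate in mutations per base; vectorised, linear in
#'   `MF_region` and inversely linear in `D` and `P`.
#' @export
error_rate_detectable <- function(MF_region, D, P) {
  if (any(D <= 0)) stop("D must be > 0", call. = FALSE)
  if (any(P <= 0 | P > 1)) stop("P must lie in (0, 1]", call. = FALSE)
  MF_region / (D * P)
}

#' Comparator-scaled error rate
#'
#' Scales a comparator enzyme's published error rate by the ratio of
#' mutant frequencies and the ratio of mean mutations per sequenced clone:
#' ER = ER_cmp x (MF_x / MF_cmp) x (m_x / m_cmp). The `m` ratio converts
#' frequencies of mutant clones into frequencies of mutations, so enzymes
#' producing multi-mutation clones are not undercounted. This formula is a
#' reconstruction: it reproduces every published comparator-scaled value
#' we checked, but the source tables do not print it.
#'
#' @param MF_x,MF_cmp mutant frequencies of the enzyme and the comparator.
#' @param m_x,m_cmp mean mutations per sequenced mutant clone.
#' @param ER_cmp comparator error rate (mutations/base).
#' @return error rate in mutations per base.
#' @export
error_rate_comparator <- function(MF_x, MF_cmp, m_x, m_cmp, ER_cmp) {
  args <- list(MF_x, MF_cmp, m_x, m_cmp, ER_cmp)
  if (any(vapply(args, function(a) any(a <= 0), logical(1)))) {
    stop("error_rate_comparator: all inputs must be > 0", call. = FALSE)
  }
  ER_cmp * (MF_x / MF_cmp) * (m_x / m_cmp)
}

#' Relative error rate
#' @param ER_x error rate of the enzyme of interest.
#' @param ER_wt baseline (wild-type) error rate, > 0.
#' @return the fold-increase at full precision.
#' @export
relative_error_rate <- function(ER_x, ER_wt) {
  if (any(ER_wt <= 0)) stop("ER_wt must be > 0", call. = FALSE)
  ER_x / ER_wt
}

## Report-layer rounding. Relative MFs are printed at 2 significant
## figures; fold-changes in error rate are printed as whole numbers below
## 100 and at 2 significant figures above (so 5.36 -> 5, 137 -> 140).
round_signif2 <- function(x) signif(x, 2)
round_fold <- function(x) ifelse(x < 100, round(x), signif(x, 2))

#' Assemble the full mutant-frequency / error-rate report table
#'
#' Takes per-enzyme summaries (mutant frequency `mf`, mean mutations per
#' sequenced clone `m`, and optionally a detectable-sites error rate
#' `er_detectable`), plus assay parameters naming comparator error rates,
#' and derives: relative mutant frequencies, comparator-scaled error rates
#' for every comparator rate, relative error rates (based on the first
#' comparator column and on the detectable-sites column), all at full
#' precision. The print method rounds to report precision.
#'
#' @param datasets data.frame with columns `enzyme`, `mf`, `m` and
#'   optionally `er_detectable`.
#' @param params an [assay_params()] carrying the comparator rates.
#' @param baseline enzyme label used as the reference (must be present).
#' @param comparator enzyme label whose `mf`/`m` anchor the
#'   comparator-scaled estimator (must be present for those columns).
#' @return object of class `fidelity_table` (a data.frame with attributes
#'   `params`, `baseline`, `comparator`).
#' @export
build_table1 <- function(datasets, params = assay_params(),
                         baseline = "WT", comparator = "Taq") {
  stopifnot(is.data.frame(datasets),
            all(c("enzyme", "mf", "m") %in% names(datasets)))
  if (!baseline %in% datasets$enzyme) {
    stop("baseline enzyme '", baseline, "' missing from datasets",
         call. = FALSE)
  }
  tab <- datasets
  if (!"er_detectable" %in% names(tab)) tab$er_detectable <- NA_real_
  wt <- tab[tab$enzyme == baseline, ]
  tab$mf_relative <- relative_mf(tab$mf, wt$mf)

  cmp_rates <- params$comparator_error_rates
  have_cmp <- comparator %in% tab$enzyme
  if (!have_cmp && length(cmp_rates)) {
    warning("comparator enzyme '", comparator,
            "' missing: comparator-scaled columns unavailable")
  }
  cmp_cols <- character(0)
  if (have_cmp && length(cmp_rates)) {
    cm <- tab[tab$enzyme == comparator, ]
    for (nm in names(cmp_rates)) {
      col <- paste0("er_", nm)
      er <- error_rate_comparator(tab$mf, cm$mf, tab$m, cm$m, cmp_rates[[nm]])
      ## the comparator's own row reports its published rate
      er[tab$enzyme == comparator] <- cmp_rates[[nm]]
      tab[[col]] <- er
      cmp_cols <- c(cmp_cols, col)
    }
    first <- cmp_cols[1]
    wt_er <- tab[tab$enzyme == baseline, first]
    tab$rel_er_comparator <- relative_error_rate(tab[[first]], wt_er)
  } else {
    tab$rel_er_comparator <- NA_real_
  }
  wt_det <- tab$er_detectable[tab$enzyme == baseline]
  tab$rel_er_detectable <- if (length(wt_det) && !is.na(wt_det) && wt_det > 0)
    ifelse(is.na(tab$er_detectable), NA_real_,
           relative_error_rate(tab$er_detectable, wt_det))
  else NA_real_
  structure(tab, class = c("fidelity_table", "data.frame"),
            params = params, baseline = baseline,
            comparator = if (have_cmp) comparator else NA_character_,
            comparator_columns = cmp_cols)
}

#' @export
print.fidelity_table <- function(x, ...) {
  cmp_cols <- attr(x, "comparator_columns")
  cat("Mutant frequencies and error rates",
      sprintf("(baseline %s)\n", attr(x, "baseline")))
  hdr <- c("enzyme", "MF", "rel.MF", "m",
           sub("^er_", "ER ", cmp_cols), "ER detect.",
           "rel.ER cmp", "rel.ER det")
  rows <- lapply(seq_len(nrow(x)), function(i) {
    c(x$enzyme[i],
      sprintf("%.3g", x$mf[i]),
      sprintf("%.2g", round_signif2(x$mf_relative[i])),
      sprintf("%.2g", x$m[i]),
      vapply(cmp_cols, function(cc) sprintf("%.2g", round_signif2(x[[cc]][i])),
             character(1)),
      ifelse(is.na(x$er_detectable[i]), "nd",
             sprintf("%.2g", x$er_detectable[i])),
      ifelse(is.na(x$rel_er_comparator[i]), "nd",
             sprintf("%g", round_fold(x$rel_er_comparator[i]))),
      ifelse(is.na(x$rel_er_detectable[i]), "nd",
             sprintf("%g", round_fold(x$rel_er_detectable[i]))))
  })
  m <- do.call(rbind, c(list(hdr), rows))
  widths <- apply(nchar(m), 2, max)
  for (r in seq_len(nrow(m))) {
    cells <- mapply(formatC, m[r, ], width = widths,
                    MoreArgs = list(flag = "-"))
    cat(paste(cells, collapse = "  "), "\n")
  }
  invisible(x)
}

#' Rounded report view of a fidelity table
#'
#' @param object a [build_table1()] result.
#' @param ... unused.
#' @return data.frame with the derived columns rounded to report precision
#'   (2 significant figures for frequencies and error rates; fold-changes
#'   as whole numbers below 100).
#' @export
summary.fidelity_table <- function(object, ...) {
  x <- as.data.frame(object)
  out <- data.frame(enzyme = x$enzyme,
                    mf = x$mf,
                    mf_relative = round_signif2(x$mf_relative),
                    m = x$m)
  for (cc in attr(object, "comparator_columns")) {
    out[[cc]] <- round_signif2(x[[cc]])
  }
  out$er_detectable <- x$er_detectable
  out$rel_er_comparator <- round_fold(x$rel_er_comparator)
  out$rel_er_detectable <- round_fold(x$rel_er_detectable)
  out
}

#' Write a fidelity table (full precision + rounded) to TSV
#' @param table a [build_table1()] result.
#' @param path output file.
#' @export
write_table1 <- function(table, path) {
  params <- attr(table, "params")
  prov <- jsonlite::toJSON(list(
    baseline = attr(table, "baseline"),
    comparator = attr(table, "comparator"),
    P = params$P, e = params$e,
    comparator_error_rates = as.list(params$comparator_error_rates)),
    auto_unbox = TRUE, digits = NA)
  write_tsv_dot(as.data.frame(table), path,
                comment = paste0("provenance: ", prov))
}

#' Detectable-sites error rate from a sequenced callset
#'
#' The pipeline estimator behind the scored-region column: restricts
#' called events to the scoring region, converts the overall mutant
#' frequency into a mutation frequency for that region, and divides by
#' D x P. The region mutant frequency is MF times the fraction of
#' sequenced clones carrying an event in the region; with
#' `multihit = TRUE` (default) it is further multiplied by the mean number
#' of in-region events among those clones, which corrects for clones
#' carrying several mutations (exact for full-weight catalogues, where
#' MF x mean-events-per-clone = P x sites x per-base rate).
#'
#' @param MF overall mutant frequency (from [mutant_frequency()]).
#' @param callset complex-merged events of the sequenced clones.
#' @param clone_ids roster of all sequenced clone ids (clones without
#'   events included).
#' @param catalogue a [site_catalogue()].
#' @param region interval set to score; defaults to the model scoring
#'   region embedded in `model`.
#' @param model a [gene_model()].
#' @param P expression probability.
#' @param multihit apply the mean-multiplicity correction.
#' @return list with `ER`, `D`, `MF_region`, `fraction_in_region`,
#'   `mean_events_in_region`.
#' @export
error_rate_from_callset <- function(MF, callset, clone_ids, catalogue,
                                    model, region = NULL, P = 0.025,
                                    multihit = TRUE) {
  region <- as_intervals(region %||% model$scoring_region)
  D <- count_detectable_sites(catalogue, region)[["D_total"]]
  n_clones <- length(clone_ids)
  if (n_clones == 0L) stop("no sequenced clones", call. = FALSE)
  in_region <- positions_in_intervals(callset$position, region)
  hits <- callset[in_region, , drop = FALSE]
  per_clone <- table(factor(hits$clone_id, levels = clone_ids))
  frac <- mean(per_clone > 0)
  mean_hits <- if (any(per_clone > 0)) mean(per_clone[per_clone > 0]) else 0
  mf_region <- MF * frac
  eff_mf <- if (multihit) mf_region * mean_hits else mf_region
  list(ER = error_rate_detectable(eff_mf, D, P), D = D,
       MF_region = mf_region, fraction_in_region = frac,
       mean_events_in_region = mean_hits)
}
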