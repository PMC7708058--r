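#' The twelve template:dNMP mispair classes
#'
#' In the assay the coding strand is the template (the gap lies on the
#' non-coding strand), so an observed coding-strand substitution ref->obs
#' corresponds to the template base `ref` mispairing with the incoming
#' dNMP complementary to `obs`. Each template base has three possible
#' mispairs (the Watson-Crick partner being correct), giving 12 classes
#' labelled "template:dNMP".
#'
#' @return character vector of the 12 class labels in canonical order.
#' @export
mispair_classes <- function() {
  unlist(lapply(DNA_BASES, function(b) {
    d <- setdiff(DNA_BASES, comp_base(b))
    paste0(b, ":", d)
  }))
}

#' Map an observed substitution to its mispair class
#'
#' @param ref_base template (coding-strand reference) base.
#' @param obs_base observed coding-strand base.
#' @return the "template:dNMP" label; e.g. a coding-strand A->T change is
#'   an A:A mispair (template adenine with incoming dAMP, seen as T->A on
#'   the synthesized strand).
#' @export
to_mispair <- function(ref_base, obs_base) {
  if (any(!ref_base %in% DNA_BASES) || any(!obs_base %in% DNA_BASES)) {
    stop("to_mispair: bases must be A/C/G/T", call. = FALSE)
  }
  if (any(ref_base == obs_base)) {
    stop("to_mispair: ref_base must differ from obs_base", call. = FALSE)
  }
  paste0(ref_base, ":", comp_base(obs_base))
}

#' Is a substitution a transversion?
#'
#' @param ref_base,obs_base coding-strand bases, `ref_base != obs_base`.
#' @return logical; `TRUE` for purine<->pyrimidine changes.
#' @export
is_transversion <- function(ref_base, obs_base) {
  purine <- c("A", "G")
  (ref_base %in% purine) != (obs_base %in% purine)
}

#' Tabulate a mutation spectrum
#'
#' Summarises complex-merged callsets into the per-enzyme spectrum: counts
#' per mispair class, single-base insertion/deletion and complex counts,
#' percentages by mutation type, the transversion fraction among
#' substitutions, and the deletion:insertion ratio. Complex events have no
#' unique template:dNMP assignment and are excluded from the mispair table
#' but included in type percentages.
#'
#' @param callset event data.frame with `clone_id` column (from
#'   [call_clones()]).
#' @param model a [gene_model()] (used for provenance only).
#' @param enzyme_label label stored with the table.
#' @return object of class `spectrum_table`.
#' @export
tabulate_spectrum <- function(callset, model = NULL, enzyme_label = "enzyme") {
  classes <- mispair_classes()
  if (is.null(callset) || nrow(callset) == 0L) {
    warning("empty callset: spectrum table of zeros")
    callset <- cbind(clone_id = character(0), empty_events())
  }
  subs <- callset[callset$kind == "substitution", , drop = FALSE]
  class_counts <- table(factor(
    if (nrow(subs)) to_mispair(subs$ref_allele, subs$alt_allele)
    else character(0),
    levels = classes))
  type_counts <- c(
    substitution = nrow(subs),
    insertion = sum(callset$kind == "insertion"),
    deletion = sum(callset$kind == "deletion"),
    complex = sum(callset$kind == "complex"))
  total <- sum(type_counts)
  percentages <- if (total > 0) 100 * type_counts / total else
    stats::setNames(rep(0, 4), names(type_counts))
  tv <- if (nrow(subs)) mean(is_transversion(subs$ref_allele,
                                             subs$alt_allele)) else NA_real_
  structure(list(
    enzyme_label = enzyme_label,
    class_counts = stats::setNames(as.integer(class_counts), classes),
    type_counts = type_counts,
    total = total,
    percentages = percentages,
    transversion_fraction = tv,
    del_ins_ratio = if (type_counts[["insertion"]] > 0)
      type_counts[["deletion"]] / type_counts[["insertion"]] else NA_real_,
    n_clones = length(unique(callset$clone_id))
  ), class = "spectrum_table")
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat("Mutation spectrum:", x$enzyme_label,
      sprintf("(%d mutations, %d clones)\n", x$total, x$n_clones))
  tp <- sprintf("  %-13s %4d  (%5.1f%%)", names(x$type_counts),
                x$type_counts, x$percentages)
  cat(tp, sep = "\n")
  if (!is.na(x$transversion_fraction)) {
    cat(sprintf("  transversions among substitutions: %.1f%%\n",
                100 * x$transversion_fraction))
  }
  nz <- x$class_counts[x$class_counts > 0]
  if (length(nz)) {
    cat("  mispair classes:",
        paste(sprintf("%s=%d", names(nz), nz), collapse = " "), "\n")
  }
  invisible(x)
}

#' Export a spectrum table as TSV
#' @param spectrum a [tabulate_spectrum()] result.
#' @param path output file.
#' @export
write_spectrum <- function(spectrum, path) {
  df <- data.frame(
    category = c(names(spectrum$class_counts), names(spectrum$type_counts)),
    group = c(rep("mispair_class", 12), rep("mutation_type", 4)),
    count = c(spectrum$class_counts, spectrum$type_counts),
    percentage = c(rep(NA_real_, 12), round(spectrum$percentages, 2)))
  write_tsv_dot(df, path, comment = paste0("spectrum: ",
                                           spectrum$enzyme_label))
}

#' Chi-squared comparison of two mutation spectra
#'
#' For each mispair class, forms the 2x2 table (class count vs all other
#' substitutions, enzyme a vs enzyme b) and applies a two-tailed
#' chi-squared test with one degree of freedom and no continuity
#' correction; the same construction is applied to the four mutation
#' types (count of type vs all other mutations). Cells with expected
#' count < 1 are flagged `low_count` (p unreliable) rather than dropped.
#'
#' @param a,b [tabulate_spectrum()] results.
#' @param alpha significance level for the `significant` flag
#'   (default 0.001, the conventional threshold for spectrum scans).
#' @return data.frame with columns `category`, `group`, `count_a`,
#'   `count_b`, `statistic`, `df`, `p`, `significant`, `low_count`.
#' @export
compare_spectra_chisq <- function(a, b, alpha = 0.001) {
  stopifnot(inherits(a, "spectrum_table"), inherits(b, "spectrum_table"))
  if (a$total == 0 || b$total == 0) {
    stop("compare_spectra_chisq: both tables must be non-empty",
         call. = FALSE)
  }
  one <- function(xa, na, xb, nb) {
    m <- matrix(c(xa, na - xa, xb, nb - xb), nrow = 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
      return(list(stat = 0, p = 1, low = TRUE))
    }
    exp_counts <- outer(rowSums(m), colSums(m)) / sum(m)
    ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    list(stat = unname(ct$statistic), p = unname(ct$p.value),
         low = any(exp_counts < 1))
  }
  rows <- list()
  ns_a <- a$type_counts[["substitution"]]
  ns_b <- b$type_counts[["substitution"]]
  for (cl in mispair_classes()) {
    r <- one(a$class_counts[[cl]], ns_a, b$class_counts[[cl]], ns_b)
    rows[[length(rows) + 1L]] <- data.frame(
      category = cl, group = "mispair_class",
      count_a = a$class_counts[[cl]], count_b = b$class_counts[[cl]],
      statistic = r$stat, df = 1L, p = r$p,
      significant = r$p < alpha & !r$low, low_count = r$low)
  }
  for (ty in names(a$type_counts)) {
    r <- one(a$type_counts[[ty]], a$total, b$type_counts[[ty]], b$total)
    rows[[length(rows) + 1L]] <- data.frame(
      category = ty, group = "mutation_type",
      count_a = a$type_counts[[ty]], count_b = b$type_counts[[ty]],
      statistic = r$stat, df = 1L, p = r$p,
      significant = r$p < alpha & !r$low, low_count = r$low)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Distances between mutations within multi-mutation clones
#'
#' For each clone with two or more events, the nucleotide distances
#' between consecutive event positions (or all pairs with
#' `all_pairs = TRUE`, for sensitivity analysis). The summary reports the
#' fractions of distances at most 60 nt, above 10 nt and above 100 nt,
#' and the maximum — the descriptors used for mutation-clustering claims.
#'
#' @param callset event data.frame with `clone_id`.
#' @param all_pairs use all within-clone pairs instead of consecutive ones.
#' @return list with `distances` (integer vector) and `summary` (list with
#'   `n`, `frac_le_60`, `frac_gt_10`, `frac_gt_100`, `max`).
#' @export
adjacent_distances <- function(callset, all_pairs = FALSE) {
  d <- unlist(lapply(split(callset$position, callset$clone_id), function(p) {
    if (length(p) < 2L) return(integer(0))
    p <- sort(p)
    if (all_pairs) {
      as.integer(utils::combn(p, 2, function(x) x[2] - x[1]))
    } else diff(p)
  }), use.names = FALSE)
  d <- as.integer(d %||% integer(0))
  list(distances = d,
       summary = list(
         n = length(d),
         frac_le_60 = if (length(d)) mean(d <= 60) else NA_real_,
         frac_gt_10 = if (length(d)) mean(d > 10) else NA_real_,
         frac_gt_100 = if (length(d)) mean(d > 100) else NA_real_,
         max = if (length(d)) max(d) else NA_integer_))
}

#' Export inter-mutation distances as a histogram TSV
#' @param distances result of [adjacent_distances()].
#' @param path output file.
#' @param binwidth histogram bin width in nt.
#' @export
write_distances <- function(distances, path, binwidth = 20L) {
  d <- distances$distances
  if (length(d) == 0L) {
    df <- data.frame(bin_start = integer(0), bin_end = integer(0),
                     count = integer(0))
  } else {
    breaks <- seq(0L, (max(d) %/% binwidth + 1L) * binwidth, by = binwidth)
    bin <- findInterval(d, breaks, left.open = TRUE)  # (start, end] bins
    counts <- tabulate(bin, nbins = length(breaks) - 1L)
    df <- data.frame(bin_start = utils::head(breaks, -1L) + 1L,
                     bin_end = breaks[-1L], count = counts)
  }
  write_tsv_dot(df, path)
}

#' Test for an excess of multi-mutation clones
#'
#' Selected mutant clones carry at least one mutation, so under
#' independent errors the per-clone mutation counts follow a
#' zero-truncated Poisson. The expected fraction of clones with two or
#' more mutations is computed under that null and compared to the
#' observed fraction with a one-sided exact binomial test; an excess is
#' the signature of correlated (burst-like) errors rather than
#' independent single events.
#'
#' The null rate `lambda` should be the marginal mutation rate per
#' replicated plasmid (mutant frequency times mean mutations per mutant,
#' divided by the expression probability — i.e. the "product of single
#' frequencies" argument: when the per-plasmid rate is small, independent
#' errors make multi-mutation clones vanishingly rare among mutants).
#' When `lambda` is not supplied it is fitted from the counts themselves
#' by matching the zero-truncated mean; note this self-matched null is
#' far weaker, since clustered counts inflate the fitted rate and hide
#' their own excess.
#'
#' @param counts_per_clone integer vector of per-clone mutation counts,
#'   all >= 1.
#' @param lambda optional null Poisson rate (events per replicated
#'   plasmid); `NULL` fits it from the truncated mean.
#' @return list with `observed_fraction`, `expected_fraction`, `p_value`,
#'   `lambda` (null Poisson rate) and `n`.
#' @export
multi_mutation_excess <- function(counts_per_clone, lambda = NULL) {
  counts <- as.integer(counts_per_clone)
  if (length(counts) == 0L || any(counts < 1L)) {
    stop("counts_per_clone: need counts >= 1 (selected mutants)",
         call. = FALSE)
  }
  n <- length(counts)
  mbar <- mean(counts)
  obs_ge2 <- sum(counts >= 2L)
  if (is.null(lambda) && mbar <= 1) {  # all singles: nothing to test
    return(list(observed_fraction = obs_ge2 / n, expected_fraction = 0,
                p_value = 1, lambda = 0, n = n))
  }
  lam <- if (!is.null(lambda)) {
    stopifnot(lambda > 0)
    lambda
  } else {
    ## zero-truncated Poisson mean: lambda / (1 - exp(-lambda)) = mbar
    stats::uniroot(function(l) l / (1 - exp(-l)) - mbar,
                   lower = 1e-12, upper = max(mbar * 2, 10),
                   tol = 1e-10)$root
  }
  p_ge2 <- (1 - exp(-lam) - lam * exp(-lam)) / (1 - exp(-lam))
  test <- stats::binom.test(obs_ge2, n, p = p_ge2, alternative = "greater")
  list(observed_fraction = obs_ge2 / n, expected_fraction = p_ge2,
       p_value = unname(test$p.value), lambda = lam, n = n)
}
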