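#' Detectable-site catalogues
#'
#' A detectable site is a position/change in the reporter gene whose
#' mutation inactivates the repressor and therefore produces the selectable
#' phenotype. The catalogue lists such changes with a penetrance weight in
#' (0, 1]; the detectable-site count D is the sum of weights, split into a
#' substitution component and an indel component. Fractional totals (such
#' as the published 51.3 substitution sites over a 99-nt scoring region)
#' arise naturally as weight sums.
#'
#' Substitution entries give a reference base and either a specific
#' alternative base or `NA` (written `.` in TSV) meaning "any substitution
#' at this position"; indel entries carry position and weight only.
#'
#' @param entries data.frame with columns `position`, `change_class`
#'   (`"substitution"` or `"indel"`), `ref_base`, `alt_base`, `weight`.
#' @param model optional [gene_model()]; when given, substitution
#'   `ref_base` values are validated against the reference sequence.
#' @return an object of class `site_catalogue` with elements `entries`,
#'   `D_sub`, `D_indel`, `D_total`.
#' @export
site_catalogue <- function(entries, model = NULL) {
  required <- c("position", "change_class", "ref_base", "alt_base", "weight")
  if (!all(required %in% names(entries))) {
    stop("catalogue entries: need columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  entries <- entries[required]
  entries$position <- as.integer(entries$position)
  entries$weight <- as.numeric(entries$weight)
  if (nrow(entries) == 0L) {
    warning("empty detectable-site catalogue: D_total = 0")
  } else {
    if (!all(entries$change_class %in% c("substitution", "indel"))) {
      stop("change_class: must be 'substitution' or 'indel'", call. = FALSE)
    }
    if (any(!is.finite(entries$weight) | entries$weight <= 0 |
            entries$weight > 1)) {
      stop("weight: must lie in (0, 1]", call. = FALSE)
    }
    is_sub <- entries$change_class == "substitution"
    bad_alt <- is_sub & !is.na(entries$alt_base) &
      (entries$alt_base == entries$ref_base |
         !entries$alt_base %in% DNA_BASES)
    if (any(bad_alt)) {
      stop("substitution entries with alt_base equal to ref_base or not ",
           "A/C/G/T at rows: ", paste(which(bad_alt), collapse = ", "),
           call. = FALSE)
    }
    if (any(is_sub & (is.na(entries$ref_base) |
                      !entries$ref_base %in% DNA_BASES))) {
      stop("substitution entries need an A/C/G/T ref_base", call. = FALSE)
    }
    if (!is.null(model)) {
      ref <- strsplit(model$coding_sequence, "", fixed = TRUE)[[1]]
      if (any(entries$position < 1L | entries$position > model$length)) {
        stop("catalogue position out of gene bounds", call. = FALSE)
      }
      mism <- is_sub & ref[entries$position] != entries$ref_base
      if (any(mism)) {
        stop("catalogue ref_base mismatches reference sequence at rows: ",
             paste(which(mism), collapse = ", "), call. = FALSE)
      }
    }
  }
  is_sub <- entries$change_class == "substitution"
  D_sub <- sum(entries$weight[is_sub])
  D_indel <- sum(entries$weight[!is_sub])
  structure(list(entries = entries, D_sub = D_sub, D_indel = D_indel,
                 D_total = D_sub + D_indel),
            class = "site_catalogue")
}

#' @export
print.site_catalogue <- function(x, ...) {
  cat("Detectable-site catalogue:", nrow(x$entries), "entries\n")
  cat(sprintf("  D_sub = %g, D_indel = %g, D_total = %g\n",
              x$D_sub, x$D_indel, x$D_total))
  invisible(x)
}

#' Load a detectable-site catalogue from TSV
#'
#' Expects a tab-separated file with header columns `position`,
#' `change_class`, `ref_base`, `alt_base`, `weight`; `.` marks empty
#' fields, `#` lines are comments.
#'
#' @param tsv path to the catalogue file.
#' @param model optional [gene_model()] for reference-base validation.
#' @return a [site_catalogue()].
#' @export
load_catalogue <- function(tsv, model = NULL) {
  df <- read_tsv_dot(tsv, colClasses = c("integer", "character", "character",
                                         "character", "numeric"))
  site_catalogue(df, model = model)
}

#' Write a catalogue back to TSV (round-trip safe)
#' @param catalogue a [site_catalogue()].
#' @param path output file.
#' @export
write_catalogue <- function(catalogue, path) {
  write_tsv_dot(catalogue$entries, path)
}

#' Count detectable sites within a region
#'
#' Restricts the weight sums to entries whose position falls in the given
#' interval set. Counts are additive over disjoint regions and an empty
#' region yields zeros.
#'
#' @param catalogue a [site_catalogue()].
#' @param region interval set (list of `c(start, end)` pairs or 2-column
#'   matrix); `NULL` means the whole catalogue.
#' @return named numeric vector `c(D_sub, D_indel, D_total)`.
#' @export
count_detectable_sites <- function(catalogue, region = NULL) {
  e <- catalogue$entries
  keep <- if (is.null(region)) rep(TRUE, nrow(e)) else
    positions_in_intervals(e$position, region)
  is_sub <- e$change_class == "substitution"
  D_sub <- sum(e$weight[keep & is_sub])
  D_indel <- sum(e$weight[keep & !is_sub])
  c(D_sub = D_sub, D_indel = D_indel, D_total = D_sub + D_indel)
}

#' Build a uniform full-weight catalogue over a region
#'
#' Convenience constructor giving every position in `region` one any-alt
#' substitution entry of the given weight and (optionally) one indel entry
#' of weight 1. Under a weight-1 any-alt catalogue, every substitution in
#' the region is detectable, so D_sub equals the region length and
#' ER = MF/(D x P) estimates the per-base substitution error rate.
#'
#' @param model a [gene_model()].
#' @param region interval set; defaults to the model's replicated interval.
#' @param sub_weight weight of each substitution entry.
#' @param indels include weight-1 indel entries at every position.
#' @return a [site_catalogue()].
#' @export
uniform_catalogue <- function(model, region = NULL, sub_weight = 1,
                              indels = TRUE) {
  region <- as_intervals(region %||% model$replicated_interval)
  pos <- sort(unique(unlist(lapply(seq_len(nrow(region)),
                                   function(i) region[i, 1]:region[i, 2]))))
  ref <- strsplit(model$coding_sequence, "", fixed = TRUE)[[1]]
  subs <- data.frame(position = pos, change_class = "substitution",
                     ref_base = ref[pos], alt_base = NA_character_,
                     weight = sub_weight, stringsAsFactors = FALSE)
  ent <- if (indels) {
    rbind(subs, data.frame(position = pos, change_class = "indel",
                           ref_base = NA_character_,
                           alt_base = NA_character_, weight = 1,
                           stringsAsFactors = FALSE))
  } else subs
  site_catalogue(ent, model = model)
}

#' Bundled synthetic detectable-site catalogue
#'
#' Loads the catalogue shipped for the synthetic reporter gene: any-alt
#' substitution entries over the 99-nt scoring region whose weights sum to
#' 51.3, plus weight-1 indel entries at all 99 scoring positions, giving
#' D_total = 150.3. The weighting is a synthetic stand-in for published
#' repressor mutational-scanning data.
#'
#' @param model optional [gene_model()] for validation; defaults to
#'   [synthetic_gene_model()].
#' @return a [site_catalogue()].
#' @export
synthetic_catalogue <- function(model = synthetic_gene_model()) {
  load_catalogue(
    system.file("extdata", "synthetic_catalogue.tsv", package = "popfid",
                mustWork = TRUE),
    model = model
  )
}
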