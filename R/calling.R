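#' Globally align a sequenced clone to the reference
#'
#' Needleman-Wunsch global alignment with affine gap penalties via
#' [Biostrings::pairwiseAlignment()] (match +1, mismatch -2, gap open -4,
#' gap extend -1; the mismatch/gap balance makes a short indel preferable
#' to a run of isolated mismatches in repeats). `N` characters in the read
#' are scored neutrally and never give rise to events downstream.
#'
#' @param read clone sequence (character or `DNAString`), A/C/G/T/N.
#' @param reference reference coding sequence.
#' @return object of class `clone_alignment`: list with the gapped
#'   `pattern` (read) and `subject` (reference) strings and the `score`.
#' @export
align_clone <- function(read, reference) {
  read <- toupper(as.character(read))
  reference <- toupper(as.character(reference))
  if (!nzchar(read) || !nzchar(reference)) {
    stop("align_clone: empty sequence", call. = FALSE)
  }
  if (grepl("[^ACGTN]", read) || grepl("[^ACGTN]", reference)) {
    stop("align_clone: sequences must contain only A/C/G/T/N", call. = FALSE)
  }
  if (nchar(read) < 0.5 * nchar(reference)) {
    warning("truncated read: shorter than 50% of reference")
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read), Biostrings::DNAString(reference),
    substitutionMatrix = alignment_submat(),
    gapOpening = 4, gapExtension = 1, type = "global")
  g <- extract_gapped(pa, read, reference)
  structure(list(pattern = g$pattern, subject = g$subject,
                 score = Biostrings::score(pa)),
            class = "clone_alignment")
}

## Fast extraction of the gapped alignment strings. The pattern()/subject()
## views are quick but trim terminal gaps, so any clipped leading/trailing
## stretch (an indel at the very start or end of the reference) is
## re-attached explicitly from the view offsets.
extract_gapped <- function(pa, reads, reference) {
  alp <- as.character(Biostrings::pattern(pa))
  als <- as.character(Biostrings::subject(pa))
  ps <- Biostrings::start(Biostrings::pattern(pa))
  pe <- Biostrings::end(Biostrings::pattern(pa))
  ss <- Biostrings::start(Biostrings::subject(pa))
  se <- Biostrings::end(Biostrings::subject(pa))
  nr <- nchar(reads)
  ns <- nchar(reference)
  fix <- which(ps > 1L | ss > 1L | pe < nr | se < ns)
  for (i in fix) {
    if (ss[i] > 1L) {  # leading deletion (ref bases absent from read)
      alp[i] <- paste0(strrep("-", ss[i] - 1L), alp[i])
      als[i] <- paste0(substr(reference, 1L, ss[i] - 1L), als[i])
    }
    if (ps[i] > 1L) {  # leading insertion
      alp[i] <- paste0(substr(reads[i], 1L, ps[i] - 1L), alp[i])
      als[i] <- paste0(strrep("-", ps[i] - 1L), als[i])
    }
    if (se[i] < ns) {  # trailing deletion
      alp[i] <- paste0(alp[i], strrep("-", ns - se[i]))
      als[i] <- paste0(als[i], substr(reference, se[i] + 1L, ns))
    }
    if (pe[i] < nr[i]) {  # trailing insertion
      alp[i] <- paste0(alp[i], substr(reads[i], pe[i] + 1L, nr[i]))
      als[i] <- paste0(als[i], strrep("-", nr[i] - pe[i]))
    }
  }
  list(pattern = alp, subject = als)
}

alignment_submat <- function() {
  b <- c(DNA_BASES, "N")
  m <- matrix(-2, 5, 5, dimnames = list(b, b))
  diag(m) <- 1
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' Call mutation events from a clone alignment
#'
#' Each maximal run of edited alignment columns becomes one event:
#' a lone mismatch is a substitution, a lone 1-base gap a single-base
#' insertion or deletion, and anything larger or mixed (multi-base indels,
#' adjacent double substitutions) a complex event. Indels are
#' left-normalised (shifted to their leftmost equivalent placement in
#' repeats). Events whose position falls outside the model's replicated
#' interval are dropped with a message. Positions are 1-based coding-strand
#' coordinates; an insertion's position is the reference base before which
#' the new bases sit.
#'
#' @param alignment a [align_clone()] result.
#' @param model a [gene_model()].
#' @return data.frame with columns `position`, `kind`, `ref_allele`,
#'   `alt_allele`, `span`, sorted by position.
#' @export
call_events <- function(alignment, model) {
  stopifnot(inherits(alignment, "clone_alignment"))
  p <- strsplit(alignment$pattern, "", fixed = TRUE)[[1]]
  s <- strsplit(alignment$subject, "", fixed = TRUE)[[1]]
  stopifnot(length(p) == length(s))
  ## edited columns; N is never an edit
  edited <- p != s & p != "N" & s != "N"
  if (!any(edited)) return(empty_events())
  refpos <- cumsum(s != "-")  # ref coordinate at each column (0 before first)
  runs <- rle(edited)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ev <- list()
  for (i in which(runs$values)) {
    j1 <- starts[i]; j2 <- ends[i]
    ref_chars <- s[j1:j2][s[j1:j2] != "-"]
    alt_chars <- p[j1:j2][p[j1:j2] != "-"]
    ref_allele <- paste(ref_chars, collapse = "")
    alt_allele <- paste(alt_chars, collapse = "")
    pos <- if (length(ref_chars) > 0L) {
      refpos[j1:j2][s[j1:j2] != "-"][1]
    } else {
      refpos[j1] + 1L  # pure insertion: before the next reference base
    }
    kind <- classify_event(ref_allele, alt_allele)
    ev[[length(ev) + 1L]] <- data.frame(
      position = as.integer(pos), kind = kind, ref_allele = ref_allele,
      alt_allele = alt_allele,
      span = max(nchar(ref_allele), nchar(alt_allele)),
      stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, ev)
  events <- normalise_events(events, model$coding_sequence)
  rep_iv <- model$replicated_interval
  inside <- events$position >= rep_iv[1] & events$position <= rep_iv[2]
  if (any(!inside)) {
    message(sum(!inside), " event(s) outside the replicated interval dropped")
    events <- events[inside, , drop = FALSE]
  }
  events[order(events$position), , drop = FALSE]
}

classify_event <- function(ref_allele, alt_allele) {
  nr <- nchar(ref_allele); na <- nchar(alt_allele)
  if (nr == 1L && na == 1L) "substitution"
  else if (nr == 0L && na == 1L) "insertion"
  else if (nr == 1L && na == 0L) "deletion"
  else "complex"
}

empty_events <- function() {
  data.frame(position = integer(0), kind = character(0),
             ref_allele = character(0), alt_allele = character(0),
             span = integer(0), stringsAsFactors = FALSE)
}

#' Left-normalise indel events against the reference
#'
#' Pure insertions and deletions that sit in a repeat are shifted to their
#' leftmost equivalent placement (the standard variant normalisation);
#' substitutions and mixed complex events are untouched. Used both by the
#' caller and by the simulator so that truth and called events share one
#' coordinate convention.
#'
#' @param events event data.frame.
#' @param reference reference coding sequence (character).
#' @return the events with shifted positions/alleles, re-sorted.
#' @export
normalise_events <- function(events, reference) {
  events <- normalise_events_core(events, reference)
  events[order(events$position), , drop = FALSE]
}

## Row-wise normalisation without re-sorting (bulk callers keep their own
## ordering, e.g. by clone then position).
normalise_events_core <- function(events, reference) {
  if (nrow(events) == 0L) return(events)
  ref <- strsplit(toupper(as.character(reference)), "", fixed = TRUE)[[1]]
  position <- events$position
  ref_allele <- events$ref_allele
  alt_allele <- events$alt_allele
  todo <- which(nchar(ref_allele) == 0L | nchar(alt_allele) == 0L)
  for (i in todo) {
    ra <- ref_allele[i]; aa <- alt_allele[i]
    pos <- position[i]
    if (nchar(aa) == 0L && nchar(ra) >= 1L) {          # pure deletion
      k <- nchar(ra)
      while (pos > 1L && ref[pos - 1L] == ref[pos + k - 1L]) {
        pos <- pos - 1L
      }
      position[i] <- pos
      ref_allele[i] <- paste(ref[pos:(pos + k - 1L)], collapse = "")
    } else if (nchar(ra) == 0L && nchar(aa) >= 1L) {   # pure insertion
      schars <- strsplit(aa, "", fixed = TRUE)[[1]]
      k <- length(schars)
      while (pos > 1L && ref[pos - 1L] == schars[k]) {
        schars <- c(schars[k], schars[-k])
        pos <- pos - 1L
      }
      position[i] <- pos
      alt_allele[i] <- paste(schars, collapse = "")
    }
  }
  events$position <- position
  events$ref_allele <- ref_allele
  events$alt_allele <- alt_allele
  events
}

#' Merge closely spaced events into complex events
#'
#' Events whose changed bases are separated by at most `window` intervening
#' reference bases are merged into a single complex event, implementing the
#' "adjacent/closely spaced changes count once" convention. A merged event
#' (and any complex event) counts as ONE mutation in per-clone counts.
#'
#' @param events sorted, non-overlapping event data.frame for one clone.
#' @param window maximum number of intervening reference bases (>= 0).
#' @param model optional [gene_model()]; needed to fill in merged alleles.
#' @return event data.frame after merging.
#' @export
merge_complex <- function(events, window = 2L, model = NULL) {
  if (window < 0) stop("window must be >= 0", call. = FALSE)
  if (nrow(events) <= 1L) return(events)
  ref_extent <- nchar(events$ref_allele)
  start <- events$position
  end <- start + pmax(ref_extent - 1L, -1L)  # extent-0 insertion: end = pos-1
  gap_to_prev <- c(Inf, start[-1L] - end[-nrow(events)] - 1L)
  grp <- cumsum(gap_to_prev > window)
  if (length(unique(grp)) == nrow(events)) return(events)
  out <- lapply(split(seq_len(nrow(events)), grp), function(idx) {
    if (length(idx) == 1L) return(events[idx, , drop = FALSE])
    pos <- start[idx[1L]]
    last_end <- max(end[idx])
    if (!is.null(model)) {
      seg_ref <- substr(model$coding_sequence, pos, last_end)
      seg_alt <- apply_events_to_sequence(
        seg_ref, shift_events(events[idx, , drop = FALSE], 1L - pos))
    } else {
      seg_ref <- NA_character_; seg_alt <- NA_character_
    }
    data.frame(position = pos, kind = "complex", ref_allele = seg_ref,
               alt_allele = seg_alt,
               span = max(last_end - pos + 1L,
                          if (is.na(seg_alt)) 0L else nchar(seg_alt)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

shift_events <- function(events, offset) {
  events$position <- events$position + offset
  events
}

apply_events_to_sequence <- function(reference, events) {
  seq <- toupper(as.character(reference))
  if (nrow(events) == 0L) return(seq)
  ord <- order(events$position, decreasing = TRUE)
  for (i in ord) {
    pos <- events$position[i]
    nref <- nchar(events$ref_allele[i])
    left <- if (pos > 1L) substr(seq, 1L, pos - 1L) else ""
    right <- substr(seq, pos + nref, nchar(seq))
    seq <- paste0(left, events$alt_allele[i], right)
  }
  seq
}

#' Reconstruct a clone sequence from reference plus events
#'
#' Inverse of calling: applies the events (right to left, so coordinates
#' stay valid) to the reference coding sequence.
#'
#' @param model a [gene_model()] (or a plain reference string).
#' @param events event data.frame.
#' @return the mutated sequence (character scalar).
#' @export
reconstruct_clone <- function(model, events) {
  reference <- if (inherits(model, "gene_model")) model$coding_sequence
               else as.character(model)
  apply_events_to_sequence(reference, events)
}

#' Call events for a set of clones
#'
#' Aligns every clone in a FASTA file (or `DNAStringSet`/named character
#' vector) against the model reference, calls events, and merges closely
#' spaced changes into complex events.
#'
#' @param clones path to a FASTA file, a `DNAStringSet`, or a named
#'   character vector of sequences.
#' @param model a [gene_model()].
#' @param window complex-merge window (intervening bases); see
#'   [merge_complex()].
#' @return data.frame of events with a leading `clone_id` column; zero rows
#'   (with a warning) for empty input.
#' @export
call_clones <- function(clones, model, window = 2L) {
  if (is.character(clones) && length(clones) == 1L && file.exists(clones)) {
    clones <- Biostrings::readDNAStringSet(clones)
  }
  seqs <- stats::setNames(as.character(clones), names(clones))
  if (length(seqs) == 0L) {
    warning("no clone sequences supplied; empty callset")
    return(cbind(clone_id = character(0), empty_events()))
  }
  ids <- names(seqs) %||% paste0("clone_", seq_along(seqs))
  ids <- sub("\\s.*$", "", ids)
  if (any(nchar(seqs) < 0.5 * model$length)) {
    warning("truncated read(s): shorter than 50% of reference")
  }
  ## one vectorised alignment pass over all clones
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(seqs),
    Biostrings::DNAString(model$coding_sequence),
    substitutionMatrix = alignment_submat(),
    gapOpening = 4, gapExtension = 1, type = "global")
  g <- extract_gapped(pa, unname(seqs), model$coding_sequence)
  alp <- g$pattern
  als <- g$subject
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    al <- structure(list(pattern = alp[[i]], subject = als[[i]],
                         score = NA_real_), class = "clone_alignment")
    ev <- call_events(al, model)
    ev <- merge_complex(ev, window = window, model = model)
    if (nrow(ev) > 0L) ev <- cbind(clone_id = ids[[i]], ev)
    else ev <- cbind(clone_id = character(0), ev)
    out[[i]] <- ev
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-clone mutation counts
#'
#' Number of called events per clone (a complex event counts as one
#' mutation). Clones listed in `clone_ids` but absent from the callset are
#' reported with zero events.
#'
#' @param callset event data.frame with `clone_id` column.
#' @param clone_ids optional full roster of sequenced clones.
#' @return named integer vector of event counts.
#' @export
mutations_per_clone <- function(callset, clone_ids = NULL) {
  ids <- clone_ids %||% unique(callset$clone_id)
  n <- table(factor(callset$clone_id, levels = ids))
  stats::setNames(as.integer(n), ids)
}

#' Write called events as TSV
#' @param callset event data.frame with `clone_id` column.
#' @param path output file.
#' @export
write_events <- function(callset, path) {
  write_tsv_dot(callset[c("clone_id", "position", "kind", "ref_allele",
                          "alt_allele", "span")], path)
}

#' Write called events as a minimal VCF-like flat file
#'
#' One record per event, 1-based and left-normalised. Indels use the usual
#' anchor-base convention (REF/ALT share the base before the indel) so the
#' records round-trip through standard tooling.
#'
#' @param callset event data.frame with `clone_id` column.
#' @param model a [gene_model()].
#' @param path output file.
#' @export
write_events_vcf <- function(callset, model, path) {
  ref <- model$coding_sequence
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", model$gene_id, ",length=",
                      model$length, ">"),
               "##INFO=<ID=CLONE,Number=1,Type=String,Description=\"Clone id\">",
               "##INFO=<ID=KIND,Number=1,Type=String,Description=\"Event kind\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(callset))) {
    pos <- callset$position[i]
    ra <- callset$ref_allele[i]; aa <- callset$alt_allele[i]
    if (nchar(ra) == 0L || nchar(aa) == 0L) {  # anchor base for indels
      anchor_pos <- max(pos - 1L, 1L)
      anchor <- substr(ref, anchor_pos, anchor_pos)
      if (pos > 1L) { ra <- paste0(anchor, ra); aa <- paste0(anchor, aa)
                      pos <- anchor_pos }
      else { ra <- paste0(ra, anchor); aa <- paste0(aa, anchor) }
    }
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tCLONE=%s;KIND=%s",
                       model$gene_id, pos, ra, aa, callset$clone_id[i],
                       callset$kind[i]), con)
  }
  invisible(path)
}
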