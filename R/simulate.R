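#' Mispair propensity matrix
#'
#' A 4x4 matrix (rows: template base, columns: incoming dNMP) of relative
#' mispair propensities. The Watson-Crick cell of each row is structurally
#' zero and every row is normalised over its three mispairs, so a row is
#' the conditional distribution of the mispairing dNMP given a
#' substitution error at a template base.
#'
#' @param propensities optional named numeric vector of relative weights
#'   keyed by "template:dNMP" labels (see [mispair_classes()]); classes
#'   not named get weight 0, rows with no mass fall back to uniform.
#'   `NULL` gives the uniform matrix (each mispair 1/3).
#' @return 4x4 row-normalised matrix with dimnames ACGT x ACGT.
#' @export
mispair_matrix <- function(propensities = NULL) {
  m <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  if (is.null(propensities)) {
    for (b in DNA_BASES) m[b, setdiff(DNA_BASES, comp_base(b))] <- 1 / 3
    return(m)
  }
  if (is.null(names(propensities)) ||
      !all(names(propensities) %in% mispair_classes())) {
    stop("propensities must be named by mispair class labels", call. = FALSE)
  }
  for (lab in names(propensities)) {
    p <- strsplit(lab, ":", fixed = TRUE)[[1]]
    m[p[1], p[2]] <- propensities[[lab]]
  }
  for (b in DNA_BASES) {
    allowed <- setdiff(DNA_BASES, comp_base(b))
    s <- sum(m[b, allowed])
    m[b, allowed] <- if (s > 0) m[b, allowed] / s else 1 / 3
    m[b, comp_base(b)] <- 0
  }
  m
}

#' Simulation configuration for the gap-filling assay
#'
#' Bundles the generative parameters of the synthetic assay. The defaults
#' describe the study conditions: a 515-nt replicated interval with a
#' 162-nt gap, expression probability P = 0.025, plating efficiency
#' e = 0.61, deletion:insertion ratio 3, and a detectable-site catalogue
#' with D = 51.3 substitution and 99 indel sites. The per-base error rate
#' defaults to a high-fidelity 5e-6; bursts (a fidelity drop after the
#' first error, generating multi-mutation clones) are off by default
#' (`burst_factor = 1`).
#'
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @param n_plasmids number of gap-filled plasmids transformed.
#' @param per_base_error_rate substitution probability per replicated
#'   base; a scalar, or a vector over the replicated interval for
#'   position-specific rates.
#' @param mispair_matrix a [mispair_matrix()].
#' @param single_indel_rate single-base indel probability per base.
#' @param del_ins_ratio deletion:insertion ratio among single indels.
#' @param complex_rate complex-mutation probability per base (multi-base
#'   deletions and adjacent double substitutions, half each).
#' @param burst_factor multiplier applied to the substitution rate for the
#'   rest of the strand once a first error has occurred (>= 1).
#' @param P expression probability.
#' @param e plating efficiency.
#' @param model a [gene_model()].
#' @param catalogue a [site_catalogue()] used for selection.
#' @param enzyme_label label carried into outputs.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_plasmids = 1e5L,
                       per_base_error_rate = 5e-6,
                       mispair_matrix = popfid::mispair_matrix(),
                       single_indel_rate = 1e-6, del_ins_ratio = 3,
                       complex_rate = 2e-7, burst_factor = 1,
                       P = 0.025, e = 0.61,
                       model = synthetic_gene_model(),
                       catalogue = synthetic_catalogue(model),
                       enzyme_label = "sim") {
  rep_iv <- model$replicated_interval
  L <- rep_iv[2] - rep_iv[1] + 1L
  eps <- per_base_error_rate
  if (!length(eps) %in% c(1L, L)) {
    stop("per_base_error_rate must be scalar or one value per replicated ",
         "position (", L, ")", call. = FALSE)
  }
  if (any(eps < 0 | eps > 1) || single_indel_rate < 0 || complex_rate < 0 ||
      single_indel_rate > 1 || complex_rate > 1) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (any(eps + single_indel_rate + complex_rate > 1)) {
    stop("per-position total event probability exceeds 1", call. = FALSE)
  }
  if (del_ins_ratio <= 0) stop("del_ins_ratio must be > 0", call. = FALSE)
  if (burst_factor < 1) stop("burst_factor must be >= 1", call. = FALSE)
  mm <- mispair_matrix
  stopifnot(is.matrix(mm), all(dim(mm) == 4))
  for (b in DNA_BASES) {
    if (abs(sum(mm[b, setdiff(DNA_BASES, comp_base(b))]) - 1) > 1e-8 ||
        mm[b, comp_base(b)] != 0) {
      stop("mispair_matrix rows must be normalised over the 3 mispairs",
           call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_plasmids = as.integer(n_plasmids),
                 per_base_error_rate = eps, mispair_matrix = mm,
                 single_indel_rate = single_indel_rate,
                 del_ins_ratio = del_ins_ratio, complex_rate = complex_rate,
                 burst_factor = burst_factor, P = P, e = e, model = model,
                 catalogue = catalogue, enzyme_label = enzyme_label),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$enzyme_label, "\n")
  cat(sprintf("  n_plasmids %d, seed %d\n", x$n_plasmids, x$seed))
  cat(sprintf("  eps %s, indel %g (del:ins %g), complex %g, burst x%g\n",
              if (length(x$per_base_error_rate) == 1L)
                format(x$per_base_error_rate) else "<per-position>",
              x$single_indel_rate, x$del_ins_ratio, x$complex_rate,
              x$burst_factor))
  cat(sprintf("  P %g, e %g, D_total %g\n", x$P, x$e, x$catalogue$D_total))
  invisible(x)
}

## Draw truth events for n clones. Replication runs from the high end of
## the replicated interval towards the start codon (gap fill followed by
## strand displacement), so "after the first error" means lower
## coordinates. Returns a data.frame(clone, position, kind, ref_allele,
## alt_allele, span), left-normalised and overlap-free.
simulate_truth_events <- function(config, n) {
  model <- config$model
  rep_iv <- model$replicated_interval
  L <- rep_iv[2] - rep_iv[1] + 1L
  ref <- strsplit(model$coding_sequence, "", fixed = TRUE)[[1]]
  eps <- config$per_base_error_rate
  ind <- config$single_indel_rate
  cx <- config$complex_rate
  scalar_eps <- length(eps) == 1L

  if (scalar_eps) {
    q <- eps + ind + cx
    n_ev <- stats::rbinom(n, L, q)
    which_mut <- which(n_ev > 0L)
    pos_list <- lapply(which_mut, function(i) {
      rep_iv[1] - 1L + sample.int(L, n_ev[i])
    })
    clone <- rep(which_mut, n_ev[which_mut])
    position <- unlist(pos_list) %||% integer(0)
    u <- stats::runif(length(position))
    kind0 <- ifelse(u < eps / q, "sub",
                    ifelse(u < (eps + ind) / q, "ind", "cx"))
  } else {
    ## position-specific rates: exact per-position Bernoulli draws
    clone <- integer(0); position <- integer(0); kind0 <- character(0)
    for (i in seq_len(n)) {
      u <- stats::runif(L)
      hit <- which(u < eps + ind + cx)
      if (!length(hit)) next
      k0 <- ifelse(u[hit] < eps[hit], "sub",
                   ifelse(u[hit] < eps[hit] + ind, "ind", "cx"))
      clone <- c(clone, rep(i, length(hit)))
      position <- c(position, rep_iv[1] - 1L + hit)
      kind0 <- c(kind0, k0)
    }
  }

  ## burst: after the first error (in replication order, i.e. the highest
  ## coordinate), the substitution rate is multiplied by burst_factor for
  ## the remainder of the strand. Implemented by complementary thinning:
  ## extra substitution draws on the not-yet-mutated positions replicated
  ## after the first error.
  if (config$burst_factor > 1 && length(clone)) {
    if (!scalar_eps) {
      stop("burst_factor > 1 requires a scalar per_base_error_rate",
           call. = FALSE)
    }
    q <- eps + ind + cx
    r_extra <- eps * (config$burst_factor - 1) / (1 - q)
    first_pos <- tapply(position, clone, max)
    for (ci in seq_along(first_pos)) {
      fp <- first_pos[[ci]]
      cl <- as.integer(names(first_pos)[ci])
      if (fp <= rep_iv[1]) next
      cand <- setdiff(rep_iv[1]:(fp - 1L), position[clone == cl])
      k <- stats::rbinom(1L, length(cand), r_extra)
      if (k > 0L) {
        newpos <- sample(cand, k)
        clone <- c(clone, rep(cl, k))
        position <- c(position, newpos)
        kind0 <- c(kind0, rep("sub", k))
      }
    }
  }

  if (!length(clone)) {
    return(cbind(clone = integer(0), empty_events()))
  }

  K <- length(position)
  ref_allele <- character(K); alt_allele <- character(K)
  kind <- character(K); span <- integer(K)

  is_sub <- kind0 == "sub"
  if (any(is_sub)) {
    tmpl <- ref[position[is_sub]]
    dnmp <- draw_mispair_dnmp(tmpl, config$mispair_matrix)
    kind[is_sub] <- "substitution"
    ref_allele[is_sub] <- tmpl
    alt_allele[is_sub] <- comp_base(dnmp)
    span[is_sub] <- 1L
  }
  is_ind <- kind0 == "ind"
  if (any(is_ind)) {
    p_del <- config$del_ins_ratio / (1 + config$del_ins_ratio)
    del <- stats::runif(sum(is_ind)) < p_del
    idx <- which(is_ind)
    kind[idx] <- ifelse(del, "deletion", "insertion")
    ref_allele[idx] <- ifelse(del, ref[position[idx]], "")
    alt_allele[idx] <- ifelse(del, "",
                              sample(DNA_BASES, sum(is_ind), replace = TRUE))
    span[idx] <- 1L
  }
  is_cx <- which(kind0 == "cx")
  for (j in is_cx) {
    p <- position[j]
    if (stats::runif(1) < 0.5 || p >= rep_iv[2]) {  # multi-base deletion
      s <- sample(2:6, 1L)
      s <- min(s, rep_iv[2] - p + 1L)
      if (s < 2L) s <- 2L
      kind[j] <- "complex"
      ref_allele[j] <- paste(ref[p:(p + s - 1L)], collapse = "")
      alt_allele[j] <- ""
      span[j] <- s
    } else {                                        # adjacent double sub
      tmpl <- ref[c(p, p + 1L)]
      obs <- comp_base(draw_mispair_dnmp(tmpl, config$mispair_matrix))
      kind[j] <- "complex"
      ref_allele[j] <- paste(tmpl, collapse = "")
      alt_allele[j] <- paste(obs, collapse = "")
      span[j] <- 2L
    }
  }

  ev <- data.frame(clone = clone, position = position, kind = kind,
                   ref_allele = ref_allele, alt_allele = alt_allele,
                   span = span, stringsAsFactors = FALSE)
  ## left-normalise indels, re-sort within clones, drop rare overlaps
  ev <- normalise_events_core(ev, model$coding_sequence)
  ev <- ev[order(ev$clone, ev$position), , drop = FALSE]
  ends <- ev$position + pmax(nchar(ev$ref_allele) - 1L, 0L)
  same_prev <- duplicated(ev$clone)
  clash <- same_prev & ev$position <= c(0L, utils::head(ends, -1L))
  if (any(clash)) {
    bad <- unique(ev$clone[clash])
    is_bad <- ev$clone %in% bad
    fixed <- do.call(rbind, lapply(split(ev[is_bad, , drop = FALSE],
                                         ev$clone[is_bad]), drop_overlaps))
    ev <- rbind(ev[!is_bad, , drop = FALSE], fixed)
    ev <- ev[order(ev$clone, ev$position), , drop = FALSE]
  }
  rownames(ev) <- NULL
  ev
}

draw_mispair_dnmp <- function(template, mm) {
  out <- character(length(template))
  for (b in unique(template)) {
    idx <- which(template == b)
    out[idx] <- sample(DNA_BASES, length(idx), replace = TRUE,
                       prob = mm[b, ])
  }
  out
}

drop_overlaps <- function(ev) {
  if (nrow(ev) <= 1L) return(ev)
  keep <- logical(nrow(ev))
  keep[1L] <- TRUE
  last_end <- ev$position[1L] + max(nchar(ev$ref_allele[1L]) - 1L, 0L)
  for (i in 2L:nrow(ev)) {
    if (ev$position[i] > last_end) {
      keep[i] <- TRUE
      last_end <- ev$position[i] + max(nchar(ev$ref_allele[i]) - 1L, 0L)
    }
  }
  ev[keep, , drop = FALSE]
}

#' Simulate replication of gapped plasmids
#'
#' Draws truth mutation events for `n` independently replicated plasmids
#' under a [sim_config()]: substitutions at the per-base error rate with
#' mispair classes from the propensity matrix (recorded as coding-strand
#' changes), single-base indels split by the deletion:insertion ratio,
#' complex events, and optionally a post-first-error burst.
#'
#' @param config a [sim_config()].
#' @param n number of plasmids (default `config$n_plasmids`).
#' @param seed seed (default `config$seed`); `NULL` to use the current RNG
#'   state.
#' @return data.frame of truth events with a leading `clone` index column;
#'   clones without events do not appear. The attribute `n` records the
#'   number of plasmids simulated.
#' @export
simulate_replication <- function(config, n = config$n_plasmids,
                                 seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  ev <- simulate_truth_events(config, n)
  attr(ev, "n") <- n
  ev
}

#' Apply the genetic selection to simulated clones
#'
#' A clone is inactivating with probability 1 - prod(1 - w_i) over the
#' catalogue weights matched by its events (substitution events match
#' substitution entries at their position with the same or any
#' alternative base; indel and complex events match indel entries
#' overlapping their reference extent). It is expressed — able to grow on
#' tetracycline — if additionally a Bernoulli(P) succeeds (the mutation
#' must sit on the expressed strand of the transformed heteroduplex), and
#' plated with probability `e`.
#'
#' @param truth truth events from [simulate_replication()].
#' @param n number of plasmids (default from the `n` attribute).
#' @param catalogue a [site_catalogue()].
#' @param P expression probability.
#' @param e plating efficiency.
#' @param seed optional seed; `NULL` (default) continues the current
#'   stream.
#' @return data.frame with one row per plasmid: `clone`, `n_events`,
#'   `inactivating`, `expressed`, `plated_tet`.
#' @export
apply_selection <- function(truth, catalogue, P, e = 1,
                            n = attr(truth, "n"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(!is.null(n))
  p_inact <- numeric(n)
  n_events <- integer(n)
  if (nrow(truth) > 0L) {
    w <- match_catalogue_weights(truth, catalogue)
    surv <- tapply(1 - w, truth$clone, prod)
    p_inact[as.integer(names(surv))] <- 1 - surv
    tab <- table(truth$clone)
    n_events[as.integer(names(tab))] <- as.integer(tab)
  }
  inact <- stats::runif(n) < p_inact
  expressed <- inact & stats::runif(n) < P
  plated <- expressed & stats::runif(n) < e
  data.frame(clone = seq_len(n), n_events = n_events, inactivating = inact,
             expressed = expressed, plated_tet = plated)
}

## Per-event matched catalogue weight (0 when no entry matches).
match_catalogue_weights <- function(events, catalogue) {
  ent <- catalogue$entries
  sub_ent <- ent[ent$change_class == "substitution", , drop = FALSE]
  ind_ent <- ent[ent$change_class == "indel", , drop = FALSE]
  w <- numeric(nrow(events))
  for (i in seq_len(nrow(events))) {
    pos <- events$position[i]
    if (events$kind[i] == "substitution") {
      hit <- sub_ent$position == pos &
        (is.na(sub_ent$alt_base) | sub_ent$alt_base == events$alt_allele[i])
      if (any(hit)) w[i] <- max(sub_ent$weight[hit])
    } else {
      extent <- max(nchar(events$ref_allele[i]), 1L)
      hit <- ind_ent$position >= pos & ind_ent$position <= pos + extent - 1L
      if (any(hit)) w[i] <- max(ind_ent$weight[hit])
    }
  }
  w
}

#' Run the full synthetic assay
#'
#' End-to-end harness: replication of `n_plasmids` gapped plasmids,
#' loss-of-function selection, expression and plating thinning, and
#' assembly of the observable outputs — colony counts, the sequences of
#' the tetracycline-resistant (sequenced) clones, and the full truth
#' table. Identical seed and config give bit-identical outputs.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_assay`: list with `colony_counts`
#'   (enzyme_label, replicate_id, n_tet, n_amp), `clones` (named character
#'   vector of tet-resistant clone sequences), `truth_events`,
#'   `truth_clones`, `config_digest`, and the `config` itself.
#' @export
simulate_assay <- function(config) {
  set.seed(config$seed)
  truth <- simulate_truth_events(config, config$n_plasmids)
  attr(truth, "n") <- config$n_plasmids
  flags <- apply_selection(truth, config$catalogue, config$P, config$e)
  n_tet <- sum(flags$plated_tet)
  counts <- data.frame(enzyme_label = config$enzyme_label,
                       replicate_id = "r1",
                       n_tet = n_tet, n_amp = config$n_plasmids)
  tet_ids <- flags$clone[flags$plated_tet]
  clone_id <- sprintf("clone_%06d", tet_ids)
  seqs <- vapply(tet_ids, function(ci) {
    apply_events_to_sequence(config$model$coding_sequence,
                             truth[truth$clone == ci, , drop = FALSE])
  }, character(1))
  names(seqs) <- clone_id
  if (n_tet == 0L) warning("no tetracycline-resistant clones simulated")
  truth_events <- truth
  truth_events$clone_id <- sprintf("clone_%06d", truth_events$clone)
  flags$clone_id <- sprintf("clone_%06d", flags$clone)
  structure(list(colony_counts = counts, clones = seqs,
                 truth_events = truth_events,
                 truth_clones = flags,
                 config = config,
                 config_digest = object_digest(unclass(config)[
                   setdiff(names(config), c("model", "catalogue"))])),
            class = "sim_assay")
}

#' @export
print.sim_assay <- function(x, ...) {
  cat("Simulated assay:", x$config$enzyme_label, "\n")
  cat(sprintf("  plasmids %d, tet-resistant %d (MF_hat = %.3g)\n",
              x$colony_counts$n_amp, x$colony_counts$n_tet,
              mutant_frequency(x$colony_counts$n_tet,
                               x$colony_counts$n_amp, x$config$e)))
  invisible(x)
}

#' Write simulated assay outputs to a directory
#'
#' Emits `clones.fasta` (tet-resistant clone sequences), `counts.tsv` and
#' `truth.tsv`; every file carries the config digest in a header comment
#' so outputs can be traced to their generating configuration.
#'
#' @param assay a [simulate_assay()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim_assay <- function(assay, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  digest <- assay$config_digest
  fa <- file.path(dir, "clones.fasta")
  seqs <- Biostrings::DNAStringSet(assay$clones)
  names(seqs) <- paste0(names(assay$clones), " config=", digest)
  Biostrings::writeXStringSet(seqs, fa)
  write_tsv_dot(assay$colony_counts, file.path(dir, "counts.tsv"),
                comment = paste0("config=", digest))
  tr <- merge(assay$truth_clones[c("clone_id", "n_events", "inactivating",
                                   "expressed", "plated_tet")],
              assay$truth_events[c("clone_id", "position", "kind",
                                   "ref_allele", "alt_allele", "span")],
              by = "clone_id", all.x = FALSE)
  tr <- tr[order(tr$clone_id, tr$position), ]
  write_tsv_dot(tr, file.path(dir, "truth.tsv"),
                comment = paste0("config=", digest))
  invisible(dir)
}
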