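`%||%` <- function(a, b) if (is.null(a)) b else a

# In-code fixtures shared across test files. Everything is generated
# programmatically from fixed seeds so the suite needs no external data.

# A small reporter gene whose whole length is replicated, convenient for
# calling/simulation tests without coordinate bookkeeping.
tiny_model <- function(n = 60L, seed = 7L) {
  set.seed(seed)
  gene_model(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                   collapse = ""),
             gene_id = "tiny",
             gap_interval = c(1L, n), replicated_interval = c(1L, n),
             scoring_region = list(c(1L, n)))
}

# Random weighted catalogue over a model, for enumeration oracles.
random_catalogue <- function(model, n_sub = 20L, n_indel = 10L, seed = 99L) {
  set.seed(seed)
  L <- model$length
  ref <- strsplit(model$coding_sequence, "")[[1]]
  sub_pos <- sample.int(L, n_sub)
  ind_pos <- sample.int(L, n_indel)
  site_catalogue(data.frame(
    position = c(sub_pos, ind_pos),
    change_class = rep(c("substitution", "indel"), c(n_sub, n_indel)),
    ref_base = c(ref[sub_pos], rep(NA, n_indel)),
    alt_base = NA_character_,
    weight = round(runif(n_sub + n_indel, 0.05, 1), 3)), model = model)
}

# Event data.frame builder.
ev_df <- function(position, kind, ref_allele, alt_allele) {
  data.frame(position = as.integer(position), kind = kind,
             ref_allele = ref_allele, alt_allele = alt_allele,
             span = pmax(nchar(ref_allele), nchar(alt_allele)),
             stringsAsFactors = FALSE)
}

# Callset (events + clone_id) builder.
cs_df <- function(clone_id, ...) cbind(clone_id = clone_id, ev_df(...))

expect_events_equal <- function(a, b) {
  cols <- c("position", "kind", "ref_allele", "alt_allele", "span")
  a <- a[cols]; b <- b[cols]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
}
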