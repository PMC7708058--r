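test_that("zero rates reproduce the reference exactly", {
  m <- tiny_model()
  catal <- uniform_catalogue(m)
  cfg <- sim_config(seed = 1, n_plasmids = 50L, per_base_error_rate = 0,
                    single_indel_rate = 0, complex_rate = 0,
                    P = 1, e = 1, model = m, catalogue = catal)
  tr <- simulate_replication(cfg)
  expect_equal(nrow(tr), 0L)
  expect_warning(a <- simulate_assay(cfg), "no tetracycline")
  expect_equal(a$colony_counts$n_tet, 0L)
})

test_that("a forced error at one position yields the designated mispair", {
  m <- tiny_model(n = 30L)
  refc <- strsplit(m$coding_sequence, "")[[1]]
  pos <- 5L
  tpl <- refc[pos]
  eps <- rep(0, 30); eps[pos] <- 1
  # all propensity mass on the template:template mispair of every base
  mm <- mispair_matrix(c("A:A" = 1, "C:C" = 1, "G:G" = 1, "T:T" = 1))
  catal <- uniform_catalogue(m)
  cfg <- sim_config(seed = 3, n_plasmids = 20L, per_base_error_rate = eps,
                    single_indel_rate = 0, complex_rate = 0,
                    P = 1, e = 1, model = m, catalogue = catal,
                    mispair_matrix = mm)
  tr <- simulate_replication(cfg)
  expect_equal(nrow(tr), 20L)  # every clone errs at the designated site
  expect_true(all(tr$position == pos))
  expect_true(all(tr$ref_allele == tpl))
  # an X:X mispair incorporates dXMP, read as complement(X) on the coding
  # strand (the published example: template A + dAMP appears as A->T)
  expect_true(all(tr$alt_allele == chartr("ACGT", "TGCA", tpl)))
  expect_equal(to_mispair(tpl, chartr("ACGT", "TGCA", tpl)),
               paste0(tpl, ":", tpl))
})

test_that("event counts match the binomial expectation", {
  m <- synthetic_gene_model()
  catal <- uniform_catalogue(m, indels = FALSE)
  eps <- 1e-4; n <- 40000L
  cfg <- sim_config(seed = 9, n_plasmids = n, per_base_error_rate = eps,
                    single_indel_rate = 0, complex_rate = 0,
                    model = m, catalogue = catal)
  tr <- simulate_replication(cfg)
  expected <- n * 515 * eps
  se <- sqrt(n * 515 * eps)  # Poisson-binomial sd of the total
  expect_lt(abs(nrow(tr) - expected), 3 * se)
})

test_that("truth events reconstruct the emitted clone sequences", {
  m <- synthetic_gene_model()
  catal <- uniform_catalogue(m)
  cfg <- sim_config(seed = 17, n_plasmids = 500L,
                    per_base_error_rate = 2e-3, single_indel_rate = 8e-4,
                    complex_rate = 2e-4, P = 1, e = 1,
                    model = m, catalogue = catal)
  a <- simulate_assay(cfg)
  expect_gt(length(a$clones), 100L)
  for (cid in names(a$clones)) {
    ev <- a$truth_events[a$truth_events$clone_id == cid, ]
    expect_identical(reconstruct_clone(m, ev), unname(a$clones[[cid]]))
  }
})

test_that("selection follows the Bernoulli product of weight and P", {
  m <- tiny_model(n = 50L)
  refc <- strsplit(m$coding_sequence, "")[[1]]
  pos <- 25L
  catal <- site_catalogue(data.frame(
    position = pos, change_class = "substitution",
    ref_base = refc[pos], alt_base = NA, weight = 0.5), model = m)
  n <- 100000L
  alt <- setdiff(c("A", "C", "G", "T"), refc[pos])[1]
  truth <- data.frame(clone = seq_len(n), position = pos,
                      kind = "substitution", ref_allele = refc[pos],
                      alt_allele = alt, span = 1L)
  attr(truth, "n") <- n
  set.seed(123)
  flags <- apply_selection(truth, catal, P = 0.025, e = 1)
  p_tet <- 0.5 * 0.025
  se <- sqrt(p_tet * (1 - p_tet) / n)
  expect_lt(abs(mean(flags$plated_tet) - p_tet), 3 * se)

  # no events: never resistant; weight 1 + P 1: always resistant
  empty <- data.frame(clone = integer(0), position = integer(0),
                      kind = character(0), ref_allele = character(0),
                      alt_allele = character(0), span = integer(0))
  attr(empty, "n") <- 100L
  f0 <- apply_selection(empty, catal, P = 1, e = 1)
  expect_false(any(f0$plated_tet))
  catal1 <- site_catalogue(data.frame(
    position = pos, change_class = "substitution",
    ref_base = refc[pos], alt_base = NA, weight = 1), model = m)
  small <- truth[1:50, ]; attr(small, "n") <- 50L
  f1 <- apply_selection(small, catal1, P = 1, e = 1)
  expect_true(all(f1$plated_tet))
})

test_that("the pipeline MF estimate matches the closed-form expectation", {
  # per-position rate chosen so that P(>=1 event per clone) = 1e-3
  m <- synthetic_gene_model()
  catal <- uniform_catalogue(m, indels = FALSE)
  q <- 1 - (1 - 1e-3)^(1 / 515)
  cfg <- sim_config(seed = 29, n_plasmids = 150000L,
                    per_base_error_rate = q, single_indel_rate = 0,
                    complex_rate = 0, P = 1, e = 1,
                    model = m, catalogue = catal)
  a <- simulate_assay(cfg)
  mf_hat <- mutant_frequency(a$colony_counts$n_tet, a$colony_counts$n_amp,
                             e = 1)
  se <- sqrt(1e-3 * (1 - 1e-3) / cfg$n_plasmids)
  expect_lt(abs(mf_hat - 1e-3), 3 * se)
})

test_that("identical seed and config give bit-identical outputs", {
  m <- synthetic_gene_model()
  catal <- synthetic_catalogue(m)
  cfg <- sim_config(seed = 77, n_plasmids = 3000L,
                    per_base_error_rate = 1e-3, single_indel_rate = 3e-4,
                    complex_rate = 1e-4, P = 0.5, e = 0.9,
                    model = m, catalogue = catal)
  a1 <- simulate_assay(cfg)
  a2 <- simulate_assay(cfg)
  expect_identical(a1$clones, a2$clones)
  expect_identical(a1$truth_events, a2$truth_events)
  expect_identical(a1$colony_counts, a2$colony_counts)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  write_sim_assay(a1, d1); write_sim_assay(a2, d2)
  for (f in c("clones.fasta", "counts.tsv", "truth.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # outputs carry the config digest
  expect_true(any(grepl(a1$config_digest,
                        readLines(file.path(d1, "counts.tsv"))[1])))
})

test_that("mispair-class frequencies recover the generative matrix", {
  m <- synthetic_gene_model()
  catal <- uniform_catalogue(m, indels = FALSE)
  mm <- mispair_matrix(c("A:A" = 6, "A:G" = 1, "A:C" = 1,
                         "T:T" = 6, "T:G" = 1, "T:C" = 1,
                         "G:A" = 2, "G:G" = 1, "G:T" = 3,
                         "C:A" = 1, "C:C" = 1, "C:T" = 4))
  cfg <- sim_config(seed = 83, n_plasmids = 4000L,
                    per_base_error_rate = 2e-3, single_indel_rate = 0,
                    complex_rate = 0, P = 1, e = 1,
                    model = m, catalogue = catal)
  cfg$mispair_matrix <- mm
  a <- simulate_assay(cfg)
  cs <- call_clones(a$clones, m)
  sp <- tabulate_spectrum(cs, m)
  refc <- strsplit(m$coding_sequence, "")[[1]]
  base_freq <- table(factor(refc[1:515], levels = c("A", "C", "G", "T")))
  n_sub <- sum(sp$class_counts)
  for (cl in mispair_classes()) {
    tpl <- substr(cl, 1, 1); dnmp <- substr(cl, 3, 3)
    p_exp <- (base_freq[[tpl]] / 515) * mm[tpl, dnmp]
    se <- sqrt(p_exp * (1 - p_exp) / n_sub)
    expect_lt(abs(sp$class_counts[[cl]] / n_sub - p_exp), 3.5 * se + 1e-9)
  }
})

test_that("transversion fraction converges to the generative value", {
  m <- synthetic_gene_model()
  catal <- uniform_catalogue(m, indels = FALSE)
  cfg <- sim_config(seed = 91, n_plasmids = 3000L,
                    per_base_error_rate = 2e-3, single_indel_rate = 0,
                    complex_rate = 0, P = 1, e = 1,
                    model = m, catalogue = catal)
  a <- simulate_assay(cfg)
  sp <- tabulate_spectrum(call_clones(a$clones, m), m)
  # uniform mispair matrix: 8 of 12 classes are transversions
  n_sub <- sum(sp$class_counts)
  se <- sqrt((2 / 3) * (1 / 3) / n_sub)
  expect_gt(n_sub, 1000)
  expect_lt(abs(sp$transversion_fraction - 2 / 3), 2 * se)
})

test_that("deletion:insertion ratio follows the configured rho", {
  m <- synthetic_gene_model()
  catal <- uniform_catalogue(m)
  cfg <- sim_config(seed = 37, n_plasmids = 3000L,
                    per_base_error_rate = 0, single_indel_rate = 2e-3,
                    complex_rate = 0, del_ins_ratio = 3,
                    P = 1, e = 1, model = m, catalogue = catal)
  tr <- simulate_replication(cfg)
  n_del <- sum(tr$kind == "deletion"); n_ins <- sum(tr$kind == "insertion")
  p_hat <- n_del / (n_del + n_ins)
  se <- sqrt(0.75 * 0.25 / (n_del + n_ins))
  expect_lt(abs(p_hat - 0.75), 3 * se)
})

test_that("config validation rejects malformed inputs", {
  m <- tiny_model()
  catal <- uniform_catalogue(m)
  expect_error(sim_config(per_base_error_rate = -1, model = m,
                          catalogue = catal), "rates")
  expect_error(sim_config(burst_factor = 0.5, model = m, catalogue = catal),
               "burst")
  expect_error(sim_config(del_ins_ratio = 0, model = m, catalogue = catal),
               "del_ins_ratio")
  bad <- mispair_matrix(); bad["A", "C"] <- 0.9
  expect_error(sim_config(mispair_matrix = bad, model = m,
                          catalogue = catal), "normalised")
})
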