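BASES <- c("A", "C", "G", "T")

test_that("mispair mapping matches the brute-force pairing table", {
  # independent oracle: build the full 12-row table from first principles
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  oracle <- list()
  for (ref in BASES) for (obs in setdiff(BASES, ref)) {
    # the coding strand is the template; the incorporated dNMP is the
    # Watson-Crick partner of the observed coding base
    oracle[[paste(ref, obs)]] <- paste0(ref, ":", wc[[obs]])
  }
  for (ref in BASES) for (obs in setdiff(BASES, ref)) {
    expect_equal(to_mispair(ref, obs), oracle[[paste(ref, obs)]])
  }
  # named cases: A->T is A:A, G->A is G:T, T->A is T:T
  expect_equal(to_mispair("A", "T"), "A:A")
  expect_equal(to_mispair("G", "A"), "G:T")
  expect_equal(to_mispair("T", "A"), "T:T")
  expect_error(to_mispair("A", "A"), "differ")
  expect_error(to_mispair("N", "A"), "A/C/G/T")
})

test_that("the 12 mispair classes are hit bijectively", {
  seen <- character(0)
  for (ref in BASES) for (obs in setdiff(BASES, ref)) {
    seen <- c(seen, to_mispair(ref, obs))
  }
  expect_equal(sort(seen), sort(mispair_classes()))
  expect_equal(anyDuplicated(seen), 0L)
})

test_that("transition/transversion classification enumerates 4 + 8", {
  n_tv <- 0L; n_ts <- 0L
  for (ref in BASES) for (obs in setdiff(BASES, ref)) {
    if (is_transversion(ref, obs)) n_tv <- n_tv + 1L else n_ts <- n_ts + 1L
  }
  expect_equal(n_ts, 4L)
  expect_equal(n_tv, 8L)
  expect_false(is_transversion("A", "G"))
  expect_true(is_transversion("A", "T"))
})

test_that("spectrum tabulation computes counts, percentages and ratios", {
  cs <- rbind(cs_df("c1", 10L, "substitution", "A", "T"),
              cs_df("c2", 20L, "substitution", "G", "A"),
              cs_df("c3", 30L, "deletion", "C", ""),
              cs_df("c4", 40L, "complex", "ATA", ""))
  sp <- tabulate_spectrum(cs, enzyme_label = "x")
  expect_equal(unname(sp$percentages),
               c(50, 0, 25, 25))  # sub, ins, del, complex
  expect_equal(sum(sp$percentages), 100)
  expect_equal(sum(sp$class_counts), sp$type_counts[["substitution"]])
  expect_equal(unname(sp$class_counts["A:A"]), 1L)
  expect_equal(unname(sp$class_counts["G:T"]), 1L)
  expect_equal(sp$transversion_fraction, 0.5)  # A->T tv, G->A ts

  # single A->T clone: transversion fraction 1, A:A count 1
  sp1 <- tabulate_spectrum(cs_df("c1", 10L, "substitution", "A", "T"))
  expect_equal(sp1$transversion_fraction, 1.0)
  expect_equal(unname(sp1$class_counts["A:A"]), 1L)

  expect_warning(sp0 <- tabulate_spectrum(cs[0, ]), "empty")
  expect_equal(sp0$total, 0L)
})

test_that("chi-squared spectrum comparison matches the textbook formula", {
  mk <- function(n_aa, n_other) {
    ev <- do.call(rbind, c(
      replicate(n_aa, cs_df("c", 1L, "substitution", "A", "T"),
                simplify = FALSE),
      replicate(n_other, cs_df("c", 2L, "substitution", "G", "A"),
                simplify = FALSE)))
    tabulate_spectrum(ev)
  }
  a <- mk(50, 50); b <- mk(5, 95)
  res <- compare_spectra_chisq(a, b)
  got <- res$statistic[res$category == "A:A"]
  # textbook 2x2 chi-squared, no continuity correction
  tab <- c(a = 50, b = 50, c = 5, d = 95)
  n <- sum(tab)
  oracle <- n * (tab["a"] * tab["d"] - tab["b"] * tab["c"])^2 /
    ((tab["a"] + tab["b"]) * (tab["c"] + tab["d"]) *
       (tab["a"] + tab["c"]) * (tab["b"] + tab["d"]))
  expect_equal(got, unname(oracle), tolerance = 1e-12)
  expect_true(res$significant[res$category == "A:A"])
  expect_equal(res$df[1], 1L)
})

test_that("a spectrum compared with itself gives zero statistics", {
  cs <- rbind(cs_df("c1", 10L, "substitution", "A", "T"),
              cs_df("c2", 20L, "substitution", "G", "A"),
              cs_df("c3", 30L, "deletion", "C", ""))
  sp <- tabulate_spectrum(cs)
  res <- compare_spectra_chisq(sp, sp)
  expect_true(all(res$statistic == 0))
  expect_true(all(res$p == 1))
  expect_false(any(res$significant))
})

test_that("low expected counts are flagged rather than trusted", {
  a <- tabulate_spectrum(cs_df("c1", 10L, "substitution", "A", "T"))
  b <- tabulate_spectrum(cs_df("c2", 20L, "substitution", "G", "A"))
  res <- compare_spectra_chisq(a, b)
  expect_true(all(res$low_count[res$group == "mispair_class" &
                                  (res$count_a + res$count_b) > 0]))
  expect_false(any(res$significant))
})

test_that("a 10-fold enriched class is detected at P < 0.001 (power check)", {
  set.seed(404)
  # enzyme a: A:A at 50% of 200 substitutions; enzyme b: 5% of 200
  draw <- function(p_aa, n) {
    aa <- rbinom(1, n, p_aa)
    do.call(rbind, c(
      replicate(aa, cs_df("c", 1L, "substitution", "A", "T"),
                simplify = FALSE),
      replicate(n - aa, cs_df("c", 2L, "substitution", "C", "A"),
                simplify = FALSE)))
  }
  a <- tabulate_spectrum(draw(0.5, 200))
  b <- tabulate_spectrum(draw(0.05, 200))
  res <- compare_spectra_chisq(a, b)
  expect_true(res$significant[res$category == "A:A"])
  expect_lt(res$p[res$category == "A:A"], 0.001)
})

test_that("inter-mutation distances use consecutive pairs by default", {
  cs <- rbind(cs_df("c1", 100L, "substitution", "A", "T"),
              cs_df("c1", 150L, "substitution", "A", "T"),
              cs_df("c1", 400L, "substitution", "A", "T"),
              cs_df("c2", 50L, "substitution", "A", "T"))
  d <- adjacent_distances(cs)
  expect_equal(sort(d$distances), c(50L, 250L))
  expect_equal(d$summary$max, 250L)
  expect_equal(d$summary$frac_le_60, 0.5)
  # all pairs adds the 100-400 span
  d2 <- adjacent_distances(cs, all_pairs = TRUE)
  expect_equal(sort(d2$distances), c(50L, 250L, 300L))
  # single-mutation clones only: empty
  d3 <- adjacent_distances(cs_df("c9", 10L, "substitution", "A", "T"))
  expect_equal(length(d3$distances), 0L)
})

test_that("adjacent distances match the order-statistics oracle", {
  # uniform placement of k events on L positions: compare the simulated
  # assay's distance distribution with a direct Monte-Carlo oracle
  m <- synthetic_gene_model()
  catal <- uniform_catalogue(m, indels = FALSE)
  cfg <- sim_config(seed = 51, n_plasmids = 1500L,
                    per_base_error_rate = 6e-3, single_indel_rate = 0,
                    complex_rate = 0, P = 1, e = 1,
                    model = m, catalogue = catal)
  a <- simulate_assay(cfg)
  cs <- call_clones(a$clones, m)
  d <- adjacent_distances(cs)$distances
  # oracle: resample uniform positions with the same per-clone counts
  set.seed(52)
  counts <- as.integer(table(cs$clone_id))
  oracle <- unlist(lapply(rep(counts[counts >= 2], 5), function(k) {
    diff(sort(sample.int(515L, k)))
  }))
  expect_gt(length(d), 100)
  se <- sqrt(var(d) / length(d) + var(oracle) / length(oracle))
  expect_lt(abs(mean(d) - mean(oracle)), 3 * se)
})

test_that("multi-mutation excess follows exact binomial arithmetic", {
  # all singles: nothing to test
  r0 <- multi_mutation_excess(rep(1L, 30))
  expect_equal(r0$p_value, 1)
  expect_equal(r0$observed_fraction, 0)

  # half 1s, half 3s (n = 40): with the self-fitted truncated-mean null
  # (lambda 1.5936...) the expected >=2 fraction EXCEEDS the observed 0.5,
  # so no excess is declared; the exact binomial oracle confirms it
  counts <- rep(c(1L, 3L), each = 20)
  r1 <- multi_mutation_excess(counts)
  lam <- r1$lambda
  expect_equal(lam / (1 - exp(-lam)), 2, tolerance = 1e-8)
  p_ge2 <- (1 - exp(-lam) - lam * exp(-lam)) / (1 - exp(-lam))
  expect_equal(r1$expected_fraction, p_ge2, tolerance = 1e-10)
  oracle_p <- sum(dbinom(20:40, 40, p_ge2))  # exact one-sided tail
  expect_equal(r1$p_value, oracle_p, tolerance = 1e-10)
  expect_gt(r1$p_value, 0.05)

  # same counts against the marginal per-plasmid rate actually implied by
  # independent errors at low frequency: strong excess
  r2 <- multi_mutation_excess(counts, lambda = 0.1)
  expect_lt(r2$p_value, 1e-10)
  expect_gt(r2$observed_fraction, r2$expected_fraction)

  expect_error(multi_mutation_excess(c(0L, 1L)), "counts")
})

test_that("burst simulations show excess against the marginal null; independent errors do not", {
  m <- synthetic_gene_model()
  catal <- uniform_catalogue(m, indels = FALSE)
  run <- function(eps, burst, seed) {
    cfg <- sim_config(seed = seed, n_plasmids = 30000L,
                      per_base_error_rate = eps, single_indel_rate = 0,
                      complex_rate = 0, burst_factor = burst,
                      P = 1, e = 0.61, model = m, catalogue = catal)
    a <- simulate_assay(cfg)
    cs <- call_clones(a$clones, m)
    cnt <- mutations_per_clone(cs, names(a$clones))
    lam <- nrow(a$truth_events) / cfg$n_plasmids
    multi_mutation_excess(cnt, lambda = lam)
  }
  # burst on, with the base rate lowered so the marginal mean mutations
  # per plasmid (~0.1) matches the burst-off run below
  on <- run(1.2e-4, 25, 61)
  off <- run(2e-4, 1, 62)
  expect_lt(on$p_value, 1e-6)
  expect_gt(off$p_value, 0.01)
})
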