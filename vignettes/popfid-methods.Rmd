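---
title: "Models and methods behind popfid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popfid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popfid)
```

## The assay

popfid analyses gap-filling forward-mutation fidelity assays scored by
positive selection. A plasmid carries the lambda CI repressor gene; the
repressor silences a tetracycline-resistance gene, so any loss-of-function
mutation in the repressor is selectable. A single-stranded gap is opened on
the non-coding strand of the repressor gene (by default nucleotides
354–515 of a 714-nt gene) and filled in vitro by the polymerase under
test; strand displacement carries synthesis onward to the start codon, so
the enzyme replicates a 515-nt stretch in total. After transformation,
tetracycline plates count expressed mutants and ampicillin plates count
all plasmid-bearing cells.

Two experimental constants connect colony counts to polymerase behaviour:

* the **expression probability** `P` (default 0.025): the transformed
  molecule is a heteroduplex, and a mutation on the newly synthesized
  strand is only expressed in the fraction of cells that resolve the
  heteroduplex toward that strand;
* the **plating efficiency** `e` (default 0.61): even a fully mutant
  plasmid yields fewer tetracycline than ampicillin colonies by this
  factor.

All coordinates in the package are 1-based closed intervals on the coding
strand. Because the gap lies on the non-coding strand, the coding strand
is the template the polymerase reads, which fixes the strand convention
used throughout (see *Mispair classes*).

## Estimators

**Mutant frequency.** `MF = (n_tet / n_amp) / e`. Replicate colony counts
are summed before the ratio is taken.

**Detectable-sites error rate.** Not every mutation inactivates the
repressor, so the scored signal must be normalised by the number of
changes that are phenotypically visible. A *detectable-site catalogue*
lists, per position, the inactivating changes with a penetrance weight in
(0, 1]; `D` is the weight sum, split into substitution and indel
components. A substitution entry may name a specific alternative base, or
leave it empty (".") to mean "any substitution at this position is
detectable with this weight". Fractional totals — such as the default
catalogue's 51.3 substitution sites over a 99-nt scoring region — arise
naturally as weight sums; the weighting itself is user data, not a
hard-coded convention. The estimator is

```
ER = MF_region / (D × P)
```

where `MF_region` is the mutant frequency attributable to the scored
region: `MF` times the fraction of sequenced clones carrying an event
there. By default the pipeline additionally multiplies by the mean number
of in-region events among those clones (`multihit = TRUE`). This
multiplicity correction converts "frequency of mutant clones" into
"frequency of mutations": for a full-weight catalogue over a region of
`L` sites it makes the estimator exactly unbiased, since
`MF × mean-events-per-clone = P × L × rate` regardless of how many errors
co-occur per molecule. Without it the estimator measures
`P(≥1 error)/L`, which saturates once the expected number of errors per
clone approaches one — at the error rates of strongly mutator enzymes the
estimate would fall ~15% short. The same logic is why the comparator
formula below carries the ratio of mean mutations per clone.

**Comparator-scaled error rate.**

```
ER = ER_cmp × (MF / MF_cmp) × (m / m_cmp)
```

scales a comparator enzyme's published per-base error rate by the
mutant-frequency ratio and the ratio of mean mutations per sequenced
clone `m`. This formula is a reconstruction: it is the natural
mutation-frequency scaling and reproduces every published derived value we
use as anchors, but it is not itself printed in the sources the package's
fixture values come from; it is kept in one function
(`error_rate_comparator()`) so it can be swapped.

**Report rounding.** All derived quantities are kept at full precision;
the report layer (`summary()`, `print()`) rounds relative mutant
frequencies and error rates to two significant figures, and fold-changes
to whole numbers below 100 and two significant figures above — matching
how such tables are conventionally printed.

## Mutation calling

Each sequenced clone is aligned globally to the reference
(Needleman–Wunsch via `Biostrings::pairwiseAlignment`) with match +1,
mismatch −2, gap open −4, gap extend −1. The mismatch/gap balance was
chosen so that a two-base indel in a repeat is preferred over two isolated
mismatches; ties in indel placement are resolved by shifting every pure
indel to its leftmost equivalent position (standard variant
normalisation), which both the caller and the simulator apply, so truth
and called events share one coordinate convention. `N` bases are scored
neutrally and never produce events.

Each maximal run of edited alignment columns becomes one event: a lone
mismatch is a substitution; a lone one-base gap a single-base insertion or
deletion; anything larger or mixed is **complex**. A second merging pass
(`merge_complex()`) folds events separated by at most `window` intervening
reference bases into one complex event. The default `window = 2` is the
minimal reading of "adjacent or closely spaced changes"; it is exposed as
a parameter (and a CLI flag) because no canonical value exists. A complex
event counts as **one** mutation in per-clone counts — the convention
required for mean-mutations-per-clone values to be comparable across
enzymes — and this is applied consistently by `mutations_per_clone()`.

One subtlety worth recording: the fast path for recovering gapped
alignment strings from `pairwiseAlignment` uses the `pattern()`/
`subject()` views, which silently trim gap columns at the extreme ends of
the alignment (e.g. a deletion of reference base 1). The caller
re-attaches any clipped terminal stretch from the view offsets, and the
test suite pins this case.

## Mispair classes and spectrum statistics

An observed coding-strand substitution ref→obs is reported as the mispair
`ref : complement(obs)` — template base paired with the incoming dNMP.
This follows from the strand geometry: the synthesized strand is the
non-coding strand, so a coding-strand A→T change means the template A
paired with an incoming dAMP (class A:A). The twelve classes (three
mispairs per template base) are enumerated by `mispair_classes()`, and the
mapping is bijective.

Spectrum tables count the twelve classes, single-base insertions and
deletions, and complex events. Complex events are excluded from the
mispair table (they have no unique template:dNMP assignment) but included
in the type percentages. Enzyme pairs are compared per class with a 2×2
chi-squared test — class count versus all other substitutions, enzyme
versus enzyme — with one degree of freedom, no continuity correction,
two-tailed, flagged significant at P < 0.001; the same construction is
applied to mutation types. Cells with an expected count below one are
flagged `low_count` rather than silently reported. The per-class 2×2
construction is isolated in `compare_spectra_chisq()` so an alternative
contingency scheme (for example one normalised by template-base
opportunity) can be swapped in.

Inter-mutation distances use consecutive event pairs within each
multi-mutation clone by default; `all_pairs = TRUE` is available for
sensitivity analysis, since summaries such as "fraction within 60 bases"
depend on that choice.

**Multi-mutation excess.** Under independent errors the per-clone counts
of selected mutants follow a zero-truncated Poisson. The test compares
the observed fraction of clones with ≥2 mutations against that null with
an exact one-sided binomial test. The null rate should be supplied as the
marginal per-plasmid mutation rate (`lambda`, obtainable as
MF × m / P): when the per-plasmid rate is small, independence makes
multi-mutation clones vanishingly rare among mutants, so clustering shows
up immediately. If `lambda` is omitted the rate is fitted from the counts
themselves by matching the zero-truncated mean; this fallback is
deliberately conservative and documented as such — clustered counts
inflate the self-fitted rate and can absorb their own excess entirely, so
a non-significant result in that mode is not evidence of independence.
The test suite pins both behaviours with exact binomial arithmetic.

## The simulator

`simulate_assay()` reproduces the assay's statistical structure end to
end with known truth:

1. **Replication.** Per replicated position: substitution with
   probability ε (the per-base error rate), class drawn from a
   mispair-propensity matrix conditioned on the template base and recorded
   as the coding-strand change; single-base indel with rate
   `single_indel_rate`, split deletion:insertion by ρ (default 3:1,
   deletions dominating as for most polymerases); complex event with rate
   `complex_rate` (half multi-base deletions of span 2–6, half adjacent
   double substitutions). ε may be a per-position vector for
   position-specific rates.
2. **Bursts.** Optionally, after the first error the substitution rate is
   multiplied by `burst_factor` for the remainder of the strand
   (replication order runs from the high end of the replicated interval
   toward the start codon, matching gap fill followed by strand
   displacement). This is the simplest mechanism producing clones with
   several clustered mutations; it is **off by default** (`burst_factor =
   1`). It is implemented by complementary thinning — base-rate draws
   everywhere, plus extra substitution draws at rate ε(b−1)/(1−q) at
   not-yet-mutated positions replicated after the first base-rate error —
   which is distributionally identical to the sequential definition.
3. **Selection.** A clone inactivates the repressor with probability
   1 − Π(1 − wᵢ) over the catalogue weights matched by its events
   (substitutions match entries at their position with the same or any
   alternative base; indel and complex events match indel entries
   overlapping their reference extent). Heteroduplex resolution is
   collapsed into a single Bernoulli(P) per clone — matching how `P` is
   measured experimentally rather than simulating strand segregation —
   and plating is a Bernoulli(e) thinning.
4. **Outputs.** Colony counts, the FASTA of tetracycline-resistant
   (sequenced) clones, and a truth table of every event and flag. All
   files carry a digest of the generating configuration.

Default configuration values are the study conditions of the assay the
package models: a 515-nt replicated interval with a 162-nt gap at
354..515, P = 0.025, e = 0.61, ρ = 3, and a catalogue with D = 51.3
substitution + 99 indel detectable sites over a 99-nt scoring region. The
default ε of 5×10⁻⁶ corresponds to a high-fidelity wild-type enzyme; the
140-fold range up to 7×10⁻⁴ spans the mutator variants.

**Randomness.** One RNG stream is seeded once per simulation
(`set.seed(config$seed)`) and all draws happen in a fixed internal order,
so identical seed + config give bit-identical outputs (FASTA and TSV
files included — the test suite compares file digests). Vectorised draws
from a single stream were chosen over per-clone substreams: the
reproducibility contract is the same, and it is what makes 10⁵-plasmid
simulations take seconds in R.

**What the generator does and does not emulate.** It reproduces the
selection structure (weighted penetrance, expression and plating
thinning), the spectrum structure (mispair propensities conditioned on
template composition), indel/complex classes, and burst-driven
multi-mutation clones. It deliberately does **not** model
sequence-context-dependent error rates (no published model exists for
them), chromatogram-level artefacts, or bacterial repair of complex
lesions. Consequently, pipeline tests on simulated data validate the
estimators and the calling machinery under the assay's sampling
structure; they do not certify behaviour on context-biased real spectra.
Likewise, published spectrum percentages that depend on per-clone
mutation lists unavailable to this package are not asserted as exact
targets anywhere; the tests instead verify that the pipeline recovers
matched generative settings within sampling error.

## Numerical choices and degenerate inputs

* Catalogue weights must lie in (0, 1]; zero-weight entries are rejected
  rather than silently kept. An empty catalogue yields D = 0 with a
  warning; `error_rate_detectable()` refuses D ≤ 0 or P ≤ 0.
* The zero-truncated Poisson rate is solved with `uniroot` at tolerance
  1e-10; an all-singles count vector short-circuits to p = 1.
* Chi-squared cells with a zero margin return statistic 0, p = 1,
  flagged `low_count`, instead of NaN.
* Simulated events that would overlap after left-normalisation (rare) are
  resolved by keeping the earlier event; positions are sampled without
  replacement within a clone.
* Empty clone FASTA input produces an empty callset with a warning and a
  zero-filled spectrum, not an error; reads shorter than half the
  reference warn as truncated.
* Test problem sizes were chosen to keep the whole suite under about two
  minutes while leaving comfortable statistical margins: 10⁵ plasmids for
  recovery checks (the binomial sampling error of ~75 tet colonies
  dominates, giving ~11% relative SE per run), 10 log-spaced rates for
  the slope check, and 3–3.5 SE bounds on all stochastic assertions.

## Known limitations

* The comparator-scaling formula is a documented reconstruction, not a
  published derivation.
* The detectable-sites estimator with *specific-alt* (partial) catalogues
  estimates the rate of the catalogued changes, not the total per-base
  rate; only full-weight any-alt catalogues make it a direct per-base
  estimate. Real catalogues derived from mutational-scanning data sit in
  between, and their weighting scheme is the user's responsibility.
* The self-fitted multi-mutation null is conservative to the point of
  blindness for strongly clustered data (see above); supply the marginal
  rate whenever mutant frequency data are available.
* Complex events are matched to indel catalogue entries during simulated
  selection; a dedicated penetrance class for complex lesions would
  require data that do not exist.
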