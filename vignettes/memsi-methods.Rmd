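---
title: "Methods: mixture-EM microsatellite instability calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixture-EM microsatellite instability calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the numerical choices and the open
design decisions behind `memsi`, at the level of detail a reviewer or a
maintainer needs. The README shows the user-facing workflow.

## Problem and model

Microsatellite instability (MSI) — the molecular footprint of a deficient
mismatch-repair system — is clinically assessed on five poly-A
mononucleotide repeats (BAT-25, BAT-26, NR-21, NR-24, NR-27). In amplicon
NGS data, every allele of such a repeat appears not as a single length but
as a *distribution* of lengths, because the PCR steps of library
preparation slip on homopolymers (stutter). A stable locus therefore shows
one stutter-shaped length distribution near the reference length; an
unstable locus shows a mixture of that distribution with one or two copies
shifted to the lengths of the unstable alleles.

`memsi` makes that picture literal. Let `g(ℓ)` be the empirical length
distribution of the locus in MSS controls, with mean `μ_ref`. Define the
location family `g(ℓ; m)` by translating `g` so its expectation is exactly
`m`: integer shifts translate bins, fractional shifts take the linear
interpolation of the two adjacent integer translations (which preserves
the empirical shape and makes the mean exact). The observed histogram is
modelled as

    f(ℓ) = P₁ g(ℓ; m₁) + P₂ g(ℓ; m₂) + P₃ g(ℓ; m₃)

— one component for the stable allele and up to two for unstable alleles —
and `{m, P}` is estimated by maximum likelihood via EM. The key assumption
is that stutter noise is a property of the locus and chemistry, not of the
allele: every component reuses the same control-derived shape. A
deliberately *not* made assumption is normality of `g`; observed stutter
distributions are asymmetric (deletion-heavy) and a symmetric parametric
shape misfits them.

## Extraction from unaligned reads

Each mate (R1 and R2 independently, no pair-level deduplication — the
observation unit mirrors the reads entering an MSI-PCR-like measurement)
is scanned for the locus's two flanking sequences with Smith–Waterman
local alignment, on the read and on its reverse complement. An anchor is
accepted when its score reaches `min_score_fraction` (default 0.8) of the
flank's perfect-match score; a read contributes only when **both** flanks
are accepted, with the 5′ anchor ending strictly before the 3′ anchor
begins. When both orientations qualify, the higher combined score wins.
The measured quantity is the full inter-flank span length, so substitution
errors *inside* the repeat do not alter the measurement — the same
property fragment-length electrophoresis has.

Scoring defaults are match +1, mismatch −1, gap open −2, gap extend −1
(a gap of length L costs `open + L·extend`), all configurable per panel.
These are deliberately tolerant: FFPE-derived reads carry scattered
substitutions, and a 20 nt flank at threshold 0.8 absorbs two mismatches.
Ambiguous bases score as mismatches. The trimmed span is retained only if
it actually contains a homopolymer of the locus base: longest run ≥ 8 nt
and base content ≥ 80% of the span (defaults; `homopolymer_rule()`). This
excludes chimeric and mispriming artefacts while tolerating isolated
sequencing errors inside the repeat.

The Smith–Waterman kernel is implemented in C++ (`src/sw.cpp`) because the
pipeline runs it millions of times; it is validated in the test suite
against `Biostrings::pairwiseAlignment` on randomized cases with identical
scoring. `build_histogram()` additionally applies a mapper-style exact-seed
screen (any 8-mer of a flank, both strands, via a rolling 2-bit hash)
before the SW pass; a mate without a single exact 8-mer from either flank
cannot realistically reach the score threshold, and the screen is
switchable (`seed_len = 0`) and tested equivalent to the exhaustive path
on mixed-locus read sets. `find_flanks()` itself never screens.

## Reference profiles

`build_reference()` sums control histograms for a locus, normalises over
the closed support `[min observed − 3, max observed + 3]`, floors each bin
at a pseudocount (default 1e-6) and renormalises. The floor prevents
minus-infinite log-likelihoods when a test sample shows a length unseen in
controls; the ±3-bin padding accommodates sampling noise at the support
edge. A minimum of 500 control reads is required by default — the
literature gives no value here; 500 makes the per-bin relative error of
the central bins a few percent, which is small against the 10%/2%
decision thresholds. Profiles serialise to a versioned, human-readable
text format (`save_profile()` / `load_profile()`), with validation of the
schema version, the probability sum and the stored mean; auditable
reference data is a clinical-adjacent requirement.

## EM details

* **Sufficient statistics.** The likelihood depends on the data only
  through binned counts, so EM runs on the histogram, not per read.
* **Initialisation.** Component 1 starts at `μ_ref`; components 2 and 3 at
  `μ_ref − 5` and `μ_ref − 10` nt with proportions (0.90, 0.05, 0.05).
  Poly-A instability in colorectal tumours is deletion-dominated, so the
  deterministic starts point left; 3 restarts with ±2 nt uniform jitter
  (seeded) still explore insertions. Best final log-likelihood wins.
* **M-step.** Proportions are the responsibility-weighted read fractions
  (exact). Locations are responsibility-weighted mean lengths — exact for
  symmetric shapes, an approximation for the skewed empirical shape — so
  the update is safeguarded: if the joint update would lower the
  log-likelihood, the location step is halved towards the previous means
  (at worst keeping them, which provably cannot decrease the likelihood).
  Monotonicity is therefore guaranteed, and asserted over randomized runs
  in the tests, alongside an exhaustive grid-search oracle that the fitted
  likelihood must match within 0.5 log-units on two-component problems.
* **Convergence.** Stop when the gain drops below 1e-6 log-units or after
  500 iterations; histograms have a few dozen bins, so cost is negligible.
* **Merging.** Components whose means end within 0.25 nt are merged
  (summed proportion, proportion-weighted mean) so one allele is never
  reported as two components.
* **Degenerate inputs.** Empty histograms refuse to fit; lengths outside
  every shifted support meet a 1e-12 density floor rather than −∞.

## Decision cascade

Thresholds live in `classification_config()`:

| parameter | default | meaning |
|---|---|---|
| `stable_mean_tolerance` | 0.10 | stable band, fraction of `μ_ref`, inclusive |
| `min_unstable_proportion` | 0.02 | minimum summed unstable proportion |
| `lrt_alpha` | 0.01 | LRT significance level |
| `power_threshold` | 0.80 | power needed to trust a negative LRT |
| `power_effect_shift` | −6 nt | shift of the power alternative |
| `min_reads` | 100 | below this a locus is non-contributory outright |
| `min_unstable_loci_for_msi` | 2 | MSI rule (≥ 2 of 5) |
| `min_contributory_loci` | 4 | loci required to claim MSS |

The 10%, 2%, 80% and 2-of-5 values are the method's defining constants.
`lrt_alpha` is a design choice (nothing published): 0.01 keeps per-locus
specificity high on a five-locus panel, and the 2% proportion gate already
suppresses trivial rejections. The ±10% boundary is inclusive ("equal to
the mean ± 10%" reads as inclusive), with a 1e-9 guard against floating
point at the exact boundary. The 2% rule is applied to the *sum* of
unstable-component proportions (the plural reads collectively); reported
unstable components are those individually at or above 2%.

The reduced (stable-only) model of the LRT is refitted with its means
constrained to the stable band. The usual case keeps one component, whose
likelihood is one-dimensional in the location and is maximised directly
(coarse grid + local refinement) — robust even when a single stable
component badly misfits strongly unstable data; multi-component reduced
models use constrained EM. Degrees of freedom: 2 per removed component
(mean + proportion); boundary effects make the χ² tail conservative,
which favours specificity. When *no* component is stable the reduced model
still keeps one band-constrained component and the same df convention —
that edge is always overwhelmingly significant anyway.

**Power gate.** The power of the LRT is estimated by seeded Monte Carlo:
draw `power_mc_replicates` (default 200) multinomial histograms of the
observed size from the minimal relevant alternative — unstable proportion
exactly at the 2% gate, shifted `power_effect_shift` (−6 nt, a typical
colorectal deletion) — refit, and count significant LRTs. The rejection
event is the *test's* rejection, not the full reporting cascade: at an
alternative sitting exactly on the 2% gate the cascade's own gate would cap
estimated power near ½ regardless of depth, which would misrepresent the
test. Estimates are cached per (locus, read count, configuration); read
counts are rounded **down** to a 250-read grid before estimation
(`power_read_grid`), which is conservative and lets one estimate serve
many samples. `min_interpretable_reads()` bisects this power curve to
produce per-locus minimum coverage requirements — the machinery behind
published per-locus minimum read counts, which depend on each laboratory's
own reference profiles.

The sample-level rule needs one convention the MSI/MSS definitions do not
cover: how many non-contributory loci still permit an MSS claim. Claiming
MSS from two informative loci is clinically unsafe, so MSS requires ≥ 4
contributory loci by default; otherwise the sample is non-contributory.
MSI is never blocked by non-contributory loci (≥ 2 unstable suffices).

## The simulator

`simulate_fastq()` emulates what the caller actually consumes: 150 nt
paired mates containing flank–homopolymer–flank embedded in random
context, full read-through (R2 is the reverse complement of R1), constant
qualities (the algorithm ignores qualities by design). Stutter is a
two-sided geometric offset: with probability π an offset occurs; its
magnitude is geometric (ratio r), its sign is a deletion with 3:1 odds.
(π, r) are solved in closed form so the offset standard deviation equals
the requested `stutter_sd` (r fixed at 0.5 until π saturates at 1, i.e.
up to sd = √5). Closed-form moments make the simulator itself testable
against analytic oracles. Flanks are random 20-mers free of ≥ 3-base runs
of the repeat base, fixed per locus by seed; `depth` counts read *pairs*,
and both mates are counted downstream, so a depth-2000 simulation yields
~4000 observations per locus. Dilution series multiply per-locus positive-
control unstable fractions (defaults 73/77/74/70/77%) by dilution factors;
the series defaults include the five classical dilutions 1/4…1/20 plus
the undiluted control, giving six points for linearity checks.

What the simulator does **not** model: substitution/indel sequencing
errors outside dedicated fixtures, flank-truncating fragmentation,
locus-specific stutter shapes, amplicon duplicates, or coverage imbalance
between loci. Passing tests on simulated data therefore demonstrate the
correctness of the algorithmic chain under its stated model — not
performance on FFPE libraries, which depends on laboratory-specific
reference profiles and flank choices.

## Problem sizes used in validation

The test-suite and acceptance-script simulations use: reference profiles
from 10,000 control pairs per locus (4,000 in the shared test fixture);
limit-of-detection runs at 2,000 pairs per locus over unstable fractions
{18.5, 9.3, 6.2, 5.0, 3.7}% with 20 seeded replicates each; dilution-series
linearity over six dilutions × 3 seeds at 2,000 pairs; specificity over
200 seeded pure-stable replicates at 1,000 observations per locus. These
sizes give binomial standard errors comfortably inside the asserted
tolerances while keeping a full run on a laptop-class single core in
minutes.

## Known limitations

* Real assay flank sequences are primer-panel specific and must be
  supplied by the user; the packaged panel's flanks are synthetic.
* The χ² calibration of the LRT is asymptotic and boundary-affected; the
  conservative df convention trades a little sensitivity for specificity.
* A germline microsatellite polymorphism looks like a ~50% unstable
  allele; it is flagged (`suspected_polymorphism`), not resolved — a
  matched normal is the only clean resolution.
* Loci whose reference mean is short (NR-21) have a narrow ±10% band
  (±2.1 nt), so small true shifts sit near the stable boundary; this is a
  property of the decision rule, not of the implementation.
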