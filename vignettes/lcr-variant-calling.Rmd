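---
title: "Multilocus variant calling in low-copy repeats: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilocus variant calling in low-copy repeats: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcrcall)
library(dplyr)
```

## The problem

Low-copy repeats (LCRs, segmental duplications) are long stretches of DNA
present in two or more nearly identical copies. Short reads from an LCR
align equally well to every copy, so mappers assign them low or zero
mapping quality and conventional callers — which analyse one genomic
interval at a time and discard ambiguous reads — lose both sensitivity and
specificity there. The only sequence signal that distinguishes the copies
is the set of paralogous sequence variants (PSVs): positions where the
copies' reference sequences differ. PSVs are themselves unreliable guides,
because many are polymorphic in the population — the "reference
difference" is absent from a substantial fraction of haplotypes.

`lcrcall` implements a multilocus strategy that turns this around. Reads
from *all* copies are pooled onto one representative copy and variants are
discovered with a polyploid genotype model at the locus's total (aggregate)
copy number, so no read is wasted. Population reference-allele frequencies
at PSVs then identify the subset of PSVs that are *informative* for the
sample — confidently reference-like on every copy — and read pairs
covering informative PSVs are probabilistically assigned to copies,
yielding paralog-specific genotypes for each variant.

Throughout, a sample's paralog-specific copy numbers `csi` (one per repeat
copy, summing to the aggregate copy number `agcn`) are taken as known
input, as produced by an upstream copy-number estimator.

## Stage 1: pooled discovery and aggregate genotyping

All alignments are projected through a homology map — a column table
derived from a multiple sequence alignment of the copies' reference
sequences (`build_homology_map()`) — onto the representative copy, keeping
per-base alignment and ignoring mapping quality entirely. Base
observations below quality 10 and allele observations that do not span a
site's full reference span are discarded; mates of one pair are collapsed
into a single observation per site (dropped when they disagree).

At a candidate site with allele set $A$ and pooled allelic depths $X$, the
likelihood of an aggregate genotype $\hat g$ (a multiset of `agcn`
alleles) is multinomial,

$$P(X \mid \hat g) = \mathrm{MN}\!\left(X;\, p(a_1, \hat g), \ldots\right),
\qquad
p(a, \hat g) = \frac{(|\bar r| - |a| - 1)\,\max\{\epsilon\,\hat c,\ \mu(a, \hat g)\}}
      {\sum_{a'} (|\bar r| - |a'| - 1)\,\max\{\epsilon\,\hat c,\ \mu(a', \hat g)\}},$$

where $\mu(a, \hat g)$ counts copies of $a$ in $\hat g$, $|\bar r|$ is the
mean aligned read length of the locus's pooled pileup, and $\epsilon$ the
sequencing error rate. The error floor $\epsilon \hat c$ keeps every
allele's weight positive; the length term down-weights long alleles, which
fewer read placements can span. Posteriors use a uniform prior over the
$\binom{agcn + |A| - 1}{|A| - 1}$ genotypes, so the MAP genotype is the
maximum-likelihood genotype. Everything is computed in log space with
log-sum-exp normalisation; depths in the hundreds would underflow a
linear-space implementation.

```{r}
aggregate_posterior(c(A = 22, G = 8), c("A", "G"), agcn = 4)
```

Candidate sites are positions with at least two non-reference read-pair
observations (or any insertion/deletion evidence), always extended with
every PSV position; non-PSV candidates whose Phred-scaled aggregate
quality falls below 1 are removed.

## Stage 2: informative PSVs

For a PSV with per-copy reference alleles $a_i^*$ and population
reference-allele frequencies $f_i \in (0,1)$, a paralog genotype $g$ (an
n-tuple of per-copy multisets) has prior

$$P(g; f) = \prod_i f_i^{\mu(a_i^*, g_i)} (1 - f_i)^{c_i - \mu(a_i^*, g_i)},$$

and posterior equal to the aggregate posterior of its flattening times this
prior renormalised within the aggregate genotype's class. A PSV is
**informative** when its MAP paralog genotype is reference-compatible
(every copy carries only its own reference allele) with posterior at least
0.99. Informative PSVs are the anchors that let read pairs be assigned to
copies.

Two practical notes on this chain. First, the aggregate-genotype factor
means informativeness needs a reasonably depth-balanced pileup as well as
high $f$: at pooled depth ~60 a depth imbalance of more than about four
reads already drops the balanced genotype's posterior below 0.99, so at
30× WGS over a two-copy locus roughly half of truly reference-like PSVs
are informative, rising above 95% at pooled depth ~120. The package's
property tests assert exactly this behaviour. Second, the single-site
posterior cannot see cross-copy gene conversions whose aggregate genotype
equals the reference multiset; those are caught (when read pairs co-cover
two PSVs) by the conflict test below.

Pairs of informative PSVs co-covered by at least three read pairs are
tested for conflict: a co-covering pair is *discordant* when its allele
combination matches no copy's reference haplotype, and the discordant
count is referred to a one-tailed binomial test with
$\pi = 2\epsilon - \epsilon^2$ (an error at either site), flagging
conflict at $p < 10^{-3}$. On the resulting conflict graph the package
keeps an edge-free subset maximising $\sum \tilde f_v$
($\tilde f_v = \min_i f_{vi}$) — a weighted maximum independent set, which
is NP-complete — via the greedy heuristic of repeatedly deleting the node
with maximal $\mathrm{degree} \cdot (1 - \tilde f_v)^{1/2}$, breaking ties
towards smaller $\tilde f_v$ and then lower coordinate so runs are
deterministic. On random graphs of up to 12 nodes the greedy solution is a
valid independent set always and optimal in roughly three quarters of
cases (the acceptance suite reports the gap against exhaustive search).

## Stage 3: paralog-specific genotyping

Each read pair $r$ covering a variant receives location probabilities over
copies from the informative PSVs $W_r$ it covers:

$$p_r(i) = \frac{c_i \prod_{v \in W_r} P(a_{vi} \mid r)}
                 {\sum_j c_j \prod_{v \in W_r} P(a_{vj} \mid r)},$$

with $P(a_{vi} \mid r) = 1 - \epsilon$ on allele match, $\epsilon$ on
mismatch, and $\epsilon^2$ when the PSV is missing from a copy (shorter
copy). With no PSVs covered the location prior is simply $c_i / \hat c$. A
pair anchored outside the duplication is treated as carrying one
perfectly-matching pseudo-PSV for that copy.

The read-pair likelihood under paralog genotype $g$ mixes per-copy allele
emissions over locations,

$$P(r \mid g) = \sum_i \frac{p_r(i)}{c_i}
  \left((1-\epsilon)\,\mu(a_r, g_i) + \epsilon\,(c_i - \mu(a_r, g_i))\right),$$

and the genotype posterior multiplies the prior — the PSV population prior
above for PSV sites, or for novel variants a mutation-rate prior that
penalises each copy carrying any non-reference allele by $\xi = 10^{-3}$
(homozygous and heterozygous equally) — by the product over reads. The
genotype space is the union of paralog genotype classes of every aggregate
genotype with posterior above $10^{-6}$; this truncation was left open in
the design and keeps the sum tractable without visibly changing
posteriors. Variants reached by no informative-PSV-linked read pair are
reported **unresolved**, with their aggregate genotype only.

Qualities: the variant QUAL is $-10\log_{10} P(\text{all-reference
genotype} \mid \text{reads})$ and each copy's GQ is $-10\log_{10}(1 -
P(\text{MAP copy genotype}))$, both capped at 1000. Variants failing a
two-sided Fisher exact test on the reference/non-reference by strand 2×2
table at $p < 0.01$ are flagged `StrandBias`; variants with QUAL below the
recommended output threshold 21 are flagged `LowQual`. Records are
annotated, never suppressed. Note that the Fisher filter fires at about
its nominal 1% rate even on error-free data — strand assignment is random
— so a small number of flagged true variants is expected, not a defect.

```{r}
# a read pair matching copy 1's allele at two informative PSVs
locate_read_pair(c("T", "G"),
                 matrix(c("T", "C", "G", "A"), 2, byrow = TRUE),
                 pscn = c(2, 2))
```

## The simulator

`simulate_bundle()` generates everything the caller consumes, so the whole
pipeline is testable without external data: copy sequences from a common
ancestor differing at substitution PSVs placed at per-column rate
$1 - \text{similarity}$; per-copy PSV reference-allele frequencies (all
0.9999 in the fixed-PSV scenario, otherwise 70% Uniform(0.9, 1) and 30%
Uniform(0.5, 0.9) per copy — a stand-in for empirical population
frequencies, which cannot be shipped); sample haplotypes that realise each
PSV reference allele with probability $f_i$; novel variants every kilobase
(80% substitutions, 10% insertions, 10% deletions of 1–4 bp, 61.5%
heterozygous, with a 20 bp edge margin and 10 bp minimal spacing so each
variant owns its site, and PSV-overlapping variants discarded by default);
and paired 150 bp reads at mean fragment 500 bp with per-base substitution
errors. `depth` is the coverage of one diploid copy (WGS convention), so a
two-copy locus at `depth = 30` pools about 60 reads per position. Fragment
starts extend past the locus ends so edge coverage does not decay. Each
pair's reported alignment copy is the best PSV-matching copy (random for
PSV-free pairs), emulating ambiguous mapping; the true copy is kept in a
tag. A mandatory seed makes every bundle byte-reproducible.

What the simulator deliberately does not model: indel PSVs (copies stay
coordinate-aligned; gapped homology maps are exercised with constructed
alignments in the tests instead), indel sequencing errors, GC or
position-dependent coverage bias, base-quality variation (all bases Q30),
and chimeric or soft-clipped alignments. Passing tests therefore
demonstrate correctness of the probabilistic machinery under the model's
own assumptions, not robustness to every artefact of real sequencing data.

```{r}
cfg <- sim_config(seed = 42, copy_length = 4000)
bundle <- simulate_bundle(cfg)
cs <- call_locus(bundle$reads, bundle$locus$map, bundle$locus$psv_table,
                 pscn = cfg$pscn)
cs
```

```{r}
ev <- evaluate_calls(cs, bundle$sample$truth)
tidy(ev)
```

## Evaluation semantics

`evaluate_calls()` scores two levels. The **aggregate** level measures the
discovery stage: only sites whose aggregate genotype differs from the
reference allele multiset participate, matched by position and shared
normalised allele. Cross-copy conversion events whose aggregate genotype
*equals* the reference multiset are invisible to pooled discovery by
construction, so they are excluded there and scored instead at the
**paralog** level, where a true positive additionally requires the full
per-copy genotype to match. Genotype concordance — the headline quality of
stage 3 — is the fraction of resolved, detection-matched calls whose
paralog genotype equals the truth. Precision is `NA` when nothing was
called; F½ (which favours precision) is reported alongside F1. Equivalent
indel representations are normalised by trimming shared suffixes before
comparison.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `epsilon` | 0.01 | per-base error rate used in all three stages (a typical Illumina short-read value) |
| `xi` | 1e-3 | mutation-rate prior penalty per non-reference copy at novel variants |
| `min_base_quality` | 10 | base observations below this are discarded |
| `informative_threshold` | 0.99 | posterior needed to call a PSV informative |
| `conflict_p`, `conflict_min_pairs` | 1e-3, 3 | binomial conflict test threshold and minimum co-covering pairs |
| `fet_p` | 0.01 | strand-bias Fisher test failure threshold |
| `min_candidate_quality` | 1 | discovery-stage quality floor for non-PSV candidates |
| `output_quality` | 21 | LowQual threshold, the recommended operating point |

`mean_read_len` is computed per locus from the pooled pileup rather than
globally; the choice is immaterial for uniform-length reads and keeps loci
independent.

## Numerical and degenerate-input choices

Alleles are ordered by (length, lexicographic) and genotype enumerations
follow a fixed canonical order, so every run is deterministic including
tie-breaks. Posterior sums are normalised with log-sum-exp. An all-zero
strand table passes the Fisher filter (no evidence). A site with no
spanning observations is never emitted as a variant. Copies with unknown
paralog-specific copy number make a locus ineligible, unless the
extended-copy fallback is requested, which merges the unknown copies into
one pseudo-copy with `pscn = agcn - sum(known)`; variants assigned there
get aggregate genotypes only — a documented approximation. In benchmark
mode, loci with five or more copies or any `pscn != 2` are skipped, with
machine-readable reasons in the manifest.

## Known limitations

Indels use the same constant error-rate emission model as SNVs, which
overstates confidence in low-complexity sequence. A gene conversion that
swaps alleles symmetrically between copies leaves the aggregate genotype
at the reference multiset and can only be caught through conflicts with
neighbouring informative PSVs; when the conflict graph is locally sparse,
pruning keeps the higher-$\tilde f$ PSV of a conflicting pair, and if the
population prior happens to favour the converted PSV the reads it anchors
are misassigned — these rare events dominate the residual paralog-level
error. Informativeness at 30× coverage is intrinsically limited by
aggregate-genotype uncertainty (see Stage 2), which bounds how many
variants can be resolved. Phasing across variants and joint multi-sample
calling are out of scope.

## Problem sizes used in the checks

The test suite validates the posterior families against brute-force
enumeration oracles on ~1000 random small instances (up to 3 alleles,
aggregate copy number 6, 20 read pairs), the statistical filters against
exact enumeration on 500 random tables, and greedy pruning against
exhaustive search on 200 random graphs of up to 12 nodes. The end-to-end
recovery check simulates twenty 10 kb two-copy loci at similarity 0.995,
30×, 1% error (and error-free fixed-PSV loci at 60× for the exact
round-trip); the acceptance script re-runs a 12-locus version of the same
computation from scratch.
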