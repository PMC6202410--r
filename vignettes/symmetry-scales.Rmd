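---
title: "Scale-resolved strand symmetries in genetic sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale-resolved strand symmetries in genetic sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symscales)
```

## The problem

Chargaff's second parity rule states that, on a *single* DNA strand, the
frequency of a short oligonucleotide approximately equals the frequency of
its reverse complement. Independently, genome sequences show non-random
structure — patchiness, isochores, long-range correlations — at scales from
tens of bases to megabases. `symscales` implements a single framework in
which both observations can be studied together: it measures *which* strand
symmetries hold at *which* genomic scales, and ships a generative domain
model that reproduces the resulting hierarchy with known ground truth.

## Observables and frequencies

The unit of counting is a *gapped pattern*
\(X = ((\alpha_0,\dots,\alpha_k), (\tau_1,\dots,\tau_k))\): bases
\(\alpha_j \in \{A,C,G,T\}\) at prescribed distances \(\tau_j \ge 1\), with
span \(\ell_X = \sum_j \tau_j + 1\). Its frequency in a sequence of length
\(N\) is the fraction of the \(N' = N - \ell_X + 1\) windows in which every
base matches:

\[
P(X) = \frac{1}{N'}\,\#_i\{s_i = \alpha_0,\; s_{i+\ell_1} = \alpha_1,\dots\},
\qquad \ell_j = \textstyle\sum_{r \le j} \tau_r .
\]

Overlapping occurrences all count; there is no circular wraparound. Counts
and window totals are kept as exact integers and divided only at reporting
time, so small worked examples are bit-exact:

```{r}
count_pattern("GGACCGGCCACAGGAA", "A1C2G")
```

The strand-symmetric partner of a pattern complements the bases and reverses
both base and gap order,
\(\hat X = ((\hat\alpha_k,\dots,\hat\alpha_0),(\tau_k,\dots,\tau_1))\)
(`revcomp_pattern()`); the extended Chargaff conjecture is
\(P(X) = P(\hat X)\) for *any* observable, including ones spanning large
distances.

## Cross-correlations and the four symmetries

To separate scales, two dinucleotides \(X_A, X_B\) are required to co-occur
at separation \(\ell\), giving the composite \(Y = (X_A, X_B; \ell)\) and
the normalized cross-correlation

\[
z_{[X_A,X_B]}(\ell) = \frac{P(X_A, X_B; \ell)}{P(X_A)\,P(X_B)},
\]

where \(z = 1\) means independence and deviations from 1 are structure.
Two elementary transformations act on composites: \(R\) swaps the pair and
\(C\) reverse-complements the first slot. Both are involutions and they do
not commute. Four symmetry groups are generated from them:

| symmetry | generators | generic closure size | interpretation |
|---|---|---|---|
| S1 | CRC | 2 | extended Chargaff: \(Y \leftrightarrow (\hat X_B, \hat X_A)\) |
| S2 | CRC, R | 4 | Chargaff plus order irrelevance |
| S3 | R, C | 8 | full group: any hat/swap combination |
| S4 | RCR, C | 4 | independent hats on each slot |

`closure()` computes the orbit of any reference pair by breadth-first
closure with set semantics; the closures nest
(\(\mathcal S_{S1} \subset \mathcal S_{S2} \subset \mathcal S_{S3}\),
\(\mathcal S_{S4} \subset \mathcal S_{S3}\)).

Transformation words are applied right-to-left (the rightmost letter acts
first), as in operator composition. For the four shipped generator sets the
generated closures are identical under either order, so the choice is
cosmetic, but it is fixed and documented. One published listing of the S3
orbit contains an element inconsistent with the group closure of
\(\{R, C\}\); the package follows the algebra, whose S3 orbit is exactly the
8 hat/swap combinations.

## The symmetry index

The strength of a symmetry \(S\) at scale \(\ell\) is the spread of \(z\)
within closures relative to the spread across all pairs:

\[
d_\ell(Y_{\mathrm{ref}}; S) =
\frac{1}{|\mathcal S_S|}\sum_{Y \in \mathcal S_S(Y_{\mathrm{ref}})}
\frac{[z_{[Y]}(\ell) - z_{[Y_{\mathrm{ref}}]}(\ell)]^2}{\sigma^2(\ell)},
\qquad
I_S(\ell) = \frac{1}{2|\mathcal A|}\sum_{Y_{\mathrm{ref}} \in \mathcal A}
d_\ell(Y_{\mathrm{ref}}; S),
\]

with \(\mathcal A\) the set of all 256 *ordered* dinucleotide pairs (ordered
is forced because \(R\) acts nontrivially) and \(\sigma(\ell)\) the
population standard deviation of the 256 \(z\) values. \(I_S = 0\) means the
symmetry holds exactly. Degenerate closures (for instance when a component
is its own reverse complement) are averaged over their actual deduplicated
size.

Two calibration facts matter when interpreting magnitudes:

* Under the null of i.i.d. \(z\) values, the expectation of a
  non-degenerate reference's contribution is not exactly
  \((|\mathcal S_S| - 1)/|\mathcal S_S|\) but that value times
  \(|\mathcal A|/(|\mathcal A| - 1) = 256/255\): because \(\sigma\) is
  estimated from the same 256 values, the normalized squared deviations sum
  exactly to a fixed total. The package's tests verify this closed form by
  Monte Carlo.
* Averaged over *all* 256 references, degenerate closures pull the null mean
  below the idealized value (most strongly for S4, where 112 of the 256
  references have a self-reverse-complement component). This is why the
  index of a structureless sequence is "of order one" rather than exactly 1.

## Detected scales and display rules

A symmetry is *present* at a scale when \(0 \le I_S \le 0.025\); the
threshold is a fixed operational cutoff, not a statistical test. Scales are
read off the dyadic grid (\(\ell = 2^i\), default \(i = 0..24\)) by first
crossing:

* **L_D** — smallest scale with S2 present (domain scale);
* **L_S** — smallest scale with S3 present (same-type domain cluster scale);
* **L_M** — smallest scale with S1 absent while S4 present (macrostructure
  scale, where Chargaff breaks).

Estimates therefore carry one dyadic step of grid resolution; raising the
threshold can only decrease L_D and L_S (monotonicity is property-tested).
For multi-sequence displays, indices are rescaled per sequence to an
intensity that is 1 at or below \(1.05\,I_{\min}\) and 0 at or above
\(6.5\,I_{\min}\), linear in between (`heatmap_table()`).

## The domain-model generator

`generate_genome()` implements a three-level generative model whose defaults
are the reference study conditions; they are fixed, not tuning knobs:

1. **Domains.** Order-1 Markov chains over A,C,G,T. The two shipped
   transition matrices (`markov_matrix_I()`, `markov_matrix_II()`) have
   stationary measures that violate Chargaff
   (\(\mu(A) \ne \mu(T)\), \(\mu(C) \ne \mu(G)\)), so no symmetry is put in
   by hand at the base level. Their correlations decay within about ten
   bases, which *is* the domain scale L_D: it emerges from the mixing time
   (reported as the second-largest eigenvalue modulus in the ground truth)
   rather than being an input.
2. **Chunks and clusters.** Chunks of length uniform on [130, 170] bases
   (mean 150) are generated independently — each chunk restarts from the
   stationary distribution, which is forced by the fact that individual
   chunks get reverse-complemented. With probability 1/2 a chunk is
   mirrored (reverse-complemented) before concatenation. Mirrored and plain
   chunks thus appear with equal abundance, and same-orientation runs are
   geometric with mean 2 chunks, giving the cluster scale
   \(L_S \simeq 2 \times 150 = 300\) bases.
3. **Macrostructures.** Chunks are concatenated until the target length
   \(L_M = 10^6\) is reached; the last chunk is kept whole (truncating it
   would bias the final chunk-length distribution), so macrostructure
   lengths lie in \([10^6, 10^6 + 170)\). One macrostructure per process is
   generated and the two are concatenated.

A single seeded R RNG drives everything in a fixed draw order — per chunk:
length, then orientation, then bases (the base-level draws run in compiled
code through the same RNG stream) — so genomes are bit-reproducible from
`domain_model_config(seed = )`.

The generator emulates the statistical skeleton of a genome — Chargaff-
symmetric domain types, clustering, compositionally distinct
macrostructures — and nothing else: no repeat families, no gene structure,
no GC-content gradients within macrostructures, no insertion/deletion
dynamics. Passing the hierarchy tests on simulated genomes shows the
analysis machinery recovers the scales the model encodes; it does not by
itself validate conclusions about real chromosomes.

## Numerical choices

* **Marginals.** In \(z\), the marginal frequencies are computed over the
  whole sequence with their own window counts, not restricted to positions
  where the composite fits; the difference is \(O(\ell/N)\).
* **Separation conventions.** The middle gap of the flattened composite is
  \(\ell\) under the default `formula` convention; the alternative `table1`
  convention uses \(\ell + 1\), i.e. \(\ell\) fully unconstrained positions
  between the dinucleotides (the 8-position layout used in published
  per-pair tables). All symmetry algebra is convention-independent because
  the separation is carried opaquely.
* **Statistical floor.** \(z\) is only reported at scales with at least
  1000 composite windows (`min_windows`); scales below the floor are
  dropped with a message, never silently.
* **Undefined values.** A vanishing marginal flags \(z\) as `NA`; reference
  pairs whose orbit contains an undefined \(z\) are excluded from
  \(\mathcal A\) with a message and the prefactor uses the reduced count.
  \(\sigma = 0\) (constant \(z\)) makes the index undefined, flagged, at
  that scale.
* **Single-pass scanning.** Per scale, all 256 joint counts come from one
  pass over the integer-coded sequence (a joint histogram of position-wise
  dinucleotide codes); the per-pattern counter is retained as the
  independent slow path and the two are required to agree exactly on
  integer counts.

## Problem sizes in the shipped tests

The test suite exercises the full default study conditions: five simulated
genomes of two \(10^6\)-base macrostructures each for the hierarchy check;
twelve replicate \(10^6\)-base stationary Markov sequences for the
closed-form \(z\) comparison at six scales; \(10^4\) Monte-Carlo replicates
for the index null; and \(10^5\)-base mirrored constructions for the exact
Chargaff checks. Unit and property tests run on sequences of \(10^3\) to
\(10^5\) bases. A note on the mirrored construction \(w + \widehat{w}\): it
is exactly self-reverse-complementary, so pattern counts equal their
hat-partner counts *exactly* (a window bijection), making it a sharp
fixture for S1.

## Known limitations

* The scanner's bulk path covers dinucleotide pairs only; longer components
  are supported one pattern at a time through `count_pattern()`.
* Presence of a symmetry is a threshold rule on \(I_S\), not a significance
  test; near-threshold calls inherit one dyadic grid step of uncertainty.
* The characteristic-scale detector assumes the canonical ordering of
  regimes; exotic inputs (e.g. a genome of one macrostructure) legitimately
  report scales as absent rather than guessing.
* Order-1 Markov domains cannot represent longer-range within-domain
  structure; L_D of order larger than tens of bases would require
  higher-order processes, which are out of scope.
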