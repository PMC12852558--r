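---
title: "Methods: virome triage, composition-based host inference, and abundance profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virome triage, composition-based host inference, and abundance profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virotriage)
```

`virotriage` covers the bench-side analytical stages of a metatranscriptome
virome survey: deciding which candidate contigs are credible viral
sequences, predicting their ORFs, profiling their nucleotide composition,
assigning putative hosts by compositional affinity, and summarising
transcriptional activity relative to endogenous control genes. This
vignette explains the models and conventions behind each stage, the
tunable parameters, and the choices made where the methodology was
genuinely open.

## Curation of candidate viral elements

Similarity searches against viral protein databases produce, for each
candidate, a ranked hit list. Two pieces of evidence enter the retention
decision:

1. the 1-based **rank of the first viral hit** among the top `depth = 30`
   protein-level matches (viral status of a subject comes from a
   user-supplied flag table, never from a live database), and
2. whether a **conserved viral domain** was annotated on the candidate by
   an external domain-search tool.

The verdict is a pure function of these two inputs: retained when a viral
hit occurs in the window *and* a viral domain is present
(`retained_domain_rule`); retained without a domain only when the first
viral hit falls within `rescue_depth = 10` (`retained_top10_rule`);
excluded otherwise. A domain alone never rescues a candidate — a viral hit
in the window is mandatory. The truth table over all 62 (rank, domain)
combinations is asserted exhaustively in the test suite.

Hit order is a genuine degree of freedom: tabular search output is already
sorted per query, but re-ranking by bitscore (ties: ascending e-value, then
input order) makes the "top k" semantics independent of upstream sorting
quirks. `bitscore_desc` is therefore the default; `file_order` replays a
file bit-exactly when that is wanted.

Exogenous-contig selection keeps contigs **strictly longer than 500 nt** —
a 500 nt contig is dropped. Candidate hosts for composition profiling are
subjects attaining **strictly more than 90% identity** in at least one hit,
optionally intersected with the set of species that have mitochondrial
genome assemblies (many mycoviruses, mitoviruses in particular, replicate
in mitochondria, so mitochondrial references matter as much as nuclear
ones).

Redundancy reduction uses greedy incremental clustering: sequences sorted
by length descending (ties: id ascending) join the first cluster whose
representative they match at ≥ 90% identity, else found a new cluster.
Identity is the fraction of identical columns over a **global alignment**
(selected under match +1, mismatch 0, gap open −10, gap extend −1); at
desk scale exact alignment is affordable and is checked against an
all-pairs oracle, so no word-based heuristics are involved. The threshold
is interpreted as nucleotide identity, since the clustered units are ORF
nucleotide sequences.

## ORF prediction

Two modes mirror the two prediction styles used in practice:

* `mode = "region"` (default, the EVE genome screen): maximal stop-free
  codon runs between stop codons or sequence ends, stop excluded, in all
  six frames, bounded by `min_len = 100` and `max_len = 6000` nt. This is
  the "region between stops" convention of getorf-style screens.
* `mode = "complete"` (contig characterisation): ATG to the next in-frame
  stop, **stop codon included in the reported length**. Conventions differ
  between tools here; including the stop is the more common one and is
  fixed explicitly so every downstream length is unambiguous. Nested ORFs
  (internal ATGs sharing a stop) are suppressed by default and available
  via `all_starts = TRUE`.

Coordinates are 0-based half-open on the forward strand throughout the
package; 1-based inclusive coordinates exist only inside read tabular hit
files. ORFs containing an ambiguity code in any codon are excluded rather
than translated fuzzily. Genetic code 1 is the default; code 4 (TGA =
Trp) is exposed because mitovirus ORFs are translated by the mitochondrial
machinery. Correctness is established against a brute-force six-frame
enumeration oracle on random sequences and by a strand-symmetry property
(ORFs of the reverse complement mirror exactly).

## Composition profiling

**Codon usage.** Codons are counted in frame over all ORFs of an entity,
pooled at count level — the semantics of running a codon-usage tool on a
concatenated gene set, not an average of per-ORF fractions. Terminal stop
codons are excluded by default because relative synonymous codon usage
(RSCU) is defined over sense codons; `include_stops = TRUE` restores the
classical whole-table behaviour. Within each synonymous family of size
$k$, $\mathrm{RSCU}(c) = n_c \, k / \sum_{c' \in \text{fam}} n_{c'}$, with
$0/0 \to 0$; the family mean is 1 whenever the family is observed, an
invariant the tests assert.

**Dinucleotides.** Overlapping dinucleotides are counted linearly per
sequence (no wraparound) and pooled; any window containing a non-ACGT
symbol is skipped. The reported statistic is the Karlin odds ratio
$\rho(XY) = f(XY)/(f(X)f(Y))$ with mononucleotide frequencies from the
pooled counts — departure from 1 flags compositional bias. The
expected-frequency convention of classical suite tools (uniform 1/16) is
deliberately not used: the odds ratio is the statistic actually
interpreted in virus–host composition work. An absent base makes the
denominator zero; the odds value is then reported missing and the feature
column is dropped (with a message) when matrices are assembled.

Whether profiles should use all ORFs of a contig or only the longest is
unstated in common practice; the package profiles whatever ORF set it is
given, and the pipeline default is all ORFs within the length bounds.

## Host inference

Viral and candidate-host profiles are compared by **Spearman correlation**
over their shared feature columns (codon fractions, dinucleotide odds, or
their concatenation; the pipeline default is `concatenated`, matching the
joint codon + dinucleotide clustering view, with the single-block modes
available for the dinucleotide-only and codon-only views). Ranks use
average ties; rho is Pearson on ranks. Rank-based correlation is the right
invariance class here: it is unaffected by any strictly monotone
distortion of a profile, which the tests verify directly.

Each virus is assigned its best-correlated host; the margin
$\rho_1 - \rho_2$ is reported as a simple confidence measure, and exact
ties break deterministically by host id and are flagged. Pooled profiles
(viruses + hosts, nuclear and mitochondrial references together) are
clustered hierarchically on the distance $1 - \rho$ with **average
linkage**. Neither the linkage nor the distance transform is canonical in
published dendrograms; $1-\rho$ (not $1-|\rho|$) is used because
anticorrelation is genuine dissimilarity for compositional affinity, and
average linkage is a middle ground that does not chain like single linkage
nor over-compact like complete linkage. Both choices are package
conventions, stated here, not facts inherited from any particular study.

## Abundance

TPM is computed as $\mathrm{TPM}_i = (c_i/l_i)/\sum_j (c_j/l_j) \times
10^6$; every library column sums to one million by construction, which the
tests assert to $10^{-3}$. Salmon-style quant tables are accepted directly;
TPM can be recomputed from counts to guarantee the invariant. Relative
transcriptional activity divides a feature's TPM by the per-library mean of
the endogenous control genes (stably expressed host genes such as ACT7, H1
and COX2); a zero control mean yields a missing ratio rather than an
infinity. Presence is called at TPM ≥ 1 by default — no universal floor
exists, 1 TPM is the conventional choice and it is configurable. Group
fold changes are ratios of arithmetic TPM means (matching how fold
differences between sample groups are conventionally reported from TPM
ranges), with an optional pseudocount; the estimate is scale-invariant at
pseudocount 0. The heatmap matrix is $\log_{10}(\mathrm{TPM}+1)$ — the
pseudocount of 1 maps zeros to zero and is required because log of zero is
undefined — with rows ordered by average-linkage clustering on
$1 - r_{\text{Pearson}}$; zero-variance rows have no defined correlation
and are placed at distance 1 from everything, with a message.

## What the synthetic generators emulate — and what they do not

The generators reproduce the statistical *structure* each stage consumes,
under a single integer seed (byte-identical reruns):

* **Host profiles**: per amino-acid family, a symmetric Dirichlet draw
  over family codons. The concentration parameter controls divergence;
  the default 0.5 yields clearly divergent hosts (minimum pairwise L1
  distance between 5 hosts above 0.2 at the tested seeds), which is the
  regime where compositional host inference is informative. Amino-acid
  usage is uniform by design, so only codon choice carries host signal —
  the exact signal the inference stage is supposed to detect, isolated
  from protein-composition effects.
* **Viral ORFs**: ATG + body + stop; each body codon follows the host
  family preference with probability $1-\text{noise}$, else is uniform
  over the family. At noise 0 the viral profile converges to the host's at
  the rate of multinomial sampling; at noise 1 assignment accuracy sits at
  chance (≈ 1/`n_hosts`). The acceptance suite measures the full noise
  grid {0, 0.25, 0.5, 0.75, 1} at 30 viruses × 300 codons × 20 seeds and
  checks accuracy is monotone non-increasing.
* **Hit tables**: 30 hits per query with strictly decreasing bitscores and
  a planted first-viral rank, emitted as literal tabular text so fixtures
  exercise the real readers.
* **Expression fixtures**: control genes at stable median TPM, viral
  features at baseline TPM in one group and baseline × planted fold in the
  other, median-preserving lognormal noise (default σ = 0.5 on the log10
  scale — heavy-tailed, strictly positive, the standard expression noise
  model), a background feature absorbing the remainder so TPM sums to
  10⁶ exactly, and fractional read counts back-computed so
  `tpm_from_counts()` reproduces the planted values exactly.

They do **not** emulate read-level noise, assembly artefacts, chimeras,
uneven amino-acid usage, GC-gradient effects, or library-size variation.
Passing tests therefore demonstrate that the *analytical* stages are
correct and well-calibrated on data satisfying their assumptions — not
that any particular real dataset will yield clean host assignments; real
profiles are noisier and real hosts less divergent than the default
generator regime.

## Numerical and testing choices

* Problem sizes in the test and acceptance suites: 50 random ≤ 2 kb
  sequences for the ORF oracle; 20 sequences (4 templates × 5 mutated
  copies at 3% substitution) for clustering; 100 kb i.i.d. sequences × 10
  seeds for odds-ratio calibration (all 16 ratios within 1 ± 0.05);
  600 virus assignments per noise level; 200 replicate fixtures per
  planted fold (2, 10, 112), median required within 25% of truth.
* The sampler-convergence bound at 10,000 codons is calibrated from an
  independent oracle (direct multinomial draws from the same profile)
  rather than fixed a priori, because the appropriate bound *is* the
  multinomial sampling error.
* Degenerate inputs: empty FASTA → empty tibble; header with no sequence →
  named format error; all-zero counts → TPM undefined (error); empty ORF
  list → profile with zero counts; single-feature heatmap → trivial order;
  all-missing correlation row → error.
* Everything downstream runs on a DNA alphabet: U is normalized to T at
  ingest, so RNA virus genomes and DNA references share one k-mer space.

## Pipeline and provenance

`run_pipeline()` wires the stages through files only (TSV/FASTA/Newick),
so each stage is independently replayable. Configuration is validated up
front (unknown keys rejected, thresholds checked against their documented
ranges) and every stage TSV starts with a comment line naming the stage
and a hash of the analytical configuration — the hash excludes the output
directory, so identical analyses written to different places produce
byte-identical artifacts. With no input files configured, the pipeline
runs end-to-end on the seeded generators, which is also how the test suite
exercises it.

## Known limitations

* Clustering identity is exact global alignment — quadratic in sequence
  length, intended for curated candidate sets (hundreds of sequences of a
  few kb), not for raw assemblies.
* Best-correlate host assignment has no significance measure; the margin
  is descriptive. Compositional affinity is evidence, not proof, of a
  host relationship.
* TPM is the only normalization offered; cross-library comparisons
  inherit TPM's compositional caveats, which is why activity is reported
  relative to endogenous control genes.
* Spliced or frameshifted genes are outside the ORF model.
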