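---
title: "Methods and design notes for mitocompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mitocompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "##")
library(mitocompare)
```

This vignette documents the statistical machinery, the parameter
choices, and the design decisions behind the package, in the spirit of
the model descriptions that accompany the established differential
expression and community ecology packages.

# Coordinates, circularity and labels

Internally every feature interval is 0-based half-open; the GenBank
boundary converts to and from 1-based inclusive coordinates.  This
removes the classic off-by-one ambiguity from sequence slicing: a
feature of length L always satisfies `end - start == L`.

Mitochondrial genomes are circular, and deposited records occasionally
write a feature as a `join` across the sequence origin.  There is no
universal origin convention, so the reader linearizes at read time:
the sequence is rotated so the wrap-around feature becomes contiguous,
and the rotation (in bases) is kept in the `originOffset` slot.  All
downstream comparisons that care about circularity (gene-order
clustering) work modulo rotation, so the choice of origin never
affects results.

Gene labels in deposited mitogenome records are notoriously mixed
("COI" vs "COX1", "l-rRNA" vs "rrnL", "cytb" vs "CYTB").  A small
alias table normalizes to one canonical scheme; labels the table does
not know pass through unchanged with feature class `other` and a
warning, rather than being dropped — unknown annotations are a fact of
real records, not an error.  Only the ambiguity letter N is accepted
in sequences; the rarer IUPAC letters are rejected with a clear error,
because codon counting and Ka/Ks need a defined policy per letter and
"skip codons containing N" is the only one we can apply consistently.

# Composition

Base percentages are computed over counted A/C/G/T with N excluded
from the denominator (so percentages always form a composition), and
skews are AT skew = (A−T)/(A+T), GC skew = (G−C)/(G+C), reported as 0
with an explicit flag when the denominator is empty.  Per-class rows
concatenate the class's feature slices in strand orientation.
Overlapping or duplicated features contribute to their class
independently, so class proportions can legitimately sum above 100% —
this matches how published feature tables report class sizes when a
gene is duplicated.  Strand orientation of class slices is a
convention choice (the A/T and G/C totals would swap under the
genome-strand convention); we fix strand-oriented and note that for
all-plus-strand genomes, which include the bivalve genomes this
toolkit was built around, the two conventions coincide.

# Codon usage and the two RSCU dialects

For codon $c$ in a synonymous family $F$ of size $k$,

$$\mathrm{RSCU}(c) = \frac{n_c}{\frac{1}{k}\sum_{c' \in F} n_{c'}},$$

the count divided by the family mean, so 1 means "no bias" and values
sum to $k$ within a fully counted family (a property-tested
invariant).

The subtle part is what "synonymous family" means for mitochondrial
data.  Translation uses the invertebrate mitochondrial code (table 5:
AUA→Met, UGA→Trp, AGA/AGG→Ser), but most published mitogenome codon
tables are computed with the *standard-code* family partition: AUA
grouped with the isoleucine codons ($k=3$), AGA/AGG with the six-codon
arginine family, UCN+AGY a six-codon serine family — and, once the
UAA/UAG stop counts are excluded, UGA sits alone in the three-codon
standard stop family, which mechanically produces RSCU(UGA) = 3.00 and
RSCU(UGG) = 1.00.  The package exposes both partitions:
`table8-standard` (default, reproduces published tables; the UGA/UGG
rows are flagged as dialect artifacts) and `table5-mito` (biologically
consistent with the translation table).  Verification against a
published venerid codon table reproduces all 62 printed RSCU values
within ±0.005 under the standard partition — including the UGA/UGG
rows — while the mito partition gives the biologically interpretable
alternative (e.g. RSCU(AUA) within the two-codon Met family).

Stop-codon handling follows the published convention "excluding the
stop codons": counts for the *translation-table* stops (UAA/UAG under
table 5) are removed from the totals, UGA counts (tryptophan) are
retained.  Rounding for table comparison is half away from zero at
2 decimals; note that a printed table may round an exact `.xx5` tie
either way, so comparisons are made on unrounded values at ±0.005.

One caution surfaced by the arithmetic: ranking amino-acid usage by
summed codon counts does not necessarily match eyeballing the tallest
RSCU bars.  In the shipped venerid table, leucine is the most used
family under every partition, but the runner-up depends on the
partition (six-codon serine edges out six-codon arginine on counts),
so `aaUsageRanking()` is defined by counts and tested against a
brute-force grouping oracle rather than against any narrative claim.

Third-position degeneracy is computed per codon by exhaustive scan of
the code table (changes to stops are not synonymous states); under
table 5 every third position is 2- or 4-fold degenerate.  The
degenerate-site composition accepts either CDS sets or a bare codon
count vector, so published tables can be analysed directly.

# Ka/Ks estimation

Both estimators operate on a gap-free codon alignment built by
protein-guided back-translation: proteins are aligned globally
(BLOSUM62, gap opening 10, extension 1 — the conventional
parameterisation for closely related mitochondrial proteins; the exact
aligner parameterisation matters little at the divergences involved,
which is why accession-level reproduction of published Ka/Ks values is
only expected within a tolerance), then each residue column is
replaced by its source codon.  Columns with gaps, N, or stop codons
are dropped and counted.

**NG86.**  Synonymous sites per codon are the per-position fractions
of one-step changes that are synonymous (changes to stops count as
nonsynonymous, preserving $S + N = 3 \times$ codons); differences are
averaged over all shortest mutational pathways between the observed
codons, excluding pathways through stops (a pair whose every pathway
is blocked is skipped and logged).  Proportions are corrected with the
one-parameter distance $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$;
$p \ge 3/4$ leaves the rate NA.  The implementation is verified
against an independent recursive pathway-enumeration oracle over all
sense-codon pairs.

**YN00-style.**  The approximate method follows the Yang–Nielsen
(2000) programme: κ is estimated from third-position nondegenerate and
fourfold-degenerate sites via the two-parameter (K80) distance, the
two site classes pooled by site-count weighting; sites are counted
weighting each possible change by κ and by F3×4 equilibrium codon
frequencies estimated jointly from both sequences (stop targets
excluded from numerator and denominator, so $S+N=3n$ is preserved
exactly); pathway weights are the products of GY94-style instantaneous
rates $\pi_{\text{target}}\,\kappa^{\mathrm{ts}}\,\omega^{\mathrm{nonsyn}}$;
synonymous and nonsynonymous proportions are split into transitions
and transversions and corrected separately with the K80 distance; and
the ω-dependent pathway weighting is iterated from ω = 0.5 until the
relative change falls below 1e-6 (cap 100 iterations; non-convergence
is flagged and the last iterate returned).  When κ is forced to 1 and
frequencies to uniform, the method reduces to NG86 within a few
percent (the residual difference comes from the K80-vs-JC correction
and from stop-neighbour handling in site counting); this reduction is
a standing test.

Both methods are exactly symmetric in their two input sequences
(pathway-weight products differ only by the constant factors
$\pi_{c_1}$ vs $\pi_{c_2}$, which cancel under normalization) — also a
standing test.

**Fisher validation.**  Each estimate carries a two-sided Fisher exact
p for the 2×2 table {synonymous, nonsynonymous} × {differences,
sites − differences}, with real-valued sites rounded to integers for
the hypergeometric support.  The two-sided rule sums all tables with
probability not exceeding the observed table's.  The p is computed
directly from the hypergeometric mass function and is tested to 1e-12
against a `choose()`-based enumeration oracle (and loosely against
`stats::fisher.test`, whose tie rule differs in the 7th decimal).
This 2×2 construction is our documented choice; published analyses
rarely state theirs.

Ka/Ks is reported NA — never 0/0 or ∞ — when Ks is 0 or the distance
correction is undefined.  When a gene is duplicated, copy 1 in genome
order is used for homologous comparison (configurable); which copy a
published analysis used is generally unstated, so this is a
convention, not a claim.

# Gene-order comparison

"Gene cluster" has no standard formal definition in the comparative
mitogenomics literature, so the package fixes one and validates it
mechanically: a cluster is a maximal run of genes contiguous and
identically ordered (and strand-compatible) in both genomes, where
genes private to one genome are *transparent* — skipped when testing
contiguity.  Without transparency, published cluster notations, which
elide species-specific tRNAs interleaved into otherwise conserved
blocks, would be irrecoverable.  Circular orders are compared over all
rotations by brute force (orders are ≤ ~50 labels, so cost is
trivial); duplicated labels are matched greedily left-to-right, a
documented heuristic backed by a replay validator
(`validateClusterMatch()`) that every reported cluster must pass in
the test suite.  Reversed clusters additionally require flipped
strands when strands are recorded; orders read from bare label lists
carry NA strands, which match either orientation, so order-only
reversals are still found.

TDRL inference is an exhaustive search over *single* tandem
duplication–random loss events: duplicate one contiguous block (≤ 6
genes by default), then keep first/second/both copies per position
("both" only for genes actually duplicated in the target), accepting
events whose replay equals the target order on the shared label set.
Every returned event is replayable by construction, and the search
space is capped with an explicit error advising a smaller window.  A
genuinely useful negative result: not every near-miss arrangement is
one TDRL away — e.g. no single TDRL maps k-l-m-n to k-m-m-l-n (the
tandem copy order forces any retained l between the two m copies),
whereas k-m-l-n to k-m-m-l-n is explained by duplicating m-l and
keeping both m copies.  The package returns the empty list in the
former case rather than forcing an explanation, matching the
two-lineage interpretation (both orders descending from an unstated
ancestor) that such patterns usually receive.

# The synthetic generators

The generators define the package's study conditions.

* `makeGeneOrder()` samples from the canonical metazoan inventory (13
  PCGs, 22 tRNAs, 2 rRNAs, control region), deterministic per seed.
* `evolveCodonPair()` evolves two independent descendants from an
  ancestor for t/2 each (star design, so a pairwise estimator sees a
  symmetric comparison at total divergence t), under a GY94-style
  continuous-time codon model with exact per-codon Gillespie
  simulation; rates to stop codons and multi-position changes are
  zero; the global rate is scaled so t is in expected substitutions
  per codon at equilibrium.  True synonymous/nonsynonymous event
  counts are recorded, and event-count conservation is a standing
  test.
* Default codon frequencies are F3×4 fitted to the shipped venerid
  codon-count table, giving realistically AT-rich coding sequences
  (synthetic whole genomes come out above 60% AT, as real bivalve
  mitogenomes do); uniform frequencies are available and are used in
  the estimator reduction tests.  Default ω = 0.2 and κ = 2 reflect
  the purifying selection and mild transition bias typical of
  mitochondrial PCGs.
* `divergenceForKs()` converts a target synonymous divergence into the
  model's t analytically from the rate structure, so recovery
  experiments can pin Ks ≈ 0.3 — deep enough to need the distance
  corrections, shallow enough that they are reliable.
* `makeGenomePair()` assembles full annotated circular genome pairs
  (evolved PCGs, shared tRNA/rRNA/control-region sequences, per-label
  intergenic spacers so identical configs yield byte-identical
  genomes) with a truth bundle sufficient to replay every planted
  event.

What the generators deliberately do not emulate: indels inside coding
sequences (the alignment stage is exercised with hand-built gap
cases), among-site rate variation, more than two lineages, and
annotation errors.  Green tests therefore demonstrate correctness of
the statistics and search procedures under the stated models, not
robustness to misannotation or alignment ambiguity in real records.

# Problem sizes and numerical choices

The test suite runs everything at sizes chosen to make sampling error
negligible relative to the tolerances while keeping the default run in
minutes: ω recovery uses 100 replicates × 1000 codons per ω ∈ {0.1,
0.3, 1.0} at κ = 2 and Ks ≈ 0.3 (mean ω̂ observed within ~3% of truth,
tested at ±15%); the NG86 reduction uses 20 pairs × 300 codons (max
relative difference observed ~2%, tested at 5%); planted-reversal and
planted-TDRL recovery use 100 seeds each (200 total) at 100% required
recovery; Fisher enumeration equality is tested at 1e-12 on margins ≤
40.  Iteration controls (1e-6 relative ω tolerance, 100-iteration
cap), the ω = 0.5 starting point, half-away-from-zero rounding for
table comparison, and the κ = 1 fallback when degenerate sites carry
no information are all fixed constants, not tuned values.

# Known limitations

* The YN00-style method is the approximate counting method, not a
  maximum-likelihood codon model; for deep divergences or strong
  codon-frequency asymmetries a likelihood method (codeml-style) is
  preferable.  Published Ka/Ks values computed with other software are
  expected to agree only within a tolerance, since aligner defaults
  and internal conventions (F3×4 estimation, pathway weighting, tie
  handling) differ between implementations.
* Gene-order comparison reports single-event TDRL explanations only;
  multi-event rearrangement distances (DCJ, sorting by reversals) are
  out of scope.
* The GenBank reader supports single-record flat files with the
  feature types a mitogenome uses; it is not a general GenBank parser.
* No multiple-testing correction is applied across genes in the Ka/Ks
  table (deliberately, matching common practice in descriptive
  mitogenome comparisons); users testing many genes formally should
  adjust the Fisher p values themselves.
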