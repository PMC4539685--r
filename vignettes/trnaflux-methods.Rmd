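---
title: "Methods: codon usage, selfish-element copy number and tRNA gene amplification"
author: "trnaflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage, selfish-element copy number and tRNA gene amplification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnaflux)
```

# The scientific question

When a bacterial lineage acquires a large volume of foreign DNA — insertion
sequences proliferating to hundreds of copies, or phage-mediated lateral
gene transfer (LGT) — the incoming genes often use codons that are rare in
the host genome. Expressing them strains the translational machinery unless
the cellular tRNA pool adjusts. One available adjustment is an increase in
the copy number of the tRNA genes that decode the over-supplied codons.
`trnaflux` provides the statistical machinery to test this hypothesis in a
strain complex: it measures the codon-usage shift introduced by selfish
genetic elements (SGEs) and LGT genes, counts gene and tRNA copies by
sequence similarity, and asks whether the amplified tRNA genes are exactly
those whose codons the foreign DNA over-uses — and whether the extra copies
arrived by within-genome duplication or by phage-mediated transfer.

# Codon usage and fold enrichment

Codon usage is tabulated per amino-acid family: for each of the 21
synonymous families (the three stop codons form one family), the relative
frequency of codon $c$ is its count divided by the family total, so each
family sums to 1. Because bacterial initiation uses several triplets
(ATG, GTG, TTG) interchangeably as formyl-methionine starts, the leading
triplet of every CDS is credited to the methionine family regardless of its
identity. Codons containing an ambiguous base are skipped individually;
genes with more than 10% ambiguous bases are dropped whole. This keeps one
bad region from discarding an entire gene while preventing heavily masked
sequences from distorting the table.

The *fold enrichment* of codon $c$ in a gene subset $S$ (the SGE set, or an
LGT set) against the genome is

$$E_c = \frac{\mathrm{rel}_S(c)}{\mathrm{rel}_G(c)},$$

where the genome table $G$ is computed over **all** genes *including* the
subset. Including the subset in the denominator makes the measure
conservative: any enrichment reported is an underestimate of the contrast
against the non-subset background. A codon unused genome-wide but used in
the subset is flagged infinite; a codon absent from both is assigned 1.
Cross-strain uncertainty is summarized by a t-interval over per-strain
folds, $\bar E_c \pm t_{(1+\gamma)/2,\,n-1}\, s_c/\sqrt{n}$, at level
$\gamma = 0.99$ by default.

# The rank-sum permutation test

To ask whether the codons decoded by the amplified tRNA genes sit
unusually high in the enrichment ranking, codons are ranked 1..64 from most
to least enriched (infinities first; ties broken by codon lexicographic
order so the ranking is always a permutation) and the ranks of the $k$
target codons are summed. Under the null, the targets are an arbitrary set
of $k$ ranks out of $n = 64$; low sums indicate coordinated enrichment, so
the test is one-tailed.

Two null samplers are provided, because "a random set of $k$ numbers
between 1 and $n$" is ambiguous: the default draws $k$ *distinct* ranks
(sets), and a with-replacement mode draws ordered $k$-tuples. Both a
Monte-Carlo estimate (default 10,000 draws, with the add-one estimator
$(\#\{\text{sum} \le S\} + 1)/(\text{reps}+1)$ so finite sampling never
reports 0) and the exact tail probability are reported. The exact value is
computed by dynamic programming over the count of $k$-subsets of
$\{1..n\}$ with sum $\le S$ (verified in the tests against brute-force
enumeration of all $\binom{64}{3} = 41{,}664$ subsets). For reference, a
rank sum of 9 with $k = 3$, $n = 64$ (targets ranked 2nd, 3rd, 4th) has
exact $p = 7/41{,}664 \approx 1.7\times 10^{-4}$ in distinct mode and
$\approx 3.2\times 10^{-4}$ with replacement. The ranking size is
configurable to $n = 61$ for sense-codon-only analyses.

# Similarity-based copy-number detection

Gene copies are found by a seed-and-extend search rather than an external
aligner, so results are deterministic and self-contained. Non-overlapping
12-mers of the query nominate candidate loci by exact match (on both
strands); each candidate window is then verified by glocal alignment —
global over the query, free end-gaps on the subject — scored +1/−1/−2
(match/mismatch/gap). Identity is matches over aligned query positions and
coverage is aligned query positions over query length, and a hit must
exceed **both** 0.95 thresholds strictly. The seed design gives a
pigeonhole guarantee: with $\lfloor L/12 \rfloor$ seeds, a copy with fewer
than that many substitutions always retains an intact seed, so every copy
near the 5% divergence boundary surfaces as a candidate and is decided by
the alignment thresholds, never by seeding luck. Overlapping hits are
merged keeping the best score, which prevents double-counting when several
diverged queries rediscover the same locus. An adapter for external
tabular search results can replace the built-in search for real genomes.

Reference genes that retrieve each other at 95/95 are clustered by single
linkage (a chain A–B, B–C links A and C even if A–C falls below
threshold), mirroring how reciprocal similarity searches group tRNA gene
clusters such as asnT/asnU/asnV/asnW. Copy counting then queries every
sequence-distinct cluster member against every strain and unions the hit
loci. When two clusters' hit-locus sets overlap reciprocally by more than
half — the signature of one diverged family discovered under two query
identities — the cluster with fewer members is culled (ties drop the
lexicographically later id). The rule is deterministic and idempotent; it
is one defensible automation of what is necessarily a judgment call, and
it errs conservative.

Two genomic signatures distinguish duplication from transfer. A *tandem
array* is a run of two or more same-strand cluster hits with successive
gaps of at most 5 kb. For non-tandem loci, the nearest annotated feature
on each side (within 10 kb, ignoring the cluster's own annotations)
classifies the context: a phage gene on either side marks the locus
`phage_flanked`, host genes on both sides mark it `host_flanked`, anything
else is `ambiguous`. The "original" copy in a strain is identified by
synteny — the hit whose flanking host genes match the reference strain's
flanks of the query gene.

# tRNA profiling and group tests

tRNA copy number is counted at the *anticodon* level, not by gene name, so
a phage-derived tRNA pools with the native isoacceptor it reinforces; the
decoded codon is the reverse complement of the anticodon. Fold change per
anticodon is the strain count over the count in a designated
ancestral-like reference strain, with 0/0 defined as 1 and an anticodon
novel to a strain (reference count 0) flagged and reported as its absolute
count. Anticodons whose group-mean fold change exceeds 2 are tested
against the comparison group with the Mann–Whitney U test, one-sided
toward enrichment by default (the direction of the hypothesis; the
sidedness is configurable). The U test enumerates all group assignments
exactly when feasible (smaller sample at most 8 and at most $2\times 10^5$
splits, ties handled through midranks) and otherwise uses the normal
approximation with tie and continuity corrections; the exact path is
validated in the tests against `wilcox.test` and a brute-force permutation
oracle. tRNA loci come from annotations; an adapter parses tRNA-scan
tabular output instead, since scanning itself is out of scope.

# LGT gene sets and independent contrasts

Each LGT gene's gain point is placed at the most recent common ancestor of
the strains possessing it — a single-gain, no-loss model, which matches
cumulative node binning and avoids inferring losses the data cannot
support. Each tip then accumulates the gene sets of every node on its
root-to-tip path. Codon use of these nested sets is summarized as the
fraction of arginine codons encoded by AGA (the canonical rare-codon
example in enterobacteria).

To correlate codon use with tRNA copy number across strains without
pseudo-replicating shared ancestry, the package re-implements
phylogenetically independent contrasts by Felsenstein pruning: the
contrast at a node is the daughter difference scaled by
$\sqrt{b_1 + b_2}$, the ancestral value is the $1/b$-weighted average, and
the parent branch is lengthened by $b_1 b_2/(b_1+b_2)$. The correlation of
two traits' contrasts is computed through the origin with
$t = r\sqrt{d}/\sqrt{1-r^2}$ on $d = (\text{contrasts} - 1)$ degrees of
freedom. Trees without branch lengths get unit lengths (a documented,
configurable default for input trees published without lengths);
polytomies are rejected unless the caller opts into an arbitrary
zero-length resolution. The implementation is cross-checked in the tests
against `ape::pic` to machine precision, and on a star tree with equal
branch lengths the contrast correlation provably reduces to the ordinary
Pearson correlation of the tip values — an analytic limit the acceptance
checks exercise at $10^{-9}$ tolerance.

# The synthetic strain generator

Real inputs for this analysis are two dozen annotated genomes; the
generator produces strain sets with the same statistical structure and a
machine-readable truth set, so every stage is testable without downloads.
Design choices, in the generator's own terms:

* **Shared ancestry.** A root genome (host genes plus one tRNA gene per
  base anticodon, interleaved between host genes) is inherited verbatim by
  every tip. This is what makes cross-strain 95% clustering meaningful.
* **Codon model.** Genes start with ATG, end with a stop drawn from the
  stop-family frequencies, and draw internal codons by a uniform
  amino-acid choice followed by the family's relative frequencies. The
  default background profile sets the alanine family to the canonical
  *E. coli* values (GCG 0.36, GCC 0.27, GCA 0.21, GCT 0.16) and is uniform
  elsewhere; it ships as a plain-text table so genome-derived profiles can
  be dropped in. Codon bias for SGE/LGT sets multiplies chosen codons'
  frequencies and renormalizes within each family.
* **Divergence.** A copy at divergence $d\%$ receives exactly
  $\mathrm{round}(d/100 \times L)$ substitutions at uniform random sites,
  no indels. The deterministic count gives the 95/95 thresholds analytic
  expectations: 4% on a 77 bp tRNA is exactly 3 substitutions (identity
  74/77 ≈ 96.1%, detected), 6% is 5 (93.5%, excluded). Copies planted in
  the reference strain are undiverged — they are the ancestral originals
  the queries are built from.
* **Contexts.** Tandem arrays are consecutive identical copies; phage-
  flanked copies carry freshly sampled phage genes immediately on both
  sides; host-flanked copies sit between host genes. Insertion sites are
  always gaps flanked by host genes, and independently placed copies keep
  at least 6 kb apart from each other and from pre-existing copies of the
  same element, so the planted context is unambiguous and classification
  can honestly be scored against truth.
* **LGT gains.** Gene sets are sampled once per gain node and inserted
  verbatim into exactly the descending tips.
* **Self-audit.** After generation, features are recounted from the
  emitted annotations and compared with the truth set; generation fails
  loudly on any disagreement.

The default configuration — the package's reference study conditions —
has 12 strains on a two-clade tree (five pathogenic "Shigella-like" tips,
seven others including the reference), ~2,000 host genes of mean length
300 codons, three SGE families planted at insertion-sequence-like loads
(140/33/45 copies per pathogenic strain versus 1–3 elsewhere, echoing
reported IS1/IS2/IS600 loads) at 0/2/4% divergence with a 4× codon bias
toward AGA, GGA and ACA, a fourth 6%-diverged family probing the
similarity cutoff, tRNA plants for the matching anticodons (7 phage-
flanked copies at 4% divergence, a 3-copy tandem array, 2 host-flanked
copies), and five LGT gene sets with increasing AGA bias gained at nested
nodes of the pathogenic clade. These sizes keep the full analysis within
minutes on one core while leaving every statistic far from its detection
boundary.

What the generator does **not** emulate: indel evolution and
rearrangement, recombination, GC-content and amino-acid composition
heterogeneity (amino acids are drawn uniformly), realistic phage sequence
models, tRNA secondary structure, and selection. Passing tests therefore
demonstrate that the statistics recover what was planted under a clean
substitution-only model — they do not certify performance on real genomes
with segmental duplications, nested mobile elements or assembly artifacts.

# Numerical choices and degenerate inputs

* Thresholds are strict inequalities: identity or coverage of exactly 0.95
  fails, matching the ">95%" reading of the cutoffs.
* Ranking ties break lexicographically by codon, so ranks are always a
  permutation and the permutation null over 1..64 matches the statistic's
  support.
* Zero-count amino-acid families have undefined (flagged) relative usage,
  never silently 0; a codon family absent from subset and genome yields
  fold 1.
* The Welch t-test for SGE loads returns p = 1 on zero-variance groups
  with equal means (and p = 0 with unequal means) instead of erroring.
* All randomness flows from one root seed, split per stage by a fixed
  affine map into 32-bit range; reruns are byte-identical.
* The single-replicon assumption is deliberate: plasmid-borne genes are
  out of scope and chromosome-only analysis is assumed throughout.

# Known limitations

The built-in search is designed for desk-scale genomes (a few Mb); for
many large genomes an external search with the tabular adapter is the
right tool. The single-gain/no-loss LGT model mis-assigns genes that were
gained once and subsequently lost in a subclade (they appear as a later
gain). Coverage is defined over the query only, so a query contained in a
much longer repeat scores full coverage. The exact Mann–Whitney path is
limited to small groups; beyond it, the corrected normal approximation is
used. PIC p-values assume the Brownian model whose calibration the
acceptance checks verify on simulated trees; published trees without
branch lengths are handled by the unit-length convention, which changes
contrast weights and should be stated alongside any result derived from
such a tree.
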