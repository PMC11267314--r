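---
title: "kiwipan methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kiwipan methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the statistics
it computes, the parameters that matter, what the synthetic cohort does and
does not emulate, and the design choices made where the design was
genuinely open. It states no empirical result that the test suite does not
itself compute.

## 1. Pan-gene model

The unit of analysis is the orthogroup cluster: a set of genes, across `N`
haplotype assemblies, inferred to descend from one ancestral gene. From the
cluster table we build a boolean presence matrix `P[c, h]` (cluster `c` has
at least one gene in assembly `h`) alongside an integer gene-count matrix.
With `k = presence count` the classification is:

| category | rule | N = 14 band |
|----------|------|-------------|
| core     | `k == N` | 14 |
| softcore | `1 < k < N` and `k/N > softcore_fraction` (strict `>`) | 12–13 |
| cloud    | `k == 1` | 1 |
| shell    | remainder | 2–11 |

Two deliberate readings: "more than 80%" is strict, and core is decided
before softcore, so `k = N` is never softcore. Because the literature mixes
"gene" and "cluster" language when reporting compartment sizes, the summary
reports *both* cluster-level fractions (each cluster counts once) and
gene-level fractions (clusters weighted by their total gene content); the
two differ systematically because core clusters hold more genes. Per-
assembly composition is gene-level by construction: it asks what fraction
of one assembly's genes fall in clusters of each category.

Saturation curves re-ask the classification question on random prefixes of
assemblies: for an ordering and prefix size `k`, `pan(k)` counts clusters
seen so far and `core(k)` clusters present in every prefix member.
Sampling uses `n_permutations = 100` seeded orderings by default;
for `N <= 8` the code switches to exhaustive enumeration of all `N!`
orderings, which is what the tests compare the sampled estimator against.
At `k = N` both statistics are order-invariant, so their standard
deviation is exactly zero — a useful free invariant.

## 2. SV catalog

Inputs are per-haplotype SV calls in reference coordinates. Only
insertions and deletions of at least `sv_min_len = 50` bp enter the merged
catalog; inversions and translocations are parsed and counted per
accession but never merged (presence/absence semantics are only clean for
InDels) and never enter the variation graph (inversion edges need side
semantics the rest of the pipeline does not use).

Merging is a deterministic clustering with two absolute tolerances:
start-to-start distance `max_distance = 50` bp and length difference
`max_size_difference = 20` bp (absolute bp, not percent — the literal
semantics of the merging tools' flags; percent would differ detectably at
the 50 bp floor). Records are scanned in `(chrom, svtype, pos)` order and
each joins the *earliest* cluster whose representative — its leftmost
member — satisfies both tolerances, else opens a new cluster. Earliest-
match (rather than most-recent-open-cluster) is the one reading that makes
the operation idempotent: representatives can never satisfy the join rule
pairwise, so re-merging the catalog is a fixed point. The representative is
never re-centred, which keeps the operation order-invariant; permuting the
input rows cannot change the output. Cross-type merging is forbidden even
at identical coordinates: an insertion and a deletion at one locus are
distinct alleles.

The accession frequency spectrum collapses carriers haplotype → accession
first, so an SV on both haplotypes of one cultivar has frequency 1.

## 3. Genomic context and group-specific SVs

An SV's interval is `[pos, pos + length - 1]` for DEL/INV and the point
`pos` for INS (the insertion sits between `pos` and `pos + 1`). Explicit-
allele VCF deletions, whose POS convention anchors one base before the
event, are shifted on input so the same interval rule applies everywhere.

Context uses ≥ 1 bp overlap with priority `exonic > intronic > promoter >
downstream > intergenic`. The promoter is the `promoter_len = 2000` bp
immediately upstream of the annotated gene start — the ATG side,
strand-aware; UTRs are not modelled, so the annotated start is the ATG
proxy. The priority order is a design choice (reports in this field give a
single label per SV without stating one); ties within a priority level go
to the leftmost overlapping feature, then lexicographic gene id, so the
labelling is deterministic. Because it is unstated whether published
"intergenic" fractions fold promoter/downstream SVs in, a collapsed
three-way view (`collapse_context()`) is emitted alongside the five-way
split. Intergenic SVs are linked to the nearest gene on their chromosome.

A group-specific SV is either presence-specific (non-empty carrier set
entirely inside the focal group — a *proper subset* of the group
qualifies, matching the situation where only some GF haplotypes carry the
allele) or absence-specific (non-empty non-carrier set entirely inside the
focal group). Detection is symmetric under relabelling of group names.

The promoter/expression intersection restricts the catalog to SVs
polymorphic between a chosen accession pair — carried by at least one
haplotype of exactly one of the two (dominant, any-haplotype coding, which
is the right resolution when hap-level genotypes differ within a
cultivar) — keeps promoter SVs, and splits their linked genes by DE
status. DE calling itself is out of scope: real data should use a
negative-binomial GLM (DESeq2); the package ships `naive_de()`, a Welch t
on `log2(x + 1)` with the standard thresholds `|log2FC| > 1`, `p < 0.05`,
*only* so the synthetic pipeline is self-contained. It is labelled
non-equivalent and should not be used on real counts.

## 4. Hotspots

Window counts use `window = 400` kb and `step = 200` kb; an SV belongs to
every window containing its start position. Membership by POS (not span)
avoids ambiguous double counting of long deletions. The final truncated
window of each chromosome is retained and flagged rather than silently
dropped. A window qualifies when its count strictly exceeds
`min_count = 80`; overlapping or adjacent qualifying windows merge into
maximal spans. Raising the threshold can only shrink the call set
(monotonicity, tested). The threshold is applied to the merged
non-redundant catalog — whether published counts used merged or pooled
per-accession calls is unstated, and the merged catalog is the
self-consistent choice here. No significance model is attached: the
procedure is a fixed count threshold by design.

## 5. Variation graph

The graph preserves linear reference coordinates: reference nodes are
segments that tile each chromosome exactly, split at every SV breakpoint.
A deletion of `[pos, pos + len - 1]` contributes an edge from the segment
ending at `pos - 1` to the segment starting at `pos + len`; an insertion
after `pos` contributes an alternate node between its flanks. One path per
chromosome spells the reference exactly; one path per haplotype takes the
alternate branch of every SV that haplotype carries. Serialization is GFA
1.0 (S/L/P lines, `0M` overlaps) with stable node numbering (by
chromosome, then coordinate, alternates directly after their left flank).
Haplotype P-lines concatenate chromosomes in reference order, so a graph
over `C` chromosomes and `H` haplotypes has `C + H` paths.

Nested or overlapping deletions are rejected rather than modelled (no
nesting policy exists to implement faithfully), and an insertion strictly
inside a deletion carried by the same haplotype is an error listing the
conflict. The module's central test is oracle equivalence: for arbitrary
non-overlapping SV sets, every haplotype path spelled from the written GFA
must equal the string obtained by editing the reference directly.

## 6. Ka/Ks and contrasts

No Ka/Ks method is standard-by-default in this pipeline's source material,
so the classical Nei–Gojobori (1986) estimator is implemented and labelled
as such: per-codon synonymous site fractions (mutations to stop codons
count as nonsynonymous) averaged over both sequences; observed differences
in multi-difference codons averaged with equal weight over every
mutational pathway, *including* pathways that pass through a stop codon —
equal weighting is the stated convention and no stop-path exclusion is
layered on top; Jukes–Cantor correction `d = -(3/4)ln(1 - 4p/3)` applied
to both proportions, with an explicit `NA` sentinel and warning when
`p >= 3/4`. Site counts always satisfy `N + S = 3 × codons`, and the
estimator is symmetric in its arguments — both are tested invariants, and
the counting itself is tested against exhaustive enumeration.

Pairs are formed between the two haplotype copies of a gene within an
accession (clusters lacking a clean 1:1 pair are skipped with a log
entry); pre-aligned, equal-length CDS input is required and terminal stop
codons are removed before counting.

Category contrasts (CDS length, expression, Ka/Ks; core vs dispensable)
use a two-sided Mann–Whitney U: exact enumeration of all rank assignments
when both groups have at most 10 values (midranks for ties, so identical
groups give exactly p = 1), otherwise a normal approximation with tie and
continuity correction. Rank tests are invariant under monotone transforms
of the values, which is tested.

## 7. The synthetic cohort: what it emulates, and what it does not

The generator writes a complete desk-scale input bundle: 7 accessions × 2
haplotypes in three colour groups (2 RF, 3 YF, 2 GF), 3 chromosomes × 2 Mb
of i.i.d. uniform A/C/G/T backbone, 2000 orthogroup clusters with category
proportions 0.466/0.126/0.407/0.001 apportioned *exactly* by largest
remainder, ~500 SV calls per haplotype, two hotspot windows at 5× density,
one GF-exclusive 51 bp promoter deletion carried by `Biyu.hap2` and
`Jinpai.hap1` only, and a negative-binomial expression matrix (log-normal
per-gene means, dispersion 0.1, two stages × 3 replicates) whose late
stage carries a planted ≥ 4-fold increase (6× by default) of the BCM-like
gene in the GF accessions. A truth table records every planted label, and
the same seed reproduces the bundle byte-for-byte.

Choices the source material left open, fixed here once:

* **Presence counts within category bands** are uniform (softcore on
  {12, 13}, shell on {2..11}); only the band edges are given, not a
  distribution.
* **Gene geometry.** 2000 genes cannot keep ≥ 5 kb spacing inside 6 Mb, so
  genes sit on a uniform grid of ~3 kb slots (two exons, 100–300 bp
  intron, CDS 426–666 nt core / 276–456 nt dispensable — shorter than real
  kiwifruit CDS, same ordering). The slot directly upstream of the
  BCM-like gene is left geneless so the planted deletion's promoter
  context cannot collide with a neighbouring gene or flank.
* **SV carrier frequency.** The stated desk-scale defaults (500 calls per
  haplotype, 6 Mb genome, 400 kb windows, hotspot threshold > 80 on the
  merged catalog) jointly force the non-redundant locus count to roughly
  1000; carriers per locus are therefore uniform on 1..12 haplotypes
  (mean 6.5). The real-data feature that *most* SVs are private to single
  lines is **not** emulated — reproducing it at this genome size would
  push every window over the hotspot threshold. Green tests therefore
  establish correct mechanics, not a realistic frequency spectrum.
* **Within-CDS divergence** between haplotype copies uses codon-aware
  point substitutions: synonymous proposals always accepted,
  nonsynonymous accepted with probability 0.15 (core) / 0.7 (dispensable),
  stops never introduced — a crude purifying-selection knob that makes the
  dispensable-higher-Ka/Ks contrast true by construction.
* **No jitter** is added to SV breakpoints across carriers, so the merged
  catalog equals the locus truth exactly; coordinate noise in real callers
  is exercised by the merging tests, not by the generator.
* Repeat structure, recombination, SNPs, UTRs, multi-copy gene families
  and read-level data are out of scope.

## 8. Numerical and degenerate-input conventions

* Internal coordinates are uniformly 1-based inclusive; conversion happens
  only at serialization boundaries (BED is 0-based half-open on disk, VCF
  and GFF3 are 1-based).
* Symbolic DELs are written with `END = POS + |SVLEN| - 1` (the deleted
  interval itself); explicit-allele DELs are shifted by +1 on input to the
  same convention. The generator and the readers agree, keeping the system
  internally consistent; this is documented rather than hidden because
  other toolchains anchor POS one base earlier.
* Empty inputs return empty, typed results (an empty BED gets a header
  comment line; a promoter/DE intersection with no qualifying genes
  returns an explicit `empty = TRUE` flag, never a division by zero).
* All randomized procedures (saturation, the generator) take explicit
  seeds and restore the caller's RNG state.
* Translocation records carry no interval semantics beyond their position:
  they are counted per accession and otherwise ignored.

## 9. Known limitations

* The Mann–Whitney exact path enumerates `choose(n1 + n2, n1)` assignments
  and is therefore capped at group sizes of 10.
* `naive_de()` is not a DE method; it exists for synthetic data only.
* The graph does not model inversions, translocations, nested SVs, or
  genotyping of new samples; it is an interchange artifact, not an
  alignment index.
* Hotspot calls carry no significance statement — only the fixed
  threshold the procedure defines.
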