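---
title: "Methods: linking floral volatile profiles to monoterpene synthase variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking floral volatile profiles to monoterpene synthase variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scentvar)
```

# The scientific problem

Ornamental lilies vary enormously in floral scent, from faint-scented
Asiatic hybrids to the intensely fragrant Oriental types. Two kinds of data
meet in this package: GC-MS headspace measurements of the volatile
compounds a flower emits, and the coding sequences of the monoterpene
synthase (monoTPS) genes that produce key scent monoterpenes such as
(E)-β-ocimene, myrcene, α-pinene, eucalyptol and linalool from geranyl
diphosphate (GPP). The package provides a tested, reusable implementation
of the full analysis chain: quantify and classify the volatile profiles,
catalogue SNP and InDel variation in a panel of near-identical monoTPS
cDNAs, estimate within-group diversity, explain block InDels as
alternative splicing by mapping cDNAs onto the genomic locus, and rank
polymorphic sites by their gray relational association with emissions.

# Volatile quantification and aroma classification

## Internal-standard quantification

`quantify_content()` implements the standard single-point internal
standard calculation. With a known amount of 3-heptanone (or any IS)
co-analysed:

$$\text{content}_c\;(\mu g/g) \;=\;
\frac{A_c \times m_{IS} / A_{IS}}{w}$$

where $A_c$ is the compound's peak area, $m_{IS}$ the IS amount in µg,
$A_{IS}$ the IS peak area and $w$ the fresh sample weight in g. Relative
percentages are computed over the total content. Two invariances follow
directly and are property-tested: contents are linear in each compound's
area, and multiplying *every* area (IS included) by a constant changes
nothing. Compounds absent from a sample are peak area 0, not missing.

## Odor classes and group assignment

Major compounds (relative amount strictly > 10 % in at least one
accession, the conventional cutoff, exposed as a parameter) are binned
into five odor classes — herbal, fruity, cool, floral, spicy — through an
editable CSV map shipped with the package. Compounds without a mapping are
reported explicitly and contribute to no class, so the five class sums
plus the unmapped share always total 100 %.

Aroma groups (faint, cool, fruity, musky, fruity-honey, lily) are assigned
by an ordered decision list over the class percentages and the total
emission, shipped as YAML and fully configurable. The defaults were chosen
as a best fit to published lily groupings:

* faint if total < 1 µg/g;
* cool if cool ≥ 40 and fruity < 20;
* musky if cool ≥ 20 and cool + fruity ≥ 55;
* lily if herbal ≥ 20 and fruity ≥ 35;
* fruity if fruity ≥ 55, cool < 5 and herbal < 5;
* fruity-honey if fruity ≥ 40; otherwise unassigned.

The specific fruity rule is deliberately ordered *before* the broader
fruity-honey rule: ester-dominated profiles with essentially no cool or
herbal component (e.g. 87.7 % fruity) are classic fruity-scented
cultivars, and the broader rule would otherwise capture them. It must be
stressed that published group membership is **not** a pure function of the
five percentages — groups with overlapping percentage profiles exist
because sensory assessment and parentage also informed them (a cultivar
with cool = 60.6 sits in the musky group while one with cool = 66.3 is in
the cool group). The rules therefore approximate; they are configuration,
not a claim of label-exact reproduction, and no test asserts full
recovery of any published table.

# Variant calling on near-identical cDNA panels

The monoTPS cDNAs of a cultivar panel differ from a chosen group-1
reference ORF by isolated substitutions plus at most two block InDels (12
nt inserted, 114 nt deleted). Under these conditions pairwise global
alignment against the single reference is exact and much easier to verify
than a progressive multiple alignment, so the catalogue is built pairwise
and merged by normalized position and alleles.

* **Alignment** (`align_pair()`) is Needleman–Wunsch with affine gaps via
  `Biostrings::pairwiseAlignment` (match +2, mismatch −3, gap open 10,
  gap extend 0.5). The scores were chosen so a contiguous 12- or 114-nt
  InDel always stays a single gap run; for near-identical sequences the
  result is insensitive to the exact values, and the short-sequence score
  is verified against an exhaustive enumeration oracle in the tests.
* **Calling** (`call_variants()`) walks the alignment: mismatch columns
  become SNPs at reference coordinates, each contiguous gap run one
  insertion or deletion. InDels are left-normalized (5′-most equivalent
  placement, VCF-style) for reproducible positions — with one guard: a
  shift never crosses another variant called on the same sequence, since
  that representation would no longer reconstruct the query. The
  round-trip identity (`apply_variants()` rebuilds the query byte-exactly)
  is asserted over thousands of random mutated pairs.
* **Coordinates** are 1-based on the reference ORF. Under this convention
  the diagnostic 12-nt insertion of the synthetic locus lands at position
  230 (before reference base 230) and the 114-nt deletion at position 874,
  i.e. immediately after the exon-3 boundary at 873; site labels that
  quote the junction position are off by one from the first-deleted-base
  convention used here. Sites carrying the ambiguity code N are excluded
  from the catalogue and counted separately.
* **Effects** (`annotate_effect()`): SNPs are synonymous or nonsynonymous
  by codon translation under the standard genetic code; InDels are
  in-frame iff their length is divisible by 3. Every SNP receives exactly
  one of the two labels, so effect counts partition the SNP total.
* **Isoform groups** (`assign_isoform_group()`): a 12-bp insertion is the
  group-2 signature, a 114-bp deletion group-3, neither group-1; both at
  once is a conflict error rather than a silent choice.

## Motif scanning

`scan_motifs()` reports non-overlapping, leftmost matches of configurable
regular expressions for the conserved terpene-synthase motifs: `RRX8W`
(`RR.{8}W`, restricted to the first 80 residues because it is N-terminal
by definition), `RX8W` (`R.{8}W`, with hits overlapping an RRX8W match
suppressed so the tandem motif is not double-counted), `DDXXD` (`DD..D`)
and `NSE/DTE` (`[ND]D..[ST]...E`, a provisional expression — this motif
family is loosely conserved and no canonical regex exists). When RRX8W is
found after residue 1, the upstream region is reported as the putative
plastid transit peptide.

# Diversity statistics

For a within-group panel of equal-length sequences,
`nucleotide_diversity()` computes π as the mean over all unordered pairs
of per-site differences; `haplotype_diversity()` uses the unbiased
estimator $\widehat{Hd} = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$ on
exact-string haplotype classes, which equals 1 exactly for a two-member
panel of distinct sequences; `segregating_sites()` counts columns with at
least two distinct non-missing bases. Missing data (gaps, N) are handled
by pairwise deletion by default — each pair is compared over its mutually
valid sites, which uses the most data — with complete deletion available
by flag; the policy is recorded in the output because the two can differ
and published tables rarely state which was used. Group-defining block
InDels are removed before within-group column statistics by analysing
groups separately (group members share the InDel, so within a group the
sequences are directly comparable). Summary tables conventionally print π
to 3 decimals and Hd to 2; machine output keeps full precision.

# Splice mapping

`map_cdna()` infers exon/intron structure by a sim4-style heuristic that
is fully testable at single-gene scale: exact k-mer anchoring of the cDNA
on the genomic sequence (default k = 15), merging anchors on a common
diagonal into maximal exact segments, selecting the collinear chain that
maximizes cDNA coverage, and closing junctions exactly. Adjacent exons may
share up to k − 1 anchored bases at an ambiguous junction; the overlap is
trimmed and re-resolved. Where the boundary can slide without changing the
spliced product, all equivalent placements are enumerated and the one
giving a GT donor **and** AG acceptor is preferred, then the 5′-most —
deterministic by construction. Introns shorter than `min_intron` (default
40 nt) are rejected rather than misreported, and up to `max_mismatch`
(default 2) substitutions per exon are tolerated during gap closure. The
exon-concatenation identity (splicing the gDNA by the returned model
reproduces the cDNA) is asserted inside the function whenever no
mismatches were used. Coordinates are 1-based inclusive on the forward
strand; reverse-strand input must be reverse-complemented by the caller.

`compare_isoforms()` classifies per-intron differences against the
canonical model: moved donor → alternative 5′ site, moved acceptor →
alternative 3′ site, plus exon skipping and intron retention for
unequal intron counts. `delta_nt` is the exonic gain (+) or loss (−) of
the query, so the alt-5′ isoform of the default locus reports +12 at
intron 1 and the alt-3′ isoform −114 at intron 3, and swapping the
arguments negates the sign.

# Gray relational association

Deng's gray relational analysis ranks polymorphic sites by similarity of
their incidence pattern to each compound's emission pattern across
cultivars. Each series is min-max normalized — the only normalization that
makes binary 0/1 incidence vectors commensurate with continuous emissions;
mean normalization is available by flag for sensitivity analysis because
the preprocessing used by legacy GRA software is typically unstated and
GRD magnitudes shift with it. With deviations
$\Delta_i(k) = |x_0'(k) - x_i'(k)|$ and global extrema over all series and
points, the relational coefficient is

$$\xi_i(k) = \frac{\Delta_{\min} + \rho\,\Delta_{\max}}
                  {\Delta_i(k) + \rho\,\Delta_{\max}}$$

and the gray relational degree is the mean coefficient. ρ defaults to
Deng's conventional 0.5 and is exposed. Properties tested: GRD ∈ (0, 1];
GRD of a series with itself is exactly 1 (the degenerate all-identical
case is handled explicitly); invariance under positive affine transforms
of any series; monotone non-decreasing in ρ. Note that Δ extrema are taken
jointly over the whole comparison set, so a site's GRD depends on which
other sites are analysed — this matches the classical formulation. The
compound vector is the reference series and site vectors are comparisons.
Constant columns carry no relational information and are excluded with a
message; cultivars lacking either sequence or emission records are dropped
listwise with a logged count.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated, echoing the real system's dimensions: a 2661-nt locus of 7
exons (229, 270, 374, 240, 280, 200, 168 nt) and 6 GT-AG introns (150,
160, 170, 140, 140, 140 nt); a 1761-nt canonical ORF encoding 586
residues; an alternative 5′ donor in intron 1 retaining 12 nt (so the
insertion lands at ORF position 230 and the alt isoform encodes 590
residues) and an alternative 3′ acceptor in intron 3 removing 114 nt
(positions 874–987; 548 residues). Exon 1 ends at 229 and exons 1–3 sum
to 873 precisely so these diagnostic coordinates arise. Both offsets are
frame preserving and both alternative splice sites are themselves GT-AG:
intron 1 carries a second GT donor after its retained prefix, and the
removed exonic block ends in AG.

Random codons are drawn from the 60 sense codons excluding tryptophan, so
W occurs only where motifs are planted: RRX8W at residues 25–35 (with a
transit-like region upstream), RX8W inside the alternatively spliced
region (residues 295–304, hence deterministically lost in the alt-3′
protein, mirroring the biology of the deletion isoform), DDXXD and
NSE/DTE downstream of it. The retained intron prefix is regenerated
deterministically (bounded retries) if it would introduce an in-frame
stop.

Cultivar panels (default n = 23, the size of a typical
sequence-plus-emission association panel) apply independent per-site
substitutions (default 0.005/site, uniform among the three alternatives,
chosen to land π near 0.010, the magnitude reported for such panels; no
back-mutation modelling is needed at this rate), and InDel carriers
(default frequency 0.3) express the alt-5′ isoform. Emissions are
baseline + effect × genotype + Gaussian noise truncated at zero, with a
3 µg/g effect against 1 µg/g noise (a 3σ effect) on (E)-β-ocimene by
default; peak areas are back-computed so quantification inverts exactly.
All randomness flows from a single explicit seed; identical seed and
configuration give byte-identical fixtures.

What the generator does **not** emulate: GC-MS noise structure
(co-elution, baseline drift, detector saturation), linkage between sites,
population structure, paralogy (the three transcript types are true splice
variants of one locus here, whereas real data could contain recent
paralogs), and realistic site-frequency spectra. Green tests therefore
demonstrate algorithmic correctness under controlled conditions, not
robustness to every artefact of real chromatograms or cloning.

# Numerical and design choices

* Problem sizes in the test-suite: round-trip checks use 1000 random
  120-nt pairs; diversity oracle checks use panels of n ≤ 10; the
  simulated-π calibration uses 200 replicates of 6 × 1761 nt panels; GRA
  recovery uses 100 stochastic replicates of the default panel. These
  sizes make every oracle exhaustive or near-exhaustive while keeping the
  whole suite to a few minutes.
* Alignment tie-breaks follow the deterministic internal rule of
  `Biostrings::pairwiseAlignment`; for the near-identical sequences this
  tool targets, the optimal alignment is unique except for InDel
  placement, which left-normalization standardizes anyway.
* Degenerate inputs are rejected loudly, not patched: empty panels,
  constant GRA series, non-positive internal-standard fields, unmappable
  cDNAs, conflicting isoform signatures and malformed rule or motif
  configurations all raise errors naming the offending field.
* `run_pipeline()` is the orchestration surface (simulate → quantify →
  classify → callvars → diversity → splice → gra) with stage gating,
  per-stage outputs written before the next stage reads them, and
  validation before any stage runs. Re-running with unchanged inputs and
  seed reproduces byte-identical outputs.

# Known limitations

* The aroma decision list cannot reproduce published group labels exactly
  (see above); it is a documented approximation.
* The splice mapper is a single-gene tool: no genome-scale indexing, no
  splice-graph assembly, no branch-point or polypyrimidine modelling, and
  reverse-strand handling is the caller's responsibility.
* GRA provides ranking, not inference: no permutation p-values, no
  population-structure correction, and GRD magnitudes depend on the
  normalization and on the comparison set.
* The NSE/DTE motif expression is provisional; edit
  `default_motif_patterns()` for stricter definitions.
* Nucleotide diversity assumes equal-length within-group sequences;
  cross-group comparisons must handle the block InDels explicitly.
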