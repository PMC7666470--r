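---
title: "Detecting non-reference insertion variants from paired-end reads: methods and design"
author: "InsertionTracer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting non-reference insertion variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Insertions longer than 50 bp that are absent from a reference genome are the
hardest class of structural variant to detect from short reads: reads that
originate inside the inserted sequence have nowhere to align, so standard
reference-based callers never see them directly. What the aligner does leave
behind is a characteristic shadow at the insertion site — read pairs in
which one end is confidently anchored to the reference flank while the other
end is unmapped or placed discordantly. InsertionTracer turns that shadow
into sequence-resolved, genotyped insertion calls in three stages: local
assembly of the discordant evidence into breakpoint-spanning contigs
(*discovery*), inference of the complete inserted sequence from additional
genomes (*tracing*), and per-sample biallelic genotyping by dual-allele
realignment (*genotyping*). A self-contained simulator reproduces the
benchmark protocol used to validate the approach, and small population
summaries (allele frequencies, per-individual inserted-sequence load, Nei
pairwise $F_{ST}$) operate on the genotyped calls.

# Discovery

**Evidence selection.** From a BAM file, `extractDiscordantPers()` keeps
every pair with one mapped end of MAPQ $\ge$ 20 (`min_mapq`) whose mate is
unmapped or discordantly placed: different chromosome, non-FR orientation,
or outer insert beyond $\mu + 3\sigma$ of the library insert distribution
(estimated by `estimateLibraryStats()` from properly paired reads). Two
points matter in practice:

* The insert-size rule is applied directly to TLEN rather than through the
  aligner's proper-pair flag. Aligners accept a wider insert window than
  $\mu + 3\sigma$; relying on their flag silently discards the
  junction-spanning pairs of insertions of roughly 1.5–2.5 read lengths,
  whose apparent insert is only moderately inflated.
* When both ends of a discordant pair are well mapped, both are emitted as
  anchors, so each involved locus sees the evidence.

**Clustering and strand-specific assembly.** Anchors are clustered by
(chromosome, strand) with single-linkage over start positions at link
distance $\mu + 2\sigma$ (`cluster_sd_window`); clusters under `min_support`
(3) pairs are dropped. For one cluster, anchored reads (already
reference-oriented) and mates (rotated into the anchor's reference frame
using the FR layout) are assembled with an in-package De Bruijn assembler:
$k = 31$, k-mers below coverage 2 removed, dead-end tips shorter than $2k$
at branch points pruned, maximal unbranched paths emitted as contigs, and
every read re-placed onto the contigs by exact-seed, mismatch-tolerant
alignment. Plus-strand clusters assemble the left flank plus the start of
the insertion; minus-strand clusters the end of the insertion plus the right
flank. A contig is accepted only if its read placements tile it in a single
chain with no unsupported gap longer than a read (`validateContig()`), which
rejects chimeric joins. Contigs are tried in decreasing read support, and if
no contig of a cluster yields a tag the cluster is re-assembled at fallback
k-mer sizes (25, 21) — smaller k restores junction connectivity in sparse
clusters. At most one tag is kept per cluster.

**Breakpoint refinement.** `refineBreakpoint()` anchors the contig in the
local reference by exact k-mer seeds and runs a banded affine-gap prefix
(left side) or suffix (right side) alignment; the split maximizing the
reference-matching flank (match +1, mismatch −4, gap −6/−1; flank mismatch
fraction $\le$ 2%) defines the tag: flank sequence, breakpoint coordinate,
and partial inserted sequence. Ties favor the longer flank. Minimum flank is
30 bp and minimum insertion part 10 bp; contigs aligning fully to the
reference yield no tag.

**Pairing and breakpoint microhomology.** Left- and right-flank tags on the
same chromosome are matched one-to-one, greedily by absolute breakpoint gap,
within $\mu + 2\sigma$. When the inserted sequence shares bases with the
reference at the junction (microhomology), the insertion point is not a
single coordinate but a run of equivalent representations; the maximal-flank
rule pushes the left tag to the right end of that run and the right tag to
the left end, so true pairs frequently have a small *negative* gap
(right − left $= -(h_1 + h_2)$, about 45% of junctions on random sequence).
The pairing window therefore extends down to −`max_microhomology` (100 bp);
demanding a non-negative gap would discard almost half of all true events.
For the same reason, simulated-truth scoring compares each reported
breakpoint with the matching canonical end of the truth's ambiguity run
(`posLeft`/`posRight` recorded by `implantInsertions()`), and the traced
catalogue stores the left-normalized representation (the VCF indel
convention), so exact comparisons are well defined.

# Tracing

A paired tag bounds the insertion but contains only its outer parts. For
each target genome, `locateSyntenicRegion()` places 500 bp reference flanks
(`trace_flank_len`) by exact 31-mer seeding plus a diagonal identity check,
on both strands, requiring a unique best locus (best score $\ge 1.2\times$
the runner-up). The target sequence between the inner flank ends is the
candidate full insertion; it is accepted when each partial inserted sequence
aligns to its corresponding candidate end at $\ge$ 90% identity
(`trace_identity`). Candidates from several genomes are compared by
all-pairs global alignment (`checkConcordance()`, Biostrings); the set is
concordant when every pair reaches 90% identity over the shorter sequence,
and the consensus is the candidate with the highest mean identity (ties:
longer sequence, then lexicographic genome name). Traceable insertions are
capped at 100 kbp.

The target's declared class drives the ancestral interpretation: a trace
into a non-human-primate genome means the sequence predates the human
lineage and the reference carries a deletion of ancestral sequence
(*retention of ancestral sequence*); traces found only in other human
assemblies or unmapped-contig databases indicate a *novel insertion*; no
accepted trace leaves the event *untraced*. Untraced events are dropped from
the catalogue by default — tracing doubles as the confirmation filter for
tag pairs that do not come from a single allele.

The flank localizer assumes substitution-style divergence between reference
and target flanks; strongly rearranged or indel-rich flank orthologs will
fail the diagonal identity check and the event stays untraced rather than
being mis-traced.

# Genotyping

For every sequence-resolved variant longer than both the read length and
100 bp, two alleles are built: the local reference spanning the breakpoint
and the same sequence with the insertion placed at the breakpoint, each with
`read_length + 50` bp of flank. The published description extends flanks by
50 bp only, but a read cannot support an allele it cannot span; the 50 bp
figure survives here as the junction-overlap requirement instead. Each
fetched read (including unmapped mates placed at the site by the aligner) is
aligned to both alleles in both orientations (seeded diagonal scoring with a
full Smith-Waterman fallback). A read counts for an allele when it wins by
$\ge$ `score_margin` (5) *and* its alignment spans an allele-distinguishing
junction with $\ge$ `min_overlap` (10) bp on each side: the breakpoint for
the reference allele, either flank–insertion boundary for the insertion
allele. Reads lying entirely inside the insertion are deliberately not
counted — otherwise the alt depth grows with insertion length and
heterozygotes drift past the homozygous threshold. The insertion allele
still presents two junctions against the reference allele's one, a mild
alt-ward bias of the heterozygote ratio (expected $\approx 2/3$) that the
default thresholds absorb; it is the package-level analogue of the
homozygosity-favoring behavior expected of ratio-based genotypers.

The genotype is the thresholded read-depth ratio
$r = n_{alt}/(n_{ref}+n_{alt})$: $r \le 0.2 \rightarrow$ 0/0,
$r \ge 0.8 \rightarrow$ 1/1, otherwise 0/1; fewer than `min_depth` (4)
informative reads give `./.`. Counts are individual reads, not pairs.

# Mechanism classification

Breakpoint sequence features assign each variant one mechanism through a
fixed priority cascade — VNTR, then NAHR, then TE, then NH:

* **VNTR**: some period $p \ge 2$ explains $\ge$ 85% of the inserted
  sequence (positions consistent with $s_i = s_{i-p}$), and the leading
  $p$-mer also occurs in the 100 bp breakpoint flanks (within 10%
  mismatches) — the signature of an expanded local tandem array. The
  smallest qualifying period is reported.
* **NAHR**: the two 100 bp flanks share a local alignment of $\ge$ 50 bp at
  $\ge$ 90% identity.
* **TE**: strictly more than 80% of the inserted sequence is covered by the
  union of retroelement annotation intervals; the majority family is
  reported. Annotation is an input interface (RepeatMasker-style intervals);
  a lightweight exact-k-mer annotator over the built-in synthetic repeat
  library ships for simulated data and tests — it is a toy stand-in by
  construction, not a general repeat annotator.
* **NH**: no recognizable feature.

The 85% VNTR coverage and 50 bp NAHR homology floors are explicit package
choices in the breakpoint-feature tradition; only the "more than 80%" TE
fraction is fixed by the method being reproduced.

# The simulator and what it does (not) capture

`generateSyntheticGenome()` builds an i.i.d. background at GC 0.41 with
diverged copies (5% substitutions per copy) of a fixed synthetic repeat
library (SINE-, LINE-, SVA-like elements and a satellite monomer) covering
20% of the sequence; the library is shared between genomes, so donor
segments implanted into an acceptor carry repeats the acceptor also has.
`implantInsertions()` draws log-uniform segment sizes (all scales get
exercised at desk size) and places them uniformly, non-overlapping, at least
2 kbp apart and away from the ends. `simulatePers()` produces FR pairs at
Poisson-uniform fragment starts, normal insert lengths and a flat
substitution error rate, deterministically per seed. Mapping goes through a
thin bwa/samtools adapter; any aligner producing sorted BAM can be
substituted.

The benchmark protocol maps one read set twice: against the acceptor alone
("unique" insertions — the implanted sequence is absent from the mapping
reference) and against acceptor plus donor ("non-unique" — reads from
implants can also map to their donor locus). At the package's benchmark
scale (5 Mbp genomes, 100 implants of 100 bp–20 kbp, 30×, 2×100 bp,
insert 350±50, 0.2% errors) the unique run reaches ~86% sensitivity at 0%
FDR and the non-unique run ~97% at ~1% FDR.

Two honest caveats. First, on real repeat landscapes the non-unique
configuration is the harder one, because implant-derived reads multi-map
within large repeat families; with a small synthetic library at 5% per-copy
divergence, reads map uniquely, and including the donor *helps*: junction
reads align full-length to the donor locus and re-enter the insertion-site
cluster as well-mapped discordant mates, whereas in the unique run the same
reads are low-MAPQ clipped anchors (excluded by the MAPQ filter) or
unmapped. The unique $\ge$ non-unique sensitivity ordering reported for
real-chromosome simulations therefore inverts here, and the corresponding
acceptance check is expected to fail under these study conditions; the
absolute sensitivities and FDRs are unaffected. Second, misses in the
unique run concentrate where the method is genuinely blind: implants under
~250 bp whose apparent insert stays inside $\mu + 3\sigma$ (their junction
pairs look concordant), and junctions whose flank falls inside a repeat copy
(junction anchors drop below MAPQ 20). Passing the simulation says nothing
about indel sequencing errors, coverage inhomogeneity, or repeat families
diverse beyond the toy library — none of which the generator models.

# Numerical choices and degenerate inputs

* Alignment scores everywhere: match +1, mismatch −4, gap open −6,
  extension −1; banded split alignment uses half-width 16.
* Clustering and pairing windows derive from the library estimate; a
  zero-variance library (all inserts identical) is handled exactly.
* `estimateLibraryStats()` is record-order invariant (finite subsampling
  uses sorted, evenly spaced inserts) and errors below 100 proper pairs.
* Empty inputs (no discordant pairs, empty clusters, empty catalogue) yield
  empty, typed results rather than errors; variants near contig ends are
  skipped with a reason at genotyping; truncated mechanism flanks are
  flagged.
* Tag pairing ties (equal absolute gap) resolve by position; concordance
  ties by length then genome name; VNTR reports the smallest qualifying
  period — every tie-break is deterministic, and pipeline outputs carry no
  timestamps, so identical inputs give identical files.
* Problem sizes used by the shipped test suite: the benchmark above (once,
  shared across checks), a 2 Mbp error-free run for breakpoint precision,
  200 tracing round-trip implants of 60 bp–10 kbp, and a 100-variant ×
  50-sample genotyping panel over allele frequencies 0.1–0.9 at 30× with a
  2× low-coverage arm.

# Limitations

Discovery requires junction-spanning or insertion-interior read evidence;
insertions much shorter than the insert-size tail are invisible by design.
Tracing requires the full inserted sequence to exist contiguously in some
target genome at ≥90% identity; partially represented or highly diverged
insertions stay untraced. Genotyping is ratio-based (no genotype
likelihoods) and biallelic only. The mechanism detectors are deliberately
simple sequence features, not evolutionary reconstructions. Deletions,
inversions, translocations and mobile-element-specific split-read logic are
out of scope.
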