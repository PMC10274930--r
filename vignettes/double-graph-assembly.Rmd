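---
title: "Double-graph hybrid assembly: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Double-graph hybrid assembly: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Accurate long reads (HiFi-grade, ~99.9%+ identity after correction) support
base-level all-vs-all overlapping and therefore a *string graph*: nodes are
reads, edges are suffix-prefix ("dovetail") overlaps, and maximal
non-branching paths collapse into unitigs. But accurate reads are often not
long enough to span long exact repeats, so the graph tangles at repeats and
the assembly fragments. Ultra-long nanopore reads are 5-10 times longer and
span those repeats, but their error rate makes direct all-vs-all overlapping
unreliable, and recurrent errors make overlaps in difficult regions nearly
impossible to call at base level.

duograph implements the double-graph answer to this tension:

1. **Backbone.** Build the string graph from accurate reads only
   (`findReadOverlaps()`, `buildStringGraph()`, `transitiveReduction()`,
   `cleanGraph()`, `makeUnitigs()`). Contained reads — reads whose span is
   entirely covered by a longer read — are *kept provisionally* instead of
   being removed as in the classic construction.
2. **Integer space.** Align every ultra-long read to the unitig graph
   (`alignUL()`) and keep only the ordered list of oriented unitig
   identifiers it traverses (`encodeInteger()`). An ultra-long read of tens
   of kilobases becomes a sequence of tens of integers, and its base-level
   errors are gone: the projection *is* the error correction.
3. **Second graph.** Build a string graph over those integer sequences with
   *exact* overlaps only (`integerOverlaps()`, `buildIntegerGraph()`),
   clean it aggressively (`aggressiveClean()`) and emit integer contigs —
   non-branching paths much longer than any single ultra-long read
   (`integerContigs()`).
4. **Incorporation.** Remove from the backbone every unitig that appears in
   an integer contig, add the contigs as nodes, and reconnect boundary edges
   (`incorporateContigs()`). A homozygous unitig used by several contigs
   backs several nodes of the final graph.
5. **Phasing.** Count haplotype-specific marker k-mers on every node
   (`buildMarkers()`, `assignMarkers()`) and emit one assembly per
   haplotype by graph binning (`graphBinning()`): nodes dominated by another
   haplotype's markers are deleted, unlabeled (homozygous) nodes are kept in
   every emission, and the surviving non-branching paths are spelled into
   contigs. Ploidy 2 and higher use the same rule.

Ultra-long information feeds back into the backbone twice. First, a
contained read is *critical* when ultra-long chains must traverse it (at
least `minRescue` chains cover its placement); all other contained reads are
removed and the graph re-unitigged (`rescueContained()`). This prevents the
haplotype breakpoints that blanket contained-read removal causes in repeats
and inter-haplotype homologous regions. Second, every unitig edge carries
the number of distinct ultra-long reads whose integer sequence uses it
(`computeEdgeSupport()`); at ambiguous branch points, supported edges
survive and zero-support competitors are cut, with the classic
longest-overlap heuristic only as a fallback when no edge is supported
(`weightedClean()`).

# The simulator and what it stands in for

All experiments run on simulated data with full ground truth
(`simGenomeSpec()`, `simulateGenome()`, `simulateReads()`):

* Haplotypes derive from one ancestral sequence per chromosome. SNV loci
  are placed at `hetRate` per bp; each locus substitutes a base on exactly
  one haplotype, so every locus is informative and, in polyploids, each
  locus marks exactly one haplotype (emulating genetic-map-derived
  per-haplotype marker sources; parental k-mer databases are emulated by
  handing the marker builder each haplotype's truth sequence).
* Repeat elements are stamped as exact copies; repeat and telomere
  intervals are excluded from SNV placement so copies stay identical across
  loci and haplotypes. A single-locus "repeat" doubles as a homozygous
  block.
* Reads have normal lengths floored at `minLen`, uniform starts (reads
  overhanging a chromosome end are clipped, keeping terminal coverage
  flat), uniform strands, and substitution-only errors. Accurate reads
  default to zero errors: upstream base-level error correction is assumed,
  not reimplemented, and the overlap machinery is exact-match centred
  accordingly.

The simulator deliberately omits indels, realistic nanopore error
profiles, structural variants and sequencing bias. Passing tests therefore
demonstrate the *graph-algorithmic* claims — contained-read rescue,
support-weighted cleaning, integer-space assembly, polyploid binning — not
robustness to real error processes. The ultra-long aligner tolerates
substitutions (anchors simply thin out) but has no indel band, which is the
main gap between this implementation and a production assembler.

# Study conditions

The flagship diploid condition (`defaultConfig()`) is a 2 x 500 kb
chromosome with a 30 kb exact repeat stamped at two loci, heterozygosity
0.002/bp, telomere arrays of 300 bp, accurate reads of mean 15 kb (minimum
5 kb) at 10-fold per haplotype and ultra-long reads of mean 80 kb at
15-fold with a 40 kb floor — the desk-scale analogue of the conventional
"ultra-long means at least 50 kb" input filter, with every length scaled to
keep one run in minutes on one CPU. Phasing checks add a 2 x 200 kb diploid
and a 4 x 100 kb tetraploid (0.006/bp, so ~150 marker loci per haplotype);
the contained-read fixture (`ulRepeatFixture()`) is a 32 kb diploid with
a 4 kb double-locus repeat and a 3 kb homozygous block. Oracle equivalence
suites use 8-12 reads of 0.5-1.2 kb or a dozen integer sequences per
instance, one hundred random instances per operation.

# Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| `k` / `minOvlp` / `maxDiv` | 21 / 250 bp / 0.02 | overlap seeding and reporting. `minOvlp >> k` suppresses spurious seeds; the query stride `(minOvlp-k+1)/2` guarantees a seed inside any true overlap. |
| `maxEdgeDiv` | 0 | only perfect overlaps become graph edges. With corrected-grade reads, any mismatch marks a haplotype or repeat-copy difference, so divergent overlaps must not join nodes. |
| `minEdgeOvlp` | 0.3 x accurate mean | edges additionally require a substantial overlap. A perfect cross-haplotype overlap must fit inside an SNV-free window and is therefore short, while within-haplotype neighbours overlap by most of a read; the threshold removes haplotype-bridging braids that would otherwise let transitive reduction stitch mosaic (allele-switching) chains. A read end whose overlaps all fall short keeps its single longest overlap, so a local coverage dip can thin branches but never disconnect the backbone. |
| `fuzz` | 10 bp | transitive reduction length tolerance; near-exact for error-free data. The removal set is defined against the input edge set, making it order-independent. |
| `tipLen`, `minEdgeReads` | error-model dependent | tips and weak bubble branches are *error artifacts*. With error-free accurate reads they are real sequence (for example the other haplotype's chromosome-end stub), so the pipeline disables both cleanups at `errorRate = 0` and uses 3 x mean read length / 2 reads otherwise. |
| `alignK`, `alignW` | 17 / 11 | ultra-long minimizer anchoring. Unitigs are indexed at *every* k-mer while reads are minimizer-sketched: anchor counts over identical sequences are then exactly equal whatever the unitig boundaries, so equivalent routes tie exactly and fall through to the deterministic tie-break (fewer nodes, then longer nodes, then smaller id) instead of being decided by boundary noise. |
| `maxGap`, `gapSlack` | 2000 bp / `k + w` | chain transitions across an edge must agree between read and graph within `maxGap`; discrepancies below `gapSlack` are within anchor resolution and carry no penalty, for the same tie-exactness reason. |
| `minUniqueTerm` | 3 | a chain keeps a terminal element only when it is anchored by at least this many uniquely-placed k-mers. A read may end inside a repeat, where any choice among copies is arbitrary; trimming leaves repeat traversal to the reads that reach unique sequence on both sides. |
| `minRescue` | 2 | chains that must cover a contained read's placement before it counts as critical, with a 30 bp slack for anchor resolution. |
| `minSupport` | 1 | edge support threshold for weighted cleaning; supports count distinct reads, never chain multiplicity. |
| `minIov` | 1 element | minimum exact integer overlap. Unitigs are long, so a single shared oriented unitig is already highly specific; the aggressive best-edge-per-side rule absorbs the residual ambiguity. |
| `tipNodes` | 2 | integer-space tip length (nodes). |
| `markerK`, `minMarkers`, `domRatio` | 31 / 2 / 2.0 | marker k-mer size and the dominance rule: a node is assigned to a haplotype only with at least 2 of its markers and a two-fold advantage over the runner-up, so sparse or conflicted nodes stay unlabeled and are emitted with every haplotype, mirroring homozygous-node handling. |
| `minContigLen` | 5 kb | reporting filter, the scaled analogue of the conventional 500 kb contig filter. |

# Numerical and degenerate-input choices

* All coordinates are 0-based half-open internally; PAF/GFA conventions are
  honoured at the boundary. N bases mismatch everything, including N.
* Overlap placements are gapless full-diagonal comparisons (exact under the
  substitution-only model); every placement of a pair is reported, the
  longest per pair (ties: smaller start, same strand first) becomes the
  edge. Mutual containments keep the earlier read as container.
* Equal-score chain routes resolve by fewer nodes, then longer nodes, then
  smaller id — which is also what lets a chain skip a redundant contained
  node in favour of its container.
* After weighted cleaning the pipeline re-aligns the ultra-long reads to
  the merged unitigs rather than remapping old chains: chains over merged
  nodes have fewer junctions and no stale adjacencies.
  (`remapIntegerSeqs()` remains available and splits any sequence whose
  adjacency was cut.)
* Integer contigs are emitted in canonical orientation (lexicographically
  smaller of the contig and its reverse, ordering elements by unitig id
  with forward before reverse). Emissions drop contigs whose sequence is an
  exact substring of a longer contig — residual stubs an incorporated
  contig already spells out.
* Empty inputs degrade gracefully: no ultra-long reads means every
  contained read is removable, all supports are zero, and incorporation of
  an empty contig set reproduces the backbone — the accurate-only baseline
  (`hifiOnly = TRUE`) is exactly this path.

# Open design points, decided here

The contained-read literature does not specify how provisionally-kept
contained nodes are wired: here they simply keep their genuine dovetail
overlaps, because any dovetail implied by an exact containment placement is
itself a reported overlap — no synthetic edge construction is needed. The
criticality test is coverage-counting (`minRescue` covering chains) rather
than junction-essentiality, matching the worked example where two covering
chains retain the critical read. "Aggressive" integer-space cleaning is
realised as the strict best-edge-per-side rule, justified by ultra-long
reads being long enough to walk through repetitive and homozygous regions.
Arbitration of nodes carrying several haplotypes' markers uses the
dominance rule above; anything short of dominance is treated as homozygous
rather than discarded.

# Known limitations

Indel-free alignment only; no Hi-C phasing (trio/per-haplotype marker
sources cover the binning logic); no consensus polishing (unitig spelling
is concatenation, exact only for error-free input); no scaffolding; graph
binning emits unlabeled nodes into every haplotype, which double-counts
long homozygous regions in assembly-length totals, as expected for this
strategy. Evaluation's exact-tiling coverage is meaningful only for
error-free simulations; use the k-mer mode otherwise.
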