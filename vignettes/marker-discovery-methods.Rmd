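---
title: "Methods: avian fecal marker discovery and assay evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: avian fecal marker discovery and assay evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avimark)
```

## The problem

Microbial source tracking (MST) asks where fecal contamination in
environmental water comes from. The approach implemented here targets the
bacterial 16S rRNA gene: fecal bacterial communities differ between host
species, so a short sequence carried only by bacteria of one host group
can serve as a qPCR marker for that host's feces. Avian hosts are a hard
case — domestic and wild birds share habitats and exchange flora — which
puts a premium on verifying both *exclusivity* (the candidate occurs in
only one host group's reads) and *uniqueness* (no near-identical sequence
exists in fecal bacteria of other hosts).

`avimark` implements the full discovery chain as reusable components:

1. **`refdb`** — build a host-annotated fecal 16S reference database from
   GenBank flat files.
2. **`seqsearch`** — k-mer seeded local alignment search with
   Karlin–Altschul E-values, and CD-HIT-style greedy identity clustering.
3. **`otu_select`** — pick OTUs from grouped amplicon reads, select
   group-exclusive ones, verify exclusivity by similarity search.
4. **`unique_finder`** — for each candidate, gather database homologs,
   reduce redundancy, build a query-anchored trimmed alignment, and scan
   18-nt sliding windows for host-unique stretches.
5. **`assay_eval`** — qPCR standard curves, amplification efficiency,
   LOD, sensitivity/specificity, and marker quantity profiles.
6. **`synthdata`** — seeded generators for every input, with ground truth.

## Reference database construction

`filter_fecal()` keeps a GenBank record iff (a) its `isolation_source`
qualifier contains one of *feces, fecal, faeces, faecal, stool* —
case-insensitive **substring** matching, the permissive, recall-oriented
reading, so "fecal swab" and "human stool" both pass; (b) the source
organism is not viral or vertebrate; and (c) a host is clearly indicated.
Rules are tested in that fixed order and each rejected record is tallied
under the first failing rule, so filter reports are deterministic.

Organism classification against a live taxonomy is an external resource,
so the viral/vertebrate test is a pluggable predicate with a shipped
word-list default (`default_taxon_exclude()`); users with taxonomy access
can supply any `function(organism) logical`. Host common names are
corrected to binomials by exact-token lookup (`normalize_host()`, e.g.
swine → *Sus scrofa*, dog → *Canis lupus*); names that cannot be resolved
are reported as unresolved, never guessed, and do not fail the record —
the host rule requires a host to be *stated*, while normalization is a
correction. IUPAC ambiguity codes are retained in sequences; the search
layer scores any non-ACGT symbol as a mismatch.

## Search layer

The search core is a seed-and-extend local aligner: exact k-mers shared
between query and subject (default k = 11 for database search, k = 8 for
short-read verification) are grouped along diagonals, and candidate
subjects are aligned by banded affine-gap Smith–Waterman (match +1,
mismatch −2, gap open −5, gap extend −2; a gap of length L costs
`-5 - 2L`). These defaults approximate megablast-like stringency and are
configurable. Queries are searched on both strands by also aligning the
reverse complement; coordinates are always reported on the subject's
forward strand, 0-based half-open (a documented divergence from BLAST's
1-based closed convention).

E-values follow `E = K·m·n·exp(-λS)` with `m` the query length and `n`
the total database length. λ is found by solving the moment condition
`Σ p_s e^{λs} = 1` numerically, H is the relative entropy, and K is
computed by the standard partial-sum convolution series on the score
lattice; for the default scoring this yields λ = 1.3327, K = 0.621,
H = 1.124. The ungapped parameters are reused for gapped scores — the
usual practical approximation; gapped parameter estimation by simulation
is out of scope, and users may supply their own (λ, K).

**Exactness.** `local_search()` has three modes. In `"exhaustive"` mode
every subject is aligned with full (unbanded) Smith–Waterman, which is
exact. In `"seeded"` mode only subjects with at least one seed are
aligned, within a padded diagonal band spanning the diagonals supported
by at least two seeds (single-seed diagonals — typically chance k-mer
repeats — would widen the band enormously; when no diagonal has two
seeds, the best-supported one is kept). This is the standard heuristic
trade-off: alignments whose identity is too scattered to contain
chained exact k-mers can be missed, exactly as in seeded search tools
generally.
The default `"auto"` mode runs exhaustively while the total DP-cell
count is small (≤ 4×10⁶) and switches to seeding beyond that, so
amplicon-scale problems are solved exactly and large databases remain
tractable.

Greedy clustering follows the CD-HIT recipe: sequences sorted by
decreasing length (ties by id), each joining the first existing cluster
whose representative it matches at or above the identity threshold, else
founding a new cluster. Identity is the number of identical aligned bases
divided by the length of the **shorter** sequence (CD-HIT's convention),
computed from an ends-free global alignment. Representatives are
therefore always a longest member. The memory/thread flags of the
original tools carry no algorithmic content and have no equivalent here.

## OTU selection and exclusivity

Reads from all groups are pooled and clustered at 97% identity (the
usual species-level proxy; 95% and 80% approximate genus and family).
An OTU is **table-exclusive** iff exactly one group has a positive count
and that count reaches `min_reads` (default 8). "Assigned only to a
single group" is read strictly — zero reads elsewhere — which matches
the specificity goal of marker design.

Exclusive candidates are then **search-verified**: the representative is
searched against every group's reads and the call is confirmed only if
qualifying hits are confined to the owner group (E ≤ 0.001 by default).
Whether a similarity floor should accompany the E-value bound is
genuinely open. The strict E-only rule is the component default. For the
end-to-end pipeline, however, `run_config()` sets
`verify_min_identity = 0.97`: 16S genes share conserved stretches across
essentially all bacteria, so *any* candidate matches *every* group's
reads at permissive E-values, and an E-only rule would refute every
candidate on a conserved-gene assay regardless of host specificity.
Defining a disqualifying "match" at the species level (the same 97% used
to delimit OTUs) makes the exclusivity claim consistent across both
filtering stages. Set `verify_min_identity = NULL` to restore the strict
rule.

An optional read pre-filter (`filter_reads()`) reproduces the usual
pyrosequencing quality rules — minimum length 200 nt, no ambiguous
bases, mean quality ≥ 25 when per-base qualities are available.

## Uniqueness scanning

For each confirmed candidate, `find_unique()`:

1. **gathers homologs** from the reference database at E ≤ 1e-10 and
   extracts the hit-spanning subject subsequences (reverse-complemented
   for minus-strand hits);
2. **reduces redundancy** by greedy clustering at 95% identity, keeping
   the longest representative per cluster — so one over-sequenced taxon
   cannot dominate the difference count;
3. **builds a query-anchored star alignment**: each representative is
   globally aligned to the query with free end gaps and the pairwise
   alignments are merged on the query coordinate frame ("once a gap,
   always a gap"), then trimmed to the query's span. Choosing the query
   as the star centre makes trimming and query-coordinate mapping exact;
   the cost is that the result is not a general-purpose multiple
   alignment — reference-vs-reference columns are not optimized, which
   is irrelevant here because only query-vs-reference differences are
   scanned;
4. **scans a sliding window** (default 18 nt, probe-sized, step 1) over
   ungapped query positions. For each window and reference row,
   mismatches are counted over the alignment columns covering the
   window (gaps count as mismatches; a row with no aligned residue in
   the window counts as fully mismatched — absence of a homologous
   segment is itself evidence of uniqueness). A row *differs* when it
   has at least `min_mismatches` (default 2 — a single mismatch rarely
   prevents hybridization); the window's `difference_fraction` is the
   fraction of rows that differ (1.0 when no homologs exist), and
   windows at or above the 0.90 threshold are flagged;
5. **merges** maximal runs of flagged windows into candidate regions for
   probe/primer design, reported as BED-like TSV plus FASTA. Downstream
   thermodynamic design and manual database checks are intentionally out
   of scope; the FASTA output is the hand-off point.

Whether the original in-house rule measured per-sequence or per-column
differences is not documented anywhere we could check; the per-sequence
reading is implemented as default and a per-column variant
(`per_column = TRUE`, mean mismatch fraction over all row×column cells)
is available. Neither is claimed to be the historical rule.

In `run_discover()`, each candidate is searched against the reference
database **excluding records of its own host**: the reference database
stands for previously catalogued fecal bacteria of *other* sources,
whereas the candidate's own host's sequences are the novel survey data.
If the owner host's records were left in, every window of a genuinely
host-unique region would still have matching own-host rows and the 90%
difference fraction would be arithmetically unreachable with few hosts.

## qPCR evaluation

Standard curves are ordinary least squares of Ct on log10 copies; the
slope is stored as a positive magnitude (printed assay tables use the
magnitude of the necessarily negative slope), and amplification
efficiency is `(10^(1/|slope|) − 1) × 100`, i.e. 100% at the perfect
doubling slope 3.3219. The LOD estimator returns the smallest copy level
with ≥ 90% positive replicates (boundary inclusive); when no level
qualifies it returns an explicit undefined result rather than an error.
Plasmid copy numbers follow the molar-mass conversion
`copies = mass·1e-9 / (length·660) × 6.022e23`.

Sensitivity is TP/(TP+FN) over an assay's target host groups and
specificity TN/(TN+FP) outside them. Which groups count as targets is
**data**, not code — shipped for the published six-assay avian panel in
`avian_panel_targets()` and overridable. Reported percentages are
floor-truncated, the only rounding consistent with published panel
tables (76.47 prints as 76; efficiencies print at mixed precisions,
84.7 vs 97); raw fractions are always retained. Box-plot profile
statistics use linear-interpolation quantiles and the 1.5×IQR outlier
rule on quantities normalized to nanograms of DNA.

## Synthetic study conditions

The generators emulate a six-host avian amplicon survey on a 500 bp
V1–V3-like backbone (the sequenced amplicon region net of adapters):

* three hypervariable regions (`[60,120)`, `[210,270)`, `[380,440)`) at
  15% per-host divergence — enough to separate hosts below the 97% OTU
  threshold while keeping all hosts as E ≤ 1e-10 homologs of each other;
* one planted, fully randomized 24 nt host-unique segment per host,
  placed in conserved segments and below the minimum read length so
  every read covers it;
* within-host (strain-level) noise of 0.5% per position **inside the
  variable regions only** — conserved 16S segments are conserved across
  strains, and this is what makes "no flagged windows in conserved
  backbone" a property of the model rather than an accident;
* 3 reference records per host plus distractor records planted to fail
  each database filter rule;
* 40 primer-anchored reads per host, lengths uniform in 420–500 nt
  (3'-truncated amplicon reads), substitution errors at 2×10⁻⁴ per base
  — the substitution-specific error rate of quality-filtered
  pyrosequencing data (indels, the dominant error mode of that
  chemistry, are out of scope throughout);
* qPCR model: Ct = 40.1 − 3.4·log10(copies) + N(0, 0.3), detection
  dropout logistic in log10 copies with steepness 8 per decade,
  calibrated so detection probability is exactly 0.90 at the 5-copy LOD
  — matching the "90% positive detection" definition of the LOD, so the
  model's true LOD level is well-defined for recovery tests.

Sample sizes are deliberately desk-scale (hundreds of reads, not tens of
thousands); they exercise every code path while keeping the full test
suite fast. What passing tests on these fixtures shows is that the
algorithms recover planted truth under a realistic noise model; what
they cannot show is robustness to real-data phenomena the generators do
not emulate — chimeras, homopolymer indels, taxonomy-realistic community
structure, or primer bias.

## Numerical choices and degenerate inputs

* All coordinates are 0-based half-open on the ungapped input query.
* Ties in clustering order are broken by ascending id; hit tables sort
  by ascending E-value, then descending score, then subject id — every
  computation is deterministic given its seed.
* Identity ties at a threshold are inclusive (`>=`), as are the window
  difference threshold and the LOD detection rate.
* Zero homologs → every window has difference fraction 1.0 and is
  flagged (a sequence with no database relatives is unique by
  definition). A window longer than the query yields an empty result
  with a warning. An empty E-value-passing hit set is a valid outcome
  everywhere.
* Duplicate subjects are legitimate database content (E-values scale
  accordingly); duplicate *ids* are an error.
* K and λ are cached per scoring scheme; the series for K is truncated
  when a term falls below 1e-13, which reproduces published constants to
  four digits.

## Known limitations

* The seeded search mode inherits the usual seed-and-extend blind spot
  for highly scattered similarity; exactness holds in exhaustive mode
  (used automatically at small scales).
* The star alignment is query-anchored, not a general MSA.
* Ungapped Karlin–Altschul parameters are applied to gapped scores.
* The substitution-only error model does not exercise indel tolerance.
* Detection-from-Ct conversion supports a single cutoff per assay;
  "detected not quantified" handling below the quantification range is a
  reporting convention left to the caller's cutoff choice.
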