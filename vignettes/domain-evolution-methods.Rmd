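---
title: "Methods: domain evolution of group XIV C-type lectin proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain evolution of group XIV C-type lectin proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctldcpevo)
```

# Scope and model organisms

The group XIV C-type lectin domain-containing proteins (CTLDcps) --
CD93, Clec14A, CD248 and Thrombomodulin -- are single-pass
transmembrane proteins whose extracellular part is a beads-on-a-string
arrangement of modules: an N-terminal C-type lectin-like domain
(CTLD), a short sushi-like module (replaced by a hydrophobic stretch
in Thrombomodulin), a family-specific number of EGF-like repeats
(five in CD93, one in Clec14A, three in CD248, six in
Thrombomodulin), a Pro/Ser/Thr-rich mucin-like region, the
transmembrane helix, and a short cytoplasmic tail.  This package
provides the analysis layer for studying how those modules evolve
across vertebrates: classifying EGF repeats by sequence signature,
cutting a protein into its regions from anchor annotations,
estimating per-region Ka/Ks, comparing gene neighbourhoods between
chromosomes, and summarising phospho-site consensus motifs.  Domain
*prediction* (CD-Search, TMHMM, NetPhos) is deliberately upstream:
their outputs are consumed as plain tables, never recomputed.

# Signature matching and EGF subtypes

EGF-like repeats are classified from three PROSITE-style signatures:

* `PS00022` -- `CxCx(5)Gx(2)C` -- the EGF 1 type;
* `PS01186` -- `CxCx(2)[GP][FYW]x(4,8)C` -- the EGF 2 type;
* `PS01187` --
  `NxNNC-x(3,14)-C-x(3,7)-CxxBxxxxAxC-x(1,6)-C-x(8,13)-Cx` -- the
  calcium-binding consensus, written in a compact dialect where `N`
  is a negatively charged or polar residue `[DEQN]`, `B` a possibly
  beta-hydroxylated residue `[DN]`, `A` an aromatic residue, `C` a
  disulfide cysteine and `x` any amino acid.

The `A` shorthand is defined here as `[FYW]`, consistent with the
explicit aromatic class appearing in `PS01186`; histidine is not
included.  The matcher (`match_pattern()`) performs reachability
dynamic programming over the element list: every start position is
scanned, and for variable-length repeats the shortest match at each
start is reported, which is sufficient because all downstream use is
presence/absence.  `X` (unknown residue) conservatively matches only
the `x` element.

`classify_egf()` implements a fixed decision table: both `PS01186`
and `PS01187` give `cbEGF`; `PS01186` alone gives `EGF2`; `PS00022`
alone gives `EGF1`; no signature gives `EGF_like`.  When `PS00022`
and `PS01186` both fire, the call is `EGF2`: the calcium-binding
refinement is defined on EGF 2 domains, and the same precedence keeps
the table total and deterministic; the ambiguity is flagged on the
result.  The Thrombomodulin-specific fifth EGF (`Tme5EGF`) is never
called from sequence: it comes from the `cl07616` anchor annotation.
Because the calcium-binding consensus frequently extends past a
tightly annotated EGF core, `PS01187` alone is evaluated on the
annotated interval padded by a configurable flank (default 10
residues each side, clipped at the protein ends); the other two
signatures are evaluated strictly on the core.  The flank default is
our choice where no convention exists: large enough to recover a
consensus that leads into the preceding linker, small enough not to
reach a neighbouring repeat in these architectures.

# Region segmentation

`segment_protein()` derives the non-anchored regions by interval
arithmetic on the anchors: the sushi-like region is the interval
between the CTLD and the first EGF-like anchor -- or the
transmembrane anchor for proteins that lost all EGF repeats, as in
some lamprey CTLDcps -- the mucin-like region runs from after the
last EGF to before the transmembrane segment, and the cytoplasmic
tail from after the transmembrane segment to the C-terminus.  Three
conventions matter:

* coordinates are 1-based closed everywhere;
* zero-length derived regions (adjacent anchors) are reported as
  absent rather than as empty intervals;
* the region before the CTLD (signal peptide and any leader) is left
  unlabelled -- it is not part of the analysis.

For Thrombomodulin the CTLD-to-EGF region is labelled
`"hydrophobic stretch"`; its boundaries are computed exactly like a
sushi-like region.  Architectures with a CTLD after the first EGF or
a transmembrane anchor before the last EGF are rejected as
inconsistent rather than silently reordered.

The sushi-like module depends on hallmark tryptophan, glycine,
proline and cysteine residues.  `check_sushi_residues()` aligns each
candidate region to a designated reference with the package's global
aligner and maps configured key columns through the alignment; a gap
at a key column counts as lost, because in real data the module
disappears by truncation as well as substitution.  Pairwise alignment
to a reference was chosen over a multiple alignment: it is
deterministic, and presence/absence of fixed reference columns does
not benefit from an MSA.  The exact key columns are configuration
(default: the first occurrence of each hallmark residue in the
reference) because no published enumeration of the critical positions
exists; the tolerance for lost columns defaults to 0.

# Ka/Ks estimation

Region pairs are aligned as proteins (Needleman-Wunsch with affine
gaps, BLOSUM62, gap open -11, extend -1, a gap of length $L$ scoring
$\mathrm{open} + L\cdot\mathrm{ext}$) and the CDS are threaded
through the alignment codon-by-codon.  Codon columns containing a
gap, an ambiguous nucleotide, or an internal stop codon in either
sequence are dropped and counted; the codon column, not the
nucleotide, is the unit of filtering.  Alignment ties are broken
deterministically (diagonal, then gap in the second sequence, then
gap in the first), so repeated runs are byte-identical.

Two counting estimators are provided.

**NG86.**  The classical Nei-Gojobori method: each codon position
contributes one site, split by the fraction of its non-stop
single-nucleotide changes that are synonymous (mutations to stop
codons are excluded from the denominator, the PAML convention), so
$S + N = 3 \times \mathrm{columns}$ exactly.  Codon pairs differing
at several positions are averaged over all shortest substitution
pathways, excluding pathways through stop codons (all pathways are
used in the rare case that every pathway is blocked).  Proportions
are corrected with the Jukes-Cantor formula
$d = -\tfrac34\ln(1 - \tfrac43 p)$, undefined at $p \ge 3/4$.  The
ratio $\mathrm{Ka}/\mathrm{Ks} = d_N/d_S$ is reported only when
$d_S > 0$.

**YN00-style.**  An approximate counting method in the spirit of
Yang & Nielsen (2000), accounting for transition/transversion bias
and codon usage.  Codon frequencies enter through the F3x4 model
(position-specific nucleotide frequencies pooled over both
sequences).  Kappa is estimated from fourfold-degenerate and
nondegenerate site pairs with the standard two-parameter (K80)
correction, the two estimates combined weighted by site counts;
kappa can also be fixed by the caller.  Site counts weight each
possible change by $\pi \cdot \kappa^{\mathrm{ts}}$; pathway weights
for multiple-hit codon pairs additionally carry
$\omega^{\mathrm{nonsyn}}$ per step and are re-weighted iteratively
with the current $\omega$ estimate until the difference counts move
by less than $10^{-6}$ (at most 100 rounds; non-convergence is
flagged and the last iterate returned).  Distances are corrected by
inverting the expected total-difference proportion of the
two-parameter model at the estimated kappa,
$p(d) = \tfrac34 - \tfrac14 e^{-4d/(\kappa+2)}
        - \tfrac12 e^{-2(\kappa+1)d/(\kappa+2)}$,
solved numerically; at $\kappa = 1$ this is exactly the Jukes-Cantor
inversion.  This correction is the package's own method-of-moments
choice standing in for the published correction chain; it keeps one
clean property that we consider part of the estimator's contract:
with kappa fixed at 1 and uniform codon frequencies the weighting is
fully symmetric, every weighted count collapses to its NG86
counterpart, and the estimator coincides with NG86 exactly.  In that
collapsed mode the $\omega$ pathway iteration is skipped, since equal
pathway weighting *is* the NG86 treatment.

Cohort aggregation (`aggregate_domain_kaks()`) pairs **all unordered
species pairs** per family and region -- the natural reading of a
pairwise per-order comparison with no designated reference species --
and summarises each family x region cell by the median and quartiles
of the defined ratios, the statistics a box plot carries.  Undefined
ratios ($d_S = 0$, or saturated proportions) stay in the long table
but are excluded from summaries: box plots cannot carry infinities.
Whether pairs should instead be pooled within taxonomic classes is
left to the caller via the `families`/`regions` arguments and the
family map.

# Synteny and gene-loss mechanism

Synteny is operationalized at the gene-family level: the block around
an anchor is every gene on the anchor's chromosome within 20 Mbp each
side (`window_bp = 2e7`; on short chromosomes this is the whole
chromosome), and two loci count as syntenic when they share at least
15 families (`min_families = 15`).  Both constants are exposed, not
hard-coded.  Strand is ignored.

For a gene absent from a genome, `classify_absence()` asks what
happened to its reference neighbours: each neighbour family is
*retained* (on the best candidate chromosome within one window of the
candidate locus centre), *relocated* (present elsewhere) or
*missing*.  The best candidate chromosome is the one carrying most
neighbour families, ties broken lexicographically; the locus centre
is the median gene midpoint there.  A retained fraction of at least
0.5 calls `locus_preserved_loss` (the neighbourhood survived; the
gene itself was deleted or pseudogenized -- the Clec14A pattern in
marsupials and monotremes), a relocated+missing fraction above 0.5
calls `chromosome_disruption` (the CD248 pattern in birds).  The 0.5
threshold and the indeterminate band are our quantitative rendering
of a qualitative published distinction; they are configurable and
recorded in every report.  Fewer than `min_families` assessable
neighbours yields `indeterminate` with a warning rather than a
confident call.

# Phospho-site logos

Phospho-site tables are filtered to the target residue (default
tyrosine) with score strictly greater than 0.5 -- the strictness
matters at the boundary and follows the usual reliability convention
for these predictors.  Windows of `2*halfwidth + 1` residues (default
halfwidth 5, configurable because published logo widths vary) are
padded at protein ends with a dedicated symbol that is excluded from
counts, keeping the matrix rectangular without shrinking end
windows.  Information content per position is
$R_i = \log_2 20 - H_i - e_n$ with the Schneider small-sample
correction $e_n = (s-1)/(2 n \ln 2)$, $s = 20$; the correction is
applied per position with that position's non-pad count, is on by
default for the entropy rendering and off for the probability
rendering, and $R_i$ is clipped at 0.  Columns with no non-pad
observations report `NA` rather than a fabricated zero.

# The synthetic-data generators

Every stage is exercised against data with known truth; the
generator defaults *are* the study conditions and are not tuned per
test.

`simulate_architecture()` builds proteins segment by segment
following the family templates (leader 18-24 aa, CTLD 120-140,
sushi-like 50-60 with the four hallmark residues placed early, EGF
repeats 40 aa -- 60 for calcium-binding ones -- emitted as contiguous
anchors, mucin 80-100 at ~70% S/T/P, transmembrane 21-25 hydrophobic
residues, tail 40-50 with periodic tyrosines).  Each planned EGF
subtype embeds its signature instance, surrounded by filler drawn
from an alphabet free of cysteine, the `[DEQN]` class and aromatics,
which guarantees -- by a counting argument on the cysteines a
`PS01187` match requires -- that no spurious signature can assemble
across segment boundaries, so segmentation plus classification
recovers the plan exactly.  The CDS is a uniform synonymous reverse
translation.

`simulate_codon_evolution()` is an exact Gillespie jump process over
codons: single-nucleotide changes at rate
$\kappa^{\mathrm{ts}}\,\omega^{\mathrm{nonsyn}}$, stop-creating
changes rejected, each lineage run for $t/2$ from the ancestor (a
star tree of two, matching the pairwise estimators), time scaled so
$t$ is the expected number of substitutions per codon site computed
on the ancestor's composition.  A jump process was preferred over
matrix exponentiation for transparency; at these sizes it is also
fast.  Default conditions: per-region $\omega$ of 0.1 for
CTLD/sushi/EGF (strong purifying selection), 2.0 for the mucin-like
region (positive selection), 0.5 for the cytoplasmic tail;
$\kappa = 2$; $t = 0.3$.

`simulate_synteny_history()` plants a target gene amid neighbour
families within 18 Mbp, then either deletes only the target
(locus-preserved loss) or additionally deletes/relocates a fraction
`intensity` (default 0.8) of the neighbours (chromosome disruption).

What the generators do **not** emulate -- and hence what passing
recovery tests cannot show about real data: insertions and deletions
within domains (alignment quality is tested separately, on its own
oracle), rate variation among sites within a region, selection on
amino-acid properties, biased codon usage in the ancestor (available
via the F3x4 option but uniform by default), gene conversion, and
annotation error in the anchor tables.

# Numerical choices and problem sizes

Degenerate inputs are handled explicitly rather than silently:
empty alignments error; $p \ge 3/4$ makes the corrected distance (and
the ratio) undefined and reported as such; identical groups give
$F = 0, p = 1$ and zero within-variance with unequal means gives
$F = \infty, p = 0$; all-pad logo columns are `NA`.  The distance
inversion uses `uniroot` at tolerance $10^{-12}$ on a bracket grown
geometrically.  Kappa estimation falls back to 1 (flagged) when
neither site class is informative, and is capped at 100.

The shipped checks run at desk scale by design: recovery studies use
500-codon sequences with 200 replicates per condition, 100 simulated
proteins per family template, 200 synteny histories and 50 cohorts
of 3 species -- sizes at which the medians of interest are stable
while a full run stays in the order of a minute or two.

# Known limitations

* The YN00-style estimator is a counting method; like the original it
  inherits counting biases at high divergence and does not replace a
  maximum-likelihood codon model.  NG86 in particular retains its
  known downward bias in Ka/Ks when transitions are favoured
  ($\kappa > 1$); the recovery studies quantify both.
* Signature classification is presence/absence; profile or PSSM
  scanning (and hence remote EGF homologs) is out of scope.
* Synteny works on family labels; it does not infer orthology from
  sequence and cannot distinguish tandem paralogs within a family.
* The sushi check is relative to a reference sequence; if the
  reference itself lost a hallmark residue the check must be re-rooted
  (the pipeline falls back to the next species and logs it).
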