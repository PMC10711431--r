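---
title: "Methods: models and design choices behind ssapkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and design choices behind ssapkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssapkit)
```

# Scope

ssapkit models the computational arc of a genus-specific SSAP
(single-stranded DNA-annealing protein) discovery campaign: mine candidate
recombinases from a protein database with an iteratively refined profile,
design the recombineering oligos that assay them, simulate the pooled
serial-enrichment screen that ranks them, analyze the barcoded long-read
output, and compute the allelic-replacement statistics used to compare
them individually. Wet-lab inputs (UniProtKB searches, sequencing runs,
plate counts, whole-genome variant calls) are replaced by a first-class
synthetic-data module, so every claim the package makes is testable
end-to-end against a known ground truth.

# Homolog mining

## Profile model

The search profile is a position-specific scoring matrix (PSSM), not a
full profile HMM: a desk-scale substitute that preserves the
search-refine-repeat structure of iterative profile search while staying
dependency-free. Column scores are log-odds in bits,

$$S_i(a) = \log_2 \frac{p_i(a)}{q(a)}, \qquad
  p_i(a) = \frac{W_i f_i(a) + \alpha\, q(a)}{W_i + \alpha},$$

where $f_i(a)$ is the weighted observed frequency of residue $a$ in
alignment column $i$ (uniform, position-independent sequence weights,
$W_i$ = summed weight of rows with a residue there), $q$ is the
Robinson-Robinson background, and $\alpha$ is the pseudocount weight.
Columns gapped in more than half the rows are dropped; X residues are
ignored in counts and score zero.

**Pseudocount weight ($\alpha = 2$, config-exposed).** With a small
$\alpha$ (say 0.2) a residue unseen among seven seeds costs about
$-5$ bits per column, which fragments local alignments of genuine
40-45%-identity family members into short islands and caps their scores
near the decoy noise floor. $\alpha = 2$ — the scale used by classic
iterative search tools, roughly "a few" pseudo-observations against
seven seeds — keeps unseen residues near $-1.3$ bits, and distant family
members then score hundreds of bits above shuffled decoys. The planted
homolog recovery test (100% recall, 0 decoys at $E \le 10^{-3}$) runs at
this default.

## Alignment and E-values

The seed alignment is a center-star progressive alignment under BLOSUM62
(from Biostrings) with affine gaps (−11/−1 half-bits, a gap of length
$L$ costing $11 + L$); ties for the center and merge order are broken by
input order, so the alignment is deterministic. Sequences are scored
against the profile by local (Smith-Waterman) DP with affine gaps in
bits (−5.5/−0.5). E-values come from a Gumbel (extreme-value) fit: 200
residue-shuffled copies of database sequences are scored per round, the
location/scale parameters are fit by maximum likelihood (moment fall-back
for degenerate samples), and
$E(s) = N \left(1 - e^{-e^{-(s-\mu)/\beta}}\right)$ for database size
$N$, capped at $N$. Length dependence of the score distribution is
ignored — adequate here because the synthetic database has a narrow
length range; a production search against a broad database would need a
length correction.

Each search round scores every not-yet-hit sequence, admits those with
$E \le$ threshold (default $10^{-3}$), aligns new hits back onto the
profile columns (insertions relative to the profile are discarded, so
the column coordinate system stays fixed at the seed alignment), and
rebuilds the profile. The loop stops when a round adds nothing or at 15
rounds. Hits accumulate monotonically, each recording the round that
found it.

## Clustering and prioritization

Greedy incremental clustering in the CD-HIT style: sequences sorted
longest-first (ties by id), each joining the first representative at or
above the identity threshold (default 0.7). Identity is exact matches
over a global alignment divided by the shorter sequence's length, so a
perfect fragment counts as identical — the convention that keeps
truncated database entries with their full-length relatives. One
candidate is drawn per cluster by smallest E-value; ties favour a phage
source (phage-derived SSAPs are the prior expectation for active
recombinases), then the lexicographically smallest id. The choice of
E-value as the primary key, with phage relevance only as a tie-break, is
one reading of a joint criterion; it is deliberate and should not be
changed silently.

# Oligo design

Recombineering oligos carry the strand complementary to the
lagging-strand template at their locus. Which strand that is follows
from the replichore: loci on the arc traversed oriC→ter in increasing
coordinates (fork direction +1) get the minus strand, the other arc the
plus strand. The convention is encoded in an explicit `replichore_map`
so it is testable and overridable per edit; a locus exactly at oriC or
ter raises an error demanding an explicit strand.

The designer takes the 60-nt plus-strand window in which the edit starts
at offset $\lfloor(60 - k)/2\rfloor + 1$ (a 1-nt edit sits at position
30 — "centered" for an even-length oligo is ambiguous by one base and
this is our fixed resolution), substitutes the 1-3 alternate bases,
verifies the reference bases against the genome, and
reverse-complements when targeting the minus strand.

Folding is scored as the minimum free energy over single stem-loop
hairpins: contiguous Watson-Crick stems scored by SantaLucia unified
nearest-neighbor $\Delta H/\Delta S$ at the working temperature (default
30 °C, the screen's growth temperature) plus an entropic loop-initiation
penalty (loop ≥ 3 nt; sizes above 30 extrapolated with
$1.75\,RT\ln(n/30)$). The recursion only admits uninterrupted stems —
no bulges or internal loops — which keeps the DP exactly equal to
brute-force structure enumeration, the property the tests assert. The
pass threshold is $\Delta G \ge -16$ kcal/mol: the published magnitude
is read as a floor on the (non-positive) predicted folding energy,
since a threshold of $+16$ kcal/mol would be unsatisfiable for energies
that are at most zero. Both the printed text and this interpretation are
recorded in the oligo output metadata. Filtering only flags designs;
nothing is removed.

# Screen simulation

The pooled screen is a Wright-Fisher-style propagation of variant
frequencies rather than an agent-based cell simulation — sufficient for
every property the analysis layer consumes. A screen cycle is:

1. **Growth.** Frequencies reweighted by
   $(\text{fitness} \times (1 - \text{dropout}_p))^{G}$ with $G$
   doublings per growth phase, then a multinomial bottleneck of $N$
   cells.
2. **Editing.** Each variant's edited fraction rises to
   $\mathrm{arf} \cdot (1 - e^{-T/\tau})$ for recovery time $T$:
   a saturating action-rate model, chosen because measured ARF
   time-courses look like saturation curves (most of the final ARF
   within the first hour for fast variants). $\tau$ is the single
   parameter separating *fast* from *efficient* recombinases.
3. **Selection.** Survivor mass = edited cells plus a spontaneous
   resistance fraction (default $10^{-8}$) of unedited cells.
4. **Bottleneck and reset** of the edited fraction for the next locus.

The default schedule — 2 pre-selection samples, 4 cycles, a
retransformation into a naive host (edited fractions zeroed, a
bottleneck applied), 4 more cycles — yields 11 sample points.

**Growth generations ($G = 12$, config-exposed).** The experimental
protocol between consecutive samples spans outgrowth and overnight
culture, i.e. on the order of ten doublings; $G = 12$ is our fixed
choice. It matters only through fitness and plasmid dropout: per-phase
dropout of 0.5 then compounds to $\sim 2 \times 10^{-4}$, which is what
empties a plasmid-losing variant out of the pre-selection samples at
realistic bottlenecks — the behaviour observed for strains that never
appear in the early barcodes.

**Active-variant parameters.** The synthetic parameter generator makes
a small active set (default 4 of 52) with saturation ARFs drawn from
0.8-2% and $\tau$ from 0.5-2 h, inert variants at ARF 0. The ARF range
matches the spread seen among individually assayed active recombinases
(a factor of ~2-3 between best and worst), and keeps the weakest active
variant above the read-fraction calling threshold through the
persistence barcode at default depth; a wider spread would push weak
actives below any fixed calling threshold — a real failure mode of
pooled screens, but not the regime the recovery tests target.

**Reads.** Read counts per sample are multinomial in the sample
frequencies; each read is a uniformly placed fragment (≥ 200 nt or the
full gene) with i.i.d. errors at 8% total, split 40/30/30 between
substitutions, insertions and deletions — representative of fast
basecalls on current nanopore chemistry, configurable. Reads are emitted
on the forward strand only (a deliberate simplification; the classifier
therefore uses forward k-mers, not canonical ones). Error correlations,
homopolymer compression, chimeras and quality-score structure are not
modeled; conclusions about classifier accuracy transfer to real data
only to the extent that shared-15-mer statistics do.

# Screen analysis

Demultiplexing splits simulator-labelled reads directly, or matches
observed barcode sequences by edit distance (≤ 3 edits; ties →
unclassified). Reads are assigned to reference genes by shared
(15,10)-minimizer count, with banded local-alignment rescoring (band 40
around the minimizer diagonal) of the top two references whenever the
runner-up shares any minimizer; a read is unassigned when the relative
score margin falls below 0.1 or when it shares no minimizer with any
reference. When the runner-up shares no minimizer the count margin is
already maximal and the best hit is assigned directly — rescoring could
not change the decision, and skipping it keeps million-read analyses
fast.

Percentages are computed per barcode over assigned reads only
(unassigned reads are tallied separately); whether the corresponding
published percentages included unmapped reads in the denominator is not
stated anywhere we can check, so ours is a documented convention, not a
claim of equivalence. A variant is called active when it holds at least
`min_fraction` (default 0.1%) of assigned reads in every selective
barcode from the first selection through the persistence barcode
(default 9) and is merely present in the pre-selection and
retransformation barcodes — an explicit, falsifiable version of a
"present at least up to barcode 9" visual call.

# Efficiency statistics

ARF = 100 × resistant/total CFU, minus the mean non-induced control ARF
of the same strain and locus, clamped at zero. The subtraction is done
on percentages, not raw counts — the natural reading when induced and
control platings have different dilutions. Replicates are summarized as
mean ± sample (n−1) SD. Group comparisons use Student's pooled-variance
two-tailed t-test (the parametric default appropriate at n = 3), with
Welch behind a flag; significance stars follow the usual legend map
(p ≤ 0.05 \*, < 0.01 \*\*, < 0.001 \*\*\*, < 0.0001 \*\*\*\*). Two
zero-variance groups with equal means return p = 1 by convention.

Action-rate time courses are normalized by their final ARF and fitted
with $A(1 - e^{-t/\tau})$ by bounded Levenberg-Marquardt
(minpack.lm), $\tau$ floored at 0.01 h; a flat course degenerates to the
floor (saturation already complete). Note that a two-point fraction such
as 1.10/1.53 prints as 71.9%, while sources computing from unrounded
means may print 71.79% — the package computes from the numbers it is
given and does not chase rounding artifacts.

Off-target counts are per-colony mutation-set differences keyed on
(position, ref, alt): mutations in the parental background are removed,
and the intended on-target edit must be declared explicitly so it is
never counted as an off-target.

# Numerical and testing choices

* All randomness flows through R's RNG; simulation entry points take
  explicit seeds and record them, and the pipeline fans one global seed
  out to per-stage seeds so stages re-run independently and outputs
  reproduce bit-for-bit (hash-verified in the tests).
* Tests compare each DP against an independent oracle: global alignment
  against exhaustive path enumeration (sequences ≤ 6), profile local DP
  against sub-alignment enumeration (profiles ≤ 5 columns), hairpin DP
  against brute-force stem enumeration (12-mers), read assignment
  against full Smith-Waterman via Biostrings, identity and clustering
  against Biostrings-based recomputation, the t-test against the closed
  form and a permutation test.
* Property checks run at deliberately modest sizes chosen as the
  package's own test conditions: a 250-sequence mining database (50
  planted, 200 decoys), 100-screen dominance and dropout batches, 20
  end-to-end screens at 4000 reads per barcode, 11 barcodes, 20
  variants. A full-scale pipeline (52 variants) runs through
  `run_pipeline()` with the same code paths.

# Known limitations

* The PSSM has no insert/delete state structure; very gappy families
  would be served better by a true profile HMM.
* E-value calibration ignores sequence length and composition beyond the
  shuffle ensemble.
* The hairpin model scores single uninterrupted stems only; bulged or
  multi-loop structures, and oligo-oligo duplexes, are out of scope.
* The simulator's dropout, fitness and spontaneous-resistance terms are
  phenomenological dials, not mechanistic models; off-target counts are
  parameterized, not simulated from a repair mechanism.
* Real screens rotate different target loci across cycles with
  locus-specific efficiencies; the simulator uses one ARF per variant
  for all cycles.
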