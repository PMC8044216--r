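---
title: "Quantifying differential cysteine redox states from biotin-switch SILAC evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying differential cysteine redox states from biotin-switch SILAC evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cysredox)
```

## The measurement model

A biotin-switch SILAC experiment turns the redox state of each protein
cysteine into a chemical label before mass spectrometry: free thiols (S-H)
are blocked with iodoacetamide and appear as carbamidomethylated cysteines;
*S*-nitrosylated thiols (S-NO) are selectively reduced with ascorbate and
tagged with iodoacetyl-PEG2-biotin; remaining reversibly oxidized thiols
(S-OX — disulfides, sulfenic acids) are reduced only later and come through
with an unmodified cysteine. Affinity enrichment additionally sorts
peptides into elution fractions (unbound, DTT, guanidine), but
classification in this package follows the chemistry labels alone: the
fraction annotation is protocol metadata, and a label/fraction disagreement
raises a warning, never an error or a reassignment.

Every light (sample) extract is mixed 1:1 with a common heavy SILAC
reference, so each quantified peptide feature carries a ratio
`H/L = reference / sample`. The reference is a fixed mixture of three
planktonic extracts spanning non-, mildly and strongly *S*-nitrosylating
conditions in proportions 5:5:1; because it is common to all samples, it
cancels from every between-condition comparison.

Writing `A_p(c,k)` for the abundance of protein `p` in condition `c`,
replicate `k`, and `theta_s(c)` for the occupancy of state `sigma` at site
`s`, the generative model the pipeline assumes is

- cysteine-free peptide ratio: `R_ref_p / A_p(c,k)` times noise,
- site-state peptide ratio: `R_ref_p * theta_ref_s(sigma) /
  (A_p(c,k) * theta_s(sigma, c))` times noise,

with multiplicative lognormal noise (`2^N(0, sigma^2)` on the ratio, the
standard SILAC error model). The per-replicate normalized ratio
`z = site ratio / protein ratio = theta_ref / theta` therefore depends only
on occupancies, which is why the pipeline normalizes site ratios to the
same replicate's protein ratio: a pure protein-expression change moves both
numerator and denominator identically and leaves `z` at its old value. The
biofilm-versus-planktonic fold change

`FC = median_k z_PK(k) / median_k z_BF(k) = theta_BF / theta_PK`

is the occupancy ratio of the state, free of expression bias and of the
reference composition.

## Pipeline steps and their parameters

1. **Evidence parsing** (`read_evidence`). Column names are mapped through
   a configurable dialect; the default matches MaxQuant `evidence.txt`, so
   such exports load unchanged. Ratios are stored internally as
   heavy/light; dialects that report light/heavy declare it and are
   inverted on load. Rows with a missing ratio are retained (they count as
   identified but not quantified); malformed rows are rejected and counted,
   and the run aborts when the rejected fraction exceeds the dialect's
   `error_tolerance` (default 1%). Row counts always satisfy
   input = parsed + rejected. Shared peptides keep the row's leading
   accession; razor-protein logic is not re-derived.
2. **Classification** (`classify_evidence`). Zero cysteines → protein
   profiling; one cysteine → REDUCED / SNO / SOX from the label map
   (defaults: Carbamidomethyl → REDUCED; IAM-biotin,
   Iodoacetyl-PEG2-biotin, Biotin-HPDP → SNO; unmodified cysteine → SOX);
   two or more cysteines → excluded from site analysis (and, being
   cysteine-containing, from protein profiling too). An unknown
   cysteine-targeted modification is an error naming the modification.
3. **Localization** (`locate_sites`). The site position is the 1-based
   start of the peptide's unique exact occurrence in the protein plus the
   cysteine offset, so sites read like "C108". Ambiguous (multiple
   occurrences) or absent peptides are flagged and set aside rather than
   guessed.
4. **Quantification** (`protein_fold_changes`, `site_fold_changes`).
   Medians aggregate peptide forms at every level; even-count medians use
   the mean-of-the-middle-two convention. Missing (site detected, protein
   undetected) replicates are dropped, never imputed.
5. **Testing and calling** (`call_differential`). Student's pooled-variance
   *t*-test on `log2 z` (Welch available by option — with five replicates
   and possibly unequal variances it is the conservative alternative), one
   Benjamini–Hochberg family per redox state per oxygen regime, since the
   four condition series come from independent LC-MS/MS runs. Defaults:
   `alpha = 0.05` on the adjusted p-value and a strictly-greater
   fold-change threshold `|FC| > 1.75`; both are recorded on every call.
   Fold changes are reported in the signed convention
   (`signed(x) = x` for `x >= 1`, else `-1/x`), so the threshold applies to
   the magnitude of the signed linear fold change.
6. **Presence/absence** (`presence_absence_call`). Features detected in at
   least `n - 1` of `n = 5` replicates of one condition and in none of the
   other are condition-specific ("BF only" / "PK only"). For cysteine
   sites this additionally requires the parent protein to be detected in
   both conditions — "detected" meaning at least one replicate with a
   quantified ratio — so a vanished protein cannot masquerade as a
   vanished modification. Sites that are neither testable (fewer than two
   quantified replicates on a side) nor condition-specific are kept as
   UNTESTABLE for audit rather than dropped.
7. **Events** (`classify_redox_events`). A significant increase in S-NO or
   S-OX is an oxidation event in the condition where it rises; an increase
   in the reduced fraction is a reduction event.
8. **Randomness QC** (`runs_qc`). Per condition, the signs of
   `log2(site ratio / protein ratio)` across sites (replicate input order,
   zeros dropped) are tested with the Wald–Wolfowitz runs test at
   `runs_alpha = 0.05`. This is a dataset-level diagnostic, reported but
   never used to filter individual sites; how the sign sequence is
   assembled is this package's choice and is documented here rather than
   asserted as canonical.

## Numerical choices

- The runs test uses the exact run-count distribution (closed form) for
  sequences up to 30 symbols, and the normal approximation with continuity
  correction beyond. The two-sided p-value is
  `min(1, 2 * min(P(R <= r), P(R >= r)))`; the test suite checks the exact
  distribution against brute-force enumeration of all arrangements for
  every composition with `n <= 12`. All-same-sign sequences have no defined
  p-value and are flagged.
- `t.test` refuses (or returns NaN for) groups that are essentially
  constant. Zero-variance groups arise naturally in noiseless synthetic
  data, so `site_ttest` short-circuits them: equal means give p = 1,
  unequal means give p = 0, which lets closed-form datasets flow through
  the caller unchanged.
- BH adjustment delegates to `stats::p.adjust(method = "BH")` behind the
  `bh_adjust` surface and is property-tested against the step-up
  definition.
- Whether condition fold changes are a ratio of replicate medians or a
  median of replicate-paired ratios is not determined by the design;
  ratio-of-medians is the default (it uses all replicates even when
  detection patterns differ between conditions) and median-of-ratios is
  available via `fc_mode`.
- Closed-form recovery assertions use a tolerance of 1e-9: with noiseless
  data every step is a product/quotient of medians, so errors stay within
  a few ulps (abundances like `2^1.5` introduce one rounding each).

## What the generator emulates — and what it does not

`simulate_redox_dataset()` emulates: the 2 × 2 × 5 design; the 5:5:1
reference mixture (as three occupancy presets over REDUCED/SNO/SOX — the
non-, mildly and strongly nitrosylating reference states); per-site
occupancy vectors; planted occupancy shifts, condition-specific absences
and protein-expression shifts with serialized ground truth; lognormal ratio
noise (`noise_sigma = 0.3` by default, a typical inter-replicate spread for
SILAC ratios); uniform dropout (`dropout_prob = 0.1`) with an optional
intensity-dependent logistic mode; duplicated oxidized-methionine peptide
forms (`dup_fraction = 0.2`) to exercise median aggregation; and an
optional fraction cross-contamination rate to exercise the consistency
warning. By default the baseline sample occupancy equals the
reference-mixture composition, so an effect-free noiseless dataset has
every normalized ratio exactly 1 — the cleanest possible null.

It does **not** emulate: spectrum-level structure (m/z, isotope envelopes,
interference), peptide identification error (the 1% PSM-level FDR is
assumed handled upstream), retention-time or batch drift, correlated
(protein-level) noise, isotope impurity or arginine-to-proline conversion,
or realistic occupancy magnitudes — the real fraction of a protein pool
carrying S-NO at a site is typically small and is not quantified here;
generator defaults are presets, not calibrated values. Passing tests
therefore demonstrate correctness of the computation under the stated
error model, not performance on any particular instrument's output.

## Validation strategy and problem sizes

The suite validates each operation against an independent oracle or a
closed form: runs-test enumeration for all sign compositions up to n = 12;
BH against the brute-force step-up definition on 1000 random vectors;
noiseless synthetic data recovered exactly (a planted S-NO occupancy shift
0.10 → 0.40 yields normalized FC 4.0; pure expression shifts yield all
normalized FCs 1); an exhaustive enumeration of the presence/absence rule;
and stochastic recovery over 50 seeds at `noise_sigma = 0.3` with datasets
of 8 proteins (sensitivity of planted |FC| = 4 sites) and 17 proteins
(~200 tested site-states per regime, global-null false-call control).
These sizes keep each simulated dataset around one to two thousand
evidence rows — large enough for every code path (dropout, duplicates,
both regimes), small enough that the whole suite runs in minutes on one
core.

## Known limitations

- Plain Student's test with n = 5 per side has limited power for modest
  occupancy shifts; no variance moderation (empirical Bayes) is applied,
  by design, to keep the statistic the classical one.
- Site-occupancy *estimation* (what fraction of the protein pool carries
  the modification) is out of scope; the pipeline quantifies relative
  changes, not absolute stoichiometry.
- Peptides mapping to several proteins are assigned to the leading
  accession; protein-inference subtleties are left to the upstream search.
- The "only" rule is a detection heuristic: with stochastic dropout a
  truly present low-abundance site can satisfy it by chance; the
  UNTESTABLE audit category and the detection counts on every call exist
  so such cases can be reviewed.
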