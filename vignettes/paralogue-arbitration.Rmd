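---
title: "Arbitrating coding status among near-identical paralogues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arbitrating coding status among near-identical paralogues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogid)
```

# The inference problem

A family of recent gene duplicates shares upwards of 95% protein identity.
Bottom-up proteomics observes peptides, not proteins, and nearly every
peptide from such a family maps to several members at once. The decisive
evidence is concentrated in a handful of *unique* peptides — those whose
sequence spans one of the few residues that differ between copies — and in
the lesions (premature stops, frameshifts, lost 5' exons) that disqualify
copies at the transcript level. `paralogid` formalizes the arbitration as a
pipeline over four independent strands of evidence: peptide attribution,
single-amino-acid-variant (SAAV) rescue, cross-species conservation, and
transcript coding status, with a distance-based phylogenetic check on the
side.

This vignette explains the model behind each stage, the tunable parameters
and the reasoning behind their defaults, what the synthetic-data generator
does and does not emulate, and the numerical choices that make results
deterministic.

# Tryptic digestion and mapping

Trypsin cleaves C-terminal to lysine or arginine. Two conventions needed
pinning:

* **Proline suppression** (`proline_rule`, default `TRUE`): a K/R
  immediately followed by proline is not cleavage-competent. Reanalysis
  pipelines behind large peptide repositories typically apply this rule,
  so it is the default, but it is a switch (and both modes are tested)
  because search engines differ.
* **Isoleucine/leucine** (`il_equivalent`, default `FALSE`): I and L are
  isobaric and indistinguishable by most mass spectrometry. The default
  nevertheless treats them as distinct, because paralogue discrimination
  is exactly the situation where a curated evidence table may encode a
  genuine I/L difference; the equivalence mode exists for raw-search
  realism. Under `il_equivalent = TRUE` any conclusion resting on an
  I-vs-L unique peptide dissolves, which is the honest behaviour.

A peptide *matches* a protein at a position when the substring is
identical, both boundaries are tryptic (protein terminus or
cleavage-competent K/R *in the protein's own context*), and the number of
internal cleavage-competent K/R is at most `max_missed` (default 2).
Occurrence search is overlap-aware: tandem repeats such as `RR` inside
`IRRR` are found at every tryptic start. The unknown residue `X` is
accepted in sequences but a peptide or window containing `X` never
matches anything — an unknown residue cannot support an identification.

Evidence filtering keeps peptides with at least `min_obs = 2` observations
(singleton removal) and at most 2 missed cleavages. The fully tryptic
requirement is deliberately enforced at mapping time, not filtering time,
because boundary status depends on the protein a peptide lands on; an
evidence table may legitimately contain semi-tryptic rows that simply
never map.

The attribution report ranks paralogues by **explained-observation
fraction**: observations of captured peptides divided by the observations
of *all* filtered peptides, mapped or not. Ties break by larger
unique-observation total, then lexicographic id — determinism matters more
than the specific rule. A peptide occurring twice in one protein counts
once toward its capture set.

# Variant rescue

An unmapped peptide may be a common protein-level allele rather than
evidence against the top candidate. `rescue_single_substitution()` scans
every window of equal length and accepts windows differing at exactly one
residue, with the crucial detail that tryptic boundaries and missed
cleavages are re-evaluated **on the substituted sequence**: a substitution
that creates a third internal cleavage site, destroys the C-terminal K/R,
or introduces a proline after the preceding K/R disqualifies the window.
Only single substitutions are considered — no indels, no double variants —
which bounds the search and mirrors how variant peptides enter curated
evidence tables in the first place.

When the evidence table contains the exact-match counterpart of a rescued
window (the reference-allele peptide), it is recorded as corroboration;
its absence is not disqualifying. A peptide explained by several windows
contributes its observations once to the variant-inclusive total, so
observation counts are conserved: unmapped + exact-explained +
variant-explained observations always equal the filtered total. The
variant-inclusive explained fraction can therefore only exceed the exact
fraction, never fall below it.

Haplotype panels (aligned protein predictions from many individuals) turn
a rescued substitution into an allele-frequency statement via
`summarize_haplotype_alleles()`, a residue histogram at one alignment
column with gaps reported separately.

# Conservation profiling

Orthologue rows carry a clade label from the nested series primates ⊂
mammals ⊂ tetrapods ⊂ vertebrates. A column is conserved at a level when,
among the rows belonging to that level, gaps are within `gap_tolerance`
(default 0) and the modal residue's frequency reaches `min_fraction`
(default 1.0, strict identity). The reported depth is the deepest level
such that the criterion holds there *and at every shallower level*. With
strict settings the monotonicity is automatic; with relaxed settings this
definition enforces it, so "conserved across vertebrates" always implies
"conserved across mammals" and SAAV totals are monotone across depths.
Strict identity is the default because the alternative (majority
consensus) is not a published, quantified convention; both are supported.

Candidate orthologues pass QC only if they carry the reference's first and
last aligned residues (ancestral N- and C-termini) and contain no
insertion or deletion run longer than 7 columns relative to the reference
— longer indels indicate annotation or assembly artefacts rather than
evolution of a functional orthologue.

Conservative versus radical substitutions use fixed physicochemical
exchange groups, pinned in the package: {A,G,P,S,T}, {I,L,M,V}, {D,E,N,Q},
{K,R,H}, {F,W,Y}, {C}. Any such grouping is a convention; pinning one
makes the call deterministic and symmetric.

Paralogues are aligned to the ungapped reference row by global alignment
(BLOSUM62, gap opening 10, extension 0.5); a non-positive score is an
error rather than a silent bad profile. Variant names (e.g. G343S) use the
paralogue's own 1-based residue coordinates; profile tables also carry the
alignment column so variants can be compared across paralogues, pooling
alternate residues at one column ("Y141D/E"-style) when requested.

# Coding status

`assess_transcript()` aligns a transcript to its parent CDS with free end
gaps (match 1, mismatch −2, gap opening 4, extension 1 — pinned, since no
single published choice exists) and reports:

* **premature stop** — an in-frame stop upstream of the parent's stop,
  sought on the *effective CDS* (parent with the aligned transcript region
  substituted in), scanning only up to the first frameshifting indel.
  Stops downstream of a frameshift are artefacts of a scrambled frame and
  are deliberately not reported.
* **frameshift** — any alignment indel with length ≢ 0 (mod 3).
* **5'-truncation** — alignment begins ≥ `trunc_codons` (default 50, the
  length of the ancestral first coding exon) codons into the parent.
* **fragment** — aligned parent coverage below 50% (configurable; "full
  length" has no published numeric definition, so the threshold is the
  package's own).

Status precedence is premature stop > frameshift > truncation > fragment,
with all detected lesions listed regardless. An upstream in-frame stop
dominates a downstream frameshift because translation terminates before
the frame is ever lost.

`classify_gene()` then combines lesions with attribution: disabling
lesions give *pseudogene*; intact plus ≥ 1 unique peptide gives *coding*;
intact with no unique peptides is *ambiguous* — unless a sibling
paralogue's variant-inclusive explained fraction reaches
`comparative_threshold` (default 0.99), in which case essentially every
observation is accounted for elsewhere and the verdict is *pseudogene*.
One refinement proved necessary: the explaining sibling must itself have
unique-peptide support. Without that condition, two identical intact
copies would each explain 100% of the evidence and argue each other into
pseudogene status; with it, mutually indistinguishable twins are correctly
left ambiguous. A 5'-truncated copy is a pseudogene unless unique peptides
survive in its retained region.

# Distances and trees

The phylogenetic question in scope is topological: do the derived copies
form their own clade, separate from the coding copy and the species
orthologues? For that, pairwise TN93 distances (computed in closed form
from the two transition proportions, the transversion proportion, and
base frequencies pooled over the pair; gap/N sites excluded pairwise;
`Inf` on saturation) feed canonical neighbor-joining. Maximum-likelihood
tree building, substitution-model selection and bootstrap support are
deliberately out of scope — they belong to dedicated phylogenetics tools —
and the NJ agglomeration itself is delegated to ape's canonical
implementation rather than re-derived, with rooting on a supplied
outgroup's pendant edge. ape's TN93 serves as an independent cross-check
of the in-package closed form in the test suite, not as the
implementation.

# The synthetic-data generator

`family_spec()` defaults *are* the study conditions: 5 paralogues of a
450-residue ancestor (the scale of the WASH1 family), per-residue SAAV
rate 0.01 on derived copies, a mean of 0.7 short indels (1–6 nt) per
derived copy, premature-stop probability 0.6, 5'-truncation probability
0.2 (50 codons), exactly one intact coding copy, one heterozygous
protein allele at frequency 16/33 on the coding copy, five singleton
contaminant peptides, and log-normal observation counts (meanlog 3.0,
sdlog 1.6) whose draws span single digits to thousands — matching the
heavy tail of real observation counts. Where a published value existed it
was used; the remaining rates were chosen once as realistic for a young
subtelomeric family and are not tuned.

Three modelling choices deserve note:

* Each copy's emitted protein is the **producible product** of its CDS —
  translation to the first in-frame stop — modelling what a proteomics
  search database holds for a damaged copy.
* The planted heterozygous allele avoids K, R and P for both alleles so
  the tryptic pattern is identical on both; rescue tests then isolate the
  substitution logic from boundary effects.
* Contaminants are singletons by default so that the singleton filter is
  exercised end to end.

All randomness flows through one seed per generator call; generators save
and restore the session RNG state, so calls never perturb the caller's
stream (base R has a single global RNG; this is the closest available
approximation to an isolated generator).

What the generator does **not** emulate: spectra and search-engine
behaviour (evidence enters at the peptide level, as in the real
procedure), retention times, shared peptides arising from unrelated
genes, tissue structure in observation counts, and genomic rearrangement.
Passing the recovery properties therefore validates the arbitration
logic, not the upstream spectral identification.

# Validation scales and determinism

The test suite validates digestion and mapping against a brute-force
all-substrings oracle on 1000 random proteins (length ≤ 60, both proline
modes), coding-copy recovery on 200 seeded families at default spec
(expected ≥ 95% top-rank recovery, ≥ 90% of replicates with
variant-inclusive fraction > 0.99), planted-allele rescue across 100
seeds, exact conservation-truth recovery across 50 seeds (200-column
panels), the four forced transcript-lesion cases, TN93 against an
independent closed-form transcription (tolerance 1e−10) and against ape,
NJ recovery of additive 4–8 taxon topologies, and ≥ 95% derived-clade
separation on divergent DNA families. These sizes were chosen as the
point where the binomial noise on the recovery rates is well below the
thresholds being asserted. Every stochastic quantity is seeded;
re-running any stage with the same configuration is bit-identical, and
the pipeline manifest records the configuration digest and seed.

# Known limitations

* Attribution is unique-peptide based; no parsimony-style protein
  inference across the family is attempted (none is needed when one copy
  explains ~all observations, which is the regime this pipeline targets).
* Rescue considers single substitutions only; a genuine double variant or
  a single-codon indel allele will stay unexplained.
* Exon structure is approximated on CDS sequences; a transcript that
  swaps exons could fool the truncation heuristic.
* The comparative pseudogene call is evidence-based, not mechanistic: an
  intact copy silenced in every sampled tissue and an intact copy that is
  genuinely untranslated are indistinguishable.
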