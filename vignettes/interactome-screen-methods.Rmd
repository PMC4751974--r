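---
title: "Designing heterospecific coiled-coil sets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing heterospecific coiled-coil sets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heterospec)
```

## The design problem

A parallel dimeric coiled coil is built on the heptad repeat `[abcdefg]n`:
`a` and `d` residues pack the hydrophobic core, while `e` and `g` residues
flank it and form interhelical salt bridges (each `g` against the partner's
`e` five residues C-terminal). *Heterospecific* design asks for groups of
peptides in which designated heterodimers form with high stability while
every other combination — all homodimers and all cross-pairings — is
destabilised below a threshold. The number of off-target constraints grows
quadratically: a 4-peptide set must control 8 off-targets, an 8-peptide set
32.

`heterospec` implements the full computational side of this design: library
generation from degenerate templates, additive free-energy scoring and a
linear predicted-Tm model for every pairwise interaction, import-time
removal of promiscuous sequences, and a pruned exhaustive search for
orthogonal sets of two and four coiled coils. A utility module simulates
and fits two-state thermal denaturation curves, the experimental observable
against which such designs are validated.

## Register model

Peptides are represented as `registered_peptide` objects: a sequence plus a
same-length register string over `g a b c d e f -`, where `-` marks capping
residues excluded from all scoring. The shipped design registers chains
g-first and e-last, so a four-heptad (27-residue) core presents exactly
four `a` core positions and eight electrostatic contacts, with no dangling
charged residue at either terminus.

Pairing enumeration is strictly in-register: heptad *n* of one chain faces
heptad *n* of the other (parallel) or heptad *N+1−n* (antiparallel). No
axial sliding is searched. This is a deliberate restriction, not an
approximation of one: the library fixes Leu at every `d` position and
places Asn/Ile options at `a`, and matched Asn–Asn core pairs are expected
to lock a single axial alignment, which is what makes the in-register
enumeration the physically relevant one for this design space. For chains
of unequal length the overlap counted from the N terminus is paired, with a
warning. Internally all coordinates are R's native 1-based indices; reports
and exports are 1-based as well.

Antiparallel `a–d'` core contacts can be enumerated
(`antiparallel_core_pairs()`) but are excluded from scoring by default:
with `d` fixed to Leu they carry no specificity signal here.

## Free-energy scoring and the Tm model

Interaction strength is decomposed additively over enumerated contacts:

* core: ΔG~core~ = Σ over `a–a'` pairs of a lookup table with
  Ile–Ile = −9.2, Asn–Asn = −2.4 and Asn–Ile = −0.5 kcal/mol (double-mutant
  derived values; the large Asn–Ile penalty is the specificity signal);
* electrostatic: ΔG~elec~ = Σ over `g–e'` contacts (or `g–g'`/`e–e'`
  antiparallel) with Glu–Lys = −1.2, Glu–Glu = +0.4, Lys–Lys = −0.3
  kcal/mol.

Missing table entries raise an error by default — in this design space a
missing pair almost always means a register mistake — with a permissive
zero mode for exploratory libraries.

The predicted melting temperature is linear in three terms:

$$T_m = w_{hp}\,\mathrm{HP} + w_{cs}\,\mathrm{CS} + w_{es}\,\mathrm{ES} + c$$

where CS and ES are the two free-energy sums and HP is the mean per-residue
helical propensity over the scored residues of both chains. The mean (not
the sum) keeps HP independent of chain length. Helicity is computed once
per peptide and cached inside the model object, since a library screen
evaluates each chain in thousands of pairs.

Two components of this model are *pluggable by design*:

* **Helicity table.** The default is the Pace–Scholtz consensus helix
  propensity scale (kcal/mol relative to Ala; larger = less helical).
* **Coefficients.** The shipped set is named `"uncalibrated-demo"`:
  round placeholder values (`w_hp = −10`, `w_cs = −2`, `w_es = −4`,
  intercept 0) chosen only so that stabilising contributions raise the
  predicted temperature. They are **not** a regression against measured
  melting data, and absolute temperatures produced with them are
  demonstration values. Every free-energy identity in the test suite is
  coefficient-independent; what the coefficients cannot change — because it
  follows from the ΔΔG structure of the library — is the *ordering*: under
  any model with negative core and electrostatic weights, a designed pair
  scores above every off-target it shares a peptide with. Users with a
  calibrated coefficient set supply it via `tm_model()` or the
  `tm_model.coefficients` config slot. One visible consequence: absolute
  screening criteria (such as the example configuration's 10 °C homodimer
  cutoff) only carry their intended meaning under a calibrated model — under
  the placeholder coefficients they typically reject everything, which is
  the correct symptom of an uncalibrated temperature scale, and the README
  example therefore demonstrates the search with thresholds sized to the
  demo model's output.

## Library generation

`parse_template()` reads a per-position description: fixed residues plus
user-defined wildcard symbols (the symbol table is configuration, not
hard-coded, so any position can be scrambled with any residue options).
The shipped 27-position template uses `h` = {Asn, Ile} at the four `a`
positions and `p` = {Glu, Lys} at the eight `e`/`g` positions, giving
2^4^·2^8^ = 4096 members. `expand_template()` enumerates the Cartesian
product in lexicographic order — deterministically, duplicate-free, in
bounded memory (chunked mixed-radix enumeration rather than materialising
the product) — and applies composition constraints. Requiring exactly two
Asn and two Ile at `a` reduces the core arrangements from 16 to
$\binom{4}{2} = 6$ and the library to 1536; the point of the constraint is
that every in-register off-target heterodimer is then forced to carry
destabilising Asn–Ile core pairs.

DNA-level templates over IUPAC degenerate codes are expanded codon-wise,
translated with the standard genetic code, and deduplicated at the protein
level (a library is a set of peptides; synonymous codons collapse). Stop
codon variants are counted and excluded.

## The interactome screen

`import_filter()` removes unusable sequences at the earliest opportunity:

1. predicted homodimer T~m~ above `max_homodimer_tm` (such a peptide can
   never appear in an orthogonal set, so scoring its pairs is wasted work);
2. optionally, peptides whose *antiparallel* homodimer is fully
   electrostatically complementary (every `g–g'`/`e–e'` contact Glu–Lys).
   The parallel model cannot see the stability of such species — Asn–Asn
   `a–a'` pairing does not exist in the antiparallel geometry, so the
   linear model's fitted domain excludes them — and the safe response is to
   drop the sequence. This filter is purely sequence-based and therefore
   independent of any model coefficients. In the shipped eight-peptide
   example it flags exactly peptides 5–8.

`screen_interactome()` then evaluates all N(N+1)/2 unordered pairs
(homodimers included), each exactly once. For homogeneous libraries the
screen runs a vectorised path over precomputed per-peptide features
(a-residues, span g/e residues, cached helicity sums); a test asserts its
equality with the single-pair reference path. The 1536-member library's
1,180,416-pair interactome screens in well under a minute on one CPU.
Interactions at or above `min_desired_tm` are flagged as *stored* — the
candidate desired pairs — while the full matrix remains exportable
(`export_heatmap()`: a symmetric TSV matrix plus a canonical long table,
written at full precision so exports are byte-stable and round-trip
exactly). The screen has no randomness; results are independent of peptide
input order up to canonical `idA ≤ idB` ordering.

## Orthogonal-set search

`find_pairs()` combines stored candidate interactions pairwise. Candidates
sharing a peptide are skipped without scoring (cross-talk is certain).
For each remaining combination the full 4-peptide mini-interactome — 10
pairings: 2 desired, 4 homodimers, 4 cross heterodimers — is evaluated;
homodimers are re-checked here even though import filtering bounds them, so
the checker is self-contained. A set is accepted iff every off-target is at
or below `max_offtarget_tm_pairs` *and* the worst-case separation
min(desired) − max(off-target) reaches `min_delta_tm_pairs`. The
separation is defined worst-case deliberately: it is the conservative
reading of a "minimum ΔT~m~ between desired and undesired pairs".

`find_quadruples()` repeats the construction over disjoint pairs of
4-peptide sets (36 pairings, 32 off-targets), with its own, typically
looser, thresholds — with four desired pairs and 32 constraints, demanding
pair-level stringency would empty the result. Sets are emitted in
canonical sorted-id form, deduplicated by their desired interactions, and
ranked by (minimum desired T~m~ descending, separation descending,
lexicographic ids) — the head of the ranking is the natural pick for
synthesis. Both searches are exhaustive-with-pruning; on small instances
the test suite checks them against completely unpruned enumeration
oracles, verifies every emitted set independently, and asserts threshold
monotonicity (tightening never adds sets, loosening never removes them).

## Two-state melt utility

Thermal denaturation of a dimeric coiled coil at total monomer
concentration P~t~ follows D ⇌ 2M with K = [M]²/[D]. With ΔC~p~ fixed at 0
(no heat-capacity term is exposed; none is needed for the narrow
temperature spans involved), van 't Hoff gives
K(T) = P~t,ref~ · exp[(ΔH~u~/R)(1/T~m~ − 1/T)], anchored so that the
folded fraction is exactly ½ at T~m~ for the reference concentration —
which is the operational definition of a dimer T~m~. The observed signal
is the folded fraction blended between two linear baselines.

`simulate_melt()` generates such curves (default grid −8 to 95 °C in 1 °C
steps, 150 μM P~t~, seeded Gaussian noise), and `fit_two_state()` recovers
the parameters by Levenberg–Marquardt least squares. Start values are
deterministic and documented: T~m~ from the steepest slope of a 5-point
running mean (evaluated only where the mean is fully defined, so edge
noise cannot masquerade as the transition, with a mid-span fallback
start), ΔH = −50 kcal/mol, baselines from straight lines through the outer
15% of points. Non-convergence, a vanishing transition amplitude (flat
curve) or a midpoint outside the data span yield a flagged result, never a
silent number. On 100 simulated curves with midpoints spanning 40–80 °C
and noise at 1% of the signal range, the median midpoint error is well
under 0.5 °C; the fitted midpoint is invariant to affine rescaling of the
signal axis. `exchange_excess()` implements the dimer-exchange comparison:
the mixture spectrum minus the average of its components, summarised as
excess helicity at 222 nm (positive = repartnering).

## What the synthetic data does and does not show

The generators used in testing — random registered peptides on the
library's register layout, toy interactomes with hand-set or planted
melting temperatures, and simulated two-state melts — emulate the
*structure* of the problem: register geometry, the additive ΔG
decomposition, threshold logic, and the two-state observable. They do not
emulate the failure modes of real peptides: antiparallel or staggered
species beyond the electrostatic-complementarity heuristic, higher-order
oligomers, concentration effects on cross-pairings, or sequence-context
deviations from additivity. A passing suite therefore certifies the
machinery — enumeration, scoring identities, search correctness, fitter
accuracy — not the predictive accuracy of any particular coefficient set
against experiments.

## Numerical and design choices

* Problem sizes in the shipped tests: full 4096/1536 expansions; the
  36-pair example interactome; search oracles on ≤ 12-peptide instances;
  100 melt fits. These keep the default suite within a couple of minutes
  on one CPU while still exercising the full-scale combinatorics.
* Free-energy identities are asserted to 10⁻⁹ (pure table sums).
* The interaction store is the in-memory long table of the `interactome`
  object plus its TSV export, not a client–server database; at the shipped
  library scale the full table is ~1.2 M rows and fits comfortably in
  memory, and only the stored (super-threshold) slice is needed
  downstream.
* Enumeration order of library expansion is lexicographic and stable;
  stability, not any particular order, is the contract relied on by the
  byte-identical-output tests.
* Terminal heptads lacking their `e` residue contribute no electrostatic
  span; only complete `g..e` spans are paired.

## Known limitations

* Absolute predicted temperatures require a calibrated coefficient set;
  the shipped one is a labelled placeholder (see above).
* The antiparallel filter is a binary complementarity heuristic; it does
  not score antiparallel species quantitatively.
* Only dimers are modelled; oligomer-state prediction is out of scope.
* The search enumerates pairs and quadruples; larger orthogonal systems
  (sextuples, octuples) would need recursion over quadruple results and
  are not implemented.
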