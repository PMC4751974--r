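# heterospec

Design of heterospecific (mutually orthogonal) coiled-coil peptide sets by
virtual interactome screening.

## The problem

Parallel dimeric coiled coils follow the heptad repeat `[abcdefg]n`: `a`/`d`
residues form the hydrophobic core, `e`/`g` residues form flanking
electrostatic contacts (each `g` pairs with the partner's `e` five residues
C-terminal). Synthetic biology needs *sets* of such peptides in which each
designated heterodimer forms strongly while every homodimer and
cross-pairing is disfavoured — for an 8-peptide set that means controlling
all 32 off-target interactions at once.

`heterospec` is for protein designers who want to derive such sets
computationally. It:

1. expands degenerate peptide (or degenerate-codon DNA) templates into
   explicit libraries, with composition constraints — e.g. a 27-position
   template with Asn/Ile options at the four `a` positions and Glu/Lys at
   the eight `e`/`g` positions gives 4096 members, reduced to 1536 by
   requiring exactly two Asn and two Ile per core;
2. scores every unordered pair in the resulting interactome (1536 peptides
   → 1,180,416 pairs) with an additive free-energy decomposition
   (core: II = −9.2, NN = −2.4, NI = −0.5 kcal/mol; electrostatic:
   EK = −1.2, EE = +0.4, KK = −0.3 kcal/mol) and a bCIPA-style linear
   melting-temperature model
   `Tm = w_hp·HP + w_cs·CS + w_es·ES + intercept`,
   where HP is mean helical propensity and CS/ES the two ΔG sums;
3. filters promiscuous sequences at import (stable homodimers; optionally
   peptides whose *antiparallel* homodimer is fully electrostatically
   complementary, an orientation the parallel model cannot score);
4. searches the stored interactions for orthogonal sets of two and four
   coiled coils (4- and 8-peptide sets), checking every off-target in each
   candidate mini-interactome against user thresholds;
5. simulates and fits two-state dimer thermal denaturation curves and
   quantifies dimer-exchange excess helicity — the experimental readouts
   used to validate such designs.

The Tm-model coefficients are pluggable; the shipped set is an explicitly
uncalibrated placeholder (see the methods vignette), and all free-energy
identities are coefficient-independent.

## Worked example

The package ships its worked example: the eight selected 32-residue
peptides (ids `1`–`8`, desired pairs 1-2, 3-4, 5-6, 7-8) and the template
they came from.

```r
library(heterospec)
oct <- heterospec_octet()

delta_g_core(oct[["1"]], oct[["2"]])           # -23.2  (2 II + 2 NN)
delta_g_electrostatic(oct[["1"]], oct[["2"]])  # -9.6   (8 EK contacts)
delta_g_core(oct[["1"]], oct[["3"]])           # -2.0   (4 NI pairs: +21.2 vs desired)
delta_g_electrostatic(oct[["3"]], oct[["3"]])  # +3.2   (8 EE: +12.8 vs desired)

x <- screen_interactome(oct, default_tm_model(),
                        screen_criteria(max_homodimer_tm = Inf))
x
#> <interactome> 8 peptides, 36 evaluated pairs (4 stored; model 'uncalibrated-demo')
head(x$interactions[order(-x$interactions$tm), ], 5)
#>    idA idB       tm stored
#> 2    1   2 82.52963   TRUE
#> 17   3   4 82.52963   TRUE
#> 28   5   6 82.52963   TRUE
#> 35   7   8 82.52963   TRUE
#> 22   4   4 53.93704  FALSE
```

Only the four designed heterodimers reach the 70 °C storage threshold; the
warmest off-target is peptide 4's homodimer. (Absolute values here come
from the placeholder coefficients — the ordering, not the temperatures, is
the meaningful output.) Searching with demonstration thresholds sized to
that model recovers the full octet as an orthogonal quadruple:

```r
crit <- screen_criteria(max_homodimer_tm = Inf, min_desired_tm = 70,
                        max_offtarget_tm_pairs = 60, min_delta_tm_pairs = 25,
                        max_offtarget_tm_quads = 60, min_delta_tm_quads = 25)
pairs <- find_pairs(x, crit)          # 6 orthogonal 4-peptide sets
quads <- find_quadruples(pairs, x, crit)
quads[[1]]
#> <orthogonal_set> {1,2,3,4,5,6,7,8}: 4 desired (min Tm 82.5),
#>   max off-target 53.9, delta 28.6
```

The antiparallel homodimer filter (sequence-based, coefficient-free) flags
exactly the second half of the octet:

```r
res <- import_filter(oct, default_tm_model(),
                     screen_criteria(max_homodimer_tm = Inf,
                                     antiparallel_filter = TRUE))
res$rejected$id     # "5" "6" "7" "8"
```

Melt-curve utility:

```r
fit <- fit_two_state(simulate_melt(tm = 63, enthalpy = -50,
                                   noise_sd = 0.3, seed = 4))
fit
#> <melt_fit> Tm = 62.56 degC, dH = -48.9 kcal/mol, rss = 6.711
```

A thin CLI over the same functions is installed at
`system.file("scripts", "heterospec", package = "heterospec")`
(subcommands `generate-library`, `screen`, `find-pairs`,
`find-quadruples`, `score-pair`, `meltfit`, `make-fixtures`, `run`).

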