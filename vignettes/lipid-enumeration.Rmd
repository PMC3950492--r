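---
title: "Enumerating the glycerophospholipid space: model, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating the glycerophospholipid space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidmz)
```

## The compositional model

Membrane glycerophospholipids are derivatives of *sn*-glycero-3-phosphate:
two carbon chains attach at the *sn*-1 and *sn*-2 positions of the glycerol
backbone and a polar headgroup esterifies the phosphate at *sn*-3. `lipidmz`
models a species as exactly this triple, and assembles its elemental
composition additively:

> composition = C3H9O6P (glycerol-3-phosphate core)
>             + headgroup delta + sn-1 chain delta + sn-2 chain delta

Chain deltas are condensation deltas (the free substituent less water). An
acyl (ester-linked) chain with `c` carbons and `u` double bonds contributes
`C_c H_(2c-2u-2) O`; an alkyl (ether, plasmanyl, `O-`) chain contributes
`C_c H_(2c-2u)`; an alkenyl (vinyl-ether, plasmenyl, `P-`) chain contributes
`C_c H_(2c-2u-2)`. Following standard plasmalogen shorthand, the `u` of an
alkenyl chain counts only double bonds *beyond* the fixed vinyl-ether bond
at chain position 1 — so `P-18:0` carries exactly one C=C, and `P-c:u` is
isobaric with `O-c:(u+1)`. A lyso position is a free hydroxyl, written
`0:0`, contributing nothing.

Sixteen headgroup variants are registered, covering twelve LIPID MAPS GP
subclasses: PA, PPA, PC, PE, PG, PGP, PS, CDP-DG, PI, and the seven
phosphoinositide metabolites PI[3]P, PI[4]P, PI[5]P, PI[3,4]P2, PI[3,5]P2,
PI[4,5]P2 and PI[3,4,5]P3. Each PIPx delta is the PI delta plus one HPO3
(79.96633 Da exact) per phosphorylated inositol carbon; the carbon positions
(subsets of {3,4,5}) are carried so that structure generation places the
phosphates on the declared ring carbons. The PC composition is the neutral
(zwitterion-summed) formula so that neutral-mass bookkeeping and adduct
arithmetic stay separate concerns. PPA is modelled as the glycerol
pyrophosphate monoester and the CDP-DG headgroup as cytidine monophosphate
condensed onto the backbone phosphate (the canonical pyrophosphate bridge
of LIPID MAPS GP11/GP13).

Masses come from a pinned plain-text constants file
(`inst/extdata/element_masses.txt`): AME2020 monoisotopic masses, IUPAC
CIAAW 2021 standard atomic weights, and the CODATA electron mass, with the
provenance string stored alongside the values. Charged adducts
([M+H]+, [M+K]+, [M+Li]+, [M+Na]+, [M−H]−) are corrected by one electron
mass per elementary charge: [M+H]+ adds a proton, 1.0072765 Da. The
correction is physically correct and, at the tightest supported tolerance
(±0.0001 Da), observable; the convention is stated here and in the
constants file because older tools differ on it. All six modes are single
charge, so m/z equals the shifted neutral mass; isotope distributions,
fine structure and multiple charging are out of scope.

## The chain rule and the size of the space

The enumerated space is governed by a `chain_rule()`: chains of 0–30
carbons with up to six unsaturations, acyl/alkyl/alkenyl linkages at both
sn positions, lyso hydroxyls at both positions, and the di-lyso species
included. Unsaturation feasibility is enforced: a `(c, u)` pair is only
admissible if at least one legal double-bond placement exists under the
drawing rule (below). Species are *ordered* (sn-1, sn-2) pairs — a species
and its chain inversion are distinct entries with equal mass, because the
two placements are biologically distinct and mass spectrometry alone cannot
separate them.

Under the default rule each position admits 498 chains (168 acyl + 168
alkyl + 161 alkenyl + the hydroxyl), giving 248,004 species per headgroup
class, 1,984,032 for the eight-member PI superfamily, and 3,968,064 in
total. Three structural identities hold by construction and are asserted in
the test suite: the per-class count is identical for all sixteen headgroups,
the PI-superfamily total is 8 × the per-class count, and the grand total is
16 × the per-class count.

The historical per-class figure published for this database family, 92,073,
is *not* reproducible from any member of the documented rule family, and we
state this openly rather than tune toward it. The argument is short:
every rule of the form "ordered pairs over two per-position chain spaces"
yields a count `n1 × n2` (minus one if the di-lyso species is excluded),
with each `n` at most 631 (3 linkages × 30 carbons × 7 unsaturation values
+ 1 hydroxyl). But 92,073 = 3 × 47 × 653 and 92,074 = 2 × 41 × 1123 have no
factorisation with both factors ≤ 631, so no such rule — whatever its
feasibility thresholds — can produce either number. Coupled-constraint
variants (capping total unsaturation, total carbons, or ether-chain counts)
were also searched and none reaches the figure with a coherent, symmetric
parameterisation. `calibrate_chain_rule()` performs this search over the
documented family by exact closed-form counting and reports the nearest
configurations honestly; the shipped default remains the rule stated above,
and the regression tests pin *our* counts.

```{r}
cal <- calibrate_chain_rule(92073L)
length(cal$matches)       # no exact member
head(cal$nearest, 3)
```

## Double-bond placement and structures

Drawn structures restrict chain double bonds to *cis* (Z) configuration,
placed "sequentially in every location" along the chain subject to a
spacing rule. A placement is a vector of starts `s_1 < ... < s_u`; bond `s`
occupies carbons `s` and `s+1`, the first start obeys `s_min` (2 for acyl —
carbon 1 is the carbonyl carbon — 2 for alkyl, 3 for the placeable bonds of
alkenyl chains, which sit beyond the vinyl ether), and consecutive starts
differ by at least `d`. We read "separated by a minimum of two carbons" as
start-to-start spacing `d = 2`, which forbids cumulated dienes but allows
conjugation; the stricter readings `d = 3` or `d = 4` would make a 10:4
chain — which the database must contain for the worked m/z-642 example —
undrawable, so they are rejected as defaults but remain available as
configuration. The number of placements has the closed form
`choose((c - s_min) - (d-1)(u-1), u)`, verified against exhaustive
generation for all `c ≤ 14`, `u ≤ 6`, `d ∈ {2,3,4}`.

The canonical structure of a species uses the earliest-position
("sequential") placement; `all_isomers = TRUE` emits the full cartesian
product of sn-1 and sn-2 placements in lexicographic order. Structures are
emitted as SMILES (and SDF via ChemmineR/ChemmineOB): the glycerol sn-2
stereocentre is specified explicitly (validated against the curated
1,2-diacyl-*sn*-glycero-3-phosphate convention), ester/ether/vinyl-ether
linkage chemistry is explicit, every stereo-flagged C=C is Z, and the
inositol ring is emitted without ring stereo by default. An opt-in
`inositol_stereo` flag emits the myo-inositol ring template (validated by
its 1,2,3,5-cis hydroxyl face pattern and meso symmetry); the
enantiomer-level numbering direction of the phosphorylated ring is fixed by
the template and has not been validated against curated reference
structures, which is why the flag defaults to off. A double bond ending on
the terminal carbon (=CH2) is non-stereogenic and necessarily carries no
flag. The test suite cross-checks ~550 generated structures against an
independent cheminformatics toolkit (RDKit): derived molecular formula
equal to the assembled composition, no E flags, and C=C counts equal to
`u1 + u2` plus one per alkenyl chain.

## Search semantics

The index stores neutral exact and average masses sorted once; a query m/z
window is transformed back to the neutral axis (inverse adduct transform),
candidates are retrieved by binary search, and the exact inclusive
predicate |theoretical − query| ≤ tolerance is applied on the m/z axis.
Tolerances are absolute Da, symmetric, inclusive at both ends, and
restricted to [0.0001, 2]; out-of-range values are rejected rather than
clamped so that behaviour never silently changes. Filters compose on top:
class (single headgroup, `PI_PLUS_PIPX`, `ALL_WITHOUT_PIPX` — which keeps
the PI precursor but drops the PIPx metabolites — or `ALL`), chain parity
(`even_only` keeps species whose every non-lyso chain has an even carbon
count), and best-prediction (all non-lyso chains must appear in a
configurable common-chain list; the default list is the prevalent mammalian
acyl chains 16:0, 16:1, 18:0, 18:1, 18:2, 18:3, 20:4, 22:6, a pragmatic
stand-in for externally curated abundance data). Indexed search is tested
for exact equality with a brute-force linear scan over 1,000 random
queries, plus tolerance monotonicity and the class-filter algebra
identities (PI ∪ non-PIPx = ALL, PI ∩ non-PIPx = PI).

## Worked example

```{r}
comp <- species_composition("PI45P2", chain("acyl", 10, 4),
                            chain("hydroxyl", 0, 0))
formula_string(comp)
adduct_mz(exact_mass(comp), "M+H")
```

The [M+H]+ m/z of PI[4,5]P2(10:4/0:0), 641.0796, falls inside 642 ± 1, so
an exact-mass, even-parity search of the PI superfamily at m/z 642 with a
1 Da tolerance returns the species together with its sn-1/sn-2 inversion
PI[4,5]P2(0:0/10:4); its four double bonds admit `choose(5, 4) = 5` cis
positional isomers, the first being Δ2,4,6,8.

## Numerical and scale choices

All masses are computed and compared in double precision; CSV exports print
masses with four decimals, matching the tightest supported tolerance.
Candidate retrieval widens the neutral-mass window by 1 nDa before the
exact boundary predicate, making the indexed result identical to the linear
scan even at window edges. Enumeration is vectorised; the full 16-class
build (~4M species) completes in well under five minutes on one CPU, and
the unit suite uses reduced databases (chains to 8–10 carbons, 2–4 classes)
chosen so that brute-force oracles stay exact and fast. Degenerate inputs
are defined, not special-cased: an empty chain space yields an empty class,
an empty index returns no hits, and an empty peak list writes a header-only
results file.

## Known limitations

The database is combinatorial, not biological: most enumerated species have
never been observed, and the search deliberately returns every theoretical
match. Sphingolipids, sterols, oxidised or branched chains, chains beyond
30 carbons, more than six unsaturations, ppm tolerances, multiply charged
ions, isotope patterns and MS/MS spectra are out of scope. 2D depiction
(atom coordinates, image rendering) is delegated to downstream tools via
the SMILES/SDF exports.
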