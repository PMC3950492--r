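# lipidmz

Assigning molecular identities to peaks in lipidomic mass spectra is hard
because, unlike genes or peptides, lipids carry no sequence signature: an
observed m/z is compatible with every theoretically possible species whose
mass falls inside the instrument's tolerance window. `lipidmz` is an R
toolkit for lipidomics researchers that makes that candidate set explicit.
It enumerates the *complete* combinatorial space of glycerophospholipids —
sixteen polar-headgroup variants spanning twelve LIPID MAPS GP subclasses,
including the full phosphoinositide family (PI and its PIP, PIP2, PIP3
metabolites phosphorylated on inositol carbons 3, 4 and/or 5) — computes
exact (monoisotopic) and average masses and single-charge adduct m/z values,
searches the database for species matching a query m/z, and generates
machine-readable structures (SMILES/SDF) including every cis double-bond
positional isomer.

## The model

A species is an ordered triple: headgroup + sn-1 chain + sn-2 chain on the
*sn*-glycero-3-phosphate backbone. Its elemental composition is assembled
additively,

    composition = C3H9O6P + Δ(headgroup) + Δ(sn-1) + Δ(sn-2)

where chain deltas follow the condensation formulas — acyl `c:u` adds
`C_c H_(2c−2u−2) O`, alkyl (`O-`) adds `C_c H_(2c−2u)`, alkenyl (`P-`) adds
`C_c H_(2c−2u−2)` (the vinyl-ether double bond is not counted in `u`), and a
lyso position (`0:0`) adds nothing — and each PIPx headgroup delta is the PI
delta plus one HPO3 per ring phosphate. Chains range over 0–30 carbons with
up to six unsaturations and all three linkage chemistries at both positions;
sn-1/sn-2 chain inversions are distinct species. Masses use pinned AME2020 /
IUPAC 2021 constants; charged adducts ([M+H]+, [M+K]+, [M+Li]+, [M+Na]+,
[M−H]−) include the electron-mass correction. Search tolerances are absolute
Da in [0.0001, 2], inclusive; structures place cis double bonds sequentially
with start-to-start spacing ≥ 2 carbons (`choose((c−s_min)−(d−1)(u−1), u)`
isomers per chain). The methods vignette
(`vignettes/lipid-enumeration.Rmd`) derives and motivates every rule.

## Worked example

The classic worked search: which phosphoinositides could explain a peak at
m/z 642 under [M+H]+, exact mass, ±1 Da, even-carbon chains only?

```r
library(lipidmz)

sp <- parse_species_name("PI[4,5]P2(10:4/0:0)")
sp
#> <species> PI[4,5]P2(10:4/0:0)  C19H31O18P3  exact 640.0723 Da
adduct_mz(exact_mass(sp$composition), "M+H")
#> [1] 641.0796

idx  <- build_index(build_database(chain_rule(carbon_max = 10),
                                   class_filter_members("PI_PLUS_PIPX")))
hits <- search_mz(idx, 642, 1, "M+H", "exact", "PI_PLUS_PIPX", "even_only")
nrow(hits)
#> [1] 90
hits[name %in% c("PI[4,5]P2(10:4/0:0)", "PI[4,5]P2(0:0/10:4)"),
     c("name", "formula", "theoretical_mz", "delta_da")]
#>                   name     formula theoretical_mz  delta_da
#> 1: PI[4,5]P2(0:0/10:4) C19H31O18P3        641.0796 -0.920398
#> 2: PI[4,5]P2(10:4/0:0) C19H31O18P3        641.0796 -0.920398
```

The computed [M+H]+ m/z, 641.0796, lies inside 642 ± 1, so the species is
returned together with its sn-1/sn-2 chain inversion — same mass, distinct
identity. Its four double bonds admit five cis positional isomers:

```r
structure_records(sp, all_isomers = TRUE)$sn1_pattern
#> [1] "2,4,6,8" "2,4,6,9" "2,4,7,9" "2,5,7,9" "3,5,7,9"
species_smiles(sp)
#> [1] "P(=O)(O)(OC[C@H](O)COC(=O)/C=C\\C=C/C=C\\C=C/C)OC1C(O)C(O)C(OP(=O)(O)O)C(OP(=O)(O)O)C1O"
```

A thin command-line tool wraps the same functions:

```sh
exec/lipidmz.R build  --out db/                       # full database + counts summary
exec/lipidmz.R search --mz 642 --tol 1 --mode M+H \
                      --class pi+pipx --parity even --out results.csv
exec/lipidmz.R draw   "PI[4,5]P2(10:4/0:0)" --all-isomers --out isomers.smi
```

Under the default chain rule each class counts 248,004 species (498 chains
per position), the PI superfamily 1,984,032, and the full sixteen-class
database 3,968,064. `calibrate_chain_rule()` searches the documented rule
family against any target per-class count and reports exact matches or the
nearest configurations; see the vignette for why the historically published
per-class figure for this database family is not attainable by any member
of that family, and how this is handled openly.

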