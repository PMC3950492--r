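# Double-bond placement combinatorics and rule-based structure generation,
# cross-checked against RDKit as an independent cheminformatics toolkit.

test_that("placement counts match stars-and-bars and exhaustive generation", {
  for (d in 2:4) {
    rule <- chain_rule(spacing = d)
    for (cc in 2:14) for (u in 0:6) {
      pl <- placements(cc, u, "acyl", rule)
      expect_identical(length(pl), count_placements(cc, u, "acyl", rule))
      brute <- brute_placements(cc, u, s_min = 2, d = d)
      expect_identical(length(pl), length(brute))
      if (length(pl) > 0) expect_identical(pl, brute)   # same lex order
    }
  }
})

test_that("placements respect linkage geometry and pattern shape", {
  pl <- placements(10, 4)
  expect_identical(length(pl), 5L)
  expect_identical(pl[[1]], c(2L, 4L, 6L, 8L))        # sequential pattern
  expect_identical(placements(12, 0), list(integer(0)))
  expect_identical(placements(4, 3), list())           # infeasible
  expect_identical(count_placements(4, 3), 0L)
  # alkenyl extra bonds start after the vinyl bond plus spacing
  pl_v <- placements(8, 1, "alkenyl")
  expect_true(all(vapply(pl_v, min, 0L) >= 3L))
  # every pattern fits the chain and the spacing rule
  for (p in placements(13, 3)) {
    expect_true(all(diff(p) >= 2))
    expect_true(p[1] >= 2 && p[3] + 1 <= 13)
  }
})

test_that("generated structures parse and conserve the species formula", {
  set.seed(23)
  picks <- list()
  for (i in 1:40) {
    h <- sample(headgroups()$id, 1)
    picks[[i]] <- species(h, random_chain(), random_chain())
  }
  smiles <- vapply(picks, function(sp)
    species_smiles(sp, inositol_stereo = (stats::runif(1) < 0.5 &&
                                          startsWith(sp$head, "PI"))), "")
  res <- rdkit_check(smiles)
  for (i in seq_along(picks)) {
    sp <- picks[[i]]
    expect_identical(res$formula[i], formula_string(sp$composition),
                     info = sp$name)
    # every emitted stereo flag is Z; no E flag ever appears
    expect_identical(res$e[i], 0L, info = sp$name)
    want_cc <- sp$sn1$unsat + sp$sn2$unsat +
      (sp$sn1$linkage == "alkenyl") + (sp$sn2$linkage == "alkenyl")
    expect_identical(res$cc[i], want_cc, info = sp$name)
  }
})

test_that("hand-picked structures carry the expected double bonds", {
  res <- rdkit_check(c(
    species_smiles("PA(0:0/0:0)"),
    species_smiles("PI[4,5]P2(10:4/0:0)"),
    species_smiles("PE(P-16:0/0:0)"),
    species_smiles("PC(18:0/18:0)")))
  expect_identical(res$formula[1], "C3H9O6P")
  expect_identical(res$cc[2], 4L)                      # all four on sn-1
  expect_identical(res$z[2], 4L)
  expect_identical(res$e[2], 0L)
  # the vinyl ether contributes exactly one (cis) C=C at chain position 1
  expect_identical(res$cc[3], 1L)
  expect_identical(res$z[3], 1L)
  expect_identical(res$cc[4], 0L)
})

test_that("all_structures is the cartesian product of the placements", {
  rec <- structure_records("PI[4,5]P2(10:4/0:0)", all_isomers = TRUE)
  expect_identical(nrow(rec), 5L)                      # 5 x 1
  expect_identical(anyDuplicated(rec$smiles), 0L)
  expect_identical(rec$sn1_pattern[1], "2,4,6,8")
  rec1 <- structure_records("PC(18:0/18:0)", all_isomers = TRUE)
  expect_identical(nrow(rec1), 1L)                     # fully saturated

  set.seed(31)
  for (i in 1:10) {
    sp <- species("PG", random_chain(chain_rule(carbon_max = 12)),
                  random_chain(chain_rule(carbon_max = 12)))
    n1 <- length(placements(sp$sn1$carbons, sp$sn1$unsat, sp$sn1$linkage))
    n2 <- length(placements(sp$sn2$carbons, sp$sn2$unsat, sp$sn2$linkage))
    expect_identical(nrow(structure_records(sp, all_isomers = TRUE)),
                     max(1L, n1) * max(1L, n2) *
                       as.integer(n1 > 0 && n2 > 0), info = sp$name)
  }
})

test_that("pattern validation rejects mismatched placements", {
  sp <- parse_species_name("PI(10:2/0:0)")
  expect_error(species_smiles(sp, p1 = c(2L, 3L)), "spacing")
  expect_error(species_smiles(sp, p1 = c(2L)), "does not match")
  expect_error(species_smiles(sp, p1 = c(8L, 10L)), "exceeds the chain")
  expect_error(species_smiles(sp, p1 = c(1L, 4L)), "s_min")
})

test_that("SMILES and SDF exports round-trip", {
  rec <- structure_records("PI[4,5]P2(10:4/0:0)", all_isomers = TRUE)
  smi_f <- tempfile(fileext = ".smi")
  write_smiles(rec, smi_f)
  lines <- readLines(smi_f)
  expect_identical(length(lines), 5L)
  expect_true(all(grepl("\tPI\\[4,5\\]P2", lines)))

  sdf_f <- tempfile(fileext = ".sdf")
  write_sdf(rec[1, ], sdf_f)
  sdf <- ChemmineR::read.SDFset(sdf_f)
  expect_identical(length(sdf), 1L)
  # formula derived by the independent toolkit matches the composition
  mf <- as.character(ChemmineR::MF(sdf[[1]], addH = TRUE))
  expect_identical(mf, "C19H31O18P3")
})
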