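# Chain spaces, class enumeration, name grammar, calibration.

toy_rule <- chain_rule(carbon_max = 2, max_unsat = 0,
                       linkages_sn1 = "acyl", linkages_sn2 = "acyl")

test_that("chain_space is deterministic, sorted, and rule-driven", {
  s <- chain_space(toy_rule, "sn1")
  expect_identical(s$linkage, c("hydroxyl", "acyl", "acyl"))
  expect_identical(s$carbons, c(0L, 1L, 2L))

  none <- chain_rule(linkages_sn1 = character(0),
                     linkages_sn2 = character(0),
                     lyso_sn1 = FALSE, lyso_sn2 = FALSE, dilyso = FALSE)
  expect_identical(nrow(chain_space(none, "sn1")), 0L)
  expect_identical(nrow(enumerate_class("PA", none)), 0L)

  # closed-form count equals materialised size across assorted rules
  rules <- list(toy_rule, chain_rule(), chain_rule(spacing = 3),
                chain_rule(enforce_feasible = FALSE),
                chain_rule(carbon_max = 12, linkages_sn2 = "acyl",
                           lyso_sn2 = FALSE))
  for (r in rules) for (pos in c("sn1", "sn2"))
    expect_identical(count_chain_space(r, pos), nrow(chain_space(r, pos)))
})

test_that("chain rule validation rejects impossible geometry", {
  expect_error(chain_rule(spacing = 1), "spacing")
  expect_error(chain_rule(s_min = c(acyl = 1, alkyl = 2, alkenyl = 3)),
               "carbonyl")
})

test_that("feasibility enforcement excludes undrawable (c,u) pairs", {
  r <- chain_rule(carbon_max = 8)
  s <- chain_space(r, "sn1")
  acyl <- s[s$linkage == "acyl", ]
  # acyl (c,u) needs c >= 2u + 1 under s_min = 2, d = 2
  expect_true(all(acyl$carbons >= 2 * acyl$unsat + 1))
  r_off <- chain_rule(carbon_max = 8, enforce_feasible = FALSE)
  s_off <- chain_space(r_off, "sn1")
  expect_true(nrow(s_off) > nrow(s))
  # even with feasibility off, chains must have a valid formula
  expect_true(all(s_off$carbons >= s_off$unsat +
                    ifelse(s_off$linkage == "alkyl", 0, 1) |
                  s_off$linkage == "hydroxyl"))
})

test_that("class enumeration forms all ordered chain pairs", {
  db <- enumerate_class("PA", toy_rule)
  expect_identical(nrow(db), 9L)                     # 3 x 3, di-lyso included
  expect_identical(anyDuplicated(db$name), 0L)
  # inversions are distinct rows
  expect_true(all(c("PA(1:0/2:0)", "PA(2:0/1:0)", "PA(0:0/0:0)") %in% db$name))
  # deterministic byte-identical streams
  expect_identical(db, enumerate_class("PA", toy_rule))
  # di-lyso excluded on request
  no_dl <- chain_rule(carbon_max = 2, max_unsat = 0, linkages_sn1 = "acyl",
                      linkages_sn2 = "acyl", dilyso = FALSE)
  expect_identical(nrow(enumerate_class("PA", no_dl)), 8L)
  expect_false("PA(0:0/0:0)" %in% enumerate_class("PA", no_dl)$name)
  # closed-form count identity
  expect_identical(nrow(db), count_class(toy_rule))
})

test_that("per-class count is headgroup-independent and mass columns check out", {
  r <- chain_rule(carbon_max = 6)
  counts <- vapply(c("PA", "PC", "PI345P3"), function(h)
    nrow(enumerate_class(h, r)), 0L)
  expect_identical(length(unique(counts)), 1L)
  db <- enumerate_class("PI", r)
  i <- match("PI(4:1/O-5:0)", db$name)
  sp <- parse_species_name("PI(4:1/O-5:0)")
  expect_equal(db$exact_mass[i], exact_mass(sp$composition),
               tolerance = 1e-9)
  expect_equal(db$average_mass[i], average_mass(sp$composition),
               tolerance = 1e-9)
  expect_identical(db$formula[i], formula_string(sp$composition))
})

test_that("default-rule sizes are pinned (regression)", {
  r <- chain_rule()
  expect_identical(count_chain_space(r, "sn1"), 498L)
  expect_identical(count_class(r), 248004L)
})

test_that("species names round-trip through the parser", {
  set.seed(5)
  for (i in 1:40) {
    h <- sample(headgroups()$id, 1)
    sp <- species(h, random_chain(), random_chain())
    back <- parse_species_name(sp$name)
    expect_identical(back$name, sp$name)
    expect_identical(unclass(back$composition), unclass(sp$composition))
  }
})

test_that("parser accepts whitespace/subscript variants and rejects junk", {
  sp <- parse_species_name("PI[3,4, 5]P_3(*O*-16:0/20:4)")
  expect_identical(sp$head, "PI345P3")
  expect_identical(sp$sn1$linkage, "alkyl")
  expect_identical(sp$sn1$carbons, 16L)
  expect_identical(sp$sn2$linkage, "acyl")
  expect_identical(sp$sn2$carbons, 20L)
  expect_identical(sp$sn2$unsat, 4L)
  expect_identical(parse_species_name("CDPDG(18:2/16:0)")$head, "CDPDG")
  expect_identical(parse_species_name("CDP-DG(18:2/16:0)")$head, "CDPDG")

  expect_error(parse_species_name("PI(40:0/0:0)"), "out of range")
  expect_error(parse_species_name("PQ(18:0/18:0)"), "unknown headgroup")
  expect_error(parse_species_name("PI(18:0)"), "malformed")
  expect_error(parse_species_name("PI(18.0/18:0)"), "malformed chain")
  expect_error(parse_species_name("PI(P-0:0/18:0)"), "lyso")
})

test_that("calibration finds exact members when they exist and reports misses", {
  fam <- list(toy_rule,
              chain_rule(carbon_max = 3, max_unsat = 0,
                         linkages_sn1 = "acyl", linkages_sn2 = "acyl"),
              chain_rule(linkages_sn1 = character(0),
                         linkages_sn2 = character(0), lyso_sn1 = FALSE,
                         lyso_sn2 = FALSE, dilyso = FALSE))
  hit9 <- calibrate_chain_rule(9L, fam)
  expect_identical(length(hit9$matches), 1L)
  expect_identical(count_class(hit9$matches[[1]]), 9L)
  hit0 <- calibrate_chain_rule(0L, fam)
  expect_identical(count_class(hit0$matches[[1]]), 0L)
  # a target between members: no match, nearest reported with signed diff
  miss <- calibrate_chain_rule(10L, fam)
  expect_identical(length(miss$matches), 0L)
  expect_identical(miss$nearest$count[1], 9L)
  expect_identical(miss$nearest$diff[1], -1L)
})

test_that("chain rules round-trip through the YAML config", {
  r <- chain_rule(carbon_max = 12, spacing = 3, lyso_sn2 = FALSE,
                  dilyso = FALSE, linkages_sn2 = c("acyl", "alkyl"))
  f <- tempfile(fileext = ".yaml")
  write_chain_rule(r, f)
  expect_identical(read_chain_rule(f), r)
})
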