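# Structural components: the sn-glycero-3-phosphate core, the sixteen polar
# headgroup variants, and the sn-1/sn-2 chain composition deltas. A species
# composition is assembled as core + headgroup delta + chain deltas.

#' Chain linkage types
#'
#' `acyl` (ester), `alkyl` (ether, `O-` prefix, plasmanyl), `alkenyl`
#' (vinyl ether, `P-` prefix, plasmenyl) and `hydroxyl` (a free hydroxyl at
#' that sn position, i.e. a lyso chain, written `0:0`).
#'
#' @return Character vector of linkage labels.
#' @export
linkages <- function() c("hydroxyl", "acyl", "alkyl", "alkenyl")

#' Construct a chain
#'
#' One sn-position substituent: a linkage, a carbon count `c` (0-30) and an
#' unsaturation count `u` (0-6). `c = 0` if and only if the linkage is
#' `hydroxyl` (and then `u = 0`). For alkenyl chains `u` counts only the
#' double bonds *beyond* the fixed vinyl-ether bond at chain position 1, the
#' standard plasmalogen shorthand (so `P-18:0` carries exactly one C=C).
#'
#' @param linkage One of [linkages()].
#' @param carbons Integer 0-30.
#' @param unsat Integer 0-6.
#' @return A `chain` object (list with `linkage`, `carbons`, `unsat`).
#' @examples
#' chain("acyl", 18, 0)
#' chain("hydroxyl", 0, 0)
#' @export
chain <- function(linkage, carbons = 0L, unsat = 0L) {
  linkage <- match.arg(linkage, linkages())
  carbons <- as.integer(carbons); unsat <- as.integer(unsat)
  if (carbons < 0L || carbons > 30L)
    stop("carbons out of range 0-30: ", carbons)
  if (unsat < 0L || unsat > 6L)
    stop("unsaturations out of range 0-6: ", unsat)
  if ((carbons == 0L) != (linkage == "hydroxyl"))
    stop("carbons = 0 if and only if linkage = 'hydroxyl'")
  if (linkage == "hydroxyl" && unsat != 0L)
    stop("a hydroxyl (lyso) chain has no unsaturations")
  if (linkage != "hydroxyl" && 2L * carbons - 2L * unsat - 2L < 0L)
    stop("unsaturation count too large for ", carbons, " carbons")
  structure(list(linkage = linkage, carbons = carbons, unsat = unsat),
            class = "chain")
}

#' @export
print.chain <- function(x, ...) {
  cat("<chain> ", chain_token(x$linkage, x$carbons, x$unsat), " (", x$linkage,
      ")\n", sep = "")
  invisible(x)
}

#' Composition delta contributed by a chain (vectorised core)
#'
#' Condensation deltas relative to a free backbone hydroxyl:
#' hydroxyl contributes nothing; acyl `(c,u)` contributes `C_c H_(2c-2u-2) O`
#' (the fatty acid less water); alkyl `(c,u)` contributes `C_c H_(2c-2u)`
#' (the fatty alcohol less water); alkenyl `(c,u)` contributes
#' `C_c H_(2c-2u-2)`, identical in composition to alkyl `(c, u+1)` because
#' the vinyl-ether double bond is not counted in `u`.
#'
#' @param linkage,carbons,unsat Parallel vectors of chain fields.
#' @return A data.frame with integer columns `C`, `H`, `O`.
#' @keywords internal
chain_delta_counts <- function(linkage, carbons, unsat) {
  carbons <- as.integer(carbons); unsat <- as.integer(unsat)
  H <- ifelse(linkage == "alkyl", 2L * carbons - 2L * unsat,
              2L * carbons - 2L * unsat - 2L)
  H <- ifelse(linkage == "hydroxyl", 0L, H)
  C <- ifelse(linkage == "hydroxyl", 0L, carbons)
  O <- ifelse(linkage == "acyl", 1L, 0L)
  if (any(H < 0L))
    stop("unsaturation count too large for chain formula (negative H)")
  data.frame(C = as.integer(C), H = as.integer(H), O = as.integer(O))
}

#' Composition delta of a single chain
#'
#' @param ch A [chain()].
#' @return An `element_count`.
#' @examples
#' chain_delta(chain("acyl", 18, 0))  # C18H34O
#' @export
chain_delta <- function(ch) {
  stopifnot(inherits(ch, "chain"))
  d <- chain_delta_counts(ch$linkage, ch$carbons, ch$unsat)
  ec(C = d$C, H = d$H, O = d$O)
}

#' The sn-glycero-3-phosphate core composition
#'
#' Glycerol-3-phosphate, C3H9O6P: glycerol (C3H8O3) condensed with phosphoric
#' acid (H3PO4) less water. Every species composition is this core plus a
#' headgroup delta plus the two chain deltas.
#'
#' @return An `element_count`.
#' @export
glycerophosphate_core <- function() ec(C = 3, H = 9, O = 6, P = 1)

.headgroup_table <- function() {
  if (!is.null(.lipidmz_env$headgroups)) return(.lipidmz_env$headgroups)
  hpo3 <- "HO3P"
  pi_delta <- "C6H10O5"
  add_p <- function(x, n) {
    out <- ec_parse(x)
    for (i in seq_len(n)) out <- ec_combine(out, ec_parse(hpo3))
    formula_string(out)
  }
  tab <- data.frame(
    id = c("PA", "PPA", "PC", "PE", "PG", "PGP", "PS", "CDPDG",
           "PI", "PI3P", "PI4P", "PI5P", "PI34P2", "PI35P2", "PI45P2",
           "PI345P3"),
    label = c("PA", "PPA", "PC", "PE", "PG", "PGP", "PS", "CDP-DG",
              "PI", "PI[3]P", "PI[4]P", "PI[5]P", "PI[3,4]P2", "PI[3,5]P2",
              "PI[4,5]P2", "PI[3,4,5]P3"),
    subclass = c("Glycerophosphates", "Glyceropyrophosphates",
                 "Glycerophosphocholines", "Glycerophosphoethanolamines",
                 "Glycerophosphoglycerols", "Glycerophosphoglycerophosphates",
                 "Glycerophosphoserines", "Cytidine 5'-diphosphate glycerols",
                 "Glycerophosphoinositols",
                 "Glycerophosphoinositol monophosphates",
                 "Glycerophosphoinositol monophosphates",
                 "Glycerophosphoinositol monophosphates",
                 "Glycerophosphoinositol bisphosphates",
                 "Glycerophosphoinositol bisphosphates",
                 "Glycerophosphoinositol bisphosphates",
                 "Glycerophosphoinositol trisphosphates"),
    lipidmaps_code = c("GP10", "GP11", "GP01", "GP02", "GP04", "GP05",
                       "GP03", "GP13", "GP06", "GP07", "GP07", "GP07",
                       "GP08", "GP08", "GP08", "GP09"),
    delta_formula = c("", hpo3, "C5H11N", "C2H5N", "C3H6O2",
                      add_p("C3H6O2", 1), "C3H5NO2", "C9H12N3O7P",
                      pi_delta, add_p(pi_delta, 1), add_p(pi_delta, 1),
                      add_p(pi_delta, 1), add_p(pi_delta, 2),
                      add_p(pi_delta, 2), add_p(pi_delta, 2),
                      add_p(pi_delta, 3)),
    phosphate_positions = c("", "", "", "", "", "", "", "",
                            "", "3", "4", "5", "3,4", "3,5", "4,5", "3,4,5"),
    stringsAsFactors = FALSE
  )
  .lipidmz_env$headgroups <- tab
  tab
}

#' The headgroup registry
#'
#' The sixteen polar-headgroup variants (eight non-phosphoinositide classes,
#' PI, and the seven phosphorylated PI metabolites), mapping onto twelve
#' distinct LIPID MAPS GP subclass codes. `delta_formula` is the composition
#' added to the sn-glycero-3-phosphate core; PIPx deltas equal the PI delta
#' plus one HPO3 per phosphorylated inositol carbon. The registry can be
#' written to a key-value text file for audit with
#' [write_headgroup_registry()].
#'
#' @return A data.frame with columns `id`, `label`, `subclass`,
#'   `lipidmaps_code`, `delta_formula`, `phosphate_positions`.
#' @export
headgroups <- function() .headgroup_table()

#' Look up one headgroup by id or display label
#'
#' @param id Headgroup id (e.g. `"PI45P2"`) or display label
#'   (e.g. `"PI[4,5]P2"`).
#' @return A one-row data.frame from [headgroups()].
#' @export
headgroup <- function(id) {
  tab <- headgroups()
  i <- match(id, tab$id)
  if (is.na(i)) i <- match(id, tab$label)
  if (is.na(i)) stop("unknown headgroup: '", id, "'")
  tab[i, ]
}

#' Inositol phosphate positions of a headgroup
#'
#' @param id Headgroup id.
#' @return Integer vector, a subset of `{3,4,5}` (empty for non-PIPx heads).
#' @export
phosphate_positions <- function(id) {
  s <- headgroup(id)$phosphate_positions
  if (!nzchar(s)) return(integer(0))
  as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
}

#' Write the headgroup registry to a key-value text file
#'
#' One line per headgroup: `id=delta_formula|lipidmaps_code|label`, so users
#' can audit the compositions the database is built from.
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_headgroup_registry <- function(path) {
  tab <- headgroups()
  writeLines(c("# headgroup registry, one entry per line as",
               "#   id  ->  delta_formula|lipidmaps_code|label",
               sprintf("%s=%s|%s|%s", tab$id, tab$delta_formula,
                       tab$lipidmaps_code, tab$label)), path)
  invisible(path)
}

#' Construct a species
#'
#' A species is a headgroup plus ordered (sn-1, sn-2) chains. Chain order is
#' significant: a species and its sn-1/sn-2 inversion are distinct (equal in
#' mass).
#'
#' @param head Headgroup id or label.
#' @param sn1,sn2 [chain()] objects.
#' @return A `species` object (list with `head`, `sn1`, `sn2`, `name`,
#'   `composition`).
#' @examples
#' species("PI", chain("acyl", 18, 0), chain("acyl", 22, 6))
#' @export
species <- function(head, sn1, sn2) {
  hg <- headgroup(head)
  stopifnot(inherits(sn1, "chain"), inherits(sn2, "chain"))
  comp <- species_composition(hg$id, sn1, sn2)
  structure(list(head = hg$id, sn1 = sn1, sn2 = sn2,
                 name = species_name(hg$id, sn1$linkage, sn1$carbons, sn1$unsat,
                                     sn2$linkage, sn2$carbons, sn2$unsat),
                 composition = comp),
            class = "species")
}

#' @export
print.species <- function(x, ...) {
  cat("<species> ", x$name, "  ", formula_string(x$composition),
      sprintf("  exact %.4f Da\n", exact_mass(x$composition)), sep = "")
  invisible(x)
}

#' Assemble a full-species elemental composition
#'
#' Returns core + headgroup delta + sn-1 chain delta + sn-2 chain delta.
#'
#' @param head Headgroup id or label.
#' @param sn1,sn2 [chain()] objects.
#' @return An `element_count`.
#' @examples
#' species_composition("PI", chain("acyl", 18, 0), chain("acyl", 22, 6))
#' # C49H83O13P
#' @export
species_composition <- function(head, sn1, sn2) {
  hg <- headgroup(head)
  out <- glycerophosphate_core()
  if (nzchar(hg$delta_formula))
    out <- ec_combine(out, ec_parse(hg$delta_formula))
  out <- ec_combine(out, chain_delta(sn1))
  ec_combine(out, chain_delta(sn2))
}
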