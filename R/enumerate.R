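# Exhaustive enumeration of the species space per headgroup under a
# configurable chain rule, shorthand naming/parsing, and calibration of the
# rule family against a target per-class species count.

#' Construct a chain rule
#'
#' The chain rule defines the admissible chain space at each sn position and
#' therefore the size of the enumerated database. Defaults describe the full
#' theoretical space: chains of 0-30 carbons with up to six unsaturations,
#' acyl/alkyl/alkenyl linkages at both positions, lyso hydroxyls at both
#' positions, the di-lyso species included, and unsaturation feasibility
#' enforced (a chain `(c,u)` is admissible only if at least one double-bond
#' placement exists under the spacing rule).
#'
#' Double-bond placement geometry: bond `s` occupies carbons `s, s+1`; the
#' first bond must start at or after `s_min` for that linkage (carbon 1 of an
#' acyl chain is the carbonyl carbon, so `s_min(acyl) >= 2`; for alkenyl
#' chains `s_min` applies to bonds *beyond* the fixed vinyl-ether bond at
#' position 1); consecutive starts must differ by at least `spacing` (`d`),
#' with `d = 2` meaning double bonds may not share a carbon.
#'
#' @param carbon_max Maximum chain length (default 30).
#' @param max_unsat Maximum unsaturations per chain (default 6).
#' @param s_min Named integer vector: first allowed double-bond start per
#'   linkage, default `c(acyl = 2, alkyl = 2, alkenyl = 3)`.
#' @param spacing Minimum start-to-start spacing `d >= 2` between double
#'   bonds (default 2).
#' @param linkages_sn1,linkages_sn2 Allowed linkages per position, subsets of
#'   `c("acyl", "alkyl", "alkenyl")`.
#' @param lyso_sn1,lyso_sn2 Allow a hydroxyl (lyso) at that position.
#' @param dilyso Include the di-lyso species.
#' @param enforce_feasible Require at least one legal double-bond placement
#'   for every admissible `(c, u)`.
#' @return A `chain_rule` object.
#' @export
chain_rule <- function(carbon_max = 30L, max_unsat = 6L,
                       s_min = c(acyl = 2L, alkyl = 2L, alkenyl = 3L),
                       spacing = 2L,
                       linkages_sn1 = c("acyl", "alkyl", "alkenyl"),
                       linkages_sn2 = c("acyl", "alkyl", "alkenyl"),
                       lyso_sn1 = TRUE, lyso_sn2 = TRUE, dilyso = TRUE,
                       enforce_feasible = TRUE) {
  s_min <- vapply(s_min, as.integer, 0L)
  stopifnot(all(c("acyl", "alkyl", "alkenyl") %in% names(s_min)))
  if (spacing < 2L)
    stop("spacing must be >= 2 (double bonds may not share a carbon)")
  if (s_min[["acyl"]] < 2L)
    stop("s_min(acyl) must be >= 2 (carbon 1 is the carbonyl carbon)")
  if (any(s_min < 1L)) stop("s_min must be >= 1")
  stopifnot(carbon_max >= 0L, carbon_max <= 30L,
            max_unsat >= 0L, max_unsat <= 6L,
            all(linkages_sn1 %in% c("acyl", "alkyl", "alkenyl")),
            all(linkages_sn2 %in% c("acyl", "alkyl", "alkenyl")))
  structure(list(carbon_max = as.integer(carbon_max),
                 max_unsat = as.integer(max_unsat),
                 s_min = s_min[c("acyl", "alkyl", "alkenyl")],
                 spacing = as.integer(spacing),
                 linkages_sn1 = linkages_sn1, linkages_sn2 = linkages_sn2,
                 lyso_sn1 = isTRUE(lyso_sn1), lyso_sn2 = isTRUE(lyso_sn2),
                 dilyso = isTRUE(dilyso),
                 enforce_feasible = isTRUE(enforce_feasible)),
            class = "chain_rule")
}

#' @export
print.chain_rule <- function(x, ...) {
  cat("<chain_rule> c<=", x$carbon_max, ", u<=", x$max_unsat,
      ", d=", x$spacing,
      ", s_min(acyl,alkyl,alkenyl)=", paste(x$s_min, collapse = ","),
      "\n  sn1: ", paste(x$linkages_sn1, collapse = "+"),
      if (x$lyso_sn1) "+lyso", "  sn2: ",
      paste(x$linkages_sn2, collapse = "+"), if (x$lyso_sn2) "+lyso",
      "  dilyso=", x$dilyso, "  feasibility=", x$enforce_feasible, "\n",
      sep = "")
  invisible(x)
}

#' Write / read a chain rule as a YAML config file
#'
#' @param rule A [chain_rule()].
#' @param path File path.
#' @return `path` (write) or a `chain_rule` (read).
#' @export
write_chain_rule <- function(rule, path) {
  stopifnot(inherits(rule, "chain_rule"))
  x <- unclass(rule)
  x$s_min <- as.list(x$s_min)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_chain_rule
#' @export
read_chain_rule <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.list(x) || is.null(names(x)))
    stop("not a chain-rule config (expected YAML key-value pairs): ", path)
  x$s_min <- unlist(x$s_min)
  do.call(chain_rule, x)
}

# smallest carbon count admitting u double bonds under the rule (per linkage)
.min_carbons <- function(linkage, u, rule) {
  base <- if (linkage == "alkenyl") 2L else 1L
  # formula validity: H count nonnegative
  hmin <- if (linkage == "alkyl") u else u + 1L
  lo <- pmax(base, hmin)
  if (rule$enforce_feasible & u > 0L) {
    s0 <- rule$s_min[[linkage]]
    lo <- pmax(lo, s0 + (rule$spacing - 1L) * (u - 1L) + u)
  }
  lo
}

#' Admissible chain space at one sn position
#'
#' Deterministic, duplicate-free list of chains, sorted by (linkage, carbons,
#' unsaturations) with the hydroxyl (if lyso is allowed at that position)
#' first. Chains whose `(c, u)` admit no legal double-bond placement are
#' excluded when the rule enforces feasibility.
#'
#' @param rule A [chain_rule()].
#' @param position `"sn1"` or `"sn2"`.
#' @return A data.frame with columns `linkage`, `carbons`, `unsat`.
#' @export
chain_space <- function(rule, position = c("sn1", "sn2")) {
  position <- match.arg(position)
  links <- if (position == "sn1") rule$linkages_sn1 else rule$linkages_sn2
  lyso <- if (position == "sn1") rule$lyso_sn1 else rule$lyso_sn2
  out <- list()
  if (lyso)
    out[[length(out) + 1L]] <-
      data.frame(linkage = "hydroxyl", carbons = 0L, unsat = 0L)
  for (lk in intersect(c("acyl", "alkyl", "alkenyl"), links)) {
    for (u in 0:rule$max_unsat) {
      lo <- .min_carbons(lk, u, rule)
      if (lo > rule$carbon_max) next
      cs <- lo:rule$carbon_max
      out[[length(out) + 1L]] <-
        data.frame(linkage = lk, carbons = cs, unsat = u)
    }
  }
  if (length(out) == 0L)
    return(data.frame(linkage = character(0), carbons = integer(0),
                      unsat = integer(0)))
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  hy <- res$linkage == "hydroxyl"
  body <- res[!hy, ]
  body <- body[order(match(body$linkage, c("acyl", "alkyl", "alkenyl")),
                     body$carbons, body$unsat), ]
  rbind(res[hy, ], body, make.row.names = FALSE)
}

#' Closed-form size of the chain space at one position
#'
#' Computed without materialising the space; agrees with
#' `nrow(chain_space(rule, position))`.
#'
#' @inheritParams chain_space
#' @return Integer count.
#' @export
count_chain_space <- function(rule, position = c("sn1", "sn2")) {
  position <- match.arg(position)
  links <- if (position == "sn1") rule$linkages_sn1 else rule$linkages_sn2
  lyso <- if (position == "sn1") rule$lyso_sn1 else rule$lyso_sn2
  n <- as.integer(lyso)
  for (lk in intersect(c("acyl", "alkyl", "alkenyl"), links))
    for (u in 0:rule$max_unsat)
      n <- n + max(0L, rule$carbon_max - .min_carbons(lk, u, rule) + 1L)
  n
}

#' Closed-form species count of one class
#'
#' `|sn1 space| * |sn2 space|`, minus one when lyso is allowed at both
#' positions but the di-lyso species is excluded. Identical for every
#' headgroup (chain combinatorics are headgroup-independent).
#'
#' @param rule A [chain_rule()].
#' @return Integer count.
#' @export
count_class <- function(rule) {
  n <- count_chain_space(rule, "sn1") * count_chain_space(rule, "sn2")
  if (rule$lyso_sn1 && rule$lyso_sn2 && !rule$dilyso) n <- n - 1L
  n
}

.chain_prefix <- c(acyl = "", alkyl = "O-", alkenyl = "P-", hydroxyl = "")

#' Shorthand token of one chain
#'
#' `"18:0"`, `"O-16:0"`, `"P-18:1"`; a hydroxyl renders as `"0:0"`.
#'
#' @param linkage,carbons,unsat Chain fields (vectorised).
#' @return Character vector of tokens.
#' @export
chain_token <- function(linkage, carbons, unsat) {
  paste0(.chain_prefix[linkage], carbons, ":", unsat)
}

#' Canonical shorthand name of a species
#'
#' `HEAD(sn1/sn2)`, e.g. `"PI[4,5]P2(O-16:0/20:4)"`. Vectorised over the
#' chain fields.
#'
#' @param head Headgroup id or label (scalar).
#' @param l1,c1,u1,l2,c2,u2 sn-1 and sn-2 chain fields.
#' @return Character vector of names.
#' @export
species_name <- function(head, l1, c1, u1, l2, c2, u2) {
  lab <- headgroup(head)$label
  paste0(lab, "(", chain_token(l1, c1, u1), "/", chain_token(l2, c2, u2), ")")
}

#' Parse a species shorthand name
#'
#' Accepts the canonical grammar `HEAD(PREFIXc:u/PREFIXc:u)` with headgroup
#' ids (`PI45P2`) or display labels (`PI[4,5]P2`), tolerating whitespace,
#' underscore subscripts and emphasis markers (`"PI[3,4, 5]P_3"` is read as
#' `"PI[3,4,5]P3"`). Strict validation: unknown headgroups, malformed chain
#' tokens and out-of-range carbon/unsaturation counts are errors.
#'
#' @param text A single species name.
#' @return A [species()] object; `parse_species_name(x$name)` round-trips.
#' @examples
#' parse_species_name("PI[3,4,5]P3(O-16:0/20:4)")
#' @export
parse_species_name <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  t <- gsub("[[:space:]_*]", "", text)
  m <- regexec("^(.+)\\(([^/()]+)/([^/()]+)\\)$", t)[[1]]
  if (m[1] == -1)
    stop("malformed species name: '", text,
         "' (expected HEAD(chain/chain), e.g. PI(18:0/22:6))")
  parts <- regmatches(t, list(m))[[1]]
  head_txt <- parts[2]
  tab <- headgroups()
  norm <- function(s) gsub("[[:space:]_]", "", s)
  i <- match(head_txt, tab$id)
  if (is.na(i)) i <- match(head_txt, norm(tab$label))
  if (is.na(i) && head_txt == "CDPDG") i <- match("CDPDG", tab$id)
  if (is.na(i))
    stop("unknown headgroup in species name: '", head_txt, "'")
  parse_chain <- function(tok) {
    cm <- regexec("^(O-|P-)?([0-9]+):([0-9]+)$", tok)[[1]]
    if (cm[1] == -1) stop("malformed chain token: '", tok, "'")
    p <- regmatches(tok, list(cm))[[1]]
    carbons <- as.integer(p[3]); unsat <- as.integer(p[4])
    if (carbons > 30L) stop("carbons out of range 0-30: ", carbons)
    if (unsat > 6L) stop("unsaturations out of range 0-6: ", unsat)
    lk <- if (carbons == 0L) {
      if (nzchar(p[2]) || unsat != 0L)
        stop("a lyso chain must be written 0:0: '", tok, "'")
      "hydroxyl"
    } else switch(p[2], "O-" = "alkyl", "P-" = "alkenyl", "acyl")
    chain(lk, carbons, unsat)
  }
  species(tab$id[i], parse_chain(parts[3]), parse_chain(parts[4]))
}

.mass_coeffs <- function(mass_type) {
  tabs <- element_masses()
  if (mass_type == "exact") tabs$monoisotopic else tabs$average
}

.vec_formula <- function(C, H, N, O, P) {
  piece <- function(sym, n)
    ifelse(n == 0L, "", paste0(sym, ifelse(n == 1L, "", as.character(n))))
  paste0(piece("C", C), piece("H", H), piece("N", N), piece("O", O),
         piece("P", P))
}

#' Enumerate every species of one headgroup class
#'
#' Forms all ordered (sn-1, sn-2) chain pairs over the rule's chain spaces --
#' sn-1/sn-2 inversions are distinct species -- and assembles name, elemental
#' composition, molecular formula and exact/average mass for each. The stream
#' is deterministic and duplicate-free, ordered by sn-1 chain then sn-2
#' chain.
#'
#' @param head Headgroup id or label.
#' @param rule A [chain_rule()].
#' @return A [data.table::data.table] with columns `name`, `headgroup_id`,
#'   `lipidmaps_code`, `sn1_linkage`, `sn1_c`, `sn1_u`, `sn2_linkage`,
#'   `sn2_c`, `sn2_u`, `formula`, `exact_mass`, `average_mass` (plus integer
#'   element-count columns `C`, `H`, `N`, `O`, `P`).
#' @export
enumerate_class <- function(head, rule = chain_rule()) {
  hg <- headgroup(head)
  s1 <- chain_space(rule, "sn1")
  s2 <- chain_space(rule, "sn2")
  n1 <- nrow(s1); n2 <- nrow(s2)
  if (n1 == 0L || n2 == 0L) {
    empty <- data.table::data.table(
      name = character(0), headgroup_id = character(0),
      lipidmaps_code = character(0), sn1_linkage = character(0),
      sn1_c = integer(0), sn1_u = integer(0), sn2_linkage = character(0),
      sn2_c = integer(0), sn2_u = integer(0), formula = character(0),
      exact_mass = numeric(0), average_mass = numeric(0),
      C = integer(0), H = integer(0), N = integer(0), O = integer(0),
      P = integer(0))
    return(empty)
  }
  i1 <- rep(seq_len(n1), each = n2)
  i2 <- rep(seq_len(n2), times = n1)
  dt <- data.table::data.table(
    sn1_linkage = s1$linkage[i1], sn1_c = s1$carbons[i1],
    sn1_u = s1$unsat[i1],
    sn2_linkage = s2$linkage[i2], sn2_c = s2$carbons[i2],
    sn2_u = s2$unsat[i2])
  if (!rule$dilyso)
    dt <- dt[!(dt$sn1_linkage == "hydroxyl" & dt$sn2_linkage == "hydroxyl"), ]
  base <- glycerophosphate_core()
  if (nzchar(hg$delta_formula))
    base <- ec_combine(base, ec_parse(hg$delta_formula))
  d1 <- chain_delta_counts(dt$sn1_linkage, dt$sn1_c, dt$sn1_u)
  d2 <- chain_delta_counts(dt$sn2_linkage, dt$sn2_c, dt$sn2_u)
  b <- unclass(base)
  dt[, c("C", "H", "N", "O", "P") := list(
    as.integer(b[["C"]] + d1$C + d2$C),
    as.integer(b[["H"]] + d1$H + d2$H),
    as.integer(b[["N"]]),
    as.integer(b[["O"]] + d1$O + d2$O),
    as.integer(b[["P"]]))]
  mono <- .mass_coeffs("exact"); avg <- .mass_coeffs("average")
  dt[, "exact_mass" := C * mono[["C"]] + H * mono[["H"]] + N * mono[["N"]] +
       O * mono[["O"]] + P * mono[["P"]]]
  dt[, "average_mass" := C * avg[["C"]] + H * avg[["H"]] + N * avg[["N"]] +
       O * avg[["O"]] + P * avg[["P"]]]
  dt[, "formula" := .vec_formula(C, H, N, O, P)]
  dt[, "name" := paste0(hg$label, "(",
                        chain_token(sn1_linkage, sn1_c, sn1_u), "/",
                        chain_token(sn2_linkage, sn2_c, sn2_u), ")")]
  dt[, "headgroup_id" := hg$id]
  dt[, "lipidmaps_code" := hg$lipidmaps_code]
  data.table::setcolorder(dt, c("name", "headgroup_id", "lipidmaps_code",
                                "sn1_linkage", "sn1_c", "sn1_u",
                                "sn2_linkage", "sn2_c", "sn2_u", "formula",
                                "exact_mass", "average_mass"))
  dt[]
}

#' Build the full species database
#'
#' Enumerates every requested headgroup class under one chain rule and binds
#' the class streams in registry order. With the default rule and all sixteen
#' headgroups this is the complete database.
#'
#' @param rule A [chain_rule()].
#' @param heads Headgroup ids (default: all sixteen, in registry order).
#' @param verbose Emit a progress message per headgroup.
#' @return A [data.table::data.table] (same columns as [enumerate_class()]).
#' @export
build_database <- function(rule = chain_rule(), heads = headgroups()$id,
                           verbose = FALSE) {
  out <- vector("list", length(heads))
  for (i in seq_along(heads)) {
    if (verbose)
      message(sprintf("[%d/%d] enumerating %s ...", i, length(heads),
                      headgroup(heads[i])$label))
    out[[i]] <- enumerate_class(heads[i], rule)
  }
  data.table::rbindlist(out)
}

#' The documented chain-rule search family
#'
#' The finite rule family searched by [calibrate_chain_rule()]: per-linkage
#' first-bond positions, start-to-start spacing, feasibility enforcement,
#' per-position linkage sets, and the lyso/di-lyso toggles. All members keep
#' the stated structural space (carbons 0-30, up to six unsaturations).
#'
#' @return A list of [chain_rule()] objects.
#' @export
chain_rule_family <- function() {
  link_opts <- list(c("acyl", "alkyl", "alkenyl"), c("acyl", "alkyl"),
                    c("acyl", "alkenyl"), "acyl")
  fam <- list()
  for (sa in 2:3) for (so in 1:3) for (sp in 2:4) for (d in 2:4)
    for (feas in c(TRUE, FALSE)) for (L1 in link_opts) for (L2 in link_opts)
      for (ly1 in c(TRUE, FALSE)) for (ly2 in c(TRUE, FALSE))
        for (dl in c(TRUE, FALSE)) {
          if (!feas && (sa != 2 || so != 2 || sp != 3 || d != 2)) next
          if (!dl && !(ly1 && ly2)) next
          fam[[length(fam) + 1L]] <- chain_rule(
            s_min = c(acyl = sa, alkyl = so, alkenyl = sp), spacing = d,
            linkages_sn1 = L1, linkages_sn2 = L2,
            lyso_sn1 = ly1, lyso_sn2 = ly2, dilyso = dl,
            enforce_feasible = feas)
        }
  fam
}

#' Calibrate the chain rule against a target per-class count
#'
#' Counts every member of a finite rule family by exact closed-form
#' enumeration arithmetic (cross-checked against materialised chain spaces)
#' and returns the members ordered by distance from the target. Exact matches,
#' if any, come first; if none exists the nearest configurations are reported
#' honestly rather than forced.
#'
#' @param target Target species count per class.
#' @param family A list of [chain_rule()]s (default: [chain_rule_family()]).
#' @param n_report How many nearest configurations to keep in the summary.
#' @return A list with `matches` (list of rules counting exactly `target`,
#'   possibly empty) and `nearest` (data.frame summary of the `n_report`
#'   closest configurations with their counts).
#' @export
calibrate_chain_rule <- function(target, family = chain_rule_family(),
                                 n_report = 10L) {
  counts <- vapply(family, count_class, 0L)
  ord <- order(abs(counts - target), counts)
  describe <- function(r, cnt) data.frame(
    count = cnt, diff = cnt - target,
    s_min_acyl = r$s_min[["acyl"]], s_min_alkyl = r$s_min[["alkyl"]],
    s_min_alkenyl = r$s_min[["alkenyl"]], spacing = r$spacing,
    feasibility = r$enforce_feasible,
    sn1 = paste(r$linkages_sn1, collapse = "+"),
    sn2 = paste(r$linkages_sn2, collapse = "+"),
    lyso_sn1 = r$lyso_sn1, lyso_sn2 = r$lyso_sn2, dilyso = r$dilyso)
  top <- ord[seq_len(min(n_report, length(ord)))]
  nearest <- do.call(rbind, Map(describe, family[top],
                                as.list(counts[top])))
  list(matches = family[counts == target],
       nearest = nearest)
}
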