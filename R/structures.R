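# Machine-readable structure generation: enumeration of cis double-bond
# positional isomers under the spacing rule, and rule-based SMILES assembly
# on the sn-glycero-3-phosphate backbone.

# first allowed start for placeable double bonds of a linkage; for alkenyl
# chains the fixed vinyl-ether bond occupies carbons 1-2, so additional bonds
# must also respect the spacing from start 1
.s_min_effective <- function(linkage, rule) {
  s0 <- rule$s_min[[linkage]]
  if (linkage == "alkenyl") max(s0, 1L + rule$spacing) else s0
}

#' Count double-bond placements (closed form)
#'
#' Stars-and-bars count of the patterns enumerated by [placements()]:
#' `choose((c - s_min) - (d - 1)(u - 1), u)`, zero when infeasible; exactly
#' one (empty) pattern when `u = 0`.
#'
#' @param carbons,unsat Chain length and number of placeable double bonds.
#' @param linkage Chain linkage (determines `s_min`).
#' @param rule A [chain_rule()] supplying `s_min` and the spacing `d`.
#' @return Integer pattern count.
#' @export
count_placements <- function(carbons, unsat, linkage = "acyl",
                             rule = chain_rule()) {
  if (unsat == 0L) return(1L)
  if (linkage == "hydroxyl") return(0L)
  smin <- .s_min_effective(linkage, rule)
  top <- (carbons - smin) - (rule$spacing - 1L) * (unsat - 1L)
  if (top < unsat) return(0L)
  as.integer(choose(top, unsat))
}

#' Enumerate double-bond placement patterns
#'
#' All strictly increasing start vectors `s_1 < ... < s_u` with
#' `s_1 >= s_min(linkage)`, start-to-start spacing `s_(k+1) - s_k >= d` and
#' `s_u + 1 <= c` (bond `s` occupies carbons `s, s+1`), in lexicographic
#' order. The first element is the "sequential" earliest-position pattern
#' used for the canonical structure. For alkenyl chains the patterns cover
#' only the bonds beyond the fixed vinyl-ether bond. An infeasible `(c, u)`
#' yields an empty list; `u = 0` yields one empty pattern.
#'
#' @inheritParams count_placements
#' @return A list of integer vectors.
#' @examples
#' placements(10, 4)           # 5 patterns; first is c(2,4,6,8)
#' @export
placements <- function(carbons, unsat, linkage = "acyl",
                       rule = chain_rule()) {
  carbons <- as.integer(carbons); unsat <- as.integer(unsat)
  if (unsat == 0L) return(list(integer(0)))
  if (linkage == "hydroxyl") return(list())
  smin <- .s_min_effective(linkage, rule)
  d <- rule$spacing
  res <- list()
  rec <- function(acc, next_min, remaining) {
    last_ok <- carbons - 1L - (remaining - 1L) * d
    if (next_min > last_ok) return()
    for (s in next_min:last_ok) {
      if (remaining == 1L) res[[length(res) + 1L]] <<- c(acc, s)
      else rec(c(acc, s), s + d, remaining - 1L)
    }
  }
  rec(integer(0), smin, unsat)
  res
}

.validate_pattern <- function(starts, ch, rule) {
  u <- ch$unsat
  if (length(starts) != u)
    stop("pattern length ", length(starts), " does not match chain with ",
         u, " unsaturations")
  if (u == 0L) return(invisible(TRUE))
  if (ch$linkage == "hydroxyl")
    stop("a hydroxyl chain carries no double-bond pattern")
  if (is.unsorted(starts, strictly = TRUE))
    stop("pattern starts must be strictly increasing")
  if (starts[1] < .s_min_effective(ch$linkage, rule))
    stop("first double bond starts before s_min for ", ch$linkage)
  if (u > 1L && any(diff(starts) < rule$spacing))
    stop("double-bond starts closer than the spacing rule d = ", rule$spacing)
  if (starts[u] + 1L > ch$carbons)
    stop("last double bond exceeds the chain length")
  invisible(TRUE)
}

# SMILES fragment for one chain, beginning with the backbone oxygen.
# Double bonds are emitted with cis (Z) directional markers; a terminal
# double bond (ending on the last carbon) is non-stereogenic and unmarked.
.chain_frag_smiles <- function(linkage, carbons, starts) {
  if (linkage == "hydroxyl") return("O")
  full <- if (linkage == "alkenyl") c(1L, starts) else starts
  n <- carbons
  dbl <- rep(FALSE, n)  # index b+1 <-> bond b (atoms b, b+1; atom 0 = attachment)
  sym <- rep("", n)
  for (s in full) dbl[s + 1L] <- TRUE
  for (s in sort(full)) {
    if (s + 1L <= n - 1L) {      # flanking single bond after exists
      pre <- s; post <- s + 2L   # indices of bonds s-1 and s+1
      if (sym[pre] == "") sym[pre] <- "/"
      sym[post] <- if (sym[pre] == "/") "\\" else "/"
    }
  }
  from <- if (linkage == "acyl") 2L else 1L
  prefix <- if (linkage == "acyl") "OC(=O)" else "O"
  if (from > n) return(prefix)
  tail <- vapply(from:n, function(a) {
    chr <- if (dbl[a]) "=" else sym[a]
    paste0(chr, "C")
  }, "")
  paste0(prefix, paste0(tail, collapse = ""))
}

# headgroup fragment attached to the sn-3 phosphate; the fragment begins with
# the phosphoester oxygen. `extra` is the remaining non-ester phosphate
# substituent ("O" hydroxyl, "[O-]" for the phosphocholine zwitterion).
.head_frag_smiles <- function(id, inositol_stereo = FALSE) {
  pos <- phosphate_positions(id)
  if (startsWith(id, "PI")) {
    subst <- rep("O", 6L)
    for (p in pos) subst[p] <- "OP(=O)(O)O"
    ring <- if (inositol_stereo) {
      # myo-inositol ring geometry (1,2,3,5-hydroxyls cis; validated by 3D
      # face pattern); ring walk follows myo numbering from the
      # phosphodiester carbon
      paste0("O[C@H]1[C@@H](O)[C@@H](", subst[3], ")[C@H](", subst[4],
             ")[C@@H](", subst[5], ")[C@@H]1O")
    } else {
      paste0("OC1C(O)C(", subst[3], ")C(", subst[4], ")C(", subst[5],
             ")C1O")
    }
    return(list(head = ring, extra = "O"))
  }
  frag <- switch(id,
    PA = "O",
    PPA = "OP(=O)(O)O",
    PC = "OCC[N+](C)(C)C",
    PE = "OCCN",
    PG = "OCC(O)CO",
    PGP = "OCC(O)COP(=O)(O)O",
    PS = "OCC(N)C(=O)O",
    CDPDG = "OP(=O)(O)OC[C@H]1O[C@@H](N2C=CC(N)=NC2=O)[C@H](O)[C@@H]1O",
    stop("no structure template for headgroup '", id, "'"))
  list(head = frag, extra = if (id == "PC") "[O-]" else "O")
}

#' Assemble the SMILES of a species under given double-bond patterns
#'
#' Emits one connected structure: the sn-glycero-3-phosphate backbone with
#' the sn-2 stereocentre specified, the headgroup esterified at the sn-3
#' phosphate (phosphates on the declared inositol carbons for the PIPx
#' family), and the sn-1/sn-2 chains with the correct linkage chemistry
#' (ester, ether or vinyl ether). All stereo-flagged chain double bonds are
#' cis (Z); the inositol ring is emitted without ring stereo unless
#' `inositol_stereo = TRUE` (myo-inositol template).
#'
#' @param sp A [species()] (or a species name, which is parsed).
#' @param p1,p2 Integer double-bond start vectors for the sn-1 and sn-2
#'   chains (default: the sequential earliest-position pattern).
#' @param rule A [chain_rule()] (spacing and s_min used for validation and
#'   default patterns).
#' @param inositol_stereo Emit myo-inositol ring stereo for PI-family heads.
#' @return A SMILES string.
#' @examples
#' species_smiles(parse_species_name("PA(0:0/0:0)"))
#' @export
species_smiles <- function(sp, p1 = NULL, p2 = NULL, rule = chain_rule(),
                           inositol_stereo = FALSE) {
  if (is.character(sp)) sp <- parse_species_name(sp)
  stopifnot(inherits(sp, "species"))
  if (is.null(p1)) p1 <- placements(sp$sn1$carbons, sp$sn1$unsat,
                                    sp$sn1$linkage, rule)[[1]]
  if (is.null(p2)) p2 <- placements(sp$sn2$carbons, sp$sn2$unsat,
                                    sp$sn2$linkage, rule)[[1]]
  .validate_pattern(p1, sp$sn1, rule)
  .validate_pattern(p2, sp$sn2, rule)
  hf <- .head_frag_smiles(sp$head, inositol_stereo)
  f1 <- .chain_frag_smiles(sp$sn1$linkage, sp$sn1$carbons, p1)
  f2 <- .chain_frag_smiles(sp$sn2$linkage, sp$sn2$carbons, p2)
  paste0("P(=O)(", hf$extra, ")(OC[C@H](", f2, ")C", f1, ")", hf$head)
}

#' Structure records for a species
#'
#' The canonical ("sequential", earliest-position) structure, or with
#' `all_isomers = TRUE` the full cartesian product of sn-1 and sn-2
#' double-bond placements, in deterministic lexicographic order (sn-1
#' pattern major).
#'
#' @inheritParams species_smiles
#' @param all_isomers Emit every positional isomer instead of the canonical
#'   structure only.
#' @return A data.frame with columns `name`, `sn1_pattern`, `sn2_pattern`
#'   (comma-separated start positions), `smiles` and `formula` (from the
#'   species composition).
#' @examples
#' nrow(structure_records("PI[4,5]P2(10:4/0:0)", all_isomers = TRUE))  # 5
#' @export
structure_records <- function(sp, all_isomers = FALSE, rule = chain_rule(),
                              inositol_stereo = FALSE) {
  if (is.character(sp)) sp <- parse_species_name(sp)
  pl1 <- placements(sp$sn1$carbons, sp$sn1$unsat, sp$sn1$linkage, rule)
  pl2 <- placements(sp$sn2$carbons, sp$sn2$unsat, sp$sn2$linkage, rule)
  if (length(pl1) == 0L || length(pl2) == 0L)
    stop("no legal double-bond placement for the chains of ", sp$name)
  if (!all_isomers) { pl1 <- pl1[1]; pl2 <- pl2[1] }
  grid <- expand.grid(j = seq_along(pl2), i = seq_along(pl1))
  fmla <- formula_string(sp$composition)
  out <- data.frame(
    name = rep(sp$name, nrow(grid)),
    sn1_pattern = vapply(pl1[grid$i], paste, "", collapse = ","),
    sn2_pattern = vapply(pl2[grid$j], paste, "", collapse = ","),
    smiles = mapply(function(i, j)
      species_smiles(sp, pl1[[i]], pl2[[j]], rule, inositol_stereo),
      grid$i, grid$j, USE.NAMES = FALSE),
    formula = fmla,
    stringsAsFactors = FALSE)
  out[order(match(out$sn1_pattern, unique(out$sn1_pattern)),
            match(out$sn2_pattern, unique(out$sn2_pattern))), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Write structure records as a SMILES file
#'
#' One record per line: SMILES, a tab, then the record name (species name
#' plus the double-bond pattern when several isomers are written).
#'
#' @param records From [structure_records()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_smiles <- function(records, path) {
  ids <- .record_ids(records)
  writeLines(paste0(records$smiles, "\t", ids), path)
  invisible(path)
}

.record_ids <- function(records) {
  if (nrow(records) > 1L)
    paste0(records$name, " [", records$sn1_pattern, "|", records$sn2_pattern,
           "]")
  else records$name
}

#' Write structure records as an SDF (v2000) file
#'
#' Converts the SMILES through ChemmineR/ChemmineOB and attaches the species
#' name, pattern and formula as data fields.
#'
#' @inheritParams write_smiles
#' @return `path`, invisibly.
#' @export
write_sdf <- function(records, path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("SDF output requires the ChemmineR package")
  smi <- records$smiles
  names(smi) <- .record_ids(records)
  sdf <- ChemmineR::smiles2sdf(smi)
  blocks <- lapply(seq_len(nrow(records)), function(i)
    c(name = records$name[i], sn1_pattern = records$sn1_pattern[i],
      sn2_pattern = records$sn2_pattern[i], formula = records$formula[i]))
  ChemmineR::datablock(sdf) <- blocks
  ChemmineR::write.SDF(sdf, file = path)
  invisible(path)
}
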