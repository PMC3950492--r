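# Indexed m/z search over the enumerated database: absolute-Da tolerance
# windows, query-time adduct handling, class / chain-parity / common-chain
# filters.

#' Class-filter vocabularies
#'
#' `PI_PLUS_PIPX` restricts to the eight PI-family headgroups;
#' `ALL_WITHOUT_PIPX` returns the eight non-PI classes plus PI itself (the PI
#' structural precursor) while excluding the phosphorylated PIPx metabolites;
#' `ALL` returns every headgroup; any single headgroup id restricts to that
#' id alone.
#'
#' @param filter A headgroup id, `"PI_PLUS_PIPX"`, `"ALL_WITHOUT_PIPX"` or
#'   `"ALL"` (case-insensitive; the CLI spellings `"pi+pipx"` and
#'   `"all-without-pipx"` are accepted).
#' @return Character vector of headgroup ids selected by the filter.
#' @export
class_filter_members <- function(filter) {
  tab <- headgroups()
  pi_family <- tab$id[startsWith(tab$id, "PI")]
  key <- toupper(gsub("[+-]", "_", filter))
  if (key == "ALL") return(tab$id)
  if (key %in% c("PI_PLUS_PIPX", "PI_PIPX")) return(pi_family)
  if (key == "ALL_WITHOUT_PIPX") return(setdiff(tab$id, setdiff(pi_family, "PI")))
  if (filter %in% tab$id) return(filter)
  i <- match(filter, tab$label)
  if (!is.na(i)) return(tab$id[i])
  stop("unknown class filter: '", filter, "'")
}

#' Default list of prevalent ("common") chains
#'
#' The common-chain list backing the best-prediction filter: the prevalent
#' mammalian fatty acyl chains 16:0, 16:1, 18:0, 18:1, 18:2, 18:3, 20:4 and
#' 22:6. The list is configurable: supply a CSV with columns
#' `linkage, carbons, unsat` to replace it.
#'
#' @param path Optional CSV path overriding the packaged default.
#' @return A data.frame with columns `linkage`, `carbons`, `unsat`.
#' @export
common_chains <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "common_chains.csv", package = "lipidmz")
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("linkage", "carbons", "unsat") %in% names(out)))
  # validate every entry as a chain
  for (i in seq_len(nrow(out)))
    chain(out$linkage[i], out$carbons[i], out$unsat[i])
  out
}

#' Build a searchable index over a species stream
#'
#' Stores the neutral exact and average masses sorted for binary search;
#' adducts are handled at query time by transforming the query m/z window
#' back to the neutral-mass axis, so one index serves all six ion modes.
#'
#' @param db A species table from [enumerate_class()] or [build_database()].
#' @return A `lipid_index` object.
#' @export
build_index <- function(db) {
  db <- data.table::as.data.table(db)
  structure(list(db = db,
                 ord_exact = order(db$exact_mass),
                 ord_average = order(db$average_mass),
                 n = nrow(db)),
            class = "lipid_index")
}

#' @export
print.lipid_index <- function(x, ...) {
  cat("<lipid_index> ", x$n, " species, ",
      length(unique(x$db$headgroup_id)), " headgroup class(es)\n", sep = "")
  invisible(x)
}

.validate_tolerance <- function(tolerance) {
  if (!is.numeric(tolerance) || length(tolerance) != 1L ||
      tolerance < 1e-4 || tolerance > 2)
    stop("tolerance must lie in [0.0001, 2] Da, got: ", tolerance)
  tolerance
}

#' Search the index for species matching a query m/z
#'
#' Returns exactly the species whose theoretical m/z (under `mass_type` and
#' `ion_mode`) lies within `mz +/- tolerance` (absolute Da, inclusive at both
#' ends) and that pass the class, chain-parity and best-prediction filters.
#' Hits are sorted by |delta| ascending, ties broken by canonical name.
#'
#' @param index A [build_index()] object.
#' @param mz Query m/z (> 0).
#' @param tolerance Absolute tolerance in Da, within `[0.0001, 2]`;
#'   out-of-range values are rejected, not clamped.
#' @param ion_mode One of `ion_modes()$label` (default `"M+H"`).
#' @param mass_type `"exact"` or `"average"`.
#' @param class_filter See [class_filter_members()] (default `"ALL"`).
#' @param parity `"all"` or `"even_only"` (keep species whose every non-lyso
#'   chain has an even carbon count).
#' @param best_prediction If `TRUE`, keep only species whose non-lyso chains
#'   all appear in the common-chain list.
#' @param common Common-chain list for the best-prediction filter
#'   (default [common_chains()]).
#' @return A data.table of hits: the species columns plus `query_mz`,
#'   `theoretical_mz` and `delta_da` (= theoretical - query, signed).
#' @export
search_mz <- function(index, mz, tolerance, ion_mode = "M+H",
                      mass_type = c("exact", "average"),
                      class_filter = "ALL", parity = c("all", "even_only"),
                      best_prediction = FALSE, common = NULL) {
  stopifnot(inherits(index, "lipid_index"))
  mass_type <- match.arg(mass_type)
  parity <- match.arg(parity)
  .validate_tolerance(tolerance)
  stopifnot(is.numeric(mz), length(mz) == 1L, mz > 0)
  members <- class_filter_members(class_filter)

  masscol <- paste0(mass_type, "_mass")
  ord <- if (mass_type == "exact") index$ord_exact else index$ord_average
  sorted <- index$db[[masscol]][ord]
  # candidate retrieval on a slightly widened neutral-mass window; the exact
  # inclusive |delta| <= tolerance predicate is applied on the m/z axis below
  win <- neutral_mass_window(mz, tolerance, ion_mode, mass_type) +
    c(-1e-9, 1e-9)
  lo <- findInterval(win[1], sorted, left.open = TRUE) + 1L
  hi <- findInterval(win[2], sorted)
  if (hi < lo) {
    hits <- index$db[0L]
  } else {
    hits <- index$db[ord[lo:hi]]
  }
  hits <- hits[hits$headgroup_id %in% members, ]
  if (parity == "even_only")
    hits <- hits[(hits$sn1_linkage == "hydroxyl" | hits$sn1_c %% 2L == 0L) &
                 (hits$sn2_linkage == "hydroxyl" | hits$sn2_c %% 2L == 0L), ]
  if (isTRUE(best_prediction)) {
    if (is.null(common)) common <- common_chains()
    hits <- best_prediction_filter(hits, common)
  }
  theo <- adduct_mz_or_neutral(hits[[masscol]], ion_mode, mass_type)
  hits[, "query_mz" := mz]
  hits[, "theoretical_mz" := theo]
  hits[, "delta_da" := theo - mz]
  hits <- hits[abs(hits$delta_da) <= tolerance, ]
  hits[order(abs(hits$delta_da), hits$name)]
}

# adduct_mz() requires positive mass and errors on empties; tolerant wrapper
adduct_mz_or_neutral <- function(m, ion_mode, mass_type) {
  if (length(m) == 0L) return(numeric(0))
  adduct_mz(m, ion_mode, mass_type)
}

#' Best-prediction filter
#'
#' Keeps hits whose non-lyso chains all appear (by linkage, carbon count and
#' unsaturation) in the common-chain list. A deterministic, idempotent subset
#' of its input; with an empty list only pure-lyso species survive.
#'
#' @param hits A species table (e.g. from [search_mz()]).
#' @param common A common-chain list, see [common_chains()].
#' @return The filtered table.
#' @export
best_prediction_filter <- function(hits, common = common_chains()) {
  keytab <- paste(common$linkage, common$carbons, common$unsat)
  ok1 <- hits$sn1_linkage == "hydroxyl" |
    paste(hits$sn1_linkage, hits$sn1_c, hits$sn1_u) %in% keytab
  ok2 <- hits$sn2_linkage == "hydroxyl" |
    paste(hits$sn2_linkage, hits$sn2_c, hits$sn2_u) %in% keytab
  hits[ok1 & ok2, ]
}

#' Annotate a peak list
#'
#' Runs [search_mz()] for every m/z in a vector or peak-list CSV (column
#' `mz`) and binds the result blocks in input order.
#'
#' @param index A [build_index()] object.
#' @param peaks Numeric vector of m/z values, or path to a CSV with an `mz`
#'   column (see [read_peaklist()]).
#' @param ... Passed to [search_mz()] (tolerance, ion_mode, ...).
#' @return A data.table of hits for all peaks (zero rows if nothing matches).
#' @export
annotate_peaklist <- function(index, peaks, ...) {
  if (is.character(peaks)) peaks <- read_peaklist(peaks)$mz
  out <- lapply(peaks, function(p) search_mz(index, p, ...))
  data.table::rbindlist(out)
}
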