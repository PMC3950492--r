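# Elemental-composition arithmetic and exact/average mass and adduct m/z
# computation. All masses are in Da (amu); compositions are integer element
# counts over the supported element set.

.lipidmz_env <- new.env(parent = emptyenv())

#' Supported element symbols
#'
#' Elements that may appear in an elemental composition. The glycerophospholipid
#' space itself only uses C, H, N, O and P; Li, Na and K are carried for the
#' alkali-metal adduct modes.
#'
#' @return Character vector of element symbols.
#' @export
supported_elements <- function() c("C", "H", "N", "O", "P", "Li", "Na", "K")

#' Pinned atomic-mass tables
#'
#' Reads the packaged plain-text constants file once per session and returns
#' the pinned monoisotopic masses, standard atomic weights, electron mass and
#' their provenance string. Users can audit the constants directly in
#' `system.file("extdata", "element_masses.txt", package = "lipidmz")`.
#'
#' @return A list with components `monoisotopic` (named numeric, Da),
#'   `average` (named numeric, Da), `electron_mass` (Da) and `version`.
#' @export
element_masses <- function() {
  if (!is.null(.lipidmz_env$masses)) return(.lipidmz_env$masses)
  path <- system.file("extdata", "element_masses.txt", package = "lipidmz")
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  pick <- function(prefix) {
    sel <- startsWith(keys, prefix)
    stats::setNames(as.numeric(vals[sel]), sub(prefix, "", keys[sel], fixed = TRUE))
  }
  mono <- pick("monoisotopic.")
  avg <- pick("average.")
  stopifnot(setequal(names(mono), supported_elements()),
            setequal(names(avg), supported_elements()))
  out <- list(
    monoisotopic = mono[supported_elements()],
    average = avg[supported_elements()],
    electron_mass = as.numeric(vals[keys == "electron_mass"]),
    version = vals[keys == "version"]
  )
  .lipidmz_env$masses <- out
  out
}

#' Construct an elemental composition
#'
#' An elemental composition is a named integer vector over
#' [supported_elements()] with class `"element_count"`. Counts must be
#' nonnegative integers; unsupported element symbols are rejected.
#'
#' @param ... Named integer counts, e.g. `ec(C = 3, H = 9, O = 6, P = 1)`.
#' @return An `element_count` object.
#' @examples
#' ec(C = 3, H = 9, O = 6, P = 1)
#' @export
ec <- function(...) {
  x <- c(...)
  if (is.null(x)) x <- numeric(0)
  bad <- setdiff(names(x), supported_elements())
  if (length(bad) > 0 || (length(x) > 0 && is.null(names(x))))
    stop("unsupported element symbol(s): ", paste(bad, collapse = ", "))
  if (any(x < 0) || any(x != round(x)))
    stop("element counts must be nonnegative integers")
  full <- stats::setNames(numeric(length(supported_elements())), supported_elements())
  full[names(x)] <- x
  structure(full, class = "element_count")
}

#' Parse a molecular formula string into an elemental composition
#'
#' Accepts plain formulas such as `"C3H9O6P"` or `"C49H83O13P"` (one- or
#' two-letter symbols, optional counts).
#'
#' @param formula A single formula string.
#' @return An `element_count` object.
#' @export
ec_parse <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  toks <- toks[nzchar(toks)]
  if (sum(nchar(toks)) != nchar(formula))
    stop("malformed formula: ", formula)
  sym <- sub("[0-9]+$", "", toks)
  cnt <- as.numeric(ifelse(grepl("[0-9]+$", toks),
                           sub("^[A-Za-z]+", "", toks), "1"))
  out <- stats::setNames(numeric(length(supported_elements())), supported_elements())
  bad <- setdiff(sym, supported_elements())
  if (length(bad) > 0)
    stop("unsupported element symbol(s): ", paste(unique(bad), collapse = ", "))
  for (i in seq_along(sym)) out[sym[i]] <- out[sym[i]] + cnt[i]
  structure(out, class = "element_count")
}

#' Add or subtract elemental compositions
#'
#' Element-wise sum (`sign = +1`) or difference (`sign = -1`). Subtraction
#' that would produce a negative count raises a composition-underflow error.
#'
#' @param a,b `element_count` objects (or named vectors coercible via [ec()]).
#' @param sign `+1` to add, `-1` to subtract `b` from `a`.
#' @return An `element_count` object.
#' @examples
#' ec_combine(ec_parse("C3H8O3"), ec_parse("H3PO4"))          # glycerol + phosphoric acid
#' ec_combine(ec_parse("C3H11O7P"), ec_parse("H2O"), sign = -1)
#' @export
ec_combine <- function(a, b, sign = +1L) {
  if (!inherits(a, "element_count")) a <- do.call(ec, as.list(a))
  if (!inherits(b, "element_count")) b <- do.call(ec, as.list(b))
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  out <- unclass(a) + sign * unclass(b)
  if (any(out < 0))
    stop("composition underflow: subtraction would give a negative ",
         paste(names(out)[out < 0], collapse = ","), " count")
  structure(out, class = "element_count")
}

#' Render a composition as a molecular formula string
#'
#' Hill-like ordering: C, H, then remaining elements alphabetically.
#'
#' @param x An `element_count` object.
#' @return A formula string such as `"C49H83O13P"`.
#' @export
formula_string <- function(x) {
  v <- unclass(x)
  ord <- c("C", "H", sort(setdiff(names(v), c("C", "H"))))
  v <- v[ord]
  v <- v[v > 0]
  if (length(v) == 0) return("")
  paste0(names(v), ifelse(v == 1, "", as.character(v)), collapse = "")
}

#' @export
print.element_count <- function(x, ...) {
  cat("<element_count> ", formula_string(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.element_count <- function(x, ...) formula_string(x)

.mass_of <- function(x, table) {
  v <- unclass(x)
  sum(v * table[names(v)])
}

#' Exact (monoisotopic) mass of a composition
#'
#' Sum of pinned monoisotopic element masses weighted by counts.
#'
#' @param x An `element_count`, or a formula string.
#' @return Mass in Da.
#' @examples
#' exact_mass(ec_parse("H2O"))  # 18.0106
#' @export
exact_mass <- function(x) {
  if (is.character(x)) x <- ec_parse(x)
  .mass_of(x, element_masses()$monoisotopic)
}

#' Average mass of a composition
#'
#' Sum of pinned standard atomic weights weighted by counts.
#'
#' @inheritParams exact_mass
#' @return Mass in Da.
#' @export
average_mass <- function(x) {
  if (is.character(x)) x <- ec_parse(x)
  .mass_of(x, element_masses()$average)
}

#' MS ion-mode registry
#'
#' The six supported single-charge-or-neutral modes: `[M+H]+`, `[M+K]+`,
#' `[M+Li]+`, `[M+Na]+`, `[M-H]-` and the neutral mass. `delta_sign` and
#' `delta_element` describe the adduct atom added (+1) or removed (-1);
#' charged modes carry an electron correction of `-charge` electron masses.
#'
#' @return A data.frame with columns `label`, `charge`, `delta_element`,
#'   `delta_sign`.
#' @export
ion_modes <- function() {
  data.frame(
    label = c("M+H", "M+K", "M+Li", "M+Na", "M-H", "Neutral"),
    charge = c(1L, 1L, 1L, 1L, -1L, 0L),
    delta_element = c("H", "K", "Li", "Na", "H", NA_character_),
    delta_sign = c(1L, 1L, 1L, 1L, -1L, 0L),
    stringsAsFactors = FALSE
  )
}

.ion_mode_row <- function(mode) {
  modes <- ion_modes()
  i <- match(mode, modes$label)
  if (is.na(i)) {
    # tolerate the typographic minus used in print
    i <- match(gsub("−", "-", mode), modes$label)
  }
  if (is.na(i))
    stop("unknown ion mode: '", mode, "' (expected one of ",
         paste(modes$label, collapse = ", "), ")")
  modes[i, ]
}

#' Adduct m/z of a neutral mass
#'
#' For the six supported modes, m/z = (M + sign * adduct atom mass -
#' charge * electron mass) / |charge|, with |charge| = 1 for all charged
#' modes; `Neutral` returns the neutral mass unchanged. The adduct atom mass
#' is taken from the table matching `mass_type`, so exact and average m/z are
#' internally consistent.
#'
#' @param neutral_mass Neutral mass(es) in Da (vectorised).
#' @param mode Ion mode label, one of `ion_modes()$label`.
#' @param mass_type `"exact"` (monoisotopic) or `"average"`.
#' @return m/z value(s).
#' @examples
#' adduct_mz(640.0723, "M+H")  # 641.0796
#' @export
adduct_mz <- function(neutral_mass, mode, mass_type = c("exact", "average")) {
  mass_type <- match.arg(mass_type)
  stopifnot(all(neutral_mass > 0))
  row <- .ion_mode_row(mode)
  if (row$charge == 0L) return(neutral_mass)
  tabs <- element_masses()
  tab <- if (mass_type == "exact") tabs$monoisotopic else tabs$average
  neutral_mass + row$delta_sign * tab[[row$delta_element]] -
    row$charge * tabs$electron_mass
}

#' Neutral-mass window equivalent to an m/z query window
#'
#' Inverts the adduct transform: given a query m/z and an absolute tolerance,
#' returns the `[lo, hi]` window on the *neutral* mass axis that corresponds
#' to `mz +/- tolerance` under `mode`. Used by the search index so that
#' adducts are handled at query time.
#'
#' @inheritParams adduct_mz
#' @param mz Query m/z.
#' @param tolerance Absolute tolerance in Da.
#' @return Numeric vector `c(lo, hi)` of neutral masses.
#' @export
neutral_mass_window <- function(mz, tolerance, mode,
                                mass_type = c("exact", "average")) {
  mass_type <- match.arg(mass_type)
  row <- .ion_mode_row(mode)
  if (row$charge == 0L) return(c(mz - tolerance, mz + tolerance))
  tabs <- element_masses()
  tab <- if (mass_type == "exact") tabs$monoisotopic else tabs$average
  shift <- row$delta_sign * tab[[row$delta_element]] -
    row$charge * tabs$electron_mass
  c(mz - tolerance - shift, mz + tolerance - shift)
}
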