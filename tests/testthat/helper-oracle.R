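# Independent oracles used across the suite. These re-derive quantities along
# a separate code path (own constant transcription, own arithmetic, plain
# loops) and never call the package internals they are checking.

# Independently transcribed element-mass tables (AME2020 monoisotopic,
# CIAAW 2021 standard atomic weights, CODATA 2018 electron mass).
oracle_mono <- c(H = 1.00782503224, C = 12.0, N = 14.00307400446,
                 O = 15.99491461960, P = 30.97376199843,
                 Li = 7.01600343666, Na = 22.98976928199,
                 K = 38.96370648661)
oracle_avg <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                P = 30.973761998, Li = 6.94, Na = 22.98976928, K = 39.0983)
oracle_electron <- 0.000548579909

# plain-loop summation over a named count vector
oracle_mass <- function(counts, table = oracle_mono) {
  total <- 0
  for (el in names(counts)) total <- total + counts[[el]] * table[[el]]
  total
}

# random composition for property sweeps
random_composition <- function() {
  ec(C = sample(0:60, 1), H = sample(0:120, 1), N = sample(0:3, 1),
     O = sample(0:20, 1), P = sample(0:4, 1))
}

# random valid chain under the default rule
random_chain <- function(rule = chain_rule()) {
  repeat {
    lk <- sample(c("acyl", "alkyl", "alkenyl", "hydroxyl"), 1)
    if (lk == "hydroxyl") return(chain("hydroxyl", 0, 0))
    us <- 0:rule$max_unsat
    u <- us[sample.int(length(us), 1)]
    lo <- lipidmz:::.min_carbons(lk, u, rule)
    if (lo > rule$carbon_max) next
    cs <- lo:rule$carbon_max
    return(chain(lk, cs[sample.int(length(cs), 1)], u))
  }
}

# brute-force m/z scan: recompute every theoretical m/z directly from the
# database rows with the oracle tables' adduct arithmetic and filter linearly
oracle_scan <- function(db, mz, tolerance, ion_mode, mass_type,
                        members, parity = "all") {
  neutral <- if (mass_type == "exact") db$exact_mass else db$average_mass
  tab <- if (mass_type == "exact") oracle_mono else oracle_avg
  theo <- switch(ion_mode,
    "Neutral" = neutral,
    "M+H" = neutral + tab[["H"]] - oracle_electron,
    "M+K" = neutral + tab[["K"]] - oracle_electron,
    "M+Li" = neutral + tab[["Li"]] - oracle_electron,
    "M+Na" = neutral + tab[["Na"]] - oracle_electron,
    "M-H" = neutral - tab[["H"]] + oracle_electron,
    stop("oracle: unknown mode"))
  keep <- abs(theo - mz) <= tolerance & db$headgroup_id %in% members
  if (parity == "even_only")
    keep <- keep &
      (db$sn1_linkage == "hydroxyl" | db$sn1_c %% 2 == 0) &
      (db$sn2_linkage == "hydroxyl" | db$sn2_c %% 2 == 0)
  db[keep, ]
}

# exhaustive double-bond pattern generation by subset filtering
brute_placements <- function(carbons, unsat, s_min, d) {
  if (unsat == 0L) return(list(integer(0)))
  cand <- seq_len(carbons - 1L)
  cand <- cand[cand >= s_min]
  if (length(cand) < unsat) return(list())
  sets <- if (length(cand) == 1L) list(cand)
          else utils::combn(cand, unsat, simplify = FALSE)
  Filter(function(s) unsat == 1L || all(diff(s) >= d), sets)
}
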