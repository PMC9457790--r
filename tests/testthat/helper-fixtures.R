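# Builders for small in-code fixtures shared across test files.

# endpoint-only timecourse: identical replicates unless `ends` is a vector
# of per-replicate end values
endpoint_tc <- function(setup_id, strain, analyte, start, end,
                        n_replicates = 3L, t_end = 240) {
  ends <- rep_len(end, n_replicates)
  rows <- do.call(rbind, lapply(seq_len(n_replicates), function(r)
    data.frame(setup_id = setup_id, strain = strain, replicate = r,
               time_h = c(0, t_end), analyte = analyte,
               value = c(start, ends[r]), unit = "mM",
               stringsAsFactors = FALSE)))
  rows
}

# paired worked-example inputs built from consumption amounts
pair_from_consumption <- function(no3_with, no3_without, fe_total,
                                  strain = "E1", n_replicates = 3L) {
  with_fe <- timecourse(rbind(
    endpoint_tc("with_fe", strain, "NO3", 10, 10 - no3_with, n_replicates),
    endpoint_tc("with_fe", strain, "Fe2", 4.5, 4.5 - fe_total, n_replicates)))
  without_fe <- timecourse(
    endpoint_tc("without_fe", strain, "NO3", 10, 10 - no3_without,
                n_replicates))
  list(with_fe = with_fe, without_fe = without_fe)
}

# brute-force balance oracle, independent of check_balance(): plain loops
# over the species registry
oracle_balance <- function(rx) {
  reg <- nrfo_species()
  count <- function(side) {
    els <- c(); ch <- 0; nox <- 0; feox <- 0
    for (sp in names(side)) {
      co <- side[[sp]][["num"]] / side[[sp]][["den"]]
      info <- reg[[sp]]
      for (el in names(info$elements)) {
        if (is.null(els[el]) || is.na(els[el])) els[el] <- 0
        els[el] <- els[el] + co * info$elements[[el]]
      }
      ch <- ch + co * info$charge
      if (!is.null(info$n_ox)) nox <- nox + co * info$elements[["N"]] * info$n_ox
      if (!is.null(info$fe_ox)) feox <- feox + co * info$elements[["Fe"]] * info$fe_ox
    }
    list(els = els, ch = ch, nox = nox, feox = feox)
  }
  L <- count(rx$reactants); R <- count(rx$products)
  els <- union(names(L$els), names(R$els))
  gv <- function(s, e) if (e %in% names(s$els)) s$els[[e]] else 0
  list(
    element = vapply(els, function(e) abs(gv(L, e) - gv(R, e)) < 1e-9,
                     logical(1)),
    charge = abs(L$ch - R$ch) < 1e-9,
    electron = abs((R$feox - L$feox) - (L$nox - R$nox)) < 1e-9
  )
}
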