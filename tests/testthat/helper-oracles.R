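# Independent oracles shared across test files.

# minimal true assignments of a (monotone) gate, computed from its truth
# table; for AND/OR gates these are exactly the reduced DNF minterms
oracle_minterms <- function(config) {
  inputs <- c("Notch", "TCF-1", "GATA-3")
  assigns <- expand.grid(rep(list(c(FALSE, TRUE)), 3))
  names(assigns) <- inputs
  truth <- apply(assigns, 1, function(a)
    eval_gate(config$ast, stats::setNames(as.list(as.logical(a)), inputs)))
  sets <- lapply(which(truth), function(i)
    inputs[as.logical(assigns[i, ])])
  minimal <- sets[vapply(seq_along(sets), function(i) {
    !any(vapply(seq_along(sets), function(j)
      j != i && all(sets[[j]] %in% sets[[i]]) &&
        length(sets[[j]]) < length(sets[[i]]), logical(1)))
  }, logical(1))]
  exps <- c(Notch = 1L, `TCF-1` = config$n_T, `GATA-3` = config$n_G)
  out <- lapply(minimal, function(s) exps[inputs[inputs %in% s]])
  out[order(vapply(out, function(m) paste(names(m), m, collapse = ","),
                   character(1)))]
}

canon_minterms <- function(minterms)
  minterms[order(vapply(minterms, function(m)
    paste(names(m), m, collapse = ","), character(1)))]
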