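# Combinatorial logic engine: the 32 BCL11B regulation variants and their
# compilation into Shea-Ackers rate laws.

#' Canonical gate forms for BCL11B regulation
#'
#' The eight AND/OR gate forms over the inputs Notch, TCF-1 and GATA-3 that,
#' combined with monomer/dimer valencies for TCF-1 and GATA-3, give the 32
#' combinatorial configurations for the BCL11B production rate.
#'
#' @return Character vector of length 8, named "1".."8".
#' @export
gate_forms <- function() {
  c("1" = "Notch OR TCF-1 OR GATA-3",
    "2" = "(Notch AND TCF-1) OR GATA-3",
    "3" = "(Notch AND GATA-3) OR TCF-1",
    "4" = "Notch OR (TCF-1 AND GATA-3)",
    "5" = "Notch AND (TCF-1 OR GATA-3)",
    "6" = "TCF-1 AND (Notch OR GATA-3)",
    "7" = "GATA-3 AND (Notch OR TCF-1)",
    "8" = "Notch AND TCF-1 AND GATA-3")
}

# valency letters: a..d -> (n_T, n_G)
.valency_letters <- list(a = c(1L, 1L), b = c(1L, 2L), c = c(2L, 1L),
                         d = c(2L, 2L))

.gate_inputs <- c("Notch", "TCF-1", "GATA-3")

#' Parse an AND/OR gate expression
#'
#' Parses a logic expression over the atoms `Notch`, `TCF-1` and `GATA-3`
#' with binary `AND`/`OR` (AND binds tighter; both left-associative) and
#' parentheses into a small abstract syntax tree.
#'
#' @param text Gate expression, e.g. `"TCF-1 AND (Notch OR GATA-3)"`.
#' @return An AST: either an atom (character scalar) or
#'   `list(op = "AND"|"OR", lhs = , rhs = )`.
#' @export
parse_gate <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  # tokenize: atoms, AND, OR, parens
  pat <- "Notch|TCF-1|GATA-3|AND|OR|\\(|\\)"
  tokens <- regmatches(text, gregexpr(pat, text))[[1]]
  leftover <- gsub(pat, "", text)
  leftover <- gsub("[[:space:]]", "", leftover)
  if (nzchar(leftover))
    stop("malformed gate expression; unrecognised token near: '",
         substr(leftover, 1, 12), "'")
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  take <- function() { tok <- peek(); pos <<- pos + 1L; tok }
  parse_or <- function() {
    node <- parse_and()
    while (identical(peek(), "OR")) {
      take()
      node <- list(op = "OR", lhs = node, rhs = parse_and())
    }
    node
  }
  parse_and <- function() {
    node <- parse_atom()
    while (identical(peek(), "AND")) {
      take()
      node <- list(op = "AND", lhs = node, rhs = parse_atom())
    }
    node
  }
  parse_atom <- function() {
    tok <- take()
    if (is.na(tok)) stop("malformed gate expression; unexpected end of input")
    if (tok == "(") {
      node <- parse_or()
      if (!identical(take(), ")"))
        stop("malformed gate expression; unbalanced parenthesis")
      return(node)
    }
    if (tok %in% .gate_inputs) return(tok)
    stop("malformed gate expression; unexpected token '", tok, "'")
  }
  ast <- parse_or()
  if (pos <= length(tokens))
    stop("malformed gate expression; trailing token '", peek(), "'")
  ast
}

#' Evaluate a gate AST on a boolean assignment
#'
#' @param ast Output of [parse_gate()].
#' @param assignment Named logical vector over the three inputs.
#' @return Logical scalar.
#' @export
eval_gate <- function(ast, assignment) {
  if (is.character(ast)) return(isTRUE(as.logical(assignment[[ast]])))
  l <- eval_gate(ast$lhs, assignment)
  r <- eval_gate(ast$rhs, assignment)
  if (ast$op == "AND") l && r else l || r
}

#' Construct a single BCL11B logic configuration
#'
#' A configuration is one of the 32 variants labelled `"1a".."8d"`: a digit
#' selecting the gate form (see [gate_forms()]) and a letter selecting the
#' Hill-coefficient (valency) pair for TCF-1 and GATA-3 action on BCL11B:
#' a = (1,1), b = (1,2), c = (2,1), d = (2,2).
#'
#' @param variant_id Label such as `"6d"`.
#' @return Object of class `logic_config` with fields `variant_id`, `gate`
#'   (the canonical gate text), `ast`, `n_T`, `n_G`.
#' @export
logic_config <- function(variant_id) {
  stopifnot(is.character(variant_id), length(variant_id) == 1L)
  m <- regmatches(variant_id, regexec("^([1-8])([abcd])$", variant_id))[[1]]
  if (length(m) == 0L)
    stop("unknown variant id '", variant_id,
         "'; expected one of \"1a\"..\"8d\"")
  gate <- gate_forms()[[m[2]]]
  val <- .valency_letters[[m[3]]]
  structure(
    list(variant_id = variant_id, gate = gate, ast = parse_gate(gate),
         n_T = val[1], n_G = val[2]),
    class = "logic_config")
}

#' @export
print.logic_config <- function(x, ...) {
  cat(sprintf("<logic_config %s> %s  (n_T = %d, n_G = %d)\n",
              x$variant_id, x$gate, x$n_T, x$n_G))
  invisible(x)
}

#' Enumerate all 32 BCL11B logic configurations
#'
#' Eight gate forms times four valency pairs, in deterministic order
#' `1a, 1b, 1c, 1d, 2a, ..., 8d`.
#'
#' @return Named list of 32 [logic_config()] objects.
#' @export
enumerate_configurations <- function() {
  ids <- as.vector(t(outer(as.character(1:8), letters[1:4], paste0)))
  stats::setNames(lapply(ids, logic_config), ids)
}

#' Compile a logic configuration into a Shea-Ackers rate law
#'
#' Expands the gate into disjunctive normal form: each OR branch (after full
#' expansion and absorption of redundant products) becomes one minterm, a
#' product of input concentrations with the configuration's Hill exponents
#' applied to TCF-1 and GATA-3 (Notch always enters with exponent 1). Each
#' minterm carries its own kinetic weight index; weights are ordered with
#' Notch-containing minterms first, then by descending TCF-1 and GATA-3
#' exponents, so that the first weight always multiplies the (first)
#' Notch-containing term.
#'
#' @param config A [logic_config()].
#' @return Object of class `rate_law`: list with `minterms` (list of named
#'   integer exponent vectors over the inputs present) and `config`.
#' @export
compile_rate_law <- function(config) {
  stopifnot(inherits(config, "logic_config"))
  expand <- function(ast) {
    if (is.character(ast)) return(list(ast))
    l <- expand(ast$lhs); r <- expand(ast$rhs)
    if (ast$op == "OR") return(c(l, r))
    # AND: cross product, union of atoms
    out <- list()
    for (a in l) for (b in r) out[[length(out) + 1L]] <- union(a, b)
    out
  }
  sets <- unique(lapply(expand(config$ast), sort))
  # absorption: drop any product that is a superset of another
  keep <- vapply(seq_along(sets), function(i) {
    !any(vapply(seq_along(sets), function(j) {
      i != j && all(sets[[j]] %in% sets[[i]]) &&
        length(sets[[j]]) < length(sets[[i]])
    }, logical(1)))
  }, logical(1))
  sets <- sets[keep]
  exps <- c(Notch = 1L, `TCF-1` = config$n_T, `GATA-3` = config$n_G)
  minterms <- lapply(sets, function(s) exps[.gate_inputs[.gate_inputs %in% s]])
  # deterministic ordering: Notch-containing first, then higher TCF-1, GATA-3
  key <- vapply(minterms, function(m) {
    e <- function(nm) if (nm %in% names(m)) m[[nm]] else 0L
    -(e("Notch") * 100 + e("TCF-1") * 10 + e("GATA-3"))
  }, numeric(1))
  minterms <- minterms[order(key)]
  structure(list(minterms = minterms, config = config), class = "rate_law")
}

#' Number of kinetic weights (minterms) of a rate law
#' @param rate_law A [compile_rate_law()] result.
#' @return Integer, between 1 and 3.
#' @export
n_kappa <- function(rate_law) length(rate_law$minterms)

#' Canonical string form of a rate law
#'
#' Plain-text rendering such as `"k1*N*T^2 + k2*T^2*G^2"`, used in logs,
#' reports and SBML notes.
#'
#' @param x A `rate_law`.
#' @param ... Unused.
#' @return Character scalar.
#' @export
format.rate_law <- function(x, ...) {
  short <- c(Notch = "N", `TCF-1` = "T", `GATA-3` = "G")
  terms <- vapply(seq_along(x$minterms), function(j) {
    m <- x$minterms[[j]]
    facs <- vapply(names(m), function(nm) {
      if (m[[nm]] == 1L) short[[nm]] else
        paste0(short[[nm]], "^", m[[nm]])
    }, character(1))
    paste0("k", j, "*", paste(facs, collapse = "*"))
  }, character(1))
  paste(terms, collapse = " + ")
}

#' @export
print.rate_law <- function(x, ...) {
  cat(sprintf("<rate_law %s> S = %s; production = S/(1+S)\n",
              x$config$variant_id, format(x)))
  invisible(x)
}

#' Shea-Ackers production ratio
#'
#' Computes `S / (1 + S)` where `S = sum_j kappa_j * prod_i x_i^e_ij` over
#' the rate law's minterms. The ratio is the thermodynamic promoter-occupancy
#' fraction and always lies in `[0, 1)`.
#'
#' @param rate_law A [compile_rate_law()] result.
#' @param kappas Nonnegative kinetic weights, one per minterm.
#' @param concentrations Named nonnegative vector with entries `Notch`,
#'   `TCF-1`, `GATA-3` (entries not used by the rate law may be omitted).
#' @return Numeric scalar in `[0, 1)`.
#' @export
production_ratio <- function(rate_law, kappas, concentrations) {
  stopifnot(inherits(rate_law, "rate_law"))
  if (length(kappas) != length(rate_law$minterms))
    stop("need exactly one kappa per minterm (",
         length(rate_law$minterms), " required)")
  if (any(kappas < 0)) stop("kappa weights must be nonnegative")
  if (any(concentrations < 0)) stop("concentrations must be nonnegative")
  S <- minterm_sum(rate_law, kappas, concentrations)
  S / (1 + S)
}

# weighted minterm sum S (internal, shared with the ODE right-hand side)
minterm_sum <- function(rate_law, kappas, concentrations) {
  S <- 0
  for (j in seq_along(rate_law$minterms)) {
    m <- rate_law$minterms[[j]]
    miss <- setdiff(names(m), names(concentrations))
    if (length(miss))
      stop("missing concentration(s): ", paste(miss, collapse = ", "))
    S <- S + kappas[j] * prod(concentrations[names(m)] ^ m)
  }
  unname(S)
}

#' Summary table of all 32 configurations
#'
#' @return A data.frame with columns `variant_id`, `gate`, `n_T`, `n_G`,
#'   `n_minterms`, `rate_law`.
#' @export
configuration_table <- function() {
  cfgs <- enumerate_configurations()
  do.call(rbind, lapply(cfgs, function(cf) {
    rl <- compile_rate_law(cf)
    data.frame(variant_id = cf$variant_id, gate = cf$gate, n_T = cf$n_T,
               n_G = cf$n_G, n_minterms = n_kappa(rl),
               rate_law = format(rl), stringsAsFactors = FALSE,
               row.names = NULL)
  }))
}
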