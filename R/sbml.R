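# SBML Level 3 Version 1 exchange. The model is a phenomenological ODE, so
# it is encoded with rate rules (one per gene) plus an assignment rule for
# the relative Notch signal, rather than a reaction/kinetic-law
# decomposition.

.sbml_ns <- "http://www.sbml.org/sbml/level3/version1/core"
.mathml_ns <- "http://www.w3.org/1998/Math/MathML"
.time_url <- "http://www.sbml.org/sbml/symbols/time"

# R expression -> MathML under a parent node (internal)
.expr_to_mathml <- function(parent, expr) {
  if (is.numeric(expr)) {
    cn <- xml2::xml_add_child(parent, "cn", format(expr, digits = 17))
    return(invisible(cn))
  }
  if (is.name(expr)) {
    nm <- as.character(expr)
    if (nm == "time") {
      cs <- xml2::xml_add_child(parent, "csymbol", "time",
                                encoding = "text",
                                definitionURL = .time_url)
      return(invisible(cs))
    }
    return(invisible(xml2::xml_add_child(parent, "ci", nm)))
  }
  if (is.call(expr)) {
    op <- as.character(expr[[1]])
    if (op == "(") return(.expr_to_mathml(parent, expr[[2]]))
    tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                  "/" = "divide", "^" = "power", "exp" = "exp",
                  stop("cannot encode operator '", op, "' as MathML"))
    ap <- xml2::xml_add_child(parent, "apply")
    xml2::xml_add_child(ap, tag)
    for (i in seq_along(expr)[-1]) .expr_to_mathml(ap, expr[[i]])
    return(invisible(ap))
  }
  stop("cannot encode expression of class ", class(expr)[1])
}

# MathML node -> R expression (internal)
.mathml_to_expr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "cn") return(as.numeric(xml2::xml_text(node)))
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "csymbol") return(as.name("time"))
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    fun <- switch(op, plus = "+", minus = "-", times = "*",
                  divide = "/", power = "^", exp = "exp",
                  stop("cannot decode MathML operator <", op, ">"))
    args <- lapply(kids[-1], .mathml_to_expr)
    return(as.call(c(as.name(fun), args)))
  }
  if (nm == "math") return(.mathml_to_expr(xml2::xml_child(node)))
  stop("unexpected MathML element <", nm, ">")
}

# gene rate-rule formula strings for a spec (internal)
.rhs_formulas <- function(spec, include_pu1) {
  p <- spec$params
  numT <- "(eta1N*notch_rel + eta2*T + eta3*G)"
  numG <- "(delta1N*notch_rel + delta2*T)"
  terms <- vapply(seq_along(spec$rate_law$minterms), function(j) {
    m <- spec$rate_law$minterms[[j]]
    facs <- c(paste0("kappa", j),
              vapply(names(m), function(nm) {
                base <- c(Notch = "notch_rel", `TCF-1` = "T",
                          `GATA-3` = "G")[[nm]]
                if (m[[nm]] == 1L) base else paste0(base, "^", m[[nm]])
              }, character(1)))
    paste(facs, collapse = "*")
  }, character(1))
  SB <- paste0("(", paste(terms, collapse = " + "), ")")
  out <- c(
    T = sprintf("f_T*%s/(1 + %s + eta4*P) - gamma_T*T", numT,
                substr(numT, 2, nchar(numT) - 1)),
    G = sprintf("f_G*%s/(1 + %s + delta3*P) - gamma_G*G", numG,
                substr(numG, 2, nchar(numG) - 1)),
    B = sprintf("f_B*%s/(1 + %s) - gamma_B*B", SB,
                substr(SB, 2, nchar(SB) - 1)))
  if (include_pu1) {
    numP <- "(rho1*P + runx_input)"
    out["P"] <- sprintf(
      "f_P*%s/(1 + %s + rho2*T + rho3*G + rho4*B) - gamma_P*P", numP,
      substr(numP, 2, nchar(numP) - 1))
  }
  out
}

# flat named vector of SBML parameter values for a spec (internal)
.sbml_parameters <- function(spec, include_pu1) {
  p <- spec$params
  k <- length(p$kappa)
  out <- c(eta1N = p$eta[1], eta2 = p$eta[2], eta3 = p$eta[3],
           eta4 = p$eta[4], f_T = unname(p$f[["T"]]),
           gamma_T = unname(p$gamma[["T"]]),
           delta1N = p$delta[1], delta2 = p$delta[2], delta3 = p$delta[3],
           f_G = unname(p$f[["G"]]), gamma_G = unname(p$gamma[["G"]]),
           stats::setNames(p$kappa, paste0("kappa", seq_len(k))),
           f_B = unname(p$f[["B"]]), gamma_B = unname(p$gamma[["B"]]),
           alpha = spec$notch$alpha)
  if (include_pu1)
    out <- c(out, rho1 = p$rho[1], rho2 = p$rho[2], rho3 = p$rho[3],
             rho4 = p$rho[4], f_P = unname(p$f[["P"]]),
             gamma_P = unname(p$gamma[["P"]]),
             runx_input = p$runx_input)
  out
}

#' Export a model as SBML Level 3 Version 1
#'
#' Emits one species per gene, the relative Notch signal as an assignment
#' rule (sigmoid of time; the floor fraction and midpoint are inlined as
#' numeric constants, the steepness `alpha` is an exposed parameter), and
#' each gene's production-minus-decay dynamics as a rate rule. Kinetic
#' parameters use the conventional symbols (`eta1N`, `kappa2`, `gamma_T`,
#' ...). The rate-law structure is also recorded in a human-readable note.
#'
#' @param spec A [model_spec()].
#' @param path Output file path (.xml).
#' @param include_pu1 Include the PU.1 species and its six parameters;
#'   default TRUE. Use FALSE to export the TCF-1/GATA-3/BCL11B + Notch
#'   subsystem only (e.g. when PU.1 parameters are not trusted).
#' @param init Initial species amounts; default [etp_initial_state()].
#' @return `path`, invisibly.
#' @export
export_sbml <- function(spec, path, include_pu1 = TRUE,
                        init = etp_initial_state(spec)) {
  stopifnot(inherits(spec, "model_spec"))
  if (include_pu1 && spec$params$f[["P"]] == 0 && all(spec$params$rho == 0))
    include_pu1 <- FALSE  # inert PU.1 shell: nothing meaningful to export
  genes <- if (include_pu1) .genes else c("T", "G", "B")
  doc <- xml2::xml_new_root("sbml", xmlns = .sbml_ns, level = "3",
                            version = "1")
  model <- xml2::xml_add_child(doc, "model",
                               id = paste0("tcell_commitment_",
                                           spec$logic$variant_id),
                               timeUnits = "day")
  notes <- xml2::xml_add_child(model, "notes")
  body <- xml2::xml_add_child(notes, "body",
                              xmlns = "http://www.w3.org/1999/xhtml")
  xml2::xml_add_child(body, "p", sprintf(
    "BCL11B configuration %s: %s; S = %s; production = f_B*S/(1+S).",
    spec$logic$variant_id, spec$logic$gate, format(spec$rate_law)))
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1",
                      spatialDimensions = "3", constant = "true")
  sps <- xml2::xml_add_child(model, "listOfSpecies")
  full_names <- c(T = "TCF1", G = "GATA3", B = "BCL11B", P = "PU1")
  for (g in genes)
    xml2::xml_add_child(sps, "species", id = g,
                        name = full_names[[g]], compartment = "cell",
                        initialConcentration =
                          format(init[[g]], digits = 17),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  pars <- xml2::xml_add_child(model, "listOfParameters")
  pv <- .sbml_parameters(spec, include_pu1)
  for (nm in names(pv))
    xml2::xml_add_child(pars, "parameter", id = nm,
                        value = format(pv[[nm]], digits = 17),
                        constant = "true")
  xml2::xml_add_child(pars, "parameter", id = "notch_rel", value = "0",
                      constant = "false")
  rules <- xml2::xml_add_child(model, "listOfRules")
  phi <- spec$notch$floor / spec$notch$n_max
  notch_txt <- sprintf(
    "%s + (1 - %s) / (1 + exp(-(time - %s) / alpha))",
    format(phi, digits = 17), format(phi, digits = 17),
    format(spec$notch$t_half, digits = 17))
  ar <- xml2::xml_add_child(rules, "assignmentRule", variable = "notch_rel")
  math <- xml2::xml_add_child(ar, "math", xmlns = .mathml_ns)
  .expr_to_mathml(math, str2lang(notch_txt))
  formulas <- .rhs_formulas(spec, include_pu1)
  for (g in genes) {
    rr <- xml2::xml_add_child(rules, "rateRule", variable = g)
    math <- xml2::xml_add_child(rr, "math", xmlns = .mathml_ns)
    .expr_to_mathml(math, str2lang(formulas[[g]]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Structural validation of an SBML document
#'
#' Checks well-formedness, the SBML L3V1 namespace, and the structural
#' contract the importer relies on: a model element; species with ids and
#' declared compartments; parameters with ids and values; every rule
#' referring to a declared species or parameter; MathML maths under each
#' rule. (A full schema validation requires an external SBML toolchain;
#' these checks plus the import round-trip cover the exchange contract.)
#'
#' @param path SBML file path.
#' @return Character vector of problems; `character(0)` if none.
#' @export
validate_sbml_structure <- function(path) {
  probs <- character(0)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) e)
  if (inherits(doc, "error"))
    return(paste("not well-formed XML:", conditionMessage(doc)))
  ns_map <- tryCatch(unclass(xml2::xml_ns(doc)), error = function(e) NULL)
  if (is.null(ns_map) || !(.sbml_ns %in% unlist(ns_map)))
    return(c(probs, "root namespace is not SBML L3V1 core"))
  if (!identical(xml2::xml_name(doc), "sbml"))
    probs <- c(probs, "root element is not <sbml>")
  model <- xml2::xml_find_first(doc, "./d1:model")
  if (inherits(model, "xml_missing"))
    return(c(probs, "missing <model> element"))
  species <- xml2::xml_find_all(model, ".//d1:species")
  comps <- xml2::xml_attr(xml2::xml_find_all(model, ".//d1:compartment"),
                          "id")
  ids <- xml2::xml_attr(species, "id")
  if (anyNA(ids)) probs <- c(probs, "species without id")
  if (!all(xml2::xml_attr(species, "compartment") %in% comps))
    probs <- c(probs, "species referencing undeclared compartment")
  params <- xml2::xml_find_all(model, ".//d1:parameter")
  pids <- xml2::xml_attr(params, "id")
  if (anyNA(pids)) probs <- c(probs, "parameter without id")
  rules <- xml2::xml_find_all(model,
                              ".//d1:rateRule | .//d1:assignmentRule")
  for (r in rules) {
    v <- xml2::xml_attr(r, "variable")
    if (!(v %in% c(ids, pids)))
      probs <- c(probs, paste("rule variable not declared:", v))
    if (inherits(xml2::xml_find_first(r, "./m:math",
                                      c(m = .mathml_ns, d1 = .sbml_ns)),
                 "xml_missing"))
      probs <- c(probs, paste("rule without MathML math:", v))
  }
  probs
}

#' Import an SBML document written by [export_sbml()]
#'
#' Parses species, parameter values and the assignment/rate rules back into
#' executable form.
#'
#' @param path SBML file path.
#' @return List with `species` (ids), `parameters` (named values), `init`
#'   (initial concentrations), and `rhs`, a function
#'   `rhs(state, t)` returning the named vector of time-derivatives.
#' @export
import_sbml <- function(path) {
  probs <- validate_sbml_structure(path)
  if (length(probs)) stop("invalid SBML document: ",
                          paste(probs, collapse = "; "))
  doc <- xml2::read_xml(path)
  ns <- c(d1 = .sbml_ns, m = .mathml_ns)
  species <- xml2::xml_find_all(doc, ".//d1:species", ns)
  sp_ids <- xml2::xml_attr(species, "id")
  init <- stats::setNames(
    as.numeric(xml2::xml_attr(species, "initialConcentration")), sp_ids)
  params <- xml2::xml_find_all(doc, ".//d1:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))
  assign_rules <- xml2::xml_find_all(doc, ".//d1:assignmentRule", ns)
  rate_rules <- xml2::xml_find_all(doc, ".//d1:rateRule", ns)
  get_expr <- function(rule)
    .mathml_to_expr(xml2::xml_find_first(rule, "./m:math", ns))
  assigns <- stats::setNames(lapply(assign_rules, get_expr),
                             xml2::xml_attr(assign_rules, "variable"))
  rates <- stats::setNames(lapply(rate_rules, get_expr),
                           xml2::xml_attr(rate_rules, "variable"))
  rhs <- function(state, t) {
    env <- list2env(as.list(pvals))
    for (nm in names(state)) assign(nm, state[[nm]], envir = env)
    assign("time", t, envir = env)
    for (nm in names(assigns)) assign(nm, eval(assigns[[nm]], env),
                                      envir = env)
    vapply(rates, function(e) eval(e, env), numeric(1))
  }
  list(species = sp_ids, parameters = pvals, init = init, rhs = rhs)
}
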