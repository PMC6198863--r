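#' Export a kinetic model to SBML Level 3 Version 1
#'
#' Writes the model as an SBML L3V1 document with a single compartment of
#' size 1 (so amounts and concentrations coincide), species, parameters and
#' reactions with MathML kinetic laws. `const` species are exported with
#' `boundaryCondition="true"`. The exported subset round-trips through
#' [read_sbml()].
#'
#' @param model a [kinetic_model].
#' @param path file to write.
#' @return the path, invisibly.
#' @export
write_sbml <- function(model, path) {
  stopifnot(inherits(model, "kinetic_model"))
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1")
  mdl <- xml2::xml_add_child(doc, "model", id = sanitize_sid(model$name))
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1",
                      spatialDimensions = "3", constant = "true")
  sps <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$species))) {
    xml2::xml_add_child(
      sps, "species",
      id = model$species$name[[i]], compartment = "cell",
      initialConcentration = fmt_num(model$species$initial[[i]]),
      hasOnlySubstanceUnits = "false",
      boundaryCondition = tolower(model$species$fixed[[i]]),
      constant = "false")
  }
  if (length(model$parameters)) {
    ps <- xml2::xml_add_child(mdl, "listOfParameters")
    for (nm in names(model$parameters))
      xml2::xml_add_child(ps, "parameter", id = nm,
                          value = fmt_num(model$parameters[[nm]]),
                          constant = "true")
  }
  if (length(model$reactions)) {
    rs <- xml2::xml_add_child(mdl, "listOfReactions")
    for (rx in model$reactions) {
      rnode <- xml2::xml_add_child(rs, "reaction", id = rx$name,
                                   reversible = "false", fast = "false")
      add_srefs <- function(tag, df) {
        if (nrow(df) == 0) return()
        lst <- xml2::xml_add_child(rnode, tag)
        for (i in seq_len(nrow(df)))
          xml2::xml_add_child(lst, "speciesReference",
                              species = df$species[[i]],
                              stoichiometry = fmt_num(df$stoich[[i]]),
                              constant = "true")
      }
      add_srefs("listOfReactants", rx$reactants)
      add_srefs("listOfProducts", rx$products)
      if (length(rx$modifiers)) {
        lst <- xml2::xml_add_child(rnode, "listOfModifiers")
        for (m in rx$modifiers)
          xml2::xml_add_child(lst, "modifierSpeciesReference", species = m)
      }
      kl <- xml2::xml_add_child(rnode, "kineticLaw")
      math <- xml2::xml_add_child(kl, "math",
                                  xmlns = "http://www.w3.org/1998/Math/MathML")
      add_mathml(math, rx$rate)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

sanitize_sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
fmt_num <- function(x) sprintf("%.17g", x)

# R expression -> MathML content markup (subset: + - * / ^ exp, ci, cn)
add_mathml <- function(parent, e) {
  if (is.numeric(e)) {
    xml2::xml_add_child(parent, "cn", fmt_num(e), type = "real")
    return(invisible())
  }
  if (is.symbol(e)) {
    xml2::xml_add_child(parent, "ci", as.character(e))
    return(invisible())
  }
  if (is.call(e)) {
    fn <- as.character(e[[1]])
    if (fn == "(") return(add_mathml(parent, e[[2]]))
    op <- switch(fn, "+" = "plus", "-" = "minus", "*" = "times",
                 "/" = "divide", "^" = "power", "exp" = "exp",
                 stop("cannot express function '", fn, "' in SBML", call. = FALSE))
    ap <- xml2::xml_add_child(parent, "apply")
    xml2::xml_add_child(ap, op)
    for (arg in as.list(e)[-1]) add_mathml(ap, arg)
    return(invisible())
  }
  stop("cannot express construct in SBML MathML", call. = FALSE)
}

# MathML content markup -> R expression
mathml_to_expr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1) stop("malformed MathML", call. = FALSE)
    return(mathml_to_expr(kids[[1]]))
  }
  if (nm == "ci") return(as.symbol(trimws(xml2::xml_text(node))))
  if (nm == "cn") return(as.numeric(trimws(xml2::xml_text(node))))
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    fn <- switch(op, plus = "+", minus = "-", times = "*",
                 divide = "/", power = "^", exp = "exp",
                 stop("unsupported MathML operator '", op, "'", call. = FALSE))
    args <- lapply(kids[-1], mathml_to_expr)
    if (fn %in% c("+", "*") && length(args) > 2) {
      out <- args[[1]]
      for (a in args[-1]) out <- call(fn, out, a)
      return(out)
    }
    return(as.call(c(as.symbol(fn), args)))
  }
  stop("unsupported MathML node '", nm, "'", call. = FALSE)
}

#' Import an SBML Level 3 model (exported subset)
#'
#' Reads SBML documents using the constructs emitted by [write_sbml()]:
#' species with initial concentrations, boundary conditions, constant
#' parameters and irreversible reactions with MathML kinetic laws over
#' `+ - * / ^ exp`. Events, rules and function definitions are not supported.
#'
#' @param path SBML file.
#' @return a [kinetic_model].
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = xml2::xml_ns(doc)[["d1"]], m = "http://www.w3.org/1998/Math/MathML")
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  spn <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  species <- data.frame(
    name = xml2::xml_attr(spn, "id"),
    initial = as.numeric(xml2::xml_attr(spn, "initialConcentration")),
    fixed = xml2::xml_attr(spn, "boundaryCondition") == "true",
    stringsAsFactors = FALSE)
  pn <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  parameters <- stats::setNames(as.numeric(xml2::xml_attr(pn, "value")),
                                xml2::xml_attr(pn, "id"))
  rxn <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  reactions <- lapply(rxn, function(rn) {
    side <- function(tag) {
      refs <- xml2::xml_find_all(rn, sprintf("./s:%s/s:speciesReference", tag), ns)
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      data.frame(species = xml2::xml_attr(refs, "species"),
                 stoich = as.integer(st), stringsAsFactors = FALSE)
    }
    math <- xml2::xml_find_first(rn, "./s:kineticLaw/m:math", ns)
    if (inherits(math, "xml_missing"))
      stop("reaction '", xml2::xml_attr(rn, "id"), "' has no kinetic law",
           call. = FALSE)
    rate <- mathml_to_expr(math)
    list(name = xml2::xml_attr(rn, "id"),
         reactants = side("listOfReactants"),
         products = side("listOfProducts"),
         modifiers = xml2::xml_attr(
           xml2::xml_find_all(rn, "./s:listOfModifiers/s:modifierSpeciesReference", ns),
           "species"),
         rate = rate, rate_text = deparse1(rate), line = NA_integer_)
  })
  model <- structure(list(name = xml2::xml_attr(mdl, "id"), species = species,
                          parameters = parameters, reactions = reactions),
                     class = "kinetic_model")
  validate_kinetic_model(model)
}
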