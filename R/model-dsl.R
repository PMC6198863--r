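#' Kinetic reaction models from a plain-text reaction language
#'
#' `parse_model()` reads a small Antimony-inspired reaction language and
#' returns a validated [kinetic_model] object. The language is line oriented;
#' `#` starts a comment. Recognised line forms:
#'
#' \preformatted{
#' model <name>              # optional header
#' species <name> = <value>  # dynamic state variable, initial amount
#' const <name> = <value>    # fixed (boundary) species, excluded from the state
#' param <name> = <value>    # kinetic parameter
#' <rname>: <reactants> -> <products> ; <rate expression>
#' end                       # optional
#' }
#'
#' Reaction sides are `+`-separated terms with optional integer stoichiometry
#' (`2 X + Y`); either side may be empty. Rate expressions are arithmetic over
#' declared species and parameters using `+ - * / ^` and `exp()`. Species
#' referenced in a rate but appearing on neither side of the arrow are recorded
#' as modifiers. Every symbol must resolve to a declared species or parameter;
#' undeclared symbols are an error naming the symbol and line.
#'
#' @param text a character scalar (or vector of lines) with the model source.
#' @return an object of class `kinetic_model`: a list with elements `name`,
#'   `species` (data.frame: `name`, `initial`, `fixed`), `parameters` (named
#'   numeric) and `reactions` (list of reaction records).
#' @seealso [serialize_model()], [simulate.kinetic_model()], [write_sbml()]
#' @examples
#' m <- parse_model("
#' model decay
#' species A = 10
#' species B = 0
#' param k1 = 0.1
#' R1: A -> B ; k1*A
#' end")
#' m
#' @export
parse_model <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  name <- "model"
  sp_name <- character(); sp_init <- numeric(); sp_fixed <- logical()
  params <- numeric()
  reactions <- list()

  decl_rx <- "^(species|const|param)\\s+([A-Za-z][A-Za-z0-9_.]*)\\s*=\\s*(\\S+)\\s*$"
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (grepl("^model\\s+", ln)) {
      name <- trimws(sub("^model\\s+", "", ln))
      next
    }
    if (ln == "end") next
    if (grepl(decl_rx, ln)) {
      kind <- sub(decl_rx, "\\1", ln)
      nm <- sub(decl_rx, "\\2", ln)
      val <- suppressWarnings(as.numeric(sub(decl_rx, "\\3", ln)))
      if (is.na(val))
        stop(sprintf("line %d: value for '%s' is not numeric", i, nm), call. = FALSE)
      if (nm %in% c(sp_name, names(params)))
        stop(sprintf("line %d: duplicate declaration of '%s'", i, nm), call. = FALSE)
      if (kind == "param") {
        params[[nm]] <- val
      } else {
        if (val < 0)
          stop(sprintf("line %d: initial amount of '%s' is negative", i, nm),
               call. = FALSE)
        sp_name <- c(sp_name, nm)
        sp_init <- c(sp_init, val)
        sp_fixed <- c(sp_fixed, kind == "const")
      }
      next
    }
    if (grepl("->", ln, fixed = TRUE)) {
      reactions[[length(reactions) + 1L]] <- parse_reaction_line(ln, i)
      next
    }
    stop(sprintf("line %d: cannot parse '%s'", i, ln), call. = FALSE)
  }

  species <- data.frame(name = sp_name, initial = sp_init, fixed = sp_fixed,
                        stringsAsFactors = FALSE)
  model <- structure(list(name = name, species = species, parameters = params,
                          reactions = reactions),
                     class = "kinetic_model")
  validate_kinetic_model(model)
}

parse_reaction_line <- function(ln, lineno) {
  has_label <- grepl("^[A-Za-z][A-Za-z0-9_.]*\\s*:", ln)
  if (has_label) {
    rname <- trimws(sub(":.*$", "", ln))
    rest <- sub("^[^:]*:", "", ln)
  } else {
    rname <- NA_character_
    rest <- ln
  }
  parts <- strsplit(rest, ";", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop(sprintf("line %d: reaction needs exactly one ';' before the rate", lineno),
         call. = FALSE)
  eqn <- strsplit(parts[[1]], "->", fixed = TRUE)[[1]]
  if (length(eqn) != 2)
    stop(sprintf("line %d: reaction needs exactly one '->'", lineno), call. = FALSE)
  rate_text <- trimws(parts[[2]])
  rate <- tryCatch(str2lang(rate_text),
                   error = function(e) stop(sprintf(
                     "line %d: cannot parse rate expression '%s'", lineno, rate_text),
                     call. = FALSE))
  list(name = rname,
       reactants = parse_side(eqn[[1]], lineno),
       products = parse_side(eqn[[2]], lineno),
       modifiers = character(),   # filled during validation
       rate = rate, rate_text = rate_text, line = lineno)
}

parse_side <- function(side, lineno) {
  side <- trimws(side)
  out <- data.frame(species = character(), stoich = integer(),
                    stringsAsFactors = FALSE)
  if (!nzchar(side)) return(out)
  for (term in trimws(strsplit(side, "+", fixed = TRUE)[[1]])) {
    m <- regmatches(term, regexec("^([0-9]*)\\s*([A-Za-z][A-Za-z0-9_.]*)$", term))[[1]]
    if (length(m) == 0)
      stop(sprintf("line %d: cannot parse reaction term '%s'", lineno, term),
           call. = FALSE)
    st <- if (nzchar(m[[2]])) as.integer(m[[2]]) else 1L
    if (st < 1L)
      stop(sprintf("line %d: stoichiometry must be a positive integer in '%s'",
                   lineno, term), call. = FALSE)
    out <- rbind(out, data.frame(species = m[[3]], stoich = st,
                                 stringsAsFactors = FALSE))
  }
  out
}

# allowed calls inside rate expressions
.rate_functions <- c("+", "-", "*", "/", "^", "exp", "(")

expr_symbols <- function(e) {
  if (is.numeric(e) || is.integer(e)) return(character())
  if (is.symbol(e)) return(as.character(e))
  if (is.call(e)) {
    fn <- as.character(e[[1]])
    if (!fn %in% .rate_functions)
      stop(sprintf("unsupported function '%s' in rate expression", fn), call. = FALSE)
    return(unique(unlist(lapply(as.list(e)[-1], expr_symbols))))
  }
  stop("unsupported construct in rate expression", call. = FALSE)
}

validate_kinetic_model <- function(model) {
  sp <- model$species
  if (anyDuplicated(sp$name))
    stop("species names are not unique", call. = FALSE)
  clash <- intersect(sp$name, names(model$parameters))
  if (length(clash))
    stop("name used for both a species and a parameter: ",
         paste(clash, collapse = ", "), call. = FALSE)
  known <- c(sp$name, names(model$parameters))
  auto <- 0L
  for (j in seq_along(model$reactions)) {
    rx <- model$reactions[[j]]
    if (is.na(rx$name)) {
      auto <- auto + 1L
      model$reactions[[j]]$name <- rx$name <- sprintf("R%d", j)
    }
    for (s in c(rx$reactants$species, rx$products$species))
      if (!s %in% sp$name)
        stop(sprintf("line %d: undeclared species '%s' in reaction '%s'",
                     rx$line, s, rx$name), call. = FALSE)
    syms <- expr_symbols(rx$rate)
    bad <- setdiff(syms, known)
    if (length(bad))
      stop(sprintf("line %d: undeclared symbol '%s' in rate of reaction '%s'",
                   rx$line, bad[[1]], rx$name), call. = FALSE)
    model$reactions[[j]]$modifiers <-
      setdiff(intersect(syms, sp$name),
              c(rx$reactants$species, rx$products$species))
  }
  if (anyDuplicated(vapply(model$reactions, `[[`, "", "name")))
    stop("reaction names are not unique", call. = FALSE)
  invisible(model)
}

#' Serialize a kinetic model back to its text form
#'
#' The output re-parses to a model equal to the input (round trip).
#'
#' @param model a [kinetic_model].
#' @return a character scalar of model-language source.
#' @export
serialize_model <- function(model) {
  stopifnot(inherits(model, "kinetic_model"))
  sp <- model$species
  lines <- c(
    paste("model", model$name),
    sprintf("%s %s = %.17g", ifelse(sp$fixed, "const", "species"),
            sp$name, sp$initial),
    sprintf("param %s = %.17g", names(model$parameters), model$parameters),
    vapply(model$reactions, function(rx) {
      side <- function(df) paste(ifelse(df$stoich == 1L, df$species,
                                        paste(df$stoich, df$species)),
                                 collapse = " + ")
      sprintf("%s: %s -> %s ; %s", rx$name, side(rx$reactants),
              side(rx$products), rx$rate_text)
    }, ""),
    "end")
  paste(lines, collapse = "\n")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("Kinetic model '%s': %d species (%d fixed), %d parameters, %d reactions\n",
              x$name, nrow(x$species), sum(x$species$fixed),
              length(x$parameters), length(x$reactions)))
  cat("Species: ", paste(sprintf("%s=%g%s", x$species$name, x$species$initial,
                                 ifelse(x$species$fixed, " (const)", "")),
                         collapse = ", "), "\n", sep = "")
  cat("Parameters: ", paste(sprintf("%s=%g", names(x$parameters), x$parameters),
                            collapse = ", "), "\n", sep = "")
  for (rx in x$reactions) {
    side <- function(df) paste(ifelse(df$stoich == 1L, df$species,
                                      paste(df$stoich, df$species)),
                               collapse = " + ")
    cat(sprintf("  %s: %s -> %s ; %s\n", rx$name, side(rx$reactants),
                side(rx$products), rx$rate_text))
  }
  invisible(x)
}

#' @exportS3Method base::all.equal
all.equal.kinetic_model <- function(target, current, ...) {
  t <- target; c2 <- current
  msgs <- character()
  if (!isTRUE(all.equal(t$species, c2$species))) msgs <- c(msgs, "species differ")
  if (!isTRUE(all.equal(t$parameters, c2$parameters))) msgs <- c(msgs, "parameters differ")
  rsig <- function(m) lapply(m$reactions, function(r)
    list(r$name, r$reactants, r$products, deparse(r$rate)))
  if (!isTRUE(all.equal(rsig(t), rsig(c2)))) msgs <- c(msgs, "reactions differ")
  if (length(msgs)) msgs else TRUE
}
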