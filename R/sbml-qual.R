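SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_QUAL_NS <- "http://www.sbml.org/sbml/level3/version1/qual/version1"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
XHTML_NS <- "http://www.w3.org/1999/xhtml"

# Attributes of a node with namespace prefixes stripped.
plain_attrs <- function(node) {
  at <- xml2::xml_attrs(node)
  names(at) <- sub("^.*:", "", names(at))
  at
}

ln_all <- function(x, name) {
  xml2::xml_find_all(x, paste0(".//*[local-name()='", name, "']"))
}
ln_first <- function(x, name) {
  xml2::xml_find_first(x, paste0("./*[local-name()='", name, "']"))
}

#' Read a qualitative regulatory network from SBML-qual
#'
#' Supports the qualitative-models package (Level 3, qual v1): qualitative
#' species with initial and maximum levels, transitions with ordered function
#' terms whose MathML bodies use `and`, `or`, `not` and the comparisons
#' `eq/neq/geq/leq/gt/lt` between one species (`ci`) and one integer constant
#' (`cn`). State/interval equivalences are read from `STATE` directives in
#' species notes (see [parse_equivalence_note()]); species without such a note
#' have no equivalences. Species without a transition are inputs whose level
#' never changes under update.
#'
#' @param path path to an SBML-qual file.
#' @return a [regulatory_network()].
#' @export
read_sbml_qual <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  sp_nodes <- ln_all(doc, "qualitativeSpecies")

  # transitions first, so an absent maxLevel can default to the largest level
  # any rule references
  tr_nodes <- ln_all(doc, "transition")
  transitions <- lapply(tr_nodes, function(tn) {
    outs <- ln_all(tn, "output")
    if (length(outs) == 0) {
      stop("transition without an output in ", path, call. = FALSE)
    }
    target <- plain_attrs(outs[[1]])[["qualitativeSpecies"]]
    default_level <- 0L
    dt <- ln_first(tn, "listOfFunctionTerms")
    terms <- list()
    if (!inherits(dt, "xml_missing")) {
      for (child in xml2::xml_children(dt)) {
        nm <- xml2::xml_name(child)
        at <- plain_attrs(child)
        if (nm == "defaultTerm") {
          default_level <- as.integer(at[["resultLevel"]])
        } else if (nm == "functionTerm") {
          math <- ln_first(child, "math")
          if (inherits(math, "xml_missing")) {
            stop("functionTerm without math for '", target, "'", call. = FALSE)
          }
          body <- xml2::xml_children(math)
          if (length(body) != 1) {
            stop("math of '", target, "' must contain exactly one expression",
                 call. = FALSE)
          }
          terms <- c(terms, list(list(condition = mathml_to_expr(body[[1]]),
                                      result_level =
                                        as.integer(at[["resultLevel"]]))))
        }
      }
    }
    qual_transition(target, terms, default_level)
  })

  level_refs <- function(id) {
    refs <- 0L
    for (tr in transitions) {
      lvls <- vapply(tr$terms, function(tm) tm$result_level, integer(1))
      if (tr$target == id) refs <- max(refs, tr$default_level, lvls, 0L)
      for (tm in tr$terms) refs <- max(refs, cmp_levels(tm$condition, id))
    }
    refs
  }

  species <- lapply(sp_nodes, function(sn) {
    at <- plain_attrs(sn)
    id <- at[["id"]]
    if (is.null(id) || is.na(id)) stop("qualitativeSpecies without id",
                                       call. = FALSE)
    if (is.na(at["initialLevel"])) {
      stop("species '", id, "' has no initial level", call. = FALSE)
    }
    eq <- NULL
    notes <- ln_first(sn, "notes")
    if (!inherits(notes, "xml_missing")) {
      ps <- ln_all(notes, "p")
      lines <- if (length(ps)) xml2::xml_text(ps) else
        strsplit(xml2::xml_text(notes), "\n", fixed = TRUE)[[1]]
      lines <- lines[grepl("STATE", lines)]
      if (length(lines)) eq <- parse_equivalence_note(lines)
    }
    init <- as.integer(at[["initialLevel"]])
    maxl <- if (!is.na(at["maxLevel"])) as.integer(at[["maxLevel"]]) else
      max(init, 1L, level_refs(id),
          if (!is.null(eq)) length(eq) - 1L else 0L)
    qual_species(id,
                 max_level = maxl,
                 initial_level = init,
                 name = if (!is.na(at["name"])) at[["name"]] else id,
                 equivalences = eq)
  })

  regulatory_network(species, transitions)
}

# Largest constant compared against `id` in a condition.
cmp_levels <- function(expr, id) {
  v <- expr_max_level(expr, id)
  if (is.finite(v)) as.integer(v) else 0L
}

mathml_to_expr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "true") return(lx_const(TRUE))
  if (nm == "false") return(lx_const(FALSE))
  if (nm != "apply") {
    stop("unsupported MathML construct <", nm, ">", call. = FALSE)
  }
  kids <- xml2::xml_children(node)
  op <- xml2::xml_name(kids[[1]])
  args <- kids[-1]
  if (op %in% c("and", "or")) {
    parsed <- lapply(args, mathml_to_expr)
    return(list(op = op, args = parsed))
  }
  if (op == "not") {
    if (length(args) != 1) stop("MathML <not> takes one argument",
                                call. = FALSE)
    return(lx_not(mathml_to_expr(args[[1]])))
  }
  cmp <- c(eq = "==", neq = "!=", geq = ">=", leq = "<=", gt = ">", lt = "<")
  if (op %in% names(cmp)) {
    if (length(args) != 2) {
      stop("MathML <", op, "> takes two arguments", call. = FALSE)
    }
    kinds <- vapply(args, xml2::xml_name, character(1))
    if (setequal(kinds, c("ci", "cn")) || all(kinds == c("ci", "cn"))) {
      flip <- kinds[1] == "cn"
      ci <- trimws(xml2::xml_text(args[[if (flip) 2 else 1]]))
      cn <- as.numeric(trimws(xml2::xml_text(args[[if (flip) 1 else 2]])))
      if (cn != round(cn)) {
        stop("comparison constant ", cn, " is not an integer", call. = FALSE)
      }
      opc <- cmp[[op]]
      if (flip) {
        opc <- c("==" = "==", "!=" = "!=", ">=" = "<=", "<=" = ">=",
                 ">" = "<", "<" = ">")[[opc]]
      }
      return(lx_cmp(ci, opc, as.integer(cn)))
    }
    stop("unsupported MathML comparison: expected one <ci> and one <cn>",
         call. = FALSE)
  }
  stop("unsupported MathML construct <", op, ">", call. = FALSE)
}

expr_to_mathml <- function(parent, expr) {
  if (expr$op == "const") {
    xml2::xml_add_child(parent, if (expr$value) "true" else "false")
    return(invisible(NULL))
  }
  if (expr$op == "cmp") {
    ap <- xml2::xml_add_child(parent, "apply")
    tag <- c("==" = "eq", "!=" = "neq", ">=" = "geq", "<=" = "leq",
             ">" = "gt", "<" = "lt")[[expr$cmp]]
    xml2::xml_add_child(ap, tag)
    ci <- xml2::xml_add_child(ap, "ci")
    xml2::xml_text(ci) <- expr$species
    cn <- xml2::xml_add_child(ap, "cn", type = "integer")
    xml2::xml_text(cn) <- as.character(expr$value)
    return(invisible(NULL))
  }
  if (expr$op == "not") {
    ap <- xml2::xml_add_child(parent, "apply")
    xml2::xml_add_child(ap, "not")
    expr_to_mathml(ap, expr$arg)
    return(invisible(NULL))
  }
  if (expr$op %in% c("and", "or")) {
    ap <- xml2::xml_add_child(parent, "apply")
    xml2::xml_add_child(ap, expr$op)
    for (a in expr$args) expr_to_mathml(ap, a)
    return(invisible(NULL))
  }
  stop("unknown expression operator '", expr$op, "'", call. = FALSE)
}

#' Write a regulatory network as SBML-qual
#'
#' Emits Level 3 + qual v1; state/interval equivalences are serialised as
#' `STATE` directives in the species notes. Reading the file back with
#' [read_sbml_qual()] reproduces the network up to ordering.
#'
#' @param net a [regulatory_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml_qual <- function(net, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_CORE_NS, "xmlns:qual" = SBML_QUAL_NS,
    level = "3", version = "1", "qual:required" = "true")
  model <- xml2::xml_add_child(doc, "model", id = "regulatory_network")
  lc <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(lc, "compartment", id = "default", constant = "true")
  lqs <- xml2::xml_add_child(model, "qual:listOfQualitativeSpecies")
  for (s in net$species) {
    sn <- xml2::xml_add_child(
      lqs, "qual:qualitativeSpecies",
      "qual:id" = s$id, "qual:name" = s$name, "qual:compartment" = "default",
      "qual:constant" = if (s$id %in% names(net$transitions)) "false" else "true",
      "qual:initialLevel" = as.character(s$initial_level),
      "qual:maxLevel" = as.character(s$max_level))
    if (!is.null(s$equivalences)) {
      notes <- xml2::xml_add_child(sn, "notes")
      body <- xml2::xml_add_child(notes, "body", xmlns = XHTML_NS)
      for (line in equivalences_to_note(s$equivalences)) {
        p <- xml2::xml_add_child(body, "p")
        xml2::xml_text(p) <- line
      }
    }
  }
  if (length(net$transitions)) {
    ltr <- xml2::xml_add_child(model, "qual:listOfTransitions")
    for (tr in net$transitions) {
      tn <- xml2::xml_add_child(ltr, "qual:transition",
                                "qual:id" = paste0("tr_", tr$target))
      inputs <- unique(unlist(lapply(tr$terms,
                                     function(tm) expr_species(tm$condition))))
      if (length(inputs)) {
        li <- xml2::xml_add_child(tn, "qual:listOfInputs")
        for (inp in inputs) {
          xml2::xml_add_child(li, "qual:input",
                              "qual:qualitativeSpecies" = inp,
                              "qual:transitionEffect" = "none")
        }
      }
      lo <- xml2::xml_add_child(tn, "qual:listOfOutputs")
      xml2::xml_add_child(lo, "qual:output",
                          "qual:qualitativeSpecies" = tr$target,
                          "qual:transitionEffect" = "assignmentLevel")
      lf <- xml2::xml_add_child(tn, "qual:listOfFunctionTerms")
      xml2::xml_add_child(lf, "qual:defaultTerm",
                          "qual:resultLevel" = as.character(tr$default_level))
      for (tm in tr$terms) {
        ft <- xml2::xml_add_child(lf, "qual:functionTerm",
                                  "qual:resultLevel" =
                                    as.character(tm$result_level))
        math <- xml2::xml_add_child(ft, "math", xmlns = MATHML_NS)
        expr_to_mathml(math, tm$condition)
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
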