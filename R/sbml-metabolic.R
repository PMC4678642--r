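SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Read a metabolic model from SBML
#'
#' Supports Level 3 with the fbc v2 package (flux bounds as referenced
#' parameters, GPR as `geneProductAssociation`, objective from the active
#' `fbc:objective`) and Level 2 in the COBRA dialect (bounds and objective
#' coefficients as kinetic-law parameters, GPR from `GENE_ASSOCIATION:`
#' notes). External metabolites are recognised by `boundaryCondition="true"`
#' or by the legacy `_b` id suffix. A GPR that fails to parse is dropped with
#' a warning; the reaction then counts as unregulated.
#'
#' @param path path to an SBML file.
#' @param default_bound magnitude used where the file specifies no bound.
#' @return a [metabolic_model()].
#' @export
read_sbml_metabolic <- function(path, default_bound = 9999) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)

  params <- ln_all(doc, "parameter")
  pvals <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id"))

  gp_nodes <- ln_all(doc, "geneProduct")
  gene_label <- stats::setNames(
    vapply(gp_nodes, function(n) {
      at <- plain_attrs(n)
      lab <- at["label"]
      if (is.na(lab)) at[["id"]] else lab
    }, character(1)),
    vapply(gp_nodes, function(n) plain_attrs(n)[["id"]], character(1)))

  mets <- lapply(ln_all(doc, "species"), function(n) {
    at <- plain_attrs(n)
    id <- at[["id"]]
    ext <- identical(at["boundaryCondition"], c(boundaryCondition = "true")) ||
      grepl("_b$", id)
    metabolite(id,
               name = if (!is.na(at["name"])) at[["name"]] else id,
               compartment = if (!is.na(at["compartment"])) at[["compartment"]]
                             else "c",
               is_external = ext)
  })
  met_ids <- vapply(mets, function(m) m$id, character(1))

  obj_coef <- numeric(0)
  obj_sense <- "max"

  rxns <- lapply(ln_all(doc, "reaction"), function(n) {
    at <- plain_attrs(n)
    id <- at[["id"]]
    stoich <- numeric(0)
    lr <- ln_first(n, "listOfReactants")
    if (!inherits(lr, "xml_missing")) {
      for (sr in ln_all(lr, "speciesReference")) {
        a <- plain_attrs(sr)
        sp <- a[["species"]]
        if (!sp %in% met_ids) {
          stop("reaction '", id, "' references unresolved species '", sp, "'",
               call. = FALSE)
        }
        k <- if (is.na(a["stoichiometry"])) 1 else as.numeric(a[["stoichiometry"]])
        stoich[sp] <- (if (is.na(stoich[sp])) 0 else stoich[sp]) - k
      }
    }
    lp <- ln_first(n, "listOfProducts")
    if (!inherits(lp, "xml_missing")) {
      for (sr in ln_all(lp, "speciesReference")) {
        a <- plain_attrs(sr)
        sp <- a[["species"]]
        if (!sp %in% met_ids) {
          stop("reaction '", id, "' references unresolved species '", sp, "'",
               call. = FALSE)
        }
        k <- if (is.na(a["stoichiometry"])) 1 else as.numeric(a[["stoichiometry"]])
        stoich[sp] <- (if (is.na(stoich[sp])) 0 else stoich[sp]) + k
      }
    }
    rev <- !identical(at["reversible"], c(reversible = "false"))
    lb <- ub <- NA_real_
    # fbc v2: bounds are parameter references
    if (!is.na(at["lowerFluxBound"])) lb <- pvals[[at[["lowerFluxBound"]]]]
    if (!is.na(at["upperFluxBound"])) ub <- pvals[[at[["upperFluxBound"]]]]
    # COBRA L2: kinetic-law parameters
    kl <- ln_first(n, "kineticLaw")
    if (!inherits(kl, "xml_missing")) {
      for (p in ln_all(kl, "parameter")) {
        a <- plain_attrs(p)
        if (identical(a[["id"]], "LOWER_BOUND")) lb <- as.numeric(a[["value"]])
        if (identical(a[["id"]], "UPPER_BOUND")) ub <- as.numeric(a[["value"]])
        if (identical(a[["id"]], "OBJECTIVE_COEFFICIENT")) {
          v <- as.numeric(a[["value"]])
          if (v != 0) obj_coef[id] <<- v
        }
      }
    }
    gpr <- read_gpr(n, gene_label, id)
    reaction(id, stoich, lb = lb, ub = ub, gpr = gpr, reversible = rev,
             name = if (!is.na(at["name"])) at[["name"]] else id)
  })

  # fbc objective
  lobj <- xml2::xml_find_first(doc, "//*[local-name()='listOfObjectives']")
  if (!inherits(lobj, "xml_missing")) {
    active <- plain_attrs(lobj)["activeObjective"]
    objs <- ln_all(lobj, "objective")
    pick <- NULL
    for (o in objs) {
      a <- plain_attrs(o)
      if (is.na(active) || identical(a[["id"]], active[[1]])) { pick <- o; break }
    }
    if (!is.null(pick)) {
      a <- plain_attrs(pick)
      if (identical(a[["type"]], "minimize")) obj_sense <- "min"
      fo <- ln_all(pick, "fluxObjective")
      obj_coef <- stats::setNames(
        vapply(fo, function(f) {
          cf <- plain_attrs(f)["coefficient"]
          if (is.na(cf)) 1 else as.numeric(cf)
        }, numeric(1)),
        vapply(fo, function(f) plain_attrs(f)[["reaction"]], character(1)))
    }
  }

  metabolic_model(mets, rxns,
                  objective = if (length(obj_coef)) obj_coef else NULL,
                  sense = obj_sense, default_bound = default_bound)
}

read_gpr <- function(rxn_node, gene_label, rxn_id) {
  gpa <- ln_first(rxn_node, "geneProductAssociation")
  if (!inherits(gpa, "xml_missing")) {
    kids <- xml2::xml_children(gpa)
    if (length(kids) == 1) {
      return(tryCatch(fbc_assoc_to_expr(kids[[1]], gene_label),
                      error = function(e) {
                        warning("GPR of '", rxn_id, "' not parsed: ",
                                conditionMessage(e), call. = FALSE)
                        NULL
                      }))
    }
  }
  notes <- ln_first(rxn_node, "notes")
  if (!inherits(notes, "xml_missing")) {
    txt <- xml2::xml_text(ln_all(notes, "p"))
    if (!length(txt)) txt <- xml2::xml_text(notes)
    ga <- grep("GENE_ASSOCIATION", txt, value = TRUE)
    if (length(ga)) {
      s <- trimws(sub(".*GENE_ASSOCIATION\\s*:", "", ga[[1]]))
      if (nzchar(s)) {
        return(tryCatch(parse_logic(s), error = function(e) {
          warning("GPR of '", rxn_id, "' not parsed: ", conditionMessage(e),
                  call. = FALSE)
          NULL
        }))
      }
    }
  }
  NULL
}

fbc_assoc_to_expr <- function(node, gene_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- plain_attrs(node)[["geneProduct"]]
    lab <- gene_label[gid]
    return(lx_cmp(if (is.na(lab)) gid else unname(lab), ">=", 1L))
  }
  if (nm %in% c("and", "or")) {
    args <- lapply(xml2::xml_children(node), fbc_assoc_to_expr,
                   gene_label = gene_label)
    return(list(op = nm, args = args))
  }
  stop("unsupported gene association element <", nm, ">", call. = FALSE)
}

#' Write a metabolic model as SBML Level 3 + fbc v2
#'
#' Round-trip support for fixtures and interchange: bounds become referenced
#' parameters, GPRs become `fbc:geneProductAssociation` trees, the objective
#' becomes the active `fbc:objective`.
#'
#' @param model a [metabolic_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml_metabolic <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_CORE_NS, "xmlns:fbc" = SBML_FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "metabolic_network",
                             "fbc:strict" = "true")
  comps <- unique(vapply(model$metabolites, function(m) m$compartment,
                         character(1)))
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in comps) {
    xml2::xml_add_child(lc, "compartment", id = cp, constant = "true")
  }
  ls_ <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (m in model$metabolites) {
    xml2::xml_add_child(ls_, "species", id = m$id, name = m$name,
                        compartment = m$compartment,
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = if (m$is_external) "true" else "false",
                        constant = "false")
  }
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (r in model$reactions) {
    xml2::xml_add_child(lp, "parameter", id = paste0("lb_", r$id),
                        value = as.character(r$lb), constant = "true")
    xml2::xml_add_child(lp, "parameter", id = paste0("ub_", r$id),
                        value = as.character(r$ub), constant = "true")
  }
  genes <- model_genes(model)
  if (length(genes)) {
    lg <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in genes) {
      xml2::xml_add_child(lg, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", g), "fbc:label" = g)
    }
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rn <- xml2::xml_add_child(lr, "reaction", id = r$id, name = r$name,
                              reversible = if (r$reversible) "true" else "false",
                              fast = "false",
                              "fbc:lowerFluxBound" = paste0("lb_", r$id),
                              "fbc:upperFluxBound" = paste0("ub_", r$id))
    subs <- r$stoich[r$stoich < 0]
    prods <- r$stoich[r$stoich > 0]
    if (length(subs)) {
      lrx <- xml2::xml_add_child(rn, "listOfReactants")
      for (m in names(subs)) {
        xml2::xml_add_child(lrx, "speciesReference", species = m,
                            stoichiometry = as.character(-subs[[m]]),
                            constant = "true")
      }
    }
    if (length(prods)) {
      lpx <- xml2::xml_add_child(rn, "listOfProducts")
      for (m in names(prods)) {
        xml2::xml_add_child(lpx, "speciesReference", species = m,
                            stoichiometry = as.character(prods[[m]]),
                            constant = "true")
      }
    }
    if (!is.null(r$gpr)) {
      gpa <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      expr_to_fbc_assoc(gpa, r$gpr)
    }
  }
  if (!is.null(model$objective)) {
    lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = if (model$sense == "max")
                                "maximize" else "minimize")
    lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    for (rid in names(model$objective)) {
      xml2::xml_add_child(lf, "fbc:fluxObjective", "fbc:reaction" = rid,
                          "fbc:coefficient" =
                            as.character(model$objective[[rid]]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

expr_to_fbc_assoc <- function(parent, expr) {
  if (expr$op == "cmp") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", expr$species))
    return(invisible(NULL))
  }
  if (expr$op %in% c("and", "or")) {
    nd <- xml2::xml_add_child(parent, paste0("fbc:", expr$op))
    for (a in expr$args) expr_to_fbc_assoc(nd, a)
    return(invisible(NULL))
  }
  stop("GPR with operator '", expr$op,
       "' cannot be written as an fbc association", call. = FALSE)
}
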