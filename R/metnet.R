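#' Metabolite of a constraint-based model
#'
#' @param id identifier (SBML SId).
#' @param name human-readable name.
#' @param compartment compartment id.
#' @param is_external `TRUE` for boundary metabolites (outside the mass
#'   balance; their pools encode the environment).
#' @return a `qf_metabolite` list.
#' @export
metabolite <- function(id, name = id, compartment = "c", is_external = FALSE) {
  stopifnot(is.character(id), length(id) == 1L)
  structure(list(id = id, name = name, compartment = compartment,
                 is_external = isTRUE(is_external)),
            class = "qf_metabolite")
}

#' Stoichiometric reaction
#'
#' @param id identifier.
#' @param stoich named numeric vector: metabolite id -> signed coefficient
#'   (negative = substrate, positive = product).
#' @param lb,ub flux bounds, mmol/(gDW h). Missing bounds default to
#'   `(-default_bound, default_bound)` for reversible reactions and
#'   `(0, default_bound)` otherwise, resolved by [metabolic_model()].
#' @param gpr gene-protein-reaction association: a logic expression, a GPR
#'   string such as `"(g1 and g2) or g3"`, or `NULL` (unregulated).
#' @param reversible reversibility flag (defaults to `lb < 0` when bounds are
#'   given).
#' @param name human-readable name.
#' @return a `qf_reaction` list.
#' @export
reaction <- function(id, stoich, lb = NA_real_, ub = NA_real_, gpr = NULL,
                     reversible = NULL, name = id) {
  stopifnot(is.character(id), length(id) == 1L)
  if (length(stoich) == 0 || is.null(names(stoich))) {
    stop("reaction '", id, "' needs a named, non-empty stoichiometry",
         call. = FALSE)
  }
  if (is.character(gpr)) gpr <- parse_logic(gpr)
  if (is.null(reversible)) reversible <- !is.na(lb) && lb < 0
  structure(list(id = id, name = name, stoich = stoich,
                 lb = as.numeric(lb), ub = as.numeric(ub), gpr = gpr,
                 reversible = isTRUE(reversible)),
            class = "qf_reaction")
}

#' Assemble and validate a metabolic model
#'
#' @param metabolites list of [metabolite()] objects.
#' @param reactions list of [reaction()] objects.
#' @param objective a reaction id, or a named numeric vector of coefficients
#'   over reaction ids (a linear combination).
#' @param sense `"max"` or `"min"`.
#' @param default_bound magnitude used for bounds the input left unspecified.
#' @return a `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, objective = NULL,
                            sense = c("max", "min"), default_bound = 9999) {
  sense <- match.arg(sense)
  mids <- vapply(metabolites, function(m) m$id, character(1))
  if (anyDuplicated(mids)) {
    stop("duplicate metabolite id: ", mids[duplicated(mids)][1], call. = FALSE)
  }
  names(metabolites) <- mids
  rids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(rids)) {
    stop("duplicate reaction id: ", rids[duplicated(rids)][1], call. = FALSE)
  }
  names(reactions) <- rids
  for (r in reactions) {
    bad <- setdiff(names(r$stoich), mids)
    if (length(bad)) {
      stop("reaction '", r$id, "' references unknown metabolite '", bad[1],
           "'", call. = FALSE)
    }
  }
  reactions <- lapply(reactions, function(r) {
    if (is.na(r$lb)) r$lb <- if (r$reversible) -default_bound else 0
    if (is.na(r$ub)) r$ub <- default_bound
    if (r$lb > r$ub) {
      stop("reaction '", r$id, "' has lb > ub", call. = FALSE)
    }
    r
  })
  obj <- normalise_objective(objective, rids)
  structure(list(metabolites = metabolites, reactions = reactions,
                 objective = obj, sense = sense,
                 default_bound = default_bound),
            class = "metabolic_model")
}

normalise_objective <- function(objective, rids) {
  if (is.null(objective)) return(NULL)
  if (is.character(objective) && length(objective) == 1L) {
    objective <- stats::setNames(1, objective)
  }
  bad <- setdiff(names(objective), rids)
  if (length(bad)) {
    stop("objective references unknown reaction '", bad[1], "'", call. = FALSE)
  }
  objective
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model: ", length(x$metabolites), " metabolites (",
      sum(vapply(x$metabolites, function(m) m$is_external, logical(1))),
      " external), ", length(x$reactions), " reactions>\n", sep = "")
  if (!is.null(x$objective)) {
    cat("  objective: ", x$sense, "(",
        paste(names(x$objective), collapse = " + "), ")\n", sep = "")
  }
  invisible(x)
}

#' Reaction table of a metabolic model
#' @param model a [metabolic_model()].
#' @return a tibble: `id`, `lb`, `ub`, `reversible`, `gpr` (text or `NA`),
#'   `equation`.
#' @export
reaction_table <- function(model) {
  tibble::tibble(
    id = names(model$reactions),
    lb = vapply(model$reactions, function(r) r$lb, numeric(1)),
    ub = vapply(model$reactions, function(r) r$ub, numeric(1)),
    reversible = vapply(model$reactions, function(r) r$reversible, logical(1)),
    gpr = vapply(model$reactions, function(r)
      if (is.null(r$gpr)) NA_character_ else expr_to_text(r$gpr), character(1)),
    equation = vapply(model$reactions, reaction_equation, character(1)))
}

reaction_equation <- function(r) {
  co <- function(v, m) if (abs(v) == 1) m else paste0(abs(v), " ", m)
  subs <- names(r$stoich)[r$stoich < 0]
  prods <- names(r$stoich)[r$stoich > 0]
  paste(paste(mapply(co, r$stoich[subs], subs), collapse = " + "),
        if (r$reversible) "<->" else "->",
        paste(mapply(co, r$stoich[prods], prods), collapse = " + "))
}

#' Identify exchange reactions of external metabolites
#'
#' Exchange reactions bridge the model boundary: they involve a single species
#' (a drain/source, e.g. `glc_e ->` or `-> glc_c`) or exactly one non-external
#' metabolite (the transport-exchange form `glc_e -> glc_c`). The uptake
#' direction is the flux sign that supplies the cell: `+1` when the
#' boundary-facing species (single form) or internal metabolite (two-species
#' form) is a product, `-1` when it is a reactant.
#'
#' @param model a [metabolic_model()].
#' @return a tibble: `metabolite` (external metabolite id), `reaction`,
#'   `uptake_direction` (+1/-1). External metabolites with no exchange
#'   reaction are dropped with a warning.
#' @export
find_exchange_reactions <- function(model) {
  ext <- names(model$metabolites)[vapply(model$metabolites,
                                         function(m) m$is_external, logical(1))]
  rows <- list()
  claimed <- character(0)
  for (r in model$reactions) {
    met <- names(r$stoich)
    is_ext <- vapply(met, function(m) model$metabolites[[m]]$is_external,
                     logical(1))
    if (length(met) == 1L) {
      dir <- if (r$stoich[[1]] > 0) 1L else -1L
      rows[[length(rows) + 1L]] <-
        list(metabolite = met, reaction = r$id, uptake_direction = dir)
      claimed <- c(claimed, met)
    } else if (sum(!is_ext) == 1L && sum(is_ext) >= 1L) {
      internal <- met[!is_ext]
      dir <- if (r$stoich[[internal]] > 0) 1L else -1L
      for (e in met[is_ext]) {
        rows[[length(rows) + 1L]] <-
          list(metabolite = e, reaction = r$id, uptake_direction = dir)
        claimed <- c(claimed, e)
      }
    }
  }
  missing <- setdiff(ext, claimed)
  if (length(missing)) {
    warning("external metabolite(s) with no exchange reaction omitted: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  if (nrow(out) == 0) {
    return(tibble::tibble(metabolite = character(0), reaction = character(0),
                          uptake_direction = integer(0)))
  }
  out
}

#' Evaluate a gene-protein-reaction association
#'
#' A gene counts as present when its level is strictly positive; genes absent
#' from `gene_states` are treated as present (unregulated).
#'
#' @param gpr a logic expression over gene ids (or `NULL`, always active).
#' @param gene_states named numeric vector or list: gene id -> level.
#' @return `TRUE` if the reaction can carry flux.
#' @export
evaluate_gpr <- function(gpr, gene_states) {
  if (is.null(gpr)) return(TRUE)
  if (is.character(gpr)) gpr <- parse_logic(gpr)
  eval_gpr_node(gpr, gene_states)
}

eval_gpr_node <- function(expr, gene_states) {
  if (expr$op == "cmp") {
    lvl <- gene_states[[expr$species]]
    if (is.null(lvl)) return(TRUE)  # unregulated gene defaults to active
    return(lvl > 0)
  }
  if (expr$op == "and") {
    for (a in expr$args) if (!eval_gpr_node(a, gene_states)) return(FALSE)
    return(TRUE)
  }
  if (expr$op == "or") {
    for (a in expr$args) if (eval_gpr_node(a, gene_states)) return(TRUE)
    return(FALSE)
  }
  if (expr$op == "not") return(!eval_gpr_node(expr$arg, gene_states))
  if (expr$op == "const") return(expr$value)
  stop("unknown GPR operator '", expr$op, "'", call. = FALSE)
}

# All gene ids referenced by any GPR in the model.
model_genes <- function(model) {
  unique(unlist(lapply(model$reactions, function(r)
    if (is.null(r$gpr)) character(0) else expr_species(r$gpr))))
}
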