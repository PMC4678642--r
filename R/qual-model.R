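#' Qualitative species
#'
#' A component of a multi-state regulatory network: a gene, protein, signalling
#' molecule, reaction or external metabolite taking integer levels
#' `0..max_level`. An optional equivalence map declares, for every level, the
#' continuous interval it abstracts (see [parse_equivalence_note()]); species
#' used as quantitative inputs or outputs need one, purely qualitative species
#' do not.
#'
#' @param id species identifier (SBML SId).
#' @param max_level largest admissible level (>= 0); Boolean species use 1.
#' @param initial_level starting level, in `[0, max_level]`.
#' @param name human-readable name.
#' @param equivalences `NULL`, or a named list mapping every level `"0"` ..
#'   `"max_level"` to a [qf_interval()]; intervals must be pairwise disjoint.
#' @return a `qual_species` object.
#' @examples
#' qual_species("M_glc_e", max_level = 1, initial_level = 0,
#'              equivalences = parse_equivalence_note(
#'                "STATE 0:[0,0]\nSTATE 1:]0,+inf["))
#' @export
qual_species <- function(id, max_level = 1L, initial_level = 0L, name = id,
                         equivalences = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  max_level <- as.integer(max_level)
  initial_level <- as.integer(initial_level)
  if (max_level < 0L) stop("max_level of '", id, "' is negative", call. = FALSE)
  if (initial_level < 0L || initial_level > max_level) {
    stop("initial level of '", id, "' outside [0, ", max_level, "]",
         call. = FALSE)
  }
  if (!is.null(equivalences)) {
    want <- as.character(0:max_level)
    if (!setequal(names(equivalences), want)) {
      stop("equivalences of '", id, "' must cover every level 0..", max_level,
           " exactly once", call. = FALSE)
    }
    check_equivalences_disjoint(equivalences)
    equivalences <- equivalences[want]
  }
  structure(list(id = id, name = name, max_level = max_level,
                 initial_level = initial_level, equivalences = equivalences),
            class = "qual_species")
}

#' Transition (update rule) of a qualitative species
#'
#' The rule assigns, at every synchronous update, the result level of the first
#' term whose condition holds in the current state, or `default_level` when no
#' term fires. A species with no transition is an input: its level never
#' changes under update.
#'
#' @param target id of the species the rule updates.
#' @param terms list of terms, each `list(condition = <logic expr or text>,
#'   result_level = <int>)`; order matters (first match wins).
#' @param default_level level assigned when no condition holds.
#' @return a `qual_transition` object.
#' @examples
#' qual_transition("B", list(list(condition = "not (I >= 1)",
#'                                result_level = 1)))
#' @export
qual_transition <- function(target, terms = list(), default_level = 0L) {
  stopifnot(is.character(target), length(target) == 1L)
  terms <- lapply(terms, function(tm) {
    cond <- tm$condition
    if (is.character(cond)) cond <- parse_logic(cond)
    list(condition = cond, result_level = as.integer(tm$result_level))
  })
  structure(list(target = target, terms = terms,
                 default_level = as.integer(default_level)),
            class = "qual_transition")
}

#' Assemble and validate a regulatory network
#'
#' @param species list of [qual_species()] objects.
#' @param transitions list of [qual_transition()] objects, at most one per
#'   target species.
#' @return a `regulatory_network` object: species and transitions stored as
#'   named lists, species sorted by id.
#' @export
regulatory_network <- function(species = list(), transitions = list()) {
  ids <- vapply(species, function(s) s$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate species id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  names(species) <- ids
  species <- species[order(ids)]
  tg <- vapply(transitions, function(t) t$target, character(1))
  if (anyDuplicated(tg)) {
    stop("more than one transition targets '", tg[duplicated(tg)][1], "'",
         call. = FALSE)
  }
  names(transitions) <- tg
  net <- structure(list(species = species, transitions = transitions),
                   class = "regulatory_network")
  validate_regulatory_network(net)
}

validate_regulatory_network <- function(net) {
  ids <- names(net$species)
  for (tr in net$transitions) {
    if (!tr$target %in% ids) {
      stop("transition targets undeclared species '", tr$target, "'",
           call. = FALSE)
    }
    maxl <- net$species[[tr$target]]$max_level
    for (tm in tr$terms) {
      refs <- expr_species(tm$condition)
      bad <- setdiff(refs, ids)
      if (length(bad)) {
        stop("rule for '", tr$target, "' references undeclared species '",
             bad[1], "'", call. = FALSE)
      }
      if (tm$result_level < 0L || tm$result_level > maxl) {
        stop("rule for '", tr$target, "' assigns level ", tm$result_level,
             " outside [0, ", maxl, "]", call. = FALSE)
      }
    }
    if (tr$default_level < 0L || tr$default_level > maxl) {
      stop("default level of '", tr$target, "' outside [0, ", maxl, "]",
           call. = FALSE)
    }
  }
  net
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("<regulatory_network: ", length(x$species), " species, ",
      length(x$transitions), " transitions>\n", sep = "")
  for (s in x$species) {
    cat("  ", s$id, " [0..", s$max_level, "] init=", s$initial_level,
        if (!is.null(s$equivalences)) " (quantitative)" else "",
        if (is.null(x$transitions[[s$id]])) " <input>" else "",
        "\n", sep = "")
  }
  invisible(x)
}

#' Species table of a regulatory network
#'
#' @param net a [regulatory_network()].
#' @return a tibble with one row per species: `id`, `name`, `max_level`,
#'   `initial_level`, `is_input` (no update rule), `has_equivalences`.
#' @export
species_table <- function(net) {
  tibble::tibble(
    id = names(net$species),
    name = vapply(net$species, function(s) s$name, character(1)),
    max_level = vapply(net$species, function(s) s$max_level, integer(1)),
    initial_level = vapply(net$species, function(s) s$initial_level, integer(1)),
    is_input = !names(net$species) %in% names(net$transitions),
    has_equivalences = vapply(net$species,
                              function(s) !is.null(s$equivalences), logical(1)))
}

# A network state is a named integer vector over the sorted species ids.
as_network_state <- function(net, levels) {
  ids <- names(net$species)
  if (is.null(names(levels))) {
    stopifnot(length(levels) == length(ids))
    names(levels) <- ids
  }
  missing <- setdiff(ids, names(levels))
  if (length(missing)) {
    stop("state is missing species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  st <- as.integer(levels[ids])
  names(st) <- ids
  maxl <- vapply(net$species, function(s) s$max_level, integer(1))
  if (any(st < 0L) || any(st > maxl)) {
    bad <- ids[st < 0L | st > maxl][1]
    stop("level of '", bad, "' outside its [0, max_level] range", call. = FALSE)
  }
  st
}

#' Size of a network's state space
#'
#' The number of distinct network states, the product of `max_level + 1` over
#' all species. Exact for Boolean networks of up to 1023 species (powers of
#' two are exact doubles).
#'
#' @param net a [regulatory_network()].
#' @return a double.
#' @export
state_space_size <- function(net) {
  prod(vapply(net$species, function(s) s$max_level + 1, numeric(1)))
}

#' Apply a transition to a state
#'
#' Returns the result level of the first term whose condition evaluates true
#' in `state`, or the default level when none fires.
#'
#' @param t a [qual_transition()].
#' @param state complete named integer state vector.
#' @return integer level.
#' @export
apply_transition <- function(t, state) {
  for (tm in t$terms) {
    if (evaluate_expr(tm$condition, state)) return(tm$result_level)
  }
  t$default_level
}
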