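#' Toy lac-operon model pair
#'
#' A minimal, self-contained reconstruction of glucose/lactose catabolite
#' repression for tests and examples. Regulatory side (all Boolean):
#' the PTS component `E` senses glucose (`E' = M_glc_e >= 1`); the repressor
#' node `I` lumps LacI with catabolite repression and is active whenever
#' glucose transport is active or lactose is absent (`I' = E or not lactose`);
#' permease `P` and beta-galactosidase `B` are expressed when the operon is
#' derepressed (`P' = B' = not I`). Knocking `I` out therefore derepresses
#' the operon even in glucose. The sugar inputs carry equivalences
#' (`0 <-> [0,0]`, `1 <-> ]0,+inf[` mmol/l). Metabolic side: both sugars feed
#' a carbon pool consumed by a biomass reaction; the lactose route is gated by
#' the GPR `P and B`. Yields are round numbers so hand LP checks are exact:
#' glucose uptake (<= 10) yields 1 carbon, lactose uptake (<= 4) yields 2,
#' biomass consumes 10 carbon per unit growth — so growth is 1.0 1/h on
#' glucose alone and 1.8 1/h on both sugars without regulation.
#'
#' @return a `toy_pair`: list with `regulatory` (a [regulatory_network()]),
#'   `metabolic` (a [metabolic_model()]), `biomass_id` and a documented
#'   `phenotypes` tibble (condition -> expected operon state and growth).
#' @export
make_lac_operon <- function() {
  sugar_eq <- parse_equivalence_note("STATE 0:[0,0]\nSTATE 1:]0,+inf[")
  reg <- regulatory_network(
    species = list(
      qual_species("M_glc_e", max_level = 1, initial_level = 0,
                   name = "extracellular D-glucose", equivalences = sugar_eq),
      qual_species("M_lcts_e", max_level = 1, initial_level = 0,
                   name = "extracellular lactose", equivalences = sugar_eq),
      qual_species("E", initial_level = 1, name = "PTS EIIA (glucose transport)"),
      qual_species("I", initial_level = 1, name = "active lac repressor"),
      qual_species("P", initial_level = 0, name = "lactose permease"),
      qual_species("B", initial_level = 0, name = "beta-galactosidase")),
    transitions = list(
      qual_transition("E", list(list(condition = "M_glc_e >= 1",
                                     result_level = 1))),
      qual_transition("I", list(list(condition = "E >= 1 or not (M_lcts_e >= 1)",
                                     result_level = 1))),
      qual_transition("P", list(list(condition = "not (I >= 1)",
                                     result_level = 1))),
      qual_transition("B", list(list(condition = "not (I >= 1)",
                                     result_level = 1)))))

  met <- metabolic_model(
    metabolites = list(
      metabolite("M_glc_e", compartment = "e", is_external = TRUE),
      metabolite("M_lcts_e", compartment = "e", is_external = TRUE),
      metabolite("M_c", name = "carbon pool")),
    reactions = list(
      reaction("R_GLC_up", c(M_glc_e = -1, M_c = 1), lb = 0, ub = 10),
      reaction("R_LCTS_up", c(M_lcts_e = -1, M_c = 2), lb = 0, ub = 4,
               gpr = "P and B"),
      reaction("R_BIOMASS", c(M_c = -10), lb = 0, ub = 1000)),
    objective = "R_BIOMASS", sense = "max")

  phenotypes <- tibble::tibble(
    condition = c("glucose", "lactose", "both", "none"),
    M_glc_e = c(11.1, 0, 11.1, 0),
    M_lcts_e = c(0, 8, 8, 0),
    B = c(0L, 1L, 0L, 0L),
    P = c(0L, 1L, 0L, 0L),
    growth = c(1.0, 0.8, 1.0, 0.0))

  structure(list(regulatory = reg, metabolic = met,
                 biomass_id = "R_BIOMASS", phenotypes = phenotypes),
            class = "toy_pair")
}

#' Maltose extension of the lac toy (multi-state glucose)
#'
#' Extends [make_lac_operon()] with a maltose operon whose induction is only
#' repressed above a glucose threshold of 0.6 mmol/l: glucose becomes a
#' three-level species with equivalences `0 <-> [0,0]`, `1 <-> ]0,0.6]`,
#' `2 <-> ]0.6,+inf[`, the maltose regulator obeys
#' `Mal' = maltose present and not (glucose level 2)`, and the lactose operon
#' stays repressed at any positive glucose. So at 0.3 mmol/l glucose the cell
#' can use maltose but not lactose, at 22 mmol/l neither, at 0 both — a
#' behaviour a two-level glucose encoding cannot express.
#'
#' @param boolean_glucose if `TRUE`, build the collapsed Boolean control:
#'   glucose keeps two levels and any positive glucose represses the maltose
#'   operon, which erases the low-glucose regime.
#' @return a `toy_pair` like [make_lac_operon()], with maltose species,
#'   regulator `Mal` and uptake reaction `R_MLT_up` added.
#' @export
make_maltose_extension <- function(boolean_glucose = FALSE) {
  base <- make_lac_operon()
  glc_eq <- if (boolean_glucose) {
    parse_equivalence_note("STATE 0:[0,0]\nSTATE 1:]0,+inf[")
  } else {
    parse_equivalence_note("STATE 0:[0,0]\nSTATE 1:]0,0.6]\nSTATE 2:]0.6,+inf[")
  }
  mal_rule <- if (boolean_glucose) {
    "M_mlt_e >= 1 and not (M_glc_e >= 1)"
  } else {
    "M_mlt_e >= 1 and not (M_glc_e >= 2)"
  }
  sugar_eq <- parse_equivalence_note("STATE 0:[0,0]\nSTATE 1:]0,+inf[")
  reg <- regulatory_network(
    species = c(
      list(qual_species("M_glc_e", max_level = if (boolean_glucose) 1 else 2,
                        initial_level = 0, name = "extracellular D-glucose",
                        equivalences = glc_eq),
           qual_species("M_mlt_e", max_level = 1, initial_level = 0,
                        name = "extracellular maltose",
                        equivalences = sugar_eq),
           qual_species("Mal", initial_level = 0,
                        name = "maltose operon proteins")),
      base$regulatory$species[c("M_lcts_e", "E", "I", "P", "B")]),
    transitions = c(
      base$regulatory$transitions,
      list(qual_transition("Mal", list(list(condition = mal_rule,
                                            result_level = 1))))))

  met <- base$metabolic
  met <- metabolic_model(
    metabolites = c(met$metabolites,
                    list(metabolite("M_mlt_e", compartment = "e",
                                    is_external = TRUE))),
    reactions = c(met$reactions,
                  list(reaction("R_MLT_up", c(M_mlt_e = -1, M_c = 2),
                                lb = 0, ub = 4, gpr = "Mal"))),
    objective = "R_BIOMASS", sense = "max")

  phenotypes <- tibble::tibble(
    condition = c("glc 0", "glc 0.3", "glc 22"),
    M_glc_e = c(0, 0.3, 22),
    lactose_usable = c(TRUE, FALSE, FALSE),
    maltose_usable = c(TRUE, TRUE, FALSE))
  if (boolean_glucose) phenotypes$maltose_usable <- c(TRUE, FALSE, FALSE)

  structure(list(regulatory = reg, metabolic = met,
                 biomass_id = "R_BIOMASS", phenotypes = phenotypes),
            class = "toy_pair")
}

#' Random Boolean regulatory network
#'
#' Oracle substrate for property tests: `n` Boolean species, each updated by
#' a random expression over at most `k` randomly chosen regulators
#' (a species drawing zero regulators gets a constant rule). Reproducible for
#' a fixed seed.
#'
#' @param n number of species (1..16).
#' @param k maximum regulators per rule.
#' @param seed integer seed.
#' @return a [regulatory_network()].
#' @export
make_random_boolean_network <- function(n, k = 2, seed) {
  stopifnot(n >= 1, n <= 16, k >= 0)
  ids <- sprintf("s%02d", seq_len(n))
  withr::with_seed(as.integer(seed), {
    species <- lapply(ids, function(id) {
      qual_species(id, max_level = 1,
                   initial_level = sample(0:1, 1))
    })
    transitions <- lapply(ids, function(id) {
      nk <- sample(0:k, 1)
      if (nk == 0) {
        return(qual_transition(id, default_level = sample(0:1, 1)))
      }
      regs <- sample(ids, nk)
      leaves <- lapply(regs, function(r) {
        leaf <- lx_cmp(r, ">=", 1L)
        if (stats::runif(1) < 0.5) lx_not(leaf) else leaf
      })
      expr <- if (length(leaves) == 1L) {
        leaves[[1]]
      } else if (stats::runif(1) < 0.5) {
        list(op = "and", args = leaves)
      } else {
        list(op = "or", args = leaves)
      }
      qual_transition(id, list(list(condition = expr, result_level = 1L)),
                      default_level = 0L)
    })
    regulatory_network(species, transitions)
  })
}

# --- independent brute-force oracle -----------------------------------------
# Deliberately re-implements expression evaluation, rule application and
# cycle canonicalisation with its own code so it can serve as an oracle for
# the attractor machinery.

oracle_eval <- function(e, st) {
  if (e$op == "const") return(e$value)
  if (e$op == "cmp") {
    l <- st[[e$species]]
    return(switch(e$cmp, "==" = l == e$value, "!=" = l != e$value,
                  ">=" = l >= e$value, "<=" = l <= e$value,
                  ">" = l > e$value, "<" = l < e$value))
  }
  if (e$op == "not") return(!oracle_eval(e$arg, st))
  vals <- vapply(e$args, oracle_eval, logical(1), st = st)
  if (e$op == "and") all(vals) else any(vals)
}

#' Exhaustive attractor census by explicit state enumeration
#'
#' Enumerates every initial state of a small network, follows each synchronous
#' trajectory by hashing successor indices in the functional state graph, and
#' returns every attractor with its basin size. The walk uses its own
#' expression evaluator and canonicalisation, independent of
#' [find_attractor()]/[multi_rsa_census()], so it can act as their oracle.
#'
#' @param net a [regulatory_network()] with at most 2^16 states.
#' @return a tibble `key` (canonical attractor key), `size` (cycle length)
#'   and `basin` (number of initial states reaching it); the attractor state
#'   matrices are carried in `attr(, "attractors")` (named by key).
#' @export
brute_force_attractors <- function(net) {
  size <- state_space_size(net)
  if (size > 2^16) {
    stop("state space of ", format(size),
         " states is too large for exhaustive enumeration", call. = FALSE)
  }
  ids <- names(net$species)
  radix <- vapply(net$species, function(s) s$max_level + 1L, integer(1))
  n <- length(ids)

  index_to_state <- function(ix) {  # 0-based mixed radix, first id fastest
    st <- integer(n)
    for (j in seq_len(n)) {
      st[j] <- ix %% radix[j]
      ix <- ix %/% radix[j]
    }
    names(st) <- ids
    st
  }
  state_to_index <- function(st) {
    ix <- 0
    mult <- 1
    for (j in seq_len(n)) {
      ix <- ix + st[[j]] * mult
      mult <- mult * radix[j]
    }
    ix
  }

  succ <- integer(size)
  states <- vector("list", size)
  for (ix in seq_len(size)) {
    st <- index_to_state(ix - 1L)
    states[[ix]] <- st
    nxt <- st
    for (tr in net$transitions) {
      lvl <- tr$default_level
      for (tm in tr$terms) {
        if (oracle_eval(tm$condition, st)) {
          lvl <- tm$result_level
          break
        }
      }
      nxt[[tr$target]] <- lvl
    }
    succ[ix] <- state_to_index(nxt) + 1L
  }

  att_of <- integer(size)           # 0 = unassigned
  cycles <- list()
  for (start in seq_len(size)) {
    if (att_of[start] != 0L) next
    path <- integer(0)
    pos_in_path <- new.env(parent = emptyenv(), hash = TRUE)
    node <- start
    repeat {
      if (att_of[node] != 0L) {
        aid <- att_of[node]
        break
      }
      p <- pos_in_path[[as.character(node)]]
      if (!is.null(p)) {          # new cycle discovered within this walk
        cyc <- path[p:length(path)]
        cycles[[length(cycles) + 1L]] <- cyc
        aid <- length(cycles)
        break
      }
      path <- c(path, node)
      pos_in_path[[as.character(node)]] <- length(path)
      node <- succ[node]
    }
    att_of[path] <- aid
  }

  keys <- vapply(cycles, function(cyc) {
    mats <- lapply(cyc, function(ix) states[[ix]])
    # rotate to the lexicographically smallest member (own comparison code)
    txt <- vapply(mats, function(s) paste(s, collapse = ","), character(1))
    pad <- vapply(mats, function(s)
      paste(sprintf("%09d", s), collapse = ","), character(1))
    best <- which.min(rank(pad, ties.method = "first"))
    paste(txt[c(seq(best, length(txt)),
                if (best > 1) seq_len(best - 1))], collapse = ";")
  }, character(1))

  basin <- tabulate(att_of, nbins = length(cycles))
  atts <- lapply(cycles, function(cyc) do.call(rbind,
                                               lapply(cyc, function(ix)
                                                 states[[ix]])))
  names(atts) <- keys
  out <- tibble::tibble(key = keys,
                        size = vapply(cycles, length, integer(1)),
                        basin = basin)
  out <- out[order(-out$basin, out$key), ]
  attr(out, "attractors") <- atts
  out
}

#' Write every fixture to disk
#'
#' Emits, under `dir`, the SBML-qual and SBML files of the lac and maltose
#' toys plus one constraint file per documented medium, exercising the
#' writers end to end.
#'
#' @param dir output directory (created if needed).
#' @return the written paths, invisibly.
#' @export
write_fixture_files <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("lac", "maltose")) {
    fx <- if (nm == "lac") make_lac_operon() else make_maltose_extension()
    pq <- file.path(dir, paste0(nm, "_regulatory.sbml.xml"))
    pm <- file.path(dir, paste0(nm, "_metabolic.sbml.xml"))
    write_sbml_qual(fx$regulatory, pq)
    write_sbml_metabolic(fx$metabolic, pm)
    paths <- c(paths, pq, pm)
  }
  media <- list(
    cons_glucose = c("obj : MAX(R_BIOMASS)", "M_glc_e 11.1", "M_lcts_e 0"),
    cons_lactose = c("obj : MAX(R_BIOMASS)", "M_glc_e 0", "M_lcts_e 8"),
    cons_both    = c("obj : MAX(R_BIOMASS)", "M_glc_e 11.1", "M_lcts_e 8"))
  for (nm in names(media)) {
    p <- file.path(dir, paste0(nm, ".txt"))
    writeLines(c("# medium definition", media[[nm]]), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
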