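#' Construct the initial network state
#'
#' Every species starts at its declared initial level unless overridden. An
#' integer override sets the level directly; a non-integer (or any value for a
#' species with equivalences flagged as quantitative) is translated through the
#' species' state/interval equivalences into the level whose interval contains
#' it — this is how an external metabolite concentration in mmol/l enters the
#' regulatory network.
#'
#' @param net a [regulatory_network()].
#' @param overrides named list or vector: species id -> value. Values are
#'   interpreted qualitatively (a level) when the species has no equivalences,
#'   quantitatively (translated via equivalences) when it has them.
#' @param frozen character vector of species ids clamped to level 0 regardless
#'   of initial level or rule (used by knockout analysis).
#' @return a complete named integer state vector.
#' @export
build_initial_state <- function(net, overrides = list(), frozen = character(0)) {
  st <- vapply(net$species, function(s) s$initial_level, integer(1))
  names(st) <- names(net$species)
  for (id in names(overrides)) {
    if (!id %in% names(st)) {
      stop("override for unknown species '", id, "'", call. = FALSE)
    }
    val <- as.numeric(overrides[[id]])
    eq <- net$species[[id]]$equivalences
    if (!is.null(eq)) {
      st[[id]] <- level_for_value(eq, val, id)
    } else {
      if (val != round(val)) {
        stop("quantitative override ", val, " for '", id,
             "', a species without equivalences", call. = FALSE)
      }
      lvl <- as.integer(val)
      if (lvl < 0L || lvl > net$species[[id]]$max_level) {
        stop("override level ", lvl, " for '", id, "' outside [0, ",
             net$species[[id]]$max_level, "]", call. = FALSE)
      }
      st[[id]] <- lvl
    }
  }
  if (length(frozen)) {
    bad <- setdiff(frozen, names(st))
    if (length(bad)) stop("cannot freeze unknown species '", bad[1], "'",
                          call. = FALSE)
    st[frozen] <- 0L
  }
  st
}

#' Synchronous update of the network state
#'
#' All regulated species simultaneously take the result of their transition
#' evaluated on the previous state; input species (no transition) and frozen
#' species are unchanged.
#'
#' @inheritParams build_initial_state
#' @param state complete named integer state vector.
#' @return the successor state.
#' @export
synchronous_step <- function(net, state, frozen = character(0)) {
  nxt <- state
  for (tr in net$transitions) {
    if (tr$target %in% frozen) next
    nxt[[tr$target]] <- apply_transition(tr, state)
  }
  nxt
}

state_key <- function(state) paste(state, collapse = ",")

# Lexicographic comparison of two integer state vectors (same id order).
state_less <- function(a, b) {
  d <- a != b
  if (!any(d)) return(FALSE)
  i <- which(d)[1]
  a[[i]] < b[[i]]
}

# Rotate a cycle of states so the lexicographically smallest comes first
# (species are already in sorted id order inside each state vector).
canonicalise_cycle <- function(states) {
  if (length(states) <= 1L) return(states)
  best <- 1L
  for (i in seq_along(states)[-1]) {
    if (state_less(states[[i]], states[[best]])) best <- i
  }
  if (best == 1L) states else c(states[best:length(states)],
                                states[seq_len(best - 1L)])
}

new_attractor <- function(states) {
  states <- canonicalise_cycle(states)
  structure(list(states = states,
                 kind = if (length(states) == 1L) "point" else "cyclic"),
            class = "qf_attractor")
}

#' @export
print.qf_attractor <- function(x, ...) {
  cat("<", x$kind, " attractor, ", length(x$states), " state",
      if (length(x$states) > 1) "s", ">\n", sep = "")
  m <- do.call(rbind, x$states)
  print(m)
  invisible(x)
}

attractor_key <- function(att) {
  paste(vapply(att$states, state_key, character(1)), collapse = ";")
}

#' Find the attractor reached from an initial state
#'
#' Iterates the synchronous update, recording every state, until a state seen
#' before recurs; because the update is deterministic the recurrence closes a
#' cycle, whose states (from the first occurrence of the repeated state up to
#' the step before its recurrence) form the attractor. A point attractor is a
#' fixed point; larger ones are cyclic. The attractor is canonicalised by
#' rotating the cycle to start at its lexicographically smallest state, so the
#' same cycle entered at different phases compares equal.
#'
#' @inheritParams synchronous_step
#' @param initial complete named integer state vector.
#' @param max_iter safety cap on update steps; the walk provably terminates
#'   within the state-space size, so hitting the cap indicates an internal
#'   error and raises one.
#' @return a `qf_attractor` with fields `states` (list of state vectors) and
#'   `kind` (`"point"` or `"cyclic"`).
#' @export
find_attractor <- function(net, initial, frozen = character(0),
                           max_iter = 1e6) {
  state <- as_network_state(net, initial)
  if (length(state) == 0L) return(new_attractor(list(state)))
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  trace <- vector("list", 64L)
  i <- 0L
  repeat {
    key <- state_key(state)
    prev <- seen[[key]]
    if (!is.null(prev)) {
      return(new_attractor(trace[seq(prev, i)]))
    }
    i <- i + 1L
    if (i > max_iter) {
      stop("attractor search exceeded the iteration cap (", max_iter,
           "); this indicates an internal error", call. = FALSE)
    }
    if (i > length(trace)) trace <- c(trace, vector("list", length(trace)))
    trace[[i]] <- state
    seen[[key]] <- i
    state <- synchronous_step(net, state, frozen = frozen)
  }
}

#' Translate an attractor into one steady-state constraint per species
#'
#' Species with state/interval equivalences: each attractor level is mapped to
#' its interval, and the constraint is the interval whose lower (upper) bound
#' is the arithmetic mean of the member lower (upper) bounds — for a point
#' attractor this is just the single translated interval. A mean over any
#' unbounded member interval is unbounded. Species without equivalences get
#' the arithmetic mean of their attractor levels as a single qualitative
#' value.
#'
#' @inheritParams synchronous_step
#' @param att a `qf_attractor` for `net`.
#' @return a `qf_steady_state`: tibble with columns `component`, `type`
#'   (`"interval"` or `"mean"`), `lb`, `ub` (interval constraints; `NA` for
#'   means) and `value` (qualitative mean; `NA` for intervals).
#' @export
attractor_to_steady_state <- function(net, att) {
  ids <- names(net$species)
  type <- character(length(ids)); lb <- ub <- val <- rep(NA_real_, length(ids))
  for (k in seq_along(ids)) {
    id <- ids[[k]]
    lv <- vapply(att$states, function(s) s[[id]], integer(1))
    eq <- net$species[[id]]$equivalences
    if (is.null(eq)) {
      type[k] <- "mean"
      val[k] <- mean(lv)
    } else {
      type[k] <- "interval"
      ivs <- lapply(as.character(lv), function(l) eq[[l]])
      lb[k] <- mean(vapply(ivs, function(v) v$lower, numeric(1)))
      ub[k] <- mean(vapply(ivs, function(v) v$upper, numeric(1)))
    }
  }
  structure(tibble::tibble(component = ids, type = type, lb = lb, ub = ub,
                           value = val),
            class = c("qf_steady_state", class(tibble::tibble())))
}

#' Regulatory steady-state analysis
#'
#' The full pipeline: build the initial state (translating quantitative
#' overrides through equivalences), iterate the synchronous update to an
#' attractor, translate attractor levels back into intervals, and average over
#' cyclic attractors to produce a single constraint per component.
#'
#' @inheritParams build_initial_state
#' @param max_iter passed to [find_attractor()].
#' @return an `rsa_result` list with elements `attractor` (a `qf_attractor`)
#'   and `steady_state` (a `qf_steady_state` tibble).
#' @examples
#' fx <- make_lac_operon()
#' rsa <- run_rsa(fx$regulatory, overrides = list(M_glc_e = 11.1, M_lcts_e = 0))
#' rsa$steady_state
#' @export
run_rsa <- function(net, overrides = list(), frozen = character(0),
                    max_iter = 1e6) {
  init <- build_initial_state(net, overrides, frozen = frozen)
  att <- find_attractor(net, init, frozen = frozen, max_iter = max_iter)
  structure(list(attractor = att,
                 steady_state = attractor_to_steady_state(net, att)),
            class = "rsa_result")
}

#' @export
print.rsa_result <- function(x, ...) {
  cat("Regulatory steady-state analysis: ", x$attractor$kind, " attractor of ",
      length(x$attractor$states), " state",
      if (length(x$attractor$states) > 1) "s", "\n", sep = "")
  print(x$steady_state)
  invisible(x)
}

#' Draw random initial states
#'
#' Each species' level is drawn independently and uniformly from
#' `0..max_level`; the draw is reproducible for a fixed seed (the caller's RNG
#' state is left untouched).
#'
#' @inheritParams build_initial_state
#' @param n number of states (>= 1).
#' @param seed integer seed.
#' @return a list of `n` named integer state vectors.
#' @export
random_initial_states <- function(net, n, seed) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be at least 1", call. = FALSE)
  ids <- names(net$species)
  maxl <- vapply(net$species, function(s) s$max_level, integer(1))
  withr::with_seed(as.integer(seed), {
    draws <- lapply(seq_along(ids), function(k) {
      sample.int(maxl[k] + 1L, n, replace = TRUE) - 1L
    })
    lapply(seq_len(n), function(i) {
      st <- vapply(draws, function(d) d[[i]], integer(1))
      names(st) <- ids
      st
    })
  })
}

#' All initial states of a small network
#'
#' Exhaustive mixed-radix enumeration of the state space. Refused for spaces
#' larger than `limit` states (genome-scale networks must be sampled with
#' [random_initial_states()] instead).
#'
#' @inheritParams build_initial_state
#' @param limit largest admissible state-space size.
#' @return list of all state vectors.
#' @export
all_initial_states <- function(net, limit = 2^16) {
  size <- state_space_size(net)
  if (size > limit) {
    stop("state space has ", format(size), " states, above the exhaustive ",
         "limit of ", format(limit), "; use random sampling instead",
         call. = FALSE)
  }
  ids <- names(net$species)
  radix <- vapply(net$species, function(s) s$max_level + 1L, integer(1))
  grid <- expand.grid(lapply(radix, function(r) 0:(r - 1L)),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- ids
  lapply(seq_len(nrow(grid)), function(i) {
    st <- as.integer(grid[i, ])
    names(st) <- ids
    st
  })
}

#' Attractor census over many initial conditions
#'
#' Runs [find_attractor()] from every supplied initial state and groups
#' identical canonical attractors (so different entry phases of one cycle
#' count as one attractor). This is the sampling strategy for large networks
#' whose state space cannot be enumerated.
#'
#' @inheritParams build_initial_state
#' @param initials list of state vectors, e.g. from
#'   [random_initial_states()] or [all_initial_states()].
#' @return an `attractor_census`: tibble with columns `attractor_id`, `kind`,
#'   `size`, `count`, `frequency`, ordered by decreasing count; the attractor
#'   objects are carried in `attr(, "attractors")` (named by `attractor_id`).
#' @examples
#' net <- make_random_boolean_network(6, k = 2, seed = 1)
#' census <- multi_rsa_census(net, random_initial_states(net, 200, seed = 2))
#' census
#' @export
multi_rsa_census <- function(net, initials) {
  counts <- new.env(parent = emptyenv(), hash = TRUE)
  atts <- new.env(parent = emptyenv(), hash = TRUE)
  for (st in initials) {
    att <- find_attractor(net, st)
    key <- attractor_key(att)
    n <- counts[[key]]
    if (is.null(n)) {
      counts[[key]] <- 1L
      atts[[key]] <- att
    } else {
      counts[[key]] <- n + 1L
    }
  }
  keys <- ls(counts)
  cnt <- vapply(keys, function(k) counts[[k]], integer(1))
  ord <- order(-cnt, keys)
  keys <- keys[ord]; cnt <- cnt[ord]
  attractors <- lapply(keys, function(k) atts[[k]])
  ids <- paste0("att_", seq_along(keys))
  names(attractors) <- ids
  out <- tibble::tibble(
    attractor_id = ids,
    kind = vapply(attractors, function(a) a$kind, character(1)),
    size = vapply(attractors, function(a) length(a$states), integer(1)),
    count = cnt,
    frequency = cnt / length(initials))
  attr(out, "attractors") <- attractors
  class(out) <- c("attractor_census", class(out))
  out
}
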