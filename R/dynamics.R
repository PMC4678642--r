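#' Uptake caps from finite external pools
#'
#' The batch environment holds `S` mmol/l of each external metabolite; in a
#' time step of `dt` hours a culture of density `X` g/l cannot take up more
#' than `S / (X dt)` mmol/(gDW h) without driving the pool negative. The cap
#' is intersected with the model's own uptake bound for the exchange
#' reaction.
#'
#' @param model a [metabolic_model()].
#' @param S named numeric vector of external metabolite concentrations,
#'   mmol/l.
#' @param X cell density, g/l (> 0).
#' @param dt step length, h (> 0).
#' @return a tibble `metabolite`, `reaction`, `uptake_direction`, `cap`
#'   (mmol/(gDW h), already intersected with the model bound).
#' @export
uptake_caps <- function(model, S, X, dt) {
  stopifnot(X > 0, dt > 0)
  exch <- find_exchange_reactions(model)
  exch <- exch[exch$metabolite %in% names(S), ]
  cap <- numeric(nrow(exch))
  for (i in seq_len(nrow(exch))) {
    raw <- S[[exch$metabolite[i]]] / (X * dt)
    r <- model$reactions[[exch$reaction[i]]]
    model_cap <- if (exch$uptake_direction[i] > 0) r$ub else -r$lb
    cap[i] <- min(raw, model_cap)
  }
  exch$cap <- cap
  exch
}

#' Integrate biomass and external concentrations over one step
#'
#' Within a step the growth rate and fluxes are constant, so cell density
#' grows exponentially, `X' = X e^(mu dt)`, and each consumed pool follows the
#' matching closed form `S' = S - v X (e^(mu dt) - 1) / mu` (`v` is the net
#' uptake flux in mmol/(gDW h), positive = consumption; secretion, negative
#' `v`, adds to the pool). The `mu -> 0` limit uses the linear form
#' `S' = S - v X dt`. Pools are clamped at 0; clamp events are returned in
#' the `clamped` attribute.
#'
#' @param state list with `t` (h), `X` (g/l) and `S` (named concentrations,
#'   mmol/l).
#' @param uptake named numeric vector: external metabolite id -> net uptake
#'   flux (positive = consumption).
#' @param mu growth rate of the step, 1/h.
#' @param dt step length, h.
#' @return the successor state (same shape, `t` advanced by `dt`).
#' @export
step_dynamics <- function(state, uptake, mu, dt) {
  stopifnot(dt > 0)
  growth <- exp(mu * dt)
  eaten_per_flux <- if (mu > 1e-9) state$X * (growth - 1) / mu else state$X * dt
  S <- state$S
  clamped <- character(0)
  for (id in names(S)) {
    v <- if (id %in% names(uptake)) uptake[[id]] else 0
    s_new <- S[[id]] - v * eaten_per_flux
    if (s_new < 0) {
      clamped <- c(clamped, id)
      s_new <- 0
    }
    S[[id]] <- s_new
  }
  out <- list(t = state$t + dt, X = state$X * growth, S = S)
  attr(out, "clamped") <- clamped
  out
}

#' Time-dependent regulated FBA of a batch culture
#'
#' Simulates the coupled system over `0..t_end` in steps of `dt` hours. Each
#' step: (1) external concentrations are translated into qualitative input
#' levels through the species' equivalences; (2) the regulatory network
#' advances by one update, where a species with a declared time delay only
#' changes level after its rule has proposed the same new level for that many
#' consecutive steps (delay 0 = plain synchronous); (3) the instantaneous
#' regulatory state is translated into flux constraints (same coupling rules
#' as [apply_steady_state()], no averaging); (4) finite pools cap uptake
#' fluxes ([uptake_caps()]); (5) an FBA maximises the biomass reaction; (6)
#' density and concentrations integrate forward ([step_dynamics()]). An
#' infeasible FBA is treated as starvation: zero growth and zero exchange for
#' that step. The whole loop is deterministic.
#'
#' @param model a [metabolic_model()].
#' @param net a [regulatory_network()] (or `NULL` for unregulated dynamics).
#' @param S0 named initial external concentrations, mmol/l.
#' @param X0 initial cell density, g/l.
#' @param biomass_id id of the biomass reaction; its flux is the growth rate
#'   mu in 1/h.
#' @param dt step, h (default 0.1).
#' @param t_end end time, h.
#' @param delays named integer vector of per-species update delays (steps).
#' @param overrides additional initial-value overrides for the regulatory
#'   network.
#' @param backend LP backend.
#' @return an `fba_trajectory` tibble: `t`, `X`, `mu`, one column per tracked
#'   metabolite; the per-step flux record is in `attr(, "fluxes")` and the
#'   per-step regulatory states in `attr(, "reg_states")`.
#' @examples
#' fx <- make_lac_operon()
#' tr <- time_dependent_fba(fx$metabolic, fx$regulatory,
#'                          S0 = c(M_glc_e = 2, M_lcts_e = 2), X0 = 0.05,
#'                          biomass_id = "R_BIOMASS", dt = 0.1, t_end = 4)
#' @export
time_dependent_fba <- function(model, net, S0, X0, biomass_id, dt = 0.1,
                               t_end, delays = NULL, overrides = list(),
                               backend = c("simplex", "boot")) {
  backend <- match.arg(backend)
  stopifnot(dt > 0, t_end > 0, X0 >= 0)
  if (!biomass_id %in% names(model$reactions)) {
    stop("biomass reaction '", biomass_id, "' not in the model",
         call. = FALSE)
  }
  model$objective <- stats::setNames(1, biomass_id)
  model$sense <- "max"
  exch <- find_exchange_reactions(model)
  exch <- exch[exch$metabolite %in% names(S0), ]

  reg <- NULL
  pend_level <- pend_count <- NULL
  if (!is.null(net)) {
    ids <- names(net$species)
    dl <- stats::setNames(rep(0L, length(ids)), ids)
    if (!is.null(delays)) {
      bad <- setdiff(names(delays), ids)
      if (length(bad)) stop("delay for unknown species '", bad[1], "'",
                            call. = FALSE)
      dl[names(delays)] <- as.integer(delays)
    }
    ov <- overrides
    for (id in intersect(names(S0), ids)) {
      if (!is.null(net$species[[id]]$equivalences)) ov[[id]] <- S0[[id]]
    }
    reg <- build_initial_state(net, ov)
    pend_level <- stats::setNames(rep(NA_integer_, length(ids)), ids)
    pend_count <- stats::setNames(rep(0L, length(ids)), ids)
  }

  refresh_inputs <- function(reg, S) {
    for (id in intersect(names(S), names(reg))) {
      eq <- net$species[[id]]$equivalences
      if (!is.null(eq)) reg[[id]] <- level_for_value(eq, S[[id]], id)
    }
    reg
  }

  n_steps <- ceiling(t_end / dt - 1e-9)
  times <- numeric(n_steps + 1L)
  Xs <- mus <- numeric(n_steps + 1L)
  Smat <- matrix(0, n_steps + 1L, length(S0),
                 dimnames = list(NULL, names(S0)))
  flux_rec <- vector("list", n_steps + 1L)
  reg_rec <- vector("list", n_steps + 1L)

  state <- list(t = 0, X = X0, S = as.list(S0))

  for (step in seq_len(n_steps + 1L)) {
    if (!is.null(net)) {
      reg <- refresh_inputs(reg, state$S)
      proposed <- synchronous_step(net, reg)
      for (id in names(net$transitions)) {
        p <- proposed[[id]]
        if (p == reg[[id]]) {
          pend_count[[id]] <- 0L
          pend_level[[id]] <- NA_integer_
          next
        }
        if (!is.na(pend_level[[id]]) && pend_level[[id]] == p) {
          pend_count[[id]] <- pend_count[[id]] + 1L
        } else {
          pend_level[[id]] <- p
          pend_count[[id]] <- 1L
        }
        if (pend_count[[id]] > dl[[id]]) {
          reg[[id]] <- p
          pend_count[[id]] <- 0L
          pend_level[[id]] <- NA_integer_
        }
      }
      reg <- refresh_inputs(reg, state$S)
    }

    cm <- as_constrained(model)
    if (!is.null(net)) {
      ss <- attractor_to_steady_state(net, new_attractor(list(reg)))
      cm <- apply_steady_state(cm, ss, net)
    }
    if (state$X > 0) {
      caps <- uptake_caps(model, unlist(state$S), state$X, dt)
      for (i in seq_len(nrow(caps))) {
        k <- match(caps$reaction[i], cm$effective_bounds$reaction)
        if (caps$uptake_direction[i] > 0) {
          cm$effective_bounds$ub[k] <- min(cm$effective_bounds$ub[k],
                                           caps$cap[i])
        } else {
          cm$effective_bounds$lb[k] <- max(cm$effective_bounds$lb[k],
                                           -caps$cap[i])
        }
        if (cm$effective_bounds$lb[k] > cm$effective_bounds$ub[k]) {
          cm$effective_bounds$lb[k] <- cm$effective_bounds$ub[k] <-
            max(0, min(cm$effective_bounds$ub[k], 0))
        }
      }
    }
    fit <- tryCatch(solve_fba(cm, backend = backend),
                    error = function(e) list(status = "infeasible"))
    if (identical(fit$status, "optimal")) {
      mu <- fit$objective_value
      fl <- stats::setNames(fit$fluxes$flux, fit$fluxes$reaction)
    } else {  # starvation step: no growth, no exchange
      mu <- 0
      fl <- stats::setNames(rep(0, length(model$reactions)),
                            names(model$reactions))
    }

    times[step] <- state$t
    Xs[step] <- state$X
    mus[step] <- mu
    Smat[step, ] <- unlist(state$S)[colnames(Smat)]
    flux_rec[[step]] <- fl
    reg_rec[[step]] <- reg

    if (step > n_steps) break
    uptake <- stats::setNames(numeric(nrow(exch)), exch$metabolite)
    for (i in seq_len(nrow(exch))) {
      uptake[[exch$metabolite[i]]] <-
        exch$uptake_direction[i] * fl[[exch$reaction[i]]]
    }
    state <- step_dynamics(state, uptake, mu, dt)
  }

  out <- tibble::tibble(t = times, X = Xs, mu = mus)
  for (mcol in colnames(Smat)) out[[mcol]] <- Smat[, mcol]
  attr(out, "fluxes") <- flux_rec
  attr(out, "reg_states") <- reg_rec
  class(out) <- c("fba_trajectory", class(out))
  out
}
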