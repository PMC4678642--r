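#' Constrain a metabolic model with regulatory steady-state output
#'
#' Regulatory components act on the model in three ways:
#'
#' * a component that is a **reaction**: its interval constraint is
#'   intersected with the model bounds (an unbounded end defers to the model
#'   bound); a purely qualitative reaction component switches the reaction off
#'   when its mean is exactly 0 and leaves it free otherwise;
#' * a component that is a **gene**: reactions whose GPR evaluates false under
#'   the gene levels get bounds `(0, 0)` — a gene counts as off only when its
#'   constraint is exactly 0 (mean 0 or interval `[0,0]`), so a positive
#'   cyclic-attractor mean leaves the gene active;
#' * a component that is an **external metabolite** with constraint exactly 0:
#'   the uptake direction of its exchange reaction is capped at 0 (secretion
#'   is untouched).
#'
#' The operation is idempotent: re-applying the same steady state to its own
#' output changes nothing.
#'
#' @param model a [metabolic_model()] or `constrained_model`.
#' @param ss a `qf_steady_state` tibble from [run_rsa()] /
#'   [attractor_to_steady_state()].
#' @param net the [regulatory_network()] that produced `ss` (used to recognise
#'   regulatory-only components; ids unknown to both model and network are
#'   ignored with a warning).
#' @return a `constrained_model`: the base model plus `effective_bounds`
#'   (tibble `reaction`, `lb`, `ub`).
#' @export
apply_steady_state <- function(model, ss, net = NULL) {
  cm <- as_constrained(model)
  base <- cm$base
  eb <- cm$effective_bounds
  rid <- eb$reaction
  genes <- model_genes(base)
  ext <- names(base$metabolites)[vapply(base$metabolites,
                                        function(m) m$is_external, logical(1))]
  exch <- find_exchange_reactions(base)
  gene_states <- list()

  is_zero <- function(row) {
    (row$type == "interval" && row$lb == 0 && row$ub == 0) ||
      (row$type == "mean" && row$value == 0)
  }

  for (i in seq_len(nrow(ss))) {
    row <- ss[i, ]
    id <- row$component
    matched <- FALSE
    if (id %in% rid) {
      matched <- TRUE
      k <- match(id, rid)
      if (row$type == "interval") {
        lo <- max(eb$lb[k], if (is.finite(row$lb)) row$lb else -Inf)
        hi <- min(eb$ub[k], if (is.finite(row$ub)) row$ub else Inf)
        if (lo > hi + 1e-9) {
          stop("steady-state interval [", row$lb, ",", row$ub,
               "] for reaction '", id, "' does not intersect its bounds [",
               eb$lb[k], ",", eb$ub[k], "]", call. = FALSE)
        }
        eb$lb[k] <- lo; eb$ub[k] <- hi
      } else if (row$value == 0) {
        eb$lb[k] <- 0; eb$ub[k] <- 0
      }
    }
    if (id %in% genes) {
      matched <- TRUE
      gene_states[[id]] <- if (is_zero(row)) 0 else 1
    }
    if (id %in% ext) {
      matched <- TRUE
      if (is_zero(row)) {
        hit <- exch[exch$metabolite == id, ]
        for (j in seq_len(nrow(hit))) {
          k <- match(hit$reaction[j], rid)
          if (hit$uptake_direction[j] > 0) {
            eb$ub[k] <- min(eb$ub[k], 0)
          } else {
            eb$lb[k] <- max(eb$lb[k], 0)
          }
          if (eb$lb[k] > eb$ub[k]) {
            stop("uptake cap on '", hit$reaction[j],
                 "' contradicts its lower bound", call. = FALSE)
          }
        }
      }
    }
    if (!matched && !(.known_to_net(id, net))) {
      warning("steady-state component '", id,
              "' matches no reaction, gene or external metabolite; ignored",
              call. = FALSE)
    }
  }

  if (length(gene_states)) {
    for (r in base$reactions) {
      if (!is.null(r$gpr) && !evaluate_gpr(r$gpr, gene_states)) {
        k <- match(r$id, rid)
        eb$lb[k] <- 0; eb$ub[k] <- 0
      }
    }
  }
  cm$effective_bounds <- eb
  cm
}

.known_to_net <- function(id, net) {
  !is.null(net) && id %in% names(net$species)
}

as_constrained <- function(model) {
  if (inherits(model, "constrained_model")) return(model)
  stopifnot(inherits(model, "metabolic_model"))
  structure(list(
    base = model,
    effective_bounds = tibble::tibble(
      reaction = names(model$reactions),
      lb = vapply(model$reactions, function(r) r$lb, numeric(1)),
      ub = vapply(model$reactions, function(r) r$ub, numeric(1)))),
    class = "constrained_model")
}

#' @export
print.constrained_model <- function(x, ...) {
  cat("<constrained_model over", length(x$base$reactions), "reactions>\n")
  changed <- x$effective_bounds
  orig <- as_constrained(x$base)$effective_bounds
  diff <- changed$lb != orig$lb | changed$ub != orig$ub
  if (any(diff)) {
    cat("  tightened bounds:\n")
    print(changed[diff, ])
  } else {
    cat("  (no bounds tightened)\n")
  }
  invisible(x)
}

# LP ingredients shared by FBA / FVA / phase analysis.
lp_ingredients <- function(cm) {
  base <- cm$base
  rid <- cm$effective_bounds$reaction
  internal <- names(base$metabolites)[!vapply(base$metabolites,
                                              function(m) m$is_external,
                                              logical(1))]
  S <- matrix(0, length(internal), length(rid),
              dimnames = list(internal, rid))
  for (r in base$reactions) {
    st <- r$stoich[names(r$stoich) %in% internal]
    if (length(st)) S[names(st), r$id] <- st
  }
  if (is.null(base$objective)) {
    stop("model has no objective; set one in the model or constraint file",
         call. = FALSE)
  }
  obj <- stats::setNames(numeric(length(rid)), rid)
  obj[names(base$objective)] <- base$objective
  list(S = S, obj = obj, lb = cm$effective_bounds$lb,
       ub = cm$effective_bounds$ub, rid = rid, sense = base$sense)
}

#' Flux balance analysis
#'
#' Maximises (or minimises) the model objective subject to steady-state mass
#' balance `S v = 0` over the internal metabolites and the effective flux
#' bounds. Note that alternate optima are common: only the objective value is
#' unique, individual fluxes of degenerate optima are not.
#'
#' @param model a [metabolic_model()] or `constrained_model` (e.g. from
#'   [apply_steady_state()]).
#' @param backend LP backend, `"simplex"` or `"boot"` (see [lp_solve()]).
#' @return an `fba_result`: list with `status`, `objective_value` and `fluxes`
#'   (tibble `reaction`, `flux`).
#' @examples
#' fx <- make_lac_operon()
#' solve_fba(fx$metabolic)
#' @export
solve_fba <- function(model, backend = c("simplex", "boot")) {
  backend <- match.arg(backend)
  cm <- as_constrained(model)
  ing <- lp_ingredients(cm)
  res <- lp_solve(ing$obj, ing$lb, ing$ub,
                  Aeq = ing$S, beq = rep(0, nrow(ing$S)),
                  sense = ing$sense, backend = backend)
  fluxes <- tibble::tibble(reaction = ing$rid,
                           flux = if (res$status == "optimal")
                             as.numeric(res$x) else NA_real_)
  structure(list(status = res$status,
                 objective_value = if (res$status == "optimal") res$value
                                   else NA_real_,
                 fluxes = fluxes),
            class = "fba_result")
}

#' @export
print.fba_result <- function(x, ...) {
  cat("FBA: ", x$status,
      if (x$status == "optimal") paste0(", objective = ",
                                        format(x$objective_value, digits = 6)),
      "\n", sep = "")
  invisible(x)
}

#' Flux variability analysis
#'
#' Solves the FBA, locks the objective at `gamma` times its optimum (within a
#' relative tolerance of 1e-6), then consecutively minimises and maximises
#' each target flux. With the built-in backend the solver restarts warm from
#' the previous optimal basis; results are identical to cold solves.
#'
#' @inheritParams solve_fba
#' @param targets reaction ids to scan (default: all reactions).
#' @param gamma fraction of the optimum retained, in `(0, 1]`.
#' @return a tibble `reaction`, `min`, `max`.
#' @export
flux_variability <- function(model, targets = NULL, gamma = 1,
                             backend = c("simplex", "boot")) {
  backend <- match.arg(backend)
  stopifnot(gamma > 0, gamma <= 1)
  cm <- as_constrained(model)
  ing <- lp_ingredients(cm)
  base_fit <- solve_fba(cm, backend = backend)
  if (base_fit$status != "optimal") {
    stop("FVA needs an optimal base FBA; status was '", base_fit$status, "'",
         call. = FALSE)
  }
  opt <- base_fit$objective_value
  slack <- 1e-6 * max(1, abs(opt))
  if (is.null(targets)) targets <- ing$rid
  bad <- setdiff(targets, ing$rid)
  if (length(bad)) stop("unknown FVA target '", bad[1], "'", call. = FALSE)

  # objective lock as an inequality row (<= form)
  if (ing$sense == "max") {
    Aub <- matrix(-ing$obj, 1)
    bub <- -(gamma * opt - slack)
  } else {
    Aub <- matrix(ing$obj, 1)
    bub <- gamma * opt + slack
  }

  n <- length(ing$rid)
  mins <- maxs <- stats::setNames(rep(NA_real_, length(targets)), targets)
  if (backend == "simplex") {
    ws <- lp_warm_new(ing$lb, ing$ub, Aeq = ing$S,
                      beq = rep(0, nrow(ing$S)), Aub = Aub, bub = bub)
    for (tg in targets) {
      e <- numeric(n); e[match(tg, ing$rid)] <- 1
      lo <- lp_warm_solve(ws, e, "min")
      hi <- lp_warm_solve(ws, e, "max")
      if (lo$status != "optimal" || hi$status != "optimal") {
        stop("FVA subproblem for '", tg, "' returned ", lo$status,
             call. = FALSE)
      }
      mins[tg] <- lo$value; maxs[tg] <- hi$value
    }
  } else {
    for (tg in targets) {
      e <- stats::setNames(numeric(n), ing$rid); e[tg] <- 1
      lo <- lp_solve(e, ing$lb, ing$ub, Aeq = ing$S,
                     beq = rep(0, nrow(ing$S)), Aub = Aub, bub = bub,
                     sense = "min", backend = "boot")
      hi <- lp_solve(e, ing$lb, ing$ub, Aeq = ing$S,
                     beq = rep(0, nrow(ing$S)), Aub = Aub, bub = bub,
                     sense = "max", backend = "boot")
      mins[tg] <- lo$value; maxs[tg] <- hi$value
    }
  }
  tibble::tibble(reaction = targets, min = as.numeric(mins),
                 max = as.numeric(maxs))
}

#' Knockout scan across metabolic and regulatory components
#'
#' Each identifier is clamped to 0 in the layer it belongs to — a reaction
#' gets bounds `(0,0)`; a regulatory component is frozen at level 0 throughout
#' the steady-state analysis, overriding its rule; a GPR gene outside the
#' network is set to 0 for GPR evaluation; an external metabolite has its
#' uptake capped at 0 — and the full pipeline (RSA where a network is given,
#' constraint application, FBA) is re-run.
#'
#' @inheritParams solve_fba
#' @param net a [regulatory_network()] or `NULL`.
#' @param ids components to knock out.
#' @param overrides initial-value overrides passed to [run_rsa()].
#' @return a tibble `id`, `status`, `objective_value`.
#' @export
knockout_scan <- function(model, net = NULL, ids, overrides = list(),
                          backend = c("simplex", "boot")) {
  backend <- match.arg(backend)
  genes <- model_genes(model)
  ext <- names(model$metabolites)[vapply(model$metabolites,
                                         function(m) m$is_external,
                                         logical(1))]
  rows <- lapply(ids, function(id) {
    cm <- as_constrained(model)
    frozen <- character(0)
    extra <- NULL
    if (!is.null(net) && id %in% names(net$species)) {
      frozen <- id
    } else if (id %in% names(model$reactions)) {
      k <- match(id, cm$effective_bounds$reaction)
      cm$effective_bounds$lb[k] <- 0
      cm$effective_bounds$ub[k] <- 0
    } else if (id %in% genes) {
      extra <- tibble::tibble(component = id, type = "mean", lb = NA_real_,
                              ub = NA_real_, value = 0)
    } else if (id %in% ext) {
      extra <- tibble::tibble(component = id, type = "interval", lb = 0,
                              ub = 0, value = NA_real_)
    } else {
      stop("knockout target '", id,
           "' is not a reaction, gene, metabolite or regulatory component",
           call. = FALSE)
    }
    ss <- NULL
    if (!is.null(net)) {
      ss <- run_rsa(net, overrides, frozen = frozen)$steady_state
    }
    if (!is.null(extra)) ss <- dplyr::bind_rows(ss, extra)
    fit <- tryCatch({
      if (!is.null(ss)) cm <- apply_steady_state(cm, ss, net)
      solve_fba(cm, backend = backend)
    }, error = function(e) list(status = "infeasible",
                                objective_value = NA_real_))
    tibble::tibble(id = id, status = fit$status,
                   objective_value = fit$objective_value)
  })
  dplyr::bind_rows(rows)
}

#' Phenotypic phase analysis
#'
#' Varies one or two reaction fluxes over a grid, fixing each grid value as an
#' equality constraint and re-optimising the objective. The shadow price along
#' each axis is the forward finite difference of the optimal objective over
#' one grid step (backward at the last grid point); grid points whose
#' shadow-price vectors agree after rounding to 6 decimals share a phase,
#' labelled by consecutive integers in scan order. Infeasible points keep
#' status `"infeasible"` and an `NA` phase.
#'
#' @inheritParams solve_fba
#' @param axes one or two reaction ids to vary.
#' @param ranges list (or single vector) of `c(lo, hi)` per axis.
#' @param steps grid points per axis (>= 2).
#' @return a `phase_grid` tibble: one column per axis (named by reaction id),
#'   `objective`, `shadow_price_1` (`_2`), `phase`, `status`.
#' @export
phenotype_phases <- function(model, axes, ranges, steps = 20,
                             backend = c("simplex", "boot")) {
  backend <- match.arg(backend)
  stopifnot(length(axes) %in% c(1L, 2L), steps >= 2)
  if (!is.list(ranges)) ranges <- list(ranges)
  stopifnot(length(ranges) == length(axes))
  cm <- as_constrained(model)
  bad <- setdiff(axes, cm$effective_bounds$reaction)
  if (length(bad)) stop("unknown axis reaction '", bad[1], "'", call. = FALSE)

  vals <- lapply(ranges, function(r) seq(r[1], r[2], length.out = steps))
  grid <- if (length(axes) == 1L) {
    data.frame(a1 = vals[[1]])
  } else {
    expand.grid(a1 = vals[[1]], a2 = vals[[2]], KEEP.OUT.ATTRS = FALSE)
  }
  obj <- rep(NA_real_, nrow(grid))
  status <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cmi <- cm
    for (k in seq_along(axes)) {
      r <- match(axes[k], cmi$effective_bounds$reaction)
      cmi$effective_bounds$lb[r] <- grid[i, k]
      cmi$effective_bounds$ub[r] <- grid[i, k]
    }
    fit <- tryCatch(solve_fba(cmi, backend = backend),
                    error = function(e) list(status = "infeasible",
                                             objective_value = NA_real_))
    obj[i] <- fit$objective_value
    status[i] <- fit$status
  }

  step_len <- vapply(vals, function(v) v[2] - v[1], numeric(1))
  dims <- vapply(vals, length, integer(1))
  idx <- function(i1, i2 = 1L) i1 + (i2 - 1L) * dims[1]
  sp <- matrix(NA_real_, nrow(grid), length(axes))
  for (i in seq_len(nrow(grid))) {
    i1 <- ((i - 1L) %% dims[1]) + 1L
    i2 <- ((i - 1L) %/% dims[1]) + 1L
    pos <- c(i1, i2)
    for (k in seq_along(axes)) {
      nb <- pos; nb[k] <- nb[k] + 1L
      if (nb[k] <= dims[k]) {
        j <- idx(nb[1], if (length(axes) == 2L) nb[2] else 1L)
        sp[i, k] <- (obj[j] - obj[i]) / step_len[k]
      } else {  # last point along axis k: backward difference
        nb[k] <- pos[k] - 1L
        j <- idx(nb[1], if (length(axes) == 2L) nb[2] else 1L)
        sp[i, k] <- (obj[i] - obj[j]) / step_len[k]
      }
    }
  }

  keys <- apply(matrix(round(sp, 6), nrow(grid)), 1, paste, collapse = "/")
  keys[status != "optimal"] <- NA
  phase <- rep(NA_integer_, nrow(grid))
  seen <- character(0)
  for (i in seq_len(nrow(grid))) {
    if (is.na(keys[i])) next
    pos <- match(keys[i], seen)
    if (is.na(pos)) {
      seen <- c(seen, keys[i])
      pos <- length(seen)
    }
    phase[i] <- pos
  }

  out <- tibble::tibble(!!axes[1] := grid$a1)
  if (length(axes) == 2L) out[[axes[2]]] <- grid$a2
  out$objective <- obj
  out$shadow_price_1 <- sp[, 1]
  if (length(axes) == 2L) out$shadow_price_2 <- sp[, 2]
  out$phase <- phase
  out$status <- status
  class(out) <- c("phase_grid", class(out))
  out
}
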