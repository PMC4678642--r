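# Independent oracles and generators shared across the suite.

# Truth-table evaluation of a logic expression by direct recursion over an
# environment of levels; written independently of evaluate_expr().
tt_eval <- function(e, lv) {
  switch(e$op,
    const = e$value,
    cmp = {
      x <- lv[[e$species]]
      if (e$cmp == "==") x == e$value
      else if (e$cmp == "!=") x != e$value
      else if (e$cmp == ">=") x >= e$value
      else if (e$cmp == "<=") x <= e$value
      else if (e$cmp == ">") x > e$value
      else x < e$value
    },
    not = !tt_eval(e$arg, lv),
    and = all(vapply(e$args, tt_eval, logical(1), lv = lv)),
    or = any(vapply(e$args, tt_eval, logical(1), lv = lv)))
}

# Random logic-expression tree over the given species, depth-bounded.
random_expr <- function(species, depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.3) {
    if (stats::runif(1) < 0.1) return(lx_const(stats::runif(1) < 0.5))
    sp <- sample(species, 1)
    op <- sample(c("==", "!=", ">=", "<=", ">", "<"), 1)
    return(lx_cmp(sp, op, sample(0:1, 1)))
  }
  kind <- sample(c("and", "or", "not"), 1)
  if (kind == "not") return(lx_not(random_expr(species, depth - 1)))
  k <- sample(2:3, 1)
  args <- lapply(seq_len(k), function(i) random_expr(species, depth - 1))
  list(op = kind, args = args)
}

# Brute-force LP oracle: enumerate vertices of {v : S v = 0, lb <= v <= ub}
# by fixing (n - rank) variables at a bound and solving for the rest.
vertex_enum_lp <- function(obj, S, lb, ub, sense = "max") {
  n <- length(obj)
  r <- if (nrow(S)) qr(S)$rank else 0L
  nfix <- n - r
  best <- NULL
  for (free in if (nfix > 0) utils::combn(n, nfix, simplify = FALSE)
       else list(integer(0))) {
    basis <- setdiff(seq_len(n), free)
    for (ci in seq_len(2^nfix)) {
      pick <- as.integer(intToBits(ci - 1))[seq_len(max(nfix, 1))][seq_len(nfix)]
      v <- numeric(n)
      v[free] <- ifelse(pick == 1, ub[free], lb[free])
      if (length(basis)) {
        rhs <- if (nrow(S)) -S[, free, drop = FALSE] %*% v[free] else numeric(0)
        xb <- tryCatch(qr.solve(S[, basis, drop = FALSE], rhs,
                                tol = 1e-10),
                       error = function(e) NULL)
        if (is.null(xb)) next
        v[basis] <- xb
      }
      if (nrow(S) && max(abs(S %*% v)) > 1e-6) next
      if (any(v < lb - 1e-7) || any(v > ub + 1e-7)) next
      val <- sum(obj * v)
      if (is.null(best) ||
          (sense == "max" && val > best) ||
          (sense == "min" && val < best)) best <- val
    }
  }
  best
}

# Random small metabolic toy with 0 always feasible (lb <= 0 <= ub).
random_toy_model <- function(n_rxn = 5, n_met = 3) {
  mets <- lapply(seq_len(n_met), function(i) metabolite(paste0("m", i)))
  mets <- c(mets, list(metabolite("x_e", is_external = TRUE)))
  rxns <- lapply(seq_len(n_rxn), function(j) {
    k <- sample(1:2, 1)
    who <- sample(n_met, k)
    st <- stats::setNames(sample(c(-2, -1, 1, 2), k, replace = TRUE),
                          paste0("m", who))
    if (j == 1) st <- c(st, x_e = -1)  # tie one reaction to the boundary
    reaction(paste0("r", j), st,
             lb = round(stats::runif(1, -5, 0), 2),
             ub = round(stats::runif(1, 0.5, 5), 2))
  })
  metabolic_model(mets, rxns, objective = paste0("r", sample(n_rxn, 1)),
                  sense = "max")
}

lp_parts <- function(model) {
  cm <- qualflux:::as_constrained(model)
  qualflux:::lp_ingredients(cm)
}

# Mass-balance residual of an FBA solution over internal metabolites.
mass_balance_residual <- function(model, fit) {
  ing <- lp_parts(model)
  v <- stats::setNames(fit$fluxes$flux, fit$fluxes$reaction)[ing$rid]
  if (!nrow(ing$S)) return(0)
  max(abs(ing$S %*% v))
}

# Two-route toy whose limiting substrate switches at axis flux 10:
# objective = a + min(a, 10) along the varied uptake a.
make_kink_toy <- function() {
  metabolic_model(
    metabolites = list(metabolite("A_e", is_external = TRUE), metabolite("A"),
                       metabolite("O2_e", is_external = TRUE),
                       metabolite("O2"), metabolite("W")),
    reactions = list(
      reaction("EX_A", c(A_e = -1, A = 1), lb = 0, ub = 30),
      reaction("EX_O2", c(O2_e = -1, O2 = 1), lb = 0, ub = 10),
      reaction("R_aer", c(A = -1, O2 = -1, W = 2), lb = 0, ub = 1000),
      reaction("R_ana", c(A = -1, W = 1), lb = 0, ub = 1000),
      reaction("R_bio", c(W = -1), lb = 0, ub = 1000)),
    objective = "R_bio")
}

# Census keys in the oracle's format, for cross-checking.
census_keys <- function(census) {
  atts <- attr(census, "attractors")
  vapply(atts, function(a)
    paste(vapply(a$states, function(s) paste(s, collapse = ","),
                 character(1)), collapse = ";"), character(1))
}
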