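# Linear-programming layer.
#
# Problems are tiny, dense flux polytopes: maximise/minimise c'v subject to
# Aeq v = beq, Aub v <= bub, lb <= v <= ub. Two interchangeable backends:
#   * "simplex": a two-phase primal simplex on the full tableau, written here;
#     keeps its basis so successive re-optimisations with new objectives (FVA)
#     restart warm from phase 2.
#   * "boot": boot::simplex() from the recommended boot package.
# Both must agree within 1e-6 on the test suite.

LP_BIG <- 1e9       # stand-in for an infinite bound inside the solver
LP_TOL <- 1e-9      # feasibility / pivot tolerance

#' Solve a bounded linear programme
#'
#' @param obj objective coefficient vector (length n).
#' @param lb,ub variable bounds (length n); infinities are admitted.
#' @param Aeq,beq equality constraints `Aeq v = beq` (may be `NULL`).
#' @param Aub,bub inequality constraints `Aub v <= bub` (may be `NULL`).
#' @param sense `"max"` or `"min"`.
#' @param backend `"simplex"` (built-in two-phase simplex) or `"boot"`
#'   (`boot::simplex`).
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `value` and `x` (named like `obj` if it has names).
#' @export
lp_solve <- function(obj, lb, ub, Aeq = NULL, beq = NULL, Aub = NULL,
                     bub = NULL, sense = c("max", "min"),
                     backend = c("simplex", "boot")) {
  sense <- match.arg(sense)
  backend <- match.arg(backend)
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(lb > ub + LP_TOL)) {
    return(list(status = "infeasible", value = NA_real_,
                x = stats::setNames(rep(NA_real_, n), names(obj))))
  }
  if (backend == "boot") {
    res <- lp_solve_boot(obj, lb, ub, Aeq, beq, Aub, bub, sense)
  } else {
    std <- lp_standardise(lb, ub, Aeq, beq, Aub, bub)
    ph1 <- lp_phase1(std)
    if (ph1$status != "feasible") {
      res <- list(status = "infeasible", value = NA_real_,
                  x = rep(NA_real_, n))
    } else {
      cost <- c(if (sense == "max") -obj else obj,
                rep(0, std$n_slack))
      ph2 <- lp_phase2(ph1$tab, ph1$basis, cost, std$n_total)
      if (ph2$status == "unbounded") {
        res <- list(status = "unbounded", value = if (sense == "max") Inf
                    else -Inf, x = rep(NA_real_, n))
      } else {
        v <- ph2$x[seq_len(n)] + std$shift
        res <- list(status = "optimal", value = sum(obj * v), x = v)
      }
    }
  }
  names(res$x) <- names(obj)
  res
}

# Shift variables to x = v - lb >= 0 and collect all rows as equalities with
# slacks (upper bounds become rows). Returns the equality system [A | b] with
# b >= 0 plus bookkeeping.
lp_standardise <- function(lb, ub, Aeq, beq, Aub, bub) {
  n <- length(lb)
  lb2 <- pmax(lb, -LP_BIG)
  ub2 <- pmin(ub, LP_BIG)
  rows <- list(); rhs <- numeric(0); kind <- character(0)
  if (!is.null(Aeq) && nrow(Aeq) > 0) {
    for (i in seq_len(nrow(Aeq))) {
      rows[[length(rows) + 1L]] <- Aeq[i, ]
      rhs <- c(rhs, beq[i] - sum(Aeq[i, ] * lb2))
      kind <- c(kind, "eq")
    }
  }
  if (!is.null(Aub) && nrow(Aub) > 0) {
    for (i in seq_len(nrow(Aub))) {
      rows[[length(rows) + 1L]] <- Aub[i, ]
      rhs <- c(rhs, bub[i] - sum(Aub[i, ] * lb2))
      kind <- c(kind, "le")
    }
  }
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    rows[[length(rows) + 1L]] <- e
    rhs <- c(rhs, ub2[j] - lb2[j])
    kind <- c(kind, "le")
  }
  m <- length(rows)
  n_slack <- sum(kind == "le")
  A <- matrix(0, m, n + n_slack)
  s <- 0L
  for (i in seq_len(m)) {
    A[i, seq_len(n)] <- rows[[i]]
    if (kind[i] == "le") {
      s <- s + 1L
      A[i, n + s] <- 1
    }
  }
  neg <- rhs < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  rhs[neg] <- -rhs[neg]
  list(A = A, b = rhs, n_vars = n, n_slack = n_slack,
       n_total = n + n_slack, shift = lb2)
}

# Phase 1: artificial variables on every row, minimise their sum.
lp_phase1 <- function(std) {
  m <- nrow(std$A)
  N <- std$n_total
  tab <- cbind(std$A, diag(m), std$b)
  basis <- N + seq_len(m)
  cost <- c(rep(0, N), rep(1, m))
  out <- lp_iterate(tab, basis, cost, allowed = N + m)
  if (out$status == "unbounded") stop("phase 1 cannot be unbounded")
  val <- sum(cost[out$basis] * out$tab[, ncol(out$tab)])
  if (val > 1e-7) return(list(status = "infeasible"))
  list(status = "feasible", tab = out$tab, basis = out$basis)
}

# Phase 2 from a feasible tableau/basis; artificial columns are blocked.
lp_phase2 <- function(tab, basis, cost, n_total) {
  full_cost <- c(cost, rep(0, ncol(tab) - 1L - n_total))
  out <- lp_iterate(tab, basis, full_cost, allowed = n_total)
  if (out$status == "unbounded") return(list(status = "unbounded"))
  b <- out$tab[, ncol(out$tab)]
  x <- numeric(ncol(out$tab) - 1L)
  x[out$basis] <- b
  list(status = "optimal", x = x, tab = out$tab, basis = out$basis,
       value = sum(full_cost[out$basis] * b))
}

# Primal simplex iterations (minimisation) with Bland's rule; `allowed` caps
# the highest column index permitted to enter the basis.
lp_iterate <- function(tab, basis, cost, allowed, max_iter = 20000L) {
  m <- nrow(tab)
  last <- ncol(tab)
  red <- cost
  zval <- 0
  for (i in seq_len(m)) {
    cb <- cost[basis[i]]
    if (cb != 0) {
      red <- red - cb * tab[i, -last]
      zval <- zval + cb * tab[i, last]
    }
  }
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) stop("simplex iteration cap exceeded", call. = FALSE)
    enter_cand <- which(red[seq_len(allowed)] < -LP_TOL)
    if (!length(enter_cand)) {
      return(list(status = "optimal", tab = tab, basis = basis))
    }
    j <- enter_cand[1L]  # Bland: lowest index
    col <- tab[, j]
    pos <- which(col > LP_TOL)
    if (!length(pos)) return(list(status = "unbounded"))
    ratio <- tab[pos, last] / col[pos]
    rmin <- min(ratio)
    ties <- pos[ratio <= rmin + LP_TOL]
    r <- ties[which.min(basis[ties])]  # Bland on the leaving variable
    piv <- tab[r, j]
    tab[r, ] <- tab[r, ] / piv
    cf <- tab[, j]
    cf[r] <- 0
    tab <- tab - outer(cf, tab[r, ])
    rc <- red[j]
    red <- red - rc * tab[r, -last]
    red[j] <- 0
    basis[r] <- j
  }
}

# Warm-restartable solver state: standardise and run phase 1 once, then
# re-optimise phase 2 from the current basis for each new objective (the
# constraint set never changes, so the basis stays primal feasible). This is
# what makes consecutive FVA re-optimisations cheap.
lp_warm_new <- function(lb, ub, Aeq = NULL, beq = NULL, Aub = NULL,
                        bub = NULL) {
  std <- lp_standardise(lb, ub, Aeq, beq, Aub, bub)
  ph1 <- lp_phase1(std)
  ws <- new.env(parent = emptyenv())
  ws$std <- std
  ws$feasible <- ph1$status == "feasible"
  if (ws$feasible) {
    ws$tab <- ph1$tab
    ws$basis <- ph1$basis
  }
  ws
}

lp_warm_solve <- function(ws, obj, sense = c("max", "min")) {
  sense <- match.arg(sense)
  n <- ws$std$n_vars
  if (!ws$feasible) {
    return(list(status = "infeasible", value = NA_real_,
                x = rep(NA_real_, n)))
  }
  cost <- c(if (sense == "max") -obj else obj, rep(0, ws$std$n_slack))
  ph2 <- lp_phase2(ws$tab, ws$basis, cost, ws$std$n_total)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded",
                value = if (sense == "max") Inf else -Inf,
                x = rep(NA_real_, n)))
  }
  ws$tab <- ph2$tab
  ws$basis <- ph2$basis
  v <- ph2$x[seq_len(n)] + ws$std$shift
  list(status = "optimal", value = sum(obj * v), x = v)
}

lp_solve_boot <- function(obj, lb, ub, Aeq, beq, Aub, bub, sense) {
  n <- length(obj)
  lb2 <- pmax(lb, -LP_BIG)
  ub2 <- pmin(ub, LP_BIG)
  # shift to x >= 0
  A1 <- diag(n); b1 <- ub2 - lb2
  if (!is.null(Aub) && nrow(Aub) > 0) {
    shift_b <- bub - as.numeric(Aub %*% lb2)
    keep_le <- shift_b >= 0
    A1 <- rbind(A1, Aub[keep_le, , drop = FALSE])
    b1 <- c(b1, shift_b[keep_le])
    A2 <- -Aub[!keep_le, , drop = FALSE]; b2 <- -shift_b[!keep_le]
  } else {
    A2 <- NULL; b2 <- NULL
  }
  if (!is.null(Aeq) && nrow(Aeq) > 0) {
    A3 <- Aeq; b3 <- beq - as.numeric(Aeq %*% lb2)
    neg <- b3 < 0
    A3[neg, ] <- -A3[neg, , drop = FALSE]; b3[neg] <- -b3[neg]
    # all-zero rows crash boot's tableau updates; drop the vacuous ones and
    # report the contradictory ones as infeasible
    zero <- apply(abs(A3), 1, max) < LP_TOL
    if (any(zero & b3 > 1e-7)) {
      return(list(status = "infeasible", value = NA_real_,
                  x = rep(NA_real_, n)))
    }
    A3 <- A3[!zero, , drop = FALSE]; b3 <- b3[!zero]
    if (nrow(A3) == 0) { A3 <- NULL; b3 <- NULL }
  } else {
    A3 <- NULL; b3 <- NULL
  }
  fit <- tryCatch(
    boot::simplex(a = obj, A1 = A1, b1 = b1,
                  A2 = if (!is.null(A2) && nrow(A2)) A2 else NULL,
                  b2 = if (!is.null(A2) && nrow(A2)) b2 else NULL,
                  A3 = A3, b3 = b3,
                  maxi = sense == "max", n.iter = 10000, eps = 1e-10),
    error = function(e) NULL)
  if (is.null(fit) || fit$solved < 1) {
    return(list(status = "infeasible", value = NA_real_,
                x = rep(NA_real_, n)))
  }
  v <- as.numeric(fit$soln) + lb2
  list(status = "optimal", value = sum(obj * v), x = v)
}
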