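test_that("steady-state constraints intersect, gate and cap as specified", {
  m <- metabolic_model(
    list(metabolite("s_e", is_external = TRUE), metabolite("c")),
    list(reaction("R1", c(s_e = -1, c = 1), lb = 0, ub = 5),
         reaction("R_LACZ", c(c = -1), lb = 0, ub = 10, gpr = "g_lacZ"),
         reaction("R_EX", c(s_e = 1), lb = -3, ub = 7)),
    objective = "R_LACZ")
  net <- regulatory_network(list(
    qual_species("R1", max_level = 1, equivalences = list(
      "0" = qf_interval(0, 0), "1" = qf_interval(2, 10))),
    qual_species("g_lacZ"), qual_species("s_e", max_level = 1,
      equivalences = list("0" = qf_interval(0, 0),
                          "1" = qf_interval(0, Inf, lower_open = TRUE)))))

  # interval constraint intersects model bounds: [2,10] n [0,5] = [2,5]
  ss <- tibble::tibble(component = "R1", type = "interval", lb = 2, ub = 10,
                       value = NA_real_)
  cm <- apply_steady_state(m, ss, net)
  eb <- cm$effective_bounds
  expect_equal(unname(unlist(eb[eb$reaction == "R1", c("lb", "ub")])),
               c(2, 5))

  # gene at 0 switches the GPR-gated reaction off
  ss2 <- tibble::tibble(component = "g_lacZ", type = "mean", lb = NA_real_,
                        ub = NA_real_, value = 0)
  cm2 <- apply_steady_state(m, ss2, net)
  eb2 <- cm2$effective_bounds
  expect_equal(unname(unlist(eb2[eb2$reaction == "R_LACZ", c("lb", "ub")])),
               c(0, 0))
  # a positive qualitative mean (cyclic attractor) leaves the gene active
  ss2b <- ss2; ss2b$value <- 0.5
  cm2b <- apply_steady_state(m, ss2b, net)
  expect_equal(unname(cm2b$effective_bounds$ub[eb2$reaction == "R_LACZ"]), 10)

  # external metabolite at 0 caps the uptake direction only; the reverse
  # (secretion) direction of each exchange survives
  ss3 <- tibble::tibble(component = "s_e", type = "interval", lb = 0, ub = 0,
                        value = NA_real_)
  cm3 <- apply_steady_state(m, ss3, net)
  eb3 <- cm3$effective_bounds
  expect_equal(unname(unlist(eb3[eb3$reaction == "R_EX", c("lb", "ub")])),
               c(-3, 0))
  # R1 transports s_e in; its uptake (positive direction) is capped too
  expect_equal(unname(eb3$ub[eb3$reaction == "R1"]), 0)

  # empty intersection errors, naming the reaction
  ss4 <- tibble::tibble(component = "R1", type = "interval", lb = 8, ub = 10,
                        value = NA_real_)
  expect_error(apply_steady_state(m, ss4, net), "R1")

  # idempotence
  cm_once <- apply_steady_state(m, ss, net)
  cm_twice <- apply_steady_state(cm_once, ss, net)
  expect_identical(cm_once$effective_bounds, cm_twice$effective_bounds)

  # a component unknown to model and network warns
  ss5 <- tibble::tibble(component = "mystery", type = "mean", lb = NA_real_,
                        ub = NA_real_, value = 1)
  expect_warning(apply_steady_state(m, ss5, net), "mystery")
})

test_that("FBA solves bottlenecks, yields and infeasibility faithfully", {
  # chain ->A->B-> with all upper bounds 10: the bottleneck caps export at 10
  chain <- metabolic_model(
    list(metabolite("A"), metabolite("B")),
    list(reaction("in_A", c(A = 1), lb = 0, ub = 10),
         reaction("A_to_B", c(A = -1, B = 1), lb = 0, ub = 10),
         reaction("out_B", c(B = -1), lb = 0, ub = 10)),
    objective = "out_B")
  for (bk in c("simplex", "boot")) {
    fit <- solve_fba(chain, backend = bk)
    expect_equal(fit$status, "optimal")
    expect_equal(fit$objective_value, 10, tolerance = 1e-9)
  }

  # glucose uptake 10 with a yield-0.8 biomass stoichiometry gives 8
  yld <- metabolic_model(
    list(metabolite("glc_e", is_external = TRUE), metabolite("glc"),
         metabolite("bio")),
    list(reaction("up", c(glc_e = -1, glc = 1), lb = 0, ub = 10),
         reaction("grow", c(glc = -1, bio = 0.8), lb = 0, ub = 1000),
         reaction("sink", c(bio = -1), lb = 0, ub = 1000)),
    objective = "sink")
  expect_equal(solve_fba(yld)$objective_value, 8, tolerance = 1e-8)

  # forced flux through a starved pathway is infeasible
  starved <- metabolic_model(
    list(metabolite("s_e", is_external = TRUE), metabolite("s")),
    list(reaction("up", c(s_e = -1, s = 1), lb = 0, ub = 0),
         reaction("use", c(s = -1), lb = 5, ub = 10)),
    objective = "use")
  expect_equal(solve_fba(starved)$status, "infeasible")
  expect_equal(solve_fba(starved, backend = "boot")$status, "infeasible")
})

test_that("LP optima match the vertex-enumeration oracle on random toys", {
  withr::with_seed(2024, {
    for (rep in 1:15) {
      m <- random_toy_model(n_rxn = sample(4:6, 1), n_met = sample(2:3, 1))
      ing <- lp_parts(m)
      oracle <- vertex_enum_lp(ing$obj, ing$S, ing$lb, ing$ub, "max")
      fit <- solve_fba(m)
      fit_boot <- solve_fba(m, backend = "boot")
      expect_equal(fit$status, "optimal")
      expect_equal(fit$objective_value, oracle, tolerance = 1e-6)
      expect_equal(fit_boot$objective_value, oracle, tolerance = 1e-6)
      expect_lt(mass_balance_residual(m, fit), 1e-6)
    }
  })
})

test_that("tightening any bound never improves a maximisation optimum", {
  fx <- make_lac_operon()
  base <- solve_fba(fx$metabolic)$objective_value
  withr::with_seed(31, {
    for (rep in 1:15) {
      cm <- qualflux:::as_constrained(fx$metabolic)
      k <- sample(nrow(cm$effective_bounds), 1)
      lo <- cm$effective_bounds$lb[k]; hi <- cm$effective_bounds$ub[k]
      cut <- sort(stats::runif(2, lo, hi))
      cm$effective_bounds$lb[k] <- cut[1]
      cm$effective_bounds$ub[k] <- cut[2]
      fit <- tryCatch(solve_fba(cm), error = function(e) NULL)
      if (!is.null(fit) && fit$status == "optimal") {
        expect_lte(fit$objective_value, base + 1e-8)
      }
    }
  })
})

test_that("FVA brackets the optimum and matches cold per-target solves", {
  fx <- make_lac_operon()
  fva <- flux_variability(fx$metabolic)
  fit <- solve_fba(fx$metabolic)
  # the objective reaction itself is pinned at the optimum
  expect_equal(fva$min[fva$reaction == "R_BIOMASS"], fit$objective_value,
               tolerance = 1e-6)
  expect_equal(fva$max[fva$reaction == "R_BIOMASS"], fit$objective_value,
               tolerance = 1e-6)
  # the FBA point lies inside every envelope
  v <- setNames(fit$fluxes$flux, fit$fluxes$reaction)
  for (i in seq_len(nrow(fva))) {
    expect_gte(v[[fva$reaction[i]]], fva$min[i] - 1e-6)
    expect_lte(v[[fva$reaction[i]]], fva$max[i] + 1e-6)
  }
  # warm-started ranges equal the boot backend's cold solves
  fva_cold <- flux_variability(fx$metabolic, backend = "boot")
  expect_equal(fva$min, fva_cold$min, tolerance = 1e-6)
  expect_equal(fva$max, fva_cold$max, tolerance = 1e-6)

  # two parallel equivalent branches bounded by 10 under demand 10: (0,10) each
  par <- metabolic_model(
    list(metabolite("A"), metabolite("B")),
    list(reaction("in_A", c(A = 1), lb = 0, ub = 20),
         reaction("br1", c(A = -1, B = 1), lb = 0, ub = 10),
         reaction("br2", c(A = -1, B = 1), lb = 0, ub = 10),
         reaction("out_B", c(B = -1), lb = 10, ub = 10)),
    objective = "out_B")
  fva2 <- flux_variability(par, targets = c("br1", "br2"))
  expect_equal(fva2$min, c(0, 0), tolerance = 1e-6)
  expect_equal(fva2$max, c(10, 10), tolerance = 1e-6)
})

test_that("knockouts propagate through reactions, genes and regulators", {
  fx <- make_lac_operon()
  both <- list(M_glc_e = 11.1, M_lcts_e = 8)
  res <- knockout_scan(fx$metabolic, fx$regulatory,
                       ids = c("R_BIOMASS", "B", "I", "M_glc_e"),
                       overrides = both)
  val <- function(id) res$objective_value[res$id == id]
  # objective reaction KO: nothing grows
  expect_equal(val("R_BIOMASS"), 0, tolerance = 1e-9)
  # gene KO equals the corresponding reaction KO by construction:
  # B off -> lactose route off -> glucose-only growth
  expect_equal(val("B"), 1.0, tolerance = 1e-6)
  # repressor KO derepresses the operon: both sugars run
  expect_equal(val("I"), 1.8, tolerance = 1e-6)
  # glucose KO: only the (derepressed) lactose route remains
  expect_equal(val("M_glc_e"), 0.8, tolerance = 1e-6)
  expect_error(knockout_scan(fx$metabolic, fx$regulatory, ids = "ghost"),
               "ghost")
})

test_that("phase analysis finds one phase for a linear response and two at a kink", {
  lin <- metabolic_model(
    list(metabolite("A")),
    list(reaction("in_A", c(A = 1), lb = 0, ub = 50),
         reaction("out_A", c(A = -1), lb = 0, ub = 1000)),
    objective = "out_A")
  pg <- phenotype_phases(lin, "in_A", c(0, 40), steps = 9)
  expect_equal(length(unique(pg$phase)), 1L)

  kink <- make_kink_toy()
  pg2 <- phenotype_phases(kink, "EX_A", c(0, 20), steps = 21)
  expect_equal(sort(unique(pg2$phase)), c(1L, 2L))
  # within a phase the shadow prices agree to the grouping tolerance
  for (ph in unique(pg2$phase)) {
    sp <- pg2$shadow_price_1[pg2$phase == ph]
    expect_lt(max(sp) - min(sp), 1e-6 * max(1, abs(mean(sp))))
  }
  # the two phases have distinct shadow prices (2 then 1 here)
  expect_equal(sort(unique(round(pg2$shadow_price_1, 6))), c(1, 2))

  # infeasible grid points are labelled, not dropped
  tight <- metabolic_model(
    list(metabolite("A")),
    list(reaction("in_A", c(A = 1), lb = 0, ub = 50),
         reaction("out_A", c(A = -1), lb = 0, ub = 5)),
    objective = "out_A")
  pg3 <- phenotype_phases(tight, "in_A", c(0, 10), steps = 11)
  expect_true(any(pg3$status == "infeasible"))
  expect_true(all(is.na(pg3$phase[pg3$status == "infeasible"])))
  expect_equal(nrow(pg3), 11)
})

test_that("both LP backends agree on the fixture pipeline", {
  fx <- make_lac_operon()
  rsa <- run_rsa(fx$regulatory, list(M_glc_e = 11.1, M_lcts_e = 8))
  cm <- apply_steady_state(fx$metabolic, rsa$steady_state, fx$regulatory)
  a <- solve_fba(cm, backend = "simplex")
  b <- solve_fba(cm, backend = "boot")
  expect_equal(a$objective_value, b$objective_value, tolerance = 1e-6)
})
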