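# two-species negation cycle: A' = not(B>=1), B' = (A>=1); from (0,0) the
# synchronous trajectory is (0,0) -> (1,0) -> (1,1) -> (0,1) -> (0,0)
make_negation_cycle <- function() {
  regulatory_network(
    list(qual_species("A"), qual_species("B")),
    list(qual_transition("A", list(list(condition = "not (B >= 1)",
                                        result_level = 1))),
         qual_transition("B", list(list(condition = "A >= 1",
                                        result_level = 1)))))
}

test_that("initial states honour declared levels and overrides", {
  net <- make_lac_operon()$regulatory
  st <- build_initial_state(net)
  expect_equal(st[["E"]], 1L)
  expect_equal(st[["M_glc_e"]], 0L)

  st2 <- build_initial_state(net, list(M_glc_e = 11.1))
  expect_equal(st2[["M_glc_e"]], 1L)
  st3 <- build_initial_state(net, list(M_glc_e = 0))
  expect_equal(st3[["M_glc_e"]], 0L)

  # qualitative override differs only at the overridden species
  st4 <- build_initial_state(net, list(P = 1))
  expect_equal(st4[["P"]], 1L)
  expect_identical(st4[names(st4) != "P"], st[names(st) != "P"])

  expect_error(build_initial_state(net, list(E = 0.5)), "equivalences")
  expect_error(build_initial_state(net, list(M_glc_e = -3)), "no declared")
  expect_error(build_initial_state(net, list(ghost = 1)), "ghost")
})

test_that("a boundary value lands on the lowest matching level", {
  net <- regulatory_network(list(
    qual_species("x", max_level = 1, equivalences = list(
      "0" = qf_interval(0, 5), "1" = qf_interval(5, 9, lower_open = TRUE)))))
  expect_equal(build_initial_state(net, list(x = 5))[["x"]], 0L)
  expect_equal(build_initial_state(net, list(x = 5.01))[["x"]], 1L)
})

test_that("synchronous update is simultaneous and deterministic", {
  net <- make_negation_cycle()
  s0 <- c(A = 0L, B = 0L)
  expect_identical(synchronous_step(net, s0), c(A = 1L, B = 0L))
  expect_identical(synchronous_step(net, s0), synchronous_step(net, s0))

  const_net <- regulatory_network(
    list(qual_species("x")),
    list(qual_transition("x", default_level = 1)))
  expect_identical(synchronous_step(const_net, c(x = 0L)),
                   synchronous_step(const_net, c(x = 1L)))
})

test_that("attractor search finds points and cycles and canonicalises", {
  net <- make_negation_cycle()
  att <- find_attractor(net, c(A = 0L, B = 0L))
  expect_equal(att$kind, "cyclic")
  expect_length(att$states, 4)
  # canonical equality: entering the cycle at any phase gives the same object
  for (st in att$states) {
    expect_identical(find_attractor(net, st)$states, att$states)
  }
  # point attractor is a fixed point
  cn <- regulatory_network(
    list(qual_species("x"), qual_species("y")),
    list(qual_transition("x", default_level = 1),
         qual_transition("y", default_level = 0)))
  p <- find_attractor(cn, c(x = 0L, y = 1L))
  expect_equal(p$kind, "point")
  expect_identical(synchronous_step(cn, p$states[[1]]), p$states[[1]])
})

test_that("attractor levels translate into averaged interval constraints", {
  eq <- list("0" = qf_interval(0, 0), "1" = qf_interval(2, 10))
  net <- regulatory_network(list(
    qual_species("r", max_level = 1, initial_level = 1, equivalences = eq),
    qual_species("q", max_level = 2, initial_level = 1)))
  # point attractor: the single translated interval
  ss <- attractor_to_steady_state(net, find_attractor(net, c(q = 1L, r = 1L)))
  expect_equal(ss$lb[ss$component == "r"], 2)
  expect_equal(ss$ub[ss$component == "r"], 10)
  expect_equal(ss$value[ss$component == "q"], 1)

  # cyclic attractor visiting r = 0 and 1: means of {0,2} and {0,10}
  att <- qualflux:::new_attractor(list(c(q = 1L, r = 0L), c(q = 2L, r = 1L)))
  ss2 <- attractor_to_steady_state(net, att)
  expect_equal(ss2$lb[ss2$component == "r"], 1)
  expect_equal(ss2$ub[ss2$component == "r"], 5)
  expect_equal(ss2$value[ss2$component == "q"], 1.5)

  # an unbounded member interval keeps the mean unbounded
  eq_inf <- list("0" = qf_interval(0, 0),
                 "1" = qf_interval(0, Inf, lower_open = TRUE))
  net3 <- regulatory_network(list(
    qual_species("r", max_level = 1, equivalences = eq_inf)))
  att3 <- qualflux:::new_attractor(list(c(r = 0L), c(r = 1L)))
  ss3 <- attractor_to_steady_state(net3, att3)
  expect_true(is.infinite(ss3$ub[1]))
})

test_that("averaged bounds equal direct arithmetic on random equivalence tables", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      maxl <- sample(1:3, 1)
      cuts <- sort(round(stats::runif(maxl, 0.5, 20), 2))
      eq <- list("0" = qf_interval(0, cuts[1], upper_open = TRUE))
      if (maxl > 1) {
        for (l in seq_len(maxl - 1)) {
          eq[[as.character(l)]] <-
            qf_interval(cuts[l], cuts[l + 1], upper_open = TRUE)
        }
      }
      eq[[as.character(maxl)]] <- qf_interval(cuts[maxl], Inf,
                                              upper_open = TRUE)
      net <- regulatory_network(list(
        qual_species("r", max_level = maxl, equivalences = eq)))
      lv <- sample(0:maxl, sample(2:4, 1), replace = TRUE)
      states <- lapply(lv, function(l) c(r = as.integer(l)))
      att <- structure(list(states = states,
                            kind = if (length(states) == 1) "point"
                                   else "cyclic"),
                       class = "qf_attractor")
      ss <- attractor_to_steady_state(net, att)
      los <- vapply(as.character(lv), function(l) eq[[l]]$lower, numeric(1))
      his <- vapply(as.character(lv), function(l) eq[[l]]$upper, numeric(1))
      expect_equal(ss$lb[1], mean(los))
      expect_equal(ss$ub[1], mean(his))
      # averaged interval stays inside the member envelope
      expect_gte(ss$lb[1], min(los))
      expect_lte(ss$ub[1], max(his))
    }
  })
})

test_that("the lac fixture reaches a point attractor in all three media", {
  net <- make_lac_operon()$regulatory
  media <- list(glucose = list(M_glc_e = 11.1, M_lcts_e = 0),
                lactose = list(M_glc_e = 0, M_lcts_e = 8),
                both = list(M_glc_e = 11.1, M_lcts_e = 8))
  for (nm in names(media)) {
    rsa <- run_rsa(net, media[[nm]])
    expect_equal(rsa$attractor$kind, "point")
  }
  both <- run_rsa(net, media$both)$steady_state
  expect_equal(both$value[both$component == "B"], 0)  # catabolite repression
  # determinism
  expect_identical(run_rsa(net, media$both), run_rsa(net, media$both))
})

test_that("empty networks give empty steady states", {
  net <- regulatory_network()
  rsa <- run_rsa(net)
  expect_equal(nrow(rsa$steady_state), 0)
  expect_length(random_initial_states(net, 1, seed = 1)[[1]], 0)
})

test_that("random initial states are seeded, uniform and validated", {
  net <- make_random_boolean_network(5, k = 2, seed = 3)
  a <- random_initial_states(net, 50, seed = 10)
  b <- random_initial_states(net, 50, seed = 10)
  expect_identical(a, b)
  expect_error(random_initial_states(net, 0, seed = 1), "at least 1")

  one <- regulatory_network(list(qual_species("x")))
  draws <- random_initial_states(one, 10000, seed = 4)
  frac <- mean(vapply(draws, function(s) s[["x"]], integer(1)))
  expect_lt(abs(frac - 0.5), 0.02)  # 4 sigma of Binomial(10000, 1/2)
})

test_that("the census groups phase-shifted cycles and counts every run", {
  net <- make_negation_cycle()
  census <- multi_rsa_census(net, all_initial_states(net))
  expect_equal(nrow(census), 1)
  expect_equal(unname(census$count), 4L)
  expect_equal(unname(census$size), 4L)
  expect_equal(sum(census$count), 4L)

  const_net <- regulatory_network(
    list(qual_species("x"), qual_species("y")),
    list(qual_transition("x", default_level = 1),
         qual_transition("y", default_level = 0)))
  census2 <- multi_rsa_census(const_net, all_initial_states(const_net))
  expect_equal(nrow(census2), 1)
  expect_equal(unname(census2$count), 4L)
})

test_that("attractor search terminates within the state-space bound", {
  withr::with_seed(5, {
    for (rep in 1:10) {
      net <- make_random_boolean_network(sample(2:10, 1), k = 3, seed = rep)
      cap <- state_space_size_bound <- prod(
        vapply(net$species, function(s) s$max_level + 1, numeric(1))) + 1
      st <- random_initial_states(net, 1, seed = rep)[[1]]
      expect_no_error(find_attractor(net, st, max_iter = cap))
    }
  })
})
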