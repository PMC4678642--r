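test_that("model assembly validates and applies default bounds", {
  m <- metabolic_model(
    list(metabolite("a"), metabolite("b")),
    list(reaction("r1", c(a = 1)),                       # irreversible default
         reaction("r2", c(a = -1, b = 1), reversible = TRUE),
         reaction("r3", c(b = -1), lb = -2, ub = 4)),
    objective = "r3")
  expect_equal(m$reactions$r1$lb, 0)
  expect_equal(m$reactions$r1$ub, 9999)
  expect_equal(m$reactions$r2$lb, -9999)
  expect_true(all(reaction_table(m)$lb <= reaction_table(m)$ub))

  expect_error(metabolic_model(list(metabolite("a")),
                               list(reaction("r", c(ghost = 1)))), "ghost")
  expect_error(metabolic_model(list(metabolite("a")),
                               list(reaction("r", c(a = 1), lb = 3, ub = 1))),
               "lb > ub")
  expect_error(metabolic_model(list(metabolite("a")),
                               list(reaction("r", c(a = 1))),
                               objective = "nope"), "unknown reaction")
})

test_that("constraint files parse objectives, values and intervals", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# medium", "obj : MAX(R_biomass)", "M_glc_e 11.1",
               "R_EX_o2 -20 0"), p)
  cf <- parse_constraint_file(p)
  expect_equal(cf$objective$sense, "max")
  expect_equal(cf$objective$expression, c(R_biomass = 1))
  ov <- cf$overrides
  expect_equal(ov$lb[ov$id == "M_glc_e"], 11.1)
  expect_true(ov$single[ov$id == "M_glc_e"])
  expect_equal(unlist(ov[ov$id == "R_EX_o2", c("lb", "ub")]),
               c(lb = -20, ub = 0))

  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("M_glc_e 1", "junk line here x"), p2)
  expect_error(parse_constraint_file(p2), "line 2")
  p3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("M_glc_e 1", "M_glc_e 2"), p3)
  expect_error(parse_constraint_file(p3), "duplicate")
})

test_that("constraint-file overrides replace bounds and route to the regulatory layer", {
  fx <- make_lac_operon()
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("obj : MAX(R_BIOMASS)", "R_GLC_up 0 5", "M_glc_e 11.1"), p)
  ap <- apply_constraint_file(fx$metabolic, parse_constraint_file(p))
  expect_equal(ap$model$reactions$R_GLC_up$ub, 5)
  expect_equal(ap$regulatory_overrides$M_glc_e, 11.1)
})

test_that("exchange reactions are recognised with the right uptake sign", {
  m <- metabolic_model(
    list(metabolite("glc_c"), metabolite("glc_e", is_external = TRUE),
         metabolite("x_e", is_external = TRUE)),
    list(reaction("R_source", c(glc_c = 1)),          # -> glc_c : import
         reaction("R_drain", c(glc_e = -1)),          # glc_e -> : export form
         reaction("R_trans", c(x_e = -1, glc_c = 1))))# transport-exchange
  ex <- find_exchange_reactions(m)
  expect_equal(ex$uptake_direction[ex$reaction == "R_source"], 1L)
  expect_equal(ex$uptake_direction[ex$reaction == "R_drain"], -1L)
  expect_equal(ex$uptake_direction[ex$reaction == "R_trans"], 1L)
  expect_equal(ex$metabolite[ex$reaction == "R_trans"], "x_e")

  # an external metabolite with no exchange reaction warns and is omitted
  m2 <- metabolic_model(
    list(metabolite("a"), metabolite("b"), metabolite("orphan_e",
                                                      is_external = TRUE)),
    list(reaction("r", c(a = -1, b = 1))))
  expect_warning(ex2 <- find_exchange_reactions(m2), "orphan_e")
  expect_false("orphan_e" %in% ex2$metabolite)

  # the lac fixture exposes exactly its two designed exchanges
  fx <- make_lac_operon()
  ex3 <- find_exchange_reactions(fx$metabolic)
  expect_setequal(ex3$metabolite[ex3$metabolite != "M_c"],
                  c("M_glc_e", "M_lcts_e"))
})

test_that("GPR evaluation treats positive levels as active and absent genes as present", {
  expect_false(evaluate_gpr("g1 and g2", list(g1 = 1, g2 = 0)))
  expect_true(evaluate_gpr("g1 or g2", list(g1 = 0, g2 = 2)))
  expect_true(evaluate_gpr("g1", list()))
  expect_true(evaluate_gpr(NULL, list(g1 = 0)))
})

test_that("the COBRA Level 2 dialect reads bounds, GPR and _b externals", {
  txt <- '<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
 <model id="toy">
  <listOfSpecies>
   <species id="M_glc_D_b" compartment="e" boundaryCondition="false"/>
   <species id="M_glc_c" compartment="c"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="R_up" reversible="false">
    <notes><body xmlns="http://www.w3.org/1999/xhtml">
      <p>GENE_ASSOCIATION: (b0001 and b0002) or b0003</p>
    </body></notes>
    <listOfReactants><speciesReference species="M_glc_D_b"/></listOfReactants>
    <listOfProducts><speciesReference species="M_glc_c" stoichiometry="2"/></listOfProducts>
    <kineticLaw>
     <listOfParameters>
      <parameter id="LOWER_BOUND" value="0"/>
      <parameter id="UPPER_BOUND" value="18.5"/>
      <parameter id="OBJECTIVE_COEFFICIENT" value="1"/>
     </listOfParameters>
    </kineticLaw>
   </reaction>
  </listOfReactions>
 </model></sbml>'
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines(txt, p)
  m <- read_sbml_metabolic(p)
  expect_true(m$metabolites$M_glc_D_b$is_external)   # legacy _b suffix
  expect_false(m$metabolites$M_glc_c$is_external)
  expect_equal(m$reactions$R_up$ub, 18.5)
  expect_equal(m$reactions$R_up$stoich, c(M_glc_D_b = -1, M_glc_c = 2))
  expect_false(evaluate_gpr(m$reactions$R_up$gpr,
                            list(b0001 = 1, b0002 = 0, b0003 = 0)))
  expect_true(evaluate_gpr(m$reactions$R_up$gpr,
                           list(b0001 = 1, b0002 = 0, b0003 = 1)))
  expect_equal(m$objective, c(R_up = 1))
})

test_that("an unparseable GPR degrades to a warning and an unregulated reaction", {
  txt <- '<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
 <model id="toy">
  <listOfSpecies><species id="M_a" compartment="c"/></listOfSpecies>
  <listOfReactions>
   <reaction id="R1" reversible="true">
    <notes><body xmlns="http://www.w3.org/1999/xhtml">
      <p>GENE_ASSOCIATION: g1 and (g2</p>
    </body></notes>
    <listOfProducts><speciesReference species="M_a"/></listOfProducts>
   </reaction>
  </listOfReactions>
 </model></sbml>'
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines(txt, p)
  expect_warning(m <- read_sbml_metabolic(p), "GPR")
  expect_null(m$reactions$R1$gpr)
  # reversible reaction without bounds gets the symmetric default
  expect_equal(m$reactions$R1$lb, -9999)
})

test_that("fixture models round-trip through SBML L3 + fbc", {
  for (fx in list(make_lac_operon(), make_maltose_extension())) {
    p <- withr::local_tempfile(fileext = ".xml")
    write_sbml_metabolic(fx$metabolic, p)
    m2 <- read_sbml_metabolic(p)
    expect_identical(names(m2$reactions), names(fx$metabolic$reactions))
    for (rid in names(m2$reactions)) {
      expect_equal(m2$reactions[[rid]]$stoich[
        order(names(m2$reactions[[rid]]$stoich))],
        fx$metabolic$reactions[[rid]]$stoich[
          order(names(fx$metabolic$reactions[[rid]]$stoich))])
      expect_equal(m2$reactions[[rid]]$lb, fx$metabolic$reactions[[rid]]$lb)
      expect_equal(m2$reactions[[rid]]$ub, fx$metabolic$reactions[[rid]]$ub)
    }
    expect_identical(m2$objective, fx$metabolic$objective)
    # GPR semantics preserved
    g <- m2$reactions$R_LCTS_up$gpr
    expect_false(evaluate_gpr(g, list(P = 1, B = 0)))
    expect_true(evaluate_gpr(g, list(P = 1, B = 1)))
  }
})
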