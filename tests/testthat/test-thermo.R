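test_that("formula parsing handles elements, multipliers and nesting", {
  expect_equal(parse_formula("H2O"), c(H = 2, O = 1))
  expect_equal(parse_formula("Au(OH)4"), c(Au = 1, O = 4, H = 4))
  expect_equal(parse_formula("S2O3"), c(S = 2, O = 3))
  expect_equal(parse_formula("Au(HS)2"), c(Au = 1, H = 2, S = 2))
  expect_equal(parse_formula("(CH3)2(NH2)3"), c(C = 2, H = 12, N = 3))
  expect_length(parse_formula(""), 0)
  expect_error(parse_formula("Au(OH"), "unbalanced")
  expect_error(parse_formula("au"), "cannot parse")
})

test_that("conversion helpers are exact inverses and match hand arithmetic", {
  const <- thermo_constants()
  expect_equal(const$lnK_factor, 2.303 * 8.314 * 298 / 1000)
  expect_equal(delta_g_from_hs(-122.82, -359.74), -122.82 + 298 * 359.74 / 1000)
  for (x in c(-455.62, -15.62, 0.5, 440)) {
    expect_equal(delta_g_from_logk(logk_from_delta_g(x)), x)
    expect_equal(potential_from_gibbs(gibbs_from_potential(3, x), 3), x)
  }
  expect_equal(gibbs_from_potential(3, -1.52), 3 * 96.49 * 1.52)
  expect_error(potential_from_gibbs(10, 0), "positive electron count")
  expect_error(gibbs_from_potential(-1, 1))
})

test_that("nernst boundary line has the textbook coefficients", {
  b <- nernst_boundary(79.84, n_electrons = 3, h = 4)
  expect_equal(b$ph_coeff, 4)
  expect_equal(b$eh_coeff, 3 * 96.49 / thermo_constants()$lnK_factor,
               tolerance = 1e-12)
  expect_equal(b$eh_coeff, 50.73, tolerance = 0.005)
  expect_equal(b$eh_at_ph(0) * b$eh_coeff, 79.84)
  # the line equation holds along its whole length
  ph <- seq(0, 14, by = 0.5)
  expect_equal(4 * ph + b$eh_coeff * b$eh_at_ph(ph), rep(79.84, length(ph)))
  expect_error(nernst_boundary(10, n_electrons = 0, h = 2), "redox")
  expect_equal(eh_to_pe(1), 96.49 / thermo_constants()$lnK_factor)
})

test_that("equation parsing round-trips and keeps charged species names", {
  r <- parse_equation("Au(s) + 0.75 O2(aq) + 3 H+ = Au3+ + 1.5 H2O",
                      logK = -11.44)
  expect_equal(r$stoich[["H+"]], -3)
  expect_equal(r$stoich[["O2(aq)"]], -0.75)
  expect_equal(r$stoich[["Au3+"]], 1)
  expect_equal(format_reaction(r), "Au(s) + 0.75 O2(aq) + 3 H+ = Au3+ + 1.5 H2O")
  expect_error(parse_equation("A + B"), "exactly one")
  half <- parse_equation("Au(s) = Au3+ + 3 e-")
  expect_equal(half$n_electrons, 3)
})

test_that("balance checking flags elements and charge independently", {
  db <- read_thermo_db()
  ok <- parse_equation("Au(s) + O2- + 4 H+ = Au3+ + 2 H2O")
  expect_true(check_balance(ok, db$species)$ok)
  bad_el <- parse_equation("Au(s) + O2- + 4 H+ = Au3+ + 3 H2O")
  expect_false(check_balance(bad_el, db$species)$ok)
  expect_equal(unname(check_balance(bad_el, db$species)$element_delta["O"]), 1)
  bad_ch <- parse_equation("Au(s) + O2- + 5 H+ = Au3+ + 2 H2O")
  res <- check_balance(bad_ch, db$species)
  expect_false(res$ok)
  expect_equal(res$charge_delta, -1)
  expect_error(check_balance(parse_equation("X = Y"), db$species),
               "unknown species")
})

test_that("every shipped reaction is element- and charge-balanced", {
  db <- read_thermo_db()
  for (r in db$reactions)
    expect_true(check_balance(r, db$species)$ok, label = r$label)
})

test_that("Hess combination adds logK and cancels stoichiometry exactly", {
  db <- read_thermo_db()
  r3 <- db$reactions$R3; r4 <- db$reactions$R4; r5 <- db$reactions$R5
  r1 <- combine_reactions(list(list(r3, 1), list(r4, 1), list(r5, 4)))
  expect_equal(r1$logK, r3$logK + r4$logK + 4 * r5$logK)
  expect_equal(sort(names(r1$stoich)),
               sort(names(db$reactions$R1$stoich)))
  expect_equal(r1$stoich[names(db$reactions$R1$stoich)],
               db$reactions$R1$stoich)
  # self-cancellation leaves the empty reaction with logK 0
  void <- combine_reactions(list(list(r5, 1), list(r5, -1)))
  expect_length(void$stoich, 0)
  expect_equal(void$logK, 0)
  expect_error(combine_reactions(list(list(parse_equation("H2O = H+ + OH-"), 1))),
               "without logK")
})

test_that("half-reaction split partitions Gibbs energy and checks the sum", {
  rxn <- parse_equation("Au(s) + O2- + 4 H+ = Au3+ + 2 H2O")
  au_half <- parse_equation("Au(s) = Au3+ + 3 e-")
  o2_half <- parse_equation("O2- + 4 H+ + 3 e- = 2 H2O")
  chain <- gold_superoxide_chain()
  dG_o2 <- half_reaction_split(rxn, au_half, o2_half,
                               dG_rxn = chain$dG_rxn3,
                               dG_known = chain$dG_au_couple)
  expect_equal(dG_o2, chain$dG_o2_couple)
  wrong <- parse_equation("O2- + 2 H+ + 3 e- = 2 H2O")
  expect_error(
    half_reaction_split(rxn, au_half, wrong, chain$dG_rxn3, chain$dG_au_couple),
    "do not sum")
})

test_that("the derivation chain reproduces the tabulated reaction constants", {
  db <- read_thermo_db()
  chain <- gold_superoxide_chain()
  expect_equal(chain$logK_rxn3, db$reactions$R3$logK, tolerance = 0.005)
  expect_equal(chain$logK_rxn1, db$reactions$R1$logK, tolerance = 0.005)
  expect_equal(chain$logK_rxn2, db$reactions$R2$logK, tolerance = 0.005)
  expect_equal(chain$logK0_o2_couple, db$reactions_table$logK[
    db$reactions_table$id == "R8"], tolerance = 0.05)
  # the shipped Au3+ formation energy is anchored to the gold couple
  expect_equal(db$species[["Au3+"]]$dGf, chain$dG_au_couple, tolerance = 0.05)
})

test_that("database loading validates species lookups", {
  db <- read_thermo_db()
  expect_s3_class(db, "thermo_db")
  expect_gt(length(db$species), 20)
  expect_error(aurox:::species_dgf(db, "Xe4+"), "unknown species")
  expect_error(aurox:::species_dgf(db, "O2-"), "no Gibbs energy")
  expect_equal(aurox:::species_dgf(db, "H2O"), -237.13)
})

test_that("species constructor validates phase and composition", {
  sp <- thermo_species("Au(OH)4-", "Au(OH)4", charge = -1, dGf = -481.95)
  expect_equal(sp$elements, c(Au = 1, O = 4, H = 4))
  expect_error(thermo_species("X", "H2O", phase = "plasma"))
})
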