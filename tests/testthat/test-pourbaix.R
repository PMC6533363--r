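test_that("mass-fraction levels convert to log activities of dissolved gold", {
  expect_equal(mass_fraction_to_log_activity("ppb"),
               log10(1e-6 / 196.97))
  expect_equal(mass_fraction_to_log_activity("ppb"), -8.29, tolerance = 0.005)
  expect_equal(mass_fraction_to_log_activity("ppm"), -5.29, tolerance = 0.005)
  expect_equal(mass_fraction_to_log_activity("ppt"), -11.29, tolerance = 0.005)
  # a numeric argument is a direct activity (the decade convention)
  expect_equal(mass_fraction_to_log_activity(1e-9), -9)
  expect_error(mass_fraction_to_log_activity("percent"), "unknown")
})

test_that("system constructor validates levels, steps and species data", {
  expect_error(pourbaix_system("carbon", au_levels = c(a = -9, b = -6)),
               "strictly decreasing")
  expect_error(pourbaix_system("carbon", ph_step = 0), "ph_step")
  expect_error(pourbaix_system("iron"))
  sys <- pourbaix_system("sulfur")
  expect_equal(sys$element, "S")
  expect_equal(sys$log_ligand_activity, -2)
  expect_true(all(c("AuHS(aq)", "Au(HS)2-") %in% sys$au_aqueous))
})

test_that("ligand predominance reproduces textbook speciation fields", {
  sc <- pourbaix_system("carbon")
  expect_equal(
    ligand_predominance(sc, c(2, 9, 12.5, 7), c(1.0, 0.5, 0.5, -0.5)),
    c("CO2(aq)", "HCO3-", "CO3-2", "CH4(aq)"))
  ss <- pourbaix_system("sulfur")
  expect_equal(
    ligand_predominance(ss, c(0.5, 3, 4, 9), c(1.0, 1.0, -0.45, -0.4)),
    c("HSO4-", "SO4-2", "H2S(aq)", "HS-"))
})

test_that("gold predominance shows the expected qualitative fields", {
  sc <- pourbaix_system("carbon")
  # strongly acidic + oxidizing: free Au3+; neutral oxidizing: Au(OH)4-;
  # neutral mid-Eh: metallic gold stays immobile
  expect_equal(au_predominance(sc, c(0.5, 7, 7), c(1.45, 1.2, 0), -9),
               c("Au3+", "Au(OH)4-", "Au(s)"))
  # sulfide complexation opens a reduced mobility window
  ss <- pourbaix_system("sulfur")
  expect_equal(au_predominance(ss, 6.5, -0.2, -9), "Au(HS)2-")
})

test_that("Au(s) immobile regions are nested across solubility levels", {
  sys <- pourbaix_system("carbon", ph_step = 0.5, eh_step = 0.05)
  field <- build_diagram(sys)
  gold <- lapply(field$au_labels, function(m) m == "Au(s)")
  # gold that cannot even reach the lowest (ppt) contour certainly cannot
  # reach a higher one: ppt-region inside ppb-region inside ppm-region
  expect_true(all(gold$ppb | !gold$ppt))
  expect_true(all(gold$ppm | !gold$ppb))
  # where gold dissolves at both levels, the predominant complex agrees
  both <- !gold$ppm & !gold$ppt
  expect_equal(field$au_labels$ppm[both], field$au_labels$ppt[both])
})

test_that("grid labels agree with the independent per-point oracle", {
  for (lig in c("carbon", "sulfur")) {
    sys <- pourbaix_system(lig, ph_step = 1, eh_step = 0.2)
    field <- build_diagram(sys)
    pts <- expand.grid(ph = field$ph, eh = field$eh)
    lig_oracle <- mapply(oracle_ligand_label, pts$ph, pts$eh,
                         MoreArgs = list(system = sys))
    expect_equal(as.vector(field$ligand_labels), unname(lig_oracle),
                 label = paste(lig, "ligand stage"))
    au_oracle <- mapply(oracle_au_label, pts$ph, pts$eh,
                        MoreArgs = list(system = sys, log_a_au = -9))
    expect_equal(as.vector(field$au_labels$ppb), unname(au_oracle),
                 label = paste(lig, "gold stage"))
  }
})

test_that("overlay lines carry the derived boundary and water window", {
  sys <- pourbaix_system("carbon", ph_step = 1, eh_step = 0.2)
  field <- build_diagram(sys)
  chain <- gold_superoxide_chain()
  expect_equal(field$overlays$superoxide_water$eh,
               chain$boundary$eh_at_ph(range(field$ph)))
  # oxygen and hydrogen water-stability lines: E0 1.23 and 0 V, slope -0.059
  expect_equal(field$overlays$o2_window$eh[1], 1.229, tolerance = 0.005)
  expect_equal(field$overlays$h2_window$eh[1], 0)
  slope <- diff(field$overlays$h2_window$eh) / diff(field$overlays$h2_window$ph)
  expect_equal(slope, -0.0591, tolerance = 0.001)
})

test_that("boundaries separate cells whose labels differ", {
  sys <- pourbaix_system("carbon", ph_step = 0.5, eh_step = 0.05)
  field <- build_diagram(sys)
  for (stage in c("ligand", "ppb")) {
    b <- field_boundaries(field, stage)
    expect_gt(nrow(b), 0)
    expect_true(all(b$label_a != b$label_b))
    # segments lie on half-step cell edges inside the frame
    expect_true(all(b$ph0 >= min(field$ph) - 0.25 &
                      b$ph1 <= max(field$ph) + 0.25))
  }
  expect_error(field_boundaries(field, "nope"), "unknown stage")
})

test_that("diagram export round-trips through the text format", {
  sys <- pourbaix_system("sulfur", ph_step = 2, eh_step = 0.4)
  field <- build_diagram(sys)
  d <- tempfile("diagram")
  dir.create(d)
  prefix <- file.path(d, "sulfur")
  paths <- export_diagram(field, prefix, header = c("test run"))
  expect_true(all(file.exists(paths)))
  grid <- read_diagram_grid(paths[1])
  expect_equal(nrow(grid), length(field$ph) * length(field$eh))
  expect_equal(grid$ligand, as.vector(field$ligand_labels))
  expect_equal(grid$au_ppb, as.vector(field$au_labels$ppb))
  expect_equal(readLines(paths[1], n = 1), "# test run")
})
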