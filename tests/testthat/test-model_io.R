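test_that("toy generator is deterministic and carbon-balanced", {
  m1 <- build_toy_model()
  m2 <- build_toy_model()
  expect_identical(m1$reactions, m2$reactions)
  expect_identical(m1$S, m2$S)
  f1 <- tempfile(fileext = ".xml"); f2 <- tempfile(fileext = ".xml")
  write_sbml(m1, f1); write_sbml(m2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1) + 10),
                   readBin(f2, "raw", file.size(f2) + 10))

  # every internal reaction balanced for carbon
  carbon <- toy_carbon(m1)
  internal <- which(m1$reactions$category == "internal")
  for (j in internal)
    expect_equal(sum(m1$S[, j] * carbon), 0, tolerance = 1e-10,
                 label = paste("carbon balance of", m1$reactions$id[j]))

  expect_error(build_toy_model(acids = c("citrate", "oxalate")), "oxalate")
})

test_that("wild-type proton maximisation secretes exactly one acid", {
  m <- get_toy()
  cfg <- configure_phase(m, "proton_production")
  sol <- solve_fba(m, bounds = cfg, objective = "EX_h")
  expect_equal(sol$status, "optimal")
  acid_ex <- c("EX_cit", "EX_succ", "EX_lac", "EX_ac")
  secreted <- acid_ex[sol$fluxes[acid_ex] > 1e-9]
  expect_identical(secreted, "EX_cit")
})

test_that("dissociation stoichiometry follows the pH limits", {
  expect_equal(dissociation_fraction(3.13, 3.13), 0.5)
  expect_gt(dissociation_fraction(3.13, 12), 0.9999)
  expect_lt(dissociation_fraction(3.13, -4), 1e-6)
  # far above all pKa values every step releases its proton
  m <- build_toy_model(ph = 14)
  f <- m$S["He", "DISS_cit"]
  expect_equal(f, 3, tolerance = 1e-3)   # triprotic, fully dissociated
})

test_that("model statistics collapse compartments and count genes", {
  m <- get_toy()
  s <- model_stats(m)
  expect_equal(s$n_reactions, nrow(m$reactions))
  expect_equal(s$n_unique_genes, 21)
  # external copies (GLCe vs GLC etc.) collapse onto the cytosolic species
  ext_with_copy <- c("GLCe", "CO2e", "O2e", "PIe", "CITe", "SUCCe", "LACe", "ACe")
  expect_equal(s$n_unique_metabolites,
               nrow(m$metabolites) - length(ext_with_copy))

  # same species in several compartments counts once
  mets <- data.frame(id = c("X", "Xe", "Xm"), name = "X",
                     compartment = c("c", "e", "m"))
  rxns <- data.frame(id = "t1", name = "t", lower_bound = 0, upper_bound = 1,
                     category = "transport", gene_association = "")
  S <- matrix(c(-1, 1, 0), 3, 1, dimnames = list(mets$id, "t1"))
  expect_equal(model_stats(metabolic_model(mets, rxns, S, "t1"))$n_unique_metabolites, 1)

  # empty model
  empty <- metabolic_model(
    data.frame(id = character(), name = character(), compartment = character()),
    data.frame(id = character(), name = character(), lower_bound = numeric(),
               upper_bound = numeric(), category = character(),
               gene_association = character()),
    matrix(0, 0, 0), objective = "none")
  se <- model_stats(empty)
  expect_equal(c(se$n_reactions, se$n_unique_metabolites, se$n_unique_genes),
               c(0, 0, 0))

  # invariance under reaction reordering
  perm <- rev(seq_len(nrow(m$reactions)))
  mp <- metabolic_model(m$metabolites, m$reactions[perm, ],
                        m$S[, perm], m$objective)
  expect_equal(unclass(model_stats(mp)), unclass(s))
})

test_that("SBML writer/reader round-trips the toy model", {
  m <- build_toy_model(acids = c("citrate", "succinate", "lactate",
                                 "acetate", "malate", "gluconate"))
  f <- tempfile(fileext = ".xml")
  write_sbml(m, f)
  m2 <- read_sbml(f)
  expect_identical(m2$reactions$id, m$reactions$id)
  expect_identical(m2$metabolites$id, m$metabolites$id)
  expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
  expect_equal(m2$reactions$upper_bound, m$reactions$upper_bound)
  expect_identical(m2$reactions$gene_association, m$reactions$gene_association)
  expect_identical(m2$reactions$category, m$reactions$category)
  expect_identical(m2$objective, m$objective)
  expect_equal(m2$S[rownames(m$S), colnames(m$S)], m$S)
  expect_equal(m2$metabolites$molar_mass, m$metabolites$molar_mass)
  rep <- attr(m2, "load_report")
  expect_equal(rep$dialect, "fbc")
})

test_that("SBML reader rejects crossed bounds, defaults missing ones", {
  m <- chain_model()
  f <- tempfile(fileext = ".xml")
  write_sbml(m, f)
  txt <- readLines(f)
  # point EX_in's lower bound at the largest parameter so lb > ub
  stopifnot(any(grepl('fbc:lowerFluxBound="bnd_1"', txt)))
  txt <- sub('fbc:lowerFluxBound="bnd_1"', 'fbc:lowerFluxBound="bnd_3"', txt)
  writeLines(txt, f)
  expect_error(read_sbml(f), "EX_in")

  # a bare SBML file without any bound information
  bare <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">',
    '<model id="bare"><listOfCompartments><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies><species id="A" compartment="c"/><species id="B" compartment="c"/></listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="r1" reversible="true"><listOfReactants><speciesReference species="A"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B"/></listOfProducts></reaction>',
    '<reaction id="src" reversible="false"><listOfProducts><speciesReference species="A"/></listOfProducts></reaction>',
    '</listOfReactions></model></sbml>'), bare)
  expect_warning(mb <- read_sbml(bare), "default")
  expect_equal(mb$reactions$lower_bound, c(-1000, 0))
  expect_equal(mb$reactions$upper_bound, c(1000, 1000))
})

test_that("SBML reader handles the legacy kinetic-law dialect and fbc GPRs", {
  f <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">',
    '<model id="legacy"><listOfSpecies>',
    '<species id="A" compartment="c"/><species id="B" compartment="c"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="r1" reversible="false">',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml"><p>GENE_ASSOCIATION: gX or gY</p></body></notes>',
    '<listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B" stoichiometry="1"/></listOfProducts>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="0"/><parameter id="UPPER_BOUND" value="42"/>',
    '</listOfParameters></kineticLaw></reaction>',
    '</listOfReactions></model></sbml>'), f)
  m <- read_sbml(f)
  expect_equal(m$reactions$upper_bound, 42)
  expect_equal(attr(m, "load_report")$dialect, "kinetic-law")
  expect_equal(m$reactions$gene_association, "gX or gY")

  # fbc geneProductAssociation flattening
  g <- xml2::read_xml(paste0(
    '<fbc:geneProductAssociation xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2">',
    '<fbc:and><fbc:geneProductRef fbc:geneProduct="g1"/>',
    '<fbc:or><fbc:geneProductRef fbc:geneProduct="g2"/>',
    '<fbc:geneProductRef fbc:geneProduct="g3"/></fbc:or></fbc:and>',
    '</fbc:geneProductAssociation>'))
  expect_equal(acidevolve:::gpr_from_fbc(g), "(g1 and (g2 or g3))")
})

test_that("protected reactions cover every non-internal category", {
  m <- get_toy()
  prot <- detect_protected(m)
  expect_true(all(c("BIOMASS", "NGAM") %in% prot))
  expect_true(all(c("GLCt", "O2t", "PIt", "CO2t") %in% prot))
  expect_true(all(grepl("^EX_|^SINK_|^DISS_", setdiff(prot,
    c("BIOMASS", "NGAM", "GLCt", "O2t", "PIt", "CO2t")))))
  expect_false(any(c("GLYC", "LDH", "NADHOX", "PRESYN") %in% prot))

  # without transport reactions only the remaining categories are protected
  ch <- chain_model()
  ch$reactions$category[ch$reactions$category == "transport"] <- "internal"
  expect_identical(sort(detect_protected(ch)), c("EX_in", "EX_out"))
})

test_that("bounds tables round-trip and reject bad overrides", {
  m <- get_toy()
  f <- tempfile(fileext = ".csv")
  write_bounds_table(m, f)
  b <- read_bounds_table(m, f)
  expect_equal(b$lb, m$reactions$lower_bound)
  expect_equal(b$ub, m$reactions$upper_bound)

  # partial table only touches the listed reactions
  utils::write.csv(data.frame(reaction_id = "NADHOX", lower_bound = 0,
                              upper_bound = 0.5), f, row.names = FALSE)
  b <- read_bounds_table(m, f)
  j <- match("NADHOX", m$reactions$id)
  expect_equal(b$ub[j], 0.5)
  expect_equal(b$ub[-j], m$reactions$upper_bound[-j])

  utils::write.csv(data.frame(reaction_id = "NADHOX", lower_bound = 2,
                              upper_bound = 1), f, row.names = FALSE)
  expect_error(read_bounds_table(m, f), "NADHOX")
  utils::write.csv(data.frame(reaction_id = "NOPE", lower_bound = 0,
                              upper_bound = 1), f, row.names = FALSE)
  expect_error(read_bounds_table(m, f), "NOPE")
})
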