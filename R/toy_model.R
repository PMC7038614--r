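#' Deterministic toy core-carbon-metabolism network
#'
#' Builds a small (~35 reaction) metabolic network that emulates the features
#' of a fungal organic-acid producer needed to exercise every part of the
#' pipeline without a genome-scale model: glucose uptake, lumped glycolysis,
#' the pyruvate node (lactate dehydrogenase, a decarboxylase route to acetate,
#' pyruvate carboxylase), TCA cycle with glyoxylate shunt and fumarate
#' reductase, an electron-transport chain recycling NADH and ubiquinol against
#' oxygen, maintenance ATP hydrolysis, a biomass reaction with a phosphate
#' requirement, and per-acid dissociation reactions that release protons
#' according to the Henderson-Hasselbalch dissociation fraction at the broth
#' pH. Construction is fully deterministic (no random numbers), and every
#' internal reaction is balanced for carbon.
#'
#' Under the default proton-production parameterisation the wild-type network
#' secretes citrate only, as the proton-richest acid per glucose; blocking
#' NADH recycling redirects output towards fermentative acids, which is the
#' behaviour the in silico evolution experiments exploit.
#'
#' @param acids organic acids to include; any subset of `"citrate"`,
#'   `"succinate"`, `"lactate"`, `"acetate"`, `"malate"`, `"gluconate"`.
#' @param ph broth pH used for the dissociation stoichiometry (protons
#'   released per exported acid molecule).
#' @param phosphate_per_biomass mmol phosphate consumed per gDW of biomass.
#' @param ngam non-growth-associated maintenance ATP demand applied by the
#'   default phase parameterisations, mmol gDW^-1 h^-1.
#' @return A [metabolic_model] with default phase parameterisations attached
#'   as `attr(model, "phases")` and default batch initial conditions as
#'   `attr(model, "batch")`.
#' @export
build_toy_model <- function(acids = c("citrate", "succinate", "lactate", "acetate"),
                            ph = 2, phosphate_per_biomass = 0.05, ngam = 0.4) {
  unknown <- setdiff(acids, names(ACID_TABLE))
  if (length(unknown))
    stop("unknown acid name(s): ", paste(unknown, collapse = ", "))
  acids <- intersect(names(ACID_TABLE), acids)  # canonical order, deterministic

  met <- function(id, comp, carbon = 0, mass = NA_real_, name = id)
    data.frame(id = id, name = name, compartment = comp,
               molar_mass = mass, carbon = carbon, stringsAsFactors = FALSE)
  mets <- rbind(
    met("GLCe", "e", 6, 0.18016, "glucose (external)"),
    met("O2e", "e"), met("PIe", "e"), met("CO2e", "e", 1), met("He", "e"),
    met("GLC", "c", 6), met("PYR", "c", 3), met("ACAL", "c", 2),
    met("AC", "c", 2), met("LAC", "c", 3), met("CIT", "c", 6),
    met("AKG", "c", 5), met("SUCC", "c", 4), met("FUM", "c", 4),
    met("MAL", "c", 4), met("OAA", "c", 4), met("GLX", "c", 2),
    met("ACCOA", "c", 2), met("CO2", "c", 1), met("O2", "c"),
    met("ATP", "c"), met("ADP", "c"), met("NADH", "c"), met("NAD", "c"),
    met("Q", "c"), met("QH2", "c"), met("PI", "c"), met("PRE", "c", 30,
        name = "biomass precursor"))
  if ("gluconate" %in% acids)
    mets <- rbind(mets, met("GLCNT", "c", 6))
  for (a in acids) {
    info <- ACID_TABLE[[a]]
    mets <- rbind(mets, met(paste0(info$met, "e"), "e", info$carbon,
                            info$molar_mass, paste0(a, " (external)")))
  }

  rx <- list()
  add <- function(id, name, stoich, lb, ub, cat, gpr = "")
    rx[[length(rx) + 1]] <<- list(id = id, name = name, stoich = stoich,
                                  lb = lb, ub = ub, cat = cat, gpr = gpr)

  # exchanges (positive flux = secretion, negative = uptake)
  add("EX_glc", "glucose exchange", c(GLCe = -1), -1000, 0, "exchange")
  add("EX_o2", "oxygen exchange", c(O2e = -1), -1000, 0, "exchange")
  add("EX_pi", "external phosphate exchange", c(PIe = -1), -1000, 0, "exchange")
  add("EX_co2", "CO2 exchange", c(CO2e = -1), -1000, 1000, "exchange")
  add("EX_h", "proton exchange", c(He = -1), 0, 1000, "exchange")
  add("SINK_pi", "internal phosphate storage/release", c(PI = -1), -1000, 1000,
      "exchange")
  # transport
  add("GLCt", "glucose transport", c(GLCe = -1, GLC = 1), 0, 1000, "transport")
  add("O2t", "oxygen transport", c(O2e = -1, O2 = 1), 0, 1000, "transport")
  add("PIt", "phosphate transport", c(PIe = -1, PI = 1), 0, 1000, "transport")
  add("CO2t", "CO2 transport", c(CO2 = -1, CO2e = 1), -1000, 1000, "transport")
  # central carbon metabolism
  add("GLYC", "glycolysis (lumped)",
      c(GLC = -1, ADP = -2, NAD = -2, PYR = 2, ATP = 2, NADH = 2),
      0, 1000, "internal", "g01 and g02")
  add("LDH", "lactate dehydrogenase",
      c(PYR = -1, NADH = -1, LAC = 1, NAD = 1), -1000, 1000, "internal",
      "g03 or g04")
  add("PDC", "pyruvate decarboxylase", c(PYR = -1, ACAL = 1, CO2 = 1),
      0, 1000, "internal", "g05")
  add("ALDH", "acetaldehyde dehydrogenase",
      c(ACAL = -1, NAD = -1, AC = 1, NADH = 1), 0, 1000, "internal", "g06")
  add("PDH", "pyruvate dehydrogenase (lumped)",
      c(PYR = -1, NAD = -1, ACCOA = 1, CO2 = 1, NADH = 1), 0, 1000,
      "internal", "g07")
  add("PYC", "pyruvate carboxylase",
      c(PYR = -1, CO2 = -1, ATP = -1, OAA = 1, ADP = 1), 0, 1000,
      "internal", "g08")
  add("CS", "citrate synthase (lumped)", c(ACCOA = -1, OAA = -1, CIT = 1),
      0, 1000, "internal", "g09")
  add("IDH", "isocitrate dehydrogenase (lumped)",
      c(CIT = -1, NAD = -1, AKG = 1, CO2 = 1, NADH = 1), 0, 1000,
      "internal", "g10")
  add("AKGDH", "2-oxoglutarate dehydrogenase (lumped)",
      c(AKG = -1, NAD = -1, SUCC = 1, CO2 = 1, NADH = 1), 0, 1000,
      "internal", "g11")
  add("SDH", "succinate dehydrogenase (ubiquinone)",
      c(SUCC = -1, Q = -1, FUM = 1, QH2 = 1), 0, 1000, "internal", "g12")
  add("FRD", "fumarate reductase (NADH)",
      c(FUM = -1, NADH = -1, SUCC = 1, NAD = 1), 0, 1000, "internal", "g13")
  add("FUMS", "fumarase", c(FUM = -1, MAL = 1), -1000, 1000, "internal", "g14")
  add("MDH", "malate dehydrogenase",
      c(MAL = -1, NAD = -1, OAA = 1, NADH = 1), -1000, 1000, "internal", "g15")
  add("ICL", "isocitrate lyase (lumped)", c(CIT = -1, SUCC = 1, GLX = 1),
      0, 1000, "internal", "g16")
  add("MALS", "malate synthase", c(GLX = -1, ACCOA = -1, MAL = 1),
      0, 1000, "internal", "g17")
  add("NADHOX", "NADH oxidase / oxidative phosphorylation (lumped)",
      c(NADH = -1, O2 = -0.5, ADP = -2, NAD = 1, ATP = 2), 0, 1000,
      "internal", "g18 and g19")
  add("QH2OX", "ubiquinol oxidase (lumped)",
      c(QH2 = -1, O2 = -0.5, ADP = -1, Q = 1, ATP = 1), 0, 1000,
      "internal", "g20")
  add("PRESYN", "biomass precursor synthesis (lumped)",
      c(PYR = -10, ATP = -40, PRE = 1, ADP = 40), 0, 1000, "internal", "g21")
  if ("gluconate" %in% acids) {
    add("GNTDH", "glucose dehydrogenase (to gluconate)",
        c(GLC = -1, NAD = -1, GLCNT = 1, NADH = 1), 0, 1000, "internal", "g22")
    add("GNTK", "gluconate catabolism (lumped)",
        c(GLCNT = -1, ATP = -1, NAD = -1, PYR = 2, ADP = 1, NADH = 1),
        0, 1000, "internal", "g23")
  }
  # maintenance and biomass
  add("NGAM", "maintenance ATP hydrolysis", c(ATP = -1, ADP = 1),
      0, 1000, "maintenance")
  add("BIOMASS", "biomass synthesis",
      c(PRE = -1, PI = -phosphate_per_biomass), 0, 1000, "biomass")
  # per-acid dissociation + export (protons released per molecule at this pH)
  cytosolic <- c(citrate = "CIT", succinate = "SUCC", lactate = "LAC",
                 acetate = "AC", malate = "MAL", gluconate = "GLCNT")
  for (a in acids) {
    info <- ACID_TABLE[[a]]
    f <- sum(dissociation_fraction(info$pka, ph))
    st <- c(-1, 1, f)
    names(st) <- c(cytosolic[[a]], paste0(info$met, "e"), "He")
    add(paste0("DISS_", tolower(info$met)), paste0(a, " dissociation/export"),
        st, 0, 1000, "dissociation")
    ex <- c(-1); names(ex) <- paste0(info$met, "e")
    add(paste0("EX_", tolower(info$met)), paste0(a, " exchange"),
        ex, 0, 1000, "exchange")
  }

  rxdf <- data.frame(id = vapply(rx, `[[`, "", "id"),
                     name = vapply(rx, `[[`, "", "name"),
                     lower_bound = vapply(rx, `[[`, 0, "lb"),
                     upper_bound = vapply(rx, `[[`, 0, "ub"),
                     category = vapply(rx, `[[`, "", "cat"),
                     gene_association = vapply(rx, `[[`, "", "gpr"),
                     stringsAsFactors = FALSE)
  S <- matrix(0, nrow(mets), nrow(rxdf), dimnames = list(mets$id, rxdf$id))
  for (k in seq_along(rx)) S[names(rx[[k]]$stoich), k] <- rx[[k]]$stoich

  model <- metabolic_model(mets, rxdf, S, objective = "EX_h", id = "toycore")
  attr(model, "toy_config") <- list(acids = acids, ph = ph,
                                    phosphate_per_biomass = phosphate_per_biomass,
                                    ngam = ngam)
  attr(model, "phases") <- list(
    phosphate_storage = list(
      objective = "BIOMASS", growth = "BIOMASS",
      substrate = "EX_glc", phosphate = "EX_pi", storage = "SINK_pi",
      proton = "EX_h",
      bounds = list(EX_glc = c(-0.5, 0), EX_pi = c(-0.02, 0),
                    SINK_pi = c(0.015, 0.015), NGAM = c(ngam, 1000))),
    proton_production = list(
      objective = "EX_h", growth = "BIOMASS",
      substrate = "EX_glc", phosphate = "EX_pi", storage = "SINK_pi",
      proton = "EX_h",
      bounds = list(EX_glc = c(-0.5, 0), EX_pi = c(0, 0),
                    SINK_pi = c(-0.0025, 0), NGAM = c(ngam, 1000))))
  attr(model, "batch") <- list(A0 = 0.05, S0 = 100, P0 = 0.09,
                               dt = 0.01, t_max = 2000, ph = ph)
  model
}
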