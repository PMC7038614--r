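#' Write a model as SBML Level 3 (fbc version 2)
#'
#' Flux bounds are emitted as global parameters referenced through the fbc
#' `lowerFluxBound`/`upperFluxBound` attributes, the objective through an fbc
#' objective list. Gene associations, reaction categories and metabolite
#' molar masses / carbon counts are carried in structured notes (the
#' COBRA-style `GENE_ASSOCIATION:` convention), which keeps the file readable
#' by standard constraint-based tools and makes the writer/reader pair a
#' lossless round trip. Output is deterministic: the same model always
#' produces byte-identical SBML.
#'
#' @param model a [metabolic_model].
#' @param path output file.
#' @export
write_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) sprintf("%.17g", x)
  out <- character(0)
  w <- function(...) out[[length(out) + 1L]] <<- paste0(...)

  mets <- model$metabolites; rxns <- model$reactions
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1" fbc:required="false">')
  w('  <model id="', esc(model$id), '" fbc:strict="true">')
  w('    <listOfCompartments>')
  for (cp in unique(mets$compartment))
    w('      <compartment id="', esc(cp), '" constant="true"/>')
  w('    </listOfCompartments>')
  w('    <listOfSpecies>')
  for (i in seq_len(nrow(mets))) {
    notes <- character(0)
    if (!is.na(mets$molar_mass[i]))
      notes <- c(notes, paste0("MOLAR_MASS: ", num(mets$molar_mass[i])))
    if (!is.na(mets$carbon[i]))
      notes <- c(notes, paste0("CARBON: ", num(mets$carbon[i])))
    open <- paste0('      <species id="', esc(mets$id[i]), '" name="',
                   esc(mets$name[i]), '" compartment="',
                   esc(mets$compartment[i]),
                   '" hasOnlySubstanceUnits="false" boundaryCondition="false"',
                   ' constant="false"')
    if (!length(notes)) { w(open, "/>") } else {
      w(open, ">")
      w('        <notes><body xmlns="http://www.w3.org/1999/xhtml">')
      for (nt in notes) w("          <p>", esc(nt), "</p>")
      w('        </body></notes>')
      w("      </species>")
    }
  }
  w('    </listOfSpecies>')
  bvals <- sort(unique(c(rxns$lower_bound, rxns$upper_bound)))
  bid <- function(v) paste0("bnd_", match(v, bvals))
  w('    <listOfParameters>')
  for (k in seq_along(bvals))
    w('      <parameter id="bnd_', k, '" value="', num(bvals[k]),
      '" constant="true"/>')
  w('    </listOfParameters>')
  w('    <listOfReactions>')
  for (j in seq_len(nrow(rxns))) {
    sj <- model$S[, j]
    rects <- which(sj < 0); prods <- which(sj > 0)
    w('      <reaction id="', esc(rxns$id[j]), '" name="', esc(rxns$name[j]),
      '" reversible="', if (rxns$lower_bound[j] < 0) "true" else "false",
      '" fast="false" fbc:lowerFluxBound="', bid(rxns$lower_bound[j]),
      '" fbc:upperFluxBound="', bid(rxns$upper_bound[j]), '">')
    w('        <notes><body xmlns="http://www.w3.org/1999/xhtml">')
    if (nzchar(rxns$gene_association[j]))
      w("          <p>GENE_ASSOCIATION: ", esc(rxns$gene_association[j]), "</p>")
    w("          <p>CATEGORY: ", esc(rxns$category[j]), "</p>")
    w('        </body></notes>')
    if (length(rects)) {
      w('        <listOfReactants>')
      for (i in rects)
        w('          <speciesReference species="', esc(mets$id[i]),
          '" stoichiometry="', num(-sj[i]), '" constant="true"/>')
      w('        </listOfReactants>')
    }
    if (length(prods)) {
      w('        <listOfProducts>')
      for (i in prods)
        w('          <speciesReference species="', esc(mets$id[i]),
          '" stoichiometry="', num(sj[i]), '" constant="true"/>')
      w('        </listOfProducts>')
    }
    w("      </reaction>")
  }
  w('    </listOfReactions>')
  w('    <fbc:listOfObjectives fbc:activeObjective="obj">')
  w('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
  w('        <fbc:listOfFluxObjectives>')
  w('          <fbc:fluxObjective fbc:reaction="', esc(model$objective),
    '" fbc:coefficient="1"/>')
  w('        </fbc:listOfFluxObjectives>')
  w('      </fbc:objective>')
  w('    </fbc:listOfObjectives>')
  w("  </model>")
  w("</sbml>")
  con <- file(path, open = "wb")           # fixed EOL for determinism
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

xml_local <- function(node, name)
  xml2::xml_find_all(node, paste0(".//*[local-name()='", name, "']"))

# one line per <p> element inside an element's <notes>
note_lines <- function(node) {
  ps <- xml2::xml_find_all(node,
    "./*[local-name()='notes']//*[local-name()='p']")
  if (!length(ps)) "" else paste(xml2::xml_text(ps), collapse = "\n")
}

note_field <- function(text, key) {
  m <- regmatches(text, regexec(paste0(key, ":\\s*([^\n<]+)"), text))[[1]]
  if (length(m) < 2) NA_character_ else trimws(m[2])
}

#' Read an SBML model
#'
#' Supports SBML Level 3 with the fbc bound-parameter dialect as well as the
#' legacy COBRA Level 2 dialect (bounds as `LOWER_BOUND`/`UPPER_BOUND`
#' kinetic-law parameters, gene associations in `GENE_ASSOCIATION:` notes).
#' Reactions without explicit bounds default to `[-1000, 1000]` (reversible)
#' or `[0, 1000]` with a logged warning. Categories are taken from
#' `CATEGORY:` notes when present, otherwise inferred via
#' [infer_categories]. A load report (dialect used, warnings, category
#' counts) is attached as `attr(model, "load_report")`.
#'
#' @param path SBML file.
#' @param objective optional objective reaction id overriding the file's
#'   active objective.
#' @return A [metabolic_model].
#' @export
read_sbml <- function(path, objective = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse failure in '", path, "': ", conditionMessage(e)))
  report <- list(source = path, dialect = "fbc", warnings = character(0))

  model_node <- xml_local(doc, "model")
  if (!length(model_node)) stop("SBML parse failure: no <model> element")
  model_id <- xml2::xml_attr(model_node[[1]], "id")
  if (is.na(model_id)) model_id <- "model"

  sp <- xml_local(doc, "species")
  if (!length(sp)) stop("SBML parse failure: no <species> elements")
  sp_notes <- vapply(sp, note_lines, "")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    molar_mass = as.numeric(vapply(sp_notes, note_field, "", key = "MOLAR_MASS")),
    carbon = as.numeric(vapply(sp_notes, note_field, "", key = "CARBON")),
    stringsAsFactors = FALSE)
  mets$compartment[is.na(mets$compartment)] <- "c"
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"

  pars <- xml2::xml_find_all(doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  rnodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (!length(rnodes)) stop("SBML parse failure: no <reaction> elements")
  nr <- length(rnodes)
  ids <- xml2::xml_attr(rnodes, "id")
  nms <- xml2::xml_attr(rnodes, "name"); nms[is.na(nms)] <- ids[is.na(nms)]
  lb <- ub <- rep(NA_real_, nr)
  gpr <- character(nr); cat0 <- rep(NA_character_, nr)
  S <- matrix(0, nrow(mets), nr, dimnames = list(mets$id, ids))
  used_kinetic <- FALSE; used_default <- FALSE

  for (j in seq_len(nr)) {
    rn <- rnodes[[j]]
    flb <- xml2::xml_attr(rn, "lowerFluxBound")
    fub <- xml2::xml_attr(rn, "upperFluxBound")
    if (!is.na(flb) && flb %in% names(parval)) lb[j] <- parval[[flb]]
    if (!is.na(fub) && fub %in% names(parval)) ub[j] <- parval[[fub]]
    if (is.na(lb[j]) || is.na(ub[j])) {
      kl <- xml_local(rn, "kineticLaw")
      if (length(kl)) {
        kp <- xml_local(kl[[1]], "parameter")
        kid <- xml2::xml_attr(kp, "id")
        kv <- as.numeric(xml2::xml_attr(kp, "value"))
        if (is.na(lb[j]) && "LOWER_BOUND" %in% kid) {
          lb[j] <- kv[match("LOWER_BOUND", kid)]; used_kinetic <- TRUE
        }
        if (is.na(ub[j]) && "UPPER_BOUND" %in% kid) {
          ub[j] <- kv[match("UPPER_BOUND", kid)]; used_kinetic <- TRUE
        }
      }
    }
    if (is.na(lb[j]) || is.na(ub[j])) {
      rev <- !identical(xml2::xml_attr(rn, "reversible"), "false")
      if (is.na(lb[j])) lb[j] <- if (rev) -1000 else 0
      if (is.na(ub[j])) ub[j] <- 1000
      used_default <- TRUE
    }
    if (lb[j] > ub[j])
      stop("format error: reaction '", ids[j],
           "' has lower bound above upper bound (", lb[j], " > ", ub[j], ")")
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(rn, paste0("./*[local-name()='", side,
        "']/*[local-name()='speciesReference']"))
      for (ref in refs) {
        sid <- xml2::xml_attr(ref, "species")
        st <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
        if (is.na(st)) st <- 1
        if (!sid %in% mets$id)
          stop("format error: reaction '", ids[j],
               "' references unknown species '", sid, "'")
        S[sid, j] <- S[sid, j] + sgn * st
      }
    }
    ntext <- note_lines(rn)
    ga <- note_field(ntext, "GENE_ASSOCIATION")
    if (is.na(ga)) {
      gp <- xml_local(rn, "geneProductAssociation")
      ga <- if (length(gp)) gpr_from_fbc(gp[[1]]) else ""
    }
    gpr[j] <- if (is.na(ga)) "" else ga
    cc <- note_field(ntext, "CATEGORY")
    if (!is.na(cc)) cat0[j] <- cc
  }
  if (used_kinetic) report$dialect <- "kinetic-law"
  if (used_default) {
    report$warnings <- c(report$warnings,
      "missing flux bounds defaulted to +/-1000")
    warning("missing flux bounds defaulted to +/-1000 in '", path, "'")
  }
  # boundary-condition species are outside the balanced system
  if (any(boundary)) S <- S * ifelse(boundary, 0, 1)

  obj <- objective
  if (is.null(obj)) {
    fo <- xml_local(doc, "fluxObjective")
    if (length(fo)) {
      obj <- xml2::xml_attr(fo[[1]], "reaction")
      if (is.na(obj))
        obj <- xml2::xml_attr(fo[[1]], "fbc:reaction")
    }
  }
  if (is.null(obj) || is.na(obj) || !obj %in% ids) {
    obj <- ids[1]
    report$warnings <- c(report$warnings,
      "no usable objective in file; defaulted to first reaction")
  }

  rxns <- data.frame(id = ids, name = nms, lower_bound = lb, upper_bound = ub,
                     category = ifelse(is.na(cat0), "internal", cat0),
                     gene_association = gpr, stringsAsFactors = FALSE)
  model <- metabolic_model(mets, rxns, S, objective = obj, id = model_id)
  attr(model, "load_report") <- report
  if (anyNA(cat0)) model <- infer_categories(model)
  else {
    report$categories <- as.list(table(rxns$category))
    attr(model, "load_report") <- report
  }
  model
}

# flatten an fbc geneProductAssociation subtree into a boolean string
gpr_from_fbc <- function(node) {
  nm <- xml2::xml_name(node)
  kids <- xml2::xml_children(node)
  if (nm == "geneProductRef") {
    g <- xml2::xml_attr(node, "geneProduct")
    return(if (is.na(g)) "" else g)
  }
  parts <- vapply(kids, gpr_from_fbc, "")
  parts <- parts[nzchar(parts)]
  if (nm == "and") paste0("(", paste(parts, collapse = " and "), ")")
  else if (nm == "or") paste0("(", paste(parts, collapse = " or "), ")")
  else if (length(parts)) parts[1] else ""
}

#' Write the load report of a model as JSON
#'
#' @param model a model returned by [read_sbml].
#' @param path output file.
#' @export
write_load_report <- function(model, path) {
  rep <- attr(model, "load_report")
  if (is.null(rep)) rep <- list(source = NA, dialect = "constructed",
                                warnings = character(0))
  writeLines(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}
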