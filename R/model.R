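#' Construct a metabolic model object
#'
#' A `metabolic_model` bundles a stoichiometric matrix with reaction bounds,
#' reaction categories, gene associations and an objective reaction. It is the
#' substrate of flux-balance analysis and of in silico evolution.
#'
#' @param metabolites data frame with columns `id`, `name`, `compartment` and
#'   optionally `molar_mass` (g/mmol) and `carbon` (atoms per molecule).
#' @param reactions data frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `category` and `gene_association` (a boolean expression
#'   over gene identifiers, `""` when none). `category` must be one of
#'   `"internal"`, `"exchange"`, `"transport"`, `"biomass"`, `"maintenance"`,
#'   `"dissociation"`.
#' @param S stoichiometric matrix, metabolites in rows and reactions in
#'   columns (row/column order must match the data frames).
#' @param objective id of the objective reaction.
#' @param id model identifier.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, S, objective, id = "model") {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$molar_mass))
    metabolites$molar_mass <- rep(NA_real_, nrow(metabolites))
  if (is.null(metabolites$carbon))
    metabolites$carbon <- rep(NA_real_, nrow(metabolites))
  if (is.null(reactions$gene_association))
    reactions$gene_association <- rep("", nrow(reactions))
  S <- as.matrix(S)
  dimnames(S) <- list(metabolites$id, reactions$id)
  m <- structure(list(id = id, metabolites = metabolites,
                      reactions = reactions, S = S, objective = objective),
                 class = "metabolic_model")
  validate_model(m)
  m
}

validate_model <- function(model) {
  mets <- model$metabolites; rxns <- model$reactions; S <- model$S
  if (anyDuplicated(mets$id)) stop("duplicate metabolite ids: ",
    paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  if (anyDuplicated(rxns$id)) stop("duplicate reaction ids: ",
    paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  if (any(!nzchar(mets$compartment))) stop("metabolites must have a compartment")
  if (nrow(S) != nrow(mets) || ncol(S) != nrow(rxns))
    stop("stoichiometric matrix dimensions do not match metabolite/reaction tables")
  bad <- which(rxns$lower_bound > rxns$upper_bound)
  if (length(bad)) stop("lower_bound > upper_bound for reaction(s): ",
    paste(rxns$id[bad], collapse = ", "))
  empty <- which(rxns$category == "internal" & colSums(S != 0) == 0)
  if (length(empty)) stop("internal reaction(s) with empty stoichiometry: ",
    paste(rxns$id[empty], collapse = ", "))
  if (nrow(rxns) && !model$objective %in% rxns$id)
    stop("objective reaction not in model: ", model$objective)
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model:", x$id, "\n")
  cat("  reactions:  ", nrow(x$reactions), "\n")
  cat("  metabolites:", nrow(x$metabolites), "\n")
  cat("  objective:  ", x$objective, "\n")
  tab <- table(x$reactions$category)
  cat("  categories: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

n_reactions <- function(model) nrow(model$reactions)

rxn_index <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (anyNA(i)) stop("unknown reaction id(s): ", paste(id[is.na(i)], collapse = ", "))
  i
}

orig_bounds <- function(model) {
  list(lb = stats::setNames(model$reactions$lower_bound, model$reactions$id),
       ub = stats::setNames(model$reactions$upper_bound, model$reactions$id))
}

# tokenise a boolean gene-association string into gene ids
gene_ids_from_gpr <- function(gpr) {
  toks <- unlist(strsplit(gpr, "[()\\s]+", perl = TRUE))
  toks <- toks[nzchar(toks)]
  toks[!tolower(toks) %in% c("and", "or")]
}

#' Model summary statistics
#'
#' Counts reactions, unique metabolites and unique genes. Metabolites are
#' counted once across compartments: a configurable suffix pattern is stripped
#' from the metabolite id (many models tag compartment copies of a species as
#' e.g. `GLC` / `GLCe` / `GLCm`), and ids that only differ by that tag or by
#' the annotated compartment collapse to one unique metabolite.
#'
#' @param model a [metabolic_model].
#' @param compartment_regex regular expression removed from the end of each
#'   metabolite id before counting unique species. The default strips a
#'   one-letter compartment tag, optionally preceded by `_` or `-`.
#' @return An object of class `model_stats` with fields `n_reactions`,
#'   `n_unique_metabolites` and `n_unique_genes`.
#' @export
model_stats <- function(model, compartment_regex = "[-_]?[a-z]$") {
  mets <- model$metabolites
  base <- sub(compartment_regex, "", mets$id)
  base[!nzchar(base)] <- mets$id[!nzchar(base)]
  genes <- unique(unlist(lapply(model$reactions$gene_association, gene_ids_from_gpr)))
  structure(list(n_reactions = nrow(model$reactions),
                 n_unique_metabolites = length(unique(base)),
                 n_unique_genes = length(genes)),
            class = "model_stats")
}

#' @export
print.model_stats <- function(x, ...) {
  cat("reactions:          ", x$n_reactions, "\n")
  cat("unique metabolites: ", x$n_unique_metabolites, "\n")
  cat("unique genes:       ", x$n_unique_genes, "\n")
  invisible(x)
}

#' Reactions protected from mutation
#'
#' The genetic algorithm never mutates flux bounds of biomass, maintenance,
#' transport, exchange or acid-dissociation reactions; evolution acts on the
#' internal metabolic network only.
#'
#' @param model a [metabolic_model].
#' @return Character vector of protected reaction ids.
#' @export
detect_protected <- function(model) {
  model$reactions$id[model$reactions$category != "internal"]
}

#' Infer reaction categories for a model read from file
#'
#' SBML has no standard reaction-category field, so categories are inferred:
#' exchange reactions touch exactly one metabolite; biomass, maintenance,
#' transport and dissociation reactions are recognised by configurable id/name
#' patterns; everything else is internal.
#'
#' @param model a [metabolic_model].
#' @param patterns named list of case-insensitive regular expressions for
#'   `biomass`, `maintenance`, `transport` and `dissociation`.
#' @return The model with categories assigned; the match counts are appended
#'   to the load report attribute.
#' @export
infer_categories <- function(model,
                             patterns = list(biomass = "biomass|growth",
                                             maintenance = "maintenance|atpm|ngam",
                                             transport = "transport|t$",
                                             dissociation = "diss")) {
  rx <- model$reactions
  key <- paste(rx$id, rx$name)
  cat <- rep("internal", nrow(rx))
  cat[colSums(model$S != 0) == 1] <- "exchange"
  for (nm in c("transport", "dissociation", "maintenance", "biomass")) {
    hit <- grepl(patterns[[nm]], key, ignore.case = TRUE) & cat == "internal"
    cat[hit] <- nm
  }
  model$reactions$category <- cat
  rep <- attr(model, "load_report")
  if (is.null(rep)) rep <- list()
  rep$categories <- as.list(table(cat))
  attr(model, "load_report") <- rep
  model
}

# molar masses (g/mmol) of common fermentation species, for g/L reporting
ACID_TABLE <- list(
  citrate   = list(pka = c(3.13, 4.76, 6.40), carbon = 6, molar_mass = 0.19212, met = "CIT"),
  succinate = list(pka = c(4.21, 5.64),       carbon = 4, molar_mass = 0.11809, met = "SUCC"),
  lactate   = list(pka = 3.86,                carbon = 3, molar_mass = 0.09008, met = "LAC"),
  acetate   = list(pka = 4.76,                carbon = 2, molar_mass = 0.06005, met = "AC"),
  malate    = list(pka = c(3.40, 5.20),       carbon = 4, molar_mass = 0.13409, met = "MAL"),
  gluconate = list(pka = 3.86,                carbon = 6, molar_mass = 0.19616, met = "GLCNT"))

#' Map an organic-acid name to its exchange reaction
#'
#' @param model a [metabolic_model].
#' @param acid an acid name (e.g. `"citrate"`) or directly an exchange
#'   reaction id present in the model.
#' @return The exchange reaction id.
#' @export
acid_exchange_id <- function(model, acid) {
  if (acid %in% model$reactions$id) return(acid)
  info <- ACID_TABLE[[acid]]
  if (!is.null(info)) {
    cand <- paste0("EX_", tolower(info$met))
    if (cand %in% model$reactions$id) return(cand)
  }
  stop("no exchange reaction found for target acid '", acid, "'")
}
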