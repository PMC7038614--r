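#' Solve a flux-balance linear program
#'
#' Maximises (or minimises) the flux through an objective reaction over the
#' steady-state flux polytope `{v : S v = 0, lb <= v <= ub}`. When an optimum
#' exists the reported flux vector is made unique by a parsimonious secondary
#' criterion: total absolute flux is minimised at the fixed objective value,
#' so degenerate optima always resolve to the same vector — a requirement of
#' the mutation-recording rule, which compares fluxes against bounds.
#'
#' @param model a [metabolic_model].
#' @param bounds optional list with numeric vectors `lb` and `ub` (length =
#'   number of reactions) overriding the model bounds.
#' @param objective objective reaction id (default: the model objective).
#' @param sense `"max"` or `"min"`.
#' @param pfba logical; apply the parsimonious tie-break (default `TRUE`).
#' @return An object of class `fba_solution`: a list with `status`
#'   (`"optimal"`, `"infeasible"` or `"unbounded"`), `fluxes` (named vector,
#'   mmol gDW^-1 h^-1) and `objective_value`.
#' @export
solve_fba <- function(model, bounds = NULL, objective = model$objective,
                      sense = c("max", "min"), pfba = TRUE) {
  sense <- match.arg(sense)
  bl <- check_bounds(model, bounds)
  cvec <- numeric(n_reactions(model))
  cvec[rxn_index(model, objective)] <- 1
  r <- .lp_fba(model$S, cvec, bl$lb, bl$ub, sense == "max", pfba)
  status <- c("optimal", "infeasible", "unbounded", "infeasible")[r$status + 1]
  fluxes <- if (status == "optimal")
    stats::setNames(as.numeric(r$fluxes), model$reactions$id) else NULL
  structure(list(status = status, fluxes = fluxes,
                 objective_value = if (status == "optimal") r$objective else NA_real_,
                 objective = objective, sense = sense),
            class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("FBA solution (", x$sense, " ", x$objective, "): ", x$status, sep = "")
  if (x$status == "optimal")
    cat(", objective = ", format(x$objective_value, digits = 6), sep = "")
  cat("\n")
  invisible(x)
}

check_bounds <- function(model, bounds) {
  if (is.null(bounds))
    return(list(lb = model$reactions$lower_bound, ub = model$reactions$upper_bound))
  lb <- as.numeric(bounds$lb); ub <- as.numeric(bounds$ub)
  n <- n_reactions(model)
  if (length(lb) != n || length(ub) != n)
    stop("bounds must have one lower and one upper bound per reaction")
  bad <- which(lb > ub + 1e-12)
  if (length(bad)) stop("lower bound exceeds upper bound for reaction(s): ",
                        paste(model$reactions$id[bad], collapse = ", "))
  list(lb = lb, ub = ub)
}

#' Maximum (or minimum) attainable flux of one reaction
#'
#' Computes the extreme flux of a reaction over the polytope defined by the
#' supplied bounds, with the queried reaction's own bounds relaxed to the
#' original model bounds. This is the reference value used to cap
#' flux-forcing mutations.
#'
#' @param model a [metabolic_model].
#' @param bounds optional bound list as in [solve_fba] (an individual's
#'   current bounds).
#' @param reaction_id reaction to query.
#' @param sense `"max"` for the largest flux, `"min"` for the smallest.
#' @return The extreme flux value; `0` (with a warning) when the polytope is
#'   infeasible.
#' @export
max_flux <- function(model, bounds = NULL, reaction_id,
                     sense = c("max", "min")) {
  sense <- match.arg(sense)
  bl <- check_bounds(model, bounds)
  j <- rxn_index(model, reaction_id)
  bl$lb[j] <- model$reactions$lower_bound[j]
  bl$ub[j] <- model$reactions$upper_bound[j]
  cvec <- numeric(n_reactions(model)); cvec[j] <- 1
  r <- .lp_fba(model$S, cvec, bl$lb, bl$ub, sense == "max", FALSE)
  if (r$status != 0) {
    warning("flux polytope infeasible when querying ", reaction_id,
            "; returning 0")
    return(0)
  }
  r$objective
}

#' Create a wild-type individual for a model
#'
#' An individual carries the evolvable genome: chromosome 1 holds the lower
#' flux bounds, chromosome 2 the upper flux bounds, aligned to the model's
#' reaction order.
#'
#' @param model a [metabolic_model].
#' @return An object of class `oae_individual` with elements `lb` and `ub`.
#' @export
wildtype_individual <- function(model) {
  structure(list(lb = stats::setNames(model$reactions$lower_bound,
                                      model$reactions$id),
                 ub = stats::setNames(model$reactions$upper_bound,
                                      model$reactions$id)),
            class = "oae_individual")
}

#' Apply an individual's genome to a model
#'
#' Returns the individual's bounds clipped into the original model bounds:
#' evolution may constrain or force flux within the wild-type range but never
#' widen it (an irreversible reaction can never be made reversible).
#'
#' @param model a [metabolic_model].
#' @param individual an individual (list with `lb`, `ub`) or `NULL` for
#'   wild type.
#' @return List with clipped numeric vectors `lb` and `ub`.
#' @export
apply_individual <- function(model, individual = NULL) {
  olb <- model$reactions$lower_bound
  oub <- model$reactions$upper_bound
  if (is.null(individual)) return(list(lb = olb, ub = oub))
  n <- n_reactions(model)
  if (length(individual$lb) != n || length(individual$ub) != n)
    stop("genome length (", length(individual$lb),
         ") does not match reaction count (", n, ")")
  lb <- pmin(pmax(as.numeric(individual$lb), olb), oub)
  ub <- pmin(pmax(as.numeric(individual$ub), olb), oub)
  bad <- lb > ub
  lb[bad] <- pmin(lb[bad], ub[bad])
  list(lb = lb, ub = ub)
}

#' Export a flux vector as CSV
#'
#' @param solution an `fba_solution` with status `"optimal"`.
#' @param path output file.
#' @export
write_flux_csv <- function(solution, path) {
  if (is.null(solution$fluxes)) stop("no fluxes to write (status: ",
                                     solution$status, ")")
  utils::write.csv(data.frame(reaction_id = names(solution$fluxes),
                              flux = as.numeric(solution$fluxes)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
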