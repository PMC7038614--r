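#' Extract candidate solutions from an evolution log
#'
#' Recorded individuals with fitness strictly greater than `threshold` times
#' the highest recorded fitness become solution candidates. Individuals with
#' identical mutation sets (same reactions, sides and bound values) are
#' collapsed to one candidate carrying the highest fitness among them.
#'
#' @param log an `evolution_log` from [run_evolution].
#' @param threshold fraction of the maximum recorded fitness (strict).
#' @return List of `oae_solution` objects (mutation table, fitness,
#'   generation, plus the wild-type bound context needed for
#'   complementation).
#' @export
extract_solutions <- function(log, threshold = 0.95) {
  if (!length(log$records)) stop("evolution log contains no recorded individuals")
  fmax <- max(vapply(log$records, `[[`, 0, "fitness"))
  keep <- Filter(function(r) r$fitness > threshold * fmax, log$records)
  if (!length(keep)) stop("no recorded individual above the solution threshold")
  key <- vapply(keep, function(r)
    paste(r$mutations$reaction_index, r$mutations$side,
          signif(r$mutations$mutant_bound, 12), collapse = ";"), "")
  sols <- list()
  for (k in unique(key)) {
    grp <- keep[key == k]
    bestr <- grp[[which.max(vapply(grp, `[[`, 0, "fitness"))]]
    mut <- bestr$mutations
    mut$reaction_id <- log$reactions[mut$reaction_index]
    o <- order(mut$reaction_index, mut$side)
    sols[[length(sols) + 1L]] <- structure(
      list(mutations = mut[o, , drop = FALSE], fitness = bestr$fitness,
           generation = bestr$generation, complementation = NULL,
           reactions = log$reactions, original_bounds = log$original_bounds,
           target = log$target),
      class = "oae_solution")
  }
  sols
}

#' @export
print.oae_solution <- function(x, ...) {
  cat("Solution: fitness", format(x$fitness, digits = 6),
      "with", nrow(x$mutations), "mutation(s)\n")
  m <- x$mutations
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %4d %-10s %s  bound %s (wild-type %s)\n",
                m$reaction_index[i], x$reactions[m$reaction_index[i]],
                m$side[i], format(m$mutant_bound[i], digits = 5),
                format(m$wildtype_bound[i], digits = 5)))
  if (!is.null(x$complementation)) {
    cat("  complementation (% fitness decrease / % acid-flux decrease / % growth increase):\n")
    cc <- x$complementation
    for (i in seq_len(nrow(cc)))
      cat(sprintf("  %4d %s  %.1f / %.1f / %s\n", cc$reaction_index[i],
                  cc$side[i], cc$pct_fitness_decrease[i],
                  cc$pct_acid_flux_decrease[i],
                  ifelse(is.na(cc$pct_growth_increase[i]), "-",
                         sprintf("%.1f", cc$pct_growth_increase[i]))))
  }
  invisible(x)
}

# build the individual carrying a subset of a solution's mutations
solution_individual <- function(solution, rows = seq_len(nrow(solution$mutations))) {
  lb <- solution$original_bounds$lb
  ub <- solution$original_bounds$ub
  m <- solution$mutations[rows, , drop = FALSE]
  for (i in seq_len(nrow(m))) {
    j <- m$reaction_index[i]
    if (m$side[i] == "LC") lb[j] <- m$mutant_bound[i]
    else ub[j] <- m$mutant_bound[i]
  }
  bad <- lb > ub
  lb[bad] <- ub[bad]
  list(lb = lb, ub = ub)
}

#' Complement one mutation of a solution with the wild type
#'
#' Restores a single mutation's bound to its wild-type value while keeping
#' all other mutations, re-evaluates the fitness, and reports the percentage
#' fitness decrease, target-acid flux decrease and growth-rate increase
#' relative to the intact solution. An infeasible complemented genome is
#' scored as fitness 0.
#'
#' @param solution an `oae_solution`.
#' @param mutation_index row number in `solution$mutations` to complement.
#' @param evaluator a [fitness_evaluator] bound to the same model, constants
#'   and target as the evolution run.
#' @return One-row data frame of complementation metrics.
#' @export
complement_mutation <- function(solution, mutation_index, evaluator) {
  intact <- evaluator(solution_individual(solution))
  rows <- setdiff(seq_len(nrow(solution$mutations)), mutation_index)
  comp <- evaluator(solution_individual(solution, rows))
  F0 <- intact$F; Fc <- if (comp$status == "ok") comp$F else 0
  p0 <- if (intact$status == "ok") intact$phase2$p2 else 0
  pc <- if (comp$status == "ok") comp$phase2$p2 else 0
  g0 <- if (intact$status == "ok") intact$phase2$mu2 else NA_real_
  gc <- if (comp$status == "ok") comp$phase2$mu2 else NA_real_
  m <- solution$mutations[mutation_index, , drop = FALSE]
  data.frame(
    reaction_index = m$reaction_index, side = m$side,
    pct_fitness_decrease = if (F0 > 0) 100 * (F0 - Fc) / F0 else 0,
    pct_acid_flux_decrease = if (p0 > 0) 100 * (p0 - pc) / p0 else 0,
    pct_growth_increase = if (!is.na(g0) && g0 > 1e-12 && !is.na(gc))
      100 * (gc - g0) / g0 else NA_real_,
    stringsAsFactors = FALSE)
}

#' Prune a solution by complementation
#'
#' Mutations are complemented one at a time in ascending reaction-index
#' order; a mutation is retained when its complementation decreases the
#' current solution fitness by more than `threshold` (5% by default),
#' otherwise it is permanently reverted to wild type and the pruned solution
#' becomes the new baseline. The pass repeats until no further mutation is
#' discarded, which makes pruning idempotent. The returned solution carries
#' a complementation table for the retained mutations.
#'
#' @param solution an `oae_solution`.
#' @param evaluator a [fitness_evaluator].
#' @param threshold fractional fitness decrease below which a mutation is
#'   considered background and discarded.
#' @return The pruned `oae_solution`.
#' @export
prune_solution <- function(solution, evaluator, threshold = 0.05) {
  repeat {
    changed <- FALSE
    o <- order(solution$mutations$reaction_index, solution$mutations$side)
    solution$mutations <- solution$mutations[o, , drop = FALSE]
    i <- 1L
    while (i <= nrow(solution$mutations)) {
      Fcur <- evaluator(solution_individual(solution))$F
      rows <- setdiff(seq_len(nrow(solution$mutations)), i)
      comp <- evaluator(solution_individual(solution, rows))
      Fc <- if (comp$status == "ok") comp$F else 0
      drop <- !(Fcur > 0) || (Fcur - Fc) <= threshold * Fcur
      if (drop) {
        solution$mutations <- solution$mutations[rows, , drop = FALSE]
        changed <- TRUE
      } else i <- i + 1L
    }
    if (!changed || nrow(solution$mutations) == 0L) break
  }
  solution$fitness <- evaluator(solution_individual(solution))$F
  if (nrow(solution$mutations)) {
    cc <- do.call(rbind, lapply(seq_len(nrow(solution$mutations)),
                                complement_mutation, solution = solution,
                                evaluator = evaluator))
    solution$complementation <- cc
  } else solution$complementation <- NULL
  solution
}

#' Mutation frequencies across solutions
#'
#' For every reaction index appearing in any solution's mutations, the
#' frequency is the number of solutions containing at least one mutation of
#' that reaction divided by the number of solutions. The raw table keeps all
#' entries; the plot export drops entries below the cut-off.
#'
#' @param solutions list of `oae_solution` objects.
#' @param cutoff frequency cut-off applied in the plot export.
#' @return Data frame (`reaction_index`, `reaction_id`, `count`,
#'   `frequency`, `above_cutoff`) sorted by reaction index, with the cut-off
#'   and solution count as attributes.
#' @export
mutation_frequencies <- function(solutions, cutoff = 0.2) {
  if (!length(solutions)) stop("no solutions supplied")
  idx <- lapply(solutions, function(s) unique(s$mutations$reaction_index))
  tab <- table(unlist(idx))
  ri <- as.integer(names(tab))
  out <- data.frame(reaction_index = ri,
                    reaction_id = solutions[[1]]$reactions[ri],
                    count = as.integer(tab),
                    frequency = as.numeric(tab) / length(solutions),
                    stringsAsFactors = FALSE)
  out <- out[order(out$reaction_index), , drop = FALSE]
  out$above_cutoff <- out$frequency >= cutoff
  attr(out, "cutoff") <- cutoff
  attr(out, "n_solutions") <- length(solutions)
  out
}

#' Choose the solution that best represents the average
#'
#' Among solutions with fitness above `threshold` times the maximum, returns
#' the one whose mutations have the largest summed frequency across all
#' solutions (ties broken by fewer mutations, then higher fitness) — the
#' solution most typical of what evolution repeatedly found, at near-maximal
#' fitness.
#'
#' @param solutions list of (pruned) `oae_solution` objects.
#' @param frequencies optional precomputed [mutation_frequencies].
#' @param threshold fitness fraction defining the near-maximal set.
#' @return One `oae_solution`.
#' @export
representative_solution <- function(solutions, frequencies = NULL,
                                    threshold = 0.95) {
  if (!length(solutions)) stop("no solutions supplied")
  if (is.null(frequencies)) frequencies <- mutation_frequencies(solutions)
  fmax <- max(vapply(solutions, `[[`, 0, "fitness"))
  cand <- Filter(function(s) s$fitness > threshold * fmax, solutions)
  if (!length(cand)) cand <- solutions[which.max(vapply(solutions, `[[`, 0, "fitness"))]
  score <- vapply(cand, function(s) {
    f <- frequencies$frequency[match(unique(s$mutations$reaction_index),
                                     frequencies$reaction_index)]
    sum(f, na.rm = TRUE)
  }, 0)
  nmut <- vapply(cand, function(s) nrow(s$mutations), 0L)
  fit <- vapply(cand, `[[`, 0, "fitness")
  o <- order(-score, nmut, -fit)
  cand[[o[1]]]
}

#' Export analysis artefacts
#'
#' `write_complementation_csv` writes a per-mutation table with the
#' complementation percentages; `write_frequency_csv` the raw frequency
#' table; `write_frequency_json` a polar-plot-ready JSON (index, frequency,
#' and whether complementation abolishes more than 95% of target-acid flux);
#' `write_solution_json` a solution with its mutations and metrics.
#'
#' @param solution an `oae_solution` (pruned, with complementation).
#' @param frequencies a [mutation_frequencies] table.
#' @param solutions list of solutions (for the acid-flux classes).
#' @param path output file.
#' @name analysis-exports
NULL

#' @rdname analysis-exports
#' @export
write_complementation_csv <- function(solution, path) {
  if (is.null(solution$complementation))
    stop("solution carries no complementation table; run prune_solution first")
  m <- solution$mutations
  cc <- solution$complementation
  utils::write.csv(data.frame(
    index = m$reaction_index,
    reaction = solution$reactions[m$reaction_index],
    mutation_effect = m$side,
    mutant_bound = m$mutant_bound,
    wildtype_bound = m$wildtype_bound,
    pct_fitness_decrease = round(cc$pct_fitness_decrease, 1),
    pct_acid_flux_decrease = round(cc$pct_acid_flux_decrease, 1),
    pct_growth_increase = round(cc$pct_growth_increase, 1)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname analysis-exports
#' @export
write_frequency_csv <- function(frequencies, path) {
  utils::write.csv(frequencies, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname analysis-exports
#' @export
write_frequency_json <- function(frequencies, solutions, path) {
  cutoff <- attr(frequencies, "cutoff")
  keep <- frequencies[frequencies$above_cutoff, , drop = FALSE]
  acid_class <- vapply(keep$reaction_index, function(ri) {
    dec <- unlist(lapply(solutions, function(s) {
      if (is.null(s$complementation)) return(NULL)
      s$complementation$pct_acid_flux_decrease[
        s$complementation$reaction_index == ri]
    }))
    if (length(dec) && max(dec) > 95) "abolishes_acid_flux" else "partial"
  }, "")
  obj <- list(cutoff = cutoff,
              n_solutions = attr(frequencies, "n_solutions"),
              points = data.frame(index = keep$reaction_index,
                                  reaction = keep$reaction_id,
                                  frequency = keep$frequency,
                                  class = acid_class))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows", pretty = TRUE), path)
  invisible(path)
}

#' @rdname analysis-exports
#' @export
write_solution_json <- function(solution, path) {
  obj <- list(fitness = solution$fitness, generation = solution$generation,
              target = solution$target,
              mutations = cbind(solution$mutations,
                                reaction_id = solution$reactions[
                                  solution$mutations$reaction_index]))
  if (!is.null(solution$complementation))
    obj$complementation <- solution$complementation
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows", pretty = TRUE), path)
  invisible(path)
}
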