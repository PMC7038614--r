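#' Genetic-algorithm configuration
#'
#' Parameters of the evolutionary loop. Defaults follow the reference design:
#' a population of 500 wild-type individuals; each generation 5% of the
#' population is eliminated (drawn uniformly from the fitness-ranked bottom
#' half) and replaced by offspring of 10% selected parents split as 1% from
#' the whole population, 2% fresh wild types and 7% from the bottom half;
#' per-gene recombination rate 0.04 from the non-dominant parent; per-gene
#' mutation rate 0.02 with Laplace-distributed bound changes; flux-forcing
#' mutations pass a secondary 30% gate and are capped at 1% of the reaction's
#' maximum flux.
#'
#' @param population_size number of individuals.
#' @param elimination_fraction fraction eliminated per generation.
#' @param selection_random,selection_wildtype,selection_bottom parent-selection
#'   fractions (must sum to twice the elimination fraction).
#' @param recombination_rate per-gene probability of inheriting from the
#'   non-dominant parent.
#' @param mutation_rate per-gene mutation probability.
#' @param forcing_rate secondary acceptance rate for flux-forcing mutations.
#' @param forcing_cap forced flux magnitude cap, as a fraction of the
#'   reaction's maximum flux.
#' @param laplace_default_scale Laplace scale used when both the wild-type
#'   flux and the maximum wild-type flux of a reaction are zero; such
#'   mutations are sign-controlled so they can never force flux.
#' @param laplace_relative_scale Laplace scale relative to the wild-type flux
#'   (or, when that is zero, to the maximum wild-type flux).
#' @param generations number of generations to run.
#' @param seed RNG seed recorded in the log.
#' @param target_acid target acid name or exchange reaction id.
#' @param fitness_mode `"simple"` or `"adapted"` (see [evaluate_individual]).
#' @param weight target-acid weight of the adapted fitness.
#' @param max_flux_cache `"individual"` recomputes the forcing cap under the
#'   individual's current bounds (faithful); `"wildtype"` uses a wild-type
#'   bound cache (faster).
#' @return A validated list of class `ga_config`.
#' @export
ga_config <- function(population_size = 500, elimination_fraction = 0.05,
                      selection_random = 0.01, selection_wildtype = 0.02,
                      selection_bottom = 0.07, recombination_rate = 0.04,
                      mutation_rate = 0.02, forcing_rate = 0.3,
                      forcing_cap = 0.01, laplace_default_scale = 0.01,
                      laplace_relative_scale = 0.1, generations = 200,
                      seed = 1, target_acid = "citrate",
                      fitness_mode = c("simple", "adapted"), weight = 10,
                      max_flux_cache = c("individual", "wildtype")) {
  cfg <- list(population_size = as.integer(population_size),
              elimination_fraction = elimination_fraction,
              selection_random = selection_random,
              selection_wildtype = selection_wildtype,
              selection_bottom = selection_bottom,
              recombination_rate = recombination_rate,
              mutation_rate = mutation_rate, forcing_rate = forcing_rate,
              forcing_cap = forcing_cap,
              laplace_default_scale = laplace_default_scale,
              laplace_relative_scale = laplace_relative_scale,
              generations = as.integer(generations), seed = as.integer(seed),
              target_acid = target_acid,
              fitness_mode = match.arg(fitness_mode), weight = weight,
              max_flux_cache = match.arg(max_flux_cache))
  rates <- c(cfg$elimination_fraction, cfg$recombination_rate,
             cfg$mutation_rate, cfg$forcing_rate, cfg$selection_random,
             cfg$selection_wildtype, cfg$selection_bottom)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  ssum <- cfg$selection_random + cfg$selection_wildtype + cfg$selection_bottom
  if (abs(ssum - 2 * cfg$elimination_fraction) > 1e-9)
    stop("selection fractions must sum to twice the elimination fraction")
  if (cfg$population_size < 4) stop("population_size must be at least 4")
  structure(cfg, class = "ga_config")
}

#' Initialise a population of wild-type individuals
#'
#' @param model a [metabolic_model].
#' @param config a [ga_config].
#' @return A `ga_population`: matrices `lb` and `ub` (individuals in rows,
#'   reactions in columns) and a `fitness` vector (unevaluated, `NA`).
#' @export
init_population <- function(model, config) {
  N <- config$population_size
  n <- n_reactions(model)
  structure(list(
    lb = matrix(model$reactions$lower_bound, N, n, byrow = TRUE,
                dimnames = list(NULL, model$reactions$id)),
    ub = matrix(model$reactions$upper_bound, N, n, byrow = TRUE,
                dimnames = list(NULL, model$reactions$id)),
    fitness = rep(NA_real_, N)), class = "ga_population")
}

# rank order used for the bottom-50% pools: by fitness, ties by index
bottom_half <- function(fitness) {
  order(fitness, seq_along(fitness))[seq_len(floor(length(fitness) / 2))]
}

#' Draw the individuals eliminated this generation
#'
#' `ceiling(elimination_fraction * N)` individuals are drawn uniformly
#' without replacement from the fitness-ranked bottom half; the top half is
#' never eliminated, so the best individual always survives.
#'
#' @param fitness numeric fitness vector of the evaluated population.
#' @param config a [ga_config].
#' @return Integer indices of eliminated individuals.
#' @export
eliminate <- function(fitness, config) {
  N <- length(fitness)
  k <- ceiling(config$elimination_fraction * N)
  pool <- bottom_half(fitness)
  pool[sample.int(length(pool), k)]
}

#' Select and pair the parents of the next generation
#'
#' Twice as many parents as eliminated individuals are drawn: a small uniform
#' draw from the whole population, fresh wild-type individuals (re-seeding
#' wild-type genes into the pool), and the remainder uniformly from the
#' fitness-ranked bottom half. Eliminated and already-selected individuals
#' are never drawn. The selected parents are shuffled and paired
#' consecutively; each pair produces one new individual.
#'
#' @param fitness numeric fitness vector.
#' @param eliminated indices from [eliminate].
#' @param config a [ga_config].
#' @return A 2-row integer matrix of parent pairs; `0` denotes a fresh
#'   wild-type parent.
#' @export
select_parents <- function(fitness, eliminated, config) {
  N <- length(fitness)
  k <- length(eliminated)
  n1 <- round(config$selection_random * N)
  n2 <- round(config$selection_wildtype * N)
  n3 <- 2L * k - n1 - n2
  if (n3 < 0) stop("selection fractions inconsistent with elimination count")
  pool1 <- setdiff(seq_len(N), eliminated)
  s1 <- pool1[sample.int(length(pool1), n1)]
  pool3 <- setdiff(bottom_half(fitness), c(eliminated, s1))
  if (length(pool3) < n3)
    stop("bottom-50% selection pool exhausted")
  s3 <- pool3[sample.int(length(pool3), n3)]
  parents <- c(s1, rep(0L, n2), s3)
  matrix(parents[sample.int(length(parents))], nrow = 2L)
}

#' Recombine two parent genomes
#'
#' One parent is chosen uniformly as dominant; each gene (one bound entry,
#' lower bounds on chromosome 1 and upper bounds on chromosome 2) is taken
#' from the non-dominant parent with probability `rate`, otherwise from the
#' dominant parent.
#'
#' @param parent_a,parent_b genomes: lists with numeric `lb` and `ub`.
#' @param rate recombination rate.
#' @return A child genome (list with `lb`, `ub`).
#' @export
recombine <- function(parent_a, parent_b, rate = 0.04) {
  n <- length(parent_a$lb)
  if (length(parent_b$lb) != n)
    stop("parent genomes differ in length")
  if (sample.int(2L, 1L) == 2L) { tmp <- parent_a; parent_a <- parent_b; parent_b <- tmp }
  take <- stats::runif(2L * n) < rate   # from the non-dominant parent
  lb <- parent_a$lb; ub <- parent_a$ub
  t1 <- take[seq_len(n)]; t2 <- take[n + seq_len(n)]
  lb[t1] <- parent_b$lb[t1]
  ub[t2] <- parent_b$ub[t2]
  # inherited bounds may cross when the chromosomes come from different
  # parents; the lower bound is clipped to the inherited upper bound (the
  # same convention mutation uses), keeping the genome feasible
  bad <- lb > ub
  lb[bad] <- ub[bad]
  list(lb = lb, ub = ub)
}

# Laplace(0, b) draws by inversion
rlaplace <- function(n, b) {
  u <- stats::runif(n) - 0.5
  -b * sign(u) * log(1 - 2 * abs(u))
}

#' Laplace scale parameter for mutating a reaction's bounds
#'
#' The mutation step size is relative to the wild-type flux of the reaction;
#' when that is zero, to the maximum wild-type flux (the largest magnitude
#' the reaction can carry under wild-type bounds); when both are zero, a
#' fixed default is used and the mutation is sign-controlled so it cannot
#' force flux.
#'
#' @param model a [metabolic_model].
#' @param reaction_id reaction to query.
#' @param wildtype_fluxes named wild-type flux vector (phase-2 parsimonious
#'   solution).
#' @param max_fluxes optional named vector of maximum wild-type flux
#'   magnitudes; computed by [max_flux] when absent.
#' @param relative_scale,default_scale see [ga_config].
#' @return List with the scale `b` and `is_default` (whether the default was
#'   used, which triggers sign control).
#' @export
laplace_scale <- function(model, reaction_id, wildtype_fluxes,
                          max_fluxes = NULL, relative_scale = 0.1,
                          default_scale = 0.01) {
  wt <- abs(wildtype_fluxes[[reaction_id]])
  if (wt > 1e-9)
    return(list(b = relative_scale * wt, is_default = FALSE))
  mf <- if (!is.null(max_fluxes)) max_fluxes[[reaction_id]] else
    max(abs(max_flux(model, NULL, reaction_id, "max")),
        abs(max_flux(model, NULL, reaction_id, "min")))
  if (mf > 1e-9)
    return(list(b = relative_scale * mf, is_default = FALSE))
  list(b = default_scale, is_default = TRUE)
}

#' Precompute the context used by the mutation operator
#'
#' Collects, once per run, everything mutation needs: original bounds, the
#' protected gene set, per-reaction Laplace scales and the phase-2 bound
#' overlay under which forcing caps are computed.
#'
#' @param model a [metabolic_model].
#' @param wildtype_fluxes named phase-2 wild-type flux vector.
#' @param config a [ga_config].
#' @param phase2 optional phase-2 configuration ([configure_phase]).
#' @return A `mutation_context` list.
#' @export
mutation_context <- function(model, wildtype_fluxes, config, phase2 = NULL) {
  if (is.null(phase2)) phase2 <- configure_phase(model, "proton_production")
  n <- n_reactions(model)
  rid <- model$reactions$id
  protected <- rid %in% detect_protected(model)
  controlled <- rxn_index(model, names(phase2$params$bounds))
  # maximum wild-type flux magnitudes under the phase-2 parameterisation
  mf_max <- mf_min <- numeric(n)
  pb <- list(lb = phase2$lb, ub = phase2$ub)
  for (j in seq_len(n)) {
    if (protected[j]) next
    mf_max[j] <- max_flux(model, pb, rid[j], "max")
    mf_min[j] <- max_flux(model, pb, rid[j], "min")
  }
  b <- numeric(n); is_default <- logical(n)
  for (j in seq_len(n)) {
    wt <- abs(wildtype_fluxes[[j]])
    cap <- max(abs(mf_max[j]), abs(mf_min[j]))
    if (wt > 1e-9) b[j] <- config$laplace_relative_scale * wt
    else if (cap > 1e-9) b[j] <- config$laplace_relative_scale * cap
    else { b[j] <- config$laplace_default_scale; is_default[j] <- TRUE }
  }
  list(model = model, olb = model$reactions$lower_bound,
       oub = model$reactions$upper_bound, protected = protected,
       controlled = controlled, phase_lb = phase2$lb, phase_ub = phase2$ub,
       b = b, is_default = is_default, wt_flux = as.numeric(wildtype_fluxes),
       mf_max = mf_max, mf_min = mf_min, n = n,
       mutation_rate = config$mutation_rate,
       forcing_rate = config$forcing_rate, forcing_cap = config$forcing_cap,
       cache = config$max_flux_cache)
}

#' Mutate a genome
#'
#' Non-protected genes are visited in random order and mutated with the
#' configured per-gene probability by adding a Laplace-distributed value to
#' the current bound; an unmutated (wild-type) gene starts from the wild-type
#' flux value instead of the bound. Results are clipped into the original
#' bounds and against the sister chromosome (lower bound can never exceed
#' upper bound). Three control steps tame flux-forcing mutations: genes with
#' the default Laplace scale are sign-controlled (negative on chromosome 1,
#' positive on chromosome 2) so they cannot force flux; a mutation whose
#' resulting bound forces flux (lower bound above zero or upper bound below
#' zero) is kept only with the secondary forcing rate; kept forcing bounds
#' are capped at `forcing_cap` times the reaction's maximum flux under the
#' individual's current other bounds.
#'
#' @param genome list with numeric `lb` and `ub`.
#' @param model a [metabolic_model].
#' @param wildtype_fluxes named phase-2 wild-type flux vector.
#' @param config a [ga_config].
#' @param context optional precomputed [mutation_context] (recommended when
#'   mutating many genomes).
#' @return The mutated genome, with an attribute `mutation_stats` counting
#'   eligible genes, genes drawn for mutation, forcing-classified mutations
#'   and forcing mutations kept.
#' @export
mutate_genome <- function(genome, model, wildtype_fluxes = NULL,
                          config = ga_config(), context = NULL) {
  if (is.null(context))
    context <- mutation_context(model, wildtype_fluxes, config)
  ctx <- context
  n <- ctx$n
  lb <- as.numeric(genome$lb); ub <- as.numeric(genome$ub)
  eligible <- which(c(!ctx$protected, !ctx$protected))
  drawn <- eligible[stats::runif(length(eligible)) < ctx$mutation_rate]
  n_forcing <- 0L; n_kept <- 0L
  if (length(drawn) > 1) drawn <- drawn[sample.int(length(drawn))]
  for (g in drawn) {
    side <- if (g <= n) 1L else 2L
    j <- if (side == 1L) g else g - n
    d <- rlaplace(1L, ctx$b[j])
    if (ctx$is_default[j]) d <- if (side == 1L) -abs(d) else abs(d)
    cur <- if (side == 1L) lb[j] else ub[j]
    wild <- if (side == 1L) cur == ctx$olb[j] else cur == ctx$oub[j]
    start <- if (wild) ctx$wt_flux[j] else cur
    nv <- min(max(start + d, ctx$olb[j]), ctx$oub[j])
    nv <- if (side == 1L) min(nv, ub[j]) else max(nv, lb[j])
    forcing <- if (side == 1L) nv > 0 else nv < 0
    if (forcing) {
      n_forcing <- n_forcing + 1L
      if (stats::runif(1L) > ctx$forcing_rate) next   # suppressed
      n_kept <- n_kept + 1L
      if (ctx$cache == "wildtype") {
        ext <- if (side == 1L) ctx$mf_max[j] else ctx$mf_min[j]
      } else {
        blb <- lb; bub <- ub
        blb[ctx$controlled] <- ctx$phase_lb[ctx$controlled]
        bub[ctx$controlled] <- ctx$phase_ub[ctx$controlled]
        ext <- suppressWarnings(
          max_flux(ctx$model, list(lb = blb, ub = bub), ctx$model$reactions$id[j],
                   if (side == 1L) "max" else "min"))
      }
      if (side == 1L) nv <- min(nv, ctx$forcing_cap * max(ext, 0))
      else nv <- max(nv, ctx$forcing_cap * min(ext, 0))
      nv <- min(max(nv, ctx$olb[j]), ctx$oub[j])
      nv <- if (side == 1L) min(nv, ub[j]) else max(nv, lb[j])
    }
    if (side == 1L) lb[j] <- nv else ub[j] <- nv
  }
  structure(list(lb = lb, ub = ub),
            mutation_stats = c(eligible = length(eligible),
                               drawn = length(drawn),
                               forcing = n_forcing, forcing_kept = n_kept))
}

#' Should a newly evaluated individual be recorded?
#'
#' When the wild type does not produce the target acid, any individual that
#' does is recorded. Otherwise an individual is recorded when its fitness
#' exceeds the running maximum or 110% of the wild-type fitness.
#'
#' @param result a `fitness_result` (or a list with `F` and `phase2$p2`).
#' @param state list with `best_so_far`, `wildtype_fitness` and
#'   `wildtype_produces_target`.
#' @return Logical.
#' @export
should_record <- function(result, state) {
  if (!isTRUE(state$wildtype_produces_target))
    return(!is.null(result$phase2) && result$phase2$p2 > 1e-9)
  result$F > state$best_so_far || result$F > 1.1 * state$wildtype_fitness
}

# genome diff vs wild type, keeping only phenotypic mutations (flux sits on
# the mutated bound, tolerance 1e-6)
phenotypic_mutations <- function(lb, ub, olb, oub, fluxes, tol = 1e-6) {
  i1 <- which(lb != olb)
  i2 <- which(ub != oub)
  keep1 <- i1[abs(fluxes[i1] - lb[i1]) <= tol]
  keep2 <- i2[abs(fluxes[i2] - ub[i2]) <= tol]
  data.frame(reaction_index = c(keep1, keep2),
             side = rep(c("LC", "UC"), c(length(keep1), length(keep2))),
             mutant_bound = c(lb[keep1], ub[keep2]),
             wildtype_bound = c(olb[keep1], oub[keep2]),
             stringsAsFactors = FALSE)
}

#' Run an in silico evolution
#'
#' Executes the full evolutionary loop — fitness evaluation, elimination,
#' selection, recombination, mutation — for the configured number of
#' generations. Only newly created individuals are evaluated (one
#' lexicographic phase-2 FBA each); existing individuals are immutable, so
#' the best population fitness is non-decreasing. Individuals that satisfy
#' the recording rule are logged as genome diffs against the wild type,
#' keeping only phenotypic mutations. The run is deterministic for a fixed
#' seed.
#'
#' @param model a [metabolic_model].
#' @param config a [ga_config].
#' @param constants optional phase-1 [fitness constants][extract_constants];
#'   computed from a wild-type dFBA simulation when absent.
#' @param progress print the best fitness every `progress` generations
#'   (0 = silent).
#' @return An object of class `evolution_log`.
#' @export
run_evolution <- function(model, config, constants = NULL, progress = 0) {
  stopifnot(inherits(config, "ga_config"))
  set.seed(config$seed)
  if (is.null(constants)) {
    traj <- simulate_batch(model, stop_after_switch = TRUE)
    constants <- extract_constants(traj)
  }
  phase2 <- configure_phase(model, "proton_production")
  rid <- model$reactions$id
  n <- n_reactions(model)
  i_gro <- rxn_index(model, phase2$growth)
  i_h <- rxn_index(model, phase2$params$proton)
  i_sub <- rxn_index(model, phase2$params$substrate)
  i_tgt <- rxn_index(model, acid_exchange_id(model, config$target_acid))
  controlled <- rxn_index(model, names(phase2$params$bounds))
  free <- setdiff(seq_len(n), controlled)
  tlb <- phase2$lb; tub <- phase2$ub

  evalg <- function(lb, ub) {
    elb <- tlb; eub <- tub
    elb[free] <- lb[free]; eub[free] <- ub[free]
    r <- .lp_phase2(model$S, elb, eub, i_gro, i_h, TRUE)
    if (r$status != 0)
      return(list(F = 0, p2 = 0, status = "infeasible", fluxes = NULL))
    v <- as.numeric(r$fluxes)
    mu2 <- max(v[i_gro], 0); f2 <- abs(v[i_sub])
    p2 <- max(v[i_tgt], 0); h <- max(v[i_h], 0)
    c_tf <- estimate_yield(p2, f2, constants$S_c)
    t_f <- estimate_tf(constants$t_c, constants$S_c, mu2, f2, constants$A_c)
    FF <- if (config$fitness_mode == "simple") fitness_simple(c_tf, t_f)
          else fitness_adapted(estimate_proton_yield(h, f2, constants$S_c),
                               c_tf, t_f, config$weight)
    list(F = FF, p2 = p2, status = "ok", fluxes = v)
  }

  olb <- model$reactions$lower_bound
  oub <- model$reactions$upper_bound
  wt <- evalg(olb, oub)
  if (wt$status != "ok") stop("wild-type phase-2 FBA is infeasible")
  ctx <- mutation_context(model, wt$fluxes, config, phase2)

  N <- config$population_size
  pop_lb <- matrix(olb, N, n, byrow = TRUE)
  pop_ub <- matrix(oub, N, n, byrow = TRUE)
  fitness <- rep(wt$F, N)
  best <- numeric(config$generations + 1L)
  running_best <- wt$F
  best[1L] <- running_best
  best_genome <- list(lb = olb, ub = oub)
  wt_produces <- wt$p2 > 1e-9

  records <- vector("list", 256L); nrecords <- 0L
  add_record <- function(rec) {
    nrecords <<- nrecords + 1L
    if (nrecords > length(records)) length(records) <<- 2L * length(records)
    records[[nrecords]] <<- rec
  }

  genome_of <- function(i) {
    if (i == 0L) list(lb = olb, ub = oub)
    else list(lb = pop_lb[i, ], ub = pop_ub[i, ])
  }

  for (gen in seq_len(config$generations)) {
    el <- eliminate(fitness, config)
    pairs <- select_parents(fitness, el, config)
    for (k in seq_len(ncol(pairs))) {
      ia <- pairs[1L, k]; ib <- pairs[2L, k]
      pa <- genome_of(ia); pb <- genome_of(ib)
      child <- recombine(pa, pb, config$recombination_rate)
      child <- mutate_genome(child, model, config = config, context = ctx)
      # an offspring identical to a parent needs no re-evaluation (and its
      # mutation set was already considered for recording when first created)
      res <- NULL
      if (identical(child$lb, pa$lb) && identical(child$ub, pa$ub)) {
        res <- list(F = if (ia == 0L) wt$F else fitness[ia], p2 = NA_real_,
                    status = "cached", fluxes = NULL)
      } else if (identical(child$lb, pb$lb) && identical(child$ub, pb$ub)) {
        res <- list(F = if (ib == 0L) wt$F else fitness[ib], p2 = NA_real_,
                    status = "cached", fluxes = NULL)
      }
      if (is.null(res)) res <- evalg(child$lb, child$ub)
      slot <- el[k]
      pop_lb[slot, ] <- child$lb
      pop_ub[slot, ] <- child$ub
      fitness[slot] <- res$F
      if (res$status == "ok" &&
          should_record(list(F = res$F, phase2 = list(p2 = res$p2)),
                        list(best_so_far = running_best,
                             wildtype_fitness = wt$F,
                             wildtype_produces_target = wt_produces))) {
        add_record(list(generation = gen, fitness = res$F, p2 = res$p2,
                        mutations = phenotypic_mutations(child$lb, child$ub,
                                                         olb, oub, res$fluxes)))
      }
      if (res$F > running_best) {
        running_best <- res$F
        best_genome <- child
      }
    }
    best[gen + 1L] <- running_best
    if (progress > 0 && gen %% progress == 0)
      cat("generation ", gen, "  best fitness ", format(running_best, digits = 6),
          "\n", sep = "")
  }

  structure(list(best = best, records = records[seq_len(nrecords)],
                 best_individual = structure(best_genome,
                                             fitness = running_best,
                                             class = "oae_individual"),
                 config = config, seed = config$seed, constants = constants,
                 wildtype = list(fitness = wt$F, produces_target = wt_produces,
                                 fluxes = stats::setNames(wt$fluxes, rid),
                                 p2 = wt$p2),
                 target = rid[i_tgt], reactions = rid,
                 original_bounds = list(lb = olb, ub = oub),
                 population = list(lb = pop_lb, ub = pop_ub, fitness = fitness),
                 model_id = model$id),
            class = "evolution_log")
}

#' @export
print.evolution_log <- function(x, ...) {
  cat("In silico evolution log (", x$model_id, ")\n", sep = "")
  cat("  target:       ", x$target, " (", x$config$fitness_mode, " fitness)\n",
      sep = "")
  cat("  generations:  ", length(x$best) - 1L, "\n")
  cat("  seed:         ", x$seed, "\n")
  cat("  wild-type F:  ", format(x$wildtype$fitness, digits = 6), "\n")
  cat("  best F:       ", format(max(x$best), digits = 6), "\n")
  cat("  recorded:     ", length(x$records), "individuals\n")
  invisible(x)
}

#' @export
summary.evolution_log <- function(object, ...) {
  gain <- if (object$wildtype$fitness > 0)
    max(object$best) / object$wildtype$fitness else Inf
  out <- list(best_fitness = max(object$best),
              wildtype_fitness = object$wildtype$fitness,
              fitness_gain = gain,
              generations = length(object$best) - 1L,
              n_recorded = length(object$records),
              first_improvement = {
                i <- which(object$best > object$best[1] + 1e-12)
                if (length(i)) i[1] - 1L else NA_integer_
              })
  class(out) <- "summary.evolution_log"
  out
}

#' @export
print.summary.evolution_log <- function(x, ...) {
  cat("best fitness:      ", format(x$best_fitness, digits = 6), "\n")
  cat("wild-type fitness: ", format(x$wildtype_fitness, digits = 6), "\n")
  cat("fitness gain:      ", format(x$fitness_gain, digits = 4), "x\n")
  cat("first improvement: generation", x$first_improvement, "\n")
  cat("recorded individuals:", x$n_recorded, "\n")
  invisible(x)
}

#' @export
plot.evolution_log <- function(x, ...) {
  graphics::plot(seq_along(x$best) - 1L, x$best, type = "l",
                 xlab = "generation", ylab = "highest population fitness",
                 main = paste("evolution towards", x$target), ...)
  graphics::abline(h = x$wildtype$fitness, lty = 3)
  invisible(x)
}

#' Export an evolution log
#'
#' Writes the per-generation best-fitness trace as CSV and the recorded
#' individuals as JSON-lines (one record per line: generation, fitness,
#' mutation list), with the configuration and seed embedded.
#'
#' @param log an `evolution_log`.
#' @param trace_path CSV output for the fitness trace (`NULL` to skip).
#' @param records_path JSON-lines output for records (`NULL` to skip).
#' @export
write_evolution_log <- function(log, trace_path = NULL, records_path = NULL) {
  if (!is.null(trace_path))
    utils::write.csv(data.frame(generation = seq_along(log$best) - 1L,
                                best_fitness = log$best),
                     trace_path, row.names = FALSE, quote = FALSE)
  if (!is.null(records_path)) {
    con <- file(records_path, "w")
    on.exit(close(con))
    writeLines(jsonlite::toJSON(list(type = "header", seed = log$seed,
                                     target = log$target,
                                     config = unclass(log$config)),
                                auto_unbox = TRUE, digits = NA), con)
    for (r in log$records)
      writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA,
                                  dataframe = "rows"), con)
  }
  invisible(log)
}
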