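test_that("configuration validates rates and selection fractions", {
  cfg <- ga_config()
  expect_equal(cfg$population_size, 500L)
  expect_error(ga_config(selection_random = 0.05), "twice the elimination")
  expect_error(ga_config(mutation_rate = 1.5), "rates")
  expect_error(ga_config(population_size = 2), "at least")
})

test_that("population initialises as wild-type copies", {
  m <- get_toy()
  pop <- init_population(m, ga_config(population_size = 12))
  expect_equal(nrow(pop$lb), 12)
  expect_true(all(t(pop$lb) == m$reactions$lower_bound))
  expect_true(all(t(pop$ub) == m$reactions$upper_bound))
  pop500 <- init_population(m, ga_config())
  expect_equal(nrow(pop500$lb), 500)
})

test_that("elimination draws only from the bottom half", {
  set.seed(1)
  fitness <- runif(500)
  el <- eliminate(fitness, ga_config())
  expect_length(el, 25)
  expect_length(unique(el), 25)
  ranked <- order(fitness)
  bottom <- ranked[1:250]
  expect_true(all(el %in% bottom))

  # the best individual is never eliminated, and a bottom-half individual is
  # hit with probability ~ 25/250 = 0.1
  best_i <- which.max(fitness)
  probe <- ranked[100]
  hits_best <- 0; hits_probe <- 0
  n <- 10000
  for (r in seq_len(n)) {
    el <- eliminate(fitness, ga_config())
    if (best_i %in% el) hits_best <- hits_best + 1
    if (probe %in% el) hits_probe <- hits_probe + 1
  }
  expect_equal(hits_best, 0)
  p <- hits_probe / n
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(p - 0.1), 3 * se + 1e-9)
})

test_that("selection yields 50 parents split 5/10/35 at N = 500", {
  set.seed(2)
  fitness <- runif(500)
  el <- eliminate(fitness, ga_config())
  for (r in 1:50) {
    pairs <- select_parents(fitness, el, ga_config())
    sel <- as.integer(pairs)
    expect_equal(length(sel), 50)
    expect_equal(sum(sel == 0), 10)                 # fresh wild types
    real <- sel[sel > 0]
    expect_false(any(real %in% el))                 # never the eliminated
    expect_equal(anyDuplicated(real), 0)            # never re-selected
    bottom <- order(fitness, seq_along(fitness))[1:250]
    expect_gte(sum(real %in% bottom), 35)           # 7% from the bottom half
  }
})

test_that("recombination inherits per-gene from the non-dominant parent", {
  n <- 32
  pa <- list(lb = rep(0, n), ub = rep(10, n))
  pb <- list(lb = rep(1, n), ub = rep(11, n))
  set.seed(3)
  # rate 0: clone of the dominant parent
  ch0 <- recombine(pa, pb, rate = 0)
  expect_true(identical(ch0$lb, pa$lb) || identical(ch0$lb, pb$lb))
  # every child gene comes from one of the parents
  ch <- recombine(pa, pb, rate = 0.3)
  expect_true(all(ch$lb %in% c(0, 1)))
  expect_true(all(ch$ub %in% c(10, 11)))
  expect_error(recombine(pa, list(lb = 1:3, ub = 4:6)), "length")

  # crossed inherited bounds are repaired (lb clipped to ub)
  pc <- list(lb = rep(5, n), ub = rep(20, n))
  pd <- list(lb = rep(0, n), ub = rep(2, n))
  for (r in 1:50) {
    chx <- recombine(pc, pd, rate = 0.5)
    expect_true(all(chx$lb <= chx$ub))
  }

  # empirical non-dominant inheritance fraction ~ 4%
  nrep <- 10000
  frac <- numeric(nrep)
  for (r in seq_len(nrep)) {
    ch <- recombine(pa, pb, rate = 0.04)
    genes <- c(ch$lb, ch$ub)
    from_a <- mean(genes %in% c(0, 10))
    frac[r] <- min(from_a, 1 - from_a)   # minority share = non-dominant
  }
  se <- sd(frac) / sqrt(nrep)
  expect_lt(abs(mean(frac) - 0.04), 3 * se)
})

test_that("Laplace scales are relative to wild-type flux with a guarded default", {
  m <- get_toy()
  k <- get_constants()
  cfg2 <- configure_phase(m, "proton_production")
  wt <- acidevolve:::phase2_fba(m, cfg2)$fluxes
  # active reaction: scale proportional to its flux
  s <- laplace_scale(m, "GLYC", wt, relative_scale = 0.1)
  expect_equal(s$b, 0.1 * abs(wt[["GLYC"]]))
  expect_false(s$is_default)
  # inactive but usable reaction: falls back to the maximum wild-type flux
  s2 <- laplace_scale(m, "LDH", wt,
                      max_fluxes = c(LDH = 2), relative_scale = 0.1)
  expect_equal(s2$b, 0.2)
  # both references zero: default with sign control
  s3 <- laplace_scale(m, "LDH", replace(wt, "LDH", 0), max_fluxes = c(LDH = 0))
  expect_equal(s3$b, 0.01)
  expect_true(s3$is_default)
  ctx <- mutation_context(m, wt, ga_config())
  expect_true(all(ctx$b > 0))
})

test_that("mutation respects protection, rates and forcing caps", {
  m <- get_toy()
  cfg <- ga_config()
  cfg2 <- configure_phase(m, "proton_production")
  wt <- acidevolve:::phase2_fba(m, cfg2)$fluxes
  ctx <- mutation_context(m, wt, cfg, cfg2)
  genome <- list(lb = m$reactions$lower_bound, ub = m$reactions$upper_bound)
  prot <- which(ctx$protected)

  set.seed(4)
  stats <- matrix(0, 0, 4)
  for (r in 1:2000) {
    g <- mutate_genome(genome, m, config = cfg, context = ctx)
    expect_true(all(g$lb[prot] == genome$lb[prot]))
    expect_true(all(g$ub[prot] == genome$ub[prot]))
    expect_true(all(g$lb <= g$ub))
    expect_true(all(g$lb >= ctx$olb & g$ub <= ctx$oub))
    stats <- rbind(stats, attr(g, "mutation_stats"))
  }
  # per-gene mutation-attempt probability ~ 0.02
  p_att <- stats[, "drawn"] / stats[, "eligible"]
  se <- sd(p_att) / sqrt(nrow(stats))
  expect_lt(abs(mean(p_att) - cfg$mutation_rate), 3 * se)
  # forcing acceptance ~ 0.3
  nf <- sum(stats[, "forcing"]); nk <- sum(stats[, "forcing_kept"])
  expect_gt(nf, 100)
  se_f <- sqrt(0.3 * 0.7 / nf)
  expect_lt(abs(nk / nf - 0.3), 3 * se_f)

  # forced bounds stay under the cap relative to the maximum flux
  set.seed(5)
  cfg_wtcache <- ga_config(max_flux_cache = "wildtype")
  ctx2 <- mutation_context(m, wt, cfg_wtcache, cfg2)
  for (r in 1:500) {
    g <- mutate_genome(genome, m, config = cfg_wtcache, context = ctx2)
    forced <- which(g$lb > 1e-12)
    for (j in forced)
      expect_lte(g$lb[j], cfg$forcing_cap * max(ctx2$mf_max[j], 0) + 1e-9)
  }
})

test_that("recording rule follows the wild-type production status", {
  st_new <- list(best_so_far = 1, wildtype_fitness = 1,
                 wildtype_produces_target = FALSE)
  expect_true(should_record(list(F = 0.1, phase2 = list(p2 = 0.2)), st_new))
  expect_false(should_record(list(F = 5, phase2 = list(p2 = 0)), st_new))
  st_wt <- list(best_so_far = 1, wildtype_fitness = 1,
                wildtype_produces_target = TRUE)
  expect_false(should_record(list(F = 1.0, phase2 = list(p2 = 1)), st_wt))
  expect_true(should_record(list(F = 1.05, phase2 = list(p2 = 1)), st_wt))
  expect_true(should_record(list(F = 1.2, phase2 = list(p2 = 1)),
                            modifyList(st_wt, list(best_so_far = 2))))
})

test_that("evolution runs are deterministic and monotone", {
  m <- get_toy()
  k <- get_constants()
  cfg <- ga_config(population_size = 40, generations = 30, seed = 9,
                   target_acid = "lactate", fitness_mode = "adapted")
  l1 <- run_evolution(m, cfg, constants = k)
  l2 <- run_evolution(m, cfg, constants = k)
  expect_identical(l1$best, l2$best)
  expect_identical(l1$records, l2$records)
  expect_identical(l1$population, l2$population)
  expect_false(is.unsorted(l1$best))

  # population invariants after the run
  pop <- l1$population
  expect_equal(nrow(pop$lb), 40)
  expect_true(all(pop$lb <= pop$ub + 1e-12))
  expect_true(all(t(pop$lb) >= m$reactions$lower_bound - 1e-12))
  expect_true(all(t(pop$ub) <= m$reactions$upper_bound + 1e-12))
  # wild-type genes persist in the gene pool
  wt_fraction <- mean(t(pop$lb) == m$reactions$lower_bound &
                      t(pop$ub) == m$reactions$upper_bound)
  expect_gt(wt_fraction, 0)

  # protected reactions never appear among recorded mutations
  prot <- match(detect_protected(m), m$reactions$id)
  for (r in l1$records)
    expect_false(any(r$mutations$reaction_index %in% prot))
})

test_that("evolution towards the wild-type acid still improves fitness", {
  m <- get_toy()
  k <- get_constants()
  cfg <- ga_config(generations = 200, seed = 1, target_acid = "citrate",
                   fitness_mode = "simple")
  log <- run_evolution(m, cfg, constants = k)
  expect_false(is.unsorted(log$best))
  expect_gt(max(log$best), log$best[1])
  # the improvement comes from tuning growth down, not from more acid flux
  fit <- evaluate_individual(m, log$best_individual, k, "citrate",
                             mode = "simple")
  wt <- evaluate_individual(m, NULL, k, "citrate", mode = "simple")
  expect_lt(fit$phase2$mu2, wt$phase2$mu2)
})

test_that("evolution logs export and read back", {
  log <- get_lactate_log()
  f_trace <- tempfile(fileext = ".csv")
  f_rec <- tempfile(fileext = ".jsonl")
  write_evolution_log(log, f_trace, f_rec)
  tr <- utils::read.csv(f_trace)
  expect_equal(tr$best_fitness, log$best)
  back <- read_evolution_log(f_rec, get_toy())
  expect_equal(length(back$records), length(log$records))
  expect_equal(back$seed, log$seed)
  i <- length(log$records)
  expect_equal(back$records[[i]]$mutations$mutant_bound,
               log$records[[i]]$mutations$mutant_bound)
})
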