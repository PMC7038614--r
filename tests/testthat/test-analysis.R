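# hand-built solution object for a model, from a data frame of mutations
make_solution <- function(model, mutations, fitness = 1, target = "EX_lac") {
  structure(list(mutations = mutations, fitness = fitness, generation = 1L,
                 complementation = NULL, reactions = model$reactions$id,
                 original_bounds = list(lb = model$reactions$lower_bound,
                                        ub = model$reactions$upper_bound),
                 target = target),
            class = "oae_solution")
}

mut_row <- function(model, id, side, bound) {
  j <- match(id, model$reactions$id)
  data.frame(reaction_index = j, side = side, mutant_bound = bound,
             wildtype_bound = if (side == "LC") model$reactions$lower_bound[j]
                              else model$reactions$upper_bound[j],
             stringsAsFactors = FALSE)
}

test_that("solution extraction applies a strict 95% threshold and dedupes", {
  m <- get_toy()
  mk <- function(fit, bound) list(generation = 1L, fitness = fit, p2 = 1,
    mutations = mut_row(m, "NADHOX", "UC", bound))
  base <- list(records = list(mk(1.0, 0.1)), reactions = m$reactions$id,
               original_bounds = list(lb = m$reactions$lower_bound,
                                      ub = m$reactions$upper_bound),
               target = "EX_lac")
  class(base) <- "evolution_log"
  sols <- extract_solutions(base)
  expect_length(sols, 1)
  expect_equal(sols[[1]]$fitness, 1.0)

  # an individual at exactly 95% of the maximum is excluded
  base$records <- list(mk(1.0, 0.1), mk(0.95, 0.2), mk(0.96, 0.3))
  expect_length(extract_solutions(base), 2)
  # identical mutation sets collapse, keeping the highest fitness
  base$records <- list(mk(1.0, 0.1), mk(0.99, 0.1), mk(0.97, 0.2))
  sols <- extract_solutions(base)
  expect_length(sols, 2)
  expect_equal(max(vapply(sols, `[[`, 0, "fitness")), 1.0)

  base$records <- list()
  expect_error(extract_solutions(base), "no recorded")
})

test_that("complementing a no-op mutation changes nothing", {
  m <- get_toy()
  ev <- fitness_evaluator(m, get_constants(), "citrate", mode = "simple")
  s <- make_solution(m, mut_row(m, "NADHOX", "UC", 1000), target = "EX_cit")
  cc <- complement_mutation(s, 1, ev)
  expect_equal(cc$pct_fitness_decrease, 0, tolerance = 1e-9)
  expect_equal(cc$pct_acid_flux_decrease, 0, tolerance = 1e-9)
  expect_equal(cc$pct_growth_increase, 0, tolerance = 1e-9)
})

test_that("pruning discards silent mutations and keeps essential ones", {
  m <- get_toy()
  k <- get_constants()
  ev <- fitness_evaluator(m, k, "lactate", mode = "adapted")
  # a constructed lactate producer: NADH oxidase and fumarate reductase
  # blocked (essential), plus a phenotypically silent decarboxylase cap
  muts <- rbind(mut_row(m, "NADHOX", "UC", 0),
                mut_row(m, "FRD", "UC", 0),
                mut_row(m, "PDC", "UC", 900))
  s <- make_solution(m, muts)
  s <- prune_solution(s, ev)
  kept <- s$reactions[s$mutations$reaction_index]
  expect_true("NADHOX" %in% kept)
  expect_false("PDC" %in% kept)
  expect_gt(s$fitness, 0)

  # pruning is idempotent
  s2 <- prune_solution(s, ev)
  expect_equal(s2$mutations[names(s$mutations)], s$mutations)

  # complementing the NADH-recycling block abolishes the lactate flux
  i <- which(kept == "NADHOX")
  cc <- s$complementation[i, ]
  expect_gte(cc$pct_acid_flux_decrease, 95)
  expect_gt(cc$pct_fitness_decrease, 50)

  # complementing everything at once reproduces the wild type
  wtF <- ev(NULL)$F
  allrev <- ev(acidevolve:::solution_individual(s, integer(0)))$F
  expect_equal(allrev, wtF, tolerance = 1e-9)
})

test_that("frequencies count solutions containing each reaction", {
  m <- get_toy()
  jN <- match("NADHOX", m$reactions$id)
  sols <- c(
    lapply(1:7, function(i) make_solution(m, rbind(
      mut_row(m, "NADHOX", "UC", 0.1 * i),
      mut_row(m, "FRD", "UC", 0)))),
    lapply(1:3, function(i) make_solution(m, mut_row(m, "QH2OX", "UC", 0))))
  fr <- mutation_frequencies(sols, cutoff = 0.2)
  expect_equal(fr$frequency[fr$reaction_index == jN], 0.7)
  expect_equal(sum(fr$count), 7 + 7 + 3)
  expect_true(all(fr$frequency >= 0 & fr$frequency <= 1))

  # invariant under reordering of the solution list
  fr2 <- mutation_frequencies(rev(sols), cutoff = 0.2)
  expect_equal(fr2, fr)

  # entries under the cut-off are retained in the table but dropped from
  # the plot export
  sols2 <- c(sols, lapply(1:90, function(i)
    make_solution(m, mut_row(m, "NADHOX", "UC", 0.001 * i))))
  fr3 <- mutation_frequencies(sols2, cutoff = 0.2)
  jQ <- match("QH2OX", m$reactions$id)
  expect_lt(fr3$frequency[fr3$reaction_index == jQ], 0.2)
  f <- tempfile(fileext = ".json")
  write_frequency_json(fr3, sols2, f)
  js <- jsonlite::fromJSON(f)
  expect_false(jQ %in% js$points$index)
  expect_true(jN %in% js$points$index)
})

test_that("the representative solution maximises frequency overlap", {
  m <- get_toy()
  common <- lapply(1:5, function(i) make_solution(m, rbind(
    mut_row(m, "NADHOX", "UC", 0.01 * i), mut_row(m, "FRD", "UC", 0)),
    fitness = 1))
  rare <- make_solution(m, mut_row(m, "MDH", "LC", 0), fitness = 1.01)
  sols <- c(common, list(rare))
  rep_sol <- representative_solution(sols)
  expect_true("NADHOX" %in% rep_sol$reactions[rep_sol$mutations$reaction_index])
  # the returned solution is always in the near-maximal set
  expect_gt(rep_sol$fitness, 0.95 * max(vapply(sols, `[[`, 0, "fitness")))
  expect_identical(representative_solution(list(rare))$mutations, rare$mutations)
})

test_that("an evolved run flows through the full analysis pipeline", {
  m <- get_toy()
  log <- get_lactate_log()
  ev <- fitness_evaluator(m, get_constants(), "lactate", mode = "adapted")
  sols <- extract_solutions(log)
  expect_gte(length(sols), 1)
  pruned <- lapply(sols[seq_len(min(5, length(sols)))], prune_solution,
                   evaluator = ev)
  pruned <- Filter(function(s) nrow(s$mutations) > 0, pruned)
  expect_gte(length(pruned), 1)
  fr <- mutation_frequencies(pruned)
  rs <- representative_solution(pruned, fr)
  expect_gt(rs$fitness, 0.95 * max(vapply(pruned, `[[`, 0, "fitness")))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".json")
  write_complementation_csv(rs, f1)
  write_solution_json(rs, f2)
  tab <- utils::read.csv(f1)
  expect_true(all(c("index", "reaction", "mutation_effect",
                    "pct_fitness_decrease") %in% names(tab)))
  js <- jsonlite::fromJSON(f2)
  expect_equal(js$fitness, rs$fitness, tolerance = 1e-9)
})
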