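#' Closed-form estimators behind the productivity fitness function
#'
#' Fitness is the estimated volumetric productivity of the target acid at the
#' moment of substrate depletion, computed from a single phase-2 FBA snapshot
#' plus the phase-1 constants: the acid yield is `c(t_f) = p2 * S_c / f2`
#' (all substrate consumed after the switch at the phase-2 acid/substrate
#' flux ratio), the proton yield analogously `h(t_f) = h * S_c / f2`, and the
#' substrate-depletion time follows from integrating exponential (or
#' non-growing) phase-2 biomass. The simple fitness is `c(t_f) / t_f`; the
#' adapted fitness, used for acids the wild type does not produce, is
#' `(h(t_f) + weight * c(t_f)) / t_f` so that proton production alone gives a
#' nonzero starting fitness while target-acid production dominates once it
#' appears.
#'
#' @param p2 target-acid output flux in phase 2, mmol gDW^-1 h^-1.
#' @param f2 substrate uptake flux magnitude in phase 2, mmol gDW^-1 h^-1.
#' @param S_c substrate concentration at the phase switch, mmol/L.
#' @return `estimate_yield`: the estimated acid yield, mmol/L.
#' @name fitness-estimators
NULL

#' @rdname fitness-estimators
#' @export
estimate_yield <- function(p2, f2, S_c) {
  if (f2 <= 0) return(0)
  p2 * S_c / f2
}

#' @rdname fitness-estimators
#' @param h proton output flux in phase 2, mmol gDW^-1 h^-1.
#' @export
estimate_proton_yield <- function(h, f2, S_c) {
  if (f2 <= 0) return(0)
  h * S_c / f2
}

#' @rdname fitness-estimators
#' @param t_c phase-switch time, h.
#' @param mu2 phase-2 specific growth rate, h^-1 (values below `1e-10` are
#'   treated as zero growth).
#' @param A_c biomass at the phase switch, g/L.
#' @return `estimate_tf`: the estimated substrate-depletion time, h
#'   (`Inf` when no substrate is consumed in phase 2).
#' @export
estimate_tf <- function(t_c, S_c, mu2, f2, A_c) {
  if (f2 <= 0 || A_c <= 0) return(Inf)
  if (mu2 > 1e-10)
    t_c + log(max(1, 1 + S_c * mu2 / (f2 * A_c))) / mu2
  else
    t_c + S_c / (f2 * A_c)
}

#' @rdname fitness-estimators
#' @param c_tf estimated target-acid yield, mmol/L.
#' @param t_f estimated substrate-depletion time, h.
#' @export
fitness_simple <- function(c_tf, t_f) {
  if (!is.finite(t_f) || t_f <= 0) return(0)
  c_tf / t_f
}

#' @rdname fitness-estimators
#' @param h_tf estimated proton yield, mmol/L.
#' @param weight weight on target-acid yield relative to proton yield.
#' @export
fitness_adapted <- function(h_tf, c_tf, t_f, weight = 10) {
  if (!is.finite(t_f) || t_f <= 0) return(0)
  (h_tf + weight * c_tf) / t_f
}

#' Evaluate the fitness of an individual
#'
#' Runs one lexicographic phase-2 FBA (growth under the phosphate-release
#' cap, then proton production, then parsimonious fluxes) with the
#' individual's bounds active, reads the phase-2 fluxes (`mu2`, `f2`, `p2`,
#' `h`) and assembles the fitness from the closed-form estimators and the
#' precomputed phase-1 constants. An infeasible FBA yields fitness 0, never
#' an error: forcing mutations can render the flux polytope empty and the
#' evolutionary loop must absorb that.
#'
#' @param model a [metabolic_model].
#' @param individual an individual genome, or `NULL` for wild type.
#' @param constants phase-1 [fitness constants][extract_constants].
#' @param target_acid acid name or exchange reaction id of the target.
#' @param mode `"simple"` (acid productivity) or `"adapted"` (weighted
#'   proton + acid productivity).
#' @param weight target-acid weight for the adapted mode.
#' @param phase2 optional phase-2 configuration from [configure_phase];
#'   computed from the model's attached parameterisation when `NULL`.
#' @return Object of class `fitness_result`: `F` (fitness), `t_f`, `c_tf`,
#'   `h_tf`, the `phase2` flux summary, the full parsimonious `fluxes`
#'   vector and `status`.
#' @export
evaluate_individual <- function(model, individual = NULL, constants,
                                target_acid, mode = c("simple", "adapted"),
                                weight = 10, phase2 = NULL) {
  mode <- match.arg(mode)
  ex_id <- acid_exchange_id(model, target_acid)
  if (is.null(phase2)) phase2 <- configure_phase(model, "proton_production")
  cfg <- overlay_individual(model, phase2, individual)
  sol <- phase2_fba(model, cfg)
  if (sol$status != "optimal") {
    return(structure(list(F = 0, t_f = NA_real_, c_tf = 0, h_tf = 0,
                          phase2 = NULL, fluxes = NULL, status = "infeasible",
                          mode = mode, target = ex_id),
                     class = "fitness_result"))
  }
  v <- sol$fluxes
  mu2 <- max(v[rxn_index(model, cfg$growth)], 0)
  f2 <- abs(v[rxn_index(model, cfg$params$substrate)])
  p2 <- max(v[rxn_index(model, ex_id)], 0)
  h <- max(v[rxn_index(model, cfg$params$proton)], 0)
  c_tf <- estimate_yield(p2, f2, constants$S_c)
  h_tf <- estimate_proton_yield(h, f2, constants$S_c)
  t_f <- estimate_tf(constants$t_c, constants$S_c, mu2, f2, constants$A_c)
  FF <- if (mode == "simple") fitness_simple(c_tf, t_f)
        else fitness_adapted(h_tf, c_tf, t_f, weight)
  structure(list(F = as.numeric(FF), t_f = as.numeric(t_f),
                 c_tf = as.numeric(c_tf), h_tf = as.numeric(h_tf),
                 phase2 = list(mu2 = as.numeric(mu2), f2 = as.numeric(f2),
                               p2 = as.numeric(p2), h = as.numeric(h)),
                 fluxes = v, status = "ok", mode = mode, target = ex_id),
            class = "fitness_result")
}

#' @export
print.fitness_result <- function(x, ...) {
  cat("fitness (", x$mode, ", target ", x$target, "): ",
      format(x$F, digits = 6), " [", x$status, "]\n", sep = "")
  if (x$status == "ok")
    cat("  c(t_f) =", format(x$c_tf, digits = 5), "mmol/L,  t_f =",
        format(x$t_f, digits = 5), "h,  mu2 =",
        format(x$phase2$mu2, digits = 4), "h^-1\n")
  invisible(x)
}

#' Build a reusable fitness evaluator
#'
#' Binds a model, phase-1 constants and a target to a closure that evaluates
#' individuals (or mutation sets applied to the wild type). Used by the
#' genetic algorithm and by the complementation analysis, which must
#' re-evaluate fitness under the exact conditions of the run.
#'
#' @inheritParams evaluate_individual
#' @return A function `f(individual)` returning a `fitness_result`.
#' @export
fitness_evaluator <- function(model, constants, target_acid,
                              mode = c("simple", "adapted"), weight = 10) {
  mode <- match.arg(mode)
  phase2 <- configure_phase(model, "proton_production")
  force(constants); force(weight)
  function(individual = NULL)
    evaluate_individual(model, individual, constants, target_acid,
                        mode = mode, weight = weight, phase2 = phase2)
}

#' Serialise a fitness result to JSON
#'
#' @param result a `fitness_result`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @export
fitness_to_json <- function(result, path = NULL) {
  obj <- result[c("F", "t_f", "c_tf", "h_tf", "phase2", "status", "mode",
                  "target")]
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
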