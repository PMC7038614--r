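#' Fraction of acid groups dissociated at a given pH
#'
#' Henderson-Hasselbalch dissociation fraction `1 / (1 + 10^(pKa - pH))` for
#' each dissociation step. The toy-network generator sums the step fractions
#' of an acid to obtain the protons released per exported molecule; models
#' read from file carry their own dissociation stoichiometry.
#'
#' @param pka acid dissociation constant(s), vectorised.
#' @param ph broth pH.
#' @return Fraction(s) in `[0, 1]`.
#' @export
dissociation_fraction <- function(pka, ph) 1 / (1 + 10^(pka - ph))

#' Configure a model for one growth phase
#'
#' Batch fermentation proceeds in two phases. During *phosphate storage*
#' external phosphate is available, biomass growth is the objective and a
#' fixed specific flux stores phosphate internally (polyphosphate). During
#' *proton production* external phosphate is exhausted and closed, growth is
#' limited by the capped release of stored phosphate, and proton export is
#' the objective. The maintenance ATP demand applies in both phases.
#'
#' @param model a [metabolic_model].
#' @param phase `"phosphate_storage"` or `"proton_production"`.
#' @param params phase parameterisation; defaults to
#'   `attr(model, "phases")[[phase]]`. A parameterisation is a list with the
#'   reaction roles `objective`, `growth`, `substrate`, `phosphate`,
#'   `storage`, `proton` and a named list `bounds` of `c(lb, ub)` pairs
#'   applied on top of the model bounds.
#' @return List with numeric vectors `lb`, `ub`, the `objective` id, the
#'   `growth` reaction id and the resolved `params`.
#' @export
configure_phase <- function(model,
                            phase = c("phosphate_storage", "proton_production"),
                            params = NULL) {
  phase <- match.arg(phase)
  if (is.null(params)) params <- attr(model, "phases")[[phase]]
  if (is.null(params))
    stop("no phase parameterisation supplied and none attached to the model")
  need <- unlist(params[c("objective", "growth", "substrate", "phosphate",
                          "storage", "proton")], use.names = FALSE)
  missing <- setdiff(c(need, names(params$bounds)), model$reactions$id)
  if (length(missing))
    stop("phase parameterisation names reaction(s) absent from the model: ",
         paste(unique(missing), collapse = ", "))
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  for (id in names(params$bounds)) {
    j <- rxn_index(model, id)
    lb[j] <- params$bounds[[id]][1]
    ub[j] <- params$bounds[[id]][2]
  }
  list(lb = lb, ub = ub, objective = params$objective,
       growth = params$growth, phase = phase, params = params)
}

# overlay an individual's (clipped) genome on a phase configuration;
# phase-controlled reactions keep their phase bounds
overlay_individual <- function(model, cfg, individual) {
  if (is.null(individual)) return(cfg)
  ab <- apply_individual(model, individual)
  controlled <- rxn_index(model, names(cfg$params$bounds))
  nb <- cfg
  nb$lb <- ab$lb; nb$ub <- ab$ub
  nb$lb[controlled] <- cfg$lb[controlled]
  nb$ub[controlled] <- cfg$ub[controlled]
  nb
}

# lexicographic phase-2 evaluation at given bounds: maximise growth under the
# phosphate-release cap, then maximise proton export, then parsimonious fluxes
phase2_fba <- function(model, cfg, pfba = TRUE) {
  r <- .lp_phase2(model$S, cfg$lb, cfg$ub,
                  rxn_index(model, cfg$growth),
                  rxn_index(model, cfg$objective), pfba)
  if (r$status != 0) return(list(status = "infeasible"))
  list(status = "optimal",
       fluxes = stats::setNames(as.numeric(r$fluxes), model$reactions$id),
       mu = r$mu, objective_value = r$objective)
}

#' Batch-fermentation initial conditions and integrator settings
#'
#' @param model a [metabolic_model]; defaults are taken from
#'   `attr(model, "batch")` where present.
#' @param A0 initial biomass, g/L.
#' @param S0 initial substrate (glucose), mmol/L.
#' @param P0 initial external phosphate, mmol/L.
#' @param dt Euler step, h.
#' @param t_max simulation horizon, h.
#' @param ph broth pH (held fixed for flux calculations; the trajectory also
#'   reports the pH implied by cumulative proton export).
#' @return List of batch parameters.
#' @export
batch_params <- function(model = NULL, A0 = NULL, S0 = NULL, P0 = NULL,
                         dt = NULL, t_max = NULL, ph = NULL) {
  def <- if (!is.null(model)) attr(model, "batch") else NULL
  pick <- function(x, d, fallback) if (!is.null(x)) x else if (!is.null(d)) d else fallback
  p <- list(A0 = pick(A0, def$A0, 0.05), S0 = pick(S0, def$S0, 100),
            P0 = pick(P0, def$P0, 0.09), dt = pick(dt, def$dt, 0.01),
            t_max = pick(t_max, def$t_max, 2000), ph = pick(ph, def$ph, 2))
  if (p$A0 <= 0 || p$S0 <= 0 || p$P0 < 0 || p$dt <= 0)
    stop("batch parameters require A0, S0, dt > 0 and P0 >= 0")
  p
}

#' Simulate a dynamic batch fermentation (dFBA)
#'
#' Explicit time-stepped dynamic FBA over the two growth phases. At each step
#' the phase FBA is solved (growth objective during phosphate storage;
#' lexicographic growth-then-proton objective during proton production) and
#' biomass, substrate, phosphate, acids and protons are updated by
#' `rate * biomass * dt`. The phase switch is located exactly within the step
#' in which external phosphate depletes, and the run ends when substrate
#' depletes (within step tolerance), the horizon is reached, or the FBA turns
#' infeasible. Mutant flux bounds are applied only from the phase switch
#' onward (`activation = "at_switch"`): mutations are modelled as induced at
#' the point of phosphate depletion, with wild-type behaviour during growth
#' phase 1.
#'
#' @param model a [metabolic_model].
#' @param params batch parameters from [batch_params()].
#' @param individual optional individual genome (mutant flux bounds).
#' @param activation `"at_switch"` (wild type during phase 1) or
#'   `"immediate"` (mutant bounds in both phases).
#' @param stop_after_switch stop shortly after the phase switch (used when
#'   only the phase-1 constants are needed).
#' @return An object of class `fermentation_trajectory` with the recorded
#'   states, the phase-switch time `t_c`, the substrate-depletion time `t_f`,
#'   termination `status`, and the phase flux vectors.
#' @export
simulate_batch <- function(model, params = batch_params(model),
                           individual = NULL,
                           activation = c("at_switch", "immediate"),
                           stop_after_switch = FALSE) {
  activation <- match.arg(activation)
  cfg1 <- configure_phase(model, "phosphate_storage")
  cfg2 <- configure_phase(model, "proton_production")
  if (!is.null(individual)) {
    cfg2 <- overlay_individual(model, cfg2, individual)
    if (activation == "immediate")
      cfg1 <- overlay_individual(model, cfg1, individual)
  }
  rid <- model$reactions$id
  i_sub <- rxn_index(model, cfg2$params$substrate)
  i_pi <- rxn_index(model, cfg2$params$phosphate)
  i_sto <- rxn_index(model, cfg2$params$storage)
  i_h <- rxn_index(model, cfg2$params$proton)
  i_gro <- rxn_index(model, cfg2$growth)
  i_ex <- grep("^EX_", rid)
  acid_ex <- setdiff(rid[i_ex],
                     c(rid[c(i_sub, i_pi, i_h)], "EX_o2", "EX_co2"))
  i_acids <- rxn_index(model, acid_ex)
  i_co2 <- match("EX_co2", rid)   # NA when the model has no CO2 exchange

  dt <- params$dt
  t <- 0; A <- params$A0; S <- params$S0; P <- params$P0
  stored <- 0; protons <- 0; co2 <- 0
  acids <- stats::setNames(numeric(length(acid_ex)), acid_ex)
  h0 <- 10^(-params$ph) * 1000   # mmol/L free protons at initial pH
  phase <- 1L; t_c <- NA_real_; t_f <- NA_real_
  status <- "t_max"
  phase1_fluxes <- NULL; phase2_fluxes <- NULL

  nmax <- ceiling(params$t_max / dt) + 3L
  rec <- matrix(NA_real_, nmax, 10 + length(acid_ex))
  colnames(rec) <- c("t", "phase", "A", "S", "P", "stored_P", "protons",
                     "co2", "pH", "mu", acid_ex)
  nrec <- 0L
  push <- function(mu) {
    nrec <<- nrec + 1L
    rec[nrec, ] <<- c(t, phase, A, S, P, stored, protons, co2,
                      -log10((h0 + protons) / 1000), mu, acids)
  }
  push(NA_real_)

  memo_key <- NULL; memo_flux <- NULL
  steps <- 0L
  while (t < params$t_max - 1e-12) {
    cfg <- if (phase == 1L) cfg1 else cfg2
    lb <- cfg$lb; ub <- cfg$ub
    # availability caps on uptakes (finite pools)
    lb[i_sub] <- max(lb[i_sub], -S / (A * dt))
    if (phase == 1L) lb[i_pi] <- max(lb[i_pi], -P / (A * dt))
    key <- c(phase, lb, ub)
    if (!is.null(memo_key) && identical(key, memo_key)) {
      v <- memo_flux
    } else {
      sol <- if (phase == 1L) {
        r <- .lp_fba(model$S, as.numeric(seq_along(rid) == i_gro),
                     lb, ub, TRUE, TRUE)
        if (r$status != 0) list(status = "infeasible")
        else list(status = "optimal",
                  fluxes = stats::setNames(as.numeric(r$fluxes), rid))
      } else phase2_fba(model, list(lb = lb, ub = ub, growth = cfg$growth,
                                    objective = cfg$objective,
                                    params = cfg$params))
      if (sol$status != "optimal") {
        if (phase == 1L) {     # cannot sustain phase 1 (phosphate exhausted)
          phase <- 2L; t_c <- t; P <- 0
          if (nrec > 0L) rec[nrec, "P"] <- 0
          memo_key <- NULL
          if (is.null(phase1_fluxes)) phase1_fluxes <- memo_flux
          if (stop_after_switch) { status <- "switched"; break }
          next
        }
        # a mutant unable to run on the last substrate crumbs has, for all
        # practical purposes, depleted the batch
        if (S < 1e-3 * params$S0) {
          t_f <- t; status <- "substrate_depleted"
        } else status <- "infeasible"
        break
      }
      v <- sol$fluxes
      memo_key <- key; memo_flux <- v
      if (phase == 1L) phase1_fluxes <- v else
        if (is.null(phase2_fluxes)) phase2_fluxes <- v
    }

    mu <- unname(v[i_gro])
    dS <- unname(v[i_sub]) * A          # per hour
    dP <- if (phase == 1L) unname(v[i_pi]) * A else 0
    frac <- 1
    event <- NULL
    if (phase == 1L && dP < 0 && P + dP * dt < 0) {
      frac <- P / (-dP * dt); event <- "switch"
    }
    if (dS < 0 && S + dS * dt * frac < 1e-9) {
      f2 <- (S - 1e-12) / (-dS * dt)
      if (f2 < frac) { frac <- f2; event <- "substrate" }
    }
    h <- dt * frac
    A_new <- A + mu * A * h
    S <- max(S + dS * h, 0)
    P <- max(P + dP * h, 0)
    stored <- stored + v[i_sto] * A * h
    protons <- protons + max(v[i_h], 0) * A * h
    if (!is.na(i_co2)) co2 <- co2 + v[i_co2] * A * h
    acids <- acids + pmax(v[i_acids], 0) * A * h
    A <- A_new
    t <- t + h
    push(mu)
    steps <- steps + 1L
    if (!is.null(event) && event == "switch") {
      phase <- 2L; t_c <- t; P <- 0
      memo_key <- NULL
      if (stop_after_switch) { status <- "switched"; break }
    } else if (!is.null(event) && event == "substrate") {
      t_f <- t; status <- "substrate_depleted"; break
    }
  }
  if (is.na(t_f) && status == "substrate_depleted") t_f <- t

  structure(list(data = as.data.frame(rec[seq_len(nrec), , drop = FALSE]),
                 t_c = t_c, t_f = t_f, status = status,
                 acid_exchanges = acid_ex,
                 phase1_fluxes = phase1_fluxes, phase2_fluxes = phase2_fluxes,
                 params = params, model_id = model$id),
            class = "fermentation_trajectory")
}

#' @export
print.fermentation_trajectory <- function(x, ...) {
  cat("Batch fermentation trajectory (", x$model_id, ")\n", sep = "")
  cat("  status:", x$status, "\n")
  cat("  phase switch t_c:", format(x$t_c, digits = 5), "h\n")
  cat("  substrate depletion t_f:", format(x$t_f, digits = 5), "h\n")
  d <- x$data
  last <- d[nrow(d), ]
  cat("  final biomass:", format(last$A, digits = 4), "g/L\n")
  for (a in x$acid_exchanges)
    if (last[[a]] > 1e-6)
      cat("  ", a, ": ", format(last[[a]], digits = 5), " mmol/L\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.fermentation_trajectory <- function(x, ...) x$data

#' @export
plot.fermentation_trajectory <- function(x, ...) {
  d <- x$data
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(d$t, d$A, type = "l", xlab = "time (h)",
                 ylab = "biomass (g/L)", main = "biomass")
  graphics::plot(d$t, d$P, type = "l", xlab = "time (h)",
                 ylab = "external phosphate (mmol/L)", main = "phosphate")
  graphics::plot(d$t, d$S, type = "l", xlab = "time (h)",
                 ylab = "glucose (mmol/L)", main = "substrate")
  acid <- x$acid_exchanges
  ymax <- max(unlist(d[acid]), 1e-9)
  graphics::plot(range(d$t), c(0, ymax), type = "n", xlab = "time (h)",
                 ylab = "acid (mmol/L)", main = "organic acids")
  for (k in seq_along(acid))
    graphics::lines(d$t, d[[acid[k]]], col = k)
  graphics::legend("topleft", legend = acid, col = seq_along(acid),
                   lty = 1, bty = "n", cex = 0.8)
  if (!is.na(x$t_c)) graphics::abline(v = x$t_c, lty = 3)
  invisible(x)
}

#' Export a trajectory as tidy CSV
#'
#' @param trajectory a `fermentation_trajectory`.
#' @param path output file.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(trajectory$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract the phase-1 fitness constants from a trajectory
#'
#' With wild-type bounds in growth phase 1, the phase-switch time and the
#' biomass and substrate levels at the switch are constants of the system;
#' they are determined once from a wild-type dFBA simulation and reused by
#' every fitness evaluation.
#'
#' @param trajectory a `fermentation_trajectory` that reached phase 2.
#' @return Object of class `fitness_constants` with `t_c` (h), `A_c` (g/L)
#'   and `S_c` (mmol/L).
#' @export
extract_constants <- function(trajectory) {
  if (is.na(trajectory$t_c))
    stop("trajectory never reached the proton-production phase; ",
         "cannot extract constants")
  d <- trajectory$data
  i <- max(which(d$t <= trajectory$t_c + 1e-12))
  structure(list(t_c = trajectory$t_c, A_c = d$A[i], S_c = d$S[i]),
            class = "fitness_constants")
}

#' @export
print.fitness_constants <- function(x, ...) {
  cat("phase-1 constants: t_c =", format(x$t_c, digits = 6),
      "h, A_c =", format(x$A_c, digits = 6),
      "g/L, S_c =", format(x$S_c, digits = 6), "mmol/L\n")
  invisible(x)
}
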