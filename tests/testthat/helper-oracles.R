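# Shared fixtures and independent oracles used across the test files.

# brute-force LP oracle: enumerate all basic solutions of
# max c'x s.t. A x = b, lb <= x <= ub (networks up to ~12 variables)
enum_lp_oracle <- function(A, b, cc, lb, ub) {
  m <- nrow(A); n <- ncol(A); best <- -Inf
  for (bas in utils::combn(n, m, simplify = FALSE)) {
    B <- A[, bas, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    nb <- setdiff(seq_len(n), bas); k <- length(nb)
    for (mask in 0:(2^k - 1)) {
      xn <- ifelse(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0, ub[nb], lb[nb])
      xb <- solve(B, b - A[, nb, drop = FALSE] %*% xn)
      if (any(xb < lb[bas] - 1e-8) || any(xb > ub[bas] + 1e-8)) next
      x <- numeric(n); x[bas] <- xb; x[nb] <- xn
      best <- max(best, sum(cc * x))
    }
  }
  best
}

# minimal linear pathway model: e_in -> A -> B -> e_out
chain_model <- function(cap_in = 10) {
  mets <- data.frame(id = c("Ae", "A", "B", "Be"), name = c("Ae", "A", "B", "Be"),
                     compartment = c("e", "c", "c", "e"))
  rxns <- data.frame(
    id = c("EX_in", "T_in", "R1", "T_out", "EX_out"),
    name = c("inflow", "uptake", "conversion", "secretion", "outflow"),
    lower_bound = c(-cap_in, 0, 0, 0, 0),
    upper_bound = c(0, 1000, 1000, 1000, 1000),
    category = c("exchange", "transport", "internal", "transport", "exchange"),
    gene_association = c("", "", "gA", "", ""))
  S <- matrix(0, 4, 5, dimnames = list(mets$id, rxns$id))
  S["Ae", "EX_in"] <- -1
  S["Ae", "T_in"] <- -1; S["A", "T_in"] <- 1
  S["A", "R1"] <- -1; S["B", "R1"] <- 1
  S["B", "T_out"] <- -1; S["Be", "T_out"] <- 1
  S["Be", "EX_out"] <- -1
  metabolic_model(mets, rxns, S, objective = "EX_out", id = "chain")
}

# toy model + wild-type constants, built once per test session
.toy_env <- new.env(parent = emptyenv())
get_toy <- function() {
  if (is.null(.toy_env$model)) .toy_env$model <- build_toy_model()
  .toy_env$model
}
get_constants <- function() {
  if (is.null(.toy_env$constants)) {
    traj <- simulate_batch(get_toy(), stop_after_switch = TRUE)
    .toy_env$constants <- extract_constants(traj)
  }
  .toy_env$constants
}
# a short evolved lactate run shared by analysis / acceptance tests
get_lactate_log <- function() {
  if (is.null(.toy_env$lactate_log)) {
    cfg <- ga_config(generations = 600, seed = 2, target_acid = "lactate",
                     fitness_mode = "adapted")
    .toy_env$lactate_log <- run_evolution(get_toy(), cfg,
                                          constants = get_constants())
  }
  .toy_env$lactate_log
}

# carbon content bookkeeping for trajectory-level conservation checks
toy_carbon <- function(model) {
  stats::setNames(model$metabolites$carbon, model$metabolites$id)
}
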