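#' Single spin-flip transition matrix over alternative configurations
#'
#' Builds the row-stochastic transition matrix of the Metropolis single
#' spin-flip chain on the `2^m` configurations of the scenario's mutable
#' alternatives, with every cue (and any extra clamped node) held active.
#' From configuration `i`, each mutable node is proposed with probability
#' `1/m`; a proposal to configuration `j` is accepted with probability
#' `min(1, exp(H_i - H_j))`, and rejected proposals stay put (the
#' diagonal). Configurations in which exactly one alternative is active
#' and that alternative is available are the choice conditions; in the
#' returned matrix `P` they are absorbing (identity rows), while the
#' unconstrained Metropolis rows are kept in `P_free` for stationary
#' analysis and forced-first-step protocols.
#'
#' @param structure A [choice_structure()].
#' @param scenario A [choice_scenario()].
#' @return An object of class `transition_model`: `state_order`
#'   (configuration matrix), `P`, `P_free`, `absorbing_index`,
#'   `absorbed_alternative` (which available alternative each absorbing
#'   state selects), `mutable`, `available`.
#' @export
build_transition_matrix <- function(structure, scenario) {
  mutable <- scenario_mutable(structure, scenario)
  m <- length(mutable)
  if (m > 20L)
    stop("more than 20 alternatives: the dense transition matrix is not ",
         "practical; use the Monte-Carlo simulator", call. = FALSE)
  sub <- scenario_structure(structure, scenario)
  clamped <- intersect(scenario_clamped(structure, scenario), sub$nodes)
  support <- enumerate_configurations(m, mutable)
  n_states <- nrow(support)
  base <- numeric(length(sub$nodes)); names(base) <- sub$nodes
  base[clamped] <- 1
  energies <- apply(support, 1L, function(row) {
    x <- base; x[mutable] <- row
    hamiltonian(sub, x)
  })
  P_free <- matrix(0, n_states, n_states)
  for (i in seq_len(n_states)) {
    stay <- 1
    for (k in seq_len(m)) {
      j <- i + (1L - 2L * support[i, k]) * 2^(k - 1L)  # flip bit k
      acc <- min(1, exp(energies[i] - energies[j]))
      P_free[i, j] <- acc / m
      stay <- stay - acc / m
    }
    P_free[i, i] <- stay
  }
  is_avail <- as.numeric(mutable %in% scenario$available)
  absorbing_index <- which(rowSums(support) == 1 &
                             as.vector(support %*% is_avail) == 1)
  absorbed_alternative <- vapply(absorbing_index, function(i)
    mutable[which(support[i, ] == 1)], character(1))
  P <- P_free
  P[absorbing_index, ] <- 0
  P[cbind(absorbing_index, absorbing_index)] <- 1
  structure(
    list(state_order = support, P = P, P_free = P_free,
         energies = energies,
         absorbing_index = as.integer(absorbing_index),
         absorbed_alternative = absorbed_alternative,
         mutable = mutable, available = scenario$available),
    class = "transition_model"
  )
}

#' Canonical absorbing-chain form
#'
#' Permutes the states of a [build_transition_matrix()] model into
#' (transient, absorbing) blocks, returning the transient-to-transient
#' block `Q`, the transient-to-absorbing block `R`, and the permutation.
#' With a single alternative there are no transient single-flip paths of
#' interest and `Q`, `R` may be degenerate (zero rows/columns).
#'
#' @param model A `transition_model`.
#' @return An object of class `canonical_chain` with elements `Q`, `R`,
#'   `permutation` (state order `c(transient, absorbing)`),
#'   `transient_index`, `absorbing_index`, `absorbed_alternative`,
#'   `available`, `state_order`.
#' @export
to_canonical_form <- function(model) {
  if (length(model$absorbing_index) == 0L)
    stop("no absorbing states: no available alternative can be chosen",
         call. = FALSE)
  n_states <- nrow(model$P)
  transient_index <- setdiff(seq_len(n_states), model$absorbing_index)
  Q <- model$P[transient_index, transient_index, drop = FALSE]
  R <- model$P[transient_index, model$absorbing_index, drop = FALSE]
  colnames(R) <- model$absorbed_alternative
  structure(
    list(Q = Q, R = R,
         permutation = c(transient_index, model$absorbing_index),
         transient_index = transient_index,
         absorbing_index = model$absorbing_index,
         absorbed_alternative = model$absorbed_alternative,
         available = model$available,
         state_order = model$state_order),
    class = "canonical_chain"
  )
}

# Aggregate per-absorbing-state quantities to per-alternative quantities
# (several absorbing states can select the same alternative only when an
# alternative id appears once, so this is a straight relabelling; kept
# general via rowsum).
absorbing_to_alternative <- function(values, absorbed_alternative, available) {
  out <- rowsum(as.numeric(values),
                factor(absorbed_alternative, levels = available))
  v <- as.vector(out)
  names(v) <- available
  v
}

# Left-multiply by (I - Q)^{-1} via LU solve, with a condition estimate.
solve_transient <- function(Q, rhs) {
  if (nrow(Q) == 0L)
    return(list(value = matrix(0, 0L, ncol(rhs)), rcond = 1))
  ImQ <- diag(nrow(Q)) - Q
  est <- tryCatch(rcond(ImQ), error = function(e) 0)
  value <- tryCatch(solve(ImQ, rhs), error = function(e)
    stop("(I - Q) is singular: some transient state cannot reach an ",
         "absorbing state", call. = FALSE))
  list(value = value, rcond = est)
}

#' First-passage choice probabilities
#'
#' Probability that each available alternative is the first whose choice
#' condition is met: `p(y) = z_a 1_y + z_t (I - Q)^{-1} R_y`, where `z` is
#' the start distribution split into absorbing (`z_a`) and transient
#' (`z_t`) mass. The linear system is solved by LU factorisation, never by
#' explicit inversion; a reciprocal condition estimate below `1e-12` sets
#' the `condition_warning` attribute.
#'
#' @param chain A [to_canonical_form()] chain.
#' @param start A `state_distribution` aligned to the chain's state order
#'   (e.g. from [resting_alternative_distribution()]), or a bare
#'   probability vector over the `2^m` states.
#' @return Named probability vector over the available alternatives, with
#'   attribute `condition_warning` (logical).
#' @export
first_passage_probabilities <- function(chain, start) {
  z <- if (inherits(start, "state_distribution")) start$probs else
    as.numeric(start)
  if (length(z) != nrow(chain$state_order))
    stop_dimension("start distribution does not match the chain state space")
  z_a <- z[chain$absorbing_index]
  z_t <- z[chain$transient_index]
  sol <- solve_transient(chain$Q, chain$R)
  p_states <- z_a + as.vector(z_t %*% sol$value)
  p <- absorbing_to_alternative(p_states, chain$absorbed_alternative,
                                chain$available)
  attr(p, "condition_warning") <- sol$rcond < 1e-12
  p
}

#' Expected number of Metropolis iterations per choice
#'
#' Conditional expected number of single spin-flip iterations (proposals,
#' counting rejected ones) before each alternative is chosen:
#' `E(t | y) = z_t (I - Q)^{-2} R_y / p(y)`, computed with two nested
#' linear solves. Alternatives whose choice probability is essentially
#' zero (below `1e-300`) are reported as `NA` rather than divided by.
#'
#' @param chain A [to_canonical_form()] chain.
#' @param start Start distribution as in [first_passage_probabilities()].
#' @param probabilities The output of [first_passage_probabilities()] on
#'   the same chain and start.
#' @return Named vector of conditional expectations, with attribute
#'   `overall` giving `sum_y p(y) E(t|y)`.
#' @export
expected_iterations <- function(chain, start, probabilities) {
  z <- if (inherits(start, "state_distribution")) start$probs else
    as.numeric(start)
  z_t <- z[chain$transient_index]
  sol1 <- solve_transient(chain$Q, chain$R)          # (I-Q)^{-1} R
  sol2 <- solve_transient(chain$Q, sol1$value)       # (I-Q)^{-2} R
  num_states <- as.vector(z_t %*% sol2$value)
  num <- absorbing_to_alternative(num_states, chain$absorbed_alternative,
                                  chain$available)
  e <- ifelse(probabilities < 1e-300, NA_real_, num / probabilities)
  names(e) <- chain$available
  attr(e, "overall") <- sum(num)
  e
}

#' Solve a choice scenario exactly
#'
#' End-to-end wrapper: builds the transition model, its canonical
#' absorbing form and the start distribution, and returns first-passage
#' choice probabilities and expected iteration counts. With
#' `forced_first_step`, start mass on a choice condition does not trigger
#' at once: one unconstrained Metropolis step is executed first
#' (re-absorption counts as choosing the start alternative and as one
#' iteration), after which the ordinary absorbing dynamics take over.
#' With trigger `"converged"` the invariant-distribution probabilities of
#' [converged_choice_probabilities()] are returned instead.
#'
#' @param structure A [choice_structure()].
#' @param scenario A [choice_scenario()].
#' @return An object of class `choice_outcome`: `probabilities`,
#'   `expected_iterations`, `overall_expected_iterations`,
#'   `condition_warning`, `trigger`.
#' @export
solve_choice <- function(structure, scenario) {
  if (scenario$trigger == "converged") {
    sub <- scenario_structure(structure, scenario)
    p <- converged_choice_probabilities(
      sub, choice_set = scenario$available,
      cue_set = intersect(scenario_clamped(structure, scenario), sub$nodes))
    return(structure(
      list(probabilities = p, expected_iterations = NULL,
           overall_expected_iterations = NA_real_,
           condition_warning = FALSE, trigger = "converged"),
      class = "choice_outcome"))
  }
  model <- build_transition_matrix(structure, scenario)
  chain <- to_canonical_form(model)
  start <- scenario_start_distribution(structure, scenario)
  z <- start$probs
  warn <- FALSE
  if (scenario$forced_first_step && any(z[model$absorbing_index] > 0)) {
    # push absorbing start mass through one unconstrained Metropolis step
    z_a <- numeric(length(z)); z_a[model$absorbing_index] <-
      z[model$absorbing_index]
    z_rest <- z; z_rest[model$absorbing_index] <- 0
    stepped <- as.vector(z_a %*% model$P_free)
    imm <- stepped[model$absorbing_index]   # absorbed at the forced step
    cont <- stepped; cont[model$absorbing_index] <- 0
    z_t_total <- (z_rest + cont)[chain$transient_index]
    sol1 <- solve_transient(chain$Q, chain$R)
    sol2 <- solve_transient(chain$Q, sol1$value)
    p_states <- imm + as.vector(z_t_total %*% sol1$value)
    p <- absorbing_to_alternative(p_states, chain$absorbed_alternative,
                                  chain$available)
    # iterations: forced step counts as 1 for all mass that took it
    cont_t <- cont[chain$transient_index]
    num_states <- imm +
      as.vector(z_t_total %*% sol2$value) +
      as.vector(cont_t %*% sol1$value)
    num <- absorbing_to_alternative(num_states, chain$absorbed_alternative,
                                    chain$available)
    e <- ifelse(p < 1e-300, NA_real_, num / p)
    names(e) <- chain$available
    warn <- sol1$rcond < 1e-12
    overall <- sum(num)
  } else {
    p <- first_passage_probabilities(chain, start)
    warn <- attr(p, "condition_warning")
    e <- expected_iterations(chain, start, p)
    overall <- attr(e, "overall")
    attr(p, "condition_warning") <- NULL
    attr(e, "overall") <- NULL
  }
  structure(
    list(probabilities = p, expected_iterations = e,
         overall_expected_iterations = overall,
         condition_warning = isTRUE(warn), trigger = "first_passage"),
    class = "choice_outcome")
}

#' @export
print.choice_outcome <- function(x, ...) {
  cat("Choice outcome (trigger:", x$trigger, ")\n")
  df <- data.frame(alternative = names(x$probabilities),
                   probability = as.numeric(x$probabilities))
  if (!is.null(x$expected_iterations))
    df$expected_iterations <- as.numeric(x$expected_iterations)
  print(df, row.names = FALSE, digits = 6)
  if (!is.na(x$overall_expected_iterations))
    cat("overall expected iterations:",
        format(x$overall_expected_iterations, digits = 6), "\n")
  if (x$condition_warning)
    cat("warning: (I - Q) solve is ill-conditioned; values may be inaccurate\n")
  invisible(x)
}

#' Closed-form binary first-passage probability
#'
#' For a two-alternative problem with cue-adjusted appeals `u_x`, `u_y`
#' (already including any beta/mu scaling), coupling `a_xy` between the
#' alternatives (on the same scale), and start probabilities
#' `(p_x, p_y, p_0, p_1)` over the four configurations (x only, y only,
#' none, both), the probability of choosing `x` is available in closed
#' form: start mass on `x` triggers immediately; from the empty
#' configuration the race between the two activation flips is a logistic
#' in the clipped appeals; from the both-active configuration it is a
#' logistic in the clipped deactivation rates.
#'
#' @param u_x,u_y Cue-adjusted appeals of the two alternatives.
#' @param a_xy Coupling between the alternatives.
#' @param start Numeric vector `c(p_x, p_y, p_0, p_1)` on the simplex.
#' @return Probability of choosing `x`.
#' @export
binary_first_passage <- function(u_x, u_y, a_xy, start) {
  assert_scalar_number(u_x, "u_x")
  assert_scalar_number(u_y, "u_y")
  assert_scalar_number(a_xy, "a_xy")
  if (!is.numeric(start) || length(start) != 4L || any(start < -1e-12) ||
      abs(sum(start) - 1) > 1e-10)
    stop("`start` must be a probability vector (p_x, p_y, p_0, p_1)",
         call. = FALSE)
  p_x <- start[1]; p_0 <- start[3]; p_1 <- start[4]
  from_empty <- 1 / (1 + exp(min(0, u_y) - min(0, u_x)))
  from_full <- 1 / (1 + exp(min(0, -(a_xy + u_x)) - min(0, -(a_xy + u_y))))
  p_x + p_0 * from_empty + p_1 * from_full
}
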