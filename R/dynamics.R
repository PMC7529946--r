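# Metropolis single spin-flip dynamics: one-step proposals, scalar trials,
# and a vectorised batch engine used for Monte-Carlo estimates.

#' One Metropolis single spin-flip step
#'
#' Samples one node uniformly from `mutable_set`, flips its state, and
#' accepts the flip outright if it lowers the energy, otherwise with
#' probability `exp(H - H*)`. Cues and clamped nodes must not appear in
#' `mutable_set`. Uses the current R random number stream.
#'
#' @param structure A [choice_structure()].
#' @param config Named 0/1 vector over `structure$nodes`.
#' @param mutable_set Character vector of proposable node ids (non-empty).
#' @return List with `config` (the resulting configuration), `accepted`
#'   (logical), and `proposed` (the sampled node id).
#' @export
metropolis_step <- function(structure, config, mutable_set) {
  if (length(mutable_set) == 0L)
    stop("`mutable_set` must be non-empty", call. = FALSE)
  node <- mutable_set[sample.int(length(mutable_set), 1L)]
  x_new <- config
  x_new[node] <- 1 - config[node]
  h_old <- hamiltonian(structure, config)
  h_new <- hamiltonian(structure, x_new)
  accept <- h_new < h_old || stats::runif(1L) < exp(h_old - h_new)
  list(config = if (accept) x_new else config,
       accepted = accept, proposed = node)
}

# Precomputed chain geometry for a scenario: acceptance probabilities per
# (state, flipped node), absorbing flags, and per-state chosen alternative.
scenario_chain_info <- function(structure, scenario) {
  model <- build_transition_matrix(structure, scenario)
  m <- length(model$mutable)
  n_states <- nrow(model$state_order)
  acc <- matrix(0, n_states, m)
  for (k in seq_len(m)) {
    j <- seq_len(n_states) +
      (1L - 2L * model$state_order[, k]) * 2^(k - 1L)
    acc[, k] <- pmin(1, exp(model$energies - model$energies[j]))
  }
  state_alt <- rep(NA_character_, n_states)
  state_alt[model$absorbing_index] <- model$absorbed_alternative
  list(m = m, mutable = model$mutable, available = model$available,
       acc = acc, energies = model$energies,
       is_condition = seq_len(n_states) %in% model$absorbing_index,
       state_alt = state_alt)
}

# Vectorised batch simulation on canonical state indices.
# mode: "first_passage" (stop at first choice condition),
#       "k_visit_first", "k_visit_proportional" (see run_k_visit_trial),
#       "free_run" (no stopping; run exactly `k` steps, return end states).
simulate_batch <- function(info, start_probs, n_trials,
                           mode = "first_passage", k = 1L,
                           forced_first_step = FALSE,
                           max_iterations = 1e7) {
  m <- info$m
  n_states <- nrow(info$acc)
  states <- sample.int(n_states, n_trials, replace = TRUE,
                       prob = start_probs)
  iters <- integer(n_trials)
  choice <- rep(NA_character_, n_trials)
  final_iters <- rep(NA_real_, n_trials)
  visits <- matrix(0L, n_trials, m, dimnames = list(NULL, info$mutable))
  active <- rep(TRUE, n_trials)
  trial_id <- seq_len(n_trials)

  count_visit <- function(idx, st) {
    hit <- info$is_condition[st]
    if (any(hit)) {
      alt <- match(info$state_alt[st[hit]], info$mutable)
      ij <- cbind(idx[hit], alt)
      visits[ij] <<- visits[ij] + 1L
    }
  }
  settle <- function(idx, st, t_now) {
    # which trials stop now, given visit counts already updated
    if (mode == "first_passage") {
      done <- info$is_condition[st]
      ch <- info$state_alt[st]
    } else if (mode == "k_visit_first") {
      vmax <- apply(visits[idx, , drop = FALSE], 1L, max)
      done <- vmax >= k
      ch <- info$mutable[max.col(visits[idx, , drop = FALSE],
                                 ties.method = "first")]
    } else if (mode == "k_visit_proportional") {
      tot <- rowSums(visits[idx, , drop = FALSE])
      done <- tot >= k
      ch <- rep(NA_character_, length(idx))
      for (w in which(done)) {
        cnt <- visits[idx[w], ]
        ch[w] <- info$mutable[sample.int(m, 1L, prob = cnt)]
      }
    } else {
      done <- rep(FALSE, length(idx))
      ch <- rep(NA_character_, length(idx))
    }
    list(done = done, choice = ch)
  }

  # iteration 0: the start configuration may already satisfy a condition
  if (mode != "free_run") {
    count_visit(trial_id, states)
    if (!forced_first_step) {
      s0 <- settle(trial_id, states, 0L)
      if (any(s0$done)) {
        choice[s0$done] <- s0$choice[s0$done]
        final_iters[s0$done] <- 0
        active[s0$done] <- FALSE
      }
    }
  }

  t_global <- 0L
  while (any(active)) {
    t_global <- t_global + 1L
    if (t_global > max_iterations)
      stop("maximum iteration guard (", format(max_iterations, scientific = FALSE),
           ") exceeded for ", sum(active), " trial(s); the chain is nearly ",
           "non-absorbing for this structure", call. = FALSE)
    idx <- trial_id[active]
    st <- states[idx]
    prop <- sample.int(m, length(idx), replace = TRUE)
    bit <- bitwAnd(st - 1L, as.integer(2^(prop - 1L))) > 0L
    accept <- stats::runif(length(idx)) < info$acc[cbind(st, prop)]
    st_new <- st + ifelse(accept, ifelse(bit, -1L, 1L) *
                            as.integer(2^(prop - 1L)), 0L)
    states[idx] <- st_new
    iters[idx] <- iters[idx] + 1L
    if (mode == "free_run") {
      if (t_global >= k) break
      next
    }
    count_visit(idx, st_new)
    s <- settle(idx, st_new, t_global)
    if (any(s$done)) {
      done_idx <- idx[s$done]
      choice[done_idx] <- s$choice[s$done]
      final_iters[done_idx] <- iters[done_idx]
      active[done_idx] <- FALSE
    }
  }
  list(choice = choice, iterations = final_iters, visits = visits,
       end_states = states)
}

# Single-trial wrapper around the batch engine.
run_single_trial <- function(structure, scenario, mode, k = 1L,
                             max_iterations = 1e7) {
  info <- scenario_chain_info(structure, scenario)
  z <- scenario_start_distribution(structure, scenario)$probs
  res <- simulate_batch(info, z, 1L, mode = mode, k = k,
                        forced_first_step = scenario$forced_first_step,
                        max_iterations = max_iterations)
  list(choice = res$choice[1L],
       iterations = res$iterations[1L],
       visit_counts = res$visits[1L, ])
}

#' Run one first-passage choice trial
#'
#' Samples a start configuration (from the scenario's start distribution
#' or its known configuration) and iterates Metropolis single spin-flip
#' steps until exactly one available alternative is active. If the start
#' already satisfies a choice condition and the scenario does not force a
#' first step, that alternative is returned with 0 iterations.
#'
#' @param structure A [choice_structure()].
#' @param scenario A [choice_scenario()].
#' @param max_iterations Guard against near-non-absorbing regimes; an
#'   error is raised when exceeded.
#' @return List with `choice` (alternative id), `iterations` (Metropolis
#'   proposals, including rejected ones), and `visit_counts`.
#' @export
run_first_passage_trial <- function(structure, scenario,
                                    max_iterations = 1e7) {
  run_single_trial(structure, scenario, "first_passage",
                   max_iterations = max_iterations)
}

#' Run one k-visit choice trial
#'
#' Deliberation variants of the first-passage trigger. With mode
#' `"first_to_k"` the process runs until some alternative's choice
#' condition has been occupied for `k` iterations, and that alternative is
#' chosen; with `"proportional"` it runs until conditions have been
#' occupied `k` iterations in total and the choice is sampled
#' proportional to the per-alternative counts. `k = 1` coincides with
#' [run_first_passage_trial()] in both modes. As `k` grows the
#' proportional variant approaches the converged (invariant-distribution)
#' probabilities, while first-to-k concentrates on the alternative with
#' the highest effective appeal.
#'
#' @inheritParams run_first_passage_trial
#' @param k Required number of condition visits (positive integer).
#' @param mode `"proportional"` or `"first_to_k"`.
#' @return As [run_first_passage_trial()].
#' @export
run_k_visit_trial <- function(structure, scenario, k,
                              mode = c("proportional", "first_to_k"),
                              max_iterations = 1e7) {
  mode <- match.arg(mode)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("`k` must be a positive integer", call. = FALSE)
  run_single_trial(structure, scenario,
                   if (mode == "proportional") "k_visit_proportional"
                   else "k_visit_first",
                   k = as.integer(k), max_iterations = max_iterations)
}

#' Monte-Carlo estimate of a choice outcome
#'
#' Aggregates independent simulated trials of the scenario's trigger into
#' empirical choice probabilities (with binomial standard errors) and mean
#' iteration counts. Serves as the stochastic counterpart of
#' [solve_choice()].
#'
#' @inheritParams run_first_passage_trial
#' @param n_trials Number of independent trials (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @param k Visit count for the k-visit triggers (ignored otherwise).
#' @return An object of class `simulation_summary` with fields
#'   `n_trials`, `empirical_probs`, `prob_standard_errors`,
#'   `mean_iterations`, `se_mean_iterations`, `mean_iterations_by_choice`,
#'   `seed`.
#' @export
estimate_choice_outcome <- function(structure, scenario, n_trials,
                                    seed = NULL, k = 1L,
                                    max_iterations = 1e7) {
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1)
    stop("`n_trials` must be at least 1", call. = FALSE)
  n_trials <- as.integer(n_trials)
  if (!is.null(seed)) set.seed(as.integer(seed))
  mode <- switch(scenario$trigger,
                 first_passage = "first_passage",
                 k_visit_proportional = "k_visit_proportional",
                 k_visit_first = "k_visit_first",
                 stop("simulation requires a stochastic trigger; got '",
                      scenario$trigger, "'", call. = FALSE))
  info <- scenario_chain_info(structure, scenario)
  z <- scenario_start_distribution(structure, scenario)$probs
  res <- simulate_batch(info, z, n_trials, mode = mode, k = as.integer(k),
                        forced_first_step = scenario$forced_first_step,
                        max_iterations = max_iterations)
  counts <- table(factor(res$choice, levels = scenario$available))
  p_hat <- as.numeric(counts) / n_trials
  names(p_hat) <- scenario$available
  se <- sqrt(p_hat * (1 - p_hat) / n_trials)
  by_choice <- tapply(res$iterations,
                      factor(res$choice, levels = scenario$available),
                      mean)
  structure(
    list(n_trials = n_trials,
         empirical_probs = p_hat,
         prob_standard_errors = se,
         mean_iterations = mean(res$iterations),
         se_mean_iterations = stats::sd(res$iterations) / sqrt(n_trials),
         mean_iterations_by_choice = by_choice,
         seed = seed),
    class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat("Simulation summary:", x$n_trials, "trials",
      if (!is.null(x$seed)) paste0("(seed ", x$seed, ")"), "\n")
  df <- data.frame(alternative = names(x$empirical_probs),
                   probability = as.numeric(x$empirical_probs),
                   std_error = as.numeric(x$prob_standard_errors))
  print(df, row.names = FALSE, digits = 4)
  cat("mean iterations:", format(x$mean_iterations, digits = 5),
      "+/-", format(x$se_mean_iterations, digits = 3), "\n")
  invisible(x)
}

# Long free run of the clamped (non-absorbing) chain; returns the end
# states of `n_chains` independent chains after `n_steps` steps each.
# Used to check detailed balance against the conditional Boltzmann
# distribution.
free_run_states <- function(structure, scenario, n_chains, n_steps,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  info <- scenario_chain_info(structure, scenario)
  z <- scenario_start_distribution(structure, scenario)$probs
  res <- simulate_batch(info, z, n_chains, mode = "free_run",
                        k = as.integer(n_steps))
  res$end_states
}
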