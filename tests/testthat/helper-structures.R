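# Shared builders and independent oracles for the test suite.

# one cue coupled to every alternative with weight `cue_w`, optional
# alternative-alternative couplings given as a named list "a|b" -> w
make_structure <- function(appeals, cue_w = 1, alt_edges = list(),
                           cue_appeal = 0, beta = 1, mu = 1) {
  alts <- names(appeals)
  nodes <- c("cue", alts)
  edges <- data.frame(from = rep("cue", length(alts)), to = alts,
                      weight = rep(cue_w, length.out = length(alts)))
  for (key in names(alt_edges)) {
    pr <- strsplit(key, "|", fixed = TRUE)[[1]]
    edges <- rbind(edges, data.frame(from = pr[1], to = pr[2],
                                     weight = alt_edges[[key]]))
  }
  choice_structure(nodes, c("cue", rep("alternative", length(alts))),
                   appeal = c(cue_appeal, unname(appeals)),
                   coupling = edge_list_matrix(nodes, edges),
                   beta = beta, mu = mu)
}

# random small structure with one cue; |couplings| and |appeals| <= 2
random_structure <- function(m) {
  alts <- paste0("a", seq_len(m))
  appeals <- stats::runif(m, -2, 2)
  names(appeals) <- alts
  alt_edges <- list()
  if (m > 1) {
    for (cmb in utils::combn(alts, 2, simplify = FALSE))
      alt_edges[[paste(cmb, collapse = "|")]] <- stats::runif(1, -2, 2)
  }
  make_structure(appeals, cue_w = stats::runif(m, -2, 2),
                 alt_edges = alt_edges,
                 cue_appeal = stats::runif(1, -2, 2))
}

# independent evaluation of the quadratic exponential probability of a
# full configuration (all nodes), straight from its definition
qexp_probability_oracle <- function(structure, config) {
  n <- length(structure$nodes)
  all_configs <- enumerate_configurations(n)
  weight <- function(x) {
    s <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      s <- s + structure$coupling[i, j] * x[i] * x[j]
    exp(structure$beta *
          (s + structure$mu * sum(structure$appeal * x)))
  }
  w_all <- apply(all_configs, 1, weight)
  weight(config) / sum(w_all)
}

# brute-force conditional of the full Boltzmann distribution given all
# cues active and exactly one alternative of `choice_set` active (other
# alternatives inactive)
brute_conditional_probs <- function(structure, choice_set) {
  n <- length(structure$nodes)
  cfgs <- enumerate_configurations(n, structure$nodes)
  w <- apply(cfgs, 1, function(x) {
    pair <- 0.5 * sum(x * (structure$coupling %*% x))
    exp(structure$beta * (pair + structure$mu * sum(structure$appeal * x)))
  })
  cues <- cue_ids(structure)
  alts <- alternative_ids(structure)
  keep <- apply(cfgs, 1, function(x)
    all(x[cues] == 1) && sum(x[alts]) == 1 && sum(x[choice_set]) == 1)
  w_keep <- w * keep
  p <- vapply(choice_set, function(a)
    sum(w_keep[cfgs[, a] == 1]), numeric(1))
  p / sum(p)
}

# first-passage probabilities by truncated power iteration on the
# absorbing transition matrix (geometric-series oracle, no linear solve)
power_iteration_probs <- function(model, z, n_steps = 4000) {
  v <- z
  for (t in seq_len(n_steps)) v <- as.vector(v %*% model$P)
  p <- vapply(model$available, function(a)
    sum(v[model$absorbing_index[model$absorbed_alternative == a]]),
    numeric(1))
  names(p) <- model$available
  p
}

expect_probability_vector <- function(p, tol = 1e-10) {
  expect_true(all(p >= -tol))
  expect_equal(sum(p), 1, tolerance = tol)
}
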