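#' Build a choice structure
#'
#' A choice structure is a network whose nodes are the cues framing a choice
#' and the alternatives that can be chosen. Symmetric couplings `a_ij`
#' describe pairwise relations (negative values implement inhibition),
#' appeals `b_i` describe each node's baseline attractiveness, and the
#' scaling constants `beta` (inverse temperature, non-negative) and `mu`
#' (appeal weight) scale the whole energy landscape. Node states are binary
#' (active / inactive) and follow the quadratic exponential (Ising)
#' distribution induced by [hamiltonian()].
#'
#' @param nodes Character vector of unique node ids.
#' @param roles Character vector, one of `"cue"` or `"alternative"` per node.
#'   At least one node must be an alternative.
#' @param appeal Numeric vector of general appeals `b_i` (default 0).
#' @param coupling Symmetric numeric matrix of couplings `a_ij` with zero
#'   diagonal, in node order (default all zero).
#' @param beta Non-negative scaling of the whole Hamiltonian (default 1).
#' @param mu Scaling of the appeal term relative to the couplings (default 1).
#' @return An object of class `choice_structure`.
#' @export
#' @examples
#' s <- choice_structure(
#'   nodes = c("R", "x", "y"),
#'   roles = c("cue", "alternative", "alternative"),
#'   appeal = c(0, 0.5, 0),
#'   coupling = edge_list_matrix(c("R", "x", "y"),
#'                               data.frame(from = c("R", "R"),
#'                                          to = c("x", "y"),
#'                                          weight = c(1, 1)))
#' )
#' s
choice_structure <- function(nodes, roles, appeal = NULL, coupling = NULL,
                             beta = 1, mu = 1) {
  if (!is.character(nodes) || length(nodes) == 0L)
    stop("`nodes` must be a non-empty character vector", call. = FALSE)
  if (anyDuplicated(nodes))
    stop("node ids must be unique; duplicated: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "),
         call. = FALSE)
  n <- length(nodes)
  if (!is.character(roles) || length(roles) != n ||
      !all(roles %in% c("cue", "alternative")))
    stop("`roles` must give 'cue' or 'alternative' for each node",
         call. = FALSE)
  if (!any(roles == "alternative"))
    stop("a choice structure needs at least one alternative node",
         call. = FALSE)
  appeal <- appeal %||% rep(0, n)
  if (!is.numeric(appeal) || length(appeal) != n || !all(is.finite(appeal)))
    stop("`appeal` must be a finite numeric vector of length ", n,
         call. = FALSE)
  coupling <- coupling %||% matrix(0, n, n)
  coupling <- as.matrix(coupling)
  if (!is.numeric(coupling) || !all(dim(coupling) == c(n, n)) ||
      !all(is.finite(coupling)))
    stop("`coupling` must be a finite numeric ", n, "x", n, " matrix",
         call. = FALSE)
  if (!isTRUE(all.equal(coupling, t(coupling), tolerance = 1e-12)))
    stop("`coupling` must be symmetric", call. = FALSE)
  if (any(abs(diag(coupling)) > 0))
    stop("`coupling` must have a zero diagonal (no self-edges)",
         call. = FALSE)
  assert_scalar_number(beta, "beta")
  if (beta < 0) stop("`beta` must be non-negative", call. = FALSE)
  assert_scalar_number(mu, "mu")
  dimnames(coupling) <- list(nodes, nodes)
  names(appeal) <- nodes
  names(roles) <- nodes
  structure(
    list(nodes = nodes, roles = roles, appeal = appeal,
         coupling = coupling, beta = beta, mu = mu),
    class = "choice_structure"
  )
}

#' Couplings matrix from an undirected edge list
#'
#' Convenience constructor for the symmetric coupling matrix of
#' [choice_structure()] from a `from`/`to`/`weight` edge list. Each
#' undirected pair may appear once; listing both directions with different
#' weights is an error.
#'
#' @param nodes Character vector of node ids, fixing the matrix order.
#' @param edges Data frame with columns `from`, `to`, `weight`.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
edge_list_matrix <- function(nodes, edges) {
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (is.null(edges) || nrow(edges) == 0L) return(A)
  for (r in seq_len(nrow(edges))) {
    i <- as.character(edges$from[r]); j <- as.character(edges$to[r])
    w <- edges$weight[r]
    if (!(i %in% nodes)) stop("edge references unknown node id '", i, "'",
                              call. = FALSE)
    if (!(j %in% nodes)) stop("edge references unknown node id '", j, "'",
                              call. = FALSE)
    if (i == j) stop("self-edge on node '", i, "' is not allowed",
                     call. = FALSE)
    if (A[i, j] != 0 && A[i, j] != w)
      stop("conflicting duplicate edge between '", i, "' and '", j, "'",
           call. = FALSE)
    A[i, j] <- w; A[j, i] <- w
  }
  A
}

#' @export
print.choice_structure <- function(x, ...) {
  n_alt <- sum(x$roles == "alternative")
  cat("Choice structure:", length(x$nodes), "nodes (",
      sum(x$roles == "cue"), "cues,", n_alt, "alternatives )\n")
  cat("  beta =", format(x$beta), " mu =", format(x$mu), "\n")
  df <- data.frame(node = x$nodes, role = unname(x$roles),
                   appeal = unname(x$appeal))
  print(df, row.names = FALSE)
  nz <- which(upper.tri(x$coupling) & x$coupling != 0, arr.ind = TRUE)
  if (nrow(nz)) {
    cat("  edges:\n")
    for (r in seq_len(nrow(nz)))
      cat(sprintf("    %s -- %s : %s\n", x$nodes[nz[r, 1]],
                  x$nodes[nz[r, 2]], format(x$coupling[nz[r, 1], nz[r, 2]])))
  }
  invisible(x)
}

#' @rdname node_sets
#' @export
alternative_ids <- function(structure) {
  structure$nodes[structure$roles == "alternative"]
}

#' Node subsets of a choice structure
#'
#' `alternative_ids()` and `cue_ids()` return the ids of the alternative and
#' cue nodes in structure order.
#'
#' @param structure A [choice_structure()].
#' @return Character vector of node ids.
#' @name node_sets
#' @export
cue_ids <- function(structure) {
  structure$nodes[structure$roles == "cue"]
}

#' Induced substructure
#'
#' Restricts a choice structure to a subset of its nodes, keeping the
#' couplings among them. Offering only a subset of alternatives is
#' modelled by restricting to the cues plus that subset: an absent node
#' is equivalent to a node clamped inactive, which contributes nothing to
#' any energy.
#'
#' @param structure A [choice_structure()].
#' @param keep Character vector of node ids to keep (structure order is
#'   preserved).
#' @return A `choice_structure` over `keep`.
#' @export
restrict_structure <- function(structure, keep) {
  miss <- setdiff(keep, structure$nodes)
  if (length(miss))
    stop("unknown node id(s): ", paste(miss, collapse = ", "), call. = FALSE)
  keep <- structure$nodes[structure$nodes %in% keep]
  choice_structure(
    nodes = keep,
    roles = unname(structure$roles[keep]),
    appeal = unname(structure$appeal[keep]),
    coupling = structure$coupling[keep, keep, drop = FALSE],
    beta = structure$beta, mu = structure$mu
  )
}

#' Energy of a configuration
#'
#' The Hamiltonian of a binary configuration `x` is
#' `H(x) = -beta * ( sum_{i<j} a_ij x_i x_j + mu * sum_i b_i x_i )`.
#' Lower energy means higher probability under the Boltzmann distribution;
#' with `beta = mu = 1` this is the unscaled energy of the quadratic
#' exponential model.
#'
#' @param structure A [choice_structure()].
#' @param config Binary vector (0/1) aligned to `structure$nodes`.
#' @return A single numeric energy value.
#' @export
hamiltonian <- function(structure, config) {
  x <- as.numeric(config)
  if (length(x) != length(structure$nodes))
    stop_dimension(sprintf(
      "configuration length %d does not match node count %d",
      length(x), length(structure$nodes)))
  if (!all(x %in% c(0, 1)))
    stop("configuration entries must be 0 or 1", call. = FALSE)
  pair_sum <- 0.5 * sum(x * (structure$coupling %*% x))
  -structure$beta * (pair_sum + structure$mu * sum(structure$appeal * x))
}

#' Boltzmann probabilities from energies
#'
#' Converts a vector of configuration energies into probabilities
#' `p_i = exp(-H_i) / sum_j exp(-H_j)`. Exponentials are shifted by the
#' minimum energy before exponentiation so very large magnitudes degrade
#' gracefully instead of overflowing.
#'
#' @param energies Non-empty numeric vector of finite energies.
#' @return Probability vector of the same length, summing to 1.
#' @export
boltzmann_probabilities <- function(energies) {
  if (length(energies) == 0L)
    stop("`energies` must be non-empty", call. = FALSE)
  if (!is.numeric(energies) || !all(is.finite(energies)))
    stop("`energies` must all be finite numbers", call. = FALSE)
  w <- exp(-(energies - min(energies)))
  w / sum(w)
}

#' Cue-adjusted appeal of an alternative
#'
#' The effective appeal of alternative `i` given a set of clamped-active
#' cues `K`: `beta * ( sum_{k in K} a_ik + mu * b_i )`. With
#' `beta = mu = 1` this is the net field `u_i` an active cue set exerts on
#' the alternative.
#'
#' @param structure A [choice_structure()].
#' @param alternative Id of an alternative node.
#' @param cue_set Character vector of clamped-active node ids (may be empty).
#' @return A single numeric value.
#' @export
cue_adjusted_appeal <- function(structure, alternative,
                                cue_set = cue_ids(structure)) {
  if (!(alternative %in% structure$nodes))
    stop("unknown node id '", alternative, "'", call. = FALSE)
  if (structure$roles[[alternative]] != "alternative")
    stop("node '", alternative, "' is not an alternative", call. = FALSE)
  miss <- setdiff(cue_set, structure$nodes)
  if (length(miss))
    stop("unknown cue id(s): ", paste(miss, collapse = ", "), call. = FALSE)
  cue_term <- if (length(cue_set))
    sum(structure$coupling[alternative, cue_set]) else 0
  structure$beta * (cue_term + structure$mu * structure$appeal[[alternative]])
}

#' Converged (rational-limit) choice probabilities
#'
#' Choice probabilities when the evaluation process is run to convergence
#' and a choice is sampled from the invariant distribution restricted to
#' the single-active-alternative configurations:
#' `p(i) = exp(u_i) / sum_m exp(u_m)` with `u_i` the
#' [cue_adjusted_appeal()]. Alternative-alternative couplings do not enter
#' because each potential-choice configuration has exactly one alternative
#' active. This limit satisfies Luce's choice axiom.
#'
#' @param structure A [choice_structure()].
#' @param choice_set Character vector of alternative ids to choose among.
#' @param cue_set Clamped-active cue ids (defaults to all cue-role nodes).
#' @return Named probability vector over `choice_set`.
#' @export
converged_choice_probabilities <- function(structure,
                                           choice_set = alternative_ids(structure),
                                           cue_set = cue_ids(structure)) {
  if (length(choice_set) == 0L)
    stop("`choice_set` must be non-empty", call. = FALSE)
  u <- vapply(choice_set, function(a)
    cue_adjusted_appeal(structure, a, cue_set), numeric(1))
  p <- boltzmann_probabilities(-u)
  names(p) <- choice_set
  p
}

#' Resting-state distribution over alternative configurations
#'
#' Before a choice is posed the whole network (cues included) rests in its
#' Boltzmann distribution. This function enumerates all configurations of
#' every free node, computes their quadratic-exponential probabilities, and
#' marginalises over the cue states, returning the start distribution `z`
#' over the `2^m` configurations of the `m` alternatives under the
#' canonical enumeration of [enumerate_configurations()]. Nodes listed in
#' `clamped_active` are held active throughout (they are not enumerated).
#'
#' @param structure A [choice_structure()].
#' @param alternatives Alternative ids spanning the returned state space
#'   (defaults to all alternatives in the structure).
#' @param clamped_active Node ids held active (e.g. an owned alternative
#'   acting as an extra cue). Cues are *not* clamped here: the resting
#'   state precedes the choice, so cue states are enumerated and
#'   marginalised out.
#' @param available Alternative ids whose single-active configurations are
#'   flagged absorbing (defaults to `alternatives`).
#' @return An object of class `state_distribution` with elements `support`
#'   (configuration matrix), `probs`, `alternatives`, `absorbing_index`.
#' @export
resting_alternative_distribution <- function(structure,
                                             alternatives = alternative_ids(structure),
                                             clamped_active = character(0),
                                             available = alternatives) {
  if (length(alternatives) == 0L)
    stop("`alternatives` must be non-empty", call. = FALSE)
  free <- setdiff(structure$nodes, clamped_active)
  if (length(free) > 20L)
    stop("more than 20 free nodes: exact enumeration is not practical; ",
         "use the Monte-Carlo simulator instead", call. = FALSE)
  if (!all(alternatives %in% free))
    stop("`alternatives` must be free (not clamped) nodes", call. = FALSE)
  full <- enumerate_configurations(length(free), free)
  n <- length(structure$nodes)
  base <- numeric(n); names(base) <- structure$nodes
  base[clamped_active] <- 1
  energies <- apply(full, 1L, function(row) {
    x <- base; x[free] <- row
    hamiltonian(structure, x)
  })
  p_full <- boltzmann_probabilities(energies)
  # marginalise over everything that is not an alternative of interest
  alt_idx <- match(alternatives, free)
  key <- as.vector(full[, alt_idx, drop = FALSE] %*%
                     2^(seq_along(alt_idx) - 1L)) + 1L
  m <- length(alternatives)
  z <- as.vector(rowsum(p_full, factor(key, levels = seq_len(2^m))))
  z[is.na(z)] <- 0
  support <- enumerate_configurations(m, alternatives)
  state_distribution(support, z, alternatives, available)
}

# constructor for the start-distribution container
state_distribution <- function(support, probs, alternatives,
                               available = alternatives) {
  if (abs(sum(probs) - 1) > 1e-12)
    stop("state probabilities must sum to 1", call. = FALSE)
  absorbing_index <- which(rowSums(support) == 1 &
                             support %*% as.numeric(alternatives %in% available) == 1)
  structure(
    list(support = support, probs = as.numeric(probs),
         alternatives = alternatives, available = available,
         absorbing_index = as.integer(absorbing_index)),
    class = "state_distribution"
  )
}

#' @export
print.state_distribution <- function(x, ...) {
  cat("State distribution over", nrow(x$support),
      "configurations of", length(x$alternatives), "alternatives\n")
  df <- as.data.frame(x$support)
  df$prob <- x$probs
  df$absorbing <- seq_len(nrow(df)) %in% x$absorbing_index
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}
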