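# Checkers for classical rationality properties of choice probabilities:
# regularity, Luce's choice axiom, binary utility classes, stochastic
# transitivity, and the weak-rationality diagnostic for binary problems.

#' Pairwise (and subset) choice probability table
#'
#' Container for observed or model-derived choice probabilities: a
#' complete (or partial) table of binary probabilities `p(x, y)` of
#' choosing `x` from `{x, y}`, optionally extended with probabilities for
#' larger subsets. Binary complements must satisfy
#' `p(x, y) + p(y, x) = 1`.
#'
#' @param alternatives Character vector of alternative ids.
#' @param p Square numeric matrix (dimnames = alternatives) with
#'   `p[x, y]` the probability of choosing `x` from `{x, y}`; the
#'   diagonal is ignored. `NA` marks unobserved pairs.
#' @param subset_probs Optional named list: each element a named
#'   probability vector over a subset of alternatives; the element name
#'   is ignored (the vector's names define the subset).
#' @return An object of class `pairwise_table`.
#' @export
pairwise_table <- function(alternatives, p, subset_probs = NULL) {
  p <- as.matrix(p)
  if (!all(dim(p) == length(alternatives)))
    stop("`p` must be a square matrix over the alternatives", call. = FALSE)
  dimnames(p) <- list(alternatives, alternatives)
  for (i in seq_along(alternatives)) for (j in seq_along(alternatives)) {
    if (i == j) next
    if (is.na(p[i, j]) != is.na(p[j, i]))
      stop("pair (", alternatives[i], ", ", alternatives[j],
           ") has only one direction recorded", call. = FALSE)
    if (!is.na(p[i, j])) {
      if (p[i, j] < -1e-12 || p[i, j] > 1 + 1e-12)
        stop("probabilities must lie in [0, 1]", call. = FALSE)
      if (abs(p[i, j] + p[j, i] - 1) > 1e-10)
        stop("p(", alternatives[i], ",", alternatives[j], ") + p(",
             alternatives[j], ",", alternatives[i], ") must equal 1",
             call. = FALSE)
    }
  }
  if (!is.null(subset_probs)) {
    subset_probs <- lapply(subset_probs, function(v) {
      if (is.null(names(v)) || !all(names(v) %in% alternatives))
        stop("subset probabilities must be named by known alternatives",
             call. = FALSE)
      if (abs(sum(v) - 1) > 1e-8)
        stop("subset probabilities must sum to 1", call. = FALSE)
      v
    })
  }
  structure(list(alternatives = alternatives, p = p,
                 subset_probs = subset_probs),
            class = "pairwise_table")
}

#' Pairwise table of a choice structure
#'
#' Solves every pairwise problem — and optionally every larger subset —
#' of a structure under the chosen trigger, returning a
#' [pairwise_table()]. Subsets are solved on the induced subnetwork (cue
#' plus offered alternatives), starting from its resting distribution.
#'
#' @param structure A [choice_structure()].
#' @param trigger `"first_passage"` or `"converged"`.
#' @param subsets `"pairs"` for binary problems only, or `"all"` for
#'   every subset of two or more alternatives.
#' @return A `pairwise_table`.
#' @export
pairwise_table_from_structure <- function(structure,
                                          trigger = c("first_passage",
                                                      "converged"),
                                          subsets = c("pairs", "all")) {
  trigger <- match.arg(trigger)
  subsets <- match.arg(subsets)
  alts <- alternative_ids(structure)
  solve_subset <- function(set) {
    solve_choice(structure,
                 choice_scenario(available = set,
                                 trigger = trigger))$probabilities
  }
  p <- matrix(NA_real_, length(alts), length(alts),
              dimnames = list(alts, alts))
  for (i in seq_along(alts)) for (j in seq_along(alts)) {
    if (i >= j) next
    pr <- solve_subset(c(alts[i], alts[j]))
    p[alts[i], alts[j]] <- pr[[alts[i]]]
    p[alts[j], alts[i]] <- pr[[alts[j]]]
  }
  subset_probs <- NULL
  if (subsets == "all" && length(alts) > 2L) {
    subset_probs <- list()
    for (k in 3:length(alts)) {
      for (cols in utils::combn(alts, k, simplify = FALSE)) {
        subset_probs[[paste(cols, collapse = ",")]] <- solve_subset(cols)
      }
    }
  }
  pairwise_table(alts, p, subset_probs)
}

# every (A subset-of S) pair recorded in the table, pairs included
nested_subset_pairs <- function(table) {
  sets <- list()
  alts <- table$alternatives
  for (i in seq_along(alts)) for (j in seq_along(alts)) {
    if (i < j && !is.na(table$p[alts[i], alts[j]])) {
      v <- c(table$p[alts[i], alts[j]], table$p[alts[j], alts[i]])
      names(v) <- c(alts[i], alts[j])
      sets[[paste(sort(names(v)), collapse = ",")]] <- v
    }
  }
  for (v in table$subset_probs)
    sets[[paste(sort(names(v)), collapse = ",")]] <- v
  out <- list()
  keys <- names(sets)
  for (a in keys) for (s in keys) {
    if (a == s) next
    A <- names(sets[[a]]); S <- names(sets[[s]])
    if (all(A %in% S))
      out[[length(out) + 1L]] <- list(sub = sets[[a]], sup = sets[[s]],
                                      sub_key = a, sup_key = s)
  }
  out
}

#' Check regularity
#'
#' Regularity — the weakest independence-from-irrelevant-alternatives
#' property — demands that adding alternatives never increases an
#' option's choice probability: `p_A(x) >= p_S(x)` whenever
#' `x` is in `A`, a subset of `S`. Returns every recorded nested pair
#' that violates this beyond tolerance.
#'
#' @param table A [pairwise_table()] including at least one nested
#'   subset/superset pair.
#' @param tol Violation tolerance (default 1e-10).
#' @return Data frame with columns `subset`, `superset`, `alternative`,
#'   `delta` (positive excess `p_S(x) - p_A(x)`); zero rows when regular.
#' @export
check_regularity <- function(table, tol = 1e-10) {
  pairs <- nested_subset_pairs(table)
  if (length(pairs) == 0L)
    stop("no nested subset pairs recorded in the table", call. = FALSE)
  out <- data.frame(subset = character(0), superset = character(0),
                    alternative = character(0), delta = numeric(0))
  for (pr in pairs) {
    for (x in names(pr$sub)) {
      delta <- pr$sup[[x]] - pr$sub[[x]]
      if (delta > tol)
        out[nrow(out) + 1L, ] <- list(pr$sub_key, pr$sup_key, x, delta)
    }
  }
  out
}

#' Check Luce's choice axiom
#'
#' The strongest independence property: for `x` in `A`, a subset of `S`,
#' `p_S(x) = p_A(x) * sum_{y in A} p_S(y)`. Returns the maximum absolute
#' deviation of this identity over all recorded nested pairs and whether
#' it stays within tolerance.
#'
#' @inheritParams check_regularity
#' @param tol Acceptance tolerance for the identity (default 1e-10).
#' @return List with `satisfied` (logical) and `max_deviation`.
#' @export
check_choice_axiom <- function(table, tol = 1e-10) {
  pairs <- nested_subset_pairs(table)
  if (length(pairs) == 0L)
    stop("no nested subset pairs recorded in the table", call. = FALSE)
  dev <- 0
  for (pr in pairs) {
    mass <- sum(pr$sup[names(pr$sub)])
    for (x in names(pr$sub))
      dev <- max(dev, abs(pr$sup[[x]] - pr$sub[[x]] * mass))
  }
  list(satisfied = dev <= tol, max_deviation = dev)
}

#' Classify binary utility representations
#'
#' Given positive utilities `v`, tests the classical binary utility
#' classes on the complete pairwise table: *strict* — the ratio rule
#' `p(x, y) = v_x / (v_x + v_y)` holds for all pairs; *strong*
#' (necessary conditions only) — `p(x, y)` depends on the utilities only
#' through `v_x - v_y`, is non-decreasing in that difference, and equals
#' 1/2 at difference zero; *weak* — `p(x, y) >= 1/2` whenever
#' `v_x >= v_y`. Whether a full distribution function representation
#' exists is not decidable from finite data and is not attempted.
#'
#' @param table A complete [pairwise_table()].
#' @param v Named vector of strictly positive utilities, one per
#'   alternative.
#' @param tol Identity tolerance (default 1e-8).
#' @return List of logicals `strict`, `strong_necessary`, `weak`.
#' @export
classify_binary_utility <- function(table, v, tol = 1e-8) {
  alts <- table$alternatives
  if (is.null(names(v))) names(v) <- alts
  if (any(v <= 0) || !all(alts %in% names(v)))
    stop("`v` must give a strictly positive utility for every alternative",
         call. = FALSE)
  pairs <- utils::combn(alts, 2, simplify = FALSE)
  strict <- TRUE; weak <- TRUE; strong <- TRUE
  diffs <- numeric(0); ps <- numeric(0)
  for (pr in pairs) {
    x <- pr[1]; y <- pr[2]
    pxy <- table$p[x, y]
    if (is.na(pxy))
      stop("pair (", x, ", ", y, ") missing from the table", call. = FALSE)
    if (abs(pxy - v[[x]] / (v[[x]] + v[[y]])) > tol) strict <- FALSE
    for (o in list(c(x, y), c(y, x))) {
      if (v[[o[1]]] >= v[[o[2]]] && table$p[o[1], o[2]] < 0.5 - tol)
        weak <- FALSE
      diffs <- c(diffs, v[[o[1]]] - v[[o[2]]])
      ps <- c(ps, table$p[o[1], o[2]])
    }
  }
  # strong (necessary): p a non-decreasing function of the difference,
  # equal differences -> equal probabilities, p = 1/2 at difference 0
  ord <- order(diffs)
  d_s <- diffs[ord]; p_s <- ps[ord]
  for (i in seq_along(d_s)[-1]) {
    if (abs(d_s[i] - d_s[i - 1]) <= tol) {
      if (abs(p_s[i] - p_s[i - 1]) > tol) strong <- FALSE
    } else if (p_s[i] < p_s[i - 1] - tol) strong <- FALSE
  }
  if (any(abs(d_s) <= tol & abs(p_s - 0.5) > tol)) strong <- FALSE
  list(strict = strict, strong_necessary = strong, weak = weak)
}

#' Grade of stochastic transitivity
#'
#' Over every ordered triple with `p(x, y) >= 1/2` and `p(y, z) >= 1/2`:
#' *strong* transitivity requires `p(x, z) >= max` of the two, *moderate*
#' `>= min`, *weak* `>= 1/2`. Returns the strongest grade satisfied by
#' all triples, or `"none"`.
#'
#' @param table A complete [pairwise_table()].
#' @param tol Comparison tolerance (default 1e-10).
#' @return One of `"strong"`, `"moderate"`, `"weak"`, `"none"`.
#' @export
stochastic_transitivity_grade <- function(table, tol = 1e-10) {
  alts <- table$alternatives
  if (any(is.na(table$p[upper.tri(table$p)])))
    stop("the pairwise table must be complete", call. = FALSE)
  strong <- TRUE; moderate <- TRUE; weak <- TRUE
  for (x in alts) for (y in alts) for (z in alts) {
    if (x == y || y == z || x == z) next
    pxy <- table$p[x, y]; pyz <- table$p[y, z]; pxz <- table$p[x, z]
    if (pxy >= 0.5 - tol && pyz >= 0.5 - tol) {
      if (pxz < max(pxy, pyz) - tol) strong <- FALSE
      if (pxz < min(pxy, pyz) - tol) moderate <- FALSE
      if (pxz < 0.5 - tol) weak <- FALSE
    }
  }
  if (strong) "strong" else if (moderate) "moderate" else if (weak) "weak"
  else "none"
}

#' Weak-rationality diagnostic for a binary choice
#'
#' Even with no coupling between two alternatives, a first-passage choice
#' can fail weak rationality: the transition probabilities depend only on
#' the difference of the cue-adjusted appeals, but the resting start
#' distribution does not, and start mass concentrated on the weaker
#' alternative's choice condition can dominate. This diagnostic computes
#' the effective appeals, the start distribution over the four binary
#' configurations, the closed-form choice probability, and flags the case
#' where the alternative with the larger appeal is chosen with
#' probability below 1/2.
#'
#' @param structure A [choice_structure()].
#' @param pair Character vector of the two alternative ids `(x, y)`.
#' @return List with `u` (appeals), `start` (`p_x`, `p_y`, `p_0`, `p_1`),
#'   `p_xy` (probability of choosing `x`), and `flagged`.
#' @export
weak_rationality_diagnostic <- function(structure, pair) {
  if (length(pair) != 2L || !all(pair %in% structure$nodes))
    stop("`pair` must name two alternatives of the structure",
         call. = FALSE)
  x <- pair[1]; y <- pair[2]
  sub <- restrict_structure(structure, c(cue_ids(structure), x, y))
  u_x <- cue_adjusted_appeal(sub, x)
  u_y <- cue_adjusted_appeal(sub, y)
  a_xy <- sub$beta * sub$coupling[x, y]
  z <- resting_alternative_distribution(sub, alternatives = c(x, y))
  # canonical order over (x, y): (0,0), (1,0), (0,1), (1,1)
  start <- c(p_x = z$probs[2], p_y = z$probs[3],
             p_0 = z$probs[1], p_1 = z$probs[4])
  p_xy <- binary_first_passage(u_x, u_y, a_xy, unname(start))
  flagged <- (u_x >= u_y && p_xy < 0.5 - 1e-10) ||
    (u_y >= u_x && 1 - p_xy < 0.5 - 1e-10)
  list(u = c(u_x, u_y), start = start, p_xy = p_xy, flagged = flagged)
}

#' Full rationality report
#'
#' Runs every applicable checker on a table: regularity violations, the
#' choice-axiom deviation, binary utility classes (when utilities are
#' supplied), and the stochastic transitivity grade. The properties are
#' reported side by side; they are deliberately not collapsed into a
#' single rational/irrational verdict.
#'
#' @param table A [pairwise_table()].
#' @param v Optional named positive utilities for
#'   [classify_binary_utility()].
#' @param tol Identity tolerance passed to the checkers.
#' @return An object of class `rationality_report`.
#' @export
rationality_report <- function(table, v = NULL, tol = 1e-10) {
  has_nested <- length(nested_subset_pairs(table)) > 0L
  reg <- if (has_nested) check_regularity(table, tol) else NULL
  axiom <- if (has_nested) check_choice_axiom(table, tol) else NULL
  utility <- if (!is.null(v)) classify_binary_utility(table, v) else NULL
  grade <- if (!any(is.na(table$p[upper.tri(table$p)])))
    stochastic_transitivity_grade(table) else NA_character_
  structure(
    list(regularity_violations = reg,
         choice_axiom = axiom,
         utility = utility,
         transitivity_grade = grade),
    class = "rationality_report")
}

#' @export
print.rationality_report <- function(x, ...) {
  cat("Rationality report\n")
  if (!is.null(x$regularity_violations)) {
    if (nrow(x$regularity_violations) == 0L)
      cat("  regularity: satisfied\n")
    else {
      cat("  regularity: VIOLATED\n")
      print(x$regularity_violations, row.names = FALSE, digits = 4)
    }
  }
  if (!is.null(x$choice_axiom))
    cat("  choice axiom:",
        if (x$choice_axiom$satisfied) "satisfied" else "violated",
        sprintf("(max deviation %.3g)\n", x$choice_axiom$max_deviation))
  if (!is.null(x$utility))
    cat("  binary utility: strict =", x$utility$strict,
        "| strong (necessary) =", x$utility$strong_necessary,
        "| weak =", x$utility$weak, "\n")
  if (!is.na(x$transitivity_grade))
    cat("  stochastic transitivity:", x$transitivity_grade, "\n")
  invisible(x)
}
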