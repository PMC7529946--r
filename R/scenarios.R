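# Worked choice phenomena as reusable protocols: endowment, re-choice,
# phantom decoys, calibrated context-effect fixtures, and the beta/mu
# phase scan.

#' Endowment switch probability
#'
#' Protocol for the endowment effect: the decision-maker already owns
#' `endowed`, so the start configuration is known (endowed active,
#' competitor inactive) and already satisfies a choice condition. One
#' Metropolis step is forced; staying put (a rejected or re-absorbing
#' proposal) counts as keeping the endowment. For two alternatives with a
#' common effective appeal `u` the switch probability is
#' `(1/2) * [ (1/2) min(1, exp(u)) + (1/2) min(1, exp(-u)) ]`, which is
#' `1/2` only at `u = 0` and strictly below `1/2` otherwise.
#'
#' @param structure A [choice_structure()] containing both alternatives.
#' @param endowed Id of the owned alternative (initially active).
#' @param competitor Id of the alternative offered in exchange.
#' @return Probability of exchanging `endowed` for `competitor`.
#' @export
endowment_switch_probability <- function(structure, endowed, competitor) {
  if (identical(endowed, competitor))
    stop("`endowed` and `competitor` must differ", call. = FALSE)
  init <- c(1, 0)
  names(init) <- c(endowed, competitor)
  sc <- choice_scenario(available = c(endowed, competitor),
                        initial = init, forced_first_step = TRUE)
  out <- solve_choice(structure, sc)
  out$probabilities[[competitor]]
}

#' Re-choice probabilities after an initial choice
#'
#' After choosing `owned` the decision-maker is asked to choose again from
#' the remaining alternatives. The owned node stays active and acts as an
#' extra cue, contributing its coupling to every remaining alternative's
#' effective appeal. By default the process restarts from the known
#' configuration in which the remaining alternatives are inactive;
#' `initial = "resting"` instead lets the remaining network re-equilibrate
#' before the second choice (which also transmits relations *between* the
#' remaining alternatives to the start state).
#'
#' @param structure A [choice_structure()].
#' @param owned Id of the already-chosen alternative (clamped active).
#' @param remaining Ids to choose among now (must not include `owned`).
#' @param initial `"known"` (all remaining inactive) or `"resting"`.
#' @return Named probability vector over `remaining`.
#' @export
rechoice_probabilities <- function(structure, owned, remaining,
                                   initial = c("known", "resting")) {
  initial <- match.arg(initial)
  if (length(remaining) == 0L)
    stop("`remaining` must be non-empty", call. = FALSE)
  if (owned %in% remaining)
    stop("`owned` cannot be in `remaining`", call. = FALSE)
  ini <- if (initial == "known") {
    v <- rep(0, length(remaining)); names(v) <- remaining; v
  } else "resting"
  sc <- choice_scenario(available = remaining, clamped_active = owned,
                        initial = ini)
  solve_choice(structure, sc)$probabilities
}

#' Phantom-decoy choice probabilities
#'
#' A phantom decoy is superior to target and rival but unavailable. If the
#' unavailability is known upfront, the decoy still takes part in the
#' evaluation dynamics (it is sampled and flipped) but its lone-active
#' configurations do not terminate the process: the choice condition is
#' that exactly one alternative overall is active *and* it is available.
#' If the unavailability is revealed only after a first choice, the
#' unconstrained three-alternative process runs first; conditional on the
#' decoy being chosen, its node is active and acts as an extra cue while
#' the choice is repeated over the remaining two alternatives from the
#' known configuration. The stage-two distribution is returned.
#'
#' @param structure A [choice_structure()].
#' @param decoy Id of the unavailable decoy alternative.
#' @param mode `"known_upfront"` or `"revealed_after"`.
#' @param available Ids of the two (or more) available alternatives;
#'   defaults to all non-decoy alternatives.
#' @return Named probability vector over `available`. For
#'   `"revealed_after"` the attribute `stage1` carries the unconstrained
#'   first-stage probabilities (including the decoy).
#' @export
phantom_choice_probabilities <- function(structure, decoy,
                                         mode = c("known_upfront",
                                                  "revealed_after"),
                                         available = NULL) {
  mode <- match.arg(mode)
  available <- available %||% setdiff(alternative_ids(structure), decoy)
  if (decoy %in% available)
    stop("`decoy` must be distinct from the available alternatives",
         call. = FALSE)
  if (mode == "known_upfront") {
    sc <- choice_scenario(available = available, unavailable_decoys = decoy)
    return(solve_choice(structure, sc)$probabilities)
  }
  stage1 <- solve_choice(structure,
                         choice_scenario(available = c(available, decoy)))
  p2 <- rechoice_probabilities(structure, owned = decoy,
                               remaining = available, initial = "known")
  attr(p2, "stage1") <- stage1$probabilities
  p2
}

#' Calibrate general appeals to pairwise anchors
#'
#' Adjusts the general appeal of selected alternatives so that specified
#' two-alternative choice probabilities hit target values, by bracketed
#' one-dimensional root finding on the exact pairwise solution. Each
#' target row is solved in order; the pairwise probability is strictly
#' increasing in the adjusted appeal, so the root is unique when it lies
#' in the bracket.
#'
#' @param template A [choice_structure()] whose appeals are adjusted.
#' @param targets Data frame with columns `alternative` (appeal to
#'   adjust), `against` (opponent id), `probability` (target in (0, 1)).
#' @param trigger `"first_passage"` (pairwise first passage from the
#'   resting distribution) or `"converged"` (invariant-distribution
#'   probabilities).
#' @param bracket Half-width of the appeal search interval around the
#'   template value (default 15).
#' @param tol Root-finding tolerance on the probability (default 1e-10;
#'   achieved residuals are checked against 1e-8).
#' @return The calibrated `choice_structure`.
#' @export
calibrate_general_appeal <- function(template, targets,
                                     trigger = c("first_passage",
                                                 "converged"),
                                     bracket = 15, tol = 1e-10) {
  trigger <- match.arg(trigger)
  s <- template
  pairwise <- function(s, a, b) {
    sub <- restrict_structure(s, c(cue_ids(s), a, b))
    solve_choice(sub, choice_scenario(available = c(a, b),
                                      trigger = trigger))$probabilities[[a]]
  }
  for (r in seq_len(nrow(targets))) {
    a <- as.character(targets$alternative[r])
    b <- as.character(targets$against[r])
    p_target <- targets$probability[r]
    if (!is.finite(p_target) || p_target <= 0 || p_target >= 1)
      stop("calibration infeasible: target probability for '", a,
           "' must lie strictly inside (0, 1)", call. = FALSE)
    b0 <- s$appeal[[a]]
    f <- function(val) {
      s2 <- s; s2$appeal[[a]] <- val
      pairwise(s2, a, b) - p_target
    }
    lo <- b0 - bracket; hi <- b0 + bracket
    if (f(lo) * f(hi) > 0)
      stop("calibration infeasible: no sign change for appeal of '", a,
           "' in [", lo, ", ", hi, "]", call. = FALSE)
    root <- stats::uniroot(f, c(lo, hi), tol = tol)$root
    s$appeal[[a]] <- root
    if (abs(f(root)) > 1e-8)
      stop("calibration residual ", abs(f(root)), " for '", a,
           "' exceeds 1e-8", call. = FALSE)
  }
  s
}

# cache so repeated fixture builds (tests, phase scans) calibrate once
.fixture_cache <- new.env(parent = emptyenv())

#' Calibrated context-effect fixtures
#'
#' Builds the worked example for a named choice phenomenon: the cue is
#' coupled to every alternative with weight 1, the alternative-alternative
#' edge carries the sign pattern that explains the effect, and general
#' appeals are calibrated so the exact first-passage predictions reproduce
#' the classical anchor values:
#'
#' * `similarity` — recordings `D_C`, `B_F`, `B_K`; strong mutual
#'   inhibition (-30) between the two interchangeable recordings; `D_C`'s
#'   appeal calibrated so each pairwise probability against a `B` is 3/5
#'   (three-alternative prediction: (3/5, 1/5, 1/5)).
#' * `attraction_a` — money, nice pen, plain pen; negative money-plain
#'   edge; money's appeal calibrated to the pairwise 64/36 split, then
#'   (plain-pen appeal, edge weight) jointly calibrated so the triple is
#'   (52, 46, 2)%.
#' * `attraction_b` — the same effect explained by a positive edge (+2)
#'   between the pens; plain-pen appeal calibrated so it is chosen 2% of
#'   the time.
#' * `repulsion` — `attraction_a` with the money-plain edge sign flipped
#'   to positive, all other parameters identical.
#' * `compromise` — cameras low/mid/high; strong low-high inhibition
#'   (-30); high's appeal calibrated so it is chosen 1/4 of the time
#'   (triple close to (1/4, 1/2, 1/4)).
#' * `phantom` — paperclips target/rival/decoy with a superior decoy
#'   (appeal 4 vs 3); decoy-rival edge calibrated so that, when the
#'   decoy's unavailability is revealed after it was chosen, the re-choice
#'   selects the target with probability 4/5.
#' * `endowment` — two equally appealing recordings (effective appeal
#'   `u = 1`), known initial endowment, forced first step.
#'
#' Symmetric non-calibrated alternatives carry baseline appeal 5 where the
#' anchor regime is a race between deactivation flips (similarity,
#' compromise) and 3 where the printed triples demand a softer regime
#' (attraction family, phantom).
#'
#' @param effect One of `"similarity"`, `"attraction_a"`,
#'   `"attraction_b"`, `"compromise"`, `"repulsion"`, `"phantom"`,
#'   `"endowment"`.
#' @return A list of class `choice_fixture`: `effect`, `structure`,
#'   `scenario` (the headline protocol), plus effect-specific ids
#'   (`target`, `rival`, `decoy`, ...).
#' @export
build_fixture <- function(effect = c("similarity", "attraction_a",
                                     "attraction_b", "compromise",
                                     "repulsion", "phantom", "endowment")) {
  effect <- match.arg(effect)
  if (!is.null(.fixture_cache[[effect]])) return(.fixture_cache[[effect]])
  fx <- switch(effect,
    similarity = {
      nodes <- c("R", "D_C", "B_F", "B_K")
      s <- choice_structure(nodes, c("cue", rep("alternative", 3)),
        appeal = c(0, 5, 5, 5),
        coupling = edge_list_matrix(nodes, data.frame(
          from = c("R", "R", "R", "B_F"),
          to = c("D_C", "B_F", "B_K", "B_K"),
          weight = c(1, 1, 1, -30))))
      s <- calibrate_general_appeal(s, data.frame(
        alternative = "D_C", against = "B_F", probability = 3 / 5))
      list(structure = s,
           scenario = choice_scenario(available = c("D_C", "B_F", "B_K")),
           target = "D_C", similar_pair = c("B_F", "B_K"))
    },
    attraction_a = build_attraction_a(),
    attraction_b = {
      a <- build_attraction_a()
      s <- a$structure
      s$coupling["money", "pen_plain"] <- 0
      s$coupling["pen_plain", "money"] <- 0
      s$coupling["pen_nice", "pen_plain"] <- 2
      s$coupling["pen_plain", "pen_nice"] <- 2
      tri <- function(bd) {
        s2 <- s; s2$appeal[["pen_plain"]] <- bd
        solve_choice(s2, a$scenario)$probabilities[["pen_plain"]]
      }
      s$appeal[["pen_plain"]] <-
        stats::uniroot(function(b) tri(b) - 0.02, c(-8, 3.5),
                       tol = 1e-10)$root
      list(structure = s, scenario = a$scenario,
           target = "pen_nice", rival = "money", decoy = "pen_plain")
    },
    repulsion = {
      a <- build_attraction_a()
      s <- a$structure
      w <- s$coupling["money", "pen_plain"]
      s$coupling["money", "pen_plain"] <- -w
      s$coupling["pen_plain", "money"] <- -w
      list(structure = s, scenario = a$scenario,
           target = "pen_nice", rival = "money", decoy = "pen_plain")
    },
    compromise = {
      nodes <- c("C", "low", "mid", "high")
      s <- choice_structure(nodes, c("cue", rep("alternative", 3)),
        appeal = c(0, 5, 5, 5),
        coupling = edge_list_matrix(nodes, data.frame(
          from = c("C", "C", "C", "low"),
          to = c("low", "mid", "high", "high"),
          weight = c(1, 1, 1, -30))))
      sc <- choice_scenario(available = c("low", "mid", "high"))
      tri <- function(bh) {
        s2 <- s; s2$appeal[["high"]] <- bh
        solve_choice(s2, sc)$probabilities[["high"]]
      }
      s$appeal[["high"]] <-
        stats::uniroot(function(b) tri(b) - 0.25, c(0, 9), tol = 1e-10)$root
      list(structure = s, scenario = sc,
           target = "mid", rival = "low", decoy = "high")
    },
    phantom = {
      nodes <- c("PC", "target", "rival", "decoy")
      mk <- function(w) choice_structure(nodes,
        c("cue", rep("alternative", 3)),
        appeal = c(0, 3, 3, 4),
        coupling = edge_list_matrix(nodes, data.frame(
          from = c("PC", "PC", "PC", "decoy"),
          to = c("target", "rival", "decoy", "rival"),
          weight = c(1, 1, 1, w))))
      stage2 <- function(w) {
        phantom_choice_probabilities(mk(w), "decoy",
          mode = "revealed_after")[["target"]]
      }
      w <- stats::uniroot(function(w) stage2(w) - 0.8, c(-12, -4),
                          tol = 1e-10)$root
      list(structure = mk(w),
           scenario = choice_scenario(available = c("target", "rival"),
                                      unavailable_decoys = "decoy"),
           target = "target", rival = "rival", decoy = "decoy")
    },
    endowment = {
      nodes <- c("R", "beethoven", "debussy")
      s <- choice_structure(nodes, c("cue", "alternative", "alternative"),
        appeal = c(0, 0, 0),
        coupling = edge_list_matrix(nodes, data.frame(
          from = c("R", "R"), to = c("beethoven", "debussy"),
          weight = c(1, 1))))
      init <- c(beethoven = 1, debussy = 0)
      list(structure = s,
           scenario = choice_scenario(available = c("beethoven", "debussy"),
                                      initial = init,
                                      forced_first_step = TRUE),
           endowed = "beethoven", competitor = "debussy")
    })
  fx <- c(list(effect = effect), fx)
  class(fx) <- "choice_fixture"
  .fixture_cache[[effect]] <- fx
  fx
}

# attraction structure (a): negative money-plain edge; shared by the
# attraction_b and repulsion variants
build_attraction_a <- function() {
  nodes <- c("R", "money", "pen_nice", "pen_plain")
  mk <- function(b_money, b_plain, w) choice_structure(nodes,
    c("cue", rep("alternative", 3)),
    appeal = c(0, b_money, 3, b_plain),
    coupling = edge_list_matrix(nodes, data.frame(
      from = c("R", "R", "R", "money"),
      to = c("money", "pen_nice", "pen_plain", "pen_plain"),
      weight = c(1, 1, 1, w))))
  base <- calibrate_general_appeal(
    mk(3, 0, -5),
    data.frame(alternative = "money", against = "pen_nice",
               probability = 0.64))
  b_money <- base$appeal[["money"]]
  sc <- choice_scenario(available = c("money", "pen_nice", "pen_plain"))
  tri <- function(b_plain, w)
    solve_choice(mk(b_money, b_plain, w), sc)$probabilities
  inner <- function(w)
    stats::uniroot(function(b) tri(b, w)[["pen_plain"]] - 0.02,
                   c(-6, 3.5), tol = 1e-10)$root
  outer <- function(w) tri(inner(w), w)[["pen_nice"]] - 0.46
  w <- stats::uniroot(outer, c(-8, -4), tol = 1e-9)$root
  b_plain <- inner(w)
  list(structure = mk(b_money, b_plain, w), scenario = sc,
       target = "pen_nice", rival = "money", decoy = "pen_plain")
}

#' @export
print.choice_fixture <- function(x, ...) {
  cat("Choice fixture:", x$effect, "\n")
  print(x$structure)
  print(x$scenario)
  invisible(x)
}

#' Classify a response phase
#'
#' Assigns one of six response-phase labels to a choice probability vector
#' from an attraction-type triple (target, rival, decoy), applied in the
#' fixed precedence order RND, AE+, RA+, RA, CA, AE:
#' random (`RND`, all probabilities within 10 points of each other),
#' strong attraction (`AE+`, target beats rival), rational (`RA+`, rival
#' above 90%), increasingly rational (`RA`, rival above 66%), choice-axiom
#' (`CA`, within 0.01 of the reference converged probabilities), normal
#' attraction (`AE`, rival below 62%), else `UNCLASSIFIED`.
#'
#' @param probs Named probability vector over the three alternatives.
#' @param reference Converged probabilities at unit scalings, same names.
#' @param target,rival Ids of the target and rival alternatives.
#' @return A single label string.
#' @export
classify_phase <- function(probs, reference, target, rival) {
  if (anyNA(probs) || any(probs < -1e-9) || abs(sum(probs) - 1) > 1e-6)
    stop("`probs` must be a probability vector", call. = FALSE)
  if (max(probs) - min(probs) <= 0.10) return("RND")
  if (probs[[target]] > probs[[rival]]) return("AE+")
  if (probs[[rival]] > 0.90) return("RA+")
  if (probs[[rival]] > 0.66) return("RA")
  if (max(abs(probs - reference[names(probs)])) < 0.01) return("CA")
  if (probs[[rival]] < 0.62) return("AE")
  "UNCLASSIFIED"
}

#' Scan choice behaviour over the beta/mu plane
#'
#' Re-solves a scenario across a grid of the scaling constants: `beta`
#' scales the whole structure (attention / inverse time-pressure), `mu`
#' the relative weight of general appeals. Each cell rescales the
#' structure, recomputes the resting start distribution, solves the
#' first-passage problem exactly, classifies the response phase with
#' [classify_phase()] against the converged reference at unit scalings,
#' and records the log of the overall expected iteration count. Cells
#' where the linear solve fails or is flagged ill-conditioned are labelled
#' `UNCLASSIFIED` (the precision-limit region).
#'
#' @param fixture A `choice_fixture` (or any list with `structure`,
#'   `scenario`, `target`, `rival`).
#' @param beta_values,mu_values Positive grids (typically log-spaced).
#' @return An object of class `phase_grid`: `beta_values`, `mu_values`,
#'   `probabilities` (cells x alternatives matrix), `log_mean_iterations`,
#'   `labels` (matrices indexed beta x mu), `reference`.
#' @export
phase_scan <- function(fixture, beta_values, mu_values) {
  if (any(beta_values <= 0) || any(mu_values <= 0))
    stop("grids must be positive", call. = FALSE)
  s <- fixture$structure
  s_unit <- s; s_unit$beta <- 1; s_unit$mu <- 1
  reference <- converged_choice_probabilities(
    s_unit, choice_set = fixture$scenario$available)
  nb <- length(beta_values); nm <- length(mu_values)
  labels <- matrix(NA_character_, nb, nm)
  logit <- matrix(NA_real_, nb, nm)
  probs <- array(NA_real_, c(nb, nm, length(fixture$scenario$available)),
                 dimnames = list(NULL, NULL, fixture$scenario$available))
  for (i in seq_len(nb)) for (j in seq_len(nm)) {
    s_ij <- s; s_ij$beta <- beta_values[i]; s_ij$mu <- mu_values[j]
    out <- tryCatch(solve_choice(s_ij, fixture$scenario),
                    error = function(e) NULL)
    bad <- is.null(out) || out$condition_warning ||
      anyNA(out$probabilities) ||
      abs(sum(out$probabilities) - 1) > 1e-6
    if (bad) {
      labels[i, j] <- "UNCLASSIFIED"
      next
    }
    probs[i, j, ] <- out$probabilities
    logit[i, j] <- log(out$overall_expected_iterations)
    labels[i, j] <- classify_phase(out$probabilities, reference,
                                   fixture$target, fixture$rival)
  }
  structure(
    list(beta_values = beta_values, mu_values = mu_values,
         probabilities = probs, log_mean_iterations = logit,
         labels = labels, reference = reference,
         target = fixture$target, rival = fixture$rival),
    class = "phase_grid")
}

#' @export
print.phase_grid <- function(x, ...) {
  cat("Phase grid:", length(x$beta_values), "beta x",
      length(x$mu_values), "mu cells\n")
  print(table(x$labels, useNA = "ifany"))
  invisible(x)
}

#' @export
plot.phase_grid <- function(x, ...) {
  phases <- c("RND", "AE+", "AE", "CA", "RA", "RA+", "UNCLASSIFIED")
  cols <- c(RND = "grey85", `AE+` = "#d7301f", AE = "#fc8d59",
            CA = "#fee8c8", RA = "#74a9cf", `RA+` = "#0570b0",
            UNCLASSIFIED = "white")
  z <- matrix(match(x$labels, phases), nrow(x$labels), ncol(x$labels))
  graphics::image(log(x$beta_values), log(x$mu_values), z,
                  col = cols[phases], zlim = c(1, length(phases)),
                  xlab = "log(beta)", ylab = "log(mu)",
                  main = "Response phases", ...)
  graphics::legend("topleft", legend = phases, fill = cols[phases],
                   cex = 0.7, bg = "white")
  invisible(x)
}

#' @export
as.data.frame.phase_grid <- function(x, ...) {
  nb <- length(x$beta_values); nm <- length(x$mu_values)
  idx <- expand.grid(i = seq_len(nb), j = seq_len(nm))
  df <- data.frame(beta = x$beta_values[idx$i], mu = x$mu_values[idx$j])
  for (alt in dimnames(x$probabilities)[[3]])
    df[[paste0("p_", alt)]] <- x$probabilities[cbind(idx$i, idx$j,
                                                     match(alt, dimnames(x$probabilities)[[3]]))]
  df$log_mean_iterations <- x$log_mean_iterations[cbind(idx$i, idx$j)]
  df$label <- x$labels[cbind(idx$i, idx$j)]
  df
}
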