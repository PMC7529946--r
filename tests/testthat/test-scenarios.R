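# Choice phenomena protocols: endowment, re-choice, phantom decoys,
# calibrated fixtures, phase classification.

# symmetric two-alternative structure with effective appeal u for both
endowment_structure <- function(u) {
  make_structure(c(beethoven = u - 1, debussy = u - 1))
}

test_that("endowment switch probability equals the forced-first-step
           closed form", {
  expect_equal(endowment_switch_probability(endowment_structure(0),
                                            "beethoven", "debussy"), 0.5)
  for (u in seq(-3, 3, by = 0.5)) {
    p <- endowment_switch_probability(endowment_structure(u),
                                      "beethoven", "debussy")
    closed <- 0.5 * (0.5 * min(1, exp(u)) + 0.5 * min(1, exp(-u)))
    expect_equal(p, closed, tolerance = 1e-10)
    if (u != 0) expect_lt(p, 0.5)
  }
  expect_error(endowment_switch_probability(endowment_structure(1),
                                            "beethoven", "beethoven"),
               "must differ")
})

test_that("re-choice with an uncoupled owned alternative reduces to the
           plain subproblem", {
  s <- make_structure(c(owned = 1, x = 0.8, y = 0.2),
                      alt_edges = list("x|y" = -0.9))
  p_re <- rechoice_probabilities(s, "owned", c("x", "y"))
  s_sub <- restrict_structure(s, c("cue", "x", "y"))
  ini <- c(x = 0, y = 0)
  p_plain <- solve_choice(s_sub,
                          choice_scenario(available = c("x", "y"),
                                          initial = ini))$probabilities
  expect_equal(p_re, p_plain, tolerance = 1e-12)

  # symmetric remaining alternatives with equal couplings to the owned
  s2 <- make_structure(c(owned = 1, x = 0.5, y = 0.5),
                       alt_edges = list("owned|x" = 0.7,
                                        "owned|y" = 0.7))
  expect_equal(unname(rechoice_probabilities(s2, "owned", c("x", "y"))),
               c(0.5, 0.5))
  expect_error(rechoice_probabilities(s, "x", c("x", "y")),
               "cannot be in")
})

test_that("owning one of two interchangeable options makes the
           dissimilar option the near-certain re-choice", {
  fx <- build_fixture("similarity")
  p <- rechoice_probabilities(fx$structure, "B_K", c("D_C", "B_F"))
  expect_gte(p[["D_C"]], 0.95)
})

test_that("phantom protocols expose the decoy through dynamics or as an
           extra cue", {
  # symmetric target/rival, decoy uncoupled: stage two is a fair coin
  s <- make_structure(c(t = 0.5, r = 0.5, d = 2))
  p2 <- phantom_choice_probabilities(s, "d", "revealed_after")
  expect_equal(unname(p2), c(0.5, 0.5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_probability_vector(attr(p2, "stage1"))

  # a decoy that almost never activates leaves the pair problem intact
  s_dead <- make_structure(c(t = 0.7, r = 0.3, d = -15))
  p_ku <- phantom_choice_probabilities(s_dead, "d", "known_upfront")
  pair <- solve_choice(restrict_structure(s_dead, c("cue", "t", "r")),
                       choice_scenario(available = c("t", "r")))
  expect_lt(max(abs(p_ku - pair$probabilities)), 0.01)

  expect_error(phantom_choice_probabilities(s, "d", "known_upfront",
                                            available = c("t", "d")),
               "distinct")
})

test_that("a fixed phantom boost needs a stronger decoy-rival coupling
           when unavailability is known upfront", {
  nodes <- c("PC", "t", "r", "d")
  mk <- function(w) choice_structure(nodes, c("cue", rep("alternative", 3)),
    appeal = c(0, 3, 3, 4),
    coupling = edge_list_matrix(nodes, data.frame(
      from = c("PC", "PC", "PC", "d"),
      to = c("t", "r", "d", "r"), weight = c(1, 1, 1, w))))
  p_t <- function(w, mode)
    phantom_choice_probabilities(mk(w), "d", mode)[["t"]]
  w_ra <- stats::uniroot(function(w) p_t(w, "revealed_after") - 0.6,
                         c(-12, -4), tol = 1e-6)$root
  w_ku <- stats::uniroot(function(w) p_t(w, "known_upfront") - 0.6,
                         c(-12, -4), tol = 1e-6)$root
  expect_gt(abs(w_ku), abs(w_ra))
})

test_that("the similarity fixture reproduces the recording anchors", {
  fx <- build_fixture("similarity")
  s <- fx$structure
  for (b in c("B_F", "B_K")) {
    sub <- restrict_structure(s, c("R", "D_C", b))
    p <- solve_choice(sub, choice_scenario(available = c("D_C", b)))
    expect_equal(p$probabilities[["D_C"]], 3 / 5, tolerance = 1e-8)
  }
  sub_bb <- restrict_structure(s, c("R", "B_F", "B_K"))
  p_bb <- solve_choice(sub_bb,
                       choice_scenario(available = c("B_F", "B_K")))
  expect_equal(p_bb$probabilities[["B_F"]], 0.5, tolerance = 1e-12)
  out <- solve_choice(s, fx$scenario)
  expect_equal(unname(out$probabilities), c(3, 1, 1) / 5,
               tolerance = 5e-3)
})

test_that("the attraction fixture reproduces the pen experiment and the
           repulsion fixture flips one edge", {
  fx <- build_fixture("attraction_a")
  s <- fx$structure
  sub <- restrict_structure(s, c("R", "money", "pen_nice"))
  pair <- solve_choice(sub, choice_scenario(c("money", "pen_nice")))
  expect_equal(pair$probabilities[["money"]], 0.64, tolerance = 1e-8)
  out <- solve_choice(s, fx$scenario)
  expect_equal(out$probabilities[["money"]], 0.52, tolerance = 1e-6)
  expect_equal(out$probabilities[["pen_nice"]], 0.46, tolerance = 1e-6)
  expect_equal(out$probabilities[["pen_plain"]], 0.02, tolerance = 1e-6)
  # regularity violation in the observed direction: the target gains
  expect_gt(out$probabilities[["pen_nice"]],
            pair$probabilities[["pen_nice"]])

  rep_fx <- build_fixture("repulsion")
  d <- rep_fx$structure$coupling - s$coupling
  expect_equal(sum(d != 0), 2)  # one undirected edge differs
  expect_equal(rep_fx$structure$coupling["money", "pen_plain"],
               -s$coupling["money", "pen_plain"])
  # repulsion boosts the rival instead of the target
  out_rep <- solve_choice(rep_fx$structure, rep_fx$scenario)
  expect_gt(out_rep$probabilities[["money"]],
            pair$probabilities[["money"]])
  expect_lt(out_rep$probabilities[["pen_nice"]],
            out$probabilities[["pen_nice"]])
})

test_that("attraction structure b explains the same boost with a
           positive pen-pen edge", {
  fx <- build_fixture("attraction_b")
  expect_gt(fx$structure$coupling["pen_nice", "pen_plain"], 0)
  expect_equal(fx$structure$coupling["money", "pen_plain"], 0,
               ignore_attr = TRUE)
  out <- solve_choice(fx$structure, fx$scenario)
  expect_equal(out$probabilities[["pen_plain"]], 0.02, tolerance = 1e-6)
  expect_gt(out$probabilities[["pen_nice"]], 0.36)
})

test_that("attracting and repulsing decoys together pull the rival
           between the pair and attraction predictions", {
  a <- build_fixture("attraction_a")
  s <- a$structure
  w <- s$coupling["money", "pen_plain"]
  nodes <- c("R", "money", "pen_nice", "pen_plain", "pen_plain2")
  s4 <- choice_structure(nodes, c("cue", rep("alternative", 4)),
    appeal = c(0, s$appeal[["money"]], s$appeal[["pen_nice"]],
               s$appeal[["pen_plain"]], s$appeal[["pen_plain"]]),
    coupling = edge_list_matrix(nodes, data.frame(
      from = c("R", "R", "R", "R", "money", "money"),
      to = c("money", "pen_nice", "pen_plain", "pen_plain2",
             "pen_plain", "pen_plain2"),
      weight = c(1, 1, 1, 1, w, -w))))
  p4 <- solve_choice(s4, choice_scenario(
    available = c("money", "pen_nice", "pen_plain",
                  "pen_plain2")))$probabilities
  p3 <- solve_choice(s, a$scenario)$probabilities
  expect_gt(p4[["money"]], p3[["money"]])
  expect_lt(p4[["money"]], 0.64)
})

test_that("the compromise fixture makes the middle option the calibrated
           compromise", {
  fx <- build_fixture("compromise")
  out <- solve_choice(fx$structure, fx$scenario)
  expect_equal(out$probabilities[["high"]], 0.25, tolerance = 1e-8)
  expect_equal(out$probabilities[["mid"]], 0.5, tolerance = 5e-3)
  # pairwise low vs mid is even, so the triple reveals the compromise
  sub <- restrict_structure(fx$structure, c("C", "low", "mid"))
  p_pair <- solve_choice(sub, choice_scenario(c("low", "mid")))
  expect_equal(p_pair$probabilities[["mid"]], 0.5, tolerance = 1e-12)
})

test_that("the phantom fixture re-chooses the target four times out of
           five", {
  fx <- build_fixture("phantom")
  p2 <- phantom_choice_probabilities(fx$structure, "decoy",
                                     "revealed_after")
  expect_equal(p2[["target"]], 0.8, tolerance = 1e-8)
  st1 <- attr(p2, "stage1")
  expect_gt(st1[["decoy"]], max(st1[["target"]], st1[["rival"]]))
  # known upfront still boosts the target, though less strongly
  p_ku <- phantom_choice_probabilities(fx$structure, "decoy",
                                       "known_upfront")
  expect_gt(p_ku[["target"]], 0.5)
  expect_lt(p_ku[["target"]], p2[["target"]])
})

test_that("appeal calibration hits targets and rejects impossible
           ones", {
  s <- make_structure(c(x = 0, y = 0))
  cal <- calibrate_general_appeal(
    s, data.frame(alternative = "x", against = "y", probability = 0.5))
  expect_equal(cal$appeal[["x"]], cal$appeal[["y"]], tolerance = 1e-7)
  cal2 <- calibrate_general_appeal(
    s, data.frame(alternative = "x", against = "y", probability = 0.7))
  sub <- restrict_structure(cal2, c("cue", "x", "y"))
  p <- solve_choice(sub, choice_scenario(c("x", "y")))
  expect_equal(p$probabilities[["x"]], 0.7, tolerance = 1e-8)
  expect_error(calibrate_general_appeal(
    s, data.frame(alternative = "x", against = "y", probability = 1)),
    "infeasible")
  expect_error(calibrate_general_appeal(
    s, data.frame(alternative = "x", against = "y", probability = 0)),
    "infeasible")
})

test_that("phase labels follow the fixed precedence order", {
  ref <- c(money = 0.6197, pen_nice = 0.3485, pen_plain = 0.0318)
  lab <- function(p) classify_phase(p, ref, "pen_nice", "money")
  expect_identical(lab(c(money = 0.34, pen_nice = 0.33,
                         pen_plain = 0.33)), "RND")
  expect_identical(lab(c(money = 0.95, pen_nice = 0.04,
                         pen_plain = 0.01)), "RA+")
  expect_identical(lab(ref), "CA")
  expect_identical(lab(c(money = 0.30, pen_nice = 0.65,
                         pen_plain = 0.05)), "AE+")
  expect_identical(lab(c(money = 0.70, pen_nice = 0.25,
                         pen_plain = 0.05)), "RA")
  expect_identical(lab(c(money = 0.55, pen_nice = 0.40,
                         pen_plain = 0.05)), "AE")
  expect_error(lab(c(money = 0.9, pen_nice = 0.9, pen_plain = 0.9)),
               "probability vector")
})

test_that("a coarse phase scan recovers the qualitative response
           phases", {
  fx <- build_fixture("attraction_a")
  grid <- exp(seq(-4, 2, length.out = 6))
  pg <- phase_scan(fx, grid, grid)
  expect_identical(pg$labels[1, 1], "RND")       # small beta, small mu
  expect_identical(pg$labels[6, 1], "AE+")       # large beta, small mu
  expect_true(any(pg$labels[5:6, 3:6] %in% c("RA", "RA+",
                                             "UNCLASSIFIED")))
  df <- as.data.frame(pg)
  expect_equal(nrow(df), 36)
  expect_true(all(c("beta", "mu", "label", "log_mean_iterations")
                  %in% names(df)))
})
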