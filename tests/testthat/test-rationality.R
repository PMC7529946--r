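# Rationality checkers: regularity, choice axiom, binary utility
# classes, stochastic transitivity, weak-rationality diagnostic.

debreu_table <- function(triple = c(3, 1, 1) / 5) {
  alts <- c("D_C", "B_F", "B_K")
  p <- matrix(NA_real_, 3, 3, dimnames = list(alts, alts))
  p["D_C", "B_F"] <- 3 / 5; p["B_F", "D_C"] <- 2 / 5
  p["D_C", "B_K"] <- 3 / 5; p["B_K", "D_C"] <- 2 / 5
  p["B_F", "B_K"] <- 1 / 2; p["B_K", "B_F"] <- 1 / 2
  names(triple) <- alts
  pairwise_table(alts, p, list(triple = triple))
}

test_that("regularity flags the attraction pattern and passes converged
           tables", {
  alts <- c("money", "pen_nice", "pen_plain")
  p <- matrix(NA_real_, 3, 3, dimnames = list(alts, alts))
  p["money", "pen_nice"] <- 0.64; p["pen_nice", "money"] <- 0.36
  triple <- c(money = 0.52, pen_nice = 0.46, pen_plain = 0.02)
  tab <- pairwise_table(alts, p, list(triple))
  v <- check_regularity(tab)
  expect_equal(nrow(v), 1)
  expect_identical(v$alternative, "pen_nice")
  expect_equal(v$delta, 0.10, tolerance = 1e-12)

  # probabilities generated by the converged trigger are regular
  set.seed(401)
  s <- random_structure(4)
  tab_conv <- pairwise_table_from_structure(s, trigger = "converged",
                                            subsets = "all")
  expect_equal(nrow(check_regularity(tab_conv)), 0)

  # a table with no nested subsets recorded cannot be checked
  p2 <- matrix(NA_real_, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(check_regularity(pairwise_table(c("a", "b"), p2)),
               "no nested")
})

test_that("the choice axiom holds for converged probabilities and fails
           for the intuitive similarity pattern", {
  set.seed(402)
  s <- random_structure(4)
  tab <- pairwise_table_from_structure(s, trigger = "converged",
                                       subsets = "all")
  res <- check_choice_axiom(tab)
  expect_true(res$satisfied)
  expect_lt(res$max_deviation, 1e-10)

  # pairwise 3/5 with triple (3/5, 1/5, 1/5): the axiom demands 3/7
  res2 <- check_choice_axiom(debreu_table())
  expect_false(res2$satisfied)
  expect_equal(res2$max_deviation, abs(3 / 5 - 3 / 5 * (3 / 5 + 1 / 5)),
               tolerance = 1e-12)
  # whereas the axiom-consistent triple passes
  res3 <- check_choice_axiom(debreu_table(c(3, 2, 2) / 7))
  expect_true(res3$satisfied)
})

test_that("binary utility classes are detected from the ratio, the
           difference, and the ordering", {
  alts <- c("x", "y")
  p <- matrix(NA_real_, 2, 2, dimnames = list(alts, alts))
  p["x", "y"] <- 2 / 3; p["y", "x"] <- 1 / 3
  tab <- pairwise_table(alts, p)
  cls <- classify_binary_utility(tab, c(x = 2, y = 1))
  expect_true(cls$strict)
  expect_true(cls$weak)

  # p = 0.6 whenever v_x > v_y: weak but not strict
  alts3 <- c("a", "b", "c")
  p3 <- matrix(NA_real_, 3, 3, dimnames = list(alts3, alts3))
  for (pr in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    p3[pr[1], pr[2]] <- 0.6; p3[pr[2], pr[1]] <- 0.4
  }
  cls3 <- classify_binary_utility(pairwise_table(alts3, p3),
                                  c(a = 3, b = 2, c = 1))
  expect_true(cls3$weak)
  expect_false(cls3$strict)

  # equal utility differences with different probabilities rule out any
  # difference-based representation
  p3b <- p3
  p3b["b", "c"] <- 0.8; p3b["c", "b"] <- 0.2  # same difference as a vs b
  cls3b <- classify_binary_utility(pairwise_table(alts3, p3b),
                                   c(a = 3, b = 2, c = 1))
  expect_false(cls3b$strong_necessary)
  expect_true(cls3b$weak)

  # constant 1/2 with distinct utilities: weak holds, strict fails
  p3c <- p3; p3c[!is.na(p3c)] <- 0.5
  clsc <- classify_binary_utility(pairwise_table(alts3, p3c),
                                  c(a = 3, b = 2, c = 1))
  expect_true(clsc$weak)
  expect_false(clsc$strict)
  expect_error(classify_binary_utility(tab, c(x = -1, y = 1)),
               "positive")
})

test_that("stochastic transitivity grades order correctly", {
  alts <- c("a", "b", "c")
  mk <- function(ab, bc, ac) {
    p <- matrix(NA_real_, 3, 3, dimnames = list(alts, alts))
    p["a", "b"] <- ab; p["b", "a"] <- 1 - ab
    p["b", "c"] <- bc; p["c", "b"] <- 1 - bc
    p["a", "c"] <- ac; p["c", "a"] <- 1 - ac
    pairwise_table(alts, p)
  }
  expect_identical(stochastic_transitivity_grade(mk(0.5, 0.5, 0.5)),
                   "strong")
  expect_identical(stochastic_transitivity_grade(mk(0.6, 0.5, 0.6)),
                   "strong")
  expect_identical(stochastic_transitivity_grade(mk(0.7, 0.6, 0.65)),
                   "moderate")
  expect_identical(stochastic_transitivity_grade(mk(0.7, 0.6, 0.55)),
                   "weak")
  # cyclic preferences: no grade survives
  expect_identical(stochastic_transitivity_grade(mk(0.9, 0.9, 0.1)),
                   "none")
})

test_that("the weak-rationality diagnostic flags start-distribution
           dominance", {
  # positive cue-x relation but negative appeal, and vice versa for y,
  # with a strongly unappealing cue: the resting state nearly always
  # starts in y's choice condition although x has the larger appeal
  s <- make_structure(c(x = -5, y = 5), cue_w = c(10, -10),
                      cue_appeal = -20)
  d <- weak_rationality_diagnostic(s, c("x", "y"))
  expect_equal(unname(d$u), c(5, -5))
  expect_true(d$flagged)
  expect_gt(d$start[["p_y"]], 0.98)
  expect_equal(d$p_xy, 1 - d$start[["p_y"]], tolerance = 1e-2)

  # no couplings, equal appeals: a fair coin, nothing to flag
  s2 <- make_structure(c(x = 0.4, y = 0.4))
  d2 <- weak_rationality_diagnostic(s2, c("x", "y"))
  expect_equal(d2$p_xy, 0.5, tolerance = 1e-12)
  expect_false(d2$flagged)

  # a uniform start cannot reverse the appeal ordering
  s3 <- make_structure(c(x = 1.5, y = 0.5)); s3$beta <- 0
  s3$beta <- 1e-12  # essentially uniform resting state
  d3 <- weak_rationality_diagnostic(s3, c("x", "y"))
  expect_false(d3$flagged)
  expect_error(weak_rationality_diagnostic(s2, c("x", "nope")),
               "must name two alternatives")
})

test_that("checkers agree with a direct re-derivation on a generated
           table", {
  set.seed(403)
  s <- random_structure(3)
  tab <- pairwise_table_from_structure(s, trigger = "first_passage",
                                       subsets = "all")
  alts <- tab$alternatives
  triple <- tab$subset_probs[[1]]
  # direct re-derivation of both checks from the same numbers
  viol <- data.frame()
  dev <- 0
  for (i in seq_along(alts)) for (j in seq_along(alts)) {
    if (i >= j) next
    x <- alts[i]; y <- alts[j]
    pair <- c(tab$p[x, y], tab$p[y, x]); names(pair) <- c(x, y)
    for (a in c(x, y)) {
      if (triple[[a]] > pair[[a]] + 1e-10)
        viol <- rbind(viol, data.frame(alternative = a))
      dev <- max(dev, abs(triple[[a]] -
                            pair[[a]] * (triple[[x]] + triple[[y]])))
    }
  }
  pkg_viol <- check_regularity(tab)
  expect_setequal(pkg_viol$alternative, if (nrow(viol)) viol$alternative
                  else character(0))
  pkg_axiom <- check_choice_axiom(tab)
  expect_equal(pkg_axiom$max_deviation, dev, tolerance = 1e-12)
})

test_that("converged tables climb the whole implication chain", {
  set.seed(404)
  s <- random_structure(5)
  tab <- pairwise_table_from_structure(s, trigger = "converged",
                                       subsets = "all")
  expect_lt(check_choice_axiom(tab)$max_deviation, 1e-10)
  expect_equal(nrow(check_regularity(tab)), 0)
  expect_identical(stochastic_transitivity_grade(tab), "strong")
  rep <- rationality_report(tab)
  expect_true(rep$choice_axiom$satisfied)
  expect_identical(rep$transitivity_grade, "strong")
})
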