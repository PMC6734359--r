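test_that("confusion counts follow the per-report set semantics", {
  pred <- list(labelled("a", "A"), labelled("b", character(0)),
               labelled("c", "A"))
  gold <- list(labelled("a", "A"), labelled("b", "A"),
               labelled("c", character(0)))
  cc <- confusion_counts(pred, gold, "A")
  expect_identical(unclass(cc)[c("tp", "fp", "fn", "tn")],
                   list(tp = 1L, fp = 1L, fn = 1L, tn = 0L))
  expect_identical(cc$tp + cc$fp + cc$fn + cc$tn, 3L)

  same <- confusion_counts(gold, gold, "A")
  expect_identical(same$fp + same$fn, 0L)

  expect_error(confusion_counts(pred[1:2], gold, "A"), "missing")
  expect_error(
    confusion_counts(list(labelled("x", "A")), list(labelled("y", "A")), "A"),
    "missing")
})

test_that("wilson interval agrees with numeric score-test inversion", {
  cases <- expand.grid(k = c(0, 1, 5, 24, 39, 50, 145, 159, 164),
                       n = c(10, 26, 41, 100, 145, 164, 700))
  cases <- cases[cases$k <= cases$n, ]
  for (i in seq_len(nrow(cases))) {
    k <- cases$k[i]; n <- cases$n[i]
    got <- wilson_ci(k, n)
    want <- wilson_oracle(k, n)
    expect_equal(unname(got), unname(want), tolerance = 1e-8,
                 info = sprintf("k=%d n=%d", k, n))
  }
})

test_that("wilson interval properties: containment, monotone width, degeneracies", {
  expect_identical(unname(wilson_ci(0, 10)["low"]), 0)
  expect_identical(unname(wilson_ci(10, 10)["high"]), 1)
  ci <- wilson_ci(50, 100)
  expect_equal(unname(ci["low"] + ci["high"]), 1, tolerance = 1e-12)
  for (kn in list(c(3, 7), c(95, 100), c(1, 50))) {
    ci <- wilson_ci(kn[1], kn[2])
    expect_true(ci["low"] <= kn[1] / kn[2] && kn[1] / kn[2] <= ci["high"])
  }
  widths <- vapply(c(10, 30, 100, 300, 1000), function(n)
    diff(wilson_ci(round(0.3 * n), n)), numeric(1))
  expect_true(all(diff(widths) < 0))
  # large-n limit: Wilson ~ Wald at p = 0.5
  n <- 1e5
  wald_half <- qnorm(0.975) * sqrt(0.25 / n)
  wi <- wilson_ci(n / 2, n)
  expect_lt(abs((wi["high"] - 0.5) - wald_half), 1e-3)
  expect_error(wilson_ci(0, 0), "n = 0")
})

test_that("report metrics match hand-computed values and expose undefined", {
  m <- report_metrics(list(tp = 39, fn = 2, fp = 2, tn = 657))
  g <- function(name, col) m[m$name == name, ][[col]]
  expect_equal(round(g("sensitivity", "estimate"), 2), 0.95)
  expect_equal(round(g("sensitivity", "ci_low"), 2), 0.84)
  expect_equal(round(g("sensitivity", "ci_high"), 2), 0.99)
  expect_equal(round(g("ppv", "estimate"), 2), 0.95)
  expect_equal(round(g("specificity", "estimate"), 2), 1.00)

  und <- report_metrics(list(tp = 0, fn = 0, fp = 3, tn = 10))
  expect_true(is.na(und$estimate[und$name == "sensitivity"]))

  perfect <- report_metrics(list(tp = 5, fn = 0, fp = 0, tn = 5))
  expect_true(all(perfect$estimate[!is.na(perfect$estimate)] == 1))
})

test_that("cohen's kappa: identity, hand-computed 2x2, symmetry, bound", {
  expect_identical(cohens_kappa(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_identical(cohens_kappa(c(1, 1, 1, 1), c(1, 1, 0, 0)), 0)
  expect_identical(cohens_kappa(c(TRUE, TRUE), c(TRUE, TRUE)), 1)
  set.seed(14)
  for (i in 1:20) {
    a <- runif(40) < 0.5; b <- runif(40) < 0.3
    expect_equal(cohens_kappa(a, b), cohens_kappa(b, a))
    expect_lte(cohens_kappa(a, b), 1)
  }
  # direct 2x2-table oracle on a random case
  a <- c(1, 1, 0, 1, 0, 0, 1, 1); b <- c(1, 0, 0, 1, 1, 0, 1, 0)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(1 - a) * mean(1 - b)
  expect_equal(cohens_kappa(a, b), (po - pe) / (1 - pe))
})

test_that("entity-level precision/recall/F1 in exact and overlap modes", {
  gold <- data.frame(type = rep("atrophy", 4),
                     start = c(0, 10, 20, 30), end = c(5, 15, 25, 35))
  expect_equal(unname(entity_prf(gold, gold)), c(1, 1, 1))

  pred <- rbind(gold, data.frame(type = "atrophy", start = 50, end = 55))
  prf <- entity_prf(gold, pred)
  expect_equal(unname(prf), c(0.8, 1, 2 * 0.8 / 1.8))

  none <- gold[0, ]
  prf2 <- entity_prf(gold, none)
  expect_true(is.na(prf2["precision"]))
  expect_identical(unname(prf2["recall"]), 0)

  shifted <- gold
  shifted$start <- shifted$start + 2  # overlaps but not exact
  expect_identical(unname(entity_prf(gold, shifted, "exact")["recall"]), 0)
  expect_identical(unname(entity_prf(gold, shifted, "overlap")["recall"]), 1)
  wrong_type <- gold; wrong_type$type <- "microbleed"
  expect_identical(unname(entity_prf(gold, wrong_type, "overlap")["recall"]), 0)
})

test_that("sample-size planner matches the linear-search oracle", {
  # oracle: smallest m whose Wilson width at p is <= the target
  oracle_m <- function(p, w) {
    z <- qnorm(0.975)
    m <- 1
    repeat {
      denom <- 1 + z^2 / m
      width <- 2 * z * sqrt(p * (1 - p) / m + z^2 / (4 * m^2)) / denom
      if (width <= w) return(m)
      m <- m + 1
    }
  }
  expect_identical(min_sample_size(0.95, 0.12, 0.10), 692L)
  expect_identical(ceiling(oracle_m(0.95, 0.10) / 0.12), 692)
  expect_identical(min_sample_size(0.5, 1, 0.2), 93L)
  expect_identical(oracle_m(0.5, 0.2), 93)
  expect_identical(min_sample_size(0.95, 0.12, 0.10, round_to = 100), 700L)
  expect_error(min_sample_size(0.5, 1, 1e-9), "unattainable")
})

test_that("evaluation table contains aggregate rows with union semantics", {
  pred <- list(labelled("r1", "Ischaemic stroke, deep, old"),
               labelled("r2", "Ischaemic stroke, cortical, recent"),
               labelled("r3", character(0)))
  gold <- list(labelled("r1", "Ischaemic stroke, deep, old"),
               labelled("r2", "Ischaemic stroke, underspecified"),
               labelled("r3", "Atrophy"))
  tab <- evaluate_labels(pred, gold)
  any_isch <- tab[tab$label == "Any ischaemic stroke", ]
  # r1 tp; r2 tp under the union (different sub-labels, same group); r3 tn
  expect_identical(any_isch$tp, 2L)
  expect_equal(any_isch$sensitivity, 1)
  sub <- tab[tab$label == "Ischaemic stroke, cortical, recent", ]
  expect_identical(sub$tp, 0L)

  tab2 <- evaluate_labels(gold, gold, suppress_below = 5)
  expect_true(all(tab2$suppressed[tab2$tp < 5]))
  fmt <- format_metrics_table(tab2)
  expect_identical(fmt[fmt$label == "Atrophy", "f1"], "-")
})
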