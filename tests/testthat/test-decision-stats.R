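# A tight, well-separated model with clusters on the horizontal axis.
toy_model <- function(spread = 0.02) {
  gmm3_model(
    weights = c(0.25, 0.5, 0.25),
    means = rbind(c(-0.4, 0), c(0.01, 0), c(0.4, 0)),
    covariances = array(rep(diag(2) * spread^2, 3L), c(2L, 2L, 3L))
  )
}

toy_training <- function(model, n_per = 30L, seed = 1L) {
  withr::with_seed(seed, {
    x <- rbind(
      cbind(stats::rnorm(n_per, -0.4, 0.02), stats::rnorm(n_per, 0, 0.02)),
      cbind(stats::rnorm(n_per, 0.01, 0.02), stats::rnorm(n_per, 0, 0.02)),
      cbind(stats::rnorm(n_per, 0.4, 0.02), stats::rnorm(n_per, 0, 0.02))
    )
    sides <- c(rep("left", n_per), sample(c("left", "right"), n_per, TRUE),
               rep("right", n_per))
    list(x = x, sides = sides)
  })
}

test_that("label_clusters aligns clusters with the training sides", {
  m <- toy_model()
  tr <- toy_training(m)
  lab <- label_clusters(m, tr$x, tr$sides)
  expect_identical(lab$classes, c("left", "centre", "right"))
  expect_identical(lab$decision_axis, 1L)

  # mirrored data: the spatial left/right labels swap, centre unchanged --
  # each cluster keeps the label of its training trials, so the cluster now
  # sitting on the positive axis is the one labelled left
  m2 <- m
  m2$means[, 1L] <- -m2$means[, 1L]
  lab2 <- label_clusters(m2, cbind(-tr$x[, 1L], tr$x[, 2L]), tr$sides)
  expect_identical(lab2$classes, lab$classes)
  expect_gt(m2$means[which(lab2$classes == "left"), 1L], 0)
  expect_identical(lab2$classes[which(lab2$classes == "centre")], "centre")
})

test_that("the returned labelling maximises training agreement over both mappings", {
  m <- toy_model()
  tr <- toy_training(m, seed = 2L)
  lab <- label_clusters(m, tr$x, tr$sides)
  assign <- apply(gmm3_posterior(m, tr$x), 1L, which.max)
  agreement <- function(classes) {
    sum(classes[assign] == tr$sides & classes[assign] != "centre")
  }
  alt <- lab$classes
  alt[alt == "left"] <- "tmp"; alt[alt == "right"] <- "left"; alt[alt == "tmp"] <- "right"
  expect_gte(agreement(lab$classes), agreement(alt))
})

test_that("labelling ties break by sign and tied centres are an error", {
  m <- toy_model()
  # no informative training trials in the lateral clusters -> tie
  lab <- label_clusters(m, matrix(c(0.01, 0), 1L, 2L), "left")
  expect_identical(lab$classes, c("left", "centre", "right"))

  m_tied <- gmm3_model(
    weights = rep(1 / 3, 3L),
    means = rbind(c(-0.4, 0), c(0.4, 0), c(0, 0.7)),
    covariances = array(rep(diag(2) * 1e-4, 3L), c(2L, 2L, 3L))
  )
  expect_error(label_clusters(m_tied, matrix(0, 1L, 2L), "left"), "tied")
})

test_that("predict_direction matches the posterior-argmax oracle", {
  m <- toy_model()
  tr <- toy_training(m)
  lab <- label_clusters(m, tr$x, tr$sides)
  expect_identical(as.character(predict_direction(m, lab, m$means[1L, , drop = FALSE])),
                   "left")
  expect_identical(as.character(predict_direction(m, lab, matrix(c(0.01, 0), 1L))),
                   "centre")
  pts <- withr::with_seed(3L, matrix(stats::rnorm(200, 0, 0.4), ncol = 2L))
  got <- predict_direction(m, lab, pts)
  want <- lab$classes[apply(oracle_posterior(m, pts), 1L, which.max)]
  expect_identical(as.character(got), want)
})

test_that("contingency tables count exactly", {
  empty <- direction_table(character(0L), character(0L))
  expect_true(all(empty == 0L))

  all_centre <- direction_table(rep("centre", 10L),
                                rep(c("left", "right"), 5L))
  expect_equal(sum(all_centre["centre", ]), 10L)
  expect_equal(n_decisions(all_centre), 0L)

  preds <- c("left", "left", "right", "centre", "left", "right", "right",
             "centre", "left", "right", "left", "centre", "right", "left",
             "centre", "right", "left", "right", "centre", "left")
  sides <- rep(c("left", "right"), 10L)
  tab <- direction_table(preds, sides, split = "training", feature_set = "head_rot")
  # brute-force hand count
  for (cl in c("left", "centre", "right")) {
    for (sd in c("left", "right")) {
      expect_equal(tab[cl, sd], sum(preds == cl & sides == sd))
    }
  }
  expect_equal(sum(tab), 20L)
  expect_error(direction_table(preds, sides[-1L]), "lengths")
})

test_that("the correct-decision rate reproduces the reference infant head-rotation value", {
  tabs <- study_direction_tables()
  tab <- tabs$head_rot$validation_infant
  expect_equal(n_correct(tab), 44L)
  expect_equal(n_decisions(tab), 76L)
  expect_equal(correct_decision_rate(tab), 44 / 76)
  expect_equal(round(100 * correct_decision_rate(tab)), 58)

  perfect <- direction_table(c("left", "right"), c("left", "right"))
  expect_equal(correct_decision_rate(perfect), 1)
  none <- direction_table(rep("centre", 4L), rep("left", 4L))
  expect_true(is.na(correct_decision_rate(none)))
})

test_that("the exact one-sided binomial test matches enumeration oracles", {
  expect_equal(binom_p_one_sided(16, 20), 0.005909, tolerance = 1e-4)
  expect_equal(binom_p_one_sided(0, 7), 1)
  # full 2^n enumeration for small n, including a non-half null
  for (n in c(5L, 9L, 12L)) {
    for (k in c(0L, 1L, n %/% 2L, n)) {
      expect_equal(binom_p_one_sided(k, n), enum_binom_tail(k, n),
                   tolerance = 1e-12)
      expect_equal(binom_p_one_sided(k, n, 0.3), enum_binom_tail(k, n, 0.3),
                   tolerance = 1e-12)
    }
  }
  # monotone non-increasing in k at fixed n
  ps <- vapply(0:20, binom_p_one_sided, numeric(1L), n = 20L)
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps > 0 & ps <= 1))
  expect_error(binom_p_one_sided(5, 4), "k <= n")
})

test_that("cross-feature-set averages reproduce the reference summary values", {
  tabs <- study_direction_tables()
  infant <- lapply(tabs, function(t) t$validation_infant)
  toddler <- lapply(tabs, function(t) t$validation_toddler)
  expect_equal(average_correct_rate(infant), 68)
  expect_equal(average_correct_rate(toddler), 96)
  # four identical tables average to their common rate
  same <- replicate(4L, tabs$gaze_left$validation_infant, simplify = FALSE)
  expect_equal(average_correct_rate(same), 80)
  undefined <- replicate(4L, direction_table(rep("centre", 2L), rep("left", 2L)),
                         simplify = FALSE)
  expect_warning(res <- average_correct_rate(undefined), "no decisions")
  expect_true(is.na(res))
})

test_that("combine_decisions follows the single-source/agree/conflict rules", {
  comb <- combine_decisions(c("centre", "left", "left", "centre"),
                            c("left", "left", "right", "centre"))
  expect_identical(as.character(comb$predictions),
                   c("left", "left", "right", "centre"))
  expect_equal(comb$stats$n_both, 2L)
  expect_equal(comb$stats$n_agree, 1L)
  expect_equal(comb$stats$n_conflict, 1L)
  expect_equal(comb$stats$n_decisions_combined, 3L)

  head <- c("left", "centre", "right", "left", "centre", "right", "left",
            "centre", "left", "right")
  gaze <- c("left", "left", "left", "centre", "centre", "right", "right",
            "right", "left", "centre")
  comb <- combine_decisions(head, gaze)
  expect_equal(comb$stats$n_both, 5L)
  expect_equal(comb$stats$n_agree, 3L)
  expect_equal(comb$stats$n_conflict, 2L)
  # conflict policy: gaze wins by default, head optionally
  expect_identical(as.character(comb$predictions)[3L], "left")
  expect_identical(as.character(combine_decisions(head, gaze, "head")$predictions)[3L],
                   "right")
  expect_error(combine_decisions(head, gaze[-1L]), "lengths")
})

test_that("combining never yields fewer decisions than either source alone", {
  withr::with_seed(14L, {
    for (i in 1:20) {
      h <- sample(c("left", "centre", "right"), 30L, TRUE)
      g <- sample(c("left", "centre", "right"), 30L, TRUE)
      nd <- combine_decisions(h, g)$stats$n_decisions_combined
      expect_gte(nd, sum(h != "centre"))
      expect_gte(nd, sum(g != "centre"))
    }
  })
})
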