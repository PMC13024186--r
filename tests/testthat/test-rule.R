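test_that("genome decoding follows threshold, swap and repair semantics", {
  sch <- toy_schema()
  # feature active iff inclusion score exceeds lambda
  g <- rule_genome(c(0.7, 0.3), c(0.2, 0.5), c(0.9, 0.6))
  r <- decode_genome(g, sch, "L")
  expect_equal(r$features, "A")
  expect_equal(r$lower, 2)
  expect_equal(r$upper, 9)
  # decoded lower > upper is swapped, not discarded
  g2 <- rule_genome(c(0.7, 0.3), c(0.8, 0.5), c(0.2, 0.6))
  r2 <- decode_genome(g2, sch, "H")
  expect_equal(c(r2$lower, r2$upper), c(2, 8))
  # all-inactive genome: repair activates the max-score feature
  g3 <- rule_genome(c(0.1, 0.4), c(0.5, 0.5), c(0.6, 0.6))
  r3 <- decode_genome(g3, sch, "M")
  expect_equal(r3$features, "B")
  # custom threshold
  expect_equal(decode_genome(g3, sch, "M", lambda_threshold = 0.05)$features,
               c("A", "B"))
})

test_that("decoding is idempotent and bounds stay inside schema ranges", {
  sch <- cherry_schema()
  set.seed(11)
  for (i in 1:50) {
    g <- random_genome(10)
    r <- decode_genome(g, sch, "L")
    expect_identical(r, decode_genome(g, sch, "L"))
    idx <- match(r$features, sch$name)
    expect_true(all(r$lower >= sch$min[idx] - 1e-12))
    expect_true(all(r$upper <= sch$max[idx] + 1e-12))
    expect_true(all(r$lower <= r$upper))
    expect_gte(length(r$features), 1)
  }
})

test_that("rule matching is conjunctive with inclusive bounds", {
  r <- interval_rule(c("Weight", "Acidity"), c(3.614, 1.059),
                     c(5.390, 1.067), "L")
  d <- data.frame(Weight = c(4.0, 6.0, 3.614), Acidity = c(1.06, 1.06, 1.059))
  expect_equal(rule_matches(r, d), c(TRUE, FALSE, TRUE))
})

test_that("confusion counts follow one-vs-rest semantics", {
  sch <- toy_schema()
  r <- interval_rule("A", 2, 8, "L")
  # one sample per match/label combination: TP, TN, FP, FN
  d <- data.frame(A = c(5, 9, 5, 9), B = 1,
                  class = c("L", "M", "M", "L"))
  expect_equal(evaluate_rule(r, d),
               c(TP = 1L, TN = 1L, FP = 1L, FN = 1L))
  # saturating cases
  d_all <- data.frame(A = rep(5, 4), B = 1, class = rep("L", 4))
  expect_equal(evaluate_rule(r, d_all)[["TP"]], 4)
  d_none <- data.frame(A = rep(9, 4), B = 1, class = rep("M", 4))
  expect_equal(evaluate_rule(r, d_none)[["TN"]], 4)
  expect_error(evaluate_rule(r, d[0, ]), "empty")
  # counts always sum to the number of samples
  set.seed(3)
  for (i in 1:20) {
    dd <- random_labelled_data(30)
    rr <- random_rule(toy_schema(), sample(c("L", "M", "H"), 1))
    expect_equal(sum(evaluate_rule(rr, dd)), 30)
  }
})

test_that("objective metrics implement the confusion-matrix formulas", {
  expect_equal(objectives(c(TP = 5, TN = 5, FP = 0, FN = 0)),
               c(accuracy = 1, precision = 1, recall = 1))
  expect_equal(objectives(c(TP = 2, TN = 3, FP = 3, FN = 2))[["accuracy"]],
               0.5)
  # degenerate cases are defined as 0, not NaN
  o <- objectives(c(TP = 0, TN = 4, FP = 0, FN = 1))
  expect_equal(o[["precision"]], 0)
  expect_equal(o[["recall"]], 0)
  expect_equal(o[["accuracy"]], 0.8)
  expect_error(objectives(c(TP = 0, TN = 0, FP = 0, FN = 0)), "domain")
})

test_that("rule text renders at 3 decimals and round-trips through parsing", {
  r <- interval_rule("Weight", 2, 5, "H")
  expect_equal(rule_to_text(r), "IF (2.000 < Weight < 5.000) THEN H")
  r2 <- interval_rule(c("Weight", "Acidity"), c(3.614, 1.059),
                      c(5.390, 1.067), "L")
  expect_equal(rule_to_text(r2),
               "IF (3.614 < Weight < 5.390) and (1.059 < Acidity < 1.067) THEN L")
  set.seed(21)
  sch <- cherry_schema()
  for (i in 1:100) {
    rr <- random_rule(sch, sample(c("L", "M", "H"), 1))
    back <- parse_rule_text(rule_to_text(rr))
    expect_equal(back$features, rr$features)
    expect_equal(back$target_class, rr$target_class)
    expect_equal(back$lower, rr$lower, tolerance = 5e-4)
    expect_equal(back$upper, rr$upper, tolerance = 5e-4)
  }
})

test_that("widening a condition never loses true positives", {
  set.seed(31)
  sch <- toy_schema()
  for (i in 1:30) {
    d <- random_labelled_data(50, sch)
    r <- random_rule(sch, "L")
    j <- sample.int(length(r$features), 1)
    wide <- r
    wide$lower[j] <- max(sch$min[match(r$features[j], sch$name)],
                         r$lower[j] - runif(1, 0, 3))
    wide$upper[j] <- min(sch$max[match(r$features[j], sch$name)],
                         r$upper[j] + runif(1, 0, 3))
    c0 <- evaluate_rule(r, d); c1 <- evaluate_rule(wide, d)
    expect_gte(c1[["TP"]], c0[["TP"]])
    expect_lte(c1[["FN"]], c0[["FN"]])
  }
})
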