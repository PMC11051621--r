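test_that("class weights normalize counts as specified", {
  # ratios of the processed training-set counts
  counts <- c(Negative = 16160, Advise = 697, Effect = 1347, Int = 157,
              Mechanism = 1193)
  a <- class_weights(counts)
  expect_equal(unname(a["Negative"]), 16160 / 19554, tolerance = 1e-12)
  expect_equal(sum(a), 1, tolerance = 1e-12)

  # equal counts give uniform weights
  expect_equal(unname(class_weights(rep(10, 5))), rep(0.2, 5))

  # any counts normalize to 1
  set.seed(1)
  for (i in 1:10) {
    expect_equal(sum(class_weights(runif(5) * 100)), 1, tolerance = 1e-12)
  }

  # inverse weighting flips the ordering
  inv <- class_weights(counts, weighting = "inverse")
  expect_lt(inv[["Negative"]], inv[["Int"]])
  expect_equal(sum(inv), 1, tolerance = 1e-12)

  expect_error(class_weights(c(0, 0, 0)), "positive")
})

test_that("focal loss matches its closed forms and limits", {
  # perfect prediction: zero loss
  expect_equal(multi_focal_loss(matrix(c(0, 1), 1), 2L, c(0.5, 0.5)), 0)

  # hand value: alpha = 1, gamma = 2, p_t = 0.5 -> 0.25 * ln 2
  expect_equal(
    multi_focal_loss(matrix(c(0.5, 0.5), 1), 1L, c(1, 1), gamma = 2),
    0.25 * log(2), tolerance = 1e-10)

  # gamma = 0 reduces to alpha-weighted cross-entropy
  set.seed(4)
  prob <- t(apply(matrix(runif(40), 8), 1, function(x) x / sum(x)))
  y <- sample(5, 8, replace = TRUE)
  alpha <- class_weights(c(5, 4, 3, 2, 1))
  ce <- mean(-alpha[y] * log(prob[cbind(1:8, y)]))
  expect_equal(multi_focal_loss(prob, y, alpha, gamma = 0), ce,
               tolerance = 1e-12)

  # printed-sum form is the true-class form rescaled by mean(alpha)/alpha_y
  lt <- multi_focal_loss(matrix(c(0.5, 0.5), 1), 1L, c(0.6, 0.4), gamma = 2)
  lp <- multi_focal_loss(matrix(c(0.5, 0.5), 1), 1L, c(0.6, 0.4), gamma = 2,
                         focal_form = "printed_sum")
  expect_equal(lp / lt, (0.5) / 0.6, tolerance = 1e-12)

  # zero probabilities clamp with a warning
  expect_warning(multi_focal_loss(matrix(c(1, 0), 1), 2L, c(0.5, 0.5)),
                 "clamping")
})

test_that("focal modulation down-weights easy instances monotonically", {
  alpha <- rep(0.2, 5)
  pts <- seq(0.05, 0.95, by = 0.1)
  for (pt in pts) {
    prob <- matrix(c(pt, rep((1 - pt) / 4, 4)), 1)
    l2 <- multi_focal_loss(prob, 1L, alpha, gamma = 2)
    l0 <- multi_focal_loss(prob, 1L, alpha, gamma = 0)
    expect_lt(l2, l0)
    expect_gte(l2, 0)
  }
  # loss decreases as p_t rises, for fixed gamma
  losses <- vapply(pts, function(pt) {
    multi_focal_loss(matrix(c(pt, rep((1 - pt) / 4, 4)), 1), 1L, alpha, 2)
  }, 1)
  expect_true(all(diff(losses) < 0))
})

test_that("evaluation matches a brute-force contingency oracle", {
  levels <- ddi_classes()
  scope <- setdiff(levels, "Negative")
  set.seed(11)
  for (rep in 1:100) {
    n <- 50L
    gold <- sample(levels, n, replace = TRUE, prob = c(0.5, rep(0.125, 4)))
    scores <- matrix(rnorm(n * 5), n, 5)
    pred <- levels[max.col(scores, ties.method = "first")]
    ev <- suppressWarnings(ddi_evaluate(gold, pred, scores))
    orc <- oracle_eval(gold, pred, scores, levels, scope)

    expect_equal(ev$per_class$tp, unname(as.integer(orc$tp)))
    expect_equal(ev$per_class$precision, unname(orc$precision),
                 tolerance = 1e-12)
    expect_equal(ev$per_class$recall, unname(orc$recall), tolerance = 1e-12)
    expect_equal(unname(ev$micro[1:3]), unname(orc$micro), tolerance = 1e-12)
    expect_equal(unname(ev$macro[1:3]), unname(orc$macro), tolerance = 1e-12)
    expect_equal(ev$per_class$auc, unname(orc$auc), tolerance = 1e-12)
    expect_equal(ev$per_class$aupr, unname(orc$aupr), tolerance = 1e-12)
    expect_equal(ev$micro[["auc"]], orc$micro_auc, tolerance = 1e-12)
    expect_equal(ev$micro[["aupr"]], orc$micro_aupr, tolerance = 1e-12)
    expect_equal(ev$macro[["auc"]], orc$macro_auc, tolerance = 1e-12)
    expect_equal(ev$macro[["aupr"]], orc$macro_aupr, tolerance = 1e-12)
  }
})

test_that("perfect predictions score 100% everywhere", {
  levels <- ddi_classes()
  gold <- rep(levels, times = 3)
  scores <- t(vapply(gold, function(g) {
    s <- rep(0, 5); s[match(g, levels)] <- 1; s
  }, numeric(5)))
  ev <- ddi_evaluate(gold, gold, scores)
  expect_equal(unname(ev$micro), rep(1, 5))
  expect_equal(unname(ev$macro), rep(1, 5))
  expect_true(all(ev$per_class$f1 == 1))
})

test_that("macro F1 is the harmonic mean of macro P and R, not the mean of
           per-class F1", {
  # an asymmetric confusion where the two definitions disagree
  gold <- c(rep("Mechanism", 8), rep("Effect", 2), rep("Advise", 2),
            rep("Int", 2))
  pred <- c(rep("Mechanism", 4), rep("Effect", 4), rep("Effect", 2),
            rep("Advise", 1), "Int", rep("Int", 2))
  ev <- suppressWarnings(ddi_evaluate(gold, pred))
  pc <- ev$per_class[ev$per_class$in_scope, ]
  harm <- 2 * mean(pc$precision) * mean(pc$recall) /
    (mean(pc$precision) + mean(pc$recall))
  expect_equal(ev$macro[["f1"]], harm, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(ev$macro[["f1"]], mean(pc$f1))))
})

test_that("pooling over all classes makes micro precision equal recall", {
  levels <- ddi_classes()
  set.seed(21)
  gold <- sample(levels, 60, replace = TRUE)
  pred <- sample(levels, 60, replace = TRUE)
  ev <- suppressWarnings(ddi_evaluate(gold, pred, classes = "all"))
  expect_equal(ev$micro[["precision"]], ev$micro[["recall"]],
               tolerance = 1e-12)
})

test_that("evaluation reports serialize and curves sweep thresholds", {
  set.seed(31)
  gold <- sample(ddi_classes(), 40, replace = TRUE)
  scores <- matrix(runif(200), 40, 5)
  pred <- ddi_classes()[max.col(scores, ties.method = "first")]
  ev <- suppressWarnings(ddi_evaluate(gold, pred, scores))

  jp <- withr::local_tempfile(fileext = ".json")
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(ev, jp, tp)
  js <- jsonlite::read_json(jp)
  expect_equal(js$micro$f1, ev$micro[["f1"]], tolerance = 1e-9)
  expect_equal(nrow(utils::read.delim(tp)), 5L)

  cur <- score_curves(gold, scores)
  expect_true(all(cur$precision >= 0 & cur$precision <= 1))
  expect_true(all(diff(subset(cur, class == "Effect")$recall) >= 0))
})
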