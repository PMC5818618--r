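test_that("univariate logistic flags separation and constant features
           instead of crashing", {
  set.seed(23)
  x <- rnorm(100)
  y_sep <- as.integer(x > median(x))
  r <- univariate_logistic(x, y_sep)
  expect_equal(r$flag, "separation")
  expect_true(is.na(r$p))
  expect_true(r$or %in% c(0, Inf))

  r2 <- univariate_logistic(rep(3, 100), rbinom(100, 1, 0.5))
  expect_equal(r2$flag, "constant")

  r3 <- univariate_logistic(rnorm(10), c(1, rep(0, 9)))
  expect_equal(r3$flag, "insufficient")
})

test_that("odds ratios are per standard deviation with bracketing Wald CIs", {
  set.seed(31)
  n <- 3000
  x <- rnorm(n, 50, 10)                 # non-unit scale on purpose
  y <- rbinom(n, 1, plogis(0.7 * scale(x)[, 1]))
  r <- univariate_logistic(x, y)
  expect_lt(r$ci[1], r$or)
  expect_gt(r$ci[2], r$or)
  expect_gt(r$or, exp(0.5)); expect_lt(r$or, exp(0.9))
  # scale invariance: same OR per SD whatever the units
  r_mm <- univariate_logistic(x * 1000, y)
  expect_equal(r_mm$or, r$or, tolerance = 1e-8)
})

test_that("per-category selection applies the min-p rule with the 0.2 gate
           and lexicographic ties", {
  pv <- data.frame(
    feature = c("volume", "mass", "energy", "range", "aaa", "bbb", "ccc"),
    category = c("global", "global", "histogram", "histogram",
                 "local", "local", "local"),
    p = c(0.5, 0.25, 0.06, 0.19, 0.1, 0.1, 0.4))
  sel <- select_per_category(pv)
  expect_true(is.na(sel$feature[sel$category == "global"]))  # none < 0.2
  expect_equal(sel$feature[sel$category == "histogram"], "energy")
  expect_equal(sel$feature[sel$category == "local"], "aaa")  # tie -> lexical
  expect_true(all(is.na(sel$p) | sel$p < 0.2))
  # NA p-values (flagged fits) never win
  pv2 <- data.frame(feature = c("f1", "f2"), category = "g",
                    p = c(NA, 0.15))
  expect_equal(select_per_category(pv2)$feature, "f2")
})

test_that("a single selected feature reduces the multivariate fit to the
           univariate one, and no selection gives a no-model entry", {
  set.seed(41)
  n <- 300
  d <- data.frame(x = rnorm(n))
  d$y <- rbinom(n, 1, plogis(0.6 * d$x))
  uni <- univariate_logistic(d$x, d$y)
  multi <- multivariate_logistic(d, "x", "y")
  expect_equal(log(multi$terms$or), log(uni$or), tolerance = 1e-6)
  expect_equal(multi$terms$p, uni$p, tolerance = 1e-6)

  expect_equal(multivariate_logistic(d, character(0), "y")$flag, "no model")
})

test_that("AUC is the Mann-Whitney statistic with midrank ties", {
  expect_equal(roc_auc(1:10, c(rep(0, 5), rep(1, 5))), 1.0)
  expect_equal(roc_auc(rep(2, 10), c(rep(0, 5), rep(1, 5))), 0.5)
  set.seed(3)
  s <- rnorm(200); y <- rbinom(200, 1, 0.4)
  expect_equal(roc_auc(s, y) + roc_auc(-s, y), 1)
  if (requireNamespace("pROC", quietly = TRUE))
    expect_equal(roc_auc(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))))
  expect_error(roc_auc(s, rep(1, 200)), "both classes")
})

test_that("smoking association: exact Fisher p and null-calibrated Wilcoxon", {
  status <- rep(c("never", "current"), each = 20)
  altered <- rep(c(0, 1), 20)
  r <- smoking_association(status, runif(40, 0, 60), altered)
  expect_equal(r$fisher_p, 1.0)   # balanced 2x2 table [[10,10],[10,10]]

  tab <- matrix(c(8, 1, 2, 5), 2)   # [[8,2],[1,5]]
  expect_equal(fisher.test(tab)$p.value, brute_fisher_2x2(tab),
               tolerance = 1e-10)

  set.seed(91)
  hits <- 0
  for (i in 1:200) {
    py <- rlnorm(60, log(30), 0.5)
    alt <- rbinom(60, 1, 0.5)
    if (sum(alt) %in% c(0, 60)) next
    p <- suppressWarnings(wilcox.test(py[alt == 1], py[alt == 0])$p.value)
    if (p > 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.9)

  expect_equal(smoking_association(rep("never", 10), runif(10),
                                   rep(1, 10))$flag, "degenerate table")
})

test_that("category-driving features are recovered from simulated cohorts", {
  drivers <- c(histogram = "range", shape = "surface_area_mm2",
               local = "maximum_probability")
  cats <- clinicoradiological_feature_list()
  cats <- cats[cats$category %in% names(drivers), ]
  hits <- setNames(numeric(length(drivers)), names(drivers))
  n_rep <- 20
  for (rep in 1:n_rep) {
    spec <- cohort_spec(
      n = 1000,
      pathway_models = list(
        redox_stress = list(intercept = 0,
                            coef = c(range = 0.8, surface_area_mm2 = -0.8,
                                     maximum_probability = 0.8)),
        apoptosis = list(intercept = 0, coef = c(range = 0)),
        proliferation = list(intercept = 0, coef = c(range = 0)),
        differentiation = list(intercept = 0, coef = c(range = 0)),
        chromatin_remodelers = list(intercept = 0, coef = c(range = 0))),
      seed = 1000 + rep)
    co <- simulate_cohort(spec)$cohort
    r <- associate_pathway(co, "redox_stress", categories = cats)
    for (cc in names(drivers))
      if (identical(r$selection$feature[r$selection$category == cc],
                    unname(drivers[cc])))
        hits[cc] <- hits[cc] + 1
  }
  expect_true(all(hits / n_rep >= 0.9))
})
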