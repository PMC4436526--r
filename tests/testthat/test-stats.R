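test_that("Fisher transform and inverse are exact and mutually inverse", {
  expect_equal(fisher_z(0), 0)
  expect_equal(inverse_fisher(0), 0)
  # reported condition means and their correlation equivalents
  expect_equal(inverse_fisher(1.28), 0.856, tolerance = 0.001 / 0.856)
  expect_equal(inverse_fisher(1.13), 0.811, tolerance = 0.001 / 0.811)
  z <- seq(-3, 3, by = 0.25)
  expect_lt(max(abs(fisher_z(inverse_fisher(z)) - z)), 1e-12)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_lt(max(abs(inverse_fisher(fisher_z(r)) - r)), 1e-12)
  # strictly increasing and odd
  expect_true(all(diff(inverse_fisher(z)) > 0))
  expect_equal(inverse_fisher(-z), -inverse_fisher(z))
  expect_error(fisher_z(1), "clip")
  expect_error(fisher_z(c(0.5, -1)), "clip")
})

test_that("condition tables are complete and correctly shaped", {
  fits <- list()
  for (p in paste0("p", 1:12))
    for (fb in c("face_to_face", "video"))
      for (df in c("simple", "complex"))
        fits[[length(fits) + 1]] <- fake_fit(p, fb, df, z = rnorm(1))
  tab <- build_condition_table(fits)
  expect_s3_class(tab, "condition_table")
  expect_equal(nrow(tab), 12 * 4 * 7)          # 48 person-condition rows per DV
  expect_equal(nrow(unique(tab[, c("person_id", "feedback", "difficulty")])), 48)

  expect_error(build_condition_table(fits[-3]), "missing condition")
})

test_that("constant per-trial correlations give the exact Fisher Z", {
  # a perfect-copy dyad: every trial's r clips to 1 - 1e-7, so with the
  # transform-before-average convention the mean Z is exactly fisher_z of
  # the clipped value, for every dependent variable
  set.seed(120)
  act <- synth_actor(n_trials = 2, trial_s = 8, rest_s = 3)
  copy <- synth_imitator(act$recording, 0, 0, 1)$recording
  fit <- suppressWarnings(
    dyad_coupling(act$recording, copy, preprocess = FALSE,
                  windows = act$truth$trial_windows, max_lag_s = 0.5))
  expect_equal(fit$means$z_mean, rep(fisher_z(1 - 1e-7), 7))
  expect_equal(fit$means$lag_mean_s, rep(0, 7))
  fit2 <- suppressWarnings(
    dyad_coupling(act$recording, copy, preprocess = FALSE,
                  windows = act$truth$trial_windows, max_lag_s = 0.5,
                  z_before_mean = FALSE))
  expect_equal(fit2$means$z_mean, fisher_z(pmin(fit2$means$r_abs_mean, 1 - 1e-7)))
})

test_that("identical condition values give null tests exactly", {
  tab <- make_table(n = 6, value = function(p, fb, df, dv) 0.8)
  for (dv_set in c("grip_position", "joint_angles", "aperture")) {
    res <- rm_2x2_test(tab, dv_set, "Z")
    expect_true(all(res$F == 0))
    expect_true(all(res$p == 1))
    expect_true(all(res$partial_eta_sq == 0))
  }
})

test_that("univariate tests match aov with within-person error strata", {
  set.seed(121)
  tab <- make_table(n = 12, dvs = "aperture")
  res <- rm_2x2_test(tab, "aperture", "Z")
  expect_equal(res$df1, rep(1, 3))
  expect_equal(res$df2, rep(11, 3))

  d <- tab
  d$feedback <- factor(d$feedback); d$difficulty <- factor(d$difficulty)
  d$person_id <- factor(d$person_id)
  fit <- stats::aov(z_mean ~ feedback * difficulty +
                      Error(person_id / (feedback * difficulty)), data = d)
  sm <- summary(fit)
  aovF <- c(sm[["Error: person_id:feedback"]][[1]]["feedback", "F value"],
            sm[["Error: person_id:difficulty"]][[1]]["difficulty", "F value"],
            sm[["Error: person_id:feedback:difficulty"]][[1]][
              "feedback:difficulty", "F value"])
  aovP <- c(sm[["Error: person_id:feedback"]][[1]]["feedback", "Pr(>F)"],
            sm[["Error: person_id:difficulty"]][[1]]["difficulty", "Pr(>F)"],
            sm[["Error: person_id:feedback:difficulty"]][[1]][
              "feedback:difficulty", "Pr(>F)"])
  expect_equal(res$F, aovF, tolerance = 1e-8)
  expect_equal(res$p, aovP, tolerance = 1e-8)
})

test_that("univariate F equals the squared paired t on condition contrasts", {
  set.seed(122)
  tab <- make_table(n = 10, dvs = "aperture")
  res <- rm_2x2_test(tab, "aperture", "Z")
  # feedback contrast per person, averaged over difficulty
  y <- tab$z_mean
  f2f <- tapply(y[tab$feedback == "face_to_face"],
                tab$person_id[tab$feedback == "face_to_face"], mean)
  vid <- tapply(y[tab$feedback == "video"],
                tab$person_id[tab$feedback == "video"], mean)
  tt <- t.test(f2f[names(vid)] - vid)
  expect_equal(res$F[res$effect == "feedback"],
               unname(tt$statistic^2), tolerance = 1e-8)
})

test_that("multivariate tests match the mlm Pillai route", {
  set.seed(123)
  tab <- make_table(n = 12, dvs = c("grip_x", "grip_y", "grip_z"))
  res <- rm_2x2_test(tab, "grip_position", "Z")
  mres <- res[res$scope == "multivariate", ]
  expect_equal(mres$df1, rep(3, 3))
  expect_equal(mres$df2, rep(9, 3))
  for (eff in c("feedback", "difficulty", "interaction")) {
    D <- dyadkin:::person_contrasts(tab, c("grip_x", "grip_y", "grip_z"),
                                    "z_mean", eff)
    an <- anova(lm(D ~ 1), test = "Pillai")
    expect_equal(mres$F[mres$effect == eff], an["(Intercept)", "approx F"],
                 tolerance = 1e-8)
    expect_equal(mres$p[mres$effect == eff], an["(Intercept)", "Pr(>F)"],
                 tolerance = 1e-8)
    expect_equal(mres$partial_eta_sq[mres$effect == eff],
                 an["(Intercept)", "Pillai"], tolerance = 1e-8)
  }
})

test_that("an injected feedback effect is detected on the right variable", {
  hits <- 0
  for (s in 1:10) {
    set.seed(2000 + s)
    tab <- make_table(n = 12, dvs = c("grip_x", "grip_y", "grip_z"),
                      value = function(p, fb, df, dv) {
                        rnorm(1, sd = 0.1) +
                          if (dv == "grip_x" && fb == "face_to_face") 0.5 else 0
                      })
    res <- rm_2x2_test(tab, "grip_position", "Z")
    uni <- res[res$scope == "univariate" & res$dv == "grip_x", ]
    if (uni$p[uni$effect == "feedback"] < 0.01 &&
        uni$p[uni$effect == "difficulty"] > 0.1) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("unbalanced or undersized tables are rejected", {
  tab <- make_table(n = 12, dvs = "aperture")
  expect_error(rm_2x2_test(tab[-1, ], "aperture", "Z"), "unbalanced")
  small <- make_table(n = 2, dvs = "aperture")
  expect_error(rm_2x2_test(small, "aperture", "Z"), "at least 3")
})
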