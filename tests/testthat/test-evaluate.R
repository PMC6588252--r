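test_that("confusion matrices count every eye in the right cell", {
  truth <- c("HC", "HC", "AD", "AD", "PD", "PD")
  cm <- confusion(truth, truth)
  expect_equal(unname(diag(cm[, 1:3])), c(2, 2, 2))
  expect_equal(sum(cm), 6)

  cm2 <- confusion(rep("Unknown", 6), truth)
  expect_equal(unname(cm2[, "Unknown"]), c(2, 2, 2))
  expect_equal(sum(cm2[, 1:3]), 0)

  # hand-built six-eye example
  pred <- c("HC", "AD", "AD", "Unknown", "PD", "HC")
  cm3 <- confusion(pred, truth)
  expect_equal(unname(cm3["HC", ]), c(1, 1, 0, 0))
  expect_equal(unname(cm3["AD", ]), c(0, 1, 0, 1))
  expect_equal(unname(cm3["PD", ]), c(1, 0, 1, 0))

  expect_error(confusion(c("HC", "XX"), c("HC", "AD")), "outside")
  expect_error(confusion(c("HC", "HC"), c("HC", "Unknown")), "outside")
})

test_that("sensitivity, specificity and accuracy follow the stated formulas", {
  perfect <- confusion(c("HC", "AD", "PD"), c("HC", "AD", "PD"))
  m <- class_metrics(perfect)
  expect_equal(unname(m$sensitivity), rep(100, 3))
  expect_equal(unname(m$specificity), rep(100, 3))
  expect_equal(m$accuracy, 100)

  # all Unknown: sensitivity 0, specificity 100 (never predicted c)
  cmu <- confusion(rep("Unknown", 4), rep("HC", 4))
  mu <- class_metrics(cmu)
  expect_equal(unname(mu$sensitivity["HC"]), 0)
  expect_true(is.na(mu$specificity["HC"]))  # no negatives present
  expect_equal(mu$accuracy, 0)

  # hand-computed 3x4 example
  cm <- rbind(c(8, 1, 1, 0), c(2, 7, 1, 0), c(1, 1, 7, 1))
  dimnames(cm) <- list(c("HC", "AD", "PD"), c("HC", "AD", "PD", "Unknown"))
  mm <- class_metrics(cm)
  expect_equal(unname(mm$sensitivity), c(80, 70, 70))
  expect_equal(mm$accuracy, 100 * 22 / 30)
  expect_equal(unname(mm$specificity["HC"]), 85)
  expect_equal(unname(mm$specificity["AD"]), 90)
  expect_equal(unname(mm$specificity["PD"]), 90)
})

test_that("two-eye agreement rates follow the subject-level definitions", {
  mk <- function(subj, pred, truth)
    data.frame(subject_id = subj, predicted = pred, truth = truth,
               stringsAsFactors = FALSE)
  # all subjects agree and are correct
  d1 <- mk(rep(c("s1", "s2"), each = 2), c("HC", "HC", "AD", "AD"),
           c("HC", "HC", "AD", "AD"))
  r1 <- two_eye_metrics(d1)
  expect_equal(r1$pct_same, 100)
  expect_equal(r1$pct_correct_given_same, 100)

  # always disagreeing eyes: conditional rate undefined
  d2 <- mk(rep("s1", 2), c("HC", "AD"), c("HC", "HC"))
  r2 <- two_eye_metrics(d2)
  expect_equal(r2$pct_same, 0)
  expect_true(is.na(r2$pct_correct_given_same))

  # five-subject hand case: s1 agree+correct, s2 agree+wrong,
  # s3 agree on Unknown (agreeing but not correct), s4 disagree,
  # s5 single-eye (excluded)
  d3 <- mk(c("s1", "s1", "s2", "s2", "s3", "s3", "s4", "s4", "s5"),
           c("HC", "HC", "PD", "PD", "Unknown", "Unknown", "AD", "PD", "HC"),
           c("HC", "HC", "AD", "AD", "PD", "PD", "AD", "AD", "HC"))
  r3 <- two_eye_metrics(d3)
  expect_equal(r3$n_subjects, 4)
  expect_equal(r3$n_single_eye, 1)
  expect_equal(r3$pct_same, 75)
  expect_equal(r3$pct_correct_given_same, 100 / 3)

  expect_equal(unknown_rate(c("HC", "Unknown", rep("AD", 48))), 2)
  expect_equal(unknown_rate(c("HC", "AD")), 0)
})

test_that("run summaries use linear-interpolation quantiles and stay ordered", {
  m <- data.frame(accuracy = c(60, 70, 80, 90, 100))
  s <- summarize_runs(m)
  expect_equal(s["Median", "accuracy"], 80)
  expect_equal(s["Q1", "accuracy"], 70)
  expect_equal(s["Q3", "accuracy"], 90)
  expect_equal(s["Max", "accuracy"], 100)
  expect_equal(s["Min", "accuracy"], 60)

  same <- data.frame(accuracy = rep(73.2, 8), unknown = rep(1.4, 8))
  ss <- summarize_runs(same)
  expect_true(all(ss$accuracy == 73.2))
  expect_true(all(ss$unknown == 1.4))

  set.seed(31)
  r <- data.frame(x = rnorm(47))
  sr <- summarize_runs(r)$x
  expect_true(all(diff(sr) <= 0))  # Max >= Q3 >= Median >= Q1 >= Min
})

test_that("feature origin tallies count selected features by region", {
  specs <- data.frame(
    pair = rep(c("HC-AD", "HC-AD", "AD-PD"), each = 2),
    feature = c("ST_contrast", "SN_energy", "ST_entropy", "G_var_p15",
                "IN_idn", "G_var_m45"),
    stringsAsFactors = FALSE)
  tab <- feature_origin_tally(specs)
  g <- function(pair, origin) {
    row <- tab[tab$pair == pair & tab$origin == origin, ]
    if (nrow(row) == 0) 0 else row$count
  }
  expect_equal(g("HC-AD", "superior-temporal"), 2)
  expect_equal(g("HC-AD", "superior-nasal"), 1)
  expect_equal(g("HC-AD", "global"), 1)
  expect_equal(g("AD-PD", "inferior-nasal"), 1)
  expect_equal(g("AD-PD", "global"), 1)
  # conservation within each pair
  expect_equal(sum(tab$count[tab$pair == "HC-AD"]), 4)
  expect_equal(sum(tab$pct[tab$pair == "AD-PD"]), 100)

  # a model bank tally conserves models x features
  layers <- c("GCL", "IPL")
  decisions <- setNames(
    as.list(rep(c("AD", "HC", "AD"), length(layers))),
    unlist(lapply(layers, function(l)
      paste(l, c("HC-AD", "HC-PD", "AD-PD"), sep = "|"))))
  bank <- stub_bank(decisions, layers)
  tb <- feature_origin_tally(bank)
  expect_equal(sum(tb$count), length(bank) * 1)  # stubs carry one feature
})

test_that("feature-thickness correlations recover known relationships", {
  set.seed(41)
  n <- 500
  thick <- rnorm(n, 300, 20)
  base <- data.frame(subject_id = sprintf("s%03d", seq_len(n)),
                     eye = "right", class_label = "HC", layer = "GCL",
                     stringsAsFactors = FALSE)
  fm <- feature_manifest()$name
  feats <- cbind(base, as.data.frame(setNames(
    lapply(fm, function(f) rnorm(n)), fm), check.names = FALSE))
  # plant: one feature proportional to thickness, one ~rho = 0.7, rest noise
  feats[["ST_contrast"]] <- 2 * thick + 5
  rho <- 0.7
  feats[["SN_energy"]] <- rho * scale(thick)[, 1] +
    sqrt(1 - rho^2) * rnorm(n)
  th <- cbind(base[, c("subject_id", "eye", "layer")],
              ST = thick, SN = thick, IT = thick, IN = thick)
  sel <- data.frame(layer = "GCL",
                    feature = c("ST_contrast", "SN_energy", "IT_idn"),
                    stringsAsFactors = FALSE)
  out <- feature_thickness_correlation(feats, th, sel)
  r_of <- function(f) out$r[out$feature == f]
  expect_equal(r_of("ST_contrast"), 1, tolerance = 1e-10)
  expect_equal(r_of("SN_energy"), 0.7, tolerance = 0.12)
  expect_lt(abs(r_of("IT_idn")), 0.12)
  expect_equal(out$strength[out$feature == "ST_contrast"], "strong")

  # fewer than 3 pairs: undefined, flagged as NA
  out2 <- feature_thickness_correlation(feats[1:2, ], th[1:2, ], sel[1, ])
  expect_true(is.na(out2$r))
})

test_that("sector ANOVA is calibrated under the null and powered under shifts", {
  set.seed(51)
  groups <- rep(c("HC", "AD", "PD"), each = 12)
  # null calibration at a modest replicate count (the acceptance suite
  # runs the full calibration)
  reps <- 400
  p <- replicate(reps, {
    sector_anova(data.frame(central = rnorm(36, 300, 15)), groups)$p
  })
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)

  # shifted means: p collapses with n
  shifted <- data.frame(central = rnorm(36, 300, 10) +
                          rep(c(0, 15, 30), each = 12))
  expect_lt(sector_anova(shifted, groups)$p, 0.01)

  expect_error(sector_anova(data.frame(x = rnorm(4)), rep("HC", 4)),
               "two groups")
  expect_warning(sector_anova(data.frame(x = rep(1, 36)), groups),
                 "degenerate")
})
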