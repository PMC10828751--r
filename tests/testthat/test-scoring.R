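test_that("component scorers reproduce the banding grid, including resolved boundaries", {
  # bmi: >=20 -> 0, [18,20) -> 1, [16,18) -> 2, <16 -> 3
  expect_identical(score_bmi(c(22, 19, 15.9, 20, 18, 16, 17.99)),
                   c(0L, 1L, 3L, 0L, 1L, 2L, 2L))
  # albumin: >=35 -> 0 (boundary to the less severe band), [28,32) -> 2
  expect_identical(score_albumin(c(36, 30, 27.9, 35, 32, 31.5)),
                   c(0L, 2L, 3L, 0L, 1L, 2L))
  # vintage: the 3-4 y band is closed at 4
  expect_identical(score_vintage(c(0.5, 2, 5, 4, 3, 1, 0)),
                   c(0L, 1L, 3L, 2L, 2L, 1L, 0L))
  # ferritin: boundary to the lower band; the 700-701 and 800-801 gaps close
  expect_identical(score_ferritin(c(500, 750, 1001, 700.5, 700, 800, 1000)),
                   c(0L, 1L, 3L, 1L, 0L, 1L, 2L))
  # comorbidity: zero maps to the least severe score
  expect_identical(score_comorbidity(c(1, 3, 5, 0, 2, 4)),
                   c(0L, 2L, 3L, 0L, 1L, 3L))
  expect_identical(score_functional(c("normal", "dependent_difficulty",
                                      "bed_chair_bound", "occasional_difficulty")),
                   c(0L, 2L, 3L, 1L))
  expect_identical(score_functional(c(0, 3)), c(0L, 3L))
})

test_that("scorers reject invalid, missing or out-of-range inputs", {
  expect_error(score_bmi(0), class = "pewrisk_invalid_input")
  expect_error(score_bmi(NA_real_), class = "pewrisk_invalid_input")
  expect_error(score_albumin(-1), class = "pewrisk_invalid_input")
  expect_error(score_vintage(-0.1), class = "pewrisk_invalid_input")
  expect_error(score_ferritin(-5), class = "pewrisk_invalid_input")
  expect_error(score_comorbidity(-1), class = "pewrisk_invalid_input")
  expect_error(score_comorbidity(1.5), class = "pewrisk_invalid_input")
  expect_error(score_functional("walking"), class = "pewrisk_invalid_input")
  expect_error(score_functional(4), class = "pewrisk_invalid_input")
})

test_that("score_components sums the six scorers and names missing fields", {
  best <- make_patient(bmi = 22, functional = "normal", vintage_years = 0.5,
                       albumin_gL = 40, ferritin_ugL = 200,
                       dm = 0, htn = 1, ihd = 0, cvd = 0)
  expect_identical(score_components(best)$total, 0L)
  worst <- make_patient(bmi = 15, functional = "bed_chair_bound",
                        vintage_years = 6, albumin_gL = 25,
                        ferritin_ugL = 1200, dm = 1, htn = 1, ihd = 1, cvd = 1)
  expect_identical(score_components(worst)$total, 18L)
  # value frozen from the single-variable scorers invoked independently
  mid <- make_patient(bmi = 21, functional = "dependent_difficulty",
                      vintage_years = 5, albumin_gL = 33, ferritin_ugL = 650,
                      dm = 1, htn = 1, ihd = 1, cvd = 0)
  got <- score_components(mid)
  expect_identical(unlist(got[c("bmi_score", "functional_score", "vintage_score",
                                "albumin_score", "ferritin_score",
                                "comorbidity_score")], use.names = FALSE),
                   c(0L, 2L, 3L, 1L, 0L, 2L))
  expect_identical(got$total, 8L)

  missing_alb <- make_patient(albumin_gL = NA)
  expect_error(score_components(missing_alb), "albumin_gL",
               class = "pewrisk_missing_data")
  expect_error(score_components(make_patient()[, -5]),
               class = "pewrisk_missing_data")
})

test_that("classify_risk is a step function flipping exactly at the threshold", {
  for (total in 0:18) {
    expect_identical(classify_risk(total, 6),
                     if (total >= 6) "high" else "low")
  }
  expect_identical(classify_risk(c(5, 6, 13)), c("low", "high", "high"))
  expect_identical(classify_risk(3, threshold = 2), "high")
  expect_error(classify_risk(19), class = "pewrisk_invalid_input")
  expect_error(classify_risk(-1), class = "pewrisk_invalid_input")
  expect_error(classify_risk(5, threshold = 0), class = "pewrisk_invalid_input")
})

test_that("aggregate_quarters applies each policy per patient", {
  coh <- rbind(make_patient("a", vintage_years = 0.5, quarter = 0L),
               make_patient("a", vintage_years = 6,
                            functional = "bed_chair_bound", quarter = 1L),
               make_patient("a", vintage_years = 2, quarter = 2L),
               make_patient("b", quarter = 0L))
  sc <- score_components(coh)
  # per-quarter totals for patient a: 0, 6, 1; patient b: 0
  agg_max <- aggregate_quarters(sc, "maximum")
  expect_identical(nrow(agg_max), 2L)
  expect_identical(agg_max$total[agg_max$patient_id == "a"], 6L)
  expect_identical(aggregate_quarters(sc, "baseline")$total, c(0L, 0L))
  expect_identical(aggregate_quarters(sc, "latest")$total[1], 1L)
  mean_r <- aggregate_quarters(sc, "mean_rounded")
  a_row <- mean_r[mean_r$patient_id == "a", ]
  # vintage scores 0,3,1 -> mean 1.33 -> 1; functional 0,3,0 -> 1
  expect_identical(a_row$vintage_score, 1L)
  expect_identical(a_row$total, sum(unlist(a_row[grep("_score$", names(a_row))])))
  # singleton passes through unchanged
  expect_identical(aggregate_quarters(sc[4, ], "maximum")$total, 0L)
  expect_error(aggregate_quarters(sc[0, ]), class = "pewrisk_invalid_input")
})

test_that("random snapshots keep components in 0..3 and total equal to their sum", {
  set.seed(101)
  for (i in 1:200) {
    p <- make_patient(bmi = runif(1, 12, 45),
                      functional = sample(default_bands()$functional, 1),
                      vintage_years = runif(1, 0, 25),
                      albumin_gL = runif(1, 15, 50),
                      ferritin_ugL = runif(1, 10, 3000),
                      dm = rbinom(1, 1, 0.5), htn = rbinom(1, 1, 0.5),
                      ihd = rbinom(1, 1, 0.5), cvd = rbinom(1, 1, 0.5))
    s <- score_components(p)
    comps <- unlist(s[grep("_score$", names(s))])
    expect_true(all(comps %in% 0:3))
    expect_identical(s$total, sum(comps))
    expect_true(s$total >= 0 && s$total <= 18)
  }
})

test_that("worsening any component never decreases the total score", {
  set.seed(202)
  fc <- default_bands()$functional
  for (i in 1:200) {
    p <- make_patient(bmi = runif(1, 13, 44),
                      functional = sample(fc[1:3], 1),
                      vintage_years = runif(1, 0, 20),
                      albumin_gL = runif(1, 16, 49),
                      ferritin_ugL = runif(1, 10, 2500),
                      dm = rbinom(1, 1, 0.5), htn = rbinom(1, 1, 0.5),
                      ihd = rbinom(1, 1, 0.5), cvd = 0)
    t0 <- score_components(p)$total
    worse <- p
    worse$bmi <- p$bmi * runif(1, 0.5, 1)
    worse$albumin_gL <- p$albumin_gL * runif(1, 0.5, 1)
    worse$ferritin_ugL <- p$ferritin_ugL * runif(1, 1, 2)
    worse$vintage_years <- p$vintage_years + runif(1, 0, 5)
    worse$functional <- fc[match(p$functional, fc) + 1]  # one level worse
    worse$cvd <- 1                                       # one more comorbidity
    expect_gte(score_components(worse)$total, t0)
  }
})

test_that("each continuous scorer partitions the positive axis with no gaps", {
  set.seed(303)
  edges <- list(bmi = c(16, 18, 20), albumin = c(28, 32, 35),
                vintage = c(1, 3, 4), ferritin = c(700, 800, 1000))
  eps <- 1e-9
  for (comp in names(edges)) {
    scorer <- switch(comp, bmi = score_bmi, albumin = score_albumin,
                     vintage = score_vintage, ferritin = score_ferritin)
    e <- edges[[comp]]
    grid <- sort(c(runif(500, 0.01, max(e) * 1.5), e, e - eps, e + eps))
    s <- scorer(grid)
    expect_true(all(s %in% 0:3))            # every value maps to one band
    expect_length(s, length(grid))
    expect_setequal(unique(s), 0:3)         # all four bands reachable
    severity <- if (comp %in% c("bmi", "albumin")) rev(s) else s
    expect_true(all(diff(severity) >= 0))   # monotone in severity direction
  }
})

test_that("band cut positions are configurable via YAML and validated", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("albumin:", "  cuts: [30.0, 33.0, 36.0]", "threshold: 7"), cfg)
  b <- read_bands(cfg)
  expect_identical(b$albumin$cuts, c(30, 33, 36))
  expect_identical(b$threshold, 7L)
  expect_identical(b$bmi$cuts, c(16, 18, 20))  # untouched defaults persist
  expect_identical(score_albumin(35, b$albumin$cuts), 1L)
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("ferritin:", "  cuts: [800, 700, 1000]"), bad)
  expect_error(read_bands(bad), class = "pewrisk_config_error")
})
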