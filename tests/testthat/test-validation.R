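test_that("confusion metrics match hand arithmetic and handle zero denominators", {
  m <- confusion_metrics(10, 0, 0, 10)
  expect_equal(unlist(m), c(sensitivity = 1, specificity = 1, ppv = 1,
                            accuracy = 1))
  m2 <- confusion_metrics(0, 0, 5, 5)
  expect_equal(m2$sensitivity, 0)
  expect_true(is.na(m2$ppv))
  # random tables against independent hand formulas
  set.seed(3)
  for (i in 1:20) {
    k <- sample(0:500, 4, replace = TRUE)
    m3 <- confusion_metrics(k[1], k[2], k[3], k[4])
    if (k[1] + k[3] > 0) expect_equal(m3$sensitivity, k[1] / (k[1] + k[3]))
    if (k[4] + k[2] > 0) expect_equal(m3$specificity, k[4] / (k[4] + k[2]))
    if (k[1] + k[2] > 0) expect_equal(m3$ppv, k[1] / (k[1] + k[2]))
    expect_equal(m3$accuracy, (k[1] + k[4]) / sum(k))
  }
  expect_error(confusion_metrics(-1, 0, 0, 0))
})

test_that("scenario analysis reproduces the published linkage-table metrics", {
  tabs <- ra_validation_tables()
  dd <- scenario_analysis(tabs$datadriven)
  worst <- dd[dd$scenario == "worst", ]
  best <- dd[dd$scenario == "best", ]
  # 1323/(1323+265), 1323/4279, 3883/4279
  expect_equal(100 * worst$sensitivity, 83.3, tolerance = 0.001)
  expect_equal(100 * worst$ppv, 30.9, tolerance = 0.001)
  expect_equal(100 * best$ppv, 90.7, tolerance = 0.001)
  expect_equal(100 * attr(dd, "prevalence_worst"), 0.33, tolerance = 0.02)

  qof <- scenario_analysis(tabs$qof)
  expect_equal(100 * qof$sensitivity[qof$scenario == "worst"], 86.7,
               tolerance = 0.001)
  expect_equal(100 * qof$ppv[qof$scenario == "worst"], 29, tolerance = 0.005)
  expect_equal(100 * qof$sensitivity[qof$scenario == "best"], 95.2,
               tolerance = 0.001)
  expect_equal(100 * qof$ppv[qof$scenario == "best"], 89.2, tolerance = 0.001)

  th <- scenario_analysis(tabs$thomas)
  expect_equal(100 * th$sensitivity[th$scenario == "worst"], 83.9,
               tolerance = 0.001)
})

test_that("scenarios collapse to plain confusion metrics without missing data", {
  tab <- linkage_table(a = 30, b = 5, e = 0, c_ = 10, d = 200, f = 0)
  sa <- scenario_analysis(tab)
  cm <- confusion_metrics(tp = 30, fp = 5, fn = 10, tn = 200)
  for (sc in c("worst", "best")) {
    row <- sa[sa$scenario == sc, ]
    expect_equal(row$sensitivity, cm$sensitivity)
    expect_equal(row$specificity, cm$specificity)
    expect_equal(row$ppv, cm$ppv)
  }
})

test_that("worst <= best for sensitivity and PPV whenever unlinked cases exist", {
  set.seed(8)
  for (i in 1:25) {
    k <- sample(0:300, 6, replace = TRUE)
    tab <- linkage_table(k[1], k[2], e = k[3] + 1, c_ = k[4], d = k[5],
                         f = k[6])
    sa <- scenario_analysis(tab)
    w <- sa[sa$scenario == "worst", ]; b <- sa[sa$scenario == "best", ]
    if (!is.na(w$sensitivity) && !is.na(b$sensitivity))
      expect_lte(w$sensitivity, b$sensitivity)
    if (!is.na(w$ppv) && !is.na(b$ppv))
      expect_lte(w$ppv, b$ppv)
  }
})

test_that("linkage tables round-trip through their text format", {
  tab <- linkage_table(a = 12, b = 3, e = 40, c_ = 5, d = 100, f = 900,
                       g = 7, h = 11, population_size = 5000)
  path <- withr::local_tempfile(fileext = ".csv")
  write_linkage_table(tab, path)
  back <- read_linkage_table(path)
  expect_equal(back$cells, tab$cells)
  expect_equal(back$population_size, tab$population_size)
})

test_that("algorithm comparison is consistent with individual analyses", {
  tabs <- ra_validation_tables()
  rep <- compare_algorithms(tabs)
  expect_equal(nrow(rep), 6)
  expect_equal(rep$algorithm, rep(names(tabs), each = 2))
  for (nm in names(tabs)) {
    sa <- scenario_analysis(tabs[[nm]])
    sub <- rep[rep$algorithm == nm, ]
    expect_equal(sub$sensitivity, sa$sensitivity)
    expect_equal(sub$ppv, sa$ppv)
  }
  expect_error(compare_algorithms(list()), class = "codephen_input_error")
})

test_that("latent truth is bracketed by the scenario bounds on simulated linkage", {
  for (s in 1:10) {
    cfg <- sim_config(n_patients = 800, linkage_rate = 0.6, seed = 40 + s)
    d <- simulate_ehr(cfg)
    recs <- build_records(d$events, d$labels)
    cc <- cohort_classify(recs)
    tab <- tabulate_linkage(cc$labels, d$labels)
    sa <- scenario_analysis(tab)
    w <- sa[sa$scenario == "worst", ]; b <- sa[sa$scenario == "best", ]
    latent <- setNames(d$truth$latent$true_label, d$truth$latent$patient_id)
    pred <- setNames(cc$labels$phenotype, cc$labels$patient_id)
    ids <- names(pred)
    # latent PPV over every flagged patient is bracketed deterministically
    flagged <- ids[pred[ids] == "RA"]
    ppv_latent <- mean(latent[flagged] == "RA")
    expect_gte(ppv_latent, w$ppv - 1e-12)
    expect_lte(ppv_latent, b$ppv + 1e-12)
    # latent sensitivity over the patients the scenarios impute (linked
    # plus unlinked flagged) is bracketed likewise
    linked <- ids[ids %in% names(d$labels)]
    scope <- union(linked, flagged)
    tp <- sum(latent[scope] == "RA" & pred[scope] == "RA")
    fn <- sum(latent[scope] == "RA" & pred[scope] == "nonRA")
    sens_latent <- tp / (tp + fn)
    expect_gte(sens_latent, w$sensitivity - 1e-12)
    expect_lte(sens_latent, b$sensitivity + 1e-12)
  }
})

test_that("yearly prevalence equals brute-force reclassification at each cutoff", {
  cfg <- sim_config(n_patients = 150, seed = 55)
  d <- simulate_ehr(cfg)
  res <- prevalence_by_year(d$events, years = c(2002, 2006, 2010))
  expect_equal(nrow(res), 3)
  for (i in seq_len(nrow(res))) {
    cutoff <- as.Date(sprintf("%d-12-31", res$year[i]))
    sub <- d$events[d$events$date <= cutoff, ]
    cc <- cohort_classify(build_records(sub))
    expect_equal(res$n_flagged[i], sum(cc$labels$phenotype == "RA"))
  }
  # denominator is the full registered cohort at every year
  expect_equal(unique(res$n_patients),
               length(unique(d$events$patient_id)))
  # single patient flagged from 2005 onward: fraction steps up and stays
  ev1 <- data.frame(patient_id = "p1",
                    code = c("N04z1", "j61z1"),
                    date = as.Date(c("2005-06-01", "2005-07-01")),
                    source = "primary")
  res1 <- prevalence_by_year(ev1, years = 2003:2007)
  expect_equal(res1$prevalence, c(0, 0, 1, 1, 1))
  # empty cohort: empty report
  expect_equal(nrow(prevalence_by_year(ev1[0, ], years = 2000:2001)), 0)
})
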