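test_that("rule-of-five counts violations correctly", {
  expect_true(passesRo5(compoundRow(mw = 400, alogp = 3, h_donors = 2,
                                    h_acceptors = 5)))
  expect_false(passesRo5(compoundRow(mw = 600, alogp = 6, h_donors = 6,
                                     h_acceptors = 11)))
  one <- compoundRow(mw = 550, alogp = 3, h_donors = 2, h_acceptors = 5)
  expect_true(passesRo5(one, maxViolations = 1))
  expect_false(passesRo5(one, maxViolations = 0))
  expect_error(passesRo5(data.frame(mw = 400, alogp = 3)), "h_donors")
})

test_that("the ADMET screen applies strict thresholds with an OR branch", {
  expect_true(passesScreen(compoundRow(ob = 35, caco2 = 0.5, dl = 0.2,
                                       half_life = 4)))
  ## low bioavailability rescued by rule-of-five compliance
  expect_true(passesScreen(compoundRow(ob = 25, caco2 = 0.5, dl = 0.19,
                                       half_life = 3.5)))
  ## neither branch of oral potential
  expect_false(passesScreen(compoundRow(ob = 25, mw = 600, alogp = 6,
                                        h_donors = 6, h_acceptors = 11)))
  ## boundaries are strict
  expect_false(passesScreen(compoundRow(caco2 = 0.4)))
  expect_false(passesScreen(compoundRow(dl = 0.18)))
  expect_false(passesScreen(compoundRow(half_life = 3)))
  expect_false(passesScreen(compoundRow(ob = 30, mw = 600, alogp = 6,
                                        h_donors = 6, h_acceptors = 11)))
})

test_that("the screen is monotone in the continuous descriptors", {
  set.seed(21)
  for (i in 1:50) {
    base <- compoundRow(ob = stats::runif(1, 0, 60),
                        caco2 = stats::runif(1, -0.5, 1.5),
                        dl = stats::runif(1, 0, 0.5),
                        half_life = stats::runif(1, 0, 10))
    if (!passesScreen(base)) next
    for (col in c("ob", "caco2", "dl", "half_life")) {
      up <- base
      up[[col]] <- up[[col]] + stats::runif(1, 0, 5)
      expect_true(passesScreen(up))
    }
  }
})

test_that("screenCompounds keeps order, reports failures, is idempotent", {
  cfg <- syntheticConfig(seed = 8, n_compounds = 200, pass_fraction = 0.5)
  tab <- genCompoundTable(cfg)
  res <- screenCompounds(tab)
  expect_gte(nrow(res$kept), 80)
  expect_lte(nrow(res$kept), 120)
  expect_equal(res$kept$compound_id,
               tab$compound_id[tab$compound_id %in% res$kept$compound_id])

  ## a compound can fail several criteria, so totals >= rejected
  expect_gte(sum(res$report), nrow(tab) - nrow(res$kept))

  ## idempotence: screening the kept set changes nothing
  again <- screenCompounds(res$kept)
  expect_equal(again$kept, res$kept)
  expect_equal(unname(again$report), rep(0L, 4))

  allPass <- genCompoundTable(syntheticConfig(seed = 8, n_compounds = 20,
                                              pass_fraction = 1))
  expect_equal(screenCompounds(allPass)$kept, allPass)

  empty <- screenCompounds(allPass[0, ])
  expect_equal(nrow(empty$kept), 0)
  expect_equal(sum(empty$report), 0)
})

test_that("toxicity summaries count active labels per endpoint", {
  df <- data.frame(hepatotoxicity = c("active", "inactive", "active"),
                   cytotoxicity = c("inactive", "inactive", "inactive"))
  tox <- summarizeToxicity(df)
  expect_equal(tox$n_active[tox$endpoint == "hepatotoxicity"], 2L)
  expect_equal(tox$n_active[tox$endpoint == "cytotoxicity"], 0L)
  ## endpoints absent from the table are reported as zero
  expect_setequal(tox$endpoint,
                  c("hepatotoxicity", "carcinogenicity", "immunotoxicity",
                    "mutagenicity", "cytotoxicity", "cardiotoxicity"))
  ## permutation invariance
  expect_equal(summarizeToxicity(df[c(3, 1, 2), ]), tox)
  expect_error(summarizeToxicity(data.frame(cytotoxicity = "toxicish")),
               "unknown toxicity label")
})
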