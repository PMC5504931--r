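# Hand-built five-patient fixture exercising the cascade rules.
fixtureCohort <- function() {
  rows <- rbind(
    # P1: gyn index diagnosis + valid CHM visit
    claimsRow("P1", "V01", specialty = "gynecology", dx = "617.0",
              ther = "", code = ""),
    claimsRow("P1", "V02", code = "A"),
    # P2: gyn index, CHM visit with endometriosis in second position only
    claimsRow("P2", "V03", specialty = "gynecology", dx = "617.9",
              ther = "", code = ""),
    claimsRow("P2", "V04", dx = "625.3;617.0", code = "A"),
    # P3: matching diagnosis but never at a gynecology visit
    claimsRow("P3", "V05", specialty = "tcm", dx = "617.0", code = "A"),
    # P4: gyn index, CHM visit with acupuncture co-management
    claimsRow("P4", "V06", specialty = "gynecology", dx = "617.1",
              ther = "", code = ""),
    claimsRow("P4", "V07", ther = "chm;acupuncture", code = "A"),
    # P5: gyn visit without matching diagnosis
    claimsRow("P5", "V08", specialty = "gynecology", dx = "625.3",
              code = "A"))
  readClaims(writeClaimsFixture(rows))
}

test_that("eligibility requires a matching diagnosis at a gynecology visit", {
  cohort <- fixtureCohort()
  expect_identical(indexPatients(cohort), c("P1", "P2", "P4"))
  # with the specialty requirement lifted, P3 and P5's codes decide
  loose <- cohortFilter(requireGynIndex = FALSE)
  expect_identical(indexPatients(cohort, loose), c("P1", "P2", "P3", "P4"))
  none <- chmCohort(visits(cohort)[0, ], visitItems(cohort)[0, ])
  expect_identical(indexPatients(none), character())
})

test_that("the cascade excludes non-primary diagnoses and excluded therapies", {
  cohort <- fixtureCohort()
  res <- filterCohort(cohort)
  # only P1's CHM visit survives: V04 fails the first-position rule,
  # V07 carries acupuncture, P3/P5 are not eligible
  expect_identical(visits(res$cohort)$visit_id, "V02")
  cnt <- attrition(res$attrition)
  expect_identical(as.integer(cnt), c(8L, 6L, 6L, 5L, 4L, 1L))
  # relaxing the primary-position rule admits V04
  resAny <- filterCohort(cohort, cohortFilter(requirePrimaryDx = FALSE))
  expect_identical(visits(resAny$cohort)$visit_id, c("V02", "V04"))
})

test_that("age bounds are inclusive in completed years at the visit date", {
  mk <- function(vdate, bdate)
    readClaims(writeClaimsFixture(rbind(
      claimsRow("P1", "V01", specialty = "gynecology", dx = "617.0",
                vdate = vdate, bdate = bdate, ther = "", code = ""),
      claimsRow("P1", "V02", vdate = vdate, bdate = bdate, code = "A"))))
  retained <- function(cohort)
    visits(filterCohort(cohort)$cohort)$visit_id
  # exactly 20 on the visit day: retained
  expect_identical(retained(mk("2005-06-15", "1985-06-15")), "V02")
  # 19 years, 364 days: excluded
  expect_identical(retained(mk("2005-06-14", "1985-06-15")), character())
  # exactly 50: retained; 51: excluded
  expect_identical(retained(mk("2005-06-15", "1955-06-15")), "V02")
  expect_identical(retained(mk("2005-06-15", "1954-06-14")), character())
})

test_that("attrition is monotone and filtering is idempotent", {
  gen <- generateCohort(cohortSpec(nPatients = 120L,
                                   decoyFraction = c(age = 0.1,
                                                     diagnosis = 0.1,
                                                     therapy = 0.1)),
                        seed = 2)
  eligible <- indexPatients(gen$cohort)
  res <- filterCohort(gen$cohort, eligible = eligible)
  expect_true(all(diff(attrition(res$attrition)) <= 0))
  again <- filterCohort(res$cohort, eligible = eligible)
  expect_equal(visits(again$cohort), visits(res$cohort))
  expect_equal(visitItems(again$cohort), visitItems(res$cohort))
  cnt <- attrition(again$attrition)
  expect_true(all(cnt == cnt[1]))
})

test_that("transactions are per-visit distinct item sets", {
  rows <- rbind(claimsRow("P1", "V01", specialty = "gynecology",
                          dx = "617.0", ther = "", code = ""),
                claimsRow("P1", "V02", code = "B"),
                claimsRow("P1", "V02", code = "A"),
                claimsRow("P1", "V02", code = "A"),  # duplicate dispense
                claimsRow("P1", "V03", code = "C"))
  res <- filterCohort(readClaims(writeClaimsFixture(rows)))
  tx <- asTransactions(res$cohort)
  expect_identical(length(tx), nVisits(res$cohort))
  expect_identical(transactionItems(tx), list(c("A", "B"), "C"))
  # itemless visits cannot form transactions
  full <- readClaims(writeClaimsFixture(rows))
  expect_error(asTransactions(full), "chmOnly")
})

test_that("transactions files round-trip", {
  tx <- txFromSets(list(c("B", "A"), c("C"), c("A", "C")))
  path <- tempfile()
  writeTransactions(tx, path)
  back <- readTransactions(path)
  expect_identical(transactionItems(back), transactionItems(tx))
  expect_identical(back@visitIds, tx@visitIds)
})
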