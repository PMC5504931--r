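test_that("frequent itemsets on the textbook fixture are exact", {
  tx <- txFromSets(list(c("A", "B"), c("A", "B"), "A", "C"))
  out <- mineFrequentItemsets(tx, miningParams(minSupport = 0.5,
                                               maxSize = 3))
  expect_identical(itemsetCountMap(out),
                   c(A = 3L, B = 2L, `A+B` = 2L))
  expect_equal(out$support, c(0.75, 0.5, 0.5))
  # ordering: size ascending, support descending
  expect_identical(out$key, c("A", "B", "A+B"))
})

test_that("an unreachable support threshold yields nothing; no transactions errors", {
  tx <- txFromSets(list(c("A", "B"), "A"))
  expect_identical(nrow(mineFrequentItemsets(tx, miningParams(minSupport = 1))),
                   1L)  # only {A} occurs in every transaction
  out <- mineFrequentItemsets(txFromSets(list("A", "B")),
                              miningParams(minSupport = 0.9))
  expect_identical(nrow(out), 0L)
  expect_error(mineFrequentItemsets(new("ChmTransactions",
                                        visitIds = character(),
                                        items = list())),
               "support is undefined")
})

test_that("rule metrics on the textbook fixture are exact", {
  tx <- txFromSets(list(c("A", "B"), c("A", "B"), "A", "C"))
  its <- mineFrequentItemsets(tx, miningParams(minSupport = 0.4))
  rules <- deriveRules(its, miningParams(minSupport = 0.4))
  ab <- rules[rules$antecedent == "A", ]
  expect_equal(ab$confidence, 2 / 3)
  expect_equal(ab$lift, (2 / 3) / 0.5)
  ba <- rules[rules$antecedent == "B", ]
  expect_equal(ba$confidence, 1)
  expect_equal(ba$lift, ab$lift)  # lift is direction-symmetric
})

test_that("mining equals the exhaustive oracle on random transaction sets", {
  set.seed(42)
  for (rep in 1:25) {
    sets <- randomTransactionSets(sample(3:10, 1), sample(20:200, 1))
    ms <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    params <- miningParams(minSupport = ms, minConfidence = 0.2,
                           minLift = 1, maxSize = 3)
    got <- mineFrequentItemsets(txFromSets(sets), params)
    want <- bruteForceItemsets(sets, ms, 3)
    wantMap <- setNames(vapply(want, function(e) e$count, 0L),
                        vapply(want, function(e)
                          paste(e$items, collapse = "+"), ""))
    expect_identical(itemsetCountMap(got), wantMap[names(itemsetCountMap(got))])
    expect_identical(length(itemsetCountMap(got)), length(wantMap))

    gotRules <- deriveRules(got, params)
    wantRules <- bruteForceRules(sets, ms, 0.2, 1, 3)
    if (is.null(wantRules)) {
      expect_identical(nrow(gotRules), 0L)
    } else {
      g <- gotRules[order(gotRules$antecedent, gotRules$consequent,
                          method = "radix"), ]
      expect_identical(paste(g$antecedent, g$consequent),
                       paste(wantRules$antecedent, wantRules$consequent))
      expect_equal(g$confidence, wantRules$confidence, tolerance = 1e-14)
      expect_equal(g$lift, wantRules$lift, tolerance = 1e-14)
      expect_identical(g$count, wantRules$count)
    }
  }
})

test_that("support is anti-monotone over the mined output", {
  set.seed(9)
  sets <- randomTransactionSets(8, 300)
  out <- mineFrequentItemsets(txFromSets(sets),
                              miningParams(minSupport = 0.01))
  sup <- setNames(out$support, out$key)
  for (i in which(out$size > 1)) {
    s <- out$items[[i]]
    for (drop in seq_along(s)) {
      sub <- paste(s[-drop], collapse = "+")
      expect_true(sup[[sub]] >= out$support[i])
    }
  }
})

test_that("screens are filters only: metrics match the unfiltered run", {
  set.seed(11)
  sets <- randomTransactionSets(7, 200)
  its <- mineFrequentItemsets(txFromSets(sets),
                              miningParams(minSupport = 0.02))
  strict <- deriveRules(its, miningParams(minSupport = 0.02,
                                          minConfidence = 0.4,
                                          minLift = 1.1))
  loose <- deriveRules(its, miningParams(minSupport = 0.02,
                                         minConfidence = 0, minLift = 0))
  key <- function(d) paste(d$antecedent, d$consequent)
  m <- match(key(strict), key(loose))
  expect_false(anyNA(m))
  expect_identical(strict$confidence, loose$confidence[m])
  expect_identical(strict$lift, loose$lift[m])
})

test_that("computeLift matches confidence over consequent support", {
  expect_equal(computeLift(0.5, 0.25), 2)
  expect_equal(computeLift(0.3, 0.3), 1)
  expect_error(computeLift(0.5, 0), "undefined")
})

test_that("top combinations collapse rule directions and rank by support", {
  tx <- txFromCounts(list(
    list(items = c("A", "B"), n = 40), list(items = "A", n = 10),
    list(items = "B", n = 50),
    list(items = c("C", "D"), n = 30), list(items = "C", n = 70),
    list(items = c("E", "F"), n = 35), list(items = "E", n = 20),
    list(items = "Z", n = 45)))
  params <- miningParams(minSupport = 0.05, minConfidence = 0.1,
                         minLift = 1)
  rules <- deriveRules(mineFrequentItemsets(tx, params), params)
  top <- topCombinations(rules, 2, 2)
  expect_identical(top$key, c("A+B", "E+F"))  # supports 40/280 > 35/280 > 30/280
  # retained direction is the higher-confidence one: A -> B (40/50 = 0.8)
  expect_identical(top$antecedent[1], "A")
  expect_equal(top$confidence[1], 40 / 50)
  # k beyond availability returns all rows, no padding
  expect_identical(nrow(topCombinations(rules, 2, 99)), 3L)
  expect_error(topCombinations(rules, 2, 0), "positive")
})
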