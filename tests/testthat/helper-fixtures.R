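# Fixtures are built in code: small hand-countable claims tables, and
# transaction sets assembled from explicit (itemset, multiplicity) counts.

claimsRow <- function(patient = "P1", visit = "V1", vdate = "2005-06-15",
                      bdate = "1975-01-10", specialty = "tcm",
                      dx = "617.0", ther = "chm", code = "HF001",
                      name = "Gui-Zhi-Fu-Ling-Wan", kind = "HF",
                      dose = 4, dur = 12) {
  data.frame(patient_id = patient, visit_id = visit, visit_date = vdate,
             birth_date = bdate, specialty = specialty, diagnoses = dx,
             therapies = ther, item_code = code, item_name = name,
             item_kind = kind, dose_g_day = dose, duration_days = dur,
             stringsAsFactors = FALSE)
}

writeClaimsFixture <- function(rows, path = tempfile(fileext = ".csv")) {
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}

# a transactions object from a list of list(items=..., n=...)
txFromCounts <- function(counts) {
  sets <- unlist(lapply(counts, function(cc)
    rep(list(sort(cc$items, method = "radix")), cc$n)), recursive = FALSE)
  new("ChmTransactions",
      visitIds = sprintf("V%04d", seq_along(sets)), items = sets)
}

txFromSets <- function(sets) {
  new("ChmTransactions",
      visitIds = sprintf("V%04d", seq_along(sets)),
      items = lapply(sets, function(s) sort(unique(s), method = "radix")))
}

# Independent oracle: exhaustive enumeration of all itemsets up to maxSize.
bruteForceItemsets <- function(sets, minSupport, maxSize = 3L) {
  labels <- sort(unique(unlist(sets)), method = "radix")
  N <- length(sets)
  out <- list()
  for (sz in seq_len(min(maxSize, length(labels)))) {
    for (cmb in combn(labels, sz, simplify = FALSE)) {
      cnt <- sum(vapply(sets, function(s) all(cmb %in% s), logical(1)))
      if (cnt / N >= minSupport)
        out[[length(out) + 1L]] <- list(items = cmb, count = cnt)
    }
  }
  out
}

# Independent oracle for rules: every frequent itemset of size >= 2, every
# proper non-empty antecedent subset, metrics from raw counts.
bruteForceRules <- function(sets, minSupport, minConfidence, minLift,
                            maxSize = 3L) {
  N <- length(sets)
  countOf <- function(cmb)
    sum(vapply(sets, function(s) all(cmb %in% s), logical(1)))
  freq <- bruteForceItemsets(sets, minSupport, maxSize)
  rows <- list()
  for (e in freq) {
    s <- e$items
    if (length(s) < 2L) next
    for (na in seq_len(length(s) - 1L)) {
      for (a in combn(s, na, simplify = FALSE)) {
        b <- setdiff(s, a)
        conf <- e$count / countOf(a)
        lift <- conf / (countOf(b) / N)
        if (conf >= minConfidence && lift > minLift)
          rows[[length(rows) + 1L]] <- data.frame(
            antecedent = paste(a, collapse = "+"),
            consequent = paste(b, collapse = "+"),
            count = e$count, support = e$count / N, confidence = conf,
            lift = lift, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$antecedent, out$consequent, method = "radix"), ,
      drop = FALSE]
}

randomTransactionSets <- function(nItems, nTx) {
  labels <- LETTERS[seq_len(nItems)]
  p <- runif(nItems, 0.05, 0.6)
  sets <- lapply(seq_len(nTx), function(i) {
    s <- labels[runif(nItems) < p]
    if (!length(s)) s <- sample(labels, 1)
    s
  })
  sets
}

itemsetCountMap <- function(df) {
  setNames(df$count, df$key)
}
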