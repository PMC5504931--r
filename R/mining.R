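# Level-wise (Apriori) frequent-itemset mining and association-rule
# derivation over prescription transactions.
#
# Counting uses per-item transaction-id lists; a candidate's count is the
# size of the intersection of its prefix's tidlist with the added item's
# tidlist. Candidate generation is the classic F_{k-1} x F_{k-1} join with
# subset pruning, so any candidate with an infrequent subset is never
# counted (anti-monotonicity of support).
#
# Threshold comparisons are done on support/confidence *fractions* computed
# as single divisions of integer counts: equal rationals round to the same
# double, so boundary cases (confidence exactly 0.30, lift exactly 1) are
# decided exactly.

#' Mining thresholds
#'
#' @param minSupport minimum itemset support, in (0, 1]; default 0.01.
#' @param minConfidence minimum rule confidence; default 0.30.
#' @param minLift rules must have lift strictly greater than this;
#'   default 1.
#' @param maxSize largest itemset size mined; default 3 (pairs and
#'   triples).
#' @return A [MiningParams-class].
#' @export
miningParams <- function(minSupport = 0.01, minConfidence = 0.30,
                         minLift = 1, maxSize = 3L) {
  new("MiningParams", minSupport = minSupport,
      minConfidence = minConfidence, minLift = minLift,
      maxSize = as.integer(maxSize))
}

itemsetKey <- function(items) paste(items, collapse = "+")

emptyItemsets <- function() {
  data.frame(key = character(), size = integer(), count = integer(),
             support = numeric(), stringsAsFactors = FALSE)
}

#' Mine frequent itemsets
#'
#' Returns exactly the itemsets of size 1..`maxSize` whose support (fraction
#' of transactions containing all the items) is at least `minSupport`,
#' sorted by size ascending, then support descending, then itemset key
#' (radix order).
#'
#' @param tx a [ChmTransactions-class].
#' @param params a [MiningParams-class].
#' @return data.frame with columns `items` (list of character vectors),
#'   `key` (items joined by "+"), `size`, `count`, `support`.
#' @export
mineFrequentItemsets <- function(tx, params = miningParams()) {
  N <- length(tx@items)
  if (N < 1) stop("no transactions: support is undefined")
  labels <- sortCodes(unique(unlist(tx@items, use.names = FALSE)))
  idxSets <- lapply(tx@items, function(s) match(s, labels))
  m <- length(labels)

  # tidlists per item
  txn <- rep.int(seq_len(N), lengths(idxSets))
  tid <- split(txn, factor(unlist(idxSets, use.names = FALSE),
                           levels = seq_len(m)))

  minS <- params@minSupport
  lev <- list()  # per size: list of list(items=int vec, tid=int vec, count)
  f1 <- which(lengths(tid) / N >= minS)
  lev[[1]] <- lapply(f1, function(i)
    list(items = i, tid = tid[[i]], count = length(tid[[i]])))

  k <- 2L
  while (k <= params@maxSize && length(lev[[k - 1L]]) >
         if (k == 2L) 1L else 0L) {
    prev <- lev[[k - 1L]]
    prevKeys <- vapply(prev, function(e) paste(e$items, collapse = " "), "")
    prevSet <- new.env(hash = TRUE, parent = emptyenv())
    for (pk in prevKeys) assign(pk, TRUE, envir = prevSet)
    # join sets sharing the first k-2 items
    pref <- vapply(prev, function(e)
      paste(e$items[-(k - 1L)], collapse = " "), "")
    groups <- split(seq_along(prev), pref)
    out <- list()
    for (g in groups) {
      if (length(g) < 2L) next
      last <- vapply(prev[g], function(e) e$items[k - 1L], 0L)
      g <- g[order(last)]
      for (a in seq_len(length(g) - 1L)) for (b in (a + 1L):length(g)) {
        ea <- prev[[g[a]]]; eb <- prev[[g[b]]]
        cand <- c(ea$items, eb$items[k - 1L])
        if (k > 2L) {  # prune: all (k-1)-subsets must be frequent
          ok <- TRUE
          for (drop in seq_len(k - 2L)) {
            sub <- paste(cand[-drop], collapse = " ")
            if (!exists(sub, envir = prevSet, inherits = FALSE)) {
              ok <- FALSE; break
            }
          }
          if (!ok) next
        }
        ctid <- intersect(ea$tid, prev[[g[b]]]$tid)
        if (length(ctid) / N >= minS)
          out[[length(out) + 1L]] <-
            list(items = cand, tid = ctid, count = length(ctid))
      }
    }
    lev[[k]] <- out
    k <- k + 1L
  }

  rows <- do.call(rbind, lapply(seq_along(lev), function(sz) {
    if (!length(lev[[sz]])) return(NULL)
    data.frame(
      key = vapply(lev[[sz]], function(e)
        itemsetKey(labels[e$items]), ""),
      size = sz,
      count = vapply(lev[[sz]], function(e) e$count, 0L),
      stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    out <- emptyItemsets()
    out$items <- list()
    out <- out[c("items", "key", "size", "count", "support")]
    attr(out, "nTransactions") <- N
    return(out)
  }
  rows$support <- rows$count / N
  rows <- rows[order(rows$size, -rows$support, rows$key,
                     method = "radix"), , drop = FALSE]
  rows$items <- strsplit(rows$key, "+", fixed = TRUE)
  rownames(rows) <- NULL
  rows <- rows[c("items", "key", "size", "count", "support")]
  attr(rows, "nTransactions") <- N
  rows
}

emptyRules <- function() {
  data.frame(antecedent = character(), consequent = character(),
             size = integer(), count = integer(), support = numeric(),
             confidence = numeric(), lift = numeric(),
             stringsAsFactors = FALSE)
}

#' Derive association rules from frequent itemsets
#'
#' For every frequent itemset S of size >= 2 and every non-empty proper
#' subset A (antecedent, consequent B = S \ A), the rule A -> B is emitted
#' iff support(S) >= `minSupport`, confidence = support(S)/support(A) >=
#' `minConfidence`, and lift = confidence/support(B) > `minLift` (strict:
#' lift exactly 1 is independence and never indicates a combination). The
#' screens are filters only — emitted metrics are identical to the
#' unfiltered ones.
#'
#' @param itemsets output of [mineFrequentItemsets()] (on the same
#'   transactions, same `minSupport`, so all subset supports are present).
#' @param params a [MiningParams-class].
#' @return data.frame with columns `antecedent`, `consequent` ("+"-joined
#'   keys), `size` (of the union), `count`, `support`, `confidence`,
#'   `lift`.
#' @export
deriveRules <- function(itemsets, params = miningParams()) {
  if (!nrow(itemsets)) return(emptyRules())
  N <- attr(itemsets, "nTransactions") %||%
    round(itemsets$count[1] / itemsets$support[1])
  look <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(itemsets)))
    assign(itemsets$key[i], itemsets$count[i], envir = look)
  cnt <- function(key) get(key, envir = look, inherits = FALSE)

  res <- list()
  big <- itemsets[itemsets$size >= 2L, , drop = FALSE]
  for (i in seq_len(nrow(big))) {
    s <- big$items[[i]]; cS <- big$count[i]; supS <- cS / N
    if (!(supS >= params@minSupport)) next
    for (na in seq_len(length(s) - 1L)) {
      ants <- combn(s, na, simplify = FALSE)
      for (a in ants) {
        b <- setdiff(s, a)
        cA <- cnt(itemsetKey(a)); cB <- cnt(itemsetKey(b))
        conf <- cS / cA
        lift <- conf / (cB / N)
        if (conf >= params@minConfidence && lift > params@minLift)
          res[[length(res) + 1L]] <- data.frame(
            antecedent = itemsetKey(a), consequent = itemsetKey(b),
            size = length(s), count = cS, support = supS,
            confidence = conf, lift = lift, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) return(emptyRules())
  out <- do.call(rbind, res)
  out <- out[order(out$size, -out$support, -out$confidence, out$antecedent,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Lift of a rule from its confidence and the consequent's support
#'
#' lift = confidence / support(consequent); 1 under independence,
#' symmetric in rule direction.
#'
#' @param confidence rule confidence in \[0, 1\].
#' @param consequentSupport marginal support of the consequent, > 0.
#' @return The lift (vectorised).
#' @export
computeLift <- function(confidence, consequentSupport) {
  if (any(consequentSupport <= 0))
    stop("lift is undefined for consequent support <= 0")
  confidence / consequentSupport
}

#' Round half up
#'
#' Reported percentages and lifts are rounded half-up (so 1.45 prints as
#' 1.5), matching the convention of published prescription tables rather
#' than IEEE banker's rounding.
#'
#' @param x numeric vector (non-negative).
#' @param digits decimal places.
#' @return Rounded vector.
#' @export
roundHalfUp <- function(x, digits = 1) floor(x * 10^digits + 0.5) / 10^digits

#' Ranked table of top CHM combinations
#'
#' Collapses directional rules to unordered itemsets of the requested size.
#' Each itemset is reported once, with the union's support ("prevalence"),
#' and the confidence/lift of the retained direction — the one with the
#' higher confidence (ties: lexicographically smaller antecedent key).
#' Because lift is direction-symmetric the reported lift does not depend on
#' the choice. Ranked by support descending, ties by lift descending then
#' itemset key.
#'
#' @param rules output of [deriveRules()].
#' @param size combination size (2 or 3).
#' @param k number of rows to return; fewer if fewer qualify.
#' @return data.frame with columns `rank`, `key`, `items`, `antecedent`,
#'   `consequent`, `count`, `support`, `confidence`, `lift`.
#' @export
topCombinations <- function(rules, size = 2L, k = 30L) {
  if (k <= 0) stop("k must be a positive integer")
  empty <- data.frame(rank = integer(), key = character(),
                      antecedent = character(), consequent = character(),
                      count = integer(), support = numeric(),
                      confidence = numeric(), lift = numeric(),
                      stringsAsFactors = FALSE)
  empty$items <- list()
  empty <- empty[c("rank", "key", "items", "antecedent", "consequent",
                   "count", "support", "confidence", "lift")]
  if (!nrow(rules)) return(empty)
  r <- rules[rules$size == size, , drop = FALSE]
  if (!nrow(r)) return(empty)
  union <- vapply(seq_len(nrow(r)), function(i)
    itemsetKey(sortCodes(c(strsplit(r$antecedent[i], "+", fixed = TRUE)[[1]],
                           strsplit(r$consequent[i], "+",
                                    fixed = TRUE)[[1]]))), "")
  r$key <- union
  pick <- vapply(split(seq_len(nrow(r)), union), function(idx) {
    best <- idx[r$confidence[idx] == max(r$confidence[idx])]
    if (length(best) > 1L)
      best <- best[orderCodes(r$antecedent[best])[1]]
    best[1]
  }, 0L)
  out <- r[pick, c("key", "antecedent", "consequent", "count", "support",
                   "confidence", "lift"), drop = FALSE]
  out <- out[order(-out$support, -out$lift, out$key,
                   method = "radix"), , drop = FALSE]
  out <- head(out, k)
  out$rank <- seq_len(nrow(out))
  out$items <- strsplit(out$key, "+", fixed = TRUE)
  rownames(out) <- NULL
  out[c("rank", "key", "items", "antecedent", "consequent", "count",
        "support", "confidence", "lift")]
}

#' Write itemsets or rules as a delimited table (with a JSON twin)
#'
#' @param x a data.frame from [mineFrequentItemsets()], [deriveRules()] or
#'   [topCombinations()].
#' @param path output path for the TSV; a `.json` twin is written next to
#'   it.
#' @return The paths, invisibly.
#' @export
writeMiningTable <- function(x, path) {
  flat <- x[!vapply(x, is.list, TRUE)]
  write.table(flat, path, sep = "\t", row.names = FALSE, quote = FALSE)
  js <- sub("\\.[^.]+$", "", path)
  js <- paste0(js, ".json")
  jsonlite::write_json(flat, js, digits = NA)
  invisible(c(path, js))
}
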