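# Descriptive utilization layer: prevalence-ranked item tables with mean
# dose and duration, and the items-per-prescription distribution.

#' Prevalence-ranked item table
#'
#' For each CHM item: the fraction of retained prescriptions containing it,
#' and mean dose (g/day) and duration (days/visit) averaged over the
#' prescriptions that contain it. Single-item prevalence here equals the
#' size-1 itemset support mined from the same data.
#'
#' @param cohort a retained [ChmCohort-class].
#' @param kind "all", "HF" or "SH".
#' @param topN number of rows to keep (default all; the full table is the
#'   analysis object, top-n is a display cut).
#' @return data.frame: rank, code, name, kind, prevalence,
#'   mean_dose_g_day, mean_duration_days; sorted by prevalence descending
#'   (ties by code).
#' @export
prevalenceTable <- function(cohort, kind = c("all", "HF", "SH"),
                            topN = Inf) {
  kind <- match.arg(kind)
  n <- nVisits(cohort)
  if (!n) stop("empty cohort")
  it <- cohort@items
  if (kind != "all") it <- it[it$kind == kind, , drop = FALSE]
  if (!nrow(it)) {
    return(data.frame(rank = integer(), code = character(),
                      name = character(), kind = character(),
                      prevalence = numeric(), mean_dose_g_day = numeric(),
                      mean_duration_days = numeric(),
                      stringsAsFactors = FALSE))
  }
  agg <- aggregate(cbind(dose_g_day, duration_days) ~ code, data = it,
                   FUN = mean)
  cnt <- table(it$code)
  first <- it[!duplicated(it$code), c("code", "name", "kind")]
  i <- match(agg$code, first$code)
  out <- data.frame(code = agg$code, name = first$name[i],
                    kind = first$kind[i],
                    prevalence = as.numeric(cnt[agg$code]) / n,
                    mean_dose_g_day = agg$dose_g_day,
                    mean_duration_days = agg$duration_days,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$prevalence, out$code, method = "radix"), ,
             drop = FALSE]
  out <- head(out, topN)
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Items-per-prescription distribution
#'
#' Histogram of the number of distinct items per prescription, as fractions
#' of all prescriptions, with the mean size. Fractions sum to 1 and the
#' mean equals sum(size * fraction).
#'
#' @param x a [ChmTransactions-class] or retained [ChmCohort-class].
#' @return list: `histogram` (data.frame size, count, fraction), `mean`.
#' @export
sizeDistribution <- function(x) {
  if (is(x, "ChmCohort")) x <- asTransactions(x)
  sz <- lengths(x@items)
  if (!length(sz)) stop("no prescriptions")
  tab <- table(sz)
  hist <- data.frame(size = as.integer(names(tab)),
                     count = as.integer(tab),
                     fraction = as.numeric(tab) / length(sz))
  list(histogram = hist, mean = mean(sz))
}

#' Write the utilization summaries of a cohort
#'
#' Writes the HF and SH prevalence tables and the size distribution as TSV
#' with JSON twins.
#'
#' @param cohort a retained [ChmCohort-class].
#' @param dir output directory.
#' @return Character vector of written paths, invisibly.
#' @export
writeSummaries <- function(cohort, dir) {
  paths <- character()
  for (k in c("HF", "SH", "all")) {
    tab <- prevalenceTable(cohort, k)
    p <- file.path(dir, sprintf("prevalence_%s.tsv", tolower(k)))
    paths <- c(paths, writeMiningTable(tab, p))
  }
  sd <- sizeDistribution(cohort)
  p <- file.path(dir, "size_distribution.tsv")
  write.table(sd$histogram, p, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(histogram = sd$histogram, mean = sd$mean),
                       file.path(dir, "size_distribution.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(c(paths, p, file.path(dir, "size_distribution.json")))
}
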