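# The inclusion/exclusion cascade: eligible patients -> age window ->
# primary diagnosis -> therapy exclusions -> CHM-dispensing visits.

#' Cohort filter configuration
#'
#' Defaults encode the usual claims conventions for an endometriosis CHM
#' cohort: the endometriosis rubric is ICD-9-CM 617.x (matched by code
#' prefix, so "617" covers "617.0", "617.9", ...), the reproductive-age
#' window 20-50 is inclusive at both ends in completed years at the visit
#' date, eligibility requires a gynecologist-made index diagnosis, and
#' visits with acupuncture, moxibustion or manual therapy are excluded so
#' the retained prescriptions reflect CHM treatment alone.
#'
#' @param dxPrefixes diagnosis code prefixes (default "617").
#' @param ageMin,ageMax inclusive age bounds in completed years.
#' @param requirePrimaryDx retain a visit only if its first-listed diagnosis
#'   matches a prefix.
#' @param requireGynIndex patient eligibility requires a matching diagnosis
#'   at a gynecology visit.
#' @param excludedTherapies therapy flags that exclude a visit.
#' @param chmOnly drop visits with no dispensed CHM item.
#' @return A [CohortFilter-class].
#' @export
cohortFilter <- function(dxPrefixes = "617", ageMin = 20, ageMax = 50,
                         requirePrimaryDx = TRUE, requireGynIndex = TRUE,
                         excludedTherapies = c("acupuncture", "moxibustion",
                                               "manual"),
                         chmOnly = TRUE) {
  new("CohortFilter", dxPrefixes = as.character(dxPrefixes),
      ageMin = ageMin, ageMax = ageMax,
      requirePrimaryDx = requirePrimaryDx,
      requireGynIndex = requireGynIndex,
      excludedTherapies = as.character(excludedTherapies),
      chmOnly = chmOnly)
}

# completed years at `date`
ageAtDate <- function(birth, date) {
  bl <- as.POSIXlt(birth); dl <- as.POSIXlt(date)
  age <- dl$year - bl$year
  before <- (dl$mon < bl$mon) | (dl$mon == bl$mon & dl$mday < bl$mday)
  age - as.integer(before)
}

matchesPrefix <- function(codes, prefixes) {
  if (!length(codes)) return(FALSE)
  any(vapply(prefixes, function(p) any(startsWith(codes, p)), logical(1)))
}

#' Identify eligible patients
#'
#' A patient is eligible if she has at least one visit where any listed
#' diagnosis matches a configured prefix and, when `requireGynIndex` is set,
#' the visit was made to a gynecologist. This is the index-diagnosis rule:
#' the condition must have been established by the relevant specialty at
#' least once, not merely coded at a CHM visit.
#'
#' @param cohort a [ChmCohort-class].
#' @param filter a [CohortFilter-class].
#' @return Sorted character vector of eligible patient ids (possibly empty).
#' @export
indexPatients <- function(cohort, filter = cohortFilter()) {
  v <- cohort@visits
  if (!nrow(v)) return(character())
  dx <- splitField(v$diagnoses)
  dxOk <- vapply(dx, matchesPrefix, logical(1), prefixes = filter@dxPrefixes)
  specOk <- if (filter@requireGynIndex) v$specialty == "gynecology" else TRUE
  sortCodes(unique(v$patient_id[dxOk & specOk]))
}

#' Apply the inclusion/exclusion cascade
#'
#' Retains the visits that pass, in order: (1) patient eligibility, (2) age
#' at visit date within the configured inclusive window, (3) primary
#' (first-listed) diagnosis matching a configured prefix (any position if
#' `requirePrimaryDx` is FALSE), (4) no excluded therapy type, (5) at least
#' one dispensed CHM item when `chmOnly`. Counts at every step are returned
#' as an [AttritionReport-class]; they are non-increasing by construction.
#'
#' @param cohort a [ChmCohort-class].
#' @param filter a [CohortFilter-class].
#' @param eligible patient ids from [indexPatients()]; computed from
#'   `cohort` by default.
#' @return list with elements `cohort` (retained [ChmCohort-class]) and
#'   `attrition` ([AttritionReport-class]).
#' @export
filterCohort <- function(cohort, filter = cohortFilter(),
                         eligible = indexPatients(cohort, filter)) {
  v <- cohort@visits
  keep <- rep(TRUE, nrow(v))
  counts <- integer(0)
  step <- function(counts, name, n) c(counts, setNames(as.integer(n), name))

  counts <- step(counts, "total_visits", nrow(v))

  keep <- keep & v$patient_id %in% eligible
  counts <- step(counts, "visits_by_eligible_patients", sum(keep))

  age <- ageAtDate(v$birth_date, v$visit_date)
  keep <- keep & age >= filter@ageMin & age <= filter@ageMax
  counts <- step(counts, "age_in_range", sum(keep))

  dx <- splitField(v$diagnoses)
  dxOk <- if (filter@requirePrimaryDx) {
    vapply(dx, function(d) matchesPrefix(d[1][nzchar(d[1]) & !is.na(d[1])],
                                         filter@dxPrefixes), logical(1))
  } else {
    vapply(dx, matchesPrefix, logical(1), prefixes = filter@dxPrefixes)
  }
  keep <- keep & dxOk
  counts <- step(counts, "primary_diagnosis_match", sum(keep))

  th <- splitField(v$therapies)
  thOk <- !vapply(th, function(t) any(t %in% filter@excludedTherapies),
                  logical(1))
  keep <- keep & thOk
  counts <- step(counts, "therapy_exclusions_passed", sum(keep))

  if (filter@chmOnly) {
    hasItems <- v$visit_id %in% cohort@items$visit_id
    keep <- keep & hasItems
  }
  counts <- step(counts, "chm_visits_retained", sum(keep))

  kept <- v$visit_id[keep]
  out <- chmCohort(v[keep, , drop = FALSE],
                   cohort@items[cohort@items$visit_id %in% kept, ,
                                drop = FALSE])
  list(cohort = out,
       attrition = new("AttritionReport", counts = counts))
}

#' Convert retained visits to transactions
#'
#' One transaction per retained visit: the set of distinct CHM codes
#' dispensed at that visit. This is the unit over which support (the
#' "prevalence" of an item or combination) is defined.
#'
#' @param cohort a retained [ChmCohort-class]; every visit must have at
#'   least one item (filter with `chmOnly = TRUE`).
#' @return A [ChmTransactions-class] with one element per visit.
#' @export
asTransactions <- function(cohort) {
  v <- cohort@visits
  bare <- setdiff(v$visit_id, cohort@items$visit_id)
  if (length(bare))
    stop("visit without dispensed items cannot form a transaction: '",
         bare[1], "' (filter with chmOnly = TRUE)")
  sets <- split(cohort@items$code, cohort@items$visit_id)
  sets <- lapply(sets, function(s) sortCodes(unique(s)))
  ids <- sortCodes(v$visit_id)
  new("ChmTransactions", visitIds = ids, items = unname(sets[ids]))
}

#' Read/write a transactions file
#'
#' One line per prescription: the visit id, a tab, then the item codes
#' joined by ";".
#'
#' @param x a [ChmTransactions-class].
#' @param path file path.
#' @return `writeTransactions()` returns `path` invisibly;
#'   `readTransactions()` a [ChmTransactions-class].
#' @export
writeTransactions <- function(x, path) {
  lines <- paste0(x@visitIds, "\t",
                  vapply(x@items, paste, "", collapse = ";"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeTransactions
#' @export
readTransactions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  new("ChmTransactions",
      visitIds = vapply(parts, `[`, "", 1L),
      items = lapply(parts, function(p)
        sortCodes(unique(strsplit(p[2], ";", fixed = TRUE)[[1]]))))
}

#' Write an attrition report
#'
#' Writes the cascade counts both as aligned key-value text and as JSON.
#'
#' @param report an [AttritionReport-class].
#' @param path base path; `.txt` and `.json` are appended.
#' @return The two paths, invisibly.
#' @export
writeAttrition <- function(report, path) {
  txt <- paste0(path, ".txt"); js <- paste0(path, ".json")
  writeLines(sprintf("%-28s %d", names(report@counts), report@counts), txt)
  jsonlite::write_json(as.list(report@counts), js, auto_unbox = TRUE)
  invisible(c(txt, js))
}
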