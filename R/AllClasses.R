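# Central S4 containers. Claims-style data are held as two plain data frames
# (one row per visit; one row per dispensed item) inside a validated object,
# so every downstream operation can rely on canonical column names and order.

VISIT_COLS <- c("visit_id", "patient_id", "visit_date", "birth_date",
                "specialty", "diagnoses", "therapies")
ITEM_COLS <- c("visit_id", "code", "name", "kind", "dose_g_day",
               "duration_days")
THERAPY_LEVELS <- c("chm", "acupuncture", "moxibustion", "manual")

#' ChmCohort: claims-style visit and dispensed-item tables
#'
#' One row of `visits` per ambulatory visit (`visit_id` unique); one row of
#' `items` per dispensed CHM item within a visit. `diagnoses` holds the
#' ordered ICD-9-CM codes of a visit joined by ";" (position 1 = primary
#' reason for the visit); `therapies` holds the therapy-type flags joined by
#' ";" (subset of chm/acupuncture/moxibustion/manual; may be empty).
#'
#' @slot visits data.frame with columns visit_id, patient_id, visit_date,
#'   birth_date (both `Date`), specialty, diagnoses, therapies.
#' @slot items data.frame with columns visit_id, code, name, kind ("HF" or
#'   "SH"), dose_g_day, duration_days.
#' @export
setClass("ChmCohort", slots = c(visits = "data.frame", items = "data.frame"))

setValidity("ChmCohort", function(object) {
  v <- object@visits; it <- object@items
  miss <- setdiff(VISIT_COLS, names(v))
  if (length(miss)) return(paste("visits: missing column", miss[1]))
  miss <- setdiff(ITEM_COLS, names(it))
  if (length(miss)) return(paste("items: missing column", miss[1]))
  if (anyDuplicated(v$visit_id)) return("visits: duplicated visit_id")
  if (!inherits(v$visit_date, "Date") || !inherits(v$birth_date, "Date"))
    return("visits: visit_date and birth_date must be Date")
  if (any(v$visit_date < v$birth_date, na.rm = TRUE))
    return("visits: visit_date earlier than birth_date")
  if (nrow(it)) {
    if (!all(it$visit_id %in% v$visit_id))
      return("items: visit_id not present in visits")
    if (anyDuplicated(it[c("visit_id", "code")]))
      return("items: duplicated (visit_id, code); merge before construction")
    if (!all(it$kind %in% c("HF", "SH")))
      return("items: kind must be 'HF' or 'SH'")
    if (any(!is.finite(it$dose_g_day)) || any(it$dose_g_day < 0))
      return("items: dose_g_day must be finite and >= 0")
    if (any(!is.finite(it$duration_days)) || any(it$duration_days < 0))
      return("items: duration_days must be finite and >= 0")
  }
  TRUE
})

#' AttritionReport: counts along the cohort inclusion/exclusion cascade
#'
#' @slot counts named integer vector; successive counts are non-increasing.
#' @export
setClass("AttritionReport", slots = c(counts = "integer"))

ATTRITION_STEPS <- c("total_visits", "visits_by_eligible_patients",
                     "age_in_range", "primary_diagnosis_match",
                     "therapy_exclusions_passed", "chm_visits_retained")

setValidity("AttritionReport", function(object) {
  cnt <- object@counts
  if (!identical(names(cnt), ATTRITION_STEPS))
    return("counts must be named by the cascade steps, in order")
  if (any(diff(cnt) > 0)) return("cascade counts must be non-increasing")
  TRUE
})

#' CohortFilter: the inclusion/exclusion cascade configuration
#'
#' @slot dxPrefixes ICD-9-CM code prefixes identifying the index condition.
#' @slot ageMin,ageMax inclusive bounds on completed years at visit date.
#' @slot requirePrimaryDx require the first-listed diagnosis to match.
#' @slot requireGynIndex patients qualify only via a gynecology visit.
#' @slot excludedTherapies therapy types whose presence excludes a visit.
#' @slot chmOnly retain only visits with at least one dispensed CHM item.
#' @export
setClass("CohortFilter",
         slots = c(dxPrefixes = "character", ageMin = "numeric",
                   ageMax = "numeric", requirePrimaryDx = "logical",
                   requireGynIndex = "logical",
                   excludedTherapies = "character", chmOnly = "logical"))

setValidity("CohortFilter", function(object) {
  if (!length(object@dxPrefixes)) return("dxPrefixes must be non-empty")
  if (object@ageMin > object@ageMax) return("ageMin must be <= ageMax")
  TRUE
})

#' ChmTransactions: one item set per retained prescription
#'
#' The unit over which support is defined: each element of `items` is the
#' set (sorted, distinct) of CHM codes dispensed at one retained visit.
#'
#' @slot visitIds character vector, one id per transaction.
#' @slot items list of character vectors, each non-empty, sorted, distinct.
#' @export
setClass("ChmTransactions",
         slots = c(visitIds = "character", items = "list"))

setValidity("ChmTransactions", function(object) {
  if (length(object@visitIds) != length(object@items))
    return("visitIds and items lengths differ")
  n <- lengths(object@items)
  if (any(n == 0)) return("transactions must be non-empty item sets")
  dup <- vapply(object@items, anyDuplicated, 0L)
  if (any(dup > 0)) return("transactions must not contain duplicate codes")
  TRUE
})

#' MiningParams: thresholds for frequent-itemset and rule mining
#'
#' Defaults follow common claims-mining practice for multi-herb
#' prescriptions: support >= 1%, confidence >= 30%, lift strictly > 1
#' (equality to 1 is statistical independence and is excluded), itemsets up
#' to size 3 (pairs and triples).
#'
#' @slot minSupport minimum itemset support (fraction of transactions).
#' @slot minConfidence minimum rule confidence.
#' @slot minLift rules must exceed this lift strictly.
#' @slot maxSize largest itemset size mined.
#' @export
setClass("MiningParams",
         slots = c(minSupport = "numeric", minConfidence = "numeric",
                   minLift = "numeric", maxSize = "integer"))

setValidity("MiningParams", function(object) {
  if (object@minSupport <= 0 || object@minSupport > 1)
    return("minSupport must be in (0, 1]")
  if (object@minConfidence < 0 || object@minConfidence > 1)
    return("minConfidence must be in [0, 1]")
  if (object@maxSize < 1) return("maxSize must be >= 1")
  TRUE
})

#' CoPrescriptionNetwork: herbs as nodes, top combinations as edges
#'
#' A simple undirected graph. Node size in the conventional rendering is the
#' single-item prevalence; edge width the pair support; edge darkness the
#' pair lift.
#'
#' @slot nodes data.frame: code, name, kind, prevalence, cluster_id
#'   (NA before clustering), is_cluster_core.
#' @slot edges data.frame: from, to (from < to in radix order), support,
#'   confidence, lift.
#' @slot modularity modularity of the stored partition (NA before
#'   clustering).
#' @slot cores list with elements `perCluster` (named character) and
#'   `global` (character), filled by [identifyCores()].
#' @export
setClass("CoPrescriptionNetwork",
         slots = c(nodes = "data.frame", edges = "data.frame",
                   modularity = "numeric", cores = "list"))

setValidity("CoPrescriptionNetwork", function(object) {
  nd <- object@nodes; ed <- object@edges
  need <- c("code", "name", "kind", "prevalence", "cluster_id",
            "is_cluster_core")
  if (!all(need %in% names(nd))) return("nodes: missing required column")
  if (anyDuplicated(nd$code)) return("nodes: duplicated code")
  if (nrow(ed)) {
    if (!all(c(ed$from, ed$to) %in% nd$code))
      return("edges: endpoint not present among nodes")
    if (any(ed$from == ed$to)) return("edges: self-loop")
    key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
    if (anyDuplicated(key)) return("edges: duplicate edge")
  }
  if (any(nd$prevalence <= 0 | nd$prevalence > 1))
    return("nodes: prevalence must be in (0, 1]")
  TRUE
})

#' SyntheticCohortSpec: parameters of the claims-style cohort generator
#'
#' @slot seed default random seed for [generateCohort()].
#' @slot nPatients number of patients.
#' @slot visitsPerPatient list(mean=, dispersion=): negative-binomial count
#'   of CHM visits per patient (dispersion = NB size; smaller = more spread).
#' @slot catalog data.frame: code, name, kind, prevalence (target marginal
#'   prevalence over prescriptions, in (0, 1]).
#' @slot itemsPerRx named numeric pmf over prescription sizes (names are the
#'   sizes).
#' @slot clusters named list of disjoint code sets with boosted
#'   within-cluster co-occurrence.
#' @slot boost multiplicative odds factor (>= 1) applied to items of an
#'   active cluster; scalar or one value per cluster.
#' @slot hubCode optional code of the dominant hub item (NA for none).
#' @slot doseModel per-kind lognormal parameters for dose (g/day) and
#'   duration (days/visit).
#' @slot decoyFraction named fractions (age, diagnosis, therapy) of
#'   prescriptions added as single-violation decoy visits.
#' @export
setClass("SyntheticCohortSpec",
         slots = c(seed = "numeric", nPatients = "integer",
                   visitsPerPatient = "list", catalog = "data.frame",
                   itemsPerRx = "numeric", clusters = "list",
                   boost = "numeric", hubCode = "character",
                   doseModel = "list", decoyFraction = "numeric"))

setValidity("SyntheticCohortSpec", function(object) {
  cat <- object@catalog
  if (!all(c("code", "name", "kind", "prevalence") %in% names(cat)))
    return("catalog needs columns code, name, kind, prevalence")
  if (anyDuplicated(cat$code)) return("catalog: duplicated code")
  if (any(cat$prevalence <= 0 | cat$prevalence > 1))
    return("catalog: prevalence targets must be in (0, 1]")
  pmf <- object@itemsPerRx
  if (is.null(names(pmf)) || any(is.na(suppressWarnings(as.integer(names(pmf))))))
    return("itemsPerRx must be named by integer sizes")
  if (any(pmf < 0) || abs(sum(pmf) - 1) > 1e-8)
    return("itemsPerRx must be a probability vector")
  if (min(as.integer(names(pmf))[pmf > 0]) < 1)
    return("itemsPerRx support must be >= 1")
  cl <- unlist(object@clusters, use.names = FALSE)
  if (anyDuplicated(cl)) return("clusters must be disjoint")
  if (!all(cl %in% cat$code)) return("clusters reference unknown codes")
  if (any(object@boost < 1)) return("boost must be >= 1")
  if (length(object@clusters) &&
      !(length(object@boost) %in% c(1L, length(object@clusters))))
    return("boost must be scalar or one value per cluster")
  if (!is.na(object@hubCode) && !(object@hubCode %in% cat$code))
    return("hubCode not present in catalog")
  df <- object@decoyFraction
  if (!all(c("age", "diagnosis", "therapy") %in% names(df)))
    return("decoyFraction needs entries age, diagnosis, therapy")
  if (any(df < 0) || any(df >= 1)) return("decoyFraction must be in [0, 1)")
  TRUE
})

#' GroundTruth: the planted structure of a synthetic cohort
#'
#' @slot assignments named integer vector: planted cluster id per item code
#'   (NA for unclustered items).
#' @slot plantedPairs data.frame (a, b, cluster): all within-cluster
#'   unordered pairs, a < b in radix order.
#' @slot marginals named numeric: intended marginal prevalence per code.
#' @slot decoyCounts named integer: decoy visits per violation type.
#' @slot counts list: nIndexVisits, nPrescriptions, nDecoys.
#' @export
setClass("GroundTruth",
         slots = c(assignments = "integer", plantedPairs = "data.frame",
                   marginals = "numeric", decoyCounts = "integer",
                   counts = "list"))

#' RunReport: record of one full pipeline run
#'
#' @slot attrition the [AttritionReport-class] of the filtering stage.
#' @slot counts list of stage counts (itemsets, rules, pairs, triples, ...).
#' @slot clusters list: count, sizes, cores, modularity (empty if the
#'   network stage was skipped).
#' @slot topPairs,topTriples ranked combination tables.
#' @slot manifest data.frame (file, md5) of every artifact written.
#' @export
setClass("RunReport",
         slots = c(attrition = "AttritionReport", counts = "list",
                   clusters = "list", topPairs = "data.frame",
                   topTriples = "data.frame", manifest = "data.frame"))
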