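#' @export
setGeneric("visits", function(x) standardGeneric("visits"))
#' @export
setGeneric("visitItems", function(x) standardGeneric("visitItems"))
#' @export
setGeneric("nVisits", function(x) standardGeneric("nVisits"))
#' @export
setGeneric("transactionItems", function(x) standardGeneric("transactionItems"))
#' @export
setGeneric("itemSupport", function(x) standardGeneric("itemSupport"))
#' @export
setGeneric("attrition", function(x) standardGeneric("attrition"))
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @export
setGeneric("networkModularity", function(x) standardGeneric("networkModularity"))
#' @export
setGeneric("coreItems", function(x) standardGeneric("coreItems"))

#' Accessors for the central containers
#'
#' `visits()` and `visitItems()` return the visit and dispensed-item tables
#' of a [ChmCohort-class]; `nVisits()` the number of visits.
#' `transactionItems()` returns the list of item sets of a
#' [ChmTransactions-class]; `itemSupport()` the named single-item support
#' vector. `attrition()` extracts the cascade counts from an
#' [AttritionReport-class] or [RunReport-class]. `networkNodes()`,
#' `networkEdges()`, `clusterLabels()`, `networkModularity()` and
#' `coreItems()` read the corresponding parts of a
#' [CoPrescriptionNetwork-class].
#'
#' @param x the object.
#' @return See details; tables are plain data frames.
#' @name accessors
#' @aliases visits visitItems nVisits transactionItems itemSupport attrition
#'   networkNodes networkEdges clusterLabels networkModularity coreItems
NULL

#' @rdname accessors
setMethod("visits", "ChmCohort", function(x) x@visits)
#' @rdname accessors
setMethod("visitItems", "ChmCohort", function(x) x@items)
#' @rdname accessors
setMethod("nVisits", "ChmCohort", function(x) nrow(x@visits))
#' @rdname accessors
setMethod("transactionItems", "ChmTransactions", function(x) x@items)
#' @rdname accessors
setMethod("attrition", "AttritionReport", function(x) x@counts)
#' @rdname accessors
setMethod("attrition", "RunReport", function(x) x@attrition@counts)
#' @rdname accessors
setMethod("networkNodes", "CoPrescriptionNetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("networkEdges", "CoPrescriptionNetwork", function(x) x@edges)
#' @rdname accessors
setMethod("clusterLabels", "CoPrescriptionNetwork",
          function(x) setNames(x@nodes$cluster_id, x@nodes$code))
#' @rdname accessors
setMethod("networkModularity", "CoPrescriptionNetwork",
          function(x) x@modularity)
#' @rdname accessors
setMethod("coreItems", "CoPrescriptionNetwork", function(x) x@cores)

setMethod("length", "ChmTransactions", function(x) length(x@items))

#' @rdname accessors
setMethod("itemSupport", "ChmTransactions", function(x) {
  n <- length(x@items)
  tab <- table(unlist(x@items, use.names = FALSE))
  s <- as.numeric(tab) / n
  setNames(s, names(tab))[sortCodes(names(tab))]
})

setMethod("show", "ChmCohort", function(object) {
  cat(sprintf("ChmCohort: %d visits, %d patients, %d dispensed items\n",
              nrow(object@visits), length(unique(object@visits$patient_id)),
              nrow(object@items)))
})

setMethod("show", "AttritionReport", function(object) {
  cat("AttritionReport (inclusion/exclusion cascade):\n")
  for (s in names(object@counts))
    cat(sprintf("  %-28s %d\n", s, object@counts[[s]]))
})

setMethod("show", "ChmTransactions", function(object) {
  sz <- lengths(object@items)
  cat(sprintf(
    "ChmTransactions: %d prescriptions, %d distinct items, mean size %.2f\n",
    length(object@items),
    length(unique(unlist(object@items, use.names = FALSE))),
    if (length(sz)) mean(sz) else NA_real_))
})

setMethod("show", "CoPrescriptionNetwork", function(object) {
  cl <- object@nodes$cluster_id
  cat(sprintf("CoPrescriptionNetwork: %d nodes, %d edges", nrow(object@nodes),
              nrow(object@edges)))
  if (!all(is.na(cl)))
    cat(sprintf("; %d clusters, modularity %.3f",
                length(unique(cl[!is.na(cl)])), object@modularity))
  cat("\n")
  if (length(object@cores))
    cat("  global core:", object@cores$global, "\n")
})

setMethod("show", "SyntheticCohortSpec", function(object) {
  cat(sprintf(paste0(
    "SyntheticCohortSpec: %d patients, catalog of %d items ",
    "(target mean %.2f items/prescription), %d planted clusters\n"),
    object@nPatients, nrow(object@catalog),
    sum(as.integer(names(object@itemsPerRx)) * object@itemsPerRx),
    length(object@clusters)))
})

setMethod("show", "RunReport", function(object) {
  cat("RunReport\n")
  show(object@attrition)
  cat(sprintf("  itemsets: %d, rules: %d, top pairs: %d, top triples: %d\n",
              object@counts$itemsets %||% 0L, object@counts$rules %||% 0L,
              nrow(object@topPairs), nrow(object@topTriples)))
  if (length(object@clusters))
    cat(sprintf("  clusters: %d (modularity %.3f), global core: %s\n",
                object@clusters$count, object@clusters$modularity,
                object@clusters$cores$global))
  cat(sprintf("  artifacts: %d files\n", nrow(object@manifest)))
})
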