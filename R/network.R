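# Co-prescription network: top-ranked pairs as weighted edges, automatic
# clustering by greedy modularity maximisation, core-herb identification,
# and graph export.

#' Build a co-prescription network from top-ranked pairs
#'
#' Nodes are the union of pair endpoints, carrying single-item prevalence
#' (and, when known, name and kind); edges carry the pair's support,
#' confidence and lift unchanged. The graph is simple and undirected:
#' duplicate pair rows are rejected.
#'
#' @param pairs a size-2 table from [topCombinations()], or any data.frame
#'   with columns `items` (list of 2 codes) or `key` ("a+b"), plus
#'   `support`, `confidence`, `lift`.
#' @param prevalence named numeric vector of single-item support, e.g.
#'   `itemSupport(tx)`; every endpoint must have an entry.
#' @param itemInfo optional data.frame (code, name, kind) used to annotate
#'   nodes.
#' @return A [CoPrescriptionNetwork-class] (unclustered).
#' @export
buildNetwork <- function(pairs, prevalence, itemInfo = NULL) {
  if (!nrow(pairs)) stop("no pairs to build a network from")
  its <- if (!is.null(pairs$items)) pairs$items
         else strsplit(pairs$key, "+", fixed = TRUE)
  if (any(lengths(its) != 2L)) stop("pairs must have exactly 2 items")
  a <- vapply(its, function(x) sortCodes(x)[1], "")
  b <- vapply(its, function(x) sortCodes(x)[2], "")
  if (any(a == b)) stop("self-loop in pair input")
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate pair in input: ", sub("\r", " + ", key[duplicated(key)][1]))
  codes <- sortCodes(unique(c(a, b)))
  missing <- setdiff(codes, names(prevalence))
  if (length(missing))
    stop("no prevalence entry for item '", missing[1], "'")
  info <- data.frame(code = codes, name = codes,
                     kind = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(itemInfo)) {
    i <- match(codes, itemInfo$code)
    info$name <- ifelse(is.na(i), codes, itemInfo$name[i])
    info$kind <- itemInfo$kind[i]
  }
  nodes <- data.frame(code = codes, name = info$name, kind = info$kind,
                      prevalence = as.numeric(prevalence[codes]),
                      cluster_id = NA_integer_, is_cluster_core = FALSE,
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = a, to = b,
                      support = pairs$support,
                      confidence = pairs$confidence,
                      lift = pairs$lift, stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  new("CoPrescriptionNetwork", nodes = nodes, edges = edges,
      modularity = NA_real_, cores = list())
}

asIgraph <- function(net) {
  nd <- net@nodes
  names(nd)[names(nd) == "name"] <- "label"  # igraph reserves 'name' for ids
  igraph::graph_from_data_frame(net@edges, directed = FALSE, vertices = nd)
}

#' Detect clusters by greedy modularity maximisation
#'
#' Runs Clauset-Newman-Moore agglomerative modularity maximisation (via
#' `igraph::cluster_fast_greedy`) on the chosen edge weights. The default
#' weight is pair support — the frequency with which a combination is
#' prescribed — so clusters group herbs that are actually dispensed
#' together. Every node receives a label; clusters are renumbered 1, 2, ...
#' by decreasing total member prevalence (ties by smallest member code), so
#' cluster 1 is the most prevalent group. The algorithm and the relabelling
#' are deterministic: identical input yields identical labels.
#'
#' @param net a [CoPrescriptionNetwork-class].
#' @param weights `"support"` (default), `"lift"`, or `"unweighted"`.
#' @return The network with `cluster_id` filled and `modularity` set.
#' @export
detectClusters <- function(net, weights = c("support", "lift",
                                            "unweighted")) {
  weights <- match.arg(weights)
  if (!nrow(net@nodes)) stop("empty network")
  g <- asIgraph(net)
  w <- if (weights == "unweighted") NULL else net@edges[[weights]]
  cl <- igraph::cluster_fast_greedy(g, weights = w)
  memb <- igraph::membership(cl)
  memb <- as.integer(memb[net@nodes$code])
  # deterministic relabelling: by decreasing summed prevalence, then by
  # lexicographically smallest member
  prev <- tapply(net@nodes$prevalence, memb, sum)
  first <- tapply(net@nodes$code, memb, function(x) sortCodes(x)[1])
  ord <- order(-as.numeric(prev), as.character(first), method = "radix")
  relab <- integer(length(prev))
  relab[as.integer(names(prev))[ord]] <- seq_along(ord)
  net@nodes$cluster_id <- relab[memb]
  net@modularity <- igraph::modularity(g, memb, weights = w)
  net
}

weightedDegree <- function(net, weight = "support") {
  wd <- setNames(numeric(nrow(net@nodes)), net@nodes$code)
  for (col in c("from", "to")) {
    s <- tapply(net@edges[[weight]], net@edges[[col]], sum)
    wd[names(s)] <- wd[names(s)] + as.numeric(s)
  }
  wd
}

#' Identify per-cluster and global core herbs
#'
#' The core of a cluster (and of the whole network) is the node maximising,
#' in order: prevalence, support-weighted degree, then smallest code. This
#' operationalises the notion of a sovereign medicinal: the most prevalent,
#' most-connected herb of a group.
#'
#' @param net a clustered [CoPrescriptionNetwork-class] (run
#'   [detectClusters()] first).
#' @return The network with `is_cluster_core` flags set and the `cores`
#'   slot filled (`perCluster`: named by cluster id; `global`).
#' @export
identifyCores <- function(net) {
  nd <- net@nodes
  if (any(is.na(nd$cluster_id)))
    stop("clusters not assigned; run detectClusters() first")
  wd <- weightedDegree(net)
  pickCore <- function(idx) {
    o <- idx[order(-nd$prevalence[idx], -wd[nd$code[idx]], nd$code[idx],
                   method = "radix")]
    o[1]
  }
  per <- vapply(split(seq_len(nrow(nd)), nd$cluster_id), pickCore, 0L)
  globalIdx <- pickCore(seq_len(nrow(nd)))
  nd$is_cluster_core <- seq_len(nrow(nd)) %in% per
  net@nodes <- nd
  net@cores <- list(perCluster = setNames(nd$code[per], names(per)),
                    global = nd$code[globalIdx])
  net
}

#' Export / import a co-prescription network
#'
#' GraphML (typed node/edge attributes, via igraph), a whitespace edge list
#' with a weight column (support), or a JSON graph. GraphML and JSON
#' round-trip through [importGraph()] reproducing nodes, edges and
#' attributes; the edge list keeps only the topology and weight.
#'
#' @param net a [CoPrescriptionNetwork-class].
#' @param path output file.
#' @param format "graphml", "edgelist" or "json".
#' @return `path` invisibly (`exportGraph`); a
#'   [CoPrescriptionNetwork-class] (`importGraph`).
#' @export
exportGraph <- function(net, path, format = c("graphml", "edgelist",
                                              "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- asIgraph(net)
    # drop all-NA attributes (e.g. cluster_id before clustering)
    for (at in igraph::vertex_attr_names(g))
      if (all(is.na(igraph::vertex_attr(g, at))))
        g <- igraph::delete_vertex_attr(g, at)
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "edgelist") {
    write.table(net@edges[c("from", "to", "support")], path,
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(
      list(nodes = net@nodes, edges = net@edges,
           modularity = net@modularity, cores = net@cores),
      path, digits = NA, auto_unbox = TRUE, na = "null")
  }
  invisible(path)
}

#' @rdname exportGraph
#' @export
importGraph <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nd <- igraph::as_data_frame(g, what = "vertices")
    ed <- igraph::as_data_frame(g, what = "edges")
    nodes <- data.frame(
      code = nd$name, name = nd$label %||% nd$name,
      kind = nd$kind %||% NA_character_,
      prevalence = nd$prevalence,
      cluster_id = as.integer(nd$cluster_id %||% NA_integer_),
      is_cluster_core = as.logical(nd$is_cluster_core %||% FALSE),
      stringsAsFactors = FALSE)
    edges <- data.frame(from = pmin(ed$from, ed$to),
                        to = pmax(ed$from, ed$to),
                        support = ed$support, confidence = ed$confidence,
                        lift = ed$lift, stringsAsFactors = FALSE)
    nodes <- nodes[orderCodes(nodes$code), , drop = FALSE]
    edges <- edges[order(edges$from, edges$to, method = "radix"), ,
                   drop = FALSE]
    rownames(nodes) <- rownames(edges) <- NULL
    new("CoPrescriptionNetwork", nodes = nodes, edges = edges,
        modularity = NA_real_, cores = list())
  } else {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    nodes <- as.data.frame(x$nodes)
    nodes$cluster_id <- as.integer(nodes$cluster_id)
    cores <- if (length(x$cores))
      list(perCluster = unlist(x$cores$perCluster), global = x$cores$global)
      else list()
    new("CoPrescriptionNetwork", nodes = nodes,
        edges = as.data.frame(x$edges),
        modularity = as.numeric(x$modularity %||% NA_real_), cores = cores)
  }
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two cluster assignments over the same
#' elements; 1 for identical partitions, ~0 for independent ones. Used to
#' score recovery of planted structure.
#'
#' @param x,y vectors of cluster labels (equal length; NAs treated as
#'   singleton labels).
#' @return The adjusted Rand index.
#' @export
adjustedRand <- function(x, y) {
  stopifnot(length(x) == length(y))
  x <- as.character(x); y <- as.character(y)
  x[is.na(x)] <- paste0(".naX", seq_along(x))[is.na(x)]
  y[is.na(y)] <- paste0(".naY", seq_along(y))[is.na(y)]
  tab <- table(x, y)
  n <- length(x)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expct <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expct) return(1)
  (sij - expct) / (mx - expct)
}

#' Score recovery of planted clusters
#'
#' Compares the detected partition with the planted assignment of a
#' synthetic cohort, over the nodes present in the network (planted items
#' absent from the network are ignored; unplanted network nodes count as
#' their own singleton truth classes).
#'
#' @param net a clustered [CoPrescriptionNetwork-class].
#' @param truth a [GroundTruth-class].
#' @return list: `nClusters`, `ari`, `globalCore` (NA if
#'   [identifyCores()] has not run).
#' @export
evaluateRecovery <- function(net, truth) {
  lab <- clusterLabels(net)
  planted <- truth@assignments[names(lab)]
  list(nClusters = length(unique(lab[!is.na(lab)])),
       ari = adjustedRand(as.vector(planted), as.vector(lab)),
       globalCore = if (length(net@cores)) net@cores$global else NA_character_)
}
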