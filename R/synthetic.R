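# Synthetic claims-style cohort generator with planted co-prescription
# structure. The generator is the study-condition oracle for the rest of
# the package: its marginal prevalences, prescription-size distribution,
# planted clusters and decoy visits define what the cohort filter, the
# miner and the network stage are expected to recover.

DEFAULT_DOSE_MODEL <- list(
  # lognormal parameters; means ~4.2 g/day (HF) and ~1.25 g/day (SH),
  # durations ~12 days/visit, matching the scales reported for reimbursed
  # CHM prescriptions
  HF = list(doseMeanlog = log(4.2) - 0.18^2 / 2, doseSdlog = 0.18,
            durMeanlog = log(12) - 0.25^2 / 2, durSdlog = 0.25),
  SH = list(doseMeanlog = log(1.25) - 0.25^2 / 2, doseSdlog = 0.25,
            durMeanlog = log(11.5) - 0.25^2 / 2, durSdlog = 0.25))

#' Default items-per-prescription distribution
#'
#' A unimodal discrete pmf on 1..15 with mean `meanItems` and mode 7,
#' mixing two binomials. The mixture is chosen to keep the index of
#' dispersion near 1 (~1.13): under odds-proportional sampling the expected
#' pairwise lift of independent items is E\[k(k-1)\]/E\[k\]^2, so a
#' near-Poisson size distribution is what makes "no planted structure" mean
#' "lift = 1".
#'
#' @param meanItems target mean prescription size (default 6.2).
#' @return Named numeric pmf over sizes 1..15.
#' @export
defaultItemsPerRx <- function(meanItems = 6.2) {
  k <- 1:15
  mix <- function(w) {
    f <- w * dbinom(k, 20, 0.36) + (1 - w) * dbinom(k, 20, 0.15)
    f / sum(f)
  }
  w <- uniroot(function(w) sum(k * mix(w)) - meanItems,
               c(0.01, 0.99), tol = 1e-12)$root
  setNames(mix(w), k)
}

# literature-scale head of the catalog: 5 formulas and 10 single herbs with
# prevalences on the scale reported for an endometriosis CHM cohort, plus
# further named items used by the planted-cluster demonstration
namedCatalog <- function() {
  data.frame(
    code = c("HF001", "HF002", "HF003", "HF004", "HF005",
             "SH001", "SH002", "SH003", "SH004", "SH005",
             "SH006", "SH007", "SH008", "SH009", "SH010",
             "SH011", "SH012", "SH013", "SH014",
             "HF006", "HF007", "HF008", "HF009"),
    name = c("Gui-Zhi-Fu-Ling-Wan", "Jia-Wei-Xiao-Yao-San",
             "Dang-Gui-Shao-Yao-San", "Shao-Fu-Zhu-Yu-Tang",
             "Wen-Jing-Tang",
             "Cyperus rotundus", "Corydalis yanhusuo",
             "Leonurus heterophyllus", "Curcuma phaelculis",
             "Salvia miltiorrhiza", "Typha angustifolia",
             "Trogopterus xanthipes", "Taraxacum mongolicum",
             "Cuscuta chinensis", "Sparganium stoloniferum",
             "Melia toosendan", "Eclipta prostrata", "Ligustrum lucidum",
             "Prunella vulgaris",
             "Xue-Fu-Zhu-Yu-Tang", "Tao-Hong-Si-Wu-Tang", "Shi-Xiao-San",
             "Dan-Shen-Yin"),
    kind = c(rep("HF", 5), rep("SH", 14), rep("HF", 4)),
    prevalence = c(0.281, 0.172, 0.150, 0.119, 0.111,
                   0.188, 0.169, 0.116, 0.103, 0.097,
                   0.086, 0.073, 0.069, 0.068, 0.068,
                   0.059, 0.095, 0.085, 0.050,
                   0.060, 0.090, 0.075, 0.065),
    stringsAsFactors = FALSE)
}

#' Default item catalog
#'
#' 23 named items (formulas and single herbs) on the prevalence scale of a
#' real CHM cohort head (1.9%-28.1%), plus a long log-spaced tail of filler
#' items below 4.5% prevalence, scaled so that total prevalence equals the
#' target mean prescription size (a feasibility identity: summed marginals
#' must equal the mean number of items drawn per prescription).
#'
#' @param meanItems target mean prescription size.
#' @param nTail number of tail items.
#' @return data.frame: code, name, kind, prevalence.
#' @export
defaultCatalog <- function(meanItems = 6.2, nTail = 172L) {
  head <- namedCatalog()
  raw <- exp(seq(log(0.044), log(0.008), length.out = nTail))
  tail <- data.frame(
    code = sprintf("CH%03d", seq_len(nTail)),
    name = sprintf("Catalog herb %03d", seq_len(nTail)),
    kind = rep_len(c("SH", "HF"), nTail),
    prevalence = raw * (meanItems - sum(head$prevalence)) / sum(raw),
    stringsAsFactors = FALSE)
  rbind(head, tail)
}

#' Construct a synthetic cohort specification
#'
#' @param nPatients number of patients.
#' @param meanVisits,dispersion negative-binomial CHM-visit count per
#'   patient (dispersion = NB size).
#' @param catalog item catalog (code, name, kind, prevalence); defaults to
#'   [defaultCatalog()].
#' @param itemsPerRx named pmf over prescription sizes; defaults to
#'   [defaultItemsPerRx()].
#' @param clusters named list of disjoint code sets to plant.
#' @param boost within-cluster odds multiplier (scalar or per cluster).
#' @param hubCode code of the dominant hub item, NA for none.
#' @param doseModel per-kind lognormal dose/duration parameters.
#' @param decoyFraction named fractions (age, diagnosis, therapy) of decoy
#'   visits, each breaking exactly one cohort rule.
#' @param seed default seed used by [generateCohort()].
#' @return A [SyntheticCohortSpec-class].
#' @export
cohortSpec <- function(nPatients = 2000L, meanVisits = 5, dispersion = 2,
                       catalog = defaultCatalog(),
                       itemsPerRx = defaultItemsPerRx(),
                       clusters = list(), boost = 1,
                       hubCode = NA_character_,
                       doseModel = DEFAULT_DOSE_MODEL,
                       decoyFraction = c(age = 0, diagnosis = 0,
                                         therapy = 0),
                       seed = 1) {
  new("SyntheticCohortSpec", seed = seed, nPatients = as.integer(nPatients),
      visitsPerPatient = list(mean = meanVisits, dispersion = dispersion),
      catalog = catalog, itemsPerRx = itemsPerRx, clusters = clusters,
      boost = boost, hubCode = hubCode, doseModel = doseModel,
      decoyFraction = decoyFraction)
}

#' The default planted-cluster specification
#'
#' Six disjoint clusters (sizes 6, 5, 4, 3, 3 and an isolated pair) over
#' the named catalog head, within-cluster odds boost 8, and the most
#' prevalent formula (target marginal 0.281) as the hub inside cluster 1 —
#' mirroring the qualitative structure of a published endometriosis
#' co-prescription network, including its isolated two-herb cluster.
#'
#' @param nPatients number of patients (10,000 with 5 visits/patient on
#'   average gives ~50,000 prescriptions).
#' @param boost within-cluster odds boost.
#' @param ... passed on to [cohortSpec()].
#' @return A [SyntheticCohortSpec-class].
#' @export
plantedCohortSpec <- function(nPatients = 10000L, boost = 8, ...) {
  clusters <- list(
    c1 = c("HF001", "HF002", "SH004", "SH010", "SH003", "SH005"),
    c2 = c("SH002", "SH006", "SH007", "SH011", "HF004"),
    c3 = c("SH001", "SH008", "SH014", "HF006"),
    c4 = c("HF003", "HF005", "SH009"),
    c5 = c("HF007", "HF008", "HF009"),
    c6 = c("SH012", "SH013"))
  cohortSpec(nPatients = nPatients, clusters = clusters, boost = boost,
             hubCode = "HF001", ...)
}

# Inclusion probabilities of the exponential-race sampler (successive
# odds-proportional sampling without replacement): item i is included in a
# size-k draw iff fewer than k of the other items' Exp(w_j) arrivals
# precede its own. The count of other arrivals by time t is approximated
# as normal; the race integral is evaluated on a fixed grid.
raceInclusion <- function(wt, pmf, sizes, grid = 512L) {
  m <- length(wt)
  kmax <- max(sizes)
  if (kmax >= m) return(rep(1, m))
  # span well past the expected k-th arrival time
  tk <- uniroot(function(t) sum(1 - exp(-wt * t)) - kmax,
                c(1e-12, 1e8), tol = 1e-10)$root
  tg <- seq(0, 4 * tk, length.out = grid + 1L)[-1L]
  dt <- tg[2L] - tg[1L]
  Q <- 1 - exp(-outer(wt, tg))               # m x T inclusion-by-t
  muAll <- colSums(Q)
  varAll <- colSums(Q * (1 - Q))
  piOut <- numeric(m)
  dens <- wt * exp(-outer(wt, tg))           # m x T arrival density
  for (i in seq_len(m)) {
    mu <- muAll - Q[i, ]
    va <- pmax(varAll - Q[i, ] * (1 - Q[i, ]), 1e-12)
    Pk <- vapply(sizes, function(kk)
      pnorm((kk - 0.5 - mu) / sqrt(va)), numeric(length(tg)))
    piOut[i] <- sum(dens[i, ] * as.vector(Pk %*% pmf)) * dt
  }
  piOut
}

# Fixed-point calibration of base odds so that realized marginals hit the
# catalog targets under the boost-free sampler. Deterministic (no RNG).
calibrateWeights <- function(p, pmf) {
  sizes <- as.integer(names(pmf))
  keep <- pmf > 0
  pmf <- pmf[keep] / sum(pmf[keep]); sizes <- sizes[keep]
  sure <- p >= 1 - 1e-9
  wt <- p / (1 - pmin(p, 0.999))
  if (all(sure)) return(list(wt = wt, sure = sure))
  # items that are always present shift the effective draw sizes
  effSizes <- pmax(sizes - sum(sure), 0L)
  if (!any(effSizes > 0)) return(list(wt = wt, sure = sure))
  wt[!sure] <- {
    w <- p[!sure] / (1 - p[!sure])
    target <- p[!sure]
    for (it in 1:25) {
      pii <- raceInclusion(w, pmf, effSizes)
      w <- w * target / pmax(pii, 1e-12)
    }
    w
  }
  list(wt = wt, sure = sure)
}

randomDates <- function(n, from, to) {
  from <- as.Date(from); to <- as.Date(to)
  from + floor(runif(n) * (as.numeric(to - from) + 1))
}

#' Generate a synthetic claims-style cohort
#'
#' Deterministic for a fixed seed. Each patient receives one index
#' gynecology visit (primary diagnosis in the 617.x rubric, no dispensed
#' items) and a negative-binomial number of CHM visits. Each prescription's
#' item set is drawn by: (1) a size k from `itemsPerRx`; (2) a seeded
#' cluster with probability proportional to summed member prevalence (when
#' clusters are planted); (3) k items by sequential odds-proportional
#' sampling without replacement, an item's odds multiplied by its cluster's
#' boost while that cluster is active (seeded, or an item of it already
#' chosen). Base odds are calibrated so that with all boosts at 1 realized
#' marginals match the catalog targets. Doses and durations are lognormal
#' by item kind. Decoy visits, `round(fraction * prescriptions)` per
#' violation type, each break exactly one cohort rule (age outside 20-50,
#' index diagnosis not in first position, or an excluded therapy flag), so
#' attrition counts are analytically predictable.
#'
#' @param spec a [SyntheticCohortSpec-class].
#' @param seed integer seed (defaults to `spec@seed`).
#' @return list: `cohort` ([ChmCohort-class]), `truth`
#'   ([GroundTruth-class]).
#' @export
generateCohort <- function(spec, seed = spec@seed) {
  validObject(spec)
  cat <- spec@catalog
  m <- nrow(cat)
  sizes <- as.integer(names(spec@itemsPerRx))
  if (max(sizes[spec@itemsPerRx > 0]) > m)
    stop("infeasible spec: prescription size exceeds catalog size")
  mu <- sum(sizes * spec@itemsPerRx)
  if (abs(sum(cat$prevalence) - mu) / mu > 0.02)
    stop("infeasible spec: summed prevalence targets (",
         round(sum(cat$prevalence), 2), ") must equal the mean ",
         "prescription size (", round(mu, 2), ")")

  calib <- calibrateWeights(cat$prevalence, spec@itemsPerRx)
  clusterOf <- rep(-1L, m)
  nc <- length(spec@clusters)
  for (ci in seq_len(nc))
    clusterOf[match(spec@clusters[[ci]], cat$code)] <- ci - 1L
  boost <- rep_len(if (length(spec@boost)) spec@boost else 1, max(nc, 1L))

  set.seed(as.integer(seed %% 2147483647))

  nP <- spec@nPatients
  patientIds <- sprintf("P%05d", seq_len(nP))
  nRx <- rnbinom(nP, mu = spec@visitsPerPatient$mean,
                 size = spec@visitsPerPatient$dispersion)
  entry <- randomDates(nP, "1998-01-01", "2011-12-31")
  entryAge <- runif(nP, 21, 47.5)  # completed-years window stays inside 20-50
  birth <- entry - round(entryAge * 365.25)

  nV <- sum(nRx)
  dec <- round(spec@decoyFraction * nV)
  nDecoy <- sum(dec)

  # --- prescription visits (valid + decoys share the item machinery) ---
  nAll <- nV + nDecoy
  kAll <- sample(sizes, nAll, replace = TRUE, prob = spec@itemsPerRx)
  # each visit seeds one planted cluster, uniformly: every cluster then
  # surfaces in the co-occurrence structure regardless of its members'
  # marginal prevalence
  seedCl <- if (nc) sample.int(nc, nAll, replace = TRUE) - 1L
            else rep(-1L, nAll)
  itemIdx <- sample_visit_items(as.integer(kAll), calib$wt, clusterOf,
                                boost, as.integer(seedCl), calib$sure)

  pat <- c(rep.int(seq_len(nP), nRx),                  # valid rx
           sample.int(nP, nDecoy, replace = TRUE))     # decoys
  # follow-up capped at ~2.4 years so every regular visit stays inside the
  # 20-50 completed-years window (entry ages are drawn in 21-47.5)
  vdate <- entry[pat] + round(runif(nAll, 0, 870))
  decType <- rep(c("none", "age", "diagnosis", "therapy"),
                 c(nV, dec["age"], dec["diagnosis"], dec["therapy"]))
  # age decoys: move the visit past the upper age bound
  isAge <- decType == "age"
  vdate[isAge] <- birth[pat[isAge]] + round(52.5 * 365.25)

  dxPool <- c("625.3", "256.4", "780.79", "626.2")
  primary <- sample(c("617.0", "617.1", "617.9"), nAll, replace = TRUE,
                    prob = c(0.6, 0.25, 0.15))
  secondary <- sample(dxPool, nAll, replace = TRUE)
  dx <- ifelse(runif(nAll) < 0.5, paste(primary, secondary, sep = ";"),
               primary)
  isDx <- decType == "diagnosis"
  dx[isDx] <- paste(secondary[isDx], primary[isDx], sep = ";")
  ther <- rep("chm", nAll)
  isTher <- decType == "therapy"
  ther[isTher] <- paste("chm", sample(c("acupuncture", "moxibustion",
                                        "manual"), sum(isTher),
                                      replace = TRUE), sep = ";")

  rxVisits <- data.frame(
    visit_id = sprintf("V%06d", seq_len(nAll)),
    patient_id = patientIds[pat],
    visit_date = vdate, birth_date = birth[pat],
    specialty = "tcm", diagnoses = dx, therapies = ther,
    stringsAsFactors = FALSE)

  # --- index gynecology visits (diagnosis established, nothing dispensed)
  idxVisits <- data.frame(
    visit_id = sprintf("G%05d", seq_len(nP)),
    patient_id = patientIds,
    visit_date = entry, birth_date = birth,
    specialty = "gynecology",
    diagnoses = sample(c("617.0", "617.1", "617.9"), nP, replace = TRUE),
    therapies = "", stringsAsFactors = FALSE)

  # --- dispensed items with lognormal doses/durations by kind ---
  rows <- rep.int(seq_len(nAll), lengths(itemIdx))
  codeIdx <- unlist(itemIdx, use.names = FALSE)
  kind <- cat$kind[codeIdx]
  dm <- spec@doseModel
  dose <- dur <- numeric(length(codeIdx))
  for (kd in c("HF", "SH")) {
    sel <- kind == kd
    dose[sel] <- rlnorm(sum(sel), dm[[kd]]$doseMeanlog, dm[[kd]]$doseSdlog)
    dur[sel] <- rlnorm(sum(sel), dm[[kd]]$durMeanlog, dm[[kd]]$durSdlog)
  }
  items <- data.frame(
    visit_id = rxVisits$visit_id[rows],
    code = cat$code[codeIdx], name = cat$name[codeIdx], kind = kind,
    dose_g_day = round(dose, 2),
    duration_days = pmax(1, round(dur)),
    stringsAsFactors = FALSE)

  cohort <- chmCohort(rbind(idxVisits, rxVisits), items)

  assign <- rep(NA_integer_, m)
  for (ci in seq_len(nc)) assign[clusterOf == ci - 1L] <- ci
  pairs <- do.call(rbind, lapply(seq_len(nc), function(ci) {
    cl <- sortCodes(spec@clusters[[ci]])
    if (length(cl) < 2) return(NULL)
    cmb <- combn(cl, 2)
    data.frame(a = cmb[1, ], b = cmb[2, ], cluster = ci,
               stringsAsFactors = FALSE)
  }))
  truth <- new("GroundTruth",
               assignments = setNames(assign, cat$code),
               plantedPairs = pairs %||%
                 data.frame(a = character(), b = character(),
                            cluster = integer(), stringsAsFactors = FALSE),
               marginals = setNames(cat$prevalence, cat$code),
               decoyCounts = setNames(as.integer(dec), names(dec)),
               counts = list(nIndexVisits = as.integer(nP),
                             nPrescriptions = as.integer(nV),
                             nDecoys = as.integer(nDecoy)))
  list(cohort = cohort, truth = truth)
}

#' Compare intended and realized generator calibration
#'
#' For every catalog item: intended vs realized marginal prevalence over
#' generated prescriptions (all visits with dispensed items), with binomial
#' standard errors and z-scores; plus the intended vs realized mean
#' prescription size. With no planted boosts every |z| is expected within
#' ~3; planted boosts deliberately shift clustered items' marginals.
#'
#' @param cohort the generated [ChmCohort-class].
#' @param spec the [SyntheticCohortSpec-class] that produced it.
#' @return list: `items` (data.frame code, target, realized, se, z),
#'   `meanItems` (list target, realized, se, z), `nPrescriptions`.
#' @export
calibrationReport <- function(cohort, spec) {
  withItems <- unique(cohort@items$visit_id)
  n <- length(withItems)
  if (!n) stop("no prescriptions in cohort")
  counts <- table(cohort@items$code)
  target <- setNames(spec@catalog$prevalence, spec@catalog$code)
  realized <- setNames(as.numeric(counts[names(target)]), names(target))
  realized[is.na(realized)] <- 0
  realized <- realized / n
  se <- sqrt(pmax(target * (1 - target), 1e-12) / n)
  itemDf <- data.frame(code = names(target), target = as.numeric(target),
                       realized = realized, se = se,
                       z = (realized - target) / se,
                       stringsAsFactors = FALSE)
  rownames(itemDf) <- NULL
  szPerVisit <- table(cohort@items$visit_id)
  muT <- sum(as.integer(names(spec@itemsPerRx)) * spec@itemsPerRx)
  varT <- sum(as.integer(names(spec@itemsPerRx))^2 * spec@itemsPerRx) -
    muT^2
  muR <- mean(as.numeric(szPerVisit))
  seMu <- sqrt(varT / n)
  list(items = itemDf,
       meanItems = list(target = muT, realized = muR, se = seMu,
                        z = (muR - muT) / seMu),
       nPrescriptions = n)
}

#' Write a synthetic spec / ground truth to disk
#'
#' The spec is written as YAML (catalog inline), the truth as JSON.
#'
#' @param spec a [SyntheticCohortSpec-class].
#' @param truth a [GroundTruth-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSpec <- function(spec, path) {
  yaml::write_yaml(list(
    seed = spec@seed, nPatients = spec@nPatients,
    visitsPerPatient = spec@visitsPerPatient,
    catalog = spec@catalog, itemsPerRx = as.list(spec@itemsPerRx),
    clusters = spec@clusters, boost = spec@boost,
    hubCode = if (is.na(spec@hubCode)) NULL else spec@hubCode,
    doseModel = spec@doseModel,
    decoyFraction = as.list(spec@decoyFraction)), path)
  invisible(path)
}

#' @rdname writeSpec
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(list(
    assignments = as.list(truth@assignments),
    plantedPairs = truth@plantedPairs,
    marginals = as.list(truth@marginals),
    decoyCounts = as.list(truth@decoyCounts),
    counts = truth@counts), path, digits = NA, auto_unbox = TRUE,
    na = "null")
  invisible(path)
}
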