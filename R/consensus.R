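# Predictor binarization, consensus calls and cohort contingency statistics.

PREDICTOR_TOOLS <- c("sift", "polyphen2", "mutationassessor", "condel")

# category -> binary maps per tool (case/punctuation-insensitive)
normalizeRaw <- function(x) gsub("[^a-z]", "", tolower(x))

PREDICTOR_MAPS <- list(
  sift = c(damaging = "damaging", deleterious = "damaging",
           tolerated = "tolerated", neutral = "tolerated"),
  polyphen2 = c(probabledeleterious = "damaging",
                probablydeleterious = "damaging",
                probablydamaging = "damaging",
                possiblydeleterious = "damaging",
                possiblydamaging = "damaging",
                benign = "tolerated"),
  mutationassessor = c(high = "damaging", medium = "damaging",
                       low = "tolerated", neutral = "tolerated"),
  condel = c(deleterious = "damaging", damaging = "damaging",
             neutral = "tolerated", tolerated = "tolerated"))

#' Binarize a raw predictor category
#'
#' PolyPhen2 "probably/possibly deleterious" and MutationAssessor
#' "high"/"medium" map to damaging; PolyPhen2 "benign" and MutationAssessor
#' "neutral"/"low" to tolerated; SIFT and Condel are natively binary. Empty
#' or unrecognized categories are unavailable.
#'
#' @param tool one of \code{"sift"}, \code{"polyphen2"},
#'   \code{"mutationassessor"}, \code{"condel"}
#' @param raw raw category string
#' @return list with \code{tool}, \code{raw}, \code{binary} (one of
#'   \code{"damaging"}, \code{"tolerated"}, \code{"unavailable"})
#' @examples binarizeVerdict("polyphen2", "possibly deleterious")
#' @export
binarizeVerdict <- function(tool, raw) {
  tool <- tolower(tool)
  if (!tool %in% PREDICTOR_TOOLS) stop("unknown predictor tool: ", tool)
  key <- normalizeRaw(raw %||% "")
  bin <- if (is.na(raw) || key == "") "unavailable"
  else unname(PREDICTOR_MAPS[[tool]][key]) %||% "unavailable"
  list(tool = tool, raw = raw, binary = bin)
}

#' Consensus call over up to four predictor verdicts
#'
#' Majority vote over the available binarized verdicts. Equal numbers of
#' damaging and tolerated responses (including none available) give a
#' noninformative call. Concordance is \code{"full"} only when all four
#' tools are available and unanimous, \code{"partial"} for other majority
#' calls, \code{"none"} for noninformative.
#'
#' @param verdicts list of verdicts from \code{\link{binarizeVerdict}}, or a
#'   data.frame with columns \code{tool} and \code{binary}; at most one
#'   verdict per tool
#' @return list with \code{call}, \code{concordance}, \code{nAvailable}
#' @export
consensusClassify <- function(verdicts) {
  if (is.data.frame(verdicts)) {
    df <- verdicts
  } else {
    df <- data.frame(tool = vapply(verdicts, `[[`, "", "tool"),
                     binary = vapply(verdicts, `[[`, "", "binary"),
                     stringsAsFactors = FALSE)
  }
  if (anyDuplicated(df$tool)) stop("duplicate predictor tool in verdicts")
  nD <- sum(df$binary == "damaging")
  nT <- sum(df$binary == "tolerated")
  nAvail <- nD + nT
  if (nD == nT) {
    return(list(call = "noninformative", concordance = "none",
                nAvailable = nAvail))
  }
  call <- if (nD > nT) "damaging" else "tolerated"
  conc <- if (nAvail == 4 && (nD == 4 || nT == 4)) "full" else "partial"
  list(call = call, concordance = conc, nAvailable = nAvail)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction by default (set \code{correct = TRUE} for
#' the Yates-corrected variant); df = 1, upper-tail p value.
#'
#' @param counts 2x2 matrix (or coercible) of nonnegative integers with all
#'   marginals positive
#' @param correct apply the continuity correction (default FALSE)
#' @return a \linkS4class{ContingencyResult}
#' @examples chiSquare2x2(matrix(c(240, 40, 536, 370), 2))
#' @export
chiSquare2x2 <- function(counts, correct = FALSE) {
  m <- as.matrix(counts)
  if (!all(dim(m) == c(2, 2))) stop("counts must be a 2x2 table")
  if (any(m < 0) || any(m != round(m))) stop("counts must be nonnegative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("all marginals must be positive")
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  new("ContingencyResult", counts = m, chi2 = unname(ct$statistic),
      df = unname(ct$parameter), pValue = unname(ct$p.value),
      correct = correct)
}

# round half up at `digits` decimals (matches printed table percentages)
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

pctOf <- function(num, den) {
  ifelse(den > 0, roundHalfUp(100 * num / den, 1), 0)
}

# ensure records carry consensus_call / concordance, deriving them from raw
# predictor columns when necessary
withConsensus <- function(records) {
  if (all(c("consensus_call", "concordance") %in% names(records)))
    return(records)
  if (!all(PREDICTOR_TOOLS %in% names(records)))
    stop("records need consensus_call/concordance or the four predictor columns")
  calls <- lapply(seq_len(nrow(records)), function(i) {
    v <- lapply(PREDICTOR_TOOLS, function(t)
      binarizeVerdict(t, records[[t]][i]))
    consensusClassify(v)
  })
  records$consensus_call <- vapply(calls, `[[`, "", "call")
  records$concordance <- vapply(calls, `[[`, "", "concordance")
  records
}

#' Cohort summary: predictor table, structure table and contingency test
#'
#' Reproduces the cohort reporting layout: per clinical class, counts and
#' percentages of damaging / tolerated / noninformative consensus calls;
#' and, for VUS records, counts of variants mapped onto structure and of
#' structurally damaging variants per consensus stratum (by all predictors /
#' by most predictors / total), with a chi-square test of structural damage
#' across damaging-vs-tolerated consensus. Percentages are recomputed from
#' the counts, rounded half-up to one decimal.
#'
#' @param records data.frame with columns \code{clinical_class} (one of
#'   deleterious/benign/vus/other), either \code{consensus_call} +
#'   \code{concordance} or the four raw predictor columns, and for the
#'   structure table \code{mapped} (logical) and \code{struct_damaging}
#'   (logical, NA when unmapped)
#' @return a \linkS4class{CohortSummary}
#' @export
summarizeCohort <- function(records) {
  emptyPred <- data.frame(clinical_class = character(), n_damaging = integer(),
                          pct_damaging = numeric(), n_tolerated = integer(),
                          pct_tolerated = numeric(),
                          n_noninformative = integer(),
                          pct_noninformative = numeric(), n_total = integer())
  if (nrow(records) == 0) {
    return(new("CohortSummary", predictionTable = emptyPred,
               structureTable = emptyStructureTable(), contingency = NULL))
  }
  records <- withConsensus(records)
  classes <- intersect(c("deleterious", "benign", "vus", "other"),
                       unique(records$clinical_class))
  pred <- do.call(rbind, lapply(classes, function(cl) {
    r <- records[records$clinical_class == cl, ]
    n <- nrow(r)
    nD <- sum(r$consensus_call == "damaging")
    nT <- sum(r$consensus_call == "tolerated")
    nN <- sum(r$consensus_call == "noninformative")
    data.frame(clinical_class = cl, n_damaging = nD,
               pct_damaging = pctOf(nD, n), n_tolerated = nT,
               pct_tolerated = pctOf(nT, n), n_noninformative = nN,
               pct_noninformative = pctOf(nN, n), n_total = n,
               stringsAsFactors = FALSE)
  }))
  vus <- records[records$clinical_class == "vus", , drop = FALSE]
  st <- structureTableOf(vus)
  cont <- NULL
  if (all(c("mapped", "struct_damaging") %in% names(vus)) && nrow(vus) > 0) {
    dm <- vus$mapped & vus$consensus_call == "damaging"
    tm <- vus$mapped & vus$consensus_call == "tolerated"
    tab <- matrix(c(sum(dm & vus$struct_damaging %in% TRUE),
                    sum(tm & vus$struct_damaging %in% TRUE),
                    sum(dm & vus$struct_damaging %in% FALSE),
                    sum(tm & vus$struct_damaging %in% FALSE)), 2)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      cont <- chiSquare2x2(tab)
  }
  if (is.null(pred)) pred <- emptyPred
  new("CohortSummary", predictionTable = pred,
      structureTable = st, contingency = cont)
}

emptyStructureTable <- function() {
  data.frame(stratum = character(), n_total = integer(), n_mapped = integer(),
             pct_mapped = numeric(), n_damaging = integer(),
             pct_damaging = numeric(), n_tolerated_effect = integer(),
             pct_tolerated_effect = numeric(), stringsAsFactors = FALSE)
}

structureTableOf <- function(vus) {
  if (nrow(vus) == 0 ||
        !all(c("mapped", "struct_damaging") %in% names(vus)))
    return(emptyStructureTable())
  strata <- list(
    damaging_by_all = quote(consensus_call == "damaging" &
                              concordance == "full"),
    damaging_by_most = quote(consensus_call == "damaging" &
                               concordance == "partial"),
    damaging_total = quote(consensus_call == "damaging"),
    noninformative = quote(consensus_call == "noninformative"),
    tolerated_by_all = quote(consensus_call == "tolerated" &
                               concordance == "full"),
    tolerated_by_most = quote(consensus_call == "tolerated" &
                                concordance == "partial"),
    tolerated_total = quote(consensus_call == "tolerated"))
  do.call(rbind, lapply(names(strata), function(s) {
    sel <- eval(strata[[s]], vus)
    r <- vus[sel, , drop = FALSE]
    n <- nrow(r)
    nm <- sum(r$mapped)
    nd <- sum(r$mapped & r$struct_damaging %in% TRUE)
    nt <- sum(r$mapped & r$struct_damaging %in% FALSE)
    data.frame(stratum = s, n_total = n, n_mapped = nm,
               pct_mapped = pctOf(nm, n), n_damaging = nd,
               pct_damaging = pctOf(nd, nm), n_tolerated_effect = nt,
               pct_tolerated_effect = pctOf(nt, nm), stringsAsFactors = FALSE)
  }))
}
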