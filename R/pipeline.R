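# End-to-end triage: variant table + structures in, per-variant reports and
# a cohort summary out. Per-variant failures are isolated and reported;
# they never abort the batch.

#' Read a variant table (TSV)
#'
#' Expected columns: \code{accession}, \code{hgvs_p}, \code{clinical_class},
#' and the raw predictor categories \code{sift}, \code{polyphen2},
#' \code{mutationassessor}, \code{condel} (empty = unavailable).
#'
#' @param path TSV file path
#' @return data.frame of variant records
#' @export
readVariantTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("accession", "hgvs_p", "clinical_class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("variant table lacks columns: ",
                         paste(miss, collapse = ", "))
  for (t in PREDICTOR_TOOLS) if (is.null(df[[t]])) df[[t]] <- ""
  df
}

#' Read canonical protein sequences from FASTA
#' @param path FASTA file path
#' @return named character vector (accession = first word of the header)
#' @export
readCanonicalFasta <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  out <- as.character(s)
  names(out) <- vapply(strsplit(names(s), "\\s+"), `[[`, "", 1)
  out
}

#' Run the structural triage pipeline over a cohort
#'
#' For each variant: parse the substitution, pick the best structure among
#' the accession's candidates, map the position (variants whose mapped
#' residue does not match the stated wild type are excluded), build the
#' repacked wild-type/mutant model pair, evaluate the eleven damage rules
#' and record the verdict. Consensus calls are derived from the predictor
#' columns, and the cohort summary (tables plus chi-square) is computed over
#' the results. Failures are confined to their variant.
#'
#' @param variants data.frame (see \code{\link{readVariantTable}}) or a TSV
#'   path
#' @param structures named list: accession -> list of
#'   \linkS4class{StructureModel} candidates; accessions absent from the
#'   list are reported unmapped
#' @param canonicalSeqs optional named character vector of canonical
#'   sequences (else author numbering is taken as canonical)
#' @param config a \linkS4class{ThresholdConfig}
#' @param outDir optional output directory for the per-variant TSV/JSON and
#'   summary JSON
#' @param skipCavity passed to \code{\link{evaluateVariant}}
#' @return list with \code{results} (one row per variant), \code{summary}
#'   (a \linkS4class{CohortSummary}) and \code{nExcluded}
#' @export
runTriage <- function(variants, structures = list(), canonicalSeqs = NULL,
                      config = thresholdConfig(), outDir = NULL,
                      skipCavity = FALSE) {
  if (is.character(variants)) variants <- readVariantTable(variants)
  n <- nrow(variants)
  rows <- vector("list", n)
  perVariant <- vector("list", n)
  for (i in seq_len(n)) {
    acc <- variants$accession[i]
    rec <- list(accession = acc, hgvs_p = variants$hgvs_p[i],
                clinical_class = variants$clinical_class[i],
                status = "not_mapped", mapped = FALSE,
                struct_damaging = NA, structure_id = NA_character_,
                triggered = "", note = "")
    res <- tryCatch({
      hp <- parseHgvsP(variants$hgvs_p[i])
      variant <- new("ProteinVariant", accession = acc,
                     position = hp$position, wtAa = hp$wt, mutAa = hp$mut,
                     clinicalClass = variants$clinical_class[i] %||% "vus")
      cands <- structures[[acc]]
      if (is.null(cands)) {
        rec
      } else {
        if (is(cands, "StructureModel")) cands <- list(cands)
        best <- selectBestStructure(cands, hp$position, config)
        if (is.null(best)) {
          rec
        } else {
          cseq <- if (!is.null(canonicalSeqs) && acc %in% names(canonicalSeqs))
            canonicalSeqs[[acc]] else NULL
          mp <- mapVariantToStructure(variant, best, canonicalSeq = cseq)
          if (!mp@mapped) {
            rec
          } else if (!mp@wtMatch) {
            rec$status <- "excluded_wt_mismatch"
            rec$note <- paste0("mapped residue is ", mp@residueAa)
            rec
          } else {
            pair <- buildModelPair(best, mp@chain, mp@resno, mp@inscode,
                                   mutantAa = hp$mut, config = config)
            flags <- evaluateVariant(pair, config, skipCavity = skipCavity)
            verdict <- structuralVerdict(flags)
            perVariant[[i]] <- list(accession = acc,
                                    hgvs_p = variants$hgvs_p[i],
                                    structure = best@id,
                                    flags = as.list(flags@flags),
                                    measurements = flags@measurements,
                                    damaging = verdict$damaging,
                                    triggered = verdict$triggered)
            rec$status <- "analyzed"
            rec$mapped <- TRUE
            rec$structure_id <- best@id
            rec$struct_damaging <- verdict$damaging
            rec$triggered <- paste(verdict$triggered, collapse = ",")
            rec
          }
        }
      }
    }, error = function(e) {
      rec$status <- "error"
      rec$note <- conditionMessage(e)
      rec
    })
    rows[[i]] <- as.data.frame(res, stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  if (is.null(results)) {
    results <- data.frame(accession = character(), hgvs_p = character(),
                          clinical_class = character(), status = character(),
                          mapped = logical(), struct_damaging = logical(),
                          structure_id = character(), triggered = character(),
                          note = character(), stringsAsFactors = FALSE)
  }
  for (t in PREDICTOR_TOOLS) results[[t]] <- variants[[t]]
  summary <- summarizeCohort(results)
  nExcluded <- sum(results$status == "excluded_wt_mismatch")
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(results, file.path(outDir, "variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      perVariant[!vapply(perVariant, is.null, logical(1))],
      file.path(outDir, "per_variant.json"), auto_unbox = TRUE, digits = NA,
      null = "null", na = "null")
    jsonlite::write_json(
      list(predictionTable = summary@predictionTable,
           structureTable = summary@structureTable,
           chi2 = if (is.null(summary@contingency)) NULL else
             list(statistic = summary@contingency@chi2,
                  p_value = summary@contingency@pValue),
           nExcluded = nExcluded),
      file.path(outDir, "summary.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  list(results = results, summary = summary, nExcluded = nExcluded)
}
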