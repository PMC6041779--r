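# Structure and variant I/O: PDB/mmCIF reading (via bio3d), PDB export,
# HGVS p. parsing, best-structure selection and variant-to-residue mapping.

WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O", "SOL")

#' Read a protein structure from PDB or mmCIF
#'
#' Parses coordinates with bio3d, removes waters, resolves alternate
#' locations to the highest-occupancy copy (ties broken alphabetically),
#' normalizes common modified residues (MSE and friends) to their parent
#' amino acid and drops other non-polymer HETATM records. Resolution and
#' experimental method are taken from REMARK 2 / EXPDTA (PDB) or the
#' _refine / _exptl categories (mmCIF).
#'
#' @param path file path
#' @param format \code{"auto"} (by extension), \code{"pdb"} or \code{"cif"}
#' @param model coordinate model to load (NMR ensembles; default 1)
#' @return a \linkS4class{StructureModel}
#' @export
readStructure <- function(path, format = c("auto", "pdb", "cif"), model = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "cif")
      suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    else suppressWarnings(bio3d::read.pdb(path, multi = model > 1L,
                                          rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("unparseable ", format, " file: ", path,
                             " (", conditionMessage(e), ")"))
  at <- parsed$atom
  if (model > 1L) {
    if (is.null(parsed$xyz) || nrow(parsed$xyz) < model)
      stop("model ", model, " not present in ", path)
    xyz <- matrix(parsed$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at <- at[!(at$resid %in% WATER_RESIDUES), , drop = FALSE]
  # normalize modified residues; drop remaining non-polymer HETATMs
  mod <- at$resid %in% names(MODIFIED_AA_PARENT)
  if (any(mod)) {
    at$elety[mod & at$elety == "SE"] <- "SD"
    at$elesy[mod & at$elesy %in% c("SE", "Se")] <- "S"
    at$resid[mod] <- MODIFIED_AA_PARENT[at$resid[mod]]
  }
  keep <- at$resid %in% names(STANDARD_AA3) | at$type == "ATOM"
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("no protein residues in ", path)
  # altloc: keep the highest-occupancy copy per atom, tie -> lowest letter
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  # restore file order
  at <- at[order(as.integer(at$eleno)), , drop = FALSE]
  elesy <- at$elesy
  bad <- is.na(elesy) | elesy == ""
  elesy[bad] <- elementOf(at$elety[bad])
  atoms <- data.frame(chain = ifelse(is.na(at$chain), "A", at$chain),
                      resno = as.integer(at$resno), inscode = at$insert,
                      resid = at$resid, elety = at$elety, elesy = elesy,
                      x = at$x, y = at$y, z = at$z,
                      o = pmin(1, pmax(0, at$o)), stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  hdr <- readHeaderMeta(path, format)
  if (nrow(unique(atoms[, c("chain", "resno", "inscode")])) == 0)
    stop("no protein residues in ", path)
  new("StructureModel",
      id = hdr$id %||% sub("\\.[^.]*$", "", basename(path)),
      method = hdr$method, resolution = hdr$resolution,
      modelIndex = as.integer(model), atoms = atoms)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

# Light-touch header metadata: resolution + method (bio3d does not expose them)
readHeaderMeta <- function(path, format) {
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) character())
  res <- NA_real_; method <- "unknown"; id <- NA_character_
  if (format == "pdb") {
    r <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
    if (length(r)) {
      m <- regmatches(r[1], regexpr("[0-9]+\\.[0-9]+", r[1]))
      if (length(m)) res <- as.numeric(m)
    }
    e <- grep("^EXPDTA", lines, value = TRUE)
    if (length(e)) {
      if (grepl("NMR", e[1])) method <- "nmr"
      else if (grepl("X-RAY|XRAY", e[1])) method <- "xray"
    }
    h <- grep("^HEADER", lines, value = TRUE)
    if (length(h) && nchar(h[1]) >= 66) id <- trimws(substr(h[1], 63, 66))
    if (!is.na(id) && id == "") id <- NA_character_
  } else {
    r <- grep("_refine\\.ls_d_res_high", lines, value = TRUE)
    if (length(r)) {
      m <- regmatches(r[1], regexpr("[0-9]+\\.?[0-9]*\\s*$", r[1]))
      if (length(m)) res <- suppressWarnings(as.numeric(trimws(m)))
    }
    e <- grep("_exptl\\.method", lines, value = TRUE)
    if (!length(e) || !grepl("NMR|X-RAY", e[1], ignore.case = TRUE)) {
      # method value may sit on a separate line (loop_ style)
      e <- grep("X-RAY DIFFRACTION|SOLUTION NMR", lines,
                ignore.case = TRUE, value = TRUE)
    }
    if (length(e)) {
      if (grepl("NMR", e[1], ignore.case = TRUE)) method <- "nmr"
      else if (grepl("X-RAY", e[1], ignore.case = TRUE)) method <- "xray"
    }
    d <- grep("^data_", lines, value = TRUE)
    if (length(d)) id <- sub("^data_", "", d[1])
  }
  if (method == "nmr") res <- NA_real_
  if (is.na(res) && method == "unknown") method <- "unknown"
  list(resolution = res, method = method, id = id)
}

#' Write a StructureModel as a PDB file
#'
#' @param structure a \linkS4class{StructureModel}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
writeStructurePdb <- function(structure, path) {
  a <- structure@atoms
  hdr <- c(
    sprintf("EXPDTA    %s", switch(structure@method,
                                   xray = "X-RAY DIFFRACTION",
                                   nmr = "SOLUTION NMR", "UNKNOWN")),
    if (!is.na(structure@resolution))
      sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", structure@resolution))
  lines <- sprintf(
    "ATOM  %5d %s%-3s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)),
    ifelse(nchar(a$elety) >= 4, "", " "),
    a$elety, a$resid, a$chain, a$resno,
    ifelse(a$inscode == "", " ", a$inscode),
    a$x, a$y, a$z, a$o, 0, a$elesy)
  writeLines(c(hdr, lines, "END"), path)
  invisible(path)
}

THREE_TO_ONE <- STANDARD_AA3
names(THREE_TO_ONE) <- paste0(substr(names(STANDARD_AA3), 1, 1),
                              tolower(substr(names(STANDARD_AA3), 2, 3)))

#' Parse an HGVS protein substitution
#'
#' Accepts three-letter substitution syntax such as \code{"p.Gly132Arg"}
#' (the leading \code{"p."} is optional).
#'
#' @param text HGVS p. string
#' @return list with \code{wt}, \code{position}, \code{mut} (one-letter codes)
#' @examples parseHgvsP("p.Gly132Arg")
#' @export
parseHgvsP <- function(text) {
  m <- regmatches(text,
                  regexec("^(?:p\\.)?([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})$",
                          text))[[1]]
  if (length(m) != 4) stop("malformed HGVS p. substitution: ", text)
  wt <- THREE_TO_ONE[m[2]]; mut <- THREE_TO_ONE[m[4]]
  if (is.na(wt) || is.na(mut))
    stop("unknown amino-acid token in: ", text)
  list(wt = unname(wt), position = as.integer(m[3]), mut = unname(mut))
}

#' Select the best structure covering a variant position
#'
#' Candidates that do not cover the position, or that resolve fewer residues
#' than the minimum (default 100), are discarded. Among x-ray structures the
#' highest resolution wins; resolutions equal within 0.05 Angstrom fall back
#' to the longest residue coverage. X-ray is preferred over NMR; among NMR
#' structures (no resolution) the longest coverage wins. Fully deterministic:
#' remaining ties break on the structure identifier.
#'
#' @param candidates list of \linkS4class{StructureModel}
#' @param position 1-based residue position (author numbering)
#' @param config a \linkS4class{ThresholdConfig}
#' @return the selected \linkS4class{StructureModel}, or \code{NULL} when no
#'   candidate survives
#' @export
selectBestStructure <- function(candidates, position,
                                config = thresholdConfig()) {
  if (length(candidates) == 0) return(NULL)
  info <- do.call(rbind, lapply(seq_along(candidates), function(i) {
    s <- candidates[[i]]
    r <- residueTable(s)
    data.frame(i = i, id = s@id, nres = nrow(r),
               covers = any(r$resno == position),
               xray = s@method == "xray",
               res = if (is.na(s@resolution)) Inf else s@resolution)
  }))
  info <- info[info$covers & info$nres >= config@minStructureResidues, ,
               drop = FALSE]
  if (nrow(info) == 0) return(NULL)
  if (any(info$xray)) info <- info[info$xray, , drop = FALSE]
  # resolution binned at the tie tolerance, then coverage, then id
  best <- info[order(info$res, -info$nres, info$id), , drop = FALSE]
  tied <- best[abs(best$res - best$res[1]) <= 0.05, , drop = FALSE]
  tied <- tied[order(-tied$nres, tied$id), , drop = FALSE]
  candidates[[tied$i[1]]]
}

#' Variant-to-structure residue mapping
#' @slot accession protein identifier
#' @slot structureId structure identifier
#' @slot chain chain used
#' @slot resno,inscode mapped author residue number
#' @slot mapped whether the position is resolved in the structure
#' @slot residueAa one-letter code of the mapped residue (NA when unmapped)
#' @slot wtMatch TRUE iff the mapped residue type equals the variant wild type
#' @export
setClass("ResidueMapping",
  representation(accession = "character", structureId = "character",
                 chain = "character", resno = "integer", inscode = "character",
                 mapped = "logical", residueAa = "character",
                 wtMatch = "logical"))

setMethod("show", "ResidueMapping", function(object) {
  if (!object@mapped) {
    cat(sprintf("ResidueMapping %s -> %s: unmapped\n",
                object@accession, object@structureId))
  } else {
    cat(sprintf("ResidueMapping %s -> %s %s%d%s (%s, wt %s)\n",
                object@accession, object@structureId, object@chain,
                object@resno, object@inscode, object@residueAa,
                if (object@wtMatch) "match" else "MISMATCH"))
  }
})

#' Map a variant position onto a structure residue
#'
#' With a canonical sequence, the observed residue sequence of the selected
#' chain is globally aligned to a local region of the canonical sequence
#' (Biostrings pairwise alignment) and the canonical position is carried
#' through the alignment; otherwise author numbering is taken as canonical.
#' Mappings whose residue type differs from the variant wild type are
#' flagged (\code{wtMatch = FALSE}) and must be excluded downstream.
#'
#' @param variant a \linkS4class{ProteinVariant}
#' @param structure a \linkS4class{StructureModel}
#' @param canonicalSeq optional canonical protein sequence (character string)
#' @param chain chain identifier; default = chain with most resolved residues
#' @return a \linkS4class{ResidueMapping}
#' @export
mapVariantToStructure <- function(variant, structure, canonicalSeq = NULL,
                                  chain = NULL) {
  r <- residueTable(structure)
  if (is.null(chain)) {
    tab <- sort(table(r$chain), decreasing = TRUE)
    chain <- names(tab)[order(-tab, names(tab))][1]
  }
  rc <- r[r$chain == chain, , drop = FALSE]
  unmappedResult <- new("ResidueMapping", accession = variant@accession,
                        structureId = structure@id, chain = chain,
                        resno = NA_integer_, inscode = "",
                        mapped = FALSE, residueAa = NA_character_,
                        wtMatch = FALSE)
  if (nrow(rc) == 0) return(unmappedResult)
  idx <- NA_integer_
  if (!is.null(canonicalSeq)) {
    obs <- paste(ifelse(is.na(rc$aa), "X", rc$aa), collapse = "")
    alpha <- c(unname(STANDARD_AA3), "X")
    submat <- matrix(-1, length(alpha), length(alpha),
                     dimnames = list(alpha, alpha))
    diag(submat) <- 2
    submat["X", ] <- 0; submat[, "X"] <- 0
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(obs),
      subject = Biostrings::AAString(as.character(canonicalSeq)),
      type = "global-local", substitutionMatrix = submat,
      gapOpening = 10, gapExtension = 0.5)
    pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    spos <- Biostrings::start(Biostrings::subject(aln)) - 1L
    ppos <- 0L
    for (k in seq_along(pat)) {
      if (sub[k] != "-") spos <- spos + 1L
      if (pat[k] != "-") ppos <- ppos + 1L
      if (sub[k] != "-" && pat[k] != "-" && spos == variant@position) {
        idx <- ppos
        break
      }
    }
  } else {
    hit <- which(rc$resno == variant@position)
    if (length(hit)) idx <- hit[1]
  }
  if (is.na(idx)) return(unmappedResult)
  new("ResidueMapping", accession = variant@accession,
      structureId = structure@id, chain = chain,
      resno = as.integer(rc$resno[idx]), inscode = rc$inscode[idx],
      mapped = TRUE, residueAa = rc$aa[idx] %||% NA_character_,
      wtMatch = identical(rc$aa[idx], variant@wtAa))
}
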