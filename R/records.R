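# Loading ligand bioactivity records and canonical structure identity.
#
# Structure identity is the canonical SMILES produced by Open Babel, with
# salts stripped (largest organic component) by default and stereochemistry
# retained by default: cross-source matching treats stereoisomers as distinct
# compounds (pairs at Tanimoto 1 in the curated data are stereoisomers that
# coexist as separate entries). A stereo-agnostic mode collapses them.

# Batch conversion through the obabel CLI. Rows are tagged with an index
# title so failed molecules never shift the alignment; failures come back NA.
.obabelBatch <- function(smiles, extraArgs = character(0), outFormat = "smi") {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = paste0(".", outFormat))
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(smiles, seq_len(n)), fin)
  status <- suppressWarnings(system2(
    "obabel", c(fin, paste0("-o", outFormat), "-xc", "-e", extraArgs,
                "-O", fout),
    stdout = FALSE, stderr = FALSE))
  out <- rep(NA_character_, n)
  if (file.exists(fout)) {
    lines <- readLines(fout, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines)) {
      parts <- strsplit(lines, "[ \t]+")
      for (p in parts) {
        idx <- suppressWarnings(as.integer(p[2]))
        if (!is.na(idx) && idx >= 1L && idx <= n && nzchar(p[1])) {
          out[idx] <- p[1]
        }
      }
    }
  }
  out
}

# choose the largest component (by heavy-atom count) of a dot-disconnected
# canonical SMILES; used for salt stripping
.largestComponent <- function(smi) {
  if (!grepl(".", smi, fixed = TRUE)) return(smi)
  frags <- strsplit(smi, ".", fixed = TRUE)[[1]]
  sizes <- vapply(frags, function(f) {
    g <- tryCatch(parseSmiles(f), error = function(e) NULL)
    if (is.null(g)) -1L else nrow(g$atoms)
  }, integer(1))
  frags[which.max(sizes)]
}

#' Canonical structure key for SMILES strings
#'
#' Maps each structure to a deterministic identity string: the Open Babel
#' canonical SMILES, optionally after salt stripping (keep the largest
#' component), charge neutralization, and/or removal of stereochemical
#' annotations. Two inputs describing the same molecule in different atom
#' orders receive the same key; the key is idempotent under
#' re-canonicalization.
#'
#' @param smiles character vector of SMILES strings.
#' @param stereo keep stereochemistry (default TRUE, so enantiomers get
#'   distinct keys); FALSE for a stereo-agnostic key.
#' @param stripSalts keep only the largest component (default TRUE).
#' @param neutralize neutralize formal charges before keying (default FALSE).
#' @param onError "error" (default) stops naming the offending string;
#'   "na" returns NA for unparseable inputs.
#' @param as identity representation: "smiles" (canonical SMILES, default)
#'   or "inchikey" (hashed InChI, computed from the canonical structure).
#' @return character vector of canonical keys.
#' @examples
#' \dontrun{
#' canonicalKey(c("CCO", "OCC"))          # same key
#' canonicalKey("c1ccccc1O") == canonicalKey("Oc1ccccc1")
#' }
#' @export
canonicalKey <- function(smiles, stereo = TRUE, stripSalts = TRUE,
                         neutralize = FALSE, onError = c("error", "na"),
                         as = c("smiles", "inchikey")) {
  onError <- match.arg(onError)
  as <- match.arg(as)
  .assertFlag(stereo, "stereo"); .assertFlag(stripSalts, "stripSalts")
  .assertFlag(neutralize, "neutralize")
  if (length(smiles) == 0L) return(character(0))
  inp <- as.character(smiles)
  if (!stereo) {
    inp <- gsub("@", "", inp, fixed = TRUE)
    inp <- gsub("[/\\\\]", "", inp)
  }
  args <- if (neutralize) "--neutralize" else character(0)
  key <- .obabelBatch(inp, extraArgs = args)
  if (stripSalts) {
    multi <- !is.na(key) & grepl(".", key, fixed = TRUE)
    if (any(multi)) {
      frag <- vapply(key[multi], .largestComponent, character(1))
      key[multi] <- .obabelBatch(frag)   # re-canonicalize the fragment alone
    }
  }
  if (as == "inchikey") {
    ok <- !is.na(key)
    if (any(ok)) {
      ik <- .obabelBatch(key[ok], extraArgs = c("-xK", "-xt"),
                         outFormat = "inchi")
      key[ok] <- ik
    }
  }
  bad <- is.na(key) & !is.na(smiles)
  if (any(bad) && onError == "error") {
    stop("unparseable SMILES: ",
         paste(utils::head(smiles[bad], 5), collapse = ", "),
         if (sum(bad) > 5) sprintf(" (and %d more)", sum(bad) - 5) else "")
  }
  unname(key)
}

#' Convert inhibition constants Ki to pKi
#'
#' pKi = -log10(Ki in molar units).
#'
#' @param ki numeric Ki values.
#' @param unit unit of the input ("M", "mM", "uM", "nM"; default "nM").
#' @return numeric pKi values.
#' @examples
#' kiToPKi(10, "nM")  # 8
#' @export
kiToPKi <- function(ki, unit = c("nM", "uM", "mM", "M")) {
  unit <- match.arg(unit)
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)[[unit]]
  -log10(ki * scale)
}

#' Construct a BioactivitySet from vectors
#'
#' Computes canonical structure keys and assembles a validated
#' \linkS4class{BioactivitySet}. pKi values outside the plausibility window
#' [0, 14] are flagged with a warning but never dropped (removal is a
#' curation decision, not a loader decision).
#'
#' @param smiles character vector of structures.
#' @param pKi numeric activities.
#' @param sourceId source label for the whole set.
#' @param ids optional record identifiers (default source-prefixed integers).
#' @param keys optional precomputed structure keys (skips canonicalization).
#' @param ... passed to [canonicalKey()].
#' @return a \linkS4class{BioactivitySet}.
#' @export
makeBioactivitySet <- function(smiles, pKi, sourceId, ids = NULL,
                               keys = NULL, ...) {
  stopifnot(length(smiles) == length(pKi))
  if (is.null(ids)) ids <- paste0(sourceId, "-", seq_along(smiles))
  if (is.null(keys)) keys <- canonicalKey(smiles, ...)
  pKi <- as.numeric(pKi)
  if (any(is.finite(pKi) & (pKi < 0 | pKi > 14))) {
    warning("pKi values outside the plausible [0, 14] window flagged as suspect",
            call. = FALSE)
  }
  new("BioactivitySet",
      records = data.frame(record_id = as.character(ids),
                           source_id = sourceId,
                           smiles = as.character(smiles),
                           structure_key = keys,
                           pKi = pKi,
                           stringsAsFactors = FALSE),
      sourceId = sourceId,
      rejected = data.frame(input = character(0), reason = character(0)))
}

#' Load bioactivity records from a file
#'
#' Every row with a parseable structure and a numeric pKi becomes a record;
#' all other rows are collected in the rejection log with a reason, never
#' silently dropped.
#'
#' @param path file to read.
#' @param format "csv" (header row; column names configurable), "smi"
#'   (one structure per line, optionally followed by tab-separated id and
#'   pKi columns), or "sdf" (V2000/V3000; pKi from a data field).
#' @param sourceId source label for the loaded set.
#' @param smilesCol,pkiCol column (or SDF data field) names; defaults
#'   "smiles" and "pKi".
#' @param kiCol optional column holding raw Ki values to be converted via
#'   [kiToPKi()] when no pKi column is present.
#' @param kiUnit unit for \code{kiCol} (default "nM").
#' @param ... passed to [canonicalKey()].
#' @return a \linkS4class{BioactivitySet}; rejected rows are available via
#'   [rejected()].
#' @export
loadRecords <- function(path, format = c("csv", "smi", "sdf"), sourceId,
                        smilesCol = "smiles", pkiCol = "pKi",
                        kiCol = NULL, kiUnit = "nM", ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- switch(format,
    csv = {
      df <- utils::read.csv(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
      if (!smilesCol %in% names(df)) {
        stop("CSV is missing the structure column '", smilesCol, "'")
      }
      if (!pkiCol %in% names(df) && is.null(kiCol)) {
        stop("CSV is missing the activity column '", pkiCol, "'")
      }
      act <- if (pkiCol %in% names(df)) df[[pkiCol]] else
        kiToPKi(suppressWarnings(as.numeric(df[[kiCol]])), kiUnit)
      data.frame(smiles = df[[smilesCol]], activity = act,
                 stringsAsFactors = FALSE)
    },
    smi = {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      parts <- strsplit(lines, "[\t ]+")
      data.frame(
        smiles = vapply(parts, `[`, character(1), 1),
        activity = vapply(parts, function(p) p[length(p)], character(1)),
        stringsAsFactors = FALSE)
    },
    sdf = {
      sdf <- ChemmineR::read.SDFset(path)
      blocks <- ChemmineR::datablock(sdf)
      act <- vapply(blocks, function(b) {
        if (pkiCol %in% names(b)) b[[pkiCol]] else NA_character_
      }, character(1))
      smi <- tryCatch(
        as.character(ChemmineR::sdf2smiles(sdf)),
        error = function(e) {
          vapply(seq_along(sdf), function(i) {
            tf <- tempfile(fileext = ".sdf")
            on.exit(unlink(tf))
            ChemmineR::write.SDF(sdf[i], tf)
            out <- suppressWarnings(system2(
              "obabel", c(tf, "-osmi"), stdout = TRUE, stderr = FALSE))
            if (length(out)) strsplit(out[1], "\t")[[1]][1] else NA_character_
          }, character(1))
        })
      data.frame(smiles = smi, activity = act, stringsAsFactors = FALSE)
    })

  if (nrow(raw) == 0L) stop("no rows found in ", path)

  reject <- data.frame(input = character(0), reason = character(0))
  pKi <- suppressWarnings(as.numeric(raw$activity))
  badAct <- is.na(pKi) | !is.finite(pKi)
  if (any(badAct)) {
    reject <- rbind(reject, data.frame(
      input = as.character(raw$smiles[badAct]),
      reason = "non-numeric or missing pKi"))
  }
  keep <- !badAct & !is.na(raw$smiles) & nzchar(trimws(raw$smiles))
  noSmi <- !badAct & !keep
  if (any(noSmi)) {
    reject <- rbind(reject, data.frame(
      input = as.character(raw$smiles[noSmi]), reason = "missing structure"))
  }
  keys <- canonicalKey(raw$smiles[keep], onError = "na", ...)
  badKey <- is.na(keys)
  if (any(badKey)) {
    reject <- rbind(reject, data.frame(
      input = raw$smiles[keep][badKey], reason = "unparseable structure"))
  }
  smi <- raw$smiles[keep][!badKey]
  act <- pKi[keep][!badKey]
  keys <- keys[!badKey]
  if (length(smi) == 0L) {
    stop("no parseable records with numeric pKi in ", path)
  }
  rs <- makeBioactivitySet(smi, act, sourceId, keys = keys)
  rs@rejected <- reject
  validObject(rs)
  rs
}

#' Write bioactivity records to CSV
#'
#' Round-trips through [loadRecords()] preserving record count, structure
#' keys and pKi values at full precision.
#'
#' @param rs a \linkS4class{BioactivitySet}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeRecords <- function(rs, path) {
  stopifnot(is(rs, "BioactivitySet"))
  df <- records(rs)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
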