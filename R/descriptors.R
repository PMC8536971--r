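# 2D molecular descriptor computation and the preprocessing pipeline:
# boolean encoding, mean imputation, constant/empty column removal.
#
# The engine is native: descriptors are computed from the molecular graph
# (plus Wildman-Crippen-type logP/MR from Open Babel). The default column
# layout is the standard 2D descriptor schema of 1613 named columns widely
# used for deposited QSAR descriptor tables; columns the native engine does
# not implement are emitted as missing and are dropped (as "empty") by
# preprocessing. schema = "native" restricts the matrix to the computed
# columns.

.schemaCache <- new.env(parent = emptyenv())

#' Names of the standard 2D descriptor schema (1613 columns)
#'
#' @return character vector of descriptor column names.
#' @export
descriptorSchema <- function() {
  if (is.null(.schemaCache$names)) {
    f <- system.file("extdata", "mordred2d_names.txt", package = "qsarStack")
    if (!nzchar(f)) {
      f <- file.path("inst", "extdata", "mordred2d_names.txt")
    }
    .schemaCache$names <- readLines(f)
  }
  .schemaCache$names
}

# full per-molecule descriptor vector (named); obRow supplies logP/MR,
# charges the per-atom partial charges on the hydrogen-included graph
.molDescriptors <- function(smi, obRow = NULL, charges = NULL) {
  g <- parseSmiles(smi)
  ctx <- .molContext(g)
  ringCounts <- .descRingCounts(ctx)
  paths <- .simplePaths(ctx, 10L)
  vals <- c(
    .descAtomCounts(ctx), .descBondCounts(ctx), .descAromatic(ctx),
    .descWeight(ctx), .descPolarizability(ctx), .descMcGowan(ctx),
    ringCounts, .descVabc(ctx, ringCounts), .descVAdjMat(ctx),
    .descFragCpx(ctx), .descABC(ctx), .descZagreb(ctx), .descWiener(ctx),
    .descTopoIndex(ctx), .descEccentric(ctx), .descBalabanJ(ctx),
    .descSpectra(ctx), .descAutocorrelation(ctx, charges = charges),
    .descTopoCharge(ctx),
    .descCarbonTypes(ctx), .descConstitutional(ctx), .descMDE(ctx),
    .descWalkCounts(ctx), .descChiKappaPaths(ctx), .descPathCounts(ctx, paths),
    .descEState(ctx), .descTopoPSA(ctx), .descHBond(ctx),
    .descRotatable(ctx), .descAcidBase(ctx),
    .descInformationContent(ctx), .descFramework(ctx))
  slogp <- if (!is.null(obRow)) obRow$logP else NA_real_
  smr <- if (!is.null(obRow)) obRow$MR else NA_real_
  vals["SLogP"] <- slogp
  vals["SMR"] <- smr
  vals <- c(vals, .descFilters(
    mw = vals[["MW"]], slogp = slogp, smr = smr,
    hbd = vals[["nHBDon"]], hba = vals[["nHBAcc"]],
    natoms = vals[["nAtom"]]))
  vals
}

# Wildman-Crippen logP/MR via the reference implementation (RDKit, called
# through the python interpreter on PATH); falls back to Open Babel's
# parametrization when unavailable. Availability is probed once per session.
.crippenState <- new.env(parent = emptyenv())

.rdkitCrippen <- function(smiles) {
  out <- data.frame(logP = rep(NA_real_, length(smiles)), MR = NA_real_)
  if (isFALSE(.crippenState$available)) return(out)
  fin <- tempfile(fileext = ".smi"); fout <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(smiles, fin)
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "from rdkit.Chem import Crippen",
    "from rdkit import RDLogger",
    "RDLogger.DisableLog('rdApp.*')",
    "out = open(sys.argv[2], 'w')",
    "for i, line in enumerate(open(sys.argv[1])):",
    "    m = Chem.MolFromSmiles(line.strip())",
    "    if m is not None:",
    "        out.write('%d\\t%.6f\\t%.6f\\n' % (i + 1, Crippen.MolLogP(m), Crippen.MolMR(m)))",
    sep = "\n")
  sf <- tempfile(fileext = ".py")
  on.exit(unlink(sf), add = TRUE)
  writeLines(script, sf)
  status <- suppressWarnings(tryCatch(
    system2("python", c(sf, fin, fout), stdout = FALSE, stderr = FALSE),
    error = function(e) 1L))
  if (!identical(status, 0L) || !file.exists(fout)) {
    .crippenState$available <- FALSE
    return(out)
  }
  .crippenState$available <- TRUE
  res <- tryCatch(utils::read.delim(fout, header = FALSE),
                  error = function(e) NULL)
  if (!is.null(res) && nrow(res)) {
    out$logP[res[[1]]] <- res[[2]]
    out$MR[res[[1]]] <- res[[3]]
  }
  out
}

# per-atom Gasteiger partial charges on the hydrogen-included molecule
# (heavy atoms in input order, then hydrogens grouped by parent), via the
# reference implementation; NULL per molecule when unavailable
.rdkitGasteiger <- function(smiles) {
  empty <- vector("list", length(smiles))
  if (isFALSE(.crippenState$available)) return(empty)
  fin <- tempfile(fileext = ".smi"); fout <- tempfile(fileext = ".tsv")
  sf <- tempfile(fileext = ".py")
  on.exit(unlink(c(fin, fout, sf)), add = TRUE)
  writeLines(smiles, fin)
  writeLines(paste(
    "import sys",
    "from rdkit import Chem, RDLogger",
    "from rdkit.Chem.rdPartialCharges import ComputeGasteigerCharges",
    "RDLogger.DisableLog('rdApp.*')",
    "out = open(sys.argv[2], 'w')",
    "for i, line in enumerate(open(sys.argv[1])):",
    "    m = Chem.MolFromSmiles(line.strip())",
    "    if m is None: continue",
    "    m = Chem.AddHs(m)",
    "    try:",
    "        ComputeGasteigerCharges(m)",
    "        ch = [a.GetDoubleProp('_GasteigerCharge') for a in m.GetAtoms()]",
    "    except Exception:",
    "        continue",
    "    if any(c != c for c in ch): continue",
    "    out.write('%d\\t%s\\n' % (i + 1, ' '.join('%.8g' % c for c in ch)))",
    sep = "\n"), sf)
  status <- suppressWarnings(tryCatch(
    system2("python", c(sf, fin, fout), stdout = FALSE, stderr = FALSE),
    error = function(e) 1L))
  if (!identical(status, 0L) || !file.exists(fout)) return(empty)
  for (line in readLines(fout, warn = FALSE)) {
    p <- strsplit(line, "\t", fixed = TRUE)[[1]]
    idx <- as.integer(p[1])
    if (!is.na(idx) && idx >= 1L && idx <= length(smiles)) {
      empty[[idx]] <- as.numeric(strsplit(p[2], " ", fixed = TRUE)[[1]])
    }
  }
  empty
}

# batch logP/MR via Open Babel
.obProperties <- function(smiles) {
  out <- data.frame(logP = rep(NA_real_, length(smiles)),
                    MR = NA_real_)
  res <- tryCatch({
    sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles,
                                                 seq_along(smiles)))
    p <- ChemmineR::propOB(sdf)
    idx <- suppressWarnings(as.integer(p$title))
    ok <- !is.na(idx)
    out$logP[idx[ok]] <- p$logP[ok]
    out$MR[idx[ok]] <- p$MR[ok]
    out
  }, error = function(e) out)
  res
}

#' Compute 2D molecular descriptors for a set of structures
#'
#' One row per structure. Descriptor cells the engine cannot compute for a
#' molecule become missing (NA), never exceptions. With the default
#' \code{schema = "mordred2d"} the matrix has the standard 1613-column 2D
#' descriptor layout (unimplemented descriptors all-missing, to be dropped
#' at preprocessing); \code{schema = "native"} keeps only computed columns.
#'
#' @param structures character vector of SMILES (all parseable; filter
#'   first via [canonicalKey()]).
#' @param keys optional row identifiers (default the structures).
#' @param schema "mordred2d" (default) or "native".
#' @param verbose print progress every 200 molecules.
#' @return a \linkS4class{DescriptorMatrix}.
#' @examples
#' \dontrun{
#' m <- computeDescriptors2D(c("CCO", "c1ccccc1O"))
#' dim(m)  # 2 x 1613
#' }
#' @export
computeDescriptors2D <- function(structures, keys = NULL,
                                 schema = c("mordred2d", "native"),
                                 verbose = FALSE) {
  schema <- match.arg(schema)
  if (length(structures) == 0L) stop("no structures given")
  if (is.null(keys)) keys <- as.character(structures)
  ob <- .rdkitCrippen(structures)
  if (all(is.na(ob$logP))) ob <- .obProperties(structures)
  gast <- .rdkitGasteiger(structures)
  rows <- vector("list", length(structures))
  for (i in seq_along(structures)) {
    rows[[i]] <- tryCatch(
      .molDescriptors(structures[i], ob[i, , drop = FALSE], gast[[i]]),
      error = function(e) {
        stop("descriptor computation failed for structure '",
             structures[i], "': ", conditionMessage(e))
      })
    if (verbose && i %% 200 == 0) {
      message("  descriptors: ", i, "/", length(structures))
    }
  }
  allNames <- if (schema == "mordred2d") descriptorSchema() else
    unique(unlist(lapply(rows, names)))
  vals <- matrix(NA_real_, length(rows), length(allNames),
                 dimnames = list(NULL, allNames))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    common <- intersect(names(r), allNames)
    vals[i, common] <- unname(r[common])
  }
  new("DescriptorMatrix", values = vals, compoundKeys = keys,
      backend = "native-graph2d", schema = schema)
}

#' Preprocess a descriptor matrix for modeling
#'
#' Boolean columns are encoded 1/0 (the engine already emits numeric 0/1
#' flags); missing cells are replaced by the column mean over observed
#' cells; columns that are entirely missing ("empty") or have max == min
#' ("constant") are then removed. Column order is preserved and full
#' provenance (dropped columns with reasons, imputation means) is recorded.
#'
#' @param m a \linkS4class{DescriptorMatrix} (or numeric matrix).
#' @return a \linkS4class{PreprocessedMatrix}.
#' @export
preprocessDescriptors <- function(m) {
  if (is(m, "DescriptorMatrix")) {
    vals <- m@values; keys <- m@compoundKeys
    backend <- m@backend; schema <- m@schema
  } else {
    vals <- .asFeatureMatrix(m); keys <- as.character(seq_len(nrow(vals)))
    backend <- "external"; schema <- "native"
  }
  if (nrow(vals) == 0L || ncol(vals) == 0L) stop("empty descriptor matrix")
  storage.mode(vals) <- "double"   # TRUE/FALSE -> 1/0

  means <- colMeans(vals, na.rm = TRUE)
  empty <- !is.finite(means)
  for (j in which(!empty)) {
    idx <- is.na(vals[, j])
    if (any(idx)) vals[idx, j] <- means[j]
  }
  rng <- apply(vals, 2, function(x) {
    if (anyNA(x)) NA_real_ else max(x) - min(x)
  })
  constant <- !empty & !is.na(rng) & rng == 0
  drop <- empty | constant
  dropped <- data.frame(
    column = colnames(vals)[drop],
    reason = ifelse(empty[drop], "empty", "constant"),
    stringsAsFactors = FALSE)
  keep <- !drop
  if (!any(keep)) stop("all columns were removed during preprocessing")
  new("PreprocessedMatrix",
      values = vals[, keep, drop = FALSE],
      compoundKeys = keys, backend = backend, schema = schema,
      provenance = list(dropped = dropped,
                        imputation_means = means[keep]))
}

#' Write a descriptor matrix in the deposited-table layout
#'
#' Tab-separated: descriptor columns followed by a final pKi column.
#'
#' @param m a \linkS4class{DescriptorMatrix} or
#'   \linkS4class{PreprocessedMatrix}.
#' @param pKi numeric response, one value per row of \code{m}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDescriptorTable <- function(m, pKi, path) {
  stopifnot(is(m, "DescriptorMatrix"), nrow(m@values) == length(pKi))
  df <- as.data.frame(m@values)
  df$pKi <- pKi
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a descriptor table in the deposited layout
#'
#' Accepts the tab-separated layout written by [writeDescriptorTable()]
#' (descriptor columns + final pKi column).
#'
#' @param path file to read.
#' @return list with \code{descriptors} (a \linkS4class{DescriptorMatrix})
#'   and \code{pKi} (numeric vector).
#' @export
readDescriptorTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"pKi" %in% names(df)) {
    # deposited variants sometimes label the response differently; take the
    # last column as the response
    names(df)[ncol(df)] <- "pKi"
  }
  pKi <- as.numeric(df$pKi)
  df$pKi <- NULL
  vals <- as.matrix(df)
  storage.mode(vals) <- "double"
  list(descriptors = new("DescriptorMatrix", values = vals,
                         compoundKeys = as.character(seq_len(nrow(vals))),
                         backend = "external", schema = "mordred2d"),
       pKi = pKi)
}
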