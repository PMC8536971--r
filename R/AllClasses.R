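#' @import methods
NULL

#' BioactivitySet: one source's ligand bioactivity records
#'
#' An ordered set of bioactivity records from a single source. Each record
#' carries a SMILES structure, its canonical structure key (the identity used
#' for all duplicate logic), and a pKi value (negative decadic logarithm of
#' the inhibition constant Ki in molar units). Rows rejected at load time are
#' kept in \code{rejected} with a reason, never silently dropped.
#'
#' @slot records data.frame with columns \code{record_id}, \code{source_id},
#'   \code{smiles}, \code{structure_key}, \code{pKi}.
#' @slot sourceId single source label shared by all records.
#' @slot rejected data.frame of rejected input rows (\code{input},
#'   \code{reason}).
#' @exportClass BioactivitySet
setClass("BioactivitySet",
  representation(records = "data.frame", sourceId = "character",
                 rejected = "data.frame"),
  prototype(records = data.frame(record_id = character(0),
                                 source_id = character(0),
                                 smiles = character(0),
                                 structure_key = character(0),
                                 pKi = numeric(0)),
            sourceId = NA_character_,
            rejected = data.frame(input = character(0), reason = character(0)))
)

setValidity("BioactivitySet", function(object) {
  need <- c("record_id", "source_id", "smiles", "structure_key", "pKi")
  r <- object@records
  if (!all(need %in% names(r))) {
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(r$record_id)) return("record_id values must be unique")
  if (length(object@sourceId) != 1L) return("sourceId must be a single label")
  if (nrow(r) && !all(r$source_id == object@sourceId)) {
    return("all records must carry the set's sourceId")
  }
  if (nrow(r) && any(!is.finite(r$pKi))) return("pKi values must be finite")
  TRUE
})

#' CuratedDatabase: deduplicated structure-to-pKi map with audit counts
#'
#' Result of resolving duplicates between two bioactivity sources. Each
#' structure key appears exactly once; the audit trail records every counter
#' of the curation procedure (per-source uniques, pooled total, duplicate
#' records, concordant pairs kept, discordant pairs dropped, final uniques).
#'
#' @slot entries data.frame with columns \code{structure_key}, \code{smiles},
#'   \code{pKi}, \code{source}.
#' @slot audit named list of curation counters.
#' @slot pairs data.frame describing every cross-source duplicate pair
#'   (\code{structure_key}, \code{pKi_a}, \code{pKi_b}, \code{delta_pKi},
#'   \code{discordant}).
#' @exportClass CuratedDatabase
setClass("CuratedDatabase",
  representation(entries = "data.frame", audit = "list", pairs = "data.frame"))

setValidity("CuratedDatabase", function(object) {
  need <- c("structure_key", "smiles", "pKi", "source")
  if (!all(need %in% names(object@entries))) {
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(object@entries$structure_key)) {
    return("entries must not share a structure_key")
  }
  a <- object@audit
  if (!is.null(a$final_uniques) && a$final_uniques != nrow(object@entries)) {
    return("audit$final_uniques must equal the number of entries")
  }
  TRUE
})

#' DescriptorMatrix: compounds x named 2D molecular descriptors
#'
#' A rectangular numeric matrix of 2D molecular descriptors, one row per
#' compound. Cells the backend could not compute are NA (the missing mask).
#' Column names follow the descriptor schema declared in \code{schema}.
#'
#' @slot values numeric matrix (rows = compounds, columns = descriptors);
#'   NA marks missing cells.
#' @slot compoundKeys character identifiers, one per row.
#' @slot backend label of the computing backend.
#' @slot schema label of the column layout ("mordred2d" or "native").
#' @exportClass DescriptorMatrix
setClass("DescriptorMatrix",
  representation(values = "matrix", compoundKeys = "character",
                 backend = "character", schema = "character"))

setValidity("DescriptorMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v))) {
    return("values must have unique column names")
  }
  if (nrow(v) != length(object@compoundKeys)) {
    return("compoundKeys must have one entry per row")
  }
  TRUE
})

#' PreprocessedMatrix: fully numeric descriptor matrix ready for modeling
#'
#' A \linkS4class{DescriptorMatrix} after boolean encoding, mean imputation
#' and removal of empty/constant columns, with full provenance: which columns
#' were dropped and why, and the imputation mean used per column.
#'
#' @slot provenance list with \code{dropped} (data.frame: \code{column},
#'   \code{reason}) and \code{imputation_means} (named numeric).
#' @exportClass PreprocessedMatrix
setClass("PreprocessedMatrix", contains = "DescriptorMatrix",
  representation(provenance = "list"))

setValidity("PreprocessedMatrix", function(object) {
  v <- object@values
  if (anyNA(v)) return("preprocessed matrix must not contain missing cells")
  if (ncol(v)) {
    rng <- apply(v, 2, function(x) max(x) - min(x))
    if (any(rng == 0)) return("preprocessed matrix must not contain constant columns")
  }
  TRUE
})

#' FeatureSubset: descriptor columns retained by importance screening
#'
#' @slot names selected descriptor columns.
#' @slot relativeImportance per-name score normalized so the top feature
#'   equals 1.
#' @slot threshold relative-importance cutoff that was applied.
#' @slot allImportance full normalized importance vector over screened
#'   columns (for reporting).
#' @exportClass FeatureSubset
setClass("FeatureSubset",
  representation(names = "character", relativeImportance = "numeric",
                 threshold = "numeric", allImportance = "numeric"))

setValidity("FeatureSubset", function(object) {
  ri <- object@relativeImportance
  if (length(ri) != length(object@names)) return("one score per selected name")
  if (length(ri) && abs(max(ri) - 1) > 1e-9) {
    return("relativeImportance must be normalized to max 1")
  }
  TRUE
})

#' StackedModel: base learners plus a non-negative linear metalearner
#'
#' A super learner: level-one base models fitted per cross-validation fold,
#' and a generalized linear metalearner trained on their out-of-fold
#' predictions under a non-negativity constraint with L1/elastic-net
#' regularization. Predictions are intercept + sum of w_j * base_j(x) with
#' every w_j >= 0.
#'
#' @slot baseModels list of fitted base-learner bundles.
#' @slot metalearner list with \code{intercept}, \code{weights} (named,
#'   all >= 0), \code{penalty}, \code{lambda}.
#' @slot ensembleMode "all" or "best_of_family".
#' @slot cvMetrics list with \code{rmse}, \code{r2}, \code{n}, per-fold
#'   values and pooled out-of-fold predictions.
#' @slot folds integer fold assignment used by every base model.
#' @slot featureNames descriptor columns the model consumes.
#' @exportClass StackedModel
setClass("StackedModel",
  representation(baseModels = "list", metalearner = "list",
                 ensembleMode = "character", cvMetrics = "list",
                 folds = "integer", featureNames = "character"))

setValidity("StackedModel", function(object) {
  w <- object@metalearner$weights
  if (is.null(w)) return("metalearner must carry weights")
  if (any(w < 0)) return("metalearner weights must be non-negative")
  if (!object@ensembleMode %in% c("all", "best_of_family")) {
    return("ensembleMode must be 'all' or 'best_of_family'")
  }
  TRUE
})

#' ShapMatrix: per-record, per-feature Shapley attributions
#'
#' Attribution values phi[i, j] in units of the model response (pKi), plus
#' the base value phi0 (expected model output over the background sample).
#' For the exact method on a deterministic model, phi0 + sum_j phi[i, j]
#' reproduces the model prediction for record i (local accuracy).
#'
#' @slot phi numeric matrix of attributions (records x features).
#' @slot baseValue expected model output over the background.
#' @slot method "exact" or "sampling".
#' @slot backgroundSpec list describing the background sample (fraction or
#'   size, seed, draw count for sampling).
#' @slot X data.frame of the explained records.
#' @exportClass ShapMatrix
setClass("ShapMatrix",
  representation(phi = "matrix", baseValue = "numeric", method = "character",
                 backgroundSpec = "list", X = "data.frame"))

setValidity("ShapMatrix", function(object) {
  if (!object@method %in% c("exact", "sampling")) {
    return("method must be 'exact' or 'sampling'")
  }
  if (length(object@baseValue) != 1L) return("baseValue must be scalar")
  TRUE
})
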