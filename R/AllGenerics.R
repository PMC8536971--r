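# Generics and accessors for the package's S4 classes.

#' @rdname BioactivitySet-class
#' @param object,x a \linkS4class{BioactivitySet}.
#' @export
setGeneric("records", function(object) standardGeneric("records"))

#' @rdname BioactivitySet-class
#' @export
setGeneric("sourceId", function(object) standardGeneric("sourceId"))

#' @rdname BioactivitySet-class
#' @export
setGeneric("rejected", function(object) standardGeneric("rejected"))

#' @rdname CuratedDatabase-class
#' @param object a \linkS4class{CuratedDatabase}.
#' @export
setGeneric("entries", function(object) standardGeneric("entries"))

#' @rdname CuratedDatabase-class
#' @export
setGeneric("auditCounts", function(object) standardGeneric("auditCounts"))

#' @rdname CuratedDatabase-class
#' @export
setGeneric("duplicatePairs", function(object) standardGeneric("duplicatePairs"))

#' @rdname DescriptorMatrix-class
#' @param object a \linkS4class{DescriptorMatrix}.
#' @export
setGeneric("descriptorValues", function(object) standardGeneric("descriptorValues"))

#' @rdname DescriptorMatrix-class
#' @export
setGeneric("compoundKeys", function(object) standardGeneric("compoundKeys"))

#' @rdname PreprocessedMatrix-class
#' @param object a \linkS4class{PreprocessedMatrix}.
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname StackedModel-class
#' @param object a \linkS4class{StackedModel}.
#' @export
setGeneric("metalearner", function(object) standardGeneric("metalearner"))

#' @rdname StackedModel-class
#' @export
setGeneric("baseModels", function(object) standardGeneric("baseModels"))

#' @rdname StackedModel-class
#' @export
setGeneric("cvMetrics", function(object) standardGeneric("cvMetrics"))

#' @rdname ShapMatrix-class
#' @param object a \linkS4class{ShapMatrix}.
#' @export
setGeneric("shapPhi", function(object) standardGeneric("shapPhi"))

#' @rdname ShapMatrix-class
#' @export
setGeneric("baseValue", function(object) standardGeneric("baseValue"))

## -- methods -----------------------------------------------------------------

#' @rdname BioactivitySet-class
#' @export
setMethod("records", "BioactivitySet", function(object) object@records)

#' @rdname BioactivitySet-class
#' @export
setMethod("sourceId", "BioactivitySet", function(object) object@sourceId)

#' @rdname BioactivitySet-class
#' @export
setMethod("rejected", "BioactivitySet", function(object) object@rejected)

#' @rdname BioactivitySet-class
#' @export
setMethod("length", "BioactivitySet", function(x) nrow(x@records))

#' @rdname BioactivitySet-class
#' @export
setMethod("show", "BioactivitySet", function(object) {
  cat("BioactivitySet of", nrow(object@records), "records from source '",
      object@sourceId, "'\n", sep = " ")
  if (nrow(object@records)) {
    cat("  pKi range:", sprintf("%.2f - %.2f", min(object@records$pKi),
        max(object@records$pKi)), "\n")
  }
  if (nrow(object@rejected)) {
    cat("  rejected rows:", nrow(object@rejected), "\n")
  }
  invisible(NULL)
})

#' @rdname CuratedDatabase-class
#' @export
setMethod("entries", "CuratedDatabase", function(object) object@entries)

#' @rdname CuratedDatabase-class
#' @export
setMethod("auditCounts", "CuratedDatabase", function(object) object@audit)

#' @rdname CuratedDatabase-class
#' @export
setMethod("duplicatePairs", "CuratedDatabase", function(object) object@pairs)

#' @rdname CuratedDatabase-class
#' @export
setMethod("length", "CuratedDatabase", function(x) nrow(x@entries))

#' @rdname CuratedDatabase-class
#' @export
setMethod("show", "CuratedDatabase", function(object) {
  a <- object@audit
  cat("CuratedDatabase:", nrow(object@entries), "unique compounds\n")
  if (length(a)) {
    cat(sprintf("  pooled %d = %s; %d duplicate records (%d pairs); %d discordant pairs dropped\n",
        a$pooled_total,
        paste(unlist(a$per_source_uniques), collapse = " + "),
        a$duplicate_records, a$pairs_total, a$pairs_discordant))
  }
  invisible(NULL)
})

#' @rdname DescriptorMatrix-class
#' @export
setMethod("descriptorValues", "DescriptorMatrix", function(object) object@values)

#' @rdname DescriptorMatrix-class
#' @export
setMethod("compoundKeys", "DescriptorMatrix", function(object) object@compoundKeys)

#' @rdname DescriptorMatrix-class
#' @export
setMethod("dim", "DescriptorMatrix", function(x) dim(x@values))

#' @rdname DescriptorMatrix-class
#' @export
setMethod("show", "DescriptorMatrix", function(object) {
  v <- object@values
  cat(class(object), ":", nrow(v), "compounds x", ncol(v), "descriptors",
      sprintf("(backend '%s', schema '%s')\n", object@backend, object@schema))
  nmiss <- sum(is.na(v))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", nmiss,
              if (length(v)) 100 * nmiss / length(v) else 0))
  invisible(NULL)
})

#' @rdname PreprocessedMatrix-class
#' @export
setMethod("provenance", "PreprocessedMatrix", function(object) object@provenance)

#' @rdname StackedModel-class
#' @export
setMethod("metalearner", "StackedModel", function(object) object@metalearner)

#' @rdname StackedModel-class
#' @export
setMethod("baseModels", "StackedModel", function(object) object@baseModels)

#' @rdname StackedModel-class
#' @export
setMethod("cvMetrics", "StackedModel", function(object) object@cvMetrics)

#' @rdname StackedModel-class
#' @export
setMethod("show", "StackedModel", function(object) {
  cat("StackedModel (", object@ensembleMode, ") with ",
      length(object@baseModels), " base models\n", sep = "")
  w <- object@metalearner$weights
  act <- sum(w > 0)
  cat(sprintf("  metalearner: %s penalty, lambda = %.4g, %d active weights\n",
      object@metalearner$penalty, object@metalearner$lambda, act))
  m <- object@cvMetrics
  if (!is.null(m$rmse)) {
    cat(sprintf("  10-CV: RMSE = %.4f, R2 = %.4f (n = %d)\n",
        m$rmse, m$r2, m$n))
  }
  invisible(NULL)
})

#' @rdname ShapMatrix-class
#' @export
setMethod("shapPhi", "ShapMatrix", function(object) object@phi)

#' @rdname ShapMatrix-class
#' @export
setMethod("baseValue", "ShapMatrix", function(object) object@baseValue)

#' @rdname ShapMatrix-class
#' @export
setMethod("show", "ShapMatrix", function(object) {
  cat("ShapMatrix:", nrow(object@phi), "records x", ncol(object@phi),
      "features, method =", object@method, "\n")
  cat(sprintf("  base value: %.4f\n", object@baseValue))
  invisible(NULL)
})
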