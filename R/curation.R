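# Curation of a two-source bioactivity pool: per-source deduplication,
# cross-source duplicate detection, and difference-threshold resolution.
#
# The resolution rule: structures present in both sources form duplicate
# pairs; a pair whose |delta pKi| exceeds the threshold is discordant and
# BOTH members are removed from the pooled database; otherwise the member
# from the priority source is kept. The default threshold is 0.1 pKi units,
# with the boundary |delta| == threshold on the keep branch.

#' Deduplicate records within one source
#'
#' Collapses groups of records sharing a structure key. Groups whose pKi
#' spread (max - min) is at most \code{threshold} collapse to the arithmetic
#' mean pKi; wider groups are removed entirely under the default
#' "consistent" policy (the measurements disagree, so the structure is
#' untrustworthy) or collapsed to the median under policy "median".
#'
#' @param rs a \linkS4class{BioactivitySet}.
#' @param threshold maximum tolerated pKi spread within a group (default 0.1).
#' @param policy "consistent" (default) or "median".
#' @return a deduplicated \linkS4class{BioactivitySet} (one record per key).
#' @examples
#' \dontrun{
#' rs <- makeBioactivitySet(c("CCO", "OCC", "CCN"), c(7.0, 7.05, 6.0), "A")
#' length(dedupeWithinSource(rs))  # 2: ethanol collapses to mean 7.025
#' }
#' @export
dedupeWithinSource <- function(rs, threshold = 0.1,
                               policy = c("consistent", "median")) {
  stopifnot(is(rs, "BioactivitySet"))
  policy <- match.arg(policy)
  .assertScalarNumber(threshold, "threshold", min = 0)
  df <- records(rs)
  if (nrow(df) == 0L || !anyDuplicated(df$structure_key)) return(rs)

  keep <- do.call(rbind, lapply(split(df, df$structure_key), function(grp) {
    if (nrow(grp) == 1L) return(grp)
    spread <- max(grp$pKi) - min(grp$pKi)
    if (spread <= threshold) {
      grp$pKi[1] <- mean(grp$pKi)
      grp[1, , drop = FALSE]
    } else if (policy == "median") {
      grp$pKi[1] <- stats::median(grp$pKi)
      grp[1, , drop = FALSE]
    } else {
      grp[0, , drop = FALSE]
    }
  }))
  keep <- keep[order(match(keep$structure_key, df$structure_key)), ,
               drop = FALSE]
  rownames(keep) <- NULL
  out <- rs
  out@records <- keep
  validObject(out)
  out
}

#' Find cross-source duplicate pairs
#'
#' One pair per structure key present in both (already deduplicated) sets,
#' with the absolute pKi difference.
#'
#' @param a,b deduplicated \linkS4class{BioactivitySet}s.
#' @return data.frame with columns \code{structure_key}, \code{pKi_a},
#'   \code{pKi_b}, \code{delta_pKi}.
#' @export
findCrossPairs <- function(a, b) {
  stopifnot(is(a, "BioactivitySet"), is(b, "BioactivitySet"))
  for (s in list(a, b)) {
    dup <- duplicated(records(s)$structure_key)
    if (any(dup)) {
      stop("input set '", sourceId(s), "' is not deduplicated; offending keys: ",
           paste(utils::head(unique(records(s)$structure_key[dup]), 5),
                 collapse = ", "))
    }
  }
  ra <- records(a); rb <- records(b)
  shared <- intersect(ra$structure_key, rb$structure_key)
  ia <- match(shared, ra$structure_key)
  ib <- match(shared, rb$structure_key)
  data.frame(structure_key = shared,
             pKi_a = ra$pKi[ia], pKi_b = rb$pKi[ib],
             delta_pKi = abs(ra$pKi[ia] - rb$pKi[ib]),
             stringsAsFactors = FALSE)
}

#' Resolve duplicates between two sources into a curated database
#'
#' Pools both (deduplicated) sources and applies the difference-threshold
#' rule to every cross-source pair: |delta pKi| > threshold drops both
#' members; |delta pKi| <= threshold keeps the priority source's value.
#' Unpaired records pass through unchanged. The audit trail reconciles all
#' counts: final = |a| + |b| - pairs_total - pairs_discordant.
#'
#' @param a,b deduplicated \linkS4class{BioactivitySet}s.
#' @param threshold pKi difference threshold (default 0.1; the boundary
#'   value itself is kept).
#' @param priority source label whose member survives a concordant pair
#'   (default the first set's source).
#' @return a \linkS4class{CuratedDatabase}.
#' @examples
#' \dontrun{
#' a <- makeBioactivitySet(c("CCO", "CCN"), c(7.0, 6.5), "ZINC")
#' b <- makeBioactivitySet(c("OCC", "CCC"), c(7.05, 8.0), "ChEMBL")
#' db <- resolveDuplicates(a, b)
#' length(db)  # 3: ethanol kept at 7.0 (ZINC priority), amine + propane
#' }
#' @export
resolveDuplicates <- function(a, b, threshold = 0.1,
                              priority = sourceId(a)) {
  stopifnot(is(a, "BioactivitySet"), is(b, "BioactivitySet"))
  .assertScalarNumber(threshold, "threshold", min = 0)
  if (!priority %in% c(sourceId(a), sourceId(b))) {
    stop("'priority' must name one of the two sources: ",
         sourceId(a), ", ", sourceId(b))
  }
  pairs <- findCrossPairs(a, b)
  pairs$discordant <- pairs$delta_pKi > threshold

  ra <- records(a); rb <- records(b)
  nA <- nrow(ra); nB <- nrow(rb)
  discKeys <- pairs$structure_key[pairs$discordant]
  concKeys <- pairs$structure_key[!pairs$discordant]

  prioIsA <- priority == sourceId(a)
  prio <- if (prioIsA) ra else rb
  other <- if (prioIsA) rb else ra

  keepPrio <- prio[!prio$structure_key %in% discKeys, , drop = FALSE]
  keepOther <- other[!other$structure_key %in%
                       c(discKeys, concKeys), , drop = FALSE]
  ent <- rbind(keepPrio, keepOther)
  entries <- data.frame(structure_key = ent$structure_key,
                        smiles = ent$smiles,
                        pKi = ent$pKi,
                        source = ent$source_id,
                        stringsAsFactors = FALSE)
  rownames(entries) <- NULL

  audit <- list(
    per_source_uniques = stats::setNames(list(nA, nB),
                                         c(sourceId(a), sourceId(b))),
    pooled_total = nA + nB,
    duplicate_records = 2L * nrow(pairs),
    pairs_total = nrow(pairs),
    pairs_kept = sum(!pairs$discordant),
    pairs_discordant = sum(pairs$discordant),
    threshold = threshold,
    priority = priority,
    final_uniques = nrow(entries)
  )
  db <- new("CuratedDatabase", entries = entries, audit = audit, pairs = pairs)
  validObject(db)
  db
}

#' Write a curated database (and optional audit trail) to disk
#'
#' @param db a \linkS4class{CuratedDatabase}.
#' @param path CSV output (columns structure_key, smiles, pKi, source).
#' @param auditPath optional JSON file receiving the audit counters.
#' @return \code{path}, invisibly.
#' @export
writeCuratedDatabase <- function(db, path, auditPath = NULL) {
  stopifnot(is(db, "CuratedDatabase"))
  utils::write.csv(entries(db), path, row.names = FALSE)
  if (!is.null(auditPath)) {
    jsonlite::write_json(auditCounts(db), auditPath,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
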