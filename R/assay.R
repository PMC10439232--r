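# Normalization and summarization of promoter-strength fluorescence
# measurements: readings are blanked on the parent (reporter-free) strain
# and scaled so the reference promoter reads 100%.

#' Normalize a fluorescence reading to reference-promoter percent
#'
#' `100 * (f_sample - f_blank) / (f_ref - f_blank)`: the parent-strain blank
#' maps to 0% and the reference promoter to 100%. Values below 0% or above
#' 100% are legitimate (sub-blank noise, promoters stronger than the
#' reference) and are returned as-is.
#'
#' @param f_sample Sample fluorescence (vectorised).
#' @param f_blank Parent-strain autofluorescence.
#' @param f_ref Reference-promoter fluorescence; must exceed `f_blank`.
#' @return Normalized strength in percent.
#' @export
normalize_strength <- function(f_sample, f_blank, f_ref) {
  if (any(!is.finite(c(f_sample, f_blank, f_ref)))) {
    pf_stop("fluorescence values must be finite", "pf_validation")
  }
  if (f_ref <= f_blank) {
    pf_stop("reference promoter is indistinguishable from the blank (f_ref <= f_blank)",
            "pf_validation")
  }
  100 * (f_sample - f_blank) / (f_ref - f_blank)
}

#' Summarize a promoter-library fluorescence table
#'
#' Input rows are single readings (`strain`, `promoter`, `medium`,
#' `instrument`, `replicate`, `fluorescence`). Readings are grouped into
#' batches by medium + instrument — normalization never crosses batches.
#' Within each batch the blank and reference levels are the means of the
#' parent-strain and reference-promoter rows; every sample replicate is
#' normalized individually and replicates are then averaged. Batches
#' missing a blank or reference are rejected with a message and reported in
#' the `rejected` attribute.
#'
#' @param records Data frame of readings; `fluorescence` in arbitrary units.
#' @param blank Promoter label identifying parent-strain (blank) rows.
#' @param reference Promoter label of the reference (100%) promoter.
#' @return Data frame, one row per promoter x medium x instrument:
#'   `rep<k>` columns with replicate-wise normalized percent, `mean_percent`,
#'   and `negative` flagging sub-blank means.
#' @export
summarize_library <- function(records, blank = "blank", reference = "TEF1") {
  need <- c("promoter", "medium", "instrument", "replicate", "fluorescence")
  if (!all(need %in% names(records))) {
    pf_stop(paste0("records must have columns ", paste(need, collapse = ", ")),
            "pf_validation")
  }
  if (any(records$fluorescence < 0 | !is.finite(records$fluorescence))) {
    pf_stop("fluorescence must be finite and >= 0", "pf_validation")
  }
  batches <- unique(records[, c("medium", "instrument")])
  out <- list()
  rejected <- character()
  for (b in seq_len(nrow(batches))) {
    sel <- records$medium == batches$medium[b] &
      records$instrument == batches$instrument[b]
    batch <- records[sel, , drop = FALSE]
    f_blank <- batch$fluorescence[batch$promoter == blank]
    f_ref <- batch$fluorescence[batch$promoter == reference]
    tag <- paste0(batches$medium[b], "/", batches$instrument[b])
    if (!length(f_blank) || !length(f_ref)) {
      pf_log(sprintf("batch %s rejected: missing %s rows", tag,
                     if (!length(f_blank)) "blank" else "reference"))
      rejected <- c(rejected, tag)
      next
    }
    fb <- mean(f_blank)
    fr <- mean(f_ref)
    batch$norm <- normalize_strength(batch$fluorescence, fb, fr)
    for (p in unique(batch$promoter)) {
      rows <- batch[batch$promoter == p, , drop = FALSE]
      rows <- rows[order(rows$replicate), ]
      vals <- rows$norm
      rec <- data.frame(promoter = p, medium = batches$medium[b],
                        instrument = batches$instrument[b],
                        n_rep = length(vals), stringsAsFactors = FALSE)
      for (k in seq_along(vals)) rec[[paste0("rep", k)]] <- vals[k]
      rec$mean_percent <- mean(vals)
      rec$negative <- rec$mean_percent < 0
      out[[length(out) + 1L]] <- rec
    }
  }
  if (!length(out)) {
    pf_stop("no batch could be normalized (all rejected)", "pf_validation")
  }
  # rows may have differing replicate counts; align columns
  cols <- unique(unlist(lapply(out, names)))
  out <- lapply(out, function(r) { r[setdiff(cols, names(r))] <- NA_real_; r[cols] })
  res <- do.call(rbind, out)
  res <- res[order(res$medium, res$instrument, res$promoter), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "rejected") <- rejected
  res
}

#' Read / write promoter-assay tables
#'
#' TSV or CSV with columns `strain`, `promoter`, `medium`, `instrument`,
#' `replicate`, `fluorescence` (separator inferred from the extension).
#' @param path Input file.
#' @export
read_assay_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname read_assay_table
#' @param table Summary table from [summarize_library()].
#' @export
write_assay_table <- function(table, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(table, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
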