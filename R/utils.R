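# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Normalize miRNA identifiers
#'
#' Lower-cases identifiers and strips a leading `"hsa-"` species prefix so
#' that differently styled miRNA names (`"hsa-miR-99a"`, `"miR-99a"`,
#' `"mir-99a"`) match across the differential-expression results and the
#' target map.
#'
#' @param x Character vector of miRNA identifiers.
#' @return Character vector of normalized identifiers.
#' @export
#' @examples
#' normalize_mirna_ids(c("hsa-miR-99a", "MIR-99A"))
normalize_mirna_ids <- function(x) {
  sub("^hsa-", "", tolower(as.character(x)))
}

# Validate a counts matrix + sample metadata pair.
check_count_matrix <- function(counts, meta = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stopf("counts must be a numeric matrix (features x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must carry feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stopf("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stopf("duplicate sample ids")
  if (any(counts < 0)) stopf("counts must be nonnegative")
  if (!is.null(meta)) {
    if (!all(colnames(counts) %in% meta$sample_id))
      stopf("sample metadata missing entries for some count columns")
    tum <- meta[meta$condition == "tumor", , drop = FALSE]
    if (any(is.na(tum$stage))) stopf("every tumor sample needs a stage")
  }
  invisible(TRUE)
}
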