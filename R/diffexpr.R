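#' Differential-expression thresholds
#'
#' Cutoffs used to call differentially expressed features: adjusted p <=
#' `adjp_max` in all modes; |signed fold change| >= `min_abs_fc_list` for the
#' reported DEG list, >= `min_abs_fc_network` for the stricter network seed
#' set; miRNAs additionally support a volcano-style rule (|FC| >=
#' `mirna_volcano_fc` and raw p <= `mirna_volcano_p`). Stage groups with
#' fewer than `stage_min_n` samples are excluded from stage-wise analyses.
#'
#' @param adjp_max Maximum Benjamini-Hochberg adjusted p.
#' @param min_abs_fc_list Minimum |FC| for the DEG list.
#' @param min_abs_fc_network Minimum |FC| for the network seed set.
#' @param mirna_volcano_fc,mirna_volcano_p Volcano cutoffs for miRNAs.
#' @param mirna_volcano_use_adjp Use adjusted instead of raw p in the miRNA
#'   volcano rule.
#' @param stage_min_n Minimum per-stage group size.
#' @return A list of class `de_thresholds`.
#' @export
de_thresholds <- function(adjp_max = 0.01, min_abs_fc_list = 1.5,
                          min_abs_fc_network = 2, mirna_volcano_fc = 2,
                          mirna_volcano_p = 1e-5,
                          mirna_volcano_use_adjp = FALSE,
                          stage_min_n = 15) {
  th <- list(adjp_max = adjp_max, min_abs_fc_list = min_abs_fc_list,
             min_abs_fc_network = min_abs_fc_network,
             mirna_volcano_fc = mirna_volcano_fc,
             mirna_volcano_p = mirna_volcano_p,
             mirna_volcano_use_adjp = mirna_volcano_use_adjp,
             stage_min_n = stage_min_n)
  if (any(unlist(th[c(1:5, 7)]) <= 0)) stopf("thresholds must be positive")
  if (th$adjp_max > 1) stopf("adjp_max must lie in (0, 1]")
  structure(th, class = "de_thresholds")
}

#' Median-of-ratios normalization
#'
#' Estimates a size factor per sample as the median, over features with a
#' positive geometric mean, of the ratio of that sample's count to the
#' feature's geometric mean across samples. Normalized counts are
#' `count / size_factor`.
#'
#' @param counts Features x samples numeric matrix of raw counts.
#' @return A list of class `norm_result` with `size_factors` (named, one per
#'   sample) and `normalized` (matrix).
#' @export
#' @examples
#' m <- matrix(c(2, 8, 4, 16), 2, dimnames = list(c("f1", "f2"), c("a", "b")))
#' median_of_ratios(m)$size_factors
median_of_ratios <- function(counts) {
  check_count_matrix(counts)
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use))
    stopf("normalization error: no feature with a positive geometric mean")
  ratios <- counts[use, , drop = FALSE] / exp(loggeo[use])
  s <- apply(ratios, 2, median)
  if (any(s <= 0)) stopf("normalization error: nonpositive size factor")
  structure(list(size_factors = s,
                 normalized = sweep(counts, 2, s, "/")),
            class = "norm_result")
}

#' @export
print.norm_result <- function(x, ...) {
  cat(sprintf("Median-of-ratios normalization: %d samples, size factors in [%.3g, %.3g]\n",
              length(x$size_factors), min(x$size_factors),
              max(x$size_factors)))
  invisible(x)
}

# Signed fold-change convention: 2^log2FC when up, -2^|log2FC| when down, so
# |FC| thresholds read naturally on both sides.
signed_fc <- function(log2fc) ifelse(log2fc >= 0, 2^log2fc, -(2^(-log2fc)))

# Per-feature method-of-moments NB dispersion within one group.
mom_dispersion <- function(mat) {
  mu <- rowMeans(mat)
  v <- apply(mat, 1, var)
  a <- (v - mu) / mu^2
  a[!is.finite(a)] <- NA
  a
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' A simplified NB Wald test on median-of-ratios-normalized counts: the log2
#' fold change is computed from pseudocount-stabilized group means, the
#' per-feature NB dispersion is estimated by the method of moments within
#' each group (pooled by degrees of freedom, floored at 1e-8), the standard
#' error follows from the delta method under NB variance `mu + alpha mu^2`,
#' and two-sided p-values come from the standard normal, adjusted across
#' features by Benjamini-Hochberg. This deliberately replaces the full
#' GLM-with-dispersion-shrinkage machinery of dedicated DE packages; it is
#' calibrated against planted-effect recovery, not against their exact
#' output.
#'
#' @param counts Features x samples raw count matrix.
#' @param norm Result of [median_of_ratios()] on `counts`.
#' @param group_a,group_b Disjoint character vectors of sample ids; the fold
#'   change is a over b (tumor over control, conventionally).
#' @param pseudocount Added to group means before taking logs.
#' @return Data frame with columns `feature`, `base_mean`, `log2fc`, `fc`
#'   (signed), `se`, `p`, `adjp`.
#' @export
nb_wald_test <- function(counts, norm, group_a, group_b, pseudocount = 0.5) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stopf("both groups must be non-empty")
  if (length(intersect(group_a, group_b)) > 0)
    stopf("groups must be disjoint")
  if (length(group_a) == 1 || length(group_b) == 1)
    warnf("a group has a single sample; the test is low-powered")
  y <- norm$normalized
  ya <- y[, group_a, drop = FALSE]
  yb <- y[, group_b, drop = FALSE]
  na <- length(group_a); nb <- length(group_b)

  ma <- rowMeans(ya); mb <- rowMeans(yb)
  log2fc <- log2((ma + pseudocount) / (mb + pseudocount))

  aa <- if (na > 1) mom_dispersion(ya) else rep(NA_real_, nrow(y))
  ab <- if (nb > 1) mom_dispersion(yb) else rep(NA_real_, nrow(y))
  wa <- max(na - 1, 0); wb <- max(nb - 1, 0)
  alpha <- rowSums(cbind(aa * wa, ab * wb), na.rm = TRUE) /
    ifelse(is.na(aa) & is.na(ab), NA,
           (!is.na(aa)) * wa + (!is.na(ab)) * wb)
  alpha <- pmax(alpha, 1e-8)
  alpha[is.na(alpha)] <- 1e-8

  # delta method: Var(log2(mean + pc)) = Var(mean) / ((mean + pc) ln 2)^2
  va <- (ma + alpha * ma^2) / na
  vb <- (mb + alpha * mb^2) / nb
  se <- sqrt(va / (ma + pseudocount)^2 + vb / (mb + pseudocount)^2) / log(2)

  z <- ifelse(se > 0, log2fc / se, 0)
  p <- ifelse(se > 0, 2 * pnorm(-abs(z)), 1)
  data.frame(feature = rownames(counts),
             base_mean = (ma * na + mb * nb) / (na + nb),
             log2fc = log2fc, fc = signed_fc(log2fc), se = se, p = p,
             adjp = p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Stage groups retained under the minimum-group-size rule.
retained_stages <- function(meta, stage_min_n) {
  tab <- table(meta$stage[meta$condition == "tumor"])
  names(tab)[tab >= stage_min_n]
}

#' One-way ANOVA across tumor stages
#'
#' Tests, per feature, whether mean log2(normalized + 1) expression differs
#' across tumor stage groups. Stages with fewer than `stage_min_n` tumor
#' samples are dropped from the design (mirroring the exclusion of very
#' small late-stage groups).
#'
#' @param counts Features x samples raw count matrix.
#' @param norm Result of [median_of_ratios()].
#' @param meta Sample metadata with `sample_id`, `condition`, `stage`.
#' @param stage_min_n Minimum tumor samples per retained stage.
#' @return Data frame `feature`, `anova_p`, `anova_adjp`, with attribute
#'   `stages_used`.
#' @export
stage_anova <- function(counts, norm, meta, stage_min_n = 15) {
  keep <- retained_stages(meta, stage_min_n)
  if (length(keep) < 2)
    stopf("need at least two stage groups with n >= %d", stage_min_n)
  sel <- meta$condition == "tumor" & meta$stage %in% keep
  ids <- meta$sample_id[sel]
  g <- factor(meta$stage[sel])
  x <- log2(norm$normalized[, ids, drop = FALSE] + 1)
  p <- apply(x, 1, function(row) {
    if (var(row) == 0) return(1)
    oneway.test(row ~ g, var.equal = TRUE)$p.value
  })
  out <- data.frame(feature = rownames(counts), anova_p = unname(p),
                    anova_adjp = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  attr(out, "stages_used") <- keep
  out
}

#' Full differential-expression analysis of one count matrix
#'
#' Runs median-of-ratios normalization, the tumor-vs-control NB Wald test,
#' per-stage (stage vs control) Wald tests for stages passing the
#' minimum-group-size rule, and the across-stage ANOVA, returning one record
#' per feature.
#'
#' @param counts Features x samples raw count matrix.
#' @param meta Sample metadata (`sample_id`, `condition`, `stage`).
#' @param thresholds A [de_thresholds()] (used for `stage_min_n` here).
#' @return A list of class `de_result`: `records` (data frame), `norm`,
#'   `stages_used`.
#' @export
de_analysis <- function(counts, meta, thresholds = de_thresholds()) {
  check_count_matrix(counts, meta)
  norm <- median_of_ratios(counts)
  tumor <- meta$sample_id[meta$condition == "tumor"]
  control <- meta$sample_id[meta$condition == "control"]
  rec <- nb_wald_test(counts, norm, tumor, control)

  keep <- retained_stages(meta, thresholds$stage_min_n)
  for (st in keep) {
    ids <- meta$sample_id[meta$condition == "tumor" & meta$stage == st]
    r <- nb_wald_test(counts, norm, ids, control)
    rec[[paste0("log2fc_", st)]] <- r$log2fc
    rec[[paste0("p_", st)]] <- r$p
    rec[[paste0("adjp_", st)]] <- r$adjp
  }
  if (length(keep) >= 2) {
    an <- stage_anova(counts, norm, meta, thresholds$stage_min_n)
    rec$anova_p <- an$anova_p
    rec$anova_adjp <- an$anova_adjp
  }
  structure(list(records = rec, norm = norm, stages_used = keep,
                 thresholds = thresholds), class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("Differential expression: %d features tested; stages retained: %s\n",
              nrow(x$records), paste(x$stages_used, collapse = ", ")))
  invisible(x)
}

#' Select differentially expressed features by thresholds
#'
#' Deterministic filter on a record table. Modes: `gene_list` (adjP and
#' |FC| >= `min_abs_fc_list`), `gene_network` (adjP and |FC| >=
#' `min_abs_fc_network`), `mirna` (volcano rule: |FC| >= `mirna_volcano_fc`
#' and p <= `mirna_volcano_p`, raw p by default).
#'
#' @param records Data frame from [nb_wald_test()] / [de_analysis()].
#' @param thresholds A [de_thresholds()].
#' @param mode One of `"gene_list"`, `"gene_network"`, `"mirna"`.
#' @return Data frame `feature`, `direction` ("up"/"down"), plus the fold
#'   change and p columns of the selected records.
#' @export
apply_thresholds <- function(records, thresholds = de_thresholds(),
                             mode = c("gene_list", "gene_network", "mirna")) {
  mode <- match.arg(mode)
  if (nrow(records) == 0)
    return(data.frame(feature = character(0), direction = character(0)))
  keep <- switch(mode,
    gene_list = records$adjp <= thresholds$adjp_max &
      abs(records$fc) >= thresholds$min_abs_fc_list,
    gene_network = records$adjp <= thresholds$adjp_max &
      abs(records$fc) >= thresholds$min_abs_fc_network,
    mirna = {
      pv <- if (thresholds$mirna_volcano_use_adjp) records$adjp else records$p
      abs(records$fc) >= thresholds$mirna_volcano_fc &
        pv <= thresholds$mirna_volcano_p
    })
  keep[is.na(keep)] <- FALSE
  out <- records[keep, , drop = FALSE]
  out$direction <- ifelse(out$fc >= 0, "up", "down")
  rownames(out) <- NULL
  out[, c("feature", "direction",
          setdiff(names(out), c("feature", "direction")))]
}

#' Volcano-plot-ready export of a DE record table
#'
#' @param records Data frame from [nb_wald_test()].
#' @param thresholds A [de_thresholds()].
#' @param mode Selection mode passed to [apply_thresholds()].
#' @return Data frame `feature`, `log2fc`, `neg_log10_p`, `significant`.
#' @export
volcano_data <- function(records, thresholds = de_thresholds(),
                         mode = "gene_list") {
  sel <- apply_thresholds(records, thresholds, mode)
  data.frame(feature = records$feature, log2fc = records$log2fc,
             neg_log10_p = -log10(pmax(records$p, .Machine$double.xmin)),
             significant = records$feature %in% sel$feature,
             stringsAsFactors = FALSE)
}
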