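#' Relative quantification of a qPCR measurement
#'
#' Efficiency-corrected ratio of target to reference gene signal in a test
#' sample relative to a calibrator:
#' \deqn{ratio = E_t^{-(Ct_t - Ct_t^{cal})} / E_r^{-(Ct_r - Ct_r^{cal})}}
#' With both efficiencies at the ideal doubling value 2 this is the familiar
#' \eqn{2^{-\Delta\Delta Ct}}. For gene dosage the reference gene is a
#' copy-number-stable locus (ALB) and the calibrator is normal blood; for
#' expression the reference gene is SDHA and the calibrator is cultured
#' fetal osteoblasts.
#'
#' All arguments are vectorised and recycled.
#'
#' @param ct_target,ct_reference Ct of target/reference gene in the test
#'   sample (cycles).
#' @param cal_ct_target,cal_ct_reference same, in the calibrator.
#' @param eff_target,eff_reference amplification efficiencies, in [1, 2.2]
#'   (2 = perfect doubling per cycle).
#' @return numeric vector of normalized ratios (>= 0).
#' @export
normalized_ratio <- function(ct_target, ct_reference,
                             cal_ct_target, cal_ct_reference,
                             eff_target = 2, eff_reference = 2) {
  cts <- c(ct_target, ct_reference, cal_ct_target, cal_ct_reference)
  if (any(!is.finite(cts))) stop("all Ct values must be finite")
  if (any(eff_target < 1) || any(eff_reference < 1))
    stop("amplification efficiency must be >= 1")
  if (any(eff_target > 2.2) || any(eff_reference > 2.2))
    stop("amplification efficiency must be <= 2.2")
  (eff_target ^ -(ct_target - cal_ct_target)) /
    (eff_reference ^ -(ct_reference - cal_ct_reference))
}

#' Gene dosage call from a normalized qPCR ratio
#'
#' A normalized ratio of 1 corresponds to two copies of the target, so
#' `copy_number = 2 * ratio`. A gene is called amplified when its copy number
#' strictly exceeds 3.5.
#'
#' @param ratio normalized ratio(s), >= 0.
#' @param threshold amplification copy-number threshold (strict `>`).
#' @return data.frame(normalized_ratio, copy_number, amplified)
#' @export
call_dosage <- function(ratio, threshold = 3.5) {
  if (any(ratio < 0)) stop("normalized ratio must be >= 0")
  cn <- 2 * ratio
  data.frame(normalized_ratio = ratio, copy_number = cn,
             amplified = cn > threshold)
}

#' The eight-gene 17p11.2-p12 marker panel
#'
#' Marker genes spanning the amplified region, ordered by position (Mb on
#' chromosome 17), used to screen tumours for amplification events.
#'
#' @return data.frame(gene, mb) with strictly increasing positions.
#' @export
marker_panel <- function() {
  data.frame(
    gene = c("SCO1", "MAP2K4", "MYOCD", "COX10", "PMP22", "NCOR1", "COPS3",
             "TOM1L2"),
    mb = c(10.6, 11.9, 12.6, 14.0, 15.1, 16.1, 17.2, 17.8),
    stringsAsFactors = FALSE
  )
}

#' Screen a cohort for region amplification
#'
#' A sample is selected when at least one panel marker is amplified
#' (copy number > 3.5 by qPCR dosage).
#'
#' @param calls data.frame with columns `sample`, `gene`, `amplified`
#'   (or `copy_number`, from which `amplified` is derived with the strict
#'   3.5 rule). Every sample must have a call for every panel marker.
#' @param panel marker panel data.frame (column `gene`); defaults to
#'   [marker_panel()].
#' @return list: `selected` (character vector, sorted), `summary` (per-sample
#'   data.frame with `n_amplified` and `selected`).
#' @export
screen_cohort <- function(calls, panel = marker_panel()) {
  stopifnot(is.data.frame(calls), all(c("sample", "gene") %in% names(calls)))
  if (!"amplified" %in% names(calls)) {
    if (!"copy_number" %in% names(calls))
      stop("calls need an 'amplified' or 'copy_number' column")
    calls$amplified <- calls$copy_number > 3.5
  }
  samples <- sort(unique(calls$sample))
  for (s in samples) {
    have <- calls$gene[calls$sample == s]
    miss <- setdiff(panel$gene, have)
    if (length(miss))
      stop(sprintf("sample '%s' is missing marker call(s): %s",
                   s, paste(miss, collapse = ", ")))
  }
  keep <- calls$gene %in% panel$gene
  n_amp <- tapply(calls$amplified[keep], calls$sample[keep], sum)
  n_amp <- n_amp[samples]
  summary <- data.frame(sample = samples, n_amplified = as.integer(n_amp),
                        selected = n_amp >= 1, row.names = NULL,
                        stringsAsFactors = FALSE)
  list(selected = samples[summary$selected], summary = summary)
}

#' Expression fold change from qRT-PCR Ct values
#'
#' Same relative-quantification arithmetic as [normalized_ratio()], with the
#' osteoblast sample as calibrator; a tumour is called overexpressed at a
#' fold change of 2 or more (inclusive).
#'
#' @inheritParams normalized_ratio
#' @param threshold overexpression fold-change threshold (inclusive `>=`).
#' @return data.frame(fold_change, overexpressed)
#' @export
qpcr_fold_change <- function(ct_target, ct_reference,
                             cal_ct_target, cal_ct_reference,
                             eff_target = 2, eff_reference = 2,
                             threshold = 2) {
  fc <- normalized_ratio(ct_target, ct_reference, cal_ct_target,
                         cal_ct_reference, eff_target, eff_reference)
  data.frame(fold_change = fc, overexpressed = fc >= threshold)
}

#' Average replicate Ct values
#'
#' Reactions are run in triplicate; replicate Cts are averaged (arithmetic
#' mean of cycles) before ratio computation.
#'
#' @param ct_table data.frame with columns `sample`, `gene`, `role`
#'   (`target`/`reference`), `context` (`test`/`calibrator`), `ct`, and
#'   optionally `efficiency`.
#' @return one row per (sample, gene, role, context) with mean `ct`.
#' @export
aggregate_ct <- function(ct_table) {
  need <- c("sample", "gene", "role", "context", "ct")
  miss <- setdiff(need, names(ct_table))
  if (length(miss)) stop("ct table missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(ct_table$ct))) stop("all Ct values must be finite")
  keys <- c("sample", "gene", "role", "context",
            intersect("efficiency", names(ct_table)))
  agg <- stats::aggregate(ct_table["ct"], by = ct_table[keys], FUN = mean)
  agg[order(agg$sample, agg$gene, agg$role, agg$context), , drop = FALSE]
}

#' Dosage calls for every sample and gene in an aggregated Ct table
#'
#' Pairs each test measurement with the single calibrator measurement of the
#' same gene and computes the dosage call.
#'
#' @param ct_agg aggregated Ct table from [aggregate_ct()]; the calibrator
#'   rows use `context == "calibrator"` with any sample id.
#' @return data.frame(sample, gene, normalized_ratio, copy_number, amplified)
#' @export
dosage_calls_from_ct <- function(ct_agg) {
  get_ct <- function(df, role) {
    x <- df$ct[df$role == role]
    if (length(x) != 1) stop("expected exactly one ", role, " Ct, got ", length(x))
    x
  }
  eff <- function(df, role) {
    if (!"efficiency" %in% names(df)) return(2)
    e <- df$efficiency[df$role == role]
    if (length(e) < 1 || is.na(e[1])) 2 else e[1]
  }
  cal <- ct_agg[ct_agg$context == "calibrator", , drop = FALSE]
  test <- ct_agg[ct_agg$context == "test", , drop = FALSE]
  out <- list()
  for (g in unique(test$gene)) {
    cg <- cal[cal$gene == g, , drop = FALSE]
    if (!nrow(cg)) stop("no calibrator measurement for gene '", g, "'")
    for (s in unique(test$sample[test$gene == g])) {
      tg <- test[test$gene == g & test$sample == s, , drop = FALSE]
      r <- normalized_ratio(get_ct(tg, "target"), get_ct(tg, "reference"),
                            get_ct(cg, "target"), get_ct(cg, "reference"),
                            eff(tg, "target"), eff(tg, "reference"))
      out[[length(out) + 1L]] <- cbind(data.frame(sample = s, gene = g,
                                                  stringsAsFactors = FALSE),
                                       call_dosage(r))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
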