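# Replicates recorded at the run-length sentinel (e.g. 45 cycles) are
# undetected and excluded from replicate means.
detected_mean <- function(cq, max_cycles) {
  keep <- cq < max_cycles
  if (!any(keep)) return(NA_real_)
  mean(cq[keep])
}

#' Per-sample dCq (target minus reference)
#'
#' Replicates are aggregated by arithmetic mean of detected Cq values;
#' replicates at the `max_cycles` sentinel are excluded. A sample whose
#' target replicates are all undetected is dropped with a warning; a sample
#' with no detected reference measurement is an error (normalization is
#' impossible without it).
#'
#' @param table Long-format Cq `data.frame` with columns `sample_id`,
#'   `assay`, `cq` (as from [simulate_cq_table()]).
#' @param target,reference Assay names for numerator and normalizer.
#' @param max_cycles Undetected sentinel (default: the table's
#'   `"max_cycles"` attribute, else 45).
#' @return Named numeric vector of dCq per retained sample, with attribute
#'   `"dropped"` listing excluded samples.
#' @export
delta_cq <- function(table, target = "target", reference = "reference",
                     max_cycles = NULL) {
  if (is.null(max_cycles)) {
    max_cycles <- attr(table, "max_cycles")
    if (is.null(max_cycles)) max_cycles <- 45
  }
  ids <- unique(table$sample_id)
  out <- numeric(0)
  dropped <- character(0)
  for (id in ids) {
    sub <- table[table$sample_id == id, ]
    ref_cq <- sub$cq[sub$assay == reference]
    if (length(ref_cq) == 0) {
      stop(sprintf("sample '%s' has no %s (reference) measurement", id,
                   reference))
    }
    ref_mean <- detected_mean(ref_cq, max_cycles)
    if (is.na(ref_mean)) {
      stop(sprintf("sample '%s': all reference replicates undetected", id))
    }
    tgt_mean <- detected_mean(sub$cq[sub$assay == target], max_cycles)
    if (is.na(tgt_mean)) {
      dropped <- c(dropped, id)
      next
    }
    out[id] <- tgt_mean - ref_mean
  }
  if (length(dropped)) {
    warning(sprintf("dropped %d sample(s) with no detected target: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  attr(out, "dropped") <- dropped
  out
}

#' Relative quantification by the 2^-ddCq method
#'
#' `FC = 2^-(dCq - calibrator)`, the Livak-Schmittgen relative expression of
#' each sample against a calibrator dCq (by default the median dCq of the
#' control samples).
#'
#' @param dcq Named numeric vector of per-sample dCq ([delta_cq()]).
#' @param calibrator_dcq Calibrator dCq; either a number or a vector of
#'   control dCq values whose median is used.
#' @return Named numeric vector of positive fold changes.
#' @export
fold_change <- function(dcq, calibrator_dcq) {
  if (length(calibrator_dcq) == 0 || all(is.na(calibrator_dcq))) {
    stop("empty control/calibrator set")
  }
  cal <- if (length(calibrator_dcq) > 1) {
    median(calibrator_dcq, na.rm = TRUE)
  } else {
    calibrator_dcq
  }
  2^(-(dcq - cal))
}

#' Spike-in recovery quality control
#'
#' Recovery of the exogenous spike-in control (a C. elegans miRNA absent
#' from humans, added at fixed amount before extraction):
#' `recovery = 2^(reference_cq - Cq_spikein)`, so one extra cycle means half
#' the material recovered. Samples outside `[floor, ceiling]` are flagged,
#' not dropped.
#'
#' @param table Long-format Cq `data.frame` containing the spike-in assay.
#' @param reference_cq Expected spike-in Cq; default: mean detected spike-in
#'   Cq across the run.
#' @param assay Spike-in assay name (default `"spikein"`).
#' @param floor,ceiling Flagging bounds on the recovery fraction
#'   (defaults 0.5 and 1, flagging both poor recovery and anomalous > 1
#'   values).
#' @param max_cycles Undetected sentinel (default: table attribute, else 45).
#' @return `data.frame` with `sample_id`, `recovery`, `flagged`.
#' @export
spikein_recovery <- function(table, reference_cq = NULL, assay = "spikein",
                             floor = 0.5, ceiling = 1, max_cycles = NULL) {
  if (is.null(max_cycles)) {
    max_cycles <- attr(table, "max_cycles")
    if (is.null(max_cycles)) max_cycles <- 45
  }
  sub <- table[table$assay == assay, ]
  if (nrow(sub) == 0) stop(sprintf("no '%s' assay present", assay))
  ids <- unique(sub$sample_id)
  cq <- vapply(ids, function(id)
    detected_mean(sub$cq[sub$sample_id == id], max_cycles), numeric(1))
  if (is.null(reference_cq)) reference_cq <- mean(cq, na.rm = TRUE)
  rec <- 2^(reference_cq - cq)
  data.frame(sample_id = ids, recovery = rec,
             flagged = is.na(rec) | rec < floor | rec > ceiling,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Dichotomize expression at the control median
#'
#' Labels each sample `low` if its value is below the median of the control
#' reference values, else `high`. Values exactly at the median are assigned
#' `high` (documented tie rule) and reported via the `"ties"` attribute.
#'
#' @param values Named numeric per-sample values (fold change or ddCq).
#' @param reference Non-empty numeric control values defining the cut-off.
#' @return Character vector of `"high"`/`"low"` labels (named like
#'   `values`), with attributes `"cutoff"` and `"ties"`.
#' @export
dichotomize_median <- function(values, reference) {
  if (length(reference) == 0 || all(is.na(reference))) {
    stop("reference values must be non-empty")
  }
  cut <- median(reference, na.rm = TRUE)
  labels <- ifelse(values < cut, "low", "high")
  ties <- names(values)[!is.na(values) & values == cut]
  if (length(ties)) {
    message(sprintf("%d value(s) exactly at the cut-off assigned 'high'",
                    length(ties)))
  }
  structure(labels, cutoff = cut, ties = ties)
}
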