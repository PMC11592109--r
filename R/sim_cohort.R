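#' Configuration for the synthetic patient/control cohort
#'
#' Parameters for generating qPCR quantification-cycle (Cq) tables and
#' time-to-event tables shaped like a small early-stage NSCLC cohort with
#' healthy-donor controls. The planted effects (fold change of the target
#' miRNA in cases, hazard ratio between expression groups) are the ground
#' truth that downstream analysis should recover.
#'
#' @param n_patients Number of cases (`>= 2`).
#' @param n_controls Number of healthy-donor controls (`>= 2`).
#' @param planted_fold_change Relative expression (2^-ddCq scale) of the
#'   target in cases versus controls; encoded as a `-log2(FC)` shift of the
#'   case target dCq.
#' @param reference_cq_mean,reference_cq_sd Mean/SD of the reference-assay Cq
#'   in cycles. The SD is the per-replicate technical noise applied to every
#'   assay.
#' @param target_delta_cq Baseline dCq (target minus reference) in controls.
#' @param spikein_cq_mean Mean Cq of the exogenous spike-in recovery control.
#' @param n_replicates Technical replicates per assay.
#' @param detection_dropout Probability that a single replicate is undetected
#'   and recorded at the `max_cycles` sentinel.
#' @param max_cycles Run length in cycles; undetected reactions are recorded
#'   at this sentinel value (45 cycles by default, matching a standard
#'   45-cycle protocol).
#' @param hazard_ratio_low_vs_high Hazard ratio of the low-expression group
#'   relative to the high-expression group (`> 0`).
#' @param median_survival_high Median event time (months) in the
#'   high-expression (reference) group.
#' @param censoring_rate Probability that a subject is censored rather than
#'   observed to the event, in `[0, 1]`.
#' @param seed Default seed used when the `simulate_*` call does not pass one.
#'
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_patients = 31L, n_controls = 10L,
                              planted_fold_change = 1,
                              reference_cq_mean = 20, reference_cq_sd = 0.2,
                              target_delta_cq = 3,
                              spikein_cq_mean = 22,
                              n_replicates = 2L,
                              detection_dropout = 0,
                              max_cycles = 45,
                              hazard_ratio_low_vs_high = 1,
                              median_survival_high = 36,
                              censoring_rate = 0.2,
                              seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_controls = as.integer(n_controls),
              planted_fold_change = planted_fold_change,
              reference_cq_mean = reference_cq_mean,
              reference_cq_sd = reference_cq_sd,
              target_delta_cq = target_delta_cq,
              spikein_cq_mean = spikein_cq_mean,
              n_replicates = as.integer(n_replicates),
              detection_dropout = detection_dropout,
              max_cycles = max_cycles,
              hazard_ratio_low_vs_high = hazard_ratio_low_vs_high,
              median_survival_high = median_survival_high,
              censoring_rate = censoring_rate,
              seed = as.integer(seed))
  check_that(cfg$n_patients >= 2, "n_patients", "must be >= 2")
  check_that(cfg$n_controls >= 2, "n_controls", "must be >= 2")
  check_that(cfg$planted_fold_change > 0, "planted_fold_change",
             "must be > 0")
  check_that(cfg$reference_cq_sd >= 0, "reference_cq_sd", "must be >= 0")
  check_that(cfg$detection_dropout >= 0 && cfg$detection_dropout < 1,
             "detection_dropout", "must be in [0, 1)")
  check_that(cfg$hazard_ratio_low_vs_high > 0, "hazard_ratio_low_vs_high",
             "must be > 0")
  check_that(cfg$censoring_rate >= 0 && cfg$censoring_rate <= 1,
             "censoring_rate", "must be in [0, 1]")
  check_that(cfg$n_replicates >= 1, "n_replicates", "must be >= 1")
  structure(cfg, class = "cohort_sim_config")
}

#' Simulate a long-format qPCR Cq table
#'
#' Each sample carries target, reference and spike-in assays with
#' `n_replicates` technical replicates. The planted fold change appears as a
#' `-log2(FC)` shift of the case target dCq, so `fold_change()` downstream
#' recovers it exactly when `reference_cq_sd = 0`. Undetected replicates are
#' emitted at the `max_cycles` sentinel.
#'
#' @param cfg A [cohort_sim_config()].
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return A `data.frame` with columns `sample_id`, `group`
#'   (`case`/`control`), `assay` (`target`/`reference`/`spikein`),
#'   `replicate`, `cq`, carrying `max_cycles` as attribute `"max_cycles"`.
#' @export
simulate_cq_table <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  set.seed(as.integer(seed))
  groups <- c(rep("case", cfg$n_patients), rep("control", cfg$n_controls))
  ids <- c(sprintf("P%02d", seq_len(cfg$n_patients)),
           sprintf("HD%02d", seq_len(cfg$n_controls)))
  shift <- -log2(cfg$planted_fold_change)  # ddCq of cases vs controls
  rows <- list()
  for (k in seq_along(ids)) {
    dcq <- cfg$target_delta_cq + if (groups[k] == "case") shift else 0
    means <- c(target = cfg$reference_cq_mean + dcq,
               reference = cfg$reference_cq_mean,
               spikein = cfg$spikein_cq_mean)
    for (assay in names(means)) {
      cq <- means[[assay]] + rnorm(cfg$n_replicates, 0, cfg$reference_cq_sd)
      undet <- runif(cfg$n_replicates) < cfg$detection_dropout
      cq[undet] <- cfg$max_cycles
      cq <- pmin(cq, cfg$max_cycles)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = ids[k], group = groups[k], assay = assay,
        replicate = seq_len(cfg$n_replicates), cq = cq,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "max_cycles") <- cfg$max_cycles
  out
}

#' Simulate a survival table with a planted hazard ratio
#'
#' Event times are exponential with a group-specific rate: the
#' high-expression group has median `median_survival_high` months and the
#' low-expression group's hazard is multiplied by
#' `hazard_ratio_low_vs_high`. Each subject is independently censored with
#' probability `censoring_rate`, at a time uniform on `(0, T)` so censoring
#' precedes the (unobserved) event.
#'
#' @param cfg A [cohort_sim_config()].
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return A `data.frame` with columns `patient_id`, `expression_group`
#'   (`high`/`low`, split evenly across `n_patients`), `time_months`,
#'   `event` (1 = event observed, 0 = censored).
#' @export
simulate_survival_table <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  check_that(cfg$hazard_ratio_low_vs_high > 0, "hazard_ratio_low_vs_high",
             "must be > 0")
  set.seed(as.integer(seed))
  n <- cfg$n_patients
  grp <- rep(c("high", "low"), length.out = n)
  base_rate <- log(2) / cfg$median_survival_high
  rate <- ifelse(grp == "low", base_rate * cfg$hazard_ratio_low_vs_high,
                 base_rate)
  t_event <- rexp(n, rate)
  censored <- runif(n) < cfg$censoring_rate
  time <- ifelse(censored, runif(n) * t_event, t_event)
  data.frame(patient_id = sprintf("P%02d", seq_len(n)),
             expression_group = grp,
             time_months = time,
             event = as.integer(!censored),
             stringsAsFactors = FALSE)
}
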