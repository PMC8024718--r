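MUTATION_GROUPS <- c("double_wt", "tp53_only", "ras_braf_only", "co_mut")

#' Aggregate per-lesion mutation calls to patient level
#'
#' A patient is `mutated` in a gene when any lesion carries the mutation,
#' `wild-type` when every known call is wild-type, and `unknown` when all
#' calls are unknown. The heterogeneity flag marks genes with both
#' mutated and wild-type calls among the patient's lesions (such patients
#' still count as mutated).
#'
#' @param lesions Lesion-level data.frame with `patient_id` and gene
#'   columns `KRAS`, `NRAS`, `BRAF`, `TP53` (levels
#'   `mutated`/`wild-type`/`unknown`).
#' @return data.frame, one row per patient: `patient_id`, per-gene status
#'   columns, and per-gene logical `<gene>_het` flags.
#' @export
patientMutationStatus <- function(lesions) {
  pid <- as.character(lesions$patient_id)
  upat <- unique(pid)
  f <- factor(pid, levels = upat)
  out <- data.frame(patient_id = upat)
  for (g in MUTATION_GENES) {
    calls <- as.character(lesions[[g]])
    calls[is.na(calls)] <- "unknown"
    anyMut <- as.vector(tapply(calls == "mutated", f, any))
    anyWt <- as.vector(tapply(calls == "wild-type", f, any))
    out[[g]] <- ifelse(anyMut, "mutated",
                       ifelse(anyWt, "wild-type", "unknown"))
    out[[paste0(g, "_het")]] <- anyMut & anyWt
  }
  out
}

#' Classify patients into RAS/BRAF-V600E/TP53 co-mutation strata
#'
#' Strata: `co_mut` (a RAS gene or BRAF mutated together with TP53),
#' `ras_braf_only`, `tp53_only`, and `double_wt` (all four wild-type).
#' A patient whose grouping genes include an `unknown` status that could
#' change the stratum gets `NA` and is excluded from group-stratified
#' analyses.
#'
#' @param status Patient-level status data.frame from
#'   [patientMutationStatus()] (or any data.frame with the four gene
#'   columns).
#' @return Factor of group labels, levels ordered
#'   `double_wt < tp53_only < ras_braf_only < co_mut`.
#' @export
classifyMutationGroup <- function(status) {
  rb <- c("KRAS", "NRAS", "BRAF")
  rasMut <- apply(status[, rb, drop = FALSE] == "mutated", 1L, any)
  rasUnk <- !rasMut &
    apply(status[, rb, drop = FALSE] == "unknown", 1L, any)
  tp53 <- as.character(status$TP53)
  grp <- ifelse(rasUnk | tp53 == "unknown", NA_character_,
         ifelse(rasMut & tp53 == "mutated", "co_mut",
         ifelse(rasMut, "ras_braf_only",
         ifelse(tp53 == "mutated", "tp53_only", "double_wt"))))
  factor(grp, levels = MUTATION_GROUPS)
}

#' Check mutual exclusivity of KRAS/NRAS/BRAF-V600E mutations
#'
#' @param status Patient-level status data.frame.
#' @return Character vector of patient ids with two or more of the three
#'   RAS-pathway genes mutated (expected empty on typical cohorts).
#' @export
exclusivityCheck <- function(status) {
  n <- rowSums(status[, c("KRAS", "NRAS", "BRAF"), drop = FALSE] == "mutated")
  as.character(status$patient_id[n >= 2])
}
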