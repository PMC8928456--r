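# Index-wise significance of ORN vs control differences, per modality and
# overall, and the DVC-eligibility flag.

#' Mann-Whitney significance table for DVH indices
#'
#' For each DVH index and each group (overall, photon, proton), the
#' two-sided Mann-Whitney p-value comparing ORN cases against controls.
#' An index is flagged DVC-eligible when p < `alpha` in both modalities
#' separately (the criterion that retained V40/V50/V60).  Groups lacking
#' either outcome class report `NA`.
#'
#' @param index_table per-patient index table from [dvh_index_table()]
#'   (typically restricted to the matched cohort).
#' @param indices index column names to test.
#' @param alpha significance level, default 0.05.
#' @return a `data.frame`: `index`, `p_overall`, `p_photon`, `p_proton`,
#'   `eligible`.
#' @export
index_significance_table <- function(index_table,
                                     indices = c("v40", "v50", "v60",
                                                 "v70", "v75", "d001cc",
                                                 "dmean"),
                                     alpha = 0.05) {
  stopifnot(all(c("modality", "orn") %in% names(index_table)))
  grp_p <- function(tab, ix) {
    v <- tab[[ix]]
    keep <- !is.na(v)
    v <- v[keep]; o <- tab$orn[keep]
    if (sum(o) == 0L || sum(!o) == 0L) return(NA_real_)
    mann_whitney_u(v[o], v[!o])$p.value
  }
  rows <- lapply(indices, function(ix) {
    p_all <- grp_p(index_table, ix)
    p_ph <- grp_p(index_table[index_table$modality == "photon", ], ix)
    p_pr <- grp_p(index_table[index_table$modality == "proton", ], ix)
    data.frame(index = ix, p_overall = p_all, p_photon = p_ph,
               p_proton = p_pr,
               eligible = !is.na(p_ph) && !is.na(p_pr) &&
                 p_ph < alpha && p_pr < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
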