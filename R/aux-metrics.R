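#' IHC H-score
#'
#' Summarises immunohistochemical staining from the percentage of tumour
#' cells at each intensity level i = 0 (negative), 1 (faint), 2 (moderate),
#' 3 (intense): `H = sum_i Pi * (i + 1)`. With the `(i + 1)` weighting the
#' score ranges from 100 (all cells negative) to 400 (all cells intense) —
#' note this differs from the common `sum Pi * i` variant with range 0-300.
#'
#' @param percent_by_intensity Numeric vector of length 4: percentages of
#'   tumour cells at intensities 0, 1, 2, 3. Must be non-negative and sum to
#'   100 (tolerance 0.01).
#' @return The H-score, a number in \[100, 400\].
#' @examples
#' h_score(c(50, 25, 15, 10))  # 185
#' @export
h_score <- function(percent_by_intensity) {
  p <- as.numeric(percent_by_intensity)
  if (length(p) != 4L || any(!is.finite(p)) || any(p < 0)) {
    rlang::abort("percent_by_intensity must be 4 non-negative percentages (intensities 0-3).")
  }
  if (abs(sum(p) - 100) > 0.01) {
    rlang::abort(sprintf("intensity percentages sum to %g, not 100.", sum(p)))
  }
  sum(p * (0:3 + 1))
}

#' EMT classification from the VIM/CDH1 ratio
#'
#' Classifies a sample as epithelial, mesenchymal or intermediate from its
#' linear-scale vimentin / E-cadherin expression ratio: epithelial when the
#' ratio is below `threshold` (default 2), mesenchymal when above. A ratio
#' exactly at the threshold — which the strict inequalities leave unassigned —
#' is called intermediate. An explicit `intermediate_band = c(lo, hi)` maps
#' the whole band to intermediate instead.
#'
#' @param vim,cdh1 Linear-scale expression of VIM and CDH1 (both > 0);
#'   vectors are classified elementwise.
#' @param threshold Ratio boundary between epithelial and mesenchymal.
#' @param intermediate_band Optional `c(lo, hi)`: ratios in \[lo, hi\] are
#'   called intermediate.
#' @return A tibble with columns `ratio` and `label` (factor epithelial /
#'   intermediate / mesenchymal).
#' @examples
#' classify_emt(vim = 10, cdh1 = 2)  # ratio 5 -> mesenchymal
#' @export
classify_emt <- function(vim, cdh1, threshold = 2, intermediate_band = NULL) {
  if (any(!is.finite(vim)) || any(!is.finite(cdh1)) || any(vim <= 0)) {
    rlang::abort("vim and cdh1 must be finite and positive (linear scale).")
  }
  if (any(cdh1 <= 0)) rlang::abort("cdh1 must be positive; VIM/CDH1 ratio undefined.")
  ratio <- vim / cdh1
  if (!is.null(intermediate_band)) {
    stopifnot(length(intermediate_band) == 2L, intermediate_band[1] <= intermediate_band[2])
    label <- ifelse(
      ratio >= intermediate_band[1] & ratio <= intermediate_band[2], "intermediate",
      ifelse(ratio < threshold, "epithelial", "mesenchymal")
    )
  } else {
    label <- ifelse(
      ratio < threshold, "epithelial",
      ifelse(ratio > threshold, "mesenchymal", "intermediate")
    )
  }
  tibble::tibble(
    ratio = ratio,
    label = factor(label, levels = c("epithelial", "intermediate", "mesenchymal"))
  )
}

#' Fold change by the delta-delta-Ct method
#'
#' Relative qPCR quantification: `ddCt = (Ct_target_case - Ct_ref_case) -
#' (Ct_target_ctrl - Ct_ref_ctrl)` and fold change `2^(-ddCt)`. The reference
#' gene (e.g. GAPDH) normalises input amounts; the control condition anchors
#' the fold change at 1.
#'
#' @param ct_target_case,ct_ref_case Ct of target and reference gene in the
#'   case (treated) condition.
#' @param ct_target_ctrl,ct_ref_ctrl Same in the control condition.
#' @return Fold change of the target in case relative to control.
#' @examples
#' delta_delta_ct(20, 18, 22, 18)  # fold = 4
#' @export
delta_delta_ct <- function(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl) {
  cts <- c(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(cts))) rlang::abort("all Ct values must be finite.")
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' Relative wound density
#'
#' Scratch-assay migration metric: cell density inside the wound region,
#' normalised to the density outside the wound so that proliferation changes
#' cancel. `RWD = 100 * (wt - w0) / (ct - w0)`, clipped to \[0, 100\]: 0 when
#' the wound density has not changed, 100 when it matches the outside.
#'
#' @param w0 Initial density inside the wound (percent confluence, 0-100).
#' @param wt Density inside the wound at the time point.
#' @param ct Density outside the wound at the time point; must exceed `w0`.
#' @return Relative wound density, a percentage in \[0, 100\].
#' @examples
#' relative_wound_density(w0 = 5, wt = 50, ct = 95)  # 50
#' @export
relative_wound_density <- function(w0, wt, ct) {
  vals <- c(w0, wt, ct)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 100)) {
    rlang::abort("densities must lie in [0, 100].")
  }
  if (ct <= w0) rlang::abort("outside density must exceed the initial wound density.")
  pmin(pmax(100 * (wt - w0) / (ct - w0), 0), 100)
}
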