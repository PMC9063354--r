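#' Score dual-luciferase reporter measurements
#'
#' The relative expression of a construct is its Fluc/Rluc ratio; the
#' enhancer activity (relative intensity) is that ratio normalized to the
#' blank control (minimal promoter only), so the blank scores exactly 1.
#' Constructs at or above `cutoff` are called positive. The scoring is
#' invariant to rescaling all luminescence readings by a shared constant.
#'
#' @param measurements Tibble with `construct_id`, `fluc`, `rluc` (see
#'   [read_reporter()]).
#' @param blank_id Construct id of the blank control (required).
#' @param cutoff Positive-enhancer threshold on relative intensity (default
#'   2.0, chosen above the negative-control activity of 1.6).
#' @return `measurements` with `relative_expression`, `relative_intensity`,
#'   `is_positive` columns.
#' @export
reporter_score <- function(measurements, blank_id, cutoff = 2.0) {
  if (!blank_id %in% measurements$construct_id) {
    abort(sprintf("blank control '%s' not found", blank_id))
  }
  if (any(measurements$rluc <= 0)) {
    abort("Rluc readings must be positive")
  }
  out <- mutate(measurements,
                relative_expression = .data$fluc / .data$rluc)
  blank <- out$relative_expression[out$construct_id == blank_id][1]
  if (blank <= 0) abort("blank control has non-positive relative expression")
  mutate(out,
    relative_intensity = .data$relative_expression / blank,
    is_positive = .data$relative_intensity >= cutoff
  )
}

#' Correlate enhancer activity with region signal densities
#'
#' Pearson correlation between reporter activities (relative intensities) and
#' per-construct signal densities (eRNA, histone marks, DHS, ...), computed
#' per feature. Extreme outliers are removed first by a logged rule: points
#' outside `median +/- mad_k * MAD` on either variable (MAD with the usual
#' 1.4826 consistency scaling; a zero MAD disables removal on that variable).
#'
#' @param data Long tibble with one row per construct x feature:
#'   `construct_id`, `feature`, `activity`, `density`.
#' @param mad_k MAD multiplier for the outlier rule (default 3).
#' @return A tibble `feature`, `r`, `n_used`, `n_removed`, `removed`
#'   (list-column of removed construct ids). `r` is `NA` when fewer than 3
#'   points survive removal.
#' @export
activity_signal_correlation <- function(data, mad_k = 3) {
  data |>
    group_by(.data$feature) |>
    group_modify(function(d, key) {
      out_x <- mad_outlier(d$activity, mad_k)
      out_y <- mad_outlier(d$density, mad_k)
      drop <- out_x | out_y
      kept <- d[!drop, ]
      r <- if (nrow(kept) < 3) {
        warn(sprintf("feature %s: fewer than 3 points after outlier removal",
                     key$feature))
        NA_real_
      } else {
        safe_cor_n2 <- function(a, b) {
          if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else cor(a, b)
        }
        safe_cor_n2(kept$activity, kept$density)
      }
      tibble(r = r, n_used = nrow(kept), n_removed = sum(drop),
             removed = list(d$construct_id[drop]))
    }) |>
    ungroup()
}

mad_outlier <- function(x, k) {
  m <- median(x)
  s <- mad(x)
  if (s == 0) rep(FALSE, length(x)) else abs(x - m) > k * s
}
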