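#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the group-statistics table of a study
#'
#' @param x a `tdcs_study`.
#' @param ... unused.
#' @return tibble with one row per group test (`comparison`, `test`,
#'   `statistic`, `p_value`, `effect`, `ci_low`, `ci_high`, `n`,
#'   `method`).
#' @method tidy tdcs_study
#' @export
tidy.tdcs_study <- function(x, ...) {
  dplyr::relocate(x$stats, "comparison")
}

#' One-row summary of a study
#'
#' @param x a `tdcs_study`.
#' @param ... unused.
#' @return one-row tibble: cohort size and failures, median conventional
#'   and optimized ROI fields, mean/max improvement, median displacement
#'   D, and the paired Wilcoxon p-value.
#' @method glance tdcs_study
#' @export
glance.tdcs_study <- function(x, ...) {
  tbl <- x$cohort[x$cohort$status == "ok", ]
  wp <- x$stats$p_value[x$stats$test == "wilcoxon_signed_rank"]
  tibble::tibble(
    n = nrow(x$cohort),
    n_failed = x$n_failed,
    conv_field_median = stats::median(tbl$conv_field),
    opt_field_median = stats::median(tbl$opt_field),
    improvement_mean_pct = mean(tbl$improvement_pct),
    improvement_max_pct = max(tbl$improvement_pct),
    d_total_median = stats::median(tbl$d_total),
    wilcoxon_p = if (length(wp)) wp[1L] else NA_real_
  )
}

#' Tidy an optimization result
#'
#' @param x an `optimization_result`.
#' @param ... unused.
#' @return tibble with one row per re-centering iteration (`iteration`,
#'   `best_score`).
#' @method tidy optimization_result
#' @export
tidy.optimization_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$trace), best_score = x$trace)
}

#' One-row summary of an optimization result
#' @param x an `optimization_result`.
#' @param ... unused.
#' @return one-row tibble: final score, iterations, pairs evaluated, and
#'   electrode centres.
#' @method glance optimization_result
#' @export
glance.optimization_result <- function(x, ...) {
  a <- x$montage$anode$center
  c <- x$montage$cathode$center
  tibble::tibble(
    score = x$score, iterations = x$iterations, n_evaluated = x$n_evaluated,
    anode_x = a[1L], anode_y = a[2L], anode_z = a[3L],
    cathode_x = c[1L], cathode_y = c[2L], cathode_z = c[3L]
  )
}

#' Tidy an ROI field summary
#' @param x a `roi_field_summary`.
#' @param ... unused.
#' @return one-row tibble.
#' @method tidy roi_field_summary
#' @export
tidy.roi_field_summary <- function(x, ...) {
  tibble::tibble(
    mean_magnitude = x$mean_magnitude,
    normal_component = x$normal_component,
    n_elements = x$n_elements
  )
}

#' Tidy a montage into an electrode table
#' @param x a `montage`.
#' @param ... unused.
#' @return tibble with one row per electrode.
#' @method tidy montage
#' @export
tidy.montage <- function(x, ...) {
  dplyr::bind_rows(lapply(c("anode", "cathode"), function(role) {
    p <- x[[role]]
    tibble::tibble(
      label = x$label, role = role,
      x = p$center[1L], y = p$center[2L], z = p$center[3L],
      current_mA = p$current, width_mm = p$size[1L], height_mm = p$size[2L],
      area_mm2 = p$area, n_facets = length(p$facet_ids)
    )
  }))
}
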