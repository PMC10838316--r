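#' Plot a study result
#'
#' Standard views of a cohort study: `"fields"` — paired conventional vs
#' optimized ROI field strengths per subject; `"improvement"` — the
#' improvement distribution; `"distance_by_class"` — displacement D by
#' lesion-location class; `"d_vs_fma"` — scatter of D against the
#' initial FMA-UE score.
#'
#' @param object a `tdcs_study`.
#' @param type one of `"fields"`, `"improvement"`, `"distance_by_class"`,
#'   `"d_vs_fma"`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot tdcs_study
#' @export
autoplot.tdcs_study <- function(object,
                                type = c("fields", "improvement",
                                         "distance_by_class", "d_vs_fma"),
                                ...) {
  type <- match.arg(type)
  tbl <- object$cohort[object$cohort$status == "ok", ]
  switch(
    type,
    fields = {
      long <- tidyr::pivot_longer(
        tbl[, c("subject_id", "conv_field", "opt_field")],
        cols = c("conv_field", "opt_field"),
        names_to = "montage", values_to = "field"
      )
      long$montage <- ifelse(long$montage == "conv_field", "conventional",
                             "optimized")
      ggplot2::ggplot(long, ggplot2::aes(
        x = .data$montage, y = .data$field, group = .data$subject_id
      )) +
        ggplot2::geom_line(alpha = 0.4) +
        ggplot2::geom_point(ggplot2::aes(colour = .data$montage), size = 2) +
        ggplot2::labs(x = NULL, y = "ROI field strength (V/m)",
                      colour = NULL,
                      title = "Target electric field per subject") +
        ggplot2::theme_minimal()
    },
    improvement = {
      ggplot2::ggplot(tbl, ggplot2::aes(x = .data$improvement_pct)) +
        ggplot2::geom_histogram(bins = 10, fill = "steelblue",
                                colour = "white") +
        ggplot2::labs(x = "Improvement of ROI field (%)", y = "Subjects",
                      title = "Optimization improvement") +
        ggplot2::theme_minimal()
    },
    distance_by_class = {
      tbl$group <- ifelse(tbl$class == "cortical", "cortical", "non-cortical")
      ggplot2::ggplot(tbl, ggplot2::aes(x = .data$group, y = .data$d_total)) +
        ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
        ggplot2::geom_jitter(width = 0.1, height = 0,
                             ggplot2::aes(colour = .data$class)) +
        ggplot2::labs(x = NULL, y = "Displacement D (mm)",
                      title = "Electrode displacement by lesion location") +
        ggplot2::theme_minimal()
    },
    d_vs_fma = {
      ggplot2::ggplot(tbl, ggplot2::aes(x = .data$fma_ue,
                                        y = .data$d_total)) +
        ggplot2::geom_point(ggplot2::aes(colour = .data$class)) +
        ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                             colour = "grey40") +
        ggplot2::labs(x = "Initial FMA-UE score", y = "Displacement D (mm)",
                      title = "Displacement vs initial motor function") +
        ggplot2::theme_minimal()
    }
  )
}

#' @rdname autoplot.tdcs_study
#' @param x a `tdcs_study`.
#' @param y unused.
#' @export
plot.tdcs_study <- function(x, y, ...) print(autoplot(x, ...))

#' @importFrom rlang .data
NULL
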