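# Simple result figures: baseline-vs-variability F1 bars with MMD overlays.

#' Plot a study summary
#'
#' Bar chart of baseline and variability mean F1 per experiment with the
#' corresponding mean MMD values overlaid as points (secondary axis scaled
#' to the F1 range). Requires ggplot2.
#'
#' @param summary The `summary` data.frame returned by [run_study()].
#' @return A ggplot object.
#' @export
plot_study <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_invalid("plot_study() requires the ggplot2 package")
  }
  long <- rbind(
    data.frame(experiment = summary$experiment_id, setting = "baseline",
               f1 = summary$baseline_f1, mmd = summary$baseline_mmd),
    data.frame(experiment = summary$experiment_id, setting = "variability",
               f1 = summary$variability_f1, mmd = summary$variability_mmd)
  )
  mmd_scale <- max(long$f1) / max(long$mmd, 1e-9)
  ggplot2::ggplot(long, ggplot2::aes(x = experiment, y = f1,
                                     fill = setting)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_point(ggplot2::aes(y = mmd * mmd_scale,
                                     colour = setting),
                        position = ggplot2::position_dodge(width = 0.9),
                        size = 2) +
    ggplot2::scale_y_continuous(
      name = "mean F1",
      sec.axis = ggplot2::sec_axis(~ . / mmd_scale, name = "mean MMD")
    ) +
    ggplot2::labs(x = NULL, fill = "F1", colour = "MMD") +
    ggplot2::theme_minimal()
}
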