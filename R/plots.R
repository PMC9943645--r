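# Figures for the two headline outputs: per-species boxplots of scenario
# abundance changes, and observed-vs-predicted forecast scatter.

#' Boxplots of scenario abundance changes across plots
#'
#' @param ... Named `"scenario_comparison"` objects (names label the
#'   projection variants, e.g. `dynamic =`, `no_dynamic =`).
#' @return A ggplot object.
#' @export
plot_scenario_changes <- function(...) {
  comps <- list(...)
  if (is.null(names(comps)) || any(names(comps) == "")) {
    names(comps) <- paste0("variant", seq_along(comps))
  }
  d <- do.call(rbind, lapply(names(comps), function(nm) {
    delta <- comps[[nm]]$delta
    data.frame(variant = nm,
               species = rep(colnames(delta), each = nrow(delta)),
               delta = as.vector(delta))
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$species, y = .data$delta,
                                  fill = .data$variant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "Change in mean adult abundance\n(climate - baseline)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Observed vs. predicted forecast scatter with 1:1 line
#'
#' @param ... Named `"forecast_report"` objects.
#' @param stage Stage to plot (`"A"`, `"S"` or `"R"`).
#' @return A ggplot object.
#' @export
plot_forecast_scatter <- function(..., stage = "A") {
  reps <- list(...)
  if (is.null(names(reps)) || any(names(reps) == "")) {
    names(reps) <- paste0("variant", seq_along(reps))
  }
  d <- do.call(rbind, lapply(names(reps), function(nm) {
    cc <- reps[[nm]]$cells
    cc <- cc[cc$stage == stage & !is.na(cc$observed), ]
    cc$variant <- nm
    cc
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$observed, y = .data$predicted,
                                  colour = .data$variant)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "black") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$q2.5, ymax = .data$q97.5),
                           width = 0, alpha = 0.4) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::labs(x = "Observed abundance", y = "Predicted abundance",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
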