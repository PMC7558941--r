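# Figures: rBias/rRMSE panels per scenario cell, and a loading-dose
# illustration of the approach to steady state.

#' Plot rBias or rRMSE panels of an SSE summary
#'
#' Bar panels of the chosen metric by parameter and dataset type, faceted
#' by cohort size and true clearance — the conventional display for
#' simulation-estimation performance across sampling designs.
#'
#' @param object An `sse_summary` tibble from [run_sse()] or
#'   [run_sse_grid()].
#' @param metric `"rbias"` or `"rrmse"`.
#' @param terms Which parameter group to show: `"structural"` (the four
#'   fixed effects), `"bsv"` (omega-squared terms), `"rv"` (sigma) or
#'   `"all"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sse_summary <- function(object, metric = c("rbias", "rrmse"),
                                 terms = "all", ...) {
  metric <- match.arg(metric)
  df <- tibble::as_tibble(object)
  df <- switch(terms,
    structural = dplyr::filter(df, .data$scale == "natural"),
    bsv = dplyr::filter(df, .data$scale == "variance"),
    rv = dplyr::filter(df, .data$scale == "sd"),
    all = df
  )
  df$term <- factor(df$term, levels = unique(df$term))
  lab <- if (metric == "rbias") "rBias (%)" else "rRMSE (%)"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$term,
                                        y = .data[[metric]],
                                        fill = .data$dataset_type)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = lab, fill = "dataset") +
    ggplot2::theme_minimal()
  if (length(unique(df$n_subjects)) > 1 || length(unique(df$CL)) > 1) {
    p <- p + ggplot2::facet_grid(
      rows = ggplot2::vars(.data$CL),
      cols = ggplot2::vars(.data$n_subjects),
      labeller = ggplot2::label_both
    )
  }
  p
}

#' Loading-dose illustration
#'
#' Concentration-time profiles under a 500 mg q12h maintenance regimen
#' preceded by different first (loading) doses, illustrating how a loading
#' dose moves the profile toward its steady-state band before the fourth
#' to fifth dose. This is a qualitative display, not a study result.
#'
#' @param params Structural parameters; defaults to the reference
#'   vancomycin model.
#' @param loading_doses First-dose amounts (mg) to compare.
#' @param maintenance Maintenance dose amount (mg).
#' @param interval Dosing interval (h).
#' @param duration Infusion duration (h).
#' @param n_doses Total number of doses.
#' @return A ggplot object.
#' @export
plot_loading_dose <- function(params = vanco_params(),
                              loading_doses = c(500, 1000, 1500),
                              maintenance = 500, interval = 12,
                              duration = 1, n_doses = 6) {
  times <- seq(0, interval * n_doses, by = 0.1)
  profiles <- purrr::map(loading_doses, function(ld) {
    reg <- regimen(purrr::map(seq_len(n_doses), function(d) {
      dose_event((d - 1) * interval, if (d == 1) ld else maintenance,
                 duration)
    }))
    conc_profile(params, reg, times) |>
      dplyr::mutate(loading = sprintf("%d mg loading", ld))
  }) |> dplyr::bind_rows()
  css <- steady_state_infusion_conc(params, maintenance / interval)
  ggplot2::ggplot(profiles, ggplot2::aes(x = .data$time, y = .data$conc,
                                         colour = .data$loading)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = css, linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(x = "time (h)", y = "concentration (mg/L)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
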