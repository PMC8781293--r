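# ggplot2 displays for pools and benchmark results.

#' Energy spectrum of a minima pool
#'
#' Stage-1 energies in ascending order; after rescoring, stage-2 energies
#' against their ranks are overlaid on a second panel.
#'
#' @param object A `qd_pool`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qd_pool
#' @export
autoplot.qd_pool <- function(object, ...) {
  tb <- as_tibble(object)
  df <- dplyr::bind_rows(
    tibble(index = seq_len(nrow(tb)), energy = tb$e_stage1,
           stage = "stage 1 (search field)"),
    if (!all(is.na(tb$e_stage2))) {
      tb2 <- tb[!is.na(tb$rank), ]
      tibble(index = tb2$rank[order(tb2$rank)],
             energy = sort(tb2$e_stage2),
             stage = "stage 2 (rescored)")
    }
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$energy)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~stage, scales = "free_y") +
    ggplot2::labs(x = "minimum index (ascending energy)",
                  y = "energy (kcal/mol)",
                  title = "Spectrum of unique low-energy minima") +
    ggplot2::theme_minimal()
}

#' Measured vs calculated binding enthalpy
#'
#' Scatter of measured against calculated binding enthalpies for each
#' stage-2 method, with the least-squares line and the Pearson correlation
#' in the panel label.
#'
#' @param table3 The enthalpy tibble from [load_paper_tables()] (columns
#'   `dh_exp`, `dh_pm6`, `dh_pm7`).
#' @return A ggplot object.
#' @export
plot_enthalpy_correlation <- function(table3) {
  long <- tidyr::pivot_longer(table3, cols = c("dh_pm6", "dh_pm7"),
                              names_to = "method", values_to = "dh_calc")
  long <- dplyr::filter(long, !is.na(.data$dh_calc))
  labs <- vapply(split(long, long$method), function(d) {
    sprintf("%s (R = %.2f)",
            ifelse(d$method[1] == "dh_pm7", "PM7+COSMO", "PM6-D3H4X+COSMO"),
            pearson_r(d$dh_exp, d$dh_calc))
  }, character(1))
  long$panel <- labs[long$method]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dh_calc, y = .data$dh_exp)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = "calculated binding enthalpy (kcal/mol)",
                  y = "measured binding enthalpy (kcal/mol)") +
    ggplot2::theme_minimal()
}
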