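# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Energy-vs-accuracy landscape of a docking pool
#'
#' With a reference complex, plots each pooled model's interface RMSD
#' against its total energy, coloured by sampling temperature — the classic
#' view for spotting near-native energy minima. Without a reference, plots
#' the energy trace along the simulation.
#'
#' @param pool a `dock_pool` tibble.
#' @param reference optional reference [cg_system()].
#' @return A ggplot object.
#' @export
plot_energy_landscape <- function(pool, reference = NULL) {
  if (!is.null(reference)) {
    ir <- vapply(seq_len(nrow(pool)), function(r)
      irmsd(pool_system(pool, r), reference), 0)
    df <- tibble::tibble(irmsd = ir, energy = pool$e_total,
                         temperature = pool$temp)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$irmsd, y = .data$energy,
                                     colour = .data$temperature)) +
      ggplot2::geom_point(alpha = 0.6, size = 0.8) +
      ggplot2::scale_colour_viridis_c(option = "plasma") +
      ggplot2::labs(x = "interface RMSD (Å)", y = "energy (kT)",
                    colour = "T") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(pool, ggplot2::aes(x = .data$sweep, y = .data$e_total,
                                       colour = .data$temp,
                                       group = .data$replica)) +
      ggplot2::geom_line(alpha = 0.7, linewidth = 0.3) +
      ggplot2::scale_colour_viridis_c(option = "plasma") +
      ggplot2::labs(x = "sweep", y = "energy (kT)", colour = "T") +
      ggplot2::theme_minimal()
  }
}

#' @exportS3Method ggplot2::autoplot
autoplot.dock_pool <- function(object, reference = NULL, ...) {
  plot_energy_landscape(object, reference)
}

#' Cluster density ranking plot
#'
#' @param object a `dock_clusters` selection from [rank_and_select()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dock_clusters <- function(object, ...) {
  df <- tidy(object)
  df$density[!is.finite(df$density)] <- max(df$density[is.finite(df$density)],
                                            1) * 1.2
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$rank), y = .data$density,
                                   fill = .data$size)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "cluster rank", y = "density (members / mean Jaccard)",
                  fill = "size") +
    ggplot2::theme_minimal()
}

#' Per-residue fluctuation profile plot
#'
#' @param profile tibble from [rmsf()] / [pool_rmsf()].
#' @return A ggplot object.
#' @export
plot_rmsf <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$residue, y = .data$rmsf)) +
    ggplot2::geom_line(colour = "#33557a") +
    ggplot2::labs(x = "residue", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}
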