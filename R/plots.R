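#' Plot a damage profile
#'
#' Conventional misincorporation plot: C->T from the 5' end in red, G->A
#' from the 3' end in blue, per-position noise (mean of the remaining
#' substitution types) in grey.  Requires ggplot2.
#'
#' @param profile a `damage_profile` from [build_profile()].
#' @return a ggplot object.
#' @export
plot_damage_profile <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  stopifnot(profile$status == "ok")
  s5 <- profile_signal(profile, "5p"); s5$channel <- "5' C>T"
  s3 <- profile_signal(profile, "3p"); s3$channel <- "3' G>A"
  nz <- profile_noise(profile)
  nz <- data.frame(position = nz$position,
                   frequency = nz$noise,
                   channel = paste0(nz$end, " noise"),
                   stringsAsFactors = FALSE)
  d <- rbind(s5, s3, nz)
  ggplot2::ggplot(d, ggplot2::aes(x = position, y = frequency,
                                  colour = channel)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c("5' C>T" = "red",
                                            "3' G>A" = "blue",
                                            "5p noise" = "grey60",
                                            "3p noise" = "grey80")) +
    ggplot2::labs(x = "position from read end (nt)",
                  y = "mismatch frequency",
                  title = paste0(profile$taxon_id, " (",
                                 profile$n_reads, " reads)")) +
    ggplot2::theme_minimal()
}

#' Plot percent damage against depth
#'
#' @param damage_stats the `damage_stats` table of [run_pipeline()].
#' @return a ggplot object.
#' @export
plot_damage_depth <- function(damage_stats) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- damage_stats[damage_stats$ok, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = depth_cmbsf,
                                  y = pct_damage,
                                  colour = dataset_label)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", se = FALSE, formula = y ~ x) +
    ggplot2::labs(x = "depth (cmbsf)", y = "% eukaryote sedaDNA damage") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("position", "frequency", "channel",
                         "depth_cmbsf", "pct_damage", "dataset_label"))
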