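#' Heat grid of E[p*] over missingness combinations
#'
#' One annotated tile per (pm0, pm1) combination, faceted by algorithm —
#' the standard display for how an allocation rule's expected allocation
#' proportion responds to differential missingness.
#'
#' @param results data frame from [run_experiment()] over a
#'   \code{"full_grid_36"} missingness grid.
#' @return a ggplot object.
#' @export
plot_heatgrid <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = factor(pm1), y = factor(pm0),
                               fill = mean_pstar)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", mean_pstar)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, low = "#2166ac",
                                  mid = "white", high = "#b2182b",
                                  limits = c(0, 1), name = "E[p*]") +
    ggplot2::facet_wrap(~algorithm) +
    ggplot2::labs(x = "missingness probability, experimental arm",
                  y = "missingness probability, control arm")
}

#' Line panels of E[p*] against the missingness rate
#'
#' Per scenario x algorithm panels with the three-pattern convention: grey
#' for equal missingness in both arms, blue for control-arm-only, red for
#' experimental-arm-only missingness. When the results carry both imputation
#' settings, solid lines show results without imputation and dashed lines
#' with mean imputation.
#'
#' @param results data frame from [run_experiment()] over a
#'   \code{"paper_16"} missingness grid.
#' @return a ggplot object.
#' @export
plot_missingness_lines <- function(results) {
  results$rate <- pmax(results$pm0, results$pm1)
  zero <- results[results$rate == 0, ]
  expand_zero <- function(pat) { z <- zero; z$pattern <- pat; z }
  results <- rbind(results[results$rate > 0, ],
                   expand_zero("equal"), expand_zero("control"),
                   expand_zero("experimental"))
  p <- ggplot2::ggplot(results,
                       ggplot2::aes(x = rate, y = mean_pstar,
                                    colour = pattern))
  if (length(unique(results$imputation)) > 1L) {
    p <- p + ggplot2::geom_line(ggplot2::aes(linetype = imputation)) +
      ggplot2::scale_linetype_manual(
        values = c(off = "solid", mean = "dashed"), name = "imputation")
  } else {
    p <- p + ggplot2::geom_line()
  }
  p +
    ggplot2::scale_colour_manual(values = c(
      equal = "grey40", control = "#2166ac", experimental = "#b2182b"),
      name = "missingness") +
    ggplot2::facet_grid(scenario ~ algorithm) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "missingness probability", y = "E[p*]")
}

#' Trajectory of one replication's allocation values
#'
#' Per-patient allocation probabilities (randomized rules) or index values
#' (deterministic and semi-randomized rules) of both arms over a single
#' simulated trial.
#'
#' @param record a \code{"replication_record"} from [run_trial()].
#' @return a ggplot object.
#' @export
plot_trace <- function(record) {
  stopifnot(inherits(record, "replication_record"))
  n <- length(record$assignments)
  df <- data.frame(
    patient = rep(seq_len(n), 2L),
    value = c(record$trajectory[, 1L], record$trajectory[, 2L]),
    arm = rep(c("control (k = 0)", "experimental (k = 1)"), each = n))
  randomized <- record$config$algorithm %in% c("FR", "TTS", "RTS", "RPW")
  ggplot2::ggplot(df, ggplot2::aes(x = patient, y = value, colour = arm)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c("#2166ac", "#b2182b"),
                                 name = NULL) +
    ggplot2::labs(x = "patient", title = record$config$algorithm,
                  y = if (randomized) "allocation probability"
                      else "index value")
}

utils::globalVariables(c("pm0", "pm1", "mean_pstar", "pattern", "rate",
                         "imputation", "algorithm", "patient", "value",
                         "arm"))
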