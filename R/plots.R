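# Figures. Default palette follows the conventional legend of F(H)
# overlays: 0 % green, 25 % light blue, 50 % pink, 75 % red, 99 % blue.

fh_palette <- c("0" = "#2ca02c", "0.25" = "#56b4e9", "0.5" = "#e377c2",
                "0.75" = "#d62728", "0.99" = "#1f4e9e")

#' Plot log D(H) curves for a set of ligands
#'
#' @param db A [constants_db()].
#' @param ligands Ligand ids (default: all).
#' @param ph_grid pH grid for the curves.
#' @return A ggplot object.
#' @export
plot_log_d <- function(db, ligands = NULL, ph_grid = seq(0, 14, by = 0.05)) {
  if (is.null(ligands)) ligands <- names(db$ligands)
  df <- do.call(rbind, lapply(ligands, function(l) {
    data.frame(ligand = l, ph = ph_grid, log_d = log_d(db_ligand(db, l), ph_grid),
               stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = ph, y = log_d,
                                   colour = ligand)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pH", y = "log D(H)", colour = "ligand") +
    ggplot2::theme_minimal()
}

#' Plot F(H) screening curves for one ligand
#'
#' Overlays the F(H) curve for each target fraction (0 % = bare log D) with
#' horizontal lines at log beta_ML for the requested metals; the abscissa
#' of each crossing is the pH at which that metal reaches that fraction.
#'
#' @param db A [constants_db()].
#' @param ligand_id Ligand to plot.
#' @param scn A [scenario()].
#' @param metals Metal ids whose formation-constant lines to draw (default:
#'   all with data for this ligand).
#' @param ph_grid pH grid.
#' @return A ggplot object.
#' @export
plot_fh_curves <- function(db, ligand_id, scn = scenario(), metals = NULL,
                           ph_grid = seq(0, 14, by = 0.05)) {
  lig <- db_ligand(db, ligand_id)
  fs <- c(0, scn$target_fractions)
  df <- do.call(rbind, lapply(fs, function(f) {
    data.frame(f = f, ph = ph_grid,
               fh = log_f_curve(lig, f, scn$m_total, scn$ratio, ph_grid))
  }))
  df$f <- factor(df$f)
  if (is.null(metals)) {
    metals <- db$complexes$metal_id[db$complexes$ligand_id == ligand_id]
  }
  lines <- do.call(rbind, lapply(metals, function(m) {
    cx <- db_complex(db, m, ligand_id)
    if (is.null(cx)) return(NULL)
    data.frame(metal = m, log_beta_ml = cx$log_beta_ml, stringsAsFactors = FALSE)
  }))
  pal <- fh_palette[levels(df$f)]
  pal[is.na(pal)] <- "#555555"
  names(pal) <- levels(df$f)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = ph, y = fh,
                                        colour = f)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = pal) +
    ggplot2::labs(x = "pH", y = "F(H)", colour = "fraction f",
                  title = sprintf("F(H) curves for %s (M0 = %g M, R = %g)",
                                  ligand_id, scn$m_total, scn$ratio)) +
    ggplot2::theme_minimal()
  if (!is.null(lines) && nrow(lines)) {
    p <- p +
      ggplot2::geom_hline(data = lines,
                          ggplot2::aes(yintercept = log_beta_ml),
                          colour = "grey40", linewidth = 0.3) +
      ggplot2::geom_text(data = lines,
                         ggplot2::aes(x = max(ph_grid), y = log_beta_ml,
                                      label = metal),
                         inherit.aes = FALSE, hjust = 1, vjust = -0.3, size = 3)
  }
  p
}

#' Plot a speciation (distribution) diagram
#'
#' Metal-basis fractions of every metal-containing species against pH, plus
#' the ML share of the ligand if requested.
#'
#' @param result A [speciate()] result.
#' @param basis `"metal"` or `"ligand"`: which total the fractions refer to.
#' @return A ggplot object.
#' @export
plot_speciation <- function(result, basis = c("metal", "ligand")) {
  basis <- match.arg(basis)
  df <- as.data.frame(result)
  df$fraction <- if (basis == "metal") df$fraction_metal_basis else
    df$fraction_ligand_basis
  keep <- vapply(split(df$fraction, df$species), function(x) any(x > 0), TRUE)
  df <- df[df$species %in% names(keep)[keep], ]
  sys <- result$system
  ggplot2::ggplot(df, ggplot2::aes(x = ph, y = 100 * fraction,
                                   colour = species)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "pH", y = sprintf("%% of total %s", basis), colour = "species",
      title = sprintf("%s-%s speciation (M0 = %g M, L0 = %g M)",
                      sys$metal$metal_id, sys$ligand$ligand_id,
                      sys$m_total, sys$l_total)
    ) +
    ggplot2::theme_minimal()
}
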