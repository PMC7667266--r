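# Decision-level outputs: pH windows of complexation per metal-ligand pair,
# screening matrices across a ligand panel, ligand ranking, and the
# soil-contamination arithmetic that turns mg/kg levels into scenarios.

#' pH window of complexation for one metal-ligand pair
#'
#' Locates, for every target fraction of the scenario, the pH at which that
#' fraction of the metal is complexed (see [ph_for_fraction()]), and formats
#' the 25-99 % interval the way screening tables print it. Values above the
#' display cap are reported as above-cap (`"> 10.0"` by default) and
#' crossings below pH 0 as `"<0"`; the raw numeric content stays available
#' in the `boundaries` field.
#'
#' @param db A [constants_db()].
#' @param metal_id,ligand_id Pair to evaluate; if the database has no
#'   formation constant for the pair the window has status
#'   `"missing_pair"` (screening tables leave the cell blank).
#' @param scn A [scenario()].
#' @param cap,floor Display cap and floor for formatted output (pH units).
#' @return An object of class `complexation_window`: list with `metal_id`,
#'   `ligand_id`, `status` (`"ok"` or `"missing_pair"`), `boundaries` (data
#'   frame `f`, `ph`, `status` — `ph` rounded to 2 decimals where numeric)
#'   and `formatted_range` (text such as `"2.79-5.05"`).
#' @examples
#' db <- builtin_table4()
#' complexation_window(db, "Cd", "NTA", scenario())
#' @export
complexation_window <- function(db, metal_id, ligand_id, scn = scenario(),
                                cap = 10, floor = 0) {
  cx <- db_complex(db, metal_id, ligand_id)
  if (is.null(cx)) {
    return(structure(
      list(metal_id = metal_id, ligand_id = ligand_id, status = "missing_pair",
           boundaries = NULL, formatted_range = ""),
      class = "complexation_window"
    ))
  }
  lig <- db_ligand(db, ligand_id)
  f <- scn$target_fractions
  res <- lapply(f, function(fi) {
    ph_for_fraction(cx$log_beta_ml, lig, fi, scn$m_total, scn$ratio)
  })
  ph <- vapply(res, `[[`, numeric(1), "ph")
  status <- vapply(res, `[[`, character(1), "status")
  # typed display outcomes relative to cap/floor
  status[status == "ok" & ph > cap] <- "above_cap"
  status[status == "ok" & ph < floor] <- "below_range"
  status[status == "above_range"] <- "above_cap"
  ph[status != "ok"] <- NA_real_
  bounds <- data.frame(f = f, ph = round(ph, 2), status = status,
                       stringsAsFactors = FALSE)
  structure(
    list(metal_id = metal_id, ligand_id = ligand_id, status = "ok",
         boundaries = bounds,
         formatted_range = format_window_range(bounds, cap = cap)),
    class = "complexation_window"
  )
}

format_boundary <- function(ph, status, cap) {
  switch(status,
    ok = sprintf("%.2f", ph),
    above_cap = sprintf("> %.1f", cap),
    below_range = "<0",
    unattainable = "n.a.",
    ""
  )
}

format_window_range <- function(bounds, cap = 10) {
  lo <- bounds[1, ]
  hi <- bounds[nrow(bounds), ]
  if (lo$status == "unattainable" && hi$status == "unattainable") return("n.a.")
  paste0(format_boundary(lo$ph, lo$status, cap), "-",
         format_boundary(hi$ph, hi$status, cap))
}

#' @export
print.complexation_window <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("<window %s-%s: no formation constant>\n", x$metal_id, x$ligand_id))
    return(invisible(x))
  }
  cat(sprintf("<window %s-%s: %s>\n", x$metal_id, x$ligand_id, x$formatted_range))
  print(x$boundaries, row.names = FALSE)
  invisible(x)
}

#' Screen a panel of ligands against a panel of metals
#'
#' Computes the complexation window of every requested pair and assembles
#' the screening matrix: rows are metals ordered by the 25 % boundary of a
#' reference ligand (strongest-bound metal first, the order screening
#' tables use), columns are ligands. Pairs without a formation constant are
#' blank. When the underlying constants were determined in different media
#' (ionic strength / temperature) a note is emitted: the comparison then
#' mixes media without correction.
#'
#' @param db A [constants_db()].
#' @param metals,ligands Character vectors of ids; default: everything in
#'   the database (metals with at least one complex).
#' @param scn A [scenario()].
#' @param reference_ligand Ligand whose 25 % boundary orders the rows
#'   (default: first of `ligands`). Metals the reference does not bind sort
#'   last.
#' @param cap,floor Display cap/floor passed to [complexation_window()].
#' @return An object of class `screen_result`: list with `windows` (list of
#'   [complexation_window()]), `table` (long data frame `metal`, `ligand`,
#'   `f`, `ph`, `status`), `metals` (row order), `ligands`, `scenario`.
#' @examples
#' db <- builtin_table4()
#' scr <- screen(db, ligands = c("NTA", "EDTA"))
#' format_screen_text(scr)
#' @export
screen <- function(db, metals = NULL, ligands = NULL, scn = scenario(),
                   reference_ligand = NULL, cap = 10, floor = 0) {
  if (is.null(ligands)) ligands <- names(db$ligands)
  if (is.null(metals)) metals <- intersect(names(db$metals), db$complexes$metal_id)
  if (!length(metals) || !length(ligands)) {
    return(structure(
      list(windows = list(),
           table = data.frame(metal = character(), ligand = character(),
                              f = numeric(), ph = numeric(), status = character(),
                              stringsAsFactors = FALSE),
           metals = metals, ligands = ligands, scenario = scn),
      class = "screen_result"
    ))
  }
  if (is.null(reference_ligand)) reference_ligand <- ligands[[1]]

  windows <- list()
  rows <- list()
  media <- character()
  for (m in metals) {
    for (l in ligands) {
      w <- complexation_window(db, m, l, scn, cap = cap, floor = floor)
      windows[[paste(m, l, sep = "-")]] <- w
      if (w$status == "ok") {
        cx <- db_complex(db, m, l)
        lg <- db_ligand(db, l)
        media <- c(media,
                   sprintf("I=%s,T=%s", format(cx$ionic_strength), format(cx$temperature)),
                   sprintf("I=%s,T=%s", format(lg$ionic_strength), format(lg$temperature)))
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(metal = m, ligand = l, stringsAsFactors = FALSE),
          w$boundaries
        )
      }
    }
  }
  if (length(unique(media)) > 1L) {
    message("note: screen compares constants determined in different media ",
            "(ionic strength/temperature); no correction is applied")
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(metal = character(), ligand = character(), f = numeric(),
               ph = numeric(), status = character(), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  names(tab)[names(tab) == "f"] <- "f"

  key <- vapply(metals, function(m) {
    w <- windows[[paste(m, reference_ligand, sep = "-")]]
    if (is.null(w) || w$status != "ok") return(Inf)
    b <- w$boundaries[1, ]
    if (b$status == "ok") b$ph
    else if (b$status == "below_range") -Inf
    else Inf
  }, numeric(1))
  metals <- metals[order(key)]

  structure(
    list(windows = windows, table = tab, metals = metals, ligands = ligands,
         scenario = scn),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(format_screen_text(x), sep = "\n")
  invisible(x)
}

#' Render a screen as an aligned text table
#'
#' One row per metal (strongest-bound first), one column per ligand, each
#' cell the formatted 25-99 % pH range.
#'
#' @param scr A [screen()] result.
#' @return Character vector of lines.
#' @export
format_screen_text <- function(scr) {
  cells <- sapply(scr$ligands, function(l) {
    vapply(scr$metals, function(m) {
      w <- scr$windows[[paste(m, l, sep = "-")]]
      if (is.null(w) || w$status != "ok") "" else w$formatted_range
    }, character(1))
  })
  cells <- matrix(cells, nrow = length(scr$metals),
                  dimnames = list(scr$metals, scr$ligands))
  body <- cbind(metal = scr$metals, cells)
  widths <- pmax(nchar(colnames(body)), apply(nchar(body), 2, max))
  fmt_row <- function(row) {
    paste(mapply(formatC, row, width = widths, flag = "-"), collapse = "  ")
  }
  c(fmt_row(colnames(body)), apply(body, 1, fmt_row), use.names = FALSE)
}

#' Write screen windows as tidy CSV
#'
#' Columns `metal, ligand, f, ph, status`, one row per boundary.
#'
#' @param scr A [screen()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_screen_csv <- function(scr, path) {
  utils::write.csv(scr$table, path, row.names = FALSE)
  invisible(path)
}

#' Rank ligands by chelating strength for one metal
#'
#' Ranking key is the 25 % boundary (the lower the pH at which a quarter of
#' the metal is already complexed, the stronger the chelator), with the
#' window width 25-99 % as tie-break (narrower wins). Ligands that cannot
#' reach 25 % sort last.
#'
#' @param scr A [screen()] result.
#' @param metal_id Metal to rank for.
#' @return Data frame `ligand`, `ph25`, `width`, ordered best first.
#' @export
rank_ligands <- function(scr, metal_id) {
  rows <- lapply(scr$ligands, function(l) {
    w <- scr$windows[[paste(metal_id, l, sep = "-")]]
    if (is.null(w) || w$status != "ok") return(NULL)
    b <- w$boundaries
    ph25 <- if (b$status[1] == "ok") b$ph[1]
      else if (b$status[1] == "below_range") -Inf else Inf
    phmax <- if (b$status[nrow(b)] == "ok") b$ph[nrow(b)] else Inf
    data.frame(ligand = l, ph25 = ph25, width = phmax - ph25,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(ligand = character(), ph25 = numeric(), width = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(out$ph25, out$width), ]
  rownames(out) <- NULL
  out
}

# ---- soil scenarios --------------------------------------------------------

#' Convert a soil contamination level to suspension molarity
#'
#' A level of `level` mg metal per kg soil, suspended at `suspension` kg of
#' soil per litre of washing solution, corresponds to
#' level * suspension / atomic_weight mmol/L of metal (assuming complete
#' transfer to solution).
#'
#' @param level Contamination level in mg/kg (>= 0).
#' @param atomic_weight Atomic weight of the metal in g/mol.
#' @param suspension kg of soil per L of solution (default 1).
#' @return Concentration in mmol/L.
#' @examples
#' soil_to_molar(530, 200.59)  # Hg at its intervention value: ~2.6 mM
#' @export
soil_to_molar <- function(level, atomic_weight, suspension = 1) {
  if (any(level < 0)) stop("level must be >= 0", call. = FALSE)
  if (any(!is.finite(atomic_weight) | atomic_weight <= 0)) {
    stop("atomic_weight must be > 0", call. = FALSE)
  }
  if (suspension <= 0) stop("suspension must be > 0", call. = FALSE)
  level * suspension / atomic_weight
}

#' Soil-washing scenario for one metal
#'
#' Bundles a contamination level with the suspension density and chelator
#' dosing ratio; convert to a screening [scenario()] with
#' [scenario_from_soil()].
#'
#' @param metal A [metal_record()] (source of the atomic weight).
#' @param level_mg_per_kg Contamination level in mg metal per kg soil.
#' @param ratio Chosen ligand-to-metal ratio R.
#' @param suspension kg soil per L of washing solution (default 1).
#' @return An object of class `soil_scenario` with the derived molarity in
#'   `molar_mm` (mmol/L).
#' @export
soil_scenario <- function(metal, level_mg_per_kg, ratio = 50, suspension = 1) {
  if (level_mg_per_kg <= 0) stop("level_mg_per_kg must be > 0", call. = FALSE)
  mm <- soil_to_molar(level_mg_per_kg, metal$atomic_weight, suspension)
  structure(
    list(metal_id = metal$metal_id, level_mg_per_kg = level_mg_per_kg,
         suspension = suspension, molar_mm = mm, ratio = ratio),
    class = "soil_scenario"
  )
}

#' @export
print.soil_scenario <- function(x, ...) {
  cat(sprintf("<soil scenario %s: %g mg/kg at %g kg/L -> %.1f mM, R = %g>\n",
              x$metal_id, x$level_mg_per_kg, x$suspension, x$molar_mm, x$ratio))
  invisible(x)
}

#' Turn a soil scenario into a screening scenario
#'
#' The metal molarity of the suspension becomes M0 (mol/L) and the dosing
#' ratio is carried over; target fractions are the standard 25/50/75/99 %.
#'
#' @param soil A [soil_scenario()].
#' @param target_fractions Passed to [scenario()].
#' @return A [scenario()].
#' @export
scenario_from_soil <- function(soil, target_fractions = c(0.25, 0.50, 0.75, 0.99)) {
  scenario(m_total = soil$molar_mm / 1000, ratio = soil$ratio,
           target_fractions = target_fractions)
}

#' Regulatory soil guideline levels for common metal pollutants
#'
#' Intervention values (contamination beyond which soil quality is severely
#' compromised) and target values (levels for full restoration of soil
#' functionality) in mg metal per kg soil for five priority metals, with
#' atomic weights.
#'
#' @return Data frame `metal_id`, `atomic_weight`, `intervention_mg_kg`,
#'   `target_mg_kg`.
#' @export
soil_guidelines <- function() {
  data.frame(
    metal_id = c("Hg", "Cd", "Pb", "Cu", "Ni"),
    atomic_weight = c(200.59, 112.41, 207.20, 63.55, 58.69),
    intervention_mg_kg = c(530, 380, 210, 10, 720),
    target_mg_kg = c(85, 100, 35, 0.3, 140),
    stringsAsFactors = FALSE
  )
}
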