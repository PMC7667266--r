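# pH-stepped speciation of one metal + one ligand.
#
# Species set is deliberately minimal: M, L, LH_1..LH_n, ML, and (optionally)
# mononuclear M(OH)_k. No protonated or hydroxo ternary complexes, no
# polynuclear species, no solids: a 1:1 ML stoichiometry plus side reactions.

#' Metal side-reaction coefficient for hydroxide competition
#'
#' alpha_M(OH) = 1 + sum_k beta_OHk \[OH-\]^k
#'             = 1 + sum_k 10^(log beta_OHk + k (pH - pKw)),
#' the factor by which hydroxide formation reduces the free metal available
#' for complexation. Metals without hydrolysis constants have coefficient 1
#' at every pH; the coefficient is non-decreasing in pH.
#'
#' @param metal A [metal_record()].
#' @param ph pH values (vectorised).
#' @param p_kw Ionic product of water as -log10 Kw (default 14.00).
#' @return The dimensionless coefficient, >= 1, same length as `ph`.
#' @export
metal_side_coefficient <- function(metal, ph, p_kw = 14) {
  h <- metal$hydrolysis
  if (is.null(h) || !nrow(h)) return(rep(1, length(ph)))
  vapply(ph, function(p) {
    10^logsum10(c(0, h$log_beta_oh + h$k * (p - p_kw)))
  }, numeric(1))
}

#' Define a metal-ligand speciation system
#'
#' @param metal A [metal_record()].
#' @param ligand A [ligand_record()].
#' @param log_beta_ml Formation constant of ML (decimal log).
#' @param m_total,l_total Total metal and ligand concentrations in mol/L
#'   (either may be 0 to inspect one component alone).
#' @param ph_grid Strictly ascending pH grid; the default 0..14 in steps of
#'   0.01 matches the resolution at which distribution diagrams are usually
#'   drawn.
#' @param include_hydrolysis If `TRUE`, the metal's mononuclear hydroxide
#'   species compete with complexation; requires hydrolysis constants on
#'   `metal`.
#' @param p_kw -log10 of the ionic product of water (default 14.00).
#' @return An object of class `speciation_system`.
#' @export
speciation_system <- function(metal, ligand, log_beta_ml, m_total, l_total,
                              ph_grid = seq(0, 14, by = 0.01),
                              include_hydrolysis = FALSE, p_kw = 14) {
  validate_ligand(ligand)
  validate_metal(metal)
  if (m_total < 0 || l_total < 0) stop("totals must be >= 0", call. = FALSE)
  if (length(ph_grid) < 1L || any(!is.finite(ph_grid)) || any(diff(ph_grid) <= 0)) {
    stop("ph_grid must be finite and strictly ascending", call. = FALSE)
  }
  if (include_hydrolysis && is.null(metal$hydrolysis)) {
    stop(sprintf("metal '%s' carries no hydrolysis constants; cannot enable hydrolysis",
                 metal$metal_id), call. = FALSE)
  }
  structure(
    list(metal = metal, ligand = ligand, log_beta_ml = as.numeric(log_beta_ml),
         m_total = m_total, l_total = l_total, ph_grid = as.numeric(ph_grid),
         include_hydrolysis = isTRUE(include_hydrolysis), p_kw = p_kw),
    class = "speciation_system"
  )
}

#' Compute the species distribution over the pH grid
#'
#' At each grid point the conditional constant
#' beta_cond = 10^log_beta_ml / (D(H) * alpha_M(OH)) folds both side
#' reactions into the 1:1 equilibrium, whose mass balances reduce to one
#' quadratic in \[ML\]; the smaller root is taken in a cancellation-safe
#' form, then free \[M\] and \[L\] are back-substituted and the ligand is
#' distributed over its protonated forms (and the metal over its hydroxo
#' forms) by the respective polynomials. Both mass balances are conserved
#' to floating-point accuracy at every grid point.
#'
#' @param system A [speciation_system()].
#' @return An object of class `speciation_result`: a list with
#'   * `system` - the input;
#'   * `species` - character vector of species names
#'     (`"M"`, `"ML"`, `"L"`, `"LH1"`.., `"MOH1"`..);
#'   * `conc` - matrix (grid points x species) of concentrations in mol/L;
#'   * `fraction_metal` - metal-basis fractions (metal-containing species
#'     divided by M0; zero columns for pure-ligand species);
#'   * `fraction_ligand` - ligand-basis fractions, analogously.
#'   Use [as.data.frame.speciation_result()] for a tidy long table.
#' @examples
#' db <- builtin_table4()
#' sys <- speciation_system(db_metal(db, "Cd"), db_ligand(db, "NTA"),
#'                          log_beta_ml = 9.8, m_total = 2e-5, l_total = 1e-3)
#' res <- speciate(sys)
#' res$fraction_metal[res$system$ph_grid == 5.05, "ML"]  # ~0.99
#' @export
speciate <- function(system) {
  stopifnot(inherits(system, "speciation_system"))
  lig <- system$ligand
  n <- lig$n_protonation
  ph <- system$ph_grid
  m0 <- system$m_total
  l0 <- system$l_total

  ld <- log_d(lig, ph)                       # log10 D(H)
  am <- if (system$include_hydrolysis) {
    metal_side_coefficient(system$metal, ph, system$p_kw)
  } else {
    rep(1, length(ph))
  }

  # conditional 1:1 equilibrium in total uncomplexed components:
  # x = [ML]; x^2 - (L0 + M0 + 1/beta_cond) x + L0 M0 = 0, smaller root
  log_beta_cond <- system$log_beta_ml - ld - log10(am)
  x <- if (m0 == 0 || l0 == 0) {
    rep(0, length(ph))
  } else {
    vapply(log_beta_cond, function(lb) {
      stable_smaller_root(l0 + m0 + 10^(-lb), l0 * m0)
    }, numeric(1))
  }

  m_free <- (m0 - x) / am                    # free aqua ion
  l_free <- (l0 - x) / 10^ld                 # fully deprotonated ligand

  species <- c("M", "ML", "L", paste0("LH", seq_len(n)))
  hyd <- system$metal$hydrolysis
  use_h <- system$include_hydrolysis && !is.null(hyd) && nrow(hyd) > 0
  if (use_h) species <- c(species, paste0("MOH", hyd$k))

  conc <- matrix(0, nrow = length(ph), ncol = length(species),
                 dimnames = list(NULL, species))
  conc[, "M"] <- m_free
  conc[, "ML"] <- x
  conc[, "L"] <- l_free
  lb <- lig$log_beta_cumulative
  for (j in seq_len(n)) {
    conc[, paste0("LH", j)] <- l_free * 10^(lb[j] - j * ph)
  }
  if (use_h) {
    for (i in seq_len(nrow(hyd))) {
      conc[, paste0("MOH", hyd$k[i])] <-
        m_free * 10^(hyd$log_beta_oh[i] + hyd$k[i] * (ph - system$p_kw))
    }
  }

  metal_species <- c("M", "ML", if (use_h) paste0("MOH", hyd$k))
  ligand_species <- c("L", paste0("LH", seq_len(n)), "ML")
  fm <- conc * 0
  fl <- conc * 0
  if (m0 > 0) fm[, metal_species] <- conc[, metal_species, drop = FALSE] / m0
  if (l0 > 0) fl[, ligand_species] <- conc[, ligand_species, drop = FALSE] / l0

  structure(
    list(system = system, species = species, conc = conc,
         fraction_metal = fm, fraction_ligand = fl),
    class = "speciation_result"
  )
}

#' @export
print.speciation_result <- function(x, ...) {
  s <- x$system
  cat(sprintf(
    "<speciation %s-%s: M0 = %g, L0 = %g mol/L, %d pH points, %d species%s>\n",
    s$metal$metal_id, s$ligand$ligand_id, s$m_total, s$l_total,
    length(s$ph_grid), length(x$species),
    if (s$include_hydrolysis) ", hydrolysis on" else ""
  ))
  invisible(x)
}

#' Tidy long-format view of a speciation result
#'
#' @param x A `speciation_result`.
#' @param row.names,optional,... Ignored (standard generic signature).
#' @return Data frame with columns `ph`, `species`, `concentration`,
#'   `fraction_metal_basis`, `fraction_ligand_basis`.
#' @export
as.data.frame.speciation_result <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  ph <- x$system$ph_grid
  ns <- length(x$species)
  data.frame(
    ph = rep(ph, times = ns),
    species = rep(x$species, each = length(ph)),
    concentration = as.vector(x$conc),
    fraction_metal_basis = as.vector(x$fraction_metal),
    fraction_ligand_basis = as.vector(x$fraction_ligand),
    stringsAsFactors = FALSE
  )
}

#' Write a speciation result as tidy CSV
#'
#' @param result A `speciation_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_speciation_csv <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}

#' Mass-balance residuals of a speciation result
#'
#' Diagnostic used by the validation suite: the largest relative error of
#' the metal and ligand balances over the grid.
#'
#' @param result A `speciation_result`.
#' @return Named numeric vector `c(metal = ..., ligand = ...)` (`NA` for a
#'   component whose total is 0).
#' @export
mass_balance_error <- function(result) {
  sys <- result$system
  n <- sys$ligand$n_protonation
  hyd <- sys$metal$hydrolysis
  use_h <- sys$include_hydrolysis && !is.null(hyd)
  msp <- c("M", "ML", if (use_h) paste0("MOH", hyd$k))
  lsp <- c("L", paste0("LH", seq_len(n)), "ML")
  me <- if (sys$m_total > 0) {
    max(abs(rowSums(result$conc[, msp, drop = FALSE]) - sys$m_total)) / sys$m_total
  } else NA_real_
  le <- if (sys$l_total > 0) {
    max(abs(rowSums(result$conc[, lsp, drop = FALSE]) - sys$l_total)) / sys$l_total
  } else NA_real_
  c(metal = me, ligand = le)
}
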