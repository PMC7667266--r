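# Frozen reference values used across the suite.

# Published cross-tabulation of required log K (rows: M0 x f, cols: R).
# 48 cells, printed to 2 decimals.
expected_required_k <- local({
  m0 <- rep(c(2e-5, 2e-4, 2e-3), each = 4)
  f <- rep(c(0.25, 0.50, 0.75, 0.99), times = 3)
  vals <- rbind(
    c(3.98, 3.23, 2.53, 2.22),
    c(4.52, 3.72, 3.00, 2.70),
    c(5.08, 4.21, 3.48, 3.18),
    c(6.69, 5.74, 5.00, 4.70),
    c(2.98, 2.23, 1.53, 1.22),
    c(3.52, 2.72, 2.00, 1.70),
    c(4.08, 3.21, 2.48, 2.18),
    c(5.69, 4.74, 4.00, 3.70),
    c(1.98, 1.23, 0.53, 0.22),
    c(2.52, 1.72, 1.00, 0.70),
    c(3.08, 2.21, 1.48, 1.18),
    c(4.69, 3.74, 3.00, 2.70)
  )
  colnames(vals) <- c("2", "10", "50", "100")
  list(m0 = m0, f = f, ratios = c(2, 10, 50, 100), vals = vals)
})

# Published 25-99 % complexation windows (pH) for 8 metals x 5 ligands.
# NA marks a non-numeric printed cell ("<0" lower for Fe-EDTA, "> 10.0"
# upper for the three high-pH calcium windows).
expected_windows <- local({
  tab <- rbind(
    c("Fe", "NTA",   0.30, 1.15), c("Fe", "HIMDA", 1.02, 2.46),
    c("Fe", "EDDG",  2.69, 3.40), c("Fe", "EDDS",  1.56, 2.13),
    c("Fe", "EDTA",  NA,   0.3),
    c("Hg", "NTA",   1.12, 2.06), c("Hg", "HIMDA", 5.81, 8.51),
    c("Hg", "EDDG",  2.41, 3.12), c("Hg", "EDDS",  3.12, 3.93),
    c("Hg", "EDTA",  0.4,  1.1),
    c("Cu", "NTA",   1.28, 2.32), c("Cu", "HIMDA", 0.99, 2.41),
    c("Cu", "EDDG",  3.55, 4.45), c("Cu", "EDDS",  1.99, 2.59),
    c("Cu", "EDTA",  1.2,  1.9),
    c("Pb", "NTA",   1.84, 3.55), c("Pb", "HIMDA", 2.27, 4.40),
    c("Pb", "EDDG",  5.05, 6.38), c("Pb", "EDDS",  4.18, 5.34),
    c("Pb", "EDTA",  1.5,  2.2),
    c("Zn", "NTA",   2.27, 4.20), c("Zn", "HIMDA", 3.35, 5.82),
    c("Zn", "EDDG",  4.40, 5.60), c("Zn", "EDDS",  3.41, 4.26),
    c("Zn", "EDTA",  1.9,  2.7),
    c("Cd", "NTA",   2.70, 5.00), c("Cd", "HIMDA", 4.16, 6.67),
    c("Cd", "EDDG",  5.05, 6.38), c("Cd", "EDDS",  4.68, 5.86),
    c("Cd", "EDTA",  1.9,  2.7),
    c("Mn", "NTA",   4.85, 7.45), c("Mn", "HIMDA", 5.81, 8.51),
    c("Mn", "EDDG",  6.05, 7.80), c("Mn", "EDDS",  5.46, 6.81),
    c("Mn", "EDTA",  2.7,  3.8),
    c("Ca", "NTA",   5.80, 8.27), c("Ca", "HIMDA", 6.75, NA),
    c("Ca", "EDDG",  9.93, NA),   c("Ca", "EDDS",  8.08, NA),
    c("Ca", "EDTA",  4.1,  5.4)
  )
  data.frame(metal = tab[, 1], ligand = tab[, 2],
             lower = as.numeric(tab[, 3]), upper = as.numeric(tab[, 4]),
             stringsAsFactors = FALSE)
})

# Regulatory soil levels (mg/kg) with the published mM conversions.
expected_soil <- data.frame(
  metal = c("Hg", "Cd", "Pb", "Cu", "Ni"),
  atomic_weight = c(200.59, 112.41, 207.20, 63.55, 58.69),
  intervention_mg_kg = c(530, 380, 210, 10, 720),
  intervention_mm = c(2.6, 3.4, 1.0, 0.2, 12.3),
  target_mg_kg = c(85, 100, 35, 0.3, 140),
  target_mm = c(0.4, 0.89, 0.17, NA, 2.4),  # Cu target cell not reproducible
  target_dp = c(1, 2, 2, NA, 1),            # decimals as printed, per cell
  stringsAsFactors = FALSE
)

# raw (unrounded) window boundary; NA unless the crossing is a plain root
raw_boundary_ph <- function(db, metal, ligand, f, scn = scenario()) {
  cx <- db_complex(db, metal, ligand)
  if (is.null(cx)) return(NA_real_)
  r <- ph_for_fraction(cx$log_beta_ml, db_ligand(db, ligand), f,
                       scn$m_total, scn$ratio)
  if (r$status == "ok") r$ph else NA_real_
}
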