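# Independent oracle for the speciation engine: solves the two mass-balance
# equations
#   M0 = [M] * alpha_M(OH) + beta [M][L]
#   L0 = [L] * D(H)        + beta [M][L]
# by damped (geometric-mean) fixed-point iteration on the free
# concentrations. Deliberately avoids the closed-form quadratic used by the
# package.
oracle_ml <- function(log_beta_ml, ligand, ph, m_total, l_total,
                      metal = NULL, p_kw = 14, max_iter = 5000L) {
  beta <- 10^log_beta_ml
  d <- 10^log_d(ligand, ph)
  a <- if (is.null(metal)) 1 else metal_side_coefficient(metal, ph, p_kw)
  if (m_total == 0 || l_total == 0) return(0)
  m <- m_total / a
  l <- l_total / d
  for (i in seq_len(max_iter)) {
    m_new <- m_total / (a + beta * l)
    l_new <- l_total / (d + beta * m)
    m_upd <- sqrt(m * m_new)
    l_upd <- sqrt(l * l_new)
    done <- abs(log(m_upd / m)) < 1e-15 && abs(log(l_upd / l)) < 1e-15
    m <- m_upd
    l <- l_upd
    if (done) break
  }
  beta * m * l
}

# deterministic random speciation system for property sweeps
random_system_params <- function(i) {
  lig <- synthesize_ligand(seed = 1000 + i, n = 1 + (i %% 4))
  set.seed(2000 + i)
  list(
    ligand = lig,
    log_beta_ml = stats::runif(1, 5, 20),
    m_total = 10^stats::runif(1, -6, -3),
    ratio = stats::runif(1, 2, 100),
    ph = stats::runif(1, 1, 12)
  )
}
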