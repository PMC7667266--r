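# Core conditional-stability machinery.
#
# Conventions used throughout:
#   * pH = -log10 [H+] on the concentration scale; no activity corrections.
#   * all equilibrium constants handled as decimal logs; sums of powers of 10
#     are evaluated with a base-10 log-sum-exp so that log beta values up to
#     ~30 and pH down to -2 never overflow.

# log10(sum(10^x)) without overflow; x may contain -Inf
logsum10 <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log10(sum(10^(x - m)))
}

#' Screening scenario
#'
#' The knobs of a screening run: total metal concentration M0, the
#' ligand-to-metal ratio R = L0/M0, and the complexed fractions f at which
#' the pH boundaries are to be located. The default scenario (M0 = 2e-5
#' mol/L, R = 50, f = 25/50/75/99 %) is the reference condition used for all
#' bundled screening tables.
#'
#' @param m_total Total metal concentration M0 in mol/L (> 0).
#' @param ratio Dimensionless ratio R = L0/M0; must exceed every target
#'   fraction, otherwise the ligand cannot complex the requested share of
#'   the metal.
#' @param target_fractions Strictly increasing fractions in (0, 1).
#' @return An object of class `scenario` with fields `m_total`, `ratio`,
#'   `l_total` (= ratio * m_total) and `target_fractions`.
#' @examples
#' scenario()                       # the reference scenario
#' scenario(m_total = 2.6e-3, ratio = 10)
#' @export
scenario <- function(m_total = 2e-5, ratio = 50,
                     target_fractions = c(0.25, 0.50, 0.75, 0.99)) {
  if (!is.finite(m_total) || m_total <= 0) stop("m_total must be > 0", call. = FALSE)
  f <- as.numeric(target_fractions)
  if (!length(f) || any(!is.finite(f)) || any(f <= 0 | f >= 1)) {
    stop("target_fractions must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(diff(f) <= 0)) stop("target_fractions must be strictly increasing", call. = FALSE)
  if (!is.finite(ratio) || ratio <= max(f)) {
    stop("ratio must exceed every target fraction", call. = FALSE)
  }
  structure(
    list(m_total = m_total, ratio = ratio, l_total = ratio * m_total,
         target_fractions = f),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario: M0 = %g mol/L, R = %g (L0 = %g mol/L), f = %s>\n",
              x$m_total, x$ratio, x$l_total,
              paste(format(x$target_fractions), collapse = "/")))
  invisible(x)
}

#' Required effective stability constant for a target complexed fraction
#'
#' For the 1:1 equilibrium M + L <-> ML with totals M0 and L0 = R * M0, the
#' effective constant needed so that a fraction f = \[ML\]/M0 of the metal is
#' complexed is
#'   K = f / (M0 * (R - f) * (1 - f)),
#' returned as log10 K. It grows with f (more complexation demands a
#' stronger complex) and falls with R and with M0 (excess ligand or more
#' concentrated solutions need weaker complexes).
#'
#' @param f Target complexed fraction, in (0, 1).
#' @param m_total Total metal M0 in mol/L.
#' @param ratio Ligand-to-metal ratio R = L0/M0; must exceed `f`.
#' @return log10 of the required effective constant. Vectorised over `f`.
#' @examples
#' required_log_beta_eff(0.25, 2e-5, 50)  # 2.53: Cd scenario, 25 %
#' @export
required_log_beta_eff <- function(f, m_total, ratio) {
  if (any(!is.finite(f)) || any(f <= 0 | f >= 1)) {
    stop("f must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.finite(m_total) || m_total <= 0) stop("m_total must be > 0", call. = FALSE)
  if (any(ratio <= f)) {
    stop("ligand cannot complex more metal than supplied: need ratio > f",
         call. = FALSE)
  }
  log10(f) - log10(m_total) - log10(ratio - f) - log10(1 - f)
}

#' Minimal ligand-to-metal ratio achieving a fraction
#'
#' Inverts the required-constant relation for R: given the effective
#' constant available at the working pH, the smallest ratio R = L0/M0 at
#' which a fraction f of the metal is complexed is
#'   R = f + f / (10^log_beta_eff * M0 * (1 - f)).
#' This is the "minimal concentration of ligand" question: how little
#' chelator can be dosed while still reaching the remediation target.
#'
#' @param f Target complexed fraction in (0, 1).
#' @param log_beta_eff Available effective constant (decimal log) at the
#'   working pH, see [log_beta_eff()].
#' @param m_total Total metal M0 in mol/L.
#' @return The ratio R; `required_log_beta_eff(f, m_total, R)` recovers
#'   `log_beta_eff` exactly.
#' @export
min_ratio_for_fraction <- function(f, log_beta_eff, m_total) {
  if (any(!is.finite(f)) || any(f <= 0 | f >= 1)) {
    stop("f must lie strictly in (0, 1)", call. = FALSE)
  }
  f + f / (10^log_beta_eff * m_total * (1 - f))
}

#' The ligand protonation polynomial log D(H)
#'
#' D(H) = 1 + sum_j beta_j \[H\]^j is the side-reaction coefficient of the
#' ligand toward protons (often written alpha_L(H)): the factor by which
#' protonation reduces the free ligand available for metal binding at a
#' given pH. Its decimal log is >= 0, strictly decreasing in pH, and tends
#' to 0 at high pH where the ligand is fully deprotonated.
#'
#' @param ligand A [ligand_record()] or a bare numeric vector of cumulative
#'   protonation constants (decimal logs).
#' @param ph pH values, vectorised; pH = -log10\[H+\], concentration scale.
#' @return log10 D(H), same length as `ph`.
#' @examples
#' nta <- ligand_record("NTA", c(9.84, 12.40, 14.23))
#' log_d(nta, c(2.79, 5.05, 14))
#' @export
log_d <- function(ligand, ph) {
  lb <- if (inherits(ligand, "ligand_record")) {
    validate_ligand(ligand)
    ligand$log_beta_cumulative
  } else {
    as.numeric(ligand)
  }
  j <- seq_along(lb)
  vapply(ph, function(p) logsum10(c(0, lb - j * p)), numeric(1))
}

#' Effective (conditional) stability constant at a given pH
#'
#' Discounts the stoichiometric formation constant for ligand protonation:
#' log beta_eff(pH) = log beta_ML - log D(H). This is the constant that
#' actually governs complexation in terms of *total* (protonated + free)
#' uncomplexed ligand, and the quantity compared against
#' [required_log_beta_eff()] when screening.
#'
#' @param log_beta_ml Formation constant of ML (decimal log).
#' @inheritParams log_d
#' @return log10 beta_eff, vectorised over `ph`; non-decreasing in pH and
#'   equal to `log_beta_ml` in the high-pH limit.
#' @examples
#' nta <- ligand_record("NTA", c(9.84, 12.40, 14.23))
#' log_beta_eff(9.8, nta, c(2.79, 5.05))  # Cd-NTA: 2.53, 5.00
#' @export
log_beta_eff <- function(log_beta_ml, ligand, ph) {
  log_beta_ml - log_d(ligand, ph)
}

#' The F(H) screening curve
#'
#' F(H) = log D(H) + required log beta_eff(f). Where the horizontal line
#' log beta_ML crosses the F(H) curve for a fraction f, that fraction of
#' the total metal is complexed. Curves for different f are exact vertical
#' translations of one another (the pH-dependence sits entirely in log D).
#' With `f = 0` the required term is zero by convention and the curve is
#' log D itself.
#'
#' @inheritParams log_d
#' @param f Target complexed fraction; `0` is allowed and means the bare
#'   log D curve.
#' @param m_total,ratio Scenario parameters, see [required_log_beta_eff()].
#' @return F(H) values, vectorised over `ph`.
#' @export
log_f_curve <- function(ligand, f, m_total, ratio, ph) {
  shift <- if (length(f) == 1L && f == 0) 0 else required_log_beta_eff(f, m_total, ratio)
  log_d(ligand, ph) + shift
}

# smaller root of x^2 - s x + p = 0 (s, p >= 0), in a cancellation-safe form:
# x = 2p / (s + sqrt(s^2 - 4p)). Handles s = Inf (-> 0).
stable_smaller_root <- function(s, p) {
  if (!is.finite(s)) return(0)
  disc <- s * s - 4 * p
  if (disc < 0) disc <- 0  # guard tiny negative from rounding at f -> max
  2 * p / (s + sqrt(disc))
}

#' Complexed fraction of the metal at a given pH
#'
#' Solves the 1:1 mass-balance system at fixed pH for the complex
#' concentration x = \[ML\]:
#'   beta_eff x^2 - (beta_eff (L0 + M0) + 1) x + beta_eff L0 M0 = 0,
#' taking the smaller (physical) root in a cancellation-safe form (the
#' effective constant spans ~20 orders of magnitude across a screen), and
#' returns f = x / M0.
#'
#' @inheritParams log_beta_eff
#' @param m_total,l_total Totals M0 and L0 in mol/L.
#' @return The fraction f in \[0, min(1, L0/M0)), vectorised over `ph`;
#'   strictly increasing in pH, in `l_total` and in `log_beta_ml`.
#' @examples
#' nta <- ligand_record("NTA", c(9.84, 12.40, 14.23))
#' complexed_fraction(9.8, nta, 3.15, m_total = 2e-5, l_total = 1e-3)  # ~0.50
#' @export
complexed_fraction <- function(log_beta_ml, ligand, ph, m_total, l_total) {
  if (!is.finite(m_total) || m_total <= 0) stop("m_total must be > 0", call. = FALSE)
  if (l_total < 0) stop("l_total must be >= 0", call. = FALSE)
  if (l_total == 0) return(rep(0, length(ph)))
  lbe <- log_beta_eff(log_beta_ml, ligand, ph)
  x <- vapply(lbe, function(lb) {
    s <- l_total + m_total + 10^(-lb)   # Inf when beta_eff underflows: x -> 0
    stable_smaller_root(s, l_total * m_total)
  }, numeric(1))
  x / m_total
}

#' pH at which a target fraction of the metal is complexed
#'
#' Finds the pH where the F(H) curve for fraction `f` crosses the line
#' log beta_ML, i.e. where log D(H) = log beta_ML - required(f). Because
#' log D is strictly decreasing the root is unique; it is located by
#' bisection on \[-2, 14\] to |dpH| <= 1e-4.
#'
#' Not every request has a root in range, and the outcome is typed rather
#' than thrown:
#' * `"ok"` - root found, `ph` holds it;
#' * `"unattainable"` - log beta_ML is below the required constant, so the
#'   fraction is not reached at *any* pH (the line never meets the curve);
#' * `"below_range"` - the crossing lies below pH -2 (screening tables
#'   print this as "<0");
#' * `"above_range"` - the crossing lies above pH 14 (only possible for
#'   marginally attainable fractions).
#'
#' @inheritParams log_beta_eff
#' @param f Target complexed fraction in (0, 1).
#' @param m_total,ratio Scenario parameters.
#' @param tol Bisection tolerance on pH.
#' @return An object of class `ph_result`: list with `status` (one of the
#'   four outcomes) and `ph` (numeric, `NA` unless status is `"ok"`).
#' @examples
#' nta <- ligand_record("NTA", c(9.84, 12.40, 14.23))
#' ph_for_fraction(9.8, nta, f = 0.99, m_total = 2e-5, ratio = 50)  # pH 5.05
#' @export
ph_for_fraction <- function(log_beta_ml, ligand, f, m_total, ratio, tol = 1e-4) {
  target <- log_beta_ml - required_log_beta_eff(f, m_total, ratio)
  ph_result_for_target(ligand, target, tol)
}

# locate pH with log_d(ligand, pH) == target (strictly decreasing curve)
ph_result_for_target <- function(ligand, target, tol = 1e-4) {
  lo <- -2; hi <- 14
  if (target < 0) return(ph_result("unattainable"))
  if (target > log_d(ligand, lo)) return(ph_result("below_range"))
  if (target < log_d(ligand, hi)) return(ph_result("above_range"))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (log_d(ligand, mid) > target) lo <- mid else hi <- mid
  }
  ph_result("ok", (lo + hi) / 2)
}

ph_result <- function(status, ph = NA_real_) {
  structure(list(status = status, ph = ph), class = "ph_result")
}

#' @export
print.ph_result <- function(x, ...) {
  if (x$status == "ok") cat(sprintf("<pH %.2f>\n", x$ph))
  else cat(sprintf("<%s>\n", gsub("_", "-", x$status)))
  invisible(x)
}
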