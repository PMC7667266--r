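#' Ligand record: cumulative protonation constants of a chelator
#'
#' A ligand is characterised by its `n` protonation equilibria
#' L + j H+ <-> LH_j, each with a cumulative formation constant beta_j.
#' Constants are stored as decimal logs of the *cumulative* betas, exactly as
#' stability-constant compilations print them; the stepwise constants
#' log K_j = log beta_j - log beta_{j-1} are derived, see [stepwise_log_k()].
#'
#' @param ligand_id Short unique token, e.g. `"NTA"`.
#' @param log_beta_cumulative Numeric vector of cumulative protonation
#'   constants (decimal logs), ordered beta_1 ... beta_n. Must be strictly
#'   increasing: every stepwise log K_j must be positive.
#' @param name Free-text ligand name.
#' @param ionic_strength Ionic strength of the source medium in mol/L
#'   (metadata only; no thermodynamic correction is ever applied).
#' @param temperature Temperature of the source medium in degrees C (metadata).
#' @param source_tag Free-text citation key for the constants.
#' @return An object of class `ligand_record`.
#' @examples
#' nta <- ligand_record("NTA", c(9.84, 12.40, 14.23))
#' stepwise_log_k(nta)
#' @export
ligand_record <- function(ligand_id, log_beta_cumulative, name = ligand_id,
                          ionic_strength = NA_real_, temperature = NA_real_,
                          source_tag = NA_character_) {
  rec <- structure(
    list(
      ligand_id = as.character(ligand_id),
      name = as.character(name),
      n_protonation = length(log_beta_cumulative),
      log_beta_cumulative = as.numeric(log_beta_cumulative),
      ionic_strength = as.numeric(ionic_strength),
      temperature = as.numeric(temperature),
      source_tag = as.character(source_tag)
    ),
    class = "ligand_record"
  )
  validate_ligand(rec)
  rec
}

validate_ligand <- function(rec) {
  probs <- character()
  lb <- rec$log_beta_cumulative
  if (!nzchar(rec$ligand_id)) probs <- c(probs, "ligand_id must be non-empty")
  if (rec$n_protonation < 1L) {
    probs <- c(probs, "at least one protonation constant is required")
  }
  if (length(lb) != rec$n_protonation) {
    probs <- c(probs, sprintf(
      "ligand '%s': %d constants given but n_protonation = %d",
      rec$ligand_id, length(lb), rec$n_protonation
    ))
  }
  if (!all(is.finite(lb))) {
    probs <- c(probs, sprintf("ligand '%s': non-finite protonation constant", rec$ligand_id))
  } else if (length(lb) > 1L && any(diff(lb) <= 0)) {
    probs <- c(probs, sprintf(
      "ligand '%s': cumulative log beta must be strictly increasing (stepwise log K > 0); got [%s]",
      rec$ligand_id, paste(format(lb), collapse = ", ")
    ))
  }
  if (length(probs)) {
    stop("invalid ligand record:\n  ", paste(probs, collapse = "\n  "), call. = FALSE)
  }
  invisible(rec)
}

#' @export
print.ligand_record <- function(x, ...) {
  cat(sprintf(
    "<ligand %s (%s): n = %d, cumulative log beta = %s>\n",
    x$ligand_id, x$name, x$n_protonation,
    paste(format(x$log_beta_cumulative), collapse = ", ")
  ))
  invisible(x)
}

#' Stepwise protonation constants of a ligand
#'
#' Converts the stored cumulative constants to stepwise ones,
#' log K_j = log beta_j - log beta_{j-1} (with log beta_0 = 0).
#'
#' @param ligand A [ligand_record()].
#' @return Numeric vector of stepwise log K, length `n_protonation`.
#' @export
stepwise_log_k <- function(ligand) {
  diff(c(0, ligand$log_beta_cumulative))
}

#' Metal record
#'
#' @param metal_id Token, e.g. `"Cd"`.
#' @param charge Positive integer charge of the free aqua ion.
#' @param atomic_weight Atomic weight in g/mol.
#' @param hydrolysis Optional mononuclear hydrolysis constants for
#'   M + k OH- <-> M(OH)_k: a data frame (or list coercible to one) with
#'   columns `k` (distinct integers in 1..4) and `log_beta_oh` (decimal log).
#'   `NULL` means no hydrolysis model; the metal side-reaction coefficient is
#'   then identically 1.
#' @return An object of class `metal_record`.
#' @examples
#' metal_record("Cd", charge = 2, atomic_weight = 112.41)
#' @export
metal_record <- function(metal_id, charge, atomic_weight, hydrolysis = NULL) {
  if (!is.null(hydrolysis)) {
    hydrolysis <- as.data.frame(hydrolysis)
    hydrolysis$k <- as.integer(hydrolysis$k)
    hydrolysis$log_beta_oh <- as.numeric(hydrolysis$log_beta_oh)
    hydrolysis <- hydrolysis[order(hydrolysis$k), c("k", "log_beta_oh"), drop = FALSE]
    rownames(hydrolysis) <- NULL
  }
  rec <- structure(
    list(
      metal_id = as.character(metal_id),
      charge = as.integer(charge),
      atomic_weight = as.numeric(atomic_weight),
      hydrolysis = hydrolysis
    ),
    class = "metal_record"
  )
  validate_metal(rec)
  rec
}

validate_metal <- function(rec) {
  probs <- character()
  if (!nzchar(rec$metal_id)) probs <- c(probs, "metal_id must be non-empty")
  if (is.na(rec$charge) || rec$charge < 1L) {
    probs <- c(probs, sprintf("metal '%s': charge must be a positive integer", rec$metal_id))
  }
  if (!is.finite(rec$atomic_weight) || rec$atomic_weight <= 0) {
    probs <- c(probs, sprintf("metal '%s': atomic_weight must be > 0", rec$metal_id))
  }
  h <- rec$hydrolysis
  if (!is.null(h)) {
    if (anyDuplicated(h$k)) {
      probs <- c(probs, sprintf("metal '%s': hydrolysis k values must be distinct", rec$metal_id))
    }
    if (any(h$k < 1L | h$k > 4L)) {
      probs <- c(probs, sprintf("metal '%s': hydrolysis k must lie in 1..4", rec$metal_id))
    }
    if (!all(is.finite(h$log_beta_oh))) {
      probs <- c(probs, sprintf("metal '%s': non-finite hydrolysis constant", rec$metal_id))
    }
  }
  if (length(probs)) {
    stop("invalid metal record:\n  ", paste(probs, collapse = "\n  "), call. = FALSE)
  }
  invisible(rec)
}

#' @export
print.metal_record <- function(x, ...) {
  hy <- if (is.null(x$hydrolysis)) "none" else
    paste(sprintf("M(OH)%d: %s", x$hydrolysis$k, format(x$hydrolysis$log_beta_oh)),
          collapse = "; ")
  cat(sprintf("<metal %s%+d: A = %s g/mol, hydrolysis: %s>\n",
              x$metal_id, x$charge, format(x$atomic_weight), hy))
  invisible(x)
}

#' Complex record: one 1:1 metal-ligand formation constant
#'
#' @param metal_id,ligand_id Tokens referencing records in the same database.
#' @param log_beta_ml Decimal log of the formation constant of
#'   M + L <-> ML.
#' @inheritParams ligand_record
#' @return An object of class `complex_record`.
#' @export
complex_record <- function(metal_id, ligand_id, log_beta_ml,
                           ionic_strength = NA_real_, temperature = NA_real_,
                           source_tag = NA_character_) {
  if (!is.finite(log_beta_ml)) {
    stop(sprintf("complex %s-%s: log_beta_ml must be finite", metal_id, ligand_id),
         call. = FALSE)
  }
  structure(
    list(
      metal_id = as.character(metal_id),
      ligand_id = as.character(ligand_id),
      log_beta_ml = as.numeric(log_beta_ml),
      ionic_strength = as.numeric(ionic_strength),
      temperature = as.numeric(temperature),
      source_tag = as.character(source_tag)
    ),
    class = "complex_record"
  )
}

#' Draw a synthetic but chemically plausible ligand record
#'
#' Property-test workhorse: generates a random polyprotic ligand whose
#' stepwise protonation constants log K_j are drawn uniformly in \[1, 11\]
#' and sorted into normal ordering (strictly decreasing with j), so the
#' cumulative sequence is strictly increasing and the record always passes
#' validation. Deterministic for a given seed; the caller's RNG state is
#' left untouched.
#'
#' @param seed Integer seed.
#' @param n Number of protonation steps, in 1..6.
#' @return A [ligand_record()] with id `"SYN<seed>"`.
#' @export
synthesize_ligand <- function(seed, n = 3L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L || n > 6L) stop("n must lie in 1..6", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  step <- sort(stats::runif(n, min = 1, max = 11), decreasing = TRUE)
  # ties have probability zero but would break strict ordering; nudge apart
  while (any(diff(step) == 0)) step <- step + cumsum(c(0, diff(step) == 0)) * -1e-9
  ligand_record(
    ligand_id = sprintf("SYN%d", as.integer(seed)),
    log_beta_cumulative = cumsum(step),
    name = sprintf("synthetic ligand (seed %d)", as.integer(seed)),
    source_tag = "synthetic"
  )
}
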