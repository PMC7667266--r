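#' Constants database
#'
#' A `constants_db` bundles ligand, metal and complex records and provides
#' lookup by id and by metal-ligand pair. Every complex must reference an
#' existing ligand and metal; ids and pairs are unique.
#'
#' @param ligands List of [ligand_record()] objects.
#' @param metals List of [metal_record()] objects.
#' @param complexes List of [complex_record()] objects.
#' @return An object of class `constants_db` with named-list components
#'   `ligands`, `metals` and a data-frame component `complexes`.
#' @seealso [builtin_table4()], [load_constants()], [save_constants()]
#' @export
constants_db <- function(ligands = list(), metals = list(), complexes = list()) {
  names(ligands) <- vapply(ligands, `[[`, "", "ligand_id")
  names(metals) <- vapply(metals, `[[`, "", "metal_id")
  cx <- if (length(complexes)) {
    do.call(rbind, lapply(complexes, function(r) {
      data.frame(
        metal_id = r$metal_id, ligand_id = r$ligand_id,
        log_beta_ml = r$log_beta_ml, ionic_strength = r$ionic_strength,
        temperature = r$temperature, source_tag = r$source_tag,
        stringsAsFactors = FALSE
      )
    }))
  } else {
    data.frame(
      metal_id = character(), ligand_id = character(), log_beta_ml = numeric(),
      ionic_strength = numeric(), temperature = numeric(),
      source_tag = character(), stringsAsFactors = FALSE
    )
  }
  rownames(cx) <- NULL
  db <- structure(list(ligands = ligands, metals = metals, complexes = cx),
                  class = "constants_db")
  validate_db(db)
}

#' Validate a constants database
#'
#' Re-runs every record-level validator and checks the cross-record
#' invariants: unique ids, unique (metal, ligand) pairs, referential
#' integrity of complexes. All violations are collected and reported
#' together.
#'
#' @param db A `constants_db`.
#' @return The database, invisibly, if valid; otherwise an error listing
#'   every offending record.
#' @export
validate_db <- function(db) {
  probs <- character()
  for (lg in db$ligands) {
    tryCatch(validate_ligand(lg), error = function(e) {
      probs <<- c(probs, conditionMessage(e))
    })
  }
  for (mt in db$metals) {
    tryCatch(validate_metal(mt), error = function(e) {
      probs <<- c(probs, conditionMessage(e))
    })
  }
  if (anyDuplicated(names(db$ligands))) {
    probs <- c(probs, sprintf("duplicated ligand ids: %s",
      paste(unique(names(db$ligands)[duplicated(names(db$ligands))]), collapse = ", ")))
  }
  if (anyDuplicated(names(db$metals))) {
    probs <- c(probs, sprintf("duplicated metal ids: %s",
      paste(unique(names(db$metals)[duplicated(names(db$metals))]), collapse = ", ")))
  }
  cx <- db$complexes
  pair <- paste(cx$metal_id, cx$ligand_id, sep = "-")
  if (anyDuplicated(pair)) {
    probs <- c(probs, sprintf("duplicated complex rows: %s",
      paste(unique(pair[duplicated(pair)]), collapse = ", ")))
  }
  bad_l <- setdiff(cx$ligand_id, names(db$ligands))
  if (length(bad_l)) {
    probs <- c(probs, sprintf("complex rows reference unknown ligands: %s",
                              paste(bad_l, collapse = ", ")))
  }
  bad_m <- setdiff(cx$metal_id, names(db$metals))
  if (length(bad_m)) {
    probs <- c(probs, sprintf("complex rows reference unknown metals: %s",
                              paste(bad_m, collapse = ", ")))
  }
  if (!all(is.finite(cx$log_beta_ml))) {
    probs <- c(probs, "non-finite log_beta_ml in complexes")
  }
  if (length(probs)) {
    stop("invalid constants database:\n  ", paste(probs, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(db)
}

#' @export
print.constants_db <- function(x, ...) {
  cat(sprintf("<constants_db: %d ligands, %d metals, %d complexes>\n",
              length(x$ligands), length(x$metals), nrow(x$complexes)))
  cat("  ligands:", paste(names(x$ligands), collapse = ", "), "\n")
  cat("  metals: ", paste(names(x$metals), collapse = ", "), "\n")
  invisible(x)
}

#' Look up records in a constants database
#'
#' `db_ligand()` and `db_metal()` error on unknown ids; `db_complex()`
#' returns `NULL` for an absent pair (absent table cells are data, not
#' errors — screening operations skip them).
#'
#' @param db A `constants_db`.
#' @param ligand_id,metal_id Record tokens.
#' @return The matching record (`db_complex()`: a `complex_record` or `NULL`).
#' @export
db_ligand <- function(db, ligand_id) {
  rec <- db$ligands[[ligand_id]]
  if (is.null(rec)) stop(sprintf("unknown ligand '%s'", ligand_id), call. = FALSE)
  rec
}

#' @rdname db_ligand
#' @export
db_metal <- function(db, metal_id) {
  rec <- db$metals[[metal_id]]
  if (is.null(rec)) stop(sprintf("unknown metal '%s'", metal_id), call. = FALSE)
  rec
}

#' @rdname db_ligand
#' @export
db_complex <- function(db, metal_id, ligand_id) {
  cx <- db$complexes
  i <- which(cx$metal_id == metal_id & cx$ligand_id == ligand_id)
  if (!length(i)) return(NULL)
  row <- cx[i, ]
  complex_record(row$metal_id, row$ligand_id, row$log_beta_ml,
                 row$ionic_strength, row$temperature, row$source_tag)
}

# ---- serialization ---------------------------------------------------------

MAX_PROTONATION <- 6L

# empty CSV cells in free-text columns mean "not recorded"
blank_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

ligands_to_frame <- function(ligands) {
  rows <- lapply(ligands, function(lg) {
    lb <- rep(NA_real_, MAX_PROTONATION)
    lb[seq_len(lg$n_protonation)] <- lg$log_beta_cumulative
    cbind(
      data.frame(ligand_id = lg$ligand_id, name = lg$name,
                 n = lg$n_protonation, stringsAsFactors = FALSE),
      as.data.frame(as.list(stats::setNames(lb, paste0("logb", 1:MAX_PROTONATION)))),
      data.frame(ionic_strength = lg$ionic_strength, temperature = lg$temperature,
                 source = lg$source_tag, stringsAsFactors = FALSE)
    )
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

frame_to_ligands <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    n <- as.integer(row$n)
    lb <- as.numeric(row[paste0("logb", seq_len(n))])
    if (anyNA(lb)) {
      stop(sprintf("ligands row %d ('%s'): n = %d but logb1..logb%d not all present",
                   i, row$ligand_id, n, n), call. = FALSE)
    }
    extra <- as.numeric(row[paste0("logb", seq_len(MAX_PROTONATION))])[-seq_len(n)]
    if (any(!is.na(extra))) {
      stop(sprintf("ligands row %d ('%s'): more constants than n = %d",
                   i, row$ligand_id, n), call. = FALSE)
    }
    ligand_record(row$ligand_id, lb, name = blank_to_na(row$name),
                  ionic_strength = row$ionic_strength,
                  temperature = row$temperature,
                  source_tag = blank_to_na(row$source))
  })
}

metals_to_frame <- function(metals) {
  rows <- lapply(metals, function(mt) {
    h <- mt$hydrolysis
    data.frame(
      metal_id = mt$metal_id, charge = mt$charge, atomic_weight = mt$atomic_weight,
      hydrolysis_k = if (is.null(h)) "" else paste(h$k, collapse = ";"),
      hydrolysis_logb = if (is.null(h)) "" else
        paste(format(h$log_beta_oh, digits = 15, trim = TRUE), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

frame_to_metals <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    hk <- as.character(row$hydrolysis_k)
    hy <- NULL
    if (!is.na(hk) && nzchar(hk)) {
      hy <- data.frame(
        k = as.integer(strsplit(hk, ";", fixed = TRUE)[[1]]),
        log_beta_oh = as.numeric(strsplit(as.character(row$hydrolysis_logb),
                                          ";", fixed = TRUE)[[1]])
      )
    }
    metal_record(row$metal_id, row$charge, row$atomic_weight, hydrolysis = hy)
  })
}

frame_to_complexes <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    complex_record(row$metal_id, row$ligand_id, row$log_beta_ml,
                   row$ionic_strength, row$temperature,
                   blank_to_na(row$source))
  })
}

#' Read a constants database from CSV or JSON
#'
#' Two on-disk layouts are supported.
#'
#' * **csv**: `path` is a directory holding `ligands.csv`, `metals.csv` and
#'   `complexes.csv`. `ligands.csv` has columns
#'   `ligand_id,name,n,logb1..logb6,ionic_strength,temperature,source`
#'   (unused `logb` cells empty); `metals.csv` has
#'   `metal_id,charge,atomic_weight,hydrolysis_k,hydrolysis_logb` with the
#'   hydrolysis columns holding `;`-separated parallel lists (empty = none);
#'   `complexes.csv` has
#'   `metal_id,ligand_id,log_beta_ml,ionic_strength,temperature,source`.
#' * **json**: `path` is a single document with arrays `ligands`, `metals`
#'   and `complexes` mirroring the same fields, with
#'   `log_beta_cumulative` and `hydrolysis` as native arrays/objects.
#'
#' The name `"table4"` resolves to the bundled database, see
#' [builtin_table4()].
#'
#' @param path Directory (csv), file (json), or the name `"table4"`.
#' @param format `"csv"` or `"json"`; inferred from `path` when missing.
#' @return A validated [constants_db()].
#' @export
load_constants <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (identical(path, "table4")) return(builtin_table4())
  if (format == "auto") {
    format <- if (dir.exists(path)) "csv"
      else if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
      else stop(sprintf("cannot infer format of '%s'; pass format=", path), call. = FALSE)
  }
  if (format == "csv") {
    files <- file.path(path, c("ligands.csv", "metals.csv", "complexes.csv"))
    missing <- files[!file.exists(files)]
    if (length(missing)) {
      stop("missing database files: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    lig_df <- utils::read.csv(files[1], stringsAsFactors = FALSE,
                              colClasses = c(ligand_id = "character", name = "character",
                                             source = "character"))
    met_df <- utils::read.csv(files[2], stringsAsFactors = FALSE,
                              colClasses = c(metal_id = "character",
                                             hydrolysis_k = "character",
                                             hydrolysis_logb = "character"))
    cx_df <- utils::read.csv(files[3], stringsAsFactors = FALSE,
                             colClasses = c(metal_id = "character",
                                            ligand_id = "character",
                                            source = "character"))
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    ligands <- lapply(doc$ligands, function(x) {
      ligand_record(x$ligand_id, unlist(x$log_beta_cumulative),
                    name = x$name %||% x$ligand_id,
                    ionic_strength = x$ionic_strength %||% NA_real_,
                    temperature = x$temperature %||% NA_real_,
                    source_tag = x$source %||% NA_character_)
    })
    metals <- lapply(doc$metals, function(x) {
      hy <- NULL
      if (!is.null(x$hydrolysis) && length(x$hydrolysis)) {
        hy <- data.frame(
          k = vapply(x$hydrolysis, function(h) as.integer(h$k), 1L),
          log_beta_oh = vapply(x$hydrolysis, function(h) as.numeric(h$log_beta_oh), 1)
        )
      }
      metal_record(x$metal_id, x$charge, x$atomic_weight, hydrolysis = hy)
    })
    complexes <- lapply(doc$complexes, function(x) {
      complex_record(x$metal_id, x$ligand_id, x$log_beta_ml,
                     ionic_strength = x$ionic_strength %||% NA_real_,
                     temperature = x$temperature %||% NA_real_,
                     source_tag = x$source %||% NA_character_)
    })
    return(constants_db(ligands, metals, complexes))
  }
  constants_db(frame_to_ligands(lig_df), frame_to_metals(met_df),
               frame_to_complexes(cx_df))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a constants database to CSV or JSON
#'
#' Inverse of [load_constants()]: `load_constants(save_constants(db, p))`
#' returns a database equal to `db`.
#'
#' @param db A [constants_db()].
#' @param path Target directory (csv) or file (json).
#' @inheritParams load_constants
#' @return `path`, invisibly.
#' @export
save_constants <- function(db, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    cx <- db$complexes
    names(cx)[names(cx) == "source_tag"] <- "source"
    utils::write.csv(ligands_to_frame(db$ligands),
                     file.path(path, "ligands.csv"), row.names = FALSE, na = "")
    utils::write.csv(metals_to_frame(db$metals),
                     file.path(path, "metals.csv"), row.names = FALSE, na = "")
    utils::write.csv(cx, file.path(path, "complexes.csv"),
                     row.names = FALSE, na = "")
  } else {
    doc <- list(
      ligands = lapply(unname(db$ligands), function(lg) list(
        ligand_id = lg$ligand_id, name = lg$name,
        log_beta_cumulative = lg$log_beta_cumulative,
        ionic_strength = lg$ionic_strength, temperature = lg$temperature,
        source = lg$source_tag
      )),
      metals = lapply(unname(db$metals), function(mt) list(
        metal_id = mt$metal_id, charge = mt$charge,
        atomic_weight = mt$atomic_weight,
        hydrolysis = if (is.null(mt$hydrolysis)) NULL else
          lapply(seq_len(nrow(mt$hydrolysis)), function(i)
            list(k = mt$hydrolysis$k[i], log_beta_oh = mt$hydrolysis$log_beta_oh[i]))
      )),
      complexes = lapply(seq_len(nrow(db$complexes)), function(i) {
        row <- db$complexes[i, ]
        list(metal_id = row$metal_id, ligand_id = row$ligand_id,
             log_beta_ml = row$log_beta_ml, ionic_strength = row$ionic_strength,
             temperature = row$temperature, source = row$source_tag)
      })
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' The bundled amino-carboxylic-chelator database
#'
#' Curated cumulative protonation constants and 1:1 complex formation
#' constants for nine amino carboxylic chelators (NTA, MNTA, GLDA, HIMDA,
#' EDDM, EDDS, EDDG, IDS, EDTA) against the heavy metals and alkaline-earth
#' ions most relevant to soil washing (Cd, Pb, Hg, Fe(III), Mn, Cu, Zn, Ca,
#' Mg, plus Ni for soil-scenario arithmetic). Constants are literature values
#' determined at ionic strengths 0.1-1.0 M and 20-30 degrees C; media are
#' carried as metadata and no correction between them is applied. Pairs with
#' no literature value are simply absent. No hydrolysis constants are
#' bundled; supply your own via [metal_record()] if hydroxide competition is
#' to be modelled.
#'
#' @return A validated [constants_db()].
#' @examples
#' db <- builtin_table4()
#' db_ligand(db, "NTA")$log_beta_cumulative
#' db_complex(db, "Cd", "NTA")$log_beta_ml
#' @export
builtin_table4 <- function() {
  dir <- system.file("extdata", "table4", package = "chelscreen", mustWork = TRUE)
  load_constants(dir, format = "csv")
}
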