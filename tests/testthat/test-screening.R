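screen_quiet <- function(...) suppressMessages(screen(...))
window_of <- function(db, m, l, ...) complexation_window(db, m, l, ...)

test_that("complexation windows reproduce the worked reference systems", {
  db <- builtin_table4()
  w <- window_of(db, "Cd", "NTA")
  expect_identical(w$status, "ok")
  expect_lt(max(abs(w$boundaries$ph - c(2.79, 3.15, 3.57, 5.05))), 0.011)
  expect_identical(w$formatted_range, "2.79-5.05")

  fe <- window_of(db, "Fe", "NTA")
  expect_lt(abs(fe$boundaries$ph[1] - 0.30), 0.011)

  # boundaries strictly increase with f for every bundled pair
  for (i in seq_len(nrow(db$complexes))) {
    row <- db$complexes[i, ]
    b <- window_of(db, row$metal_id, row$ligand_id)$boundaries
    ph <- b$ph[b$status == "ok"]
    expect_true(all(diff(ph) > 0),
                info = paste(row$metal_id, row$ligand_id))
  }
})

test_that("windows type their degenerate outcomes", {
  db <- builtin_table4()
  expect_identical(window_of(db, "Cd", "GLDA")$status, "missing_pair")

  # a hopeless chelator: constant below the 25 % requirement
  weak <- constants_db(
    ligands = list(ligand_record("WK", c(9, 11))),
    metals = list(metal_record("Cd", 2, 112.41)),
    complexes = list(complex_record("Cd", "WK", 1.0))
  )
  w <- window_of(weak, "Cd", "WK")
  expect_true(all(w$boundaries$status == "unattainable"))
  expect_identical(w$formatted_range, "n.a.")
  expect_true(all(is.na(w$boundaries$ph)))

  # calcium with the weak diglutamate binder only starts above the cap
  ca <- window_of(db, "Ca", "EDDG")
  expect_identical(ca$boundaries$status[1], "above_cap")
  # very strong pairs begin below pH 0: formatted with the floor marker
  fe <- window_of(db, "Fe", "EDTA")
  expect_identical(fe$boundaries$status[1], "below_range")
  expect_match(fe$formatted_range, "^<0-")
})

test_that("published windows for the well-behaved ligand panel reproduce", {
  # the published screening table for NTA, EDDG, EDDS and EDTA; the HIMDA
  # column of that table is internally inconsistent with any single D(H)
  # curve and is checked only for metal ordering below. Two further printed
  # cells do not recompute from the bundled constants and are excluded here:
  # the Pb-NTA lower bound (1.84 printed, 1.95 recomputed) and the Ca-EDDG
  # lower bound (9.93 printed, 10.25 recomputed, beyond the display cap).
  db <- builtin_table4()
  sub <- expected_windows[expected_windows$ligand != "HIMDA", ]
  irreproducible_lower <- c("Pb-NTA", "Ca-EDDG")
  for (i in seq_len(nrow(sub))) {
    e <- sub[i, ]
    lo <- raw_boundary_ph(db, e$metal, e$ligand, 0.25)
    hi <- raw_boundary_ph(db, e$metal, e$ligand, 0.99)
    if (!is.na(e$lower) &&
        !(paste(e$metal, e$ligand, sep = "-") %in% irreproducible_lower)) {
      expect_true(!is.na(lo) && abs(lo - e$lower) <= 0.1,
                  info = sprintf("%s-%s lower", e$metal, e$ligand))
    }
    if (!is.na(e$upper)) {
      expect_true(!is.na(hi) && abs(hi - e$upper) <= 0.1,
                  info = sprintf("%s-%s upper", e$metal, e$ligand))
    }
  }
  # HIMDA: the published metal ordering still holds
  lo_himda <- vapply(c("Cu", "Fe", "Pb", "Zn", "Cd", "Mn", "Ca"), function(m)
    raw_boundary_ph(db, m, "HIMDA", 0.25), 1)
  expect_true(all(diff(lo_himda[c("Fe", "Pb", "Zn", "Cd", "Mn", "Ca")]) > 0))
})

test_that("screen assembles, orders and formats the window matrix", {
  db <- builtin_table4()
  panel <- c("NTA", "HIMDA", "EDDG", "EDDS", "EDTA")
  heavy <- c("Ca", "Cd", "Cu", "Fe", "Hg", "Mn", "Pb", "Zn")  # unordered input
  scr <- screen_quiet(db, metals = heavy, ligands = panel)
  # ordering by the 25 % boundary of the reference ligand (NTA)
  expect_identical(scr$metals[1], "Fe")
  expect_identical(scr$metals[length(scr$metals)], "Ca")
  expect_true(which(scr$metals == "Hg") < which(scr$metals == "Cd"))

  txt <- format_screen_text(scr)
  expect_match(txt[1], "^metal\\s+NTA\\s+HIMDA")
  expect_match(txt[2], "^Fe\\b")
  expect_true(any(grepl("2.79-5.05", txt, fixed = TRUE)))
  # mixed-media comparison emits a note
  expect_message(screen(db, metals = heavy, ligands = panel), "different media")

  # empty requests give empty results
  empty <- screen_quiet(db, metals = character(0))
  expect_identical(nrow(empty$table), 0L)
  expect_length(empty$windows, 0)

  path <- withr::local_tempfile(fileext = ".csv")
  write_screen_csv(scr, path)
  back <- utils::read.csv(path)
  expect_named(back, c("metal", "ligand", "f", "ph", "status"))
  expect_gt(nrow(back), 100)
})

test_that("screening is deterministic and EDTA dominates the panel", {
  db <- builtin_table4()
  panel <- c("NTA", "HIMDA", "EDDG", "EDDS", "EDTA")
  a <- format_screen_text(screen_quiet(db, ligands = panel))
  b <- format_screen_text(screen_quiet(db, ligands = panel))
  expect_identical(a, b)

  # EDTA complexes every metal at the lowest pH of any bundled ligand, with
  # one real exception: copper, whose iminodiacetate-type binders (HIMDA,
  # MNTA) start complexing 0.2 pH below EDTA. The screening conclusion
  # carves copper out explicitly, so the exception is asserted, not skipped.
  exceptions <- list(c("Cu", "HIMDA"), c("Cu", "MNTA"))
  for (m in unique(db$complexes$metal_id)) {
    e <- raw_boundary_ph(db, m, "EDTA", 0.25)
    edta25 <- if (is.na(e)) -2 else e  # Fe-EDTA crosses below the pH floor
    for (l in setdiff(names(db$ligands), "EDTA")) {
      o <- raw_boundary_ph(db, m, l, 0.25)
      if (is.na(o)) next
      if (list(c(m, l)) %in% exceptions) {
        expect_lt(o, edta25, label = sprintf("%s-%s exception", m, l))
      } else {
        expect_lte(edta25, o, label = sprintf("EDTA vs %s for %s", l, m))
      }
    }
  }
})

test_that("larger ligand excess shifts windows to lower pH", {
  db <- builtin_table4()
  lig <- db_ligand(db, "NTA")
  for (f in c(0.25, 0.99)) {
    ph <- vapply(c(2, 10, 50, 100), function(r)
      ph_for_fraction(9.8, lig, f, 2e-5, r)$ph, 1)
    expect_true(all(diff(ph) < 0))
  }
})

test_that("ligand ranking uses the 25 percent boundary with width tie-break", {
  db <- builtin_table4()
  scr <- screen_quiet(db, metals = "Cd",
                      ligands = c("NTA", "HIMDA", "EDDS", "EDTA"))
  rk <- rank_ligands(scr, "Cd")
  expect_identical(rk$ligand[1], "EDTA")
  expect_identical(rk$ligand[nrow(rk)], "EDDS")
  expect_true(all(diff(rk$ph25) >= 0))
})

test_that("soil levels convert to suspension molarity as published", {
  sg <- soil_guidelines()
  expect_identical(sg$metal_id, expected_soil$metal)
  got_mm <- soil_to_molar(sg$intervention_mg_kg, sg$atomic_weight)
  expect_equal(round(got_mm, 1), expected_soil$intervention_mm)
  expect_equal(round(soil_to_molar(210, 207.20), 1), 1.0)  # Pb
  expect_equal(soil_to_molar(0, 200.59), 0)
  # denser suspensions scale linearly
  expect_equal(soil_to_molar(530, 200.59, suspension = 2),
               2 * soil_to_molar(530, 200.59))
  expect_error(soil_to_molar(10, 0), "atomic_weight")
  expect_error(soil_to_molar(-1, 10), ">= 0")
})

test_that("soil scenarios carry through to screening scenarios", {
  db <- builtin_table4()
  hg <- soil_scenario(db_metal(db, "Hg"), level_mg_per_kg = 530, ratio = 50)
  expect_equal(hg$molar_mm, 530 / 200.59)
  scn <- scenario_from_soil(hg)
  expect_equal(scn$m_total, 530 / 200.59 / 1000)  # 2.642e-3 mol/L
  expect_equal(scn$ratio, 50)
  expect_error(soil_scenario(db_metal(db, "Hg"), 0), "level")
})
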