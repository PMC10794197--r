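models <- default_property_models()
tg <- lexicon_tagger(character(0))

tagged <- function(txt) tag_cems(segment_sentences(txt)[[1]], tg)

test_that("sentence templates extract property, value, unit and compound", {
  recs <- parse_sentence(tagged("The delayed lifetime of 2CzPN is 3.2 μs."),
                         models$tau_d,
                         provenance = list(doc_id = "d", element_index = 1L,
                                           sentence_index = 1L))
  expect_length(recs, 1)
  expect_identical(recs[[1]]$property_id, "tau_d")
  expect_equal(recs[[1]]$quantity$values, 3.2)
  expect_identical(recs[[1]]$quantity$unit, "μs")
  expect_identical(recs[[1]]$compound$names, "2CzPN")
  expect_identical(recs[[1]]$provenance$parser, "sentence")

  # no specifier -> no record
  expect_length(parse_sentence(tagged("The device efficiency was 20%."),
                               models$plqy), 0)

  recs3 <- parse_sentence(
    tagged("ΔEST of 4CzIPN was measured to be 0.05 eV at 300 K."),
    models$delta_e_st
  )
  expect_length(recs3, 1)
  expect_equal(recs3[[1]]$standard_value, 0.05)
  expect_identical(recs3[[1]]$compound$names, "4CzIPN")
})

test_that("temperature phrases are captured into extra fields", {
  r1 <- parse_sentence(tagged("The delayed lifetime of 2CzPN is 3.2 μs at 77 K."),
                       models$tau_d)[[1]]
  expect_equal(r1$extra$temperature, 77)
  r2 <- parse_sentence(
    tagged("The delayed lifetime of 2CzPN is 3.2 μs at room temperature."),
    models$tau_d
  )[[1]]
  expect_true(r2$extra$room_temperature)
})

test_that("cell serialization joins headers outer-to-inner with the separator", {
  expect_identical(CELL_SEPARATOR, strrep("\U0001F643", 4))
  tab <- fixture_table(list(c("τd (μs)")), list(c("3.2")))
  expect_identical(serialize_cell(tab, 1, 1),
                   paste0("τd (μs)", CELL_SEPARATOR, "3.2"))
  tab2 <- fixture_table(
    list(c("1" = "Photophysics"), c("ΦPL (%)")),
    list(c("68"))
  )
  expect_identical(
    serialize_cell(tab2, 1, 1),
    paste0("Photophysics", CELL_SEPARATOR, "ΦPL (%)", CELL_SEPARATOR, "68")
  )
  expect_error(serialize_cell(tab, 2, 1), "out of range")
  # empty cell serializes to a trailing empty segment and parses to nothing
  tab3 <- fixture_table(list(c("λem (nm)")), list(c("")))
  cs <- serialize_cell(tab3, 1, 1)
  expect_true(endsWith(cs, CELL_SEPARATOR))
  expect_length(parse_cell(cs, models$lambda_em), 0)
})

test_that("generic cell parser is first-come-first-served with header units", {
  recs <- parse_cell(cell_string("λem (nm)", "470"), models$lambda_em, "2CzPN")
  expect_length(recs, 1)
  expect_equal(recs[[1]]$standard_value, 470)
  expect_identical(recs[[1]]$compound$names, "2CzPN")

  # first compatible number wins
  recs2 <- parse_cell(cell_string("λem (nm)", "470, 3.2"), models$lambda_em)
  expect_equal(recs2[[1]]$quantity$values, 470)

  # no specifier in headers -> no record
  expect_length(parse_cell(cell_string("Year", "2019"), models$lambda_em), 0)
})

test_that("combined singlet/triplet/splitting cells parse positionally", {
  recs <- parse_combined_est_cell(cell_string("ES/ET/ΔEST (eV)", "3.0/2.9/0.1"))
  expect_length(recs, 1)
  expect_identical(recs[[1]]$property_id, "delta_e_st")
  expect_equal(recs[[1]]$standard_value, 0.1)
  expect_identical(recs[[1]]$provenance$parser, "combined_est")
  expect_null(recs[[1]]$extra$consistency_warning)

  # field-count mismatch -> no record
  expect_length(
    parse_combined_est_cell(cell_string("ES/ET/ΔEST (eV)", "3.0/2.9")), 0
  )

  # inconsistent energies raise the warning flag
  recs3 <- parse_combined_est_cell(cell_string("ES/ET/ΔEST (eV)", "3.0/2.9/0.5"))
  expect_equal(recs3[[1]]$standard_value, 0.5)
  expect_true(recs3[[1]]$extra$consistency_warning)
})

test_that("fractional quantum-yield cells convert to percent", {
  recs <- parse_fractional_plqy_cell(cell_string("ΦPL", "0.68"))
  expect_length(recs, 1)
  expect_equal(recs[[1]]$standard_value, 68)
  expect_identical(recs[[1]]$provenance$parser, "fractional_plqy")

  # percent-labelled cells defer to the generic parser
  expect_length(parse_fractional_plqy_cell(cell_string("ΦPL (%)", "68")), 0)
  recs2 <- parse_cell(cell_string("ΦPL (%)", "68"), models$plqy)
  expect_equal(recs2[[1]]$standard_value, 68)

  # boundary value 1.0 -> 100 %
  recs3 <- parse_fractional_plqy_cell(cell_string("ΦPL", "1.0"))
  expect_equal(recs3[[1]]$standard_value, 100)
})

test_that("shared lifetime cells emit only the delayed-lifetime slot", {
  recs <- parse_shared_lifetime_cell(cell_string("τp/τd (ns/μs)", "25/3.2"))
  expect_length(recs, 1)
  expect_identical(recs[[1]]$property_id, "tau_d")
  expect_equal(recs[[1]]$standard_value, 3.2)
  expect_identical(recs[[1]]$quantity$unit, "μs")

  recs2 <- parse_shared_lifetime_cell(cell_string("λem/τd (nm/μs)", "470/3.2"))
  expect_equal(recs2[[1]]$standard_value, 3.2)

  # prompt-lifetime-only cell yields no delayed-lifetime record
  expect_length(parse_shared_lifetime_cell(cell_string("τp (ns)", "25")), 0)
  # alignment failure -> no record
  expect_length(
    parse_shared_lifetime_cell(cell_string("τp/τd (ns/μs)", "25")), 0
  )
})

test_that("special parsers claim header patterns exclusively in dispatch", {
  tab <- fixture_table(
    list(c("Compounds", "ES/ET/ΔEST (eV)", "ΦPL", "τp/τd (ns/μs)")),
    list(c("2CzPN", "3.0/2.9/0.1", "0.68", "25/3.2"))
  )
  recs <- parse_table(tab, models)
  parsers <- vapply(recs, function(r) r$provenance$parser, character(1))
  props <- vapply(recs, function(r) r$property_id, character(1))
  # one record per cell, each from its dedicated parser
  expect_length(recs, 3)
  expect_setequal(parsers, c("combined_est", "fractional_plqy",
                             "shared_lifetime"))
  expect_false(any(duplicated(paste(props, vapply(recs, function(r)
    paste(r$provenance$cell, collapse = ","), character(1))))))
  # all rows carry the row compound
  expect_true(all(vapply(recs, function(r) "2CzPN" %in% r$compound$names,
                         logical(1))))
})
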