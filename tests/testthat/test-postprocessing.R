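mk_rec <- function(property_id, std, unit = NULL, extra = list(),
                   parser = "sentence") {
  units <- c(lambda_em = "nm", plqy = "%", delta_e_st = "eV", tau_d = "μs")
  structure(list(
    property_id = property_id,
    quantity = structure(list(values = std, unit = unit %||% units[[property_id]],
                              raw_text = NULL), class = "tadf_quantity"),
    standard_value = std, compound = list(names = "2CzPN", labels = character(0)),
    extra = extra,
    provenance = list(doc_id = "d", element_index = 1L, parser = parser)
  ), class = "tadf_candidate")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("physical-range bounds are exclusive except the inclusive PLQY", {
  expect_false(filter_physical_range(mk_rec("lambda_em", 250))$keep)
  expect_true(filter_physical_range(mk_rec("lambda_em", 470))$keep)
  expect_false(filter_physical_range(mk_rec("lambda_em", 300))$keep)
  expect_false(filter_physical_range(mk_rec("lambda_em", 1600))$keep)
  expect_true(filter_physical_range(mk_rec("plqy", 100))$keep)
  expect_true(filter_physical_range(mk_rec("plqy", 0))$keep)
  expect_false(filter_physical_range(mk_rec("plqy", 100.1))$keep)
  expect_true(filter_physical_range(mk_rec("delta_e_st", -0.2))$keep)
  expect_false(filter_physical_range(mk_rec("delta_e_st", 1.5))$keep)
  expect_false(filter_physical_range(mk_rec("tau_d", 0.05))$keep)  # 50 ns
  expect_true(filter_physical_range(mk_rec("tau_d", 0.2))$keep)    # 200 ns
  expect_false(filter_physical_range(mk_rec("tau_d", 1e7))$keep)   # 10 s
  # a range quantity drops when either endpoint violates
  expect_false(filter_physical_range(mk_rec("lambda_em", c(290, 400)))$keep)
})

test_that("every record surviving the filter satisfies its printed bounds", {
  withr::with_seed(17, {
    recs <- replicate(300, random_clean_record(), simplify = FALSE)
    out <- postprocess_records(recs)$records
    for (r in out) {
      v <- r$standard_value
      switch(r$property_id,
        lambda_em = expect_true(all(v > 300 & v < 1600)),
        plqy = expect_true(all(v >= 0 & v <= 100)),
        delta_e_st = expect_true(all(v > -1.5 & v < 1.5)),
        tau_d = expect_true(all(v > 0.1 & v < 1e7))
      )
    }
    # filtering is idempotent
    again <- postprocess_records(out)$records
    expect_length(again, length(out))
  })
})

test_that("room-temperature flags standardize to 293 K with explicit priority", {
  r1 <- standardize_temperature(
    mk_rec("tau_d", 3.2, extra = list(room_temperature = TRUE))
  )
  expect_equal(r1$extra$temperature, 293)
  r2 <- standardize_temperature(
    mk_rec("tau_d", 3.2, extra = list(room_temperature = TRUE,
                                      temperature = 77))
  )
  expect_equal(r2$extra$temperature, 77)
  r3 <- standardize_temperature(mk_rec("tau_d", 3.2))
  expect_null(r3$extra$temperature)
  # non-physical temperature drops the record
  expect_null(standardize_temperature(
    mk_rec("tau_d", 3.2, extra = list(temperature = -5))
  ))
  # other properties never gain a temperature field
  r4 <- standardize_temperature(
    mk_rec("plqy", 68, extra = list(room_temperature = TRUE))
  )
  expect_null(r4$extra$temperature)
})

test_that("classifier context joins section, first sentence and record sentence", {
  r <- mk_rec("delta_e_st", 0.09, extra = list(
    section = "Photophysical properties",
    first_sentence = "All emitters were measured in toluene.",
    sentence_text = "ΔEST of 2CzPN is 0.09 eV."
  ))
  expect_identical(
    build_classifier_context(r),
    paste("Photophysical properties",
          "All emitters were measured in toluene.",
          "ΔEST of 2CzPN is 0.09 eV.")
  )
  # record sentence that IS the first sentence appears once
  r2 <- mk_rec("delta_e_st", 0.09, extra = list(
    section = "Results", first_sentence = "ΔEST of 2CzPN is 0.09 eV.",
    sentence_text = "ΔEST of 2CzPN is 0.09 eV."
  ))
  expect_identical(build_classifier_context(r2),
                   "Results ΔEST of 2CzPN is 0.09 eV.")
  # standalone table records have no context
  r3 <- mk_rec("delta_e_st", 0.09, parser = "table_cell")
  expect_null(build_classifier_context(r3))
})

test_that("keyword classifier distinguishes computed from measured splittings", {
  expect_false(classify_is_experimental("TD-DFT calculations gave the gap"))
  expect_true(classify_is_experimental(
    "estimated from the onsets of fluorescence and phosphorescence spectra"
  ))
  expect_true(is.na(classify_is_experimental("The gap is small.")))
  expect_true(is.na(classify_is_experimental(NULL)))
  # conflicting cues stay unknown
  expect_true(is.na(classify_is_experimental(
    "measured values agree with DFT calculations"
  )))
  # table-only records always carry unknown through postprocessing
  out <- postprocess_records(list(mk_rec("delta_e_st", 0.1,
                                         parser = "table_cell")))$records
  expect_true(is.na(out[[1]]$extra$is_experimental))
})

test_that("phase and atmosphere keywords are scanned from the source text", {
  expect_identical(extract_phase("measured in a doped film"), "doped film")
  expect_identical(extract_atmosphere("under nitrogen"), "nitrogen")
  expect_identical(extract_atmosphere("in air"), "air")
  expect_identical(extract_atmosphere("on a substrate"), "unknown")
  r <- postprocess_records(list(
    mk_rec("plqy", 68, extra = list(sentence_text =
      "The PLQY of 2CzPN is 68% in a doped film under nitrogen."))
  ))$records[[1]]
  expect_identical(r$extra$phase, "doped film")
  expect_identical(r$extra$atmosphere, "nitrogen")
})
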