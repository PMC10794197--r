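test_that("sentence segmentation splits on terminators but not abbreviations", {
  expect_length(segment_sentences("A. B."), 2)
  expect_length(segment_sentences(""), 0)
  ss <- segment_sentences("The PLQY is 68%. The τd is 3.2 μs.")
  expect_length(ss, 2)
  expect_match(ss[[1]]$text, "68")
  expect_match(ss[[2]]$text, "3.2")
  # abbreviating periods do not split
  expect_length(segment_sentences("See Fig. 3 for details."), 1)
  expect_length(segment_sentences("A value of approx. 5 nm was found."), 1)
  # decimal points do not split
  expect_length(segment_sentences("The value 3.2 was reported."), 1)
})

test_that("segmentation offsets reconstruct the paragraph", {
  paras <- c(
    "First sentence. Second sentence! Third?",
    "One only",
    "The τd is 3.2 μs. The PLQY is 68%."
  )
  for (p in paras) {
    for (s in segment_sentences(p)) {
      expect_identical(substr(p, s$start + 1, s$end), s$text)
    }
  }
})

test_that("lexicon tagger finds names and morphology-shaped tokens", {
  tg <- lexicon_tagger(c("toluene", "2CzPN"))
  s <- tag_cems(segment_sentences("2CzPN was dissolved in toluene.")[[1]], tg)
  expect_length(s$cem_spans, 2)
  # empty lexicon, no morphology hit
  tg0 <- lexicon_tagger(character(0))
  s0 <- tag_cems(segment_sentences("The film was annealed.")[[1]], tg0)
  expect_length(s0$cem_spans, 0)
  # morphology rule alone tags the 4CzIPN shape
  s1 <- tag_cems(segment_sentences("The emitter 4CzIPN emits blue.")[[1]], tg0)
  expect_length(s1$cem_spans, 1)
  expect_identical(s1$cem_spans[[1]]$name, "4CzIPN")
  # specifier-like tokens are not tagged
  s2 <- tag_cems(segment_sentences("The PLQY and TADF results agree.")[[1]], tg0)
  expect_length(s2$cem_spans, 0)
})

test_that("tagging is deterministic and spans are valid and sorted", {
  tg <- lexicon_tagger(c("toluene"))
  txt <- "4CzIPN and 2CzPN in toluene with 5AcTRZ."
  s1 <- tag_cems(segment_sentences(txt)[[1]], tg)
  s2 <- tag_cems(segment_sentences(txt)[[1]], tg)
  expect_identical(s1$cem_spans, s2$cem_spans)
  starts <- vapply(s1$cem_spans, function(x) x$start, integer(1))
  ends <- vapply(s1$cem_spans, function(x) x$end, integer(1))
  expect_true(all(diff(starts) > 0))
  expect_true(all(ends <= nchar(txt)))
  for (sp in s1$cem_spans) {
    expect_identical(substr(txt, sp$start + 1, sp$end), sp$name)
  }
})

test_that("bracket and equality abbreviation rules fire on tagged CEMs", {
  tg <- lexicon_tagger(character(0))
  long <- "4,5-Bis(carbazol-9-yl)-1,2-dicyanobenzene"

  s <- tag_cems(segment_sentences(paste0(long, " (2CzPN) was made."))[[1]], tg)
  pairs <- detect_abbreviations(s)
  expect_length(pairs, 1)
  expect_identical(pairs[[1]]$short_form, "2CzPN")
  expect_identical(pairs[[1]]$long_form, long)
  expect_identical(pairs[[1]]$evidence, "brackets")

  s2 <- tag_cems(segment_sentences(paste0("2CzPN = ", long))[[1]], tg)
  pairs2 <- detect_abbreviations(s2)
  expect_true(any(vapply(pairs2, function(p) {
    p$short_form == "2CzPN" && p$long_form == long && p$evidence == "equality"
  }, logical(1))))

  # non-adjacent bracketed word is not an abbreviation
  s3 <- tag_cems(segment_sentences("2CzPN. The film (blue) was cast.")[[1]], tg)
  expect_length(detect_abbreviations(s3), 0)
})

test_that("letters-in-order rule covers non-chemical acronyms", {
  tg <- lexicon_tagger(character(0))
  s <- tag_cems(segment_sentences(
    "thermally activated delayed fluorescence (TADF) is exploited.")[[1]], tg)
  pairs <- detect_abbreviations(s)
  expect_length(pairs, 1)
  expect_identical(pairs[[1]]$short_form, "TADF")
  expect_identical(pairs[[1]]$long_form,
                   "thermally activated delayed fluorescence")
  expect_identical(pairs[[1]]$evidence, "letters-in-order")
})

test_that("every emitted pair has a strictly shorter short form", {
  tg <- lexicon_tagger(c("toluene"))
  texts <- c(
    "4,5-Bis(carbazol-9-yl)-1,2-dicyanobenzene (2CzPN) was made.",
    "reverse intersystem crossing (RISC) is fast.",
    "5AcTRZ = 2,3-Bis(acridin-9-yl)-4,5-dicyanopyridine",
    "The device (OLED) works."
  )
  for (txt in texts) {
    s <- tag_cems(segment_sentences(txt)[[1]], tg)
    for (p in detect_abbreviations(s)) {
      expect_lt(nchar(p$short_form), nchar(p$long_form))
    }
  }
})

test_that("bracket rule subsumes letters-in-order pairs whose long form is a CEM", {
  # when the long form is a tagged chemical name, the CEM bracket rule finds
  # the pair even where initials are NOT in order (the motivating failure of
  # the classic rule)
  tg <- lexicon_tagger(character(0))
  long <- "4,5-Bis(carbazol-9-yl)-1,2-dicyanobenzene"
  s <- tag_cems(segment_sentences(paste0(long, " (2CzPN)."))[[1]], tg)
  pairs <- detect_abbreviations(s)
  expect_true(any(vapply(pairs, function(p) p$long_form == long, logical(1))))
})
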