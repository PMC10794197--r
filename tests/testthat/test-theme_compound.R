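test_that("frequency table counts each name once per document", {
  stream <- data.frame(
    doc_id = c(rep("a", 5), "b", "c"),
    name = c(rep("toluene", 5), "toluene", "toluene")
  )
  ft <- build_frequency_table(stream)
  expect_identical(unname(ft$counts["toluene"]), 3L)
  expect_identical(ft$n_documents, 3L)

  one <- build_frequency_table(data.frame(doc_id = rep("a", 5),
                                          name = rep("toluene", 5)))
  expect_identical(unname(one$counts["toluene"]), 1L)

  empty <- build_frequency_table(data.frame(doc_id = character(0),
                                            name = character(0)))
  expect_length(empty$counts, 0)
})

test_that("frequency counts equal a brute-force oracle on random streams", {
  withr::with_seed(23, {
    for (rep in 1:5) {
      docs <- paste0("doc", 1:8)
      names <- c("toluene", "2CzPN", "benzene", "THF", "4CzIPN")
      stream <- data.frame(
        doc_id = sample(docs, 200, replace = TRUE),
        name = sample(names, 200, replace = TRUE)
      )
      ft <- build_frequency_table(stream)
      for (nm in unique(stream$name)) {
        oracle <- length(unique(stream$doc_id[stream$name == nm]))
        expect_identical(unname(ft$counts[nm]), oracle)
      }
    }
  })
})

test_that("blocklist threshold scales by ceiling of the corpus fraction", {
  mk_freq <- function(counts, n) {
    structure(list(counts = counts, n_documents = n),
              class = "tadf_frequency_table")
  }
  # seven or more out of 1200 blocklisted, six is not
  ft <- mk_freq(c(common = 7L, rare = 6L), 1200L)
  bl <- build_blocklist(ft, 7 / 1200)
  expect_true("common" %in% bl$entries)
  expect_false("rare" %in% bl$entries)
  # half-size corpus: cut-off ceil(3.5) = 4
  ft2 <- mk_freq(c(four = 4L, three = 3L), 600L)
  bl2 <- build_blocklist(ft2, 7 / 1200)
  expect_true("four" %in% bl2$entries)
  expect_false("three" %in% bl2$entries)
  # degenerate cut-off below 2 warns
  ft3 <- mk_freq(c(x = 1L), 20L)
  expect_warning(build_blocklist(ft3, 7 / 1200), "cut-off below 2")
})

test_that("lowering the threshold never shrinks the frequency entry set", {
  withr::with_seed(31, {
    counts <- setNames(sample(1:40, 30, replace = TRUE),
                       paste0("cem", 1:30))
    ft <- structure(list(counts = counts, n_documents = 40L),
                    class = "tadf_frequency_table")
    fracs <- sort(runif(6, 0.05, 0.9))
    entry_sets <- lapply(fracs, function(f) {
      suppressWarnings(build_blocklist(ft, f))$entries
    })
    for (i in seq_len(length(fracs) - 1)) {
      expect_true(all(entry_sets[[i + 1]] %in% entry_sets[[i]]))
    }
  })
})

test_that("name rules block fragment suffixes, morphology and hard patterns", {
  expect_identical(apply_name_rules("amino")$verdict, "block")
  expect_identical(apply_name_rules("phenyl")$verdict, "block")
  expect_identical(apply_name_rules("pyridine-based")$verdict, "block")
  expect_identical(apply_name_rules("2CzPN")$verdict, "allow")
  expect_identical(
    apply_name_rules(paste0("junk", CELL_SEPARATOR, "cell"))$verdict, "block"
  )
  doc <- fixture_doc(basic_article())
  expect_identical(apply_name_rules("x 10.5555/test.001 y", doc)$verdict,
                   "block")
  expect_identical(
    apply_name_rules("pyridine", following_text = "-based emitters")$verdict,
    "block"
  )
  # allowlist overrides any rule
  expect_identical(
    apply_name_rules("amino", allowlist = "amino")$verdict, "allow"
  )
  expect_identical(
    apply_name_rules("DMAC-TRZ", allowlist = "DMAC-TRZ")$verdict, "allow"
  )
})

test_that("label rules block dates, states, units, percents and long strings", {
  expect_identical(apply_label_rules("15%")$verdict, "block")
  expect_identical(apply_label_rules("5 wt %")$verdict, "block")
  expect_identical(apply_label_rules("ABCDE")$verdict, "block")
  expect_identical(apply_label_rules("T1")$verdict, "block")
  expect_identical(apply_label_rules("S0")$verdict, "block")
  expect_identical(apply_label_rules("nm")$verdict, "block")
  expect_identical(apply_label_rules("3a")$verdict, "allow")
})

test_that("theme registry resolves nearest compound and resets per document", {
  reg <- new_theme_registry("d1")
  registry_add(reg, "2CzPN", "name", element_index = 2L, token_offset = 0L)
  registry_add(reg, "4CzIPN", "name", element_index = 2L, token_offset = 80L)
  rec <- structure(list(
    property_id = "plqy",
    quantity = structure(list(values = 68, unit = "%", raw_text = NULL),
                         class = "tadf_quantity"),
    standard_value = 68, compound = NULL, extra = list(),
    provenance = list(doc_id = "d1", element_index = 2L,
                      specifier_offset = 30L)
  ), class = "tadf_candidate")
  out <- resolve_compound(rec, reg)
  expect_identical(out$compound$names, "2CzPN")   # nearer (30 vs 50)

  # record in an element with no theme compound is dropped
  rec2 <- rec; rec2$provenance$element_index <- 5L
  expect_null(resolve_compound(rec2, reg))

  registry_reset(reg)
  expect_length(reg$entries, 0)
  expect_null(resolve_compound(rec, reg))
})

test_that("ties in resolution distance break toward the preceding compound", {
  reg <- new_theme_registry("d1")
  registry_add(reg, "before", "name", element_index = 1L, token_offset = 10L)
  registry_add(reg, "after", "name", element_index = 1L, token_offset = 30L)
  rec <- structure(list(
    property_id = "plqy",
    quantity = structure(list(values = 1, unit = "%", raw_text = NULL),
                         class = "tadf_quantity"),
    standard_value = 1, compound = NULL, extra = list(),
    provenance = list(doc_id = "d1", element_index = 1L,
                      specifier_offset = 20L)
  ), class = "tadf_candidate")
  expect_identical(resolve_compound(rec, reg)$compound$names, "before")
})

test_that("document outputs are invariant to processing order", {
  dir <- shared_corpus()
  paths <- list.files(file.path(dir, "docs"), full.names = TRUE)[1:3]
  cfg <- pipeline_config(lexicon = file.path(dir, "lexicon.txt"),
                         threshold_fraction = 0.25)
  read1 <- function(p) read_document(p, if (endsWith(p, ".html"))
    "html-like" else "xml-like")
  # extract B alone, then A then B: identical outputs for B
  b_alone <- extract_document(read1(paths[2]), cfg)$records
  invisible(extract_document(read1(paths[1]), cfg))
  b_after <- extract_document(read1(paths[2]), cfg)$records
  expect_identical(b_alone, b_after)
})

test_that("no emitted record's compound is blocklisted unless allowlisted", {
  out <- shared_pipeline_result()
  bl <- out$result$blocklist
  for (r in out$result$records) {
    for (nm in r$compound$names) {
      expect_false(tolower(normalize_name(nm)) %in% tolower(bl$entries))
    }
  }
})
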