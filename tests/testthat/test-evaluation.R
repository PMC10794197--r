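gold_like <- function(property_id, std, names, doc = "d1", temp = NULL,
                      unit = NULL) {
  units <- c(lambda_em = "nm", plqy = "%", delta_e_st = "eV", tau_d = "μs")
  extra <- list(); if (!is.null(temp)) extra$temperature <- temp
  structure(list(
    property_id = property_id,
    quantity = structure(list(values = std,
                              unit = if (is.null(unit)) units[[property_id]] else unit,
                              raw_text = NULL), class = "tadf_quantity"),
    standard_value = std,
    compound = list(names = names, labels = character(0)),
    extra = extra,
    provenance = list(doc_id = doc, parser = "x")
  ), class = "tadf_candidate")
}

test_that("metric arithmetic follows the defining ratios and conventions", {
  m <- compute_metrics(5, 0, 0)
  expect_equal(unlist(m), c(precision = 1, recall = 1, f_score = 1))
  m0 <- compute_metrics(0, 3, 2)
  expect_equal(unlist(m0), c(precision = 0, recall = 0, f_score = 0))
  # harmonic mean sits between precision and recall
  withr::with_seed(3, {
    for (i in 1:30) {
      tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
      mm <- compute_metrics(tp, fp, fn)
      if (mm$precision + mm$recall > 0) {
        expect_gte(mm$f_score, min(mm$precision, mm$recall) - 1e-12)
        expect_lte(mm$f_score, max(mm$precision, mm$recall) + 1e-12)
      }
    }
  })
})

test_that("three-clause matching judges value+unit, compound, temperature", {
  g <- gold_like("tau_d", 3.2, "2CzPN", temp = 300)
  # full agreement -> TP
  m <- match_records(list(gold_like("tau_d", 3.2, "2CzPN", temp = 300)), list(g))
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))
  # wrong standardized value (unit error) -> FP + FN
  bad_unit <- gold_like("tau_d", 3.2e-3, "2CzPN", temp = 300, unit = "ns")
  m2 <- match_records(list(bad_unit), list(g))
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0, 1, 1))
  # wrong temperature on a delayed-lifetime record -> FP + FN
  m3 <- match_records(list(gold_like("tau_d", 3.2, "2CzPN", temp = 77)), list(g))
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(0, 1, 1))
  # gold fact never extracted -> FN
  m4 <- match_records(list(), list(g))
  expect_equal(c(m4$tp, m4$fp, m4$fn), c(0, 0, 1))
  # temperature clause only binds delayed lifetimes
  g2 <- gold_like("plqy", 68, "2CzPN")
  e2 <- gold_like("plqy", 68, "2CzPN"); e2$extra$temperature <- 300
  expect_equal(match_records(list(e2), list(g2))$tp, 1)
})

test_that("matching is per-document and one-to-one", {
  g <- list(gold_like("plqy", 68, "A", doc = "d1"),
            gold_like("plqy", 68, "A", doc = "d2"))
  e <- list(gold_like("plqy", 68, "A", doc = "d1"))
  m <- match_records(e, g)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 1))
  # two identical extractions cannot both claim one gold record
  e2 <- list(gold_like("plqy", 68, "A", doc = "d1"),
             gold_like("plqy", 68, "A", doc = "d1"))
  m2 <- match_records(e2, list(g[[1]]))
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1, 1, 0))
})

test_that("swapping extracted and gold swaps FP and FN", {
  withr::with_seed(5, {
    mk <- function(n, doc) lapply(seq_len(n), function(i) {
      gold_like("plqy", sample(1:99, 1), sample(LETTERS, 1), doc = doc)
    })
    a <- c(mk(8, "d1"), mk(5, "d2"))
    b <- c(mk(6, "d1"), mk(7, "d2"))
    m_ab <- match_records(a, b)
    m_ba <- match_records(b, a)
    expect_equal(m_ab$tp, m_ba$tp)
    expect_equal(m_ab$fp, m_ba$fn)
    expect_equal(m_ab$fn, m_ba$fp)
  })
})

test_that("accumulative curves end at the overall metric for any order", {
  flat <- accumulative_curves(rep(TRUE, 10), n_orders = 5, seed = 9)
  expect_true(all(vapply(flat$curves, function(cv) all(cv == 1), logical(1))))

  two <- accumulative_curves(c(TRUE, FALSE), n_orders = 1, seed = 1)
  expect_setequal(round(two$curves[[1]], 10), round(c(1, 0.5), 10))

  withr::with_seed(13, {
    for (i in 1:10) {
      labels <- runif(sample(5:40, 1)) < runif(1)
      cv <- accumulative_curves(labels, n_orders = 5, seed = i)
      finals <- vapply(cv$curves, function(x) x[length(x)], numeric(1))
      expect_true(all(abs(finals - mean(labels)) < 1e-12))
      expect_equal(cv$mean_curve[length(cv$mean_curve)], mean(labels))
    }
  })
  expect_error(accumulative_curves(c(TRUE), n_orders = 0), "n_orders")
})

test_that("curves are bit-for-bit reproducible under a fixed seed", {
  labels <- rep(c(TRUE, TRUE, FALSE), 10)
  a <- accumulative_curves(labels, n_orders = 5, seed = 99)
  b <- accumulative_curves(labels, n_orders = 5, seed = 99)
  expect_identical(a, b)
  c2 <- accumulative_curves(labels, n_orders = 5, seed = 100)
  expect_false(identical(a$curves, c2$curves))
})

test_that("mean precision reports simple and record-weighted variants", {
  p <- c(84.5, 78.2, 80.9, 78.2)
  n <- c(11264, 6711, 5050, 2457)
  mp <- mean_precision(p, n)
  expect_equal(mp$simple, mean(p))
  expect_equal(mp$weighted, sum(p * n) / sum(n))
  expect_gt(mp$weighted, mp$simple)  # wavelength records dominate
})
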