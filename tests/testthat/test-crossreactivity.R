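test_that("digestion outcomes map onto the four-level key", {
  expect_equal(as.character(classify_cell(c(1, 0.95, 0.5, 0.05, 0.005, 0))),
               c("++", "++", "+", "-", "--", "--"))
  # boundaries are left-closed
  expect_equal(as.character(classify_cell(c(0.90, 0.10, 0.01))),
               c("++", "+", "-"))
  custom <- c(high = 0.8, clear = 0.2, trace = 0.05)
  expect_equal(as.character(classify_cell(0.1, custom)), "-")
  expect_error(classify_cell(0.5, c(high = 0.1, clear = 0.5, trace = 0.9)),
               "thresholds")
  expect_error(classify_cell(1.5), "fraction")
})

test_that("identity specificity makes every cognate pair mutually orthogonal", {
  prots <- paste0("P", 1:4)
  subs <- paste0("S", 1:4)
  spec <- diag(4)
  dimnames(spec) <- list(prots, subs)
  cog <- setNames(prots, subs)
  g <- gen_crossreact(spec, cog, noise = noise_model(0, 0, 0), seed = 1)
  calls <- orthogonality_calls(g)
  v <- calls$verdicts
  expect_true(all(v[upper.tri(v)]))
  expect_true(all(is.na(diag(v))))
  expect_equal(length(calls$max_orthogonal_sets), 1L)
  expect_equal(calls$max_orthogonal_sets[[1]],
               sort(paste(prots, subs, sep = "/")))
})

test_that("the published qualitative cross-reactivity pattern yields the published orthogonality calls", {
  g <- gen_crossreact(fig8b_specificity(), fig8b_cognates(),
                      noise = noise_model(0, 0, 0), seed = 1)
  calls <- orthogonality_calls(g)
  v <- calls$verdicts
  atg <- c("xAtg4B/xLC3B", "xAtg4B/xGATE16", "trAtg4/trAtg8")
  others <- c("bdSENP1/bdSUMO", "bdNEDP1/bdNEDD8", "TEV/tevSite")
  # Atg4/Atg8 pairs are orthogonal to every non-Atg8 pair...
  expect_true(all(v[atg, others]))
  # ...but not to each other, because trAtg4 also cleaves xGATE16/trAtg8
  # and xAtg4B cleaves all three Atg8-type substrates
  expect_false(any(v[atg, atg], na.rm = TRUE))
  expect_true(all(v[others, others], na.rm = TRUE))
  # category matrix shows cognate cleavage on the diagonal blocks only
  m <- category_matrix(calls)
  expect_equal(m["xAtg4B", "xLC3B"], "++")
  expect_equal(m["trAtg4", "xLC3B"], "--")
  expect_equal(m["bdSENP1", "xLC3B"], "--")
})

test_that("verdicts are symmetric and monotone in the trace threshold on random grids", {
  set.seed(99)
  for (rep in 1:5) {
    n <- 4
    spec <- matrix(0, n, n, dimnames = list(paste0("P", 1:n),
                                            paste0("S", 1:n)))
    diag(spec) <- 1
    # random sub-threshold cross-activities plus one strong off-target
    spec[spec == 0] <- runif(n * n - n, 0, 2e-5)
    spec[1, 2] <- runif(1, 0.05, 0.5)
    cog <- setNames(rownames(spec), colnames(spec))
    g <- gen_crossreact(spec, cog, noise = noise_model(0, 0, 0), seed = rep)
    v1 <- orthogonality_calls(g)$verdicts
    expect_true(isSymmetric(unname(ifelse(is.na(v1), -1, v1 * 1))))
    # raising the trace cutoff can only add orthogonal pairs
    loose <- default_class_thresholds()
    loose["trace"] <- 0.05
    v2 <- orthogonality_calls(g, thresholds = loose)$verdicts
    expect_true(all(v2[v1 & !is.na(v1)]))
  }
})

test_that("sub-threshold noise leaves a planted specificity pattern recoverable", {
  spec <- fig8b_specificity()
  g <- gen_crossreact(spec, fig8b_cognates(),
                      noise = noise_model(fraction_sigma = 0.004), seed = 5)
  calls <- orthogonality_calls(g)
  planted <- gen_crossreact(spec, fig8b_cognates(),
                            noise = noise_model(0, 0, 0), seed = 5)
  expected <- orthogonality_calls(planted)
  expect_identical(calls$verdicts, expected$verdicts)
  expect_equal(as.character(calls$categories$category),
               as.character(expected$categories$category))
})

test_that("incomplete grids are refused with the absent pairs named", {
  d <- gen_crossreact(fig8b_specificity(), fig8b_cognates(),
                      noise = noise_model(0, 0, 0), seed = 1)$data
  d <- d[!(d$protease == "TEV" & d$substrate == "xLC3B"), ]
  g <- crossreact_grid(d, fig8b_cognates())
  expect_error(orthogonality_calls(g), "incomplete-grid.*TEV.*xLC3B")
})
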