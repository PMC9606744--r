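test_that("registries carry exactly 39 parameters and 40 principles", {
  pars <- triz_parameters(); prin <- triz_principles()
  expect_equal(pars$index, 1:39)
  expect_equal(prin$index, 1:40)
  expect_false(anyDuplicated(pars$name) > 0)
  expect_false(anyDuplicated(prin$name) > 0)
  expect_equal(pars$name[pars$index == 26], "Amount of substance")
  expect_equal(pars$name[pars$index == 35], "Adaptability or versatility")
  expect_equal(prin$name[prin$index == 25], "Self-service")
})

test_that("contradiction-matrix lookup returns stored cells in order", {
  m <- default_contradiction_matrix()
  expect_equal(lookup_matrix(9, 22, m), c(20L, 14L, 19L, 35L))
  expect_equal(lookup_matrix(35, 36, m), c(15L, 29L, 28L, 37L))
  expect_equal(lookup_matrix(35, 22, m), c(18L, 15L, 1L))
  expect_error(lookup_matrix(9, 9, m), "self-contradiction")
  expect_error(lookup_matrix(0, 22, m), "1\\.\\.39")
  expect_message(absent <- lookup_matrix(1, 2, m), "no cell")
  expect_length(absent, 0)
})

test_that("the eight case cells survive a serialization round trip", {
  m <- default_contradiction_matrix()
  tmp <- tempfile(fileext = ".csv")
  df <- data.frame(
    improving = as.integer(sub(":.*", "", names(m))),
    worsening = as.integer(sub(".*:", "", names(m))),
    principles = vapply(m, paste, character(1), collapse = " "))
  write.csv(df, tmp, row.names = FALSE)
  m2 <- read_contradiction_matrix(tmp)
  expect_equal(m2[names(m)], m[names(m)], ignore_attr = TRUE)
  expect_true(validate_matrix_assets(m2)$ok)
})

test_that("asset validation reports size and cell deviations", {
  rep <- validate_matrix_assets()
  expect_true(rep$ok)
  expect_length(rep$deviations, 0)
  m <- default_contradiction_matrix()
  m[["9:22"]] <- c(1L, 2L)
  rep2 <- validate_matrix_assets(m)
  expect_false(rep2$ok)
  expect_match(rep2$deviations, "9, 22", all = FALSE)
  rep3 <- validate_matrix_assets(principles = triz_principles()[1:39, ])
  expect_false(rep3$ok)
  expect_match(rep3$deviations, "principle registry", all = FALSE)
})

test_that("cause-to-parameter mapping follows determinant tags in order", {
  reg <- case_register_fixture()
  dmap <- read_determinant_map(fmeatriz_extdata("case_determinants.yaml"))
  expect_equal(map_causes_to_parameters(reg[reg$id == "F1", ], dmap),
               c(26L, 35L))
  expect_equal(map_causes_to_parameters(reg[reg$id == "F2", ], dmap),
               c(26L, 9L))
  expect_equal(map_causes_to_parameters(reg[reg$id == "F6", ], dmap),
               c(26L, 17L))
  # untagged cause is named in the error
  expect_error(map_causes_to_parameters(reg[reg$id == "F3", ], dmap),
               "Inexperienced healthcare workers")
  # unmapped determinant id
  f <- reg[reg$id == "F1", ]
  f$causes[[1]]$determinants[[1]] <- 99L
  expect_error(map_causes_to_parameters(f, dmap), "unmapped determinant 99")
})

test_that("principle suggestion pools the case failures into 7 screened principles", {
  reg <- case_register_fixture()
  dmap <- read_determinant_map(fmeatriz_extdata("case_determinants.yaml"))
  top <- reg[match(c("F1", "F6", "F2"), reg$id), ]
  sug <- suggest_principles(top, dmap, dmap$worsening, roster = dmap$roster)
  expect_equal(sug$improving, c(26L, 35L, 17L, 9L))
  expect_setequal(sug$screened, c(1L, 4L, 21L, 25L, 27L, 10L, 28L))
  expect_length(sug$screened, 7)
  expect_true(all(sug$screened %in% sug$raw_union))
  expect_equal(nrow(sug$cells), 8)  # 4 improving x 2 worsening
  # provenance: each failure chains cause -> determinant -> parameter
  for (f in sug$failures) {
    expect_equal(length(f$causes), length(f$determinants))
    expect_true(length(f$parameters) >= 1)
  }
  # no roster: screened equals raw union
  sug2 <- suggest_principles(top, dmap, dmap$worsening)
  expect_equal(sug2$screened, sug2$raw_union)
  # disjoint roster: empty screened list, raw union preserved
  sug3 <- suggest_principles(top, dmap, dmap$worsening, roster = c(39L, 40L))
  expect_length(sug3$screened, 0)
  expect_gt(length(sug3$raw_union), 0)
  # no failures: empty report
  sug4 <- suggest_principles(reg[0, ], dmap, dmap$worsening)
  expect_length(sug4$raw_union, 0)
  expect_error(suggest_principles(top, dmap, integer(0)), "non-empty")
})

test_that("adding a failure never shrinks the raw principle union", {
  reg <- case_register_fixture()
  dmap <- read_determinant_map(fmeatriz_extdata("case_determinants.yaml"))
  ids <- c("F1", "F6", "F2")
  prev <- integer(0)
  for (k in seq_along(ids)) {
    sug <- suggest_principles(reg[match(ids[seq_len(k)], reg$id), ],
                              dmap, dmap$worsening)
    expect_true(all(prev %in% sug$raw_union))
    prev <- sug$raw_union
  }
})
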