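test_that("the example Hymenoptera template parses with four mandatory fields", {
  tpl <- hymenoptera_template()
  expect_s3_class(tpl, "template_spec")
  expect_equal(tpl$name, "Hymenoptera")
  expect_equal(nrow(tpl$fields), 4L)
  expect_true(all(tpl$fields$mandatory))
  expect_equal(tpl$fields$name[1], "Catalog number")
  expect_equal(tpl$fields$parser[1], "regex")
  expect_true(all(lengths(tpl$fields$choices[2:4]) > 0L))
})

test_that("template schema violations are named errors", {
  expect_error(parse_template("name: x\nbogus_key: 1\nfields:\n  - name: a\n"),
               regexp = "bogus_key", class = "drawerseg_schema_error")
  expect_error(parse_template("fields:\n  - name: a\n"),
               regexp = "name", class = "drawerseg_schema_error")
  expect_error(parse_template("name: x\n"),
               regexp = "fields", class = "drawerseg_schema_error")
  expect_error(parse_template("name: x\nfields:\n  - name: a\n    parser: regex\n"),
               class = "drawerseg_pattern_error")
  expect_error(parse_template("name: x\nfields:\n  - name: a\n    parser: regex\n    pattern: '['\n"),
               class = "drawerseg_pattern_error")
  expect_error(parse_template("name: x\nfields:\n  - name: a\n  - name: a\n"),
               regexp = "duplicate", class = "drawerseg_schema_error")
  expect_error(parse_template(": ::\n  bad yaml ["), class = "drawerseg_format_error")
})

test_that("thumbnail width is carried from the template", {
  tpl <- parse_template("name: x\nthumbnail_width: 2048\nfields:\n  - name: a\n")
  expect_equal(tpl$thumbnail_width, 2048L)
  # default when unspecified
  tpl2 <- parse_template("name: x\nfields:\n  - name: a\n")
  expect_equal(tpl2$thumbnail_width, 4096L)
})

test_that("templates round-trip through their YAML rendering", {
  tpls <- list(
    hymenoptera_template(),
    parse_template("name: min\nfields:\n  - name: only\n"),
    parse_template(paste0("name: mix\nthumbnail_width: 512\ncrop_filename: [id]\n",
                          "fields:\n  - name: id\n    parser: integer-gt-zero\n",
                          "  - name: lat\n    parser: latitude\n    mandatory: true\n"))
  )
  for (tpl in tpls) {
    back <- parse_template(render_template(tpl))
    expect_equal(back, tpl)
  }
})

test_that("the nine-digit catalog rule accepts exactly nine plain digits", {
  field <- tibble::tibble(name = "Catalog number", mandatory = TRUE,
                          choices = list(character()), parser = "regex",
                          pattern = "^[0-9]{9}$")
  expect_true(is.na(validate_value("012345678", field)))
  expect_equal(validate_value("A12345678", field), "parse-failure")
  expect_equal(validate_value(" 012345678", field), "parse-failure")
  expect_equal(validate_value("0123456789", field), "parse-failure")
  # unanchored patterns are still matched against the full string
  field$pattern <- "[0-9]{9}"
  expect_equal(validate_value("x012345678y", field), "parse-failure")
  expect_true(is.na(validate_value("012345678", field)))
})

test_that("built-in parsers accept their documented sets and reject the rest", {
  f <- function(parser) tibble::tibble(name = "v", mandatory = FALSE,
                                       choices = list(character()),
                                       parser = parser, pattern = NA_character_)
  lat <- f("latitude"); lon <- f("longitude")
  expect_true(is.na(validate_value("-90", lat)))
  expect_true(is.na(validate_value("90.0", lat)))
  expect_equal(validate_value("91.0", lat), "parse-failure")
  expect_equal(validate_value("-90.001", lat), "parse-failure")
  expect_true(is.na(validate_value("-180", lon)))
  expect_equal(validate_value("180.5", lon), "parse-failure")
  expect_equal(validate_value("12,5", lon), "parse-failure")

  # integer-gt-zero over the exhaustive length-<=3 alphabet {0, 1, a, -}
  alphabet <- c("0", "1", "a", "-")
  strs <- unlist(lapply(1:3, function(n) {
    do.call(paste0, expand.grid(rep(list(alphabet), n)))
  }))
  igz <- f("integer-gt-zero")
  for (s in strs) {
    want_ok <- grepl("^[0-9]+$", s) && suppressWarnings(as.numeric(s)) > 0
    expect_equal(is.na(validate_value(s, igz)), want_ok, label = sprintf("'%s'", s))
  }
})

test_that("date validation agrees with a day-count calendar oracle", {
  dat <- tibble::tibble(name = "d", mandatory = FALSE, choices = list(character()),
                        parser = "date-ymd", pattern = NA_character_)
  cases <- expand.grid(y = c(1900L, 1999L, 2000L, 2015L, 2016L),
                       m = c(1L, 2L, 4L, 12L, 13L),
                       d = c(1L, 28L, 29L, 30L, 31L))
  for (k in seq_len(nrow(cases))) {
    s <- sprintf("%04d-%02d-%02d", cases$y[k], cases$m[k], cases$d[k])
    expect_equal(is.na(validate_value(s, dat)),
                 valid_date_oracle(cases$y[k], cases$m[k], cases$d[k]),
                 label = s)
  }
  expect_equal(validate_value("2015-02-30", dat), "parse-failure")
  expect_equal(validate_value("2015-2-3", dat), "parse-failure")
  expect_equal(validate_value("20150203", dat), "parse-failure")
})

test_that("validate_box aggregates violations and flags unknown fields", {
  tpl <- hymenoptera_template()
  good <- c(`Catalog number` = "013244667", Location = "Africa",
            Family = "Apidae", Subfamily = "Apinae")
  rep1 <- validate_box(good, tpl)
  expect_true(rep1$ok)
  expect_equal(nrow(rep1$violations), 0L)

  rep2 <- validate_box(good[-1], tpl)
  expect_false(rep2$ok)
  expect_equal(rep2$violations$field, "Catalog number")
  expect_equal(rep2$violations$reason, "missing-mandatory")

  rep3 <- validate_box(c(good, rogue = "x"), tpl)
  expect_false(rep3$ok)
  expect_true("unknown-field" %in% rep3$violations$reason)

  bad_choice <- good; bad_choice["Family"] <- "Hominidae"
  expect_equal(validate_box(bad_choice, tpl)$violations$reason, "not-in-choices")

  # vacuous validity: no mandatory fields, empty metadata
  lax <- parse_template("name: lax\nfields:\n  - name: note\n")
  expect_true(validate_box(stats::setNames(character(), character()), lax)$ok)
})

test_that("ok is equivalent to an empty violation set over random field maps", {
  tpl <- hymenoptera_template()
  vals <- list(`Catalog number` = c("013244667", "13", NA),
               Location = c("Africa", "Atlantis", NA),
               Family = c("Apidae", NA), Subfamily = c("Apinae", "x", NA))
  withr::with_seed(99L, {
    for (k in 1:25) {
      fm <- unlist(lapply(names(vals), function(nm) {
        v <- sample(vals[[nm]], 1L)
        if (is.na(v)) NULL else stats::setNames(v, nm)
      }))
      rep <- validate_box(fm, tpl)
      expect_equal(rep$ok, nrow(rep$violations) == 0L)
      expect_equal(rep$ok,
                   identical(unname(fm[c("Catalog number", "Location", "Family", "Subfamily")]),
                             c("013244667", "Africa", "Apidae", "Apinae")))
    }
  })
})

test_that("the built-in Simple Darwin Core template has unique optional terms", {
  tpl <- default_darwin_core_template()
  expect_true("catalogNumber" %in% tpl$fields$name)
  expect_true("scientificName" %in% tpl$fields$name)
  expect_false(any(tpl$fields$mandatory))
  expect_false(anyDuplicated(tpl$fields$name) > 0L)
  expect_true(all(tpl$fields$parser == "free-text"))
  expect_identical(get_template("dwc-simple")$name, "dwc-simple")
})
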