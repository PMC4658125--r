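test_that("cropping at rotation 0 equals direct subarray extraction", {
  src <- numbered_pattern(100L, 150L)
  # the worked case: pixels (10,20)-(30,50) exclusive
  b <- boxes(x0 = 10 / 150, y0 = 20 / 100, x1 = 30 / 150, y1 = 50 / 100)
  crop <- crop_box(src, b[1, ])
  expect_identical(dim(crop$pixels)[1:2], c(30L, 20L))
  expect_identical(crop$pixels, src$pixels[21:50, 11:30, , drop = FALSE])

  withr::with_seed(5L, {
    for (k in 1:10) {
      x0 <- sample(0:120, 1L); y0 <- sample(0:80, 1L)
      x1 <- x0 + sample(1:(150 - x0), 1L); y1 <- y0 + sample(1:(100 - y0), 1L)
      bb <- boxes(x0 = x0 / 150, y0 = y0 / 100, x1 = x1 / 150, y1 = y1 / 100)
      expect_identical(crop_box(src, bb[1, ])$pixels,
                       src$pixels[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE])
    }
  })
})

test_that("rotations map pixels according to the coordinate oracle", {
  src <- numbered_pattern(20L, 30L)
  full <- boxes(x0 = 0, y0 = 0, x1 = 1, y1 = 1, rotation = 90L)
  r90 <- crop_box(src, full[1, ])$pixels
  expect_identical(dim(r90)[1:2], c(30L, 20L))
  # 90 cw: output (r, c) comes from source (H - c + 1, r)
  H <- 20L
  for (r in seq_len(30L)) for (c in seq_len(20L)) {
    expect_identical(r90[r, c, ], src$pixels[H - c + 1L, r, ])
  }

  full$rotation <- 180L
  r180 <- crop_box(src, full[1, ])$pixels
  expect_identical(r180[20:1, 30:1, , drop = FALSE], src$pixels)
  # 180 twice restores the original
  expect_identical(crop_box(source_image(r180), full[1, ])$pixels, src$pixels)

  full$rotation <- 270L
  r270 <- crop_box(src, full[1, ])$pixels
  W <- 30L
  for (r in seq_len(30L)) for (c in seq_len(20L)) {
    expect_identical(r270[r, c, ], src$pixels[c, W - r + 1L, ])
  }
})

test_that("degenerate and out-of-range boxes are handled", {
  src <- numbered_pattern(40L, 40L)
  tiny <- tibble::tibble(x0 = 0.5, y0 = 0.5, x1 = 0.505, y1 = 0.8, rotation = 0L)
  expect_error(crop_box(src, tiny), class = "drawerseg_geometry_error")
  # boundary clamp: no invented pixels
  wide <- boxes(x0 = 0.5, y0 = 0.5, x1 = 1, y1 = 1)
  expect_identical(dim(crop_box(src, wide[1, ])$pixels)[1:2], c(20L, 20L))
})

test_that("crop filenames come from metadata with an index fallback", {
  tpl <- hymenoptera_template()
  b <- boxes(x0 = 0.1, y0 = 0.1, x1 = 0.2, y1 = 0.2,
             fields = list(c(`Catalog number` = "013244667")))
  expect_equal(crop_filename(b[1, ], 1L, tpl), "013244667.jpg")

  b$fields[[1]] <- stats::setNames(character(), character())
  expect_equal(crop_filename(b[1, ], 7L, tpl), "0007.jpg")
  expect_equal(crop_filename(b[1, ], 7L, NULL), "0007.jpg")

  b$fields[[1]] <- c(`Catalog number` = "a/b c")
  expect_equal(crop_filename(b[1, ], 1L, tpl), "a-b-c.jpg")
})

test_that("export_crops writes one file per box and resolves collisions", {
  dir <- withr::local_tempdir()
  scan <- make_test_scan(dir, h = 80L, w = 120L)
  bx <- boxes(x0 = c(0, 0.5, 0), y0 = c(0, 0, 0.5), x1 = c(0.4, 0.9, 0.4),
              y1 = c(0.4, 0.4, 0.9),
              fields = list(c(`Catalog number` = "000000001"),
                            c(`Catalog number` = "000000001"),
                            stats::setNames(character(), character())))
  doc <- new_document(scan, thumbnail_path_for(scan), boxes = bx)
  out <- export_crops(doc, template = hymenoptera_template(),
                      out_dir = file.path(dir, "crops"))
  expect_equal(nrow(out), 3L)
  expect_true(all(file.exists(out$path)))
  expect_equal(basename(out$path),
               c("000000001.jpg", "000000001-1.jpg", "0003.jpg"))

  empty_doc <- new_document(scan, thumbnail_path_for(scan))
  expect_equal(nrow(export_crops(empty_doc, out_dir = file.path(dir, "crops"))), 0L)
})

test_that("crop areas add up to the denormalized box areas", {
  dir <- withr::local_tempdir()
  scan <- make_test_scan(dir, h = 90L, w = 140L)
  bx <- random_boxes(6L, seed = 2L)
  bx$rotation <- 0L
  doc <- new_document(scan, thumbnail_path_for(scan), boxes = bx)
  out <- export_crops(doc, out_dir = file.path(dir, "c"))
  areas <- vapply(seq_len(nrow(bx)), function(i) {
    d <- dim(crop_box(load_image(scan), bx[i, ])$pixels)
    d[1] * d[2]
  }, double(1))
  want <- vapply(seq_len(nrow(bx)), function(i) {
    prod(pmax(round(bx$x1[i] * 140) - round(bx$x0[i] * 140), 0) *
         pmax(round(bx$y1[i] * 90) - round(bx$y0[i] * 90), 0))
  }, double(1))
  expect_equal(sum(areas), sum(want))
})

test_that("export_csv emits the documented schema", {
  scan <- "somewhere/drawer7.png"
  bx <- boxes(x0 = c(0.1, 0.3), y0 = c(0.1, 0.3), x1 = c(0.2, 0.4), y1 = c(0.2, 0.4),
              rotation = c(0L, 90L),
              fields = list(c(`Catalog number` = "013244667", Location = "Africa",
                              Family = "Apidae", Subfamily = "Apinae"),
                            c(`Catalog number` = "013244668")))
  doc <- new_document(scan, "t.jpg", boxes = bx)
  tpl <- hymenoptera_template()
  tab <- export_csv(doc, template = tpl)
  expect_equal(ncol(tab), 11L)  # 7 fixed + 4 template fields
  expect_equal(nrow(tab), 2L)
  expect_equal(names(tab)[1:7], c("file", "box", "x0", "y0", "x1", "y1", "rotation"))
  expect_equal(tab$file, rep("drawer7", 2L))

  empty <- new_document(scan, "t.jpg")
  expect_equal(nrow(export_csv(empty, template = tpl)), 0L)
  expect_equal(ncol(export_csv(empty)), 7L)
})

test_that("CSV files round-trip through an independent reader", {
  dir <- withr::local_tempdir()
  bx <- random_boxes(5L, seed = 9L)
  doc <- new_document("d.png", "t.jpg", boxes = bx)
  path <- file.path(dir, "d.csv")
  export_csv(doc, path = path)
  back <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  expect_equal(nrow(back), 5L)
  expect_equal(as.numeric(back$x0), bx$x0, tolerance = 1e-6)
  expect_equal(as.numeric(back$y1), bx$y1, tolerance = 1e-6)
  expect_equal(as.integer(back$rotation), bx$rotation)
  expect_equal(back$catalogNumber[2], bx$fields[[2]][["catalogNumber"]])
})
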