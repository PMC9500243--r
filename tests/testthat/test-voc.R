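make_record <- function(n_boxes = 3, w = 200, h = 150, seed = 1) {
  boxes <- with(list(), {
    set.seed(seed)
    random_boxes(n_boxes, size = min(w, h), min_side = 3, max_side = 30)
  })
  image_record("img.ppm", w, h, boxes)
}

test_that("read_voc converts the 1-based inclusive VOC dialect", {
  xml <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    "<annotation><filename>img.ppm</filename>",
    "<size><width>50</width><height>40</height><depth>3</depth></size>",
    "<object><name>platelet</name><bndbox>",
    "<xmin>1</xmin><ymin>1</ymin><xmax>10</xmax><ymax>10</ymax>",
    "</bndbox></object></annotation>"), xml)
  rec <- read_voc(xml)
  b <- rec$boxes[[1]]
  expect_equal(c(b$x_min, b$y_min, b$x_max, b$y_max), c(0, 0, 10, 10))
  expect_identical(b$label, "platelet")
  expect_identical(c(rec$width, rec$height), c(50L, 40L))
})

test_that("read_voc handles empty, malformed and degenerate annotations", {
  xml <- withr::local_tempfile(fileext = ".xml")
  writeLines(c("<annotation><filename>a.ppm</filename>",
               "<size><width>30</width><height>30</height></size>",
               "</annotation>"), xml)
  expect_length(read_voc(xml)$boxes, 0)
  writeLines("<annotation><filename>a.ppm</filename></annotation>", xml)
  expect_error(read_voc(xml), "size")
  writeLines(c("<annotation><filename>a.ppm</filename>",
               "<size><width>30</width><height>30</height></size>",
               "<object><name>platelet</name><bndbox>",
               "<xmin>10</xmin><ymin>5</ymin><xmax>10</xmax><ymax>9</ymax>",
               "</bndbox></object></annotation>"), xml)
  expect_warning(rec <- read_voc(xml), "dropped")
  expect_length(rec$boxes, 0)
})

test_that("write_voc / read_voc round-trips coordinates", {
  # integer coordinates (the native VOC/LabelImg case) round-trip bit-exactly
  int_rec <- image_record("i.ppm", 60, 60,
                          list(box(0, 0, 10, 10), box(3, 7, 41, 59)))
  xml0 <- withr::local_tempfile(fileext = ".xml")
  write_voc(int_rec, xml0)
  back0 <- read_voc(xml0)
  for (i in seq_along(int_rec$boxes)) {
    expect_identical(unlist(back0$boxes[[i]][1:4]),
                     unlist(int_rec$boxes[[i]][1:4]))
  }
  # continuous coordinates round-trip to within one ulp of the 1-based shift
  for (seed in 1:5) {
    rec <- make_record(n_boxes = 4, seed = seed)
    xml <- withr::local_tempfile(fileext = ".xml")
    write_voc(rec, xml)
    back <- read_voc(xml)
    expect_length(back$boxes, length(rec$boxes))
    for (i in seq_along(rec$boxes)) {
      expect_equal(
        unlist(back$boxes[[i]][1:4]), unlist(rec$boxes[[i]][1:4]),
        tolerance = 1e-12)
    }
    expect_identical(c(back$width, back$height), c(rec$width, rec$height))
  }
  # empty record stays a valid file with 0 objects
  xml <- withr::local_tempfile(fileext = ".xml")
  write_voc(image_record("e.ppm", 20, 20, list()), xml)
  expect_length(read_voc(xml)$boxes, 0)
})

test_that("image_record clips out-of-bounds boxes and drops empty ones", {
  expect_warning(
    rec <- image_record("x.ppm", 50, 50,
                        list(box(-5, 10, 20, 30), box(45, 45, 70, 70),
                             box(60, 60, 80, 80))),
    "clipped")
  expect_length(rec$boxes, 2)  # fully outside box became degenerate, dropped
  for (b in rec$boxes) {
    expect_gte(b$x_min, 0); expect_lte(b$x_max, 50)
    expect_gt(box_area(b), 0)
  }
})

test_that("split_dataset partitions deterministically with the 296/33/83 shape", {
  recs <- lapply(1:412, function(i) image_record(sprintf("i%03d.ppm", i), 10, 10))
  sp <- split_dataset(recs, counts = c(296, 33, 83), seed = 4)
  expect_identical(vapply(sp, length, integer(1)),
                   c(train = 296L, val = 33L, test = 83L))
  # default counts mirror the same proportions
  sp2 <- split_dataset(recs, seed = 4)
  expect_identical(vapply(sp2, length, integer(1)),
                   c(train = 296L, val = 33L, test = 83L))
  sp3 <- split_dataset(recs, seed = 4)
  expect_identical(sp2, sp3)
  expect_error(split_dataset(recs, counts = c(100, 100, 100)), "summing")
  # partition property on random sizes
  set.seed(9)
  for (n in c(5, 17, 103)) {
    recs_n <- recs[1:n]
    sp_n <- split_dataset(recs_n, seed = n)
    ids <- unlist(lapply(sp_n, function(part) {
      vapply(part, function(r) r$image_path, character(1))
    }))
    expect_setequal(ids, vapply(recs_n, function(r) r$image_path, character(1)))
    expect_identical(anyDuplicated(ids), 0L)
  }
})

test_that("letterbox geometry: scale, padding, and the worked 832x416 case", {
  rec <- image_record("w.ppm", 832, 416, list(box(0, 0, 832, 416)))
  out <- letterbox(NULL, rec, target_size = 416)
  b <- out$record$boxes[[1]]
  expect_equal(c(b$x_min, b$y_min, b$x_max, b$y_max), c(0, 104, 416, 312))
  # square image: pure scale, no padding
  rec_sq <- image_record("s.ppm", 100, 100, list(box(10, 20, 30, 40)))
  out_sq <- letterbox(NULL, rec_sq, target_size = 416)
  b2 <- out_sq$record$boxes[[1]]
  expect_equal(c(b2$x_min, b2$y_min, b2$x_max, b2$y_max),
               c(10, 20, 30, 40) * 4.16)
  expect_error(letterbox(NULL, rec_sq, target_size = 100), "divisible")
})

test_that("letterbox inverse map recovers original boxes and preserves IOU", {
  set.seed(13)
  for (i in 1:20) {
    w <- sample(60:500, 1); h <- sample(60:500, 1)
    boxes <- random_boxes(4, size = min(w, h), min_side = 5, max_side = 25)
    rec <- image_record("r.ppm", w, h, boxes)
    out <- letterbox(NULL, rec, target_size = 416)
    inv <- attr(out$record, "inv_map")
    for (j in seq_along(boxes)) {
      back <- unletterbox_box(out$record$boxes[[j]], inv)
      expect_equal(unlist(back[1:4]), unlist(boxes[[j]][1:4]),
                   tolerance = 1e-6)
    }
    # uniform scaling preserves IOU exactly between any two boxes
    expect_equal(iou(out$record$boxes[[1]], out$record$boxes[[2]]),
                 iou(boxes[[1]], boxes[[2]]), tolerance = 1e-12)
  }
})

test_that("letterboxed image has gray padding and the content in place", {
  img <- array(1, dim = c(50, 100, 3))  # white, wide
  rec <- image_record("w.ppm", 100, 50, list())
  out <- letterbox(img, rec, target_size = 64, divisor = 32)
  expect_identical(dim(out$image), c(64L, 64L, 3L))
  expect_equal(out$image[1, 1, 1], 0.5)    # top pad
  expect_equal(out$image[32, 32, 1], 1)    # content centre
})
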