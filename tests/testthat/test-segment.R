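test_that("blank and malformed inputs are handled", {
  expect_equal(nrow(segment_cells(matrix(500, 64, 64))), 0) # uniform image
  expect_error(segment_cells(array(1, c(4, 4, 2))), class = "rodmapr_format_error")
  expect_error(cells_from_labels(matrix(0.5, 4, 4)), class = "rodmapr_format_error")
  expect_equal(nrow(cells_from_labels(matrix(0L, 32, 32))), 0) # labels {0}
})

test_that("label ids are preserved and geometry is exact on rectangles", {
  lab <- rect_labels(id = 3L)
  lab[45:54, 10:49] <- 7L
  cells <- cells_from_labels(lab, pixel_size = 0.064)
  expect_equal(cells$cell_id, c(3L, 7L))
  # 40 x 10 px rectangles: pole-to-pole length 40 px within 1 px
  expect_equal(cells$length_um / 0.064, c(40, 40), tolerance = 1 / 40)
  expect_equal(cells$area_px, c(400L, 400L))
  # interior diameter: 10 px
  for (d in cells$diameter_profile) {
    expect_equal(median(d[10:40]) / 0.064, 10, tolerance = 0.05)
  }
})

test_that("a single noiseless rendered rod is segmented with correct length", {
  sc <- one_cell_scene(length_um = 2.56, width_um = 0.64)
  cells <- segment_cells(sc$images$phase, pixel_size = 0.064)
  expect_equal(nrow(cells), 1)
  expect_equal(cells$length_um[1] / 0.064, 40, tolerance = 2 / 40) # 40 +/- 2 px
})

test_that("separated rods give disjoint masks", {
  lab <- rect_labels(id = 1L)
  lab[45:54, 10:49] <- 2L
  cells <- cells_from_labels(lab)
  expect_equal(nrow(cells), 2)
  i1 <- cells$mask[[1]][, 1] + 60 * cells$mask[[1]][, 2]
  i2 <- cells$mask[[2]][, 1] + 60 * cells$mask[[2]][, 2]
  expect_length(intersect(i1, i2), 0)
})

test_that("blob-like objects raise a shape error and are reported", {
  lab <- matrix(0L, 40, 40)
  lab[10:19, 10:19] <- 1L # 10x10 square
  expect_warning(cells <- cells_from_labels(lab), "not rod-shaped")
  expect_false(cells$shape_ok[1])
  expect_error(medial_axis_profile(cells[1, ]), class = "rodmapr_shape_error")
})

test_that("constricted rods show a mid-cell diameter minimum", {
  # two lobes joined by a 50%-width neck
  lab <- matrix(0L, 60, 100)
  lab[20:39, 15:45] <- 1L
  lab[20:39, 56:86] <- 1L
  lab[25:34, 46:55] <- 1L # neck: 10 px wide vs 20 px lobes
  cells <- cells_from_labels(lab)
  d <- cells$diameter_profile[[1]]
  expect_true(which.min(d) > 0.4 * length(d) && which.min(d) < 0.6 * length(d))
})

test_that("length is not decreased by mask dilation", {
  lab <- rect_labels()
  base <- cells_from_labels(lab)$length_um
  dil <- matrix(0L, 60, 80)
  dil[24:35, 19:60] <- 1L # 1-px dilation of the same rod
  expect_gte(cells_from_labels(dil)$length_um, base)
})

test_that("noiseless synthetic scenes are segmented with perfect detection", {
  pop <- sample_population(40, growth_model(), seed = 15)
  sc <- render_scene(pop, list(channel_model("cytoplasmic", 100)), seed = 16)
  cells <- segment_cells(sc$images$phase)
  expect_equal(nrow(cells), 40) # recall 1 and precision 1
  m <- match_truth(cells, sc)
  expect_false(anyNA(m))
  expect_equal(length(unique(m)), 40)
  err_px <- abs(cells$length_um - sc$cells$length_um[m]) / 0.064
  expect_lte(mean(err_px), 2)
  # masks stay within the field and pairwise disjoint
  all_idx <- unlist(lapply(cells$mask, function(mm) mm[, 1] + (mm[, 2] - 1) * nrow(sc$images$phase)))
  expect_equal(anyDuplicated(all_idx), 0)
})
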