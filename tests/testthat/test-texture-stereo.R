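test_that("filtered-noise texture is deterministic and hits target contrast", {
  t1 <- make_nonoriented_texture(size_px = 256, seed = 5)
  t2 <- make_nonoriented_texture(size_px = 256, seed = 5)
  t3 <- make_nonoriented_texture(size_px = 256, seed = 6)
  expect_identical(t1, t2)
  expect_false(identical(t1, t3))
  expect_lt(abs(michelson_contrast(t1) - 80), 0.5)
  expect_equal(mean(t1), 0.5, tolerance = 0.02)

  t30 <- make_nonoriented_texture(size_px = 256, target_contrast = 30, seed = 5)
  expect_lt(abs(michelson_contrast(t30) - 30), 0.5)

  expect_error(make_nonoriented_texture(target_contrast = 0),
               class = "indecision_input_error")
  expect_error(make_nonoriented_texture(target_contrast = 120),
               class = "indecision_input_error")
})

test_that("the 18-band texture is isotropic; a single band is not", {
  iso <- make_nonoriented_texture(size_px = 512, seed = 1)
  expect_lt(orientation_energy(iso)$cv, 0.15)

  oriented <- make_nonoriented_texture(size_px = 512, n_orientations = 1,
                                       seed = 1)
  expect_gt(orientation_energy(oriented)$cv, 0.5)
})

test_that("stereo pairs shift right-eye elements by integer-pixel disparity", {
  # zero disparity: the eyes see identical images
  pair <- render_stereo_pair(list(
    element_grating(outer_diameter_deg = 2, contrast_pct = 30),
    element_grating(inner_diameter_deg = 2.5, outer_diameter_deg = 4,
                    orientation_deg = 135, contrast_pct = 80)),
    canvas_px = 200)
  expect_identical(pair$left, pair$right)
  expect_true(all(pair$left >= 0 & pair$left <= 1))

  # a surround at -0.1 deg moves by deg_to_px(-0.1) = -4 px in the right eye
  ann <- element_grating(inner_diameter_deg = 1, outer_diameter_deg = 2.2,
                         contrast_pct = 80, disparity_deg = -0.1)
  pair <- render_stereo_pair(list(ann), canvas_px = 200)
  s <- deg_to_px(-0.1)
  expect_identical(s, -4L)
  shifted <- pair$left[, ((seq_len(200) - 1 - s) %% 200) + 1]
  expect_lt(max(abs(pair$right - shifted)), 1e-12)

  # wedge annulus: the four slots leave background along the slot axes
  wedges <- element_grating(inner_diameter_deg = 3, outer_diameter_deg = 8,
                            contrast_pct = 80, n_slots = 4,
                            slot_width_deg = 0.33)
  pw <- render_stereo_pair(list(wedges), canvas_px = 400)
  ny <- 400; mid <- (ny + 1) / 2
  pitch <- monitor_geometry()$pixel_pitch_deg
  r_px <- round(2.75 / pitch / sqrt(2))  # a point mid-annulus on a slot axis
  expect_equal(pw$left[round(mid + r_px), round(mid + r_px)], 0.5)
  # and grating off the slot axes
  expect_false(pw$left[round(mid), round(mid + round(2.75 / pitch))] == 0.5)

  expect_error(render_stereo_pair(list(element_grating(outer_diameter_deg = 20)),
                                  canvas_px = 200),
               class = "indecision_input_error")
})

test_that("bump element renders per-ring disparities in the right eye only", {
  scene <- list(element_bump(outer_diameter_deg = 6))
  p1 <- render_stereo_pair(scene, canvas_px = 340, seed = 9)
  p2 <- render_stereo_pair(scene, canvas_px = 340, seed = 9)
  expect_identical(p1$left, p2$left)
  expect_identical(p1$right, p2$right)
  # disparity makes the eyes differ, but only outside the flat top
  expect_false(identical(p1$left, p1$right))
  mid <- (340 + 1) / 2
  pitch <- monitor_geometry()$pixel_pitch_deg
  # square whose corners stay inside the 1.13 deg flat-top radius
  hw <- floor(1.13 / sqrt(2) * 0.9 / pitch)
  rows <- round(mid + (-hw:hw)); cols <- rows
  expect_identical(p1$left[rows, cols], p1$right[rows, cols])

  # fixation-lock dot squares are binary and deterministic
  fix <- render_stereo_pair(list(element_dot_square(center = c(2, 2))),
                            canvas_px = 300, seed = 4)
  vals <- unique(as.vector(fix$left))
  expect_setequal(vals, c(0, 0.5, 1))
})
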