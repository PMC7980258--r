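# Image pipelines: z-stack segmentation, structure measurement, movie
# preprocessing, pixel classification, mask-to-skeleton reduction,
# longest-path lengths, Hungarian linking and track velocities.

test_that("z-stack segmentation recovers a noiseless vertical rod", {
  sc <- gen_rod_stack(1, z_planes = 10, psf_sigma_px = 1, noise_sd = 0,
                      seed = 2, max_tilt_deg = 0, length_um = 4)
  objs <- segment_fls_stack(sc$stack, z_step_um = sc$z_step_um,
                            px_size_um = sc$px_size_um)
  expect_length(objs, 1)
  o <- objs[[1]]
  gt <- sc$ground_truth
  expect_lt(sqrt((o$base_centroid[1] - gt$base_x_px)^2 +
                   (o$base_centroid[2] - gt$base_y_px)^2), 1)
  expect_lt(abs(o$length_path_um - gt$length_um), sc$z_step_um)
  expect_equal(o$straightness, 1, tolerance = 1e-6)
  # two rods with separated bases give two structures
  sc2 <- gen_rod_stack(2, z_planes = 8, psf_sigma_px = 1, noise_sd = 0.02,
                       seed = 5)
  expect_length(segment_fls_stack(sc2$stack), 2)
  # zero tracing radius confines objects to the base plane; min_planes = 2
  # then discards everything
  expect_length(segment_fls_stack(sc$stack, max_trace_radius = 0), 0)
  expect_error(segment_fls_stack(sc$stack, base_plane = 99), "base_plane")
})

test_that("crossing rods with distinct bases stay anchored to their own base", {
  # built by hand: two rods leaning toward each other, crossing in upper
  # planes
  nr <- 48; nc <- 48; nz <- 7
  stack <- array(0.05, c(nr, nc, nz))
  for (z in 0:(nz - 1)) {
    for (px in list(filodyn:::disk_pixels(12 + 3 * z, 24, 2, nr, nc),
                    filodyn:::disk_pixels(36 - 3 * z, 24, 2, nr, nc)))
      stack[cbind(px, z + 1)] <- 1
  }
  for (z in seq_len(nz)) stack[, , z] <- EBImage::gblur(stack[, , z], 1)
  objs <- segment_fls_stack(stack, max_trace_radius = 4)
  expect_length(objs, 2)
  bases <- sort(vapply(objs, function(o) o$base_centroid[1], numeric(1)))
  expect_equal(bases, c(12, 36), tolerance = 1.5)
})

test_that("structure measurement recovers planted intensities and straightness", {
  base_px <- filodyn:::disk_pixels(20, 20, 3, 64, 64)
  obj <- structure(list(base_centroid = c(20, 20), base_pixels = base_px,
                        centroids = rbind(c(20, 20), c(20, 20)),
                        planes = 1:2, length_path_um = 1,
                        length_straight_um = 1, straightness = 1),
                   class = "fls_object")
  img <- matrix(0.2, 64, 64)            # uniform background 0.2
  img[base_px] <- 0.2 + 0.7             # planted signal 0.7 on the base
  rec <- measure_fls(obj, list(gfp = img))
  expect_equal(rec$background_gfp, 0.2, tolerance = 1e-9)
  expect_lt(abs(rec$intensity_gfp - 0.7) / 0.7, 0.02)
  expect_equal(rec$base_area_um2, nrow(base_px) * 0.1487^2)
  # a neighbouring base inside the ring is excluded from the background
  nb_px <- filodyn:::disk_pixels(20, 29, 3, 64, 64)
  img2 <- img; img2[nb_px] <- 5
  rec2 <- measure_fls(obj, list(gfp = img2),
                      all_base_pixels = rbind(base_px, nb_px))
  expect_equal(rec2$background_gfp, 0.2, tolerance = 1e-9)
})

test_that("a helically curved rod yields the planted chord/arc straightness", {
  nr <- 48; nc <- 48; nz <- 10
  t_z <- seq(0, pi, length.out = nz)
  centres <- cbind(x = 24 + 6 * cos(t_z), y = 18 + 6 * sin(t_z))
  stack <- array(0.05, c(nr, nc, nz))
  for (z in seq_len(nz)) {
    px <- filodyn:::disk_pixels(centres[z, "x"], centres[z, "y"], 2, nr, nc)
    stack[cbind(px, z)] <- 1
    stack[, , z] <- EBImage::gblur(stack[, , z], 1)
  }
  objs <- segment_fls_stack(stack, max_trace_radius = 4, px_size_um = 0.2,
                            z_step_um = 0.4)
  expect_length(objs, 1)
  steps <- cbind(diff(centres[, "x"]) * 0.2, diff(centres[, "y"]) * 0.2, 0.4)
  true_path <- sum(sqrt(rowSums(steps^2)))
  true_chord <- sqrt(sum(((centres[nz, ] - centres[1, ]) * 0.2)^2) +
                       ((nz - 1) * 0.4)^2)
  expect_lt(abs(objs[[1]]$straightness - true_chord / true_path), 0.05)
  expect_lt(objs[[1]]$straightness, 1)
})

test_that("local Gaussian threshold marks lines, ignores flat and offset fields", {
  expect_false(any(preprocess_movie(matrix(5, 32, 32))))
  img <- matrix(0, 32, 32)
  img[16, 5:28] <- 1
  mask <- preprocess_movie(img)
  expect_true(all(mask[16, 8:25]))
  expect_false(any(mask[1:10, ]))
  # invariant to a global additive offset
  expect_identical(mask, preprocess_movie(img + 100))
  expect_error(preprocess_movie(matrix(0, 5, 5)), "smaller")
})

test_that("pixel classifier is exact on separable frames and 20:1 balanced", {
  set.seed(3)
  img <- matrix(rnorm(64 * 64, 0, 0.05), 64, 64)
  truth <- matrix(FALSE, 64, 64)
  truth[line_px(10, 5, 10, 58)] <- TRUE
  truth[line_px(40, 8, 20, 50)] <- TRUE
  img[truth] <- img[truth] + 1
  clf <- train_pixel_classifier(list(img), list(truth), seed = 9)
  expect_equal(clf$n_neg, 20 * clf$n_pos)
  mask <- classify_frame(clf, img)
  expect_gte(mean(mask[truth]), 0.95)
  # determinism: identical predictions across two training runs
  clf2 <- train_pixel_classifier(list(img), list(truth), seed = 9)
  expect_identical(mask, classify_frame(clf2, img))
  expect_error(train_pixel_classifier(list(img),
                                      list(matrix(FALSE, 64, 64))),
               "no positive")
})

test_that("mask cleanup honours the strict 40-pixel gate and join gates", {
  # masks are two pixels thick, as the classifier produces them
  # 39-px component removed, 40-px kept
  m39 <- matrix(FALSE, 60, 60); m39[30:31, 1:20] <- TRUE; m39[31, 20] <- FALSE
  m40 <- matrix(FALSE, 60, 60); m40[30:31, 1:20] <- TRUE
  expect_length(mask_to_filopodia(m39), 0)
  expect_length(mask_to_filopodia(m40), 1)
  # collinear fragments, tips ~15 px apart, tangents parallel: joined
  mj <- matrix(FALSE, 60, 120)
  mj[30:31, 5:49] <- TRUE
  mj[30:31, 65:109] <- TRUE
  joined <- mask_to_filopodia(mj)
  expect_length(joined, 1)
  expect_gt(measure_skeleton_length(joined[[1]])$length_px, 85)
  # beyond the 20-px distance gate: not joined
  mfar <- matrix(FALSE, 60, 130)
  mfar[30:31, 5:49] <- TRUE
  mfar[30:31, 75:119] <- TRUE
  expect_length(mask_to_filopodia(mfar), 2)
  # perpendicular fragments at ~10 px: angle gate blocks the join
  mperp <- matrix(FALSE, 90, 90)
  mperp[40:41, 5:49] <- TRUE
  mperp[51:90, 59:60] <- TRUE
  expect_length(mask_to_filopodia(mperp), 2)
})

test_that("longest-path lengths match hand values and brute-force enumeration", {
  horiz <- line_px(5, 1, 5, 10)
  expect_equal(measure_skeleton_length(horiz)$length_px, 9)
  diag10 <- cbind(1:10, 1:10)
  expect_equal(measure_skeleton_length(diag10)$length_px, 9 * sqrt(2))
  # Y skeleton: arms of 20, 15 and 10 px from a junction
  junction <- c(30, 30)
  armA <- line_px(30, 30, 30, 10)    # 20 px left
  armB <- line_px(30, 30, 30, 45)    # 15 px right
  armC <- line_px(30, 30, 20, 30)    # 10 px up
  y_px <- unique(rbind(armA, armB, armC))
  res <- measure_skeleton_length(y_px)
  expect_equal(res$length_px, 35)
  expect_length(res$branches, 1)
  expect_equal(nrow(res$branches[[1]]), 10)  # the 10-px arm off the junction
  # oracle equivalence on small random skeletons
  set.seed(5)
  for (i in 1:5) {
    px <- unique(rbind(line_px(10, 10, 10, 18),
                       line_px(10, 14, 6 + i, 14 + i),
                       line_px(10, 18, 14, 18)))
    expect_equal(measure_skeleton_length(px)$length_px,
                 brute_longest_path(px), tolerance = 1e-9)
  }
  # cyclic skeleton flagged and broken
  ring <- rbind(line_px(10, 10, 10, 20), line_px(10, 20, 16, 20),
                line_px(16, 20, 16, 10), line_px(16, 10, 10, 10))
  ring <- unique(ring)
  res2 <- measure_skeleton_length(ring)
  expect_true(res2$had_cycle)
  expect_gt(res2$length_px, 0)
})

test_that("Hungarian linking equals brute force and honours the 30-px gate", {
  set.seed(6)
  for (i in 1:50) {
    n <- sample(2:4, 1); m <- sample(2:4, 1)
    cost <- matrix(round(runif(n * m, 0, 10), 3), n, m)
    if (i %% 3 == 0) cost[sample(length(cost), 2)] <- Inf
    match <- solve_assignment(cost)
    got <- sum(cost[cbind(which(!is.na(match)), match[!is.na(match)])])
    oracle <- brute_assignment(cost)
    expect_equal(sum(!is.na(match)), oracle$cardinality)
    expect_equal(got, oracle$cost, tolerance = 1e-9)
  }
  # single filament moving 5 px/frame: one unbroken track
  det <- lapply(0:9, function(fr)
    data.frame(cx = 10 + 5 * fr, cy = 20, length_px = 30))
  tr <- link_tracks(det)
  expect_equal(length(unique(tr$track_id)), 1)
  # 31-px displacement: track terminates, new one begins
  det2 <- list(data.frame(cx = 10, cy = 10, length_px = 30),
               data.frame(cx = 41, cy = 10, length_px = 30))
  expect_equal(length(unique(link_tracks(det2)$track_id)), 2)
  # exactly 30 px is still allowed
  det3 <- list(data.frame(cx = 10, cy = 10, length_px = 30),
               data.frame(cx = 40, cy = 10, length_px = 30))
  expect_equal(length(unique(link_tracks(det3)$track_id)), 1)
  # length term preserves identities when filaments approach each other
  detA <- list(data.frame(cx = c(10, 30), cy = 10, length_px = c(10, 60)),
               data.frame(cx = c(22, 18), cy = 10, length_px = c(12, 58)))
  trA <- link_tracks(detA)
  id_short <- trA$track_id[trA$frame == 1 & trA$length_px == 10]
  expect_equal(trA$track_id[trA$frame == 2 & trA$length_px == 12], id_short)
})

test_that("track velocities drop short tracks and convert units correctly", {
  # 4-frame track removed
  tr4 <- data.frame(track_id = 1, frame = 1:4, cx = 0, cy = 0,
                    length_px = 1:4)
  expect_equal(nrow(track_velocities(tr4)), 0)
  # 1 px/frame at 15 s/frame and 0.1487 um/px -> 0.5948 um/min
  tr <- data.frame(track_id = 1, frame = 1:11, cx = 0, cy = 0,
                   length_px = 20 + 1:11)
  tv <- track_velocities(tr, frame_interval_s = 15, px_size_um = 0.1487)
  inner <- 3:9
  expect_equal(tv$velocity_um_min[inner],
               rep(0.1487 * 4, length(inner)), tolerance = 1e-9)
})

test_that("noiseless movie pipeline meets the end-to-end oracle bounds", {
  gm <- growth_model_params(M = 2, N = 2, theta = 11, eta = 2,
                            duration = 6, seed = 8)
  mv <- gen_filament_movie(n_filaments = 5, frames = 20, growth_model = gm,
                           seed = 8)
  dets <- lapply(seq_len(20), function(fr) {
    fil <- mask_to_filopodia(mv$movie[, , fr] > 0.5)
    do.call(rbind, lapply(fil, function(px) {
      m <- measure_skeleton_length(px)
      com <- colMeans(m$chain)
      data.frame(cy = com[1], cx = com[2], length_px = m$length_px)
    }))
  })
  # identity preservation: as many tracks as filaments, all full length
  tracks <- link_tracks(dets)
  expect_equal(length(unique(tracks$track_id)), 5)
  expect_true(all(table(tracks$track_id) == 20))
  # per-frame length error < 10% for filaments >= 20 px
  errs <- unlist(lapply(seq_len(20), function(fr) {
    gt <- mv$tracks[mv$tracks$frame == fr, ]
    d <- dets[[fr]]
    vapply(seq_len(nrow(d)), function(i) {
      j <- which.min((gt$cx - d$cx[i])^2 + (gt$cy - d$cy[i])^2)
      if (gt$arc_length_px[j] < 20) return(NA_real_)
      abs(d$length_px[i] - gt$arc_length_px[j]) / gt$arc_length_px[j]
    }, numeric(1))
  }))
  expect_lt(max(errs, na.rm = TRUE), 0.10)
})

test_that("stacks and movies survive the 16-bit TIFF round trip", {
  sc <- gen_rod_stack(2, z_planes = 5, seed = 3, noise_sd = 0.01)
  path <- tempfile(fileext = ".tif")
  write_stack_tiff(sc$stack, path)
  back <- read_stack_tiff(path)
  expect_equal(dim(back), dim(sc$stack))
  rng <- range(sc$stack)
  expect_equal(back * diff(rng) + rng[1], sc$stack, tolerance = 2e-4)
  unlink(path)
})
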