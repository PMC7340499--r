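# Puncta detection, proximity filtering, per-soma counting and bias.

square_soma <- function(cx, cy, half = 5, marker = TRUE, id = 1L) {
  soma_contour(cbind(cx + c(-half, half, half, -half),
                     cy + c(-half, -half, half, half)),
               marker_positive = marker, soma_id = id)
}

test_that("max-intensity projection takes the per-pixel maximum over the
           leading slices", {
  st <- array(3, dim = c(4, 5, 7))
  expect_equal(max_intensity_projection(st, 7), matrix(3, 4, 5))
  st[2, 3, 3] <- 9
  st[1, 1, 7] <- 99  # beyond the projected slices
  mip <- max_intensity_projection(st, 5)
  expect_equal(mip[2, 3], 9)
  expect_equal(mip[1, 1], 3)
  set.seed(2)
  st2 <- array(runif(4 * 5 * 7), dim = c(4, 5, 7))
  brute <- pmax(st2[, , 1], st2[, , 2], st2[, , 3])
  expect_equal(max_intensity_projection(st2, 3), brute)
  expect_error(max_intensity_projection(st2, 8),
               class = "ca1quant_sizing_error")
})

test_that("the blob detector recovers known spot centres and ignores blank
           or merged-free fields", {
  set.seed(5)
  px <- 0.04
  # rejection-sample spot centres at least 0.75 um apart (3x the expected
  # diameter) so no pair merges
  pts <- matrix(numeric(0), ncol = 2)
  while (nrow(pts) < 25) {
    cand <- c(runif(1, 1, 9), runif(1, 1, 9))
    if (!nrow(pts) || min(sqrt(colSums((t(pts) - cand)^2))) > 0.75)
      pts <- rbind(pts, cand)
  }
  truth <- data.frame(x = pts[, 1], y = pts[, 2])
  img <- render_puncta_image(truth, field_um = 10, pixel_size_um = px,
                             spot_sigma_um = 0.1, snr = 10, seed = 3L)
  det <- detect_puncta(img, px, expected_diameter_um = 0.25)
  expect_equal(nrow(det), 25L)
  near <- vapply(seq_len(nrow(truth)), function(i)
    min(sqrt((det$x - truth$x[i])^2 + (det$y - truth$y[i])^2)), numeric(1))
  expect_true(all(near <= px * 1.5))

  expect_warning(d0 <- detect_puncta(matrix(0, 100, 100), px), "blank")
  expect_equal(nrow(d0), 0L)

  # two spots separated by 3x the expected diameter stay distinct
  pair <- data.frame(x = c(2, 2.75), y = c(2, 2))
  img2 <- render_puncta_image(pair, field_um = 5, pixel_size_um = px,
                              snr = 20, seed = 4L)
  expect_equal(nrow(detect_puncta(img2, px)), 2L)
})

test_that("proximity filters apply their distance rules exactly", {
  soma <- square_soma(10, 10)
  geph <- data.frame(x = c(5, 10, 16.5, 10), y = c(10, 10, 10, 15.9))
  kept <- filter_gephyrin_by_soma(geph, list(soma), 1.0)
  # on the vertex-side boundary, inside, 1.5 um out, 0.9 um out
  expect_equal(nrow(kept), 3L)
  expect_false(16.5 %in% kept$x)

  pre <- data.frame(x = c(5.9, 5, 20), y = c(10, 11.01, 20))
  kp <- filter_presyn_by_gephyrin(pre, data.frame(x = 5, y = 10), 1.0)
  expect_equal(kp$x, 5.9)  # 0.9 um kept; 1.01 um and far point dropped
})

test_that("counting assigns each punctum once, to the nearest qualifying
           soma with ties to the lower id", {
  somas <- list(square_soma(10, 10, id = 2L, marker = TRUE),
                square_soma(30, 10, id = 1L, marker = FALSE))
  # equidistant between the two facing edges (15.1 um from x=15 and x=25)
  pre <- data.frame(x = c(20, 15.1, 24.9, 20), y = c(10, 10, 10, 30))
  cnt <- count_on_somas(pre, somas, radius_um = 0.2)
  expect_equal(cnt$soma_id, c(1L, 2L))
  # the tie point is 5 um from both: too far; 15.1 is 0.1 from soma 2;
  # 24.9 is 0.1 from soma 1; the distant point is uncounted
  expect_equal(cnt$count[cnt$soma_id == 2L], 1L)
  expect_equal(cnt$count[cnt$soma_id == 1L], 1L)

  tie <- data.frame(x = 20, y = 10)
  somas_close <- list(square_soma(15, 10, half = 4.9, id = 5L),
                      square_soma(25, 10, half = 4.9, id = 3L))
  cnt2 <- count_on_somas(tie, somas_close, radius_um = 0.2)
  expect_equal(cnt2$count[cnt2$soma_id == 3L], 1L)  # tie -> lower id
  expect_equal(cnt2$count[cnt2$soma_id == 5L], 0L)
})

test_that("the bias ratio divides summed counts and rejects an empty
           negative class", {
  counts <- data.frame(soma_id = 1:4,
                       marker_positive = c(TRUE, TRUE, FALSE, FALSE),
                       count = c(30L, 36L, 20L, 30L))
  b <- innervation_bias(counts)
  expect_equal(b$bias_ratio, 66 / 50)
  expect_equal(b$total_pos, 66L)

  even <- counts; even$count <- c(30L, 30L, 30L, 30L)
  expect_equal(innervation_bias(even)$bias_ratio, 1.0)

  zero <- counts; zero$count[3:4] <- 0L
  expect_error(innervation_bias(zero),
               class = "ca1quant_undefined_ratio_error")
})

test_that("pipeline counts survive a brute-force re-derivation and filter
           order does not matter", {
  for (s in 1:5) {
    scene <- gen_scene(bias = 1.2, puncta_rate_per_soma = 20, seed = 900 + s)
    res <- quantify_scene(scene)
    brute <- brute_force_scene_counts(scene)
    expect_equal(stats::setNames(res$per_soma$count,
                                 res$per_soma$soma_id), brute)
    # order independence: soma-count rule applied before the gephyrin
    # pairing rule gives the same final counts
    pre_near_soma <- scene$puncta$presynaptic[
      vapply(seq_len(nrow(scene$puncta$presynaptic)), function(i) {
        any(vapply(scene$somas, function(sc)
          ca1quant:::point_soma_distance(
            cbind(scene$puncta$presynaptic$x[i],
                  scene$puncta$presynaptic$y[i]), sc$vertices),
          numeric(1)) <= 0.2)
      }, logical(1)), ]
    gk <- filter_gephyrin_by_soma(scene$puncta$gephyrin, scene$somas)
    pk2 <- filter_presyn_by_gephyrin(pre_near_soma, gk)
    cnt2 <- count_on_somas(pk2, scene$somas)
    expect_equal(cnt2$count, res$per_soma$count)
  }
})

test_that("counts are invariant under rigid motion of the whole scene", {
  scene <- gen_scene(bias = 1.0, puncta_rate_per_soma = 25, seed = 31L)
  res0 <- quantify_scene(scene)
  th <- 0.7; R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  move <- function(m) sweep(m %*% t(R), 2, c(-40, 17), `+`)
  somas2 <- lapply(scene$somas, function(s) {
    soma_contour(move(s$vertices), s$marker_positive, s$soma_id)
  })
  mv_pts <- function(df) {
    xy <- move(cbind(df$x, df$y)); df$x <- xy[, 1]; df$y <- xy[, 2]; df
  }
  scene2 <- puncta_scene(somas2, lapply(scene$puncta, mv_pts))
  res1 <- quantify_scene(scene2)
  expect_equal(res1$per_soma$count, res0$per_soma$count)
  expect_equal(res1$bias_ratio, res0$bias_ratio)
})
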