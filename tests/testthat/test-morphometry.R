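# Apical-tree extraction, branch indices, bifurcation selection, Sholl.

test_that("extract_apical keeps only the apical compartment with correct
           cumulative distances", {
  nm <- y_tree_neuron(split_at = 50, daughter_len = 20)
  n_apical <- sum(nm$compartment == "apical")
  tr <- extract_apical(nm)
  expect_equal(nrow(tr), n_apical)

  cable <- extract_apical(straight_cable_neuron(300))
  expect_equal(max(cable$cum_dist), 300)
  expect_equal(tree_total_length(cable), 300)
  expect_error(extract_apical(straight_cable_neuron(100), "axon"),
               class = "ca1quant_empty_compartment_error")
})

test_that("total length and bifurcation counts match a naive edge-by-edge
           re-count on random synthetic trees", {
  for (i in 1:10) {
    nm <- gen_tree(if (i %% 2) "complex" else "simple", seed = 1000L + i)
    tr <- extract_apical(nm)
    # brute force: sum Euclidean parent-child distances over apical nodes,
    # using the raw morphology table
    ap <- nm[nm$compartment == "apical", ]
    px <- nm$x[ap$parent]; py <- nm$y[ap$parent]; pz <- nm$z[ap$parent]
    naive_len <- sum(sqrt((ap$x - px)^2 + (ap$y - py)^2 + (ap$z - pz)^2))
    expect_equal(tree_total_length(tr), naive_len, tolerance = 1e-9)
    kids <- table(factor(tr$parent, levels = tr$id))
    expect_identical(tree_bifurcation_count(tr), sum(kids >= 2))
  }
})

test_that("first prominent bifurcation honours the prominence rule", {
  # symmetric Y at 150 um with two 200 um daughters
  fb <- first_prominent_bifurcation(extract_apical(y_tree_neuron(150, 200)))
  expect_true(fb$prominent)
  expect_equal(fb$distance_um, 150)

  # a 5 um twig at 50 um must be skipped; the balanced split at 300 wins
  rows <- list(data.frame(id = 1, parent = NA, x = 0, y = 0, z = 0,
                          radius = 5, compartment = "soma"))
  id <- 1
  add <- function(parent, x, y, z) {
    id <<- id + 1
    rows[[length(rows) + 1]] <<- data.frame(
      id = id, parent = parent, x = x, y = y, z = z, radius = 0.5,
      compartment = "apical")
    id
  }
  p <- 1
  for (yy in seq(10, 300, 10)) {
    p <- add(p, 0, yy, 0)
    if (yy == 50) add(p, 5, 50, 0)             # 5 um twig
  }
  for (side in c(1, -1)) {
    q <- p
    for (s in 1:10) q <- add(q, side * s * 7, 300 + s * 7, 0)
  }
  nm <- neuron_morphology(do.call(rbind, rows))
  fb2 <- first_prominent_bifurcation(extract_apical(nm),
                                     prominence_frac = 0.2)
  expect_true(fb2$prominent)
  expect_equal(fb2$distance_um, 300)
  expect_equal(fb2$n_skipped, 1L)

  # unbranched cable: flagged, distance = full extent
  fb3 <- first_prominent_bifurcation(extract_apical(
    straight_cable_neuron(220)))
  expect_false(fb3$prominent)
  expect_true(is.na(fb3$node))
  expect_equal(fb3$distance_um, 220)
})

test_that("LRI and ORI match the stated formulas on a constructed tree", {
  nm <- index_fixture_neuron(trunk_um = 100)
  tr <- extract_apical(nm)
  f <- lri_ori(tr, index_config(d0_um = 150))
  # Lp = 100, Ld1 = Ld2 = 100, Nd1 = Nd2 = 2, Np = 0
  expect_equal(f$lri, log(2), tolerance = 1e-12)
  expect_equal(f$ori, log(6), tolerance = 1e-12)
  expect_false(f$distant_scaled)

  # same topology, trunk 300 > D0 = 150: both indices scaled by 150/300
  nm2 <- index_fixture_neuron(trunk_um = 300)
  f2 <- lri_ori(extract_apical(nm2), index_config(d0_um = 150))
  f2_raw <- lri_ori(extract_apical(nm2), index_config(d0_um = Inf))
  expect_true(f2$distant_scaled)
  expect_equal(f2$lri, f2_raw$lri * 0.5, tolerance = 1e-12)
  expect_equal(f2$ori, f2_raw$ori * 0.5, tolerance = 1e-12)

  # unbranched tree: undefined-index flag
  f3 <- lri_ori(extract_apical(straight_cable_neuron(200)))
  expect_false(f3$defined)
  expect_true(is.na(f3$lri))
})

test_that("extending a daughter subtree strictly increases LRI", {
  nm <- index_fixture_neuron(100)
  base <- lri_ori(extract_apical(nm), index_config(d0_um = Inf))$lri
  # graft 30 um onto one daughter tip (node farthest out on +x side)
  tip <- which.max(nm$x)
  graft <- data.frame(id = nrow(nm) + (1:3), parent = c(tip, nrow(nm) + 1:2),
                      x = nm$x[tip] + (1:3) * 10, y = nm$y[tip],
                      z = nm$z[tip], radius = 0.5, compartment = "apical")
  nm2 <- neuron_morphology(rbind(as.data.frame(nm), graft))
  longer <- lri_ori(extract_apical(nm2), index_config(d0_um = Inf))$lri
  expect_gt(longer, base)
})

test_that("the branch indices are invariant under rigid motion", {
  nm <- gen_tree("complex", seed = 7L)
  f0 <- lri_ori(extract_apical(nm))
  rot <- rotation3(0.4, -0.9, 1.3)
  xyz <- as.matrix(as.data.frame(nm)[, c("x", "y", "z")]) %*% t(rot)
  moved <- as.data.frame(nm)
  moved$x <- xyz[, 1] + 55; moved$y <- xyz[, 2] - 12; moved$z <- xyz[, 3] + 3
  f1 <- lri_ori(extract_apical(neuron_morphology(moved)))
  expect_equal(f1$lri, f0$lri, tolerance = 1e-9)
  expect_equal(f1$ori, f0$ori, tolerance = 1e-9)
})

test_that("Sholl crossings match hand counts and vanish beyond the tips", {
  s1 <- sholl(extract_apical(straight_cable_neuron(300)), step_um = 50)
  expect_equal(s1$intersections[1:6], rep(1L, 6))
  expect_true(all(s1$intersections[s1$radii > 300] == 0))

  # Y-tree splitting at 75 um, daughters to radius 200
  nm <- y_tree_neuron(split_at = 75, daughter_len = 150)
  s2 <- sholl(extract_apical(nm), step_um = 50)
  expect_equal(s2$intersections[1:3], c(1L, 2L, 2L))
  expect_equal(s2$peak_count, 2L)

  # property: zero beyond the maximum tip distance on random trees
  for (seed in 11:14) {
    tr <- extract_apical(gen_tree("complex", seed = seed))
    s <- sholl(tr)
    expect_true(all(s$intersections[s$radii > max(tr$cum_dist)] == 0))
  }
})

test_that("synthetic cohorts reproduce the expected morphometric contrasts", {
  coh <- gen_tree_cohort(25, 25, seed = 3L)
  ft <- morpho_feature_table(coh)
  cx <- attr(coh, "truth") == "complex"
  # complex cells bifurcate sooner and score higher on both indices
  expect_lt(mean(ft$first_bif_um[cx]), mean(ft$first_bif_um[!cx]))
  expect_gt(mean(ft$lri[cx]), mean(ft$lri[!cx]))
  expect_gt(mean(ft$ori[cx]), mean(ft$ori[!cx]))
  # wild-type-like complex cohort: Sholl peak 8-11 crossings
  pk <- vapply(which(cx), function(i)
    sholl(extract_apical(coh[[i]]))$peak_count, integer(1))
  expect_gte(mean(pk), 8)
  expect_lte(mean(pk), 11)
})
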