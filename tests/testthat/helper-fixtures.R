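# Fixture builders and independent oracles used across the suite.
# Everything is generated in code; no stored data.

# Minimal morphology: soma at origin plus an unbranched apical cable along
# +y, sampled every `step` um out to `length_um`.
straight_cable_neuron <- function(length_um = 300, step = 10) {
  n_seg <- length_um / step
  nodes <- data.frame(
    id = seq_len(n_seg + 1L),
    parent = c(NA, seq_len(n_seg)),
    x = 0, y = c(0, seq_len(n_seg) * step), z = 0,
    radius = c(5, rep(0.5, n_seg)),
    compartment = c("soma", rep("apical", n_seg)))
  neuron_morphology(nodes)
}

# Y-shaped apical tree: trunk along +y to `split_at`, two straight daughters
# (one +x-leaning, one -x-leaning) each extending `daughter_len` more.
y_tree_neuron <- function(split_at = 150, daughter_len = 200, step = 10) {
  rows <- list(data.frame(id = 1, parent = NA, x = 0, y = 0, z = 0,
                          radius = 5, compartment = "soma"))
  id <- 1
  add_chain <- function(from_id, start, dir, len) {
    n_seg <- round(len / step)
    for (s in seq_len(n_seg)) {
      id <<- id + 1
      pos <- start + dir * s * step
      rows[[length(rows) + 1]] <<- data.frame(
        id = id, parent = if (s == 1) from_id else id - 1,
        x = pos[1], y = pos[2], z = pos[3], radius = 0.5,
        compartment = "apical")
    }
    id
  }
  top <- add_chain(1, c(0, 0, 0), c(0, 1, 0), split_at)
  apex <- c(0, split_at, 0)
  add_chain(top, apex, c(sin(0.5), cos(0.5), 0), daughter_len)
  add_chain(top, apex, c(-sin(0.5), cos(0.5), 0), daughter_len)
  neuron_morphology(do.call(rbind, rows))
}

# Tree with exactly known index inputs: trunk of `trunk_um`, then two
# daughter subtrees each of total cable length 100 um containing exactly 2
# bifurcations. Daughter layout (lengths in um):
#   stem 20 -> bif -> branch 30 | branch 10 -> bif -> 20 | 20   (= 100)
index_fixture_neuron <- function(trunk_um = 100) {
  step <- 10
  rows <- list(data.frame(id = 1, parent = NA, x = 0, y = 0, z = 0,
                          radius = 5, compartment = "soma"))
  id <- 1
  add <- function(parent, pos) {
    id <<- id + 1
    rows[[length(rows) + 1]] <<- data.frame(
      id = id, parent = parent, x = pos[1], y = pos[2], z = pos[3],
      radius = 0.5, compartment = "apical")
    id
  }
  add_chain <- function(parent, start, dir, len) {
    n <- round(len / step)
    for (s in seq_len(n)) parent <- add(parent, start + dir * s * step)
    parent
  }
  top <- add_chain(1, c(0, 0, 0), c(0, 1, 0), trunk_um)
  apex <- c(0, trunk_um, 0)
  for (side in c(1, -1)) {
    dir_out <- c(side, 0, 0)
    d_bif <- add_chain(top, apex, dir_out, 20)
    p_bif <- apex + dir_out * 20
    add_chain(d_bif, p_bif, c(0, 0, 1), 30)            # branch A: 30
    d2 <- add_chain(d_bif, p_bif, c(0, 0, -1), 10)     # branch B stem: 10
    p2 <- p_bif + c(0, 0, -10)
    add_chain(d2, p2, c(side * 0.6, 0.8, 0), 20)       # B1: 20
    add_chain(d2, p2, c(side * 0.6, -0.8, 0), 20)      # B2: 20
  }
  neuron_morphology(do.call(rbind, rows))
}

# Analytic RC + sag neuron: hyperpolarizing step response
#   V(t) = bl - A1 (1 - e^(-t/tau1)) + A2 (1 - e^(-t/tau2)),  t from onset.
# True steady deflection = A1 - A2 (so true Rin = (A1 - A2)/|I|); the true
# peak deflection has the closed-form optimum below.
rc_sag_model <- function(i_pA = -100, rin_MOhm = 150, sag_true = 0.667,
                         tau1 = 0.01, tau2 = 0.05, bl = -65,
                         fs = 20000, t_pre = 0.2, t_step = 1.5,
                         t_post = 0.2) {
  a_ss <- abs(i_pA) * rin_MOhm / 1000          # steady deflection, mV
  a_peak <- a_ss / sag_true                    # target true peak deflection
  # solve for A1, A2 with peak constraint: deflection f(t) =
  # A1(1-e^-t/tau1) - A2(1-e^-t/tau2); A1 - A2 = a_ss and max f = a_peak.
  # One-dimensional search on A1 is exact enough for a fixture oracle.
  peak_of <- function(a1) {
    a2 <- a1 - a_ss
    r <- (a1 / tau1) / (a2 / tau2)
    t_star <- log(r) / (1 / tau1 - 1 / tau2)
    a1 * (1 - exp(-t_star / tau1)) - a2 * (1 - exp(-t_star / tau2))
  }
  a1 <- stats::uniroot(function(a) peak_of(a) - a_peak,
                       c(a_ss + 1e-9, 40 * a_ss))$root
  a2 <- a1 - a_ss
  t <- seq(0, t_pre + t_step + t_post - 1 / fs, by = 1 / fs)
  v <- rep(bl, length(t))
  in_step <- t >= t_pre & t < t_pre + t_step
  ts <- t[in_step] - t_pre
  v[in_step] <- bl - a1 * (1 - exp(-ts / tau1)) + a2 * (1 - exp(-ts / tau2))
  after <- t >= t_pre + t_step
  v[after] <- bl
  list(sweep = ephys_sweep(v, fs, t_pre, t_pre + t_step, i_pA),
       true_rin = a_ss / abs(i_pA) * 1000,
       true_sag = a_ss / peak_of(a1))
}

# Stylized spike train: slow ramp to threshold (below the dV/dt criterion),
# fast rise to the peak, fast fall to an AHP trough, recovery to baseline.
spike_train_sweep <- function(spike_times_s, fs = 20000, bl = -70,
                              thr = -45, peak = 35, trough = -60,
                              t_pre = 0.1, t_total = 0.7,
                              step_end = 0.6) {
  n <- round(t_total * fs)
  v <- rep(bl, n)
  # slopes: 5 mV/ms approach (below the 20 mV/ms criterion), then exactly
  # 20 mV/ms for 0.2 ms at threshold (the detected crossing), then fast
  ramp_ms <- 5; kink_ms <- 0.2; rise_ms <- 0.4; fall_ms <- 0.6; rec_ms <- 4
  for (t0 in spike_times_s) {
    seg <- function(t_from, t_to, v_from, v_to) {
      i0 <- round(t_from * fs) + 1L; i1 <- round(t_to * fs)
      if (i1 >= i0 && i1 <= n)
        v[i0:i1] <<- seq(v_from, v_to, length.out = i1 - i0 + 1L)
    }
    t_thr <- t0 - (rise_ms + kink_ms) / 1000
    seg(t_thr - ramp_ms / 1000, t_thr, bl, thr)
    seg(t_thr, t_thr + kink_ms / 1000, thr, thr + 20 * kink_ms)
    seg(t_thr + kink_ms / 1000, t0, thr + 20 * kink_ms, peak)
    seg(t0, t0 + fall_ms / 1000, peak, trough)
    seg(t0 + fall_ms / 1000, t0 + fall_ms / 1000 + rec_ms / 1000,
        trough, bl)
  }
  ephys_sweep(v, fs, t_pre, step_end, 200)
}

# Independent time-domain cross-correlation oracle:
# c(k) = sum_t x[t] y[t+k] over the overlapping (zero-padded) region.
xcorr_time_domain <- function(x, y, max_lag) {
  n <- length(x)
  vapply(-max_lag:max_lag, function(k) {
    if (k >= 0) sum(x[1:(n - k)] * y[(1 + k):n])
    else sum(x[(1 - k):n] * y[1:(n + k)])
  }, numeric(1))
}

# Brute-force re-derivation of per-soma counts straight from the raw scene
# (point-to-every-edge distances, all-pairs proximity, nearest-soma
# assignment with the lower-id tie rule). Distances reuse only the
# elementary point/segment primitives, not the pipeline's filter functions.
brute_force_scene_counts <- function(scene, geph_r = 1.0, pre_r = 1.0,
                                     soma_r = 0.2) {
  seg_dist <- function(px, py, ax, ay, bx, by) {
    t <- ((px - ax) * (bx - ax) + (py - ay) * (by - ay)) /
      pmax((bx - ax)^2 + (by - ay)^2, 1e-300)
    t <- pmin(1, pmax(0, t))
    sqrt((px - (ax + t * (bx - ax)))^2 + (py - (ay + t * (by - ay)))^2)
  }
  one_soma_dist <- function(px, py, poly) {
    nv <- nrow(poly)
    d <- Inf
    inside <- FALSE
    j <- nv
    for (i in seq_len(nv)) {
      j2 <- if (i == nv) 1L else i + 1L
      d <- min(d, seg_dist(px, py, poly[i, 1], poly[i, 2],
                           poly[j2, 1], poly[j2, 2]))
      if ((poly[i, 2] > py) != (poly[j, 2] > py) &&
          px < (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) /
            (poly[j, 2] - poly[i, 2]) + poly[i, 1]) inside <- !inside
      j <- i
    }
    if (inside) 0 else d
  }
  geph <- scene$puncta$gephyrin
  pre <- scene$puncta$presynaptic
  ids <- vapply(scene$somas, `[[`, integer(1), "soma_id")
  geph_keep <- vapply(seq_len(nrow(geph)), function(i) {
    any(vapply(scene$somas, function(s)
      one_soma_dist(geph$x[i], geph$y[i], s$vertices), numeric(1)) <=
        geph_r)
  }, logical(1))
  gx <- geph$x[geph_keep]; gy <- geph$y[geph_keep]
  counts <- stats::setNames(integer(length(ids)), sort(ids))
  for (i in seq_len(nrow(pre))) {
    if (!any((pre$x[i] - gx)^2 + (pre$y[i] - gy)^2 <= pre_r^2)) next
    d <- vapply(scene$somas, function(s)
      one_soma_dist(pre$x[i], pre$y[i], s$vertices), numeric(1))
    ord <- order(d, ids)
    if (d[ord[1]] <= soma_r) {
      key <- as.character(ids[ord[1]])
      counts[key] <- counts[key] + 1L
    }
  }
  counts
}

# Rigid 3D rotation matrix from Euler-like angles.
rotation3 <- function(a, b, c) {
  rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
               byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
               byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cos(c), -sin(c), 0, sin(c), cos(c)), 3,
               byrow = TRUE)
  rz %*% ry %*% rx
}
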