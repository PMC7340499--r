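# Seeded generators giving every pipeline stage inputs with known ground
# truth: dendritic-tree archetypes, intrinsic-physiology cohorts, wash-in
# series, puncta scenes with a controllable innervation bias, two-channel
# gamma oscillations with an injected lag, and positional censuses.
# Identical configuration (including seed) gives bit-identical output; each
# generator draws from its own seeded stream.

unit <- function(v) v / sqrt(sum(v^2))

# Rotate unit vector v by angle theta toward a random perpendicular
# direction (isotropic azimuth).
jitter_direction <- function(v, theta) {
  r <- stats::rnorm(3)
  perp <- r - sum(r * v) * v
  if (sum(perp^2) < 1e-12) perp <- c(v[2], -v[1], 0)
  unit(cos(theta) * v + sin(theta) * unit(perp))
}

#' Generate a synthetic pyramidal-cell morphology
#'
#' Two apical archetypes: *complex* cells place their first prominent
#' bifurcation early (drawn uniformly over `bif_range`, default 150-250 µm)
#' and branch richly beyond it; *simple* cells run a long sparsely branched
#' trunk (first bifurcation 300-400 µm). Both carry a soma, short basal
#' stubs, and occasionally a small non-prominent twig on the trunk. Growth
#' proceeds in 10 µm segments, mostly radially with small angular jitter,
#' daughters diverging by 20-40 degrees; branch tips bifurcate with
#' probability `branch_prob` per step (within `branch_zone_um` of the
#' first bifurcation) and terminate with increasing probability beyond
#' `term_start_um`. The defaults for the complex archetype are calibrated
#' so a wild-type-like cohort's Sholl profiles peak at 8-11 crossings in
#' the 200-280 µm range beyond the soma.
#'
#' @param archetype `"complex"` or `"simple"`.
#' @param seed integer seed.
#' @param bif_range first-bifurcation draw (µm); default depends on
#'   archetype.
#' @param branch_prob per-10 µm-step bifurcation probability beyond the
#'   first bifurcation.
#' @param branch_zone_um distance past the first bifurcation within which
#'   `branch_prob` applies (an eighth of it beyond).
#' @param term_start_um,max_extent_um termination ramp (µm past the first
#'   bifurcation).
#' @param twig_prob probability of one short (10 µm) trunk twig.
#' @return A [neuron_morphology] with `metadata$archetype` recording the
#'   ground truth.
#' @export
gen_tree <- function(archetype = c("complex", "simple"), seed = 1L,
                     bif_range = NULL, branch_prob = NULL,
                     branch_zone_um = 100, term_start_um = NULL,
                     max_extent_um = NULL, twig_prob = 0.5) {
  archetype <- match.arg(archetype)
  defaults <- if (archetype == "complex") {
    list(bif = c(150, 250), pb = 0.18, term = 50, maxe = 150, fs = 3L)
  } else {
    list(bif = c(300, 400), pb = 0.03, term = 30, maxe = 90, fs = 1L)
  }
  if (is.null(bif_range)) bif_range <- defaults$bif
  if (is.null(branch_prob)) branch_prob <- defaults$pb
  if (is.null(term_start_um)) term_start_um <- defaults$term
  if (is.null(max_extent_um)) max_extent_um <- defaults$maxe
  force_splits <- defaults$fs
  step <- 10

  with_seed(seed, {
    cap <- 8192L
    nd_parent <- integer(cap); nd_x <- nd_y <- nd_z <- numeric(cap)
    nd_comp <- character(cap); nd_rad <- numeric(cap)
    n_nodes <- 1L
    nd_parent[1] <- NA_integer_; nd_rad[1] <- 6; nd_comp[1] <- "soma"
    add_node <- function(parent, pos, comp, radius = 0.5) {
      id <- n_nodes + 1L
      n_nodes <<- id
      nd_parent[id] <<- parent
      nd_x[id] <<- pos[1]; nd_y[id] <<- pos[2]; nd_z[id] <<- pos[3]
      nd_rad[id] <<- radius; nd_comp[id] <<- comp
      id
    }
    # basal stubs
    for (ang in c(-2.2, -1.6, -1.0)) {
      p <- 1L
      dir <- c(sin(ang), cos(ang) * -1, stats::runif(1, -0.2, 0.2))
      pos <- c(0, 0, 0)
      for (s in 1:5) {
        dir <- jitter_direction(unit(dir), abs(stats::rnorm(1, 0, 0.08)))
        pos <- pos + dir * step
        p <- add_node(p, pos, "basal")
      }
    }
    # apical trunk to the first prominent bifurcation
    bif_at <- stats::runif(1, bif_range[1], bif_range[2])
    n_trunk <- max(2L, round(bif_at / step))
    twig_seg <- if (stats::runif(1) < twig_prob)
      sample(2:(n_trunk - 1L), 1L) else 0L
    p <- 1L
    dir <- c(0, 1, 0)
    pos <- c(0, 0, 0)
    dist <- 0
    for (s in seq_len(n_trunk)) {
      dir <- jitter_direction(dir, abs(stats::rnorm(1, 0, 0.05)))
      pos <- pos + dir * step
      dist <- dist + step
      p <- add_node(p, pos, "apical")
      if (s == twig_seg) add_node(p, pos + c(0.7, 0.2, 0.7) / sqrt(1.02) *
                                    step, "apical")
    }
    # branch growth beyond the first bifurcation; the first `force_splits`
    # branch generations always bifurcate (dense early branching is the
    # complex hallmark), later ones stochastically
    grow <- function(parent, pos, dir, dist) {
      tips <- list(list(p = parent, pos = pos, dir = dir, dist = dist,
                        gen = 0L, steps = 0L))
      while (length(tips)) {
        nxt <- list()
        for (tp in tips) {
          due <- tp$gen < force_splits && tp$steps >= 2L
          branch_now <- (tp$gen == 0L) || due ||
            stats::runif(1) < (if (tp$dist < bif_at + branch_zone_um)
              branch_prob else branch_prob / 8)
          n_out <- if (branch_now) 2L else 1L
          for (b in seq_len(n_out)) {
            theta <- if (n_out == 2L)
              stats::runif(1, 0.35, 0.7) * (if (b == 1L) 1 else -1) else
              abs(stats::rnorm(1, 0, 0.07))
            d2 <- jitter_direction(tp$dir, abs(theta))
            pos2 <- tp$pos + d2 * step
            dist2 <- tp$dist + step
            id2 <- add_node(tp$p, pos2, "apical")
            past <- dist2 - bif_at
            p_term <- if (past < term_start_um) 0 else
              ((past - term_start_um) / (max_extent_um - term_start_um))^2
            if (past < max_extent_um && stats::runif(1) >= p_term) {
              nxt[[length(nxt) + 1L]] <-
                list(p = id2, pos = pos2, dir = d2, dist = dist2,
                     gen = tp$gen + (n_out == 2L),
                     steps = if (n_out == 2L) 0L else tp$steps + 1L)
            }
          }
        }
        tips <- nxt
      }
    }
    grow(p, pos, dir, dist)
    idx <- seq_len(n_nodes)
    nodes <- data.frame(id = idx, parent = nd_parent[idx], x = nd_x[idx],
                        y = nd_y[idx], z = nd_z[idx], radius = nd_rad[idx],
                        compartment = nd_comp[idx])
    nodes$parent[1] <- NA_integer_
    neuron_morphology(nodes,
                      metadata = list(archetype = archetype, seed = seed))
  })
}

#' Generate a cohort of synthetic morphologies
#'
#' @param n_complex,n_simple cohort sizes.
#' @param seed master seed; each tree gets a derived sub-seed.
#' @param ... passed to [gen_tree()].
#' @return Named list of morphologies with a `truth` attribute (archetype
#'   per cell).
#' @export
gen_tree_cohort <- function(n_complex = 100L, n_simple = 100L, seed = 1L,
                            ...) {
  arche <- c(rep("complex", n_complex), rep("simple", n_simple))
  trees <- lapply(seq_along(arche), function(i) {
    gen_tree(arche[i], seed = derive_seed(seed, i), ...)
  })
  names(trees) <- sprintf("%s%03d", arche, seq_along(arche))
  attr(trees, "truth") <- stats::setNames(arche, names(trees))
  trees
}

# Per-class generating means for the eight intrinsic features. The three
# printed group statistics (RMP, sag, input resistance) follow the
# wild-type complex/simple values; the remaining five are realistic CA1
# pyramidal-cell values with modest class differences.
PHYS_CLASS_MEANS <- list(
  complex = c(rmp_mV = -63.3, sag_index = 0.75, rin_MOhm = 120.4,
              spike_threshold_mV = -45, spike_amplitude_mV = 78,
              ahp_mV = 10.5, adaptation_ratio = 2.2, f_2x_Hz = 22),
  simple = c(rmp_mV = -60.3, sag_index = 0.79, rin_MOhm = 149.3,
             spike_threshold_mV = -44, spike_amplitude_mV = 75,
             ahp_mV = 9.5, adaptation_ratio = 1.9, f_2x_Hz = 26)
)
PHYS_FEATURE_SD <- c(rmp_mV = 4, sag_index = 0.07, rin_MOhm = 35,
                     spike_threshold_mV = 3, spike_amplitude_mV = 8,
                     ahp_mV = 3, adaptation_ratio = 0.6, f_2x_Hz = 6)

#' Generate a two-class intrinsic-physiology cohort
#'
#' Independent normal draws per feature around the per-class means, giving
#' partially overlapping classes (physiology only loosely tracks
#' morphology at the default noise level).
#'
#' @param n_per_class cells per class. Default 50.
#' @param seed integer seed.
#' @param class_means named list `complex`/`simple` of 8-feature vectors.
#' @param feature_sd per-feature generating sd (shared across classes).
#' @param noise_scale multiplier on `feature_sd`; 0 gives perfectly
#'   separable classes. Default 1.
#' @return data.frame of the 8 features with `cell_id` and ground-truth
#'   `true_class` columns.
#' @export
gen_physiology <- function(n_per_class = 50L, seed = 1L,
                           class_means = PHYS_CLASS_MEANS,
                           feature_sd = PHYS_FEATURE_SD, noise_scale = 1) {
  feats <- names(class_means[[1]])
  with_seed(seed, {
    rows <- lapply(names(class_means), function(cl) {
      m <- matrix(stats::rnorm(n_per_class * length(feats),
                               mean = rep(class_means[[cl]],
                                          each = n_per_class),
                               sd = rep(feature_sd * noise_scale,
                                        each = n_per_class)),
                  nrow = n_per_class)
      colnames(m) <- feats
      cbind(data.frame(true_class = cl), as.data.frame(m))
    })
    out <- do.call(rbind, rows)
    out$cell_id <- sprintf("cell%03d", seq_len(nrow(out)))
    out[, c("cell_id", "true_class", feats)]
  })
}

#' Generate a wash-in amplitude series
#'
#' Events occur on a fixed schedule; the mean amplitude steps from
#' `baseline_pA` to `drug_factor * baseline_pA` at drug onset with a
#' 1-minute exponential approach, with multiplicative lognormal event
#' noise of coefficient of variation `event_cv`.
#'
#' @param baseline_pA baseline evoked amplitude. Default 200.
#' @param drug_factor post-drug steady-state scale (1 = no effect).
#' @param event_cv event-to-event coefficient of variation. Default 0.1.
#' @param interval_min event spacing, minutes. Default 0.2.
#' @param t_start_min,t_end_min schedule extent relative to drug onset.
#' @param tau_min exponential approach time constant. Default 1.
#' @param seed integer seed.
#' @return A [washin_series()] with ground truth in a `truth` attribute.
#' @export
gen_washin <- function(baseline_pA = 200, drug_factor = 0.5,
                       event_cv = 0.1, interval_min = 0.2,
                       t_start_min = -5, t_end_min = 12.4, tau_min = 1,
                       seed = 1L) {
  t <- seq(t_start_min, t_end_min, by = interval_min)
  mu <- ifelse(t < 0, baseline_pA,
               baseline_pA * (drug_factor +
                                (1 - drug_factor) * exp(-t / tau_min)))
  sdlog <- sqrt(log(1 + event_cv^2))
  amps <- with_seed(seed,
    mu * stats::rlnorm(length(t), meanlog = -sdlog^2 / 2, sdlog = sdlog))
  out <- washin_series(t, amps, drug_label = "synthetic")
  attr(out, "truth") <- list(baseline_pA = baseline_pA,
                             drug_factor = drug_factor,
                             event_cv = event_cv)
  out
}

ellipse_polygon <- function(center, a, b, phi, n = 40L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- a * cos(th); y <- b * sin(th)
  cbind(center[1] + x * cos(phi) - y * sin(phi),
        center[2] + x * sin(phi) + y * cos(phi))
}

#' Generate a synaptic-puncta scene with a controllable innervation bias
#'
#' Twelve elliptical somas (six marker-positive, six marker-negative) on a
#' jittered grid. Presynaptic boutons are placed on soma perimeters with
#' per-class Poisson rates in ratio `bias` (positive class rate =
#' `bias * puncta_rate_per_soma`); each bouton is paired with a gephyrin
#' punctum jittered by at most 0.15 µm. Unpaired distractor puncta are
#' added in both channels: presynaptic distractors off-soma (they fail the
#' 0.2 µm soma rule) and gephyrin distractors anywhere.
#'
#' @param bias true perimeter-rate ratio (positive/negative). Default 1.
#' @param puncta_rate_per_soma expected boutons per negative soma.
#'   Default 40.
#' @param n_distractor_presyn,n_distractor_geph distractor counts.
#' @param field_um square field side. Default 56.
#' @param seed integer seed.
#' @return A [puncta_scene()] with ground truth in a `truth` attribute.
#' @export
gen_scene <- function(bias = 1.0, puncta_rate_per_soma = 40,
                      n_distractor_presyn = 60L, n_distractor_geph = 80L,
                      field_um = 56, seed = 1L) {
  with_seed(seed, {
    centers <- expand.grid(x = c(8, 21, 34, 47), y = c(9.5, 28, 46.5))
    centers <- centers + matrix(stats::runif(24, -1, 1), ncol = 2)
    marker <- sample(rep(c(TRUE, FALSE), each = 6L))
    somas <- lapply(seq_len(12L), function(i) {
      soma_contour(ellipse_polygon(as.numeric(centers[i, ]),
                                   a = stats::runif(1, 4, 5.2),
                                   b = stats::runif(1, 3, 4.2),
                                   phi = stats::runif(1, 0, pi)),
                   marker_positive = marker[i], soma_id = i)
    })
    pre <- list(); geph <- list()
    for (i in seq_len(12L)) {
      rate <- puncta_rate_per_soma * if (marker[i]) bias else 1
      n_b <- stats::rpois(1, rate)
      if (n_b > 0) {
        poly <- somas[[i]]$vertices
        # random positions on the perimeter with a small normal offset
        seg <- sample(nrow(poly), n_b, replace = TRUE)
        frac <- stats::runif(n_b)
        nxt <- ifelse(seg == nrow(poly), 1L, seg + 1L)
        bx <- poly[seg, 1] + frac * (poly[nxt, 1] - poly[seg, 1])
        by <- poly[seg, 2] + frac * (poly[nxt, 2] - poly[seg, 2])
        off <- stats::runif(n_b, -0.1, 0.1)
        cx <- mean(poly[, 1]); cy <- mean(poly[, 2])
        nrm <- sqrt((bx - cx)^2 + (by - cy)^2)
        bx <- bx + off * (bx - cx) / nrm
        by <- by + off * (by - cy) / nrm
        pre[[length(pre) + 1L]] <-
          data.frame(x = bx, y = by, diameter_um = 0.25, soma_id = i)
        gth <- stats::runif(n_b, 0, 2 * pi)
        gr <- stats::runif(n_b, 0, 0.1)
        geph[[length(geph) + 1L]] <-
          data.frame(x = bx + gr * cos(gth), y = by + gr * sin(gth),
                     diameter_um = 0.25)
      }
    }
    # off-soma presynaptic distractors (rejection-sampled, > 1.5 um away)
    dpre <- matrix(numeric(0), ncol = 2)
    while (nrow(dpre) < n_distractor_presyn) {
      cand <- cbind(stats::runif(n_distractor_presyn, 0, field_um),
                    stats::runif(n_distractor_presyn, 0, field_um))
      d <- Reduce(pmin, lapply(somas, function(s)
        point_soma_distance(cand, s$vertices)))
      dpre <- rbind(dpre, cand[d > 1.5, , drop = FALSE])
    }
    dpre <- dpre[seq_len(n_distractor_presyn), , drop = FALSE]
    dgeph <- cbind(stats::runif(n_distractor_geph, 0, field_um),
                   stats::runif(n_distractor_geph, 0, field_um))
    pre_df <- rbind(
      do.call(rbind, pre)[, c("x", "y", "diameter_um")],
      data.frame(x = dpre[, 1], y = dpre[, 2], diameter_um = 0.25))
    geph_df <- rbind(do.call(rbind, geph),
                     data.frame(x = dgeph[, 1], y = dgeph[, 2],
                                diameter_um = 0.25))
    scene <- puncta_scene(somas,
                          list(presynaptic = pre_df, gephyrin = geph_df))
    attr(scene, "truth") <- list(bias = bias,
                                 rate_per_soma = puncta_rate_per_soma)
    scene
  })
}

#' Render a puncta table to a synthetic fluorescence image
#'
#' Gaussian spots of width `spot_sigma_um` plus white noise, for exercising
#' the blob detector against known centres.
#'
#' @param puncta data.frame with `x`, `y` (µm).
#' @param field_um square field side.
#' @param pixel_size_um default 0.04.
#' @param spot_sigma_um default 0.1.
#' @param amplitude peak spot intensity. Default 100.
#' @param snr peak amplitude over noise sd. Default 10.
#' @param seed integer seed (for the noise).
#' @return Image matrix (rows = y, cols = x).
#' @export
render_puncta_image <- function(puncta, field_um, pixel_size_um = 0.04,
                                spot_sigma_um = 0.1, amplitude = 100,
                                snr = 10, seed = 1L) {
  npx <- ceiling(field_um / pixel_size_um)
  img <- matrix(0, npx, npx)
  s_px <- spot_sigma_um / pixel_size_um
  half <- ceiling(4 * s_px)
  for (i in seq_len(nrow(puncta))) {
    r0 <- puncta$y[i] / pixel_size_um + 0.5
    c0 <- puncta$x[i] / pixel_size_um + 0.5
    rr <- max(1, round(r0) - half):min(npx, round(r0) + half)
    cc <- max(1, round(c0) - half):min(npx, round(c0) + half)
    img[rr, cc] <- img[rr, cc] + amplitude *
      exp(-outer((rr - r0)^2, (cc - c0)^2, `+`) / (2 * s_px^2))
  }
  img + with_seed(seed, matrix(stats::rnorm(npx * npx, 0, amplitude / snr),
                               npx, npx))
}

narrowband_oscillator <- function(n, fs, f0, half_bw = 2) {
  pad <- round(fs)  # 1 s settle
  w <- stats::rnorm(n + 2 * pad)
  bf <- signal::butter(2, c(f0 - half_bw, f0 + half_bw) / (fs / 2),
                       type = "pass")
  osc <- as.numeric(signal::filtfilt(bf, w))
  osc[(pad + 1):(pad + n)] / stats::sd(osc[(pad + 1):(pad + n)])
}

#' Generate a two-channel gamma-oscillation experiment
#'
#' A shared narrow-band oscillator (filtered noise peaked at `f0_Hz`) is
#' copied to both channels with the superficial channel delayed by
#' `lag_ms` (positive = the deep channel leads), plus independent white
#' channel noise at amplitude ratio `snr`. The post (drug) condition scales
#' the oscillator amplitude by `drug_power_factor` with freshly drawn
#' noise.
#'
#' @param f0_Hz oscillator centre frequency in the 18-50 Hz gamma band.
#'   Default 30.
#' @param lag_ms injected inter-channel lag (rounded to whole samples).
#'   Default 1.
#' @param amp oscillator sd (arbitrary voltage units). Default 50.
#' @param snr oscillator sd over channel-noise sd. Default 5.
#' @param drug_power_factor post-condition oscillator scale. Default 1.
#' @param duration_s record length. Default 10.
#' @param fs sampling rate, Hz. Default 10000.
#' @param seed integer seed.
#' @return List of class `lfp_experiment` with `pre` and `post`
#'   `lfp_recording` objects (`channel_deep`, `channel_superficial`,
#'   `sampling_rate`, `condition`) and a `truth` attribute.
#' @export
gen_lfp <- function(f0_Hz = 30, lag_ms = 1.0, amp = 50, snr = 5,
                    drug_power_factor = 1, duration_s = 10, fs = 10000,
                    seed = 1L) {
  n <- round(duration_s * fs)
  d <- round(lag_ms / 1000 * fs)
  # one ongoing oscillation shared by both conditions; the drug scales its
  # amplitude while the channel noise is drawn fresh per condition
  osc <- with_seed(derive_seed(seed, 1L),
                   narrowband_oscillator(n + abs(d), fs, f0_Hz) * amp)
  if (d >= 0) { deep <- osc[(abs(d) + 1):(abs(d) + n)]
                sup <- osc[1:n] }
  else        { deep <- osc[1:n]
                sup <- osc[(abs(d) + 1):(abs(d) + n)] }
  make_cond <- function(scale, condition, sub) {
    with_seed(derive_seed(seed, sub), {
      list(channel_deep = deep * scale + stats::rnorm(n, 0, amp / snr),
           channel_superficial = sup * scale +
             stats::rnorm(n, 0, amp / snr),
           sampling_rate = fs, condition = condition)
    })
  }
  out <- list(pre = make_cond(1, "CCh", 2L),
              post = make_cond(drug_power_factor, "CCh+WIN", 3L))
  attr(out, "truth") <- list(f0_Hz = f0_Hz,
                             lag_ms = d / fs * 1000,
                             drug_power_factor = drug_power_factor,
                             snr = snr)
  class(out) <- "lfp_experiment"
  out
}

#' Generate a positional census
#'
#' DAPI-identified somas are placed uniformly within each band's depth
#' interval; the marker is assigned by the stated per-band probability.
#'
#' @param n_per_band named counts `c(deep = , superficial = )`.
#' @param p_marker named per-band marker probabilities.
#' @param rois a [band_rois()]. Default: two 150 µm bands on the radial
#'   axis.
#' @param seed integer seed.
#' @return List: `cells` (data.frame with depth, `dapi`, `calbindin`),
#'   `rois`, `truth`.
#' @export
gen_census <- function(n_per_band = c(deep = 100L, superficial = 100L),
                       p_marker = c(deep = 0.089, superficial = 0.251),
                       rois = band_rois(c(0, 150), c(150, 300)),
                       seed = 1L) {
  with_seed(seed, {
    mk <- function(band) {
      iv <- rois[[band]]
      n <- n_per_band[[band]]
      depth <- stats::runif(n, iv[1], iv[2])
      data.frame(cell_id = paste0(band, seq_len(n)),
                 x_um = stats::runif(n, 0, 300),
                 dapi = TRUE,
                 calbindin = stats::runif(n) < p_marker[[band]],
                 depth = depth)
    }
    cells <- rbind(mk("deep"), mk("superficial"))
    names(cells)[names(cells) == "depth"] <- rois$depth_field
    list(cells = cells, rois = rois, truth = as.list(p_marker))
  })
}
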