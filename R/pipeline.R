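# Orchestration: run every stage on synthetic data with one master seed and
# emit a consolidated report mirroring the study's figure-level summaries.

#' Welch's t-test summary for two independent groups
#' @param x,y numeric vectors.
#' @return List: `mean_x`, `mean_y`, `sem_x`, `sem_y`, `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(mean_x = mean(x), mean_y = mean(y), sem_x = sem(x), sem_y = sem(y),
       t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Paired t-test summary for within-experiment pre/post comparisons
#' @param pre,post numeric vectors, paired by position.
#' @return List: `mean_pre`, `mean_post`, `mean_diff`, `t`, `df`, `p`.
#' @export
paired_t <- function(pre, post) {
  ht <- stats::t.test(post, pre, paired = TRUE)
  list(mean_pre = mean(pre), mean_post = mean(post),
       mean_diff = mean(post - pre), t = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value)
}

#' Pearson correlation summary
#' @param x,y numeric vectors.
#' @return List: `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' Write per-cell morphometric features as CSV
#' @param features data.frame from [morpho_feature_table()].
#' @param path output path.
#' @export
write_morpho_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Write Sholl profiles in long format as CSV
#' @param profiles named list of `sholl_profile` objects.
#' @param path output path.
#' @export
write_sholl_profiles <- function(profiles, path) {
  rows <- lapply(names(profiles), function(id) {
    data.frame(cell_id = id, radius_um = profiles[[id]]$radii,
               n_intersections = profiles[[id]]$intersections)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic study
#'
#' Generates synthetic inputs for every stage from one master seed, runs
#' each analysis, and returns a consolidated report: morphometric
#' classification and first-bifurcation distances, intrinsic-physiology
#' clustering and morphology-physiology concordance, wash-in
#' pharmacology with the inclusion rule, feedforward I/E ratios, puncta
#' innervation biases for a CCK-like (calbindin-preferring) and a PV-like
#' (calbindin-avoiding) condition, gamma spectra/cross-correlation, and a
#' positional census. Identical `seed` and configuration give an
#' identical report.
#'
#' @param seed master seed; all stage sub-streams derive from it.
#' @param out_dir optional directory for CSV/JSON artifacts.
#' @param n_trees_per_class morphology cohort size per archetype.
#'   Default 30.
#' @param n_phys_per_class physiology cohort size per class. Default 40.
#' @param n_scenes puncta scenes per condition. Default 5.
#' @param n_lfp gamma experiments. Default 5.
#' @param lfp_duration_s record length per experiment. Default 10.
#' @return Nested report list (see sections in the value).
#' @export
run_synthetic_study <- function(seed = 1L, out_dir = NULL,
                                n_trees_per_class = 30L,
                                n_phys_per_class = 40L,
                                n_scenes = 5L, n_lfp = 5L,
                                lfp_duration_s = 10) {
  report <- list(seed = seed)

  ## morphometry + clustering -------------------------------------------
  coh <- gen_tree_cohort(n_trees_per_class, n_trees_per_class,
                         seed = derive_seed(seed, 101L))
  truth <- attr(coh, "truth")
  feats <- morpho_feature_table(coh)
  km <- km_cluster(as.matrix(feats[, c("lri", "ori")]), 2,
                   seed = derive_seed(seed, 102L))
  pred <- ifelse(km$labels == 1L, "complex", "simple")
  cx <- truth == "complex"
  report$morphometry <- list(
    n_cells = nrow(feats),
    purity = mean(pred == truth),
    centers = km$centers,
    first_bif_um = welch_t(feats$first_bif_um[cx], feats$first_bif_um[!cx]),
    mean_lri_complex = mean(feats$lri[cx]),
    mean_lri_simple = mean(feats$lri[!cx]),
    mean_ori_complex = mean(feats$ori[cx]),
    mean_ori_simple = mean(feats$ori[!cx]))

  ## intrinsic physiology -------------------------------------------------
  phys <- gen_physiology(n_phys_per_class, seed = derive_seed(seed, 103L))
  scores <- zscore_pca(phys[, -(1:2)], n_components = 2L)
  kphys <- km_cluster(scores, 2, seed = derive_seed(seed, 104L))
  conc <- concordance(
    stats::setNames(phys$true_class, phys$cell_id),
    stats::setNames(kphys$labels, phys$cell_id))
  report$physiology <- list(
    n_cells = nrow(phys),
    pca_var_explained = attr(scores, "var_explained")[1:2],
    concordance_with_morphology = conc$agreement,
    contingency = unclass(conc$table),
    rmp_by_class = welch_t(phys$rmp_mV[phys$true_class == "complex"],
                           phys$rmp_mV[phys$true_class == "simple"]))

  ## wash-in pharmacology -------------------------------------------------
  washin_group <- function(factor, n, off) {
    vapply(seq_len(n), function(i) {
      washin_percent_of_baseline(
        gen_washin(drug_factor = factor,
                   seed = derive_seed(seed, off + i)))
    }, numeric(1))
  }
  wx <- washin_group(0.525, 8L, 200L)   # complex-like conotoxin response
  ws <- washin_group(0.756, 8L, 300L)   # simple-like
  report$washin <- list(
    complex = list(mean = mean(wx), sem = sem(wx), n = length(wx)),
    simple = list(mean = mean(ws), sem = sem(ws), n = length(ws)),
    welch = welch_t(wx, ws),
    n_excluded = sum(c(wx, ws) > 70))

  ## feedforward I/E ------------------------------------------------------
  ie <- with_seed(derive_seed(seed, 400L), {
    mk <- function(target, n) {
      vapply(seq_len(n), function(i) {
        epsc <- stats::rlnorm(1, log(100), 0.3)
        mono <- stats::rlnorm(1, log(60), 0.3)
        dis <- epsc * target * exp(stats::rnorm(1, 0, 0.25))
        ie_ratio(epsc, mono + dis, mono)$ie_ratio
      }, numeric(1))
    }
    list(complex = mk(3.15, 23L), simple = mk(5.70, 23L))
  })
  report$feedforward <- list(
    complex = list(mean = mean(ie$complex), sem = sem(ie$complex),
                   n = length(ie$complex)),
    simple = list(mean = mean(ie$simple), sem = sem(ie$simple),
                  n = length(ie$simple)),
    welch = welch_t(ie$complex, ie$simple))

  ## puncta innervation bias ---------------------------------------------
  bias_cond <- function(true_bias, off) {
    vapply(seq_len(n_scenes), function(i) {
      quantify_scene(gen_scene(bias = true_bias,
                               seed = derive_seed(seed, off + i)))$bias_ratio
    }, numeric(1))
  }
  cck <- bias_cond(1.32, 500L)
  pv <- bias_cond(0.74, 600L)
  report$puncta <- list(
    cck_like = list(true_bias = 1.32, mean = mean(cck), sem = sem(cck),
                    n = n_scenes),
    pv_like = list(true_bias = 0.74, mean = mean(pv), sem = sem(pv),
                   n = n_scenes))

  ## gamma oscillations ---------------------------------------------------
  lfp <- with_seed(derive_seed(seed, 700L), {
    f0s <- stats::runif(n_lfp, 20, 30)
    res <- lapply(seq_len(n_lfp), function(i) {
      ex <- gen_lfp(f0_Hz = f0s[i], lag_ms = 1.0, drug_power_factor = 0.93,
                    duration_s = lfp_duration_s,
                    seed = derive_seed(seed, 700L + i))
      pre <- analyze_lfp(ex$pre)
      post_sig <- lfp_preprocess(ex$post$channel_deep,
                                 ex$post$sampling_rate)
      post_spec <- power_spectrum(post_sig, ex$post$sampling_rate)
      list(peak_freq = pre$peak_freq_Hz,
           lag_ms = pre$xcorr$lag_at_max_ms,
           xcorr_max = pre$xcorr$max_value,
           norm_power = normalized_peak_power(pre$spectrum_deep, post_spec))
    })
    list(f0s = f0s, res = res)
  })
  pf <- vapply(lfp$res, `[[`, numeric(1), "peak_freq")
  lg <- vapply(lfp$res, `[[`, numeric(1), "lag_ms")
  np <- vapply(lfp$res, `[[`, numeric(1), "norm_power")
  report$lfp <- list(
    n = n_lfp,
    peak_freq_Hz = list(mean = mean(pf), sem = sem(pf),
                        true_mean = mean(lfp$f0s)),
    lag_ms = list(mean = mean(lg), sem = sem(lg), true = 1.0),
    norm_peak_power = list(mean = mean(np), sem = sem(np), true = 0.93),
    power_paired_t = if (n_lfp >= 2L) paired_t(rep(1, n_lfp), np) else
      list(mean_pre = 1, mean_post = mean(np), mean_diff = mean(np) - 1,
           t = NA_real_, df = NA_real_, p = NA_real_))

  ## census ---------------------------------------------------------------
  cen <- gen_census(seed = derive_seed(seed, 800L))
  bf <- band_marker_fraction(cen$cells, cen$rois)
  report$census <- list(
    fractions = bf,
    true_p = cen$truth,
    histogram = position_histogram(
      cen$cells$depth_radial_um[cen$cells$calbindin]))

  ## artifacts ------------------------------------------------------------
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_morpho_features(feats, file.path(out_dir, "morpho_features.csv"))
    write_report(report, file.path(out_dir, "report.json"))
  }
  report
}

#' Write a consolidated report as JSON
#'
#' Serialization is deterministic: the same report writes byte-identical
#' JSON.
#'
#' @param report list from [run_synthetic_study()].
#' @param path output path.
#' @export
write_report <- function(report, path) {
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, dataframe = "columns")
  writeLines(json, path)
  invisible(path)
}
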