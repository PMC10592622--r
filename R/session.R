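# Session-level orchestration and group comparison.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full single-session analysis
#'
#' Executes the whole chain on one recording session: smoothing, walking
#' bouts, strides and limb phase, whole-body motion bouts, and -- for each
#' supplied unit -- phase coding (jitter test), start/stop coding, speed
#' coding and, when a laser protocol is present, optogenetic tagging.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{pose}{A `pose_track`, or the path of a pose CSV (see
#'       [read_pose_csv()]); CSV input additionally needs `frame_rate`
#'       and `pixel_scale`.}
#'     \item{spikes}{Optional list of `spike_train` objects or spike-time
#'       CSV paths. Omitting it yields a kinematics-only report.}
#'     \item{genotype}{`"D1-Cre"`, `"A2a-Cre"` or `"none"` (default).}
#'     \item{group}{Free-form group label attached to the report.}
#'     \item{gait}{Named list of [gait_config()] overrides.}
#'     \item{overrides}{Bout accept/reject overrides
#'       ([find_walking_bouts()]).}
#'     \item{jitter_n_iter, speed_n_iter}{Null-iteration counts
#'       (default 100).}
#'     \item{outlier_cutoff}{Vector-length outlier cutoff (default 0.9).}
#'     \item{seed}{Integer seed for all randomized tests (default 1).}
#'     \item{out_dir}{Optional directory; when given, tables are written
#'       as CSV/JSON.}
#'   }
#' @return A list of class `session_report`: `config`, `strides` (a
#'   `stride_table`), `gait` (from [gait_summary()]), `motion_bouts`,
#'   `tuning` (unit x limb data frame), `units` (per-unit data frame),
#'   `venn`, `excluded_units`.
#' @export
run_session <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$pose)) stop("config must name a pose track ('pose')")
  track <- if (inherits(config$pose, "pose_track")) config$pose else
    read_pose_csv(config$pose, frame_rate = config$frame_rate %||% 80,
                  pixel_scale = config$pixel_scale %||% 0.3)
  gc <- do.call(gait_config, config$gait %||% list())
  seed <- as.integer(config$seed %||% 1L)

  sm <- smooth_track(track, gc$sg_window, gc$max_gap_frames)
  bouts <- find_walking_bouts(sm, gc, config$overrides)
  strides <- detect_strides(sm, bouts, gc)
  phase <- assign_phase(strides, sm)
  st <- stride_table(strides, phase, bouts, sm$frame_times, sm$frame_rate)
  gait <- gait_summary(st, sm)
  speed <- body_speed(sm)
  mbouts <- detect_motion_bouts(speed, track$frame_rate)

  spikes <- config$spikes
  if (!is.null(spikes) && !inherits(spikes, "list")) spikes <- list(spikes)
  tuning <- NULL
  units <- NULL
  venn <- NULL
  excluded <- character()
  if (length(spikes)) {
    spikes <- lapply(seq_along(spikes), function(i) {
      s <- spikes[[i]]
      if (inherits(s, "spike_train")) s else
        read_spike_csv(s, session_end = n_frames(track) / track$frame_rate)
    })
    res <- lapply(seq_along(spikes), function(i) {
      sp <- spikes[[i]]
      set.seed(seed + i)
      tun <- phase_coding_unit(sp, st,
                               n_iter = config$jitter_n_iter %||% 100)
      start <- start_stop_test(sp, mbouts, "start")
      stop_ <- start_stop_test(sp, mbouts, "stop")
      spd <- speed_coding(sp, speed, sm$frame_times, sm$frame_rate,
                          n_iter = config$speed_n_iter %||% 100)
      tag <- if (!is.null(sp$laser) && !is.null(sp$waveforms)) {
        classify_unit(sp, genotype = config$genotype %||% "none")
      } else NULL
      unit <- data.frame(
        unit_id = sp$unit_id,
        session_rate = session_firing_rate(sp),
        phase_coding = any(tun$significant),
        best_vector_length = max(tun$vector_length),
        start_p = start$p_value, start_significant = start$significant,
        start_modulation = start$modulation_index,
        stop_p = stop_$p_value, stop_significant = stop_$significant,
        stop_modulation = stop_$modulation_index,
        startstop_coding = start$significant || stop_$significant,
        speed_score = spd$score, speed_coding = isTRUE(spd$significant),
        coupling_class = limb_coupling_profile(tun)$class,
        tag_label = if (is.null(tag)) NA_character_ else tag$label,
        tagged = if (is.null(tag)) NA else tag$tagged
      )
      list(tuning = tun, unit = unit)
    })
    tuning <- do.call(rbind, lapply(res, `[[`, "tuning"))
    units <- do.call(rbind, lapply(res, `[[`, "unit"))
    ex <- exclude_outliers(tuning, config$outlier_cutoff %||% 0.9)
    excluded <- ex$excluded
    kept <- units[!units$unit_id %in% excluded, , drop = FALSE]
    venn <- coding_venn(kept)
  }

  report <- structure(
    list(config = config[setdiff(names(config), c("pose", "spikes"))],
         group = config$group %||% "default",
         genotype = config$genotype %||% "none",
         strides = st, gait = gait, motion_bouts = mbouts,
         tuning = tuning, units = units, venn = venn,
         excluded_units = excluded),
    class = "session_report"
  )
  if (!is.null(config$out_dir)) write_session_report(report, config$out_dir)
  report
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report> group=%s: %d strides, %d motion bouts, %s units\n",
              x$group, nrow(x$strides$strides), nrow(x$motion_bouts),
              if (is.null(x$units)) "no" else nrow(x$units)))
  invisible(x)
}

#' Compare two groups of units and sessions
#'
#' Group-level statistics in the factor layout used for cell-type and
#' lesion contrasts: vector length compared by two-way ANOVA (group x
#' limb, reported both pooled and with a per-unit error stratum, since
#' limbs are repeated measures within unit); vector angles compared per
#' limb by the angular permutation test with Bonferroni correction over
#' the four limbs; start modulation index and speed score by two-sample
#' t-tests; and any per-session gait metrics by t-tests.
#'
#' @param reports List of `session_report` objects (their `group` fields
#'   must form exactly two groups), or a list with elements `tuning` and
#'   `units` already pooled (each with a `group` column).
#' @param n_perm Permutation iterations for the angular tests (default
#'   1000).
#' @param alpha Significance level (default 0.05).
#' @param outlier_cutoff Vector-length outlier cutoff applied before
#'   comparison (default 0.9).
#' @return A list of class `group_report` with components
#'   `vector_length` (ANOVA tables and group means +/- SEM),
#'   `vector_angle` (per-limb permutation tests), `start_modulation`,
#'   `speed_score`, `gait` (optional), `groups`, `n_units`.
#' @export
compare_groups <- function(reports, n_perm = 1000, alpha = 0.05,
                           outlier_cutoff = 0.9) {
  if (!is.null(reports$tuning)) {
    tuning <- reports$tuning
    units <- reports$units
    gaitdf <- reports$gait
  } else {
    tuning <- do.call(rbind, lapply(reports, function(r) {
      if (is.null(r$tuning)) return(NULL)
      cbind(r$tuning, group = r$group)
    }))
    units <- do.call(rbind, lapply(reports, function(r) {
      if (is.null(r$units)) return(NULL)
      cbind(r$units, group = r$group)
    }))
    gaitdf <- do.call(rbind, lapply(reports, function(r) {
      tl <- r$gait$totals
      data.frame(group = r$group,
                 mean_body_speed = tl$mean_body_speed,
                 total_distance_mm = tl$total_distance_mm,
                 initiation_rate_per_min = tl$initiation_rate_per_min,
                 mean_stride_length = mean(r$gait$per_limb$length_mean),
                 mean_stride_duration = mean(r$gait$per_limb$duration_mean),
                 mean_swing_stance_ratio =
                   mean(r$gait$per_limb$swing_stance_ratio_mean))
    }))
  }
  if (is.null(tuning) || !nrow(tuning)) stop("no unit tuning data to compare")
  groups <- unique(tuning$group)
  if (length(groups) != 2) stop("exactly two groups are required")
  if (any(table(tuning$group) == 0)) stop("empty group")

  ex <- exclude_outliers(tuning, outlier_cutoff)
  tuning <- ex$kept
  if (!is.null(units)) {
    units <- units[!units$unit_id %in% ex$excluded, , drop = FALSE]
  }

  tuning$group <- factor(tuning$group, levels = groups)
  tuning$limb <- factor(tuning$limb, levels = gait_limbs())
  fit <- stats::aov(vector_length ~ group * limb, data = tuning)
  tab <- summary(fit)[[1]]
  rownames(tab) <- trimws(rownames(tab))
  fit_rm <- stats::aov(vector_length ~ group * limb +
                         Error(factor(unit_id)), data = tuning)
  rm_tab <- summary(fit_rm)
  # between-unit stratum: the group effect tested against unit-to-unit
  # variation (limbs are repeated measures within unit, so the pooled
  # table above is anticonservative for the group factor)
  unit_stratum <- rm_tab[[grep("unit_id", names(rm_tab))]][[1]]
  rownames(unit_stratum) <- trimws(rownames(unit_stratum))
  grp_stats <- do.call(rbind, lapply(groups, function(g) {
    v <- tuning$vector_length[tuning$group == g]
    data.frame(group = g, mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)), n = length(v))
  }))
  vl <- list(anova_table = tab,
             group_p = tab["group", "Pr(>F)"],
             group_F = tab["group", "F value"],
             group_p_units = unit_stratum["group", "Pr(>F)"],
             repeated_measures = rm_tab,
             group_means = grp_stats)

  va <- do.call(rbind, lapply(gait_limbs(), function(l) {
    a <- tuning$vector_angle[tuning$limb == l & tuning$group == groups[1]]
    b <- tuning$vector_angle[tuning$limb == l & tuning$group == groups[2]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (!length(a) || !length(b)) {
      return(data.frame(limb = l, distance = NA_real_, p = NA_real_,
                        significant = NA))
    }
    pt <- angular_permutation_test(a, b, n_iter = n_perm, alpha = alpha,
                                   n_comparisons = 4)
    data.frame(limb = l, distance = pt$distance, p = pt$p,
               significant = pt$significant)
  }))

  two_sample <- function(col) {
    if (is.null(units) || !col %in% names(units)) return(NULL)
    x <- units[units$group == groups[1], col]
    y <- units[units$group == groups[2], col]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) return(NULL)
    tt <- stats::t.test(x, y)
    list(mean = stats::setNames(c(mean(x), mean(y)), groups),
         p = tt$p.value, significant = tt$p.value < alpha)
  }
  gait_cmp <- NULL
  if (!is.null(gaitdf) && nrow(gaitdf) >= 4) {
    metrics <- setdiff(names(gaitdf), "group")
    gait_cmp <- lapply(metrics, function(m) {
      x <- gaitdf[gaitdf$group == groups[1], m]
      y <- gaitdf[gaitdf$group == groups[2], m]
      if (length(x) < 2 || length(y) < 2) return(NULL)
      tt <- stats::t.test(x, y)
      list(metric = m, mean = stats::setNames(c(mean(x), mean(y)), groups),
           p = tt$p.value)
    })
    names(gait_cmp) <- metrics
  }

  structure(
    list(groups = as.character(groups),
         n_units = table(unique(tuning[c("unit_id", "group")])$group),
         vector_length = vl, vector_angle = va,
         start_modulation = two_sample("start_modulation"),
         speed_score = two_sample("speed_score"),
         gait = gait_cmp,
         excluded_units = ex$excluded),
    class = "group_report"
  )
}

#' @export
print.group_report <- function(x, ...) {
  cat(sprintf("<group_report> %s vs %s\n", x$groups[1], x$groups[2]))
  cat(sprintf("  vector length: group F=%.2f p=%.3g\n",
              x$vector_length$group_F, x$vector_length$group_p))
  sig <- x$vector_angle$significant
  cat(sprintf("  vector angle: %d/%d limbs significant (Bonferroni x4)\n",
              sum(sig, na.rm = TRUE), length(sig)))
  invisible(x)
}
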