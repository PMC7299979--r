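#' Detect events for every recording of a cohort
#'
#' @param recordings list of `gaze_recording`.
#' @param ... passed to [detect_events()].
#' @return named list (`participant/stimulus`) with `trace`, `events`,
#'   `participant`, `group`, `stimulus`.
#' @export
preprocess_cohort <- function(recordings, ...) {
  out <- lapply(recordings, function(r) {
    trace <- recording_to_trace(r)
    list(participant = r$participant, group = r$group, stimulus = r$stimulus,
         trace = trace, events = detect_events(trace, ...))
  })
  names(out) <- vapply(out, function(e)
    paste0(e$participant, "/", e$stimulus), "")
  out
}

combined_image_saccades <- function(entries) {
  do.call(rbind, lapply(entries, function(e) e$events$saccades))
}

#' Per-participant biomarker table for a cohort
#'
#' Computes the four biomarkers per participant per stimulus: median saccade
#' amplitude, 95% BCEA of aligned endpoints, SLV against the moderate and/or
#' advanced scotoma mask (controls carry both columns, impaired groups the
#' one matching their own condition), and for videos the mean per-frame KDE
#' probability score. The three images are concatenated into a single
#' `"images"` stream before summarising, mirroring the study's reporting.
#'
#' @param recordings cohort from [generate_cohort()] (or read back), with the
#'   `config` attribute, or pass `config`.
#' @param config `cohort_config`; defaults to the cohort attribute.
#' @param masks list with `moderate`, `advanced` `scotoma_mask`s; defaults to
#'   the cohort attribute (regenerated if absent).
#' @param h,contamination,n_trees,kde_seed KDE scoring parameters.
#' @param ... passed to [detect_events()].
#' @return list: `biomarkers` (data.frame, one row per participant x
#'   stimulus), `kde_traces` (list of `kde_trace_set` per video), `events`
#'   (the [preprocess_cohort()] output).
#' @export
build_biomarkers <- function(recordings, config = attr(recordings, "config"),
                             masks = attr(recordings, "masks"), h = 1.5,
                             contamination = 0.05, n_trees = 100,
                             kde_seed = 1, ...) {
  if (is.null(config)) stop("cohort config required")
  if (is.null(masks))
    masks <- list(moderate = scotoma_mask(synthetic_perimetry("moderate")$ivf),
                  advanced = scotoma_mask(synthetic_perimetry("advanced")$ivf))
  prep <- preprocess_cohort(recordings, ...)
  meta <- unique(data.frame(
    participant = vapply(prep, `[[`, "", "participant"),
    group = vapply(prep, `[[`, "", "group")))
  rownames(meta) <- meta$participant
  stim_kind <- vapply(config$stimuli, `[[`, "", "kind")
  stim_ids <- vapply(config$stimuli, `[[`, "", "id")
  videos <- stim_ids[stim_kind == "video"]
  images <- stim_ids[stim_kind == "image"]

  slv_cols <- function(events_or_sac, group) {
    s_mod <- s_adv <- NA_real_
    ev <- if (inherits(events_or_sac, "event_sequence")) events_or_sac
          else list(saccades = events_or_sac)
    class(ev) <- "event_sequence"
    if (group %in% c("none", "moderate")) s_mod <- slv(ev, masks$moderate)
    if (group %in% c("none", "advanced")) s_adv <- slv(ev, masks$advanced)
    c(s_mod, s_adv)
  }

  rows <- list()
  for (p in meta$participant) {
    grp <- meta[p, "group"]
    for (v in videos) {
      ev <- prep[[paste0(p, "/", v)]]$events
      sv <- slv_cols(ev, grp)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, group = grp, stimulus = v,
        median_amp_deg = median_amplitude(ev),
        bcea95_deg2 = as.numeric(bcea95(aligned_endpoints(ev))),
        slv_mod = sv[1], slv_adv = sv[2], kde_mean = NA_real_,
        n_saccades = nrow(ev$saccades))
    }
    if (length(images)) {
      entries <- prep[paste0(p, "/", images)]
      sac <- combined_image_saccades(entries)
      sv <- slv_cols(sac, grp)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, group = grp, stimulus = "images",
        median_amp_deg = median_amplitude(sac$amplitude),
        bcea95_deg2 = as.numeric(bcea95(aligned_endpoints(sac))),
        slv_mod = sv[1], slv_adv = sv[2], kde_mean = NA_real_,
        n_saccades = nrow(sac))
    }
  }
  bio <- do.call(rbind, rows)

  kde_traces <- list()
  for (v in videos) {
    dur <- config$stimuli[[which(stim_ids == v)]]$duration
    fp <- lapply(meta$participant, function(p) {
      e <- prep[[paste0(p, "/", v)]]
      frame_gaze(e$trace, e$events, frame_rate = 30, duration = dur)
    })
    kt <- kde_scores(fp, meta$group, h = h, contamination = contamination,
                     n_trees = n_trees, seed = kde_seed)
    kde_traces[[v]] <- kt
    bio$kde_mean[bio$stimulus == v] <-
      kt$mean_score[match(bio$participant[bio$stimulus == v],
                          meta$participant)]
  }
  list(biomarkers = bio, kde_traces = kde_traces, events = prep)
}

feature_value <- function(bio, feature) {
  # SLV: each impaired participant carries the value for their own mask;
  # controls contribute the column matching the comparison, and the
  # moderate-mask column in the omnibus test
  switch(feature,
    median_amp = bio$median_amp_deg,
    bcea = bio$bcea95_deg2,
    kde = bio$kde_mean,
    slv = ifelse(bio$group == "advanced", bio$slv_adv, bio$slv_mod))
}

#' Nonparametric group statistics for every biomarker x stimulus
#'
#' Kruskal-Wallis across the three groups, then pairwise Mann-Whitney tests
#' (Bonferroni corrected for three comparisons) with rank eta-squared. For
#' SLV the none-vs-advanced pair compares the advanced-mask columns and the
#' other pairs the moderate-mask columns, matching how controls carry two
#' SLV values.
#'
#' @param biomarkers data.frame from [build_biomarkers()].
#' @return data.frame, one row per feature x stimulus x (omnibus | pair).
#' @export
group_stats <- function(biomarkers) {
  rows <- list()
  for (stim in unique(biomarkers$stimulus)) {
    bio <- biomarkers[biomarkers$stimulus == stim, ]
    for (feat in c("median_amp", "bcea", "slv", "kde")) {
      vals <- feature_value(bio, feat)
      if (all(!is.finite(vals))) next
      kw <- tryCatch(kruskal_wallis(vals, bio$group), error = function(e) NULL)
      if (!is.null(kw))
        rows[[length(rows) + 1L]] <- data.frame(
          feature = feat, stimulus = stim, comparison = "omnibus",
          statistic = kw$chi2, p = kw$p, eta2 = NA_real_)
      for (pr in list(c("none", "moderate"), c("none", "advanced"),
                      c("moderate", "advanced"))) {
        sel <- bio$group %in% pr
        v <- if (feat == "slv" && identical(pr, c("none", "advanced")))
          bio$slv_adv[sel] else feature_value(bio[sel, ], feat)
        g <- bio$group[sel]
        if (sum(is.finite(v[g == pr[1]])) < 2 ||
            sum(is.finite(v[g == pr[2]])) < 2) next
        mw <- mann_whitney(v[g == pr[1]], v[g == pr[2]], bonferroni = 3)
        rows[[length(rows) + 1L]] <- data.frame(
          feature = feat, stimulus = stim,
          comparison = paste(pr, collapse = "-"),
          statistic = mw$U, p = mw$p_adj, eta2 = mw$eta2)
      }
    }
  }
  do.call(rbind, rows)
}

#' ROC diagnostic accuracy per biomarker and group pair
#'
#' Lower values mark impairment for amplitude, BCEA and KDE; higher values
#' for SLV.
#'
#' @param biomarkers data.frame from [build_biomarkers()].
#' @return data.frame `feature`, `stimulus`, `pair`, `auc`,
#'   `sens_at_spec90`; attribute `rocs` holds the `roc_result` objects.
#' @export
roc_table <- function(biomarkers) {
  dirs <- c(median_amp = "lower", bcea = "lower", kde = "lower",
            slv = "higher")
  rows <- list(); rocs <- list()
  for (stim in unique(biomarkers$stimulus)) {
    bio <- biomarkers[biomarkers$stimulus == stim, ]
    for (feat in names(dirs)) {
      for (pos in c("moderate", "advanced")) {
        v_neg <- if (feat == "slv")
          (if (pos == "advanced") bio$slv_adv else bio$slv_mod)[bio$group == "none"]
        else feature_value(bio[bio$group == "none", ], feat)
        v_pos <- feature_value(bio[bio$group == pos, ], feat)
        if (sum(is.finite(v_neg)) == 0 || sum(is.finite(v_pos)) == 0) next
        r <- roc(v_neg, v_pos, dirs[[feat]])
        key <- paste(feat, stim, pos, sep = "/")
        rocs[[key]] <- r
        rows[[length(rows) + 1L]] <- data.frame(
          feature = feat, stimulus = stim, pair = paste0("none-", pos),
          auc = r$auc, sens_at_spec90 = r$sens_at_spec90)
      }
    }
  }
  structure(do.call(rbind, rows), rocs = rocs)
}

#' Multi-feature classifier vectors per stimulus
#'
#' Serialises, per participant, the 84 saccade-map features plus median
#' amplitude, BCEA and (videos only) the mean KDE score: 87 features per
#' video, 86 per image stream.
#'
#' @param bundle output of [build_biomarkers()].
#' @param map_fun feature-bank function (default: Gaussian-smoothed
#'   [saccade_map_features()] with `smooth_sd = 1`); must return a
#'   fixed-length named vector given a saccade data.frame.
#' @return list per stimulus: `X` (matrix), `participants`, `groups`.
#' @export
build_feature_table <- function(bundle,
                                map_fun = function(ep)
                                  saccade_map_features(ep, smooth_sd = 1)) {
  bio <- bundle$biomarkers
  out <- list()
  for (stim in unique(bio$stimulus)) {
    b <- bio[bio$stimulus == stim, ]
    rowsX <- lapply(seq_len(nrow(b)), function(i) {
      p <- b$participant[i]
      sac <- if (stim == "images") {
        img <- grep(paste0("^", p, "/image"), names(bundle$events), value = TRUE)
        combined_image_saccades(bundle$events[img])
      } else bundle$events[[paste0(p, "/", stim)]]$events$saccades
      mf <- map_fun(aligned_endpoints(sac))
      extra <- c(median_amp = b$median_amp_deg[i], bcea = b$bcea95_deg2[i])
      if (stim != "images") extra <- c(extra, kde_mean = b$kde_mean[i])
      c(mf, extra)
    })
    X <- do.call(rbind, rowsX)
    X[!is.finite(X)] <- 0
    rownames(X) <- b$participant
    out[[stim]] <- list(X = X, participants = b$participant,
                        groups = b$group)
  }
  out
}

#' Run the full analysis pipeline
#'
#' generate -> preprocess -> biomarkers -> group statistics -> ROC ->
#' (optionally) windowed KDE AUC and the KPCA + AdaBoost leave-one-out
#' classifier. Deterministic given the config seed. When `out_dir` is given,
#' writes `biomarkers.csv`, `stats.csv`, `roc.csv`, `summary.csv`,
#' `loo_scores.csv` (if classifier run) and `run_config.json`.
#'
#' @param config `cohort_config`.
#' @param out_dir optional output directory.
#' @param classify run the LOO classifier (slowest stage).
#' @param hyper_grid classifier grid (see [default_hyper_grid()]).
#' @param classify_stimuli stimuli to classify (default all).
#' @param windows optional named list of window data.frames (per video) for
#'   windowed KDE AUC.
#' @param rounds boosting rounds.
#' @param B_ci bootstrap replicates for group-median CIs (0 skips).
#' @param ... passed to [build_biomarkers()] (detector and KDE parameters).
#' @return list with `biomarkers`, `stats`, `roc`, `summary`, `kde_traces`,
#'   `windowed`, `loo`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL, classify = FALSE,
                         hyper_grid = default_hyper_grid(),
                         classify_stimuli = NULL, windows = NULL,
                         rounds = 50, B_ci = 0, ...) {
  stopifnot(inherits(config, "cohort_config"))
  recordings <- generate_cohort(config)
  bundle <- build_biomarkers(recordings, kde_seed = config$seed, ...)
  bio <- bundle$biomarkers
  stats_tab <- group_stats(bio)
  roc_tab <- roc_table(bio)

  summ <- list()
  for (stim in unique(bio$stimulus)) for (grp in unique(bio$group))
    for (feat in c("median_amp", "bcea", "slv", "kde")) {
      v <- feature_value(bio[bio$stimulus == stim & bio$group == grp, ], feat)
      v <- v[is.finite(v)]
      if (!length(v)) next
      ci <- if (B_ci >= 100 && length(v) >= 3)
        bootstrap_ci(stats::median, v, B = B_ci, seed = config$seed)
      else c(NA_real_, NA_real_)
      summ[[length(summ) + 1L]] <- data.frame(
        stimulus = stim, group = grp, feature = feat, n = length(v),
        median = stats::median(v), ci_lo = ci[1], ci_hi = ci[2])
    }
  summ <- do.call(rbind, summ)

  windowed <- NULL
  if (!is.null(windows)) {
    windowed <- lapply(names(windows), function(v) {
      list(video = v,
           full = windowed_auc(bundle$kde_traces[[v]], NULL),
           windowed = windowed_auc(bundle$kde_traces[[v]], windows[[v]]))
    })
    names(windowed) <- names(windows)
  }

  loo <- NULL
  if (classify) {
    feats <- build_feature_table(bundle)
    if (is.null(classify_stimuli)) classify_stimuli <- names(feats)
    loo <- list()
    for (stim in classify_stimuli)
      for (pos in c("moderate", "advanced")) {
        ft <- feats[[stim]]
        sel <- ft$groups %in% c("none", pos)
        if (min(table(ft$groups[sel])) < 3) next
        loo[[paste(stim, pos, sep = "/")]] <-
          adaboost_loo(ft$X[sel, , drop = FALSE], ft$groups[sel],
                       hyper_grid = hyper_grid, seed = config$seed,
                       rounds = rounds, positive = pos)
      }
  }

  res <- list(biomarkers = bio, stats = stats_tab, roc = roc_tab,
              summary = summ, kde_traces = bundle$kde_traces,
              windowed = windowed, loo = loo, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(bio, file.path(out_dir, "biomarkers.csv"),
                     row.names = FALSE)
    utils::write.csv(stats_tab, file.path(out_dir, "stats.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(roc_tab), file.path(out_dir, "roc.csv"),
                     row.names = FALSE)
    utils::write.csv(summ, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    if (!is.null(loo)) {
      ls <- do.call(rbind, lapply(names(loo), function(k)
        data.frame(task = k, participant = seq_along(loo[[k]]$scores),
                   label = loo[[k]]$labels, score = loo[[k]]$scores)))
      utils::write.csv(ls, file.path(out_dir, "loo_scores.csv"),
                       row.names = FALSE)
    }
    cfg <- list(seed = config$seed,
                n = c(config$n_control, config$n_moderate, config$n_advanced),
                stimuli = lapply(config$stimuli, unclass),
                effect = unclass(config$effect),
                sample_rate = config$sample_rate,
                scotoma_cutoff = config$scotoma_cutoff)
    jsonlite::write_json(cfg, file.path(out_dir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  res
}
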