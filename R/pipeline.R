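#' Pipeline configuration
#'
#' Bundles the input paths and analysis options for [run_pipeline()].
#' Options mirror the individual stage functions: dominance-index variant
#' and zero-dyad convention, the Mauchly alpha that triggers the
#' Greenhouse-Geisser correction, and per-behavior appearance thresholds
#' (integer or `"auto"`).
#'
#' @param events_path Event-log CSV path.
#' @param physio_path Physiology CSV path (`NULL` to skip physiological
#'   analyses).
#' @param out_dir Output directory for the emitted tables.
#' @param ds_variant `"chance_corrected"` or `"raw"`.
#' @param zero_dyad `"zero"` or `"half"`.
#' @param gg_alpha Sphericity alpha for the GG trigger.
#' @param appearance_thresholds Named list per behavior, each an integer or
#'   `"auto"`.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic; the seed matters for `simulate`-style uses).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(events_path, physio_path = NULL,
                            out_dir = "stressrank-out",
                            ds_variant = c("chance_corrected", "raw"),
                            zero_dyad = c("zero", "half"),
                            gg_alpha = 0.05,
                            appearance_thresholds = list(AGG = "auto",
                                                         GRO = "auto"),
                            seed = NULL) {
  structure(list(events_path = events_path, physio_path = physio_path,
                 out_dir = out_dir, ds_variant = match.arg(ds_variant),
                 zero_dyad = match.arg(zero_dyad), gg_alpha = gg_alpha,
                 appearance_thresholds = appearance_thresholds, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Field names match the arguments of [pipeline_config()].
#'
#' @param path YAML (or JSON) configuration file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown pipeline config field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

## per subject x observation totals of initiated / received behavior
subject_behavior_totals <- function(events, behavior) {
  out <- list()
  for (g in unique(events$group_id)) {
    ev_g <- events[events$group_id == g, , drop = FALSE]
    roster <- event_roster(ev_g, g)
    for (obs in OBSERVATION_LEVELS) {
      M <- aggregate_interactions(ev_g, behavior, obs, roster)
      out[[paste(g, obs)]] <- data.frame(
        group_id = g, subject_id = roster, observation_id = obs,
        initiated = as.vector(rowSums(M)), received = as.vector(colSums(M)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

wide_by_timepoint <- function(df, id = "subject_id", time = "timepoint",
                              value = "value") {
  stats::reshape(df[, c(id, time, value)], direction = "wide",
                 idvar = id, timevar = time)
}

#' Run the full colony stress analysis
#'
#' Orchestrates every stage end to end: reads and validates the event log
#' (and physiology panel, if given), computes the per-observation dominance
#' tables, classifies subjects HR/LR on their baseline (Observation 1)
#' ranks, runs the split-plot ANOVAs (time x rank class on individual
#' behavior and physiology; time x dyad type and time x appearance stratum
#' on dyad frequencies), the Holm-adjusted time post hocs, the
#' rank-collapsed rank-vs-change correlations, the partial correlation of
#' initiated vs received grooming change controlling oxytocin change, and
#' the dyad-level baseline-vs-change correlations. All results are written
#' as TSVs plus a machine-readable JSON manifest; the same config and
#' inputs always yield byte-identical outputs.
#'
#' @param config A `pipeline_config` (or a path to one readable by
#'   [read_pipeline_config()]).
#' @return Invisibly, a named list with the paths of `ds_table`,
#'   `anova_table`, `posthoc`, `correlations`, `dyad_summary`,
#'   `manifest` and `log`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  events <- stage("read_events", {
    ev <- read_event_log(config$events_path)
    if (nrow(ev) == 0) stop("empty event log", call. = FALSE)
    ev
  })
  note("read_events: ", nrow(events), " rows, ",
       length(unique(events$group_id)), " group(s)")

  panel <- NULL
  if (!is.null(config$physio_path)) {
    panel <- stage("read_physiology", read_physio_panel(config$physio_path))
    note("read_physiology: ", nrow(panel), " rows")
  }

  ds <- stage("rank", ds_table(events, config$ds_variant, config$zero_dyad))
  ds_path <- write_tsv(ds, file.path(config$out_dir, "ds_table.tsv"))
  note("rank: ", nrow(ds), " subject-observation scores")

  ## baseline (Observation 1) classes drive all downstream stratifications
  base <- ds[ds$observation_id == "OBS1", , drop = FALSE]
  classes <- data.frame(group_id = base$group_id, subject = base$subject_id,
                        class = base$class, stringsAsFactors = FALSE)
  n_boundary <- sum(classes$class == "BOUNDARY")
  if (n_boundary > 0) {
    note("rank: WARNING ", n_boundary, " BOUNDARY subject(s) excluded ",
         "from HR/LR contrasts")
  }

  dyads <- stage("dyads", suppressWarnings(
    dyad_summary(events, classes,
                 thresholds = config$appearance_thresholds)))
  dyad_path <- write_tsv(dyads, file.path(config$out_dir, "dyad_summary.tsv"))
  note("dyads: ", nrow(dyads), " dyad-behavior rows; undefined deltas: ",
       sum(is.na(dyads$delta_3avs1)))

  ## ----- split-plot ANOVAs + post hocs ---------------------------------
  anova_rows <- list(); posthoc_rows <- list()
  keep_cls <- classes[classes$class %in% c("HR", "LR"), , drop = FALSE]
  run_aov <- function(analysis, dat, between) {
    res <- tryCatch(
      suppressWarnings(mixed_anova(dat, value = "value", unit = "unit",
                                   within = "within", between = between,
                                   gg_alpha = config$gg_alpha)),
      error = function(e) NULL)
    if (is.null(res)) {
      note("anova: skipped ", analysis, " (design not estimable)")
      return()
    }
    df <- as.data.frame(res)
    df <- cbind(analysis = analysis, df,
                epsilon = attr(res, "epsilon"),
                mauchly_p = attr(res, "mauchly_p"),
                gg_applied = attr(res, "gg_applied"))
    anova_rows[[length(anova_rows) + 1L]] <<- df
    ph <- tryCatch(suppressWarnings(
      posthoc_time_contrasts(dat, value = "value", unit = "unit",
                             within = "within")),
      error = function(e) NULL)
    if (!is.null(ph)) {
      posthoc_rows[[length(posthoc_rows) + 1L]] <<-
        cbind(analysis = analysis, ph)
    }
  }

  stage("anova_behavior", {
    for (beh in BEHAVIOR_LEVELS) {
      tot <- subject_behavior_totals(events, beh)
      tot <- merge(tot, keep_cls,
                   by.x = c("group_id", "subject_id"),
                   by.y = c("group_id", "subject"))
      for (role in c("initiated", "received")) {
        dat <- data.frame(unit = tot$subject_id, within = tot$observation_id,
                          between = tot$class, value = tot[[role]])
        run_aov(paste0(beh, "_", role, "_by_class"), dat, "between")
      }
    }
  })

  if (!is.null(panel)) {
    stage("anova_physiology", {
      for (an in unique(panel$analyte)) {
        pa <- panel[panel$analyte == an, , drop = FALSE]
        pa <- merge(pa, keep_cls,
                    by.x = c("group_id", "subject_id"),
                    by.y = c("group_id", "subject"))
        dat <- data.frame(unit = pa$subject_id, within = pa$timepoint,
                          between = pa$class, value = pa$value)
        run_aov(paste0(an, "_by_class"), dat, "between")
      }
    })
  }

  stage("anova_dyads", {
    for (beh in BEHAVIOR_LEVELS) {
      db <- dyads[dyads$behavior == beh, , drop = FALSE]
      long <- data.frame(
        unit = rep(paste(db$group_id, db$initiator, db$receiver, sep = ":"),
                   3),
        within = rep(OBSERVATION_LEVELS, each = nrow(db)),
        dtype = rep(db$dtype, 3),
        appearance = rep(db$appearance, 3),
        value = c(db$freq_obs1, db$freq_obs3a, db$freq_obs3b))
      run_aov(paste0(beh, "_dyads_by_type"),
              data.frame(long, between = long$dtype), "between")
      if (beh %in% c("AGG", "GRO")) {
        run_aov(paste0(beh, "_dyads_by_appearance"),
                data.frame(long, between = long$appearance), "between")
      }
    }
  })

  anova_tab <- do.call(rbind, anova_rows)
  anova_path <- write_tsv(anova_tab,
                          file.path(config$out_dir, "anova_table.tsv"))
  note("anova: ", length(anova_rows), " analyses")
  posthoc_tab <- do.call(rbind, posthoc_rows)
  posthoc_path <- write_tsv(posthoc_tab,
                            file.path(config$out_dir, "posthoc.tsv"))
  note("posthoc: ", nrow(posthoc_tab), " contrasts")

  ## ----- correlations ---------------------------------------------------
  cor_rows <- list()
  add_cor <- function(x_name, y_name, res, control = "") {
    cor_rows[[length(cor_rows) + 1L]] <<- data.frame(
      variable_x = x_name, variable_y = y_name, control = control,
      method = res$method, r = res$r, p = res$p, n = res$n,
      stringsAsFactors = FALSE)
  }
  stage("correlate", {
    ## social rank: within-group rank of baseline normDS, larger = higher
    base_rank <- stats::ave(base$normDS, base$group_id, FUN = rank)
    rank_df <- data.frame(group_id = base$group_id,
                          subject_id = base$subject_id,
                          social_rank = base_rank, stringsAsFactors = FALSE)
    if (!is.null(panel)) {
      for (an in intersect(c("HC", "OT", "AVP", "WEIGHT"),
                           unique(panel$analyte))) {
        wide <- wide_by_timepoint(panel[panel$analyte == an, ])
        m <- merge(rank_df, wide, by = "subject_id")
        for (cmp in list(c("S2", "S1"), c("S3", "S2"), c("S3", "S1"))) {
          delta <- suppressWarnings(change_score(
            m[[paste0("value.", cmp[1])]], m[[paste0("value.", cmp[2])]],
            na_undefined = TRUE))
          res <- tryCatch(
            rank_collapse_correlation(m$social_rank, delta, m$group_id),
            error = function(e) NULL)
          if (!is.null(res)) {
            add_cor("social_rank",
                    paste0("delta_", an, "_", cmp[1], "vs", cmp[2]), res)
          }
        }
      }
    }
    ## rank vs change in initiated / received behavior
    for (beh in BEHAVIOR_LEVELS) {
      tot <- subject_behavior_totals(events, beh)
      w <- stats::reshape(tot, direction = "wide",
                          idvar = c("group_id", "subject_id"),
                          timevar = "observation_id")
      m <- merge(rank_df, w, by = c("group_id", "subject_id"))
      for (role in c("initiated", "received")) {
        delta <- suppressWarnings(change_score(
          m[[paste0(role, ".OBS3A")]], m[[paste0(role, ".OBS1")]],
          na_undefined = TRUE))
        res <- tryCatch(
          rank_collapse_correlation(m$social_rank, delta, m$group_id),
          error = function(e) NULL)
        if (!is.null(res)) {
          add_cor("social_rank", paste0("delta_", role, "_", beh, "_3Avs1"),
                  res)
        }
      }
    }
    ## initiated vs received grooming change, controlling OT change
    if (!is.null(panel) && "OT" %in% panel$analyte) {
      tot <- subject_behavior_totals(events, "GRO")
      w <- stats::reshape(tot, direction = "wide",
                          idvar = c("group_id", "subject_id"),
                          timevar = "observation_id")
      ot <- wide_by_timepoint(panel[panel$analyte == "OT", ])
      m <- merge(w, ot, by = "subject_id")
      d_i <- suppressWarnings(change_score(m$initiated.OBS3B,
                                           m$initiated.OBS3A,
                                           na_undefined = TRUE))
      d_r <- suppressWarnings(change_score(m$received.OBS3B,
                                           m$received.OBS3A,
                                           na_undefined = TRUE))
      d_ot <- suppressWarnings(change_score(m$value.S3, m$value.S2,
                                            na_undefined = TRUE))
      res <- tryCatch(pearson_correlation(d_i, d_r),
                      error = function(e) NULL)
      if (!is.null(res)) {
        add_cor("delta_initiated_GRO_3Bvs3A", "delta_received_GRO_3Bvs3A",
                res)
      }
      res <- tryCatch(partial_correlation(d_i, d_r, d_ot),
                      error = function(e) NULL)
      if (!is.null(res)) {
        add_cor("delta_initiated_GRO_3Bvs3A", "delta_received_GRO_3Bvs3A",
                res, control = "delta_OT_S3vsS2")
      }
    }
    ## dyad-level baseline vs change among existing pairs
    for (beh in c("AGG", "GRO")) {
      db <- dyads[dyads$behavior == beh, , drop = FALSE]
      res <- tryCatch(dyad_change_correlation(db$freq_obs1, db$freq_obs3a),
                      error = function(e) NULL)
      if (!is.null(res)) {
        add_cor(paste0(beh, "_dyad_obs1"),
                paste0(beh, "_dyad_delta_3Avs1"), res)
      }
    }
  })
  cor_tab <- do.call(rbind, cor_rows)
  cor_path <- write_tsv(cor_tab,
                        file.path(config$out_dir, "correlations.tsv"))
  note("correlate: ", nrow(cor_tab), " correlations")

  ## ----- manifest & log -------------------------------------------------
  manifest <- list(
    package = "stressrank",
    version = as.character(utils::packageVersion("stressrank")),
    seed = config$seed,
    config = list(ds_variant = config$ds_variant,
                  zero_dyad = config$zero_dyad,
                  gg_alpha = config$gg_alpha,
                  appearance_thresholds = config$appearance_thresholds),
    inputs = list(
      events = unname(tools::md5sum(config$events_path)),
      physiology = if (is.null(config$physio_path)) NULL
                   else unname(tools::md5sum(config$physio_path))),
    outputs = c("ds_table.tsv", "anova_table.tsv", "posthoc.tsv",
                "correlations.tsv", "dyad_summary.tsv"))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  log_path <- file.path(config$out_dir, "pipeline.log")
  writeLines(log_lines, log_path)

  invisible(list(ds_table = ds_path, anova_table = anova_path,
                 posthoc = posthoc_path, correlations = cor_path,
                 dyad_summary = dyad_path, manifest = manifest_path,
                 log = log_path))
}
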