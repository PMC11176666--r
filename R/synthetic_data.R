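## deterministic substream seeds derived from the single global seed
substream_seed <- function(seed, stream) {
  as.integer((as.double(seed) %% 1e6) * 2099 + stream * 104729) %% 2147483647L
}

#' Configuration for the synthetic colony generator
#'
#' Defines the simulated study: two colonies of adult females (7 and 6 by
#' default), a planted strict dominance order per colony, three six-day
#' behavioral observation periods (baseline OBS1 and post-stress OBS3A /
#' OBS3B), the three-sample physiology schedule (S1 end of baseline, S2 end
#' of a four-week isolation/stress phase, S3 end of a four-week recovery
#' phase), and five weekly fecal immunoglobulin samples during isolation.
#'
#' Agonistic encounters are Poisson per unordered dyad; each decided
#' encounter emits one aggressive event (winner to loser) and one matching
#' submissive event (loser to winner), the higher-planted animal winning
#' with probability `dominance_prob`. Grooming and proximity are Poisson
#' per ordered dyad. A per-dyad gamma rate multiplier (`dyad_dispersion` =
#' gamma shape, mean 1; `Inf` disables it) makes some pairs interact much
#' more than others, as real colonies do, so baseline "appearance" strata
#' are non-trivial. Post-stress shifts multiply rates from OBS3A on:
#' aggression down and grooming up within low-ranking/low-ranking (LL)
#' dyads, proximity up across all dyad types.
#'
#' @param group_sizes Integer vector of colony sizes (each >= 2); names are
#'   used as group ids (default `BJ`, `SZ` naming for two colonies).
#' @param interactions_per_dyad Mean decided agonistic encounters per
#'   unordered dyad per observation period.
#' @param dominance_prob Probability the higher-planted animal wins a
#'   decided encounter, in [0.5, 1].
#' @param behavior_rates Mean frequencies per ordered dyad per observation
#'   for grooming (`GRO`) and proximity (`PRO`). Aggression and submission
#'   counts are fully determined by `interactions_per_dyad` and
#'   `dominance_prob`.
#' @param dyad_dispersion Gamma shape of the per-dyad rate multiplier;
#'   smaller values give more heterogeneous dyads, `Inf` gives none.
#' @param stress_effects Named list of physiological effect sizes (all
#'   proportional to baseline): `hc_global_increase` and `hc_rank_slope`
#'   (hair cortisol rise at S2 and its increase with normalized rank),
#'   `ot_baseline_rank_slope`, `ot_global_increase`,
#'   `ot_recovery_rank_slope` (extra S3 oxytocin rise for lower-ranked
#'   animals), `avp_shift` (global S2 vasopressin rise),
#'   `avp_s3_rank_slope` (rank-proportional S3 decline),
#'   `igg_iga_ramp_onset_week`, `igg_iga_elevation`, `igg_iga_rank_slope`
#'   (larger immunoglobulin elevation for lower-ranked animals),
#'   `igg_iga_week4_retention` (fraction of the elevation left at week 4),
#'   `weight_s3_increase`.
#' @param post_stress_shifts Named list of behavioral rate multipliers
#'   applied at OBS3A/OBS3B: `ll_agg_decrease` (< 1), `ll_gro_increase`
#'   (> 1), `pro_increase_all_types` (> 1).
#' @param baselines,noise_sd Named vectors of assay-unit baselines and
#'   Gaussian noise standard deviations per analyte
#'   (HC, OT, AVP, IGG, IGA, WEIGHT; weight in kg).
#' @param seed Single global seed; behavioral and physiological substreams
#'   are derived from it independently.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(group_sizes = c(BJ = 7, SZ = 6),
                              interactions_per_dyad = 20,
                              dominance_prob = 0.9,
                              behavior_rates = c(GRO = 15, PRO = 12),
                              dyad_dispersion = 1,
                              stress_effects = list(),
                              post_stress_shifts = list(),
                              baselines = c(HC = 50, OT = 200, AVP = 100,
                                            IGG = 80, IGA = 60, WEIGHT = 6),
                              noise_sd = c(HC = 3, OT = 10, AVP = 6,
                                           IGG = 5, IGA = 5, WEIGHT = 0.1),
                              seed = 20260115) {
  se_default <- list(hc_global_increase = 0.3, hc_rank_slope = 0.6,
                     ot_baseline_rank_slope = 0.3, ot_global_increase = 0.3,
                     ot_recovery_rank_slope = 0.25, avp_shift = 0.4,
                     avp_s3_rank_slope = 0.2, igg_iga_ramp_onset_week = 2,
                     igg_iga_elevation = 0.5, igg_iga_rank_slope = 0.2,
                     igg_iga_week4_retention = 0.5, weight_s3_increase = 0.05)
  ps_default <- list(ll_agg_decrease = 0.4, ll_gro_increase = 1.8,
                     pro_increase_all_types = 1.5)
  unknown <- setdiff(names(stress_effects), names(se_default))
  if (length(unknown) > 0) {
    stop("unknown stress_effects field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(post_stress_shifts), names(ps_default))
  if (length(unknown) > 0) {
    stop("unknown post_stress_shifts field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  se <- utils::modifyList(se_default, stress_effects)
  ps <- utils::modifyList(ps_default, post_stress_shifts)

  if (length(group_sizes) < 1 || any(group_sizes < 2)) {
    stop("group sizes must be >= 2", call. = FALSE)
  }
  if (is.null(names(group_sizes)) || any(names(group_sizes) == "")) {
    names(group_sizes) <- paste0("G", seq_along(group_sizes))
  }
  if (dominance_prob < 0.5 || dominance_prob > 1) {
    stop("dominance_prob must lie in [0.5, 1]", call. = FALSE)
  }
  if (interactions_per_dyad < 0) {
    stop("interactions_per_dyad must be non-negative", call. = FALSE)
  }
  if (!all(c("GRO", "PRO") %in% names(behavior_rates)) ||
      any(behavior_rates < 0)) {
    stop("behavior_rates needs non-negative GRO and PRO entries",
         call. = FALSE)
  }
  if (dyad_dispersion <= 0) {
    stop("dyad_dispersion must be positive (Inf to disable)", call. = FALSE)
  }
  if (ps$ll_agg_decrease < 0 || ps$ll_gro_increase < 0 ||
      ps$pro_increase_all_types < 0) {
    stop("post_stress_shifts must be non-negative multipliers", call. = FALSE)
  }
  analytes <- c("HC", "OT", "AVP", "IGG", "IGA", "WEIGHT")
  if (!all(analytes %in% names(baselines)) ||
      !all(analytes %in% names(noise_sd))) {
    stop("baselines and noise_sd must cover ",
         paste(analytes, collapse = ", "), call. = FALSE)
  }
  if (any(baselines < 0) || any(noise_sd < 0)) {
    stop("baselines and noise_sd must be non-negative", call. = FALSE)
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)

  structure(list(group_sizes = group_sizes,
                 interactions_per_dyad = interactions_per_dyad,
                 dominance_prob = dominance_prob,
                 behavior_rates = behavior_rates,
                 dyad_dispersion = dyad_dispersion,
                 stress_effects = se, post_stress_shifts = ps,
                 baselines = baselines, noise_sd = noise_sd, seed = seed),
            class = "simulation_config")
}

#' Planted hierarchy of a simulated study
#'
#' Subjects are created in strict dominance order within each colony:
#' planted rank 1 is the top animal. The planted normalized score is
#' linear, `(n - rank) / (n - 1)`, and the planted HR/LR class splits each
#' colony at the middle (the top `ceiling(n/2)` animals are HR), giving
#' the 4/3 and 3/3 splits of the emulated two-colony design.
#'
#' @param config A `simulation_config`.
#' @return Data frame: `group_id, subject, planted_rank, planted_normDS,
#'   planted_class`.
#' @export
planted_hierarchy <- function(config) {
  out <- lapply(names(config$group_sizes), function(g) {
    n <- config$group_sizes[[g]]
    i <- seq_len(n)
    data.frame(group_id = g, subject = sprintf("%s-%d", g, i),
               planted_rank = i,
               planted_normDS = (n - i) / (n - 1),
               planted_class = ifelse(i <= ceiling(n / 2), "HR", "LR"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## spread a count over the six observation days
spread_days <- function(count) {
  if (count == 0) return(integer(0))
  as.vector(stats::rmultinom(1, count, rep(1 / 6, 6)))
}

dyad_multiplier <- function(shape) {
  if (is.infinite(shape)) 1 else stats::rgamma(1, shape = shape, rate = shape)
}

#' Simulate behavioral event logs for the planted colonies
#'
#' Draws three observation periods of directed behavior for every colony in
#' the configuration. The planted order drives agonistic outcomes; the
#' post-stress rate shifts apply from OBS3A on. Fully reproducible: the
#' behavioral substream is derived from `config$seed` and is independent of
#' the physiological substream.
#'
#' @param config A `simulation_config`.
#' @return A validated event-log data frame.
#' @export
simulate_colony <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(substream_seed(config$seed, 1L))
  planted <- planted_hierarchy(config)
  ps <- config$post_stress_shifts
  rows <- list()
  add <- function(g, obs, day_counts, from, to, beh) {
    keep <- which(day_counts > 0)
    if (length(keep) == 0) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      group_id = g, observation_id = obs, day = keep, initiator = from,
      receiver = to, behavior = beh, count = day_counts[keep],
      stringsAsFactors = FALSE)
  }
  for (g in names(config$group_sizes)) {
    pg <- planted[planted$group_id == g, , drop = FALSE]
    n <- nrow(pg)
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        si <- pg$subject[i]; sj <- pg$subject[j]
        is_ll <- pg$planted_class[i] == "LR" && pg$planted_class[j] == "LR"
        m_ag <- dyad_multiplier(config$dyad_dispersion)
        m_gro_ij <- dyad_multiplier(config$dyad_dispersion)
        m_gro_ji <- dyad_multiplier(config$dyad_dispersion)
        m_pro_ij <- dyad_multiplier(config$dyad_dispersion)
        m_pro_ji <- dyad_multiplier(config$dyad_dispersion)
        for (obs in OBSERVATION_LEVELS) {
          post <- obs != "OBS1"
          rate_ag <- config$interactions_per_dyad * m_ag *
            (if (post && is_ll) ps$ll_agg_decrease else 1)
          n_int <- stats::rpois(1, rate_ag)
          wins_i <- stats::rbinom(1, n_int, config$dominance_prob)
          wins_j <- n_int - wins_i
          ## each decided encounter yields one AGG (winner -> loser) and a
          ## matching SUB (loser -> winner) on the same day
          d_i <- spread_days(wins_i); d_j <- spread_days(wins_j)
          add(g, obs, d_i, si, sj, "AGG")
          add(g, obs, d_i, sj, si, "SUB")
          add(g, obs, d_j, sj, si, "AGG")
          add(g, obs, d_j, si, sj, "SUB")
          gro_mult <- if (post && is_ll) ps$ll_gro_increase else 1
          pro_mult <- if (post) ps$pro_increase_all_types else 1
          add(g, obs, spread_days(stats::rpois(
            1, config$behavior_rates[["GRO"]] * m_gro_ij * gro_mult)),
            si, sj, "GRO")
          add(g, obs, spread_days(stats::rpois(
            1, config$behavior_rates[["GRO"]] * m_gro_ji * gro_mult)),
            sj, si, "GRO")
          add(g, obs, spread_days(stats::rpois(
            1, config$behavior_rates[["PRO"]] * m_pro_ij * pro_mult)),
            si, sj, "PRO")
          add(g, obs, spread_days(stats::rpois(
            1, config$behavior_rates[["PRO"]] * m_pro_ji * pro_mult)),
            sj, si, "PRO")
        }
      }
    }
  }
  events <- do.call(rbind, rows)
  events <- events[order(match(events$group_id, names(config$group_sizes)),
                         match(events$observation_id, OBSERVATION_LEVELS),
                         match(events$behavior, BEHAVIOR_LEVELS),
                         events$initiator, events$receiver, events$day), ]
  rownames(events) <- NULL
  validate_event_log(events)
  events
}

#' Simulate longitudinal physiology with rank-dependent stress effects
#'
#' Generates the full sampling schedule per subject: hair cortisol (HC),
#' plasma oxytocin (OT) and vasopressin (AVP) and body weight at S1/S2/S3,
#' fecal IgG/IgA at weeks 0-4 of the isolation phase. Effects, all
#' proportional to baseline: HC rises at S2 with a positive slope in
#' planted rank and partially recovers at S3; OT starts higher in
#' higher-ranked animals, rises globally at S2, and keeps rising at S3 the
#' more the lower the rank; AVP rises globally at S2 and declines at S3 in
#' proportion to rank; IgG/IgA stay flat until the ramp-onset week, then
#' are elevated (more so for lower-ranked animals) with partial decline at
#' week 4; weight is flat through S2 and increases at S3. Gaussian noise is
#' added per analyte. The physiological substream is independent of the
#' behavioral one.
#'
#' @param config A `simulation_config`.
#' @param planted Planted hierarchy data frame; defaults to
#'   [planted_hierarchy()] of `config`.
#' @return A validated long-format physiology panel.
#' @export
simulate_physiology <- function(config, planted = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(planted)) planted <- planted_hierarchy(config)
  set.seed(substream_seed(config$seed, 2L))
  se <- config$stress_effects
  b <- config$baselines; sd_ <- config$noise_sd
  rows <- list()
  for (k in seq_len(nrow(planted))) {
    s <- planted$planted_normDS[k]
    sid <- planted$subject[k]; g <- planted$group_id[k]
    hc_rise <- se$hc_global_increase + se$hc_rank_slope * s
    tri <- list(
      HC = b[["HC"]] * c(1, 1 + hc_rise, 1 + 0.5 * hc_rise),
      OT = b[["OT"]] * (1 + se$ot_baseline_rank_slope * s) *
        c(1, 1 + se$ot_global_increase,
          (1 + se$ot_global_increase) *
            (1 + se$ot_recovery_rank_slope * (1 - s))),
      AVP = b[["AVP"]] * c(1, 1 + se$avp_shift,
                           (1 + se$avp_shift) *
                             (1 - se$avp_s3_rank_slope * s)),
      WEIGHT = b[["WEIGHT"]] * c(1, 1, 1 + se$weight_s3_increase))
    for (an in names(tri)) {
      vals <- pmax(0, tri[[an]] + stats::rnorm(3, 0, sd_[[an]]))
      rows[[length(rows) + 1L]] <- data.frame(
        group_id = g, subject_id = sid, analyte = an,
        timepoint = TRIPHASE_TIMEPOINTS, value = vals,
        stringsAsFactors = FALSE)
    }
    elev <- se$igg_iga_elevation * (1 + se$igg_iga_rank_slope * (1 - s))
    week_mult <- vapply(0:4, function(w) {
      if (w < se$igg_iga_ramp_onset_week) 1
      else if (w == 4) 1 + se$igg_iga_week4_retention * elev
      else 1 + elev
    }, numeric(1))
    for (an in WEEKLY_ANALYTES) {
      vals <- pmax(0, b[[an]] * week_mult + stats::rnorm(5, 0, sd_[[an]]))
      rows[[length(rows) + 1L]] <- data.frame(
        group_id = g, subject_id = sid, analyte = an,
        timepoint = WEEKLY_TIMEPOINTS, value = vals,
        stringsAsFactors = FALSE)
    }
  }
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  validate_physio_panel(panel)
  panel
}

#' Write a complete synthetic study to disk
#'
#' Emits `events.csv` and `physiology.csv` in the package's event-log and
#' physiology schemas, for the full two-colony design (three observation
#' periods, three-sample and five-sample physiology schedules).
#' Deterministic under `config$seed`.
#'
#' @param config A `simulation_config`.
#' @param out_dir Writable output directory (created if absent).
#' @return Named character vector with the `events` and `physiology` paths.
#' @export
generate_fixture_study <- function(config = simulation_config(),
                                   out_dir = tempfile("study")) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  events_path <- file.path(out_dir, "events.csv")
  physio_path <- file.path(out_dir, "physiology.csv")
  write_event_log(simulate_colony(config), events_path)
  write_physio_panel(simulate_physiology(config), physio_path)
  c(events = events_path, physiology = physio_path)
}
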