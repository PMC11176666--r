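#' Enumerate ordered dyads with interaction types
#'
#' Every ordered (initiator, receiver) pair within a group is typed by the
#' HR/LR classes of its members: LL (initiated by a low-ranking animal,
#' received by a low-ranking one), HL (high -> low), LH (low -> high),
#' HH (high -> high). A group with h HR and l LR animals yields l(l-1) LL,
#' h(h-1) HH, and h*l each of HL and LH ordered dyads. BOUNDARY subjects
#' (normalized score exactly 0.5) are excluded with a warning.
#'
#' @param classes Data frame with columns `group_id`, `subject`, `class`
#'   (values `"HR"`, `"LR"`, or `"BOUNDARY"`), e.g. built from
#'   [dominance_ranks()] output.
#' @return Data frame of ordered dyads: `group_id, initiator, receiver,
#'   dtype`.
#' @export
classify_dyad_types <- function(classes) {
  stopifnot(all(c("group_id", "subject", "class") %in% names(classes)))
  if (any(classes$class == "BOUNDARY")) {
    warning("excluding ", sum(classes$class == "BOUNDARY"),
            " BOUNDARY subject(s) from dyad typing", call. = FALSE)
    classes <- classes[classes$class != "BOUNDARY", , drop = FALSE]
  }
  if (!all(classes$class %in% c("HR", "LR"))) {
    stop("classes must be HR or LR", call. = FALSE)
  }
  out <- list()
  for (g in unique(classes$group_id)) {
    cg <- classes[classes$group_id == g, , drop = FALSE]
    n <- nrow(cg)
    if (n < 2) next
    idx <- expand.grid(i = seq_len(n), j = seq_len(n))
    idx <- idx[idx$i != idx$j, , drop = FALSE]
    ci <- cg$class[idx$i]; cj <- cg$class[idx$j]
    dtype <- paste0(ifelse(ci == "HR", "H", "L"),
                    ifelse(cj == "HR", "H", "L"))
    out[[g]] <- data.frame(group_id = g,
                           initiator = cg$subject[idx$i],
                           receiver = cg$subject[idx$j],
                           dtype = dtype, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Stratify dyads by baseline appearance
#'
#' Splits dyads into Zero-Appearance (the behavior was never observed in
#' the pair at baseline), Low-Appearance (frequency strictly between 0 and
#' the threshold) and High-Appearance (frequency at or above the
#' threshold), using baseline (Observation 1) frequencies. With
#' `threshold = "auto"` the integer cut point is chosen to minimize the
#' absolute size difference between the Low and High strata among nonzero
#' dyads, ties resolved toward the smaller threshold — the "similar sample
#' size" rule for choosing a split point.
#'
#' @param baseline_freqs Named or unnamed vector of non-negative integer
#'   baseline frequencies, one per ordered dyad.
#' @param threshold Positive integer cut point, or `"auto"`.
#' @return Character vector (`"ZERO"`, `"LOW"`, `"HIGH"`) aligned with the
#'   input, with the chosen threshold in attribute `threshold`.
#' @export
stratify_appearance <- function(baseline_freqs, threshold = "auto") {
  f <- baseline_freqs
  if (any(is.na(f)) || any(f < 0)) {
    stop("baseline frequencies must be non-negative", call. = FALSE)
  }
  nz <- f[f > 0]
  if (identical(threshold, "auto") || identical(threshold, "AUTO")) {
    if (length(nz) == 0) {
      stop("cannot choose a threshold automatically: all baseline ",
           "frequencies are zero", call. = FALSE)
    }
    cand <- sort(unique(c(nz, max(nz) + 1)))
    imbalance <- vapply(cand, function(th)
      abs(sum(nz > 0 & nz < th) - sum(nz >= th)), numeric(1))
    threshold <- cand[which.min(imbalance)]   # which.min takes the smallest tie
  } else {
    threshold <- as.integer(threshold)
    if (is.na(threshold) || threshold < 1) {
      stop("threshold must be a positive integer or 'auto'", call. = FALSE)
    }
  }
  out <- ifelse(f == 0, "ZERO", ifelse(f < threshold, "LOW", "HIGH"))
  attr(out, "threshold") <- threshold
  out
}

#' Baseline-vs-change correlation over existing dyads
#'
#' Tests whether the amount of behavior a dyad showed at baseline predicts
#' how much it changed after chronic stress. Dyads with zero baseline are
#' excluded first (the proportional change score is undefined at zero, and
#' non-existing pairs carry no information about change in existing ones);
#' the change score `(followup - baseline) / baseline` is then correlated
#' with the baseline frequency by two-tailed Pearson correlation.
#'
#' @param baseline Baseline (Observation 1) frequencies per dyad.
#' @param followup Frequencies for the same dyads at the later observation.
#' @return A `cor_result` with attribute `n_excluded` (zero-baseline dyads
#'   dropped).
#' @export
dyad_change_correlation <- function(baseline, followup) {
  stopifnot(length(baseline) == length(followup))
  keep <- !is.na(baseline) & baseline > 0 & !is.na(followup)
  n_excluded <- sum(!keep)
  b <- baseline[keep]; fu <- followup[keep]
  if (length(b) < 4) {
    stop("insufficient data: fewer than 4 existing dyads", call. = FALSE)
  }
  delta <- change_score(fu, b)
  if (stats::sd(delta) == 0 || stats::sd(b) == 0) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  res <- pearson_correlation(b, delta)
  attr(res, "n_excluded") <- n_excluded
  res
}

#' Per-dyad behavior summary across observations
#'
#' Builds the long dyad table used throughout the dyad-level analyses: one
#' row per ordered dyad per behavior, with the dyad's interaction type,
#' its appearance stratum (from Observation 1), frequencies at the three
#' observations, and proportional change scores. Change scores with a zero
#' reference are `NA` (flagged by the `n_excluded`-style warnings of
#' [change_score()]).
#'
#' @param events Validated event log (may span several groups).
#' @param classes HR/LR classification data frame as for
#'   [classify_dyad_types()].
#' @param behaviors Behaviors to summarize (default all four).
#' @param thresholds Named list/vector of appearance thresholds per
#'   behavior (integer or `"auto"`); strata are computed on the pooled
#'   dyads per behavior. Default `"auto"` for all.
#' @return Data frame with columns `group_id, initiator, receiver,
#'   behavior, dtype, appearance, freq_obs1, freq_obs3a, freq_obs3b,
#'   delta_3avs1, delta_3bvs3a, delta_3bvs1`.
#' @export
dyad_summary <- function(events, classes,
                         behaviors = BEHAVIOR_LEVELS,
                         thresholds = NULL) {
  events <- validate_event_log(events)
  dyads <- classify_dyad_types(classes)
  out <- list()
  for (beh in behaviors) {
    mats <- list()
    for (g in unique(dyads$group_id)) {
      ev_g <- events[events$group_id == g, , drop = FALSE]
      roster <- event_roster(ev_g, g)
      mats[[g]] <- lapply(stats::setNames(OBSERVATION_LEVELS,
                                          OBSERVATION_LEVELS),
                          function(obs)
                            aggregate_interactions(ev_g, beh, obs, roster))
    }
    d <- dyads
    d$behavior <- beh
    freq_of <- function(obs) {
      vapply(seq_len(nrow(d)), function(k) {
        M <- mats[[d$group_id[k]]][[obs]]
        as.numeric(M[d$initiator[k], d$receiver[k]])
      }, numeric(1))
    }
    d$freq_obs1 <- freq_of("OBS1")
    d$freq_obs3a <- freq_of("OBS3A")
    d$freq_obs3b <- freq_of("OBS3B")
    th <- if (is.null(thresholds) || is.null(thresholds[[beh]])) "auto"
          else thresholds[[beh]]
    d$appearance <- as.character(stratify_appearance(d$freq_obs1, th))
    suppressWarnings({
      d$delta_3avs1 <- change_score(d$freq_obs3a, d$freq_obs1,
                                    na_undefined = TRUE)
      d$delta_3bvs3a <- change_score(d$freq_obs3b, d$freq_obs3a,
                                     na_undefined = TRUE)
      d$delta_3bvs1 <- change_score(d$freq_obs3b, d$freq_obs1,
                                    na_undefined = TRUE)
    })
    out[[beh]] <- d[, c("group_id", "initiator", "receiver", "behavior",
                        "dtype", "appearance", "freq_obs1", "freq_obs3a",
                        "freq_obs3b", "delta_3avs1", "delta_3bvs3a",
                        "delta_3bvs1")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
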