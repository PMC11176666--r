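#' Build a win matrix from aggression and submission matrices
#'
#' A "win" of i over j is either an aggressive act initiated by i toward j
#' or a submissive act initiated by j toward i, so
#' `W[i, j] = agg[i, j] + t(sub)[i, j]`. Both agonistic behavior classes
#' therefore contribute to rank.
#'
#' @param agg `interaction_matrix` of aggressive acts.
#' @param sub `interaction_matrix` of submissive acts on the same roster and
#'   observation period.
#' @return A `win_matrix`: integer matrix with zero diagonal carrying the
#'   `observation_id` and `group_id` attributes.
#' @export
build_win_matrix <- function(agg, sub) {
  if (!identical(rownames(agg), rownames(sub)) ||
      !identical(colnames(agg), colnames(sub))) {
    stop("roster mismatch between aggression and submission matrices",
         call. = FALSE)
  }
  oa <- attr(agg, "observation_id"); os <- attr(sub, "observation_id")
  if (!is.null(oa) && !is.null(os) && !identical(oa, os)) {
    stop("observation mismatch: ", oa, " vs ", os, call. = FALSE)
  }
  W <- unclass(agg) + t(unclass(sub))
  diag(W) <- 0L
  structure(W, class = c("win_matrix", "matrix", "array"),
            observation_id = oa, group_id = attr(agg, "group_id"))
}

#' Construct a win matrix directly
#'
#' @param W Square non-negative matrix with subject dimnames; the diagonal
#'   is forced to zero.
#' @param observation_id Optional observation label.
#' @param group_id Optional group label.
#' @return A `win_matrix`.
#' @export
win_matrix <- function(W, observation_id = NULL, group_id = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("win matrix must be square", call. = FALSE)
  if (any(W < 0)) stop("win matrix entries must be non-negative", call. = FALSE)
  if (is.null(rownames(W))) {
    rownames(W) <- colnames(W) <- paste0("S", seq_len(nrow(W)))
  }
  diag(W) <- 0
  structure(W, class = c("win_matrix", "matrix", "array"),
            observation_id = observation_id, group_id = group_id)
}

#' Dyadic dominance indices from a win matrix
#'
#' For each ordered pair with `n_ij = W[i,j] + W[j,i]` interactions, the raw
#' index is the win proportion `P_ij = W[i,j] / n_ij`. The chance-corrected
#' variant shrinks sparse dyads toward 0.5:
#' `D_ij = P_ij - (P_ij - 0.5) / (n_ij + 1)`, discounting proportions backed
#' by few observations. Dyads that never interacted contribute 0 to both
#' directions by default ("zero" convention: no dominance is invented), or
#' 0.5 to each under the "half" convention.
#'
#' @param W A `win_matrix`.
#' @param variant `"chance_corrected"` (default) or `"raw"`.
#' @param zero_dyad Convention for dyads with `n_ij = 0`: `"zero"` (default)
#'   or `"half"`.
#' @return A `dominance_components` list with the index matrix; pass to
#'   [david_score()].
#' @export
dyadic_index <- function(W, variant = c("chance_corrected", "raw"),
                         zero_dyad = c("zero", "half")) {
  variant <- match.arg(variant)
  zero_dyad <- match.arg(zero_dyad)
  Wm <- unclass(W)
  n <- nrow(Wm)
  N <- Wm + t(Wm)                      # n_ij, symmetric
  P <- matrix(0, n, n, dimnames = dimnames(Wm))
  pos <- N > 0
  P[pos] <- Wm[pos] / N[pos]
  if (variant == "chance_corrected") {
    P[pos] <- P[pos] - (P[pos] - 0.5) / (N[pos] + 1)
  }
  if (zero_dyad == "half") {
    off <- !pos; diag(off) <- FALSE
    P[off] <- 0.5
  }
  diag(P) <- 0
  structure(list(index_matrix = P, variant = variant, zero_dyad = zero_dyad,
                 subjects = rownames(Wm),
                 observation_id = attr(W, "observation_id"),
                 group_id = attr(W, "group_id")),
            class = "dominance_components")
}

#' David's score from dyadic indices
#'
#' Per individual: `w = rowSums(index)`, `l = colSums(index)`, the
#' opponent-weighted terms `w2_i = sum_j index[i,j] * w_j` and
#' `l2_i = sum_j index[j,i] * l_j`, and `DS = w + w2 - l - l2`. Scores sum
#' to zero over the group.
#'
#' @param components `dominance_components` from [dyadic_index()].
#' @return The components with `w`, `w2`, `l`, `l2` and `DS` filled in.
#' @export
david_score <- function(components) {
  P <- components$index_matrix
  w <- rowSums(P)
  l <- colSums(P)
  w2 <- as.vector(P %*% w)
  l2 <- as.vector(t(P) %*% l)
  names(w2) <- names(l2) <- rownames(P)
  components$w <- w; components$w2 <- w2
  components$l <- l; components$l2 <- l2
  components$DS <- w + w2 - l - l2
  components
}

#' Normalize David's scores onto [0, 1]
#'
#' Two-step min-max normalization: shift so the minimum becomes zero,
#' `DS'_i = DS_i + |min DS|`, then divide by the shifted maximum,
#' `normDS_i = DS'_i / max DS'`. The highest-ranking individual of a group
#' gets 1 and the lowest 0, making ranks comparable across groups of
#' different size.
#'
#' @param DS Numeric vector of David's scores, length >= 2.
#' @return Numeric vector of normalized scores with attributes `DS_min` and
#'   `DS_shift_max` recording the two normalization constants.
#' @export
normalize_ds <- function(DS) {
  if (length(DS) < 2) stop("need at least two subjects", call. = FALSE)
  ds_min <- min(DS)
  shifted <- DS + abs(ds_min)
  smax <- max(shifted)
  if (smax <= 0 || isTRUE(all.equal(max(DS), min(DS)))) {
    stop("degenerate hierarchy: all David's scores equal", call. = FALSE)
  }
  out <- shifted / smax
  attr(out, "DS_min") <- ds_min
  attr(out, "DS_shift_max") <- smax
  out
}

#' Rank a colony from a win matrix
#'
#' Runs the full chain dyadic index -> David's score -> normalization ->
#' high-/low-ranking classification. Individuals with normalized score
#' above 0.5 are classed HR (high-ranking), below 0.5 LR (low-ranking);
#' a score of exactly 0.5 is flagged BOUNDARY and excluded from HR/LR
#' contrasts downstream (with a warning). Ordinal rank 1 is the highest
#' score; ties are broken by roster order with a warning.
#'
#' @inheritParams dyadic_index
#' @return A `dominance_result` data frame with columns `subject`, `DS`,
#'   `normDS`, `ordinal_rank`, `class`, plus attributes `DS_min`,
#'   `DS_shift_max`, `variant`, `observation_id`, `group_id`.
#' @export
dominance_ranks <- function(W, variant = c("chance_corrected", "raw"),
                            zero_dyad = c("zero", "half")) {
  comp <- david_score(dyadic_index(W, variant, zero_dyad))
  normDS <- normalize_ds(comp$DS)
  res <- data.frame(subject = comp$subjects,
                    DS = unname(comp$DS),
                    normDS = as.vector(normDS),
                    stringsAsFactors = FALSE)
  res$ordinal_rank <- ordinal_ranks(res$normDS)
  res$class <- partition_hr_lr(res$normDS)
  structure(res, class = c("dominance_result", "data.frame"),
            DS_min = attr(normDS, "DS_min"),
            DS_shift_max = attr(normDS, "DS_shift_max"),
            variant = comp$variant,
            observation_id = comp$observation_id,
            group_id = comp$group_id)
}

#' HR/LR classification of normalized scores
#'
#' @param normDS Numeric vector of normalized David's scores.
#' @return Character vector: `"HR"` where normDS > 0.5, `"LR"` where < 0.5,
#'   `"BOUNDARY"` at exactly 0.5 (warned).
#' @export
partition_hr_lr <- function(normDS) {
  klass <- ifelse(normDS > 0.5, "HR", ifelse(normDS < 0.5, "LR", "BOUNDARY"))
  if (any(klass == "BOUNDARY")) {
    warning("subject(s) at normDS = 0.5 classed BOUNDARY; ",
            "they are excluded from HR/LR contrasts", call. = FALSE)
  }
  klass
}

## rank 1 = highest score; ties broken by position with a warning
ordinal_ranks <- function(normDS) {
  if (anyDuplicated(normDS)) {
    warning("tied normalized scores; ordinal ranks broken by roster order",
            call. = FALSE)
  }
  rank(-normDS, ties.method = "first")
}

#' Hierarchy stability between two observation periods
#'
#' Compares the ordinal rankings of two dominance results on the same
#' roster: Kendall's tau, Spearman's rho, and the list of subject pairs
#' whose relative order switched (discordant pairs).
#'
#' @param result_a,result_b `dominance_result` objects for the same roster.
#' @return A list with `tau`, `rho`, and `switched_pairs` (two-column
#'   character matrix; zero rows when the orders agree).
#' @export
hierarchy_stability <- function(result_a, result_b) {
  if (!setequal(result_a$subject, result_b$subject)) {
    stop("roster mismatch between dominance results", call. = FALSE)
  }
  ord <- match(result_a$subject, result_b$subject)
  ra <- result_a$ordinal_rank
  rb <- result_b$ordinal_rank[ord]
  tau <- stats::cor(ra, rb, method = "kendall")
  rho <- stats::cor(ra, rb, method = "spearman")
  pairs <- utils::combn(seq_along(ra), 2)
  disc <- (ra[pairs[1, ]] - ra[pairs[2, ]]) *
          (rb[pairs[1, ]] - rb[pairs[2, ]]) < 0
  switched <- cbind(result_a$subject[pairs[1, disc]],
                    result_a$subject[pairs[2, disc]])
  colnames(switched) <- c("subject_a", "subject_b")
  list(tau = tau, rho = rho, switched_pairs = switched)
}

#' Dominance table for a full study
#'
#' Computes per-group, per-observation dominance results from an event log
#' and stacks them into the long table written as `ds_table.tsv`.
#'
#' @param events Validated event log covering one or more groups.
#' @inheritParams dyadic_index
#' @return Data frame with columns `group_id, observation_id, subject_id,
#'   DS, normDS, ordinal_rank, class`.
#' @export
ds_table <- function(events, variant = c("chance_corrected", "raw"),
                     zero_dyad = c("zero", "half")) {
  variant <- match.arg(variant); zero_dyad <- match.arg(zero_dyad)
  events <- validate_event_log(events)
  out <- list()
  for (g in unique(events$group_id)) {
    ev_g <- events[events$group_id == g, , drop = FALSE]
    roster <- event_roster(ev_g, g)
    for (obs in intersect(OBSERVATION_LEVELS, unique(ev_g$observation_id))) {
      agg <- aggregate_interactions(ev_g, "AGG", obs, roster)
      sub <- aggregate_interactions(ev_g, "SUB", obs, roster)
      res <- dominance_ranks(build_win_matrix(agg, sub), variant, zero_dyad)
      out[[length(out) + 1L]] <- data.frame(
        group_id = g, observation_id = obs, subject_id = res$subject,
        DS = res$DS, normDS = res$normDS, ordinal_rank = res$ordinal_rank,
        class = res$class, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
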