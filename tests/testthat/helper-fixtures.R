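# Shared fixtures built in code.

# minimal hand-written event log rows
make_events <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(group_id = r[[1]], observation_id = r[[2]],
               day = as.integer(r[[3]]), initiator = r[[4]],
               receiver = r[[5]], behavior = r[[6]],
               count = as.integer(r[[7]]), stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

# random non-negative win matrix with zero diagonal
random_win_matrix <- function(n, lambda = 5) {
  W <- matrix(rpois(n * n, lambda), n, n,
              dimnames = list(LETTERS[1:n], LETTERS[1:n]))
  diag(W) <- 0
  win_matrix(W)
}

# strict transitive tournament: higher-planted subject wins every encounter
transitive_tournament <- function(n, wins = 4) {
  W <- matrix(0, n, n, dimnames = list(LETTERS[1:n], LETTERS[1:n]))
  W[upper.tri(W)] <- wins
  win_matrix(W)
}

# random balanced long dataset for the mixed ANOVA
random_mixed_data <- function(n_per_group = 6, t = 3, g = 2,
                              effect = 1, noise = 1) {
  units <- paste0("u", seq_len(n_per_group * g))
  grp <- rep(paste0("g", seq_len(g)), each = n_per_group)
  expand_rows <- expand.grid(unit = units, within = paste0("t", seq_len(t)),
                             stringsAsFactors = FALSE)
  expand_rows$between <- grp[match(expand_rows$unit, units)]
  expand_rows$value <- rnorm(nrow(expand_rows), 0, noise) +
    effect * as.integer(factor(expand_rows$within)) *
    as.integer(factor(expand_rows$between)) +
    rep(rnorm(length(units), 0, noise),
        times = t)[match(expand_rows$unit, units)]
  expand_rows
}

# independent split-plot oracle: aov() strata + mlm sphericity machinery
oracle_mixed_anova <- function(dat) {
  d <- dat
  d$unit <- factor(d$unit); d$within <- factor(d$within)
  d$between <- factor(d$between)
  fit <- summary(aov(value ~ between * within + Error(unit/within), data = d))
  betw <- fit[["Error: unit"]][[1]]
  wtab <- fit[["Error: unit:within"]][[1]]
  rownames(betw) <- trimws(rownames(betw))
  rownames(wtab) <- trimws(rownames(wtab))
  Y <- reshape(d[, c("unit", "within", "value")], direction = "wide",
               idvar = "unit", timevar = "within")
  grp <- d$between[match(Y$unit, d$unit)]
  Ym <- as.matrix(Y[, -1])
  mfit <- lm(Ym ~ grp)
  idata <- data.frame(time = factor(colnames(Ym)))
  a_w <- anova(mfit, M = ~ time, X = ~ 1, idata = idata, test = "Spherical")
  heading <- attr(a_w, "heading")
  eps_line <- grep("Greenhouse-Geisser epsilon", heading, value = TRUE)
  eps <- as.numeric(sub(".*epsilon:\\s*", "", eps_line))
  mau <- mauchly.test(mfit, M = ~ time, X = ~ 1, idata = idata)
  list(
    F_within = wtab["within", "F value"],
    F_inter = wtab["between:within", "F value"],
    F_between = betw["between", "F value"],
    SS_within = wtab["within", "Sum Sq"],
    SS_inter = wtab["between:within", "Sum Sq"],
    SS_between = betw["between", "Sum Sq"],
    SS_err_w = wtab["Residuals", "Sum Sq"],
    SS_err_b = betw["Residuals", "Sum Sq"],
    p_within = wtab["within", "Pr(>F)"],
    p_between = betw["between", "Pr(>F)"],
    p_inter = wtab["between:within", "Pr(>F)"],
    epsilon = eps,
    mauchly_W = unname(mau$statistic),
    mauchly_p = mau$p.value,
    p_gg_within = a_w["(Intercept)", "G-G Pr"],
    p_gg_inter = a_w["grp", "G-G Pr"])
}

# planted classes data frame from a simulation config
planted_classes <- function(config) {
  pl <- planted_hierarchy(config)
  data.frame(group_id = pl$group_id, subject = pl$subject,
             class = pl$planted_class, stringsAsFactors = FALSE)
}
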