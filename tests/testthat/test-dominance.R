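test_that("win matrix composition combines aggression and submission", {
  roster <- c("A", "B", "C")
  agg <- matrix(0L, 3, 3, dimnames = list(roster, roster))
  sub <- agg
  agg["A", "B"] <- 2L           # A attacks B
  sub["B", "A"] <- 3L           # B submits to A
  mk <- function(M, beh) structure(M, class = c("interaction_matrix",
                                                "matrix", "array"),
                                   behavior = beh, observation_id = "OBS1",
                                   group_id = "G1")
  W <- build_win_matrix(mk(agg, "AGG"), mk(sub, "SUB"))
  expect_equal(W["A", "B"], 5)
  expect_equal(sum(W), 5)

  # zero in, zero out
  W0 <- build_win_matrix(mk(agg * 0L, "AGG"), mk(sub * 0L, "SUB"))
  expect_equal(sum(W0), 0)

  # total wins equal total agonistic acts for random matrices
  set.seed(21)
  for (rep in 1:10) {
    A <- matrix(rpois(16, 3), 4, 4); diag(A) <- 0
    S <- matrix(rpois(16, 3), 4, 4); diag(S) <- 0
    dimnames(A) <- dimnames(S) <- list(LETTERS[1:4], LETTERS[1:4])
    W <- build_win_matrix(mk(A, "AGG"), mk(S, "SUB"))
    expect_equal(sum(W), sum(A) + sum(S))
  }

  bad <- mk(agg, "SUB")
  rownames(bad) <- colnames(bad) <- c("X", "Y", "Z")
  expect_error(build_win_matrix(mk(agg, "AGG"), bad), "roster")
})

test_that("dyadic indices follow the win-proportion formulas", {
  W <- win_matrix(matrix(c(0, 4, 0, 0), 2, 2, byrow = TRUE,
                         dimnames = list(c("A", "B"), c("A", "B"))))
  raw <- dyadic_index(W, "raw")$index_matrix
  expect_equal(raw["A", "B"], 1)
  expect_equal(raw["B", "A"], 0)

  # chance-corrected: 1 - (1 - 0.5)/(4 + 1) = 0.9
  cc <- dyadic_index(W, "chance_corrected")$index_matrix
  expect_equal(cc["A", "B"], 0.9)
  expect_equal(cc["B", "A"], 0.1)

  # zero-interaction dyads: both zero by default, 0.5 each under "half"
  Z <- win_matrix(matrix(0, 2, 2))
  expect_equal(sum(dyadic_index(Z)$index_matrix), 0)
  half <- dyadic_index(Z, zero_dyad = "half")$index_matrix
  expect_equal(half[1, 2], 0.5)
  expect_equal(half[2, 1], 0.5)

  # directed proportions of an interacting dyad always sum to 1
  set.seed(5)
  for (variant in c("raw", "chance_corrected")) {
    W <- random_win_matrix(5)
    P <- dyadic_index(W, variant)$index_matrix
    N <- unclass(W) + t(unclass(W))
    off <- which(upper.tri(N) & N > 0, arr.ind = TRUE)
    expect_equal(P[off] + t(P)[off], rep(1, nrow(off)))
    expect_true(all(P >= 0 & P <= 1))
  }
})

test_that("David's scores match hand computation and sum to zero", {
  W <- win_matrix(matrix(c(0, 4, 0, 0), 2, 2, byrow = TRUE))
  comp <- david_score(dyadic_index(W, "raw"))
  expect_equal(unname(comp$DS), c(1, -1))

  # fully tied dyads: every score zero
  Wt <- win_matrix(matrix(3, 3, 3))
  expect_equal(unname(david_score(dyadic_index(Wt, "raw"))$DS), c(0, 0, 0))

  set.seed(31)
  for (rep in 1:50) {
    W <- random_win_matrix(sample(3:8, 1))
    for (variant in c("raw", "chance_corrected")) {
      DS <- david_score(dyadic_index(W, variant))$DS
      expect_lt(abs(sum(DS)), 1e-9)
    }
  }
})

test_that("normalization maps groups onto [0, 1] with the right endpoints", {
  expect_equal(as.vector(normalize_ds(c(2, 0, -2))), c(1, 0.5, 0))

  # highest individual gets 1, lowest 0. The |min|-shift construction is
  # min-max scaling whenever the minimum is non-positive — always true of
  # David's scores, which sum to zero — and on that domain it is invariant
  # to constant shifts that keep the minimum at or below zero.
  set.seed(41)
  for (rep in 1:20) {
    DS <- rnorm(6); DS <- DS - mean(DS)
    nds <- normalize_ds(DS)
    expect_equal(max(nds), 1)
    expect_equal(min(nds), 0)
    expect_equal(which.max(nds), which.max(DS))
    shifted <- normalize_ds(DS - runif(1, 0, 5) - max(DS))
    expect_equal(as.vector(shifted), as.vector(nds))
  }

  expect_error(normalize_ds(c(3, 3, 3)), "degenerate")
  expect_error(normalize_ds(2), "two subjects")
})

test_that("HR/LR partition and ordinal ranks follow the 0.5 split", {
  nds <- c(1, .8, .6, .4, .2, 0)
  expect_equal(partition_hr_lr(nds),
               c("HR", "HR", "HR", "LR", "LR", "LR"))
  expect_warning(k <- partition_hr_lr(c(1, 0.5, 0)), "BOUNDARY")
  expect_equal(k[2], "BOUNDARY")
  expect_equal(stressrank:::ordinal_ranks(nds), 1:6)
})

test_that("a strict transitive tournament is recovered exactly", {
  for (variant in c("raw", "chance_corrected")) {
    res <- dominance_ranks(transitive_tournament(6), variant)
    expect_equal(res$ordinal_rank, 1:6)
    expect_equal(res$normDS[1], 1)
    expect_equal(res$normDS[6], 0)
    expect_equal(res$class, c("HR", "HR", "HR", "LR", "LR", "LR"))
  }
})

test_that("variants agree ordinally on balanced strict hierarchies", {
  # Both index variants are affine in the win proportion when every dyad
  # shares the same number of interactions, but they weight the first- and
  # second-order terms differently, so near-tied individuals can swap
  # between variants in noisy data. Where the hierarchy is strict (every
  # dominant animal wins every encounter) both variants must recover the
  # same — the planted — order.
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    W <- transitive_tournament(n, wins = sample(2:10, 1))
    # odd n puts the middle animal at exactly 0.5 -> expected BOUNDARY note
    r_raw <- suppressWarnings(dominance_ranks(W, "raw"))
    r_cc <- suppressWarnings(dominance_ranks(W, "chance_corrected"))
    expect_equal(r_raw$ordinal_rank, r_cc$ordinal_rank)
    expect_equal(r_cc$ordinal_rank, seq_len(n))
  }
})

test_that("hierarchy stability reports tau, rho and switched pairs", {
  res_a <- suppressWarnings(dominance_ranks(transitive_tournament(7)))
  expect_equal(hierarchy_stability(res_a, res_a)$tau, 1)

  rev_b <- res_a
  rev_b$ordinal_rank <- rev(res_a$ordinal_rank)
  expect_equal(hierarchy_stability(res_a, rev_b)$tau, -1)

  # one adjacent swap among 7: brute-force concordance count gives 19/21
  swap_b <- res_a
  swap_b$ordinal_rank[c(4, 5)] <- res_a$ordinal_rank[c(5, 4)]
  pairs <- combn(7, 2)
  conc <- sum((res_a$ordinal_rank[pairs[1, ]] - res_a$ordinal_rank[pairs[2, ]]) *
              (swap_b$ordinal_rank[pairs[1, ]] - swap_b$ordinal_rank[pairs[2, ]]) > 0)
  disc <- ncol(pairs) - conc
  expect_equal((conc - disc) / ncol(pairs), 19 / 21)

  st <- hierarchy_stability(res_a, swap_b)
  expect_equal(st$tau, 19 / 21)
  expect_equal(nrow(st$switched_pairs), 1)
  expect_setequal(as.vector(st$switched_pairs), res_a$subject[4:5])

  stranger <- res_a; stranger$subject <- paste0("Z", 1:7)
  expect_error(hierarchy_stability(res_a, stranger), "roster")
})

test_that("ds_table stacks per-group, per-observation results", {
  cfg <- simulation_config(group_sizes = c(P = 5, Q = 4), seed = 99)
  ev <- simulate_colony(cfg)
  tab <- suppressWarnings(ds_table(ev))
  expect_equal(nrow(tab), (5 + 4) * 3)
  expect_setequal(unique(tab$observation_id), c("OBS1", "OBS3A", "OBS3B"))
  # per group and observation: normDS spans [0, 1], ranks are a permutation
  for (g in c("P", "Q")) for (obs in unique(tab$observation_id)) {
    s <- tab[tab$group_id == g & tab$observation_id == obs, ]
    expect_equal(max(s$normDS), 1)
    expect_equal(min(s$normDS), 0)
    expect_setequal(s$ordinal_rank, seq_len(nrow(s)))
  }
})
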