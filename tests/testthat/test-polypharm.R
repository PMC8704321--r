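test_that("simple bounds and urn estimate match hand enumeration", {
  toy <- toy_example_relation()
  p1 <- ligand_profile(toy, "l1")
  expect_identical(polypharm_min(p1), 2L)
  expect_identical(polypharm_max(p1), 4L)
  r <- active_rate(p1)
  expect_equal(r$p_hat, 2 / 3)
  expect_identical(r$source, "ligand-specific")
  est <- polypharm_max_estimated(p1, r$p_hat)
  expect_equal(est$p_tilde_max, 10 / 3)
  expect_equal(est$delta_e_tilde, 4 / 3)

  allnull <- ligand_profile(lt_relation(ligands = "a",
                                        targets = paste0("t", 1:5)), "a")
  expect_identical(polypharm_min(allnull), 0L)
  expect_identical(polypharm_max(allnull), 5L)
  expect_identical(active_rate(allnull)$source, "undefined")
  fb <- active_rate(allnull, fallback = 0.06)
  expect_equal(fb$p_hat, 0.06)
  expect_identical(fb$source, "global-fallback")
  expect_error(polypharm_max_estimated(allnull, NA_real_), "fallback")

  onlyneg <- lt_relation(data.frame(ligand = "a", target = "t1",
                                    status = "inactive"),
                         targets = c("t1", "t2"))
  expect_equal(active_rate(ligand_profile(onlyneg, "a"))$p_hat, 0)

  # saturation: p_hat of 1 or 0 collapses the estimate onto a bound
  expect_equal(polypharm_max_estimated(p1, 1)$p_tilde_max, 4)
  expect_equal(polypharm_max_estimated(p1, 0)$p_tilde_max, 2)
})

test_that("jeffreys interval matches beta quantiles with boundary rules", {
  expect_equal(unname(jeffreys_interval(0, 10)[1]), 0)
  expect_equal(unname(jeffreys_interval(10, 10)[2]), 1)
  ji <- jeffreys_interval(2, 3, alpha = 0.05)
  expect_equal(unname(ji), qbeta(c(0.025, 0.975), 2.5, 1.5))
  ji <- jeffreys_interval(7, 50, alpha = 0.10)
  expect_equal(unname(ji), qbeta(c(0.05, 0.95), 7.5, 43.5))
  nd <- jeffreys_interval(0, 0)
  expect_equal(as.numeric(nd), c(0, 1))
  expect_true(attr(nd, "no_data"))
  expect_error(jeffreys_interval(4, 3), "k <= n")
  expect_error(jeffreys_interval(1, 3, alpha = 1.2), "alpha")
})

test_that("per-ligand report maps the Jeffreys interval through the bound", {
  toy <- toy_example_relation()
  est <- polypharm(toy)
  expect_identical(nrow(est), 2L)
  row <- est[est$ligand == "l1", ]
  expect_identical(row$p_min, 2L)
  expect_identical(row$p_max, 4L)
  expect_equal(row$p_tilde_max, 10 / 3)
  q <- jeffreys_interval(2, 3)
  expect_equal(row$ci_low, 2 + q[["low"]] * 2)
  expect_equal(row$ci_high, 2 + q[["high"]] * 2)

  # fully measured data: intervals collapse to the point pmin = pmax
  full <- lt_relation(data.frame(
    ligand = rep(c("a", "b"), each = 2), target = rep(c("x", "y"), 2),
    status = c("active", "inactive", "inactive", "inactive")))
  estf <- polypharm(full)
  expect_equal(estf$ci_low, estf$ci_low)
  expect_equal(estf$p_tilde_max, as.numeric(estf$p_min))
  expect_equal(estf$ci_low, as.numeric(estf$p_min))
  expect_equal(estf$ci_high, as.numeric(estf$p_min))
  expect_equal(estf$delta_e_max, c(0L, 0L))
})

test_that("fallback policy fills unmeasured ligands from the global rate", {
  rel <- lt_relation(data.frame(ligand = c("a", "a", "a", "a"),
                                target = paste0("t", 1:4),
                                status = c("active", rep("inactive", 3))),
                     ligands = c("a", "b"), targets = paste0("t", 1:4))
  est <- polypharm(rel, fallback = "global")
  b <- est[est$ligand == "b", ]
  expect_identical(b$p_hat_source, "global-fallback")
  expect_equal(b$p_hat, 0.25)
  # no-data CI spans the full [pmin, pmax] interval
  expect_equal(b$ci_low, 0)
  expect_equal(b$ci_high, 4)

  strict <- polypharm(rel, fallback = "strict")
  bs <- strict[strict$ligand == "b", ]
  expect_identical(bs$p_hat_source, "undefined")
  expect_true(is.na(bs$p_hat) && is.na(bs$p_tilde_max) && is.na(bs$ci_low))
})

test_that("interval orderings and error identities hold on random relations", {
  set.seed(202)
  for (i in 1:30) {
    rel <- random_relation(sample(2:15, 1), sample(2:25, 1),
                           probs = c(0.15, 0.45, 0.4))
    est <- polypharm(rel)
    ok <- !is.na(est$p_tilde_max)
    expect_true(all(est$p_min[ok] <= est$p_tilde_max[ok] + 1e-12))
    expect_true(all(est$p_tilde_max[ok] <= est$p_max[ok] + 1e-12))
    expect_true(all(est$ci_low[ok] <= est$p_tilde_max[ok] + 1e-12))
    expect_true(all(est$p_tilde_max[ok] <= est$ci_high[ok] + 1e-12))
    expect_true(all(est$ci_low[ok] >= est$p_min[ok] - 1e-12))
    expect_true(all(est$ci_high[ok] <= est$p_max[ok] + 1e-12))
    expect_identical(est$delta_e_max, est$p_max - est$p_min)
    expect_identical(est$delta_e_max, est$n_null)
    expect_identical(est$n_null,
                     ncol(rel) - est$n_active - est$n_inactive)
    expect_equal(est$delta_e_tilde[ok],
                 est$p_tilde_max[ok] - est$p_min[ok])
    expect_true(all(est$delta_e_tilde[ok] <= est$delta_e_max[ok] + 1e-12))
  }
})

test_that("measuring a null pair as inactive shrinks only the upper bound", {
  set.seed(31)
  rel <- random_relation(5, 10)
  codes <- unclass(rel)
  nulls <- which(codes == 3L, arr.ind = TRUE)
  cell <- nulls[sample(nrow(nulls), 1), ]
  codes[cell[1], cell[2]] <- 2L
  rel2 <- structure(codes, class = "lt_relation")
  lig <- rownames(codes)[cell[1]]
  before <- ligand_profile(rel, lig)
  after <- ligand_profile(rel2, lig)
  expect_identical(polypharm_min(after), polypharm_min(before))
  expect_identical(polypharm_max(after), polypharm_max(before) - 1L)
})

test_that("joint partition matches hand enumeration and transposes", {
  toy <- toy_example_relation()
  p1 <- ligand_profile(toy, "l1")
  p2 <- ligand_profile(toy, "l2")
  jp <- joint_partition(p1, p2)
  expected <- matrix(c(1L, 0L, 1L,
                       0L, 0L, 1L,
                       1L, 1L, 0L), 3, 3, byrow = TRUE,
                     dimnames = list(lt_states(), lt_states()))
  expect_identical(unclass(jp)[, ], expected)
  expect_identical(sum(jp), length(targets(toy)))
  expect_identical(unclass(joint_partition(p2, p1))[, ], t(expected))

  # self-pair: diagonal equals the ligand's own class sizes
  self <- joint_partition(p1, p1)
  expect_identical(diag(unclass(self)[, ]), c(active = 2L, inactive = 1L,
                                              null = 2L))
  expect_identical(sum(unclass(self)[, ] * (1L - diag(3L))), 0)
})

test_that("joint bounds, probabilities and estimates match hand enumeration", {
  toy <- toy_example_relation()
  jp <- joint_partition(ligand_profile(toy, "l1"),
                        ligand_profile(toy, "l2"))
  expect_identical(joint_polypharm_min(jp), 1L)
  expect_identical(joint_polypharm_max(jp), 3L)

  pj <- joint_prob_estimates(jp, "joint")
  expect_equal(as.numeric(pj), c(1, 1, 1))
  expect_equal(joint_polypharm_max_estimated(jp, pj), 3)

  pi <- joint_prob_estimates(jp, "independence", p_hat_a = 2 / 3,
                             p_hat_b = 2 / 3)
  expect_equal(as.numeric(pi), c(2 / 3, 2 / 3, 4 / 9))
  expect_equal(joint_polypharm_max_estimated(jp, pi), 7 / 3)

  expect_equal(joint_polypharm_max_estimated(jp, c(0, 0, 0)), 1)

  # self-pair reduces to the simple quantities
  self <- joint_partition(ligand_profile(toy, "l1"),
                          ligand_profile(toy, "l1"))
  expect_identical(joint_polypharm_min(self), 2L)
  expect_identical(joint_polypharm_max(self), 4L)
})

test_that("zero-count numerators and denominators are handled by flags", {
  rel <- lt_relation(data.frame(
    ligand = c("a", "a", "b", "b"), target = c("t1", "t2", "t1", "t2"),
    status = c("inactive", "active", "active", "inactive")),
    targets = c("t1", "t2", "t3"))
  jp <- joint_partition(ligand_profile(rel, "a"), ligand_profile(rel, "b"))
  pj <- joint_prob_estimates(jp, "joint")
  expect_equal(as.numeric(pj), c(0, 0, 0))

  # disjoint actives, no nulls: pmin = pmax = 0
  rel2 <- lt_relation(data.frame(
    ligand = c("a", "a", "b", "b"), target = c("t1", "t2", "t1", "t2"),
    status = c("active", "inactive", "inactive", "active")))
  jp2 <- joint_partition(ligand_profile(rel2, "a"), ligand_profile(rel2, "b"))
  expect_identical(joint_polypharm_min(jp2), 0L)
  expect_identical(joint_polypharm_max(jp2), 0L)

  # no doubly measured targets: joint-mode probabilities undefined
  rel3 <- lt_relation(data.frame(
    ligand = c("a", "b"), target = c("t1", "t2"),
    status = c("active", "active")), targets = c("t1", "t2", "t3"))
  jp3 <- joint_partition(ligand_profile(rel3, "a"), ligand_profile(rel3, "b"))
  pj3 <- joint_prob_estimates(jp3, "joint")
  expect_true(all(is.na(pj3)))
  expect_identical(attr(pj3, "source"), rep("undefined", 3))
  pj3f <- joint_prob_estimates(jp3, "joint", fallback = 0.1)
  expect_equal(as.numeric(pj3f), rep(0.1, 3))
  expect_error(joint_polypharm_max_estimated(jp3, pj3), "fallback")
})

test_that("joint report agrees with the naive oracle on small relations", {
  set.seed(77)
  for (i in 1:20) {
    rel <- random_relation(sample(2:6, 1), sample(1:6, 1))
    tr <- oracle_triples(rel)
    est <- joint_polypharm(rel, fallback = "strict")
    pairs <- ligand_pairs(rel)
    expect_identical(nrow(est), nrow(pairs))
    for (r in seq_len(nrow(est))) {
      counts <- oracle_joint_counts(tr, est$id1[r], est$id2[r])
      expect_identical(
        c(est$n_pp[r], est$n_pi[r], est$n_p0[r],
          est$n_ip[r], est$n_ii[r], est$n_i0[r],
          est$n_0p[r], est$n_0i[r], est$n_00[r]),
        as.vector(t(counts)))
      expect_identical(est$p_min[r], counts["active", "active"])
      expect_identical(est$p_max[r],
                       counts["active", "active"] + counts["active", "null"] +
                         counts["null", "active"] + counts["null", "null"])
      # joint pmin is bounded by both individual pmins
      expect_lte(est$p_min[r],
                 min(oracle_pmin(tr, est$id1[r]), oracle_pmin(tr, est$id2[r])))
    }
    ok <- !is.na(est$p_tilde_max_joint)
    expect_true(all(est$p_min[ok] <= est$p_tilde_max_joint[ok] + 1e-9))
    expect_true(all(est$p_tilde_max_joint[ok] <= est$p_max[ok] + 1e-9))
    ok2 <- !is.na(est$p_tilde_max_indep)
    expect_true(all(est$p_min[ok2] <= est$p_tilde_max_indep[ok2] + 1e-9))
    expect_true(all(est$p_tilde_max_indep[ok2] <= est$p_max[ok2] + 1e-9))
  }
})

test_that("pair enumeration is n(n-1)/2, ordered, with selector support", {
  ids <- sprintf("L%03d", 1:6)
  pairs <- ligand_pairs(ids)
  expect_identical(nrow(pairs), 15L)
  expect_true(all(match(pairs[, 1], ids) < match(pairs[, 2], ids)))
  one <- ligand_pairs(ids, ligand = "L003")
  expect_identical(nrow(one), 5L)
  expect_true(all(one[, 1] == "L003"))
  expect_error(ligand_pairs(ids, ligand = "L999"), "L999")
})

test_that("monte carlo joint CI is seeded, contained, and collapses", {
  toy <- toy_example_relation()
  jp <- joint_partition(ligand_profile(toy, "l1"),
                        ligand_profile(toy, "l2"))
  ci1 <- joint_ci(jp, mode = "joint", seed = 9, n_draws = 4000)
  ci2 <- joint_ci(jp, mode = "joint", seed = 9, n_draws = 4000)
  expect_identical(ci1, ci2)
  expect_gte(ci1[["low"]], joint_polypharm_min(jp))
  expect_lte(ci1[["high"]], joint_polypharm_max(jp))

  marg <- list(a = c(k = 2, n = 3), b = c(k = 2, n = 3))
  cii <- joint_ci(jp, mode = "independence", seed = 9, n_draws = 4000,
                  marginals = marg)
  est <- joint_polypharm_max_estimated(
    jp, joint_prob_estimates(jp, "independence", 2 / 3, 2 / 3))
  expect_gte(est, cii[["low"]] - 0.2)
  expect_lte(est, cii[["high"]] + 0.2)

  # convergence: doubling the draws moves endpoints only within MC noise
  ci4 <- joint_ci(jp, mode = "joint", seed = 9, n_draws = 8000)
  expect_equal(unname(ci1), unname(ci4), tolerance = 0.05)

  # no populated null cell: the interval is the point |S++|
  full <- lt_relation(data.frame(
    ligand = rep(c("a", "b"), each = 2), target = rep(c("x", "y"), 2),
    status = c("active", "active", "active", "inactive")))
  jpf <- joint_partition(ligand_profile(full, "a"), ligand_profile(full, "b"))
  expect_equal(unname(joint_ci(jpf, seed = 1)), c(1, 1))

  expect_error(joint_ci(jp, seed = 1, n_draws = 10), "1000")
  expect_error(joint_ci(jp, seed = 1, alpha = 0), "alpha")
  # RNG state of the caller is left untouched
  set.seed(123); before <- .Random.seed
  invisible(joint_ci(jp, mode = "joint", seed = 5))
  expect_identical(.Random.seed, before)
})
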