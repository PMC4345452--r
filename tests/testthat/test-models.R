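test_that("the dyad table carries relatedness, categories and needs", {
  cfg <- small_cfg(seed = 31)
  sim <- simulate_society(cfg)
  dy <- family_dyad_table(sim$ledger, sim$pedigree)
  fams <- unique(sim$pedigree$family_id)
  expect_equal(nrow(dy), choose(length(fams), 2))
  expect_true(all(dy$category %in% c("parent-offspring", "sibling",
                                     "other-kin", "non-kin")))
  k <- which(dy$r_fam > 0)[1]
  expect_equal(dy$r_fam[k],
               family_relatedness(sim$pedigree, dy$fam_i[k], dy$fam_j[k]))
  expect_true(all(dy$head_age_i >= dy$head_age_j))
  expect_false(anyNA(dy$need_i_estimated))
})

test_that("rank-deficient designs fail loudly, naming the constant term", {
  d <- simulate_dyadic_data(n_dyads = 200, seed = 1)$dyads
  d$r_fam <- 0.25
  expect_error(fit_family_interaction_model(d), "r_fam")
  d2 <- simulate_dyadic_data(n_dyads = 200, seed = 1)$dyads
  d2$need_i_estimated <- 1
  expect_error(fit_family_interaction_model(d2), "need_i_estimated")
})

test_that("the mixed model recovers known coefficients without bias", {
  est <- matrix(NA, 10, 5)
  truth <- c(r = 1, need_i = 0, need_j = 0, `r:need_i` = -1.5,
             `r:need_j` = 0.6)
  for (k in 1:10) {
    g <- simulate_dyadic_data(n_dyads = 3000, seed = 400 + k)
    fit <- fit_family_interaction_model(g$dyads, "estimated", scale = FALSE)
    cf <- fit$coefficients
    est[k, ] <- cf$B[match(names(truth), cf$term)]
    expect_true(fit$converged)
    expect_equal(fit$n, 3000)
  }
  bias <- colMeans(est) - truth
  # Monte-Carlo tolerance at 10 replicates
  expect_true(all(abs(bias) < 0.15),
              info = paste(round(bias, 3), collapse = ", "))
})

test_that("need-directed but kin-blind sharing yields main effects only", {
  hits_main <- 0; hits_int <- 0
  for (sd in 41:42) {
    cfg <- society_config(n_communities = 2, families_per_community = 20,
                          study_days = 60, seed = sd)
    sim <- simulate_society(cfg, policy = transfer_policy(mode = "need_only"))
    dy <- family_dyad_table(sim$ledger, sim$pedigree)
    fit <- fit_family_interaction_model(dy, "estimated")
    cf <- fit$coefficients
    ni <- cf[cf$term == "need_i"]; nj <- cf[cf$term == "need_j"]
    if (ni$B < 0 && ni$p < 0.05 && nj$B > 0 && nj$p < 0.05)
      hits_main <- hits_main + 1
    ii <- cf[cf$term == "r:need_i"]; jj <- cf[cf$term == "r:need_j"]
    if (ii$p > 0.05 && jj$p > 0.05) hits_int <- hits_int + 1
  }
  expect_equal(hits_main, 2)  # charity: flows track need everywhere
  expect_equal(hits_int, 2)   # but nothing interacts with relatedness
})

test_that("per-category models report means and need slopes", {
  cfg <- society_config(n_communities = 2, families_per_community = 20,
                        study_days = 60, seed = 43)
  sim <- simulate_society(cfg)
  dy <- family_dyad_table(sim$ledger, sim$pedigree)
  rel <- fit_by_relationship(dy)
  expect_equal(rel$category, c("parent-offspring", "sibling", "other-kin",
                               "non-kin"))
  expect_equal(rel$n, as.vector(table(dy$category)[rel$category]))
  # downward parental flows respond to both sides' needs as predicted
  po <- rel[rel$category == "parent-offspring"]
  expect_gt(po$mean, 0)
  expect_lt(po$beta_i_estimated, 0)
  expect_gt(po$beta_j_estimated, 0)
  # unknown labels are rejected
  bad <- copy(dy)[1, category := "step-kin"]
  expect_error(fit_by_relationship(bad), "unknown category")
})

test_that("age profiles are zero for a transfer-free ledger and sign-flip", {
  ped <- three_gen_ped()
  persons <- data.frame(id = ped$id, family_id = ped$family_id,
                        community_id = ped$community_id)
  rec <- data.frame(day = 1, type = "meal-portion", producer_id = ped$id,
                    recipient_id = ped$id, kcal = 2000)  # self-consumption only
  led <- manual_ledger(rec, persons, study_days = 1)
  nt <- individual_net_matrix(led)
  prof <- fit_age_profiles(nt, ped, "children")
  expect_true(all(prof$mean == 0))
  # direction reversal negates estimates
  cfg <- small_cfg(seed = 44)
  sim <- simulate_society(cfg)
  nts <- individual_net_matrix(sim$ledger)
  a <- fit_age_profiles(nts, sim$pedigree, "children", "from_focal")
  b <- fit_age_profiles(nts, sim$pedigree, "children", "to_focal")
  m <- merge(a, b, by = c("sex", "age_bin"))
  expect_equal(m$mean.x, -m$mean.y, tolerance = 1e-6)
})

test_that("simulated parents provision children with a juvenile receipt peak", {
  cfg <- society_config(seed = 45)
  sim <- simulate_society(cfg)
  nt <- individual_net_matrix(sim$ledger)
  pc <- fit_age_profiles(nt, sim$pedigree, "children", "from_focal")
  expect_gt(pc[pc$sex == "M" & pc$age_bin == "all"]$mean, 0)
  expect_gt(pc[pc$sex == "F" & pc$age_bin == "all"]$mean, 0)
  gg <- fit_age_profiles(nt, sim$pedigree, "grandchildren", "from_focal")
  expect_gt(gg[gg$sex == "M" & gg$age_bin == "all"]$mean, 0)
  # fathers' transfers to children largest in the prime-productivity decades
  pcd <- fit_age_profiles(nt, sim$pedigree, "children", "from_focal",
                          breaks = seq(0, 100, 10))
  m30s <- pcd[pcd$sex == "M" & pcd$age_bin == "[30,40)"]$mean
  expect_gt(m30s, pcd[pcd$sex == "M" & pcd$age_bin == "all"]$mean)
  # offspring receipts from parents peak before adulthood
  rp <- fit_age_profiles(nt, sim$pedigree, "parents", "to_focal")
  peaks <- rp[rp$age_bin != "all" & rp$n >= 3]
  peak_bin <- peaks$age_bin[which.max(peaks$mean)]
  expect_lt(as.integer(sub("\\[(\\d+),.*", "\\1", peak_bin)), 18)
})
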