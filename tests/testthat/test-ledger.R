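# two single-adult families in one community, used in several tests
two_person_roster <- function() {
  list(ped = pedigree(data.frame(
         id = 1:2, sex = c("M", "F"), birth_year = c(1960, 1965),
         mother_id = NA, father_id = NA, spouse_id = NA,
         family_id = c(1, 2), community_id = 1), ref_year = 2000),
       persons = data.frame(id = 1:2, family_id = c(1, 2), community_id = 1))
}

test_that("net transfers divide by jointly observed days", {
  tp <- two_person_roster()
  rec <- data.frame(day = c(1, 1), type = c("production", "raw-gift"),
                    producer_id = 1L, recipient_id = c(NA, 2L),
                    kcal = c(1000, 1000))
  led <- manual_ledger(rec, tp$persons, study_days = 2)
  nt <- individual_net_matrix(led)
  expect_equal(nt_value(nt, 1, 2), 500)
  expect_equal(nt_value(nt, 2, 1), -500)
  M <- as.matrix(nt)
  expect_equal(M["1", "2"], 500)
  expect_equal(M + t(M), matrix(0, 2, 2, dimnames = dimnames(M)))
})

test_that("perfectly reciprocal flows net to zero", {
  tp <- two_person_roster()
  rec <- data.frame(day = c(1, 2), type = "raw-gift",
                    producer_id = c(1L, 2L), recipient_id = c(2L, 1L),
                    kcal = 800)
  led <- manual_ledger(rec, tp$persons, study_days = 2)
  nt <- individual_net_matrix(led)
  expect_equal(nt_value(nt, 1, 2), 0)
})

test_that("equal meal portions attribute a dish to its eaters", {
  persons <- data.frame(id = 1:3, family_id = 1, community_id = 1)
  rec <- data.frame(day = 1, type = "meal-portion", producer_id = 1L,
                    recipient_id = 1:3, kcal = 400)
  led <- manual_ledger(rec, persons, study_days = 1)
  nt <- individual_net_matrix(led)
  expect_equal(nt_value(nt, 1, 2), 400)
  expect_equal(nt_value(nt, 1, 3), 400)
  expect_equal(nt_value(nt, 2, 3), 0)
})

test_that("ledger validation catches inconsistent input", {
  persons <- data.frame(id = 1:2, family_id = 1:2, community_id = 1)
  good <- data.frame(day = 1, type = "raw-gift", producer_id = 1L,
                     recipient_id = 2L, kcal = 10)
  expect_error(manual_ledger(transform(good, kcal = -5), persons, 1),
               "non-negative")
  expect_error(manual_ledger(transform(good, recipient_id = 1L), persons, 1),
               "producer != recipient")
  expect_error(manual_ledger(transform(good, day = 5), persons, 1),
               "study window")
  expect_error(manual_ledger(transform(good, recipient_id = 9L), persons, 1),
               "missing from the roster")
  # records for a person whose family was never observed
  led <- sharing_ledger(good,
                        data.frame(family_id = 1L, day = 1L),
                        persons, 1)
  expect_error(individual_net_matrix(led), "zero observed days")
})

test_that("matrices are antisymmetric and conserve within communities", {
  worst <- 0
  for (seed in 1:30) {
    led <- random_test_ledger(seed)
    nt <- individual_net_matrix(led)
    M <- as.matrix(nt)
    worst <- max(worst, max(abs(M + t(M))))
    per <- led$persons
    ntf <- suppressMessages(family_net_matrix(nt, ledger_ped(led)))
    Mf <- as.matrix(ntf)
    worst <- max(worst, max(abs(Mf + t(Mf))))
    for (com in unique(per$community_id)) {
      ids <- as.character(per$id[per$community_id == com])
      worst <- max(worst, abs(sum(M[ids, ids])))
      fams <- as.character(unique(per$family_id[per$community_id == com]))
      fams <- fams[fams %in% rownames(Mf)]
      if (length(fams) < 2) next
      worst <- max(worst, abs(sum(Mf[fams, fams])))
      for (a in fams) for (b in fams) {
        if (a >= b) next
        pa <- as.character(per$id[per$family_id == as.integer(a)])
        pb <- as.character(per$id[per$family_id == as.integer(b)])
        worst <- max(worst,
                     abs(sum(M[pa, pb, drop = FALSE]) -
                           nt_value(ntf, as.integer(a), as.integer(b))))
      }
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("category sums are additive and sign-reverse with direction", {
  ped <- three_gen_ped()
  persons <- data.frame(id = ped$id, family_id = ped$family_id,
                        community_id = ped$community_id)
  # grandfather 1 gives grandchild 5 two gifts; no other flows
  rec <- data.frame(day = c(1, 1), type = "raw-gift", producer_id = 1L,
                    recipient_id = 5L, kcal = c(100, 237))
  led <- manual_ledger(rec, persons, study_days = 1)
  nt <- individual_net_matrix(led)
  expect_equal(focal_category_sum(nt, ped, 1, "grandchildren"), 337)
  expect_equal(focal_category_sum(nt, ped, 1, "grandchildren",
                                  direction = "to_focal"), -337)
  expect_equal(focal_category_sum(nt, ped, 5, "grandparents",
                                  direction = "to_focal"), 337)
  expect_equal(focal_category_sum(nt, ped, 1, "children"), 0)
  expect_error(focal_category_sum(nt, ped, 1, "cousins"), "unknown")
  # focal with no alters in the category
  expect_equal(focal_category_sum(nt, ped, 5, "children"), 0)
})

test_that("kin alter sets cover the in-law relations", {
  ped <- three_gen_ped()
  expect_setequal(kin_alters(ped, 1, "children"), c(3, 4))
  expect_setequal(kin_alters(ped, 1, "children-in-law"), c(6, 7))
  expect_setequal(kin_alters(ped, 6, "parents-in-law"), c(1, 2))
  expect_setequal(kin_alters(ped, 5, "grandparents"), c(1, 2))
  expect_equal(kin_alters(ped, 1, "parents"), integer(0))
})

test_that("noise-free daily-sampled output reproduces true flows exactly", {
  cfg <- society_config(n_communities = 1, families_per_community = 6,
                        study_days = 10, interviews_per_week = 7 * 400,
                        recall_days = 1, reporting_cv = 0, seed = 11)
  sim <- simulate_society(cfg)
  cov_days <- sort(unique(sim$ledger$coverage$day))
  nt <- individual_net_matrix(sim$ledger)
  ntf <- suppressMessages(family_net_matrix(nt, sim$pedigree))
  g <- sim$truth$gifts[day %in% cov_days]
  g[, `:=`(a = pmin(fam_from, fam_to), b = pmax(fam_from, fam_to),
           signed = fifelse(fam_from < fam_to, kcal, -kcal))]
  truth <- g[, .(rate = sum(signed) / length(cov_days)), by = .(a, b)]
  for (k in seq_len(nrow(truth)))
    expect_equal(nt_value(ntf, truth$a[k], truth$b[k]), truth$rate[k],
                 tolerance = 1e-6)
})

test_that("family matrix orients older household to younger", {
  ped <- pedigree(data.frame(
    id = 1:2, sex = c("M", "M"), birth_year = c(1940, 1970),
    mother_id = NA, father_id = NA, spouse_id = NA,
    family_id = c(1, 2), community_id = 1), ref_year = 2000)
  persons <- data.frame(id = 1:2, family_id = 1:2, community_id = 1)
  rec <- data.frame(day = 1, type = "raw-gift", producer_id = 2L,
                    recipient_id = 1L, kcal = 100)
  led <- manual_ledger(rec, persons, study_days = 1)
  nt <- individual_net_matrix(led)
  ntf <- family_net_matrix(nt, ped)
  # row family is the 60-year-old's; upward flow appears negative
  expect_equal(ntf$fam_i, 1L)
  expect_equal(ntf$fam_j, 2L)
  expect_equal(ntf$kcal_day, -100)
  expect_equal(ntf$head_age_i, 60)
  # two one-person families: family net equals person net
  expect_equal(ntf$kcal_day, nt_value(nt, 1, 2))
  # age tie breaks to the smaller family id, with a message
  ped2 <- pedigree(data.frame(
    id = 1:2, sex = c("M", "M"), birth_year = 1950,
    mother_id = NA, father_id = NA, spouse_id = NA,
    family_id = c(2, 1), community_id = 1), ref_year = 2000)
  expect_message(ntf2 <- family_net_matrix(nt, ped2), "tied head ages")
  expect_equal(ntf2$fam_i, 1L)
})

test_that("net production profiles bin correctly and handle empty data", {
  tp <- two_person_roster()
  rec <- data.frame(day = 1, type = c("production", "meal-portion"),
                    producer_id = 1L, recipient_id = c(NA, 1L),
                    kcal = c(3000, 2000))
  led <- manual_ledger(rec, tp$persons, study_days = 1)
  prof <- net_production_profile(led, tp$ped, "individual",
                                 breaks = seq(0, 100, 10))
  row <- prof[prof$age_bin == "[40,50)"]
  expect_equal(row$mean, 1000)  # person 1, age 40: 3000 produced, 2000 eaten
  # all-zero ledger: all bins zero
  rec0 <- transform(rec, kcal = 0)
  led0 <- manual_ledger(rec0, tp$persons, study_days = 1)
  prof0 <- net_production_profile(led0, tp$ped, "individual")
  expect_true(all(prof0$mean == 0))
})

test_that("ledgers and matrices round-trip through files", {
  cfg <- small_cfg(seed = 12)
  sim <- simulate_society(cfg)
  rp <- tempfile(fileext = ".tsv"); cp <- tempfile(fileext = ".tsv")
  write_ledger(sim$ledger, rp, cp)
  led2 <- read_ledger(rp, cp, sim$pedigree, study_days = cfg$study_days)
  expect_equal(led2$records$kcal, sim$ledger$records$kcal)
  expect_equal(led2$days_observed, sim$ledger$days_observed)
  nt <- individual_net_matrix(sim$ledger)
  nt2 <- individual_net_matrix(led2)
  expect_equal(as.matrix(nt), as.matrix(nt2))
  np <- tempfile(fileext = ".tsv")
  write_net_matrix(nt, np)
  back <- fread(np, sep = "\t")
  expect_equal(back$kcal_day, nt$kcal_day)
  expect_equal(unique(back$level), "individual")
})
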