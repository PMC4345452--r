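library(data.table)

# Founder couple (1, 2), their married son 3 (wife 6, child 5) and married
# daughter 4 (husband 7). Three nuclear families in one community.
three_gen_ped <- function() {
  pedigree(data.frame(
    id = 1:7,
    sex = c("M", "F", "M", "F", "M", "F", "M"),
    birth_year = c(1940, 1945, 1970, 1972, 1995, 1974, 1996),
    mother_id = c(NA, NA, 2, 2, 6, NA, NA),
    father_id = c(NA, NA, 1, 1, 3, NA, NA),
    spouse_id = c(2, 1, 6, 7, NA, 3, 4),
    family_id = c(1, 1, 2, 3, 2, 2, 3),
    community_id = 1))
}

# Textbook constellation: grandparents, two full brothers with wives,
# their children (first cousins), and a half-sibling via a remarried widower.
textbook_ped <- function() {
  pedigree(data.frame(
    id = 1:12,
    sex = c("M", "F", "M", "M", "F", "F", "M", "F", "F", "M", "F", "M"),
    birth_year = c(1930, 1932, 1955, 1958, 1957, 1960, 1980, 1982,
                   1985, 1990, 1962, 1992),
    #            gf   gm   bro1 bro2 w1   w2   c1   c2   halfsib  w3
    mother_id = c(NA, NA, 2, 2, NA, NA, 5, 6, 5, 11, NA, 6),
    father_id = c(NA, NA, 1, 1, NA, NA, 3, 4, 3, 3, NA, 4),
    spouse_id = c(2, 1, 5, 6, 3, 4, NA, NA, NA, NA, NA, NA),
    family_id = c(1, 1, 2, 3, 2, 3, 2, 3, 2, 2, 4, 3),
    community_id = 1))
}

# Random pedigree generator independent of the package simulator: builds a
# layered structure where each non-founder draws parents from couples formed
# in the previous layer.
random_test_pedigree <- function(seed, n_target = 25) {
  set.seed(seed)
  rows <- list()
  nid <- 0L
  new_person <- function(sex, by, mo = NA, fa = NA) {
    nid <<- nid + 1L
    rows[[nid]] <<- data.frame(id = nid, sex = sex, birth_year = by,
                               mother_id = mo, father_id = fa,
                               spouse_id = NA_integer_,
                               family_id = nid, community_id = 1L)
    nid
  }
  n_founder_couples <- sample(3:5, 1)
  couples <- list()
  for (k in seq_len(n_founder_couples)) {
    m <- new_person("M", 1940); f <- new_person("F", 1942)
    couples[[k]] <- c(m, f)
  }
  layer_year <- 1965
  while (nid < n_target) {
    n_children <- sample(1:3, 1)
    par <- couples[[sample(length(couples), 1)]]
    kids <- replicate(n_children,
      new_person(sample(c("M", "F"), 1), layer_year, mo = par[2], fa = par[1]))
    # some children pair with new unrelated mates and found new couples
    for (kid in kids) {
      if (runif(1) < 0.6 && nid < n_target) {
        kid_sex <- rows[[kid]]$sex
        mate <- new_person(if (kid_sex == "M") "F" else "M", layer_year)
        couples[[length(couples) + 1]] <-
          if (kid_sex == "M") c(kid, mate) else c(mate, kid)
      }
    }
    layer_year <- layer_year + sample(18:25, 1)
  }
  df <- do.call(rbind, rows)
  # group into a few families/communities so the pedigree validates
  df$family_id <- (df$id %% 5L) + 1L
  df$community_id <- 1L
  pedigree(df)
}

# Manual sharing ledger: full coverage of every family over study_days.
manual_ledger <- function(records, persons, study_days) {
  coverage <- CJ(family_id = unique(persons$family_id),
                 day = seq_len(study_days))
  sharing_ledger(as.data.table(records), coverage,
                 as.data.table(persons), study_days)
}

# Random small society ledger for conservation property tests: random
# families/communities and random gift/meal/production records.
random_test_ledger <- function(seed) {
  set.seed(seed)
  n <- sample(10:24, 1)
  n_fam <- sample(3:6, 1)
  persons <- data.table(id = seq_len(n),
                        family_id = sample(n_fam, n, replace = TRUE),
                        community_id = sample(2, n, replace = TRUE))
  # community must be constant within family
  fam_com <- sample(2, n_fam, replace = TRUE)
  persons[, community_id := fam_com[family_id]]
  D <- sample(3:8, 1)
  n_rec <- sample(30:120, 1)
  prod <- data.table(day = sample(D, n_rec, TRUE), type = "production",
                     producer_id = sample(n, n_rec, TRUE),
                     recipient_id = NA_integer_,
                     kcal = runif(n_rec, 0, 3000))
  pr <- sample(n, n_rec, TRUE)
  re <- sample(n, n_rec, TRUE)
  portions <- data.table(day = sample(D, n_rec, TRUE),
                         type = ifelse(pr == re, "meal-portion",
                                       sample(c("meal-portion", "raw-gift"),
                                              n_rec, TRUE)),
                         producer_id = pr, recipient_id = re,
                         kcal = runif(n_rec, 0, 2000))
  manual_ledger(rbind(prod, portions), persons, D)
}

small_cfg <- function(seed = 1, ...) {
  society_config(n_communities = 1, families_per_community = 10,
                 study_days = 30, seed = seed, ...)
}

# minimal all-founder pedigree matching a ledger's person roster (distinct
# adult ages so family orientation is unambiguous)
ledger_ped <- function(led) {
  per <- led$persons
  pedigree(data.frame(id = per$id, sex = "M",
                      birth_year = 1900 + per$id,
                      mother_id = NA, father_id = NA, spouse_id = NA,
                      family_id = per$family_id,
                      community_id = per$community_id),
           ref_year = 2000)
}
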