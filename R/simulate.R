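# Synthetic-society simulator: pedigree demography, daily production,
# Hamilton-rule transfer allocation, and interview-style ledger emission.

#' Simulate a multi-generation pedigree
#'
#' Communities are assembled from patrilineages: a founder grandparent couple
#' (ages ~63-75), their adult children who marry in spouses from outside the
#' pedigree and head their own nuclear families with dependent children, and
#' grandchildren old enough to have founded young families of their own.
#' Unmarried children remain in the natal family. Lineages within a community
#' are mutually unrelated, so communities contain parent-offspring, sibling,
#' other-kin and non-kin family dyads. Marriages are exogamous, hence
#' non-incestuous and non-inbreeding.
#'
#' @param cfg a [society_config()]
#' @return a validated [pedigree()]
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "society_config"))
  seeds <- derive_seeds(cfg$seed)
  set.seed(seeds[["demography"]])
  rows <- vector("list", 0L)
  counter <- new.env()
  counter$id <- 0L
  counter$fam <- 0L
  for (com in seq_len(cfg$n_communities)) {
    fams <- 0L
    while (fams < cfg$families_per_community) {
      lin <- build_lineage(cfg, com, counter)
      rows[[length(rows) + 1L]] <- lin$rows
      fams <- fams + lin$n_families
    }
  }
  df <- rbindlist(rows)
  df[, birth_year := cfg$ref_year - age]
  df[, age := NULL]
  pedigree(df, ref_year = cfg$ref_year)
}

# ages of a mother's surviving children: Poisson count prorated by the lived
# fraction of the reproductive window (first_birth_age .. 45), birth times
# uniform over that window
child_ages_for <- function(mother_age, cfg, max_n = 10L) {
  window <- 45 - cfg$first_birth_age
  span <- max(0, min(mother_age, 45) - cfg$first_birth_age)
  if (span <= 0) return(numeric(0))
  n <- min(max_n, rpois(1, cfg$fertility_mean * span / window))
  if (n == 0L) return(numeric(0))
  birth_ages <- runif(n, cfg$first_birth_age, min(mother_age, 45))
  sort(mother_age - birth_ages, decreasing = TRUE)
}

# One lineage: grandparent couple, married children's families, and
# grandchild-headed families. Returns person rows (with current age).
build_lineage <- function(cfg, com, counter) {
  persons <- list()
  new_id <- function() (counter$id <- counter$id + 1L)
  new_fam <- function() (counter$fam <- counter$fam + 1L)
  add <- function(sex, age, mother = NA_integer_, father = NA_integer_,
                  spouse = NA_integer_, fam, com_) {
    id <- new_id()
    persons[[length(persons) + 1L]] <<- data.table(
      id = id, sex = sex, age = as.integer(round(age)),
      mother_id = mother, father_id = father, spouse_id = spouse,
      family_id = fam, community_id = com_)
    id
  }
  link_spouses <- function(a, b) {
    for (p in seq_along(persons)) {
      if (persons[[p]]$id == a) persons[[p]]$spouse_id <- b
      if (persons[[p]]$id == b) persons[[p]]$spouse_id <- a
    }
  }
  n_fam <- 0L

  fam0 <- new_fam(); n_fam <- n_fam + 1L
  gf_age <- runif(1, 63, 75)
  gm_age <- max(40, gf_age - runif(1, 0, 8))
  gf <- add("M", gf_age, fam = fam0, com_ = com)
  gm <- add("F", gm_age, fam = fam0, com_ = com)
  link_spouses(gf, gm)

  # couple's children, spread over the grandmother's reproductive window;
  # women marry out of the natal household earlier than men
  for (ca in child_ages_for(gm_age, cfg)) {
    csex <- if (runif(1) < 0.5) "F" else "M"
    m_age <- if (csex == "F") cfg$marriage_age - 3 else cfg$marriage_age
    married <- ca >= m_age && runif(1) < cfg$marriage_prob
    if (!married) {
      add(csex, ca, mother = gm, father = gf, fam = fam0, com_ = com)
      next
    }
    famc <- new_fam(); n_fam <- n_fam + 1L
    child <- add(csex, ca, mother = gm, father = gf, fam = famc, com_ = com)
    if (csex == "M") {
      w_age <- max(18, ca - runif(1, 0, 6))
      spouse <- add("F", w_age, fam = famc, com_ = com)
      mother_age <- w_age; mo <- spouse; fa <- child
    } else {
      h_age <- max(18, ca + runif(1, 0, 6))
      spouse <- add("M", h_age, fam = famc, com_ = com)
      mother_age <- ca; mo <- child; fa <- spouse
    }
    link_spouses(child, spouse)
    # grandchildren of the founder couple
    for (ga in child_ages_for(mother_age, cfg)) {
      gsex <- if (runif(1) < 0.5) "F" else "M"
      gm_min <- if (gsex == "F") cfg$marriage_age - 2 else cfg$marriage_age + 2
      gmarried <- ga >= gm_min && runif(1) < 0.75
      if (!gmarried) {
        add(gsex, ga, mother = mo, father = fa, fam = famc, com_ = com)
      } else {
        famg <- new_fam(); n_fam <- n_fam + 1L
        gk <- add(gsex, ga, mother = mo, father = fa, fam = famg, com_ = com)
        if (gsex == "M") {
          wa <- max(18, ga - runif(1, 0, 4))
          gsp <- add("F", wa, fam = famg, com_ = com)
          gmo <- gsp; gfa <- gk; ma <- wa
        } else {
          ha <- max(18, ga + runif(1, 0, 4))
          gsp <- add("M", ha, fam = famg, com_ = com)
          gmo <- gk; gfa <- gsp; ma <- ga
        }
        link_spouses(gk, gsp)
        for (ba in child_ages_for(ma, cfg, max_n = 4L))
          add(if (runif(1) < 0.5) "F" else "M", ba,
              mother = gmo, father = gfa, fam = famg, com_ = com)
      }
    }
  }
  list(rows = rbindlist(persons), n_families = n_fam)
}

#' Hamilton-rule transfer allocation among agents
#'
#' Given each agent's available calories, pairwise relatedness weights and a
#' concave-utility [transfer_policy()], gifts flow from donor i to recipient j
#' while r_ij * u'(c_j / w_j) > u'(c_i / w_i), i.e. while the r-devalued
#' marginal benefit to the recipient exceeds the donor's marginal cost
#' (b r > c at the margin). Each gift event moves the currently
#' highest-gain pair to its first-order-condition optimum, which for
#' isoelastic utility is t = (c_i - K c_j) / (1 + K) with
#' K = r^(-1/curvature) * w_i / w_j; gifts smaller than the policy's
#' granularity are not made. Calories are conserved.
#'
#' Agents can be individuals or (pooled) families; \code{weights} are
#' consumption requirements, so marginal utility is evaluated on consumption
#' relative to requirement.
#'
#' @param available numeric vector of calories available to each agent
#' @param r pairwise relatedness: scalar (applied to all pairs) or symmetric
#'   matrix
#' @param weights consumption-requirement weights (default all 1)
#' @param policy a [transfer_policy()]
#' @param max_events safety cap on gift events
#' @return list with \code{transfers} (matrix, entry \[i, j\] = kcal moved
#'   from i to j) and \code{consumed} (final calories per agent)
#' @export
hamilton_transfers <- function(available, r, weights = NULL,
                               policy = transfer_policy(),
                               max_events = NULL) {
  n <- length(available)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0), all(available >= 0))
  if (length(r) == 1L) {
    r <- matrix(r, n, n); diag(r) <- 0
  }
  stopifnot(is.matrix(r), nrow(r) == n, ncol(r) == n)
  eta <- policy$curvature
  gran <- policy$gift_granularity
  if (is.null(max_events)) max_events <- 50L * n * n + 100L
  Tm <- matrix(0, n, n)
  idx <- which(r > 0 & row(r) != col(r))
  if (!length(idx))
    return(list(transfers = Tm, consumed = available))
  pi <- row(r)[idx]; pj <- col(r)[idx]
  rp <- r[idx]
  K <- rp^(-1 / eta) * weights[pi] / weights[pj]
  cons <- available
  for (it in seq_len(max_events)) {
    tcand <- (cons[pi] - K * cons[pj]) / (1 + K)
    ok <- tcand >= gran
    if (!any(ok)) break
    mu <- (pmax(cons, 1e-12) / weights)^(-eta)
    gain <- rp * mu[pj] - mu[pi]
    gain[!ok] <- -Inf
    b <- which.max(gain)
    t <- tcand[b]
    i <- pi[b]; j <- pj[b]
    Tm[i, j] <- Tm[i, j] + t
    cons[i] <- cons[i] - t
    cons[j] <- cons[j] + t
  }
  list(transfers = Tm, consumed = cons)
}

# Daily production matrix (persons x days) plus consumption requirements.
simulate_production <- function(ped, schedule, cfg) {
  seeds <- derive_seeds(cfg$seed)
  set.seed(seeds[["production"]])
  n <- nrow(ped)
  D <- cfg$study_days
  age <- ped_age(ped)
  mu <- production_mean(schedule, age, ped$sex)
  req <- consumption_mean(schedule, age, ped$sex)
  scale <- mu / 2500  # noise scales with productive capacity (2500 = ref adult)
  fam <- as.factor(ped$family_id)
  fam_eff <- rnorm(nlevels(fam), 0, schedule$production_sd_family)[as.integer(fam)]
  if (D == 0L)
    return(list(production = matrix(0, n, 0), requirement = req))
  eps <- matrix(rnorm(n * D, 0, schedule$production_sd_day), n, D)
  prod <- pmax(mu + scale * (fam_eff + eps), 0)
  list(production = prod, requirement = req)
}

#' Allocate one day's transfers across a society
#'
#' Pools production within nuclear families, then moves calories between
#' co-resident families according to the policy: under \code{kin_need},
#' Hamilton allocation over each connected kin component (families linked by
#' mean relatedness > 0); under \code{need_only}, Hamilton allocation over all
#' co-resident families at the constant \code{social_weight}; under
#' \code{need_blind}, random kin- and need-blind gifting. Total calories are
#' conserved.
#'
#' @param ped pedigree
#' @param production per-person gross production for the day (kcal)
#' @param requirement per-person consumption requirement (kcal)
#' @param policy a [transfer_policy()]
#' @param fam_r optional precomputed allocation-weight matrix, by default the
#'   head-to-head [head_relatedness_matrix()]
#' @return list with \code{gifts} (data.table: fam_from, fam_to, kcal) and
#'   \code{family_consumed} (named vector of family availability totals)
#' @export
allocate_transfers <- function(ped, production, requirement,
                               policy = transfer_policy(), fam_r = NULL) {
  stopifnot(length(production) == nrow(ped),
            length(requirement) == nrow(ped))
  if (is.null(fam_r)) fam_r <- head_relatedness_matrix(ped)
  fam <- as.factor(ped$family_id)
  P <- rowsum(production, fam)[, 1]
  R <- rowsum(requirement, fam)[, 1]
  fam_ids <- as.integer(levels(fam))
  fam_com <- ped$community_id[match(as.integer(levels(fam)), ped$family_id)]
  st <- alloc_state(fam_ids, fam_com, fam_r, R, policy,
                    head_age = family_head_ages(ped, fam_ids))
  res <- alloc_day(P, st, policy)
  list(gifts = data.table(fam_from = res$fam_from, fam_to = res$fam_to,
                          kcal = res$kcal),
       family_consumed = setNames(res$consumed, fam_ids))
}

# oldest core adult per family
family_head_ages <- function(ped, fam_ids) {
  vapply(fam_ids, function(f)
    max(ped_age(ped)[match(family_heads(ped, f), ped$id)]), numeric(1))
}

# Static allocation state reused across days: per-community kin components
# (or whole communities), pair index sets, K constants. Under kin_need the
# pair weight is head relatedness times the life-history benefit bias
# exp(slope x (head_age_donor - head_age_recipient)).
alloc_state <- function(fam_ids, fam_com, fam_r, R, policy, head_age = NULL) {
  eta <- policy$curvature
  if (is.null(head_age)) head_age <- rep(0, length(fam_ids))
  comps <- list()
  for (com in unique(fam_com)) {
    members <- which(fam_com == com)
    if (length(members) < 2) next
    if (policy$mode == "need_only") {
      groups <- list(members)
      wmat <- matrix(policy$social_weight, length(fam_ids), length(fam_ids))
      diag(wmat) <- 0
    } else {
      adj <- fam_r[members, members, drop = FALSE] > 0
      adj[is.na(adj)] <- FALSE
      lab <- components_labels(adj)
      groups <- split(members, lab)
      groups <- groups[lengths(groups) >= 2]
      # benefit premium saturates after ~one generation of age difference
      d <- policy$benefit_age_slope
      da <- pmax(pmin(outer(head_age, head_age, "-"), 30), -30)
      wmat <- fam_r * exp(d * da)
    }
    for (g in groups) {
      sub <- wmat[g, g, drop = FALSE]
      diag(sub) <- 0
      idx <- which(sub > 0)
      if (!length(idx)) next
      pi <- row(sub)[idx]; pj <- col(sub)[idx]
      comps[[length(comps) + 1L]] <- list(
        members = g,
        pi = pi, pj = pj, rp = sub[idx],
        K = sub[idx]^(-1 / eta) * R[g][pi] / R[g][pj])
    }
  }
  list(fam_ids = fam_ids, fam_com = fam_com, R = R, comps = comps)
}

# One day of between-family allocation given pooled family production P.
# Returns plain vectors (fam_from, fam_to, kcal) for speed; callers assemble
# data.tables once per run.
alloc_day <- function(P, st, policy) {
  cons <- P
  gf <- integer(0); gt <- integer(0); gk <- numeric(0)
  if (policy$mode == "need_blind") {
    givers <- which(runif(length(P)) < policy$give_prob & P > 0)
    for (i in givers) {
      others <- which(st$fam_com == st$fam_com[i])
      others <- others[others != i]
      if (!length(others)) next
      j <- if (length(others) == 1L) others else sample(others, 1L)
      # fixed-scale random amount so the null is blind to productivity too
      amt <- min(cons[i], policy$give_kcal_scale *
                   rlnorm(1, 0, policy$give_frac_sd))
      if (amt < policy$gift_granularity) next
      cons[i] <- cons[i] - amt
      cons[j] <- cons[j] + amt
      gf <- c(gf, st$fam_ids[i]); gt <- c(gt, st$fam_ids[j])
      gk <- c(gk, amt)
    }
  } else {
    eta <- policy$curvature
    gran <- policy$gift_granularity
    for (cp in st$comps) {
      g <- cp$members
      cg <- cons[g]
      w <- st$R[g]
      pi <- cp$pi; pj <- cp$pj; K <- cp$K; rp <- cp$rp
      Tacc <- numeric(length(pi))
      for (it in seq_len(200L + 20L * length(pi))) {
        tcand <- (cg[pi] - K * cg[pj]) / (1 + K)
        ok <- tcand >= gran
        if (!any(ok)) break
        mu <- (pmax(cg, 1e-12) / w)^(-eta)
        gain <- rp * mu[pj] - mu[pi]
        gain[!ok] <- -Inf
        b <- which.max(gain)
        t <- tcand[b]
        Tacc[b] <- Tacc[b] + t
        cg[pi[b]] <- cg[pi[b]] - t
        cg[pj[b]] <- cg[pj[b]] + t
      }
      cons[g] <- cg
      nz <- which(Tacc > 0)
      if (length(nz)) {
        gf <- c(gf, st$fam_ids[g][pi[nz]])
        gt <- c(gt, st$fam_ids[g][pj[nz]])
        gk <- c(gk, Tacc[nz])
      }
    }
  }
  list(fam_from = gf, fam_to = gt, kcal = gk, consumed = cons)
}

# union-find style connected components on a logical adjacency matrix
components_labels <- function(adj) {
  n <- nrow(adj)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      if (length(nb)) {
        m <- min(lab[i], lab[nb])
        if (any(c(lab[i], lab[nb]) != m)) {
          lab[c(i, nb)] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

#' Simulate a society and emit its interview ledger
#'
#' Runs the full generative model: pedigree, daily production, within-family
#' pooling, between-family allocation under the policy, and interview-style
#' recording. Returns the pedigree, the [sharing_ledger] and the underlying
#' truth (complete daily gift flows, production and requirement) for
#' validation.
#'
#' @param cfg a [society_config()]
#' @param schedule an [age_schedule()]
#' @param policy a [transfer_policy()]
#' @return list with components \code{pedigree}, \code{ledger}, \code{truth}
#'   (list: gifts, production, requirement, family_consumed)
#' @export
simulate_society <- function(cfg,
                             schedule = age_schedule(),
                             policy = transfer_policy()) {
  ped <- simulate_pedigree(cfg)
  sim <- simulate_production(ped, schedule, cfg)
  D <- cfg$study_days
  fam <- as.factor(ped$family_id)
  fam_ids <- as.integer(levels(fam))
  fam_com <- ped$community_id[match(fam_ids, ped$family_id)]
  R <- rowsum(sim$requirement, fam)[, 1]
  fam_r <- head_relatedness_matrix(ped)
  st <- alloc_state(fam_ids, fam_com, fam_r, R, policy,
                    head_age = family_head_ages(ped, fam_ids))
  gf <- vector("list", D); gt <- vector("list", D)
  gk <- vector("list", D); gd <- vector("list", D)
  consumed <- matrix(0, length(fam_ids), D)
  if (D > 0) {
    # null-policy randomness belongs to the production stream
    Pmat <- rowsum(sim$production, fam)
    for (d in seq_len(D)) {
      res <- alloc_day(Pmat[, d], st, policy)
      gf[[d]] <- res$fam_from; gt[[d]] <- res$fam_to
      gk[[d]] <- res$kcal; gd[[d]] <- rep(d, length(res$kcal))
      consumed[, d] <- res$consumed
    }
  }
  gifts <- data.table(fam_from = as.integer(unlist(gf)),
                      fam_to = as.integer(unlist(gt)),
                      kcal = as.numeric(unlist(gk)),
                      day = as.integer(unlist(gd)))
  ledger <- emit_ledger(ped, sim, gifts, cfg, policy)
  # consumed currently holds availability; satiation splits it into eaten
  # calories and carried surplus
  eaten <- pmin(consumed, policy$satiation_ratio * R)
  list(pedigree = ped,
       ledger = ledger,
       truth = list(gifts = gifts,
                    production = sim$production,
                    requirement = sim$requirement,
                    family_available = consumed,
                    family_eaten = eaten,
                    family_carried = consumed - eaten))
}

#' Emit an interview-style sharing ledger
#'
#' Converts true daily flows into dated interview records. Each family is
#' interviewed on random days at the configured weekly rate; an interview's
#' recall covers the preceding \code{recall_days} days. Three record types
#' are produced for covered days: \code{production} rows carry each
#' producer's gross product total (no recipient); \code{meal-portion} rows
#' attribute the eaten part of the family's retained production to members in
#' proportion to their consumption requirements (families eat at most
#' \code{satiation_ratio} times their summed requirement; the remainder is
#' carried surplus and attributed to no eater); \code{raw-gift} rows carry
#' between-family gifts, attributed to producers in proportion to that day's
#' production and to recipients in proportion to requirement. A production or
#' meal record enters the ledger when the producing family's recall covers
#' the day; a gift record when both families' recalls cover it (so per-dyad
#' kcal/day estimates over jointly observed days are unbiased). Recorded kcal
#' optionally carry multiplicative mean-one lognormal reporting noise.
#'
#' @param ped pedigree
#' @param sim output of the internal production stage (list with
#'   \code{production} matrix and \code{requirement} vector)
#' @param gifts data.table of true daily family-level gifts
#'   (fam_from, fam_to, kcal, day)
#' @param cfg a [society_config()]
#' @param policy the [transfer_policy()] in force (satiation ratio)
#' @return a \code{sharing_ledger}: list with \code{records} (data.table:
#'   day, type, producer_id, recipient_id, kcal), \code{coverage}
#'   (data.table: family_id, day), \code{persons} (id, family_id,
#'   community_id), \code{days_observed} (per person), \code{study_days}
#' @export
emit_ledger <- function(ped, sim, gifts, cfg, policy = transfer_policy()) {
  seeds <- derive_seeds(cfg$seed)
  set.seed(seeds[["interview"]])
  D <- cfg$study_days
  fam_ids <- sort(unique(ped$family_id))
  nf <- length(fam_ids)
  if (D == 0L) {
    cov <- data.table(family_id = integer(), day = integer())
  } else {
    p_int <- min(1, cfg$interviews_per_week / 7)
    int_days <- matrix(runif(nf * D) < p_int, nf, D)
    covm <- matrix(FALSE, nf, D)
    for (lag in seq_len(cfg$recall_days)) {
      if (D > lag)
        covm[, seq_len(D - lag)] <-
          covm[, seq_len(D - lag)] | int_days[, (lag + 1):D, drop = FALSE]
    }
    cov <- data.table(family_id = rep(fam_ids, D),
                      day = rep(seq_len(D), each = nf),
                      covered = as.vector(covm))[covered == TRUE][, covered := NULL]
  }
  persons <- data.table(id = ped$id, family_id = ped$family_id,
                        community_id = ped$community_id,
                        req = sim$requirement)
  persons[, share := req / sum(req), by = family_id]

  records <- list()
  if (D > 0L && nrow(cov)) {
    # long production table, producers with output
    prod_dt <- data.table(id = rep(ped$id, D),
                          family_id = rep(ped$family_id, D),
                          day = rep(seq_len(D), each = nrow(ped)),
                          prod = as.vector(sim$production))
    prod_dt <- prod_dt[prod > 0]
    # family-day budget: production, gifts out/in, availability, eaten
    fam_day <- prod_dt[, .(P = sum(prod)), by = .(family_id, day)]
    fam_req <- persons[, .(R = sum(req)), by = family_id]
    out_day <- gifts[, .(out = sum(kcal)), by = .(family_id = fam_from, day)]
    in_day <- gifts[, .(inn = sum(kcal)), by = .(family_id = fam_to, day)]
    grid <- CJ(family_id = fam_ids, day = seq_len(D))
    fam_day <- merge(grid, fam_day, by = c("family_id", "day"), all.x = TRUE)
    fam_day <- merge(fam_day, out_day, by = c("family_id", "day"), all.x = TRUE)
    fam_day <- merge(fam_day, in_day, by = c("family_id", "day"), all.x = TRUE)
    for (col in c("P", "out", "inn")) fam_day[is.na(get(col)), (col) := 0]
    fam_day <- merge(fam_day, fam_req, by = "family_id")
    fam_day[, avail := P - out + inn]
    fam_day[, eaten_frac := fifelse(avail > 0,
                                    pmin(1, policy$satiation_ratio * R / avail),
                                    1)]
    fam_day[, out_frac := fifelse(P > 0, pmin(1, out / P), 0)]

    prod_cov <- merge(prod_dt, cov, by = c("family_id", "day"))
    records[[length(records) + 1L]] <-
      prod_cov[, .(day, type = "production", producer_id = id,
                   recipient_id = NA_integer_, kcal = prod)]
    prod_cov <- merge(prod_cov,
                      fam_day[, .(family_id, day, out_frac, eaten_frac)],
                      by = c("family_id", "day"))
    prod_cov[, retained := prod * (1 - out_frac) * eaten_frac]
    meal <- merge(prod_cov[retained > 0],
                  persons[, .(recipient_id = id, family_id, share)],
                  by = "family_id", allow.cartesian = TRUE)
    meal <- meal[, .(day, type = "meal-portion", producer_id = id,
                     recipient_id, kcal = retained * share)]
    records[[length(records) + 1L]] <- meal

    if (nrow(gifts)) {
      g <- merge(gifts, cov[, .(fam_from = family_id, day)],
                 by = c("fam_from", "day"))
      g <- merge(g, cov[, .(fam_to = family_id, day)],
                 by = c("fam_to", "day"))
      if (nrow(g)) {
        g <- merge(g, fam_day[, .(fam_from = family_id, day, P)],
                   by = c("fam_from", "day"))
        gp <- merge(g, prod_dt[, .(fam_from = family_id, day,
                                   producer_id = id, prod)],
                    by = c("fam_from", "day"), allow.cartesian = TRUE)
        gp[, prod_share := prod / P]
        gpr <- merge(gp, persons[, .(fam_to = family_id, recipient_id = id,
                                     share)],
                     by = "fam_to", allow.cartesian = TRUE)
        raw <- gpr[, .(day, type = "raw-gift", producer_id,
                       recipient_id, kcal = kcal * prod_share * share)]
        records[[length(records) + 1L]] <- raw[kcal > 0]
      }
    }
  }
  records <- if (length(records)) rbindlist(records) else
    data.table(day = integer(), type = character(),
               producer_id = integer(), recipient_id = integer(),
               kcal = numeric())
  if (nrow(records) && cfg$reporting_cv > 0) {
    cv <- cfg$reporting_cv
    sdlog <- sqrt(log(1 + cv^2))
    records[, kcal := kcal * rlnorm(.N, -sdlog^2 / 2, sdlog)]
  }
  setorder(records, day, producer_id, recipient_id)
  days_obs <- cov[, .N, by = family_id]
  days_observed <- setNames(rep(0L, nrow(ped)), ped$id)
  m <- match(ped$family_id, days_obs$family_id)
  days_observed[!is.na(m)] <- days_obs$N[m[!is.na(m)]]
  structure(list(records = records,
                 coverage = cov,
                 persons = persons[, .(id, family_id, community_id)],
                 days_observed = days_observed,
                 study_days = D),
            class = "sharing_ledger")
}
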