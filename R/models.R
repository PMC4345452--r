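# Mixed-effect dyadic models: family-level interaction models, per-category
# models, and age-sex transfer profiles.

#' Assemble the family-dyad modelling table
#'
#' One row per ordered co-resident family dyad (older family i -> younger
#' family j): net transfer, mean relatedness, relationship category, and both
#' need variants for each side.
#'
#' @param ledger a \code{sharing_ledger}
#' @param ped pedigree
#' @param nt_fam optional precomputed [family_net_matrix()]
#' @param needs optional precomputed [need_index()] table
#' @return data.table with columns fam_i, fam_j, community, net_kcal_day,
#'   days, r_fam, category, need_i_measured, need_j_measured,
#'   need_i_estimated, need_j_estimated
#' @export
family_dyad_table <- function(ledger, ped, nt_fam = NULL, needs = NULL) {
  if (is.null(nt_fam)) {
    nt <- individual_net_matrix(ledger)
    nt_fam <- family_net_matrix(nt, ped)
  }
  if (is.null(needs)) needs <- need_index(ledger, ped)
  rmat <- relatedness_matrix(ped)
  fr <- family_relatedness_matrix(ped, rmat = rmat)
  d <- as.data.table(nt_fam)
  d[, r_fam := fr[cbind(as.character(fam_i), as.character(fam_j))]]
  d[, category := classify_family_dyads(ped, fam_i, fam_j, rmat = rmat)]
  d <- merge(d, needs[, .(fam_i = family_id,
                          need_i_measured = measured_need,
                          need_i_estimated = estimated_need)],
             by = "fam_i", all.x = TRUE)
  d <- merge(d, needs[, .(fam_j = family_id,
                          need_j_measured = measured_need,
                          need_j_estimated = estimated_need)],
             by = "fam_j", all.x = TRUE)
  setnames(d, "kcal_day", "net_kcal_day")
  setcolorder(d, c("fam_i", "fam_j", "community", "net_kcal_day", "days",
                   "r_fam", "category"))
  d[]
}

wald_p <- function(b, se) 2 * pnorm(-abs(b / se))

# fixed-effect table with Wald p; returns NULL if the covariance matrix is
# degenerate (caller falls back)
coef_table <- function(fit) {
  sm <- tryCatch(suppressWarnings(coef(summary(fit))),
                 error = function(e) NULL)
  if (is.null(sm) || anyNA(sm[, "Std. Error"]) ||
      any(sm[, "Std. Error"] <= 0))
    return(NULL)
  out <- data.table(term = rownames(sm), B = sm[, "Estimate"],
                    se = sm[, "Std. Error"])
  out[, p := wald_p(B, se)]
  out[]
}

#' Mixed-effect model of family net transfers on relatedness and need
#'
#' Fits the family-dyad model: standardized net transfer from older family i
#' to younger family j regressed on mean relatedness, the standardized net
#' need of each family, and the need-by-relatedness interactions, with
#' crossed random intercepts for donor family, recipient family, and
#' community (maximum likelihood, Wald p-values). The theory predicts a
#' positive relatedness effect, a negative donor-need-by-relatedness
#' interaction, and a positive recipient-need-by-relatedness interaction.
#'
#' Under degenerate random-effect structure the fit falls back to ordinary
#' least squares with cluster-robust (donor and recipient family)
#' standard errors, loudly flagged.
#'
#' @param dyads a [family_dyad_table()] (or any data.frame with the same
#'   columns)
#' @param need_variant \code{"estimated"} (instrumental) or \code{"measured"}
#' @param scale if \code{TRUE} (default), outcome and needs are standardized
#'   over the dyad sample before fitting
#' @return object of class \code{model_fit}: list with \code{coefficients}
#'   (term, B, se, p), \code{n}, \code{formula}, \code{ranef_var},
#'   \code{converged}, \code{singular}, \code{fallback}, \code{need_variant}
#' @export
fit_family_interaction_model <- function(dyads,
                                         need_variant = c("estimated",
                                                          "measured"),
                                         scale = TRUE) {
  need_variant <- match.arg(need_variant)
  d <- as.data.table(dyads)
  d <- d[complete.cases(d[, .(net_kcal_day, r_fam)])]
  ni <- d[[paste0("need_i_", need_variant)]]
  nj <- d[[paste0("need_j_", need_variant)]]
  keep <- !is.na(ni) & !is.na(nj)
  d <- d[keep]; ni <- ni[keep]; nj <- nj[keep]
  if (nrow(d) < 10) stop("too few dyads to fit the interaction model")
  if (scale && sd(d$net_kcal_day) == 0)
    stop("net transfers are constant over the dyad sample; nothing to model")
  bad <- character(0)
  if (sd(d$r_fam) == 0) bad <- c(bad, "r_fam")
  if (sd(ni) == 0) bad <- c(bad, paste0("need_i_", need_variant))
  if (sd(nj) == 0) bad <- c(bad, paste0("need_j_", need_variant))
  if (length(bad))
    stop("rank-deficient design; constant term(s): ",
         paste(bad, collapse = ", "))
  md <- data.table(
    y = if (scale) standardize(d$net_kcal_day) else d$net_kcal_day,
    r = d$r_fam,
    need_i = if (scale) standardize(ni) else ni,
    need_j = if (scale) standardize(nj) else nj,
    fam_i = factor(d$fam_i), fam_j = factor(d$fam_j),
    community = factor(d$community))
  form <- y ~ r + need_i + need_j + need_i:r + need_j:r +
    (1 | fam_i) + (1 | fam_j) + (1 | community)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(form, data = md, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")))),
    error = function(e) e)
  cf <- if (inherits(fit, "error")) NULL else coef_table(fit)
  if (is.null(cf)) {
    ols <- lm(y ~ r + need_i + need_j + need_i:r + need_j:r, data = md)
    vc <- sandwich::vcovCL(ols, cluster = md[, .(fam_i, fam_j)])
    cf <- data.table(term = names(coef(ols)), B = coef(ols),
                     se = sqrt(diag(vc)))
    cf[, p := wald_p(B, se)]
    warning("degenerate mixed-model fit; ",
            "fell back to OLS with cluster-robust errors")
    return(structure(list(coefficients = cf[], n = nrow(md),
                          n_communities = nlevels(md$community),
                          formula = deparse(form), ranef_var = NULL,
                          converged = FALSE, singular = NA,
                          fallback = "ols_cluster",
                          need_variant = need_variant),
                     class = "model_fit"))
  }
  vc <- as.data.table(lme4::VarCorr(fit))
  structure(list(coefficients = cf, n = nrow(md),
                 n_communities = nlevels(md$community),
                 formula = deparse(form),
                 ranef_var = vc[, .(grp, vcov)],
                 converged = length(fit@optinfo$conv$lme4) == 0,
                 singular = lme4::isSingular(fit),
                 fallback = NULL,
                 need_variant = need_variant),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("Dyadic mixed-model fit (", x$need_variant, " need), n = ", x$n,
      " dyads, ", x$n_communities, " communities\n", sep = "")
  if (!is.null(x$fallback)) cat("** fallback:", x$fallback, "**\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Per-relationship-category models of net transfers and need
#'
#' For each family-dyad relationship category (parent-offspring, sibling,
#' other-kin, non-kin): (1) the mean net transfer (kcal/day) with its
#' standard error and p-value from an intercept-only mixed model; (2, 3) the
#' standardized regression coefficients of donor and recipient need on the
#' standardized net transfer, for the estimated and measured need variants.
#' Standardization uses the full dyad sample. Categories with fewer than 3
#' dyads are reported as \code{NA} and flagged.
#'
#' @param dyads a [family_dyad_table()]
#' @return object of class \code{relationship_fit}: data.table with one row
#'   per category (n, mean, se, p, beta_i/beta_j with se and p per variant)
#' @export
fit_by_relationship <- function(dyads) {
  d <- as.data.table(dyads)
  cats <- c("parent-offspring", "sibling", "other-kin", "non-kin")
  if (!all(d$category %in% cats))
    stop("unknown category label: ",
         paste(setdiff(unique(d$category), cats), collapse = ", "))
  if (sd(d$net_kcal_day) == 0)
    stop("net transfers are constant over the dyad sample; nothing to model")
  y_std <- standardize(d$net_kcal_day)
  rows <- list()
  for (cat_k in cats) {
    s <- which(d$category == cat_k)
    row <- data.table(category = cat_k, n = length(s),
                      mean = NA_real_, se = NA_real_, p = NA_real_,
                      flagged = length(s) < 3)
    for (v in c("estimated", "measured"))
      for (side in c("i", "j"))
        for (col in c("beta", "se", "p"))
          row[[paste(col, side, v, sep = "_")]] <- NA_real_
    if (length(s) >= 3) {
      md <- data.table(y = d$net_kcal_day[s],
                       fam_i = factor(d$fam_i[s]),
                       fam_j = factor(d$fam_j[s]),
                       community = factor(d$community[s]))
      m1 <- fit_mean_model(md)
      row$mean <- m1$B; row$se <- m1$se; row$p <- m1$p
      for (v in c("estimated", "measured")) {
        ni <- standardize(d[[paste0("need_i_", v)]])[s]
        nj <- standardize(d[[paste0("need_j_", v)]])[s]
        if (sd(ni) == 0 || sd(nj) == 0) next
        mdv <- copy(md)
        mdv[, `:=`(y = y_std[s], need_i = ni, need_j = nj)]
        bf <- tryCatch(
          suppressMessages(suppressWarnings(
            lme4::lmer(y ~ need_i + need_j + (1 | fam_i) + (1 | fam_j) +
                         (1 | community),
                       data = mdv, REML = FALSE,
                       control = lme4::lmerControl(
                         calc.derivs = FALSE,
                         check.conv.singular = "ignore")))),
          error = function(e) NULL)
        cf <- if (is.null(bf)) NULL else coef_table(bf)
        if (is.null(cf)) {
          # degenerate mixed fit: plain OLS betas, flagged
          ols <- lm(y ~ need_i + need_j, data = mdv)
          sm <- coef(summary(ols))
          cf <- data.table(term = rownames(sm), B = sm[, 1], se = sm[, 2])
          cf[, p := wald_p(B, se)]
          row$flagged <- TRUE
        }
        for (side in c("i", "j")) {
          k <- cf[term == paste0("need_", side)]
          row[[paste0("beta_", side, "_", v)]] <- k$B
          row[[paste0("se_", side, "_", v)]] <- k$se
          row[[paste0("p_", side, "_", v)]] <- k$p
        }
      }
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- rbindlist(rows)
  setattr(out, "class", c("relationship_fit", class(data.table())))
  out[]
}

# intercept-only mixed model (mean with clustered uncertainty)
fit_mean_model <- function(md) {
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(y ~ 1 + (1 | fam_i) + (1 | fam_j) + (1 | community),
                 data = md, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")))),
    error = function(e) NULL)
  cf <- if (is.null(fit)) NULL else coef_table(fit)
  if (is.null(cf)) {
    m <- mean(md$y); se <- sd(md$y) / sqrt(nrow(md))
    return(list(B = m, se = se, p = wald_p(m, se)))
  }
  list(B = cf$B[1], se = cf$se[1], p = cf$p[1])
}

#' Age-sex profiles of net transfers by relationship category
#'
#' Characterizes net food transfers between focal individuals and a category
#' of kin as a function of focal sex and age: per age bin and sex, the mean
#' net transfer (kcal/day, positive = flowing in the requested direction)
#' with standard error and Wald p-value from a mixed model with a community
#' random intercept, plus an all-ages row per sex. Focals are all persons
#' with at least one alter in the category. Bins containing a single focal
#' report the estimate without a p-value and are flagged; degenerate mixed
#' fits fall back to per-bin means, flagged.
#'
#' @param nt individual-level \code{net_transfer_matrix}
#' @param ped pedigree
#' @param category relationship category (see [kin_alters()])
#' @param direction \code{"from_focal"} or \code{"to_focal"}
#' @param breaks age-bin breaks (default 5-year bins)
#' @return data.table: sex, age_bin (\code{"all"} rows included), n, mean,
#'   se, p, flagged
#' @export
fit_age_profiles <- function(nt, ped, category,
                             direction = c("from_focal", "to_focal"),
                             breaks = seq(0, 100, 5)) {
  direction <- match.arg(direction)
  sums <- category_sums(nt, ped, category, direction)
  if (!nrow(sums))
    return(data.table(sex = character(), age_bin = character(),
                      n = integer(), mean = numeric(), se = numeric(),
                      p = numeric(), flagged = logical()))
  sums[, age := ped_age(ped)[match(focal, ped$id)]]
  sums[, sex := ped$sex[match(focal, ped$id)]]
  per <- attr(nt, "persons")
  sums[, community := per$community_id[match(focal, per$id)]]
  sums[, age_bin := as.character(cut(age, breaks, right = FALSE,
                                     include.lowest = TRUE))]
  out <- list()
  for (sx in unique(sums$sex)) {
    ds <- sums[sex == sx]
    out[[length(out) + 1L]] <- profile_fit(ds, sx)
  }
  rbindlist(out)
}

# per-sex profile: one mixed model with age-bin fixed effects and a community
# random intercept, plus an intercept-only all-ages fit
profile_fit <- function(ds, sx) {
  ds <- copy(ds)
  ds[, age_bin := factor(age_bin)]
  multi_com <- length(unique(ds$community)) > 1L
  fit_one <- function(form) {
    if (!multi_com) return(NULL)
    f <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(form, data = ds, REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore")))),
      error = function(e) NULL)
    if (is.null(f)) NULL else coef_table(f)
  }
  all_cf <- fit_one(kcal_day ~ 1 + (1 | community))
  if (is.null(all_cf)) {
    m <- mean(ds$kcal_day); se <- sd(ds$kcal_day) / sqrt(nrow(ds))
    all_row <- data.table(sex = sx, age_bin = "all", n = nrow(ds), mean = m,
                          se = se, p = if (is.finite(se) && se > 0)
                            wald_p(m, se) else NA_real_,
                          flagged = multi_com)
  } else {
    all_row <- data.table(sex = sx, age_bin = "all", n = nrow(ds),
                          mean = all_cf$B[1], se = all_cf$se[1],
                          p = all_cf$p[1], flagged = FALSE)
  }
  bins <- levels(droplevels(ds$age_bin))
  cnt <- ds[, .N, by = age_bin]
  bin_cf <- if (length(bins) > 1L)
    fit_one(kcal_day ~ 0 + age_bin + (1 | community)) else NULL
  if (is.null(bin_cf)) {
    bin_rows <- ds[, .(n = .N, mean = mean(kcal_day),
                       se = if (.N > 1) sd(kcal_day) / sqrt(.N) else NA_real_),
                   by = age_bin]
    bin_rows[, `:=`(sex = sx,
                    p = fifelse(!is.na(se) & se > 0, wald_p(mean, se),
                                NA_real_),
                    flagged = TRUE)]
    bin_rows <- bin_rows[, .(sex, age_bin = as.character(age_bin), n, mean,
                             se, p, flagged)]
  } else {
    bin_cf[, age_bin := sub("^age_bin", "", term)]
    bin_rows <- merge(bin_cf, cnt, by = "age_bin")
    bin_rows[, `:=`(sex = sx, flagged = N == 1L)]
    bin_rows[N == 1L, p := NA_real_]
    bin_rows <- bin_rows[, .(sex, age_bin, n = N, mean = B, se, p, flagged)]
  }
  setorder(bin_rows, age_bin)
  rbind(all_row, bin_rows)
}

#' Simulate dyadic data from the interaction model's own assumptions
#'
#' Generates family-dyad data exactly under the fitted model's assumptions
#' (linear fixed effects plus Gaussian random intercepts for donor family,
#' recipient family and community, plus residual noise), for estimator
#' calibration: coefficient recovery and confidence-interval coverage.
#' Relatedness is drawn as a mixture of exact zero (non-kin) and canonical
#' kin coefficients; needs are standard normal at the family level.
#'
#' @param n_dyads number of dyads
#' @param beta named fixed effects: intercept, r, need_i, need_j,
#'   need_i_r, need_j_r
#' @param sd_donor,sd_recipient,sd_community,sd_resid random-effect and
#'   residual standard deviations
#' @param n_communities,families_per_community design layout
#' @param p_nonkin probability a dyad has r = 0
#' @param seed optional RNG seed
#' @return list with \code{dyads} (a [family_dyad_table()]-shaped table with
#'   both need variants set to the same generated needs) and \code{beta}
#' @export
simulate_dyadic_data <- function(n_dyads = 3000,
                                 beta = c(intercept = 0, r = 1,
                                          need_i = 0, need_j = 0,
                                          need_i_r = -1.5, need_j_r = 0.6),
                                 sd_donor = 0.4, sd_recipient = 0.4,
                                 sd_community = 0.2, sd_resid = 1,
                                 n_communities = 8,
                                 families_per_community = 40,
                                 p_nonkin = 0.6,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nf <- n_communities * families_per_community
  fam <- data.table(family_id = seq_len(nf),
                    community = rep(seq_len(n_communities),
                                    each = families_per_community),
                    need = rnorm(nf),
                    a = rnorm(nf, 0, sd_donor),
                    b = rnorm(nf, 0, sd_recipient))
  ce <- rnorm(n_communities, 0, sd_community)
  pairs <- fam[fam, on = "community", allow.cartesian = TRUE]
  pairs <- pairs[family_id < i.family_id]
  if (nrow(pairs) < n_dyads)
    stop("design too small for requested n_dyads")
  pairs <- pairs[sample(.N, n_dyads)]
  r <- ifelse(runif(n_dyads) < p_nonkin, 0,
              sample(c(0.5, 0.25, 0.125, 0.0625), n_dyads, TRUE,
                     prob = c(0.35, 0.3, 0.2, 0.15)))
  y <- beta[["intercept"]] + beta[["r"]] * r +
    beta[["need_i"]] * pairs$need + beta[["need_j"]] * pairs$i.need +
    beta[["need_i_r"]] * pairs$need * r +
    beta[["need_j_r"]] * pairs$i.need * r +
    pairs$a + pairs$i.b + ce[pairs$community] +
    rnorm(n_dyads, 0, sd_resid)
  dyads <- data.table(fam_i = pairs$family_id, fam_j = pairs$i.family_id,
                      community = pairs$community,
                      net_kcal_day = y, days = NA_integer_,
                      r_fam = r, category = NA_character_,
                      need_i_measured = pairs$need,
                      need_j_measured = pairs$i.need,
                      need_i_estimated = pairs$need,
                      need_j_estimated = pairs$i.need)
  list(dyads = dyads, beta = beta)
}
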