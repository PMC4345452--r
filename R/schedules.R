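# Age-sex caloric schedules, transfer policy, and society configuration.

# Default production / consumption knots (kcal/day), linearly interpolated.
# Shapes follow the canonical subsistence life course: children run caloric
# deficits through the teens, adults produce large surpluses from the late
# 20s through the 60s, and net production turns negative again in the 70s.
DEFAULT_KNOTS <- list(
  age    = c(0, 5, 10, 15, 20, 25, 30, 40, 50, 60, 70, 80, 95),
  prod_M = c(0, 50, 500, 1400, 2450, 2900, 3800, 4200, 4100, 3500, 1800, 600, 200),
  cons_M = c(700, 1150, 1550, 2050, 2350, 2400, 2400, 2400, 2350, 2250, 2100, 2000, 1900),
  prod_F = c(0, 50, 400, 1200, 2000, 2300, 2600, 3000, 2800, 2400, 1600, 500, 200),
  cons_F = c(650, 1050, 1400, 1800, 2050, 2100, 2100, 2100, 2050, 2000, 1900, 1800, 1700)
)

#' Age-sex schedule of caloric production and consumption
#'
#' Tabulated mean gross production and consumption requirement (kcal/day) by
#' age and sex, linearly interpolated between knots, plus the scales of
#' family-level and day-level production noise. Under the default knots,
#' individual net production (production minus consumption) is negative
#' through the teens, crosses zero in the early 20s, stays positive from the
#' late 20s through the 60s, and turns negative again in the 70s.
#'
#' @param knots list with components \code{age}, \code{prod_M}, \code{cons_M},
#'   \code{prod_F}, \code{cons_F} (equal-length numeric vectors, kcal/day)
#' @param production_sd_family family-level random productivity effect scale
#'   (kcal/day, applied per reference adult; see [simulate_society()])
#' @param production_sd_day day-to-day production noise scale (kcal/day)
#' @return object of class \code{age_schedule}
#' @export
age_schedule <- function(knots = DEFAULT_KNOTS,
                         production_sd_family = 400,
                         production_sd_day = 600) {
  stopifnot(all(lengths(knots) == length(knots$age)),
            all(knots$prod_M >= 0), all(knots$prod_F >= 0),
            all(knots$cons_M >= 0), all(knots$cons_F >= 0),
            production_sd_family >= 0, production_sd_day >= 0)
  structure(list(knots = knots,
                 production_sd_family = production_sd_family,
                 production_sd_day = production_sd_day),
            class = "age_schedule")
}

#' Mean production / consumption at given ages
#'
#' @param schedule an [age_schedule()]
#' @param age numeric vector of ages (years)
#' @param sex character vector, \code{"F"}/\code{"M"}
#' @return kcal/day vector
#' @export
production_mean <- function(schedule, age, sex) {
  schedule_lookup(schedule, age, sex, "prod")
}

#' @rdname production_mean
#' @export
consumption_mean <- function(schedule, age, sex) {
  schedule_lookup(schedule, age, sex, "cons")
}

schedule_lookup <- function(schedule, age, sex, what) {
  k <- schedule$knots
  out <- numeric(length(age))
  for (s in c("F", "M")) {
    sel <- sex == s
    if (any(sel))
      out[sel] <- approx(k$age, k[[paste0(what, "_", s)]],
                         xout = age[sel], rule = 2)$y
  }
  out
}

#' Transfer allocation policy
#'
#' Encodes how surplus calories move between individuals or families. Utility
#' of consumption is isoelastic (CRRA), u(x) = log(x) for
#' \code{curvature} = 1 and x^(1-curvature)/(1-curvature) otherwise, so
#' marginal utility is u'(x) = x^(-curvature): strictly increasing utility and
#' strictly diminishing returns require \code{curvature} > 0. The marginal
#' benefit b of a transfer is the recipient's marginal utility and the
#' marginal cost c the donor's, so a donor gives while r * u'(recipient) >
#' u'(donor) -- Hamilton's rule b r > c at the margin.
#'
#' Modes:
#' \describe{
#'   \item{kin_need}{Hamilton allocation: gifts flow along relatedness,
#'     weighted by r, toward higher marginal need (the default).}
#'   \item{need_only}{kin-blind but need-directed "charity": every pair is
#'     weighted by the constant \code{social_weight} instead of r.}
#'   \item{need_blind}{null policy: random, need- and kin-blind gifting
#'     (each family gives with probability \code{give_prob} a random share of
#'     its production to one random co-resident family).}
#' }
#'
#' @param curvature CRRA utility curvature (> 0); 1 = logarithmic. The
#'   default of 3 reflects the steep marginal value of calories near
#'   subsistence: a donor family gives kin of mean relatedness r while the
#'   recipient's consumption/requirement ratio is below r^(1/curvature) times
#'   its own, so curvature 3 produces transfers at ~1.6-fold need asymmetry
#'   for r = 0.25, where logarithmic utility would require 4-fold.
#' @param kin_weighting if \code{FALSE} and \code{mode} is unset, the mode
#'   becomes \code{"need_only"} (allocation independent of r)
#' @param mode allocation mode, see Details
#' @param gift_granularity smallest gift worth making (kcal); also the
#'   stopping tolerance of the allocation
#' @param social_weight pair weight replacing r under \code{need_only}
#' @param give_prob,give_frac_sd,give_kcal_scale parameters of the
#'   \code{need_blind} null: per-day gift probability, lognormal spread, and
#'   kcal scale of the random gift (independent of the donor's productivity,
#'   capped by what it has)
#' @param satiation_ratio families eat at most this multiple of their summed
#'   consumption requirement per day; calories available beyond it are carried
#'   surplus (stored, processed, wasted) and attributed to no eater
#' @param benefit_age_slope life-history weighting of the recipient's marginal
#'   benefit in the family-level allocation: the benefit side of b r > c is
#'   multiplied by exp(-slope x head age), so calories consumed by young,
#'   growing households carry a higher fitness return than the same calories
#'   consumed late in life. 0 recovers a pure current-need allocator
#' @return object of class \code{transfer_policy}
#' @export
transfer_policy <- function(curvature = 3,
                            kin_weighting = TRUE,
                            mode = NULL,
                            gift_granularity = 1,
                            social_weight = 0.5,
                            give_prob = 0.3,
                            give_frac_sd = 0.5,
                            give_kcal_scale = 600,
                            satiation_ratio = 1.2,
                            benefit_age_slope = 0.03) {
  if (!is.numeric(curvature) || curvature <= 0)
    stop("utility must be strictly concave: curvature must be > 0")
  if (is.null(mode)) mode <- if (kin_weighting) "kin_need" else "need_only"
  mode <- match.arg(mode, c("kin_need", "need_only", "need_blind"))
  stopifnot(gift_granularity > 0, social_weight > 0, social_weight <= 1,
            give_prob >= 0, give_prob <= 1, satiation_ratio >= 1,
            benefit_age_slope >= 0)
  structure(list(curvature = curvature, kin_weighting = kin_weighting,
                 mode = mode, gift_granularity = gift_granularity,
                 social_weight = social_weight, give_prob = give_prob,
                 give_frac_sd = give_frac_sd,
                 give_kcal_scale = give_kcal_scale,
                 satiation_ratio = satiation_ratio,
                 benefit_age_slope = benefit_age_slope),
            class = "transfer_policy")
}

#' Society configuration
#'
#' Parameters of the synthetic-society generator: community layout, lineage
#' demography, study length, and the interview observation design (families
#' interviewed about twice a week, each interview recalling the preceding two
#' days). One seed fully determines the output; internally the seed feeds a
#' named generator hierarchy (demography / production noise / interview
#' sampling) so the stages can be varied independently.
#'
#' @param n_communities number of communities (>= 1)
#' @param families_per_community target nuclear families per community; lineages
#'   are added until the target is reached, so realized counts can slightly
#'   exceed it
#' @param fertility_mean mean number of surviving children per couple (Poisson)
#' @param marriage_age,marriage_prob age from which, and probability with
#'   which, an adult child marries out of the natal family and founds a
#'   nuclear family (spouses marry in from outside the pedigree)
#' @param first_birth_age mother's age at first birth
#' @param birth_spacing mean spacing between births (years)
#' @param study_days length of the observation window (days)
#' @param interviews_per_week production-and-sharing interview rate per family
#' @param recall_days days covered by each interview recall
#' @param reporting_cv multiplicative lognormal reporting noise (cv; 0 = exact)
#' @param ref_year calendar year of observation (birth years derive from it)
#' @param seed integer seed determining the whole run
#' @return object of class \code{society_config}
#' @export
society_config <- function(n_communities = 2,
                           families_per_community = 40,
                           fertility_mean = 6,
                           marriage_age = 21,
                           marriage_prob = 0.9,
                           first_birth_age = 19,
                           birth_spacing = 2.6,
                           study_days = 120,
                           interviews_per_week = 2,
                           recall_days = 2,
                           reporting_cv = 0.1,
                           ref_year = 2000,
                           seed = 1L) {
  cfg <- list(n_communities = as.integer(n_communities),
              families_per_community = as.integer(families_per_community),
              fertility_mean = fertility_mean,
              marriage_age = marriage_age,
              marriage_prob = marriage_prob,
              first_birth_age = first_birth_age,
              birth_spacing = birth_spacing,
              study_days = as.integer(study_days),
              interviews_per_week = interviews_per_week,
              recall_days = as.integer(recall_days),
              reporting_cv = reporting_cv,
              ref_year = as.integer(ref_year),
              seed = as.integer(seed))
  if (cfg$n_communities < 1 || cfg$families_per_community < 1)
    stop("infeasible parameters: need at least one community and one family")
  if (cfg$study_days < 0) stop("study_days must be >= 0")
  if (cfg$fertility_mean < 0 || cfg$marriage_prob < 0 || cfg$marriage_prob > 1)
    stop("infeasible demographic parameters")
  if (cfg$interviews_per_week <= 0 || cfg$recall_days < 1)
    stop("interviews_per_week must be > 0 and recall_days >= 1")
  structure(cfg, class = "society_config")
}

# Named sub-seeds for the generator hierarchy.
derive_seeds <- function(seed) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 3L)
  names(s) <- c("demography", "production", "interview")
  s
}
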