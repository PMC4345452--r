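# Reduction of sharing ledgers to dyadic net-transfer matrices and
# net-production profiles.

#' Construct a sharing ledger from its component tables
#'
#' @param records data.table/data.frame with columns \code{day},
#'   \code{type} (\code{"meal-portion"} or \code{"raw-gift"}),
#'   \code{producer_id}, \code{recipient_id}, \code{kcal}
#' @param coverage data.table with columns \code{family_id}, \code{day}:
#'   the days each family's interview recall covered
#' @param persons data.table with columns \code{id}, \code{family_id},
#'   \code{community_id}
#' @param study_days length of the study window (days)
#' @return object of class \code{sharing_ledger}
#' @export
sharing_ledger <- function(records, coverage, persons, study_days) {
  records <- as.data.table(records)
  coverage <- as.data.table(coverage)
  persons <- as.data.table(persons)
  stopifnot(all(c("day", "type", "producer_id", "recipient_id", "kcal")
                %in% names(records)),
            all(c("family_id", "day") %in% names(coverage)),
            all(c("id", "family_id", "community_id") %in% names(persons)))
  if (nrow(records)) {
    if (!all(records$type %in% c("production", "meal-portion", "raw-gift")))
      stop("unknown ledger record type")
    if (any(records$kcal < 0)) stop("ledger kcal must be non-negative")
    if (any(records$type == "raw-gift" &
            records$producer_id == records$recipient_id, na.rm = TRUE))
      stop("gift records require producer != recipient")
    if (any(records$day < 1 | records$day > study_days))
      stop("record dates must lie within the study window")
    ids <- persons$id
    rid <- records$recipient_id[records$type != "production"]
    if (!all(records$producer_id %in% ids) || anyNA(rid) ||
        !all(rid %in% ids))
      stop("ledger references persons missing from the roster")
  }
  nobs <- coverage[, .N, by = family_id]
  days_observed <- setNames(rep(0L, nrow(persons)), persons$id)
  m <- match(persons$family_id, nobs$family_id)
  days_observed[!is.na(m)] <- nobs$N[m[!is.na(m)]]
  structure(list(records = records, coverage = coverage,
                 persons = persons[, .(id, family_id, community_id)],
                 days_observed = days_observed,
                 study_days = as.integer(study_days)),
            class = "sharing_ledger")
}

# days both families' recalls covered, as a family x family matrix
joint_days_matrix <- function(ledger) {
  fam_ids <- sort(unique(ledger$persons$family_id))
  D <- ledger$study_days
  M <- matrix(0, length(fam_ids), max(1L, D))
  if (nrow(ledger$coverage))
    M[cbind(match(ledger$coverage$family_id, fam_ids),
            ledger$coverage$day)] <- 1
  J <- M %*% t(M)
  dimnames(J) <- list(fam_ids, fam_ids)
  J
}

#' Individual-level dyadic net-transfer matrix
#'
#' For every ordered person pair, the net flow T(i, j) is the kcal of i's
#' production consumed by or gifted to j, minus the reverse, divided by the
#' number of days on which both persons' families were observed. Meal-portion
#' records attribute a dish's calories to its eaters. The result is
#' antisymmetric with a zero diagonal.
#'
#' @param ledger a \code{sharing_ledger}
#' @return object of class \code{net_transfer_matrix}: a data.table edge list
#'   (\code{i}, \code{j}, \code{kcal_day}, \code{days}) over canonical pairs
#'   i < j (sign = net flow from i to j), with attributes \code{level} and
#'   \code{persons}; see [nt_value()] and [as.matrix.net_transfer_matrix()]
#' @export
individual_net_matrix <- function(ledger) {
  stopifnot(inherits(ledger, "sharing_ledger"))
  rec <- ledger$records
  if (!nrow(rec))
    stop("cannot reduce an empty ledger to a net-transfer matrix")
  appearing <- unique(c(rec$producer_id, rec$recipient_id))
  appearing <- appearing[!is.na(appearing)]
  if (any(ledger$days_observed[as.character(appearing)] == 0))
    stop("inconsistent ledger: person appears in records but has zero observed days")
  flows <- rec[type != "production" & producer_id != recipient_id,
               .(kcal = sum(kcal)), by = .(producer_id, recipient_id)]
  flows[, `:=`(i = pmin(producer_id, recipient_id),
               j = pmax(producer_id, recipient_id),
               signed = fifelse(producer_id < recipient_id, kcal, -kcal))]
  net <- flows[, .(net = sum(signed)), by = .(i, j)]
  per <- ledger$persons
  J <- joint_days_matrix(ledger)
  fi <- as.character(per$family_id[match(net$i, per$id)])
  fj <- as.character(per$family_id[match(net$j, per$id)])
  net[, days := J[cbind(fi, fj)]]
  net[, kcal_day := net / days]
  out <- net[, .(i, j, kcal_day, days)]
  setattr(out, "class", c("net_transfer_matrix", class(data.table())))
  setattr(out, "level", "individual")
  setattr(out, "persons", copy(ledger$persons))
  setattr(out, "joint_days", J)
  out[]
}

#' Look up a net-transfer value
#'
#' @param nt a \code{net_transfer_matrix}
#' @param i,j ids (persons or families depending on level); for family level
#'   the value is the net flow from \code{i}'s row orientation
#' @return kcal/day net flow from i to j (0 if the dyad has no recorded flow)
#' @export
nt_value <- function(nt, i, j) {
  if (i == j) return(0)
  lev <- attr(nt, "level")
  if (lev == "individual") {
    a <- min(i, j); b <- max(i, j)
    row <- nt[nt$i == a & nt$j == b]
    v <- if (nrow(row)) row$kcal_day[1] else 0
    if (i < j) v else -v
  } else {
    row <- nt[(nt$fam_i == i & nt$fam_j == j)]
    if (nrow(row)) return(row$kcal_day[1])
    row <- nt[(nt$fam_i == j & nt$fam_j == i)]
    if (nrow(row)) -row$kcal_day[1] else 0
  }
}

#' Dense antisymmetric matrix form of a net-transfer object
#'
#' @param x a \code{net_transfer_matrix}
#' @param ... unused
#' @return square antisymmetric numeric matrix
#' @export
as.matrix.net_transfer_matrix <- function(x, ...) {
  lev <- attr(x, "level")
  if (lev == "individual") {
    ids <- sort(attr(x, "persons")$id)
    M <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    M[cbind(match(x$i, ids), match(x$j, ids))] <- x$kcal_day
    M[cbind(match(x$j, ids), match(x$i, ids))] <- -x$kcal_day
  } else {
    ids <- sort(unique(c(x$fam_i, x$fam_j)))
    M <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    M[cbind(match(x$fam_i, ids), match(x$fam_j, ids))] <- x$kcal_day
    M[cbind(match(x$fam_j, ids), match(x$fam_i, ids))] <- -x$kcal_day
  }
  M
}

#' Family-level net-transfer matrix
#'
#' Sums individual net flows across family memberships and orients each
#' co-resident dyad from the older family (by age of its oldest core adult)
#' to the younger; age ties break toward the smaller family id, with a
#' message. All within-community family dyads are retained, including those
#' with zero recorded flow (they are data for the dyadic models); only
#' same-community pairs are kept. Within-family flows cancel by construction.
#'
#' @param nt individual-level \code{net_transfer_matrix}
#' @param ped pedigree
#' @return \code{net_transfer_matrix} at family level: data.table
#'   (\code{fam_i}, \code{fam_j}, \code{kcal_day}, \code{days},
#'   \code{community}, \code{head_age_i}, \code{head_age_j})
#' @export
family_net_matrix <- function(nt, ped) {
  stopifnot(attr(nt, "level") == "individual")
  per <- attr(nt, "persons")
  e <- copy(nt)
  e[, fam_i := per$family_id[match(i, per$id)]]
  e[, fam_j := per$family_id[match(j, per$id)]]
  cross <- e[fam_i != fam_j,
             .(flow = sum(kcal_day)), by = .(fam_i, fam_j)]
  # collapse orientation to canonical (min, max) family pair
  cross[, `:=`(a = pmin(fam_i, fam_j), b = pmax(fam_i, fam_j),
               signed = fifelse(fam_i < fam_j, flow, -flow))]
  flows <- cross[, .(net = sum(signed)), by = .(a, b)]

  fams <- unique(per[, .(family_id, community_id)])
  head_age <- vapply(fams$family_id, function(f)
    max(ped_age(ped)[match(family_heads(ped, f), ped$id)]), numeric(1))
  fams[, head_age := head_age]
  # dyad universe: all within-community pairs
  dy <- fams[fams, on = "community_id", allow.cartesian = TRUE]
  dy <- dy[family_id < i.family_id]
  setnames(dy, c("family_id", "head_age", "i.family_id", "i.head_age"),
           c("a", "age_a", "b", "age_b"))
  dy <- merge(dy, flows, by = c("a", "b"), all.x = TRUE)
  dy[is.na(net), net := 0]
  J <- attr(nt, "joint_days")
  dy[, days := J[cbind(as.character(a), as.character(b))]]
  ties <- dy[age_a == age_b]
  if (nrow(ties))
    message(nrow(ties), " family dyad(s) with tied head ages; ",
            "oriented toward the smaller family id")
  older_first <- dy$age_a >= dy$age_b  # tie -> smaller id (a) first
  out <- data.table(
    fam_i = fifelse(older_first, dy$a, dy$b),
    fam_j = fifelse(older_first, dy$b, dy$a),
    kcal_day = fifelse(older_first, dy$net, -dy$net),
    days = dy$days,
    community = dy$community_id,
    head_age_i = pmax(dy$age_a, dy$age_b),
    head_age_j = pmin(dy$age_a, dy$age_b))
  setattr(out, "class", c("net_transfer_matrix", class(data.table())))
  setattr(out, "level", "family")
  setattr(out, "persons", per)
  out[]
}

# alters standing in a named relation to the focal person
KIN_CATEGORIES <- c("children", "grandchildren", "spouse", "children-in-law",
                    "parents", "grandparents", "parents-in-law")

#' Alters of a focal person by relationship category
#'
#' @param ped pedigree
#' @param focal focal person id
#' @param category one of children, grandchildren, spouse, children-in-law,
#'   parents, grandparents, parents-in-law
#' @return integer vector of alter ids (possibly empty)
#' @export
kin_alters <- function(ped, focal, category) {
  if (!(category %in% KIN_CATEGORIES))
    stop("unknown relationship category: ", category)
  if (!(focal %in% ped$id)) stop("unknown person id: ", focal)
  row <- ped[ped$id == focal]
  children <- ped$id[(!is.na(ped$mother_id) & ped$mother_id == focal) |
                     (!is.na(ped$father_id) & ped$father_id == focal)]
  switch(category,
    "children" = children,
    "grandchildren" = ped$id[(!is.na(ped$mother_id) & ped$mother_id %in% children) |
                             (!is.na(ped$father_id) & ped$father_id %in% children)],
    "spouse" = if (is.na(row$spouse_id)) integer(0) else row$spouse_id,
    "children-in-law" = {
      sp <- ped$spouse_id[match(children, ped$id)]
      sp[!is.na(sp)]
    },
    "parents" = c(row$mother_id, row$father_id)[
      !is.na(c(row$mother_id, row$father_id))],
    "grandparents" = {
      par <- c(row$mother_id, row$father_id)
      par <- par[!is.na(par)]
      gp <- c(ped$mother_id[match(par, ped$id)],
              ped$father_id[match(par, ped$id)])
      gp[!is.na(gp)]
    },
    "parents-in-law" = {
      if (is.na(row$spouse_id)) integer(0) else {
        sp <- ped[ped$id == row$spouse_id]
        p <- c(sp$mother_id, sp$father_id)
        p[!is.na(p)]
      }
    })
}

#' Net transfer between a focal person and a relationship category
#'
#' Sums the dyadic net transfers between the focal and every alter standing
#' in the named relation, signed by direction: \code{from_focal} counts flows
#' focal -> alter as positive, \code{to_focal} the reverse.
#'
#' @param nt individual-level \code{net_transfer_matrix}
#' @param ped pedigree
#' @param focal focal person id
#' @param category relationship category (see [kin_alters()])
#' @param direction \code{"from_focal"} or \code{"to_focal"}
#' @return kcal/day
#' @export
focal_category_sum <- function(nt, ped, focal, category,
                               direction = c("from_focal", "to_focal")) {
  direction <- match.arg(direction)
  alters <- kin_alters(ped, focal, category)
  if (!length(alters)) return(0)
  v <- sum(vapply(alters, function(a) nt_value(nt, focal, a), numeric(1)))
  if (direction == "from_focal") v else -v
}

# vectorized per-focal category sums (focals = persons with >= 1 alter)
category_sums <- function(nt, ped, category,
                          direction = c("from_focal", "to_focal")) {
  direction <- match.arg(direction)
  rel <- relation_table(ped, category)
  per <- attr(nt, "persons")
  base <- data.table(focal = ped$id)
  base <- base[focal %in% unique(rel$focal)]
  if (!nrow(base))
    return(data.table(focal = integer(), kcal_day = numeric()))
  edges <- rbind(
    nt[, .(focal = i, alter = j, v = kcal_day)],
    nt[, .(focal = j, alter = i, v = -kcal_day)])
  x <- merge(rel, edges, by = c("focal", "alter"))
  sums <- x[, .(kcal_day = sum(v)), by = focal]
  out <- merge(base, sums, by = "focal", all.x = TRUE)
  out[is.na(kcal_day), kcal_day := 0]
  if (direction == "to_focal") out[, kcal_day := -kcal_day]
  out[]
}

# (focal, alter) pairs for a category, across the whole pedigree
relation_table <- function(ped, category) {
  if (!(category %in% KIN_CATEGORIES))
    stop("unknown relationship category: ", category)
  id <- ped$id; mo <- ped$mother_id; fa <- ped$father_id; sp <- ped$spouse_id
  pc <- rbind(
    data.table(focal = mo[!is.na(mo)], alter = id[!is.na(mo)]),
    data.table(focal = fa[!is.na(fa)], alter = id[!is.na(fa)]))  # parent->child
  out <- switch(category,
    "children" = pc,
    "parents" = pc[, .(focal = alter, alter = focal)],
    "grandchildren" = {
      gc <- merge(pc, pc, by.x = "alter", by.y = "focal",
                  allow.cartesian = TRUE)
      gc[, .(focal, alter = alter.y)]
    },
    "grandparents" = {
      gc <- merge(pc, pc, by.x = "alter", by.y = "focal",
                  allow.cartesian = TRUE)
      gc[, .(focal = alter.y, alter = focal)]
    },
    "spouse" = data.table(focal = id[!is.na(sp)], alter = sp[!is.na(sp)]),
    "children-in-law" = {
      x <- pc[, .(focal, alter, asp = sp[match(alter, id)])]
      x[!is.na(asp), .(focal, alter = asp)]
    },
    "parents-in-law" = {
      x <- pc[, .(focal, alter, asp = sp[match(alter, id)])]
      x[!is.na(asp), .(focal = asp, alter = focal)]
    })
  unique(out)
}

#' Net-production profile by age bin
#'
#' Per-person (or per-family) net production = observed gross production
#' minus observed consumption, per observed day, averaged within age bins.
#' Family age is the age of the family's oldest core adult. Empty bins are
#' flagged and excluded.
#'
#' @param ledger a \code{sharing_ledger}
#' @param ped pedigree
#' @param level \code{"individual"} or \code{"family"}
#' @param breaks age-bin breaks (years)
#' @return data.table: age_bin, n, mean, se (kcal/day)
#' @export
net_production_profile <- function(ledger, ped,
                                   level = c("individual", "family"),
                                   breaks = NULL) {
  level <- match.arg(level)
  if (is.null(breaks))
    breaks <- if (level == "individual") seq(0, 100, 5) else seq(0, 100, 10)
  rec <- ledger$records
  per <- ledger$persons
  prod <- rec[type == "production",
              .(prod = sum(kcal)), by = .(id = producer_id)]
  cons <- rec[type != "production",
              .(cons = sum(kcal)), by = .(id = recipient_id)]
  x <- data.table(id = per$id)
  x <- merge(x, prod, by = "id", all.x = TRUE)
  x <- merge(x, cons, by = "id", all.x = TRUE)
  x[is.na(prod), prod := 0]
  x[is.na(cons), cons := 0]
  x[, days := ledger$days_observed[as.character(id)]]
  x <- x[days > 0]
  x[, net := (prod - cons) / days]
  if (level == "individual") {
    x[, age := ped_age(ped)[match(id, ped$id)]]
  } else {
    x[, family_id := per$family_id[match(id, per$id)]]
    x <- x[, .(net = sum(net)), by = family_id]
    head_age <- vapply(x$family_id, function(f)
      max(ped_age(ped)[match(family_heads(ped, f), ped$id)]), numeric(1))
    x[, age := head_age]
  }
  x[, age_bin := cut(age, breaks, right = FALSE, include.lowest = TRUE)]
  all_bins <- levels(x$age_bin)
  out <- x[!is.na(age_bin),
           .(n = .N, mean = mean(net),
             se = if (.N > 1) sd(net) / sqrt(.N) else NA_real_),
           by = age_bin]
  setorder(out, age_bin)
  empty <- setdiff(all_bins[seq_len(max(0, max(as.integer(out$age_bin), 0)))],
                   as.character(out$age_bin))
  setattr(out, "empty_bins", empty)
  out[]
}

#' Read / write sharing ledgers and net-transfer edge lists
#'
#' Ledgers are stored as two tab-delimited tables: dated records
#' (day, type, producer_id, recipient_id, kcal) and the interview coverage
#' (family_id, day), plus the person roster which is re-read from the
#' pedigree file. Net-transfer matrices are stored as long-format edge lists
#' and read back losslessly.
#'
#' @param ledger sharing ledger
#' @param records_path,coverage_path file paths for the two ledger tables
#' @return [read_ledger()] returns a \code{sharing_ledger}
#' @export
write_ledger <- function(ledger, records_path, coverage_path) {
  fwrite(ledger$records, records_path, sep = "\t")
  fwrite(ledger$coverage, coverage_path, sep = "\t")
  invisible(records_path)
}

#' @rdname write_ledger
#' @param ped pedigree providing the person roster
#' @param study_days study window length; defaults to the max day present
#' @export
read_ledger <- function(records_path, coverage_path, ped, study_days = NULL) {
  records <- fread(records_path, sep = "\t")
  coverage <- fread(coverage_path, sep = "\t")
  if (is.null(study_days))
    study_days <- max(c(records$day, coverage$day, 0L))
  persons <- data.table(id = ped$id, family_id = ped$family_id,
                        community_id = ped$community_id)
  sharing_ledger(records, coverage, persons, study_days)
}

#' @rdname write_ledger
#' @param nt net-transfer matrix
#' @param path edge-list file path
#' @export
write_net_matrix <- function(nt, path) {
  out <- copy(nt)
  setattr(out, "class", class(data.table()))
  out[, level := attr(nt, "level")]
  fwrite(out, path, sep = "\t")
  invisible(path)
}
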