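# Measured and instrumental (composition-based) family net-need indices.

#' Measured net caloric need of families
#'
#' Measured need is daily consumption minus gross production: the sum of the
#' members' observed consumption minus their observed production, divided by
#' the family's observed days. Positive values mean needy.
#'
#' @param ledger a \code{sharing_ledger}
#' @param ped pedigree
#' @param family_id optional single family id; default all families
#' @param drop_unobserved drop families with zero observed days (with a
#'   warning) instead of raising an error; used by the pipeline so one
#'   never-interviewed family does not abort a whole analysis
#' @return data.table: family_id, measured_need (kcal/day)
#' @export
measured_need <- function(ledger, ped, family_id = NULL,
                          drop_unobserved = FALSE) {
  per <- ledger$persons
  rec <- ledger$records
  prod <- rec[type == "production",
              .(prod = sum(kcal)), by = .(id = producer_id)]
  cons <- rec[type != "production",
              .(cons = sum(kcal)), by = .(id = recipient_id)]
  x <- data.table(id = per$id, family_id = per$family_id)
  x <- merge(x, prod, by = "id", all.x = TRUE)
  x <- merge(x, cons, by = "id", all.x = TRUE)
  x[is.na(prod), prod := 0]
  x[is.na(cons), cons := 0]
  fam <- x[, .(prod = sum(prod), cons = sum(cons)), by = family_id]
  nobs <- ledger$coverage[, .N, by = family_id]
  fam <- merge(fam, nobs, by = "family_id", all.x = TRUE)
  fam[is.na(N), N := 0L]
  if (!is.null(family_id)) {
    fam <- fam[fam$family_id == family_id]
    if (!nrow(fam)) stop("unknown family: ", family_id)
  }
  if (any(fam$N == 0)) {
    if (drop_unobserved) {
      warning("dropping families with zero observed days: ",
              paste(head(fam$family_id[fam$N == 0], 5), collapse = ", "))
      fam <- fam[N > 0]
    } else {
      stop("family with zero observed days: ",
           paste(head(fam$family_id[fam$N == 0], 5), collapse = ", "))
    }
  }
  fam[, .(family_id, measured_need = (cons - prod) / N)]
}

#' Instrumental estimated net need from demographic composition
#'
#' The instrumental need variable predicts each family's net need from its
#' age-sex composition alone: mean observed production and consumption per
#' day are fitted for every age-sex cell across the whole sample excluding
#' the focal family (leave-one-family-out), and the family's need is the sum
#' over members of predicted consumption minus predicted production. By
#' construction it is invariant to the family's own realized (noisy) output,
#' which is what makes it robust to endogeneity and measurement error. Cells
#' left empty after exclusion borrow from the nearest age cell of the same
#' sex (logged in the \code{borrowed} attribute).
#'
#' @param ledger a \code{sharing_ledger}
#' @param ped pedigree
#' @param age_breaks age-bin breaks defining cells
#' @return data.table: family_id, estimated_need (kcal/day)
#' @export
estimated_need <- function(ledger, ped, age_breaks = seq(0, 100, 5)) {
  per <- ledger$persons
  rec <- ledger$records
  prod <- rec[type == "production",
              .(prod = sum(kcal)), by = .(id = producer_id)]
  cons <- rec[type != "production",
              .(cons = sum(kcal)), by = .(id = recipient_id)]
  x <- data.table(id = per$id, family_id = per$family_id)
  x <- merge(x, prod, by = "id", all.x = TRUE)
  x <- merge(x, cons, by = "id", all.x = TRUE)
  x[is.na(prod), prod := 0]
  x[is.na(cons), cons := 0]
  x[, days := ledger$days_observed[as.character(id)]]
  x <- x[days > 0]
  x[, `:=`(prod = prod / days, cons = cons / days)]
  x[, age := ped_age(ped)[match(id, ped$id)]]
  x[, sex := ped$sex[match(id, ped$id)]]
  x[, cell := paste(sex, as.integer(cut(age, age_breaks, right = FALSE,
                                        include.lowest = TRUE)))]
  cell_tot <- x[, .(sp = sum(prod), sc = sum(cons), n = .N), by = cell]
  fam_cell <- x[, .(fam_p = sum(prod), fam_c = sum(cons), fam_n = .N),
                by = .(family_id, cell)]
  fx <- merge(fam_cell, cell_tot, by = "cell")
  fx[, loo_n := n - fam_n]
  borrowed <- list()
  # leave-one-out cell means; empty cells borrow nearest age cell, same sex
  fx[, `:=`(est_prod = NA_real_, est_cons = NA_real_)]
  fx[loo_n > 0, `:=`(est_prod = (sp - fam_p) / loo_n,
                     est_cons = (sc - fam_c) / loo_n)]
  if (any(fx$loo_n == 0)) {
    for (k in which(fx$loo_n == 0)) {
      cl <- fx$cell[k]
      sx <- sub(" .*", "", cl)
      bin_k <- as.integer(sub(".* ", "", cl))
      alt <- cell_tot[grepl(paste0("^", sx, " "), cell) & cell != cl]
      if (!nrow(alt)) next
      alt[, bin := as.integer(sub(".* ", "", cell))]
      # exclude focal family's contribution where possible
      altf <- merge(alt, fam_cell[family_id == fx$family_id[k],
                                  .(cell, fam_p, fam_c, fam_n)],
                    by = "cell", all.x = TRUE)
      for (col in c("fam_p", "fam_c", "fam_n"))
        altf[is.na(get(col)), (col) := 0]
      altf <- altf[n - fam_n > 0]
      if (!nrow(altf)) next
      best <- altf[which.min(abs(altf$bin - bin_k))]
      set(fx, i = k, j = "est_prod",
          value = (best$sp - best$fam_p) / (best$n - best$fam_n))
      set(fx, i = k, j = "est_cons",
          value = (best$sc - best$fam_c) / (best$n - best$fam_n))
      borrowed[[length(borrowed) + 1L]] <-
        data.table(family_id = fx$family_id[k], cell = cl, from = best$cell)
    }
  }
  fx <- fx[!is.na(est_prod)]
  out <- fx[, .(estimated_need = sum(fam_n * (est_cons - est_prod))),
            by = family_id]
  setorder(out, family_id)
  setattr(out, "borrowed",
          if (length(borrowed)) rbindlist(borrowed) else NULL)
  out[]
}

#' Per-family need index table
#'
#' Joins [measured_need()] and [estimated_need()]; both carry the same sign
#' convention (positive = needy). Standardization to the modelling sample is
#' performed by the model-fitting functions, not here.
#'
#' @inheritParams estimated_need
#' @return data.table: family_id, measured_need, estimated_need
#' @export
need_index <- function(ledger, ped, age_breaks = seq(0, 100, 5)) {
  m <- measured_need(ledger, ped, drop_unobserved = TRUE)
  e <- estimated_need(ledger, ped, age_breaks = age_breaks)
  merge(m, e, by = "family_id", all = TRUE)
}

#' Standardize a numeric vector
#'
#' (x - mean) / sd with the n - 1 denominator, over the supplied sample.
#'
#' @param x numeric vector with at least two distinct values
#' @return unitless scores with mean 0 and sd 1
#' @export
standardize <- function(x) {
  if (length(x) < 2) stop("standardize requires at least 2 values")
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant input")
  (x - mean(x)) / s
}
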