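# Pedigree representation, relatedness, and family dyad classification.

PED_COLS <- c("id", "sex", "birth_year", "mother_id", "father_id",
              "spouse_id", "family_id", "community_id")

#' Construct and validate a pedigree
#'
#' A pedigree is the genealogical roster of a study population: one row per
#' person with sex, birth year, parent links, spouse link, and the nuclear
#' family and community the person belongs to. It is the sole source of
#' genetic relatedness for the analysis.
#'
#' Validation enforces: unique ids; sex in \code{"F"}/\code{"M"}; parent links
#' that resolve to rows of the pedigree with the right sex; acyclic descent;
#' symmetric spouse links; and exactly one family and community per person.
#'
#' @param x data.frame with columns \code{id}, \code{sex}, \code{birth_year},
#'   \code{mother_id}, \code{father_id}, \code{spouse_id}, \code{family_id},
#'   \code{community_id}. Missing parents/spouses are \code{NA} (or the
#'   sentinel \code{0} as used in files).
#' @param ref_year reference (observation) year used to convert birth years to
#'   ages; defaults to the maximum birth year present (youngest person age 0).
#' @return object of class \code{pedigree} (a \code{data.table}) with a
#'   \code{ref_year} attribute and a precomputed generation-\code{depth}
#'   attribute (founders at depth 0).
#' @export
pedigree <- function(x, ref_year = NULL) {
  x <- as.data.table(x)
  missing_cols <- setdiff(PED_COLS, names(x))
  if (length(missing_cols))
    stop("pedigree is missing columns: ", paste(missing_cols, collapse = ", "))
  x <- x[, ..PED_COLS]
  for (col in c("id", "mother_id", "father_id", "spouse_id",
                "family_id", "community_id", "birth_year")) {
    v <- x[[col]]
    if (is.character(v)) v <- suppressWarnings(as.integer(v))
    v <- as.integer(v)
    v[!is.na(v) & v == 0L & col %in% c("mother_id", "father_id", "spouse_id")] <- NA_integer_
    set(x, j = col, value = v)
  }
  if (anyNA(x$id) || anyDuplicated(x$id))
    stop("pedigree ids must be unique and non-missing")
  if (!all(x$sex %in% c("F", "M")))
    stop("sex must be 'F' or 'M'")
  if (anyNA(x$family_id) || anyNA(x$community_id))
    stop("every person must belong to exactly one nuclear family and community")
  # one family implies one community for that family
  fc <- unique(x[, .(family_id, community_id)])
  if (anyDuplicated(fc$family_id))
    stop("a nuclear family cannot span communities")
  for (col in c("mother_id", "father_id")) {
    p <- x[[col]]
    bad <- !is.na(p) & !(p %in% x$id)
    if (any(bad))
      stop("unknown ", col, " for person(s): ",
           paste(head(x$id[bad], 5), collapse = ", "))
  }
  msex <- x$sex[match(x$mother_id, x$id)]
  if (any(!is.na(msex) & msex != "F")) stop("mother_id must point to a female")
  fsex <- x$sex[match(x$father_id, x$id)]
  if (any(!is.na(fsex) & fsex != "M")) stop("father_id must point to a male")
  sp <- x$spouse_id
  known_sp <- !is.na(sp)
  if (any(known_sp & !(sp %in% x$id)))
    stop("unknown spouse_id")
  back <- x$spouse_id[match(sp[known_sp], x$id)]
  if (any(is.na(back) | back != x$id[known_sp]))
    stop("spouse links must be symmetric")
  depth <- ped_depth(x)
  if (is.null(ref_year)) ref_year <- max(x$birth_year)
  setattr(x, "class", c("pedigree", class(data.table())))
  setattr(x, "ref_year", as.integer(ref_year))
  setattr(x, "depth", depth)
  x[]
}

# generation depth; errors on parental cycles
ped_depth <- function(x) {
  n <- nrow(x)
  mi <- match(x$mother_id, x$id)
  fi <- match(x$father_id, x$id)
  depth <- rep(NA_integer_, n)
  depth[is.na(mi) & is.na(fi)] <- 0L
  repeat {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    dm <- ifelse(is.na(mi[todo]), -1L, depth[mi[todo]])
    df <- ifelse(is.na(fi[todo]), -1L, depth[fi[todo]])
    ready <- !( (!is.na(mi[todo]) & is.na(dm)) | (!is.na(fi[todo]) & is.na(df)) )
    if (!any(ready))
      stop("parent links contain a cycle")
    depth[todo[ready]] <- pmax(dm[ready], df[ready]) + 1L
  }
  depth
}

#' Ages of pedigree members at the reference year
#' @param ped pedigree
#' @return integer vector of ages, in pedigree row order
#' @export
ped_age <- function(ped) {
  attr(ped, "ref_year") - ped$birth_year
}

#' Kinship coefficient matrix
#'
#' Standard recursive kinship computation over the pedigree, processing
#' individuals in generation order: for person i with parents (m, f),
#' phi(i, j) = (phi(m, j) + phi(f, j)) / 2 for previously placed j (a missing
#' parent contributes 0), and phi(i, i) = (1 + phi(m, f)) / 2. Founders are
#' assumed mutually unrelated and non-inbred.
#'
#' @param ped pedigree
#' @return symmetric numeric matrix of kinship coefficients, dimnames = ids
#' @export
kinship_matrix <- function(ped) {
  n <- nrow(ped)
  ids <- ped$id
  mi <- match(ped$mother_id, ids)
  fi <- match(ped$father_id, ids)
  ord <- order(attr(ped, "depth"))
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in ord) {
    m <- mi[i]; f <- fi[i]
    if (is.na(m) && is.na(f)) {
      phi[i, i] <- 0.5
      next
    }
    row_m <- if (is.na(m)) 0 else phi[m, ]
    row_f <- if (is.na(f)) 0 else phi[f, ]
    v <- (row_m + row_f) / 2
    phi_mf <- if (is.na(m) || is.na(f)) 0 else phi[m, f]
    phi[i, ] <- v
    phi[, i] <- v
    phi[i, i] <- (1 + phi_mf) / 2
  }
  phi
}

#' Coefficient-of-relatedness matrix
#'
#' r = 2 * kinship; r(i, i) = 1 for non-inbred individuals, r = 0 for pairs
#' with no common ancestor.
#'
#' @param ped pedigree
#' @return symmetric numeric matrix with entries in \[0, 1\] (non-inbred case)
#' @export
relatedness_matrix <- function(ped) {
  2 * kinship_matrix(ped)
}

#' Pairwise coefficient of relatedness
#'
#' @param ped pedigree
#' @param i,j person ids
#' @return scalar relatedness in \[0, 1\]
#' @export
relatedness <- function(ped, i, j) {
  ids <- ped$id
  if (!(i %in% ids)) stop("unknown person id: ", i)
  if (!(j %in% ids)) stop("unknown person id: ", j)
  r <- relatedness_matrix(ped)
  r[as.character(i), as.character(j)]
}

#' Gene-dropping Monte-Carlo estimate of relatedness
#'
#' Brute-force validation oracle for the recursive kinship computation:
#' founder alleles are labelled uniquely, dropped through the pedigree by
#' Mendelian transmission \code{n_drops} times, and relatedness is estimated
#' for every pair as the mean allele-sharing statistic
#' s = (#matching allele pairs) / 2, whose expectation is r = 2 * kinship.
#'
#' @param ped pedigree
#' @param n_drops number of independent drops
#' @param seed optional RNG seed
#' @return list with matrices \code{r} (estimates) and \code{se}
#'   (Monte-Carlo standard errors)
#' @export
gene_drop_relatedness <- function(ped, n_drops = 20000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  ids <- ped$id
  mi <- match(ped$mother_id, ids)
  fi <- match(ped$father_id, ids)
  ord <- order(attr(ped, "depth"))
  a1 <- matrix(0L, n_drops, n)
  a2 <- matrix(0L, n_drops, n)
  next_allele <- 1L
  for (i in ord) {
    m <- mi[i]; f <- fi[i]
    if (is.na(m)) {
      a1[, i] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- runif(n_drops) < 0.5
      a1[, i] <- ifelse(pick, a1[, m], a2[, m])
    }
    if (is.na(f)) {
      a2[, i] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- runif(n_drops) < 0.5
      a2[, i] <- ifelse(pick, a1[, f], a2[, f])
    }
  }
  r <- matrix(0, n, n, dimnames = list(ids, ids))
  se <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- ((a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
            (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])) / 2
      r[i, j] <- r[j, i] <- mean(s)
      se[i, j] <- se[j, i] <- sd(s) / sqrt(n_drops)
    }
  }
  list(r = r, se = se)
}

#' Mean relatedness between two nuclear families
#'
#' Arithmetic mean of the coefficient of relatedness over all cross-family
#' person pairs.
#'
#' @param ped pedigree
#' @param fam_i,fam_j distinct family ids
#' @param rmat optional precomputed relatedness matrix
#' @return scalar mean relatedness
#' @export
family_relatedness <- function(ped, fam_i, fam_j, rmat = NULL) {
  if (fam_i == fam_j)
    stop("families must be disjoint (a person cannot be in both)")
  mi <- which(ped$family_id == fam_i)
  mj <- which(ped$family_id == fam_j)
  if (!length(mi)) stop("unknown or empty family: ", fam_i)
  if (!length(mj)) stop("unknown or empty family: ", fam_j)
  if (is.null(rmat)) rmat <- relatedness_matrix(ped)
  mean(rmat[mi, mj])
}

#' Family-by-family mean relatedness matrix
#'
#' @param ped pedigree
#' @param rmat optional precomputed person-level relatedness matrix
#' @return square matrix over family ids; diagonal \code{NA}
#' @export
family_relatedness_matrix <- function(ped, rmat = NULL) {
  if (is.null(rmat)) rmat <- relatedness_matrix(ped)
  fam <- as.factor(ped$family_id)
  sums <- rowsum(t(rowsum(rmat, fam)), fam)  # family x family sums
  n <- as.vector(table(fam))
  out <- sums / outer(n, n)
  dimnames(out) <- list(levels(fam), levels(fam))
  diag(out) <- NA_real_
  out
}

#' Maximum head-to-head relatedness between families
#'
#' The largest coefficient of relatedness between the core adults of each
#' pair of families. This is the simulator's allocation weight: gifts
#' between households are decided by their heads, so Hamilton's rule runs on
#' the decision-makers' own relatedness (0.5 between sibling heads or a
#' parent-child head pair) rather than the member-mean r-bar used in the
#' dyadic analysis.
#'
#' @param ped pedigree
#' @param rmat optional precomputed person-level relatedness matrix
#' @return square matrix over family ids; diagonal \code{NA}
#' @export
head_relatedness_matrix <- function(ped, rmat = NULL) {
  if (is.null(rmat)) rmat <- relatedness_matrix(ped)
  fams <- sort(unique(ped$family_id))
  idx <- lapply(fams, function(f)
    match(family_heads(ped, f), ped$id))
  n <- length(fams)
  out <- matrix(NA_real_, n, n, dimnames = list(fams, fams))
  for (a in seq_len(n - 1)) {
    ra <- rmat[idx[[a]], , drop = FALSE]
    for (b in (a + 1):n) {
      m <- max(ra[, idx[[b]]])
      out[a, b] <- out[b, a] <- m
    }
  }
  out
}

#' Core adults (heads) of a nuclear family
#'
#' Heads are the members who are parents of another member of the same family,
#' together with their in-family spouses; if no member has in-family children
#' (e.g. an older couple whose children have all left), the adult members
#' (age >= 18) are the heads.
#'
#' @param ped pedigree
#' @param fam family id
#' @return integer vector of person ids
#' @export
family_heads <- function(ped, fam) {
  m <- ped[ped$family_id == fam]
  if (!nrow(m)) stop("unknown or empty family: ", fam)
  parents <- unique(c(m$mother_id, m$father_id))
  parents <- parents[!is.na(parents)]
  heads <- m$id[m$id %in% parents]
  if (length(heads)) {
    sp <- m$spouse_id[match(heads, m$id)]
    heads <- unique(c(heads, sp[!is.na(sp) & sp %in% m$id]))
  } else {
    age <- attr(ped, "ref_year") - m$birth_year
    heads <- m$id[age >= 18]
  }
  if (!length(heads))
    stop("family ", fam, " has no core adult")
  sort(heads)
}

#' Classify the relationship between two nuclear families
#'
#' Categories follow the genealogical links between the core adults of the two
#' families with precedence parent-offspring > sibling > other-kin; a dyad is
#' non-kin iff its mean family relatedness is exactly 0.
#'
#' @param ped pedigree
#' @param fam_i,fam_j distinct family ids
#' @param rmat optional precomputed relatedness matrix
#' @return one of \code{"parent-offspring"}, \code{"sibling"},
#'   \code{"other-kin"}, \code{"non-kin"}
#' @export
classify_family_dyad <- function(ped, fam_i, fam_j, rmat = NULL) {
  if (fam_i == fam_j) stop("families must be disjoint")
  classify_family_dyads(ped, fam_i, fam_j, rmat = rmat)
}

#' @rdname classify_family_dyad
#' @param fam_a,fam_b equal-length vectors of family ids forming the dyads
#' @export
classify_family_dyads <- function(ped, fam_a, fam_b, rmat = NULL) {
  stopifnot(length(fam_a) == length(fam_b))
  fams <- unique(c(fam_a, fam_b))
  heads <- rbindlist(lapply(fams, function(f)
    data.table(family_id = f, head_id = family_heads(ped, f))))
  heads[, `:=`(mother_id = ped$mother_id[match(head_id, ped$id)],
               father_id = ped$father_id[match(head_id, ped$id)])]
  # family pairs linked head-to-head as parent-offspring
  hp <- rbind(heads[!is.na(mother_id),
                    .(family_id, parent = mother_id)],
              heads[!is.na(father_id),
                    .(family_id, parent = father_id)])
  po <- merge(hp, heads[, .(pfam = family_id, parent = head_id)],
              by = "parent", allow.cartesian = TRUE)
  po_keys <- unique(po[family_id != pfam,
                       paste(pmin(family_id, pfam), pmax(family_id, pfam))])
  # family pairs whose heads share a parent (full or half siblings)
  sib <- merge(hp, hp, by = "parent", allow.cartesian = TRUE)
  sib_keys <- unique(sib[family_id.x != family_id.y,
                         paste(pmin(family_id.x, family_id.y),
                               pmax(family_id.x, family_id.y))])
  if (is.null(rmat)) rmat <- relatedness_matrix(ped)
  fr <- family_relatedness_matrix(ped, rmat = rmat)
  keys <- paste(pmin(fam_a, fam_b), pmax(fam_a, fam_b))
  rbar <- fr[cbind(as.character(fam_a), as.character(fam_b))]
  out <- rep("non-kin", length(fam_a))
  out[rbar > 0] <- "other-kin"
  out[keys %in% sib_keys] <- "sibling"
  out[keys %in% po_keys] <- "parent-offspring"
  out
}

#' Read / write pedigree files
#'
#' Pedigrees are stored as tab-delimited tables, one row per person, with the
#' columns of [pedigree()]. A missing parent or spouse is encoded with the
#' sentinel \code{0}.
#'
#' @param path file path
#' @param ref_year observation year (see [pedigree()])
#' @return [read_pedigree()] returns a validated pedigree;
#'   [write_pedigree()] returns \code{path} invisibly.
#' @export
read_pedigree <- function(path, ref_year = NULL) {
  x <- fread(path, sep = "\t", colClasses = list(character = "sex"))
  pedigree(x, ref_year = ref_year)
}

#' @rdname read_pedigree
#' @param ped pedigree to write
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.table(ped)
  for (col in c("mother_id", "father_id", "spouse_id"))
    set(out, j = col, value = fifelse(is.na(out[[col]]), 0L, out[[col]]))
  fwrite(out, path, sep = "\t")
  invisible(path)
}
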