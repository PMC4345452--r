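# Orchestration: config files, simulate / analyze / replicate runs, manifests.

config_keys <- function() list(
  society = names(formals(society_config)),
  policy = names(formals(transfer_policy)),
  schedule = c("production_sd_family", "production_sd_day"),
  analysis = c("age_bin_individual", "age_bin_family", "need_age_bin")
)

#' Read and validate a run configuration
#'
#' Configurations are YAML key-value files with up to four blocks:
#' \code{society} (see [society_config()]), \code{policy}
#' (see [transfer_policy()]), \code{schedule} (noise scales of
#' [age_schedule()]) and \code{analysis} (age-bin widths), plus a required
#' top-level \code{seed}. Unknown keys raise an error naming them; a missing
#' required key raises a named error.
#'
#' @param path YAML file path
#' @return list with validated components \code{cfg}, \code{policy},
#'   \code{schedule}, \code{analysis}, \code{seed}, \code{path}
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  keys <- config_keys()
  unknown_top <- setdiff(names(raw), c(names(keys), "seed"))
  if (length(unknown_top))
    stop("invalid config keys: ", paste(unknown_top, collapse = ", "))
  if (is.null(raw$seed)) stop("missing required config key: seed")
  for (block in names(keys)) {
    unknown <- setdiff(names(raw[[block]]), keys[[block]])
    if (length(unknown))
      stop("invalid config keys in '", block, "': ",
           paste(unknown, collapse = ", "))
  }
  soc <- raw$society %||% list()
  soc$seed <- raw$seed
  cfg <- do.call(society_config, soc)
  policy <- do.call(transfer_policy, raw$policy %||% list())
  schedule <- do.call(age_schedule, raw$schedule %||% list())
  analysis <- modifyList(list(age_bin_individual = 5, age_bin_family = 10,
                              need_age_bin = 5),
                         raw$analysis %||% list())
  list(cfg = cfg, policy = policy, schedule = schedule,
       analysis = analysis, seed = as.integer(raw$seed), path = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_manifest <- function(config, extra = list()) {
  c(list(package = "kinshare",
         version = as.character(packageVersion("kinshare")),
         seed = config$seed,
         config_hash = if (!is.null(config$path) && file.exists(config$path))
           unname(tools::md5sum(config$path)) else NA_character_,
         timestamp = format(Sys.time(), tz = "UTC")),
    extra)
}

#' Run the simulator from a configuration
#'
#' Simulates a society and writes its pedigree, ledger records, interview
#' coverage and a JSON manifest (seed, config hash, file list) to
#' \code{out_dir}. Identical config + seed produce byte-identical tables.
#'
#' @param config path to a YAML config, or the list from [read_config()]
#' @param out_dir output directory (created if needed)
#' @return (invisibly) list with the simulation output and file paths
#' @export
run_simulate <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_society(config$cfg, schedule = config$schedule,
                          policy = config$policy)
  paths <- list(pedigree = file.path(out_dir, "pedigree.tsv"),
                records = file.path(out_dir, "ledger_records.tsv"),
                coverage = file.path(out_dir, "ledger_coverage.tsv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_pedigree(sim$pedigree, paths$pedigree)
  write_ledger(sim$ledger, paths$records, paths$coverage)
  manifest <- run_manifest(config, list(
    outputs = vapply(paths, identity, character(1)),
    n_persons = nrow(sim$pedigree),
    n_families = length(unique(sim$pedigree$family_id)),
    study_days = config$cfg$study_days))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(sim = sim, paths = paths))
}

#' Run the full analysis chain on simulator output
#'
#' Reads a pedigree and ledger (files or in-memory objects), then computes
#' net-production profiles, age-sex transfer profiles per relationship
#' category, the family-dyad interaction models (both need variants) and the
#' per-category models, writing each as a delimited table plus a JSON
#' manifest recording formulas and convergence.
#'
#' @param pedigree_file pedigree TSV (or a pedigree object)
#' @param records_file,coverage_file ledger TSVs (or a sharing_ledger as
#'   \code{records_file})
#' @param config config list from [read_config()] (or path); analysis
#'   settings and \code{ref_year} are taken from it
#' @param out_dir optional output directory; if \code{NULL}, nothing is
#'   written and results are only returned
#' @param profiles which age-profile categories to fit
#' @return list of results (profiles, models, need table, dyad table)
#' @export
run_analyze <- function(pedigree_file, records_file, coverage_file = NULL,
                        config = NULL, out_dir = NULL,
                        profiles = c("children", "grandchildren", "spouse",
                                     "parents")) {
  if (is.character(config)) config <- read_config(config)
  ref_year <- if (!is.null(config)) config$cfg$ref_year else NULL
  ped <- if (inherits(pedigree_file, "pedigree")) pedigree_file
         else read_pedigree(pedigree_file, ref_year = ref_year)
  ledger <- if (inherits(records_file, "sharing_ledger")) records_file
            else read_ledger(records_file, coverage_file, ped,
                             study_days = if (!is.null(config))
                               config$cfg$study_days else NULL)
  check_ids(ped, ledger)
  analysis <- if (!is.null(config)) config$analysis else
    list(age_bin_individual = 5, age_bin_family = 10, need_age_bin = 5)
  if (!nrow(ledger$records)) {
    warning("empty ledger: writing empty-but-valid outputs")
    out <- list(empty = TRUE, profiles = list(), models = list())
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      fwrite(data.table(age_bin = character(), n = integer(),
                        mean = numeric(), se = numeric()),
             file.path(out_dir, "net_production_individual.tsv"), sep = "\t")
    }
    return(invisible(out))
  }
  nt <- individual_net_matrix(ledger)
  nt_fam <- family_net_matrix(nt, ped)
  needs <- need_index(ledger, ped,
                      age_breaks = seq(0, 100, analysis$need_age_bin))
  dyads <- family_dyad_table(ledger, ped, nt_fam = nt_fam, needs = needs)
  bi <- seq(0, 100, analysis$age_bin_individual)
  bf <- seq(0, 100, analysis$age_bin_family)
  # a degenerate sample (e.g. constant transfers) fails one model, not the run
  try_fit <- function(expr) {
    tryCatch(expr, error = function(e) {
      warning("model stage failed: ", conditionMessage(e), call. = FALSE)
      structure(list(error = conditionMessage(e)), class = "failed_fit")
    })
  }
  res <- list(
    net_production_individual = net_production_profile(ledger, ped,
                                                       "individual", bi),
    net_production_family = net_production_profile(ledger, ped, "family", bf),
    age_profiles = setNames(lapply(profiles, function(catg)
      try_fit(fit_age_profiles(nt, ped, catg,
                       direction = if (catg %in% c("parents", "grandparents",
                                                   "parents-in-law"))
                         "to_focal" else "from_focal",
                       breaks = bi))), profiles),
    interaction_estimated = try_fit(fit_family_interaction_model(dyads,
                                                                 "estimated")),
    interaction_measured = try_fit(fit_family_interaction_model(dyads,
                                                                "measured")),
    by_relationship = try_fit(fit_by_relationship(dyads)),
    needs = needs, dyads = dyads)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fwrite(res$net_production_individual,
           file.path(out_dir, "net_production_individual.tsv"), sep = "\t")
    fwrite(res$net_production_family,
           file.path(out_dir, "net_production_family.tsv"), sep = "\t")
    for (catg in names(res$age_profiles))
      if (!inherits(res$age_profiles[[catg]], "failed_fit"))
        fwrite(res$age_profiles[[catg]],
               file.path(out_dir, paste0("age_profile_", catg, ".tsv")),
               sep = "\t")
    for (v in c("estimated", "measured"))
      if (!inherits(res[[paste0("interaction_", v)]], "failed_fit"))
        fwrite(res[[paste0("interaction_", v)]]$coefficients,
               file.path(out_dir, paste0("family_interaction_", v, ".tsv")),
               sep = "\t")
    if (!inherits(res$by_relationship, "failed_fit"))
      fwrite(res$by_relationship,
             file.path(out_dir, "relationship_categories.tsv"), sep = "\t")
    fwrite(res$needs, file.path(out_dir, "need_index.tsv"), sep = "\t")
    fit_state <- function(f) {
      if (inherits(f, "failed_fit")) paste("failed:", f$error)
      else if (isTRUE(f$converged)) "converged" else "flagged"
    }
    manifest <- run_manifest(config %||% list(seed = NA), list(
      models = list(
        interaction_formula = if (!inherits(res$interaction_estimated,
                                            "failed_fit"))
          res$interaction_estimated$formula else NA,
        interaction_state = list(
          estimated = fit_state(res$interaction_estimated),
          measured = fit_state(res$interaction_measured))),
      n_dyads = nrow(dyads)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(res)
}

check_ids <- function(ped, ledger) {
  ids <- ped$id
  rec <- ledger$records
  seen <- unique(c(rec$producer_id, rec$recipient_id))
  bad <- setdiff(seen[!is.na(seen)], ids)
  if (length(bad))
    stop("pedigree/ledger id mismatch; ledger ids not in pedigree: ",
         paste(head(bad, 10), collapse = ", "))
  badf <- setdiff(unique(ledger$coverage$family_id), unique(ped$family_id))
  if (length(badf))
    stop("pedigree/ledger id mismatch; unknown families: ",
         paste(head(badf, 10), collapse = ", "))
  invisible(TRUE)
}

#' Replicate simulate + analyze over many seeds
#'
#' Reruns the full pipeline over \code{n_seeds} seeds and aggregates the
#' quantities used to judge qualitative recovery: interaction-model
#' coefficients and p-values (both need variants), per-category mean net
#' transfers, need-index correlation, and (optionally) the age-profile
#' summaries behind the parent/grandparent predictions.
#'
#' @param cfg a [society_config()] (its seed is replaced per replicate)
#' @param n_seeds number of replicates
#' @param seeds explicit seed vector (overrides \code{n_seeds})
#' @param policy a [transfer_policy()]
#' @param schedule an [age_schedule()]
#' @param profiles if \code{TRUE}, also compute the age-profile summaries
#' @return object of class \code{replicate_study}: list with \code{per_seed}
#'   (data.table) and \code{summary} (sign-recovery rates)
#' @export
run_replicate <- function(cfg, n_seeds = 20, seeds = NULL,
                          policy = transfer_policy(),
                          schedule = age_schedule(),
                          profiles = TRUE) {
  if (is.null(seeds)) seeds <- seq_len(n_seeds)
  rows <- vector("list", length(seeds))
  for (k in seq_along(seeds)) {
    cfg_k <- cfg
    cfg_k$seed <- as.integer(seeds[k])
    rows[[k]] <- replicate_one(cfg_k, policy, schedule, profiles)
  }
  per_seed <- rbindlist(rows, fill = TRUE)
  structure(list(per_seed = per_seed,
                 summary = summarize_replicates(per_seed)),
            class = "replicate_study")
}

replicate_one <- function(cfg, policy, schedule, profiles) {
  sim <- simulate_society(cfg, schedule = schedule, policy = policy)
  ped <- sim$pedigree
  ledger <- sim$ledger
  nt <- individual_net_matrix(ledger)
  nt_fam <- suppressMessages(family_net_matrix(nt, ped))
  needs <- need_index(ledger, ped)
  dyads <- family_dyad_table(ledger, ped, nt_fam = nt_fam, needs = needs)
  out <- data.table(seed = cfg$seed, n_dyads = nrow(dyads))
  for (v in c("estimated", "measured")) {
    fit <- fit_family_interaction_model(dyads, v)
    cf <- fit$coefficients
    pick <- function(term_) cf[term == term_]
    for (tm in c("r", "need_i", "need_j", "r:need_i", "r:need_j")) {
      key <- gsub("[:]", "_x_", tm)
      out[[paste0("B_", key, "_", v)]] <- pick(tm)$B
      out[[paste0("p_", key, "_", v)]] <- pick(tm)$p
    }
  }
  rel <- fit_by_relationship(dyads)
  for (cat_k in rel$category) {
    key <- gsub("-", "_", cat_k)
    out[[paste0("mean_", key)]] <- rel[category == cat_k]$mean
    out[[paste0("se_", key)]] <- rel[category == cat_k]$se
  }
  out$corr_need <- cor(needs$estimated_need, needs$measured_need,
                       use = "complete.obs")
  if (profiles) {
    prof_sum <- function(catg, direction) {
      fit_age_profiles(nt, ped, catg, direction = direction)
    }
    pc <- prof_sum("children", "from_focal")
    gg <- prof_sum("grandchildren", "from_focal")
    rp <- prof_sum("parents", "to_focal")
    allages <- function(pr, sx) {
      row <- pr[pr$sex == sx & pr$age_bin == "all"]
      if (nrow(row)) row$mean else NA_real_
    }
    out$parents_to_children_M <- allages(pc, "M")
    out$parents_to_children_F <- allages(pc, "F")
    out$grandparents_to_grandchildren_M <- allages(gg, "M")
    out$grandparents_to_grandchildren_F <- allages(gg, "F")
    # age at which net receipts from parents peak (midpoint of peak 5-y bin)
    peaks <- rp[rp$age_bin != "all" & rp$n >= 3]
    if (nrow(peaks)) {
      b <- peaks$age_bin[which.max(peaks$mean)]
      out$receipt_peak_age <- bin_mid(b)
    } else out$receipt_peak_age <- NA_real_
  }
  out
}

bin_mid <- function(lab) {
  nums <- as.numeric(strsplit(gsub("[\\[\\)\\]]", "", lab, perl = TRUE),
                              ",")[[1]])
  mean(nums)
}

summarize_replicates <- function(per_seed) {
  alpha <- 0.05
  sig_pat <- function(v)
    per_seed[[paste0("B_r_", v)]] > 0 &
    per_seed[[paste0("p_r_", v)]] < alpha &
    per_seed[[paste0("B_r_x_need_i_", v)]] < 0 &
    per_seed[[paste0("p_r_x_need_i_", v)]] < alpha &
    per_seed[[paste0("B_r_x_need_j_", v)]] > 0 &
    per_seed[[paste0("p_r_x_need_j_", v)]] < alpha
  same_sign <- sign(per_seed$B_r_x_need_i_estimated) ==
    sign(per_seed$B_r_x_need_i_measured) &
    sign(per_seed$B_r_x_need_j_estimated) ==
    sign(per_seed$B_r_x_need_j_measured)
  ordering <- per_seed$mean_parent_offspring > per_seed$mean_sibling &
    per_seed$mean_sibling > per_seed$mean_other_kin
  nonkin_null <- abs(per_seed$mean_non_kin) <= 2 * per_seed$se_non_kin + 1e-9
  out <- list(
    n_seeds = nrow(per_seed),
    sign_recovery_estimated = mean(sig_pat("estimated")),
    sign_recovery_measured = mean(sig_pat("measured")),
    interaction_same_sign = mean(same_sign),
    category_ordering = mean(ordering),
    nonkin_within_2se = mean(nonkin_null),
    mean_corr_need = mean(per_seed$corr_need),
    fp_need_i_x_r = mean(per_seed$p_r_x_need_i_estimated < alpha),
    fp_need_j_x_r = mean(per_seed$p_r_x_need_j_estimated < alpha))
  if ("parents_to_children_M" %in% names(per_seed)) {
    out$parents_positive <- mean(per_seed$parents_to_children_M > 0 &
                                   per_seed$parents_to_children_F > 0)
    out$grandparents_positive <-
      mean(per_seed$grandparents_to_grandchildren_M > 0 &
             per_seed$grandparents_to_grandchildren_F > 0)
    out$receipts_peak_juvenile <-
      mean(per_seed$receipt_peak_age < 18, na.rm = TRUE)
  }
  out
}

#' @export
print.replicate_study <- function(x, ...) {
  cat("Replicate study over", x$summary$n_seeds, "seeds\n")
  str(x$summary, give.attr = FALSE)
  invisible(x)
}
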