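# End-to-end analysis on a synthetic cohort: generate -> preprocess ->
# FCS -> CBF -> coupling -> group stats -> mediation. Each stage consumes
# only what the corresponding real-data stage would see (BOLD + motion,
# ASL + PD reference, mask, atlas, demographics).

#' Regional means of a map
#'
#' @param vol a [masked_volume].
#' @param atlas an [atlas_parcellation].
#' @param mask optional common mask.
#' @return Named numeric vector, one mean per region id (`NA` when a region
#'   has no in-mask voxel).
#' @export
region_means <- function(vol, atlas, mask = NULL) {
  if (is.null(mask)) mask <- vol$mask
  lab <- as.vector(atlas$labels)[as.vector(mask)]
  v <- vol$data[mask]
  ids <- atlas$regions$id
  out <- vapply(ids, function(id) {
    i <- lab == id
    if (!any(i)) NA_real_ else mean(v[i])
  }, numeric(1))
  names(out) <- as.character(ids)
  out
}

#' Run the complete analysis on a synthetic cohort
#'
#' Generates a cohort from `spec`, then runs every analysis stage per
#' subject (temporal preprocessing, FCS, single-compartment CBF
#' quantification, smoothed/z-scored CBF-FCS coupling), assembles regional
#' measure matrices, and performs the group inference: demographics table,
#' region-wise Freedman-Lane permutation ANCOVA (age and sex as covariates)
#' for CBF, FCS, and regional coupling, cognition z-scoring, partial
#' correlations of lesion load with each cognitive domain (age, sex,
#' education as covariates), and percentile-bootstrap mediation of the
#' load-cognition relationship through regional CBF.
#'
#' @param spec a [cohort_spec].
#' @param seed optional master seed overriding the spec's.
#' @param fwhm_mm coupling-stage smoothing kernel FWHM (mm).
#' @param n_perm permutations for the region-wise ANCOVA.
#' @param n_boot bootstrap resamples for mediation.
#' @param alpha omnibus significance threshold (default 0.01).
#' @param out_dir optional directory for TSV outputs.
#' @return Object of class `neurocouple_run`.
#' @export
run_all <- function(spec = cohort_spec(), seed = NULL, fwhm_mm = 6,
                    n_perm = 1000, n_boot = 5000, alpha = 0.01,
                    out_dir = NULL) {
  if (!is.null(seed)) spec$seed <- seed
  at <- generate_atlas(spec)
  subjects <- generate_tables(spec)
  n <- nrow(subjects)
  K <- nrow(at$atlas$regions)
  ids <- as.character(at$atlas$regions$id)
  nc_log("run_all", n_subjects = n, n_regions = K, seed = spec$seed)

  cbf_reg <- matrix(NA_real_, n, K, dimnames = list(subjects$id, ids))
  fcs_reg <- matrix(NA_real_, n, K, dimnames = list(subjects$id, ids))
  cpl_reg <- matrix(NA_real_, n, K, dimnames = list(subjects$id, ids))
  global_cpl <- numeric(n)
  global_cbf <- numeric(n)
  global_fcs <- numeric(n)
  fd_mean <- numeric(n)
  motion_pass <- logical(n)

  for (i in seq_len(n)) {
    g <- subjects$group[i]
    bold <- generate_subject_bold(at$atlas, at$mask, spec,
                                  sub_seed(spec$seed, i, 3L))
    motion_pass[i] <- motion_exclusion(bold$motion_params)$pass
    fd_mean[i] <- mean(framewise_displacement(bold$motion_params))
    pre <- preprocess_bold(bold, nuisance_from_bold(bold), spec$n_discard)
    fcs <- compute_fcs(pre, at$mask)
    fcs_z_gen <- zscore_map(fcs)
    cbf_true <- generate_subject_cbf(fcs_z_gen, spec$coupling_by_group[[g]],
                                     group_effect = spec$hub_effect_d[[g]],
                                     atlas = at$atlas,
                                     seed = sub_seed(spec$seed, i, 4L))
    asl <- generate_subject_asl(cbf_true, n_pairs = spec$n_asl_pairs,
                                noise_sd = spec$asl_noise_sd,
                                seed = sub_seed(spec$seed, i, 5L))
    # ---- analysis side: only bold/asl/mask/atlas from here on
    cbf <- estimate_cbf(asl, at$mask)
    cpl <- coupling_analysis(cbf, fcs, at$atlas, at$mask, fwhm_mm,
                             subject_id = subjects$id[i])
    global_cpl[i] <- cpl$global_r
    cpl_reg[i, ] <- cpl$regional$r
    cbf_reg[i, ] <- region_means(cbf, at$atlas, at$mask)
    fcs_reg[i, ] <- region_means(fcs, at$atlas, at$mask)
    global_cbf[i] <- mean(in_mask(cbf))
    global_fcs[i] <- mean(in_mask(fcs))
  }

  subjects$fd_mean <- fd_mean
  subjects$motion_pass <- motion_pass
  covars <- data.frame(age = subjects$age,
                       sex = as.integer(subjects$sex == "M"))

  demo <- demographics_table(subjects,
                             continuous = c(age = "kruskal",
                                            education_years = "kruskal",
                                            fd_mean = "anova"))
  stats_by_measure <- list(
    cbf = region_stats(cbf_reg, subjects$group, covars, n_perm, alpha,
                       seed = sub_seed(spec$seed, 1L, 13L)),
    fcs = region_stats(fcs_reg, subjects$group, covars, n_perm, alpha,
                       seed = sub_seed(spec$seed, 2L, 13L)),
    coupling = region_stats(cpl_reg, subjects$group, covars, n_perm, alpha,
                            seed = sub_seed(spec$seed, 3L, 13L)))

  timed <- names(Filter(function(p) isTRUE(p$timed), spec$cognition))
  domains <- vapply(spec$cognition, `[[`, character(1), "domain")
  cog_z <- zscore_cognition(subjects[, names(spec$cognition)], timed, domains)

  covars3 <- cbind(covars, education = subjects$education_years)
  cog_cor <- do.call(rbind, lapply(names(cog_z), function(d) {
    pc <- partial_correlation(subjects$fazekas_total, cog_z[[d]], covars3)
    data.frame(domain = d, r = pc$r, p = pc$p)
  }))

  # mediator: the CBF region with the strongest group effect
  med_region <- with(stats_by_measure$cbf,
                     region[which.min(ifelse(significant, p_perm, NA))])
  mediations <- list()
  if (length(med_region) == 1 && !is.na(med_region)) {
    mvals <- cbf_reg[, med_region]
    for (d in cog_cor$domain[cog_cor$p < 0.05]) {
      mediations[[d]] <- bootstrap_indirect(
        subjects$fazekas_total, mvals, cog_z[[d]], covars3,
        n_boot = n_boot, seed = sub_seed(spec$seed, match(d, names(cog_z)), 17L))
    }
  }

  cpl_group <- tapply(global_cpl, factor(subjects$group, wmh_groups()), mean)

  res <- structure(list(
    spec = spec, atlas = at$atlas, mask = at$mask, subjects = subjects,
    cognition_z = cog_z, demographics = demo,
    measures = list(cbf = cbf_reg, fcs = fcs_reg, coupling = cpl_reg),
    global = data.frame(id = subjects$id, group = subjects$group,
                        cbf = global_cbf, fcs = global_fcs,
                        coupling = global_cpl),
    coupling_group_means = cpl_group,
    region_stats = stats_by_measure,
    cognition_correlations = cog_cor,
    mediation = mediations, mediator_region = med_region,
    alpha = alpha, n_perm = n_perm, n_boot = n_boot),
    class = "neurocouple_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(demo, file.path(out_dir, "demographics.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (msr in names(stats_by_measure))
      write.table(stats_by_measure[[msr]],
                  file.path(out_dir, sprintf("regionstats_%s.tsv", msr)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$global, file.path(out_dir, "global_measures.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' @export
print.neurocouple_run <- function(x, ...) {
  hubs <- as.character(x$atlas$regions$id[x$atlas$regions$is_hub])
  cat(sprintf("Neurovascular coupling analysis: %d subjects, %d regions (%d hubs)\n",
              nrow(x$subjects), nrow(x$atlas$regions), length(hubs)))
  cat(sprintf("Group-mean global CBF-FCS coupling: %s\n",
              paste(sprintf("%s %.3f", names(x$coupling_group_means),
                            x$coupling_group_means), collapse = ", ")))
  for (msr in names(x$region_stats)) {
    sig <- x$region_stats[[msr]]$region[x$region_stats[[msr]]$significant]
    cat(sprintf("%-9s significant regions (p < %.2g): %s\n", msr, x$alpha,
                if (length(sig)) paste(sig, collapse = " ") else "none"))
  }
  cat(sprintf("Hub regions: %s\n", paste(hubs, collapse = " ")))
  if (length(x$mediation)) {
    cat(sprintf("Mediation through CBF region %s:\n", x$mediator_region))
    for (d in names(x$mediation)) {
      mf <- x$mediation[[d]]
      cat(sprintf("  %-20s indirect = %7.4f [%.4f, %.4f]%s\n", d,
                  mf$indirect, mf$ci_low, mf$ci_high,
                  if (mf$significant) " *" else ""))
    }
  }
  invisible(x)
}

#' Summary of significant regions against the hub set
#'
#' @param run a `neurocouple_run`.
#' @param measure which measure's region stats to summarize.
#' @return list with `significant`, `hubs`, `hub_hits` (hubs detected),
#'   `false_positives` (significant non-hubs).
#' @export
hub_detection <- function(run, measure = "cbf") {
  st <- run$region_stats[[measure]]
  hubs <- as.character(run$atlas$regions$id[run$atlas$regions$is_hub])
  sig <- as.character(st$region[st$significant])
  list(significant = sig, hubs = hubs,
       hub_hits = intersect(sig, hubs),
       false_positives = setdiff(sig, hubs))
}
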