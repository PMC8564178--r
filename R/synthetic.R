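# Synthetic cohort generator. Produces, entirely in code, a cohort with the
# statistical structure the downstream analysis assumes: community-structured
# BOLD, ASL series consistent with a target CBF map under the
# single-compartment model, per-group CBF-FCS coupling strengths, hub-region
# perfusion/connectivity deficits, and a Table-1-style demographics table.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# deterministic per-subject / per-purpose sub-seed from a master seed
sub_seed <- function(seed, i, salt = 0L) {
  (as.numeric(seed) * 1009 + i * 9973 + salt * 31L) %% 2147483647
}

#' Specification of a synthetic cohort
#'
#' Defaults encode the emulated study design: three white-matter-
#' hyperintensity groups of 32/24/30 subjects, BOLD with TR 2 s and 130
#' frames of which the first 10 are discarded, group-wise global CBF-FCS
#' coupling targets of 0.225/0.209/0.156 (mild/moderate/severe), and
#' standardized hub-region CBF/FCS reductions growing with lesion load.
#'
#' @param group_sizes named integer vector, subjects per group.
#' @param atlas_shape length-3 grid dimensions.
#' @param n_regions number of atlas regions.
#' @param hub_fraction fraction of regions flagged as network hubs.
#' @param gm_margin width (voxels) of the non-gray border excluded from the
#'   gray-matter mask; defaults to 1 on grids of at least 12 voxels per axis,
#'   else 0.
#' @param n_frames BOLD frames acquired (including the ones to discard).
#' @param n_discard initial BOLD frames to drop.
#' @param tr_s repetition time in seconds.
#' @param coupling_by_group named vector of target within-subject global
#'   CBF-FCS correlations per group.
#' @param hub_effect_d named vector of standardized hub-region CBF/FCS
#'   reductions (in SD units) per group.
#' @param bold_community_weight weight `w` of the shared community signal in
#'   each voxel's BOLD series (`1 - w` is white noise).
#' @param n_communities number of communities the regions are grouped into.
#' @param n_asl_pairs label/control pairs per ASL series.
#' @param asl_noise_sd additive Gaussian noise SD on ASL frames, in raw
#'   signal units (the noise-free label/control difference at CBF 50 is about
#'   4.5 units at the default proton density of 1000).
#' @param voxel_size_mm voxel edge lengths in mm.
#' @param risk_prevalences 4 x 3 matrix of per-group prevalences (rows
#'   hypertension, diabetes, smoking, drinking; columns mild/moderate/severe).
#' @param demographics list with per-group `age_mean`, `age_sd`,
#'   `male_fraction`, `edu_mean`, `edu_sd`.
#' @param cognition list of per-test generation parameters; timed tests are
#'   on a seconds scale where larger is worse.
#' @param seed master seed; every randomized step derives its own sub-seed
#'   from it, so full generation is bit-reproducible.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(mild = 32, moderate = 24, severe = 30),
                        atlas_shape = c(18, 18, 18),
                        n_regions = 24,
                        hub_fraction = 0.25,
                        gm_margin = if (min(atlas_shape) >= 12) 1L else 0L,
                        n_frames = 130,
                        n_discard = 10,
                        tr_s = 2.0,
                        coupling_by_group = c(mild = 0.225, moderate = 0.209,
                                              severe = 0.156),
                        hub_effect_d = c(mild = 0, moderate = 0.6, severe = 1.2),
                        bold_community_weight = 0.5,
                        n_communities = 4,
                        n_asl_pairs = 20,
                        asl_noise_sd = 1.0,
                        voxel_size_mm = c(3, 3, 3),
                        risk_prevalences = default_risk_prevalences(),
                        demographics = default_demographics(),
                        cognition = default_cognition(),
                        seed = 42) {
  spec <- structure(as.list(environment()), class = "cohort_spec")
  if (any(group_sizes < 3))
    stop_nc("each group needs at least 3 subjects", "nc_validation_error")
  if (any(abs(coupling_by_group) >= 1))
    stop_nc("coupling targets must lie in (-1, 1)", "nc_validation_error")
  if (n_frames <= n_discard)
    stop_nc("n_frames must exceed n_discard", "nc_validation_error")
  if (n_frames - n_discard < 20)
    stop_nc("need at least 20 frames after discard", "nc_validation_error")
  spec
}

default_risk_prevalences <- function() {
  m <- matrix(c(6/32, 17/24, 21/30,
                3/32,  4/24,  8/30,
                5/32,  7/24, 10/30,
                8/32,  3/24,  3/30), nrow = 4, byrow = TRUE,
              dimnames = list(c("hypertension", "diabetes", "smoking", "drinking"),
                              wmh_groups()))
  m
}

default_demographics <- function() {
  list(age_mean = c(mild = 63.69, moderate = 64.33, severe = 66.43),
       age_sd = c(mild = 5.47, moderate = 6.65, severe = 5.07),
       male_fraction = c(mild = 16/32, moderate = 13/24, severe = 18/30),
       edu_mean = c(mild = 10.78, moderate = 11.08, severe = 9.10),
       edu_sd = c(mild = 3.13, moderate = 3.69, severe = 3.89))
}

# Raw-score generation parameters per neuropsychological test. TMT-A/B are
# timed (seconds, larger = worse), exercising the sign flip in the cognition
# z-scoring. Severe-group means sit clearly worst in every domain but
# processing speed, where the moderate group is (as in the emulated design)
# nominally fastest.
default_cognition <- function() {
  list(
    mmse = list(domain = "global_cognition", timed = FALSE,
                mean = c(mild = 27.5, moderate = 27.3, severe = 25.4),
                sd = c(mild = 1.8, moderate = 1.8, severe = 2.4)),
    tmt_a = list(domain = "processing_speed", timed = TRUE,
                 mean = c(mild = 52, moderate = 50, severe = 68),
                 sd = c(mild = 18, moderate = 18, severe = 22)),
    tmt_b = list(domain = "executive_function", timed = TRUE,
                 mean = c(mild = 128, moderate = 132, severe = 175),
                 sd = c(mild = 35, moderate = 40, severe = 45)),
    avlt_recall = list(domain = "episodic_memory", timed = FALSE,
                       mean = c(mild = 6.2, moderate = 5.8, severe = 4.5),
                       sd = c(mild = 1.8, moderate = 2.0, severe = 2.0)),
    vft = list(domain = "language", timed = FALSE,
               mean = c(mild = 16.5, moderate = 15.8, severe = 14.0),
               sd = c(mild = 3.5, moderate = 4.0, severe = 4.0)))
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec: n=%s on %s grid, %d regions, seed %s>\n",
              paste(x$group_sizes, collapse = "/"),
              paste(x$atlas_shape, collapse = "x"), x$n_regions,
              format(x$seed)))
  invisible(x)
}

# near-cubic factorization of n into 3 integers, best-balanced split
factor_triple <- function(n, shape) {
  best <- NULL; best_score <- Inf
  for (a in 1:n) if (n %% a == 0) {
    for (b in 1:(n %/% a)) if ((n %/% a) %% b == 0) {
      trip <- c(a, b, n / (a * b))
      score <- sum((log(trip) - log(shape / mean(shape) * n^(1/3)))^2)
      if (score < best_score) { best <- trip; best_score <- score }
    }
  }
  best
}

#' Generate a block-tiled atlas and gray-matter mask
#'
#' Tiles the in-mask grid with contiguous, roughly equally sized rectangular
#' regions and flags a fraction of them as hubs. Stands in for any labeled
#' parcellation on the analysis grid.
#'
#' @param spec a [cohort_spec].
#' @return list with `atlas` ([atlas_parcellation]) and `mask` (3D logical).
#' @export
generate_atlas <- function(spec) {
  shape <- spec$atlas_shape
  m <- spec$gm_margin
  mask <- array(FALSE, shape)
  idx <- lapply(shape, function(L) (1 + m):(L - m))
  mask[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  inner <- shape - 2 * m
  if (spec$n_regions > prod(inner) / 8)
    stop_nc("tiling infeasible: fewer than 8 voxels per region",
            "nc_tiling_error")
  trip <- factor_triple(spec$n_regions, inner)
  if (any(trip > inner))
    stop_nc("tiling infeasible for this grid shape", "nc_tiling_error")
  # split each axis into trip[k] nearly equal segments
  seg <- lapply(1:3, function(k) {
    cuts <- round(seq(0, inner[k], length.out = trip[k] + 1))
    rep(seq_len(trip[k]), diff(cuts))
  })
  labels <- array(0L, shape)
  block <- outer(seg[[1]], (seg[[2]] - 1) * trip[1], `+`)
  block3 <- outer(block, (seg[[3]] - 1) * trip[1] * trip[2], `+`)
  labels[idx[[1]], idx[[2]], idx[[3]]] <- as.integer(block3)
  n_hub <- max(1L, round(spec$hub_fraction * spec$n_regions))
  hubs <- with_seed(sub_seed(spec$seed, 0L, 1L),
                    sort(sample.int(spec$n_regions, n_hub)))
  regions <- data.frame(id = seq_len(spec$n_regions),
                        name = sprintf("R%03d", seq_len(spec$n_regions)),
                        is_hub = seq_len(spec$n_regions) %in% hubs)
  nc_log("generate_atlas", grid = shape, n_regions = spec$n_regions,
         n_hub = n_hub, seed = spec$seed)
  list(atlas = atlas_parcellation(labels, regions), mask = mask)
}

# region id -> community id, contiguous blocks of regions
region_communities <- function(n_regions, n_communities) {
  cuts <- round(seq(0, n_regions, length.out = n_communities + 1))
  rep(seq_len(n_communities), diff(cuts))
}

#' Generate one subject's community-structured BOLD series
#'
#' Each in-mask voxel's series is `w * latent(community) + (1 - w) * noise`,
#' where regions are grouped into communities sharing a latent time course,
#' so suprathreshold positive correlations concentrate within communities.
#' Motion parameters are bounded random walks; white-matter/CSF nuisance
#' signals are attached as attributes. A positive `group_effect` attenuates
#' the community weight inside hub regions (by a quarter of the standardized
#' effect), so subjects with higher lesion load show reduced hub
#' connectivity strength.
#'
#' @param atlas an [atlas_parcellation].
#' @param mask 3D logical gray-matter mask.
#' @param spec a [cohort_spec].
#' @param subject_seed integer seed for this subject.
#' @param group_effect standardized hub FCS reduction for this subject's
#'   group (0 = none).
#' @return A [bold_series] with attributes `wm_mean` and `csf_mean`.
#' @export
generate_subject_bold <- function(atlas, mask, spec, subject_seed,
                                  group_effect = 0) {
  w <- spec$bold_community_weight
  nt <- spec$n_frames
  comm <- region_communities(spec$n_regions, spec$n_communities)
  lab <- as.vector(atlas$labels)[as.vector(mask)]
  nvox <- length(lab)
  hub_ids <- atlas$regions$id[atlas$regions$is_hub]
  w_vox <- rep(w, nvox)
  if (group_effect > 0)
    w_vox[lab %in% hub_ids] <- w * max(0, 1 - 0.25 * group_effect)
  with_seed(subject_seed, {
    latent <- matrix(rnorm(nt * spec$n_communities), nt)
    vox_comm <- comm[lab]
    sig <- w_vox * t(latent[, vox_comm, drop = FALSE]) +
      (1 - w_vox) * matrix(rnorm(nvox * nt), nvox)
    arr <- array(0, c(dim(mask), nt))
    flat <- matrix(arr, ncol = nt)
    flat[as.vector(mask), ] <- sig
    arr <- array(flat, c(dim(mask), nt))
    steps <- matrix(rnorm(nt * 6, sd = 0.04), nt)
    mp <- apply(steps, 2, cumsum)
    mp <- pmax(pmin(mp, 2.5), -2.5)          # bounded walk, under the 3 mm/deg gate
    wm <- as.numeric(stats::filter(rnorm(nt), 0.8, method = "recursive"))
    csf <- as.numeric(stats::filter(rnorm(nt), 0.8, method = "recursive"))
    bold <- bold_series(arr, tr_s = spec$tr_s, motion_params = mp,
                        voxel_size_mm = spec$voxel_size_mm)
    attr(bold, "wm_mean") <- wm
    attr(bold, "csf_mean") <- csf
    bold
  })
}

#' Generate a CBF map coupled to an FCS z-map
#'
#' Induces a target voxelwise CBF-FCS correlation `rho` on z-maps
#' (`cbf_z = rho * fcs_z + sqrt(1 - rho^2) * noise`), rescales to a mean of
#' 50 and SD of 10 ml/100g/min within the mask, then reduces hub-region
#' values by `group_effect` standard deviations. Because the coupling is
#' induced on z-maps and only affine maps follow, `rho` is exactly the
#' population value of the global coupling statistic.
#'
#' @param fcs_zmap z-scored FCS [masked_volume].
#' @param rho target correlation, |rho| < 1.
#' @param group_effect standardized hub CBF reduction (SD units).
#' @param atlas [atlas_parcellation] supplying the hub flags (may be `NULL`
#'   when `group_effect` is 0).
#' @param seed integer seed.
#' @return CBF [masked_volume] in ml/100g/min (floored at 0).
#' @export
generate_subject_cbf <- function(fcs_zmap, rho, group_effect = 0, atlas = NULL,
                                 seed = 1) {
  if (abs(rho) >= 1)
    stop_nc("|rho| must be < 1", "nc_validation_error")
  mask <- fcs_zmap$mask
  fz <- fcs_zmap$data[mask]
  with_seed(seed, {
    eps <- rnorm(length(fz))
    cz <- rho * fz + sqrt(1 - rho^2) * eps
    cz <- (cz - mean(cz)) / sd(cz)
    cbf <- 50 + 10 * cz
    if (group_effect != 0) {
      if (is.null(atlas))
        stop_nc("atlas required for a hub effect", "nc_validation_error")
      hub_ids <- atlas$regions$id[atlas$regions$is_hub]
      hub <- as.vector(atlas$labels)[as.vector(mask)] %in% hub_ids
      cbf[hub] <- cbf[hub] - group_effect * 10
    }
    out <- fcs_zmap$data * 0
    out[mask] <- pmax(cbf, 0)
    masked_volume(out, mask, fcs_zmap$voxel_size_mm)
  })
}

#' Generate an ASL series encoding a CBF map
#'
#' Inverts the single-compartment quantification: the expected control-label
#' difference satisfies [quantify_cbf()] exactly, so quantification of the
#' generated series recovers the input map (exactly at zero noise, unbiasedly
#' under additive Gaussian frame noise).
#'
#' @param cbf_map nonnegative CBF [masked_volume], ml/100g/min.
#' @param acq_params pCASL parameters, see [asl_params()].
#' @param n_pairs number of label/control pairs.
#' @param noise_sd additive Gaussian noise SD per frame.
#' @param seed integer seed.
#' @param pd_value proton-density reference level (raw signal units).
#' @return An [asl_series].
#' @export
generate_subject_asl <- function(cbf_map, acq_params = asl_params(),
                                 n_pairs = 20, noise_sd = 1, seed = 1,
                                 pd_value = 1000) {
  if (any(in_mask(cbf_map) < 0))
    stop_nc("CBF map must be nonnegative", "nc_validation_error")
  check_asl_params(acq_params)
  dims <- dim(cbf_map$data)
  pd <- array(pd_value, dims)
  dm <- cbf_map$data / cbf_scaling_factor(acq_params, pd)   # exact inverse
  base <- pd * 0.5
  nf <- 2L * n_pairs
  tags <- rep(c("control", "label"), n_pairs)
  with_seed(seed, {
    frames <- array(rnorm(prod(dims) * nf, sd = noise_sd), c(dims, nf))
    for (k in seq_len(nf)) {
      s <- if (tags[k] == "control") 0.5 else -0.5
      frames[, , , k] <- frames[, , , k] + base + s * dm
    }
    asl_series(frames, tags, pd, acq_params, cbf_map$voxel_size_mm)
  })
}

#' Generate a Table-1-style demographics and cognition table
#'
#' Per group: total Fazekas scores uniform within the group's band, ages,
#' education and raw cognition scores Gaussian with the group parameters, sex
#' and vascular risk factors Bernoulli with the group prevalences.
#'
#' @param spec a [cohort_spec].
#' @param seed integer seed (defaults to the spec's).
#' @return data.frame with one row per subject.
#' @export
generate_tables <- function(spec, seed = spec$seed) {
  bands <- list(mild = 1:2, moderate = 3:4, severe = 5:6)
  with_seed(sub_seed(seed, 0L, 2L), {
    rows <- lapply(wmh_groups(), function(g) {
      n <- spec$group_sizes[[g]]
      d <- spec$demographics
      df <- data.frame(
        id = character(n), group = g,
        fazekas_total = sample(bands[[g]], n, replace = TRUE),
        age = rnorm(n, d$age_mean[[g]], d$age_sd[[g]]),
        sex = ifelse(runif(n) < d$male_fraction[[g]], "M", "F"),
        education_years = pmax(5, rnorm(n, d$edu_mean[[g]], d$edu_sd[[g]])),
        stringsAsFactors = FALSE)
      for (rf in rownames(spec$risk_prevalences))
        df[[rf]] <- runif(n) < spec$risk_prevalences[rf, g]
      for (ts in names(spec$cognition)) {
        p <- spec$cognition[[ts]]
        df[[ts]] <- rnorm(n, p$mean[[g]], p$sd[[g]])
      }
      df
    })
    df <- do.call(rbind, rows)
    df$id <- sprintf("S%03d", seq_len(nrow(df)))
    df$group <- as.character(fazekas_group(df$fazekas_total))
    nc_log("generate_tables", n = nrow(df), seed = seed)
    df
  })
}

#' Generate a complete synthetic cohort
#'
#' Runs the whole generator: atlas + mask, demographics table, and per
#' subject a BOLD series, its FCS z-map, a CBF map coupled to that FCS with
#' the subject's group coupling target and hub deficit, and an ASL series
#' encoding the CBF map. With `out_dir` set, everything is written to disk
#' (NIfTI volumes, TSV tables, and a `config.yaml` that [load_cohort()] can
#' read back); otherwise volumes are returned in memory.
#'
#' @param spec a [cohort_spec].
#' @param out_dir optional output directory.
#' @param keep_volumes with `out_dir` set, also keep volumes in memory.
#' @return Object of class `synthetic_cohort`: list with `spec`, `atlas`,
#'   `mask`, `subjects` (table), and per-subject `bold`, `cbf`, `asl`,
#'   `fcs_z` lists (unless written out only).
#' @export
simulate_cohort <- function(spec = cohort_spec(), out_dir = NULL,
                            keep_volumes = is.null(out_dir)) {
  at <- generate_atlas(spec)
  subjects <- generate_tables(spec)
  n <- nrow(subjects)
  nc_log("simulate_cohort", n_subjects = n, grid = spec$atlas_shape,
         seed = spec$seed)
  bold_l <- vector("list", n); cbf_l <- vector("list", n)
  asl_l <- vector("list", n); fcs_l <- vector("list", n)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n)) {
    g <- subjects$group[i]
    bold <- generate_subject_bold(at$atlas, at$mask, spec,
                                  sub_seed(spec$seed, i, 3L))
    pre <- preprocess_bold(bold, nuisance = nuisance_from_bold(bold),
                           n_discard = spec$n_discard)
    fcs <- compute_fcs(pre, at$mask)
    fcs_z <- zscore_map(fcs)
    cbf <- generate_subject_cbf(fcs_z, spec$coupling_by_group[[g]],
                                group_effect = spec$hub_effect_d[[g]],
                                atlas = at$atlas,
                                seed = sub_seed(spec$seed, i, 4L))
    asl <- generate_subject_asl(cbf, n_pairs = spec$n_asl_pairs,
                                noise_sd = spec$asl_noise_sd,
                                seed = sub_seed(spec$seed, i, 5L))
    if (!is.null(out_dir)) {
      id <- subjects$id[i]
      write_volume(bold, file.path(out_dir, paste0(id, "_bold.nii.gz")))
      write_volume(cbf, file.path(out_dir, paste0(id, "_cbf.nii.gz")))
      write_volume(asl_to_4d(asl), file.path(out_dir, paste0(id, "_asl.nii.gz")))
      write_volume(asl$pd_reference, file.path(out_dir, paste0(id, "_pd.nii.gz")))
    }
    if (keep_volumes) {
      bold_l[[i]] <- bold; cbf_l[[i]] <- cbf; asl_l[[i]] <- asl; fcs_l[[i]] <- fcs_z
    }
  }
  if (!is.null(out_dir)) {
    write.table(subjects, file.path(out_dir, "cohort.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_volume(masked_volume(array(as.numeric(at$mask), dim(at$mask)),
                               voxel_size_mm = spec$voxel_size_mm),
                 file.path(out_dir, "mask.nii.gz"))
    write_volume(at$atlas, file.path(out_dir, "atlas.nii.gz"))
    write_regions(at$atlas$regions, file.path(out_dir, "regions.tsv"))
    cfg <- list(cohort = "cohort.tsv", mask = "mask.nii.gz",
                atlas = "atlas.nii.gz", regions = "regions.tsv",
                volumes = list(bold = "{id}_bold.nii.gz",
                               cbf = "{id}_cbf.nii.gz"))
    yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  }
  structure(list(spec = spec, atlas = at$atlas, mask = at$mask,
                 subjects = subjects, bold = bold_l, cbf = cbf_l,
                 asl = asl_l, fcs_z = fcs_l, out_dir = out_dir),
            class = "synthetic_cohort")
}

asl_to_4d <- function(asl) {
  bold_series(asl$frames, tr_s = 1, voxel_size_mm = asl$voxel_size_mm)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d subjects on %s grid>\n",
              nrow(x$subjects), paste(dim(x$mask), collapse = "x")))
  invisible(x)
}

# nuisance regressors carried by a generated BOLD series
nuisance_from_bold <- function(bold) {
  nuisance_set(linear_trend = TRUE,
               wm_mean = attr(bold, "wm_mean"),
               csf_mean = attr(bold, "csf_mean"),
               motion_regressors = bold$motion_params)
}
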