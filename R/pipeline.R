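#' Assemble and validate a pipeline run configuration
#'
#' Collects the fixed constants of the analysis chain — the 0.5 mask
#' re-binarization threshold, the 0.2/0.5 GM probability cut-offs, the
#' 4 mm (prior building) and 6 mm (statistics) smoothing kernels, the
#' permutation count and FWE level — together with cohort and seed
#' settings. Values can be overridden from a YAML file via `config_file`.
#'
#' @param out_dir Output directory for artifacts.
#' @param n_subjects Cohort size; default 5.
#' @param seed Master seed; default 1.
#' @param age_range Cohort age range (years); default `c(21, 88)`.
#' @param channel Channel segmented in the LOO stage; default `"mt"`.
#' @param mask_threshold Warp re-binarization threshold; default 0.5.
#' @param gm_thresholds GM probability cut-offs; default `c(0.2, 0.5)`.
#' @param mbp_fwhm_mm Prior-building smoothing FWHM; default 4.
#' @param stats_fwhm_mm Statistics smoothing FWHM; default 6.
#' @param n_perm Permutations for FWE control; default 1000.
#' @param alpha FWE level; default 0.05.
#' @param n_raters Simulated raters; default 4.
#' @param flip_prob Rater boundary flip probability; default 0.1.
#' @param config_file Optional YAML file whose top-level keys override the
#'   above.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir = "subprior_out", n_subjects = 5L, seed = 1L,
                       age_range = c(21, 88), channel = "mt",
                       mask_threshold = 0.5, gm_thresholds = c(0.2, 0.5),
                       mbp_fwhm_mm = 4, stats_fwhm_mm = 6,
                       n_perm = 1000L, alpha = 0.05,
                       n_raters = 4L, flip_prob = 0.1,
                       config_file = NULL) {
  cfg <- list(out_dir = out_dir, n_subjects = n_subjects, seed = seed,
              age_range = age_range, channel = channel,
              mask_threshold = mask_threshold,
              gm_thresholds = gm_thresholds,
              mbp_fwhm_mm = mbp_fwhm_mm, stats_fwhm_mm = stats_fwhm_mm,
              n_perm = n_perm, alpha = alpha,
              n_raters = n_raters, flip_prob = flip_prob)
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) stop("config file not found: ", config_file)
    over <- yaml::read_yaml(config_file)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) > 0) {
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(over)] <- over
  }
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  bad <- function(field, why) {
    stop("invalid config field '", field, "': ", why, call. = FALSE)
  }
  if (cfg$mask_threshold <= 0 || cfg$mask_threshold >= 1) {
    bad("mask_threshold", "must be in (0,1)")
  }
  for (th in cfg$gm_thresholds) {
    if (th <= 0 || th >= 1) bad("gm_threshold", "must be in (0,1)")
  }
  if (cfg$alpha <= 0 || cfg$alpha > 1) bad("alpha", "must be in (0,1]")
  if (cfg$n_subjects < 3) bad("n_subjects", "must be >= 3")
  if (cfg$mbp_fwhm_mm < 0) bad("mbp_fwhm_mm", "must be >= 0")
  if (cfg$stats_fwhm_mm < 0) bad("stats_fwhm_mm", "must be >= 0")
  if (cfg$flip_prob < 0 || cfg$flip_prob >= 0.5) {
    bad("flip_prob", "must be in [0, 0.5)")
  }
  if (cfg$n_perm < 1) bad("n_perm", "must be >= 1")
  invisible(TRUE)
}

write_sidecar <- function(cfg, stage, files) {
  tmp <- tempfile()
  writeLines(yaml::as.yaml(unclass(cfg)), tmp)
  side <- list(
    stage = stage,
    config = unclass(cfg),
    config_md5 = unname(tools::md5sum(tmp)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("subprior")),
    outputs = files
  )
  unlink(tmp)
  path <- file.path(cfg$out_dir, paste0(stage, ".json"))
  jsonlite::write_json(side, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run pipeline stages on a phantom cohort
#'
#' Chains the package's stages end-to-end on a deterministic phantom
#' cohort: `phantom` (generate and write the cohort), `build-tpm`
#' (conventional priors, nucleus probability map, merged priors),
#' `agree` (inter-rater agreement table), `r2star` (per-subject nucleus
#' R2* from simulated multi-echo data), `loo` (leave-one-out validation
#' table and tests), `vbm` (cohort age-bias analysis), or `all`. Every
#' stage writes its tabular outputs as CSV plus a JSON sidecar recording
#' the full configuration, its MD5, the seed and the package version, so
#' any artifact is reproducible from its sidecar alone. On failure the
#' stage's partial outputs are removed.
#'
#' @param config A `run_config`.
#' @param stage One of `"phantom"`, `"build-tpm"`, `"agree"`, `"r2star"`,
#'   `"loo"`, `"vbm"`, `"all"`.
#' @return Invisible list of per-stage results.
#' @export
run_pipeline <- function(config, stage = "all") {
  stopifnot(inherits(config, "run_config"))
  stages <- c("phantom", "build-tpm", "agree", "r2star", "loo", "vbm")
  stage <- match.arg(stage, c(stages, "all"))
  todo <- if (stage == "all") stages else stage
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- make_age_cohort(
    n_subjects = config$n_subjects, age_range = config$age_range,
    seed = config$seed, n_raters = config$n_raters,
    flip_prob = config$flip_prob,
    out_dir = if ("phantom" %in% todo) file.path(config$out_dir, "cohort")
  )
  base_tpm <- make_base_tpm(cohort$spec)
  results <- list()

  run_stage <- function(name, fn) {
    written <- character(0)
    note <- function(p) { written <<- c(written, p); p }
    res <- tryCatch(fn(note), error = function(e) {
      unlink(written)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    write_sidecar(config, name, written)
    res
  }

  for (st in todo) {
    results[[st]] <- switch(st,
      "phantom" = run_stage("phantom", function(note) {
        note(file.path(config$out_dir, "cohort", "manifest.csv"))
        note(file.path(config$out_dir, "cohort", "covars.csv"))
        cohort
      }),
      "build-tpm" = run_stage("build-tpm", function(note) {
        warped <- warp_cohort_masks(cohort, config$mask_threshold)
        mbp <- mbp_from_warped_masks(warped, config$mbp_fwhm_mm)
        new_tpm <- merge_into_tpm(base_tpm, mbp)
        note(write_volume(mbp, file.path(config$out_dir, "mbp.nii.gz")))
        for (p in write_tpm(new_tpm, file.path(config$out_dir, "newtpm"))) {
          note(p)
        }
        list(mbp = mbp, new_tpm = new_tpm)
      }),
      "agree" = run_stage("agree", function(note) {
        rows <- list()
        for (s in cohort$subjects) {
          for (nm in names(s$raters)) {
            rows[[length(rows) + 1L]] <- cbind(
              subject = s$id,
              pairwise_summary(s$raters[[nm]], structure = nm)
            )
          }
        }
        tab <- do.call(rbind, rows)
        utils::write.csv(tab,
                         note(file.path(config$out_dir, "agreement.csv")),
                         row.names = FALSE)
        tab
      }),
      "r2star" = run_stage("r2star", function(note) {
        rows <- lapply(cohort$subjects, function(s) {
          nuc <- s$phantom$nuclei_masks[[cohort$spec$iron$structure]]
          series <- simulate_multiecho(
            s$phantom$r2s_true,
            as_volume(array(100, dim = cohort$spec$grid_shape),
                      cohort$spec$affine),
            noise_sd = 2, seed = config$seed + match(s$id, cohort$covariates$subject))
          fit <- fit_r2star(series, nuc)
          data.frame(subject = s$id, age = s$age,
                     r2s_nucleus = mean(fit$r2star$data[nuc$data == 1],
                                        na.rm = TRUE),
                     r2s_true = s$phantom$nucleus_r2s)
        })
        tab <- do.call(rbind, rows)
        utils::write.csv(tab, note(file.path(config$out_dir, "r2star.csv")),
                         row.names = FALSE)
        tab
      }),
      "loo" = run_stage("loo", function(note) {
        val <- loo_validate(cohort, base_tpm, channel = config$channel,
                            mbp_fwhm_mm = config$mbp_fwhm_mm,
                            mask_threshold = config$mask_threshold,
                            gm_thresholds = config$gm_thresholds,
                            seed = config$seed)
        utils::write.csv(val$records,
                         note(file.path(config$out_dir, "validation.csv")),
                         row.names = FALSE)
        utils::write.csv(val$tests,
                         note(file.path(config$out_dir, "validation_tests.csv")),
                         row.names = FALSE)
        val
      }),
      "vbm" = run_stage("vbm", function(note) {
        ab <- age_bias_analysis(cohort, base_tpm,
                                mbp_fwhm_mm = config$mbp_fwhm_mm,
                                smooth_fwhm_mm = config$stats_fwhm_mm,
                                seed = config$seed)
        utils::write.csv(ab$volumes,
                         note(file.path(config$out_dir, "vbm_volumes.csv")),
                         row.names = FALSE)
        summ <- data.frame(
          slope_old = ab$slope_old, slope_new = ab$slope_new,
          t_age_old = ab$t_age_old, t_age_new = ab$t_age_new,
          beta_r2s = ab$r2s_regression$beta,
          t_beta_r2s = ab$r2s_regression$t_beta,
          r2s_age_slope = ab$r2s_age_fit$slope,
          r2s_age_t = ab$r2s_age_fit$t
        )
        utils::write.csv(summ,
                         note(file.path(config$out_dir, "vbm_summary.csv")),
                         row.names = FALSE)
        ab
      })
    )
  }
  invisible(results)
}
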