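#' Configuration of an end-to-end analysis run
#'
#' Bundles the inputs (a [simulation_config()] or paths to the three
#' TSV inputs), the clock specifications, and the EWAS thresholds. The
#' strict significance threshold defaults to `1e-4`, the value used for
#' within-species full-lifespan EWAS; cross-species conserved-probe
#' runs conventionally use `0.005`.
#'
#' @param simulation A [simulation_config()] describing the dataset to
#'   generate, or `NULL` when `input_paths` is given.
#' @param input_paths Optional named list with `beta`, `samples`,
#'   `constants`, `annotation` TSV paths.
#' @param clocks List of clock specs, each a list with `name` and
#'   `transform` (`"identity"`, `"relative"`, `"loglinear"`).
#' @param p_strict Strict EWAS threshold (default 1e-4).
#' @param p_lenient Lenient threshold for sector plots (default 0.05).
#' @param k_per_direction Top-CpG count per direction (default 500).
#' @param enrichment_features Annotation features to test for
#'   enrichment in top CpGs.
#' @param age_windows Which age windows to screen: any of `"all"`,
#'   `"development"` (age <= `development_cutoff_years`), `"adult"`
#'   (age > species maturity).
#' @param development_cutoff_years Development window upper bound
#'   (default 6 weeks = 6/52 years).
#' @param seed Global seed; every stage derives its seed from it.
#' @return A `run_config` list.
#' @export
run_config <- function(simulation = default_run_simulation(),
                       input_paths = NULL,
                       clocks = list(list(name = "pan_tissue",
                                          transform = "identity")),
                       p_strict = 1e-4,
                       p_lenient = 0.05,
                       k_per_direction = 500L,
                       enrichment_features = c("island_flag", "tss_category",
                                               "prc2_bound"),
                       age_windows = "all",
                       development_cutoff_years = 6 / 52,
                       seed = 1L) {
  stopifnot(p_strict > 0, p_strict < p_lenient, p_lenient < 1,
            k_per_direction > 0,
            all(age_windows %in% c("all", "development", "adult")))
  structure(list(simulation = simulation, input_paths = input_paths,
                 clocks = clocks, p_strict = p_strict,
                 p_lenient = p_lenient,
                 k_per_direction = as.integer(k_per_direction),
                 enrichment_features = enrichment_features,
                 age_windows = age_windows,
                 development_cutoff_years = development_cutoff_years,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Default two-species simulation used by [run_config()]
#'
#' A desk-scale two-species, three-tissue design: a short-lived
#' marsupial-like species and a mouse-like species, 10 samples per
#' species-tissue stratum, 4000 probes.
#'
#' @return A [simulation_config()].
#' @export
default_run_simulation <- function() {
  simulation_config(
    species = data.frame(species = c("opossum", "mouse"),
                         max_lifespan_years = c(4.2, 4.0),
                         maturity_years = c(0.5, 0.16),
                         n_per_tissue = c(10, 10)),
    tissues = c("ear", "liver", "tail"),
    n_probes = 4000
  )
}

#' Restrict a sample sheet to an age window
#'
#' `"development"` keeps samples aged at most the cutoff (default 6
#' weeks); `"adult"` keeps samples older than their species' average
#' age at sexual maturity; `"all"` keeps everything.
#'
#' @param samples Sample sheet.
#' @param window One of `"all"`, `"development"`, `"adult"`.
#' @param development_cutoff_years Upper age bound of the development
#'   window.
#' @return The row-subset sample sheet.
#' @export
stratify_age_window <- function(samples,
                                window = c("all", "development", "adult"),
                                development_cutoff_years = 6 / 52) {
  window <- match.arg(window)
  keep <- switch(window,
                 all = rep(TRUE, nrow(samples)),
                 development = samples$age_years <= development_cutoff_years,
                 adult = samples$age_years > samples$maturity_years)
  samples[keep, , drop = FALSE]
}

#' Overlap between development- and aging-related top CpGs
#'
#' Selects the top `k` CpGs per direction from each screen (at
#' `p_threshold`) and reports the fraction of the top aging CpGs that
#' also appear among the top development CpGs, per direction and
#' combined — the statistic contrasting the epigenetic programs of
#' development and later aging.
#'
#' @param ewas_dev,ewas_aging [correlation_screen()] outputs on a
#'   shared probe universe.
#' @param k Top CpGs per direction (default 500).
#' @param p_threshold Selection threshold (default 0.005).
#' @return List with per-direction and combined counts and overlap
#'   percentages (percent of the top aging set).
#' @export
compare_development_vs_aging <- function(ewas_dev, ewas_aging, k = 500L,
                                         p_threshold = 0.005) {
  top_dev <- select_top_cpgs(ewas_dev, k, p_threshold)
  top_age <- select_top_cpgs(ewas_aging, k, p_threshold)
  if (length(c(top_age$up, top_age$down)) == 0L ||
      length(c(top_dev$up, top_dev$down)) == 0L) {
    stop("empty top set in one of the screens")
  }
  pct <- function(aging, dev) {
    n <- length(aging)
    if (n == 0L) return(list(n_aging = 0L, n_overlap = 0L, percent = NA_real_))
    ov <- length(intersect(aging, dev))
    list(n_aging = n, n_overlap = ov, percent = round(100 * ov / n, 1))
  }
  list(up = pct(top_age$up, top_dev$up),
       down = pct(top_age$down, top_dev$down),
       combined = pct(c(top_age$up, top_age$down),
                      c(top_dev$up, top_dev$down)))
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> QC -> per-stratum EWAS (+ optional age
#' windows) -> Stouffer meta per species -> pairwise sector tables and
#' z concordance -> Venn overlaps of top CpGs -> enrichment -> clock
#' LOOCV, writing every result as TSV/JSON under `out_dir` together
#' with a machine-readable `summary.json` and a run log. Reruns with
#' the same configuration and seed reproduce the summary byte for
#' byte.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The summary list, invisibly; all files are under `out_dir`.
#' @export
run_full_analysis <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- c(sprintf("crossclock run, seed %d", config$seed),
                 sprintf("R %s, glmnet %s", getRversion(),
                         as.character(utils::packageVersion("glmnet"))))

  ## inputs
  if (!is.null(config$input_paths)) {
    beta <- read_beta_matrix(config$input_paths$beta)
    samples <- read_sample_sheet(config$input_paths$samples,
                                 config$input_paths$constants)
    annotation <- read_probe_annotation(config$input_paths$annotation)
    log_lines <- c(log_lines, "inputs: files")
  } else {
    sim <- config$simulation
    sim$seed <- config$seed
    dataset <- simulate_dataset(sim)
    beta <- dataset$beta
    samples <- dataset$samples
    annotation <- dataset$annotation
    log_lines <- c(log_lines,
                   sprintf("inputs: simulated (%d probes, %d samples, %s)",
                           nrow(beta), ncol(beta), sim$island_aging_mode))
  }
  summary <- list(seed = config$seed,
                  n_probes = nrow(beta), n_samples = ncol(beta))

  ## QC per species
  summary$qc <- lapply(split(samples$sample_id, samples$species), function(ids) {
    qc_report(beta[, ids, drop = FALSE], samples, seed = config$seed)
  })

  ## per-stratum EWAS
  strata <- unique(samples[c("species", "tissue")])
  screens <- list()
  for (w in config$age_windows) {
    sub_sheet <- stratify_age_window(samples, w,
                                     config$development_cutoff_years)
    for (i in seq_len(nrow(strata))) {
      sp <- strata$species[i]; ti <- strata$tissue[i]
      ids <- sub_sheet$sample_id[sub_sheet$species == sp &
                                   sub_sheet$tissue == ti]
      if (length(ids) < 4L) next
      key <- paste(sp, ti, w, sep = ".")
      scr <- correlation_screen(beta[, ids, drop = FALSE], sub_sheet)
      screens[[key]] <- scr
      write_tsv(scr, file.path(out_dir, paste0("ewas_", key, ".tsv")))
      write_tsv(manhattan_table(scr, annotation),
                file.path(out_dir, paste0("manhattan_", key, ".tsv")))
      write_tsv(data.frame(sample_id = ids),
                file.path(out_dir, paste0("samples_", key, ".tsv")))
    }
  }
  summary$n_significant <- lapply(screens, function(s) {
    sum(s$valid & s$p < config$p_strict)
  })

  ## meta-analysis across tissues, per species (window "all")
  all_keys <- grep("\\.all$", names(screens), value = TRUE)
  for (sp in unique(strata$species)) {
    keys <- all_keys[startsWith(all_keys, paste0(sp, "."))]
    if (length(keys) < 2L) next
    meta <- stouffer_meta(screens[keys])
    write_tsv(meta, file.path(out_dir, paste0("meta_", sp, ".tsv")))
    summary$n_significant_meta[[sp]] <- sum(meta$valid &
                                              meta$p_meta < config$p_strict)
  }

  ## top CpGs, Venn, sectors, concordance (window "all")
  tops <- lapply(screens[all_keys], select_top_cpgs,
                 k_per_direction = config$k_per_direction,
                 p_threshold = config$p_strict)
  top_sets <- lapply(tops, function(t) c(t$up, t$down))
  if (length(top_sets) >= 2L) {
    venn_sets <- top_sets[seq_len(min(4L, length(top_sets)))]
    names(venn_sets) <- sub("\\.all$", "", names(venn_sets))
    write_tsv(overlap_counts(venn_sets), file.path(out_dir, "venn.tsv"))
  }
  if (length(all_keys) >= 2L) {
    pairs <- utils::combn(all_keys, 2L, simplify = FALSE)
    conc <- lapply(pairs, function(pr) {
      a <- screens[[pr[1L]]]; b <- screens[[pr[2L]]]
      common <- intersect(a$probe_id[a$valid], b$probe_id[b$valid])
      za <- a$z[match(common, a$probe_id)]
      zb <- b$z[match(common, b$probe_id)]
      sect <- sector_classify(za, zb, config$p_strict, config$p_lenient)
      write_tsv(data.frame(probe_id = common, z_x = za, z_y = zb,
                           sector = as.character(sect)),
                file.path(out_dir, sprintf("sectors_%s_vs_%s.tsv",
                                           sub("\\.all$", "", pr[1L]),
                                           sub("\\.all$", "", pr[2L]))))
      as.numeric(zscore_concordance(za, zb))
    })
    names(conc) <- vapply(pairs, function(pr) {
      paste(sub("\\.all$", "", pr), collapse = "_vs_")
    }, character(1L))
    summary$z_concordance <- conc
  }

  ## enrichment per stratum (window "all")
  background <- annotation$probe_id[annotation$probe_id %in% rownames(beta)]
  for (key in all_keys) {
    for (dir_name in c("up", "down")) {
      top <- tops[[key]][[dir_name]]
      if (length(top) == 0L) next
      for (feat in config$enrichment_features) {
        enr <- feature_fisher_enrichment(top, background, annotation,
                                         feature = feat,
                                         direction = dir_name)
        write_tsv(enr, file.path(out_dir,
                                 sprintf("enrichment_%s_%s_%s.tsv",
                                         sub("\\.all$", "", key), feat,
                                         dir_name)))
      }
    }
    scr <- screens[[key]]
    flags <- annotation$island_flag[match(scr$probe_id, annotation$probe_id)]
    shift <- tryCatch(island_shift_test(scr$z[scr$valid], flags[scr$valid]),
                      error = function(e) NULL)
    if (!is.null(shift)) {
      summary$island_shift[[sub("\\.all$", "", key)]] <-
        list(t = shift$t, p = shift$p)
    }
  }

  ## clocks
  for (spec in config$clocks) {
    transform <- age_transform(spec$transform)
    loo <- loocv_evaluate(beta, samples, transform = transform,
                          seed = config$seed)
    write_tsv(loo$predictions,
              file.path(out_dir, paste0("loocv_", spec$name, ".tsv")))
    model <- fit_clock(beta, samples, transform = transform,
                       seed = config$seed)
    write_clock_model(model, file.path(out_dir,
                                       paste0("clock_", spec$name, ".json")))
    summary$clocks[[spec$name]] <- list(
      transform = spec$transform,
      loocv_r = loo$evaluation$pearson_r,
      loocv_mae = loo$evaluation$median_abs_error,
      n = loo$evaluation$n,
      n_nonzero = length(model$coefficients))
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_echo <- config
  cfg_echo$simulation <- unclass(cfg_echo$simulation)
  log_lines <- c(log_lines, "config:",
                 jsonlite::toJSON(unclass(cfg_echo), auto_unbox = TRUE,
                                  digits = NA, null = "null"))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(summary)
}
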