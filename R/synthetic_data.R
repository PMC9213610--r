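#' Configuration for the methylation simulator
#'
#' Describes a multi-species, multi-tissue methylation study with a
#' known fraction of age-related probes. Age enters every age-related
#' probe through relative age (age / species maximum lifespan) on the
#' logit scale, so that species with very different lifespans share
#' methylation trajectories by construction — the premise a relative-age
#' clock exploits. Observed betas are Beta-distributed around the model
#' mean, respecting the \[0, 1\] support.
#'
#' `island_aging_mode` controls how aging couples to annotation:
#' \describe{
#'   \item{`"placental_like"`}{age-related probes are drawn from all
#'     probes and those in CpG islands bound by PRC2 are forced to gain
#'     methylation with age (positive slope), producing the island/PRC2
#'     methylation gain seen in placental mammals and most marsupials.}
#'   \item{`"opossum_like"`}{age-related probes are drawn outside the
#'     island-and-PRC2 stratum (its true slopes are exactly zero) and all
#'     slope signs are symmetric coin flips, so islands show no
#'     systematic gain — the opossum pattern.}
#' }
#'
#' @param species data.frame with columns `species`,
#'   `max_lifespan_years`, `maturity_years`, `n_per_tissue`.
#' @param tissues Character vector of tissue labels.
#' @param n_probes Number of probes.
#' @param frac_age_related Fraction of probes with a true age effect.
#' @param slope_range Magnitude range (logit units per unit relative
#'   age) of true slopes.
#' @param frac_island Fraction of probes flagged as CpG-island.
#' @param frac_prc2 Fraction flagged PRC2-bound (independent of island).
#' @param island_aging_mode `"placental_like"` or `"opossum_like"`.
#' @param noise_precision Beta precision phi; observed beta ~
#'   Beta(mu*phi, (1-mu)*phi).
#' @param baseline_logit_sd SD of per-probe baseline logits, drawn
#'   independently per species x tissue (creates the tissue/species
#'   separation seen in clustering QC).
#' @param seed Integer seed; one seeded generator drives all draws.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(species = data.frame(
                                species = "opossum",
                                max_lifespan_years = 4.2,
                                maturity_years = 0.5,
                                n_per_tissue = 40),
                              tissues = c("ear", "liver"),
                              n_probes = 2000,
                              frac_age_related = 0.1,
                              slope_range = c(1, 3),
                              frac_island = 0.5,
                              frac_prc2 = 0.3,
                              island_aging_mode = c("opossum_like",
                                                    "placental_like"),
                              noise_precision = 50,
                              baseline_logit_sd = 1,
                              seed = 1L) {
  island_aging_mode <- match.arg(island_aging_mode)
  stopifnot(
    is.data.frame(species),
    all(c("species", "max_lifespan_years", "maturity_years",
          "n_per_tissue") %in% names(species)),
    n_probes >= 1,
    frac_age_related >= 0, frac_age_related <= 1,
    length(slope_range) == 2L, slope_range[1L] <= slope_range[2L],
    all(slope_range > 0),
    frac_island >= 0, frac_island <= 1,
    frac_prc2 >= 0, frac_prc2 <= 1,
    noise_precision > 0,
    baseline_logit_sd > 0
  )
  structure(list(species = species, tissues = tissues, n_probes = n_probes,
                 frac_age_related = frac_age_related,
                 slope_range = slope_range, frac_island = frac_island,
                 frac_prc2 = frac_prc2, island_aging_mode = island_aging_mode,
                 noise_precision = noise_precision,
                 baseline_logit_sd = baseline_logit_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

CHROMATIN_STATES <- c("TSS", "PromF", "BivProm", "ReprPC", "EnhA", "Tx",
                      "Quies")

#' Simulate a multi-species methylation dataset with known age effects
#'
#' For sample i and probe j the model mean is
#' `mu_ij = plogis(b0_j(species_i, tissue_i) + s_j * g(age_i))` with
#' `g(age) = age / max_lifespan` (relative age) and `s_j` the true
#' slope (0 for null probes); the observed beta is drawn
#' `Beta(mu * phi, (1 - mu) * phi)`. Draw order is fixed (annotation,
#' slopes, baselines, ages/sex, noise), so identical config and seed
#' give bit-identical output.
#'
#' @param config A [simulation_config()].
#' @return A list of class `methylation_simulation` with elements
#'   `beta` (probes x samples matrix), `samples` (sample sheet),
#'   `annotation` (probe annotation), `truth` (per-probe `true_slope`
#'   plus flags), and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  p <- config$n_probes
  probe_ids <- sprintf("cg%06d", seq_len(p))

  ## 1. annotation
  annotation <- data.frame(
    probe_id = probe_ids,
    assembly = "synthetic_v1",
    chrom = sample(paste0("chr", 1:8), p, replace = TRUE),
    pos = sample.int(1e8L, p, replace = TRUE),
    strand = sample(c("+", "-"), p, replace = TRUE),
    stringsAsFactors = FALSE
  )
  annotation$mappable_species <- rep(list(config$species$species), p)
  annotation$island_flag <- stats::runif(p) < config$frac_island
  annotation$tss_category <- sample(TSS_CATEGORIES, p, replace = TRUE,
                                    prob = c(0.1, 0.05, 0.15, 0.3, 0.05,
                                             0.05, 0.3))
  annotation$chromatin_state <- sample(CHROMATIN_STATES, p, replace = TRUE)
  annotation$prc2_bound <- stats::runif(p) < config$frac_prc2
  annotation$gene_symbol <- sprintf("GENE%04d", sample.int(max(p %/% 2L, 1L),
                                                           p, replace = TRUE))
  annotation <- annotation[c("probe_id", "assembly", "chrom", "pos", "strand",
                             "mappable_species", "island_flag", "tss_category",
                             "chromatin_state", "prc2_bound", "gene_symbol")]

  ## 2. true slopes
  n_age <- round(config$frac_age_related * p)
  slopes <- numeric(p)
  island_prc2 <- annotation$island_flag & annotation$prc2_bound
  pool <- if (config$island_aging_mode == "opossum_like") {
    which(!island_prc2)
  } else {
    seq_len(p)
  }
  if (n_age > length(pool)) {
    stop("frac_age_related too large for the eligible probe pool")
  }
  idx_age <- sort(sample(pool, n_age))
  if (n_age > 0L) {
    mag <- stats::runif(n_age, config$slope_range[1L], config$slope_range[2L])
    sign <- sample(c(-1, 1), n_age, replace = TRUE)
    if (config$island_aging_mode == "placental_like") {
      sign[island_prc2[idx_age]] <- 1
    }
    slopes[idx_age] <- mag * sign
  }
  truth <- data.frame(probe_id = probe_ids, true_slope = slopes,
                      island_flag = annotation$island_flag,
                      prc2_bound = annotation$prc2_bound,
                      stringsAsFactors = FALSE)

  ## 3. baselines per species x tissue
  strata <- expand.grid(tissue = config$tissues,
                        species = config$species$species,
                        stringsAsFactors = FALSE)[, c("species", "tissue")]
  b0 <- matrix(stats::rnorm(p * nrow(strata), 0, config$baseline_logit_sd),
               nrow = p)
  colnames(b0) <- paste(strata$species, strata$tissue, sep = ".")

  ## 4. samples
  rows <- list()
  for (si in seq_len(nrow(config$species))) {
    sp <- config$species[si, ]
    for (ti in config$tissues) {
      n <- sp$n_per_tissue
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp$species, tissue = ti,
        sex = sample(c("F", "M"), n, replace = TRUE),
        age_years = stats::runif(n, 0, sp$max_lifespan_years),
        max_lifespan_years = sp$max_lifespan_years,
        maturity_years = sp$maturity_years,
        stringsAsFactors = FALSE
      )
    }
  }
  samples <- do.call(rbind, rows)
  samples <- data.frame(sample_id = sprintf("s%04d", seq_len(nrow(samples))),
                        samples, stringsAsFactors = FALSE)

  ## 5. observed betas
  g <- samples$age_years / samples$max_lifespan_years
  stratum_of <- paste(samples$species, samples$tissue, sep = ".")
  mu <- stats::plogis(b0[, stratum_of, drop = FALSE] +
                 outer(slopes, g))
  phi <- config$noise_precision
  beta <- matrix(stats::rbeta(length(mu), mu * phi, (1 - mu) * phi),
                 nrow = p, dimnames = list(probe_ids, samples$sample_id))
  # keep observations strictly inside (0,1); Beta draws can underflow to
  # the boundary when mu*phi is tiny
  eps <- 1e-6
  beta <- pmin(pmax(beta, eps), 1 - eps)

  structure(list(beta = beta, samples = samples, annotation = annotation,
                 truth = truth, config = config),
            class = "methylation_simulation")
}

#' @export
print.methylation_simulation <- function(x, ...) {
  cat(sprintf("methylation simulation: %d probes x %d samples (%s; %d species, %d tissues)\n",
              nrow(x$beta), ncol(x$beta), x$config$island_aging_mode,
              nrow(x$config$species), length(x$config$tissues)))
  invisible(x)
}

#' Export a simulated dataset as plain-text fixtures
#'
#' Writes `beta.tsv`, `samples.tsv`, `species_constants.tsv`,
#' `probe_annotation.tsv` and `ground_truth.tsv` into `out_dir` in the
#' package's canonical TSV dialects; re-reading with the `read_*`
#' functions reproduces the dataset, and two exports of the same dataset
#' are byte-identical.
#'
#' @param dataset A `methylation_simulation`.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the file paths, invisibly.
#' @export
export_fixture <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "methylation_simulation"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(beta = file.path(out_dir, "beta.tsv"),
             samples = file.path(out_dir, "samples.tsv"),
             constants = file.path(out_dir, "species_constants.tsv"),
             annotation = file.path(out_dir, "probe_annotation.tsv"),
             truth = file.path(out_dir, "ground_truth.tsv"))
  write_beta_matrix(dataset$beta, paths[["beta"]])
  write_sample_sheet(dataset$samples, paths[["samples"]], paths[["constants"]])
  write_probe_annotation(dataset$annotation, paths[["annotation"]])
  truth <- dataset$truth
  truth$true_slope <- vapply(truth$true_slope, format_number, character(1L))
  utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
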