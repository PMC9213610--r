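#' Per-probe correlation screen of methylation against age
#'
#' The EWAS primitive: for every probe, the Pearson correlation of its
#' beta values with (optionally transformed) age across the samples of
#' one stratum, with a two-sided Student t p-value on `n - 2` degrees of
#' freedom (`t = r * sqrt(n - 2) / sqrt(1 - r^2)`) and the Fisher z
#' effect statistic `z = atanh(r) * sqrt(n - 3)`. Missing betas are
#' handled pairwise-complete and `n_used` records the samples actually
#' used; probes with fewer than 4 complete pairs or zero variance are
#' marked invalid (`r = 0`, `p = 1`). `r` is clipped to `|r| <= 1 - 1e-12`
#' before `atanh` so z stays finite. BH-FDR and Bonferroni columns are
#' always emitted alongside the nominal p.
#'
#' @param beta Probes x samples beta matrix.
#' @param samples Sample sheet aligned with `colnames(beta)` (one
#'   species, one tissue).
#' @param transform Optional [age_transform()] applied to age before
#'   correlating (default identity, i.e., chronological years).
#' @param p_method `"student"` (default, exact t reference) or
#'   `"normal"` (normal approximation `2 * pnorm(-|z|)`).
#' @return data.frame with columns `probe_id`, `n_used`, `r`, `z`, `p`,
#'   `fdr_bh`, `bonferroni`, `valid`; the stratum label is attached as
#'   attribute `"stratum"`.
#' @export
correlation_screen <- function(beta, samples,
                               transform = age_transform("identity"),
                               p_method = c("student", "normal")) {
  p_method <- match.arg(p_method)
  validate_beta_matrix(beta)
  samples <- align_samples(beta, samples)
  if (length(unique(samples$species)) > 1L ||
      length(unique(samples$tissue)) > 1L) {
    stop("correlation_screen expects a homogeneous stratum (one species, one tissue)")
  }
  if (ncol(beta) < 4L) stop("stratum has fewer than 4 samples")
  age <- transform_age(transform, samples$age_years, samples)

  obs <- !is.na(beta)
  b0 <- beta
  b0[!obs] <- 0
  n <- rowSums(obs)
  sum_y <- rowSums(b0)
  sum_y2 <- rowSums(b0^2)
  sum_a <- as.vector(obs %*% age)
  sum_a2 <- as.vector(obs %*% age^2)
  sum_ya <- as.vector(b0 %*% age)
  var_y <- n * sum_y2 - sum_y^2
  var_a <- n * sum_a2 - sum_a^2
  denom <- sqrt(pmax(var_y, 0) * pmax(var_a, 0))
  r <- ifelse(denom > 0, (n * sum_ya - sum_y * sum_a) / denom, NA_real_)
  # text round-trips and constant probes can push |r| marginally past 1
  r <- pmin(pmax(r, -1), 1)

  valid <- n >= 4L & !is.na(r) & denom > 0
  r[!valid] <- 0
  r_clip <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  z <- atanh(r_clip) * sqrt(pmax(n - 3, 0))
  p <- if (p_method == "student") {
    tt <- r_clip * sqrt(pmax(n - 2, 0)) / sqrt(1 - r_clip^2)
    2 * stats::pt(-abs(tt), df = pmax(n - 2, 1))
  } else {
    2 * stats::pnorm(-abs(z))
  }
  z[!valid] <- 0
  p[!valid] <- 1
  p <- pmin(p, 1)

  out <- data.frame(probe_id = rownames(beta), n_used = as.integer(n),
                    r = r, z = z, p = p,
                    fdr_bh = stats::p.adjust(p, "BH"),
                    bonferroni = stats::p.adjust(p, "bonferroni"),
                    valid = valid, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "stratum") <- c(species = unique(samples$species),
                            tissue = unique(samples$tissue))
  out
}

align_samples <- function(beta, samples) {
  if (!all(colnames(beta) %in% samples$sample_id)) {
    stop("samples missing from sample sheet: ",
         paste(setdiff(colnames(beta), samples$sample_id), collapse = ", "))
  }
  samples[match(colnames(beta), samples$sample_id), , drop = FALSE]
}

#' Stouffer meta-analysis of EWAS screens across strata
#'
#' Combines per-probe Fisher z statistics over strata as
#' `z_meta = sum(w_i * z_i) / sqrt(sum(w_i^2))`, by default with
#' `w_i = sqrt(n_i)` (the per-probe sample count of stratum i);
#' `p_meta = 2 * pnorm(-|z_meta|)`. The probe universe is the union:
#' probes invalid or absent in a stratum contribute nothing there and
#' the weights renormalize over the strata that do contribute
#' (`k_strata` records how many).
#'
#' @param results List of [correlation_screen()] outputs.
#' @param weights Optional numeric vector, one weight per stratum,
#'   overriding the default `sqrt(n_i)` per-probe weights.
#' @return data.frame with `probe_id`, `z_meta`, `p_meta`, `k_strata`,
#'   `fdr_bh`, `bonferroni`, `valid`.
#' @export
stouffer_meta <- function(results, weights = NULL) {
  stopifnot(length(results) >= 1L)
  if (!is.null(weights) && length(weights) != length(results)) {
    stop("need one weight per stratum")
  }
  probes <- unique(unlist(lapply(results, function(r) r$probe_id)))
  num <- den <- kk <- numeric(length(probes))
  names(num) <- names(den) <- names(kk) <- probes
  for (i in seq_along(results)) {
    res <- results[[i]]
    ok <- res$valid
    ids <- res$probe_id[ok]
    w <- if (is.null(weights)) sqrt(res$n_used[ok]) else rep(weights[i], sum(ok))
    num[ids] <- num[ids] + w * res$z[ok]
    den[ids] <- den[ids] + w^2
    kk[ids] <- kk[ids] + 1
  }
  valid <- den > 0
  z_meta <- ifelse(valid, num / sqrt(pmax(den, .Machine$double.eps)), 0)
  p_meta <- ifelse(valid, 2 * stats::pnorm(-abs(z_meta)), 1)
  out <- data.frame(probe_id = probes, z_meta = z_meta, p_meta = p_meta,
                    k_strata = as.integer(kk),
                    fdr_bh = stats::p.adjust(p_meta, "BH"),
                    bonferroni = stats::p.adjust(p_meta, "bonferroni"),
                    valid = valid, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Select the top age-related CpGs per direction of change
#'
#' Among probes significant at `p_threshold`, takes up to
#' `k_per_direction` of the most significant with positive z (gain of
#' methylation with age) and likewise with negative z — "up to 1000
#' CpGs, 500 per direction" semantics. Ordering: ascending p, ties by
#' descending |z|, then probe id.
#'
#' @param result A [correlation_screen()] or [stouffer_meta()] output.
#' @param k_per_direction Maximum probes per direction (default 500).
#' @param p_threshold Nominal significance threshold.
#' @return List with character vectors `up` and `down` (ordered).
#' @export
select_top_cpgs <- function(result, k_per_direction = 500, p_threshold) {
  if (k_per_direction <= 0) stop("k_per_direction must be positive")
  zcol <- if ("z_meta" %in% names(result)) "z_meta" else "z"
  pcol <- if ("p_meta" %in% names(result)) "p_meta" else "p"
  keep <- result$valid & result[[pcol]] < p_threshold
  pick <- function(dir) {
    sub <- result[keep & sign(result[[zcol]]) == dir, , drop = FALSE]
    ord <- order(sub[[pcol]], -abs(sub[[zcol]]), sub$probe_id)
    utils::head(sub$probe_id[ord], k_per_direction)
  }
  list(up = pick(1), down = pick(-1))
}

#' Venn region counts for 2-4 named probe sets
#'
#' @param sets Named list of 2-4 character vectors.
#' @return data.frame with one row per non-empty membership pattern:
#'   logical columns (one per set) and `count`. Region counts sum to the
#'   size of the union.
#' @export
overlap_counts <- function(sets) {
  if (length(sets) < 2L || length(sets) > 4L) {
    stop("overlap_counts supports 2-4 sets")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be named")
  }
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, ncol = length(sets),
                   dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  names(patterns) <- names(sets)
  patterns <- patterns[rowSums(patterns) > 0L, , drop = FALSE]
  patterns$count <- apply(patterns[names(sets)], 1L, function(pt) {
    sum(apply(member, 1L, function(row) all(row == pt)))
  })
  rownames(patterns) <- NULL
  patterns
}

#' Classify probes into cross-stratum significance sectors
#'
#' The sector-plot logic: with normal-quantile thresholds
#' `z* = qnorm(1 - p/2)` at a strict and a lenient p, a probe is
#' `shared_up` / `shared_down` when it exceeds the strict threshold in
#' the same direction in both strata, `divergent` when it exceeds it in
#' opposite directions, `x_only` / `y_only` when strictly significant in
#' one stratum and below the lenient threshold in the other, and `null`
#' otherwise.
#'
#' @param zx,zy Aligned per-probe Fisher z vectors for the two strata.
#' @param p_strict Strict two-sided p threshold (e.g., 1e-4 or 0.005).
#' @param p_lenient Lenient threshold (default 0.05).
#' @return Factor with levels `shared_up`, `shared_down`, `divergent`,
#'   `x_only`, `y_only`, `null`; thresholds attached as attributes.
#' @export
sector_classify <- function(zx, zy, p_strict, p_lenient = 0.05) {
  if (!(p_strict > 0 && p_strict < p_lenient && p_lenient < 1)) {
    stop("need 0 < p_strict < p_lenient < 1")
  }
  stopifnot(length(zx) == length(zy))
  zs <- stats::qnorm(1 - p_strict / 2)
  zl <- stats::qnorm(1 - p_lenient / 2)
  out <- rep("null", length(zx))
  out[zx > zs & zy > zs] <- "shared_up"
  out[zx < -zs & zy < -zs] <- "shared_down"
  out[(zx > zs & zy < -zs) | (zx < -zs & zy > zs)] <- "divergent"
  out[abs(zx) > zs & abs(zy) < zl & out == "null"] <- "x_only"
  out[abs(zy) > zs & abs(zx) < zl & out == "null"] <- "y_only"
  out <- factor(out, levels = c("shared_up", "shared_down", "divergent",
                                "x_only", "y_only", "null"))
  attr(out, "z_strict") <- zs
  attr(out, "z_lenient") <- zl
  out
}

#' Concordance of aging z scores between two strata
#'
#' Pearson correlation of the paired per-probe Fisher z statistics —
#' the cross-tissue / cross-species agreement summary of sector plots.
#' Degenerate input (zero variance in either vector) returns 0 with
#' attribute `degenerate = TRUE` instead of an error.
#'
#' @param zx,zy Aligned per-probe z vectors (>= 3 probes).
#' @return Scalar correlation.
#' @export
zscore_concordance <- function(zx, zy) {
  ok <- !is.na(zx) & !is.na(zy)
  if (sum(ok) < 3L) stop("need at least 3 aligned probes")
  if (stats::sd(zx[ok]) == 0 || stats::sd(zy[ok]) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  structure(stats::cor(zx[ok], zy[ok]), degenerate = FALSE)
}

#' Manhattan-plot-ready table from an EWAS screen
#'
#' Joins probe coordinates onto an EWAS result and adds the signed
#' `-log10(p)` column (sign of z) that Manhattan plots of aging EWAS
#' use.
#'
#' @param result A [correlation_screen()] or [stouffer_meta()] output.
#' @param annotation Probe annotation supplying `chrom` and `pos`.
#' @return data.frame `probe_id`, `chrom`, `pos`, `signed_log10_p`.
#' @export
manhattan_table <- function(result, annotation) {
  zcol <- if ("z_meta" %in% names(result)) "z_meta" else "z"
  pcol <- if ("p_meta" %in% names(result)) "p_meta" else "p"
  idx <- match(result$probe_id, annotation$probe_id)
  if (anyNA(idx)) stop("EWAS probes missing from annotation")
  data.frame(probe_id = result$probe_id,
             chrom = annotation$chrom[idx],
             pos = annotation$pos[idx],
             signed_log10_p = ifelse(result[[zcol]] < 0, -1, 1) *
               -log10(pmax(result[[pcol]], .Machine$double.xmin)),
             stringsAsFactors = FALSE)
}
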