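#' Island shift test on aging z scores
#'
#' Two-sample pooled-variance Student t test of the per-probe Fisher z
#' statistics, CpG-island probes versus non-island probes. A positive t
#' means islands gain methylation with age faster than non-islands (the
#' placental pattern); a null result is the opossum pattern.
#'
#' @param z Per-probe Fisher z statistics.
#' @param island_flag Logical vector aligned with `z`.
#' @return List with `t`, `p` (two-sided), `mean_island`,
#'   `mean_non_island`, and group sizes.
#' @export
island_shift_test <- function(z, island_flag) {
  stopifnot(length(z) == length(island_flag))
  ok <- !is.na(z) & !is.na(island_flag)
  zi <- z[ok & island_flag]
  zo <- z[ok & !island_flag]
  if (length(zi) < 2L || length(zo) < 2L) {
    stop("need at least 2 probes in each island group")
  }
  ht <- stats::t.test(zi, zo, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       mean_island = mean(zi), mean_non_island = mean(zo),
       n_island = length(zi), n_non_island = length(zo))
}

significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", ""))
}

enrichment_table <- function(category, direction, k_in, n_top, K_in, N_bg,
                             odds_ratio, p) {
  data.frame(category = as.character(category), direction = direction,
             k_in = k_in, n_top = n_top, K_in = K_in, N_bg = N_bg,
             odds_ratio = odds_ratio, p = p,
             fdr_bh = stats::p.adjust(p, "BH"),
             bonferroni = stats::p.adjust(p, "bonferroni"),
             stars = as.character(significance_stars(p)),
             stringsAsFactors = FALSE)
}

sample_odds_ratio <- function(k_in, n_top, K_in, N_bg) {
  a <- k_in                      # top & in category
  b <- n_top - k_in              # top & out
  c <- K_in - k_in               # background-only & in
  d <- N_bg - K_in - n_top + k_in  # background-only & out
  ifelse(b * c == 0, ifelse(a * d == 0, NaN, Inf), (a * d) / (b * c))
}

#' Fisher exact enrichment of an annotation feature in a top-CpG set
#'
#' For each level of an annotation feature (TSS-relative category, CpG
#' island flag, PRC2 flag or chromatin state), tests the 2x2 table of
#' top-set membership against category membership with the Fisher exact
#' test; the two-sided p is the classic sum over margin-fixed tables
#' with probability no greater than the observed one. The reported odds
#' ratio is the sample (cross-product) OR computed on the
#' top-versus-background-remainder table (`Inf` for a zero off-diagonal
#' cell). Background is the probe universe the top set was drawn from
#' (typically all probes mappable to the species).
#'
#' @param top_probes Character vector of top probe ids (subset of
#'   `background`).
#' @param background Character vector of background probe ids.
#' @param annotation Probe annotation.
#' @param feature One of `"tss_category"`, `"island_flag"`,
#'   `"prc2_bound"`, `"chromatin_state"`.
#' @param direction Label recorded in the output (`"up"`, `"down"`,
#'   `"combined"`).
#' @return data.frame with one row per category: counts, odds ratio,
#'   two-sided p, BH and Bonferroni adjustments, significance stars
#'   (0.05/0.01/0.001/0.0001).
#' @export
feature_fisher_enrichment <- function(top_probes, background, annotation,
                                      feature = c("tss_category",
                                                  "island_flag",
                                                  "prc2_bound",
                                                  "chromatin_state"),
                                      direction = "combined") {
  feature <- match.arg(feature)
  if (length(top_probes) == 0L) stop("top set is empty")
  if (!all(top_probes %in% background)) stop("top set must be a subset of background")
  values <- annotation[[feature]][match(background, annotation$probe_id)]
  if (anyNA(match(background, annotation$probe_id))) {
    stop("background probes missing from annotation")
  }
  in_top <- background %in% top_probes
  cats <- sort(unique(as.character(values)))
  rows <- lapply(cats, function(cat) {
    in_cat <- as.character(values) == cat
    k_in <- sum(in_top & in_cat)
    n_top <- sum(in_top)
    K_in <- sum(in_cat)
    N_bg <- length(background)
    tab <- matrix(c(k_in, n_top - k_in, K_in - k_in,
                    N_bg - K_in - n_top + k_in), nrow = 2L)
    p <- stats::fisher.test(tab)$p.value
    data.frame(category = cat, k_in = k_in, n_top = n_top, K_in = K_in,
               N_bg = N_bg, odds_ratio = sample_odds_ratio(k_in, n_top,
                                                           K_in, N_bg),
               p = p, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  enrichment_table(rows$category, direction, rows$k_in, rows$n_top,
                   rows$K_in, rows$N_bg, rows$odds_ratio, rows$p)
}

#' Hypergeometric chromatin-state enrichment of a top-CpG set
#'
#' For each chromatin state, the enrichment p is the upper
#' hypergeometric tail `P(X >= k_in)` with `X ~
#' Hypergeom(N_bg, K_in, n_top)`; the depletion tail `P(X <= k_in)` and
#' the fold change `(k_in / n_top) / (K_in / N_bg)` are reported
#' alongside.
#'
#' @param top_probes Top probe ids (subset of `background`).
#' @param background Background probe ids.
#' @param annotation Probe annotation.
#' @param states Optional character vector of states to test (default:
#'   all states present in the background); a state absent from the
#'   background is an error.
#' @param feature Annotation column holding the state labels (default
#'   `"chromatin_state"`; `"prc2_bound"` tests the PRC2 stratum).
#' @param direction Label recorded in the output.
#' @return data.frame with one row per state: counts, `fold`,
#'   enrichment `p`, `p_depletion`, adjustments, stars.
#' @export
hypergeom_state_enrichment <- function(top_probes, background, annotation,
                                       states = NULL,
                                       feature = "chromatin_state",
                                       direction = "combined") {
  if (length(top_probes) == 0L) stop("top set is empty")
  if (!all(top_probes %in% background)) stop("top set must be a subset of background")
  values <- as.character(annotation[[feature]][match(background,
                                                     annotation$probe_id)])
  present <- unique(values)
  if (is.null(states)) states <- sort(present)
  missing <- setdiff(as.character(states), present)
  if (length(missing) > 0L) {
    stop("state absent from background: ", paste(missing, collapse = ", "))
  }
  in_top <- background %in% top_probes
  n_top <- sum(in_top)
  N_bg <- length(background)
  rows <- lapply(as.character(states), function(st) {
    K_in <- sum(values == st)
    k_in <- sum(in_top & values == st)
    p_enr <- stats::phyper(k_in - 1L, K_in, N_bg - K_in, n_top,
                           lower.tail = FALSE)
    p_dep <- stats::phyper(k_in, K_in, N_bg - K_in, n_top)
    data.frame(category = st, k_in = k_in, K_in = K_in,
               fold = (k_in / n_top) / (K_in / N_bg),
               p = p_enr, p_depletion = p_dep, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  out <- enrichment_table(rows$category, direction, rows$k_in, n_top,
                          rows$K_in, N_bg, NA_real_, rows$p)
  out$odds_ratio <- NULL
  out$fold <- rows$fold
  out$p_depletion <- rows$p_depletion
  out[c("category", "direction", "k_in", "n_top", "K_in", "N_bg", "fold",
        "p", "p_depletion", "fdr_bh", "bonferroni", "stars")]
}

#' Adjust p-values for multiple testing
#'
#' Step-up Benjamini-Hochberg FDR or Bonferroni (`min(1, m * p)`),
#' preserving input order. Thin, validated wrapper so every enrichment
#' table reports nominal p plus both adjustments the same way.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param method `"bh"` or `"bonferroni"`.
#' @return Adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, if (method == "bh") "BH" else "bonferroni")
}

#' Gene-set enrichment of a top-CpG set via annotated genes
#'
#' Maps probes to their single annotated (nearest) gene and tests each
#' gene set with the upper hypergeometric tail over the background gene
#' universe. Sets outside the size bounds (after intersecting with the
#' universe) are dropped, mirroring the "between 10 and 3,000 genes"
#' filter used to curb multiple testing. This is a deliberately simpler
#' surrogate for region-based regulatory-domain tools: no basal-plus-
#' extension regulatory domains, one gene per probe.
#'
#' @param top_probes Top probe ids (subset of `background`).
#' @param background Background probe ids.
#' @param annotation Probe annotation with `gene_symbol`.
#' @param gene_sets Named list: set name -> character vector of gene
#'   symbols.
#' @param size_bounds Inclusive (min, max) gene-set size filter,
#'   default `c(10, 3000)`.
#' @param direction Label recorded in the output.
#' @return data.frame, one row per retained set: gene counts, `fold`,
#'   hypergeometric `p`, BH and Bonferroni adjustments, stars.
#' @export
gene_set_enrichment <- function(top_probes, background, annotation, gene_sets,
                                size_bounds = c(10, 3000),
                                direction = "combined") {
  if (!all(top_probes %in% background)) stop("top set must be a subset of background")
  genes_of <- function(probes) {
    g <- annotation$gene_symbol[match(probes, annotation$probe_id)]
    unique(g[!is.na(g)])
  }
  universe <- genes_of(background)
  if (length(universe) == 0L) stop("empty gene universe")
  top_genes <- genes_of(top_probes)
  N <- length(universe)
  n <- length(top_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    K <- length(set)
    if (K < size_bounds[1L] || K > size_bounds[2L]) return(NULL)
    k <- length(intersect(set, top_genes))
    data.frame(category = nm, k_in = k, K_in = K,
               fold = (k / max(n, 1L)) / (K / N),
               p = stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    return(enrichment_table(character(0), character(0), integer(0),
                            integer(0), integer(0), integer(0), numeric(0),
                            numeric(0))[0, ])
  }
  out <- enrichment_table(rows$category, direction, rows$k_in, n, rows$K_in,
                          N, NA_real_, rows$p)
  out$odds_ratio <- NULL
  out$fold <- rows$fold
  out[c("category", "direction", "k_in", "n_top", "K_in", "N_bg", "fold",
        "p", "fdr_bh", "bonferroni", "stars")]
}
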