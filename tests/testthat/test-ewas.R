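screen_fixture <- function(betas, ages) {
  ss <- tiny_samples(length(ages), ages = ages)
  beta <- tiny_beta(matrix(betas, nrow = 1), probes = "cg001",
                    samples = ss$sample_id)
  list(beta = beta, samples = ss)
}

test_that("correlation screen agrees with cor.test probe by probe", {
  set.seed(31)
  ss <- tiny_samples(12, ages = runif(12, 0, 4))
  beta <- tiny_beta(matrix(runif(60), 5, 12), samples = ss$sample_id)
  beta[2, ] <- plogis(qlogis(0.3) + 0.5 * ss$age_years) # a real effect
  beta[4, c(3, 7)] <- NA                                # pairwise-complete
  scr <- correlation_screen(beta, ss)
  for (i in 1:5) {
    ok <- !is.na(beta[i, ])
    ct <- cor.test(beta[i, ok], ss$age_years[ok])
    expect_equal(scr$r[i], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(scr$p[i], ct$p.value, tolerance = 1e-10)
    expect_equal(scr$n_used[i], sum(ok))
    expect_equal(scr$z[i], atanh(unname(ct$estimate)) * sqrt(sum(ok) - 3),
                 tolerance = 1e-10)
  }
})

test_that("degenerate probes are marked invalid with r = 0, p = 1", {
  ss <- tiny_samples(6)
  beta <- tiny_beta(rbind(rep(0.4, 6), runif(6)), samples = ss$sample_id)
  scr <- correlation_screen(beta, ss)
  expect_false(scr$valid[1])
  expect_equal(scr$r[1], 0)
  expect_equal(scr$p[1], 1)
  expect_true(scr$valid[2])
  # fewer than 4 complete pairs is invalid too
  beta[2, 1:3] <- NA
  scr <- correlation_screen(beta, ss)
  expect_false(scr$valid[2])
})

test_that("negating ages flips r and z but not p", {
  set.seed(32)
  ss <- tiny_samples(10, ages = runif(10, 0.1, 4))
  beta <- tiny_beta(matrix(runif(50), 5, 10), samples = ss$sample_id)
  a <- correlation_screen(beta, ss)
  ss2 <- ss
  ss2$age_years <- max(ss$age_years) - ss$age_years  # reverses order
  b <- correlation_screen(beta, ss2)
  expect_equal(b$r, -a$r, tolerance = 1e-10)
  expect_equal(b$z, -a$z, tolerance = 1e-10)
  expect_equal(b$p, a$p, tolerance = 1e-10)
})

test_that("Stouffer combination matches its closed forms", {
  mk <- function(z, n) data.frame(probe_id = "cg001", n_used = n, r = 0,
                                  z = z, p = 0.5, valid = TRUE)
  # 4 identical equally weighted strata: 4 * 1 / sqrt(4) = 2
  meta <- stouffer_meta(lapply(1:4, function(i) mk(1, 10)),
                        weights = rep(1, 4))
  expect_equal(meta$z_meta, 2)
  expect_equal(meta$k_strata, 4L)
  # z = (2, 0), w = (sqrt(10), sqrt(40)): 2*sqrt(10)/sqrt(50)
  meta <- stouffer_meta(list(mk(2, 10), mk(0, 40)))
  expect_equal(meta$z_meta, 2 * sqrt(10) / sqrt(50))
  expect_equal(meta$z_meta, 0.894427, tolerance = 1e-6)
  # single stratum: identity, p = 2 * pnorm(-|z|)
  meta <- stouffer_meta(list(mk(1.5, 20)))
  expect_equal(meta$z_meta, 1.5)
  expect_equal(meta$p_meta, 2 * pnorm(-1.5))
  # equal weights: invariant to stratum ordering; |z| of k identical = |z|*sqrt(k)
  strata <- list(mk(-1.2, 8), mk(0.4, 8), mk(2.2, 8))
  m1 <- stouffer_meta(strata, weights = c(1, 1, 1))
  m2 <- stouffer_meta(rev(strata), weights = c(1, 1, 1))
  expect_equal(m1$z_meta, m2$z_meta)
  mk9 <- stouffer_meta(lapply(1:9, function(i) mk(-0.7, 5)),
                       weights = rep(1, 9))
  expect_equal(abs(mk9$z_meta), 0.7 * 3)
})

test_that("meta-analysis renormalizes over contributing strata", {
  a <- data.frame(probe_id = c("p1", "p2"), n_used = c(10L, 10L),
                  r = 0, z = c(1, 1), p = 0.5, valid = c(TRUE, FALSE))
  b <- data.frame(probe_id = "p1", n_used = 10L, r = 0, z = 1, p = 0.5,
                  valid = TRUE)
  meta <- stouffer_meta(list(a, b))
  expect_equal(meta$k_strata, c(2L, 0L))
  expect_equal(meta$z_meta[1], 2 * sqrt(10) / sqrt(20))
  expect_false(meta$valid[2])
})

test_that("top-CpG selection honors 'up to k per direction' and tie rules", {
  res <- data.frame(probe_id = sprintf("p%02d", 1:10),
                    n_used = 20L,
                    r = 0.5,
                    z = c(3, 4, 5, 2.5, -3, -4, 0.1, -0.1, 0.2, -0.2),
                    p = c(0.001, 0.0005, 0.0001, 0.004, 0.002, 0.0008,
                          0.9, 0.8, 0.7, 0.6),
                    valid = TRUE)
  top <- select_top_cpgs(res, 500, 0.005)
  expect_equal(length(top$up), 4L)
  expect_equal(length(top$down), 2L)
  top3 <- select_top_cpgs(res, 3, 0.005)
  expect_equal(top3$up, c("p03", "p02", "p01"))  # ascending p
  # ties broken by larger |z|
  res2 <- data.frame(probe_id = c("a", "b"), n_used = 20L, r = 0.5,
                     z = c(3, 4), p = c(0.001, 0.001), valid = TRUE)
  expect_equal(select_top_cpgs(res2, 1, 0.05)$up, "b")
  expect_error(select_top_cpgs(res, 0, 0.05), "positive")
})

test_that("top-CpG selection with huge k returns all significant; idempotent", {
  set.seed(33)
  res <- data.frame(probe_id = sprintf("p%03d", 1:200), n_used = 20L,
                    r = 0, z = rnorm(200), p = runif(200), valid = TRUE)
  top <- select_top_cpgs(res, 1e6, 0.1)
  expect_equal(sort(c(top$up, top$down)),
               sort(res$probe_id[res$p < 0.1 & res$z != 0]))
  sub <- res[res$probe_id %in% c(top$up, top$down), ]
  top2 <- select_top_cpgs(sub, 1e6, 0.1)
  expect_identical(top, top2)
})

test_that("Venn region counts are exact and sum to the union", {
  out <- overlap_counts(list(A = c("1", "2", "3"), B = c("2", "3", "4")))
  get <- function(a, b) out$count[out$A == a & out$B == b]
  expect_equal(get(TRUE, FALSE), 1L)
  expect_equal(get(FALSE, TRUE), 1L)
  expect_equal(get(TRUE, TRUE), 2L)

  s <- sprintf("x%d", 1:5)
  out3 <- overlap_counts(list(a = s, b = s, c = s))
  expect_equal(sum(out3$count), 5L)
  expect_equal(out3$count[out3$a & out3$b & out3$c], 5L)

  # brute-force oracle on random sets
  set.seed(34)
  sets <- lapply(1:3, function(i) sample(sprintf("p%02d", 1:30), 12))
  names(sets) <- c("s1", "s2", "s3")
  out <- overlap_counts(sets)
  universe <- unique(unlist(sets))
  for (i in seq_len(nrow(out))) {
    expected <- sum(vapply(universe, function(el) {
      all(vapply(names(sets),
                 function(nm) (el %in% sets[[nm]]) == out[i, nm],
                 logical(1)))
    }, logical(1)))
    expect_equal(out$count[i], expected)
  }
  expect_equal(sum(out$count), length(universe))
  expect_error(overlap_counts(list(a = "1")), "2-4")
})

test_that("sector classification follows the threshold geometry", {
  cls <- function(zx, zy) as.character(sector_classify(zx, zy, 1e-4, 0.05))
  expect_equal(cls(4, 4), "shared_up")       # z* strict = 3.8906
  expect_equal(cls(-4, -4), "shared_down")
  expect_equal(cls(4, -4), "divergent")
  expect_equal(cls(4, 0.5), "x_only")        # z* lenient = 1.96
  expect_equal(cls(0.5, 4), "y_only")
  expect_equal(cls(4, 2.5), "null")          # significant-ish in y: neither
  expect_equal(cls(1, 1), "null")
  expect_equal(attr(sector_classify(1, 1, 1e-4, 0.05), "z_strict"),
               qnorm(1 - 1e-4 / 2))
  expect_error(sector_classify(1, 1, 0.05, 0.05), "p_strict")
  # exclusive and exhaustive on a random grid
  set.seed(35)
  z1 <- rnorm(500, 0, 3); z2 <- rnorm(500, 0, 3)
  out <- sector_classify(z1, z2, 0.005, 0.05)
  expect_false(anyNA(out))
})

test_that("z-score concordance is Pearson r with a degenerate guard", {
  z <- rnorm(50)
  expect_equal(as.numeric(zscore_concordance(z, z)), 1)
  expect_equal(as.numeric(zscore_concordance(z, -z)), -1)
  flat <- zscore_concordance(z, rep(0, 50))
  expect_equal(as.numeric(flat), 0)
  expect_true(attr(flat, "degenerate"))
  expect_error(zscore_concordance(1:2, 1:2), "at least 3")
})

test_that("shared simulated signal yields positive cross-stratum concordance", {
  ds <- simulate_dataset(simulation_config(
    species = data.frame(species = "sp", max_lifespan_years = 4.2,
                         maturity_years = 0.5, n_per_tissue = 40),
    tissues = c("ear", "liver"), n_probes = 4000, frac_age_related = 0.5,
    seed = 36))
  ear <- correlation_screen(ds$beta[, ds$samples$tissue == "ear"], ds$samples)
  liv <- correlation_screen(ds$beta[, ds$samples$tissue == "liver"], ds$samples)
  expect_gt(as.numeric(zscore_concordance(ear$z, liv$z)), 0.3)
})

test_that("null EWAS p-values are uniform (KS) and z/p columns consistent", {
  ds <- simulate_dataset(simulation_config(
    species = data.frame(species = "sp", max_lifespan_years = 4.2,
                         maturity_years = 0.5, n_per_tissue = 50),
    tissues = "ear", n_probes = 2000, frac_age_related = 0, seed = 37))
  scr <- correlation_screen(ds$beta, ds$samples)
  expect_gt(ks.test(scr$p, "punif")$p.value, 0.01)
  expect_true(all(sign(scr$z) == sign(scr$r)))
})

test_that("manhattan table carries signed -log10 p on probe coordinates", {
  ds <- default_sim(seed = 38, n_probes = 100)
  scr <- correlation_screen(ds$beta[, ds$samples$tissue == "ear"], ds$samples)
  man <- manhattan_table(scr, ds$annotation)
  expect_equal(man$pos, ds$annotation$pos)
  i <- which.max(abs(man$signed_log10_p))
  expect_equal(sign(man$signed_log10_p[i]), sign(scr$z[i]))
  expect_equal(abs(man$signed_log10_p[i]), -log10(scr$p[i]))
})
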