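# Small in-code fixtures shared across tests.

tiny_beta <- function(values, probes = sprintf("cg%03d", seq_len(nrow(values))),
                      samples = sprintf("s%02d", seq_len(ncol(values)))) {
  dimnames(values) <- list(probes, samples)
  values
}

tiny_samples <- function(n, species = "opossum", tissue = "ear",
                         ages = seq(0.1, 3, length.out = n),
                         lifespan = 4.2, maturity = 0.5,
                         ids = sprintf("s%02d", seq_len(n))) {
  data.frame(sample_id = ids, species = species, tissue = tissue,
             sex = rep(c("F", "M"), length.out = n), age_years = ages,
             max_lifespan_years = lifespan, maturity_years = maturity,
             stringsAsFactors = FALSE)
}

tiny_annotation <- function(probes, mappable = list(c("opossum")),
                            island = FALSE, prc2 = FALSE,
                            tss = "distal", state = "Quies",
                            gene = NA_character_) {
  n <- length(probes)
  data.frame(probe_id = probes, assembly = "synthetic_v1",
             chrom = "chr1", pos = seq_len(n) * 100L, strand = "+",
             stringsAsFactors = FALSE) |>
    (\(d) {
      d$mappable_species <- rep(mappable, length.out = n)
      d$island_flag <- rep(island, length.out = n)
      d$tss_category <- rep(tss, length.out = n)
      d$chromatin_state <- rep(state, length.out = n)
      d$prc2_bound <- rep(prc2, length.out = n)
      d$gene_symbol <- rep(gene, length.out = n)
      d
    })()
}

# default-conditions simulation used by several tests
default_sim <- function(seed = 1L, ...) {
  simulate_dataset(simulation_config(seed = seed, ...))
}

# builds a background/top pair whose 2x2 table against a logical feature
# is exactly [[k_in, n_top-k_in], [K_in-k_in, rest]]
table_fixture <- function(k_in, n_top, K_in, N_bg) {
  probes <- sprintf("p%03d", seq_len(N_bg))
  feat <- rep(FALSE, N_bg)
  feat[seq_len(K_in)] <- TRUE
  top <- c(probes[seq_len(k_in)],
           if (n_top > k_in) probes[K_in + seq_len(n_top - k_in)])
  ann <- tiny_annotation(probes, island = feat)
  list(top = top, background = probes, ann = ann)
}
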