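# Small in-code fixtures shared across test files.

toy_table <- function() {
  feature_table(
    mz = c(100.1, 200.2, 300.3),
    rt = c(60, 120, 180),
    intensity = matrix(c(10, 20, 1, 2, NA, 30), nrow = 3, byrow = TRUE),
    sample_ids = c("A", "B")
  )
}

# feature table with an exact block-correlation structure: each "chemical"
# contributes `k` features sharing one latent log2 profile (zero feature
# noise unless sigma > 0)
block_table <- function(n_chem = 3, k = 3, n = 24, sigma = 0,
                        effect = 0, seed = 42) {
  stopifnot(n %% 2 == 0)
  set.seed(seed)
  grp <- rep(c("case", "control"), each = n / 2)
  mz <- numeric(0); intens <- NULL
  for (j in seq_len(n_chem)) {
    latent <- 15 + rnorm(n) + effect * (grp == "case")
    for (i in seq_len(k)) {
      mz <- c(mz, 100 * j + i)
      intens <- rbind(intens, 2^(latent + log2(i) + rnorm(n, 0, sigma)))
    }
  }
  list(table = feature_table(mz, rt = seq_along(mz) * 10, intens,
                             sprintf("S%02d", seq_len(n))),
       samples = data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                            group = grp, stringsAsFactors = FALSE),
       chem = rep(seq_len(n_chem), each = k))
}

small_db <- function() {
  read_metabolite_db(system.file("extdata", "metabolite_db_small.tsv",
                                 package = "mwaskit"))
}
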