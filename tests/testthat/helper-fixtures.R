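# Shared fixtures: small libraries built in code at test time.

EBOX <- "CACGTG"

# deterministic 170 bp background with no E-box occurrence
promoter_template <- function(seed = 42, length = 170) {
  t <- ccra:::with_seed(seed, ccra:::random_dna(1, length))
  stopifnot(!grepl(EBOX, t), !grepl(EBOX, ccra:::revcomp(t)))
  t
}

# manifest of n single-motif promoters (motif at offset 80)
single_motif_library <- function(n = 4, seed = 7, offset = 80) {
  tmpl <- promoter_template()
  pl <- motif_placement(EBOX, offset)
  proms <- rep(place_motif(tmpl, pl), n)
  build_library(proms, seed = seed)
}

# motif centre on full-sequence coordinates (promoter starts at 31, 0-based)
motif_center_full <- function(offset = 80, motif = EBOX) {
  20 + 11 + offset + nchar(motif) / 2
}

# simulate events for every manifest element with shared truth parameters
simulate_library_events <- function(manifest, n_per_element = 50, pi = 0.8,
                                    sigma = 10, mu = motif_center_full(),
                                    seed = 1) {
  do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
    e <- simulate_insertions(manifest$full_sequence[i], n_per_element,
                             pi = pi, sigma = sigma, mu = mu,
                             seed = seed + i)
    e$element_id <- manifest$element_id[i]
    e
  }))
}

# Gaussian/uniform position mixture on [0, L) with exact component counts
mixture_positions <- function(n, pi, mu, sigma, L, seed) {
  ccra:::with_seed(seed, {
    n_tf <- round(n * pi)
    x <- c(round(rnorm(n_tf, mu, sigma)),
           sample.int(L, n - n_tf, replace = TRUE) - 1L)
    pmin(pmax(x, 0), L - 1)
  })
}
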