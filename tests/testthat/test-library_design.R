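test_that("barcode designer returns sets at the required pairwise distance", {
  b1 <- design_barcodes(1, length = 12, min_dist = 3, seed = 0)
  expect_length(b1, 1)
  expect_equal(nchar(b1), 12)

  b40 <- design_barcodes(40, length = 12, min_dist = 3, seed = 1)
  expect_length(b40, 40)
  expect_false(any(duplicated(b40)))
  expect_gte(min_pairwise_distance(b40), 3)

  # deterministic given the seed
  expect_identical(b40, design_barcodes(40, length = 12, min_dist = 3,
                                        seed = 1))

  # property: distance bound holds across lengths/sizes/seeds
  for (cfg in list(c(10, 8, 2, 5), c(25, 12, 4, 9), c(60, 12, 3, 3))) {
    b <- design_barcodes(cfg[1], cfg[2], cfg[3], seed = cfg[4])
    expect_gte(min_pairwise_distance(b), cfg[3])
  }
})

test_that("barcode designer rejects impossible requests", {
  expect_error(design_barcodes(2, length = 2, min_dist = 3), "min_dist")
  expect_error(design_barcodes(100, length = 2, min_dist = 1),
               "too small")
  expect_error(design_barcodes(3, length = 4, min_dist = 4, seed = 1,
                               max_attempts = 5), "attempts")
})

test_that("element assembly obeys the five-region concatenation invariant", {
  prom <- promoter_template()
  el <- build_element(prom, "GATCCTCTAGA", "ACGTACGTACGT")
  expect_equal(nchar(el$full_sequence), 230)
  expect_identical(
    el$full_sequence,
    paste0(el$homology_arm, el$sublib_index, el$promoter, el$barcode,
           el$pcr_tail))
  # invertible by offset arithmetic
  off <- el$region_offsets
  expect_identical(substr(el$full_sequence, off[["promoter"]] + 1,
                          off[["promoter"]] + 170), prom)
  expect_identical(substr(el$full_sequence, off[["barcode"]] + 1,
                          off[["barcode"]] + 12), el$barcode)

  # non-default promoter length: 20+11+100+12+17
  el100 <- build_element(promoter_template(length = 100), "GATCCTCTAGA",
                         "ACGTACGTACGT")
  expect_equal(nchar(el100$full_sequence), 160)

  expect_error(build_element(sub("^.", "N", prom), "GATCCTCTAGA",
                             "ACGTACGTACGT"), "ACGT")
  expect_error(build_element(prom, "GATCC", "ACGTACGTACGT"), "length")
})

test_that("single-bp variant series covers every one-off motif exactly once", {
  tmpl <- promoter_template()
  pl <- motif_placement(EBOX, 80)
  prom <- place_motif(tmpl, pl)
  v <- single_bp_variants(prom, pl)
  expect_equal(nrow(v), 3 * 6 + 1)
  expect_false(any(duplicated(v$promoter)))
  expect_equal(v$label[1], "consensus")

  # each variant differs from consensus at exactly one motif position
  cons <- v$promoter[v$label == "consensus"]
  for (p in v$promoter[v$label != "consensus"]) {
    d <- which(strsplit(p, "")[[1]] != strsplit(cons, "")[[1]])
    expect_length(d, 1)
    expect_true(d >= 81 && d <= 86)
  }

  pl8 <- motif_placement("GTCACGTG", 80)
  v8 <- single_bp_variants(place_motif(tmpl, pl8), pl8)
  expect_equal(nrow(v8), 3 * 8 + 1)
})

test_that("spacing series places two motif copies at the stated distances", {
  tmpl <- promoter_template()
  s <- spacing_series(tmpl, EBOX, seq(9, 41, by = 2))
  expect_equal(nrow(s), 17)
  for (i in seq_len(nrow(s))) {
    # both copies present at offset1 and offset1 + d (centre-to-centre)
    p <- s$promoter[i]
    expect_identical(substr(p, 41, 46), EBOX)
    o2 <- 40 + s$distance[i]
    expect_identical(substr(p, o2 + 1, o2 + 6), EBOX)
  }
  # all non-motif positions identical across the series
  mask <- function(p, d) {
    for (o in c(40, 40 + d)) substr(p, o + 1, o + 6) <- "NNNNNN"
    p
  }
  masked <- mapply(mask, s$promoter, s$distance)
  base_chars <- strsplit(mask(s$promoter[1], s$distance[1]), "")[[1]]
  for (m in masked) {
    mc <- strsplit(m, "")[[1]]
    expect_true(all(mc == base_chars | mc == "N" | base_chars == "N"))
  }

  expect_error(spacing_series(tmpl, EBOX, 300), "past the promoter end")
  expect_error(spacing_series(tmpl, EBOX, 3), "overlap")

  s11 <- spacing_series(tmpl, EBOX, 11)
  expect_identical(substr(s11$promoter, 52, 57), EBOX)
})

test_that("site knockout combinations enumerate 2^k promoters", {
  tmpl <- promoter_template()
  pwm <- pwm_from_consensus(EBOX)
  sites <- list(motif_placement(EBOX, 20), motif_placement(EBOX, 60),
                motif_placement(EBOX, 100), motif_placement(EBOX, 130),
                motif_placement(EBOX, 160))
  prom <- Reduce(place_motif, sites, accumulate = FALSE, init = tmpl)
  ko <- site_knockout_combinations(prom, sites, pwm = pwm, seed = 3)
  expect_equal(nrow(ko), 32)
  expect_identical(ko$promoter[ko$label == "1_2_3_4_5"], prom)
  expect_false(any(duplicated(ko$promoter)))

  # scrambled sites never rescan above the PWM cutoff
  none <- ko$promoter[ko$label == "none"]
  expect_equal(nrow(scan_pwm(none, pwm)), 0)
  # intact-site counts match the scan
  for (i in sample(nrow(ko), 8)) {
    expect_equal(nrow(scan_pwm(ko$promoter[i], pwm)), ko$n_intact[i])
  }

  k2 <- site_knockout_combinations(prom, sites[1:2], seed = 3)
  expect_setequal(k2$label, c("1_2", "1", "2", "none"))
  k0 <- site_knockout_combinations(prom, list())
  expect_equal(nrow(k0), 1)

  overlapping <- list(motif_placement(EBOX, 20), motif_placement(EBOX, 23))
  expect_error(site_knockout_combinations(prom, overlapping), "overlap")
})

test_that("library assembly pairs every promoter with a distinct barcode", {
  man <- single_motif_library(n = 3)
  expect_equal(nrow(man), 3)
  expect_gte(min_pairwise_distance(man$barcode), 3)
  expect_true(all(nchar(man$full_sequence) == 230))

  reps <- build_library(setNames(rep(promoter_template(), 2),
                                 c("a", "b")),
                        seed = 5, n_replicates = 2)
  expect_equal(nrow(reps), 4)
  expect_setequal(reps$element_id,
                  c("a_rep1", "a_rep2", "b_rep1", "b_rep2"))
  expect_false(any(duplicated(reps$barcode)))
})
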