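test_that("read pairs classify to category, element, flank and UMI", {
  man <- single_motif_library(n = 3)
  layout <- read_layout()
  ev <- simulate_insertions(man$full_sequence[2], 5, pi = 1, sigma = 5,
                            mu = motif_center_full(), seed = 4)
  ev$element_id <- man$element_id[2]
  sim <- simulate_reads(ev, man, seed = 4, n_fulllength = 0)
  for (i in seq_along(sim$r1)) {
    cl <- filter_and_classify(sim$r1[i], sim$r2[i], layout, man$barcode,
                              "ACGTAC")
    expect_true(cl$accepted)
    expect_equal(cl$barcode_index, 2)
    expect_true(cl$category %in% c("fwd_upstream", "rev_upstream",
                                   "fwd_downstream", "rev_downstream"))
    expect_equal(nchar(cl$flank), 12)
    expect_equal(nchar(cl$umi), 4)
  }
})

test_that("single-base barcode errors are corrected; ambiguity is rejected", {
  man <- single_motif_library(n = 5)
  layout <- read_layout()
  r1 <- paste0(layout$category_signatures[["fwd_upstream"]],
               substr(man$full_sequence[3], 51, 62), "AAAA")
  bc <- man$barcode[3]
  substr(bc, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                              substr(bc, 5, 5))[1]
  cl <- filter_and_classify(r1, paste0("ACGTAC", bc), layout,
                            man$barcode, "ACGTAC", mismatch_tol = 1)
  expect_true(cl$accepted)
  expect_equal(cl$barcode_index, 3)  # design distance >= 3 makes it unique

  # a barcode equidistant from two designed barcodes is ambiguous
  cl2 <- filter_and_classify(r1, paste0("ACGTAC", man$barcode[1]), layout,
                             c(man$barcode[1], man$barcode[1]), "ACGTAC")
  expect_false(cl2$accepted)
  expect_equal(cl2$reason, "ambiguous_barcode")

  # unknown signature -> unclassified
  cl3 <- filter_and_classify(paste0(strrep("A", 20), strrep("C", 16)),
                             paste0("ACGTAC", man$barcode[1]), layout,
                             man$barcode, "ACGTAC")
  expect_false(cl3$accepted)
  expect_equal(cl3$reason, "unclassified")

  # wrong TF barcode is filtered out
  cl4 <- filter_and_classify(r1, paste0("GGGGGG", man$barcode[3]), layout,
                             man$barcode, "ACGTAC")
  expect_equal(cl4$reason, "tf_barcode")
})

test_that("flank mapping recovers the junction coordinate on both strands", {
  full <- single_motif_library(n = 1)$full_sequence
  # forward: flank equals full_sequence[51..62] (1-based) -> coordinate 50
  mp <- map_insertion(substr(full, 51, 62), full, "fwd_upstream")
  expect_true(mp$mapped)
  expect_equal(mp$coordinate, 50)
  expect_equal(mp$strand, "+")

  # reverse: flank is the revcomp of the 12 bp ending at the junction
  flank_rev <- ccra:::revcomp(substr(full, 51, 62))
  mp2 <- map_insertion(flank_rev, full, "rev_downstream")
  expect_true(mp2$mapped)
  expect_equal(mp2$coordinate, 61)
  expect_equal(mp2$strand, "-")

  # simulator round trip at a known coordinate
  ev <- data.frame(element_id = "x", coordinate = 100L, strand = "+",
                   umi = "ACGT")
  fl <- ccra:::event_flank(full, 100L, "+")
  mp3 <- map_insertion(fl, full, "fwd_downstream")
  expect_equal(mp3$coordinate, 100)

  expect_equal(map_insertion("ACGTACGTACGT", strrep("G", 230),
                             "fwd_upstream")$reason, "unmapped")
  poly <- paste0(strrep("A", 100), strrep("C", 30), strrep("A", 100))
  expect_equal(map_insertion(strrep("A", 12), poly,
                             "fwd_upstream")$reason, "multimapped")
})

test_that("deduplication keys on (element, coordinate, strand, UMI)", {
  base <- data.frame(element_id = "e1", coordinate = 50L, strand = "+",
                     umi = "AAAA", stringsAsFactors = FALSE)
  # same position, different UMI -> two unique insertions
  two_umis <- rbind(base, transform(base, umi = "AAAC"))
  expect_equal(nrow(dedup_insertions(two_umis)), 2)

  # 100 identical reads -> one unique insertion, multiplicity 100
  d <- dedup_insertions(base[rep(1, 100), ])
  expect_equal(nrow(d), 1)
  expect_equal(d$multiplicity, 100)

  # opposite strands at one coordinate stay distinct
  expect_equal(nrow(dedup_insertions(rbind(base,
                                           transform(base, strand = "-")))),
               2)

  # idempotent and order-invariant
  ev <- simulate_insertions(single_motif_library(1)$full_sequence, 200,
                            pi = 0.5, sigma = 8, seed = 11)
  d1 <- dedup_insertions(ev)
  d2 <- dedup_insertions(ev[sample(nrow(ev)), ])
  expect_identical(d1, d2)
  d3 <- dedup_insertions(d1[rep(seq_len(nrow(d1)), d1$multiplicity), ])
  expect_identical(d3$coordinate, d1$coordinate)
  expect_identical(d3$multiplicity, d1$multiplicity)
})

test_that("abundance fractions and NBS follow their closed forms", {
  expect_equal(abundance_from_fulllength(c(a = 10, b = 30)),
               c(a = 0.25, b = 0.75))
  expect_equal(abundance_from_fulllength(c(a = 5)), c(a = 1))
  expect_error(abundance_from_fulllength(c(a = 0, b = 0)), "zero")

  t1 <- compute_nbs(c(a = 10, b = 40), c(0.5, 0.5), scale = 100)
  expect_equal(t1$nbs, c(40, 160))

  # doubling every count leaves NBS unchanged (total normalization)
  t2 <- compute_nbs(c(a = 20, b = 80), c(0.5, 0.5), scale = 100)
  expect_equal(t2$nbs, t1$nbs)

  expect_equal(compute_nbs(c(a = 3), 1, scale = 1)$nbs, 1)
  expect_error(compute_nbs(c(a = 5, b = 1), c(0, 1)), "zero abundance")

  # depth invariance: scaling insertion and abundance reads together
  n <- c(a = 12, b = 30, c = 3)
  f <- abundance_from_fulllength(c(a = 100, b = 50, c = 50))
  f2 <- abundance_from_fulllength(3 * c(a = 100, b = 50, c = 50))
  expect_equal(compute_nbs(5 * n, f2)$nbs, compute_nbs(n, f)$nbs)
})

test_that("workflow read accounting conserves the input total", {
  man <- single_motif_library(n = 4)
  ev <- simulate_library_events(man, n_per_element = 30)
  sim <- simulate_reads(ev, man, reads_per_event = 2, seed = 3,
                        error_rate = 0.02)
  res <- run_binding_workflow(sim$r1, sim$r2, man)
  expect_equal(sum(res$stats), length(sim$r1))
  expect_gt(res$stats[["insertion_events"]], 0)
})
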