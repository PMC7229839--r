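test_that("insertion simulator honours mixture composition and bounds", {
  full <- single_motif_library(1)$full_sequence
  mu <- motif_center_full()

  # pi = 1 with tight sigma: all coordinates near the motif centre
  tight <- simulate_insertions(full, 200, pi = 1, sigma = 0.5, mu = mu,
                               seed = 1)
  expect_true(all(abs(tight$coordinate - mu) <= 3))
  expect_equal(nrow(tight), 200)

  # pi = 0: coordinates are uniform (KS test against U(0, L))
  bg <- simulate_insertions(full, 1000, pi = 0, sigma = 5, mu = mu,
                            seed = 2)
  ks <- suppressWarnings(
    stats::ks.test(bg$coordinate, "punif", 0, nchar(full)))
  expect_gt(ks$p.value, 0.01)

  # empty request
  expect_equal(nrow(simulate_insertions(full, 0, seed = 3)), 0)

  # coordinates always in [0, L), strands balanced-ish, reproducible
  ev <- simulate_insertions(full, 500, pi = 0.5, sigma = 20, mu = mu,
                            seed = 4)
  expect_true(all(ev$coordinate >= 0 & ev$coordinate < nchar(full)))
  expect_true(all(ev$strand %in% c("+", "-")))
  expect_identical(ev, simulate_insertions(full, 500, pi = 0.5,
                                           sigma = 20, mu = mu, seed = 4))
})

test_that("read simulator round-trips exactly at zero error rate", {
  man <- single_motif_library(n = 5, seed = 12)
  ev <- simulate_library_events(man, n_per_element = 40, seed = 30)
  sim <- simulate_reads(ev, man, reads_per_event = 5, seed = 31,
                        n_fulllength = 100)
  res <- run_binding_workflow(sim$r1, sim$r2, man)
  # 5x duplication collapses exactly; counts equal the ground truth
  expect_equal(res$binding_table$n_unique,
               as.numeric(sim$truth$n_unique[res$binding_table$element_id]))
  expect_equal(sum(res$stats[c("unmapped", "multimapped", "unclassified",
                               "unknown_barcode")]), 0)
})

test_that("read simulator tolerates sequencing errors without mis-assignment", {
  man <- single_motif_library(n = 4, seed = 13)
  ev <- simulate_library_events(man, n_per_element = 50, seed = 40)
  sim <- simulate_reads(ev, man, reads_per_event = 3, error_rate = 0.01,
                        seed = 41, n_fulllength = 80)
  res <- run_binding_workflow(sim$r1, sim$r2, man)
  # compare at the (element, coordinate, strand) level: UMI sequencing
  # errors can split one event into two UMIs, but never move an event
  key <- function(d) unique(paste(d$element_id, d$coordinate, d$strand))
  truth_keys <- key(ev)
  got_keys <- key(res$unique_events)
  # recovery: >= 95% of true insertion sites recovered at this duplication
  expect_gte(mean(truth_keys %in% got_keys), 0.95)
  # no mis-assignment: every recovered site exists in the ground truth
  # (barcode design distance >= 3 at correction tolerance 1)
  expect_true(all(got_keys %in% truth_keys))
})

test_that("cooperative series generator matches its closed form", {
  d <- seq(9, 41, 2)
  s <- simulate_cooperative_series(d, A = 1, period = 10.65, d0 = 2,
                                   C = 2.5, noise_sd = 0)
  expect_equal(s$occupancy,
               2.5 + cos(2 * pi * (s$distance - 2) / 10.65),
               tolerance = 1e-12)
  # max/min of a noiseless series sampled at the extrema = (C+A)/(C-A)
  ext <- simulate_cooperative_series(10.65 * seq(0.5, 4, 0.5), A = 1,
                                     period = 10.65, d0 = 0, C = 2)
  expect_equal(max(ext$occupancy) / min(ext$occupancy), 3,
               tolerance = 1e-9)
  # replicates and noise are seeded and reproducible
  n1 <- simulate_cooperative_series(d, noise_sd = 0.2, replicates = 4,
                                    seed = 6)
  expect_identical(n1, simulate_cooperative_series(d, noise_sd = 0.2,
                                                   replicates = 4,
                                                   seed = 6))
  expect_equal(nrow(n1), 4 * length(d))
  expect_error(simulate_cooperative_series(d, A = 2, C = 1), "C > A")
})

test_that("flat-amplitude series control the cosine F-test type-I rate", {
  d <- seq(9, 41, 2)
  pvals <- vapply(1:100, function(s) {
    y <- ccra:::with_seed(700 + s, rnorm(length(d), 2, 0.2))
    fit_cosine(d, y)$p_value
  }, numeric(1))
  # amplitude 0: the F-test should stay insignificant in >= 90% of seeds
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("FASTQ and manifest round-trips preserve the simulation", {
  man <- single_motif_library(n = 2, seed = 14)
  ev <- simulate_library_events(man, n_per_element = 10, seed = 50)
  sim <- simulate_reads(ev, man, seed = 51)
  tmp <- tempfile()
  dir.create(tmp)
  write_manifest(man, file.path(tmp, "manifest.tsv"))
  write_library_fasta(man, file.path(tmp, "library.fa"))
  write_read_fastq(sim, file.path(tmp, "r1.fq"), file.path(tmp, "r2.fq"))
  man2 <- read_manifest(file.path(tmp, "manifest.tsv"))
  expect_equal(man2$full_sequence, man$full_sequence)
  reads <- read_read_fastq(file.path(tmp, "r1.fq"),
                           file.path(tmp, "r2.fq"))
  expect_equal(unname(reads$r1), sim$r1)
  res <- run_binding_workflow(file.path(tmp, "r1.fq"),
                              file.path(tmp, "r2.fq"),
                              file.path(tmp, "manifest.tsv"),
                              out_dir = file.path(tmp, "out"))
  expect_equal(res$binding_table$n_unique,
               as.numeric(sim$truth$n_unique[res$binding_table$element_id]))
  expect_true(file.exists(file.path(tmp, "out", "binding_table.tsv")))
  expect_true(file.exists(file.path(tmp, "out", "insertions.qbed.tsv")))
  unlink(tmp, recursive = TRUE)
})
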