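#' Simulate transposon insertion events for one element
#'
#' Generative mirror of the background model: a fraction \code{pi} of
#' insertions is TF-directed and lands at positions drawn from a rounded
#' Gaussian centred on the motif (\code{mu}, \code{sigma}); the remainder
#' is background, uniform over the element. Strands are Bernoulli(0.5)
#' and UMIs uniform random 4-mers. Coordinates are clipped into the
#' strand's mappable range ("+": [0, L-12], "-": [11, L-1]) so that a
#' 12 bp mapping flank exists for every event; clipping slightly distorts
#' the extreme edges only.
#'
#' @param element A \code{ccra_element} or full sequence string.
#' @param n Number of insertion events.
#' @param pi TF-directed fraction in [0, 1].
#' @param sigma Gaussian SD in bp.
#' @param mu Gaussian mean (motif centre) on full-sequence coordinates.
#' @param seed Integer seed.
#' @param flank_len Mapping flank length (default 12).
#' @param umi_len UMI length (default 4).
#' @return data.frame (element_id, coordinate, strand, umi) of exactly
#'   \code{n} events; \code{round(n * pi)} are TF-directed.
#' @export
simulate_insertions <- function(element, n, pi = 0.9, sigma = 10, mu = NULL,
                                seed = NULL, flank_len = 12L,
                                umi_len = 4L) {
  seq_full <- if (inherits(element, "ccra_element")) element$full_sequence
              else element
  eid <- if (inherits(element, "ccra_element")) element$element_id else
    "element_1"
  L <- nchar(seq_full)
  stopifnot(pi >= 0, pi <= 1, sigma > 0)
  if (is.null(mu)) mu <- L / 2
  if (n == 0) {
    return(data.frame(element_id = character(0), coordinate = integer(0),
                      strand = character(0), umi = character(0),
                      stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    n_tf <- round(n * pi)
    pos_tf <- round(rnorm(n_tf, mu, sigma))
    pos_bg <- sample.int(L, n - n_tf, replace = TRUE) - 1L
    pos <- c(pos_tf, pos_bg)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    lo <- ifelse(strand == "+", 0L, flank_len - 1L)
    hi <- ifelse(strand == "+", L - flank_len, L - 1L)
    pos <- pmin(pmax(pos, lo), hi)
    data.frame(element_id = eid, coordinate = as.integer(pos),
               strand = strand, umi = random_dna(n, umi_len),
               stringsAsFactors = FALSE)
  })
}

event_flank <- function(full_sequence, coordinate, strand,
                        flank_len = 12L) {
  p1 <- coordinate + 1L  # 1-based junction base
  ifelse(strand == "+",
         substr(rep(full_sequence, length(coordinate)), p1,
                p1 + flank_len - 1L),
         revcomp(substr(rep(full_sequence, length(coordinate)),
                        p1 - flank_len + 1L, p1)))
}

#' Simulate paired sequencing reads for insertion events
#'
#' Emits the reference read dialect of [read_layout()]: read 1 = category
#' signature + mapping flank + UMI; read 2 = TF barcode + library barcode.
#' Each event yields \code{reads_per_event} duplicate pairs (PCR
#' duplication); the category is chosen consistently with the event's
#' strand (upstream/downstream side at random). Full-length pairs are
#' added per element in proportion to the supplied abundance weights.
#' Optional iid substitution errors corrupt each base at
#' \code{error_rate}.
#'
#' @param events data.frame of events (element_id, coordinate, strand,
#'   umi), e.g. from [simulate_insertions()].
#' @param manifest Library manifest ([build_library()]).
#' @param abundance Named weights per element for full-length reads
#'   (default equal).
#' @param n_fulllength Total full-length read pairs (default 2 per
#'   element).
#' @param layout A [read_layout()].
#' @param tf_barcode TF barcode placed on read 2.
#' @param reads_per_event Duplicate read pairs per event (default 1).
#' @param error_rate Per-base substitution probability (default 0).
#' @param seed Integer seed.
#' @return List with \code{r1}, \code{r2} (character vectors, shuffled)
#'   and \code{truth}: the per-element unique insertion counts and
#'   full-length counts actually emitted.
#' @export
simulate_reads <- function(events, manifest, abundance = NULL,
                           n_fulllength = 2L * nrow(manifest),
                           layout = read_layout(), tf_barcode = "ACGTAC",
                           reads_per_event = 1L, error_rate = 0,
                           seed = NULL) {
  with_seed(seed, {
    seq_of <- setNames(manifest$full_sequence, manifest$element_id)
    bc_of <- setNames(manifest$barcode, manifest$element_id)
    sigs <- layout$category_signatures
    ## insertion read pairs
    r1 <- r2 <- character(0)
    if (nrow(events) > 0) {
      side <- sample(c("upstream", "downstream"), nrow(events),
                     replace = TRUE)
      catg <- paste0(ifelse(events$strand == "+", "fwd_", "rev_"), side)
      flank <- vapply(seq_len(nrow(events)), function(i) {
        event_flank(seq_of[[events$element_id[i]]], events$coordinate[i],
                    events$strand[i], layout$flank_len)
      }, character(1))
      r1 <- rep(paste0(sigs[catg], flank, events$umi),
                each = reads_per_event)
      r2 <- rep(paste0(tf_barcode, bc_of[events$element_id]),
                each = reads_per_event)
    }
    ## full-length (abundance) read pairs
    if (is.null(abundance)) {
      abundance <- setNames(rep(1, nrow(manifest)), manifest$element_id)
    }
    fl_ids <- character(0)
    if (n_fulllength > 0) {
      fl_ids <- sample(manifest$element_id, n_fulllength, replace = TRUE,
                       prob = abundance[manifest$element_id])
      fl_flank <- substr(seq_of[fl_ids], 1, layout$flank_len)
      r1 <- c(r1, paste0(sigs[["full_length"]], fl_flank,
                         random_dna(n_fulllength, layout$umi_len)))
      r2 <- c(r2, paste0(tf_barcode, bc_of[fl_ids]))
    }
    if (error_rate > 0) {
      r1 <- mutate_reads(r1, error_rate)
      r2 <- mutate_reads(r2, error_rate)
    }
    ord <- sample(length(r1))
    uniq <- dedup_insertions(events)
    list(r1 = r1[ord], r2 = r2[ord],
         truth = list(
           n_unique = count_unique(uniq, manifest$element_id),
           fulllength = table(factor(fl_ids,
                                     levels = manifest$element_id))))
  })
}

## iid per-base substitutions at rate `rate`
mutate_reads <- function(reads, rate) {
  vapply(reads, function(r) {
    b <- strsplit(r, "")[[1]]
    hit <- runif(length(b)) < rate
    if (any(hit)) {
      b[hit] <- vapply(b[hit], function(x)
        sample(setdiff(DNA_BASES, x), 1), character(1))
    }
    paste(b, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a motif-spacing occupancy series
#'
#' Generative mirror of [fit_cosine()]: occupancy at spacing d is
#' \eqn{C + A\cos(2\pi(d - d_0)/T)} plus iid Gaussian noise, with
#' \code{replicates} observations per distance.
#'
#' @param distances Spacings in bp.
#' @param A,period,d0,C Cosine parameters (requires C > A >= 0).
#' @param noise_sd Gaussian noise SD (occupancy units).
#' @param replicates Observations per distance.
#' @param seed Integer seed.
#' @return data.frame (distance, replicate, occupancy).
#' @export
simulate_cooperative_series <- function(distances, A = 1, period = 10.65,
                                        d0 = 0, C = 2, noise_sd = 0,
                                        replicates = 1L, seed = NULL) {
  stopifnot(C > A, A >= 0)
  with_seed(seed, {
    g <- expand.grid(replicate = seq_len(replicates), distance = distances)
    mu <- C + A * cos(2 * pi * (g$distance - d0) / period)
    data.frame(distance = g$distance, replicate = g$replicate,
               occupancy = mu + rnorm(nrow(g), 0, noise_sd))
  })
}

#' Simulate a Sort-Seq bin count matrix
#'
#' Per element, cells fluoresce at \code{N(true_expression, noise_sd^2)}
#' and fall into bins whose gates are the midpoints between consecutive
#' bin values; per bin, a fixed sequencing depth is drawn multinomially
#' from the elements' cell masses in that bin, so column sums equal the
#' configured depths.
#'
#' @param true_expression Named numeric vector of true expression levels
#'   (on the bin-value scale).
#' @param design A [sortseq_design()].
#' @param reads_per_bin Sequencing depth per bin (single value or vector).
#' @param noise_sd Cell-to-cell fluorescence SD (default 0.5 bin units).
#' @param cells_per_element Cells simulated per element (default 2000).
#' @param seed Integer seed.
#' @return Integer matrix elements x bins (dimnames set).
#' @export
simulate_sortseq <- function(true_expression, design = sortseq_design(),
                             reads_per_bin = 1000L, noise_sd = 0.5,
                             cells_per_element = 2000L, seed = NULL) {
  n_el <- length(true_expression)
  ids <- if (!is.null(names(true_expression))) names(true_expression) else
    paste0("el", seq_len(n_el))
  gates <- (design$bin_values[-1] + design$bin_values[-design$n_bins]) / 2
  depth <- rep_len(as.integer(reads_per_bin), design$n_bins)
  with_seed(seed, {
    cells <- matrix(0, n_el, design$n_bins)
    for (i in seq_len(n_el)) {
      f <- rnorm(cells_per_element, true_expression[i], noise_sd)
      bin <- findInterval(f, gates) + 1L
      cells[i, ] <- tabulate(bin, design$n_bins)
    }
    counts <- matrix(0L, n_el, design$n_bins,
                     dimnames = list(ids, paste0("bin_",
                                                 seq_len(design$n_bins))))
    for (b in seq_len(design$n_bins)) {
      if (sum(cells[, b]) == 0) {
        ## empty bin: spread depth uniformly so downstream column checks
        ## still hold
        prob <- rep(1, n_el)
      } else {
        prob <- cells[, b]
      }
      counts[, b] <- rmultinom(1, depth[b], prob)[, 1]
    }
    counts
  })
}
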