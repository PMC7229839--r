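#' Paired-end read layout for insertion sequencing
#'
#' Defines the reference read dialect produced by [simulate_reads()] and
#' consumed by [process_reads()]. Read 1 carries a 20 bp category signature,
#' then the 12 bp flank used to map the insertion junction, then the 4 bp
#' UMI. Read 2 carries the 6 bp TF barcode followed by the 12 bp library
#' (promoter) barcode. The five categories are the four insertion classes
#' (transposon end x side of the barcode) plus full-length elements without
#' an insertion, used for abundance normalization. Signatures are mutually
#' distant 20-mers, so classification tolerates mismatches.
#'
#' @param signature_tol Mismatches tolerated when matching the 20 bp
#'   category signature (default 2); ties or worse are unclassified.
#' @return List of class \code{ccra_layout}.
#' @export
read_layout <- function(signature_tol = 2L) {
  structure(list(
    category_prefix_len = 20L, flank_len = 12L, umi_len = 4L,
    library_barcode_len = 12L, tf_barcode_len = 6L,
    signature_tol = as.integer(signature_tol),
    category_signatures = c(
      fwd_upstream   = "TGCAGGTTAACCTGGCTTAT",  # Ty5 3' LTR, upstream side
      rev_upstream   = "ACGCTAGGATCCGTTGCAAC",  # Ty5 5' LTR, upstream side
      fwd_downstream = "CCTTAGACATGCAATGCTCG",  # Ty5 3' LTR, downstream
      rev_downstream = "GAAGTTCCTATACTTTCTAG",  # Ty5 5' LTR, downstream
      full_length    = "ATAACTTCGTATAATGTATG"   # plasmid constant, no insert
    )), class = "ccra_layout")
}

INSERTION_CATEGORIES <- c("fwd_upstream", "rev_upstream",
                          "fwd_downstream", "rev_downstream")

category_strand <- function(category) {
  ifelse(grepl("^fwd", category), "+", "-")
}

## nearest match of `x` in `pool` within `tol` mismatches
## returns index, or 0 = no match, -1 = ambiguous (tie at the minimum)
nearest_within <- function(x, pool, tol) {
  d <- hamming(pool, x)
  m <- min(d)
  if (m > tol) return(0L)
  hits <- which(d == m)
  if (length(hits) > 1) return(-1L)
  hits
}

#' Classify one read pair against the layout and barcode sets
#'
#' Filters for the expected TF barcode and a known library barcode (both
#' error-corrected within \code{mismatch_tol}; library barcodes designed at
#' Hamming distance >= 3 are uniquely correctable at tolerance 1), then
#' assigns one of the five read categories from the 20 bp read-1 prefix and
#' extracts the 12 bp mapping flank and 4 bp UMI.
#'
#' @param r1,r2 Read sequences (single strings).
#' @param layout A [read_layout()].
#' @param lib_barcodes Character vector of manifest library barcodes.
#' @param tf_barcode Expected 6 bp TF barcode.
#' @param mismatch_tol Barcode mismatches tolerated (default 1).
#' @return List with \code{accepted} (logical); on acceptance
#'   \code{category}, \code{barcode_index}, \code{flank}, \code{umi}; on
#'   rejection \code{reason} (one of "short_read", "tf_barcode",
#'   "unknown_barcode", "ambiguous_barcode", "unclassified").
#' @export
filter_and_classify <- function(r1, r2, layout, lib_barcodes, tf_barcode,
                                mismatch_tol = 1L) {
  need1 <- layout$category_prefix_len + layout$flank_len + layout$umi_len
  need2 <- layout$tf_barcode_len + layout$library_barcode_len
  if (nchar(r1) < need1 || nchar(r2) < need2) {
    return(list(accepted = FALSE, reason = "short_read"))
  }
  tf <- substr(r2, 1, layout$tf_barcode_len)
  if (hamming(tf, tf_barcode) > mismatch_tol) {
    return(list(accepted = FALSE, reason = "tf_barcode"))
  }
  lb <- substr(r2, layout$tf_barcode_len + 1, need2)
  bi <- nearest_within(lb, lib_barcodes, mismatch_tol)
  if (bi == 0L) return(list(accepted = FALSE, reason = "unknown_barcode"))
  if (bi < 0L) return(list(accepted = FALSE, reason = "ambiguous_barcode"))
  sig <- substr(r1, 1, layout$category_prefix_len)
  ci <- nearest_within(sig, layout$category_signatures, layout$signature_tol)
  if (ci <= 0L) return(list(accepted = FALSE, reason = "unclassified"))
  list(accepted = TRUE,
       category = names(layout$category_signatures)[ci],
       barcode_index = bi,
       flank = substr(r1, layout$category_prefix_len + 1,
                      layout$category_prefix_len + layout$flank_len),
       umi = substr(r1, layout$category_prefix_len + layout$flank_len + 1,
                    need1))
}

#' Map a 12 bp flank to an insertion junction on an element
#'
#' The junction coordinate is 0-based on the element's full sequence. For
#' forward-strand categories the flank is the 12 bp immediately 3' of the
#' junction; for reverse-strand categories it is the reverse complement of
#' the 12 bp ending at the junction. The flank must match exactly and
#' uniquely.
#'
#' @param flank 12 bp flank from [filter_and_classify()].
#' @param full_sequence Element full sequence.
#' @param category One of the four insertion categories.
#' @return List with \code{mapped} (logical); on success \code{coordinate}
#'   (0-based) and \code{strand}; on failure \code{reason} ("unmapped" or
#'   "multimapped").
#' @export
map_insertion <- function(flank, full_sequence, category) {
  strand <- category_strand(category)
  query <- if (strand == "+") flank else revcomp(flank)
  starts <- integer(0)
  from <- 1L
  repeat {
    hit <- regexpr(query, substr(full_sequence, from,
                                 nchar(full_sequence)), fixed = TRUE)
    if (hit == -1L) break
    starts <- c(starts, from + as.integer(hit) - 1L)
    from <- from + as.integer(hit)
  }
  if (length(starts) == 0) return(list(mapped = FALSE, reason = "unmapped"))
  if (length(starts) > 1) return(list(mapped = FALSE,
                                      reason = "multimapped"))
  coord <- if (strand == "+") starts - 1L else
    starts - 1L + nchar(flank) - 1L
  list(mapped = TRUE, coordinate = as.integer(coord), strand = strand)
}

#' Process paired reads into insertion events and abundance counts
#'
#' Runs [filter_and_classify()] and [map_insertion()] over all read pairs.
#' Full-length reads are tallied per element as abundance evidence;
#' insertion reads become [dedup_insertions()] input. Read accounting is
#' conserved: accepted insertion events + full-length reads + rejections
#' (by reason) sum to the number of input pairs.
#'
#' @param r1,r2 Character vectors of read sequences (same length).
#' @param manifest Library manifest (element_id, barcode, full_sequence).
#' @param layout A [read_layout()].
#' @param tf_barcode Expected TF barcode.
#' @param mismatch_tol Barcode mismatch tolerance.
#' @return List with \code{events} (data.frame element_id, coordinate,
#'   strand, umi, category), \code{fulllength_counts} (named integer per
#'   element), and \code{stats} (named integer accounting).
#' @export
process_reads <- function(r1, r2, manifest, layout = read_layout(),
                          tf_barcode = "ACGTAC", mismatch_tol = 1L) {
  stopifnot(length(r1) == length(r2))
  if (length(r1) == 0) stop("no reads supplied")
  reasons <- c("short_read", "tf_barcode", "unknown_barcode",
               "ambiguous_barcode", "unclassified", "unmapped",
               "multimapped")
  stats <- setNames(integer(length(reasons) + 2),
                    c("insertion_events", "full_length", reasons))
  full_counts <- setNames(integer(nrow(manifest)), manifest$element_id)
  ev <- vector("list", length(r1))
  n_ev <- 0L
  for (i in seq_along(r1)) {
    cl <- filter_and_classify(r1[i], r2[i], layout, manifest$barcode,
                              tf_barcode, mismatch_tol)
    if (!cl$accepted) {
      stats[cl$reason] <- stats[cl$reason] + 1L
      next
    }
    eid <- manifest$element_id[cl$barcode_index]
    if (cl$category == "full_length") {
      full_counts[eid] <- full_counts[eid] + 1L
      stats["full_length"] <- stats["full_length"] + 1L
      next
    }
    mp <- map_insertion(cl$flank,
                        manifest$full_sequence[cl$barcode_index],
                        cl$category)
    if (!mp$mapped) {
      stats[mp$reason] <- stats[mp$reason] + 1L
      next
    }
    n_ev <- n_ev + 1L
    ev[[n_ev]] <- data.frame(element_id = eid, coordinate = mp$coordinate,
                             strand = mp$strand, umi = cl$umi,
                             category = cl$category,
                             stringsAsFactors = FALSE)
    stats["insertion_events"] <- stats["insertion_events"] + 1L
  }
  events <- if (n_ev > 0) do.call(rbind, ev[seq_len(n_ev)]) else
    data.frame(element_id = character(0), coordinate = integer(0),
               strand = character(0), umi = character(0),
               category = character(0), stringsAsFactors = FALSE)
  list(events = events, fulllength_counts = full_counts, stats = stats)
}

#' Collapse insertion events to unique transpositions
#'
#' A transposition is unique if it differs in insertion coordinate on its
#' element, in strand, or — when several insertions landed at the same
#' position — in UMI. PCR and sequencing duplicates collapse onto one event
#' whose multiplicity records read support. Idempotent and order-invariant.
#'
#' @param events data.frame from [process_reads()].
#' @return data.frame of unique events (element_id, coordinate, strand,
#'   umi, multiplicity), sorted by element, coordinate, strand, umi.
#' @export
dedup_insertions <- function(events) {
  if (nrow(events) == 0) {
    return(data.frame(element_id = character(0), coordinate = integer(0),
                      strand = character(0), umi = character(0),
                      multiplicity = integer(0), stringsAsFactors = FALSE))
  }
  key <- paste(events$element_id, events$coordinate, events$strand,
               events$umi, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    element_id = vapply(parts, `[`, character(1), 1),
    coordinate = as.integer(vapply(parts, `[`, character(1), 2)),
    strand = vapply(parts, `[`, character(1), 3),
    umi = vapply(parts, `[`, character(1), 4),
    multiplicity = as.integer(tab), stringsAsFactors = FALSE)
  out[order(out$element_id, out$coordinate, out$strand, out$umi), ,
      drop = FALSE]
}

#' Per-element unique-insertion counts
#' @param unique_events data.frame from [dedup_insertions()].
#' @param element_ids All element ids (so zero counts are kept).
#' @return Named integer vector.
#' @export
count_unique <- function(unique_events, element_ids) {
  n <- setNames(integer(length(element_ids)), element_ids)
  t <- table(unique_events$element_id)
  n[names(t)] <- as.integer(t)
  n
}

#' Library abundance fractions from full-length read counts
#'
#' The number of full-length (no-insertion) sequences recovered per element
#' normalizes for variation in element abundance within the library.
#'
#' @param counts Named numeric vector of full-length read counts.
#' @return Fractions summing to 1.
#' @export
abundance_from_fulllength <- function(counts) {
  if (length(counts) == 0 || sum(counts) <= 0) {
    stop("no abundance evidence: all full-length counts are zero")
  }
  counts / sum(counts)
}

#' Normalized binding score (NBS)
#'
#' Unique insertion counts corrected for each element's abundance in the
#' library and for the experiment's total number of transpositions, so that
#' scores are comparable across elements and across experiments:
#' NBS_i = scale * (n_i / f_i) / sum_j(n_j).
#'
#' @param n_unique Named numeric vector of unique insertion counts.
#' @param f Abundance fractions from [abundance_from_fulllength()], same
#'   order.
#' @param scale Reported scale constant (default 1e4).
#' @return data.frame of class \code{ccra_binding_table} with columns
#'   \code{element_id}, \code{n_unique}, \code{abundance}, \code{nbs}; the
#'   scale is stored in \code{attr(, "scale")}.
#' @export
compute_nbs <- function(n_unique, f, scale = 1e4) {
  stopifnot(length(n_unique) == length(f))
  if (sum(n_unique) <= 0) stop("no unique insertions to normalize")
  if (any(f == 0 & n_unique > 0)) {
    stop("element with insertions but zero abundance; ",
         "abundance PCR failed to sample it")
  }
  nbs <- ifelse(f == 0, 0, scale * (n_unique / f) / sum(n_unique))
  out <- data.frame(
    element_id = if (!is.null(names(n_unique))) names(n_unique) else
      paste0("el", seq_along(n_unique)),
    n_unique = as.numeric(n_unique), abundance = as.numeric(f),
    nbs = as.numeric(nbs), stringsAsFactors = FALSE)
  attr(out, "scale") <- scale
  class(out) <- c("ccra_binding_table", "data.frame")
  out
}
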