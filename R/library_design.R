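#' Design a set of mutually distant promoter barcodes
#'
#' Barcodes identify each synthetic promoter at the sequencing step; they are
#' required to differ from every other barcode by at least \code{min_dist}
#' substitutions so that synthesis, PCR and sequencing errors cannot convert
#' one designed barcode into another. Candidates are drawn by seeded rejection
#' sampling and accepted greedily if they satisfy the distance bound against
#' all previously accepted barcodes.
#'
#' @param n Number of barcodes to design.
#' @param length Barcode length in bp (default 12).
#' @param min_dist Minimum pairwise Hamming distance (default 3).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param max_attempts Candidate draws allowed before giving up.
#' @return Character vector of \code{n} distinct barcodes.
#' @examples
#' bc <- design_barcodes(40, seed = 1)
#' min(dist_matrix <- outer(bc, bc, Vectorize(function(a, b)
#'   sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])))[upper.tri(diag(40))])
#' @export
design_barcodes <- function(n, length = 12L, min_dist = 3L, seed = NULL,
                            max_attempts = 1000L * n) {
  stopifnot(n >= 1, length >= 1, min_dist >= 1)
  if (min_dist > length) {
    stop("min_dist (", min_dist, ") exceeds barcode length (", length, ")")
  }
  if (4^length < 4 * n) {
    stop("barcode space 4^", length, " is too small for n = ", n)
  }
  with_seed(seed, {
    accepted <- character(0)
    attempts <- 0L
    while (base::length(accepted) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("could not find ", n, " barcodes of length ", length,
             " at min_dist ", min_dist, " within ", max_attempts,
             " attempts")
      }
      cand <- random_dna(1, length)
      if (base::length(accepted) == 0 ||
          all(hamming(accepted, cand) >= min_dist)) {
        accepted <- c(accepted, cand)
      }
    }
    accepted
  })
}

#' Minimum pairwise Hamming distance of a barcode set
#'
#' @param barcodes Character vector of equal-length DNA barcodes.
#' @return Integer minimum over all pairs; \code{Inf} for a single barcode.
#' @export
min_pairwise_distance <- function(barcodes) {
  k <- length(barcodes)
  if (k < 2) return(Inf)
  m <- Inf
  for (i in seq_len(k - 1)) {
    m <- min(m, min(hamming(barcodes[(i + 1):k], barcodes[i])))
  }
  m
}

#' Default region lengths of a library element
#'
#' Each element is a single synthesized oligonucleotide made of five
#' concatenated regions: a cloning homology arm, a sub-library index used to
#' amplify subsets of a synthesis batch, the user-defined variable promoter,
#' the promoter barcode, and a constant PCR tail. With the default lengths
#' the full element is 20+11+170+12+17 = 230 bp.
#'
#' @param homology_arm,sublib_index,promoter,barcode,pcr_tail Region lengths
#'   in bp.
#' @return Named integer vector of region lengths, in element order.
#' @export
region_lengths <- function(homology_arm = 20L, sublib_index = 11L,
                           promoter = 170L, barcode = 12L, pcr_tail = 17L) {
  c(homology_arm = as.integer(homology_arm),
    sublib_index = as.integer(sublib_index),
    promoter = as.integer(promoter),
    barcode = as.integer(barcode),
    pcr_tail = as.integer(pcr_tail))
}

## fixed placeholder constant regions of the default lengths (the production
## sequences are assembly-specific and always user-configurable)
default_arms <- function() {
  list(homology_arm = "ACTGGCCGTCGTTTTACAAC",
       pcr_tail     = "GTCATAGCTGTTTCCTG")
}

#' Assemble a library element from its five regions
#'
#' @param promoter Variable promoter sequence (default length 170 bp).
#' @param sublib_index Sub-library index sequence (default length 11 bp).
#' @param barcode Promoter barcode (default length 12 bp).
#' @param element_id Identifier string.
#' @param homology_arm,pcr_tail Constant regions; defaults are fixed
#'   placeholders of the standard lengths.
#' @param lengths Expected region lengths, from [region_lengths()].
#' @return A \code{ccra_element}: list with the five regions, the
#'   concatenated \code{full_sequence}, and region offsets (0-based,
#'   half-open) so regions can be re-sliced from the full sequence.
#' @export
build_element <- function(promoter, sublib_index, barcode,
                          element_id = "element_1",
                          homology_arm = default_arms()$homology_arm,
                          pcr_tail = default_arms()$pcr_tail,
                          lengths = region_lengths(promoter = nchar(promoter))) {
  regions <- list(homology_arm = homology_arm, sublib_index = sublib_index,
                  promoter = promoter, barcode = barcode,
                  pcr_tail = pcr_tail)
  for (nm in names(regions)) {
    s <- regions[[nm]]
    if (!is.character(s) || length(s) != 1 || !is_dna(s)) {
      stop(nm, " must be a single ACGT string")
    }
    if (nchar(s) != lengths[[nm]]) {
      stop(nm, " has length ", nchar(s), ", expected ", lengths[[nm]])
    }
  }
  full <- paste0(homology_arm, sublib_index, promoter, barcode, pcr_tail)
  offs <- cumsum(c(0L, lengths))[seq_along(lengths)]
  names(offs) <- names(lengths)
  structure(c(list(element_id = element_id), regions,
              list(full_sequence = full, region_offsets = offs)),
            class = "ccra_element")
}

#' @export
print.ccra_element <- function(x, ...) {
  cat("<ccra_element> ", x$element_id, ": ", nchar(x$full_sequence),
      " bp (promoter ", nchar(x$promoter), " bp, barcode ", x$barcode,
      ")\n", sep = "")
  invisible(x)
}

#' Motif placement within a promoter
#'
#' Anchors motif-centred analyses: the motif centre (used as the Gaussian
#' mean of TF-directed insertions) is \code{offset + nchar(motif)/2},
#' measured within the promoter region.
#'
#' @param motif Motif sequence.
#' @param offset 0-based offset of the motif start within the promoter.
#' @param strand \code{"+"} or \code{"-"}.
#' @param promoter_length Promoter length the placement must fit in.
#' @return List of class \code{ccra_placement} with a \code{center} field.
#' @export
motif_placement <- function(motif, offset, strand = "+",
                            promoter_length = 170L) {
  stopifnot(is_dna(motif), strand %in% c("+", "-"))
  offset <- as.integer(offset)
  if (offset < 0 || offset > promoter_length - nchar(motif)) {
    stop("motif at offset ", offset, " does not fit a ",
         promoter_length, " bp promoter")
  }
  structure(list(motif = motif, offset = offset, strand = strand,
                 center = offset + nchar(motif) / 2),
            class = "ccra_placement")
}

#' Place a motif into a promoter template
#' @param template Promoter background sequence.
#' @param placement A [motif_placement()].
#' @return The promoter with the motif substituted at the placement.
#' @export
place_motif <- function(template, placement) {
  m <- if (placement$strand == "-") revcomp(placement$motif) else
    placement$motif
  i <- placement$offset
  paste0(substr(template, 1, i), m,
         substr(template, i + nchar(m) + 1, nchar(template)))
}

#' All single-base variants of a placed motif
#'
#' Generates the consensus promoter plus every promoter differing from it at
#' exactly one motif position (3 substitutions per position), the variant
#' series from which a single-bp binding-energy landscape is measured.
#'
#' @param promoter Consensus promoter carrying the motif.
#' @param placement [motif_placement()] of the motif in \code{promoter}.
#' @return data.frame with columns \code{label} ("consensus" or
#'   "pos<i><base>", i 1-based within the motif), \code{position} (NA for
#'   consensus), \code{base}, and \code{promoter}. \code{3*nchar(motif)+1}
#'   rows.
#' @export
single_bp_variants <- function(promoter, placement) {
  motif <- substr(promoter, placement$offset + 1,
                  placement$offset + nchar(placement$motif))
  rows <- list(data.frame(label = "consensus", position = NA_integer_,
                          base = NA_character_, promoter = promoter,
                          stringsAsFactors = FALSE))
  for (i in seq_len(nchar(motif))) {
    ref <- substr(motif, i, i)
    for (b in setdiff(DNA_BASES, ref)) {
      p <- promoter
      substr(p, placement$offset + i, placement$offset + i) <- b
      rows[[length(rows) + 1]] <- data.frame(
        label = paste0("pos", i, b), position = i, base = b, promoter = p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Promoter series varying the spacing between two motif copies
#'
#' Builds one promoter per requested distance, holding the first motif copy
#' fixed and moving the second, so that only the second site's position
#' changes across the series. "Distance" is centre-to-centre by default
#' (equivalently start-to-start for two copies of the same motif); the
#' \code{"edge"} convention counts the gap between the end of the first copy
#' and the start of the second.
#'
#' @param template Promoter background (no motif).
#' @param motif Motif sequence placed twice.
#' @param distances Integer vector of spacings in bp.
#' @param offset1 0-based offset of the first motif copy (default 40).
#' @param convention \code{"center"} (default) or \code{"edge"}.
#' @return data.frame with columns \code{distance} and \code{promoter}.
#' @export
spacing_series <- function(template, motif, distances, offset1 = 40L,
                           convention = c("center", "edge")) {
  convention <- match.arg(convention)
  L <- nchar(template)
  k <- nchar(motif)
  rows <- lapply(distances, function(d) {
    off2 <- if (convention == "center") offset1 + d else offset1 + k + d
    if (off2 < offset1 + k) {
      stop("distance ", d, " makes the two motif copies overlap")
    }
    if (off2 + k > L) {
      stop("distance ", d, " places the second motif past the promoter end")
    }
    p <- place_motif(template, motif_placement(motif, offset1,
                                               promoter_length = L))
    p <- place_motif(p, motif_placement(motif, off2, promoter_length = L))
    data.frame(distance = d, promoter = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Scramble a binding site until it no longer scores as a site
#'
#' Default site-knockout rule: a seeded random permutation of the site's
#' bases, redrawn until the scrambled sequence (and its reverse complement)
#' scores below the PWM cutoff when a PWM is supplied, or until it differs
#' from the original otherwise.
#'
#' @param site Site sequence to scramble.
#' @param pwm Optional [ccra_pwm()] used to verify knockout.
#' @param seed Integer seed.
#' @param max_tries Permutations attempted before erroring.
#' @return Scrambled sequence of the same length and base composition.
#' @export
scramble_site <- function(site, pwm = NULL, seed = NULL, max_tries = 1000L) {
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      s <- paste(sample(strsplit(site, "")[[1]]), collapse = "")
      ok <- if (is.null(pwm)) s != site else
        max(score_sequence(s, pwm), score_sequence(revcomp(s), pwm)) <
          pwm$cutoff
      if (ok) return(s)
    }
    stop("could not scramble site below cutoff in ", max_tries, " tries")
  })
}

#' All combinations of intact / knocked-out binding sites
#'
#' For k non-overlapping sites, builds the 2^k promoters in which each site
#' is either intact or replaced by its scrambled counterpart, including the
#' wild type (all intact) and the fully scrambled promoter.
#'
#' @param promoter Wild-type promoter.
#' @param sites List of [motif_placement()]s, non-overlapping.
#' @param scrambles Character vector of replacement sequences, one per site
#'   (same lengths); if \code{NULL}, generated by [scramble_site()] with
#'   \code{seed}.
#' @param pwm Optional PWM passed to [scramble_site()].
#' @param seed Seed for default scrambling.
#' @return data.frame with columns \code{label} (underscore-joined 1-based
#'   indices of intact sites; "none" when all are scrambled), \code{n_intact}
#'   and \code{promoter}; \code{2^length(sites)} rows, wild type first.
#' @export
site_knockout_combinations <- function(promoter, sites, scrambles = NULL,
                                       pwm = NULL, seed = NULL) {
  k <- length(sites)
  if (k == 0) {
    return(data.frame(label = "all", n_intact = 0L, promoter = promoter,
                      stringsAsFactors = FALSE))
  }
  spans <- t(vapply(sites, function(s)
    c(s$offset, s$offset + nchar(s$motif)), numeric(2)))
  o <- order(spans[, 1])
  if (k > 1 && any(spans[o, 1][-1] < spans[o, 2][-k])) {
    stop("sites overlap; knockout combinations require disjoint sites")
  }
  if (is.null(scrambles)) {
    scrambles <- vapply(seq_len(k), function(i) {
      site <- substr(promoter, sites[[i]]$offset + 1,
                     sites[[i]]$offset + nchar(sites[[i]]$motif))
      scramble_site(site, pwm = pwm,
                    seed = if (is.null(seed)) NULL else seed + i)
    }, character(1))
  }
  stopifnot(length(scrambles) == k)
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), k))
  rows <- lapply(seq_len(nrow(combos)), function(r) {
    intact <- unlist(combos[r, ])
    p <- promoter
    for (i in which(!intact)) {
      off <- sites[[i]]$offset
      len <- nchar(sites[[i]]$motif)
      substr(p, off + 1, off + len) <- scrambles[i]
    }
    lab <- if (any(intact)) paste(which(intact), collapse = "_") else "none"
    data.frame(label = lab, n_intact = sum(intact), promoter = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble a library manifest from promoters
#'
#' Designs one barcode per promoter (with replicate barcodes if requested)
#' and assembles full elements.
#'
#' @param promoters Named or unnamed character vector of promoter sequences.
#' @param sublib_index Shared sub-library index (default a fixed 11-mer).
#' @param n_replicates Barcoded replicates per promoter.
#' @param seed Seed for barcode design.
#' @param ids Optional element id prefixes; default "el<N>".
#' @return data.frame manifest with columns \code{element_id},
#'   \code{sublib_index}, \code{barcode}, \code{promoter},
#'   \code{full_sequence}.
#' @export
build_library <- function(promoters, sublib_index = "GATCCTCTAGA",
                          n_replicates = 1L, seed = 1L, ids = NULL) {
  n <- length(promoters) * n_replicates
  barcodes <- design_barcodes(n, seed = seed)
  if (is.null(ids)) {
    ids <- if (!is.null(names(promoters))) names(promoters) else
      paste0("el", seq_along(promoters))
  }
  rows <- list()
  j <- 0L
  for (i in seq_along(promoters)) {
    for (r in seq_len(n_replicates)) {
      j <- j + 1L
      eid <- if (n_replicates > 1) paste0(ids[i], "_rep", r) else ids[i]
      el <- build_element(promoters[[i]], sublib_index, barcodes[j],
                          element_id = eid)
      rows[[j]] <- data.frame(element_id = eid, sublib_index = sublib_index,
                              barcode = barcodes[j],
                              promoter = promoters[[i]],
                              full_sequence = el$full_sequence,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
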