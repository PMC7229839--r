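#' Sort-Seq experiment design
#'
#' Describes the fluorescence-sorting layout: number of bins, the
#' expression level assigned to each bin (ideally the mean log2 YFP/mCherry
#' of the bin's gate; the bin index is the fallback when gate values are
#' not recorded), and the fraction of sorted cells per bin (equal by
#' default, matching a sort of equal-size bins).
#'
#' @param n_bins Number of bins (default 8).
#' @param bin_values Numeric vector of per-bin expression levels; default
#'   \code{1:n_bins} ("bin units").
#' @param cell_fractions Fractions of sorted cells per bin, summing to 1.
#' @return List of class \code{ccra_sortseq_design}.
#' @export
sortseq_design <- function(n_bins = 8L, bin_values = seq_len(n_bins),
                           cell_fractions = rep(1 / n_bins, n_bins)) {
  stopifnot(n_bins >= 2, length(bin_values) == n_bins,
            length(cell_fractions) == n_bins, all(cell_fractions > 0))
  if (abs(sum(cell_fractions) - 1) > 1e-8) {
    stop("cell_fractions must sum to 1")
  }
  structure(list(n_bins = as.integer(n_bins),
                 bin_values = as.numeric(bin_values),
                 cell_fractions = as.numeric(cell_fractions)),
            class = "ccra_sortseq_design")
}

sortseq_profile <- function(counts, design) {
  depth <- colSums(counts)
  q <- sweep(counts, 2, depth, "/")          # within-bin element fractions
  p <- sweep(q, 2, design$cell_fractions, "*")  # cell-weighted profile
  sweep(p, 1, rowSums(p), "/")
}

#' Estimate per-element reporter expression from Sort-Seq bin counts
#'
#' Each element's reads are first normalized within each bin (so the
#' estimate is invariant to per-bin sequencing depth), weighted by the
#' fraction of sorted cells the bin represents, and the expression is the
#' resulting profile's weighted mean of the bin expression levels:
#' \deqn{E_i = \sum_b p_{ib} m_b, \quad p_{ib} \propto
#'   (c_{ib}/\sum_i c_{ib}) w_b.}
#' Standard errors come from multinomial resampling of each element's
#' reads across bins. Elements with fewer than \code{min_reads} total
#' reads are flagged \code{low_reads} and get NA estimates rather than
#' being dropped silently.
#'
#' @param counts Numeric matrix, rows = elements (rownames = ids),
#'   columns = bins.
#' @param design A [sortseq_design()].
#' @param min_reads Minimum total reads per element (default 20).
#' @param n_boot Bootstrap draws for the SE (default 200; 0 disables).
#' @param seed Seed for the bootstrap.
#' @return data.frame (element_id, expression, se, total_reads, flag);
#'   expression is bounded by [min(bin_values), max(bin_values)].
#' @export
expression_estimate <- function(counts, design = sortseq_design(),
                                min_reads = 20, n_boot = 200L,
                                seed = NULL) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == design$n_bins)
  if (any(colSums(counts) <= 0)) stop("every bin must have reads")
  total <- rowSums(counts)
  p <- sortseq_profile(counts, design)
  expr <- as.numeric(p %*% design$bin_values)
  se <- rep(NA_real_, nrow(counts))
  if (n_boot > 0) {
    se <- with_seed(seed, {
      depth <- colSums(counts)
      vapply(seq_len(nrow(counts)), function(i) {
        if (total[i] == 0) return(NA_real_)
        prob <- counts[i, ] / total[i]
        draws <- rmultinom(n_boot, total[i], prob)
        q <- draws / depth
        pw <- q * design$cell_fractions
        est <- colSums(pw * design$bin_values) / colSums(pw)
        sd(est)
      }, numeric(1))
    })
  }
  low <- total < min_reads
  expr[low] <- NA_real_
  se[low] <- NA_real_
  data.frame(
    element_id = if (!is.null(rownames(counts))) rownames(counts) else
      paste0("el", seq_len(nrow(counts))),
    expression = expr, se = se, total_reads = as.numeric(total),
    flag = ifelse(low, "low_reads", "ok"), stringsAsFactors = FALSE)
}
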