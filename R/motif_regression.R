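#' Construct a position weight matrix object
#'
#' Weights are log2-odds against a uniform 0.25 background when built from
#' a probability matrix; pre-computed log-odds matrices are accepted as-is.
#' A cutoff score defines the presence or absence of a site.
#'
#' @param matrix Numeric matrix: 4 rows named A, C, G, T (or 4 such
#'   columns, auto-transposed), positions across the other dimension.
#'   Probabilities (columns summing to 1) are converted to log2-odds.
#' @param name PWM name.
#' @param cutoff Score threshold defining a site call.
#' @param pseudo Pseudo-probability added before taking logs of a
#'   probability matrix (default 1e-3).
#' @return List of class \code{ccra_pwm} with \code{matrix} (4 x width
#'   log-odds), \code{width}, \code{name}, \code{cutoff}.
#' @export
ccra_pwm <- function(matrix, name = "pwm", cutoff = 0, pseudo = 1e-3) {
  m <- as.matrix(matrix)
  if (ncol(m) == 4 && !is.null(colnames(m)) &&
      all(DNA_BASES %in% colnames(m))) {
    m <- t(m[, DNA_BASES])
  }
  if (nrow(m) != 4) stop("PWM needs 4 rows (A, C, G, T)")
  if (is.null(rownames(m))) rownames(m) <- DNA_BASES
  m <- m[DNA_BASES, , drop = FALSE]
  if (all(m >= 0) && all(abs(colSums(m) - 1) < 1e-6)) {
    m <- log2((m + pseudo) / (1 + 4 * pseudo)) - log2(0.25)
  }
  stopifnot(is.finite(cutoff))
  structure(list(matrix = m, width = ncol(m), name = name,
                 cutoff = cutoff), class = "ccra_pwm")
}

#' Build a PWM from a consensus sequence
#'
#' Convenience constructor: each consensus base gets probability
#' \code{1 - 3 * mismatch_prob}, other bases \code{mismatch_prob}.
#'
#' @param consensus Consensus DNA string.
#' @param mismatch_prob Per-base probability of each non-consensus base.
#' @param name,cutoff Passed to [ccra_pwm()]; default cutoff is 60% of the
#'   consensus score.
#' @export
pwm_from_consensus <- function(consensus, mismatch_prob = 0.02,
                               name = consensus, cutoff = NULL) {
  bases <- strsplit(consensus, "")[[1]]
  m <- matrix(mismatch_prob, 4, length(bases), dimnames = list(DNA_BASES))
  for (i in seq_along(bases)) m[bases[i], i] <- 1 - 3 * mismatch_prob
  pwm <- ccra_pwm(m, name = name, cutoff = 0)
  max_score <- sum(apply(pwm$matrix, 2, max))
  pwm$cutoff <- if (is.null(cutoff)) 0.6 * max_score else cutoff
  pwm
}

#' Read a PWM from a 4-column/4-row TSV
#'
#' Accepts either orientation: base rows labelled A/C/G/T with positions as
#' columns, or position rows with columns headed A/C/G/T.
#'
#' @param path TSV path.
#' @param name,cutoff Passed to [ccra_pwm()].
#' @export
read_pwm <- function(path, name = basename(path), cutoff = 0) {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (all(DNA_BASES %in% names(raw))) {
    m <- t(as.matrix(raw[, DNA_BASES]))
  } else {
    rn <- as.character(raw[[1]])
    if (all(DNA_BASES %in% rn)) {
      m <- as.matrix(raw[, -1])
      rownames(m) <- rn
      m <- m[DNA_BASES, , drop = FALSE]
    } else {
      stop("PWM TSV must label bases A, C, G, T in its header or first ",
           "column")
    }
  }
  ccra_pwm(m, name = name, cutoff = cutoff)
}

#' Score a sequence window against a PWM
#' @param window DNA string of exactly the PWM width.
#' @param pwm A [ccra_pwm()].
#' @return Log-odds score.
#' @export
score_sequence <- function(window, pwm) {
  b <- match(strsplit(window, "")[[1]], DNA_BASES)
  stopifnot(length(b) == pwm$width, !anyNA(b))
  sum(pwm$matrix[cbind(b, seq_along(b))])
}

scan_strand <- function(promoter, pwm) {
  L <- nchar(promoter)
  w <- pwm$width
  if (L < w) return(numeric(0))
  b <- strsplit(promoter, "")[[1]]
  idx <- match(b, DNA_BASES)
  scores <- vapply(seq_len(L - w + 1), function(i) {
    sum(pwm$matrix[cbind(idx[i:(i + w - 1)], seq_len(w))])
  }, numeric(1))
  scores
}

#' Scan a promoter for PWM sites on both strands
#'
#' Every window scoring at or above the PWM cutoff is a site call;
#' overlapping calls on the same strand are resolved greedily to local
#' maxima (highest score first, discarding overlaps), giving a
#' deterministic site count. Palindromic motifs that score identically on
#' both strands at the same offset are reported once (forward strand).
#'
#' @param promoter DNA string.
#' @param pwm A [ccra_pwm()].
#' @return data.frame of calls: pwm_name, offset (0-based, forward-strand
#'   coordinates), strand, score. Zero rows if no site passes the cutoff.
#' @export
scan_pwm <- function(promoter, pwm) {
  fw <- scan_strand(promoter, pwm)
  rv <- rev(scan_strand(revcomp(promoter), pwm))
  hit_f <- which(fw >= pwm$cutoff)
  hit_r <- which(rv >= pwm$cutoff)
  calls <- rbind(
    data.frame(offset = hit_f - 1L, strand = rep("+", length(hit_f)),
               score = fw[hit_f], stringsAsFactors = FALSE),
    data.frame(offset = hit_r - 1L, strand = rep("-", length(hit_r)),
               score = rv[hit_r], stringsAsFactors = FALSE))
  if (nrow(calls) == 0) {
    return(data.frame(pwm_name = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  ## drop reverse-strand duplicates of palindromic forward calls
  dup <- calls$strand == "-" &
    paste(calls$offset, round(calls$score, 9)) %in%
      paste(calls$offset[calls$strand == "+"],
            round(calls$score[calls$strand == "+"], 9))
  calls <- calls[!dup, , drop = FALSE]
  ## greedy local-maximum overlap resolution within each strand
  keep <- logical(nrow(calls))
  for (s in unique(calls$strand)) {
    idx <- which(calls$strand == s)
    idx <- idx[order(-calls$score[idx], calls$offset[idx])]
    taken <- integer(0)
    for (i in idx) {
      if (all(abs(calls$offset[i] - taken) >= pwm$width)) {
        keep[i] <- TRUE
        taken <- c(taken, calls$offset[i])
      }
    }
  }
  out <- calls[keep, , drop = FALSE]
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  data.frame(pwm_name = pwm$name, out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Summed PWM score of all called sites on a promoter
#'
#' The sum of log-odds scores over all site calls for all supplied PWMs —
#' a linear proxy for the total free energy of binding available to a TF
#' collective on the promoter. Zero when no site passes any cutoff.
#'
#' @param promoter DNA string.
#' @param pwms A [ccra_pwm()] or list of them.
#' @return Numeric score.
#' @export
site_energy_sum <- function(promoter, pwms) {
  if (inherits(pwms, "ccra_pwm")) pwms <- list(pwms)
  sum(vapply(pwms, function(p) sum(scan_pwm(promoter, p)$score),
             numeric(1)))
}

#' Regress a response on a predictor with correlation statistics
#'
#' Ordinary least squares of y on x plus Pearson and Spearman correlations
#' with two-sided p-values — the reduction used to ask how well summed
#' site energies predict binding or expression.
#'
#' @param x,y Paired numeric vectors (>= 3 complete pairs).
#' @return List: slope, intercept, r_squared, pearson_r, pearson_p,
#'   spearman_r, spearman_p, n.
#' @export
regress_binding <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 paired observations")
  if (var(x) == 0) stop("predictor has zero variance")
  fit <- lm(y ~ x)
  pe <- cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_r = unname(sp$estimate), spearman_p = sp$p.value,
       n = length(x))
}
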