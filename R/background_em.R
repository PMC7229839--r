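#' EM fit of the Gaussian + uniform insertion mixture
#'
#' TF-directed transpositions cluster approximately normally around the TF
#' recognition site, while background transpositions land uniformly across
#' the element. For each element this fits, by expectation-maximization,
#' the two-component mixture
#' \deqn{p(x) = \pi N(x; \mu, \sigma^2) + (1-\pi)/L}
#' with the mean fixed at the motif centre, estimating the TF-directed
#' fraction \eqn{\pi} and the spread \eqn{\sigma}. E-step responsibilities
#' are \eqn{r_i = \pi\phi(x_i) / (\pi\phi(x_i) + (1-\pi)/L)}; the M-step
#' sets \eqn{\pi} to their mean and \eqn{\sigma^2} to the responsibility-
#' weighted squared deviation from \eqn{\mu}. Iterates at most
#' \code{max_iter} times (default 1000) or until the parameters no longer
#' change; the log-likelihood is non-decreasing at every iteration.
#'
#' @param positions Insertion coordinates in \code{[0, L)}.
#' @param mu Fixed Gaussian mean: the motif centre, in bp.
#' @param L Element (or promoter) length in bp; uniform density is 1/L.
#' @param pi0,sigma0 Initial values (defaults 0.9 and L/6).
#' @param max_iter Maximum EM iterations (default 1000).
#' @param tol Convergence tolerance: stops when |d pi| < tol and
#'   |d sigma| < tol * L.
#' @param sigma_floor Lower bound on sigma in bp (default 0.5) preventing
#'   degenerate spikes when all mass sits on \code{mu}.
#' @param truncate If TRUE, renormalize the Gaussian to \code{[0, L)}
#'   (default FALSE: the Gaussian is untruncated).
#' @return Object of class \code{ccra_em}: list with \code{pi},
#'   \code{sigma}, \code{mu}, \code{n}, \code{corrected_count}
#'   (= pi * n), \code{iterations}, \code{converged}, and the per-iteration
#'   \code{loglik} trace.
#' @export
em_fit <- function(positions, mu, L, pi0 = 0.9, sigma0 = L / 6,
                   max_iter = 1000L, tol = 1e-6, sigma_floor = 0.5,
                   truncate = FALSE) {
  x <- as.numeric(positions)
  n <- length(x)
  if (n < 2) stop("EM fit needs at least 2 insertions")
  if (mu < 0 || mu >= L) stop("mu must lie within [0, L)")
  gauss <- function(sigma) {
    d <- dnorm(x, mu, sigma)
    if (truncate) {
      z <- pnorm(L, mu, sigma) - pnorm(0, mu, sigma)
      d <- d / z
    }
    d
  }
  unif <- 1 / L
  pi_hat <- pi0
  sigma <- max(sigma0, sigma_floor)
  ll <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    g <- gauss(sigma)
    num <- pi_hat * g
    den <- num + (1 - pi_hat) * unif
    ll[iter] <- sum(log(den))
    r <- num / den
    pi_new <- mean(r)
    sr <- sum(r)
    sigma_new <- if (sr > 0) sqrt(sum(r * (x - mu)^2) / sr) else sigma
    sigma_new <- max(sigma_new, sigma_floor)
    moved <- abs(pi_new - pi_hat) >= tol || abs(sigma_new - sigma) >= tol * L
    pi_hat <- pi_new
    sigma <- sigma_new
    if (!moved) {
      converged <- TRUE
      break
    }
  }
  structure(list(pi = pi_hat, sigma = sigma, mu = mu, L = L, n = n,
                 corrected_count = pi_hat * n, iterations = iter,
                 converged = converged, loglik = ll),
            class = "ccra_em")
}

#' @export
print.ccra_em <- function(x, ...) {
  cat(sprintf(
    "<ccra_em> n=%d  pi=%.3f  sigma=%.2f bp  mu=%.1f  iter=%d%s\n",
    x$n, x$pi, x$sigma, x$mu, x$iterations,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Fit the insertion mixture for every element of a library
#'
#' @param unique_events Unique insertions from [dedup_insertions()].
#' @param motif_centers Named numeric vector: motif centre per element, on
#'   full-sequence coordinates.
#' @param L Element length in bp.
#' @param ... Passed to [em_fit()].
#' @return data.frame (element_id, pi, sigma, n_raw, n_corrected,
#'   iterations, converged); elements with fewer than 2 insertions are
#'   skipped.
#' @export
em_fit_library <- function(unique_events, motif_centers, L, ...) {
  ids <- intersect(names(motif_centers), unique(unique_events$element_id))
  rows <- lapply(ids, function(eid) {
    pos <- unique_events$coordinate[unique_events$element_id == eid]
    if (length(pos) < 2) return(NULL)
    f <- em_fit(pos, motif_centers[[eid]], L, ...)
    data.frame(element_id = eid, pi = f$pi, sigma = f$sigma,
               n_raw = f$n, n_corrected = f$corrected_count,
               iterations = f$iterations, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Background-correct a binding table with per-element EM fits
#'
#' Multiplies each element's raw unique-insertion count by its estimated
#' TF-directed fraction and recomputes NBS from the corrected counts. This
#' removes non-specific transpositions (typically 0-20% of insertions) and
#' is appropriate only where the single-Gaussian assumption holds — i.e.
#' single-motif elements used for binding-energy landscapes. Multi-site
#' elements are refused unless \code{force = TRUE}.
#'
#' @param table A \code{ccra_binding_table} from [compute_nbs()].
#' @param fits data.frame from [em_fit_library()] (or columns element_id,
#'   pi).
#' @param multi_site Logical or named logical per element; if any TRUE and
#'   \code{force} is FALSE the call errors, since a single Gaussian does
#'   not describe insertions around several sites.
#' @param force Apply the correction regardless of \code{multi_site}.
#' @return Corrected \code{ccra_binding_table} with extra columns
#'   \code{pi} and \code{removed_fraction}; counts never increase.
#' @export
correct_counts <- function(table, fits, multi_site = FALSE, force = FALSE) {
  if (any(multi_site) && !force) {
    stop("background correction assumes one Gaussian around a single ",
         "motif; refusing multi-site elements (use force = TRUE to ",
         "override)")
  }
  pi_hat <- setNames(fits$pi, fits$element_id)[table$element_id]
  pi_hat[is.na(pi_hat)] <- 1  # no fit: leave the element uncorrected
  stopifnot(all(pi_hat >= 0 & pi_hat <= 1))
  out <- table
  out$pi <- as.numeric(pi_hat)
  out$removed_fraction <- 1 - out$pi
  out$n_unique <- table$n_unique * out$pi
  scale <- attr(table, "scale")
  nbs <- ifelse(out$abundance == 0, 0,
                scale * (out$n_unique / out$abundance) / sum(out$n_unique))
  out$nbs <- nbs
  attr(out, "scale") <- scale
  out
}
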