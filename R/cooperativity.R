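#' Equilibrium occupancy of a two-site promoter
#'
#' Closed form for the expected number of bound sites (0..2 scale) of a
#' promoter with two binding sites loaded sequentially with stepwise
#' association constants K1 and K2 at free TF concentration P:
#' \deqn{Occ = \frac{2 K_1 P + 2 K_1 K_2 P^2}{1 + 2 K_1 P + K_1 K_2 P^2}.}
#' When K1 = K2 this reduces algebraically to \eqn{2KP/(1+KP)} — twice the
#' single-site occupancy — which is the additive (independent-binding)
#' null; cooperativity appears as K2 > K1.
#'
#' @param K1,K2 Stepwise association constants (shared arbitrary units).
#' @param P Free TF concentration (same units as 1/K).
#' @return Occupancy in [0, 2]; vectorised.
#' @export
occupancy_two_site <- function(K1, K2, P) {
  stopifnot(all(K1 > 0), all(K2 > 0), all(P >= 0))
  (2 * K1 * P + 2 * K1 * K2 * P^2) / (1 + 2 * K1 * P + K1 * K2 * P^2)
}

#' Test observed multi-site binding against the additive null
#'
#' Under independent binding the occupancy of a promoter with several sites
#' equals the sum of the occupancies of the matched single-site promoters.
#' The test compares replicate NBS at the intact promoter against the
#' per-replicate sums of the single-site NBS with a one-sided Welch t-test;
#' cooperativity is called when the observed mean exceeds the additive
#' expectation significantly.
#'
#' @param obs_multi Numeric vector: replicate NBS at the intact (multi-
#'   site) promoter; at least 2 replicates.
#' @param singles List of numeric vectors, one per single-site promoter
#'   (each at least 2 replicates).
#' @param alpha Significance level for the cooperativity call.
#' @return List: \code{expected_sum} (sum of single-site means),
#'   \code{observed_mean}, \code{t_statistic}, \code{p_value},
#'   \code{cooperative}.
#' @export
additive_null_test <- function(obs_multi, singles, alpha = 0.05) {
  if (length(obs_multi) < 2) stop("need >= 2 replicates of multi-site NBS")
  lens <- lengths(singles)
  if (any(lens < 2)) {
    stop("each single-site promoter needs >= 2 replicates")
  }
  n_rep <- min(lens)
  if (length(unique(lens)) > 1) {
    warning("replicate counts differ across single-site promoters; ",
            "using the first ", n_rep, " replicates of each (unpaired ",
            "test)")
  }
  sums <- rowSums(vapply(singles, function(v) v[seq_len(n_rep)],
                         numeric(n_rep)))
  tt <- t.test(obs_multi, sums, alternative = "greater")
  expected <- sum(vapply(singles, mean, numeric(1)))
  list(expected_sum = expected, observed_mean = mean(obs_multi),
       t_statistic = unname(tt$statistic), p_value = tt$p.value,
       cooperative = mean(obs_multi) > expected && tt$p.value < alpha)
}

## RSS of the best cosine of fixed period through (d, y), by linear solve
## of y ~ a cos(wd) + b sin(wd) + C; returns coefficients too
cosine_rss <- function(d, y, period) {
  w <- 2 * pi / period
  X <- cbind(cosd = cos(w * d), sind = sin(w * d), C = 1)
  fit <- stats::lm.fit(X, y)
  list(rss = sum(fit$residuals^2), coef = fit$coefficients)
}

#' Fit a helical-period cosine to a motif-spacing series
#'
#' Models binding occupancy as a function of the distance d between two
#' motif copies:
#' \deqn{Occ(d) = C + A \cos(2\pi (d - d_0)/T),}
#' the signature of helical phasing: sites on the same face of the double
#' helix (d near a multiple of the helical repeat T ~ 10.5 bp) bind
#' cooperatively, sites on opposite faces pay a twist penalty. The period
#' is initialized by grid search over [8, 14] bp in 0.05 bp steps — each
#' grid point solved linearly for (A, phase, C) — then refined by golden-
#' section minimization of the RSS. Model fit is assessed by an ANOVA
#' F-test of the 4-parameter cosine against the intercept-only model with
#' (3, n - 4) degrees of freedom. Replicates enter as independent points.
#'
#' @param distances Numeric vector of spacings (bp), one per observation.
#' @param occupancies Numeric vector of NBS, same length.
#' @param period_range Grid-search bounds in bp (default c(8, 14),
#'   bracketing the helical repeat and excluding harmonics).
#' @param grid_step Grid resolution in bp (default 0.05).
#' @return Object of class \code{ccra_cosine}: amplitude, period, phase
#'   (d0, bp, in [0, period)), phase_rad, baseline, fitted values,
#'   rss_model, rss_null, F statistic, p_value, n.
#' @export
fit_cosine <- function(distances, occupancies, period_range = c(8, 14),
                       grid_step = 0.05) {
  d <- as.numeric(distances)
  y <- as.numeric(occupancies)
  stopifnot(length(d) == length(y))
  n <- length(y)
  if (n < 5) stop("cosine fit needs more observations than parameters (4)")
  if (length(unique(d)) < 6) {
    stop("need >= 6 distinct distances to constrain the period")
  }
  grid <- seq(period_range[1], period_range[2], by = grid_step)
  rss_g <- vapply(grid, function(p) cosine_rss(d, y, p)$rss, numeric(1))
  best <- which.min(rss_g)
  lo <- grid[max(1, best - 1)]
  hi <- grid[min(length(grid), best + 1)]
  opt <- optimize(function(p) cosine_rss(d, y, p)$rss, c(lo, hi),
                  tol = 1e-9)
  period <- opt$minimum
  sol <- cosine_rss(d, y, period)
  a <- sol$coef[["cosd"]]; b <- sol$coef[["sind"]]; C <- sol$coef[["C"]]
  A <- sqrt(a^2 + b^2)
  phi <- atan2(b, a)                  # y = C + A cos(w d - phi)
  d0 <- (phi * period / (2 * pi)) %% period
  rss_model <- sol$rss
  rss_null <- sum((y - mean(y))^2)
  Fstat <- ((rss_null - rss_model) / 3) / (rss_model / (n - 4))
  fitted <- C + A * cos(2 * pi * (d - d0) / period)
  structure(list(amplitude = A, period = period, phase = d0,
                 phase_rad = phi, baseline = C, fitted = fitted,
                 residuals = y - fitted, rss_model = rss_model,
                 rss_null = rss_null, F = Fstat,
                 p_value = pf(Fstat, 3, n - 4, lower.tail = FALSE),
                 n = n),
            class = "ccra_cosine")
}

#' @export
print.ccra_cosine <- function(x, ...) {
  cat(sprintf(
    "<ccra_cosine> period=%.2f bp  amplitude=%.3g  baseline=%.3g  phase=%.2f bp\n  F(3,%d)=%.2f  p=%.3g\n",
    x$period, x$amplitude, x$baseline, x$phase, x$n - 4, x$F, x$p_value))
  invisible(x)
}

#' Free-energy cost of twisting DNA between helical phases
#'
#' The fold difference between the highest (in-phase) and lowest (out-of-
#' phase) occupancy of a spacing series converts to the free energy lost to
#' twisting: \eqn{\Delta\Delta G_{twist} = RT \ln(fold)}. The fold is
#' either supplied directly (max/min of the data) or taken from a cosine
#' fit as (C + A)/(C - A); the two coincide on noiseless data.
#'
#' @param x A \code{ccra_cosine} fit, or a single numeric fold >= 1.
#' @param cfg [energetics_config()].
#' @return List with \code{fold}, \code{kj_mol} and \code{kbt}.
#' @export
twist_penalty <- function(x, cfg = energetics_config()) {
  fold <- if (inherits(x, "ccra_cosine")) {
    if (x$baseline <= x$amplitude) {
      stop("baseline <= amplitude: fitted minimum occupancy is not ",
           "positive, fold undefined")
    }
    (x$baseline + x$amplitude) / (x$baseline - x$amplitude)
  } else {
    if (!is.numeric(x) || length(x) != 1 || x < 1) {
      stop("fold must be a single number >= 1")
    }
    x
  }
  kj <- rt_kj(cfg) * log(fold)
  list(fold = fold, kj_mol = kj, kbt = kj / rt_kj(cfg))
}

#' Classify a site pair as in or out of helical phase
#'
#' Two sites separated by a multiple of the helical repeat (~10.5 bp)
#' present their major grooves on the same face of the double helix
#' (in phase); a multiple plus ~half a turn puts them on opposite faces.
#'
#' @param distance Distance(s) between site pairs in bp.
#' @param period Helical repeat (default 10.5 bp).
#' @param window Distance-from-multiple (bp) still counted in phase;
#'   default period/4, splitting the turn evenly between the classes.
#' @return Character vector: "in_phase" or "out_of_phase". Periodic:
#'   classification is invariant to adding whole periods.
#' @export
classify_phase <- function(distance, period = 10.5, window = period / 4) {
  stopifnot(all(distance > 0))
  r <- distance %% period
  ifelse(pmin(r, period - r) <= window, "in_phase", "out_of_phase")
}

#' Compare binding between in-phase and out-of-phase site pairs
#'
#' Groups site pairs by [classify_phase()] and compares their binding
#' scores with a two-sample Welch t-test.
#'
#' @param distances Pair distances in bp.
#' @param scores Binding scores, same length.
#' @param period,window Passed to [classify_phase()].
#' @return List with \code{group_means} (named), \code{n} per group,
#'   \code{t_statistic}, \code{p_value}.
#' @export
phase_group_test <- function(distances, scores, period = 10.5,
                             window = period / 4) {
  stopifnot(length(distances) == length(scores))
  g <- classify_phase(distances, period, window)
  if (sum(g == "in_phase") < 2 || sum(g == "out_of_phase") < 2) {
    stop("need >= 2 site pairs in each phase group")
  }
  tt <- t.test(scores[g == "in_phase"], scores[g == "out_of_phase"])
  list(group_means = c(in_phase = mean(scores[g == "in_phase"]),
                       out_of_phase = mean(scores[g == "out_of_phase"])),
       n = c(in_phase = sum(g == "in_phase"),
             out_of_phase = sum(g == "out_of_phase")),
       t_statistic = unname(tt$statistic), p_value = tt$p.value)
}
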