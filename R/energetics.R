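#' Thermodynamic configuration for free-energy conversions
#'
#' @param temperature Absolute temperature in kelvin. Default 303.15 K
#'   (30 degrees C, standard yeast growth temperature).
#' @param units Energy units for reported values: \code{"kJ/mol"} or
#'   \code{"kbt"} (thermal energy; per mole, 1 kbt = RT).
#' @return List of class \code{ccra_energetics} with fields
#'   \code{temperature}, \code{R} (8.314 J/(mol K)) and \code{units}.
#' @export
energetics_config <- function(temperature = 303.15,
                              units = c("kJ/mol", "kbt")) {
  stopifnot(temperature > 0)
  structure(list(temperature = temperature, R = 8.314,
                 units = match.arg(units)),
            class = "ccra_energetics")
}

rt_kj <- function(cfg) cfg$R * cfg$temperature / 1000  # kJ/mol

in_units <- function(kj, cfg) {
  if (cfg$units == "kbt") kj / rt_kj(cfg) else kj
}

#' Convert between kJ/mol and kbt
#' @param value Energy value.
#' @param from,to \code{"kJ/mol"} or \code{"kbt"}.
#' @param cfg [energetics_config()] supplying the temperature.
#' @export
convert_energy <- function(value, from = "kJ/mol", to = "kbt",
                           cfg = energetics_config()) {
  kj <- if (from == "kbt") value * rt_kj(cfg) else value
  if (to == "kbt") kj / rt_kj(cfg) else kj
}

#' Binding free-energy difference from an occupancy ratio
#'
#' In the low-occupancy regime (dissociation constant much larger than the
#' free TF concentration) occupancy is proportional to 1/K, so the change
#' in binding free energy between a variant site and the consensus is
#' \deqn{\Delta\Delta G = -RT \ln(Occ_{mut} / Occ_{cons}),}
#' positive when the variant binds more weakly. Occupancy is proxied by the
#' background-corrected NBS; ratios make the result independent of the NBS
#' scale constant.
#'
#' @param occ_mut,occ_cons Occupancies (corrected NBS) of variant and
#'   consensus; must be positive.
#' @param cfg [energetics_config()].
#' @return Energy in \code{cfg$units}.
#' @export
delta_delta_g <- function(occ_mut, occ_cons, cfg = energetics_config()) {
  if (any(occ_mut <= 0) || any(occ_cons <= 0)) {
    stop("occupancies must be positive; for zero-count variants add a ",
         "pseudocount (see build_landscape(pseudocount=)) and report the ",
         "result as a lower bound")
  }
  in_units(-rt_kj(cfg) * log(occ_mut / occ_cons), cfg)
}

#' Binding free energy from an association constant
#'
#' \eqn{\Delta G = -RT \ln(K_a \cdot 1 M)}, referenced to the 1 M standard
#' state; negative for favourable binding.
#'
#' @param ka Association constant in 1/M.
#' @param cfg [energetics_config()].
#' @return Energy in \code{cfg$units}.
#' @export
dg_from_ka <- function(ka, cfg = energetics_config()) {
  if (any(ka <= 0)) stop("association constant must be positive")
  in_units(-rt_kj(cfg) * log(ka), cfg)
}

#' Dissociation constant of a variant from a reference Kd and a ddG
#'
#' \eqn{K_{d,mut} = K_{d,ref} \exp(\Delta\Delta G / RT)}.
#'
#' @param kd_ref Reference dissociation constant (any concentration unit;
#'   the result is in the same unit).
#' @param ddg Free-energy penalty in kJ/mol.
#' @param cfg [energetics_config()].
#' @export
kd_from_ddg <- function(kd_ref, ddg, cfg = energetics_config()) {
  if (any(kd_ref <= 0)) stop("kd_ref must be positive")
  kd_ref * exp(ddg / rt_kj(cfg))
}

#' Build a single-bp binding-energy landscape from replicate occupancies
#'
#' Aggregates background-corrected NBS across replicates (mean occupancy
#' per variant, then the log-ratio to the consensus), yielding the ddG of
#' every variant relative to the consensus site. The ddG standard deviation
#' is propagated by the delta method from the replicate spread of both the
#' variant and the consensus:
#' \eqn{sd(\Delta\Delta G) \approx RT \sqrt{cv_{mut}^2/n_{mut} +
#' cv_{cons}^2/n_{cons}}}.
#'
#' @param occupancies data.frame with columns \code{label},
#'   \code{replicate}, \code{nbs} (and optionally \code{position},
#'   \code{base} from [single_bp_variants()]).
#' @param consensus_label Label of the reference variant (default
#'   "consensus").
#' @param cfg [energetics_config()].
#' @param pseudocount Added to every occupancy before the ratio (default 0,
#'   i.e. off); with a pseudocount, zero-occupancy variants yield a lower
#'   bound on ddG, flagged in the \code{bound} column.
#' @return data.frame of class \code{ccra_landscape}: one row per variant
#'   with mean_nbs, sd_nbs, n_replicates, ddg_kj, ddg_kbt, sd_ddg_kj,
#'   bound; the consensus row has ddg 0 by construction. Sorted by motif
#'   position then base, consensus first.
#' @export
build_landscape <- function(occupancies, consensus_label = "consensus",
                            cfg = energetics_config(), pseudocount = 0) {
  stopifnot(all(c("label", "nbs") %in% names(occupancies)))
  if (!consensus_label %in% occupancies$label) {
    stop("consensus label '", consensus_label, "' not found")
  }
  agg <- do.call(rbind, lapply(split(occupancies, occupancies$label),
    function(d) {
      data.frame(label = d$label[1],
                 position = if ("position" %in% names(d)) d$position[1]
                            else NA_integer_,
                 base = if ("base" %in% names(d)) d$base[1]
                        else NA_character_,
                 mean_nbs = mean(d$nbs), sd_nbs = sd(d$nbs),
                 n_replicates = nrow(d), stringsAsFactors = FALSE)
    }))
  cons <- agg[agg$label == consensus_label, ]
  occ_c <- cons$mean_nbs + pseudocount
  occ_m <- agg$mean_nbs + pseudocount
  if (occ_c <= 0 || any(occ_m <= 0)) {
    stop("non-positive occupancy; set pseudocount > 0 to obtain lower ",
         "bounds for unbound variants")
  }
  rt <- rt_kj(cfg)
  agg$ddg_kj <- -rt * log(occ_m / occ_c)
  agg$ddg_kbt <- agg$ddg_kj / rt
  cv2 <- function(m, s, n) ifelse(n > 1 & m > 0, (s / m)^2 / n, 0)
  agg$sd_ddg_kj <- rt * sqrt(cv2(occ_m, agg$sd_nbs, agg$n_replicates) +
                             cv2(occ_c, cons$sd_nbs, cons$n_replicates))
  agg$bound <- pseudocount > 0 & agg$mean_nbs <= 0
  ord <- order(!is.na(agg$position), agg$position, agg$base,
               na.last = FALSE)
  agg <- agg[ord, , drop = FALSE]
  agg <- rbind(agg[agg$label == consensus_label, , drop = FALSE],
               agg[agg$label != consensus_label, , drop = FALSE])
  rownames(agg) <- NULL
  class(agg) <- c("ccra_landscape", "data.frame")
  attr(agg, "temperature") <- cfg$temperature
  agg
}
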