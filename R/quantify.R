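## KP quantification: per-domain FITC means, the microcap partition
## coefficient, and the equilibrium plateau check for time-lapse traces.

#' Mean FITC intensity per domain
#'
#' Arithmetic (voxel-count weighted) mean of the FITC signal over each
#' nonempty domain. Empty domains are absent from the result, not reported as
#' zero.
#'
#' @param fitc 3-D numeric array, the FITC channel.
#' @param labels a [DomainLabelVolume-class] of the same shape.
#' @return Named numeric vector of means (subset of
#'   `water`, `hydrogel`, `microsphere`, `coupon`).
#' @export
domainMeans <- function(fitc, labels) {
  lab <- labelArray(labels)
  if (!identical(dim(fitc), dim(lab)))
    stop("fitc and labels must share one shape")
  out <- vapply(names(DOMAIN_CODES), function(nm) {
    sel <- lab == DOMAIN_CODES[[nm]]
    if (!any(sel)) NA_real_ else mean(fitc[sel])
  }, numeric(1))
  out[!is.na(out)]
}

#' Microcap partition coefficient from a labeled FITC volume
#'
#' Computes \eqn{K_P = [\mathrm{FITC}]_{microcap} / [\mathrm{FITC}]_{water}}:
#' the numerator is the voxel-weighted mean over the union of the hydrogel
#' and microsphere domains (not an average of the two domain means); the
#' denominator is the mean over the water domain, excluding the
#' `waterGuardLayers` z-layers immediately above the highest coupon voxel
#' (the coupon surface reflection would otherwise bias the water mean).
#'
#' @inheritParams domainMeans
#' @param waterGuardLayers water z-layers above the coupon top excluded from
#'   the water mean (default 1).
#' @param saturationLevel intensities at or above this are counted as
#'   saturated in diagnostics (default `Inf`, i.e. off); values are never
#'   clipped.
#' @param baseline optional characterization-phase FITC volume (same shape)
#'   subtracted voxel-wise before any statistic; off (`NULL`) by default —
#'   the source procedure states no background subtraction.
#' @return A [PartitionResult-class].
#' @examples
#' g <- makeGeometry(capRadius = 20, couponZ = 2, seed = 1)
#' cfg <- imagingConfig(dim = c(48, 48, 32), voxelSize = 1, seed = 1)
#' fld <- concentrationField(fitcWater = 100, fitcHydrogel = 70)
#' gt <- groundTruth(g, cfg, fld)
#' stk <- renderStack(g, fld, cfg)
#' partitionCoefficient(channel(stk, "fitc"), gt$labels)
#' @export
partitionCoefficient <- function(fitc, labels, waterGuardLayers = 1L,
                                 saturationLevel = Inf, baseline = NULL) {
  lab <- labelArray(labels)
  if (!identical(dim(fitc), dim(lab)))
    stop("fitc and labels must share one shape")
  if (!is.null(baseline)) {
    if (!identical(dim(baseline), dim(fitc)))
      stop("baseline and fitc must share one shape")
    fitc <- fitc - baseline
  }
  means <- domainMeans(fitc, labels)
  cnt <- domainCounts(labels)
  nMicro <- cnt[["hydrogel"]] + cnt[["microsphere"]]
  if (nMicro == 0L)
    stop("domain empty: microcap domain (hydrogel + microsphere) has no voxels")
  if (cnt[["water"]] == 0L)
    stop("domain empty: water domain has no voxels; KP undefined")
  micro <- lab == DOMAIN_CODES[["hydrogel"]] | lab == DOMAIN_CODES[["microsphere"]]
  fitcMicrocap <- mean(fitc[micro])

  water <- lab == DOMAIN_CODES[["water"]]
  nExcluded <- 0
  couponAny <- lab == DOMAIN_CODES[["coupon"]]
  if (waterGuardLayers > 0L && any(couponAny)) {
    zTop <- max(which(apply(couponAny, 3L, any)))
    guard <- seq(zTop + 1L, min(zTop + waterGuardLayers, dim(lab)[3L]))
    if (length(guard) && guard[1L] <= dim(lab)[3L]) {
      before <- sum(water)
      water[, , guard] <- FALSE
      nExcluded <- before - sum(water)
    }
  }
  if (!any(water))
    stop("domain empty: water domain vanished after the guard band; KP undefined")
  fitcWater <- mean(fitc[water])
  if (fitcWater <= 0)
    stop("undefined KP: water mean is not positive")
  nSat <- sum(fitc >= saturationLevel)
  if (nSat > 0)
    warning(nSat, " saturated voxel(s) at or above ", saturationLevel)
  new("PartitionResult",
      domainMeans = means, domainCounts = as.numeric(cnt),
      fitcMicrocap = fitcMicrocap, fitcWater = fitcWater,
      kp = fitcMicrocap / fitcWater, nWaterExcluded = as.numeric(nExcluded))
}

#' Has a time-lapse intensity trace reached equilibrium?
#'
#' During the accumulation phase a single z-plane is imaged over time; the
#' system is at equilibrium when the trace has plateaued. The check fits a
#' least-squares line to the tail window (the last `tailFraction` of the
#' samples), normalizes its slope by the tail mean, and declares equilibrium
#' when the normalized slope magnitude is at most `slopeTol`.
#'
#' @param times sample times in seconds, strictly increasing.
#' @param values mean ROI intensity per frame, same length.
#' @param tailFraction fraction of samples in the tail window (default 0.25).
#' @param slopeTol tolerance on |slope| / mean, per minute (default 0.01,
#'   i.e. 1 percent of the plateau per minute).
#' @return Logical with attributes `slopePerMin` (normalized slope, /min),
#'   `tailMean`, and `nTail`.
#' @examples
#' t <- seq(0, 1440, by = 30)
#' equilibriumReached(t, 100 * (1 - exp(-t / 180)))
#' @export
equilibriumReached <- function(times, values, tailFraction = 0.25,
                               slopeTol = 0.01) {
  if (length(times) != length(values))
    stop("times and values must have one length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  nTail <- max(5L, ceiling(length(times) * tailFraction))
  if (length(times) < nTail || nTail < 5L)
    stop("insufficient trace: need at least 5 samples in the tail window")
  idx <- seq(length(times) - nTail + 1L, length(times))
  tt <- times[idx] / 60                     # minutes
  vv <- values[idx]
  m <- mean(vv)
  if (m == 0) stop("insufficient trace: tail mean is zero")
  slope <- stats::cov(tt, vv) / stats::var(tt)
  norm <- slope / m
  structure(abs(norm) <= slopeTol,
            slopePerMin = norm, tailMean = m, nTail = nTail)
}

#' Write per-microcap partition results to CSV
#'
#' One row per result: id, domain means, voxel counts, and KP.
#'
#' @param results named list of [PartitionResult-class] objects.
#' @param path output CSV path.
#' @return The data.frame, invisibly.
#' @export
writePartitionCsv <- function(results, path) {
  rows <- lapply(names(results), function(id) {
    r <- results[[id]]
    m <- domainMeansOf(r)
    full <- stats::setNames(rep(NA_real_, 4L), names(DOMAIN_CODES))
    full[names(m)] <- m
    data.frame(microcap_id = id,
               mean_water = full[["water"]], mean_hydrogel = full[["hydrogel"]],
               mean_microsphere = full[["microsphere"]],
               mean_coupon = full[["coupon"]],
               n_water = r@domainCounts[1L], n_hydrogel = r@domainCounts[2L],
               n_microsphere = r@domainCounts[3L], n_coupon = r@domainCounts[4L],
               fitc_microcap = r@fitcMicrocap, fitc_water = r@fitcWater,
               kp = r@kp)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
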