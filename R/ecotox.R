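## Bioconcentration conversions linking the microcap partition coefficient to
## the ecotoxicological BCF/pBCF scale, the dry-to-wet mass rescaling, and
## the pore-water correction for porous biofilms.

#' Convert between KP and the study's pBCF scale
#'
#' Study rows report `pbcf = -log10(kp)`; this sign reproduces the headline
#' 30 percent partition-coefficient decrease from the printed pBCF pair of
#' the two neutral dextrans (0.164 vs 0.319) and keeps the pore-water factor
#' consistent. Literature BCFs are on their own (positive-log) scale and are
#' never re-derived through this convention; the comparison table carries a
#' convention column instead of silently mixing scales.
#'
#' @param kp partition coefficient(s), > 0.
#' @param pbcf log-scale value(s).
#' @return `kpToPbcf`: pbcf; `pbcfToKp`: kp. Exact inverses.
#' @examples
#' kpToPbcf(1)            # 0
#' pbcfToKp(0.164) / pbcfToKp(0.319)  # the ~30% size-exclusion decrease
#' @export
kpToPbcf <- function(kp) {
  if (any(kp <= 0)) stop("kp must be > 0")
  -log10(kp)
}

#' @rdname kpToPbcf
#' @export
pbcfToKp <- function(pbcf) 10^(-pbcf)

#' Rescale a dry-mass BCF to a wet-mass basis
#'
#' Periphytic biofilms are hydrated in the environment, so wet-weight BCFs
#' are the comparable quantity; dry-weight values are rescaled assuming a
#' 100:1 biofilm wet:dry mass ratio — a log10 shift of exactly 2.
#'
#' @param bcfDry dry-basis BCF(s), > 0.
#' @param wetToDry wet:dry mass ratio (default 100).
#' @return Wet-basis BCF(s).
#' @examples
#' dryToWetBcf(100)   # 1
#' @export
dryToWetBcf <- function(bcfDry, wetToDry = 100) {
  if (any(bcfDry <= 0)) stop("bcfDry must be > 0")
  if (wetToDry <= 0) stop("wetToDry must be > 0")
  bcfDry / wetToDry
}

#' Pore-water-corrected bioconcentration factor
#'
#' Biofilms contain channels filled with pore water. If that pore water is in
#' equilibrium with the surrounding water, a BCF computed over the whole
#' porous biofilm (solids + pore water in the denominator mass) is strictly
#' smaller than one computed against the solid mass alone:
#' \deqn{\frac{(m_{b,bound} + m_{pore}) / (m_b + m_w)}{c_{bulk}} <
#'       \frac{(m_{b,bound} + m_{pore}) / m_b}{c_{bulk}}}
#' for any pore-water mass \eqn{m_w > 0}. On the log scale the two differ by
#' `delta_pbcf = log10((m_b + m_w) / m_b)` — log10(2) for a biofilm of equal
#' weight to water — which depends only on the ratio `m_w / m_b`.
#'
#' @param mNdxBound mass of diffusing species bound in the biofilm solids.
#' @param mB biofilm solid mass, > 0.
#' @param mW pore-water mass, >= 0.
#' @param cBulk bulk-water concentration (mass per mass), > 0.
#' @param mNdxPore mass in the pore water; defaults to the equilibrium value
#'   `cBulk * mW`.
#' @return list with `bcfWithPores`, `bcfWithoutPores`, `deltaPbcf`.
#' @examples
#' poreCorrectedBcf(mNdxBound = 5, mB = 1, mW = 1, cBulk = 0.1)$deltaPbcf  # log10(2)
#' @export
poreCorrectedBcf <- function(mNdxBound, mB, mW, cBulk, mNdxPore = cBulk * mW) {
  if (mB <= 0) stop("mB must be > 0")
  if (cBulk <= 0) stop("cBulk must be > 0")
  if (mNdxBound < 0 || mW < 0 || mNdxPore < 0)
    stop("masses must be >= 0")
  tot <- mNdxBound + mNdxPore
  list(bcfWithPores = (tot / (mB + mW)) / cBulk,
       bcfWithoutPores = (tot / mB) / cBulk,
       deltaPbcf = log10((mB + mW) / mB))
}

#' Load the literature bioconcentration fixture table
#'
#' Literature pBCF rows for engineered nanomaterials in periphytic biofilms,
#' shipped verbatim as a version-controlled CSV (never recomputed). Some
#' pBCF cells are printed ranges; they are kept as text with a parsed numeric
#' midpoint alongside.
#'
#' @return data.frame with columns `type`, `biofilm`, `size_nm`, `hydropathy`,
#'   `charge`, `t_c`, `pbcf` (text as printed), `pbcf_mid` (numeric),
#'   `source`, `convention`.
#' @export
literatureBcfTable <- function() {
  path <- system.file("extdata", "literature_bcf.csv", package = "microcapKP",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("type", "biofilm", "size_nm", "hydropathy", "charge", "t_c",
            "pbcf", "source")
  if (!all(need %in% names(df)))
    stop("malformed fixture: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$pbcf_mid <- vapply(df$pbcf, function(s) {
    v <- suppressWarnings(as.numeric(
      regmatches(s, gregexpr("[0-9]+\\.?[0-9]*", s))[[1L]]))
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1), USE.NAMES = FALSE)
  df$convention <- "literature log10 BCF (as published)"
  df
}

#' Merge study KP rows with the literature fixture
#'
#' Study rows are converted to pBCF via [kpToPbcf()]; literature rows pass
#' through verbatim. The `convention` column records which log scale each row
#' is on.
#'
#' @param studyRecords data.frame with at least `type`, `biofilm`, `kp`;
#'   optional `size_nm`, `hydropathy`, `charge`, `t_c`.
#' @param literature fixture table (default [literatureBcfTable()]).
#' @return data.frame with columns `type`, `biofilm`, `size_nm`,
#'   `hydropathy`, `charge`, `t_c`, `pbcf`, `pbcf_mid`, `source`,
#'   `convention`; row count = study rows + fixture rows.
#' @examples
#' buildComparisonTable(data.frame(type = "FITC-Dx-150", biofilm = "Hydrogel",
#'                                 kp = 0.703))
#' @export
buildComparisonTable <- function(studyRecords = NULL,
                                 literature = literatureBcfTable()) {
  cols <- c("type", "biofilm", "size_nm", "hydropathy", "charge", "t_c",
            "pbcf", "pbcf_mid", "source", "convention")
  lit <- literature[, cols]
  if (is.null(studyRecords) || nrow(studyRecords) == 0L) return(lit)
  if (!all(c("type", "biofilm", "kp") %in% names(studyRecords)))
    stop("studyRecords needs columns type, biofilm, kp")
  pb <- kpToPbcf(studyRecords$kp)
  study <- data.frame(
    type = studyRecords$type, biofilm = studyRecords$biofilm,
    size_nm = if ("size_nm" %in% names(studyRecords)) studyRecords$size_nm else "",
    hydropathy = if ("hydropathy" %in% names(studyRecords)) studyRecords$hydropathy else "Hydrophilic",
    charge = if ("charge" %in% names(studyRecords)) studyRecords$charge else "",
    t_c = if ("t_c" %in% names(studyRecords)) studyRecords$t_c else "24 min",
    pbcf = formatC(pb, digits = 3, format = "fg"),
    pbcf_mid = pb,
    source = "this-study",
    convention = "-log10(KP)",
    stringsAsFactors = FALSE
  )
  rbind(study[, cols], lit)
}
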