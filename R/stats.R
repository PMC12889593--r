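## Replicate aggregation and the directional hypothesis battery: technical
## (microcap) replicates are averaged per coupon, batches form the sample
## (n = 3 per condition), and each effect is tested with a one-tailed Welch
## test at alpha = 0.05, gated by Shapiro-Wilk normality. No multiple-testing
## correction is applied (fidelity to the source procedure); the battery
## reports the number of comparisons so users can apply their own.

#' Average technical (microcap) replicates per coupon
#'
#' The three microcaps on a coupon are technical replicates and are averaged;
#' each coupon (one per batch and condition) then contributes one KP, so the
#' per-condition sample size equals the number of batches.
#'
#' @param dataset data.frame with columns `microsphere_type`, `nanodextran`,
#'   `batch`, `coupon`, `microcap`, `kp` (as produced by [simulateStudy()]).
#' @param microcapsPerCoupon expected technical replicates per coupon
#'   (default 3); coupons with fewer draw a warning and are averaged over what
#'   is available.
#' @return data.frame with one row per coupon: `microsphere_type`,
#'   `nanodextran`, `batch`, `coupon`, `kp` (the technical mean) and
#'   `n_microcaps`.
#' @export
aggregateTechnical <- function(dataset, microcapsPerCoupon = 3L) {
  need <- c("microsphere_type", "nanodextran", "batch", "coupon", "kp")
  if (!all(need %in% names(dataset)))
    stop("dataset lacks columns: ",
         paste(setdiff(need, names(dataset)), collapse = ", "))
  if (any(dataset$kp < 0)) stop("kp values must be >= 0")
  key <- interaction(dataset$microsphere_type, dataset$nanodextran,
                     dataset$batch, dataset$coupon, drop = TRUE)
  idx <- split(seq_len(nrow(dataset)), key)
  rows <- lapply(idx, function(i) {
    d <- dataset[i, ]
    data.frame(microsphere_type = d$microsphere_type[1L],
               nanodextran = d$nanodextran[1L],
               batch = d$batch[1L], coupon = d$coupon[1L],
               kp = mean(d$kp), n_microcaps = nrow(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  short <- out$n_microcaps < microcapsPerCoupon
  if (any(short))
    warning(sum(short), " coupon(s) have fewer than ", microcapsPerCoupon,
            " microcap replicates; averaged over what is available")
  out[order(out$microsphere_type, out$nanodextran, out$batch), ]
}

#' One-tailed Welch two-sample t-test
#'
#' Welch's unequal-variance t statistic
#' \deqn{t = (\bar a - \bar b) / \sqrt{s_a^2/n_a + s_b^2/n_b}}
#' with Welch-Satterthwaite degrees of freedom, and a one-tailed p-value in
#' the stated direction (`"greater"`: evidence that a exceeds b). One-tailed
#' tests are used because only an effect in one direction constitutes
#' evidence for each transport hypothesis.
#'
#' @param a,b numeric samples, each with at least 2 values.
#' @param direction `"greater"` or `"less"` (alternative for mean(a) vs
#'   mean(b)).
#' @param alpha significance level (default 0.05).
#' @return data.frame row: `t`, `df`, `p`, `direction`, `alpha`,
#'   `significant`.
#' @examples
#' welchOneTailed(c(0.5, 0.6, 0.7), c(0.3, 0.4, 0.5), "greater")
#' @export
welchOneTailed <- function(a, b, direction = c("greater", "less"),
                           alpha = 0.05) {
  direction <- match.arg(direction)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b))
      stop("degenerate test: zero variance in both samples with equal means")
    # unambiguous separation with no spread: report an infinite statistic
    t <- sign(mean(a) - mean(b)) * Inf
    df <- length(a) + length(b) - 2
  } else {
    se2 <- va / length(a) + vb / length(b)
    t <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                   (vb / length(b))^2 / (length(b) - 1))
  }
  p <- if (direction == "greater") stats::pt(t, df, lower.tail = FALSE)
       else stats::pt(t, df, lower.tail = TRUE)
  data.frame(t = t, df = df, p = p, direction = direction, alpha = alpha,
             significant = p <= alpha)
}

#' Shapiro-Wilk normality test
#'
#' For the study-typical n = 3 the exact closed form applies:
#' \deqn{W = \left(a_1 (x_{(3)} - x_{(1)})\right)^2 / \sum_i (x_i - \bar x)^2}
#' with \eqn{a_1 = 1/\sqrt 2}, and
#' \eqn{p = (6/\pi)(\arcsin\sqrt W - \arcsin\sqrt{3/4})}. For 4 <= n <= 50
#' the computation delegates to [stats::shapiro.test()] (Royston's
#' approximation).
#'
#' @param x numeric sample, 3 <= length <= 50, not constant.
#' @return list with `W` and `p`.
#' @examples
#' shapiroWilk(c(1, 2, 3))   # W exactly 1
#' @export
shapiroWilk <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L || n > 50L) stop("sample size must be in [3, 50]")
  if (stats::var(x) == 0) stop("degenerate sample: zero variance")
  if (n == 3L) {
    s <- sort(x)
    W <- ((s[3L] - s[1L]) / sqrt(2))^2 / sum((x - mean(x))^2)
    W <- min(W, 1)
    p <- (6 / pi) * (asin(sqrt(W)) - asin(sqrt(0.75)))
    list(W = W, p = min(max(p, 0), 1))
  } else {
    st <- stats::shapiro.test(x)
    list(W = unname(st$statistic), p = st$p.value)
  }
}

#' 95 percent confidence interval on a sample mean
#'
#' `mean(x) +/- t(0.975, n-1) * s / sqrt(n)` — the error bars of the study's
#' condition plots.
#'
#' @param x numeric sample, n >= 2.
#' @return Named numeric `c(low, high)`.
#' @export
confidenceInterval95 <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 values for a confidence interval")
  half <- stats::qt(0.975, n - 1L) * stats::sd(x) / sqrt(n)
  c(low = mean(x) - half, high = mean(x) + half)
}

#' The directional hypothesis battery of the microcap study
#'
#' `hypothesisSpecs()` enumerates the six primary comparisons (conditions are
#' `"<microsphere_type>/<nanodextran>"` keys):
#' \itemize{
#'   \item size exclusion (1): plain/Dx-150 > plain/Dx-2000 — a larger
#'     dextran reaches a lower equilibrium level in the mesh.
#'   \item volume exclusion (1): none/Dx-150 > plain/Dx-150 — impermeable
#'     spheres remove accessible volume.
#'   \item attachment (4): each oppositely charged pairing (amino spheres +
#'     CM dextran; carboxyl spheres + DEAE dextran) is expected to exceed
#'     both of its controls (charged dextran with plain spheres; neutral
#'     dextran with the same charged spheres).
#' }
#' `runHypothesisBattery()` aggregates technical replicates, gates each
#' sample with [shapiroWilk()] at `alpha`, and runs a one-tailed
#' [welchOneTailed()] per comparison.
#'
#' @param dataset microcap-level data.frame (see [aggregateTechnical()]).
#' @param specs comparison table as from `hypothesisSpecs()`.
#' @param alpha significance level (default 0.05).
#' @param normality `"warn"` (default) warns and proceeds when a sample fails
#'   the normality gate; `"strict"` aborts.
#' @return data.frame: one row per comparison with `effect`, `condition_a`,
#'   `condition_b`, `direction`, `t`, `df`, `p`, `significant`, plus
#'   attribute `n_comparisons` (no multiple-testing correction is applied).
#' @examples
#' plan <- studyPlan()
#' ds <- simulateStudy(plan, studyEffectKp(), noiseSd = 0.05, seed = 1)
#' runHypothesisBattery(ds)
#' @export
runHypothesisBattery <- function(dataset, specs = hypothesisSpecs(),
                                 alpha = 0.05,
                                 normality = c("warn", "strict")) {
  normality <- match.arg(normality)
  agg <- aggregateTechnical(dataset)
  key <- paste(agg$microsphere_type, agg$nanodextran, sep = "/")
  samples <- split(agg$kp, key)
  missing <- setdiff(unique(c(specs$condition_a, specs$condition_b)),
                     names(samples))
  if (length(missing))
    stop("missing condition(s): ", paste(missing, collapse = ", "))
  for (cond in unique(c(specs$condition_a, specs$condition_b))) {
    sw <- shapiroWilk(samples[[cond]])
    if (sw$p < alpha) {
      msg <- sprintf("condition %s fails the normality gate (W = %.3f, p = %.3g)",
                     cond, sw$W, sw$p)
      if (normality == "strict") stop(msg) else warning(msg)
    }
  }
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    w <- welchOneTailed(samples[[specs$condition_a[i]]],
                        samples[[specs$condition_b[i]]],
                        specs$direction[i], alpha)
    cbind(specs[i, c("effect", "condition_a", "condition_b")], w)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_comparisons") <- nrow(out)
  out
}

#' @rdname runHypothesisBattery
#' @export
hypothesisSpecs <- function() {
  data.frame(
    effect = c("size_exclusion", "volume_exclusion",
               "attachment", "attachment", "attachment", "attachment"),
    condition_a = c("plain/Dx-150", "none/Dx-150",
                    "amino/CM-150", "amino/CM-150",
                    "carboxyl/DEAE-150", "carboxyl/DEAE-150"),
    condition_b = c("plain/Dx-2000", "plain/Dx-150",
                    "plain/CM-150", "amino/Dx-150",
                    "plain/DEAE-150", "carboxyl/Dx-150"),
    direction = "greater",
    stringsAsFactors = FALSE
  )
}
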