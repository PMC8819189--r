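#' Conical frustum volume of the upper primary root
#'
#' The upper 5 cm of the primary root is modelled as a conical frustum from
#' two diameter measurements: immediately below the leaf rosette (`d1`) and
#' 5 cm further down (`d2`). `V = pi * h * (r1^2 + r1 r2 + r2^2) / 3` with
#' radii in cm (diameters are given in mm). Symmetric in the two diameters
#' and strictly increasing in each.
#'
#' @param d1_mm,d2_mm Diameters in millimetres (> 0; vectors allowed).
#' @param h_cm Segment height in centimetres (default 5).
#' @return Volume in cubic centimetres.
#' @export
frustum_volume <- function(d1_mm, d2_mm, h_cm = 5) {
  if (any(d1_mm <= 0) || any(d2_mm <= 0) || any(h_cm <= 0))
    stop("diameters and height must be positive")
  r1 <- d1_mm / 20  # mm diameter -> cm radius
  r2 <- d2_mm / 20
  pi * h_cm * (r1^2 + r1 * r2 + r2^2) / 3
}

.p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "n.s.")))
}

.lillie_p <- function(x) {
  # Kolmogorov-Smirnov normality with estimated parameters (Lilliefors);
  # undefined below n = 5 or at zero variance
  if (length(x) < 5 || sd(x) == 0) return(NA_real_)
  nortest::lillie.test(x)$p.value
}

#' Pool characterization statistics
#'
#' For each phenotype variable: a KS (Lilliefors) normality p-value per
#' pool, and a two-tailed two-sample t-test for every pool pair with the
#' usual significance stars (* < 0.05, ** < 0.01, *** < 0.001). Degenerate
#' zero-variance pairs get p = 1 when the means agree and p = 0 otherwise.
#'
#' @param phenotypes Data.frame with a `pool` column and the variables.
#' @param variables Variables to test (default length and frustum volume).
#' @return List with `normality` and `tests` data.frames.
#' @export
pool_stats <- function(phenotypes,
                       variables = c("length_cm", "volume_cm3")) {
  stopifnot(all(c("pool", variables) %in% names(phenotypes)))
  pools <- sort(unique(phenotypes$pool))
  sizes <- table(phenotypes$pool)
  if (any(sizes < 3))
    stop("every pool needs at least 3 plants; smallest has ", min(sizes))
  normality <- do.call(rbind, lapply(variables, function(v) {
    data.frame(variable = v, pool = pools,
               n = as.integer(sizes[pools]),
               ks_p = vapply(pools, function(p)
                 .lillie_p(phenotypes[[v]][phenotypes$pool == p]), 1),
               stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(pools, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(variables, function(v) {
    do.call(rbind, lapply(pairs, function(pr) {
      x <- phenotypes[[v]][phenotypes$pool == pr[1]]
      y <- phenotypes[[v]][phenotypes$pool == pr[2]]
      if (sd(x) == 0 && sd(y) == 0) {
        tt <- list(statistic = 0, p.value = as.numeric(mean(x) == mean(y)))
      } else {
        tt <- t.test(x, y, alternative = "two.sided")
      }
      data.frame(variable = v, pool1 = pr[1], pool2 = pr[2],
                 t = unname(tt$statistic), p = tt$p.value,
                 stars = .p_stars(tt$p.value), stringsAsFactors = FALSE)
    }))
  }))
  rownames(normality) <- rownames(tests) <- NULL
  list(normality = normality, tests = tests)
}

#' Primer efficiency from a standard curve
#'
#' Fits quantification cycle against log10 template dilution by least
#' squares; the per-cycle amplification factor is `b = 10^(-1/slope)`
#' (perfect doubling gives slope -3.3219 and `b = 2`), reported also as
#' percentage efficiency `(b - 1) * 100`.
#'
#' @param log10_dilution Numeric vector of log10 dilution factors.
#' @param cq Matching quantification cycles.
#' @return List with `slope`, `intercept`, `amplification_base`,
#'   `percent_efficiency`.
#' @export
primer_efficiency <- function(log10_dilution, cq) {
  stopifnot(length(log10_dilution) == length(cq))
  if (length(cq) < 3) stop("need at least 3 dilution points")
  if (sd(log10_dilution) == 0) stop("dilutions must not be constant")
  fit <- lm(cq ~ log10_dilution)
  slope <- unname(coef(fit)[2])
  b <- 10^(-1 / slope)
  list(slope = slope, intercept = unname(coef(fit)[1]),
       amplification_base = b, percent_efficiency = (b - 1) * 100)
}

#' Efficiency-corrected normalized expression
#'
#' Pfaffl-style ratio: the target's efficiency-weighted fold change from the
#' calibrator sample, divided by the geometric mean of the same quantity
#' over the reference genes:
#' `NE_i = b_t^(Cq_t,cal - Cq_t,i) / geomean_r( b_r^(Cq_r,cal - Cq_r,i) )`.
#' The calibrator defaults to the sample holding the lower-median target Cq;
#' any fixed choice only rescales all values and leaves correlations
#' untouched.
#'
#' @param cq Long-format Cq table (`plant_id`, `assay`, `Cq`).
#' @param efficiencies Data.frame (`assay`, `amplification_base`); bases must
#'   lie in (1.5, 2.5).
#' @param target Target assay id.
#' @param reference_genes Reference assay ids (two expected).
#' @param calibrator Optional plant id to calibrate against.
#' @return Data.frame `plant_id`, `normalized_expression` (positive).
#' @export
qpcr_normalize <- function(cq, efficiencies, target,
                           reference_genes = c("TkEF1a", "TkRP"),
                           calibrator = NULL) {
  stopifnot(all(c("plant_id", "assay", "Cq") %in% names(cq)),
            all(c("assay", "amplification_base") %in% names(efficiencies)))
  assays <- c(target, reference_genes)
  miss <- setdiff(assays, efficiencies$assay)
  if (length(miss)) stop("efficiency missing for assay(s): ",
                         paste(miss, collapse = ", "))
  b <- setNames(efficiencies$amplification_base, efficiencies$assay)[assays]
  if (any(b <= 1.5 | b >= 2.5))
    stop("amplification bases must lie in (1.5, 2.5)")
  wide <- lapply(assays, function(a) {
    sub <- cq[cq$assay == a, c("plant_id", "Cq")]
    setNames(sub$Cq, sub$plant_id)
  })
  names(wide) <- assays
  plants <- names(wide[[target]])
  for (r in reference_genes) {
    miss <- setdiff(plants, names(wide[[r]]))
    if (length(miss))
      stop("reference assay ", r, " lacks Cq for plant(s): ",
           paste(utils::head(miss, 3), collapse = ", "))
  }
  if (is.null(calibrator)) {
    ord <- order(wide[[target]])
    calibrator <- plants[ord[floor((length(plants) + 1) / 2)]]
  }
  if (!calibrator %in% plants) stop("calibrator not among measured plants")
  ratio_t <- b[target]^(wide[[target]][calibrator] - wide[[target]][plants])
  ref_log <- rowMeans(vapply(reference_genes, function(r)
    (wide[[r]][calibrator] - wide[[r]][plants]) * log(b[r]),
    numeric(length(plants))))
  ne <- unname(ratio_t / exp(ref_log))
  data.frame(plant_id = plants, normalized_expression = ne,
             stringsAsFactors = FALSE)
}

.grubbs_critical <- function(n, alpha) {
  t <- qt(1 - alpha / (2 * n), n - 2)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Iterative Grubbs outlier removal
#'
#' Repeatedly tests the most extreme point (`G = max|x - mean| / sd`)
#' against the Grubbs critical value from the t distribution and removes it
#' while `G > G_crit`, stopping at n = 3. Zero-variance input returns
#' unchanged. Never removes more than `n - 3` points.
#'
#' @param values Numeric vector (n >= 3).
#' @param alpha Significance level (default 0.05, two-sided).
#' @return List with `values` (retained), `removed` (values), and `indices`
#'   (positions in the original vector that were removed).
#' @export
grubbs_remove <- function(values, alpha = 0.05) {
  if (length(values) < 3) stop("Grubbs's test needs at least 3 values")
  keep <- seq_along(values)
  removed <- integer()
  repeat {
    x <- values[keep]
    n <- length(x)
    if (n <= 3) break
    s <- sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    g <- max(dev) / s
    if (g <= .grubbs_critical(n, alpha)) break
    drop_i <- keep[which.max(dev)]
    removed <- c(removed, drop_i)
    keep <- setdiff(keep, drop_i)
  }
  list(values = values[keep], removed = values[removed], indices = removed)
}

#' Correlate expression with a phenotype
#'
#' The validation pipeline for one gene: KS (Lilliefors) normality of each
#' variable (reported, never gating), iterative Grubbs outlier removal per
#' variable (a plant removed in either variable drops the pair), then a
#' least-squares line and Pearson's correlation coefficient.
#'
#' @param x Phenotype values (e.g. root volume).
#' @param y Normalized expression values, paired with `x`.
#' @param alpha Grubbs significance level (default 0.05).
#' @return List of class `correlation_report`: `n_before`, `n_after`,
#'   `ks_p_x`, `ks_p_y`, `outliers_removed`, `slope`, `intercept`, `r`,
#'   `r_squared`.
#' @export
correlate <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n_before <- length(x)
  if (n_before < 3) stop("need at least 3 complete pairs")
  ks_x <- .lillie_p(x)
  ks_y <- .lillie_p(y)
  gx <- grubbs_remove(x, alpha)
  gy <- grubbs_remove(y, alpha)
  drop <- union(gx$indices, gy$indices)
  keep <- setdiff(seq_len(n_before), drop)
  if (length(keep) < 3) stop("fewer than 3 pairs remain after outlier removal")
  x <- x[keep]; y <- y[keep]
  fit <- lm(y ~ x)
  r <- cor(x, y)
  structure(list(n_before = n_before, n_after = length(keep),
                 ks_p_x = ks_x, ks_p_y = ks_y,
                 outliers_removed = length(drop),
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = r, r_squared = r^2),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Correlation report (n = %d of %d after outlier removal)\n",
              x$n_after, x$n_before))
  cat(sprintf("  KS normality p: x = %s, y = %s\n",
              format(x$ks_p_x, digits = 3), format(x$ks_p_y, digits = 3)))
  cat(sprintf("  regression: y = %.4g + %.4g x\n", x$intercept, x$slope))
  cat(sprintf("  Pearson R = %.4f, R^2 = %.4f\n", x$r, x$r_squared))
  invisible(x)
}
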