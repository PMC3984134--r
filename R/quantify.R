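# Normalization of mapped read counts to percentages, detection-limit
# estimation from pure samples, and the validation statistics: Goodman-Kruskal
# gamma rank correlation with a permutation test, bootstrap confidence
# intervals, and residual over/under-estimation summaries.

#' Normalize mapped counts and aggregate to type level
#'
#' Reference-level counts are expressed as a percentage of the sample's total
#' mapped reads (controlling for variable read depth); type-level percentages
#' are the sums over each type's member references. Samples with zero mapped
#' reads are flagged and their percentages set to NA.
#'
#' @param counts samples x references count matrix, or long data.frame
#'   (`sample_id`, `reference_id`, `count`).
#' @param annotations annotation table mapping `reference_id` to `type_name`.
#' @return object of class `abundance_table`: list with `counts`,
#'   `ref_percent`, `type_percent` (matrices), `annotations`,
#'   `zero_samples`.
#' @export
normalize_and_aggregate <- function(counts, annotations) {
  cm <- as_count_matrix(counts)
  if (any(cm < 0)) stop("counts must be non-negative", call. = FALSE)
  missing <- setdiff(colnames(cm), annotations$reference_id)
  if (length(missing) > 0L) {
    stop("annotations missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  totals <- rowSums(cm)
  zero <- totals == 0
  if (any(zero)) {
    warning("samples with zero mapped reads: ",
            paste(rownames(cm)[zero], collapse = ", "), call. = FALSE)
  }
  ref_percent <- 100 * sweep(cm, 1L, ifelse(zero, NA_real_, totals), "/")
  types <- annotations$type_name[match(colnames(cm), annotations$reference_id)]
  utypes <- sort(unique(types[!is.na(types)]))
  type_percent <- sapply(utypes, function(ty) {
    cols <- which(!is.na(types) & types == ty)
    rowSums(ref_percent[, cols, drop = FALSE])
  })
  if (is.null(dim(type_percent))) {
    type_percent <- matrix(type_percent, nrow = nrow(cm),
                           dimnames = list(rownames(cm), utypes))
  }
  structure(
    list(counts = cm, ref_percent = ref_percent, type_percent = type_percent,
         annotations = annotations, zero_samples = rownames(cm)[zero]),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d references (%d types)\n",
              nrow(x$counts), ncol(x$counts), ncol(x$type_percent)))
  invisible(x)
}

#' Detection-limit cutoff formula
#'
#' The conservative cutoff is the mean false-positive percentage plus two
#' standard errors.
#'
#' @param mean_fp mean false-positive abundance (percent).
#' @param se_fp its standard error (percent).
#' @return cutoff in percent.
#' @export
detection_cutoff <- function(mean_fp, se_fp) {
  stopifnot_scalar_number(mean_fp, "mean_fp", min = 0)
  stopifnot_scalar_number(se_fp, "se_fp", min = 0)
  mean_fp + 2 * se_fp
}

#' Estimate the detection limit from designed-absent types
#'
#' False-positive observations are the observed percentages of types whose
#' design fraction in a sample is zero (in pure samples: all non-dominant
#' types). Outliers (e.g. a biologically contaminated cell stock) are flagged
#' iteratively: the largest value is excluded while it exceeds
#' `mean + outlier_k * sd` of the *remaining* values (leave-one-out, so a
#' gross outlier cannot mask itself by inflating the spread). Mean, standard
#' error (sd/sqrt(n)) and the cutoff `mean + 2*SE` are then computed from the
#' retained values.
#'
#' @param abundance an `abundance_table`.
#' @param designs mixture designs (list or long table).
#' @param outlier_k outlier multiplier (default 5).
#' @return object of class `detection_limit`: list with `fp_values`,
#'   `outliers`, `mean_fp`, `se_fp`, `cutoff` (all in percent).
#' @export
estimate_detection_limit <- function(abundance, designs, outlier_k = 5) {
  dt <- as_design_table(designs)
  tp <- abundance$type_percent
  fp <- numeric(0)
  fp_label <- character(0)
  for (i in seq_len(nrow(dt))) {
    sid <- dt$sample_id[i]
    ty <- dt$type_name[i]
    if (dt$cell_fraction[i] == 0 && sid %in% rownames(tp) &&
        ty %in% colnames(tp) && !is.na(tp[sid, ty])) {
      fp <- c(fp, tp[sid, ty])
      fp_label <- c(fp_label, paste0(sid, ":", ty))
    }
  }
  if (length(fp) == 0L) {
    stop("no designed-absent type observations; cannot estimate detection limit",
         call. = FALSE)
  }
  names(fp) <- fp_label
  used <- fp
  outliers <- fp[0]
  while (length(used) >= 3L) {
    mx <- which.max(used)
    rest <- used[-mx]
    s <- sd(rest)
    if (is.na(s)) s <- 0
    if (used[mx] > mean(rest) + outlier_k * s) {
      outliers <- c(outliers, used[mx])
      used <- rest
    } else break
  }
  mean_fp <- mean(used)
  se_fp <- if (length(used) > 1L) sd(used) / sqrt(length(used)) else 0
  structure(
    list(fp_values = used, outliers = outliers, mean_fp = mean_fp,
         se_fp = se_fp, cutoff = detection_cutoff(mean_fp, se_fp)),
    class = "detection_limit"
  )
}

#' @export
print.detection_limit <- function(x, ...) {
  cat(sprintf(
    "<detection_limit> mean FP %.4f%% (SE %.4f%%), cutoff %.4f%%; %d values, %d outlier(s)\n",
    x$mean_fp, x$se_fp, x$cutoff, length(x$fp_values), length(x$outliers)))
  invisible(x)
}

#' Goodman-Kruskal gamma rank correlation
#'
#' Over all index pairs i < j, a pair is concordant when the differences in x
#' and y have the same sign, discordant when opposite; gamma = (Nc - Nd) /
#' (Nc + Nd). A robust tolerance `tolerance_r` treats pairs whose absolute
#' difference in either variable is <= r as ties (excluded), following
#' robust gamma rank correlation practice.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @param tolerance_r tie tolerance (default 0 = classical gamma).
#' @return object of class `gamma_result`: list with `gamma`,
#'   `n_concordant`, `n_discordant`, `tolerance_r`. `gamma` is NA with an
#'   `undefined` flag when no pair is informative.
#' @export
gamma_correlation <- function(x, y, tolerance_r = 0) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  dx <- outer(x, x, "-")
  dy <- outer(y, y, "-")
  up <- upper.tri(dx)
  dx <- -dx[up]  # x_j - x_i for i < j; sign is all that matters
  dy <- -dy[up]
  informative <- abs(dx) > tolerance_r & abs(dy) > tolerance_r
  nc <- sum(informative & sign(dx) == sign(dy))
  nd <- sum(informative & sign(dx) != sign(dy))
  g <- if (nc + nd == 0L) NA_real_ else (nc - nd) / (nc + nd)
  structure(
    list(gamma = g, n_concordant = nc, n_discordant = nd,
         tolerance_r = tolerance_r, undefined = nc + nd == 0L),
    class = "gamma_result"
  )
}

#' @export
print.gamma_result <- function(x, ...) {
  if (x$undefined) {
    cat("<gamma_result> undefined (no informative pairs)\n")
  } else {
    cat(sprintf("<gamma_result> gamma = %.4f (Nc = %d, Nd = %d)%s\n",
                x$gamma, x$n_concordant, x$n_discordant,
                if (!is.null(x$p_value)) sprintf(", p = %.4g", x$p_value) else ""))
  }
  invisible(x)
}

#' Permutation p-value for gamma
#'
#' One-sided test of positive association: y is permuted `n_iter` times and
#' p = (1 + number of permuted gammas at or above the observed) /
#' (n_iter + 1). The pseudocount keeps p strictly positive.
#'
#' @param x,y numeric vectors.
#' @param tolerance_r tie tolerance passed to [gamma_correlation()].
#' @param n_iter number of permutations (default 1000).
#' @param seed RNG seed.
#' @return a `gamma_result` with `p_value` and `n_permutations` filled in.
#' @export
gamma_permutation_p <- function(x, y, tolerance_r = 0, n_iter = 1000, seed = 1) {
  obs <- gamma_correlation(x, y, tolerance_r)
  if (obs$undefined) {
    stop("gamma is undefined (no informative pairs); cannot test", call. = FALSE)
  }
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_iter), function(i) {
      g <- gamma_correlation(x, sample(y), tolerance_r)
      !g$undefined && g$gamma >= obs$gamma
    }, logical(1)))
  })
  obs$p_value <- (1 + exceed) / (n_iter + 1)
  obs$n_permutations <- n_iter
  obs
}

#' Non-parametric bootstrap confidence interval for a mean
#'
#' Percentile 95% interval of the resampled mean.
#'
#' @param values numeric vector (length >= 1).
#' @param n_resamples bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return object of class `bootstrap_ci`: list with `mean`, `lower`,
#'   `upper`, `n_resamples`, `seed`.
#' @export
bootstrap_ci <- function(values, n_resamples = 1000, seed = 1) {
  stopifnot(length(values) >= 1L)
  means <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      mean(sample(values, replace = TRUE))
    }, numeric(1))
  })
  q <- unname(quantile(means, c(0.025, 0.975)))
  structure(
    list(mean = mean(values), lower = q[1], upper = q[2],
         n_resamples = n_resamples, seed = seed),
    class = "bootstrap_ci"
  )
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("<bootstrap_ci> mean %.4f [%.4f, %.4f] (%d resamples)\n",
              x$mean, x$lower, x$upper, x$n_resamples))
  invisible(x)
}

#' Residual over/under-estimation summary
#'
#' Fits observed ~ expected by least squares and counts positive (over-
#' estimated) and negative (under-estimated) residuals at each expected
#' abundance level.
#'
#' @param observed,expected paired numeric vectors (length >= 3).
#' @return list with `residuals`, `fit` coefficients, and `by_level`
#'   (data.frame `expected`, `n_over`, `n_under`).
#' @export
residual_bias <- function(observed, expected) {
  stopifnot(length(observed) == length(expected), length(observed) >= 3L)
  if (length(unique(expected)) < 2L) {
    stop("expected values are degenerate (all equal)", call. = FALSE)
  }
  fit <- lm(observed ~ expected)
  res <- unname(residuals(fit))
  levels <- sort(unique(expected))
  by_level <- data.frame(
    expected = levels,
    n_over = vapply(levels, function(l) sum(res[expected == l] > 1e-12), integer(1)),
    n_under = vapply(levels, function(l) sum(res[expected == l] < -1e-12), integer(1))
  )
  list(residuals = res, fit = coef(fit), by_level = by_level)
}

#' @importFrom stats coef
NULL
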