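#' Threshold a probability map into a voxel mask
#'
#' Selects voxels whose probability is strictly greater than the threshold
#' (so a boundary voxel at exactly 0.5 is excluded under the default).
#'
#' @param probability_map numeric array with values in [0, 1].
#' @param threshold scalar in [0, 1], default 0.5.
#' @param strict use strict `>` (default). Set FALSE for `>=`.
#' @return logical array of the same shape.
#' @export
threshold_mask <- function(probability_map, threshold = 0.5, strict = TRUE) {
  if (!is.finite(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  if (strict) probability_map > threshold else probability_map >= threshold
}

#' Mean and standard deviation across subjects
#'
#' Group summaries use the population SD convention (divisor n) by default:
#' reported cohort SDs for regional flow and T1 are reproduced by divisor-n
#' recomputation from the per-subject rows. The divisor is switchable.
#'
#' @param values numeric vector of per-subject values, length >= 2.
#' @param sd_divisor `"n"` (population, default) or `"n-1"` (sample).
#' @return named numeric vector `c(mean =, sd =)`.
#' @export
summarize_subjects <- function(values, sd_divisor = c("n", "n-1")) {
  sd_divisor <- match.arg(sd_divisor)
  values <- as.numeric(values)
  if (length(values) < 2 || !all(is.finite(values))) {
    stop("need at least 2 finite values", call. = FALSE)
  }
  m <- mean(values)
  s <- if (sd_divisor == "n") {
    sqrt(mean((values - m)^2))
  } else {
    stats::sd(values)
  }
  c(mean = m, sd = s)
}

#' Exact paired Wilcoxon signed-rank test by full enumeration
#'
#' Computes the exact two-sided p-value of the paired Wilcoxon signed-rank
#' test by enumerating all 2^n sign assignments of the ranked absolute
#' differences (ties receive average ranks; zero differences are dropped
#' before ranking, the classic treatment). The two-sided p is
#' `min(1, 2 * min(P(W <= W_obs), P(W >= W_obs)))` under the enumeration
#' null. Exactness makes the test valid at very small n where the normal
#' approximation is not.
#'
#' @param x,y paired numeric vectors of equal length; at most 20 non-zero
#'   differences (the enumeration is 2^n).
#' @return list with `p` (two-sided p-value in (0, 1]), `statistic` (W, sum
#'   of ranks of positive differences), `n` (pairs used after dropping zero
#'   differences), and `degenerate` (TRUE when all differences are zero, in
#'   which case p = 1).
#' @examples
#' wilcoxon_exact_paired(c(2.45, 2.85, 1.94), c(1.93, 1.83, 1.83))
#' @export
wilcoxon_exact_paired <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  d <- as.numeric(x) - as.numeric(y)
  if (!all(is.finite(d))) stop("differences must be finite", call. = FALSE)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(p = 1.0, statistic = NA_real_, n = 0L, degenerate = TRUE))
  }
  if (n > 20L) stop("exact enumeration supported for at most 20 non-zero differences",
                    call. = FALSE)
  r <- rank(abs(d))  # average ranks for ties
  w_obs <- sum(r[d > 0])
  # all 2^n sign assignments by recursive doubling: element k of `sums` is
  # the W statistic of one assignment
  sums <- 0
  for (ri in r) sums <- c(sums, sums + ri)
  eps <- sqrt(.Machine$double.eps)
  p_le <- mean(sums <= w_obs + eps)
  p_ge <- mean(sums >= w_obs - eps)
  list(p = min(1, 2 * min(p_le, p_ge)), statistic = w_obs, n = n,
       degenerate = FALSE)
}

#' Per-subject regional perfusion summary
#'
#' Bundles the fitted gray-matter and choroid plexus parameters of one
#' subject with the choroid plexus volume and total flow, in group-table
#' layout.
#'
#' @param subject_id identifier.
#' @param gm_fit,cp_fit `asl_fit` objects (see [fit_series()]) for the
#'   gray-matter and choroid plexus regions.
#' @param cp_n_voxels choroid plexus mask voxel count.
#' @param constants an [acquisition_constants()] (supplies `rho` and
#'   `voxel_volume` for the volume and total-flow conversions).
#' @return one-row data.frame with columns `subject`, `gm_f`, `gm_att`,
#'   `gm_t1`, `gm_r2`, `cp_f`, `cp_att`, `cp_t1`, `cp_r2`, `cp_volume_ml`,
#'   `cp_total_flow`.
#' @export
subject_summary <- function(subject_id, gm_fit, cp_fit, cp_n_voxels,
                            constants = acquisition_constants()) {
  data.frame(
    subject = subject_id,
    gm_f = gm_fit$params$f, gm_att = gm_fit$params$delta,
    gm_t1 = gm_fit$params$T1, gm_r2 = gm_fit$r2,
    cp_f = cp_fit$params$f, cp_att = cp_fit$params$delta,
    cp_t1 = cp_fit$params$T1, cp_r2 = cp_fit$r2,
    cp_volume_ml = cp_n_voxels * constants$voxel_volume,
    cp_total_flow = total_flow(cp_fit$params$f, cp_n_voxels, constants))
}

#' Group report: per-subject rows, mean/SD, and paired tests
#'
#' Builds the group table from per-subject summaries: a Mean and an SD row
#' over the six regional measures (gray matter and choroid plexus flow,
#' transit time, T1), plus exact paired Wilcoxon signed-rank p-values
#' comparing the two regions on each measure, flagged at the given
#' significance level.
#'
#' @param summaries data.frame with one row per subject and columns `gm_f`,
#'   `gm_att`, `gm_t1`, `cp_f`, `cp_att`, `cp_t1` (e.g. rbind of
#'   [subject_summary()] rows, or a table of published values); >= 2 rows.
#' @param alpha significance level for the report flags (default 0.02).
#' @param sd_divisor passed to [summarize_subjects()].
#' @return An object of class `group_table`: list with `rows` (the input),
#'   `mean_row`, `sd_row` (named vectors over the six measures), `p_values`
#'   (named: flow, att, t1), `significant` (logical flags), `alpha`.
#' @export
group_report <- function(summaries, alpha = 0.02, sd_divisor = "n") {
  measures <- c("gm_f", "gm_att", "gm_t1", "cp_f", "cp_att", "cp_t1")
  if (!all(measures %in% names(summaries))) {
    stop("summaries must contain columns ", paste(measures, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(summaries) < 2) stop("need at least 2 subjects", call. = FALSE)
  stats_m <- vapply(measures,
                    function(m) summarize_subjects(summaries[[m]], sd_divisor),
                    numeric(2))
  p_values <- c(
    flow = wilcoxon_exact_paired(summaries$gm_f, summaries$cp_f)$p,
    att = wilcoxon_exact_paired(summaries$gm_att, summaries$cp_att)$p,
    t1 = wilcoxon_exact_paired(summaries$gm_t1, summaries$cp_t1)$p)
  structure(list(rows = summaries,
                 mean_row = stats_m["mean", ],
                 sd_row = stats_m["sd", ],
                 p_values = p_values,
                 significant = p_values < alpha,
                 alpha = alpha),
            class = "group_table")
}

#' @export
print.group_table <- function(x, ...) {
  cat(sprintf("Group perfusion table (%d subjects)\n", nrow(x$rows)))
  tab <- rbind(Mean = x$mean_row, SD = x$sd_row)
  print(round(tab, 3))
  cat("Paired Wilcoxon (gray matter vs choroid plexus), exact two-sided p:\n")
  for (nm in names(x$p_values)) {
    cat(sprintf("  %-5s p = %.6f%s\n", nm, x$p_values[[nm]],
                ifelse(x$significant[[nm]],
                       sprintf(" (significant at %.2g)", x$alpha), "")))
  }
  invisible(x)
}

#' Write a group table to CSV
#'
#' Per-subject rows followed by Mean and SD footer rows; p-values appended
#' as additional footer rows. All numerics are finite; missing fits appear
#' as empty fields.
#'
#' @param x a `group_table` from [group_report()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_group_report <- function(x, path) {
  rows <- x$rows
  num_cols <- names(rows)[vapply(rows, is.numeric, logical(1))]
  out <- rows
  out$subject <- as.character(out$subject)
  footer <- function(label, vals) {
    r <- out[1, , drop = FALSE]
    r[1, ] <- NA
    r$subject <- label
    for (nm in names(vals)) if (nm %in% num_cols) r[[nm]] <- vals[[nm]]
    r
  }
  out <- rbind(out,
               footer("mean", x$mean_row),
               footer("sd", x$sd_row),
               footer("p_value", c(gm_f = NA, cp_f = x$p_values[["flow"]],
                                   gm_att = NA, cp_att = x$p_values[["att"]],
                                   gm_t1 = NA, cp_t1 = x$p_values[["t1"]])))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Published reference cohort of regional perfusion values
#'
#' Per-subject gray-matter and choroid plexus apparent blood flow
#' (ml/100 g/min), arterial transit time (s) and tissue T1 (s) for seven
#' healthy adults, as printed in a published multi-delay ASL study of
#' choroid plexus perfusion. Used as the reference input for group-level
#' arithmetic checks.
#'
#' @return data.frame with columns `subject`, `gm_f`, `gm_att`, `gm_t1`,
#'   `cp_f`, `cp_att`, `cp_t1`.
#' @export
reference_cohort <- function() {
  path <- system.file("extdata", "reference_subjects.csv", package = "cpasl",
                      mustWork = TRUE)
  utils::read.csv(path)
}
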