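#' Vehicle-referenced z-score normalization of a screening plate
#'
#' Each treated replicate readout `X_s` is normalized against the vehicle
#' wells of its vehicle class on the same plate:
#' `z = (X_s - mean(X_v)) / SD(X_v)`, with `mean(X_v)` and `SD(X_v)` the
#' mean and sample (n-1) standard deviation of the vehicle replicates.
#' Platinum-based conditions are referenced to the H2O vehicle and all
#' others to DMSO, as encoded in the wells' `vehicle_class`. Vehicle wells
#' themselves are standardized against their own statistics (mean 0, sample
#' SD 1). The z-scores are invariant under affine rescaling of the whole
#' plate's readouts.
#'
#' @param plate A [plate_data()].
#' @return A data.frame of class `drug_response` with one row per
#'   condition: `sample_id`, `condition`, `vehicle_class`, `is_vehicle`,
#'   `n_replicates`, `mean_z`, and list-columns `z` (per-replicate
#'   z-scores) and `readouts`.
#' @export
normalize_plate <- function(plate) {
  stopifnot(inherits(plate, "plate_data"))
  wells <- plate$wells
  is_vehicle <- wells$condition == wells$vehicle_class
  veh_stats <- lapply(split(wells$readout[is_vehicle],
                            wells$vehicle_class[is_vehicle]),
                      function(x) {
    if (length(x) < 2)
      stop("sample ", plate$sample_id,
           ": need >= 2 vehicle replicates for an SD")
    s <- stats::sd(x)
    if (s == 0)
      stop("sample ", plate$sample_id,
           ": vehicle SD is zero; z-scores undefined")
    list(mean = mean(x), sd = s)
  })
  conditions <- unique(wells$condition)
  rows <- lapply(conditions, function(cond) {
    w <- wells[wells$condition == cond, , drop = FALSE]
    vc <- w$vehicle_class[1]
    vs <- veh_stats[[vc]]
    if (is.null(vs))
      stop("sample ", plate$sample_id, ": no ", vc,
           " vehicle wells for condition ", cond)
    z <- (w$readout - vs$mean) / vs$sd
    data.frame(sample_id = plate$sample_id, condition = cond,
               vehicle_class = vc, is_vehicle = cond == vc,
               n_replicates = nrow(w), mean_z = mean(z),
               z = I(list(z)), readouts = I(list(w$readout)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("drug_response", "data.frame")
  out
}

#' Growth inhibition from plate readouts
#'
#' Fold-change of each replicate readout with respect to the mean vehicle
#' readout of its vehicle class, and the growth inhibition
#' `1 - fold_change` (0 at the vehicle level, 1 for a complete kill).
#'
#' @param plate A [plate_data()].
#' @return Data.frame with one row per well: `condition`, `vehicle_class`,
#'   `replicate`, `readout`, `fold_change`, `inhibition`.
#' @export
growth_inhibition <- function(plate) {
  stopifnot(inherits(plate, "plate_data"))
  wells <- plate$wells
  is_vehicle <- wells$condition == wells$vehicle_class
  veh_mean <- vapply(split(wells$readout[is_vehicle],
                           wells$vehicle_class[is_vehicle]), mean, 1)
  if (any(veh_mean <= 0))
    stop("vehicle mean readout must be positive for fold-changes")
  fc <- wells$readout / veh_mean[wells$vehicle_class]
  out <- wells
  out$fold_change <- unname(fc)
  out$inhibition <- 1 - out$fold_change
  out
}

#' Call drug hits with ANOVA and Dunnett many-to-one comparison
#'
#' Within each vehicle class of a sample, fits a one-way ANOVA of the
#' replicate z-scores across all conditions (vehicle included) and computes
#' Dunnett-adjusted p-values of every drug against the vehicle reference
#' (many-to-one multivariate-t adjustment). A condition is a hit when its
#' mean z-score is at most `z_cut` and its adjusted p-value at most
#' `p_cut`; both criteria are required, so a drug with a strong p-value but
#' a mild effect size is not a hit. Conditions with a single replicate are
#' excluded from the test with a warning.
#'
#' The multivariate-t integration is stochastic; a fixed internal seed
#' makes the adjusted p-values reproducible (to ~1e-4).
#'
#' @param responses A `drug_response` from [normalize_plate()].
#' @param z_cut Mean z-score threshold (default -1.5, inclusive).
#' @param p_cut Adjusted p-value threshold (default 0.05, inclusive).
#' @return The input with columns `adj_p` and `hit` added (NA / FALSE for
#'   vehicle rows and untestable conditions).
#' @export
call_hits <- function(responses, z_cut = -1.5, p_cut = 0.05) {
  stopifnot(inherits(responses, "drug_response"))
  responses$adj_p <- NA_real_
  responses$hit <- FALSE
  for (vc in unique(responses$vehicle_class)) {
    idx <- which(responses$vehicle_class == vc)
    sub <- responses[idx, , drop = FALSE]
    singleton <- sub$n_replicates < 2
    if (any(singleton))
      warning("excluding singleton condition(s) from testing: ",
              paste(sub$condition[singleton], collapse = ", "))
    sub <- sub[!singleton, , drop = FALSE]
    if (!any(sub$is_vehicle) || nrow(sub) < 2) next
    long <- data.frame(
      z = unlist(sub$z),
      condition = rep(sub$condition, lengths(sub$z)))
    # vehicle first so Dunnett contrasts are many-to-one against it
    long$condition <- stats::relevel(factor(long$condition),
                                     ref = vc)
    fit <- stats::aov(z ~ condition, data = long)
    adj <- local({
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
      set.seed(20230418L)
      summary(multcomp::glht(fit, linfct = multcomp::mcp(condition = "Dunnett")))
    })
    pvals <- as.numeric(adj$test$pvalues)
    names(pvals) <- sub("^condition", "",
                        sub(paste0(" - ", vc, "$"), "", names(adj$test$coefficients)))
    hit_rows <- match(names(pvals), responses$condition[idx])
    responses$adj_p[idx[hit_rows]] <- pvals
    responses$hit[idx[hit_rows]] <-
      responses$mean_z[idx[hit_rows]] <= z_cut & pvals <= p_cut
  }
  responses
}

#' Compare one drug's response between two samples
#'
#' Exact two-sided rank-sum test between the replicate z-scores of the same
#' drug in two samples (e.g. baseline vs relapse organoids). With 4
#' replicates per side, complete separation gives p = 0.0286 and a single
#' rank crossing p = 0.0571.
#'
#' @param z_a,z_b Replicate z-score vectors (each length >= 2).
#' @return Two-sided p-value.
#' @export
compare_samples_for_drug <- function(z_a, z_b) {
  if (length(z_a) < 2 || length(z_b) < 2)
    stop("need >= 2 replicates per sample")
  rank_sum_test(z_a, z_b)
}

#' Inter-drug response correlation across samples
#'
#' Pearson correlation (with two-sided p) between the per-sample mean
#' z-scores of every drug pair, using pairwise-complete samples. Pairs with
#' fewer than 3 complete observations are masked (NA).
#'
#' @param mean_z Numeric matrix, samples x drugs (NA for unscreened cells).
#' @return List of matrices `r` and `p` (drugs x drugs, unit diagonal).
#' @export
interdrug_correlation <- function(mean_z) {
  stopifnot(is.matrix(mean_z))
  drugs <- colnames(mean_z) %||% paste0("drug", seq_len(ncol(mean_z)))
  nd <- ncol(mean_z)
  r <- matrix(NA_real_, nd, nd, dimnames = list(drugs, drugs))
  p <- r
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(nd - 1)) for (j in (i + 1):nd) {
    ok <- stats::complete.cases(mean_z[, c(i, j)])
    if (sum(ok) < 3) next
    ct <- stats::cor.test(mean_z[ok, i], mean_z[ok, j], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- unname(ct$p.value)
  }
  list(r = r, p = p)
}

#' Organoid-forming efficiency comparison
#'
#' Two-sided Fisher exact test on the 2x2 table of formation successes and
#' failures in two groups (e.g. NMIBC 21/24 vs MIBC 19/25 gives
#' p = 0.4635), plus the per-group formation rates.
#'
#' @param successes_a,total_a,successes_b,total_b Non-negative counts with
#'   `successes <= total`.
#' @return List with `p`, `rate_a`, `rate_b`.
#' @export
formation_rate_test <- function(successes_a, total_a, successes_b, total_b) {
  counts <- c(successes_a, total_a, successes_b, total_b)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (successes_a > total_a || successes_b > total_b)
    stop("successes cannot exceed totals")
  tab <- matrix(c(successes_a, total_a - successes_a,
                  successes_b, total_b - successes_b), nrow = 2, byrow = TRUE)
  list(p = stats::fisher.test(tab, alternative = "two.sided")$p.value,
       rate_a = successes_a / total_a, rate_b = successes_b / total_b)
}
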