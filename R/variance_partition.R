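# Variance partitioning: per-level percentage of total variation with the
# multiple-membership average-contribution adjustment, explained variance
# from covariates, and the deviance information criterion.

#' Average contribution of a multiple-membership level to the total variance
#'
#' For a multiple-membership classification, a child in groups j with
#' weights w_ij contributes variance sigma2 * sum_j w_ij^2.  The level's
#' average contribution is sigma2 times the mean of sum_j w_ij^2 over the
#' roster, children with no memberships contributing zero.
#'
#' @param sigma2 The level's random-effect variance (non-negative).
#' @param weights A [build_weight_matrix()] object.
#' @param children Character vector of roster child IDs to average over.
#' @return The adjusted variance contribution (same units as `sigma2`).
#' @export
mm_average_contribution <- function(sigma2, weights, children) {
  stopifnot(inherits(weights, "membership_weights"), is.finite(sigma2), sigma2 >= 0)
  children <- as.character(children)
  if (length(children) == 0L) stop("children roster must be non-empty")
  sw2 <- stats::setNames(numeric(length(children)), children)
  if (nrow(weights$weights)) {
    agg <- tapply(weights$weights$weight^2, weights$weights$child_id, sum)
    hit <- intersect(names(agg), children)
    sw2[hit] <- agg[hit]
  }
  sigma2 * mean(sw2)
}

# per-draw variance components for one column (gender or pooled)
.vpc_components <- function(chains, who = c("all", "boy", "girl")) {
  who <- match.arg(who)
  comps <- list()
  for (cl in chains$classes) {
    adj <- if (cl$multiple) cl$abar[[who]] else 1
    v <- if (cl$slopes == "by_gender") {
      if (who == "boy") cl$draws[, "var_boy"] else cl$draws[, "var_girl"]
    } else cl$draws[, "sigma2"]
    comps[[cl$label]] <- v * adj
  }
  comps$individual <- if (ncol(chains$residual) == 2L) {
    chains$residual[, who]
  } else chains$residual[, 1L]
  comps
}

#' Variance partition table
#'
#' Converts posterior chains into the reporting quantities: total variation
#' and the percentage of it at each level (neighbourhood, school, triad,
#' dyad, individual), per gender when the model has gender random slopes.
#' Multiple-membership levels are adjusted by their average contribution
#' ([mm_average_contribution()]); shares are computed per posterior draw and
#' summarised by the posterior mean (`"mean_of_ratios"`, default) or as the
#' ratio of posterior means (`"ratio_of_means"`).
#'
#' @param chains An [fit_mmmc()] result.
#' @param summary `"mean_of_ratios"` or `"ratio_of_means"`.
#' @param explained Optional named vector of explained-variance percentages
#'   per column (from [explained_variance()]); residual shares are then
#'   scaled so the column still sums to 100.
#' @param dic Optional [mmmc_dic()] result to display with the table.
#' @param rounding Digits for the printed percentages (default 0, table
#'   style); raw values are retained in the object.
#' @return An object of class `vpc_table`: `total` (posterior-mean total
#'   variation per column, outcome-squared units), `shares` (levels x
#'   columns, percent), optional `explained`, `dic`.
#' @export
vpc_table <- function(chains, summary = c("mean_of_ratios", "ratio_of_means"),
                      explained = NULL, dic = NULL, rounding = 0) {
  stopifnot(inherits(chains, "mmmc_chains"))
  summary <- match.arg(summary)
  by_gender <- ncol(chains$residual) == 2L ||
    any(vapply(chains$classes, function(cl) cl$slopes == "by_gender", TRUE))
  cols <- if (by_gender) c("boy", "girl") else "all"
  levels <- c(names(chains$classes), "individual")

  shares <- matrix(NA_real_, length(levels), length(cols),
                   dimnames = list(levels, cols))
  total <- stats::setNames(numeric(length(cols)), cols)
  for (g in cols) {
    comps <- .vpc_components(chains, g)
    cm <- do.call(cbind, comps)           # draws x levels
    tot <- rowSums(cm)
    total[g] <- mean(tot)
    shares[, g] <- if (summary == "mean_of_ratios") {
      colMeans(cm / tot) * 100
    } else colMeans(cm) / mean(tot) * 100
  }
  if (!is.null(explained)) {
    explained <- explained[cols]
    for (g in cols) shares[, g] <- shares[, g] * (100 - explained[g]) / 100
  }
  structure(list(total = total, shares = shares, explained = explained,
                 dic = dic, summary = summary, rounding = rounding),
            class = "vpc_table")
}

#' @export
print.vpc_table <- function(x, ...) {
  r <- x$rounding
  hdr <- colnames(x$shares)
  cat("Percentage of variation\n")
  cat(sprintf("%-18s %s\n", "", paste(sprintf("%8s", hdr), collapse = " ")))
  cat(sprintf("%-18s %s\n", "Total variation",
              paste(sprintf("%8.1f", x$total), collapse = " ")))
  if (!is.null(x$explained))
    cat(sprintf("%-18s %s\n", "Explained",
                paste(sprintf("%7.*f%%", r, x$explained), collapse = " ")))
  lab <- c(neighbourhood = "Neighbourhood", school = "School",
           triad = "Triads", dyad = "Dyads", individual = "Individual")
  for (lv in rownames(x$shares)) {
    nm <- if (lv %in% names(lab)) lab[[lv]] else lv
    cat(sprintf("%-18s %s\n", nm,
                paste(sprintf("%7.*f%%", r, x$shares[lv, ]), collapse = " ")))
  }
  if (!is.null(x$dic))
    cat(sprintf("%-18s %8.1f\n", "DIC", x$dic$dic))
  invisible(x)
}

#' @export
as.data.frame.vpc_table <- function(x, ...) {
  df <- as.data.frame(x$shares)
  df <- cbind(level = rownames(x$shares), df)
  rownames(df) <- NULL
  df
}

#' Percentage of total variation explained by covariates
#'
#' The default (`"linear_predictor"`) definition: the variance across
#' children (within gender) of the covariate linear predictor x_i' beta-hat
#' -- excluding the intercept and the gender contrast -- divided by the
#' baseline total variation (the gender-specific total from the model
#' without those covariates, which is held fixed in reporting).  The
#' alternative `"residual_reduction"` definition is the relative drop in
#' the model-implied total variation.
#'
#' @param chains Chains from the covariate (full) model.
#' @param assembled The matching [assemble_mmmc()] object.
#' @param baseline_total Named vector `c(boy = , girl = )` (or `c(all = )`)
#'   of baseline total variation, e.g. `vpc_table(chains2)$total`.
#' @param method `"linear_predictor"` (default) or `"residual_reduction"`.
#' @return Named vector of explained percentages per column.
#' @export
explained_variance <- function(chains, assembled, baseline_total,
                               method = c("linear_predictor", "residual_reduction")) {
  method <- match.arg(method)
  if (any(!is.finite(baseline_total)) || any(baseline_total <= 0))
    stop("baseline_total must be positive")
  cols <- names(baseline_total)
  out <- stats::setNames(numeric(length(cols)), cols)
  if (method == "linear_predictor") {
    betahat <- colMeans(chains$beta)
    drop_cols <- colnames(assembled$X) %in% c("(Intercept)", "gender_girl")
    lp <- as.numeric(assembled$X[, !drop_cols, drop = FALSE] %*%
                       betahat[!drop_cols])
    for (g in cols) {
      idx <- if (g == "all") seq_len(assembled$n)
             else which(assembled$gender_idx == match(g, .gender_levels))
      out[g] <- stats::var(lp[idx]) / baseline_total[g] * 100
    }
  } else {
    vt <- vpc_table(chains)
    for (g in cols)
      out[g] <- (baseline_total[g] - vt$total[g]) / baseline_total[g] * 100
  }
  out
}

#' Deviance information criterion
#'
#' DIC = Dbar + pD with Dbar the posterior mean of the conditional deviance
#' and pD = Dbar - D(theta-bar), where theta-bar plugs in the posterior
#' means of the fixed effects, random effects and residual variances.
#' Lower DIC indicates better fit.
#'
#' @param chains An [fit_mmmc()] result.
#' @param assembled The matching [assemble_mmmc()] object.
#' @return List with `dic`, `pD`, `Dbar` and `Dhat`.
#' @export
mmmc_dic <- function(chains, assembled) {
  stopifnot(inherits(chains, "mmmc_chains"), inherits(assembled, "mmmc_assembled"))
  Dbar <- mean(chains$deviance)
  betabar <- colMeans(chains$beta)
  ubar <- lapply(chains$classes, function(cl) cl$u_mean)
  s2bar <- colMeans(chains$residual)
  if (length(s2bar) == 2L) names(s2bar) <- .gender_levels
  Dhat <- mmmc_deviance(assembled, betabar, ubar, s2bar)
  pD <- Dbar - Dhat
  list(dic = Dbar + pD, pD = pD, Dbar = Dbar, Dhat = Dhat)
}
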