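# Multiple-membership multiple-classification (MMMC) Gaussian multilevel
# models: specification, assembly into sparse design structures, and a Gibbs
# sampler with gender random slopes and gender-specific residual variances.

#' Specify an MMMC model
#'
#' Describes the fixed effects, the classification structure (any mix of
#' nested, cross-classified and multiple-membership levels) and whether
#' random effects and residuals are gender specific.
#'
#' @param fixed Character vector of fixed-effect covariate names (an
#'   intercept is always included).  Use `"gender"` for the gender contrast.
#'   `NULL` gives an intercept-only model.
#' @param classifications Named list, in reporting order.  Each element is
#'   either the name of a grouping column in the data (single membership,
#'   e.g. `"school_id"`) or the string `"weights"`, meaning a
#'   [build_weight_matrix()] object supplied to [assemble_mmmc()] under the
#'   same label (multiple membership).
#' @param slopes `"pooled"` (one variance per classification) or
#'   `"by_gender"` (a 2x2 covariance of boy/girl effects per
#'   classification).  `"by_gender"` requires `"gender"` in `fixed`.
#' @param residual `"pooled"` or `"by_gender"` residual (individual-level)
#'   variance.
#' @return An object of class `mmmc_spec`.
#' @seealso [model1_spec()], [model2_spec()], [model3_spec()]
#' @export
mmmc_spec <- function(fixed = NULL,
                      classifications = list(),
                      slopes = c("pooled", "by_gender"),
                      residual = c("pooled", "by_gender")) {
  slopes <- match.arg(slopes)
  residual <- match.arg(residual)
  if (length(classifications)) {
    if (is.null(names(classifications)) || anyDuplicated(names(classifications)))
      stop("classifications must be uniquely named")
  }
  if (slopes == "by_gender" && !("gender" %in% fixed))
    stop("gender random slopes require 'gender' among the fixed effects")
  structure(list(fixed = fixed, classifications = classifications,
                 slopes = slopes, residual = residual),
            class = "mmmc_spec")
}

#' Standard model specifications
#'
#' `model1_spec()` is the variance-component model: intercept only, pooled
#' random intercepts at the neighbourhood, school, triad and dyad levels.
#' `model2_spec()` adds gender as a fixed effect and gender random effects
#' at every level, with gender-specific residual variances.
#' `model3_spec(covariates)` adds child, parent, school and neighbourhood
#' covariates as further fixed effects, keeping Model 2's random part.
#'
#' @param covariates Character vector of covariate column names (Model 3).
#' @return An `mmmc_spec`.
#' @rdname standard_specs
#' @export
model1_spec <- function() {
  mmmc_spec(fixed = NULL,
            classifications = list(neighbourhood = "neighbourhood_id",
                                   school = "school_id",
                                   triad = "weights",
                                   dyad = "weights"),
            slopes = "pooled", residual = "pooled")
}

#' @rdname standard_specs
#' @export
model2_spec <- function() {
  mmmc_spec(fixed = "gender",
            classifications = list(neighbourhood = "neighbourhood_id",
                                   school = "school_id",
                                   triad = "weights",
                                   dyad = "weights"),
            slopes = "by_gender", residual = "by_gender")
}

#' @rdname standard_specs
#' @export
model3_spec <- function(covariates) {
  stopifnot(is.character(covariates), length(covariates) >= 1)
  sp <- model2_spec()
  sp$fixed <- c("gender", setdiff(covariates, "gender"))
  sp
}

#' MCMC options
#'
#' @param seed Integer seed; required so that chains are reproducible.
#' @param burn_in Discarded initial iterations (default 5000).
#' @param iterations Monitored (kept, pre-thinning) iterations after
#'   burn-in (default 50000).
#' @param thin Keep every `thin`-th monitored draw (default 1).
#' @param priors See [mmmc_priors()].
#' @param interweave Add an ancillarity-sufficiency interweaving (ASIS)
#'   rescaling move after each classification's centred update (default
#'   `TRUE`).  This greatly improves mixing of weakly identified
#'   multiple-membership variance components; it applies to pooled
#'   variances and to diagonal gender covariances, and is skipped when the
#'   full boy-girl covariance is estimated.
#' @return An object of class `mcmc_options`.
#' @export
mcmc_options <- function(seed, burn_in = 5000, iterations = 50000, thin = 1,
                         priors = mmmc_priors(), interweave = TRUE) {
  if (missing(seed) || !is.finite(seed)) stop("an explicit seed is required")
  stopifnot(iterations > 0, burn_in >= 0, thin >= 1)
  structure(list(seed = as.integer(seed), burn_in = as.integer(burn_in),
                 iterations = as.integer(iterations), thin = as.integer(thin),
                 priors = priors, interweave = isTRUE(interweave)),
            class = "mcmc_options")
}

#' Prior hyperparameters
#'
#' Fixed effects get an improper uniform prior.  Scalar variances get an
#' inverse-Gamma(shape, rate) family that includes the common choices:
#' the default `shape = -1, rate = 0` is the improper Uniform(0, Inf) prior
#' on the variance, which in calibration studies on the synthetic cohort
#' recovers weakly identified multiple-membership components markedly
#' better than inverse-Gamma(0.001, 0.001) (whose spike at zero collapses
#' them); set `variance_shape = 0.001, variance_rate = 0.001` for the
#' classical default of multilevel MCMC software.  The uniform prior
#' requires at least three groups per classification.  2x2 gender
#' covariance matrices (when estimated) get an inverse-Wishart with
#' identity scale and minimal degrees of freedom.
#'
#' @param variance_shape,variance_rate Inverse-Gamma hyperparameters for
#'   scalar variances; `(-1, 0)` (default) is uniform on the variance,
#'   `(-0.5, 0)` uniform on the standard deviation.
#' @param wishart_df Inverse-Wishart degrees of freedom for 2x2 gender
#'   covariances (default 2, the dimension).
#' @param wishart_scale 2x2 inverse-Wishart scale matrix (default identity).
#' @param estimate_gender_cov If `TRUE`, the boy-girl covariance at each
#'   level is estimated with the inverse-Wishart prior.  The default
#'   (`FALSE`) constrains it to zero, giving each gender's variance an
#'   independent inverse-Gamma prior; the reported tables use only the
#'   per-gender variances, and the diagonal structure admits the
#'   interweaving move that keeps the sampler well mixed.
#' @return A list of class `mmmc_priors`.
#' @export
mmmc_priors <- function(variance_shape = -1, variance_rate = 0,
                        wishart_df = 2, wishart_scale = diag(2),
                        estimate_gender_cov = FALSE) {
  structure(list(variance_shape = variance_shape, variance_rate = variance_rate,
                 wishart_df = wishart_df, wishart_scale = wishart_scale,
                 estimate_gender_cov = isTRUE(estimate_gender_cov)),
            class = "mmmc_priors")
}

# ---------------------------------------------------------------------------
# Assembly

.gender_levels <- c("boy", "girl")

.check_gender <- function(g) {
  g <- as.character(g)
  if (anyNA(g) || !all(g %in% .gender_levels))
    stop("gender must be 'boy' or 'girl' with no missing values")
  factor(g, levels = .gender_levels)
}

# one classification -> sparse design + bookkeeping
.build_class <- function(label, source, data, weights, slopes, gender_idx) {
  n <- nrow(data)
  if (identical(source, "weights")) {
    mw <- weights[[label]]
    if (is.null(mw))
      stop("classification '", label, "' needs a membership_weights object")
    stopifnot(inherits(mw, "membership_weights"))
    if (!all(data$child_id %in% mw$children))
      stop("children in data missing from the '", label, "' weight roster")
    w <- mw$weights[mw$weights$child_id %in% data$child_id, , drop = FALSE]
    i <- match(w$child_id, data$child_id)
    j <- w$group
    x <- w$weight
    m <- length(mw$groups)
    multiple <- TRUE
  } else {
    col <- data[[source]]
    if (is.null(col)) stop("grouping column '", source, "' not found")
    if (anyNA(col)) stop("grouping column '", source, "' has missing values")
    f <- factor(as.character(col))
    i <- seq_len(n)
    j <- as.integer(f)
    x <- rep(1, n)
    m <- nlevels(f)
    multiple <- FALSE
  }
  sw2 <- numeric(n)
  if (length(i)) {
    agg <- rowsum(x^2, i)
    sw2[as.integer(rownames(agg))] <- agg[, 1]
  }
  if (slopes == "by_gender") {
    jj <- 2L * (j - 1L) + gender_idx[i]
    Z <- Matrix::sparseMatrix(i = i, j = jj, x = x, dims = c(n, 2L * m))
    q <- 2L * m
  } else {
    Z <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, m))
    q <- m
  }
  abar <- c(all = mean(sw2),
            boy = if (any(gender_idx == 1L)) mean(sw2[gender_idx == 1L]) else NA_real_,
            girl = if (any(gender_idx == 2L)) mean(sw2[gender_idx == 2L]) else NA_real_)
  list(label = label, Z = Z, m = m, q = q, multiple = multiple,
       slopes = slopes, sw2 = sw2, abar = abar)
}

#' Assemble an MMMC model
#'
#' Turns a specification plus child-level data (and multiple-membership
#' weight objects) into the response vector, fixed-effect design and sparse
#' per-classification incidence structures the sampler needs.  School and
#' neighbourhood enter as cross-classified (non-nested) single-membership
#' levels; dyads and triads as weighted multiple-membership levels.
#'
#' @param spec An [mmmc_spec()].
#' @param data data.frame with one row per child: `child_id`, outcome `y`,
#'   `gender` (`"boy"`/`"girl"` where required), any grouping columns and
#'   covariates the spec references.  Covariates must be complete; run
#'   [complete_case_filter()] first.
#' @param weights Named list of [build_weight_matrix()] objects for each
#'   `"weights"` classification.
#' @param outcome Name of the outcome column (default `"y"`).
#' @return An object of class `mmmc_assembled` with elements `y`, `X`,
#'   `gender`, `classes` and `variance_sources` (classification labels plus
#'   `"individual"`).
#' @export
assemble_mmmc <- function(spec, data, weights = list(), outcome = "y") {
  stopifnot(inherits(spec, "mmmc_spec"), is.data.frame(data))
  if (is.null(data$child_id)) stop("data must have a child_id column")
  if (anyDuplicated(data$child_id)) stop("duplicate child_id in data")
  y <- data[[outcome]]
  if (is.null(y)) stop("outcome column '", outcome, "' not found")
  if (anyNA(y) || !all(is.finite(y))) stop("outcome must be finite and non-missing")
  n <- nrow(data)

  need_gender <- spec$slopes == "by_gender" || spec$residual == "by_gender" ||
    "gender" %in% spec$fixed
  gender <- NULL
  gender_idx <- rep(1L, n)
  if (need_gender) {
    gender <- .check_gender(data$gender)
    gender_idx <- as.integer(gender)
  }

  # fixed-effect design: intercept + gender contrast + covariates
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (v in spec$fixed) {
    if (v == "gender") {
      X <- cbind(X, gender_girl = as.numeric(gender_idx == 2L))
    } else {
      col <- data[[v]]
      if (is.null(col)) stop("covariate '", v, "' not found")
      if (anyNA(col))
        stop("covariate '", v, "' has missing values; apply complete_case_filter first")
      if (is.factor(col) || is.character(col)) {
        f <- factor(col)
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(v, "_", levels(f)[-1])
        X <- cbind(X, mm)
      } else {
        X <- cbind(X, stats::setNames(data.frame(as.numeric(col)), v)[[1]])
        colnames(X)[ncol(X)] <- v
      }
    }
  }

  classes <- list()
  for (label in names(spec$classifications)) {
    classes[[label]] <- .build_class(label, spec$classifications[[label]],
                                     data, weights, spec$slopes, gender_idx)
  }

  structure(list(y = as.numeric(y), X = X, n = n,
                 gender = gender, gender_idx = gender_idx,
                 child_id = as.character(data$child_id),
                 spec = spec, classes = classes,
                 variance_sources = c(names(spec$classifications), "individual")),
            class = "mmmc_assembled")
}

#' @export
print.mmmc_assembled <- function(x, ...) {
  cat(sprintf("<mmmc_assembled> n = %d children, %d fixed effect(s)\n",
              x$n, ncol(x$X)))
  for (cl in x$classes)
    cat(sprintf("  %-14s %5d groups (%s, %s)\n", cl$label, cl$m,
                if (cl$multiple) "multiple membership" else "single membership",
                cl$slopes))
  cat("  individual     residual (", x$spec$residual, ")\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Gibbs sampler

# inverse-gamma draw parameterised by shape/rate on the variance scale
.rinvgamma <- function(shape, rate) {
  if (shape <= 0)
    stop("variance full conditional has non-positive shape; the improper ",
         "uniform variance prior needs at least 3 groups per classification ",
         "(use mmmc_priors(variance_shape = 0.001, variance_rate = 0.001))")
  1 / stats::rgamma(1L, shape = shape, rate = rate)
}

# sample u ~ N(P^{-1} b, P^{-1}) from sparse precision P
.sample_gaussian_sparse <- function(P, b, ch = NULL) {
  if (is.null(ch))
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(P), LDL = FALSE, perm = TRUE)
  else ch <- Matrix::update(ch, P)
  mu <- Matrix::solve(ch, b, system = "A")
  z <- stats::rnorm(nrow(P))
  dev <- Matrix::solve(ch, Matrix::solve(ch, z, system = "Lt"), system = "Pt")
  list(u = as.numeric(mu) + as.numeric(dev), ch = ch)
}

# univariate slice sampler (stepping out + shrinkage)
.slice1 <- function(logf, x0, w, max_steps = 50L) {
  y <- logf(x0) - stats::rexp(1L)
  u <- stats::runif(1L)
  L <- x0 - w * u
  R <- L + w
  s <- 0L
  while (s < max_steps && logf(L) > y) { L <- L - w; s <- s + 1L }
  s <- 0L
  while (s < max_steps && logf(R) > y) { R <- R + w; s <- s + 1L }
  repeat {
    x1 <- stats::runif(1L, L, R)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# stored-entry keys of a column-compressed symmetric (upper) sparse matrix
.dsc_keys <- function(M) {
  q <- nrow(M)
  j <- rep.int(seq_len(q) - 1L, diff(M@p))
  M@i + q * j
}

# precomputed per-classification working structures:
# - under the diagonal gender structure, (group x gender) columns with no
#   member children are dropped: they carry no information, and their
#   prior-only draws would otherwise dominate (and freeze) the variance
#   updates at levels where most cliques are single gender
# - the precision P = sum_g CtC_g / s2e_g + prior is assembled by writing
#   into a fixed sparsity pattern so the CHOLMOD symbolic factorisation is
#   reused across iterations
.class_cache <- function(cl, X_rows, full_cov) {
  Z <- cl$Z
  keep <- seq_len(cl$q)
  col_gender <- NULL
  if (cl$slopes == "by_gender") {
    if (full_cov) {
      col_gender <- rep_len(c(1L, 2L), cl$q)
    } else {
      keep <- which(Matrix::colSums(Z != 0) > 0)
      Z <- Z[, keep, drop = FALSE]
      col_gender <- ((keep - 1L) %% 2L) + 1L
    }
  }
  q <- ncol(Z)
  Zt <- Matrix::t(Z)
  if (q == 0L) return(list(empty = TRUE, Zt = Zt, keep = keep))
  comps <- lapply(X_rows, function(rows)
    as(Matrix::forceSymmetric(Matrix::crossprod(Z[rows, , drop = FALSE])),
       "CsparseMatrix"))
  if (cl$slopes == "by_gender" && full_cov) {
    jj <- seq_len(cl$m) * 2L
    pi <- as.vector(rbind(jj - 1L, jj - 1L, jj))
    pj <- as.vector(rbind(jj - 1L, jj, jj))
  } else {
    pi <- pj <- seq_len(q)
  }
  keys_comp <- lapply(comps, .dsc_keys)
  keys_prior <- (pi - 1L) + q * (pj - 1L)
  all_keys <- sort(unique(c(unlist(keys_comp), keys_prior)))
  P <- Matrix::sparseMatrix(i = all_keys %% q + 1L,
                            j = all_keys %/% q + 1L,
                            x = 1, dims = c(q, q), symmetric = TRUE)
  keys_P <- .dsc_keys(P)
  list(empty = FALSE, Z = Z, Zt = Zt, keep = keep, q = q,
       col_gender = col_gender,
       n_cols_gender = if (!is.null(col_gender)) tabulate(col_gender, 2L),
       P = P, nnz = length(keys_P),
       comp_x = lapply(comps, function(M) M@x),
       comp_map = lapply(keys_comp, match, keys_P),
       prior_map = match(keys_prior, keys_P),
       ch = NULL)
}

#' Gaussian (conditional) deviance
#'
#' Minus twice the Gaussian log-likelihood of the outcome given the fixed
#' effects, the realised random effects and the residual variance(s) -- the
#' conditional deviance used for DIC in multilevel MCMC software.
#'
#' @param assembled An [assemble_mmmc()] object.
#' @param beta Fixed-effect vector.
#' @param u Named list of random-effect vectors, one per classification (in
#'   the sampler's column order); may be `NULL` when there are none.
#' @param sigma2_e Residual variance: scalar (pooled) or length-2 named
#'   vector `c(boy = , girl = )`.
#' @return The deviance (a scalar).
#' @export
mmmc_deviance <- function(assembled, beta, u = NULL, sigma2_e) {
  e <- assembled$y - as.numeric(assembled$X %*% beta)
  for (label in names(assembled$classes))
    e <- e - as.numeric(assembled$classes[[label]]$Z %*% u[[label]])
  s2 <- if (length(sigma2_e) == 2L) sigma2_e[assembled$gender_idx]
        else rep(sigma2_e, assembled$n)
  sum(log(2 * pi * s2) + e^2 / s2)
}

#' Fit an MMMC model by Gibbs sampling
#'
#' Full-conditional updates: fixed effects from a multivariate normal;
#' each classification's random-effect block jointly from a sparse
#' multivariate normal (multiple-membership weights enter the linear
#' predictor as the weighted sum of clique effects); scalar variances from
#' inverse-Gamma; 2x2 gender covariances from inverse-Wishart; and
#' gender-specific residual variances from gender-partitioned residuals.
#' Chains are reproducible bit-exactly for a fixed seed.
#'
#' @param assembled An [assemble_mmmc()] object.
#' @param opts An [mcmc_options()] object.
#' @param verbose Print progress every 1000 iterations.
#' @return An object of class `mmmc_chains`: post-burn-in, thinned draws of
#'   `beta` (matrix), per-classification variances (`sigma2` vector or
#'   `Omega` matrix with columns var_boy, var_girl, cov), residual
#'   variances, the per-draw conditional `deviance`, posterior means of the
#'   random effects (`u_mean`), and the options used.
#' @export
fit_mmmc <- function(assembled, opts, verbose = FALSE) {
  stopifnot(inherits(assembled, "mmmc_assembled"), inherits(opts, "mcmc_options"))
  set.seed(opts$seed)
  pr <- opts$priors
  full_cov <- pr$estimate_gender_cov
  y <- assembled$y
  X <- assembled$X
  n <- assembled$n
  p <- ncol(X)
  g_idx <- assembled$gender_idx
  by_gender_resid <- assembled$spec$residual == "by_gender"
  classes <- assembled$classes
  n_class <- length(classes)

  # gender row partitions for residual-variance-weighted cross products
  if (by_gender_resid) {
    row_sets <- list(which(g_idx == 1L), which(g_idx == 2L))
    XtX_parts <- lapply(row_sets, function(r) crossprod(X[r, , drop = FALSE]))
  } else {
    row_sets <- list(seq_len(n))
    XtX_parts <- list(crossprod(X))
  }
  cache <- lapply(classes, .class_cache, X_rows = row_sets, full_cov = full_cov)

  # initial values
  beta <- qr.coef(qr(X), y)
  beta[!is.finite(beta)] <- 0
  s2e <- rep(stats::var(as.numeric(y - X %*% beta)),
             if (by_gender_resid) 2L else 1L)
  if (by_gender_resid) names(s2e) <- .gender_levels
  u <- lapply(cache, function(cc) numeric(if (cc$empty) 0L else cc$q))
  eta <- lapply(classes, function(cl) numeric(n))
  eta_tot <- numeric(n)
  v0 <- stats::var(y) / (n_class + 1)
  sigma2_c <- lapply(classes, function(cl) {
    if (cl$slopes == "by_gender") diag(2) * v0 else v0
  })

  n_iter <- opts$burn_in + opts$iterations
  keep <- seq(opts$burn_in + opts$thin, n_iter, by = opts$thin)
  n_keep <- length(keep)
  beta_draws <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, colnames(X)))
  resid_draws <- matrix(NA_real_, n_keep, length(s2e),
                        dimnames = list(NULL, if (by_gender_resid) .gender_levels else "pooled"))
  var_draws <- lapply(classes, function(cl) {
    if (cl$slopes == "by_gender")
      matrix(NA_real_, n_keep, 3L, dimnames = list(NULL, c("var_boy", "var_girl", "cov")))
    else matrix(NA_real_, n_keep, 1L, dimnames = list(NULL, "sigma2"))
  })
  dev_draws <- numeric(n_keep)
  u_sum <- lapply(classes, function(cl) numeric(cl$q))
  kept <- 0L

  a0 <- pr$variance_shape; b0 <- pr$variance_rate
  S0 <- pr$wishart_scale; nu0 <- pr$wishart_df

  # log-density of an ASIS scale move: Gaussian likelihood in s times the
  # prior transformed from inverse-Gamma on s^2
  scale_logf <- function(prec, xmu) {
    force(prec); force(xmu)
    function(s) -0.5 * prec * (s - xmu)^2 - (2 * a0 + 1) * log(abs(s)) - b0 / s^2
  }

  for (it in seq_len(n_iter)) {
    dinv <- if (by_gender_resid) 1 / s2e[g_idx] else rep(1 / s2e, n)

    # --- fixed effects (flat prior)
    r <- y - eta_tot
    A <- Reduce(`+`, Map(function(M, s2) M / s2, XtX_parts, as.list(s2e)))
    bv <- crossprod(X, dinv * r)
    U <- chol(A)
    mu_b <- backsolve(U, backsolve(U, bv, transpose = TRUE))
    beta <- as.numeric(mu_b + backsolve(U, stats::rnorm(p)))
    Xb <- as.numeric(X %*% beta)

    # --- random-effect blocks
    for (k in seq_len(n_class)) {
      cl <- classes[[k]]
      cc <- cache[[k]]
      if (cc$empty) next
      r_k <- y - Xb - (eta_tot - eta[[k]])

      # precision assembled into the fixed sparsity pattern
      xv <- numeric(cc$nnz)
      for (gp in seq_along(cc$comp_x))
        xv[cc$comp_map[[gp]]] <- xv[cc$comp_map[[gp]]] + cc$comp_x[[gp]] / s2e[gp]
      if (cl$slopes == "by_gender") {
        if (full_cov) {
          Oinv <- solve(sigma2_c[[k]])
          pv <- rep(c(Oinv[1L, 1L], Oinv[1L, 2L], Oinv[2L, 2L]), cl$m)
        } else {
          dg <- diag(sigma2_c[[k]])
          pv <- (1 / dg)[cc$col_gender]
        }
      } else pv <- rep(1 / sigma2_c[[k]], cc$q)
      xv[cc$prior_map] <- xv[cc$prior_map] + pv
      P <- cc$P
      P@x <- xv

      bvec <- as.numeric(cc$Zt %*% (dinv * r_k))
      sam <- .sample_gaussian_sparse(P, bvec, cache[[k]]$ch)
      cache[[k]]$ch <- sam$ch
      u_new <- sam$u
      eta_new <- as.numeric(cc$Z %*% u_new)
      eta_tot <- eta_tot - eta[[k]] + eta_new
      eta[[k]] <- eta_new
      u[[k]] <- u_new

      # --- classification variance (centred conjugate update)
      if (cl$slopes == "by_gender") {
        if (full_cov) {
          Um <- matrix(u_new, ncol = 2L, byrow = TRUE)    # m x 2 (boy, girl)
          Sp <- S0 + crossprod(Um)
          W <- stats::rWishart(1L, df = nu0 + cl$m, Sigma = solve(Sp))[, , 1L]
          sigma2_c[[k]] <- solve(W)
        } else {
          # only member-bearing columns exist, so each gender's update is
          # informed by exactly its own groups
          for (g in 1:2) {
            cols <- cc$col_gender == g
            sigma2_c[[k]][g, g] <- .rinvgamma(a0 + sum(cols) / 2,
                                              b0 + sum(u_new[cols]^2) / 2)
          }
        }
      } else {
        sigma2_c[[k]] <- .rinvgamma(a0 + cc$q / 2, b0 + sum(u_new^2) / 2)
      }

      # --- interweaved (ancillary) rescaling: holding u / s fixed, move the
      # scale s against the data, then map back; targets the same posterior
      # but decorrelates u from its variance
      if (opts$interweave && !(cl$slopes == "by_gender" && full_cov)) {
        if (cl$slopes == "by_gender") {
          for (g in 1:2) {
            s_old <- sqrt(diag(sigma2_c[[k]])[g])
            rows <- which(g_idx == g)
            cvec <- eta[[k]][rows] / s_old
            prec0 <- sum(cvec^2 * dinv[rows])
            if (prec0 <= 0) next
            xmu <- sum(cvec * r_k[rows] * dinv[rows]) / prec0
            s_new <- .slice1(scale_logf(prec0, xmu), s_old, w = 2 / sqrt(prec0))
            fac <- s_new / s_old
            cols <- which(cc$col_gender == g)
            u[[k]][cols] <- u[[k]][cols] * fac
            eta_tot[rows] <- eta_tot[rows] + (fac - 1) * eta[[k]][rows]
            eta[[k]][rows] <- eta[[k]][rows] * fac
            sigma2_c[[k]][g, g] <- s_new^2
          }
        } else {
          s_old <- sqrt(sigma2_c[[k]])
          cvec <- eta[[k]] / s_old
          prec0 <- sum(cvec^2 * dinv)
          if (prec0 > 0) {
            xmu <- sum(cvec * r_k * dinv) / prec0
            s_new <- .slice1(scale_logf(prec0, xmu), s_old, w = 2 / sqrt(prec0))
            fac <- s_new / s_old
            u[[k]] <- u[[k]] * fac
            eta_tot <- eta_tot + (fac - 1) * eta[[k]]
            eta[[k]] <- eta[[k]] * fac
            sigma2_c[[k]] <- s_new^2
          }
        }
      }
    }

    # --- joint rescaling across classifications: conditional on all scaled
    # effects u_c / s_c, the model is linear in the per-level scales, so the
    # whole scale vector has a Gaussian-times-prior conditional; proposing
    # from the Gaussian and accepting on the prior ratio moves along the
    # between-level ridge (e.g. dyad vs triad) in a single step
    if (opts$interweave && n_class > 0L) {
      gset <- if (any(vapply(classes, function(cl) cl$slopes == "by_gender",
                             TRUE))) 1:2 else 0L
      for (g in gset) {
        ks <- which(vapply(seq_len(n_class), function(k) {
          !cache[[k]]$empty &&
            (if (g == 0L) classes[[k]]$slopes == "pooled"
             else classes[[k]]$slopes == "by_gender" && !full_cov)
        }, TRUE))
        if (length(ks) < 2L) next
        rows <- if (g == 0L) seq_len(n) else row_sets[[g]]
        s_old <- vapply(ks, function(k) {
          if (g == 0L) sqrt(sigma2_c[[k]]) else sqrt(sigma2_c[[k]][g, g])
        }, 0)
        Q <- vapply(ks, function(k) eta[[k]][rows], numeric(length(rows)))
        Q <- sweep(Q, 2L, s_old, "/")
        live <- colSums(Q^2) > 1e-10
        if (sum(live) < 2L) next
        ks <- ks[live]; s_old <- s_old[live]; Q <- Q[, live, drop = FALSE]
        s2g <- if (by_gender_resid) s2e[max(g, 1L)] else s2e
        r_g <- (y - Xb - eta_tot)[rows] + Q %*% s_old
        M <- crossprod(Q) / s2g
        bq <- crossprod(Q, r_g) / s2g
        Um <- tryCatch(chol(M), error = function(e) NULL)
        if (is.null(Um)) next
        mu_s <- backsolve(Um, backsolve(Um, bq, transpose = TRUE))
        s_prop <- as.numeric(mu_s + backsolve(Um, stats::rnorm(length(ks))))
        logp <- function(s) sum(-(2 * a0 + 1) * log(abs(s)) - b0 / s^2)
        if (all(abs(s_prop) > 1e-12) &&
            log(stats::runif(1L)) < logp(s_prop) - logp(s_old)) {
          for (idx in seq_along(ks)) {
            k <- ks[idx]
            fac <- s_prop[idx] / s_old[idx]
            if (g == 0L) {
              u[[k]] <- u[[k]] * fac
              eta_tot <- eta_tot + (fac - 1) * eta[[k]]
              eta[[k]] <- eta[[k]] * fac
              sigma2_c[[k]] <- s_prop[idx]^2
            } else {
              cols <- which(cache[[k]]$col_gender == g)
              u[[k]][cols] <- u[[k]][cols] * fac
              eta_tot[rows] <- eta_tot[rows] + (fac - 1) * eta[[k]][rows]
              eta[[k]][rows] <- eta[[k]][rows] * fac
              sigma2_c[[k]][g, g] <- s_prop[idx]^2
            }
          }
        }
      }
    }

    # --- residual variance(s)
    e <- y - Xb - eta_tot
    if (by_gender_resid) {
      for (g in 1:2) {
        rows <- row_sets[[g]]
        s2e[g] <- .rinvgamma(a0 + length(rows) / 2, b0 + sum(e[rows]^2) / 2)
      }
    } else {
      s2e <- .rinvgamma(a0 + n / 2, b0 + sum(e^2) / 2)
    }

    # --- store
    if (it > opts$burn_in && (it - opts$burn_in) %% opts$thin == 0L) {
      kept <- kept + 1L
      beta_draws[kept, ] <- beta
      resid_draws[kept, ] <- s2e
      for (k in seq_len(n_class)) {
        if (cache[[k]]$empty) {
          var_draws[[k]][kept, ] <- 0           # no groups: zero contribution
        } else if (classes[[k]]$slopes == "by_gender") {
          O <- sigma2_c[[k]]
          var_draws[[k]][kept, ] <- c(O[1L, 1L], O[2L, 2L], O[1L, 2L])
        } else var_draws[[k]][kept, 1L] <- sigma2_c[[k]]
        if (!cache[[k]]$empty)
          u_sum[[k]][cache[[k]]$keep] <- u_sum[[k]][cache[[k]]$keep] + u[[k]]
      }
      s2vec <- if (by_gender_resid) s2e[g_idx] else rep(s2e, n)
      dev_draws[kept] <- sum(log(2 * pi * s2vec) + e^2 / s2vec)
      if (!all(is.finite(dev_draws[kept])))
        stop("divergence: non-finite deviance at iteration ", it)
    }
    if (verbose && it %% 1000L == 0L)
      message("iteration ", it, "/", n_iter)
  }

  structure(list(beta = beta_draws,
                 classes = stats::setNames(lapply(seq_len(n_class), function(k) {
                   list(label = classes[[k]]$label,
                        slopes = classes[[k]]$slopes,
                        multiple = classes[[k]]$multiple,
                        m = classes[[k]]$m,
                        abar = classes[[k]]$abar,
                        draws = var_draws[[k]],
                        u_mean = u_sum[[k]] / max(kept, 1L))
                 }), names(classes)),
                 residual = resid_draws,
                 deviance = dev_draws,
                 n = n, n_draws = n_keep,
                 options = opts),
            class = "mmmc_chains")
}

#' @export
print.mmmc_chains <- function(x, ...) {
  cat(sprintf("<mmmc_chains> %d draws (burn-in %d, thin %d)\n",
              x$n_draws, x$options$burn_in, x$options$thin))
  bm <- colMeans(x$beta)
  cat("fixed effects (posterior means):\n")
  print(round(bm, 3))
  for (cl in x$classes) {
    cm <- colMeans(cl$draws)
    cat(sprintf("  %-14s %s\n", cl$label,
                paste(sprintf("%s=%.2f", colnames(cl$draws), cm), collapse = " ")))
  }
  cat("  residual      ",
      paste(sprintf("%s=%.2f", colnames(x$residual), colMeans(x$residual)),
            collapse = " "), "\n")
  invisible(x)
}
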