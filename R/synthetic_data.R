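# Synthetic cohort generator: school/neighbourhood structure, gendered
# friendship nominations, covariates and Gaussian outcomes with known
# variance components per gender.

#' Configuration for the synthetic cohort
#'
#' Defaults emulate the structure of a primary-school accelerometer cohort
#' at age 9: 47 schools of 7-65 participants (mean about 26), roughly 350
#' realised neighbourhoods cross-classified with schools, 55% girls,
#' within-school gender-homophilous friendship nominations capped at 4 per
#' child, and weekday MVPA outcomes whose true variance decomposes over
#' neighbourhood / school / triad / dyad / individual levels with
#' gender-specific magnitudes.
#'
#' @param seed Root seed for [simulate_study()].
#' @param n_schools Number of schools.
#' @param school_size_range Admissible school participant counts.
#' @param school_size_meanlog,school_size_sdlog Log-normal parameters for
#'   school sizes (right-skewed, clamped to `school_size_range`).
#' @param n_neighbourhoods Size of the neighbourhood pool.
#' @param neighbourhoods_per_school Catchment size; each school's children
#'   are spread over this many nearby neighbourhoods, with catchments
#'   overlapping between schools (true cross-classification).
#' @param pct_female Probability a child is a girl.
#' @param nomination_cap Maximum nominations per child.
#' @param nominations_range Range the per-child nomination count is drawn
#'   from (capped at `nomination_cap` and school size).
#' @param homophily Probability a nomination is restricted to same-gender
#'   schoolmates (when any exist).
#' @param reciprocity Probability a nomination is reciprocated (within the
#'   nominee's cap).
#' @param transitivity Probability a nomination is drawn from
#'   friends-of-friends (when any exist), which generates triads.
#' @param beta0 Intercept: mean weekday MVPA (min/day) for boys at
#'   covariate zero.
#' @param beta_girl Fixed gender contrast (girls minus boys, min/day).
#' @param covariates Named list of covariate generators: each element a
#'   list with `mean`,`sd` (normal) or `p` (binary 0/1), and `beta`.
#' @param sigma2 Named list of true variance components (min^2), each a
#'   `c(boy=, girl=)` vector, for `neighbourhood`, `school`, `triad`,
#'   `dyad` and `individual` (residual).
#' @param gender_cor Correlation of boy and girl random effects within a
#'   level (default 0).
#' @param missing_rates Named numeric vector of MCAR missingness rates per
#'   covariate; the special name `parent_block` masks all `parent_*`
#'   columns jointly (questionnaire non-return).  Default: none.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_schools = 47L,
                       school_size_range = c(7L, 65L),
                       school_size_meanlog = log(23),
                       school_size_sdlog = 0.45,
                       n_neighbourhoods = 1200L,
                       neighbourhoods_per_school = 8L,
                       pct_female = 0.55,
                       nomination_cap = 4L,
                       nominations_range = c(2L, 4L),
                       homophily = 0.85,
                       reciprocity = 0.5,
                       transitivity = 0.5,
                       beta0 = 68,
                       beta_girl = -11,
                       covariates = list(
                         bmi_z = list(mean = 0.35, sd = 1.07, beta = -3.5),
                         child_age = list(mean = 9.0, sd = 0.5, beta = 2),
                         play_outside = list(mean = 1.2, sd = 0.8, beta = 3),
                         parent_mvpa = list(mean = 54.2, sd = 28.9, beta = 0.15),
                         parent_bmi = list(mean = 25.9, sd = 4.9, beta = 0),
                         household_degree = list(p = 0.52, beta = 4)),
                       sigma2 = list(
                         neighbourhood = c(boy = 57.0, girl = 21.2),
                         school = c(boy = 91.2, girl = 59.3),
                         triad = c(boy = 146, girl = 65),
                         dyad = c(boy = 296, girl = 102),
                         individual = c(boy = 290.6, girl = 292.4)),
                       gender_cor = 0,
                       missing_rates = numeric()) {
  stopifnot(pct_female >= 0, pct_female <= 1,
            homophily >= 0, homophily <= 1,
            reciprocity >= 0, reciprocity <= 1,
            transitivity >= 0, transitivity <= 1,
            nomination_cap >= 0)
  for (s2 in sigma2) stopifnot(all(s2 > 0))
  if (length(missing_rates))
    stopifnot(all(missing_rates >= 0 & missing_rates <= 1))
  structure(as.list(environment()), class = "sim_config")
}

#' Generate the school / neighbourhood / gender structure
#'
#' Children are assigned to schools (sizes drawn in the configured range)
#' and to neighbourhoods sampled from a school-specific catchment of nearby
#' neighbourhoods; catchments overlap between schools, so school and
#' neighbourhood are genuinely cross-classified.  Covariates are drawn
#' independently per child.  Uses the current RNG state; seed via
#' [simulate_study()] or `set.seed()`.
#'
#' @param cfg A [sim_config()].
#' @return data.frame: `child_id`, `school_id`, `neighbourhood_id`,
#'   `gender`, plus one column per configured covariate.
#' @export
generate_structure <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sizes <- round(stats::rlnorm(cfg$n_schools, cfg$school_size_meanlog,
                               cfg$school_size_sdlog))
  sizes <- pmin(pmax(sizes, cfg$school_size_range[1]), cfg$school_size_range[2])
  n <- sum(sizes)
  school <- rep(sprintf("s%02d", seq_len(cfg$n_schools)), sizes)

  # contiguous catchment window per school on a ring of neighbourhoods
  N <- cfg$n_neighbourhoods
  k <- min(cfg$neighbourhoods_per_school, N)
  centre <- sample.int(N, cfg$n_schools, replace = TRUE)
  nbhd <- character(n)
  pos <- 1L
  for (s in seq_len(cfg$n_schools)) {
    catch <- ((centre[s] + seq_len(k) - 2L) %% N) + 1L
    idx <- pos:(pos + sizes[s] - 1L)
    nbhd[idx] <- sprintf("n%03d", sample(catch, sizes[s], replace = TRUE))
    pos <- pos + sizes[s]
  }

  children <- data.frame(
    child_id = sprintf("c%05d", seq_len(n)),
    school_id = school,
    neighbourhood_id = nbhd,
    gender = ifelse(stats::runif(n) < cfg$pct_female, "girl", "boy"),
    stringsAsFactors = FALSE)

  for (v in names(cfg$covariates)) {
    cv <- cfg$covariates[[v]]
    x <- if (!is.null(cv$p)) as.numeric(stats::runif(n) < cv$p)
         else stats::rnorm(n, cv$mean, cv$sd)
    # minute- and count-valued covariates cannot go negative
    if (grepl("_mvpa$|_bmi$", v)) x <- pmax(x, 0)
    children[[v]] <- x
  }
  children
}

#' Generate friendship nominations
#'
#' Each child nominates up to `nomination_cap` schoolmates: candidates are
#' restricted to the same gender with probability `homophily`, drawn from
#' friends-of-friends with probability `transitivity` (creating triads),
#' and nominations are reciprocated with probability `reciprocity` when the
#' nominee has spare capacity.  The cap is never exceeded.
#'
#' @param children Output of [generate_structure()].
#' @param cfg A [sim_config()].
#' @return data.frame of directed nominations: `nominator_id`, `nominee_id`.
#' @export
generate_network <- function(children, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$nomination_cap == 0L)
    return(data.frame(nominator_id = character(), nominee_id = character(),
                      stringsAsFactors = FALSE))
  out <- new.env(parent = emptyenv())     # directed nominations per child
  nbrs <- new.env(parent = emptyenv())    # undirected ties so far
  for (id in children$child_id) { assign(id, character(), out); assign(id, character(), nbrs) }
  gender <- stats::setNames(children$gender, children$child_id)
  lo <- min(cfg$nominations_range); hi <- max(cfg$nominations_range)

  add_tie <- function(a, b) {
    assign(a, union(get(a, nbrs), b), nbrs)
    assign(b, union(get(b, nbrs), a), nbrs)
  }
  pick1 <- function(v) v[sample.int(length(v), 1L)]

  for (sch in split(children$child_id, children$school_id)) {
    for (i in sample(sch)) {
      target <- min(cfg$nomination_cap, length(sch) - 1L,
                    if (hi > lo) sample(lo:hi, 1L) else lo)
      while (length(get(i, out)) < target) {
        cand <- setdiff(sch, c(i, get(i, out)))
        if (!length(cand)) break
        if (stats::runif(1) < cfg$transitivity) {
          ff <- setdiff(unique(unlist(lapply(get(i, nbrs), get, envir = nbrs))),
                        c(i, get(i, out)))
          ff <- intersect(ff, cand)
          if (length(ff)) cand <- ff
        }
        if (stats::runif(1) < cfg$homophily) {
          sg <- cand[gender[cand] == gender[i]]
          if (length(sg)) cand <- sg
        }
        j <- pick1(cand)
        assign(i, c(get(i, out), j), out)
        add_tie(i, j)
        if (stats::runif(1) < cfg$reciprocity &&
            length(get(j, out)) < cfg$nomination_cap &&
            !(i %in% get(j, out)))
          assign(j, c(get(j, out), i), out)
      }
    }
  }
  nominator <- rep(children$child_id,
                   vapply(children$child_id, function(id) length(get(id, out)), 0L))
  nominee <- unlist(lapply(children$child_id, get, envir = out), use.names = FALSE)
  data.frame(nominator_id = nominator,
             nominee_id = if (is.null(nominee)) character() else nominee,
             stringsAsFactors = FALSE)
}

# draw m iid 2-vectors with per-gender variances and correlation rho
.draw_gender_effects <- function(m, s2, rho) {
  sd_b <- sqrt(s2[["boy"]]); sd_g <- sqrt(s2[["girl"]])
  z <- matrix(stats::rnorm(2L * m), m, 2L)
  u_boy <- sd_b * z[, 1L]
  u_girl <- sd_g * (rho * z[, 1L] + sqrt(1 - rho^2) * z[, 2L])
  cbind(boy = u_boy, girl = u_girl)
}

#' Generate outcomes with known variance components
#'
#' y_i = x_i' beta + u_neighbourhood + u_school + sum_j w_ij u_dyad,j +
#' sum_k w_ik u_triad,k + e_i, with gender-specific variances at every
#' level.  All random effects and residuals are drawn independently.
#'
#' @param children Output of [generate_structure()].
#' @param weights Named list with `dyad` and `triad`
#'   [build_weight_matrix()] objects for these children.
#' @param cfg A [sim_config()].
#' @return List: `children` (with outcome column `y`) and `truth` -- the
#'   generating parameters, realised random effects, per-gender mean
#'   sum-of-squared-weights (`abar`), the implied per-level variance
#'   contributions and shares per gender, and the covariate
#'   linear-predictor variance per gender.
#' @export
generate_outcomes <- function(children, weights, cfg) {
  stopifnot(inherits(cfg, "sim_config"),
            all(c("dyad", "triad") %in% names(weights)))
  n <- nrow(children)
  g_idx <- ifelse(children$gender == "girl", 2L, 1L)
  rho <- cfg$gender_cor

  # fixed part
  xb <- rep(cfg$beta0, n) + cfg$beta_girl * (g_idx == 2L)
  lp_cov <- numeric(n)
  for (v in names(cfg$covariates))
    lp_cov <- lp_cov + cfg$covariates[[v]]$beta * children[[v]]
  xb <- xb + lp_cov

  eff <- matrix(0, n, 4L,
                dimnames = list(NULL, c("neighbourhood", "school", "triad", "dyad")))
  u_all <- list()
  for (lev in c("neighbourhood", "school")) {
    col <- paste0(lev, "_id")
    f <- factor(children[[col]])
    u <- .draw_gender_effects(nlevels(f), cfg$sigma2[[lev]], rho)
    rownames(u) <- levels(f)
    eff[, lev] <- u[cbind(as.integer(f), g_idx)]
    u_all[[lev]] <- u
  }
  abar <- list()
  for (lev in c("triad", "dyad")) {
    mw <- weights[[lev]]
    m <- length(mw$groups)
    u <- .draw_gender_effects(max(m, 1L), cfg$sigma2[[lev]], rho)
    if (m > 0L && nrow(mw$weights)) {
      w <- mw$weights
      i <- match(w$child_id, children$child_id)
      contrib <- w$weight * u[cbind(w$group, g_idx[i])]
      agg <- rowsum(contrib, i)
      eff[as.integer(rownames(agg)), lev] <- agg[, 1L]
      sw2 <- numeric(n)
      agg2 <- rowsum(w$weight^2, i)
      sw2[as.integer(rownames(agg2))] <- agg2[, 1L]
    } else sw2 <- numeric(n)
    abar[[lev]] <- c(all = mean(sw2),
                     boy = mean(sw2[g_idx == 1L]),
                     girl = mean(sw2[g_idx == 2L]))
    u_all[[lev]] <- u
  }

  e <- stats::rnorm(n, 0, sqrt(cfg$sigma2$individual[c("boy", "girl")][g_idx]))
  children$y <- xb + rowSums(eff) + e

  # implied per-gender components and shares (multiple-membership adjusted)
  comp <- matrix(NA_real_, 5L, 2L,
                 dimnames = list(c("neighbourhood", "school", "triad", "dyad",
                                   "individual"), c("boy", "girl")))
  for (g in c("boy", "girl")) {
    comp["neighbourhood", g] <- cfg$sigma2$neighbourhood[[g]]
    comp["school", g] <- cfg$sigma2$school[[g]]
    comp["triad", g] <- cfg$sigma2$triad[[g]] * abar$triad[[g]]
    comp["dyad", g] <- cfg$sigma2$dyad[[g]] * abar$dyad[[g]]
    comp["individual", g] <- cfg$sigma2$individual[[g]]
  }
  total <- colSums(comp)
  truth <- list(config = cfg,
                u = u_all,
                abar = abar,
                components = comp,
                total = total,
                shares = sweep(comp, 2L, total, "/") * 100,
                lp_cov_var = c(boy = stats::var(lp_cov[g_idx == 1L]),
                               girl = stats::var(lp_cov[g_idx == 2L])))
  list(children = children, truth = truth)
}

#' Mask values completely at random
#'
#' Applies the configured MCAR rates; the `parent_block` rate masks every
#' `parent_*` column jointly per child, mimicking parent questionnaire
#' non-return.
#'
#' @param children data.frame of child records.
#' @param cfg A [sim_config()] with non-empty `missing_rates`.
#' @return The data.frame with masked entries set to `NA`.
#' @export
apply_missingness <- function(children, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  rates <- cfg$missing_rates
  n <- nrow(children)
  for (v in names(rates)) {
    if (v == "parent_block") {
      cols <- grep("^parent_", names(children), value = TRUE)
      hit <- stats::runif(n) < rates[[v]]
      children[hit, cols] <- NA
    } else if (v %in% names(children)) {
      children[stats::runif(n) < rates[[v]], v] <- NA
    }
  }
  children
}

#' Simulate a complete study dataset
#'
#' Seeds the RNG once from `cfg$seed` and chains structure, network,
#' clique/weight construction and outcome generation; the same seed gives a
#' byte-identical dataset.
#'
#' @param cfg A [sim_config()].
#' @return List: `children` (with `y`; masked if missingness configured),
#'   `children_complete` (pre-masking), `nominations`, `network`,
#'   `cliques` (`dyad`, `triad` lists), `weights` (`dyad`, `triad`
#'   [build_weight_matrix()] objects) and `truth`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  children <- generate_structure(cfg)
  noms <- generate_network(children, cfg)
  net <- build_adjacency(noms, children$child_id)
  cl2 <- enumerate_cliques(net, 2L)
  cl3 <- enumerate_cliques(net, 3L)
  w <- list(dyad = build_weight_matrix(net, cl2, "dyad"),
            triad = build_weight_matrix(net, cl3, "triad"))
  outc <- generate_outcomes(children, w, cfg)
  children <- outc$children
  masked <- if (length(cfg$missing_rates)) apply_missingness(children, cfg)
            else children
  list(children = masked, children_complete = children,
       nominations = noms, network = net,
       cliques = list(dyad = cl2, triad = cl3),
       weights = w, truth = outc$truth, config = cfg)
}
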