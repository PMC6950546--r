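# Shared fixtures and independent oracles, built in code.

# --- accelerometry -----------------------------------------------------------

# epoch series from a per-minute count pattern (each minute block-constant)
series_from_minutes <- function(min_counts, epoch_s = 10L, child = "c1",
                                start = as.POSIXct("2016-03-07 00:00:00", tz = "UTC")) {
  epm <- 60L %/% epoch_s
  counts <- rep(min_counts, each = epm)
  ts <- start + seq_along(counts) * epoch_s - epoch_s
  epoch_series(child, ts, counts, epoch_s)
}

# independent epoch-level scan for nonwear (prefix sums, no rle):
# a window starting at zero epoch s ends at the last zero epoch e with
# cumulative nonzero epochs in [s, e] <= allowed; it qualifies if its zero
# epochs reach the threshold.  Emitted left to right without overlap.
nonwear_oracle <- function(counts, epoch_s, zero_run_min = 60,
                           interruption_allow_min = 2) {
  epm <- 60L %/% epoch_s
  thr <- zero_run_min * epm
  allow <- interruption_allow_min * epm
  n <- length(counts)
  nz <- cumsum(counts != 0)
  res <- NULL
  s <- 1L
  while (s <= n) {
    if (counts[s] != 0) { s <- s + 1L; next }
    base <- if (s > 1L) nz[s - 1L] else 0L
    ok <- which(counts[s:n] == 0 & (nz[s:n] - base) <= allow)
    e <- s + max(ok) - 1L
    zeros <- (e - s + 1L) - (nz[e] - base)
    if (zeros >= thr) {
      res <- rbind(res, c(s, e))
      s <- e + 1L
    } else s <- s + 1L
  }
  if (is.null(res)) matrix(integer(), 0, 2) else res
}

# --- networks ----------------------------------------------------------------

random_network <- function(n, p) {
  ids <- sprintf("v%02d", seq_len(n))
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p
  noms <- data.frame(nominator_id = pairs[keep, 1],
                     nominee_id = pairs[keep, 2],
                     stringsAsFactors = FALSE)
  build_adjacency(noms, ids)
}

# exhaustive subset enumeration of complete subgraphs of a given size
brute_cliques <- function(net, size) {
  ids <- net$nodes
  if (length(ids) < size) return(list())
  ekey <- paste(net$edges[, 1], net$edges[, 2])
  has_edge <- function(a, b) paste(min(a, b), max(a, b)) %in% ekey
  subs <- combn(ids, size, simplify = FALSE)
  keep <- vapply(subs, function(s) {
    all(apply(combn(s, 2), 2, function(pr) has_edge(pr[1], pr[2])))
  }, TRUE)
  out <- lapply(subs[keep], sort)
  out[order(vapply(out, paste, "", collapse = "\r"))]
}

# --- models ------------------------------------------------------------------

# 4-child toy: children A,B share dyad d1; C in dyads d2+d3; D friendless
toy_assembled <- function() {
  data <- data.frame(child_id = c("A", "B", "C", "D"),
                     y = c(1, 2, 3, 4),
                     gender = c("boy", "girl", "boy", "girl"),
                     school_id = c("s1", "s1", "s2", "s2"),
                     neighbourhood_id = c("n1", "n2", "n1", "n2"),
                     stringsAsFactors = FALSE)
  groups <- list(c("A", "B"), c("C", "X1"), c("C", "X2"))
  w <- data.frame(child_id = c("A", "B", "C", "C"),
                  group = c(1L, 1L, 2L, 3L),
                  weight = c(1, 1, 0.5, 0.5),
                  stringsAsFactors = FALSE)
  mw <- structure(list(label = "dyad", groups = groups,
                       children = c("A", "B", "C", "D", "X1", "X2"),
                       weights = w),
                  class = "membership_weights")
  spec <- mmmc_spec(classifications = list(dyad = "weights"),
                    residual = "by_gender")
  list(assembled = assemble_mmmc(spec, data, weights = list(dyad = mw)),
       weights = mw, data = data)
}

# hand-constructed chains object for variance-partition arithmetic
fake_chains <- function(class_draws, residual, abar = NULL, multiple = NULL,
                        beta = NULL, deviance = NULL, u_mean = NULL) {
  n_draws <- length(residual[[1]])
  classes <- lapply(names(class_draws), function(lb) {
    d <- class_draws[[lb]]
    if (is.null(dim(d))) d <- matrix(d, ncol = 1, dimnames = list(NULL, "sigma2"))
    list(label = lb, slopes = if (ncol(d) == 3) "by_gender" else "pooled",
         multiple = if (!is.null(multiple)) multiple[[lb]] else FALSE,
         m = 1L,
         abar = if (!is.null(abar)) abar[[lb]] else c(all = 1, boy = 1, girl = 1),
         draws = d,
         u_mean = if (!is.null(u_mean)) u_mean[[lb]] else numeric())
  })
  names(classes) <- names(class_draws)
  res <- do.call(cbind, residual)
  colnames(res) <- names(residual)
  structure(list(beta = if (is.null(beta))
                   matrix(0, n_draws, 1, dimnames = list(NULL, "(Intercept)"))
                 else beta,
                 classes = classes, residual = res,
                 deviance = if (is.null(deviance)) numeric(n_draws) else deviance,
                 n = 10L, n_draws = n_draws,
                 options = NULL),
            class = "mmmc_chains")
}

# small, fast simulation configuration for pipeline-level tests
small_sim_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_schools = 8L, school_size_range = c(7L, 30L),
             n_neighbourhoods = 60L, neighbourhoods_per_school = 5L, ...)
}
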