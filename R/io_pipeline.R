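# Readers/writers, the complete-case filter and the end-to-end pipeline.

#' Read child records from CSV
#'
#' Validates types and plausibility: the outcome and any MVPA columns must
#' be non-negative, BMI z-scores outside +/-6 are flagged with a warning,
#' and row identity is preserved.
#'
#' @param path CSV with one row per child; must contain `child_id`.
#' @param outcome Name of the outcome column to range-check (default `"y"`,
#'   skipped if absent).
#' @return data.frame of child records.
#' @export
read_children <- function(path, outcome = "y") {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(d$child_id)) stop("child data must have a child_id column")
  d$child_id <- as.character(d$child_id)
  if (anyDuplicated(d$child_id)) stop("duplicate child_id values")
  for (v in intersect(c(outcome, grep("mvpa", names(d), value = TRUE)), names(d))) {
    bad <- which(!is.na(d[[v]]) & d[[v]] < 0)
    if (length(bad))
      stop("negative values in '", v, "' at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  if ("bmi_z" %in% names(d)) {
    odd <- which(!is.na(d$bmi_z) & abs(d$bmi_z) > 6)
    if (length(odd))
      warning(length(odd), " BMI z-score(s) outside +/-6 (rows ",
              paste(utils::head(odd, 5), collapse = ", "), ")")
  }
  d
}

#' Write child records to CSV
#'
#' @param children data.frame of child records.
#' @param path Output path.
#' @export
write_children <- function(children, path) {
  utils::write.csv(children, path, row.names = FALSE)
  invisible(path)
}

#' Complete-case (listwise deletion) filter
#'
#' Restricts the data to children complete on all required variables and
#' reports how many children each variable would drop.
#'
#' @param children data.frame of child records.
#' @param required Character vector of variable names that must be
#'   non-missing.
#' @return List: `kept` (filtered data.frame), `dropped` (the removed
#'   rows), `report` (data.frame: variable, n_missing).
#' @export
complete_case_filter <- function(children, required) {
  stopifnot(is.data.frame(children))
  missing_vars <- setdiff(required, names(children))
  if (length(missing_vars))
    stop("required variable(s) not in data: ", paste(missing_vars, collapse = ", "))
  miss <- vapply(required, function(v) is.na(children[[v]]),
                 logical(nrow(children)))
  miss <- matrix(miss, nrow = nrow(children))
  drop <- rowSums(miss) > 0
  list(kept = children[!drop, , drop = FALSE],
       dropped = children[drop, , drop = FALSE],
       report = data.frame(variable = required,
                           n_missing = colSums(miss),
                           row.names = NULL))
}

.log_stage <- function(verbose, ...) if (verbose) message("[mmmcfit] ", ...)

#' Run the full analysis pipeline
#'
#' read (or accept in-memory data) -> complete-case filter -> friendship
#' network -> clique weights -> assemble -> MCMC fit -> variance partition
#' and DIC.  Weekday and weekend outcomes are separate runs of this
#' pipeline with different `outcome` columns.
#'
#' @param children data.frame of child records, or a path to a CSV.
#' @param nominations data.frame of nominations (`nominator_id`,
#'   `nominee_id`), or a path to a CSV.
#' @param model 1, 2 or 3 (see [model1_spec()] and friends).
#' @param covariates Covariate names (required for model 3; also the
#'   complete-case variables).
#' @param outcome Outcome column (default `"y"`).
#' @param mcmc An [mcmc_options()] object.
#' @param outdir Optional directory; when given, the VPC table (CSV) and a
#'   JSON summary are written there.
#' @param verbose Log stage-by-stage counts (default `TRUE`).
#' @return List: `vpc` ([vpc_table()]), `dic`, `chains`, `assembled`,
#'   `filter_report`, `network_summaries`.
#' @export
run_pipeline <- function(children, nominations, model = 1, covariates = NULL,
                         outcome = "y", mcmc, outdir = NULL, verbose = TRUE) {
  if (is.character(children)) children <- read_children(children, outcome)
  if (is.character(nominations)) {
    if (!file.exists(nominations)) stop("file not found: ", nominations)
    nominations <- utils::read.csv(nominations, stringsAsFactors = FALSE)
  }
  stopifnot(model %in% 1:3, inherits(mcmc, "mcmc_options"))
  if (model == 3 && is.null(covariates))
    stop("model 3 requires a covariate list")
  n_in <- nrow(children)
  .log_stage(verbose, "input: ", n_in, " children")

  required <- c(outcome, "school_id", "neighbourhood_id",
                if (model >= 2) "gender", covariates)
  cc <- complete_case_filter(children, intersect(required, names(children)))
  data <- cc$kept
  .log_stage(verbose, "complete cases: ", nrow(data), " kept, ",
             nrow(cc$dropped), " dropped (input = kept + dropped: ",
             nrow(data) + nrow(cc$dropped) == n_in, ")")

  # networks are rebuilt on the filtered roster: omitting a child omits its ties
  net <- build_adjacency(nominations, data$child_id)
  cl2 <- enumerate_cliques(net, 2L)
  cl3 <- enumerate_cliques(net, 3L)
  w <- list(dyad = build_weight_matrix(net, cl2, "dyad"),
            triad = build_weight_matrix(net, cl3, "triad"))
  .log_stage(verbose, "network: ", nrow(net$edges), " ties, ",
             length(cl2), " dyads, ", length(cl3), " triads")

  spec <- switch(model, model1_spec(), model2_spec(), model3_spec(covariates))
  if (!is.null(covariates) && model == 2) spec <- model2_spec()
  names(data)[names(data) == outcome] <- "y"
  assembled <- assemble_mmmc(spec, data, weights = w)
  .log_stage(verbose, "assembled: ", length(assembled$variance_sources),
             " variance sources (", paste(assembled$variance_sources,
                                          collapse = ", "), ")")

  chains <- fit_mmmc(assembled, mcmc)
  d <- mmmc_dic(chains, assembled)
  vpc <- vpc_table(chains, dic = d)
  .log_stage(verbose, "fit: ", chains$n_draws, " draws, DIC = ",
             round(d$dic, 1))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(vpc),
                     file.path(outdir, "vpc_table.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(total_variation = as.list(vpc$total),
           shares_pct = as.data.frame(vpc),
           dic = d$dic, pD = d$pD,
           posterior_mean_beta = as.list(colMeans(chains$beta))),
      file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  list(vpc = vpc, dic = d, chains = chains, assembled = assembled,
       filter_report = cc$report,
       network_summaries = network_summaries(net, cl2, cl3))
}
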