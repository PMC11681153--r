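#' Pipeline configuration
#'
#' Collects every tunable of a full run.  The defaults are the study
#' conditions of the bundled COVID-19 case study: equal local/global
#' emphasis (`alpha = 0.5`), group-sum global weights, column-scoped
#' min-max, the crisp score-scale stage, and the default [bam_config()].
#'
#' @param alpha Local/global blend in `[0, 1]`.
#' @param gc_mode `"group_sum"` or `"reciprocal"` (see [global_weights()]).
#' @param stage `"score"` or `"fuzzy"` (see [decision_matrix()]).
#' @param minmax_scope `"column"` or `"matrix"`.
#' @param policy A [membership_policy()].
#' @param bam A [bam_config()].
#' @param seed Integer seed recorded in every report (used by stochastic
#'   helpers; the pipeline itself is deterministic).
#' @return An `appss_config`.
#' @export
appss_config <- function(alpha = 0.5,
                         gc_mode = c("group_sum", "reciprocal"),
                         stage = c("score", "fuzzy"),
                         minmax_scope = c("column", "matrix"),
                         policy = default_policy(),
                         bam = bam_config(),
                         seed = 0L) {
  stopifnot(alpha >= 0, alpha <= 1)
  structure(list(alpha = alpha, gc_mode = match.arg(gc_mode),
                 stage = match.arg(stage),
                 minmax_scope = match.arg(minmax_scope),
                 policy = policy, bam = bam, seed = as.integer(seed)),
            class = "appss_config")
}

#' Assemble a decision problem
#'
#' @param plpm Pairwise linguistic preference matrix over the criteria: a
#'   tibble with leading row-label column (cells are term codes, diagonal
#'   `"-"`), as read by [read_linguistic_csv()].
#' @param performance Alternatives-by-criteria data: either counts (an
#'   all-numeric body, binned with `bins`) or term codes.
#' @param scale An [linguistic_scale()].
#' @param bins A [bin_table()] (required when `performance` holds counts).
#' @param hierarchy A [criteria_hierarchy()] grouping the criteria.
#' @return An `appss_problem`.
#' @export
appss_problem <- function(plpm, performance, scale = default_scale(),
                          bins = NULL, hierarchy) {
  plpm_m <- as_code_matrix(plpm)
  if (nrow(plpm_m) != ncol(plpm_m)) {
    stop("the pairwise preference matrix must be square", call. = FALSE)
  }
  perf_m <- as_code_matrix(performance)
  numericish <- !anyNA(suppressWarnings(as.numeric(perf_m)))
  if (numericish) {
    if (is.null(bins)) {
      stop("performance data holds counts: a bin table is required",
           call. = FALSE)
    }
    counts <- perf_m
    storage.mode(counts) <- "double"
    codes <- matrix(bin_value(as.vector(counts), bins),
                    nrow(counts), ncol(counts), dimnames = dimnames(counts))
  } else {
    counts <- NULL
    codes <- perf_m
  }
  if (!setequal(colnames(codes), rownames(plpm_m))) {
    stop("performance columns must match the criteria of the preference ",
         "matrix", call. = FALSE)
  }
  codes <- codes[, rownames(plpm_m), drop = FALSE]
  structure(list(plpm = plpm_m, performance_codes = codes,
                 performance_counts = counts, scale = scale, bins = bins,
                 hierarchy = criteria_hierarchy(unclass(hierarchy))),
            class = "appss_problem")
}

#' Run the full preference-performance pipeline
#'
#' Segment I: the pairwise linguistic preference matrix is fuzzified,
#' standardized, normalized and defuzzified ([decision_matrix()]), and the
#' criteria weights are derived ([criteria_preference()]).  Segment II:
#' the performance data are binned, fuzzified and put through the same
#' stage, then the BAM iteration seeded with the weights is run to its
#' fixed point and the alternatives ranked.  Segment III: the
#' satisfaction measure compares the BAM ranking with the outranking-flow
#' ranking.
#'
#' Precomputed crisp matrices may be injected to skip the fuzzy stages:
#' `criteria_matrix` replaces the Segment-I defuzzified matrix (useful to
#' reproduce published intermediate tables), `performance_matrix` the
#' Segment-II one.
#'
#' @param problem An [appss_problem()].
#' @param config An [appss_config()].
#' @param criteria_matrix,performance_matrix Optional crisp injections.
#' @return An `appss_report`: list with `preference`
#'   ([preference_vector()] tibble), `criteria_matrix`,
#'   `performance_matrix`, `bam` (`bam_state`), `ranking` (tibble),
#'   `satisfaction` ([satisfactory_measure()] tibble), `config`.
#' @export
appss_run <- function(problem, config = appss_config(),
                      criteria_matrix = NULL, performance_matrix = NULL) {
  stopifnot(inherits(problem, "appss_problem"),
            inherits(config, "appss_config"))
  g <- nrow(problem$plpm)
  if (is.null(criteria_matrix)) {
    criteria_matrix <- decision_matrix(
      problem$plpm, problem$scale, stage = config$stage,
      scope = config$minmax_scope, mean_divisor = g,
      sd_divisor = max(1L, g - 1L), policy = config$policy)
  }
  pref <- criteria_preference(criteria_matrix, problem$hierarchy,
                              alpha = config$alpha, gc_mode = config$gc_mode)
  f <- nrow(problem$performance_codes)
  if (is.null(performance_matrix)) {
    performance_matrix <- decision_matrix(
      problem$performance_codes, problem$scale, stage = config$stage,
      scope = config$minmax_scope, mean_divisor = f,
      sd_divisor = max(1L, f - 1L), policy = config$policy)
  }
  bam <- bam_iterate(performance_matrix, pref, config$bam)
  ranking <- tidy(bam)
  sat <- satisfactory_measure(bam$x, rank_alternatives(bam$x))
  structure(list(preference = pref, criteria_matrix = criteria_matrix,
                 performance_matrix = performance_matrix, bam = bam,
                 ranking = ranking, satisfaction = sat, config = config),
            class = "appss_report")
}

#' @export
print.appss_report <- function(x, ...) {
  cat("APPSS report (alpha = ", x$config$alpha, ", stage = ",
      x$config$stage, ")\n", sep = "")
  cat("Preference weights:\n")
  print(round(stats::setNames(x$preference$weight, x$preference$criterion),
              4))
  cat("BAM ", if (x$bam$converged) "converged" else "did NOT converge",
      " in ", x$bam$iterations, " iteration(s)\n", sep = "")
  print(as.data.frame(x$ranking))
  invisible(x)
}

#' @method tidy appss_report
#' @export
tidy.appss_report <- function(x, ...) {
  dplyr::left_join(x$ranking, tibble::as_tibble(x$satisfaction)[,
    c("alternative", "flow_net", "rank_flow", "satisfaction", "class")],
    by = "alternative")
}

#' @method glance appss_report
#' @export
glance.appss_report <- function(x, ...) {
  tibble::tibble(alpha = x$config$alpha, stage = x$config$stage,
                 lambda = x$config$bam$lambda,
                 iterations = x$bam$iterations,
                 converged = x$bam$converged,
                 top = x$ranking$alternative[x$ranking$rank == 1][1])
}

#' @method autoplot appss_report
#' @export
autoplot.appss_report <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat,
                  ggplot2::aes(x = stats::reorder(.data$alternative,
                                                  .data$rank),
                               y = .data$score, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "alternative", y = "converged BAM score",
                  fill = "satisfaction") +
    ggplot2::theme_minimal()
}

#' Sensitivity sweep over the blend parameter
#'
#' One full pipeline run per `alpha`; reports the per-alpha rankings and
#' whether the alternative ordering is identical across the sweep.
#'
#' @param problem An [appss_problem()].
#' @param config Base [appss_config()]; its `alpha` is replaced per run.
#' @param alphas Blend values in `[0, 1]`.
#' @return A tibble of class `appss_sweep`: one row per alpha with a
#'   list-column `ranks` (named integer vector) and the ordering as text;
#'   attribute `stable` flags an identical ordering across the sweep.
#' @export
alpha_sweep <- function(problem, config = appss_config(),
                        alphas = seq(0, 1, by = 0.1)) {
  stopifnot(all(alphas >= 0 & alphas <= 1))
  rows <- lapply(alphas, function(a) {
    cfg <- config
    cfg$alpha <- a
    rep <- appss_run(problem, cfg)
    rk <- stats::setNames(rep$ranking$rank, rep$ranking$alternative)
    ordering <- paste(rep$ranking$alternative[order(rep$ranking$rank)],
                      collapse = " > ")
    tibble::tibble(alpha = a, ranks = list(rk), ordering = ordering)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("appss_sweep", class(out)),
            stable = length(unique(out$ordering)) == 1)
}

#' @export
print.appss_sweep <- function(x, ...) {
  cat("Alpha sweep over", nrow(x), "values;",
      if (attr(x, "stable")) "ordering stable\n" else "ordering CHANGES\n")
  print(tibble::as_tibble(x)[, c("alpha", "ordering")])
  invisible(x)
}

#' @method autoplot appss_sweep
#' @export
autoplot.appss_sweep <- function(object, ...) {
  dat <- tidyr::unnest_longer(
    dplyr::mutate(tibble::as_tibble(object),
                  alternative = purrr::map(.data$ranks, names)),
    c("ranks", "alternative"))
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$alpha),
                                    y = .data$alternative,
                                    fill = .data$ranks)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = "alpha", y = "alternative", fill = "rank") +
    ggplot2::theme_minimal()
}

#' Random decision problems
#'
#' Generates a reproducible random problem: a pairwise linguistic
#' preference matrix with terms drawn uniformly from the scale
#' (off-diagonal), a count table stratified across the bin table so that
#' several bins are exercised, and a hierarchy that splits the criteria
#' into contiguous groups.
#'
#' @param seed Integer seed; identical seeds give identical problems.
#' @param f Number of alternatives (>= 2).
#' @param g Number of criteria (>= 2).
#' @param n_groups Number of global criteria groups.
#' @param scale,bins The linguistic scale and bin table to draw from.
#' @return An [appss_problem()].
#' @export
generate_problem <- function(seed, f = 5, g = 4, n_groups = 2,
                             scale = default_scale(correct_k1 = TRUE),
                             bins = covid_bins()) {
  stopifnot(f >= 2, g >= 2, n_groups >= 1, n_groups <= g)
  withr::with_seed(as.integer(seed), {
    crit <- paste0("C", seq_len(g))
    alt <- paste0("d", seq_len(f))
    plpm <- matrix(sample(scale$code, g * g, replace = TRUE), g, g,
                   dimnames = list(crit, crit))
    diag(plpm) <- "-"
    # stratified counts: draw the target bin first, then a count inside it
    bin_idx <- matrix(sample(nrow(bins), f * g, replace = TRUE), f, g)
    counts <- matrix(0, f, g, dimnames = list(alt, crit))
    for (i in seq_len(f)) for (j in seq_len(g)) {
      k <- bin_idx[i, j]
      lo <- bins$lower[k]
      hi <- if (is.infinite(bins$upper[k])) bins$lower[k] * 2 + 1000 else
        bins$upper[k]
      counts[i, j] <- floor(stats::runif(1, lo, hi + 1))
    }
    splits <- sort(sample(seq_len(g - 1), n_groups - 1))
    grp <- findInterval(seq_len(g), c(1, splits + 1))
    hierarchy <- split(crit, paste0("G", grp))
    appss_problem(plpm, counts, scale = scale, bins = bins,
                  hierarchy = criteria_hierarchy(hierarchy))
  })
}

#' Bundled case-study fixtures
#'
#' The COVID-19 India age-group case study: eleven age groups (`d1`
#' Infant ... `d11` eldest) assessed on six criteria (`C1`/`C2`
#' male/female positives, `C3`/`C4` hospitalized, `C5`/`C6` deaths).
#' Available fixtures:
#'
#' * `"covid-india-plpm"`: the pairwise linguistic preference matrix;
#' * `"covid-india-scale"`: the eleven-term scale as published;
#' * `"covid-india-bins"`: the case-count bin table;
#' * `"covid-india-data"`: the transcribed counts per age group;
#' * `"covid-india-defuzzified"`: the published defuzzified criteria
#'   matrix (used for stage injection);
#' * `"covid-india-hierarchy"`: the criteria grouping.
#'
#' @param name Fixture name.
#' @return The fixture in its natural class (tibble, scale, bins, matrix
#'   or hierarchy).
#' @export
appss_fixture <- function(name = c("covid-india-plpm", "covid-india-scale",
                                   "covid-india-bins", "covid-india-data",
                                   "covid-india-defuzzified",
                                   "covid-india-hierarchy")) {
  name <- match.arg(name)
  path <- function(file) system.file("extdata", file, package = "appss",
                                     mustWork = TRUE)
  switch(name,
    "covid-india-plpm" = read_linguistic_csv(path("covid_india_plpm.csv")),
    "covid-india-scale" = read_scale_json(path("covid_india_scale.json")),
    "covid-india-bins" = read_bins_json(path("covid_india_bins.json")),
    "covid-india-data" = read_linguistic_csv(path("covid_india_data.csv")),
    "covid-india-defuzzified" =
      read_crisp_csv(path("covid_india_defuzzified.csv")),
    "covid-india-hierarchy" =
      read_hierarchy_json(path("covid_india_hierarchy.json")))
}

#' The COVID-19 case study as a ready-to-run problem
#'
#' Assembles the bundled fixtures into an [appss_problem()].  By default
#' the scale is used with the `K1` belonging-degree correction (see
#' [default_scale()]); pass `correct_k1 = FALSE` for the published values
#' verbatim.
#'
#' @param correct_k1 Apply the scale correction (default `TRUE`)?
#' @return An [appss_problem()].
#' @export
covid_problem <- function(correct_k1 = TRUE) {
  scale <- if (correct_k1) default_scale(correct_k1 = TRUE) else
    appss_fixture("covid-india-scale")
  appss_problem(
    plpm = appss_fixture("covid-india-plpm"),
    performance = appss_fixture("covid-india-data"),
    scale = scale,
    bins = appss_fixture("covid-india-bins"),
    hierarchy = appss_fixture("covid-india-hierarchy"))
}
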