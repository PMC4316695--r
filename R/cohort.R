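#' Two-tailed paired Student's t-test
#'
#' The significance machinery behind the cohort tables: per-patient values of
#' one quantity are compared against per-patient values of another, paired by
#' patient. Two degenerate cases are handled explicitly: if every difference
#' is exactly zero the series agree perfectly and `p = 1` is returned; if the
#' differences are a nonzero constant the t statistic is unbounded and
#' `p = 0` is returned.
#'
#' @param a,b Numeric vectors of equal length `n >= 2`, paired by patient.
#' @return Two-tailed p-value in `[0, 1]`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("paired series must have equal length", call. = FALSE)
  if (length(a) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("paired series must be complete", call. = FALSE)
  d <- a - b
  if (all(d == 0)) return(1)
  if (stats::sd(d) == 0) return(0)
  unname(stats::t.test(a, b, paired = TRUE)$p.value)
}

#' Significance flag under a discrepancy or agreement criterion
#'
#' In discrepancy mode a difference is claimed significant when `p < alpha`;
#' in agreement mode, agreement is claimed significant when `p > alpha`
#' (both inequalities strict; `p == alpha` is never significant). The
#' agreement criterion reproduces the reporting procedure it is modelled on;
#' note the usual caveat that absence of a significant difference is not by
#' itself evidence of equivalence.
#'
#' @param p A p-value in `[0, 1]`.
#' @param mode `"discrepancy"` or `"agreement"`.
#' @param alpha Significance threshold, default 0.05.
#' @return Logical flag.
#' @export
flag_significance <- function(p, mode = c("discrepancy", "agreement"),
                              alpha = 0.05) {
  mode <- match.arg(mode)
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  if (mode == "discrepancy") p < alpha else p > alpha
}

#' Per-patient DVF comparison record
#'
#' Runs the full per-patient analysis: Jacobian maps and JVH statistics per
#' algorithm (weighted mean, SD, low/high `J_X` tail boundaries, ratio to the
#' observer contour volume ratio when supplied), DICE before and after
#' propagating the moving-image structures, and spatial-discrepancy tail
#' boundaries for every pair of algorithms. All results are returned long, as
#' one tidy tibble.
#'
#' @param fields Named list of [displacement_field()] objects, one per
#'   registration algorithm (at least one; at least two for SD sections).
#' @param masks_target Named list of [structure_mask()] on the fields' grid —
#'   the segmented structures on the target (histogram-carrying) image.
#' @param masks_moving Optional named list of [structure_mask()]: the same
#'   structures delineated on the moving image, used for DICE. Structures
#'   missing from this list simply produce no DICE rows.
#' @param volume_ratios Optional named numeric: observer contour volume ratio
#'   per structure, enabling `jvh_ratio` rows.
#' @param patient_id Identifier copied into every row.
#' @param x_list Volume percentages for the SD boundary series.
#' @param j_tail_x Volume percentage for the two-sided Jacobian tail
#'   boundaries (default 2.5).
#' @return A `patient_record` tibble with columns `patient`, `structure`,
#'   `metric`, `algorithm`, `algorithm_b`, `value`.
#' @export
analyze_patient <- function(fields, masks_target, masks_moving = NULL,
                            volume_ratios = NULL, patient_id = "patient",
                            x_list = c(2.5, 5, 10, 15, 20, 25, 30, 35),
                            j_tail_x = 2.5) {
  if (length(fields) < 1 || is.null(names(fields)) || any(!nzchar(names(fields)))) {
    stop("`fields` must be a named list with at least one algorithm", call. = FALSE)
  }
  if (length(masks_target) < 1) stop("need at least one target structure", call. = FALSE)
  if (is.null(names(masks_target))) {
    names(masks_target) <- vapply(masks_target, function(m) m$label, character(1))
  }
  algs <- names(fields)
  for (f in fields) assert_same_grid(fields[[1]]$geometry, f$geometry)
  for (m in masks_target) assert_same_grid(fields[[1]]$geometry, m$geometry)

  rows <- list()
  add <- function(structure, metric, value, algorithm = NA_character_,
                  algorithm_b = NA_character_) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      patient = patient_id, structure = structure, metric = metric,
      algorithm = algorithm, algorithm_b = algorithm_b, value = value
    )
  }

  jmaps <- lapply(fields, jacobian_map)
  for (sname in names(masks_target)) {
    tmask <- masks_target[[sname]]
    if (!is.null(volume_ratios) && sname %in% names(volume_ratios)) {
      add(sname, "contour_volume_ratio", unname(volume_ratios[[sname]]))
    }
    for (alg in algs) {
      smp <- sample_structure(jmaps[[alg]], tmask)
      add(sname, "jvh_mean", weighted_mean(smp), alg)
      add(sname, "jvh_std", weighted_std(smp), alg)
      add(sname, sprintf("j_low_%g", j_tail_x),
          tail_boundary(smp, j_tail_x, "low")$boundary, alg)
      add(sname, sprintf("j_high_%g", j_tail_x),
          tail_boundary(smp, j_tail_x, "high")$boundary, alg)
      add(sname, "frac_folded", fraction_below(jmaps[[alg]], tmask, 0), alg)
      if (!is.null(volume_ratios) && sname %in% names(volume_ratios)) {
        add(sname, "jvh_ratio", jvh_ratio(smp, volume_ratios[[sname]]), alg)
      }
    }
    # DICE: original and propagated
    if (!is.null(masks_moving) && sname %in% names(masks_moving)) {
      mmask <- masks_moving[[sname]]
      assert_same_grid(tmask$geometry, mmask$geometry)
      add(sname, "dice_orig", dice(mmask, tmask))
      for (alg in algs) {
        add(sname, "dice_deformed", dice(warp_mask(mmask, fields[[alg]]), tmask), alg)
      }
    }
    # pairwise spatial discrepancy
    if (length(algs) >= 2) {
      pairs <- utils::combn(algs, 2, simplify = FALSE)
      for (pr in pairs) {
        smp <- sample_structure(sd_map(fields[[pr[1]]], fields[[pr[2]]]), tmask)
        series <- sd_boundary_series(smp, x_list)
        for (r in seq_len(nrow(series))) {
          add(sname, sprintf("sd_%g", series$X[r]), series$boundary[r],
              pr[1], pr[2])
        }
        add(sname, "sd_mean", weighted_mean(smp), pr[1], pr[2])
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("patient_record", class(out))
  out
}

#' Declare a cohort comparison
#'
#' Helper describing one paired t-test to run in [summarize_cohort()]: pick a
#' per-patient quantity for each side by `(metric, algorithm, algorithm_b)`,
#' a structure, and the significance mode. Side `b = "zero"` tests a quantity
#' against the all-zero baseline.
#'
#' @param structure Structure label the comparison applies to.
#' @param a,b Each a list with `metric` and optionally `algorithm`,
#'   `algorithm_b`; or for `b`, the string `"zero"`.
#' @param mode `"discrepancy"` or `"agreement"`.
#' @param label Optional display label.
#' @return A `cohort_comparison` specification.
#' @export
comparison <- function(structure, a, b, mode = c("discrepancy", "agreement"),
                       label = NULL) {
  mode <- match.arg(mode)
  norm <- function(side) {
    if (identical(side, "zero")) return("zero")
    stopifnot(is.list(side), !is.null(side$metric))
    list(metric = side$metric,
         algorithm = side$algorithm %||% NA_character_,
         algorithm_b = side$algorithm_b %||% NA_character_)
  }
  a <- norm(a); b <- norm(b)
  if (is.null(label)) {
    fmt <- function(s) if (identical(s, "zero")) "0" else
      paste(stats::na.omit(c(s$metric, s$algorithm, s$algorithm_b)), collapse = ":")
    label <- sprintf("%s %s vs %s", structure, fmt(a), fmt(b))
  }
  structure(list(structure = structure, a = a, b = b, mode = mode,
                 label = label),
            class = "cohort_comparison")
}

#' Cohort-level summary of per-patient records
#'
#' Aggregates per-patient comparison records into per-cell summaries
#' (mean, SD, min, max, n across patients) and runs the declared paired
#' t-tests with discrepancy/agreement significance flags. Patients missing a
#' structure simply reduce `n` for the affected cells.
#'
#' @param records A list of `patient_record` tibbles (from
#'   [analyze_patient()]) or one bound tibble; at least 2 patients.
#' @param comparisons Optional list of [comparison()] declarations.
#' @param alpha Significance threshold for the flags.
#' @return A `cohort_summary`: list with `stats` (tibble of per-cell
#'   summaries), `tests` (tibble of p-values and flags; absent rows if no
#'   comparisons declared) and `n_patients`. Supports [tidy()], [glance()]
#'   and `print()`.
#' @export
summarize_cohort <- function(records, comparisons = NULL, alpha = 0.05) {
  if (is.list(records) && !inherits(records, "data.frame")) {
    records <- dplyr::bind_rows(records)
  }
  n_patients <- length(unique(records$patient))
  if (n_patients < 2) stop("need records from at least 2 patients", call. = FALSE)
  stats_tbl <- records |>
    dplyr::group_by(.data$structure, .data$metric, .data$algorithm,
                    .data$algorithm_b) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      min = min(.data$value),
      max = max(.data$value),
      n = dplyr::n(),
      .groups = "drop"
    )
  tests <- NULL
  if (length(comparisons) > 0) {
    tests <- dplyr::bind_rows(lapply(comparisons, function(cmp) {
      va <- extract_series(records, cmp$structure, cmp$a)
      vb <- if (identical(cmp$b, "zero")) {
        stats::setNames(rep(0, length(va)), names(va))
      } else {
        extract_series(records, cmp$structure, cmp$b)
      }
      common <- intersect(names(va), names(vb))
      if (length(common) < 2) {
        stop(sprintf("comparison '%s': fewer than 2 complete pairs", cmp$label),
             call. = FALSE)
      }
      p <- paired_t_test(va[common], vb[common])
      tibble::tibble(
        label = cmp$label, structure = cmp$structure, mode = cmp$mode,
        n = length(common), p_value = p,
        significant = flag_significance(p, cmp$mode, alpha)
      )
    }))
  }
  structure(list(stats = stats_tbl, tests = tests, n_patients = n_patients,
                 alpha = alpha),
            class = "cohort_summary")
}

extract_series <- function(records, structure, side) {
  sel <- records$structure == structure & records$metric == side$metric
  sel <- sel & (if (is.na(side$algorithm)) is.na(records$algorithm)
                else !is.na(records$algorithm) & records$algorithm == side$algorithm)
  sel <- sel & (if (is.na(side$algorithm_b)) is.na(records$algorithm_b)
                else !is.na(records$algorithm_b) & records$algorithm_b == side$algorithm_b)
  sub <- records[sel, ]
  if (any(duplicated(sub$patient))) {
    stop("comparison side selects more than one value per patient", call. = FALSE)
  }
  stats::setNames(sub$value, sub$patient)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d patients, %d cells\n",
              x$n_patients, nrow(x$stats)))
  tbl <- x$stats
  tbl$cell <- format_mean_sd(tbl$mean, tbl$sd)
  print(tbl[, c("structure", "metric", "algorithm", "algorithm_b", "cell",
                "min", "max", "n")], n = 20)
  if (!is.null(x$tests)) {
    cat("\nDeclared comparisons:\n")
    print(x$tests)
  }
  invisible(x)
}

#' Report-style cell formatting
#'
#' Formats cohort cells as `"mean +/- SD"` at two significant figures on the
#' SD, the convention of clinical QA summary tables. Full precision remains
#' available in the `stats` tibble.
#'
#' @param mean,sd Numeric vectors.
#' @return Character vector of formatted cells.
#' @export
format_mean_sd <- function(mean, sd) {
  sprintf("%s ± %s", signif(mean, 2), signif(sd, 2))
}

#' Wide report table for one metric
#'
#' Casts the cohort summary of one metric into the familiar
#' structure-by-algorithm table of `"mean +/- SD"` cells.
#'
#' @param summary A `cohort_summary`.
#' @param metric Metric name, e.g. `"jvh_std"` or `"sd_2.5"`.
#' @return A wide tibble, one row per structure.
#' @export
cohort_table <- function(summary, metric) {
  stopifnot(inherits(summary, "cohort_summary"))
  sub <- summary$stats[summary$stats$metric == metric, ]
  if (nrow(sub) == 0) stop(sprintf("no cells for metric '%s'", metric), call. = FALSE)
  sub$column <- ifelse(
    is.na(sub$algorithm), metric,
    ifelse(is.na(sub$algorithm_b), sub$algorithm,
           paste(sub$algorithm, sub$algorithm_b, sep = "-"))
  )
  sub$cell <- format_mean_sd(sub$mean, sub$sd)
  # manual pivot keeps tidyr out of Imports
  cols <- unique(sub$column)
  out <- tibble::tibble(structure = unique(sub$structure))
  for (cl in cols) {
    m <- sub[sub$column == cl, ]
    out[[cl]] <- m$cell[match(out$structure, m$structure)]
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cohort summary
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return The per-cell `stats` tibble.
#' @export
tidy.cohort_summary <- function(x, ...) x$stats

#' One-row overview of a cohort summary
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return A one-row tibble with cohort-level counts.
#' @export
glance.cohort_summary <- function(x, ...) {
  tibble::tibble(
    n_patients = x$n_patients,
    n_structures = length(unique(x$stats$structure)),
    n_metrics = length(unique(x$stats$metric)),
    n_tests = if (is.null(x$tests)) 0L else nrow(x$tests),
    alpha = x$alpha
  )
}
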