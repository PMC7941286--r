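#' @title Cell-survival statistics
#' @description Survival fractions and significance testing for irradiated
#'   versus control replicate cell counts.
#' @name cell_response
NULL

validate_cell_table <- function(table) {
  need <- c("condition", "timepoint_h", "replicate", "count")
  if (!all(need %in% names(table))) {
    stop("cell count table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(table$count < 0)) stop("counts must be non-negative")
  invisible(table)
}

#' Survival fraction of irradiated versus control cultures
#'
#' `mean(treated) / mean(control)` at a timepoint, with the standard
#' error propagated to first order from the replicate SEMs.
#'
#' @param table data.frame with columns `condition` (`control` / `MBI`),
#'   `timepoint_h`, `replicate`, `count`.
#' @param timepoint_h timepoint to evaluate, hours.
#' @param treated,control condition labels.
#' @return list with `fraction`, `sem`, and per-group summaries.
#' @export
survival_fraction <- function(table, timepoint_h, treated = "MBI",
                              control = "control") {
  validate_cell_table(table)
  sub <- table[table$timepoint_h == timepoint_h, ]
  ct <- sub$count[sub$condition == control]
  tr <- sub$count[sub$condition == treated]
  if (length(ct) < 2 || length(tr) < 2) {
    stop("both conditions need >= 2 replicates at this timepoint")
  }
  mc <- mean(ct)
  mt <- mean(tr)
  if (mc <= 0) stop("zero control mean")
  sec <- stats::sd(ct) / sqrt(length(ct))
  set_ <- stats::sd(tr) / sqrt(length(tr))
  f <- mt / mc
  sem <- f * sqrt((set_ / mt)^2 + (sec / mc)^2)
  list(fraction = f, sem = sem,
       treated = list(mean = mt, sem = set_, n = length(tr)),
       control = list(mean = mc, sem = sec, n = length(ct)))
}

#' Two-sided significance test of treated versus control counts
#'
#' Pooled-variance (Student) two-sample t-test on log-transformed counts
#' by default: replicate count noise is multiplicative, so the log scale
#' equalizes the group variances that differ strongly between treated and
#' control on the raw scale, and with triplicates it retains the degrees
#' of freedom that Welch's correction gives away. Welch's t-test and an
#' exact/Monte Carlo permutation test are available; set
#' `log_counts = FALSE` to test on the raw scale. Identical groups
#' short-circuit to p = 1.
#'
#' @inheritParams survival_fraction
#' @param test `"student"`, `"welch"` or `"permutation"`.
#' @param log_counts test log-transformed counts (requires all counts
#'   positive; falls back to the raw scale otherwise).
#' @param n_perm permutation count (used when groups are too large to
#'   enumerate).
#' @return two-sided p-value.
#' @export
compare_conditions <- function(table, timepoint_h,
                               test = c("student", "welch", "permutation"),
                               treated = "MBI", control = "control",
                               log_counts = TRUE, n_perm = 10000) {
  test <- match.arg(test)
  validate_cell_table(table)
  sub <- table[table$timepoint_h == timepoint_h, ]
  x <- sub$count[sub$condition == treated]
  y <- sub$count[sub$condition == control]
  if (length(x) < 2 || length(y) < 2) {
    stop("both conditions need >= 2 replicates at this timepoint")
  }
  # degenerate-variance shortcut: identical groups are not evidence
  if (stats::sd(c(x, y)) == 0 ||
      (isTRUE(all.equal(sort(x), sort(y))) && length(x) == length(y))) {
    return(1)
  }
  if (log_counts && test != "permutation") {
    if (all(x > 0) && all(y > 0)) {
      x <- log(x)
      y <- log(y)
    } else {
      warning("non-positive counts; testing on the raw scale")
    }
  }
  if (test == "permutation") {
    obs <- abs(mean(x) - mean(y))
    pool <- c(x, y)
    n <- length(x)
    combs <- choose(length(pool), n)
    if (combs <= 1e5) {
      idx <- utils::combn(length(pool), n)
      stat <- apply(idx, 2, function(i) {
        abs(mean(pool[i]) - mean(pool[-i]))
      })
    } else {
      stat <- replicate(n_perm, {
        i <- sample.int(length(pool), n)
        abs(mean(pool[i]) - mean(pool[-i]))
      })
    }
    return(mean(stat >= obs - 1e-12))
  }
  stats::t.test(x, y, var.equal = (test == "student"))$p.value
}

#' Read a cell-count table from CSV
#' @param path CSV with columns condition, timepoint_h, replicate, count.
#' @export
read_cell_counts <- function(path) {
  validate_cell_table(utils::read.csv(path))
}

#' Write a cell-count table to CSV
#' @param table the table.
#' @param path output path.
#' @export
write_cell_counts <- function(table, path) {
  validate_cell_table(table)
  utils::write.csv(table, path, row.names = FALSE)
}

#' Full survival report for a cell-count table
#'
#' @param table cell-count table.
#' @param test significance test passed to [compare_conditions()].
#' @return data.frame with one row per timepoint: survival fraction, SEM
#'   and p-value.
#' @export
cell_report <- function(table, test = "student") {
  validate_cell_table(table)
  tps <- sort(unique(table$timepoint_h))
  do.call(rbind, lapply(tps, function(tp) {
    sf <- survival_fraction(table, tp)
    data.frame(timepoint_h = tp, survival_fraction = sf$fraction,
               sem = sf$sem,
               p_value = compare_conditions(table, tp, test = test))
  }))
}
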