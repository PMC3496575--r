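# Delimited-file interface: readers for per-hypothesis statistics or raw
# observation matrices, and writers for the per-hypothesis analysis table
# plus a JSON run summary.

#' Read a per-hypothesis statistics table
#'
#' Reads a TSV with columns `id`, `z1`, `z2`, `n1`, `n2` (header required;
#' `z2` may be `NA` for hypotheses without second-stage data).
#'
#' @param path Path to the TSV file.
#'
#' @return A [two_stage_dataset()].
#' @export
read_stats_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "z1", "z2", "n1", "n2")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop(sprintf("statistics table %s lacks column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (length(unique(tab$n1)) != 1L || length(unique(tab$n2)) != 1L) {
    stop("per-stage sample sizes must be shared by all hypotheses",
         call. = FALSE)
  }
  two_stage_dataset(tab$z1, tab$z2, tab$n1[1], tab$n2[1], ids = tab$id)
}

#' Read raw per-observation stage matrices
#'
#' Reads two TSV matrices (rows = hypotheses keyed by an `id` column,
#' remaining columns = observations; stage-2 rows may be missing for
#' non-selected hypotheses) and converts them into a [two_stage_dataset()]
#' via stage-wise t-tests with the normal approximation: the standardized
#' mean is reconstructed as \eqn{\Phi^{-1}(1 - p/2)\,\mathrm{sign}} from the
#' two-sided t-test p-value of each stage.
#'
#' @param stage1_path,stage2_path Paths to the stage TSV files.
#'
#' @return A [two_stage_dataset()] (with `z2 = NA` where stage-2 rows are
#'   absent).
#' @export
read_stage_matrices <- function(stage1_path, stage2_path) {
  read_mat <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!"id" %in% names(tab)) {
      stop(sprintf("%s lacks an `id` column", path), call. = FALSE)
    }
    if (anyDuplicated(tab$id)) {
      stop(sprintf("%s has duplicated hypothesis ids", path), call. = FALSE)
    }
    tab
  }
  s1 <- read_mat(stage1_path)
  s2 <- read_mat(stage2_path)
  unknown <- setdiff(s2$id, s1$id)
  if (length(unknown)) {
    stop(sprintf("stage-2 ids absent from stage 1: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  z_from_row <- function(x) {
    x <- x[is.finite(x)]
    p <- p_from_samples_tapprox(x)
    sign(mean(x)) * stats::qnorm(1 - min(p, 1 - 1e-16) / 2)
  }
  x1 <- as.matrix(s1[, setdiff(names(s1), "id"), drop = FALSE])
  z1 <- apply(x1, 1, z_from_row)
  n1 <- ncol(x1)
  x2 <- as.matrix(s2[, setdiff(names(s2), "id"), drop = FALSE])
  z2 <- rep(NA_real_, nrow(s1))
  z2[match(s2$id, s1$id)] <- apply(x2, 1, z_from_row)
  two_stage_dataset(z1, z2, n1, ncol(x2), ids = s1$id)
}

#' Full two-stage analysis of a dataset
#'
#' Runs the interim selection and the requested final analyses on a dataset
#' and assembles the per-hypothesis result table and a run summary.
#'
#' @param data A [two_stage_dataset()].
#' @param rule A [selection_rule()].
#' @param alpha Overall FDR level.
#' @param approach `"integrated"`, `"pilot"` or `"both"`.
#' @param settings Integration settings.
#'
#' @return A list of class `"two_stage_analysis"`:
#'   \describe{
#'     \item{table}{`data.frame` with columns `id`, `p1`, `p2`,
#'       `p_sequential`, `selected`, `rejected_integrated`, `rejected_pilot`
#'       (the p/rejection columns present for the approaches run).}
#'     \item{summary}{list with m, m2, gamma1_effective, stopped and per
#'       approach R (and V, S when truth labels exist).}
#'   }
#' @export
analyze_two_stage <- function(data, rule, alpha = 0.05,
                              approach = c("both", "integrated", "pilot"),
                              settings = quad_settings()) {
  approach <- match.arg(approach)
  stopifnot(inherits(data, "two_stage_dataset"))
  p1 <- two_sided_p_from_z(data$z1)
  tab <- data.frame(id = data$ids, p1 = p1,
                    p2 = ifelse(is.finite(data$z2),
                                2 * stats::pnorm(-abs(data$z2)), NA_real_),
                    stringsAsFactors = FALSE)
  summary <- list(m = data$m, alpha = alpha, rule = rule$kind,
                  rule_params = rule[setdiff(names(rule), "kind")],
                  approach = approach)
  fa_ref <- NULL
  if (approach %in% c("both", "integrated")) {
    fa <- run_integrated(data, rule, alpha, settings)
    tab$p_sequential <- if (fa$stopped) NA_real_ else fa$final_p
    tab$rejected_integrated <- seq_len(data$m) %in% fa$rejected
    summary$integrated <- list(R = fa$R, V = fa$V, S = fa$S)
    fa_ref <- fa
  }
  if (approach %in% c("both", "pilot")) {
    fa <- run_pilot(data, rule, alpha)
    tab$rejected_pilot <- seq_len(data$m) %in% fa$rejected
    summary$pilot <- list(R = fa$R, V = fa$V, S = fa$S)
    if (is.null(fa_ref)) fa_ref <- fa
  }
  tab$selected <- fa_ref$selection$selected
  summary$m2 <- fa_ref$m2
  summary$gamma1_effective <- fa_ref$gamma1_effective
  summary$stopped <- fa_ref$stopped
  structure(list(table = tab, summary = summary),
            class = "two_stage_analysis")
}

#' @export
print.two_stage_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Two-stage analysis (%s rule): m = %d, m2 = %d%s\n",
              s$rule, s$m, s$m2,
              if (isTRUE(s$stopped)) ", stopped at interim" else ""))
  for (ap in c("integrated", "pilot")) {
    if (!is.null(s[[ap]])) cat(sprintf("  %s: R = %d\n", ap, s[[ap]]$R))
  }
  invisible(x)
}

#' Write an analysis result to disk
#'
#' Writes the per-hypothesis table as TSV and the run summary as JSON.
#'
#' @param result A `"two_stage_analysis"` from [analyze_two_stage()].
#' @param table_path Output TSV path.
#' @param summary_path Output JSON path (optional).
#'
#' @return Invisibly, the paths written.
#' @export
write_analysis <- function(result, table_path, summary_path = NULL) {
  stopifnot(inherits(result, "two_stage_analysis"))
  utils::write.table(result$table, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(summary_path)) {
    jsonlite::write_json(result$summary, summary_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  invisible(c(table_path, summary_path))
}
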