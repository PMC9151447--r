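#' Build a category-by-group contingency table
#'
#' Cross-tabulates a clinical variable against a grouping variable. Missing
#' entries (NA or any label in \code{missingLabels}, case-insensitive) are
#' tallied separately and excluded from the counts.
#'
#' @param metadata data.frame of per-sample labels.
#' @param variable column name of the categorical variable.
#' @param group column name of the grouping variable (e.g. ancestry).
#' @param missingLabels values treated as missing.
#' @return list with \code{table} (integer matrix, categories x groups) and
#'   \code{excludedMissing} (count of omitted samples).
#' @export
buildContingencyTable <- function(metadata, variable, group,
                                  missingLabels = c("Missing", "Unknown",
                                                    "NA")) {
  if (!variable %in% names(metadata) || !group %in% names(metadata))
    stop("variable or group not found in metadata", call. = FALSE)
  v <- as.character(metadata[[variable]])
  g <- as.character(metadata[[group]])
  isMissing <- function(x) is.na(x) | tolower(x) %in% tolower(missingLabels)
  miss <- isMissing(v) | isMissing(g)
  tab <- table(v[!miss], g[!miss])
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("fewer than 2 categories or 2 groups after missing exclusion",
         call. = FALSE)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  list(table = m, excludedMissing = sum(miss))
}

#' Pearson chi-squared test of independence
#'
#' Uncorrected Pearson statistic \eqn{\sum (O-E)^2/E} with
#' \eqn{E = row \cdot col / N}, df = (r-1)(c-1), upper-tail p-value. Errors
#' on a structural zero margin (expected cell of 0).
#'
#' @param table integer matrix of counts, or the list returned by
#'   [buildContingencyTable()].
#' @return list with \code{statistic}, \code{df}, \code{p.value}.
#' @export
chiSquaredTest <- function(table) {
  if (is.list(table)) table <- table$table
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("structural zero margin: expected cell of 0", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = unname(ct$p.value))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted q-values with enforced monotonicity, capped at 1, in the
#' order of the input vector.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values aligned with \code{p}.
#' @export
bhAdjust <- function(p) {
  .assertProb(p)
  stats::p.adjust(p, method = "BH")
}

#' Demographic association tests over several variables
#'
#' Runs [buildContingencyTable()] + [chiSquaredTest()] for each variable
#' against the grouping column and BH-adjusts the p-values.
#'
#' @param metadata per-sample metadata.
#' @param variables character vector of variable columns.
#' @param group grouping column.
#' @return data.frame with variable, statistic, df, p, q, excluded_missing.
#' @export
cohortAssociationTests <- function(metadata,
                                   variables = c("age_group",
                                                 "tumor_location", "stage",
                                                 "msi_status"),
                                   group = "ancestry") {
  rows <- lapply(variables, function(v) {
    tab <- buildContingencyTable(metadata, v, group)
    ts <- chiSquaredTest(tab)
    data.frame(variable = v, statistic = ts$statistic, df = ts$df,
               p = ts$p.value, excluded_missing = tab$excludedMissing,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bhAdjust(out$p)
  out[, c("variable", "statistic", "df", "p", "q", "excluded_missing")]
}
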