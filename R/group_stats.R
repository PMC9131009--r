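#' Contingency table of CA1 gamma participation
#'
#' Builds the 2x2 table comparing two cohort groups on whether slices with
#' CA3 gamma oscillations also exhibit coincident CA1 gamma. Slices failing
#' CA3 QC are excluded from both margins (only CA3-positive slices enter the
#' analysis).
#'
#' @param slice_metrics Data frame with one row per slice per region carrying
#'   at least `slice_id`, `region` (`CA3`/`CA1`), `qc_pass`, and the grouping
#'   column.
#' @param group_col Name of the grouping column (e.g. `"genotype"`).
#' @param groupA,groupB The two group levels to compare (rows of the table).
#' @return `gp_contingency`: 2x2 integer matrix (rows = groups, cols =
#'   `CA1_yes` / `CA1_no`) with attributes naming rows and outcome.
#' @export
participation_table <- function(slice_metrics, group_col = "genotype",
                                groupA = "control", groupB = "mutant") {
  stopifnot(is.data.frame(slice_metrics),
            all(c("slice_id", "region", "qc_pass", group_col) %in%
                  names(slice_metrics)))
  count_group <- function(g) {
    sm <- slice_metrics[slice_metrics[[group_col]] == g, , drop = FALSE]
    if (!nrow(sm)) stop(sprintf("no slices in group '%s'", g))
    ca3 <- sm[sm$region == "CA3", c("slice_id", "qc_pass")]
    ca1 <- sm[sm$region == "CA1", c("slice_id", "qc_pass")]
    ids <- ca3$slice_id[ca3$qc_pass]          # CA3-positive slices only
    if (!length(ids)) stop(sprintf("group '%s' has no CA3-positive slices", g))
    yes <- sum(ca1$qc_pass[match(ids, ca1$slice_id)], na.rm = TRUE)
    c(yes = yes, no = length(ids) - yes)
  }
  tab <- rbind(count_group(groupA), count_group(groupB))
  contingency_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                  row_labels = c(groupA, groupB),
                  outcome = "coincident CA1 gamma")
}

#' Construct a labelled 2x2 contingency table
#'
#' @param a,b Counts for the first group (outcome yes / no).
#' @param c,d Counts for the second group (outcome yes / no).
#' @param row_labels Length-2 character vector naming the groups.
#' @param outcome Label for the outcome variable.
#' @return `gp_contingency` matrix.
#' @export
contingency_2x2 <- function(a, b, c, d, row_labels = c("A", "B"),
                            outcome = "outcome") {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) < 1) stop("grand total must be at least 1")
  m <- matrix(as.integer(counts), nrow = 2, byrow = TRUE,
              dimnames = list(row_labels, c("yes", "no")))
  structure(m, class = c("gp_contingency", "matrix", "array"),
            outcome = outcome)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Shortcut formula `chi2 = N (ad - bc)^2 / (r1 r2 c1 c2)` with 1 degree of
#' freedom; the optional Yates continuity correction subtracts N/2 from
#' `|ad - bc|` first. The correction is off by default: the participation
#' p-values printed in the source figures are reproduced from the legend
#' counts only without it.
#'
#' @param tab A `gp_contingency` (or plain 2x2 matrix of counts).
#' @param correction Apply Yates continuity correction.
#' @return List with `chi2`, `df = 1`, `p`.
#' @export
chi_square_2x2 <- function(tab, correction = FALSE) {
  m <- unclass(tab)
  stopifnot(is.matrix(m), all(dim(m) == c(2L, 2L)))
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  N <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0))
    stop("chi-square undefined: a table margin is zero")
  num <- abs(a * d - b * c)
  if (correction) num <- max(0, num - N / 2)
  chi2 <- N * num^2 / (r1 * r2 * c1 * c2)
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Does a p-value round to a printed value?
#'
#' Helper encoding the rounding contract used when comparing full-precision
#' p-values with values printed to a fixed number of decimals.
#'
#' @param p Numeric p-value.
#' @param printed The printed value (e.g. 0.03).
#' @param digits Decimals the printed value carries.
#' @return Logical.
#' @export
rounds_to <- function(p, printed, digits = nchar(sub("^[^.]*\\.?", "",
                                                     format(printed)))) {
  round(p, digits) == printed
}

#' Group participation summary
#'
#' Per-group counts and percentage of CA3-positive slices with coincident CA1
#' gamma, plus the chi-square comparison, as one tidy row set.
#'
#' @param tab A `gp_contingency` from [participation_table()].
#' @param correction Passed to [chi_square_2x2()].
#' @return Data frame with one row per group: `group`, `n_slices`,
#'   `n_ca1_coincident`, `percent`, `chi2`, `p` (test values repeated on both
#'   rows; `NA` when a zero margin makes the test undefined).
#' @export
participation_summary <- function(tab, correction = FALSE) {
  ct <- tryCatch(chi_square_2x2(tab, correction), error = function(e) {
    warning(conditionMessage(e))
    list(chi2 = NA_real_, p = NA_real_)
  })
  data.frame(group = rownames(tab),
             n_slices = as.integer(rowSums(tab)),
             n_ca1_coincident = as.integer(tab[, "yes"]),
             percent = 100 * tab[, "yes"] / rowSums(tab),
             chi2 = ct$chi2, p = ct$p,
             row.names = NULL, stringsAsFactors = FALSE)
}
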