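#' Multi-expert grade table
#'
#' Wraps a data frame with an `image_id` column and one integer column per
#' expert holding ordinal grades on the 5-level scale (1 = Normal,
#' 2 = pre-Plus, 3 = Plus1, 4 = Plus2, 5 = Plus3). Missing grades are allowed
#' as `NA` and are excluded pairwise downstream.
#'
#' @param df data frame with `image_id` plus expert columns.
#' @param n_levels number of ordinal levels (default 5).
#' @return A `grade_table` (data frame subclass).
#' @export
grade_table <- function(df, n_levels = 5) {
  if (!"image_id" %in% names(df)) pq_stop("grade table needs an image_id column")
  experts <- setdiff(names(df), "image_id")
  if (length(experts) < 1) pq_stop("grade table needs at least one expert column")
  for (e in experts) {
    g <- df[[e]]
    if (!all(is.na(g) | (g == round(g) & g >= 1 & g <= n_levels)))
      pq_stop(sprintf("grades in column %s must be integers in 1..%d", e, n_levels))
    df[[e]] <- as.integer(g)
  }
  structure(df, experts = experts, n_levels = n_levels,
            class = c("grade_table", "data.frame"))
}

#' @rdname grade_table
#' @param path CSV path with `image_id` and expert columns.
#' @export
read_grade_table <- function(path, n_levels = 5) {
  grade_table(read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
              n_levels = n_levels)
}

grade_matrix <- function(table) {
  as.matrix(as.data.frame(table)[, attr(table, "experts"), drop = FALSE])
}

#' Reference standard diagnosis (majority grade) for one image
#'
#' Strict-majority mode of the grades. Ties cannot reproduce the group
#' adjudication sessions used with human panels, so they are flagged and
#' resolved by a deterministic, configurable rule (default: round-half-up of
#' the mean grade).
#'
#' @param grades integer grades for one image (NAs dropped).
#' @param tie_rule `"round_mean"` (round-half-up of the mean), `"min"` or
#'   `"max"` (smallest/largest modal grade).
#' @return List with `rsd` (integer) and `tie` (logical flag).
#' @export
compute_rsd <- function(grades, tie_rule = c("round_mean", "min", "max")) {
  tie_rule <- match.arg(tie_rule)
  g <- grades[!is.na(grades)]
  if (length(g) < 2) pq_stop("need at least 2 grades")
  tab <- table(g)
  top <- as.integer(names(tab)[tab == max(tab)])
  if (length(top) == 1)
    return(list(rsd = top, tie = FALSE))
  rsd <- switch(tie_rule,
                round_mean = as.integer(floor(mean(g) + 0.5)), # round half up
                min = min(top),
                max = max(top))
  list(rsd = rsd, tie = TRUE)
}

#' Average severity score of one image
#'
#' Arithmetic mean of the present grades — the continuous training target of
#' the severity regression.
#'
#' @param grades integer grades (NAs dropped).
#' @return Mean score in `[1, 5]`.
#' @export
average_score <- function(grades) {
  g <- grades[!is.na(grades)]
  if (!length(g)) pq_stop("no grades")
  mean(g)
}

#' Collapse 5-level grades to the conventional 3-level scale
#'
#' `1 -> 1` (Normal), `2 -> 2` (pre-Plus), `3/4/5 -> 3` (aggregated Plus).
#'
#' @param grade integer grade(s) in 1..5 (NA passed through).
#' @return Integer grade(s) in 1..3.
#' @export
collapse_3level <- function(grade) {
  ok <- is.na(grade) | (grade %in% 1:5)
  if (!all(ok)) pq_stop("grades must be in 1..5")
  out <- ifelse(grade >= 3, 3L, as.integer(grade))
  out
}

#' Linearly weighted Cohen's kappa
#'
#' `kappa = 1 - sum(w * O) / sum(w * E)` with linear weights
#' `w[i,j] = |i - j| / (n_levels - 1)`, observed proportions `O` and expected
#' proportions `E` from the outer product of the marginals (population
#' proportions, the standard Cohen formulation). Pairs with a missing grade
#' are dropped.
#'
#' @param a,b integer grade vectors of equal length.
#' @param n_levels number of ordinal levels.
#' @return Kappa in `[-1, 1]`; 1 when both raters are constant and equal
#'   (zero expected disagreement).
#' @export
weighted_kappa_linear <- function(a, b, n_levels = 5) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2) pq_stop("need at least 2 paired grades")
  if (!all(c(a, b) %in% seq_len(n_levels)))
    pq_stop("grades outside 1..n_levels")
  n <- length(a)
  O <- table(factor(a, levels = seq_len(n_levels)),
             factor(b, levels = seq_len(n_levels))) / n
  E <- outer(rowSums(O), colSums(O))
  w <- abs(outer(seq_len(n_levels), seq_len(n_levels), "-")) / (n_levels - 1)
  denom <- sum(w * E)
  if (denom == 0) return(1) # both constant and equal: perfect agreement
  1 - sum(w * O) / denom
}

#' Agreement and per-rater loss report for a grade table
#'
#' Pairwise linearly weighted kappas between experts, each expert's kappa
#' against the RSD, and each expert's MSE/MAE against the per-image average
#' score.
#'
#' @param table a [grade_table()].
#' @param n_levels number of levels.
#' @param tie_rule RSD tie rule, see [compute_rsd()].
#' @return `agreement_report`: list with `pairwise_kappa` (matrix),
#'   `kappa_vs_rsd`, `mse_vs_avg`, `mae_vs_avg` (named vectors), `rsd`,
#'   `avg_score`, `tie_flag` (per image) and `low_n` flag.
#' @export
rater_losses <- function(table, n_levels = attr(table, "n_levels"),
                         tie_rule = "round_mean") {
  g <- grade_matrix(table)
  experts <- colnames(g)
  n_img <- nrow(g)
  rsd_list <- apply(g, 1, function(r) compute_rsd(r, tie_rule = tie_rule))
  rsd <- vapply(rsd_list, `[[`, integer(1), "rsd")
  tie <- vapply(rsd_list, `[[`, logical(1), "tie")
  avg <- apply(g, 1, average_score)
  K <- matrix(NA_real_, length(experts), length(experts),
              dimnames = list(experts, experts))
  for (i in seq_along(experts)) {
    K[i, i] <- 1
    for (j in seq_along(experts)) {
      if (j <= i) next
      K[i, j] <- K[j, i] <- weighted_kappa_linear(g[, i], g[, j], n_levels)
    }
  }
  kap_rsd <- vapply(experts, function(e)
    weighted_kappa_linear(g[, e], rsd, n_levels), numeric(1))
  mse <- vapply(experts, function(e) mean((g[, e] - avg)^2, na.rm = TRUE),
                numeric(1))
  mae <- vapply(experts, function(e) mean(abs(g[, e] - avg), na.rm = TRUE),
                numeric(1))
  if (n_img < 2) pq_warn("single-image table: losses computed but low-n")
  structure(list(pairwise_kappa = K, kappa_vs_rsd = kap_rsd,
                 mse_vs_avg = mse, mae_vs_avg = mae,
                 rsd = rsd, avg_score = avg, tie_flag = tie,
                 low_n = n_img < 2),
            class = "agreement_report")
}

#' Write an agreement report to CSV + JSON
#'
#' @param report an `agreement_report`.
#' @param path base path (without extension).
#' @export
write_agreement_report <- function(report, path) {
  write.csv(as.data.frame(report$pairwise_kappa),
            paste0(path, "_pairwise_kappa.csv"))
  per <- data.frame(expert = names(report$kappa_vs_rsd),
                    kappa_vs_rsd = report$kappa_vs_rsd,
                    mse_vs_avg = report$mse_vs_avg,
                    mae_vs_avg = report$mae_vs_avg)
  write.csv(per, paste0(path, "_per_expert.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(pairwise_kappa = report$pairwise_kappa,
         kappa_vs_rsd = as.list(report$kappa_vs_rsd),
         mse_vs_avg = as.list(report$mse_vs_avg),
         mae_vs_avg = as.list(report$mae_vs_avg),
         rsd = report$rsd, avg_score = report$avg_score,
         tie_flag = report$tie_flag),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
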