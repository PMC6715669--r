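# Downstream stages: RIP-Seq consensus intersection, paired group
# comparison, and biomarker ROC.

#' Consensus methylated-miRNA calls across RIP-Seq samples
#'
#' Per sample, a miRNA is called methylated iff its IP channel reaches
#' `min_rpm` reads per million AND the IP/input RPM enrichment reaches
#' `min_enrichment` (input RPM floored at `input_floor` to avoid division
#' by zero).  Both thresholds are deliberately required arguments: the
#' methylation-call criterion is an explicit analysis choice, not a silent
#' default.  Reports per-sample sets, Venn counts over every non-empty
#' sample subset, and the full intersection — the consensus set of miRNAs
#' methylated in all samples.
#'
#' @param tables Named list of per-sample counts data frames, each with
#'   columns `mirna`, `ip`, `input` (non-negative integer read counts).
#' @param min_rpm Minimum IP RPM.
#' @param min_enrichment Minimum IP/input RPM ratio.
#' @param input_floor RPM floor for the input channel (default 0.5).
#' @return List of class `consensus_calls`: `per_sample` (named list of
#'   character vectors), `intersection`, `venn` (named integer vector of
#'   exclusive region counts, names like `"s1&s2"`).
#' @export
consensus_methylated <- function(tables, min_rpm, min_enrichment,
                                 input_floor = 0.5) {
  if (!length(tables)) stop("need at least one sample", call. = FALSE)
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- paste0("sample", seq_along(tables))
  }
  per_sample <- lapply(names(tables), function(nm) {
    tb <- tables[[nm]]
    if (!all(c("mirna", "ip", "input") %in% names(tb))) {
      stop("sample '", nm, "' lacks a required channel column ",
           "(need mirna, ip, input)", call. = FALSE)
    }
    if (any(tb$ip < 0) || any(tb$input < 0) ||
        any(tb$ip != round(tb$ip)) || any(tb$input != round(tb$input))) {
      stop("counts must be non-negative integers (sample '", nm, "')",
           call. = FALSE)
    }
    lib_ip <- sum(tb$ip); lib_in <- sum(tb$input)
    if (lib_ip == 0 || lib_in == 0) {
      stop("zero library size in sample '", nm, "'", call. = FALSE)
    }
    rpm_ip <- tb$ip / lib_ip * 1e6
    rpm_in <- tb$input / lib_in * 1e6
    call <- rpm_ip >= min_rpm &
      rpm_ip / pmax(rpm_in, input_floor) >= min_enrichment
    sort(unique(tb$mirna[call]))
  })
  names(per_sample) <- names(tables)
  inter <- Reduce(intersect, per_sample)
  universe <- sort(unique(unlist(per_sample)))
  membership <- vapply(per_sample, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1)
  venn <- integer(0)
  if (length(universe)) {
    key <- apply(membership, 1, function(m) {
      paste(names(per_sample)[m], collapse = "&")
    })
    venn <- vapply(split(seq_along(key), key), length, integer(1))
  }
  structure(list(per_sample = per_sample, intersection = inter,
                 venn = venn),
            class = "consensus_calls")
}

#' @export
print.consensus_calls <- function(x, ...) {
  cat("<consensus_calls>\n")
  for (nm in names(x$per_sample)) {
    cat(sprintf("  %s: %d called\n", nm, length(x$per_sample[[nm]])))
  }
  cat(sprintf("  intersection: %d miRNA(s)\n", length(x$intersection)))
  invisible(x)
}

#' Paired comparison of case vs control methylation fractions
#'
#' Closed-form paired t-test on within-pair differences (case - control):
#' t = mean(d) / (sd(d) / sqrt(n)), df = n - 1, two-sided p from the t
#' distribution.  Zero variance of differences is reported as t = 0 /
#' p = 1 when the mean difference is also 0, and as infinite t / p = 0
#' otherwise (degenerate complete-separation convention).  A Wilcoxon
#' signed-rank alternative is available behind `method`.
#'
#' @param table A cohort data frame with columns `group`
#'   (`"case"`/`"control"`), `pair_id`, and the value column.
#' @param value Name of the value column (default `"fraction"`).
#' @param method `"t"` (default) or `"wilcoxon"`.
#' @return List: `statistic`, `df` (t only), `p_value`, `n_pairs`,
#'   `mean_difference`, `method`.
#' @export
paired_test <- function(table, value = "fraction", method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  stopifnot(all(c("group", "pair_id", value) %in% names(table)))
  cases <- table[table$group == "case", c("pair_id", value)]
  ctrls <- table[table$group == "control", c("pair_id", value)]
  if (anyDuplicated(cases$pair_id) || anyDuplicated(ctrls$pair_id)) {
    stop("a pair_id appears more than once within a group", call. = FALSE)
  }
  ids <- intersect(cases$pair_id, ctrls$pair_id)
  if (length(ids) < 2) stop("paired test needs >= 2 complete pairs",
                            call. = FALSE)
  d <- cases[[value]][match(ids, cases$pair_id)] -
    ctrls[[value]][match(ids, ctrls$pair_id)]
  n <- length(d)
  if (method == "wilcoxon") {
    wt <- suppressWarnings(stats::wilcox.test(d, exact = FALSE))
    return(list(statistic = unname(wt$statistic), df = NA_real_,
                p_value = wt$p.value, n_pairs = n,
                mean_difference = mean(d), method = "wilcoxon"))
  }
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(mean(d)) * Inf; p <- 0
    }
  } else {
    t_stat <- mean(d) / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  list(statistic = t_stat, df = n - 1, p_value = p, n_pairs = n,
       mean_difference = mean(d), method = "t")
}

#' ROC curve and AUC for a cohort biomarker
#'
#' AUC by the Mann-Whitney identity with tie correction (a tied
#' case/control pair counts one half), computed from mid-ranks; ROC points
#' are produced at every distinct threshold (classify positive when value
#' >= threshold).  Missing marker values are treated as below the
#' detection limit and set to 0.
#'
#' @param table Cohort data frame with a `group` column
#'   (`"case"`/`"control"`).
#' @param marker Name of the value column (default `"fraction"`).
#' @return List of class `roc_result`: `auc`, `points` (data frame with
#'   `threshold`, `fpr`, `tpr`), `n_case`, `n_control`.
#' @export
roc_auc <- function(table, marker = "fraction") {
  stopifnot(all(c("group", marker) %in% names(table)))
  vals <- table[[marker]]
  vals[is.na(vals)] <- 0   # below the detection limit reported as zero
  is_case <- table$group == "case"
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(vals)   # mid-ranks handle ties (tied pairs count 1/2)
  auc <- (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thresholds <- sort(unique(vals), decreasing = TRUE)
  pts <- data.frame(threshold = c(Inf, thresholds),
                    fpr = NA_real_, tpr = NA_real_)
  for (i in seq_len(nrow(pts))) {
    pos <- vals >= pts$threshold[i]
    pts$tpr[i] <- sum(pos & is_case) / n1
    pts$fpr[i] <- sum(pos & !is_case) / n0
  }
  structure(list(auc = auc, points = pts, n_case = n1, n_control = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d cases vs %d controls)\n",
              x$auc, x$n_case, x$n_control))
  invisible(x)
}

#' Read a TSV counts or cohort table
#'
#' Plain tab-separated tables with a header row; convenience wrapper used
#' by the command-line interface.
#'
#' @param path TSV file.
#' @return Data frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
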