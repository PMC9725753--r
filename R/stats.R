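#' Significance stars for a p-value
#'
#' The reporting convention used throughout the package: \code{ns} for p >=
#' 0.01, \code{**} for p < 0.01, \code{***} for p < 0.001 and \code{****}
#' for p < 0.0001.
#'
#' @param p p-value(s) in [0, 1].
#' @return character vector of star annotations.
#' @export
significanceStars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < 1e-4, "****", ifelse(p < 1e-3, "***",
         ifelse(p < 1e-2, "**", "ns")))
}

.checkGroups <- function(groups) {
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list of numeric vectors")
  if (any(vapply(groups, length, integer(1)) == 0))
    stop("every group must be non-empty")
  invisible(groups)
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' Omnibus F test across conditions followed by all pairwise comparisons
#' adjusted with Tukey's honestly-significant-difference procedure
#' (studentized range distribution) — the test used for every multi-group
#' comparison in the scoring pipeline. A dataset with zero total variance
#' returns F = 0, p = 1 by convention.
#'
#' @param groups named list: condition label -> numeric vector of per-cell
#'   values.
#' @return list of class \code{"StatResult"}: \code{test}, \code{statistic}
#'   (F), \code{df}, \code{p.value}, \code{pairwise} (data.frame comparison,
#'   diff, p.adj, stars), \code{stars}.
#' @export
anovaTukey <- function(groups) {
  .checkGroups(groups)
  if (length(groups) < 2) stop("ANOVA needs at least 2 conditions")
  n <- vapply(groups, length, integer(1))
  if (sum(n) < 3) stop("need at least 3 observations in total")
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    condition = factor(rep(names(groups), n), levels = names(groups)))
  if (var(df$value) == 0) {
    pw <- t(combn(names(groups), 2))
    pairwise <- data.frame(
      comparison = paste(pw[, 2], pw[, 1], sep = "-"),
      diff = 0, p.adj = 1, stars = "ns")
    return(structure(list(test = "one-way ANOVA + Tukey HSD",
                          statistic = 0, df = c(length(groups) - 1,
                                                sum(n) - length(groups)),
                          p.value = 1, pairwise = pairwise, stars = "ns"),
                     class = "StatResult"))
  }
  fit <- aov(value ~ condition, data = df)
  s <- summary(fit)[[1]]
  Fval <- s[["F value"]][1]
  p <- s[["Pr(>F)"]][1]
  tk <- TukeyHSD(fit)$condition
  pairwise <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                         p.adj = tk[, "p adj"],
                         stars = significanceStars(pmin(pmax(
                           tk[, "p adj"], 0), 1)))
  rownames(pairwise) <- NULL
  structure(list(test = "one-way ANOVA + Tukey HSD", statistic = Fval,
                 df = c(s$Df[1], s$Df[2]), p.value = p, pairwise = pairwise,
                 stars = significanceStars(p)),
            class = "StatResult")
}

#' Two-tailed two-sample t test
#'
#' Classical Student's t test (equal variances pooled by default; Welch with
#' \code{welch = TRUE}), two-sided — the test used when exactly two
#' conditions are compared.
#'
#' @param a,b numeric samples of size >= 2.
#' @param welch use the Welch unequal-variance form.
#' @return list of class \code{"StatResult"}: \code{test}, \code{statistic}
#'   (t), \code{df}, \code{p.value}, \code{stars}.
#' @export
tTestTwoTailed <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 observations")
  ht <- t.test(a, b, var.equal = !welch, alternative = "two.sided")
  structure(list(test = ht$method, statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p.value = ht$p.value,
                 stars = significanceStars(ht$p.value)),
            class = "StatResult")
}

#' @export
print.StatResult <- function(x, ...) {
  cat(x$test, "\n")
  cat(sprintf("  statistic = %.6g, df = %s, p = %.4g (%s)\n", x$statistic,
              paste(signif(x$df, 6), collapse = ", "), x$p.value, x$stars))
  if (!is.null(x$pairwise)) {
    cat("  pairwise (Tukey-adjusted):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Per-condition summary for violin-style reporting
#'
#' n, median and quartiles (linear-interpolation convention, type 7) per
#' condition — the values drawn as the bold and peripheral lines of a violin
#' plot.
#'
#' @param groups named list: condition -> numeric vector.
#' @return data.frame with condition, n, median, q1, q3.
#' @export
summarizeGroups <- function(groups) {
  .checkGroups(groups)
  do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(condition = g, n = length(v), median = q[2], q1 = q[1],
               q3 = q[3])
  }))
}

#' LFQ enrichment ranking between two conditions
#'
#' Averages label-free-quantitation intensities over technical replicates
#' per condition, forms the WT/MUT enrichment ratio per protein, and ranks
#' proteins by descending ratio; proteins with equal means sit on the
#' equivalent-enrichment diagonal (ratio 1). Missing intensities (NA or 0)
#' are floor-imputed at half the smallest positive intensity in the table
#' and the protein is flagged one-sided.
#'
#' @param table data.frame with a \code{protein} column and replicate
#'   intensity columns.
#' @param wtCols,mutCols names of the replicate columns for each condition.
#' @return data.frame: protein, meanWT, meanMUT, ratio, rank, oneSided;
#'   sorted by rank.
#' @export
lfqEnrichment <- function(table, wtCols, mutCols) {
  stopifnot("protein" %in% names(table),
            all(c(wtCols, mutCols) %in% names(table)))
  w <- as.matrix(table[, wtCols, drop = FALSE])
  m <- as.matrix(table[, mutCols, drop = FALSE])
  w[w == 0] <- NA; m[m == 0] <- NA
  allv <- c(w, m)
  if (all(is.na(allv))) stop("no quantified intensities in the table")
  floorv <- min(allv, na.rm = TRUE) / 2
  oneSided <- rowSums(!is.na(w)) == 0 | rowSums(!is.na(m)) == 0
  if (any(rowSums(!is.na(w)) == 0 & rowSums(!is.na(m)) == 0))
    stop("protein absent from both conditions")
  w[is.na(w)] <- floorv
  m[is.na(m)] <- floorv
  meanWT <- rowMeans(w)
  meanMUT <- rowMeans(m)
  out <- data.frame(protein = table$protein, meanWT = meanWT,
                    meanMUT = meanMUT, ratio = meanWT / meanMUT,
                    oneSided = oneSided)
  out <- out[order(-out$ratio), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
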